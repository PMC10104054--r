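## Value RNN (GRU + linear value readout, trained end-to-end by semi-gradient
## TD) and Value ESN (frozen gain-scaled orthogonal reservoir; only the
## readout learns). The training loop and batched BPTT live in src/gru.cpp;
## the plain-R gru_step() here doubles as readable documentation of the cell.

gru_param_names <- c("W_ir", "W_iu", "W_in", "W_hr", "W_hu", "W_hn",
                     "b_ir", "b_iu", "b_in", "b_hr", "b_hu", "b_hn",
                     "w", "w0")

check_gru_params <- function(params, H = NULL) {
  stopifnot(all(gru_param_names %in% names(params)))
  if (is.null(H)) H <- nrow(params$W_hr)
  for (nm in c("W_ir", "W_iu", "W_in")) {
    stopifnot(identical(dim(params[[nm]]), c(H, 2L)))
  }
  for (nm in c("W_hr", "W_hu", "W_hn")) {
    stopifnot(identical(dim(params[[nm]]), c(H, H)))
  }
  for (nm in c("b_ir", "b_iu", "b_in", "b_hr", "b_hu", "b_hn", "w")) {
    stopifnot(length(params[[nm]]) == H)
  }
  stopifnot(length(params$w0) == 1)
  invisible(H)
}

#' Default GRU initialization
#'
#' All GRU weights and biases, and the value readout, are drawn i.i.d.
#' uniform on `(-a, a)` with `a = 1/sqrt(H)`.
#'
#' @param H Hidden size.
#' @param seed Integer seed.
#' @return Named list of GRU parameters (see [gru_step()]).
#' @export
gru_init <- function(H, seed) {
  stopifnot(H >= 1)
  set.seed(seed)
  a <- 1 / sqrt(H)
  u <- function(n, m = NULL) {
    x <- stats::runif(n * max(1, m), -a, a)
    if (is.null(m)) x else matrix(x, n, m)
  }
  p <- list(W_ir = u(H, 2), W_iu = u(H, 2), W_in = u(H, 2),
            W_hr = u(H, H), W_hu = u(H, H), W_hn = u(H, H),
            b_ir = u(H), b_iu = u(H), b_in = u(H),
            b_hr = u(H), b_hu = u(H), b_hn = u(H),
            w = u(H), w0 = stats::runif(1, -a, a))
  p
}

#' Echo-state (reservoir) initialization
#'
#' Biases are zero; each gate's recurrent matrix is an independent random
#' orthogonal matrix scaled by `gain` (`Q'Q = gain^2 I` per gate), which
#' places the edge of stability at gain 2 (the null-input linearization of
#' the cell has spectral radius `0.5 + gain/4`); input weights are
#' Xavier-uniform on `(-a, a)` with `a = sqrt(6 / (2 + H))`; the value
#' readout uses the default `1/sqrt(H)` initialization. These parameters are
#' frozen during training.
#'
#' @param H Hidden size.
#' @param gain Scale of the orthogonal recurrent matrix; gains above ~2 put
#'   the reservoir past the edge of stability (transients no longer decay).
#' @param seed Integer seed.
#' @return Named list of GRU parameters.
#' @export
esn_init <- function(H, gain, seed) {
  stopifnot(H >= 1, gain > 0)
  set.seed(seed)
  rand_orth <- function() {
    qrA <- qr(matrix(stats::rnorm(H * H), H, H))
    ## sign fix makes the factor Haar-distributed
    gain * qr.Q(qrA) %*% diag(sign(diag(qr.R(qrA))), H)
  }
  a_in <- sqrt(6 / (2 + H))
  a_w <- 1 / sqrt(H)
  list(W_ir = matrix(stats::runif(2 * H, -a_in, a_in), H, 2),
       W_iu = matrix(stats::runif(2 * H, -a_in, a_in), H, 2),
       W_in = matrix(stats::runif(2 * H, -a_in, a_in), H, 2),
       W_hr = rand_orth(),
       W_hu = rand_orth(),
       W_hn = rand_orth(),
       b_ir = numeric(H), b_iu = numeric(H), b_in = numeric(H),
       b_hr = numeric(H), b_hu = numeric(H), b_hn = numeric(H),
       w = stats::runif(H, -a_w, a_w), w0 = stats::runif(1, -a_w, a_w))
}

#' Construct a value network
#'
#' @param H Hidden size.
#' @param seed Integer seed for the initialization.
#' @param type `"gru"` (all parameters trainable) or `"esn"` (recurrent,
#'   input, and bias parameters frozen; only the value readout learns).
#' @param gain ESN reservoir gain (ignored for `type = "gru"`).
#' @return A `value_rnn` object.
#' @export
value_rnn <- function(H, seed, type = c("gru", "esn"), gain = 1) {
  type <- match.arg(type)
  params <- if (type == "esn") esn_init(H, gain, seed) else gru_init(H, seed)
  structure(list(H = as.integer(H), type = type, gain = gain, seed = seed,
                 params = params, trained = FALSE, loss = NULL,
                 best_epoch = NA_integer_),
            class = "value_rnn")
}

#' @export
print.value_rnn <- function(x, ...) {
  cat(sprintf("<value_rnn> %s, H = %d%s, seed %s, %s\n",
              toupper(x$type), x$H,
              if (x$type == "esn") sprintf(", gain %.2f", x$gain) else "",
              format(x$seed),
              if (x$trained) sprintf("trained (best epoch %d of %d)",
                                     x$best_epoch, length(x$loss))
              else "untrained"))
  invisible(x)
}

#' One GRU step (reference implementation)
#'
#' Standard gated recurrent unit with reset gate
#' `sigmoid(W_ir o + b_ir + W_hr z + b_hr)`, update gate
#' `sigmoid(W_iu o + b_iu + W_hu z + b_hu)`, candidate
#' `tanh(W_in o + b_in + reset * (W_hn z + b_hn))`, and new state
#' `(1 - update) * candidate + update * z`.
#'
#' @param params Named parameter list (see [gru_init()]).
#' @param z_prev Hidden state, length `H`.
#' @param o Observation vector, length 2.
#' @return The next hidden state.
#' @export
gru_step <- function(params, z_prev, o) {
  H <- check_gru_params(params)
  if (length(z_prev) != H || length(o) != 2) stop("shape mismatch")
  sig <- function(x) 1 / (1 + exp(-x))
  r <- sig(params$W_ir %*% o + params$b_ir + params$W_hr %*% z_prev + params$b_hr)
  u <- sig(params$W_iu %*% o + params$b_iu + params$W_hu %*% z_prev + params$b_hu)
  n <- tanh(params$W_in %*% o + params$b_in +
              r * (params$W_hn %*% z_prev + params$b_hn))
  as.vector((1 - u) * n + u * z_prev)
}

#' Run a value network over a session
#'
#' Deterministic forward pass from a zero hidden state.
#'
#' @param model A `value_rnn`.
#' @param session A `cond_session` or a `T x 2` observation matrix.
#' @return List with `Z` (`T x H` hidden-state trace) and `V` (value trace
#'   from the model's own readout).
#' @export
rnn_forward <- function(model, session) {
  obs <- if (is.matrix(session)) session else session_observations(session)
  cpp_gru_forward(model$params, obs)
}

#' TD training configuration
#'
#' @param episode_len Trials per episode (20 for Starkweather, 50 for
#'   Babayan).
#' @param batch_size Episodes per gradient step.
#' @param max_epochs Epoch cap.
#' @param lr Adam learning rate.
#' @param patience Consecutive loss increases that trigger early stopping.
#' @param gamma Discount factor.
#' @param seed Seed for the per-epoch episode shuffling.
#' @return A list of class `train_config`.
#' @export
train_config <- function(episode_len = 20L, batch_size = 12L,
                         max_epochs = 150L, lr = 0.003, patience = 4L,
                         gamma = 0.93, seed = 1L) {
  stopifnot(episode_len >= 1, batch_size >= 1, max_epochs >= 1, lr >= 0,
            patience >= 1, gamma >= 0, gamma < 1)
  structure(list(episode_len = as.integer(episode_len),
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), lr = lr,
                 patience = as.integer(patience), gamma = gamma,
                 seed = as.integer(seed)),
            class = "train_config")
}

episode_bounds <- function(session, episode_len) {
  tr <- session$trial_index
  n_trials <- max(tr)
  n_ep <- n_trials %/% episode_len
  if (n_ep < 1) stop("session shorter than one episode")
  first <- match(seq_len(n_trials), tr)
  last <- length(tr) - match(seq_len(n_trials), rev(tr)) + 1L
  ep_start <- first[seq(1L, by = episode_len, length.out = n_ep)]
  ep_end <- last[seq(episode_len, by = episode_len, length.out = n_ep)]
  cbind(start = ep_start, end = ep_end)
}

#' Train a value network by semi-gradient TD
#'
#' Episodes are disjoint consecutive blocks of `episode_len` trials from the
#' session, shuffled each epoch and batched; the squared TD error (with the
#' bootstrap target held constant) is backpropagated through time and
#' parameters are updated with Adam. Training stops early after `patience`
#' consecutive epoch-loss increases, and the parameters from the best epoch
#' are retained. For ESNs only the value readout is updated.
#'
#' @param model A `value_rnn`.
#' @param session Training `cond_session`.
#' @param config A [train_config()].
#' @return The trained `value_rnn` (with `loss` history and `best_epoch`).
#' @export
train_td <- function(model, session, config = train_config()) {
  stopifnot(inherits(model, "value_rnn"), inherits(config, "train_config"))
  obs <- session_observations(session)
  eps <- episode_bounds(session, config$episode_len)
  fit <- cpp_train_td(model$params, obs,
                      matrix(as.integer(eps), ncol = 2),
                      config$gamma, config$lr, config$max_epochs,
                      config$batch_size, config$patience,
                      train_phi = model$type != "esn",
                      seed = config$seed)
  model$params <- lapply(fit$params, function(x) {
    if (is.matrix(x) || length(x) > 1) x else as.numeric(x)
  })
  ## C++ returns H x 1 matrices for the bias/readout vectors; flatten them
  for (nm in c("b_ir", "b_iu", "b_in", "b_hr", "b_hu", "b_hn", "w")) {
    model$params[[nm]] <- as.numeric(model$params[[nm]])
  }
  model$params$w0 <- as.numeric(model$params$w0)
  model$trained <- TRUE
  model$loss <- as.numeric(fit$loss)
  model$best_epoch <- fit$best_epoch
  model
}

#' Save / load a value network checkpoint (JSON)
#'
#' Flat named-array container holding the parameters, configuration fields,
#' seed, and loss history; the loader validates shapes.
#'
#' @param model A `value_rnn`.
#' @param path JSON path.
#' @export
write_value_rnn <- function(model, path) {
  jsonlite::write_json(
    list(H = model$H, type = model$type, gain = model$gain,
         seed = model$seed, trained = model$trained,
         loss = model$loss, best_epoch = model$best_epoch,
         params = model$params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_value_rnn
#' @export
read_value_rnn <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  H <- as.integer(x$H)
  p <- x$params
  for (nm in c("W_ir", "W_iu", "W_in")) {
    if (!is.matrix(p[[nm]])) p[[nm]] <- matrix(p[[nm]], H, 2, byrow = TRUE)
  }
  for (nm in c("W_hr", "W_hu", "W_hn")) {
    if (!is.matrix(p[[nm]])) p[[nm]] <- matrix(p[[nm]], H, H, byrow = TRUE)
  }
  check_gru_params(p, H)
  structure(list(H = H, type = x$type, gain = x$gain, seed = x$seed,
                 params = p, trained = isTRUE(x$trained),
                 loss = x$loss,
                 best_epoch = if (is.null(x$best_epoch)) NA_integer_
                              else x$best_epoch),
            class = "value_rnn")
}
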