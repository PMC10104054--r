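## Fixed-point identification and observation-memory durations for any
## state-update map (belief update or RNN forward map).

#' Step maps for dynamics analyses
#'
#' A step map is a function `f(z, o)` giving the next state for observation
#' `o = c(odor, reward)`. `belief_step_map()` wraps a micro-state space's
#' Bayesian update (for the Babayan task, the 2K composite update);
#' `rnn_step_map()` wraps a network's GRU cell.
#'
#' For dynamics probes the belief map is extended by continuity at states
#' where an observation has zero likelihood (e.g. a reward delivered at the
#' ITI fixed point): the posterior limit for any prior with vanishing mass on
#' the emitting states is the update applied to a uniform prior over those
#' states — for a reward this is a point mass at the ITI entry state,
#' matching the deterministic post-reward march used in the memory analyses.
#' [belief_step()] itself still treats such observations as hard errors.
#'
#' @param space A `microstate_space`.
#' @return A function `f(z, o)`.
#' @export
belief_step_map <- function(space) {
  if (space$task == "babayan") {
    K <- space$K
    function(z, o) {
      p <- sum(z[seq_len(K)])
      b1 <- if (p > 0) z[seq_len(K)] / p else {
        b <- numeric(K); b[K] <- 1; b
      }
      q <- sum(z[K + seq_len(K)])
      b2 <- if (q > 0) z[K + seq_len(K)] / q else {
        b <- numeric(K); b[K] <- 1; b
      }
      bb <- structure(list(p = p, b1 = b1, b2 = b2, K = K),
                      class = "block_belief")
      bb$b1 <- belief_step_limit(space, bb$b1, c(o[1], as.numeric(o[2] > 0)))
      bb$b2 <- belief_step_limit(space, bb$b2, c(o[1], as.numeric(o[2] > 0)))
      if (o[2] > 0) {
        bb$p <- block_likelihood(o[2], mu = space$config$block_rewards)
      }
      composite_belief(bb)
    }
  } else {
    function(z, o) belief_step_limit(space, z, o)
  }
}

## belief update extended by continuity to zero-likelihood observations
belief_step_limit <- function(space, b_prev, obs) {
  o <- classify_obs(obs)
  b <- as.vector(space$M[[o]] %*% b_prev)
  s <- sum(b)
  if (s <= 0) {
    emitting <- colSums(space$M[[o]]) > 0
    if (!any(emitting)) {
      stop(sprintf("observation '%s' is impossible from every state", o))
    }
    u <- as.numeric(emitting) / sum(emitting)
    b <- as.vector(space$M[[o]] %*% u)
    s <- sum(b)
  }
  b / s
}

#' @param model A `value_rnn`.
#' @rdname belief_step_map
#' @export
rnn_step_map <- function(model) {
  params <- model$params
  function(z, o) gru_step(params, z, o)
}

null_obs <- c(0, 0)

#' Find null-input fixed points of a step map
#'
#' From each seed state, the null observation is applied until the squared
#' step size `||z_t - z_{t-1}||^2` drops below `eps`; converged candidates
#' additionally satisfying the residual test `||f(null, z) - z||^2 < eps` are
#' merged whenever they lie within `merge_tol` of each other.
#'
#' @param step_map A function `f(z, o)`.
#' @param seed_states Matrix of starting states (one per row).
#' @param eps Convergence threshold on the squared step size (default 1e-5).
#' @param merge_tol Distance below which two candidates are considered the
#'   same fixed point (default 1e-3).
#' @param max_iter Iteration cap per seed (default 1000).
#' @param refine_tol After the `eps` criterion is met, iteration continues
#'   (within the same cap) until the squared step size falls below this much
#'   tighter tolerance, so that all seeds flowing into one attractor coincide
#'   instead of stranding as scattered slow points; marginally stable maps
#'   simply keep the `eps`-level candidate.
#' @return A `fixed_point_set`: list with `points` (matrix, one fixed point
#'   per row), `n_converged`, `n_seeds`, and the tolerances used. If no seed
#'   converges the point set is empty and a diagnostic message is attached.
#' @export
find_fixed_points <- function(step_map, seed_states, eps = 1e-5,
                              merge_tol = 1e-3, max_iter = 1000L,
                              refine_tol = 1e-14) {
  seed_states <- as.matrix(seed_states)
  stopifnot(nrow(seed_states) >= 1)
  candidates <- list()
  n_conv <- 0L
  for (i in seq_len(nrow(seed_states))) {
    z <- seed_states[i, ]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      z_new <- step_map(z, null_obs)
      step2 <- sum((z_new - z)^2)
      z <- z_new
      if (!converged && step2 < eps) converged <- TRUE
      if (step2 < refine_tol) break
    }
    if (converged && sum((step_map(z, null_obs) - z)^2) < eps) {
      n_conv <- n_conv + 1L
      candidates[[length(candidates) + 1L]] <- z
    }
  }
  pts <- list()
  for (z in candidates) {
    dup <- any(vapply(pts, function(p) sqrt(sum((p - z)^2)) < merge_tol,
                      logical(1)))
    if (!dup) pts[[length(pts) + 1L]] <- z
  }
  structure(list(points = if (length(pts)) do.call(rbind, pts)
                          else matrix(numeric(0), 0, ncol(seed_states)),
                 n_converged = n_conv, n_seeds = nrow(seed_states),
                 eps = eps, merge_tol = merge_tol,
                 diagnostic = if (n_conv == 0)
                   sprintf("no seed converged within %d null steps", max_iter)
                 else NULL),
            class = "fixed_point_set")
}

#' @export
print.fixed_point_set <- function(x, ...) {
  cat(sprintf("<fixed_point_set> %d fixed point(s) from %d/%d converged seeds (eps %.0e)\n",
              nrow(x$points), x$n_converged, x$n_seeds, x$eps))
  invisible(x)
}

#' Observation-memory duration of a step map
#'
#' Starting from a fixed point, a single odor (or reward) observation is
#' applied at `t = 1`, followed by null inputs; `eta_t = ||z_t - z_0||^2`
#' measures the distance back to the fixed point, and the memory is the first
#' `t` with `eta_t < threshold`. If the trajectory has not returned within
#' `max_steps`, `steps` is `NA` and `capped` is `TRUE` (reported as
#' "> max_steps").
#'
#' @param step_map A function `f(z, o)`.
#' @param fixed_point State vector at the fixed point.
#' @param observation `"odor"` or `"reward"`.
#' @param reward_size Magnitude used for the reward observation.
#' @param threshold Squared-distance threshold (default 1e-3).
#' @param max_steps Iteration cap (default 1000).
#' @return A `memory_duration`: list with `observation`, `steps`, `capped`,
#'   and the distance trace `eta`.
#' @export
memory_duration <- function(step_map, fixed_point,
                            observation = c("odor", "reward"),
                            reward_size = 1, threshold = 1e-3,
                            max_steps = 1000L) {
  observation <- match.arg(observation)
  stopifnot(threshold > 0)
  o <- if (observation == "odor") c(1, 0) else c(0, reward_size)
  z0 <- fixed_point
  z <- step_map(z0, o)
  eta <- numeric(max_steps)
  steps <- NA_integer_
  for (t in seq_len(max_steps)) {
    eta[t] <- sum((z - z0)^2)
    if (eta[t] < threshold) { steps <- t; break }
    z <- step_map(z, null_obs)
  }
  n <- if (is.na(steps)) max_steps else steps
  structure(list(observation = observation, steps = steps,
                 capped = is.na(steps), threshold = threshold,
                 eta = eta[seq_len(n)]),
            class = "memory_duration")
}

#' @export
print.memory_duration <- function(x, ...) {
  cat(sprintf("<memory_duration> %s memory: %s steps (threshold %.0e)\n",
              x$observation,
              if (x$capped) paste0("> ", length(x$eta)) else x$steps,
              x$threshold))
  invisible(x)
}

#' Collect post-observation seed states from a network's test activity
#'
#' Runs the model over a session and samples hidden states from the steps
#' immediately following odor or reward observations, the recommended seeding
#' for [find_fixed_points()].
#'
#' @param model A `value_rnn`.
#' @param session A `cond_session`.
#' @param n Number of seed states (default 20).
#' @param seed Optional RNG seed for the sampling.
#' @return Matrix of seed states (one per row).
#' @export
collect_seed_states <- function(model, session, n = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Z <- rnn_forward(model, session)$Z
  idx <- which(session$odor > 0 | session$reward > 0)
  idx <- pmin(idx + 1L, nrow(Z))
  take <- sample(idx, min(n, length(idx)))
  Z[take, , drop = FALSE]
}
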