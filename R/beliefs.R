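## Micro-state POMDP construction and Bayesian belief filtering.
##
## Conventions: T[k2, k1] = P(k1 -> k2); O[[obs]][k2, k1] = probability of
## observing `obs` on the transition k1 -> k2. Observations attach to
## transitions, so a belief update is b_t proportional to (O_o * T) %*% b_prev.

new_microstate_space <- function(K, Tm, O, labels, hazard, pmf, task, config) {
  M <- lapply(O, function(Oo) Oo * Tm)
  structure(list(K = K, T = Tm, O = O, M = M, labels = labels,
                 hazard = hazard, isi_pmf = pmf,
                 absorbing = K, task = task, config = config),
            class = "microstate_space")
}

#' @export
print.microstate_space <- function(x, ...) {
  cat(sprintf("<microstate_space> %s: K = %d (%d ISI + %d ITI micro-states)\n",
              x$task, x$K, sum(x$labels == "isi"), sum(x$labels == "iti")))
  invisible(x)
}

#' Reward hazard over the ISI
#'
#' `h_t = p_t / (1 - F_{t-1})`: the probability of reward at delay `t` given
#' no reward has occurred yet. At the last possible reward time the hazard
#' is 1.
#'
#' @param pmf Named probability vector over the ISI support (names are the
#'   integer delays).
#' @return Named vector of hazards over the same support.
#' @export
isi_hazard <- function(pmf) {
  Fprev <- c(0, cumsum(pmf)[-length(pmf)])
  h <- pmf / (1 - Fprev)
  h[length(h)] <- 1   # exact despite rounding
  h
}

build_space_from_config <- function(config, p_omission, reward_label = "reward") {
  n_isi <- n_isi_states(config)
  K <- n_states(config)
  iti_entry <- n_isi + 1L
  pmf <- isi_pmf(config)
  support <- config$isi_support
  h_full <- numeric(n_isi)                 # hazard indexed by ISI micro-state
  h_full[support] <- isi_hazard(pmf)

  Tm <- matrix(0, K, K)
  On <- matrix(0, K, K); Oo <- matrix(0, K, K); Orw <- matrix(0, K, K)

  for (t in seq_len(n_isi - 1L)) {         # ISI advance, hazard exit
    Tm[t + 1L, t] <- 1 - h_full[t]
    if (h_full[t] > 0) Tm[iti_entry, t] <- h_full[t]
  }
  Tm[iti_entry, n_isi] <- 1                # hazard at max delay is 1
  for (t in iti_entry:(K - 1L)) Tm[t + 1L, t] <- 1   # ITI advance
  Tm[K, K] <- 1 - config$p_iti
  Tm[1L, K] <- config$p_iti * (1 - p_omission)
  if (p_omission > 0) Tm[iti_entry, K] <- config$p_iti * p_omission

  for (t in seq_len(K - 1L)) {
    if (t != n_isi) On[t + 1L, t] <- 1     # null advance
  }
  On[K, K] <- 1                            # ITI dwell
  Oo[1L, K] <- 1                           # odor entry into the ISI
  if (p_omission > 0) Oo[iti_entry, K] <- 1   # omission odor stays in the ITI
  for (t in support) Orw[iti_entry, t] <- 1   # reward exits into the ITI

  labels <- c(rep("isi", n_isi), rep("iti", K - n_isi))
  new_microstate_space(K, Tm, list(null = On, odor = Oo, reward = Orw),
                       labels, h_full[support], pmf, config$task, config)
}

#' Build the Starkweather micro-state space
#'
#' ISI micro-states 1..14 and ITI micro-states 15..25 (K = 25). ISI states
#' advance deterministically except for the hazard exit into the first ITI
#' state on reward; the last ITI state is absorbing with odor hazard `p_iti`.
#' In Task 2, the odor transition splits between the first ISI state (prob
#' `1 - p_omission`) and the first ITI state (prob `p_omission`).
#'
#' @param variant `"task1"`, `"task2"`, or a full [starkweather_config()].
#' @return A `microstate_space`.
#' @export
build_starkweather_space <- function(variant = c("task1", "task2")) {
  config <- if (inherits(variant, "stark_config")) variant
            else starkweather_config(match.arg(variant))
  build_space_from_config(config, config$p_omission)
}

#' Build the Babayan per-block micro-state space
#'
#' One copy of the 22-state space (11 ISI + 11 ITI micro-states) used for
#' each hidden block; hazards follow the uniform ISI over \{9, 10, 11\}
#' (1/3, 1/2, 1). The composite belief concatenates the two copies weighted
#' by the block posterior (see [run_beliefs()]).
#'
#' @param config A [babayan_config()].
#' @return A `microstate_space` with `K = 22`.
#' @export
build_babayan_space <- function(config = babayan_config()) {
  stopifnot(inherits(config, "babayan_config"))
  build_space_from_config(config, p_omission = 0)
}

classify_obs <- function(obs) {
  if (length(obs) != 2 || any(obs < 0)) stop("observation must be (odor, reward), both >= 0")
  if (obs[1] > 0 && obs[2] > 0) stop("odor and reward cannot co-occur")
  if (obs[1] > 0) "odor" else if (obs[2] > 0) "reward" else "null"
}

#' One Bayesian belief update
#'
#' `b_t(k') \propto sum_k O_o(k', k) T(k', k) b_{t-1}(k)`, renormalized.
#'
#' @param space A `microstate_space`.
#' @param b_prev Belief vector on the simplex (length `space$K`).
#' @param obs Observation vector `c(odor, reward)`.
#' @return The updated belief vector.
#' @export
belief_step <- function(space, b_prev, obs) {
  o <- classify_obs(obs)
  b <- as.vector(space$M[[o]] %*% b_prev)
  s <- sum(b)
  if (s <= 0) {
    stop(sprintf("impossible observation '%s' under the %s micro-state model",
                 o, space$task))
  }
  b / s
}

#' Block posterior from a reward magnitude
#'
#' Normal likelihood ratio with means at the two block rewards and a shared,
#' arbitrarily small sd (`sigma_r`): `f(r) = phi(r; mu1, sigma_r) /
#' (phi(r; mu1, sigma_r) + phi(r; mu2, sigma_r))`. Evaluated on the log scale
#' so tiny `sigma_r` does not underflow.
#'
#' @param r Observed nonzero reward magnitude.
#' @param mu Length-2 vector of block reward magnitudes.
#' @param sigma_r Likelihood sd (default 0.001).
#' @return `P(block 1 | r)` in `[0, 1]`.
#' @export
block_likelihood <- function(r, mu = c(1, 10), sigma_r = 0.001) {
  ll <- stats::dnorm(r, mean = mu, sd = sigma_r, log = TRUE)
  1 / (1 + exp(ll[2] - ll[1]))
}

new_block_belief <- function(space, p = 0.5) {
  b0 <- numeric(space$K); b0[space$absorbing] <- 1
  structure(list(p = p, b1 = b0, b2 = b0, K = space$K),
            class = "block_belief")
}

#' Composite belief vector of a block belief
#'
#' Concatenation `[p * b1, (1 - p) * b2]` over the two block copies
#' (length `2K = 44` for the default task); sums to 1.
#'
#' @param bb A `block_belief`.
#' @return Numeric vector of length `2 * K`.
#' @export
composite_belief <- function(bb) c(bb$p * bb$b1, (1 - bb$p) * bb$b2)

#' One Babayan composite belief update
#'
#' Each block copy is advanced by [belief_step()]; the block posterior `p_t`
#' is replaced by the reward-likelihood value `f(r_t)` when a nonzero reward
#' is observed and is carried over otherwise.
#'
#' @param space The per-block `microstate_space` from [build_babayan_space()].
#' @param bb A `block_belief` (see [run_beliefs()] for initialization).
#' @param obs Observation vector `c(odor, reward)`.
#' @param sigma_r Reward-likelihood sd.
#' @return The updated `block_belief`.
#' @export
babayan_belief_step <- function(space, bb, obs, sigma_r = 0.001) {
  ## the per-copy filter only cares whether a reward occurred, not its size
  o <- c(obs[1], as.numeric(obs[2] > 0))
  bb$b1 <- belief_step(space, bb$b1, o)
  bb$b2 <- belief_step(space, bb$b2, o)
  if (obs[2] > 0) {
    bb$p <- block_likelihood(obs[2], mu = space$config$block_rewards,
                             sigma_r = sigma_r)
  }
  bb
}

#' Run the belief filter over a session
#'
#' The initial belief is a point mass at the absorbing ITI micro-state
#' (sessions begin in an intertrial interval). For the Babayan task the trace
#' is the 2K-dimensional composite belief with a uniform initial block prior
#' (`p_0 = 0.5`).
#'
#' @param space A `microstate_space` matching the session's task.
#' @param session A `cond_session`.
#' @return A `T x K` (or `T x 2K`) matrix of class `belief_trace`; rows lie
#'   on the probability simplex.
#' @export
run_beliefs <- function(space, session) {
  obs <- session_observations(session)
  Tlen <- nrow(obs)
  if (space$task == "babayan") {
    bb <- new_block_belief(space)
    B <- matrix(0, Tlen, 2L * space$K)
    for (t in seq_len(Tlen)) {
      bb <- babayan_belief_step(space, bb, obs[t, ])
      B[t, ] <- composite_belief(bb)
    }
  } else {
    Mn <- space$M$null; Mo <- space$M$odor; Mr <- space$M$reward
    b <- numeric(space$K); b[space$absorbing] <- 1
    B <- matrix(0, Tlen, space$K)
    for (t in seq_len(Tlen)) {
      M <- if (obs[t, 1] > 0) Mo else if (obs[t, 2] > 0) Mr else Mn
      b <- as.vector(M %*% b)
      s <- sum(b)
      if (s <= 0) stop(sprintf("impossible observation at step %d", t))
      b <- b / s
      B[t, ] <- b
    }
  }
  structure(B, class = c("belief_trace", "matrix", "array"), space = space)
}

#' Write / read a belief trace as CSV
#'
#' Columns are named after micro-states; row order matches the session's time
#' indexing.
#'
#' @param beliefs A `belief_trace` (or plain matrix).
#' @param path CSV path.
#' @export
write_belief_trace <- function(beliefs, path) {
  B <- as.matrix(beliefs)
  colnames(B) <- paste0("s", seq_len(ncol(B)))
  utils::write.csv(format(as.data.frame(B), digits = 17, scientific = TRUE,
                          trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_belief_trace
#' @export
read_belief_trace <- function(path) {
  as.matrix(utils::read.csv(path))
}
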