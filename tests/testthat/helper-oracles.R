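# Independent oracles, deliberately written in a plain, loop-based style so
# they share no code path with the package implementations they check.

# Brute-force forward-algorithm filter over the micro-state space: explicit
# double loop over source/destination states.
oracle_forward_filter <- function(space, obs) {
  K <- space$K
  b <- numeric(K); b[K] <- 1
  B <- matrix(0, nrow(obs), K)
  for (t in seq_len(nrow(obs))) {
    o <- if (obs[t, 1] > 0) "odor" else if (obs[t, 2] > 0) "reward" else "null"
    b_new <- numeric(K)
    for (k2 in seq_len(K)) {
      acc <- 0
      for (k1 in seq_len(K)) {
        acc <- acc + space$O[[o]][k2, k1] * space$T[k2, k1] * b[k1]
      }
      b_new[k2] <- acc
    }
    s <- sum(b_new)
    if (s <= 0) stop("oracle: impossible observation at step ", t)
    b <- b_new / s
    B[t, ] <- b
  }
  B
}

# Composite Babayan filter written directly from the block-belief definition.
oracle_babayan_filter <- function(space, obs, mu = c(1, 10), sigma_r = 0.001) {
  K <- space$K
  b1 <- numeric(K); b1[K] <- 1
  b2 <- b1
  p <- 0.5
  B <- matrix(0, nrow(obs), 2 * K)
  step_one <- function(b, o) {
    M <- space$O[[o]] * space$T
    v <- as.vector(M %*% b)
    v / sum(v)
  }
  for (t in seq_len(nrow(obs))) {
    o <- if (obs[t, 1] > 0) "odor" else if (obs[t, 2] > 0) "reward" else "null"
    b1 <- step_one(b1, o)
    b2 <- step_one(b2, o)
    r <- obs[t, 2]
    if (r > 0) {
      l1 <- stats::dnorm(r, mu[1], sigma_r, log = TRUE)
      l2 <- stats::dnorm(r, mu[2], sigma_r, log = TRUE)
      p <- 1 / (1 + exp(l2 - l1))
    }
    B[t, ] <- c(p * b1, (1 - p) * b2)
  }
  B
}

# Bellman linear solve over micro-states with rewards on transitions:
# V(k) = rbar(k) + gamma * sum_k2 T(k2, k) V(k2),
# rbar(k) = expected one-step reward leaving state k.
oracle_bellman_values <- function(space, gamma, reward_size = 1) {
  K <- space$K
  rbar <- numeric(K)
  for (k in seq_len(K)) {
    for (k2 in seq_len(K)) {
      rbar[k] <- rbar[k] +
        space$T[k2, k] * space$O$reward[k2, k] * reward_size
    }
  }
  solve(diag(K) - gamma * t(space$T), rbar)
}

# Scalar, per-unit GRU step (no matrix ops) as a reference implementation.
oracle_gru_step <- function(p, z, o) {
  H <- length(z)
  sig <- function(x) 1 / (1 + exp(-x))
  z_new <- numeric(H)
  for (i in seq_len(H)) {
    ri <- sum(p$W_ir[i, ] * o) + p$b_ir[i] + sum(p$W_hr[i, ] * z) + p$b_hr[i]
    ui <- sum(p$W_iu[i, ] * o) + p$b_iu[i] + sum(p$W_hu[i, ] * z) + p$b_hu[i]
    ni <- sum(p$W_in[i, ] * o) + p$b_in[i] +
      sig(ri) * (sum(p$W_hn[i, ] * z) + p$b_hn[i])
    z_new[i] <- (1 - sig(ui)) * tanh(ni) + sig(ui) * z[i]
  }
  z_new
}

# Label/observation consistency: every consecutive labelled transition must
# be possible under the transition model and emit the observed symbol. For
# the Babayan composite labels, transitions are checked within the per-block
# copy (the copy offset may jump at block boundaries; micro-states may not).
check_session_consistency <- function(space, session) {
  obs <- cbind(session$odor, session$reward)
  st <- session$state
  K <- space$K
  for (t in 2:nrow(obs)) {
    k1 <- (st[t - 1] - 1) %% K + 1
    k2 <- (st[t] - 1) %% K + 1
    o <- if (obs[t, 1] > 0) "odor" else if (obs[t, 2] > 0) "reward" else "null"
    if (space$T[k2, k1] <= 0 || space$O[[o]][k2, k1] != 1) {
      return(sprintf("inconsistent transition %d -> %d under '%s' at step %d",
                     st[t - 1], st[t], o, t))
    }
  }
  TRUE
}

# Small random observation sequences that are *possible* under a task, used
# for filter-vs-oracle comparisons (generated from real short sessions).
random_session_obs <- function(task, n_trials, seed) {
  config <- switch(task,
                   task1 = starkweather_config("task1"),
                   task2 = starkweather_config("task2"),
                   babayan = babayan_config())
  generate_session(config, n_trials, seed = seed)
}

# Direct simulation of the micro-state Markov chain (transition + emission
# sampling). The trial-based generator intentionally deviates from the chain
# after omission trials (a fresh full ITI follows the omission "ISI"), so
# checks of exact model self-consistency (Bellman values, zero-mean TD
# errors) use chain-generated observation streams instead.
simulate_chain <- function(space, n_steps, seed, reward_size = 1) {
  set.seed(seed)
  K <- space$K
  obs <- matrix(0, n_steps, 2)
  states <- integer(n_steps)
  k1 <- K
  for (t in seq_len(n_steps)) {
    k2 <- sample.int(K, 1, prob = space$T[, k1])
    if (space$O$odor[k2, k1] == 1) {
      obs[t, ] <- c(1, 0)
    } else if (space$O$reward[k2, k1] == 1) {
      obs[t, ] <- c(0, reward_size)
    }
    states[t] <- k2
    k1 <- k2
  }
  list(obs = obs, states = states)
}
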