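# The TD index convention used throughout: delta[t] = r[t+1] + gamma*V[t+1]
# - V[t], the error of the transition t -> t+1, so a trial's reward RPE uses
# the pre-reward value. LSTD uses the matching pairing.

test_that("LSTD degenerate cases: zero rewards and gamma = 0", {
  set.seed(21)
  Z <- matrix(rnorm(600), 200, 3)
  ro <- lstd_fit(Z, rep(0, 200), gamma = 0.9)
  expect_equal(ro$w, rep(0, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ro$w0, 0, tolerance = 1e-12)
  # gamma = 0 reduces to ordinary least squares of r_{t+1} on z_t
  r <- rnorm(200)
  ro0 <- lstd_fit(Z, r, gamma = 0)
  ols <- lm.fit(cbind(Z[-200, ], 1), r[-1])$coefficients
  expect_equal(c(ro0$w, ro0$w0), unname(ols), tolerance = 1e-8)
})

test_that("LSTD fails loudly on rank-deficient features unless ridged", {
  set.seed(22)
  Z <- matrix(rnorm(300), 100, 3)
  Z <- cbind(Z, Z[, 1] + Z[, 2])          # exact collinearity
  r <- rnorm(100)
  expect_error(lstd_fit(Z, r, 0.9, rep_name = "degenerate rep"),
               "rank deficient")
  expect_error(lstd_fit(Z, r, 0.9, rep_name = "degenerate rep"),
               "degenerate rep")
  ro <- lstd_fit(Z, r, 0.9, ridge = 1e-8)
  expect_length(ro$w, 4)
})

test_that("LSTD on beliefs recovers the Bellman value function", {
  # Exact self-consistency holds on observation streams generated by the
  # micro-state chain itself (the trial-based generator deliberately departs
  # from the chain after omission trials). Fitted *values* are compared on
  # the belief trajectory: in Task 2 the beliefs span an ill-conditioned
  # subspace, so the coefficient vector is weakly identified even though the
  # value function itself is exact.
  gamma <- 0.93
  for (task in c("task1", "task2")) {
    sp <- build_starkweather_space(task)
    V_star <- oracle_bellman_values(sp, gamma)
    run_filter <- function(obs) {
      run_beliefs(sp, data.frame(odor = obs[, 1], reward = obs[, 2]))
    }
    errs <- sapply(c(15000, 120000), function(n) {
      obs <- simulate_chain(sp, n, seed = 23)$obs
      B <- run_filter(obs)
      ro <- lstd_fit(B, obs[, 2], gamma, intercept = FALSE)
      max(abs(value_trace(ro, B) - as.vector(B %*% V_star)))
    })
    expect_lt(errs[2], errs[1])             # tolerance shrinks with length
    expect_lt(errs[2], 0.05)
    # Task 1 beliefs are point masses, so there the coefficients themselves
    # are the micro-state values
    if (task == "task1") {
      obs <- simulate_chain(sp, 120000, seed = 23)$obs
      B <- run_filter(obs)
      ro <- lstd_fit(B, obs[, 2], gamma, intercept = FALSE)
      expect_lt(max(abs(ro$w - V_star)), 0.05)
    }
    # with the true values, the mean TD error is ~0; TD errors are strongly
    # autocorrelated, so the standard error comes from block means
    obs <- simulate_chain(sp, 120000, seed = 24)$obs
    B <- run_filter(obs)
    delta <- td_errors(as.vector(B %*% V_star), obs[, 2], gamma)$delta
    bm <- tapply(delta, (seq_along(delta) - 1) %/% 300, mean)
    expect_lt(abs(mean(bm)), 3 * sd(bm) / sqrt(length(bm)))
  }
})

test_that("TD error algebra: constant traces and constant offsets", {
  V <- rep(2.5, 100)
  d <- td_errors(V, rep(0, 100), gamma = 0.9)$delta
  expect_equal(d, rep((0.9 - 1) * 2.5, 99))
  # a constant value offset shifts every delta by (gamma-1)c, so the
  # reward-time MSE against the unshifted trace is ((1-gamma)c)^2 exactly
  s <- generate_session(starkweather_config("task1"), 50, seed = 25)
  sp <- build_starkweather_space("task1")
  B <- run_beliefs(sp, s)
  ro <- lstd_fit(B, s$reward, 0.93, intercept = FALSE)
  V <- value_trace(ro, B)
  rp <- td_errors(V, s$reward, 0.93)
  rp_off <- td_errors(V + 1.7, s$reward, 0.93)
  expect_equal(rpe_mse(s, rp_off, rp), ((1 - 0.93) * 1.7)^2, tolerance = 1e-10)
  expect_equal(rpe_mse(s, rp, rp), 0)
  # no rewarded trials -> error
  s0 <- s[s$reward == 0, ]
  expect_error(rpe_mse(structure(s0, class = class(s)),
                       td_errors(rnorm(10), rep(0, 10), 0.9),
                       td_errors(rnorm(10), rep(0, 10), 0.9)),
               "no rewarded trials")
})

test_that("belief-model reward RPEs: hazard makes Task 1 fall to zero, omission belief makes Task 2 rise late", {
  # In Task 1 the reward hazard reaches 1 at the last delay, so the reward
  # there is fully predicted (zero RPE) and the curve decreases with delay.
  # In Task 2 the growing omission belief depresses the pre-reward value at
  # long delays, so late rewards regain surprise and the curve turns up.
  gamma <- 0.93
  curves <- lapply(c("task1", "task2"), function(task) {
    sp <- build_starkweather_space(task)
    s <- generate_session(starkweather_config(task), 4000, seed = 26)
    B <- run_beliefs(sp, s)
    ro <- lstd_fit(B, s$reward, gamma, intercept = FALSE)
    rp <- td_errors(value_trace(ro, B), s$reward, gamma)
    rpe_summaries(s, rp)
  })
  names(curves) <- c("task1", "task2")
  c1 <- curves$task1; c2 <- curves$task2
  expect_equal(c1$isi, 6:14)
  expect_true(all(diff(c1$mean) < 0))                  # Task 1 decreasing
  expect_lt(abs(c1$mean[c1$isi == 14]), 0.02)          # fully predicted
  late <- c2$mean[c2$isi >= 10]
  expect_true(all(diff(late) > 0))                     # Task 2 rises late
  expect_gt(c2$mean[c2$isi == 14], c2$mean[c2$isi == 6])
  # the two tasks disagree in direction over the late delays
  expect_lt(c1$mean[c1$isi == 14] - c1$mean[c1$isi == 10], 0)
  expect_gt(c2$mean[c2$isi == 14] - c2$mean[c2$isi == 10], 0)
})

test_that("Babayan belief RPEs track the within-block trial index", {
  gamma <- 0.93
  sp <- build_babayan_space()
  s <- generate_session(babayan_config(), 3000, seed = 27)
  B <- run_beliefs(sp, s)
  ro <- lstd_fit(B, s$reward, gamma, intercept = FALSE)
  rp <- td_errors(value_trace(ro, B), s$reward, gamma)
  cur <- rpe_summaries(s, rp)
  # first large reward after a small-reward block is a bigger surprise than
  # the fifth (the block identity has been inferred by then)
  rw <- cur[cur$event == "reward" & cur$prev_reward == 1 & cur$cur_reward == 10, ]
  expect_gt(rw$mean[rw$trial_in_block == 1], rw$mean[rw$trial_in_block == 5])
  # odor RPEs grow across a large-reward block as confidence builds
  od <- cur[cur$event == "odor" & cur$prev_reward == 1 & cur$cur_reward == 10, ]
  expect_gt(od$mean[od$trial_in_block == 5], od$mean[od$trial_in_block == 1])
})

test_that("a degenerate single-delay task yields a one-point curve", {
  cfg <- starkweather_config("task1", isi_support = 8L, isi_mean = 8)
  s <- generate_session(cfg, 300, seed = 28)
  sp <- build_starkweather_space(cfg)
  B <- run_beliefs(sp, s)
  ro <- lstd_fit(B, s$reward, 0.93, intercept = FALSE)
  rp <- td_errors(value_trace(ro, B), s$reward, 0.93)
  cur <- rpe_summaries(s, rp)
  expect_equal(nrow(cur), 1)
  expect_equal(cur$mean, mean(rpe_at_reward(s, rp)$rpe))
})
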