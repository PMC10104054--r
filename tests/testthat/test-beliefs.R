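test_that("Starkweather spaces have 25 states with stochastic transitions", {
  for (v in c("task1", "task2")) {
    sp <- build_starkweather_space(v)
    expect_equal(sp$K, 25)
    expect_equal(unname(colSums(sp$T)), rep(1, 25), tolerance = 1e-12)
    # every possible transition carries exactly one observation
    mass <- sp$O$null + sp$O$odor + sp$O$reward
    pos <- sp$T > 0
    expect_true(all(mass[pos] == 1))
  }
  # the Task-2 odor splits between ISI entry and ITI entry
  sp2 <- build_starkweather_space("task2")
  expect_equal(sp2$T[1, 25], (1 / 8) * 0.9)
  expect_equal(sp2$T[15, 25], (1 / 8) * 0.1)
})

test_that("the ISI hazard has the conditional form and ends at 1", {
  pmf <- isi_pmf(starkweather_config("task1"))
  h <- isi_hazard(pmf)
  # brute force h_t = p_t / (1 - F_{t-1}) from the pmf
  for (i in seq_along(pmf)) {
    Fprev <- if (i == 1) 0 else sum(pmf[1:(i - 1)])
    expect_equal(unname(h[i]), unname(pmf[i] / (1 - Fprev)), tolerance = 1e-9)
  }
  expect_equal(unname(h[length(h)]), 1)
})

test_that("the Babayan space has 22 states per block copy", {
  sp <- build_babayan_space()
  expect_equal(sp$K, 22)
  expect_equal(sum(sp$labels == "isi"), 11)
  expect_equal(unname(colSums(sp$T)), rep(1, 22), tolerance = 1e-12)
  expect_equal(unname(sp$hazard), c(1 / 3, 1 / 2, 1), tolerance = 1e-12)
  # composite belief over both copies is 44-dimensional
  bb <- beliefrnn:::new_block_belief(sp)
  expect_length(composite_belief(bb), 44)
})

test_that("belief updates collapse on the event-defined states", {
  sp1 <- build_starkweather_space("task1")
  # odor from anywhere in the ITI lands on ISI state 1
  b_iti <- rep(0, 25); b_iti[20:25] <- 1 / 6
  expect_equal(belief_step(sp1, b_iti, c(1, 0)), c(1, rep(0, 24)))
  # reward from any ISI state lands on ITI entry state 15
  b_isi <- rep(0, 25); b_isi[6:14] <- 1 / 9
  b <- belief_step(sp1, b_isi, c(0, 1))
  expect_equal(which(b > 0), 15L)
  # the absorbing ITI state is a null-input fixed point
  d25 <- rep(0, 25); d25[25] <- 1
  expect_equal(belief_step(sp1, d25, c(0, 0)), d25)
  # impossible observations are a hard error, not silent renormalization
  d3 <- rep(0, 25); d3[3] <- 1
  expect_error(belief_step(sp1, d3, c(1, 0)), "impossible")
  expect_error(belief_step(sp1, d25, c(0, 1)), "impossible")
})

test_that("the filter matches a brute-force forward algorithm to 1e-12", {
  for (task in c("task1", "task2")) {
    sp <- build_starkweather_space(task)
    s <- random_session_obs(task, 3, seed = 11)[1:50, ]
    B <- run_beliefs(sp, s)
    B_oracle <- oracle_forward_filter(sp, cbind(s$odor, s$reward))
    expect_lt(max(abs(B - B_oracle)), 1e-12)
    expect_equal(rowSums(B), rep(1, nrow(B)), tolerance = 1e-12)
    expect_true(all(B >= 0))
  }
})

test_that("Task 1 beliefs are point masses; Task 2 splits 0.9/0.1 at odor", {
  s1 <- generate_session(starkweather_config("task1"), 100, seed = 12)
  B1 <- run_beliefs(build_starkweather_space("task1"), s1)
  entropy <- apply(B1, 1, function(b) -sum(b[b > 0] * log(b[b > 0])))
  expect_equal(max(entropy), 0)
  expect_true(all(apply(B1, 1, which.max) == s1$state))

  sp2 <- build_starkweather_space("task2")
  s2 <- generate_session(starkweather_config("task2"), 100, seed = 13)
  B2 <- run_beliefs(sp2, s2)
  odor_rows <- which(s2$odor > 0)
  isi_mass <- rowSums(B2[odor_rows, sp2$labels == "isi", drop = FALSE])
  expect_equal(unname(isi_mass), rep(0.9, length(odor_rows)), tolerance = 1e-12)
  # on omission trials the ISI-macro mass is gone 15 steps after the odor
  om <- attr(s2, "trials")$omission
  om_odors <- odor_rows[om[s2$trial_index[odor_rows]]]
  om_odors <- om_odors[om_odors + 15 <= nrow(B2)]
  # only steps still free of new observations 15 steps later
  ok <- vapply(om_odors, function(i) all(s2$odor[(i + 1):(i + 15)] == 0),
               logical(1))
  for (i in om_odors[ok]) {
    expect_lt(sum(B2[i + 15, sp2$labels == "isi"]), 1e-12)
  }
})

test_that("the reward likelihood pins the Babayan block posterior", {
  expect_equal(block_likelihood(1), 1)        # block-1 reward
  expect_equal(block_likelihood(10), 0)       # block-2 reward
  expect_equal(block_likelihood(5.5), 0.5)    # symmetry midpoint
  sp <- build_babayan_space()
  bb <- beliefrnn:::new_block_belief(sp)
  bb$p <- 0.37
  bb2 <- babayan_belief_step(sp, bb, c(0, 0))
  expect_equal(bb2$p, 0.37)                   # unchanged without reward
  # a unit reward (observed at an ISI state) makes block 1 nearly certain
  bb$b1 <- bb$b2 <- replace(rep(0, 22), 9, 1)
  bb3 <- babayan_belief_step(sp, bb, c(0, 1))
  expect_equal(bb3$p, 1)
})

test_that("the composite Babayan filter matches its brute-force oracle", {
  sp <- build_babayan_space()
  s <- generate_session(babayan_config(), 30, seed = 14)
  B <- run_beliefs(sp, s)
  expect_equal(dim(B), c(nrow(s), 44))
  B_oracle <- oracle_babayan_filter(sp, cbind(s$odor, s$reward))
  expect_lt(max(abs(B - B_oracle)), 1e-12)
  expect_equal(rowSums(B), rep(1, nrow(B)), tolerance = 1e-12)
})

test_that("belief traces round-trip through CSV", {
  sp <- build_starkweather_space("task2")
  s <- generate_session(starkweather_config("task2"), 5, seed = 15)
  B <- run_beliefs(sp, s)
  path <- file.path(tempdir(), "beliefs.csv")
  write_belief_trace(B, path)
  B2 <- read_belief_trace(path)
  expect_equal(dim(B2), dim(B))
  expect_equal(max(abs(unclass(B) - B2)), 0, tolerance = 1e-15)
  unlink(path)
})
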