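test_that("GRU step limit cases: zero parameters and saturated update gate", {
  H <- 4
  zero <- gru_init(H, seed = 1)
  for (nm in names(zero)) zero[[nm]] <- zero[[nm]] * 0
  z <- c(0.3, -0.2, 0.5, 1)
  # gates at 0.5, candidate 0 -> z' = 0.5 z
  expect_equal(gru_step(zero, z, c(1, 0)), 0.5 * z)
  # saturated update gate copies the previous state (perfect memory)
  mem <- zero
  mem$b_iu <- rep(50, H)
  expect_equal(gru_step(mem, z, c(0, 1)), z, tolerance = 1e-12)
  expect_error(gru_step(zero, z[1:2], c(0, 0)), "shape")
})

test_that("C++ forward pass matches the per-unit reference GRU", {
  set.seed(31)
  p <- gru_init(7, seed = 31)
  obs <- cbind(rbinom(40, 1, 0.2), rbinom(40, 1, 0.1) * runif(40, 0, 2))
  obs[obs[, 1] > 0, 2] <- 0
  model <- structure(list(H = 7L, type = "gru", params = p, seed = 31,
                          trained = FALSE), class = "value_rnn")
  fwd <- rnn_forward(model, obs)
  z <- rep(0, 7); V <- numeric(40)
  Zref <- matrix(0, 40, 7)
  for (t in 1:40) {
    z <- oracle_gru_step(p, z, obs[t, ])
    Zref[t, ] <- z
    V[t] <- sum(p$w * z) + p$w0
  }
  expect_lt(max(abs(fwd$Z - Zref)), 1e-6)
  expect_lt(max(abs(fwd$V - V)), 1e-6)
  # and the R step function agrees too
  expect_equal(gru_step(p, rep(0, 7), obs[1, ]), Zref[1, ], tolerance = 1e-12)
})

test_that("default initialization is uniform within 1/sqrt(H) and reproducible", {
  p <- gru_init(50, seed = 7)
  a <- 1 / sqrt(50)
  expect_equal(a, 0.1414, tolerance = 1e-3)
  allv <- unlist(p)
  expect_lte(max(abs(allv)), a)
  expect_gt(max(abs(allv)), 0.9 * a)     # actually fills the range
  expect_identical(p, gru_init(50, seed = 7))
  expect_false(identical(p, gru_init(50, seed = 8)))
  # untrained networks respond to observations with decaying transients
  m <- value_rnn(50, seed = 7)
  fp <- find_fixed_points(rnn_step_map(m), matrix(0, 1, 50))$points[1, ]
  md <- memory_duration(rnn_step_map(m), fp, "odor")
  expect_false(md$capped)
  expect_gt(md$eta[1], md$threshold)     # perturbed away, then returns
})

test_that("ESN initialization is a gain-scaled orthogonal reservoir", {
  p <- esn_init(30, gain = 1.3, seed = 9)
  for (nm in c("W_hr", "W_hu", "W_hn")) {
    expect_equal(crossprod(p[[nm]]), diag(1.3^2, 30), tolerance = 1e-10,
                 info = nm)
  }
  expect_false(isTRUE(all.equal(p$W_hr, p$W_hu)))   # independent draws
  for (nm in grep("^b_", names(p), value = TRUE)) {
    expect_equal(p[[nm]], rep(0, 30))
  }
  a_in <- sqrt(6 / (2 + 30))
  expect_lte(max(abs(c(p$W_ir, p$W_iu, p$W_in))), a_in)
})

test_that("training with zero learning rate is a no-op", {
  s <- generate_session(starkweather_config("task2"), 60, seed = 32)
  m <- value_rnn(8, seed = 32)
  cfg <- train_config(episode_len = 5, max_epochs = 3, lr = 0, seed = 1)
  mt <- train_td(m, s, cfg)
  for (nm in names(m$params)) {
    expect_equal(mt$params[[nm]], m$params[[nm]], tolerance = 0,
                 ignore_attr = TRUE, info = nm)
  }
  expect_equal(diff(range(mt$loss)), 0, tolerance = 1e-12)
})

test_that("ESN training never mutates the frozen reservoir", {
  s <- generate_session(starkweather_config("task2"), 200, seed = 33)
  m <- value_rnn(10, seed = 33, type = "esn", gain = 1.2)
  cfg <- train_config(episode_len = 10, max_epochs = 3, seed = 2)
  mt <- train_td(m, s, cfg)
  frozen <- setdiff(names(m$params), c("w", "w0"))
  for (nm in frozen) {
    expect_identical(unname(mt$params[[nm]]), unname(m$params[[nm]]), info = nm)
  }
  expect_false(isTRUE(all.equal(mt$params$w, m$params$w)))
})

test_that("semi-gradient TD training reduces the loss and is deterministic", {
  s <- generate_session(starkweather_config("task2"), 600, seed = 34)
  m <- value_rnn(16, seed = 34)
  cfg <- train_config(max_epochs = 10, seed = 3)
  mt <- train_td(m, s, cfg)
  expect_true(all(is.finite(mt$loss)))
  expect_lt(min(mt$loss), mt$loss[1])
  expect_equal(mt$loss[mt$best_epoch], min(mt$loss))
  mt2 <- train_td(value_rnn(16, seed = 34), s, cfg)
  expect_identical(mt$loss, mt2$loss)
  expect_equal(mt$params, mt2$params, tolerance = 0)
  # forward determinism
  f1 <- rnn_forward(mt, s); f2 <- rnn_forward(mt, s)
  expect_identical(f1$Z, f2$Z)
})

test_that("training moves the RPEs toward the belief model's", {
  gamma <- 0.93
  ds <- probe_datasets("task2", seed = 35, n_trials = 300)
  tr <- generate_session(starkweather_config("task2"), 2000,
                         seed = derive_seed(35, "train"))
  m <- value_rnn(16, seed = 35)
  r_unt <- probe_model(m, ds, noise_seed = 1, dynamics = FALSE, decode = FALSE)
  mt <- train_td(m, tr, train_config(max_epochs = 30, seed = 4))
  r_tr <- probe_model(mt, ds, noise_seed = 1, dynamics = FALSE, decode = FALSE)
  expect_lt(r_tr$rpe_mse, r_unt$rpe_mse / 5)
  expect_gt(r_tr$belief_r2, r_unt$belief_r2)
})

test_that("checkpoints round-trip through JSON", {
  m <- value_rnn(6, seed = 36, type = "esn", gain = 0.8)
  m$loss <- c(0.5, 0.4); m$trained <- TRUE; m$best_epoch <- 2L
  path <- file.path(tempdir(), "model.json")
  write_value_rnn(m, path)
  m2 <- read_value_rnn(path)
  expect_equal(m$params, m2$params, tolerance = 1e-12)
  expect_equal(m2$type, "esn")
  expect_equal(m2$gain, 0.8)
  expect_equal(m2$loss, m$loss)
  # loader validates shapes
  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$params$w <- bad$params$w[1:3]
  jsonlite::write_json(bad, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_value_rnn(path))
  unlink(path)
})
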