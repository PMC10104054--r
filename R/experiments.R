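## End-to-end orchestration: train/evaluate model cohorts, sweep ESN gains,
## and regenerate the computational figure panels from stored results.

#' Deterministic seed derivation
#'
#' Spawns a per-model seed from a global seed and a set of labels, so cohort
#' reruns are exactly reproducible. Values stay below 2^31.
#'
#' @param global Global integer seed.
#' @param ... Further integer or character labels.
#' @return An integer seed.
#' @export
derive_seed <- function(global, ...) {
  parts <- list(...)
  h <- as.double(global) %% 2147483629
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(p) else as.double(p)
    for (x in codes) h <- (h * 69069 + x + 1) %% 2147483629
  }
  as.integer(h + 1)
}

task_config <- function(task) {
  switch(task,
         task1 = starkweather_config("task1"),
         task2 = starkweather_config("task2"),
         babayan = babayan_config(),
         stop("unknown task: ", task))
}

task_space <- function(config) {
  if (config$task == "babayan") build_babayan_space(config)
  else build_starkweather_space(config)
}

belief_dim <- function(space) {
  if (space$task == "babayan") 2L * space$K else space$K
}

#' Evaluation datasets for probing a representation
#'
#' Generates disjoint fit and evaluation sessions (1,000 trials each by
#' default), runs the belief filter on both, and fits the belief model's
#' value readout by LSTD — the reference against which model RPEs are
#' scored.
#'
#' @param task `"task1"`, `"task2"`, or `"babayan"`.
#' @param seed Global seed (sessions derive their own seeds from it).
#' @param n_trials Trials per session.
#' @param gamma Discount factor.
#' @return A list bundling the sessions, the micro-state space, belief
#'   traces, belief values, and belief RPEs.
#' @export
probe_datasets <- function(task, seed, n_trials = 1000, gamma = 0.93) {
  config <- task_config(task)
  space <- task_space(config)
  fit_session <- generate_session(config, n_trials,
                                  seed = derive_seed(seed, task, "fit"))
  eval_session <- generate_session(config, n_trials,
                                   seed = derive_seed(seed, task, "eval"))
  B_fit <- run_beliefs(space, fit_session)
  B_eval <- run_beliefs(space, eval_session)
  belief_readout <- lstd_fit(B_fit, fit_session$reward, gamma,
                             intercept = FALSE, rep_name = "beliefs")
  belief_values <- value_trace(belief_readout, B_eval)
  belief_rpes <- td_errors(belief_values, eval_session$reward, gamma)
  list(task = task, config = config, space = space, gamma = gamma,
       fit_session = fit_session, eval_session = eval_session,
       B_fit = B_fit, B_eval = B_eval,
       belief_readout = belief_readout, belief_rpes = belief_rpes)
}

#' Probe one model against the belief reference
#'
#' Runs the network over the fit and evaluation sessions, injects 40 dB
#' noise (fresh draws per session) for the fitted probes, refits the value
#' readout by LSTD on the fit session, and reports the belief-likeness
#' metrics. PCA and dynamics use the noise-free evaluation trace.
#'
#' @param model A `value_rnn`.
#' @param ds A [probe_datasets()] bundle.
#' @param noise_seed Seed for the noise draws.
#' @param dynamics Also compute fixed points and odor/reward memories.
#' @param decode Also fit the state decoder (the slowest probe).
#' @return One-row `data.frame` of metrics, with the model attached as an
#'   attribute.
#' @export
probe_model <- function(model, ds, noise_seed = 1, dynamics = TRUE,
                        decode = TRUE) {
  fwd_fit <- rnn_forward(model, ds$fit_session)
  fwd_eval <- rnn_forward(model, ds$eval_session)
  Zf <- inject_noise(fwd_fit$Z, seed = derive_seed(noise_seed, "fit"))
  Ze <- inject_noise(fwd_eval$Z, seed = derive_seed(noise_seed, "eval"))

  readout <- lstd_fit(Zf, ds$fit_session$reward, ds$gamma,
                      rep_name = sprintf("%s H=%d", model$type, model$H))
  values <- value_trace(readout, Ze)
  rpes <- td_errors(values, ds$eval_session$reward, ds$gamma)

  res <- data.frame(
    type = model$type, H = model$H, seed = model$seed,
    gain = if (model$type == "esn") model$gain else NA_real_,
    trained = model$trained,
    rpe_mse = rpe_mse(ds$eval_session, rpes, ds$belief_rpes),
    belief_r2 = belief_r2(Zf, ds$B_fit, Ze, ds$B_eval),
    pca2_var = pca_top2(fwd_eval$Z)$var_frac)

  if (decode) {
    dec <- fit_state_decoder(Zf, ds$fit_session$state,
                             n_states = belief_dim(ds$space))
    keep <- eval_keep_steps(ds)
    res$decoder_ll <- as.numeric(
      decoder_loglik(dec, Ze, ds$eval_session$state, keep = keep))
    res$decoder_converged <- dec$converged
  }

  if (dynamics) {
    seeds <- collect_seed_states(model, ds$eval_session, n = 20,
                                 seed = derive_seed(noise_seed, "seeds"))
    fps <- find_fixed_points(rnn_step_map(model), seeds)
    res$n_fixed_points <- nrow(fps$points)
    if (nrow(fps$points) >= 1) {
      fp <- fps$points[1, ]
      rs <- if (ds$task == "babayan") max(ds$config$block_rewards)
            else ds$config$reward_size
      om <- memory_duration(rnn_step_map(model), fp, "odor")
      rm <- memory_duration(rnn_step_map(model), fp, "reward",
                            reward_size = rs)
      res$odor_memory <- ifelse(om$capped, NA_integer_, om$steps)
      res$reward_memory <- ifelse(rm$capped, NA_integer_, rm$steps)
    } else {
      res$odor_memory <- NA_integer_
      res$reward_memory <- NA_integer_
    }
  }
  attr(res, "model") <- model
  res
}

## Babayan decoding drops every block's first trial (beliefs do not know the
## trial count per block, so only then are they a proper ceiling)
eval_keep_steps <- function(ds) {
  if (ds$task != "babayan") return(NULL)
  trials <- attr(ds$eval_session, "trials")
  first_of_block <- trials$trial_index[!duplicated(trials$block_id)]
  !(ds$eval_session$trial_index %in% first_of_block)
}

#' Log-likelihood ceiling from the beliefs themselves
#'
#' @param ds A [probe_datasets()] bundle.
#' @return Mean log-likelihood using `pi_t = b_t` on the evaluation session.
#' @export
belief_ll_ceiling <- function(ds) {
  as.numeric(decoder_loglik(ds$B_eval, states_eval = ds$eval_session$state,
                            keep = eval_keep_steps(ds)))
}

#' Train and evaluate a cohort of value networks
#'
#' Trains `n_networks` networks with distinct derived seeds on a task, then
#' probes each against the belief reference. Individual training failures
#' are logged and excluded (with a count) rather than aborting the cohort.
#'
#' @param task `"task1"`, `"task2"`, or `"babayan"`.
#' @param H Hidden size.
#' @param n_networks Cohort size.
#' @param train If `FALSE`, probe the untrained initializations.
#' @param seed Global seed.
#' @param train_trials Trials in the training session.
#' @param config A [train_config()]; episode length defaults to 20 trials
#'   (50 for the Babayan task).
#' @param dynamics,decode Passed to [probe_model()].
#' @param ds Optionally a precomputed [probe_datasets()] bundle to share
#'   across cohorts.
#' @return List with `results` (per-model data frame), `summary`
#'   (mean and SE per metric), `models`, `ds`, and `n_failed`.
#' @export
run_cohort <- function(task, H = 50, n_networks = 12, train = TRUE, seed = 1,
                       train_trials = 10000,
                       config = NULL, dynamics = TRUE, decode = TRUE,
                       ds = NULL) {
  if (is.null(config)) {
    config <- train_config(episode_len = if (task == "babayan") 50L else 20L)
  }
  if (is.null(ds)) ds <- probe_datasets(task, seed, gamma = config$gamma)
  train_session <- if (train) {
    generate_session(task_config(task), train_trials,
                     seed = derive_seed(seed, task, "train"))
  } else NULL

  rows <- list(); models <- list(); n_failed <- 0L
  for (i in seq_len(n_networks)) {
    mseed <- derive_seed(seed, task, H, i)
    model <- value_rnn(H, seed = mseed)
    row <- tryCatch({
      if (train) {
        cfg_i <- config
        cfg_i$seed <- derive_seed(mseed, "shuffle")
        model <- train_td(model, train_session, cfg_i)
      }
      probe_model(model, ds, noise_seed = mseed, dynamics = dynamics,
                  decode = decode)
    }, error = function(e) {
      message(sprintf("model %d failed: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(row)) { n_failed <- n_failed + 1L; next }
    models[[length(models) + 1L]] <- attr(row, "model")
    attr(row, "model") <- NULL
    rows[[length(rows) + 1L]] <- row
  }
  results <- do.call(rbind, rows)
  list(task = task, results = results, summary = cohort_summary(results),
       models = models, ds = ds, n_failed = n_failed)
}

#' Cohort summary (mean and standard error per metric)
#'
#' @param results Per-model data frame from [run_cohort()].
#' @return Data frame with `metric`, `mean`, `se`, `n`.
#' @export
cohort_summary <- function(results) {
  metrics <- intersect(c("rpe_mse", "belief_r2", "pca2_var", "decoder_ll",
                         "n_fixed_points", "odor_memory", "reward_memory"),
                       names(results))
  do.call(rbind, lapply(metrics, function(m) {
    v <- results[[m]][!is.na(results[[m]])]
    data.frame(metric = m, mean = mean(v),
               se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
               n = length(v))
  }))
}

#' Sweep ESN reservoir gains
#'
#' Probes frozen echo-state initializations across a gain grid: value fits
#' use LSTD (no gradient training is needed for a frozen reservoir), and the
#' odor memory flags the instability regime where activity never returns to
#' a fixed point.
#'
#' @param gains Numeric vector of gains.
#' @param H Hidden size.
#' @param task Task name (the reference experiment uses `"task2"`).
#' @param seed Global seed.
#' @param n_per_gain Networks per gain.
#' @param decode Also fit state decoders (slow; default `FALSE`).
#' @return List with `results` (one row per network) and `ds`.
#' @export
run_esn_sweep <- function(gains, H = 50, task = "task2", seed = 1,
                          n_per_gain = 1, decode = FALSE) {
  ds <- probe_datasets(task, seed)
  rows <- list()
  for (g in gains) {
    for (i in seq_len(n_per_gain)) {
      mseed <- derive_seed(seed, task, "esn", round(1000 * g), i)
      model <- value_rnn(H, seed = mseed, type = "esn", gain = g)
      row <- probe_model(model, ds, noise_seed = mseed, dynamics = TRUE,
                         decode = decode)
      attr(row, "model") <- NULL
      row$unstable <- is.na(row$odor_memory)
      rows[[length(rows) + 1L]] <- row
    }
  }
  list(results = do.call(rbind, rows), ds = ds)
}
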