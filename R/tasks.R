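#' Configuration for the Starkweather trace-conditioning tasks
#'
#' Both task variants pair a single odor cue with a unit reward delivered at a
#' variable delay (the interstimulus interval, ISI) drawn from a discretized
#' Gaussian. Variant `"task1"` rewards every trial; variant `"task2"` omits the
#' reward on a fraction `p_omission` of trials, making the post-odor state
#' ambiguous. Time is discrete; one step corresponds to 200 ms (stored as
#' metadata only).
#'
#' @param variant `"task1"` (no omissions) or `"task2"` (10% omissions).
#' @param p_iti Per-step odor hazard once the minimum intertrial interval has
#'   elapsed. The ITI is `iti_min + G` with `G ~ Geometric(p_iti)` on
#'   \{1, 2, ...\}, so the minimum realizable ITI is `iti_min + 1` steps.
#' @param iti_min Deterministic portion of the intertrial interval, in steps.
#' @param isi_support Integer vector of possible reward delays (steps).
#' @param isi_mean,isi_sd Mean and standard deviation of the Gaussian that is
#'   discretized over `isi_support`.
#' @param p_omission Probability a trial's reward is withheld. Defaults to 0
#'   for `"task1"` and 0.1 for `"task2"`.
#' @param reward_size Magnitude of a delivered reward.
#'
#' @return An object of class `stark_config`.
#' @seealso [generate_session()], [build_starkweather_space()]
#' @export
starkweather_config <- function(variant = c("task1", "task2"),
                                p_iti = 1 / 8, iti_min = 10L,
                                isi_support = 6:14,
                                isi_mean = 10, isi_sd = 2.5,
                                p_omission = NULL,
                                reward_size = 1) {
  variant <- match.arg(variant)
  if (is.null(p_omission)) {
    p_omission <- if (variant == "task1") 0 else 0.1
  }
  if (variant == "task1" && p_omission != 0) {
    stop("task1 has no omission trials (p_omission must be 0)")
  }
  if (variant == "task2" && p_omission <= 0) {
    stop("task2 requires p_omission > 0")
  }
  stopifnot(p_iti > 0, p_iti <= 1, iti_min >= 0,
            all(isi_support >= 1), !is.unsorted(isi_support),
            isi_sd > 0, reward_size > 0)
  structure(list(task = "starkweather", variant = variant,
                 p_iti = p_iti, iti_min = as.integer(iti_min),
                 isi_support = as.integer(isi_support),
                 isi_mean = isi_mean, isi_sd = isi_sd,
                 p_omission = p_omission, reward_size = reward_size,
                 time_bin_ms = 200),
            class = c("stark_config", "task_config"))
}

#' Configuration for the Babayan block task
#'
#' Every trial is rewarded, but the reward magnitude is set by a hidden block
#' identity that is resampled uniformly every `block_len` trials: block 1
#' delivers `block_rewards[1]`, block 2 delivers `block_rewards[2]`. Reward
#' delays are uniform over `isi_support`. Probe sessions additionally mix in
#' blocks of intermediate reward magnitudes.
#'
#' @param block_rewards Length-2 numeric, the block 1 / block 2 reward sizes.
#' @param block_len Trials per block.
#' @param isi_support Integer vector of possible reward delays (uniform).
#' @param p_iti,iti_min As in [starkweather_config()].
#' @param probe_enabled If `TRUE`, block rewards are drawn from
#'   `probe_rewards` with `probe_weights`; the standard magnitudes dominate
#'   the mixture (~90% of trials).
#' @param probe_rewards,probe_weights Probe-block reward magnitudes and their
#'   mixture weights (must sum to 1; the two standard magnitudes must be
#'   included).
#'
#' @return An object of class `babayan_config`.
#' @export
babayan_config <- function(block_rewards = c(1, 10), block_len = 5L,
                           isi_support = 9:11,
                           p_iti = 1 / 8, iti_min = 10L,
                           probe_enabled = FALSE,
                           probe_rewards = c(1, 2, 4, 6, 8, 10),
                           probe_weights = c(0.45, 0.025, 0.025, 0.025, 0.025, 0.45)) {
  stopifnot(length(block_rewards) == 2, block_rewards[1] != block_rewards[2],
            block_len >= 1, all(isi_support >= 1),
            p_iti > 0, p_iti <= 1,
            length(probe_rewards) == length(probe_weights),
            abs(sum(probe_weights) - 1) < 1e-12,
            all(block_rewards %in% probe_rewards))
  structure(list(task = "babayan",
                 block_rewards = block_rewards,
                 block_len = as.integer(block_len),
                 isi_support = as.integer(isi_support),
                 p_iti = p_iti, iti_min = as.integer(iti_min),
                 probe_enabled = probe_enabled,
                 probe_rewards = probe_rewards,
                 probe_weights = probe_weights,
                 time_bin_ms = 200),
            class = c("babayan_config", "task_config"))
}

#' Interstimulus-interval probability mass function
#'
#' Starkweather tasks use a Gaussian evaluated at the integer support points
#' and renormalized; the Babayan task uses a uniform distribution.
#'
#' @param config A task configuration.
#' @return Named numeric vector of probabilities over `config$isi_support`.
#' @export
isi_pmf <- function(config) {
  s <- config$isi_support
  if (inherits(config, "stark_config")) {
    p <- stats::dnorm(s, mean = config$isi_mean, sd = config$isi_sd)
  } else {
    p <- rep(1, length(s))
  }
  p <- p / sum(p)
  names(p) <- s
  p
}

#' Sample intertrial intervals
#'
#' `t_ITI = iti_min + G` with `G ~ Geometric(p_iti)` supported on \{1, 2, ...\}
#' (at least one step in the hazard state, so the minimum ITI is
#' `iti_min + 1`). Draws use R's global RNG.
#'
#' @param config A task configuration.
#' @param n Number of draws.
#' @return Integer vector of ITIs in steps.
#' @export
sample_iti <- function(config, n = 1) {
  config$iti_min + 1L + stats::rgeom(n, config$p_iti)
}

#' Sample interstimulus intervals
#'
#' @inheritParams sample_iti
#' @return Integer vector of reward delays in steps.
#' @export
sample_isi <- function(config, n = 1) {
  p <- isi_pmf(config)
  config$isi_support[sample.int(length(p), n, replace = TRUE, prob = p)]
}

## Micro-state label bookkeeping. ISI micro-states are 1..max(isi_support);
## ITI micro-states continue to K, with the last one absorbing. A reward (or,
## in Task 2, an omission odor) enters the first ITI micro-state; null steps
## then advance deterministically until the absorbing state.
n_isi_states <- function(config) max(config$isi_support)
n_states <- function(config) n_isi_states(config) + config$iti_min + 1L

#' Generate a session of concatenated trials
#'
#' Emits the per-time-step observation table for `n_trials` concatenated
#' trials: intertrial nulls, one odor, interstimulus nulls, then a reward
#' (unless the trial is an omission trial). Ground-truth micro-state labels
#' are attached; on omission trials the agent's true state re-enters the
#' intertrial progression at the odor (there is no "omission ISI" state).
#' For the Babayan task the hidden block identity is resampled every
#' `block_len` trials and the labels live in the 2 x K composite space
#' (block 2 states are offset by K).
#'
#' @param config A task configuration from [starkweather_config()] or
#'   [babayan_config()].
#' @param n_trials Number of trials.
#' @param seed Optional integer seed (sets the global RNG; recorded in the
#'   session metadata).
#' @return A `data.frame` of class `cond_session` with columns `t`, `odor`,
#'   `reward`, `state`, `trial_index`, `block_id`, and attributes `trials`
#'   (per-trial metadata), `config`, and `seed`.
#' @export
generate_session <- function(config, n_trials, seed = NULL) {
  if (!inherits(config, "task_config")) stop("invalid task configuration")
  stopifnot(n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)

  babayan <- inherits(config, "babayan_config")
  itis <- sample_iti(config, n_trials)
  isis <- sample_isi(config, n_trials)
  if (babayan) {
    n_blocks <- ceiling(n_trials / config$block_len)
    if (config$probe_enabled) {
      br <- config$probe_rewards[sample.int(length(config$probe_rewards),
                                            n_blocks, replace = TRUE,
                                            prob = config$probe_weights)]
    } else {
      br <- config$block_rewards[sample.int(2L, n_blocks, replace = TRUE)]
    }
    block_of_trial <- rep(seq_len(n_blocks), each = config$block_len)[seq_len(n_trials)]
    reward_of_trial <- br[block_of_trial]
    omit <- rep(FALSE, n_trials)
  } else {
    block_of_trial <- rep(NA_integer_, n_trials)
    reward_of_trial <- rep(config$reward_size, n_trials)
    omit <- stats::runif(n_trials) < config$p_omission
  }

  n_isi <- n_isi_states(config)
  K <- n_states(config)
  iti_entry <- n_isi + 1L          # first ITI micro-state (post-reward)

  ## per trial: (iti-1) nulls + odor + (isi-1) nulls + reward   [rewarded]
  ##            (iti-1) nulls + odor + isi nulls                [omission]
  total <- sum(itis - 1L) + n_trials + sum(ifelse(omit, isis, isis - 1L)) + sum(!omit)
  odor <- integer(total); reward <- numeric(total); state <- integer(total)
  trial_index <- integer(total)

  blk_off <- function(b) if (babayan) (b - 1L) * K else 0L
  ## block used for ground-truth labels; probe blocks take the nearer magnitude
  label_block <- if (babayan) {
    ifelse(abs(reward_of_trial - config$block_rewards[1]) <=
             abs(reward_of_trial - config$block_rewards[2]), 1L, 2L)
  } else rep(1L, n_trials)

  ## `pos` tracks steps since the state last entered the ITI progression; it
  ## carries across omission trials so the micro-state sequence stays
  ## consistent with the transition model. Babayan labels use the current
  ## trial's true block throughout the trial (only the copy offset jumps at a
  ## block boundary; the within-copy micro progression is continuous).
  ## Sessions begin in the absorbing ITI state (matching the initial belief),
  ## so the first trial's pre-odor labels sit at the absorbing state.
  pos <- K
  i <- 0L
  for (tr in seq_len(n_trials)) {
    off <- blk_off(label_block[tr])
    for (j in seq_len(itis[tr] - 1L)) {
      i <- i + 1L
      state[i] <- off + min(iti_entry + pos, K)
      trial_index[i] <- tr
      pos <- pos + 1L
    }
    i <- i + 1L                       # odor step
    odor[i] <- 1L
    trial_index[i] <- tr
    if (omit[tr]) {
      state[i] <- off + iti_entry
      pos <- 1L
      for (j in seq_len(isis[tr])) {
        i <- i + 1L
        state[i] <- off + min(iti_entry + pos, K)
        trial_index[i] <- tr
        pos <- pos + 1L
      }
    } else {
      state[i] <- off + 1L
      for (j in seq_len(isis[tr] - 1L)) {
        i <- i + 1L
        state[i] <- off + 1L + j
        trial_index[i] <- tr
      }
      i <- i + 1L                     # reward step
      reward[i] <- reward_of_trial[tr]
      state[i] <- off + iti_entry
      trial_index[i] <- tr
      pos <- 1L
    }
  }
  stopifnot(i == total)

  trials <- data.frame(trial_index = seq_len(n_trials),
                       iti = itis, isi = isis,
                       reward_size = ifelse(omit, 0, reward_of_trial),
                       omission = omit,
                       block_id = block_of_trial,
                       block_reward = if (babayan) reward_of_trial else NA_real_)
  out <- data.frame(t = seq_len(total), odor = odor, reward = reward,
                    state = state, trial_index = trial_index,
                    block_id = if (babayan) block_of_trial[trial_index]
                               else NA_integer_)
  structure(out, trials = trials, config = config,
            seed = if (is.null(seed)) NA_integer_ else seed,
            class = c("cond_session", "data.frame"))
}

#' @export
print.cond_session <- function(x, ...) {
  cfg <- attr(x, "config")
  tr <- attr(x, "trials")
  cat(sprintf("<cond_session> %s%s: %d trials, %d time steps (%d rewarded)\n",
              cfg$task,
              if (!is.null(cfg$variant)) paste0("/", cfg$variant) else "",
              nrow(tr), nrow(x), sum(tr$reward_size > 0)))
  invisible(x)
}

#' Observation matrix of a session
#'
#' @param session A `cond_session`.
#' @return A `T x 2` matrix with columns (odor, reward) — the observation
#'   vector `o_t` fed to value models.
#' @export
session_observations <- function(session) {
  cbind(odor = session$odor, reward = session$reward)
}

#' Write / read a session as CSV plus a JSON sidecar
#'
#' The CSV holds the per-step table; the sidecar records the task
#' configuration, the seed, and the per-trial metadata, so the round trip is
#' lossless.
#'
#' @param session A `cond_session`.
#' @param path CSV path; the sidecar is written next to it as `<path>.json`.
#' @return `write_session` returns `path` invisibly; `read_session` returns
#'   the reconstructed `cond_session`.
#' @export
write_session <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
  cfg <- attr(session, "config")
  side <- list(config = unclass(cfg),
               config_class = class(cfg),
               seed = attr(session, "seed"),
               trials = attr(session, "trials"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  tab <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- side$config
  cfg$isi_support <- as.integer(cfg$isi_support)
  class(cfg) <- side$config_class
  trials <- as.data.frame(side$trials)
  trials$block_id <- as.integer(trials$block_id)
  structure(tab, trials = trials, config = cfg,
            seed = if (is.null(side$seed)) NA_integer_ else side$seed,
            class = c("cond_session", "data.frame"))
}
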