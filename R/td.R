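## Value estimation on an arbitrary representation: LSTD readout fitting,
## value traces, TD errors, and per-trial RPE summaries.
##
## Index convention: rewards ride on transitions. The TD error attributed to
## the transition t -> t+1 is
##     delta_t = r_{t+1} + gamma * V_{t+1} - V_t,
## so the RPE "at reward" on a trial is the delta of the transition that
## delivers the reward, computed from the pre-reward value. (Reading the
## textbook form delta_t = r_t + gamma*V_{t+1} - V_t with r_t paired to the
## same-step posterior representation would make the converged reward-time
## RPE identically zero, since the post-reward state already accounts for its
## own reward.) LSTD uses the matching pairing, so its fixed point satisfies
## E[delta_t | z_t] = 0.

#' Fit a linear value readout by least-squares TD
#'
#' Solves `w = D^{-1} d` with `D = sum_t z_t (z_t - gamma z_{t+1})'` and
#' `d = sum_t r_{t+1} z_t`, the closed-form TD fixed point for a linear value
#' function on features `Z`. With `intercept = TRUE` a constant-1 feature is
#' appended so the offset `w0` is estimated jointly; for simplex-valued
#' features (beliefs) the constant is already in the feature span, so use
#' `intercept = FALSE`.
#'
#' @param Z `T x D` representation matrix (rows are time steps).
#' @param rewards Length-`T` reward vector aligned with the rows of `Z`.
#' @param gamma Discount factor in `[0, 1)`.
#' @param intercept Append a constant-1 feature (default `TRUE`).
#' @param ridge Optional nonnegative ridge added to the diagonal of `D` (in
#'   units of the mean diagonal); default 0. With `ridge = 0` a rank-deficient
#'   `D` is an error rather than a silent pseudo-inverse.
#' @param rep_name Label used in error messages.
#' @return A `value_readout`: list with `w`, `w0`, `gamma`, `intercept`.
#' @export
lstd_fit <- function(Z, rewards, gamma, intercept = TRUE, ridge = 0,
                     rep_name = "representation") {
  Z <- as.matrix(Z)
  Tlen <- nrow(Z)
  stopifnot(Tlen >= 2, length(rewards) == Tlen, gamma >= 0, gamma < 1)
  if (intercept) Z <- cbind(Z, 1)
  Zt <- Z[-Tlen, , drop = FALSE]
  Zn <- Z[-1, , drop = FALSE]
  D <- crossprod(Zt, Zt - gamma * Zn)
  d <- crossprod(Zt, rewards[-1])
  if (ridge > 0) {
    D <- D + diag(ridge * mean(diag(D)), ncol(D))
  } else {
    ## flag (near-)exact singularity only; merely ill-conditioned systems
    ## (e.g. weakly driven units) remain solvable in double precision
    qrD <- qr(D, tol = 1e-12)
    if (qrD$rank < ncol(D)) {
      stop(sprintf("LSTD system for %s is rank deficient (rank %d < %d); %s",
                   rep_name, qrD$rank, ncol(D),
                   "drop redundant features, set intercept = FALSE, or use ridge"))
    }
  }
  w <- solve(D, d)
  out <- list(gamma = gamma, intercept = intercept)
  if (intercept) {
    out$w <- w[-length(w)]
    out$w0 <- w[length(w)]
  } else {
    out$w <- as.vector(w)
    out$w0 <- 0
  }
  structure(out, class = "value_readout")
}

#' Value trace of a readout on a representation
#'
#' @param readout A `value_readout` from [lstd_fit()] (or a list with `w`,
#'   `w0`).
#' @param Z `T x D` representation matrix.
#' @return Numeric vector `V_t = z_t' w + w0`.
#' @export
value_trace <- function(readout, Z) {
  as.vector(as.matrix(Z) %*% readout$w) + readout$w0
}

#' Temporal-difference errors of a value trace
#'
#' `delta_t = r_{t+1} + gamma * V_{t+1} - V_t` for `t = 1..T-1` (the final
#' step has no successor and is dropped). `delta[t]` is the TD error of the
#' transition `t -> t+1`; a reward observed at step `t+1` therefore appears
#' in `delta[t]` together with the pre-reward value `V_t`.
#'
#' @param values Length-`T` value trace.
#' @param rewards Length-`T` reward vector.
#' @param gamma Discount factor.
#' @return An `rpe_trace`: list with `delta` (length `T-1`) and `gamma`.
#' @export
td_errors <- function(values, rewards, gamma) {
  Tlen <- length(values)
  stopifnot(Tlen >= 2, length(rewards) == Tlen)
  delta <- rewards[-1] + gamma * values[-1] - values[-Tlen]
  structure(list(delta = delta, gamma = gamma), class = "rpe_trace")
}

## delta index carrying the reward of step i is i - 1
reward_delta_index <- function(session) {
  idx <- which(session$reward > 0) - 1L
  idx[idx >= 1L]
}

#' Per-trial RPEs at reward delivery
#'
#' @param session A `cond_session`.
#' @param rpes An `rpe_trace` computed on that session.
#' @return Data frame with one row per rewarded trial: `trial_index`, `isi`,
#'   `block_id`, `rpe`.
#' @export
rpe_at_reward <- function(session, rpes) {
  idx <- reward_delta_index(session)
  tr_ids <- session$trial_index[idx + 1L]
  trials <- attr(session, "trials")
  data.frame(trial_index = tr_ids,
             isi = trials$isi[tr_ids],
             block_id = trials$block_id[tr_ids],
             rpe = rpes$delta[idx])
}

#' Mean squared RPE error between a model and the belief model
#'
#' Mean over rewarded trials of the squared difference between the two
#' models' TD errors at the reward-delivery step, both evaluated on the same
#' session.
#'
#' @param session The shared evaluation session.
#' @param model_rpes,belief_rpes `rpe_trace` objects for the model and the
#'   belief reference.
#' @return Scalar MSE.
#' @export
rpe_mse <- function(session, model_rpes, belief_rpes) {
  idx <- reward_delta_index(session)
  if (length(idx) == 0) stop("session contains no rewarded trials")
  mean((model_rpes$delta[idx] - belief_rpes$delta[idx])^2)
}

#' Summarize RPEs by task condition
#'
#' Starkweather sessions: mean RPE at reward grouped by reward time (ISI).
#' Babayan sessions: mean RPE at odor and at reward grouped by the trial's
#' index within its block and the (previous block, current block) pair.
#'
#' @param session A `cond_session`.
#' @param rpes An `rpe_trace` for that session.
#' @return A tidy data frame with columns `group` variables, `mean`, `sem`,
#'   `n`.
#' @export
rpe_summaries <- function(session, rpes) {
  cfg <- attr(session, "config")
  summarize_by <- function(df, keys) {
    agg <- stats::aggregate(df$value, df[keys],
                            function(v) c(mean = mean(v),
                                          sem = stats::sd(v) / sqrt(length(v)),
                                          n = length(v)))
    out <- cbind(agg[keys], as.data.frame(agg$x))
    out$sem[is.na(out$sem)] <- 0
    out
  }
  if (cfg$task == "starkweather") {
    at_rw <- rpe_at_reward(session, rpes)
    df <- data.frame(isi = at_rw$isi, value = at_rw$rpe)
    summarize_by(df, "isi")
  } else {
    trials <- attr(session, "trials")
    n_blk <- max(trials$block_id)
    trials$trial_in_block <- trials$trial_index -
      (trials$block_id - 1L) * cfg$block_len
    blk_reward <- trials$block_reward[!duplicated(trials$block_id)]
    trials$cur_reward <- blk_reward[trials$block_id]
    trials$prev_reward <- c(NA, blk_reward)[trials$block_id]

    odor_idx <- which(session$odor > 0) - 1L
    odor_idx <- odor_idx[odor_idx >= 1L]
    odor_tr <- session$trial_index[odor_idx + 1L]
    rw <- rpe_at_reward(session, rpes)
    df <- rbind(
      data.frame(event = "odor", trial_index = odor_tr,
                 value = rpes$delta[odor_idx]),
      data.frame(event = "reward", trial_index = rw$trial_index,
                 value = rw$rpe))
    df <- merge(df, trials[, c("trial_index", "trial_in_block",
                               "cur_reward", "prev_reward")],
                by = "trial_index")
    df <- df[!is.na(df$prev_reward), ]
    summarize_by(df, c("event", "trial_in_block", "prev_reward", "cur_reward"))
  }
}

#' Write RPE summary curves as tidy CSV
#'
#' @param curves Output of [rpe_summaries()].
#' @param path CSV path.
#' @export
write_rpe_curves <- function(curves, path) {
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
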