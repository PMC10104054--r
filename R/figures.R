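## Figure regeneration from stored cohort/sweep results: RPE-by-reward-time
## curves, before/after training metric dots, memory distance traces,
## capacity sweeps, and ESN gain sweeps. ggplot2 is suggested, not imported.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("figure regeneration requires the ggplot2 package")
  }
}

#' RPE-by-reward-time curves (belief model vs. a network)
#'
#' @param ds A [probe_datasets()] bundle (Starkweather tasks).
#' @param model Optional `value_rnn` to overlay (solid) against the belief
#'   model (dashed).
#' @return A ggplot object.
#' @export
plot_rpe_by_reward_time <- function(ds, model = NULL) {
  need_ggplot()
  curves <- rpe_summaries(ds$eval_session, ds$belief_rpes)
  curves$model <- "beliefs"
  if (!is.null(model)) {
    fwd <- rnn_forward(model, ds$fit_session)
    Zf <- inject_noise(fwd$Z, seed = 1)
    ro <- lstd_fit(Zf, ds$fit_session$reward, ds$gamma)
    Ze <- inject_noise(rnn_forward(model, ds$eval_session)$Z, seed = 2)
    rpes <- td_errors(value_trace(ro, Ze), ds$eval_session$reward, ds$gamma)
    mc <- rpe_summaries(ds$eval_session, rpes)
    mc$model <- sprintf("%s H=%d", model$type, model$H)
    curves <- rbind(curves, mc)
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$isi, y = .data$mean,
                                       color = .data$model,
                                       linetype = .data$model)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = "reward time (steps after odor)",
                  y = "RPE at reward", title = ds$task) +
    ggplot2::theme_classic()
}

#' Dot plot of a cohort metric across conditions
#'
#' @param results Row-bound per-model results (e.g. trained and untrained
#'   cohorts with a `trained` column).
#' @param metric Column to plot.
#' @param by Grouping column on the x axis (default `"trained"`).
#' @return A ggplot object.
#' @export
plot_cohort_metric <- function(results, metric, by = "trained") {
  need_ggplot()
  ggplot2::ggplot(results,
                  ggplot2::aes(x = factor(.data[[by]]), y = .data[[metric]])) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = stats::median, geom = "point", size = 3,
                          shape = 21, fill = "white") +
    ggplot2::labs(x = by, y = metric) +
    ggplot2::theme_classic()
}

#' Normalized distance-from-fixed-point traces after an observation
#'
#' Distances are normalized by their maximum, as in the reference panels.
#'
#' @param traces Named list of `memory_duration` objects.
#' @return A ggplot object.
#' @export
plot_memory_traces <- function(traces) {
  need_ggplot()
  df <- do.call(rbind, lapply(names(traces), function(nm) {
    md <- traces[[nm]]
    data.frame(model = nm, t = seq_along(md$eta),
               eta = md$eta / max(md$eta))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$eta,
                                   color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "steps after observation",
                  y = "normalized squared distance from fixed point") +
    ggplot2::theme_classic()
}

#' ESN gain-sweep panels
#'
#' @param sweep Output of [run_esn_sweep()].
#' @param metric One of `"odor_memory"`, `"rpe_mse"`, `"belief_r2"`.
#' @return A ggplot object.
#' @export
plot_esn_sweep <- function(sweep, metric = "odor_memory") {
  need_ggplot()
  ggplot2::ggplot(sweep$results,
                  ggplot2::aes(x = .data$gain, y = .data[[metric]])) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "ESN gain", y = metric) +
    ggplot2::theme_classic()
}

#' Regenerate figure panels from cohort results
#'
#' Writes the standard panel set for whatever results are supplied; missing
#' inputs are named explicitly.
#'
#' @param results Named list; recognized elements are `ds` (probe datasets),
#'   `example_model`, `cohorts` (row-bound cohort results), `esn_sweep`.
#' @param dir Output directory for PNG files.
#' @return Invisibly, the written file paths.
#' @export
reproduce_figures <- function(results, dir) {
  need_ggplot()
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  save <- function(name, p) {
    path <- file.path(dir, paste0(name, ".png"))
    ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 150)
    written <<- c(written, path)
  }
  if (!is.null(results$ds) && results$ds$task != "babayan") {
    save("rpe_by_reward_time",
         plot_rpe_by_reward_time(results$ds, results$example_model))
  } else if (is.null(results$ds)) {
    message("missing input: ds (probe datasets) - skipping RPE panel")
  }
  if (!is.null(results$cohorts)) {
    for (m in intersect(c("rpe_mse", "belief_r2", "decoder_ll"),
                        names(results$cohorts))) {
      save(paste0("cohort_", m), plot_cohort_metric(results$cohorts, m))
    }
  } else {
    message("missing input: cohorts - skipping cohort panels")
  }
  if (!is.null(results$esn_sweep)) {
    for (m in c("odor_memory", "rpe_mse", "belief_r2")) {
      save(paste0("esn_", m), plot_esn_sweep(results$esn_sweep, m))
    }
  }
  invisible(written)
}
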