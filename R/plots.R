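#' Plot agent trajectories (one panel per alpha)
#'
#' Position of every agent against time for one realization per
#' social-influence weight, with the landscape's critical levels marked.
#' At alpha = 0 agents cross independently; at small positive alpha a
#' pioneer crossing triggers the swift follow-the-leader migration.
#'
#' @param records A named list of [simulate_trajectory()] results recorded
#'   with `record_every > 0`; names (or the stored alpha) label the panels.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(records) {
  if (inherits(records, "trajectory_record")) records <- list(records)
  if (length(records) == 0L)
    stop("no trajectories supplied", call. = FALSE)
  tabs <- lapply(records, function(r) {
    tt <- trajectory_table(r)
    tt$alpha <- r$params$alpha
    tt
  })
  dat <- do.call(rbind, tabs)
  if (!all(c("time", "agent_id", "position") %in% names(dat)))
    stop("trajectory table lacks required columns", call. = FALSE)
  ls <- quartic_landscape()
  cp <- critical_points(ls)
  ggplot2::ggplot(dat, ggplot2::aes(
      x = .data$time, y = .data$position,
      group = .data$agent_id)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = c(cp$x_old, cp$x_barrier, cp$x_new),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~alpha, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time", y = "position x") +
    ggplot2::theme_minimal()
}

#' Plot the mean shift-time curve (one curve per population size)
#'
#' Mean community shift time against the social-influence weight alpha,
#' with standard-error bars, one curve per n. The three-regime shape —
#' decrease, increase, decrease — is the model's signature.
#'
#' @param sweep A [alpha_sweep()] result.
#' @param log_y Log-scale the time axis (default TRUE; shift times are
#'   right-skewed).
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep, log_y = TRUE) {
  stopifnot(inherits(sweep, "sweep_result"))
  tab <- sweep$table
  if (nrow(tab) == 0L) stop("empty sweep table", call. = FALSE)
  tab$n <- factor(tab$n)
  p <- ggplot2::ggplot(tab, ggplot2::aes(
      x = .data$alpha, y = .data$mean_ts,
      colour = .data$n, group = .data$n)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_ts - .data$se_ts,
      ymax = .data$mean_ts + .data$se_ts), width = 0.01) +
    ggplot2::labs(x = expression(alpha~"(weight on social influence)"),
                  y = "mean time to paradigm shift", colour = "n") +
    ggplot2::theme_minimal()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @importFrom rlang .data
NULL
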