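#' Plot a participant's CRP ensemble
#'
#' Per-cycle CRP waveforms with the ensemble mean and a +/- 1 SD ribbon,
#' over the gait cycle.
#'
#' @param object a [crp_ensemble()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.crp_ensemble <- function(object, ...) {
  cyc <- tibble::tibble(
    cycle = rep(seq_len(nrow(object$cycles)), each = 101L),
    pct = rep(seq(0, 100, length.out = 101L), nrow(object$cycles)),
    crp_deg = as.vector(t(object$cycles))
  )
  ggplot2::ggplot(object$curves, ggplot2::aes(x = .data$pct)) +
    ggplot2::geom_line(data = cyc,
                       ggplot2::aes(y = .data$crp_deg, group = .data$cycle),
                       colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$crp_mean_deg - .data$crp_sd_deg,
      ymax = .data$crp_mean_deg + .data$crp_sd_deg), alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$crp_mean_deg), linewidth = 0.9) +
    ggplot2::labs(x = "Gait cycle (%)", y = "CRP (deg)",
                  title = sprintf("%s %s: MARP %.1f deg, DP %s",
                                  object$participant, object$speed_cond,
                                  object$marp_deg,
                                  ifelse(is.na(object$dp_deg), "NA",
                                         sprintf("%.1f deg", object$dp_deg)))) +
    ggplot2::theme_minimal()
}

#' Plot an SPM t-trace with its critical threshold
#'
#' The pointwise t statistic over the gait cycle with the permutation
#' critical threshold `t*` as dashed lines and supra-threshold clusters
#' shaded.
#'
#' @param object an [spm_ttest2()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.spm_result <- function(object, ...) {
  d <- tidy(object)
  gg <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$t)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = c(-object$t_star, object$t_star),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "Gait cycle (%)", y = "SPM {t}",
                  subtitle = sprintf("t* = %.2f (alpha = %.2f, %d permutations)",
                                     object$t_star, object$alpha, object$n_perm)) +
    ggplot2::theme_minimal()
  if (nrow(object$clusters) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = object$clusters, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_pct, xmax = .data$end_pct,
                   ymin = -Inf, ymax = Inf),
      fill = "red", alpha = 0.12)
  }
  gg
}

#' Group ensemble CRP curves by speed condition
#'
#' Group mean +/- 1 SD of the participant ensemble CRP curves, one panel
#' per speed condition.
#'
#' @param curves the `curves` tibble of a [analyze_cohort()] result.
#' @return a ggplot object.
#' @export
plot_group_curves <- function(curves) {
  gm <- dplyr::summarise(
    dplyr::group_by(curves, .data$group, .data$speed_cond, .data$pct),
    m = mean(.data$crp_mean_deg), s = stats::sd(.data$crp_mean_deg),
    .groups = "drop")
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$pct, y = .data$m,
                                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$m - .data$s,
                                      ymax = .data$m + .data$s),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(linewidth = 0.9) +
    ggplot2::facet_wrap(~speed_cond) +
    ggplot2::labs(x = "Gait cycle (%)", y = "CRP (deg)",
                  colour = "Group", fill = "Group") +
    ggplot2::theme_minimal()
}

#' Panel of SPM traces
#'
#' @param spm_list named list of [spm_ttest2()] results (as produced by
#'   [gait_group_stats()]).
#' @return a ggplot object faceted by comparison.
#' @export
plot_spm_panels <- function(spm_list) {
  d <- purrr::imap_dfr(spm_list, function(s, nm) {
    dplyr::mutate(tidy(s), comparison = nm)
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$t)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$t_star), linetype = "dashed",
                       colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = -.data$t_star), linetype = "dashed",
                       colour = "red") +
    ggplot2::facet_wrap(~comparison) +
    ggplot2::labs(x = "Gait cycle (%)", y = "SPM {t}") +
    ggplot2::theme_minimal()
}
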