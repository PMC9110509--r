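# ggplot2 visualisations: stratified conditional Q-Q curves, conditional and
# conjunction Manhattan plots, locus posterior plots, MR scatter.

#' @export
autoplot.qq_strata <- function(object, ...) {
  curves <- object$curves
  curves$stratum <- factor(
    ifelse(curves$threshold >= 1, "all SNPs",
           sprintf("p < %g", curves$threshold)),
    levels = unique(ifelse(curves$threshold >= 1, "all SNPs",
                           sprintf("p < %g", curves$threshold)))
  )
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$neglog_q, y = .data$neglog_p,
                               colour = .data$stratum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression("empirical" ~ -log[10] (q)),
      y = expression("nominal" ~ -log[10] (p)),
      colour = "conditional stratum",
      title = sprintf("Stratified conditional Q-Q, principal trait %d",
                      object$principal)
    ) +
    ggplot2::theme_minimal()
}

#' Stratified conditional Q-Q plot
#' @param data A `merged_pair`.
#' @param principal Principal trait slot (1 or 2).
#' @param ... Passed to [stratified_qq()].
#' @return A ggplot.
#' @export
plot_qq <- function(data, principal = 1, ...) {
  autoplot(stratified_qq(data, principal = principal, ...))
}

#' @export
autoplot.cfdr_tbl <- function(object,
                              mode = c("conjunction", "cfdr_1_given_2",
                                       "cfdr_2_given_1"), ...) {
  mode <- match.arg(mode)
  md <- manhattan_data(object, mode = mode)
  centers <- attr(md, "chrom_centers", exact = TRUE)
  ggplot2::ggplot(md, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = factor(.data$chrom_index %% 2))) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(md, "ref_line", exact = TRUE),
                        colour = "red") +
    ggplot2::scale_colour_manual(values = c("grey30", "steelblue")) +
    ggplot2::scale_x_continuous(breaks = centers$center,
                                labels = centers$chrom) +
    ggplot2::labs(x = "chromosome",
                  y = sprintf("-log10 %s",
                              if (mode == "conjunction") "ccFDR" else "cFDR")) +
    ggplot2::theme_minimal()
}

#' Conditional or conjunction Manhattan plot
#' @param records A `cfdr_tbl`.
#' @param mode See [manhattan_data()].
#' @return A ggplot with the reference line at `-log10(0.05) = 1.3`.
#' @export
plot_manhattan <- function(records, mode = "conjunction") {
  autoplot.cfdr_tbl(records, mode = mode)
}

#' @export
autoplot.finemap_result <- function(object, ...) {
  map_id <- attr(object, "map_snp", exact = TRUE)
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$pos, y = .data$posterior)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0),
                          colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$snp_id == map_id),
                        show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "position (bp)", y = "posterior probability of causality") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.mr_fit <- function(object, ...) {
  inst <- object$instruments
  ggplot2::ggplot(inst, ggplot2::aes(x = .data$beta_x, y = .data$beta_y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_y - .data$se_y,
                                        ymax = .data$beta_y + .data$se_y),
                           colour = "grey70", width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_x - .data$se_x,
                                         xmax = .data$beta_x + .data$se_x),
                            colour = "grey70", height = 0) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$estimate, intercept = 0,
                         colour = "red") +
    ggplot2::labs(x = "exposure association (beta_x)",
                  y = "outcome association (beta_y)",
                  title = sprintf("%s causal estimate = %.3g", object$method,
                                  object$estimate)) +
    ggplot2::theme_minimal()
}
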