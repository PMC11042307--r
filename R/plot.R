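# ggplot2 views of the package's result objects. The TSV exports are the
# contract; these plots are conveniences for inspection.

#' Plot a genetic path
#'
#' Two panels: the cumulative path `theta(i)` with its null line, and the
#' anchored difference `delta(i)`. A paraboloid `delta` (one dominant
#' interior extremum) signals a constant allelic effect; a sigmoid `delta`
#' (interior zero crossing) signals a scale-dependent one.
#'
#' @param object A `"gift_path"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gift_path <- function(object, ...) {
  df <- object$path |>
    tidyr::pivot_longer(c("theta", "delta"), names_to = "panel",
                        values_to = "value") |>
    dplyr::mutate(panel = factor(.data$panel, levels = c("theta", "delta"),
                                 labels = c("theta(i)", "delta(i)")))
  null_df <- tibble::tibble(
    position = object$path$position,
    value = object$slope * object$path$position,
    panel = factor("theta(i)", levels = c("theta(i)", "delta(i)"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$value)) +
    ggplot2::geom_line(data = null_df, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(
      data = tibble::tibble(panel = factor("delta(i)",
                                           levels = c("theta(i)", "delta(i)"))),
      ggplot2::aes(yintercept = 0), linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "position in residual-ranked string",
      y = NULL,
      title = object$snp_id %||% "genetic path"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a permutation-null envelope
#'
#' Mean null path with a plus/minus two standard deviation band; the
#' analytic closed-form sd is overlaid for reference.
#'
#' @param object A `"gift_null_ensemble"` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gift_null_ensemble <- function(object, ...) {
  df <- object$summary
  counts <- c(object$counts$n_plus, object$counts$n_zero, object$counts$n_minus)
  df$sd_analytic <- sqrt(null_variance(counts, df$position))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - 2 * .data$sd,
                   ymax = .data$mean + 2 * .data$sd),
      fill = "grey80"
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean + 2 * .data$sd_analytic),
                       linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean - 2 * .data$sd_analytic),
                       linetype = "dotted") +
    ggplot2::labs(x = "position", y = "null path theta0(i)",
                  title = paste0("permutation null envelope (K = ", object$K, ")")) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of a scan
#'
#' `-log10 p_hat` (path statistic) or `-log10 p` of the OLS baseline per
#' SNP, coloured by chromosome, with optional significance lines.
#'
#' @param object A `"gift_scan"` tibble.
#' @param method `"gift"` (default) or `"gwas"`.
#' @param thresholds Optional `"gift_thresholds"` (drawn for
#'   `method = "gift"`).
#' @param bonferroni Optional numeric `-log10` line(s) for
#'   `method = "gwas"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gift_scan <- function(object, method = c("gift", "gwas"),
                               thresholds = NULL, bonferroni = NULL, ...) {
  method <- match.arg(method)
  ycol <- if (method == "gift") "mlog10_p_hat" else "mlog10_p_gwas"
  df <- dplyr::filter(object, !is.na(.data[[ycol]])) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(index = dplyr::row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data[[ycol]],
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(
      x = "SNP index",
      y = paste0("-log10 p (", method, ")"),
      title = paste("Manhattan plot,", method)
    ) +
    ggplot2::theme_minimal()
  if (method == "gift" && !is.null(thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$level95,
                          linetype = "dashed", colour = "red") +
      ggplot2::geom_hline(yintercept = thresholds$level99,
                          linetype = "dashed", colour = "darkred")
  }
  if (method == "gwas" && !is.null(bonferroni)) {
    p <- p + ggplot2::geom_hline(yintercept = bonferroni,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Group-mean view of one SNP
#'
#' Residuals stratified by microstate with group means -- the
#' mean-comparison picture a conventional single-marker test sees.
#'
#' @param residuals Numeric residuals.
#' @param microstate Integer microstates.
#' @return A ggplot.
#' @export
plot_group_means <- function(residuals, microstate) {
  keep <- !is.na(microstate)
  df <- tibble::tibble(
    microstate = factor(microstate[keep], levels = c(-1, 0, 1)),
    residual = residuals[keep]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$microstate, y = .data$residual)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.5,
                          colour = "red") +
    ggplot2::labs(x = "microstate", y = "phenotypic residual") +
    ggplot2::theme_minimal()
}
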