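#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a minP null distribution
#'
#' ECDF of the minimum p-value over replicates on a log axis, with the
#' threshold at `alpha` marked: the visual form of the
#' threshold-to-alpha mapping every correction is judged by.
#'
#' @param object A `minp_null` object.
#' @param alpha Level to mark (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.minp_null <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  thr <- null_threshold(object, alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$min_p)) +
    ggplot2::stat_ecdf() +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "minimum p-value per replicate",
      y = "cumulative fraction of replicates",
      title = sprintf("%s minP null (B = %d)",
                      attr(object, "method"), attr(object, "B")),
      subtitle = sprintf("alpha = %.2g threshold = %.3g", alpha, thr)
    )
}

#' Plot an LD block partition
#'
#' Block spans along the SNP index, one horizontal segment per block;
#' singleton SNPs appear as points.
#'
#' @param object An `ld_partition` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ld_partition <- function(object, ...) {
  blk <- tidy(object)
  covered <- rep(FALSE, object$n_snps)
  for (i in seq_len(nrow(blk))) covered[blk$start_index[i]:blk$end_index[i]] <- TRUE
  singles <- tibble::tibble(idx = which(!covered))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = blk,
      ggplot2::aes(x = .data$start_index, xend = .data$end_index,
                   y = 1, yend = 1),
      linewidth = 3
    ) +
    ggplot2::geom_point(
      data = singles, ggplot2::aes(x = .data$idx, y = 1),
      shape = 124, size = 2
    ) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(
      x = "SNP index",
      title = sprintf("%s: %d blocks + %d singletons",
                      object$algorithm, nrow(blk), n_singletons(object))
    )
}

#' Plot a method comparison
#'
#' Corresponding study-wide alpha per method, with the nominal level
#' marked; bars above the line are anti-conservative corrections.
#'
#' @param object A `threshold_comparison` from [compare_methods()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$method, .data$corresponding_alpha),
    y = .data$corresponding_alpha
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$alpha), linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~alpha, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "corresponding study-wide alpha",
      title = "Corrections gauged against the permutation minP null"
    )
}
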