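#' Depth profile for a coverage report
#'
#' @param object A `pf_coverage` report.
#' @param ... Unused.
#' @return A ggplot of per-base depth with the breadth annotated.
#' @export
autoplot.pf_coverage <- function(object, ...) {
  depth <- object$depth[[1]]
  df <- tibble::tibble(pos = seq_along(depth), depth = depth)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "steelblue") +
    ggplot2::labs(
      x = "position (bp)", y = "depth",
      title = object$ref_id,
      subtitle = sprintf("BoC %.1f%%, mean depth %.1fx",
                         object$breadth, object$mean_depth)
    ) +
    ggplot2::theme_minimal()
}

#' Pre/post-capture coverage comparison plot
#'
#' Side-by-side depth profiles of the same reference before and after
#' capture, annotated with the breadth-of-coverage gain.
#'
#' @param pre,post `pf_coverage` reports on the same reference.
#' @return A ggplot with one facet per dataset.
#' @export
plot_coverage_comparison <- function(pre, post) {
  if (!identical(pre$ref_id, post$ref_id)) {
    rlang::abort("reports must be on the same reference")
  }
  df <- dplyr::bind_rows(
    tibble::tibble(dataset = "pre-capture", pos = seq_len(pre$ref_length),
                   depth = pre$depth[[1]]),
    tibble::tibble(dataset = "post-capture", pos = seq_len(post$ref_length),
                   depth = post$depth[[1]])
  )
  df$dataset <- factor(df$dataset, levels = c("pre-capture", "post-capture"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(ggplot2::aes(fill = .data$dataset), show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("firebrick", "steelblue")) +
    ggplot2::facet_wrap(~dataset, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "position (bp)", y = "depth", title = pre$ref_id,
      subtitle = sprintf("BoC gain %+.1f percentage points", boc_gain(pre, post))
    ) +
    ggplot2::theme_minimal()
}
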