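#' Plot an FHR record
#'
#' @param object An [fhr_record].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fhr_record
#' @export
autoplot.fhr_record <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s / 60, y = .data$fhr_bpm)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "FHR (bpm)",
                  title = object$record_id,
                  subtitle = if (!is.na(object$ph))
                    sprintf("pH %.2f (%s)", object$ph, object$label) else NULL) +
    ggplot2::theme_minimal()
}

#' Plot a recurrence-plot image
#'
#' White marks recurrent pairs, black non-recurrent ones; axes are
#' phase-space point indices.
#'
#' @param object An `rp_image`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rp_image
#' @export
autoplot.rp_image <- function(object, ...) {
  m <- unclass(object)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$value <- m[cbind(df$i, df$j)]
  p <- attr(object, "params")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "j", y = "i", fill = "intensity",
                  title = if (!is.null(p))
                    sprintf("m=%d, tau=%d, k=%d", p$m, p$tau, p$k) else NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot of per-fold Acc/Se/Sp/AUC with across-fold means.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[, c("fold", "accuracy", "sensitivity", "specificity", "auc")],
    -"fold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_hline(
      data = tidyr::pivot_longer(object$summary, dplyr::everything(),
                                 names_to = "metric", values_to = "value"),
      ggplot2::aes(yintercept = .data$value), linetype = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "fold", y = "percent") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
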