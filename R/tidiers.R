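# broom-style tidiers and ggplot2 autoplot methods for fitted result
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the per-trial metrics of a leave-center-out experiment
#'
#' @param x A `cyst_experiment` from [run_radiomics_experiment()].
#' @param ... Unused.
#' @return Long tibble: `trial_id`, `test_n`, `n_features`, `metric`,
#'   `value`.
#' @export
tidy.cyst_experiment <- function(x, ...) {
  tidyr::pivot_longer(
    x$per_trial,
    cols = c("auc", "acc", "sens", "spec", "ppv", "f1"),
    names_to = "metric", values_to = "value"
  )
}

#' One-row summary of a leave-center-out experiment
#'
#' @param x A `cyst_experiment`.
#' @param ... Unused.
#' @return One-row tibble with unweighted (`mean_*`) and test-size-weighted
#'   (`weighted_*`) aggregate metrics plus bookkeeping columns.
#' @export
glance.cyst_experiment <- function(x, ...) {
  agg <- x$aggregate
  wagg <- x$aggregate_weighted
  names(agg) <- paste0("mean_", names(agg))
  names(wagg) <- paste0("weighted_", names(wagg))
  dplyr::bind_cols(
    tibble::tibble(n_trials = nrow(x$per_trial), mode = x$mode, seed = x$seed),
    agg, wagg
  )
}

#' Bar chart of per-trial test metrics
#'
#' @param object A `cyst_experiment`.
#' @param metrics Metrics to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyst_experiment <- function(object, metrics = c("auc", "acc", "f1"), ...) {
  df <- dplyr::filter(tidy(object), .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial_id, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "trial (held-out center)", y = "held-out metric",
                  title = sprintf("%s radiomics, leave-center-out testing", object$mode)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a 2D quality-indicator embedding
#'
#' @param object A `qc_embedding` from [embed_2d()].
#' @param colour Optional grouping vector (e.g. center ids) of matching
#'   length.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.qc_embedding <- function(object, colour = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(colour)) df$group <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2",
                  title = "2D embedding of image-quality indicators") +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = "center")
  }
}
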