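#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_histogram geom_tile labs theme_minimal scale_color_manual
NULL

#' @export
ggplot2::autoplot

#' Plot a column-divergence scan
#'
#' Divergence per reference column; masked columns (seed region, low
#' occupancy) are shown in grey.
#'
#' @param object a [jsd_scan()] result.
#' @param top_n highlight the `top_n` best-ranked columns.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.jsd_scan <- function(object, top_n = 10, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    status = dplyr::case_when(
      masked ~ "masked",
      !is.na(rank) & rank <= top_n ~ "top-ranked",
      TRUE ~ "scored"))
  ggplot(df, aes(x = column, y = jsd, color = status)) +
    geom_point(size = 0.9, na.rm = TRUE) +
    scale_color_manual(values = c(masked = "grey70", scored = "steelblue",
                                  `top-ranked` = "firebrick")) +
    labs(x = "reference column", y = "Jensen-Shannon divergence (bits)",
         color = NULL) +
    theme_minimal()
}

#' Plot a training trace
#'
#' Training and validation negative log-likelihood per evaluation.
#'
#' @param object an `lm_train_report` from [train_lm()] or [train_gnn()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.lm_train_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("train_nll", "val_nll"),
                            names_to = "split", values_to = "nll")
  ggplot(df, aes(x = iteration, y = nll, color = split)) +
    geom_line() +
    labs(x = "iteration", y = "NLL per token", color = NULL) +
    theme_minimal()
}

#' Plot a single-mutant reference distribution
#'
#' Histogram of ddlogP over all single mutants; candidate scores can be
#' marked with vertical lines.
#'
#' @param object a [single_mutant_reference()].
#' @param highlight optional named numeric vector of candidate ddlogP values.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.single_mutant_reference <- function(object, highlight = NULL, ...) {
  p <- ggplot(object$scores, aes(x = ddlogp)) +
    geom_histogram(bins = 60, fill = "steelblue") +
    labs(x = expression(Delta * Delta * "logP"), y = "single mutants") +
    theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::geom_vline(xintercept = unname(highlight),
                                 color = "firebrick", linetype = 2)
  }
  p
}

#' Plot a contact map
#'
#' @param object a `contact_map`.
#' @param ... unused.
#' @return a ggplot with one point per contact.
#' @export
autoplot.contact_map <- function(object, ...) {
  idx <- which(object$M == 1, arr.ind = TRUE)
  df <- tibble(i = idx[, 1], j = idx[, 2])
  ggplot(df, aes(x = j, y = i)) +
    geom_point(shape = 15, size = 0.4) +
    ggplot2::scale_y_reverse() +
    labs(x = "nucleotide", y = "nucleotide",
         title = sprintf("%s contact map (%s = %s)", object$method,
                         names(object$param), object$param)) +
    theme_minimal()
}

#' Plot a diversity curve
#'
#' @param curve the tibble returned by [diversity_curve()].
#' @return a ggplot of cluster counts against identity threshold.
#' @export
plot_diversity_curve <- function(curve) {
  ggplot(curve, aes(x = threshold, y = n_clusters)) +
    geom_line() + geom_point() +
    labs(x = "identity threshold", y = "clusters") +
    theme_minimal()
}
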