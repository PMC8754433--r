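## Table-wide disproportionality scoring and PCA on log expected counts.

#' Relative reporting ratio
#'
#' `RR = N / E`: the observed count of a drug-ADE pair relative to its
#' baseline expected count under drug-event independence. `RR = 100` means
#' the pair was reported 100 times as frequently as the baseline. RR is
#' unstable for small counts, which is what the GPS shrinkage corrects.
#'
#' @param n Observed count(s), non-negative.
#' @param e Baseline expected count(s), strictly positive.
#' @return `n / e`.
#' @examples
#' relative_reporting_ratio(200, 2) # 100
#' @export
relative_reporting_ratio <- function(n, e) {
  if (any(!is.finite(e)) || any(e <= 0)) stop_input("E must be positive")
  if (any(n < 0)) stop_input("N must be non-negative")
  n / e
}

#' Score every drug-ADE cell of a count table
#'
#' Computes, for every cell (including zero counts, so downstream block
#' designs stay complete): the count `n`, baseline `e`, relative reporting
#' ratio `rr`, posterior component weight `qn`, shrinkage score `ebgm`, and
#' posterior 5th/95th percentiles `eb05`/`eb95`.
#'
#' @param counts A `pv_counts` object.
#' @param model A fitted `pv_gps_model`, or a `pv_gps_fit` from [fit_gps()].
#' @return A `pv_signals` tibble with columns
#'   `drug, ade, n, e, rr, qn, ebgm, eb05, eb95`.
#' @export
score_table <- function(counts, model) {
  stopifnot(inherits(counts, "pv_counts"))
  if (inherits(model, "pv_gps_fit")) model <- model$model
  stopifnot(inherits(model, "pv_gps_model"))
  cells <- tidy(counts)
  keep <- cells$e > 0
  cells <- cells[keep, ]
  out <- cells |>
    dplyr::mutate(
      rr = relative_reporting_ratio(.data$n, .data$e),
      qn = posterior_weight(.data$n, .data$e, model),
      ebgm = ebgm_score(.data$n, .data$e, model),
      eb05 = eb_quantile(.data$n, .data$e, model, 0.05),
      eb95 = eb_quantile(.data$n, .data$e, model, 0.95)
    )
  structure(out, class = c("pv_signals", class(tibble::tibble()))) |>
    add_signal_model(model)
}

add_signal_model <- function(x, model) {
  attr(x, "gps_model") <- model
  x
}

#' Pivot a signal table into a drug x ADE score matrix
#'
#' @param signals A `pv_signals` tibble (or any tibble with `drug`, `ade`
#'   and the requested value column).
#' @param value Which column to spread (default `"ebgm"`).
#' @return A numeric matrix, drugs as rows, ADEs as columns.
#' @export
signal_matrix <- function(signals, value = "ebgm") {
  stopifnot(value %in% names(signals))
  wide <- tidyr::pivot_wider(signals[, c("drug", "ade", value)],
                             names_from = "ade", values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$drug
  m
}

#' @export
print.pv_signals <- function(x, ...) {
  cat("<pv_signals> ", dplyr::n_distinct(x$drug), " drugs x ",
      dplyr::n_distinct(x$ade), " ADEs\n", sep = "")
  NextMethod()
}

#' Shrinkage plot of a signal table
#'
#' Plots EBGM against RR on log axes: points below the identity show the
#' empirical-Bayes shrinkage of unstable small-count ratios toward the
#' prior mean.
#'
#' @param object A `pv_signals` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_signals <- function(object, ...) {
  df <- dplyr::filter(object, .data$rr > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rr, y = .data$ebgm)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative reporting ratio (N/E)",
                  y = "EBGM (shrunk ratio)", size = "count N") +
    ggplot2::theme_minimal()
}

#' Principal component analysis of log expected counts
#'
#' Decomposes the column-centered `log(E)` matrix (drugs as rows, analyzed
#' ADE terms as columns) by singular values, the exploratory view used to
#' compare drugs by their expected-count profiles before shrinkage scoring.
#' Columns are mean-centered but not scaled: the log already stabilizes the
#' variance across terms.
#'
#' @param x A positive numeric matrix (e.g. the `E` slot of a `pv_counts`),
#'   or a `pv_counts` object.
#' @return A `pv_pca`: list with `scores` (drugs x components), `loadings`
#'   (ADEs x components), and `var_explained` (fractions summing to 1).
#' @export
pca_log_expected <- function(x) {
  if (inherits(x, "pv_counts")) x <- x$E
  x <- as.matrix(x)
  if (any(x <= 0) || any(!is.finite(x))) {
    stop_input("all matrix entries must be positive (log is taken)")
  }
  pc <- prcomp(log(x), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = pc$x, loadings = pc$rotation, var_explained = ve),
    class = "pv_pca"
  )
}

#' @export
print.pv_pca <- function(x, ...) {
  cat("<pv_pca> ", nrow(x$scores), " drugs, ", length(x$var_explained),
      " components; PC1-PC3 explain ",
      sprintf("%.1f%%", 100 * sum(utils::head(x$var_explained, 3L))), "\n", sep = "")
  invisible(x)
}

#' @rdname pca_log_expected
#' @param x A `pv_pca` object.
#' @param ... Unused.
#' @export
tidy.pv_pca <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$var_explained),
    var_explained = x$var_explained,
    cumulative = cumsum(x$var_explained)
  )
}

#' Biplot of a log-expected-count PCA
#'
#' @param object A `pv_pca` object.
#' @param components Which two components to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_pca <- function(object, components = c(1L, 2L), ...) {
  sc <- tibble::as_tibble(object$scores[, components, drop = FALSE],
                          .name_repair = ~ c("x", "y"))
  sc$drug <- rownames(object$scores)
  ld <- tibble::as_tibble(object$loadings[, components, drop = FALSE],
                          .name_repair = ~ c("x", "y"))
  ld$ade <- rownames(object$loadings)
  scale_ld <- max(abs(sc$x), abs(sc$y)) / max(abs(ld$x), abs(ld$y))
  labs <- sprintf("PC%d (%.1f%%)", components,
                  100 * object$var_explained[components])
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(shape = 15, colour = "grey30") +
    ggplot2::geom_text(
      data = dplyr::mutate(ld, x = .data$x * scale_ld, y = .data$y * scale_ld),
      ggplot2::aes(label = .data$ade), colour = "steelblue", size = 3
    ) +
    ggplot2::labs(x = labs[1L], y = labs[2L]) +
    ggplot2::theme_minimal()
}
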