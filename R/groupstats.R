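## Non-parametric class-homogeneity testing: Friedman tests of EBGM
## profiles within ATC classes / GL clusters, and pairwise class
## comparisons by Wilcoxon signed-rank with Bonferroni correction.

#' Friedman rank test over matched blocks
#'
#' Values are ranked within each block (midranks for ties); the
#' chi-square statistic is
#' `12 * sum_j (R_j - b(k+1)/2)^2 / (b*k*(k+1) - C)` with the standard tie
#' correction `C = sum(t^3 - t) / (k - 1)` over tie groups, referred to a
#' chi-square with `k - 1` df. Being rank-based, the statistic is
#' invariant under any strictly monotone within-block transform. A design
#' in which every block is completely tied carries no information and is
#' reported as statistic 0, p = 1.
#'
#' @param block_matrix Numeric matrix: blocks (e.g. analyzed ADE terms) as
#'   rows, treatments (drugs) as columns; must be complete.
#' @return A one-row `pv_test` tibble: `statistic`, `df`, `p_value`,
#'   `adjusted_p`, `n_blocks`, `n_treatments`, `method`.
#' @export
friedman_test <- function(block_matrix) {
  y <- as.matrix(block_matrix)
  b <- nrow(y); k <- ncol(y)
  if (k < 2L || b < 2L) stop_input("need at least 2 blocks and 2 treatments")
  if (anyNA(y)) stop_input("block matrix must be complete")
  r <- t(apply(y, 1L, rank))
  Rj <- colSums(r)
  ties <- apply(y, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  denom <- b * k * (k + 1) - sum(ties) / (k - 1)
  if (denom <= 0) { # every block fully tied: no evidence either way
    stat <- 0
    p <- 1
  } else {
    stat <- 12 * sum((Rj - b * (k + 1) / 2)^2) / denom
    p <- pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  new_pv_test(
    method = "friedman", statistic = stat, df = k - 1L, p_value = p,
    n_blocks = b, n_treatments = k
  )
}

new_pv_test <- function(method, statistic, df, p_value, n_blocks,
                        n_treatments, n_comparisons = 1L) {
  structure(
    tibble::tibble(
      method = method, statistic = statistic, df = df, p_value = p_value,
      adjusted_p = pmin(1, p_value * n_comparisons),
      n_blocks = n_blocks, n_treatments = n_treatments
    ),
    class = c("pv_test", class(tibble::tibble()))
  )
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided test of symmetry of the paired differences about zero. Zero
#' differences are dropped; with `n` non-zero pairs at most `exact_max`
#' the exact null distribution of the positive-rank sum is enumerated by
#' convolution over the (mid)ranks, otherwise a normal approximation with
#' tie and continuity corrections is used. All-zero differences carry no
#' evidence and return p = 1 with a warning.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return A one-row `pv_test` tibble; `statistic` is the positive-rank
#'   sum V, `n_blocks` the number of non-zero pairs.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; returning p = 1")
    return(new_pv_test("wilcoxon_signed_rank", statistic = 0, df = NA_integer_,
                       p_value = 1, n_blocks = 0L, n_treatments = 2L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of 2V by convolution over doubled (integer) ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- c(1, numeric(total))
    for (w in r2) {
      shifted <- c(numeric(w), f[seq_len(total + 1L - w)])
      f <- f + shifted
    }
    f <- f / 2^n
    v2 <- as.integer(round(2 * v))
    p_le <- sum(f[seq_len(v2 + 1L)])
    p_ge <- sum(f[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  new_pv_test("wilcoxon_signed_rank", statistic = v, df = NA_integer_,
              p_value = p, n_blocks = n, n_treatments = 2L)
}

group_block_matrix <- function(signals, drugs, ades = NULL) {
  m <- signal_matrix(signals, "ebgm")
  if (is.null(ades)) ades <- colnames(m)
  t(m[drugs, ades, drop = FALSE]) # blocks = ADEs (rows), treatments = drugs
}

#' Friedman homogeneity tests within drug groups
#'
#' For each group (ATC class or GL cluster) with at least two drugs, runs
#' a Friedman test on the complete blocks-by-treatments EBGM matrix whose
#' blocks are the analyzed pulmonary ADEs and whose treatments are the
#' group's drugs (zero-count cells contribute their n = 0 posterior EBGM,
#' keeping blocks complete). Single-drug groups are reported untestable.
#' Bonferroni adjustment across the testable groups is included.
#'
#' @param signals A `pv_signals` tibble covering the analyzed ADEs.
#' @param groups A data frame with columns `drug` and `group`, or a named
#'   vector drug -> group label.
#' @param drop Optional drug name: its group is additionally re-tested
#'   with that drug excluded (a leave-one-out sensitivity row); unknown
#'   names raise an error.
#' @return A tibble with one row per group (plus one per `drop` re-run):
#'   `group`, `n_drugs`, `excluded`, `statistic`, `df`, `p_value`,
#'   `adjusted_p`, `testable`.
#' @export
within_group_homogeneity <- function(signals, groups, drop = NULL) {
  groups <- as_group_table(groups)
  groups <- groups[groups$drug %in% unique(signals$drug), ]
  if (!is.null(drop) && !drop %in% groups$drug) {
    stop_input("drop drug '%s' is not in the grouping", drop)
  }
  split_drugs <- split(groups$drug, groups$group)

  run_one <- function(group, drugs, excluded = NA_character_) {
    drugs <- setdiff(drugs, excluded[!is.na(excluded)])
    if (length(drugs) < 2L) {
      return(tibble::tibble(group = group, n_drugs = length(drugs),
                            excluded = excluded, statistic = NA_real_,
                            df = NA_integer_, p_value = NA_real_,
                            testable = FALSE))
    }
    res <- friedman_test(group_block_matrix(signals, drugs))
    tibble::tibble(group = group, n_drugs = length(drugs), excluded = excluded,
                   statistic = res$statistic, df = res$df,
                   p_value = res$p_value, testable = TRUE)
  }

  out <- purrr::imap(split_drugs, function(drugs, group) run_one(group, drugs)) |>
    purrr::list_rbind()
  if (!is.null(drop)) {
    grp <- groups$group[match(drop, groups$drug)]
    out <- dplyr::bind_rows(out, run_one(grp, split_drugs[[as.character(grp)]],
                                         excluded = drop))
  }
  n_tests <- sum(out$testable)
  out$adjusted_p <- pmin(1, out$p_value * max(n_tests, 1L))
  dplyr::relocate(out, "adjusted_p", .after = "p_value")
}

as_group_table <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("drug", "group") %in% names(groups)))
    tibble::as_tibble(groups[, c("drug", "group")])
  } else {
    tibble::tibble(drug = names(groups), group = unname(groups))
  }
}

#' Pairwise drug-class comparisons with Bonferroni correction
#'
#' For every unordered pair of groups, the per-ADE mean EBGM of group A
#' (averaged over its drugs) is paired against that of group B over the
#' analyzed ADE terms and tested with the Wilcoxon signed-rank test;
#' two-sided p-values are Bonferroni-multiplied by the number of pairs.
#' Pairing group means per ADE keeps the compared vectors matched and
#' equal length even for unequal-sized groups.
#'
#' @inheritParams within_group_homogeneity
#' @param exclude Optional drug(s) removed before comparison.
#' @return A `pv_pairwise` tibble (`group1`, `group2`, `statistic`,
#'   `p_value`, `adjusted_p`, `n_ades`); `as.matrix()` yields the
#'   symmetric adjusted-p matrix.
#' @export
pairwise_class_comparison <- function(signals, groups, exclude = NULL) {
  groups <- as_group_table(groups)
  groups <- groups[groups$drug %in% unique(signals$drug), ]
  if (!is.null(exclude)) groups <- groups[!groups$drug %in% exclude, ]
  labs <- sort(unique(as.character(groups$group)))
  if (length(labs) < 2L) stop_input("need at least two groups")
  m <- signal_matrix(signals, "ebgm")
  means <- vapply(labs, function(g) {
    colMeans(m[groups$drug[groups$group == g], , drop = FALSE])
  }, numeric(ncol(m)))

  pairs <- utils::combn(labs, 2L)
  n_pairs <- ncol(pairs)
  out <- purrr::map(seq_len(n_pairs), function(i) {
    g1 <- pairs[1L, i]; g2 <- pairs[2L, i]
    res <- suppressWarnings(wilcoxon_signed_rank(means[, g1], means[, g2]))
    tibble::tibble(group1 = g1, group2 = g2, statistic = res$statistic,
                   p_value = res$p_value, n_ades = nrow(means))
  }) |> purrr::list_rbind() |>
    dplyr::mutate(adjusted_p = pmin(1, .data$p_value * n_pairs)) |>
    dplyr::relocate("adjusted_p", .after = "p_value")
  structure(out, class = c("pv_pairwise", class(tibble::tibble())),
            groups = labs)
}

#' @export
as.matrix.pv_pairwise <- function(x, ...) {
  labs <- attr(x, "groups")
  m <- matrix(NA_real_, length(labs), length(labs), dimnames = list(labs, labs))
  diag(m) <- 1
  for (i in seq_len(nrow(x))) {
    m[x$group1[i], x$group2[i]] <- m[x$group2[i], x$group1[i]] <- x$adjusted_p[i]
  }
  m
}

#' Heatmap of pairwise class comparisons
#'
#' @param object A `pv_pairwise` tibble.
#' @param alpha Significance threshold highlighted in the labels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_pairwise <- function(object, alpha = 0.05, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group1, y = .data$group2,
                                   fill = .data$adjusted_p)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$adjusted_p < alpha,
                     sprintf("%.3g *", .data$adjusted_p),
                     sprintf("%.3g", .data$adjusted_p))), size = 3) +
    ggplot2::scale_fill_gradient(low = "tomato", high = "white",
                                 limits = c(0, 1), name = "adj. p") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
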