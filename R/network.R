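## Drug association network: EBGM-profile correlation, retention-calibrated
## graphical-lasso tuning, GL clusters, RCM ordering, diagram exports.

#' Pearson correlation of drug EBGM profiles
#'
#' Each drug's profile is its vector of EBGM scores over the analyzed ADE
#' terms; the drug-drug association matrix is the Pearson correlation of
#' these row vectors. Profiles span different EBGM scales, which is why the
#' network stage consumes the correlation rather than the covariance.
#'
#' @param profiles Numeric matrix, drugs as rows and ADEs as columns
#'   (e.g. from [signal_matrix()]), with at least two drugs.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
profile_correlation <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop_input("need at least two drug profiles")
  v <- apply(profiles, 1L, stats::var)
  if (any(v == 0)) {
    stop_input("zero-variance profile(s): %s",
               paste((rownames(profiles) %||% seq_len(nrow(profiles)))[v == 0],
                     collapse = ", "))
  }
  cor(t(profiles))
}

new_drug_graph <- function(glasso_fit, nodes = NULL) {
  adj <- glasso_fit$adjacency
  if (is.null(nodes)) nodes <- rownames(adj)
  g <- structure(
    list(nodes = nodes,
         adjacency = adj[nodes, nodes, drop = FALSE],
         precision = glasso_fit$precision[nodes, nodes, drop = FALSE],
         penalty = glasso_fit$penalty,
         clusters = NULL),
    class = "pv_drug_graph"
  )
  g$clusters <- extract_clusters(g)
  g
}

#' Tune the graphical-lasso penalty to a target drug-retention fraction
#'
#' A drug is "shrunk away" when its node is isolated (no nonzero
#' off-diagonal precision entries). The penalty is searched on a
#' log-spaced grid between zero-like and the full-shrinkage penalty
#' `max|off-diagonal correlation|`, then refined by bisection around the
#' best grid point, targeting `retained/m` closest to `target_fraction`;
#' ties go to the larger penalty (the sparser graph). If no penalty
#' attains the target exactly (retention can jump by more than one drug),
#' the closest achievable penalty is returned and flagged.
#'
#' @param profiles Drugs x ADEs EBGM matrix (the EB05-selected drug set).
#' @param target_fraction Desired fraction of drugs retained (default 0.5).
#' @param grid_size Number of penalties on the initial grid.
#' @param refine_iters Bisection refinement steps.
#' @param tol,max_iter Passed to [glasso_estimate()].
#' @return A `pv_retention` list: `penalty`, `retained` (drug ids),
#'   `fraction`, `target_attained` flag, `graph` (a `pv_drug_graph` with
#'   isolated nodes dropped), and the search `trace` tibble.
#' @export
tune_retention <- function(profiles, target_fraction = 0.5, grid_size = 25L,
                           refine_iters = 12L, tol = 1e-6, max_iter = 200L) {
  profiles <- as.matrix(profiles)
  if (target_fraction < 0 || target_fraction > 1) {
    stop_input("target_fraction must lie in [0, 1]")
  }
  m <- nrow(profiles)
  corr <- profile_correlation(profiles)
  rho_max <- max(abs(corr[upper.tri(corr)]))
  if (rho_max == 0) rho_max <- 1

  evals <- new.env()
  eval_penalty <- function(rho) {
    key <- sprintf("%.12g", rho)
    if (!is.null(evals[[key]])) return(evals[[key]])
    fit <- glasso_estimate(corr, rho, tol = tol, max_iter = max_iter)
    res <- list(penalty = rho, fit = fit,
                n_retained = sum(rowSums(fit$adjacency) > 0))
    evals[[key]] <- res
    res
  }

  grid <- if (target_fraction >= 1) 0 else
    exp(seq(log(rho_max * 1e-3), log(rho_max * 1.001), length.out = grid_size))
  results <- purrr::map(grid, eval_penalty)

  target_n <- target_fraction * m
  pick_best <- function(rs) {
    d <- vapply(rs, function(r) abs(r$n_retained - target_n), numeric(1))
    rho <- vapply(rs, function(r) r$penalty, numeric(1))
    rs[[order(d, -rho)[1L]]] # ties -> larger penalty (sparser)
  }
  best <- pick_best(results)

  # bisection refinement between the best grid point and its neighbours
  k <- match(best$penalty, grid)
  lo <- if (!is.na(k) && k > 1L) grid[k - 1L] else best$penalty / 2
  hi <- if (!is.na(k) && k < length(grid)) grid[k + 1L] else best$penalty * 2
  for (i in seq_len(refine_iters)) {
    if (abs(best$n_retained - target_n) < 0.5) break
    mid <- sqrt(lo * hi)
    r <- eval_penalty(mid)
    best <- pick_best(list(best, r))
    if (r$n_retained > target_n) lo <- mid else hi <- mid
  }

  retained <- rownames(best$fit$adjacency)[rowSums(best$fit$adjacency) > 0]
  graph <- new_drug_graph(best$fit, nodes = retained)
  trace <- purrr::map(as.list(evals), function(r) {
    tibble::tibble(penalty = r$penalty, n_retained = r$n_retained)
  }) |> purrr::list_rbind() |> dplyr::arrange(.data$penalty)

  attained <- abs(length(retained) - target_n) < 0.5
  if (!attained) {
    warning(sprintf(
      "retention target %.3g unreachable: closest achievable is %d/%d drugs",
      target_fraction, length(retained), m))
  }
  structure(
    list(penalty = best$penalty, retained = retained,
         fraction = length(retained) / m, target_attained = attained,
         graph = graph, trace = trace),
    class = "pv_retention"
  )
}

#' @export
print.pv_retention <- function(x, ...) {
  cat(sprintf("<pv_retention> penalty %.4g keeps %d drugs (%.1f%%)%s\n",
              x$penalty, length(x$retained), 100 * x$fraction,
              if (x$target_attained) "" else " [target not attained]"))
  invisible(x)
}

#' GL clusters: connected components of the drug graph
#'
#' Components are labeled 1..K in decreasing size order, ties broken by
#' the lexicographically smallest member id, so "cluster 1" is always the
#' largest drug group.
#'
#' @param graph A `pv_drug_graph` (isolated nodes already dropped), or a
#'   logical/numeric symmetric adjacency matrix.
#' @return Named integer vector: drug -> cluster label (empty for an
#'   empty graph).
#' @export
extract_clusters <- function(graph) {
  adj <- if (inherits(graph, "pv_drug_graph")) graph$adjacency else as.matrix(graph)
  if (nrow(adj) == 0L) return(setNames(integer(0), character(0)))
  ig <- igraph::graph_from_adjacency_matrix(adj != 0, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(ig)
  sizes <- comp$csize
  first_member <- vapply(seq_along(sizes), function(k) {
    min(rownames(adj)[comp$membership == k])
  }, character(1))
  new_label <- order(order(-sizes, first_member))
  setNames(new_label[comp$membership], rownames(adj))
}

#' Reverse Cuthill-McKee node ordering
#'
#' Breadth-first Cuthill-McKee from a pseudo-peripheral start node (found
#' by repeated BFS eccentricity climbing), visiting neighbours in
#' ascending degree with ties by node index, order reversed. Permuting a
#' sparse symmetric matrix by this order concentrates its nonzeros near
#' the diagonal, which untangles arc/circular diagram layouts.
#'
#' @param adjacency Symmetric logical/numeric adjacency matrix.
#' @return Integer permutation of node indices (names preserved).
#' @export
rcm_order <- function(adjacency) {
  A <- as.matrix(adjacency) != 0
  n <- nrow(A)
  if (n == 0L) return(integer(0))
  if (!isTRUE(all.equal(A, t(A)))) stop_input("adjacency must be symmetric")
  diag(A) <- FALSE
  deg <- rowSums(A)

  bfs_levels <- function(start, avail) {
    lev <- rep(NA_integer_, n)
    lev[start] <- 0L
    frontier <- start
    while (length(frontier)) {
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] & avail))))
      nxt <- nxt[is.na(lev[nxt])]
      if (!length(nxt)) break
      lev[nxt] <- lev[frontier[1L]] + 1L
      frontier <- nxt
    }
    lev
  }

  pseudo_peripheral <- function(avail) {
    cand <- which(avail)
    v <- cand[order(deg[cand], cand)][1L]
    repeat {
      lev <- bfs_levels(v, avail)
      ecc <- max(lev, na.rm = TRUE)
      last <- which(!is.na(lev) & lev == ecc)
      u <- last[order(deg[last], last)][1L]
      lev_u <- bfs_levels(u, avail)
      if (max(lev_u, na.rm = TRUE) <= ecc) return(u)
      v <- u
    }
  }

  visited <- rep(FALSE, n)
  order_cm <- integer(0)
  while (!all(visited)) {
    avail <- !visited
    start <- pseudo_peripheral(avail)
    queue <- start
    visited[start] <- TRUE
    while (length(queue)) {
      v <- queue[1L]
      queue <- queue[-1L]
      order_cm <- c(order_cm, v)
      nb <- which(A[v, ] & !visited)
      nb <- nb[order(deg[nb], nb)]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  perm <- rev(order_cm)
  names(perm) <- rownames(A)[perm]
  perm
}

#' Bandwidth of a symmetric adjacency matrix
#'
#' Maximum |i - j| over nonzero entries; 0 for an edgeless matrix.
#'
#' @param adjacency Symmetric matrix.
#' @param perm Optional node permutation applied before measuring.
#' @return Integer bandwidth.
#' @export
matrix_bandwidth <- function(adjacency, perm = NULL) {
  A <- as.matrix(adjacency) != 0
  diag(A) <- FALSE
  if (!is.null(perm)) A <- A[perm, perm, drop = FALSE]
  idx <- which(A, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  as.integer(max(abs(idx[, 1L] - idx[, 2L])))
}

#' Expand a drug x ADE profile matrix into block-diagonal layout
#'
#' For diagram rendering, each drug's ADE columns are placed in its own
#' column block with all other rows zero: an `m x q` matrix becomes
#' `m x (m*q)`, row `i` occupying columns `((i-1)*q + 1):(i*q)`.
#'
#' @param profiles Numeric matrix (`m x q`).
#' @return Numeric `m x (m*q)` matrix; column names combine drug and ADE.
#' @export
expand_block_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  m <- nrow(profiles); q <- ncol(profiles)
  stopifnot(m >= 1L, q >= 1L)
  out <- matrix(0, m, m * q)
  for (i in seq_len(m)) out[i, ((i - 1L) * q + 1L):(i * q)] <- profiles[i, ]
  rownames(out) <- rownames(profiles)
  drugs <- rownames(profiles) %||% paste0("r", seq_len(m))
  ades <- colnames(profiles) %||% paste0("c", seq_len(q))
  colnames(out) <- paste(rep(drugs, each = q), rep(ades, m), sep = "|")
  out
}

#' Export a drug graph for diagram rendering
#'
#' Writes a node table (drug, ATC class, GL cluster, RCM position), a
#' weighted edge list (partial correlations from the precision matrix),
#' the adjacency in Matrix Market format, and optionally the
#' block-expanded profile matrix. Output is byte-stable for fixed inputs.
#'
#' @param graph A `pv_drug_graph`.
#' @param dir Output directory (created if missing).
#' @param expansion Optional matrix from [expand_block_matrix()].
#' @param dictionary Optional dictionary tibble supplying ATC classes.
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of written paths.
#' @export
export_diagram <- function(graph, dir, expansion = NULL, dictionary = NULL,
                           prefix = "drug_graph") {
  stopifnot(inherits(graph, "pv_drug_graph"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  perm <- rcm_order(graph$adjacency)
  pos <- match(seq_along(graph$nodes), perm)
  atc <- if (!is.null(dictionary)) {
    lut <- dplyr::distinct(dictionary, .data$ingredient, .data$atc_class)
    lut$atc_class[match(graph$nodes, lut$ingredient)]
  } else {
    rep(NA_character_, length(graph$nodes))
  }
  nodes <- tibble::tibble(
    drug = graph$nodes, atc_class = atc,
    gl_cluster = unname(graph$clusters[graph$nodes]),
    rcm_position = pos
  )
  edges <- tidy(graph)
  paths <- list(
    nodes = file.path(dir, paste0(prefix, "_nodes.tsv")),
    edges = file.path(dir, paste0(prefix, "_edges.tsv")),
    adjacency = file.path(dir, paste0(prefix, "_adjacency.mtx"))
  )
  readr::write_tsv(nodes, paths$nodes)
  readr::write_tsv(edges, paths$edges)
  Matrix::writeMM(Matrix::Matrix(graph$adjacency * 1, sparse = TRUE),
                  paths$adjacency)
  if (!is.null(expansion)) {
    paths$expansion <- file.path(dir, paste0(prefix, "_expansion.tsv"))
    readr::write_tsv(tibble::as_tibble(expansion, rownames = "drug"),
                     paths$expansion)
  }
  invisible(paths)
}

#' @export
print.pv_drug_graph <- function(x, ...) {
  cat(sprintf("<pv_drug_graph> %d drugs, %d edges, %d GL clusters (penalty %.4g)\n",
              length(x$nodes), sum(x$adjacency) / 2,
              length(unique(x$clusters)), x$penalty))
  invisible(x)
}

#' @rdname tune_retention
#' @param x A `pv_drug_graph`.
#' @param ... Unused.
#' @export
tidy.pv_drug_graph <- function(x, ...) {
  adj <- x$adjacency
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(tibble::tibble(from = character(0), to = character(0),
                          weight = numeric(0)))
  }
  th <- x$precision
  pcor <- -th / sqrt(outer(diag(th), diag(th)))
  tibble::tibble(
    from = rownames(adj)[idx[, 1L]],
    to = colnames(adj)[idx[, 2L]],
    weight = pcor[idx]
  ) |> dplyr::arrange(.data$from, .data$to)
}

#' @rdname tune_retention
#' @export
glance.pv_drug_graph <- function(x, ...) {
  tibble::tibble(
    n_drugs = length(x$nodes), n_edges = sum(x$adjacency) / 2,
    n_clusters = length(unique(x$clusters)), penalty = x$penalty
  )
}

#' Circular diagram of a drug graph
#'
#' Nodes are placed on a circle in reverse Cuthill-McKee order (so
#' associated drugs sit near each other) and coloured by GL cluster;
#' edges are chords weighted by partial correlation.
#'
#' @param object A `pv_drug_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pv_drug_graph <- function(object, ...) {
  n <- length(object$nodes)
  if (n == 0L) return(ggplot2::ggplot() + ggplot2::theme_void())
  perm <- rcm_order(object$adjacency)
  ang <- 2 * pi * (seq_len(n) - 1L) / n
  pos <- tibble::tibble(
    drug = rownames(object$adjacency)[perm],
    x = cos(ang), y = sin(ang),
    cluster = factor(object$clusters[rownames(object$adjacency)[perm]])
  )
  ed <- tidy(object) |>
    dplyr::left_join(pos[, c("drug", "x", "y")], by = c(from = "drug")) |>
    dplyr::left_join(pos[, c("drug", "x", "y")], by = c(to = "drug"),
                     suffix = c("", "end"))
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(xend = .data$xend, yend = .data$yend,
                   linewidth = abs(.data$weight)),
      colour = "grey60", alpha = 0.6
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cluster), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$drug, x = 1.12 * .data$x,
                                    y = 1.12 * .data$y), size = 3) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::labs(colour = "GL cluster") +
    ggplot2::theme_void()
}
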