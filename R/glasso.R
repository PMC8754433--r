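## Graphical lasso: L1-penalized Gaussian precision estimation. The block
## coordinate descent core (each column solved as a coordinate-descent
## lasso on the current covariance estimate) is compiled C++.

#' Sparse precision matrix by the graphical lasso
#'
#' Maximizes `log det(Theta) - tr(S Theta) - penalty * ||Theta||_1` by
#' block coordinate descent over columns of the covariance estimate `W`,
#' each block solved with coordinate-descent lasso. The soft-threshold
#' updates leave exact zeros in the off-diagonal precision entries; an
#' edge is declared where `|theta_ij| > edge_tol` (guarding round-off).
#'
#' @param s Symmetric correlation (or covariance) matrix; if not positive
#'   semi-definite to working precision, 1e-8 is added to the diagonal.
#' @param penalty Non-negative L1 penalty. At `penalty = 0` (and `s` well
#'   conditioned) the estimate converges to `solve(s)`.
#' @param tol Convergence tolerance on the maximum elementwise change of
#'   `W` between sweeps (default 1e-6).
#' @param max_iter Maximum outer sweeps.
#' @param edge_tol Absolute precision threshold defining adjacency.
#' @return A `pv_glasso` list: `precision`, `cov`, logical hollow
#'   `adjacency`, `penalty`, `iterations`, `converged`.
#' @export
glasso_estimate <- function(s, penalty, tol = 1e-6, max_iter = 200L,
                            edge_tol = 1e-8) {
  s <- as.matrix(s)
  p <- nrow(s)
  if (p != ncol(s) || max(abs(s - t(s))) > 1e-8) {
    stop_input("s must be a symmetric square matrix")
  }
  if (penalty < 0) stop_input("penalty must be non-negative")
  s <- (s + t(s)) / 2
  if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    s <- s + diag(1e-8, p)
  }
  ids <- rownames(s) %||% paste0("v", seq_len(p))

  if (p == 1L) {
    theta <- matrix(1 / s[1, 1], 1, 1, dimnames = list(ids, ids))
    return(structure(list(precision = theta, cov = s,
                          adjacency = matrix(FALSE, 1, 1, dimnames = list(ids, ids)),
                          penalty = penalty, iterations = 0L, converged = TRUE),
                     class = "pv_glasso"))
  }

  fit <- .glasso_bcd(s, penalty, tol, as.integer(max_iter))
  if (fit$delta >= tol) {
    stop_input("graphical lasso failed to converge in %d sweeps (residual %.3g)",
               max_iter, fit$delta)
  }
  # zero patterns agree across the two triangles; average for symmetry
  theta <- (fit$Theta + t(fit$Theta)) / 2
  W <- fit$W
  dimnames(theta) <- dimnames(W) <- list(ids, ids)
  adj <- abs(theta) > edge_tol
  diag(adj) <- FALSE
  structure(
    list(precision = theta, cov = W, adjacency = adj, penalty = penalty,
         iterations = fit$iterations, converged = TRUE),
    class = "pv_glasso"
  )
}

#' @export
print.pv_glasso <- function(x, ...) {
  cat(sprintf("<pv_glasso> %d nodes, %d edges, penalty %.4g (%d sweeps)\n",
              nrow(x$precision), sum(x$adjacency) / 2, x$penalty, x$iterations))
  invisible(x)
}
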