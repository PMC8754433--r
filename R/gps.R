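## Gamma-Poisson Shrinker: two-gamma mixture prior on the Poisson rate
## multiplier lambda, negative-binomial marginals, empirical-Bayes fitting,
## and posterior summaries (Qn, EBGM, EB05/EB95).

#' Construct a Gamma-Poisson Shrinker prior model
#'
#' The GPS model places a two-component gamma mixture prior on the rate
#' multiplier lambda = mu/E of each drug-ADE cell:
#' `P * Gamma(alpha1, beta1) + (1-P) * Gamma(alpha2, beta2)`.
#' Gammas use the *rate* parameterization (mean `alpha/beta`), the GPS
#' convention -- shape/scale confusion is the classic implementation bug,
#' so the prior mean `P*alpha1/beta1 + (1-P)*alpha2/beta2` is worth
#' checking whenever hyperparameters are set by hand.
#'
#' @param alpha1,beta1 Shape and rate of the first gamma component (> 0).
#' @param alpha2,beta2 Shape and rate of the second component (> 0).
#' @param p Mixture weight of component 1 in `[0, 1]`; the boundary values
#'   0 and 1 give a single-component (degenerate) model.
#' @return A `pv_gps_model` object (named list of the five hyperparameters).
#' @examples
#' gps_model(0.2, 0.1, 2, 4, 1/3) # conventional starting point
#' @export
gps_model <- function(alpha1, beta1, alpha2, beta2, p) {
  vals <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop_input("gamma hyperparameters must be positive and finite")
  }
  if (!is.finite(p) || p < 0 || p > 1) stop_input("p must lie in [0, 1]")
  structure(list(alpha1 = alpha1, beta1 = beta1,
                 alpha2 = alpha2, beta2 = beta2, p = p),
            class = "pv_gps_model")
}

#' @export
print.pv_gps_model <- function(x, ...) {
  cat(sprintf(
    "<pv_gps_model> alpha1=%.4g beta1=%.4g alpha2=%.4g beta2=%.4g P=%.4g (prior mean %.4g)\n",
    x$alpha1, x$beta1, x$alpha2, x$beta2, x$p,
    x$p * x$alpha1 / x$beta1 + (1 - x$p) * x$alpha2 / x$beta2))
  invisible(x)
}

#' Prior mean of a GPS model
#' @param model A `pv_gps_model`.
#' @return `P*alpha1/beta1 + (1-P)*alpha2/beta2`.
#' @export
gps_prior_mean <- function(model) {
  model$p * model$alpha1 / model$beta1 +
    (1 - model$p) * model$alpha2 / model$beta2
}

# log negative-binomial marginal of N when lambda ~ Gamma(shape a, rate b)
# and N | lambda ~ Poisson(lambda * E): success-odds E/(b+E), shape a.
log_nb <- function(n, a, b, e) {
  lgamma(a + n) - lgamma(a) - lfactorial(n) +
    a * log(b / (b + e)) + n * log(e / (b + e))
}

check_cells <- function(n, e) {
  if (any(e <= 0) || any(!is.finite(e))) stop_input("E must be positive")
  if (any(n < 0) || any(n != round(n))) stop_input("N must be non-negative integers")
}

#' Log marginal likelihood of a drug-ADE cell count
#'
#' The marginal distribution of a cell count under the GPS model is a
#' mixture of two negative binomials (gamma-mixed Poissons). Computed in
#' log-space, stable for counts up to at least 1e5.
#'
#' @param n Observed count(s), non-negative integers.
#' @param e Baseline expected count(s), positive.
#' @param model A `pv_gps_model`.
#' @return Log-probability of each `n`.
#' @export
marginal_cell_loglik <- function(n, e, model) {
  stopifnot(inherits(model, "pv_gps_model"))
  check_cells(n, e)
  l1 <- log_nb(n, model$alpha1, model$beta1, e)
  l2 <- log_nb(n, model$alpha2, model$beta2, e)
  if (model$p >= 1) return(l1)
  if (model$p <= 0) return(l2)
  log_add(log(model$p) + l1, log1p(-model$p) + l2)
}

#' Posterior weight of the first mixture component
#'
#' `Qn = P*nb1 / (P*nb1 + (1-P)*nb2)`, the posterior probability that a
#' cell's lambda was drawn from component 1 given its count; evaluated in
#' log-space.
#'
#' @inheritParams marginal_cell_loglik
#' @return Posterior weight(s) in `[0, 1]`.
#' @export
posterior_weight <- function(n, e, model) {
  stopifnot(inherits(model, "pv_gps_model"))
  check_cells(n, e)
  if (model$p >= 1) return(rep(1, length(n)))
  if (model$p <= 0) return(rep(0, length(n)))
  l1 <- log(model$p) + log_nb(n, model$alpha1, model$beta1, e)
  l2 <- log1p(-model$p) + log_nb(n, model$alpha2, model$beta2, e)
  exp(l1 - log_add(l1, l2))
}

#' Empirical Bayes geometric mean of the posterior rate multiplier
#'
#' `EBGM = exp(E[log lambda | N = n])`. Given the count, lambda's posterior
#' is the gamma mixture with updated components `Gamma(alpha_k + n,
#' beta_k + E)` and weight `Qn`, so `E[log lambda]` is a weighted digamma
#' expression. EBGM is the shrinkage-corrected reporting ratio: close to
#' the prior mean for tiny counts, and approaching `RR = N/E` as the count
#' grows.
#'
#' @inheritParams marginal_cell_loglik
#' @return EBGM score(s), positive.
#' @export
ebgm_score <- function(n, e, model) {
  qn <- posterior_weight(n, e, model)
  exp(qn * (digamma(model$alpha1 + n) - log(model$beta1 + e)) +
        (1 - qn) * (digamma(model$alpha2 + n) - log(model$beta2 + e)))
}

#' Posterior quantile of the rate multiplier (EB05, EB95)
#'
#' Solves `F(lambda) = Qn*G1(lambda) + (1-Qn)*G2(lambda) = p` for the
#' posterior gamma-mixture CDF by bracketed bisection between the two
#' component quantiles (the mixture quantile always lies between them);
#' absolute tolerance 1e-9. `EB05 = eb_quantile(..., p = 0.05)` is the
#' conservative lower signal score; `EB95` the upper.
#'
#' @inheritParams marginal_cell_loglik
#' @param p A single probability in (0, 1).
#' @return Posterior lambda quantile(s).
#' @export
eb_quantile <- function(n, e, model, p) {
  stopifnot(inherits(model, "pv_gps_model"))
  check_cells(n, e)
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1) {
    stop_input("p must be a single probability strictly inside (0, 1)")
  }
  qn <- posterior_weight(n, e, model)
  a1 <- model$alpha1 + n; b1 <- model$beta1 + e
  a2 <- model$alpha2 + n; b2 <- model$beta2 + e
  q1 <- qgamma(p, shape = a1, rate = b1)
  q2 <- qgamma(p, shape = a2, rate = b2)
  lo <- pmin(q1, q2)
  hi <- pmax(q1, q2)
  cdf <- function(x) qn * pgamma(x, a1, rate = b1) + (1 - qn) * pgamma(x, a2, rate = b2)
  for (iter in seq_len(200L)) {
    if (max(hi - lo) < 1e-9) break
    mid <- (lo + hi) / 2
    below <- cdf(mid) < p
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  (lo + hi) / 2
}

#' Fit GPS hyperparameters by marginal maximum likelihood
#'
#' Maximizes the summed negative-binomial-mixture log likelihood over the
#' five hyperparameters via quasi-Newton optimization on transformed
#' coordinates (log for shapes and rates, logit for P), from several
#' jittered restarts of the conventional initial value
#' `(0.2, 0.1, 2, 4, 1/3)`; the best converged likelihood wins, ties going
#' to the first start found. Component labels are only identified up to a
#' swap, so the fit is canonicalized with component 1 the larger-prior-mean
#' component. A fitted P within `boundary_tol` of 0 or 1 is flagged as a
#' single-component (degenerate) fit.
#'
#' @param counts A `pv_counts` object (or a tidy data frame with columns
#'   `n` and `e`) with at least `min_cells` cells.
#' @param starts Number of optimization restarts (first is unjittered).
#' @param seed Integer seed controlling start jitter; fits are
#'   deterministic given `seed`.
#' @param init Starting `pv_gps_model`.
#' @param min_cells Minimum number of usable cells (guards against
#'   unidentifiable fits).
#' @param boundary_tol A fitted mixture weight within this distance of 0
#'   or 1 effectively describes a single-component prior and is flagged
#'   degenerate.
#' @return A `pv_gps_fit`: list with `model` (`pv_gps_model`), `loglik`,
#'   `n_cells`, `boundary` flag, and a per-start `starts` tibble.
#' @export
fit_gps <- function(counts, starts = 5L, seed = 1L,
                    init = gps_model(0.2, 0.1, 2, 4, 1/3),
                    min_cells = 50L, boundary_tol = 0.05) {
  if (inherits(counts, "pv_counts")) {
    n <- as.vector(counts$N); e <- as.vector(counts$E)
  } else {
    stopifnot(all(c("n", "e") %in% names(counts)))
    n <- counts$n; e <- counts$e
  }
  keep <- e > 0
  n <- n[keep]; e <- e[keep]
  if (length(n) < min_cells) {
    stop_input("need at least %d cells with E > 0 to fit (got %d)",
               min_cells, length(n))
  }

  nll <- function(phi) {
    m <- phi_to_model(phi)
    ll <- sum(marginal_cell_loglik(n, e, m))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  phi0 <- model_to_phi(init)
  jitter <- local_rng(seed, {
    matrix(rnorm(5L * starts, 0, 0.4), nrow = starts)
  })
  jitter[1L, ] <- 0 # first start is the unjittered init

  runs <- purrr::map(seq_len(starts), function(k) {
    fit <- tryCatch(
      nlminb(phi0 + jitter[k, ], nll, control = list(iter.max = 500L)),
      error = function(err) NULL
    )
    if (is.null(fit)) {
      return(tibble::tibble(start = k, loglik = NA_real_, converged = FALSE,
                            par = list(NULL)))
    }
    tibble::tibble(start = k, loglik = -fit$objective,
                   converged = fit$convergence == 0L, par = list(fit$par))
  }) |> purrr::list_rbind()

  # flat likelihoods make quasi-Newton optimizers report "false
  # convergence" at a perfectly usable optimum, so any start with a
  # finite objective competes; the per-start convergence codes are kept
  # in the report
  ok <- runs[is.finite(runs$loglik), ]
  if (nrow(ok) == 0L) {
    stop_input("GPS fit failed to converge from any of %d starts", starts)
  }
  best <- ok[which.max(ok$loglik), ]
  model <- canonicalize_gps(phi_to_model(best$par[[1L]]))
  boundary <- model$p < boundary_tol || model$p > 1 - boundary_tol
  structure(
    list(model = model, loglik = best$loglik, n_cells = length(n),
         boundary = boundary, starts = runs[, c("start", "loglik", "converged")]),
    class = "pv_gps_fit"
  )
}

phi_to_model <- function(phi) {
  gps_model(exp(phi[1L]), exp(phi[2L]), exp(phi[3L]), exp(phi[4L]),
            stats::plogis(phi[5L]))
}

model_to_phi <- function(m) {
  c(log(m$alpha1), log(m$beta1), log(m$alpha2), log(m$beta2), stats::qlogis(m$p))
}

canonicalize_gps <- function(m) {
  if (m$alpha1 / m$beta1 >= m$alpha2 / m$beta2) return(m)
  gps_model(m$alpha2, m$beta2, m$alpha1, m$beta1, 1 - m$p)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
print.pv_gps_fit <- function(x, ...) {
  cat(sprintf("<pv_gps_fit> loglik %.3f on %d cells%s\n", x$loglik, x$n_cells,
              if (x$boundary) " [P at boundary: single-component fit]" else ""))
  print(x$model)
  invisible(x)
}

#' @rdname fit_gps
#' @param x A `pv_gps_fit` object.
#' @param ... Unused.
#' @export
tidy.pv_gps_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "p"),
    estimate = unlist(x$model[c("alpha1", "beta1", "alpha2", "beta2", "p")])
  )
}

#' @rdname fit_gps
#' @export
glance.pv_gps_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, n_cells = x$n_cells, prior_mean = gps_prior_mean(x$model),
    boundary = x$boundary,
    n_starts = nrow(x$starts), n_converged = sum(x$starts$converged)
  )
}
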