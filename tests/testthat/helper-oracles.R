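# Independent oracles used across tests. These deliberately avoid the
# package's own computational paths: posterior quantities come from direct
# numeric integration of Poisson x gamma-mixture densities, and the rank
# tests are checked by exhaustive enumeration.

# Unnormalized posterior density of lambda given count n at baseline e.
oracle_post_density <- function(lambda, n, e, th) {
  prior <- th$p * dgamma(lambda, th$alpha1, rate = th$beta1) +
    (1 - th$p) * dgamma(lambda, th$alpha2, rate = th$beta2)
  dpois(n, lambda * e) * prior
}

oracle_norm <- function(n, e, th) {
  integrate(oracle_post_density, 0, Inf, n = n, e = e, th = th,
            rel.tol = 1e-10, subdivisions = 500L)$value
}

# Posterior probability the cell's lambda came from mixture component 1.
oracle_qn <- function(n, e, th) {
  comp1 <- integrate(function(l) dpois(n, l * e) * dgamma(l, th$alpha1, rate = th$beta1),
                     0, Inf, rel.tol = 1e-10, subdivisions = 500L)$value
  th$p * comp1 / oracle_norm(n, e, th)
}

# exp(E[log lambda | n]) by quadrature.
oracle_ebgm <- function(n, e, th) {
  z <- oracle_norm(n, e, th)
  elog <- integrate(function(l) log(l) * oracle_post_density(l, n, e, th),
                    0, Inf, rel.tol = 1e-10, subdivisions = 500L)$value / z
  exp(elog)
}

# Posterior lambda quantile by root-finding on the integrated density.
oracle_eb_quantile <- function(n, e, th, p) {
  z <- oracle_norm(n, e, th)
  cdf <- function(q) {
    integrate(oracle_post_density, 0, q, n = n, e = e, th = th,
              rel.tol = 1e-10, subdivisions = 500L)$value / z
  }
  uniroot(function(q) cdf(q) - p, c(1e-8, 100), tol = 1e-10)$root
}

# Friedman statistic straight from its definition (no tie correction),
# for hand-checkable tie-free designs.
oracle_friedman_stat <- function(y) {
  b <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1, rank))
  12 / (b * k * (k + 1)) * sum(colSums(r)^2) - 3 * b * (k + 1)
}

# Exact permutation p-value for the Friedman statistic: enumerate all
# within-block orderings ((k!)^b designs) of the observed values.
oracle_friedman_perm_p <- function(y) {
  b <- nrow(y); k <- ncol(y)
  perms <- as.matrix(expand.grid(rep(list(1:k), k)))
  perms <- perms[apply(perms, 1, function(x) length(unique(x)) == k), , drop = FALSE]
  obs <- oracle_friedman_stat(y)
  choices <- rep(list(seq_len(nrow(perms))), b)
  grid <- as.matrix(expand.grid(choices))
  stats <- apply(grid, 1, function(sel) {
    yy <- y
    for (i in seq_len(b)) yy[i, ] <- y[i, perms[sel[i], ]]
    oracle_friedman_stat(yy)
  })
  mean(stats >= obs - 1e-12)
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign vectors.
oracle_wilcoxon_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs + 1e-12), mean(v_all >= v_obs - 1e-12)))
}

canonical_theta <- function() gps_model(0.2, 0.1, 2, 4, 1/3)

# Small ingest fixture shared by ingest/selection tests.
toy_dictionary <- function() {
  tibble::tibble(
    variant = c("sildenafil", "revatio", "viagra", "bosentan", "amlodipine"),
    ingredient = c("sildenafil", "sildenafil", "sildenafil", "bosentan", "amlodipine"),
    atc_class = c("UAs", "UAs", "UAs", "AHAs", "CCBs"),
    atc3 = c("G04B", "G04B", "G04B", "C02K", "C08C")
  )
}
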