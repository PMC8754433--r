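test_that("profile correlations match hand-computed Pearson values", {
  prof <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), d = c(2, 4, 6, 8))
  expect_equal(profile_correlation(prof)["a", "b"], 1)
  neg <- rbind(a = c(1, 2, 3), b = -c(1, 2, 3))
  expect_equal(profile_correlation(neg)["a", "b"], -1)

  # three hand-entered profiles, correlation from the definition
  x <- c(1, 4, 2); y <- c(2, 5, 9); z <- c(7, 1, 3)
  hand <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  cc <- profile_correlation(rbind(x = x, y = y, z = z))
  expect_equal(cc["x", "y"], hand(x, y), tolerance = 1e-12)
  expect_equal(cc["x", "z"], hand(x, z), tolerance = 1e-12)
  expect_equal(cc["y", "z"], hand(y, z), tolerance = 1e-12)
  expect_equal(unname(diag(cc)), rep(1, 3))

  expect_error(profile_correlation(rbind(a = c(1, 1, 1), b = 1:3)), "a")
})

test_that("graphical lasso recovers the inverse at zero penalty and
           full sparsity at large penalty", {
  set.seed(51)
  for (rep in 1:3) {
    S <- cor(matrix(rnorm(400 * 5), 400, 5))
    g0 <- glasso_estimate(S, 0)
    expect_lt(max(abs(g0$precision - solve(S))), 1e-4)
  }

  S <- cor(matrix(rnorm(200 * 6), 200, 6))
  gmax <- glasso_estimate(S, 1.01 * max(abs(S[upper.tri(S)])))
  expect_false(any(gmax$adjacency))
  expect_equal(unname(diag(gmax$precision)),
               1 / (diag(S) + gmax$penalty), tolerance = 1e-6)

  expect_error(glasso_estimate(S, -1), "non-negative")
  expect_error(glasso_estimate(S[, 1:3], 0.1), "symmetric")
})

test_that("independent blocks never acquire cross-block edges", {
  set.seed(52)
  z1 <- rnorm(300); z2 <- rnorm(300)
  X <- cbind(z1 + rnorm(300, 0, 0.3), z1 + rnorm(300, 0, 0.3),
             z1 + rnorm(300, 0, 0.3), z2 + rnorm(300, 0, 0.3),
             z2 + rnorm(300, 0, 0.3), z2 + rnorm(300, 0, 0.3))
  S <- cor(X)
  # exact block-diagonal input: cross-block precision must stay zero
  S0 <- S
  S0[1:3, 4:6] <- 0
  S0[4:6, 1:3] <- 0
  for (rho in c(0.01, 0.1, 0.4)) {
    g <- glasso_estimate(S0, rho)
    expect_false(any(g$adjacency[1:3, 4:6]))
  }
})

test_that("penalty tuning hits the 50% retention calibration", {
  gp <- gen_clustered_profiles(sim_config(seed = 7))
  tuned <- tune_retention(gp$profiles, 0.5)
  expect_identical(length(tuned$retained), 22L)
  expect_equal(tuned$fraction, 0.5)
  expect_true(tuned$target_attained)
  # retained drugs are exactly the planted cluster drugs
  expect_setequal(tuned$retained, names(gp$labels)[gp$labels > 0])

  small <- gp$profiles[1:8, ]
  all_in <- tune_retention(small, 1)
  expect_identical(length(all_in$retained), 8L)
  none <- suppressWarnings(tune_retention(small, 0))
  expect_identical(length(none$retained), 0L)

  # retention is monotone non-increasing along the penalty trace
  tr <- tuned$trace
  expect_true(all(diff(tr$n_retained[order(tr$penalty)]) <= 0))
})

test_that("planted blocks are recovered as GL clusters", {
  skip_if_not_installed("mclust")
  gp <- gen_clustered_profiles(sim_config(seed = 7))
  tuned <- tune_retention(gp$profiles, 0.5)
  cl <- tuned$graph$clusters
  ari <- mclust::adjustedRandIndex(cl, gp$labels[names(cl)])
  expect_gte(ari, 0.9)
})

test_that("cluster labels are ordered by size with deterministic ties", {
  adj <- matrix(0, 9, 9, dimnames = list(letters[1:9], letters[1:9]))
  adj[1:7, 1:7] <- 1 # seven-node clique
  diag(adj) <- 0
  adj["h", "i"] <- adj["i", "h"] <- 1
  cl <- extract_clusters(adj)
  expect_identical(unname(cl[letters[1:7]]), rep(1L, 7))
  expect_identical(unname(cl[c("h", "i")]), c(2L, 2L))

  path <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  path[cbind(1:3, 2:4)] <- 1
  path <- path + t(path)
  expect_identical(unname(unique(extract_clusters(path))), 1L)

  expect_identical(length(extract_clusters(matrix(0, 0, 0))), 0L)
})

test_that("RCM ordering reduces bandwidth deterministically", {
  # a shuffled path graph comes back to bandwidth 1 (the optimum)
  n <- 9
  A <- matrix(0, n, n)
  A[cbind(1:(n - 1), 2:n)] <- 1
  A <- A + t(A)
  set.seed(53)
  p <- sample(n)
  Ap <- A[p, p]
  expect_identical(matrix_bandwidth(Ap, rcm_order(Ap)), 1L)

  # an already-banded matrix is not made worse
  expect_lte(matrix_bandwidth(A, rcm_order(A)), matrix_bandwidth(A))

  # twenty random sparse graphs: never worse than the input order
  for (rep in 1:20) {
    m <- 12
    B <- matrix(rbinom(m * m, 1, 0.15), m, m)
    B <- (B + t(B)) > 0
    diag(B) <- FALSE
    expect_lte(matrix_bandwidth(B, rcm_order(B)), matrix_bandwidth(B))
  }

  # determinism
  expect_identical(rcm_order(Ap), rcm_order(Ap))
})

test_that("block expansion lays profiles on the diagonal", {
  prof <- rbind(d1 = c(1, 2, 3), d2 = c(4, 5, 6))
  ex <- expand_block_matrix(prof)
  expect_identical(dim(ex), c(2L, 6L))
  expect_equal(unname(ex[1, ]), c(1, 2, 3, 0, 0, 0))
  expect_equal(unname(ex[2, ]), c(0, 0, 0, 4, 5, 6))
  expect_equal(unname(colSums(ex)), c(1, 2, 3, 4, 5, 6))

  wide <- matrix(1, 22, 17)
  expect_identical(dim(expand_block_matrix(wide)), c(22L, 374L))
})

test_that("diagram exports are complete and byte-stable", {
  gp <- gen_clustered_profiles(sim_config(n_drugs = 12, n_ades = 17,
                                          drug_scale = rep(3, 12),
                                          blocks = list(list(drugs = 1:4, ades = 1:6),
                                                        list(drugs = 5:8, ades = 10:15)),
                                          seed = 54))
  tuned <- tune_retention(gp$profiles, 8 / 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- export_diagram(tuned$graph, d1, dictionary = sim_dictionary(tuned$graph$nodes))
  p2 <- export_diagram(tuned$graph, d2, dictionary = sim_dictionary(tuned$graph$nodes))
  for (f in c("nodes", "edges", "adjacency")) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  nodes <- readr::read_tsv(p1$nodes, show_col_types = FALSE)
  expect_identical(nrow(nodes), length(tuned$graph$nodes))
  expect_true(all(c("drug", "atc_class", "gl_cluster", "rcm_position") %in% names(nodes)))

  # two-node, one-edge graph exports exactly one edge row
  pair <- tune_retention(gp$profiles[c(1, 2, 9), ], 2 / 3)
  dp <- withr::local_tempdir()
  pe <- export_diagram(pair$graph, dp)
  expect_identical(nrow(readr::read_tsv(pe$edges, show_col_types = FALSE)), 1L)

  # empty graph: header-only tables
  none <- suppressWarnings(tune_retention(gp$profiles[1:4, ], 0))
  d0 <- withr::local_tempdir()
  p0 <- export_diagram(none$graph, d0)
  expect_identical(nrow(readr::read_tsv(p0$nodes, show_col_types = FALSE)), 0L)
  expect_identical(nrow(readr::read_tsv(p0$edges, show_col_types = FALSE)), 0L)
})
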