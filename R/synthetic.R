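## Synthetic spontaneous-report generator: FAERS-like inputs with known
## ground truth (lambda matrix, planted drug blocks, name variants,
## multi-drug cases) so every pipeline stage is testable without downloads.

#' Configure the synthetic report simulator
#'
#' Defaults describe the cohort geometry the package's validation scenarios
#' use throughout: 44 drugs by 17 pulmonary HLT terms, with 22 signal drugs
#' in four blocks (sizes 6, 6, 5, 5) sharing elevated ADE profiles at
#' multiplier 5 with profile noise sd 0.5, baseline expected counts between
#' 5 and 50, a two-gamma mixture prior at the conventional hyperparameters
#' (0.2, 0.1, 2, 4, 1/3), 30% of drug mentions written as name variants,
#' and 28% of cases listing two drugs (echoing the ~1.28 per-drug-rows to
#' cases ratio typical of hypertension-cohort spontaneous reports).
#'
#' @param n_drugs,n_ades Table dimensions.
#' @param theta_true `pv_gps_model` prior generating the cell rate
#'   multipliers lambda.
#' @param drug_scale,ade_scale Positive vectors; baseline expected counts
#'   are `E = outer(drug_scale, ade_scale)`.
#' @param blocks List of cluster blocks, each `list(drugs =, ades =)` with
#'   integer index vectors; drug sets must be disjoint. Drugs outside all
#'   blocks are null (noise) drugs.
#' @param signal_multiplier Elevated profile level for block cells (> 1).
#' @param noise_sd Gaussian sd added to clustered profiles.
#' @param synonym_rate Fraction of drug mentions emitted under a dictionary
#'   name variant instead of the ingredient id.
#' @param multidrug_rate Fraction of cases carrying two drugs.
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A `pv_sim_config` list.
#' @export
sim_config <- function(n_drugs = 44L, n_ades = 17L,
                       theta_true = gps_model(0.2, 0.1, 2, 4, 1/3),
                       drug_scale = seq(sqrt(5), sqrt(50), length.out = n_drugs),
                       ade_scale = seq(sqrt(5), sqrt(50), length.out = n_ades),
                       blocks = default_blocks(n_drugs, n_ades),
                       signal_multiplier = 5, noise_sd = 0.5,
                       synonym_rate = 0.3, multidrug_rate = 0.28,
                       seed = 1L) {
  stopifnot(n_drugs >= 1L, n_ades >= 1L, inherits(theta_true, "pv_gps_model"))
  if (any(drug_scale <= 0) || any(ade_scale <= 0)) {
    stop_input("margin-profile scales must be positive")
  }
  if (length(drug_scale) != n_drugs || length(ade_scale) != n_ades) {
    stop_input("scale lengths must match n_drugs / n_ades")
  }
  if (signal_multiplier <= 1) stop_input("signal_multiplier must exceed 1")
  if (length(blocks)) {
    all_drugs <- unlist(purrr::map(blocks, "drugs"))
    if (anyDuplicated(all_drugs)) stop_input("cluster blocks must be disjoint")
    if (any(all_drugs < 1L | all_drugs > n_drugs)) stop_input("block drug index out of range")
    if (any(unlist(purrr::map(blocks, "ades")) > n_ades)) stop_input("block ADE index out of range")
  }
  if (synonym_rate < 0 || synonym_rate > 1 || multidrug_rate < 0 || multidrug_rate > 1) {
    stop_input("rates must lie in [0, 1]")
  }
  structure(
    list(n_drugs = as.integer(n_drugs), n_ades = as.integer(n_ades),
         theta_true = theta_true, drug_scale = drug_scale, ade_scale = ade_scale,
         blocks = blocks, signal_multiplier = signal_multiplier,
         noise_sd = noise_sd, synonym_rate = synonym_rate,
         multidrug_rate = multidrug_rate, seed = as.integer(seed)),
    class = "pv_sim_config"
  )
}

# Four disjoint blocks over the first 22 drugs with partially overlapping
# elevated-ADE windows; empty when the table is too small to host them.
default_blocks <- function(n_drugs, n_ades) {
  if (n_drugs < 22L || n_ades < 17L) return(list())
  sizes <- c(6L, 6L, 5L, 5L)
  starts <- cumsum(c(1L, utils::head(sizes, -1L)))
  ade_sets <- list(1:5, 5:9, 9:13, 13:17)
  purrr::map(1:4, function(k) {
    list(drugs = seq.int(starts[k], length.out = sizes[k]), ades = ade_sets[[k]])
  })
}

sim_drug_ids <- function(n) sprintf("drug%02d", seq_len(n))
sim_ade_ids <- function(n) sprintf("ade%02d", seq_len(n))

#' Simulate a drug x ADE count table from the GPS generative model
#'
#' Each cell's rate multiplier is drawn from the two-gamma mixture prior
#' (`P Gamma(alpha1, beta1) + (1-P) Gamma(alpha2, beta2)`, rate
#' parameterization), then `N_ij ~ Poisson(lambda_ij * E_ij)` with the
#' design baseline `E = outer(drug_scale, ade_scale)`. The returned count
#' table carries this design `E` (the true baseline), not the
#' independence-estimated one an ingest pass would compute.
#'
#' @param config A `pv_sim_config`.
#' @return A list with `counts` (`pv_counts`, with design baseline) and
#'   `lambda` (the ground-truth rate-multiplier matrix).
#' @export
gen_gps_counts <- function(config) {
  stopifnot(inherits(config, "pv_sim_config"))
  th <- config$theta_true
  nd <- config$n_drugs; na <- config$n_ades
  E <- outer(config$drug_scale, config$ade_scale)
  local_rng(config$seed, {
    z <- runif(nd * na) < th$p
    lambda <- ifelse(z,
                     rgamma(nd * na, shape = th$alpha1, rate = th$beta1),
                     rgamma(nd * na, shape = th$alpha2, rate = th$beta2))
    N <- rpois(nd * na, lambda * as.vector(E))
    lambda <- matrix(lambda, nd, na)
    N <- matrix(as.double(N), nd, na)
    dimnames(N) <- dimnames(lambda) <- dimnames(E) <-
      list(sim_drug_ids(nd), sim_ade_ids(na))
    counts <- structure(
      list(drugs = rownames(N), ades = colnames(N), N = N, E = E,
           row_margins = rowSums(N), col_margins = colSums(N),
           grand_total = sum(N), baseline = "design"),
      class = "pv_counts"
    )
    list(counts = counts, lambda = lambda)
  })
}

#' Simulate clustered EBGM-like drug profiles with ground-truth labels
#'
#' Drugs inside a block share an elevated mean profile
#' (`signal_multiplier`) on the block's ADE index set (baseline 1
#' elsewhere) plus independent Gaussian noise; drugs outside all blocks are
#' pure noise around baseline and are mutually independent. Labels (block
#' number, 0 for null drugs) are returned for cluster-recovery scoring.
#'
#' @param config A `pv_sim_config`.
#' @return A list with `profiles` (drugs x ADEs matrix) and `labels`
#'   (integer vector, 0 = no block).
#' @export
gen_clustered_profiles <- function(config) {
  stopifnot(inherits(config, "pv_sim_config"))
  nd <- config$n_drugs; na <- config$n_ades
  mean_mat <- matrix(1, nd, na)
  labels <- integer(nd)
  for (k in seq_along(config$blocks)) {
    b <- config$blocks[[k]]
    mean_mat[b$drugs, b$ades] <- config$signal_multiplier
    labels[b$drugs] <- k
  }
  profiles <- local_rng(config$seed, {
    mean_mat + matrix(rnorm(nd * na, 0, config$noise_sd), nd, na)
  })
  dimnames(profiles) <- list(sim_drug_ids(nd), sim_ade_ids(na))
  names(labels) <- rownames(profiles)
  list(profiles = profiles, labels = labels)
}

sim_atc_classes <- function() {
  c("ACEIs", "ARBs", "Other RAS agents", "Other antihypertensives",
    "Antithrombotic agents", "Beta blocking agents", "Calcium channel blockers",
    "Diuretics", "Lipid modifying agents", "Urologicals", "Vasoprotectives",
    "Combinations")
}

#' Build the synthetic drug dictionary
#'
#' Four name variants per ingredient: the ingredient itself, a salt form
#' (`"<ingredient> citrate"`), a manufacturer-prefixed form
#' (`"apo <ingredient>"`), and a brand-like alias (`"<ingredient>ol"`) that
#' only resolves through the dictionary. ATC classes cycle through the 12
#' antihypertensive-cohort classes.
#'
#' @param drug_ids Character vector of ingredient ids.
#' @return A dictionary tibble (`variant`, `ingredient`, `atc_class`, `atc3`).
#' @export
sim_dictionary <- function(drug_ids) {
  cls <- sim_atc_classes()
  atc <- rep(cls, length.out = length(drug_ids))
  purrr::map2(drug_ids, atc, function(d, a) {
    tibble::tibble(
      variant = c(d, paste(d, "citrate"), paste("apo", d), paste0(d, "ol")),
      ingredient = d, atc_class = a,
      atc3 = paste0("L3-", sprintf("%02d", match(a, cls)))
    )
  }) |> purrr::list_rbind()
}

#' Simulate a count table with planted signal drugs over a quiet baseline
#'
#' Unlike [gen_gps_counts()] (whose cell multipliers are all prior draws),
#' this generator plants interpretable structure for end-to-end filter and
#' clustering tests: baseline cells have rate multiplier ~= 1 (mild
#' lognormal jitter, so null drugs carry no signal), drugs in the config's
#' cluster blocks share `signal_multiplier` on their block's ADE set
#' (correlated profiles, recoverable as GL clusters), and optional
#' "scattered" signal drugs are elevated on their own random small ADE
#' sets (signals that pass the EB05 rule but, being idiosyncratic,
#' are shrunk away by the graphical lasso).
#'
#' @param config A `pv_sim_config`.
#' @param scattered Integer indices of scattered-signal drugs (disjoint
#'   from the block drugs).
#' @param scattered_n_ades Number of elevated ADEs per scattered drug.
#' @param jitter_sd Lognormal sd of the baseline multiplier jitter.
#' @return A list with `counts` (`pv_counts`, design baseline), `lambda`,
#'   and `truth` (tibble: `drug`, `role` in planted/scattered/null,
#'   `block`).
#' @export
gen_planted_counts <- function(config, scattered = integer(),
                               scattered_n_ades = 3L, jitter_sd = 0.05) {
  stopifnot(inherits(config, "pv_sim_config"))
  nd <- config$n_drugs; na <- config$n_ades
  block_drugs <- unlist(purrr::map(config$blocks, "drugs"))
  if (length(intersect(scattered, block_drugs))) {
    stop_input("scattered drugs must be disjoint from block drugs")
  }
  E <- outer(config$drug_scale, config$ade_scale)
  local_rng(config$seed + 2L, {
    mult <- matrix(1, nd, na)
    block_of <- integer(nd)
    for (k in seq_along(config$blocks)) {
      b <- config$blocks[[k]]
      mult[b$drugs, b$ades] <- config$signal_multiplier
      block_of[b$drugs] <- k
    }
    for (d in scattered) {
      mult[d, sample.int(na, scattered_n_ades)] <- config$signal_multiplier
    }
    lambda <- mult * matrix(exp(rnorm(nd * na, 0, jitter_sd)), nd, na)
    N <- matrix(as.double(rpois(nd * na, lambda * as.vector(E))), nd, na)
    dimnames(N) <- dimnames(lambda) <- dimnames(E) <-
      list(sim_drug_ids(nd), sim_ade_ids(na))
    counts <- structure(
      list(drugs = rownames(N), ades = colnames(N), N = N, E = E,
           row_margins = rowSums(N), col_margins = colSums(N),
           grand_total = sum(N), baseline = "design"),
      class = "pv_counts"
    )
    truth <- tibble::tibble(
      drug = rownames(N),
      role = dplyr::case_when(
        block_of > 0L ~ "planted",
        seq_len(nd) %in% scattered ~ "scattered",
        TRUE ~ "null"
      ),
      block = block_of
    )
    list(counts = counts, lambda = lambda, truth = truth)
  })
}

#' Simulate case-level report files realizing a known count table
#'
#' Draws a target count table from the GPS model, then writes case-level
#' rows realizing it exactly: each cell count becomes that many drug
#' mentions, a configured fraction of cases list two (distinct) drugs for
#' the same event, and a configured fraction of mentions use dictionary
#' name variants. Ingesting the emitted files with the emitted dictionary
#' reproduces the target counts exactly; ingesting without the dictionary
#' does not (variant rows go unmatched).
#'
#' @param config A `pv_sim_config`.
#' @param dir Output directory (created if missing).
#' @param counts Optional target `pv_counts` to realize (defaults to a
#'   fresh [gen_gps_counts()] draw).
#' @return A list with file paths `reports`, `dictionary`, `vocabulary`,
#'   plus the ground truth `counts` (`pv_counts`) and `lambda` (`NULL`
#'   when `counts` was supplied).
#' @export
gen_case_reports <- function(config, dir = tempfile("pvsim"), counts = NULL) {
  stopifnot(inherits(config, "pv_sim_config"))
  sim <- if (is.null(counts)) gen_gps_counts(config)
         else list(counts = counts, lambda = NULL)
  N <- sim$counts$N
  drug_ids <- rownames(N); ade_ids <- colnames(N)
  dict <- sim_dictionary(drug_ids)
  # variant matrix: column 1 is the ingredient itself, 2..4 are aliases
  vmat <- matrix(dict$variant, nrow = 4L)[, match(drug_ids, unique(dict$ingredient)),
                                          drop = FALSE]

  cases <- local_rng(config$seed + 1L, {
    per_ade <- purrr::map(seq_along(ade_ids), function(j) {
      slots <- rep(seq_along(drug_ids), times = N[, j])
      if (!length(slots)) return(NULL)
      slots <- sample(slots)
      L <- length(slots)
      # greedy sequential pairing of adjacent distinct-drug slots
      upair <- runif(L) < config$multidrug_rate
      case_of <- integer(L)
      cid <- 0L
      i <- 1L
      while (i <= L) {
        cid <- cid + 1L
        if (i < L && upair[i] && slots[i] != slots[i + 1L]) {
          case_of[c(i, i + 1L)] <- cid
          i <- i + 2L
        } else {
          case_of[i] <- cid
          i <- i + 1L
        }
      }
      use_var <- runif(L) < config$synonym_rate
      vrow <- sample(2:4, L, replace = TRUE)
      name <- ifelse(use_var, vmat[cbind(vrow, slots)], drug_ids[slots])
      tibble::tibble(ade = j, case = case_of, name = name)
    })
    per_ade <- purrr::list_rbind(purrr::compact(per_ade))
    per_ade |>
      dplyr::group_by(.data$ade, .data$case) |>
      dplyr::summarise(drug = paste(.data$name, collapse = ";"), .groups = "drop") |>
      dplyr::mutate(
        case_id = sprintf("C%06d", dplyr::row_number()),
        hlt = ade_ids[.data$ade],
        soc = "Respiratory, thoracic and mediastinal disorders"
      ) |>
      dplyr::select("case_id", "drug", "hlt", "soc")
  })

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(reports = file.path(dir, "reports.tsv"),
                dictionary = file.path(dir, "dictionary.tsv"),
                vocabulary = file.path(dir, "vocabulary.tsv"))
  write_reports(cases, paths$reports)
  readr::write_tsv(dict, paths$dictionary)
  readr::write_tsv(
    tibble::tibble(hlt = ade_ids,
                   soc = "Respiratory, thoracic and mediastinal disorders"),
    paths$vocabulary
  )
  c(paths, list(counts = sim$counts, lambda = sim$lambda))
}

#' Build a complete desk-scale pipeline scenario on disk
#'
#' A 60-drug by 17-ADE cohort mirroring the staged funnel the full
#' pipeline is designed around: 22 drugs in four planted cluster blocks
#' (correlated elevated profiles), 22 scattered-signal drugs (elevated on
#' idiosyncratic small ADE sets, so they pass the EB05 rule but fall to
#' the graphical lasso), and 16 null drugs. Report files, dictionary and
#' vocabulary are written via [gen_case_reports()].
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return As [gen_case_reports()], plus `truth` (drug roles/blocks) and
#'   the `config` used.
#' @export
gen_pipeline_scenario <- function(dir = tempfile("pvscn"), seed = 1L) {
  cfg <- sim_config(n_drugs = 60L, n_ades = 17L, seed = seed)
  planted <- gen_planted_counts(cfg, scattered = 23:44)
  out <- gen_case_reports(cfg, dir, counts = planted$counts)
  out$lambda <- planted$lambda
  out$truth <- planted$truth
  out$config <- cfg
  out
}
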