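## End-to-end pipeline: ingest -> score -> filter -> cluster -> compare ->
## export, driven by a single config with one root seed, emitting a
## manifest that fully reconstructs every threshold used.

#' Build a pipeline configuration
#'
#' @param reports,dictionary,vocabulary Paths to the three input files
#'   (see [read_reports()], [read_drug_dictionary()],
#'   [read_ade_vocabulary()]).
#' @param out_dir Output directory.
#' @param min_reports Per-drug report-row floor (default 500).
#' @param rr_threshold RR selection cut-off (default 2).
#' @param eb05_threshold,min_ades EB05 selection rule (defaults 1 and 2).
#' @param retention Target fraction of drugs retained by the
#'   graphical-lasso tuning, in (0, 1] (default 0.5).
#' @param exclusions Named pulmonary HLT exclusions.
#' @param soc_include,extra_hlts Pulmonary vocabulary definition; see
#'   [pulmonary_subset()].
#' @param seed Root seed for every stochastic step.
#' @return A `pv_pipeline_config` list.
#' @export
pipeline_config <- function(reports, dictionary, vocabulary, out_dir,
                            min_reports = 500, rr_threshold = 2,
                            eb05_threshold = 1, min_ades = 2,
                            retention = 0.5,
                            exclusions = pv_unrelated_pulmonary_terms(),
                            soc_include = "Respiratory, thoracic and mediastinal disorders",
                            extra_hlts = character(), seed = 1L) {
  for (field in c("reports", "dictionary", "vocabulary")) {
    path <- get(field)
    if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
      stop_input("config field '%s' must name an existing file", field)
    }
  }
  if (min_reports < 0 || rr_threshold <= 0 || eb05_threshold <= 0 || min_ades < 1) {
    stop_input("thresholds must be positive")
  }
  if (retention <= 0 || retention > 1) stop_input("retention must lie in (0, 1]")
  structure(
    list(reports = reports, dictionary = dictionary, vocabulary = vocabulary,
         out_dir = out_dir, min_reports = min_reports,
         rr_threshold = rr_threshold, eb05_threshold = eb05_threshold,
         min_ades = min_ades, retention = retention, exclusions = exclusions,
         soc_include = soc_include, extra_hlts = extra_hlts,
         seed = as.integer(seed)),
    class = "pv_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Fields mirror the arguments of [pipeline_config()]; relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pv_pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (field in c("reports", "dictionary", "vocabulary", "out_dir")) {
    if (!is.null(y[[field]]) && !grepl("^(/|[A-Za-z]:)", y[[field]])) {
      y[[field]] <- file.path(base, y[[field]])
    }
  }
  args <- utils::modifyList(y, list(...))
  do.call(pipeline_config, args)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(err) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(err)),
         call. = FALSE)
  })
}

#' Run the full signal-detection pipeline
#'
#' Executes the fixed stage order ingest -> GPS scoring -> staged
#' filtering -> graphical-lasso clustering -> group comparison -> export,
#' writing per-stage tables under `config$out_dir` and a JSON manifest
#' recording the package version, seed, every threshold, and per-stage
#' row/drug counts. Identical config and seed give byte-identical
#' manifests and outputs.
#'
#' @param config A `pv_pipeline_config` (or path to a YAML config).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pv_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    seed = config$seed,
    thresholds = config[c("min_reports", "rr_threshold", "eb05_threshold",
                          "min_ades", "retention")],
    stages = list()
  )

  # -- ingest ----------------------------------------------------------
  ing <- run_stage("ingest", {
    cases <- read_reports(config$reports)
    dict <- read_drug_dictionary(config$dictionary)
    vocab <- read_ade_vocabulary(config$vocabulary)
    records <- ingest_reports(cases, dict, vocabulary = vocab, quiet = TRUE)
    list(cases = cases, dict = dict, vocab = vocab, records = records)
  })
  manifest$stages$ingest <- list(
    n_cases = nrow(ing$cases), n_records = nrow(ing$records),
    n_unmatched_rows = sum(attr(ing$records, "unmatched")$n_rows %||% 0L),
    n_drugs = dplyr::n_distinct(ing$records$drug),
    n_ades = dplyr::n_distinct(ing$records$hlt)
  )

  # -- report-count floor, then the frozen baseline table --------------
  flt <- run_stage("filter_min_reports", {
    filter_min_reports(ing$records, config$min_reports, ing$dict)
  })
  kept <- retained_drugs(flt)
  records <- ing$records[ing$records$drug %in% kept, ]
  counts <- run_stage("count_table", build_count_table(records))
  manifest$stages$min_reports <- list(
    threshold = config$min_reports, n_drugs_retained = length(kept),
    n_reports = nrow(records)
  )

  # -- GPS scoring on the full post-floor table ------------------------
  fit <- run_stage("gps_fit", fit_gps(counts, seed = config$seed))
  signals <- run_stage("score", score_table(counts, fit))
  readr::write_tsv(tibble::as_tibble(signals), file.path(config$out_dir, "signals.tsv"))
  jsonlite::write_json(
    c(unclass(fit$model), list(loglik = fit$loglik, n_cells = fit$n_cells)),
    file.path(config$out_dir, "gps_model.json"), auto_unbox = TRUE, digits = NA
  )
  manifest$stages$gps <- c(unclass(fit$model),
                           list(loglik = fit$loglik, boundary = fit$boundary))

  # -- pulmonary subsetting and the selection rules --------------------
  sel <- run_stage("selection", {
    vocab_status <- pulmonary_subset(ing$vocab, config$exclusions, records,
                                     soc_include = config$soc_include,
                                     extra_hlts = config$extra_hlts)
    ades <- analyzed_ades(vocab_status)
    pulmo <- signals[signals$ade %in% ades, ]
    rr_prof <- select_by_rr(pulmo, config$rr_threshold)
    eb_prof <- select_by_eb05(pulmo, config$eb05_threshold, config$min_ades,
                              dictionary = ing$dict)
    list(vocab_status = vocab_status, ades = ades, pulmo = pulmo,
         rr_prof = rr_prof, eb_prof = eb_prof)
  })
  selected <- retained_drugs(sel$eb_prof)
  readr::write_tsv(sel$vocab_status, file.path(config$out_dir, "ade_vocabulary_status.tsv"))
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(sel$eb_prof), -dplyr::where(is.list)),
    file.path(config$out_dir, "drug_profiles_eb05.tsv")
  )
  manifest$stages$selection <- list(
    n_analyzed_ades = length(sel$ades),
    n_drugs_rr = sum(sel$rr_prof$n_flagged > 0),
    n_drugs_selected = length(selected),
    rank_ebgm = rank_drugs(sel$eb_prof, "ebgm")
  )
  if (length(selected) < 2L) {
    stop("pipeline stage 'network' failed: fewer than two drugs selected",
         call. = FALSE)
  }

  # -- graphical-lasso clustering --------------------------------------
  net <- run_stage("network", {
    prof <- signal_matrix(sel$pulmo, "ebgm")[selected, sel$ades, drop = FALSE]
    tuned <- tune_retention(prof, config$retention)
    expansion <- expand_block_matrix(prof[tuned$retained, , drop = FALSE])
    paths <- export_diagram(tuned$graph, config$out_dir, expansion = expansion,
                            dictionary = ing$dict)
    list(tuned = tuned, paths = paths)
  })
  manifest$stages$network <- list(
    penalty = net$tuned$penalty,
    n_input_drugs = length(selected),
    n_retained = length(net$tuned$retained),
    retained_fraction = net$tuned$fraction,
    target_attained = net$tuned$target_attained,
    n_clusters = length(unique(net$tuned$graph$clusters))
  )

  # -- homogeneity and pairwise comparisons ----------------------------
  cmp <- run_stage("compare", {
    atc <- dplyr::distinct(ing$dict, drug = .data$ingredient, .data$atc_class)
    pulmo_sel <- sel$pulmo[sel$pulmo$drug %in% net$tuned$retained, ]
    atc_groups <- dplyr::filter(
      dplyr::transmute(atc, drug = .data$drug, group = .data$atc_class),
      .data$drug %in% net$tuned$retained
    )
    gl_groups <- tibble::tibble(drug = names(net$tuned$graph$clusters),
                                group = paste0("GL", net$tuned$graph$clusters))
    res <- dplyr::bind_rows(
      dplyr::mutate(within_group_homogeneity(pulmo_sel, atc_groups), grouping = "atc"),
      dplyr::mutate(within_group_homogeneity(pulmo_sel, gl_groups), grouping = "gl")
    )
    pw <- pairwise_class_comparison(pulmo_sel, gl_groups)
    list(res = res, pw = pw)
  })
  readr::write_tsv(cmp$res, file.path(config$out_dir, "group_homogeneity.tsv"))
  readr::write_tsv(tibble::as_tibble(cmp$pw), file.path(config$out_dir, "pairwise_gl.tsv"))
  manifest$stages$compare <- list(
    n_atc_groups_testable = sum(cmp$res$testable[cmp$res$grouping == "atc"]),
    n_gl_groups_testable = sum(cmp$res$testable[cmp$res$grouping == "gl"]),
    n_pairwise = nrow(cmp$pw)
  )

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
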