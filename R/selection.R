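## Staged signal filtering: report-count floor, pulmonary HLT subsetting,
## RR-rule and EB05-rule drug selection, profiles, ranking.

#' Retain drugs with a minimum number of report rows
#'
#' Counts exploded per-drug report rows (one row per case-drug-event
#' triple) and retains drugs at or above the floor; rarely reported drugs
#' produce noise-driven disproportionality scores and are excluded before
#' any scoring.
#'
#' @param records A records tibble (`case_id`, `drug`, `hlt`).
#' @param threshold Minimum per-drug row count (default 500, i.e. drugs
#'   "reported less than 500 times" are dropped).
#' @param dictionary Optional dictionary tibble supplying `atc_class` per
#'   ingredient for the per-class tally.
#' @return A tibble (`drug`, `atc_class`, `n_reports`, `retained`) sorted
#'   by drug, with attribute `atc_tally`: per-class report and
#'   retained-drug totals (the "# Reports / # Drugs after initial
#'   filtering" style summary).
#' @export
filter_min_reports <- function(records, threshold = 500, dictionary = NULL) {
  stopifnot(all(c("drug") %in% names(records)))
  out <- records |>
    dplyr::count(.data$drug, name = "n_reports") |>
    dplyr::mutate(retained = .data$n_reports >= threshold) |>
    dplyr::arrange(.data$drug)
  atc <- if (!is.null(dictionary)) {
    dplyr::distinct(dictionary, drug = .data$ingredient, .data$atc_class)
  } else {
    tibble::tibble(drug = out$drug, atc_class = NA_character_)
  }
  out <- dplyr::left_join(out, atc, by = "drug") |>
    dplyr::select("drug", "atc_class", "n_reports", "retained")
  attr(out, "atc_tally") <- out |>
    dplyr::group_by(.data$atc_class) |>
    dplyr::summarise(n_reports = sum(.data$n_reports),
                     n_drugs = dplyr::n(),
                     n_drugs_retained = sum(.data$retained),
                     .groups = "drop")
  out
}

#' Drugs retained by a selection step
#'
#' @param x A tibble carrying a logical `retained` column (from
#'   [filter_min_reports()] or [select_by_eb05()]).
#' @return Character vector of retained drug ids.
#' @export
retained_drugs <- function(x) {
  stopifnot("retained" %in% names(x))
  x$drug[x$retained]
}

#' The five pulmonary terms excluded as unrelated
#'
#' Named HLT terms present in a pulmonary vocabulary but excluded from
#' analysis as unrelated to the drug-induced pulmonary question
#' (infection nomenclature for other pathogens, neonatal conditions, and
#' the indication itself).
#'
#' @return Character vector of five HLT names.
#' @export
pv_unrelated_pulmonary_terms <- function() {
  c("Coronavirus infections",
    "Conditions associated with abnormal gas exchange",
    "Neonatal hypoxic conditions",
    "Newborn respiratory disorders NEC",
    "Pulmonary hypertensions")
}

#' Select the analyzed pulmonary ADE vocabulary
#'
#' Starting from the vocabulary terms flagged as pulmonary (respiratory
#' SOC membership plus explicitly listed extra HLTs such as the viral
#' lower-respiratory infections), removes the named exclusions, then
#' removes terms with zero reports in the cohort. The survivors, in
#' vocabulary order, are the analyzed ADE list every downstream rule is
#' restricted to.
#'
#' @param vocabulary Vocabulary tibble (`hlt`, `soc`).
#' @param exclusions Character vector of HLT names to exclude by name;
#'   names absent from the vocabulary raise a warning.
#' @param records Records tibble used to find zero-count terms.
#' @param soc_include SOC labels whose HLTs count as pulmonary.
#' @param extra_hlts Additional HLT names treated as pulmonary regardless
#'   of SOC.
#' @return A tibble (`hlt`, `soc`, `status`) where `status` is one of
#'   `analyzed`, `excluded_named`, `excluded_zero_count`, `not_pulmonary`;
#'   attribute `analyzed` holds the ordered analyzed HLT vector (also
#'   returned by [analyzed_ades()]).
#' @export
pulmonary_subset <- function(vocabulary, exclusions = pv_unrelated_pulmonary_terms(),
                             records = NULL,
                             soc_include = "Respiratory, thoracic and mediastinal disorders",
                             extra_hlts = character()) {
  stopifnot(all(c("hlt", "soc") %in% names(vocabulary)))
  missing_excl <- setdiff(exclusions, vocabulary$hlt)
  if (length(missing_excl)) {
    warning("named exclusions absent from vocabulary: ",
            paste(missing_excl, collapse = ", "))
  }
  counts <- if (!is.null(records)) {
    dplyr::count(records, hlt = .data$hlt, name = "n_reports")
  } else {
    tibble::tibble(hlt = character(), n_reports = integer())
  }
  out <- tibble::as_tibble(vocabulary) |>
    dplyr::left_join(counts, by = "hlt") |>
    dplyr::mutate(
      n_reports = dplyr::coalesce(.data$n_reports, 0L),
      pulmonary = .data$soc %in% soc_include | .data$hlt %in% extra_hlts,
      status = dplyr::case_when(
        !.data$pulmonary ~ "not_pulmonary",
        .data$hlt %in% exclusions ~ "excluded_named",
        !is.null(records) & .data$n_reports == 0L ~ "excluded_zero_count",
        TRUE ~ "analyzed"
      )
    ) |>
    dplyr::select("hlt", "soc", "n_reports", "status")
  analyzed <- out$hlt[out$status == "analyzed"]
  if (!length(analyzed)) warning("no analyzed pulmonary ADEs remain")
  attr(out, "analyzed") <- analyzed
  out
}

#' @rdname pulmonary_subset
#' @param x Result of `pulmonary_subset()`.
#' @export
analyzed_ades <- function(x) attr(x, "analyzed")

build_profiles <- function(signals, flag, rule, threshold) {
  df <- signals |>
    dplyr::mutate(.flag = flag) |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(
      n_flagged = sum(.data$.flag),
      flagged_ades = list(.data$ade[.data$.flag]),
      ebgm_values = list(setNames(.data$ebgm[.data$.flag], .data$ade[.data$.flag])),
      max_ebgm = if (any(.data$.flag)) max(.data$ebgm[.data$.flag]) else NA_real_,
      max_rr = if (any(.data$.flag)) max(.data$rr[.data$.flag]) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$drug)
  structure(df, class = c("pv_profiles", class(tibble::tibble())),
            rule = rule, threshold = threshold)
}

#' Flag per-drug ADE profiles by the RR rule
#'
#' Flags, for every drug, the analyzed ADEs with `RR > rr_threshold`
#' (strict inequality; a cell at exactly the threshold is not flagged).
#'
#' @param signals A `pv_signals` tibble restricted to the analyzed
#'   pulmonary ADEs (see [pulmonary_subset()]).
#' @param rr_threshold RR cut-off (default 2).
#' @return A `pv_profiles` tibble: `drug`, `n_flagged`, `flagged_ades`
#'   (list), `ebgm_values` (list), `max_ebgm`, `max_rr`.
#' @export
select_by_rr <- function(signals, rr_threshold = 2) {
  stopifnot(all(c("drug", "ade", "rr", "ebgm") %in% names(signals)))
  build_profiles(signals, signals$rr > rr_threshold, "rr", rr_threshold)
}

#' Select signal drugs by the conservative EB05 rule
#'
#' Flags ADEs with `EB05 > eb05_threshold` (strict) and retains drugs
#' carrying at least `min_ades` distinct flagged pulmonary ADEs -- the
#' two-condition rule used to pick the signal drug set fed to the
#' graphical-lasso stage.
#'
#' @inheritParams select_by_rr
#' @param eb05_threshold EB05 cut-off (default 1).
#' @param min_ades Minimum number of distinct flagged ADEs (default 2).
#' @param dictionary Optional dictionary for a per-ATC-class tally of
#'   selected drugs (attribute `atc_tally`).
#' @return A `pv_profiles` tibble as in [select_by_rr()] plus a logical
#'   `retained` column; [retained_drugs()] extracts the selected set.
#' @export
select_by_eb05 <- function(signals, eb05_threshold = 1, min_ades = 2,
                           dictionary = NULL) {
  stopifnot(all(c("drug", "ade", "eb05", "ebgm") %in% names(signals)))
  out <- build_profiles(signals, signals$eb05 > eb05_threshold, "eb05",
                        eb05_threshold) |>
    dplyr::mutate(retained = .data$n_flagged >= min_ades)
  if (!is.null(dictionary)) {
    atc <- dplyr::distinct(dictionary, drug = .data$ingredient, .data$atc_class)
    attr(out, "atc_tally") <- out |>
      dplyr::left_join(atc, by = "drug") |>
      dplyr::group_by(.data$atc_class) |>
      dplyr::summarise(n_drugs = dplyr::n(),
                       n_drugs_selected = sum(.data$retained),
                       .groups = "drop")
  }
  structure(out, class = c("pv_profiles", class(tibble::tibble())),
            rule = "eb05", threshold = eb05_threshold, min_ades = min_ades)
}

#' Number of flagged ADEs in a drug profile
#'
#' @param profiles A `pv_profiles` tibble.
#' @param drug Optional single drug id; if omitted, sizes for all drugs.
#' @return Named integer vector of flagged-ADE counts.
#' @export
profile_size <- function(profiles, drug = NULL) {
  stopifnot(all(c("drug", "n_flagged") %in% names(profiles)))
  sizes <- setNames(as.integer(profiles$n_flagged), profiles$drug)
  if (is.null(drug)) return(sizes)
  if (!all(drug %in% names(sizes))) {
    stop_input("unknown drug(s): %s", paste(setdiff(drug, names(sizes)), collapse = ", "))
  }
  sizes[drug]
}

#' Rank drugs by profile size
#'
#' Descending by the number of flagged ADEs; ties broken by descending
#' maximum flagged-cell score (EBGM or RR according to `key`), then by
#' drug id. Stable and deterministic.
#'
#' @param profiles A `pv_profiles` tibble built under the matching rule.
#' @param key `"ebgm"` or `"rr"`.
#' @return Character vector of drug ids in rank order.
#' @export
rank_drugs <- function(profiles, key = c("ebgm", "rr")) {
  key <- match.arg(key)
  score <- if (key == "ebgm") profiles$max_ebgm else profiles$max_rr
  score[is.na(score)] <- -Inf
  profiles$drug[order(-profiles$n_flagged, -score, profiles$drug)]
}

#' @export
print.pv_profiles <- function(x, ...) {
  cat("<pv_profiles> rule ", attr(x, "rule"), " > ", attr(x, "threshold"),
      "; ", nrow(x), " drugs", sep = "")
  if ("retained" %in% names(x)) cat(", ", sum(x$retained), " selected", sep = "")
  cat("\n")
  NextMethod()
}
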