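## Ingest: reading report/dictionary files, drug-name normalization,
## multi-drug case explosion, and the drug x ADE contingency table.

#' Read case-level adverse-event reports
#'
#' Reads a delimited report file with header `case_id,drug,hlt,soc`. Two
#' dialects are accepted: one row per (case, drug, HLT) triple, or a
#' pre-explosion dialect in which `drug` and/or `hlt` hold `;`-separated
#' lists for multi-drug / multi-event cases (see
#' [explode_multidrug_cases()]).
#'
#' @param path Path to a TSV or CSV file (delimiter sniffed from the header).
#' @return A tibble with character columns `case_id`, `drug`, `hlt`, `soc`.
#' @export
read_reports <- function(path) {
  df <- read_delim_auto(path)
  need <- c("case_id", "drug", "hlt")
  if (!all(need %in% names(df))) {
    stop_input("report file must have columns case_id, drug, hlt (got: %s)",
               paste(names(df), collapse = ", "))
  }
  if (!"soc" %in% names(df)) df$soc <- NA_character_
  tibble::as_tibble(df)[, c("case_id", "drug", "hlt", "soc")] |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.character))
}

#' Write case-level reports
#'
#' Inverse of [read_reports()]; used by the simulator and for round-trip
#' checks. Always writes tab-separated text.
#'
#' @param records A data frame with columns `case_id`, `drug`, `hlt`, `soc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reports <- function(records, path) {
  readr::write_tsv(records[, c("case_id", "drug", "hlt", "soc")], path)
  invisible(path)
}

#' Read a drug synonym/ATC dictionary
#'
#' The dictionary maps raw name variants (brand names, salts, formulations)
#' to active-ingredient identifiers and ATC class labels. Expected columns:
#' `variant`, `ingredient`, `atc_class`, `atc3`.
#'
#' @param path Path to a TSV or CSV file.
#' @return A tibble with one row per variant.
#' @export
read_drug_dictionary <- function(path) {
  df <- read_delim_auto(path)
  need <- c("variant", "ingredient")
  if (!all(need %in% names(df))) {
    stop_input("dictionary file must have columns variant, ingredient")
  }
  if (!"atc_class" %in% names(df)) df$atc_class <- NA_character_
  if (!"atc3" %in% names(df)) df$atc3 <- NA_character_
  out <- tibble::as_tibble(df)[, c("variant", "ingredient", "atc_class", "atc3")] |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.character))
  if (any(!nzchar(out$variant))) stop_input("dictionary contains empty variants")
  out
}

#' Read an ADE vocabulary
#'
#' Expected columns: `hlt` (high-level term) and `soc` (system organ class).
#'
#' @param path Path to a TSV or CSV file.
#' @return A tibble with one row per HLT.
#' @export
read_ade_vocabulary <- function(path) {
  df <- read_delim_auto(path)
  if (!all(c("hlt", "soc") %in% names(df))) {
    stop_input("vocabulary file must have columns hlt, soc")
  }
  tibble::as_tibble(df)[, c("hlt", "soc")] |>
    dplyr::mutate(dplyr::across(dplyr::everything(), as.character))
}

read_delim_auto <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE)
}

#' Default salt / formulation / manufacturer tokens
#'
#' Tokens stripped from the ends of a raw drug name during normalization
#' when the full string has no dictionary match. Deterministic token
#' stripping (rather than fuzzy matching) keeps name combining auditable:
#' e.g. "sildenafil citrate" and "teva sildenafil" both resolve to the
#' ingredient `sildenafil`.
#'
#' @return A character vector of lower-case tokens.
#' @export
pv_salt_tokens <- function() {
  c(
    # salts / counter-ions
    "citrate", "mesylate", "besylate", "maleate", "tartrate", "fumarate",
    "succinate", "hydrochloride", "hcl", "sodium", "potassium", "calcium",
    # formulation words
    "tablet", "tablets", "capsule", "capsules", "film", "coated",
    "filmtabletten", "oral", "injection", "sup",
    # manufacturer tokens seen on spontaneous reports
    "pfizer", "teva", "apo", "aurobindo", "pharma", "amneal",
    "pharmaceuticals", "greenstone", "hormosan"
  )
}

norm_string <- function(x) {
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[[:punct:]]+", " ")
  stringr::str_squish(x)
}

#' Normalize raw drug names to active ingredients
#'
#' Deterministic normalization: trim, case-fold, strip punctuation, then
#' exact dictionary lookup; if the full string has no entry, salt /
#' formulation / manufacturer tokens are stripped one at a time from either
#' end and the lookup retried. Unmatched names are returned as `NA` (the
#' unmatched marker) and reported via a message -- never silently dropped.
#'
#' @param raw Character vector of raw drug names (non-empty).
#' @param dictionary A dictionary tibble from [read_drug_dictionary()].
#' @param tokens Strippable suffix/prefix tokens; see [pv_salt_tokens()].
#' @param quiet Suppress the unmatched-name message.
#' @return Character vector of ingredient ids, `NA` where unmatched.
#' @examples
#' dict <- tibble::tibble(variant = c("sildenafil", "revatio"),
#'                        ingredient = "sildenafil",
#'                        atc_class = "UAs", atc3 = "G04B")
#' normalize_drug_name(c("Sildenafil citrate", "REVATIO", "notadrugxyz"), dict)
#' @export
normalize_drug_name <- function(raw, dictionary, tokens = pv_salt_tokens(),
                                quiet = FALSE) {
  if (length(raw) == 0L) return(character(0))
  if (any(is.na(raw)) || any(!nzchar(trimws(raw)))) {
    stop_input("raw drug names must be non-empty")
  }
  lut <- setNames(dictionary$ingredient, norm_string(dictionary$variant))
  tokens <- norm_string(tokens)

  lookup_one <- function(key) {
    hit <- lut[key]
    if (!is.na(hit)) return(unname(hit))
    words <- strsplit(key, " ", fixed = TRUE)[[1]]
    repeat {
      if (length(words) <= 1L) return(NA_character_)
      if (words[length(words)] %in% tokens) {
        words <- words[-length(words)]
      } else if (words[1L] %in% tokens) {
        words <- words[-1L]
      } else {
        return(NA_character_)
      }
      hit <- lut[paste(words, collapse = " ")]
      if (!is.na(hit)) return(unname(hit))
    }
  }

  keys <- norm_string(raw)
  out <- unname(lut[keys]) # fast path: exact hits
  miss <- which(is.na(out))
  if (length(miss)) {
    out[miss] <- vapply(unique(keys[miss]), lookup_one,
                        character(1))[keys[miss]]
  }
  out <- unname(out)
  if (!quiet && anyNA(out)) {
    bad <- unique(raw[is.na(out)])
    message("unmatched drug names (", length(bad), "): ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) ", ...")
  }
  out
}

#' Explode multi-drug / multi-event cases into one record per pair
#'
#' A single case reporting several suspect drugs and several adverse events
#' contributes one report row for every (drug, HLT) combination, so a case
#' with two drugs and one event yields two records. Input columns `drug`
#' and `hlt` may hold `;`-separated lists or list-columns.
#'
#' @param cases A data frame with columns `case_id`, `drug`, `hlt` and
#'   optionally `soc` (a `;`-separated list parallel to `hlt`, or a single
#'   value recycled over the case's HLTs).
#' @return A tibble of records, one row per (case, drug, HLT) triple; the
#'   row count equals `sum(n_drugs * n_hlts)` over cases.
#' @export
explode_multidrug_cases <- function(cases) {
  stopifnot(all(c("case_id", "drug", "hlt") %in% names(cases)))
  cases <- tibble::as_tibble(cases)
  if (!"soc" %in% names(cases)) cases$soc <- NA_character_

  split_field <- function(x) {
    if (is.list(x)) purrr::map(x, as.character)
    else strsplit(as.character(x), ";", fixed = TRUE)
  }
  drugs <- split_field(cases$drug)
  hlts <- split_field(cases$hlt)
  socs <- split_field(cases$soc)

  keep <- lengths(drugs) > 0L & lengths(hlts) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " case(s) with no drug or no event dropped")
    cases <- cases[keep, ]
    drugs <- drugs[keep]; hlts <- hlts[keep]; socs <- socs[keep]
  }
  # recycle a single soc over the case's HLTs
  short <- lengths(socs) != lengths(hlts)
  socs[short] <- purrr::map2(socs[short], lengths(hlts)[short],
                             ~ rep(.x[1L], .y))

  nd <- lengths(drugs)
  nh <- lengths(hlts)
  tibble::tibble(
    case_id = rep(cases$case_id, nd * nh),
    drug = trimws(unlist(purrr::map2(drugs, nh, ~ rep(.x, each = .y)),
                         use.names = FALSE)),
    hlt = trimws(unlist(purrr::map2(hlts, nd, ~ rep(.x, times = .y)),
                        use.names = FALSE)),
    soc = trimws(unlist(purrr::map2(socs, nd, ~ rep(.x, times = .y)),
                        use.names = FALSE))
  )
}

#' Normalize, validate and explode raw cases into analysis records
#'
#' Convenience wrapper over [explode_multidrug_cases()] and
#' [normalize_drug_name()]: explodes cases, maps raw names to ingredients,
#' drops (and reports) unmatched drugs, and optionally checks HLTs against
#' a vocabulary.
#'
#' @inheritParams normalize_drug_name
#' @param cases Raw cases as from [read_reports()].
#' @param vocabulary Optional vocabulary tibble; records whose `hlt` is not
#'   listed raise an error.
#' @return A records tibble (`case_id`, `drug`, `hlt`, `soc`) with
#'   attribute `unmatched`: a tibble of dropped raw names and their row
#'   counts.
#' @export
ingest_reports <- function(cases, dictionary, vocabulary = NULL,
                           tokens = pv_salt_tokens(), quiet = FALSE) {
  recs <- explode_multidrug_cases(cases)
  ing <- normalize_drug_name(recs$drug, dictionary, tokens = tokens, quiet = quiet)
  unmatched <- recs$drug[is.na(ing)]
  unmatched_tbl <- tibble::tibble(raw = unmatched) |>
    dplyr::count(.data$raw, name = "n_rows")
  recs$drug <- ing
  recs <- recs[!is.na(ing), ]
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(recs$hlt), vocabulary$hlt)
    if (length(bad)) {
      stop_input("records carry HLTs absent from the vocabulary: %s",
                 paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  attr(recs, "unmatched") <- unmatched_tbl
  recs
}

#' Build the drug x ADE contingency table with baseline expected counts
#'
#' Tabulates records into a non-negative count matrix `N` (drugs as rows,
#' HLT terms as columns) and attaches the two-way independence baseline
#' `E_ij = n_i. * n_.j / n..`, the expectation for cell (i, j) if drug and
#' event were reported independently. `E` is computed on the full table at
#' this stage and reused unchanged by every downstream filter, so later
#' subsetting never silently changes the baseline.
#'
#' @param records A records tibble (`case_id`, `drug`, `hlt`) with drugs
#'   already normalized to ingredient ids.
#' @param dedup Count duplicate identical (case, drug, hlt) rows once
#'   (default `TRUE`); spontaneous-report databases are known to contain
#'   replicated transmissions of one case.
#' @return A `pv_counts` object: list with `drugs`, `ades`, integer matrix
#'   `N`, real matrix `E`, `row_margins`, `col_margins`, `grand_total`.
#' @examples
#' recs <- tibble::tibble(case_id = as.character(1:4),
#'                        drug = c("a", "a", "b", "b"),
#'                        hlt = c("x", "y", "x", "y"))
#' build_count_table(recs)
#' @export
build_count_table <- function(records, dedup = TRUE) {
  stopifnot(all(c("case_id", "drug", "hlt") %in% names(records)))
  if (nrow(records) == 0L) stop_input("no records to tabulate")
  if (dedup) {
    records <- dplyr::distinct(records, .data$case_id, .data$drug, .data$hlt,
                               .keep_all = TRUE)
  }
  N <- unclass(table(factor(records$drug), factor(records$hlt)))
  storage.mode(N) <- "double"
  new_pv_counts(N)
}

new_pv_counts <- function(N) {
  rm_ <- rowSums(N)
  cm_ <- colSums(N)
  gt <- sum(N)
  if (gt <= 0) stop_input("count table is empty")
  E <- outer(rm_, cm_) / gt
  structure(
    list(drugs = rownames(N), ades = colnames(N), N = N, E = E,
         row_margins = rm_, col_margins = cm_, grand_total = gt),
    class = "pv_counts"
  )
}

#' @export
print.pv_counts <- function(x, ...) {
  cat("<pv_counts> ", length(x$drugs), " drugs x ", length(x$ades),
      " ADEs, ", format(x$grand_total, big.mark = ","), " reports\n", sep = "")
  invisible(x)
}

#' @export
dim.pv_counts <- function(x) dim(x$N)

#' Subset a count table to selected drugs/ADEs
#'
#' Keeps the frozen baseline `E` for the retained cells (margins are
#' recomputed for bookkeeping only; `E` is not rebuilt).
#'
#' @param x A `pv_counts` object.
#' @param drugs,ades Optional character vectors of row/column ids to keep.
#' @return A `pv_counts` object.
#' @export
subset_counts <- function(x, drugs = NULL, ades = NULL) {
  stopifnot(inherits(x, "pv_counts"))
  di <- if (is.null(drugs)) x$drugs else intersect(drugs, x$drugs)
  ai <- if (is.null(ades)) x$ades else intersect(ades, x$ades)
  out <- x
  out$drugs <- di
  out$ades <- ai
  out$N <- x$N[di, ai, drop = FALSE]
  out$E <- x$E[di, ai, drop = FALSE]
  out$row_margins <- rowSums(out$N)
  out$col_margins <- colSums(out$N)
  out$grand_total <- sum(out$N)
  out
}

#' @rdname build_count_table
#' @param x A `pv_counts` object.
#' @param ... Unused.
#' @export
tidy.pv_counts <- function(x, ...) {
  tibble::tibble(
    drug = rep(x$drugs, times = length(x$ades)),
    ade = rep(x$ades, each = length(x$drugs)),
    n = as.vector(x$N),
    e = as.vector(x$E)
  )
}
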