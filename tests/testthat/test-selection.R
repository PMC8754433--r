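make_records <- function(n_per_drug) {
  purrr::imap(n_per_drug, function(n, d) {
    tibble::tibble(case_id = sprintf("%s-%d", d, seq_len(n)), drug = d,
                   hlt = rep(c("x", "y"), length.out = n), soc = "s")
  }) |> purrr::list_rbind()
}

test_that("report-count floor retains drugs at the boundary and above", {
  recs <- make_records(c(a = 499, b = 500, c = 501))
  flt <- filter_min_reports(recs, 500)
  expect_identical(retained_drugs(flt), c("b", "c"))

  cohort <- make_records(setNames(c(rep(600, 10), rep(100, 5)),
                                  sprintf("d%02d", 1:15)))
  expect_identical(length(retained_drugs(filter_min_reports(cohort, 500))), 10L)
  expect_identical(length(retained_drugs(filter_min_reports(cohort, 0))), 15L)

  # per-class tally sums match the per-drug counts
  dict <- tibble::tibble(variant = c("a", "b", "c"), ingredient = c("a", "b", "c"),
                         atc_class = c("ACEIs", "ACEIs", "CCBs"), atc3 = NA)
  flt2 <- filter_min_reports(recs, 500, dict)
  tally <- attr(flt2, "atc_tally")
  expect_equal(sum(tally$n_reports), nrow(recs))
  expect_equal(tally$n_drugs_retained[tally$atc_class == "ACEIs"], 1L)
})

test_that("pulmonary subsetting removes named then unreported terms", {
  vocab <- read_ade_vocabulary(pv_extdata("synthetic_pulmonary_vocabulary.tsv"))
  expect_identical(nrow(vocab), 30L)
  # reports cover every pulmonary term except the five named exclusions
  reported <- setdiff(vocab$hlt, pv_unrelated_pulmonary_terms())
  recs <- tibble::tibble(case_id = as.character(seq_along(reported)),
                         drug = "a", hlt = reported, soc = "s")
  sub <- pulmonary_subset(vocab, records = recs,
                          extra_hlts = c("Respiratory syncytial viral infections",
                                         "Coronavirus infections"))
  expect_identical(length(analyzed_ades(sub)), 25L)
  expect_identical(sum(sub$status == "excluded_named"), 5L)

  # no exclusions and full reporting: identity on the pulmonary set
  all_recs <- tibble::tibble(case_id = as.character(seq_len(30)), drug = "a",
                             hlt = vocab$hlt, soc = "s")
  sub2 <- pulmonary_subset(vocab, exclusions = character(), records = all_recs,
                           soc_include = unique(vocab$soc))
  expect_identical(analyzed_ades(sub2), vocab$hlt)

  # nothing reported: empty analyzed list with a warning
  expect_warning(
    sub3 <- pulmonary_subset(vocab, exclusions = character(),
                             records = all_recs[0, ]),
    "no analyzed"
  )
  expect_identical(length(analyzed_ades(sub3)), 0L)

  expect_warning(pulmonary_subset(vocab, exclusions = "Not A Term"),
                 "absent")
})

test_that("RR rule flags strictly above threshold", {
  sig <- tibble::tibble(
    drug = "d1", ade = c("a1", "a2", "a3"),
    n = c(5, 19, 8), e = c(2, 10, 2),
    rr = c(2.5, 1.9, 4), ebgm = c(2, 1.5, 3), eb05 = c(1.2, 0.9, 2)
  )
  prof <- select_by_rr(sig, 2)
  expect_identical(unname(profile_size(prof, "d1")), 2L)
  expect_setequal(prof$flagged_ades[[1]], c("a1", "a3"))

  exact <- dplyr::mutate(sig, rr = 2)
  expect_identical(unname(profile_size(select_by_rr(exact, 2), "d1")), 0L)

  worked <- tibble::tibble(drug = "d", ade = "a", n = 200, e = 2, rr = 100,
                           ebgm = 80, eb05 = 60)
  expect_identical(unname(profile_size(select_by_rr(worked, 2), "d")), 1L)
})

test_that("EB05 rule needs at least two distinct flagged ADEs", {
  sig <- tibble::tibble(
    drug = rep(c("two", "one"), each = 3),
    ade = rep(c("a1", "a2", "a3"), 2),
    n = 5, e = 2, rr = 2.5,
    ebgm = 2,
    eb05 = c(1.5, 1.2, 0.8, 1.5, 0.8, 0.7)
  )
  sel <- select_by_eb05(sig, 1, 2)
  expect_identical(retained_drugs(sel), "two")
  expect_identical(unname(profile_size(sel, "one")), 1L)
})

test_that("planted signal drugs survive the EB05 rule and nulls are culled", {
  cfg <- sim_config(
    n_drugs = 40, n_ades = 17, seed = 41,
    drug_scale = rep(sqrt(25), 40), ade_scale = rep(sqrt(25), 17),
    blocks = list(list(drugs = 1:5, ades = 1:6),
                  list(drugs = 6:10, ades = 9:14))
  )
  planted <- gen_planted_counts(cfg)
  fit <- fit_gps(planted$counts, seed = 41)
  st <- score_table(planted$counts, fit)
  sel <- select_by_eb05(st)
  picked <- retained_drugs(sel)
  truth <- planted$truth
  expect_true(all(truth$drug[truth$role == "planted"] %in% picked))
  null_kept <- intersect(picked, truth$drug[truth$role == "null"])
  expect_lte(length(null_kept), 0.1 * sum(truth$role == "null"))
})

test_that("profile sizes parse from printed index lists", {
  prof <- readr::read_tsv(pv_extdata("faers_hypertension_profiles.tsv"),
                          show_col_types = FALSE)
  idx <- parse_ade_indices(prof$ade_indices)
  sizes <- setNames(lengths(idx), prof$drug)
  expect_identical(unname(sizes["macitentan"]), 16L)
  expect_identical(unname(sizes["bosentan"]), 14L)
  expect_identical(parse_ade_indices("")[[1]], integer(0))
  expect_identical(parse_ade_indices("1-15,17")[[1]], c(1:15, 17L))
})

test_that("drug ranking orders by size, then flagged score, then id", {
  prof <- tibble::tibble(
    drug = c("epoprostenol", "macitentan", "bosentan"),
    n_flagged = c(11L, 16L, 14L),
    flagged_ades = list("a", "a", "a"),
    ebgm_values = list(1, 1, 1),
    max_ebgm = c(3, 8, 5), max_rr = c(4, 9, 6)
  )
  expect_identical(rank_drugs(prof, "ebgm"),
                   c("macitentan", "bosentan", "epoprostenol"))

  tie <- tibble::tibble(
    drug = c("zeta", "alpha", "mid"),
    n_flagged = c(3L, 3L, 3L),
    flagged_ades = list("a", "a", "a"),
    ebgm_values = list(1, 1, 1),
    max_ebgm = c(9, 2, 2), max_rr = c(1, 1, 1)
  )
  expect_identical(rank_drugs(tie, "ebgm"), c("zeta", "alpha", "mid"))
  expect_identical(rank_drugs(tie[1, ], "ebgm"), "zeta")
})

test_that("raising thresholds never grows profiles or the selected set", {
  cfg <- sim_config(n_drugs = 25, n_ades = 17, seed = 43,
                    drug_scale = rep(4, 25),
                    blocks = list(list(drugs = 1:6, ades = 1:8)))
  planted <- gen_planted_counts(cfg)
  st <- score_table(planted$counts, canonical_theta())
  prev_rr <- NULL
  prev_sel <- NULL
  for (thr in c(1, 2, 4, 8)) {
    sizes <- profile_size(select_by_rr(st, thr))
    sel <- retained_drugs(select_by_eb05(st, thr, 2))
    if (!is.null(prev_rr)) {
      expect_true(all(sizes <= prev_rr))
      expect_true(all(sel %in% prev_sel))
    }
    prev_rr <- sizes
    prev_sel <- sel
  }
})
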