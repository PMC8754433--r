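#' Bundled example data files
#'
#' Paths to the plain-text fixtures shipped with the package:
#'
#' * `faers_hypertension_profiles.tsv` -- per-drug pulmonary ADE profiles
#'   (flagged-term index lists under the EB05 > 1 rule, ATC class, GL
#'   cluster) as published for a FAERS hypertension cohort; see
#'   [parse_ade_indices()].
#' * `pulmonary_ade_index.tsv` -- the numbered 17-term pulmonary HLT
#'   vocabulary those index lists refer to.
#' * `synthetic_pulmonary_vocabulary.tsv` -- a 30-term pulmonary HLT/SOC
#'   vocabulary for testing [pulmonary_subset()]; term names follow
#'   MedDRA-style HLT conventions but the file is a synthetic stand-in,
#'   not the licensed dictionary.
#'
#' @param file File name within the package's `extdata` directory; with
#'   no argument, lists available files.
#' @return A file path (or vector of file names).
#' @examples
#' pv_extdata()
#' head(readr::read_tsv(pv_extdata("pulmonary_ade_index.tsv"),
#'                      show_col_types = FALSE))
#' @export
pv_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "pvsignal")))
  }
  path <- system.file("extdata", file, package = "pvsignal")
  if (!nzchar(path)) stop_input("no bundled file named '%s'", file)
  path
}
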