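## Internal numeric helpers shared across modules.

# log(exp(a) + exp(b)) element-wise without overflow
log_add <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf: log(0 + 0)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

#' Parse a printed ADE index list
#'
#' Profile tables in pharmacovigilance reports often print the set of
#' flagged adverse-event terms for a drug as a compact index list such as
#' `"1-15,17"` (en dashes are accepted). This expands such a string into the
#' integer indices it denotes.
#'
#' @param x Character vector of printed index lists, e.g. `"1,2,4-15"`.
#' @return A list of sorted integer vectors, one per element of `x`.
#' @examples
#' parse_ade_indices(c("1-15,17", "1,2,4-15"))
#' @export
parse_ade_indices <- function(x) {
  stopifnot(is.character(x))
  purrr::map(x, function(s) {
    s <- gsub("–|—", "-", s)
    s <- gsub("\\s", "", s)
    if (!nzchar(s)) {
      return(integer(0))
    }
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    idx <- purrr::map(parts, function(p) {
      if (grepl("-", p, fixed = TRUE)) {
        ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
        if (length(ab) != 2L || anyNA(ab)) stop_input("cannot parse index range '%s'", p)
        seq.int(ab[1], ab[2])
      } else {
        v <- as.integer(p)
        if (is.na(v)) stop_input("cannot parse index '%s'", p)
        v
      }
    })
    sort(unique(unlist(idx)))
  })
}
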