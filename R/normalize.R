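# Deterministic normalization of imprecise intake data.

#' Impute an integer age from an imprecise age record
#'
#' Third-party pedigrees often record ages as decade ranges. The intake
#' convention collapses them deterministically: an early decade takes the
#' integer 2 ("early 70s" becomes 72), a late decade the integer 8 ("late
#' 70s" becomes 78), and a whole decade its median ("70s" becomes 75).
#' Exact ages pass through unchanged, so imputation is idempotent.
#'
#' Unknown ages have no defensible imputation: they satisfy only "at any
#' age" clauses, never age-bounded ones. With `strict = TRUE` (the default)
#' an `UNKNOWN` record is an error, signalling the caller to route the
#' diagnosis to any-age clauses; with `strict = FALSE` it returns `NA`.
#'
#' @param age An [age_record()] or plain number.
#' @param offsets Integer offsets added to the decade start for
#'   `EARLY_DECADE`, `LATE_DECADE` and `DECADE` kinds (defaults 2, 8, 5).
#' @param strict Error on `UNKNOWN` ages rather than returning `NA`.
#' @return Integer age in years.
#' @examples
#' impute_age(age_record("EARLY_DECADE", 70))  # 72
#' impute_age(age_record("LATE_DECADE", 70))   # 78
#' impute_age(age_record("DECADE", 70))        # 75
#' @export
impute_age <- function(age, offsets = c(EARLY_DECADE = 2L, LATE_DECADE = 8L,
                                        DECADE = 5L),
                       strict = TRUE) {
  age <- .as_age(age)
  if (age$kind == "UNKNOWN") {
    if (strict) {
      stop("age is UNKNOWN: route this diagnosis to 'at any age' clauses only")
    }
    return(NA_integer_)
  }
  if (age$kind == "EXACT") return(age$value)
  age$value + as.integer(offsets[[age$kind]])
}

#' Normalize every diagnosis in a pedigree
#'
#' Applies the prostate assumption (no Gleason data recorded implies
#' high-risk, Gleason score > 7) and verifies every cancer type is
#' canonical. Free-text types must already have gone through
#' [normalize_cancer()]; this pass is idempotent.
#'
#' @param ped A [pedigree()].
#' @return The normalized pedigree.
#' @export
normalize_pedigree <- function(ped) {
  fix <- function(m) {
    m$diagnoses <- lapply(m$diagnoses, function(d) {
      if (d$cancer_type == "prostate" && !"GLEASON_GT7" %in% d$qualifiers) {
        d$qualifiers <- union(d$qualifiers, "GLEASON_GT7")
      }
      d
    })
    m
  }
  ped$proband <- fix(ped$proband)
  ped$members <- lapply(ped$members, fix)
  ped
}
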