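# Compact builders for test pedigrees.

fm <- function(label, ..., sex = NULL, polyps = NA_integer_) {
  dxs <- list(...)
  family_member(label, sex = sex, diagnoses = dxs, polyp_count = polyps)
}

dx <- function(type, age = NULL, q = character(), idx = 1L) {
  diagnosis(type,
            age = if (is.null(age)) age_record("UNKNOWN") else age,
            qualifiers = q, primary_index = idx)
}

ped_with <- function(..., proband = NULL, ethnicities = "Caucasian",
                     mutations = list(), family_sizes = list()) {
  pedigree(
    proband = proband %||% family_member("self", sex = "female"),
    members = list(...),
    ethnicities = ethnicities, mutations = mutations,
    family_sizes = family_sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
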