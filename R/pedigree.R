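# The pedigree data model: the unit of evaluation for the criteria engine.
#
# A pedigree is the proband (their own diagnoses, polyp count and
# ethnicities) plus a list of relatives identified by controlled
# relationship labels, the family's known mutation findings, and optional
# per-generation family-size counts. The three-generation scope is
# structural: labels beyond degree 3 are not representable.

.sexes <- c("female", "male", "unknown")
.ethnicities <- c("African American", "Ashkenazi Jewish", "Asian",
                  "Caucasian", "Hispanic", "Native American", "Unknown")
.age_kinds <- c("EXACT", "EARLY_DECADE", "LATE_DECADE", "DECADE", "UNKNOWN")
.qualifiers <- c("DCIS", "TRIPLE_NEGATIVE", "GLEASON_GT7", "SYNCHRONOUS",
                 "METACHRONOUS")
.gene_groups <- c("BRCA1_BRCA2", "LYNCH", "APC_MUTYH")

#' Age-at-diagnosis record
#'
#' Ages on third-party pedigrees are often imprecise ("early 70s", "late
#' 70s", "70s"). An age record keeps the stated precision; [impute_age()]
#' collapses it to the integer the intake convention dictates.
#'
#' @param kind One of `"EXACT"`, `"EARLY_DECADE"`, `"LATE_DECADE"`,
#'   `"DECADE"`, `"UNKNOWN"`.
#' @param value Age in years for `EXACT` (0--120); the decade start (a
#'   multiple of 10) for the decade kinds; ignored for `UNKNOWN`.
#' @return An object of class `hcs_age`.
#' @examples
#' age_record("EARLY_DECADE", 70)
#' age_record("EXACT", 44)
#' @export
age_record <- function(kind = "EXACT", value = NULL) {
  kind <- match.arg(kind, .age_kinds)
  if (kind == "UNKNOWN") {
    value <- NA_integer_
  } else {
    stopifnot(is.numeric(value), length(value) == 1L, !is.na(value))
    value <- as.integer(value)
    if (kind == "EXACT") {
      if (value < 0L || value > 120L) stop("EXACT age must be in [0, 120]")
    } else if (value %% 10L != 0L) {
      stop("decade age kinds take the decade start (a multiple of 10)")
    }
  }
  structure(list(kind = kind, value = value), class = "hcs_age")
}

#' @export
print.hcs_age <- function(x, ...) {
  txt <- switch(x$kind,
    EXACT = as.character(x$value),
    EARLY_DECADE = sprintf("early %ds", x$value),
    LATE_DECADE = sprintf("late %ds", x$value),
    DECADE = sprintf("%ds", x$value),
    UNKNOWN = "unknown")
  cat("<age>", txt, "\n")
  invisible(x)
}

.as_age <- function(age) {
  if (inherits(age, "hcs_age")) return(age)
  if (is.numeric(age) && length(age) == 1L && !is.na(age)) {
    return(age_record("EXACT", age))
  }
  if (is.list(age) && !is.null(age$kind)) {
    return(age_record(age$kind, age$value))
  }
  stop("age must be an age_record(), a single number, or a {kind, value} list")
}

#' One tumor diagnosis
#'
#' @param cancer_type Canonical cancer-type identifier (see
#'   [cancer_vocabulary()]); free text should go through
#'   [normalize_cancer()] instead.
#' @param age An [age_record()] or a plain number (taken as exact years).
#' @param qualifiers Character vector among `"DCIS"`, `"TRIPLE_NEGATIVE"`,
#'   `"GLEASON_GT7"`, `"SYNCHRONOUS"`, `"METACHRONOUS"`.
#' @param primary_index Ordinal separating multiple primaries of the same
#'   type in one person; bilateral breast disease (or two clearly separate
#'   ipsilateral primaries) is represented as two diagnoses with distinct
#'   indices.
#' @return An object of class `hcs_diagnosis`.
#' @examples
#' diagnosis("breast", 44)
#' diagnosis("breast", age_record("DECADE", 40), primary_index = 2)
#' @export
diagnosis <- function(cancer_type, age = age_record("UNKNOWN"),
                      qualifiers = character(), primary_index = 1L) {
  stopifnot(is.character(cancer_type), length(cancer_type) == 1L)
  if (!cancer_type %in% c(.canonical_types, .other_type)) {
    stop("not a canonical cancer type: ", sQuote(cancer_type),
         "; use normalize_cancer() for free text")
  }
  qualifiers <- unique(as.character(qualifiers))
  bad <- setdiff(qualifiers, .qualifiers)
  if (length(bad)) stop("unknown qualifiers: ", paste(bad, collapse = ", "))
  structure(list(cancer_type = cancer_type, age = .as_age(age),
                 qualifiers = qualifiers,
                 primary_index = as.integer(primary_index)),
            class = "hcs_diagnosis")
}

#' A known familial mutation finding
#'
#' @param gene_group One of `"BRCA1_BRCA2"`, `"LYNCH"`, `"APC_MUTYH"` (the
#'   gene groups the intake questionnaire asks about).
#' @param carrier Relationship label of the tested person (`"self"` for the
#'   proband).
#' @return An object of class `hcs_mutation`.
#' @examples
#' mutation_finding("BRCA1_BRCA2", "maternal aunt")
#' @export
mutation_finding <- function(gene_group, carrier = "self") {
  gene_group <- match.arg(gene_group, .gene_groups)
  .kin_lookup(carrier)
  structure(list(gene_group = gene_group, carrier = carrier),
            class = "hcs_mutation")
}

#' A family member (or the proband)
#'
#' @param relationship Controlled relationship label; `"self"` for the
#'   proband. Half-siblings must use a side-tagged label
#'   (`"maternal half-sister"` etc.); lineage is undefined otherwise.
#' @param sex `"female"`, `"male"`, or `"unknown"`. Must not contradict a
#'   sexed label (a mother is female); males may carry breast-cancer
#'   diagnoses (male breast cancer has its own criterion).
#' @param diagnoses List of [diagnosis()] objects.
#' @param polyp_count Cumulative colon adenoma count; `NA` when unknown.
#' @param deceased Optional flag.
#' @return An object of class `hcs_member`.
#' @examples
#' family_member("mother", diagnoses = list(diagnosis("colorectal", 48)))
#' @export
family_member <- function(relationship, sex = NULL, diagnoses = list(),
                          polyp_count = NA_integer_, deceased = NA) {
  row <- .kin_lookup(relationship)
  implied <- row$sex
  if (is.null(sex)) sex <- if (is.na(implied)) "unknown" else implied
  sex <- match.arg(sex, .sexes)
  if (!is.na(implied) && sex != "unknown" && sex != implied) {
    stop("sex ", sQuote(sex), " contradicts relationship label ",
         sQuote(relationship))
  }
  stopifnot(is.list(diagnoses))
  diagnoses <- lapply(diagnoses, function(d) {
    if (!inherits(d, "hcs_diagnosis")) stop("diagnoses must be diagnosis() objects")
    d
  })
  if (!is.na(polyp_count)) {
    stopifnot(is.numeric(polyp_count), polyp_count >= 0)
    polyp_count <- as.integer(polyp_count)
  } else {
    polyp_count <- NA_integer_
  }
  structure(list(relationship = relationship, sex = sex,
                 diagnoses = diagnoses, polyp_count = polyp_count,
                 deceased = deceased),
            class = "hcs_member")
}

#' Assemble a pedigree
#'
#' The unit of evaluation: a proband with their own history, relatives with
#' controlled relationship labels, known familial mutation findings, and
#' optional per-generation family-size counts (used by the limited-family-
#' history clause).
#'
#' @param proband A [family_member()] with relationship `"self"`.
#' @param members List of [family_member()] objects (relatives only).
#' @param ethnicities Character vector from the intake ethnicity list
#'   (African American, Ashkenazi Jewish, Asian, Caucasian, Hispanic,
#'   Native American, Unknown).
#' @param mutations List of [mutation_finding()] objects.
#' @param family_sizes Optional named list of relative counts per
#'   generation/side (e.g. `list(maternal_aunts_uncles = 3)`); the logical
#'   entry `unknown = TRUE` declares unreported structure.
#' @param id Optional pedigree identifier.
#' @return An object of class `hcs_pedigree`.
#' @examples
#' p <- pedigree(
#'   proband = family_member("self", sex = "female",
#'                           diagnoses = list(diagnosis("breast", 44))),
#'   ethnicities = "Caucasian"
#' )
#' p
#' @export
pedigree <- function(proband = family_member("self", sex = "female"),
                     members = list(), ethnicities = "Unknown",
                     mutations = list(), family_sizes = list(), id = NULL) {
  stopifnot(inherits(proband, "hcs_member"))
  if (proband$relationship != "self") {
    stop("the proband must have relationship 'self'")
  }
  stopifnot(is.list(members))
  for (m in members) {
    if (!inherits(m, "hcs_member")) stop("members must be family_member() objects")
    if (m$relationship == "self") {
      stop("at most one member with relationship 'self' (the proband slot)")
    }
  }
  # lineal positions are unique slots; collaterals may repeat
  unique_slots <- c("mother", "father",
                    "maternal grandmother", "maternal grandfather",
                    "paternal grandmother", "paternal grandfather",
                    "maternal great-grandmother", "maternal great-grandfather",
                    "paternal great-grandmother", "paternal great-grandfather")
  labs <- vapply(members, `[[`, character(1), "relationship")
  dup <- labs[duplicated(labs) & labs %in% unique_slots]
  if (length(dup)) {
    stop("duplicate unique relative position(s): ",
         paste(unique(dup), collapse = ", "))
  }
  ethnicities <- unique(as.character(ethnicities))
  bad <- setdiff(ethnicities, .ethnicities)
  if (length(bad)) stop("unknown ethnicities: ", paste(bad, collapse = ", "))
  stopifnot(is.list(mutations))
  for (mu in mutations) {
    if (!inherits(mu, "hcs_mutation")) stop("mutations must be mutation_finding() objects")
  }
  stopifnot(is.list(family_sizes))
  structure(list(proband = proband, members = members,
                 ethnicities = ethnicities, mutations = mutations,
                 family_sizes = family_sizes, id = id),
            class = "hcs_pedigree")
}

#' @export
print.hcs_pedigree <- function(x, ...) {
  n_dx <- sum(vapply(c(list(x$proband), x$members),
                     function(m) length(m$diagnoses), integer(1)))
  cat(sprintf("<pedigree%s> proband (%s) + %d relatives, %d diagnoses, %d mutation findings\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              x$proband$sex, length(x$members), n_dx, length(x$mutations)))
  cat("  ethnicities:", paste(x$ethnicities, collapse = ", "), "\n")
  for (m in x$members) {
    dx <- if (length(m$diagnoses)) {
      paste(vapply(m$diagnoses, function(d) {
        a <- impute_age(d$age, strict = FALSE)
        paste0(d$cancer_type, if (!is.na(a)) paste0("@", a) else "")
      }, character(1)), collapse = ", ")
    } else "unaffected"
    cat(sprintf("  - %s (%s): %s\n", m$relationship, m$sex, dx))
  }
  invisible(x)
}

# All persons (proband first) as a flat list.
.all_persons <- function(ped) c(list(ped$proband), ped$members)

#' Close blood relatives on one side of the family
#'
#' Close blood relatives are first-, second-, and third-degree relatives on
#' the same side of the family. Full siblings, children and grandchildren
#' share both parental bloodlines and therefore appear on either side. The
#' proband is never a member of the returned set.
#'
#' @param ped A [pedigree()].
#' @param side `"maternal"` or `"paternal"`.
#' @return A list of `hcs_member` objects.
#' @examples
#' p <- pedigree(members = list(family_member("mother"),
#'                              family_member("paternal uncle")))
#' length(close_blood_relatives(p, "maternal"))
#' @export
close_blood_relatives <- function(ped, side = c("maternal", "paternal")) {
  side <- match.arg(side)
  keep <- vapply(ped$members, function(m) {
    lin <- lineage_of(m$relationship)
    degree_of(m$relationship) <= 3L && (lin == side || lin == "both")
  }, logical(1))
  ped$members[keep]
}

#' Re-root a pedigree at a first- or second-degree relative
#'
#' Family-history-only criteria apply when a first- or second-degree blood
#' relative would themselves meet a personal-history criterion. Re-rooting
#' produces the pedigree as seen from that relative: every original person
#' whose relationship to the new root is derivable from the label algebra
#' is re-labeled (the original proband becomes a member); persons who are
#' not blood relatives of the root, or whose re-rooted position falls
#' outside the three-generation vocabulary, are dropped. Ethnicities and
#' family-size counts are family-level and carry over; mutation findings
#' carry over with re-labeled carriers (dropped if the carrier is not a
#' blood relative of the root).
#'
#' @param ped A [pedigree()].
#' @param new_root The index (into `ped$members`) or the relationship label
#'   of the member to re-root at; must have degree 1 or 2.
#' @return A new [pedigree()] rooted at `new_root`.
#' @examples
#' p <- pedigree(members = list(
#'   family_member("mother", diagnoses = list(diagnosis("ovarian", 62))),
#'   family_member("maternal grandmother")))
#' reroot(p, "mother")
#' @export
reroot <- function(ped, new_root) {
  if (is.character(new_root)) {
    idx <- which(vapply(ped$members, function(m) m$relationship, character(1)) == new_root)
    if (!length(idx)) stop("no member with relationship ", sQuote(new_root))
    new_root <- idx[1]
  }
  stopifnot(new_root >= 1L, new_root <= length(ped$members))
  root <- ped$members[[new_root]]
  if (!degree_of(root$relationship) %in% c(1L, 2L)) {
    stop("re-rooting requires a first- or second-degree relative; ",
         sQuote(root$relationship), " has degree ",
         degree_of(root$relationship))
  }
  ps <- ped$proband$sex
  relabel <- function(member_label, member_sex) {
    .reroot_label(root$relationship, member_label, proband_sex = ps,
                  member_sex = member_sex)
  }
  new_proband <- root
  new_proband$relationship <- "self"
  new_members <- list()
  old_proband <- ped$proband
  lbl <- relabel("self", ps)
  if (!is.na(lbl)) {
    old_proband$relationship <- lbl
    new_members <- c(new_members, list(old_proband))
  }
  for (i in seq_along(ped$members)) {
    if (i == new_root) next
    m <- ped$members[[i]]
    lbl <- relabel(m$relationship, m$sex)
    if (is.na(lbl)) next
    m$relationship <- lbl
    new_members <- c(new_members, list(m))
  }
  new_mutations <- list()
  for (mu in ped$mutations) {
    carrier <- if (mu$carrier == "self") relabel("self", ps)
               else if (mu$carrier == root$relationship) "self"
               else relabel(mu$carrier, NA_character_)
    if (is.na(carrier)) next
    new_mutations <- c(new_mutations, list(mutation_finding(mu$gene_group, carrier)))
  }
  pedigree(proband = new_proband, members = new_members,
           ethnicities = ped$ethnicities, mutations = new_mutations,
           family_sizes = ped$family_sizes,
           id = if (!is.null(ped$id)) paste0(ped$id, ":", root$relationship))
}
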