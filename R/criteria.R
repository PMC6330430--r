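# The criteria engine: one-to-one matching of a pedigree against the
# enumerated BRCA-related, Lynch-syndrome, and polyposis genetic-testing
# criteria (V2.2017 semantics), including family-history mirroring and the
# Amsterdam II criteria.
#
# Conventions encoded here (see the vignette for rationale):
#   * Counting clauses of the form "index case + k close relatives" require
#     the counted relatives to share one side of the family; "both"-lineage
#     members (full siblings, children, grandchildren) are usable on either
#     side. The index person never counts among their own supporters;
#     distinct people, not distinct tumors, are counted -- except the
#     additional-breast-primary clause, which is about one person.
#   * Breast-criteria age bounds are inclusive (<=45 / <=50 / <=60);
#     Lynch and Amsterdam II "before 50" bounds are strict.
#   * Diagnoses with unknown age satisfy only "at any age" clauses.
#   * Known-mutation criteria fire on any blood relative of degree <= 3,
#     or on the proband.

#' Engine configuration
#'
#' @param brca_age_inclusive Treat the breast-criteria age bounds as
#'   inclusive (`<=45`/`<=50`/`<=60`, the guideline reading) rather than
#'   strict. Lynch and Amsterdam "before age 50" bounds are always strict.
#' @param polyp_threshold Cumulative adenoma count at or above which the
#'   polyposis count criteria fire.
#' @param limited_family_min A side is "limited" when it has fewer than
#'   this many reported relatives beyond the parents; the
#'   limited/unknown-family-history clause needs both sides limited (or
#'   `family_sizes$unknown = TRUE`).
#' @param combination_mode How low-risk same-lineage histories group into
#'   combination events: one event per side (`"per_side"`, default) or one
#'   per pair (`"per_pair"`).
#' @return A list of class `hcs_config`.
#' @export
engine_config <- function(brca_age_inclusive = TRUE, polyp_threshold = 10L,
                          limited_family_min = 2L,
                          combination_mode = c("per_side", "per_pair")) {
  structure(list(brca_age_inclusive = isTRUE(brca_age_inclusive),
                 polyp_threshold = as.integer(polyp_threshold),
                 limited_family_min = as.integer(limited_family_min),
                 combination_mode = match.arg(combination_mode)),
            class = "hcs_config")
}

#' The criterion registry
#'
#' Stable identifiers, syndrome, and printed text of every implemented
#' criterion. The guideline sets contain 25 BRCA-related, 16 Lynch and 3
#' polyposis criteria in full; the registry implements the enumerated
#' subset the validation exercised (tumor-testing and mutation-probability
#' criteria are out of scope), with the three polyposis rules as
#' configuration-exposed reconstructions.
#'
#' @return A data frame with columns `id`, `syndrome`, `description`.
#' @export
criteria_registry <- function() {
  reg <- rbind(
    c("B1",  "BRCA", "Individual from a family with a known BRCA1/BRCA2 mutation"),
    c("B2",  "BRCA", "Personal history of breast cancer diagnosed <= 45 y"),
    c("B3",  "BRCA", "Breast cancer <= 50 y with an additional breast cancer primary"),
    c("B4",  "BRCA", "Breast cancer <= 50 y with >= 1 close blood relative with breast cancer"),
    c("B5",  "BRCA", "Breast cancer <= 50 y with >= 1 close blood relative with pancreatic cancer"),
    c("B6",  "BRCA", "Breast cancer <= 50 y with >= 1 close blood relative with prostate cancer"),
    c("B7",  "BRCA", "Breast cancer <= 50 y with an unknown or limited family history"),
    c("B8",  "BRCA", "Triple-negative breast cancer diagnosed <= 60 y"),
    c("B9",  "BRCA", "Breast cancer at any age with >= 2 close blood relatives with breast, pancreatic, or prostate cancer at any age"),
    c("B10", "BRCA", "Breast cancer at any age with >= 1 close blood relative with breast cancer diagnosed <= 50 y"),
    c("B11", "BRCA", "Breast cancer at any age with >= 1 close blood relative with ovarian carcinoma"),
    c("B12", "BRCA", "Breast cancer at any age with a close male blood relative with breast cancer"),
    c("B13", "BRCA", "Breast cancer at any age in an individual of ethnicity associated with higher mutation frequency (e.g., Ashkenazi Jewish)"),
    c("B14", "BRCA", "Personal history of ovarian carcinoma (includes fallopian tube and primary peritoneal)"),
    c("B15", "BRCA", "Personal history of male breast cancer"),
    c("B16", "BRCA", "Personal history of prostate cancer (Gleason > 7) with qualifying family pattern"),
    c("B17", "BRCA", "Personal history of pancreatic cancer with qualifying family pattern"),
    c("B18", "BRCA", "First- or second-degree blood relative meeting any of the personal-history criteria"),
    c("B19", "BRCA", "Third-degree relative with breast and/or ovarian carcinoma and >= 2 close blood relatives with breast cancer (at least one <= 50 y) and/or ovarian carcinoma"),
    c("L1",  "LYNCH", "Known Lynch syndrome mutation in the family"),
    c("L2",  "LYNCH", ">= 1 first-degree relative with colorectal or endometrial cancer diagnosed < 50 y"),
    c("L3",  "LYNCH", ">= 1 first-degree relative with colorectal or endometrial cancer and another synchronous or metachronous LS-related cancer"),
    c("L4",  "LYNCH", ">= 2 first- or second-degree relatives with LS-related cancer, including one diagnosed < 50 y"),
    c("L5",  "LYNCH", ">= 3 first- or second-degree relatives with LS-related cancer, regardless of age"),
    c("L6",  "LYNCH", "Family meets Amsterdam II criteria"),
    c("P1",  "POLYPOSIS", "Known APC/MUTYH mutation in the family"),
    c("P2",  "POLYPOSIS", "Personal cumulative adenoma count at or above threshold"),
    c("P3",  "POLYPOSIS", "First-degree relative with cumulative adenoma count at or above threshold")
  )
  data.frame(id = reg[, 1], syndrome = reg[, 2], description = reg[, 3],
             stringsAsFactors = FALSE)
}

# One fulfilled criterion: the unit of the validation analysis.
.criterion_event <- function(id, syndrome, contributing, contributing_uids,
                             index_person = "self", side = NA_character_,
                             mirrored = NA_character_) {
  structure(list(criterion_id = id, syndrome = syndrome,
                 contributing_members = contributing,
                 contributing_uids = contributing_uids,
                 index_person = index_person, side = side,
                 mirrored_criterion = mirrored),
            class = "hcs_criterion_event")
}

#' @export
print.hcs_criterion_event <- function(x, ...) {
  cat(sprintf("<criterion %s (%s)> index=%s%s; members: %s\n",
              x$criterion_id, x$syndrome, x$index_person,
              if (!is.na(x$mirrored_criterion)) paste0(" mirrors ", x$mirrored_criterion) else "",
              paste(x$contributing_members, collapse = ", ")))
  invisible(x)
}

# ---- internal evaluation machinery -----------------------------------------

.tag_uids <- function(ped) {
  if (is.null(ped$proband$uid)) ped$proband$uid <- "P"
  for (i in seq_along(ped$members)) {
    if (is.null(ped$members[[i]]$uid)) ped$members[[i]]$uid <- paste0("M", i)
  }
  ped
}

.uid_labels <- function(ped) {
  labs <- c(ped$proband$relationship,
            vapply(ped$members, `[[`, character(1), "relationship"))
  names(labs) <- c(ped$proband$uid,
                   vapply(ped$members, `[[`, character(1), "uid"))
  labs
}

# Flat person x diagnosis table. Persons without diagnoses still get one
# row (type NA) so person-level facts (sex, polyps) are queryable.
.dx_table <- function(ped) {
  persons <- .all_persons(ped)
  rows <- lapply(seq_along(persons), function(i) {
    p <- persons[[i]]
    is_proband <- i == 1L
    deg <- degree_of(p$relationship)
    lin <- lineage_of(p$relationship)
    base <- data.frame(uid = p$uid, relationship = p$relationship,
                       degree = deg, lineage = lin, sex = p$sex,
                       is_proband = is_proband,
                       polyp_count = p$polyp_count,
                       stringsAsFactors = FALSE)
    if (!length(p$diagnoses)) {
      cbind(base, data.frame(type = NA_character_, age = NA_integer_,
                             tn = FALSE, dcis = FALSE, gleason = FALSE,
                             sync_meta = FALSE, primary_index = NA_integer_))
    } else {
      do.call(rbind, lapply(p$diagnoses, function(d) {
        cbind(base, data.frame(
          type = d$cancer_type,
          age = impute_age(d$age, strict = FALSE),
          tn = "TRIPLE_NEGATIVE" %in% d$qualifiers,
          dcis = "DCIS" %in% d$qualifiers,
          gleason = "GLEASON_GT7" %in% d$qualifiers,
          sync_meta = any(c("SYNCHRONOUS", "METACHRONOUS") %in% d$qualifiers),
          primary_index = d$primary_index))
      }))
    }
  })
  do.call(rbind, rows)
}

# Age comparison against a bound; unknown ages never satisfy bounded clauses.
.age_le <- function(age, bound, inclusive) {
  !is.na(age) & if (inclusive) age <= bound else age < bound
}

.is_breast <- function(tab) !is.na(tab$type) & tab$type == "breast"

# Rows of close blood relatives (degree 1-3) usable on `side`.
.close_idx <- function(tab, side) {
  !tab$is_proband & tab$degree >= 1L & tab$degree <= 3L &
    (tab$lineage == side | tab$lineage == "both")
}

# Distinct persons among close relatives on some single side whose rows
# satisfy `rowpred` (logical over tab rows); returns list(side, uids) for
# the first side reaching `k` persons, else NULL. `extra` optionally adds a
# person-level requirement over the selected persons' qualifying rows.
.same_side_persons <- function(tab, rowpred, k, extra = NULL) {
  for (side in c("maternal", "paternal")) {
    sel <- .close_idx(tab, side) & rowpred
    uids <- unique(tab$uid[sel])
    if (length(uids) >= k) {
      if (!is.null(extra) && !extra(tab[sel, , drop = FALSE])) next
      return(list(side = side, uids = uids[seq_len(max(k, 1L))],
                  all_uids = uids))
    }
  }
  NULL
}

.limited_family <- function(ped, config) {
  fs <- ped$family_sizes
  if (isTRUE(fs$unknown)) return(TRUE)
  for (side in c("maternal", "paternal")) {
    n <- sum(vapply(ped$members, function(m) {
      lin <- lineage_of(m$relationship)
      (lin == side || lin == "both") &&
        !m$relationship %in% c("mother", "father")
    }, logical(1)))
    declared <- fs[[paste0(side, "_relatives")]]
    if (!is.null(declared)) n <- max(n, declared)
    if (n >= .limited_min(config)) return(FALSE)
  }
  TRUE
}

.limited_min <- function(config) config$limited_family_min

# Personal-history BRCA criteria (B2-B17) evaluated with the pedigree's own
# proband as the index case. Used directly and under mirroring.
.personal_brca <- function(ped, tab, config) {
  events <- list()
  add <- function(id, uids, side = NA_character_) {
    labs <- .uid_labels(ped)
    events[[length(events) + 1L]] <<- .criterion_event(
      id, "BRCA", unname(labs[uids]), uids, side = side)
  }
  inc <- config$brca_age_inclusive
  pro <- tab$is_proband
  puid <- tab$uid[pro][1]
  breast <- .is_breast(tab) & pro
  has_breast <- any(breast)

  if (any(breast & .age_le(tab$age, 45, inc))) add("B2", puid)
  b50 <- any(breast & .age_le(tab$age, 50, inc))
  if (b50 && sum(breast) >= 2L) add("B3", puid)
  if (b50) {
    for (spec in list(c("B4", "breast"), c("B5", "pancreatic"),
                      c("B6", "prostate"))) {
      hit <- .same_side_persons(tab, !is.na(tab$type) & tab$type == spec[2], 1L)
      if (!is.null(hit)) add(spec[1], c(puid, hit$uids), hit$side)
    }
    if (.limited_family(ped, config)) add("B7", puid)
  }
  if (any(breast & tab$tn & .age_le(tab$age, 60, inc))) add("B8", puid)
  if (has_breast) {
    bpp <- !is.na(tab$type) & tab$type %in% c("breast", "pancreatic", "prostate")
    hit <- .same_side_persons(tab, bpp, 2L)
    if (!is.null(hit)) add("B9", c(puid, hit$uids), hit$side)
    hit <- .same_side_persons(tab, .is_breast(tab) & .age_le(tab$age, 50, inc), 1L)
    if (!is.null(hit)) add("B10", c(puid, hit$uids), hit$side)
    hit <- .same_side_persons(tab, !is.na(tab$type) & is_ovarian_equivalent(tab$type), 1L)
    if (!is.null(hit)) add("B11", c(puid, hit$uids), hit$side)
    hit <- .same_side_persons(tab, .is_breast(tab) & tab$sex == "male", 1L)
    if (!is.null(hit)) add("B12", c(puid, hit$uids), hit$side)
    if ("Ashkenazi Jewish" %in% ped$ethnicities) add("B13", puid)
  }
  if (any(pro & !is.na(tab$type) & is_ovarian_equivalent(tab$type))) add("B14", puid)
  if (any(breast & tab$sex == "male")) add("B15", puid)
  fam_pattern <- function() {
    hit <- .same_side_persons(tab, !is.na(tab$type) & is_ovarian_equivalent(tab$type), 1L)
    if (!is.null(hit)) return(hit)
    hit <- .same_side_persons(tab, .is_breast(tab) & .age_le(tab$age, 50, inc), 1L)
    if (!is.null(hit)) return(hit)
    .same_side_persons(tab, !is.na(tab$type) &
                         tab$type %in% c("breast", "pancreatic", "prostate"), 2L)
  }
  if (any(pro & !is.na(tab$type) & tab$type == "prostate" & tab$gleason)) {
    hit <- fam_pattern()
    if (!is.null(hit)) add("B16", c(puid, hit$uids), hit$side)
  }
  if (any(pro & !is.na(tab$type) & tab$type == "pancreatic")) {
    hit <- fam_pattern()
    if (!is.null(hit)) add("B17", c(puid, hit$uids), hit$side)
  }
  events
}

#' Evaluate the BRCA-related criteria
#'
#' Returns every fulfilled BRCA-related criterion event: the known-mutation
#' criterion, the personal-history criteria with the proband as index case,
#' the family-history mirror (a first- or second-degree relative meeting a
#' personal-history criterion as index, computed by [reroot()]-ing the
#' pedigree at each eligible relative), and the third-degree-relative
#' breast/ovarian cluster criterion.
#'
#' @param ped A [pedigree()].
#' @param config An [engine_config()].
#' @return A list of criterion events.
#' @export
evaluate_brca <- function(ped, config = engine_config()) {
  ped <- .tag_uids(normalize_pedigree(ped))
  tab <- .dx_table(ped)
  labs <- .uid_labels(ped)
  events <- list()

  for (mu in ped$mutations) {
    if (mu$gene_group == "BRCA1_BRCA2") {
      events[[length(events) + 1L]] <- .criterion_event(
        "B1", "BRCA", mu$carrier, NA_character_)
      break
    }
  }
  events <- c(events, .personal_brca(ped, tab, config))

  # B18: mirror at each first-/second-degree relative
  for (i in seq_along(ped$members)) {
    m <- ped$members[[i]]
    if (!degree_of(m$relationship) %in% c(1L, 2L)) next
    if (!length(m$diagnoses)) next   # index must have a personal history
    rp <- reroot(ped, i)
    rtab <- .dx_table(rp)
    mirrored <- .personal_brca(rp, rtab, config)
    for (ev in mirrored) {
      uids <- unique(c(m$uid, ev$contributing_uids))
      uids <- uids[uids %in% names(labs)]
      events[[length(events) + 1L]] <- .criterion_event(
        "B18", "BRCA", unname(labs[uids]), uids,
        index_person = m$relationship, side = ev$side,
        mirrored = ev$criterion_id)
    }
  }

  # B19: third-degree relative with breast/ovarian plus a breast/ovarian
  # cluster among their close blood relatives (the proband may support)
  tdr <- !tab$is_proband & tab$degree == 3L & !is.na(tab$type) &
    (tab$type == "breast" | is_ovarian_equivalent(tab$type))
  for (uid in unique(tab$uid[tdr])) {
    t_side <- tab$lineage[tab$uid == uid][1]
    cand <- tab$uid != uid & !is.na(tab$type) &
      (tab$lineage %in% c(t_side, "both") | tab$is_proband) &
      (.is_breast(tab) | is_ovarian_equivalent(tab$type))
    sup_rows <- tab[cand, , drop = FALSE]
    sup <- unique(sup_rows$uid)
    strong <- sup_rows$uid[is_ovarian_equivalent(ifelse(is.na(sup_rows$type), "", sup_rows$type)) |
                             (.is_breast(sup_rows) &
                                .age_le(sup_rows$age, 50, config$brca_age_inclusive))]
    if (length(sup) >= 2L && length(strong) >= 1L) {
      uids <- unique(c(uid, sup))
      events[[length(events) + 1L]] <- .criterion_event(
        "B19", "BRCA", unname(labs[uids]), uids,
        index_person = labs[[uid]], side = t_side)
      break
    }
  }
  events
}

#' Evaluate the Lynch syndrome criteria
#'
#' @inheritParams evaluate_brca
#' @return A list of criterion events among the known-mutation criterion,
#'   the first-degree-relative clauses, the relative-cluster clauses, and
#'   Amsterdam II.
#' @export
evaluate_lynch <- function(ped, config = engine_config()) {
  ped <- .tag_uids(normalize_pedigree(ped))
  tab <- .dx_table(ped)
  labs <- .uid_labels(ped)
  events <- list()
  add <- function(id, uids, side = NA_character_, index = "self") {
    uids <- unique(uids)
    events[[length(events) + 1L]] <<- .criterion_event(
      id, "LYNCH", unname(labs[uids]), uids, index_person = index, side = side)
  }

  for (mu in ped$mutations) {
    if (mu$gene_group == "LYNCH") {
      events[[length(events) + 1L]] <- .criterion_event(
        "L1", "LYNCH", mu$carrier, NA_character_)
      break
    }
  }

  fdr <- !tab$is_proband & tab$degree == 1L
  crc_endo <- !is.na(tab$type) & tab$type %in% c("colorectal", "endometrial")
  ls <- !is.na(tab$type) & is_ls_related(tab$type)

  # L2: FDR with colorectal/endometrial before 50 (strict)
  l2 <- fdr & crc_endo & .age_le(tab$age, 50, inclusive = FALSE)
  if (any(l2)) add("L2", tab$uid[l2][1])

  # L3: the same FDR carries colorectal/endometrial plus a second LS-related
  # cancer (flagged synchronous/metachronous, or simply a second LS primary)
  for (uid in unique(tab$uid[fdr & crc_endo])) {
    rows <- which(tab$uid == uid & ls)
    anchor <- which(tab$uid == uid & crc_endo)[1]
    other <- setdiff(rows, anchor)
    if (length(other)) { add("L3", uid); break }
  }

  # L4 / L5: clusters of FDR/SDR with LS-related cancer on one side
  fdr_sdr_ls <- !tab$is_proband & tab$degree <= 2L & ls
  hit <- .same_side_persons(tab, fdr_sdr_ls, 2L,
                            extra = function(rows) any(.age_le(rows$age, 50, FALSE)))
  if (!is.null(hit)) add("L4", hit$all_uids, hit$side)
  hit <- .same_side_persons(tab, fdr_sdr_ls, 3L)
  if (!is.null(hit)) add("L5", hit$all_uids, hit$side)

  ams <- meets_amsterdam_ii(ped, config)
  if (ams$meets) add("L6", ams$uids)
  events
}

#' Amsterdam II criteria
#'
#' A family meets Amsterdam II when at least three relatives (the proband
#' may be one) have Amsterdam-associated cancers (colorectal, endometrial,
#' small intestinal, ureter/renal pelvis), one of them is a first-degree
#' relative of the other two, at least two successive generations are
#' affected, and at least one diagnosis was made before age 50.
#'
#' @inheritParams evaluate_brca
#' @return A list with `meets` (flag), `members` (contributing relationship
#'   labels) and `uids` (internal person identifiers).
#' @export
meets_amsterdam_ii <- function(ped, config = engine_config()) {
  ped <- .tag_uids(normalize_pedigree(ped))
  tab <- .dx_table(ped)
  labs <- .uid_labels(ped)
  ams <- !is.na(tab$type) & is_amsterdam_cancer(tab$type)
  affected <- unique(tab$uid[ams])
  no <- list(meets = FALSE, members = character(), uids = character())
  if (length(affected) < 3L) return(no)
  gen <- vapply(affected, function(u) generation_of(labs[[u]]), integer(1))
  young <- vapply(affected, function(u) {
    any(.age_le(tab$age[tab$uid == u & ams], 50, inclusive = FALSE))
  }, logical(1))
  combs <- utils::combn(seq_along(affected), 3L)
  for (j in seq_len(ncol(combs))) {
    trio <- affected[combs[, j]]
    lt <- labs[trio]
    linked <- FALSE
    for (a in 1:3) {
      others <- setdiff(1:3, a)
      d1 <- .degree_between(lt[[a]], lt[[others[1]]])
      d2 <- .degree_between(lt[[a]], lt[[others[2]]])
      if (!is.na(d1) && !is.na(d2) && d1 == 1L && d2 == 1L) { linked <- TRUE; break }
    }
    if (!linked) next
    g <- sort(unique(gen[combs[, j]]))
    if (!any(diff(g) == 1L)) next
    if (!any(young[combs[, j]])) next
    return(list(meets = TRUE, members = unname(unlist(lt)), uids = trio))
  }
  no
}

#' Evaluate the polyposis criteria
#'
#' The validation cohort contained no polyposis-qualifying histories and
#' the underlying rules are not enumerated; these three rules are
#' configuration-exposed reconstructions: a known APC/MUTYH mutation in the
#' family, a personal cumulative adenoma count at or above the threshold,
#' and a first-degree relative at or above the threshold.
#'
#' @inheritParams evaluate_brca
#' @return A list of criterion events.
#' @export
evaluate_polyposis <- function(ped, config = engine_config()) {
  ped <- .tag_uids(ped)
  events <- list()
  for (mu in ped$mutations) {
    if (mu$gene_group == "APC_MUTYH") {
      events[[length(events) + 1L]] <- .criterion_event(
        "P1", "POLYPOSIS", mu$carrier, NA_character_)
      break
    }
  }
  thr <- config$polyp_threshold
  pc <- ped$proband$polyp_count
  if (!is.na(pc) && pc >= thr) {
    events[[length(events) + 1L]] <- .criterion_event(
      "P2", "POLYPOSIS", "self", ped$proband$uid)
  }
  for (m in ped$members) {
    if (degree_of(m$relationship) == 1L && !is.na(m$polyp_count) &&
        m$polyp_count >= thr) {
      events[[length(events) + 1L]] <- .criterion_event(
        "P3", "POLYPOSIS", m$relationship, m$uid)
      break
    }
  }
  events
}

#' Evaluate a pedigree against all criteria
#'
#' Runs the full registry (BRCA-related, Lynch, polyposis) and reports
#' every fulfilled criterion -- all matches, not the first. The evaluation
#' is deterministic and leaves the input unchanged. When any criterion is
#' fulfilled the report carries the fixed recommendation string
#' "genetic screening should be considered at this time".
#'
#' @inheritParams evaluate_brca
#' @return An object of class `hcs_report`: `meets_any`, `events` (all
#'   fulfilled criterion events), `per_syndrome`, `recommendation_text`.
#' @examples
#' p <- pedigree(proband = family_member("self", sex = "female",
#'                 diagnoses = list(diagnosis("breast", 44))))
#' evaluate_pedigree(p)
#' @export
evaluate_pedigree <- function(ped, config = engine_config()) {
  stopifnot(inherits(ped, "hcs_pedigree"), inherits(config, "hcs_config"))
  per <- list(BRCA = evaluate_brca(ped, config),
              LYNCH = evaluate_lynch(ped, config),
              POLYPOSIS = evaluate_polyposis(ped, config))
  events <- c(per$BRCA, per$LYNCH, per$POLYPOSIS)
  meets <- length(events) > 0L
  structure(list(
    meets_any = meets,
    events = events,
    per_syndrome = per,
    recommendation_text = if (meets) "genetic screening should be considered at this time"
                          else NA_character_),
    class = "hcs_report")
}

#' @export
print.hcs_report <- function(x, ...) {
  cat("<screening report>", if (x$meets_any) "MEETS criteria" else "does not meet criteria", "\n")
  if (x$meets_any) {
    ids <- vapply(x$events, `[[`, character(1), "criterion_id")
    cat("  fulfilled:", paste(sort(unique(ids)), collapse = ", "), "\n")
    cat("  ", x$recommendation_text, "\n", sep = "")
  }
  invisible(x)
}

#' Fulfilled criterion identifiers
#'
#' @param x An `hcs_report` or list of criterion events.
#' @return Sorted unique character vector of criterion ids.
#' @export
fulfilled_ids <- function(x) {
  events <- if (inherits(x, "hcs_report")) x$events else x
  sort(unique(vapply(events, `[[`, character(1), "criterion_id")))
}
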