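# File I/O: the canonical pedigree JSON interchange format (schema shipped
# under inst/schema/), an events CSV view, report output, and a minimal
# linkage-format (PED) export for interoperability.

.schema_fail <- function(where, what) {
  stop(sprintf("pedigree schema violation at %s: %s", where, what),
       call. = FALSE)
}

.validate_age_json <- function(x, where) {
  if (!is.list(x) || is.null(x$kind)) .schema_fail(where, "age must be a {kind, value} object")
  if (!x$kind %in% .age_kinds) .schema_fail(where, paste("unknown age kind", x$kind))
  unknown <- setdiff(names(x), c("kind", "value"))
  if (length(unknown)) .schema_fail(where, paste("unknown field(s):",
                                                 paste(unknown, collapse = ", ")))
  age_record(x$kind, x$value)
}

.validate_dx_json <- function(x, where) {
  if (is.null(x$cancer_type)) .schema_fail(where, "missing cancer_type")
  unknown <- setdiff(names(x), c("cancer_type", "age", "qualifiers", "primary_index"))
  if (length(unknown)) .schema_fail(where, paste("unknown field(s):",
                                                 paste(unknown, collapse = ", ")))
  age <- if (is.null(x$age)) age_record("UNKNOWN")
         else .validate_age_json(x$age, paste0(where, ".age"))
  tryCatch(
    diagnosis(x$cancer_type, age = age,
              qualifiers = unlist(x$qualifiers) %||% character(),
              primary_index = x$primary_index %||% 1L),
    error = function(e) .schema_fail(where, conditionMessage(e)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.validate_member_json <- function(x, where) {
  if (is.null(x$relationship)) .schema_fail(where, "missing relationship")
  unknown <- setdiff(names(x), c("relationship", "sex", "diagnoses",
                                 "polyp_count", "deceased"))
  if (length(unknown)) .schema_fail(where, paste("unknown field(s):",
                                                 paste(unknown, collapse = ", ")))
  dxs <- lapply(seq_along(x$diagnoses %||% list()), function(j) {
    .validate_dx_json(x$diagnoses[[j]], sprintf("%s.diagnoses[%d]", where, j))
  })
  tryCatch(
    family_member(x$relationship, sex = x$sex,
                  diagnoses = dxs,
                  polyp_count = x$polyp_count %||% NA_integer_,
                  deceased = x$deceased %||% NA),
    error = function(e) .schema_fail(where, conditionMessage(e)))
}

#' Read a pedigree from its JSON interchange format
#'
#' The canonical format is a JSON object `{proband, members, ethnicities,
#' mutations, family_sizes, id}` with ages as `{"kind": ..., "value": n}`;
#' the machine-readable schema ships with the package
#' (`system.file("schema", "pedigree-schema.json", package = "hcscreen")`).
#' Documents are validated on read: unknown fields and constraint
#' violations are rejected with the offending location named.
#'
#' @param path Path to a pedigree JSON file.
#' @return A [pedigree()].
#' @export
read_pedigree <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  pedigree_from_list(raw)
}

#' @rdname read_pedigree
#' @param x A list in the shape of the JSON document.
#' @export
pedigree_from_list <- function(x) {
  unknown <- setdiff(names(x), c("proband", "members", "ethnicities",
                                 "mutations", "family_sizes", "id"))
  if (length(unknown)) .schema_fail("$", paste("unknown field(s):",
                                               paste(unknown, collapse = ", ")))
  if (is.null(x$proband)) .schema_fail("$", "missing proband")
  proband <- .validate_member_json(x$proband, "$.proband")
  if (proband$relationship != "self") {
    .schema_fail("$.proband.relationship", "must be 'self'")
  }
  members <- lapply(seq_along(x$members %||% list()), function(i) {
    .validate_member_json(x$members[[i]], sprintf("$.members[%d]", i))
  })
  mutations <- lapply(seq_along(x$mutations %||% list()), function(i) {
    mu <- x$mutations[[i]]
    where <- sprintf("$.mutations[%d]", i)
    if (is.null(mu$gene_group)) .schema_fail(where, "missing gene_group")
    tryCatch(mutation_finding(mu$gene_group, mu$carrier %||% "self"),
             error = function(e) .schema_fail(where, conditionMessage(e)))
  })
  tryCatch(
    pedigree(proband = proband, members = members,
             ethnicities = unlist(x$ethnicities) %||% "Unknown",
             mutations = mutations,
             family_sizes = x$family_sizes %||% list(),
             id = x$id),
    error = function(e) .schema_fail("$", conditionMessage(e)))
}

.age_to_list <- function(a) {
  if (a$kind == "UNKNOWN") list(kind = "UNKNOWN") else
    list(kind = a$kind, value = a$value)
}

.member_to_list <- function(m) {
  out <- list(relationship = m$relationship, sex = m$sex)
  if (length(m$diagnoses)) {
    out$diagnoses <- lapply(m$diagnoses, function(d) {
      dl <- list(cancer_type = d$cancer_type, age = .age_to_list(d$age))
      if (length(d$qualifiers)) dl$qualifiers <- as.list(d$qualifiers)
      if (!identical(d$primary_index, 1L)) dl$primary_index <- d$primary_index
      dl
    })
  }
  if (!is.na(m$polyp_count)) out$polyp_count <- m$polyp_count
  if (!is.na(m$deceased)) out$deceased <- m$deceased
  out
}

#' Write a pedigree to JSON
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "hcs_pedigree"))
  doc <- list(proband = .member_to_list(ped$proband),
              members = lapply(ped$members, .member_to_list),
              ethnicities = as.list(ped$ethnicities),
              mutations = lapply(ped$mutations, function(mu) {
                list(gene_group = mu$gene_group, carrier = mu$carrier)
              }),
              family_sizes = ped$family_sizes)
  if (!is.null(ped$id)) doc$id <- ped$id
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' Write a screening report
#'
#' Emits the evaluation result as structured JSON or human-readable text.
#' When any criterion is met the report carries the fixed recommendation
#' string "genetic screening should be considered at this time".
#'
#' @param report An `hcs_report` from [evaluate_pedigree()].
#' @param path Output path.
#' @param format `"json"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "text")) {
  stopifnot(inherits(report, "hcs_report"))
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      meets_any = report$meets_any,
      recommendation = if (report$meets_any) report$recommendation_text else NULL,
      fulfilled = lapply(report$events, function(ev) {
        list(criterion_id = ev$criterion_id, syndrome = ev$syndrome,
             index_person = ev$index_person,
             mirrored_criterion = if (is.na(ev$mirrored_criterion)) NULL
                                  else ev$mirrored_criterion,
             contributing_members = as.list(ev$contributing_members),
             side = if (is.na(ev$side)) NULL else ev$side)
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    lines <- c(
      if (report$meets_any) {
        c("RESULT: meets criteria",
          paste("RECOMMENDATION:", report$recommendation_text),
          "",
          vapply(report$events, function(ev) {
            sprintf("- %s (%s), index %s%s; members: %s",
                    ev$criterion_id, ev$syndrome, ev$index_person,
                    if (!is.na(ev$mirrored_criterion))
                      paste0(" [mirrors ", ev$mirrored_criterion, "]") else "",
                    paste(ev$contributing_members, collapse = ", "))
          }, character(1)))
      } else "RESULT: does not meet criteria")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write / read independent events as CSV
#'
#' The analysis table of a validation run: one row per independent event
#' with columns `pedigree_id`, `event_kind`, `criterion_id`, `syndrome`,
#' `relationship`, `degree`, `side`, `cancer_type`, `age`, `group_label`.
#'
#' @param events A list of independent events (from
#'   [extract_high_risk_events()], [extract_low_risk_events()] or a
#'   cohort), or an `hcs_cohort`.
#' @param path CSV path.
#' @return For the writer, `path` invisibly; for the reader, a data frame.
#' @export
write_events_csv <- function(events, path) {
  if (inherits(events, "hcs_cohort")) events <- events$events
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    base <- data.frame(pedigree_id = ev$pedigree_id, event_kind = ev$kind,
                       criterion_id = NA_character_, syndrome = NA_character_,
                       relationship = NA_character_, degree = NA_integer_,
                       side = NA_character_, cancer_type = NA_character_,
                       age = NA_integer_, group_label = NA_character_,
                       stringsAsFactors = FALSE)
    if (ev$kind == "CRITERION") {
      base$criterion_id <- ev$payload$criterion_id
      base$syndrome <- ev$payload$syndrome
      base$relationship <- ev$payload$index_person
      base$side <- ev$payload$side
      base
    } else if (ev$kind == "SINGLE_HISTORY") {
      s <- ev$payload
      base$relationship <- s$relationship
      base$degree <- s$degree
      base$side <- s$side
      base$cancer_type <- s$cancer_type
      base$age <- s$age
      base
    } else if (ev$kind == "COMBINATION") {
      g <- ev$payload
      do.call(rbind, lapply(g$singles, function(s) {
        r <- base
        r$relationship <- s$relationship; r$degree <- s$degree
        r$side <- g$side; r$cancer_type <- s$cancer_type; r$age <- s$age
        r$group_label <- sprintf("combo_%s_%d", g$side, i)
        r
      }))
    } else base
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(pedigree_id = "character",
                                 event_kind = "character"))
}

#' Export family structure in linkage (PED) format
#'
#' A convenience interoperability export of structure and sex only (no
#' phenotypes): columns FID, IID, father, mother, sex (1 = male, 2 =
#' female, 0 = unknown), phenotype (0). Parent pointers are filled where
#' the label algebra determines them (proband and full siblings to the
#' parents, parents to the same-side grandparents, children to the
#' proband); other relatives get unknown parents.
#'
#' @param ped A [pedigree()].
#' @param path Output path.
#' @param family_id Family identifier for the FID column.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, family_id = ped$id %||% "FAM1") {
  persons <- .all_persons(ped)
  labels <- vapply(persons, `[[`, character(1), "relationship")
  iid <- seq_along(persons)
  id_of <- function(lbl) {
    i <- which(labels == lbl)
    if (length(i)) i[1] else 0L
  }
  sex_code <- function(s) switch(s, male = 1L, female = 2L, 0L)
  rows <- vapply(seq_along(persons), function(i) {
    lbl <- labels[i]
    par <- c(father = 0L, mother = 0L)
    if (lbl %in% c("self", "sister", "brother")) {
      par <- c(id_of("father"), id_of("mother"))
    } else if (lbl == "mother") {
      par <- c(id_of("maternal grandfather"), id_of("maternal grandmother"))
    } else if (lbl == "father") {
      par <- c(id_of("paternal grandfather"), id_of("paternal grandmother"))
    } else if (lbl %in% c("maternal aunt", "maternal uncle")) {
      par <- c(id_of("maternal grandfather"), id_of("maternal grandmother"))
    } else if (lbl %in% c("paternal aunt", "paternal uncle")) {
      par <- c(id_of("paternal grandfather"), id_of("paternal grandmother"))
    } else if (lbl %in% c("daughter", "son")) {
      par <- c(0L, id_of("self"))
      if (persons[[1]]$sex == "male") par <- rev(par)
    }
    paste(family_id, iid[i], par[1], par[2],
          sex_code(persons[[i]]$sex), 0L, sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}
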