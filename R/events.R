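# Independent events: the unit of the validation analysis.
#
# High-risk pedigrees contribute one event per fulfilled criterion (one
# pedigree can fulfill several). Low-risk pedigrees contribute one
# single-history event per (person, diagnosis), plus combination events
# grouping >= 2 single histories within one lineage, plus a dedicated
# "no family history" event when nothing remains.

.independent_event <- function(kind, payload, pedigree_id = NA_character_) {
  structure(list(kind = kind, payload = payload, pedigree_id = pedigree_id),
            class = "hcs_event")
}

#' @export
print.hcs_event <- function(x, ...) {
  desc <- switch(x$kind,
    CRITERION = x$payload$criterion_id,
    SINGLE_HISTORY = sprintf("%s@%s in %s", x$payload$cancer_type,
                             ifelse(is.na(x$payload$age), "?", x$payload$age),
                             x$payload$relationship),
    COMBINATION = sprintf("%d histories, %s side", length(x$payload$singles),
                          x$payload$side),
    NO_FAMILY_HISTORY = "no family history")
  cat(sprintf("<event %s> %s\n", x$kind, desc))
  invisible(x)
}

#' Extract independent events from a high-risk pedigree
#'
#' One `CRITERION` event per fulfilled criterion: the event unit of the
#' validation analysis is the criterion (one pedigree can fulfill
#' several). Family-history mirror matches are keyed by the mirrored
#' personal-history criterion, so two relatives mirroring the same
#' criterion contribute one event while mirrors of different criteria
#' contribute one each. A low-risk pedigree is rejected: route it to
#' [extract_low_risk_events()].
#'
#' @param ped A [pedigree()] that meets at least one criterion.
#' @param config An [engine_config()].
#' @return List of events of kind `CRITERION`.
#' @export
extract_high_risk_events <- function(ped, config = engine_config()) {
  report <- evaluate_pedigree(ped, config)
  if (!report$meets_any) {
    stop("pedigree is low-risk: use extract_low_risk_events()")
  }
  seen <- character()
  out <- list()
  for (ev in report$events) {
    key <- paste(ev$criterion_id, ev$mirrored_criterion)
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- .independent_event("CRITERION", ev,
                                                  pedigree_id = .ped_id(ped))
  }
  out
}

.ped_id <- function(ped) if (is.null(ped$id)) NA_character_ else ped$id

# Single-history tuples of a pedigree: one per (person, diagnosis), plus
# polyp-count findings, which the validation counted as testable histories.
.single_tuples <- function(ped) {
  out <- list()
  persons <- .all_persons(ped)
  for (i in seq_along(persons)) {
    p <- persons[[i]]
    side <- lineage_of(p$relationship)
    deg <- degree_of(p$relationship)
    for (d in p$diagnoses) {
      out[[length(out) + 1L]] <- list(
        person = i, relationship = p$relationship, degree = deg, side = side,
        cancer_type = d$cancer_type,
        age = impute_age(d$age, strict = FALSE))
    }
    if (!is.na(p$polyp_count) && p$polyp_count > 0L) {
      out[[length(out) + 1L]] <- list(
        person = i, relationship = p$relationship, degree = deg, side = side,
        cancer_type = "colon_polyps", age = NA_integer_)
    }
  }
  out
}

#' Extract independent events from a low-risk pedigree
#'
#' One `SINGLE_HISTORY` event per (person, diagnosis) tuple; one
#' `COMBINATION` event per same-lineage grouping of two or more single
#' histories ("both"-lineage histories, including the proband's own, are
#' usable on either side; identical groupings on the two sides are emitted
#' once); exactly one `NO_FAMILY_HISTORY` event when no history exists.
#' With `combination_mode = "per_pair"` every same-side pair becomes its
#' own combination event instead.
#'
#' @param ped A [pedigree()] that meets no criterion.
#' @param config An [engine_config()].
#' @return List of events.
#' @export
extract_low_risk_events <- function(ped, config = engine_config()) {
  report <- evaluate_pedigree(ped, config)
  if (report$meets_any) {
    stop("pedigree is high-risk: use extract_high_risk_events()")
  }
  id <- .ped_id(ped)
  singles <- .single_tuples(ped)
  if (!length(singles)) {
    return(list(.independent_event("NO_FAMILY_HISTORY", list(), id)))
  }
  events <- lapply(singles, function(s) {
    .independent_event("SINGLE_HISTORY", s, id)
  })
  usable <- function(s, side) s$side %in% c(side, "both", "self")
  groups <- list()
  for (side in c("maternal", "paternal")) {
    grp <- Filter(function(s) usable(s, side), singles)
    if (length(grp) >= 2L) {
      key <- paste(vapply(grp, function(s) {
        paste(s$relationship, s$cancer_type, s$age)
      }, character(1)), collapse = "|")
      if (!key %in% names(groups)) {
        groups[[key]] <- list(side = side, singles = grp)
      }
    }
  }
  for (g in groups) {
    if (config$combination_mode == "per_side") {
      events[[length(events) + 1L]] <-
        .independent_event("COMBINATION", g, id)
    } else {
      idx <- utils::combn(length(g$singles), 2L)
      for (j in seq_len(ncol(idx))) {
        events[[length(events) + 1L]] <- .independent_event(
          "COMBINATION", list(side = g$side,
                              singles = g$singles[idx[, j]]), id)
      }
    }
  }
  events
}

# Removable history items of a pedigree: every diagnosis, every mutation
# finding, and every non-zero polyp count.
.removable_items <- function(ped) {
  items <- list()
  persons <- .all_persons(ped)
  for (i in seq_along(persons)) {
    p <- persons[[i]]
    for (j in seq_along(p$diagnoses)) {
      items[[length(items) + 1L]] <- list(
        kind = "diagnosis", person = i, dx = j,
        age = impute_age(p$diagnoses[[j]]$age, strict = FALSE))
    }
    if (!is.na(p$polyp_count) && p$polyp_count > 0L) {
      items[[length(items) + 1L]] <- list(kind = "polyps", person = i,
                                          dx = NA_integer_, age = NA_integer_)
    }
  }
  for (k in seq_along(ped$mutations)) {
    items[[length(items) + 1L]] <- list(kind = "mutation", person = NA_integer_,
                                        dx = k, age = NA_integer_)
  }
  items
}

.remove_item <- function(ped, item) {
  if (item$kind == "mutation") {
    ped$mutations[[item$dx]] <- NULL
    return(ped)
  }
  set_person <- function(p) {
    if (item$kind == "diagnosis") p$diagnoses[[item$dx]] <- NULL
    else p$polyp_count <- 0L
    p
  }
  if (item$person == 1L) ped$proband <- set_person(ped$proband)
  else ped$members[[item$person - 1L]] <- set_person(ped$members[[item$person - 1L]])
  ped
}

#' Model a low-risk case from a high-risk pedigree
#'
#' Reproduces the modeled-case construction of the validation: qualifying
#' events that would otherwise fulfill criteria are removed from a
#' high-risk pedigree, and everything that remains is preserved verbatim.
#' Removal is greedy and deterministic: at each step the history item
#' (diagnosis, mutation finding, or polyp count) whose removal extinguishes
#' the most currently fulfilled criteria is deleted, ties broken by
#' youngest age at diagnosis, then by member order. If every item must go,
#' the result is a valid empty-history pedigree (a "no family history"
#' case). The operation is idempotent: a low-risk input is returned
#' unchanged.
#'
#' @param ped A [pedigree()].
#' @param config An [engine_config()].
#' @return A pedigree for which `evaluate_pedigree()$meets_any` is `FALSE`.
#' @export
model_low_risk <- function(ped, config = engine_config()) {
  repeat {
    report <- evaluate_pedigree(ped, config)
    if (!report$meets_any) return(ped)
    n_now <- length(report$events)
    items <- .removable_items(ped)
    if (!length(items)) {
      stop("pedigree fulfills criteria but has no removable history")
    }
    impact <- vapply(items, function(it) {
      n_now - length(evaluate_pedigree(.remove_item(ped, it), config)$events)
    }, numeric(1))
    # when no single removal extinguishes a criterion (e.g. a cluster clause
    # with spare supporters), prefer items that at least contribute to one,
    # so unrelated history is preserved verbatim
    used_uids <- unique(unlist(lapply(report$events, `[[`, "contributing_uids")))
    used_genes <- c(B1 = "BRCA1_BRCA2", L1 = "LYNCH", P1 = "APC_MUTYH")[
      intersect(c("B1", "L1", "P1"), fulfilled_ids(report))]
    relevant <- vapply(items, function(it) {
      if (it$kind == "mutation") {
        ped$mutations[[it$dx]]$gene_group %in% used_genes
      } else {
        uid <- if (it$person == 1L) "P" else paste0("M", it$person - 1L)
        uid %in% used_uids
      }
    }, logical(1))
    age_key <- vapply(items, function(it) {
      if (is.na(it$age)) Inf else as.numeric(it$age)
    }, numeric(1))
    ord <- order(-impact, -as.numeric(relevant), age_key, seq_along(items))
    ped <- .remove_item(ped, items[[ord[1]]])
  }
}
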