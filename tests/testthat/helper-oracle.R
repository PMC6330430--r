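# Independent brute-force oracle for the criteria engine.
#
# Evaluates each printed clause literally by enumerating (index person,
# relative subset, side) combinations. It shares only the kinship label
# algebra with the engine (degree_of/lineage_of/generation_of tables and
# reroot()); all clause logic, counting and age handling is written
# independently, in exhaustive-enumeration style rather than the engine's
# incremental counting.

orc_age <- function(a) {
  switch(a$kind,
    EXACT = a$value,
    EARLY_DECADE = a$value + 2L,
    LATE_DECADE = a$value + 8L,
    DECADE = a$value + 5L,
    NA_integer_)
}

orc_persons <- function(ped) {
  all <- c(list(ped$proband), ped$members)
  lapply(seq_along(all), function(i) {
    p <- all[[i]]
    list(idx = i, label = p$relationship, sex = p$sex,
         degree = degree_of(p$relationship),
         lineage = lineage_of(p$relationship),
         polyps = p$polyp_count,
         dxs = lapply(p$diagnoses, function(d) {
           list(type = d$cancer_type, age = orc_age(d$age),
                tn = "TRIPLE_NEGATIVE" %in% d$qualifiers)
         }))
  })
}

orc_has <- function(p, types, max_age = NA, inclusive = TRUE, tn = FALSE,
                    male = FALSE) {
  if (male && p$sex != "male") return(FALSE)
  for (d in p$dxs) {
    if (!d$type %in% types) next
    if (tn && !d$tn) next
    if (is.na(max_age)) return(TRUE)
    if (is.na(d$age)) next
    if (inclusive && d$age <= max_age) return(TRUE)
    if (!inclusive && d$age < max_age) return(TRUE)
  }
  FALSE
}

orc_ov <- c("ovarian", "fallopian_tube", "primary_peritoneal")
orc_ls <- c("colorectal", "endometrial", "gastric", "ovarian", "pancreatic",
            "renal_pelvis_ureter", "cns_brain", "small_intestine",
            "sebaceous_adenoma", "sebaceous_carcinoma", "keratoacanthoma")
orc_ams <- c("colorectal", "endometrial", "small_intestine",
             "renal_pelvis_ureter")

# TRUE when some k-subset of non-index relatives (degree 1-3) satisfies
# `pred` person-wise while all sharing one side of the family.
orc_subset_exists <- function(persons, k, pred) {
  cand <- Filter(function(p) {
    p$idx != 1L && p$degree >= 1L && p$degree <= 3L && pred(p)
  }, persons)
  if (length(cand) < k) return(FALSE)
  for (cols in utils::combn(length(cand), k, simplify = FALSE)) {
    lins <- vapply(cand[cols], `[[`, character(1), "lineage")
    for (side in c("maternal", "paternal")) {
      if (all(lins %in% c(side, "both"))) return(TRUE)
    }
  }
  FALSE
}

orc_limited <- function(ped, cfg) {
  if (isTRUE(ped$family_sizes$unknown)) return(TRUE)
  counts <- c(maternal = 0, paternal = 0)
  for (m in ped$members) {
    if (m$relationship %in% c("mother", "father")) next
    lin <- lineage_of(m$relationship)
    for (side in names(counts)) {
      if (lin %in% c(side, "both")) counts[side] <- counts[side] + 1
    }
  }
  for (side in names(counts)) {
    d <- ped$family_sizes[[paste0(side, "_relatives")]]
    if (!is.null(d)) counts[side] <- max(counts[side], d)
  }
  all(counts < cfg$limited_family_min)
}

# Personal-history clauses B2-B17 with persons[[1]] as the index case.
orc_personal_brca <- function(ped, persons, cfg) {
  me <- persons[[1]]
  inc <- cfg$brca_age_inclusive
  out <- character()
  breast_any <- orc_has(me, "breast")
  breast50 <- orc_has(me, "breast", 50, inc)
  if (orc_has(me, "breast", 45, inc)) out <- c(out, "B2")
  n_breast <- sum(vapply(me$dxs, function(d) d$type == "breast", logical(1)))
  if (breast50 && n_breast >= 2L) out <- c(out, "B3")
  if (breast50) {
    if (orc_subset_exists(persons, 1, function(p) orc_has(p, "breast")))
      out <- c(out, "B4")
    if (orc_subset_exists(persons, 1, function(p) orc_has(p, "pancreatic")))
      out <- c(out, "B5")
    if (orc_subset_exists(persons, 1, function(p) orc_has(p, "prostate")))
      out <- c(out, "B6")
    if (orc_limited(ped, cfg)) out <- c(out, "B7")
  }
  if (orc_has(me, "breast", 60, inc, tn = TRUE)) out <- c(out, "B8")
  if (breast_any) {
    if (orc_subset_exists(persons, 2, function(p) {
      orc_has(p, c("breast", "pancreatic", "prostate"))
    })) out <- c(out, "B9")
    if (orc_subset_exists(persons, 1, function(p) orc_has(p, "breast", 50, inc)))
      out <- c(out, "B10")
    if (orc_subset_exists(persons, 1, function(p) orc_has(p, orc_ov)))
      out <- c(out, "B11")
    if (orc_subset_exists(persons, 1, function(p) orc_has(p, "breast", male = TRUE)))
      out <- c(out, "B12")
    if ("Ashkenazi Jewish" %in% ped$ethnicities) out <- c(out, "B13")
  }
  if (orc_has(me, orc_ov)) out <- c(out, "B14")
  if (orc_has(me, "breast", male = TRUE)) out <- c(out, "B15")
  pattern <- function() {
    orc_subset_exists(persons, 1, function(p) orc_has(p, orc_ov)) ||
      orc_subset_exists(persons, 1, function(p) orc_has(p, "breast", 50, inc)) ||
      orc_subset_exists(persons, 2, function(p) {
        orc_has(p, c("breast", "pancreatic", "prostate"))
      })
  }
  if (orc_has(me, "prostate") && pattern()) out <- c(out, "B16")
  if (orc_has(me, "pancreatic") && pattern()) out <- c(out, "B17")
  out
}

orc_tag <- function(ped) {
  for (i in seq_along(ped$members)) ped$members[[i]]$ouid <- i
  ped
}

# Degree between persons i and j (indices into the persons list, 1 =
# proband) derived through reroot(); NA when not derivable.
orc_degree_between <- function(ped, i, j) {
  if (i == j) return(0L)
  if (i == 1L) return(degree_of(ped$members[[j - 1L]]$relationship))
  if (j == 1L) return(degree_of(ped$members[[i - 1L]]$relationship))
  for (ord in list(c(i, j), c(j, i))) {
    root <- ord[1] - 1L; other <- ord[2] - 1L
    if (!degree_of(ped$members[[root]]$relationship) %in% c(1L, 2L)) next
    rp <- reroot(ped, root)
    for (m in rp$members) {
      if (identical(m$ouid, ped$members[[other]]$ouid)) {
        return(degree_of(m$relationship))
      }
    }
    return(NA_integer_)
  }
  NA_integer_
}

orc_amsterdam <- function(ped, persons) {
  aff <- Filter(function(p) orc_has(p, orc_ams), persons)
  if (length(aff) < 3L) return(FALSE)
  for (trio in utils::combn(length(aff), 3L, simplify = FALSE)) {
    t <- aff[trio]
    ok_link <- FALSE
    for (a in 1:3) {
      o <- setdiff(1:3, a)
      d1 <- orc_degree_between(ped, t[[a]]$idx, t[[o[1]]]$idx)
      d2 <- orc_degree_between(ped, t[[a]]$idx, t[[o[2]]]$idx)
      if (!is.na(d1) && !is.na(d2) && d1 == 1L && d2 == 1L) ok_link <- TRUE
    }
    if (!ok_link) next
    gens <- sort(unique(vapply(t, function(p) generation_of(p$label), integer(1))))
    if (!any(diff(gens) == 1L)) next
    if (!any(vapply(t, function(p) orc_has(p, orc_ams, 50, inclusive = FALSE),
                    logical(1)))) next
    return(TRUE)
  }
  FALSE
}

oracle_ids <- function(ped, cfg = engine_config()) {
  ped <- orc_tag(ped)
  persons <- orc_persons(ped)
  out <- character()
  genes <- vapply(ped$mutations, `[[`, character(1), "gene_group")
  if ("BRCA1_BRCA2" %in% genes) out <- c(out, "B1")
  out <- c(out, orc_personal_brca(ped, persons, cfg))

  # B18: mirror at every first-/second-degree relative with a history
  for (k in seq_along(ped$members)) {
    m <- ped$members[[k]]
    if (!degree_of(m$relationship) %in% c(1L, 2L)) next
    if (!length(m$diagnoses)) next
    rp <- reroot(ped, k)
    if (length(orc_personal_brca(rp, orc_persons(rp), cfg))) {
      out <- c(out, "B18")
      break
    }
  }

  # B19: third-degree relative with breast/ovarian plus cluster
  for (p in persons) {
    if (p$idx == 1L || p$degree != 3L) next
    if (!orc_has(p, c("breast", orc_ov))) next
    side <- p$lineage
    sup <- Filter(function(q) {
      q$idx != p$idx && (q$idx == 1L || q$lineage %in% c(side, "both")) &&
        orc_has(q, c("breast", orc_ov))
    }, persons)
    strong <- any(vapply(sup, function(q) {
      orc_has(q, orc_ov) || orc_has(q, "breast", 50, cfg$brca_age_inclusive)
    }, logical(1)))
    if (length(sup) >= 2L && strong) { out <- c(out, "B19"); break }
  }

  if ("LYNCH" %in% genes) out <- c(out, "L1")
  fdr <- Filter(function(p) p$idx != 1L && p$degree == 1L, persons)
  if (any(vapply(fdr, function(p) {
    orc_has(p, c("colorectal", "endometrial"), 50, inclusive = FALSE)
  }, logical(1)))) out <- c(out, "L2")
  if (any(vapply(fdr, function(p) {
    has_anchor <- orc_has(p, c("colorectal", "endometrial"))
    if (!has_anchor) return(FALSE)
    anchor <- which(vapply(p$dxs, function(d) {
      d$type %in% c("colorectal", "endometrial")
    }, logical(1)))[1]
    any(vapply(seq_along(p$dxs), function(j) {
      j != anchor && p$dxs[[j]]$type %in% orc_ls
    }, logical(1)))
  }, logical(1)))) out <- c(out, "L3")
  fdr_sdr_ls <- function(p) p$degree <= 2L && orc_has(p, orc_ls)
  # L4: a same-side pair with LS cancer, at least one diagnosed before 50
  cand <- Filter(function(p) p$idx != 1L && fdr_sdr_ls(p), persons)
  l4 <- FALSE
  if (length(cand) >= 2L) {
    for (pair in utils::combn(length(cand), 2L, simplify = FALSE)) {
      lins <- vapply(cand[pair], `[[`, character(1), "lineage")
      same <- any(vapply(c("maternal", "paternal"), function(s) {
        all(lins %in% c(s, "both"))
      }, logical(1)))
      young <- any(vapply(cand[pair], function(p) {
        orc_has(p, orc_ls, 50, inclusive = FALSE)
      }, logical(1)))
      if (same && young) { l4 <- TRUE; break }
    }
  }
  if (l4) out <- c(out, "L4")
  if (orc_subset_exists(persons, 3, function(p) p$degree <= 2L && orc_has(p, orc_ls)))
    out <- c(out, "L5")
  if (orc_amsterdam(ped, persons)) out <- c(out, "L6")

  if ("APC_MUTYH" %in% genes) out <- c(out, "P1")
  if (!is.na(persons[[1]]$polyps) && persons[[1]]$polyps >= cfg$polyp_threshold)
    out <- c(out, "P2")
  if (any(vapply(fdr, function(p) {
    !is.na(p$polyps) && p$polyps >= cfg$polyp_threshold
  }, logical(1)))) out <- c(out, "P3")
  sort(unique(out))
}
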