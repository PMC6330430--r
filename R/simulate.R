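# Seeded synthetic-pedigree and cohort generator.
#
# The generator emulates the validation cohort: three-generation family
# histories with the ethnicity mix, personal-history rate, cancer-type mix
# and degree-of-relation mix of the published demographic tables. Gold
# labels come from the same criteria semantics the engine implements, so
# the simulator validates plumbing; criteria correctness is validated
# separately against a brute-force oracle and hand-checked examples.

#' Simulation configuration
#'
#' Defaults approximate the validation cohort's marginal mixes: the
#' ethnicity distribution and 28% personal-history rate of the high-risk
#' demographics table, a relative-level cancer mix echoing the low-risk
#' cancer-type table (female breast, colon, lung, prostate, melanoma and
#' skin most frequent), and a motif mix echoing the criterion-fulfilment
#' margins (early breast, breast clusters and ovarian carcinoma dominate,
#' Lynch-pattern families about a tenth, known mutations and male breast
#' rare). Polyp incidence defaults to 0: the cohort contained no
#' polyposis-qualifying histories.
#'
#' @param seed Mandatory integer seed; every sampled quantity derives from it.
#' @param ethnicity_freqs Named probability vector over the intake
#'   ethnicity list.
#' @param member_cancer_prob Probability a relative carries at least one
#'   cancer diagnosis in the baseline (pre-motif) history.
#' @param proband_cancer_prob Probability the proband carries a baseline
#'   (non-motif) diagnosis.
#' @param type_weights Named sampling weights over canonical cancer types
#'   for baseline diagnoses.
#' @param age_means,age_sds Named per-type age-at-diagnosis means/sds
#'   (years); types not named use `age_default`.
#' @param age_default Fallback `c(mean, sd)`.
#' @param age_range Truncation bounds for sampled ages.
#' @param decade_mask_prob Fraction of relatives' ages re-encoded as
#'   decade/early/late-decade records, exercising the imputation path.
#' @param n_siblings_lambda,n_children_lambda,n_aunts_uncles_lambda,
#'   n_cousins_lambda Poisson means for family structure (aunts/uncles and
#'   cousins are per side).
#' @param polyp_incidence Probability a relative has a recorded polyp
#'   history.
#' @param motif_weights Named weights over the high-risk motifs
#'   `early_breast`, `breast_cluster`, `ovarian`, `male_breast`,
#'   `ashkenazi_breast`, `lynch_fdr_young`, `lynch_cluster`,
#'   `known_mutation`.
#' @param proband_affected_prob Probability a high-risk motif lands on the
#'   proband rather than a relative.
#' @param max_retries Resampling budget for the high-risk verification
#'   loop.
#' @return A list of class `hcs_sim_config`.
#' @export
sim_config <- function(
    seed,
    ethnicity_freqs = c("African American" = 0.056, "Ashkenazi Jewish" = 0.086,
                        "Asian" = 0.036, "Caucasian" = 0.736,
                        "Hispanic" = 0.046, "Native American" = 0.025,
                        "Unknown" = 0.015),
    member_cancer_prob = 0.16,
    proband_cancer_prob = 0.15,
    type_weights = c(breast = 0.123, colorectal = 0.070, lung = 0.089,
                     prostate = 0.060, melanoma = 0.055,
                     skin_unspecified = 0.068, leukemia = 0.034,
                     pancreatic = 0.037, thyroid = 0.029, cervical = 0.026,
                     gastric = 0.021, renal = 0.018, cns_brain = 0.024,
                     bladder = 0.013, lymphoma_unspecified = 0.013,
                     non_hodgkin_lymphoma = 0.016,
                     endometrial = 0.016, liver = 0.005, bone = 0.010,
                     gallbladder = 0.003, hodgkin_lymphoma = 0.003,
                     sarcoma = 0.003, other_unspecified = 0.044),
    age_means = c(breast = 62, colorectal = 66, lung = 67, prostate = 68,
                  melanoma = 58, skin_unspecified = 60, leukemia = 55,
                  pancreatic = 68, thyroid = 48, cervical = 48,
                  gastric = 67, renal = 63, cns_brain = 58, bladder = 70,
                  endometrial = 62, ovarian = 62),
    age_sds = c(breast = 11, colorectal = 11, lung = 9, prostate = 8,
                melanoma = 14, skin_unspecified = 13, leukemia = 18,
                pancreatic = 9, thyroid = 15, cervical = 13, gastric = 10,
                renal = 11, cns_brain = 16, bladder = 9, endometrial = 10,
                ovarian = 11),
    age_default = c(62, 13),
    age_range = c(20, 94),
    decade_mask_prob = 0.30,
    n_siblings_lambda = 1.0,
    n_children_lambda = 0.5,
    n_aunts_uncles_lambda = 1.5,
    n_cousins_lambda = 0.35,
    polyp_incidence = 0,
    motif_weights = c(early_breast = 0.26, breast_cluster = 0.22,
                      ovarian = 0.28, male_breast = 0.005,
                      ashkenazi_breast = 0.03, lynch_fdr_young = 0.03,
                      lynch_cluster = 0.10, known_mutation = 0.045),
    proband_affected_prob = 0.28,
    max_retries = 30L) {
  if (missing(seed)) stop("a seed is mandatory")
  tw <- type_weights[type_weights > 0]
  structure(list(
    seed = as.integer(seed),
    ethnicity_freqs = ethnicity_freqs / sum(ethnicity_freqs),
    member_cancer_prob = member_cancer_prob,
    proband_cancer_prob = proband_cancer_prob,
    type_weights = tw / sum(tw),
    age_means = age_means, age_sds = age_sds, age_default = age_default,
    age_range = age_range, decade_mask_prob = decade_mask_prob,
    n_siblings_lambda = n_siblings_lambda,
    n_children_lambda = n_children_lambda,
    n_aunts_uncles_lambda = n_aunts_uncles_lambda,
    n_cousins_lambda = n_cousins_lambda,
    polyp_incidence = polyp_incidence,
    motif_weights = motif_weights / sum(motif_weights),
    proband_affected_prob = proband_affected_prob,
    max_retries = as.integer(max_retries)), class = "hcs_sim_config")
}

.female_only <- c("ovarian", "fallopian_tube", "primary_peritoneal",
                  "cervical", "endometrial")
.male_only <- c("prostate", "testicular")

.sample_age <- function(type, config) {
  m <- config$age_means[type]; s <- config$age_sds[type]
  if (is.na(m)) { m <- config$age_default[1]; s <- config$age_default[2] }
  a <- round(stats::rnorm(1, m, s))
  min(max(a, config$age_range[1]), config$age_range[2])
}

.sample_type <- function(sex, config) {
  w <- config$type_weights
  if (sex == "female") w <- w[!names(w) %in% .male_only]
  if (sex == "male") w <- w[!names(w) %in% .female_only]
  sample(names(w), 1L, prob = w)
}

.mask_age <- function(age, config) {
  if (stats::runif(1) >= config$decade_mask_prob || age < 20) {
    return(age_record("EXACT", age))
  }
  kind <- sample(c("EARLY_DECADE", "LATE_DECADE", "DECADE"), 1L)
  age_record(kind, (age %/% 10L) * 10L)
}

.baseline_member <- function(label, sex, config) {
  dx <- list()
  if (stats::runif(1) < config$member_cancer_prob) {
    type <- .sample_type(sex, config)
    dx <- list(diagnosis(type, .mask_age(.sample_age(type, config), config)))
  }
  pc <- NA_integer_
  if (config$polyp_incidence > 0 && stats::runif(1) < config$polyp_incidence) {
    pc <- sample(1:30, 1L)
  }
  family_member(label, sex = sex, diagnoses = dx, polyp_count = pc)
}

.baseline_structure <- function(config) {
  members <- list()
  add <- function(label, sex = NULL) {
    members[[length(members) + 1L]] <<- .baseline_member(
      label, if (is.null(sex)) .label_sex(label) else sex, config)
  }
  add("mother"); add("father")
  add("maternal grandmother"); add("maternal grandfather")
  add("paternal grandmother"); add("paternal grandfather")
  for (i in seq_len(stats::rpois(1, config$n_siblings_lambda))) {
    add(sample(c("sister", "brother"), 1L))
  }
  for (i in seq_len(stats::rpois(1, config$n_children_lambda))) {
    add(sample(c("daughter", "son"), 1L))
  }
  for (side in c("maternal", "paternal")) {
    for (i in seq_len(stats::rpois(1, config$n_aunts_uncles_lambda))) {
      add(paste(side, sample(c("aunt", "uncle"), 1L)))
    }
    for (i in seq_len(stats::rpois(1, config$n_cousins_lambda))) {
      add(paste(side, "first cousin"), sample(c("female", "male"), 1L))
    }
  }
  members
}

.baseline_pedigree <- function(config, id = NULL) {
  eth <- sample(names(config$ethnicity_freqs), 1L,
                prob = config$ethnicity_freqs)
  pro_dx <- list()
  if (stats::runif(1) < config$proband_cancer_prob) {
    type <- .sample_type("female", config)
    pro_dx <- list(diagnosis(type, age_record("EXACT", .sample_age(type, config))))
  }
  pedigree(
    proband = family_member("self", sex = "female", diagnoses = pro_dx),
    members = .baseline_structure(config),
    ethnicities = eth, id = id)
}

# Declare family sizes from the realized structure (the intake tool always
# collects them): relatives beyond the parents, per side.
.with_family_sizes <- function(ped) {
  count <- function(side) {
    sum(vapply(ped$members, function(m) {
      lin <- lineage_of(m$relationship)
      (lin == side || lin == "both") &&
        !m$relationship %in% c("mother", "father")
    }, logical(1)))
  }
  ped$family_sizes <- list(maternal_relatives = count("maternal"),
                           paternal_relatives = count("paternal"))
  ped
}

# Add a diagnosis to member index i (0 = proband).
.add_dx <- function(ped, i, dx) {
  if (i == 0L) ped$proband$diagnoses <- c(ped$proband$diagnoses, list(dx))
  else ped$members[[i]]$diagnoses <- c(ped$members[[i]]$diagnoses, list(dx))
  ped
}

.pick_member <- function(ped, pred) {
  ok <- which(vapply(ped$members, pred, logical(1)))
  if (!length(ok)) return(NA_integer_)
  if (length(ok) == 1L) ok else sample(ok, 1L)
}

.ensure_member <- function(ped, label, sex = NULL) {
  m <- family_member(label, sex = sex)
  ped$members <- c(ped$members, list(m))
  list(ped = ped, idx = length(ped$members))
}

.inject_motif <- function(ped, motif, config) {
  female_fdr_sdr <- function(m) {
    m$sex == "female" && degree_of(m$relationship) <= 2L
  }
  target <- function() {
    if (stats::runif(1) < config$proband_affected_prob) return(0L)
    i <- .pick_member(ped, female_fdr_sdr)
    if (is.na(i)) 0L else i
  }
  switch(motif,
    early_breast = {
      .add_dx(ped, target(),
              diagnosis("breast", sample(28:45, 1L)))
    },
    breast_cluster = {
      side <- sample(c("maternal", "paternal"), 1L)
      on_side <- function(m) {
        m$sex == "female" && degree_of(m$relationship) <= 2L &&
          lineage_of(m$relationship) %in% c(side, "both")
      }
      i1 <- .pick_member(ped, on_side)
      if (is.na(i1)) { r <- .ensure_member(ped, paste(side, "aunt")); ped <- r$ped; i1 <- r$idx }
      r <- .ensure_member(ped, paste(side, "aunt")); ped <- r$ped; i2 <- r$idx
      ped <- .add_dx(ped, i1, diagnosis("breast", sample(38:48, 1L)))
      .add_dx(ped, i2, diagnosis("breast", sample(40:68, 1L)))
    },
    ovarian = {
      .add_dx(ped, target(), diagnosis("ovarian", sample(42:70, 1L)))
    },
    male_breast = {
      i <- .pick_member(ped, function(m) {
        m$sex == "male" && degree_of(m$relationship) <= 2L
      })
      if (is.na(i)) { r <- .ensure_member(ped, "maternal uncle"); ped <- r$ped; i <- r$idx }
      .add_dx(ped, i, diagnosis("breast", sample(45:75, 1L)))
    },
    ashkenazi_breast = {
      ped$ethnicities <- unique(c(ped$ethnicities, "Ashkenazi Jewish"))
      .add_dx(ped, target(), diagnosis("breast", sample(46:70, 1L)))
    },
    lynch_fdr_young = {
      i <- .pick_member(ped, function(m) degree_of(m$relationship) == 1L)
      if (is.na(i)) i <- 0L
      if (i == 0L) {
        .add_dx(ped, 0L, diagnosis("colorectal", sample(35:49, 1L)))
      } else {
        type <- if (ped$members[[i]]$sex == "male") "colorectal"
                else sample(c("colorectal", "endometrial"), 1L)
        .add_dx(ped, i, diagnosis(type, sample(35:49, 1L)))
      }
    },
    lynch_cluster = {
      side <- sample(c("maternal", "paternal"), 1L)
      on_side <- function(m) {
        degree_of(m$relationship) <= 2L &&
          lineage_of(m$relationship) %in% c(side, "both")
      }
      n <- sample(2:3, 1L)
      idx <- integer(0)
      for (k in seq_len(n)) {
        i <- setdiff(which(vapply(ped$members, on_side, logical(1))), idx)
        if (length(i)) i <- i[1] else {
          r <- .ensure_member(ped, paste(side, sample(c("aunt", "uncle"), 1L)))
          ped <- r$ped; i <- r$idx
        }
        idx <- c(idx, i)
        sex <- ped$members[[i]]$sex
        type <- sample(c("colorectal", "gastric",
                         if (sex == "female") "endometrial" else "small_intestine"), 1L)
        age <- if (k == 1L) sample(38:49, 1L) else sample(45:75, 1L)
        ped <- .add_dx(ped, i, diagnosis(type, age))
      }
      ped
    },
    known_mutation = {
      gene <- sample(c("BRCA1_BRCA2", "LYNCH"), 1L, prob = c(0.85, 0.15))
      carrier <- if (length(ped$members)) {
        sample(vapply(ped$members, `[[`, character(1), "relationship"), 1L)
      } else "self"
      ped$mutations <- c(ped$mutations, list(mutation_finding(gene, carrier)))
      ped
    },
    stop("unknown motif: ", motif))
}

#' Generate one synthetic pedigree
#'
#' `role = "high_risk"`: samples a baseline history, injects one sampled
#' high-risk motif, and verifies the result fulfills at least one
#' criterion (resampling within a bounded retry budget). `role =
#' "low_risk"`: samples a baseline history and applies [model_low_risk()]
#' so no criterion is fulfilled. Fully determined by `seed`.
#'
#' @param config A [sim_config()].
#' @param role `"high_risk"` or `"low_risk"`.
#' @param seed Seed for this pedigree (defaults to `config$seed`).
#' @param id Optional pedigree identifier.
#' @return A [pedigree()].
#' @export
generate_pedigree <- function(config, role = c("high_risk", "low_risk"),
                              seed = config$seed, id = NULL) {
  stopifnot(inherits(config, "hcs_sim_config"))
  role <- match.arg(role)
  set.seed(seed)
  econf <- engine_config()
  if (role == "low_risk") {
    ped <- .with_family_sizes(.baseline_pedigree(config, id = id))
    return(model_low_risk(ped, econf))
  }
  for (try in seq_len(config$max_retries)) {
    ped <- .baseline_pedigree(config, id = id)
    motif <- sample(names(config$motif_weights), 1L,
                    prob = config$motif_weights)
    ped <- .with_family_sizes(.inject_motif(ped, motif, config))
    if (evaluate_pedigree(ped, econf)$meets_any) {
      attr(ped, "motif") <- motif
      return(ped)
    }
  }
  stop("retry budget exhausted: config cannot produce a high-risk pedigree")
}

#' Generate a labelled synthetic cohort
#'
#' Generates `n_high` high-risk and `n_low` low-risk pedigrees, extracts
#' their independent events ([extract_high_risk_events()] /
#' [extract_low_risk_events()]), and attaches per-pedigree and per-event
#' gold labels from the adjudicated construction.
#'
#' @param config A [sim_config()].
#' @param n_high,n_low Pedigree counts per group.
#' @return A list of class `hcs_cohort`: `pedigrees` (named list),
#'   `labels` (data frame: `pedigree_id`, `role`), `events` (list of
#'   independent events), `event_labels` (data frame: `pedigree_id`,
#'   `kind`, `gold`), `config`.
#' @export
generate_cohort <- function(config, n_high, n_low) {
  stopifnot(inherits(config, "hcs_sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_high + n_low)
  econf <- engine_config()
  pedigrees <- list(); labels <- list(); events <- list(); ev_labels <- list()
  roles <- c(rep("high_risk", n_high), rep("low_risk", n_low))
  for (i in seq_along(roles)) {
    id <- sprintf("ped%03d", i)
    ped <- generate_pedigree(config, roles[i], seed = seeds[i], id = id)
    pedigrees[[id]] <- ped
    labels[[i]] <- data.frame(pedigree_id = id, role = roles[i],
                              stringsAsFactors = FALSE)
    evs <- if (roles[i] == "high_risk") extract_high_risk_events(ped, econf)
           else extract_low_risk_events(ped, econf)
    gold <- if (roles[i] == "high_risk") "meets" else "does-not-meet"
    for (ev in evs) {
      events[[length(events) + 1L]] <- ev
      ev_labels[[length(ev_labels) + 1L]] <- data.frame(
        pedigree_id = id, kind = ev$kind, gold = gold,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(pedigrees = pedigrees,
                 labels = do.call(rbind, labels),
                 events = events,
                 event_labels = do.call(rbind, ev_labels),
                 config = config),
            class = "hcs_cohort")
}

#' @export
print.hcs_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d pedigrees (%d high-risk, %d low-risk), %d events\n",
              nrow(x$labels), sum(x$labels$role == "high_risk"),
              sum(x$labels$role == "low_risk"), length(x$events)))
  invisible(x)
}

# Rebuild the minimal pedigree a single independent event represents, for
# one-to-one re-entry into the engine.
.event_pedigree <- function(event, source) {
  if (event$kind == "CRITERION") {
    ev <- event$payload
    uids <- ev$contributing_uids
    keep <- if (all(is.na(uids))) integer(0) else {
      idx <- suppressWarnings(as.integer(sub("^M", "", uids[uids != "P" & !is.na(uids)])))
      idx[!is.na(idx)]
    }
    pro <- source$proband
    if (!(any(is.na(uids)) || "P" %in% uids)) pro$diagnoses <- list()
    return(pedigree(proband = pro, members = source$members[keep],
                    ethnicities = source$ethnicities,
                    mutations = source$mutations,
                    family_sizes = source$family_sizes))
  }
  if (event$kind == "NO_FAMILY_HISTORY") {
    return(pedigree(ethnicities = source$ethnicities,
                    family_sizes = source$family_sizes))
  }
  singles <- if (event$kind == "SINGLE_HISTORY") list(event$payload)
             else event$payload$singles
  # one reconstructed person per original person: two diagnoses carried by
  # one relative must not become two relatives (person counts matter)
  by_person <- split(singles, vapply(singles, `[[`, integer(1), "person"))
  members <- list(); pro_dx <- list(); pro_polyps <- NA_integer_
  for (grp in by_person) {
    dxs <- list(); polyps <- NA_integer_
    for (s in grp) {
      if (s$cancer_type == "colon_polyps") polyps <- 1L
      else dxs <- c(dxs, list(diagnosis(
        s$cancer_type,
        if (is.na(s$age)) age_record("UNKNOWN") else age_record("EXACT", s$age))))
    }
    if (grp[[1]]$relationship == "self") {
      pro_dx <- dxs; pro_polyps <- polyps
    } else {
      members <- c(members, list(family_member(
        grp[[1]]$relationship, diagnoses = dxs, polyp_count = polyps)))
    }
  }
  pedigree(proband = family_member("self", sex = "female",
                                   diagnoses = pro_dx,
                                   polyp_count = pro_polyps),
           members = members, ethnicities = source$ethnicities,
           family_sizes = source$family_sizes)
}

#' Engine predictions for a cohort's independent events
#'
#' Re-enters each independent event into the engine as its own minimal
#' history -- the one-to-one entry protocol of the validation -- and
#' returns paired gold/predicted labels ready for [confusion()].
#'
#' @param cohort An `hcs_cohort` from [generate_cohort()].
#' @param config An [engine_config()].
#' @return A data frame with columns `pedigree_id`, `kind`, `gold`,
#'   `predicted`.
#' @export
predict_events <- function(cohort, config = engine_config()) {
  stopifnot(inherits(cohort, "hcs_cohort"))
  preds <- vapply(cohort$events, function(ev) {
    src <- cohort$pedigrees[[ev$pedigree_id]]
    src <- .tag_uids(src)
    p <- .event_pedigree(ev, src)
    if (evaluate_pedigree(p, config)$meets_any) "meets" else "does-not-meet"
  }, character(1))
  out <- cohort$event_labels
  out$predicted <- preds
  out
}

#' Shift exact diagnosis ages in a pedigree
#'
#' A perturbation operator for discordance injection in validation
#' experiments: adds `delta` years to the exact-age diagnoses of the
#' selected members, which can move diagnoses across the criteria's age
#' thresholds.
#'
#' @param ped A [pedigree()].
#' @param delta Years to add (may be negative).
#' @param members Indices into `ped$members`, or `0` for the proband;
#'   default all persons.
#' @return The perturbed pedigree.
#' @export
perturb_ages <- function(ped, delta, members = NULL) {
  idx <- if (is.null(members)) 0:length(ped$members) else members
  shift <- function(p) {
    p$diagnoses <- lapply(p$diagnoses, function(d) {
      if (d$age$kind == "EXACT") {
        d$age$value <- as.integer(min(max(d$age$value + delta, 0L), 120L))
      }
      d
    })
    p
  }
  for (i in idx) {
    if (i == 0L) ped$proband <- shift(ped$proband)
    else ped$members[[i]] <- shift(ped$members[[i]])
  }
  ped
}
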