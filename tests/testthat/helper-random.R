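# Random small-pedigree generator for property-style tests. Uses the
# session RNG; callers set the seed. Kept independent of the package's
# cohort simulator so engine properties are exercised on unconstrained
# structures (duplicate labels, unknown ages, odd type mixes).

rnd_type_pool <- c(breast = 0.20, ovarian = 0.06, colorectal = 0.12,
                   endometrial = 0.06, pancreatic = 0.06, prostate = 0.06,
                   lung = 0.09, cns_brain = 0.06, gastric = 0.05,
                   melanoma = 0.06, fallopian_tube = 0.02, cervical = 0.04,
                   skin_unspecified = 0.04, thyroid = 0.04,
                   other_unspecified = 0.03, small_intestine = 0.02,
                   renal = 0.03, primary_peritoneal = 0.01,
                   renal_pelvis_ureter = 0.02)

rnd_dx <- function(sex) {
  w <- rnd_type_pool
  if (sex == "female") w <- w[names(w) != "prostate"]
  if (sex == "male") {
    w <- w[!names(w) %in% c("ovarian", "fallopian_tube",
                            "primary_peritoneal", "endometrial", "cervical")]
  }
  type <- sample(names(w), 1L, prob = w)
  u <- stats::runif(1)
  age <- if (u < 0.10) {
    age_record("UNKNOWN")
  } else if (u < 0.20) {
    age_record(sample(c("EARLY_DECADE", "LATE_DECADE", "DECADE"), 1L),
               sample(3:8, 1L) * 10L)
  } else {
    age_record("EXACT", sample(25:85, 1L))
  }
  q <- character()
  if (type == "breast" && stats::runif(1) < 0.30) q <- "TRIPLE_NEGATIVE"
  diagnosis(type, age = age, qualifiers = q)
}

rnd_member <- function(label) {
  sex <- .labels_sex_cache[[label]]
  if (is.na(sex)) sex <- sample(c("female", "male"), 1L)
  n_dx <- sample(0:2, 1L, prob = c(0.45, 0.45, 0.10))
  dxs <- lapply(seq_len(n_dx), function(i) rnd_dx(sex))
  polyps <- if (stats::runif(1) < 0.05) sample(1:20, 1L) else NA_integer_
  family_member(label, sex = sex, diagnoses = dxs, polyp_count = polyps)
}

.labels_sex_cache <- local({
  tab <- relationship_labels()
  out <- as.list(tab$sex)
  names(out) <- tab$label
  out
})

rnd_unique_slots <- c("mother", "father",
                      "maternal grandmother", "maternal grandfather",
                      "paternal grandmother", "paternal grandfather",
                      "maternal great-grandmother", "maternal great-grandfather",
                      "paternal great-grandmother", "paternal great-grandfather")

random_pedigree <- function(max_members = 8L) {
  labels <- setdiff(relationship_labels()$label, "self")
  n <- sample(0:(max_members - 1L), 1L)
  picked <- character()
  while (length(picked) < n) {
    l <- sample(labels, 1L)
    if (l %in% rnd_unique_slots && l %in% picked) next
    picked <- c(picked, l)
  }
  members <- lapply(picked, rnd_member)
  pro_dx <- if (stats::runif(1) < 0.35) list(rnd_dx("female")) else list()
  pro_polyps <- if (stats::runif(1) < 0.04) sample(1:20, 1L) else NA_integer_
  mutations <- if (stats::runif(1) < 0.07) {
    carrier <- if (n > 0) sample(vapply(members, `[[`, character(1),
                                        "relationship"), 1L) else "self"
    list(mutation_finding(sample(c("BRCA1_BRCA2", "LYNCH", "APC_MUTYH"), 1L),
                          carrier))
  } else list()
  eth <- if (stats::runif(1) < 0.10) "Ashkenazi Jewish" else "Caucasian"
  pedigree(
    proband = family_member("self", sex = "female", diagnoses = pro_dx,
                            polyp_count = pro_polyps),
    members = members, ethnicities = eth, mutations = mutations)
}
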