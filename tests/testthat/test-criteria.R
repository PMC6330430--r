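test_that("empty histories meet nothing", {
  r <- evaluate_pedigree(pedigree())
  expect_false(r$meets_any)
  expect_length(r$events, 0L)
  expect_true(is.na(r$recommendation_text))
})

test_that("isolated early brain cancers do not meet criteria", {
  # the two histories the expert adjudication classed as low risk
  r1 <- evaluate_pedigree(ped_with(fm("father", dx("cns_brain", 45))))
  expect_false(r1$meets_any)
  r2 <- evaluate_pedigree(ped_with(fm("maternal uncle", dx("cns_brain", 43))))
  expect_false(r2$meets_any)
})

test_that("personal breast cancer criteria fire at the printed bounds", {
  p44 <- pedigree(proband = fm("self", dx("breast", 44), sex = "female"))
  r <- evaluate_pedigree(p44)
  expect_true(r$meets_any)
  expect_true("B2" %in% fulfilled_ids(r))
  expect_identical(r$recommendation_text,
                   "genetic screening should be considered at this time")

  # inclusive bound: diagnosed at exactly 45 qualifies
  p45 <- pedigree(proband = fm("self", dx("breast", 45), sex = "female"))
  expect_true("B2" %in% fulfilled_ids(evaluate_pedigree(p45)))
  p46 <- pedigree(proband = fm("self", dx("breast", 46), sex = "female"),
                  members = list(fm("mother"), fm("sister"), fm("brother"),
                                 fm("maternal aunt"), fm("paternal aunt")))
  expect_false("B2" %in% fulfilled_ids(evaluate_pedigree(p46)))
  # strict bounds on request
  strict <- engine_config(brca_age_inclusive = FALSE)
  expect_false("B2" %in% fulfilled_ids(evaluate_pedigree(p45, strict)))
})

test_that("two breast primaries fulfill both the early and the
           second-primary criteria", {
  p <- pedigree(proband = fm("self", dx("breast", 41), dx("breast", 48, idx = 2L),
                             sex = "female"),
                members = list(fm("mother"), fm("sister"), fm("brother"),
                               fm("maternal aunt"), fm("paternal aunt")))
  ids <- fulfilled_ids(evaluate_pedigree(p))
  expect_true(all(c("B2", "B3") %in% ids))
})

test_that("Ashkenazi ethnicity plus breast cancer fires the ethnicity
           criterion", {
  p <- pedigree(proband = fm("self", dx("breast", 65), sex = "female"),
                members = list(fm("mother"), fm("sister"), fm("maternal aunt"),
                               fm("paternal aunt")),
                ethnicities = c("Ashkenazi Jewish"))
  expect_true("B13" %in% fulfilled_ids(evaluate_pedigree(p)))
})

test_that("family-history-only ovarian cancer mirrors through a relative", {
  p <- ped_with(fm("mother", dx("ovarian", 62)))
  r <- evaluate_pedigree(p)
  expect_true(r$meets_any)
  b18 <- Filter(function(e) e$criterion_id == "B18", r$events)
  expect_gt(length(b18), 0L)
  expect_identical(b18[[1]]$mirrored_criterion, "B14")
  expect_identical(b18[[1]]$index_person, "mother")
})

test_that("the mirror is consistent with explicit re-rooting", {
  set.seed(303)
  checked <- 0L
  for (rep in 1:40) {
    p <- random_pedigree()
    r <- evaluate_pedigree(p)
    fired <- any(vapply(r$events, function(e) e$criterion_id == "B18",
                        logical(1)))
    manual <- FALSE
    for (i in seq_along(p$members)) {
      m <- p$members[[i]]
      if (!degree_of(m$relationship) %in% c(1L, 2L)) next
      if (!length(m$diagnoses)) next
      sub <- evaluate_brca(reroot(p, i))
      if (any(vapply(sub, function(e) {
        e$criterion_id %in% paste0("B", 2:17) && e$index_person == "self"
      }, logical(1)))) manual <- TRUE
    }
    expect_identical(fired, manual)
    checked <- checked + 1L
  }
  expect_gte(checked, 40L)
})

test_that("a breast-only history never satisfies Lynch criteria and
           melanoma satisfies nothing", {
  p <- pedigree(proband = fm("self", dx("melanoma", 40), sex = "female"),
                members = list(fm("mother"), fm("sister")))
  expect_length(fulfilled_ids(evaluate_pedigree(p)), 0L)
})

test_that("Lynch first-degree-relative clauses fire as printed", {
  expect_true("L2" %in% fulfilled_ids(evaluate_pedigree(
    ped_with(fm("mother", dx("colorectal", 48))))))
  # diagnosed at exactly 50: the bound is strict
  expect_false("L2" %in% fulfilled_ids(evaluate_pedigree(
    ped_with(fm("mother", dx("colorectal", 50))))))
  # a lone affected second-degree relative is not enough
  expect_length(fulfilled_ids(evaluate_pedigree(
    ped_with(fm("maternal aunt", dx("colorectal", 45))))), 0L)
  # L3: same relative with colorectal plus a second LS-related primary
  expect_true("L3" %in% fulfilled_ids(evaluate_pedigree(
    ped_with(fm("mother", dx("colorectal", 55),
                dx("endometrial", 58, q = "METACHRONOUS"))))))
})

test_that("Lynch cluster clauses count same-side relatives", {
  p <- ped_with(
    fm("maternal grandmother", dx("gastric", 55)),
    fm("maternal uncle", dx("colorectal", 62)),
    fm("mother", dx("endometrial", 60)))
  ids <- fulfilled_ids(evaluate_pedigree(p))
  expect_true("L5" %in% ids)
  expect_false("L4" %in% ids)  # nobody diagnosed before 50

  p2 <- ped_with(
    fm("maternal aunt", dx("colorectal", 45)),
    fm("maternal grandfather", dx("gastric", 70)))
  expect_true("L4" %in% fulfilled_ids(evaluate_pedigree(p2)))
  # the two relatives must share a side
  p3 <- ped_with(
    fm("maternal aunt", dx("colorectal", 45)),
    fm("paternal uncle", dx("gastric", 70)))
  expect_false("L4" %in% fulfilled_ids(evaluate_pedigree(p3)))
})

test_that("Amsterdam II requires linkage, succession, and an early
           diagnosis", {
  base <- list(
    fm("mother", dx("colorectal", 49)),
    fm("maternal grandfather", dx("colorectal", 60)))
  p <- pedigree(proband = fm("self", dx("endometrial", 55), sex = "female"),
                members = base)
  a <- meets_amsterdam_ii(p)
  expect_true(a$meets)
  expect_setequal(a$members, c("self", "mother", "maternal grandfather"))
  expect_true("L6" %in% fulfilled_ids(evaluate_pedigree(p)))

  # all in one generation: the successive-generations clause fails
  p2 <- ped_with(
    fm("mother", dx("colorectal", 45)),
    fm("maternal aunt", dx("colorectal", 52)),
    fm("maternal uncle", dx("endometrial", 60), sex = NULL))
  expect_false(meets_amsterdam_ii(p2)$meets)

  # no diagnosis before 50
  p3 <- pedigree(proband = fm("self", dx("endometrial", 55), sex = "female"),
                 members = list(fm("mother", dx("colorectal", 52)),
                                fm("maternal grandfather", dx("colorectal", 60))))
  expect_false(meets_amsterdam_ii(p3)$meets)

  expect_false(meets_amsterdam_ii(pedigree())$meets)
})

test_that("known-mutation criteria fire on any blood relative", {
  expect_true("B1" %in% fulfilled_ids(evaluate_pedigree(pedigree(
    mutations = list(mutation_finding("BRCA1_BRCA2", "maternal aunt"))))))
  expect_true("L1" %in% fulfilled_ids(evaluate_pedigree(pedigree(
    mutations = list(mutation_finding("LYNCH", "self"))))))
  expect_true("P1" %in% fulfilled_ids(evaluate_pedigree(pedigree(
    mutations = list(mutation_finding("APC_MUTYH", "father"))))))
})

test_that("polyposis count rules respect the configured threshold", {
  p0 <- pedigree(proband = family_member("self", sex = "female",
                                         polyp_count = 0L))
  expect_length(fulfilled_ids(evaluate_pedigree(p0)), 0L)
  p15 <- pedigree(proband = family_member("self", sex = "female",
                                          polyp_count = 15L))
  expect_true("P2" %in% fulfilled_ids(evaluate_pedigree(p15)))
  expect_false("P2" %in% fulfilled_ids(
    evaluate_pedigree(p15, engine_config(polyp_threshold = 20L))))
  pf <- ped_with(fm("father", polyps = 12L))
  expect_true("P3" %in% fulfilled_ids(evaluate_pedigree(pf)))
  # second-degree polyp counts do not fire the first-degree rule
  pa <- ped_with(fm("maternal aunt", polyps = 12L))
  expect_false("P3" %in% fulfilled_ids(evaluate_pedigree(pa)))
})

test_that("unknown ages satisfy only any-age clauses", {
  # ovarian at any age qualifies even with unknown age
  p <- ped_with(fm("mother", dx("ovarian")))
  expect_true(evaluate_pedigree(p)$meets_any)
  # colorectal before 50 does not fire on an unknown age
  p2 <- ped_with(fm("mother", dx("colorectal")))
  expect_false("L2" %in% fulfilled_ids(evaluate_pedigree(p2)))
})

test_that("criterion events are self-certifying", {
  set.seed(404)
  tested <- 0L
  for (rep in 1:60) {
    p <- random_pedigree()
    if (!evaluate_pedigree(p)$meets_any) next
    p$id <- "x"
    evs <- extract_high_risk_events(p)
    src <- hcscreen:::.tag_uids(p)
    for (ev in evs) {
      sub <- hcscreen:::.event_pedigree(ev, src)
      expect_true(evaluate_pedigree(sub)$meets_any)
      tested <- tested + 1L
    }
    if (tested > 30L) break
  }
  expect_gt(tested, 10L)
})

test_that("the registry enumerates unique, well-formed identifiers", {
  reg <- criteria_registry()
  expect_false(any(duplicated(reg$id)))
  expect_setequal(unique(reg$syndrome), c("BRCA", "LYNCH", "POLYPOSIS"))
  expect_identical(sum(reg$syndrome == "BRCA"), 19L)
  expect_identical(sum(reg$syndrome == "LYNCH"), 6L)
  expect_identical(sum(reg$syndrome == "POLYPOSIS"), 3L)
})

test_that("evaluation is pure and deterministic", {
  p <- ped_with(fm("mother", dx("ovarian", 62)), fm("father", dx("lung", 70)))
  before <- p
  r1 <- evaluate_pedigree(p)
  r2 <- evaluate_pedigree(p)
  expect_identical(p, before)
  expect_identical(fulfilled_ids(r1), fulfilled_ids(r2))
})
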