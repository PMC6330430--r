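test_that("high-risk extraction yields one event per fulfilled criterion", {
  p <- pedigree(proband = fm("self", dx("breast", 44), sex = "female"),
                members = list(fm("mother", dx("ovarian", 60)),
                               fm("sister"), fm("brother"),
                               fm("maternal aunt"), fm("paternal aunt")),
                id = "hr1")
  ids <- fulfilled_ids(evaluate_pedigree(p))
  expect_true(all(c("B2", "B11") %in% ids))
  evs <- extract_high_risk_events(p)
  expect_gte(length(evs), 2L)
  expect_true(all(vapply(evs, `[[`, character(1), "kind") == "CRITERION"))
  expect_true(all(vapply(evs, `[[`, character(1), "pedigree_id") == "hr1"))

  single <- pedigree(proband = fm("self", dx("ovarian", 55), sex = "female"),
                     members = list(fm("mother"), fm("sister"), fm("brother"),
                                    fm("maternal aunt"), fm("paternal aunt")))
  evs2 <- extract_high_risk_events(single)
  expect_length(evs2, 1L)
  expect_identical(evs2[[1]]$payload$criterion_id, "B14")

  expect_error(extract_high_risk_events(pedigree()), "low-risk")
})

test_that("mirror events deduplicate by mirrored criterion", {
  # two relatives each mirroring the ovarian criterion: one event
  p <- ped_with(fm("mother", dx("ovarian", 62)),
                fm("maternal aunt", dx("ovarian", 64)))
  evs <- extract_high_risk_events(p)
  keys <- vapply(evs, function(e) {
    paste(e$payload$criterion_id, e$payload$mirrored_criterion)
  }, character(1))
  expect_false(any(duplicated(keys)))
  expect_identical(sum(vapply(evs, function(e) {
    e$payload$criterion_id == "B18" && e$payload$mirrored_criterion == "B14"
  }, logical(1))), 1L)
})

test_that("low-risk extraction yields singles, combinations, and
           no-family-history events", {
  p <- ped_with(fm("maternal aunt", dx("lung", 60)),
                fm("maternal grandfather", dx("colorectal", 65)))
  evs <- extract_low_risk_events(p)
  kinds <- vapply(evs, `[[`, character(1), "kind")
  expect_identical(sum(kinds == "SINGLE_HISTORY"), 2L)
  expect_identical(sum(kinds == "COMBINATION"), 1L)
  combo <- evs[[which(kinds == "COMBINATION")]]
  expect_identical(combo$payload$side, "maternal")
  expect_length(combo$payload$singles, 2L)

  expect_length(extract_low_risk_events(ped_with(fm("father", dx("bladder", 70)))), 1L)

  empty <- extract_low_risk_events(pedigree())
  expect_length(empty, 1L)
  expect_identical(empty[[1]]$kind, "NO_FAMILY_HISTORY")

  high <- pedigree(proband = fm("self", dx("breast", 40), sex = "female"))
  expect_error(extract_low_risk_events(high), "high-risk")
})

test_that("per-pair combination mode enumerates pairs", {
  p <- ped_with(fm("maternal aunt", dx("lung", 60)),
                fm("maternal uncle", dx("bladder", 70)),
                fm("maternal grandfather", dx("colorectal", 65)))
  per_side <- extract_low_risk_events(p, engine_config())
  expect_identical(sum(vapply(per_side, `[[`, character(1), "kind") ==
                         "COMBINATION"), 1L)
  per_pair <- extract_low_risk_events(
    p, engine_config(combination_mode = "per_pair"))
  expect_identical(sum(vapply(per_pair, `[[`, character(1), "kind") ==
                         "COMBINATION"), 3L)
})

test_that("both-lineage histories join either side's combination", {
  p <- ped_with(fm("sister", dx("thyroid", 40)),
                fm("paternal uncle", dx("lung", 66)))
  evs <- extract_low_risk_events(p)
  kinds <- vapply(evs, `[[`, character(1), "kind")
  combo <- evs[kinds == "COMBINATION"]
  expect_length(combo, 1L)
  expect_identical(combo[[1]]$payload$side, "paternal")
})

test_that("low-risk modeling removes qualifying events and keeps the rest", {
  p <- ped_with(fm("mother", dx("ovarian", 52)),
                fm("maternal grandfather", dx("lung", 60)))
  expect_true(evaluate_pedigree(p)$meets_any)
  low <- model_low_risk(p)
  expect_false(evaluate_pedigree(low)$meets_any)
  remaining <- unlist(lapply(low$members, function(m) {
    vapply(m$diagnoses, function(d) d$cancer_type, character(1))
  }))
  expect_identical(remaining, "lung")

  # a sole qualifying personal history leaves an empty-history pedigree
  p2 <- pedigree(proband = fm("self", dx("breast", 44), sex = "female"))
  low2 <- model_low_risk(p2)
  expect_length(low2$proband$diagnoses, 0L)
  expect_length(extract_low_risk_events(low2), 1L)
  expect_identical(extract_low_risk_events(low2)[[1]]$kind,
                   "NO_FAMILY_HISTORY")
})

test_that("low-risk modeling is idempotent and always ends low-risk", {
  set.seed(505)
  n_checked <- 0L
  for (rep in 1:40) {
    p <- random_pedigree()
    low <- model_low_risk(p)
    expect_false(evaluate_pedigree(low)$meets_any)
    expect_identical(model_low_risk(low), low)
    n_checked <- n_checked + 1L
  }
  expect_identical(n_checked, 40L)
})

test_that("low-risk payloads entered alone never evaluate high-risk", {
  set.seed(606)
  tested <- 0L
  for (rep in 1:50) {
    p <- model_low_risk(random_pedigree())
    p$id <- "lr"
    src <- hcscreen:::.tag_uids(p)
    for (ev in extract_low_risk_events(p)) {
      sub <- hcscreen:::.event_pedigree(ev, src)
      expect_false(evaluate_pedigree(sub)$meets_any)
      tested <- tested + 1L
    }
  }
  expect_gt(tested, 50L)
})

test_that("event extraction round-trips high/low membership", {
  set.seed(707)
  for (rep in 1:30) {
    p <- random_pedigree()
    meets <- evaluate_pedigree(p)$meets_any
    if (meets) {
      expect_gte(length(extract_high_risk_events(p)), 1L)
    } else {
      expect_error(extract_high_risk_events(p), "low-risk")
    }
  }
})
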