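test_that("labels map to standard consanguinity degrees", {
  expect_identical(degree_of("self"), 0L)
  expect_identical(degree_of(c("mother", "sister", "daughter")), c(1L, 1L, 1L))
  expect_identical(
    degree_of(c("maternal aunt", "paternal grandfather", "niece",
                "maternal half-sister", "grandson")),
    c(2L, 2L, 2L, 2L, 2L))
  expect_identical(
    degree_of(c("paternal first cousin", "maternal great-grandmother",
                "paternal great-uncle")),
    c(3L, 3L, 3L))
  expect_error(degree_of("stepfather"), "stepfather")
})

test_that("lineage maps sides, with shared-bloodline kin on both", {
  expect_identical(lineage_of("maternal grandmother"), "maternal")
  expect_identical(lineage_of("paternal uncle"), "paternal")
  expect_identical(lineage_of(c("sister", "son", "granddaughter", "nephew")),
                   rep("both", 4))
  expect_identical(lineage_of("maternal half-sister"), "maternal")
  expect_identical(lineage_of("self"), "self")
  expect_error(lineage_of("cousin"), "cousin")
})

test_that("kinship maps are total and mutually consistent", {
  tab <- relationship_labels()
  expect_true(all(tab$degree %in% 0:3))
  expect_true(all(tab$lineage %in% c("maternal", "paternal", "both", "self")))
  # generation offset magnitude never exceeds the degree
  expect_true(all(abs(tab$generation) <= pmax(tab$degree, 0L)))
  expect_identical(generation_of(c("self", "mother", "maternal grandmother",
                                   "daughter", "granddaughter", "niece")),
                   c(0L, 1L, 2L, -1L, -2L, -1L))
})

test_that("close blood relatives filter degree 1-3 on one side", {
  p <- ped_with(fm("mother"), fm("paternal uncle"))
  expect_identical(
    vapply(close_blood_relatives(p, "maternal"), `[[`, character(1),
           "relationship"),
    "mother")
  # "both"-lineage members appear on either side
  p2 <- ped_with(fm("sister"))
  expect_identical(
    vapply(close_blood_relatives(p2, "paternal"), `[[`, character(1),
           "relationship"),
    "sister")
})

test_that("close_blood_relatives equals a brute-force filter and the two
           sides cover all non-proband members", {
  set.seed(101)
  for (rep in 1:25) {
    p <- random_pedigree()
    for (side in c("maternal", "paternal")) {
      got <- vapply(close_blood_relatives(p, side), `[[`, character(1),
                    "relationship")
      want <- vapply(Filter(function(m) {
        d <- degree_of(m$relationship)
        l <- lineage_of(m$relationship)
        d >= 1 && d <= 3 && (l == side || l == "both")
      }, p$members), `[[`, character(1), "relationship")
      expect_identical(got, want)
    }
    all_labels <- vapply(p$members, `[[`, character(1), "relationship")
    covered <- c(
      vapply(close_blood_relatives(p, "maternal"), `[[`, character(1),
             "relationship"),
      vapply(close_blood_relatives(p, "paternal"), `[[`, character(1),
             "relationship"))
    expect_setequal(covered, all_labels)
  }
})

test_that("re-rooting follows the kinship arithmetic", {
  p <- ped_with(
    fm("mother"),
    fm("maternal grandmother"),
    fm("maternal aunt"),
    fm("sister"),
    fm("paternal uncle"))
  r <- reroot(p, "mother")
  labs <- vapply(r$members, `[[`, character(1), "relationship")
  # grandmother (SDR of proband) becomes the root's mother (FDR)
  expect_true("mother" %in% labs)
  # the original proband becomes a daughter of the root
  expect_true("daughter" %in% labs)
  # mother's sister stays a full sibling
  expect_true("sister" %in% labs)
  # the paternal uncle is not a blood relative of the mother
  expect_false(any(grepl("uncle", labs)))

  r2 <- reroot(p, "maternal aunt")
  labs2 <- vapply(r2$members, `[[`, character(1), "relationship")
  expect_false(any(grepl("uncle", labs2)))
  expect_true("niece" %in% labs2)  # the proband, via her mother

  expect_error(reroot(ped_with(fm("maternal first cousin")), 1),
               "first- or second-degree")
})

test_that("re-rooted degrees satisfy the triangle inequality", {
  set.seed(202)
  checked <- 0L
  for (rep in 1:40) {
    p <- random_pedigree()
    for (i in seq_along(p$members)) {
      d_root <- degree_of(p$members[[i]]$relationship)
      if (!d_root %in% c(1L, 2L)) next
      p_tag <- p
      for (k in seq_along(p_tag$members)) p_tag$members[[k]]$tag <- k
      r <- reroot(p_tag, i)
      for (m in r$members) {
        if (is.null(m$tag)) next   # the original proband carries no tag
        d_old <- degree_of(p$members[[m$tag]]$relationship)
        d_new <- degree_of(m$relationship)
        expect_lte(abs(d_new - d_old), d_root)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 100L)
})

test_that("sex must be consistent with sexed labels", {
  expect_error(family_member("mother", sex = "male"), "contradicts")
  expect_silent(family_member("maternal first cousin", sex = "male"))
  # male members may carry breast cancer
  expect_silent(fm("brother", dx("breast", 52)))
})

test_that("duplicate unique lineal positions are rejected", {
  expect_error(ped_with(fm("mother"), fm("mother")), "duplicate")
  expect_silent(ped_with(fm("maternal aunt"), fm("maternal aunt")))
})
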