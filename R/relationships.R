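# Controlled kinship vocabulary and table-driven kinship algebra.
#
# Every relative in a three-generation history is identified by a controlled
# relationship label relative to the proband, not by an explicit pedigree
# graph: the label determines the consanguinity degree, the lineage (side of
# the family) and the generation offset that the screening criteria consume.
# Coordinates (up, down, half) encode the genealogical path: `up` generations
# from the proband to the closest common ancestral couple, `down` generations
# from that couple to the relative; `half` marks a single shared ancestor
# (half-siblings).

.kinship_row <- function(label, sex, degree, lineage, generation, up, down,
                         half = FALSE) {
  data.frame(label = label, sex = sex, degree = degree, lineage = lineage,
             generation = generation, up = up, down = down, half = half,
             stringsAsFactors = FALSE)
}

.build_kinship_table <- function() {
  rows <- list(
    .kinship_row("self",                      NA,       0L, "self",     0L, 0L, 0L),
    .kinship_row("mother",                    "female", 1L, "maternal", 1L, 1L, 0L),
    .kinship_row("father",                    "male",   1L, "paternal", 1L, 1L, 0L),
    .kinship_row("sister",                    "female", 1L, "both",     0L, 1L, 1L),
    .kinship_row("brother",                   "male",   1L, "both",     0L, 1L, 1L),
    .kinship_row("daughter",                  "female", 1L, "both",    -1L, 0L, 1L),
    .kinship_row("son",                       "male",   1L, "both",    -1L, 0L, 1L),
    .kinship_row("maternal grandmother",      "female", 2L, "maternal", 2L, 2L, 0L),
    .kinship_row("maternal grandfather",      "male",   2L, "maternal", 2L, 2L, 0L),
    .kinship_row("paternal grandmother",      "female", 2L, "paternal", 2L, 2L, 0L),
    .kinship_row("paternal grandfather",      "male",   2L, "paternal", 2L, 2L, 0L),
    .kinship_row("maternal aunt",             "female", 2L, "maternal", 1L, 2L, 1L),
    .kinship_row("maternal uncle",            "male",   2L, "maternal", 1L, 2L, 1L),
    .kinship_row("paternal aunt",             "female", 2L, "paternal", 1L, 2L, 1L),
    .kinship_row("paternal uncle",            "male",   2L, "paternal", 1L, 2L, 1L),
    .kinship_row("niece",                     "female", 2L, "both",    -1L, 1L, 2L),
    .kinship_row("nephew",                    "male",   2L, "both",    -1L, 1L, 2L),
    .kinship_row("granddaughter",             "female", 2L, "both",    -2L, 0L, 2L),
    .kinship_row("grandson",                  "male",   2L, "both",    -2L, 0L, 2L),
    .kinship_row("maternal half-sister",      "female", 2L, "maternal", 0L, 1L, 1L, TRUE),
    .kinship_row("maternal half-brother",     "male",   2L, "maternal", 0L, 1L, 1L, TRUE),
    .kinship_row("paternal half-sister",      "female", 2L, "paternal", 0L, 1L, 1L, TRUE),
    .kinship_row("paternal half-brother",     "male",   2L, "paternal", 0L, 1L, 1L, TRUE),
    .kinship_row("maternal first cousin",     NA,       3L, "maternal", 0L, 2L, 2L),
    .kinship_row("paternal first cousin",     NA,       3L, "paternal", 0L, 2L, 2L),
    .kinship_row("maternal great-grandmother","female", 3L, "maternal", 3L, 3L, 0L),
    .kinship_row("maternal great-grandfather","male",   3L, "maternal", 3L, 3L, 0L),
    .kinship_row("paternal great-grandmother","female", 3L, "paternal", 3L, 3L, 0L),
    .kinship_row("paternal great-grandfather","male",   3L, "paternal", 3L, 3L, 0L),
    .kinship_row("maternal great-aunt",       "female", 3L, "maternal", 2L, 3L, 1L),
    .kinship_row("maternal great-uncle",      "male",   3L, "maternal", 2L, 3L, 1L),
    .kinship_row("paternal great-aunt",       "female", 3L, "paternal", 2L, 3L, 1L),
    .kinship_row("paternal great-uncle",      "male",   3L, "paternal", 2L, 3L, 1L)
  )
  do.call(rbind, rows)
}

.kinship <- .build_kinship_table()

.kin_lookup <- function(label) {
  i <- match(label, .kinship$label)
  if (any(is.na(i))) {
    bad <- unique(label[is.na(i)])
    stop("unknown relationship label: ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  .kinship[i, , drop = FALSE]
}

#' Controlled relationship labels
#'
#' The closed vocabulary of kinship terms (relative to the proband) that the
#' pedigree model accepts. Each label maps to exactly one consanguinity
#' degree in 0--3, one lineage in maternal/paternal/both/self, and one
#' generation offset (proband = 0, parents = +1, children = -1).
#'
#' @return A data frame with columns `label`, `sex` (sex implied by the
#'   label, `NA` when unsexed), `degree`, `lineage`, and `generation`.
#' @examples
#' head(relationship_labels())
#' @export
relationship_labels <- function() {
  .kinship[, c("label", "sex", "degree", "lineage", "generation")]
}

#' Kinship quantities of a relationship label
#'
#' `degree_of()` returns the standard consanguinity degree (self = 0,
#' parent/sibling/child = 1, grandparent/aunt/uncle/half-sibling/niece/
#' nephew/grandchild = 2, great-grandparent/great-aunt/first cousin = 3).
#' `lineage_of()` returns the side of the family: full siblings, children
#' and grandchildren share both parental bloodlines and map to `"both"`.
#' `generation_of()` returns the generation offset from the proband.
#'
#' @param relationship Character vector of controlled relationship labels
#'   (see [relationship_labels()]).
#' @return An integer vector (`degree_of`, `generation_of`) or character
#'   vector (`lineage_of`) of the same length.
#' @examples
#' degree_of(c("mother", "maternal aunt", "paternal first cousin"))
#' lineage_of(c("maternal grandmother", "sister", "maternal half-sister"))
#' @export
degree_of <- function(relationship) {
  .kin_lookup(relationship)$degree
}

#' @rdname degree_of
#' @export
lineage_of <- function(relationship) {
  .kin_lookup(relationship)$lineage
}

#' @rdname degree_of
#' @export
generation_of <- function(relationship) {
  .kin_lookup(relationship)$generation
}

# Sex implied by a label ("female"/"male"/NA).
.label_sex <- function(relationship) {
  .kin_lookup(relationship)$sex
}

# Map path coordinates back to a controlled label, or NA when the position
# is not representable in a three-generation history. `side` is required for
# labels that carry a side tag; `sex` selects the gendered variant.
.coords_to_label <- function(up, down, side, half, sex) {
  if (is.na(sex) || !sex %in% c("female", "male")) sex <- "female"
  f <- sex == "female"
  pick <- function(fl, ml) if (f) fl else ml
  sided <- function(stub) {
    if (!side %in% c("maternal", "paternal")) return(NA_character_)
    paste(side, stub)
  }
  if (half) {
    if (up == 1L && down == 1L) return(sided(pick("half-sister", "half-brother")))
    return(NA_character_)  # other half-relations fall outside the vocabulary
  }
  key <- paste(up, down)
  switch(key,
    "0 0" = "self",
    "1 0" = pick("mother", "father"),
    "1 1" = pick("sister", "brother"),
    "0 1" = pick("daughter", "son"),
    "2 0" = sided(pick("grandmother", "grandfather")),
    "2 1" = sided(pick("aunt", "uncle")),
    "1 2" = pick("niece", "nephew"),
    "0 2" = pick("granddaughter", "grandson"),
    "2 2" = sided("first cousin"),
    "3 0" = sided(pick("great-grandmother", "great-grandfather")),
    "3 1" = sided(pick("great-aunt", "great-uncle")),
    NA_character_
  )
}

# Relationship of `member` to a new root, both given as labels relative to
# the original proband. Returns a controlled label or NA when the member is
# not a blood relative of the root or the position is not representable.
#
# Conventions (see the package vignette): when a collateral relative could
# connect either through the root or through another relative (a niece
# relative to a sibling root, a first cousin relative to an aunt root), the
# interpretation NOT passing through the root is used, which yields the more
# distant, conservative relationship. After re-rooting, side tags act as
# bloodline identifiers: original side tags are preserved where the
# bloodlines survive, deeper same-side ancestors are routed through the
# root's own line, and "both"-lineage members forced to one side are tagged
# maternal.
.reroot_label <- function(root, member, proband_sex = "female",
                          member_sex = NA_character_) {
  r <- .kin_lookup(root)
  if (!r$degree %in% c(1L, 2L)) {
    stop("re-rooting is only defined at first- or second-degree relatives; ",
         sQuote(root), " has degree ", r$degree, call. = FALSE)
  }
  m <- .kin_lookup(member)
  sex <- if (!is.na(member_sex) && member_sex %in% c("female", "male")) {
    member_sex
  } else if (member == "self") proband_sex else m$sex
  mu <- m$up; md <- m$down; ms <- m$lineage; mh <- m$half
  rs <- r$lineage
  out <- NULL  # list(up, down, side, half)

  same_side <- function() ms == rs || ms == "both"

  if (r$up == 1L && r$down == 0L) {              # root is a parent
    if (member == "self") out <- list(0L, 1L, NA, FALSE)
    else if (mu == 0L) out <- list(0L, md + 1L, NA, FALSE)
    else if (same_side()) {
      # connecting through the parent: one generation closer; a half-sibling
      # sharing this parent becomes the parent's full child
      out <- list(mu - 1L, md, "maternal", FALSE)
    }
  } else if (r$up == 1L && r$down == 1L && !r$half) { # root is a full sibling
    if (member == "self") out <- list(1L, 1L, NA, FALSE)
    else if (mu == 0L) out <- list(1L, md + 1L, NA, FALSE)
    else out <- list(mu, md, ms, mh)             # shared parents: unchanged
  } else if (r$up == 0L && r$down == 1L) {       # root is a child
    if (member == "self") out <- list(1L, 0L, NA, FALSE)
    else if (mu == 0L) {
      # other descendants of the proband: a second child is treated as a
      # full sibling of the root; a grandchild as another child's child
      if (md == 1L) out <- list(1L, 1L, NA, FALSE)
      else out <- list(1L, md, NA, FALSE)
    } else if (!mh) out <- list(mu + 1L, md, ms, FALSE)
  } else if (r$up == 2L && r$down == 0L) {       # root is a grandparent
    if (ms == rs && mu >= 2L) {
      if (m$up == 2L && m$down == 0L) out <- NULL       # the other grandparent: spouse
      else out <- list(mu - 2L, md, "maternal", FALSE)
    } else if ((same_side() || member == "self") && mu < 2L) {
      out <- list(0L, md + (2L - mu), NA, FALSE)
    }
  } else if (r$up == 2L && r$down == 1L) {       # root is an aunt/uncle
    if (ms == rs && mu >= 2L) out <- list(mu - 1L, md, "maternal", FALSE)
    else if ((same_side() || member == "self") && mu < 2L) {
      out <- list(1L, md + (2L - mu), NA, FALSE)
    }
  } else if (r$half) {                           # root is a half-sibling
    shared_parent_side <- rs                     # side tag names the shared parent
    if (member == "self") out <- list(1L, 1L, shared_parent_side, TRUE)
    else if (mu == 1L && md == 1L && !mh && ms == "both") {
      out <- list(1L, 1L, shared_parent_side, TRUE)  # full siblings of proband
    } else if (mh && ms == rs) out <- list(1L, 1L, shared_parent_side, TRUE)
    else if (ms == rs && mu >= 1L && !(mu == 1L && md >= 1L)) {
      out <- list(mu, md, ms, FALSE)             # shared parent and their side
    }
  } else if (r$up == 1L && r$down == 2L) {       # root is a niece/nephew
    if (member == "self") out <- list(2L, 1L, "maternal", FALSE)
    else if (mu == 0L) out <- list(2L, md + 1L, "maternal", FALSE)
    else if (!mh) {
      side <- if (ms == "both") "maternal" else ms
      out <- list(mu + 1L, md, side, FALSE)
    }
  } else if (r$up == 0L && r$down == 2L) {       # root is a grandchild
    if (member == "self") out <- list(2L, 0L, "maternal", FALSE)
    else if (mu == 0L) out <- list(2L, md, "maternal", FALSE)
    else if (!mh) {
      side <- if (ms == "both") "maternal" else ms
      out <- list(mu + 2L, md, side, FALSE)
    }
  }

  if (is.null(out)) return(NA_character_)
  side <- out[[3]]
  if (is.na(side) || is.null(side)) side <- "maternal"
  .coords_to_label(out[[1]], out[[2]], side, out[[4]], sex)
}

# Consanguinity degree between two labels (both relative to the proband), or
# NA when not derivable from the label algebra. Used by the Amsterdam II
# first-degree-linkage clause.
.degree_between <- function(a, b) {
  if (a == "self") return(degree_of(b))
  if (b == "self") return(degree_of(a))
  da <- degree_of(a); db <- degree_of(b)
  root <- NULL; other <- NULL
  if (da <= 2L) { root <- a; other <- b } else if (db <= 2L) { root <- b; other <- a }
  if (is.null(root)) return(NA_integer_)
  lbl <- .reroot_label(root, other)
  if (is.na(lbl)) return(NA_integer_)
  degree_of(lbl)
}
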