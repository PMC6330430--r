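# Canonical cancer-type vocabulary and synonym normalization.
#
# The intake tool records 36 named cancer types; anything else is recorded
# as "other / unspecified", never rejected. The canonical identifier set
# shipped here is a reconstruction assembled from the types the validation
# cohort exercised, the ovarian-equivalent set, and the Lynch-syndrome-
# related set, padded with common referral types; it is extensible at run
# time via `extra` synonyms.

.canonical_types <- c(
  "bladder", "bone", "breast", "cervical", "cns_brain", "colorectal",
  "endometrial", "esophageal", "fallopian_tube", "gallbladder", "gastric",
  "head_neck", "hodgkin_lymphoma", "keratoacanthoma", "leukemia", "liver",
  "lung", "lymphoma_unspecified", "melanoma", "multiple_myeloma",
  "neuroendocrine", "non_hodgkin_lymphoma", "ovarian", "pancreatic",
  "primary_peritoneal", "prostate", "renal", "renal_pelvis_ureter",
  "sarcoma", "sebaceous_adenoma", "sebaceous_carcinoma", "skin_unspecified",
  "small_intestine", "testicular", "thyroid", "wilms_tumor"
)

.other_type <- "other_unspecified"

# Lowercased, punctuation-stripped synonym -> canonical id. The canonical
# ids are their own synonyms so normalize(canonical) is the identity.
.base_synonyms <- local({
  syn <- c(
    "colon" = "colorectal", "rectal" = "colorectal", "rectum" = "colorectal",
    "colorectal cancer" = "colorectal", "bowel" = "colorectal",
    "uterine" = "endometrial", "uterus" = "endometrial",
    "endometrium" = "endometrial", "womb" = "endometrial",
    "stomach" = "gastric", "gastric cancer" = "gastric",
    "brain" = "cns_brain", "cns" = "cns_brain", "cns brain" = "cns_brain",
    "brain cns" = "cns_brain", "glioma" = "cns_brain",
    "glioblastoma" = "cns_brain",
    "kidney" = "renal", "renal cell" = "renal",
    "ureter" = "renal_pelvis_ureter", "renal pelvis" = "renal_pelvis_ureter",
    "ureter and renal pelvis" = "renal_pelvis_ureter",
    "skin" = "skin_unspecified", "skin unspecified" = "skin_unspecified",
    "lymphoma" = "lymphoma_unspecified",
    "lymphoma unspecified" = "lymphoma_unspecified",
    "hodgkins lymphoma" = "hodgkin_lymphoma",
    "hodgkin lymphoma" = "hodgkin_lymphoma",
    "lymphoma hodgkins" = "hodgkin_lymphoma",
    "non hodgkins lymphoma" = "non_hodgkin_lymphoma",
    "non hodgkin lymphoma" = "non_hodgkin_lymphoma",
    "lymphoma non hodgkins" = "non_hodgkin_lymphoma",
    "nhl" = "non_hodgkin_lymphoma",
    "wilms tumor" = "wilms_tumor", "wilms" = "wilms_tumor",
    "fallopian tube" = "fallopian_tube",
    "fallopian tube cancer" = "fallopian_tube",
    "peritoneal" = "primary_peritoneal",
    "primary peritoneal" = "primary_peritoneal",
    "ovary" = "ovarian", "ovarian carcinoma" = "ovarian",
    "pancreas" = "pancreatic", "pancreas cancer" = "pancreatic",
    "small intestine" = "small_intestine",
    "small intestinal" = "small_intestine", "small bowel" = "small_intestine",
    "sebaceous adenoma" = "sebaceous_adenoma",
    "sebaceous carcinoma" = "sebaceous_carcinoma",
    "esophagus" = "esophageal",
    "head and neck" = "head_neck", "throat" = "head_neck",
    "myeloma" = "multiple_myeloma", "multiple myeloma" = "multiple_myeloma",
    "cervix" = "cervical", "liver cancer" = "liver",
    "hepatocellular" = "liver", "thyroid cancer" = "thyroid",
    "osteosarcoma" = "bone", "leukaemia" = "leukemia",
    "cns brain tumor" = "cns_brain", "breast cancer" = "breast"
  )
  ids <- .canonical_types
  names(ids) <- gsub("_", " ", ids)
  c(syn, ids)
})

.clean_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:punct:]]+", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

#' The cancer-type vocabulary
#'
#' @param extra Optional named character vector of additional synonyms
#'   (names are raw labels, values canonical type identifiers).
#' @return A list with `types` (the 36 canonical identifiers), `other` (the
#'   fallback identifier), and `synonyms` (cleaned-synonym -> canonical map).
#' @examples
#' v <- cancer_vocabulary()
#' length(v$types)
#' @export
cancer_vocabulary <- function(extra = NULL) {
  syn <- .base_synonyms
  if (!is.null(extra)) {
    stopifnot(is.character(extra), !is.null(names(extra)),
              all(extra %in% c(.canonical_types, .other_type)))
    names(extra) <- .clean_label(names(extra))
    syn[names(extra)] <- extra
  }
  list(types = .canonical_types, other = .other_type, synonyms = syn)
}

#' Normalize a recorded cancer type
#'
#' Maps a free-text cancer label onto the canonical vocabulary. Unmapped
#' labels normalize to `"other_unspecified"`, never to an error, mirroring
#' how unlisted types are recorded as "other / unspecified" at intake.
#' Breast subtypes spelled in the label ("DCIS", "triple negative") become
#' qualifiers; prostate cancers without Gleason information are assumed
#' high-risk (Gleason score > 7), as pedigrees rarely record aggressivity.
#'
#' @param label Free-text cancer type (length 1).
#' @param age An [age_record()], or a plain number taken as an exact age.
#' @param qualifiers Optional character vector of qualifiers among
#'   `"DCIS"`, `"TRIPLE_NEGATIVE"`, `"GLEASON_GT7"`, `"SYNCHRONOUS"`,
#'   `"METACHRONOUS"`.
#' @param primary_index Ordinal distinguishing multiple primaries of the
#'   same type in one person (bilateral breast disease is two primaries).
#' @param vocabulary A [cancer_vocabulary()].
#' @return A `hcs_diagnosis` object (see [diagnosis()]).
#' @examples
#' normalize_cancer("Breast - DCIS", age_record("EXACT", 52))
#' normalize_cancer("prostate", age_record("DECADE", 60))$qualifiers
#' normalize_cancer("myxofibrosarcoma of the toe", 70)$cancer_type
#' @export
normalize_cancer <- function(label, age = age_record("UNKNOWN"),
                             qualifiers = character(), primary_index = 1L,
                             vocabulary = cancer_vocabulary()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(trimws(label)))
  clean <- .clean_label(label)
  qualifiers <- unique(as.character(qualifiers))
  if (grepl("\\bdcis\\b|ductal carcinoma in situ", clean)) {
    qualifiers <- union(qualifiers, "DCIS")
    clean <- .clean_label(gsub("dcis|ductal carcinoma in situ", "", clean))
  }
  if (grepl("triple negative", clean)) {
    qualifiers <- union(qualifiers, "TRIPLE_NEGATIVE")
    clean <- .clean_label(gsub("triple negative", "", clean))
  }
  type <- unname(vocabulary$synonyms[clean])
  if (is.na(type)) type <- vocabulary$other
  if (type == "prostate" && !any(grepl("^GLEASON", qualifiers))) {
    qualifiers <- union(qualifiers, "GLEASON_GT7")
  }
  diagnosis(type, age = age, qualifiers = qualifiers,
            primary_index = primary_index)
}

#' Cancer-type class membership used by the criteria
#'
#' `is_ovarian_equivalent()` is true for ovarian carcinoma and its
#' guideline equivalents (fallopian tube and primary peritoneal cancers).
#' `is_ls_related()` is true for the Lynch-syndrome-related set: colorectal,
#' endometrial, gastric, ovarian, pancreatic, ureter/renal pelvis,
#' brain/CNS, small intestinal cancers, plus the sebaceous adenomas and
#' carcinomas and keratoacanthomas of Muir-Torre syndrome.
#' `is_amsterdam_cancer()` is the narrower Amsterdam II set: colorectal,
#' endometrial, small intestinal, and ureter/renal pelvis cancers.
#'
#' @param type Character vector of canonical cancer-type identifiers.
#' @return Logical vector.
#' @examples
#' is_ovarian_equivalent(c("fallopian_tube", "cervical"))
#' is_ls_related(c("gastric", "cns_brain", "lung"))
#' @export
is_ovarian_equivalent <- function(type) {
  type %in% c("ovarian", "fallopian_tube", "primary_peritoneal")
}

#' @rdname is_ovarian_equivalent
#' @export
is_ls_related <- function(type) {
  type %in% c("colorectal", "endometrial", "gastric", "ovarian", "pancreatic",
              "renal_pelvis_ureter", "cns_brain", "small_intestine",
              "sebaceous_adenoma", "sebaceous_carcinoma", "keratoacanthoma")
}

#' @rdname is_ovarian_equivalent
#' @export
is_amsterdam_cancer <- function(type) {
  type %in% c("colorectal", "endometrial", "small_intestine",
              "renal_pelvis_ureter")
}
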