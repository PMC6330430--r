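# The intake questionnaire: six primary prompts with stepwise follow-ups,
# matching the question categories of the screening tool. Follow-up
# prompts appear only after an affirmative answer to their trigger.

.intake_prompts <- list(
  ethnicity = list(
    text = "How would you describe your ethnic background?",
    followup = NULL),
  personal_cancer = list(
    text = "Have you ever been diagnosed with cancer?",
    followup = "If so, what type and at what age?"),
  family_cancer = list(
    text = "Is there a family history of cancer?",
    followup = "If so, who, what type and at what age?"),
  polyps = list(
    text = "Have you/family member had any colon polyps?",
    followup = "If so, who/how many?"),
  mutation = list(
    text = "Has anyone in your family tested positive for a cancer-related gene mutation?",
    followup = "If so, from BRCA1/BRCA2, Lynch syndrome, APC/MUTYH?"),
  family_size = list(
    text = "Help us understand the size of your family.",
    followup = "Enter number of family members in each generation.")
)

#' Start an intake session
#'
#' @return An object of class `hcs_intake` tracking answers to the six
#'   primary prompts and any pending follow-up.
#' @export
intake_state <- function() {
  structure(list(answers = list(), pending_followup = NULL),
            class = "hcs_intake")
}

#' Next intake prompt
#'
#' Emits the prompts in fixed order (ethnicity; personal cancer; family
#' cancer; polyps; known mutation; family size), inserting the follow-up
#' prompt (type/age/who details) only after an affirmative answer to its
#' trigger. Returns `NULL` when all six primary prompts are resolved.
#'
#' @param state An `hcs_intake` state.
#' @return A list `list(id, text, followup)` describing the next prompt,
#'   or `NULL` when intake is complete.
#' @export
next_prompt <- function(state) {
  stopifnot(inherits(state, "hcs_intake"))
  if (!is.null(state$pending_followup)) {
    id <- state$pending_followup
    return(list(id = paste0(id, "_detail"),
                text = .intake_prompts[[id]]$followup, followup = TRUE))
  }
  for (id in names(.intake_prompts)) {
    if (is.null(state$answers[[id]])) {
      return(list(id = id, text = .intake_prompts[[id]]$text,
                  followup = FALSE))
    }
  }
  NULL
}

#' Record an answer and advance the intake
#'
#' For yes/no trigger prompts an affirmative answer (`TRUE`, `"yes"`)
#' queues the follow-up; the follow-up answer carries the structured
#' detail (diagnoses, relatives, counts, gene group).
#'
#' @param state An `hcs_intake` state.
#' @param value The answer to the prompt currently returned by
#'   [next_prompt()].
#' @return The updated state.
#' @export
submit_answer <- function(state, value) {
  stopifnot(inherits(state, "hcs_intake"))
  p <- next_prompt(state)
  if (is.null(p)) stop("intake is already complete")
  if (isTRUE(p$followup)) {
    id <- state$pending_followup
    state$answers[[id]] <- list(affirmative = TRUE, detail = value)
    state$pending_followup <- NULL
    return(state)
  }
  id <- p$id
  has_followup <- !is.null(.intake_prompts[[id]]$followup)
  affirmative <- isTRUE(value) ||
    (is.character(value) && tolower(value[1]) %in% c("yes", "y", "true"))
  if (has_followup && id != "family_size" && !affirmative) {
    state$answers[[id]] <- list(affirmative = FALSE, detail = NULL)
  } else if (has_followup) {
    state$pending_followup <- id
    state$answers[[id]] <- NULL   # resolved when the follow-up is answered
    # mark the trigger so next_prompt() serves the follow-up next
  } else {
    state$answers[[id]] <- list(affirmative = NA, detail = value)
  }
  state
}

#' Assemble a pedigree from a completed intake
#'
#' Expects follow-up details in constructor-ready form: `personal_cancer`
#' and `family_cancer` details as lists of
#' `list(relationship, cancer_type, age, sex)`, `polyps` as
#' `list(list(relationship, count))`, `mutation` as
#' `list(gene_group, carrier)`, `family_size` as a named list.
#'
#' @param state A completed `hcs_intake` state.
#' @return A [pedigree()].
#' @export
assemble_pedigree <- function(state) {
  stopifnot(inherits(state, "hcs_intake"))
  if (!is.null(next_prompt(state))) stop("intake is not complete")
  a <- state$answers
  eth <- a$ethnicity$detail %||% "Unknown"
  members <- list(); pro_dx <- list(); pro_polyps <- NA_integer_
  to_age <- function(x) if (is.null(x)) age_record("UNKNOWN") else .as_age(x)
  if (isTRUE(a$personal_cancer$affirmative)) {
    for (d in a$personal_cancer$detail) {
      pro_dx <- c(pro_dx, list(normalize_cancer(d$cancer_type, to_age(d$age))))
    }
  }
  member_env <- new.env()
  get_member <- function(rel, sex = NULL) {
    key <- rel
    if (is.null(member_env[[key]])) {
      member_env[[key]] <- family_member(rel, sex = sex)
    }
    key
  }
  if (isTRUE(a$family_cancer$affirmative)) {
    for (d in a$family_cancer$detail) {
      key <- get_member(d$relationship, d$sex)
      m <- member_env[[key]]
      m$diagnoses <- c(m$diagnoses,
                       list(normalize_cancer(d$cancer_type, to_age(d$age))))
      member_env[[key]] <- m
    }
  }
  if (isTRUE(a$polyps$affirmative)) {
    for (d in a$polyps$detail) {
      if (d$relationship == "self") pro_polyps <- as.integer(d$count)
      else {
        key <- get_member(d$relationship)
        m <- member_env[[key]]
        m$polyp_count <- as.integer(d$count)
        member_env[[key]] <- m
      }
    }
  }
  mutations <- list()
  if (isTRUE(a$mutation$affirmative)) {
    d <- a$mutation$detail
    mutations <- list(mutation_finding(d$gene_group, d$carrier %||% "self"))
  }
  members <- mget(ls(member_env), envir = member_env)
  pedigree(
    proband = family_member("self", sex = "female", diagnoses = pro_dx,
                            polyp_count = pro_polyps),
    members = unname(members),
    ethnicities = unlist(eth),
    mutations = mutations,
    family_sizes = a$family_size$detail %||% list())
}
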