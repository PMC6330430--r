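# Validation statistics: confusion matrix, accuracy panel, exact binomial
# confidence intervals, sample-size planning.

#' Confusion matrix for screening validation
#'
#' Tallies paired per-event labels into the standard 2x2 layout: truth is
#' the expert (pedigree-review) adjudication, test is the screening
#' engine's call. `A` = true positives, `B` = false positives, `C` = false
#' negatives, `D` = true negatives.
#'
#' @param truth,predicted Equal-length vectors with values `"meets"` or
#'   `"does-not-meet"` (logicals are accepted; `TRUE` = meets).
#' @return An object of class `hcs_confusion` with fields `A`, `B`, `C`,
#'   `D`, `total`.
#' @examples
#' confusion(c("meets", "does-not-meet"), c("meets", "does-not-meet"))
#' @export
confusion <- function(truth, predicted) {
  norm <- function(x) {
    if (is.logical(x)) x <- ifelse(x, "meets", "does-not-meet")
    x <- as.character(x)
    bad <- setdiff(unique(x), c("meets", "does-not-meet"))
    if (length(bad)) stop("labels must be 'meets'/'does-not-meet'; got ",
                          paste(bad, collapse = ", "))
    x == "meets"
  }
  t <- norm(truth); p <- norm(predicted)
  if (length(t) != length(p)) {
    stop("truth and predicted must have equal length (", length(t),
         " vs ", length(p), ")")
  }
  m <- list(A = sum(t & p), B = sum(!t & p), C = sum(t & !p),
            D = sum(!t & !p))
  m$total <- m$A + m$B + m$C + m$D
  structure(m, class = "hcs_confusion")
}

#' Build a confusion matrix directly from counts
#'
#' @param A,B,C,D True-positive, false-positive, false-negative and
#'   true-negative counts.
#' @return An `hcs_confusion`.
#' @export
confusion_counts <- function(A, B, C, D) {
  stopifnot(A >= 0, B >= 0, C >= 0, D >= 0)
  structure(list(A = as.integer(A), B = as.integer(B), C = as.integer(C),
                 D = as.integer(D), total = as.integer(A + B + C + D)),
            class = "hcs_confusion")
}

#' @export
print.hcs_confusion <- function(x, ...) {
  cat(sprintf("<confusion> A=%d B=%d C=%d D=%d (total %d)\n",
              x$A, x$B, x$C, x$D, x$total))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The beta-quantile formulation of the exact interval: lower bound
#' `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper bound
#' `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param confidence Confidence level (default 0.95).
#' @return An object of class `hcs_interval`: `point`, `lower`, `upper`,
#'   `confidence`, `successes`, `trials`.
#' @examples
#' exact_binomial_ci(382, 382)  # lower bound 0.9904
#' exact_binomial_ci(381, 383)
#' @export
exact_binomial_ci <- function(successes, trials, confidence = 0.95) {
  stopifnot(length(successes) == 1L, length(trials) == 1L,
            is.numeric(successes), is.numeric(trials))
  if (trials <= 0 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials with trials > 0")
  }
  stopifnot(confidence > 0, confidence < 1)
  x <- successes; n <- trials
  alpha <- 1 - confidence
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(point = x / n, lower = lower, upper = upper,
                 confidence = confidence, successes = x, trials = n),
            class = "hcs_interval")
}

#' @export
print.hcs_interval <- function(x, ...) {
  cat(sprintf("%d/%d = %.2f%% (%.2f-%.2f%% CI at %g%%)\n",
              x$successes, x$trials, 100 * x$point, 100 * x$lower,
              100 * x$upper, 100 * x$confidence))
  invisible(x)
}

#' Accuracy panel of a confusion matrix
#'
#' Sensitivity `A/(A+C)`, specificity `D/(D+B)` and accuracy
#' `(A+D)/(A+B+C+D)`, each as an exact ratio with its Clopper-Pearson
#' confidence interval. A quantity with a zero denominator is reported as
#' undefined (`NULL`), not as 0.
#'
#' @param m An `hcs_confusion`.
#' @param confidence Confidence level for the intervals.
#' @return A list with elements `sensitivity`, `specificity`, `accuracy`
#'   (each an `hcs_interval` or `NULL` when undefined).
#' @examples
#' accuracy_panel(confusion_counts(382, 2, 0, 381))
#' @export
accuracy_panel <- function(m, confidence = 0.95) {
  stopifnot(inherits(m, "hcs_confusion"))
  ratio <- function(x, n) {
    if (n == 0) return(NULL)
    exact_binomial_ci(x, n, confidence)
  }
  list(sensitivity = ratio(m$A, m$A + m$C),
       specificity = ratio(m$D, m$D + m$B),
       accuracy = ratio(m$A + m$D, m$total))
}

#' Sample size for a one-sample proportion
#'
#' Smallest `n` from the normal-approximation one-sample proportion
#' formula `n = (z[1-alpha/2] + z[power])^2 p (1-p) / delta^2`, rounded up.
#'
#' @param assumed_p Assumed proportion, in (0, 1).
#' @param delta Absolute difference to detect; must be feasible
#'   (`0 < delta < min(p, 1-p)` margin against the boundary).
#' @param alpha Two-sided type I error rate.
#' @param power Desired power.
#' @return Integer sample size.
#' @examples
#' sample_size_proportion(0.90, 0.05)  # 379
#' sample_size_proportion(0.50, 0.05)  # 1051
#' @export
sample_size_proportion <- function(assumed_p, delta, alpha = 0.05,
                                   power = 0.90) {
  stopifnot(assumed_p > 0, assumed_p < 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (delta <= 0 || delta >= min(assumed_p, 1 - assumed_p)) {
    stop("delta is infeasible for the assumed proportion")
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(z^2 * assumed_p * (1 - assumed_p) / delta^2))
}

#' Events per pedigree
#'
#' @param events,pedigrees Counts; `pedigrees > 0`.
#' @return The rate `events/pedigrees`, rounded to 2 decimal places.
#' @examples
#' event_rate(765, 197)  # 3.88
#' @export
event_rate <- function(events, pedigrees) {
  stopifnot(is.numeric(events), is.numeric(pedigrees))
  if (pedigrees <= 0) stop("pedigrees must be positive")
  round(events / pedigrees, 2)
}
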