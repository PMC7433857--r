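# Normative screening: mean - k*SD cut-offs from a control sample, and the
# eligibility rules used to assemble an anomic PPA cohort.

#' Derive a normative cut-off from a control sample
#'
#' Returns `mean - k * SD` of a control sample (sample SD, n - 1
#' denominator). The real-valued threshold informs, but does not dictate, the
#' integer screening cut-off: published integer cut-offs are configuration
#' (see [normative_cutoffs()]) because a single rounding rule does not
#' reproduce both published values (60 is the floor of 60.81 while 54 is the
#' ceiling of 53.84).
#'
#' Either pass raw control `scores`, or the summary `mean` and `sd` directly
#' when only published norms are available.
#'
#' @param scores integer control scores (at least 2), or `NULL` when `mean`
#'   and `sd` are given.
#' @param k SD multiplier (default 2, the conventional abnormality band).
#' @param mean,sd optional summary statistics used instead of `scores`.
#' @return a list of class `normative_cutoff` with `mean`, `sd`, `n`, `k`
#'   and the real-valued `threshold`.
#' @examples
#' derive_cutoff(mean = 62.81, sd = 1.00)$threshold  # 60.81
#' derive_cutoff(mean = 58.80, sd = 2.48)$threshold  # 53.84
#' @export
derive_cutoff <- function(scores = NULL, k = 2, mean = NULL, sd = NULL) {
  stopifnot(k > 0)
  if (is.null(scores)) {
    if (is.null(mean) || is.null(sd)) {
      ssl_abort("supply either control scores or mean and sd", "ssl_invalid_input")
    }
    m <- mean; s <- sd; n <- NA_integer_
  } else {
    if (length(scores) < 2 || anyNA(scores)) {
      ssl_abort("at least 2 complete control scores are required",
                "ssl_invalid_input")
    }
    m <- base::mean(scores)
    s <- stats::sd(scores)       # sample SD, n - 1
    n <- length(scores)
  }
  if (s < 0) ssl_abort("SD must be non-negative", "ssl_invalid_input")
  structure(list(mean = m, sd = s, n = n, k = k, threshold = m - k * s),
            class = "normative_cutoff")
}

#' @export
print.normative_cutoff <- function(x, ...) {
  cat(sprintf("Normative cut-off: mean %.2f, SD %.2f (n = %s); mean - %g SD = %.2f\n",
              x$mean, x$sd, ifelse(is.na(x$n), "summary", x$n), x$k, x$threshold))
  invisible(x)
}

#' Screening thresholds
#'
#' Container for the integer eligibility thresholds. Defaults are the
#' published values: abnormal naming is a Cambridge Naming score below 60,
#' abnormal semantic memory a CCT-Picture score below 54, and participants
#' with very mild anomia (spontaneous naming above 59) are excluded.
#'
#' @param naming_abnormal_below naming scores below this are abnormal.
#' @param cct_abnormal_below CCT-Picture scores below this are abnormal.
#' @param naming_exclude_above naming scores above this are excluded as very
#'   mild anomia.
#' @param naming_max,cct_max instrument maxima used for range validation.
#' @return a list of class `normative_cutoffs`.
#' @export
normative_cutoffs <- function(naming_abnormal_below = 60L,
                              cct_abnormal_below = 54L,
                              naming_exclude_above = 59L,
                              naming_max = 64L, cct_max = 64L) {
  if (naming_abnormal_below < 0 || naming_abnormal_below > naming_max + 1 ||
      cct_abnormal_below < 0 || cct_abnormal_below > cct_max + 1 ||
      naming_exclude_above < 0 || naming_exclude_above > naming_max) {
    ssl_abort("thresholds must lie within each instrument's score range",
              "ssl_invalid_input")
  }
  structure(list(naming_abnormal_below = as.integer(naming_abnormal_below),
                 cct_abnormal_below = as.integer(cct_abnormal_below),
                 naming_exclude_above = as.integer(naming_exclude_above)),
            class = "normative_cutoffs")
}

#' Screen a participant for study eligibility
#'
#' Applies the cohort-entry rules: eligible iff naming is abnormal
#' (`< naming_abnormal_below`), naming is not above the very-mild-anomia
#' exclusion (`<= naming_exclude_above`), and CCT-Picture is abnormal
#' (`< cct_abnormal_below`). Every failed rule contributes a reason code:
#' `"naming-not-abnormal"`, `"naming-above-exclusion"`, `"cct-not-abnormal"`.
#'
#' @param naming_correct spontaneous naming score.
#' @param cct_picture CCT-Picture score; may be `NA` only when
#'   `require_cct = FALSE` (naming-only screening).
#' @param cutoffs a [normative_cutoffs()] object.
#' @param require_cct is the semantic-memory criterion required?
#' @return list with `eligible` (logical) and `reasons` (character vector,
#'   empty when eligible).
#' @examples
#' screen_participant(61, 40)  # ineligible: naming-above-exclusion
#' screen_participant(51, 50)  # eligible
#' @export
screen_participant <- function(naming_correct, cct_picture,
                               cutoffs = normative_cutoffs(),
                               require_cct = TRUE) {
  stopifnot(inherits(cutoffs, "normative_cutoffs"))
  check_count(naming_correct, "naming_correct", 64L)
  reasons <- character()
  if (naming_correct >= cutoffs$naming_abnormal_below) {
    reasons <- c(reasons, "naming-not-abnormal")
  }
  if (naming_correct > cutoffs$naming_exclude_above) {
    reasons <- c(reasons, "naming-above-exclusion")
  }
  if (is.na(cct_picture)) {
    if (require_cct) {
      ssl_abort("cct_picture is required unless screening is configured naming-only",
                "ssl_cct_required")
    }
  } else {
    check_count(cct_picture, "cct_picture", 64L)
    if (cct_picture >= cutoffs$cct_abnormal_below) {
      reasons <- c(reasons, "cct-not-abnormal")
    }
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Screen a cohort data frame
#'
#' Vectorized wrapper around [screen_participant()].
#'
#' @param records data frame with `naming_correct` and (unless
#'   `require_cct = FALSE`) `cct_picture` columns.
#' @inheritParams screen_participant
#' @return the input with appended `eligible` (logical) and `reasons`
#'   (comma-joined reason codes).
#' @export
screen_cohort <- function(records, cutoffs = normative_cutoffs(),
                          require_cct = TRUE) {
  cct <- if ("cct_picture" %in% names(records)) records$cct_picture
         else rep(NA_integer_, nrow(records))
  out <- records
  out$eligible <- NA
  out$reasons <- ""
  for (i in seq_len(nrow(records))) {
    d <- screen_participant(records$naming_correct[i], cct[i],
                            cutoffs = cutoffs, require_cct = require_cct)
    out$eligible[i] <- d$eligible
    out$reasons[i] <- join_flags(d$reasons)
  }
  out
}
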