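# Core SSL scoring: the three component scores and the omnibus composite.
#
# The omnibus semantic storage loss (SSL) score is the unweighted mean of
# three sub-scores, each in [0, 1], each approaching 0 with more severe
# semantic storage impairment:
#   c_cue         proportion of spontaneous-naming misses recovered with a
#                 phonemic cue
#   c_consistency proportion of spontaneous-naming misses nonetheless
#                 recognized in word-picture matching (WPMT)
#   c_ratio       naming proportion / (naming proportion + MMSE proportion)

#' Construct a participant record
#'
#' Validates one participant's aggregate task counts against the instrument
#' maxima and the cumulative-cueing invariant (every spontaneous hit is also
#' a cued hit, so `naming_correct <= cued_correct`).
#'
#' @param participant_id opaque identifier.
#' @param naming_correct spontaneous naming correct count, 0--`naming_max`.
#' @param cued_correct cumulative cued naming correct count (spontaneous OR
#'   cued), 0--`naming_max`.
#' @param wpmt_correct word-picture matching correct count, 0--`naming_max`.
#' @param mmse MMSE total, 0--`mmse_max`.
#' @param group_label optional clinical group label (e.g. "nfvPPA"); carried
#'   as opaque metadata.
#' @param moca,cct_picture optional covariates (MoCA 0--30, CCT-Picture
#'   0--64).
#' @param roi_ratios optional named numeric vector of regional FDG-uptake
#'   ratios (cerebellar gray reference = 1.00); must be strictly positive.
#' @param naming_max,mmse_max instrument maxima; defaults are the 64-item
#'   naming battery and the 30-point MMSE.
#' @return an object of class `participant_record` (a named list).
#' @export
participant_record <- function(participant_id, naming_correct, cued_correct,
                               wpmt_correct, mmse, group_label = NA_character_,
                               moca = NA_integer_, cct_picture = NA_integer_,
                               roi_ratios = NULL,
                               naming_max = 64L, mmse_max = 30L) {
  check_count(naming_correct, "naming_correct", naming_max)
  check_count(cued_correct, "cued_correct", naming_max)
  check_count(wpmt_correct, "wpmt_correct", naming_max)
  check_count(mmse, "mmse", mmse_max)
  if (cued_correct < naming_correct) {
    ssl_abort("cued_correct < naming_correct violates the cumulative-cueing invariant",
              "ssl_invariant_violation")
  }
  if (!is.na(moca)) check_count(moca, "moca", 30L)
  if (!is.na(cct_picture)) check_count(cct_picture, "cct_picture", naming_max)
  if (!is.null(roi_ratios)) {
    if (!is.numeric(roi_ratios) || is.null(names(roi_ratios)) ||
        any(roi_ratios <= 0, na.rm = TRUE)) {
      ssl_abort("roi_ratios must be a named numeric vector of strictly positive ratios",
                "ssl_invalid_input")
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         group_label = as.character(group_label),
         naming_correct = as.integer(naming_correct),
         cued_correct = as.integer(cued_correct),
         wpmt_correct = as.integer(wpmt_correct),
         mmse = as.integer(mmse),
         moca = as.integer(moca),
         cct_picture = as.integer(cct_picture),
         roi_ratios = roi_ratios,
         naming_max = as.integer(naming_max),
         mmse_max = as.integer(mmse_max)),
    class = "participant_record"
  )
}

#' Construct item-level task outcomes
#'
#' Holds the per-item outcome triple for the 64-item battery (8 semantic
#' categories, 8 items each): whether the item was named spontaneously,
#' named only after a phonemic cue, and recognized in word-picture matching.
#' `named_with_cue` is defined only for items missed spontaneously and is
#' ignored (stored as `NA`) for spontaneous hits.
#'
#' @param named_spontaneously logical vector, one entry per item.
#' @param named_with_cue logical vector; entries for spontaneously named
#'   items are ignored.
#' @param recognized_in_wpmt logical vector, one entry per item.
#' @param n_items number of items in the battery (default 64).
#' @return an object of class `item_outcomes`.
#' @seealso [as_participant_record()] for aggregation to counts.
#' @export
item_outcomes <- function(named_spontaneously, named_with_cue,
                          recognized_in_wpmt, n_items = 64L) {
  lens <- c(length(named_spontaneously), length(named_with_cue),
            length(recognized_in_wpmt))
  if (any(lens != n_items)) {
    ssl_abort(sprintf("all outcome vectors must have exactly %d items", n_items),
              "ssl_invalid_input")
  }
  if (!is.logical(named_spontaneously) || anyNA(named_spontaneously) ||
      !is.logical(recognized_in_wpmt) || anyNA(recognized_in_wpmt) ||
      !is.logical(named_with_cue)) {
    ssl_abort("outcomes must be logical; only named_with_cue may be NA (on spontaneous hits)",
              "ssl_invalid_input")
  }
  cue <- named_with_cue
  cue[named_spontaneously] <- NA       # undefined for spontaneous hits
  if (anyNA(cue[!named_spontaneously])) {
    ssl_abort("named_with_cue must be TRUE/FALSE for every spontaneously missed item",
              "ssl_invalid_input")
  }
  structure(
    list(named_spontaneously = named_spontaneously,
         named_with_cue = cue,
         recognized_in_wpmt = recognized_in_wpmt,
         n_items = as.integer(n_items)),
    class = "item_outcomes"
  )
}

#' Aggregate item-level outcomes to a participant record
#'
#' `naming_correct` counts spontaneous hits; `cued_correct` is cumulative
#' (spontaneous hits plus cue recoveries); `wpmt_correct` counts all items
#' recognized in matching.
#'
#' @param items an [item_outcomes()] object.
#' @param mmse MMSE total for the same participant.
#' @param participant_id identifier for the resulting record.
#' @param ... further arguments passed to [participant_record()].
#' @return a `participant_record`.
#' @export
as_participant_record <- function(items, mmse, participant_id = "anonymous",
                                  ...) {
  stopifnot(inherits(items, "item_outcomes"))
  naming <- sum(items$named_spontaneously)
  cued <- naming + sum(items$named_with_cue[!items$named_spontaneously])
  wpmt <- sum(items$recognized_in_wpmt)
  participant_record(participant_id = participant_id,
                     naming_correct = naming, cued_correct = cued,
                     wpmt_correct = wpmt, mmse = mmse,
                     naming_max = items$n_items, ...)
}

#' Cue-retrieval score
#'
#' Proportion of items missed in spontaneous naming that were recovered when
#' given a phonemic cue: `(cued_correct - naming_correct) / (total -
#' naming_correct)`. Low values (cue-resistant anomia) indicate semantic
#' storage loss; cue-responsive anomia suggests a processing/access deficit.
#'
#' @param naming_correct spontaneous naming correct count.
#' @param cued_correct cumulative cued naming correct count.
#' @param total number of items (default 64).
#' @return proportion in \[0, 1\].
#' @section Errors: `naming_correct == total` leaves no missed items and the
#'   score undefined: a condition of class `ssl_no_missed_items` is raised
#'   (such participants are screened out, not scored). `cued_correct <
#'   naming_correct` raises `ssl_invariant_violation`.
#' @examples
#' cue_retrieval_score(51, 61)   # 10/13
#' cue_retrieval_score(57, 64)   # 1
#' @export
cue_retrieval_score <- function(naming_correct, cued_correct, total = 64L) {
  check_count(naming_correct, "naming_correct", total)
  check_count(cued_correct, "cued_correct", total)
  if (cued_correct < naming_correct) {
    ssl_abort("cued_correct < naming_correct violates the cumulative-cueing invariant",
              "ssl_invariant_violation")
  }
  if (naming_correct == total) {
    ssl_abort("no missed items: cue-retrieval score is undefined when naming is at ceiling",
              "ssl_no_missed_items")
  }
  (cued_correct - naming_correct) / (total - naming_correct)
}

#' Consistency score from aggregate counts
#'
#' Reconstructs the naming-to-comprehension consistency score -- the
#' proportion of spontaneous-naming misses that were nonetheless recognized
#' in word-picture matching -- from aggregate counts as
#' `(wpmt_correct - naming_correct) / (total - naming_correct)`.
#'
#' This reconstruction assumes every spontaneously named item was also
#' recognized in matching; with item-level data use
#' [consistency_score_items()], which needs no such assumption. When
#' `wpmt_correct < naming_correct` the raw value is negative and is clamped
#' to 0 (the quantity is a proportion); callers can detect this via
#' `attr(, "clamped")`.
#'
#' @inheritParams cue_retrieval_score
#' @param wpmt_correct word-picture matching correct count.
#' @param baseline `"spontaneous"` (canonical: misses of the spontaneous
#'   naming task) or `"cued"` (non-canonical variant: items missed even with
#'   a cue, i.e. relative to `cued_correct`). The spontaneous baseline is the
#'   definition that reproduces the published worked examples.
#' @param cued_correct required only for `baseline = "cued"`.
#' @return proportion in \[0, 1\], with logical attribute `"clamped"`.
#' @export
consistency_score_aggregate <- function(naming_correct, wpmt_correct,
                                        total = 64L,
                                        baseline = c("spontaneous", "cued"),
                                        cued_correct = NULL) {
  baseline <- match.arg(baseline)
  check_count(naming_correct, "naming_correct", total)
  check_count(wpmt_correct, "wpmt_correct", total)
  ref <- naming_correct
  if (baseline == "cued") {
    if (is.null(cued_correct)) {
      ssl_abort("cued_correct is required for the cued baseline", "ssl_invalid_input")
    }
    check_count(cued_correct, "cued_correct", total)
    ref <- cued_correct
  }
  if (ref == total) {
    ssl_abort("no missed items: consistency score is undefined when naming is at ceiling",
              "ssl_no_missed_items")
  }
  raw <- (wpmt_correct - ref) / (total - ref)
  structure(max(0, min(1, raw)), clamped = raw < 0)
}

#' Consistency score from item-level outcomes
#'
#' The literal definition: over exactly the items missed in spontaneous
#' naming, the fraction recognized in word-picture matching. This is the
#' canonical form when item-level data exist; the aggregate reconstruction
#' is exact only when every spontaneous hit was also recognized.
#'
#' @param items an [item_outcomes()] object with at least one missed item.
#' @return proportion in \[0, 1\].
#' @export
consistency_score_items <- function(items) {
  stopifnot(inherits(items, "item_outcomes"))
  missed <- !items$named_spontaneously
  if (!any(missed)) {
    ssl_abort("no missed items: consistency score is undefined when naming is at ceiling",
              "ssl_no_missed_items")
  }
  mean(items$recognized_in_wpmt[missed])
}

#' Naming-to-general-cognition ratio
#'
#' The third SSL component: `f(x, y) = x / (x + y)` where `x` is the naming
#' proportion (`naming_correct / naming_max`) and `y` the MMSE proportion
#' (`mmse / mmse_max`). Equal proportions give 0.5; the value approaches 0
#' when general cognition outstrips naming (anomia out of proportion to
#' dementia severity, i.e. storage-like) and 1 when naming outstrips
#' cognition.
#'
#' @param naming_correct spontaneous naming correct count.
#' @param mmse MMSE total.
#' @param naming_max,mmse_max instrument maxima (64, 30).
#' @return value in \[0, 1\].
#' @section Errors: `naming_correct == 0 && mmse == 0` leaves the ratio
#'   undefined (`ssl_undefined_ratio`).
#' @examples
#' naming_general_ratio(32, 15)  # equal proportions -> 0.5
#' @export
naming_general_ratio <- function(naming_correct, mmse,
                                 naming_max = 64L, mmse_max = 30L) {
  check_count(naming_correct, "naming_correct", naming_max)
  check_count(mmse, "mmse", mmse_max)
  if (naming_correct == 0 && mmse == 0) {
    ssl_abort("naming and MMSE are both zero: x/(x+y) is undefined",
              "ssl_undefined_ratio")
  }
  x <- naming_correct / naming_max
  y <- mmse / mmse_max
  x / (x + y)
}

#' Omnibus semantic storage loss score
#'
#' Computes the three SSL components and their unweighted mean. Scores near 0
#' indicate severe semantic storage loss (cue-resistant, cross-task
#' consistent anomia despite relatively preserved cognition); scores near 1
#' indicate anomia better explained by general cognitive impairment or a
#' processing/access deficit.
#'
#' `ssl_score()` is generic: it accepts a [participant_record()] (aggregate
#' mode), an [item_outcomes()] object plus `mmse` (item-level mode, the
#' canonical consistency definition), or raw counts via the default method.
#' Display rounding (2 decimals, half away from zero) is never applied
#' internally; use [round_display()] or the `ssl_display` column of
#' [score_cohort()].
#'
#' @param x a `participant_record`, `item_outcomes`, or naming count.
#' @param ... passed to methods.
#' @return an object of class `ssl_components`: a list with `c_cue`,
#'   `c_consistency`, `c_ratio`, `ssl` and a character vector `flags`
#'   (possible flags: `"aggregate-mode"`, `"clamped"`).
#' @examples
#' ssl_score(51, cued_correct = 61, wpmt_correct = 63, mmse = 19)$ssl
#' @export
ssl_score <- function(x, ...) UseMethod("ssl_score")

#' @rdname ssl_score
#' @param cued_correct,wpmt_correct,mmse aggregate counts (default method).
#' @param naming_max,mmse_max instrument maxima.
#' @export
ssl_score.default <- function(x, cued_correct, wpmt_correct, mmse,
                              naming_max = 64L, mmse_max = 30L, ...) {
  naming_correct <- x
  c_cue <- cue_retrieval_score(naming_correct, cued_correct, total = naming_max)
  cons <- consistency_score_aggregate(naming_correct, wpmt_correct,
                                      total = naming_max)
  c_ratio <- naming_general_ratio(naming_correct, mmse,
                                  naming_max = naming_max, mmse_max = mmse_max)
  flags <- "aggregate-mode"
  if (isTRUE(attr(cons, "clamped"))) flags <- c(flags, "clamped")
  new_ssl_components(c_cue, as.numeric(cons), c_ratio, flags)
}

#' @rdname ssl_score
#' @export
ssl_score.participant_record <- function(x, ...) {
  ssl_score.default(x$naming_correct, cued_correct = x$cued_correct,
                    wpmt_correct = x$wpmt_correct, mmse = x$mmse,
                    naming_max = x$naming_max, mmse_max = x$mmse_max)
}

#' @rdname ssl_score
#' @export
ssl_score.item_outcomes <- function(x, mmse, mmse_max = 30L, ...) {
  naming <- sum(x$named_spontaneously)
  cued <- naming + sum(x$named_with_cue[!x$named_spontaneously])
  c_cue <- cue_retrieval_score(naming, cued, total = x$n_items)
  c_cons <- consistency_score_items(x)
  c_ratio <- naming_general_ratio(naming, mmse, naming_max = x$n_items,
                                  mmse_max = mmse_max)
  new_ssl_components(c_cue, c_cons, c_ratio, character())
}

new_ssl_components <- function(c_cue, c_consistency, c_ratio, flags) {
  structure(
    list(c_cue = c_cue, c_consistency = c_consistency, c_ratio = c_ratio,
         ssl = (c_cue + c_consistency + c_ratio) / 3,
         flags = flags),
    class = "ssl_components"
  )
}

#' @export
print.ssl_components <- function(x, ...) {
  cat(sprintf(
    "SSL components: cue %.4f | consistency %.4f | naming:MMSE %.4f\n",
    x$c_cue, x$c_consistency, x$c_ratio))
  cat(sprintf("SSL score: %.4f (display %.2f)%s\n", x$ssl,
              round_display(x$ssl),
              if (length(x$flags)) paste0("  [", join_flags(x$flags), "]") else ""))
  invisible(x)
}

#' Score a cohort of participants
#'
#' Applies [ssl_score()] row-wise to a cohort data frame (the aggregate CSV
#' schema; see [read_cohort_csv()]). Unscorable rows -- naming at ceiling
#' (`no-missed-items`) or naming and MMSE both zero (`undefined-ratio`) --
#' are retained with `NA` scores and an explicit reason code, never dropped.
#'
#' @param records data frame with columns `participant_id`, `naming_correct`,
#'   `cued_correct`, `wpmt_correct`, `mmse` (extra columns are carried
#'   through untouched).
#' @param naming_max,mmse_max instrument maxima.
#' @return the input data frame with appended columns `c_cue`,
#'   `c_consistency`, `c_ratio`, `ssl` (full precision), `ssl_display`
#'   (2 dp, half away from zero), `scorable`, and `flags`.
#' @export
score_cohort <- function(records, naming_max = 64L, mmse_max = 30L) {
  required <- c("participant_id", "naming_correct", "cued_correct",
                "wpmt_correct", "mmse")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    ssl_abort(paste("missing required columns:",
                    paste(missing_cols, collapse = ", ")),
              "ssl_invalid_input")
  }
  if (anyDuplicated(records$participant_id)) {
    dup <- unique(records$participant_id[duplicated(records$participant_id)])
    ssl_abort(paste("duplicate participant_id:", paste(dup, collapse = ", ")),
              "ssl_invalid_input")
  }
  n <- nrow(records)
  out <- records
  out$c_cue <- out$c_consistency <- out$c_ratio <- out$ssl <-
    rep(NA_real_, n)
  out$ssl_display <- rep(NA_real_, n)
  out$scorable <- rep(FALSE, n)
  out$flags <- rep("", n)
  for (i in seq_len(n)) {
    res <- tryCatch(
      ssl_score(records$naming_correct[i],
                cued_correct = records$cued_correct[i],
                wpmt_correct = records$wpmt_correct[i],
                mmse = records$mmse[i],
                naming_max = naming_max, mmse_max = mmse_max),
      ssl_no_missed_items = function(e) "no-missed-items",
      ssl_undefined_ratio = function(e) "undefined-ratio"
    )
    if (is.character(res)) {
      out$flags[i] <- res
    } else {
      out$c_cue[i] <- res$c_cue
      out$c_consistency[i] <- res$c_consistency
      out$c_ratio[i] <- res$c_ratio
      out$ssl[i] <- res$ssl
      out$ssl_display[i] <- round_display(res$ssl)
      out$scorable[i] <- TRUE
      out$flags[i] <- join_flags(res$flags)
    }
  }
  out
}
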