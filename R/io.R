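# CSV I/O and the embedded 28-participant reference cohort.

AGGREGATE_REQUIRED <- c("participant_id", "naming_correct", "cued_correct",
                        "wpmt_correct", "mmse")
AGGREGATE_KNOWN <- c(AGGREGATE_REQUIRED, "group_label", "pathology", "sex",
                     "age", "education_years", "moca", "cct_picture",
                     "ssl_printed", "atl_left", "atl_right", "dlpfc_left",
                     "dlpfc_right", "latent_s", "latent_g")
ITEM_REQUIRED <- c("participant_id", "item_index", "named_spontaneously",
                   "named_with_cue", "recognized_in_wpmt")
ITEM_KNOWN <- c(ITEM_REQUIRED, "category")

#' Load the embedded 28-participant reference cohort
#'
#' The package ships an anonymized 28-participant PPA cohort (11 nfvPPA, 5
#' svPPA, 12 lvPPA) with spontaneous naming, cumulative cued naming,
#' word-picture matching and MMSE scores plus the SSL value originally
#' reported for each participant (`ssl_printed`, 2 decimals).
#'
#' The returned data frame adds two computed columns: `ssl_recomputed` (the
#' score recomputed from the raw counts at full precision) and
#' `reproduces_printed` (does the recomputed score, displayed at 2 decimals,
#' equal `ssl_printed`?). Two rows (DL, WB) do not reproduce their printed
#' value from their printed task scores -- probable transcription errors in
#' the source table -- and are conventionally excluded from exact-agreement
#' checks.
#'
#' @return data frame with 28 rows.
#' @examples
#' fx <- load_fixture()
#' table(fx$group_label)
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "ppa_cohort_28.csv", package = "sslscore",
                      mustWork = TRUE)
  fx <- utils::read.csv(path, stringsAsFactors = FALSE)
  scored <- score_cohort(fx)
  fx$ssl_recomputed <- scored$ssl
  fx$reproduces_printed <-
    !is.na(scored$ssl_display) & scored$ssl_display == fx$ssl_printed
  fx
}

#' Read a cohort CSV
#'
#' Reads and validates either schema:
#' \describe{
#'   \item{aggregate}{one row per participant: `participant_id`,
#'     `naming_correct`, `cued_correct`, `wpmt_correct`, `mmse`, plus
#'     optional covariate and ROI columns.}
#'   \item{item_level}{long format, one row per item: `participant_id`,
#'     `item_index`, `named_spontaneously`, `named_with_cue`,
#'     `recognized_in_wpmt` (and optional `category`).}
#' }
#' Unknown columns trigger a warning and are carried through. Rows violating
#' range or ordering invariants are collected and reported in a single typed
#' error (`ssl_validation_error`) listing the offending line numbers.
#'
#' @param path CSV file path (UTF-8, comma-delimited, header row).
#' @param schema `"aggregate"` or `"item_level"`.
#' @param naming_max,mmse_max instrument maxima for range validation.
#' @return validated data frame (possibly zero rows).
#' @export
read_cohort_csv <- function(path, schema = c("aggregate", "item_level"),
                            naming_max = 64L, mmse_max = 30L) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    ssl_abort(paste("file not found:", path), "ssl_invalid_input")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- if (schema == "aggregate") AGGREGATE_REQUIRED else ITEM_REQUIRED
  known <- if (schema == "aggregate") AGGREGATE_KNOWN else ITEM_KNOWN
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    ssl_abort(paste0("header does not match the ", schema, " schema; missing: ",
                     paste(missing_cols, collapse = ", ")),
              "ssl_invalid_input")
  }
  unknown <- setdiff(names(df), known)
  if (length(unknown)) {
    warning("unknown columns carried through unvalidated: ",
            paste(unknown, collapse = ", "))
  }
  if (nrow(df) == 0) return(df)
  problems <- character()
  # data line numbers in the file (header is line 1)
  line <- seq_len(nrow(df)) + 1L
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    if (any(cond)) {
      problems <<- c(problems,
                     sprintf("line %d: %s", line[cond], msg))
    }
  }
  if (schema == "aggregate") {
    in_range <- function(x, lo, hi) !is.na(x) & x >= lo & x <= hi & x == trunc(x)
    bad(!in_range(df$naming_correct, 0, naming_max),
        sprintf("naming_correct out of [0, %d]", naming_max))
    bad(!in_range(df$cued_correct, 0, naming_max),
        sprintf("cued_correct out of [0, %d]", naming_max))
    bad(!in_range(df$wpmt_correct, 0, naming_max),
        sprintf("wpmt_correct out of [0, %d]", naming_max))
    bad(!in_range(df$mmse, 0, mmse_max),
        sprintf("mmse out of [0, %d]", mmse_max))
    bad(df$cued_correct < df$naming_correct,
        "cued_correct < naming_correct (cued naming is cumulative)")
  } else {
    bad(is.na(df$item_index) | df$item_index < 1 | df$item_index > naming_max,
        sprintf("item_index out of [1, %d]", naming_max))
    for (col in c("named_spontaneously", "recognized_in_wpmt")) {
      df[[col]] <- as.logical(df[[col]])
      bad(is.na(df[[col]]), paste(col, "must be TRUE/FALSE"))
    }
    df$named_with_cue <- as.logical(df$named_with_cue)
    bad(!df$named_spontaneously & is.na(df$named_with_cue),
        "named_with_cue required for spontaneously missed items")
  }
  if (length(problems)) {
    ssl_abort(paste0("invalid rows in ", path, ":\n  ",
                     paste(problems, collapse = "\n  ")),
              "ssl_validation_error")
  }
  df
}

#' Write a cohort CSV
#'
#' Plain comma-delimited UTF-8 output with header, no row names and no
#' quoting beyond what the values require, so that write/read round-trips
#' are lossless.
#'
#' @param records data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a long item-level data frame to item_outcomes objects
#'
#' @param items long data frame in the item-level schema (possibly holding
#'   several participants).
#' @return named list of [item_outcomes()], one per participant.
#' @export
items_from_long <- function(items) {
  split_items <- split(items, items$participant_id)
  lapply(split_items, function(d) {
    d <- d[order(d$item_index), ]
    item_outcomes(d$named_spontaneously, d$named_with_cue,
                  d$recognized_in_wpmt, n_items = nrow(d))
  })
}

#' Read a key = value configuration file
#'
#' Minimal declarative format for screening thresholds and simulation
#' profiles: one `key = value` pair per line, `#` comments and blank lines
#' ignored; values are parsed as numbers where possible.
#'
#' @param path configuration file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) {
      ssl_abort(paste("malformed config line:", ln), "ssl_invalid_input")
    }
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}
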