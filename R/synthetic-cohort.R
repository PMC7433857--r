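# Synthetic PPA-like cohorts. Each participant is driven by two latent
# traits on [0, 1]: semantic integrity s (probability of naming an item
# spontaneously) and general cognition g (MMSE success probability). Deficit
# profiles differ in cue responsiveness and cross-task consistency --
# storage-like participants are cue-resistant and fail the same items across
# tasks, processing-like participants recover with cues -- and regional
# FDG-uptake ratios are coupled linearly to the latents (ATL to s, dlPFC to
# g) so that score-metabolism correlations have a known generating value.

#' Define a simulated deficit profile
#'
#' @param label group label (e.g. "storage-like").
#' @param s_mean,s_sd mean and SD of the latent semantic-integrity trait
#'   `s`, drawn from a normal truncated to \[0, 1\]. `p_name(s) = s`:
#'   each of the 64 items is named spontaneously with probability `s`.
#' @param g_mean,g_sd latent general-cognition trait `g` (truncated normal);
#'   MMSE is Binomial(30, g).
#' @param p_cue_given_miss probability a spontaneously missed item is
#'   recovered with a phonemic cue.
#' @param p_wpmt_given_miss probability a spontaneously missed item is still
#'   recognized in word-picture matching.
#' @param p_wpmt_given_hit recognition probability for spontaneously named
#'   items; default 0.98 (not 1) so the item-level and aggregate consistency
#'   definitions can diverge, as they may in real data.
#' @param atl_beta0,atl_beta1 intercept and slope coupling the ATL FDG ratio
#'   to `s`: `atl = beta0 + beta1 * s + Normal(0, sigma)`.
#' @param dlpfc_gamma0,dlpfc_gamma1 same coupling of the dlPFC ratio to `g`.
#' @param sigma SD of the ROI ratio noise (>= 0).
#' @param n_items,mmse_max instrument sizes (64, 30).
#' @return a list of class `group_profile`.
#' @export
group_profile <- function(label,
                          s_mean, s_sd, g_mean, g_sd,
                          p_cue_given_miss, p_wpmt_given_miss,
                          p_wpmt_given_hit = 0.98,
                          atl_beta0 = 0.70, atl_beta1 = 0.50,
                          dlpfc_gamma0 = 0.70, dlpfc_gamma1 = 0.40,
                          sigma = 0.05,
                          n_items = 64L, mmse_max = 30L) {
  probs <- c(p_cue_given_miss, p_wpmt_given_miss, p_wpmt_given_hit)
  if (any(probs < 0 | probs > 1)) {
    ssl_abort("profile probabilities must lie in [0, 1]", "ssl_invalid_input")
  }
  if (sigma < 0 || s_sd < 0 || g_sd < 0) {
    ssl_abort("standard deviations must be non-negative", "ssl_invalid_input")
  }
  structure(list(label = as.character(label),
                 s_mean = s_mean, s_sd = s_sd, g_mean = g_mean, g_sd = g_sd,
                 p_cue_given_miss = p_cue_given_miss,
                 p_wpmt_given_miss = p_wpmt_given_miss,
                 p_wpmt_given_hit = p_wpmt_given_hit,
                 atl_beta0 = atl_beta0, atl_beta1 = atl_beta1,
                 dlpfc_gamma0 = dlpfc_gamma0, dlpfc_gamma1 = dlpfc_gamma1,
                 sigma = sigma, n_items = as.integer(n_items),
                 mmse_max = as.integer(mmse_max)),
            class = "group_profile")
}

#' Default deficit profiles
#'
#' Three profiles spanning the deficit spectrum: `storage-like`
#' (cue-resistant, cross-task-consistent failures, relatively preserved
#' cognition -- the svPPA-like extreme), `intermediate` (lvPPA-like), and
#' `processing-like` (cue-responsive anomia with matching cognitive
#' impairment -- the nfvPPA-like extreme). Parameters are calibrated so the
#' expected group-mean SSL scores land near 0.29 / 0.51 / 0.69; they are
#' tuning targets for realism, not ground truth.
#'
#' @return named list of three [group_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    `storage-like` = group_profile("storage-like",
      s_mean = 0.20, s_sd = 0.10, g_mean = 0.55, g_sd = 0.15,
      p_cue_given_miss = 0.10, p_wpmt_given_miss = 0.45),
    intermediate = group_profile("intermediate",
      s_mean = 0.35, s_sd = 0.12, g_mean = 0.45, g_sd = 0.15,
      p_cue_given_miss = 0.50, p_wpmt_given_miss = 0.60),
    `processing-like` = group_profile("processing-like",
      s_mean = 0.65, s_sd = 0.12, g_mean = 0.65, g_sd = 0.12,
      p_cue_given_miss = 0.75, p_wpmt_given_miss = 0.85)
  )
}

# Normal truncated to [0, 1] by rejection (vectorized).
rtrunc01 <- function(n, mean, sd) {
  if (sd == 0) return(rep(min(1, max(0, mean)), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    ok <- x >= 0 & x <= 1
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

# Draw n participants from one profile using the current RNG stream.
# Returns list(records = data.frame, items = long data.frame).
r_profile <- function(n, profile, id_prefix = profile$label) {
  k <- profile$n_items
  s <- rtrunc01(n, profile$s_mean, profile$s_sd)
  g <- rtrunc01(n, profile$g_mean, profile$g_sd)
  named <- matrix(stats::runif(n * k), n, k) < s
  cued <- matrix(stats::runif(n * k), n, k) < profile$p_cue_given_miss
  cued[named] <- NA
  p_rec <- ifelse(named, profile$p_wpmt_given_hit, profile$p_wpmt_given_miss)
  recog <- matrix(stats::runif(n * k), n, k) < p_rec
  mmse <- stats::rbinom(n, profile$mmse_max, g)
  atl_l <- profile$atl_beta0 + profile$atl_beta1 * s +
    stats::rnorm(n, 0, profile$sigma)
  atl_r <- profile$atl_beta0 + profile$atl_beta1 * s +
    stats::rnorm(n, 0, profile$sigma)
  dlpfc_l <- profile$dlpfc_gamma0 + profile$dlpfc_gamma1 * g +
    stats::rnorm(n, 0, profile$sigma)
  dlpfc_r <- profile$dlpfc_gamma0 + profile$dlpfc_gamma1 * g +
    stats::rnorm(n, 0, profile$sigma)
  eps <- 1e-6   # ROI ratios are strictly positive by contract
  ids <- sprintf("%s-%03d", id_prefix, seq_len(n))
  naming <- rowSums(named)
  records <- data.frame(
    participant_id = ids,
    group_label = profile$label,
    naming_correct = naming,
    cued_correct = naming + rowSums(cued & !named, na.rm = TRUE),
    wpmt_correct = rowSums(recog),
    mmse = mmse,
    atl_left = pmax(eps, atl_l), atl_right = pmax(eps, atl_r),
    dlpfc_left = pmax(eps, dlpfc_l), dlpfc_right = pmax(eps, dlpfc_r),
    latent_s = s, latent_g = g,
    stringsAsFactors = FALSE
  )
  items <- data.frame(
    participant_id = rep(ids, each = k),
    item_index = rep(seq_len(k), times = n),
    category = rep(ceiling(seq_len(k) / 8), times = n),
    named_spontaneously = as.vector(t(named)),
    named_with_cue = as.vector(t(cued)),
    recognized_in_wpmt = as.vector(t(recog)),
    stringsAsFactors = FALSE
  )
  list(records = records, items = items)
}

#' Simulate one participant
#'
#' Draws a single participant from a deficit profile using the current RNG
#' state (seed it with [set.seed()] for reproducibility; [simulate_cohort()]
#' manages seeding for whole cohorts). A draw whose naming lands at ceiling
#' (no missed items) is valid but unscorable; [score_cohort()] flags it.
#'
#' @param profile a [group_profile()].
#' @param id participant identifier.
#' @return list with `items` (an [item_outcomes()] object) and `record`
#'   (a one-row data frame in the aggregate schema).
#' @export
simulate_participant <- function(profile, id = paste0(profile$label, "-001")) {
  stopifnot(inherits(profile, "group_profile"))
  d <- r_profile(1, profile)
  d$records$participant_id <- id
  d$items$participant_id <- id
  items <- item_outcomes(d$items$named_spontaneously,
                         d$items$named_with_cue,
                         d$items$recognized_in_wpmt,
                         n_items = profile$n_items)
  list(items = items, record = d$records)
}

#' Simulate a multi-group cohort
#'
#' Generates `n[i]` participants from each profile, reproducibly: the same
#' `(profiles, n, seed)` always yields identical output. A single RNG stream
#' is seeded once and consumed in profile order.
#'
#' @param profiles list of [group_profile()] objects (default
#'   [default_profiles()]); labels must be unique.
#' @param n integer vector of group sizes (recycled to `length(profiles)`).
#' @param seed integer seed.
#' @return list of class `simulated_cohort` with `records` (aggregate data
#'   frame, one row per participant, including ROI ratio columns and the
#'   generating latents), `items` (long item-level data frame), `profiles`,
#'   `n`, `seed`.
#' @export
simulate_cohort <- function(profiles = default_profiles(), n = 100L,
                            seed = 1L) {
  stopifnot(length(profiles) >= 1, all(n >= 1))
  labels <- vapply(profiles, function(p) p$label, character(1))
  if (anyDuplicated(labels)) {
    ssl_abort("profile labels must be unique", "ssl_invalid_input")
  }
  n <- rep_len(as.integer(n), length(profiles))
  set.seed(as.integer(seed))
  parts <- lapply(seq_along(profiles),
                  function(i) r_profile(n[i], profiles[[i]]))
  structure(list(
    records = do.call(rbind, lapply(parts, `[[`, "records")),
    items = do.call(rbind, lapply(parts, `[[`, "items")),
    profiles = profiles, n = n, seed = as.integer(seed)),
    class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d participants (%s), seed %d\n",
              nrow(x$records),
              paste(sprintf("%s n=%d",
                            vapply(x$profiles, `[[`, character(1), "label"),
                            x$n), collapse = ", "),
              x$seed))
  invisible(x)
}
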