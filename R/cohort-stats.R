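# Validation statistics: group summaries, one-way ANOVA with Scheffe post hoc
# contrasts, Pearson correlation with the t transform, and hierarchical OLS
# regression with the R-squared-change F test. Implemented from the classical
# definitions; the test suite checks each against the corresponding base-R
# routine as an independent oracle.

#' Per-group summary statistics
#'
#' @param values numeric vector.
#' @param labels group labels, same length as `values`.
#' @return data frame with one row per group: `group`, `n`, `mean`, `sd`
#'   (sample SD; `NA` for singleton groups).
#' @export
group_summary <- function(values, labels) {
  if (length(values) != length(labels)) {
    ssl_abort("values and labels must have equal length", "ssl_invalid_input")
  }
  if (length(values) == 0) {
    ssl_abort("at least one value per group is required", "ssl_invalid_input")
  }
  labels <- as.character(labels)
  groups <- unique(labels)
  data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(labels == g), integer(1)),
    mean = vapply(groups, function(g) mean(values[labels == g]), numeric(1)),
    sd = vapply(groups, function(g) stats::sd(values[labels == g]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition: `F = MSB / MSW` with
#' `df = (g - 1, n - g)`, p from the upper tail of the F distribution.
#'
#' @inheritParams group_summary
#' @return list of class `ssl_anova`: `F`, `df_between`, `df_within`, `p`,
#'   plus `ss_between`, `ss_within`, `ms_within`, and the per-group summary.
#' @section Errors: fewer than two groups, or zero within-group variance
#'   (`ssl_degenerate_variance`), raise typed errors.
#' @examples
#' oneway_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$F  # 13.5
#' @export
oneway_anova <- function(values, labels) {
  gs <- group_summary(values, labels)
  g <- nrow(gs)
  n <- length(values)
  if (g < 2) ssl_abort("at least two groups are required", "ssl_invalid_input")
  if (n <= g) ssl_abort("total n must exceed the number of groups",
                        "ssl_invalid_input")
  grand <- mean(values)
  ssb <- sum(gs$n * (gs$mean - grand)^2)
  ssw <- sum(vapply(seq_len(g), function(i) {
    v <- values[as.character(labels) == gs$group[i]]
    sum((v - gs$mean[i])^2)
  }, numeric(1)))
  df_b <- g - 1
  df_w <- n - g
  msw <- ssw / df_w
  if (msw == 0) {
    ssl_abort("zero within-group variance: F is undefined",
              "ssl_degenerate_variance")
  }
  f <- (ssb / df_b) / msw
  structure(list(F = f, df_between = df_b, df_within = df_w,
                 p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
                 ss_between = ssb, ss_within = ssw, ms_within = msw,
                 groups = gs),
            class = "ssl_anova")
}

#' @export
print.ssl_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Scheffe post hoc pairwise contrasts
#'
#' For each pair of groups the contrast statistic
#' `(mean_i - mean_j)^2 / (MSW * (1/n_i + 1/n_j))` is compared against the
#' Scheffe criterion `(g - 1) * qf(1 - alpha, g - 1, df_within)`. With two
#' groups the decision coincides with the omnibus ANOVA.
#'
#' @inheritParams group_summary
#' @param alpha familywise significance level (default 0.05).
#' @return data frame with one row per unordered pair: `group_i`, `group_j`,
#'   `diff`, `statistic`, `criterion`, `significant`.
#' @export
scheffe_posthoc <- function(values, labels, alpha = 0.05) {
  av <- oneway_anova(values, labels)
  gs <- av$groups
  g <- nrow(gs)
  crit <- (g - 1) * stats::qf(1 - alpha, g - 1, av$df_within)
  pairs <- utils::combn(g, 2)
  res <- data.frame(
    group_i = gs$group[pairs[1, ]],
    group_j = gs$group[pairs[2, ]],
    diff = gs$mean[pairs[1, ]] - gs$mean[pairs[2, ]],
    stringsAsFactors = FALSE
  )
  res$statistic <- res$diff^2 /
    (av$ms_within * (1 / gs$n[pairs[1, ]] + 1 / gs$n[pairs[2, ]]))
  res$criterion <- crit
  res$significant <- res$statistic > crit
  res
}

#' Pearson correlation with two-tailed p value
#'
#' Product-moment correlation with pairwise-complete deletion of missing
#' values; p from the t transform `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n - 2` degrees of freedom, two-tailed.
#'
#' @param x,y numeric vectors of equal length; pairs with any `NA` are
#'   dropped before computation.
#' @return list of class `ssl_correlation`: `r`, `n` (complete pairs), `t`,
#'   `df`, `p`.
#' @section Errors: fewer than 3 complete pairs, or a constant variable,
#'   raise `ssl_undefined_correlation`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    ssl_abort("x and y must have equal length", "ssl_invalid_input")
  }
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    ssl_abort("at least 3 complete pairs are required", "ssl_undefined_correlation")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ssl_abort("correlation is undefined for a constant variable",
              "ssl_undefined_correlation")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  }
  structure(list(r = r, n = n, t = t, df = n - 2, p = p),
            class = "ssl_correlation")
}

#' @export
print.ssl_correlation <- function(x, ...) {
  cat(sprintf("Pearson r(%d) = %.3f, p = %.4g (n = %d)\n", x$n, x$r, x$p, x$n))
  invisible(x)
}

# OLS R^2 via QR; errors on rank deficiency, naming the offending columns.
ols_r2 <- function(y, X) {
  X1 <- cbind(`(intercept)` = 1, X)
  qrd <- qr(X1)
  if (qrd$rank < ncol(X1)) {
    bad <- colnames(X1)[qrd$pivot[(qrd$rank + 1):ncol(X1)]]
    ssl_abort(paste("design matrix is rank deficient; collinear columns:",
                    paste(bad, collapse = ", ")),
              "ssl_rank_deficient")
  }
  fitted <- qr.fitted(qrd, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) ssl_abort("response is constant", "ssl_invalid_input")
  1 - sum((y - fitted)^2) / tss
}

#' Hierarchical regression with an R-squared-change F test
#'
#' Fits two nested ordinary-least-squares models (both with intercept): the
#' base model on `base_predictors` and the full model adding
#' `added_predictors`. The improvement is tested with
#' `F_change = (dR2 / q) / ((1 - R2_full) / (n - k_full - 1))`,
#' `q` = number of added predictors.
#'
#' Rows with any missing value across response or predictors are dropped
#' listwise before fitting. An exact full-model fit (`R2_full = 1`) reports
#' `F_change = Inf` with `p = 0`.
#'
#' @param response numeric response vector.
#' @param base_predictors numeric matrix/data frame/vector of base-model
#'   predictors.
#' @param added_predictors predictors added in the full model.
#' @return list of class `ssl_r2_change`: `r2_base`, `r2_full`, `delta_r2`,
#'   `F_change`, `df1`, `df2`, `p`, `n`.
#' @export
hierarchical_r2_change <- function(response, base_predictors, added_predictors) {
  Xb <- as.matrix(base_predictors)
  Xa <- as.matrix(added_predictors)
  if (is.null(colnames(Xb))) colnames(Xb) <- paste0("base", seq_len(ncol(Xb)))
  if (is.null(colnames(Xa))) colnames(Xa) <- paste0("added", seq_len(ncol(Xa)))
  keep <- stats::complete.cases(response, Xb, Xa)
  y <- response[keep]; Xb <- Xb[keep, , drop = FALSE]; Xa <- Xa[keep, , drop = FALSE]
  n <- length(y)
  k_full <- ncol(Xb) + ncol(Xa)
  q <- ncol(Xa)
  if (n <= k_full + 1) {
    ssl_abort("n must exceed the number of full-model predictors plus one",
              "ssl_invalid_input")
  }
  r2_base <- ols_r2(y, Xb)
  r2_full <- ols_r2(y, cbind(Xb, Xa))
  delta <- max(0, r2_full - r2_base)   # guard tiny negative rounding
  df2 <- n - k_full - 1
  if (1 - r2_full < .Machine$double.eps^0.75) {
    f <- Inf; p <- 0
  } else {
    f <- (delta / q) / ((1 - r2_full) / df2)
    p <- stats::pf(f, q, df2, lower.tail = FALSE)
  }
  structure(list(r2_base = r2_base, r2_full = r2_full, delta_r2 = delta,
                 F_change = f, df1 = q, df2 = df2, p = p, n = n),
            class = "ssl_r2_change")
}

#' @export
print.ssl_r2_change <- function(x, ...) {
  cat(sprintf(
    "Hierarchical OLS: R2 %.3f -> %.3f (dR2 = %.3f); F_change(%d, %d) = %.2f, p = %.4g\n",
    x$r2_base, x$r2_full, x$delta_r2, x$df1, x$df2, x$F_change, x$p))
  invisible(x)
}

#' Correlation battery against ROI metabolism columns
#'
#' Convenience loop over [pearson_r()]: correlates each score column with
#' each ROI FDG-ratio column, pairwise-complete, mirroring a comparison
#' battery table (SSL and rival scores vs left/right ATL and dlPFC ratios).
#'
#' @param records scored cohort data frame.
#' @param score_cols character vector of score column names.
#' @param roi_cols character vector of ROI ratio column names.
#' @return data frame with `score`, `roi`, `r`, `n`, `p`.
#' @export
correlation_battery <- function(records,
                                score_cols = "ssl",
                                roi_cols = c("atl_left", "atl_right",
                                             "dlpfc_left", "dlpfc_right")) {
  score_cols <- intersect(score_cols, names(records))
  roi_cols <- intersect(roi_cols, names(records))
  grid <- expand.grid(score = score_cols, roi = roi_cols,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ct <- tryCatch(pearson_r(records[[grid$score[i]]], records[[grid$roi[i]]]),
                   ssl_undefined_correlation = function(e) NULL)
    if (is.null(ct)) c(r = NA_real_, n = NA_real_, p = NA_real_)
    else c(r = ct$r, n = ct$n, p = ct$p)
  })
  cbind(grid, do.call(rbind, res))
}
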