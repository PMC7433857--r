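# Component scores and the omnibus SSL composite.

test_that("cue_retrieval_score matches hand-computed proportions", {
  expect_equal(cue_retrieval_score(51, 61), 10 / 13)
  expect_equal(cue_retrieval_score(11, 11), 0)
  expect_equal(cue_retrieval_score(57, 64), 1)
})

test_that("cue_retrieval_score rejects degenerate and invalid input", {
  expect_error(cue_retrieval_score(64, 64), class = "ssl_no_missed_items")
  expect_error(cue_retrieval_score(12, 11), class = "ssl_invariant_violation")
  expect_error(cue_retrieval_score(-1, 5), class = "ssl_invalid_input")
  expect_error(cue_retrieval_score(10, 65), class = "ssl_invalid_input")
})

test_that("aggregate consistency score reconstructs, clamps and flags", {
  expect_equal(as.numeric(consistency_score_aggregate(51, 63)), 12 / 13)
  expect_equal(as.numeric(consistency_score_aggregate(31, 45)), 14 / 33)
  expect_equal(as.numeric(consistency_score_aggregate(10, 10)), 0)
  # WPMT below spontaneous naming: raw value negative, clamped to 0
  clamped <- consistency_score_aggregate(30, 20)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  expect_false(attr(consistency_score_aggregate(31, 45), "clamped"))
  expect_error(consistency_score_aggregate(64, 60),
               class = "ssl_no_missed_items")
})

test_that("non-canonical cued baseline measures misses relative to cued naming", {
  # 51 cued-correct, 43 recognized: (43 - 51) / (64 - 51) clamps to 0;
  # canonical spontaneous baseline gives (43 - 27) / (64 - 27)
  v <- consistency_score_aggregate(27, 43, baseline = "cued", cued_correct = 51)
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "clamped"))
  expect_equal(as.numeric(consistency_score_aggregate(27, 43)), 16 / 37)
  expect_error(consistency_score_aggregate(27, 43, baseline = "cued"),
               class = "ssl_invalid_input")
})

test_that("item-level consistency uses exactly the missed items", {
  items <- make_items(naming = 51, cue_hits = 10, rec_miss = 12)
  expect_equal(consistency_score_items(items), 12 / 13)
  none <- make_items(naming = 51, cue_hits = 10, rec_miss = 0)
  expect_equal(consistency_score_items(none), 0)
  all_named <- make_items(naming = 64, cue_hits = 0, rec_miss = 0)
  expect_error(consistency_score_items(all_named),
               class = "ssl_no_missed_items")
})

test_that("item-level and aggregate consistency diverge when named items go unrecognized", {
  # naming 31, three named items NOT recognized, 17/33 missed recognized:
  # aggregate wpmt count is 28 + 17 = 45, reconstructing (45-31)/33 = 14/33,
  # but the literal item-level definition gives 17/33.
  items <- make_items(naming = 31, cue_hits = 5, rec_hit = 28, rec_miss = 17)
  rec <- as_participant_record(items, mmse = 20)
  expect_equal(rec$naming_correct, 31)
  expect_equal(rec$wpmt_correct, 45)
  expect_equal(consistency_score_items(items), 17 / 33)
  expect_equal(as.numeric(consistency_score_aggregate(31, 45)), 14 / 33)
})

test_that("item/aggregate consistency agree whenever named items are all recognized", {
  set.seed(7)
  for (i in 1:50) {
    naming <- sample(0:63, 1)
    items <- make_items(naming = naming,
                        cue_hits = sample(0:(64 - naming), 1),
                        rec_hit = naming,              # nesting holds
                        rec_miss = sample(0:(64 - naming), 1))
    rec <- as_participant_record(items, mmse = 15)
    expect_equal(
      consistency_score_items(items),
      as.numeric(consistency_score_aggregate(rec$naming_correct,
                                             rec$wpmt_correct)))
  }
})

test_that("naming_general_ratio implements x/(x+y) on proportion scores", {
  expect_equal(naming_general_ratio(32, 15), 0.5)   # equal proportions
  expect_equal(naming_general_ratio(51, 19),
               (51 / 64) / (51 / 64 + 19 / 30))
  expect_equal(naming_general_ratio(10, 0), 1)      # y = 0 limit
  expect_equal(naming_general_ratio(0, 10), 0)
  expect_error(naming_general_ratio(0, 0), class = "ssl_undefined_ratio")
})

test_that("ssl_score reproduces worked examples and the all-maximal case", {
  mr <- ssl_score(51, cued_correct = 61, wpmt_correct = 63, mmse = 19)
  expect_equal(mr$ssl, ssl_oracle(51, 61, 63, 19))
  expect_equal(round_display(mr$ssl), 0.75)
  expect_equal(mr$ssl, 0.7498, tolerance = 1e-3)

  mc <- ssl_score(12, cued_correct = 16, wpmt_correct = 24, mmse = 17)
  expect_equal(round_display(mc$ssl), 0.19)
  expect_equal(mc$ssl, 0.1854, tolerance = 1e-3)

  top <- ssl_score(63, cued_correct = 64, wpmt_correct = 64, mmse = 0)
  expect_equal(c(top$c_cue, top$c_consistency, top$c_ratio), c(1, 1, 1))
  expect_equal(top$ssl, 1)
})

test_that("ssl_score dispatches on records and item outcomes", {
  rec <- participant_record("MR", 51, 61, 63, 19)
  expect_equal(ssl_score(rec)$ssl, ssl_oracle(51, 61, 63, 19))
  expect_true("aggregate-mode" %in% ssl_score(rec)$flags)

  items <- make_items(naming = 51, cue_hits = 10, rec_miss = 12)
  by_items <- ssl_score(items, mmse = 19)
  expect_equal(by_items$ssl, ssl_oracle(51, 61, 63, 19))
  expect_false("aggregate-mode" %in% by_items$flags)
})

test_that("ssl is always the exact mean of its components, in [0, 1]", {
  set.seed(11)
  for (i in 1:200) {
    r <- random_record()
    s <- ssl_score(r$naming, cued_correct = r$cued,
                   wpmt_correct = r$wpmt, mmse = r$mmse)
    expect_identical(s$ssl, (s$c_cue + s$c_consistency + s$c_ratio) / 3)
    expect_true(s$ssl >= 0 && s$ssl <= 1)
    expect_true(all(c(s$c_cue, s$c_consistency, s$c_ratio) >= 0))
    expect_true(all(c(s$c_cue, s$c_consistency, s$c_ratio) <= 1))
  }
})

test_that("ssl is monotone in cued naming, WPMT and (inversely) MMSE", {
  set.seed(13)
  for (i in 1:100) {
    r <- random_record()
    base <- ssl_score(r$naming, cued_correct = r$cued,
                      wpmt_correct = r$wpmt, mmse = r$mmse)$ssl
    if (r$cued < 64) {
      expect_gte(ssl_score(r$naming, cued_correct = r$cued + 1,
                           wpmt_correct = r$wpmt, mmse = r$mmse)$ssl, base)
    }
    if (r$wpmt < 64) {
      expect_gte(ssl_score(r$naming, cued_correct = r$cued,
                           wpmt_correct = r$wpmt + 1, mmse = r$mmse)$ssl, base)
    }
    if (r$mmse < 30) {
      expect_lte(ssl_score(r$naming, cued_correct = r$cued,
                           wpmt_correct = r$wpmt, mmse = r$mmse + 1)$ssl, base)
    }
  }
})

test_that("score_cohort scores the reference cohort and keeps unscorable rows", {
  fx <- load_fixture()
  sc <- score_cohort(fx)
  expect_equal(nrow(sc), 28)
  expect_true(all(sc$scorable))
  expect_equal(sum(sc$ssl_display == fx$ssl_printed), 26)

  degenerate <- data.frame(participant_id = c("a", "b"),
                           naming_correct = c(64, 0),
                           cued_correct = c(64, 0),
                           wpmt_correct = c(64, 10),
                           mmse = c(30, 0))
  sc2 <- score_cohort(degenerate)
  expect_false(any(sc2$scorable))
  expect_equal(sc2$flags, c("no-missed-items", "undefined-ratio"))
  expect_true(all(is.na(sc2$ssl)))
})

test_that("score_cohort handles empty input and rejects duplicate ids", {
  fx <- load_fixture()
  empty <- fx[0, ]
  expect_equal(nrow(score_cohort(empty)), 0)
  expect_error(score_cohort(fx[c(1, 1), ]), class = "ssl_invalid_input")
  expect_error(score_cohort(fx[, -1]), class = "ssl_invalid_input")
})

test_that("participant_record and item_outcomes enforce their invariants", {
  expect_error(participant_record("x", 10, 9, 20, 15),
               class = "ssl_invariant_violation")
  expect_error(participant_record("x", 10, 12, 20, 31),
               class = "ssl_invalid_input")
  expect_error(participant_record("x", 10, 12, 20, 15,
                                  roi_ratios = c(atl_left = -0.2)),
               class = "ssl_invalid_input")
  expect_error(item_outcomes(rep(TRUE, 63), rep(NA, 63), rep(TRUE, 63)),
               class = "ssl_invalid_input")
  # named_with_cue must be defined on misses
  expect_error(item_outcomes(rep(FALSE, 64), rep(NA, 64), rep(TRUE, 64)),
               class = "ssl_invalid_input")
})

test_that("display rounding goes half away from zero", {
  expect_equal(round_display(0.505), 0.51)
  expect_equal(round_display(0.125, 2), 0.13)
  expect_equal(round_display(-0.125, 2), -0.13)
  expect_equal(round_display(0.7497), 0.75)
})
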