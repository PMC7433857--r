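# Shared test helpers.

# Build an item_outcomes object from target counts:
#   naming   spontaneous hits
#   cue_hits misses recovered with a cue
#   rec_hit  spontaneously named items also recognized in matching
#   rec_miss missed items recognized in matching
make_items <- function(naming, cue_hits, rec_hit = naming, rec_miss,
                       n_items = 64L) {
  stopifnot(naming <= n_items, cue_hits <= n_items - naming,
            rec_hit <= naming, rec_miss <= n_items - naming)
  named <- rep(c(TRUE, FALSE), c(naming, n_items - naming))
  cue <- rep(NA, n_items)
  cue[!named] <- rep(c(TRUE, FALSE), c(cue_hits, n_items - naming - cue_hits))
  recog <- logical(n_items)
  recog[which(named)[seq_len(rec_hit)]] <- TRUE
  recog[which(!named)[seq_len(rec_miss)]] <- TRUE
  item_outcomes(named, cue, recog, n_items = n_items)
}

# Direct-formula oracle for the omnibus score from aggregate counts,
# written independently of the component functions.
ssl_oracle <- function(naming, cued, wpmt, mmse,
                       naming_max = 64, mmse_max = 30) {
  c1 <- (cued - naming) / (naming_max - naming)
  c2 <- max(0, (wpmt - naming) / (naming_max - naming))
  x <- naming / naming_max
  y <- mmse / mmse_max
  (c1 + c2 + x / (x + y)) / 3
}

# Random valid aggregate counts for property tests.
random_record <- function() {
  naming <- sample(0:63, 1)
  mmse <- sample(0:30, 1)
  if (naming == 0 && mmse == 0) mmse <- 1
  list(naming = naming,
       cued = naming + sample(0:(64 - naming), 1),
       wpmt = sample(0:64, 1),
       mmse = mmse)
}
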