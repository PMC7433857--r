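# sslscore

Quantifies the degree of **semantic storage loss** — loss of amodal concept
representations, the impairment underlying cue-resistant, cross-task
consistent anomia — in an individual with primary progressive aphasia (PPA)
or related neurodegenerative disease. It is written for clinical
neuropsychology researchers who have a 64-item confrontation-naming battery
(spontaneous + phonemic-cued naming and word–picture matching) and an MMSE
for each participant, and who want a graded score rather than a binary
impaired/normal classification.

## The score

With $N$ = spontaneous naming correct (max 64), $C$ = cumulative cued
naming correct ($C \ge N$), $W$ = word–picture matching correct (max 64)
and $M$ = MMSE (max 30), the semantic storage loss (SSL) score is the mean
of three components, each in $[0, 1]$:

$$\mathrm{SSL} = \frac{1}{3}\left[
  \underbrace{\frac{C-N}{64-N}}_{\text{cue recovery}} +
  \underbrace{\frac{W-N}{64-N}}_{\text{consistency}} +
  \underbrace{\frac{x}{x+y}}_{\substack{\text{naming:cognition}\\ x=N/64,\; y=M/30}}
\right]$$

Scores near **0** indicate severe storage loss (cues don't help, the same
items fail in comprehension, naming is poor out of proportion to general
cognition — the semantic-variant-PPA profile); scores near **1** indicate
anomia better explained by access/processing failure or global impairment.

The package also provides normative screening (mean − 2 SD cut-offs),
the validation statistics (one-way ANOVA + Scheffé post hoc, Pearson
correlations with two-tailed t-transform p values, hierarchical regression
with the R²-change F test), a reproducible item-level cohort simulator with
latent-trait-coupled regional FDG-uptake ratios, and a CLI.

## Worked example

```r
library(sslscore)

# one participant: naming 51/64, cued 61/64, WPMT 63/64, MMSE 19/30
ssl_score(51, cued_correct = 61, wpmt_correct = 63, mmse = 19)
#> SSL components: cue 0.7692 | consistency 0.9231 | naming:MMSE 0.5572
#> SSL score: 0.7498 (display 0.75)  [aggregate-mode]
```

The three components read: 77% of the 13 naming failures were recovered
with a cue, 92% of them were still recognized in matching, and naming
slightly outstrips general cognition (0.56 > 0.5) — cue-responsive,
inconsistent anomia, i.e. *little* storage loss (SSL 0.75).

The embedded 28-participant reference cohort (11 nfvPPA, 5 svPPA, 12
lvPPA) scores in one call:

```r
fx <- load_fixture()
sc <- score_cohort(fx)
head(sc[, c("participant_id", "group_label", "ssl", "ssl_display", "flags")], 4)
#>   participant_id group_label       ssl ssl_display          flags
#> 1             KD      nfvPPA 0.6127845        0.61 aggregate-mode
#> 2             MR      nfvPPA 0.7498273        0.75 aggregate-mode
#> 3             BJ      nfvPPA 0.8294308        0.83 aggregate-mode
#> 4             LR      nfvPPA 0.7803030        0.78 aggregate-mode

group_summary(sc$ssl, sc$group_label)
#>    group  n      mean         sd
#> 1 nfvPPA 11 0.6827648 0.11341919
#> 2  svPPA  5 0.2882382 0.09249295
#> 3  lvPPA 12 0.5005066 0.11767349
```

The group ordering (non-fluent ≈ 0.68 > logopenic ≈ 0.50 > semantic ≈
0.29) matches the expectation that storage loss is mildest in nfvPPA and
most severe in svPPA; `oneway_anova()` / `scheffe_posthoc()` confirm all
three pairwise contrasts are significant at α = 0.05. Recomputation
reproduces 26 of the 28 originally reported 2-decimal scores exactly (see
`load_fixture()` docs and the vignette for the two flagged rows).

## Command line

```sh
SSLSCORE=$(Rscript -e 'cat(system.file("exec", "sslscore", package = "sslscore"))')
Rscript "$SSLSCORE" score --fixture                 # scored CSV on stdout
Rscript "$SSLSCORE" summarize --fixture --var ssl_printed
Rscript "$SSLSCORE" simulate --n 100,100,100 --seed 1 --out sim/
Rscript "$SSLSCORE" screen --input cohort.csv --naming-cutoff 60
```

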