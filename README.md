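# endocomm

Community-diversity analysis for culturable fungal endophyte isolation
surveys.

In a culturable-endophyte survey, surface-sterilized plant fragments (stem
segments, typically) are plated on nutrient media and every fungus that
emerges is recorded as one isolation event: *which species emerged from
which fragment of which plant, on which medium, from which stem-age class*.
`endocomm` takes such record tables and computes the statistics this kind of
study reports:

- **Colonization accounting** — colonization rate
  `CR% = 100 · (fragments yielding ≥ 1 isolate) / (fragments plated)` and
  per-species colonization frequency
  `CF% = 100 · (fragments colonized by the species) / (fragments plated)`,
  with the counting rule that a species isolated twice from one fragment
  counts once, while distinct species co-colonizing a fragment all count.
- **Alpha diversity** — Margalef richness `d = (S−1)/ln N`, Brillouin
  `HB = (ln N! − Σᵢ ln nᵢ!)/N` (via log-gamma), Simpson's index of diversity
  `1 − D = 1 − Σ (nᵢ/N)²` (plug-in; the unbiased
  `1 − Σ nᵢ(nᵢ−1)/(N(N−1))` is also exposed), and Fisher's log-series alpha,
  the root of `S = α·ln(1 + N/α)` found by bracketed root search (with the
  `S = N` degenerate case returned as a flagged 0 sentinel).
- **Beta diversity** — Sorensen–Dice similarity `QS = 2C/(A+B)` on
  presence/absence sets, pairwise similarity matrices, and an exact
  zero-similarity census.
- **Clustering** — UPGMA on `1 − QS` dissimilarities with deterministic
  tie-breaking, species-column bootstrap supports, and Newick export.
- **Simulation** — a log-series survey generator (`generateSurvey`) with
  tunable host specificity, per-species medium preference and per-fragment
  colonization probability, so every stage is testable end to end and
  Fisher's-alpha parameter recovery can be asserted.

The package ships fixtures transcribing the printed occurrence tables of a
published ten-plant *Artemisia thuscula* survey from the Canary Islands
(La Palma and Tenerife) and reproduces its diversity statistics exactly;
`reproduceReference()` reports every comparison, including the four printed
values that are *not* recoverable from the published tables (kept as
documented expected mismatches).

Data live in Bioconductor-style containers: `OccurrenceExperiment` extends
`SummarizedExperiment` (species × samples counts, fragment totals in
`colData`), similarity matrices are a small validated S4 class, and trees
interoperate with `ape::phylo`.

## Worked example

```r
library(endocomm)

t5 <- loadFixture("table5")            # CF table + reconstructed records
oe <- buildOccurrenceMatrix(t5$records, "plant_id", t5$frame_totals)

head(colonizationRate(oe), 4)
#>   sample_id colonized_fragments total_fragments cr_percent
#> 1       LP1                  14              29   48.27586
#> 2       TF8                   2               8   25.00000
#> 3       TF7                   2               8   25.00000
#> 4       TF4                   4               8   50.00000

diversityProfile(oe, round = TRUE)[c(1, 2, 8), ]
#>   sample_id  S  N margalef brillouin simpson_1d fisher_alpha degenerate_fisher
#> 1       LP1 11 23     3.19      1.63       0.84         8.27             FALSE
#> 2       TF8  2  2     1.44      0.35       0.50         0.00              TRUE
#> 8       LP2 15 38     3.85      1.82       0.84         9.15             FALSE

ss <- t5$species_sets
roundHalfUp(100 * sorensenDice(ss$TF2, ss$TF7), 0)   # 57 (%)
zeroSimilarityCensus(similarityMatrix(ss))           # 14 of 45 pairs disjoint

tree <- bootstrapSupport(oe, n_iter = 1000, seed = 1)
```

LP1 has 14 of 29 fragments colonized (CR 48.28%); its 11 species over 23
colonized-fragment counts give Margalef 3.19 and a finite Fisher's alpha,
while TF8 — two species, each on one fragment — is the degenerate `S = N`
case where the log-series alpha diverges and the flagged sentinel 0 is
reported. TF2 and TF7 share 2 of their 4 + 3 species (QS = 57%), and 14 of
the 45 plant pairs share no species at all. In the bootstrapped tree, the
two La Palma plants LP1 and LP2 form a strongly supported cluster and TF8
splits off at the backbone.

(Per-sample `N` here comes from the CF table's fragment counts, which the
published per-locality diversity table does not always agree with; the
diversity-table reproduction therefore runs on its own printed `(S, N)`
pairs — see `reproduceReference()` and the vignette.)

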