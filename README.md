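# fminer

Data mining for multi-ingredient herbal prescription collections.

Clinical research on traditional Chinese medicine (TCM) routinely collects
hundreds or thousands of prescriptions ("formulas"), each a set of herbs,
often with syndrome and symptom annotations. Before any statistics can be
computed these records need standardization (the same herb appears under
many variant names), and afterwards the questions are always the same ones:
which herbs and herb combinations recur, which attributes (natures, flavors,
meridian tropism, efficacy classes) dominate, which herb pairs are
positively associated, how the herbs cluster, and how similar whole
prescriptions — or whole prescription groups — are to one another. `fminer`
implements that workflow end to end for researchers and students working
with prescription datasets, as an R library plus a small command-line tool.

## The methods at its core

A prescription is a transaction: a set of standardized ingredient labels.
On the resulting binary incidence structure the package computes

* **Association rules** (Apriori): for a rule A → C,
  `support = P(A ∪ C)`, `confidence = P(C | A)`,
  `lift = confidence / P(C)`; `explore_rules()` evaluates a whole grid of
  (minimum support, minimum confidence) combinations at once, keeps only
  rules with lift > 1, and drops combinations whose rule set is empty (the
  undefined-range cases), so parameter choice is evidence-based rather than
  one arbitrary pair.
* **Phi correlation**: for two binary columns with 2×2 table (a, b, c, d),
  `phi = (ad − bc) / √((a+b)(c+d)(a+c)(b+d))`, with p-values from
  `chi² = n·phi²` on 1 df and a star matrix at p < 0.05.
* **Hierarchical clustering** under the seven standard linkages (ward.D,
  ward.D2, single, complete, average, centroid, median), with
  `k_selection()` letting a panel of twelve internal validity indices vote
  for the number of clusters.
* **Formula similarity**: Jaccard coefficient `J(A,B) = |A∩B| / |A∪B|`
  between prescriptions; the inter-group score
  `grpSimScore = (1/nm) Σᵢ Σⱼ J(Aᵢ, Bⱼ)`; a role-weighted variant using the
  classical Monarch/Minister/Assistant/Envoy ranking; and similarity
  networks thresholded at J > 0.8 with per-formula degree centrality.
* **Synthetic data**: `simulate_formulas()` generates seeded prescription
  collections with Zipf-like ingredient frequencies, planted core herb
  combinations, and controllable synonym/duplicate transcription noise, so
  the whole pipeline is testable without clinical data.

## A worked example

```r
library(fminer)

# 1. Simulate 500 prescriptions with a planted three-herb core combination
vocab <- load_fixture("attributes")$herb
cfg <- sim_config(n_formulas = 500, vocabulary_size = 60,
                  planted_motifs = list(list(items = vocab[30:32], prob = 0.8)),
                  seed = 1)
ds <- sim_dataset(simulate_formulas(cfg))
ds
#> <formula_dataset> 500 formulas, 60 distinct ingredients

# 2. Mine association rules with lift > 1
rules <- extract_rules(ds, min_support = 0.5, min_confidence = 0.7,
                       retain_lift_gt1 = TRUE, max_len = 3)
head(rules, 3)
#> # A tibble: 3 × 6
#>   antecedent     consequent support confidence  lift count
#>   <chr>          <chr>        <dbl>      <dbl> <dbl> <int>
#> 1 duzhong|taoren niuxi        0.818      0.998  1.20   409
#> 2 duzhong|niuxi  taoren       0.818      0.993  1.18   409
#> 3 niuxi|taoren   duzhong      0.818      0.993  1.17   409
```

The planted core combination (here `taoren`, `niuxi`, `duzhong`, ranks
30–32 of the vocabulary) comes out as the top rules: the trio occurs
together in 81.8% of prescriptions (the planted 80% plus background
draws), a formula containing two of the herbs contains the third over 99%
of the time (confidence), and lift > 1 marks the association as positive
rather than a frequency artifact.

```r
# 3. How many clusters do the herbs form?
m <- to_wide(ds)
kv <- k_selection(compute_distance(m, "jaccard_binary"), c(2, 8), data = m)
kv$winner
#> [1] 8
```

Here the vote lands at the top of the candidate range: apart from one
planted trio this dataset is unstructured Zipf background, so there is no
block structure for the indices to agree on. On data with genuine
co-occurrence blocks the vote concentrates — `scripts/acceptance.R` plants
two blocks and recovers k = 2 with over 90% of the votes.

## Command line

```sh
Rscript inst/cli/fminer.R simulate --n 500 --vocab 120 --seed 42 --out sim/
Rscript inst/cli/fminer.R standardize --input raw.csv --lookup lut.csv --drop-unmatched --out clean/
Rscript inst/cli/fminer.R rules-explore --input sim/sim_long.csv \
    --supports 0.05,0.1,0.2 --confidences 0.5,0.7,0.9 --out rules/
Rscript inst/cli/fminer.R jaccard --input clean/clean.csv --threshold 0.8 --out net/
```

Every command writes its CSV/GraphML artifacts plus a `manifest.json`
(package version, parameters, input checksums) into `--out`.

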