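---
title: "Mining herbal prescription datasets with fminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining herbal prescription datasets with fminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fminer)
```

## The data model

`fminer` treats a prescription collection as a set of transactions: each
formula is a *set* of standardized ingredient labels (duplicates collapsed,
order ignored), optionally annotated with syndrome, symptom and diagnosis
terms. Everything downstream — frequency tables, association rules, phi
correlation, clustering, similarity — is computed on this binary incidence
structure, materialized on demand by `to_wide()` as a formulas × herbs 0/1
matrix whose column order (total frequency descending, ties alphabetical)
is fixed so that outputs are byte-reproducible.

## Standardization

Raw clinical records name the same herb many ways. `make_lookup()` compares
a dataset against a reference lookup table and splits its distinct terms
into matched (including identity hits on the standard vocabulary) and
unmatched; `clean_dataset()` then rewrites the records and collapses
within-record duplicates.

Matching is **exact after normalization**: trim, collapse internal
whitespace, case-fold Latin letters, convert full-width ASCII and the
ideographic space to half-width. CJK ideographs are compared as-is. We
deliberately implement no fuzzy or edit-distance matching: on herb names,
one-character differences are frequently *semantic* (different herbs or
different processing), so approximate matching would silently merge
distinct entities. The cost is that genuinely equivalent spellings absent
from the lookup surface as unmatched — which is the auditable behavior we
want, since `add_reference_terms()` lets the user extend the lookup
explicitly (and refuses to overwrite an existing mapping with a different
one).

Formulas left empty after cleaning are dropped by default, with a logged
count; `keep_empty = TRUE` retains them for record-keeping.

## Attribute statistics

`calc_property()` and `calc_func()` tally the four natures, flavors,
meridian tropism and efficacy classes of the herbs in a dataset. Each
category is reported twice: the **unweighted** count is the number of
distinct herbs carrying it; the **weighted** count sums those herbs'
occurrence counts across formulas. We weight by occurrence count rather
than dose because doses are frequently absent from compiled prescription
datasets, and occurrence weighting is the only reading under which both a
weighted and an unweighted figure are well defined for every category.
Multi-valued attributes (a herb usually enters several meridians and has
more than one flavor) contribute to every category they carry, so flavor
and meridian columns do not sum to the number of herbs — only the
single-valued nature table does.

## Association rules and the parameter grid

The miner is a textbook level-wise Apriori with candidate join and prune;
`max_len` (default 5) bounds itemset size, which matters on dense herbal
data where a handful of tonic herbs co-occur very widely. Rules default to
singleton consequents (one rule per frequent itemset and consequent item,
the convention users of rule-mining software expect); multi-item
consequents sit behind `multi_consequent = TRUE`. Rule order is fixed
(lift desc, support desc, then lexicographic) for reproducibility.

Choosing minimum support and confidence by trial and error is the weak
point of most published prescription-mining analyses. `explore_rules()`
evaluates the full support × confidence grid in one call — it mines once at
the loosest thresholds and filters per cell, which is exactly equivalent to
re-mining per cell but much cheaper. Grid cells whose rule set is empty
have undefined range statistics; rather than propagating infinities we drop
them from the returned table and keep the complete grid (with
`n_rules = 0`) in the `full_grid` attribute for bubble-chart export. Within
`explore_rules()` only rules with lift strictly greater than 1 are counted,
since a rule at or below lift 1 describes no positive association.

## Phi correlation

For binary columns the Pearson correlation reduces to the phi coefficient
of the 2×2 table, and the chi-square statistic is `n·phi²` on 1 df. We use
that identity for the p-values and therefore apply **no continuity
correction** by default (`yates = TRUE` is available); the star matrix
marks p < 0.05. No multiple-testing correction is applied — with hundreds
of herb pairs the stars are descriptive screening marks, not confirmatory
tests, and users needing error control should adjust `p` themselves.
Zero-variance columns (an ingredient present in every formula or none)
have undefined phi; we report 0 with p = 1 and flag the column rather than
propagate NaN through downstream clustering.

## Clustering and the cluster-number vote

Items are clustered on either binary Jaccard distance or `1 − phi`
(clipped to [0, 2]). Agglomeration delegates to `stats::hclust()`, whose
seven method tags are exactly the linkages exposed here; `ward.D` applies
Ward's update to raw dissimilarities and `ward.D2` to squared ones (the
two conventions both in circulation), and `centroid`/`median` may show
height inversions, which is inherent to those linkages.

`k_selection()` cuts one tree (default `ward.D2`, configurable) at each
candidate k and lets a panel of internal validity indices vote. The panel
is twelve documented indices — silhouette, Calinski–Harabasz,
Davies–Bouldin, Dunn, C-index, McClain–Rao, point-biserial, Baker–Hubert
gamma, G+, Xie–Beni, a within-dispersion elbow (maximum second
difference), and Ratkowsky–Lance. The contract is the *vote*, not the
identity of the indices; we chose indices with standard distance-based
formulations, using cluster medoids where a classical definition needs
centroids, so that any dissimilarity can be voted on. Two caveats are
intentional:

* Ratkowsky–Lance needs per-variable between-group sums of squares, i.e.
  the underlying binary matrix, not just distances; it is skipped (with a
  message) when `data` is not supplied.
* An index that fails on a degenerate partition (e.g. all-singleton
  clusters) is excluded from the tally with a warning rather than
  invalidating the vote.

Ties for the winning k resolve to the smallest k, on parsimony grounds.

## Formula similarity

`calc_jaccard()` returns the full matrix and a pair table filtered at
`J ≥ threshold`; `similarity_network()` keeps edges with `J > threshold`
**strictly** — the conventional cut for "highly similar" prescriptions is
J > 0.8 — and computes degree centrality normalized by (n − 1). The
asymmetry (≥ for the table, > for the network) is deliberate and
documented: the table is a report, the network cut follows the strict
convention. The inter-group score is the mean Jaccard over all n×m cross
pairs; it is symmetric and equals 1 exactly when every cross pair is
identical.

`wt_similarity()` generalizes Jaccard with the classical
Monarch/Minister/Assistant/Envoy role ranking: the score is the
role-weight mass of the shared herbs over the role-weight mass of the
union, with non-core herbs at the `unassigned` weight. No canonical
weighting exists in the literature; the defaults (4, 3, 2, 1, 1) encode
the role hierarchy and are fully configurable, and with all weights equal
the score provably reduces to plain Jaccard (a property the test suite
checks). Dose-aware similarity is out of scope.

## The synthetic generator

`simulate_formulas()` emulates the structural features of compiled
prescription datasets that the pipeline must handle:

* **Zipf rank-frequency** ingredient usage (default exponent 1.0): a few
  workhorse herbs carry most occurrences, with a long tail — the
  heavy-tailed shape real herb-frequency tables show.
* **Planted motifs**: core herb combinations included wholesale with a set
  probability, the ground-truth analogue of the recurring combinations
  rule mining is meant to find.
* **Transcription noise**: synonym swaps (a standardized term replaced by
  a raw variant from the packaged lookup) and duplicated entries — the two
  artifacts standardization is there to undo.

Defaults are 6–15 ingredients per formula over a 120-term vocabulary,
plausible for compiled clinical collections. The generator emits its
ground truth (motif membership, term map) alongside the records, so tests
never reverse-engineer it from output. What it does **not** emulate:
dose structure, syndrome-conditional ingredient choice, temporal or
source-lineage structure, and correlated background herbs beyond the
planted motifs. Passing tests on simulated data therefore demonstrate
correctness of the computations, not clinical validity of any particular
threshold choice on real data.

The packaged fixtures (`load_fixture()`: lookup, attributes, classics) are
small synthetic stand-ins with plausible but non-authoritative content;
their filenames carry the `synthetic_` prefix and they must not be used as
a pharmacopoeia reference.

## Numerical and scale choices

Support thresholds are compared with a 1e-12 slack so that counts at the
exact boundary are kept regardless of floating-point representation.
Lift retention is strict (`> 1`). Dissimilarities from `1 − phi` are
clipped to [0, 2]. The test suite's problem sizes — 200 random transaction
sets of ≤ 10 items for the oracle-equivalence checks, 100 random ≤ 8-item
matrices for the linkage cross-check against an independent
Lance–Williams implementation, 2000 simulated formulas for motif
recovery — are chosen so that exhaustive brute-force oracles remain exact
and the whole suite runs in about a minute on one CPU.
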