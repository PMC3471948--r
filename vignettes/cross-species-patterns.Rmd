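---
title: "Comparing stage-wise expression changes across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing stage-wise expression changes across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossexpr)
```

## The problem

During preimplantation development, the transition from morula to
blastocyst produces the first two distinct cell populations: the
trophoblast and the inner cell mass (ICM), from which embryonic stem
cells are derived. Mouse and rat embryos pass through the same stages
but differ markedly in how easily stable embryonic stem cells can be
established from them, so a natural question is which genes change
expression *differently* between the two species as these populations
form.

`crossexpr` implements a comparative workflow for exactly this design:
two species, three cell populations (morula, blastocyst, ICM), and a
small number of replicate expression profiles per stage (two in the
emulated design — far too few for per-gene variance estimation, which
is why the method works with fold-change heuristics rather than
statistical tests). The input is a summarized gene-level log2
expression matrix per species (e.g. RMA output), a mouse-to-rat
ortholog translation table, and optionally gene-set collections
(pathways, gene families) in GMT format.

## The method

**Fold changes.** For each species, the per-gene mean log2 signal is
computed per stage, and the fold change of a comparison is the
difference of the two stage means — a log2 ratio. The three canonical
comparisons are blastocyst vs morula (`B_vs_M`), ICM vs blastocyst
(`ICM_vs_B`) and ICM vs morula (`ICM_vs_M`). Because the stage means
are computed once and reused, the fold changes are exactly additive:
`FC(ICM_vs_M) = FC(ICM_vs_B) + FC(B_vs_M)` for every gene, and
reversing a comparison negates its fold change. Both identities are
enforced by the test suite at `1e-12`.

**Threshold selection and Venn overlaps.** Within each species, genes
are selected per comparison at a log2 fold-change threshold, by default
at the two canonical values 1.5 and 3. Selection is on the absolute
value with a strict inequality: fold-change thresholds are magnitudes
of change in either direction, and downregulated genes matter as much
as upregulated ones. The three per-comparison selections feed a
three-set Venn decomposition (7 regions, exact set algebra). Because
`|FC| > 3` implies `|FC| > 1.5`, the stricter selection is always
nested in the looser one.

**Heatmap selection.** For a global view, the top `n` genes by
absolute fold change in each comparison (default `n = 20`) are pooled;
their union is row-centered (each gene's mean log2 value subtracted)
and clustered. Note that additivity couples the comparisons: a gene
with a large fold change in one comparison necessarily has a large one
in at least one other, so the three top lists typically overlap very
little but can never be built to be "large in exactly one comparison"
in absolute terms.

**Cross-species pairing and pattern classification.** Fold changes of
the two species are joined through the ortholog table. The table may
be many-to-many; by default every ortholog pair is expanded to its own
row (a `one_to_one` filter is available). Pairs with either gene
unmeasured are dropped and tallied in a coverage report. Each pair is
then labelled per comparison by two interval heuristics on the log2
scale:

* **similar** — the two fold changes differ by less than 0.2;
* **different** — they differ by more than 0.4 *and* both exceed 0.2
  in absolute value, which keeps the pair off the scatterplot diagonal
  while excluding genes that are simply not differentially expressed
  in one of the species;
* **neither** — everything else, including the gap band where the
  difference lies between 0.2 and 0.4.

All three inequalities are strict, so boundary values fall to
`neither`; the labels are a partition by construction (verified
exhaustively against an independent re-evaluation of the inequalities
on a 6,561-point grid). On scatterplots the labels map to red, green
and black points respectively. The classification is per comparison
and symmetric in the two species.

**Gene-set summaries.** Gene sets are defined on species-A identifiers
and restricted through the ortholog map, mirroring a mouse-anchored
pathway extraction; per set and comparison the label counts and the
ranked list of "different" genes (largest inter-species gap first) are
reported.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| selection `threshold` | 1.5 and 3 | log2 | per-species gene selection |
| `t_similar` | 0.2 | log2 | max gap for "similar" |
| `t_different` | 0.4 | log2 | min gap for "different" |
| `t_min` | 0.2 | log2 | min per-species activity for "different" |
| `top_n` | 20 | genes | heatmap selection per comparison |

The constraint `t_different >= t_similar >= 0` is enforced; raising
`t_similar` can only grow the similar class and raising `t_different`
can only shrink the different class (tested as monotonicity
properties).

## Numerical and design choices

* **Tie-breaking** is deterministic everywhere: `|FC|` descending,
  then gene identifier ascending. Selections and top-N lists are
  therefore reproducible byte for byte.
* **Clustering** uses Euclidean distance with average linkage on
  row-centered values. Centering (rather than z-scoring) removes the
  baseline while preserving fold-change magnitudes across genes, so a
  gene changing by 4 log2 units still looks different from one
  changing by 1. Distance and linkage are a common heatmap default;
  they are recorded in the heatmap spec so figures are traceable.
* **Replicate aggregation** is the unweighted arithmetic mean of log2
  values. With two replicates per stage there is no basis for
  variance moderation, and none is attempted.
* **Profile plots** use the figure stage order morula, ICM,
  blastocyst, which is not temporal order but keeps the pluripotent
  populations adjacent.
* **Degenerate inputs**: empty selections, empty pairings (with a
  warning), all-constant genes (cluster at distance zero after
  centering) and single-gene tables are all defined behavior covered
  by tests.

## What the simulator emulates — and what it does not

`simulate_bundle()` generates the full study design: two species,
three stages, `n_replicates = 2` samples per stage, per-gene baselines
`Normal(8, 2)` on the log2 scale and per-replicate noise
`Normal(0, noise_sd)` with `noise_sd = 0.15` by default — values
chosen once to resemble RMA-scale microarray summaries; they are
configuration, not estimates from any dataset. Each ortholog pair is
planted in one of four classes (default mix 0.7 / 0.1 / 0.1 / 0.1):

* `null` — no stage effects; the true fold-change gap is 0, so the
  expected label is "similar";
* `concordant` — identical stage-effect vectors (magnitude
  `effect_size = 1`) in both species, again "similar" by construction;
* `discordant` — stage effects `(0, s, 2s)` vs `(0, s+g, 2(s+g))`
  with `s = effect_size / 2` and gap `g = discordant_gap = 1`, giving
  per-comparison gaps `(g, g, 2g)` and every true `|FC| >= s = 0.5`:
  the "different" conditions hold with margin in all three comparisons;
* `species_specific` — an effect in one species only; the gap is large
  but one fold change is 0, so the expected label is "neither" — this
  class exists precisely to exercise the `t_min` exclusion.

Expected labels are always computed from the *noise-free* fold changes,
so ground truth is unambiguous and at `noise_sd = 0` the pipeline must
reproduce it exactly (it does, as a test asserts). At `noise_sd = 0.05`
with two replicates, the fold-change estimator of each species has
standard deviation `noise_sd` and the cross-species gap estimator
`noise_sd * sqrt(2) ~ 0.071`; the planted margins then sit 6-8.5
standard deviations from the thresholds, which is why the recovery
tests can demand sensitivities above 0.99 from an analytic argument
rather than a tuned one.

The simulator also plants an `unpaired_fraction` (5%) of genes
measured but absent from the ortholog map, and a
`many_to_many_fraction` (2%) of duplicated species-A partners sharing
a species-B gene and truth class, to exercise the coverage report and
the expansion policy. Everything is driven by one seed and is
byte-reproducible.

What it does **not** emulate: probe-level intensities, array spatial
artifacts, normalization effects, correlated noise between genes,
pooling heterogeneity across embryos, or any biological pathway
structure beyond the planted classes. A pipeline that passes the
recovery tests is therefore shown to implement the *method* correctly
under its own assumptions — not to guarantee biological findings on
real arrays.

Test and validation problem sizes (1,000-gene algebra checks,
1,000 random Venn triples, 2,000-pair recovery runs) were chosen as
the smallest sizes at which the multinomial class counts and
recovery-rate estimates are stable to well under the margins being
asserted.

## A worked run

```{r example}
bundle <- simulate_bundle(simulation_config(n_pairs = 500, seed = 7))
fc_a <- compute_fold_changes(bundle$dataset_a)
fc_b <- compute_fold_changes(bundle$dataset_b)
paired <- pair_fold_changes(fc_a, fc_b, bundle$map)
labelled <- classify_table(paired)
attr(labelled, "label_counts")

recovery <- evaluate_recovery(labelled, bundle$truth)
recovery$rates
```

The whole chain, including threshold selections, Venn counts, gene-set
summaries, figures and a manifest with checksums, runs from one
configuration via `run_pipeline()`; see the README for the file-level
interface.

## Known limitations

* No statistical testing: with two replicates the heuristics are the
  method, and no p-values or FDR control are offered or implied.
* Many-to-many ortholog expansion means one gene can contribute
  several scatterplot points; collapse to one-to-one pairs with
  `one_to_one = TRUE` if that matters for an analysis.
* The classification thresholds are fixed tuning constants on the
  log2 scale, not estimated quantities; sensitivity to them can be
  explored via `classification_params()` but the defaults are part of
  the method definition.
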