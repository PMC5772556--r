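---
title: "Predicting CRP regulatory roles from binding-site sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting CRP regulatory roles from binding-site sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crproles)
```

## The problem

The cAMP–CRP complex binds 22-bp palindromic sites in *E. coli* promoters
and either activates transcription (typically by recruiting RNA polymerase
from an upstream position) or represses it (typically by occluding the
polymerase footprint or the early transcribed region). Classic positional
heuristics — Class I sites centred near −61.5, Class II near −41.5,
Class III multi-site promoters — only describe activation, and say nothing
about when CRP represses. This package predicts the role (activator vs
repressor) of a site from two kinds of information: where the site sits on
the TSS-relative axis, and which short motifs its sequence contains.

Two complementary predictors are provided: a black-box RBF-SVM trained on a
wrapper-selected feature subset, and a white-box four-rule classifier whose
antecedents a biologist can read directly.

## Coordinate conventions

All coordinates are TSS-relative with the TSS at 0 and downstream positive.
A site occupies the closed integer interval `[left, right]`, one nucleotide
per integer. Minus-strand sites are reflected about the TSS at parse time
(`rel = tss − abs`), so "upstream" is always negative regardless of strand;
reflection is an involution and round-trips through `writeSiteTable()`.

The rules' location scalar, *Region*, defaults to the site centre
`(left + right)/2`. For even-length (22-nt) sites centres are half-integers,
which is exactly the resolution of the rule thresholds (−49.5, −70.5,
−28.5, 70.5) and of the Class I/II anchors (−61.5, −41.5). We note one
unresolved tension: the A1 region (centre ≤ −49.5) does not actually
contain the Class II anchor −41.5 under centre semantics, although the
rules are described as subsuming Class II. Leftmost-position semantics
would reconcile this, so `ruleFeatures(semantics =)` offers
`"center"` (default), `"leftmost"` and `"rightmost"`; we keep centre as the
default because the half-integer thresholds are only meaningful for centres
of even-length sites.

Whether the TSS itself is position 0 or +1 is not standardised in site
databases; we fix the origin at 0 and document it, since every interval and
window shifts consistently either way.

## Curation

`curateSites()` applies four steps in order: TF-name filter, evidence-tier
filter (strong = mutation-experiment support), removal of redundant entries
sharing a TSS with identical leftmost/rightmost coordinates (first
occurrence wins — the minimal reading of "redundant", since no tie rule is
published), and a 22-bp length filter. The step order matters only for the
log counts; the surviving set is order-independent, and curation is
idempotent. Malformed rows at parse time go to a reject report with
per-row reasons rather than being silently dropped.

The 2:1 train/test split is stratified by role. Per class, the test set
receives `floor(n/3)` sites and training the remainder; this test-first
flooring is what reproduces per-class counts such as 89/44 for a 133-site
class, where train-first flooring would give 88/45.

## The 380-feature descriptor

Sites are extended from 22 to 42 nt by adding k = 10 flanking bases per
side, so that composition features can see the immediate *cis*-regulatory
context. Flanks come from the generator's record (or a genome slice via the
`flankSource` hook); shortfalls are N-padded with a warning, and N
contributes to no k-mer window. The blocks, in fixed order:

* **4-mer counts (256)** and **3-mer counts (64)** — raw overlapping
  occurrence counts on the forward strand of the 42-mer, lexicographic over
  ACGT. Counts, not frequencies, because the rule predicate "at most two
  TTTT motifs" is a count. Whether the published motif counts were taken on
  the 22-mer or the 42-mer is not stated; we count on the extension
  (features are defined post-extension and the rule engine reuses them) and
  expose `motifSequence = "core"` as the alternative.
* **Location windows (17)** — the overlap length, in integer positions,
  between the site interval and 17 fixed promoter windows. Four windows are
  published and fixed verbatim: L3 = [−35, −10] (the polymerase −35/−10
  region), L6 = [−10, 2], L12 = [−60, 60], L15 = [−95, −35]. The other
  thirteen are not published in the main text; our defaults tile
  [−120, 60] over canonical promoter elements (distal upstream, UP-element
  region, the Class I and Class II site spans, −35 and −10 hexamer
  neighbourhoods, downstream blocks), keep the published four at their
  printed indices, and are wholly overridable via `descriptorSpec()` for a
  user holding the original supplementary catalogue.
* **Physicochemical (3)** — GC fraction, purine fraction, and the Wallace
  2(A+T) + 4(G+C) melting-temperature estimate (°C). The published trio is
  supplementary-only; these are documented defaults and overridable in
  layout.
* **Global (40)** — 4 mononucleotide fractions, 16 dinucleotide transition
  frequencies, and 20 distribution features (for each base, the normalized
  position of its first, 25 %, 50 %, 75 % and last occurrence; 0 when
  absent). Again a documented interpretation of a supplementary-only block,
  with the 4 + 16 + 20 layout stated in `globalDescriptor()`.

The dimension identity 256 + 64 + 17 + 3 + 40 = 380 is asserted at
extraction, and feature names are stable across runs and serialization.

## Feature selection: IBCGA around an RBF SVM

Selecting m of n = 380 features while maximising classifier accuracy is the
bi-objective combinatorial problem C(n, m). The IBCGA sweeps subset sizes
r = r_start … r_end in a single run: at each r it evolves a population of
exactly-r-feature masks, then inherits the population into size r + 1 by
adding one random unselected feature to each individual, exploiting the
similarity between good solutions of neighbouring sizes.

Fitness is stratified k-fold cross-validated accuracy of an RBF SVM on the
masked columns (default k = 24: with 24 training repressors this puts one
repressor per fold, maximising repressors available to each training fold).
Within a run, folds are fixed once from the seed so fitness values are
comparable and cacheable across generations.

Operator choices, where the published description is not prescriptive:

* **Crossover** — uniform crossover with repair to exactly r features
  (shared features kept, remainder drawn from the symmetric difference).
  The orthogonal-array "intelligent" crossover of the original algorithm
  family needs OA parameters that are not published; the strategy is an
  injectable function (`crossoverFun`) so it can be restored.
* **Mutation** — a single swap (one selected feature exchanged for one
  unselected), probability 0.05 per offspring.
* **Duplicate replacement** — an offspring identical to one already in the
  pool is forced through a swap mutation. With small populations, uniform
  crossover between similar parents regenerates the same masks and the
  population collapses; duplicate replacement maintains diversity without
  raising the mutation rate.
* **Elitism** — the best individual survives unchanged.
* **Tie-breaking** — among sweep sizes with equal fitness the smaller r
  wins, consistent with minimising the feature count as the second
  objective.
* **SVM parameters** — a grid search over γ and C fixes the kernel for the
  sweep, and is re-run on the winning subset. Grid ties break to the
  smallest C, then the smallest γ. No class reweighting is applied;
  stratification is the only imbalance measure.
* **Defaults** (population 50, 30 generations per r, r = 5…30) stand in for
  unpublished settings and are fully config-driven.

Everything derives from one master seed through named stage streams
(`deriveSeed(seed, stage)`), so the generator, folds, grid and evolution
are independently reproducible and a fixed seed gives a bit-identical
`SelectionResult`.

## Rule acquisition and the canonical ruleset

`fitC45()` grows a binary tree with information-gain-ratio splits at
midpoints between adjacent observed feature values — hence half-integer
thresholds on integer-valued features — with a minimum leaf size and
pessimistic pruning (Clopper–Pearson upper confidence bound on the leaf
error at CF = 0.25, the C4.5 convention). `extractRules()` converts each
root-to-leaf path into a rule, collapsing repeated bounds on one feature
into an interval; the rules partition the feature space and classify
identically to the tree.

The published four-rule classifier was derived from such raw paths by
manual inference that is not mechanically reproducible, so the package
ships the finished product as data: `canonicalRuleset()` returns A1, A2,
R1, R2 with the printed thresholds. Two encoding decisions:

* A1's paired conditions "Region ≤ −49.5 and Region ≥ 49.5" (and R1's
  analogous pair) are unsatisfiable as conjunctions; they are encoded as
  interval unions. The separately reported per-branch cover counts (87 + 1
  activators for A1; 9 + 5 repressors for R1) confirm the union reading.
* Endpoint openness follows the printed forms exactly: "2 < Region < 70.5"
  strict, "−49.5 ≤ Region < −10" half-open, the A2/R2 ranges closed.

Classification is first-match in the order A1, A2, R1, R2, with every
matching rule reported so conflicts are visible. Uncovered sites are
reported as `uncovered` by default (the ruleset is not forced to guess);
a majority fallback and delegation to the SVM (via `screenCandidates()`)
are available.

Coverage statistics mirror the published counting: a rule's *coverage* is
the fraction of its consequent class matched by its antecedent (evaluated
independently, not first-match), its *accuracy* the fraction of all
antecedent matches carrying that class.

## Evaluation

Repressor is the positive class everywhere. MCC returns 0 when its
denominator vanishes (the convention is otherwise undefined for degenerate
predictions). ROC curves sweep unique score thresholds with ties grouped,
so the trapezoid AUC equals the Mann–Whitney pairwise statistic with ties
counted half; this is asserted against an O(n²) oracle. Printing rounds to
two decimals, mirroring the field's reporting; full precision is retained.

`reconstructConfusion()` rebuilds a confusion matrix from class sizes and
two-decimal SEN/SPE (rounding TP and TN to integers); applied to the
published class sizes (24/89 training, 12/44 test) it reproduces the
printed ACC/MCC pairs (0.98/0.95 and 0.93/0.79), which the acceptance
script recomputes.

## Consensus screening

Candidate (weak-evidence) sites pass when positions 5, 7, 16 and 18 of the
22-mer are G, G, C, C — the four positions of the palindromic consensus
that dominate binding free energy. Only these four are enforced; no PWM
score and no additional TSS-distance filter are applied before screening.
Passing sites are annotated with both the model's and the ruleset's role,
and disagreements are flagged.

## The synthetic generator

`generateSites()` defines the study conditions for every test. Per site it
draws a target rule (default mixture proportional to the published cover
counts, 88 : 31 : 14 : 7, plus an uncovered tail of 29/169 so roughly
five-sixths of sites are rule-covered), places a 22-nt interval whose
centre satisfies that rule's region predicate (A1's two branches weighted
87 : 1 and R1's 9 : 5 as reported), and synthesizes a core on the full
consensus backbone with the 12 N positions randomised. Motif contents are
then planted or suppressed so that **first-match evaluation yields exactly
the target consequent**: a site assigned to a later rule whose centre also
falls in an earlier rule's region gets that earlier rule blocked (three
overlapping TTTT copies planted in a flank to exceed A1's cap; an AACG
planted to block A2). Labels flip with probability `labelNoise`; flanks are
generated and recorded so extension is exact; 5 % of sites sit exactly on
rule thresholds to stress endpoint conventions; the default size 169 and
repressor fraction 36/169 mirror the curated strong-evidence dataset.

What the generator does **not** emulate: real promoter base composition and
phylogenetic correlation between sites, genuine genomic flanks, sites whose
role contradicts the four rules (beyond independent label noise), and
lengths other than 22 bp. Passing closed-loop tests therefore show that the
pipeline is faithful to the rule semantics and the consensus constraint —
not that the published real-data accuracies transfer; those depend on a
specific database snapshot and wet-lab validation and are covered only via
the worked-example reconstructions.

## Numerical choices and problem sizes

Degenerate inputs: empty curation output is legal; a single-class response
yields a one-leaf tree; an all-N sequence gives zero physicochemical
features with a warning; `k > nchar(seq)` gives a zero k-mer vector; fold
counts reduce with a warning when a class is smaller than k. Grid and
sweep ties break deterministically (smallest C, then γ; smallest r).

Test and acceptance runs use desk-scale sizes chosen to exercise every code
path with comfortable statistical margins: 300-site closed loops (binomial
3-SD bands), a 50-feature/2-planted GA recovery repeated over ten seeds
(population 30, 20 generations per size, r = 1…5, 5-fold fitness), and
200-point oracle comparisons. These sizes are the package's own test
design; the algorithms themselves have no built-in scale limits.

## Known limitations

* The 13 unpublished location windows, the physicochemical trio and the
  global block are documented reconstructions, overridable but not
  guaranteed to match the original supplementary catalogue; consequently
  the exact published 12-feature subset is not reproducible here (it also
  requires the original database snapshot).
* The manual path-merging that produced the four published rules from raw
  C4.5 output is not automated; `extractRules()` returns raw paths.
* Region semantics ("centre" vs "leftmost") cannot be fully settled from
  the main text; both are implemented.
* The SVM is RBF-only by design; alternative kernels would enter through
  `trainModel()`'s signature without affecting the module contracts.
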