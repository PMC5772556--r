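# crproles

Predicting whether the cyclic AMP receptor protein (CRP) of *Escherichia
coli* **activates** or **represses** transcription at a given binding site,
from the site's sequence and its position relative to the transcription
start site (TSS).

CRP is a global regulator: the cAMP–CRP complex binds a 22-bp palindromic
site and, depending on where that site sits in the promoter and what it
contains, either recruits RNA polymerase (activation) or obstructs it
(repression). Classic heuristics (the Class I/II/III rules, anchored at
site centres −61.5 and −41.5) only describe activation. This package
implements a complete role predictor for people working on bacterial
regulatory genomics: curators of binding-site databases, and anyone who
wants to assign a regulatory sign to candidate TF sites.

## What it computes

Given curated 22-nt sites on a TSS-relative axis (TSS = 0, downstream
positive, minus-strand sites reflected):

1. **Descriptor** — each site, extended by k = 10 flanking bases per side to
   42 nt, is mapped to a 380-dimensional vector:
   256 4-mer counts + 64 3-mer counts + 17 promoter-window overlap lengths
   (windows L3 = [−35, −10], L6 = [−10, 2], L12 = [−60, 60],
   L15 = [−95, −35] among them) + 3 physicochemical scalars + 40 global
   sequence features.
2. **Wrapper feature selection** — the inheritable bi-objective
   combinatorial GA (IBCGA) solves C(n, m): minimise the number of selected
   features m while maximising k-fold cross-validated accuracy of an RBF
   SVM, sweeping subset sizes r = r_start … r_end in one run by inheriting
   each size-r population into size r + 1. Repressor is the positive class;
   with 24 training repressors, 24-fold CV puts one repressor per fold.
3. **Interpretable rules** — a C4.5-style gain-ratio decision tree over the
   selected features yields root-to-leaf rules; the canonical published
   four-rule classifier ships as `canonicalRuleset()`:

   | rule | Region (site centre) | motif condition | role |
   |------|----------------------|-----------------|------|
   | A1 | ≤ −49.5 or ≥ 49.5 | #TTTT ≤ 2 | activator |
   | A2 | [−70.5, −28.5] | no AACG | activator |
   | R1 | (2, 70.5) or [−49.5, −10) | no TTAC | repressor |
   | R2 | [−31, 23] | no TTAC, no GAGC | repressor |

4. **Evaluation** — confusion metrics (ACC, SEN, SPE, MCC, repressor
   positive) and tie-aware ROC/AUC.
5. **Consensus screening** — candidate sites pass when positions 5, 7, 16,
   18 of the 22-mer are G, G, C, C (the key free-energy positions of the
   palindromic consensus `NNNTGTGANNNNNNTCACANNN`), then get dual
   model/ruleset role predictions.
6. **Synthetic data** — `generateSites()` builds labeled CRP-like datasets
   (consensus backbone, rule-consistent placements, controllable label
   noise) so the whole pipeline is testable without any database access.

## Worked example

```r
library(crproles)

sites <- generateSites(synthConfig(nSites = 169, seed = 1))
sites
#> SiteSet 'synthetic-CRP': 169 site(s) (129 activator, 40 repressor, 0 unknown)
#>   extended sequences: absent

sites <- extendSites(sites, k = 10)          # 22 nt -> 42 nt
X <- extractFeatures(sites)
dim(X)
#> [1] 169 380

res <- applyRuleset(ruleFeatures(sites), canonicalRuleset())
head(res, 3)
#>              role matched first_rule n_matched
#> syn0001 activator      A1         A1         1
#> syn0002 activator      A1         A1         1
#> syn0003 activator   A1,A2         A1         2

cov <- ruleCoverage(canonicalRuleset(), ruleFeatures(sites), roles(sites))
cov$perRule[, c("rule", "coverage", "accuracy")]
#>   rule  coverage  accuracy
#> 1   A1 0.6899225 1.0000000
#> 2   A2 0.3798450 1.0000000
#> 3   R1 0.7000000 0.6829268
#> 4   R2 0.5000000 0.9090909

cm <- confusionMetrics(roles(sites), res$role)
cm
#> ConfusionMetrics (positive class: repressor)
#>   TP=29 FP=0 TN=129 FN=11
#>   ACC=0.93 SEN=0.72 SPE=1.00 MCC=0.82
```

The coverage column reads "fraction of the rule's own class matched by its
antecedent"; accuracy is the fraction of all antecedent matches that carry
the rule's role. The eleven false negatives are the repressor-labelled sites of the
generator's uncovered tail (sites upstream of −80 that match no rule and
are reported `uncovered` rather than guessed). A command-line wrapper with the same
operations (`simulate`, `curate`, `extract`, `rules`, `select`, `train`,
`predict`, `evaluate`, `screen`) is in `inst/scripts/crptool.R`.

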