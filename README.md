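# ifser — effective-range filter feature selection

`ifser` is an R package for filter feature selection on class-labeled
numeric matrices — the "few samples, thousands of features" regime of
gene-expression classification, where a selector must rank features by
intrinsic discriminability before any classifier sees the data.

It implements two related interval-geometry scores:

* **ERGS** (effective-range based gene selection): each class's values for a
  feature are summarized by the effective range
  `μ_ij ± (1 − p_j)·γ·σ_ij`, where `γ = 1.732` comes from the Chebyshev
  bound (`μ ± γσ` holds at least 2/3 of any finite-variance distribution)
  and `p_j` is the class prior. The feature weight is the normalized area
  coefficient of the pairwise *overlapping area* `OA_i = Σ_{j<k} φ_i(j,k)`
  between class ranges: small overlap relative to the hull means a
  discriminative feature.
* **IFSER** (improved feature selection based on effective range): adds the
  *including area* `IA_i = Σ_{j<k} ψ_i(j,k)` — the width of class ranges
  completely nested inside another class's range, a confusion pattern pure
  overlap cannot distinguish — and the proportion of samples actually
  trapped in the overlap and inclusion regions (`NH_i`, `GH_i`). The final
  weight is `W_i = NAC_i × (NH_i + GH_i)`, with
  `NAC_i = 1 − AC_i / max_s AC_s` and `AC_i = (OA_i + IA_i) / hull_i`.

Features are ranked by descending `W` (stable, index-tie-broken) and the
top *k* are selected. A leakage-safe leave-one-out cross-validation harness
(per-fold re-ranking, classifiers from `class`, `rpart`, `e1071` behind a
registry), a synthetic-data generator with planted informative features,
delimited-text I/O and a command-line interface round out the package.

## Worked example

```r
library(ifser)

# 2 classes x 50 samples, 200 features, 20 informative at 3 sigma
g <- generate_labeled_matrix(synthetic_spec(seed = 42))
w <- ifser_weights(g$data)
w
#> feature_weights: method = ifser, gamma = 1.732051, 200 features
#> top features: F20 (w=2), F24 (w=2), F47 (w=2), F49 (w=2), F65 (w=2), F71 (w=2)

head(as.data.frame(w), 5)
#>    name index oa ia ac nac nh gh w rank
#> 20  F20    20  0  0  0   1  1  1 2    1
#> 24  F24    24  0  0  0   1  1  1 2    2
#> 47  F47    47  0  0  0   1  1  1 2    3
#> 49  F49    49  0  0  0   1  1  1 2    4
#> 65  F65    65  0  0  0   1  1  1 2    5

length(intersect(select_top_k(w, 20), g$informative))
#> [1] 20
```

At 3σ separation a planted feature's class ranges are disjoint: zero
overlap and inclusion area (`oa = ia = ac = 0`, so `nac = 1`), no trapped
samples (`nh = gh = 1`), hence the maximal weight `w = 2`. Noise features
have heavily overlapping ranges and trapped samples, so all 20 planted
features head the ranking. Downstream accuracy confirms the selection:

```r
evaluate_loocv(g$data, k_grid = c(10, 30), classifiers = c("nn", "tree"))
#>   classifier  k10  k30
#> 1         nn 1.00 1.00
#> 2       tree 0.97 0.97
```

Real data enters through `read_labeled_matrix()` (CSV/TSV, samples-in-rows
or the transposed features-in-rows gene layout, explicit missing-value
policy), and `write_ranking_report()` writes a per-feature TSV report of
all scores.

## Command line

```sh
Rscript inst/cli/ifser.R simulate --n-per-class 50,50 --d-total 200 --out data.tsv
Rscript inst/cli/ifser.R rank --input data.tsv --method ifser --k 10 --out report.tsv
Rscript inst/cli/ifser.R evaluate --input data.tsv --classifier nn,svm --k-grid 10,30,50 --out acc.tsv
```

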