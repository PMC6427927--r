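# mstconnect

Minimum-spanning-tree (MST) analysis of wavelet-based functional brain
connectivity.

`mstconnect` is for researchers comparing resting-state fMRI functional
networks between two groups (e.g. patients vs. controls) without the
arbitrary thresholding choices that plague conventional graph analyses.
Starting from regional BOLD time series (e.g. 116 AAL regions), it builds,
per subject:

1. **Wavelet correlation matrices.** Each region's series is decomposed
   with the maximal-overlap discrete wavelet transform (MODWT, length-8
   Daubechies filter), and regions are correlated scale by scale:
   `r_ij = cov(λ_i(s), λ_j(s)) / sqrt(var λ_i(s) · var λ_j(s))`. At
   TR = 2.5 s the four scales cover 0.1–0.2, 0.05–0.1, 0.025–0.05 and
   0.0125–0.025 Hz; scale 2 is the conventional resting-state band.
   Global connectivity is summarised by **strength** (mean of column
   means), **diversity** (mean of column variances) and **zero
   correlation** (fraction of pairs not significant under the
   mutual-information test `MI = -N ln(1-r²)/2`, with `2·MI ~ χ²₁`).
2. **TOM-weighted graphs.** Non-significant correlations are zeroed and the
   topological overlap measure
   `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` re-expresses each
   edge by how much its endpoints share neighbourhoods; edge weights are
   `w_ij = min(1/TOM_ij, 100)/100`, so small weight = strong connection.
3. **Minimum spanning trees.** Prim's algorithm extracts the N-node,
   (N−1)-edge backbone; seven global tree metrics (maximum degree `k_max`,
   maximum betweenness `B_max`, diameter `d`, eccentricity `Ecc`,
   assortativity `Ass`, degree divergence `K = ⟨k²⟩/⟨k⟩`, leaf fraction
   `Lf`) locate each tree between its path-like and star-like extremes,
   and the extreme value index α of the weight distribution
   `F(x) ~ c·xᵅ` (log–log OLS slope, with its R²) diagnoses the
   strong-disorder regime in which the MST carries the network's shortest
   paths.
4. **Two-group topology.** On group-averaged matrices: superhighway
   extraction (edges removed weakest-first until the Molloy–Reed ratio
   `K < 2`; the surviving component marks the MST's information-flow
   backbone), node betweenness gain/loss with the threshold `b` =
   non-zero median of |case − control| differences, geodesic MST
   clustering (Spearman distance between hop-distance profiles,
   average linkage, dendrogram cut 0.2), hub labelling (degree > 5), and
   the survival ratio (fraction of shared tree edges).
5. **Statistics.** Wilcoxon rank-sum tests per measure with
   Benjamini–Hochberg correction, residualisation on age, sex and
   age×sex, and a 10000-iteration label-permutation test.

A synthetic-cohort generator (`synthetic_spec()`, `generate_cohort()`)
produces two-group cohorts with block-structured (lobe-wise) regional
correlation, bridging hubs, AR(1)-coloured Gaussian series and attenuated
between-block/hub coupling in the case group, so the whole pipeline is
testable without imaging data.

## Worked example

```r
library(mstconnect)

spec <- synthetic_spec(n_control = 12, n_case = 12, seed = 20)
co   <- generate_cohort(spec)          # 116 regions x 193 timepoints each
cfg  <- fc_config()                    # TR 2.5 s, scale 2, alpha 0.05, ...

scale_bands(cfg$tr_seconds, cfg$n_scales)
#>   scale   f_lo  f_hi
#> 1     1 0.1000 0.200
#> 2     2 0.0500 0.100
#> 3     3 0.0250 0.050
#> 4     4 0.0125 0.025

tbl <- cohort_measures(co, cfg)        # 24 rows x 12 measures
res <- rank_tests(residualize(tbl))
res[, c("measure", "p_adj", "direction", "significant")]
#>             measure    p_adj    direction significant
#> 1          strength 0.000234 case<control        TRUE
#> 2         diversity 0.000220 case>control        TRUE
#> 3  zero_correlation 0.000220 case>control        TRUE
#> 4             k_max 0.004652 case<control        TRUE
#> 5             B_max 0.002924 case<control        TRUE
#> 6                 d 0.000717 case>control        TRUE
#> 7               Ecc 0.000717 case>control        TRUE
#> 8               Ass 0.174853 case>control       FALSE
#> 9                 K 0.002203 case<control        TRUE
#> 10               Lf 0.000492 case<control        TRUE
#> 11            alpha 0.000234 case<control        TRUE
#> 12        r_squared 0.000234 case>control        TRUE
```

The attenuated case group shows weaker, less heterogeneous connectivity
(lower strength, more zero correlations), and its trees drift from the
star-like towards the path-like extreme (lower `k_max`/`Lf`, higher
diameter and eccentricity) — the canonical signature of network
fragmentation; assortativity stays negative and non-discriminant.

```r
mats <- lapply(co$series, subject_correlation)
grp  <- co$manifest$group
cmp  <- compare_groups(mats[grp == "case"], mats[grp == "control"], cfg)
cmp$survival_ratio        # 0.096 - the two group MSTs share ~10% of edges
cmp$betweenness$b         # 1080  - gain/loss threshold on raw betweenness
cmp$control$hubs          # 3 28 47 67 86 92 99 (the designed hubs among them)
permutation_test(tbl$strength[grp == "case"],
                 tbl$strength[grp == "control"], B = 10000, seed = 20)$p
#> 2e-04
```

Trees can be serialised with node/edge annotations via
`write_tree(tree, aal116_atlas(), "tree.graphml", ...)` and re-read with
`read_tree()`.

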