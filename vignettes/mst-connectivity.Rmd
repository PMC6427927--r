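---
title: "Methods: MST analysis of wavelet functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MST analysis of wavelet functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstconnect)
```

This vignette is the package's account of its method: the model and its
assumptions, the parameters that matter, what the synthetic generator
emulates (and does not), the numerical choices, and the design decisions
taken where the method description left room.

## The model

Functional connectivity between brain regions is estimated in the wavelet
domain. Each regional BOLD series is decomposed with the maximal-overlap
discrete wavelet transform (MODWT), a shift-invariant, length-preserving,
energy-preserving decomposition whose scale-$s$ detail coefficients
$\lambda_i(s)$ occupy the band $(f_N/2^s,\, f_N/2^{s-1}]$ with
$f_N = 1/(2\,\mathrm{TR})$ the Nyquist frequency. The wavelet correlation
at scale $s$ is

$$ r_{ij} \;=\; \frac{\operatorname{cov}\!\big(\lambda_i(s), \lambda_j(s)\big)}
   {\sqrt{\operatorname{var}\lambda_i(s)\,\operatorname{var}\lambda_j(s)}}. $$

Correlating band-limited coefficients rather than raw series makes the
estimate robust to the non-stationary, coloured character of BOLD noise.
Significance of each $r_{ij}$ is assessed with the mutual-information
statistic $MI = -N\ln(1-r_{ij}^2)/2$; under $H_0: \rho_{ij}=0$, $2\,MI$ is
the Gaussian likelihood-ratio statistic and asymptotically $\chi^2_1$,
which is the reference distribution used for (two-sided) p-values.

Non-significant correlations are set to zero and the remaining adjacency
$a_{ij}$ is re-expressed by the topological overlap

$$ \mathrm{TOM}_{ij} \;=\; \frac{l_{ij} + a_{ij}}
   {\min\{k_i, k_j\} + 1 - a_{ij}}, \qquad
   l_{ij} = \sum_{u \neq i,j} a_{iu} a_{ju},\quad k_i = \sum_{u\neq i} a_{iu}, $$

which credits an edge for the neighbourhood its endpoints share and thus
re-injects the triangle information that a tree, by construction, cannot
hold. Edge weights are $w_{ij} = \min(1/\mathrm{TOM}_{ij}, c)/c$ with
$c = 100$: weights live in $(0, 1]$, small weight = strong connection, and
overlaps at or below $1/c$ saturate at $w = 1$. Prim's algorithm then
extracts the minimum spanning tree, and seven global metrics ($k_{max}$,
$B_{max}$, $d$, $Ecc$, $Ass$, $K = \langle k^2\rangle/\langle k\rangle$,
$Lf$) place each tree between its path-like and star-like extremes.

Whether the MST is a faithful backbone of the full graph is diagnosed by
the extreme value index: modelling the near-zero weight distribution as
$F(x) = \Pr(X \le x) \sim c\,x^\alpha$, $\alpha$ is the slope of the OLS
fit of $\log_{10} F$ on $\log_{10} x$ over the empirical CDF. As
$\alpha \to 0$ (strong disorder) the shortest-path tree of the full graph
coincides with the MST; $\alpha = 1$ corresponds to uniform weights. The
package flags $\hat\alpha < 1$.

Group-level topology is compared on subject-averaged correlation matrices:
the full TOM-weighted graph is percolated by deleting edges from the
weakest (largest $w$) down, tracking $K$ over the nodes that still have
edges; the process stops at the first $K < 2$ (the Molloy–Reed criterion)
and the largest surviving component marks the superhighways — reported, by
default, as the MST edges inside that component, since superhighways are
displayed and interpreted as tree paths (an option returns the raw
component edges). Node betweenness gain/loss uses raw pair counts with the
threshold $b$ = non-zero median of $|$case $-$ control$|$; geodesic
clustering compares rows of the hop-distance matrix by Spearman distance
$d_S = 1 - r_S$ and cuts an average-linkage dendrogram at 0.2; hubs are
nodes of tree degree $> 5$; the survival ratio counts shared tree edges
over $N-1$.

## Parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tr_seconds` | 2.5 | s | acquisition TR; sets $f_N = 0.2$ Hz |
| `wavelet_filter` | `d8` | — | length-8 extremal-phase Daubechies; `la8` (least asymmetric, same length) offered since only family and length are fixed by the method |
| `n_scales` / `analysis_scale` | 4 / 2 | — | scale 2 (0.05–0.1 Hz at TR 2.5 s) is the band where resting-state group differences concentrate |
| `sig_alpha` | 0.05 | — | MI-test level for zeroing correlations and for the zero-correlation count |
| `tom_cap` | 100 | — | cap of the $w = \min(1/TOM, c)/c$ transform; reproduces the printed transform exactly |
| `dendro_cut` | 0.2 | $d_S$ | dendrogram cut height for geodesic clustering |
| `hub_degree_threshold` | 5 | edges | hubs are tree nodes with degree $> 5$ |
| `n_permutations` | 10000 | — | label permutations for the group test |

## Design decisions

* **Adjacency for TOM.** The overlap formula assumes $a \in [0,1]$, but
  significant wavelet correlations can be negative. The default takes
  $a_{ij} = |r^{(0)}_{ij}|$, which keeps $\mathrm{TOM} \in [0,1]$; a
  `signed = TRUE` option preserves signs at the cost of the bounds. The
  diagonal is excluded from $k_i$ and $l_{ij}$, and the $+1$ in the
  denominator already prevents division by zero, so no extra epsilon is
  added.
* **MI-test sample size.** $N$ is taken as the coefficient-series length
  (193 for the reference layout). The MODWT is length-preserving, so this
  matches the printed formula's natural reading; boundary-affected
  coefficients are retained by default (`drop_boundary = FALSE`), keeping
  the effective $N$ equal to the series length.
* **Strength/diversity exclude the diagonal.** Unit self-correlations are
  not connectivity; including them would shift both measures by a constant
  and shrink variances toward zero.
* **Prim tie-breaking.** Among equal-weight candidates the smallest node
  index is attached first and an equal-weight parent update keeps the
  lexicographically smaller edge, so trees are bit-reproducible across
  runs and platforms.
* **Betweenness normalisation.** $B_{max}$ is normalised by
  $(N-1)(N-2)/2$ to live in $[0,1]$; raw pair counts are retained because
  the gain/loss analysis and its threshold $b$ operate on values in the
  hundreds-to-thousands range.
* **Degree divergence.** "Variability over average of node connections" is
  implemented as the Molloy–Reed ratio
  $K = \langle k^2\rangle/\langle k\rangle$ — the quantity whose critical
  value 2 the superhighway stopping rule invokes, which fixes the reading.
* **$\alpha$ fit.** The fit uses the upper-triangle weights of the *full*
  TOM-weighted graph (not only tree edges), excludes cap-saturated
  weights and duplicate abscissae, and requires at least 10 distinct
  points; otherwise a degenerate-fit error is raised. $Ecc$ and $d$ are
  hop-based (edge counts), consistent with the diameter's definition.
* **$K$ during percolation** is computed over nodes of non-zero degree:
  letting isolates accumulate in the average would drive
  $\langle k\rangle \to 0$ and distort the $K<2$ criterion.
* **Spearman profile distance.** For rows $i, j$ of the hop-distance
  matrix, the self and mutual entries (positions $i$ and $j$) are removed
  from both vectors; ties use midranks. If both profiles are constant
  $r_S := 1$ (a star centre compared with a star centre), if exactly one
  is constant $r_S := 0$.
* **Cluster counts.** The dendrogram is cut at the same height in both
  groups and counts are reported as-is; a matched-$k$ cut (`k =`) is
  available when equal cluster numbers are wanted.
* **Rank test.** The two groups are independent samples, so the rank-sum
  (Mann–Whitney) test is used, with BH correction across the 12 measures;
  measures are residualised on age, sex and age×sex *before* testing.
  The permutation test permutes subjects' measure values between groups
  and uses the $(1 + \#\{\ge\})/(B+1)$ convention, flooring p at
  $1/(B+1)$.

## The synthetic cohort generator

`synthetic_spec()` defines a two-group cohort whose defaults mirror the
reference study scale: 39 controls / 41 cases, 116 regions × 193
timepoints at TR 2.5 s, eight contiguous correlation blocks sized like the
atlas lobes (30, 2, 12, 12, 12, 8, 14, 26), and four connector hubs
(regions 47, 54, 67, 99 — occipital, parietal and cerebellar positions in
the packaged layout). The ground truth is an entry-wise correlation
matrix: `rho_within = 0.5` inside blocks, `rho_between = 0.15` across
blocks, `rho_hub = 0.25` on hub rows outside the hub's own block; the case
group multiplies all off-block (including hub) entries by
`case_attenuation = 0.5`. Subject series are Gaussian with this
covariance, coloured by an AR(1) recursion (`ar1_coef = 0.4`) driven by
the spatially correlated innovations and re-standardised, which preserves
the designed cross-correlations in expectation while giving the wavelet
scales non-trivial content. Ages are Normal(65, 7) truncated positive;
sex probabilities are configurable per group so covariate correction can
be exercised.

The within/between magnitudes are typical of within-lobe vs between-lobe
resting-state wavelet correlations. `rho_hub` is additionally constrained
by geometry: a region cannot correlate at 0.35 with a hundred mutually
weakly-correlated regions — the entry-wise matrix becomes indefinite
(minimum eigenvalue −0.56 at 116 regions). At 0.25 both group matrices
are comfortably positive definite (minimum eigenvalues +0.11 control,
+0.33 case), so the generator's defaults need no jitter; the jitter path
(diagonal inflation plus rescaling, with a message) exists for
user-specified structures near the feasibility boundary.

With these conditions the pipeline reproduces the qualitative two-group
pattern — case group: lower strength, higher diversity and
zero-correlation fraction, lower $k_{max}$ and $Lf$, higher $d$ and
$Ecc$, non-significant assortativity — and the designed hubs surface in
the control tree's hub set (see the test suite, which checks the direction
pattern over ten seeds at 20 subjects per group, and the README example).

What the generator does **not** emulate: BOLD hemodynamics and its
frequency-dependent coupling, scanner noise spectra, head motion,
physiological confounds, spatial autocorrelation beyond the block
structure, and negative correlations (the ground-truth matrix is
non-negative; negative sample correlations arise only from noise). A
passing pipeline on synthetic cohorts therefore demonstrates algorithmic
correctness and sensitivity to block/hub attenuation, not fidelity to real
fMRI — in particular, the empirical $\hat\alpha$ of synthetic graphs need
not fall in the strong-disorder range observed on real data.

## Problem sizes and determinism

The test suite validates: the MODWT against a direct equivalent-filter
convolution and the Parseval identity (both length-8 filters); the MST
against exhaustive Prüfer-sequence enumeration on complete graphs of up to
7 nodes (all $n^{n-2}$ labelled trees) and against an independent MST
implementation at 116 nodes; tree betweenness against explicit pair-path
enumeration on random trees of up to 50 nodes; the TOM against a
triple-loop evaluation at 10 nodes (to 1e−12); MI-test calibration on
10,000 null pairs of length 193; $\alpha$-recovery at $\binom{116}{2} =
6670$ weights; and the direction pattern on ten seeded cohorts of 20 + 20
subjects at the full 116 × 193 layout. All randomised tests fix their
seeds; cohorts are bit-reproducible functions of `spec$seed`.

Known limitations: hop-based (not weighted) distances in $Ecc$ and $d$;
the $\chi^2_1$ reference for the MI test is asymptotic (calibration is
verified at $N = 193$, shorter series may deviate); GraphML round-trips
preserve attributes but not the class of empty optional fields; and the
geodesic clustering is $O(N^2)$ Spearman correlations, adequate for
atlas-scale networks but not for voxel-level graphs.
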