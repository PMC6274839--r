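# coilflex

Bending flexibility of two-chain α-helical coiled-coils (tropomyosin-style
molecules) from conformational ensembles — molecular-dynamics snapshots or
synthetic worm-like-chain draws with known ground truth.

Coiled-coil proteins such as tropomyosin act as semi-rigid mechanical
struts, and their bending stiffness is physiologically meaningful: it sets
how cooperatively a tropomyosin strand transmits regulatory movement along
an actin filament, and it changes under chemical modifications such as the
inter-chain disulfide cross-link found in failing myocardium. `coilflex`
turns an ensemble of conformations into that stiffness number and its
companions:

* **Polygonal molecular axis** — per snapshot, weighted centroids of
  11-residue C-alpha segments of each chain (shared endpoint residues at
  weight 1/2), chain-pair midpoints as polygon vertices, unit tangents
  `t_ij` between consecutive vertices.
* **Tangent-correlation profile** — `c_i = ⟨(t_ij, ⟨t_i⟩)⟩_j` against the
  mean-tangent direction `⟨t_i⟩ = Σ_j t_ij / |Σ_j t_ij|`, the estimator
  that stays unbiased for intrinsically *curved* coiled-coils (the classic
  correlation with the first tangent, `⟨(t(s), t(0))⟩ = exp(−s/Lp)`, is
  available for comparison and is biased low on curved rods).
* **Persistence length** — `Lp = −1/slope` of `ln c` vs contour distance
  `s`, by least squares over all positions and by the secant through the
  end points; `Lp = k/(k_B T)` converts to bending stiffness. Block
  averaging (8 contiguous blocks) provides autocorrelation-robust SEMs;
  Student's t-tests on block-wise estimates compare conditions.
* **Local flexibility** — central-difference local slopes of `ln c` locate
  the most flexible residue interval.
* **Main-chain hydrogen bonds** — geometric criterion (N···O ≤ 0.35 nm,
  H–N···O ≤ 30° when hydrogens are present), counted per frame over named
  residue regions, mean ± SD.
* **Inter-helix distances** — per-segment distance between the two chains'
  centroids, mean ± SD.
* **Synthetic ground truth** — exact inverse-CDF sampler for the discrete
  Kratky–Porod chain (straight, intrinsically curved, or locally softened)
  and a pseudo-atomic two-chain builder around it, so the whole estimator
  chain is validated by parameter recovery.

Ensembles come in as multi-model PDB or a plain TSV coordinate table;
everything user-facing is a tibble, chains with the pipe, and plots via
`autoplot()`.

## Worked example

Generate a worm-like-chain ensemble with a known persistence length of
100 nm at the study geometry (10 tangents of 1.485 nm, i.e. residues
106–216 at 0.1485 nm rise per residue), wrap a pseudo-atomic coiled-coil
around it, and run the full analysis:

```r
library(coilflex)

w    <- sample_wlc_ensemble(n_vertices = 11, b_nm = 1.485, lp_nm = 100,
                            n_frames = 2000, seed = 1)
ens  <- build_coiled_coil_ensemble(w, backbone = "N-CA-C-O")
cond <- run_analysis(ens, name = "synthetic", align = FALSE,
                     regions = tpm_middle_regions())
cond
#> <condition_summary> synthetic @ 300 K: Lp = 98.3 nm (secant 98.1)
#>   H-bonds:
#>     106-129,138-160    84.9 +/- 1.8
#>     129-138            19.6 +/- 1.0
#>     161-215            108.2 +/- 2.5

tidy(cond$fits$least_squares)
#> # A tibble: 1 × 5
#>   method        lp_nm lp_se_nm temperature_K stiffness_J_nm
#>   <chr>         <dbl>    <dbl>         <dbl>          <dbl>
#> 1 least_squares  98.3    0.900           300       4.07e-19
```

Both estimators land within 2% of the generator's 100 nm; the stiffness
column is `Lp · k_B · T` in J·nm. The H-bond means are the per-frame counts
of backbone i+4 → i bonds summed over both chains in each region (e.g. the
10-residue region 129–138 holds ~20 bonds across the two chains in an
intact helix, and its drop flags local melting). `autoplot(cond$profile)`
draws the flexibility plot (`ln c` vs `s` with the two fitted lines).

Comparing conditions reproduces the standard table arithmetic — ratios as
`"least-squares(secant)"`, percent changes across temperature, t-tests on
block estimates:

```r
compare_conditions(list(cond_a, cond_b), reference = "cond_a")
```

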