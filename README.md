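# somatomap

Somatotopic finger mapping and representational analysis of (simulated) BOLD
fMRI data from the primary somatosensory (S1) hand area.

## The scientific problem

The S1 hand area hosts an ordered map of the five fingers (thumb laterally to
little finger medially). Two complementary fMRI readouts characterise that
map and how it changes after deafferentation such as cervical spinal cord
injury (SCI):

* **Travelling-wave (phase-encoded) mapping.** Fingers are cued in a fixed
  50 s cycle (10 s each, 7 cycles per run, TR 2 s, 182 volumes). A gamma-HRF
  reference model is shifted by one TR at a time across the cycle (25 lagged
  models); each voxel's time course is correlated with every model, the
  Fisher-z values of the five lags belonging to each finger are averaged, and
  a winner-take-all rule assigns the voxel to the finger with the maximal z.
  Backward-sequence runs cancel order biases. Split-half reliability is
  quantified with the Dice overlap coefficient
  `DOC = 2|A∩B| / (|A| + |B|)` across same, neighbouring and non-neighbouring
  finger pairs.

* **Representational similarity analysis (RSA).** From blocked-design runs
  (8 s blocks, 5 finger conditions + rest, 127 volumes, 4 runs) a
  double-gamma GLM yields per-finger activity patterns. The cross-validated
  squared Mahalanobis (crossnobis) distance between each finger pair,

  d_ij = (2 / (R(R−1) P)) Σ_{r<s} (u_i,r − u_j,r)ᵀ (u_i,s − u_j,s),

  with runs as folds and residual-based prewhitening, is unbiased: expected 0
  when patterns are identical. The 5×5 RDM's ten unique values give
  *separability* (their mean) and *typicality* (Spearman correlation with a
  canonical RDM, Fisher r-to-z transformed).

Because raw patient data are not distributable, the package ships a synthetic
BOLD cohort generator with known somatotopic ground truth: controls, SCI
patients whose deterioration δ grows with simulated years since injury, and
congenital one-handers (δ = 1, no finger tuning). Deterioration degrades
tuning specificity while *exactly* preserving net activity, so the pipeline's
headline dissociation — normal overall task activity, degraded somatotopy —
is recoverable ground truth. Every estimator is validated against that
generator plus brute-force oracles.

## Worked example

```r
library(somatomap)

cfg <- pipeline_config(n_controls = 6, n_sci = 6, n_onehanders = 4,
                       grid_shape = c(10, 6, 4), bootstrap_reps = 2000, seed = 1)
man <- run_pipeline(cfg, out_dir = "somatomap_out")
res <- man$results

round(tapply(res$rsa$typicality_z, res$cohort$manifest$group, mean), 2)
#>    control one_hander        sci
#>       2.31      -0.05       1.07

round(colMeans(res$dice[res$dice$group == "control", 3:5]), 3)
#>          same     neighbour non_neighbour
#>         0.965         0.018         0.000

round(tapply(res$psc$psc, res$cohort$manifest$group, mean), 3)
#>    control one_hander        sci
#>      0.399      0.379      0.387

round(c(hand = mean(res$rsa$separability_hand),
        csf  = mean(res$rsa$separability_csf)), 3)
#>  hand   csf
#> 0.270 0.004

res$stats$typicality_correlations[, c("covariate", "rho", "p")]
#>         covariate         rho           p
#> 1 years_since_sci -0.94285714 0.004804665
#> 2     motor_score  0.94285714 0.004804665
#> 3   sensory_score  0.88571429 0.018845481
#> 4  tissue_bridges  0.08571429 0.871743440
#> 5       cord_area  0.02857143 0.957154519
```

Reading the numbers: hand-map typicality is highest in controls, intermediate
in SCI patients and at chance in one-handers, and within the SCI group it
declines with years since injury (ρ = −0.94) and tracks retained motor
function — while percent signal change (overall task activity) is
indistinguishable across groups and finger separability is present in the
hand ROI but absent in CSF. Split-half Dice overlap is far higher for same
than neighbouring than non-neighbouring finger pairs, the signature of a
reliable somatotopic gradient. The output directory holds every table as CSV
(`winner_maps.csv`, `dice_table.csv`, `psc.csv`, `rdms.csv`,
`rsa_scores.csv`, `mds_coordinates.csv`, probability maps per group), a JSON
statistics summary, and a hashed run manifest; `verify_manifest()` re-checks
the hashes. A command-line wrapper lives at `inst/cli/somatomap.R`
(`Rscript somatomap.R all --config cfg.json --seed 1 --out dir`).

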