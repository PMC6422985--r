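# fetalrp

Computer-aided screening for fetal hypoxia from cardiotocograms (CTG), for
researchers working on automated fetal heart rate (FHR) analysis. The
package turns a 4 Hz FHR trace into recurrence-plot images and classifies
them as **normal** or **pathological** — hypoxia being defined objectively
by umbilical-artery pH < 7.15 at delivery — with a compact convolutional
network and 10-fold cross-validated evaluation. A synthetic CTG generator
makes the entire pipeline buildable and testable without downloading any
clinical data.

## The method

Given a preprocessed scalar series *u₁…u_L*, the trace is embedded in an
*m*-dimensional phase space by time delays (delay *τ*, in samples):

    x_k = (u_k, u_{k+τ}, …, u_{k+(m−1)τ}),   k = 1…N,   N = L − (m−1)τ

The recurrence plot is the binary N×N matrix

    R_ij = Θ(ε_i − ‖x_i − x_j‖),   Θ(z) = 1 if z > 0, else 0

with ε_i chosen per point as the Euclidean distance to x_i's k-th nearest
neighbour (the fixed-amount-of-neighbours criterion), so every row carries
the same number of recurrences. R is rendered as a 64×64 grayscale image by
exact area averaging and fed — channels replicated to 64×64×3 — to an
8-layer network (conv 5×5×8 → BN → ReLU → avg-pool 3×3/2, twice; dense 144;
dropout 0.8; dense 2; softmax) trained with Adam (lr 1e-3, squared-gradient
decay 0.6, ε 1e-6), L2 1e-4, mini-batch 64, 10 epochs. Varying (m, τ, k)
over a grid (m ∈ {2,3}, τ, k ∈ 1..10) augments each record into 200 images.
Metrics follow the source convention that the *normal* class is positive:
Acc = (TP+TN)/total, Se = TP/(TP+FN), Sp = TN/(FP+TN), plus trapezoidal
ROC/AUC.

## Worked example

```r
library(fetalrp)

rec <- generate_fhr(synth_config("pathological", duration_s = 1200, seed = 42))
rec
#> <fhr_record> synth_path_42: 4800 samples @ 4 Hz (20.0 min)
#>   pH 6.96  label pathological

clean <- preprocess_fhr(rec)        # gaps -> stability -> range repair
seg   <- select_segment(clean, 13)  # final 13 minutes (closest to delivery)
img   <- signal_to_rp(seg, m = 2, tau = 1, k = 6)
img
#> <rp_image> 64 x 64, mean intensity 0.0019  (m=2, tau=1, k=6, per-point)

label_by_ph(rec$ph)
#> [1] "pathological"
```

The record prints its attached delivery pH (6.96, below the 7.15
borderline, hence the pathological label); the rendered recurrence plot has
mean intensity ≈ 0.0019, i.e. the plot's recurrence rate — with per-point
k-NN thresholds this is ≈ k/N by construction.

End to end on a synthetic cohort (this trains 10 networks; a few minutes on
one CPU):

```r
run <- run_pipeline(n_per_class = 30, duration_s = 1200,
                    grid = augmentation_grid(2, 1:2, c(2, 6)),
                    n_folds = 10, fold_mode = "record", seed = 2024)
run$report
#> <cv_report> 10-fold (record-level), architecture I-C-P-C-P-F-F-O
#>   averaged: Acc 96.25%  Se 94.17%  Sp 98.33%  AUC 100.00%
```

(Those are the numbers this code prints at seed 2024: record-level folds,
so no augmented image of a test record was seen in training. `tidy(run$report)`
gives the per-fold table, `autoplot(run$report)` the fold plot.)

To work with the real CTU-UHB intrapartum database instead, download it with
`scripts/fetch_ctu_uhb.sh` (PhysioNet, open access) and read records with
`read_physionet_record()`; `label_by_ph()` + `balance_classes()` reproduce
the 105-vs-105 balanced design, and `make_folds(mode = "image")` reproduces
the published image-level protocol (see the methods vignette for why that
protocol flatters the metrics).

A thin command-line front end lives at `inst/cli/fetalrp`
(`simulate`, `preprocess`, `rp`, `run` subcommands).

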