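# emgrasp

Surface-EMG pattern recognition for object-grasp classification degrades when
the arm moves: the same grasp performed at a different limb position shifts
the EMG feature distributions (the *limb-position effect*), so a classifier
trained at one position misfires at others. `emgrasp` is an R package for
studying this effect at desk scale. It provides a seeded simulator of
multi-channel EMG + IMU grasp trials (5 grasp classes x 9 placement
positions), the classical time-domain feature pipeline, four
feature-projection techniques, seven classifiers under five-fold
cross-validation, and the cluster-quality statistics used to compare
projections. It is aimed at researchers in myoelectric control and
biomedical signal processing who want a reproducible, fully synthetic
testbed for projection/classifier choices.

## The pipeline

1. **Signals.** Six EMG channels at 1024 Hz (AR(2)-filtered Gaussian
   processes whose amplitude and pole placement encode the grasp, scaled by
   per-position channel gains) and six IMU channels at 60 Hz (gravity vector
   rotated by the position's azimuth/distance, plus gyroscope noise), 2 s per
   trial.
2. **Conditioning.** 5th-order Butterworth band-pass 20-450 Hz, 50 Hz notch
   (Q = 30), IMU moving average; sliding windows of 150 ms with 50 ms
   increments (100 ms overlap).
3. **Features (66-D).** Per EMG channel and window: MAV, ZC, WL, SSC and
   AR(6) coefficients (Burg); per IMU channel: RMS. Min-max normalized to
   [-1, 1] with training-set statistics.
4. **Projection to k = 4** (grasp classes minus one):
   - PCA — top-k eigenvectors of the training covariance;
   - LDA — top-k eigenvectors of `solve(Sw) %*% Sb`;
   - SRELM — spectral-regression extreme learning machine: random hidden
     layer `h(x) = g(a_i . x + b_i)`, `g(d) = 1/(1 + e^d)`, orthonormalized
     class-indicator responses `Z`, ridge solution
     `U = solve(H'H + alpha I, H'Z)`;
   - t-SNE — transductive KL-minimizing embedding with per-point bandwidths
     calibrated to a target perplexity.
5. **Classification.** LDA, Gaussian naive Bayes, KNN (k = 3), linear / RBF /
   polynomial SVM (cost = 1, gamma = 1), and a 4-14-5 tan-sigmoid neural
   network, scored by five-fold cross-validation (projection refitted inside
   each training fold).
6. **Cluster metrics.** For class means `mu_i` and covariances `S_i`:
   - SI (separability): mean over classes of
     `min_j 0.5 * sqrt((mu_i - mu_j)' solve((S_i + S_j)/2) (mu_i - mu_j))`;
   - MSA (compactness): mean geometric mean of the per-class covariance
     ellipsoid semi-axes `sqrt(lambda_ij)`;
   - RI (repeatability): mean half Mahalanobis distance between train and
     test class means under the training covariance.

## Worked example

```r
library(emgrasp)

cfg  <- graspGeneratorConfig(nSubjects = 1, nReps = 2, seed = 1)
recs <- generateGraspDataset(cfg)          # 90 labeled trials
fs   <- featuresFromRecordings(recs, windowStride = 8)
fs
#> GraspFeatureSet: 450 windows x 66 features

grid <- runProjectionClassifierGrid(fs, seed = 1)
grid$metrics
#>   subject projection        SI         MSA
#> 1     S01        pca  2.157810 0.492198142
#> 2     S01        lda  6.118965 0.063614034
#> 3     S01      srelm 21.592141 0.002078944
#> 4     S01       tsne  5.046678 3.471183523
```

The supervised projections (LDA, SRELM) separate the five grasp clusters far
better than the unsupervised ones (PCA, t-SNE), and SRELM is both the most
separated (highest SI) and the most compact (lowest MSA). The same ordering
shows up in the cross-validated errors: mean error across the seven
classifiers is 13.9% for PCA and 3.0% for t-SNE, but essentially zero for
LDA and SRELM, and the classifier-to-classifier spread under SRELM (0.2
points) is an order of magnitude smaller than under PCA (6.9 points) — with
a good projection, the classifier choice barely matters.

```r
red <- runPositionReduction(fs, seed = 1)   # SRELM + NN, 1..9 training positions
red$records[c(1, 9), c("n_positions", "error_percent", "RI")]
#>   n_positions error_percent        RI
#> 1           1     22.222222 95.555292
#> 9           9      1.111111  0.958525
```

Training at a single position leaves 22% error on windows from all nine
positions; training across all nine drops the error to about 1% and the
repeatability index RI falls by two orders of magnitude — adding training
positions makes the projected features reproduce on unseen data.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "emgrasp.R", package = "emgrasp")` with subcommands
`simulate`, `extract`, `project`, `classify`, `metrics` and `experiment`.

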