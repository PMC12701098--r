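# ailabel3d

AI-assisted segmentation-label generation for paired T1-/T2-weighted 3D MRI,
with a phantom test bed. The package is aimed at researchers who need voxel
labels for 3D tumor segmentation but want to cut the manual annotation down
to a few expert clicks — and at anyone who wants to study how reliable such
semi-automatic labels are compared to fully manual ones.

## What it does

**Step 1 — unsupervised multi-modal clustering.** Two parallel 3D CNN
branches (no shared weights), one per modality, each produce 30 feature
channels per voxel; the concatenated, batch-normalized 60-channel embedding
is the *response map* `r`. Each voxel joins cluster
`c(v) = argmax_k r_k(v)`, and the network trains itself by minimizing

```
L = CE(softmax(r), argmax labels)  +  mu * ||forward differences of r||_1 ,   mu = 1
```

the cross-entropy *feature similarity* term plus an L1 *spatial continuity*
term over the horizontal, vertical and depth axes. Unused channels stop
winning voxels, so the initial 60 clusters merge away by extinction until a
handful remain.

**Step 2/3 — seeded refinement into an AI-assisted label (AI-L).** The two
expert labels are added element-wise and multiplied with the cluster map to
isolate the region of interest; seed "clicks" placed in the region grow to
whole 6-connected components of their cluster label; components bigger than
3x the estimated tumor volume are discarded; the union of the survivors is
the AI-L.

**Downstream.** A dual-input-channel 3D U-Net (Adam, soft Dice loss) can be
trained on expert labels or AI-L, and the package provides Dice / FNR / FPR,
intra-cluster homogeneity analysis (tumors, being heterogeneous, should be
the highest-variance cluster), and a blinded model-comparison harness
(randomized order/colors, 2-of-3 majority tally).

**Phantoms.** Because clinical cohorts cannot ship, `make_phantom()` builds
multi-modal volumes with six tissue classes, a randomly placed ellipsoidal
tumor whose intensity variance is the highest by construction, and simulated
(biased + jittered) expert labels. Everything below runs on phantoms.

## Worked example

```r
library(ailabel3d)

# a reproducible 3-case phantom cohort, z-normalized
cohort <- make_cohort(3, shape = c(32, 32, 16), rng_seed = 42)
pairs <- lapply(cohort, function(ph) {
  p <- ph$pair; p$t1 <- znormalize(p$t1); p$t2 <- znormalize(p$t2); p
})

# unsupervised clustering (desk-scale settings; see the methods vignette)
fit <- train_unsupervised(pairs,
  cluster_train_config(lr = 0.3, batch_size = 1, max_epochs = 15,
                       patience = 15, continuity_reduction = "pairs",
                       rng_seed = 42))
tail(fit$history, 1)
#>    epoch      loss n_active_clusters best_loss epochs_since_improvement
#> 15    15 0.3633419                41 0.3633419                        0

# seeded refinement of case 1
ph <- cohort[[1]]
maps <- lapply(pairs, function(p) predict_clusters(fit$params, p))
ail <- generate_ai_label(maps[[1]], ph$el_t1, ph$el_t2,
                         n_seeds = 5, rng_seed = 1)
dice(ail$ail, ph$tumor_mask)          # AI-L vs ground-truth tumor
#> [1] 0.8419689
label_overlap(ail$ail, (ph$el_t1 + ph$el_t2) > 0)  # AI-L vs combined expert label
#> [1] 0.8593666
```

The training history shows the cluster count falling from 60 as channels go
extinct (to 41 after these 15 short, gently-smoothed epochs; the collapse
experiment in `scripts/acceptance.R` drives it to a handful); the final Dice
values say that the label assembled from whole cluster components both
recovers the true tumor (0.84) and stays close to what the simulated expert
drew (0.86) — the label is expert-like yet derived from the image
structure, which is the point of the framework.

## Layout

```
R/               io_prep, phantom, featcluster, refine, unet3d, evalx modules
src/             float32 im2col convolution, pooling, upsampling, region-grow kernels
inst/cli/        thin command-line front end (prep / phantom / cluster / refine / metrics)
scripts/         acceptance.R
vignettes/       label-generation-methods.Rmd — models, parameters, design choices
tests/testthat/  unit, property and acceptance tests
```
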