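# nucseg3d

3D instance segmentation of fluorescently labeled nuclei in microscopy
volumes, trained **entirely on synthetic data** — no manual 3D annotation
anywhere in the loop.

Deep-tissue fluorescence volumes (optically cleared kidney, intestine, and
similar preparations imaged hundreds of microns deep) show nuclei that are
blurred axially by the PSF, darkened toward slice corners by vignetting,
progressively washed out with depth, and packed tightly enough to touch.
Supervised 3D networks segment such data well but need voxel-level 3D ground
truth that takes days to draw per volume. This package implements the
synthetic-training alternative end to end:

1. **Phantoms** — binary volumes of ellipsoidal nuclei with random sizes,
   rotations and translations, under the protocol constraint that no two
   nuclei overlap by more than 5 voxels (`generate_mask_dataset()`).
2. **Synthesis** — microscopy-like intensities from the phantoms, either
   via a classical degradation renderer (blur, vignetting, depth decay,
   noise; `render_volume()`) or a spatially constrained CycleGAN trained on
   unpaired real volumes (`train_spcyclegan()` / `synthesize()`).
3. **Pairs** — each volume is subdivided 2×2×2, giving 8 registered
   (mask, image) training pairs per volume; the full-scale protocol's 200
   volumes yield 1600 pairs (`build_training_pairs()`).
4. **Segmenter** — a five-level 3D U-Net-style encoder-decoder
   (3×3×3 convolutions, stride-2 max pooling, transpose-convolution
   upsampling, skip concatenation, sigmoid head) trained with Adam
   (lr 0.001) on the combined loss

   L_seg(T, S) = mu1 * L_Dice(T, S) + mu2 * L_BCE(T, S)

   where T is the binary target, S the predicted probability map
   (`train_segmenter()`, `predict_volume()`).
5. **Instances** — a quasi-3D watershed: per-slice 2D distance-transform
   watersheds in the three orthogonal orientations accumulate split lines
   that are removed before 3D relabeling (`quasi3d_watershed()`), with
   optional competitive label dilation for cytometry sampling
   (`dilate_labels()`).
6. **Evaluation** — voxel metrics (accuracy, Type-I/II error; the identity
   VA + I + II = 1 holds exactly) and object metrics (precision, recall,
   F1 = 2PR/(P+R)) under a 50 %-overlap true-positive rule
   (`evaluate_pair()`), plus an Otsu + 3D-watershed classical baseline
   (`run_baseline()`).

The 3D conv-net engine (im2col + BLAS GEMM forward/backward, Adam) is part
of the package, as are an exact 3D Euclidean distance transform and a
deterministic tolerance watershed; volumes are plain R arrays with
dim = (z, y, x) read/written as multi-page grayscale TIFF.

## Worked example: the desk-scale study

The `desk` preset is a complete CPU-scale instance of the pipeline: 4
phantom volumes of 64³ with 80 nuclei each → renderer synthesis → 32
training pairs of 32³ → a three-level network (4 base channels) trained 15
epochs → inference on a fifth, held-out phantom → quasi-3D watershed →
evaluation against the phantom's true labels.

```r
library(nucseg3d)
cfg <- pipeline_config("desk", master_seed = 17)
res <- run_end_to_end(cfg)     # ~5 minutes on one CPU
res$data_manifest$n_pairs
#> [1] 32
res$report$row
#>    type_I   type_II  accuracy precision    recall        F1
#>      2.89      0.06     97.04    100.00     70.00     82.35
```

Reading the row: 2.89 % of voxels are false-positive foreground (the network
slightly over-covers blurred nucleus boundaries), essentially no nucleus
voxels are missed (Type II 0.06 %), and of the 80 held-out nuclei the
pipeline recovers 56 as one-to-one matches covering ≥ 50 % of their volume
(recall 70 %) with no spurious objects (precision 100 %), for an object F1
of 82.35 %. The classical baseline on the same volume:

```r
bl <- run_baseline(res$holdout$intensity)
evaluate_pair(res$holdout$labels, bl)$row
#>    type_I   type_II  accuracy precision    recall        F1
#>      2.30      0.68     97.02    100.00     70.00     82.35
```

On this mildly degraded synthetic fixture the global-threshold baseline is
competitive with the learned pipeline (the two tie on object metrics at this
seed); the learned method's margin is in Type-II error — it recovers the dim
nucleus voxels the global threshold misses — and grows as vignetting/depth
decay strengthen, which is the regime it exists for (see the methods
vignette, `vignettes/nucseg3d-methods.Rmd`, for what the desk study does and
does not demonstrate).

F1 arithmetic worked example — published precision/recall operating points
reproduce their printed F1 cells:

```r
round(f1_score(72.80, 90.55), 2)   # 80.71
round(f1_score(89.38, 95.26), 2)   # 92.23
```

A thin CLI wrapping these functions ships in `inst/cli/nucseg3d`
(subcommands `generate-masks`, `render`, `train-gan`, `synthesize`,
`train-seg`, `segment`, `postprocess`, `baseline-otsu`, `evaluate`,
`run-all`, `show-config`).

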