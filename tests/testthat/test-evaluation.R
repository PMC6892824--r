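test_that("voxel metrics satisfy the identity and the trivial cases", {
  T0 <- array(as.integer(runif(4^3) > 0.6), c(4, 4, 4))
  vm <- voxel_metrics(T0, T0)
  expect_equal(vm$VA, 1)
  expect_equal(vm$type_I, 0)
  expect_equal(vm$type_II, 0)
  comp <- array(1L - T0, dim(T0))
  vc <- voxel_metrics(T0, comp)
  expect_equal(vc$VA, 0)
  expect_equal(vc$type_I, mean(T0 == 0))
  expect_equal(vc$type_II, mean(T0 == 1))
  expect_error(voxel_metrics(T0, array(0L, c(4, 4, 5))), "mismatch")
})

test_that("voxel counts match the per-voxel oracle on random pairs", {
  set.seed(77)
  for (rep in 1:20) {
    T0 <- array(as.integer(runif(5^3) > runif(1)), c(5, 5, 5))
    S0 <- array(as.integer(runif(5^3) > runif(1)), c(5, 5, 5))
    vm <- voxel_metrics(T0, S0)
    orc <- oracle_voxel_counts(as.vector(T0), as.vector(S0))
    expect_equal(c(vm$n_tp, vm$n_tn, vm$n_fp, vm$n_fn), unname(orc))
    expect_equal(vm$VA + vm$type_I + vm$type_II, 1)
    expect_equal(vm$n_tp + vm$n_tn + vm$n_fp + vm$n_fn, vm$n_total)
  }
})

test_that("matching a labeling against itself is all true positives", {
  fx <- two_sphere_fixture()
  gt <- quasi3d_watershed(fx$mask)
  oc <- match_objects(gt, gt)
  expect_equal(oc$n_tp_o, 2)
  expect_equal(oc$n_fp_o, 0)
  expect_equal(oc$n_fn_o, 0)
  expect_true(all(oc$matching$overlap_fraction == 1))
})

test_that("empty segmentation counts every ground-truth object as missed", {
  set.seed(4)
  mv <- generate_mask_volume(
    mask_gen_config(volume_shape = c(24, 24, 24), n_nuclei = 7,
                    semi_axis_range = c(2, 3), seed = 4))
  oc <- match_objects(mv$labels, array(0L, c(24, 24, 24)))
  expect_equal(oc$n_fn_o, 7)
  expect_equal(oc$n_tp_o, 0)
  expect_equal(oc$n_fp_o, 0)
  om <- suppressWarnings(object_metrics(oc))
  expect_equal(om$P, 0)
  expect_equal(om$R, 0)
  expect_equal(om$F1, 0)
  expect_true(om$degenerate)
})

test_that("an object covering only 40% of its nucleus is one fp plus one fn", {
  gt <- array(0L, c(4, 4, 10))
  gt[, , 1:5] <- 1L                      # one nucleus of 80 voxels
  seg <- array(0L, c(4, 4, 10))
  seg[, , 1:2] <- 1L                     # covers 32/80 = 40% < 50%
  oc <- match_objects(gt, seg, match_config(min_overlap_fraction = 0.5,
                                            denominator = "gt"))
  expect_equal(oc$n_tp_o, 0)
  expect_equal(oc$n_fp_o, 1)
  expect_equal(oc$n_fn_o, 1)
  # at 60% coverage the same pair becomes a true positive
  seg[, , 3] <- 1L
  oc2 <- match_objects(gt, seg)
  expect_equal(oc2$n_tp_o, 1)
})

test_that("matching is invariant to label-id permutation", {
  set.seed(12)
  mv <- generate_mask_volume(
    mask_gen_config(volume_shape = c(24, 24, 24), n_nuclei = 6,
                    semi_axis_range = c(2, 4), seed = 12))
  gt <- mv$labels
  perm <- sample(6)
  seg <- array(0L, dim(gt))
  seg[gt > 0] <- perm[gt[gt > 0]]
  oc <- match_objects(gt, seg)
  expect_equal(oc$n_tp_o, 6)
  expect_equal(oc$n_fp_o, 0)
})

test_that("object metrics follow the harmonic-mean closed form", {
  counts <- structure(list(n_tp_o = 30, n_fp_o = 10, n_fn_o = 5,
                           matching = NULL), class = "object_counts")
  om <- object_metrics(counts)
  expect_equal(om$P, 30 / 40)
  expect_equal(om$R, 30 / 35)
  expect_equal(om$F1, 2 * om$P * om$R / (om$P + om$R))
  expect_equal(f1_score(om$P, om$R), f1_score(om$R, om$P))  # symmetry
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
})

test_that("evaluate_pair reports the conventional row and handles crops", {
  fx <- two_sphere_fixture()
  gt <- quasi3d_watershed(fx$mask)
  rep <- evaluate_pair(gt, gt)
  expect_equal(unname(rep$row),
               c(0, 0, 100, 100, 100, 100))
  expect_equal(names(rep$row),
               c("type_I", "type_II", "accuracy", "precision", "recall", "F1"))
  # 64^3-style crop protocol: a crop restricts the evaluated region
  mv <- generate_mask_volume(
    mask_gen_config(volume_shape = c(32, 32, 32), n_nuclei = 8,
                    semi_axis_range = c(2, 4), seed = 3))
  crop <- list(z = c(0, 16), y = c(0, 16), x = c(0, 16))
  rc <- evaluate_pair(mv$labels, mv$labels, crop = crop)
  expect_equal(rc$voxel$n_total, 16^3)
  expect_equal(rc$voxel$VA + rc$voxel$type_I + rc$voxel$type_II, 1)
})
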