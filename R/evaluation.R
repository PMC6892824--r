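#' @title Voxel- and object-level segmentation metrics
#' @name evaluation
#' @description Quantifies segmentation quality the way 3D nucleus
#'   segmentation benchmarks report it: voxel-level accuracy with Type-I
#'   (false-positive) and Type-II (false-negative) voxel fractions, and
#'   object-level precision/recall/F1 under a one-to-one matching where a
#'   segmented nucleus counts as a true positive only if it overlaps its
#'   ground-truth nucleus by at least a configurable fraction (default 50%).
NULL

#' Voxel-level metrics between a binary ground truth and a binary result
#'
#' `VA = (n_tp + n_tn) / n_total`, `type_I = n_fp / n_total`,
#' `type_II = n_fn / n_total`; the identity `VA + type_I + type_II = 1`
#' holds exactly.
#'
#' @param T 0/1 ground-truth array.
#' @param S_bin 0/1 segmentation array, same shape.
#' @return a `voxel_metrics` list with the four counts, `n_total`, and the
#'   three fractions.
#' @export
voxel_metrics <- function(T, S_bin) {
  if (!all(dim(T) == dim(S_bin))) stop("shape mismatch between T and S_bin")
  t <- as.vector(T) > 0
  s <- as.vector(S_bin) > 0
  n_tp <- sum(t & s)
  n_tn <- sum(!t & !s)
  n_fp <- sum(!t & s)
  n_fn <- sum(t & !s)
  n_total <- length(t)
  structure(list(n_tp = n_tp, n_tn = n_tn, n_fp = n_fp, n_fn = n_fn,
                 n_total = n_total,
                 VA = (n_tp + n_tn) / n_total,
                 type_I = n_fp / n_total,
                 type_II = n_fn / n_total),
            class = "voxel_metrics")
}

#' Object matching configuration
#'
#' @param min_overlap_fraction minimum overlap fraction for a true positive
#'   (default 0.5), in (0, 1\].
#' @param denominator what the intersection is divided by: the ground-truth
#'   nucleus volume ("gt", default), the segmented nucleus volume ("seg"),
#'   or their union ("union").
#' @return a `match_config` object.
#' @export
match_config <- function(min_overlap_fraction = 0.5,
                         denominator = c("gt", "seg", "union")) {
  denominator <- match.arg(denominator)
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    stop("min_overlap_fraction must be in (0, 1]")
  structure(list(min_overlap_fraction = min_overlap_fraction,
                 denominator = denominator),
            class = "match_config")
}

#' Match segmented objects to ground-truth objects
#'
#' Candidate (gt, seg) pairs are scored by overlap fraction and assigned
#' one-to-one greedily in descending fraction (ties: lower gt id, then lower
#' seg id). Pairs at or above the threshold are true positives; unmatched
#' segmented objects are false positives, unmatched ground-truth objects
#' false negatives.
#'
#' @param gt integer ground-truth label array.
#' @param seg integer segmentation label array, same shape.
#' @param cfg a [match_config()].
#' @return an `object_counts` list: `n_tp_o`, `n_fp_o`, `n_fn_o`, and
#'   `matching` (data.frame gt_id, seg_id, overlap_fraction).
#' @export
match_objects <- function(gt, seg, cfg = match_config()) {
  if (!all(dim(gt) == dim(seg))) stop("shape mismatch between gt and seg")
  stopifnot(inherits(cfg, "match_config"))
  gv <- as.vector(gt)
  sv <- as.vector(seg)
  gt_ids <- sort(unique(gv[gv > 0]))
  seg_ids <- sort(unique(sv[sv > 0]))
  gt_sizes <- tabulate(gv[gv > 0], nbins = max(gv, 0))
  seg_sizes <- tabulate(sv[sv > 0], nbins = max(sv, 0))
  both <- gv > 0 & sv > 0
  matching <- data.frame(gt_id = integer(0), seg_id = integer(0),
                         overlap_fraction = numeric(0))
  if (any(both)) {
    key <- data.frame(g = gv[both], s = sv[both])
    inter <- as.data.frame(table(key$g, key$s), stringsAsFactors = FALSE)
    inter <- inter[inter$Freq > 0, ]
    g <- as.integer(inter$Var1)
    s <- as.integer(inter$Var2)
    denom <- switch(cfg$denominator,
                    gt = gt_sizes[g],
                    seg = seg_sizes[s],
                    union = gt_sizes[g] + seg_sizes[s] - inter$Freq)
    frac <- inter$Freq / denom
    ord <- order(-frac, g, s)
    g_taken <- logical(max(gv)); s_taken <- logical(max(sv))
    for (i in ord) {
      if (frac[i] < cfg$min_overlap_fraction) break
      if (g_taken[g[i]] || s_taken[s[i]]) next
      g_taken[g[i]] <- TRUE
      s_taken[s[i]] <- TRUE
      matching <- rbind(matching,
                        data.frame(gt_id = g[i], seg_id = s[i],
                                   overlap_fraction = frac[i]))
    }
  }
  n_tp <- nrow(matching)
  structure(list(n_tp_o = n_tp,
                 n_fp_o = length(seg_ids) - n_tp,
                 n_fn_o = length(gt_ids) - n_tp,
                 matching = matching),
            class = "object_counts")
}

#' F1 score from precision and recall
#'
#' `F1 = 2 P R / (P + R)`; scale-invariant, so P and R may be fractions or
#' percentages (the result is on the same scale). Returns 0 when P + R = 0.
#'
#' @param P precision.
#' @param R recall.
#' @return the harmonic mean of P and R.
#' @export
f1_score <- function(P, R) {
  if (P + R <= 0) return(0)
  2 * P * R / (P + R)
}

#' Object-level precision, recall and F1 from match counts
#'
#' `P = n_tp / (n_tp + n_fp)`, `R = n_tp / (n_tp + n_fn)`,
#' `F1 = 2PR/(P+R)`. Zero-denominator cases return 0 and set the
#' `degenerate` flag.
#'
#' @param counts an `object_counts` from [match_objects()].
#' @return an `object_metrics` list: `P`, `R`, `F1`, `degenerate`.
#' @export
object_metrics <- function(counts) {
  stopifnot(inherits(counts, "object_counts"))
  if (with(counts, any(c(n_tp_o, n_fp_o, n_fn_o) < 0)))
    stop("negative object counts")
  dp <- counts$n_tp_o + counts$n_fp_o
  dr <- counts$n_tp_o + counts$n_fn_o
  degenerate <- dp == 0 || dr == 0
  if (degenerate)
    warning("zero denominator in precision or recall; reporting 0")
  P <- if (dp > 0) counts$n_tp_o / dp else 0
  R <- if (dr > 0) counts$n_tp_o / dr else 0
  structure(list(P = P, R = R, F1 = f1_score(P, R), degenerate = degenerate),
            class = "object_metrics")
}

# Half-up rounding to `digits` decimals (matches how report tables are
# conventionally formatted; R's round() is half-even).
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

apply_crop <- function(vol, crop) {
  # crop: list(z =, y =, x =), each c(from, to), 0-based half-open
  idx <- lapply(c("z", "y", "x"), function(a) {
    r <- crop[[a]]
    if (is.null(r)) return(seq_len(dim(vol)[match(a, c("z", "y", "x"))]))
    (r[1] + 1):r[2]
  })
  vol[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Evaluate a segmentation against ground truth
#'
#' Computes both metric families and renders a single machine-readable row
#' in the conventional column order (Type I, Type II, Accuracy, Precision,
#' Recall, F1), as percentages rounded half-up to two decimals.
#'
#' @param gt integer ground-truth label array.
#' @param seg integer segmentation label array.
#' @param cfg a [match_config()].
#' @param crop optional sub-region, `list(z = c(z0, z1), y =, x =)` with
#'   0-based half-open ranges (e.g. a 64^3 evaluation subregion); applied to
#'   both volumes before computing any metric.
#' @return an `evaluation_report`: `voxel` (voxel_metrics), `counts`
#'   (object_counts), `objects` (object_metrics), `row` (named numeric,
#'   percent scale), `cfg`.
#' @export
evaluate_pair <- function(gt, seg, cfg = match_config(), crop = NULL) {
  if (!all(dim(gt) == dim(seg))) stop("shape mismatch between gt and seg")
  if (!is.null(crop)) {
    gt <- apply_crop(gt, crop)
    seg <- apply_crop(seg, crop)
  }
  vm <- voxel_metrics(array(as.integer(gt > 0), dim(gt)),
                      array(as.integer(seg > 0), dim(seg)))
  oc <- match_objects(gt, seg, cfg)
  om <- object_metrics(oc)
  row <- c(type_I = round_half_up(100 * vm$type_I),
           type_II = round_half_up(100 * vm$type_II),
           accuracy = round_half_up(100 * vm$VA),
           precision = round_half_up(100 * om$P),
           recall = round_half_up(100 * om$R),
           F1 = round_half_up(100 * om$F1))
  structure(list(voxel = vm, counts = oc, objects = om, row = row, cfg = cfg),
            class = "evaluation_report")
}
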