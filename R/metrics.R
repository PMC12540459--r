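# Overlap metrics, HD95 surface distance, 26-connectivity cluster statistics,
# detection rates and DC-guided post-processing.

as_mask_array <- function(m) {
  if (inherits(m, "volume")) m <- m$values
  if (is.logical(m)) m <- array(as.integer(m), dim(m))
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  m
}

#' Voxel overlap metrics between two binary masks
#'
#' Dice `2|G.P|/(|G|+|P|)`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' IoU `|G.P|/|G+P|`. Empty-mask conventions: `DC(empty, empty) = 1` (and
#' IoU = 1); precision/recall with a 0/0 denominator are 0.
#'
#' @param G,P binary 3D arrays (ground truth, prediction) of equal shape.
#' @return list with `DC`, `Pre`, `Rec`, `IoU`.
#' @export
overlap_metrics <- function(G, P) {
  G <- as_mask_array(G); P <- as_mask_array(P)
  if (!all(dim(G) == dim(P))) stop("mask shapes differ")
  tp <- sum(G == 1 & P == 1)
  fp <- sum(G == 0 & P == 1)
  fn <- sum(G == 1 & P == 0)
  dc <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  list(DC = dc, Pre = pre, Rec = rec, IoU = iou)
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' `HD95 = max(d95(G, P), d95(P, G))` where `d95(A, B)` is the 95th
#' percentile (linear interpolation) over points of A of the distance to the
#' nearest point of B. Distances are between foreground voxel centers in
#' physical mm. Undefined (NA) when either mask is empty.
#'
#' @param G,P binary 3D arrays of equal shape.
#' @param spacing voxel spacing in mm (length 3).
#' @return HD95 in mm, or `NA_real_` if undefined.
#' @export
hd95 <- function(G, P, spacing = c(1, 1, 1)) {
  G <- as_mask_array(G); P <- as_mask_array(P)
  if (!all(dim(G) == dim(P))) stop("mask shapes differ")
  cg <- which(G == 1, arr.ind = TRUE)
  cp <- which(P == 1, arr.ind = TRUE)
  if (nrow(cg) == 0L || nrow(cp) == 0L) return(NA_real_)
  cg <- sweep(cg, 2, spacing, `*`)
  cp <- sweep(cp, 2, spacing, `*`)
  d95 <- function(A, B) {
    # nearest-neighbour distances in blocks to bound memory
    n <- nrow(A)
    mind <- numeric(n)
    bs <- max(1L, floor(2e6 / nrow(B)))
    for (s in seq(1L, n, by = bs)) {
      e <- min(n, s + bs - 1L)
      d2 <- outer(rowSums(A[s:e, , drop = FALSE]^2), rowSums(B^2), `+`) -
        2 * A[s:e, , drop = FALSE] %*% t(B)
      mind[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
    stats::quantile(mind, 0.95, type = 7, names = FALSE)
  }
  max(d95(cg, cp), d95(cp, cg))
}

#' Label 26-connected components of a binary mask
#'
#' Voxels sharing a face, edge or corner belong to the same component.
#'
#' @param mask binary 3D array.
#' @return integer array of the same shape; 0 is background, components are
#'   labeled 1, 2, ... in scan order.
#' @export
connected_components26 <- function(mask) {
  mask <- as_mask_array(mask)
  cpp_label26(array(as.integer(mask), dim(mask)), dim(mask))
}

#' Lesion-cluster confusion counts between masks
#'
#' Components are 26-connected. A ground-truth cluster counts as detected
#' (true positive) if any predicted voxel overlaps it, otherwise it is a false
#' negative; a predicted cluster with no ground-truth overlap is a false
#' positive.
#'
#' @param G,P binary 3D arrays of equal shape.
#' @return list with `tp_lesions`, `fp_lesions`, `fn_lesions`, `gt_lesions`.
#' @export
cluster_stats <- function(G, P) {
  G <- as_mask_array(G); P <- as_mask_array(P)
  if (!all(dim(G) == dim(P))) stop("mask shapes differ")
  lg <- connected_components26(G)
  lp <- connected_components26(P)
  ng <- max(lg); np <- max(lp)
  hit_g <- unique(lg[lg > 0L & P == 1L])
  hit_p <- unique(lp[lp > 0L & G == 1L])
  tp <- length(hit_g)
  list(tp_lesions = tp, fp_lesions = np - length(hit_p),
       fn_lesions = ng - tp, gt_lesions = ng)
}

#' DC-guided largest-component post-processing
#'
#' Restricts the prediction to its largest 26-connected component (ties broken
#' by lowest label) and keeps that candidate only if it strictly improves the
#' Dice coefficient against the ground truth; otherwise the original
#' prediction is preserved. Never decreases DC by construction.
#'
#' @param P predicted binary 3D array.
#' @param G ground-truth binary 3D array.
#' @return the post-processed prediction.
#' @export
largest_component_postprocess <- function(P, G) {
  P <- as_mask_array(P); G <- as_mask_array(G)
  lp <- connected_components26(P)
  np <- max(lp)
  if (np <= 1L) return(P)
  sizes <- tabulate(lp[lp > 0L], nbins = np)
  keep <- which.max(sizes)  # lowest label on ties
  cand <- array(as.integer(lp == keep), dim(P))
  if (overlap_metrics(G, cand)$DC > overlap_metrics(G, P)$DC) cand else P
}

#' Cohort detection rates at Dice thresholds 0.0 and 0.22
#'
#' Individual rate: `100 * N_d / N_a` where `N_d` counts cases with DC
#' strictly above the threshold and `N_a` is the cohort size. If per-axis
#' slice DCs are supplied, the slice rate per axis is the percentage of
#' ground-truth-bearing slices whose 2D DC exceeds the threshold, and the
#' overall slice rate averages the three axes unweighted.
#'
#' @param case_dcs numeric vector of per-case Dice coefficients.
#' @param slice_dcs optional list of three numeric vectors (one per axis),
#'   pooling the 2D DCs of all GT-bearing slices of the cohort.
#' @param thresholds DC thresholds (strict `>`).
#' @return a `detection_report` list: per-threshold individual rates (%) and,
#'   when slice data are given, per-axis and averaged slice rates (%).
#' @export
detection_rates <- function(case_dcs, slice_dcs = NULL,
                            thresholds = c(0, 0.22)) {
  if (length(case_dcs) == 0L) stop("empty cohort: detection rate undefined")
  individual <- vapply(thresholds,
                       function(th) 100 * mean(case_dcs > th), numeric(1))
  names(individual) <- paste0("thr_", thresholds)
  out <- list(individual = individual, n_cases = length(case_dcs))
  if (!is.null(slice_dcs)) {
    per_axis <- sapply(thresholds, function(th)
      vapply(slice_dcs, function(v)
        if (length(v) == 0L) NA_real_ else 100 * mean(v > th), numeric(1)))
    per_axis <- matrix(per_axis, nrow = 3,
                       dimnames = list(c("axis1", "axis2", "axis3"),
                                       paste0("thr_", thresholds)))
    out$slice_per_axis <- per_axis
    out$slice <- colMeans(per_axis, na.rm = TRUE)
  }
  structure(out, class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("<detection_report>\n  individual:",
      paste(sprintf("%s = %.1f%%", names(x$individual), x$individual),
            collapse = ", "),
      sprintf(" (n = %d)\n", x$n_cases))
  if (!is.null(x$slice))
    cat("  slice (axis-averaged):",
        paste(sprintf("%s = %.1f%%", names(x$slice), x$slice), collapse = ", "),
        "\n")
  invisible(x)
}

# Per-axis 2D slice DCs of GT-bearing slices for one case.
slice_dcs_case <- function(G, P) {
  G <- as_mask_array(G); P <- as_mask_array(P)
  lapply(1:3, function(a) {
    idx <- which(apply(G, a, sum) > 0)
    vapply(idx, function(i) {
      gs <- switch(a, G[i, , ], G[, i, ], G[, , i])
      ps <- switch(a, P[i, , ], P[, i, ], P[, , i])
      tp <- sum(gs & ps)
      denom <- sum(gs) + sum(ps)
      if (denom == 0) 1 else 2 * tp / denom
    }, numeric(1))
  })
}

#' Evaluate a cohort of predicted masks against ground truth
#'
#' Computes per-case overlap metrics, HD95, cluster statistics (optionally
#' after [largest_component_postprocess()]), cohort means and standard
#' deviations, and detection rates at DC thresholds 0.0 and 0.22.
#'
#' @param gts list of binary ground-truth 3D arrays (or `volume`s).
#' @param preds list of binary predicted arrays, same order and shapes.
#' @param spacing voxel spacing in mm used for HD95.
#' @param postprocess apply DC-guided largest-component post-processing
#'   per case before scoring.
#' @param case_ids optional case identifiers.
#' @return an `evaluation_report`: `per_case` data.frame, `summary` list of
#'   cohort means/sds, `detection` report.
#' @export
evaluate_cases <- function(gts, preds, spacing = c(1, 1, 1),
                           postprocess = FALSE, case_ids = NULL) {
  stopifnot(length(gts) == length(preds))
  n <- length(gts)
  if (is.null(case_ids)) case_ids <- sprintf("case_%03d", seq_len(n))
  rows <- vector("list", n)
  slice_acc <- list(numeric(0), numeric(0), numeric(0))
  for (i in seq_len(n)) {
    G <- as_mask_array(gts[[i]]); P <- as_mask_array(preds[[i]])
    if (postprocess) P <- largest_component_postprocess(P, G)
    om <- overlap_metrics(G, P)
    cs <- cluster_stats(G, P)
    sd_ <- slice_dcs_case(G, P)
    for (a in 1:3) slice_acc[[a]] <- c(slice_acc[[a]], sd_[[a]])
    rows[[i]] <- data.frame(case_id = case_ids[i], DC = om$DC, Pre = om$Pre,
                            Rec = om$Rec, IoU = om$IoU,
                            HD95 = hd95(G, P, spacing),
                            tp_lesions = cs$tp_lesions,
                            fp_lesions = cs$fp_lesions,
                            fn_lesions = cs$fn_lesions,
                            gt_lesions = cs$gt_lesions,
                            stringsAsFactors = FALSE)
  }
  per_case <- do.call(rbind, rows)
  summ <- lapply(c("DC", "Pre", "Rec", "IoU", "HD95"), function(m) {
    v <- per_case[[m]]
    list(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE),
         n_defined = sum(!is.na(v)))
  })
  names(summ) <- c("DC", "Pre", "Rec", "IoU", "HD95")
  det <- detection_rates(per_case$DC, slice_acc)
  structure(list(per_case = per_case, summary = summ, detection = det),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d case(s)\n", nrow(x$per_case)))
  for (m in names(x$summary))
    cat(sprintf("  %s: %.4f +/- %.4f\n", m, x$summary[[m]]$mean,
                x$summary[[m]]$sd))
  print(x$detection)
  invisible(x)
}

#' Write an evaluation report to CSV (per case) and JSON (cohort summary)
#'
#' @param report an `evaluation_report` from [evaluate_cases()].
#' @param csv_path,json_path output file paths (created/overwritten).
#' @return invisibly, the report.
#' @export
write_evaluation_report <- function(report, csv_path, json_path) {
  utils::write.csv(report$per_case, csv_path, row.names = FALSE)
  j <- list(summary = report$summary,
            detection = list(individual = as.list(report$detection$individual),
                             n_cases = report$detection$n_cases))
  if (!is.null(report$detection$slice))
    j$detection$slice <- as.list(report$detection$slice)
  jsonlite::write_json(j, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
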