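test_that("overlap metrics match direct voxel counting", {
  G <- array(0L, c(4, 4, 4)); P <- array(0L, c(4, 4, 4))
  G[1:2, 1, 1] <- 1L; G[1:2, 2, 1] <- 1L       # |G| = 4
  P[1:2, 1, 1] <- 1L                            # |P| = 2, overlap 2
  m <- overlap_metrics(G, P)
  expect_equal(m$DC, 2 * 2 / 6)
  expect_equal(m$Pre, 1)
  expect_equal(m$Rec, 0.5)
  expect_equal(m$IoU, 0.5)

  expect_equal(overlap_metrics(G, G), list(DC = 1, Pre = 1, Rec = 1, IoU = 1))
  Q <- array(0L, c(4, 4, 4)); Q[4, 4, 4] <- 1L
  md <- overlap_metrics(G, Q)
  expect_equal(unlist(md), c(DC = 0, Pre = 0, Rec = 0, IoU = 0))
  # empty-mask conventions
  E <- array(0L, c(4, 4, 4))
  expect_equal(overlap_metrics(E, E)$DC, 1)
  expect_equal(overlap_metrics(G, E)$Pre, 0)
})

test_that("DC and IoU satisfy their algebraic identity on random masks", {
  set.seed(19)
  for (r in 1:20) {
    G <- random_mask(c(8, 8, 8), 0.2); P <- random_mask(c(8, 8, 8), 0.2)
    m <- overlap_metrics(G, P)
    if (sum(G | P) > 0)
      expect_equal(m$DC, 2 * m$IoU / (1 + m$IoU), tolerance = 1e-12)
  }
})

test_that("HD95 matches the all-pairs brute-force oracle", {
  G <- array(0L, c(8, 8, 8)); P <- array(0L, c(8, 8, 8))
  G[2, 2, 2] <- 1L; P[5, 2, 2] <- 1L
  expect_equal(hd95(G, P), 3)
  expect_equal(hd95(G, G), 0)
  expect_true(is.na(hd95(G, array(0L, c(8, 8, 8)))))
  expect_equal(hd95(G, P, spacing = c(2, 1, 1)), 6)

  set.seed(20)
  for (r in 1:10) {
    G <- random_mask(c(12, 12, 12), 0.05)
    P <- random_mask(c(12, 12, 12), 0.05)
    if (sum(G) == 0 || sum(P) == 0) next
    expect_equal(hd95(G, P), oracle_hd95(G, P), tolerance = 1e-10)
  }
})

test_that("HD95 is monotone non-increasing as the prediction grows toward GT", {
  set.seed(27)
  G <- array(0L, c(10, 10, 10)); G[3:8, 3:8, 3:8] <- 1L
  vox <- which(G == 1)
  prev <- Inf
  for (frac in c(0.1, 0.4, 0.7, 1)) {
    P <- array(0L, dim(G)); P[vox[seq_len(ceiling(frac * length(vox)))]] <- 1L
    h <- hd95(G, P)
    expect_lte(h, prev + 1e-12)
    prev <- h
  }
  expect_equal(prev, 0)
})

test_that("26-connectivity labelling agrees with flood fill", {
  m <- array(0L, c(4, 4, 4)); m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L  # corner contact
  expect_equal(max(connected_components26(m)), 1L)
  m2 <- array(0L, c(5, 4, 4)); m2[1, 1, 1] <- 1L; m2[3, 1, 1] <- 1L  # 1-voxel gap
  expect_equal(max(connected_components26(m2)), 2L)
  set.seed(22)
  for (r in 1:8) {
    m <- random_mask(c(9, 9, 9), 0.12)
    expect_true(same_partition(connected_components26(m), oracle_label26(m)))
  }
})

test_that("cluster statistics count lesion hits, misses and false alarms", {
  G <- array(0L, c(10, 10, 10))
  G[2:3, 2:3, 2:3] <- 1L; G[7:8, 7:8, 7:8] <- 1L
  expect_equal(cluster_stats(G, G),
               list(tp_lesions = 2L, fp_lesions = 0L, fn_lesions = 0L, gt_lesions = 2L))
  E <- array(0L, dim(G))
  expect_equal(cluster_stats(G, E),
               list(tp_lesions = 0L, fp_lesions = 0L, fn_lesions = 2L, gt_lesions = 2L))
  # overlap one lesion, add an isolated blob
  P <- array(0L, dim(G)); P[2, 2:3, 2] <- 1L; P[5, 5, 9] <- 1L
  cs <- cluster_stats(G, P)
  expect_equal(cs, list(tp_lesions = 1L, fp_lesions = 1L, fn_lesions = 1L,
                        gt_lesions = 2L))
  expect_equal(cs$tp_lesions + cs$fn_lesions, cs$gt_lesions)
})

test_that("largest-component post-processing keeps only strict DC improvements", {
  G <- array(0L, c(10, 10, 10)); G[2:5, 2:5, 2:5] <- 1L
  # single component: unchanged
  expect_identical(largest_component_postprocess(G, G), G)
  # true positive plus a small disjoint blob: blob removed (DC increases)
  P <- G; P[9, 9, 9] <- 1L
  pp <- largest_component_postprocess(P, G)
  expect_equal(pp, G)
  expect_gt(overlap_metrics(G, pp)$DC, overlap_metrics(G, P)$DC)
  # largest component is a false positive: removal would hurt, so P kept
  P2 <- array(0L, dim(G))
  P2[2:3, 2:3, 2:3] <- 1L                # overlaps GT (8 voxels)
  P2[7:10, 7:10, 7:9] <- 1L              # disjoint blob, larger (48 voxels)
  pp2 <- largest_component_postprocess(P2, G)
  expect_identical(pp2, P2)
})

test_that("post-processing never lowers DC on random prediction/GT pairs", {
  set.seed(23)
  for (r in 1:15) {
    G <- random_mask(c(10, 10, 10), 0.08)
    P <- random_mask(c(10, 10, 10), 0.08)
    expect_gte(overlap_metrics(G, largest_component_postprocess(P, G))$DC,
               overlap_metrics(G, P)$DC)
  }
})

test_that("detection rates implement the strict-threshold counting rule", {
  r <- detection_rates(c(0.5, 0.3, 0.25, 0.9))
  expect_equal(unname(r$individual), c(100, 100))
  r2 <- detection_rates(c(0.5, 0))
  expect_equal(unname(r2$individual["thr_0"]), 50)  # strict >
  # scripted cohort with hand-counted rates
  dcs <- c(0.8, 0.5, 0.3, 0.25, 0.23, 0.22, 0.1, 0.05, 0.0, 0.0)
  r3 <- detection_rates(dcs)
  expect_equal(unname(r3$individual["thr_0"]), 80)     # 8 of 10 above 0
  expect_equal(unname(r3$individual["thr_0.22"]), 50)  # 5 of 10 above 0.22 (0.22 excluded)
  expect_lte(r3$individual["thr_0.22"], r3$individual["thr_0"])
  expect_error(detection_rates(numeric(0)), "empty")
  # slice rates averaged over axes
  r4 <- detection_rates(c(1, 1), slice_dcs = list(c(0.5, 0.1), c(0.5, 0.5), c(0, 0)))
  expect_equal(unname(r4$slice_per_axis[, "thr_0.22"]), c(50, 100, 0))
  expect_equal(unname(r4$slice["thr_0.22"]), 50)
})

test_that("the deep-supervision loss matches hand arithmetic on a toy volume", {
  # 2x2x2 grid, 2 classes, one level; probabilities written out explicitly
  p1 <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)  # P(class 1) per voxel
  gt <- array(c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L), c(2, 2, 2))
  probs <- array(0, c(2, 2, 2, 2))
  probs[2, , , ] <- p1; probs[1, , , ] <- 1 - p1
  out <- structure(list(probs), class = "segmentation_output")
  w <- loss_weights(1)
  # hand computation (independent arithmetic)
  pt <- ifelse(as.numeric(gt) == 1, p1, 1 - p1)
  lce <- -mean(log(pt))
  g <- as.numeric(gt)
  ldice <- 1 - (2 * sum(p1 * g) + 1e-5) / (sum(p1^2) + sum(g) + 1e-5)
  expect_equal(combined_loss(out, gt, w), ldice + lce, tolerance = 1e-12)
  # perfect confident prediction -> loss ~ 0; zero weights -> exactly 0
  hard <- array(0, c(2, 2, 2, 2))
  hard[2, , , ] <- as.numeric(gt); hard[1, , , ] <- 1 - as.numeric(gt)
  hard <- pmin(pmax(hard, 1e-7), 1 - 1e-7)
  expect_lt(combined_loss(structure(list(hard), class = "segmentation_output"), gt, w), 1e-3)
  w0 <- loss_weights(1, w_dice = 0, w_ce = 0)
  expect_equal(combined_loss(out, gt, w0), 0)
})

test_that("soft Dice loss equals 1 - DC for exactly binary probabilities", {
  set.seed(24)
  for (r in 1:10) {
    G <- random_mask(c(6, 6, 6), 0.3)
    P <- random_mask(c(6, 6, 6), 0.3)
    probs <- array(0, c(2, 6, 6, 6))
    probs[2, , , ] <- P; probs[1, , , ] <- 1 - P
    ld <- lemunet:::soft_dice_loss(probs, G)
    dc <- overlap_metrics(G, P)$DC
    if (sum(G) + sum(P) > 0)
      expect_equal(ld, 1 - dc, tolerance = 1e-3)
  }
})

test_that("ground-truth decimation follows the grid halving of the decoder", {
  g <- array(0L, c(8, 8, 8)); g[1, 1, 1] <- 1L; g[4, 4, 4] <- 1L
  d2 <- downsample_gt(g, 2)
  expect_equal(dim(d2), c(4L, 4L, 4L))
  expect_equal(d2[1, 1, 1], 1L)   # voxel at odd position survives
  expect_equal(sum(d2), 1L)       # voxel at even position dies
  cst <- array(1L, c(8, 8, 8))
  expect_true(all(downsample_gt(cst, 3) == 1L))
  expect_equal(dim(downsample_gt(cst, 4)), c(1L, 1L, 1L))
})

test_that("cohort evaluation produces a coherent report and serializes", {
  set.seed(25)
  gts <- preds <- list()
  for (i in 1:4) {
    G <- array(0L, c(10, 10, 10)); G[3:6, 3:6, 3:6] <- 1L
    gts[[i]] <- G
    preds[[i]] <- if (i <= 3) G else array(0L, dim(G))
  }
  rep_ <- evaluate_cases(gts, preds)
  expect_equal(nrow(rep_$per_case), 4)
  expect_equal(rep_$per_case$DC, c(1, 1, 1, 0))
  expect_equal(unname(rep_$detection$individual), c(75, 75))
  expect_equal(rep_$summary$DC$mean, 0.75)
  expect_equal(rep_$summary$HD95$n_defined, 3)  # empty prediction excluded
  td <- tempfile(); dir.create(td)
  write_evaluation_report(rep_, file.path(td, "e.csv"), file.path(td, "e.json"))
  back <- read.csv(file.path(td, "e.csv"))
  expect_equal(back$DC, c(1, 1, 1, 0))
  js <- jsonlite::read_json(file.path(td, "e.json"), simplifyVector = TRUE)
  expect_equal(js$summary$DC$mean, 0.75)
})
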