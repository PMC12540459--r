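# Multi-strategy feature fusion and the assembled edge-guided network:
# pyramid -> T1 branch -> edge attention at encoder stages 1-2 -> standard
# encoder/bottleneck/decoder -> fused features added to the last two decoder
# layers -> deep-supervision softmax heads.

binom5 <- c(1, 4, 6, 4, 1) / 16

gs3_arr <- function(v) {
  for (a in 1:3) v <- conv_axis_reflect(v, binom5, a)
  v
}

conv_axis_reflect_adj <- function(dy, kernel, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  y <- aperm(dy, perm)
  n <- dim(y)[1]
  p <- (length(kernel) - 1L) %/% 2L
  dxp <- array(0, dim(y) + c(2L * p, 0L, 0L))
  for (t in seq_along(kernel))
    dxp[t:(t + n - 1L), , ] <- dxp[t:(t + n - 1L), , ] + kernel[t] * y
  idx <- reflect_index((-p):(n - 1L + p), n)
  dx <- array(0, dim(y))
  for (q in seq_len(n + 2L * p))
    dx[idx[q], , ] <- dx[idx[q], , ] + dxp[q, , ]
  aperm(dx, order(perm))
}

gs3_arr_adj <- function(v) {
  for (a in 1:3) v <- conv_axis_reflect_adj(v, binom5, a)
  v
}

#' High-frequency residual of a feature map
#'
#' Per channel, `M = fd - up(d(gs(fd)))`: the one-level Laplacian residual
#' computed with the pyramid module's smoothing, decimation and trilinear
#' upsampling operators. Constant channels give identically zero output.
#'
#' @param fd numeric 4D feature array (C, D, H, W), every axis >= 2.
#' @return array of the same shape.
#' @export
highfreq_residual <- function(fd) {
  d <- dim(fd)
  if (length(d) != 4L || any(d[-1] < 2L)) stop("every spatial axis must be >= 2")
  out <- array(0, d)
  for (ch in seq_len(d[1])) {
    v <- array(fd[ch, , , ], d[-1])
    g <- gs3_arr(v)
    g <- g[seq(1L, d[2], 2L), seq(1L, d[3], 2L), seq(1L, d[4], 2L), drop = FALSE]
    for (a in 1:3) g <- lin_interp_axis(g, d[a + 1L], a)
    out[ch, , , ] <- v - g
  }
  out
}

# Adjoint: given dL/dM, returns dL/dfd.
highfreq_residual_adj <- function(dM) {
  d <- dim(dM)
  out <- array(0, d)
  half <- ceiling(d[-1] / 2)
  for (ch in seq_len(d[1])) {
    v <- array(dM[ch, , , ], d[-1])
    u <- v
    for (a in 1:3) u <- lin_interp_axis_adj(u, half[a], a)
    z <- array(0, d[-1])
    z[seq(1L, d[2], 2L), seq(1L, d[3], 2L), seq(1L, d[4], 2L)] <- u
    out[ch, , , ] <- v - gs3_arr_adj(z)
  }
  out
}

#' First multi-strategy fusion: gate edge features by decoder high frequencies
#'
#' `f_mff^1 = sigmoid(M^1) * f_edge^1` with `M^1 = highfreq_residual(fd1)`.
#'
#' @param fd1 decoder feature at full resolution (C, D, H, W).
#' @param fedge1 edge attention feature of the same shape.
#' @return fused feature, same shape.
#' @export
mff1 <- function(fd1, fedge1) {
  if (!all(dim(fd1) == dim(fedge1))) stop("shape mismatch")
  sigmoid(highfreq_residual(fd1)) * fedge1
}

#' Second multi-strategy fusion: combine both edge levels at half resolution
#'
#' `I = sigmoid(Conv(fedge2))`; `bridge = Conv(d(fedge1))` (stride-2 channel
#' subsampling, then a 1x1x1 channel-lifting convolution C -> 2C);
#' `f_mff^2 = sigmoid(M^2) * (fedge2 + bridge * I)`.
#'
#' @param params MFF parameter list (`conv_i` 2C->2C, `bridge` C->2C).
#' @param fd2 decoder feature at half resolution (2C channels).
#' @param fedge1 full-resolution edge feature (C channels).
#' @param fedge2 half-resolution edge feature (2C channels).
#' @return fused feature shaped like `fd2`.
#' @export
mff2 <- function(params, fd2, fedge1, fedge2) {
  if (!all(dim(fd2) == dim(fedge2))) stop("fd2/fedge2 shape mismatch")
  if (!all(ceiling(dim(fedge1)[-1] / 2) == dim(fd2)[-1])) stop("fedge1 resolution mismatch")
  I <- sigmoid(pw_fwd(params$conv_i, fedge2))
  br <- pw_fwd(params$bridge, stride2_sub(fedge1))
  sigmoid(highfreq_residual(fd2)) * (fedge2 + br * I)
}

#' Build the edge-guided segmentation network
#'
#' Assembles the full model: the MedNeXt-style backbone of [backbone_config()]
#' plus (i) a T1 encoding branch mirroring the first two encoder stages with
#' its own weights, (ii) a Laplacian edge attention (LEA) block at each of
#' encoder stages 1 and 2, and (iii) the multi-strategy fusion convolutions
#' applied at the last two decoder layers. With the same `cfg` and `seed` the
#' backbone weights are identical to [mednext_backbone()]'s.
#'
#' @param cfg a [backbone_config()].
#' @param lambda_init initial value of each LEA block's mixing weight
#'   (unconstrained scalar; 0.5 by default).
#' @param cbam_reduction channel-attention bottleneck ratio (hidden width is
#'   capped below at 1).
#' @param cbam_spatial_kernel odd kernel size of the spatial attention conv.
#' @param seed integer RNG seed for weight initialization.
#' @return a model object of class `lemunet_model`, type `"lemunet"`.
#' @export
lemunet <- function(cfg = backbone_config("M"), lambda_init = 0.5,
                    cbam_reduction = 16L, cbam_spatial_kernel = 7L, seed = 1L) {
  if (lambda_init < 0 || lambda_init > 1) stop("lambda_init must be in [0, 1]")
  set.seed(seed)
  C <- cfg$C; k <- cfg$k; B <- cfg$B; R <- cfg$R
  p <- backbone_params_init(cfg)
  p$t1_stem <- pw_init(1L, C)
  p$t1_enc0 <- stage_init(B[1], C, R[1], k)
  p$t1_down0 <- block_init(C, 2L * C, R[2], k, "down")
  p$t1_enc1 <- stage_init(B[2], 2L * C, R[2], k)
  p$lea1 <- lea_init(C, lambda_init, cbam_reduction, cbam_spatial_kernel)
  p$lea2 <- lea_init(2L * C, lambda_init, cbam_reduction, cbam_spatial_kernel)
  p$mff <- list(conv_i = pw_init(2L * C, 2L * C), bridge = pw_init(C, 2L * C))
  structure(list(params = p, cfg = cfg, type = "lemunet"),
            class = "lemunet_model")
}

#' T1 branch forward pass
#'
#' Runs the dedicated single-channel T1 encoder (own stem, stage-1 blocks,
#' down block, stage-2 blocks; weights not shared with the main encoder).
#'
#' @param model a `"lemunet"` model.
#' @param t1 3D array: the preprocessed T1 channel.
#' @return list with `feT1_1` (C x full res) and `feT1_2` (2C x half res).
#' @export
t1_branch_forward <- function(model, t1) {
  p <- model$params
  x <- array(t1, c(1L, dim(t1)))
  f1 <- stage_fwd(p$t1_enc0, pw_fwd(p$t1_stem, x))$y
  f2 <- stage_fwd(p$t1_enc1, block_fwd(p$t1_down0, f1, "down")$y)$y
  list(feT1_1 = f1, feT1_2 = f2)
}

## -- full network forward ----------------------------------------------------

net_fwd <- function(model, x, fusion_on = NULL, keep_cache = FALSE) {
  p <- model$params; cfg <- model$cfg
  d <- dim(x)
  if (length(d) != 4L) stop("input must be (channels, D, H, W)")
  if (d[1] != cfg$in_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$in_channels, d[1]))
  if (any(d[-1] %% 16L != 0L)) stop("grid must be divisible by 16")
  if (is.null(fusion_on)) fusion_on <- model$type == "lemunet"
  fusion_on <- fusion_on && model$type == "lemunet"
  cc <- list(x = x)

  if (fusion_on) {
    t1 <- array(x[1, , , ], d[-1])
    pyr <- build_laplacian_pyramid(volume(t1), 2L)
    cc$fl1 <- pyr$levels[[1]]$values
    cc$fl2 <- pyr$levels[[2]]$values
    cc$xt1 <- array(t1, c(1L, d[-1]))
    st1 <- pw_fwd(p$t1_stem, cc$xt1)
    cc$st1 <- st1
    cc$t1e0 <- stage_fwd(p$t1_enc0, st1)
    cc$t1dn <- block_fwd(p$t1_down0, cc$t1e0$y, "down")
    cc$t1e1 <- stage_fwd(p$t1_enc1, cc$t1dn$y)
  }

  s <- pw_fwd(p$stem, x)
  cc$e0 <- stage_fwd(p$enc0, s)
  fe1 <- cc$e0$y
  cc$dn0 <- block_fwd(p$down0, fe1, "down")
  cc$e1 <- stage_fwd(p$enc1, cc$dn0$y)
  fe2 <- cc$e1$y

  if (fusion_on) {
    cc$lea1 <- lea_fwd(p$lea1, fe1, cc$t1e0$y, cc$fl1)
    cc$lea2 <- lea_fwd(p$lea2, fe2, cc$t1e1$y, cc$fl2)
  }

  cc$dn1 <- block_fwd(p$down1, fe2, "down")
  cc$e2 <- stage_fwd(p$enc2, cc$dn1$y)
  cc$dn2 <- block_fwd(p$down2, cc$e2$y, "down")
  cc$e3 <- stage_fwd(p$enc3, cc$dn2$y)
  cc$dn3 <- block_fwd(p$down3, cc$e3$y, "down")
  cc$bn <- stage_fwd(p$bottleneck, cc$dn3$y)

  cc$u3 <- block_fwd(p$up3, cc$bn$y, "up")
  cc$o3 <- stage_fwd(p$dec3, cc$u3$y + cc$e3$y)
  cc$u2 <- block_fwd(p$up2, cc$o3$y, "up")
  cc$o2 <- stage_fwd(p$dec2, cc$u2$y + cc$e2$y)
  cc$u1 <- block_fwd(p$up1, cc$o2$y, "up")
  fd2 <- cc$u1$y + fe2
  cc$fd2 <- fd2

  if (fusion_on) {
    fedge1 <- cc$lea1$y; fedge2 <- cc$lea2$y
    cc$sM2 <- sigmoid(highfreq_residual(fd2))
    cc$I <- sigmoid(pw_fwd(p$mff$conv_i, fedge2))
    cc$fe1d <- stride2_sub(fedge1)
    cc$br <- pw_fwd(p$mff$bridge, cc$fe1d)
    fmff2 <- cc$sM2 * (fedge2 + cc$br * cc$I)
    fd2f <- fd2 + fmff2
  } else fd2f <- fd2
  cc$o1 <- stage_fwd(p$dec1, fd2f)
  cc$u0 <- block_fwd(p$up0, cc$o1$y, "up")
  fd1 <- cc$u0$y + fe1
  cc$fd1 <- fd1
  if (fusion_on) {
    cc$sM1 <- sigmoid(highfreq_residual(fd1))
    fmff1 <- cc$sM1 * fedge1
    fd1f <- fd1 + fmff1
  } else fd1f <- fd1
  cc$o0 <- stage_fwd(p$dec0, fd1f)

  feats <- list(cc$o0$y, cc$o1$y, cc$o2$y, cc$o3$y, cc$bn$y)
  z <- lapply(seq_len(cfg$ds_levels), function(i) pw_fwd(p$heads[[i]], feats[[i]]))
  cc$feats <- feats[seq_len(cfg$ds_levels)]
  cc$fusion_on <- fusion_on
  list(logits = z, cache = if (keep_cache) cc else NULL,
       features = if (fusion_on)
         list(fe1 = fe1, fe2 = fe2, fedge1 = cc$lea1$y, fedge2 = cc$lea2$y,
              fmff1 = fmff1, fmff2 = fmff2) else list(fe1 = fe1, fe2 = fe2))
}

## -- full network backward ---------------------------------------------------

net_bwd <- function(model, cc, dz) {
  p <- model$params
  fusion_on <- cc$fusion_on
  g <- stats::setNames(vector("list", length(p)), names(p))

  g$heads <- stats::setNames(vector("list", length(p$heads)), names(p$heads))
  dfeat <- vector("list", length(dz))
  for (i in seq_along(dz)) {
    hb <- pw_bwd(p$heads[[i]], cc$feats[[i]], dz[[i]])
    g$heads[[i]] <- hb$g
    dfeat[[i]] <- hb$dx
  }
  zero_like <- function(a) array(0, dim(a))
  getd <- function(i, a) if (i <= length(dfeat)) dfeat[[i]] else zero_like(a)

  fe1 <- cc$e0$y; fe2 <- cc$e1$y

  r0 <- stage_bwd(p$dec0, cc$o0$caches, getd(1L, cc$o0$y))
  g$dec0 <- r0$g
  dfd1 <- r0$dx
  dfedge1 <- NULL
  if (fusion_on) {
    fedge1 <- cc$lea1$y
    dfmff1 <- r0$dx
    dM1 <- dfmff1 * fedge1 * cc$sM1 * (1 - cc$sM1)
    dfedge1 <- dfmff1 * cc$sM1
    dfd1 <- dfd1 + highfreq_residual_adj(dM1)
  }
  bu0 <- block_bwd(p$up0, cc$u0$cache, dfd1, "up")
  g$up0 <- bu0$g
  de0 <- dfd1
  do1 <- getd(2L, cc$o1$y) + bu0$dx

  r1 <- stage_bwd(p$dec1, cc$o1$caches, do1)
  g$dec1 <- r1$g
  dfd2 <- r1$dx
  dfedge2 <- NULL
  if (fusion_on) {
    fedge2 <- cc$lea2$y
    dfmff2 <- r1$dx
    tt <- fedge2 + cc$br * cc$I
    dM2 <- dfmff2 * tt * cc$sM2 * (1 - cc$sM2)
    dfd2 <- dfd2 + highfreq_residual_adj(dM2)
    dt <- dfmff2 * cc$sM2
    dfedge2 <- dt
    dbr <- dt * cc$I
    dIpre <- dt * cc$br * cc$I * (1 - cc$I)
    bci <- pw_bwd(p$mff$conv_i, fedge2, dIpre)
    dfedge2 <- dfedge2 + bci$dx
    bbr <- pw_bwd(p$mff$bridge, cc$fe1d, dbr)
    dfedge1 <- dfedge1 + stride2_sub_adj(bbr$dx, dim(fedge1))
    g$mff <- list(conv_i = bci$g, bridge = bbr$g)
  }
  bu1 <- block_bwd(p$up1, cc$u1$cache, dfd2, "up")
  g$up1 <- bu1$g
  de1 <- dfd2
  do2 <- getd(3L, cc$o2$y) + bu1$dx

  r2 <- stage_bwd(p$dec2, cc$o2$caches, do2)
  g$dec2 <- r2$g
  bu2 <- block_bwd(p$up2, cc$u2$cache, r2$dx, "up")
  g$up2 <- bu2$g
  de2 <- r2$dx
  do3 <- getd(4L, cc$o3$y) + bu2$dx

  r3 <- stage_bwd(p$dec3, cc$o3$caches, do3)
  g$dec3 <- r3$g
  bu3 <- block_bwd(p$up3, cc$u3$cache, r3$dx, "up")
  g$up3 <- bu3$g
  de3 <- r3$dx
  dbn <- getd(5L, cc$bn$y) + bu3$dx

  rb <- stage_bwd(p$bottleneck, cc$bn$caches, dbn)
  g$bottleneck <- rb$g
  b3 <- block_bwd(p$down3, cc$dn3$cache, rb$dx, "down")
  g$down3 <- b3$g
  de3 <- de3 + b3$dx
  r3e <- stage_bwd(p$enc3, cc$e3$caches, de3)
  g$enc3 <- r3e$g
  b2 <- block_bwd(p$down2, cc$dn2$cache, r3e$dx, "down")
  g$down2 <- b2$g
  de2 <- de2 + b2$dx
  r2e <- stage_bwd(p$enc2, cc$e2$caches, de2)
  g$enc2 <- r2e$g
  b1 <- block_bwd(p$down1, cc$dn1$cache, r2e$dx, "down")
  g$down1 <- b1$g
  de1 <- de1 + b1$dx

  dfeT1_1 <- dfeT1_2 <- NULL
  if (fusion_on) {
    l2 <- lea_bwd(p$lea2, cc$lea2$cache, dfedge2)
    g$lea2 <- l2$g
    de1 <- de1 + l2$dfe
    dfeT1_2 <- l2$dfeT1
  }
  r1e <- stage_bwd(p$enc1, cc$e1$caches, de1)
  g$enc1 <- r1e$g
  b0 <- block_bwd(p$down0, cc$dn0$cache, r1e$dx, "down")
  g$down0 <- b0$g
  de0 <- de0 + b0$dx
  if (fusion_on) {
    l1 <- lea_bwd(p$lea1, cc$lea1$cache, dfedge1)
    g$lea1 <- l1$g
    de0 <- de0 + l1$dfe
    dfeT1_1 <- l1$dfeT1
  }
  r0e <- stage_bwd(p$enc0, cc$e0$caches, de0)
  g$enc0 <- r0e$g
  sb <- pw_bwd(p$stem, cc$x, r0e$dx)
  g$stem <- sb$g

  if (fusion_on) {
    rt1 <- stage_bwd(p$t1_enc1, cc$t1e1$caches, dfeT1_2)
    g$t1_enc1 <- rt1$g
    bt1 <- block_bwd(p$t1_down0, cc$t1dn$cache, rt1$dx, "down")
    g$t1_down0 <- bt1$g
    dfeT1_1 <- dfeT1_1 + bt1$dx
    rt0 <- stage_bwd(p$t1_enc0, cc$t1e0$caches, dfeT1_1)
    g$t1_enc0 <- rt0$g
    st1b <- pw_bwd(p$t1_stem, cc$xt1, rt0$dx)
    g$t1_stem <- st1b$g
  } else if (model$type == "lemunet") {
    # fill untouched parameter groups with zeros so the gradient structure
    # always mirrors the parameter structure
    zg <- function(x) if (is.list(x)) lapply(x, zg) else array(0, dim(x) %||% length(x))
    for (nm in c("t1_stem", "t1_enc0", "t1_down0", "t1_enc1", "lea1", "lea2", "mff"))
      g[[nm]] <- zg(p[[nm]])
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the segmentation network
#'
#' Forward pass on one multimodal case tensor. The first channel must be the
#' (preprocessed) T1 image: it feeds the Laplacian pyramid and the T1 encoding
#' branch. Returns per-voxel class probabilities at every deep-supervision
#' level, full resolution first.
#'
#' @param model a model from [lemunet()] or [mednext_backbone()].
#' @param x numeric 4D array (in_channels, D, H, W); grid divisible by 16.
#' @param fusion_off if `TRUE`, forces both fused features to zero so the
#'   network reduces exactly to the plain backbone.
#' @return object of class `segmentation_output`: list of probability arrays
#'   (out_classes, D/2^(i-1), ...), one per level.
#' @export
lemunet_forward <- function(model, x, fusion_off = FALSE) {
  r <- net_fwd(model, x, fusion_on = if (fusion_off) FALSE else NULL)
  probs <- lapply(r$logits, softmax_channels)
  structure(probs, class = "segmentation_output")
}

#' @export
print.segmentation_output <- function(x, ...) {
  cat(sprintf("<segmentation_output> %d deep-supervision level(s)\n", length(x)))
  for (i in seq_along(x))
    cat(sprintf("  level %d: %s\n", i, paste(dim(x[[i]]), collapse = " x ")))
  invisible(x)
}

#' @export
predict.lemunet_model <- function(object, x, postprocess = FALSE, gt = NULL, ...) {
  probs <- lemunet_forward(object, x)
  cls <- max.col(t(fm_mat(probs[[1]])), ties.method = "first") - 1L
  mask <- array(as.integer(cls > 0L), dim(probs[[1]])[-1])
  if (postprocess && !is.null(gt)) mask <- largest_component_postprocess(mask, gt)
  mask
}
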