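# Laplacian edge attention: CBAM on the main-encoder and T1-branch features,
# learnable-lambda mixing, and sigmoid gating with the Laplacian
# high-frequency level.

## -- CBAM --------------------------------------------------------------------
## Channel attention: sigmoid(MLP(avgpool) + MLP(maxpool)) scales channels;
## spatial attention: sigmoid(dense k^3 conv over the channel-wise mean/max
## maps) scales voxels. Channel-then-spatial, separate weights per branch.

cbam_init <- function(C, reduction = 16L, spatial_kernel = 7L) {
  h <- max(1L, C %/% reduction)
  list(W1 = init_mat(h, C, C), b1 = numeric(h),
       W2 = init_mat(C, h, h), b2 = numeric(C),
       wsp = array(stats::runif(spatial_kernel^3 * 2, -1, 1) / sqrt(2 * spatial_kernel^3),
                   c(spatial_kernel, spatial_kernel, spatial_kernel, 2L, 1L)),
       bsp = numeric(1))
}

cbam_fwd <- function(p, x) {
  d <- dim(x); C <- d[1]; V <- prod(d[-1])
  xm <- fm_mat(x)
  avg <- rowMeans(xm)
  argmax_vox <- apply(xm, 1, which.max)
  mx <- xm[cbind(seq_len(C), argmax_vox)]
  h_avg <- relu_fwd(drop(p$W1 %*% avg) + p$b1)
  h_max <- relu_fwd(drop(p$W1 %*% mx) + p$b1)
  u <- drop(p$W2 %*% h_avg) + drop(p$W2 %*% h_max) + 2 * p$b2
  s <- sigmoid(u)
  y1 <- x * s
  y1m <- fm_mat(y1)
  meanmap <- colMeans(y1m)
  ty <- t(y1m)
  argmax_ch <- max.col(ty, ties.method = "first")
  maxmap <- ty[cbind(seq_len(V), argmax_ch)]
  spin <- rbind(meanmap, maxmap)
  dim(spin) <- c(2L, d[-1])
  pre <- cpp_dense3_fwd(spin, dim(spin), p$wsp, dim(p$wsp)[1], 1L, p$bsp)
  m <- sigmoid(pre)
  mv <- as.numeric(m)
  y <- y1 * rep(mv, each = C)
  dim(y) <- d
  list(y = y, cache = list(x = x, avg = avg, mx = mx, argmax_vox = argmax_vox,
                           h_avg = h_avg, h_max = h_max, s = s, y1 = y1,
                           argmax_ch = argmax_ch, spin = spin, m = mv))
}

cbam_bwd <- function(p, cache, dy) {
  d <- dim(dy); C <- d[1]; V <- prod(d[-1])
  dym <- fm_mat(dy)
  y1m <- fm_mat(cache$y1)
  mrep <- rep(cache$m, each = C)
  dy1m <- dym * mrep
  dmv <- colSums(dym * y1m)
  dpre <- dmv * cache$m * (1 - cache$m)
  dim(dpre) <- c(1L, d[-1])
  bs <- cpp_dense3_bwd(dpre, cache$spin, dim(cache$spin), p$wsp, dim(p$wsp)[1], 1L)
  dspin <- fm_mat(bs$dx)
  dy1m <- dy1m + matrix(dspin[1, ] / C, C, V, byrow = TRUE)
  idx <- cbind(cache$argmax_ch, seq_len(V))
  dy1m[idx] <- dy1m[idx] + dspin[2, ]
  xm <- fm_mat(cache$x)
  dxm <- dy1m * cache$s
  ds <- rowSums(dy1m * xm)
  du <- ds * cache$s * (1 - cache$s)
  db2 <- 2 * du
  dh_avg <- drop(crossprod(p$W2, du)) * (cache$h_avg > 0)
  dh_max <- drop(crossprod(p$W2, du)) * (cache$h_max > 0)
  dW2 <- tcrossprod(du, cache$h_avg) + tcrossprod(du, cache$h_max)
  dW1 <- tcrossprod(dh_avg, cache$avg) + tcrossprod(dh_max, cache$mx)
  db1 <- dh_avg + dh_max
  davg <- drop(crossprod(p$W1, dh_avg))
  dmx <- drop(crossprod(p$W1, dh_max))
  dxm <- dxm + davg / V
  midx <- cbind(seq_len(C), cache$argmax_vox)
  dxm[midx] <- dxm[midx] + dmx
  dx <- dxm
  dim(dx) <- d
  list(dx = dx, g = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                         wsp = bs$dw, bsp = bs$db))
}

#' Convolutional block attention (CBAM) forward pass
#'
#' @param params CBAM parameter list (`W1`, `b1`, `W2`, `b2`, `wsp`, `bsp`).
#' @param x numeric 4D array (C, D, H, W); C must be divisible so the reduced
#'   hidden layer is at least 1 (builders cap the reduction).
#' @return gated feature array, same shape as `x`.
#' @export
cbam <- function(params, x) cbam_fwd(params, x)$y

## -- LEA block ---------------------------------------------------------------

lea_init <- function(C, lambda_init = 0.5, reduction = 16L, spatial_kernel = 7L) {
  list(cbam_main = cbam_init(C, reduction, spatial_kernel),
       cbam_t1 = cbam_init(C, reduction, spatial_kernel),
       lambda = lambda_init,
       bn_mix = cn_init(C),
       conv = pw_init(C + 1L, C),
       bn_out = cn_init(C))
}

lea_fwd <- function(p, fe, feT1, fl) {
  if (!all(dim(fe) == dim(feT1))) stop("fe and feT1 must share shape")
  if (!all(dim(fe)[-1] == dim(fl))) stop("Laplacian level resolution mismatch")
  a <- cbam_fwd(p$cbam_main, fe)
  b <- cbam_fwd(p$cbam_t1, feT1)
  lam <- p$lambda
  mix <- lam * a$y + (1 - lam) * b$y
  nm <- cn_fwd(p$bn_mix, mix)
  d <- dim(fe)
  cat_ <- array(0, c(d[1] + 1L, d[-1]))
  cat_[1, , , ] <- fl
  cat_[-1, , , ] <- nm$y
  map <- sigmoid(cat_)
  z <- pw_fwd(p$conv, map)
  no <- cn_fwd(p$bn_out, z)
  fedge <- gelu_fwd(no$y)
  list(y = fedge, cache = list(a = a, b = b, nm = nm, map = map, z = z, no = no))
}

lea_bwd <- function(p, cache, dy) {
  dno_y <- gelu_bwd(cache$no$y, dy)
  bo <- cn_bwd(p$bn_out, cache$no, dno_y)
  bz <- pw_bwd(p$conv, cache$map, bo$dx)
  dcat <- bz$dx * cache$map * (1 - cache$map)
  dnm_y <- dcat[-1, , , , drop = FALSE]
  bm <- cn_bwd(p$bn_mix, cache$nm, dnm_y)
  lam <- p$lambda
  dlam <- sum(bm$dx * (cache$a$y - cache$b$y))
  ca <- cbam_bwd(p$cbam_main, cache$a$cache, lam * bm$dx)
  cb <- cbam_bwd(p$cbam_t1, cache$b$cache, (1 - lam) * bm$dx)
  list(dfe = ca$dx, dfeT1 = cb$dx,
       g = list(cbam_main = ca$g, cbam_t1 = cb$g, lambda = dlam,
                bn_mix = bm$g, conv = bz$g, bn_out = bo$g))
}

#' Mix main-branch and T1-branch attention features
#'
#' Computes `BN(CBAM(fe) * lambda + CBAM(feT1) * (1 - lambda))`; the mixing
#' weight of the T1 branch is structurally `1 - lambda`.
#'
#' @param params LEA parameter list.
#' @param fe,feT1 (C, D, H, W) feature arrays of identical shape.
#' @param lambda optional override of the block's mixing weight.
#' @return the mixed, normalized feature map.
#' @export
combine_branches <- function(params, fe, feT1, lambda = NULL) {
  if (!all(dim(fe) == dim(feT1))) stop("fe and feT1 must share shape")
  lam <- if (is.null(lambda)) params$lambda else lambda
  a <- cbam_fwd(params$cbam_main, fe)$y
  b <- cbam_fwd(params$cbam_t1, feT1)$y
  cn_fwd(params$bn_mix, lam * a + (1 - lam) * b)$y
}

#' Gate a feature map with a Laplacian high-frequency level
#'
#' `map = sigmoid(concat[fl, fmap])` (C+1 channels), then
#' `f_edge = GELU(BN(Conv_1x1x1(map)))` back to C channels.
#'
#' @param params LEA parameter list (uses `conv` and `bn_out`).
#' @param fl 3D array (or 1-channel 4D array): the Laplacian level.
#' @param fmap (C, D, H, W) mixed feature map at the same resolution.
#' @return (C, D, H, W) edge attention feature.
#' @export
edge_attend <- function(params, fl, fmap) {
  if (length(dim(fl)) == 4L) {
    if (dim(fl)[1] != 1L) stop("fl must have exactly 1 channel")
    fl <- array(fl, dim(fl)[-1])
  }
  if (!all(dim(fmap)[-1] == dim(fl))) stop("resolution mismatch")
  d <- dim(fmap)
  cat_ <- array(0, c(d[1] + 1L, d[-1]))
  cat_[1, , , ] <- fl
  cat_[-1, , , ] <- fmap
  map <- sigmoid(cat_)
  gelu_fwd(cn_fwd(params$bn_out, pw_fwd(params$conv, map))$y)
}
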