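#' Backbone configuration
#'
#' Describes the ConvNeXt-style encoder-decoder: base width `C`, depthwise
#' kernel size `k`, the nine per-stage block counts `B` and expansion ratios
#' `R` (4 encoder stages, bottleneck, 4 decoder stages, in that order), the
#' number of input channels and output classes, and the number of
#' deep-supervision levels `D` (full resolution first).
#'
#' The named sizes follow the reference compound-scaled configurations:
#' `"M"` has `B = c(3,4,4,4,4,4,4,4,3)`, `R = c(2,3,4,4,4,4,4,3,2)`; `"L"` has
#' `B = c(3,4,8,8,8,8,8,4,3)`, `R = c(3,4,8,8,8,8,8,4,3)`; both with `C = 32`.
#'
#' @param size `"M"`, `"L"`, or `"custom"` (then give `B` and `R`).
#' @param C base channel count (width of the full-resolution stage).
#' @param k odd depthwise kernel size.
#' @param B integer length-9 block counts (used when `size = "custom"`).
#' @param R integer length-9 expansion ratios (used when `size = "custom"`).
#' @param in_channels number of input image channels (T1 first).
#' @param out_classes number of segmentation classes (>= 2).
#' @param ds_levels number of deep-supervision outputs (1..5).
#' @return a `backbone_config` list.
#' @export
backbone_config <- function(size = c("M", "L", "custom"), C = 32L, k = 3L,
                            B = NULL, R = NULL, in_channels = 3L,
                            out_classes = 2L, ds_levels = 5L) {
  size <- match.arg(size)
  if (size == "M") { B <- c(3L, 4L, 4L, 4L, 4L, 4L, 4L, 4L, 3L); R <- c(2L, 3L, 4L, 4L, 4L, 4L, 4L, 3L, 2L) }
  if (size == "L") { B <- c(3L, 4L, 8L, 8L, 8L, 8L, 8L, 4L, 3L); R <- c(3L, 4L, 8L, 8L, 8L, 8L, 8L, 4L, 3L) }
  B <- as.integer(B); R <- as.integer(R)
  if (length(B) != 9L || length(R) != 9L) stop("B and R must have length 9")
  if (any(B < 1L) || any(R < 1L)) stop("all entries of B and R must be >= 1")
  if (C < 1L) stop("C must be >= 1")
  if (k %% 2L != 1L) stop("kernel size must be odd")
  if (out_classes < 2L) stop("out_classes must be >= 2")
  if (ds_levels < 1L || ds_levels > 5L) stop("ds_levels must be in 1..5")
  structure(list(size = size, C = as.integer(C), k = as.integer(k), B = B, R = R,
                 in_channels = as.integer(in_channels),
                 out_classes = as.integer(out_classes),
                 ds_levels = as.integer(ds_levels)),
            class = "backbone_config")
}

## -- one ConvNeXt-style block ------------------------------------------------
## depthwise k^3 conv -> per-channel norm -> 1x1x1 expansion (R*C) with GELU
## -> 1x1x1 compression -> residual. Down blocks stride the depthwise conv and
## add a 1x1x1 stride-2 residual conv; up blocks use transposed convolutions.

block_init <- function(cin, cout, R, k, type = c("plain", "down", "up")) {
  type <- match.arg(type)
  p <- list(dw = dw_init(cin, k), norm = cn_init(cin),
            exp = pw_init(cin, R * cin), comp = pw_init(R * cin, cout))
  if (type != "plain") p$res <- pw_init(cin, cout)
  p
}

stride2_sub <- function(x) {
  d <- dim(x)
  x[, seq(1L, d[2], by = 2L), seq(1L, d[3], by = 2L), seq(1L, d[4], by = 2L),
    drop = FALSE]
}

stride2_sub_adj <- function(dy, d) {
  out <- array(0, d)
  out[, seq(1L, d[2], by = 2L), seq(1L, d[3], by = 2L), seq(1L, d[4], by = 2L)] <- dy
  out
}

block_fwd <- function(p, x, type = "plain") {
  h1 <- switch(type,
    plain = dw_fwd(p$dw, x, 1L),
    down  = dw_fwd(p$dw, x, 2L),
    up    = dwt_fwd(p$dw, x))
  nrm <- cn_fwd(p$norm, h1)
  e <- pw_fwd(p$exp, nrm$y)
  a <- gelu_fwd(e)
  y <- pw_fwd(p$comp, a)
  cache <- list(x = x, nrm = nrm, e = e, a = a)
  if (type == "plain") {
    y <- y + x
  } else if (type == "down") {
    cache$xsub <- stride2_sub(x)
    y <- y + pw_fwd(p$res, cache$xsub)
  } else {
    y <- y + pwt2_fwd(p$res, x)
  }
  list(y = y, cache = cache)
}

block_bwd <- function(p, cache, dy, type = "plain") {
  bc <- pw_bwd(p$comp, cache$a, dy)
  de <- gelu_bwd(cache$e, bc$dx)
  be <- pw_bwd(p$exp, cache$nrm$y, de)
  bn <- cn_bwd(p$norm, cache$nrm, be$dx)
  g <- list(dw = NULL, norm = bn$g, exp = be$g, comp = bc$g)
  if (type == "plain") {
    bd <- dw_bwd(p$dw, cache$x, bn$dx, 1L)
    g$dw <- bd$g
    dx <- bd$dx + dy
  } else if (type == "down") {
    bd <- dw_bwd(p$dw, cache$x, bn$dx, 2L)
    g$dw <- bd$g
    br <- pw_bwd(p$res, cache$xsub, dy)
    g$res <- br$g
    dx <- bd$dx + stride2_sub_adj(br$dx, dim(cache$x))
  } else {
    bd <- dwt_bwd(p$dw, cache$x, bn$dx)
    g$dw <- bd$g
    br <- pwt2_bwd(p$res, cache$x, dy)
    g$res <- br$g
    dx <- bd$dx + br$dx
  }
  list(dx = dx, g = g[names(p)])
}

stage_init <- function(n, C, R, k) lapply(seq_len(n), function(i) block_init(C, C, R, k))

stage_fwd <- function(ps, x) {
  caches <- vector("list", length(ps))
  for (i in seq_along(ps)) {
    r <- block_fwd(ps[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, caches = caches)
}

stage_bwd <- function(ps, caches, dy) {
  g <- vector("list", length(ps))
  for (i in rev(seq_along(ps))) {
    r <- block_bwd(ps[[i]], caches[[i]], dy)
    dy <- r$dx
    g[[i]] <- r$g
  }
  list(dx = dy, g = g)
}

backbone_params_init <- function(cfg) {
  C <- cfg$C; k <- cfg$k; B <- cfg$B; R <- cfg$R
  widths <- C * c(1L, 2L, 4L, 8L, 16L)
  p <- list(
    stem = pw_init(cfg$in_channels, C),
    enc0 = stage_init(B[1], widths[1], R[1], k),
    down0 = block_init(widths[1], widths[2], R[2], k, "down"),
    enc1 = stage_init(B[2], widths[2], R[2], k),
    down1 = block_init(widths[2], widths[3], R[3], k, "down"),
    enc2 = stage_init(B[3], widths[3], R[3], k),
    down2 = block_init(widths[3], widths[4], R[4], k, "down"),
    enc3 = stage_init(B[4], widths[4], R[4], k),
    down3 = block_init(widths[4], widths[5], R[5], k, "down"),
    bottleneck = stage_init(B[5], widths[5], R[5], k),
    up3 = block_init(widths[5], widths[4], R[6], k, "up"),
    dec3 = stage_init(B[6], widths[4], R[6], k),
    up2 = block_init(widths[4], widths[3], R[7], k, "up"),
    dec2 = stage_init(B[7], widths[3], R[7], k),
    up1 = block_init(widths[3], widths[2], R[8], k, "up"),
    dec1 = stage_init(B[8], widths[2], R[8], k),
    up0 = block_init(widths[2], widths[1], R[9], k, "up"),
    dec0 = stage_init(B[9], widths[1], R[9], k)
  )
  p$heads <- lapply(seq_len(cfg$ds_levels),
                    function(i) pw_init(widths[i], cfg$out_classes))
  names(p$heads) <- paste0("h", seq_len(cfg$ds_levels))
  p
}

#' Build a plain MedNeXt-style backbone
#'
#' Encoder (stem + 4 stages with 2x down blocks), bottleneck, decoder
#' (4 stages with 2x up blocks and additive skips), and one softmax head per
#' deep-supervision level. Initialization is fully determined by `seed`.
#'
#' @param cfg a [backbone_config()].
#' @param seed integer RNG seed for weight initialization.
#' @return a model object of class `lemunet_model`, type `"mednext"`.
#' @export
mednext_backbone <- function(cfg = backbone_config("M"), seed = 1L) {
  set.seed(seed)
  structure(list(params = backbone_params_init(cfg), cfg = cfg,
                 type = "mednext"),
            class = "lemunet_model")
}

#' @export
print.lemunet_model <- function(x, ...) {
  cat(sprintf("<%s model> size %s, C=%d, kernel %d, in=%d, classes=%d, ds=%d\n",
              x$type, x$cfg$size, x$cfg$C, x$cfg$k, x$cfg$in_channels,
              x$cfg$out_classes, x$cfg$ds_levels))
  cat(sprintf("  trainable parameters: %s (%.2f M)\n",
              format(count_parameters(x), big.mark = ","),
              count_parameters(x) / 1e6))
  invisible(x)
}

#' Forward pass of a single ConvNeXt-style block
#'
#' Exposed for inspection and testing: applies one residual block with the
#' given parameters to a (C, D, H, W) feature array.
#'
#' @param params block parameter list as produced by the model builders
#'   (fields `dw`, `norm`, `exp`, `comp`, optionally `res`).
#' @param x numeric 4D array (C, D, H, W).
#' @param type `"plain"`, `"down"` or `"up"`.
#' @return the output feature array.
#' @export
mednext_block <- function(params, x, type = "plain") {
  if (dim(x)[1] != dim(params$dw$w)[4])
    stop("channel mismatch with block's configured width")
  block_fwd(params, x, type)$y
}
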