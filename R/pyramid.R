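#' 3D Gaussian smoothing with the binomial pyramid kernel
#'
#' Separable smoothing with the classic 5-tap binomial kernel
#' `[1,4,6,4,1]/16` along each axis, using reflect (mirror) borders. The
#' kernel has unit sum and is symmetric, so spatially constant volumes are
#' unchanged and interior affine ramps are preserved.
#'
#' @param vol a [volume()].
#' @return a smoothed `volume` with the same shape and spacing.
#' @export
gaussian_smooth <- function(vol) {
  stopifnot_volume(vol)
  k <- c(1, 4, 6, 4, 1) / 16
  v <- vol$values
  for (a in 1:3) v <- conv_axis_reflect(v, k, a)
  volume(v, vol$spacing)
}

#' Decimate a volume by 2 along every axis
#'
#' Keeps voxels at even 0-based positions (output voxel (i,j,k) equals input
#' voxel (2i,2j,2k)); axis lengths become `ceiling(n/2)` and spacing doubles.
#'
#' @param vol a [volume()].
#' @return the decimated `volume`.
#' @export
downsample2 <- function(vol) {
  stopifnot_volume(vol)
  d <- dim(vol$values)
  v <- vol$values[seq(1, d[1], by = 2), seq(1, d[2], by = 2), seq(1, d[3], by = 2),
                  drop = FALSE]
  volume(v, vol$spacing * 2)
}

#' Upsample a volume by 2 with trilinear interpolation
#'
#' Endpoint-aligned trilinear interpolation to an explicit `target_shape`, each
#' axis of which must be `2n-1` or `2n` of the input's `n` (so pyramid
#' round-trips restore the exact original shape). Constants map to constants.
#'
#' @param vol a [volume()].
#' @param target_shape integer length-3.
#' @return the upsampled `volume`, spacing halved.
#' @export
upsample2 <- function(vol, target_shape) {
  stopifnot_volume(vol)
  d <- dim(vol$values)
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != 3L || any(target_shape < 2 * d - 1 | target_shape > 2 * d))
    stop("target_shape must be 2n-1 or 2n per axis")
  v <- vol$values
  for (a in 1:3) v <- lin_interp_axis(v, target_shape[a], a)
  volume(v, vol$spacing / 2)
}

#' Build a 3D Laplacian pyramid
#'
#' The Gaussian chain is `N_0 = N`, `N_{k+1} = d(gs(N_k))` (binomial smoothing
#' then 2x decimation), and level `k` stores the high-frequency residual
#' `L_k = N_k - up(N_{k+1})`. The returned object holds the `K` residual
#' levels plus the top Gaussian level, from which the input can be
#' reconstructed exactly.
#'
#' @param vol a [volume()]; every axis must be at least `2^K`.
#' @param K number of residual levels (>= 1).
#' @return an object of class `laplacian_pyramid` with fields `levels` (list of
#'   `volume`, `L_0 ... L_{K-1}`), `top` (Gaussian level `N_K`) and
#'   `source_shape`.
#' @export
build_laplacian_pyramid <- function(vol, K = 2L) {
  stopifnot_volume(vol)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (any(dim(vol$values) < 2^K))
    stop(sprintf("every axis must be >= 2^K = %d for K = %d levels", 2^K, K))
  N <- vol
  levels <- vector("list", K)
  for (k in seq_len(K)) {
    Nnext <- downsample2(gaussian_smooth(N))
    upv <- upsample2(Nnext, dim(N$values))
    levels[[k]] <- volume(N$values - upv$values, N$spacing)
    N <- Nnext
  }
  structure(list(levels = levels, top = N, source_shape = dim(vol$values)),
            class = "laplacian_pyramid")
}

#' Reconstruct a volume from its Laplacian pyramid
#'
#' Applies `N_k = L_k + up(N_{k+1})` from the top down; exact (to float
#' round-off) by construction.
#'
#' @param pyr a `laplacian_pyramid`.
#' @return the reconstructed `volume`.
#' @export
reconstruct_pyramid <- function(pyr) {
  if (!inherits(pyr, "laplacian_pyramid")) stop("expected a `laplacian_pyramid`")
  N <- pyr$top
  for (k in rev(seq_along(pyr$levels))) {
    L <- pyr$levels[[k]]
    up <- upsample2(N, dim(L$values))
    N <- volume(L$values + up$values, L$spacing)
  }
  N
}

#' @export
print.laplacian_pyramid <- function(x, ...) {
  cat(sprintf("<laplacian_pyramid> %d residual level(s) from a %s grid\n",
              length(x$levels), paste(x$source_shape, collapse = " x ")))
  for (k in seq_along(x$levels))
    cat(sprintf("  L_%d: %s\n", k - 1L,
                paste(dim(x$levels[[k]]$values), collapse = " x ")))
  cat(sprintf("  top: %s\n", paste(dim(x$top$values), collapse = " x ")))
  invisible(x)
}
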