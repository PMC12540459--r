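#' Construct a 3D image volume
#'
#' A volume is the basic unit every image operation in the package consumes and
#' produces: a dense 3D scalar grid plus the physical voxel spacing in mm.
#'
#' @param values numeric 3D array (D x H x W); all values must be finite.
#' @param spacing numeric length-3, mm per voxel along each axis; strictly positive.
#' @return an object of class `volume` with fields `values` and `spacing`.
#' @export
volume <- function(values, spacing = c(1, 1, 1)) {
  if (is.null(dim(values)) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (!all(is.finite(values)))
    stop("`values` must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers")
  structure(list(values = values, spacing = spacing), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

as_volume <- function(x, spacing = c(1, 1, 1)) {
  if (inherits(x, "volume")) x else volume(x, spacing)
}

stopifnot_volume <- function(vol) {
  if (!inherits(vol, "volume")) stop("expected a `volume` object")
  if (!all(is.finite(vol$values))) stop("volume contains non-finite values")
  invisible(vol)
}

# 0-based reflect (mirror without edge repetition) index for positions i of an
# axis of length n; returns 1-based indices into the axis.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  m <- ((i %% period) + period) %% period
  m <- ifelse(m >= n, period - m, m)
  as.integer(m) + 1L
}

# Apply a symmetric 1D kernel along one axis of a 3D array with reflect borders.
conv_axis_reflect <- function(x, kernel, axis) {
  n <- dim(x)[axis]
  p <- (length(kernel) - 1L) %/% 2L
  idx <- reflect_index((-p):(n - 1L + p), n)
  xp <- switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
               x[, , idx, drop = FALSE])
  out <- array(0, dim(x))
  for (t in seq_along(kernel)) {
    sl <- t:(t + n - 1L)
    out <- out + kernel[t] * switch(axis,
      xp[sl, , , drop = FALSE], xp[, sl, , drop = FALSE], xp[, , sl, drop = FALSE])
  }
  out
}

# Linear interpolation of one axis to m samples using endpoint-aligned
# positions (constant-preserving; exact for m == n).
lin_interp_axis <- function(x, m, axis) {
  n <- dim(x)[axis]
  if (m == n) return(x)
  if (n == 1L) {
    per <- rep(1L, m)
    return(switch(axis, x[per, , , drop = FALSE], x[, per, , drop = FALSE],
                  x[, , per, drop = FALSE]))
  }
  pos <- (0:(m - 1L)) * (n - 1) / (m - 1)
  i0 <- pmin(floor(pos), n - 2)
  w <- pos - i0
  i0 <- as.integer(i0) + 1L
  i1 <- i0 + 1L
  a <- switch(axis, x[i0, , , drop = FALSE], x[, i0, , drop = FALSE], x[, , i0, drop = FALSE])
  b <- switch(axis, x[i1, , , drop = FALSE], x[, i1, , drop = FALSE], x[, , i1, drop = FALSE])
  wr <- switch(axis, array(w, c(m, dim(x)[2], dim(x)[3])),
               aperm(array(w, c(m, dim(x)[1], dim(x)[3])), c(2, 1, 3)),
               aperm(array(w, c(m, dim(x)[1], dim(x)[2])), c(2, 3, 1)))
  (1 - wr) * a + wr * b
}

# Adjoint of lin_interp_axis: scatter a gradient on m samples back to n.
lin_interp_axis_adj <- function(dy, n, axis) {
  m <- dim(dy)[axis]
  if (m == n) return(dy)
  dms <- dim(dy)
  out_dim <- dms; out_dim[axis] <- n
  out <- array(0, out_dim)
  if (n == 1L) {
    s <- apply(dy, setdiff(1:3, axis), sum)
    out[] <- array(s, out_dim[setdiff(1:3, axis)])  # only axis length 1 case
    return(out)
  }
  pos <- (0:(m - 1L)) * (n - 1) / (m - 1)
  i0 <- pmin(floor(pos), n - 2)
  w <- pos - i0
  i0 <- as.integer(i0) + 1L
  for (j in seq_len(m)) {
    sl <- switch(axis, dy[j, , , drop = FALSE], dy[, j, , drop = FALSE], dy[, , j, drop = FALSE])
    add <- function(i, coef) {
      if (coef == 0) return()
      if (axis == 1L) out[i, , ] <<- out[i, , ] + coef * sl[1, , ]
      else if (axis == 2L) out[, i, ] <<- out[, i, ] + coef * sl[, 1, ]
      else out[, , i] <<- out[, , i] + coef * sl[, , 1]
    }
    add(i0[j], 1 - w[j]); add(i0[j] + 1L, w[j])
  }
  out
}

#' Pad or crop a 3D array symmetrically to a target shape
#'
#' Center pad (with a constant) or center crop each axis to reach `target`.
#' Used to bring preprocessed volumes to the fixed network grid.
#'
#' @param x 3D array.
#' @param target integer length-3 target shape.
#' @param pad_value value used for padding (default 0).
#' @return list with `values` (the padded/cropped array) and `offset`, the
#'   0-based position of the original array's first voxel inside the output
#'   (negative when cropped), needed to invert the operation.
#' @export
pad_crop_center <- function(x, target, pad_value = 0) {
  d <- dim(x)
  target <- as.integer(target)
  off <- (target - d) %/% 2L
  out <- array(pad_value, target)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (off[a] >= 0) { src[[a]] <- 1:d[a]; dst[[a]] <- (off[a] + 1L):(off[a] + d[a]) }
    else { src[[a]] <- (-off[a] + 1L):(-off[a] + target[a]); dst[[a]] <- 1:target[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  list(values = out, offset = off)
}
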