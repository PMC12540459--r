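# Low-level neural net primitives. Feature maps are arrays of dim
# (C, D, H, W) with the channel index fastest, so per-channel scalars recycle
# naturally in elementwise products. Every *_fwd has a matching *_bwd with the
# hand-derived gradient; all gradients are checked against finite differences
# in the test suite.

fm_mat <- function(x) { d <- dim(x); dim(x) <- c(d[1], prod(d[-1])); x }

## -- pointwise (1x1x1) convolution: a channel-mixing matmul ------------------

# Kaiming-uniform fan-in initialization (the convention of the reference
# convnet framework): weights ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in)), zero bias.
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
}

pw_init <- function(cin, cout) {
  list(W = init_mat(cout, cin, cin), b = numeric(cout))
}

pw_fwd <- function(p, x) {
  d <- dim(x)
  y <- p$W %*% fm_mat(x) + p$b
  dim(y) <- c(nrow(p$W), d[-1])
  y
}

pw_bwd <- function(p, x, dy) {
  d <- dim(x)
  dym <- fm_mat(dy)
  xm <- fm_mat(x)
  dx <- crossprod(p$W, dym)
  dim(dx) <- d
  list(dx = dx, g = list(W = tcrossprod(dym, xm), b = rowSums(dym)))
}

## -- depthwise k^3 convolution (optionally strided) and its transpose --------

dw_init <- function(C, k) {
  list(w = array(stats::runif(k^3 * C, -1, 1) / sqrt(k^3), c(k, k, k, C)),
       b = numeric(C))
}

dw_fwd <- function(p, x, stride = 1L)
  cpp_dw3_fwd(x, dim(x), p$w, dim(p$w)[1], p$b, as.integer(stride))

dw_bwd <- function(p, x, dy, stride = 1L) {
  r <- cpp_dw3_bwd(dy, x, dim(x), p$w, dim(p$w)[1], as.integer(stride))
  list(dx = r$dx, g = list(w = r$dw, b = r$db))
}

dwt_fwd <- function(p, x) cpp_dwt3_fwd(x, dim(x), p$w, dim(p$w)[1], p$b)

dwt_bwd <- function(p, x, dy) {
  r <- cpp_dwt3_bwd(dy, x, dim(x), p$w, dim(p$w)[1])
  list(dx = r$dx, g = list(w = r$dw, b = r$db))
}

## 1x1x1 transposed convolution with stride 2 (residual path of up blocks):
## output voxel (2i+1, 2j+1, 2k+1) (0-based) carries W x[i,j,k]; the leading
## slab per axis is the zero padding that rounds 2n-1 up to 2n; the bias covers
## everything except that slab.

pwt2_fwd <- function(p, x) {
  d <- dim(x)
  cout <- nrow(p$W)
  y <- p$W %*% fm_mat(x)
  out <- array(0, c(cout, 2L * d[2], 2L * d[3], 2L * d[4]))
  out[, -1L, -1L, -1L] <- p$b
  ii <- seq(2L, 2L * d[2], by = 2L); jj <- seq(2L, 2L * d[3], by = 2L)
  kk <- seq(2L, 2L * d[4], by = 2L)
  dim(y) <- c(cout, d[-1])
  out[, ii, jj, kk] <- y + p$b
  out
}

pwt2_bwd <- function(p, x, dy) {
  d <- dim(x)
  ii <- seq(2L, 2L * d[2], by = 2L); jj <- seq(2L, 2L * d[3], by = 2L)
  kk <- seq(2L, 2L * d[4], by = 2L)
  g <- dy[, ii, jj, kk, drop = FALSE]
  gm <- fm_mat(g)
  dx <- crossprod(p$W, gm)
  dim(dx) <- d
  db <- rowSums(fm_mat(dy[, -1L, -1L, -1L, drop = FALSE]))
  list(dx = dx, g = list(W = tcrossprod(gm, fm_mat(x)), b = db))
}

## -- per-channel normalization ----------------------------------------------
## Normalizes each channel over its spatial voxels (group normalization with
## one group per channel; also the batch-size-1 realization of batch norm).

cn_init <- function(C) list(g = rep(1, C), b = numeric(C))

cn_fwd <- function(p, x, eps = 1e-5) {
  xm <- fm_mat(x)
  mu <- rowMeans(xm)
  va <- rowMeans(xm * xm) - mu^2
  sd_ <- sqrt(va + eps)
  xhat <- (x - mu) / sd_
  list(y = xhat * p$g + p$b, xhat = xhat, sd = sd_)
}

cn_bwd <- function(p, cache, dy) {
  xhat <- cache$xhat
  dyh <- dy * p$g
  dym <- fm_mat(dy)
  dg <- rowSums(fm_mat(dy * xhat))
  db <- rowSums(dym)
  m1 <- rowMeans(fm_mat(dyh))
  m2 <- rowMeans(fm_mat(dyh * xhat))
  dx <- (dyh - m1 - xhat * m2) / cache$sd
  list(dx = dx, g = list(g = dg, b = db))
}

## -- activations -------------------------------------------------------------

gelu_fwd <- function(x) cpp_gelu_fwd(x)
gelu_bwd <- function(x, dy) cpp_gelu_bwd(x, dy)

sigmoid <- function(x) stats::plogis(x)

relu_fwd <- function(x) pmax(x, 0)

softmax_channels <- function(z) {
  K <- dim(z)[1]
  zm <- fm_mat(z)
  m <- zm[1, ]
  if (K > 1L) for (i in 2:K) m <- pmax(m, zm[i, ])
  e <- exp(zm - rep(m, each = K))
  p <- e / rep(colSums(e), each = K)
  dim(p) <- dim(z)
  p
}

## -- parameter plumbing ------------------------------------------------------

# Depth-first flatten of a nested list of numeric arrays into one vector,
# remembering the skeleton so gradients/updates can be restored.
flatten_params <- function(p) {
  leaves <- list()
  walk <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) walk(x[[i]])
    } else {
      leaves[[length(leaves) + 1L]] <<- x
    }
  }
  walk(p)
  list(vec = unlist(leaves, use.names = FALSE),
       dims = lapply(leaves, dim),
       lens = vapply(leaves, length, integer(1)))
}

# Rebuild a nested list shaped like `template` from a flat vector.
unflatten_params <- function(vec, template) {
  pos <- 0L
  rebuild <- function(tpl) {
    if (is.list(tpl)) {
      out <- lapply(tpl, rebuild)
      names(out) <- names(tpl)
      out
    } else {
      v <- vec[(pos + 1L):(pos + length(tpl))]
      pos <<- pos + length(tpl)
      dim(v) <- dim(tpl)
      v
    }
  }
  rebuild(template)
}

# Structural sum of two nested grad lists (either may be NULL).
grad_add <- function(a, b) {
  if (is.null(b)) return(a)
  if (is.null(a)) return(b)
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) grad_add(a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else a + b
}

#' Count trainable parameters of a model
#'
#' @param model a model built by [mednext_backbone()] or [lemunet()], or any
#'   nested list of numeric parameter arrays.
#' @return integer: total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  p <- if (!is.null(model$params)) model$params else model
  n <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else n <<- n + length(x)
    invisible(NULL)
  }
  walk(p)
  as.integer(n)
}

## -- AdamW -------------------------------------------------------------------

adamw_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adamw_step <- function(theta, grad, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8, weight_decay = 1e-5) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^state$t)
  vh <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mh / (sqrt(vh) + eps) + weight_decay * theta)
  list(theta = theta, state = state)
}
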