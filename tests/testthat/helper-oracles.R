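# Independent brute-force oracles used to check the fast implementations.
# These are deliberately naive (nested loops, dense enumerations) and never
# share code with the package internals they verify.

# Dense 3D convolution by direct summation with zero padding (same size).
oracle_conv3_dense <- function(x3, kern) {
  d <- dim(x3); k <- dim(kern)[1]; p <- (k - 1) %/% 2
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (l in 1:d[3]) {
    acc <- 0
    for (a in 1:k) for (b in 1:k) for (cc in 1:k) {
      ii <- i + a - p - 1; jj <- j + b - p - 1; ll <- l + cc - p - 1
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] && ll >= 1 && ll <= d[3])
        acc <- acc + kern[a, b, cc] * x3[ii, jj, ll]
    }
    out[i, j, l] <- acc
  }
  out
}

# Trilinear interpolation by explicit per-output weight summation
# (endpoint-aligned positions, matching upsample2's convention).
oracle_trilinear <- function(x3, target) {
  d <- dim(x3)
  pos <- lapply(1:3, function(a) {
    if (d[a] == 1) rep(0, target[a]) else (0:(target[a] - 1)) * (d[a] - 1) / (target[a] - 1)
  })
  out <- array(0, target)
  for (i in 1:target[1]) for (j in 1:target[2]) for (l in 1:target[3]) {
    ps <- c(pos[[1]][i], pos[[2]][j], pos[[3]][l])
    i0 <- pmin(floor(ps), pmax(d - 2, 0)); w <- ps - i0
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      wt <- (if (a == 0) 1 - w[1] else w[1]) *
            (if (b == 0) 1 - w[2] else w[2]) *
            (if (cc == 0) 1 - w[3] else w[3])
      idx <- pmin(i0 + c(a, b, cc), d - 1) + 1
      acc <- acc + wt * x3[idx[1], idx[2], idx[3]]
    }
    out[i, j, l] <- acc
  }
  out
}

# Laplacian pyramid by naive step-by-step reimplementation of the recursion
# using the dense-convolution oracle (reflect padding realized by explicit
# index mirroring).
oracle_reflect_pad <- function(x3, p) {
  refl <- function(n) {
    idx <- (-p):(n - 1 + p)
    per <- 2 * (n - 1)
    m <- ((idx %% per) + per) %% per
    ifelse(m >= n, per - m, m) + 1
  }
  x3[refl(dim(x3)[1]), refl(dim(x3)[2]), refl(dim(x3)[3]), drop = FALSE]
}

oracle_gs <- function(x3) {
  k1 <- c(1, 4, 6, 4, 1) / 16
  kern <- array(0, c(5, 5, 5))
  for (a in 1:5) for (b in 1:5) for (cc in 1:5) kern[a, b, cc] <- k1[a] * k1[b] * k1[cc]
  xp <- oracle_reflect_pad(x3, 2)
  full <- oracle_conv3_dense(xp, kern)
  d <- dim(x3)
  full[3:(2 + d[1]), 3:(2 + d[2]), 3:(2 + d[3]), drop = FALSE]
}

oracle_laplacian <- function(x3, K) {
  N <- x3
  levels <- list()
  for (k in seq_len(K)) {
    g <- oracle_gs(N)
    d <- dim(N)
    Nn <- g[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2), drop = FALSE]
    up <- oracle_trilinear(Nn, d)
    levels[[k]] <- N - up
    N <- Nn
  }
  list(levels = levels, top = N)
}

# Brute-force HD95: full pairwise distance matrix + quantile.
oracle_hd95 <- function(G, P, spacing = c(1, 1, 1)) {
  cg <- which(G == 1, arr.ind = TRUE); cp <- which(P == 1, arr.ind = TRUE)
  if (nrow(cg) == 0 || nrow(cp) == 0) return(NA_real_)
  cg <- sweep(cg, 2, spacing, `*`); cp <- sweep(cp, 2, spacing, `*`)
  dm <- matrix(0, nrow(cg), nrow(cp))
  for (i in seq_len(nrow(cg))) for (j in seq_len(nrow(cp)))
    dm[i, j] <- sqrt(sum((cg[i, ] - cp[j, ])^2))
  d1 <- quantile(apply(dm, 1, min), 0.95, names = FALSE)
  d2 <- quantile(apply(dm, 2, min), 0.95, names = FALSE)
  max(d1, d2)
}

# Flood-fill 26-connectivity labelling with an explicit queue.
oracle_label26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextl <- 0L
  for (s in which(mask == 1 & lab == 0)) {
    if (lab[s] != 0L) next
    nextl <- nextl + 1L
    queue <- s
    lab[s] <- nextl
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      vi <- arrayInd(v, d)
      for (dd in -1:1) for (dh in -1:1) for (dw in -1:1) {
        if (dd == 0 && dh == 0 && dw == 0) next
        u <- vi + c(dd, dh, dw)
        if (any(u < 1) || any(u > d)) next
        ul <- u[1] + d[1] * (u[2] - 1) + d[1] * d[2] * (u[3] - 1)
        if (mask[ul] == 1 && lab[ul] == 0L) { lab[ul] <- nextl; queue <- c(queue, ul) }
      }
    }
  }
  lab
}

# Same-partition check up to relabelling.
same_partition <- function(a, b) {
  fg <- a > 0
  if (!identical(fg, b > 0)) return(FALSE)
  ta <- table(a[fg], b[fg])
  all(rowSums(ta > 0) == 1) && all(colSums(ta > 0) == 1)
}

# Small random binary mask with a few blobs.
random_mask <- function(d, p = 0.08) {
  m <- array(as.integer(runif(prod(d)) < p), d)
  m
}

# Tiny reduced network config used across network tests.
tiny_cfg <- function(in_channels = 2L, ds = 5L)
  backbone_config("custom", C = 4L, B = rep(1L, 9), R = rep(2L, 9),
                  in_channels = in_channels, out_classes = 2L, ds_levels = ds)

# Finite-difference directional check of a model's full gradient.
fd_directional <- function(model, x, y, eps = 1e-6, seed = 7) {
  w <- lemunet:::loss_weights(model$cfg$ds_levels)
  r <- lemunet:::net_fwd(model, x, keep_cache = TRUE)
  lg <- lemunet:::seg_loss_grad(r$logits, y, w)
  g <- lemunet:::net_bwd(model, r$cache, lg$dz)
  gv <- lemunet:::flatten_params(g)$vec
  fl <- lemunet:::flatten_params(model$params)
  set.seed(seed)
  v <- rnorm(length(fl$vec)); v <- v / sqrt(sum(v^2))
  lossat <- function(vec) {
    m <- model
    m$params <- lemunet:::unflatten_params(vec, model$params)
    rr <- lemunet:::net_fwd(m, x)
    lemunet:::seg_loss_grad(rr$logits, y, w)$loss
  }
  num <- (lossat(fl$vec + eps * v) - lossat(fl$vec - eps * v)) / (2 * eps)
  ana <- sum(gv * v)
  list(num = num, ana = ana,
       rel = abs(num - ana) / max(abs(num) + abs(ana), 1e-9), grad = g)
}

fd_param_check <- function(pinit, fwd, bwd, xdim, nidx = 30, eps = 1e-6,
                           tol = 1e-5) {
  set.seed(11)
  p <- pinit()
  x <- array(rnorm(prod(xdim)), xdim)
  functional <- function(y) sum(sin(seq_along(y) / 7) * as.numeric(y))
  y0 <- fwd(p, x)
  dy <- array(sin(seq_along(y0) / 7), dim(y0))
  r <- bwd(p, x, dy)
  fl <- lemunet:::flatten_params(p)
  gv <- lemunet:::flatten_params(r$g)$vec
  set.seed(2)
  idx <- sort(sample(length(fl$vec), min(nidx, length(fl$vec))))
  for (i in idx) {
    tp <- fl$vec; tp[i] <- tp[i] + eps
    tm <- fl$vec; tm[i] <- tm[i] - eps
    num <- (functional(fwd(lemunet:::unflatten_params(tp, p), x)) -
            functional(fwd(lemunet:::unflatten_params(tm, p), x))) / (2 * eps)
    expect_lt(abs(num - gv[i]), tol * max(1, abs(num)))
  }
  # input gradient
  set.seed(3)
  for (i in sample(length(x), 10)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (functional(fwd(p, xp)) - functional(fwd(p, xm))) / (2 * eps)
    expect_lt(abs(num - r$dx[i]), tol * max(1, abs(num)))
  }
}

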