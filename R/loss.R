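# Deep-supervision composite loss: per level, soft Dice (squared-denominator
# form) plus mean voxel cross-entropy, combined with per-level weights.

#' Deep-supervision loss weights
#'
#' Default halving scheme: level i (full resolution first) gets weight
#' proportional to 2^-(i-1), normalized to sum 1; the Dice and cross-entropy
#' weights are equal per level.
#'
#' @param D number of supervised levels.
#' @param w_dice,w_ce optional explicit per-level weight vectors.
#' @return list with `w_dice`, `w_ce` and `levels`.
#' @export
loss_weights <- function(D, w_dice = NULL, w_ce = NULL) {
  D <- as.integer(D)
  if (is.null(w_dice)) { w <- 2^-(seq_len(D) - 1); w_dice <- w / sum(w) }
  if (is.null(w_ce)) w_ce <- w_dice
  if (length(w_dice) != D || length(w_ce) != D)
    stop("weight vectors must have length D")
  if (any(w_dice < 0) || any(w_ce < 0)) stop("weights must be non-negative")
  list(w_dice = as.numeric(w_dice), w_ce = as.numeric(w_ce), levels = D)
}

#' Downsample a label mask to a deep-supervision level
#'
#' Nearest-neighbor decimation by 2^(level-1) along every axis (level 1 is
#' the identity), matching the network's grid halving.
#'
#' @param gt binary 3D array.
#' @param level supervision level (>= 1).
#' @return the decimated binary array.
#' @export
downsample_gt <- function(gt, level) {
  level <- as.integer(level)
  if (level < 1L) stop("level must be >= 1")
  if (level == 1L) return(gt)
  s <- 2L^(level - 1L)
  d <- dim(gt)
  gt[seq(1L, d[1], by = s), seq(1L, d[2], by = s), seq(1L, d[3], by = s),
     drop = FALSE]
}

DICE_SMOOTH <- 1e-5

# soft Dice loss (1 - soft DC) of a probability map vs binary target,
# squared-denominator form, averaged over foreground classes.
soft_dice_loss <- function(p, g) {
  K <- dim(p)[1]
  pm <- fm_mat(p)
  gv <- as.numeric(g)
  ls <- vapply(2:K, function(cl) {
    pc <- pm[cl, ]
    gc <- as.numeric(gv == (cl - 1L))
    1 - (2 * sum(pc * gc) + DICE_SMOOTH) / (sum(pc^2) + sum(gc) + DICE_SMOOTH)
  }, numeric(1))
  mean(ls)
}

#' Combined Dice + cross-entropy deep-supervision loss
#'
#' `L = sum_i w_dice_i * L_Dice(f_i, g_i) + w_ce_i * L_CE(f_i, g_i)` over the
#' supervised levels, where `f_i` are class-probability maps and `g_i` the
#' ground truth decimated with [downsample_gt()]. The soft Dice loss uses the
#' squared-denominator form with smoothing 1e-5; cross-entropy is the mean
#' voxel negative log-probability of the true class.
#'
#' @param outputs a `segmentation_output` (list of probability arrays,
#'   full resolution first).
#' @param gt binary 3D ground-truth array at full resolution.
#' @param w a [loss_weights()] list matching `length(outputs)`.
#' @return scalar loss.
#' @export
combined_loss <- function(outputs, gt, w = loss_weights(length(outputs))) {
  if (w$levels != length(outputs)) stop("level count mismatch")
  total <- 0
  for (i in seq_along(outputs)) {
    if (w$w_dice[i] == 0 && w$w_ce[i] == 0) next
    p <- outputs[[i]]
    g <- downsample_gt(gt, i)
    if (!all(dim(p)[-1] == dim(g))) stop("output/GT grid mismatch at level ", i)
    K <- dim(p)[1]
    pm <- fm_mat(p)
    idx <- cbind(as.integer(g) + 1L, seq_len(ncol(pm)))
    lce <- -mean(log(pmax(pm[idx], 1e-12)))
    total <- total + w$w_dice[i] * soft_dice_loss(p, g) + w$w_ce[i] * lce
  }
  total
}

# Loss and gradient with respect to the logits of every level; used by the
# trainer (keeps the softmax jacobian fused for stability).
seg_loss_grad <- function(zlist, gt, w = loss_weights(length(zlist))) {
  loss <- 0
  dz <- vector("list", length(zlist))
  nfg <- NULL
  for (i in seq_along(zlist)) {
    z <- zlist[[i]]
    K <- dim(z)[1]
    g <- downsample_gt(gt, i)
    V <- length(g)
    p <- softmax_channels(z)
    pm <- fm_mat(p)
    gv <- as.integer(g)
    onehot <- matrix(0, K, V)
    onehot[cbind(gv + 1L, seq_len(V))] <- 1
    # cross entropy
    lce <- -mean(log(pmax(pm[cbind(gv + 1L, seq_len(V))], 1e-12)))
    dz_ce <- (pm - onehot) / V
    # soft dice over foreground classes
    dldp <- matrix(0, K, V)
    ld <- 0
    nfg <- K - 1L
    for (cl in 2:K) {
      pc <- pm[cl, ]
      gc <- onehot[cl, ]
      num <- 2 * sum(pc * gc) + DICE_SMOOTH
      den <- sum(pc^2) + sum(gc) + DICE_SMOOTH
      ld <- ld + (1 - num / den)
      dldp[cl, ] <- -(2 * gc * den - num * 2 * pc) / den^2 / nfg
    }
    ld <- ld / nfg
    # chain through softmax
    dot <- colSums(dldp * pm)
    dz_dice <- pm * (dldp - rep(dot, each = K))
    dzi <- w$w_dice[i] * dz_dice + w$w_ce[i] * dz_ce
    dim(dzi) <- dim(z)
    dz[[i]] <- dzi
    loss <- loss + w$w_dice[i] * ld + w$w_ce[i] * lce
  }
  list(loss = loss, dz = dz)
}
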