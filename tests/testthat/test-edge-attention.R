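test_that("CBAM gates shrink every element and match a hand-rolled oracle", {
  set.seed(3)
  C <- 2
  p <- lemunet:::cbam_init(C, reduction = 2L, spatial_kernel = 3L)
  x <- array(rnorm(C * 4^3), c(C, 4, 4, 4))
  y <- cbam(p, x)
  expect_equal(dim(y), dim(x))
  nz <- x != 0
  expect_true(all(abs(y[nz]) < abs(x[nz])))  # both gates strictly in (0,1)

  # oracle: explicit pooled-MLP channel gate then mean/max-map spatial conv
  xm <- matrix(x, C)
  avg <- rowMeans(xm); mx <- apply(xm, 1, max)
  mlp <- function(v) p$W2 %*% pmax(p$W1 %*% v + p$b1, 0) + p$b2
  s <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  y1 <- x * as.numeric(s)
  y1m <- matrix(y1, C)
  meanmap <- array(colMeans(y1m), dim(x)[-1])
  maxmap <- array(apply(y1m, 2, max), dim(x)[-1])
  pre <- oracle_conv3_dense(meanmap, p$wsp[, , , 1, 1]) +
         oracle_conv3_dense(maxmap, p$wsp[, , , 2, 1]) + p$bsp
  m <- 1 / (1 + exp(-pre))
  yo <- y1 * rep(as.numeric(m), each = C)
  expect_equal(as.numeric(y), as.numeric(yo), tolerance = 1e-10)
})

test_that("CBAM gradients match finite differences", {
  fd_param_check(function() lemunet:::cbam_init(4, 2, 3),
                 function(p, x) lemunet:::cbam_fwd(p, x)$y,
                 function(p, x, dy)
                   lemunet:::cbam_bwd(p, lemunet:::cbam_fwd(p, x)$cache, dy),
                 c(4, 5, 5, 5))
})

test_that("branch mixing honors lambda and is symmetric under weight tying", {
  set.seed(7)
  C <- 4
  p <- lemunet:::lea_init(C, lambda_init = 0.5, reduction = 2L, spatial_kernel = 3L)
  fe <- array(rnorm(C * 4^3), c(C, 4, 4, 4))
  fT <- array(rnorm(C * 4^3), c(C, 4, 4, 4))
  # lambda = 1: T1 branch ignored
  only_main <- combine_branches(p, fe, fT, lambda = 1)
  expect_equal(only_main, combine_branches(p, fe, fe * 2 + 1, lambda = 1))
  # lambda = 0: main branch ignored
  only_t1 <- combine_branches(p, fe, fT, lambda = 0)
  expect_equal(only_t1, combine_branches(p, fe * -3, fT, lambda = 0))
  # tie the two CBAMs: swapping inputs at lambda = 0.5 leaves output unchanged
  p$cbam_t1 <- p$cbam_main
  expect_equal(combine_branches(p, fe, fT, lambda = 0.5),
               combine_branches(p, fT, fe, lambda = 0.5), tolerance = 1e-12)
})

test_that("edge gating concatenates, squashes into (0,1) and restores C channels", {
  set.seed(8)
  C <- 4
  p <- lemunet:::lea_init(C, 0.5, 2L, 3L)
  fmap <- array(rnorm(C * 4^3), c(C, 4, 4, 4))
  fl <- array(rnorm(4^3), c(4, 4, 4))
  fe <- edge_attend(p, fl, fmap)
  expect_equal(dim(fe), dim(fmap))
  # the pre-conv gate values are sigmoid outputs
  cat_ <- array(0, c(C + 1, 4, 4, 4)); cat_[1, , , ] <- fl; cat_[-1, , , ] <- fmap
  map <- 1 / (1 + exp(-cat_))
  expect_true(all(map > 0 & map < 1))
  expect_equal(dim(map)[1], C + 1L)
  expect_error(edge_attend(p, array(0, c(2, 4, 4, 4)), fmap), "1 channel")
  expect_error(edge_attend(p, array(0, c(3, 3, 3)), fmap), "mismatch")
  # zero Laplacian input still yields finite, nonzero output (sigmoid(0) = 0.5)
  fe0 <- edge_attend(p, array(0, c(4, 4, 4)), fmap)
  expect_true(all(is.finite(fe0)) && any(fe0 != 0))
})

test_that("the T1 branch sees only the first channel and mirrors stage shapes", {
  set.seed(9)
  cfg <- tiny_cfg(in_channels = 3L)
  mod <- lemunet(cfg, seed = 5)
  t1 <- array(rnorm(16^3), c(16, 16, 16))
  r <- t1_branch_forward(mod, t1)
  expect_equal(dim(r$feT1_1), c(cfg$C, 16L, 16L, 16L))
  expect_equal(dim(r$feT1_2), c(2L * cfg$C, 8L, 8L, 8L))
  # oracle: sequential application of the already-audited block operations
  p <- mod$params
  f1 <- lemunet:::stage_fwd(p$t1_enc0,
          lemunet:::pw_fwd(p$t1_stem, array(t1, c(1, 16, 16, 16))))$y
  expect_equal(r$feT1_1, f1)
  # perturbing FLAIR/PET channels leaves the branch output unchanged
  x <- array(rnorm(3 * 16^3), c(3, 16, 16, 16))
  x2 <- x; x2[2, , , ] <- x2[2, , , ] + 10; x2[3, , , ] <- -x2[3, , , ]
  ra <- lemunet:::net_fwd(mod, x, keep_cache = TRUE)
  rb <- lemunet:::net_fwd(mod, x2, keep_cache = TRUE)
  expect_identical(ra$cache$t1e0$y, rb$cache$t1e0$y)
  expect_identical(ra$cache$t1e1$y, rb$cache$t1e1$y)
})

test_that("lambda is trainable: its gradient is nonzero on generic inputs", {
  set.seed(10)
  cfg <- tiny_cfg(in_channels = 2L)
  mod <- lemunet(cfg, seed = 2)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  y <- array(0L, c(16, 16, 16)); y[5:9, 5:9, 5:9] <- 1L
  r <- fd_directional(mod, x, y)
  expect_true(abs(r$grad$lea1$lambda) > 0)
  expect_true(abs(r$grad$lea2$lambda) > 0)
  # and the full-network gradient agrees with finite differences
  expect_lt(r$rel, 1e-4)
})
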