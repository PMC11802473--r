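test_that("padding produces the minimal square grid and unpadding inverts it", {
  for (N in c(1L, 2L, 5L, 9L, 10L, 100L)) {
    Z <- matrix(rnorm(N * 3L), N, 3L)
    g <- pad_and_square(Z)
    expect_gte(g$M^2, N)
    expect_true(g$M == 1L || (g$M - 1L)^2 < N)  # minimality
    expect_identical(sum(g$valid_mask), N)
    expect_identical(flatten_and_unpad(g), Z)
  }
})

test_that("padded positions are zero and sit at the raster tail", {
  Z <- matrix(rnorm(10 * 2L), 10, 2L)
  g <- pad_and_square(Z)     # M = 4, 6 pad positions
  Gm <- camil:::grid_array_to_matrix(g$grid)
  expect_equal(Gm[11:16, ], matrix(0, 6, 2))
  expect_identical(as.vector(t(g$valid_mask)), c(rep(TRUE, 10), rep(FALSE, 6)))
})

test_that("raster grid converters are exact inverses", {
  set.seed(31)
  Gm <- matrix(rnorm(9 * 4), 9, 4)
  arr <- camil:::grid_matrix_to_array(Gm, 3L)
  expect_identical(camil:::grid_array_to_matrix(arr), Gm)
  # spot-check raster order: row-major, grid[r, c, ] is token (r-1)*M + c
  expect_identical(arr[2L, 3L, ], Gm[6L, ])
})

test_that("conv branch matches explicit sliding-window convolution", {
  set.seed(32)
  d <- 5L
  pars <- mcab_params(d, kernel_sizes = c(3L, 5L), reduction_ratio = 2L,
                      seed = 12L)
  p1 <- list(dw = pars$c1.dw, db = pars$c1.db, pw = pars$c1.pw, pb = pars$c1.pb)
  Z <- matrix(rnorm(13 * d), 13, d)
  g <- pad_and_square(Z) # M = 4
  out <- conv_branch(g, 3L, p1, use_pwconv = TRUE)
  Gm <- camil:::grid_array_to_matrix(g$grid)
  M <- g$M
  dw_ora <- matrix(0, M * M, d)
  for (r in seq_len(M)) for (cc in seq_len(M)) for (ch in seq_len(d)) {
    acc <- 0; o <- 0L
    for (dr in -1:1) for (dc in -1:1) {
      o <- o + 1L
      rr <- r + dr; c2 <- cc + dc
      v <- if (rr >= 1 && rr <= M && c2 >= 1 && c2 <= M)
        Gm[(rr - 1L) * M + c2, ch] else 0
      acc <- acc + v * p1$dw[o, ch]
    }
    dw_ora[(r - 1L) * M + cc, ch] <- acc
  }
  relu <- pmax(dw_ora + matrix(p1$db, M * M, d, byrow = TRUE), 0)
  ora <- relu %*% p1$pw + matrix(p1$pb, M * M, d, byrow = TRUE)
  expect_lt(max(abs(camil:::grid_array_to_matrix(out) - ora)), 1e-12)
  # and without the point-wise convolution
  out2 <- conv_branch(g, 3L, p1, use_pwconv = FALSE)
  expect_lt(max(abs(camil:::grid_array_to_matrix(out2) - relu)), 1e-12)
})

test_that("depth-wise convolution is shape-preserving for every kernel", {
  set.seed(33)
  d <- 4L
  Z <- matrix(rnorm(10 * d), 10, d)
  g <- pad_and_square(Z)
  for (k in c(1L, 3L, 5L, 7L)) {
    pars <- mcab_params(d, kernel_sizes = c(k, k), seed = 13L)
    p1 <- list(dw = pars$c1.dw, db = pars$c1.db, pw = pars$c1.pw,
               pb = pars$c1.pb)
    out <- conv_branch(g, k, p1)
    expect_identical(dim(out), c(g$M, g$M, d))
  }
  expect_error(conv_branch(g, 4L, list()), "odd")
  expect_error(conv_branch(g, 9L, list()), "config error")
})

test_that("zero gate-MLP weights give 0.5 gates and the closed-form output", {
  set.seed(34)
  d <- 6L; M <- 3L
  mk <- function() array(rnorm(M * M * d), c(M, M, d))
  Z1 <- mk(); Z2 <- mk(); Zg <- mk()
  hid <- 3L
  params <- list(W1 = matrix(0, d, hid), b1 = matrix(0, 1L, hid),
                 W2 = matrix(0, hid, 3L * d), b2 = matrix(0, 1L, 3L * d))
  res <- channel_gate(Z1, Z2, Zg, params, temperature = 2)
  for (g in res$gates) expect_identical(g, rep(0.5, d))
  expect_identical(res$grid, (Z1 + Zg + Z2) * 0.5)
})

test_that("channel gates always lie strictly inside (0, 1)", {
  set.seed(35)
  d <- 4L; M <- 2L
  pars <- mcab_params(d, reduction_ratio = 2L, seed = 14L)
  gp <- list(W1 = pars$g.W1, b1 = pars$g.b1, W2 = pars$g.W2, b2 = pars$g.b2)
  mk <- function() array(rnorm(M * M * d, sd = 2), c(M, M, d))
  res <- channel_gate(mk(), mk(), mk(), gp, temperature = 3)
  for (g in res$gates) expect_true(all(g > 0 & g < 1))
  expect_length(res$L, 3L * d)
})

test_that("the gate splits L by source: L1 gates Z1, L2 gates the identity path", {
  # make branches distinguishable: Z1 = 1s, Z2 = 2s, Zg = 4s, open only one
  # gate far beyond the others via b2 and read off which source passes
  d <- 2L; M <- 2L
  ones <- function(v) array(v, c(M, M, d))
  hid <- 1L
  base <- list(W1 = matrix(0, d, hid), b1 = matrix(0, 1L, hid),
               W2 = matrix(0, hid, 3L * d))
  sel <- function(block) {
    b2 <- matrix(-30, 1L, 3L * d)
    b2[1L, (block - 1L) * d + seq_len(d)] <- 30
    p <- base; p$b2 <- b2 * 0.5 # two MLP passes sum: total +-30
    channel_gate(ones(1), ones(2), ones(4), p, temperature = 1)$grid[1, 1, 1]
  }
  expect_equal(sel(1L), 1, tolerance = 1e-9)  # L1 -> Z1
  expect_equal(sel(2L), 4, tolerance = 1e-9)  # L2 -> identity path
  expect_equal(sel(3L), 2, tolerance = 1e-9)  # L3 -> Z2
})

test_that("mcab_forward preserves length and is sensitive to token order", {
  set.seed(36)
  d <- 6L
  pars <- mcab_params(d, reduction_ratio = 2L, seed = 15L)
  for (N in c(1L, 2L, 5L, 10L)) {
    Z <- matrix(rnorm(N * d), N, d)
    out <- mcab_forward(Z, pars)
    expect_identical(dim(out), dim(Z))
  }
  Z <- matrix(rnorm(12 * d), 12, d)
  perm <- c(5L, 1L, 12L, 7L, 3L, 9L, 2L, 11L, 6L, 8L, 10L, 4L)
  direct <- mcab_forward(Z, pars)
  permed <- mcab_forward(Z[perm, ], pars)
  # a permutation-equivariant map would satisfy permed == direct[perm, ]
  expect_gt(max(abs(permed - direct[perm, ])), 1e-6)
})

test_that("flatten_and_unpad rejects masks that are not a raster prefix", {
  Z <- matrix(rnorm(6), 3L, 2L)
  g <- pad_and_square(Z)
  g$valid_mask <- matrix(c(TRUE, FALSE, TRUE, TRUE), 2L, 2L)
  expect_error(flatten_and_unpad(g), "invariant error")
})
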