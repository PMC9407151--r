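# The filter bank: convolution correctness against brute-force oracles,
# analytic checks on known signals, and shared contracts (constancy,
# translation equivariance, determinism).

test_that("separable and FFT correlation match the brute-force oracle", {
  set.seed(11)
  img <- matrix(runif(21 * 17), 21, 17)
  k1 <- frfseg:::gauss_kernel(1.3, 0L)
  sep <- frfseg:::correlate_sep(img, k1, k1)
  expect_equal(sep, brute_correlate(img, outer(k1, k1)), tolerance = 1e-10)
  kern <- matrix(runif(25), 5, 5)
  expect_equal(frfseg:::correlate2(img, kern), brute_correlate(img, kern),
               tolerance = 1e-9)
})

test_that("Gaussian-derivative kernels recover analytic derivatives", {
  nr <- 31; nc <- 31
  xg <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  quad <- xg^2 / nc^2                        # I(x) = (x/nc)^2, d2I/dx2 = 2/nc^2
  d2 <- frfseg:::gauss_deriv(quad, 1.5, 0L, 2L)
  interior <- d2[10:22, 10:22]
  expect_equal(interior, matrix(2 / nc^2, 13, 13), tolerance = 1e-6)
  ramp <- xg / nc
  d1 <- frfseg:::gauss_deriv(ramp, 1.5, 0L, 1L)
  expect_equal(d1[10:22, 10:22], matrix(1 / nc, 13, 13), tolerance = 1e-6)
})

test_that("flat images are fixed points (or zeros) of every filter kind", {
  const <- matrix(0.4, 20, 20)
  expect_equal(apply_filter(const, "gaussian", sigma = 2)[[1]], const)
  expect_equal(apply_filter(const, "sobel", sigma = 1)[[1]],
               matrix(0, 20, 20))
  expect_equal(apply_filter(const, "dog", sigma_a = 1, sigma_b = 2)[[1]],
               matrix(0, 20, 20), tolerance = 1e-12)
  expect_equal(apply_filter(const, "aniso_diffusion")[[1]], const)
  gab <- apply_filter(const, "gabor", sigma = 1)
  for (g in gab) expect_equal(g, matrix(0, 20, 20), tolerance = 1e-10)
  ls <- apply_filter(const, "local_stats", sigma = 2)
  expect_equal(ls$local_mean_s2, const)
  expect_equal(ls$local_var_s2, matrix(0, 20, 20))
  st <- apply_filter(const, "structure", sigma = 1)
  expect_equal(st[[1]], matrix(0, 20, 20), tolerance = 1e-12)
})

test_that("dog equals the difference of independently composed blurs", {
  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  d <- apply_filter(img, "dog", sigma_a = 1, sigma_b = 3)[[1]]
  g1 <- apply_filter(img, "gaussian", sigma = 1)[[1]]
  g3 <- apply_filter(img, "gaussian", sigma = 3)[[1]]
  expect_equal(d, g1 - g3)
})

test_that("local statistics match direct computation on a small patch", {
  set.seed(5)
  img <- matrix(runif(15 * 15), 15, 15)
  out <- apply_filter(img, "local_stats", sigma = 2)
  # check an interior pixel against a hand-collected disc neighbourhood
  i <- 8; j <- 8; r <- 2
  nb <- c()
  for (a in -r:r) for (b in -r:r) {
    if (a^2 + b^2 <= r^2 + 1e-9) nb <- c(nb, img[i + a, j + b])
  }
  expect_equal(out$local_mean_s2[i, j], mean(nb))
  expect_equal(out$local_min_s2[i, j], min(nb))
  expect_equal(out$local_max_s2[i, j], max(nb))
  expect_equal(out$local_var_s2[i, j], var(nb))
  expect_equal(out$local_median_s2[i, j], median(nb))
})

test_that("shift planes translate the image by the requested offset", {
  set.seed(7)
  img <- matrix(runif(100), 10, 10)
  sh <- apply_filter(img, "shift", sigma = 2)
  expect_equal(sh$shift_up_s2[3:10, ], img[1:8, ])
  expect_equal(sh$shift_down_s2[1:8, ], img[3:10, ])
  expect_equal(sh$shift_left_s2[, 3:10], img[, 1:8])
  expect_equal(sh$shift_right_s2[, 1:8], img[, 3:10])
})

test_that("structure-tensor planes agree with eigen() at sampled pixels", {
  set.seed(9)
  img <- frfseg:::gauss_blur(matrix(runif(30 * 30), 30, 30), 1)
  sg <- 1.5
  st <- apply_filter(img, "structure", sigma = sg)
  gx <- frfseg:::gauss_deriv(img, sg, 0L, 1L)
  gy <- frfseg:::gauss_deriv(img, sg, 1L, 0L)
  jxx <- frfseg:::gauss_blur(gx * gx, sg)
  jxy <- frfseg:::gauss_blur(gx * gy, sg)
  jyy <- frfseg:::gauss_blur(gy * gy, sg)
  for (px in list(c(10, 12), c(20, 7), c(15, 25))) {
    J <- matrix(c(jxx[px[1], px[2]], jxy[px[1], px[2]],
                  jxy[px[1], px[2]], jyy[px[1], px[2]]), 2, 2)
    ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(st[[1]][px[1], px[2]], ev[1], tolerance = 1e-9)
    expect_equal(st[[2]][px[1], px[2]], ev[2], tolerance = 1e-9)
  }
})

test_that("Lipschitz covers bound the image with the configured slope", {
  set.seed(13)
  img <- matrix(runif(20 * 20), 20, 20)
  slope <- 5 / 255
  lo <- frfseg:::lipschitz_cover(img, slope, lower = TRUE)
  hi <- frfseg:::lipschitz_cover(img, slope, lower = FALSE)
  expect_true(all(lo >= img - 1e-12))
  expect_true(all(hi <= img + 1e-12))
  # slope bound along rows and columns
  expect_true(max(abs(diff(lo))) <= slope + 1e-12)
  expect_true(max(abs(t(diff(t(lo))))) <= slope + 1e-12)
  out <- apply_filter(img, "lipschitz")
  expect_named(out, c("lipschitz_top", "lipschitz_bottom"))
  expect_true(all(out$lipschitz_top >= -1e-12))
})

test_that("bilateral filtering preserves a step edge better than Gaussian", {
  img <- matrix(0.2, 20, 20); img[, 11:20] <- 0.8
  bi <- apply_filter(img, "bilateral", sigma = 2, sigma_r = 0.05)[[1]]
  ga <- apply_filter(img, "gaussian", sigma = 2)[[1]]
  # at the edge column the bilateral output stays near the original level
  expect_lt(abs(bi[10, 10] - 0.2), abs(ga[10, 10] - 0.2))
  expect_lt(max(abs(bi - img)), 0.05)
})

test_that("filters are translation-equivariant away from borders", {
  set.seed(17)
  base <- frfseg:::gauss_blur(matrix(runif(40 * 40), 40, 40), 1)
  shifted <- base[6:40, ]                    # shift up by 5 rows
  inner <- 10:25
  for (kind in c("gaussian", "sobel")) {
    a <- apply_filter(base, kind, sigma = 2)[[1]]
    b <- apply_filter(shifted, kind, sigma = 2)[[1]]
    expect_equal(a[inner + 5, inner], b[inner, inner], tolerance = 1e-9)
  }
  hm <- hessian_features(base, 2)$trace
  hs <- hessian_features(shifted, 2)$trace
  expect_equal(hm[inner + 5, inner], hs[inner, inner], tolerance = 1e-9)
  mm <- membrane_projections(base, 1, 9)$membrane_max_t1_p9
  ms <- membrane_projections(shifted, 1, 9)$membrane_max_t1_p9
  expect_equal(mm[inner + 5, inner], ms[inner, inner], tolerance = 1e-8)
})

test_that("unknown filter kinds and bad parameters are rejected", {
  img <- matrix(0.5, 5, 5)
  expect_error(apply_filter(img, "swirl"), class = "frfseg_parameter_error")
  expect_error(frfseg:::gauss_kernel(-1), class = "frfseg_parameter_error")
  expect_error(membrane_projections(img, 1, 4),
               class = "frfseg_parameter_error")
})
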