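aniso_fw_spec <- function(f, shape = c(14, 14, 8), noise = "none", snr = 30,
                          seed = 1) {
  phantom_spec(shape = shape,
               regions = list(background = list(evals = rep(0.8e-3, 3), f = 0.05),
                              projection = list(evals = c(1.7e-3, 0.2e-3, 0.2e-3), f = f),
                              association = list(evals = c(1.2e-3, 1.7e-3, 0.6e-3), f = f)),
               noise = noise, snr = snr, seed = seed)
}

test_that("initializer interpolates MD and clips", {
  cfg <- fw_config()
  expect_equal(init_fw(3.0e-3, cfg), 0.95)
  expect_equal(init_fw(0.6e-3, cfg), 0.05)
  expect_equal(init_fw(1.8e-3, cfg), 0.5)
  md <- seq(0.2e-3, 3.2e-3, length.out = 50)
  expect_true(all(diff(init_fw(md, cfg)) >= 0))
})

test_that("free-water fit recovers noise-free fractions on anisotropic tissue", {
  ph <- build_phantom(aniso_fw_spec(0.3))
  slab <- ph$truth$labels == "projection"
  fw <- fit_fw(ph$dwi, mask = slab, cfg = fw_config(sigma = 0))
  expect_lt(max(abs(fw$f[slab] - 0.3)), 0.03)
  expect_equal(fw$iterations, 1L)

  # pure tissue: estimates stay at the bottom of the range
  ph0 <- build_phantom(aniso_fw_spec(0))
  fw0 <- fit_fw(ph0$dwi, mask = ph0$truth$labels == "projection",
                cfg = fw_config(sigma = 0))
  expect_true(all(fw0$f[ph0$truth$labels == "projection"] <= 0.05))

  # monotone across a grid of true fractions
  fhat <- vapply(c(0.1, 0.3, 0.5), function(ft) {
    p <- build_phantom(aniso_fw_spec(ft))
    s <- p$truth$labels == "projection"
    median(fit_fw(p$dwi, mask = s, cfg = fw_config(sigma = 0))$f[s])
  }, numeric(1))
  expect_true(all(diff(fhat) > 0))
})

test_that("f stays in bounds, is s0 invariant, and flags flat ridges", {
  ph <- build_phantom(aniso_fw_spec(0.3, noise = "rician", snr = 20, seed = 3))
  m <- ph$truth$labels != "background"
  fw <- fit_fw(ph$dwi, mask = m)
  expect_true(all(fw$f[m] >= 0 & fw$f[m] <= 1))

  # scaling the input signal leaves the FW index unchanged
  scaled <- dwi_volume(ph$dwi$signal * 7.3, ph$dwi$affine, ph$dwi$gtab)
  fw2 <- fit_fw(scaled, mask = m)
  expect_equal(fw2$f, fw$f, tolerance = 1e-9)

  # isotropic voxels sit on the documented ridge and are flagged but kept
  iso <- build_phantom(phantom_spec(
    shape = c(10, 10, 6),
    regions = list(background = list(evals = rep(0.8e-3, 3), f = 0.2),
                   projection = list(evals = rep(0.8e-3, 3), f = 0.2),
                   association = list(evals = rep(0.8e-3, 3), f = 0.2)),
    noise = "none"))
  mi <- array(FALSE, c(10, 10, 6)); mi[which(iso$truth$labels == "background")[1:30]] <- TRUE
  fwi <- fit_fw(iso$dwi, mask = mi, cfg = fw_config(sigma = 0))
  expect_true(all(fwi$ridge_flag[mi]))
  expect_true(all(is.finite(fwi$f[mi])))
})

test_that("skeleton is the medial plane of a slab, idempotent, deterministic", {
  fa <- array(0, c(9, 9, 9))
  fa[, , 3:7] <- 0.5                       # 5-voxel-thick slab spanning x, y
  sk <- wm_skeleton(fa, fa_threshold = 0.2)
  expect_equal(which(apply(sk$data, 3, any)), 5)   # medial plane only
  expect_true(all(sk$data[, , 5]))
  # idempotence
  sk2 <- wm_skeleton(array(as.numeric(sk$data) * 0.5, dim(sk$data)),
                     fa_threshold = 0.2)
  expect_identical(sk2$data, sk$data)
  expect_error(wm_skeleton(array(0.1, c(5, 5, 5)), fa_threshold = 0.2), "threshold")
})

test_that("skeleton mean excludes lesions and matches a brute-force loop", {
  set.seed(4)
  f <- array(runif(6 * 6 * 6), c(6, 6, 6))
  sk <- array(runif(216) > 0.5, c(6, 6, 6))
  les <- array(runif(216) > 0.7, c(6, 6, 6))
  got <- mean_fw_on_skeleton(f, sk, les)
  acc <- c(); nex <- 0
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    if (sk[i, j, k] && !les[i, j, k]) acc <- c(acc, f[i, j, k])
    if (sk[i, j, k] && les[i, j, k]) nex <- nex + 1
  }
  expect_equal(got$fw_index, mean(acc))
  expect_equal(got$n_used, length(acc))
  expect_equal(got$n_excluded, nex)

  # exclusion semantics: deviant lesion values never leak into the mean
  f2 <- array(0.2, c(6, 6, 6)); f2[les] <- 0.9
  expect_equal(mean_fw_on_skeleton(f2, sk, les)$fw_index, 0.2)
  # empty lesion mask equals the plain mean
  expect_equal(mean_fw_on_skeleton(f, sk)$fw_index, mean(f[sk]))
  expect_error(mean_fw_on_skeleton(f, array(FALSE, c(6, 6, 6))), "usable")
})
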