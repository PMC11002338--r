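test_that("bi-tensor signal matches closed forms", {
  gt <- test_gtab(6)
  # pure free water: S/s0 = exp(-b d_w)
  s <- simulate_signal(diag(c(1.7, 0.2, 0.2)) * 1e-3, f = 1, gt, s0 = 100)
  expect_equal(s[-1] / 100, rep(exp(-3), 6), tolerance = 1e-12)
  expect_equal(s[1], 100)
  # pure isotropic tissue: mono-exponential
  s2 <- simulate_signal(diag(3) * 1e-3, f = 0, gt, s0 = 1)
  expect_equal(s2[-1], rep(exp(-1), 6), tolerance = 1e-12)
  # mixed voxel along the principal axis
  gt3 <- gradient_table(c(0, rep(1000, 6)),
                        rbind(c(0, 0, 0), c(1, 0, 0), dwi_directions(5)))
  s3 <- simulate_signal(diag(c(1.7, 0.2, 0.2)) * 1e-3, f = 0.3, gt3, s0 = 1)
  expect_equal(s3[2], 0.7 * exp(-1.7) + 0.3 * exp(-3), tolerance = 1e-12)
  expect_error(simulate_signal(diag(c(-1, 1, 1)) * 1e-3, 0, gt), "semi-definite")
  expect_error(simulate_signal(diag(3) * 1e-3, 1.2, gt), "\\[0, 1\\]")
})

test_that("noise models are reproducible and match Rician moments", {
  s <- rep(500, 1000)
  expect_identical(add_noise(s, snr = 30, model = "none"), s)
  a <- add_noise(s, snr = 30, s0 = 1000, model = "rician", seed = 9)
  b <- add_noise(s, snr = 30, s0 = 1000, model = "rician", seed = 9)
  expect_identical(a, b)
  expect_error(add_noise(s, snr = 30, model = "bogus"))

  # sample mean over 1e5 draws vs analytic Rician mean, within 3 SE
  n <- 1e5; s0 <- 1000; snr <- 30; sigma <- s0 / snr
  draws <- add_noise(rep(s0, n), snr = snr, s0 = s0, model = "rician", seed = 4)
  mu <- oracle_rician_mean(s0, sigma)
  se <- sd(draws) / sqrt(n)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("phantom construction is exact, bounded, and reproducible", {
  spec <- phantom_spec(shape = c(10, 10, 6), noise = "none")
  ph <- build_phantom(spec)
  # noise-free signal equals simulate_signal of the voxel ground truth
  v <- c(5, 3, 3)  # inside the projection slab
  expect_equal(as.character(ph$truth$labels[v[1], v[2], v[3]]), "projection")
  d6 <- ph$truth$tensor6[v[1], v[2], v[3], ]
  D <- matrix(c(d6[1], d6[4], d6[5], d6[4], d6[2], d6[6], d6[5], d6[6], d6[3]), 3)
  expect_equal(ph$dwi$signal[v[1], v[2], v[3], ],
               simulate_signal(D, ph$truth$f[v[1], v[2], v[3]], ph$dwi$gtab,
                               s0 = spec$s0),
               tolerance = 1e-12)
  # analytic ALPS of the default slab layout
  expect_equal(build_phantom(phantom_spec(shape = c(10, 10, 6),
                                          regions = pure_tissue_regions(),
                                          noise = "none"))$truth$alps_analytic, 2.0)
  # signals positive and bounded by s0
  expect_true(all(ph$dwi$signal > 0))
  expect_true(all(ph$dwi$signal <= spec$s0 + 1e-9))
  # analytic ALPS invariant to s0 and grid size
  expect_equal(build_phantom(phantom_spec(shape = c(8, 8, 4), s0 = 5,
                                          noise = "none"))$truth$alps_analytic,
               ph$truth$alps_analytic)
  # byte-identical phantom under a fixed seed
  p1 <- build_phantom(phantom_spec(shape = c(8, 8, 4), snr = 20, seed = 5))
  p2 <- build_phantom(phantom_spec(shape = c(8, 8, 4), snr = 20, seed = 5))
  expect_identical(p1$dwi$signal, p2$dwi$signal)
})

test_that("lesions override regions; out-of-grid lesions are skipped", {
  les <- list(list(center_mm = c(0, 0, 0), radius_mm = 3,
                   diffusivity = 2.5e-3, f = 0.8))
  ph <- build_phantom(phantom_spec(shape = c(10, 10, 6), lesions = les,
                                   noise = "none"))
  expect_gt(sum(ph$truth$lesion_mask$data), 0)
  inside <- ph$truth$lesion_mask$data
  expect_true(all(ph$truth$f[inside] == 0.8))
  expect_true(all(ph$truth$tensor6[, , , 1][inside] == 2.5e-3))

  expect_warning(
    ph2 <- build_phantom(phantom_spec(shape = c(10, 10, 6),
                                      lesions = list(list(center_mm = c(500, 0, 0),
                                                          radius_mm = 2,
                                                          diffusivity = 1e-3, f = 0.5)),
                                      noise = "none")),
    "outside")
  expect_equal(sum(ph2$truth$lesion_mask$data), 0)
})

test_that("cohort simulator reproduces its generative model", {
  # degenerate noise: group effect recovered exactly
  cs <- cohort_spec(fw = list(intercept = 0.2, delta = 0, beta_age = 0,
                              beta_edss = 0, sd = 1e-12),
                    alps = list(intercept = 1.5, delta = 0.2, beta_age = 0,
                                beta_edss = 0, sd = 1e-12),
                    seed = 2)
  tab <- simulate_cohort(cs)
  expect_equal(diff(tapply(tab$alps, tab$group, mean)), c(NMOSD = 0.2),
               tolerance = 1e-9)
  expect_equal(diff(tapply(tab$fw, tab$group, mean)), c(NMOSD = 0),
               tolerance = 1e-9)
  # group coding: MS = 0, NMOSD = 1
  expect_identical(unique(tab$group_code[tab$group == "MS"]), 0L)
  expect_identical(unique(tab$group_code[tab$group == "NMOSD"]), 1L)
  expect_equal(sum(tab$group == "MS"), 42)
  expect_equal(sum(tab$group == "NMOSD"), 21)

  # column means converge to generative values at n = 1e4 (3 SE)
  big <- cohort_spec(n_ms = 5000, n_nmosd = 5000,
                     age_mean = c(40, 40), age_sd = c(8, 8),
                     edss_mean = c(5, 5), edss_sd = c(0.5, 0.5),
                     fw = list(intercept = 0.1, delta = 0, beta_age = 1e-3,
                               beta_edss = 2e-3, sd = 0.01),
                     seed = 8)
  bt <- simulate_cohort(big)
  expect_lt(abs(mean(bt$age) - 40), 3 * 8 / sqrt(1e4))
  mu_fw <- 0.1 + 1e-3 * mean(bt$age) + 2e-3 * mean(bt$edss)
  expect_lt(abs(mean(bt$fw) - mu_fw), 3 * 0.01 / sqrt(1e4))
})

test_that("back-solved phantoms target the tabled indices", {
  tab <- simulate_cohort(cohort_spec(n_ms = 2, n_nmosd = 2, seed = 3),
                         phantoms = TRUE)
  sp <- tab$phantom[[1]]
  f <- sp$regions$projection$f
  ev <- sp$regions$projection$evals
  # measured (effective) diffusivity ratio equals the tabled ALPS value
  eff <- function(lam) -log((1 - f) * exp(-1000 * lam) + f * exp(-3)) / 1000
  expect_equal(eff(ev[1]) / eff(ev[2]), tab$alps[1], tolerance = 1e-6)
  expect_equal(f, tab$fw[1])
})
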