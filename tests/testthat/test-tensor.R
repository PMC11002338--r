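make_single_voxel_dwi <- function(D, f = 0, gtab = test_gtab(), s0 = 1000,
                                  shape = c(3, 3, 3)) {
  sig <- simulate_signal(D, f, gtab, s0 = s0)
  arr <- array(rep(sig, each = prod(shape)), c(shape, length(sig)))
  dwi_volume(arr, diag(c(2, 2, 2, 1)), gtab)
}

test_that("noise-free tensor recovery is exact for ols and wls", {
  D <- diag(c(1.7, 0.2, 0.2)) * 1e-3
  dwi <- make_single_voxel_dwi(D)
  for (method in c("ols", "wls")) {
    tm <- fit_tensor(dwi, method = method)
    expect_lt(max(abs(tm$dxx - 1.7e-3)), 1e-9)
    expect_lt(max(abs(tm$dyy - 0.2e-3)), 1e-9)
    expect_lt(max(abs(tm$dzz - 0.2e-3)), 1e-9)
    expect_lt(max(abs(tm$tensor[, , , 4:6])), 1e-9)
    expect_equal(unique(as.vector(tm$s0)), 1000, tolerance = 1e-6)
  }
  # isotropic: FA = 0, MD exact
  ti <- fit_tensor(make_single_voxel_dwi(diag(3) * 1e-3))
  expect_equal(unique(as.vector(ti$fa)), 0, tolerance = 1e-9)
  expect_equal(unique(as.vector(ti$md)), 1e-3, tolerance = 1e-12)
})

test_that("two-compartment signal yields intermediate MD", {
  D <- diag(c(1.7, 0.2, 0.2)) * 1e-3
  tm <- fit_tensor(make_single_voxel_dwi(D, f = 0.4))
  md_tissue <- mean(c(1.7, 0.2, 0.2)) * 1e-3
  md_hat <- unique(round(as.vector(tm$md), 12))
  expect_gt(md_hat, md_tissue)
  expect_lt(md_hat, 3.0e-3)
})

test_that("FA matches its closed form and is scale invariant", {
  expect_equal(as.numeric(fa_from_eigenvalues(1e-3, 1e-3, 1e-3)), 0)
  expect_equal(as.numeric(fa_from_eigenvalues(1, 0, 0)), 1)
  expect_equal(as.numeric(fa_from_eigenvalues(1.7e-3, 0.2e-3, 0.2e-3)),
               oracle_fa(1.7, 0.2, 0.2), tolerance = 1e-9)
  # frozen closed-form value for the study-like eigenvalue triple
  expect_equal(oracle_fa(1.7, 0.2, 0.2), 0.8703883, tolerance = 1e-7)
  set.seed(2)
  l <- matrix(runif(30, 0.1, 2), 10)
  l <- t(apply(l, 1, sort, decreasing = TRUE))
  expect_equal(as.numeric(fa_from_eigenvalues(l[, 1], l[, 2], l[, 3])),
               as.numeric(fa_from_eigenvalues(7 * l[, 1], 7 * l[, 2], 7 * l[, 3])),
               tolerance = 1e-12)
  z <- fa_from_eigenvalues(0, 0, 0)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "zero_flag"))
  expect_error(fa_from_eigenvalues(-1, 0, 0), ">= 0")
})

test_that("axis diffusivities are the image-frame diagonal", {
  D <- diag(c(3, 5, 7)) * 1e-4
  tm <- fit_tensor(make_single_voxel_dwi(D))
  ad <- axis_diffusivities(tm)
  expect_equal(unique(as.vector(ad$dxx)), 3e-4, tolerance = 1e-10)
  expect_equal(unique(as.vector(ad$dyy)), 5e-4, tolerance = 1e-10)
  expect_equal(unique(as.vector(ad$dzz)), 7e-4, tolerance = 1e-10)

  # rotating the tensor 90 degrees about z swaps Dxx and Dyy
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  Drot <- Rz %*% D %*% t(Rz)
  tr <- fit_tensor(make_single_voxel_dwi(Drot))
  adr <- axis_diffusivities(tr)
  expect_equal(unique(round(as.vector(adr$dxx), 12)), 5e-4, tolerance = 1e-9)
  expect_equal(unique(round(as.vector(adr$dyy), 12)), 3e-4, tolerance = 1e-9)
  expect_equal(unique(round(as.vector(adr$dzz), 12)), 7e-4, tolerance = 1e-9)
  # trace equals eigenvalue sum (similarity invariance)
  expect_equal(adr$dxx + adr$dyy + adr$dzz,
               tr$evals[, , , 1] + tr$evals[, , , 2] + tr$evals[, , , 3],
               tolerance = 1e-12)
})

test_that("degenerate designs are rejected with a condition number", {
  dirs <- dwi_directions(32)
  # exactly planar directions cannot span the six tensor elements
  planar <- cbind(dirs[, 1], dirs[, 2], 0)
  planar <- planar / sqrt(rowSums(planar^2))
  expect_error(gradient_table(c(0, rep(1000, 32)), rbind(c(0, 0, 0), planar)),
               "non-collinear")
  # nearly planar directions slip past the rank check but leave the design
  # numerically unusable; the fit refuses with a condition number
  nearly <- cbind(dirs[, 1], dirs[, 2], 1e-8 * sign(dirs[, 3]))
  nearly <- nearly / sqrt(rowSums(nearly^2))
  gt <- gradient_table(c(0, rep(1000, 32)), rbind(c(0, 0, 0), nearly))
  dwi <- make_single_voxel_dwi(diag(3) * 1e-3, gtab = gt)
  expect_error(fit_tensor(dwi), "condition number")
})

test_that("FA bias under Rician noise stays small on an anisotropic slab", {
  reg <- pure_tissue_regions(proj = c(1.7e-3, 0.2e-3, 0.2e-3))
  ph <- build_phantom(phantom_spec(shape = c(20, 20, 10), regions = reg,
                                   noise = "rician", snr = 30, seed = 6))
  tm <- fit_tensor(ph$dwi)
  slab <- ph$truth$labels == "projection"
  vox <- which(slab)[1:200]
  fa_true <- oracle_fa(1.7, 0.2, 0.2)
  expect_lt(abs(median(tm$fa[vox]) - fa_true), 0.03)
})
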