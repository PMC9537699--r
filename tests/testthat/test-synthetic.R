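test_that("generators are pure functions of spec and seed", {
  spec <- fast_cell_spec(axis_curvature = 0.2)
  a <- generate_cell_image(spec, seed = 5)
  b <- generate_cell_image(spec, seed = 5)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$nucleus_mask, b$truth$nucleus_mask)
  c <- generate_cell_image(spec, seed = 6)
  expect_false(identical(a$stack$channels$dapi, c$stack$channels$dapi))
})

test_that("straight cell at p = 0.5: nucleus centroid sits at the midline midpoint", {
  spec <- fast_cell_spec(axis_curvature = 0, true_relative_position = 0.5)
  sim <- generate_cell_image(spec, seed = 1)
  ctr <- mask_centroid(sim$truth$nucleus_mask, spec$voxel_size) +
    sim$truth$origin[c("x", "y", "z")]
  mid <- (sim$truth$landmarks$apical + sim$truth$landmarks$basal) / 2
  expect_lt(max(abs(ctr - mid)), max(spec$voxel_size))  # within one voxel
})

test_that("k = 1 with zero noise gives a uniform reporter over the cell body", {
  spec <- fast_cell_spec(ne_enrichment_factor = 1, noise_model = NULL)
  sim <- generate_cell_image(spec, seed = 1)
  vals <- sim$stack$channels$reporter[sim$truth$cell_mask]
  expect_equal(length(unique(vals)), 1L)
})

test_that("recorded ground-truth lengths match a dense polyline oracle within 0.1%", {
  spec <- cell_spec(cell_length = 30, axis_curvature = 0.3,
                    true_relative_position = 0.75,
                    voxel_size = c(z = 0.5, y = 0.25, x = 0.25))
  sim <- generate_cell_image(spec, seed = 7)
  # independent re-integration of the generative midline family
  A <- 0.3 * 30 / 2
  arc_of <- function(D, n = 400001) {
    u <- seq(0, 1, length.out = n)
    sum(sqrt(rowSums(diff(cbind(A * sin(pi * u), D * u))^2)))
  }
  D <- uniroot(function(D) arc_of(D, 40001) - 30, c(10, 30), tol = 1e-10)$root
  u <- seq(0, 1, length.out = 400001)
  pts <- cbind(A * sin(pi * u), D * u)
  s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  L <- s[length(s)]
  expect_lt(abs(sim$truth$true_total_length - L) / L, 1e-3)
  # nucleus centre must sit at arc fraction 0.75 of the oracle curve
  ustar <- approx(s, u, xout = 0.75 * L)$y
  ctr_oracle <- c(A * sin(pi * ustar), D * ustar, 0)
  expect_lt(sqrt(sum((sim$truth$nucleus_center - ctr_oracle)^2)), 30 * 1e-3)
  expect_equal(sim$truth$true_relative_position, 0.75, tolerance = 1e-6)
})

test_that("noiseless DAPI thresholded at the background/nucleus midpoint reproduces the mask", {
  spec <- fast_cell_spec(noise_model = NULL)
  sim <- generate_cell_image(spec, seed = 2)
  thr <- (spec$background_intensity + spec$cytoplasm_intensity) / 2
  expect_identical(sim$stack$channels$dapi > thr, sim$truth$nucleus_mask)
  # nucleus strictly inside the cell, envelope disjoint from nucleus
  expect_true(all(sim$truth$cell_mask[sim$truth$nucleus_mask]))
  expect_false(any(sim$truth$ne_mask & sim$truth$nucleus_mask))
})

test_that("voxel size changes voxel counts but not physical ground truth", {
  s1 <- cell_spec(axis_curvature = 0.2, voxel_size = c(z = 0.5, y = 0.2, x = 0.2))
  s2 <- cell_spec(axis_curvature = 0.2, voxel_size = c(z = 0.4, y = 0.3, x = 0.3))
  a <- generate_cell_image(s1, seed = 3)
  b <- generate_cell_image(s2, seed = 3)
  expect_false(identical(dim(a$stack), dim(b$stack)))
  expect_equal(a$truth$true_total_length, b$truth$true_total_length,
               tolerance = 1e-9)
  # physical nucleus volumes agree to a voxel-quantisation margin
  v1 <- sum(a$truth$nucleus_mask) * prod(s1$voxel_size)
  v2 <- sum(b$truth$nucleus_mask) * prod(s2$voxel_size)
  expect_lt(abs(v1 - v2) / v1, 0.05)
})

test_that("a nucleus that cannot fit is rejected with an explanatory error", {
  expect_error(cell_spec(nucleus_radius = 4, cell_radius = 3.2),
               "does not fit")
  expect_error(cell_spec(true_relative_position = 0.01), "clearance")
})

test_that("cohorts are reproducible, truncated and hit their target means", {
  spec <- cohort_spec(5, group_means = list(a = 0.7, b = 0.5),
                      group_sds = list(a = 0.05, b = 0.05), seed = 42)
  t1 <- generate_cohort(spec)$table
  t2 <- generate_cohort(spec)$table
  expect_identical(t1, t2)
  expect_error(cohort_spec(5, list(a = 0.5), list(a = -1)), "sd")
  expect_error(cohort_spec(0, list(a = 0.5), list(a = 0.1)), "non-empty")
  # standard-error bound on recovered group means
  big <- generate_cohort(cohort_spec(30,
    group_means = list(A = 0.75, B = 0.50),
    group_sds = list(A = 0.03, B = 0.08), seed = 9))$table
  mA <- mean(big$value[big$group == "A"])
  mB <- mean(big$value[big$group == "B"])
  expect_lt(abs(mA - 0.75), 3 * 0.03 / sqrt(30))
  expect_lt(abs(mB - 0.50), 3 * 0.08 / sqrt(30))
  expect_true(all(big$value >= 0 & big$value <= 1))
})

test_that("null cohorts give uniform Mann-Whitney p over seeds", {
  ps <- vapply(1:200, function(r) {
    co <- generate_cohort(cohort_spec(30,
      group_means = list(a = 0.6, b = 0.6),
      group_sds = list(a = 0.05, b = 0.05), seed = r))$table
    mann_whitney(co$value[co$group == "a"], co$value[co$group == "b"])$p_value
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("cisternae profile construction matches the requested layout", {
  g <- generate_cisternae_profile(20, c(2, 2, 2), c(1, 1))
  expect_equal(unname(g$profile$segments),
               cbind(c(0, 3, 6), c(2, 5, 8)), ignore_attr = TRUE)
  one <- generate_cisternae_profile(10, 4)
  expect_length(gap_lengths(one$profile)$gaps, 0)
  expect_error(generate_cisternae_profile(5, c(3, 3), 1), "exceed")
  expect_error(generate_cisternae_profile(10, c(2, 2), numeric(0)), "one gap fewer")
})

test_that("randomised cisternae layouts round-trip their gaps exactly", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    segs <- runif(n, 0.5, 3)
    gaps <- runif(n - 1, 0.1, 2)
    g <- generate_cisternae_profile(sum(segs) + sum(gaps) + 5, segs, gaps,
                                    seed = i, randomize = TRUE)
    expect_equal(gap_lengths(g$profile)$gaps, gaps, tolerance = 1e-12)
  }
})
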