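test_that("rigid_transform enforces rigidity and composes/inverts correctly", {
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3), c(0, 0, 0)),
               "orthonormal")
  R <- rotation_about_axis(c(1, 1, 0), 25)
  expect_error(rigid_transform(R %*% diag(c(1, 1, -1)) %*% t(R) %*% R),
               "orthonormal|reflection")

  tr <- rigid_transform(R, c(0.3, -0.2, 1))
  inv <- transform_invert(tr)
  expect_equal(unclass(transform_compose(tr, inv)), diag(4),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(rotation_angle_deg(tr), 25, tolerance = 1e-9)

  # rigid motions preserve pairwise distances
  set.seed(3)
  pts <- matrix(rnorm(30), 10, 3)
  moved <- transform_points(tr, pts)
  expect_equal(as.vector(dist(moved)), as.vector(dist(pts)),
               tolerance = 1e-12)
})

test_that("sample_surface_points is area-uniform and deterministic", {
  # two triangles with area ratio 3:1
  s <- surface_scan(
    vertices = rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0),
                     c(10, 0, 0), c(11, 0, 0), c(10, 2, 0)),
    faces = rbind(c(1, 2, 3), c(4, 5, 6))
  )
  sp <- sample_surface_points(s, 10000, seed = 8)
  n_big <- sum(sp$face == 1)
  # binomial 99% CI around p = 0.75
  expect_lt(abs(n_big / 10000 - 0.75), 2.58 * sqrt(0.75 * 0.25 / 10000))
  # samples lie on their source triangles (z = 0 plane here, inside bounds)
  expect_true(all(abs(sp$points[, 3]) < 1e-12))

  sp3 <- sample_surface_points(s, 3, seed = 1)
  expect_equal(nrow(sp3$points), 3)
  expect_identical(sample_surface_points(s, 50, seed = 4)$points,
                   sample_surface_points(s, 50, seed = 4)$points)
  expect_error(sample_surface_points(s, 2), "n >= 3")
})

test_that("icp recovers a known rigid transform on the crown", {
  cr <- generate_crown(seed = 13)
  ref <- region_submesh(cr, c("buccal", "lingual"))$scan
  tr_true <- rigid_transform(rotation_about_axis(c(0.2, 1, 0.4), 3),
                             c(0.5, -0.2, 0.1))
  sp <- sample_surface_points(ref, 2000, seed = 2)
  moving <- transform_points(tr_true, sp$points)
  init <- wearbench:::principal_axes_init(ref$vertices, moving)

  # default metric (point_to_plane): exact recovery from a coarse init
  rep_ <- icp(ref, moving, alignment_config(), init = init)
  err <- transform_compose(rep_$transform, tr_true)
  expect_lt(rotation_angle_deg(err), 0.05)
  expect_lt(sqrt(sum(translation_mm(err)^2)) * 1000, 5)

  # point_to_point slides tangentially and converges more slowly; it must
  # still reach a few-um residual on this noise-free problem
  rep_pp <- icp(ref, moving, alignment_config(metric = "point_to_point"),
                init = init)
  expect_lt(rep_pp$rms_um, 10)
})

test_that("icp on already-aligned data stops immediately with ~0 RMS", {
  cr <- generate_crown(seed = 13)
  ref <- region_submesh(cr, c("buccal", "lingual"))$scan
  sp <- sample_surface_points(ref, 500, seed = 3)
  rep_ <- icp(ref, sp$points, alignment_config())
  expect_lte(rep_$iterations, 2)
  expect_lt(rep_$rms_um, 1e-6)
})

test_that("point_to_point icp objective is monotone non-increasing", {
  cr <- generate_crown(seed = 14)
  ref <- region_submesh(cr, c("buccal", "lingual"))$scan
  sp <- sample_surface_points(ref, 800, seed = 5)
  moving <- transform_points(
    rigid_transform(rotation_about_axis(c(0, 0, 1), 4), c(0.8, 0.3, -0.4)),
    sp$points)
  rep_ <- icp(ref, moving, alignment_config(metric = "point_to_point"))
  expect_true(all(diff(rep_$trace) <= 1e-9))
})

test_that("trimmed icp excludes gross outliers", {
  fp <- flat_patch(40, 10, z = 0)
  set.seed(9)
  n <- 500
  pts <- cbind(runif(n, 1, 9), runif(n, 1, 9), 0)
  out_idx <- sample(n, n * 0.2)
  pts[out_idx, 3] <- 1  # 20% gross outliers at 1 mm
  cfg <- alignment_config(inlier_threshold_um = 25, max_iterations = 20)
  rep_ <- icp(fp, pts, cfg, trim = TRUE)
  expect_equal(rep_$inlier_fraction, 0.8, tolerance = 0.02)
  expect_lt(rep_$rms_um, 5)

  # fewer than 3 inliers is a degenerate-alignment error
  far <- cbind(runif(10, 1, 9), runif(10, 1, 9), 5)
  expect_error(icp(fp, far, cfg, trim = TRUE), "degenerate alignment")
})

test_that("feature_global_align lands inside the ICP basin at 30 degrees", {
  cr <- generate_crown(seed = 21)
  tr_true <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30),
                             c(1, -0.5, 0.3))
  moving <- transform_scan(tr_true, cr)
  coarse <- feature_global_align(cr, moving, seed = 2)
  expect_false(isTRUE(attr(coarse, "fallback")))
  err <- transform_compose(coarse, tr_true)
  # residual after coarse alignment, measured on the moved vertices
  resid <- sqrt(rowSums((transform_points(err, cr$vertices) - cr$vertices)^2))
  expect_lt(sqrt(mean(resid^2)), 0.2)

  near <- feature_global_align(cr, cr, seed = 3)
  expect_lt(rotation_angle_deg(near), 0.5)
})

test_that("featureless sphere falls back to principal axes with a warning", {
  sp <- sphere_mesh(3, radius = 4)
  expect_warning(tr <- feature_global_align(sp, sp, seed = 1),
                 "falling back to principal axes")
  expect_true(isTRUE(attr(tr, "fallback")))
})

test_that("both strategies recover the true pose on a noise-free pair", {
  cr <- generate_crown(seed = 23)
  w <- apply_wear(cr, lesion_config(lesion_gaussian(c(0.4, 0.2), 0.3, 0.8)))
  pp <- perturb_pose(w$scan, 5, 2, seed = 31)
  for (st in c("bestfit", "feature_trimmed")) {
    al <- align_pair(cr, pp$scan, st)
    err <- transform_compose(al$report$transform, pp$transform)
    expect_lt(rotation_angle_deg(err), 0.05)
    expect_lt(sqrt(sum(translation_mm(err)^2)) * 1000, 5)
    # returned transform is rigid: within-scan distances preserved
    v0 <- pp$scan$vertices[c(1, 100, 2000), ]
    v1 <- al$aligned$vertices[c(1, 100, 2000), ]
    expect_equal(as.vector(dist(v1)), as.vector(dist(v0)), tolerance = 1e-9)
  }
})

test_that("strategies are equivariant under a common rigid motion", {
  cr <- generate_crown(seed = 24)
  w <- apply_wear(cr, lesion_config(lesion_gaussian(c(-0.3, 0.5), 0.35, 0.7)))
  pp <- perturb_pose(w$scan, 4, 1.5, seed = 8)
  g <- rigid_transform(rotation_about_axis(c(1, 2, 0.5), 12), c(3, -1, 2))

  for (st in c("bestfit", "feature_trimmed")) {
    al1 <- align_pair(cr, pp$scan, st)
    m1 <- measure_wear(cr, al1$aligned)
    al2 <- align_pair(transform_scan(g, cr), transform_scan(g, pp$scan), st)
    m2 <- measure_wear(transform_scan(g, cr), al2$aligned)
    expect_equal(m2$volume_change_mm3, m1$volume_change_mm3, tolerance = 1e-4)
    expect_equal(m2$max_point_loss_um, m1$max_point_loss_um, tolerance = 0.1)
  }
})

test_that("trimmed inlier RMS reflects the combined noise of two 2.6 um scans", {
  cr <- generate_crown(seed = 25)
  noisy <- function(seed) {
    s <- cr
    s$vertices <- s$vertices + with(list(n = length(s$vertices)), {
      set.seed(seed)
      matrix(rnorm(n, 0, 2.6e-3), ncol = 3)
    })
    s
  }
  al <- align_feature_trimmed_style(noisy(1), noisy(2))
  expect_gt(al$report$rms_um, 2)
  expect_lt(al$report$rms_um, 5)
})

test_that("reference areas deviating beyond 25 um are excluded from the solve", {
  cr <- generate_crown(seed = 26)
  ctr <- cr$vertices[which(cr$labels == "buccal")[40], ]
  worn_ref <- apply_reference_wear(cr, ctr, 0.08, sigma_mm = 1.2)
  al <- align_feature_trimmed_style(cr, worn_ref)
  # a noise-free pair would keep every correspondence; the 80 um wall lesion
  # forces a visible excluded fraction
  expect_lt(al$report$inlier_fraction, 0.995)
  expect_gt(al$report$inlier_fraction, 0.5)
  expect_lt(al$report$rms_um, 25)
})
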