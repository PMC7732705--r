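test_that("occlusal_direction is the outward occlusal plane normal", {
  fp <- flat_patch(8, 4, z = 2)
  expect_equal(occlusal_direction(fp), c(0, 0, 1), tolerance = 1e-9)

  cr <- generate_crown(seed = 3)
  d0 <- occlusal_direction(cr)
  expect_lt(acos(min(1, sum(d0 * c(0, 0, 1)))) * 180 / pi, 3)

  # rotation equivariance: tilting the crown 10 deg tilts the direction
  g <- rigid_transform(rotation_about_axis(c(1, 0, 0), 10))
  d1 <- occlusal_direction(transform_scan(g, cr))
  expect_equal(d1, as.vector(g[1:3, 1:3] %*% d0), tolerance = 1e-9)

  bad <- fp
  bad$labels <- rep("other", nrow(bad$vertices))
  expect_error(occlusal_direction(bad), "no occlusal vertices")
})

test_that("distance_map signs, flags and areas behave", {
  fp <- flat_patch(12, 6, z = 1)
  dm0 <- distance_map(fp, fp)
  expect_true(all(abs(dm0$distance_um) < 1e-9))
  expect_equal(dm0$valid_fraction, 1)
  # one-third areas tile the region
  expect_equal(sum(dm0$area_mm2), 36, tolerance = 1e-9)

  # follow-up shifted down 20 um: every distance is -20 um
  down <- fp
  down$vertices[, 3] <- down$vertices[, 3] - 0.02
  dm <- distance_map(fp, down)
  expect_true(all(abs(dm$distance_um + 20) < 1e-9))
  expect_equal(volume_change(dm), -0.02 * 36, tolerance = 1e-9)

  # shifted follow-up far sideways: rays miss -> coverage error
  off <- fp
  off$vertices[, 1] <- off$vertices[, 1] + 100
  expect_error(distance_map(fp, off), "rays hit")
})

test_that("distance map reproduces the lesion depth field pointwise", {
  cr <- generate_crown(seed = 7)
  lc <- lesion_config(lesion_gaussian(c(0, 0), 0.4, 0.9))
  w <- apply_wear(cr, lc)
  dm <- distance_map(cr, w$scan)
  sub <- region_submesh(cr, "occlusal")
  # deepest point sits at the lesion centre with depth = amplitude
  expect_equal(max_point_loss(dm), 400, tolerance = 4)
  # pointwise: d_i ~ -depth(v_i) within 1 um at the centre region
  ctr_idx <- which(rowSums(sub$scan$vertices[, 1:2]^2) < 0.05^2)
  expect_true(length(ctr_idx) >= 1)
  expect_true(all(abs(dm$distance_um[ctr_idx] + 1000 * 0.4 *
    exp(-rowSums(sub$scan$vertices[ctr_idx, 1:2, drop = FALSE]^2) /
          (2 * 0.9^2))) < 1))
})

test_that("volume_change is additive over disjoint occlusal partitions", {
  cr <- generate_crown(seed = 9)
  w <- apply_wear(cr, lesion_config(lesion_gaussian(c(0.3, 0.1), 0.3, 0.8)))
  dm <- distance_map(cr, w$scan)
  total <- volume_change(dm)

  # the integral decomposes exactly over any disjoint vertex partition
  sub <- region_submesh(cr, "occlusal")
  left <- sub$scan$vertices[, 1] > 0
  ok <- dm$valid
  part <- function(sel) sum(dm$distance_um[sel & ok] / 1000 *
                              dm$area_mm2[sel & ok])
  expect_equal(part(left) + part(!left), total, tolerance = 1e-9)

  # and relabelling a region moves its contribution between partitions:
  # integrating over a sub-label region matches the vertex-level sum for
  # faces wholly inside it
  expect_lt(abs(total - (-w$true_volume_mm3)) / w$true_volume_mm3, 0.02)
})

test_that("mean_profile_loss averages loss vertices only", {
  fp <- flat_patch(21, 10, z = 0)
  half <- fp
  half$vertices[, 3] <- ifelse(half$vertices[, 1] > 5, -0.04, 0)
  # drop the step-edge column from the region to avoid straddle faces
  keep <- abs(half$vertices[, 1] - 5) > 0.25
  fp2 <- fp
  fp2$labels[!keep] <- "other"
  dm <- distance_map(fp2, half)
  expect_equal(mean_profile_loss(dm), 40, tolerance = 0.5)
  expect_equal(mean_profile_loss(dm, loss_only = FALSE),
               40 * sum(dm$area_mm2[dm$distance_um < -1]) / sum(dm$area_mm2),
               tolerance = 1)

  # uniform -20 um
  down <- fp
  down$vertices[, 3] <- -0.02
  expect_equal(mean_profile_loss(distance_map(fp, down)), 20, tolerance = 1e-6)

  # all-zero map
  expect_equal(mean_profile_loss(distance_map(fp, fp)), 0)
  expect_equal(max_point_loss(distance_map(fp, fp)), 0)
})

test_that("max_point_loss is a pointwise extreme (outlier-sensitive)", {
  fp <- flat_patch(10, 4, z = 0)
  one <- fp
  one$vertices[40, 3] <- -3e-3  # single vertex 3 um down
  dm <- distance_map(fp, one)
  expect_equal(max_point_loss(dm), 3, tolerance = 0.01)
})

test_that("truncation semantics: per-surface and per-vertex variants", {
  expect_equal(truncate_positive(c(-0.37, 0.51, 0)), c(-0.37, 0, 0))
  expect_equal(truncate_positive(c(-1, -2.5)), c(-1, -2.5))

  # per-vertex variant on a pure-gain map is 0
  fp <- flat_patch(10, 4, z = 0)
  up <- fp
  up$vertices[, 3] <- 0.03
  dm <- distance_map(fp, up)
  expect_equal(truncate_map_positive(dm), 0)
  expect_gt(volume_change(dm), 0)

  # truncated volume is never above 0 nor above the raw volume
  cr <- generate_crown(seed = 10)
  w <- apply_wear(cr, lesion_config(lesion_gaussian(c(0, 0.4), 0.25, 0.7)))
  dm2 <- distance_map(cr, w$scan)
  v <- volume_change(dm2)
  expect_lte(truncate_positive(v), 0)
  expect_lte(truncate_positive(v), max(v, 0))
  expect_lte(truncate_map_positive(dm2), min(v, 0) + 1e-12)
})

test_that("metrics are invariant under simultaneous rigid motion", {
  cr <- generate_crown(seed = 11)
  w <- apply_wear(cr, lesion_config(lesion_gaussian(c(0.2, -0.2), 0.3, 0.8)))
  m0 <- measure_wear(cr, w$scan)
  g <- rigid_transform(rotation_about_axis(c(0.3, 1, 0.2), 35), c(5, -2, 1))
  m1 <- measure_wear(transform_scan(g, cr), transform_scan(g, w$scan))
  expect_equal(m1$volume_change_mm3, m0$volume_change_mm3, tolerance = 1e-6)
  expect_equal(m1$max_point_loss_um, m0$max_point_loss_um, tolerance = 1e-3)
  expect_equal(m1$mean_profile_loss_um, m0$mean_profile_loss_um,
               tolerance = 1e-3)
})
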