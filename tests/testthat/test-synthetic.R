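test_that("generate_crown is deterministic, labelled and manifold", {
  a <- generate_crown(seed = 17)
  b <- generate_crown(seed = 17)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$vertices, generate_crown(seed = 18)$vertices))

  expect_true(validate_scan(a, manifold = TRUE))
  expect_setequal(unique(a$labels), c("occlusal", "buccal", "lingual", "other"))
})

test_that("occlusal footprint area matches the generator's design radius", {
  cr <- generate_crown(seed = 1, size_mm = 10)
  occ <- region_submesh(cr, "occlusal")$scan
  dir <- occlusal_direction(cr)
  # projected (footprint) area vs the nominal disk pi * (0.35 * size)^2
  footprint <- sum(face_areas(occ) * abs(face_normals(occ) %*% dir))
  expect_equal(footprint, pi * 3.5^2, tolerance = 0.15)
})

test_that("the crown has genuine undercuts on the bulged walls", {
  cr <- generate_crown(seed = 1)
  # probe just outside the wall top radius, inside the bulge crest
  hits <- wearbench:::line_hit_count(cr, c(0, 4.3, -1), c(0, 0, 1))
  expect_gte(hits, 2)
  hits2 <- wearbench:::line_hit_count(cr, c(0, -4.3, -1), c(0, 0, 1))
  expect_gte(hits2, 2)
})

test_that("apply_wear has exact closed-form volume and touches only occlusal", {
  cr <- generate_crown(seed = 4)
  # empty lesion list: identity
  w0 <- apply_wear(cr, lesion_config(list()))
  expect_identical(w0$scan$vertices, cr$vertices)
  expect_equal(w0$true_volume_mm3, 0)

  lc <- lesion_config(lesion_gaussian(c(0, 0), 0.5, 1))
  expect_equal(lc$true_volume_mm3, 2 * pi * 0.5 * 1, tolerance = 1e-12)
  w <- apply_wear(cr, lc)
  nonocc <- cr$labels != "occlusal"
  expect_identical(w$scan$vertices[nonocc, ], cr$vertices[nonocc, ])
  expect_false(identical(w$scan$vertices[!nonocc, ], cr$vertices[!nonocc, ]))

  # spherical cap volume formula
  cap <- lesion_cap(c(0.5, 0), radius_mm = 2, height_mm = 0.3)
  expect_equal(lesion_config(cap)$true_volume_mm3,
               pi * 0.3^2 * (3 * 2 - 0.3) / 3, tolerance = 1e-12)

  # quadrature oracle: summed depth on a 10 um grid matches the closed form
  gx <- seq(-3.5, 3.5, by = 0.01)
  dd <- outer(gx, gx, function(x, y) 0.5 * exp(-(x^2 + y^2) / 2))
  expect_equal(sum(dd) * 0.01^2, lc$true_volume_mm3, tolerance = 0.005)

  expect_error(apply_wear(cr, lesion_config(lesion_gaussian(c(3, 0), 0.3, 1))),
               "footprint")
  expect_error(apply_wear(cr, lesion_config(lesion_gaussian(c(0, 0), 6, 0.5))),
               "thickness")
})

test_that("profilometer capture is an exact noise-free height field", {
  fp <- flat_patch(11, 5, z = 1.25)
  cfg <- scanner_config("profilometer", step_um = 250, noise_sd_um = 0)
  out <- simulate_profilometer(fp, cfg)
  expect_true(all(abs(out$vertices[, 3] - 1.25) < 1e-12))

  cr <- generate_crown(seed = 6)
  prof <- simulate_profilometer(cr, scanner_config("profilometer",
                                                   noise_sd_um = 0, seed = 1))
  # undercuts invisible: every vertical line hits at most once
  set.seed(31)
  bvh <- scan_bvh(prof)
  for (i in 1:40) {
    o <- c(runif(1, -4.4, 4.4), runif(1, -4.4, 4.4), -10)
    expect_lte(wearbench:::line_hit_count(prof, o, c(0, 0, 1), bvh = bvh), 1L)
  }
  # but the source crown shows 2+ hits through the bulge
  expect_gte(wearbench:::line_hit_count(cr, c(0, 4.3, -10), c(0, 0, 1)), 2)
})

test_that("profilometer noise recovers the configured 2.6 um SD", {
  fp <- flat_patch(6, 8, z = 0)  # large flat plate -> many grid nodes
  cfg <- scanner_config("profilometer", step_um = 50, noise_sd_um = 2.6,
                        seed = 77)
  out <- simulate_profilometer(fp, cfg)
  resid_um <- out$vertices[, 3] * 1000  # truth is z = 0
  expect_gt(length(resid_um), 1e4)
  expect_equal(sd(resid_um), 2.6, tolerance = 0.1)
  expect_lt(abs(mean(resid_um)), 3 * 2.6 / sqrt(length(resid_um)))
})

test_that("intraoral capture: identity config, contractive peaks, undercuts kept", {
  cr <- generate_crown(seed = 6)
  idcfg <- scanner_config("intraoral", noise_sd_um = 0,
                          smoothing_iterations = 0, remesh_edge_mm = 0)
  out <- simulate_intraoral(cr, idcfg)
  expect_equal(out$vertices, cr$vertices, tolerance = 1e-15)
  expect_equal(out$faces, cr$faces)

  # smoothing is contractive at maxima: a sharp peak strictly drops
  peak <- flat_patch(21, 4, z = 0)
  d2 <- rowSums(sweep(peak$vertices[, 1:2], 2, c(2, 2))^2)
  peak$vertices[, 3] <- 0.8 * exp(-d2 / (2 * 0.15^2))
  sm <- simulate_intraoral(peak, scanner_config("intraoral", noise_sd_um = 0,
                                                smoothing_iterations = 5,
                                                remesh_edge_mm = 0))
  expect_lt(max(sm$vertices[, 3]), max(peak$vertices[, 3]))

  io <- simulate_intraoral(cr, scanner_config("intraoral", seed = 9))
  expect_gte(wearbench:::line_hit_count(io, c(0, 4.3, -10), c(0, 0, 1)), 2)
  # labels survive the transfer
  expect_setequal(unique(io$labels), c("occlusal", "buccal", "lingual", "other"))
})

test_that("perturb_pose is bounded, invertible and deterministic", {
  cr <- generate_crown(seed = 2)
  p0 <- perturb_pose(cr, 0, 0, seed = 5)
  expect_equal(unclass(p0$transform), diag(4), ignore_attr = TRUE)
  expect_equal(p0$scan$vertices, cr$vertices)

  p <- perturb_pose(cr, 5, 2, seed = 6)
  expect_lte(rotation_angle_deg(p$transform), 5)
  expect_true(all(abs(translation_mm(p$transform)) <= 2))
  back <- transform_scan(transform_invert(p$transform), p$scan)
  expect_equal(back$vertices, cr$vertices, tolerance = 1e-12)

  p2 <- perturb_pose(cr, 5, 2, seed = 6)
  expect_identical(unclass(p$transform), unclass(p2$transform))
})

test_that("apply_reference_wear touches only buccal/lingual vertices", {
  cr <- generate_crown(seed = 8)
  ctr <- cr$vertices[which(cr$labels == "buccal")[10], ]
  worn <- apply_reference_wear(cr, ctr, 0.04, sigma_mm = 1)
  wall <- cr$labels %in% c("buccal", "lingual")
  expect_identical(worn$vertices[!wall, ], cr$vertices[!wall, ])
  moved <- sqrt(rowSums((worn$vertices - cr$vertices)^2))
  expect_equal(max(moved), 0.04, tolerance = 0.05)
})

test_that("generate_cohort is deterministic with complete bundles", {
  co <- generate_cohort(n_surfaces = 3, seed = 12,
                        capture_models = c("ideal"))
  co2 <- generate_cohort(n_surfaces = 3, seed = 12,
                         capture_models = c("ideal"))
  expect_identical(co$ground_truth, co2$ground_truth)
  expect_identical(co$bundles[[2]]$scans$ideal$followup$vertices,
                   co2$bundles[[2]]$scans$ideal$followup$vertices)

  b <- co$bundles[[1]]
  expect_named(b$scans, "ideal")
  expect_named(b$scans$ideal, c("baseline", "followup"))
  expect_equal(b$true_volume_mm3, b$lesions$true_volume_mm3)
  # truth attaches to the ideal surface: the stored volume equals the
  # closed-form sum over the lesion list
  expect_equal(b$true_volume_mm3,
               sum(sapply(b$lesions$lesions, function(l) 2 * pi * l$a * l$sigma^2)),
               tolerance = 1e-12)

  co4 <- generate_cohort(n_surfaces = 2, seed = 3,
                         capture_models = c("profilometer", "intraoral"))
  expect_length(co4$bundles[[1]]$scans, 2)
  expect_equal(nrow(co4$ground_truth), 2)
  expect_true(all(c("true_volume_mm3", "t11", "t34") %in%
                    names(co4$ground_truth)))
})

test_that("cohort lesion volumes match the log-normal moment (Monte Carlo)", {
  # amplitudes ~ LN(log 0.25, 0.5), widths ~ LN(log 0.5, 0.25) truncated at
  # 0.9 / 0.8; per-lesion volume 2 pi a sigma^2. The empirical mean over many
  # lesions must sit within 3 SE of the analytic mean of the untruncated law
  # (truncation effects at these quantiles are < 1%, absorbed in the 3 SE).
  co <- generate_cohort(n_surfaces = 120, seed = 77, capture_models = "ideal",
                        max_angle_deg = 0.1, max_translation_mm = 0.1)
  vols <- unlist(lapply(co$bundles, function(b)
    vapply(b$lesions$lesions, function(l) 2 * pi * l$a * l$sigma^2, 1.0)))
  m_a <- exp(log(0.25) + 0.5^2 / 2)
  m_s2 <- exp(2 * log(0.5) + 2 * 0.25^2)
  analytic <- 2 * pi * m_a * m_s2
  se <- sd(vols) / sqrt(length(vols))
  expect_lt(abs(mean(vols) - analytic), 3 * se + 0.02 * analytic)
})
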