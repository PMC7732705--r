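test_that("surface_scan enforces its invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_error(surface_scan(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(surface_scan(v, rbind(c(1, 2, 3)), labels = c("a", "b", "c")),
               "unknown region label")
  expect_error(surface_scan(v, rbind(c(1, 2, 3)), labels = "occlusal"),
               "must equal vertex count")
  expect_error(surface_scan(rbind(v, c(NA, 0, 0)), rbind(c(1, 2, 3))),
               "finite")
  # degenerate faces are dropped at construction
  s <- surface_scan(rbind(v, c(2, 0, 0)), rbind(c(1, 2, 3), c(1, 2, 2)))
  expect_equal(nrow(s$faces), 1)
})

test_that("grid_to_scan triangulates complete quads and skips missing cells", {
  # 2x2 flat grid: 2 triangles, area = one grid cell
  g <- raster_grid(matrix(0, 2, 2), x_step = 50, y_step = 50)
  s <- grid_to_scan(g)
  expect_equal(nrow(s$faces), 2)
  expect_equal(sum(face_areas(s)), 0.05 * 0.05, tolerance = 1e-12)

  # 3x3 grid with centre missing: the oracle enumerates quads whose 4
  # corners are valid; all 4 quads touch the centre, so no faces remain
  h <- matrix(0, 3, 3)
  h[2, 2] <- NA
  valid <- is.finite(h)
  quads_ok <- sum(vapply(1:2, function(i) sum(vapply(1:2, function(j)
    valid[i, j] && valid[i + 1, j] && valid[i, j + 1] && valid[i + 1, j + 1],
    TRUE)), 0L))
  expect_equal(quads_ok, 0L)
  expect_error(grid_to_scan(raster_grid(h)), "no complete quads")

  # same oracle on a richer pattern
  h2 <- matrix(0, 4, 5)
  h2[cbind(c(1, 3), c(2, 4))] <- NA
  valid <- is.finite(h2)
  quads_ok <- 0L
  for (i in 1:3) for (j in 1:4) {
    if (valid[i, j] && valid[i + 1, j] && valid[i, j + 1] &&
        valid[i + 1, j + 1]) quads_ok <- quads_ok + 1L
  }
  s2 <- grid_to_scan(raster_grid(h2))
  expect_equal(nrow(s2$faces), 2L * quads_ok)

  # plane z = x: every triangle normal is (-1, 0, 1)/sqrt(2)
  xs <- seq(0, 0.2, by = 0.05)
  hz <- matrix(xs, 5, 5, byrow = TRUE)  # z[i, j] = x_j
  sp <- grid_to_scan(raster_grid(hz, 50, 50))
  fn <- face_normals(sp)
  expect_true(all(abs(sweep(fn, 2, c(-1, 0, 1) / sqrt(2))) < 1e-9))

  expect_error(grid_to_scan(raster_grid(matrix(1, 1, 5))), "at least 2 x 2")
  expect_error(raster_grid(matrix(NA_real_, 3, 3)), "no valid cells")
})

test_that("height-field meshes have no undercuts (<= 1 distinct vertical hit)", {
  set.seed(11)
  h <- matrix(runif(15 * 15, 0, 2), 15, 15)
  h[sample(225, 12)] <- NA
  s <- grid_to_scan(raster_grid(h, 100, 100))
  for (i in 1:60) {
    o <- c(runif(1, 0, 1.4), runif(1, 0, 1.4), -5)
    expect_lte(wearbench:::line_hit_count(s, o, c(0, 0, 1)), 1L)
  }
})

test_that("vertex_normals are area-weighted, oriented, and flip with winding", {
  fp <- flat_patch(6, 2, z = 0.3)
  vn <- vertex_normals(fp)
  expect_true(all(abs(sweep(vn, 2, c(0, 0, 1))) < 1e-12))

  flipped <- fp
  flipped$faces <- fp$faces[, c(1, 3, 2)]
  expect_equal(vertex_normals(flipped), -vn, tolerance = 1e-12)

  sp <- sphere_mesh(4)  # ~2000 vertices
  vn <- vertex_normals(sp)
  ana <- sp$vertices / sqrt(rowSums(sp$vertices^2))
  ang <- acos(pmin(1, rowSums(vn * ana))) * 180 / pi
  expect_lt(max(ang), 2)
  # convex shape: all normals point away from the centroid
  ctr <- colMeans(sp$vertices)
  expect_true(all(rowSums(vn * sweep(sp$vertices, 2, ctr)) > 0))
})

test_that("region_submesh extracts label regions and partitions area", {
  cr <- generate_crown(seed = 2)
  all_s <- region_submesh(cr, c("occlusal", "buccal", "lingual", "other"))
  expect_equal(sum(face_areas(all_s$scan)), sum(face_areas(cr)),
               tolerance = 1e-12)
  expect_equal(nrow(all_s$scan$faces), nrow(cr$faces))

  refs <- region_submesh(cr, c("buccal", "lingual"))
  expect_false(any(refs$scan$labels == "occlusal"))
  # index map is injective and consistent with parent coordinates
  expect_equal(anyDuplicated(refs$index_map), 0L)
  expect_equal(refs$scan$vertices, cr$vertices[refs$index_map, ])

  # faces selected by complementary label sets are disjoint subsets of parent
  occ <- region_submesh(cr, "occlusal")
  rest <- region_submesh(cr, c("buccal", "lingual", "other"))
  key <- function(sub) {
    f <- matrix(sub$index_map[sub$scan$faces], ncol = 3)
    paste(f[, 1], f[, 2], f[, 3])
  }
  parent_key <- paste(cr$faces[, 1], cr$faces[, 2], cr$faces[, 3])
  expect_length(intersect(key(occ), key(rest)), 0)
  expect_true(all(c(key(occ), key(rest)) %in% parent_key))

  expect_error(region_submesh(cr, character(0)))
})

test_that("fit_plane is total least squares with oriented normal", {
  set.seed(4)
  pts <- cbind(runif(50), runif(50), 1.5)
  pl <- fit_plane(pts, normal_hint = c(0, 0, 1))
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(pl$offset, 1.5, tolerance = 1e-9)

  # plane x + z = 0
  u <- runif(60, -1, 1); w <- runif(60, -1, 1)
  pts2 <- cbind(u, w, -u)
  pl2 <- fit_plane(pts2)
  expect_equal(abs(sum(pl2$normal * c(1, 0, 1) / sqrt(2))), 1, tolerance = 1e-9)

  # noisy plane (sigma 10 um, n = 500): normal within 0.2 deg of the SVD
  # fit on the generating plane
  set.seed(99)
  n_true <- c(0.1, -0.2, 1); n_true <- n_true / sqrt(sum(n_true^2))
  b1 <- c(1, 0, 0) - n_true[1] * n_true; b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(n_true[2] * b1[3] - n_true[3] * b1[2],
          n_true[3] * b1[1] - n_true[1] * b1[3],
          n_true[1] * b1[2] - n_true[2] * b1[1])
  uv <- cbind(runif(500, -3, 3), runif(500, -3, 3))
  pts3 <- uv[, 1] %o% b1 + uv[, 2] %o% b2 +
    rnorm(500, 0, 0.01) %o% n_true
  pl3 <- fit_plane(pts3, normal_hint = n_true)
  expect_lt(acos(min(1, sum(pl3$normal * n_true))) * 180 / pi, 0.2)

  expect_error(fit_plane(cbind(1:5, 1:5, 1:5)), "collinear")
  expect_error(fit_plane(pts[1:2, ]))
})

test_that("closest_point matches the brute-force oracle", {
  set.seed(21)
  s <- sphere_mesh(2)  # 128 faces: brute force is cheap
  bvh <- scan_bvh(s)
  for (i in 1:100) {
    q <- runif(3, -2, 2)
    got <- closest_point(s, q, bvh = bvh)
    want <- brute_closest(s, q)
    expect_equal(got$dist2, want$dist2, tolerance = 1e-12)
    expect_equal(as.vector(got$point), as.vector(want$point), tolerance = 1e-9)
  }
  # query exactly on a vertex
  got <- closest_point(s, s$vertices[5, ])
  expect_equal(got$dist2, 0, tolerance = 1e-15)
  # query above the centre of a flat patch at height h
  fp <- flat_patch(5, 2, z = 0.75)
  got <- closest_point(fp, c(1, 1, 2))
  expect_equal(sqrt(got$dist2), 1.25, tolerance = 1e-12)
})

test_that("ray_intersect matches the brute-force oracle and signs t", {
  set.seed(22)
  s <- sphere_mesh(2)
  bvh <- scan_bvh(s)
  for (i in 1:100) {
    o <- runif(3, -1.5, 1.5)
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    got <- ray_intersect(s, o, d, bvh = bvh)
    want <- brute_line_hit(s, o, d)
    if (is.na(want$t)) {
      expect_true(is.na(got$t))
    } else {
      expect_equal(got$t, want$t, tolerance = 1e-9)
    }
  }
  fp <- flat_patch(5, 2, z = 0)
  expect_equal(ray_intersect(fp, c(1, 1, -3), c(0, 0, 1))$t, 3,
               tolerance = 1e-12)
  expect_equal(ray_intersect(fp, c(1, 1, 3), c(0, 0, 1))$t, -3,
               tolerance = 1e-12)
  expect_true(is.na(ray_intersect(fp, c(1, 1, 1), c(1, 0, 0))$t))
  expect_error(ray_intersect(fp, c(0, 0, 0), c(0, 0, 2)), "unit length")
})

test_that("weld_vertices merges duplicates and drops collapsed faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0) + 1e-12, c(0, 1, 0), c(1, 1, 0))
  s <- surface_scan(v, rbind(c(1, 2, 3), c(4, 6, 5)))
  w <- weld_vertices(s, tol = 1e-9)
  expect_equal(nrow(w$vertices), 4)
  expect_equal(nrow(w$faces), 2)
})
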