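#' Lesion configuration with closed-form ground-truth volume
#'
#' Wear lesions are depth fields subtracted from the occlusal surface along
#' the occlusal-plane normal. Modelling wear as a height-field makes the
#' ground-truth volume exact by construction: a Gaussian lesion of amplitude
#' `a` and width `sigma` removes `2*pi*a*sigma^2` mm^3; a spherical cap of
#' sphere radius `r` and height `h` removes `pi*h^2*(3r - h)/3` mm^3.
#'
#' @param ... lesions built with [lesion_gaussian()] or [lesion_cap()].
#' @return object of class `lesion_config` with element `true_volume_mm3`.
#' @examples
#' lc <- lesion_config(lesion_gaussian(c(0, 0), amplitude_mm = 0.5, sigma_mm = 1))
#' lc$true_volume_mm3  # 2*pi*0.5*1^2
#' @export
lesion_config <- function(...) {
  lesions <- list(...)
  if (length(lesions) == 1 && is.list(lesions[[1]]) &&
      !inherits(lesions[[1]], "wear_lesion")) {
    lesions <- lesions[[1]]
  }
  stopifnot(all(vapply(lesions, inherits, TRUE, "wear_lesion")))
  structure(
    list(lesions = lesions,
         true_volume_mm3 = sum(vapply(lesions, lesion_volume, 1.0))),
    class = "lesion_config"
  )
}

#' @rdname lesion_config
#' @param center length-2 lesion centre in occlusal-plane coordinates (mm).
#' @param amplitude_mm peak depth `a` (mm), > 0.
#' @param sigma_mm Gaussian width (mm), > 0.
#' @export
lesion_gaussian <- function(center, amplitude_mm, sigma_mm) {
  stopifnot(length(center) == 2, amplitude_mm > 0, sigma_mm > 0)
  structure(list(shape = "gaussian", center = as.numeric(center),
                 a = amplitude_mm, sigma = sigma_mm),
            class = "wear_lesion")
}

#' @rdname lesion_config
#' @param radius_mm sphere radius `r` of the indenting sphere (mm).
#' @param height_mm cap height `h` (mm), 0 < h <= r.
#' @export
lesion_cap <- function(center, radius_mm, height_mm) {
  stopifnot(length(center) == 2, radius_mm > 0,
            height_mm > 0, height_mm <= radius_mm)
  structure(list(shape = "spherical_cap", center = as.numeric(center),
                 r = radius_mm, h = height_mm),
            class = "wear_lesion")
}

lesion_volume <- function(l) {
  switch(l$shape,
    gaussian = 2 * pi * l$a * l$sigma^2,
    spherical_cap = pi * l$h^2 * (3 * l$r - l$h) / 3
  )
}

lesion_depth <- function(l, d) {
  # depth at in-plane distance d from the lesion centre
  switch(l$shape,
    gaussian = l$a * exp(-d^2 / (2 * l$sigma^2)),
    spherical_cap = {
      extent2 <- l$h * (2 * l$r - l$h)
      out <- numeric(length(d))
      inside <- d^2 < extent2
      out[inside] <- sqrt(l$r^2 - d[inside]^2) - (l$r - l$h)
      out
    }
  )
}

lesion_extent <- function(l) {
  # radius beyond which the depth is (numerically) negligible
  switch(l$shape,
    gaussian = 3 * l$sigma,
    spherical_cap = sqrt(l$h * (2 * l$r - l$h))
  )
}

#' Scanner capture configuration
#'
#' Holds the capture-model parameters. The profilometer model samples the
#' top-most surface on a raster grid (step-over 50 um) with i.i.d. Gaussian
#' height noise (repeatability 2.6 um) and cannot see undercuts. The
#' intraoral model keeps undercuts but coarsens the mesh (vertex-clustering
#' remesh to ~0.2 mm edges), applies Laplacian smoothing (the
#' interpolation/averaging that smooths topography) and adds vertex noise.
#' `"ideal"` is a pass-through used for ground-truth runs.
#'
#' @param capture_model `"profilometer"`, `"intraoral"` or `"ideal"`.
#' @param step_um raster step-over (profilometer), um.
#' @param noise_sd_um Gaussian noise SD, um (2.6 for the profilometer,
#'   10 for the intraoral model).
#' @param smoothing_iterations,smoothing_lambda Laplacian smoothing
#'   (intraoral only).
#' @param remesh_edge_mm target cluster size for the intraoral remesh
#'   (0 disables).
#' @param seed RNG seed for the capture noise.
#' @return object of class `scanner_config`.
#' @export
scanner_config <- function(capture_model = c("profilometer", "intraoral", "ideal"),
                           step_um = 50,
                           noise_sd_um = NULL,
                           smoothing_iterations = 10,
                           smoothing_lambda = 0.5,
                           remesh_edge_mm = 0.2,
                           seed = 1L) {
  capture_model <- match.arg(capture_model)
  if (is.null(noise_sd_um)) {
    noise_sd_um <- switch(capture_model, profilometer = 2.6, intraoral = 10, 0)
  }
  stopifnot(step_um > 0, noise_sd_um >= 0, smoothing_iterations >= 0,
            smoothing_lambda >= 0, remesh_edge_mm >= 0)
  structure(list(capture_model = capture_model, step_um = step_um,
                 noise_sd_um = noise_sd_um,
                 smoothing_iterations = smoothing_iterations,
                 smoothing_lambda = smoothing_lambda,
                 remesh_edge_mm = remesh_edge_mm, seed = as.integer(seed)),
            class = "scanner_config")
}

#' Generate a synthetic tooth crown
#'
#' Builds a molar-like shell in canonical pose (occlusal normal ~ +z): a
#' gently domed top carrying `cusp_count` Gaussian cusps (labelled
#' `occlusal` inside a footprint of radius `0.35 * size_mm`), near-vertical
#' side walls with a mild mid-height bulge on the two opposite cheek/tongue
#' sides (labelled `buccal` / `lingual`) which produces genuine undercuts,
#' and a base ring labelled `other`. Small seeded shape variation (cusp
#' amplitude/position jitter plus a low-frequency surface ripple) makes each
#' crown individual, which is what the feature-based coarse alignment keys
#' on. Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param size_mm nominal crown diameter (mm).
#' @param cusp_count number of occlusal cusps.
#' @param resolution list with `n_radial`, `n_angular`, `n_wall` grid sizes.
#' @return a [surface_scan()] (connected manifold shell with boundary).
#' @export
generate_crown <- function(seed = 1L, size_mm = 10, cusp_count = 4,
                           resolution = list(n_radial = 34, n_angular = 96,
                                             n_wall = 20)) {
  nr <- resolution$n_radial
  na <- resolution$n_angular
  nw <- resolution$n_wall
  r_top <- 0.42 * size_mm
  r_occ <- 0.35 * size_mm
  z_rim <- 0.6 * size_mm
  h_dome <- 0.05 * size_mm

  with_preserved_seed(seed, {
    cusp_r <- 0.55 * r_occ * runif(cusp_count, 0.9, 1.1)
    cusp_th <- (seq_len(cusp_count) - 0.5) * 2 * pi / cusp_count +
      runif(cusp_count, -0.1, 0.1)
    cusp_a <- 0.07 * size_mm * runif(cusp_count, 0.85, 1.15)
    cusp_s <- 0.08 * size_mm * runif(cusp_count, 0.9, 1.1)
    # low-frequency ripple (~25 um) so surfaces have distinctive features
    n_rip <- 6L
    rip_a <- rnorm(n_rip, 0, 0.025)
    rip_kx <- runif(n_rip, 0.2, 0.9)
    rip_ky <- runif(n_rip, 0.2, 0.9)
    rip_ph <- runif(n_rip, 0, 2 * pi)
  })
  ripple <- function(x, y) {
    z <- 0
    for (k in seq_len(6L)) {
      z <- z + rip_a[k] * sin(rip_kx[k] * x + rip_ky[k] * y + rip_ph[k])
    }
    z
  }
  top_height <- function(r, th) {
    x <- r * cos(th)
    y <- r * sin(th)
    z <- z_rim + h_dome * (1 - (r / r_top)^2)
    for (k in seq_along(cusp_a)) {
      cx <- cusp_r[k] * cos(cusp_th[k])
      cy <- cusp_r[k] * sin(cusp_th[k])
      z <- z + cusp_a[k] * exp(-((x - cx)^2 + (y - cy)^2) / (2 * cusp_s[k]^2))
    }
    z + ripple(x, y)
  }

  th <- (seq_len(na) - 1) * 2 * pi / na
  verts <- matrix(0, 1 + (nr + nw) * na, 3)
  verts[1, ] <- c(0, 0, top_height(0, 0))
  idx <- function(ring, j) 1L + (ring - 1L) * na + j  # ring >= 1
  # top disk rings
  for (k in seq_len(nr)) {
    r <- r_top * k / nr
    z <- top_height(r, th)
    verts[idx(k, seq_len(na)), ] <- cbind(r * cos(th), r * sin(th), z)
  }
  # wall rows (row w: from just below the rim down to the base)
  taper <- function(z) 0.88 + 0.12 * z / z_rim
  for (w in seq_len(nw)) {
    z <- z_rim * (1 - w / nw)
    bulge <- 1 + 0.12 * sin(th)^2 * sin(pi * (1 - z / z_rim))
    rho <- r_top * taper(z) * bulge +
      ripple(r_top * cos(th) * 0.8, r_top * sin(th) * 0.8 + z)
    verts[idx(nr + w, seq_len(na)), ] <- cbind(rho * cos(th), rho * sin(th), z)
  }

  # faces: centre fan + quad strips; wound counter-clockwise from outside
  jn <- c(seq_len(na - 1) + 1L, 1L)  # next angular index
  faces <- cbind(1L, idx(1, seq_len(na)), idx(1, jn))
  for (ring in seq_len(nr + nw - 1)) {
    a <- idx(ring, seq_len(na)); b <- idx(ring, jn)
    c_ <- idx(ring + 1, seq_len(na)); d <- idx(ring + 1, jn)
    faces <- rbind(faces, cbind(a, d, b), cbind(a, c_, d))
  }

  rr <- sqrt(verts[, 1]^2 + verts[, 2]^2)
  ring_of <- c(0L, rep(seq_len(nr + nw), each = na))
  labels <- rep("other", nrow(verts))
  on_top <- ring_of <= nr
  labels[on_top & rr <= r_occ] <- "occlusal"
  sth <- ifelse(rr > 0, verts[, 2] / rr, 0)
  side <- ring_of > nr | (on_top & rr > r_occ)
  labels[side & sth > 0.34] <- "buccal"
  labels[side & sth < -0.34] <- "lingual"
  labels[ring_of >= nr + nw - 1] <- "other"  # base ring

  surface_scan(verts, faces, labels,
               provenance = list(capture_model = "ideal",
                                 timepoint = "baseline", seed = seed))
}

# Deterministic in-plane frame for the occlusal region: origin at the
# occlusal centroid projected to the best-fit plane, u = projection of +x.
occlusal_frame <- function(scan) {
  occ <- scan$labels == "occlusal"
  if (!any(occ)) stop("scan has no occlusal vertices")
  pts <- scan$vertices[occ, , drop = FALSE]
  vn <- vertex_normals(scan)
  hint <- colMeans(vn[occ, , drop = FALSE])
  pl <- fit_plane(pts, normal_hint = hint)
  n <- pl$normal
  ex <- c(1, 0, 0)
  if (abs(sum(ex * n)) > 0.9) ex <- c(0, 1, 0)
  u <- ex - sum(ex * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  ctr <- colMeans(pts)
  origin <- ctr - (sum(n * ctr) - pl$offset) * n
  list(normal = n, u = u, v = v, origin = origin, plane = pl)
}

#' Apply known wear to the occlusal surface
#'
#' Displaces occlusal vertices along the negative occlusal-plane normal by
#' the summed lesion depth field evaluated in occlusal-plane coordinates;
#' all non-occlusal vertices are untouched (bitwise). Because wear is a
#' height field over the plane, the removed volume equals the analytic
#' integral of the depth field exactly, giving an uncontestable oracle for
#' the primary outcome.
#'
#' @param scan a [surface_scan()] with a nonempty occlusal region.
#' @param lesions a [lesion_config()]. All lesions must lie inside the
#'   occlusal footprint (centre + extent within the footprint radius) so the
#'   closed-form volume holds.
#' @param seed unused (wear is deterministic); kept for interface symmetry.
#' @return list with `scan` (worn copy, provenance timepoint = "followup")
#'   and `true_volume_mm3`.
#' @export
apply_wear <- function(scan, lesions, seed = NULL) {
  stopifnot(inherits(lesions, "lesion_config"))
  occ <- which(scan$labels == "occlusal")
  worn <- scan
  worn$provenance$timepoint <- "followup"
  if (length(lesions$lesions) == 0) {
    return(list(scan = worn, true_volume_mm3 = 0))
  }
  fr <- occlusal_frame(scan)
  rel <- sweep(scan$vertices[occ, , drop = FALSE], 2, fr$origin)
  uu <- as.vector(rel %*% fr$u)
  vv <- as.vector(rel %*% fr$v)
  r_fp <- max(sqrt(uu^2 + vv^2))

  depth <- numeric(length(occ))
  for (l in lesions$lesions) {
    if (sqrt(sum(l$center^2)) + lesion_extent(l) > r_fp + 1e-9) {
      stop("lesion extends beyond the occlusal footprint (radius ",
           format(r_fp, digits = 4), " mm)")
    }
    d <- sqrt((uu - l$center[1])^2 + (vv - l$center[2])^2)
    depth <- depth + lesion_depth(l, d)
  }
  # crown thickness guard: wear must not punch through toward the base
  hts <- as.vector(scan$vertices %*% fr$normal)
  clearance <- hts[occ] - min(hts)
  if (any(depth > 0.8 * clearance)) {
    stop("lesion deeper than local crown thickness")
  }
  worn$vertices[occ, ] <- scan$vertices[occ, , drop = FALSE] -
    outer(depth, fr$normal)
  list(scan = worn, true_volume_mm3 = lesions$true_volume_mm3)
}

#' Simulate a raster profilometer capture
#'
#' Samples the top-most surface height on a `step_um` raster (the smallest
#' positive depth seen from above, so undercut under-sides are invisible),
#' adds i.i.d. Gaussian height noise of SD `noise_sd_um`, and triangulates
#' the grid with [grid_to_scan()]. Region labels are transferred from the
#' nearest source vertex. Grid nodes whose vertical line misses the surface
#' become missing cells and are dropped, not interpolated.
#'
#' @param scan source [surface_scan()] (the "physical" object).
#' @param cfg a [scanner_config()] with `capture_model = "profilometer"`.
#' @return a [surface_scan()].
#' @export
simulate_profilometer <- function(scan, cfg) {
  stopifnot(inherits(cfg, "scanner_config"), cfg$capture_model == "profilometer")
  step <- cfg$step_um / UM_PER_MM
  v <- scan$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- seq(xr[1], xr[2], by = step)
  ys <- seq(yr[1], yr[2], by = step)
  g <- expand.grid(x = xs, y = ys)
  ztop <- max(v[, 3]) + 1
  bvh <- scan_bvh(scan)
  hit <- .bvh_line_hits(bvh, cbind(g$x, g$y, ztop),
                        matrix(c(0, 0, -1), nrow(g), 3, byrow = TRUE))
  z <- ztop - hit$t  # smallest |t| from above = top-most surface
  h <- matrix(z, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  if (cfg$noise_sd_um > 0) {
    noise <- with_preserved_seed(cfg$seed,
      matrix(rnorm(length(h), 0, cfg$noise_sd_um / UM_PER_MM),
             nrow(h), ncol(h)))
    h <- h + noise
  }
  out <- grid_to_scan(raster_grid(h, cfg$step_um, cfg$step_um,
                                  origin = c(xs[1], ys[1])))
  out$labels <- transfer_labels(scan, out$vertices, bvh = bvh)
  out$provenance <- list(capture_model = "profilometer",
                         timepoint = scan$provenance$timepoint %||% NA,
                         seed = cfg$seed)
  out
}

#' Simulate an intraoral-scanner capture
#'
#' Emulates the loss of effective resolution and the interpolation /
#' averaging of hand-held intraoral scanners: a vertex-clustering remesh to
#' roughly `remesh_edge_mm` (coarser than the profilometer raster), followed
#' by uniform-weight Laplacian smoothing and small isotropic Gaussian vertex
#' noise. Undercut geometry is retained — unlike the profilometer path.
#' Labels are transferred from the nearest source vertex.
#'
#' @param scan source [surface_scan()].
#' @param cfg a [scanner_config()] with `capture_model = "intraoral"`.
#' @return a [surface_scan()].
#' @export
simulate_intraoral <- function(scan, cfg) {
  stopifnot(inherits(cfg, "scanner_config"), cfg$capture_model == "intraoral")
  out <- scan
  if (cfg$remesh_edge_mm > 0) out <- cluster_remesh(out, cfg$remesh_edge_mm)
  if (cfg$smoothing_iterations > 0 && cfg$smoothing_lambda > 0) {
    out <- laplacian_smooth(out, cfg$smoothing_iterations, cfg$smoothing_lambda)
  }
  if (cfg$noise_sd_um > 0) {
    out$vertices <- out$vertices + with_preserved_seed(cfg$seed,
      matrix(rnorm(length(out$vertices), 0, cfg$noise_sd_um / UM_PER_MM),
             nrow(out$vertices), 3))
  }
  out$labels <- transfer_labels(scan, out$vertices)
  out$provenance <- list(capture_model = "intraoral",
                         timepoint = scan$provenance$timepoint %||% NA,
                         seed = cfg$seed)
  out
}

#' @rdname simulate_profilometer
#' @export
simulate_scan <- function(scan, cfg) {
  switch(cfg$capture_model,
    profilometer = simulate_profilometer(scan, cfg),
    intraoral = simulate_intraoral(scan, cfg),
    ideal = {
      out <- scan
      out$provenance$capture_model <- "ideal"
      out
    }
  )
}

# Rossignac-Borrel vertex clustering: snap vertices to an edge_mm grid,
# merge clusters at their centroids, drop collapsed/duplicate faces.
# The grid lives in the scan's own principal-axes frame (deterministic sign
# convention) so the capture artifact travels with the object rather than
# depending on the arbitrary pose the scan arrived in.
cluster_remesh <- function(scan, edge_mm) {
  v0 <- scan$vertices
  ctr <- colMeans(v0)
  E <- eigen(stats::cov(v0), symmetric = TRUE)$vectors
  for (k in 1:3) {
    if (E[which.max(abs(E[, k])), k] < 0) E[, k] <- -E[, k]
  }
  if (det(E) < 0) E[, 3] <- -E[, 3]
  v <- sweep(v0, 2, ctr) %*% E
  cell <- cbind(floor(v[, 1] / edge_mm), floor(v[, 2] / edge_mm),
                floor(v[, 3] / edge_mm))
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  cid <- match(key, unique(key))
  nc <- max(cid)
  cnt <- tabulate(cid, nc)
  newv <- cbind(tapply2(v[, 1], cid, nc) / cnt,
                tapply2(v[, 2], cid, nc) / cnt,
                tapply2(v[, 3], cid, nc) / cnt)
  f <- matrix(cid[scan$faces], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  f <- f[!degen, , drop = FALSE]
  fkey <- paste(pmin(f[, 1], pmin(f[, 2], f[, 3])),
                f[, 1] + f[, 2] + f[, 3],
                pmax(f[, 1], pmax(f[, 2], f[, 3])))
  f <- f[!duplicated(fkey), , drop = FALSE]
  lab <- scan$labels[match(seq_len(nc), cid)]  # representative label
  newv <- sweep(newv %*% t(E), 2, -ctr)  # back to world frame
  surface_scan(newv, f, lab, scan$provenance)
}

#' Apply shallow smooth-surface wear to the reference walls
#'
#' Erosive patients lose material on buccal/lingual smooth surfaces too, not
#' only occlusally — and changed reference areas are precisely what breaks
#' the assumption behind unconstrained best-fit alignment. This displaces
#' buccal/lingual vertices inward along their vertex normals by Gaussian
#' depth patches centred on chosen wall vertices. The occlusal surface and
#' its ground-truth volume are untouched.
#'
#' @param scan a [surface_scan()].
#' @param centers matrix (k x 3) of patch centres (mm), typically wall
#'   vertex positions.
#' @param depths_mm length-k peak depths (mm, e.g. 0.02-0.06).
#' @param sigma_mm patch width (mm).
#' @return the worn scan.
#' @export
apply_reference_wear <- function(scan, centers, depths_mm, sigma_mm = 1) {
  centers <- matrix(centers, ncol = 3)
  stopifnot(nrow(centers) == length(depths_mm), all(depths_mm >= 0))
  wall <- which(scan$labels %in% c("buccal", "lingual"))
  if (length(wall) == 0 || nrow(centers) == 0) return(scan)
  vn <- vertex_normals(scan)
  depth <- numeric(length(wall))
  for (k in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(scan$vertices[wall, , drop = FALSE], 2,
                        centers[k, ])^2)
    depth <- depth + depths_mm[k] * exp(-d2 / (2 * sigma_mm^2))
  }
  scan$vertices[wall, ] <- scan$vertices[wall, , drop = FALSE] -
    vn[wall, , drop = FALSE] * depth
  scan
}

# 0/1 vertex adjacency from face connectivity (deduplicated)
vertex_adjacency <- function(faces, n) {
  i <- c(faces[, 1], faces[, 2], faces[, 2], faces[, 3], faces[, 1], faces[, 3])
  j <- c(faces[, 2], faces[, 1], faces[, 3], faces[, 2], faces[, 3], faces[, 1])
  key <- (as.numeric(i) - 1) * n + as.numeric(j)
  keep <- !duplicated(key)
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1, dims = c(n, n))
}

# uniform-weight Laplacian smoothing: v <- v + lambda * (mean(nbrs) - v)
laplacian_smooth <- function(scan, iterations, lambda) {
  n <- nrow(scan$vertices)
  A <- vertex_adjacency(scan$faces, n)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  v <- scan$vertices
  for (it in seq_len(iterations)) {
    mean_nbr <- as.matrix(A %*% v) / deg
    v <- v + lambda * (mean_nbr - v)
  }
  scan$vertices <- v
  scan
}

# label of the nearest source vertex (via closest surface point, then the
# nearest corner of the hit face)
transfer_labels <- function(source, points, bvh = NULL) {
  if (is.null(bvh)) bvh <- scan_bvh(source)
  cp <- .bvh_closest(bvh, points)
  f <- source$faces[cp$face, , drop = FALSE]
  d1 <- rowSums((source$vertices[f[, 1], , drop = FALSE] - points)^2)
  d2 <- rowSums((source$vertices[f[, 2], , drop = FALSE] - points)^2)
  d3 <- rowSums((source$vertices[f[, 3], , drop = FALSE] - points)^2)
  pick <- max.col(-cbind(d1, d2, d3), ties.method = "first")
  source$labels[f[cbind(seq_len(nrow(f)), pick)]]
}

#' Displace a scan by a random rigid motion
#'
#' Draws a uniform random rotation axis, an angle uniform on
#' `[0, max_angle_deg]` and translation components uniform on
#' `[-max_translation_mm, max_translation_mm]`, applies the motion and
#' returns it, emulating the arbitrary pose difference between visits.
#'
#' @param scan a [surface_scan()].
#' @param max_angle_deg,max_translation_mm perturbation bounds (>= 0).
#' @param seed integer seed (deterministic given seed).
#' @return list with `scan` (displaced) and `transform` (the applied
#'   [rigid_transform()]; its inverse re-aligns the scan).
#' @export
perturb_pose <- function(scan, max_angle_deg = 5, max_translation_mm = 2,
                         seed = 1L) {
  stopifnot(max_angle_deg >= 0, max_translation_mm >= 0)
  tr <- with_preserved_seed(seed, {
    ax <- rnorm(3)
    if (sum(ax^2) == 0) ax <- c(0, 0, 1)
    ang <- runif(1, 0, max_angle_deg)
    tt <- runif(3, -max_translation_mm, max_translation_mm)
    rigid_transform(rotation_about_axis(ax, ang), tt)
  })
  list(scan = transform_scan(tr, scan), transform = tr)
}

#' Generate a synthetic cohort of baseline/follow-up scan pairs
#'
#' For each surface: an individual crown is generated, worn with 2-3
#' occlusal lesions (log-normal amplitudes sized so the typical per-surface
#' true volume is of order 1 mm^3, the order of magnitude reported for
#' 3-year clinical wear), the worn crown is pose-perturbed (<= 5 deg,
#' <= 2 mm by default) and both timepoints are rendered under each
#' requested capture model. Fully deterministic given `seed`.
#'
#' @param n_surfaces number of synthetic tooth surfaces.
#' @param seed master seed; all per-surface seeds derive from it.
#' @param capture_models character vector among
#'   `c("profilometer", "intraoral", "ideal")`.
#' @param lesion_count_range integer range for the number of lesions.
#' @param amplitude_meanlog,amplitude_sdlog log-normal peak-depth (mm)
#'   parameters.
#' @param sigma_meanlog,sigma_sdlog log-normal lesion-width (mm) parameters.
#' @param max_angle_deg,max_translation_mm pose perturbation bounds.
#' @param reference_wear also apply shallow smooth-surface wear to the
#'   follow-up's buccal/lingual reference walls (see
#'   [apply_reference_wear()]); changed reference areas are the clinically
#'   documented failure mode of unconstrained best-fit alignment.
#' @param ref_wear_prob probability each wall side carries a lesion.
#' @param ref_depth_meanlog,ref_depth_sdlog log-normal peak depth (mm) of
#'   the wall lesions (median 35 um by default).
#' @param ref_sigma_mm wall lesion patch width.
#' @param scanner_overrides named list of [scanner_config()] objects to use
#'   instead of the defaults (names = capture models).
#' @return list of class `wear_cohort`: `bundles` (per surface: ideal pair,
#'   captured scans per model/timepoint, truth) and `ground_truth`
#'   (data.frame with `surface_id`, `true_volume_mm3`, the applied transform
#'   flattened row-major into `t11..t34`, and seeds).
#' @export
generate_cohort <- function(n_surfaces = 30, seed = 1L,
                            capture_models = c("profilometer", "intraoral"),
                            lesion_count_range = c(2L, 3L),
                            amplitude_meanlog = log(0.25), amplitude_sdlog = 0.5,
                            sigma_meanlog = log(0.5), sigma_sdlog = 0.25,
                            max_angle_deg = 5, max_translation_mm = 2,
                            reference_wear = TRUE,
                            ref_wear_prob = 0.7,
                            ref_depth_meanlog = log(0.035),
                            ref_depth_sdlog = 0.5,
                            ref_sigma_mm = 1.0,
                            scanner_overrides = list()) {
  stopifnot(n_surfaces >= 1)
  bundles <- vector("list", n_surfaces)
  gt <- vector("list", n_surfaces)
  for (i in seq_len(n_surfaces)) {
    s_crown <- derive_seed(seed, i * 11 + 1)
    s_lesion <- derive_seed(seed, i * 11 + 2)
    s_pose <- derive_seed(seed, i * 11 + 3)
    crown <- generate_crown(seed = s_crown)

    lesions <- with_preserved_seed(s_lesion, {
      k <- sample(seq(lesion_count_range[1], lesion_count_range[2]), 1)
      ls <- vector("list", k)
      for (j in seq_len(k)) {
        a <- rlnorm(1, amplitude_meanlog, amplitude_sdlog)
        sg <- min(rlnorm(1, sigma_meanlog, sigma_sdlog), 0.9)
        a <- min(a, 0.8)  # stay well above the crown floor
        rmax <- max(0.1, 3.5 - 3 * sg - 0.05)
        rc <- rmax * sqrt(runif(1))
        thc <- runif(1, 0, 2 * pi)
        ls[[j]] <- lesion_gaussian(rc * c(cos(thc), sin(thc)), a, sg)
      }
      lesion_config(ls)
    })
    worn <- apply_wear(crown, lesions)
    followup_ideal <- worn$scan
    if (reference_wear) {
      s_ref <- derive_seed(seed, i * 11 + 4)
      followup_ideal <- with_preserved_seed(s_ref, {
        centers <- NULL
        depths <- numeric(0)
        for (side in c("buccal", "lingual")) {
          if (runif(1) > ref_wear_prob) next
          cand <- which(crown$labels == side)
          z <- crown$vertices[cand, 3]
          # smooth-surface lesions sit in the occlusal third of the wall
          upper <- cand[z >= quantile(z, 2 / 3)]
          ctr <- crown$vertices[upper[sample.int(length(upper), 1)], ]
          centers <- rbind(centers, ctr)
          depths <- c(depths, min(rlnorm(1, ref_depth_meanlog,
                                         ref_depth_sdlog), 0.12))
        }
        if (length(depths) == 0) followup_ideal else
          apply_reference_wear(followup_ideal, centers, depths, ref_sigma_mm)
      })
    }
    pp <- perturb_pose(followup_ideal, max_angle_deg, max_translation_mm,
                       seed = s_pose)

    scans <- list()
    for (cm in capture_models) {
      cfg_b <- scanner_overrides[[cm]] %||% scanner_config(cm)
      cfg_b$seed <- derive_seed(seed, i * 101 + match(cm, capture_models) * 2)
      cfg_f <- cfg_b
      cfg_f$seed <- derive_seed(seed, i * 101 + match(cm, capture_models) * 2 + 1)
      scans[[cm]] <- list(
        baseline = simulate_scan(crown, cfg_b),
        followup = simulate_scan(pp$scan, cfg_f)
      )
      scans[[cm]]$baseline$provenance$timepoint <- "baseline"
      scans[[cm]]$followup$provenance$timepoint <- "followup"
    }

    bundles[[i]] <- list(
      surface_id = sprintf("S%03d", i),
      ideal_baseline = crown,
      ideal_followup = followup_ideal,
      scans = scans,
      lesions = lesions,
      true_volume_mm3 = worn$true_volume_mm3,
      true_transform = pp$transform,
      seeds = c(crown = s_crown, lesion = s_lesion, pose = s_pose)
    )
    tr <- unclass(pp$transform)[1:3, ]
    gt[[i]] <- data.frame(
      surface_id = sprintf("S%03d", i),
      true_volume_mm3 = worn$true_volume_mm3,
      matrix(as.vector(t(tr)), nrow = 1,
             dimnames = list(NULL, paste0("t", rep(1:3, each = 4), 1:4))),
      seed_crown = s_crown, seed_lesion = s_lesion, seed_pose = s_pose
    )
  }
  structure(list(bundles = bundles, ground_truth = do.call(rbind, gt),
                 seed = seed),
            class = "wear_cohort")
}

#' @export
print.wear_cohort <- function(x, ...) {
  cat("wear_cohort:", length(x$bundles), "surfaces, capture models:",
      paste(names(x$bundles[[1]]$scans), collapse = ", "), "\n")
  invisible(x)
}
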