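#' Alignment configuration
#'
#' Parameter bundle for the two alignment strategies. The defaults encode
#' the published protocols: the best-fit strategy samples 1000 then 5000
#' points on the reference surfaces with no outlier rejection; the
#' feature-initialised strategy trims correspondences to reference areas
#' within 25 um of each other, re-evaluated every iteration.
#'
#' @param strategy `"bestfit"` or `"feature_trimmed"`.
#' @param coarse_sample_n,fine_sample_n sample sizes for the two ICP stages.
#' @param inlier_threshold_um trimming band (feature_trimmed only).
#' @param max_iterations ICP iteration cap.
#' @param convergence_tol_um stop when the inlier RMS improves by less than
#'   this (default 0.1 um, below the scanner noise floor).
#' @param metric `"point_to_plane"` (default) or `"point_to_point"`.
#' @param seed RNG seed for sampling and RANSAC.
#' @return object of class `alignment_config`.
#' @export
alignment_config <- function(strategy = c("bestfit", "feature_trimmed"),
                             coarse_sample_n = 1000,
                             fine_sample_n = 5000,
                             inlier_threshold_um = 25,
                             max_iterations = 100,
                             convergence_tol_um = 0.1,
                             metric = c("point_to_plane", "point_to_point"),
                             seed = 1L) {
  strategy <- match.arg(strategy)
  metric <- match.arg(metric)
  stopifnot(coarse_sample_n > 0, fine_sample_n > 0, inlier_threshold_um > 0,
            max_iterations >= 1, convergence_tol_um > 0)
  structure(list(strategy = strategy, coarse_sample_n = coarse_sample_n,
                 fine_sample_n = fine_sample_n,
                 inlier_threshold_um = inlier_threshold_um,
                 max_iterations = max_iterations,
                 convergence_tol_um = convergence_tol_um,
                 metric = metric, seed = as.integer(seed)),
            class = "alignment_config")
}

#' Area-uniform random surface sampling
#'
#' Draws faces with probability proportional to area, then a uniform
#' barycentric point within each face. Deterministic given `seed`.
#'
#' @param scan a [surface_scan()].
#' @param n number of points (>= 3).
#' @param seed integer seed.
#' @return list with `points` (n x 3, mm), `normals` (face normals at the
#'   samples) and `face` (source face index).
#' @export
sample_surface_points <- function(scan, n, seed = 1L) {
  stopifnot(n >= 3)
  if (nrow(scan$faces) == 0) stop("cannot sample an empty mesh")
  a <- face_areas(scan)
  fn <- face_normals(scan)
  with_preserved_seed(seed, {
    fidx <- sample.int(length(a), n, replace = TRUE, prob = a)
    r1 <- runif(n)
    r2 <- runif(n)
    s <- sqrt(r1)
    w1 <- 1 - s
    w2 <- s * (1 - r2)
    w3 <- s * r2
    f <- scan$faces[fidx, , drop = FALSE]
    pts <- scan$vertices[f[, 1], , drop = FALSE] * w1 +
      scan$vertices[f[, 2], , drop = FALSE] * w2 +
      scan$vertices[f[, 3], , drop = FALSE] * w3
    list(points = pts, normals = fn[fidx, , drop = FALSE], face = fidx)
  })
}

#' Iterative closest point alignment
#'
#' Iterates closest-point correspondence, optional distance trimming, rigid
#' solve and update until the inlier RMS improves by less than
#' `convergence_tol_um` or `max_iterations` is reached. The rigid solve is
#' the closed-form SVD (Kabsch) for `point_to_point` — whose objective is
#' monotone non-increasing when untrimmed — or a linearised least squares
#' with re-orthonormalisation for `point_to_plane`. Reflections from the
#' SVD are corrected by a sign flip; fewer than 3 inliers after trimming is
#' a degenerate-alignment error.
#'
#' @param fixed the fixed [surface_scan()] (or a prebuilt tree via `bvh`).
#' @param moving_points n x 3 matrix of points to align to `fixed`.
#' @param cfg an [alignment_config()].
#' @param init initial [rigid_transform()] (default identity).
#' @param trim apply the `inlier_threshold_um` band each iteration.
#' @param bvh optional prebuilt [scan_bvh()] of `fixed`.
#' @return object of class `alignment_report`: `transform` (maps moving into
#'   the fixed frame), `iterations`, `rms_um` (inlier RMS), `inlier_fraction`,
#'   `trace` (per-iteration RMS, um), `converged`.
#' @export
icp <- function(fixed, moving_points, cfg = alignment_config(),
                init = rigid_transform(), trim = FALSE, bvh = NULL) {
  if (is.null(bvh)) bvh <- scan_bvh(fixed)
  fn <- face_normals(fixed)
  P <- as.matrix(moving_points)
  if (nrow(P) < 3) stop("icp needs at least 3 points")
  tr <- init
  thresh_mm <- cfg$inlier_threshold_um / UM_PER_MM
  tol_mm <- cfg$convergence_tol_um / UM_PER_MM
  trace <- numeric(0)
  prev_rms <- Inf
  inlier_fraction <- 1
  converged <- FALSE
  iterations <- 0

  for (it in seq_len(cfg$max_iterations)) {
    iterations <- it
    Q <- transform_points(tr, P)
    cp <- .bvh_closest(bvh, Q)
    d <- sqrt(cp$dist2)
    keep <- if (trim) d <= thresh_mm else rep(TRUE, length(d))
    if (sum(keep) < 3) {
      stop("degenerate alignment: fewer than 3 inliers within ",
           cfg$inlier_threshold_um, " um")
    }
    inlier_fraction <- mean(keep)
    rms <- sqrt(mean(d[keep]^2))
    trace <- c(trace, rms * UM_PER_MM)
    if (abs(prev_rms - rms) < tol_mm) {
      converged <- TRUE
      break
    }
    prev_rms <- rms

    A <- Q[keep, , drop = FALSE]
    B <- cp$point[keep, , drop = FALSE]
    delta <- if (cfg$metric == "point_to_point") {
      kabsch(A, B)
    } else {
      point_to_plane_step(A, B, fn[cp$face[keep], , drop = FALSE])
    }
    tr <- transform_compose(delta, tr)
  }

  structure(list(transform = tr, iterations = iterations,
                 rms_um = tail(trace, 1), inlier_fraction = inlier_fraction,
                 trace = trace, converged = converged,
                 metric = cfg$metric, trimmed = trim),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  cat("alignment_report:", x$iterations, "iterations, RMS",
      format(x$rms_um, digits = 4), "um, inliers",
      format(100 * x$inlier_fraction, digits = 4), "%",
      if (isTRUE(x$converged)) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}

# closed-form rigid solve mapping A onto B (Kabsch, reflection-safe)
kabsch <- function(A, B) {
  ca <- colMeans(A)
  cb <- colMeans(B)
  H <- crossprod(sweep(A, 2, ca), sweep(B, 2, cb))
  s <- svd(H)
  D <- diag(3)
  D[3, 3] <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% D %*% t(s$u)
  rigid_transform(R, cb - as.vector(R %*% ca))
}

# one linearised point-to-plane Gauss-Newton step mapping A toward B along
# normals N; returns a rigid transform
point_to_plane_step <- function(A, B, N) {
  r <- rowSums((A - B) * N)           # signed plane distances
  C <- cbind(
    A[, 2] * N[, 3] - A[, 3] * N[, 2],
    A[, 3] * N[, 1] - A[, 1] * N[, 3],
    A[, 1] * N[, 2] - A[, 2] * N[, 1],
    N
  )
  M <- crossprod(C)
  # tiny Tikhonov term guards rank deficiency (e.g. planar regions)
  x <- tryCatch(solve(M + 1e-12 * diag(6), -crossprod(C, r)),
                error = function(e) rep(0, 6))
  omega <- x[1:3]
  ang <- sqrt(sum(omega^2))
  R <- if (ang > 0) rotation_about_axis(omega, ang * 180 / pi) else diag(3)
  rigid_transform(orthonormalize_rotation(R), x[4:6])
}

# principal axes + centroid initial alignment (deterministic sign fix)
principal_axes_init <- function(fixed_pts, moving_pts) {
  cf <- colMeans(fixed_pts)
  cm <- colMeans(moving_pts)
  Ef <- eigen(stats::cov(fixed_pts), symmetric = TRUE)$vectors
  Em <- eigen(stats::cov(moving_pts), symmetric = TRUE)$vectors
  for (k in 1:3) {
    if (sum(Ef[, k] * Em[, k]) < 0) Em[, k] <- -Em[, k]
  }
  if (det(Ef) * det(Em) < 0) Em[, 3] <- -Em[, 3]
  R <- Ef %*% t(Em)
  R <- orthonormalize_rotation(R)
  rigid_transform(R, cf - as.vector(R %*% cm))
}

#' Feature-based coarse global alignment
#'
#' Keypoints are high-mean-curvature vertices (non-maximum suppressed);
#' descriptors are multi-scale histograms of the deviation between the
#' keypoint normal and neighbouring vertex normals; a RANSAC loop over
#' mutual descriptor matches estimates the rigid transform with the largest
#' consensus. If consensus falls below 10 matches (e.g. a featureless
#' sphere) the method falls back to principal axes + centroid with a
#' warning. Deterministic given `seed`.
#'
#' @param fixed,moving [surface_scan()] objects.
#' @param seed integer seed for RANSAC.
#' @param n_keypoints keypoints kept per mesh after suppression.
#' @param nms_radius_mm non-maximum suppression radius.
#' @param descriptor_radii_mm neighbourhood radii for the descriptor scales.
#' @param ransac_iterations,consensus_radius_mm RANSAC controls.
#' @return a [rigid_transform()] mapping `moving` into the `fixed` frame,
#'   with attribute `"fallback"` = TRUE when the principal-axes path was
#'   taken.
#' @export
feature_global_align <- function(fixed, moving, seed = 1L,
                                 n_keypoints = 120,
                                 nms_radius_mm = 0.5,
                                 descriptor_radii_mm = c(0.6, 1.2, 1.8),
                                 ransac_iterations = 600,
                                 consensus_radius_mm = 0.4) {
  kf <- keypoint_descriptors(fixed, n_keypoints, nms_radius_mm,
                             descriptor_radii_mm)
  km <- keypoint_descriptors(moving, n_keypoints, nms_radius_mm,
                             descriptor_radii_mm)
  fallback <- function(msg) {
    warning("feature_global_align: ", msg,
            "; falling back to principal axes + centroid")
    tr <- principal_axes_init(fixed$vertices, moving$vertices)
    attr(tr, "fallback") <- TRUE
    tr
  }
  if (nrow(kf$desc) < 3 || nrow(km$desc) < 3) {
    return(fallback("too few stable keypoints"))
  }

  # mutual nearest-descriptor matches
  D <- outer(rowSums(km$desc^2), rowSums(kf$desc^2), `+`) -
    2 * km$desc %*% t(kf$desc)
  m2f <- max.col(-D, ties.method = "first")
  f2m <- max.col(-t(D), ties.method = "first")
  mutual <- which(f2m[m2f] == seq_along(m2f))
  if (length(mutual) < 3) return(fallback("fewer than 3 descriptor matches"))
  mp <- km$points[mutual, , drop = FALSE]
  fp <- kf$points[m2f[mutual], , drop = FALSE]

  nmatch <- nrow(mp)
  best <- NULL
  best_count <- -1L
  with_preserved_seed(seed, {
    for (it in seq_len(ransac_iterations)) {
      pick <- sample.int(nmatch, 3)
      a <- mp[pick, , drop = FALSE]
      # skip near-collinear triples
      if (sqrt(sum(crossprod2(a[2, ] - a[1, ], a[3, ] - a[1, ])^2)) < 1e-4) next
      tr <- tryCatch(kabsch(a, fp[pick, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tr)) next
      resid <- sqrt(rowSums((transform_points(tr, mp) - fp)^2))
      cnt <- sum(resid < consensus_radius_mm)
      if (cnt > best_count) {
        best_count <- cnt
        best <- tr
      }
    }
  })
  if (best_count < 10) return(fallback("consensus below 10 matches"))
  resid <- sqrt(rowSums((transform_points(best, mp) - fp)^2))
  inl <- resid < consensus_radius_mm
  out <- kabsch(mp[inl, , drop = FALSE], fp[inl, , drop = FALSE])
  attr(out, "fallback") <- FALSE
  out
}

crossprod2 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

keypoint_descriptors <- function(scan, n_keypoints, nms_radius_mm, radii) {
  # dense capture meshes are decimated to ~0.15 mm for detection (keypoints
  # describe ~mm-scale anatomy, and this bounds the cost on raster scans),
  # then mildly smoothed so curvature reflects structure, not capture noise
  if (nrow(scan$vertices) > 8000) scan <- cluster_remesh(scan, 0.15)
  sm <- laplacian_smooth(scan, 4, 0.5)
  v <- sm$vertices
  n <- nrow(v)
  vn <- vertex_normals(sm)
  f <- sm$faces
  A <- vertex_adjacency(f, n)
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  mean_nbr <- as.matrix(A %*% v) / deg
  # umbrella mean-curvature proxy: normal component of the Laplacian
  curv <- abs(rowSums((mean_nbr - v) * vn))
  # suppress mesh-boundary vertices (one-sided umbrellas give spurious
  # curvature along raster silhouettes and the base rim)
  fe <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ekey <- pmin(fe[, 1], fe[, 2]) * (n + 1) + pmax(fe[, 1], fe[, 2])
  dup <- ekey %in% ekey[duplicated(ekey)]
  curv[unique(as.vector(fe[!dup, , drop = FALSE]))] <- 0

  ord <- order(-curv, seq_len(n))  # deterministic tie-break
  ord <- ord[seq_len(min(3000L, n))]
  ord <- ord[curv[ord] > 0]
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) >= n_keypoints) break
    if (length(chosen) == 0) {
      chosen <- i
      next
    }
    d2 <- rowSums(sweep(v[chosen, , drop = FALSE], 2, v[i, ])^2)
    if (min(d2) > nms_radius_mm^2) chosen <- c(chosen, i)
  }
  if (length(chosen) < 3) {
    return(list(points = v[chosen, , drop = FALSE],
                desc = matrix(0, length(chosen), 0)))
  }

  nbins <- 8
  desc <- matrix(0, length(chosen), nbins * length(radii))
  d2all <- outer_dist2(v[chosen, , drop = FALSE], v)
  for (ri in seq_along(radii)) {
    r2 <- radii[ri]^2
    for (ki in seq_along(chosen)) {
      nb <- which(d2all[ki, ] <= r2)
      if (length(nb) < 5) next
      ang <- acos(pmin(1, pmax(-1, as.vector(vn[nb, , drop = FALSE] %*%
                                               vn[chosen[ki], ]))))
      h <- tabulate(pmin(nbins, floor(ang / pi * nbins) + 1L), nbins)
      desc[ki, (ri - 1) * nbins + seq_len(nbins)] <- h / sum(h)
    }
  }
  keep <- rowSums(abs(desc)) > 0
  list(points = v[chosen[keep], , drop = FALSE],
       desc = desc[keep, , drop = FALSE])
}

outer_dist2 <- function(A, B) {
  outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
}

REFERENCE_LABELS <- c("buccal", "lingual")

#' Best-fit style alignment (unconstrained two-stage ICP)
#'
#' Reproduces the engineering-software protocol: the occlusal surface is
#' deleted from both datasets, leaving the buccal and lingual reference
#' surfaces; an untrimmed ICP runs on 1000 sampled reference points, then is
#' refined with 5000 points; the composed transformation matrix is applied
#' to the complete displaced (follow-up) dataset. Initialisation is
#' principal axes + centroid of the reference submeshes.
#'
#' @param baseline,followup [surface_scan()] objects carrying buccal and
#'   lingual labels.
#' @param cfg an [alignment_config()] (strategy field is ignored here).
#' @return list with `report` (an `alignment_report`) and `aligned` (the
#'   complete follow-up scan moved into the baseline frame).
#' @export
align_bestfit_style <- function(baseline, followup,
                                cfg = alignment_config("bestfit")) {
  refB <- region_submesh(baseline, REFERENCE_LABELS)$scan
  refF <- region_submesh(followup, REFERENCE_LABELS)$scan
  bvh <- scan_bvh(refB)
  init <- principal_axes_init(refB$vertices, refF$vertices)

  s1 <- sample_surface_points(refF, cfg$coarse_sample_n, seed = cfg$seed)
  r1 <- icp(refB, s1$points, cfg, init = init, trim = FALSE, bvh = bvh)
  s2 <- sample_surface_points(refF, cfg$fine_sample_n,
                              seed = derive_seed(cfg$seed, 2))
  r2 <- icp(refB, s2$points, cfg, init = r1$transform, trim = FALSE, bvh = bvh)
  r2$strategy <- "bestfit"
  list(report = r2, aligned = transform_scan(r2$transform, followup))
}

#' Feature-initialised trimmed ICP alignment
#'
#' Reproduces the freeware protocol: an initial global alignment using
#' feature recognition on the full scans, then refined ICP on the buccal
#' and lingual reference surfaces in which only corresponding reference
#' areas within 25 um of each other are kept (re-evaluated every
#' iteration). A brief untrimmed warm-up stage (at `coarse_sample_n`)
#' bridges the gap between the coarse feature alignment and the narrow
#' trimming band. Fewer than 3 inliers at 25 um raises a
#' degenerate-alignment error rather than silently proceeding.
#'
#' @inheritParams align_bestfit_style
#' @return list with `report` (inlier fraction refers to the 25 um band on
#'   reference surfaces) and `aligned` (complete follow-up in the baseline
#'   frame).
#' @export
align_feature_trimmed_style <- function(baseline, followup,
                                        cfg = alignment_config("feature_trimmed")) {
  coarse <- feature_global_align(baseline, followup, seed = cfg$seed)
  refB <- region_submesh(baseline, REFERENCE_LABELS)$scan
  refF <- region_submesh(followup, REFERENCE_LABELS)$scan
  bvh <- scan_bvh(refB)

  s1 <- sample_surface_points(refF, cfg$coarse_sample_n,
                              seed = derive_seed(cfg$seed, 3))
  warm <- icp(refB, s1$points, cfg, init = coarse, trim = FALSE, bvh = bvh)
  s2 <- sample_surface_points(refF, cfg$fine_sample_n,
                              seed = derive_seed(cfg$seed, 4))
  r2 <- icp(refB, s2$points, cfg, init = warm$transform, trim = TRUE, bvh = bvh)
  r2$strategy <- "feature_trimmed"
  r2$coarse_fallback <- isTRUE(attr(coarse, "fallback"))
  list(report = r2, aligned = transform_scan(r2$transform, followup))
}

#' Align a scan pair with a named strategy
#'
#' @param baseline,followup [surface_scan()] objects.
#' @param strategy `"bestfit"` or `"feature_trimmed"`.
#' @param cfg optional [alignment_config()].
#' @return see [align_bestfit_style()].
#' @export
align_pair <- function(baseline, followup,
                       strategy = c("bestfit", "feature_trimmed"),
                       cfg = NULL) {
  strategy <- match.arg(strategy)
  cfg <- cfg %||% alignment_config(strategy)
  switch(strategy,
    bestfit = align_bestfit_style(baseline, followup, cfg),
    feature_trimmed = align_feature_trimmed_style(baseline, followup, cfg)
  )
}
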