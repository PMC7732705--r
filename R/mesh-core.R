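#' Labelled triangle mesh of one tooth at one timepoint
#'
#' The central data structure: a triangle shell (2-manifold with boundary,
#' not a closed solid) with per-vertex region labels. All coordinates are in
#' mm; metric outputs are converted to um / mm^3 only at the reporting layer.
#'
#' Region labels live on vertices; a face belongs to a region iff all three
#' of its vertices do, which makes submesh extraction unambiguous.
#'
#' @param vertices n x 3 numeric matrix of coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param labels character vector of length n with values in
#'   `c("occlusal", "buccal", "lingual", "other")`; defaults to `"other"`.
#' @param provenance list with optional entries `capture_model`
#'   (`"profilometer"`, `"intraoral"` or `"ideal"`), `timepoint`
#'   (`"baseline"` or `"followup"`) and `seed`.
#' @return An object of class `surface_scan`.
#' @examples
#' sq <- surface_scan(
#'   vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
#'   faces = rbind(c(1, 2, 3), c(1, 3, 4))
#' )
#' face_areas(sq)
#' @export
surface_scan <- function(vertices, faces, labels = NULL, provenance = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3) stop("vertices must be an n x 3 matrix")
  if (nrow(faces) > 0 && ncol(faces) != 3) stop("faces must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  n <- nrow(vertices)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > n)) {
    stop("face index out of range")
  }
  if (is.null(labels)) labels <- rep("other", n)
  labels <- as.character(labels)
  if (length(labels) != n) {
    stop("region_labels length (", length(labels),
         ") must equal vertex count (", n, ")")
  }
  bad <- !labels %in% REGION_LEVELS
  if (any(bad)) stop("unknown region label: ", labels[which(bad)[1]])

  scan <- structure(
    list(vertices = vertices, faces = faces, labels = labels,
         provenance = provenance),
    class = "surface_scan"
  )
  # degenerate (zero-area) faces are dropped at construction
  if (nrow(faces) > 0) {
    a <- face_areas(scan)
    keep <- a > 1e-14
    if (!all(keep)) scan$faces <- scan$faces[keep, , drop = FALSE]
  }
  scan
}

REGION_LEVELS <- c("other", "occlusal", "buccal", "lingual")

#' @export
print.surface_scan <- function(x, ...) {
  cat("surface_scan:", nrow(x$vertices), "vertices,", nrow(x$faces), "faces\n")
  tb <- table(factor(x$labels, levels = REGION_LEVELS))
  cat("  regions:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  pv <- x$provenance
  if (length(pv)) {
    cat("  provenance:",
        paste(names(pv), vapply(pv, function(v) paste(format(v), collapse = ","),
                                ""), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Validate a surface scan
#'
#' Checks the structural invariants: valid face indices, finite coordinates,
#' label length, no degenerate faces, and (optionally) that the mesh is a
#' connected 2-manifold with boundary (every edge shared by at most two
#' faces, single connected component).
#'
#' @param scan a [surface_scan()].
#' @param manifold if `TRUE`, also check edge-manifoldness and connectivity.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_scan <- function(scan, manifold = FALSE) {
  stopifnot(inherits(scan, "surface_scan"))
  n <- nrow(scan$vertices)
  if (!all(is.finite(scan$vertices))) stop("non-finite vertex coordinates")
  if (length(scan$labels) != n) stop("label length mismatch")
  if (nrow(scan$faces) == 0) stop("scan has no faces")
  if (min(scan$faces) < 1 || max(scan$faces) > n) stop("face index out of range")
  if (any(face_areas(scan) <= 1e-14)) stop("degenerate face present")
  if (manifold) {
    e <- edge_table(scan)
    if (any(e$count > 2)) stop("non-manifold edge (shared by >2 faces)")
    if (n_components(scan) != 1) stop("mesh is not connected")
  }
  invisible(TRUE)
}

edge_table <- function(scan) {
  f <- scan$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tb <- table(key)
  list(count = as.integer(tb))
}

n_components <- function(scan) {
  # union-find over face-connected vertices
  n <- nrow(scan$vertices)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- scan$faces
  for (k in seq_len(nrow(f))) {
    a <- find(f[k, 1]); b <- find(f[k, 2]); c_ <- find(f[k, 3])
    parent[b] <- a
    parent[find(c_)] <- find(a)
  }
  used <- sort(unique(as.vector(f)))
  length(unique(vapply(used, find, 1L)))
}

#' Per-face geometry
#'
#' @param scan a [surface_scan()].
#' @return `face_areas`: face areas (mm^2). `face_normals`: m x 3 matrix of
#'   unit normals following the right-hand winding rule.
#' @export
face_areas <- function(scan) {
  cr <- face_cross(scan)
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(scan) {
  cr <- face_cross(scan)
  nrm <- sqrt(rowSums(cr^2))
  nrm[nrm == 0] <- 1
  cr / nrm
}

face_cross <- function(scan) {
  v <- scan$vertices
  f <- scan$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Area-weighted per-vertex unit normals
#'
#' Averages incident face normals weighted by face area, then normalizes.
#' Orientation follows the face winding; generator meshes are wound so
#' normals point outward (away from the crown interior). Isolated vertices
#' (no incident face) receive a zero normal.
#'
#' @param scan a [surface_scan()].
#' @return n x 3 matrix of unit normals (zero rows for isolated vertices).
#' @export
vertex_normals <- function(scan) {
  n <- nrow(scan$vertices)
  f <- scan$faces
  cr <- face_cross(scan)  # length = 2 * area, direction = face normal
  acc <- matrix(0, n, 3)
  for (k in 1:3) {
    for (d in 1:3) {
      acc[, d] <- acc[, d] + unname(tapply2(cr[, d], f[, k], n))
    }
  }
  nrm <- sqrt(rowSums(acc^2))
  out <- acc
  pos <- nrm > 0
  out[pos, ] <- acc[pos, , drop = FALSE] / nrm[pos]
  out
}

# fast grouped sum into a length-n vector
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

#' One-third (barycentric) vertex areas
#'
#' Each face contributes one third of its area to each of its vertices.
#' With `direction` given, face areas are first projected onto the plane
#' perpendicular to `direction` (i.e. scaled by |cos| of the angle between
#' the face normal and `direction`), which is the correct area measure when
#' integrating a depth field along that direction.
#'
#' @param scan a [surface_scan()].
#' @param direction optional unit 3-vector; see Details.
#' @return numeric vector of per-vertex areas (mm^2).
#' @export
vertex_areas <- function(scan, direction = NULL) {
  a <- face_areas(scan)
  if (!is.null(direction)) {
    fn <- face_normals(scan)
    a <- a * abs(as.vector(fn %*% direction))
  }
  n <- nrow(scan$vertices)
  f <- scan$faces
  out <- numeric(n)
  for (k in 1:3) out <- out + tapply2(a / 3, f[, k], n)
  out
}

#' Extract the submesh carrying a set of region labels
#'
#' Keeps exactly the faces whose three vertices all carry one of the
#' requested labels, mirroring the protocol step in which the occlusal
#' surface is deleted from the dataset, leaving the buccal and lingual
#' reference surfaces. The returned scan keeps only referenced vertices;
#' `index_map` maps its vertex indices back to the parent scan.
#'
#' @param scan a [surface_scan()].
#' @param labels nonempty character vector of region labels.
#' @return list with elements `scan` (the submesh) and `index_map`
#'   (integer vector, submesh vertex i == parent vertex `index_map[i]`).
#' @export
region_submesh <- function(scan, labels) {
  stopifnot(length(labels) >= 1)
  inset <- scan$labels %in% labels
  f <- scan$faces
  keep <- inset[f[, 1]] & inset[f[, 2]] & inset[f[, 3]]
  f <- f[keep, , drop = FALSE]
  if (nrow(f) == 0) {
    stop("region_submesh: no faces with all vertices in {",
         paste(labels, collapse = ", "), "}")
  }
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(scan$vertices))
  remap[used] <- seq_along(used)
  sub <- surface_scan(
    vertices = scan$vertices[used, , drop = FALSE],
    faces = matrix(remap[f], ncol = 3),
    labels = scan$labels[used],
    provenance = scan$provenance
  )
  list(scan = sub, index_map = used)
}

#' Total-least-squares plane fit
#'
#' Fits a plane minimizing orthogonal distances (smallest singular vector of
#' the centred point cloud). The normal sign can be pinned with
#' `normal_hint` (e.g. the mean vertex normal of a region) so "outward" is
#' well defined.
#'
#' @param points n x 3 matrix (mm), n >= 3, not collinear.
#' @param normal_hint optional 3-vector; the returned normal satisfies
#'   `sum(normal * normal_hint) >= 0`.
#' @return list of class `plane` with unit `normal` and `offset` such that
#'   points p on the plane satisfy `sum(normal * p) == offset` (mm).
#' @export
fit_plane <- function(points, normal_hint = NULL) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("fit_plane needs at least 3 points")
  ctr <- colMeans(points)
  s <- svd(sweep(points, 2, ctr), nu = 0)
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300)) {
    stop("fit_plane: points are collinear or coincident")
  }
  normal <- s$v[, 3]
  if (!is.null(normal_hint) && sum(normal * normal_hint) < 0) normal <- -normal
  structure(list(normal = normal, offset = sum(normal * ctr)), class = "plane")
}

#' Exact closest point on a triangle mesh
#'
#' Accelerated by a bounding-volume hierarchy; the result is identical to
#' brute force over all triangles (ties broken by lowest face index).
#'
#' @param scan a [surface_scan()].
#' @param query n x 3 matrix (or length-3 vector) of query points (mm).
#' @param bvh optional prebuilt tree from [scan_bvh()] (rebuilt otherwise).
#' @return list with `point` (n x 3 closest points), `dist2` (squared
#'   distances, mm^2) and `face` (1-based face index).
#' @export
closest_point <- function(scan, query, bvh = NULL) {
  if (nrow(scan$faces) == 0) stop("closest_point: empty mesh")
  query <- matrix(query, ncol = 3)
  if (is.null(bvh)) bvh <- scan_bvh(scan)
  .bvh_closest(bvh, query)
}

#' Nearest bidirectional ray-mesh intersection
#'
#' Intersects the infinite line `origin + t * direction` with the mesh and
#' returns the hit of smallest absolute `t`; the sign of `t` is positive
#' along `direction` and negative against it. A miss returns `NA`.
#'
#' @param scan a [surface_scan()].
#' @param origin length-3 origin or n x 3 matrix (mm).
#' @param direction unit direction (recycled to match origins).
#' @param bvh optional prebuilt tree from [scan_bvh()].
#' @return list with `t` (signed distance, mm, `NA` on miss) and `face`.
#' @export
ray_intersect <- function(scan, origin, direction, bvh = NULL) {
  origin <- matrix(origin, ncol = 3)
  direction <- matrix(direction, ncol = 3)
  if (nrow(direction) == 1 && nrow(origin) > 1) {
    direction <- direction[rep(1, nrow(origin)), , drop = FALSE]
  }
  nd <- sqrt(rowSums(direction^2))
  if (any(abs(nd - 1) > 1e-8)) stop("direction must be unit length")
  if (is.null(bvh)) bvh <- scan_bvh(scan)
  .bvh_line_hits(bvh, origin, direction)
}

#' @rdname closest_point
#' @export
scan_bvh <- function(scan) {
  .bvh_build(scan$vertices, scan$faces)
}

# distinct |t| hits of one line (shared-edge grazings collapse to one);
# diagnostics for undercuts
line_hit_count <- function(scan, origin, direction, bvh = NULL, tol = 1e-7) {
  if (is.null(bvh)) bvh <- scan_bvh(scan)
  h <- .bvh_all_line_hits(bvh, as.numeric(origin), as.numeric(direction))
  if (length(h$t) == 0) return(0L)
  ts <- sort(h$t)
  sum(c(TRUE, diff(ts) > tol))
}

#' Weld duplicate vertices
#'
#' Merges vertices closer than `tol` (used when reading STL, which stores
#' no vertex identity). Quantises coordinates onto a `tol` grid.
#'
#' @param scan a [surface_scan()].
#' @param tol weld tolerance in mm.
#' @return a [surface_scan()] with merged vertices.
#' @export
weld_vertices <- function(scan, tol = 1e-9) {
  v <- scan$vertices
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  newid <- match(key, key[first])  # already the new (deduplicated) index
  keepv <- which(first)
  f <- matrix(newid[scan$faces], ncol = 3)
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  surface_scan(v[keepv, , drop = FALSE], f[!degen, , drop = FALSE],
               scan$labels[keepv], scan$provenance)
}
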