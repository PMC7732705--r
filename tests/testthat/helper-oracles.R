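# Independent pure-R oracles. These deliberately avoid the package's C++
# query path so the two routes can be checked against each other.

# closest point on one triangle to p (region-by-region barycentric clamp)
closest_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
    return(b + (c - b) * w)
  }
  den <- va + vb + vc
  a + ab * (vb / den) + ac * (vc / den)
}

# exhaustive closest point over all triangles
brute_closest <- function(scan, p) {
  best <- Inf; bp <- NULL; bf <- NA
  for (f in seq_len(nrow(scan$faces))) {
    tri <- scan$faces[f, ]
    q <- closest_on_triangle(p, scan$vertices[tri[1], ],
                             scan$vertices[tri[2], ], scan$vertices[tri[3], ])
    d2 <- sum((p - q)^2)
    if (d2 < best - 1e-15) {
      best <- d2; bp <- q; bf <- f
    }
  }
  list(point = bp, dist2 = best, face = bf)
}

# exhaustive bidirectional Moller-Trumbore; smallest |t|
brute_line_hit <- function(scan, origin, dir) {
  best_abs <- Inf; best_t <- NA; best_f <- NA
  for (f in seq_len(nrow(scan$faces))) {
    tri <- scan$faces[f, ]
    a <- scan$vertices[tri[1], ]; b <- scan$vertices[tri[2], ]
    cc <- scan$vertices[tri[3], ]
    e1 <- b - a; e2 <- cc - a
    pv <- c(dir[2] * e2[3] - dir[3] * e2[2],
            dir[3] * e2[1] - dir[1] * e2[3],
            dir[1] * e2[2] - dir[2] * e2[1])
    det <- sum(e1 * pv)
    if (abs(det) < 1e-12) next
    tv <- origin - a
    u <- sum(tv * pv) / det
    if (u < -1e-12 || u > 1 + 1e-12) next
    qv <- c(tv[2] * e1[3] - tv[3] * e1[2],
            tv[3] * e1[1] - tv[1] * e1[3],
            tv[1] * e1[2] - tv[2] * e1[1])
    v <- sum(dir * qv) / det
    if (v < -1e-12 || u + v > 1 + 1e-12) next
    t <- sum(e2 * qv) / det
    if (abs(t) < best_abs) {
      best_abs <- abs(t); best_t <- t; best_f <- f
    }
  }
  list(t = best_t, face = best_f)
}

# exact Wilcoxon two-sided p by explicit 2^n enumeration of sign vectors
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- 2^n
  count <- 0
  for (mask in 0:(total - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    wp <- sum(r[signs])
    wm <- sum(r[!signs])
    if (min(wp, wm) <= w_obs) count <- count + 1
  }
  count / total
}

# small fixtures -------------------------------------------------------------

two_triangle_square <- function(z = 0) {
  surface_scan(
    vertices = rbind(c(0, 0, z), c(1, 0, z), c(1, 1, z), c(0, 1, z)),
    faces = rbind(c(1, 2, 3), c(1, 3, 4)),
    labels = c("occlusal", "occlusal", "buccal", "lingual")
  )
}

# flat triangulated patch on [0, w] x [0, w], n x n vertices, at height z
flat_patch <- function(n = 10, w = 5, z = 0, label = "occlusal") {
  g <- raster_grid(matrix(z, n, n), x_step = w / (n - 1) * 1000,
                   y_step = w / (n - 1) * 1000)
  s <- grid_to_scan(g)
  s$labels <- rep(label, nrow(s$vertices))
  s
}

# triangulated sphere via subdivided octahedron projection
sphere_mesh <- function(subdiv = 4, radius = 1) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  for (s in seq_len(subdiv)) {
    nf <- nrow(f)
    newf <- matrix(0L, nf * 4, 3)
    mid_env <- new.env()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid_env[[key]])) return(mid_env[[key]])
      m <- (v[i, ] + v[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_env[[key]] <- nrow(v)
      nrow(v)
    }
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- newf
  }
  surface_scan(v * radius, f)
}
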