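#' Read a surface scan from PLY, STL or OBJ
#'
#' PLY is the canonical lossless format: region labels travel as a per-vertex
#' `uchar` property `region` (0 = other, 1 = occlusal, 2 = buccal,
#' 3 = lingual). Both `ascii` and `binary_little_endian` PLY are read. STL
#' and OBJ carry no vertex attributes, so labels come from an optional
#' sidecar CSV with columns `vertex_index` (1-based) and `region`; STL
#' vertices are welded at 1e-9 mm before labelling (STL stores no vertex
#' identity). Unlabelled vertices get `"other"`.
#'
#' @param path file path.
#' @param format one of `"ply"`, `"stl"`, `"obj"`; guessed from the file
#'   extension when missing.
#' @param labels_path optional sidecar CSV path (`vertex_index,region`).
#' @return a [surface_scan()].
#' @export
read_scan <- function(path, format = NULL, labels_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% tolower(tools::file_ext(path))
  scan <- switch(format,
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path),
    stop("unsupported scan format: ", format)
  )
  if (!is.null(labels_path)) {
    tb <- read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("vertex_index", "region") %in% names(tb))) {
      stop("label sidecar needs columns vertex_index,region")
    }
    if (nrow(tb) != nrow(scan$vertices)) {
      stop("label sidecar has ", nrow(tb), " rows but scan has ",
           nrow(scan$vertices), " vertices")
    }
    lab <- rep("other", nrow(scan$vertices))
    lab[tb$vertex_index] <- tb$region
    scan$labels <- lab
    scan <- surface_scan(scan$vertices, scan$faces, lab, scan$provenance)
  }
  scan
}

#' Write a surface scan
#'
#' @param scan a [surface_scan()].
#' @param path output file path.
#' @param format `"ply"` (labels embedded), `"stl"` or `"obj"` (labels go to
#'   a `<path>.labels.csv` sidecar when `sidecar = TRUE`).
#' @param binary write binary little-endian PLY instead of ascii.
#' @param sidecar write the label sidecar for STL/OBJ.
#' @return the path, invisibly.
#' @export
write_scan <- function(scan, path, format = NULL, binary = FALSE,
                       sidecar = TRUE) {
  stopifnot(inherits(scan, "surface_scan"))
  format <- format %||% tolower(tools::file_ext(path))
  switch(format,
    ply = write_ply(scan, path, binary = binary),
    stl = write_stl(scan, path),
    obj = write_obj(scan, path),
    stop("unsupported scan format: ", format)
  )
  if (format %in% c("stl", "obj") && sidecar) {
    write.csv(
      data.frame(vertex_index = seq_len(nrow(scan$vertices)),
                 region = scan$labels),
      paste0(path, ".labels.csv"), row.names = FALSE, quote = FALSE
    )
  }
  invisible(path)
}

REGION_CODES <- c(other = 0L, occlusal = 1L, buccal = 2L, lingual = 3L)

# ---- PLY ----

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("PLY: unexpected end of header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)
  fmt <- strsplit(trimws(fmt_line[1]), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }

  # parse element/property declarations in order
  elems <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list") {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[5], type = tok[4], list = TRUE, count_type = tok[3])
      } else {
        cur$props[[length(cur$props) + 1]] <-
          list(name = tok[3], type = tok[2], list = FALSE)
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (!all(c("vertex", "face") %in% names(elems))) {
    stop("PLY must declare vertex and face elements")
  }

  if (fmt == "ascii") {
    body <- readLines(con)
    dat <- read_ply_ascii(body, elems)
  } else {
    dat <- read_ply_binary(con, elems)
  }
  v <- dat$vertex
  labels <- NULL
  if ("region" %in% colnames(v)) {
    code <- as.integer(v[, "region"])
    labels <- names(REGION_CODES)[match(code, REGION_CODES)]
    labels[is.na(labels)] <- "other"
  }
  surface_scan(v[, c("x", "y", "z"), drop = FALSE], dat$face + 1L, labels)
}

read_ply_ascii <- function(body, elems) {
  body <- body[nzchar(trimws(body))]
  pos <- 0L
  out <- list()
  for (el in elems) {
    lines <- body[pos + seq_len(el$count)]
    pos <- pos + el$count
    toks <- strsplit(trimws(lines), "\\s+")
    if (el$name == "face") {
      f <- t(vapply(toks, function(tk) as.integer(tk[2:4]), integer(3)))
      out$face <- f
    } else {
      nm <- vapply(el$props, `[[`, "", "name")
      m <- t(vapply(toks, function(tk) as.numeric(tk[seq_along(nm)]),
                    numeric(length(nm))))
      if (el$count == 1) m <- matrix(m, nrow = 1)
      colnames(m) <- nm
      out[[el$name]] <- m
    }
  }
  out
}

ply_type_info <- function(type) {
  switch(type,
    char = , int8 = list(what = integer(), size = 1, signed = TRUE),
    uchar = , uint8 = list(what = integer(), size = 1, signed = FALSE),
    short = , int16 = list(what = integer(), size = 2, signed = TRUE),
    ushort = , uint16 = list(what = integer(), size = 2, signed = FALSE),
    int = , int32 = list(what = integer(), size = 4, signed = TRUE),
    uint = , uint32 = list(what = integer(), size = 4, signed = TRUE),
    float = , float32 = list(what = numeric(), size = 4, signed = TRUE),
    double = , float64 = list(what = numeric(), size = 8, signed = TRUE),
    stop("unsupported PLY type: ", type)
  )
}

read_ply_scalar <- function(con, type) {
  ti <- ply_type_info(type)
  readBin(con, what = ti$what, n = 1, size = ti$size,
          signed = ti$signed, endian = "little")
}

read_ply_binary <- function(con, elems) {
  out <- list()
  for (el in elems) {
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      # element with a list property (faces): read row by row
      rows <- vector("list", el$count)
      for (i in seq_len(el$count)) {
        vals <- integer(0)
        for (p in el$props) {
          if (p$list) {
            cnt <- read_ply_scalar(con, p$count_type)
            item <- vapply(seq_len(cnt), function(j)
              as.integer(read_ply_scalar(con, p$type)), integer(1))
            if (cnt != 3) stop("PLY: only triangle faces are supported")
            vals <- c(vals, item)
          } else {
            read_ply_scalar(con, p$type)
          }
        }
        rows[[i]] <- vals
      }
      out[[el$name]] <- do.call(rbind, rows)
    } else {
      # fixed-width element: bulk read as raw, then decode columns
      sizes <- vapply(el$props, function(p) ply_type_info(p$type)$size, 1)
      stride <- sum(sizes)
      raw <- readBin(con, "raw", n = stride * el$count)
      m <- matrix(NA_real_, el$count, length(el$props))
      off <- 0
      for (j in seq_along(el$props)) {
        ti <- ply_type_info(el$props[[j]]$type)
        idx <- as.vector(outer(seq_len(ti$size), (seq_len(el$count) - 1) * stride
                               + off, `+`))
        col <- readBin(raw[idx], what = ti$what, n = el$count, size = ti$size,
                       signed = ti$signed, endian = "little")
        m[, j] <- as.numeric(col)
        off <- off + ti$size
      }
      colnames(m) <- vapply(el$props, `[[`, "", "name")
      out[[el$name]] <- m
    }
  }
  out
}

write_ply <- function(scan, path, binary = FALSE) {
  n <- nrow(scan$vertices)
  m <- nrow(scan$faces)
  code <- REGION_CODES[scan$labels]
  header <- c(
    "ply",
    if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
    "comment written by wearbench",
    paste("element vertex", n),
    "property double x", "property double y", "property double z",
    "property uchar region",
    paste("element face", m),
    "property list uchar int vertex_indices",
    "end_header"
  )
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    for (i in seq_len(n)) {
      writeBin(as.numeric(scan$vertices[i, ]), con, size = 8, endian = "little")
      writeBin(as.raw(code[i]), con)
    }
    for (i in seq_len(m)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(scan$faces[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    vtxt <- paste(format_coord(scan$vertices[, 1]),
                  format_coord(scan$vertices[, 2]),
                  format_coord(scan$vertices[, 3]), code)
    ftxt <- paste(3, scan$faces[, 1] - 1L, scan$faces[, 2] - 1L,
                  scan$faces[, 3] - 1L)
    writeLines(c(header, vtxt, ftxt), path)
  }
  invisible(path)
}

format_coord <- function(x) formatC(x, format = "g", digits = 17)

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path)
  vt <- lines[startsWith(lines, "v ")]
  ft <- lines[startsWith(lines, "f ")]
  v <- t(vapply(strsplit(trimws(vt), "\\s+"),
                function(tk) as.numeric(tk[2:4]), numeric(3)))
  f <- t(vapply(strsplit(trimws(ft), "\\s+"), function(tk) {
    idx <- vapply(tk[2:4], function(s) as.integer(strsplit(s, "/")[[1]][1]), 1L)
    idx
  }, integer(3)))
  surface_scan(v, f)
}

write_obj <- function(scan, path) {
  v <- scan$vertices
  lines <- c(
    paste("v", format_coord(v[, 1]), format_coord(v[, 2]), format_coord(v[, 3])),
    paste("f", scan$faces[, 1], scan$faces[, 2], scan$faces[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

# ---- STL (ascii) ----

read_stl <- function(path) {
  lines <- trimws(readLines(path))
  vl <- lines[startsWith(lines, "vertex")]
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    stop("STL parse failure: expected facet vertex triplets")
  }
  v <- t(vapply(strsplit(vl, "\\s+"), function(tk) as.numeric(tk[2:4]),
                numeric(3)))
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  weld_vertices(surface_scan(v, f), tol = 1e-9)
}

write_stl <- function(scan, path) {
  v <- scan$vertices
  f <- scan$faces
  fn <- face_normals(scan)
  out <- c("solid wearbench")
  blocks <- vapply(seq_len(nrow(f)), function(i) {
    paste0(
      "facet normal ", paste(format_coord(fn[i, ]), collapse = " "), "\n",
      "  outer loop\n",
      paste0("    vertex ", apply(v[f[i, ], , drop = FALSE], 1, function(p)
        paste(format_coord(p), collapse = " ")), collapse = "\n"), "\n",
      "  endloop\n",
      "endfacet"
    )
  }, "")
  writeLines(c(out, blocks, "endsolid wearbench"), path)
  invisible(path)
}
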