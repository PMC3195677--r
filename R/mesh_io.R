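#' Read a triangle surface mesh
#'
#' Reads STL (binary or ASCII, auto-detected) or Wavefront OBJ files into a
#' [triangle_mesh()]. Coordinates are assumed to be millimeters; no unit
#' conversion is applied. The mesh is cleaned on read: duplicate vertices
#' merged within 1e-6 mm (STL stores each triangle independently) and
#' zero-area faces dropped.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"stl"`, `"obj"`. `"auto"` decides by file
#'   extension, defaulting to STL.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("mesh file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "obj") "obj" else "stl"
  }
  switch(format, stl = read_stl(path), obj = read_obj(path))
}

# binary STL: 80-byte header, uint32 count, 50 bytes per facet
stl_is_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 80L)
  if (length(head) < 80L) return(FALSE)
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(n) == 1L && !is.na(n) && sz == 84 + 50 * as.numeric(n))
    return(TRUE)
  # fall back on the "solid" keyword heuristic
  !identical(rawToChar(head[1:5]), "solid")
}

read_stl <- function(path) {
  if (stl_is_binary(path)) {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", 80L)
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (is.na(n) || n < 0L)
      stop("unreadable binary STL: ", path, call. = FALSE)
    raw <- readBin(con, "raw", 50L * n)
    if (length(raw) < 50L * n)
      stop("truncated binary STL: ", path, call. = FALSE)
    # keep the 9 vertex floats of each 50-byte record (skip normal + attr)
    keep <- rep((seq_len(n) - 1L) * 50L, each = 36L) +
      rep(12L + seq_len(36L), times = n)
    flo <- readBin(raw[keep], "numeric", 9L * n, size = 4L,
                   endian = "little")
    verts <- matrix(flo, ncol = 3L, byrow = TRUE)
  } else {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("unreadable ASCII STL: ", path, call. = FALSE)
    toks <- strsplit(trimws(vl), "\\s+")
    verts <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (anyNA(verts))
      stop("unreadable ASCII STL: ", path, call. = FALSE)
  }
  nf <- nrow(verts) / 3L
  faces <- matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE)
  triangle_mesh(verts, faces)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vt <- strsplit(trimws(grep("^v\\s", lines, value = TRUE)), "\\s+")
  ft <- strsplit(trimws(grep("^f\\s", lines, value = TRUE)), "\\s+")
  if (length(vt) == 0L || length(ft) == 0L)
    stop("unreadable OBJ: ", path, call. = FALSE)
  verts <- t(vapply(vt, function(tk) as.numeric(tk[2:4]), numeric(3)))
  faces <- t(vapply(ft, function(tk) {
    as.integer(vapply(strsplit(tk[2:4], "/"), `[`, character(1), 1L))
  }, integer(3)))
  triangle_mesh(verts, faces)
}

#' Write a triangle mesh to STL
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param ascii write ASCII STL instead of binary. Coordinates are stored as
#'   32-bit floats in binary mode (round-trip accurate to about 1e-5 mm for
#'   coordinates below 100 mm).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- cc - a
  nx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  ny <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  nz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  nn <- pmax(sqrt(nx^2 + ny^2 + nz^2), .Machine$double.eps)
  nrm <- cbind(nx, ny, nz) / nn
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid trabl", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (p in list(a[i, ], b[i, ], cc[i, ]))
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           p[1], p[2], p[3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid trabl", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], cc[i, ])), con,
               size = 4L, endian = "little")
      writeBin(0L, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}
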