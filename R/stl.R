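#' Read and write STL surface meshes
#'
#' Reads binary or ASCII stereolithography (STL) files into a [fem_mesh],
#' merging coincident vertices (coordinates equal after rounding to 1e-6 mm)
#' so that watertight connectivity is recovered from the triangle soup.
#' `write_stl()` writes binary STL by default; pass `binary = FALSE` for the
#' ASCII dialect. Units are not stored in STL; the package convention is mm.
#'
#' @param path file path.
#' @param mesh a [fem_mesh].
#' @param binary write binary (default) or ASCII STL.
#' @return `read_stl()`: a `fem_mesh`. `write_stl()`: `path`, invisibly.
#' @export
read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", 80L)
  sz <- file.size(path)
  is_binary <- FALSE
  if (sz >= 84) {
    n_tri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (!is.na(n_tri) && n_tri > 0 && sz == 84 + 50 * as.numeric(n_tri)) {
      is_binary <- TRUE
    }
  }
  if (is_binary) {
    tri <- matrix(0, n_tri * 3L, 3L)
    for (k in seq_len(n_tri)) {
      vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
      readBin(con, "raw", 2L) # attribute byte count
      tri[3L * k - 2L, ] <- vals[4:6]
      tri[3L * k - 1L, ] <- vals[7:9]
      tri[3L * k, ] <- vals[10:12]
    }
  } else {
    close(con); on.exit()
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) {
      fc_abort("not a valid STL file (no vertex records)", "femcurve_input_error")
    }
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p) {
      as.numeric(p[2:4])
    }))
  }
  soup_to_mesh(tri)
}

# collapse a triangle soup (3 rows per face) into an indexed mesh
soup_to_mesh <- function(tri, digits = 6L) {
  key <- paste(round(tri[, 1], digits), round(tri[, 2], digits),
               round(tri[, 3], digits))
  idx <- match(key, unique(key))
  verts <- tri[!duplicated(key), , drop = FALSE]
  faces <- matrix(idx, ncol = 3L, byrow = TRUE)
  fem_mesh(verts, faces)
}

#' @rdname read_stl
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  stopifnot(inherits(mesh, "fem_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- charToRaw(sprintf("%-80s", "femcurve binary STL (mm)"))
    writeBin(hdr[1:80], con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (k in seq_len(nrow(f))) {
      writeBin(as.numeric(c(n[k, ], v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])),
               con, size = 4L, endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    lines <- character(7L * nrow(f) + 2L)
    lines[1] <- "solid femcurve"
    for (k in seq_len(nrow(f))) {
      i <- 7L * (k - 1L) + 1L
      lines[i + 1] <- sprintf("facet normal %.9g %.9g %.9g", n[k, 1], n[k, 2], n[k, 3])
      lines[i + 2] <- "  outer loop"
      lines[i + 3] <- sprintf("    vertex %.9g %.9g %.9g",
                              v[f[k, 1], 1], v[f[k, 1], 2], v[f[k, 1], 3])
      lines[i + 4] <- sprintf("    vertex %.9g %.9g %.9g",
                              v[f[k, 2], 1], v[f[k, 2], 2], v[f[k, 2], 3])
      lines[i + 5] <- sprintf("    vertex %.9g %.9g %.9g",
                              v[f[k, 3], 1], v[f[k, 3], 2], v[f[k, 3], 3])
      lines[i + 6] <- "  endloop"
      lines[i + 7] <- "endfacet"
    }
    lines[length(lines)] <- "endsolid femcurve"
    writeLines(lines, path)
  }
  invisible(path)
}
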