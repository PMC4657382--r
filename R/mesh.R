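#' Triangle meshes
#'
#' `fem_mesh()` wraps a triangulated surface as a vertex matrix (n x 3, mm)
#' plus a face index matrix (m x 3, 1-based, counter-clockwise seen from
#' outside). All geometric measurements in the package operate on watertight
#' meshes of this class.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `fem_mesh`.
#' @seealso [read_stl()], [write_stl()], [mesh_volume()], [is_watertight()]
#' @export
fem_mesh <- function(vertices, faces) {
  vertices <- unname(as.matrix(vertices))
  storage.mode(vertices) <- "double"
  faces <- unname(as.matrix(faces))
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L) {
    fc_abort("vertices and faces must both have 3 columns",
             "femcurve_input_error")
  }
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    fc_abort("face indices out of range", "femcurve_input_error")
  }
  structure(list(vertices = vertices, faces = faces), class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("<fem_mesh> %d vertices, %d faces, watertight: %s\n",
              nrow(x$vertices), nrow(x$faces), is_watertight(x)))
  invisible(x)
}

#' @export
apply_transform.fem_mesh <- function(transform, x) {
  fem_mesh(apply_transform.default(transform, x$vertices), x$faces)
}

#' Watertightness check
#'
#' A mesh is watertight when every edge is shared by exactly two faces with
#' opposite orientation (a closed, consistently wound 2-manifold), which is
#' required before enclosed volume, center of mass or inside/outside queries
#' are meaningful.
#'
#' @param mesh a [fem_mesh].
#' @return `TRUE` or `FALSE`.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) < 4L) return(FALSE)
  e_from <- c(f[, 1], f[, 2], f[, 3])
  e_to <- c(f[, 2], f[, 3], f[, 1])
  directed <- paste(e_from, e_to)
  if (anyDuplicated(directed)) return(FALSE)      # inconsistent winding
  reversed <- paste(e_to, e_from)
  all(directed %in% reversed)                     # every edge paired
}

#' Enclosed volume, center of mass and surface area
#'
#' Volume and center of mass are computed by the divergence theorem over
#' signed tetrahedra spanned from the origin; they assume a watertight,
#' outward-wound mesh. `mesh_area()` sums triangle areas and has no such
#' requirement.
#'
#' @param mesh a [fem_mesh].
#' @return `mesh_volume()`: volume in mm^3; `mesh_center_of_mass()`:
#'   length-3 point (mm); `mesh_area()`: area in mm^2.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(rowSums(a * cr)) / 6
}

#' @rdname mesh_volume
#' @export
mesh_center_of_mass <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  w <- rowSums(a * cr) / 6           # signed tetra volumes
  vol <- sum(w)
  if (abs(vol) < 1e-9) {
    fc_abort("mesh has (near) zero enclosed volume", "femcurve_input_error")
  }
  centroid <- (a + b + c_) / 4       # tetra centroid (4th vertex is origin)
  as.numeric(colSums(centroid * w) / vol)
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Mirror a mesh across the sagittal plane
#'
#' Reflects x to -x and reverses face winding so that orientation stays
#' outward-consistent. Used to relate left and right femurs.
#'
#' @param mesh a [fem_mesh].
#' @return The mirrored `fem_mesh`.
#' @export
mirror_mesh <- function(mesh) {
  v <- mesh$vertices
  v[, 1] <- -v[, 1]
  fem_mesh(v, mesh$faces[, c(1L, 3L, 2L), drop = FALSE])
}

# ensure outward-consistent winding (positive enclosed volume); the
# generator builds faces in a fixed pattern and fixes the sign here
orient_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) {
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  }
  mesh
}

#' Signed distance from points to a watertight mesh surface
#'
#' Distance is the Euclidean distance to the nearest triangle; the sign is
#' positive for points inside the mesh (generalized winding number > 1/2)
#' and negative outside.
#'
#' @param points n x 3 matrix of query points (mm).
#' @param mesh a watertight [fem_mesh].
#' @return Numeric vector of signed distances (mm).
#' @export
signed_distance <- function(points, mesh) {
  if (!is_watertight(mesh)) {
    fc_abort("signed distance requires a watertight mesh",
             "femcurve_input_error")
  }
  points <- as.matrix(points)
  d <- .cpp_point_mesh_distance(points, mesh$vertices, mesh$faces)
  w <- .cpp_winding_number(points, mesh$vertices, mesh$faces)
  ifelse(w > 0.5, d, -d)
}

#' Convex hull of mesh vertices
#'
#' Incremental 3D convex hull. Facets are triangles with outward unit
#' normals; used by the resting-pose (osteometric board) computation.
#'
#' @param points n x 3 matrix (n >= 4, not all coplanar).
#' @return List with `faces` (m x 3, 1-based indices into `points`) and
#'   `normals` (m x 3 outward unit normals).
#' @export
convex_hull_3d <- function(points) {
  points <- as.matrix(points)
  tryCatch(
    .cpp_convex_hull(points),
    error = function(e) fc_abort(conditionMessage(e), "femcurve_degeneracy_error")
  )
}
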