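#' Triangle mesh constructor
#'
#' @param vertices n x 3 matrix of mm coordinates
#' @param faces m x 3 integer matrix of 1-based vertex indices
#' @return object of class `trimesh`
#' @export
trimesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            all(faces >= 1), all(faces <= nrow(vertices)))
  structure(list(vertices = vertices, faces = as.matrix(faces)),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat("<trimesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces\n", sep = "")
  invisible(x)
}

face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `trimesh`
#' @return scalar area
#' @export
mesh_area <- function(mesh) sum(sqrt(rowSums(face_cross(mesh)^2))) / 2

#' Area-weighted outward vertex normals
#' @param mesh a `trimesh`
#' @return n x 3 matrix of unit normals
#' @export
vertex_normals <- function(mesh) {
  fc <- face_cross(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (d in 1:3) n[, d] <- n[, d] + unname(tapply(fc[, d], factor(idx, levels = seq_len(nrow(n))), sum, default = 0))
  }
  n[is.na(n)] <- 0
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n / len
}

#' Euler characteristic V - E + F
#' @param mesh a `trimesh`
#' @return integer
#' @export
euler_characteristic <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  nrow(mesh$vertices) - nrow(unique(e)) + nrow(f)
}

# drop zero-area faces (can arise when the iso level hits a grid node)
drop_degenerate_faces <- function(mesh, tol = 1e-12) {
  areas <- sqrt(rowSums(face_cross(mesh)^2)) / 2
  mesh$faces <- mesh$faces[areas > tol, , drop = FALSE]
  mesh
}

#' Extract the isosurface of a binary label volume
#'
#' Builds a signed Euclidean distance field from the binary volume (exact
#' separable transform) and extracts its zero level set by tetrahedral
#' decomposition (6 tetrahedra per grid cell), which yields a watertight,
#' consistently oriented triangle mesh whose vertex coordinates are mapped
#' to mm via the volume's spacing and origin. The distance-field
#' formulation places the surface halfway between foreground and background
#' voxel centers and keeps the mesh smooth enough that surface areas of
#' voxelized solids match their analytic values closely.
#'
#' @param label a `label_volume`, or a 3D array (then `spacing` and
#'   `origin` apply)
#' @param iso iso level on the occupancy scale; 0.5 keeps the conventional
#'   contract (the distance field is thresholded at 0)
#' @param spacing,origin grid geometry when `label` is a plain array
#' @param smooth_sigma Gaussian smoothing of the distance field (voxels);
#'   suppresses the voxelization staircase. If smoothing would erase the
#'   foreground entirely (tiny structures), the unsmoothed field is used.
#' @return a `trimesh` in mm
#' @export
marching_cubes <- function(label, iso = 0.5, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0), smooth_sigma = 1) {
  if (inherits(label, "label_volume")) {
    spacing <- label$spacing; origin <- label$origin; label <- label$labels
  }
  mask <- (label >= iso) * 1
  if (sum(mask) == 0) stop("empty-mesh error: no foreground voxels")
  if (all(mask == 1)) stop("empty-mesh error: no background voxels")
  # crop to the foreground bounding box (plus margin) for speed
  idx <- which(mask > 0, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 4L, 1L)
  hi <- pmin(apply(idx, 2, max) + 4L, dim(mask))
  mask <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin <- origin + (lo - 1) * spacing
  # pad so surfaces around border voxels close
  dims <- dim(mask)
  pm <- array(0, dims + 2L)
  pm[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  phi <- sqrt(edt_cpp(pm)) - sqrt(edt_cpp(1 - pm))
  if (smooth_sigma > 0) {
    sm <- gauss3_cpp(phi, smooth_sigma)
    if (min(sm) < 0) phi <- sm
  }
  mt <- march_tets_cpp(phi, 0)
  v <- mt$vertices
  v <- sweep(sweep(v - 1, 2, spacing, `*`), 2, origin, `+`)
  drop_degenerate_faces(trimesh(v, mt$faces))
}

#' Dice overlap of two binary volumes
#'
#' `2|A intersect B| / (|A| + |B|)`; two empty volumes score 1.
#'
#' @param A,B binary arrays or `label_volume`s of the same shape
#' @return scalar in `[0, 1]`
#' @export
dice_score <- function(A, B) {
  if (inherits(A, "label_volume")) A <- A$labels
  if (inherits(B, "label_volume")) B <- B$labels
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  a <- A > 0; b <- B > 0
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Mean vertex-to-closest-surface distance (mm)
#'
#' Asymmetric: averages, over the vertices of `pred`, the exact distance to
#' the closest point on any triangle of `truth` (point-to-triangle, via a
#' uniform spatial index over triangles).
#'
#' @param pred,truth `trimesh` objects
#' @param method `"grid"` (indexed) or `"brute"` (all-triangle scan)
#' @return scalar mm
#' @export
mean_surface_distance <- function(pred, truth, method = c("grid", "brute")) {
  method <- match.arg(method)
  if (!nrow(pred$vertices) || !nrow(truth$faces)) stop("empty mesh")
  d <- if (method == "grid")
    mesh_point_dist_cpp(pred$vertices, truth$vertices, truth$faces, -1)
  else mesh_point_dist_brute_cpp(pred$vertices, truth$vertices, truth$faces)
  mean(d)
}

#' Write a mesh as ASCII STL
#' @param mesh a `trimesh`
#' @param path output file
#' @export
write_stl <- function(mesh, path) {
  fc <- face_cross(mesh)
  len <- sqrt(rowSums(fc^2)); len[len == 0] <- 1
  nrm <- fc / len
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid mesh", con)
  v <- mesh$vertices; f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("facet normal %.9g %.9g %.9g",
                       nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
    writeLines("  outer loop", con)
    for (k in 1:3)
      writeLines(sprintf("    vertex %.9g %.9g %.9g", v[f[i, k], 1],
                         v[f[i, k], 2], v[f[i, k], 3]), con)
    writeLines("  endloop", con)
    writeLines("endfacet", con)
  }
  writeLines("endsolid mesh", con)
  invisible(path)
}

#' Read an ASCII STL mesh
#' @param path STL file
#' @return a `trimesh` (vertices deduplicated)
#' @export
read_stl <- function(path) {
  ln <- trimws(readLines(path))
  vl <- ln[startsWith(ln, "vertex")]
  m <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  key <- apply(m, 1, paste, collapse = ",")
  uk <- !duplicated(key)
  verts <- m[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  trimesh(verts, matrix(idx, ncol = 3, byrow = TRUE))
}

#' Write a mesh as ASCII PLY
#' @param mesh a `trimesh`
#' @param path output file
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(mesh$vertices, con, row.names = FALSE, col.names = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
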