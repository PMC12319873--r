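# Cortical ribbon fixtures: paired pial/white triangle meshes with 1:1 vertex
# correspondence.  Shapes are parametric height-field sheets, which makes the
# true equivolume depth of any point available in closed form (see depth.R)
# while still exercising the mesh-based estimator.

#' Build a synthetic cortical ribbon (pial/white mesh pair)
#'
#' Constructs two triangulated sheets with identical face lists and 1:1
#' vertex correspondence spanning a cortical ribbon of the given thickness:
#'
#' * `"slab"` — parallel flat sheets; pial and white neighbourhood areas are
#'   equal everywhere, so equivolume depth reduces to Euclidean depth.
#' * `"wedge"` — a curved gyrus crown: concentric half-cylindrical sheets
#'   with white radius `thickness / (ratio - 1)` and pial radius
#'   `ratio x` that, so the per-vertex pial:white neighbourhood-area ratio
#'   is exactly `ratio`, cortical columns are radial (perpendicular to both
#'   surfaces), and cross-sectional area varies linearly across depth — the
#'   geometry the equivolume model assumes.
#' * `"sinusoidal"` — the white sheet undulates (`wave_amp`, `wave_period`)
#'   and the pial sheet is offset along the local surface normal, so the
#'   area ratio varies smoothly with curvature.
#'
#' @param shape one of `"slab"`, `"wedge"`, `"sinusoidal"`.
#' @param n_vertices approximate vertex count per surface (>= 4); the sheet
#'   is a `round(sqrt(n))` square grid.
#' @param thickness ribbon thickness in mm (> 0).
#' @param extent sheet extent `c(Lx, Ly)` in mm.
#' @param ratio pial:white area ratio for the wedge shape.
#' @param wave_amp,wave_period undulation amplitude and period in mm for the
#'   sinusoidal shape.
#' @return an object of class `mesh_pair`: list with `vertices_pial`,
#'   `vertices_white` (V x 3 mm), `faces` (F x 3 indices), `area_pial`,
#'   `area_white` (1-ring barycentric vertex areas, mm^2), and a `geometry`
#'   attribute recording the generating parameters.
#' @export
make_cortical_ribbon <- function(shape = c("slab", "wedge", "sinusoidal"),
                                 n_vertices = 400, thickness = 2,
                                 extent = c(20, 10), ratio = 2,
                                 wave_amp = 1, wave_period = 10) {
  shape <- match.arg(shape)
  if (n_vertices < 4) stop("`n_vertices` must be >= 4", call. = FALSE)
  stopifnot_scalar_pos(thickness, "thickness")

  n_side <- max(2L, round(sqrt(n_vertices)))
  xs <- seq(0, extent[1], length.out = n_side)
  ys <- seq(0, extent[2], length.out = n_side)
  gx <- rep(xs, times = n_side)
  gy <- rep(ys, each = n_side)

  if (shape == "wedge") {
    if (ratio <= 1) stop("wedge needs `ratio` > 1 (use the slab otherwise)",
                         call. = FALSE)
    r_white <- thickness / (ratio - 1)
    r_pial <- ratio * r_white
    theta <- rep(seq(-pi / 2, pi / 2, length.out = n_side), times = n_side)
    gy2 <- rep(ys, each = n_side)
    white <- cbind(r_white * sin(theta), gy2, r_white * cos(theta))
    pial <- cbind(r_pial * sin(theta), gy2, r_pial * cos(theta))
  } else {
    white <- switch(shape,
      slab = cbind(gx, gy, 0),
      sinusoidal = cbind(gx, gy, wave_amp * sin(2 * pi * gx / wave_period))
    )
    pial <- switch(shape,
      slab = cbind(gx, gy, thickness),
      sinusoidal = {
        fp <- wave_amp * 2 * pi / wave_period * cos(2 * pi * gx / wave_period)
        nrm <- cbind(-fp, 0, 1) / sqrt(1 + fp^2)
        white + thickness * nrm
      }
    )
  }
  colnames(white) <- colnames(pial) <- c("x", "y", "z")

  faces <- grid_faces(n_side, n_side)
  a_w <- vertex_neighborhood_areas(white, faces)
  a_p <- vertex_neighborhood_areas(pial, faces)
  if (any(triangle_areas(white, faces) < 1e-12) ||
      any(triangle_areas(pial, faces) < 1e-12)) {
    stop("degenerate (zero-area) faces in generated ribbon", call. = FALSE)
  }

  structure(
    list(vertices_pial = pial, vertices_white = white, faces = faces,
         area_pial = a_p, area_white = a_w),
    class = "mesh_pair",
    geometry = list(shape = shape, n_side = n_side, extent = extent,
                    thickness = thickness, ratio = ratio,
                    wave_amp = wave_amp, wave_period = wave_period)
  )
}

grid_faces <- function(nx, ny) {
  f <- matrix(0L, nrow = 2L * (nx - 1L) * (ny - 1L), ncol = 3L)
  k <- 1L
  for (j in seq_len(ny - 1L)) {
    for (i in seq_len(nx - 1L)) {
      v00 <- (j - 1L) * nx + i
      v10 <- v00 + 1L
      v01 <- v00 + nx
      v11 <- v01 + 1L
      f[k, ] <- c(v00, v10, v11); k <- k + 1L
      f[k, ] <- c(v00, v11, v01); k <- k + 1L
    }
  }
  f
}

triangle_areas <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a
  v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-vertex 1-ring neighbourhood areas
#'
#' Barycentric vertex areas: each triangle contributes one third of its area
#' to each of its three vertices.
#'
#' @param vertices V x 3 coordinate matrix.
#' @param faces F x 3 index matrix.
#' @return numeric vector of length V (mm^2).
#' @export
vertex_neighborhood_areas <- function(vertices, faces) {
  ta <- triangle_areas(vertices, faces)
  area <- numeric(nrow(vertices))
  for (k in 1:3) {
    contrib <- tapply(ta, faces[, k], sum)
    idx <- as.integer(names(contrib))
    area[idx] <- area[idx] + contrib
  }
  area / 3
}

#' Validity check for a ribbon mesh pair
#'
#' Verifies 1:1 vertex correspondence, identical face lists, finite
#' coordinates, strictly positive triangle and vertex areas, and strictly
#' positive pial-white separation at every vertex.
#'
#' @param mesh a `mesh_pair`.
#' @return `TRUE` if valid, otherwise `FALSE` with a `reasons` attribute.
#' @export
ribbon_valid <- function(mesh) {
  reasons <- character()
  if (!identical(dim(mesh$vertices_pial), dim(mesh$vertices_white))) {
    reasons <- c(reasons, "vertex count mismatch")
  }
  if (!all(is.finite(mesh$vertices_pial)) || !all(is.finite(mesh$vertices_white))) {
    reasons <- c(reasons, "non-finite coordinates")
  }
  if (any(triangle_areas(mesh$vertices_pial, mesh$faces) <= 1e-12) ||
      any(triangle_areas(mesh$vertices_white, mesh$faces) <= 1e-12)) {
    reasons <- c(reasons, "degenerate faces")
  }
  if (any(mesh$area_pial <= 0) || any(mesh$area_white <= 0)) {
    reasons <- c(reasons, "non-positive vertex areas")
  }
  sep <- sqrt(rowSums((mesh$vertices_pial - mesh$vertices_white)^2))
  if (any(sep <= 0)) reasons <- c(reasons, "pial and white surfaces touch")
  ok <- length(reasons) == 0L
  if (!ok) attr(ok, "reasons") <- reasons
  ok
}

#' @export
print.mesh_pair <- function(x, ...) {
  g <- attr(x, "geometry")
  cat(sprintf("<mesh_pair: %s, %d vertices, %d faces, thickness %.2f mm>\n",
              g$shape, nrow(x$vertices_white), nrow(x$faces), g$thickness))
  invisible(x)
}
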