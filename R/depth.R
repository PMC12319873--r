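# Equivolume cortical depth.
#
# At a vertex pair with pial neighbourhood area A_p and white neighbourhood
# area A_w, local cross-sectional area is modelled as varying linearly from
# A_p (depth 0, pial) to A_w (depth 1, white).  The cumulative volume down to
# Euclidean fraction x is int_0^x [(1-t) A_p + t A_w] dt; the equivolume
# coordinate alpha is that volume normalised by the column total
# (A_p + A_w)/2.  Intermediate surfaces are placed at equispaced alpha by
# inverting this relation, and voxel depths are linearly interpolated between
# the two nearest surfaces along the assigned vertex column.

#' Euclidean position of an equivolume surface
#'
#' Solves the wedge-volume equation
#' \eqn{\int_0^x [(1-t)A_p + tA_w]\,dt = \alpha\,(A_p+A_w)/2} for the
#' Euclidean fraction `x` (0 = pial, 1 = white) at which the surface
#' enclosing pial-side volume fraction `alpha` sits.
#'
#' @param alpha volume fraction(s) in \[0, 1\].
#' @param area_pial,area_white neighbourhood areas of the vertex pair
#'   (recycled against `alpha`).
#' @return Euclidean fraction(s) in \[0, 1\].  For `area_pial == area_white`
#'   this is `alpha` itself.
#' @export
equivolume_frac <- function(alpha, area_pial, area_white) {
  n <- max(length(alpha), length(area_pial), length(area_white))
  alpha <- rep_len(alpha, n)
  ap <- rep_len(area_pial, n)
  aw <- rep_len(area_white, n)
  if (any(ap + aw <= 0)) stop("vertex with zero total area", call. = FALSE)
  a <- (aw - ap) / 2
  b <- ap
  cc <- -alpha * (ap + aw) / 2
  x <- ifelse(
    abs(a) < 1e-12 * pmax(b, 1e-300),
    alpha,
    (-b + sqrt(pmax(b^2 - 4 * a * cc, 0))) / (2 * a)
  )
  pmin(pmax(x, 0), 1)
}

#' Volume fraction at a Euclidean position (closed form)
#'
#' Forward companion of [equivolume_frac()]: the pial-side volume fraction
#' enclosed down to Euclidean fraction `t`.  Used as the analytic ground
#' truth for voxel depths in the simulator, independently of the
#' intermediate-surface interpolation path.
#'
#' @param t Euclidean fraction(s), 0 = pial, 1 = white.
#' @param area_pial,area_white neighbourhood areas.
#' @return volume fraction(s) in \[0, 1\].
#' @export
alpha_from_frac <- function(t, area_pial, area_white) {
  (area_pial * t + (area_white - area_pial) * t^2 / 2) /
    ((area_pial + area_white) / 2)
}

# nearest vertex-column assignment: for each point, the vertex whose
# pial-white segment midpoint is closest, then the orthogonal projection
# parameter t along that segment (0 = pial, 1 = white).
assign_columns <- function(mesh, coords, chunk = 2048L, exclude = integer()) {
  mid <- (mesh$vertices_pial + mesh$vertices_white) / 2
  if (length(exclude)) mid[exclude, ] <- 1e9 # degenerate vertices never win
  m <- nrow(coords)
  vid <- integer(m)
  rs_mid <- rowSums(mid^2)
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    cc <- coords[idx, , drop = FALSE]
    d2 <- outer(rowSums(cc^2), rs_mid, "+") - 2 * cc %*% t(mid)
    vid[idx] <- max.col(-d2, ties.method = "first")
  }
  p <- mesh$vertices_pial[vid, , drop = FALSE]
  w <- mesh$vertices_white[vid, , drop = FALSE]
  dvec <- w - p
  len2 <- rowSums(dvec^2)
  t_raw <- rowSums((coords - p) * dvec) / len2
  perp <- sqrt(pmax(rowSums((coords - p - dvec * t_raw)^2), 0))
  list(vertex_id = vid, t_raw = t_raw, perp = perp)
}

ribbon_grid <- function(mesh, spacing) {
  spacing <- rep_len(spacing, 3L)
  v <- rbind(mesh$vertices_pial, mesh$vertices_white)
  lo <- apply(v, 2, min) + spacing / 2
  hi <- apply(v, 2, max) - spacing / 2
  ax <- lapply(1:3, function(k) {
    if (hi[k] <= lo[k]) mean(c(lo[k], hi[k])) else seq(lo[k], hi[k], by = spacing[k])
  })
  coords <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  list(coords = coords, dims = lengths(ax), spacing = spacing,
       origin = vapply(ax, `[`, numeric(1), 1L))
}

#' Equivolume depth of grid voxels inside a cortical ribbon
#'
#' Generates `n_surfaces` intermediate surfaces at equispaced equivolume
#' fractions (via [equivolume_frac()], using the per-vertex pial/white
#' neighbourhood-area ratio to account for curvature), assigns every voxel
#' centre to its nearest vertex column, and linearly interpolates the
#' voxel's depth between the two nearest intermediate surfaces.  Depth is 0
#' at the pial and 1 at the white surface.
#'
#' @param mesh a `mesh_pair`.
#' @param voxels optional M x 3 matrix of voxel-centre coordinates; if
#'   `NULL`, a regular grid with `spacing` covering the ribbon is used.
#' @param spacing grid spacing in mm (scalar or length 3) when `voxels` is
#'   `NULL`.
#' @param n_surfaces number of intermediate surfaces (>= 9).
#' @param max_dist maximum orthogonal distance (mm) from a voxel centre to
#'   its vertex column for gray-matter membership; default is the median
#'   white-surface edge length.
#' @param tol tolerance on the projection parameter for gray-matter
#'   membership at the pial/white boundaries (default 0: a voxel centre is
#'   gray matter only if it lies strictly between the surfaces).
#' @return an object of class `depth_volume`: list with `coords` (gray
#'   matter voxel centres), `depth` in \[0, 1\], `vertex_id` (assigned
#'   column), `t` (Euclidean fraction), and `grid` metadata (`dims`,
#'   `spacing`, `origin`, `index` linear indices of gray-matter voxels) when
#'   a grid was generated internally.
#' @export
equivolume_depth <- function(mesh, voxels = NULL, spacing = 0.5,
                             n_surfaces = 11, max_dist = NULL, tol = 0) {
  if (n_surfaces < 9) stop("`n_surfaces` must be >= 9", call. = FALSE)
  degenerate <- which(mesh$area_pial + mesh$area_white <= 0)
  if (length(degenerate) == nrow(mesh$vertices_white)) {
    stop("all vertices have zero area", call. = FALSE)
  }
  grid <- NULL
  if (is.null(voxels)) {
    g <- ribbon_grid(mesh, spacing)
    voxels <- g$coords
    grid <- g
  }
  if (is.null(max_dist)) {
    e <- mesh$vertices_white[mesh$faces[, 1], ] - mesh$vertices_white[mesh$faces[, 2], ]
    max_dist <- stats::median(sqrt(rowSums(e^2)))
  }

  asg <- assign_columns(mesh, voxels, exclude = degenerate)
  gm <- asg$t_raw >= -tol & asg$t_raw <= 1 + tol & asg$perp <= max_dist
  if (!any(gm)) stop("no voxels fall inside the ribbon", call. = FALSE)

  vid <- asg$vertex_id[gm]
  tt <- pmin(pmax(asg$t_raw[gm], 0), 1)

  alphas <- seq(0, 1, length.out = n_surfaces)
  ap <- mesh$area_pial
  aw <- mesh$area_white
  ap[degenerate] <- 1 # placeholders; excluded vertices are never assigned
  aw[degenerate] <- 1
  xsurf <- vapply(alphas, function(a) equivolume_frac(a, ap, aw),
                  numeric(length(ap))) # V x K Euclidean fractions

  depth <- numeric(length(vid))
  done <- logical(length(vid))
  for (k in seq_len(n_surfaces - 1L)) {
    x0 <- xsurf[cbind(vid, k)]
    x1 <- xsurf[cbind(vid, k + 1L)]
    sel <- !done & tt >= x0 & (tt <= x1 | k == n_surfaces - 1L)
    f <- ifelse(x1[sel] > x0[sel], (tt[sel] - x0[sel]) / (x1[sel] - x0[sel]), 0)
    depth[sel] <- alphas[k] + (alphas[k + 1L] - alphas[k]) * f
    done[sel] <- TRUE
  }
  depth <- pmin(pmax(depth, 0), 1)

  out <- list(coords = voxels[gm, , drop = FALSE], depth = depth,
              vertex_id = vid, t = tt, n_vertices = nrow(mesh$vertices_white))
  if (!is.null(grid)) {
    out$grid <- list(dims = grid$dims, spacing = grid$spacing,
                     origin = grid$origin, index = which(gm))
  }
  structure(out, class = "depth_volume")
}

#' @export
print.depth_volume <- function(x, ...) {
  cat(sprintf("<depth_volume: %d gray-matter voxels, depth in [%.3f, %.3f]>\n",
              length(x$depth), min(x$depth), max(x$depth)))
  invisible(x)
}

#' Assign equal-volume layer compartments from equivolume depth
#'
#' Splits gray matter into superficial (`depth < 1/3`), middle
#' (`1/3 <= depth < 2/3`), and deep (`depth >= 2/3`) compartments.  Because
#' the depth coordinate is equivolume, equal depth intervals enclose equal
#' tissue volumes, so the three compartments each hold one third of the
#' gray-matter volume.
#'
#' @param depth a `depth_volume` or a numeric vector of depths in \[0, 1\].
#' @return factor with levels `superficial`, `middle`, `deep`.
#' @export
assign_layers <- function(depth) {
  d <- if (inherits(depth, "depth_volume")) depth$depth else depth
  if (length(d) == 0L) stop("empty gray-matter mask", call. = FALSE)
  if (any(d < 0 | d > 1)) stop("depths must lie in [0, 1]", call. = FALSE)
  cut(d, breaks = c(-Inf, 1 / 3, 2 / 3, Inf),
      labels = c("superficial", "middle", "deep"), right = FALSE)
}

#' Compartment volume fractions
#'
#' @param layers factor from [assign_layers()].
#' @return named numeric vector of volume fractions summing to 1 (voxels
#'   are equal-volume grid cells).
#' @export
layer_volume_fractions <- function(layers) {
  tab <- table(layers)
  fr <- as.numeric(tab) / sum(tab)
  names(fr) <- names(tab)
  fr
}
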