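#' Parametric solute surfaces as implicit signed-distance shapes
#'
#' Builds a solute surface of prescribed curvature as an implicit solid:
#' negative signed distance inside the solid, zero on the surface, positive
#' outside. Available kinds:
#'
#' * `"sphere"`: radius `radius`, centre `center` (convex everywhere);
#' * `"slab"`: a rectangular block with top face at `z_top`, lateral patch
#'   `patch` = c(Lx, Ly) and `thickness` along z (flat reference surface);
#' * `"concave_pocket"`: a slab with a hemispherical pocket of radius
#'   `pocket_radius` carved into the centre of the top face (negative
#'   curvature at the working patch);
#' * `"convex_bump"`: a slab with a hemispherical bump of radius
#'   `bump_radius` on the centre of the top face (positive curvature);
#' * `"composite"`: the union of a list of shapes passed as `components`.
#'
#' Signed distances are exact for spheres and slabs and exact away from the
#' boolean intersection curves for the pocket/bump/composite constructions
#' (the usual min/max CSG bound). Surface area and volume are analytic for
#' all single-solid kinds (hemisphere geometry for pocket and bump) and
#' estimated by low-discrepancy Monte Carlo for composites, with a reported
#' standard error (see [estimate_sa_vol()]).
#'
#' @param kind one of `"sphere"`, `"slab"`, `"concave_pocket"`,
#'   `"convex_bump"`, `"composite"`.
#' @param radius sphere radius, Angstrom.
#' @param center sphere centre, length-3, Angstrom.
#' @param patch lateral extents c(Lx, Ly) of the slab, Angstrom.
#' @param thickness slab thickness along z, Angstrom.
#' @param z_top z coordinate of the slab top face, Angstrom.
#' @param pocket_radius,bump_radius hemisphere radius of the carved pocket
#'   or mounted bump, Angstrom; must not exceed the slab thickness or half
#'   the patch width.
#' @param components for `kind = "composite"`, a list of `solute_shape`
#'   objects whose union is taken.
#' @param n_mc Monte Carlo points used for composite surface-area/volume
#'   estimation.
#' @return An object of class `solute_shape` with fields `kind`, `params`,
#'   `sdf` (vectorised signed-distance function over an N x 3 matrix),
#'   `bbox` (3 x 2 bounding box), `surface_area`, `volume`, and standard
#'   errors `sa_se`, `vol_se` (0 for analytic kinds).
#' @examples
#' sph <- make_shape("sphere", radius = 5)
#' surface_area(sph) / shape_volume(sph) # 3/R
#' @export
make_shape <- function(kind = c("sphere", "slab", "concave_pocket",
                                "convex_bump", "composite"),
                       radius = 5, center = c(0, 0, 0),
                       patch = c(30, 30), thickness = 10, z_top = 0,
                       pocket_radius = 6, bump_radius = 6,
                       components = NULL, n_mc = 2e5) {
  kind <- match.arg(kind)
  shape <- switch(
    kind,
    sphere = .shape_sphere(radius, center),
    slab = .shape_slab(patch, thickness, z_top),
    concave_pocket = .shape_pocket(patch, thickness, z_top, pocket_radius),
    convex_bump = .shape_bump(patch, thickness, z_top, bump_radius),
    composite = .shape_composite(components, n_mc)
  )
  shape
}

.new_shape <- function(kind, params, sdf, bbox, sa, vol,
                       sa_se = 0, vol_se = 0) {
  structure(list(kind = kind, params = params, sdf = sdf, bbox = bbox,
                 surface_area = sa, volume = vol,
                 sa_se = sa_se, vol_se = vol_se),
            class = "solute_shape")
}

.as_points <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  if (ncol(points) != 3) .stop_domain("points must be N x 3")
  points
}

.shape_sphere <- function(radius, center) {
  if (!is.finite(radius) || radius <= 0) .stop_domain("'radius' must be > 0")
  stopifnot(length(center) == 3)
  force(radius); force(center)
  sdf <- function(points) {
    p <- .as_points(points)
    sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2 +
           (p[, 3] - center[3])^2) - radius
  }
  bbox <- cbind(center - radius, center + radius)
  .new_shape("sphere", list(radius = radius, center = center), sdf, bbox,
             sa = 4 * pi * radius^2, vol = 4 / 3 * pi * radius^3)
}

## axis-aligned box occupying [-Lx/2,Lx/2] x [-Ly/2,Ly/2] x [z_top-th, z_top]
.box_sdf <- function(half, center) {
  force(half); force(center)
  function(points) {
    p <- .as_points(points)
    qx <- abs(p[, 1] - center[1]) - half[1]
    qy <- abs(p[, 2] - center[2]) - half[2]
    qz <- abs(p[, 3] - center[3]) - half[3]
    outside <- sqrt(pmax(qx, 0)^2 + pmax(qy, 0)^2 + pmax(qz, 0)^2)
    inside <- pmin(pmax(qx, pmax(qy, qz)), 0)
    outside + inside
  }
}

.shape_slab <- function(patch, thickness, z_top) {
  if (any(!is.finite(c(patch, thickness))) || any(c(patch, thickness) <= 0))
    .stop_domain("slab 'patch' and 'thickness' must be > 0")
  half <- c(patch[1] / 2, patch[2] / 2, thickness / 2)
  center <- c(0, 0, z_top - thickness / 2)
  sdf <- .box_sdf(half, center)
  bbox <- cbind(center - half, center + half)
  sa <- 2 * (patch[1] * patch[2] + patch[1] * thickness +
               patch[2] * thickness)
  .new_shape("slab",
             list(patch = patch, thickness = thickness, z_top = z_top),
             sdf, bbox, sa = sa, vol = patch[1] * patch[2] * thickness)
}

.shape_pocket <- function(patch, thickness, z_top, pocket_radius) {
  if (pocket_radius <= 0 || pocket_radius > thickness ||
      2 * pocket_radius > min(patch))
    .stop_domain("'pocket_radius' must be positive and fit inside the slab")
  slab <- .shape_slab(patch, thickness, z_top)
  pc <- c(0, 0, z_top)
  sph <- .shape_sphere(pocket_radius, pc)
  slab_sdf <- slab$sdf; sph_sdf <- sph$sdf
  sdf <- function(points) pmax(slab_sdf(points), -sph_sdf(points))
  ## hemisphere carved out of the top face
  vol <- slab$volume - 2 / 3 * pi * pocket_radius^3
  sa <- slab$surface_area - pi * pocket_radius^2 + 2 * pi * pocket_radius^2
  .new_shape("concave_pocket",
             list(patch = patch, thickness = thickness, z_top = z_top,
                  pocket_radius = pocket_radius, pocket_center = pc),
             sdf, slab$bbox, sa = sa, vol = vol)
}

.shape_bump <- function(patch, thickness, z_top, bump_radius) {
  if (bump_radius <= 0 || 2 * bump_radius > min(patch))
    .stop_domain("'bump_radius' must be positive and fit on the slab patch")
  slab <- .shape_slab(patch, thickness, z_top)
  bc <- c(0, 0, z_top)
  sph <- .shape_sphere(bump_radius, bc)
  slab_sdf <- slab$sdf; sph_sdf <- sph$sdf
  sdf <- function(points) pmin(slab_sdf(points), sph_sdf(points))
  vol <- slab$volume + 2 / 3 * pi * bump_radius^3
  sa <- slab$surface_area - pi * bump_radius^2 + 2 * pi * bump_radius^2
  bbox <- slab$bbox
  bbox[3, 2] <- z_top + bump_radius
  .new_shape("convex_bump",
             list(patch = patch, thickness = thickness, z_top = z_top,
                  bump_radius = bump_radius, bump_center = bc),
             sdf, bbox, sa = sa, vol = vol)
}

.shape_composite <- function(components, n_mc) {
  if (is.null(components) || length(components) < 1 ||
      !all(vapply(components, inherits, logical(1), "solute_shape")))
    .stop_domain("'components' must be a non-empty list of solute_shape")
  sdfs <- lapply(components, `[[`, "sdf")
  sdf <- function(points) {
    vals <- vapply(sdfs, function(f) f(points),
                   numeric(nrow(.as_points(points))))
    if (is.null(dim(vals))) min(vals) else apply(vals, 1, min)
  }
  boxes <- lapply(components, `[[`, "bbox")
  bbox <- cbind(
    apply(vapply(boxes, function(b) b[, 1], numeric(3)), 1, min),
    apply(vapply(boxes, function(b) b[, 2], numeric(3)), 1, max)
  )
  shape <- .new_shape("composite", list(n_components = length(components)),
                      sdf, bbox, sa = NA_real_, vol = NA_real_,
                      sa_se = NA_real_, vol_se = NA_real_)
  shape$components <- components
  if (n_mc > 0) {
    est <- estimate_sa_vol(shape, n = n_mc)
    shape$surface_area <- est$surface_area
    shape$volume <- est$volume
    shape$sa_se <- est$sa_se
    shape$vol_se <- est$vol_se
  }
  shape
}

#' Signed distance from points to a solute surface
#'
#' @param shape a [make_shape()] object.
#' @param points an N x 3 matrix (or length-3 vector) of coordinates,
#'   Angstrom.
#' @return numeric vector of signed distances (negative inside the solid).
#' @export
signed_distance <- function(shape, points) {
  if (!inherits(shape, "solute_shape"))
    .stop_domain("'shape' must be a solute_shape")
  shape$sdf(points)
}

#' @rdname make_shape
#' @param shape a `solute_shape`.
#' @export
surface_area <- function(shape) shape$surface_area

#' @rdname make_shape
#' @export
shape_volume <- function(shape) shape$volume

#' @export
print.solute_shape <- function(x, ...) {
  cat(sprintf("Solute shape '%s'\n", x$kind))
  cat(sprintf("  surface area %.3f A^2 (se %.3g), volume %.3f A^3 (se %.3g)\n",
              x$surface_area, x$sa_se, x$volume, x$vol_se))
  cat(sprintf("  SA/V = %.4f 1/A\n", x$surface_area / x$volume))
  invisible(x)
}

## Halton low-discrepancy sequence (radical inverse, bases 2/3/5)
.halton <- function(n, bases = c(2, 3, 5)) {
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (any(i > 0)) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  idx <- seq_len(n)
  vapply(bases, function(b) radical_inverse(idx, b), numeric(n))
}

#' Monte Carlo surface area and volume of an implicit shape
#'
#' Estimates the volume as the bounding-box volume times the fraction of
#' low-discrepancy (Halton) points with non-positive signed distance, and
#' the surface area from the measure of the shell `|sd| <= eps` divided by
#' `2 * eps`. Standard errors use the binomial formula, a conservative
#' bound for low-discrepancy sampling.
#'
#' @param shape a [make_shape()] object.
#' @param n number of sample points.
#' @param eps half-width of the surface shell, Angstrom.
#' @param pad bounding-box padding, Angstrom (must exceed `eps`).
#' @return list with `surface_area`, `volume`, `sa_se`, `vol_se`, `n`.
#' @export
estimate_sa_vol <- function(shape, n = 2e5, eps = 0.05, pad = 0.5) {
  if (!inherits(shape, "solute_shape"))
    .stop_domain("'shape' must be a solute_shape")
  lo <- shape$bbox[, 1] - pad
  hi <- shape$bbox[, 2] + pad
  u <- .halton(n)
  pts <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  sd <- shape$sdf(pts)
  vbox <- prod(hi - lo)
  p_in <- mean(sd <= 0)
  p_shell <- mean(abs(sd) <= eps)
  list(
    volume = vbox * p_in,
    surface_area = vbox * p_shell / (2 * eps),
    vol_se = vbox * sqrt(p_in * (1 - p_in) / n),
    sa_se = vbox * sqrt(p_shell * (1 - p_shell) / n) / (2 * eps),
    n = n
  )
}
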