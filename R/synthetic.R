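## Seeded generators: every input the analysis layers need, with known
## ground truth (shape geometry, water packings, biased samples from a
## specified free-energy profile, association trajectories with planted
## interfacial-to-bulk transition counts).

#' A ground-truth free-energy profile for sampler validation
#'
#' Analytic reaction-coordinate free energies with known extrema:
#'
#' * `"double_well"` (default): two Gaussian wells plus a repulsive
#'   `c_tail / (r - r_wall)` contact tail, the shape of a solvated
#'   association PMF (contact minimum, barrier, solvent-separated
#'   minimum). Extrema are located at construction by derivative root
#'   refinement on a fine grid.
#' * `"flat"`: identically zero (uniform unbiased density);
#' * `"harmonic"`: `0.5 k_truth (r - c0)^2`.
#'
#' @param kind profile family.
#' @param domain reaction-coordinate domain c(min, max), Angstrom.
#' @param well_depths,well_centers,well_widths Gaussian well parameters
#'   (kJ/mol, Angstrom, Angstrom) for `"double_well"`.
#' @param c_tail tail amplitude, kJ/mol*Angstrom; `r_wall` tail pole,
#'   Angstrom (must lie below `domain[1]`).
#' @param k_truth,c0 harmonic parameters for `"harmonic"`.
#' @return An object of class `ground_truth_pmf`: list with vectorised
#'   `fun`, `domain`, `extrema` (data frame `position`, `value`, `type`)
#'   and `params`.
#' @examples
#' truth <- ground_truth_pmf()
#' truth$extrema
#' @export
ground_truth_pmf <- function(kind = c("double_well", "flat", "harmonic"),
                             domain = c(1.8, 13),
                             well_depths = c(10, 4),
                             well_centers = c(3, 6),
                             well_widths = c(0.6, 0.8),
                             c_tail = 8, r_wall = 1.0,
                             k_truth = 10, c0 = mean(domain)) {
  kind <- match.arg(kind)
  if (domain[1] >= domain[2]) .stop_domain("'domain' must be increasing")
  if (kind == "double_well" && r_wall >= domain[1])
    .stop_domain("'r_wall' must lie below the domain")
  fun <- switch(
    kind,
    flat = function(r) rep(0, length(r)),
    harmonic = function(r) 0.5 * k_truth * (r - c0)^2,
    double_well = function(r) {
      v <- c_tail / (r - r_wall)
      for (w in seq_along(well_depths))
        v <- v - well_depths[w] *
          exp(-(r - well_centers[w])^2 / (2 * well_widths[w]^2))
      v
    }
  )
  extrema <- switch(
    kind,
    flat = data.frame(position = numeric(0), value = numeric(0),
                      type = character(0)),
    harmonic = data.frame(position = c0, value = 0, type = "minimum"),
    double_well = .locate_extrema(fun, domain)
  )
  structure(list(fun = fun, domain = domain, extrema = extrema,
                 params = list(kind = kind, well_depths = well_depths,
                               well_centers = well_centers,
                               well_widths = well_widths, c_tail = c_tail,
                               r_wall = r_wall, k_truth = k_truth, c0 = c0)),
            class = "ground_truth_pmf")
}

.locate_extrema <- function(fun, domain, n_grid = 4001) {
  x <- seq(domain[1], domain[2], length.out = n_grid)
  y <- fun(x)
  dy <- diff(y)
  turns <- which(dy[-1] * dy[-length(dy)] < 0) + 1L
  if (length(turns) == 0)
    return(data.frame(position = numeric(0), value = numeric(0),
                      type = character(0)))
  rows <- lapply(turns, function(i) {
    lo <- x[max(1, i - 2)]; hi <- x[min(n_grid, i + 2)]
    is_min <- y[i] < y[i - 1]
    opt <- stats::optimize(fun, c(lo, hi), maximum = !is_min,
                           tol = 1e-10)
    data.frame(position = if (is_min) opt$minimum else opt$maximum,
               value = opt$objective,
               type = if (is_min) "minimum" else "maximum")
  })
  do.call(rbind, rows)
}

#' @export
print.ground_truth_pmf <- function(x, ...) {
  cat(sprintf("ground_truth_pmf '%s' on [%.2f, %.2f] A, %d extrema\n",
              x$params$kind, x$domain[1], x$domain[2], nrow(x$extrema)))
  invisible(x)
}

#' Evaluate a ground-truth profile on a grid as a `pmf_profile`
#'
#' @param truth a [ground_truth_pmf()].
#' @param grid bin centres, Angstrom (inside the truth domain).
#' @param reference_point passed to [pmf_profile()].
#' @return a `pmf_profile` with provenance `"ground_truth"`.
#' @export
truth_profile <- function(truth, grid, reference_point = NULL) {
  stopifnot(inherits(truth, "ground_truth_pmf"))
  pmf_profile(grid, truth$fun(grid), provenance = "ground_truth",
              pin = TRUE, reference_point = reference_point)
}

## two hydrogens at 0.96 A from O, internal H-O-H angle 104.5 deg,
## uniformly random orientation; n x 2 x 3 array
.random_hydrogens <- function(oxygen, d_OH = 0.96, angle_HOH = 104.5) {
  n <- nrow(oxygen)
  out <- array(NA_real_, c(n, 2, 3))
  if (n == 0) return(out)
  ## first O-H direction: uniform on the sphere
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u * u))
  ## random perpendicular to u
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v - u * rowSums(u * v)
  v <- v / sqrt(rowSums(v * v))
  a <- angle_HOH * pi / 180
  w <- cos(a) * u + sin(a) * v
  out[, 1, ] <- oxygen + d_OH * u
  out[, 2, ] <- oxygen + d_OH * w
  out
}

#' Generate a water-like packing around a solute
#'
#' Rejection-samples oxygen positions uniformly in an orthorhombic box,
#' outside the solute and with all pairwise O-O distances at least
#' `min_OO` (minimum image when `periodic`), then attaches two hydrogens
#' per oxygen at 0.96 Angstrom with uniformly random orientation. The
#' target count is `density` times the box volume not occupied by the
#' solute. Deterministic under `seed`.
#'
#' @param box box lengths c(Lx, Ly, Lz), Angstrom.
#' @param density target number density, waters/Angstrom^3 (bulk water is
#'   about 0.0334).
#' @param shape optional [make_shape()] solute excluded from placement;
#'   it must lie inside the box.
#' @param min_OO minimum O-O distance, Angstrom. Default 2.4.
#' @param seed integer seed.
#' @param periodic apply the minimum-image convention during placement
#'   and record the box on the frame. Default TRUE.
#' @param max_attempts_factor insertion attempts allowed per target
#'   water before giving up.
#' @return a [water_frame()].
#' @export
generate_water_box <- function(box, density, shape = NULL, min_OO = 2.4,
                               seed = 1, periodic = TRUE,
                               max_attempts_factor = 200) {
  if (length(box) != 3 || any(box <= 0)) .stop_domain("'box' must be 3 positive lengths")
  if (density < 0) .stop_domain("'density' must be >= 0")
  set.seed(seed)
  v_box <- prod(box)
  v_excl <- if (is.null(shape)) 0 else shape$volume
  if (is.na(v_excl)) v_excl <- 0
  n_target <- round(density * max(v_box - v_excl, 0))
  if (n_target == 0) {
    return(water_frame(matrix(numeric(0), 0, 3),
                       array(numeric(0), c(0, 2, 3)),
                       box = if (periodic) box else NULL))
  }
  pbc <- if (periodic) box else NULL
  ## cell list: cell edge >= min_OO so neighbours suffice
  ncell <- pmax(1L, floor(box / min_OO))
  cell_len <- box / ncell
  cells <- new.env(hash = TRUE, parent = emptyenv())
  cell_key <- function(ci) paste(ci, collapse = ",")
  cell_of <- function(p) pmin(floor(p / cell_len), ncell - 1L)
  pos <- matrix(NA_real_, n_target, 3)
  n_placed <- 0L
  attempts <- 0L
  max_attempts <- max_attempts_factor * n_target
  offsets <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  while (n_placed < n_target) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n_target, " waters after ", max_attempts,
           " attempts; lower the density or min_OO", call. = FALSE)
    p <- stats::runif(3) * box
    if (!is.null(shape) && signed_distance(shape, p) <= 0) next
    ci <- cell_of(p)
    clash <- FALSE
    for (k in seq_len(nrow(offsets))) {
      nb <- ci + offsets[k, ]
      if (periodic) nb <- nb %% ncell
      else if (any(nb < 0) || any(nb >= ncell)) next
      idx <- cells[[cell_key(nb)]]
      if (is.null(idx)) next
      d <- .min_image(pos[idx, , drop = FALSE] -
                        matrix(p, length(idx), 3, byrow = TRUE), pbc)
      if (any(rowSums(d * d) < min_OO^2)) { clash <- TRUE; break }
    }
    if (clash) next
    n_placed <- n_placed + 1L
    pos[n_placed, ] <- p
    key <- cell_key(ci)
    cells[[key]] <- c(cells[[key]], n_placed)
  }
  water_frame(pos, .random_hydrogens(pos), box = pbc)
}

#' Draw umbrella-window samples from a known free-energy profile
#'
#' For each bias centre, runs a 1-D Metropolis random walk targeting the
#' biased density `exp(-(U(r) + 0.5 k (r - c)^2) / kT)` on the truth
#' domain. The step size is tuned to 30-50% acceptance during burn-in and
#' then frozen; one sample is kept every `stride` steps. Deterministic
#' under `seed`; burn-in, stride and the realised acceptance rate are
#' recorded in each window's `meta`.
#'
#' @param truth a [ground_truth_pmf()].
#' @param centers bias centres, Angstrom, inside the truth domain.
#' @param spring_k harmonic constant, kJ/mol/Angstrom^2.
#' @param n_samples samples kept per window.
#' @param temperature K. Default 300.
#' @param seed integer seed.
#' @param burn_in discarded tuning steps. Default 5000.
#' @param stride steps between kept samples. Default 10.
#' @return list of [umbrella_window()]s, one per centre.
#' @export
generate_umbrella_samples <- function(truth, centers, spring_k,
                                      n_samples = 5000, temperature = 300,
                                      seed = 1, burn_in = 5000, stride = 10) {
  stopifnot(inherits(truth, "ground_truth_pmf"))
  if (any(centers < truth$domain[1]) || any(centers > truth$domain[2]))
    .stop_domain("all bias centres must lie inside the truth domain")
  set.seed(seed)
  kT <- .kB * temperature
  ufun <- truth$fun
  lo <- truth$domain[1]; hi <- truth$domain[2]
  lapply(centers, function(c0) {
    half_k <- 0.5 * spring_k
    r <- c0
    u_cur <- ufun(r) + half_k * (r - c0)^2
    step <- max(sqrt(kT / spring_k), 1e-3)
    ## burn-in with step adaptation every 200 steps
    acc_win <- 0L
    for (t in seq_len(burn_in)) {
      rp <- r + stats::runif(1, -step, step)
      if (rp >= lo && rp <= hi) {
        u_prop <- ufun(rp) + half_k * (rp - c0)^2
        if (u_prop <= u_cur ||
            stats::runif(1) < exp(-(u_prop - u_cur) / kT)) {
          r <- rp; u_cur <- u_prop; acc_win <- acc_win + 1L
        }
      }
      if (t %% 200L == 0L) {
        rate <- acc_win / 200
        if (rate < 0.3) step <- step * 0.8
        else if (rate > 0.5) step <- step * 1.25
        acc_win <- 0L
      }
    }
    if (ufun(r) + half_k * (r - c0)^2 > 1e8)
      stop("sampler failed to move during burn-in; adjust step size",
           call. = FALSE)
    n_steps <- n_samples * stride
    eps <- stats::runif(n_steps, -step, step)
    urand <- stats::runif(n_steps)
    out <- numeric(n_samples)
    n_acc <- 0L
    kept <- 0L
    for (t in seq_len(n_steps)) {
      rp <- r + eps[t]
      if (rp >= lo && rp <= hi) {
        u_prop <- ufun(rp) + half_k * (rp - c0)^2
        if (u_prop <= u_cur || urand[t] < exp(-(u_prop - u_cur) / kT)) {
          r <- rp; u_cur <- u_prop; n_acc <- n_acc + 1L
        }
      }
      if (t %% stride == 0L) {
        kept <- kept + 1L
        out[kept] <- r
      }
    }
    umbrella_window(center = c0, spring_k = spring_k, samples = out,
                    temperature = temperature,
                    meta = list(seed = seed, burn_in = burn_in,
                                stride = stride, step = step,
                                acceptance = n_acc / n_steps))
  })
}

#' Association trajectory with planted interfacial-to-bulk transitions
#'
#' Emulates a spherical probe approaching a target surface (flat slab,
#' concave pocket, or convex bump) along z. Interfacial waters sit on a
#' lattice of sites in the approach region, each within `layer_cutoff` of
#' the target surface. As the separation shrinks, the descending probe
#' squeezes sites out of the narrowing gap (signed distance to the probe
#' below `margin`); a squeezed site permanently releases its water to a
#' bulk reservoir, so the per-frame interfacial count is non-increasing
#' and the cumulative interfacial-to-bulk transition count non-decreasing.
#' Molecule order is fixed across frames, and by construction
#' [classify_layers()] against the frame's composite geometry reproduces
#' the planted labels exactly. At matched schedules the planted totals
#' order concave >= flat >= convex: the pocket wraps the probe and loses
#' the most interfacial sites, the bump the fewest.
#'
#' @param target one of `"flat"`, `"concave"`, `"convex"`.
#' @param separations non-increasing surface-to-surface separations,
#'   Angstrom; the first must exceed `layer_cutoff` and the last must be
#'   >= 0 (contact).
#' @param sphere_radius probe radius, Angstrom. Default 5.
#' @param layer_cutoff interfacial layer thickness, Angstrom. Default 3.5.
#' @param seed integer seed (hydrogen orientations).
#' @param site_spacing interfacial-site lattice spacing, Angstrom.
#'   Default 1.5.
#' @param margin minimum signed distance a site keeps from both surfaces,
#'   Angstrom; a site dies once the probe comes closer. Default 0.6.
#' @param n_reservoir permanent bulk waters. Default 40.
#' @param n_static permanent interfacial waters on the target far from
#'   the gap (present in whole-box counts but not in gap counts).
#'   Default 12.
#' @param patch,thickness slab geometry, Angstrom.
#' @param pocket_clearance radial clearance of the concave pocket over
#'   the probe, Angstrom. Default 2.5.
#' @param bump_radius convex bump radius, Angstrom. Default 4.
#' @return list with `frames` (list of [water_frame()]s), `shape_at_frame`
#'   (function: frame position -> composite `solute_shape`), `schedule`
#'   (data frame: `frame`, `separation_A`, `n_interfacial_gap`,
#'   `n_interfacial_box`, `n_bulk`, `transitions`,
#'   `cum_interfacial_to_bulk`), `labels` (list of planted per-frame
#'   label vectors) and the generator parameters.
#' @export
generate_association_trajectory <- function(
    target = c("flat", "concave", "convex"),
    separations = seq(8, 0, by = -0.5),
    sphere_radius = 5, layer_cutoff = 3.5, seed = 1,
    site_spacing = 1.5, margin = 0.6,
    n_reservoir = 40, n_static = 12,
    patch = c(30, 30), thickness = 10,
    pocket_clearance = 2.5, bump_radius = 4) {
  target <- match.arg(target)
  if (length(separations) < 1 || is.unsorted(rev(separations)))
    .stop_domain("'separations' must be non-increasing")
  if (min(separations) < 0)
    .stop_domain("final separation must be >= 0 (contact)")
  if (layer_cutoff >= separations[1])
    .stop_domain("'layer_cutoff' (", layer_cutoff,
                 " A) is not smaller than the initial gap (",
                 separations[1], " A)")
  set.seed(seed)
  Rs <- sphere_radius
  base <- switch(target,
    flat = make_shape("slab", patch = patch, thickness = thickness),
    concave = make_shape("concave_pocket", patch = patch,
                         thickness = thickness,
                         pocket_radius = Rs + pocket_clearance),
    convex = make_shape("convex_bump", patch = patch,
                        thickness = thickness, bump_radius = bump_radius))
  z_contact <- switch(target,
    flat = Rs,
    concave = Rs - (Rs + pocket_clearance),
    convex = Rs + bump_radius)
  z_center <- z_contact + separations
  nf <- length(separations)

  probe_at <- function(t) make_shape("sphere", radius = Rs,
                                     center = c(0, 0, z_center[t]))
  shape_at <- function(t) make_shape("composite",
                                     components = list(base, probe_at(t)),
                                     n_mc = 0)

  ## interfacial-site lattice in the approach region: each site sits
  ## within the interfacial layer of the target surface
  lat <- site_spacing
  xy_max <- Rs + layer_cutoff + 1.5
  z_lo <- if (target == "concave") -(Rs + pocket_clearance) - 0.5 else -0.5
  z_hi_sites <- layer_cutoff +
    (if (target == "convex") bump_radius else 0) + 0.5
  cand <- as.matrix(expand.grid(
    x = seq(-xy_max, xy_max, by = lat),
    y = seq(-xy_max, xy_max, by = lat),
    z = seq(z_lo, z_hi_sites, by = lat)))
  sd_base <- signed_distance(base, cand)
  sites <- cand[sd_base >= margin & sd_base <= layer_cutoff, , drop = FALSE]

  ## a site is alive while the probe keeps its distance; once squeezed it
  ## stays dead (cumulative AND), so occupancy is monotone
  alive <- matrix(FALSE, nrow(sites), nf)
  for (t in seq_len(nf))
    alive[, t] <- signed_distance(probe_at(t), sites) >= margin
  present <- alive
  if (nf > 1)
    for (t in 2:nf) present[, t] <- present[, t - 1] & alive[, t]
  ## drop sites already squeezed at the initial separation
  keep <- present[, 1]
  sites <- sites[keep, , drop = FALSE]
  present <- present[keep, , drop = FALSE]
  n_gap <- nrow(sites)

  ## sub-region count: sites currently facing both surfaces
  in_gap <- matrix(FALSE, n_gap, nf)
  for (t in seq_len(nf))
    in_gap[, t] <- present[, t] &
      signed_distance(probe_at(t), sites) <= layer_cutoff

  ## bulk destinations: lattice high above the trajectory
  z_bulk <- max(z_center) + Rs + layer_cutoff + 3
  n_bulk_pts <- n_gap + n_reservoir
  side <- ceiling(sqrt(n_bulk_pts))
  gx <- (seq_len(side) - (side + 1) / 2) * 3
  bulk_pts <- as.matrix(expand.grid(x = gx, y = gx, z = z_bulk))
  while (nrow(bulk_pts) < n_bulk_pts) {
    z_bulk <- z_bulk + 3
    bulk_pts <- rbind(bulk_pts,
                      as.matrix(expand.grid(x = gx, y = gx, z = z_bulk)))
  }
  bulk_dest <- bulk_pts[seq_len(n_gap), , drop = FALSE]
  reservoir <- bulk_pts[n_gap + seq_len(n_reservoir), , drop = FALSE]

  ## static interfacial waters on the target, far from the gap
  static_pts <- NULL
  if (n_static > 0) {
    half <- ceiling(n_static / 2)
    ys <- (seq_len(half) - (half + 1) / 2) * 2.5
    static_pts <- rbind(
      cbind(x = rep(-patch[1] / 2 + 1.5, half), y = ys, z = 1.5),
      cbind(x = rep(patch[1] / 2 - 1.5, half), y = ys, z = 1.5))
    static_pts <- static_pts[seq_len(n_static), , drop = FALSE]
  }

  frames <- vector("list", nf)
  labels <- vector("list", nf)
  transitions <- integer(nf)
  for (t in seq_len(nf)) {
    on_site <- present[, t]
    oxy <- sites
    oxy[!on_site, ] <- bulk_dest[!on_site, , drop = FALSE]
    oxy <- rbind(oxy, static_pts, reservoir)
    lab <- c(ifelse(on_site, "interfacial", "bulk"),
             rep("interfacial", n_static),
             rep("bulk", n_reservoir))
    frames[[t]] <- water_frame(oxy, .random_hydrogens(oxy),
                               frame_index = t)
    labels[[t]] <- lab
    transitions[t] <- if (t == 1) 0L else
      sum(present[, t - 1] & !present[, t])
  }
  schedule <- data.frame(
    frame = seq_len(nf),
    separation_A = separations,
    n_interfacial_gap = colSums(in_gap),
    n_interfacial_box = colSums(present) + n_static,
    n_bulk = (n_gap - colSums(present)) + n_reservoir,
    transitions = transitions,
    cum_interfacial_to_bulk = cumsum(transitions)
  )
  list(frames = frames, shape_at_frame = shape_at, schedule = schedule,
       labels = labels,
       params = list(target = target, sphere_radius = Rs,
                     layer_cutoff = layer_cutoff, seed = seed,
                     site_spacing = site_spacing, margin = margin,
                     patch = patch, thickness = thickness,
                     pocket_clearance = pocket_clearance,
                     bump_radius = bump_radius, z_contact = z_contact))
}
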