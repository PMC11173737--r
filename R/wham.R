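#' One umbrella-sampling window
#'
#' Reaction-coordinate samples collected under a harmonic bias
#' `0.5 * spring_k * (r - center)^2`.
#'
#' @param center bias centre, Angstrom.
#' @param spring_k harmonic constant, kJ/mol/Angstrom^2; positive.
#' @param samples reaction-coordinate values, Angstrom; at least one,
#'   all finite.
#' @param temperature K.
#' @param meta optional list of sampler metadata (seed, burn-in, stride,
#'   acceptance rate).
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring_k, samples, temperature = 300,
                            meta = NULL) {
  if (!is.finite(spring_k) || spring_k <= 0)
    .stop_domain("'spring_k' must be > 0")
  if (length(samples) < 1 || any(!is.finite(samples)))
    .stop_domain("'samples' must be non-empty and finite")
  if (!is.finite(temperature) || temperature <= 0)
    .stop_domain("'temperature' must be > 0")
  structure(list(center = center, spring_k = spring_k,
                 samples = as.numeric(samples),
                 temperature = temperature, meta = meta),
            class = "umbrella_window")
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("umbrella_window: center %.3f A, k %.3g kJ/mol/A^2, %d samples, %g K\n",
              x$center, x$spring_k, length(x$samples), x$temperature))
  invisible(x)
}

#' A free-energy profile on a reaction-coordinate grid
#'
#' @param grid strictly increasing bin centres, Angstrom.
#' @param values free energies, kJ/mol; `NA` marks masked (unsampled) bins.
#' @param provenance one of `"total"`, `"vacuum"`, `"water_induced"`,
#'   `"ground_truth"`.
#' @param counts optional per-bin sample counts.
#' @param pin pin the profile to zero at `reference_point` (default: the
#'   largest grid point with a finite value).
#' @param reference_point grid location pinned to zero.
#' @return An object of class `pmf_profile`.
#' @export
pmf_profile <- function(grid, values,
                        provenance = c("total", "vacuum", "water_induced",
                                       "ground_truth"),
                        counts = NULL, pin = TRUE, reference_point = NULL) {
  provenance <- match.arg(provenance)
  if (length(grid) != length(values))
    .stop_domain("'grid' and 'values' lengths differ")
  if (is.unsorted(grid, strictly = TRUE))
    .stop_domain("'grid' must be strictly increasing")
  values <- as.numeric(values)
  if (pin) {
    finite <- which(is.finite(values))
    if (length(finite) == 0) .stop_domain("profile has no finite values")
    if (is.null(reference_point)) reference_point <- grid[max(finite)]
    ref_idx <- which.min(abs(grid - reference_point))
    if (!is.finite(values[ref_idx]))
      .stop_domain("reference point falls on a masked bin")
    values <- values - values[ref_idx]
  } else {
    reference_point <- if (is.null(reference_point)) NA_real_ else reference_point
  }
  structure(list(grid = as.numeric(grid), values = values,
                 provenance = provenance, counts = counts,
                 reference_point = reference_point),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  fin <- is.finite(x$values)
  cat(sprintf("pmf_profile (%s): %d bins on [%.3f, %.3f] A, %d masked\n",
              x$provenance, length(x$grid), min(x$grid), max(x$grid),
              sum(!fin)))
  if (any(fin))
    cat(sprintf("  range %.3f .. %.3f kJ/mol, pinned at r = %.3f A\n",
                min(x$values[fin]), max(x$values[fin]), x$reference_point))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...,
                             xlab = "separation (A)",
                             ylab = "free energy (kJ/mol)") {
  graphics::plot(x$grid, x$values, type = "l", xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
summary.pmf_profile <- function(object, ...) {
  feats <- tryCatch(find_minima_barriers(object), error = function(e) NULL)
  out <- list(profile = object, features = feats)
  class(out) <- "summary.pmf_profile"
  out
}

#' @export
print.summary.pmf_profile <- function(x, ...) {
  print(x$profile)
  if (!is.null(x$features)) print(x$features)
  invisible(x)
}

#' Reconstruct a PMF from umbrella windows by self-consistent WHAM
#'
#' Combines the biased histograms of all windows into one unbiased
#' free-energy profile by iterating the weighted-histogram equations:
#' given window free-energy constants `f_i`, the unbiased bin probability
#' is the total count divided by `sum_i N_i exp((f_i - u_i(x)) / kT)` with
#' `u_i` the harmonic bias, and the `f_i` are recomputed from the
#' probabilities until the largest change falls below `tolerance`. Empty
#' bins inside the sampled range are masked, never interpolated. The
#' profile is pinned to zero at the largest sampled bin by default.
#'
#' @param windows list of [umbrella_window()]s with a common temperature;
#'   the sampled ranges of adjacent windows (ordered by centre) must
#'   overlap.
#' @param bin_width histogram bin width, Angstrom. Default 0.1.
#' @param tolerance convergence threshold on the maximum absolute change
#'   of the window constants, kJ/mol. Default 1e-7.
#' @param max_iter iteration cap. Default 1e5.
#' @param reference_point grid location pinned to 0; default the largest
#'   sampled bin.
#' @return a [pmf_profile()] with provenance `"total"`, plus attributes in
#'   `$wham`: iterations used, final residual, window constants `f`.
#' @examples
#' truth <- ground_truth_pmf()
#' win <- generate_umbrella_samples(truth, centers = 2:12, spring_k = 25,
#'                                  n_samples = 2000, seed = 1)
#' prof <- wham(win)
#' @export
wham <- function(windows, bin_width = 0.1, tolerance = 1e-7,
                 max_iter = 1e5, reference_point = NULL) {
  if (inherits(windows, "umbrella_window")) windows <- list(windows)
  if (length(windows) < 1) .stop_domain("need at least one window")
  if (!all(vapply(windows, inherits, logical(1), "umbrella_window")))
    .stop_domain("'windows' must be umbrella_window objects")
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (max(temps) - min(temps) > 1e-9)
    .stop_domain("mixed window temperatures are not supported ",
                 "(single-temperature WHAM)")
  kT <- .kB * temps[1]
  .check_window_overlap(windows)

  all_s <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(all_s) / bin_width) * bin_width
  hi <- ceiling(max(all_s) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  grid <- edges[-length(edges)] + bin_width / 2
  B <- length(grid)
  S <- length(windows)

  counts <- vapply(windows, function(w) {
    idx <- pmin(pmax(floor((w$samples - lo) / bin_width) + 1L, 1L), B)
    tabulate(idx, nbins = B)
  }, numeric(B))
  counts <- matrix(counts, nrow = B)
  n_tot <- rowSums(counts)
  N <- colSums(counts)

  centers <- vapply(windows, `[[`, numeric(1), "center")
  ks <- vapply(windows, `[[`, numeric(1), "spring_k")
  ## B x S matrix of exp(-u_i(x_b)/kT)
  bias <- outer(grid, centers, function(x, c0) x - c0)
  bias <- 0.5 * sweep(bias^2, 2, ks, "*")
  expb <- exp(-bias / kT)

  f <- numeric(S)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- expb %*% (N * exp(f / kT))
    P <- n_tot / denom
    P[n_tot == 0] <- 0
    z <- crossprod(expb, P)          # S x 1
    f_new <- -kT * log(as.numeric(z))
    f_new <- f_new - f_new[1]
    resid <- max(abs(f_new - f))
    f <- f_new
    if (resid < tolerance) break
    if (iter >= max_iter)
      stop("WHAM did not converge in ", max_iter,
           " iterations (residual ", signif(resid, 3), " kJ/mol)",
           call. = FALSE)
  }
  values <- ifelse(n_tot > 0, -kT * log(P), NA_real_)
  prof <- pmf_profile(grid, values, provenance = "total", counts = n_tot,
                      pin = TRUE, reference_point = reference_point)
  prof$wham <- list(iterations = iter, residual = resid, f = f,
                    kT = kT, bin_width = bin_width)
  prof
}

.check_window_overlap <- function(windows) {
  if (length(windows) < 2) return(invisible(TRUE))
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  rng <- t(vapply(windows[ord], function(w) range(w$samples), numeric(2)))
  for (i in seq_len(nrow(rng) - 1)) {
    if (rng[i, 2] < rng[i + 1, 1]) {
      stop(sprintf(
        "umbrella windows do not overlap: gap between %.3f and %.3f A (windows centred %.3f and %.3f A)",
        rng[i, 2], rng[i + 1, 1],
        windows[[ord[i]]]$center, windows[[ord[i + 1]]]$center),
        call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Root-mean-square deviation between two free-energy profiles
#'
#' Compares two profiles on the finite bins of the first, resampling the
#' second by linear interpolation where the grids differ. Because a PMF
#' is defined only up to an additive constant, the default removes the
#' mean difference before computing the RMSE (`align = "offset"`);
#' `align = "none"` compares the values as pinned.
#'
#' @param profile,reference `pmf_profile` objects.
#' @param align `"offset"` (default) or `"none"`.
#' @return RMSE in kJ/mol.
#' @export
pmf_rmse <- function(profile, reference, align = c("offset", "none")) {
  align <- match.arg(align)
  stopifnot(inherits(profile, "pmf_profile"),
            inherits(reference, "pmf_profile"))
  fin <- is.finite(profile$values)
  rf <- is.finite(reference$values)
  x <- profile$grid[fin]
  keep <- x >= min(reference$grid[rf]) & x <= max(reference$grid[rf])
  if (!any(keep)) .stop_domain("profiles share no grid overlap")
  x <- x[keep]
  a <- profile$values[fin][keep]
  b <- stats::approx(reference$grid[rf], reference$values[rf], xout = x)$y
  d <- a - b
  if (align == "offset") d <- d - mean(d)
  sqrt(mean(d^2))
}

#' Water-induced component of a PMF
#'
#' Subtracts the vacuum profile of the same solutes from the total
#' (solvated) profile: the remainder is the solvent's contribution to the
#' interaction. Profiles are resampled by linear interpolation onto the
#' overlap of their grids, and the difference is re-pinned to zero at its
#' largest-separation bin.
#'
#' @param total a `pmf_profile` with the solvated PMF.
#' @param vacuum a `pmf_profile` with the in-vacuum PMF.
#' @return a `pmf_profile` with provenance `"water_induced"`.
#' @export
water_induced_pmf <- function(total, vacuum) {
  stopifnot(inherits(total, "pmf_profile"), inherits(vacuum, "pmf_profile"))
  tf <- is.finite(total$values); vf <- is.finite(vacuum$values)
  lo <- max(min(total$grid[tf]), min(vacuum$grid[vf]))
  hi <- min(max(total$grid[tf]), max(vacuum$grid[vf]))
  if (lo >= hi) .stop_domain("profiles share no grid overlap")
  grid <- total$grid[total$grid >= lo & total$grid <= hi & tf]
  tot_i <- stats::approx(total$grid[tf], total$values[tf], xout = grid)$y
  vac_i <- stats::approx(vacuum$grid[vf], vacuum$values[vf], xout = grid)$y
  pmf_profile(grid, tot_i - vac_i, provenance = "water_induced", pin = TRUE)
}

#' Locate minima and barriers in a free-energy profile
#'
#' Local minima are detected on the (finite part of the) profile and
#' filtered by topographic prominence; the barrier between two adjacent
#' retained minima is the highest intervening value minus the left
#' minimum's value, so barriers are climbed left to right (decreasing
#' separation is to the left, so this is the barrier met on approach from
#' the right minimum's side reversed; heights are non-negative either way).
#'
#' @param profile a `pmf_profile` with at least 5 grid points.
#' @param prominence_min minimum prominence for a minimum to be reported,
#'   kJ/mol. Default 0.5.
#' @return An object of class `pmf_features`: list with `minima`
#'   (data frame `position`, `depth`, `rank`; rank 1 = smallest position,
#'   the contact minimum) and `barriers` (data frame `position`, `height`
#'   above the preceding minimum).
#' @export
find_minima_barriers <- function(profile, prominence_min = 0.5) {
  stopifnot(inherits(profile, "pmf_profile"))
  fin <- is.finite(profile$values)
  x <- profile$grid[fin]
  y <- profile$values[fin]
  if (length(y) < 5) .stop_domain("profile too short (need >= 5 finite bins)")
  mins <- .local_minima(y)
  keep <- mins[vapply(mins, function(i) .prominence(y, i) >= prominence_min,
                      logical(1))]
  minima <- data.frame(position = x[keep], depth = y[keep],
                       rank = seq_along(keep))
  if (length(keep) >= 2) {
    bpos <- numeric(length(keep) - 1)
    bheight <- numeric(length(keep) - 1)
    for (k in seq_len(length(keep) - 1)) {
      seg <- keep[k]:keep[k + 1]
      top <- seg[which.max(y[seg])]
      bpos[k] <- x[top]
      bheight[k] <- y[top] - y[keep[k]]
    }
    barriers <- data.frame(position = bpos, height = bheight)
  } else {
    barriers <- data.frame(position = numeric(0), height = numeric(0))
  }
  structure(list(minima = minima, barriers = barriers),
            class = "pmf_features")
}

## indices of strict local minima (plateaus: first index of the plateau)
.local_minima <- function(y) {
  n <- length(y)
  out <- integer(0)
  i <- 2L
  while (i < n) {
    if (y[i] < y[i - 1]) {
      j <- i
      while (j < n && y[j + 1] == y[j]) j <- j + 1L
      if (j < n && y[j + 1] > y[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

## topographic prominence of a minimum (on the inverted profile)
.prominence <- function(y, i) {
  n <- length(y)
  left <- if (i > 1) {
    lower <- which(y[1:(i - 1)] < y[i])
    seg <- if (length(lower)) (max(lower) + 1):(i - 1) else 1:(i - 1)
    if (length(seg)) max(y[seg]) else Inf
  } else Inf
  right <- if (i < n) {
    lower <- which(y[(i + 1):n] < y[i]) + i
    seg <- if (length(lower)) (i + 1):(min(lower) - 1) else (i + 1):n
    if (length(seg)) max(y[seg]) else Inf
  } else Inf
  min(left, right) - y[i]
}

#' @export
print.pmf_features <- function(x, ...) {
  cat(sprintf("pmf_features: %d minima, %d barriers\n",
              nrow(x$minima), nrow(x$barriers)))
  if (nrow(x$minima)) {
    cat("  minima (position A, depth kJ/mol):\n")
    for (k in seq_len(nrow(x$minima)))
      cat(sprintf("    #%d at %.3f: %.3f\n", x$minima$rank[k],
                  x$minima$position[k], x$minima$depth[k]))
  }
  if (nrow(x$barriers)) {
    cat("  barriers (position A, height kJ/mol above preceding minimum):\n")
    for (k in seq_len(nrow(x$barriers)))
      cat(sprintf("    at %.3f: %.3f\n", x$barriers$position[k],
                  x$barriers$height[k]))
  }
  invisible(x)
}

#' Linear relation between water-induced energy and expelled waters
#'
#' Ordinary least-squares line and Pearson correlation between the
#' water-induced free energy and the count of interfacial-to-bulk
#' transitions. Under the transfer model the slope is the per-molecule
#' tetrahedral bond free energy.
#'
#' @param dG water-induced free energies, kJ/mol.
#' @param n_transitions interfacial-to-bulk counts.
#' @return list with `slope`, `intercept`, `correlation`, `n`.
#' @export
correlate_energy_transitions <- function(dG, n_transitions) {
  if (length(dG) != length(n_transitions))
    .stop_domain("'dG' and 'n_transitions' lengths differ")
  if (length(dG) < 3) .stop_domain("need at least 3 pairs")
  if (stats::var(n_transitions) == 0)
    .stop_domain("degenerate data: counts have zero variance")
  fit <- stats::lm(dG ~ n_transitions)
  cf <- stats::coef(fit)
  list(slope = unname(cf[2]), intercept = unname(cf[1]),
       correlation = stats::cor(dG, n_transitions), n = length(dG))
}

#' Rank surfaces by contact-minimum depth and first-barrier height
#'
#' Orders labelled water-induced profiles (typically concave, flat,
#' convex) by the depth of their first (contact) minimum, ascending (most
#' negative = strongest attraction first), and by their first barrier
#' height, descending. Profiles in which no minimum passes the prominence
#' filter are excluded with a warning; ties are reported.
#'
#' @param profiles named list of `pmf_profile`s.
#' @param prominence_min passed to [find_minima_barriers()].
#' @return list with `table` (data frame: label, first-minimum position
#'   and depth, first-barrier height), `by_depth` and `by_barrier`
#'   (label orderings), `ties` (logical: any exact ties in depth).
#' @export
rank_surface_interactions <- function(profiles, prominence_min = 0.5) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    .stop_domain("'profiles' must be a named list")
  rows <- list()
  for (lbl in names(profiles)) {
    ft <- find_minima_barriers(profiles[[lbl]], prominence_min)
    if (nrow(ft$minima) == 0) {
      warning("profile '", lbl, "' has no detected minimum; excluded")
      next
    }
    rows[[lbl]] <- data.frame(
      label = lbl,
      min_position = ft$minima$position[1],
      min_depth = ft$minima$depth[1],
      first_barrier = if (nrow(ft$barriers)) ft$barriers$height[1] else NA_real_
    )
  }
  if (length(rows) == 0) .stop_domain("no profile has a detected minimum")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(
    table = tab,
    by_depth = tab$label[order(tab$min_depth)],
    by_barrier = tab$label[order(-tab$first_barrier)],
    ties = anyDuplicated(tab$min_depth) > 0
  )
}
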