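kT300 <- 0.008314462618 * 300

test_that("window and profile containers validate their invariants", {
  expect_error(umbrella_window(5, -1, c(5, 5.1)), "spring_k")
  expect_error(umbrella_window(5, 10, numeric(0)), "samples")
  expect_error(umbrella_window(5, 10, c(5, NA)), "samples")
  expect_error(pmf_profile(c(1, 2, 2), c(0, 0, 0)), "strictly increasing")
  p <- pmf_profile(1:10, (1:10)^2)
  expect_equal(p$values[10], 0)               # pinned at the far end
  expect_equal(p$reference_point, 10)
})

test_that("near-unbiased uniform samples give a flat profile", {
  set.seed(2)
  w <- umbrella_window(center = 5, spring_k = 1e-6,
                       samples = runif(50000, 0, 10))
  prof <- wham(list(w), bin_width = 0.5)
  fin <- is.finite(prof$values)
  expect_true(all(fin))
  expect_lt(max(abs(prof$values[fin])), 0.2)  # sampling noise only
})

test_that("WHAM recovers a known double-well profile from biased windows", {
  truth <- ground_truth_pmf()
  win <- generate_umbrella_samples(truth, centers = 2:12, spring_k = 25,
                                   n_samples = 3000, seed = 7)
  prof <- wham(win)
  fin <- is.finite(prof$values)
  tp <- truth_profile(truth, prof$grid[fin])
  rmse <- pmf_rmse(prof, tp)
  expect_lt(rmse, 0.5)
  ## invariance under window reordering (same samples, permuted order)
  prof2 <- wham(rev(win))
  expect_equal(prof2$values, prof$values, tolerance = 1e-6)
  ## duplicating the whole window set leaves the estimate unchanged
  prof3 <- wham(c(win, win))
  expect_equal(prof3$values, prof$values, tolerance = 1e-6)
})

test_that("a duplicated single window gives the single-window profile", {
  truth <- ground_truth_pmf()
  w <- generate_umbrella_samples(truth, centers = 6, spring_k = 10,
                                 n_samples = 3000, seed = 9)[[1]]
  p1 <- wham(list(w))
  p2 <- wham(list(w, w))
  expect_equal(p2$values, p1$values, tolerance = 1e-6)
})

test_that("recovery error shrinks with samples per window", {
  truth <- ground_truth_pmf()
  rmse_at <- function(n) {
    win <- generate_umbrella_samples(truth, centers = 2:12, spring_k = 25,
                                     n_samples = n, seed = 21)
    prof <- wham(win)
    fin <- is.finite(prof$values)
    pmf_rmse(prof, truth_profile(truth, prof$grid[fin]))
  }
  r <- vapply(c(1e3, 1e4, 5e4), rmse_at, numeric(1))
  expect_lt(r[2], r[1])
  expect_lt(r[3], r[1])
  expect_lt(r[3], 0.5)
})

test_that("disconnected windows and mixed temperatures are rejected", {
  set.seed(5)
  w1 <- umbrella_window(2, 50, rnorm(200, 2, 0.15))
  w2 <- umbrella_window(9, 50, rnorm(200, 9, 0.15))
  expect_error(wham(list(w1, w2)), "do not overlap")
  w3 <- umbrella_window(2.2, 50, rnorm(200, 2.2, 0.2), temperature = 310)
  expect_error(wham(list(w1, w3)), "temperature")
  w4 <- umbrella_window(2.5, 50, rnorm(200, 2.5, 0.2))
  expect_error(wham(list(w1, w4), max_iter = 1), "converge")
})

test_that("water-induced decomposition is an exact pointwise difference", {
  grid <- seq(2, 10, by = 0.1)
  vac_vals <- 0.5 * (grid - 6)^2
  wat_vals <- -4 * exp(-(grid - 3)^2)
  tot <- pmf_profile(grid, vac_vals + wat_vals, "total")
  vac <- pmf_profile(grid, vac_vals, "vacuum")
  wi <- water_induced_pmf(tot, vac)
  expect_equal(wi$provenance, "water_induced")
  truth <- wat_vals - wat_vals[length(wat_vals)]
  expect_equal(wi$values, truth, tolerance = 1e-9)
  ## vacuum of zeros returns the total unchanged; total = vacuum gives zero
  zero <- pmf_profile(grid, rep(0, length(grid)), "vacuum", pin = FALSE)
  expect_equal(water_induced_pmf(tot, zero)$values, tot$values,
               tolerance = 1e-12)
  expect_true(all(abs(water_induced_pmf(vac, vac)$values) < 1e-12))
  ## reconstruction: water_induced + vacuum = total after consistent pinning
  recon <- wi$values + (vac_vals - vac_vals[length(vac_vals)])
  expect_equal(recon, tot$values, tolerance = 1e-9)
  far <- pmf_profile(seq(20, 30, 0.1), rep(0, 101), "vacuum")
  expect_error(water_induced_pmf(tot, far), "overlap")
})

test_that("minima and barriers: analytic double well, monotone, parabola", {
  grid <- seq(2, 10, by = 0.02)
  ## 5 cos(2 pi (r-2) / 4): minima at r = 4, 8; maxima at 2, 6, 10
  vals <- 5 * cos(2 * pi * (grid - 2) / 4)
  ft <- find_minima_barriers(pmf_profile(grid, vals), prominence_min = 1)
  expect_equal(nrow(ft$minima), 2)
  expect_equal(ft$minima$position, c(4, 8), tolerance = 0.02 / 4)
  expect_equal(nrow(ft$barriers), 1)
  expect_equal(ft$barriers$position, 6, tolerance = 0.02 / 6)
  expect_equal(ft$barriers$height, 10, tolerance = 1e-6)
  expect_true(all(ft$barriers$height >= 0))
  ## monotone profile: no features
  mono <- find_minima_barriers(pmf_profile(grid, 2 * grid))
  expect_equal(nrow(mono$minima), 0)
  expect_equal(nrow(mono$barriers), 0)
  ## single parabola: exactly one minimum at the vertex bin
  par1 <- find_minima_barriers(pmf_profile(grid, (grid - 6.37)^2))
  expect_equal(nrow(par1$minima), 1)
  expect_lt(abs(par1$minima$position - 6.37), 0.02)
  expect_error(find_minima_barriers(pmf_profile(1:3, c(1, 0, 1))), "short")
})

test_that("energy/transition correlation recovers the transfer model exactly", {
  n <- 0:12
  dG <- hydrophobic_interaction_energy(n)
  res <- correlate_energy_transitions(dG, n)
  expect_equal(res$slope, -2.66, tolerance = 1e-9)
  expect_equal(res$intercept, 0, tolerance = 1e-9)
  expect_equal(abs(res$correlation), 1, tolerance = 1e-12)
  ## any exact line has |correlation| 1
  res2 <- correlate_energy_transitions(3 + 2 * (1:5), 1:5)
  expect_equal(res2$correlation, 1, tolerance = 1e-12)
  expect_error(correlate_energy_transitions(c(1, 2), c(1, 2)), "3 pairs")
  expect_error(correlate_energy_transitions(c(1, 2, 3), c(2, 2, 2)),
               "zero variance")
})

test_that("surfaces rank by contact-minimum depth and first-barrier height", {
  grid <- seq(1, 12, by = 0.05)
  mk <- function(depth, barrier) {
    v <- depth * exp(-(grid - 2.5)^2 / 0.5) +
      barrier * exp(-(grid - 4.5)^2 / 0.3) -
      2 * exp(-(grid - 6.5)^2 / 0.5)
    pmf_profile(grid, v, "water_induced")
  }
  profs <- list(concave = mk(-10, 4), flat = mk(-6, 3), convex = mk(-3, 2))
  rk <- rank_surface_interactions(profs)
  expect_equal(rk$by_depth, c("concave", "flat", "convex"))
  expect_equal(rk$by_barrier, c("concave", "flat", "convex"))
  expect_false(rk$ties)
  ## identical profiles: tie reported
  rk2 <- rank_surface_interactions(list(a = mk(-5, 2), b = mk(-5, 2)))
  expect_true(rk2$ties)
  ## two profiles only
  rk3 <- rank_surface_interactions(profs[1:2])
  expect_equal(rk3$by_depth, c("concave", "flat"))
  ## featureless profile excluded with a warning
  flatp <- pmf_profile(grid, rep(0, length(grid)), "water_induced",
                       pin = FALSE)
  expect_warning(rk4 <- rank_surface_interactions(c(profs[1:2],
                                                    list(none = flatp))),
                 "excluded")
  expect_equal(sort(rk4$table$label), c("concave", "flat"))
})
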