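test_that("ground-truth profiles expose consistent analytic extrema", {
  truth <- ground_truth_pmf()
  ex <- truth$extrema
  expect_true(all(ex$type %in% c("minimum", "maximum")))
  expect_true(!is.unsorted(ex$position))
  ## each tabulated extremum matches the callable locally
  for (i in seq_len(nrow(ex))) {
    x0 <- ex$position[i]
    expect_equal(truth$fun(x0), ex$value[i], tolerance = 1e-8)
    probe <- truth$fun(x0 + c(-0.01, 0.01))
    if (ex$type[i] == "minimum") expect_true(all(probe > ex$value[i]))
    else expect_true(all(probe < ex$value[i]))
  }
  flat <- ground_truth_pmf("flat")
  expect_equal(flat$fun(c(2, 5, 9)), c(0, 0, 0))
  expect_error(ground_truth_pmf(domain = c(5, 2)), "increasing")
  expect_error(ground_truth_pmf(r_wall = 2.5), "r_wall")
})

test_that("water box generation: count, exclusion, min distance, determinism", {
  box <- c(22, 22, 22)
  fr <- generate_water_box(box, density = 0.0334, seed = 5)
  expect_equal(nrow(fr$oxygen), round(0.0334 * prod(box)))
  ## validator pass: all pairwise minimum-image distances >= min_OO
  n <- nrow(fr$oxygen)
  dmin <- Inf
  for (i in seq_len(n - 1)) {
    d <- sweep(fr$oxygen[(i + 1):n, , drop = FALSE], 2, fr$oxygen[i, ])
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    dmin <- min(dmin, sqrt(min(rowSums(d * d))))
  }
  expect_gte(dmin, 2.4)
  ## O-H bond lengths as constructed
  expect_equal(sqrt(rowSums((fr$hydrogen[, 1, ] - fr$oxygen)^2)),
               rep(0.96, n), tolerance = 1e-9)
  ## solute exclusion
  sph <- make_shape("sphere", radius = 5, center = c(11, 11, 11))
  fr2 <- generate_water_box(box, density = 0.0334, shape = sph, seed = 5)
  expect_true(all(signed_distance(sph, fr2$oxygen) > 0))
  expect_lt(nrow(fr2$oxygen), nrow(fr$oxygen))
  ## determinism and the empty limit
  fr3 <- generate_water_box(box, density = 0.0334, seed = 5)
  expect_identical(fr, fr3)
  expect_equal(nrow(generate_water_box(box, density = 0, seed = 1)$oxygen), 0)
  expect_error(generate_water_box(c(8, 8, 8), density = 0.2, seed = 1,
                                  max_attempts_factor = 5),
               "lower the density")
})

test_that("umbrella sampler hits the analytic biased density", {
  kT <- 0.008314462618 * 300
  ## flat truth + stiff spring: truncated-Gaussian limit
  flat <- ground_truth_pmf("flat", domain = c(0, 20))
  w <- generate_umbrella_samples(flat, centers = 10, spring_k = 5,
                                 n_samples = 4000, seed = 5)[[1]]
  sd_th <- sqrt(kT / 5)
  expect_lt(abs(mean(w$samples) - 10), 3 * sd_th / sqrt(400))
  ks <- suppressWarnings(
    stats::ks.test(w$samples[seq(1, 4000, by = 2)], "pnorm",
                   mean = 10, sd = sd_th))
  expect_gt(ks$p.value, 0.01)
  expect_true(w$meta$acceptance > 0.2 && w$meta$acceptance < 0.7)
  ## harmonic truth + harmonic bias: variance kT/(k_truth + k_bias)
  harm <- ground_truth_pmf("harmonic", domain = c(0, 20), k_truth = 10,
                           c0 = 10)
  w2 <- generate_umbrella_samples(harm, centers = 10, spring_k = 5,
                                  n_samples = 4000, seed = 6)[[1]]
  v_th <- kT / 15
  expect_lt(abs(var(w2$samples) - v_th), 3 * v_th * sqrt(2 / 400))
  ## determinism
  w3 <- generate_umbrella_samples(flat, centers = 10, spring_k = 5,
                                  n_samples = 100, seed = 42)[[1]]
  w4 <- generate_umbrella_samples(flat, centers = 10, spring_k = 5,
                                  n_samples = 100, seed = 42)[[1]]
  expect_identical(w3$samples, w4$samples)
  expect_error(generate_umbrella_samples(flat, centers = 30, spring_k = 5),
               "domain")
})

test_that("association trajectories plant reproducible labels and counts", {
  traj <- generate_association_trajectory("flat", seed = 3)
  sch <- traj$schedule
  expect_true(all(diff(sch$separation_A) <= 0))
  expect_true(all(diff(sch$cum_interfacial_to_bulk) >= 0))
  n_waters <- nrow(traj$frames[[1]]$oxygen)
  for (t in seq_along(traj$frames)) {
    ## classification against the frame geometry reproduces planted labels
    ll <- classify_layers(traj$frames[[t]], traj$shape_at_frame(t), 3.5)
    expect_identical(ll$labels, traj$labels[[t]])
    expect_equal(sch$n_interfacial_box[t],
                 sum(traj$labels[[t]] == "interfacial"))
    expect_equal(sch$n_bulk[t], sum(traj$labels[[t]] == "bulk"))
    expect_equal(nrow(traj$frames[[t]]$oxygen), n_waters)
    ## measured transitions equal the planted per-frame counts
    if (t > 1) {
      got <- count_interfacial_to_bulk(traj$labels[[t - 1]], traj$labels[[t]])
      expect_equal(got$n_interfacial_to_bulk, sch$transitions[t])
    }
  }
  ## interfacial counts fall (weakly) as the solutes approach
  ts <- layer_counts_timeseries(traj$frames, traj$shape_at_frame, 3.5)
  expect_true(all(ts$n_interfacial + ts$n_bulk == n_waters))
  expect_lt(ts$n_interfacial[nrow(ts)], max(ts$n_interfacial))
  ## static separation: no transitions planted
  still <- generate_association_trajectory("flat", separations = rep(6, 4),
                                           seed = 1)
  expect_true(all(still$schedule$transitions == 0))
  expect_error(generate_association_trajectory("flat",
                                               separations = c(2, 1),
                                               layer_cutoff = 3.5),
               "initial gap")
})

test_that("matched schedules order planted transitions concave >= flat >= convex", {
  tot <- vapply(c("concave", "flat", "convex"), function(tg) {
    traj <- generate_association_trajectory(tg, seed = 3)
    utils::tail(traj$schedule$cum_interfacial_to_bulk, 1)
  }, numeric(1))
  expect_gte(tot[["concave"]], tot[["flat"]])
  expect_gte(tot[["flat"]], tot[["convex"]])
  expect_gt(tot[["concave"]], tot[["convex"]])
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generate_association_trajectory("concave", seed = 11)
  b <- generate_association_trajectory("concave", seed = 11)
  expect_identical(a$schedule, b$schedule)
  expect_identical(a$frames[[3]]$oxygen, b$frames[[3]]$oxygen)
  expect_identical(a$frames[[3]]$hydrogen, b$frames[[3]]$hydrogen)
  t1 <- ground_truth_pmf()
  w1 <- generate_umbrella_samples(t1, centers = c(3, 4), spring_k = 25,
                                  n_samples = 200, seed = 8)
  w2 <- generate_umbrella_samples(t1, centers = c(3, 4), spring_k = 25,
                                  n_samples = 200, seed = 8)
  expect_identical(lapply(w1, `[[`, "samples"), lapply(w2, `[[`, "samples"))
})
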