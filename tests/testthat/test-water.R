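test_that("frame validation: hydrogen count and O-H bond lengths", {
  o <- matrix(c(0, 0, 0), 1, 3)
  h_ok <- array(c(0.96, 0, 0, 0, 0.96, 0), c(1, 2, 3))
  h_ok[1, 1, ] <- c(0.96, 0, 0); h_ok[1, 2, ] <- c(0, 0.96, 0)
  expect_s3_class(water_frame(o, h_ok), "water_frame")
  h_bad <- h_ok; h_bad[1, 2, ] <- c(0, 3, 0)
  expect_error(water_frame(o, h_bad), "malformed hydrogens")
  expect_error(water_frame(o, array(0.96, c(1, 1, 3))), "N x 2 x 3")
  empty <- water_frame(matrix(numeric(0), 0, 3), NULL)
  expect_equal(nrow(empty$oxygen), 0)
})

test_that("single-pair geometry: distance and angle cuts", {
  crit <- hbond_criterion()
  ## donor O-H along the O-O axis at 2.8 A: one bond
  g <- detect_hbonds(two_water_frame(2.8, 0), crit)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$donor, 1)
  expect_equal(g$edges$acceptor, 2)
  expect_equal(g$edges$r_OO, 2.8)
  ## beyond the distance cut: none
  expect_equal(nrow(detect_hbonds(two_water_frame(4.0, 0), crit)$edges), 0)
  ## perpendicular O-H: angle cut kills it
  expect_equal(nrow(detect_hbonds(two_water_frame(2.8, 90), crit)$edges), 0)
  ## just inside vs outside the 30 degree threshold
  expect_equal(nrow(detect_hbonds(two_water_frame(2.8, 29.9), crit)$edges), 1)
  expect_equal(nrow(detect_hbonds(two_water_frame(2.8, 30.1), crit)$edges), 0)
})

test_that("detector matches the all-pairs brute-force oracle, with and without a box", {
  crit <- hbond_criterion()
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(2:50, 1)
    box <- if (rep %% 2 == 0) c(11, 13, 12) else NULL
    fr <- random_frame(n, side = 11, box = box)
    got <- detect_hbonds(fr, crit)$edges
    want <- brute_force_hbonds(fr, crit)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$donor, want$donor)
      expect_equal(got$hydrogen, want$hydrogen)
      expect_equal(got$acceptor, want$acceptor)
      expect_equal(got$r_OO, want$r_OO, tolerance = 1e-12)
    }
  }
})

test_that("edge count equals total donated equals total accepted", {
  set.seed(7)
  fr <- random_frame(80, side = 13, box = c(13, 13, 13))
  g <- detect_hbonds(fr)
  expect_equal(nrow(g$edges), sum(g$donor_count))
  expect_equal(nrow(g$edges), sum(g$acceptor_count))
  expect_true(all(g$edges$donor != g$edges$acceptor))
  ## a donated hydrogen goes to at most one acceptor
  expect_false(any(duplicated(g$edges[, c("donor", "hydrogen")])))
  expect_true(all(g$donor_count <= 2))
})

test_that("mean hydrogen bonds per molecule over subsets", {
  g <- detect_hbonds(two_water_frame(2.8, 0))
  expect_equal(mean_hbonds_per_molecule(g), 1.0)   # 2 bond ends / 2 molecules
  expect_equal(mean_hbonds_per_molecule(g, 1), 1)
  expect_error(mean_hbonds_per_molecule(g, integer(0)), "empty")
  expect_error(mean_hbonds_per_molecule(g, 5), "out of range")
  empty <- detect_hbonds(two_water_frame(4.5, 0))
  expect_equal(mean_hbonds_per_molecule(empty), 0)
  set.seed(31)
  dense <- random_frame(100, side = (100 / 0.033)^(1 / 3))
  m <- mean_hbonds_per_molecule(detect_hbonds(dense))
  expect_gte(m, 0); expect_lte(m, 4)
})

test_that("local network classes follow the donor/acceptor map", {
  expect_equal(classify_local_network(2, 2), "DDAA")
  expect_equal(classify_local_network(2, 1), "DDA")
  expect_equal(classify_local_network(1, 2), "DAA")
  expect_equal(classify_local_network(1, 1), "DA")
  expect_equal(classify_local_network(0, 0), "free")
  ## combinations outside the five listed classes are 'other'
  expect_equal(classify_local_network(2, 0), "other")
  expect_equal(classify_local_network(0, 2), "other")
  expect_equal(classify_local_network(0, 1), "other")
  expect_equal(classify_local_network(c(2, 0), c(2, 0)), c("DDAA", "free"))
  expect_error(classify_local_network(-1, 0), "non-negative")
})

test_that("layer classification partitions every frame totally", {
  sph <- make_shape("sphere", radius = 5)
  o <- rbind(c(6, 0, 0), c(20, 0, 0), c(0, 0, 8.5))
  fr <- water_frame(o, random_hydrogens_for(o))
  ll <- classify_layers(fr, sph, layer_cutoff = 3.5)
  expect_equal(ll$labels, c("interfacial", "bulk", "interfacial"))
  expect_equal(sum(ll$labels == "interfacial") + sum(ll$labels == "bulk"),
               nrow(o))
  ## boundary: exactly at the cutoff is interfacial (closed boundary)
  slab <- make_shape("slab")
  o2 <- matrix(c(0, 0, 3.5), 1, 3)
  fr2 <- water_frame(o2, random_hydrogens_for(o2))
  expect_equal(classify_layers(fr2, slab, 3.5)$labels, "interfacial")
  ## inside the solute: flagged but still interfacial, partition still total
  o3 <- rbind(c(0, 0, 0), c(9, 0, 0))
  fr3 <- water_frame(o3, random_hydrogens_for(o3))
  expect_warning(ll3 <- classify_layers(fr3, sph, 3.5), "inside the solute")
  expect_equal(ll3$labels, c("interfacial", "bulk"))
})

test_that("interfacial-to-bulk transition counting and its identities", {
  b <- c("interfacial", "interfacial", "bulk", "interfacial")
  a <- c("bulk", "interfacial", "interfacial", "bulk")
  res <- count_interfacial_to_bulk(b, a)
  expect_equal(res$n_interfacial_to_bulk, 2L)
  expect_equal(res$n_bulk_to_interfacial, 1L)
  expect_equal(res$net, 1L)
  expect_equal(count_interfacial_to_bulk(b, b)$n_interfacial_to_bulk, 0L)
  all_i <- rep("interfacial", 7); all_b <- rep("bulk", 7)
  expect_equal(count_interfacial_to_bulk(all_i, all_b)$n_interfacial_to_bulk, 7L)
  ## forward + reverse bounds the net interfacial change
  set.seed(12)
  for (i in 1:20) {
    x <- sample(c("interfacial", "bulk"), 30, replace = TRUE)
    y <- sample(c("interfacial", "bulk"), 30, replace = TRUE)
    res <- count_interfacial_to_bulk(x, y)
    expect_gte(res$n_interfacial_to_bulk + res$n_bulk_to_interfacial,
               abs(sum(y == "interfacial") - sum(x == "interfacial")))
  }
  expect_error(count_interfacial_to_bulk(b, a[1:2]), "same molecules")
})

test_that("layer count time series: totals conserved, static geometry constant", {
  sph <- make_shape("sphere", radius = 4)
  set.seed(9)
  o <- matrix(runif(3 * 30, -10, 10), 30, 3)
  o <- o[signed_distance(sph, o) > 0, , drop = FALSE]
  fr <- water_frame(o, random_hydrogens_for(o))
  ts <- layer_counts_timeseries(list(fr, fr, fr), sph, 3.5)
  expect_equal(nrow(ts), 3)
  expect_true(all(ts$n_interfacial + ts$n_bulk == nrow(o)))
  expect_equal(length(unique(ts$n_interfacial)), 1)
  one <- layer_counts_timeseries(list(fr), sph, 3.5)
  expect_equal(nrow(one), 1)
  expect_error(layer_counts_timeseries(list(), sph), "at least one")
})

test_that("interfacial waters bond less than bulk near a large flat wall", {
  wall <- make_shape("slab", patch = c(40, 40), thickness = 8)
  fr <- generate_water_box(box = c(40, 40, 20), density = 0.0334,
                           seed = 9, periodic = FALSE)
  o <- sweep(fr$oxygen, 2, c(-20, -20, 0.3), "+")
  h <- fr$hydrogen
  for (k in 1:3) h[, , k] <- h[, , k] + c(-20, -20, 0.3)[k]
  fr <- water_frame(o, h)
  ll <- classify_layers(fr, wall, 3.5)
  g <- detect_hbonds(fr)
  m_int <- mean_hbonds_per_molecule(g, which(ll$labels == "interfacial"))
  m_blk <- mean_hbonds_per_molecule(g, which(ll$labels == "bulk"))
  expect_lte(m_int, m_blk)
})
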