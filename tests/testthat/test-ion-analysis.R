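test_that("rdf is zero-flagged without ions and flat for a uniform field", {
  s <- synthetic_spec(model = "rod", n_monomers = 30, bond_length = 0.5,
                      box = 31, n_frames = 2, ion_model = "uniform",
                      n_monovalent = 0, n_divalent = 0, seed = 1)
  sys <- generate_system(s)
  r0 <- compute_rdf(sys$trajectory, sys$topology)
  expect_true(r0$empty)
  expect_true(all(r0$g == 0))

  s1 <- synthetic_spec(model = "rod", n_monomers = 30, bond_length = 0.5,
                       box = 31, n_frames = 150, ion_model = "uniform",
                       n_monovalent = 200, n_divalent = 100, seed = 6)
  sys1 <- generate_system(s1)
  r1 <- compute_rdf(sys1$trajectory, sys1$topology, r_max = 3, n_bins = 200)
  tail_mean <- mean(r1$g[r1$bin_centers >= 2.5])
  expect_equal(tail_mean, 1, tolerance = 0.05)
})

test_that("rdf peaks at the planted binding shell", {
  # every ion pinned inside a thin shell around the charged sites
  s <- synthetic_spec(model = "rod", n_monomers = 20, bond_length = 0.5,
                      box = 21, n_frames = 60, frame_time = 10,
                      ion_model = "planted_bound", n_monovalent = 30,
                      binding_shell = c(0.24, 0.26),
                      dwell_tau_bound = 50, dwell_tau_unbound = 0.001,
                      seed = 13)
  sys <- generate_system(s)
  r <- compute_rdf(sys$trajectory, sys$topology, r_max = 3, n_bins = 200)
  peak <- r$bin_centers[which.max(r$g)]
  expect_lt(abs(peak - 0.25), 0.015)
})

test_that("rdf bin counting conserves the mean neighbour count", {
  s <- synthetic_spec(model = "rod", n_monomers = 12, bond_length = 0.5,
                      box = 13, n_frames = 25, ion_model = "uniform",
                      n_monovalent = 40, n_divalent = 0, seed = 3)
  sys <- generate_system(s)
  r <- compute_rdf(sys$trajectory, sys$topology, r_max = 3, n_bins = 200)
  edges <- seq(0, r$r_max, length.out = r$n_bins + 1)
  shell_vol <- 4 / 3 * pi * diff(edges^3)
  rho <- 40 / prod(sys$trajectory$box)
  recovered <- sum(r$g * rho * shell_vol)
  # direct mean count of ions within r_max per charged site
  cs <- charged_sites(sys$topology)
  direct <- mean(vapply(seq_len(25), function(i) {
    d <- min_image_dist(sys$trajectory$polymer[cs, , i],
                        sys$trajectory$ion_coords[, , i],
                        sys$trajectory$box)
    sum(d < r$r_max) / length(cs)
  }, numeric(1)))
  expect_equal(recovered, direct, tolerance = 1e-10)
})

test_that("rdf range is truncated when the box is too small", {
  s <- synthetic_spec(model = "fjc", n_monomers = 10, bond_length = 0.3,
                      box = 4, n_frames = 3, ion_model = "uniform",
                      n_monovalent = 10, seed = 2)
  sys <- generate_system(s)
  expect_warning(r <- compute_rdf(sys$trajectory, sys$topology, r_max = 3),
                 "truncat")
  expect_lte(r$r_max, 2)
})

test_that("binding cutoff separates 0.49 from 0.51 nm", {
  cfg <- list(sites = matrix(c(5, 5, 5), ncol = 3), box = rep(10, 3))
  near <- config_system(modifyList(cfg, list(ions = matrix(c(5.49, 5, 5),
                                                           ncol = 3))))
  far <- config_system(modifyList(cfg, list(ions = matrix(c(5.51, 5, 5),
                                                          ncol = 3))))
  expect_equal(count_bound(near$tr, near$top), 1L)
  expect_equal(count_bound(far$tr, far$top), 0L)
})

test_that("bound/neutralized/bridged match brute-force oracles on 100 configs", {
  for (seed in 1:100) {
    cfg <- random_config(seed)
    sys <- config_system(cfg)
    ns <- nrow(cfg$sites); ni <- nrow(cfg$ions)
    # O(n^2) all-pairs oracle with explicit minimum image
    adj <- matrix(FALSE, ns, max(ni, 1))
    if (ni > 0) {
      for (a in seq_len(ns)) for (b in seq_len(ni)) {
        adj[a, b] <- brute_min_image(cfg$sites[a, ], cfg$ions[b, ],
                                     cfg$box) <= 0.5
      }
    }
    bound_oracle <- if (ni > 0) sum(colSums(adj) >= 1) else 0L
    neut_oracle <- sum(rowSums(adj) >= 1) / ns
    expect_identical(count_bound(sys$tr, sys$top), as.integer(bound_oracle))
    expect_equal(neutralized_fraction(sys$tr, sys$top), neut_oracle)
    # graph oracle: a site is bridged iff adjacent to an ion of degree >= 2
    bf <- bridging_fraction(sys$tr, sys$top)
    if (neut_oracle == 0) {
      expect_true(is.na(bf))
    } else {
      deg2 <- colSums(adj) >= 2
      bridged <- sum(apply(adj[, deg2, drop = FALSE], 1, any) &
                       rowSums(adj) >= 1)
      expect_equal(bf, bridged / sum(rowSums(adj) >= 1))
    }
  }
})

test_that("planted occupancy yields the exact neutralized fraction", {
  set.seed(5)
  sites <- cbind(seq(1, 10, by = 1), 5, 5)   # 10 sites >= 1 nm apart
  occupied <- c(1, 4, 6, 9)                  # plant ions at 40% of sites
  ions <- sweep(sites[occupied, ], 2, c(0.3, 0, 0), "+")
  sys <- config_system(list(sites = sites, ions = ions, box = rep(20, 3)))
  expect_equal(neutralized_fraction(sys$tr, sys$top), 0.4)
  expect_equal(count_bound(sys$tr, sys$top), 4L)
})

test_that("a shared cation bridges both its sites", {
  sites <- rbind(c(4.7, 5, 5), c(5.3, 5, 5))
  ion <- matrix(c(5, 5, 5), ncol = 3)
  sys <- config_system(list(sites = sites, ions = ion, box = rep(10, 3)))
  expect_equal(bridging_fraction(sys$tr, sys$top), 1.0)
  # one distinct cation per site: nothing bridges
  sites2 <- rbind(c(2, 5, 5), c(8, 5, 5))
  ions2 <- rbind(c(2.3, 5, 5), c(8.3, 5, 5))
  sys2 <- config_system(list(sites = sites2, ions = ions2, box = rep(10, 3)))
  expect_equal(bridging_fraction(sys2$tr, sys2$top), 0.0)
})

test_that("interaction fractions survive relabeling and rigid motion", {
  # compact configuration centred in a large box, so no pair wraps and a
  # rigid motion of the raw coordinates preserves every distance
  set.seed(7)
  cfg <- random_config(7)
  cfg$sites <- sweep(cfg$sites, 2, c(8, 8, 8), "+")
  cfg$ions <- sweep(cfg$ions, 2, c(8, 8, 8), "+")
  cfg$box <- rep(20, 3)
  sys <- config_system(cfg)
  base_n <- neutralized_fraction(sys$tr, sys$top)
  base_b <- bridging_fraction(sys$tr, sys$top)
  # relabel ions
  perm <- sample(nrow(cfg$ions))
  sys2 <- config_system(modifyList(cfg, list(ions = cfg$ions[perm, ,
                                                             drop = FALSE])))
  expect_equal(neutralized_fraction(sys2$tr, sys2$top), base_n)
  expect_equal(bridging_fraction(sys2$tr, sys2$top), base_b)
  # rigid rotation+translation of the whole frame, re-centred in the box
  all_pts <- rbind(cfg$sites, cfg$ions)
  moved <- random_rigid(all_pts, seed = 2)
  moved <- sweep(moved, 2, c(10, 10, 10) - colMeans(moved), "+")
  cfg3 <- list(sites = moved[seq_len(nrow(cfg$sites)), , drop = FALSE],
               ions = moved[-seq_len(nrow(cfg$sites)), , drop = FALSE],
               box = rep(20, 3))
  sys3 <- config_system(cfg3)
  expect_equal(neutralized_fraction(sys3$tr, sys3$top), base_n)
  expect_equal(bridging_fraction(sys3$tr, sys3$top), base_b)
})

test_that("survival curve of a single event is a step function", {
  # one ion within cutoff for frames 3..7 of 12 (k = 5 frames), then away
  sites <- matrix(c(5, 5, 5), ncol = 3)
  frames <- lapply(1:12, function(i) {
    if (i >= 3 && i <= 7) matrix(c(5.3, 5, 5), ncol = 3) else
      matrix(c(1, 1, 1), ncol = 3)
  })
  atoms <- data.frame(atom_id = 1:2, atom_label = c("BB", "SC"),
                      chain_id = "A", monomer_index = c(0L, 1L),
                      role = c("backbone_anchor", "charged_site"),
                      formal_charge = c(0, -1), stringsAsFactors = FALSE)
  top <- poly_topology(atoms, dx = 0.5)
  poly_frames <- rep(list(rbind(c(5, 5, 4), sites[1, ])), 12)
  tr <- traj_from_frames(poly_frames, box = 10, frame_time = 10,
                         ions = ion_set(1), ion_frames = frames)
  expect_warning(fit <- residence_time(tr, top), "unreliable")
  expect_equal(fit$n_events, 1L)
  expect_equal(fit$censored_count, 0L)
  # S drops from 1 to 0 at the event duration k * frame_time = 0.05 ns
  expect_equal(fit$survival[fit$survival_lags < 0.05 - 1e-9], rep(1, 5))
  expect_equal(fit$survival[abs(fit$survival_lags - 0.05) < 1e-9], 0)
  expect_true(all(diff(fit$survival) <= 1e-12))
})

test_that("an ion bound for the whole run is censored, not fitted", {
  sites <- matrix(c(5, 5, 5), ncol = 3)
  atoms <- data.frame(atom_id = 1:2, atom_label = c("BB", "SC"),
                      chain_id = "A", monomer_index = c(0L, 1L),
                      role = c("backbone_anchor", "charged_site"),
                      formal_charge = c(0, -1), stringsAsFactors = FALSE)
  top <- poly_topology(atoms, dx = 0.5)
  poly_frames <- rep(list(rbind(c(5, 5, 4), sites[1, ])), 10)
  # ion 1 always bound; ion 2 bound frames 2..4 only
  ionf <- lapply(1:10, function(i) {
    rbind(c(5.2, 5, 5),
          if (i >= 2 && i <= 4) c(5, 5.2, 5) else c(1, 1, 1))
  })
  tr <- traj_from_frames(poly_frames, box = 10, frame_time = 10,
                         ions = ion_set(2), ion_frames = ionf)
  expect_warning(fit <- residence_time(tr, top), "unreliable")
  expect_equal(fit$censored_count, 1L)
  expect_equal(fit$n_events, 1L)
  expect_equal(fit$durations_ns, 0.03)
})

test_that("gap tolerance merges brief excursions when requested", {
  sites <- matrix(c(5, 5, 5), ncol = 3)
  atoms <- data.frame(atom_id = 1:2, atom_label = c("BB", "SC"),
                      chain_id = "A", monomer_index = c(0L, 1L),
                      role = c("backbone_anchor", "charged_site"),
                      formal_charge = c(0, -1), stringsAsFactors = FALSE)
  top <- poly_topology(atoms, dx = 0.5)
  poly_frames <- rep(list(rbind(c(5, 5, 4), sites[1, ])), 12)
  bound_pattern <- c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                     FALSE, FALSE, FALSE, FALSE, FALSE)
  ionf <- lapply(1:12, function(i) {
    matrix(if (bound_pattern[i]) c(5.3, 5, 5) else c(1, 1, 1), ncol = 3)
  })
  tr <- traj_from_frames(poly_frames, box = 10, frame_time = 10,
                         ions = ion_set(1), ion_frames = ionf)
  expect_warning(strict <- residence_time(tr, top), "unreliable")
  expect_equal(strict$n_events, 2L)
  expect_warning(merged <- residence_time(tr, top, gap_tolerance = 1L),
                 "unreliable")
  expect_equal(merged$n_events, 1L)
  expect_equal(merged$durations_ns, 0.07)
})

test_that("hydration numbers report exact planted counts", {
  # single ion keeps shells from overlapping, so counts are exact
  s <- synthetic_spec(model = "rod", n_monomers = 20, bond_length = 0.5,
                      box = 21, n_frames = 600, frame_time = 10,
                      ion_model = "planted_bound", n_monovalent = 1,
                      waters_per_ion = 5, n_decoy_waters = 10, seed = 29)
  sys <- generate_system(s)
  h <- hydration_numbers(sys$trajectory, sys$topology)
  assigned <- h$per_peak[h$per_peak$n > 0, ]
  expect_gt(sum(assigned$n), 0)
  expect_true(all(assigned$mean == 5))
  expect_true(all(assigned$sd[assigned$n > 1] == 0))

  # no waters planted at all
  s0 <- synthetic_spec(model = "rod", n_monomers = 20, bond_length = 0.5,
                       box = 21, n_frames = 40, frame_time = 10,
                       ion_model = "planted_bound", n_monovalent = 1,
                       waters_per_ion = 0, n_decoy_waters = 6, seed = 31)
  sys0 <- generate_system(s0)
  h0 <- hydration_numbers(sys0$trajectory, sys0$topology)
  nonempty <- h0$per_peak$n > 0
  expect_true(all(h0$per_peak$mean[nonempty] == 0))
})

test_that("mixed planted hydration counts give the planted mean and sd", {
  # three well-separated ions in the first shell with 4, 5, 6 waters each
  set.seed(11)
  sites <- rbind(c(3, 10, 10), c(10, 10, 10), c(17, 10, 10))
  ions <- rbind(c(3.3, 10, 10), c(10.3, 10, 10), c(17.3, 10, 10))
  waters <- do.call(rbind, lapply(1:3, function(j) {
    nw <- c(4, 5, 6)[j]
    sweep(matrix(stats::runif(3 * nw, -0.1, 0.1), ncol = 3), 2,
          ions[j, ], "+")
  }))
  sys <- config_system(list(sites = sites, ions = ions, box = rep(20, 3)))
  tr <- traj_from_frames(list(sys$tr$polymer[, , 1]), box = 20,
                         ions = sys$tr$ions, ion_frames = list(ions),
                         water_frames = list(waters))
  h <- hydration_numbers(tr, sys$top)
  first <- h$per_peak[1, ]
  expect_equal(first$n, 3L)
  expect_equal(first$mean, 5.0)
  expect_equal(first$sd, stats::sd(c(4, 5, 6)))
})
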