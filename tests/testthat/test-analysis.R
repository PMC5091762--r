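test_that("shear-modulus bounds match an independent evaluation", {
  p <- preset_parameters("stoodley2002")
  # single-phase limit: c2 = 0 collapses the lower bound onto the matrix
  b0 <- hashin_shtrikman_bounds(p$props_eps, p$props_bact, 0)
  expect_equal(b0$G_l, 0.33)
  # identical phases: both bounds equal the common modulus
  bid <- hashin_shtrikman_bounds(p$props_eps, p$props_eps, 0.4)
  expect_equal(bid$G_l, bid$G_u)
  expect_equal(bid$G_l, 0.33)

  # frozen value computed by hand from the bound formula before the
  # implementation existed
  b26 <- hashin_shtrikman_bounds(p$props_eps, p$props_bact, 0.26)
  expect_equal(b26$G_l, 0.5742898, tolerance = 1e-6)

  for (c2 in c(0.26, 0.42, 0.55, 0.9)) {
    b <- hashin_shtrikman_bounds(p$props_eps, p$props_bact, c2)
    ref <- hs_reference(0.33, 1.0, 33.33, 100.0, c2)
    expect_equal(c(b$G_l, b$G_u), ref, tolerance = 1e-12)
    expect_lte(b$G_l, b$G_u)
    expect_gte(b$G_l, 0.33)
    expect_lte(b$G_u, 33.33)
  }
  expect_error(hashin_shtrikman_bounds(p$props_eps, p$props_bact, 1.2), "c2")
})

test_that("tangent stiffness recovers analytic slopes", {
  g <- seq(0.01, 0.3, by = 0.01)
  expect_equal(tangent_stiffness(g, 2 * g, window = 5), rep(2, length(g)))
  expect_equal(tangent_stiffness(g, rep(3.3, length(g))), rep(0, length(g)))
  gt <- tangent_stiffness(g, g^2, window = 5)
  expect_equal(gt[which.min(abs(g - 0.1))], 0.2, tolerance = 0.02)
  expect_error(tangent_stiffness(rev(g), 2 * g), "increasing")
  expect_error(tangent_stiffness(g[1:2], g[1:2]), "3 points")
})

test_that("localization map categorizes springs and never reverts", {
  sim <- preset_study("stoodley2002", "uniform", 0.42, seed = 11L,
                      gamma_max = 0.35, snapshot_gammas = c(0.05, 0.2, 0.35))
  m05 <- localization_map(sim, 0.05)
  m20 <- localization_map(sim, 0.2)
  m35 <- localization_map(sim, 0.35)
  expect_setequal(unique(m05$category),
                  intersect(unique(m05$category),
                            c("pristine", "unfolding", "ruptured")))
  # irreversibility: unfold counts only grow between snapshots
  expect_true(all(m20$m >= m05$m))
  expect_true(all(m35$m >= m20$m))
  expect_error(localization_map(sim, 0.123), "no snapshot")

  # a run without any events is entirely pristine
  net <- build_lattice(NULL, spacing = 1 / 14)
  quiet <- run_shear_simulation(net, threshold_spec(1e3, 1e2),
                                load_program(0.1, 0.01),
                                snapshot_gammas = 0.1)
  mq <- localization_map(quiet, 0.1)
  expect_true(all(mq$category == "pristine"))
})

test_that("detachment detection agrees with constructed isolation", {
  # pristine network: nothing detached
  fx <- make_fixture("one_inclusion")
  spec <- threshold_spec(1e-4, 0.2e-4, rupture_value = 5e-4)
  st <- spring_states(fx$network, spec)
  expect_length(detect_detached_bacteria(fx$network, st), 0)

  # manually rupture every EPS spring touching the inclusion: exactly that
  # bacterium is reported, and an independent flood fill agrees
  s <- fx$network$springs
  bn <- unique(c(s$i[s$bacterium > 0], s$j[s$bacterium > 0]))
  ring <- s$phase == "EPS" & (s$i %in% bn | s$j %in% bn)
  st$intact[ring] <- FALSE
  det <- detect_detached_bacteria(fx$network, st)
  expect_equal(det, 1L)

  # oracle: breadth-first search from the bottom over intact springs
  n <- fx$network$n_nodes
  adj <- vector("list", n)
  for (sp in which(st$intact)) {
    adj[[s$i[sp]]] <- c(adj[[s$i[sp]]], s$j[sp])
    adj[[s$j[sp]]] <- c(adj[[s$j[sp]]], s$i[sp])
  }
  reach <- rep(FALSE, n)
  queue <- fx$network$bottom_nodes
  reach[queue] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- adj[[v]]
    new <- nb[!reach[nb]]
    reach[new] <- TRUE
    queue <- c(queue, new)
  }
  expect_false(any(reach[bn]))
})

test_that("diagonal band summary separates in-band and off-band springs", {
  sim <- preset_study("stoodley2002", "uniform", 0.42, seed = 11L,
                      gamma_max = 0.35)
  map <- localization_map(sim, 0.35)
  bd <- band_unfolding_density(map, sim$network)
  expect_gt(bd$n_in, 0)
  expect_gt(bd$n_off, 0)
  expect_true(bd$in_band >= 0 && bd$in_band <= 1)
  expect_true(bd$off_band >= 0 && bd$off_band <= 1)
})
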