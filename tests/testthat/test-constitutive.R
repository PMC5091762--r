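test_that("threshold sampling respects the uniform law and sorting", {
  spec <- threshold_spec(1.25e-5, 0.25e-5, seed = 2L)
  thr <- sample_thresholds(spec, 500L)
  expect_true(all(thr >= 1.0e-5 & thr <= 1.5e-5))
  expect_true(all(apply(thr, 1, function(x) all(diff(x) >= 0))))

  # Monte-Carlo check of the law: empirical extremes within 0.5 % of bounds
  big <- sample_thresholds(threshold_spec(1.25e-5, 0.25e-5, seed = 5L), 12500L)
  expect_lt(abs(min(big) - 1.0e-5) / 1.25e-5, 0.005)
  expect_lt(abs(max(big) - 1.5e-5) / 1.25e-5, 0.005)

  # degenerate half-width: all thresholds equal the mean
  d <- sample_thresholds(threshold_spec(2e-3, 0, rupture_value = 4e-3), 10L)
  expect_true(all(d == 2e-3))

  # determinism
  expect_identical(sample_thresholds(spec, 50L), sample_thresholds(spec, 50L))
})

test_that("threshold spec invariants reject inconsistent values", {
  expect_error(threshold_spec(1e-5, 2e-5), "unfold_mean")
  expect_error(threshold_spec(1e-3, 1e-4, rupture_value = 1e-3), "rupture_value")
  expect_error(threshold_spec(1e-3, 1e-4, beta = 1), "beta")
})

test_that("series sub-spring law has the closed-form limits", {
  k <- 2.3
  expect_equal(effective_stiffness(0, k, beta = 100), k)
  expect_equal(effective_stiffness(8, k, beta = 100), 100 * k)
  # large-beta limit at m = 4 is 8/(8-4) = 2
  expect_equal(effective_stiffness(4, k, beta = 1e12), 2 * k, tolerance = 1e-9)
  # strictly increasing in m
  ks <- effective_stiffness(0:8, k, beta = 8)
  expect_true(all(diff(ks) > 0))
  expect_error(effective_stiffness(9, k), "0..8")
  expect_error(effective_stiffness(-1, k), "0..8")
})

test_that("event rules: one unfold per sweep, nine events over a ramp", {
  fx <- make_fixture("strip")
  spec <- threshold_spec(1e-4, 0.2e-4, rupture_value = 5e-4, seed = 1L)
  st <- spring_states(fx$network, spec, grip_layers = FALSE)
  sp <- which(st$eps)[1]

  # energies below every threshold: no events
  ev <- process_events(st, energies = rep(0, length(st$m)))
  expect_equal(nrow(ev$events), 0L)

  # drive one spring's energy up; exactly one unfold per sweep, in order,
  # then one rupture: nine events in total
  log <- character(0)
  for (i in 1:12) {
    en <- rep(0, length(st$m))
    en[sp] <- 1e-3  # above all thresholds and the rupture value
    ev <- process_events(st, energies = en)
    st <- ev$states
    if (nrow(ev$events)) {
      expect_equal(ev$events$spring, sp)
      log <- c(log, ev$events$type)
    }
  }
  expect_equal(log, c(rep("unfold", 8), "rupture"))
  expect_false(st$intact[sp])
  expect_equal(st$k_eff[sp], 0)

  # ruptured spring emits nothing further
  en <- rep(1e-3, length(st$m))
  ev2 <- process_events(st, energies = en)
  expect_false(sp %in% ev2$events$spring)
})

test_that("rupture rule fires just above the threshold at m = 8", {
  fx <- make_fixture("strip")
  spec <- threshold_spec(1e-4, 0.2e-4, rupture_value = 5e-4, seed = 1L)
  st <- spring_states(fx$network, spec, grip_layers = FALSE)
  sp <- which(st$evolving)[2]
  st$m[sp] <- 8L
  en <- rep(0, length(st$m)); en[sp] <- 5e-4 * 1.01
  ev <- process_events(st, energies = en)
  expect_equal(ev$events$type, "rupture")
  expect_equal(ev$events$spring, sp)
})

test_that("bacterial springs never carry thresholds or events", {
  spec <- morphology_spec("uniform", 0.4, seed = 2L)
  mic <- generate_microstructure(spec, grid_shape = c(96L, 96L))
  net <- build_lattice(mic, spacing = 1 / 20)
  st <- spring_states(net, threshold_spec(1e-4, 0.2e-4), grip_layers = FALSE)
  bact <- net$springs$phase == "bacterium"
  expect_true(any(bact))
  expect_true(all(is.na(st$thresholds[bact, ])))
  ev <- process_events(st, energies = rep(1, length(st$m)))
  expect_length(intersect(ev$events$spring, which(bact)), 0)
})

test_that("grip layers exclude plate-adjacent springs from evolution", {
  fx <- make_fixture("homogeneous")
  spec <- threshold_spec(1e-4, 0.2e-4)
  st <- spring_states(fx$network, spec, grip_layers = TRUE)
  grip_nodes <- c(fx$network$bottom_nodes, fx$network$top_nodes)
  s <- fx$network$springs
  touches <- s$i %in% grip_nodes | s$j %in% grip_nodes
  expect_true(all(!st$evolving[touches]))
  expect_true(all(st$evolving[!touches & st$eps]))
})
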