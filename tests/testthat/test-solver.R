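test_that("assembled operator is symmetric PSD and handles a single spring", {
  fx <- make_fixture("strip")
  spec <- threshold_spec(1e-4, 0.2e-4)
  st <- spring_states(fx$network, spec, grip_layers = FALSE)
  sys <- assemble_system(fx$network, st)
  A <- as.matrix(sys$K)
  expect_equal(max(abs(A - t(A))), 0)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10 * max(ev)))

  # one horizontal spring: reduced system is scalar with stiffness k
  tri <- make_fixture("triangle")$network
  tri$springs <- tri$springs[1, ]  # spring 1-2 along x
  st1 <- list(k_eff = tri$springs$k, intact = TRUE, eps = TRUE,
              evolving = TRUE)
  sys1 <- assemble_system(tri, st1)
  dof_x2 <- 3L  # node 2, x
  expect_equal(as.numeric(sys1$K[dof_x2, dof_x2]), tri$springs$k[1])
})

test_that("solver matches brute-force energy minimization on tiny fixtures", {
  # equilateral triangle under confined shear
  for (name in c("triangle", "strip")) {
    net <- make_fixture(name)$network
    spec <- threshold_spec(1e-4, 0.2e-4)
    st <- spring_states(net, spec, grip_layers = FALSE)
    gamma <- 0.07
    eq <- solve_increment(net, st, 0, gamma)
    cons_nodes <- c(net$bottom_nodes, net$top_nodes)
    cons <- sort(c(2L * cons_nodes - 1L, 2L * cons_nodes))
    u_cons <- numeric(length(cons))
    u_cons[match(2L * net$top_nodes - 1L, cons)] <- gamma * net$height
    u_star <- minimize_energy(net, st$k_eff, cons, u_cons)
    scale <- max(abs(u_star), 1e-30)
    expect_lt(max(abs(eq$u - u_star)) / scale, 1e-8)
  }
})

test_that("confined shear of a homogeneous slab is near-uniform simple shear", {
  # wide slab so the traction-free lateral edges do not bias the interior
  net <- build_lattice(NULL, spacing = 1 / 12, width = 16, height = 1)
  spec <- threshold_spec(1e-4, 0.2e-4)
  st <- spring_states(net, spec)
  gamma <- 0.01
  eq <- solve_increment(net, st, 0, gamma)

  # tau/gamma equals the calibrated network shear modulus (3/8) E within 3 %
  G_net <- sqrt(3) / 4 * calibrate_spring_constant(net$props_eps$E)
  expect_lt(abs(eq$tau / gamma - G_net) / G_net, 0.03)

  # interior elongations match the affine simple-shear field within 3 %
  s <- net$springs
  mx <- (net$nodes[s$i, 1] + net$nodes[s$j, 1]) / 2
  my <- (net$nodes[s$i, 2] + net$nodes[s$j, 2]) / 2
  dx <- (net$nodes[s$j, 1] - net$nodes[s$i, 1]) / s$rest
  dy <- (net$nodes[s$j, 2] - net$nodes[s$i, 2]) / s$rest
  interior <- mx > 2 & mx < 14 & my > 0.2 & my < 0.8 & abs(dy) > 0.1
  e_affine <- gamma * s$rest * dx * dy
  expect_lt(max(abs(eq$elongation[interior] - e_affine[interior]) /
                  max(abs(e_affine[interior]))), 0.03)

  # equal strains give a zero increment
  eq2 <- solve_increment(net, st, gamma, gamma)
  expect_equal(max(abs(eq2$du)), 0)

  # global force balance: top and bottom horizontal reactions cancel
  top_fx <- sum(eq$reactions[2L * net$top_nodes - 1L])
  bot_fx <- sum(eq$reactions[2L * net$bottom_nodes - 1L])
  expect_lt(abs(top_fx + bot_fx) / abs(top_fx), 1e-8)
})

test_that("a rigid inclusion concentrates force near the stiff phase", {
  fx <- make_fixture("one_inclusion")
  spec <- threshold_spec(1e-4, 0.2e-4)
  st <- spring_states(fx$network, spec)
  eq <- solve_increment(fx$network, st, 0, 0.02)
  s <- fx$network$springs
  mx <- (fx$network$nodes[s$i, 1] + fx$network$nodes[s$j, 1]) / 2
  my <- (fx$network$nodes[s$i, 2] + fx$network$nodes[s$j, 2]) / 2
  r <- sqrt((mx - 0.5)^2 + (my - fx$network$height / 2)^2)
  near <- r < 0.28 & my > 0.2 & my < 0.8  # in or next to the inclusion
  far <- s$phase == "EPS" & mx < 0.2 & my > 0.2 & my < 0.8
  expect_gt(max(abs(eq$force[near])), 1.5 * max(abs(eq$force[far])))
})

test_that("energy bookkeeping has the stated closed forms", {
  st <- list(k_base = 1, k_eff = 1, intact = TRUE, psi = 0)
  # spring k = 1 stretched to elongation 2: psi = 2
  expect_equal(update_energies(st, 2, mode = "base")$psi, 2)
  expect_equal(update_energies(st, 2, mode = "stored")$psi, 2)
  # zero increment leaves accumulating modes unchanged
  st$psi <- 0.7
  expect_equal(update_energies(st, 2, "work", elongation_prev = 2)$psi, 0.7)
  expect_equal(update_energies(st, 2, "increment", elongation_prev = 2)$psi, 0.7)
  # work mode is path-independent over a fixed-stiffness ramp
  st$psi <- 0
  e_grid <- seq(0, 2, length.out = 101)
  for (i in 2:101) {
    st <- update_energies(st, e_grid[i], "work", elongation_prev = e_grid[i - 1])
  }
  expect_equal(st$psi, 2, tolerance = 1e-12)
  # the literal increment form shrinks with refinement: N equal steps sum
  # to psi_exact / N
  st$psi <- 0
  for (i in 2:101) {
    st <- update_energies(st, e_grid[i], "increment",
                          elongation_prev = e_grid[i - 1])
  }
  expect_equal(st$psi, 2 / 100, tolerance = 1e-12)
})

test_that("without events the response is exactly linear and reproducible", {
  net <- build_lattice(NULL, spacing = 1 / 14, width = 1, height = 1)
  # thresholds far above anything reachable: no unfolding, no rupture
  spec <- threshold_spec(1e3, 1e2, seed = 3L)
  sim <- run_shear_simulation(net, spec, load_program(0.2, 0.01))
  st <- sim$steps
  expect_equal(sum(st$n_unfold_events), 0)
  slope <- st$tau / st$gamma
  expect_lt(diff(range(slope)) / mean(slope), 1e-10)
  expect_true(all(st$residual <= 1e-8 * max(abs(st$tau)) + 1e-12))

  sim2 <- run_shear_simulation(net, spec, load_program(0.2, 0.01))
  expect_identical(sim$steps, sim2$steps)
})

test_that("full runs are seed-deterministic with monotone damage", {
  sim <- preset_study("korstgens2001", "uniform", 0.42, seed = 4L,
                      gamma_max = 0.2)
  sim2 <- preset_study("korstgens2001", "uniform", 0.42, seed = 4L,
                       gamma_max = 0.2)
  expect_identical(sim$steps, sim2$steps)
  expect_identical(sim$events, sim2$events)

  st <- sim$steps
  expect_true(all(diff(st$n_ruptured) >= 0))
  expect_true(all(diff(st$n_unfold_events) >= 0))
  # per-spring caps: at most 8 unfolds and 1 rupture
  ev <- sim$events
  n_unf <- table(ev$spring[ev$type == "unfold"])
  expect_true(all(n_unf <= 8))
  n_rup <- table(ev$spring[ev$type == "rupture"])
  expect_true(all(n_rup <= 1))
  # no bacterial spring ever unfolds or ruptures
  bact <- which(sim$network$springs$phase == "bacterium")
  expect_length(intersect(unique(ev$spring), bact), 0)
})

test_that("load program validates its invariants", {
  expect_error(load_program(0.6), "gamma_max")
  expect_error(load_program(0.3, 0), "delta_gamma")
  expect_error(load_program(0.3, 0.4), "delta_gamma")
})
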