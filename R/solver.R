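#' Loading program for confined shear
#'
#' Quasi-static program: the applied engineering shear strain gamma (top
#' plate displacement / network height) is raised from `delta_gamma` to
#' `gamma_max` in equal increments, with full re-equilibration and event
#' processing at every step.  Biofilms are reported to sustain shear
#' strains up to about 50%, so `gamma_max` is capped at 0.5.
#'
#' @param gamma_max final shear strain (dimensionless), in (0, 0.5].
#' @param delta_gamma strain increment, in (0, gamma_max].
#' @param mode only `"confined_shear"` is implemented: bottom plate fixed,
#'   top plate displaced horizontally with vertical motion suppressed.
#' @return object of class `load_program`.
#' @export
load_program <- function(gamma_max, delta_gamma = 0.001,
                         mode = "confined_shear") {
  mode <- match.arg(mode)
  if (!(delta_gamma > 0 && delta_gamma <= gamma_max)) {
    stop("need 0 < delta_gamma <= gamma_max")
  }
  if (gamma_max > 0.5) stop("'gamma_max' must not exceed 0.5")
  structure(list(gamma_max = gamma_max, delta_gamma = delta_gamma,
                 mode = mode),
            class = "load_program")
}

# --- internal geometry/dof helpers -----------------------------------------

.dof_x <- function(node) 2L * node - 1L
.dof_y <- function(node) 2L * node

# sparse incidence operator B (n_springs x 2 n_nodes): (B u)_s is the axial
# elongation of spring s for nodal displacement u
.incidence <- function(network) {
  s <- network$springs
  dx <- (network$nodes[s$j, 1L] - network$nodes[s$i, 1L]) / s$rest
  dy <- (network$nodes[s$j, 2L] - network$nodes[s$i, 2L]) / s$rest
  ns <- nrow(s)
  rows <- rep(seq_len(ns), 4L)
  cols <- c(.dof_x(s$i), .dof_y(s$i), .dof_x(s$j), .dof_y(s$j))
  vals <- c(-dx, -dy, dx, dy)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(ns, 2L * network$n_nodes))
}

# nodes whose connected component (through intact springs) contains no
# boundary-constrained node; they carry no load path and are pinned at zero
.floating_nodes <- function(network, intact) {
  s <- network$springs
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = FALSE)
  if (any(intact)) {
    g <- igraph::add_edges(g, rbind(s$i[intact], s$j[intact]))
  }
  comp <- igraph::components(g)$membership
  anchored <- unique(comp[c(network$bottom_nodes, network$top_nodes)])
  which(!(comp %in% anchored))
}

# TRUE when no intact path connects the top to the bottom boundary
.load_path_broken <- function(network, intact) {
  s <- network$springs
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = FALSE)
  if (any(intact)) {
    g <- igraph::add_edges(g, rbind(s$i[intact], s$j[intact]))
  }
  comp <- igraph::components(g)$membership
  length(intersect(comp[network$top_nodes], comp[network$bottom_nodes])) == 0L
}

#' Assemble the linear elastic operator of the network
#'
#' Direct-stiffness assembly: each intact spring of stiffness `k_eff` and
#' unit direction d contributes `k_eff (d %o% d)` blocks, giving a
#' symmetric positive semi-definite operator `K = t(B) diag(k) B` with `B`
#' the axial incidence operator.  Ruptured springs contribute nothing.
#' Also returns the degree-of-freedom partition for confined shear (bottom
#' and top nodes constrained) and flags floating nodes — nodes left without
#' any intact path to a constrained boundary — which are pinned with zero
#' load so that the reduced system stays definite after rupture.
#'
#' @param network a `lattice_network`.
#' @param states a `spring_states` covering all springs.
#' @return list with `K` (sparse 2n x 2n), `B`, `free`, `constrained`
#'   (dof index vectors), `pinned_nodes`, `top_x_dofs`.
#' @export
assemble_system <- function(network, states) {
  stopifnot(inherits(network, "lattice_network"),
            length(states$k_eff) == nrow(network$springs))
  B <- .incidence(network)
  k <- states$k_eff * states$intact
  K <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(k)) %*% B)
  pinned <- if (all(states$intact)) integer(0) else
    .floating_nodes(network, states$intact)
  bnd <- c(network$bottom_nodes, network$top_nodes)
  cons_nodes <- union(bnd, pinned)
  cons <- sort(c(.dof_x(cons_nodes), .dof_y(cons_nodes)))
  free <- setdiff(seq_len(2L * network$n_nodes), cons)
  list(K = K, B = B, free = free, constrained = cons,
       pinned_nodes = pinned, top_x_dofs = .dof_x(network$top_nodes))
}

# generic constrained solve: K u = 0 on free dofs with u[cons] prescribed.
# A tiny diagonal shift (1e-11 of the largest diagonal) keeps the reduced
# operator definite in the presence of isolated floppy modes; those carry
# no load, so the perturbation is far below the solver tolerance.
.solve_bc <- function(K, cons, u_cons, n_dof) {
  free <- setdiff(seq_len(n_dof), cons)
  u <- numeric(n_dof)
  u[cons] <- u_cons
  reg <- 1e-11 * max(Matrix::diag(K), .Machine$double.xmin)
  Kff <- K[free, free, drop = FALSE] + Matrix::Diagonal(length(free), reg)
  rhs <- -K[free, cons, drop = FALSE] %*% u[cons]
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                 error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  u[free] <- as.numeric(Matrix::solve(ch, rhs))
  r <- as.numeric(K %*% u)
  list(u = u, r = r, free = free,
       residual = if (length(free)) max(abs(r[free])) else 0)
}

#' Uniaxial tension test of a network
#'
#' Applies a vertical strain between frictionless rigid platens (bottom
#' nodes held at uy = 0, top nodes at uy = strain * H, horizontal motion
#' free everywhere, one bottom node pinned against rigid translation) and
#' measures the emergent Young's modulus from the platen reactions and the
#' emergent Poisson's ratio from the lateral contraction of the interior
#' (fitted as the slope of ux against x over the central rows, which
#' avoids platen-edge effects).
#'
#' @param network a `lattice_network`.
#' @param strain applied axial strain (default 0.01).
#' @return list with `E` (N/m^2), `nu`, `residual`.
#' @export
uniaxial_test <- function(network, strain = 0.01) {
  states <- list(k_eff = network$springs$k,
                 intact = rep(TRUE, nrow(network$springs)))
  B <- .incidence(network)
  K <- Matrix::crossprod(Matrix::Diagonal(x = sqrt(states$k_eff)) %*% B)
  n_dof <- 2L * network$n_nodes
  H <- network$height
  cons <- c(.dof_y(network$bottom_nodes), .dof_y(network$top_nodes),
            .dof_x(network$bottom_nodes[1L]))
  u_cons <- c(rep(0, length(network$bottom_nodes)),
              rep(strain * H, length(network$top_nodes)), 0)
  sol <- .solve_bc(K, cons, u_cons, n_dof)
  if (is.null(sol)) stop("singular system in uniaxial test")
  sigma <- sum(sol$r[.dof_y(network$top_nodes)]) /
    (network$width * network$thickness)
  E_eff <- sigma / strain
  # lateral strain from interior nodes (central half of the rows)
  y <- network$nodes[, 2L]
  mid <- which(y > 0.25 * H & y < 0.75 * H)
  ux <- sol$u[.dof_x(mid)]
  eps_x <- stats::coef(stats::lm(ux ~ network$nodes[mid, 1L]))[[2L]]
  list(E = E_eff, nu = -eps_x / strain, residual = sol$residual)
}

# degree-of-freedom partition for confined shear at the current intact set,
# with the incidence operator pre-split into free/constrained columns so the
# reduced operator can be assembled without subsetting the full stiffness
.shear_partition <- function(network, intact, B) {
  pinned <- if (all(intact)) integer(0) else .floating_nodes(network, intact)
  bnd_nodes <- union(c(network$bottom_nodes, network$top_nodes), pinned)
  cons <- c(.dof_x(bnd_nodes), .dof_y(bnd_nodes))
  free <- setdiff(seq_len(2L * network$n_nodes), cons)
  uc_unit <- numeric(2L * network$n_nodes)
  uc_unit[.dof_x(setdiff(network$top_nodes, pinned))] <- network$height
  list(free = free, cons = cons, pinned = pinned,
       Bf = B[, free, drop = FALSE],
       e_cons = as.numeric(B %*% uc_unit),  # elongation from prescribed part
       uc_unit = uc_unit)
}

# factorized unit-shear system for the current stiffness distribution.
# Linearity makes u(gamma) = gamma * u_unit, so steps without events need
# no further solves.  `part` is a .shear_partition for the current intact
# set (rebuilt by the caller when springs rupture).
.unit_system <- function(network, states, B, part) {
  k <- states$k_eff * states$intact
  sk <- sqrt(k)
  Kff <- Matrix::crossprod(Matrix::Diagonal(x = sk) %*% part$Bf)
  reg <- 1e-11 * max(Matrix::diag(Kff), .Machine$double.xmin)
  Kff <- Kff + Matrix::Diagonal(length(part$free), reg)
  # rhs = -Kfc u_c = -t(Bf) diag(k) (B u_c)
  rhs <- -Matrix::crossprod(part$Bf, k * part$e_cons)
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(Kff)),
                 error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  u <- part$uc_unit
  u[part$free] <- as.numeric(Matrix::solve(ch, rhs))
  e <- part$e_cons
  if (length(part$free)) {
    e <- e + as.numeric(part$Bf %*% u[part$free])
  }
  r <- as.numeric(Matrix::crossprod(B, k * e))
  list(
    u_unit = u,
    e_unit = e,
    r_unit = r,
    residual_unit = if (length(part$free)) max(abs(r[part$free])) else 0,
    tau_unit = sum(r[.dof_x(network$top_nodes)]) /
      (network$width * network$thickness),
    free = part$free, constrained = part$cons, B = B
  )
}

#' Solve one equilibrium under confined shear
#'
#' Boundary conditions: bottom nodes fully fixed; top nodes prescribed
#' horizontal displacement `gamma * H` with vertical motion suppressed;
#' lateral nodes free.  Spring stiffnesses are frozen at their current
#' values, so the solve is linear; the incremental displacement between
#' `gamma_prev` and `gamma_next` is reported alongside the total state.
#'
#' @param network a `lattice_network`.
#' @param states a `spring_states`.
#' @param gamma_prev,gamma_next previous and new shear strain,
#'   `gamma_next >= gamma_prev`.
#' @return object of class `equilibrium_state`: `u` (2n displacement
#'   vector), `du` (increment), `elongation`, `force` per spring,
#'   `reactions` (per-dof nodal constraint force, nonzero only on
#'   constrained dofs up to the solver residual), `tau` (macroscopic shear
#'   stress, N/m^2), `residual`.
#' @export
solve_increment <- function(network, states, gamma_prev, gamma_next) {
  if (gamma_next < gamma_prev) stop("'gamma_next' must be >= 'gamma_prev'")
  B <- .incidence(network)
  part <- .shear_partition(network, states$intact, B)
  sys <- .unit_system(network, states, B, part)
  if (is.null(sys)) {
    stop("singular system: the network no longer carries the applied load")
  }
  e <- gamma_next * sys$e_unit
  structure(
    list(
      u = gamma_next * sys$u_unit,
      du = (gamma_next - gamma_prev) * sys$u_unit,
      elongation = e,
      force = states$k_eff * states$intact * e,
      reactions = gamma_next * sys$r_unit,
      tau = gamma_next * sys$tau_unit,
      residual = gamma_next * sys$residual_unit,
      gamma = gamma_next
    ),
    class = "equilibrium_state"
  )
}

#' Update per-spring strain energies
#'
#' The energy bookkeeping that drives sub-spring uncoiling admits several
#' readings, and the choice matters because an uncoiling event changes the
#' spring stiffness at frozen elongation:
#'
#' * `"base"` (default): psi = 1/2 k_base e^2, the strain energy the
#'   spring would store in its reference (fully folded) state at the
#'   current elongation.  The uncoiling thresholds are properties of the
#'   folded chain, so they are compared against this reference-state
#'   energy; psi is then continuous through events, each sub-spring
#'   uncoils at a well-defined elongation, and stiffening is progressive.
#' * `"stored"`: psi = 1/2 k_eff e^2, the elastic energy actually stored
#'   at the current stiffness (the 1/2 f u identity).  Because psi jumps
#'   by the stiffness ratio at each event, a spring that crosses its first
#'   threshold tends to avalanche through the whole ladder at once.
#' * `"work"`: accumulated mechanical work psi <- psi + f du + 1/2 df du
#'   over accepted solves.  Continuous through events, but a stiffened
#'   spring that is later unloaded by redistribution accumulates large
#'   negative work, which can stall its ladder permanently.
#' * `"increment"`: the literal half-increment form
#'   psi <- psi + 1/2 df du.  It omits the f du work term, so the
#'   accumulated energy shrinks as the strain increment is refined; kept
#'   for fidelity studies only.
#'
#' The simulation loop always evaluates the rupture rule against the
#' current stored energy, whatever mode drives uncoiling: scission of a
#' fully extended chain is governed by the load it carries now.
#'
#' @param states a `spring_states`.
#' @param elongation current per-spring elongation (m).
#' @param mode `"base"`, `"stored"`, `"work"` or `"increment"`.
#' @param elongation_prev elongation at the previous accepted solve
#'   (required for the two accumulating modes).
#' @return `states` with updated `psi`.
#' @export
update_energies <- function(states, elongation,
                            mode = c("base", "stored", "work", "increment"),
                            elongation_prev = NULL) {
  mode <- match.arg(mode)
  if (mode == "base") {
    states$psi <- 0.5 * states$k_base * states$intact * elongation^2
    return(states)
  }
  if (mode == "stored") {
    states$psi <- 0.5 * states$k_eff * states$intact * elongation^2
    return(states)
  }
  if (is.null(elongation_prev)) {
    stop("mode '", mode, "' needs 'elongation_prev'")
  }
  de <- (elongation - elongation_prev) * states$intact
  states$psi <- if (mode == "work") {
    states$psi + states$k_eff * states$intact *
      (elongation_prev * de + 0.5 * de^2)
  } else {
    states$psi + 0.5 * states$k_eff * de^2
  }
  states
}

#' Run a quasi-static confined-shear simulation
#'
#' For each strain step: solve the network at frozen stiffnesses, update
#' spring energies, process unfolding/rupture events; whenever events
#' occur, re-solve at the same strain and sweep again until a sweep yields
#' no events (or the sweep cap is hit, in which case the step is flagged
#' and the run continues).  If rupture severs every intact path between the
#' top and bottom boundaries the run terminates early with a partial result
#' flagged as structural failure.  Fully reproducible given the threshold
#' seed.
#'
#' @param network a `lattice_network`.
#' @param spec a [threshold_spec] (quenched disorder + stiffening ratio).
#' @param program a [load_program].
#' @param energy_mode `"base"` (default), `"stored"`, `"work"` or
#'   `"increment"`, see
#'   [update_energies()].
#' @param sweep_cap maximum event sweeps per strain step (default 200).
#' @param snapshot_gammas strains at which per-spring force/state fields
#'   are recorded (matched to the nearest computed step).
#' @param seed threshold-sampling seed, defaults to `spec$seed`.
#' @param keep_events if `FALSE`, the per-event log is dropped (saves
#'   memory on large runs).
#' @param grip_layers passed to [spring_states()]: exclude plate-adjacent
#'   springs from unfolding and rupture (default `TRUE`).
#' @return object of class `shear_sim` with components `steps`
#'   (data.frame: gamma, tau, n_unfold_events, n_unfolded_springs,
#'   n_ruptured, sweeps, residual, flagged), `events` (data.frame: step,
#'   gamma, spring, type, psi), `states` (final `spring_states`),
#'   `snapshots`, `network`, `program`, `failed`, `detached` (bacterium ids
#'   detached at the end of the run).
#' @export
run_shear_simulation <- function(network, spec, program,
                                 energy_mode = c("base", "stored", "work",
                                                 "increment"),
                                 sweep_cap = 200L,
                                 snapshot_gammas = numeric(0),
                                 seed = spec$seed,
                                 keep_events = TRUE,
                                 grip_layers = TRUE) {
  stopifnot(inherits(network, "lattice_network"),
            inherits(spec, "threshold_spec"),
            inherits(program, "load_program"))
  energy_mode <- match.arg(energy_mode)
  states <- spring_states(network, spec, seed = seed,
                          grip_layers = grip_layers)
  B <- .incidence(network)
  n_steps <- max(1L, round(program$gamma_max / program$delta_gamma))
  gammas <- seq_len(n_steps) * program$delta_gamma
  snap_idx <- if (length(snapshot_gammas)) {
    vapply(snapshot_gammas, function(g) which.min(abs(gammas - g)), 1L)
  } else integer(0)

  steps <- data.frame(gamma = gammas, tau = NA_real_,
                      n_unfold_events = 0L, n_unfolded_springs = 0L,
                      n_ruptured = 0L, sweeps = 0L,
                      residual = NA_real_, flagged = FALSE)
  events <- vector("list", 64L); n_ev <- 0L
  snapshots <- list()
  failed <- FALSE
  part <- .shear_partition(network, states$intact, B)
  sys <- .unit_system(network, states, B, part)
  e_prev <- numeric(nrow(network$springs))
  cum_unfold <- 0L

  for (step in seq_len(n_steps)) {
    gamma <- gammas[step]
    sweep <- 0L
    repeat {
      if (is.null(sys)) { failed <- TRUE; break }
      e <- gamma * sys$e_unit
      states <- update_energies(states, e, mode = energy_mode,
                                elongation_prev = e_prev)
      e_prev <- e
      stored <- 0.5 * states$k_eff * states$intact * e^2
      ev <- process_events(states, rupture_energies = stored)
      if (nrow(ev$events) == 0L) break
      states <- ev$states
      cum_unfold <- cum_unfold + sum(ev$events$type == "unfold")
      if (keep_events) {
        n_ev <- n_ev + 1L
        if (n_ev > length(events)) events <- c(events, vector("list", length(events)))
        events[[n_ev]] <- cbind(step = step, gamma = gamma, ev$events)
      }
      if (any(ev$events$type == "rupture")) {
        if (.load_path_broken(network, states$intact)) {
          failed <- TRUE
          break
        }
        part <- .shear_partition(network, states$intact, B)
      }
      sweep <- sweep + 1L
      if (sweep >= sweep_cap) {
        steps$flagged[step] <- TRUE
        break
      }
      sys <- .unit_system(network, states, B, part)  # stiffness changed
    }
    if (failed) {
      steps <- steps[seq_len(step - 1L), , drop = FALSE]
      break
    }
    steps$tau[step] <- gamma * sys$tau_unit
    steps$residual[step] <- gamma * sys$residual_unit
    steps$sweeps[step] <- sweep
    steps$n_unfold_events[step] <- cum_unfold
    steps$n_unfolded_springs[step] <- sum(states$m > 0L)
    steps$n_ruptured[step] <- sum(!states$intact)
    if (step %in% snap_idx) {
      snapshots[[length(snapshots) + 1L]] <- list(
        gamma = gamma,
        force = states$k_eff * states$intact * gamma * sys$e_unit,
        m = states$m, intact = states$intact,
        u = gamma * sys$u_unit)
    }
  }
  events <- if (n_ev) do.call(rbind, events[seq_len(n_ev)]) else
    data.frame(step = integer(0), gamma = numeric(0), spring = integer(0),
               type = character(0), psi = numeric(0))
  res <- structure(
    list(steps = steps, events = events, states = states,
         snapshots = snapshots, network = network, program = program,
         spec = spec, energy_mode = energy_mode, seed = seed,
         failed = failed),
    class = "shear_sim")
  res$detached <- detect_detached_bacteria(network, states)
  res
}

#' @export
#' @method print shear_sim
print.shear_sim <- function(x, ...) {
  st <- x$steps
  cat(sprintf(
    "shear_sim: %d steps to gamma = %.3g (%s energy mode)\n",
    nrow(st), if (nrow(st)) st$gamma[nrow(st)] else NA, x$energy_mode))
  if (nrow(st)) {
    last <- st[nrow(st), ]
    cat(sprintf("  final tau = %.4g N/m^2, %d unfolded springs, %d ruptured\n",
                last$tau, last$n_unfolded_springs, last$n_ruptured))
  }
  if (x$failed) cat("  run ended early: structural failure of the network\n")
  if (length(x$detached)) {
    cat(sprintf("  detached bacteria: %s\n", paste(x$detached, collapse = ", ")))
  }
  invisible(x)
}

#' @export
#' @method summary shear_sim
summary.shear_sim <- function(object, window = 5L, ...) {
  st <- object$steps
  gt <- tangent_stiffness(st$gamma, st$tau, window = window)
  first_rupture <- if (any(st$n_ruptured > 0L)) {
    i <- which(st$n_ruptured > 0L)[1L]
    c(gamma = st$gamma[i], tau = st$tau[i])
  } else c(gamma = NA_real_, tau = NA_real_)
  out <- list(
    n_steps = nrow(st),
    gamma_max = if (nrow(st)) st$gamma[nrow(st)] else NA_real_,
    secant_stiffness = if (nrow(st)) st$tau[nrow(st)] / st$gamma[nrow(st)]
      else NA_real_,
    peak_tangent = if (length(gt)) max(gt, na.rm = TRUE) else NA_real_,
    gamma_at_peak_tangent = if (length(gt)) st$gamma[which.max(gt)]
      else NA_real_,
    first_rupture = first_rupture,
    n_ruptured = if (nrow(st)) st$n_ruptured[nrow(st)] else 0L,
    n_detached = length(object$detached),
    failed = object$failed
  )
  class(out) <- "summary.shear_sim"
  out
}

#' @export
#' @method print summary.shear_sim
print.summary.shear_sim <- function(x, ...) {
  cat(sprintf("confined shear to gamma = %.3g over %d steps\n",
              x$gamma_max, x$n_steps))
  cat(sprintf("  secant stiffness tau/gamma at gamma_max: %.4g N/m^2\n",
              x$secant_stiffness))
  cat(sprintf("  peak tangent stiffness: %.4g N/m^2 at gamma = %.3g\n",
              x$peak_tangent, x$gamma_at_peak_tangent))
  if (!is.na(x$first_rupture["gamma"])) {
    cat(sprintf("  first rupture at gamma = %.3g (tau = %.4g N/m^2); %d springs ruptured\n",
                x$first_rupture["gamma"], x$first_rupture["tau"], x$n_ruptured))
  } else {
    cat("  no rupture\n")
  }
  cat(sprintf("  detached bacteria: %d%s\n", x$n_detached,
              if (x$failed) "; structural failure" else ""))
  invisible(x)
}

#' @export
plot.shear_sim <- function(x, which = c("stress", "stiffness"), window = 5L,
                           ...) {
  which <- match.arg(which)
  st <- x$steps
  if (which == "stress") {
    graphics::plot(st$gamma, st$tau, type = "l",
                   xlab = expression(gamma), ylab = expression(tau ~ (N/m^2)),
                   ...)
  } else {
    gt <- tangent_stiffness(st$gamma, st$tau, window = window)
    graphics::plot(st$gamma, gt, type = "l",
                   xlab = expression(gamma),
                   ylab = expression(G[t] ~ (N/m^2)), ...)
  }
  invisible(x)
}

#' @export
as.data.frame.shear_sim <- function(x, ...) x$steps
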