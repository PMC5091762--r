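#' Quenched energy-threshold specification for EPS springs
#'
#' Each EPS spring carries eight folded sub-springs.  Sub-spring i uncoils
#' when the spring's stored strain energy first exceeds its i-th threshold;
#' the eight thresholds are i.i.d. Uniform[mean - halfwidth,
#' mean + halfwidth] draws, sorted ascending (equivalent in law to order
#' statistics), drawn once at setup and never redrawn (quenched disorder).
#' A fully unfolded spring ruptures — is removed from the network for good
#' — when its energy exceeds `rupture_value`; `rupture_value = Inf`
#' disables rupture.
#'
#' @param unfold_mean,unfold_halfwidth centre and half-width (J) of the
#'   uniform law for the eight uncoiling thresholds;
#'   `unfold_mean - unfold_halfwidth` must be positive.
#' @param rupture_value rupture threshold (J), must exceed
#'   `unfold_mean + unfold_halfwidth` (may be `Inf`).
#' @param beta terminal stiffening ratio k_eff(8)/k_eff(0) of a fully
#'   unfolded spring.  The published account only sketches the uncoiled
#'   chain as (near) rigid, so beta is a model constant; the default 8 is
#'   calibrated so that the maximum spring force between 5% and 35% shear
#'   of a reference 42%-loading specimen amplifies about fifteen-fold,
#'   the nonlinearity reported for that comparison.
#' @param seed RNG seed for threshold sampling.
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(unfold_mean, unfold_halfwidth,
                           rupture_value = Inf, beta = 8, seed = 1L) {
  if (unfold_mean - unfold_halfwidth <= 0) {
    stop("need unfold_mean - unfold_halfwidth > 0")
  }
  if (unfold_halfwidth < 0) stop("'unfold_halfwidth' must be >= 0")
  if (rupture_value <= unfold_mean + unfold_halfwidth) {
    stop("'rupture_value' must exceed unfold_mean + unfold_halfwidth")
  }
  if (beta <= 1) stop("'beta' must exceed 1")
  structure(
    list(unfold_mean = unfold_mean, unfold_halfwidth = unfold_halfwidth,
         rupture_value = rupture_value, beta = beta, seed = as.integer(seed)),
    class = "threshold_spec"
  )
}

#' Sample quenched unfolding thresholds
#'
#' Draws the eight sorted uncoiling thresholds for every EPS spring.
#' Bacterial springs never unfold or rupture and get `NA` rows.
#'
#' @param spec a [threshold_spec].
#' @param n_springs number of springs.
#' @param eps logical vector of length `n_springs`; `TRUE` where the spring
#'   is EPS (defaults to all).
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return numeric `n_springs x 8` matrix, rows sorted ascending.
#' @export
sample_thresholds <- function(spec, n_springs, eps = rep(TRUE, n_springs),
                              seed = spec$seed) {
  stopifnot(inherits(spec, "threshold_spec"), n_springs >= 1L)
  set.seed(seed)
  thr <- matrix(NA_real_, n_springs, 8L)
  n_eps <- sum(eps)
  if (n_eps > 0L) {
    lo <- spec$unfold_mean - spec$unfold_halfwidth
    hi <- spec$unfold_mean + spec$unfold_halfwidth
    draws <- matrix(stats::runif(n_eps * 8L, lo, hi), nrow = n_eps)
    thr[eps, ] <- t(apply(draws, 1L, sort))
  }
  thr
}

#' Stiffness of a partially unfolded spring
#'
#' A spring is eight folded sub-springs in series; an uncoiled sub-spring
#' is `beta` times stiffer than a folded one, so after m uncoilings
#' k_eff = 8 k_base / ((8 - m) + m / beta).  This is strictly increasing in
#' m, equals `k_base` at m = 0 and `beta * k_base` at m = 8 (and tends to
#' 8 k_base / (8 - m) as beta grows, i.e. to infinite stiffness when the
#' chain is straight).
#'
#' @param m integer vector of unfolded counts, each in 0..8.
#' @param k_base base spring constant(s) (N/m).
#' @param beta sub-spring stiffening ratio, > 1.
#' @return effective stiffness, same length as `m`.
#' @export
effective_stiffness <- function(m, k_base, beta = 8) {
  if (any(m < 0 | m > 8)) stop("'m' must lie in 0..8")
  if (beta <= 1) stop("'beta' must exceed 1")
  8 * k_base / ((8 - m) + m / beta)
}

#' Initial per-spring state for a network
#'
#' Builds the mutable per-spring state tracked through a simulation:
#' unfolded count, quenched thresholds, accumulated strain energy, intact
#' flag and current stiffness.
#'
#' @param network a `lattice_network`.
#' @param spec a [threshold_spec].
#' @param seed RNG seed for threshold sampling (defaults to `spec$seed`).
#' @param grip_layers if `TRUE` (default), springs incident to the clamped
#'   top and bottom node rows are treated as part of the grips: they stay
#'   linearly elastic and never unfold or rupture.  The loading plates are
#'   bonded to the biofilm; without this exclusion the slight energy bias
#'   of the constrained rows nucleates spurious plate delamination instead
#'   of damage in the bulk, especially at narrow threshold disorder.
#' @return object of class `spring_states`.
#' @export
spring_states <- function(network, spec, seed = spec$seed,
                          grip_layers = TRUE) {
  s <- network$springs
  ns <- nrow(s)
  eps <- s$phase == "EPS"
  evolving <- eps
  if (grip_layers) {
    grip_nodes <- c(network$bottom_nodes, network$top_nodes)
    evolving <- evolving & !(s$i %in% grip_nodes | s$j %in% grip_nodes)
  }
  thr <- sample_thresholds(spec, ns, eps = evolving, seed = seed)
  structure(
    list(
      m = integer(ns),
      thresholds = thr,
      rupture_threshold = ifelse(evolving, spec$rupture_value, NA_real_),
      psi = numeric(ns),
      intact = rep(TRUE, ns),
      eps = eps,
      evolving = evolving,
      k_base = s$k,
      k_eff = s$k,
      beta = spec$beta
    ),
    class = "spring_states"
  )
}

#' Unfolding and rupture events for the current energies
#'
#' Applies the event rules once ("one sweep"): every intact EPS spring
#' whose stored energy exceeds its next uncoiling threshold unfolds exactly
#' one sub-spring; a fully unfolded spring whose energy exceeds its rupture
#' threshold is removed irreversibly.  At most one event per spring per
#' sweep, so stiffness and load redistribute between events when the caller
#' re-equilibrates and calls again.
#'
#' @param states a `spring_states`.
#' @param energies current per-spring strain energies (J); defaults to
#'   `states$psi`.
#' @param rupture_energies energies tested against the rupture threshold;
#'   defaults to `energies`.  The simulation loop passes the current
#'   stored elastic energy here: uncoiling is a history-dependent work
#'   process, while scission of a fully extended chain is governed by the
#'   load it carries right now.
#' @return list with `states` (updated) and `events` (data.frame
#'   `spring`, `type` in "unfold"/"rupture", `psi`).
#' @export
process_events <- function(states, energies = states$psi,
                           rupture_energies = energies) {
  active <- states$intact &
    (if (is.null(states$evolving)) states$eps else states$evolving)
  m <- states$m
  # next threshold for springs that can still unfold
  can_unfold <- active & m < 8L
  nxt <- rep(Inf, length(m))
  if (any(can_unfold)) {
    nxt[can_unfold] <- states$thresholds[cbind(which(can_unfold),
                                               m[can_unfold] + 1L)]
  }
  unfold <- can_unfold & energies > nxt
  rupture <- active & m == 8L & rupture_energies > states$rupture_threshold
  if (any(unfold)) {
    states$m[unfold] <- states$m[unfold] + 1L
    states$k_eff[unfold] <- effective_stiffness(states$m[unfold],
                                                states$k_base[unfold],
                                                states$beta)
  }
  if (any(rupture)) {
    states$intact[rupture] <- FALSE
    states$k_eff[rupture] <- 0
  }
  events <- data.frame(
    spring = c(which(unfold), which(rupture)),
    type = c(rep("unfold", sum(unfold)), rep("rupture", sum(rupture))),
    psi = c(energies[unfold], rupture_energies[rupture]),
    stringsAsFactors = FALSE
  )
  list(states = states, events = events)
}
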