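#' Hashin-Shtrikman bounds on the composite shear modulus
#'
#' Variational bounds on the effective shear modulus of a two-phase
#' composite with matrix (phase 1, the EPS) shear/bulk moduli G1, K1,
#' inclusion (phase 2, the bacteria) moduli G2, K2 and inclusion volume
#' fraction c2:
#'
#'   G_l = G1 + c2 / ( 1/(G2 - G1) + 6 (K1 + 2 G1) c1 / (5 G1 (3 K1 + 4 G1)) )
#'   G_u = G2 + c1 / ( 1/(G1 - G2) + 6 (K2 + 2 G2) c2 / (5 G2 (3 K2 + 4 G2)) )
#'
#' with c1 = 1 - c2.  The bounds hold for any isotropic arrangement of the
#' phases and are the standard validity check for effective stiffnesses
#' measured on simulated microstructures.  The labels assume phase 2 is the
#' stiffer phase; for identical phases both bounds collapse to the common
#' modulus.
#'
#' @param props1 [phase_properties] of the EPS matrix (phase 1).
#' @param props2 [phase_properties] of the bacteria (phase 2).
#' @param c2 bacterial volume (area) fraction, in `[0, 1]`.
#' @return object of class `hs_bounds`: list with `G_l`, `G_u`.
#' @export
hashin_shtrikman_bounds <- function(props1, props2, c2) {
  stopifnot(inherits(props1, "phase_properties"),
            inherits(props2, "phase_properties"))
  if (!is.numeric(c2) || c2 < 0 || c2 > 1) stop("'c2' must lie in [0, 1]")
  c1 <- 1 - c2
  G1 <- props1$G; K1 <- props1$K
  G2 <- props2$G; K2 <- props2$K
  if (G1 == G2) {
    bounds <- c(G1, G1)
  } else {
    G_l <- G1 + c2 / (1 / (G2 - G1) + 6 * (K1 + 2 * G1) * c1 /
                        (5 * G1 * (3 * K1 + 4 * G1)))
    G_u <- G2 + c1 / (1 / (G1 - G2) + 6 * (K2 + 2 * G2) * c2 /
                        (5 * G2 * (3 * K2 + 4 * G2)))
    bounds <- sort(c(G_l, G_u))
  }
  structure(list(G_l = bounds[1L], G_u = bounds[2L], c2 = c2),
            class = "hs_bounds")
}

#' @export
#' @method print hs_bounds
print.hs_bounds <- function(x, ...) {
  cat(sprintf("Hashin-Shtrikman shear bounds at c2 = %.3g: [%.4g, %.4g] N/m^2\n",
              x$c2, x$G_l, x$G_u))
  invisible(x)
}

#' Tangent stiffness of a stress-strain series
#'
#' Central finite difference d tau / d gamma (one-sided at the ends)
#' smoothed by a centred moving average of the given window.
#'
#' @param gammas strictly increasing strain series (length >= 3).
#' @param taus stress series of the same length.
#' @param window moving-average window in steps (default 5); 1 disables
#'   smoothing.
#' @return numeric vector of tangent stiffness, same length as `gammas`.
#' @export
tangent_stiffness <- function(gammas, taus, window = 5L) {
  n <- length(gammas)
  if (length(taus) != n) stop("'gammas' and 'taus' must have equal length")
  if (n < 3L) stop("need at least 3 points")
  if (any(diff(gammas) <= 0)) stop("'gammas' must be strictly increasing")
  g <- numeric(n)
  g[1L] <- (taus[2L] - taus[1L]) / (gammas[2L] - gammas[1L])
  g[n] <- (taus[n] - taus[n - 1L]) / (gammas[n] - gammas[n - 1L])
  mid <- 2:(n - 1L)
  g[mid] <- (taus[mid + 1L] - taus[mid - 1L]) / (gammas[mid + 1L] - gammas[mid - 1L])
  window <- as.integer(window)
  if (window > 1L) {
    half <- window %/% 2L
    g <- vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      mean(g[lo:hi])
    }, numeric(1))
  }
  g
}

#' Per-spring localization map at a snapshot
#'
#' Tabulates, for the snapshot nearest the requested strain, each spring's
#' midpoint, its category — `pristine` (no sub-spring unfolded),
#' `unfolding` (1..8 unfolded), `ruptured` — and the magnitude of its axial
#' force, ready for plotting force contours or strain-hardening maps.
#'
#' @param sim a `shear_sim` run with `snapshot_gammas` set.
#' @param gamma requested strain; must be within half a strain increment of
#'   a recorded snapshot.
#' @return data.frame: `spring`, `x`, `y` (midpoint), `phase`, `category`,
#'   `force`, `m`.
#' @export
localization_map <- function(sim, gamma) {
  stopifnot(inherits(sim, "shear_sim"))
  if (length(sim$snapshots) == 0L) stop("run recorded no snapshots")
  gs <- vapply(sim$snapshots, `[[`, numeric(1), "gamma")
  i <- which.min(abs(gs - gamma))
  if (abs(gs[i] - gamma) > sim$program$delta_gamma / 2 + 1e-12) {
    stop(sprintf("no snapshot at gamma = %g (nearest recorded: %g)",
                 gamma, gs[i]))
  }
  snap <- sim$snapshots[[i]]
  net <- sim$network
  s <- net$springs
  category <- ifelse(!snap$intact, "ruptured",
                     ifelse(snap$m > 0L, "unfolding", "pristine"))
  data.frame(
    spring = seq_len(nrow(s)),
    x = (net$nodes[s$i, 1L] + net$nodes[s$j, 1L]) / 2,
    y = (net$nodes[s$i, 2L] + net$nodes[s$j, 2L]) / 2,
    phase = s$phase,
    category = category,
    force = abs(snap$force),
    m = snap$m,
    stringsAsFactors = FALSE
  )
}

#' Unfolding density inside and outside the diagonal shear band
#'
#' Under confined shear, strain localizes along the domain diagonal (a
#' shear band at 45 degrees).  This summarizes a localization map by the
#' fraction of EPS springs with at least one unfolded sub-spring inside
#' the diagonal band `|x/W - y/H| <= halfwidth` versus outside it.
#'
#' @param map a data.frame from [localization_map()].
#' @param network the `lattice_network` the map was computed on.
#' @param halfwidth band half-width in normalized diagonal coordinate
#'   (default 0.25).
#' @return list with `in_band`, `off_band` (unfolded fractions) and counts.
#' @export
band_unfolding_density <- function(map, network, halfwidth = 0.25) {
  eps <- map$phase == "EPS"
  sbar <- map$x / network$width - map$y / network$height
  in_band <- abs(sbar) <= halfwidth
  unfolded <- map$m > 0L | map$category == "ruptured"
  list(
    in_band = mean(unfolded[eps & in_band]),
    off_band = mean(unfolded[eps & !in_band]),
    n_in = sum(eps & in_band),
    n_off = sum(eps & !in_band)
  )
}

#' Bacteria detached from the load-bearing network
#'
#' A bacterium is completely detached when none of its nodes is connected,
#' through intact springs, to the fixed bottom boundary: it has lost its
#' mechanical path to the substratum, the reading of detachment as
#' mechanical (and nutrient/communication) isolation.
#'
#' @param network a `lattice_network`.
#' @param states a `spring_states` (e.g. the final state of a run).
#' @return integer vector of detached bacterium ids (possibly empty).
#' @export
detect_detached_bacteria <- function(network, states) {
  s <- network$springs
  b_ids <- sort(unique(s$bacterium[s$bacterium > 0L]))
  if (length(b_ids) == 0L) return(integer(0))
  g <- igraph::make_empty_graph(n = network$n_nodes, directed = FALSE)
  if (any(states$intact)) {
    g <- igraph::add_edges(g, rbind(s$i[states$intact], s$j[states$intact]))
  }
  comp <- igraph::components(g)$membership
  anchored <- unique(comp[network$bottom_nodes])
  detached <- integer(0)
  for (b in b_ids) {
    sel <- s$bacterium == b
    nodes <- unique(c(s$i[sel], s$j[sel]))
    if (!any(comp[nodes] %in% anchored)) detached <- c(detached, b)
  }
  detached
}
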