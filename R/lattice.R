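#' Elastic properties of one phase
#'
#' Isotropic elastic constants of one phase of the composite.  The lattice
#' itself fixes Poisson's ratio at 1/3 (a triangular net of equal axial
#' springs), so `nu` defaults to 1/3; the shear modulus `G` may be supplied
#' independently because published parameter sets sometimes quote G = E/3,
#' and those printed values are what enters the composite bounds.  The bulk
#' modulus is derived as K = E / (3 (1 - 2 nu)).
#'
#' @param E Young's modulus (N/m^2).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param G shear modulus (N/m^2); defaults to the isotropic value
#'   E / (2 (1 + nu)).
#' @return object of class `phase_properties` with fields `E`, `nu`, `G`, `K`.
#' @export
phase_properties <- function(E, nu = 1 / 3, G = NULL) {
  if (!is.numeric(E) || E <= 0) stop("'E' must be positive")
  if (!is.numeric(nu) || nu <= 0 || nu >= 0.5) stop("'nu' must lie in (0, 0.5)")
  if (is.null(G)) G <- E / (2 * (1 + nu))
  if (G <= 0) stop("'G' must be positive")
  structure(list(E = E, nu = nu, G = G, K = E / (3 * (1 - 2 * nu))),
            class = "phase_properties")
}

#' @export
#' @method print phase_properties
print.phase_properties <- function(x, ...) {
  cat(sprintf("phase: E = %g, nu = %g, G = %g, K = %g (N/m^2)\n",
              x$E, x$nu, x$G, x$K))
  invisible(x)
}

#' Spring constant reproducing a continuum Young's modulus
#'
#' For a triangular lattice of equal axial springs the affine-limit
#' identity k = (sqrt(3)/2) E t maps a target (plane-stress) Young's
#' modulus E to the spring constant k, independent of the lattice spacing.
#' The emergent Poisson's ratio of the net is 1/3 and its shear modulus is
#' (sqrt(3)/4) k = (3/8) E t.
#'
#' @param E target Young's modulus (N/m^2).
#' @param spacing lattice spacing a (m); accepted for interface symmetry,
#'   the identity does not depend on it.
#' @param thickness out-of-plane thickness t (m), default 1.
#' @return spring constant k (N/m).
#' @export
calibrate_spring_constant <- function(E, spacing = NULL, thickness = 1) {
  if (!is.numeric(E) || length(E) != 1L || E <= 0) stop("'E' must be positive")
  sqrt(3) / 2 * E * thickness
}

#' Build the triangular lattice-spring network over a microstructure
#'
#' Lays a triangular net of axial springs over the domain (row pitch
#' a*sqrt(3)/2, alternate rows offset by a/2, coordination number six in
#' the interior) and assigns each spring a phase: a spring is bacterial iff
#' both endpoints and its midpoint fall on bacterial pixels, otherwise it
#' belongs to the EPS matrix.  This endpoint-and-midpoint rule avoids
#' labelling boundary-straddling springs rigid, which would artificially
#' thicken the cells.  Base stiffness per phase comes from
#' [calibrate_spring_constant()].
#'
#' Node indices are row-major from the bottom row; origin bottom-left,
#' x rightward, y upward.
#'
#' @param micro a [microstructure] (or `NULL` for an all-EPS net over a
#'   `width` x `height` domain).
#' @param spacing lattice spacing a (m); must be < min(width, height)/10.
#' @param props_eps,props_bact [phase_properties] of matrix and bacteria.
#' @param width,height domain size; defaults to the microstructure's.
#' @param thickness out-of-plane thickness (m).
#' @return object of class `lattice_network`: `nodes` (n x 2 matrix),
#'   `springs` (data.frame: i, j, rest, phase, bacterium, k),
#'   `bottom_nodes`, `top_nodes`, `side_nodes`, `width`, `height`,
#'   `spacing`, `thickness`, and `n_nodes`.
#' @export
build_lattice <- function(micro = NULL, spacing,
                          props_eps = phase_properties(1),
                          props_bact = phase_properties(100),
                          width = NULL, height = NULL, thickness = 1) {
  if (!is.null(micro)) {
    stopifnot(inherits(micro, "microstructure"))
    if (is.null(width)) width <- micro$width
    if (is.null(height)) height <- micro$height
    if (sum(micro$grid) + sum(!micro$grid) == 0L) stop("microstructure empty")
  } else {
    if (is.null(width)) width <- 1
    if (is.null(height)) height <- 1
  }
  a <- spacing
  if (!is.numeric(a) || a <= 0) stop("'spacing' must be positive")
  if (a >= min(width, height) / 10) {
    stop("'spacing' must be smaller than min(width, height)/10")
  }
  pitch <- a * sqrt(3) / 2
  n_rows <- floor(height / pitch) + 1L
  n_cols <- floor((width - a / 2) / a) + 1L
  rows <- rep(seq_len(n_rows), each = n_cols)
  cols <- rep(seq_len(n_cols), times = n_rows)
  offset <- ((rows - 1L) %% 2L) * a / 2
  x <- (cols - 1L) * a + offset
  y <- (rows - 1L) * pitch
  nodes <- cbind(x = x, y = y)
  n <- nrow(nodes)
  id <- function(r, c) (r - 1L) * n_cols + c

  # horizontal springs
  hr <- rows[cols < n_cols & TRUE]
  h_i <- id(rep(seq_len(n_rows), each = n_cols - 1L),
            rep(seq_len(n_cols - 1L), times = n_rows))
  h_j <- h_i + 1L
  # diagonal springs to the row above
  di <- integer(0); dj <- integer(0)
  for (r in seq_len(n_rows - 1L)) {
    p <- (r - 1L) %% 2L
    cs <- seq_len(n_cols)
    if (p == 0L) {
      # row above is offset +a/2: neighbours (r+1, c) and (r+1, c-1)
      di <- c(di, id(r, cs), id(r, cs[cs > 1L]))
      dj <- c(dj, id(r + 1L, cs), id(r + 1L, cs[cs > 1L] - 1L))
    } else {
      # row above has no offset: neighbours (r+1, c) and (r+1, c+1)
      di <- c(di, id(r, cs), id(r, cs[cs < n_cols]))
      dj <- c(dj, id(r + 1L, cs), id(r + 1L, cs[cs < n_cols] + 1L))
    }
  }
  si <- c(h_i, di)
  sj <- c(h_j, dj)
  dx <- nodes[sj, 1L] - nodes[si, 1L]
  dy <- nodes[sj, 2L] - nodes[si, 2L]
  len <- sqrt(dx^2 + dy^2)
  stopifnot(all(abs(len - a) < 1e-9 * a))

  mx <- (nodes[si, 1L] + nodes[sj, 1L]) / 2
  my <- (nodes[si, 2L] + nodes[sj, 2L]) / 2
  if (!is.null(micro)) {
    bact <- phase_at(micro, nodes[si, 1L], nodes[si, 2L]) &
      phase_at(micro, nodes[sj, 1L], nodes[sj, 2L]) &
      phase_at(micro, mx, my)
    b_id <- ifelse(bact, label_at(micro, mx, my), 0L)
  } else {
    bact <- rep(FALSE, length(si))
    b_id <- rep(0L, length(si))
  }
  k_eps <- calibrate_spring_constant(props_eps$E, a, thickness)
  k_bact <- calibrate_spring_constant(props_bact$E, a, thickness)
  springs <- data.frame(
    i = si, j = sj, rest = len,
    phase = ifelse(bact, "bacterium", "EPS"),
    bacterium = as.integer(b_id),
    k = ifelse(bact, k_bact, k_eps),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      nodes = nodes,
      springs = springs,
      bottom_nodes = which(rows == 1L),
      top_nodes = which(rows == n_rows),
      side_nodes = which(cols == 1L | cols == n_cols),
      n_rows = n_rows, n_cols = n_cols,
      width = width, height = max(y), spacing = a, thickness = thickness,
      props_eps = props_eps, props_bact = props_bact,
      n_nodes = n
    ),
    class = "lattice_network"
  )
}

#' @export
#' @method print lattice_network
print.lattice_network <- function(x, ...) {
  nb <- sum(x$springs$phase == "bacterium")
  cat(sprintf(
    "lattice_network: %d nodes (%d x %d), %d springs (%d bacterial, %.1f%%), a = %g m\n",
    x$n_nodes, x$n_rows, x$n_cols, nrow(x$springs), nb,
    100 * nb / nrow(x$springs), x$spacing))
  invisible(x)
}

#' @export
plot.lattice_network <- function(x, col_eps = "grey70", col_bact = "firebrick",
                                 ...) {
  s <- x$springs
  graphics::plot(NA, xlim = range(x$nodes[, 1L]), ylim = range(x$nodes[, 2L]),
                 xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  graphics::segments(x$nodes[s$i, 1L], x$nodes[s$i, 2L],
                     x$nodes[s$j, 1L], x$nodes[s$j, 2L],
                     col = ifelse(s$phase == "bacterium", col_bact, col_eps))
  invisible(x)
}

#' Export a network as plain-text tables
#'
#' Writes `<stem>_nodes.csv` (id,x,y), `<stem>_springs.csv`
#' (id,i,j,phase,bacterium,k) and a JSON header `<stem>.json` with the
#' scalar metadata.
#'
#' @param network a `lattice_network`.
#' @param stem output path stem.
#' @return `stem`, invisibly.
#' @export
write_network <- function(network, stem) {
  nodes <- data.frame(id = seq_len(network$n_nodes),
                      x = network$nodes[, 1L], y = network$nodes[, 2L])
  utils::write.csv(nodes, paste0(stem, "_nodes.csv"), row.names = FALSE)
  s <- network$springs
  s$id <- seq_len(nrow(s))
  utils::write.csv(s[, c("id", "i", "j", "phase", "bacterium", "k")],
                   paste0(stem, "_springs.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_nodes = network$n_nodes, n_springs = nrow(s),
         spacing = network$spacing, width = network$width,
         height = network$height, thickness = network$thickness),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

# incidence count per node (used by tests and by boundary handling)
node_degree <- function(network) {
  tabulate(c(network$springs$i, network$springs$j), nbins = network$n_nodes)
}
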