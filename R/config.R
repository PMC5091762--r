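#' Named parameter presets
#'
#' Two published biofilm parameter sets are bundled.  `"stoodley2002"`:
#' soft EPS (E = 1 N/m^2, G = 0.33) with 100x stiffer bacteria and
#' sub-spring uncoiling thresholds 1.25e-5 +/- 0.25e-5 J, rupture disabled
#' — the strain-hardening regime of a mixed-species flow-cell biofilm.
#' `"korstgens2001"`: stiff EPS (E = 8000 N/m^2, G = 3000) with uncoiling
#' thresholds 1.05e-3 +/- 0.05e-3 J and a 4.0e-3 J rupture threshold — the
#' hardening-then-tearing regime of a Pseudomonas aeruginosa biofilm.
#' Poisson's ratio is 1/3 in both phases, the value the triangular spring
#' net itself exhibits; bulk moduli follow as K = E/(3(1 - 2 nu)) = E.
#' The printed shear moduli (E/3) are carried for use in the
#' Hashin-Shtrikman formulas.
#'
#' Each preset also carries the reference specimen it is studied on.  The
#' published parameter sets give energies in joules but no physical
#' specimen dimensions, so the absolute scale of each digital specimen is
#' a free constant; it is fixed once per preset by calibrating one
#' observable against the corresponding experiment and then held fixed
#' (see the package vignette).  For `"stoodley2002"` the specimen is a
#' 0.8 m square (strain stiffening at a 42% uniform loading becomes
#' appreciable around 15% shear, as in the reported stress-strain
#' curves); for `"korstgens2001"` it is a wide slab, 0.09 m x 0.045 m,
#' whose aspect ratio reflects imaged cross-sections (and lets a central
#' cluster span the gap), sized so that rupture in uniform 42% specimens
#' initiates near the reported 1300 N/m^2 stress level.
#'
#' @param name `"stoodley2002"` or `"korstgens2001"`.
#' @param seed threshold seed stored in the returned spec.
#' @return list with `props_eps`, `props_bact` ([phase_properties]),
#'   `thresholds` ([threshold_spec]), and the reference specimen:
#'   `width`, `height` (m), `spacing` (lattice constant, m), `grid_shape`
#'   (mask pixels), `rod_length`, `rod_width`, `cluster_sigma` (m),
#'   `delta_gamma`.
#' @export
preset_parameters <- function(name = c("stoodley2002", "korstgens2001"),
                              seed = 1L) {
  name <- match.arg(name)
  if (name == "stoodley2002") {
    L <- 0.8
    list(
      name = name,
      props_eps = phase_properties(E = 1.0, nu = 1 / 3, G = 0.33),
      props_bact = phase_properties(E = 100.0, nu = 1 / 3, G = 33.33),
      thresholds = threshold_spec(unfold_mean = 1.25e-5,
                                  unfold_halfwidth = 0.25e-5,
                                  rupture_value = Inf, seed = seed),
      width = L, height = L, spacing = L / 32,
      grid_shape = c(128L, 128L),
      rod_length = 0.18 * L, rod_width = 0.07 * L,
      cluster_sigma = 0.15 * L,
      delta_gamma = 0.0025
    )
  } else {
    H <- 0.045
    list(
      name = name,
      props_eps = phase_properties(E = 8000.0, nu = 1 / 3, G = 3000.0),
      props_bact = phase_properties(E = 800000.0, nu = 1 / 3, G = 300000.0),
      thresholds = threshold_spec(unfold_mean = 1.05e-3,
                                  unfold_halfwidth = 0.05e-3,
                                  rupture_value = 4.0e-3, seed = seed),
      width = 2 * H, height = H, spacing = H / 26,
      grid_shape = c(128L, 256L),
      rod_length = 0.18 * H, rod_width = 0.07 * H,
      cluster_sigma = 0.35 * H,
      delta_gamma = 0.0025
    )
  }
}

#' One preset study run
#'
#' Convenience wrapper assembling the whole pipeline for a preset on its
#' reference specimen: synthesize the morphology, build the lattice, run
#' confined shear.  Used throughout the examples, tests and the
#' reproduction script.
#'
#' @param preset preset name, see [preset_parameters()].
#' @param kind morphology kind, see [morphology_spec()].
#' @param loading target bacterial area fraction.
#' @param seed seed for both the morphology and the quenched thresholds.
#' @param gamma_max final shear strain (default 0.35).
#' @param snapshot_gammas strains at which per-spring fields are kept.
#' @param ... further arguments passed to [run_shear_simulation()].
#' @return a `shear_sim` object; its `network` and the generated
#'   `microstructure` (attached as attribute `"microstructure"`) give
#'   access to the specimen.
#' @export
preset_study <- function(preset, kind = "uniform", loading = 0.42,
                         seed = 1L, gamma_max = 0.35,
                         snapshot_gammas = c(0.05, 0.35), ...) {
  p <- preset_parameters(preset, seed = seed)
  ms <- morphology_spec(kind, loading,
                        rod_length = p$rod_length, rod_width = p$rod_width,
                        cluster_sigma = p$cluster_sigma, seed = seed)
  mic <- generate_microstructure(ms, grid_shape = p$grid_shape,
                                 width = p$width, height = p$height)
  net <- build_lattice(mic, spacing = p$spacing,
                       props_eps = p$props_eps, props_bact = p$props_bact)
  sim <- run_shear_simulation(net, p$thresholds,
                              load_program(gamma_max, p$delta_gamma),
                              snapshot_gammas = snapshot_gammas,
                              seed = seed, ...)
  attr(sim, "microstructure") <- mic
  sim
}

.config_keys <- c("preset", "props_eps", "props_bact", "thresholds",
                  "program", "morphology", "grid_shape", "spacing",
                  "width", "height", "thickness", "energy_mode",
                  "sweep_cap", "snapshot_gammas",
                  "seed_microstructure", "seed_thresholds", "out_dir")

#' Assemble and validate a run configuration
#'
#' Collects everything one simulation needs: the two phase property sets
#' (or a preset name), the quenched-threshold spec, the loading program,
#' the synthetic-morphology spec (ignored when a mask file is supplied at
#' run time), lattice spacing and domain size, and two independent seeds —
#' one for the microstructure geometry, one for the threshold disorder —
#' so morphology can be held fixed while the disorder is resampled.
#'
#' @param ... named fields; see `Details` in [load_config()].  Unknown
#'   fields are rejected.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(
    spacing = 1 / 32, width = 1, height = 1, thickness = 1,
    energy_mode = "base", sweep_cap = 200L,
    snapshot_gammas = numeric(0), grid_shape = c(128L, 128L),
    seed_microstructure = 1L, seed_thresholds = 1L, out_dir = NULL
  )
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!is.null(cfg$preset)) {
    p <- preset_parameters(cfg$preset, seed = cfg$seed_thresholds)
    if (is.null(cfg$props_eps)) cfg$props_eps <- p$props_eps
    if (is.null(cfg$props_bact)) cfg$props_bact <- p$props_bact
    if (is.null(cfg$thresholds)) cfg$thresholds <- p$thresholds
  }
  for (f in c("props_eps", "props_bact", "thresholds", "program")) {
    if (is.null(cfg[[f]])) stop("config is missing required field '", f, "'")
  }
  stopifnot(inherits(cfg$props_eps, "phase_properties"),
            inherits(cfg$props_bact, "phase_properties"),
            inherits(cfg$thresholds, "threshold_spec"),
            inherits(cfg$program, "load_program"))
  if (!is.null(cfg$morphology)) stopifnot(inherits(cfg$morphology, "morphology_spec"))
  if (cfg$spacing <= 0) stop("'spacing' must be positive")
  if (!cfg$energy_mode %in% c("base", "stored", "work", "increment")) {
    stop("'energy_mode' must be one of \"base\", \"stored\", \"work\", \"increment\"")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' The file may contain (all optional unless noted): `preset`
#' ("stoodley2002"/"korstgens2001"), `props_eps`/`props_bact` (maps with
#' `E`, optional `nu`, `G`), `thresholds` (map with `unfold_mean`,
#' `unfold_halfwidth`, optional `rupture_value`, `beta`), `program`
#' (required unless preset defaults suffice: map with `gamma_max`,
#' `delta_gamma`), `morphology` (map with `kind`, `target_loading`,
#' optional rod geometry), `grid_shape`, `spacing`, `width`, `height`,
#' `thickness`, `energy_mode`, `sweep_cap`, `snapshot_gammas`,
#' `seed_microstructure`, `seed_thresholds`, `out_dir`.  Unknown keys are
#' rejected with a field-level message; all invariants of the component
#' specifications are enforced by their constructors.
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @return a [run_config()] object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  args <- raw
  if (!is.null(raw$props_eps)) args$props_eps <- do.call(phase_properties, raw$props_eps)
  if (!is.null(raw$props_bact)) args$props_bact <- do.call(phase_properties, raw$props_bact)
  if (!is.null(raw$thresholds)) args$thresholds <- do.call(threshold_spec, raw$thresholds)
  if (!is.null(raw$program)) args$program <- do.call(load_program, raw$program)
  if (!is.null(raw$morphology)) args$morphology <- do.call(morphology_spec, raw$morphology)
  if (!is.null(raw$grid_shape)) args$grid_shape <- as.integer(raw$grid_shape)
  do.call(run_config, args)
}

#' Write a run configuration to YAML
#'
#' Inverse of [load_config()]; the round trip is lossless for all fields.
#'
#' @param cfg a `run_config`.
#' @param path output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list()
  out$props_eps <- cfg$props_eps[c("E", "nu", "G")]
  out$props_bact <- cfg$props_bact[c("E", "nu", "G")]
  ts <- unclass(cfg$thresholds)
  if (!is.finite(ts$rupture_value)) ts$rupture_value <- NULL
  out$thresholds <- ts
  out$program <- unclass(cfg$program)
  if (!is.null(cfg$morphology)) out$morphology <- unclass(cfg$morphology)
  for (k in c("grid_shape", "spacing", "width", "height", "thickness",
              "energy_mode", "sweep_cap", "snapshot_gammas",
              "seed_microstructure", "seed_thresholds", "out_dir")) {
    if (!is.null(cfg[[k]]) && length(cfg[[k]])) out[[k]] <- cfg[[k]]
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run a full simulation from a configuration
#'
#' Generates (or loads) the microstructure, builds the lattice, runs the
#' confined-shear program and optionally writes the standard output set to
#' `cfg$out_dir`: `stress_strain.csv` (gamma, tau, tangent stiffness,
#' event counts), `events.csv`, one `springs_gamma*.csv` field table per
#' snapshot, and `run_log.json` with seeds and package version.
#'
#' @param cfg a `run_config`.
#' @param mask optional path to a mask file (overrides `cfg$morphology`).
#' @return the `shear_sim` result, invisibly when writing output.
#' @export
run_from_config <- function(cfg, mask = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  micro <- if (!is.null(mask)) {
    read_mask(mask, width = cfg$width, height = cfg$height)
  } else {
    if (is.null(cfg$morphology)) {
      stop("config has no 'morphology' and no mask file was given")
    }
    m <- cfg$morphology
    m$seed <- cfg$seed_microstructure
    generate_microstructure(m, grid_shape = cfg$grid_shape,
                            width = cfg$width, height = cfg$height)
  }
  net <- build_lattice(micro, spacing = cfg$spacing,
                       props_eps = cfg$props_eps,
                       props_bact = cfg$props_bact,
                       thickness = cfg$thickness)
  sim <- run_shear_simulation(net, cfg$thresholds, cfg$program,
                              energy_mode = cfg$energy_mode,
                              sweep_cap = cfg$sweep_cap,
                              snapshot_gammas = cfg$snapshot_gammas,
                              seed = cfg$seed_thresholds)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    st <- sim$steps
    st$G_t <- tangent_stiffness(st$gamma, st$tau)
    utils::write.csv(st, file.path(cfg$out_dir, "stress_strain.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$events, file.path(cfg$out_dir, "events.csv"),
                     row.names = FALSE)
    for (snap in sim$snapshots) {
      map <- localization_map(sim, snap$gamma)
      utils::write.csv(map, file.path(cfg$out_dir,
                                      sprintf("springs_gamma%.3f.csv",
                                              snap$gamma)),
                       row.names = FALSE)
    }
    jsonlite::write_json(
      list(seed_microstructure = cfg$seed_microstructure,
           seed_thresholds = cfg$seed_thresholds,
           package_version = as.character(utils::packageVersion("biofilmshear")),
           loading = micro$loading, n_bacteria = micro$n_bacteria,
           detached = sim$detached, failed = sim$failed),
      file.path(cfg$out_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA)
    return(invisible(sim))
  }
  sim
}

#' Deterministic tiny test networks
#'
#' Small instances used throughout the test-suite and the examples:
#' `"triangle"` — one equilateral triangle (3 nodes, 3 springs);
#' `"strip"` — a shallow lattice strip a few rows tall; `"homogeneous"` —
#' a 20-column all-EPS lattice on the unit square;
#' `"one_inclusion"` — homogeneous matrix with a single
#' centred circular bacterium occupying about 10% of the area.
#'
#' @param name fixture name.
#' @param props_eps,props_bact phase properties for the generated network.
#' @return list with `micro` (a [microstructure] or `NULL` for
#'   `"triangle"`) and `network` (a `lattice_network`).
#' @export
make_fixture <- function(name = c("triangle", "strip", "homogeneous",
                                  "one_inclusion"),
                         props_eps = phase_properties(1),
                         props_bact = phase_properties(100)) {
  name <- match.arg(name)
  if (name == "triangle") {
    a <- 1
    nodes <- rbind(c(0, 0), c(a, 0), c(a / 2, a * sqrt(3) / 2))
    k <- calibrate_spring_constant(props_eps$E, a)
    springs <- data.frame(i = c(1L, 2L, 1L), j = c(2L, 3L, 3L),
                          rest = a, phase = "EPS", bacterium = 0L, k = k,
                          stringsAsFactors = FALSE)
    net <- structure(
      list(nodes = nodes, springs = springs,
           bottom_nodes = c(1L, 2L), top_nodes = 3L, side_nodes = c(1L, 2L),
           n_rows = 2L, n_cols = NA_integer_,
           width = a, height = a * sqrt(3) / 2, spacing = a, thickness = 1,
           props_eps = props_eps, props_bact = props_bact, n_nodes = 3L),
      class = "lattice_network")
    return(list(micro = NULL, network = net))
  }
  if (name == "strip") {
    # three staggered rows of four nodes each: twelve nodes, hand-built so
    # the fixture stays small enough for brute-force oracles (the middle
    # row is free under confined shear)
    a <- 1
    nc <- 4L
    x1 <- (seq_len(nc) - 1) * a
    nodes <- rbind(cbind(x1, 0),
                   cbind(x1 + a / 2, a * sqrt(3) / 2),
                   cbind(x1, a * sqrt(3)))
    h_i <- c(outer(seq_len(nc - 1L), (0:2) * nc, `+`))
    h_j <- h_i + 1L
    d_i <- c(seq_len(nc), 2:nc,                    # row1 -> row2
             nc + seq_len(nc), nc + seq_len(nc - 1L))  # row2 -> row3
    d_j <- c(nc + seq_len(nc), nc + seq_len(nc - 1L),
             2L * nc + seq_len(nc), 2L * nc + 1L + seq_len(nc - 1L))
    k <- calibrate_spring_constant(props_eps$E, a)
    springs <- data.frame(
      i = c(h_i, d_i), j = c(h_j, d_j),
      rest = a, phase = "EPS", bacterium = 0L, k = k,
      stringsAsFactors = FALSE)
    net <- structure(
      list(nodes = nodes, springs = springs,
           bottom_nodes = seq_len(nc), top_nodes = 2L * nc + seq_len(nc),
           side_nodes = c(1L, nc, nc + 1L, 2L * nc, 2L * nc + 1L, 3L * nc),
           n_rows = 3L, n_cols = nc,
           width = max(nodes[, 1]), height = a * sqrt(3),
           spacing = a, thickness = 1,
           props_eps = props_eps, props_bact = props_bact,
           n_nodes = 3L * nc),
      class = "lattice_network")
    return(list(micro = NULL, network = net))
  }
  if (name == "homogeneous") {
    grid <- matrix(FALSE, 64L, 64L)
    micro <- microstructure(grid)
    net <- build_lattice(micro, spacing = 1 / 19.5, props_eps = props_eps,
                         props_bact = props_bact)
    return(list(micro = micro, network = net))
  }
  # one_inclusion: centred disc, area fraction ~0.1 -> radius sqrt(0.1/pi)
  n <- 128L
  xs <- (seq_len(n) - 0.5) / n
  r <- sqrt(0.1 / pi)
  grid <- outer(rev(xs), xs, function(y, x) (x - 0.5)^2 + (y - 0.5)^2 <= r^2)
  micro <- microstructure(grid)
  net <- build_lattice(micro, spacing = 1 / 32, props_eps = props_eps,
                       props_bact = props_bact)
  list(micro = micro, network = net)
}
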