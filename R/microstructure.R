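#' Two-phase biofilm microstructure
#'
#' A `microstructure` object is a binary phase map of a biofilm
#' cross-section: `TRUE` pixels are bacterial cells, `FALSE` pixels are the
#' extracellular polymeric substance (EPS) matrix.  The grid is stored in
#' image convention (row 1 is the top scan line); physical coordinates put
#' the origin at the bottom-left with y increasing upward.  Connected
#' bacterial regions (8-connectivity) are labelled so that individual
#' bacteria can be tracked, e.g. for detachment analysis.
#'
#' @param grid logical (or 0/1) matrix; `TRUE` = bacterium.
#' @param width,height physical extent of the imaged domain (m).  Default is
#'   the 1 m x 1 m unit square: all comparisons made by the package except
#'   absolute force magnitudes are scale-free.
#'
#' @return An object of class `microstructure` with components `grid`
#'   (logical matrix), `labels` (integer matrix, 0 = EPS), `loading` (area
#'   fraction of the bacterial phase, the c2 of the composite-bound
#'   formulas), `n_bacteria`, `width`, `height`, `pixel_size`.
#' @export
microstructure <- function(grid, width = 1, height = 1) {
  if (is.numeric(grid)) {
    storage.mode(grid) <- "logical"
  }
  if (!is.matrix(grid) || !is.logical(grid)) {
    stop("'grid' must be a logical or 0/1 matrix")
  }
  if (any(is.na(grid))) stop("'grid' contains missing values")
  if (nrow(grid) < 1 || ncol(grid) < 1) stop("'grid' is empty")
  labels <- label_bacteria(grid)
  structure(
    list(
      grid = grid,
      labels = labels,
      loading = mean(grid),
      n_bacteria = max(labels),
      width = width,
      height = height,
      pixel_size = width / ncol(grid)
    ),
    class = "microstructure"
  )
}

#' Label connected bacterial regions
#'
#' Connected-component labelling of the bacterial phase under
#' 8-connectivity (diagonal pixel contact on a digitized image is physical
#' contact between cells).
#'
#' @param grid logical matrix, `TRUE` = bacterium.
#' @return integer matrix of the same shape; 0 for EPS pixels, and labels
#'   `1..n` for the `n` connected bacterial regions.
#' @export
label_bacteria <- function(grid) {
  nr <- nrow(grid)
  nc <- ncol(grid)
  idx <- which(grid)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  r <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  # vertex id for each bacterial pixel
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  edges <- vector("list", 4L)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))
  for (i in seq_along(offs)) {
    r2 <- r + offs[[i]][1L]
    c2 <- cc + offs[[i]][2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    lin2 <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- grid[lin2]
    edges[[i]] <- cbind(vid[idx[ok][keep]], vid[lin2[keep]])
  }
  el <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(el) && nrow(el) > 0L) {
    g <- igraph::add_edges(g, t(el))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Read a binary microstructure mask
#'
#' Reads either a plain-text 0/1 grid (one row of the image per line,
#' optional whitespace between digits) or a single-channel PNG/TIFF image
#' which is thresholded at `threshold` (pixels with grey value >=
#' `threshold` are bacterial, matching masks where bacteria are drawn
#' white).
#'
#' @param path file path; format chosen by extension (`.png`, `.tif(f)`,
#'   anything else is read as text).
#' @param threshold grey-level threshold in `[0, 1]` for image input.
#' @param width,height physical extent of the domain (m).
#' @return a [microstructure] object.
#' @export
read_mask <- function(path, threshold = 0.5, width = 1, height = 1) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG masks requires the 'png' package")
    }
    img <- png::readPNG(path)
    grid <- .collapse_channels(img) >= threshold
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF masks requires the 'tiff' package")
    }
    img <- tiff::readTIFF(path)
    grid <- .collapse_channels(img) >= threshold
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty mask file: ", path)
    rows <- lapply(lines, function(l) {
      ch <- strsplit(gsub("[[:space:]]", "", l), "")[[1L]]
      if (!all(ch %in% c("0", "1"))) {
        stop("text mask must contain only 0/1 digits: ", path)
      }
      as.integer(ch)
    })
    n <- lengths(rows)
    if (length(unique(n)) != 1L) stop("ragged rows in text mask: ", path)
    grid <- matrix(unlist(rows) == 1L, nrow = length(rows), byrow = TRUE)
  }
  microstructure(grid, width = width, height = height)
}

.collapse_channels <- function(img) {
  if (length(dim(img)) == 3L) {
    # average colour channels, drop alpha if present
    nch <- min(dim(img)[3L], 3L)
    apply(img[, , seq_len(nch), drop = FALSE], c(1L, 2L), mean)
  } else if (length(dim(img)) == 2L) {
    img
  } else {
    stop("mask image must be 2-D (greyscale) or 2-D with channels")
  }
}

#' Write a microstructure mask
#'
#' Writes the phase grid as a plain-text 0/1 grid plus a JSON sidecar
#' (`<path>.json`) recording loading, bacterium count, pixel size and the
#' generator seed when one is known.
#'
#' @param micro a [microstructure].
#' @param path output file path for the text grid.
#' @param seed optional generator seed to record in the sidecar.
#' @return `path`, invisibly.
#' @export
write_mask <- function(micro, path, seed = NULL) {
  stopifnot(inherits(micro, "microstructure"))
  txt <- apply(micro$grid, 1L, function(row) paste(as.integer(row), collapse = ""))
  writeLines(txt, path)
  meta <- list(
    loading = micro$loading,
    n_bacteria = micro$n_bacteria,
    pixel_size = micro$pixel_size,
    width = micro$width,
    height = micro$height
  )
  if (!is.null(seed)) meta$seed <- seed
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Morphology specification for synthetic microstructures
#'
#' Describes how rod-shaped bacteria are laid out when synthesizing a
#' cross-section: uniformly over the domain, clustered around the centre,
#' or clustered at the four corners.  Rod dimensions default to values that
#' give cells an aspect ratio of about 2.5 and leave each rod several
#' lattice spacings wide at the default mesh, mimicking the merged rod-like
#' cell outlines seen in digitized cross-sections.
#'
#' @param kind `"uniform"`, `"central_cluster"` or `"corner_cluster"`.
#' @param target_loading desired bacterial area fraction, in (0, 1).
#' @param rod_length,rod_width rod dimensions (m); `rod_length >= rod_width`.
#' @param cluster_sigma standard deviation (m) of the Gaussian used to place
#'   rod centres for the clustered kinds.
#' @param shape cell outline, `"capsule"` (rectangle with semicircular
#'   caps, the default) or `"ellipse"`; cell morphology has little effect
#'   on the shear response, so this is a plain option.
#' @param max_overlap largest fraction of a candidate rod's area that may
#'   already be bacterial; candidates overlapping more are rejected.  The
#'   default 0.15 lets cells touch and partially fuse — as they do in
#'   dense colonies — while keeping most cells distinct, so that clusters
#'   are tightly packed cells separated by thin EPS films rather than one
#'   solid blob.  Set to 1 for unrestricted overlap.
#' @param min_rods if 0, an empty grid is a valid result for tiny target
#'   loadings; the default 1 requires at least one rod.
#' @param seed RNG seed making generation reproducible.
#' @return an object of class `morphology_spec`.
#' @export
morphology_spec <- function(kind = c("uniform", "central_cluster", "corner_cluster"),
                            target_loading,
                            rod_length = 0.18,
                            rod_width = 0.07,
                            cluster_sigma = 0.14,
                            shape = c("capsule", "ellipse"),
                            max_overlap = 0.15,
                            min_rods = 1L,
                            seed = 1L) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (!is.numeric(target_loading) || target_loading <= 0 || target_loading >= 1) {
    stop("'target_loading' must lie in (0, 1)")
  }
  if (!(rod_length >= rod_width && rod_width > 0)) {
    stop("need rod_length >= rod_width > 0")
  }
  if (cluster_sigma <= 0) stop("'cluster_sigma' must be positive")
  if (!is.numeric(max_overlap) || max_overlap < 0 || max_overlap > 1) {
    stop("'max_overlap' must lie in [0, 1]")
  }
  structure(
    list(kind = kind, target_loading = target_loading,
         rod_length = rod_length, rod_width = rod_width,
         cluster_sigma = cluster_sigma, shape = shape,
         max_overlap = max_overlap,
         min_rods = as.integer(min_rods), seed = as.integer(seed)),
    class = "morphology_spec"
  )
}

#' Synthesize a two-phase microstructure
#'
#' Stamps rod-shaped bacteria (discretized capsules of
#' `rod_length x rod_width`, uniformly random orientation) onto an empty
#' grid until the bacterial area fraction is within `tol` of the target.
#' Centres are drawn uniformly over the domain (`uniform`), from a Gaussian
#' about the domain centre (`central_cluster`), or from an equal mixture of
#' Gaussians at the four corners (`corner_cluster`).  Overlapping rods are
#' allowed — real clusters touch and merge — and union area is counted
#' once.  A candidate rod that would overshoot the target band is rejected,
#' so the walk terminates inside the band; identical spec (including seed)
#' gives a bit-identical grid.
#'
#' @param spec a [morphology_spec].
#' @param grid_shape integer `c(rows, cols)` of the pixel grid.
#' @param width,height physical extent (m).
#' @param tol acceptable |loading - target| (default 0.01).
#' @param max_attempts cap on placement attempts before giving up.
#' @return a [microstructure]; its `loading` is within `tol` of
#'   `spec$target_loading`.
#' @export
generate_microstructure <- function(spec, grid_shape = c(128L, 128L),
                                    width = 1, height = 1, tol = 0.01,
                                    max_attempts = 20000L) {
  stopifnot(inherits(spec, "morphology_spec"))
  nr <- as.integer(grid_shape[1L])
  nc <- as.integer(grid_shape[2L])
  px <- width / nc
  py <- height / nr
  if (spec$rod_length > min(width, height)) {
    stop("grid/domain too small to hold one rod")
  }
  grid <- matrix(FALSE, nr, nc)
  target <- spec$target_loading
  if (spec$min_rods < 1L && target <= tol) {
    return(microstructure(grid, width = width, height = height))
  }
  # pixel centre coordinates (origin bottom-left, y upward)
  xs <- (seq_len(nc) - 0.5) * px
  ys <- rev((seq_len(nr) - 0.5) * py)  # row 1 = top scan line
  total <- nr * nc
  filled <- 0L
  attempts <- 0L
  set.seed(spec$seed)
  corners <- rbind(c(0, 0), c(width, 0), c(0, height), c(width, height))
  repeat {
    loading <- filled / total
    if (abs(loading - target) <= tol && (filled > 0L || spec$min_rods < 1L)) break
    if (attempts >= max_attempts) {
      stop(sprintf(
        "could not reach target loading %.3f within %d attempts (achieved %.3f)",
        target, max_attempts, loading))
    }
    attempts <- attempts + 1L
    centre <- switch(spec$kind,
      uniform = c(stats::runif(1, 0, width), stats::runif(1, 0, height)),
      central_cluster = c(stats::rnorm(1, width / 2, spec$cluster_sigma),
                          stats::rnorm(1, height / 2, spec$cluster_sigma)),
      corner_cluster = {
        k <- sample.int(4L, 1L)
        corners[k, ] + stats::rnorm(2, 0, spec$cluster_sigma)
      })
    theta <- stats::runif(1, 0, pi)
    mask <- .stamp_rod(xs, ys, centre, theta, spec$rod_length, spec$rod_width,
                       spec$shape)
    n_mask <- sum(mask)
    if (n_mask == 0L) next
    added <- mask & !grid
    overlap <- if (is.null(spec$max_overlap)) 0 else
      (n_mask - sum(added)) / n_mask
    if (!is.null(spec$max_overlap) && overlap > spec$max_overlap) next
    new_loading <- (filled + sum(added)) / total
    if (new_loading > target + tol) next  # would overshoot the band
    grid <- grid | added
    filled <- filled + sum(added)
  }
  microstructure(grid, width = width, height = height)
}

# Pixel mask of one rod: capsule = distance to central segment <= w/2;
# ellipse = axis-aligned-in-body-frame quadratic form.
.stamp_rod <- function(xs, ys, centre, theta, L, w, shape) {
  d <- c(cos(theta), sin(theta))
  half <- max(L / 2 - w / 2, 0)
  nr <- length(ys); nc <- length(xs)
  # bounding box to limit work
  r_out <- L / 2 + w  # generous
  cx <- which(xs >= centre[1] - r_out & xs <= centre[1] + r_out)
  cy <- which(ys >= centre[2] - r_out & ys <= centre[2] + r_out)
  mask <- matrix(FALSE, nr, nc)
  if (length(cx) == 0L || length(cy) == 0L) return(mask)
  X <- matrix(xs[cx], length(cy), length(cx), byrow = TRUE) - centre[1]
  Y <- matrix(ys[cy], length(cy), length(cx)) - centre[2]
  # body-frame coordinates
  u <- X * d[1] + Y * d[2]
  v <- -X * d[2] + Y * d[1]
  inside <- if (shape == "capsule") {
    uu <- pmin(pmax(u, -half), half)  # nearest point on the spine segment
    (u - uu)^2 + v^2 <= (w / 2)^2
  } else {
    (u / (L / 2))^2 + (v / (w / 2))^2 <= 1
  }
  mask[cy, cx] <- inside
  mask
}

#' @export
#' @method print microstructure
print.microstructure <- function(x, ...) {
  cat(sprintf(
    "microstructure: %d x %d pixels, loading %.3f (%d bacteria), %g x %g m\n",
    nrow(x$grid), ncol(x$grid), x$loading, x$n_bacteria, x$width, x$height))
  invisible(x)
}

#' @export
plot.microstructure <- function(x, ...) {
  # flip so that plotted y runs upward like physical y
  img <- t(x$grid[rev(seq_len(nrow(x$grid))), , drop = FALSE])
  graphics::image(seq(0, x$width, length.out = nrow(img)),
                  seq(0, x$height, length.out = ncol(img)),
                  img + 0, col = c("black", "white"),
                  xlab = "x (m)", ylab = "y (m)", asp = 1, ...)
  invisible(x)
}

# phase lookup at a physical point; TRUE = bacterium.  Also used to fetch
# the bacterium label at a point (label = 0 for EPS).
.pixel_index <- function(micro, x, y) {
  nc <- ncol(micro$grid); nr <- nrow(micro$grid)
  col <- pmin(pmax(floor(x / micro$width * nc) + 1L, 1L), nc)
  row_from_bottom <- pmin(pmax(floor(y / micro$height * nr) + 1L, 1L), nr)
  row <- nr + 1L - row_from_bottom
  cbind(row, col)
}

phase_at <- function(micro, x, y) {
  micro$grid[.pixel_index(micro, x, y)]
}

label_at <- function(micro, x, y) {
  micro$labels[.pixel_index(micro, x, y)]
}
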