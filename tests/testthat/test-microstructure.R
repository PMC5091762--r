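test_that("degenerate grids give the expected loading and bacterium count", {
  m0 <- microstructure(matrix(FALSE, 10, 10))
  expect_equal(m0$loading, 0)
  expect_equal(m0$n_bacteria, 0L)

  m1 <- microstructure(matrix(TRUE, 10, 10))
  expect_equal(m1$loading, 1)
  expect_equal(m1$n_bacteria, 1L)
})

test_that("labelling matches an independent flood fill, incl. checkerboard", {
  # checkerboard: the eight single pixels of one checker colour all touch
  # diagonally, so 8-connectivity merges them into one component (value
  # computed with the independent flood fill below)
  cb <- outer(1:4, 1:4, function(r, c) (r + c) %% 2 == 0)
  m <- microstructure(cb)
  oracle <- flood_fill_labels(cb)
  expect_equal(m$loading, 0.5)
  expect_equal(m$n_bacteria, max(oracle))
  expect_equal(m$n_bacteria, 1L)

  set.seed(42)
  for (i in 1:5) {
    g <- matrix(runif(20 * 17) < 0.35, 20, 17)
    lab <- label_bacteria(g)
    oracle <- flood_fill_labels(g)
    expect_equal(max(lab), max(oracle))
    # same partition up to relabelling
    key <- paste(lab[g], oracle[g])
    expect_equal(length(unique(key)), max(oracle))
  }
})

test_that("text mask IO round-trips the grid and rejects bad input", {
  g <- matrix(runif(12 * 9) < 0.3, 12, 9)
  m <- microstructure(g)
  path <- withr::local_tempfile(fileext = ".txt")
  write_mask(m, path, seed = 7L)
  m2 <- read_mask(path)
  expect_identical(m2$grid, g)
  expect_equal(m2$loading, m$loading)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(meta$seed, 7)

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0101", "01x1"), bad)
  expect_error(read_mask(bad), "0/1")
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_mask(empty), "empty")
  expect_error(read_mask(file.path(tempdir(), "nope.txt")), "no such file")
})

test_that("generator reaches target loadings within one percent", {
  for (target in c(0.15, 0.26, 0.42, 0.55)) {
    spec <- morphology_spec("uniform", target, rod_length = 0.14,
                            rod_width = 0.06, seed = 3L)
    m <- generate_microstructure(spec, grid_shape = c(150L, 150L))
    expect_true(abs(m$loading - target) <= 0.01,
                info = sprintf("target %.2f achieved %.3f", target, m$loading))
  }
})

test_that("generation is deterministic in the seed", {
  spec <- morphology_spec("central_cluster", 0.3, seed = 9L)
  a <- generate_microstructure(spec, grid_shape = c(100L, 100L))
  b <- generate_microstructure(spec, grid_shape = c(100L, 100L))
  expect_identical(a$grid, b$grid)
  spec2 <- morphology_spec("central_cluster", 0.3, seed = 10L)
  c <- generate_microstructure(spec2, grid_shape = c(100L, 100L))
  expect_false(identical(a$grid, c$grid))
})

test_that("central clustering concentrates bacteria around the centre", {
  dists <- sapply(1:10, function(seed) {
    sapply(c("uniform", "central_cluster"), function(kind) {
      spec <- morphology_spec(kind, 0.3, cluster_sigma = 0.12, seed = seed)
      m <- generate_microstructure(spec, grid_shape = c(120L, 120L))
      idx <- which(m$grid, arr.ind = TRUE)
      mean(sqrt((idx[, 1] / 120 - 0.5)^2 + (idx[, 2] / 120 - 0.5)^2))
    })
  })
  expect_lt(mean(dists["central_cluster", ]), mean(dists["uniform", ]))
})

test_that("morphology invariants are enforced", {
  expect_error(morphology_spec("uniform", 0), "target_loading")
  expect_error(morphology_spec("uniform", 1.2), "target_loading")
  expect_error(morphology_spec("uniform", 0.3, rod_length = 0.05,
                               rod_width = 0.1), "rod_length")
  expect_error(generate_microstructure(
    morphology_spec("uniform", 0.3, rod_length = 2, rod_width = 0.1)),
    "too small")
})
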