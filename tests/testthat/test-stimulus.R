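test_that("dot displays satisfy the constant-area geometry invariants", {
  A <- default_total_area()
  for (n in c(1L, 7L, 20L)) {
    d <- generate_dot_display(n, seed = n)
    expect_identical(d$numerosity, n)
    expect_identical(nrow(d$dot_centres), n)
    # analytic radii conserve total area exactly
    expect_equal(n * pi * d$dot_radius^2, A, tolerance = 1e-9)
    # whole discs inside the 0.75 degree field
    rad <- sqrt(rowSums(d$dot_centres^2))
    expect_true(all(rad + d$dot_radius <= d$field_radius + 1e-12))
    if (n > 1) {
      dm <- as.matrix(stats::dist(d$dot_centres))
      expect_gte(min(dm[upper.tri(dm)]), 2.2 * d$dot_radius - 1e-12)
    }
  }
  # single dot has radius sqrt(A / pi)
  expect_equal(generate_dot_display(1, seed = 5)$dot_radius, sqrt(A / pi))
})

test_that("display generation is deterministic in the seed and varies across seeds", {
  a <- generate_dot_display(20, seed = 0)
  b <- generate_dot_display(20, seed = 0)
  c2 <- generate_dot_display(20, seed = 1)
  expect_identical(a$dot_centres, b$dot_centres)
  expect_false(isTRUE(all.equal(a$dot_centres, c2$dot_centres)))
})

test_that("infeasible packings raise an error instead of a bad display", {
  expect_error(generate_dot_display(30, seed = 1, min_spacing = 0.3,
                                    max_restarts = 2),
               "infeasible")
  expect_error(generate_dot_display(1, total_area = pi * 0.8^2), "infeasible")
})

test_that("rasterization conserves dot area independent of numerosity", {
  area_est <- function(d, ppd = 64) {
    img <- rasterize_display(d, pixels_per_degree = ppd)
    sum(abs(img - 0.5)) / (0.5 * ppd^2)
  }
  d1 <- generate_dot_display(1, seed = 2)
  d7 <- generate_dot_display(7, seed = 3)
  expect_equal(area_est(d1), area_est(d7), tolerance = 0.02)
  # refining the grid converges toward the analytic area
  est <- vapply(c(32, 64, 256), function(p) area_est(d7, p), numeric(1))
  err <- abs(est - default_total_area())
  expect_lt(err[3], err[1])
  expect_equal(est[3], default_total_area(), tolerance = 0.01)
  # zero dots -> uniform background; small extents are rejected
  empty <- list(numerosity = 0L, dot_centres = NULL, dot_radius = 0.1,
                colour = "black", field_radius = 0.75)
  expect_true(all(rasterize_display(empty) == 0.5))
  expect_error(rasterize_display(d1, image_extent = 1), "cover")
})

test_that("aggregate Fourier power is spectral contrast energy", {
  expect_identical(aggregate_fourier_power(matrix(0.5, 32, 32)), 0)
  img <- rasterize_display(generate_dot_display(5, seed = 4))
  img2 <- 0.5 + 2 * (img - 0.5)
  attr(img2, "pixels_per_degree") <- 64
  # |F|^2 is quadratic, |F| linear, in image contrast
  expect_equal(aggregate_fourier_power(img2, "squared"),
               4 * aggregate_fourier_power(img, "squared"))
  expect_equal(aggregate_fourier_power(img2, "magnitude"),
               2 * aggregate_fourier_power(img, "magnitude"))
  expect_gt(aggregate_fourier_power(img), 0)
  # band-limited aggregation needs resolution metadata and reduces power
  expect_lt(aggregate_fourier_power(img, "squared", band = c(5, 15)),
            aggregate_fourier_power(img, "squared"))
  unattributed <- matrix(img, nrow(img))
  expect_error(aggregate_fourier_power(unattributed, band = c(1, 5)),
               "pixels_per_degree")
})

test_that("mean aggregate power increases with numerosity at fixed total area", {
  pt <- fourier_power_table(n_seeds = 6, seed = 3)
  expect_true(all(diff(pt) > 0))
})

test_that("run sequences implement the three-condition adaptor protocol", {
  seqs <- lapply(c(low = "low", high = "high", changing = "changing"),
                 build_run_sequence, seed = 9)
  for (s in seqs) {
    expect_identical(nrow(s), 264L)
    expect_equal(run_duration(s), 369.6)
    # each changing numerosity 1-7 shown in exactly 24 TRs
    counts <- table(s$changing_numerosity)
    expect_true(all(counts[as.character(1:7)] == 24))
    expect_identical(unname(counts["20"]), 96L)
  }
  # the changing schedule is shared; adaptors are condition-specific
  expect_identical(seqs$low$changing_numerosity, seqs$high$changing_numerosity)
  expect_identical(seqs$low$changing_numerosity,
                   seqs$changing$changing_numerosity)
  expect_true(all(seqs$low$adaptor_numerosity == 1))
  expect_true(all(seqs$high$adaptor_numerosity == 20))
  expect_identical(seqs$changing$adaptor_numerosity,
                   seqs$changing$changing_numerosity)
  # within a cycle, ascending and descending halves show the same multiset
  cyc <- seqs$low$changing_numerosity[1:66]
  expect_identical(sort(cyc[1:21]), sort(cyc[34:54]))
  # per-TR timing: 300 + 400 + 300 + 400 ms = one 1.4 s TR
  expect_equal(sum(attr(seqs$low, "within_tr_timing")),
               attr(seqs$low, "tr_seconds"))
})

test_that("oddball flags are drawn at the configured rate and reproducibly", {
  draws <- unlist(lapply(1:8, function(s) {
    sq <- build_run_sequence("low", seed = s)
    c(sq$oddball_adaptor, sq$oddball_changing)
  }))
  expect_equal(mean(draws), 0.10, tolerance = 0.015)
  expect_identical(build_run_sequence("low", seed = 1),
                   build_run_sequence("low", seed = 1))
})

test_that("display and event exports round-trip through delimited text", {
  d <- generate_dot_display(5, seed = 6)
  f <- tempfile(fileext = ".tsv")
  write_display_table(d, f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_identical(nrow(tab), 5L)
  expect_equal(tab$x_deg, d$dot_centres[, 1], tolerance = 1e-12)

  s <- build_run_sequence("changing", seed = 1)
  ev <- write_events_table(s)
  expect_identical(nrow(ev), 2L * 264L)
  expect_true(all(ev$duration_s == 0.3))
  expect_equal(ev$onset_s[1:2], c(0, 0.7))
  expect_setequal(unique(ev$role), c("adaptor", "changing"))
})
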