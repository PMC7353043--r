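# Ground-truth roster construction: deterministic subset sizes, nesting,
# reproducibility and placement geometry.

test_that("capable and responder set sizes follow the round-half-up rule", {
  r <- simulate_roster(spark_config(n_cells = 1000, frac_capable = 0.5,
                                    hormone_panel = list(),
                                    frame_shape = c(2048L, 2048L), seed = 1))
  expect_equal(sum(r$capable), 500)

  panel <- list(adenosine = list(responder_frac = 0.37,
                                 archetype_weights = c(transient = 1,
                                                       sustained = 0,
                                                       dissolving = 0),
                                 amplitude_mean = 1, amplitude_cv = 0.3))
  r2 <- simulate_roster(spark_config(n_cells = 1000, frac_capable = 0.482,
                                     hormone_panel = panel,
                                     frame_shape = c(2048L, 2048L), seed = 2))
  expect_equal(sum(r2$resp_adenosine), 370)
  expect_true(all(r2$capable[r2$resp_adenosine]))
})

test_that("nested mode yields a largest-first chain of responder subsets", {
  arch <- c(transient = 1, sustained = 0, dissolving = 0)
  panel <- list(h1 = list(responder_frac = 0.37, archetype_weights = arch,
                          amplitude_mean = 1, amplitude_cv = 0.3),
                h2 = list(responder_frac = 0.347, archetype_weights = arch,
                          amplitude_mean = 1, amplitude_cv = 0.3))
  r <- simulate_roster(spark_config(n_cells = 1000, frac_capable = 0.482,
                                    hormone_panel = panel,
                                    frame_shape = c(2048L, 2048L), seed = 5))
  s1 <- which(r$resp_h1); s2 <- which(r$resp_h2)
  expect_length(union(s1, s2), 370)
  expect_length(setdiff(s2, s1), 0)
})

test_that("impossible nested subsets and invalid configs are rejected", {
  arch <- c(transient = 1, sustained = 0, dissolving = 0)
  panel <- list(h = list(responder_frac = 0.6, archetype_weights = arch,
                         amplitude_mean = 1, amplitude_cv = 0.3))
  expect_error(spark_config(frac_capable = 0.5, hormone_panel = panel),
               "exceeds frac_capable")
  bad <- panel
  bad$h$archetype_weights <- c(transient = 0.5, sustained = 0.4,
                               dissolving = 0.2)
  expect_error(spark_config(frac_capable = 0.7, hormone_panel = bad),
               "sum to 1")
})

test_that("rosters are reproducible by seed with seed-independent set sizes", {
  cfg <- spark_config(n_cells = 120, seed = 11)
  expect_identical(simulate_roster(cfg), simulate_roster(cfg))
  cfg2 <- cfg; cfg2$seed <- 12L
  a <- simulate_roster(cfg); b <- simulate_roster(cfg2)
  expect_false(identical(a$x, b$x))
  expect_equal(sum(a$capable), sum(b$capable))
  for (h in attr(a, "hormones"))
    expect_equal(sum(a[[paste0("resp_", h)]]), sum(b[[paste0("resp_", h)]]))
})

test_that("cell discs do not overlap and stay inside the frame", {
  cfg <- spark_config(n_cells = 80, seed = 3)
  r <- simulate_roster(cfg)
  d <- as.matrix(dist(cbind(r$x, r$y)))
  diag(d) <- Inf
  expect_true(min(d) >= 2 * cfg$cell_radius)
  expect_true(all(r$x > cfg$cell_radius & r$x < cfg$frame_shape[1] - cfg$cell_radius))
  expect_true(all(r$y > cfg$cell_radius & r$y < cfg$frame_shape[2] - cfg$cell_radius))
})

test_that("non-capable cells carry no droplet-forming hormone membership", {
  r <- simulate_roster(spark_config(n_cells = 300, frame_shape = c(1280L, 1280L), seed = 8))
  for (h in attr(r, "hormones")) {
    arch <- r[[paste0("arch_", h)]]
    forming <- !is.na(arch) & arch %in% c("transient", "sustained")
    expect_true(all(r$capable[forming]))
  }
})

test_that("independent overlap mode matches the analytic overlap expectation", {
  # with frac_capable = 1 the sets are independent draws from all cells, so
  # E[new responders to h2] = n * f2 * (1 - f1)
  arch <- c(transient = 1, sustained = 0, dissolving = 0)
  panel <- list(h1 = list(responder_frac = 0.4, archetype_weights = arch,
                          amplitude_mean = 1, amplitude_cv = 0.3),
                h2 = list(responder_frac = 0.3, archetype_weights = arch,
                          amplitude_mean = 1, amplitude_cv = 0.3))
  n <- 400
  new2 <- vapply(1:30, function(s) {
    r <- simulate_roster(spark_config(n_cells = n, frac_capable = 1,
                                      hormone_panel = panel,
                                      overlap_mode = "independent",
                                      frame_shape = c(1280L, 1280L), seed = s))
    length(setdiff(which(r$resp_h2), which(r$resp_h1)))
  }, numeric(1))
  expect_equal(mean(new2), n * 0.3 * (1 - 0.4), tolerance = 0.05)
})

test_that("rosters round-trip through CSV", {
  r <- simulate_roster(spark_config(n_cells = 15, seed = 2))
  p <- withr::local_tempfile(fileext = ".csv")
  write_roster(r, p)
  r2 <- read_roster(p)
  expect_equal(attr(r2, "hormones"), attr(r, "hormones"))
  expect_equal(r2$expression, r$expression, tolerance = 1e-12)
  expect_equal(r2$capable, r$capable)
})
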