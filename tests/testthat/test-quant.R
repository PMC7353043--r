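# Rolling-ball subtraction, segmentation, gating and droplet detection.

test_that("rolling-ball output matches brute-force flat-disc opening", {
  for (s in 1:3) {
    set.seed(s)
    f <- matrix(runif(32 * 32, 0, 5000), 32, 32)
    r <- c(3, 4, 6)[s]
    sub <- rolling_ball_subtract(f, r)
    expect_equal(unclass(sub), f - bf_opening(f, r), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("a constant frame subtracts to zero", {
  f <- matrix(7, 40, 40)
  expect_true(all(rolling_ball_subtract(f, 5) == 0))
})

test_that("a small punctum survives subtraction, the rest vanishes", {
  f <- matrix(10, 32, 32)
  f[15:17, 15:17] <- 10 + 50
  s <- rolling_ball_subtract(f, 10)
  expect_equal(s[16, 16], 50)
  expect_true(all(s[15:17, 15:17] == 50))
  expect_true(all(s[-(14:18), ] == 0))
})

test_that("a cell-sized plateau is removed by a ball between punctum and cell size", {
  # radius-15 disc, radius-10 ball: the ball fits inside the disc, so the
  # opening reconstructs the plateau and subtraction flattens it
  f <- matrix(100, 64, 64)
  idx <- interior <- integer(0)
  for (i in 1:64) for (j in 1:64) {
    d2 <- (i - 32)^2 + (j - 32)^2
    if (d2 <= 15^2) idx <- c(idx, i + (j - 1) * 64)
    if (d2 <= 12^2) interior <- c(interior, i + (j - 1) * 64)
  }
  f[idx] <- 250
  s <- rolling_ball_subtract(f, 10)
  # interior flattened exactly; only a thin digital-edge rim may remain
  expect_true(all(s[interior] == 0))
  expect_lt(mean(s[idx] > 0), 0.15)
})

test_that("oversized radii are rejected", {
  expect_error(rolling_ball_subtract(matrix(0, 32, 32), 20), "exceeds")
  expect_error(rolling_ball_subtract(matrix(0, 32, 32), 0.5), ">= 1")
})

test_that("the background estimate is idempotent and translation-equivariant", {
  set.seed(4)
  f <- matrix(runif(40 * 40, 0, 100), 40, 40)
  b1 <- attr(rolling_ball_subtract(f, 4), "background")
  b2 <- attr(rolling_ball_subtract(b1, 4), "background")
  expect_equal(b2, b1, tolerance = 1e-9)
  # translation equivariance away from borders
  g <- matrix(0, 40, 40)
  g[1:30, 1:30] <- f[1:30, 1:30]
  g2 <- matrix(0, 40, 40)
  g2[6:35, 6:35] <- f[1:30, 1:30]
  s1 <- rolling_ball_subtract(g, 3)
  s2 <- rolling_ball_subtract(g2, 3)
  # compare content pixels at least 2*radius from the content border
  expect_equal(s2[13:28, 13:28], s1[8:23, 8:23], tolerance = 1e-9,
               ignore_attr = TRUE)
})

render_field <- function(n_cells, seed, frame = c(384L, 384L)) {
  cfg <- spark_config(n_cells = n_cells, frac_capable = 0,
                      frac_pka_responsive = 0, hormone_panel = list(),
                      frame_shape = frame, seed = seed)
  r <- simulate_roster(cfg)
  a <- simulate_activity(r, protocol_forskolin(), kinetic_params())
  list(roster = r,
       stack = render_stack(r, a, optics_config(frame_shape = frame)))
}

test_that("segmentation finds exactly the rendered cells", {
  q <- render_field(50, seed = 21, frame = c(768L, 768L))
  mask <- segment_cells(q$stack$frames[[1]])
  expect_equal(nrow(mask$cells), 50)
  expect_true(all(mask$cells$label == seq_len(50)))
  expect_true(all(mask$cells$b_mean > 0))
  m <- match_cells(mask, q$roster)
  expect_false(any(is.na(m)))
})

test_that("a blank frame yields the no-cells error", {
  set.seed(1)
  f <- matrix(rnorm(256 * 256, 100, 3), 256, 256)
  expect_error(segment_cells(f), "no cells detected")
})

test_that("doubling a cell's expression doubles its background-free brightness", {
  cfg <- spark_config(n_cells = 6, frac_capable = 0, hormone_panel = list(),
                      frac_pka_responsive = 0, frame_shape = c(256L, 256L),
                      seed = 31)
  r1 <- simulate_roster(cfg)
  r2 <- r1
  r2$expression[3] <- 2 * r1$expression[3]
  a <- simulate_activity(r1, protocol_forskolin(), kinetic_params())
  opt <- optics_config(frame_shape = c(256L, 256L), seed = 5)
  b_of <- function(r) {
    st <- render_stack(r, a, opt)
    f <- st$frames[[1]]
    mask <- segment_cells(f)
    i <- which(match_cells(mask, r) == 3)
    mask$cells$b_mean[i] - median(f)
  }
  expect_equal(b_of(r2) / b_of(r1), 2, tolerance = 0.05)
})

test_that("expression gating is correct at the extremes and monotone", {
  q <- render_field(12, seed = 22)
  mask <- segment_cells(q$stack$frames[[1]])
  g0 <- gate_expression(mask, threshold = 0)
  expect_true(all(g0$cells$gated))
  ghi <- gate_expression(mask, threshold = max(mask$cells$b_mean) + 1)
  expect_false(any(ghi$cells$gated))
  thrs <- seq(0, max(mask$cells$b_mean) + 10, length.out = 25)
  n_gated <- vapply(thrs, function(t)
    sum(gate_expression(mask, threshold = t)$cells$gated), numeric(1))
  expect_true(all(diff(n_gated) <= 0))
  # percentile mode gates the stated share of cells
  gp <- gate_expression(mask, threshold = 50,
                        params = quant_params(expression_mode = "percentile",
                                              expression_threshold = 50))
  expect_equal(sum(gp$cells$gated), floor(nrow(gp$cells) / 2))
  expect_error(quant_params(expression_mode = "percentile",
                            expression_threshold = 120),
               "in \\(0, 100\\)")
})

test_that("droplet false positives on pure noise stay below 1 per 100 cells", {
  q <- render_field(12, seed = 23)
  mask <- gate_expression(segment_cells(q$stack$frames[[1]]), threshold = 0)
  total <- 0; cells <- 0
  for (f in seq(1, 41, by = 4)) {
    sub <- rolling_ball_subtract(q$stack$frames[[f]], 8)
    dd <- detect_droplets(sub, mask, quant_params())
    total <- total + nrow(dd)
    cells <- cells + nrow(mask$cells)
  }
  expect_gte(cells, 100)
  expect_lt(total / cells, 1 / 100)
})

test_that("a clear constructed punctum is detected as exactly one droplet", {
  f <- matrix(0, 64, 64)
  idx <- disc <- integer(0)
  for (i in 1:64) for (j in 1:64)
    if ((i - 32)^2 + (j - 32)^2 <= 12^2) disc <- c(disc, i + (j - 1) * 64)
  set.seed(2)
  f[disc] <- abs(rnorm(length(disc), 0, 1))
  f[31:33, 31:33] <- 20 * mad(f[disc])
  attr(f, "subtracted") <- TRUE
  mask <- structure(list(labels = NULL,
                         cells = data.frame(label = 1L, area = length(disc),
                                            cx = 32, cy = 32, b_mean = 100,
                                            gated = TRUE),
                         pixels = list("1" = disc)), class = "cell_mask")
  dd <- detect_droplets(f, mask, quant_params())
  expect_equal(nrow(dd), 1)
  expect_gte(dd$area[1], 4)
  expect_true(all(attr(dd, "pixels")[[1]] %in% disc))
})

test_that("detection refuses an unsubtracted frame and droplets stay in-cell", {
  q <- render_field(5, seed = 24)
  mask <- gate_expression(segment_cells(q$stack$frames[[1]]), threshold = 0)
  expect_error(detect_droplets(q$stack$frames[[1]], mask),
               "background-subtracted")
  cfg <- tiny_config(seed = 12)
  r <- simulate_roster(cfg)
  a <- simulate_activity(r, protocol_forskolin(), kinetic_params())
  st <- render_stack(r, a, tiny_optics(seed = 12))
  m2 <- gate_expression(segment_cells(st$frames[[1]]), threshold = 0)
  sub <- rolling_ball_subtract(st$frames[[30]], 8)
  dd <- detect_droplets(sub, m2, quant_params())
  cell_px <- m2$pixels[["1"]]
  for (p in attr(dd, "pixels")) expect_true(all(p %in% cell_px))
})

test_that("detected droplet components agree with brute-force 8-connected labelling", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(runif(20 * 20) < 0.25, 20, 20)
    lab <- bf_label8(m)
    comp <- sparkdrop:::label_components8(which(m), dim(m))
    idx <- attr(comp, "idx")
    # same partition: equal number of components and identical grouping
    expect_equal(max(comp), max(lab))
    expect_true(all(tapply(lab[idx], comp, function(x) length(unique(x))) == 1))
  }
})
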