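test_that("connected component labelling honours connectivity and the speck filter", {
  mask <- matrix(FALSE, 12, 12)
  mask[2:4, 2:4] <- TRUE
  mask[7:9, 7:9] <- TRUE
  comps <- label_particles(mask, 8L, 1L)
  expect_length(comps, 2L)
  expect_equal(sort(vapply(comps, nrow, 1L)), c(9L, 9L))
  # corner touch: one component under 8-connectivity, two under 4
  corner <- matrix(FALSE, 8, 8)
  corner[2:3, 2:3] <- TRUE
  corner[4:5, 4:5] <- TRUE
  expect_length(label_particles(corner, 8L, 1L), 1L)
  expect_length(label_particles(corner, 4L, 1L), 2L)
  # speck filter
  speck <- matrix(FALSE, 8, 8); speck[2, 2] <- TRUE; speck[5:6, 5:6] <- TRUE
  expect_length(label_particles(speck, 8L, 2L), 1L)
  # empty mask
  expect_length(label_particles(matrix(FALSE, 4, 4)), 0L)
  # border exclusion
  border <- matrix(FALSE, 8, 8); border[1:2, 1:2] <- TRUE; border[4:5, 4:5] <- TRUE
  expect_length(label_particles(border, 8L, 1L, exclude_border = TRUE), 1L)
})

test_that("an axis-aligned rectangle measures exactly", {
  px <- as.matrix(expand.grid(x = 0:19, y = 0:9))
  gray <- matrix(100, 30, 30)
  m <- measure_particle(px, gray)
  expect_equal(m$Area, 200L)
  expect_equal(m$Solidity, 1)
  expect_equal(m$AR, 2, tolerance = 0.05)
  expect_equal(m$Round, 0.5, tolerance = 0.05)
  expect_equal(m$MaxFeret, sqrt(20^2 + 10^2))  # across pixel-square corners
  expect_equal(m$MinFeret, 10)
  expect_equal(m$Mean, 100); expect_equal(m$StdDev, 0)
})

test_that("circularity of a rasterised disk is 1.0 within tolerance and capped", {
  n <- 111
  disk <- which(outer(1:n, 1:n, function(y, x) (x - 56)^2 + (y - 56)^2 <= 50^2))
  px <- cbind(x = (disk - 1) %/% n, y = (disk - 1) %% n)
  gray <- matrix(50, n, n)
  m <- measure_particle(px, gray)
  expect_equal(m$Circ, 1)
  circ_precap <- 4 * pi * m$Area / m$Perim^2
  expect_lt(abs(circ_precap - 1), 0.05)
})

test_that("intensity statistics follow their defining formulas", {
  px <- cbind(x = 0:9, y = rep(0L, 10))
  gray <- matrix(100, 1, 10)
  m <- measure_particle(px, gray)
  expect_equal(m$Mean, 100)
  expect_equal(m$IntDen, 1000)
  expect_equal(m$RawIntDen, 1000)
  expect_equal(m$StdDev, 0)
  expect_equal(m$Skew, 0); expect_equal(m$Kurt, 0)  # documented convention
  gray2 <- matrix(c(10, 10, 20), 1, 3)
  m2 <- measure_particle(cbind(x = 0:2, y = rep(0L, 3)), gray2)
  expect_equal(m2$Mode, 10)
  expect_equal(m2$Median, 10)
  expect_equal(m2$Min, 10); expect_equal(m2$Max, 20)
  # mode ties resolve to the smallest gray value
  gray3 <- matrix(c(7, 7, 9, 9), 1, 4)
  expect_equal(measure_particle(cbind(x = 0:3, y = rep(0L, 4)), gray3)$Mode, 7)
})

test_that("a single-pixel particle reports the documented degenerate values", {
  m <- measure_particle(cbind(x = 3L, y = 3L), matrix(42, 8, 8))
  expect_equal(m$Circ, 1); expect_equal(m$AR, 1); expect_equal(m$Round, 1)
  expect_equal(m$Solidity, 1)
  expect_equal(m$MaxFeret, 1); expect_equal(m$MinFeret, 1)
  expect_equal(m$Perim, 4)
  expect_equal(m$StdDev, 0)
})

test_that("measurements agree with brute-force oracles on random shapes", {
  set.seed(99)
  n_shapes <- 110
  for (s in seq_len(n_shapes)) {
    px <- random_shape_pixels(1000 + s)
    if (nrow(px) < 4) next
    H <- max(px[, 2]) + 2L; W <- max(px[, 1]) + 2L
    gray <- matrix(sample(0:255, H * W, replace = TRUE), H, W)
    m <- measure_particle(px, gray)
    vals <- gray[cbind(px[, 2] + 1L, px[, 1] + 1L)]
    # intensity moments by direct summation
    expect_equal(m$Mean, sum(vals) / length(vals), tolerance = 1e-12)
    expect_equal(m$RawIntDen, sum(vals))
    expect_equal(m$IntDen, nrow(px) * mean(vals), tolerance = 1e-9)
    mu <- mean(vals); m2 <- mean((vals - mu)^2)
    expect_equal(m$Skew, mean((vals - mu)^3) / m2^1.5, tolerance = 1e-9)
    expect_equal(m$Kurt, mean((vals - mu)^4) / m2^2 - 3, tolerance = 1e-9)
    expect_equal(m$StdDev, sqrt(sum((vals - mu)^2) / (length(vals) - 1)),
                 tolerance = 1e-9)
    # geometry against exhaustive searches
    expect_equal(m$MaxFeret, oracle_max_feret(px), tolerance = 1e-9)
    expect_equal(m$MinFeret, oracle_min_feret(px), tolerance = 5e-3)
    expect_equal(m$Solidity, nrow(px) / oracle_hull_area(px), tolerance = 1e-9)
    expect_true(m$AR >= 1 && m$Round > 0 && m$Round <= 1)
    expect_equal(m$Round, 1 / m$AR, tolerance = 1e-12)
  }
})

test_that("measurements scale correctly with linear size", {
  rect <- function(w, h) as.matrix(expand.grid(x = 0:(w - 1), y = 0:(h - 1)))
  gray <- matrix(10, 60, 60)
  m1 <- measure_particle(rect(14, 7), gray)
  m2 <- measure_particle(rect(28, 14), gray)
  expect_equal(m2$Area, 4 * m1$Area)
  ellipse <- function(scale) {
    a <- 12 * scale; b <- 8 * scale
    n <- ceiling(a) * 2 + 3
    g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
    c0 <- n / 2
    as.matrix(g[((g$x - c0) / a)^2 + ((g$y - c0) / b)^2 <= 1, ])
  }
  g2 <- matrix(10, 120, 120)
  e1 <- measure_particle(ellipse(1), g2)
  e2 <- measure_particle(ellipse(2), g2)
  expect_equal(e2$Perim / e1$Perim, 2, tolerance = 0.03)
  for (f in c("Circ", "AR", "Round", "Solidity"))
    expect_equal(e2[[f]] / e1[[f]], 1, tolerance = 0.03)
})

test_that("aspect ratio and solidity are robust to rotation of the generating ellipse", {
  shapes <- lapply(seq(0, 150, by = 30), function(deg) {
    th <- deg * pi / 180
    n <- 61; c0 <- 31
    g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
    dx <- g$x - c0; dy <- g$y - c0
    xr <- dx * cos(th) + dy * sin(th); yr <- -dx * sin(th) + dy * cos(th)
    as.matrix(g[(xr / 18)^2 + (yr / 10)^2 <= 1, ])
  })
  gray <- matrix(10, 62, 62)
  ms <- lapply(shapes, measure_particle, gray = gray)
  ars <- vapply(ms, function(m) m$AR, numeric(1))
  sol <- vapply(ms, function(m) m$Solidity, numeric(1))
  expect_lt((max(ars) - min(ars)) / mean(ars), 0.05)
  expect_lt((max(sol) - min(sol)) / mean(sol), 0.05)
})

test_that("image totals sum particle areas and count particles", {
  expect_equal(image_totals(fake_particles(numeric(0))),
               list(count = 0L, total_area_px = 0))
  tot <- image_totals(fake_particles(c(9, 9)))
  expect_equal(tot$count, 2L)
  expect_equal(tot$total_area_px, 18)
})
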