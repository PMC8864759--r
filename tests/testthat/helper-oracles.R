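# Brute-force oracles, intentionally independent of the package internals.

# all pixel-square corner points of a pixel set (0-based centres)
oracle_corners <- function(px) {
  x <- rep(px[, 1], 4) + rep(c(-0.5, 0.5, -0.5, 0.5), each = nrow(px))
  y <- rep(px[, 2], 4) + rep(c(-0.5, -0.5, 0.5, 0.5), each = nrow(px))
  unique(cbind(x, y))
}

# max Feret: max pairwise distance over ALL corner points (O(n^2))
oracle_max_feret <- function(px) {
  p <- oracle_corners(px)
  m <- as.matrix(dist(p))
  max(m)
}

# min Feret: minimum projected width over a fine caliper rotation sweep
oracle_min_feret <- function(px, step_deg = 0.25) {
  p <- oracle_corners(px)
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  widths <- vapply(ang, function(a) {
    proj <- p[, 1] * cos(a) + p[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  min(widths)
}

# convex hull area by an independent route: Andrew's monotone chain +
# triangle fan area (no chull(), no shoelace on the package's hull)
oracle_hull_area <- function(px) {
  p <- oracle_corners(px)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  cross <- function(o, a, b)
    unname((a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1]))
  build <- function(pts) {
    h <- list()
    for (i in seq_len(nrow(pts))) {
      while (length(h) >= 2 &&
             cross(h[[length(h) - 1]], h[[length(h)]], pts[i, ]) <= 0)
        h[[length(h)]] <- NULL
      h[[length(h) + 1]] <- pts[i, ]
    }
    h
  }
  lower <- build(p)
  upper <- build(p[rev(seq_len(nrow(p))), , drop = FALSE])
  hull <- do.call(rbind, c(lower[-length(lower)], upper[-length(upper)]))
  a <- 0
  for (i in 2:(nrow(hull) - 1))
    a <- a + cross(hull[1, ], hull[i, ], hull[i + 1, ])
  abs(a) / 2
}

# exhaustive Otsu: try every threshold, compute between-class variance
# directly from the two class populations
oracle_otsu <- function(values) {
  values <- as.integer(round(values))
  best_t <- NA; best_s <- -Inf
  for (t in 0:254) {
    lo <- values[values <= t]; hi <- values[values > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(values); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

# AUC by all-pairs Mann-Whitney counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# pooled-variance two-sided Student's t p-value from the closed form
oracle_student_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(t), nx + ny - 2)
}

# random rasterised shapes for oracle-equivalence sweeps
random_shape_pixels <- function(seed) {
  set.seed(seed)
  kind <- sample(c("ellipse", "rect", "blob"), 1)
  if (kind == "rect") {
    w <- sample(3:30, 1); h <- sample(3:30, 1)
    as.matrix(expand.grid(x = 0:(w - 1), y = 0:(h - 1)))
  } else if (kind == "ellipse") {
    a <- runif(1, 4, 20); b <- runif(1, 2, a); th <- runif(1, 0, pi)
    n <- ceiling(a) * 2 + 3; c0 <- n / 2
    g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
    dx <- g$x - c0; dy <- g$y - c0
    xr <- dx * cos(th) + dy * sin(th); yr <- -dx * sin(th) + dy * cos(th)
    as.matrix(g[(xr / a)^2 + (yr / b)^2 <= 1, ])
  } else {
    # union of 2-3 overlapping ellipses: an irregular connected blob
    n <- 50; keep <- matrix(FALSE, n, n)
    nk <- sample(2:3, 1)
    cx <- 25 + cumsum(c(0, runif(nk - 1, -6, 6)))
    cy <- 25 + cumsum(c(0, runif(nk - 1, -6, 6)))
    for (k in seq_len(nk)) {
      a <- runif(1, 5, 12); b <- runif(1, 3, a); th <- runif(1, 0, pi)
      g <- expand.grid(x = 0:(n - 1), y = 0:(n - 1))
      dx <- g$x - cx[k]; dy <- g$y - cy[k]
      xr <- dx * cos(th) + dy * sin(th); yr <- -dx * sin(th) + dy * cos(th)
      keep[as.matrix(g[(xr / a)^2 + (yr / b)^2 <= 1, c("y", "x")]) + 1L] <- TRUE
    }
    idx <- which(keep)
    cbind(x = (idx - 1) %/% n, y = (idx - 1) %% n)
  }
}
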