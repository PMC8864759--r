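#' Parametric description of a synthetic ThinPrep-like field image
#'
#' A `scene_spec` describes one microscopy field: a bright background with
#' dark elliptical nuclei whose count (cellularity), overlap structure
#' (architecture), size/shape and intensity texture (chromatin) are all
#' class-controllable. Rendering a spec gives an RGB image plus exact ground
#' truth, so segmentation and feature extraction can be validated end to end.
#'
#' Nuclei are rendered hematoxylin-like: the green channel is the most
#' absorbed inside nuclei (purple stain transmits red and blue), so the green
#' channel carries the strongest nucleus/background contrast - the reason the
#' downstream pipeline keeps only that channel.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param background_gray_green Background level of the green channel
#'   (0-255); bright, near 230 for ThinPrep.
#' @param nucleus_count_mean Poisson mean of the per-field nucleus count.
#' @param nucleus_count Optional exact count; overrides the Poisson draw.
#' @param cluster_fraction Fraction of nuclei placed into overlapping groups.
#' @param cluster_size_mean Mean nuclei per cluster (>= 2).
#' @param nucleus_major_axis_px,nucleus_minor_axis_px Length-2 numeric
#'   `c(mean, sd)` of the full major/minor ellipse axes, in pixels.
#' @param nucleus_gray_mean,nucleus_gray_sd Per-nucleus green-channel base
#'   intensity model (0-255); must be darker than the background.
#' @param texture_noise_sd SD of additive per-pixel Gaussian texture noise
#'   inside nuclei (chromatin texture proxy); 0 gives perfectly flat nuclei.
#' @param seed Integer RNG seed; rendering is deterministic given the spec.
#' @return An object of class `scene_spec` (a validated list).
#' @seealso [render_scene()], [study_scene_spec()], [make_cohort()]
#' @export
scene_spec <- function(width_px = 1024L, height_px = 768L,
                       background_gray_green = 230,
                       nucleus_count_mean = 25, nucleus_count = NULL,
                       cluster_fraction = 0.2, cluster_size_mean = 3,
                       nucleus_major_axis_px = c(mean = 28, sd = 3),
                       nucleus_minor_axis_px = c(mean = 21, sd = 2.5),
                       nucleus_gray_mean = 80, nucleus_gray_sd = 8,
                       texture_noise_sd = 15, seed = 1L) {
  spec <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
               background_gray_green = background_gray_green,
               nucleus_count_mean = nucleus_count_mean,
               nucleus_count = if (is.null(nucleus_count)) NULL else as.integer(nucleus_count),
               cluster_fraction = cluster_fraction,
               cluster_size_mean = cluster_size_mean,
               nucleus_major_axis_px = unname(nucleus_major_axis_px),
               nucleus_minor_axis_px = unname(nucleus_minor_axis_px),
               nucleus_gray_mean = nucleus_gray_mean,
               nucleus_gray_sd = nucleus_gray_sd,
               texture_noise_sd = texture_noise_sd,
               seed = as.integer(seed))
  validate_scene_spec(spec)
  class(spec) <- "scene_spec"
  spec
}

validate_scene_spec <- function(spec) {
  stopifnot(spec$width_px >= 8, spec$height_px >= 8,
            spec$background_gray_green >= 0, spec$background_gray_green <= 255,
            spec$nucleus_count_mean >= 0,
            spec$cluster_fraction >= 0, spec$cluster_fraction <= 1,
            spec$cluster_size_mean >= 2,
            length(spec$nucleus_major_axis_px) == 2,
            length(spec$nucleus_minor_axis_px) == 2,
            spec$nucleus_gray_sd >= 0, spec$texture_noise_sd >= 0)
  if (spec$nucleus_gray_mean >= spec$background_gray_green)
    stop("nucleus_gray_mean must be darker than background_gray_green")
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("scene_spec: %dx%d px, bg %g, count mean %g%s, cluster fraction %g\n",
              x$width_px, x$height_px, x$background_gray_green,
              x$nucleus_count_mean,
              if (!is.null(x$nucleus_count)) sprintf(" (fixed %d)", x$nucleus_count) else "",
              x$cluster_fraction))
  invisible(x)
}

#' Class- and magnification-conditional scene defaults for the study design
#'
#' Returns a [scene_spec()] whose parameters emulate the two diagnostic
#' classes of the thyroid FNA study (follicular adenoma = positive, benign
#' thyroid = negative) at the two magnification tiers. Defaults are anchored
#' to the printed per-class feature means of the clinical cohort: mid-power
#' nucleus count about 269 vs 164 per field, mid-power nuclear area about
#' 153 vs 129 px, high-power single-nucleus area about 482 vs 462 px with
#' aspect ratio near 1.3, darker and more textured chromatin and a higher
#' clustered fraction in adenoma.
#'
#' When a non-default frame size is requested, the nucleus count mean is
#' scaled by the frame-area ratio so nuclear density (the quantity cellularity
#' actually measures) is preserved at reduced rendering scales.
#'
#' @param class `"adenoma"` (positive) or `"benign"` (negative).
#' @param magnification `"mid"` (100x overview field) or `"high"` (400x).
#' @param width_px,height_px Frame size; defaults 1024x768.
#' @param seed RNG seed stored in the spec.
#' @param ... Overrides passed on to [scene_spec()].
#' @return A `scene_spec`.
#' @export
study_scene_spec <- function(class = c("adenoma", "benign"),
                             magnification = c("mid", "high"),
                             width_px = 1024L, height_px = 768L,
                             seed = 1L, ...) {
  class <- match.arg(class)
  magnification <- match.arg(magnification)
  scale <- (as.double(width_px) * height_px) / (1024 * 768)
  base <- if (magnification == "mid") {
    if (class == "adenoma")
      list(nucleus_count_mean = 269 * scale, cluster_fraction = 0.15,
           cluster_size_mean = 3,
           nucleus_major_axis_px = c(16.0, 2.0), nucleus_minor_axis_px = c(12.2, 1.5),
           nucleus_gray_mean = 168, nucleus_gray_sd = 6, texture_noise_sd = 10)
    else
      list(nucleus_count_mean = 164 * scale, cluster_fraction = 0.12,
           cluster_size_mean = 3,
           nucleus_major_axis_px = c(14.7, 2.0), nucleus_minor_axis_px = c(11.2, 1.5),
           nucleus_gray_mean = 172, nucleus_gray_sd = 6, texture_noise_sd = 10)
  } else {
    if (class == "adenoma")
      list(nucleus_count_mean = 28 * scale, cluster_fraction = 0.35,
           cluster_size_mean = 4,
           nucleus_major_axis_px = c(28.4, 3.0), nucleus_minor_axis_px = c(21.7, 2.5),
           nucleus_gray_mean = 82, nucleus_gray_sd = 8, texture_noise_sd = 20)
    else
      list(nucleus_count_mean = 20 * scale, cluster_fraction = 0.20,
           cluster_size_mean = 3,
           nucleus_major_axis_px = c(28.1, 3.0), nucleus_minor_axis_px = c(21.0, 2.5),
           nucleus_gray_mean = 92, nucleus_gray_sd = 8, texture_noise_sd = 18)
  }
  args <- utils::modifyList(
    c(list(width_px = width_px, height_px = height_px, seed = seed), base),
    list(...))
  do.call(scene_spec, args)
}

# Sample per-nucleus geometry; full axes -> semi-axes, major >= minor >= 1.2.
sample_nuclei_geometry <- function(n, spec) {
  maj <- rnorm(n, spec$nucleus_major_axis_px[1], spec$nucleus_major_axis_px[2])
  mnr <- rnorm(n, spec$nucleus_minor_axis_px[1], spec$nucleus_minor_axis_px[2])
  a <- pmax(maj, mnr) / 2
  b <- pmin(maj, mnr) / 2
  a <- pmax(a, 1.2); b <- pmax(b, 1.2)
  data.frame(a = a, b = b, theta = runif(n, 0, pi),
             gray = clip255(rnorm(n, spec$nucleus_gray_mean, spec$nucleus_gray_sd)))
}

# Partition m clustered nuclei into cluster sizes (each >= 2).
sample_cluster_sizes <- function(m, cluster_size_mean) {
  sizes <- integer(0)
  while (m >= 2) {
    s <- 2 + rpois(1, max(0, cluster_size_mean - 2))
    s <- min(s, m)
    if (m - s == 1) s <- s + 1  # avoid a leftover singleton "cluster"
    sizes <- c(sizes, s)
    m <- m - s
  }
  sizes
}

#' Render a synthetic field image with ground truth
#'
#' Deterministically renders the scene described by a [scene_spec()]: nuclei
#' are filled rotated ellipses with per-nucleus base gray and additive
#' per-pixel Gaussian texture noise, on a flat bright background. Non-cluster
#' nuclei are rejection-sampled to be pairwise disjoint; cluster members are
#' placed with centre separation at most 0.8 times the sum of their minor
#' semi-axes, which guarantees pairwise overlap (every ellipse contains the
#' circle of its minor semi-axis), so each cluster forms one connected dark
#' region. All nuclei lie fully inside the frame.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{image}{integer array `height x width x 3` (R, G, B), 0-255.}
#'     \item{truth}{list with `count`, `nuclei` (data frame: `id`, `cx`, `cy`
#'       continuous 0-based centre coordinates, semi-axes `a`, `b`, angle
#'       `theta`, `cluster` id or `NA`), and `clusters` (member-id lists).}
#'   }
#' @export
render_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, render_scene_impl(spec))
}

render_scene_impl <- function(spec) {
  W <- spec$width_px; H <- spec$height_px
  n <- if (!is.null(spec$nucleus_count)) spec$nucleus_count else rpois(1, spec$nucleus_count_mean)

  bg <- spec$background_gray_green
  G <- matrix(bg, nrow = H, ncol = W)
  empty_truth <- list(count = 0L,
                      nuclei = data.frame(id = integer(0), cx = double(0), cy = double(0),
                                          a = double(0), b = double(0), theta = double(0),
                                          cluster = integer(0)),
                      clusters = list())
  if (n == 0) {
    return(list(image = compose_rgb(G, matrix(FALSE, H, W), bg), truth = empty_truth))
  }

  geom <- sample_nuclei_geometry(n, spec)
  m <- round(spec$cluster_fraction * n)
  if (m < 2) m <- 0
  sizes <- sample_cluster_sizes(m, spec$cluster_size_mean)
  m <- sum(sizes)

  # placement: (cx, cy, clearance radius) of every accepted nucleus
  placed <- matrix(numeric(0), ncol = 3)
  nuc <- data.frame(id = seq_len(n), cx = NA_real_, cy = NA_real_,
                    a = geom$a, b = geom$b, theta = geom$theta,
                    cluster = NA_integer_)
  clusters <- list()
  next_id <- 1L

  place_free <- function(a, clearance_against, margin, max_try = 1000L) {
    # rejection-sample a centre with the ellipse fully in frame and no
    # overlap against previously placed clearance circles
    for (i in seq_len(max_try)) {
      cx <- runif(1, margin, W - 1 - margin)
      cy <- runif(1, margin, H - 1 - margin)
      if (nrow(clearance_against) == 0) return(c(cx, cy))
      d <- sqrt((clearance_against[, 1] - cx)^2 + (clearance_against[, 2] - cy)^2)
      if (all(d > clearance_against[, 3] + a + 1)) return(c(cx, cy))
    }
    stop("placement failure: frame too small for the requested nuclei")
  }

  # clusters first (they need the most room)
  ci <- 0L
  for (s in sizes) {
    ci <- ci + 1L
    ids <- next_id:(next_id + s - 1L); next_id <- next_id + s
    ext <- 2.2 * max(geom$a[ids]) * sqrt(s) / 2 + max(geom$a[ids])
    ctr <- place_free(ext, placed, margin = min(ext + 1, (min(W, H) - 2) / 2 - 1))
    members <- matrix(numeric(0), ncol = 2)
    for (k in seq_along(ids)) {
      id <- ids[k]
      if (k == 1) {
        pos <- ctr
      } else {
        ok <- FALSE
        for (tries in seq_len(1000L)) {
          anchor <- members[sample.int(nrow(members), 1), ]
          j <- ids[sample.int(k - 1, 1)]  # overlap partner already placed
          dist <- runif(1, 0.35, 0.8) * (geom$b[id] + geom$b[j])
          ang <- runif(1, 0, 2 * pi)
          pos <- c(anchor[1] + dist * cos(ang), anchor[2] + dist * sin(ang))
          mar <- geom$a[id] + 1
          if (pos[1] >= mar && pos[1] <= W - 1 - mar &&
              pos[2] >= mar && pos[2] <= H - 1 - mar) { ok <- TRUE; break }
        }
        if (!ok) stop("placement failure: cluster member does not fit in frame")
      }
      members <- rbind(members, pos)
      nuc$cx[id] <- pos[1]; nuc$cy[id] <- pos[2]; nuc$cluster[id] <- ci
    }
    clusters[[ci]] <- ids
    placed <- rbind(placed, c(ctr[1], ctr[2], ext))
  }

  # isolated singles: pairwise disjoint from everything
  if (next_id <= n) for (id in next_id:n) {
    pos <- place_free(geom$a[id], placed, margin = geom$a[id] + 1)
    nuc$cx[id] <- pos[1]; nuc$cy[id] <- pos[2]
    placed <- rbind(placed, c(pos[1], pos[2], geom$a[id]))
  }

  # rasterise (pixel (x, y) has centre (x, y), 0-based)
  inside <- matrix(FALSE, H, W)
  for (id in seq_len(n)) {
    px <- ellipse_pixels(nuc$cx[id], nuc$cy[id], nuc$a[id], nuc$b[id], nuc$theta[id], W, H)
    if (nrow(px) == 0) next
    lin <- px[, 2] + 1L + (px[, 1]) * H
    G[lin] <- geom$gray[id]
    inside[lin] <- TRUE
  }
  if (spec$texture_noise_sd > 0) {
    idx <- which(inside)
    G[idx] <- clip255(G[idx] + rnorm(length(idx), 0, spec$texture_noise_sd))
  }
  G <- round(G)

  list(image = compose_rgb(G, inside, bg),
       truth = list(count = n, nuclei = nuc, clusters = clusters))
}

# Pixel centres inside a rotated ellipse, clipped to the frame.
# Returns a matrix with columns x, y (0-based integer coordinates).
ellipse_pixels <- function(cx, cy, a, b, theta, W, H) {
  r <- ceiling(a) + 1
  xs <- max(0, floor(cx - r)):min(W - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(H - 1, ceiling(cy + r))
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  dx <- gx - cx; dy <- gy - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  keep <- (xr / a)^2 + (yr / b)^2 <= 1
  cbind(x = gx[keep], y = gy[keep])
}

# Hematoxylin-like colouring: green most absorbed inside nuclei, blue least.
compose_rgb <- function(G, nucleus_mask, bg) {
  H <- nrow(G); W <- ncol(G)
  R <- matrix(bg, H, W); B <- matrix(bg, H, W)
  idx <- which(nucleus_mask)
  R[idx] <- clip255(G[idx] + 35)
  B[idx] <- clip255(G[idx] + 75)
  img <- array(0L, dim = c(H, W, 3))
  img[, , 1] <- as.integer(round(R))
  img[, , 2] <- as.integer(round(G))
  img[, , 3] <- as.integer(round(B))
  img
}

#' Generate a labelled synthetic cohort on disk
#'
#' Emulates the study design: `n_cases_per_class` cases per diagnostic class,
#' each contributing `mid_per_case` mid-power (100x) and `high_per_case`
#' high-power (400x) field images (defaults 10 + 10, so 20 + 20 cases yield
#' 800 images). Per-image seeds are derived deterministically from the master
#' seed. Writes images, one ground-truth JSON per image, and a
#' `manifest.csv` with columns `case_id,label,magnification,image_path`
#' (paths relative to `out_dir`).
#'
#' @param class_pos,class_neg Scene specs for the positive (follicular
#'   adenoma) and negative (benign) class: either a single [scene_spec()]
#'   used for both tiers, or a list with elements `mid` and `high`.
#' @param n_cases_per_class Cases per class (>= 1).
#' @param mid_per_case,high_per_case Fields per case per tier (0 allowed).
#' @param out_dir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param format `"png"` (default) or `"tiff"`.
#' @return Invisibly, the manifest data frame (also written to
#'   `file.path(out_dir, "manifest.csv")`).
#' @export
make_cohort <- function(class_pos, class_neg, n_cases_per_class,
                        mid_per_case = 10L, high_per_case = 10L,
                        out_dir, seed = 1L, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(n_cases_per_class >= 1, mid_per_case >= 0, high_per_case >= 0)
  as_tier_list <- function(x) {
    if (inherits(x, "scene_spec")) list(mid = x, high = x)
    else { stopifnot(is.list(x), all(c("mid", "high") %in% names(x))); x }
  }
  class_pos <- as_tier_list(class_pos); class_neg <- as_tier_list(class_neg)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  rows <- list()
  labels <- c(pos = "adenoma", neg = "benign")
  for (cls in c("pos", "neg")) {
    specs <- if (cls == "pos") class_pos else class_neg
    for (i in seq_len(n_cases_per_class)) {
      case_id <- sprintf("%s_%03d", labels[[cls]], i)
      for (mag in c("mid", "high")) {
        nfield <- if (mag == "mid") mid_per_case else high_per_case
        for (j in seq_len(nfield)) {
          sp <- specs[[mag]]
          sp$seed <- derive_seed(seed, match(cls, c("pos", "neg")), i,
                                 match(mag, c("mid", "high")), j)
          scene <- render_scene(sp)
          base <- sprintf("%s_%s_%02d", case_id, mag, j)
          rel <- file.path("images", paste0(base, ".", format))
          write_field_image(scene$image, file.path(out_dir, rel), format)
          truth <- scene$truth
          jsonlite::write_json(
            list(count = truth$count, nuclei = truth$nuclei, clusters = truth$clusters),
            file.path(out_dir, "images", paste0(base, ".json")),
            auto_unbox = TRUE, digits = NA, na = "null")
          rows[[length(rows) + 1L]] <- data.frame(
            case_id = case_id, label = labels[[cls]], magnification = mag,
            image_path = rel, stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Write an RGB field image to disk
#' @param img integer array `H x W x 3`, 0-255.
#' @param path Destination file.
#' @param format `"png"` or `"tiff"`.
#' @export
write_field_image <- function(img, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  arr <- img / 255
  if (format == "png") png::writePNG(arr, target = path)
  else tiff::writeTIFF(arr, where = path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an RGB field image (PNG or TIFF) as an integer 0-255 array
#' @param path Image file; format inferred from the extension.
#' @return Integer array `H x W x 3`.
#' @export
read_field_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  array(as.integer(round(arr * 255)), dim = dim(arr))
}
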