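# Small-frame scene builders and in-memory cohort rendering used across the
# integration tests. Frames are reduced (256x192 or smaller) with nucleus
# counts chosen to keep per-field nuclear density realistic, so suites stay
# fast while exercising the full pipeline.

fast_cfg <- function(...) dia_config(background_radius = 25L, ...)

# high-power-like field: ~480 px nuclei
hp_spec <- function(count_mean = 10, gray_mean = 85, cluster_fraction = 0.25,
                    seed = 1L, width = 288L, height = 216L, ...) {
  scene_spec(width_px = width, height_px = height,
             nucleus_count_mean = count_mean,
             cluster_fraction = cluster_fraction, cluster_size_mean = 3,
             nucleus_major_axis_px = c(28.4, 3), nucleus_minor_axis_px = c(21.7, 2.5),
             nucleus_gray_mean = gray_mean, nucleus_gray_sd = 8,
             texture_noise_sd = 18, seed = seed, ...)
}

# mid-power-like field: ~150 px nuclei, higher count
mp_spec <- function(count_mean = 30, gray_mean = 168, seed = 1L,
                    width = 288L, height = 216L, ...) {
  scene_spec(width_px = width, height_px = height,
             nucleus_count_mean = count_mean, cluster_fraction = 0.12,
             cluster_size_mean = 3,
             nucleus_major_axis_px = c(16, 2), nucleus_minor_axis_px = c(12.2, 1.5),
             nucleus_gray_mean = gray_mean, nucleus_gray_sd = 6,
             texture_noise_sd = 10, seed = seed, ...)
}

# very small nuclei in a very small frame: for layout/counting tests where
# only file structure matters, not morphometry
tiny_spec <- function(count_mean = 3, seed = 1L) {
  scene_spec(width_px = 96L, height_px = 72L, nucleus_count_mean = count_mean,
             cluster_fraction = 0, nucleus_major_axis_px = c(12, 1.5),
             nucleus_minor_axis_px = c(9, 1), nucleus_gray_mean = 120,
             nucleus_gray_sd = 6, texture_noise_sd = 8, seed = seed)
}

# Render a labelled cohort in memory and return its feature table.
# pos/neg: named lists of scene specs by magnification tier, e.g.
# list(high = hp_spec()); n_fields applies per tier.
render_table <- function(pos, neg, n_cases = 10, n_fields = 4, seed = 7L,
                         config = fast_cfg()) {
  feats <- config$schema$name
  rows <- list()
  for (cls in c("adenoma", "benign")) {
    specs <- if (cls == "adenoma") pos else neg
    for (i in seq_len(n_cases)) {
      case_id <- sprintf("%s_%03d", cls, i)
      for (mag in names(specs)) for (j in seq_len(n_fields)) {
        sp <- specs[[mag]]
        sp$seed <- tpdia:::derive_seed(seed, match(cls, c("adenoma", "benign")),
                                       i, match(mag, c("mid", "high")), j)
        fv <- extract_image_features(render_scene(sp)$image, mag, config)
        full <- setNames(rep(NA_real_, length(feats)), feats)
        full[names(fv)] <- fv
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(image_id = sprintf("%s_%s_%02d", case_id, mag, j),
                     case_id = case_id, label = cls, magnification = mag,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(full)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Hand-built feature table (no images) for pure modeling tests: `gen` maps
# (label, n) to a named list of feature columns.
toy_table <- function(gen, n_cases_per_class = 20, images_per_case = 2,
                      magnification = "high", seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (cls in c("adenoma", "benign")) {
    for (i in seq_len(n_cases_per_class)) {
      n <- images_per_case
      vals <- gen(cls, n)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(image_id = sprintf("%s_%03d_%d", cls, i, seq_len(n)),
                   case_id = sprintf("%s_%03d", cls, i), label = cls,
                   magnification = magnification, stringsAsFactors = FALSE),
        as.data.frame(vals))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Particle data frame with every measurement column present; area/circ are
# controlled, everything else is filler noise.
fake_particles <- function(area, circ = rep(0.8, length(area)), seed = 1L) {
  set.seed(seed)
  n <- length(area)
  filler <- function() runif(n, 1, 10)
  data.frame(particle_id = seq_len(n), Area = area, Perim = filler(),
             Circ = circ, AR = filler(), Round = filler(), Solidity = filler(),
             MaxFeret = filler(), MinFeret = filler(), Mean = filler(),
             Median = filler(), Mode = filler(), Min = filler(), Max = filler(),
             StdDev = filler(), Skew = filler(), Kurt = filler(),
             IntDen = filler(), RawIntDen = filler())
}
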