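#' Gate configuration: single nuclei versus overlapping clusters
#'
#' High-power particles are gated by area and circularity: single nuclei
#' have areas in \[100, 1200) px and circularity in \[0.5, 1.0\]; overlapping
#' clusters have areas in \[1200, Inf) px and circularity in \[0.0, 1.0\].
#' Everything matching neither rule (debris, specks, elongated artefacts) is
#' rejected. Area intervals are half-open so the two rules are disjoint and
#' a particle of exactly 1200 px is a cluster; circularity bounds are closed.
#' Mid-power fields are not gated (`apply = FALSE`): every particle belongs
#' to one ungated population.
#'
#' @param single_area,cluster_area Length-2 numeric area ranges (px).
#' @param single_circ,cluster_circ Length-2 circularity ranges.
#' @param apply Apply the gate (`FALSE` = pass-through "none" label).
#' @return Object of class `gate_config`.
#' @export
gate_config <- function(single_area = c(100, 1200), single_circ = c(0.5, 1),
                        cluster_area = c(1200, Inf), cluster_circ = c(0, 1),
                        apply = TRUE) {
  stopifnot(single_area[2] <= cluster_area[1])  # ranges disjoint (half-open)
  structure(list(single_area = single_area, single_circ = single_circ,
                 cluster_area = cluster_area, cluster_circ = cluster_circ,
                 apply = apply),
            class = "gate_config")
}

#' Assign particles to the single / cluster / rejected populations
#'
#' @param area,circ Numeric vectors of particle area (px) and circularity.
#' @param cfg A [gate_config()].
#' @return Character vector: `"single"`, `"cluster"` or `"rejected"`
#'   (`"none"` for every particle when `cfg$apply` is `FALSE`).
#' @export
gate_particle <- function(area, circ, cfg = gate_config()) {
  if (!cfg$apply) return(rep("none", length(area)))
  single <- area >= cfg$single_area[1] & area < cfg$single_area[2] &
    circ >= cfg$single_circ[1] & circ <= cfg$single_circ[2]
  cluster <- area >= cfg$cluster_area[1] & area < cfg$cluster_area[2] &
    circ >= cfg$cluster_circ[1] & circ <= cfg$cluster_circ[2]
  out <- rep("rejected", length(area))
  out[single] <- "single"
  out[cluster] <- "cluster"
  out
}

#' The 86-feature engineered schema
#'
#' Registry of every engineered feature with its magnification tier, gate,
#' base measurement, aggregation and feature-model membership. The mid-power
#' (100x) tier has 14 features: the two cellularity measurements (`Count`,
#' `TotalArea`) plus the per-image means of 12 ungated particle
#' measurements. The high-power (400x) tier has 72: 16 architecture features
#' (mean and standard deviation of 8 geometry measurements over
#' cluster-gated particles), 40 chromatin features (10 intensity
#' measurements x single/cluster gate x mean/StdDv), 14 shape features
#' (7 geometry measurements over single nuclei x mean/StdDv) and 2 size
#' features (`AreaSingleMean`, `AreaSingleStdDv`). Cytology is the union of
#' chromatin, shape and size (56 features).
#'
#' Feature names follow `{Base}{Gate}{Agg}` (e.g. `IntDenSingleStdDv`);
#' mid-power features use gate label `None` and `Count`/`TotalArea` keep
#' their plain names.
#'
#' @return Data frame with columns `name`, `magnification` (`mid`/`high`),
#'   `gate` (`none`/`single`/`cluster`), `base`, `aggregation`
#'   (`mean`/`stddv`/`total`), `medium_group`, `high_group`.
#' @export
feature_schema <- function() {
  rows <- list()
  add <- function(base, mag, gate, agg, medium, high) {
    nm <- if (base %in% c("Count", "TotalArea")) base
          else paste0(base, tools::toTitleCase(gate), c(mean = "Mean", stddv = "StdDv")[agg])
    rows[[length(rows) + 1L]] <<- data.frame(
      name = nm, magnification = mag, gate = gate, base = base,
      aggregation = agg, medium_group = medium, high_group = high,
      stringsAsFactors = FALSE)
  }
  # mid-power: cellularity totals + ungated means
  add("Count", "mid", "none", "total", "none", "cellularity")
  add("TotalArea", "mid", "none", "total", "none", "cellularity")
  for (b in c("Area", "Circ", "MaxFeret", "IntDen", "Kurt", "Mean", "Median",
              "MinFeret", "Mode", "Perim", "Skew", "Solidity"))
    add(b, "mid", "none", "mean", "none", "none")
  # high-power architecture: cluster-gated geometry
  for (b in c("AR", "Area", "Circ", "MaxFeret", "MinFeret", "Perim", "Round",
              "Solidity"))
    for (agg in c("mean", "stddv"))
      add(b, "high", "cluster", agg, "none", "architecture")
  # high-power chromatin: intensity statistics over both gates
  for (b in c("IntDen", "Kurt", "Max", "Mean", "Median", "Min", "Mode",
              "RawIntDen", "Skew", "StdDev"))
    for (gate in c("single", "cluster"))
      for (agg in c("mean", "stddv"))
        add(b, "high", gate, agg, "chromatin", "cytology")
  # high-power shape: single-gated geometry (no Area - that is size)
  for (b in c("AR", "Circ", "MaxFeret", "MinFeret", "Perim", "Round",
              "Solidity"))
    for (agg in c("mean", "stddv"))
      add(b, "high", "single", agg, "shape", "cytology")
  # high-power size
  for (agg in c("mean", "stddv"))
    add("Area", "high", "single", agg, "size", "cytology")
  do.call(rbind, rows)
}

#' Feature-model subsets of the schema
#'
#' @param name One of `"mid_power"`, `"high_power"`, `"cellularity"`,
#'   `"architecture"`, `"cytology"`, `"chromatin"`, `"shape"`, `"size"`.
#' @param schema Schema data frame (defaults to [feature_schema()]).
#' @return Character vector of feature names, in stable schema order.
#' @export
schema_subset <- function(name, schema = feature_schema()) {
  switch(name,
         mid_power = schema$name[schema$magnification == "mid"],
         high_power = schema$name[schema$magnification == "high"],
         cellularity = schema$name[schema$high_group == "cellularity"],
         architecture = schema$name[schema$high_group == "architecture"],
         cytology = schema$name[schema$high_group == "cytology"],
         chromatin = schema$name[schema$medium_group == "chromatin"],
         shape = schema$name[schema$medium_group == "shape"],
         size = schema$name[schema$medium_group == "size"],
         stop("unknown feature subset: ", name))
}

#' Aggregate measured particles into one per-image feature vector
#'
#' For each schema feature of the image's magnification tier, computes the
#' mean or sample standard deviation of the base measurement over the
#' particles carrying the feature's gate label (`Count` and `TotalArea` come
#' from [image_totals()]). Gates with no particle yield `NA` means; gates
#' with fewer than two particles yield `NA` standard deviations -
#' missingness is data, not an error.
#'
#' @param particles Data frame from [measure_all()].
#' @param totals List from [image_totals()].
#' @param magnification `"mid"` or `"high"`.
#' @param cfg [gate_config()]; the gate is only applied at high power.
#' @param schema Schema data frame.
#' @return Named numeric vector over the tier's schema feature names.
#' @export
aggregate_image <- function(particles, totals, magnification = c("high", "mid"),
                            cfg = gate_config(), schema = feature_schema()) {
  magnification <- match.arg(magnification)
  sch <- schema[schema$magnification == magnification, ]
  cfg$apply <- cfg$apply && magnification == "high"
  lab <- if (nrow(particles)) gate_particle(particles$Area, particles$Circ, cfg)
         else character(0)
  out <- setNames(rep(NA_real_, nrow(sch)), sch$name)
  for (i in seq_len(nrow(sch))) {
    base <- sch$base[i]
    if (base == "Count") { out[i] <- totals$count; next }
    if (base == "TotalArea") { out[i] <- totals$total_area_px; next }
    v <- particles[[base]][lab == sch$gate[i]]
    out[i] <- if (sch$aggregation[i] == "mean") {
      if (length(v) >= 1) mean(v) else NA_real_
    } else {
      if (length(v) >= 2) sd(v) else NA_real_
    }
  }
  out
}

#' Extract the per-image feature vector from an RGB field image
#'
#' Full single-image pipeline: segmentation ([segment_nuclei()]), particle
#' measurement ([measure_all()]), gating and aggregation
#' ([aggregate_image()]).
#'
#' @param img Integer RGB array (0-255).
#' @param magnification `"mid"` or `"high"`.
#' @param config A [dia_config()].
#' @return Named numeric feature vector for the tier.
#' @export
extract_image_features <- function(img, magnification = c("high", "mid"),
                                   config = dia_config()) {
  magnification <- match.arg(magnification)
  seg <- segment_nuclei(img, config)
  particles <- measure_all(seg$mask, seg$gray, config, magnification)
  aggregate_image(particles, image_totals(particles), magnification,
                  config$gate, config$schema)
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the image pipeline: threshold method,
#' background-subtraction radius, per-tier speck filters, connectivity,
#' border handling and the gate. Defaults reproduce the reference pipeline;
#' the speck filters (4 px mid, 20 px high) sit safely below the 100 px
#' single-nucleus gate floor.
#'
#' @param threshold_method `"otsu"` (default) or `"isodata"`.
#' @param background_radius Disc radius for [subtract_background()].
#' @param min_area_px Named list/vector with `mid` and `high` minimum areas.
#' @param connectivity 4 or 8.
#' @param exclude_border Drop border-touching particles (default `FALSE`).
#' @param gate A [gate_config()].
#' @param positive_label Manifest label of the positive class.
#' @return Object of class `dia_config`.
#' @export
dia_config <- function(threshold_method = "otsu", background_radius = 50L,
                       min_area_px = list(mid = 4L, high = 20L),
                       connectivity = 8L, exclude_border = FALSE,
                       gate = gate_config(), positive_label = "adenoma") {
  structure(list(threshold_method = threshold_method,
                 background_radius = background_radius,
                 min_area_px = as.list(min_area_px),
                 connectivity = connectivity,
                 exclude_border = exclude_border,
                 gate = gate,
                 schema = feature_schema(),
                 positive_label = positive_label),
            class = "dia_config")
}

#' Build the per-image feature table for a whole cohort
#'
#' Applies the full pipeline to every manifest row and assembles one wide
#' table: identifiers plus all 86 schema columns (mid-power rows carry `NA`
#' in high-power columns and vice versa). Unreadable images are skipped with
#' a warning; the number of failures is attached as attribute `n_failed`.
#'
#' @param manifest Data frame with columns `case_id`, `label`,
#'   `magnification`, `image_path`, or the path of a manifest CSV.
#' @param config A [dia_config()].
#' @param base_dir Directory image paths are relative to (defaults to the
#'   manifest's directory when `manifest` is a path, else `"."`).
#' @return Data frame: `image_id`, `case_id`, `label`, `magnification` +
#'   one column per schema feature.
#' @export
build_feature_table <- function(manifest, config = dia_config(),
                                base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (is.null(base_dir)) base_dir <- "."
  need <- c("case_id", "label", "magnification", "image_path")
  stopifnot(all(need %in% names(manifest)))
  feats <- config$schema$name
  rows <- vector("list", nrow(manifest))
  n_failed <- 0L
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$image_path[i]
    if (!file.exists(path)) path <- file.path(base_dir, manifest$image_path[i])
    fv <- tryCatch({
      img <- read_field_image(path)
      extract_image_features(img, manifest$magnification[i], config)
    }, error = function(e) {
      warning(sprintf("skipping %s: %s", manifest$image_path[i], conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(fv)) { n_failed <- n_failed + 1L; next }
    full <- setNames(rep(NA_real_, length(feats)), feats)
    full[names(fv)] <- fv
    rows[[i]] <- cbind(
      data.frame(image_id = sub("\\.[^.]+$", "", basename(manifest$image_path[i])),
                 case_id = manifest$case_id[i], label = manifest$label[i],
                 magnification = manifest$magnification[i],
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(full)))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- cbind(data.frame(image_id = character(0), case_id = character(0),
                            label = character(0), magnification = character(0)),
                 as.data.frame(matrix(numeric(0), 0, length(feats),
                                      dimnames = list(NULL, feats))))
  }
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}
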