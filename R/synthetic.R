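#' @useDynLib histonet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp rnorm runif sd var predict quantile setNames
#' @importFrom utils read.csv write.csv
NULL

# ---- layout -----------------------------------------------------------------

#' Describe a synthetic tissue layout
#'
#' A layout is a canvas size plus an ordered list of geometric regions, painted
#' in order (later regions overwrite earlier ones), so that every pixel ends up
#' with exactly one label. Regions are axis-aligned rectangles or discs, which
#' keeps exact pixel-count oracles trivial.
#'
#' @param shape Integer (height, width) in pixels.
#' @param regions List of regions from [region_rect()] / [region_disc()]. The
#'   first region usually covers the full canvas.
#' @return An object of class `synth_layout`.
#' @export
synth_layout <- function(shape, regions) {
  stopifnot(length(shape) == 2L, all(shape >= 1L))
  shape <- as.integer(shape)
  for (rg in regions) {
    if (!inherits(rg, "synth_region")) stop("regions must be built with region_rect()/region_disc()")
    if (rg$type == "rect") {
      if (rg$row0 < 0L || rg$col0 < 0L ||
          rg$row0 + rg$height > shape[1] || rg$col0 + rg$width > shape[2])
        stop("rectangle region outside image bounds")
    } else {
      if (rg$row - rg$radius < 0 || rg$col - rg$radius < 0 ||
          rg$row + rg$radius > shape[1] || rg$col + rg$radius > shape[2])
        stop("disc region outside image bounds")
    }
  }
  structure(list(shape = shape, regions = regions), class = "synth_layout")
}

#' @rdname synth_layout
#' @param class Integer label id in 0..7.
#' @param row0,col0 Top-left corner (0-based, half-open box).
#' @param height,width Box extent in pixels.
#' @export
region_rect <- function(class, row0, col0, height, width) {
  structure(list(type = "rect", class = as.integer(class),
                 row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(height), width = as.integer(width)),
            class = "synth_region")
}

#' @rdname synth_layout
#' @param row,col Disc center (0-based pixel coordinates).
#' @param radius Disc radius in pixels; a pixel belongs to the disc when its
#'   center lies within `radius` of (`row`, `col`).
#' @export
region_disc <- function(class, row, col, radius) {
  structure(list(type = "disc", class = as.integer(class),
                 row = row, col = col, radius = radius),
            class = "synth_region")
}

rasterize_layout <- function(layout) {
  h <- layout$shape[1]; w <- layout$shape[2]
  labels <- matrix(NA_integer_, h, w)
  rows <- matrix(0:(h - 1L), h, w)
  cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  for (rg in layout$regions) {
    if (rg$type == "rect") {
      labels[rg$row0 + seq_len(rg$height), rg$col0 + seq_len(rg$width)] <- rg$class
    } else {
      inside <- (rows - rg$row)^2 + (cols - rg$col)^2 <= rg$radius^2
      labels[inside] <- rg$class
    }
  }
  if (anyNA(labels)) stop("layout regions do not tile the image; add a base region")
  labels
}

# ---- texture model ----------------------------------------------------------

# Per-class appearance: base color pulled toward the display color but
# desaturated (real tissue is never a pure primary), a class-specific
# sinusoidal texture (period and orientation differ per class), pixel noise,
# and a whole-tile stain shift emulating slide-level staining variability.
synth_texture_params <- function() {
  disp <- palette_colors()
  base <- 0.2 + 0.6 * disp
  list(
    base_color   = base,
    period       = c(5, 7, 9, 11, 13, 15, 17, 19),
    angle        = (0:7) * pi / 8,
    tex_amp      = 0.10,
    noise_sd     = 0.08,
    stain_jitter = 0.05
  )
}

#' Render a synthetic H&E-like tile with pixel-accurate labels
#'
#' Each class region is rendered with a distinct base color near its display
#' color, a class-specific sinusoidal texture, i.i.d. pixel noise, and a random
#' whole-tile stain shift (a crude stand-in for slide-to-slide staining
#' variability). The same (layout, seed) pair always yields bit-identical
#' output.
#'
#' @param layout A [synth_layout()].
#' @param seed Integer seed.
#' @param params Texture parameters; see source of `synth_texture_params`.
#' @return List with `image` (H x W x 3 array in \[0,1\]) and `annotation`
#'   (H x W integer matrix of label ids 0..7).
#' @export
synth_tissue_sample <- function(layout, seed, params = synth_texture_params()) {
  labels <- rasterize_layout(layout)
  set.seed(seed)
  h <- nrow(labels); w <- ncol(labels)
  rows <- matrix(0:(h - 1L), h, w)
  cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
  img <- array(0, c(h, w, 3))
  for (cl in sort(unique(as.vector(labels)))) {
    idx <- labels == cl
    k <- cl + 1L
    phase <- runif(1, 0, 2 * pi)
    wave <- sin(2 * pi * (rows * cos(params$angle[k]) + cols * sin(params$angle[k])) /
                  params$period[k] + phase)
    for (ch in 1:3)
      img[, , ch][idx] <- params$base_color[k, ch] + params$tex_amp * wave[idx]
  }
  jitter <- rnorm(3, 0, params$stain_jitter)
  for (ch in 1:3)
    img[, , ch] <- img[, , ch] + jitter[ch]
  img <- img + array(rnorm(h * w * 3, 0, params$noise_sd), c(h, w, 3))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, annotation = labels)
}

#' Standard synthetic segmentation benchmark tiles
#'
#' Draws multi-class tiles for training/evaluating the segmentation network
#' and the texture baseline: each tile has a random base class plus 3-5
#' random rectangles and discs of other classes, so class boundaries and all
#' eight classes occur across a modest number of tiles.
#'
#' @param n_tiles Number of tiles.
#' @param shape Tile (height, width).
#' @param seed Integer seed.
#' @return List of samples, each with `image` and `annotation`.
#' @export
synth_benchmark <- function(n_tiles, shape = c(48L, 48L), seed = 1L) {
  set.seed(seed)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  lapply(seq_len(n_tiles), function(i) {
    # cycle the base class so every class gets large support across the set
    base_cl <- (i - 1L) %% 8L
    regions <- list(region_rect(base_cl, 0, 0, h, w))
    for (j in seq_len(sample(3:5, 1))) {
      cl <- sample(0:7, 1)
      if (runif(1) < 0.5) {
        rh <- sample(seq(h %/% 6, h %/% 2), 1)
        rw <- sample(seq(w %/% 6, w %/% 2), 1)
        regions[[length(regions) + 1L]] <-
          region_rect(cl, sample(0:(h - rh), 1), sample(0:(w - rw), 1), rh, rw)
      } else {
        rad <- runif(1, min(h, w) / 10, min(h, w) / 4)
        regions[[length(regions) + 1L]] <-
          region_disc(cl, runif(1, rad, h - 1 - rad), runif(1, rad, w - 1 - rad), rad)
      }
    }
    synth_tissue_sample(synth_layout(c(h, w), regions), seed = seed + 1000L + i)
  })
}

# ---- CD45 -------------------------------------------------------------------

#' Generate a two-stain CD45-like immunohistochemistry patch
#'
#' A hematoxylin-blue counterstain background with diaminobenzidine-brown
#' positive blobs covering approximately `positive_fraction` of the stained
#' area. The exact positive mask used for rendering is returned, so stain
#' decomposition and positive-fraction estimates can be scored against ground
#' truth.
#'
#' @param shape Integer (height, width).
#' @param positive_fraction Target fraction of stained pixels that are
#'   DAB-positive, in \[0, 1\].
#' @param seed Integer seed.
#' @return List with `image` (H x W x 3), `mask` (logical H x W, TRUE on
#'   positive pixels) and `stained` (logical H x W; here all pixels).
#' @export
synth_cd45_patch <- function(shape, positive_fraction, seed) {
  stopifnot(positive_fraction >= 0, positive_fraction <= 1)
  set.seed(seed)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  # unstained glass margin around the tissue, as after foreground selection
  margin <- max(2L, round(0.08 * min(h, w)))
  stained <- matrix(FALSE, h, w)
  stained[(margin + 1L):(h - margin), (margin + 1L):(w - margin)] <- TRUE
  mask <- matrix(FALSE, h, w)
  target <- round(positive_fraction * sum(stained))
  if (positive_fraction >= 1) {
    mask <- stained
  } else if (target > 0) {
    rows <- matrix(0:(h - 1L), h, w)
    cols <- matrix(0:(w - 1L), h, w, byrow = TRUE)
    r_blob <- max(2, round(min(h, w) / 12))
    for (i in seq_len(10000L)) {
      if (sum(mask) >= target) break
      cr <- runif(1, margin, h - 1 - margin); cc <- runif(1, margin, w - 1 - margin)
      rad <- runif(1, r_blob / 2, r_blob)
      blob <- (rows - cr)^2 + (cols - cc)^2 <= rad^2 & stained
      # trim the last blob so the planted fraction is hit closely
      overshoot <- sum(mask | blob) - target
      if (overshoot > 0) {
        cand <- which(blob & !mask)
        d <- ((rows - cr)^2 + (cols - cc)^2)[cand]
        blob[cand[order(d, decreasing = TRUE)][seq_len(min(overshoot, length(cand)))]] <- FALSE
      }
      mask <- mask | blob
    }
  }
  # render via additive optical density: every stained pixel carries the
  # hematoxylin counterstain, DAB adds on top of it inside the positive mask
  v_hema <- c(0.650, 0.704, 0.286); v_hema <- v_hema / sqrt(sum(v_hema^2))
  v_dab  <- c(0.268, 0.570, 0.776); v_dab  <- v_dab / sqrt(sum(v_dab^2))
  c_hema <- ifelse(stained, 1 + rnorm(h * w, 0, 0.05), 0)
  c_dab  <- ifelse(mask, 1.2 + rnorm(h * w, 0, 0.05), 0)
  od <- outer(as.vector(c_hema), v_hema) + outer(as.vector(pmax(c_dab, 0)), v_dab)
  img <- array((256 * exp(-od) - 1) / 255, c(h, w, 3))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, stained = stained)
}

# ---- BLC/NEC confusion fixture ---------------------------------------------

#' Fixture carrying the blood-cell/necrosis confusion signature
#'
#' Builds a tissue map with a rectangular BLC region on a tumor background and
#' a per-class variance volume with equal variance mass on BLC and NEC inside
#' that region, zero elsewhere. Rendered in class colors this gives the
#' light-green signature (red/green ratio exactly 0.5, blue exactly 0) that the
#' automated correction rule targets. The ground-truth corrected map (BLC
#' region relabeled to NEC) is returned alongside.
#'
#' @param shape Integer (height, width), at least 32 px per side.
#' @param seed Integer seed (jitters the region placement).
#' @return List with `labels`, `variance` (H x W x 8 per-class variance),
#'   `variance_rgb` (rendered variance image), `expected` (corrected map) and
#'   `region` (logical mask of the planted confusion region).
#' @export
synth_confusion_fixture <- function(shape, seed) {
  set.seed(seed)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  stopifnot(h >= 32L, w >= 32L)
  rh <- max(8L, h %/% 3); rw <- max(8L, w %/% 3)
  r0 <- sample.int(h - rh - 8L, 1L) + 4L
  c0 <- sample.int(w - rw - 8L, 1L) + 4L
  labels <- matrix(class_id("TUM"), h, w)
  labels[r0 + seq_len(rh), c0 + seq_len(rw)] <- class_id("BLC")
  region <- matrix(FALSE, h, w)
  region[r0 + seq_len(rh), c0 + seq_len(rw)] <- TRUE
  vol <- array(0, c(h, w, 8L))
  v <- 0.2
  vol[, , class_id("BLC") + 1L][region] <- v
  vol[, , class_id("NEC") + 1L][region] <- v
  expected <- labels
  expected[region] <- class_id("NEC")
  list(labels = labels, variance = vol,
       variance_rgb = render_variance(vol),
       expected = expected, region = region)
}

# ---- SMT cohort -------------------------------------------------------------

#' Generate a synthetic single-mouse-trial cohort with a planted response effect
#'
#' Emulates the single-mouse-trial design: every tumor model contributes one
#' isotype-control slide plus one slide per treatment arm (anti-PD-L1,
#' anti-CTLA4, combination). Each treated sample carries a planted
#' responder/non-responder label; responders are generated with a smaller
#' absolute tumor area and a larger relative necrosis fraction than
#' non-responders, and a larger CD45 shift against their isotype — the feature
#' structure the decision-support stage is expected to recover. `effect = 0`
#' removes the planted differences entirely, so downstream classification must
#' fall to chance.
#'
#' Tissue maps are synthesized directly as label maps (a stroma field with a
#' tumor disc, a concentric necrotic core and a small blood-vessel disc); the
#' decision stage consumes meta-features of label maps, so generating labels
#' directly isolates it from the segmentation stage.
#'
#' @param n_models Number of tumor models (>= 2); the cohort holds
#'   `4 * n_models` samples.
#' @param effect Effect-size multiplier >= 0; 1 is the default planted effect
#'   (responders shrink tumor radius by ~35% and gain ~25 percentage points of
#'   relative necrosis), 0 plants no effect.
#' @param seed Integer seed.
#' @param shape Tissue-map size per sample.
#' @param p_responder Probability a treated sample is a responder.
#' @return Object of class `smt_cohort`: list of `samples`, each with
#'   `model_id`, `treatment`, `response`, `labels` (tissue map) and
#'   `cd45_fraction` (planted CD45-positive fraction).
#' @export
synth_smt_cohort <- function(n_models, effect = 1, seed = 1L,
                             shape = c(96L, 96L), p_responder = 0.5) {
  stopifnot(n_models >= 2L, effect >= 0)
  set.seed(seed)
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  arms <- c("antiPDL1", "antiCTLA4", "combo")
  samples <- list()
  for (m in seq_len(n_models)) {
    model_id <- sprintf("PDX%03d", m)
    iso_rad  <- runif(1, 0.30, 0.36) * min(h, w)
    iso_nec  <- runif(1, 0.05, 0.15)   # necrotic fraction of the tumor disc
    iso_cd45 <- runif(1, 0.10, 0.20)
    samples[[length(samples) + 1L]] <- smt_sample(
      model_id, "isotype", "not_applicable", h, w, iso_rad, iso_nec, iso_cd45)
    for (arm in arms) {
      responder <- runif(1) < p_responder
      # both classes share the same baseline noise; the planted effect only
      # shifts the responder means, so effect = 0 leaves no signal at all
      shift <- if (responder) effect else 0
      rad  <- iso_rad * max(0.2, 1 + rnorm(1, 0.03, 0.03) - shift * rnorm(1, 0.38, 0.05))
      nec  <- min(0.8, max(0.02, iso_nec + rnorm(1, 0, 0.02) + shift * rnorm(1, 0.25, 0.05)))
      cd45 <- min(0.9, max(0.02, iso_cd45 + rnorm(1, 0, 0.02) + shift * rnorm(1, 0.15, 0.03)))
      rad <- min(rad, 0.45 * min(h, w))
      samples[[length(samples) + 1L]] <- smt_sample(
        model_id, arm, if (responder) "responder" else "non_responder",
        h, w, rad, nec, cd45)
    }
  }
  structure(list(samples = samples, n_models = as.integer(n_models),
                 effect = effect, seed = as.integer(seed)),
            class = "smt_cohort")
}

smt_sample <- function(model_id, treatment, response, h, w, tum_rad, nec_frac, cd45) {
  cr <- h / 2 + runif(1, -2, 2); cc <- w / 2 + runif(1, -2, 2)
  regions <- list(
    region_rect(class_id("MST"), 0, 0, h, w),
    region_rect(class_id("BGR"), 0, 0, h, 3L),
    region_disc(class_id("TUM"), cr, cc, tum_rad),
    region_disc(class_id("NEC"), cr, cc, sqrt(nec_frac) * tum_rad),
    region_disc(class_id("BLC"), h * 0.12 + 4, w * 0.85 - 4, 3)
  )
  labels <- rasterize_layout(synth_layout(c(h, w), regions))
  list(model_id = model_id, treatment = treatment, response = response,
       labels = labels, cd45_fraction = cd45)
}

#' Validate the structural invariants of an SMT cohort
#'
#' Checks that every tumor model has exactly one isotype sample, that isotype
#' samples carry the `not_applicable` response, and that all label maps are
#' valid 8-class maps.
#'
#' @param cohort An `smt_cohort`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "smt_cohort"))
  meta <- cohort_metadata(cohort)
  for (mid in unique(meta$model_id)) {
    iso <- meta$treatment[meta$model_id == mid] == "isotype"
    if (sum(iso) != 1L) stop("model ", mid, " must have exactly one isotype sample")
  }
  if (!all(meta$response[meta$treatment == "isotype"] == "not_applicable"))
    stop("isotype samples must have response 'not_applicable'")
  for (s in cohort$samples) stopifnot_labels(s$labels)
  invisible(TRUE)
}

#' Cohort metadata as a data frame
#' @param cohort An `smt_cohort`.
#' @return Data frame with columns `model_id`, `treatment`, `response`,
#'   `cd45_fraction`.
#' @export
cohort_metadata <- function(cohort) {
  data.frame(
    model_id = vapply(cohort$samples, `[[`, "", "model_id"),
    treatment = vapply(cohort$samples, `[[`, "", "treatment"),
    response = vapply(cohort$samples, `[[`, "", "response"),
    cd45_fraction = vapply(cohort$samples, `[[`, 0, "cd45_fraction"),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort to disk as paired PNGs plus a metadata CSV
#'
#' Label maps are written as single-channel 8-bit PNGs (raw label ids), their
#' color renderings as RGB PNGs, and the metadata (model id, treatment arm,
#' response, CD45 fraction, file paths) as CSV.
#'
#' @param cohort An `smt_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata data frame including paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- cohort_metadata(cohort)
  meta$labels_path <- file.path(dir, sprintf("%s_%s_labels.png", meta$model_id, meta$treatment))
  meta$render_path <- file.path(dir, sprintf("%s_%s_tissue.png", meta$model_id, meta$treatment))
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    write_label_png(s$labels, meta$labels_path[i])
    png::writePNG(render_labels(s$labels), meta$render_path[i])
  }
  write.csv(meta, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(meta)
}
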