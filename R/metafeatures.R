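# Closed-form tumor-micro-environment meta-features of corrected tissue maps
# and CD45 stain decompositions: absolute per-class pixel counts, the tissue
# area (main classes only), relative areas, differences against the isotype
# control, and the CD45-positive fraction.

#' Absolute per-class pixel counts
#'
#' `f_abs[i]` is the number of pixels labeled with class id `i - 1`.
#'
#' @param labels Integer H x W label matrix (0..7).
#' @return Named integer vector of length 8 (names = class names).
#' @export
absolute_areas <- function(labels) {
  stopifnot_labels(labels)
  f <- tabulate(as.vector(labels) + 1L, nbins = 8L)
  names(f) <- make_palette()$name
  f
}

#' Tissue area
#'
#' Sum of the absolute areas of the six main tissue classes; technical
#' artifacts (TAR) and background (BGR) are excluded.
#'
#' @param f_abs Length-8 vector from [absolute_areas()].
#' @return Scalar pixel count.
#' @export
tissue_area <- function(f_abs) {
  sum(f_abs[main_class_ids() + 1L])
}

#' Relative per-class areas
#'
#' `f_rel[i] = f_abs[i] / A` for the six main classes; TAR and BGR are not
#' part of the tissue area and get `NA` (they are reported in absolute mode
#' only). When the tissue area is zero the result is flagged undefined and
#' all entries are `NA`.
#'
#' @param f_abs Length-8 vector from [absolute_areas()].
#' @return Named length-8 vector with attribute `defined` (logical).
#' @export
relative_areas <- function(f_abs) {
  A <- tissue_area(f_abs)
  out <- rep(NA_real_, 8L)
  names(out) <- make_palette()$name
  if (A > 0) {
    out[main_class_ids() + 1L] <- f_abs[main_class_ids() + 1L] / A
    attr(out, "defined") <- TRUE
  } else {
    attr(out, "defined") <- FALSE
  }
  out
}

#' All meta-features of one sample
#'
#' @param labels Integer label matrix.
#' @param cd45_fraction Optional CD45-positive fraction for the sample's
#'   immunostain (from [cd45_fraction()]), or `NA`.
#' @return Object of class `meta_features`: `f_abs`, `area`, `f_rel`,
#'   `cd45_fraction`.
#' @export
meta_features <- function(labels, cd45_fraction = NA_real_) {
  f_abs <- absolute_areas(labels)
  structure(list(f_abs = f_abs, area = tissue_area(f_abs),
                 f_rel = relative_areas(f_abs),
                 cd45_fraction = cd45_fraction),
            class = "meta_features")
}

#' Difference of a meta-feature against the isotype control
#'
#' Treatment effects are expressed as deviations from the same tumor model's
#' isotype sample: `delta = f_sample - f_isotype`, applicable to absolute or
#' relative class areas, the total tissue area `A` (`which = "A"`), and the
#' CD45 fraction (`which = "cd45"`). An isotype compared against itself gives
#' 0 for every defined feature; undefined operands propagate `NA`.
#'
#' @param sample,isotype [meta_features()] objects.
#' @param which Class name (`"TUM"`, ..., `"MUS"`), `"A"` or `"cd45"`.
#' @param mode `"abs"` or `"rel"` (ignored for `"A"` and `"cd45"`).
#' @return Scalar difference, or `NA` if either operand is undefined.
#' @export
isotype_delta <- function(sample, isotype, which, mode = c("abs", "rel")) {
  mode <- match.arg(mode)
  get1 <- function(f) {
    if (which == "A") return(f$area)
    if (which == "cd45") return(f$cd45_fraction)
    v <- if (mode == "abs") f$f_abs else f$f_rel
    if (!which %in% names(v)) stop("unknown feature: ", which)
    unname(v[which])
  }
  a <- get1(sample); b <- get1(isotype)
  if (is.na(a) || is.na(b)) return(NA_real_)
  a - b
}

#' CD45-positive fraction of a stain decomposition
#'
#' Counts pixels above threshold in the positive (DAB) channel and normalizes
#' by the number of counterstain pixels. Thresholds default to Otsu's method
#' on each channel (a channel that is effectively empty — dynamic range below
#' `1e-3` — counts zero pixels).
#'
#' @param positive,counterstain H x W stain density maps from
#'   [destain_cd45()].
#' @param positive_threshold,counterstain_threshold Optional numeric
#'   overrides for the Otsu thresholds.
#' @return Fraction (>= 0), or `NA` if no counterstain pixels are found.
#' @export
cd45_fraction <- function(positive, counterstain,
                          positive_threshold = NULL,
                          counterstain_threshold = NULL) {
  stopifnot(all(dim(positive) == dim(counterstain)))
  count_above <- function(x, thr) {
    if (is.null(thr)) {
      if (max(x) - min(x) < 1e-3) return(0L)
      thr <- EBImage::otsu(EBImage::Image(x), range = range(x))
    }
    sum(x > thr)
  }
  n_pos <- count_above(positive, positive_threshold)
  n_cs <- count_above(counterstain, counterstain_threshold)
  if (n_cs == 0L) return(NA_real_)
  n_pos / n_cs
}

#' Feature table of an SMT cohort for decision learning
#'
#' Builds the decision-support feature combination per treated sample:
#' absolute tumor area, relative tumor area, relative stroma area, and
#' isotype differences of the relative necrosis area, the CD45 fraction and
#' the total tissue area. Isotype samples are used only as the per-model
#' delta reference; samples labeled `unknown` are dropped.
#'
#' @param cohort An `smt_cohort` (each sample needs `labels` and either a
#'   `cd45_fraction` value or CD45 maps).
#' @return List with `features` (data frame, one row per usable treated
#'   sample: `abs_TUM`, `rel_TUM`, `rel_MST`, `d_rel_NEC`, `d_cd45`, `d_A`),
#'   `labels` (factor responder/non_responder) and `meta` (sample metadata).
#' @export
build_feature_table <- function(cohort) {
  validate_cohort(cohort)
  meta <- cohort_metadata(cohort)
  mf <- lapply(cohort$samples, function(s)
    meta_features(s$labels, cd45_fraction = s$cd45_fraction))
  iso_of <- function(mid) {
    i <- which(meta$model_id == mid & meta$treatment == "isotype")
    if (length(i) != 1L) stop("model ", mid, " lacks an isotype sample")
    i
  }
  rows <- which(meta$treatment != "isotype" & meta$response != "unknown")
  feat <- do.call(rbind, lapply(rows, function(i) {
    iso <- mf[[iso_of(meta$model_id[i])]]
    data.frame(
      abs_TUM   = unname(mf[[i]]$f_abs["TUM"]),
      rel_TUM   = unname(mf[[i]]$f_rel["TUM"]),
      rel_MST   = unname(mf[[i]]$f_rel["MST"]),
      d_rel_NEC = isotype_delta(mf[[i]], iso, "NEC", "rel"),
      d_cd45    = isotype_delta(mf[[i]], iso, "cd45"),
      d_A       = isotype_delta(mf[[i]], iso, "A")
    )
  }))
  rownames(feat) <- NULL
  list(features = feat,
       labels = factor(meta$response[rows],
                       levels = c("non_responder", "responder")),
       meta = meta[rows, , drop = FALSE])
}
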