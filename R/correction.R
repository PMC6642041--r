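# Automated correction of the systematic blood-cell/necrosis confusion.
# Where the network wavers between BLC (rendered green) and NEC (rendered
# yellow), the variance map shows light green: an equal mixture gives a
# red-to-green channel ratio of exactly 0.5 with no blue. Pixels whose
# variance color falls in that band are relabeled to necrosis, after a
# Gaussian smoothing of the selection mask so the relabeled region blends
# into the tissue map.

#' Parameters of the confusion-correction rule
#'
#' @param r_min,r_max Accepted band for the red/green ratio `r = Vr/Vg` of
#'   the variance rendering (the equal-mixture signature sits at 0.5).
#' @param blue_max Upper bound quantifying "blue close to zero" on the
#'   normalized variance rendering.
#' @param sigma Gaussian blur width for the selection mask, in pixels.
#' @param mask_threshold Blurred-mask level above which a pixel is relabeled.
#' @return Object of class `correction_params`.
#' @export
correction_params <- function(r_min = 0.35, r_max = 0.7, blue_max = 0.1,
                              sigma = 5, mask_threshold = 0.5) {
  stopifnot(r_min >= 0, r_min < r_max, sigma > 0,
            mask_threshold > 0, mask_threshold < 1)
  structure(list(r_min = r_min, r_max = r_max, blue_max = blue_max,
                 sigma = sigma, mask_threshold = mask_threshold),
            class = "correction_params")
}

#' Relabel the blood-cell/necrosis confusion to necrosis
#'
#' Selects pixels of the variance rendering with `Vg > 0`,
#' `Vr/Vg` strictly inside `(r_min, r_max)` and `Vb <= blue_max` (pixels
#' without green are never selected — the ratio is undefined there), blurs
#' the binary selection with a Gaussian of width `sigma`, and sets the labels
#' of pixels where the blurred mask reaches `mask_threshold` to NEC. All
#' other labels are left untouched; the operation only ever adds necrosis.
#'
#' @param labels Integer H x W label matrix (0..7).
#' @param variance Variance rendering: H x W x 3 RGB array in \[0,1\].
#' @param params A [correction_params()].
#' @return Corrected label matrix.
#' @export
correct_blc_nec <- function(labels, variance, params = correction_params()) {
  stopifnot_labels(labels)
  d <- dim(variance)
  if (length(d) != 3L || d[1] != nrow(labels) || d[2] != ncol(labels))
    stop("labels and variance must share spatial shape")
  vr <- variance[, , 1]; vg <- variance[, , 2]; vb <- variance[, , 3]
  r <- ifelse(vg > 0, vr / pmax(vg, 1e-12), Inf)
  sel <- vg > 0 & r > params$r_min & r < params$r_max & vb <= params$blue_max
  if (!any(sel)) return(labels)
  blurred <- EBImage::imageData(EBImage::gblur(EBImage::Image(sel * 1),
                                               sigma = params$sigma))
  out <- labels
  out[blurred >= params$mask_threshold] <- class_id("NEC")
  out
}
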