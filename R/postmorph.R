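# Post-processing of the segmenter output: morphological closing connects
# fragmented detections, small components are discarded, and the largest
# remaining component is reported as the lesion (centroid, pixel area,
# optional physical area). Components use 8-connectivity throughout.

binaryTumorMask <- function(mask) {
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0L, 255L)))
    stop("expected a binary tumor mask over {0, 255}")
  mask == 255L
}

#' Morphological refinement of a binary tumor mask
#'
#' Closing (dilation then erosion) with a disk structuring element of the
#' given radius connects nearby fragments; connected components smaller than
#' `min_size` pixels are then removed. Closing never decreases the
#' foreground pixel count and the removal step never increases it.
#'
#' @param mask Integer matrix over {0, 255}.
#' @param radius Disk radius in pixels (default 5 at 256 x 256).
#' @param min_size Minimum component area kept, in pixels (default 20).
#' @return Refined mask over {0, 255} with attributes `n_components_before`
#'   and `n_components_after`.
#' @export
morphologicalRefine <- function(mask, radius = 5L, min_size = 20L) {
  bin <- binaryTumorMask(mask)
  n_before <- max(label_components8(bin))
  if (radius > 0 && any(bin)) {
    kern <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    closed <- EBImage::closing(EBImage::Image(t(bin) * 1), kern)
    bin <- t(EBImage::imageData(closed)) > 0.5
  }
  lab <- label_components8(bin)
  n_comp <- max(lab)
  if (n_comp > 0 && min_size > 1) {
    sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
    drop_ <- which(sizes < min_size)
    if (length(drop_)) bin[lab %in% drop_] <- FALSE
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[bin] <- 255L
  attr(out, "n_components_before") <- n_before
  attr(out, "n_components_after") <- max(label_components8(bin))
  out
}

#' Locate and size the lesion in a refined mask
#'
#' Reports the largest 8-connected tumor component: centroid (mean pixel
#' coordinate, 1-based row/col), pixel area, bounding box, and -- when a
#' pixel spacing is supplied -- the physical area `area * spacing^2` in
#' mm^2. A single 2-D frame cannot give a volume, so size is deliberately
#' reported as an area. An empty mask yields `present = FALSE`.
#'
#' @param mask Refined binary mask over {0, 255}.
#' @param pixel_spacing Optional pixel edge length in mm.
#' @return A [LesionReport-class].
#' @examples
#' ph <- generatePhantom(phantomParams("benign", lesion_axes = c(15, 10)))
#' bin <- matrix(0L, 256, 256); bin[ph$mask == 255L] <- 255L
#' lesionReport(bin)
#' @export
lesionReport <- function(mask, pixel_spacing = NULL) {
  bin <- binaryTumorMask(mask)
  n_after <- if (is.null(attr(mask, "n_components_after")))
    max(label_components8(bin)) else attr(mask, "n_components_after")
  n_before <- attr(mask, "n_components_before")
  if (is.null(n_before)) n_before <- NA_real_
  if (!any(bin))
    return(new("LesionReport", present = FALSE,
               centroid = c(NA_real_, NA_real_), area = NA_real_,
               areaPhysical = NA_real_, bbox = rep(NA_real_, 4),
               nComponentsBefore = as.numeric(n_before),
               nComponentsAfter = as.numeric(n_after)))
  lab <- label_components8(bin)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  big <- which.max(sizes)
  idx <- which(lab == big, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1]), mean(idx[, 2]))
  area <- nrow(idx)
  new("LesionReport", present = TRUE, centroid = centroid,
      area = as.numeric(area),
      areaPhysical = if (is.null(pixel_spacing)) NA_real_
                     else area * pixel_spacing^2,
      bbox = c(min(idx[, 1]), max(idx[, 1]), min(idx[, 2]), max(idx[, 2])),
      nComponentsBefore = as.numeric(n_before),
      nComponentsAfter = as.numeric(n_after))
}

#' Serialize a lesion report to a plain list (for JSON output)
#'
#' @param report A [LesionReport-class].
#' @return Named list mirroring the slots.
#' @export
lesionReportAsList <- function(report) {
  list(present = report@present,
       centroid_row = report@centroid[1], centroid_col = report@centroid[2],
       area_px = report@area, area_mm2 = report@areaPhysical,
       bbox = report@bbox,
       n_components_before = report@nComponentsBefore,
       n_components_after = report@nComponentsAfter)
}
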