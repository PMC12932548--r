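## Segmentation of two-channel neuron images: nuclei by thresholding plus
## watershed splitting, marker positivity from a perinuclear ring, neurite
## mask by thresholding the marker channel outside the somas.

#' Morphometry segmentation parameters
#'
#' @param otsu_offset Added to the Otsu threshold of each channel (same
#'   intensity units as the image).
#' @param nucleus_min_area Minimum nucleus area in px; smaller detections
#'   are discarded as debris.
#' @param ring_width Width in px of the perinuclear ring over which marker
#'   positivity is assessed.
#' @param marker_positive_factor A nucleus is marker-positive when the
#'   median marker intensity in its ring exceeds this multiple of the
#'   marker background (median outside all cell regions), measured above
#'   background.
#' @param soma_dilate Dilation in px applied to marker-positive nuclei to
#'   form the soma mask.
#' @param neurite_min_component Minimum connected-component area in px kept
#'   in the neurite mask.
#' @param prune_px Skeleton spurs shorter than this (px) are removed before
#'   graph construction.
#' @param root_reach Geodesic budget in px for root detection: a skeleton
#'   endpoint becomes a root when a soma is reachable from it through the
#'   neurite mask within this many steps (thinning can retract endpoints
#'   from the soma contact, so the walk runs through the mask).
#' @return An object of class `morphometry_params`.
#' @export
morphometry_params <- function(otsu_offset = 0, nucleus_min_area = 15,
                               ring_width = 3, marker_positive_factor = 2,
                               soma_dilate = 6, neurite_min_component = 8,
                               prune_px = 5, root_reach = 15) {
  structure(list(otsu_offset = otsu_offset,
                 nucleus_min_area = nucleus_min_area,
                 ring_width = ring_width,
                 marker_positive_factor = marker_positive_factor,
                 soma_dilate = soma_dilate,
                 neurite_min_component = neurite_min_component,
                 prune_px = prune_px, root_reach = root_reach),
            class = "morphometry_params")
}

odd_brush <- function(px) EBImage::makeBrush(2L * as.integer(px) + 1L, "disc")

#' Segment somas and compute the marker-positive fraction
#'
#' Nuclei are detected on the nuclei channel by Otsu thresholding followed
#' by watershed splitting of touching objects on the distance transform.  A
#' nucleus is marker-positive when the median neurite-marker intensity in a
#' dilated perinuclear ring exceeds the marker background by the configured
#' factor; marker-positive nuclei dilated by `soma_dilate` form the soma
#' mask.  The marker-positive fraction is the QC statistic of the assay.
#'
#' @param image A `neuron_image` (fields `nuclei`, `marker`) or a list with
#'   those two matrices.
#' @param params A [morphometry_params()].
#' @return List with `soma_labels` (integer matrix, 0 = background),
#'   `cells` (`data.frame`: `cell`, `x`, `y`, `area`, `marker_positive`),
#'   `n_cells`, and `marker_positive_fraction` (`NA` with a warning when no
#'   cell is found).
#' @export
segment_cells <- function(image, params = morphometry_params()) {
  nuc <- image$nuclei; mk <- image$marker
  stop_if(is.null(nuc) || is.null(mk), "`image` needs nuclei and marker")
  stop_if(!all(dim(nuc) == dim(mk)), "channel shapes differ")
  thr <- EBImage::otsu(EBImage::Image(nuc)) + params$otsu_offset
  mask <- nuc > thr
  if (!any(mask)) {
    warning("blank nuclei channel: no cells found")
    return(list(soma_labels = matrix(0L, nrow(nuc), ncol(nuc)),
                cells = data.frame(cell = integer(), x = numeric(),
                                   y = numeric(), area = integer(),
                                   marker_positive = logical()),
                n_cells = 0L, marker_positive_fraction = NA_real_))
  }
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1,
                                                  ext = 1))
  areas <- table(labels[labels > 0])
  keep <- as.integer(names(areas)[areas >= params$nucleus_min_area])
  labels[!(labels %in% keep)] <- 0L
  ids <- sort(unique(labels[labels > 0]))
  ## marker background: outside every (dilated) nucleus region
  allmask <- labels > 0
  dil_all <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(allmask * 1),
                    odd_brush(params$ring_width + params$soma_dilate))) > 0
  bg <- stats::median(mk[!dil_all])
  if (!is.finite(bg)) bg <- 0
  w <- nrow(nuc)
  cells <- data.frame(cell = integer(), x = numeric(), y = numeric(),
                      area = integer(), marker_positive = logical())
  soma_labels <- matrix(0L, nrow(nuc), ncol(nuc))
  new_id <- 0L
  for (id in ids) {
    obj <- labels == id
    idx <- which(obj)
    xs <- ((idx - 1L) %% w) + 1L
    ys <- ((idx - 1L) %/% w) + 1L
    ring <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(obj * 1),
                      odd_brush(params$ring_width))) > 0 & !obj
    med <- stats::median(mk[ring])
    positive <- isTRUE((med - bg) > params$marker_positive_factor *
                         max(bg, 0.01))
    new_id <- new_id + 1L
    cells <- rbind(cells, data.frame(cell = new_id, x = mean(xs),
                                     y = mean(ys), area = length(idx),
                                     marker_positive = positive))
    if (positive) {
      soma <- EBImage::imageData(
        EBImage::dilate(EBImage::Image(obj * 1),
                        odd_brush(params$soma_dilate))) > 0
      soma_labels[soma] <- new_id
    }
  }
  list(soma_labels = soma_labels, cells = cells, n_cells = nrow(cells),
       marker_positive_fraction = mean(cells$marker_positive))
}

#' Segment the neurite mask
#'
#' Thresholds the neurite-marker channel (Otsu plus offset), removes soma
#' interiors and small components, and returns the binary mask of thin
#' marker-positive structures.
#'
#' @inheritParams segment_cells
#' @param soma_labels Integer soma label matrix from [segment_cells()].
#' @return Logical matrix, `TRUE` on neurite pixels.
#' @export
segment_neurites <- function(image, soma_labels,
                             params = morphometry_params()) {
  mk <- image$marker
  stop_if(!all(dim(mk) == dim(soma_labels)),
          "`soma_labels` shape must match the image")
  if (max(mk) <= 0) return(matrix(FALSE, nrow(mk), ncol(mk)))
  thr <- EBImage::otsu(EBImage::Image(mk)) + params$otsu_offset
  mask <- mk > thr & soma_labels == 0L
  if (!any(mask)) return(mask)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  areas <- table(lab[lab > 0])
  small <- as.integer(names(areas)[areas < params$neurite_min_component])
  mask[lab %in% small] <- FALSE
  mask
}
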