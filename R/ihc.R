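# Chromogenic (H-DAB) section quantification: threshold-based colonoid
# segmentation, annotation filtering, CK20 positive-area fraction, nucleus
# detection on the hematoxylin channel, Ki67 positive-nucleus classification.

#' Segment colonoid regions from an OD image
#'
#' Fixed-threshold stand-in for a trained pixel classifier: the total stain
#' OD (hematoxylin + DAB) is Gaussian-smoothed and thresholded, small gaps
#' closed (morphological closing, 2 px radius), holes filled, and connected
#' components become annotations carrying shape and intensity measurements.
#' The segmenter is deliberately simple and swappable: any function producing
#' the same annotation tibble can replace it upstream of the area metrics.
#'
#' @param od an `od_image` from [deconvolve_stains()].
#' @param od_sum_threshold threshold on smoothed total OD (> 0).
#' @param smoothing_sigma Gaussian sigma in px.
#' @return Tibble of annotations: id, `area_px`, `area_um2`, `od_sum_mean`
#'   (mean hematoxylin + DAB OD over the object, unsmoothed), `residual_mean`,
#'   `solidity`, centroid, and a `pixels` list-column of linear pixel indices.
#' @export
segment_colonoid_regions <- function(od, od_sum_threshold = 0.15,
                                     smoothing_sigma = 2) {
  stopifnot(inherits(od, "od_image"))
  if (od_sum_threshold <= 0) {
    stop("`od_sum_threshold` must be > 0", call. = FALSE)
  }
  cal <- attr(od, "calibration")
  total <- od$hematoxylin + od$dab
  sm <- EBImage::gblur(total, sigma = smoothing_sigma)
  mask <- matrix(as.numeric(sm > od_sum_threshold), nrow(sm), ncol(sm))
  mask <- EBImage::closing(mask, EBImage::makeBrush(5, "disc"))
  mask <- EBImage::fillHull(mask)
  lab <- label_components(mask, 8)
  tab <- label_table(lab)
  if (nrow(tab) == 0) {
    return(tibble::tibble(id = integer(), area_px = integer(),
                          area_um2 = numeric(), od_sum_mean = numeric(),
                          residual_mean = numeric(), solidity = numeric(),
                          centroid_row = numeric(), centroid_col = numeric(),
                          pixels = list()))
  }
  pix <- split(which(lab > 0), lab[lab > 0])
  tibble::tibble(id = tab$id,
                 area_px = tab$area_px,
                 area_um2 = tab$area_px * cal^2,
                 od_sum_mean = label_means(lab, total),
                 residual_mean = label_means(lab, od$residual),
                 solidity = label_solidity(lab, tab$id),
                 centroid_row = tab$centroid_row - 1,
                 centroid_col = tab$centroid_col - 1,
                 pixels = unname(pix))
}

#' Filter colonoid annotations by the exclusion rules
#'
#' Keeps annotations with mean OD sum at or above `od_sum_cutoff`, solidity
#' at or above `solidity_cutoff`, and residual-channel mean at or below
#' `residual_cutoff` (plus a small numerical tolerance: a literal "> 0"
#' exclusion would fire on float noise for every object). Order is preserved
#' and the count never increases.
#'
#' @param annotations tibble from [segment_colonoid_regions()].
#' @param od_sum_cutoff minimum mean OD sum (default 0.15).
#' @param solidity_cutoff minimum solidity (default 0.25).
#' @param residual_cutoff maximum residual-colour mean (default 0).
#' @param residual_tol numerical tolerance added to `residual_cutoff`
#'   (default 1e-3 OD).
#' @return The kept annotations.
#' @export
filter_annotations <- function(annotations, od_sum_cutoff = 0.15,
                               solidity_cutoff = 0.25, residual_cutoff = 0,
                               residual_tol = 1e-3) {
  need <- c("od_sum_mean", "solidity", "residual_mean")
  miss <- setdiff(need, names(annotations))
  if (length(miss)) {
    stop("annotations lack measurement(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  dplyr::filter(annotations,
                .data$od_sum_mean >= od_sum_cutoff,
                .data$solidity >= solidity_cutoff,
                .data$residual_mean <= residual_cutoff + residual_tol)
}

#' CK20 positive-area percentage of a section
#'
#' Smooths the DAB OD channel (Gaussian, default sigma 2.5 px), marks pixels
#' inside the kept annotations with smoothed DAB above the threshold as
#' positive, and returns 100 x positive pixels / total annotation pixels.
#'
#' @param annotations kept annotations (with `pixels` list-column).
#' @param od the `od_image` the annotations were segmented from.
#' @param dab_mean_threshold positivity threshold on smoothed DAB OD
#'   (default 0.3).
#' @param sigma Gaussian sigma in px (default 2.5).
#' @return One-row tibble: `positive_px`, `total_px`, `percent_positive`.
#' @export
ck20_positive_area <- function(annotations, od, dab_mean_threshold = 0.3,
                               sigma = 2.5) {
  stopifnot(inherits(od, "od_image"))
  if (nrow(annotations) == 0) {
    stop("no annotations; nothing to quantify", call. = FALSE)
  }
  idx <- unique(unlist(annotations$pixels))
  if (length(idx) == 0) stop("zero total annotation area", call. = FALSE)
  sm <- EBImage::gblur(od$dab, sigma = sigma)
  pos <- sum(sm[idx] > dab_mean_threshold)
  tibble::tibble(positive_px = pos, total_px = length(idx),
                 percent_positive = 100 * pos / length(idx))
}

#' Nucleus-detection parameters for chromogenic sections
#'
#' Defaults follow the positive-cell-detection settings used for the Ki67
#' stain: analysis pixel size 0.5 um, background radius 8 um, no median
#' filter, Gaussian sigma 1.3 um, nucleus area 15--200 um^2, detection
#' threshold 0.1 OD.
#'
#' @param requested_pixel_size analysis pixel size, um.
#' @param background_radius radius of the background opening, um (0 skips
#'   background subtraction).
#' @param median_radius median-filter radius, um (0 skips the median step).
#' @param sigma detection Gaussian sigma, um.
#' @param min_area,max_area nucleus area bounds, um^2.
#' @param detection_threshold threshold on the smoothed hematoxylin OD.
#' @return A `nucleus_detection_params` list.
#' @export
nucleus_detection_params <- function(requested_pixel_size = 0.5,
                                     background_radius = 8,
                                     median_radius = 0,
                                     sigma = 1.3,
                                     min_area = 15,
                                     max_area = 200,
                                     detection_threshold = 0.1) {
  if (min_area >= max_area) stop("min_area must be < max_area", call. = FALSE)
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(requested_pixel_size = requested_pixel_size,
                 background_radius = background_radius,
                 median_radius = median_radius, sigma = sigma,
                 min_area = min_area, max_area = max_area,
                 detection_threshold = detection_threshold),
            class = "nucleus_detection_params")
}

odd_brush <- function(radius_px) {
  EBImage::makeBrush(2L * max(1L, round(radius_px)) + 1L, "disc")
}

#' Detect nuclei on the hematoxylin channel of an OD image
#'
#' Classical positive-cell-detection analogue: resample to the requested
#' pixel size, estimate background by morphological opening and subtract it,
#' Gaussian-smooth, threshold, split touching nuclei by watershed on the
#' distance map, and keep components within the area bounds. Per-nucleus
#' hematoxylin and DAB OD means are measured on the unsmoothed channels.
#'
#' @param od an `od_image` (hematoxylin and dab channels required).
#' @param params a [nucleus_detection_params()].
#' @return Tibble of detections: id, centroid (0-based px, original scale),
#'   `nucleus_area_um2`, `hematoxylin_mean`, `dab_mean`.
#' @export
detect_nuclei_brightfield <- function(od, params = nucleus_detection_params()) {
  stopifnot(inherits(od, "od_image"))
  if (is.null(od$hematoxylin)) stop("hematoxylin channel missing", call. = FALSE)
  cal <- attr(od, "calibration")
  req <- params$requested_pixel_size
  hema <- od$hematoxylin
  dab <- od$dab
  scale <- cal / req
  if (abs(scale - 1) > 1e-9) {
    nd <- round(dim(hema) * scale)
    hema <- EBImage::resize(hema, w = nd[1], h = nd[2])
    dab <- EBImage::resize(dab, w = nd[1], h = nd[2])
  }
  work <- hema
  if (params$background_radius > 0) {
    bg <- EBImage::opening(work, odd_brush(params$background_radius / req))
    work <- pmax(work - bg, 0)
  }
  if (params$median_radius > 0) {
    work <- EBImage::medianFilter(work / max(work, 1),
                                  max(1L, round(params$median_radius / req))) *
      max(work, 1)
  }
  sm <- EBImage::gblur(work, sigma = params$sigma / req)
  mask <- sm > params$detection_threshold
  if (!any(mask)) {
    return(tibble::tibble(id = integer(), centroid_row = numeric(),
                          centroid_col = numeric(),
                          nucleus_area_um2 = numeric(),
                          hematoxylin_mean = numeric(), dab_mean = numeric()))
  }
  dm <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- EBImage::watershed(dm, tolerance = 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  tab <- label_table(lab)
  area_um2 <- tab$area_px * req^2
  keep <- area_um2 >= params$min_area & area_um2 <= params$max_area
  ids <- tab$id[keep]
  if (length(ids) == 0) {
    return(tibble::tibble(id = integer(), centroid_row = numeric(),
                          centroid_col = numeric(),
                          nucleus_area_um2 = numeric(),
                          hematoxylin_mean = numeric(), dab_mean = numeric()))
  }
  hm <- label_means(lab, hema)[match(ids, sort(unique(lab[lab > 0])))]
  dm2 <- label_means(lab, dab)[match(ids, sort(unique(lab[lab > 0])))]
  tibble::tibble(id = seq_along(ids),
                 centroid_row = (tab$centroid_row[keep] - 1) / scale,
                 centroid_col = (tab$centroid_col[keep] - 1) / scale,
                 nucleus_area_um2 = area_um2[keep],
                 hematoxylin_mean = hm, dab_mean = dm2)
}

#' Classify Ki67 positivity of detected nuclei
#'
#' Nuclei with hematoxylin mean strictly below `hematoxylin_min` are
#' excluded; of the rest, nuclei with DAB OD mean strictly above
#' `dab_positive` are positive. Percent positive is
#' `100 * positive / (positive + negative)`.
#'
#' @param detections tibble from [detect_nuclei_brightfield()].
#' @param hematoxylin_min exclusion threshold on hematoxylin mean
#'   (default 0.11; "less than" excludes).
#' @param dab_positive positivity threshold on DAB mean (default 0.15;
#'   "greater than" is positive).
#' @return List: `percent_positive`, `detections` (input plus a `class`
#'   column in {positive, negative, excluded}).
#' @export
classify_ki67 <- function(detections, hematoxylin_min = 0.11,
                          dab_positive = 0.15) {
  need <- c("hematoxylin_mean", "dab_mean")
  if (!all(need %in% names(detections))) {
    stop("detections must carry hematoxylin_mean and dab_mean", call. = FALSE)
  }
  cls <- dplyr::mutate(detections, class = dplyr::case_when(
    .data$hematoxylin_mean < hematoxylin_min ~ "excluded",
    .data$dab_mean > dab_positive ~ "positive",
    TRUE ~ "negative"))
  n_pos <- sum(cls$class == "positive")
  n_neg <- sum(cls$class == "negative")
  if (n_pos + n_neg == 0) {
    stop("no nuclei left after hematoxylin exclusion", call. = FALSE)
  }
  list(percent_positive = 100 * n_pos / (n_pos + n_neg), detections = cls)
}
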