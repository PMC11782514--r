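# Brightfield colonoid morphometry: Phansalkar local threshold, particle
# extraction with the Fiji-style filters (fill holes, exclude edge particles,
# minimum size), per-well top-K mean area, condition summaries.

#' Phansalkar local adaptive threshold
#'
#' The local threshold designed for low-contrast objects:
#' `t = m * (1 + p * exp(-q * m) + k * (s / r - 1))`, with `m` and `s` the
#' local mean and (population) standard deviation of the image normalised to
#' `[0, 1]` in a `(2 * radius + 1)^2` square window (mirror padding at the
#' borders). Foreground is `value < t` for `dark_objects` (the brightfield
#' colonoid polarity: dark rims on a bright background) or `value > t` for
#' `bright_objects`.
#'
#' @param image an 8-bit single-channel [raster_image()] or an integer-valued
#'   matrix in 0--255.
#' @param radius window half-width in pixels (>= 1).
#' @param k,r,p,q Phansalkar constants (defaults 0.25, 0.5, 2, 10 — the
#'   standard published values, also ImageJ's defaults).
#' @param polarity `"dark_objects"` (default) or `"bright_objects"`.
#' @return Logical foreground mask (matrix).
#' @export
phansalkar_threshold <- function(image, radius, k = 0.25, r = 0.5,
                                 p = 2, q = 10,
                                 polarity = c("dark_objects",
                                              "bright_objects")) {
  polarity <- match.arg(polarity)
  if (inherits(image, "raster_image")) {
    if (image$bit_depth != "8") {
      stop("Phansalkar thresholding expects an 8-bit image; run to_8bit() first",
           call. = FALSE)
    }
    image <- image$pixels[[1]]
  }
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (any(image < 0 | image > 255) || any(image != round(image))) {
    stop("pixel values must be 8-bit integers in 0..255; run to_8bit() first",
         call. = FALSE)
  }
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  if (r <= 0) stop("`r` must be > 0", call. = FALSE)
  x <- image / 255
  st <- local_mean_sd(x, as.integer(radius))
  thr <- st$mean * (1 + p * exp(-q * st$mean) + k * (st$sd / r - 1))
  if (polarity == "dark_objects") x < thr else x > thr
}

#' Extract colonoid particles from a binary mask
#'
#' Applies the particle-analysis rules: fill holes on the full mask, label
#' connected components (8-connectivity, the ImageJ convention), drop
#' particles touching the image border, drop particles with any pixel outside
#' the region of interest, and drop particles below the minimum size.
#'
#' @param mask logical/binary matrix (e.g. from [phansalkar_threshold()]).
#' @param calibration um/pixel.
#' @param roi optional region-of-interest polygon, a matrix/data frame with
#'   columns (row, col) in pixel coordinates (vertices of the Matrigel
#'   region); `NULL` keeps the whole image.
#' @param min_size minimum size, by default an area in um^2 (the Fiji
#'   particle-size field on a calibrated image); set
#'   `size_is_area = FALSE` to read it as an equivalent diameter in um.
#' @param size_is_area interpret `min_size` as area (default) or diameter.
#' @return Tibble of particle records: id, `area_px`, `area` (um^2), centroid
#'   (0-based pixel coordinates), `solidity`.
#' @export
analyze_particles <- function(mask, calibration, roi = NULL, min_size = 10,
                              size_is_area = TRUE) {
  if (calibration <= 0) stop("`calibration` must be > 0", call. = FALSE)
  if (!is.null(roi)) {
    roi <- as.matrix(roi)
    if (nrow(roi) < 3 || abs(shoelace_area(roi)) <= 0) {
      stop("`roi` polygon is empty or degenerate", call. = FALSE)
    }
  }
  filled <- EBImage::fillHull(matrix(as.numeric(mask != 0),
                                     nrow(mask), ncol(mask)))
  lab <- label_components(filled, connectivity = 8)
  tab <- label_table(lab)
  if (nrow(tab) == 0) {
    return(tibble::tibble(id = integer(), area_px = integer(),
                          area = numeric(), centroid_row = numeric(),
                          centroid_col = numeric(), solidity = numeric()))
  }
  keep <- !tab$touches_edge
  if (!is.null(roi)) {
    nr <- nrow(lab)
    idx <- which(lab > 0)
    rr <- (idx - 1) %% nr + 1
    cc <- (idx - 1) %/% nr + 1
    inside <- points_in_polygon(rr, cc, roi)
    out_ids <- unique(lab[idx][!inside])
    keep <- keep & !(tab$id %in% out_ids)
  }
  area_um2 <- tab$area_px * calibration^2
  size_ok <- if (size_is_area) {
    area_um2 >= min_size
  } else {
    2 * sqrt(area_um2 / pi) >= min_size
  }
  keep <- keep & size_ok
  ids <- tab$id[keep]
  if (length(ids) == 0) {
    return(tibble::tibble(id = integer(), area_px = integer(),
                          area = numeric(), centroid_row = numeric(),
                          centroid_col = numeric(), solidity = numeric()))
  }
  tibble::tibble(id = seq_along(ids),
                 area_px = tab$area_px[keep],
                 area = area_um2[keep],
                 centroid_row = tab$centroid_row[keep] - 1,
                 centroid_col = tab$centroid_col[keep] - 1,
                 solidity = label_solidity(lab, ids))
}

#' Mean area of the top-K largest particles in a well
#'
#' The per-well summary statistic: particles sorted by area descending (ties
#' broken by ascending id for determinism), mean over the first
#' `min(k, n)`; `truncated` flags wells with fewer than `k` particles.
#'
#' @param particles tibble from [analyze_particles()] (columns `id`, `area`).
#' @param k number of largest particles to average (default 100).
#' @param key optional one-row data frame of sample-key columns (donor,
#'   oxygen, condition, well, ...) prepended to the summary.
#' @return One-row tibble: `n_particles`, `top_k` (count used),
#'   `mean_top_k_area` (um^2), `truncated`.
#' @export
topk_mean_area <- function(particles, k = 100, key = NULL) {
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (is.null(particles) || nrow(particles) == 0) {
    stop("no particles to summarise (empty well)", call. = FALSE)
  }
  ord <- order(-particles$area, particles$id)
  kk <- min(k, nrow(particles))
  out <- tibble::tibble(n_particles = nrow(particles), top_k = kk,
                        mean_top_k_area = mean(particles$area[ord][seq_len(kk)]),
                        truncated = nrow(particles) < k)
  if (!is.null(key)) out <- dplyr::bind_cols(tibble::as_tibble(key), out)
  out
}

#' Summarise well-level size statistics per condition
#'
#' Averages the per-well top-K mean areas over wells within each
#' donor x oxygen x condition group, yielding the tidy table consumed by the
#' statistics layer.
#'
#' @param summaries tibble of well summaries (rows from [topk_mean_area()]
#'   with key columns).
#' @param by grouping columns (default donor, oxygen, condition — those
#'   present are used).
#' @return Tibble with the grouping columns, `n_wells`, and
#'   `mean_top_k_area` (um^2, mean over wells).
#' @export
summarize_condition <- function(summaries,
                                by = c("donor", "oxygen", "condition")) {
  by <- intersect(by, names(summaries))
  if (length(by) == 0) stop("no grouping columns found", call. = FALSE)
  if ("calibration" %in% names(summaries)) {
    bad <- summaries |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(n_cal = dplyr::n_distinct(.data$calibration),
                       .groups = "drop") |>
      dplyr::filter(.data$n_cal > 1)
    if (nrow(bad)) {
      stop("mixed calibrations within a group; refusing to average areas",
           call. = FALSE)
    }
  }
  summaries |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_wells = dplyr::n(),
                     mean_top_k_area = mean(.data$mean_top_k_area),
                     .groups = "drop")
}

#' Quantify one brightfield well end to end
#'
#' Convenience wrapper chaining [to_8bit()] (when needed),
#' [phansalkar_threshold()], [analyze_particles()] and [topk_mean_area()].
#'
#' @param image a single-channel [raster_image()].
#' @param radius Phansalkar window radius in px (per-experiment setting).
#' @param roi,min_size,size_is_area passed to [analyze_particles()].
#' @param k passed to [topk_mean_area()].
#' @param key optional sample-key row.
#' @param ... further arguments to [phansalkar_threshold()].
#' @return One-row well-summary tibble.
#' @export
quantify_brightfield_well <- function(image, radius = 15, roi = NULL,
                                      min_size = 10, size_is_area = TRUE,
                                      k = 100, key = NULL, ...) {
  stopifnot(inherits(image, "raster_image"))
  if (image$bit_depth != "8") image <- to_8bit(image)
  mask <- phansalkar_threshold(image, radius = radius, ...)
  particles <- analyze_particles(mask, image$calibration, roi = roi,
                                 min_size = min_size,
                                 size_is_area = size_is_area)
  topk_mean_area(particles, k = k, key = key)
}
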