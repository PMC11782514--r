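# Fluorescence section quantification: nucleus detection on DAPI with a
# pluggable detector, area/intensity exclusion rules, cytoplasm expansion
# (geodesic Voronoi), Ki67/CK20 compound classification, and the TUNEL
# area-per-cell metric with polygon simplification.

# channel aliases as exported by acquisition software
fluo_channel_aliases <- c("Ch1-T2" = "DAPI", "ch1-t2" = "DAPI",
                          "Blue" = "DAPI", "Green" = "TUNEL")

resolve_channel <- function(image, name) {
  if (name %in% image$channels) return(name)
  alias <- unname(fluo_channel_aliases[name])
  if (!is.na(alias) && alias %in% image$channels) return(alias)
  rev_alias <- names(fluo_channel_aliases)[fluo_channel_aliases == name]
  hit <- intersect(rev_alias, image$channels)
  if (length(hit)) return(hit[1])
  stop(sprintf("channel '%s' not found (have: %s)", name,
               paste(image$channels, collapse = ", ")), call. = FALSE)
}

#' Fluorescence nucleus-detection parameters
#'
#' Defaults follow the TUNEL analysis settings: detection probability
#' threshold 0.6, DAPI channel (alias "Ch1-T2"), analysis pixel size
#' 0.225 um, nucleus area 12--175 um^2, minimum DAPI mean 60 (use 25 for the
#' triple-positive analysis), cytoplasm expansion 5 um.
#'
#' @param probability_threshold minimum per-object detection score, in
#'   `[0, 1]`.
#' @param dapi_channel channel carrying the nuclear counterstain.
#' @param requested_pixel_size analysis pixel size, um.
#' @param area_min,area_max nucleus area bounds, um^2.
#' @param dapi_min_mean minimum mean DAPI signal (0--255 scale).
#' @param expansion_radius cytoplasm expansion radius, um.
#' @param mask_threshold initial segmentation threshold on the smoothed DAPI
#'   channel (0--255).
#' @param smooth_sigma Gaussian sigma (px) of the detector's smoothing.
#' @return A `fluo_detection_params` list.
#' @export
fluo_detection_params <- function(probability_threshold = 0.6,
                                  dapi_channel = "DAPI",
                                  requested_pixel_size = 0.225,
                                  area_min = 12, area_max = 175,
                                  dapi_min_mean = 60,
                                  expansion_radius = 5,
                                  mask_threshold = 30,
                                  smooth_sigma = 2) {
  if (probability_threshold < 0 || probability_threshold > 1) {
    stop("`probability_threshold` must be in [0, 1]", call. = FALSE)
  }
  if (area_min >= area_max) stop("area_min must be < area_max", call. = FALSE)
  structure(list(probability_threshold = probability_threshold,
                 dapi_channel = dapi_channel,
                 requested_pixel_size = requested_pixel_size,
                 area_min = area_min, area_max = area_max,
                 dapi_min_mean = dapi_min_mean,
                 expansion_radius = expansion_radius,
                 mask_threshold = mask_threshold,
                 smooth_sigma = smooth_sigma),
            class = "fluo_detection_params")
}

#' Default classical nucleus detector
#'
#' Deterministic stand-in for a learned instance-segmentation model, behind
#' the same interface (DAPI matrix in, labelled nuclei plus per-object scores
#' out): Gaussian smoothing, fixed threshold, hole filling, watershed on the
#' distance map to split touching nuclei. The detection score is the
#' normalised peak smoothed response, `max(smoothed) / 256`, strictly below 1
#' by construction.
#'
#' @param dapi numeric matrix (0--255) of the nuclear channel at the analysis
#'   pixel size.
#' @param params a [fluo_detection_params()].
#' @return List: `labels` (integer matrix), `scores` (numeric, one per
#'   label).
#' @export
detect_nuclei_classical <- function(dapi, params = fluo_detection_params()) {
  sm <- EBImage::gblur(dapi, sigma = params$smooth_sigma)
  mask <- sm > params$mask_threshold
  if (!any(mask)) {
    return(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                scores = numeric(0)))
  }
  m <- EBImage::fillHull(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- EBImage::watershed(EBImage::distmap(m), tolerance = 1)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  n <- max(lab)
  scores <- as.numeric(tapply(sm[lab > 0], lab[lab > 0], max)) / 256
  list(labels = lab, scores = scores)
}

#' Detect nuclei in a fluorescence section
#'
#' Resamples to the analysis pixel size, runs the detector (default
#' [detect_nuclei_classical()]; any function with the same signature can be
#' plugged in), drops objects scoring below the probability threshold, and
#' measures per-nucleus area and per-channel mean intensities.
#'
#' @param image a multi-channel [raster_image()] with a DAPI channel.
#' @param params a [fluo_detection_params()].
#' @param detector detector function `(dapi_matrix, params) -> list(labels,
#'   scores)`; `NULL` uses the classical default.
#' @return A `fluo_cells` tibble: id, `label`, score, centroid (0-based px,
#'   original scale), `area_um2`, one `<channel>_mean` column per channel.
#'   Carries the label matrix and resampled channels as attributes for the
#'   downstream cytoplasm/TUNEL steps.
#' @export
detect_nuclei_fluor <- function(image, params = fluo_detection_params(),
                                detector = NULL) {
  stopifnot(inherits(image, "raster_image"))
  dapi_name <- resolve_channel(image, params$dapi_channel)
  req <- params$requested_pixel_size
  scale <- image$calibration / req
  chans <- image$pixels
  if (abs(scale - 1) > 1e-9) {
    nd <- round(dim(chans[[1]]) * scale)
    chans <- lapply(chans, EBImage::resize, w = nd[1], h = nd[2])
  }
  if (is.null(detector)) detector <- detect_nuclei_classical
  det <- detector(chans[[dapi_name]], params)
  lab <- det$labels
  empty <- function() {
    cols <- c(list(id = integer(), label = integer(), score = numeric(),
                   centroid_row = numeric(), centroid_col = numeric(),
                   area_um2 = numeric()),
              stats::setNames(rep(list(numeric()), length(chans)),
                              paste0(tolower(names(chans)), "_mean")))
    out <- tibble::as_tibble(cols)
    fluo_cells(out, lab * 0L, chans, req, image$calibration)
  }
  if (length(det$scores) == 0) return(empty())
  keep_ids <- which(det$scores >= params$probability_threshold)
  if (length(keep_ids) == 0) return(empty())
  tab <- label_table(lab)
  tab <- tab[tab$id %in% keep_ids, , drop = FALSE]
  means <- lapply(chans, function(ch) {
    label_means(lab, ch)[match(tab$id, sort(unique(lab[lab > 0])))]
  })
  names(means) <- paste0(tolower(names(chans)), "_mean")
  out <- tibble::tibble(id = seq_len(nrow(tab)), label = tab$id,
                        score = det$scores[tab$id],
                        centroid_row = (tab$centroid_row - 1) / scale,
                        centroid_col = (tab$centroid_col - 1) / scale,
                        area_um2 = tab$area_px * req^2)
  out <- dplyr::bind_cols(out, tibble::as_tibble(means))
  fluo_cells(out, lab, chans, req, image$calibration)
}

fluo_cells <- function(df, labels, channels, pixel_size, calibration) {
  attr(df, "labels") <- labels
  attr(df, "channels") <- channels
  attr(df, "pixel_size") <- pixel_size
  attr(df, "calibration") <- calibration
  class(df) <- c("fluo_cells", class(df))
  df
}

keep_fluo_attrs <- function(new, old) {
  fluo_cells(new, attr(old, "labels"), attr(old, "channels"),
             attr(old, "pixel_size"), attr(old, "calibration"))
}

#' Apply nucleus exclusion rules
#'
#' Keeps nuclei with `area_min <= area <= area_max` and mean DAPI signal at
#' or above `dapi_min_mean`. Pure and order-independent.
#'
#' @param cells a `fluo_cells` tibble from [detect_nuclei_fluor()].
#' @param params a [fluo_detection_params()].
#' @return The kept cells (possibly empty).
#' @export
filter_nuclei <- function(cells, params = fluo_detection_params()) {
  if (!all(c("area_um2", "dapi_mean") %in% names(cells))) {
    stop("cells must carry area_um2 and dapi_mean", call. = FALSE)
  }
  out <- dplyr::filter(tibble::as_tibble(cells),
                       .data$area_um2 >= params$area_min,
                       .data$area_um2 <= params$area_max,
                       .data$dapi_mean >= params$dapi_min_mean)
  keep_fluo_attrs(out, cells)
}

#' Expand nuclei into simulated cytoplasm
#'
#' Dilates each nucleus by `radius` um; where expansions would overlap,
#' pixels are partitioned to the nearest nucleus (geodesic Voronoi region
#' growing), so cytoplasm masks are always disjoint and disjoint from all
#' nuclei. Adds cytoplasm area and per-channel cytoplasm means.
#'
#' @param cells a `fluo_cells` tibble.
#' @param radius expansion radius in um (>= 0); 0 yields empty cytoplasm.
#' @return `cells` with `cyto_area_um2` and `<channel>_cyto_mean` columns;
#'   the cytoplasm label matrix is attached as attribute `cyto_labels`.
#' @export
expand_cytoplasm <- function(cells, radius = 5) {
  if (radius < 0) stop("`radius` must be >= 0", call. = FALSE)
  chans <- attr(cells, "channels")
  labfull <- attr(cells, "labels")
  px <- attr(cells, "pixel_size")
  nmcols <- paste0(tolower(names(chans)), "_cyto_mean")
  if (nrow(cells) == 0 || radius == 0) {
    out <- dplyr::mutate(tibble::as_tibble(cells), cyto_area_um2 = 0)
    for (nm in nmcols) out[[nm]] <- NA_real_
    out <- keep_fluo_attrs(out, cells)
    attr(out, "cyto_labels") <- labfull * 0L
    return(out)
  }
  lab <- labfull
  lab[!(lab %in% cells$label)] <- 0L
  nucmask <- lab > 0
  dist <- EBImage::distmap(matrix(as.numeric(!nucmask), nrow(lab), ncol(lab)))
  grow <- nucmask | (dist > 0 & dist <= radius / px)
  vor <- EBImage::propagate(matrix(0, nrow(lab), ncol(lab)), seeds = lab,
                            mask = grow)
  vor <- matrix(as.integer(vor), nrow(lab), ncol(lab))
  cyto <- vor
  cyto[nucmask] <- 0L
  present <- sort(unique(cyto[cyto > 0]))
  counts <- tabulate(cyto[cyto > 0], nbins = max(cells$label))
  out <- tibble::as_tibble(cells)
  out$cyto_area_um2 <- counts[out$label] * px^2
  for (i in seq_along(chans)) {
    mns <- rep(NA_real_, max(cells$label))
    if (length(present)) {
      mns[present] <- as.numeric(tapply(chans[[i]][cyto > 0], cyto[cyto > 0],
                                        mean))
    }
    out[[nmcols[i]]] <- mns[out$label]
  }
  out <- keep_fluo_attrs(out, cells)
  attr(out, "cyto_labels") <- cyto
  out
}

#' Compound Ki67/CK20 classification
#'
#' A cell is CK20 positive iff its cytoplasm CK20 mean exceeds `ck20_cutoff`,
#' and Ki67 positive iff its nucleus Ki67 mean exceeds `ki67_cutoff`. Returns
#' the 2x2 class table and the percentage of Ki67-positive cells within the
#' CK20-positive population.
#'
#' @param cells `fluo_cells` with cytoplasm measurements
#'   (see [expand_cytoplasm()]).
#' @param ck20_cutoff cytoplasm CK20 positivity cut-off (default 15).
#' @param ki67_cutoff nuclear Ki67 positivity cut-off (default 25).
#' @return List: `counts` (tibble ck20_pos x ki67_pos x n),
#'   `percent_ki67_in_ck20_pos`, and the classified `cells`.
#' @export
classify_compound <- function(cells, ck20_cutoff = 15, ki67_cutoff = 25) {
  if (!all(c("ck20_cyto_mean", "ki67_mean") %in% names(cells))) {
    stop("cells lack cytoplasm CK20 / nuclear Ki67 means; run expand_cytoplasm() first",
         call. = FALSE)
  }
  out <- dplyr::mutate(tibble::as_tibble(cells),
                       ck20_pos = !is.na(.data$ck20_cyto_mean) &
                         .data$ck20_cyto_mean > ck20_cutoff,
                       ki67_pos = .data$ki67_mean > ki67_cutoff)
  counts <- out |>
    dplyr::count(.data$ck20_pos, .data$ki67_pos, name = "n") |>
    tidyr::complete(ck20_pos = c(FALSE, TRUE), ki67_pos = c(FALSE, TRUE),
                    fill = list(n = 0L))
  n_ck20 <- sum(out$ck20_pos)
  if (n_ck20 == 0) {
    stop("no CK20-positive cells; percent Ki67+ within CK20+ is undefined",
         call. = FALSE)
  }
  pct <- 100 * sum(out$ck20_pos & out$ki67_pos) / n_ck20
  list(counts = counts, percent_ki67_in_ck20_pos = pct,
       cells = keep_fluo_attrs(out, cells))
}

#' TUNEL-positive area per DAPI cell
#'
#' Smooths the TUNEL (green) channel, thresholds it, converts each connected
#' region to its boundary polygon, simplifies the polygon
#' (Visvalingam vertex elimination: vertices forming triangles smaller than
#' the tolerance are removed), re-rasterizes the simplified polygons, and
#' sums their area. The metric is total TUNEL area divided by the number of
#' kept DAPI cells.
#'
#' @param image the fluorescence [raster_image()] (TUNEL channel required).
#' @param cells kept cells from [filter_nuclei()] (>= 1 required).
#' @param green_threshold threshold on the smoothed TUNEL channel
#'   (default 68.2).
#' @param simplify_tolerance Visvalingam triangle-area tolerance in px^2
#'   (default 1.5).
#' @param smooth_sigma Gaussian sigma in px applied before thresholding
#'   (default 1).
#' @return One-row tibble: `tunel_area_um2`, `n_dapi_cells`, `um2_per_cell`;
#'   simplified polygons (pixel-corner coordinates) attached as attribute
#'   `polygons`.
#' @export
tunel_area_metric <- function(image, cells, green_threshold = 68.2,
                              simplify_tolerance = 1.5, smooth_sigma = 1) {
  stopifnot(inherits(image, "raster_image"))
  tun <- get_channel(image, resolve_channel(image, "TUNEL"))
  if (nrow(cells) == 0) {
    stop("zero kept DAPI cells; the per-cell metric is undefined",
         call. = FALSE)
  }
  cal <- image$calibration
  sm <- EBImage::gblur(tun, sigma = smooth_sigma)
  mask <- matrix(as.numeric(sm > green_threshold), nrow(sm), ncol(sm))
  mask <- EBImage::fillHull(mask)
  lab <- label_components(mask, 8)
  polys <- list()
  total_px <- 0
  if (max(lab) > 0) {
    for (i in seq_len(max(lab))) {
      poly <- trace_region_boundary(lab, i)
      sp <- simplify_polygon(poly, simplify_tolerance)
      polys[[i]] <- sp
      total_px <- total_px + rasterized_pixel_count(sp, nrow(lab), ncol(lab))
    }
  }
  out <- tibble::tibble(tunel_area_um2 = total_px * cal^2,
                        n_dapi_cells = nrow(cells),
                        um2_per_cell = total_px * cal^2 / nrow(cells))
  attr(out, "polygons") <- polys
  out
}
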