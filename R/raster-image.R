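#' Calibrated raster image
#'
#' A `raster_image` is a list of equally sized numeric matrices (one per
#' channel, `[row, col]` indexing, 0-based pixel-centre convention for
#' coordinates reported elsewhere) plus a spatial calibration in micrometres
#' per pixel and a nominal bit depth. Pixel values are stored in native units:
#' 0--255 for 8-bit, 0--65535 for 16-bit, arbitrary for `"float"`.
#'
#' @param pixels a matrix (single channel) or named list of matrices.
#' @param channels character vector of channel names; defaults to the list
#'   names or `"Ch1"`, `"Ch2"`, ...
#' @param calibration pixel size in micrometres per pixel (> 0).
#' @param bit_depth one of `8`, `16` or `"float"`.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(pixels, channels = NULL, calibration, bit_depth = 8) {
  if (is.matrix(pixels)) pixels <- list(pixels)
  stopifnot(is.list(pixels), length(pixels) >= 1)
  if (is.null(channels)) {
    channels <- names(pixels)
    if (is.null(channels)) channels <- paste0("Ch", seq_along(pixels))
  }
  if (length(channels) != length(pixels)) {
    stop("`channels` must name every pixel matrix", call. = FALSE)
  }
  dims <- vapply(pixels, function(m) dim(m), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all channels must share the same dimensions", call. = FALSE)
  }
  if (!is.numeric(calibration) || length(calibration) != 1 ||
      !is.finite(calibration) || calibration <= 0) {
    stop("`calibration` (um/pixel) must be a single positive number",
         call. = FALSE)
  }
  bit_depth <- as.character(bit_depth)
  if (!bit_depth %in% c("8", "16", "float")) {
    stop("`bit_depth` must be 8, 16 or \"float\"", call. = FALSE)
  }
  names(pixels) <- channels
  structure(
    list(pixels = pixels, channels = channels,
         calibration = calibration, bit_depth = bit_depth),
    class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels[[1]])
  cat(sprintf("<raster_image> %d x %d px, %s um/px, %s-bit\n",
              d[1], d[2], format(x$calibration), x$bit_depth))
  cat("channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$pixels[[1]])

#' Extract one channel as a matrix
#'
#' @param image a [raster_image()].
#' @param channel channel name or index.
#' @return The pixel matrix of the requested channel.
#' @export
get_channel <- function(image, channel = 1) {
  stopifnot(inherits(image, "raster_image"))
  if (is.character(channel) && !channel %in% image$channels) {
    stop(sprintf("channel '%s' not found (have: %s)", channel,
                 paste(image$channels, collapse = ", ")), call. = FALSE)
  }
  image$pixels[[channel]]
}

max_native <- function(bit_depth) {
  switch(as.character(bit_depth), "8" = 255, "16" = 65535,
         stop("float images have no native integer range", call. = FALSE))
}

#' Read a calibrated raster image from TIFF or PNG
#'
#' TIFF files written by [write_image()] round-trip losslessly at 8 or 16 bit,
#' with one TIFF directory per channel and the calibration plus channel names
#' in a JSON sidecar (`<path>.meta.json`) written alongside the image. PNG is
#' read as RGB with channels named `R`, `G`, `B` on a 0--255 scale.
#'
#' @param path file to read.
#' @param calibration um/pixel; required when the file carries no calibration.
#' @param bit_depth bit depth to assume for files without metadata.
#' @return A [raster_image()].
#' @export
read_image <- function(path, calibration = NULL, bit_depth = 8) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    meta <- NULL
    sidecar <- paste0(path, ".meta.json")
    if (file.exists(sidecar)) {
      meta <- tryCatch(jsonlite::fromJSON(sidecar), error = function(e) NULL)
    }
    if (is.null(calibration)) calibration <- meta$calibration
    if (is.null(calibration)) {
      stop("no calibration in TIFF metadata; supply `calibration` (um/pixel)",
           call. = FALSE)
    }
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits)) bit_depth <- bits
    scale <- max_native(bit_depth)
    mats <- lapply(pages, function(pg) {
      round(matrix(as.numeric(pg), nrow(pg), ncol(pg)) * scale)
    })
    channels <- meta$channels
    if (is.null(channels)) channels <- paste0("Ch", seq_along(mats))
    raster_image(mats, channels, calibration, bit_depth)
  } else if (ext == "png") {
    if (is.null(calibration)) {
      stop("PNG carries no calibration; supply `calibration` (um/pixel)",
           call. = FALSE)
    }
    a <- png::readPNG(path)
    if (length(dim(a)) == 2) {
      raster_image(list(Gray = round(a * 255)), "Gray", calibration, 8)
    } else {
      mats <- lapply(seq_len(min(3, dim(a)[3])),
                     function(k) round(a[, , k] * 255))
      raster_image(mats, c("R", "G", "B"), calibration, 8)
    }
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
}

#' Write a calibrated raster image
#'
#' @param image a [raster_image()].
#' @param path destination; `.tif`/`.tiff` (any channel count, lossless for
#'   8/16-bit) or `.png` (1 or 3 channels, 8-bit).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (image$bit_depth == "float") {
      stop("only 8/16-bit TIFF output is supported", call. = FALSE)
    }
    scale <- max_native(image$bit_depth)
    pages <- lapply(image$pixels, function(m) m / scale)
    tiff::writeTIFF(pages, path,
                    bits.per.sample = as.integer(image$bit_depth))
    jsonlite::write_json(
      list(calibration = image$calibration, channels = image$channels),
      paste0(path, ".meta.json"), auto_unbox = TRUE)
  } else if (ext == "png") {
    if (!length(image$channels) %in% c(1, 3)) {
      stop("PNG output needs 1 or 3 channels", call. = FALSE)
    }
    if (length(image$channels) == 1) {
      png::writePNG(image$pixels[[1]] / 255, path)
    } else {
      d <- dim(image$pixels[[1]])
      a <- array(0, c(d, 3))
      for (k in 1:3) a[, , k] <- image$pixels[[k]] / 255
      png::writePNG(a, path)
    }
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Convert a single-channel image to 8 bit
#'
#' `minmax` maps the observed `[min, max]` linearly onto `[0, 255]` (a
#' constant image maps to 0 by convention); `fixed` uses a supplied display
#' `range`, clipping outside values. Rounding is round-half-even, and pixel
#' ordering is preserved.
#'
#' @param image a single-channel [raster_image()].
#' @param mode `"minmax"` or `"fixed"`.
#' @param range length-2 numeric display range, required for `mode = "fixed"`.
#' @return An 8-bit [raster_image()].
#' @export
to_8bit <- function(image, mode = c("minmax", "fixed"), range = NULL) {
  stopifnot(inherits(image, "raster_image"))
  mode <- match.arg(mode)
  if (length(image$channels) != 1) {
    stop("to_8bit() expects a single-channel image", call. = FALSE)
  }
  m <- image$pixels[[1]]
  if (length(m) == 0) stop("empty image", call. = FALSE)
  if (mode == "minmax") {
    lo <- min(m); hi <- max(m)
    out <- if (hi > lo) round((m - lo) / (hi - lo) * 255) else m * 0
  } else {
    if (is.null(range) || length(range) != 2 || range[2] <= range[1]) {
      stop("`range` must be c(lo, hi) with hi > lo for mode = \"fixed\"",
           call. = FALSE)
    }
    out <- round(pmin(pmax((m - range[1]) / (range[2] - range[1]), 0), 1) * 255)
  }
  raster_image(list(out), image$channels, image$calibration, 8)
}

#' RGB intensities to optical density
#'
#' Beer--Lambert transform `OD_c = -log10((I_c + eps) / I0_c)`, with `eps = 1`
#' guarding against zero intensity and OD clipped to `[0, od_max]`. Background
#' pixels at the white level map to OD 0.
#'
#' @param image a 3-channel [raster_image()] (RGB).
#' @param I0 white level per channel (recycled), > 0.
#' @param eps additive intensity offset (default 1).
#' @param od_max clip ceiling for OD (default 3).
#' @return A list of OD matrices named after the input channels, with
#'   attributes `calibration`.
#' @export
rgb_to_od <- function(image, I0 = 255, eps = 1, od_max = 3) {
  stopifnot(inherits(image, "raster_image"))
  if (length(image$channels) != 3) {
    stop("rgb_to_od() expects a 3-channel RGB image", call. = FALSE)
  }
  I0 <- rep_len(I0, 3)
  if (any(!is.finite(I0)) || any(I0 <= 0)) stop("I0 must be > 0", call. = FALSE)
  od <- purrr::map2(image$pixels, as.list(I0), function(m, w) {
    pmin(pmax(-log10((m + eps) / w), 0), od_max)
  })
  names(od) <- image$channels
  attr(od, "calibration") <- image$calibration
  od
}

#' Stain vector set for colour deconvolution
#'
#' Column-normalised 3x3 matrix of stain OD vectors. The residual vector
#' defaults to the normalised cross product of the first two, giving a
#' complete, invertible basis. The matrix inverse is cached as an attribute.
#'
#' @param hematoxylin,dab,residual length-3 numeric OD vectors; `residual`
#'   may be `NULL`.
#' @return A 3x3 matrix of class `stain_vectors` (columns hematoxylin, dab,
#'   residual) with the cached inverse in `attr(, "inverse")`.
#' @export
stain_vectors <- function(hematoxylin, dab, residual = NULL) {
  unitize <- function(v, nm) {
    v <- as.numeric(v)
    if (length(v) != 3 || !all(is.finite(v))) {
      stop(nm, " must be a finite length-3 vector", call. = FALSE)
    }
    n <- sqrt(sum(v^2))
    if (n < 1e-12) stop(nm, " has zero norm", call. = FALSE)
    v / n
  }
  h <- unitize(hematoxylin, "hematoxylin")
  d <- unitize(dab, "dab")
  if (is.null(residual)) {
    residual <- c(h[2] * d[3] - h[3] * d[2],
                  h[3] * d[1] - h[1] * d[3],
                  h[1] * d[2] - h[2] * d[1])
    if (sqrt(sum(residual^2)) < 1e-8) {
      stop("hematoxylin and dab vectors are collinear; stain matrix rank < 2",
           call. = FALSE)
    }
  }
  r <- unitize(residual, "residual")
  M <- cbind(hematoxylin = h, dab = d, residual = r)
  inv <- tryCatch(solve(M), error = function(e) {
    stop("stain matrix is singular for vectors: ",
         paste(sprintf("(%.3f,%.3f,%.3f)", M[1, ], M[2, ], M[3, ]),
               collapse = " "), call. = FALSE)
  })
  if (!all(is.finite(inv)) || kappa(M) > 1e8) {
    stop("stain matrix is numerically singular", call. = FALSE)
  }
  structure(M, inverse = inv, class = c("stain_vectors", "matrix", "array"))
}

#' Standard H-DAB stain vectors
#'
#' The widely used published hematoxylin/DAB OD vectors (Ruifrok-style),
#' hematoxylin about (0.65, 0.70, 0.29) and DAB about (0.27, 0.57, 0.78),
#' with the residual completed as the normalised cross product. Slide-specific
#' vectors can be supplied to any function accepting `vectors`.
#'
#' @return A [stain_vectors()] object.
#' @export
hdab_vectors <- function() {
  stain_vectors(c(0.65, 0.70, 0.29), c(0.27, 0.57, 0.78))
}

#' Colour deconvolution of an OD image
#'
#' Per-pixel solve of `M c = od` where the columns of `M` are the stain
#' vectors; negative concentrations are clipped to zero.
#'
#' @param od a list of 3 OD matrices as from [rgb_to_od()].
#' @param vectors a [stain_vectors()] object.
#' @return An `od_image`: list of matrices `hematoxylin`, `dab`, `residual`
#'   with the calibration attribute inherited from `od`.
#' @export
deconvolve_stains <- function(od, vectors = hdab_vectors()) {
  if (!inherits(vectors, "stain_vectors")) {
    stop("`vectors` must be a stain_vectors object", call. = FALSE)
  }
  stopifnot(is.list(od), length(od) == 3)
  inv <- attr(vectors, "inverse")
  d <- dim(od[[1]])
  flat <- cbind(as.vector(od[[1]]), as.vector(od[[2]]), as.vector(od[[3]]))
  conc <- flat %*% t(inv)
  conc[conc < 0] <- 0
  out <- list(hematoxylin = matrix(conc[, 1], d[1], d[2]),
              dab = matrix(conc[, 2], d[1], d[2]),
              residual = matrix(conc[, 3], d[1], d[2]))
  attr(out, "calibration") <- attr(od, "calibration")
  class(out) <- "od_image"
  out
}

#' @export
print.od_image <- function(x, ...) {
  d <- dim(x$hematoxylin)
  cat(sprintf("<od_image> %d x %d px, %s um/px (hematoxylin/dab/residual)\n",
              d[1], d[2], format(attr(x, "calibration"))))
  invisible(x)
}
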