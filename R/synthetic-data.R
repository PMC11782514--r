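# Ground-truthed synthetic generators for every pipeline stage. Each
# generator is seeded and returns both the rendered input and a truth table
# sufficient to compute the expected downstream result without re-reading
# pixels.

# rejection-sample n non-overlapping centres with per-object clearance radii;
# margin keeps objects clear of the border (negative margin allows overlap)
place_centres <- function(n, clearance, nr, nc, margin, max_tries = 4000) {
  ys <- numeric(0); xs <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      lo_y <- 1 + margin[i]; hi_y <- nr - margin[i]
      lo_x <- 1 + margin[i]; hi_x <- nc - margin[i]
      if (hi_y <= lo_y || hi_x <= lo_x) break
      y <- stats::runif(1, lo_y, hi_y); x <- stats::runif(1, lo_x, hi_x)
      if (length(ys) == 0 ||
          all((ys - y)^2 + (xs - x)^2 >
              (clearance[seq_along(ys)] + clearance[i])^2)) {
        ys <- c(ys, y); xs <- c(xs, x); ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("could not place ", n, " objects without overlap; ",
           "use a larger image or fewer/smaller objects", call. = FALSE)
    }
  }
  cbind(row = ys, col = xs)
}

#' Synthetic brightfield well of dark-rimmed colonoids
#'
#' Renders an 8-bit brightfield-like well: bright background, ellipsoidal
#' colonoids drawn as a dark rim around a lighter lumen (the polarity the
#' morphometry stage expects). Object areas are drawn log-normally
#' (heavy-tailed, like real colonoid size distributions); a fraction of
#' objects is placed crossing the image border to exercise the
#' edge-exclusion rule. The default object count is a scaled-down well
#' (60--120 objects, a tenth of a full well) so validation runs stay fast.
#'
#' @param n_objects number of colonoids to plant (>= 0).
#' @param size_meanlog,size_sdlog log-normal parameters of object area in
#'   um^2 (defaults: median 2000 um^2, sdlog 0.6).
#' @param calibration um/pixel (> 0), default 2.
#' @param dim image size in pixels `c(rows, cols)`.
#' @param edge_fraction fraction of objects planted touching the border.
#' @param intensities named list: `bg`, `rim`, `lumen` grey levels (0--255).
#' @param rim_px rim thickness in pixels.
#' @param seed integer seed; fully determines the scene.
#' @return List with `image` (8-bit single-channel [raster_image()], channel
#'   `"BF"`) and `truth`: tibble of id, centroid (0-based px), axes,
#'   `area_px` (rasterized pixel count), `area_um2`, `touches_edge`.
#' @export
generate_brightfield_well <- function(n_objects = 90,
                                      size_meanlog = log(2000),
                                      size_sdlog = 0.6,
                                      calibration = 2,
                                      dim = c(800, 800),
                                      edge_fraction = 0.1,
                                      intensities = list(bg = 220, rim = 40,
                                                         lumen = 180),
                                      rim_px = 2.5,
                                      seed = 1) {
  if (calibration <= 0) stop("`calibration` must be > 0", call. = FALSE)
  stopifnot(n_objects >= 0)
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  img <- matrix(intensities$bg, nr, nc)
  truth <- tibble::tibble(id = integer(), centroid_row = numeric(),
                          centroid_col = numeric(), axis_a = numeric(),
                          axis_b = numeric(), angle = numeric(),
                          area_px = integer(), area_um2 = numeric(),
                          touches_edge = logical())
  if (n_objects == 0) {
    return(list(image = raster_image(list(BF = img), "BF", calibration, 8),
                truth = truth))
  }
  area_um2 <- stats::rlnorm(n_objects, size_meanlog, size_sdlog)
  area_px <- area_um2 / calibration^2
  aspect <- stats::runif(n_objects, 0.7, 1)
  a <- pmin(sqrt(area_px / (pi * aspect)), min(nr, nc) / 8)
  b <- a * aspect
  theta <- stats::runif(n_objects, 0, pi)
  n_edge <- round(edge_fraction * n_objects)
  is_edge <- c(rep(TRUE, n_edge), rep(FALSE, n_objects - n_edge))
  rmax <- pmax(a, b)
  # interior objects first (clear of the border), then edge objects planted
  # straddling a randomly chosen border side
  interior <- place_centres(n_objects - n_edge, rmax[!is_edge] + 4, nr, nc,
                            rmax[!is_edge] + 4)
  centres <- matrix(NA_real_, n_objects, 2)
  centres[!is_edge, ] <- interior
  if (n_edge > 0) {
    ys <- interior[, 1]; xs <- interior[, 2]
    cl <- rmax[!is_edge] + 4
    for (i in which(is_edge)) {
      placed <- FALSE
      for (t in 1:4000) {
        side <- sample(4, 1)
        off <- stats::runif(1, -0.5, 0.5) * min(a[i], b[i])
        pos <- stats::runif(1, 1, if (side <= 2) nc else nr)
        cand <- switch(side,
                       c(1 + off, pos), c(nr - off, pos),
                       c(pos, 1 + off), c(pos, nc - off))
        if (length(ys) == 0 ||
            all((ys - cand[1])^2 + (xs - cand[2])^2 >
                (cl + rmax[i] + 4)^2)) {
          centres[i, ] <- cand
          ys <- c(ys, cand[1]); xs <- c(xs, cand[2]); cl <- c(cl, rmax[i] + 4)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place edge objects; enlarge the image",
                        call. = FALSE)
    }
  }
  rows <- vector("list", n_objects)
  for (i in seq_len(n_objects)) {
    px <- ellipse_pixels(centres[i, 1], centres[i, 2], a[i], b[i], theta[i],
                         nr, nc)
    ai <- max(a[i] - rim_px, 0); bi <- max(b[i] - rim_px, 0)
    inner <- ellipse_pixels(centres[i, 1], centres[i, 2], ai, bi, theta[i],
                            nr, nc)
    img[px] <- intensities$rim
    if (nrow(inner)) img[inner] <- intensities$lumen
    touches <- any(px[, 1] %in% c(1L, nr)) || any(px[, 2] %in% c(1L, nc))
    rows[[i]] <- tibble::tibble(
      id = i, centroid_row = centres[i, 1] - 1, centroid_col = centres[i, 2] - 1,
      axis_a = a[i], axis_b = b[i], angle = theta[i],
      area_px = nrow(px), area_um2 = nrow(px) * calibration^2,
      touches_edge = touches)
  }
  list(image = raster_image(list(BF = img), "BF", calibration, 8),
       truth = dplyr::bind_rows(rows))
}

#' Synthetic H-DAB section with known per-nucleus positivity
#'
#' Composes an RGB chromogenic image by Beer--Lambert mixing,
#' `I = round(I0 * 10^(-M c) - eps)`, from planted per-pixel hematoxylin and
#' DAB OD maps: every nucleus is a disk of hematoxylin counterstain, and a
#' known fraction additionally carries DAB chromogen. The synthesis is the
#' exact inverse of [rgb_to_od()] + [deconvolve_stains()] up to 8-bit
#' quantization.
#'
#' @param n_cells number of nuclei.
#' @param dab_positive_fraction fraction of nuclei carrying DAB, in `[0, 1]`;
#'   the planted count is exactly `round(fraction * n_cells)`.
#' @param calibration um/pixel (default 0.5, matching the downstream
#'   detection pixel size).
#' @param dim image size `c(rows, cols)`.
#' @param nucleus_area_range area range (um^2) for uniform nucleus sizes.
#' @param hema_od,dab_od mean planted OD of counterstain and chromogen.
#' @param vectors stain basis used for mixing ([stain_vectors()]).
#' @param seed integer seed.
#' @return List with `image` (RGB [raster_image()]), `truth` (tibble: id,
#'   centroid, `area_um2`, `dab_positive`, planted `hema_od`, `dab_od`), and
#'   `od_truth` (list of the planted hematoxylin/dab OD matrices).
#' @export
generate_ihc_section <- function(n_cells = 200,
                                 dab_positive_fraction = 0.5,
                                 calibration = 0.5,
                                 dim = c(900, 900),
                                 nucleus_area_range = c(30, 80),
                                 hema_od = 0.6, dab_od = 0.7,
                                 vectors = hdab_vectors(),
                                 seed = 1) {
  if (dab_positive_fraction < 0 || dab_positive_fraction > 1) {
    stop("`dab_positive_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (!inherits(vectors, "stain_vectors")) {
    stop("`vectors` must be a stain_vectors object", call. = FALSE)
  }
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  od_h <- matrix(0, nr, nc); od_d <- matrix(0, nr, nc)
  truth <- tibble::tibble()
  if (n_cells > 0) {
    area <- stats::runif(n_cells, nucleus_area_range[1], nucleus_area_range[2])
    r_px <- sqrt(area / pi) / calibration
    n_pos <- round(dab_positive_fraction * n_cells)
    positive <- sample(rep(c(TRUE, FALSE), c(n_pos, n_cells - n_pos)))
    centres <- place_centres(n_cells, r_px + 4 / calibration, nr, nc,
                             r_px + 3)
    h_i <- pmax(stats::rnorm(n_cells, hema_od, 0.05), 0.2)
    d_i <- ifelse(positive, pmax(stats::rnorm(n_cells, dab_od, 0.05), 0.3),
                  0.01)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      px <- ellipse_pixels(centres[i, 1], centres[i, 2], r_px[i], r_px[i], 0,
                           nr, nc)
      od_h[px] <- h_i[i]
      od_d[px] <- d_i[i]
      rows[[i]] <- tibble::tibble(
        id = i, centroid_row = centres[i, 1] - 1,
        centroid_col = centres[i, 2] - 1,
        area_um2 = nrow(px) * calibration^2,
        dab_positive = positive[i], hema_od = h_i[i], dab_od = d_i[i])
    }
    truth <- dplyr::bind_rows(rows)
  }
  M <- unclass(vectors)
  flat <- cbind(as.vector(od_h), as.vector(od_d), 0) %*% t(M)
  I0 <- 255; eps <- 1
  rgb <- pmin(pmax(round(I0 * 10^(-flat) - eps), 0), 255)
  mats <- lapply(1:3, function(k) matrix(rgb[, k], nr, nc))
  list(image = raster_image(mats, c("R", "G", "B"), calibration, 8),
       truth = truth,
       od_truth = list(hematoxylin = od_h, dab = od_d))
}

#' Synthetic multi-channel fluorescence section
#'
#' Renders 8-bit (0--255) channels named `DAPI`, `KI67`, `CK20`, `TUNEL`:
#' nuclear DAPI and Ki67 signal as disks, CK20 as a perinuclear ring
#' (cytoplasmic stain), and TUNEL as diffuse patches of known area. Cell
#' classes are planted at exact counts (largest-remainder rounding of
#' `class_mix * n_cells`).
#'
#' @param n_cells number of cells.
#' @param class_mix named fractions over
#'   `c("ki67_ck20", "ki67_only", "ck20_only", "negative", "tunel")`,
#'   summing to 1. `tunel`-class cells carry a green patch over the cell.
#' @param calibration um/pixel (default 0.225, the analysis pixel size).
#' @param dim image size `c(rows, cols)`; enlarge for big `n_cells`.
#' @param intensity named list of mean channel levels:
#'   `dapi`, `ki67_pos`, `ki67_neg`, `ck20_pos`, `ck20_neg`, `tunel`, `bg`.
#' @param noise_sd Gaussian pixel noise sd (applied to every channel, then
#'   clamped to 0--255 and rounded).
#' @param nucleus_area_range nucleus area range in um^2 (uniform).
#' @param ring_um width of the CK20 perinuclear ring in um.
#' @param tunel_patch_areas_um2 optional numeric vector of free-standing
#'   TUNEL patch areas (um^2) planted away from the border.
#' @param seed integer seed.
#' @return List with `image` (4-channel [raster_image()]), `truth` (tibble:
#'   id, centroid, `area_um2`, class flags `ki67_pos`, `ck20_pos`, `tunel`),
#'   and `tunel_truth` (tibble of patch areas; `total_um2` attribute equals
#'   the rasterized TUNEL-positive area).
#' @export
generate_fluorescence_section <- function(n_cells = 300,
                                          class_mix = c(ki67_ck20 = 0.3,
                                                        ki67_only = 0.2,
                                                        ck20_only = 0.3,
                                                        negative = 0.2,
                                                        tunel = 0),
                                          calibration = 0.225,
                                          dim = c(1600, 1600),
                                          intensity = list(dapi = 180,
                                                           ki67_pos = 100,
                                                           ki67_neg = 5,
                                                           ck20_pos = 90,
                                                           ck20_neg = 2,
                                                           tunel = 150,
                                                           bg = 2),
                                          noise_sd = 2,
                                          nucleus_area_range = c(30, 80),
                                          ring_um = 2,
                                          tunel_patch_areas_um2 = numeric(0),
                                          seed = 1) {
  classes <- c("ki67_ck20", "ki67_only", "ck20_only", "negative", "tunel")
  mix <- class_mix[classes]
  mix[is.na(mix)] <- 0
  if (abs(sum(mix) - 1) > 1e-8) stop("`class_mix` must sum to 1", call. = FALSE)
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  ch <- list(DAPI = matrix(intensity$bg, nr, nc),
             KI67 = matrix(intensity$bg, nr, nc),
             CK20 = matrix(intensity$bg, nr, nc),
             TUNEL = matrix(intensity$bg, nr, nc))
  truth <- tibble::tibble()
  tunel_px_total <- 0L
  patch_rows <- list()
  if (n_cells > 0) {
    # exact class counts by largest remainder
    raw <- mix * n_cells
    cnt <- floor(raw)
    left <- n_cells - sum(cnt)
    if (left > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(left)]
      cnt[extra] <- cnt[extra] + 1
    }
    cls <- sample(rep(classes, cnt))
    area <- stats::runif(n_cells, nucleus_area_range[1], nucleus_area_range[2])
    r_px <- sqrt(area / pi) / calibration
    ring_px <- ring_um / calibration
    clr <- r_px + ring_px + 2
    centres <- place_centres(n_cells, clr, nr, nc, clr + 3)
    rows <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      nuc <- ellipse_pixels(centres[i, 1], centres[i, 2], r_px[i], r_px[i], 0,
                            nr, nc)
      ring_out <- ellipse_pixels(centres[i, 1], centres[i, 2],
                                 r_px[i] + ring_px, r_px[i] + ring_px, 0,
                                 nr, nc)
      ch$DAPI[nuc] <- intensity$dapi
      ki67_pos <- cls[i] %in% c("ki67_ck20", "ki67_only")
      ck20_pos <- cls[i] %in% c("ki67_ck20", "ck20_only")
      ch$KI67[nuc] <- if (ki67_pos) intensity$ki67_pos else intensity$ki67_neg
      ck20_val <- if (ck20_pos) intensity$ck20_pos else intensity$ck20_neg
      ch$CK20[ring_out] <- ck20_val   # ring value; nucleus overwritten next
      ch$CK20[nuc] <- intensity$bg
      if (cls[i] == "tunel") {
        ch$TUNEL[ring_out] <- intensity$tunel
        tunel_px_total <- tunel_px_total + nrow(ring_out)
      }
      rows[[i]] <- tibble::tibble(
        id = i, centroid_row = centres[i, 1] - 1,
        centroid_col = centres[i, 2] - 1,
        area_um2 = nrow(nuc) * calibration^2,
        class = cls[i], ki67_pos = ki67_pos, ck20_pos = ck20_pos,
        tunel = cls[i] == "tunel")
    }
    truth <- dplyr::bind_rows(rows)
  }
  if (length(tunel_patch_areas_um2)) {
    pr <- sqrt(tunel_patch_areas_um2 / pi) / calibration
    pc <- place_centres(length(pr), pr + 8, nr, nc, pr + 4)
    for (i in seq_along(pr)) {
      px <- ellipse_pixels(pc[i, 1], pc[i, 2], pr[i], pr[i], 0, nr, nc)
      ch$TUNEL[px] <- intensity$tunel
      tunel_px_total <- tunel_px_total + nrow(px)
      patch_rows[[i]] <- tibble::tibble(
        patch = i, centroid_row = pc[i, 1] - 1, centroid_col = pc[i, 2] - 1,
        area_px = nrow(px), area_um2 = nrow(px) * calibration^2)
    }
  }
  if (noise_sd > 0) {
    ch <- lapply(ch, function(m) {
      pmin(pmax(round(m + stats::rnorm(length(m), 0, noise_sd)), 0), 255)
    })
  }
  tunel_truth <- dplyr::bind_rows(patch_rows)
  attr(tunel_truth, "total_um2") <- tunel_px_total * calibration^2
  list(image = raster_image(ch, names(ch), calibration, 8),
       truth = truth, tunel_truth = tunel_truth)
}

#' Configuration for the chemokine-panel simulator
#'
#' Log-normal generative model mirroring the analysis model: for each
#' donor/condition/oxygen/well cell,
#' `log Value = baseline + condition effect + oxygen effect + interaction +
#' donor intercept + noise`, with values below `lower_limit` censored to the
#' token `"OOR <"`.
#'
#' @param n_donors number of donors.
#' @param analytes character vector of analyte names.
#' @param baseline_log_mean baseline of log concentration (single value or
#'   named per analyte), log pg/mL.
#' @param condition_effects named numeric (by condition label) of additive
#'   log-scale effects, applied to every analyte; or a matrix with analyte
#'   rownames and condition colnames.
#' @param oxygen_effect additive log-scale effect of 20% vs 2% oxygen.
#' @param interaction_effects named numeric (by condition) of extra effect at
#'   20% oxygen.
#' @param donor_sd sd of the donor random intercept (log units, >= 0).
#' @param residual_sd residual sd (log units, >= 0).
#' @param lower_limit lower detection limit in pg/mL (>= 0).
#' @param n_wells technical replicate wells per cell.
#' @param asterisk_fraction fraction of numeric tokens flagged with a
#'   trailing `"*"` (instrument annotation), exercising token cleaning.
#' @param seed integer seed.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_donors = 6,
                             analytes = c("CXCL1", "CXCL2", "CXCL5", "CXCL10",
                                          "CXCL11", "CX3CL1", "CSF2", "CCL2"),
                             baseline_log_mean = log(200),
                             condition_effects = NULL,
                             oxygen_effect = 0,
                             interaction_effects = NULL,
                             donor_sd = 0.3,
                             residual_sd = 0.2,
                             lower_limit = 0,
                             n_wells = 1,
                             asterisk_fraction = 0,
                             seed = 1) {
  if (donor_sd < 0 || residual_sd < 0) stop("sds must be >= 0", call. = FALSE)
  if (lower_limit < 0) stop("`lower_limit` must be >= 0", call. = FALSE)
  structure(list(n_donors = n_donors, analytes = analytes,
                 baseline_log_mean = baseline_log_mean,
                 condition_effects = condition_effects,
                 oxygen_effect = oxygen_effect,
                 interaction_effects = interaction_effects,
                 donor_sd = donor_sd, residual_sd = residual_sd,
                 lower_limit = lower_limit, n_wells = n_wells,
                 asterisk_fraction = asterisk_fraction, seed = seed),
            class = "panel_sim_config")
}

#' Simulate a multiplex chemokine panel
#'
#' @param config a [panel_sim_config()].
#' @return Tibble with columns donor, oxygen, condition, well, analyte,
#'   `token` (text as exported by assay software: numeric, possibly
#'   asterisked, or `"OOR <"`), and `true_value` (the uncensored
#'   concentration, for validation only). Balanced over the full grid.
#' @export
simulate_chemokine_panel <- function(config = panel_sim_config()) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  donors <- paste0("D", seq_len(config$n_donors))
  grid <- tidyr::expand_grid(donor = donors,
                             oxygen = oxygen_levels(),
                             condition = condition_levels(),
                             well = seq_len(config$n_wells),
                             analyte = config$analytes)
  base <- config$baseline_log_mean
  if (is.null(names(base))) {
    base_v <- rep(base[1], nrow(grid))
  } else {
    base_v <- base[grid$analyte]
  }
  ce <- rep(0, nrow(grid))
  if (!is.null(config$condition_effects)) {
    if (is.matrix(config$condition_effects)) {
      ce <- config$condition_effects[cbind(grid$analyte, grid$condition)]
    } else {
      v <- config$condition_effects[grid$condition]
      ce <- ifelse(is.na(v), 0, v)
    }
  }
  oe <- ifelse(grid$oxygen == "20%", config$oxygen_effect, 0)
  ie <- rep(0, nrow(grid))
  if (!is.null(config$interaction_effects)) {
    v <- config$interaction_effects[grid$condition]
    ie <- ifelse(grid$oxygen == "20%" & !is.na(v), v, 0)
  }
  donor_int <- stats::rnorm(config$n_donors, 0, config$donor_sd)
  names(donor_int) <- donors
  noise <- stats::rnorm(nrow(grid), 0, config$residual_sd)
  value <- exp(unname(base_v) + unname(ce) + oe + unname(ie) +
               unname(donor_int[grid$donor]) + noise)
  token <- formatC(value, format = "f", digits = 2)
  if (config$asterisk_fraction > 0) {
    star <- stats::runif(nrow(grid)) < config$asterisk_fraction
    token[star] <- paste0(token[star], "*")
  }
  censored <- value < config$lower_limit
  token[censored] <- "OOR <"
  dplyr::mutate(grid, token = token, true_value = value)
}

#' Simulate an immunoblot band-intensity table
#'
#' Target band = donor level x condition fold change x log-normal noise;
#' GAPDH loading control = donor level x log-normal noise. With zero noise,
#' GAPDH-normalised fold changes recover the planted values exactly.
#'
#' @param n_donors number of donors.
#' @param fold_changes named numeric of true fold changes per condition
#'   (relative to DMSO); conditions not named get fold 1. All > 0.
#' @param target marker name.
#' @param noise_sd log-scale sd of multiplicative noise (>= 0).
#' @param donor_sd log-scale sd of per-donor lane scale.
#' @param control_level mean band intensity of the DMSO target (AU).
#' @param oxygen oxygen label for the table.
#' @param seed integer seed.
#' @return Tibble: donor, oxygen, condition, target, `target_intensity`,
#'   `gapdh_intensity`, plus the planted `true_fold`.
#' @export
simulate_blot_table <- function(n_donors = 6,
                                fold_changes = c(DMSO = 1),
                                target = "LGR5",
                                noise_sd = 0,
                                donor_sd = 0,
                                control_level = 1000,
                                oxygen = "2%",
                                seed = 1) {
  if (any(fold_changes <= 0)) stop("fold changes must be > 0", call. = FALSE)
  set.seed(seed)
  folds <- stats::setNames(rep(1, 6), condition_levels())
  folds[names(fold_changes)] <- fold_changes
  donors <- paste0("D", seq_len(n_donors))
  grid <- tidyr::expand_grid(donor = donors, oxygen = oxygen,
                             condition = condition_levels())
  lane <- exp(stats::rnorm(n_donors, 0, donor_sd))
  names(lane) <- donors
  tnoise <- exp(stats::rnorm(nrow(grid), 0, noise_sd))
  gnoise <- exp(stats::rnorm(nrow(grid), 0, noise_sd))
  dplyr::mutate(grid,
    target = target,
    true_fold = unname(folds[.data$condition]),
    target_intensity = control_level * unname(lane[.data$donor]) *
      .data$true_fold * tnoise,
    gapdh_intensity = control_level * unname(lane[.data$donor]) * gnoise)
}
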