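# Immunoblot normalisation: target / GAPDH ratios, fold change relative to
# the DMSO vehicle within each donor x oxygen group, and paired marker
# ratios (pMLKL/MLKL, cleaved caspase-3 / caspase-3).

check_blot_intensities <- function(rows, floor = 0) {
  bad <- !is.finite(rows$target_intensity) | rows$target_intensity <= floor |
    !is.finite(rows$gapdh_intensity) | rows$gapdh_intensity <= floor
  if (any(bad)) {
    ex <- rows[bad, , drop = FALSE][1, ]
    stop(sprintf(
      "non-positive (or below-floor) band intensity for donor %s, %s, %s",
      ex$donor, ex$oxygen, ex$condition), call. = FALSE)
  }
}

#' Normalise immunoblot bands to GAPDH and the DMSO control
#'
#' Per row, `ratio = target / gapdh`; per donor x oxygen (x target) group,
#' `fold = ratio / ratio(DMSO)`. Scale-invariant: rescaling all intensities
#' in a lane leaves folds unchanged, and every DMSO row maps to fold 1.
#'
#' @param rows tibble with columns donor, oxygen, condition,
#'   `target_intensity`, `gapdh_intensity` (and optionally `target`).
#' @param floor intensities at or below this are rejected (default 0): a
#'   near-zero denominator silently blows up folds, so it is an error.
#' @return Input tibble plus `ratio` and `fold` columns.
#' @export
normalize_blot <- function(rows, floor = 0) {
  need <- c("donor", "oxygen", "condition", "target_intensity",
            "gapdh_intensity")
  miss <- setdiff(need, names(rows))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  check_blot_intensities(rows, floor)
  grp <- intersect(c("donor", "oxygen", "target"), names(rows))
  out <- rows |>
    dplyr::mutate(ratio = .data$target_intensity / .data$gapdh_intensity,
                  condition = as.character(.data$condition)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.ref = .data$ratio[match("DMSO", .data$condition)]) |>
    dplyr::ungroup()
  if (any(is.na(out$.ref))) {
    ex <- out[is.na(out$.ref), , drop = FALSE][1, ]
    stop(sprintf("no DMSO reference row for donor %s at %s oxygen",
                 ex$donor, ex$oxygen), call. = FALSE)
  }
  dplyr::mutate(out, fold = .data$ratio / .data$.ref, .ref = NULL)
}

#' Ratio of a phospho/cleaved marker to its total form
#'
#' Joins the two marker tables by sample key, takes the per-key ratio of
#' GAPDH-normalised intensities (e.g. pMLKL/MLKL, cleaved caspase-3 /
#' caspase-3), then expresses it as fold change versus the DMSO control
#' within each donor x oxygen group, as in [normalize_blot()].
#'
#' @param phospho,total tibbles in the [normalize_blot()] input format.
#' @return Tibble keyed by donor, oxygen, condition with `ratio` (normalised
#'   phospho / normalised total) and `fold` (vs DMSO).
#' @export
marker_ratio <- function(phospho, total) {
  check_blot_intensities(phospho)
  check_blot_intensities(total)
  key <- c("donor", "oxygen", "condition")
  p <- dplyr::mutate(phospho, .p = .data$target_intensity / .data$gapdh_intensity)
  t <- dplyr::mutate(total, .t = .data$target_intensity / .data$gapdh_intensity)
  j <- dplyr::inner_join(dplyr::select(p, dplyr::all_of(key), ".p"),
                         dplyr::select(t, dplyr::all_of(key), ".t"),
                         by = key)
  if (nrow(j) != nrow(p) || nrow(j) != nrow(t)) {
    stop("unmatched sample keys between the phospho and total tables",
         call. = FALSE)
  }
  out <- j |>
    dplyr::mutate(ratio = .data$.p / .data$.t,
                  condition = as.character(.data$condition)) |>
    dplyr::group_by(.data$donor, .data$oxygen) |>
    dplyr::mutate(fold = .data$ratio / .data$ratio[match("DMSO", .data$condition)]) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(key), "ratio", "fold")
  if (any(is.na(out$fold))) {
    stop("a donor x oxygen group lacks its DMSO reference row", call. = FALSE)
  }
  out
}
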