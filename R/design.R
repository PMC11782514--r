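#' Canonical treatment conditions
#'
#' The six-arm factorial used throughout: DMSO vehicle (reference), the JAK
#' inhibitor tofacitinib, the corticosteroid budesonide, inflammatory
#' stimulation with TNF + Poly(I:C), and each drug combined with stimulation.
#' Crossed with two oxygen levels (2% physioxia vs 20% atmospheric) and
#' cultured per donor.
#'
#' @return Character vector of the six condition labels in canonical order
#'   (DMSO first, the reference level).
#' @export
condition_levels <- function() {
  c("DMSO", "TOFA", "BUD", "TNF_PIC", "TOFA_TNF_PIC", "BUD_TNF_PIC")
}

#' @rdname condition_levels
#' @return `oxygen_levels()`: the two oxygen labels, reference first.
#' @export
oxygen_levels <- function() c("2%", "20%")

# alias map for condition labels found in the wild; keys are lower-case with
# non-alphanumerics stripped
condition_aliases <- c(
  "dmso" = "DMSO", "vehicle" = "DMSO", "control" = "DMSO", "1" = "DMSO",
  "tofa" = "TOFA", "tofacitinib" = "TOFA", "2" = "TOFA",
  "bud" = "BUD", "budesonide" = "BUD", "3" = "BUD",
  "tnfpic" = "TNF_PIC", "tnfpolyic" = "TNF_PIC", "stim" = "TNF_PIC",
  "4" = "TNF_PIC",
  "tofatnfpic" = "TOFA_TNF_PIC", "tofacitinibtnfpolyic" = "TOFA_TNF_PIC",
  "5" = "TOFA_TNF_PIC",
  "budtnfpic" = "BUD_TNF_PIC", "budesonidetnfpolyic" = "BUD_TNF_PIC",
  "6" = "BUD_TNF_PIC")

#' Normalise condition labels to the canonical set
#'
#' Resolves common synonyms ("Tofa", "tofacitinib", numeric arm indices 1-6)
#' to the canonical labels and returns a factor with DMSO as reference.
#'
#' @param x character or factor of condition labels.
#' @return Factor with levels [condition_levels()].
#' @export
normalize_condition <- function(x) {
  key <- gsub("[^a-z0-9]", "", tolower(as.character(x)))
  canon <- ifelse(toupper(as.character(x)) %in% condition_levels(),
                  toupper(as.character(x)),
                  unname(condition_aliases[key]))
  bad <- unique(as.character(x)[is.na(canon)])
  if (length(bad)) {
    stop("unrecognised condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  factor(canon, levels = condition_levels())
}

#' Condition manifest
#'
#' @return Tibble with one row per treatment arm: index (1-6), canonical
#'   label, description, and dosing where applicable (molar concentration,
#'   molar mass, derived mass concentration).
#' @export
condition_manifest <- function() {
  path <- system.file("extdata", "conditions.json", package = "colonoidquant")
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' Convert a molar to a mass concentration
#'
#' `mass (ug/mL) = molar (umol/L) x molar mass (g/mol) / 1000`. Used for the
#' dosing bookkeeping of the treatment arms, e.g. 50 uM tofacitinib citrate
#' (504.5 g/mol) is 25.2 ug/mL.
#'
#' @param molar_concentration umol/L, finite and >= 0.
#' @param molar_mass g/mol, finite and >= 0.
#' @param digits optional rounding for presentation; `NULL` returns the
#'   exact value.
#' @return Mass concentration in ug/mL.
#' @export
molar_to_mass_concentration <- function(molar_concentration, molar_mass,
                                        digits = NULL) {
  if (any(!is.finite(molar_concentration)) || any(!is.finite(molar_mass))) {
    stop("arguments must be finite", call. = FALSE)
  }
  if (any(molar_concentration < 0) || any(molar_mass < 0)) {
    stop("concentrations and molar masses must be >= 0", call. = FALSE)
  }
  out <- molar_concentration * molar_mass / 1000
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Validate a sample-key design table
#'
#' Checks a table keyed by donor / oxygen / condition (optionally well and
#' experiment) for missing donor x oxygen x condition cells and duplicated
#' keys. Report-only: the input is never modified.
#'
#' @param design data frame with columns `donor`, `oxygen`, `condition`, and
#'   optionally `well`, `experiment`.
#' @return A `design_report` list: `complete` (logical), `missing_cells`
#'   (tibble), `duplicates` (tibble of repeated full keys).
#' @export
validate_design <- function(design) {
  if (!is.data.frame(design) || nrow(design) == 0) {
    stop("`design` must be a non-empty data frame", call. = FALSE)
  }
  need <- c("donor", "oxygen", "condition")
  miss <- setdiff(need, names(design))
  if (length(miss)) {
    stop("missing design columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  design <- dplyr::mutate(tibble::as_tibble(design),
                          condition = as.character(normalize_condition(.data$condition)),
                          oxygen = as.character(.data$oxygen))
  full <- tidyr::expand_grid(donor = unique(design$donor),
                             oxygen = unique(design$oxygen),
                             condition = condition_levels())
  present <- dplyr::distinct(design, .data$donor, .data$oxygen, .data$condition)
  missing_cells <- dplyr::anti_join(full, present,
                                    by = c("donor", "oxygen", "condition"))
  keycols <- intersect(c("donor", "oxygen", "condition", "well", "experiment"),
                       names(design))
  duplicates <- design |>
    dplyr::count(dplyr::across(dplyr::all_of(keycols)), name = "n_rows") |>
    dplyr::filter(.data$n_rows > 1)
  structure(list(complete = nrow(missing_cells) == 0 && nrow(duplicates) == 0,
                 missing_cells = missing_cells, duplicates = duplicates),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  if (x$complete) {
    cat("design complete: all donor x oxygen x condition cells present, no duplicate keys\n")
  } else {
    if (nrow(x$missing_cells)) {
      cat("missing cells:\n"); print(x$missing_cells)
    }
    if (nrow(x$duplicates)) {
      cat("duplicate keys:\n"); print(x$duplicates)
    }
  }
  invisible(x)
}
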