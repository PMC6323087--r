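#' Spatially resolved mass spectra on a raster grid
#'
#' A `spectra_dataset` holds one mass spectrum per image pixel. After
#' [resample()] all pixels share a common m/z grid and intensities form a
#' pixel-by-bin matrix; straight from [load_dataset()] the per-pixel m/z axes
#' may still differ (`is_common_grid()` is then `FALSE`), which only
#' [resample()] accepts.
#'
#' Pixels are kept in deterministic row-major order (by y, then x),
#' independent of the order of records in the source file. Coordinates are
#' 0-based integer raster indices; the physical raster pitch (default 100 um)
#' is metadata only.
#'
#' @param mz_axis Strictly increasing numeric m/z grid (Da), or `NULL` when
#'   `mz_list` is given.
#' @param intensities Pixel x bin matrix of nonnegative intensities, or
#'   `NULL` when `intensity_list` is given.
#' @param coords Data frame with integer columns `x`, `y`, one row per pixel.
#' @param specimen_id Free-text specimen identifier.
#' @param domain `"peptide"` or `"lipid"`.
#' @param mass_range Length-2 numeric `(low, high)` in Da. Defaults to the
#'   instrument ranges used for each domain: 800-4000 (peptide),
#'   300-1200 (lipid).
#' @param pitch_um Raster pitch in micrometres (metadata only).
#' @param mz_list,intensity_list Per-pixel axes/intensities for the
#'   heterogeneous (pre-resampling) layout.
#' @return An object of class `spectra_dataset`.
#' @export
spectra_dataset <- function(mz_axis = NULL, intensities = NULL, coords,
                            specimen_id = "specimen",
                            domain = c("peptide", "lipid"),
                            mass_range = NULL, pitch_um = 100,
                            mz_list = NULL, intensity_list = NULL) {
  domain <- match.arg(domain)
  if (is.null(mass_range))
    mass_range <- if (domain == "peptide") c(800, 4000) else c(300, 1200)
  coords <- as.data.frame(coords)
  if (!all(c("x", "y") %in% names(coords)))
    abort_msi("coords must have columns x and y")
  coords$x <- as.integer(coords$x)
  coords$y <- as.integer(coords$y)
  if (anyDuplicated(coords[c("x", "y")]))
    abort_msi("duplicate pixel coordinates", class = "msidiscrim_dup_coords")
  ord <- order(coords$y, coords$x)

  common <- !is.null(mz_axis)
  if (common) {
    mz_axis <- as.numeric(mz_axis)
    if (length(mz_axis) > 1 && any(diff(mz_axis) <= 0))
      abort_msi("mz_axis must be strictly increasing")
    if (min(mz_axis) < mass_range[1] - 1e-9 || max(mz_axis) > mass_range[2] + 1e-9)
      abort_msi("mz_axis outside mass_range")
    intensities <- as.matrix(intensities)
    if (nrow(intensities) != nrow(coords))
      abort_msi("intensities row count must equal coords row count")
    if (ncol(intensities) != length(mz_axis))
      abort_msi("intensities column count must equal mz_axis length")
    if (anyNA(intensities) || any(intensities < 0))
      abort_msi("intensities must be nonnegative and finite",
                class = "msidiscrim_negative_intensity")
    intensities <- intensities[ord, , drop = FALSE]
    structure(list(mz_axis = mz_axis, intensities = intensities,
                   coords = coords[ord, , drop = FALSE],
                   specimen_id = specimen_id, domain = domain,
                   mass_range = mass_range, pitch_um = pitch_um),
              class = "spectra_dataset")
  } else {
    if (is.null(mz_list) || is.null(intensity_list))
      abort_msi("either mz_axis/intensities or mz_list/intensity_list required")
    if (length(mz_list) != nrow(coords) || length(intensity_list) != nrow(coords))
      abort_msi("per-pixel spectra count must equal coords row count")
    for (i in seq_along(mz_list)) {
      m <- mz_list[[i]]
      if (length(m) > 1 && any(diff(m) <= 0))
        abort_msi("pixel ", i, ": m/z values must be strictly increasing")
      if (anyNA(intensity_list[[i]]) || any(intensity_list[[i]] < 0))
        abort_msi("pixel ", i, ": negative or missing intensity",
                  class = "msidiscrim_negative_intensity")
      if (length(m) != length(intensity_list[[i]]))
        abort_msi("pixel ", i, ": m/z and intensity lengths differ")
    }
    structure(list(mz_list = mz_list[ord], intensity_list = intensity_list[ord],
                   coords = coords[ord, , drop = FALSE],
                   specimen_id = specimen_id, domain = domain,
                   mass_range = mass_range, pitch_um = pitch_um),
              class = "spectra_dataset")
  }
}

#' @rdname spectra_dataset
#' @param x A `spectra_dataset`.
#' @export
is_common_grid <- function(x) {
  stopifnot(inherits(x, "spectra_dataset"))
  !is.null(x$mz_axis)
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat("<spectra_dataset> ", x$specimen_id, " [", x$domain, "]\n", sep = "")
  cat("  pixels:    ", n_pixels(x), "\n", sep = "")
  if (is_common_grid(x)) {
    cat("  m/z grid:  ", length(x$mz_axis), " bins, ",
        format(min(x$mz_axis)), "-", format(max(x$mz_axis)), " Da\n", sep = "")
  } else {
    cat("  m/z axes:  heterogeneous (resample() to get a common grid)\n")
  }
  cat("  raster:    ", x$pitch_um, " um pitch\n", sep = "")
  invisible(x)
}

#' Number of pixels in a dataset
#' @param x A `spectra_dataset`.
#' @export
n_pixels <- function(x) nrow(x$coords)

# total ion current per pixel (common grid only)
pixel_tic <- function(x) {
  stopifnot(is_common_grid(x))
  rowSums(x$intensities)
}

#' Per-pixel region-of-interest labels
#'
#' Labels are one of `"cancer"`, `"epithelium"`, `"unassigned"`, one per
#' dataset pixel, in the dataset's row-major pixel order.
#'
#' @param labels Character or factor vector of labels.
#' @return An object of class `roi_mask` (a factor with fixed levels).
#' @export
roi_mask <- function(labels) {
  lv <- c("cancer", "epithelium", "unassigned")
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), lv)
  if (length(bad))
    abort_msi("unknown ROI label(s): ", paste(bad, collapse = ", "))
  structure(factor(labels, levels = lv), class = c("roi_mask", "factor"))
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> ", length(x), " pixels: ", sep = "")
  tb <- table(unclass(x))
  cat(paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# both comparison groups must be present for comparative stages
check_two_groups <- function(mask) {
  tb <- table(mask)
  if (tb[["cancer"]] < 1 || tb[["epithelium"]] < 1)
    abort_msi("mask must contain at least one cancer and one epithelium pixel")
  invisible(mask)
}

#' Candidate masses for component annotation
#'
#' @param id Unique record identifiers.
#' @param mass Positive masses in Da. For `kind = "peptide"` these are
#'   observed singly protonated (MH+) masses; for `kind = "lipid"` they are
#'   neutral monoisotopic masses (adducts are generated at matching time).
#' @param kind `"peptide"` or `"lipid"` per record.
#' @param class_label Optional lipid class (e.g. phosphatidylcholine).
#' @return A `candidate_mass_list` data frame.
#' @export
candidate_mass_list <- function(id, mass, kind, class_label = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) abort_msi("candidate ids must be unique")
  mass <- as.numeric(mass)
  if (anyNA(mass) || any(mass <= 0)) abort_msi("candidate masses must be > 0")
  kind <- as.character(kind)
  if (!all(kind %in% c("peptide", "lipid")))
    abort_msi("kind must be 'peptide' or 'lipid'")
  structure(data.frame(id = id, mass = mass, kind = kind,
                       class_label = as.character(class_label),
                       stringsAsFactors = FALSE),
            class = c("candidate_mass_list", "data.frame"))
}

#' Component-by-pixel abundance table
#'
#' The quantified "molecular components": one row per surviving mixture
#' component (labelled by its centre m/z), one column per retained pixel.
#'
#' @param component_ids Numeric component centre m/z values (row labels).
#' @param abundances Component x pixel numeric matrix (finite, >= 0 up to
#'   numerical noise from quantification).
#' @param domain `"peptide"` or `"lipid"`.
#' @param coords Optional pixel coordinates (for image rendering).
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(component_ids, abundances, domain = "peptide",
                          coords = NULL) {
  abundances <- as.matrix(abundances)
  if (length(component_ids) != nrow(abundances))
    abort_msi("component_ids length must equal abundance row count")
  if (anyNA(abundances) || any(!is.finite(abundances)))
    abort_msi("abundances must be finite")
  if (!is.null(coords) && nrow(coords) != ncol(abundances))
    abort_msi("coords row count must equal pixel count")
  structure(list(component_ids = as.numeric(component_ids),
                 abundances = abundances, domain = domain, coords = coords),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> [", x$domain, "] ", nrow(x$abundances),
      " components x ", ncol(x$abundances), " pixels\n", sep = "")
  invisible(x)
}
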