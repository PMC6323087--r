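#' Read a spectra dataset
#'
#' Two on-disk representations are supported: a tab-separated text dialect
#' (one block per pixel: an `x<TAB>y` header line followed by
#' `mz<TAB>intensity` lines, blocks separated by blank lines, metadata in
#' leading `#key value` comments) and a minimal continuous-mode imzML
#' (XML descriptor plus `.ibd` binary, see [save_dataset()]).
#'
#' Per-pixel m/z axes may differ in a text-table file; such datasets must be
#' passed through [resample()] before any downstream stage.
#'
#' @param path File path (`.imzML` or text table).
#' @param format `"auto"` (by extension), `"text_table"` or `"imzml"`.
#' @return A [spectra_dataset()].
#' @export
load_dataset <- function(path, format = c("auto", "text_table", "imzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort_msi("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "text_table"
  if (format == "imzml") read_imzml(path) else read_text_table(path)
}

#' Write a spectra dataset
#'
#' @param dataset A [spectra_dataset()] (common grid required for imzML).
#' @param path Output path; `.imzML` selects imzML (a sibling `.ibd` binary
#'   file is written next to it), anything else the text dialect.
#' @param format As in [load_dataset()].
#' @return `path`, invisibly.
#' @export
save_dataset <- function(dataset, path, format = c("auto", "text_table", "imzml")) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.imzml$", path, ignore.case = TRUE)) "imzml" else "text_table"
  if (format == "imzml") write_imzml(dataset, path) else write_text_table(dataset, path)
  invisible(path)
}

write_text_table <- function(dataset, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "#msidiscrim spectra v1",
    paste0("#specimen\t", dataset$specimen_id),
    paste0("#domain\t", dataset$domain),
    paste0("#mass_range\t", fmt_full(dataset$mass_range[1]), "\t",
           fmt_full(dataset$mass_range[2])),
    paste0("#pitch_um\t", fmt_full(dataset$pitch_um))), con)
  common <- is_common_grid(dataset)
  for (i in seq_len(n_pixels(dataset))) {
    writeLines(paste0(dataset$coords$x[i], "\t", dataset$coords$y[i]), con)
    if (common) {
      mz <- dataset$mz_axis
      it <- dataset$intensities[i, ]
    } else {
      mz <- dataset$mz_list[[i]]
      it <- dataset$intensity_list[[i]]
    }
    writeLines(paste0(fmt_full(mz), "\t", fmt_full(it)), con)
    writeLines("", con)
  }
}

read_text_table <- function(path) {
  lines <- readLines(path)
  meta <- list(specimen = "specimen", domain = "peptide",
               mass_range = NULL, pitch_um = 100)
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "#")) {
    f <- strsplit(sub("^#", "", lines[i]), "\t", fixed = TRUE)[[1]]
    if (f[1] == "specimen") meta$specimen <- f[2]
    if (f[1] == "domain") meta$domain <- f[2]
    if (f[1] == "mass_range") meta$mass_range <- as.numeric(f[2:3])
    if (f[1] == "pitch_um") meta$pitch_um <- as.numeric(f[2])
    i <- i + 1L
  }
  body <- if (i <= length(lines)) lines[i:length(lines)] else character(0)
  nz <- nzchar(trimws(body))
  if (!any(nz)) abort_msi("no pixels in file", class = "msidiscrim_parse_error")
  # blocks = maximal runs of nonblank lines; the first line of each block
  # is the "x<TAB>y" pixel header
  starts <- nz & !c(FALSE, nz[-length(nz)])
  block_of <- cumsum(starts)[nz]
  line_no <- which(nz) + i - 1L          # original line numbers
  sp <- strsplit(body[nz], "\t", fixed = TRUE)
  bad <- which(lengths(sp) != 2L)
  if (length(bad))
    abort_msi("line ", line_no[bad[1]],
              ": expected two tab-separated fields",
              class = "msidiscrim_parse_error")
  m <- matrix(unlist(sp), ncol = 2L, byrow = TRUE)
  v1 <- suppressWarnings(as.numeric(m[, 1]))
  v2 <- suppressWarnings(as.numeric(m[, 2]))
  nav <- which(is.na(v1) | is.na(v2))
  if (length(nav))
    abort_msi("line ", line_no[nav[1]], " (pixel ", block_of[nav[1]],
              "): malformed m/z-intensity pair",
              class = "msidiscrim_parse_error")
  is_hdr <- starts[nz]
  hdr_idx <- which(is_hdr)
  xs <- as.integer(round(v1[hdr_idx])); ys <- as.integer(round(v2[hdr_idx]))
  if (any(abs(v1[hdr_idx] - xs) > 1e-9) || any(abs(v2[hdr_idx] - ys) > 1e-9))
    abort_msi("line ", line_no[hdr_idx[1]], ": malformed pixel header",
              class = "msidiscrim_parse_error")
  neg <- which(v2 < 0 & !is_hdr)
  if (length(neg))
    abort_msi("line ", line_no[neg[1]], " (pixel ", block_of[neg[1]],
              "): negative intensity",
              class = "msidiscrim_negative_intensity")
  mz_list <- split(v1[!is_hdr], block_of[!is_hdr])
  int_list <- split(v2[!is_hdr], block_of[!is_hdr])
  if (length(mz_list) != length(xs))
    abort_msi("pixel block without data lines",
              class = "msidiscrim_parse_error")
  names(mz_list) <- names(int_list) <- NULL
  coords <- data.frame(x = xs, y = ys)
  if (is.null(meta$mass_range))
    meta$mass_range <- range(unlist(mz_list))
  # collapse to matrix layout when all axes are identical
  ax <- mz_list[[1]]
  common <- all(vapply(mz_list, function(m)
    length(m) == length(ax) && all(m == ax), logical(1)))
  if (common) {
    spectra_dataset(mz_axis = ax,
                    intensities = do.call(rbind, int_list),
                    coords = coords, specimen_id = meta$specimen,
                    domain = meta$domain, mass_range = meta$mass_range,
                    pitch_um = meta$pitch_um)
  } else {
    spectra_dataset(mz_list = mz_list, intensity_list = int_list,
                    coords = coords, specimen_id = meta$specimen,
                    domain = meta$domain, mass_range = meta$mass_range,
                    pitch_um = meta$pitch_um)
  }
}

# ---- minimal continuous-mode imzML -----------------------------------------
# Covers exactly the subset this package writes: one shared float64 m/z array
# plus one float64 intensity array per pixel, offsets/lengths in cvParam
# attributes, 16-byte UUID at the head of the .ibd file. Vendor files using
# other encodings are out of scope.

ibd_path <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

write_imzml <- function(dataset, path) {
  if (!is_common_grid(dataset))
    abort_msi("imzML export requires a common m/z grid; resample() first")
  n <- n_pixels(dataset)
  nbin <- length(dataset$mz_axis)
  uuid <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  bin <- file(ibd_path(path), open = "wb")
  writeBin(uuid, bin)
  writeBin(as.numeric(dataset$mz_axis), bin, size = 8, endian = "little")
  for (i in seq_len(n))
    writeBin(as.numeric(dataset$intensities[i, ]), bin, size = 8,
             endian = "little")
  close(bin)
  mz_off <- 16
  int_off0 <- 16 + 8 * nbin
  spectra <- vapply(seq_len(n), function(i) paste0(
    '<spectrum index="', i - 1L, '">',
    '<scan x="', dataset$coords$x[i], '" y="', dataset$coords$y[i], '"/>',
    '<mzArray offset="', mz_off, '" length="', nbin, '"/>',
    '<intensityArray offset="', int_off0 + (i - 1) * 8 * nbin,
    '" length="', nbin, '"/>',
    '</spectrum>'), character(1))
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<fileDescription><cvParam accession="IMS:1000030" name="continuous"/>',
    '<cvParam accession="IMS:1000080" name="universally unique identifier" value="',
    paste(sprintf("%02x", as.integer(uuid)), collapse = ""), '"/></fileDescription>\n',
    '<referenceableParamGroupList>',
    '<msidiscrim specimen="', dataset$specimen_id,
    '" domain="', dataset$domain,
    '" massLow="', fmt_full(dataset$mass_range[1]),
    '" massHigh="', fmt_full(dataset$mass_range[2]),
    '" pitch="', fmt_full(dataset$pitch_um), '"/>',
    '</referenceableParamGroupList>\n',
    '<run><spectrumList count="', n, '">\n',
    paste(spectra, collapse = "\n"),
    '\n</spectrumList></run>\n</mzML>\n')
  writeLines(xml, path, sep = "")
}

read_imzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  meta <- xml2::xml_find_first(doc, ".//msidiscrim")
  sp <- xml2::xml_find_all(doc, ".//spectrum")
  if (!length(sp)) abort_msi("no spectra in imzML", class = "msidiscrim_parse_error")
  bin <- file(ibd_path(path), open = "rb")
  on.exit(close(bin))
  readBin(bin, "raw", 16)  # uuid
  xs <- ys <- integer(length(sp))
  ints <- NULL; mz <- NULL
  for (i in seq_along(sp)) {
    sc <- xml2::xml_find_first(sp[[i]], "./scan")
    xs[i] <- as.integer(xml2::xml_attr(sc, "x"))
    ys[i] <- as.integer(xml2::xml_attr(sc, "y"))
    ma <- xml2::xml_find_first(sp[[i]], "./mzArray")
    ia <- xml2::xml_find_first(sp[[i]], "./intensityArray")
    if (is.null(mz)) {
      seek(bin, as.numeric(xml2::xml_attr(ma, "offset")))
      mz <- readBin(bin, "double", as.integer(xml2::xml_attr(ma, "length")),
                    size = 8, endian = "little")
      ints <- matrix(0, length(sp), length(mz))
    }
    seek(bin, as.numeric(xml2::xml_attr(ia, "offset")))
    ints[i, ] <- readBin(bin, "double", as.integer(xml2::xml_attr(ia, "length")),
                         size = 8, endian = "little")
  }
  spectra_dataset(
    mz_axis = mz, intensities = ints, coords = data.frame(x = xs, y = ys),
    specimen_id = if (!is.na(xml2::xml_attr(meta, "specimen")))
      xml2::xml_attr(meta, "specimen") else "specimen",
    domain = xml2::xml_attr(meta, "domain"),
    mass_range = c(as.numeric(xml2::xml_attr(meta, "massLow")),
                   as.numeric(xml2::xml_attr(meta, "massHigh"))),
    pitch_um = as.numeric(xml2::xml_attr(meta, "pitch")))
}

# ---- feature tables ---------------------------------------------------------

#' Write / read a feature table
#'
#' Tab-separated text: first two columns are the pixel raster coordinates,
#' remaining columns one per component, named by centre m/z. Values are
#' written with 17 significant digits so a reload reproduces them exactly.
#'
#' @param table A [feature_table()].
#' @param path Output/input path.
#' @return `save_feature_table()` returns `path` invisibly;
#'   `load_feature_table()` returns a [feature_table()].
#' @export
save_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$abundances) == 0L || ncol(table$abundances) == 0L)
    abort_msi("feature table is empty")
  coords <- table$coords
  if (is.null(coords))
    coords <- data.frame(x = seq_len(ncol(table$abundances)) - 1L, y = 0L)
  hdr <- paste(c("x", "y", fmt_full(table$component_ids)), collapse = "\t")
  body <- apply(cbind(coords$x, coords$y, t(table$abundances)), 1, function(r)
    paste(c(as.character(as.integer(r[1])), as.character(as.integer(r[2])),
            fmt_full(r[-(1:2)])), collapse = "\t"))
  writeLines(c(paste0("#domain\t", table$domain), hdr, body), path)
  invisible(path)
}

#' @rdname save_feature_table
#' @export
load_feature_table <- function(path) {
  lines <- readLines(path)
  domain <- "peptide"
  if (startsWith(lines[1], "#domain")) {
    domain <- strsplit(lines[1], "\t")[[1]][2]
    lines <- lines[-1]
  }
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  ids <- as.numeric(hdr[-(1:2)])
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  m <- t(vapply(rows, function(f) as.numeric(f), numeric(length(hdr))))
  feature_table(component_ids = ids, abundances = t(m[, -(1:2), drop = FALSE]),
                domain = domain,
                coords = data.frame(x = as.integer(m[, 1]), y = as.integer(m[, 2])))
}

# ---- ROI masks --------------------------------------------------------------

#' Write / read a per-pixel ROI mask
#'
#' TSV with columns `x`, `y`, `label`. On load, dataset pixels absent from
#' the file become `"unassigned"`; the mask may not reference pixels the
#' dataset does not have.
#'
#' @param mask A [roi_mask()].
#' @param coords Pixel coordinates matching the mask.
#' @param path File path.
#' @param dataset The [spectra_dataset()] the mask refers to.
#' @return `load_roi_mask()` returns a [roi_mask()] aligned with the
#'   dataset's pixel order.
#' @export
save_roi_mask <- function(mask, coords, path) {
  stopifnot(inherits(mask, "roi_mask"), nrow(coords) == length(mask))
  writeLines(c("x\ty\tlabel",
               paste(coords$x, coords$y, as.character(mask), sep = "\t")), path)
  invisible(path)
}

#' @rdname save_roi_mask
#' @export
load_roi_mask <- function(path, dataset) {
  stopifnot(inherits(dataset, "spectra_dataset"))
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lv <- c("cancer", "epithelium", "unassigned")
  bad <- setdiff(unique(tb$label), lv)
  if (length(bad))
    abort_msi("unknown ROI label(s): ", paste(bad, collapse = ", "))
  key_ds <- paste(dataset$coords$x, dataset$coords$y)
  key_mk <- paste(tb$x, tb$y)
  if (!all(key_mk %in% key_ds))
    abort_msi("mask references coordinates absent from the dataset")
  labels <- rep("unassigned", n_pixels(dataset))
  labels[match(key_mk, key_ds)] <- tb$label
  out <- roi_mask(labels)
  tbc <- table(unclass(out))
  msi_log("ROI labels: ", paste(names(tbc), tbc, sep = "=", collapse = ", "))
  out
}

# ---- candidate mass lists ---------------------------------------------------

#' Read a candidate-mass list for annotation
#'
#' TSV with columns `id`, `mass`, `kind` (`peptide`/`lipid`) and optional
#' `class` (lipid class label).
#'
#' @param path File path.
#' @return A [candidate_mass_list()].
#' @export
load_candidate_masses <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  candidate_mass_list(id = tb$id, mass = tb$mass, kind = tb$kind,
                      class_label = if ("class" %in% names(tb)) tb$class
                                    else NA_character_)
}
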