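#' An ordered stack of B-scans for one eye
#'
#' The unit of pair sampling: an ordered list of grayscale 2D intensity
#' arrays in `[0, 1]`, all of one size, with a clinically determined central
#' (foveal) slice and the acquisition slice spacing.
#'
#' @param eye_id opaque eye identifier.
#' @param slices list of numeric matrices in `[0, 1]`, identical dimensions.
#' @param central 1-based index of the central (foveal) slice. The CSV
#'   manifest schema stores the same quantity 0-based as
#'   `central_slice_index`; conversion happens at the file boundary only.
#' @param slice_spacing_um distance between adjacent slices (micrometers).
#' @param pixel_size_um `(axial, lateral)` pixel size at the retina
#'   (micrometers); the Spectralis export default is `c(3.87, 11.38)`.
#'
#' @return An object of class `bscan_volume`.
#' @export
bscan_volume <- function(eye_id, slices, central,
                         slice_spacing_um = 243,
                         pixel_size_um = c(3.87, 11.38)) {
  if (!is.list(slices) || length(slices) < 1L)
    stop_config("slices must be a non-empty list of matrices")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_format("all slices must share one height x width")
  rng <- range(vapply(slices, range, numeric(2)))
  if (rng[1] < 0 || rng[2] > 1)
    stop_domain("slice intensities must lie in [0, 1]")
  central <- as.integer(central)
  if (central < 1L || central > length(slices))
    stop_config("central slice index out of range")
  structure(list(eye_id = as.character(eye_id), slices = slices,
                 central = central,
                 slice_spacing_um = slice_spacing_um,
                 pixel_size_um = pixel_size_um),
            class = "bscan_volume")
}

#' @export
print.bscan_volume <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<bscan_volume %s: %d slices of %dx%d, central #%d, spacing %g um>\n",
              x$eye_id, length(x$slices), d[1], d[2], x$central,
              x$slice_spacing_um))
  invisible(x)
}

#' Number of slices in a volume
#' @param volume a [bscan_volume()].
#' @return Integer slice count.
#' @export
n_slices <- function(volume) length(volume$slices)

#' Extract the central (foveal) B-scan of a volume
#' @param volume a [bscan_volume()].
#' @return A numeric matrix.
#' @export
central_slice <- function(volume) volume$slices[[volume$central]]

# the up-to-three foveal slices used for supervised fine-tuning
training_slices <- function(volume, max_slices = 3L) {
  n <- n_slices(volume)
  k <- min(max_slices, n)
  half <- (k - 1L) %/% 2L
  lo <- max(1L, min(volume$central - half, n - k + 1L))
  seq(lo, length.out = k)
}

#' Read a B-scan volume from a single- or multi-page grayscale TIFF
#'
#' Integer pixel types are rescaled to `[0, 1]` by dividing by the dtype
#' maximum; TIFF page order is preserved as slice order. Color pages are
#' rejected rather than silently converted, since a luminance conversion
#' could distort intensities.
#'
#' @param path TIFF file path.
#' @param central 1-based central slice index (from the manifest, which is
#'   authoritative; filenames are never parsed).
#' @param slice_spacing_um slice spacing in micrometers.
#' @param eye_id identifier to attach (defaults to the file stem).
#' @param pixel_size_um `(axial, lateral)` micrometers.
#' @return A [bscan_volume()].
#' @export
read_volume <- function(path, central = 1, slice_spacing_um = 243,
                        eye_id = NULL,
                        pixel_size_um = c(3.87, 11.38)) {
  if (!file.exists(path)) stop_format("cannot read TIFF: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop_format("unreadable TIFF ", path,
                                                    ": ", conditionMessage(e)))
  for (i in seq_along(pages)) {
    d <- dim(pages[[i]])
    if (length(d) == 3L) {
      if (d[3] == 1L) pages[[i]] <- pages[[i]][, , 1]
      else stop_format("page ", i, " of ", path,
                       " is a color image; only grayscale is supported")
    }
    if (!identical(dim(pages[[i]]), dim(pages[[1]])))
      stop_format("page ", i, " of ", path,
                  " has inconsistent shape")
  }
  bscan_volume(eye_id = eye_id %||% sub("\\.tiff?$", "", basename(path)),
               slices = pages, central = central,
               slice_spacing_um = slice_spacing_um,
               pixel_size_um = pixel_size_um)
}

#' Write a B-scan volume as a multi-page grayscale TIFF
#'
#' Lossless up to quantization at the chosen bit depth: the round-trip
#' per-pixel error is at most `1 / (2^bit_depth - 1)`.
#'
#' @param volume a [bscan_volume()].
#' @param path output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bit_depth = 8) {
  if (!bit_depth %in% c(8, 16))
    stop_config("bit_depth must be 8 or 16")
  ok <- tryCatch({
    tiff::writeTIFF(volume$slices, path, bits.per.sample = bit_depth)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_format("cannot write TIFF: ", path)
  invisible(path)
}

manifest_columns <- c("eye_id", "patient_id", "laterality", "diagnosis",
                      "age", "sex", "preop_vision", "n_slices",
                      "central_slice_index", "slice_spacing_um", "path")

#' Write a dataset manifest as CSV
#'
#' Schema: `eye_id, patient_id, laterality, diagnosis, age, sex,
#' preop_vision, n_slices, central_slice_index, slice_spacing_um, path`,
#' with `central_slice_index` 0-based. Fields round-trip exactly through
#' [read_manifest()].
#'
#' @param manifest a manifest `data.frame`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  missing_cols <- setdiff(manifest_columns, names(manifest))
  if (length(missing_cols))
    stop_config("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  write.csv(manifest[, manifest_columns], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a dataset manifest CSV
#' @param path CSV path (schema of [write_manifest()]).
#' @return A manifest `data.frame`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_format("cannot read manifest: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(eye_id = "character", patient_id = "character",
                               laterality = "character", diagnosis = "character",
                               sex = "character", path = "character",
                               age = "numeric", preop_vision = "numeric",
                               slice_spacing_um = "numeric",
                               n_slices = "integer",
                               central_slice_index = "integer"))
  missing_cols <- setdiff(manifest_columns, names(m))
  if (length(missing_cols))
    stop_format("manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  m
}

#' Write a cohort (volumes + manifest) to a dataset directory
#'
#' One multi-page grayscale TIFF per eye plus `manifest.csv`; the manifest
#' `path` column holds paths relative to the directory.
#'
#' @param cohort list with `volumes` and `manifest` (as from
#'   [generate_cohort()]).
#' @param dir output directory (created if needed).
#' @param bit_depth 8 or 16.
#' @return The manifest with populated `path` column, invisibly.
#' @export
write_cohort <- function(cohort, dir, bit_depth = 8) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort$manifest
  for (i in seq_len(nrow(manifest))) {
    rel <- paste0(manifest$eye_id[i], ".tiff")
    write_volume(cohort$volumes[[manifest$eye_id[i]]],
                 file.path(dir, rel), bit_depth = bit_depth)
    manifest$path[i] <- rel
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Load all volumes referenced by a manifest
#' @param manifest a manifest `data.frame` with populated `path`.
#' @param root directory the `path` column is relative to.
#' @return Named list of [bscan_volume()] keyed by eye id.
#' @export
read_cohort <- function(manifest, root) {
  vols <- lapply(seq_len(nrow(manifest)), function(i) {
    read_volume(file.path(root, manifest$path[i]),
                central = manifest$central_slice_index[i] + 1L,
                slice_spacing_um = manifest$slice_spacing_um[i],
                eye_id = manifest$eye_id[i])
  })
  setNames(vols, manifest$eye_id)
}

#' Validate a dataset against its manifest
#'
#' Checks for missing files, page-count and shape mismatches, central-index
#' violations, duplicate eye ids, and patients with more than two eyes.
#' Problems are report rows, not errors; an empty report means the dataset
#' is usable.
#'
#' @param manifest a manifest `data.frame`.
#' @param root dataset directory.
#' @return A `data.frame` of class `rascl_validation` with columns
#'   `eye_id`, `check`, `message` (zero rows if clean).
#' @export
validate_dataset <- function(manifest, root) {
  entries <- list()
  note <- function(eye_id, check, message) {
    entries[[length(entries) + 1L]] <<- data.frame(
      eye_id = eye_id, check = check, message = message,
      stringsAsFactors = FALSE)
  }
  dup <- manifest$eye_id[duplicated(manifest$eye_id)]
  for (id in unique(dup)) note(id, "duplicate_eye_id", "eye_id appears more than once")
  tab <- table(manifest$patient_id)
  for (pid in names(tab)[tab > 2])
    note(pid, "patient_excess_eyes",
         sprintf("patient maps to %d eyes (max 2)", tab[[pid]]))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$eye_id[i]
    ci <- manifest$central_slice_index[i]
    if (is.na(ci) || ci < 0 || ci >= manifest$n_slices[i])
      note(id, "central_index",
           sprintf("central_slice_index %s outside [0, %d)", ci,
                   manifest$n_slices[i]))
    p <- manifest$path[i]
    if (is.na(p) || !file.exists(file.path(root, p))) {
      note(id, "missing_file", sprintf("file not found: %s", p))
      next
    }
    vol <- tryCatch(read_volume(file.path(root, p)), error = function(e) e)
    if (inherits(vol, "error")) {
      note(id, "unreadable", conditionMessage(vol))
    } else if (n_slices(vol) != manifest$n_slices[i]) {
      note(id, "n_slices_mismatch",
           sprintf("manifest says %d slices, file has %d",
                   manifest$n_slices[i], n_slices(vol)))
    }
  }
  report <- if (length(entries)) do.call(rbind, entries) else
    data.frame(eye_id = character(), check = character(),
               message = character(), stringsAsFactors = FALSE)
  class(report) <- c("rascl_validation", "data.frame")
  report
}

#' @export
print.rascl_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("dataset OK: no problems found\n")
  else {
    cat(nrow(x), "problem(s) found:\n")
    print.data.frame(x, ...)
  }
  invisible(x)
}
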