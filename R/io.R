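sidecar_path <- function(path) paste0(path, ".json")

#' Write a voxel stack as a multi-page TIFF with a JSON sidecar
#'
#' One z-slice per TIFF page, 32-bit float, intensities normalized to `[0, 1]`
#' by a scale recorded in the sidecar. The sidecar (`<path>.json`) carries the
#' physical voxel spacing, origin, channel label and intensity scale that the
#' TIFF itself cannot represent portably.
#'
#' @param stack A [voxel_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "voxel_stack"))
  arr <- stack$intensities
  scale <- max(arr, 1)
  pages <- lapply(seq_len(dim(arr)[3]),
                  function(k) t(arr[, , k]) / scale)  # page rows = y
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  meta <- list(spacing_um = stack$spacing_um, origin_um = stack$origin_um,
               channel_label = stack$channel_label, intensity_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a voxel stack from a multi-page TIFF with a JSON sidecar
#'
#' @param path TIFF path written by [write_stack()] (or any multi-page TIFF
#'   accompanied by a `<path>.json` sidecar with `spacing_um`).
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("no spacing metadata: expected a JSON sidecar at ", sc,
         " with at least `spacing_um`")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$spacing_um))
    stop("sidecar ", sc, " lacks `spacing_um`")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("expected a 3D stack (multi-page TIFF); ", path,
         " holds a single 2D plane")
  dims <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  arr <- array(0, dim = dims)
  for (k in seq_along(pages)) arr[, , k] <- t(pages[[k]])
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  voxel_stack(arr * scale, spacing_um = meta$spacing_um,
              channel_label = if (is.null(meta$channel_label)) NA_character_
                              else meta$channel_label,
              origin_um = if (is.null(meta$origin_um)) c(0, 0, 0)
                          else meta$origin_um)
}

#' Write per-position pairwise distances as CSV
#'
#' Columns `position, d_AWA_ASE, d_AWA_AFD, d_AFD_ASE` at full double
#' precision, so downstream analysis (binning, classification, statistics)
#' can run from the spreadsheet alone without re-tracing. Deleting leading or
#' trailing rows of this file is equivalent to [trim_trace()]-style end
#' correction.
#'
#' @param sections A `cross_sections` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(sections, path) {
  stopifnot(all(c("position", PAIR_NAMES) %in% names(sections)))
  df <- data.frame(position = sections$position)
  for (cn in PAIR_NAMES) df[[cn]] <- sprintf("%.17g", sections[[cn]])
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a pairwise-distance CSV back into cross-sections
#'
#' Width and middle-dendrite calls are recomputed from the three distances
#' (they are functions of the distances alone). Malformed rows are reported
#' with their line number.
#'
#' @param path CSV path written by [write_distance_csv()].
#' @return A `cross_sections` data.frame (empty for a header-only file).
#' @export
read_distance_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  need <- c("position", PAIR_NAMES)
  if (!all(need %in% header))
    stop("malformed header in ", path, ": expected columns ",
         paste(need, collapse = ", "))
  if (length(lines) == 1L) {
    empty <- data.frame(position = integer(0), d_AWA_ASE = numeric(0),
                        d_AWA_AFD = numeric(0), d_AFD_ASE = numeric(0))
    return(sections_from_distances(empty))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))) {
    vals <- suppressWarnings(as.numeric(df[i, need]))
    if (anyNA(vals))
      stop("malformed row at line ", i + 1L, " of ", path)
  }
  for (cn in need) df[[cn]] <- as.numeric(df[[cn]])
  sections_from_distances(df)
}

#' Write/read a dendrite trace as CSV
#'
#' Columns `x_um, y_um, z_um`, one row per point, full double precision.
#'
#' @param trace A [dendrite_trace].
#' @param path CSV path.
#' @return `path` invisibly (write); a [dendrite_trace] (read).
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "dendrite_trace"))
  df <- as.data.frame(apply(trace$points, 2, sprintf, fmt = "%.17g"))
  if (nrow(trace$points) == 1L) df <- as.data.frame(t(df))
  names(df) <- c("x_um", "y_um", "z_um")
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param label,source Metadata attached to the trace on read.
#' @export
read_trace_csv <- function(path, label = NA_character_, source = "imported") {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "y_um", "z_um") %in% names(df)))
    stop("malformed trace CSV ", path, ": expected columns x_um, y_um, z_um")
  dendrite_trace(as.matrix(df[, c("x_um", "y_um", "z_um")]), label = label,
                 source = source)
}

#' Write ground truth as JSON
#'
#' Trace coordinates (um), planned middle labels, defasciculation flags and
#' bin assignments of a synthetic bundle.
#'
#' @param truth A [generate_bundle_traces()] result.
#' @param path Output JSON path.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "bundle_truth"))
  obj <- list(
    traces = lapply(truth$traces, function(t)
      list(label = t$label, points = unname(t$points))),
    middle_labels = truth$middle_labels,
    defasc_flags = truth$defasc_flags,
    bins = truth$bins)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
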