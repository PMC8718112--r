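#' Two-channel image stack
#'
#' Container for a registered two-channel fluorescence Z-stack: a cytoplasmic
#' fill channel (`gfp`) used for segmentation and a receptor-label channel
#' (`a594`) in which intensities are measured. Arrays are indexed
#' `[slice, row, col]` (0.5 um axial spacing and ~0.08 um/px in the typical
#' two-photon acquisition this models). Intensities are stored as doubles in
#' arbitrary units (AU) regardless of on-disk bit depth.
#'
#' @param gfp,a594 3-D numeric arrays `[slice, row, col]` of identical shape,
#'   all values finite and >= 0. A matrix is accepted for a single slice.
#' @param pixel_size_um physical pixel size in micrometres (> 0).
#' @param slice_spacing_um axial spacing between optical slices (> 0).
#' @param cell_id,condition free-text identifiers carried into reports.
#' @return An object of class `two_channel_stack`.
#' @examples
#' st <- two_channel_stack(array(1, c(2, 8, 8)), array(2, c(2, 8, 8)))
#' dim(st$gfp)
#' @export
two_channel_stack <- function(gfp, a594, pixel_size_um = 0.08,
                              slice_spacing_um = 0.5,
                              cell_id = "cell", condition = "") {
  as_planes <- function(x) {
    if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
    if (!is.array(x) || length(dim(x)) != 3L)
      stop("channel must be a 3-D array [slice, row, col] or a matrix")
    storage.mode(x) <- "double"
    x
  }
  gfp <- as_planes(gfp); a594 <- as_planes(a594)
  if (!identical(dim(gfp), dim(a594)))
    stop("gfp and a594 must have identical dimensions")
  if (dim(gfp)[1L] < 1L) stop("stack needs at least one slice")
  if (anyNA(gfp) || anyNA(a594) || any(!is.finite(gfp)) || any(!is.finite(a594)))
    stop("intensities must be finite")
  if (min(gfp) < 0 || min(a594) < 0) stop("intensities must be >= 0")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  if (!is.numeric(slice_spacing_um) || slice_spacing_um <= 0)
    stop("slice_spacing_um must be > 0")
  structure(
    list(gfp = gfp, a594 = a594,
         pixel_size_um = as.numeric(pixel_size_um),
         slice_spacing_um = as.numeric(slice_spacing_um),
         cell_id = as.character(cell_id), condition = as.character(condition)),
    class = "two_channel_stack")
}

#' @export
print.two_channel_stack <- function(x, ...) {
  d <- dim(x$gfp)
  cat(sprintf(
    "two_channel_stack '%s'%s: %d slice(s) of %d x %d px (%.3g um/px, %.3g um spacing)\n",
    x$cell_id, if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
    d[1L], d[2L], d[3L], x$pixel_size_um, x$slice_spacing_um))
  invisible(x)
}

n_slices <- function(stack) dim(stack$gfp)[1L]

#' Analysis configuration
#'
#' Bundle of the tunable parameters shared by the image and spike pipelines.
#'
#' @param blur_sigma Gaussian smoothing width for segmentation, in pixels.
#' @param erosion_px inward erosion width defining the cytoplasm region, in
#'   pixels (integer; 8 px at 0.08 um/px is a ~0.6 um band).
#' @param n_slices_analyzed number of consecutive optical slices analyzed.
#' @param rng_seed seed for the (measurement-irrelevant) random contour break.
#' @param spike_threshold_sd spike detection threshold in multiples of the
#'   robust (MAD-based) trace noise SD.
#' @param bin_seconds bin width for firing-rate time courses, in seconds.
#' @return A list of class `analysis_config`.
#' @examples
#' analysis_config(blur_sigma = 2)$blur_sigma
#' @export
analysis_config <- function(blur_sigma = 1, erosion_px = 8L,
                            n_slices_analyzed = 10L, rng_seed = 1L,
                            spike_threshold_sd = 4, bin_seconds = 15) {
  stopifnot(blur_sigma > 0, erosion_px >= 1, erosion_px == round(erosion_px),
            n_slices_analyzed >= 1, spike_threshold_sd > 0, bin_seconds > 0)
  structure(list(blur_sigma = blur_sigma, erosion_px = as.integer(erosion_px),
                 n_slices_analyzed = as.integer(n_slices_analyzed),
                 rng_seed = as.integer(rng_seed),
                 spike_threshold_sd = spike_threshold_sd,
                 bin_seconds = bin_seconds),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML key-value file
#'
#' Unknown keys are rejected so that typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file with any subset of the [analysis_config()] fields.
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' Split an interleaved page sequence into two channels
#'
#' Two-photon acquisitions interleave the channels plane by plane; plane `i`
#' of each channel comes from page `2i-1` or `2i` (1-based) according to the
#' declared order.
#'
#' @param pages list of numeric matrices (TIFF pages), even count.
#' @param first which channel the first page belongs to.
#' @return `list(gfp = <list of planes>, a594 = <list of planes>)`.
#' @examples
#' p <- lapply(1:4, function(i) matrix(i, 2, 2))
#' deinterleave(p)$gfp[[2]][1, 1]  # page 3
#' @export
deinterleave <- function(pages, first = c("gfp", "a594")) {
  first <- match.arg(first)
  if (!is.list(pages) || length(pages) == 0L) stop("pages must be a non-empty list")
  if (length(pages) %% 2L != 0L)
    stop("malformed file: odd page count (", length(pages),
         ") cannot be deinterleaved into two channels")
  odd <- pages[seq(1L, length(pages), by = 2L)]
  even <- pages[seq(2L, length(pages), by = 2L)]
  if (first == "gfp") list(gfp = odd, a594 = even) else list(gfp = even, a594 = odd)
}

.planes_to_array <- function(planes) {
  d <- dim(planes[[1L]])
  arr <- array(0, c(length(planes), d[1L], d[2L]))
  for (i in seq_along(planes)) {
    if (!identical(dim(planes[[i]]), d)) stop("pages differ in size")
    arr[i, , ] <- planes[[i]]
  }
  arr
}

#' Read a two-channel stack from a multi-page TIFF
#'
#' Supports the interleaved layout (channels alternating page by page) and a
#' stacked layout (all pages of one channel followed by all pages of the
#' other). Pixel values are read as stored (no rescaling). Acquisition
#' metadata (pixel size, slice spacing, cell id, condition) is taken from a
#' JSON sidecar `<path>.json` when present; explicit arguments override it.
#'
#' @param path multi-page TIFF file.
#' @param layout page layout, `"interleaved"` or `"stacked"`.
#' @param channel_order which channel comes first. Channel identity is always
#'   declared by the caller; wavelength tags are not interpreted.
#' @param pixel_size_um,slice_spacing_um,cell_id,condition overrides for the
#'   sidecar metadata.
#' @return A [two_channel_stack()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, layout = c("interleaved", "stacked"),
                       channel_order = c("gfp", "a594"),
                       pixel_size_um = NULL, slice_spacing_um = NULL,
                       cell_id = NULL, condition = NULL) {
  layout <- match.arg(layout)
  first <- match.arg(channel_order)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) %% 2L != 0L)
    stop("malformed file: odd page count in two-channel TIFF '", path, "'")
  meta <- list()
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pick <- function(override, key, default) {
    if (!is.null(override)) override
    else if (!is.null(meta[[key]])) meta[[key]]
    else default
  }
  px <- pick(pixel_size_um, "pixel_size_um", NULL)
  if (is.null(px))
    stop("pixel size unknown: no sidecar metadata and no pixel_size_um override")
  if (layout == "interleaved") {
    ch <- deinterleave(pages, first = first)
  } else {
    half <- length(pages) / 2L
    a <- pages[seq_len(half)]; b <- pages[half + seq_len(half)]
    ch <- if (first == "gfp") list(gfp = a, a594 = b) else list(gfp = b, a594 = a)
  }
  two_channel_stack(.planes_to_array(ch$gfp), .planes_to_array(ch$a594),
                    pixel_size_um = px,
                    slice_spacing_um = pick(slice_spacing_um, "slice_spacing_um", 0.5),
                    cell_id = pick(cell_id, "cell_id", "cell"),
                    condition = pick(condition, "condition", ""))
}

#' Write a two-channel stack as an interleaved multi-page TIFF
#'
#' Pages alternate gfp/a594 (gfp first). Samples are written at 16-bit
#' integer depth, so intensities must be integer-valued in `[0, 65535]`;
#' integer-valued stacks round-trip through [read_stack()] bit for bit.
#' Metadata is written to a JSON sidecar `<path>.json`.
#'
#' @param stack a [two_channel_stack()].
#' @param path output file.
#' @param sidecar write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "two_channel_stack"))
  vals <- c(stack$gfp, stack$a594)
  if (max(vals) > 65535 || any(vals != round(vals)))
    stop("16-bit TIFF output requires integer intensities in [0, 65535]")
  ns <- n_slices(stack)
  pages <- vector("list", 2L * ns)
  for (i in seq_len(ns)) {
    pages[[2L * i - 1L]] <- stack$gfp[i, , ] / 65535
    pages[[2L * i]] <- stack$a594[i, , ] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (sidecar) {
    jsonlite::write_json(
      list(pixel_size_um = stack$pixel_size_um,
           slice_spacing_um = stack$slice_spacing_um,
           cell_id = stack$cell_id, condition = stack$condition),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
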