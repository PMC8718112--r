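#' Erosion-defined cytoplasm region of a mask slice
#'
#' Morphological erosion of the cell mask with a Euclidean disk structuring
#' element of radius `erosion_px`: a pixel is retained when no background
#' pixel (image borders count as background) lies within `erosion_px` of it.
#' The excluded annulus approximates the membrane-plus-optical-blur band
#' (8 px at 0.08 um/px is ~0.6 um), so the region is the neuron's
#' cytoplasmic portion, strictly inside the mask.
#'
#' @param mask_slice logical (or 0/1) matrix.
#' @param erosion_px erosion radius in pixels (integer >= 1).
#' @return Logical matrix, a subset of `mask_slice`.
#' @export
cytoplasm_region <- function(mask_slice, erosion_px) {
  if (length(erosion_px) != 1L || erosion_px < 1 || erosion_px != round(erosion_px))
    stop("erosion_px must be a single integer >= 1")
  bw <- mask_slice > 0
  nr <- nrow(bw); nc <- ncol(bw)
  pad <- matrix(0, nr + 2L, nc + 2L)         # borders are background
  pad[2:(nr + 1L), 2:(nc + 1L)] <- bw
  d <- EBImage::distmap(pad)[2:(nr + 1L), 2:(nc + 1L)]
  region <- d > erosion_px
  if (!any(region))
    stop("degenerate geometry: erosion by ", erosion_px,
         " px empties the mask (cell too thin)")
  region
}

#' Physical width of the excluded membrane band
#'
#' @param erosion_px erosion radius in pixels.
#' @param pixel_size_um pixel size in micrometres.
#' @return Band width in micrometres (`erosion_px * pixel_size_um`).
#' @examples
#' erosion_band_um(8, 0.08)  # ~0.6 um
#' @export
erosion_band_um <- function(erosion_px, pixel_size_um) {
  stopifnot(erosion_px > 0, pixel_size_um > 0)
  erosion_px * pixel_size_um
}

#' Pooled cytoplasmic fluorescence of a neuron (F-cyt)
#'
#' Per-slice mean of the label channel over the cytoplasm region, then an
#' equal-weight mean across slices.
#'
#' @param region_masks logical 3-D array `[slice, row, col]` of cytoplasm
#'   regions, or a list of matrices named/ordered by slice.
#' @param a594_stack numeric 3-D array of the label channel (or a
#'   [two_channel_stack()], whose `a594` is used).
#' @param slices integer indices of slices to pool (default: slices whose
#'   region is non-empty must be all of them; see Details). For a list input
#'   the default is all elements.
#' @return `f_cyt` scalar with attribute `per_slice_means`.
#' @export
f_cyt <- function(region_masks, a594_stack, slices = NULL) {
  if (inherits(a594_stack, "two_channel_stack")) a594_stack <- a594_stack$a594
  if (is.list(region_masks)) {
    if (is.null(slices)) slices <- seq_along(region_masks)
    regions <- region_masks
  } else {
    if (is.null(slices)) slices <- seq_len(dim(region_masks)[1L])
    regions <- lapply(slices, function(s) region_masks[s, , ])
  }
  means <- vapply(seq_along(slices), function(i) {
    reg <- regions[[i]] > 0
    if (!any(reg)) stop("empty cytoplasm region in slice ", slices[i])
    mean(a594_stack[slices[i], , ][reg])
  }, numeric(1L))
  names(means) <- slices
  structure(mean(means), per_slice_means = means)
}

#' Membrane/cytoplasm compartment fractions
#'
#' @param f_memb,f_cyt compartment mean intensities (AU, >= 0, not both 0).
#' @return Object of class `compartment_measurement` with `f_memb`, `f_cyt`,
#'   `memb_fraction = f_memb / (f_memb + f_cyt)` and
#'   `cyt_fraction = f_cyt / (f_memb + f_cyt)`; the fractions sum to 1
#'   exactly.
#' @examples
#' compartment_fractions(150, 50)$memb_fraction  # 0.75
#' @export
compartment_fractions <- function(f_memb, f_cyt) {
  f_memb <- as.numeric(f_memb); f_cyt <- as.numeric(f_cyt)
  stopifnot(length(f_memb) == 1L, length(f_cyt) == 1L,
            f_memb >= 0, f_cyt >= 0)
  tot <- f_memb + f_cyt
  if (tot <= 0) stop("f_memb + f_cyt must be > 0")
  memb <- f_memb / tot
  structure(list(f_memb = f_memb, f_cyt = f_cyt,
                 memb_fraction = memb, cyt_fraction = 1 - memb),
            class = "compartment_measurement")
}

#' @export
print.compartment_measurement <- function(x, ...) {
  cat(sprintf("F-memb = %.2f, F-cyt = %.2f; fractions %.3f / %.3f\n",
              x$f_memb, x$f_cyt, x$memb_fraction, x$cyt_fraction))
  invisible(x)
}

#' Full compartment measurement of one stack
#'
#' Convenience wrapper running the whole single-timepoint pipeline:
#' segmentation, membrane contour mean (F-memb), erosion-defined cytoplasm
#' mean (F-cyt), and the compartment fractions. Raw means are used (no
#' background subtraction), matching the measurement protocol this
#' implements.
#'
#' @inheritParams build_cell_mask
#' @return A `compartment_measurement` with extra fields `membrane`
#'   (the [pooled_f_memb()] result), `f_cyt_per_slice`, and `mask`.
#' @export
measure_compartments <- function(stack, config = analysis_config(),
                                 exclude_slices = integer()) {
  mask <- build_cell_mask(stack, config, exclude_slices)
  memb <- pooled_f_memb(stack, mask, config)
  regions <- lapply(mask$analyzed, function(s)
    cytoplasm_region(mask$masks[s, , ], config$erosion_px))
  fc <- f_cyt(regions, stack, slices = mask$analyzed)
  out <- compartment_fractions(memb$f_memb, as.numeric(fc))
  out$membrane <- memb
  out$f_cyt_per_slice <- attr(fc, "per_slice_means")
  out$mask <- mask
  out
}

#' Before/after internalization ratios (F/F0)
#'
#' F is a compartment's fluorescence fraction after treatment and F0 the
#' same fraction before. Because fractions, not raw intensities, are
#' compared, both ratios are invariant to uniform acquisition-gain changes
#' between the two timepoints. A cytoplasmic ratio above 1 indicates
#' receptor internalization.
#'
#' @param before,after `compartment_measurement`s of the same cell.
#' @return Object of class `internalization_result` with `f_over_f0_cyt`,
#'   `f_over_f0_memb`, `before`, `after`.
#' @export
internalization_ratios <- function(before, after) {
  stopifnot(inherits(before, "compartment_measurement"),
            inherits(after, "compartment_measurement"))
  if (before$cyt_fraction == 0 || before$memb_fraction == 0)
    stop("zero baseline compartment fraction: F/F0 undefined")
  structure(list(
    f_over_f0_cyt = after$cyt_fraction / before$cyt_fraction,
    f_over_f0_memb = after$memb_fraction / before$memb_fraction,
    before = before, after = after),
    class = "internalization_result")
}

#' @export
print.internalization_result <- function(x, ...) {
  cat(sprintf("F/F0 cytoplasm = %.3f, membrane = %.3f\n",
              x$f_over_f0_cyt, x$f_over_f0_memb))
  invisible(x)
}
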