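#' Convert a mask slice to an ordered one-pixel membrane contour
#'
#' The outer boundary of the mask (foreground pixels with an edge-adjacent
#' background pixel, image borders counting as background) is ordered by
#' Moore-neighbour boundary tracing, clockwise, giving a closed 8-connected
#' ring one pixel wide. Following the
#' original macro, which converts a closed selection to a line, a random
#' break position is introduced: the closed ring is stored as an open
#' sequence starting at a seeded random position. The break is irrelevant to
#' any mean computed along the path; it is kept for fidelity and
#' reproducibility.
#'
#' @param mask_slice logical (or 0/1) matrix: one connected component
#'   without holes.
#' @param rng_seed seed for the break position; `NULL` leaves the break at
#'   the tracing start.
#' @return An object of class `membrane_contour`: `path` (n x 2 integer
#'   matrix of row, col), `length_px`, `break_index` (position in the
#'   original ring where the open sequence starts).
#' @export
mask_to_contour <- function(mask_slice, rng_seed = NULL) {
  bw <- mask_slice > 0
  if (!any(bw)) stop("empty mask")
  if (!identical(bw, .largest_component8(bw)))
    stop("contract violation: mask is not a single connected component")
  if (!identical(bw, .fill_holes(bw)))
    stop("contract violation: mask has internal holes")
  nr <- nrow(bw); nc <- ncol(bw)
  fg <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc && bw[r, c]
  if (sum(bw) == 1L) {
    rc <- which(bw, arr.ind = TRUE)
    path <- matrix(as.integer(rc), 1L, 2L)
  } else {
    # clockwise neighbour order (row grows downward): N NE E SE S SW W NW
    dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
    dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
    start <- which(bw, arr.ind = TRUE)
    start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
    start <- as.integer(start)
    cur <- start
    back <- 7L                               # pretend we entered from the west
    path <- matrix(0L, 0L, 2L)
    limit <- 8L * sum(bw) + 8L
    repeat {
      path <- rbind(path, cur)
      moved <- FALSE
      for (k in seq_len(8L)) {
        d <- ((back + k - 1L) %% 8L) + 1L    # scan clockwise after backtrack
        r2 <- cur[1L] + dr[d]; c2 <- cur[2L] + dc[d]
        if (fg(r2, c2)) {
          back <- ((d + 4L - 1L) %% 8L) + 1L # direction pointing back to cur
          cur <- c(r2, c2)
          moved <- TRUE
          break
        }
      }
      if (!moved || identical(cur, start) || nrow(path) > limit) break
    }
    # collapse revisits at one-pixel-wide necks (rare; blobs visit each once)
    path <- unique(path)
  }
  n <- nrow(path)
  brk <- 1L
  if (!is.null(rng_seed) && n > 1L) {
    brk <- withr_seed(rng_seed, sample.int(n, 1L))
    path <- path[c(brk:n, seq_len(brk - 1L)), , drop = FALSE]
  }
  dimnames(path) <- list(NULL, c("row", "col"))
  structure(list(path = path, length_px = n, break_index = brk),
            class = "membrane_contour")
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Mean intensity along a membrane contour
#'
#' Arithmetic mean of the label-channel intensities at the contour pixels,
#' each boundary pixel weighted once. The break position has no effect.
#'
#' @param contour a [mask_to_contour()] result.
#' @param a594_slice numeric matrix of the label channel for the same slice.
#' @return Mean intensity (AU).
#' @export
membrane_mean <- function(contour, a594_slice) {
  stopifnot(inherits(contour, "membrane_contour"))
  p <- contour$path
  if (nrow(p) == 0L) stop("empty contour")
  if (max(p[, 1L]) > nrow(a594_slice) || max(p[, 2L]) > ncol(a594_slice))
    stop("contour coordinates outside slice bounds")
  mean(a594_slice[p])
}

#' Pooled membrane fluorescence of a neuron (F-memb)
#'
#' Per analyzed slice, the mask edge is traced and the label channel is
#' averaged along it; slice means are then pooled with equal weights into
#' the neuron's mean membrane fluorescence F-memb (a mean of slice means,
#' not a pixel-count-weighted mean).
#'
#' @param stack a [two_channel_stack()].
#' @param cell_mask a [build_cell_mask()] result for the same stack.
#' @param config an [analysis_config()] (`rng_seed` seeds the contour breaks).
#' @param exclude_slices additional slices to drop at this stage.
#' @return An object of class `membrane_measurement`: `per_slice_means`
#'   (named by slice), `f_memb`, `n_slices`, and the `contours` used.
#' @export
pooled_f_memb <- function(stack, cell_mask, config = analysis_config(),
                          exclude_slices = integer()) {
  stopifnot(inherits(stack, "two_channel_stack"), inherits(cell_mask, "cell_mask"))
  slices <- setdiff(cell_mask$analyzed, as.integer(exclude_slices))
  if (length(slices) == 0L) stop("all slices excluded")
  contours <- lapply(slices, function(s)
    mask_to_contour(cell_mask$masks[s, , ], rng_seed = config$rng_seed + s))
  means <- vapply(seq_along(slices), function(i)
    membrane_mean(contours[[i]], stack$a594[slices[i], , ]), numeric(1L))
  names(means) <- slices
  structure(list(per_slice_means = means, f_memb = mean(means),
                 n_slices = length(slices), contours = contours),
            class = "membrane_measurement")
}

#' @export
print.membrane_measurement <- function(x, ...) {
  cat(sprintf("F-memb = %.2f AU over %d slice(s)\n", x$f_memb, x$n_slices))
  invisible(x)
}

#' Group mean as a percentage of a control mean
#'
#' Reported to the nearest integer percent, as in summary comparisons of
#' labeling conditions against label-alone controls.
#'
#' @param group_mean,control_mean group and control means (`control_mean`
#'   must be > 0). `group_mean` may be a vector.
#' @return Integer percent(s): `round(100 * group_mean / control_mean)`.
#' @examples
#' percent_of_control(115.5, 170.7)  # 68
#' @export
percent_of_control <- function(group_mean, control_mean) {
  if (!is.numeric(control_mean) || length(control_mean) != 1L || control_mean <= 0)
    stop("control_mean must be a single positive value")
  round(100 * group_mean / control_mean)
}

#' Export a contour as an ordered coordinate table
#'
#' @param contour a [mask_to_contour()] result.
#' @param path CSV output file; `NULL` returns the data frame only.
#' @return Data frame with `order`, `row`, `col`.
#' @export
contour_to_csv <- function(contour, path = NULL) {
  stopifnot(inherits(contour, "membrane_contour"))
  df <- data.frame(order = seq_len(nrow(contour$path)),
                   row = contour$path[, 1L], col = contour$path[, 2L])
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
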