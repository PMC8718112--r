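#' Gaussian smoothing of a single image plane
#'
#' Separable convolution with a truncated, renormalized Gaussian kernel
#' (half-width `ceiling(4 * sigma)` pixels). Borders are handled by symmetric
#' reflection, which avoids the edge darkening that circular or zero padding
#' would introduce next to the membrane. A constant plane is returned
#' unchanged and total intensity mass is conserved in the interior.
#'
#' @param plane numeric matrix of finite intensities.
#' @param sigma kernel standard deviation in pixels (> 0).
#' @return A matrix of the same dimensions.
#' @examples
#' p <- matrix(0, 9, 9); p[5, 5] <- 1
#' sum(gaussian_smooth(p, 1))  # mass conserved: 1
#' @export
gaussian_smooth <- function(plane, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single value > 0")
  if (!is.matrix(plane) || any(!is.finite(plane)))
    stop("plane must be a numeric matrix of finite values")
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  reflect_idx <- function(n) {
    if (r > n) stop("plane too small for the smoothing kernel")
    c(seq(r, 1L), seq_len(n), seq(n, n - r + 1L))
  }
  pass <- function(x) { # smooth along rows (dimension 1)
    xp <- x[reflect_idx(nrow(x)), , drop = FALSE]
    out <- matrix(0, nrow(x), ncol(x))
    for (k in 0:(2L * r))
      out <- out + w[k + 1L] * xp[(1L + k):(nrow(x) + k), , drop = FALSE]
    out
  }
  t(pass(t(pass(plane))))
}

# g(p) = standardized third moment of a two-level distribution with mass p
# below; strictly decreasing in p on (0, 1).
.bilevel_skew <- function(p) (1 - 2 * p) / sqrt(p * (1 - p))

#' Moment-preserving (Tsai) threshold
#'
#' Selects the bilevel quantization of the intensity distribution that
#' preserves its first three sample moments: the closed-form solution gives
#' the below-threshold mass fraction `p0`, and the returned threshold is the
#' sample value whose attainable fraction best matches `p0` in the
#' third-moment sense (the first two moments are matched exactly by the
#' representative levels for any candidate). Pixels strictly greater than the
#' threshold are foreground.
#'
#' @param plane numeric matrix or vector with at least two distinct values.
#' @return The threshold, one of the sample values.
#' @examples
#' moments_threshold(c(rep(0, 50), rep(255, 50)))  # 0: foreground = the 255s
#' @export
moments_threshold <- function(plane) {
  vals <- as.numeric(plane)
  if (anyNA(vals) || any(!is.finite(vals))) stop("intensities must be finite")
  u <- sort(unique(vals))
  if (length(u) < 2L)
    stop("degenerate histogram: plane has fewer than two distinct values")
  m1 <- mean(vals); m2 <- mean(vals^2); m3 <- mean(vals^3)
  v <- m2 - m1^2
  # representative levels z0 < z1 solving the three moment equations
  c0 <- (m1 * m3 - m2^2) / v
  c1 <- (m1 * m2 - m3) / v
  disc <- sqrt(c1^2 - 4 * c0)
  z0 <- (-c1 - disc) / 2
  z1 <- (-c1 + disc) / 2
  p0 <- (z1 - m1) / (z1 - z0)
  target <- .bilevel_skew(p0)
  cand <- u[-length(u)]                      # foreground must be nonempty
  cum <- cumsum(tabulate(match(vals, u))) / length(vals)
  p <- cum[-length(u)]
  cand[which.min(abs(.bilevel_skew(p) - target))]
}

# flood-fill style hole filling via EBImage; input/output logical matrix
.fill_holes <- function(bw) {
  EBImage::fillHull(bw * 1L) > 0L
}

# largest 8-connected foreground component (EBImage::bwlabel is 4-connected;
# labels touching diagonally are merged by union-find)
.largest_component8 <- function(bw) {
  lab <- EBImage::bwlabel(bw * 1L)
  nlab <- max(lab)
  if (nlab == 0L) return(matrix(FALSE, nrow(bw), ncol(bw)))
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    keep <- a > 0L & b > 0L & a != b
    unique(cbind(a[keep], b[keep]))
  }
  prs <- rbind(
    diag_pairs(lab[-nr, -nc], lab[-1, -1]),
    diag_pairs(lab[-nr, -1], lab[-1, -nc]))
  if (nrow(prs)) for (k in seq_len(nrow(prs))) union(prs[k, 1L], prs[k, 2L])
  roots <- vapply(seq_len(nlab), find, integer(1L))
  merged <- matrix(0L, nr, nc)
  merged[lab > 0L] <- roots[lab[lab > 0L]]
  sizes <- tabulate(merged[merged > 0L], nbins = nlab)
  keep <- which.max(sizes)                   # ties: smallest label, fixed rule
  merged == keep
}

#' Per-slice binary cell mask
#'
#' Segments one neuron from the cytoplasmic fill channel, slice by slice:
#' Gaussian smoothing ([gaussian_smooth()]), moment-preserving thresholding
#' ([moments_threshold()]), hole filling, and retention of the largest
#' 8-connected foreground component (so neurites of other labeled cells do
#' not corrupt the boundary). Thresholds are recorded per slice.
#'
#' @param stack a [two_channel_stack()].
#' @param config an [analysis_config()]; `blur_sigma` and
#'   `n_slices_analyzed` are used.
#' @param exclude_slices integer indices of slices to drop from analysis
#'   (e.g. slices with truncated masks along dendritic branching planes,
#'   judged by eye as in the original protocol).
#' @return An object of class `cell_mask`: logical array `masks` of the
#'   stack's shape (FALSE outside analyzed slices), numeric `thresholds`
#'   (NA for excluded slices), integer `analyzed`, and `source = "gfp"`.
#' @export
build_cell_mask <- function(stack, config = analysis_config(),
                            exclude_slices = integer()) {
  stopifnot(inherits(stack, "two_channel_stack"),
            inherits(config, "analysis_config"))
  ns <- n_slices(stack)
  analyzed <- setdiff(seq_len(min(ns, config$n_slices_analyzed)),
                      as.integer(exclude_slices))
  if (length(analyzed) == 0L) stop("no slices left to analyze")
  masks <- array(FALSE, dim(stack$gfp))
  thresholds <- rep(NA_real_, ns)
  for (s in analyzed) {
    sm <- gaussian_smooth(stack$gfp[s, , ], config$blur_sigma)
    thr <- tryCatch(moments_threshold(sm), error = function(e)
      stop("segmentation failure in slice ", s, ": ", conditionMessage(e)))
    bw <- .largest_component8(.fill_holes(sm > thr))
    if (!any(bw))
      stop("segmentation failure in slice ", s, ": empty foreground")
    masks[s, , ] <- bw
    thresholds[s] <- thr
  }
  structure(list(masks = masks, thresholds = thresholds,
                 analyzed = analyzed, source = "gfp"),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("cell_mask: %d analyzed slice(s), %d x %d px\n",
              length(x$analyzed), dim(x$masks)[2L], dim(x$masks)[3L]))
  invisible(x)
}

#' Export a cell mask as a multi-page TIFF (0/255)
#'
#' @param mask a `cell_mask` from [build_cell_mask()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  pages <- lapply(seq_len(dim(mask$masks)[1L]),
                  function(s) (mask$masks[s, , ] * 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
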