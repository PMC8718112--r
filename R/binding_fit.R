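#' On-cell western binding plate
#'
#' Validates a long-format plate table for saturation-labeling analysis.
#' Each well carries the two detection signals: 784 nm (labeled receptor)
#' and 658 nm (total receptor), plus condition flags.
#'
#' @param wells data frame with columns `concentration_nM`, `signal_784`,
#'   `signal_658`, `blocked` (antagonist co-incubation, defines nonspecific
#'   labeling), `no_primary` (background well) and optionally
#'   `replicate_id`.
#' @return The validated data frame with class `binding_plate`.
#' @export
binding_plate <- function(wells) {
  need <- c("concentration_nM", "signal_784", "signal_658", "blocked", "no_primary")
  missing_cols <- setdiff(need, names(wells))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"replicate_id" %in% names(wells)) wells$replicate_id <- seq_len(nrow(wells))
  if (any(wells$concentration_nM < 0)) stop("concentrations must be >= 0")
  if (!any(wells$no_primary)) stop("at least one background (no-primary) well required")
  conc <- unique(wells$concentration_nM[!wells$no_primary & wells$concentration_nM > 0])
  has_both <- vapply(conc, function(cc) {
    sub <- wells[!wells$no_primary & wells$concentration_nM == cc, ]
    any(sub$blocked) && any(!sub$blocked)
  }, logical(1L))
  if (!all(has_both))
    stop("every nonzero concentration needs both blocked and unblocked wells")
  structure(wells, class = c("binding_plate", "data.frame"))
}

#' Read a binding plate from long-format CSV
#'
#' @param path CSV with the [binding_plate()] columns.
#' @return A `binding_plate`.
#' @export
read_binding_plate <- function(path) {
  df <- read.csv(path)
  df$blocked <- as.logical(df$blocked)
  df$no_primary <- as.logical(df$no_primary)
  binding_plate(df)
}

#' Background-subtract and ratio-normalize plate wells
#'
#' The background (mean of the no-primary wells, per wavelength) is
#' subtracted from every signal, and the 784 nm signal of each well is
#' normalized to the 658 nm signal of the same well:
#' `ratio = (s784 - bg784) / (s658 - bg658)`. Wells whose denominator is
#' not positive after subtraction are flagged and excluded from fitting.
#'
#' @param plate a [binding_plate()].
#' @return The plate with columns `ratio` (NA when excluded) and
#'   `excluded`, plus attributes `bg_784` and `bg_658`.
#' @export
normalize_wells <- function(plate) {
  plate <- binding_plate(as.data.frame(plate))
  bg <- plate[plate$no_primary, ]
  bg784 <- mean(bg$signal_784); bg658 <- mean(bg$signal_658)
  num <- plate$signal_784 - bg784
  den <- plate$signal_658 - bg658
  excluded <- plate$no_primary | den <= 0
  plate$ratio <- ifelse(excluded, NA_real_, num / den)
  plate$excluded <- excluded
  n_flag <- sum(excluded & !plate$no_primary)
  if (n_flag)
    warning(n_flag, " well(s) excluded: nonpositive 658 nm signal after ",
            "background subtraction")
  attr(plate, "bg_784") <- bg784
  attr(plate, "bg_658") <- bg658
  plate
}

#' One-site saturation fit with linear nonspecific labeling
#'
#' Models the blocked (antagonist co-incubated) wells as nonspecific
#' labeling, linear through the origin (`ns_slope * L`), and the total
#' (unblocked) wells as `Bmax * L / (Kd + L) + ns_slope * L`. By default the
#' nonspecific slope is estimated first from the blocked wells alone and
#' held fixed while `Bmax` and `Kd` are fit to the total wells by nonlinear
#' least squares (`method = "sequential"`); `method = "shared"` fits all
#' three parameters simultaneously to both curves. Ordinary (unweighted)
#' least squares on the normalized ratios is used throughout. For covalent
#' labeling reagents the apparent Kd is a labeling coefficient, not an
#' equilibrium constant.
#'
#' @param concentrations ligand concentrations (nM), >= 4 distinct nonzero
#'   values; replicates allowed (vectors are aligned elementwise).
#' @param total_ratios normalized ratios of the unblocked wells.
#' @param blocked_ratios normalized ratios of the blocked wells (same
#'   length/order of concentrations; may carry NAs for excluded wells).
#' @param blocked_concentrations concentrations for the blocked wells when
#'   they differ from `concentrations`.
#' @param method `"sequential"` (default) or `"shared"`.
#' @return Object of class `binding_fit`: `kd_nM`, `bmax`, `ns_slope`,
#'   `se` (named standard errors), `fit_covariance` (Kd/Bmax), and
#'   `curve`, a per-concentration table of fitted total, nonspecific and
#'   specific (`total - nonspecific`) values.
#' @examples
#' L <- rep(c(1, 3, 10, 30, 100), 2)
#' fit <- fit_one_site(L, 1 * L / (5 + L) + 0.001 * L, 0.001 * L)
#' fit$kd_nM
#' @export
fit_one_site <- function(concentrations, total_ratios, blocked_ratios,
                         blocked_concentrations = concentrations,
                         method = c("sequential", "shared")) {
  method <- match.arg(method)
  tot <- data.frame(L = concentrations, y = total_ratios)
  blk <- data.frame(L = blocked_concentrations, y = blocked_ratios)
  tot <- tot[stats::complete.cases(tot), ]
  blk <- blk[stats::complete.cases(blk), ]
  if (length(unique(tot$L[tot$L > 0])) < 4L)
    stop("need at least 4 distinct nonzero concentrations")
  # starting values: slope from blocked wells, half-saturation from the
  # specific component
  ns0 <- sum(blk$L * blk$y) / sum(blk$L^2)
  spec0 <- tot$y - ns0 * tot$L
  bmax0 <- max(spec0, 1e-8)
  kd0 <- tryCatch({
    above <- tot$L[spec0 >= bmax0 / 2]
    max(min(above), 1e-3)
  }, error = function(e) median(tot$L[tot$L > 0]))
  if (method == "sequential") {
    ns_fit <- lm(y ~ 0 + L, data = blk)
    ns <- unname(coef(ns_fit)[1L])
    fit <- minpack.lm::nlsLM(
      y ~ bmax * L / (kd + L) + ns * L, data = tot,
      start = list(bmax = bmax0, kd = kd0),
      lower = c(1e-12, 1e-9), control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    kd <- unname(cf["kd"]); bmax <- unname(cf["bmax"])
    vc <- vcov(fit)
    se <- c(kd = sqrt(vc["kd", "kd"]), bmax = sqrt(vc["bmax", "bmax"]),
            ns_slope = suppressWarnings(summary(ns_fit)$coefficients[1L, 2L]))
  } else {
    both <- rbind(cbind(tot, is_total = 1), cbind(blk, is_total = 0))
    fit <- minpack.lm::nlsLM(
      y ~ is_total * bmax * L / (kd + L) + ns * L, data = both,
      start = list(bmax = bmax0, kd = kd0, ns = max(ns0, 1e-12)),
      lower = c(1e-12, 1e-9, 0), control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- coef(fit)
    kd <- unname(cf["kd"]); bmax <- unname(cf["bmax"]); ns <- unname(cf["ns"])
    vc <- vcov(fit)[c("kd", "bmax"), c("kd", "bmax")]
    se <- c(kd = sqrt(vc["kd", "kd"]), bmax = sqrt(vc["bmax", "bmax"]),
            ns_slope = sqrt(vcov(fit)["ns", "ns"]))
  }
  if (!is.finite(kd) || kd <= 0 || bmax <= 0)
    stop("fit did not converge to a valid one-site model")
  if (kd > 10 * max(tot$L))
    warning("Kd estimate (", signif(kd, 3), " nM) far above the tested range")
  Lu <- sort(unique(tot$L))
  curve <- data.frame(concentration_nM = Lu,
                      total = bmax * Lu / (kd + Lu) + ns * Lu,
                      nonspecific = ns * Lu)
  curve$specific <- curve$total - curve$nonspecific
  structure(list(kd_nM = kd, bmax = bmax, ns_slope = ns, se = se,
                 fit_covariance = if (method == "sequential") vcov(fit) else vc,
                 curve = curve, method = method, n_total = nrow(tot),
                 n_blocked = nrow(blk)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf(
    "one-site fit (%s): Kd = %.3g nM (SE %.2g), Bmax = %.3g (SE %.2g), ns = %.3g /nM\n",
    x$method, x$kd_nM, x$se["kd"], x$bmax, x$se["bmax"], x$ns_slope))
  invisible(x)
}

#' Fit a normalized plate in one call
#'
#' Normalizes wells ([normalize_wells()]) and fits [fit_one_site()] on the
#' per-well ratios (wells are normalized individually, then enter the fit
#' as replicate points).
#'
#' @param plate a [binding_plate()].
#' @param ... passed to [fit_one_site()].
#' @return A `binding_fit`.
#' @export
fit_binding_plate <- function(plate, ...) {
  norm <- normalize_wells(plate)
  use <- !norm$excluded
  tot <- norm[use & !norm$blocked, ]
  blk <- norm[use & norm$blocked, ]
  fit_one_site(tot$concentration_nM, tot$ratio, blk$ratio,
               blocked_concentrations = blk$concentration_nM, ...)
}
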