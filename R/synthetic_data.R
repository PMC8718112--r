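# Ground-truth generators for the three pipelines. Every generator returns
# the simulated data together with a machine-readable truth record from
# which all downstream expected outputs follow in closed form, and is
# deterministic under a fixed rng_seed.

# distance-to-background of a padded binary shape (borders = background)
.shape_dist <- function(bw) {
  nr <- nrow(bw); nc <- ncol(bw)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- bw
  EBImage::distmap(pad)[2:(nr + 1L), 2:(nc + 1L)]
}

#' Synthetic two-channel cell stack with known ground truth
#'
#' Renders a convex-ish cell body: a cytoplasmic fill in the segmentation
#' channel and, in the label channel, a bright membrane rim a few pixels
#' wide with a dimmer uniform cytoplasm, optionally with bright cytoplasmic
#' puncta. Internalization is emulated by moving a fraction of the total
#' rim signal into the puncta, conserving summed intensity, so the expected
#' F-memb, F-cyt and compartment fractions are known analytically. An
#' optional Gaussian point-spread blur is applied before noise; additive
#' Gaussian noise (clamped at zero) approximates the PMT regime of
#' two-photon acquisition, and planes are rounded to integer counts.
#'
#' @param shape `"disk"`, `"ellipse"` or `"blobby"` (sinusoidally perturbed
#'   radius).
#' @param size_px image side length; `n_slices` optical slices are rendered
#'   with identical geometry.
#' @param radius_px cell radius in pixels (semi-major axis for ellipses).
#' @param aspect ellipse axis ratio (>= 1); ignored for disks.
#' @param lobes,lobe_amp blobby-shape perturbation count and relative
#'   amplitude.
#' @param rim_width_px membrane rim width (1-3 px typical).
#' @param membrane_intensity rim intensity before internalization (AU).
#' @param cytoplasm_a594_intensity label-channel cytoplasm base (AU).
#' @param gfp_fill_intensity fill-channel intensity over the cell (AU).
#' @param gfp_background,a594_background off-cell levels (AU).
#' @param internalized_fraction share of total rim signal moved into
#'   puncta, in `[0, 1]`.
#' @param puncta_count,puncta_radius_px puncta geometry; when
#'   `internalized_fraction > 0` and `puncta_count == 0`, 10 puncta are
#'   used.
#' @param erosion_px erosion used for the analytic cytoplasm truth (must
#'   match the analysis configuration; default 8).
#' @param psf_sigma optical blur sigma in pixels (0 = none).
#' @param noise_sd additive Gaussian noise SD (AU; 0 = none).
#' @param n_slices slices in the stack.
#' @param pixel_size_um,slice_spacing_um,cell_id,condition stack metadata.
#' @param rng_seed seed for puncta placement and noise.
#' @return `list(stack = two_channel_stack, truth = list(...))`; the truth
#'   record carries the geometry masks (`cell`, `rim`, `cytoplasm`), the
#'   expected `f_memb`, `f_cyt`, `memb_fraction`, `cyt_fraction`, and the
#'   parameters.
#' @export
make_cell_stack <- function(shape = c("disk", "ellipse", "blobby"),
                            size_px = 256, radius_px = 60, aspect = 1.4,
                            lobes = 5, lobe_amp = 0.1,
                            rim_width_px = 3,
                            membrane_intensity = 200,
                            cytoplasm_a594_intensity = 20,
                            gfp_fill_intensity = 150,
                            gfp_background = 10, a594_background = 10,
                            internalized_fraction = 0,
                            puncta_count = 0, puncta_radius_px = 2,
                            erosion_px = 8,
                            psf_sigma = 0, noise_sd = 0,
                            n_slices = 10, pixel_size_um = 0.08,
                            slice_spacing_um = 0.5,
                            cell_id = "phantom", condition = "",
                            rng_seed = 1) {
  shape <- match.arg(shape)
  stopifnot(rim_width_px >= 1, internalized_fraction >= 0,
            internalized_fraction <= 1, membrane_intensity >= 0,
            cytoplasm_a594_intensity >= 0, gfp_fill_intensity >= 0)
  ctr <- (size_px + 1) / 2
  xy <- expand.grid(row = seq_len(size_px), col = seq_len(size_px))
  dx <- xy$col - ctr; dy <- xy$row - ctr
  theta <- atan2(dy, dx)
  rad_at <- switch(shape,
    disk = rep(radius_px, length(theta)),
    ellipse = {
      b <- radius_px / aspect
      radius_px * b / sqrt((b * cos(theta))^2 + (radius_px * sin(theta))^2)
    },
    blobby = {
      phase <- withr_seed(rng_seed, runif(1, 0, 2 * pi))
      radius_px * (1 + lobe_amp * cos(lobes * theta + phase))
    })
  if (max(rad_at) + 1 > min(ctr - 1, size_px - ctr))
    stop("cell rim falls outside the image bounds")
  cell <- matrix(sqrt(dx^2 + dy^2) <= rad_at, size_px, size_px)
  d <- .shape_dist(cell)
  rim <- cell & d <= rim_width_px
  interior <- cell & !rim
  cyt_region <- d > erosion_px
  if (!any(cyt_region)) stop("cell too thin for the requested erosion")

  rim_value <- membrane_intensity * (1 - internalized_fraction)
  moved_total <- membrane_intensity * internalized_fraction * sum(rim)
  if (internalized_fraction > 0 && puncta_count == 0) puncta_count <- 10L

  puncta <- matrix(FALSE, size_px, size_px)
  if (puncta_count > 0) {
    allowed <- d > erosion_px + puncta_radius_px + 1
    if (!any(allowed)) stop("no room for puncta inside the cytoplasm region")
    centers <- withr_seed(rng_seed + 1L, {
      cand <- which(allowed, arr.ind = TRUE)
      picked <- matrix(0L, 0L, 2L)
      guard <- 0L
      while (nrow(picked) < puncta_count && guard < 10000L) {
        guard <- guard + 1L
        p <- cand[sample.int(nrow(cand), 1L), ]
        if (nrow(picked) == 0L ||
            all(sqrt((picked[, 1] - p[1])^2 + (picked[, 2] - p[2])^2) >
                2 * puncta_radius_px + 1))
          picked <- rbind(picked, p)
      }
      if (nrow(picked) < puncta_count)
        stop("could not place ", puncta_count, " non-overlapping puncta")
      picked
    })
    for (k in seq_len(nrow(centers))) {
      dd <- sqrt((xy$row - centers[k, 1])^2 + (xy$col - centers[k, 2])^2)
      puncta <- puncta | matrix(dd <= puncta_radius_px, size_px, size_px)
    }
  }
  puncta_add <- if (any(puncta)) moved_total / sum(puncta) else 0

  gfp0 <- matrix(gfp_background, size_px, size_px)
  gfp0[cell] <- gfp_background + gfp_fill_intensity
  a0 <- matrix(a594_background, size_px, size_px)
  a0[interior] <- cytoplasm_a594_intensity
  a0[rim] <- rim_value
  a0[puncta] <- a0[puncta] + puncta_add
  if (psf_sigma > 0) {
    gfp0 <- gaussian_smooth(gfp0, psf_sigma)
    a0 <- gaussian_smooth(a0, psf_sigma)
  }

  gfp <- array(0, c(n_slices, size_px, size_px))
  a594 <- array(0, c(n_slices, size_px, size_px))
  for (s in seq_len(n_slices)) {
    if (noise_sd > 0) {
      eg <- withr_seed(rng_seed + 100L + s,
                       matrix(rnorm(size_px^2, 0, noise_sd), size_px))
      ea <- withr_seed(rng_seed + 200L + s,
                       matrix(rnorm(size_px^2, 0, noise_sd), size_px))
    } else {
      eg <- ea <- 0
    }
    gfp[s, , ] <- round(pmax(gfp0 + eg, 0))
    a594[s, , ] <- round(pmax(a0 + ea, 0))
  }
  stack <- two_channel_stack(gfp, a594, pixel_size_um = pixel_size_um,
                             slice_spacing_um = slice_spacing_um,
                             cell_id = cell_id, condition = condition)
  f_cyt_true <- cytoplasm_a594_intensity + moved_total / sum(cyt_region)
  fr <- compartment_fractions(rim_value, f_cyt_true)
  truth <- list(cell = cell, rim = rim, cytoplasm = cyt_region,
                puncta = puncta,
                f_memb = rim_value, f_cyt = f_cyt_true,
                memb_fraction = fr$memb_fraction,
                cyt_fraction = fr$cyt_fraction,
                params = list(shape = shape, radius_px = radius_px,
                              rim_width_px = rim_width_px,
                              membrane_intensity = membrane_intensity,
                              internalized_fraction = internalized_fraction,
                              erosion_px = erosion_px,
                              psf_sigma = psf_sigma, noise_sd = noise_sd,
                              rng_seed = rng_seed))
  list(stack = stack, truth = truth)
}

# mean of the inhibition profile i(u) over the window [w1, w2] seconds after
# agonist onset; i(u) = d on [0, u0], then d*(1 - p*(1 - exp(-(u-u0)/tau)))
.mean_inhibition <- function(d, p, tau, u0, w1, w2) {
  stopifnot(w2 > w1)
  seg1 <- max(0, min(w2, u0) - w1)                   # time spent at depth d
  int <- d * seg1
  a <- max(w1, u0); b <- w2
  if (b > a) {
    s1 <- a - u0; s2 <- b - u0
    int <- int + d * (1 - p) * (b - a) +
      d * p * tau * (exp(-s1 / tau) - exp(-s2 / tau))
  }
  int / (w2 - w1)
}

#' Solve generator parameters for target inhibition/desensitization
#'
#' Given target percent inhibition (early window) and percent
#' desensitization (early minus late window), returns the inhibition depth
#' `d` and recovery fraction `p` of the firing phantom's rate model. The
#' depth is held through `plateau_s` (covering the early window), then the
#' inhibition relaxes exponentially toward `d * (1 - p)`. `p > 1` produces
#' rebound firing above baseline; the late-window inhibition then clamps at
#' zero in the measured metric, which the expected values returned here
#' account for.
#'
#' @param target_inhibition,target_desensitization percents in `[0, 100]`.
#' @param tau_s recovery time constant (s).
#' @param plateau_s full-depth hold after onset (s); must cover the early
#'   window.
#' @param early_window_s,late_window_s metric windows (s after onset).
#' @return List with `depth`, `recovery`, and the expected measured
#'   `inhibition`, `inhibition_late`, `desensitization` (clamped as the
#'   metrics clamp).
#' @export
solve_firing_params <- function(target_inhibition, target_desensitization,
                                tau_s = 90, plateau_s = 120,
                                early_window_s = c(60, 120),
                                late_window_s = c(270, 300)) {
  stopifnot(target_inhibition >= 0, target_inhibition <= 100,
            target_desensitization >= 0,
            plateau_s >= early_window_s[2L])
  d <- target_inhibition / 100
  A <- .mean_inhibition(1, 1, tau_s, plateau_s,
                        late_window_s[1L], late_window_s[2L])
  # A = mean of (1 - recovery term); late mean = d - d*p*(1 - A)
  p <- if (target_desensitization == 0 || d == 0) 0 else
    (target_desensitization / 100) / (d * (1 - A))
  early <- 100 * .mean_inhibition(d, p, tau_s, plateau_s,
                                  early_window_s[1L], early_window_s[2L])
  late <- 100 * .mean_inhibition(d, p, tau_s, plateau_s,
                                 late_window_s[1L], late_window_s[2L])
  clamp <- function(x) min(100, max(0, x))
  list(depth = d, recovery = p,
       inhibition = clamp(early), inhibition_late = clamp(late),
       desensitization = clamp(clamp(early) - clamp(late)))
}

#' Synthetic spike experiment with known ground truth
#'
#' Inhomogeneous Poisson spike times under the rate model
#' `r(t) = baseline * (1 - i(t))` with `i(t) = 0` before agonist onset,
#' `i = depth` for `plateau_s` after onset, then exponential relaxation of
#' the inhibition toward `depth * (1 - recovery)` with time constant
#' `tau_s` (desensitization; `recovery > 1` yields rebound firing).
#' Sampling uses thinning, so the times are exact draws from the rate
#' profile. The truth record carries the analytic expected values of the
#' window metrics.
#'
#' @param baseline_rate_hz spontaneous rate (default 1.5 Hz, typical of
#'   striatal cholinergic interneurons).
#' @param baseline_s,agonist_s,washout_s epoch durations (s); agonist onset
#'   is at `baseline_s`.
#' @param depth inhibition depth in `[0, 1]`.
#' @param recovery fraction of the inhibition recovered at steady state
#'   (>= 0; values above 1 give rebound).
#' @param tau_s recovery time constant (s).
#' @param plateau_s full-depth hold after onset (s).
#' @param rng_seed seed.
#' @param cell_id,label metadata.
#' @return `list(experiment = spike_experiment, truth = list(...))`.
#' @export
make_spike_experiment <- function(baseline_rate_hz = 1.5,
                                  baseline_s = 180, agonist_s = 300,
                                  washout_s = 0,
                                  depth = 1, recovery = 0, tau_s = 90,
                                  plateau_s = 120,
                                  rng_seed = 1,
                                  cell_id = "phantom", label = "") {
  stopifnot(baseline_rate_hz >= 0, depth >= 0, depth <= 1, recovery >= 0,
            tau_s > 0, baseline_s >= 60)
  t0 <- baseline_s
  dur <- baseline_s + agonist_s + washout_s
  inhibition_at <- function(t) {
    u <- t - t0
    i <- numeric(length(t))
    on <- u >= 0
    i[on & u <= plateau_s] <- depth
    rec <- on & u > plateau_s
    i[rec] <- depth * (1 - recovery * (1 - exp(-(u[rec] - plateau_s) / tau_s)))
    # washout: treat agonist as present to the end of the record unless a
    # washout epoch is given, in which case inhibition relaxes the same way
    i
  }
  lam_max <- baseline_rate_hz * max(1, 1 - depth * (1 - recovery))
  spikes <- withr_seed(rng_seed, {
    n <- rpois(1L, lam_max * dur)
    tt <- sort(runif(n, 0, dur))
    keep <- runif(n) <= baseline_rate_hz * (1 - inhibition_at(tt)) /
      max(lam_max, .Machine$double.eps)
    tt[keep]
  })
  ex <- spike_experiment(spikes, agonist_onset_s = t0, duration_s = dur,
                         cell_id = cell_id, label = label)
  clamp <- function(x) min(100, max(0, x))
  early <- 100 * .mean_inhibition(depth, recovery, tau_s, plateau_s, 60, 120)
  late <- 100 * .mean_inhibition(depth, recovery, tau_s, plateau_s, 270, 300)
  truth <- list(baseline_rate_hz = baseline_rate_hz, depth = depth,
                recovery = recovery, tau_s = tau_s, plateau_s = plateau_s,
                inhibition = clamp(early), inhibition_late = clamp(late),
                desensitization = clamp(clamp(early) - clamp(late)),
                rng_seed = rng_seed)
  list(experiment = ex, truth = truth)
}

#' Render spike times to a noisy extracellular trace
#'
#' Each spike becomes a biphasic waveform (one-sample-wide lobes are
#' avoided by a smooth kernel) of amplitude `amplitude_sd_units` times the
#' Gaussian noise SD, on zero-mean noise at the given sampling rate.
#'
#' @param spike_times spike times (s).
#' @param duration_s trace duration (s).
#' @param sampling_rate_hz samples per second (default 10 kHz).
#' @param amplitude_sd_units spike peak in noise-SD multiples.
#' @param noise_sd noise SD (AU).
#' @param rng_seed seed.
#' @return Numeric trace vector.
#' @export
make_spike_trace <- function(spike_times, duration_s,
                             sampling_rate_hz = 1e4,
                             amplitude_sd_units = 8, noise_sd = 1,
                             rng_seed = 1) {
  n <- as.integer(round(duration_s * sampling_rate_hz))
  trace <- withr_seed(rng_seed, rnorm(n, 0, noise_sd))
  # biphasic kernel: ~1 ms total
  k <- round(sampling_rate_hz / 1000)
  wave <- c(seq(0, 1, length.out = k + 1L)[-1L],
            seq(1, -0.4, length.out = k + 1L)[-1L],
            seq(-0.4, 0, length.out = k + 1L)[-1L])
  wave <- wave * amplitude_sd_units * noise_sd
  for (t in spike_times) {
    i0 <- as.integer(round(t * sampling_rate_hz)) + 1L
    idx <- i0 + seq_along(wave) - 1L
    ok <- idx >= 1L & idx <= n
    trace[idx[ok]] <- trace[idx[ok]] + wave[ok]
  }
  trace
}

#' Synthetic on-cell western plate with known ground truth
#'
#' Wells follow the one-site + linear model: total ratio
#' `bmax * L / (kd + L) + ns_slope * L`, blocked ratio `ns_slope * L`.
#' Two-wavelength signals are rendered so that per-well normalization
#' recovers the ratios exactly in the noise-free case; multiplicative
#' Gaussian noise (`noise_frac`) perturbs the net signals. Background
#' (no-primary) wells are included.
#'
#' @param kd_nM,bmax,ns_slope true model parameters.
#' @param noise_frac multiplicative noise SD as a fraction of signal.
#' @param concentrations_nM labeling concentrations (the standard design is
#'   `c(0, 1, 3, 10, 30, 100)` nM).
#' @param replicates,blocked_replicates wells per concentration (triplicate
#'   total, duplicate blocked is the typical design).
#' @param n_background no-primary background wells.
#' @param s658_level,bg_784,bg_658 signal scale and backgrounds (AU).
#' @param rng_seed seed.
#' @return A [binding_plate()] with attribute `truth`.
#' @export
make_binding_plate <- function(kd_nM = 5, bmax = 1, ns_slope = 0.001,
                               noise_frac = 0,
                               concentrations_nM = c(0, 1, 3, 10, 30, 100),
                               replicates = 3, blocked_replicates = 2,
                               n_background = 3,
                               s658_level = 900, bg_784 = 100, bg_658 = 100,
                               rng_seed = 1) {
  stopifnot(kd_nM > 0, bmax > 0, ns_slope >= 0, noise_frac >= 0)
  if (all(concentrations_nM == 0))
    stop("degenerate design: all concentrations are zero")
  ratio_total <- function(L) bmax * L / (kd_nM + L) + ns_slope * L
  ratio_blocked <- function(L) ns_slope * L
  rows <- list()
  add <- function(L, blocked, rep_id, ratio) {
    rows[[length(rows) + 1L]] <<- data.frame(
      concentration_nM = L, signal_784 = bg_784 + ratio * s658_level,
      signal_658 = bg_658 + s658_level, blocked = blocked,
      no_primary = FALSE,
      replicate_id = paste0(ifelse(blocked, "blk", "tot"), "_", L, "_", rep_id))
  }
  for (L in concentrations_nM) {
    for (r in seq_len(replicates)) add(L, FALSE, r, ratio_total(L))
    for (r in seq_len(blocked_replicates)) add(L, TRUE, r, ratio_blocked(L))
  }
  for (r in seq_len(n_background)) {
    rows[[length(rows) + 1L]] <- data.frame(
      concentration_nM = 100, signal_784 = bg_784, signal_658 = bg_658,
      blocked = FALSE, no_primary = TRUE,
      replicate_id = paste0("bg_", r))
  }
  df <- do.call(rbind, rows)
  if (noise_frac > 0) {
    df <- withr_seed(rng_seed, {
      net784 <- df$signal_784 - bg_784
      net658 <- df$signal_658 - bg_658
      df$signal_784 <- bg_784 + net784 * (1 + rnorm(nrow(df), 0, noise_frac))
      df$signal_658 <- bg_658 + net658 * (1 + rnorm(nrow(df), 0, noise_frac))
      df
    })
  }
  plate <- binding_plate(df)
  attr(plate, "truth") <- list(kd_nM = kd_nM, bmax = bmax,
                               ns_slope = ns_slope, noise_frac = noise_frac,
                               rng_seed = rng_seed)
  plate
}
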