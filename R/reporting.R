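# Report assembly: per-cell tables, group summaries, and a run manifest so
# every output is reproducible from its inputs and configuration.

.manifest <- function(config, inputs, warnings = character()) {
  list(package_version = as.character(utils::packageVersion("slicequant")),
       config = unclass(config),
       inputs = inputs,
       rng_seed = config$rng_seed,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       warnings = warnings)
}

.group_summary <- function(df, value_col, group_col = "condition") {
  groups <- split(df[[value_col]], df[[group_col]])
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1L)),
    mean = vapply(groups, mean, numeric(1L)),
    sd = vapply(groups, function(x) if (length(x) > 1L) sd(x) else NA_real_,
                numeric(1L)))
  out$sem <- out$sd / sqrt(out$n)
  rownames(out) <- NULL
  out
}

.write_outputs <- function(result, out_dir, stem) {
  if (is.null(out_dir)) return(invisible(result))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(result$report, file.path(out_dir, paste0(stem, "_cells.csv")),
            row.names = FALSE)
  if (!is.null(result$summary))
    write.csv(result$summary, file.path(out_dir, paste0(stem, "_summary.csv")),
              row.names = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, paste0(stem, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Batch membrane-fluorescence quantification
#'
#' Runs segmentation and F-memb measurement over a batch of stacks. Per-cell
#' failures (e.g. segmentation failures) are logged and reported; the run
#' continues. When `control_condition` is given, group summaries gain a
#' percent-of-control column.
#'
#' @param stacks list of [two_channel_stack()] objects, or character paths
#'   read via [read_stack()].
#' @param config an [analysis_config()].
#' @param control_condition condition label serving as the 100% reference.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return List with `report` (one row per analyzed cell: `cell_id`,
#'   `condition`, `f_memb`, `n_slices`), `summary` (group mean, SD, SEM, n,
#'   optional `percent_of_control`), `failures`, `manifest`.
#' @export
run_membrane_quant <- function(stacks, config = analysis_config(),
                               control_condition = NULL, out_dir = NULL) {
  if (length(stacks) == 0L) stop("empty input list")
  if (is.character(stacks)) stacks <- lapply(stacks, read_stack)
  rows <- list(); fails <- list(); warns <- character()
  for (st in stacks) {
    res <- tryCatch({
      mask <- build_cell_mask(st, config)
      mm <- pooled_f_memb(st, mask, config)
      data.frame(cell_id = st$cell_id, condition = st$condition,
                 f_memb = mm$f_memb, n_slices = mm$n_slices)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      fails[[length(fails) + 1L]] <- data.frame(cell_id = st$cell_id,
                                                error = msg)
      warns <- c(warns, paste0(st$cell_id, ": ", msg))
    } else rows[[length(rows) + 1L]] <- res
  }
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), condition = character(),
               f_memb = numeric(), n_slices = integer())
  summary <- if (nrow(report)) .group_summary(report, "f_memb") else NULL
  if (!is.null(summary) && !is.null(control_condition)) {
    if (!control_condition %in% summary$group)
      stop("control condition '", control_condition, "' not present")
    ctrl <- summary$mean[summary$group == control_condition]
    summary$percent_of_control <- percent_of_control(summary$mean, ctrl)
  }
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(cell_id = character(), error = character())
  out <- list(report = report, summary = summary, failures = failures,
              manifest = .manifest(config,
                                   vapply(stacks, function(s) s$cell_id, ""),
                                   warns))
  .write_outputs(out, out_dir, "membrane")
}

#' Batch internalization (F/F0) quantification
#'
#' Pairs before/after stacks by `cell_id`, measures compartments in each,
#' and reports both F/F0 ratios per cell plus per-condition summaries.
#'
#' @param before,after lists of [two_channel_stack()]s; every cell must
#'   appear in both (unmatched ids are an error listing the orphans) with
#'   identically shaped images.
#' @inheritParams run_membrane_quant
#' @return List with `report` (per cell: fractions before/after and the
#'   ratios), `summary` (per condition), `failures`, `manifest`.
#' @export
run_endocytosis <- function(before, after, config = analysis_config(),
                            out_dir = NULL) {
  ids_b <- vapply(before, function(s) s$cell_id, "")
  ids_a <- vapply(after, function(s) s$cell_id, "")
  orphans <- c(setdiff(ids_b, ids_a), setdiff(ids_a, ids_b))
  if (length(orphans))
    stop("unmatched cell_id(s): ", paste(unique(orphans), collapse = ", "))
  names(before) <- ids_b; names(after) <- ids_a
  rows <- list(); fails <- list(); warns <- character()
  for (id in ids_b) {
    res <- tryCatch({
      b <- before[[id]]; a <- after[[id]]
      if (!identical(dim(b$gfp), dim(a$gfp)))
        stop("before/after stacks differ in shape")
      cb <- measure_compartments(b, config)
      ca <- measure_compartments(a, config)
      rat <- internalization_ratios(cb, ca)
      data.frame(cell_id = id, condition = b$condition,
                 f_memb_before = cb$f_memb, f_cyt_before = cb$f_cyt,
                 f_memb_after = ca$f_memb, f_cyt_after = ca$f_cyt,
                 memb_fraction_before = cb$memb_fraction,
                 cyt_fraction_before = cb$cyt_fraction,
                 f_over_f0_cyt = rat$f_over_f0_cyt,
                 f_over_f0_memb = rat$f_over_f0_memb)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      fails[[length(fails) + 1L]] <- data.frame(cell_id = id, error = msg)
      warns <- c(warns, paste0(id, ": ", msg))
    } else rows[[length(rows) + 1L]] <- res
  }
  report <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (!is.null(report)) {
    s1 <- .group_summary(report, "f_over_f0_cyt")
    s2 <- .group_summary(report, "f_over_f0_memb")
    names(s1)[-1] <- paste0("cyt_", names(s1)[-1])
    names(s2)[-1] <- paste0("memb_", names(s2)[-1])
    merge(s1, s2, by = "group")
  } else NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(cell_id = character(), error = character())
  out <- list(report = report, summary = summary, failures = failures,
              manifest = .manifest(config, ids_b, warns))
  .write_outputs(out, out_dir, "endocytosis")
}

#' Batch spike-train metrics
#'
#' Computes baseline rate, percent inhibition and (when the agonist epoch
#' is long enough) percent desensitization for each recording; recordings
#' with missing epochs are skipped with a log entry. Group statistics are
#' mean, SD, SEM and n; inferential statistics are left to the user's
#' statistics environment.
#'
#' @param experiments list of [spike_experiment()]s.
#' @inheritParams run_membrane_quant
#' @return List with `report` (per cell: `baseline_rate_hz`,
#'   `percent_inhibition`, `percent_desensitization`), `summary` (grouped
#'   by the experiments' `label`), `failures`, `manifest`, and `bins` (a
#'   long table of 15-s binned counts for time-course plots).
#' @export
run_spike_metrics <- function(experiments, config = analysis_config(),
                              out_dir = NULL) {
  if (length(experiments) == 0L) stop("empty input list")
  rows <- list(); fails <- list(); warns <- character(); bins <- list()
  for (ex in experiments) {
    res <- tryCatch({
      pi_ <- percent_inhibition(ex)
      pd <- tryCatch(as.numeric(percent_desensitization(ex)),
                     error = function(e) NA_real_)
      data.frame(cell_id = ex$cell_id, label = ex$label,
                 baseline_rate_hz = baseline_rate(ex),
                 percent_inhibition = as.numeric(pi_),
                 percent_desensitization = pd)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      msg <- conditionMessage(res)
      fails[[length(fails) + 1L]] <- data.frame(cell_id = ex$cell_id,
                                                error = msg)
      warns <- c(warns, paste0(ex$cell_id, ": ", msg))
    } else {
      rows[[length(rows) + 1L]] <- res
      b <- bin_rates(ex$spike_times, config$bin_seconds, t_max = ex$duration_s)
      b$cell_id <- ex$cell_id
      bins[[length(bins) + 1L]] <- b
    }
  }
  report <- if (length(rows)) do.call(rbind, rows) else NULL
  summary <- if (!is.null(report))
    .group_summary(report, "percent_inhibition", "label") else NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(cell_id = character(), error = character())
  out <- list(report = report, summary = summary, failures = failures,
              bins = if (length(bins)) do.call(rbind, bins) else NULL,
              manifest = .manifest(
                config, vapply(experiments, function(e) e$cell_id, ""), warns))
  .write_outputs(out, out_dir, "spikes")
}
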