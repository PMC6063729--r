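# Cell bundles are directories: metadata.json plus one long-format CSV per
# protocol (columns time_ms, rep_index, vm_mV). CSV is the normative test
# format; it is plain text and diffable.

stim_to_list <- function(stim) {
  if (is.character(stim)) return(list(kind = "spontaneous"))
  if (inherits(stim, "lso_tone")) return(c(list(kind = "tone"), unclass(stim)))
  if (inherits(stim, "lso_step")) return(c(list(kind = "step"), unclass(stim)))
  stop("unknown stimulus")
}

stim_from_list <- function(x) {
  switch(x$kind,
    spontaneous = "spontaneous",
    tone = tone_stimulus(x$ear, x$frequency,
                         level_ipsi = if (is.null(x$level_ipsi)) NA_real_ else x$level_ipsi,
                         level_contra = if (is.null(x$level_contra)) NA_real_ else x$level_contra,
                         duration = x$duration, onset = x$onset, n_reps = x$n_reps),
    step = current_step(x$amplitude, x$duration, x$onset),
    stop("unknown stimulus kind: ", x$kind))
}

#' Write a cell record to a bundle directory
#'
#' Serializes metadata (cell fields, per-protocol sweep metadata) to
#' `metadata.json` and sample data to one `<protocol>.csv` per protocol in
#' long format (`time_ms, rep_index, vm_mV`). Writing then reading
#' reproduces all metadata exactly and samples to numeric precision.
#'
#' @param cell an `lso_cell`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_cell_bundle <- function(cell, path) {
  stopifnot(inherits(cell, "lso_cell"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    cell_id = cell$cell_id, anatomical_class = cell$anatomical_class,
    CF = cell$CF, BF = cell$BF,
    normalized_position = cell$normalized_position,
    coverage_percent = cell$coverage_percent,
    protocols = lapply(cell$sweeps, function(proto) {
      lapply(proto, function(s) list(
        sampling_rate = s$sampling_rate, t0_offset = s$t0_offset,
        stimulus = stim_to_list(s$stimulus),
        series_resistance = s$series_resistance,
        junction_corrected = s$junction_corrected, n = length(s$samples)))
    }))
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  for (proto in names(cell$sweeps)) {
    sw <- cell$sweeps[[proto]]
    dt <- data.table::rbindlist(lapply(seq_along(sw), function(i) {
      data.table::data.table(time_ms = sweep_times(sw[[i]]), rep_index = i,
                             vm_mV = sw[[i]]$samples)
    }))
    data.table::fwrite(dt, file.path(path, paste0(proto, ".csv")))
  }
  invisible(path)
}

#' Read a cell record from a bundle directory
#'
#' Inverse of [write_cell_bundle()]. Validates the metadata schema, the
#' monotonicity of each repetition's time column, and that all sweeps within
#' a protocol share one sampling rate.
#'
#' @param path bundle directory containing `metadata.json`.
#' @return an `lso_cell`.
#' @export
read_cell_bundle <- function(path) {
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(meta_file)) stop("bundle has no metadata.json: ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = FALSE)
  for (key in c("cell_id", "anatomical_class", "protocols")) {
    if (is.null(meta[[key]])) stop("metadata missing required key: ", key)
  }
  num_or_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  sweeps <- list()
  for (proto in names(meta$protocols)) {
    pmeta <- meta$protocols[[proto]]
    csv <- file.path(path, paste0(proto, ".csv"))
    if (!file.exists(csv)) stop("bundle missing trace table for protocol: ", proto)
    dt <- data.table::fread(csv)
    if (!all(c("time_ms", "rep_index", "vm_mV") %in% names(dt)))
      stop("trace table must have columns time_ms, rep_index, vm_mV: ", csv)
    fs_all <- vapply(pmeta, function(m) as.numeric(m$sampling_rate), numeric(1))
    if (length(unique(fs_all)) > 1L)
      stop(sprintf("protocol '%s': mismatched sampling rates within protocol", proto))
    sweeps[[proto]] <- lapply(seq_along(pmeta), function(i) {
      m <- pmeta[[i]]
      sub <- dt[dt$rep_index == i, ]
      if (nrow(sub) != m$n)
        stop(sprintf("protocol '%s' rep %d: expected %d samples, found %d",
                     proto, i, m$n, nrow(sub)))
      if (is.unsorted(sub$time_ms, strictly = TRUE))
        stop(sprintf("protocol '%s' rep %d: time column not strictly increasing",
                     proto, i))
      sweep_trace(sub$vm_mV, m$sampling_rate, t0_offset = m$t0_offset,
                  stimulus = stim_from_list(m$stimulus),
                  series_resistance = num_or_na(m$series_resistance),
                  junction_corrected = isTRUE(m$junction_corrected))
    })
  }
  cell_record(meta$cell_id, sweeps = sweeps,
              anatomical_class = meta$anatomical_class,
              CF = num_or_na(meta$CF), BF = num_or_na(meta$BF),
              normalized_position = num_or_na(meta$normalized_position),
              coverage_percent = num_or_na(meta$coverage_percent))
}

#' Correct a sweep for the liquid junction potential
#'
#' Subtracts 10 mV from every sample and sets the `junction_corrected` flag.
#' Applying the correction twice is an error.
#'
#' @param sweep an `lso_sweep` with `junction_corrected = FALSE`.
#' @param offset_mV the junction potential (mV); 10 for the recording
#'   solutions used here.
#' @return the corrected sweep.
#' @export
correct_junction_potential <- function(sweep, offset_mV = 10) {
  stopifnot(inherits(sweep, "lso_sweep"))
  if (isTRUE(sweep$junction_corrected))
    stop("double correction: sweep is already junction-corrected")
  sweep$samples <- sweep$samples - offset_mV
  sweep$junction_corrected <- TRUE
  sweep
}

#' Median membrane potential in a time window
#'
#' Returns the median of all samples whose times fall in the half-open
#' window `[window_ms[1], window_ms[2])` (ms relative to stimulus onset).
#'
#' @param sweep an `lso_sweep`.
#' @param window_ms numeric length-2, `a < b`, within the sweep extent.
#' @return median Vm (mV).
#' @export
baseline_median <- function(sweep, window_ms) {
  stopifnot(inherits(sweep, "lso_sweep"), length(window_ms) == 2L)
  if (window_ms[2] <= window_ms[1]) stop("empty window")
  t <- sweep_times(sweep)
  sel <- t >= window_ms[1] & t < window_ms[2]
  if (!any(sel)) stop("window contains no samples")
  stats::median(sweep$samples[sel])
}
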