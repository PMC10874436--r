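#' Read and write the package's delimited tables
#'
#' All tabular interchange uses plain CSV with fixed schemas:
#' \describe{
#'   \item{traces}{`time_s` plus one column per cell (values are 100 x
#'     dF/F0); the frame interval is inferred from `time_s`.}
#'   \item{spikes}{`cell_id`, `peak_time_s`, `amplitude`, `fwhm_s`.}
#'   \item{events}{`frame`, `time_s`, `x_um`, `y_um`, `intensity`.}
#'   \item{tracks}{`track_id`, `frame`, `time_s`, `x_um`, `y_um` plus a
#'     separate summary table.}
#' }
#' Readers validate the schema and report malformed rows with their line
#' number and column. Writing then reading a table reproduces it (numeric
#' fields to full double precision).
#'
#' @param path file path.
#' @return `read_events()`: a data.frame in the events schema.
#' @name mz_io
NULL

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
}

check_finite <- function(df, cols, path) {
  for (cl in cols) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad))
      stop("file '", path, "': malformed value in column '", cl,
           "' at data row ", bad[1], " (file line ", bad[1] + 1L, ")",
           call. = FALSE)
  }
}

#' @rdname mz_io
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path)
  check_columns(df, c("frame", "time_s", "x_um", "y_um"), path)
  if (is.null(df$intensity)) df$intensity <- NA_real_
  check_finite(df, c("frame", "time_s", "x_um", "y_um"), path)
  df$frame <- as.integer(df$frame)
  df
}

#' @rdname mz_io
#' @param events data.frame in the events schema.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mz_io
#' @param tracks an `mz_tracks` object from [link_events()].
#' @param summary_path optional path for the per-track summary table.
#' @export
write_tracks <- function(tracks, path, summary_path = NULL) {
  ev <- tracks$events[, c("track_id", "frame", "time_s", "x_um", "y_um")]
  utils::write.csv(ev, path, row.names = FALSE)
  if (!is.null(summary_path))
    utils::write.csv(tracks$summary, summary_path, row.names = FALSE)
  invisible(path)
}

#' @rdname mz_io
#' @export
read_tracks <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("track_id", "frame", "time_s", "x_um", "y_um"), path)
  check_finite(df, c("track_id", "frame", "time_s", "x_um", "y_um"), path)
  df$track_id <- as.integer(df$track_id)
  df$frame <- as.integer(df$frame)
  df
}

#' @rdname mz_io
#' @param traces either the list returned by [make_traces()] or a list of
#'   `mz_trace` objects sharing a time grid.
#' @export
write_traces <- function(traces, path) {
  if (!is.null(traces$values)) {
    df <- data.frame(time_s = traces$times)
    vals <- as.data.frame(traces$values)
    names(vals) <- sprintf("cell_%03d", seq_len(ncol(vals)))
    df <- cbind(df, vals)
  } else {
    df <- data.frame(time_s = traces[[1]]$times)
    for (tr in traces) df[[tr$cell_id]] <- tr$values
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mz_io
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, "time_s", path)
  if (ncol(df) < 2L) stop("file '", path, "' has no cell columns")
  check_finite(df, names(df), path)
  if (nrow(df) > 1L) {
    dt <- diff(df$time_s)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6 * dt[1])
      stop("file '", path, "': time_s must be strictly increasing and ",
           "uniformly spaced", call. = FALSE)
  }
  lapply(names(df)[-1], function(nm)
    structure(list(times = df$time_s, values = df[[nm]],
                   cell_id = nm, region = "unknown"), class = "mz_trace"))
}

#' @rdname mz_io
#' @param spikes data.frame of spike calls with a `cell_id` column.
#' @export
write_spikes <- function(spikes, path) {
  out <- data.frame(cell_id = spikes$cell_id,
                    peak_time_s = spikes$peak_time,
                    amplitude = spikes$amplitude,
                    fwhm_s = spikes$fwhm)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname mz_io
#' @export
read_spikes <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("cell_id", "peak_time_s", "amplitude", "fwhm_s"), path)
  df
}

#' Read or write a multi-frame image stack
#'
#' Stacks are stored as multi-page 32-bit TIFF, one page per frame. Because
#' the TIFF writer stores normalised samples in \[0, 1\], intensities are
#' mapped through the fixed affine transform `(v + 4096) / 8192` on write
#' and inverted on read; this supports intensities in (-4096, 4096) with an
#' absolute round-trip precision of about 2e-6 intensity units.
#'
#' @param path TIFF file path.
#' @param stack numeric array rows x cols x frames (or a matrix for a single
#'   frame).
#' @return `read_image_stack()`: array rows x cols x frames.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (max(stack) >= 4096 || min(stack) <= -4096)
    stop("image intensities must lie in (-4096, 4096)")
  pages <- lapply(seq_len(dim(stack)[3]),
                  function(k) (stack[, , k] + 4096) / 8192)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  array(unlist(pages) * 8192 - 4096, dim = c(dim(pages[[1]]), length(pages)))
}

#' Load and validate a configuration file
#'
#' Reads a YAML configuration and dispatches on its top-level blocks:
#' a `params:` block builds an [mz_params()] object, `scenario:` an
#' [scenario_config()], `traces:` a [trace_synth_config()] and `field:` a
#' [field_synth_config()]. Unknown keys are rejected with a field-level
#' message, and all type invariants (including the threshold ordering
#' `beta_V > beta_C` and the Euler stability bound) are enforced by the
#' constructors.
#'
#' @param path YAML file path.
#' @return Named list with one validated object per recognised block.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c(params = NA, scenario = NA, traces = NA, field = NA)
  unknown <- setdiff(names(raw), names(known))
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(block, fn, fn_name) {
    extra <- setdiff(names(block), names(formals(fn)))
    if (length(extra))
      stop("unknown key(s) in ", fn_name, " block: ",
           paste(extra, collapse = ", "), call. = FALSE)
    do.call(fn, block)
  }
  out <- list()
  if (!is.null(raw$params))
    out$params <- build(raw$params, mz_params, "params")
  if (!is.null(raw$scenario))
    out$scenario <- build(raw$scenario, scenario_config, "scenario")
  if (!is.null(raw$traces))
    out$traces <- build(raw$traces, trace_synth_config, "traces")
  if (!is.null(raw$field))
    out$field <- build(raw$field, field_synth_config, "field")
  out
}

#' Write a run manifest
#'
#' Records what produced a set of outputs: the command label, the seed, the
#' configuration, the package version, a timestamp and any warning counters
#' (for the ring model, the clamped-negative count). Re-running with the
#' manifest's seed and configuration reproduces the outputs.
#'
#' @param path output YAML path.
#' @param command short label of the producing step.
#' @param seed integer seed used (or `NA`).
#' @param config configuration object or list (stored as plain lists).
#' @param counters named list of warning counters.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, seed = NA, config = list(),
                           counters = list()) {
  manifest <- list(command = command,
                   seed = seed,
                   package = "mzring",
                   version = as.character(utils::packageVersion("mzring")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = strip_class(config),
                   counters = counters)
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}

strip_class <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, strip_class)
  } else x
}
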