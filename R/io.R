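# File-format plumbing: delimited-text records, JSON summaries, and a
# JSON-based hierarchical container for complex spectral data.
#
# The container mirrors an HDF5-style layout (named datasets + attributes)
# but is stored as plain JSON so every artifact stays text and
# locale-independent.  Complex arrays are split into `*_real` / `*_imag`
# datasets; acquisition metadata live under `attrs`.

#' Read prescan records from CSV
#'
#' Expected header: `experiment_id, coil, nucleus, f0_hz, tg_db` (or
#' `tg_raw` in 0.1-dB units instead of `tg_db`).
#'
#' @param path CSV file path.
#' @return Data frame suitable for [aggregate_scaling()].
#' @export
read_prescan_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("experiment_id", "nucleus")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("prescan CSV missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"f0_hz" %in% names(df)) df$f0_hz <- NA_real_
  if (!"tg_db" %in% names(df) && "tg_raw" %in% names(df)) {
    df$tg_db <- tg_raw_to_db(df$tg_raw)
  }
  if (!"tg_db" %in% names(df)) df$tg_db <- NA_real_
  bad <- !df$nucleus %in% VALID_NUCLEI
  if (any(bad)) stop("unknown nucleus label(s): ",
                     paste(unique(df$nucleus[bad]), collapse = ", "), call. = FALSE)
  df
}

#' Read a subject calibration log from CSV
#'
#' Expected header: `subject_id, date, f_pyr_invivo_hz, f_phantom_hz,
#' f_water_h1_hz`; the last two may be blank.  Dates are ISO-8601.
#'
#' @param path CSV file path.
#' @return Data frame with `date` parsed to `Date`.
#' @export
read_subject_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "date", "f_pyr_invivo_hz")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("subject log missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date(s) in subject log", call. = FALSE)
  for (col in c("f_phantom_hz", "f_water_h1_hz")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  df
}

#' Write a subject calibration log to CSV
#' @param records Data frame as returned by [gen_subject_log()].
#' @param path Output path.
#' @export
write_subject_log <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

json_spectrum <- function(sp) {
  list(values_real = Re(sp$values), values_imag = Im(sp$values),
       attrs = list(phase0 = sp$phase0, transmit_f0_hz = sp$transmit_f0))
}

unjson_spectrum <- function(obj, freq_axis) {
  new_spectrum(complex(real = obj$values_real, imaginary = obj$values_imag),
               freq_axis,
               phase0 = obj$attrs$phase0 %||% 0,
               transmit_f0 = obj$attrs$transmit_f0_hz %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a double-angle CSI study to a JSON container
#'
#' @param study List with `grid_a` and `grid_2a` ([csi_grid()]s) sharing one
#'   frequency axis, e.g. from [gen_csi_study()].
#' @param path Output `.json` path.
#' @export
write_csi_container <- function(study, path) {
  pack_grid <- function(g) {
    list(attrs = list(nx = g$nx, ny = g$ny, nominal_flip_deg = g$nominal_flip,
                      nucleus = g$nucleus, tr_s = g$tr, nex = g$nex),
         spectra = lapply(g$spectra, json_spectrum))
  }
  obj <- list(format = "hypercal-csi-1",
              freq_axis_hz = study$grid_a$spectra[[1L]]$freq_axis,
              grid_a = pack_grid(study$grid_a),
              grid_2a = pack_grid(study$grid_2a))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a double-angle CSI study from a JSON container
#' @param path Container path written by [write_csi_container()].
#' @return List with `grid_a` and `grid_2a`.
#' @export
read_csi_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "hypercal-csi-1")) {
    stop("not a hypercal CSI container: ", path, call. = FALSE)
  }
  ax <- obj$freq_axis_hz
  unpack <- function(g) {
    at <- g$attrs
    csi_grid(lapply(g$spectra, unjson_spectrum, freq_axis = ax),
             nx = at$nx, ny = at$ny, nominal_flip = at$nominal_flip_deg,
             nucleus = at$nucleus, tr = at$tr_s %||% NA_real_, nex = at$nex %||% 1L)
  }
  missing_grids <- setdiff(c("grid_a", "grid_2a"), names(obj))
  if (length(missing_grids)) {
    stop("container lacks grid(s): ", paste(missing_grids, collapse = ", "),
         call. = FALSE)
  }
  list(grid_a = unpack(obj$grid_a), grid_2a = unpack(obj$grid_2a))
}

#' Write a dynamic study to a JSON container
#' @param dyn A [dynamic_spectra()] object.
#' @param path Output `.json` path.
#' @export
write_dynamic_container <- function(dyn, path) {
  stopifnot(inherits(dyn, "dynamic_spectra"))
  obj <- list(format = "hypercal-dyn-1",
              freq_axis_hz = dyn$frames[[1L]]$freq_axis,
              attrs = list(tr_s = dyn$tr, flip_deg = dyn$flip,
                           n_timepoints = dyn$n_timepoints),
              frames = lapply(dyn$frames, json_spectrum))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dynamic study from a JSON container
#' @param path Container path written by [write_dynamic_container()].
#' @return A [dynamic_spectra()] object.
#' @export
read_dynamic_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  if (!identical(obj$format, "hypercal-dyn-1")) {
    stop("not a hypercal dynamic container: ", path, call. = FALSE)
  }
  ax <- obj$freq_axis_hz
  dynamic_spectra(lapply(obj$frames, unjson_spectrum, freq_axis = ax),
                  tr = obj$attrs$tr_s, flip = obj$attrs$flip_deg)
}

#' Export a scalar map as a delimited-text grid
#' @param map A [scalar_map()].
#' @param path Output TSV path (masked voxels are written as `NA`).
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(map$values, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
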