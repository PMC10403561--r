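need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the rhdf5 package is required for HDF5 container I/O",
         call. = FALSE)
}

sidecar_path <- function(path) sub("\\.h5$", ".json", path)

#' Write a TDI acquisition to an HDF5 container
#'
#' Container layout: datasets `/velocity` and `/echogenicity`
#' (T x H x W, cm/s and arbitrary units), `/ecg` (mV); root attributes
#' `frame_rate_hz`, `ecg_fs_hz`, `lead`, plus the sector geometry as a JSON
#' attribute. When ground truth is supplied, a JSON sidecar (same path with
#' `.json` extension) duplicates its scalar fields, beat times and wall
#' mask for test use (the full clean component traces stay in memory only).
#'
#' @param tdi A `tdi_sequence`.
#' @param path Output path ending in `.h5`.
#' @param truth Optional `ground_truth` to serialize as a sidecar.
#' @return `path`, invisibly.
#' @export
write_tdi_container <- function(tdi, path, truth = NULL) {
  need_rhdf5()
  if (!inherits(tdi, "tdi_sequence"))
    stop("tdi must be a tdi_sequence", call. = FALSE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(tdi$velocity, path, "velocity")
  rhdf5::h5write(tdi$echogenicity, path, "echogenicity")
  rhdf5::h5write(tdi$simultaneous_ecg$samples, path, "ecg")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(tdi$frame_rate, fid, "frame_rate_hz")
  rhdf5::h5writeAttribute(tdi$simultaneous_ecg$fs, fid, "ecg_fs_hz")
  rhdf5::h5writeAttribute(tdi$simultaneous_ecg$lead, fid, "lead")
  rhdf5::h5writeAttribute(
    as.character(jsonlite::toJSON(tdi$sector_geometry, auto_unbox = TRUE)),
    fid, "sector_geometry_json")
  rhdf5::H5Fclose(fid)

  if (!is.null(truth)) {
    side <- list(true_ear = truth$true_ear, true_mar = truth$true_mar,
                 true_dissociation = truth$true_dissociation,
                 ventricular_beat_times = truth$ventricular_beat_times,
                 wall_mask = truth$wall_mask,
                 scenario = truth$scenario, seed = truth$seed)
    jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a TDI acquisition from an HDF5 container
#'
#' @param path Path to a container written by [write_tdi_container()].
#' @return List with `tdi` (a `tdi_sequence`) and `truth` (sidecar contents
#'   as a list, or `NULL` if no sidecar exists).
#' @export
read_tdi_container <- function(path) {
  need_rhdf5()
  if (!file.exists(path)) stop("container not found: ", path, call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "/")
  geom <- if (!is.null(at$sector_geometry_json)) {
    g <- jsonlite::fromJSON(at$sector_geometry_json)
    g$apex <- stats::setNames(as.numeric(unlist(g$apex)), c("row", "col"))
    g
  } else {
    NULL
  }
  ecg <- structure(list(samples = as.numeric(rhdf5::h5read(path, "ecg")),
                        fs = as.numeric(at$ecg_fs_hz),
                        lead = as.character(at$lead)),
                   class = "ecg_record")
  tdi <- structure(list(velocity = rhdf5::h5read(path, "velocity"),
                        echogenicity = rhdf5::h5read(path, "echogenicity"),
                        frame_rate = as.numeric(at$frame_rate_hz),
                        sector_geometry = geom,
                        simultaneous_ecg = ecg),
                   class = "tdi_sequence")
  truth <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    truth <- jsonlite::fromJSON(sp)
    if (!is.null(truth$wall_mask))
      truth$wall_mask <- matrix(as.logical(truth$wall_mask),
                                nrow = nrow(as.matrix(truth$wall_mask)))
  }
  list(tdi = tdi, truth = truth)
}

#' Write an ECG record as a two-column CSV
#'
#' Columns `time_s` and `mv`.
#'
#' @param ecg An `ecg_record`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(ecg, path) {
  if (!inherits(ecg, "ecg_record"))
    stop("ecg must be an ecg_record", call. = FALSE)
  tt <- (seq_along(ecg$samples) - 1) / ecg$fs
  utils::write.csv(data.frame(time_s = tt, mv = ecg$samples), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an ECG record from a two-column CSV
#'
#' Expects columns `time_s` and `mv` (as written by [write_ecg_csv()]);
#' the sampling rate is recovered from the time column.
#'
#' @param path CSV path.
#' @param lead Lead label (default "II").
#' @return An `ecg_record`.
#' @export
read_ecg_csv <- function(path, lead = "II") {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "mv") %in% names(d)))
    stop("CSV must have columns time_s and mv", call. = FALSE)
  dt <- diff(d$time_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6)
    stop("time column is not uniformly sampled", call. = FALSE)
  structure(list(samples = d$mv, fs = 1 / mean(dt), lead = lead),
            class = "ecg_record")
}

#' Write an optical recording to an HDF5 container
#'
#' Datasets `/vm_num`, `/vm_den`, `/ca_num`, `/ca_den`; root attribute
#' `fs_hz`. The channel-pair convention is fixed by the dataset names.
#'
#' @param rec A `ratiometric_recording`.
#' @param path Output path ending in `.h5`.
#' @return `path`, invisibly.
#' @export
write_optical_container <- function(rec, path) {
  need_rhdf5()
  if (!inherits(rec, "ratiometric_recording"))
    stop("rec must be a ratiometric_recording", call. = FALSE)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  for (ch in c("vm_num", "vm_den", "ca_num", "ca_den"))
    rhdf5::h5write(rec[[ch]], path, ch)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(rec$fs, fid, "fs_hz")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Read an optical recording from an HDF5 container
#'
#' @param path Path written by [write_optical_container()].
#' @return A `ratiometric_recording`.
#' @export
read_optical_container <- function(path) {
  need_rhdf5()
  if (!file.exists(path)) stop("container not found: ", path, call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "/")
  ch <- lapply(c(vm_num = "vm_num", vm_den = "vm_den",
                 ca_num = "ca_num", ca_den = "ca_den"),
               function(d) as.numeric(rhdf5::h5read(path, d)))
  structure(c(ch, list(fs = as.numeric(at$fs_hz))),
            class = "ratiometric_recording")
}
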