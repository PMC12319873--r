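# Standard-format I/O: BIDS-style event TSV, vertex/face mesh text, NIfTI
# volumes, and a flat-binary + JSON sidecar EEG container.

#' Write / read a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `trial_type`.
#'
#' @param events event table from [make_block_design()].
#' @param path file path (`*_events.tsv`).
#' @return `read_events_tsv` returns the event table with the package's
#'   `condition` column naming.
#' @export
write_events_tsv <- function(events, path) {
  out <- data.frame(onset = events$onset, duration = events$duration,
                    trial_type = events$condition)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  data.frame(onset = x$onset, duration = x$duration,
             condition = x$trial_type, stringsAsFactors = FALSE)
}

#' Write / read a mesh pair as plain text
#'
#' OBJ-flavoured text per surface (`v x y z` vertex lines, `f i j k` face
#' lines) in `<prefix>_pial.obj` and `<prefix>_white.obj`.
#'
#' @param mesh a `mesh_pair`.
#' @param prefix path prefix.
#' @return `read_mesh_text` returns a `mesh_pair` (areas recomputed).
#' @export
write_mesh_text <- function(mesh, prefix) {
  write_one <- function(v, faces, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
  }
  write_one(mesh$vertices_pial, mesh$faces, paste0(prefix, "_pial.obj"))
  write_one(mesh$vertices_white, mesh$faces, paste0(prefix, "_white.obj"))
  invisible(prefix)
}

#' @rdname write_mesh_text
#' @export
read_mesh_text <- function(prefix) {
  read_one <- function(path) {
    lines <- readLines(path)
    vs <- do.call(rbind, lapply(strsplit(grep("^v ", lines, value = TRUE), " "),
                                function(p) as.numeric(p[2:4])))
    fs <- do.call(rbind, lapply(strsplit(grep("^f ", lines, value = TRUE), " "),
                                function(p) as.integer(p[2:4])))
    list(v = vs, f = fs)
  }
  p <- read_one(paste0(prefix, "_pial.obj"))
  w <- read_one(paste0(prefix, "_white.obj"))
  colnames(p$v) <- colnames(w$v) <- c("x", "y", "z")
  structure(
    list(vertices_pial = p$v, vertices_white = w$v, faces = p$f,
         area_pial = vertex_neighborhood_areas(p$v, p$f),
         area_white = vertex_neighborhood_areas(w$v, w$f)),
    class = "mesh_pair",
    geometry = list(shape = "file", thickness = NA_real_)
  )
}

#' Write a depth volume as NIfTI-1
#'
#' Gray-matter voxel depths on the generating grid; non-gray voxels are
#' `NA`.
#'
#' @param depth a `depth_volume` built on an internal grid.
#' @param path output `.nii` / `.nii.gz` path.
#' @export
write_depth_nifti <- function(depth, path) {
  if (is.null(depth$grid)) stop("depth_volume has no grid metadata", call. = FALSE)
  arr <- array(NA_real_, dim = depth$grid$dims)
  arr[depth$grid$index] <- depth$depth
  img <- RNifti::asNifti(arr, pixdim = depth$grid$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a simulated BOLD run as 4-D NIfTI-1
#'
#' @param bold a `bold_run`.
#' @param path output path.
#' @export
write_bold_nifti <- function(bold, path) {
  dims <- c(bold$grid$dims, ncol(bold$data))
  arr <- array(0, dim = dims)
  n_xyz <- prod(bold$grid$dims)
  for (tvol in seq_len(ncol(bold$data))) {
    slice <- numeric(n_xyz)
    slice[bold$grid$index] <- bold$data[, tvol]
    arr[, , , tvol] <- slice
  }
  img <- RNifti::asNifti(arr, pixdim = c(bold$grid$spacing, bold$tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read the flat-binary EEG container
#'
#' Data as little-endian float64 (`<prefix>.dat`, channel-major: all
#' samples of channel 1, then channel 2, ...) plus a JSON sidecar
#' (`<prefix>.json`) with channels, sampling rate, and the trial table.
#'
#' @param rec an `eeg_recording`.
#' @param prefix path prefix.
#' @return `read_eeg_recording` returns an `eeg_recording`.
#' @export
write_eeg_recording <- function(rec, prefix) {
  con <- file(paste0(prefix, ".dat"), "wb")
  writeBin(as.vector(t(rec$data)), con, size = 8, endian = "little")
  close(con)
  sidecar <- list(channels = rec$channels, srate = rec$srate,
                  n_samples = ncol(rec$data),
                  trial_samples = rec$trial_samples, trials = rec$trials)
  jsonlite::write_json(sidecar, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_eeg_recording
#' @export
read_eeg_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  con <- file(paste0(prefix, ".dat"), "rb")
  n <- length(meta$channels) * meta$n_samples
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  close(con)
  structure(
    list(data = t(matrix(x, nrow = meta$n_samples)), srate = meta$srate,
         channels = meta$channels, trials = as.data.frame(meta$trials),
         trial_samples = meta$trial_samples),
    class = "eeg_recording"
  )
}

#' Write a data frame as TSV
#'
#' @param x data frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
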