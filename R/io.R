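# On-disk interchange: NPY v1.0 arrays (the DEAP dialect) with JSON
# sidecars, annotation CSVs, and epoch containers.

#' Write / read a numeric array in NumPy NPY v1.0 format
#'
#' Little-endian float64, C-order. Covers the subset of the format needed
#' to interchange recording and epoch arrays with NumPy tooling.
#'
#' @param x Numeric array (any number of dimensions).
#' @param path File path (`.npy`).
#' @return `npy_save`: `path` invisibly. `npy_load`: the array.
#' @export
npy_save <- function(x, path) {
  stopifnot(is.numeric(x))
  dims <- dim(x) %||% length(x)
  shape <- paste0("(", paste0(dims, ",", collapse = " "), ")")
  shape <- sub(", \\)$", ")", sub(",\\)$", ",)", shape))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': %s, }",
                    shape)
  # total preamble (10 bytes) + header must be a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  if (length(dims) > 1L) {
    x <- aperm(x, rev(seq_along(dims)))           # column-major -> C order
  }
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname npy_save
#' @export
npy_load <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY"))))) {
    stopf("%s is not an NPY file", path)
  }
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("'descr':\\s*'<f8'", header)) {
    stopf("unsupported NPY dtype in %s (only '<f8' is handled)", header)
  }
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_str <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_str), ",")[[1]])
  dims <- dims[!is.na(dims)]
  n <- prod(dims)
  x <- readBin(con, "numeric", n, size = 8L, endian = "little")
  if (length(dims) <= 1L) return(x)
  if (fortran) {
    array(x, dims)
  } else {
    aperm(array(x, rev(dims)), rev(seq_along(dims)))
  }
}

#' Write / read a recording set (one NPY per participant + JSON sidecar)
#'
#' @param rec A `recording_set`.
#' @param dir Output directory (created if needed).
#' @return `write_recordings`: `dir` invisibly. `read_recordings`: the
#'   `recording_set`.
#' @export
write_recordings <- function(rec, dir) {
  stopifnot(inherits(rec, "recording_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(rec$data)) {
    npy_save(rec$data[[p]], file.path(dir, sprintf("s%02d.npy", p)))
  }
  side <- list(
    fs = rec$fs, channel_names = rec$channel_names,
    n_participants = length(rec$data),
    n_videos = rec$n_videos, n_trials = rec$n_trials,
    baseline_s = rec$baseline_s, trial_duration_s = rec$trial_duration_s,
    shape = dim(rec$data[[1]])
  )
  jsonlite::write_json(side, file.path(dir, "recordings.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "recordings.json"),
                              simplifyVector = TRUE)
  data <- lapply(seq_len(side$n_participants), function(p) {
    npy_load(file.path(dir, sprintf("s%02d.npy", p)))
  })
  structure(
    list(data = data, fs = side$fs, channel_names = side$channel_names,
         n_videos = side$n_videos, n_trials = side$n_trials,
         baseline_s = side$baseline_s,
         trial_duration_s = side$trial_duration_s),
    class = "recording_set"
  )
}

#' Write / read an epoch set (NPY array + metadata CSV + sidecar)
#'
#' The array file holds `n_epochs x time x channels` (C order), matching
#' the matrix-per-epoch convention of downstream consumers.
#'
#' @param es An [epoch_set].
#' @param dir Output directory.
#' @return `write_epochs`: `dir` invisibly; `read_epochs`: the
#'   `epoch_set`.
#' @export
write_epochs <- function(es, dir) {
  stopifnot(inherits(es, "epoch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  npy_save(aperm(es$data, c(3L, 1L, 2L)), file.path(dir, "epochs.npy"))
  utils::write.csv(es$meta, file.path(dir, "epochs_meta.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(fs = es$fs, normalized = es$normalized),
                       file.path(dir, "epochs.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "epochs.json"),
                              simplifyVector = TRUE)
  arr <- npy_load(file.path(dir, "epochs.npy"))
  meta <- tibble::as_tibble(
    utils::read.csv(file.path(dir, "epochs_meta.csv"),
                    stringsAsFactors = FALSE)
  )
  new_epoch_set(aperm(arr, c(2L, 3L, 1L)), meta, fs = side$fs,
                normalized = side$normalized)
}

#' Write / read expert annotation CSVs
#'
#' Schema: `video_id`, `second` (0-based), `vdep`, `expert_id`, `label`
#' (`"1"`, `"2"` or `"unclear"`). Both experts live in one file.
#'
#' @param tags A list of per-expert tag tibbles (as from
#'   [make_expert_tags()]) or a single combined tibble.
#' @param path CSV path.
#' @return `write_annotations`: `path` invisibly. `read_annotations`: list
#'   of per-expert tag tibbles.
#' @export
write_annotations <- function(tags, path) {
  if (is.data.frame(tags)) tags <- list(tags)
  combined <- do.call(rbind, tags)
  utils::write.csv(combined, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(label = "character"))
  lapply(sort(unique(d$expert_id)), function(ex) {
    tibble::as_tibble(d[d$expert_id == ex, ])
  })
}
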