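#' Read and write sweep tables
#'
#' Sweeps travel as tab-delimited text with the exact header
#' `time_s<TAB>current_pa`; units are encoded in the column names. A sweep's
#' laser command level, when known, lives in the recording's JSON sidecar,
#' not in the table.
#'
#' @param path File path.
#' @param sweep A `sweep_trace` (see [new_sweep()]).
#' @return `read_sweep_table()` returns a `sweep_trace`;
#'   `write_sweep_table()` returns `path` invisibly.
#' @export
read_sweep_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!identical(names(tab), c("time_s", "current_pa"))) {
    stop("malformed sweep table ", path,
         ": expected header columns 'time_s' and 'current_pa' (tab-",
         "delimited), got: ", paste(names(tab), collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(tab$time_s) <= 0)) {
    stop("sweep table ", path, " has a non-monotone time axis", call. = FALSE)
  }
  new_sweep(tab$time_s, tab$current_pa)
}

#' @rdname read_sweep_table
#' @export
write_sweep_table <- function(sweep, path) {
  validate_sweep(sweep)
  utils::write.table(data.frame(time_s = sweep$time_s,
                                current_pa = sweep$current_pa),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a whole recording
#'
#' One tab-delimited file per sweep (`<cell>_sweep<NN>.tsv`), parallel
#' ground-truth temperature files for synthetic data
#' (`<cell>_truth<NN>.tsv`, columns `time_s`, `temperature_k`), and a JSON
#' sidecar `<cell>_metadata.json` holding the cell metadata, command levels
#' and the file manifest.
#'
#' @param rec A `channel_recording`.
#' @param dir Output directory (created if needed).
#' @param cell_id Cell identifier; for reading, names the sidecar to load.
#' @return `write_recording()` returns the sidecar path invisibly;
#'   `read_recording()` returns the reassembled `channel_recording`.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "channel_recording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- rec$metadata$cell_id
  sweep_files <- character(length(rec$sweeps))
  truth_files <- character(length(rec$true_temperature))
  for (i in seq_along(rec$sweeps)) {
    sweep_files[i] <- sprintf("%s_sweep%02d.tsv", id, i)
    write_sweep_table(rec$sweeps[[i]], file.path(dir, sweep_files[i]))
  }
  for (i in seq_along(rec$true_temperature)) {
    truth_files[i] <- sprintf("%s_truth%02d.tsv", id, i)
    utils::write.table(rec$true_temperature[[i]],
                       file.path(dir, truth_files[i]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  sidecar <- file.path(dir, sprintf("%s_metadata.json", id))
  jsonlite::write_json(
    c(rec$metadata, list(sweep_files = sweep_files,
                         truth_files = truth_files)),
    sidecar, auto_unbox = TRUE, digits = I(17)
  )
  invisible(sidecar)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir, cell_id) {
  sidecar <- file.path(dir, sprintf("%s_metadata.json", cell_id))
  if (!file.exists(sidecar)) {
    stop("no metadata sidecar for cell '", cell_id, "' in ", dir,
         call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  sweeps <- lapply(seq_along(meta$sweep_files), function(i) {
    sweep <- read_sweep_table(file.path(dir, meta$sweep_files[i]))
    attr(sweep, "command_level") <- meta$setpoints_c[i]
    sweep
  })
  truths <- lapply(meta$truth_files, function(f) {
    utils::read.table(file.path(dir, f), header = TRUE, sep = "\t")
  })
  meta$sweep_files <- NULL
  meta$truth_files <- NULL
  structure(list(sweeps = sweeps, true_temperature = truths,
                 metadata = meta),
            class = "channel_recording")
}
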