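# Canonical on-disk formats: delimited-matrix recordings with a JSON
# sidecar, CSV design and score tables. Numbers are written with 17
# significant digits so round trips are bit-exact.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a recording in the matrix + JSON-sidecar dialect
#'
#' `<prefix>.tsv` holds the channels x samples matrix, tab-separated, no
#' header; `<prefix>.json` holds
#' `{sampling_rate, channel_names, positions, reference, units}`. Values
#' are stored in volts with 17 significant digits, so the round trip is
#' bit-exact (a microvolt scaling would round twice). A sidecar declaring
#' `units: "uV"` is honored on read.
#'
#' @param rec an `eeg_recording`.
#' @param prefix file path without extension.
#' @return `write_recording`: the prefix, invisibly. `read_recording`: an
#'   `eeg_recording` (volts).
#' @export
write_recording <- function(rec, prefix) {
  m <- apply(rec$data, c(1, 2), fmt_num)
  utils::write.table(m, paste0(prefix, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  side <- list(sampling_rate = rec$srate, channel_names = rec$ch_names,
               positions = rec$positions, reference = rec$reference,
               units = "V")
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  tsv <- paste0(prefix, ".tsv")
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(tsv)) stop("matrix file not found: ", tsv)
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for matrix dialect: ", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(tsv, sep = "\t", header = FALSE))
  dimnames(data) <- NULL
  if (length(side$channel_names) != nrow(data))
    stop("sidecar lists ", length(side$channel_names),
         " channels but the matrix has ", nrow(data), " rows")
  units <- if (is.null(side$units)) "V" else side$units
  scale <- switch(units, V = 1, uV = 1e-6,
                  stop("unknown units in sidecar: ", units))
  new_recording(data * scale, side$sampling_rate, side$channel_names,
                as.matrix(side$positions), side$reference)
}

#' Write / read a design table as CSV
#'
#' Header `block,trial,condition,onset_sample`; onset samples are
#' expressed at the timing's sampling rate, supplied on read via `timing`.
#'
#' @param design an `eeg_design`.
#' @param path CSV path.
#' @param timing a [design_timing()] list attached on read.
#' @return `read_design`: an `eeg_design`.
#' @export
write_design <- function(design, path) {
  utils::write.csv(as.data.frame(design)[
    , c("block", "trial", "condition", "onset_sample")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, timing = design_timing()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("block", "trial", "condition", "onset_sample")
  if (!all(need %in% names(d)))
    stop("design CSV must have header ", paste(need, collapse = ","))
  attr(d, "timing") <- timing
  class(d) <- c("eeg_design", "data.frame")
  d
}

#' Write / read a suppression score table as CSV
#'
#' Header `participant,condition,region,log_ratio`.
#'
#' @param scores a `suppression_table`.
#' @param path CSV path.
#' @return `read_suppression`: a `suppression_table`.
#' @export
write_suppression <- function(scores, path) {
  df <- as.data.frame(scores)
  df$log_ratio <- fmt_num(df$log_ratio)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_suppression
#' @export
read_suppression <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "condition", "region", "log_ratio")
  if (!all(need %in% names(d)))
    stop("score CSV must have header ", paste(need, collapse = ","))
  class(d) <- c("suppression_table", "data.frame")
  d
}

#' Write / read a source image as CSV
#'
#' One row per voxel: `x,y,z` grid position (meters, head-centered) and
#' `value` (e.g. normalized log band power or a t statistic).
#'
#' @param grid voxels x 3 matrix of positions.
#' @param values numeric vector, one value per voxel.
#' @param path CSV path.
#' @return `read_source_image`: list with `grid` and `values`.
#' @export
write_source_image <- function(grid, values, path) {
  stopifnot(nrow(grid) == length(values))
  df <- data.frame(x = fmt_num(grid[, 1]), y = fmt_num(grid[, 2]),
                   z = fmt_num(grid[, 3]), value = fmt_num(values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_source_image
#' @export
read_source_image <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y", "z", "value") %in% names(d)))
    stop("source image CSV must have header x,y,z,value")
  list(grid = as.matrix(d[, c("x", "y", "z")]), values = d$value)
}

# tiny FNV-1a hash over a serialized object, for provenance records
fnv1a <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h %% 2^31, b) + (h - h %% 2^31)  # xor low bits only
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}
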