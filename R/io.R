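# Plain-text interchange: traces as TSV, spectra and binding series as CSV,
# sequences as FASTA, disorder/domain tables as TSV, ground-truth sidecars
# as JSON.

#' Write / read bead-extension traces (TSV)
#'
#' Long format with columns `trace_id`, `role`, `time_s`, `extension_nm`.
#'
#' @param traces A list of [fs_trace()] objects or an `fs_simulation`.
#' @param file Path to the TSV file.
#' @return `write_traces()` returns `file` invisibly; `read_traces()`
#'   returns a list of `fs_trace` objects.
#' @export
write_traces <- function(traces, file) {
  if (inherits(traces, "fs_simulation")) traces <- traces$traces
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace_id = tr$trace_id, role = tr$role,
               time_s = tr$time, extension_nm = tr$extension)))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_traces
#' @export
read_traces <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("trace_id", "role", "time_s", "extension_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    halopol_error(sprintf("trace table is missing column(s): %s",
                          paste(missing_cols, collapse = ", ")),
                  "halopol_format_error")
  lapply(split(df, df$trace_id)[unique(df$trace_id)], function(d)
    fs_trace(d$trace_id[1], d$role[1], d$time_s, d$extension_nm, "nm"))
}

#' Write the ground-truth sidecar of a trace simulation (JSON)
#'
#' Per-trace segment and pause boundaries in both seconds and 0-based
#' half-open sample indices, with true per-segment rates and lengths.
#'
#' @param sim An `fs_simulation`.
#' @param file Path to the JSON file.
#' @export
write_trace_truth <- function(sim, file) {
  stopifnot(inherits(sim, "fs_simulation"))
  jsonlite::write_json(sim$truth, file, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' Write / read a Raman spectrum (CSV)
#'
#' Columns `wavenumber_cm1`, `intensity`.
#'
#' @param spectrum Data frame with `wavenumber`, `intensity` (or a
#'   `raman_simulation`).
#' @param file Path to the CSV file.
#' @export
write_spectrum <- function(spectrum, file) {
  if (inherits(spectrum, "raman_simulation")) spectrum <- spectrum$spectrum
  utils::write.csv(data.frame(wavenumber_cm1 = spectrum$wavenumber,
                              intensity = spectrum$intensity),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("wavenumber_cm1", "intensity") %in% names(df)))
    halopol_error("spectrum CSV needs columns wavenumber_cm1, intensity",
                  "halopol_format_error")
  data.frame(wavenumber = df$wavenumber_cm1, intensity = df$intensity)
}

#' Write / read an equilibrium binding series (CSV)
#'
#' Columns `concentration_nM`, `response_RU`.
#'
#' @param series A [binding_series()] (or `binding_simulation`).
#' @param file Path to the CSV file.
#' @export
write_binding <- function(series, file) {
  if (inherits(series, "binding_simulation")) series <- series$series
  utils::write.csv(data.frame(concentration_nM = series$concentrations,
                              response_RU = series$responses),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_binding
#' @export
read_binding <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("concentration_nM", "response_RU") %in% names(df)))
    halopol_error("binding CSV needs columns concentration_nM, response_RU",
                  "halopol_format_error")
  binding_series(df$concentration_nM, df$response_RU)
}

#' Write / read protein sequences (FASTA, wrapped at 60 columns)
#'
#' @param seqs Named character vector of sequences, or a single
#'   `sequence_simulation` record.
#' @param file Path to the FASTA file.
#' @export
write_fasta <- function(seqs, file) {
  if (inherits(seqs, "sequence_simulation"))
    seqs <- stats::setNames(seqs$record$residues, seqs$record$id)
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, file, width = 60)
  invisible(file)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readAAStringSet(file)
  stats::setNames(as.character(x), names(x))
}

#' Write / read a per-residue disorder-probability track (TSV)
#'
#' Columns `position` (1-based), `probability`.
#'
#' @param track Numeric probability vector (or a `sequence_simulation`).
#' @param file Path to the TSV file.
#' @export
write_disorder <- function(track, file) {
  if (inherits(track, "sequence_simulation")) track <- track$disorder
  utils::write.table(data.frame(position = seq_along(track),
                                probability = track),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_disorder
#' @export
read_disorder <- function(file) {
  df <- utils::read.delim(file)
  if (!all(c("position", "probability") %in% names(df)))
    halopol_error("disorder TSV needs columns position, probability",
                  "halopol_format_error")
  df$probability[order(df$position)]
}

#' Write / read domain annotations (TSV, 1-based inclusive)
#'
#' Columns `name`, `start`, `end`.
#'
#' @param domains Data frame with `name`, `start`, `end`.
#' @param file Path to the TSV file.
#' @export
write_domains <- function(domains, file) {
  utils::write.table(domains[, c("name", "start", "end")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_domains
#' @export
read_domains <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("name", "start", "end") %in% names(df)))
    halopol_error("domain TSV needs columns name, start, end",
                  "halopol_format_error")
  df
}
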