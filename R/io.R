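# Plain-text record exchange. A record is stored as two CSV files:
#   <name>.csv      with columns sample_index (0-based), amplitude
#   <name>.ann.csv  with columns sample_index (0-based R peak), label
# The same reader serves synthetic exports and user-supplied data.

#' Write an ECG record as CSV sample/annotation files
#'
#' @param record An `ecg_record` (see [generate_record()]).
#' @param dir Output directory (created if missing).
#' @param name Base file name; defaults to the record id.
#' @return Invisibly, the two file paths written.
#' @export
write_record_csv <- function(record, dir, name = record$record_id) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sig <- file.path(dir, paste0(name, ".csv"))
  ann <- file.path(dir, paste0(name, ".ann.csv"))
  utils::write.csv(
    data.frame(sample_index = seq_along(record$samples) - 1L,
               amplitude = record$samples),
    sig, row.names = FALSE)
  utils::write.csv(
    data.frame(sample_index = record$r_peaks - 1L, label = record$labels),
    ann, row.names = FALSE)
  invisible(c(signal = sig, annotation = ann))
}

#' Read an ECG record from CSV sample/annotation files
#'
#' @param path Path to the sample CSV; the annotation file is looked up by
#'   replacing `.csv` with `.ann.csv`.
#' @param fs Sampling rate in Hz of the stored samples.
#' @param record_id Identifier; defaults to the file base name.
#' @return An `ecg_record`.
#' @export
read_record_csv <- function(path, fs = 360,
                            record_id = sub("\\.csv$", "", basename(path))) {
  ann_path <- sub("\\.csv$", ".ann.csv", path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(ann_path)) stop("no annotation file: ", ann_path)
  sig <- utils::read.csv(path)
  ann <- utils::read.csv(ann_path, colClasses = c("integer", "character"))
  if (is.unsorted(ann$sample_index, strictly = TRUE)) {
    stop("annotation sample_index must be strictly increasing")
  }
  if (!all(ann$label %in% beat_classes())) {
    stop("unknown labels in annotation file: ",
         paste(setdiff(ann$label, beat_classes()), collapse = ","))
  }
  samples <- sig$amplitude
  r_peaks <- ann$sample_index + 1L
  structure(list(samples = samples, fs = fs, r_peaks = r_peaks,
                 labels = ann$label,
                 truncated = (r_peaks - 1L) < 100L * fs / 360 |
                   (length(samples) - r_peaks) < 200L * fs / 360,
                 record_id = record_id, seed = NA_integer_),
            class = "ecg_record")
}

#' Write a binary image as a PGM file
#'
#' Writes plain-text (P2) or binary-pixel-as-ASCII PGM for quick visual
#' inspection of binarized beat images; 1-pixels are written black on a
#' white background.
#'
#' @param image 0/1 integer matrix.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_image_pgm <- function(image, path) {
  assert_binary(image)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "1"), con)
  write(t(1L - image), file = con, ncolumns = ncol(image))
  invisible(path)
}

#' Write a dataset manifest as JSON lines
#'
#' One JSON object per beat with fields `record_id`, `beat`, `label` and
#' `rr_code` (integer RR quantization code), mirroring the order of the
#' dataset rows.
#'
#' @param dataset A `beat_dataset` (see [build_dataset()]).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(dataset, path) {
  stopifnot(inherits(dataset, "beat_dataset"))
  n <- length(dataset$label)
  lines <- vapply(seq_len(n), function(i) {
    jsonlite::toJSON(list(record_id = dataset$record_id[i], beat = i,
                          label = dataset$label[i],
                          rr_code = dataset$rr_int[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
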