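#' Write a recording as delimited numeric text
#'
#' Layout: `#` metadata lines (fs, subjectId, condition), then a tab-separated
#' header row of channel labels, then samples x channels numeric rows.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @param digits signal precision (significant digits) in the file.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, digits = 8) {
  writeLines(c(
    sprintf("# fs\t%.10g", rec@fs),
    sprintf("# subjectId\t%s", rec@subjectId),
    sprintf("# condition\t%s", rec@condition)
  ), path)
  dt <- data.table::as.data.table(signif(t(rec@data), digits))
  data.table::setnames(dt, rec@channelLabels)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a recording from delimited numeric text
#'
#' @param path file written by [writeRecording()] (or any delimited file with
#'   the same layout).
#' @param requireChannels channels that must be present; defaults to the full
#'   eight-channel montage. A missing label raises a typed error naming it.
#' @return an [EEGRecording-class].
#' @export
readRecording <- function(path, requireChannels = ALL_CHANNELS) {
  if (!file.exists(path))
    stopTyped("earstress_read_error", "file not found: %s", path)
  hdr <- readLines(path, n = 16)
  meta <- hdr[startsWith(hdr, "# ")]
  if (!length(meta))
    stopTyped("earstress_read_error", "no metadata header in %s", path)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "\t"))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  if (is.na(suppressWarnings(as.numeric(meta["fs"]))))
    stopTyped("earstress_read_error", "file %s does not declare fs", path)
  dt <- tryCatch(
    data.table::fread(path, sep = "\t", skip = length(which(startsWith(hdr, "# "))),
                      header = TRUE),
    error = function(e) stopTyped("earstress_read_error",
                                  "unreadable delimited file %s: %s",
                                  path, conditionMessage(e)))
  labels <- names(dt)
  missing <- setdiff(requireChannels, labels)
  if (length(missing))
    stopTyped("earstress_missing_channel",
              "file %s is missing channel(s): %s", path,
              paste(missing, collapse = ", "))
  mat <- t(as.matrix(dt))
  if (anyNA(mat))
    stopTyped("earstress_read_error", "non-numeric or missing samples in %s", path)
  EEGRecording(mat, fs = as.numeric(meta[["fs"]]), channelLabels = labels,
               subjectId = meta[["subjectId"]] %||% "unknown",
               condition = meta[["condition"]] %||% "relax")
}

#' Write a dataset of recordings plus a TSV manifest
#'
#' @param recordings list of [EEGRecording-class] (e.g. from
#'   [generatePairedDataset()]).
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (subjectId, condition, path, fs),
#'   invisibly; also written to `dir/manifest.tsv`.
#' @export
writeDataset <- function(recordings, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(recordings, function(rec) {
    fname <- sprintf("%s_%s.tsv", rec@subjectId, rec@condition)
    writeRecording(rec, file.path(dir, fname))
    data.frame(subjectId = rec@subjectId, condition = rec@condition,
               path = fname, fs = rec@fs, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  data.table::fwrite(manifest, file.path(dir, "manifest.tsv"), sep = "\t")
  invisible(manifest)
}

#' Read a dataset back from a manifest
#'
#' @param manifestPath path to a `manifest.tsv` written by [writeDataset()].
#' @return list of [EEGRecording-class].
#' @export
readDataset <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stopTyped("earstress_read_error", "manifest not found: %s", manifestPath)
  manifest <- data.table::fread(manifestPath, sep = "\t")
  base <- dirname(manifestPath)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    rec <- readRecording(file.path(base, manifest$path[i]))
    rec@subjectId <- as.character(manifest$subjectId[i])
    rec@condition <- as.character(manifest$condition[i])
    rec
  })
  attr(recs, "manifest") <- as.data.frame(manifest)
  recs
}
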