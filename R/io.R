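# Dataset persistence: segments (RDS array container) + CSV event sidecar
# (segment_id, class, event_kind, onset_sample, offset_sample; 0-based,
# half-open) + JSON manifest recording the conventions in force.

#' Write a dataset to a directory
#'
#' Writes `segments.rds` (the array container), `events.csv` (sidecar),
#' `manifest.json`, and optionally one EDF per the concatenated record.
#'
#' @param dataset List of [eeg_segment()] objects.
#' @param dir Output directory (created if absent).
#' @param edf Also write `record.edf` holding the concatenated segments.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, edf = FALSE) {
  check_that(length(dataset) > 0, "`dataset` must be non-empty")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(dataset, file.path(dir, "segments.rds"))
  ev <- do.call(rbind, lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    if (nrow(s$events) == 0)
      data.frame(segment_id = s$source_id, class = s$label,
                 event_kind = NA_character_, onset_sample = NA_integer_,
                 offset_sample = NA_integer_, stringsAsFactors = FALSE)
    else
      data.frame(segment_id = s$source_id, class = s$label,
                 event_kind = s$events$kind,
                 onset_sample = s$events$onset_sample,
                 offset_sample = s$events$offset_sample,
                 stringsAsFactors = FALSE)
  }))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  fs <- dataset[[1]]$fs
  manifest <- list(
    n_segments = length(dataset), fs = fs,
    segment_samples = length(dataset[[1]]$samples),
    classes = ieeg_classes(),
    class_counts = as.list(table(factor(vapply(dataset, function(s) s$label, ""),
                                        levels = ieeg_classes()))),
    event_convention = "0-based half-open sample intervals",
    spec = if (!is.null(attr(dataset, "spec"))) unclass(attr(dataset, "spec")),
    package = "ieegnet",
    version = as.character(utils::packageVersion("ieegnet")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (edf)
    write_edf(unlist(lapply(dataset, function(s) s$samples)), fs,
              file.path(dir, "record.edf"))
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return The list of [eeg_segment()] objects.
#' @export
read_dataset <- function(dir) {
  path <- file.path(dir, "segments.rds")
  check_that(file.exists(path), sprintf("`dir` %s holds no segments.rds", dir))
  readRDS(path)
}

#' Write a classification heatmap as CSV
#'
#' Columns: `sample_index` (0-based), one probability column per class.
#'
#' @param hm A `prob_heatmap`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_heatmap_csv <- function(hm, path) {
  p <- hm$probs
  df <- data.frame(sample_index = seq_len(nrow(p)) - 1L, p,
                   check.names = FALSE)
  names(df)[-1] <- paste0("p_", colnames(p))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
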