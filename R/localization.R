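#' Fraction of a feature's peaks located in open chromatin
#'
#' Presence of a chromatin feature within accessible chromatin is
#' decided by overlap (any amount, >= 1 bp) with the DHS peak set; a
#' peak overlapping several DHSs counts once.
#'
#' @param peaks a non-empty `PeakSet` for one chromatin feature.
#' @param dhs the DHS `PeakSet`.
#' @param feature_class `"HM"` or `"TF"`.
#' @return One-row `data.frame`: `feature`, `class`, `n_peaks`,
#'   `n_in_dhs`, `percent_in_dhs` (0-100).
#' @export
fraction_in_open <- function(peaks, dhs, feature_class = NA_character_) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(dhs, "PeakSet"))
  if (length(peaks) == 0L)
    stop("empty PeakSet '", peaks$name, "': percentage undefined")
  hit <- overlaps_any(peaks, dhs)
  data.frame(feature = peaks$name,
             class = feature_class,
             n_peaks = length(peaks),
             n_in_dhs = sum(hit),
             percent_in_dhs = 100 * sum(hit) / length(peaks),
             stringsAsFactors = FALSE)
}

#' Peak localization table across features, with per-class means
#'
#' Computes, for every chromatin feature, the percentage of its peaks
#' overlapping a DHS, and the unweighted arithmetic mean percentage of
#' each feature class (each feature contributes one percentage
#' regardless of its peak count).
#'
#' @param feature_peaksets list of `PeakSet` objects.
#' @param classes character vector (`"HM"`/`"TF"`), one per peak set.
#' @param dhs the DHS `PeakSet`.
#' @return A list with `table` (one row per feature, sorted by
#'   decreasing percentage) and `class_means` (named numeric).
#' @export
localization_table <- function(feature_peaksets, classes, dhs) {
  stopifnot(length(feature_peaksets) == length(classes),
            all(classes %in% c("HM", "TF")))
  rows <- mapply(function(ps, cl) fraction_in_open(ps, dhs, cl),
                 feature_peaksets, classes, SIMPLIFY = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(-tab$percent_in_dhs, tab$feature), , drop = FALSE]
  means <- vapply(split(tab$percent_in_dhs, tab$class), mean, 0)
  list(table = tab, class_means = means)
}

#' Write a localization table as TSV with a class-mean footer
#'
#' @param loc result of [localization_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_localization_table <- function(loc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  write.table(loc$table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  for (cl in names(loc$class_means))
    cat(sprintf("# mean_%s\t%.4f\n", cl, loc$class_means[[cl]]), file = con)
  invisible(path)
}
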