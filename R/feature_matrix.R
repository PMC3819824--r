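#' Build the regions-by-features signal matrix and DNase target
#'
#' For every DHS region, aggregates (max or avg) the DNase-seq signal
#' and the signal of each chromatin feature over the region. The same
#' aggregation method is applied to predictors and target, pairing
#' max-with-max and avg-with-avg. Regions are used exactly as given
#' (no resizing or merging), in sorted DHS order; features with zero
#' signal everywhere are retained as constant columns.
#'
#' @param dhs `PeakSet` of DHS regions.
#' @param dnase_track `SignalTrack` of DNase-seq signal (the target).
#' @param feature_tracks named list of `SignalTrack` objects; names (or
#'   track names) must be unique.
#' @param aggregation `"max"` or `"avg"`.
#' @return A `FeatureMatrix`: list with `region_ids`
#'   (`chrom:start-end`, 0-based half-open), `feature_names`, `X`
#'   (matrix, rows = regions), `y` (DNase vector), `aggregation`.
#' @export
build_feature_matrix <- function(dhs, dnase_track, feature_tracks,
                                 aggregation = c("max", "avg")) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(dhs, "PeakSet"), inherits(dnase_track, "SignalTrack"))
  if (length(dhs) == 0L) stop("zero DHS regions")
  nms <- names(feature_tracks)
  if (is.null(nms))
    nms <- vapply(feature_tracks, function(t) t$name, "")
  if (anyDuplicated(nms)) stop("duplicate feature names")
  df <- as.data.frame(dhs)
  region_ids <- sprintf("%s:%d-%d", df$chrom, df$start, df$end)
  X <- vapply(feature_tracks,
              function(t) aggregate_signal(t, dhs, aggregation),
              numeric(length(dhs)))
  X <- matrix(X, nrow = length(dhs),
              dimnames = list(region_ids, nms))
  y <- aggregate_signal(dnase_track, dhs, aggregation)
  feature_matrix(region_ids, nms, X, y, aggregation)
}

#' Construct a FeatureMatrix from components
#'
#' @param region_ids region identifiers, one per row.
#' @param feature_names column labels.
#' @param X numeric matrix of aggregated feature signals.
#' @param y numeric vector of aggregated DNase signals.
#' @param aggregation `"max"` or `"avg"`.
#' @return A `FeatureMatrix` object.
#' @export
feature_matrix <- function(region_ids, feature_names, X, y,
                           aggregation = c("max", "avg")) {
  aggregation <- match.arg(aggregation)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(region_ids), ncol(X) == length(feature_names),
            length(y) == length(region_ids))
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite values in feature matrix")
  if (any(X < 0) || any(y < 0))
    stop("negative aggregated signal")
  dimnames(X) <- list(region_ids, feature_names)
  structure(list(region_ids = region_ids,
                 feature_names = feature_names,
                 X = X, y = as.numeric(y), aggregation = aggregation),
            class = "FeatureMatrix")
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$X)

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d regions x %d features (aggregation = %s)\n",
              nrow(x$X), ncol(x$X), x$aggregation))
  invisible(x)
}

#' Randomly sample regions (rows) of a FeatureMatrix
#'
#' Uniform sampling without replacement of `min(n, nrow)` rows,
#' deterministic given `seed`; the pairing of each `X` row with its `y`
#' entry is preserved. If `n` meets or exceeds the number of rows, the
#' matrix is returned unchanged (original order).
#'
#' @param matrix a `FeatureMatrix`.
#' @param n number of regions to keep.
#' @param seed integer seed.
#' @return A `FeatureMatrix` with at most `n` rows.
#' @export
sample_regions <- function(matrix, n, seed) {
  stopifnot(inherits(matrix, "FeatureMatrix"), n >= 1)
  total <- nrow(matrix$X)
  if (n >= total) return(matrix)
  idx <- with_seed(seed, sort(sample.int(total, n)))
  feature_matrix(matrix$region_ids[idx], matrix$feature_names,
                 matrix$X[idx, , drop = FALSE], matrix$y[idx],
                 matrix$aggregation)
}

#' Write / read a FeatureMatrix as a tab-separated table
#'
#' Layout: a `# aggregation=<max|avg>` comment, then a header row, a
#' `region_id` column, one column per feature and a final `DNase`
#' target column.
#'
#' @param matrix a `FeatureMatrix`.
#' @param path file path.
#' @return `write_feature_matrix`: `path`, invisibly;
#'   `read_feature_matrix`: a `FeatureMatrix`.
#' @export
write_feature_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  cat(sprintf("# aggregation=%s\n", matrix$aggregation), file = con)
  df <- data.frame(region_id = matrix$region_ids,
                   matrix$X, DNase = matrix$y, check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  agg <- sub("^# aggregation=", "", first)
  if (!(agg %in% c("max", "avg")))
    stop("missing '# aggregation=' header in ", path)
  df <- read.table(path, sep = "\t", header = TRUE, skip = 1L,
                   check.names = FALSE, comment.char = "")
  nc <- ncol(df)
  feature_matrix(df$region_id, colnames(df)[2:(nc - 1L)],
                 as.matrix(df[, 2:(nc - 1L), drop = FALSE]),
                 df[[nc]], agg)
}
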