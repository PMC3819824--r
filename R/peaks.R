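#' Peak sets: genomic locations of a chromatin feature
#'
#' A `PeakSet` holds the peak intervals of one chromatin feature (or the
#' DHS regions themselves) as a sorted [GenomicRanges::GRanges].
#' Coordinates at the interface are BED-convention: 0-based, half-open
#' `[start, end)`; internally a 1-based closed `GRanges` is kept so all
#' Bioconductor interval machinery applies. Intervals are stored as
#' given (sorted, never merged).
#'
#' @param name feature label.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return An object of class `PeakSet` with elements `name` and `gr`.
#' @examples
#' ps <- peak_set("H3k4me3", c("chr1", "chr1"), c(100, 500), c(300, 900))
#' length(ps)
#' @export
peak_set <- function(name, chrom = character(), start = integer(),
                     end = integer()) {
  stopifnot(is.character(name), length(name) == 1L,
            length(chrom) == length(start), length(start) == length(end))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("interval with start >= end")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end))
  gr <- GenomicRanges::sort(gr)
  structure(list(name = name, gr = gr), class = "PeakSet")
}

peak_set_from_granges <- function(name, gr) {
  structure(list(name = name, gr = GenomicRanges::sort(gr)),
            class = "PeakSet")
}

#' @export
length.PeakSet <- function(x) length(x$gr)

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d intervals on %d chromosome(s)\n",
              x$name, length(x$gr),
              length(GenomicRanges::seqnames(GenomicRanges::seqinfo(x$gr)))))
  invisible(x)
}

#' Data-frame view of a PeakSet (0-based half-open coordinates)
#'
#' @param x a `PeakSet`.
#' @param ... unused.
#' @return `data.frame` with columns `chrom`, `start`, `end`.
#' @export
as.data.frame.PeakSet <- function(x, ...) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x$gr)),
             start = GenomicRanges::start(x$gr) - 1L,
             end = GenomicRanges::end(x$gr),
             stringsAsFactors = FALSE)
}

#' Read a BED file into a PeakSet
#'
#' Accepts >= 3 whitespace/tab-separated columns; extra columns are
#' ignored. `track`, `browser` and `#` comment lines are skipped.
#' Malformed coordinates (non-integer, `start >= end`) raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @param name feature label; defaults to the file base name.
#' @return A sorted `PeakSet` (possibly empty).
#' @export
read_bed <- function(path, name = sub("\\.bed$", "", basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(peak_set(name))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", idx[which(nf < 3L)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("line ", idx[bad[1]], ": non-integer coordinate")
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("line ", idx[bad[1]], ": invalid interval (start >= end or start < 0)")
  peak_set(name, chrom, start, end)
}

#' Write a PeakSet as a 3-column BED file
#'
#' @param x a `PeakSet`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "PeakSet"))
  df <- as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Does each query interval overlap any target interval?
#'
#' Overlap means at least one shared base under half-open arithmetic:
#' touching intervals (`[a,b)` vs `[b,c)`) do not overlap. Backed by
#' the interval-tree machinery of GenomicRanges (no full scan).
#'
#' @param query a `PeakSet` or `GRanges` of query intervals.
#' @param targets a `PeakSet` or `GRanges` of sorted target intervals.
#' @return Logical vector, one element per query interval.
#' @export
overlaps_any <- function(query, targets) {
  qgr <- if (inherits(query, "PeakSet")) query$gr else query
  tgr <- if (inherits(targets, "PeakSet")) targets$gr else targets
  # disjoint chromosome sets are a normal "no overlap" case, not a
  # seqlevel mismatch worth warning about
  suppressWarnings(IRanges::overlapsAny(qgr, tgr, minoverlap = 1L))
}
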