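#' Signal tracks: piecewise-constant per-base sequencing signal
#'
#' A `SignalTrack` stores bedGraph-semantics signal: sorted,
#' non-overlapping segments each carrying a non-negative value; any base
#' not covered by a segment has value exactly 0 (sequencing-coverage
#' semantics, not missing data). Segment coordinates at the interface
#' are 0-based half-open.
#'
#' @param name track label.
#' @param chrom,start,end segment coordinates (0-based half-open).
#' @param value non-negative signal values, one per segment.
#' @return An object of class `SignalTrack` with elements `name` and
#'   `gr` (a `GRanges` with a `score` column).
#' @export
signal_track <- function(name, chrom = character(), start = integer(),
                         end = integer(), value = numeric()) {
  stopifnot(is.character(name), length(name) == 1L,
            length(chrom) == length(start), length(start) == length(end),
            length(end) == length(value))
  start <- as.numeric(start); end <- as.numeric(end)
  value <- as.numeric(value)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("segment with start >= end")
  if (any(!is.finite(value))) stop("non-finite signal value")
  if (any(value < 0)) stop("negative signal value")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               score = value)
  gr <- GenomicRanges::sort(gr)
  if (!GenomicRanges::isDisjoint(gr)) stop("overlapping signal segments")
  structure(list(name = name, gr = gr), class = "SignalTrack")
}

#' @export
length.SignalTrack <- function(x) length(x$gr)

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf("SignalTrack '%s': %d segments, total covered %g bp\n",
              x$name, length(x$gr), sum(GenomicRanges::width(x$gr))))
  invisible(x)
}

#' @export
as.data.frame.SignalTrack <- function(x, ...) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(x$gr)),
             start = GenomicRanges::start(x$gr) - 1L,
             end = GenomicRanges::end(x$gr),
             value = S4Vectors::mcols(x$gr)$score,
             stringsAsFactors = FALSE)
}

#' Read a signal track from bedGraph or wiggle text
#'
#' bedGraph lines are `chrom start end value` (0-based half-open).
#' Wiggle `fixedStep`/`variableStep` blocks follow the UCSC standard
#' (1-based, inclusive; `span` defaults to 1) and are converted to the
#' internal 0-based half-open convention on read. `track`, `browser`
#' and `#` lines are skipped. Overlapping segments and negative values
#' are errors (overlap would make the per-base signal ambiguous).
#'
#' @param path file path.
#' @param dialect `"bedgraph"` or `"wiggle"`.
#' @param name track label; defaults to the file base name.
#' @return A `SignalTrack`.
#' @export
read_signal_track <- function(path, dialect = c("bedgraph", "wiggle"),
                              name = sub("\\.(bedgraph|bdg|wig)$", "",
                                         basename(path))) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  if (dialect == "bedgraph") {
    if (length(lines) == 0L)
      return(signal_track(name))
    fields <- strsplit(trimws(lines), "[ \t]+")
    if (any(lengths(fields) < 4L))
      stop("bedGraph line with fewer than 4 fields")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- as.numeric(vapply(fields, `[[`, "", 2L))
    end <- as.numeric(vapply(fields, `[[`, "", 3L))
    value <- as.numeric(vapply(fields, `[[`, "", 4L))
    if (any(!is.finite(start) | !is.finite(end)))
      stop("malformed bedGraph coordinate")
    return(signal_track(name, chrom, start, end, value))
  }
  parse_kv <- function(line) {
    kv <- regmatches(line, gregexpr("[A-Za-z]+=[^ \t]+", line))[[1]]
    vals <- sub("^[A-Za-z]+=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    vals
  }
  chrom <- character(); start <- numeric(); end <- numeric()
  value <- numeric()
  mode <- NULL; cur_chrom <- NULL; cur_pos <- NULL
  cur_step <- NULL; cur_span <- 1
  for (line in trimws(lines)) {
    if (grepl("^fixedStep\\b", line)) {
      kv <- parse_kv(line)
      if (!all(c("chrom", "start", "step") %in% names(kv)))
        stop("fixedStep declaration missing chrom/start/step")
      mode <- "fixed"; cur_chrom <- kv[["chrom"]]
      cur_pos <- as.numeric(kv[["start"]]) - 1  # to 0-based
      cur_step <- as.numeric(kv[["step"]])
      cur_span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
    } else if (grepl("^variableStep\\b", line)) {
      kv <- parse_kv(line)
      if (!("chrom" %in% names(kv)))
        stop("variableStep declaration missing chrom")
      mode <- "variable"; cur_chrom <- kv[["chrom"]]
      cur_span <- if ("span" %in% names(kv)) as.numeric(kv[["span"]]) else 1
    } else if (is.null(mode)) {
      stop("wiggle data line before any step declaration")
    } else if (mode == "fixed") {
      v <- as.numeric(line)
      if (!is.finite(v)) stop("malformed fixedStep value: ", line)
      chrom <- c(chrom, cur_chrom); start <- c(start, cur_pos)
      end <- c(end, cur_pos + cur_span); value <- c(value, v)
      cur_pos <- cur_pos + cur_step
    } else {
      f <- strsplit(line, "[ \t]+")[[1]]
      if (length(f) != 2L) stop("malformed variableStep line: ", line)
      pos <- as.numeric(f[1]) - 1  # to 0-based
      v <- as.numeric(f[2])
      if (!is.finite(pos) || !is.finite(v))
        stop("malformed variableStep line: ", line)
      chrom <- c(chrom, cur_chrom); start <- c(start, pos)
      end <- c(end, pos + cur_span); value <- c(value, v)
    }
  }
  signal_track(name, chrom, start, end, value)
}

#' Write a SignalTrack as bedGraph (6 significant digits)
#'
#' @param x a `SignalTrack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  stopifnot(inherits(x, "SignalTrack"))
  df <- as.data.frame(x)
  out <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                 as.integer(df$end), formatC(df$value, digits = 6,
                                             format = "g"))
  writeLines(out, path)
  invisible(path)
}

#' Aggregate a signal track over regions
#'
#' For each region, `max` is the maximum per-base value over all bases
#' of the region (uncovered bases count as 0) and `avg` is the
#' base-weighted mean (uncovered bases contribute 0). A region with no
#' overlapping segment yields 0 under both methods. Because values are
#' non-negative, `max >= avg` always holds.
#'
#' @param track a `SignalTrack`.
#' @param regions a `PeakSet` or `GRanges` of regions.
#' @param method `"max"` or `"avg"`.
#' @return Numeric vector, one value per region.
#' @export
aggregate_signal <- function(track, regions, method = c("max", "avg")) {
  method <- match.arg(method)
  stopifnot(inherits(track, "SignalTrack"))
  rgr <- if (inherits(regions, "PeakSet")) regions$gr else regions
  tgr <- track$gr
  out <- numeric(length(rgr))
  # suppress the benign seqlevels-in-common warning: a region on a
  # chromosome the track never covers simply aggregates to 0
  hits <- suppressWarnings(GenomicRanges::findOverlaps(rgr, tgr))
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  inter <- GenomicRanges::pintersect(rgr[q], tgr[s])
  w <- GenomicRanges::width(inter)
  v <- S4Vectors::mcols(tgr)$score[s]
  if (method == "max") {
    agg <- tapply(v, q, max)
  } else {
    agg <- tapply(v * w, q, sum)
    agg <- agg / GenomicRanges::width(rgr)[as.integer(names(agg))]
  }
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}
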