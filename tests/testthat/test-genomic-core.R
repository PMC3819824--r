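test_that("read_bed parses, sorts, skips headers and ignores extra columns", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "# a comment",
               "chr1\t20\t30\tpeakB\t7",
               "chr1 0 10",
               "chr2\t5\t8"), f)
  ps <- read_bed(f, "demo")
  expect_s3_class(ps, "PeakSet")
  expect_equal(length(ps), 3L)
  df <- as.data.frame(ps)
  expect_equal(df$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(df$start, c(0, 20, 5))
  expect_equal(df$end, c(10, 30, 8))
})

test_that("read_bed handles empty files and names bad lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(character(), f)
  expect_equal(length(read_bed(f)), 0L)

  writeLines(c("chr1 0 10", "chr1 30 20"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1 0 ten"), f)
  expect_error(read_bed(f), "line 1")
  writeLines(c("chr1 5"), f)
  expect_error(read_bed(f), "fewer than 3")
})

test_that("PeakSet round-trips through BED", {
  ps <- peak_set("x", c("chr2", "chr1", "chr1"), c(5, 20, 0), c(8, 30, 10))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(ps, f)
  expect_equal(as.data.frame(read_bed(f, "x")), as.data.frame(ps))
})

test_that("bedGraph reader: values, overlap and negative-value errors", {
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeLines(c("track type=bedGraph", "chr1 0 5 10.0", "chr1 5 10 2.0"), f)
  tr <- read_signal_track(f, "bedgraph")
  expect_equal(length(tr), 2L)
  # value at base 7 via a 1-bp region
  expect_equal(aggregate_signal(tr, peak_set("q", "chr1", 7, 8), "max"), 2.0)

  writeLines(c("chr1 0 5 1", "chr1 3 8 1"), f)
  expect_error(read_signal_track(f, "bedgraph"), "overlap")
  writeLines(c("chr1 0 5 -1"), f)
  expect_error(read_signal_track(f, "bedgraph"), "negative")
})

test_that("wiggle reader converts 1-based declarations to 0-based", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1", "3", "4"), f)
  df <- as.data.frame(read_signal_track(f, "wiggle"))
  expect_equal(df$start, c(0, 1))
  expect_equal(df$end, c(1, 2))
  expect_equal(df$value, c(3, 4))

  writeLines(c("fixedStep chrom=chr1 start=11 step=20 span=5",
               "1.5", "2.5"), f)
  df <- as.data.frame(read_signal_track(f, "wiggle"))
  expect_equal(df$start, c(10, 30))
  expect_equal(df$end, c(15, 35))

  writeLines(c("variableStep chrom=chr2 span=3", "11 7.0", "21 8.0"), f)
  df <- as.data.frame(read_signal_track(f, "wiggle"))
  expect_equal(df$start, c(10, 20))
  expect_equal(df$end, c(13, 23))
  expect_equal(df$value, c(7, 8))

  writeLines(c("5 1.0"), f)
  expect_error(read_signal_track(f, "wiggle"), "declaration")
})

test_that("SignalTrack round-trips through bedGraph", {
  tr <- signal_track("t", c("chr1", "chr1", "chr2"), c(0, 10, 3),
                     c(5, 20, 9), c(1.25, 3.5, 0.125))
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  expect_equal(as.data.frame(read_signal_track(f, "bedgraph", "t")),
               as.data.frame(tr))
})

test_that("aggregate_signal matches hand examples", {
  tr <- signal_track("t", "c1", 0, 100, 5.0)
  reg <- peak_set("r", "c1", 10, 40)
  expect_equal(aggregate_signal(tr, reg, "max"), 5.0)
  expect_equal(aggregate_signal(tr, reg, "avg"), 5.0)

  # half-covered region: max keeps the height, avg dilutes by coverage
  tr2 <- signal_track("t2", "c1", 0, 5, 10.0)
  reg2 <- peak_set("r2", "c1", 0, 10)
  expect_equal(aggregate_signal(tr2, reg2, "max"), 10.0)
  expect_equal(aggregate_signal(tr2, reg2, "avg"), 5.0)

  # uncovered region
  reg3 <- peak_set("r3", "c1", 500, 600)
  expect_equal(aggregate_signal(tr2, reg3, "max"), 0)
  expect_equal(aggregate_signal(tr2, reg3, "avg"), 0)
})

test_that("aggregation agrees with the per-base oracle on random tracks", {
  set.seed(101)
  L <- 2000
  for (rep in 1:100) {
    tr <- random_track(sample(1:8, 1), L)
    qs <- sort(sample(0:(L - 1), 2))
    if (qs[1] == qs[2]) qs[2] <- qs[2] + 1
    reg <- peak_set("q", "c1", qs[1], qs[2])
    v <- brute_signal_vector(tr, "c1", qs[1], qs[2])
    mx <- aggregate_signal(tr, reg, "max")
    av <- aggregate_signal(tr, reg, "avg")
    expect_equal(mx, max(v))
    expect_equal(av, mean(v))
    expect_gte(mx, av)
  }
})

test_that("overlaps_any: half-open semantics and per-base oracle", {
  targets <- peak_set("t", c("c1", "c1"), c(19, 20), c(25, 30))
  # one shared base ([19,20) vs [19,25)) is an overlap
  expect_true(overlaps_any(peak_set("q", "c1", 10, 20), targets))
  # touching intervals do not overlap
  expect_false(overlaps_any(peak_set("q", "c1", 10, 20),
                            peak_set("t", "c1", 20, 30)))

  set.seed(77)
  L <- 10000
  ts <- sort(sample(0:(L - 1), 60)); te <- pmin(ts + sample(1:50, 60, TRUE), L)
  keep <- ts < te
  tgt <- peak_set("t", rep("c1", sum(keep)), ts[keep], te[keep])
  qs <- sort(sample(0:(L - 2), 200)); qe <- pmin(qs + sample(1:80, 200, TRUE), L)
  qry <- peak_set("q", rep("c1", 200), qs, qe)
  got <- overlaps_any(qry, tgt)
  # oracle works on the sorted coordinates used internally
  qdf <- as.data.frame(qry); tdf <- as.data.frame(tgt)
  want <- brute_overlaps(qdf$start, qdf$end, tdf$start, tdf$end, L)
  expect_equal(got, want)
})

test_that("constructors enforce invariants", {
  expect_error(peak_set("x", "c1", 10, 10), "start >= end")
  expect_error(peak_set("x", "c1", -1, 5), "negative")
  expect_error(signal_track("t", c("c1", "c1"), c(0, 3), c(5, 8), c(1, 1)),
               "overlap")
  expect_error(signal_track("t", "c1", 0, 5, NaN), "non-finite")
})
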