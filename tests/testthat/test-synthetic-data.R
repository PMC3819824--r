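small_cfg <- function(seed = 1, feats = list(
  feature_spec("fa", "HM", beta = 1, tau = 0, latent_share = 1,
               p_in_dhs = 1, n_peaks = 50)), ...) {
  synthetic_config(seed = seed, chrom_length = 1e6, n_dhs = 100,
                   features = feats, ...)
}

test_that("simulate_regions places non-overlapping regions,
           deterministically", {
  cfg <- small_cfg()
  reg <- simulate_regions(cfg)
  expect_equal(length(reg$dhs), 100L)
  df <- as.data.frame(reg$dhs)
  expect_true(all(df$start[-1] >= df$end[-nrow(df)])) # no overlap
  expect_true(all(df$end <= cfg$chrom_length))
  expect_identical(reg, simulate_regions(cfg))

  cfg2 <- small_cfg(seed = 2)
  expect_false(identical(as.data.frame(simulate_regions(cfg2)$dhs), df))

  # degenerate latent distribution
  cfg3 <- small_cfg(latent_sigma = 0, latent_mu = 1.5)
  expect_equal(simulate_regions(cfg3)$latents, rep(exp(1.5), 100))

  expect_error(synthetic_config(chrom_length = 1e4, n_dhs = 100),
               "n_dhs")
})

test_that("noise-free unit-link feature track mirrors the DNase track", {
  cfg <- small_cfg(dnase_noise_sd = 0)
  reg <- simulate_regions(cfg)
  sig <- simulate_signal_tracks(reg$dhs, reg$latents, cfg)
  mx_f <- aggregate_signal(sig$feature_tracks$fa, reg$dhs, "max")
  mx_d <- aggregate_signal(sig$dnase_track, reg$dhs, "max")
  expect_equal(mx_f, mx_d, tolerance = 1e-12)
  expect_equal(mx_d, reg$latents, tolerance = 1e-12)
})

test_that("bump closed form: apex equals height, integral is half
           base-times-height", {
  # fixed region length 400, bump width exactly half the region
  cfg <- small_cfg(dnase_noise_sd = 0, dhs_length_range = c(400L, 400L),
                   bump_frac_range = c(0.5, 0.5))
  reg <- simulate_regions(cfg)
  sig <- simulate_signal_tracks(reg$dhs, reg$latents, cfg)
  mx <- aggregate_signal(sig$dnase_track, reg$dhs, "max")
  av <- aggregate_signal(sig$dnase_track, reg$dhs, "avg")
  expect_equal(mx, reg$latents, tolerance = 1e-12)
  expect_equal(av, mx / 4, tolerance = 1e-9)
})

test_that("generated tracks satisfy the signal-track invariants", {
  cfg <- default_paper_like_config(seed = 3, n_dhs = 150, n_peaks = 100)
  ds <- simulate_dataset(cfg)
  for (tr in c(list(ds$dnase_track), ds$feature_tracks[1:4])) {
    gr <- tr$gr
    expect_true(GenomicRanges::isDisjoint(gr))
    expect_false(is.unsorted(GenomicRanges::start(gr)))
    expect_true(all(S4Vectors::mcols(gr)$score >= 0))
  }
})

test_that("a null feature's max signal is uncorrelated with accessibility", {
  cfg <- synthetic_config(seed = 13, chrom_length = 8e6, n_dhs = 2000,
                          features = list(
                            feature_spec("null", "TF", beta = 0, tau = 0.6,
                                         latent_share = 0, n_peaks = 50)))
  reg <- simulate_regions(cfg)
  sig <- simulate_signal_tracks(reg$dhs, reg$latents, cfg)
  mx_f <- aggregate_signal(sig$feature_tracks$null, reg$dhs, "max")
  mx_d <- aggregate_signal(sig$dnase_track, reg$dhs, "max")
  expect_lt(abs(cor(mx_f, mx_d)), 0.1)
})

test_that("simulate_peaks hits configured in-DHS rates at the extremes
           and in between", {
  feats <- list(
    feature_spec("all_in", "HM", p_in_dhs = 1, n_peaks = 300),
    feature_spec("all_out", "HM", p_in_dhs = 0, n_peaks = 300),
    feature_spec("mid", "TF", p_in_dhs = 0.6, n_peaks = 5000))
  cfg <- synthetic_config(seed = 23, chrom_length = 2e6, n_dhs = 200,
                          features = feats)
  reg <- simulate_regions(cfg)
  peaks <- simulate_peaks(reg$dhs, cfg)
  loc <- localization_table(peaks, c("HM", "HM", "TF"), reg$dhs)
  p <- setNames(loc$table$percent_in_dhs, loc$table$feature)
  expect_equal(unname(p["all_in"]), 100)
  expect_equal(unname(p["all_out"]), 0)
  expect_lt(abs(p[["mid"]] - 60), 2)
})

test_that("default world: 33 features (10 HM + 23 TF), TF localization
           above HM, config round-trips", {
  cfg <- default_paper_like_config()
  cls <- vapply(cfg$features, function(f) f$class, "")
  expect_equal(length(cfg$features), 33L)
  expect_equal(sum(cls == "HM"), 10L)
  expect_equal(sum(cls == "TF"), 23L)
  p_in <- vapply(cfg$features, function(f) f$p_in_dhs, 0)
  expect_gt(mean(p_in[cls == "TF"]), mean(p_in[cls == "HM"]))
  expect_true(all(p_in >= 0.06 & p_in <= 0.825))
  # at least one pure-noise feature for null-behaviour checks
  expect_gte(sum(vapply(cfg$features, function(f) !f$informative, TRUE)), 1L)

  f <- withr::local_tempfile(fileext = ".json")
  write_synthetic_config(cfg, f)
  expect_equal(read_synthetic_config(f), cfg)
})

test_that("full simulation is deterministic given config and seed", {
  cfg <- small_cfg(feats = list(
    feature_spec("fa", "HM", p_in_dhs = 0.5, n_peaks = 100),
    feature_spec("fb", "TF", beta = 0.5, tau = 0.4, latent_share = 0.7,
                 p_in_dhs = 0.3, n_peaks = 100)))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(as.data.frame(d1$dnase_track),
                   as.data.frame(d2$dnase_track))
  expect_identical(as.data.frame(d1$feature_tracks$fb),
                   as.data.frame(d2$feature_tracks$fb))
  expect_identical(as.data.frame(d1$peaksets$fa),
                   as.data.frame(d2$peaksets$fa))
})
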