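#' Specification of one synthetic chromatin feature
#'
#' Describes how a feature's ChIP-seq-like signal and peaks are
#' generated. Informative features read a latent per-DHS accessibility
#' value through a monotone power link with multiplicative log-normal
#' noise; `latent_share` mixes the shared accessibility latent with a
#' feature-private latent (high share across several features creates
#' redundancy); `beta = 0` gives a pure-noise feature whose signal is
#' independent of accessibility.
#'
#' @param name feature label.
#' @param class `"HM"` or `"TF"`.
#' @param beta link exponent (signal height ~ latent^beta); 0 = null.
#' @param tau multiplicative log-noise scale on the signal height.
#' @param latent_share weight in `[0,1]` on the shared accessibility
#'   latent versus a feature-private latent.
#' @param p_in_dhs probability a peak falls inside a DHS.
#' @param n_peaks number of peaks to simulate.
#' @param scale multiplicative height scale (arbitrary signal units).
#' @return A `FeatureSpec` list.
#' @export
feature_spec <- function(name, class = c("HM", "TF"), beta = 1, tau = 0.3,
                         latent_share = 1, p_in_dhs = 0.5,
                         n_peaks = 2000L, scale = 1) {
  class <- match.arg(class)
  stopifnot(p_in_dhs >= 0, p_in_dhs <= 1, latent_share >= 0,
            latent_share <= 1, tau >= 0, scale > 0)
  structure(list(name = name, class = class, beta = beta, tau = tau,
                 latent_share = latent_share, p_in_dhs = p_in_dhs,
                 n_peaks = as.integer(n_peaks), scale = scale,
                 informative = beta != 0),
            class = "FeatureSpec")
}

#' Configuration of the synthetic DHS world
#'
#' One synthetic chromosome carries `n_dhs` non-overlapping DHS
#' regions. Each DHS i has a latent accessibility
#' `a_i ~ LogNormal(latent_mu, latent_sigma)` that drives the DNase
#' signal directly and each informative feature's signal through its
#' [feature_spec()] link. Within a DHS every track is a unimodal
#' staircase "bump" whose apex equals the sampled height exactly and
#' whose integral equals height * width / 2 (a discretized triangle),
#' so per-region max reads the height cleanly while per-region avg is
#' additionally diluted by the randomized bump-width/region-length
#' ratio -- which is what makes max the better readout by construction.
#'
#' @param seed integer seed.
#' @param chrom_length chromosome length in bases.
#' @param n_dhs number of DHS regions.
#' @param dhs_length_range `(min, max)` DHS length in bases.
#' @param latent_mu,latent_sigma log-normal parameters of `a_i`.
#' @param features list of [feature_spec()] objects (unique names).
#' @param dnase_noise_sd multiplicative log-noise on the DNase height.
#' @param bump_frac_range `(min, max)` bump width as a fraction of the
#'   region length, drawn independently per region and per track.
#' @param bump_segments segments per bump staircase (odd).
#' @param peak_length_range `(min, max)` simulated peak length.
#' @param background_height background bump height outside DHSs; 0
#'   disables background (the analysis only reads signal inside DHSs).
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed = 1L, chrom_length = 2e6, n_dhs = 500L,
                             dhs_length_range = c(200L, 1000L),
                             latent_mu = 2, latent_sigma = 0.8,
                             features = list(),
                             dnase_noise_sd = 0.25,
                             bump_frac_range = c(0.3, 0.9),
                             bump_segments = 9L,
                             peak_length_range = c(150L, 500L),
                             background_height = 0) {
  stopifnot(latent_sigma >= 0, dnase_noise_sd >= 0,
            n_dhs * max(dhs_length_range) < chrom_length,
            bump_frac_range[1] > 0, bump_frac_range[2] <= 1,
            bump_segments %% 2 == 1)
  nms <- vapply(features, function(f) f$name, "")
  if (anyDuplicated(nms)) stop("duplicate feature names")
  structure(list(seed = as.integer(seed), chrom = "chrS",
                 chrom_length = chrom_length, n_dhs = as.integer(n_dhs),
                 dhs_length_range = dhs_length_range,
                 latent_mu = latent_mu, latent_sigma = latent_sigma,
                 features = features, dnase_noise_sd = dnase_noise_sd,
                 bump_frac_range = bump_frac_range,
                 bump_segments = as.integer(bump_segments),
                 peak_length_range = peak_length_range,
                 background_height = background_height),
            class = "SyntheticConfig")
}

#' Simulate non-overlapping DHS regions and their latent accessibility
#'
#' Region lengths are uniform in the configured range; placements are
#' uniform via random gap spacings (guaranteeing non-overlap without
#' rejection). Latents are i.i.d. log-normal.
#'
#' @param config a [synthetic_config()].
#' @return List with `dhs` (a `PeakSet`) and `latents` (per-region
#'   `a_i`, aligned with the sorted regions).
#' @export
simulate_regions <- function(config) {
  with_seed(config$seed, {
    n <- config$n_dhs
    rng <- config$dhs_length_range
    len <- rng[1] + sample.int(rng[2] - rng[1] + 1L, n, replace = TRUE) - 1L
    slack <- config$chrom_length - sum(len)
    if (slack <= n) stop("genome too crowded to place regions")
    g <- runif(n + 1)
    gaps <- floor(g / sum(g) * slack)
    start <- cumsum(gaps[seq_len(n)]) + cumsum(c(0, len[-n]))
    latents <- rlnorm(n, config$latent_mu, config$latent_sigma)
    dhs <- peak_set("DHS", rep(config$chrom, n), start, start + len)
    # regions were generated in coordinate order, so latents stay aligned
    list(dhs = dhs, latents = latents)
  })
}

# Exact triangle integral: J(x) = int_0^x (1 - |2t/w - 1|) dt, 0<=x<=w
.tri_cum <- function(x, w) {
  ifelse(x <= w / 2, x^2 / w, 2 * x - x^2 / w - w / 2)
}

# Staircase-triangle bump over [0, w): `m` integer segments whose apex
# value is exactly `h` and whose total integral is exactly h*w/2.
# Returns matrix with columns rel_start, rel_end, value.
.bump_profile <- function(w, h, m) {
  if (w < 2 * m) return(cbind(0, w, h))
  br <- round(seq(0, w, length.out = m + 1))
  a <- br[-(m + 1)]; b <- br[-1]
  v <- h * (.tri_cum(b, w) - .tri_cum(a, w)) / (b - a)
  apex <- (m + 1) %/% 2
  target <- h * w / 2 - h * (b[apex] - a[apex])
  rest <- sum(v[-apex] * (b - a)[-apex])
  v[-apex] <- if (rest > 0) v[-apex] * target / rest else v[-apex]
  v[apex] <- h
  cbind(a, b, v)
}

#' Simulate DNase and feature signal tracks over the DHS regions
#'
#' Within DHS i each track is one bump; its height is
#' `scale * u_i^beta * exp(eps)`, `eps ~ N(0, tau^2)`, with effective
#' latent `u_i = latent_share * a_i + (1 - latent_share) * b_i` (`b_i`
#' a feature-private log-normal draw). The DNase height is
#' `a_i * exp(N(0, dnase_noise_sd^2))`. Bump widths are drawn per
#' region and per track. Optional low flat background bumps are placed
#' in inter-DHS gaps when `background_height > 0`.
#'
#' @param dhs `PeakSet` from [simulate_regions()].
#' @param latents aligned latent vector from [simulate_regions()].
#' @param config a [synthetic_config()].
#' @return List with `dnase_track` and named list `feature_tracks`.
#' @export
simulate_signal_tracks <- function(dhs, latents, config) {
  df <- as.data.frame(dhs)
  n <- nrow(df)
  stopifnot(length(latents) == n)
  m <- config$bump_segments

  build_track <- function(name, heights) {
    frac <- runif(n, config$bump_frac_range[1], config$bump_frac_range[2])
    w <- pmax(1, round(frac * (df$end - df$start)))
    off <- df$start + floor(((df$end - df$start) - w) / 2)
    segs <- lapply(seq_len(n), function(i) {
      p <- .bump_profile(w[i], heights[i], m)
      keep <- p[, 2] > p[, 1]
      cbind(off[i] + p[keep, 1], off[i] + p[keep, 2], p[keep, 3])
    })
    segs <- do.call(rbind, segs)
    if (config$background_height > 0) {
      gap_start <- c(0, df$end)
      gap_end <- c(df$start, config$chrom_length)
      ok <- which(gap_end - gap_start >= 400)
      bw <- pmin(200, (gap_end - gap_start)[ok] - 2)
      bs <- gap_start[ok] + 1
      segs <- rbind(segs, cbind(bs, bs + bw,
                                config$background_height *
                                  rlnorm(length(ok), 0, 0.5)))
    }
    signal_track(name, rep(config$chrom, nrow(segs)),
                 segs[, 1], segs[, 2], segs[, 3])
  }

  with_seed(derive_seed(config$seed, "tracks"), {
    dnase_h <- latents * exp(rnorm(n, 0, config$dnase_noise_sd))
    dnase <- build_track("DNase", dnase_h)
    tracks <- lapply(config$features, function(fs) {
      priv <- rlnorm(n, config$latent_mu, config$latent_sigma)
      u <- fs$latent_share * latents + (1 - fs$latent_share) * priv
      h <- fs$scale * u^fs$beta * exp(rnorm(n, 0, fs$tau))
      build_track(fs$name, h)
    })
    names(tracks) <- vapply(config$features, function(f) f$name, "")
    list(dnase_track = dnase, feature_tracks = tracks)
  })
}

#' Simulate per-feature peak sets with controlled in-DHS fractions
#'
#' Each peak lands inside a uniformly chosen DHS with probability
#' `p_in_dhs` (placed fully inside, guaranteeing overlap), otherwise
#' uniformly (base-weighted) in an inter-DHS gap, never touching a DHS.
#' Peak lengths are uniform in the configured range, clipped to fit.
#'
#' @param dhs `PeakSet` of DHS regions.
#' @param config a [synthetic_config()].
#' @return Named list of `PeakSet`, one per feature.
#' @export
simulate_peaks <- function(dhs, config) {
  df <- as.data.frame(dhs)
  gaps <- data.frame(start = c(0, df$end),
                     end = c(df$start, config$chrom_length))
  gaps <- gaps[gaps$end - gaps$start > 2, , drop = FALSE]
  if (nrow(gaps) == 0L) stop("no gap space available between DHSs")
  lr <- config$peak_length_range
  with_seed(derive_seed(config$seed, "peaks"), {
    out <- lapply(config$features, function(fs) {
      np <- fs$n_peaks
      inside <- runif(np) < fs$p_in_dhs
      len <- lr[1] + sample.int(lr[2] - lr[1] + 1L, np, replace = TRUE) - 1L
      start <- numeric(np); end <- numeric(np)
      n_in <- sum(inside)
      if (n_in > 0) {
        ri <- sample.int(nrow(df), n_in, replace = TRUE)
        l <- pmin(len[inside], df$end[ri] - df$start[ri])
        s <- df$start[ri] +
          floor(runif(n_in) * (df$end[ri] - df$start[ri] - l + 1))
        start[inside] <- s; end[inside] <- s + l
      }
      n_out <- np - n_in
      if (n_out > 0) {
        gw <- gaps$end - gaps$start
        gi <- sample.int(nrow(gaps), n_out, replace = TRUE, prob = gw)
        l <- pmin(len[!inside], gaps$end[gi] - gaps$start[gi] - 2)
        s <- gaps$start[gi] + 1 +
          floor(runif(n_out) * (gaps$end[gi] - gaps$start[gi] - l - 1))
        start[!inside] <- s; end[!inside] <- s + l
      }
      peak_set(fs$name, rep(config$chrom, np), start, end)
    })
    names(out) <- vapply(config$features, function(f) f$name, "")
    out
  })
}

#' Default synthetic world echoing the real 33-feature design
#'
#' 33 features (10 histone modifications, 23 transcription factors):
#' a few strongly informative, highly shared features (H3k4me2/H3k4me3/
#' H3k9ac-like), many moderately informative redundant features,
#' several weakly informative features (H3k9me3/H3k36me3-like) and two
#' pure-noise features (`beta = 0`) so null behaviour is testable.
#' In-DHS peak probabilities are spread over roughly 0.06-0.82 with the
#' TF class mean above the HM class mean.
#'
#' @param seed integer seed.
#' @param n_dhs number of DHS regions (default 6000).
#' @param n_peaks peaks per feature (default 2000).
#' @return A `SyntheticConfig`.
#' @export
default_paper_like_config <- function(seed = 1L, n_dhs = 6000L,
                                      n_peaks = 2000L) {
  hm <- list(
    #            name        beta tau  share p_in
    c("H3k4me2",  1.00, 0.48, 0.86, 0.75),
    c("H3k4me3",  1.05, 0.50, 0.85, 0.822),
    c("H3k9ac",   0.95, 0.52, 0.84, 0.70),
    c("H3k27ac",  0.90, 0.60, 0.76, 0.50),
    c("H2az",     0.85, 0.62, 0.74, 0.48),
    c("H3k4me1",  0.80, 0.65, 0.70, 0.45),
    c("H4k20me1", 0.60, 0.70, 0.62, 0.30),
    c("H3k27me3", 0.55, 0.75, 0.58, 0.25),
    c("H3k9me3",  0.50, 0.80, 0.58, 0.063),
    c("H3k36me3", 0.45, 0.85, 0.52, 0.18))
  hm_names <- c("H3k4me2", "H3k4me3", "H3k9ac", "H3k27ac", "H2az",
                "H3k4me1", "H4k20me1", "H3k27me3", "H3k9me3", "H3k36me3")
  tf <- list(
    c("SIN3A",  1.00, 0.50, 0.85, 0.78),
    c("ZNF143", 1.00, 0.52, 0.84, 0.76),
    c("TAF1",   0.95, 0.52, 0.83, 0.80),
    c("POL2",   0.90, 0.55, 0.82, 0.78),
    c("NANOG",  0.90, 0.55, 0.80, 0.70),
    c("POU5F1", 0.85, 0.56, 0.80, 0.72),
    c("SOX2",   0.85, 0.58, 0.78, 0.68),
    c("MYC",    0.80, 0.58, 0.78, 0.66),
    c("MAX",    0.80, 0.60, 0.76, 0.64),
    c("EGR1",   0.75, 0.60, 0.76, 0.62),
    c("GABP",   0.75, 0.62, 0.74, 0.62),
    c("SP1",    0.70, 0.62, 0.74, 0.60),
    c("YY1",    0.70, 0.64, 0.72, 0.58),
    c("USF1",   0.70, 0.64, 0.71, 0.58),
    c("TCF12",  0.65, 0.66, 0.70, 0.56),
    c("JUND",   0.65, 0.66, 0.68, 0.54),
    c("SRF",    0.60, 0.68, 0.67, 0.52),
    c("NRSF",   0.60, 0.68, 0.65, 0.48),
    c("RAD21",  0.60, 0.70, 0.64, 0.46),
    c("SUZ12",  0.55, 0.70, 0.65, 0.30),
    c("CTCF",   0.55, 0.72, 0.63, 0.35),
    c("ZNF274", 0.50, 0.75, 0.60, 0.10),
    c("SIX5",   0.00, 0.60, 0.00, 0.45))
  tf_names <- c("SIN3A", "ZNF143", "TAF1", "POL2", "NANOG", "POU5F1",
                "SOX2", "MYC", "MAX", "EGR1", "GABP", "SP1", "YY1",
                "USF1", "TCF12", "JUND", "SRF", "NRSF", "RAD21",
                "SUZ12", "CTCF", "ZNF274", "SIX5")
  make <- function(rows, names, class) {
    mapply(function(r, nm)
      feature_spec(nm, class, beta = as.numeric(r[2]),
                   tau = as.numeric(r[3]),
                   latent_share = as.numeric(r[4]),
                   p_in_dhs = as.numeric(r[5]), n_peaks = n_peaks),
      rows, names, SIMPLIFY = FALSE)
  }
  synthetic_config(seed = seed, chrom_length = 2e7, n_dhs = n_dhs,
                   features = c(make(hm, hm_names, "HM"),
                                make(tf, tf_names, "TF")))
}

#' Synthetic world with nonlinear saturating feature links
#'
#' Configuration for the qualitative model-comparison check: each
#' informative feature reads the accessibility latent through a convex
#' power link (`beta` around 2.5, low noise, high latent share), so
#' accessibility is a monotone *saturating* function of feature signal
#' and the radial-basis SVR has a genuine advantage over the linear
#' model; randomized bump widths make the per-region average a noisier
#' readout than the maximum. Together these reproduce, by
#' construction, the direction of every comparison in the four-way
#' model table (SVR over linear, max over avg).
#'
#' @param seed integer seed.
#' @param n_dhs number of DHS regions (default 2200).
#' @param n_features number of features, split between HM and TF.
#' @return A `SyntheticConfig`.
#' @export
nonlinear_table1_config <- function(seed = 1L, n_dhs = 2200L,
                                    n_features = 8L) {
  stopifnot(n_features >= 2)
  n_hm <- n_features %/% 2
  feats <- lapply(seq_len(n_features), function(i)
    feature_spec(sprintf("%s%02d", if (i <= n_hm) "HM" else "TF", i),
                 if (i <= n_hm) "HM" else "TF",
                 beta = 2.2 + 0.6 * (i - 1) / max(1, n_features - 1),
                 tau = 0.15, latent_share = 0.95, p_in_dhs = 0.5,
                 n_peaks = 200L))
  synthetic_config(seed = seed, chrom_length = 8e6, n_dhs = n_dhs,
                   latent_sigma = 0.5, dnase_noise_sd = 0.15,
                   features = feats)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper running [simulate_regions()],
#' [simulate_signal_tracks()] and [simulate_peaks()].
#'
#' @param config a [synthetic_config()].
#' @return List: `dhs`, `latents`, `dnase_track`, `feature_tracks`,
#'   `peaksets`, `classes` (named feature->class vector), `truth`
#'   (`data.frame` of generator parameters per feature).
#' @export
simulate_dataset <- function(config) {
  reg <- simulate_regions(config)
  sig <- simulate_signal_tracks(reg$dhs, reg$latents, config)
  peaks <- simulate_peaks(reg$dhs, config)
  classes <- vapply(config$features, function(f) f$class, "")
  names(classes) <- vapply(config$features, function(f) f$name, "")
  truth <- do.call(rbind, lapply(config$features, function(f)
    data.frame(feature = f$name, class = f$class, beta = f$beta,
               tau = f$tau, latent_share = f$latent_share,
               p_in_dhs = f$p_in_dhs, n_peaks = f$n_peaks,
               informative = f$informative, stringsAsFactors = FALSE)))
  list(dhs = reg$dhs, latents = reg$latents,
       dnase_track = sig$dnase_track, feature_tracks = sig$feature_tracks,
       peaksets = peaks, classes = classes, truth = truth)
}

#' Serialize / restore a SyntheticConfig (JSON)
#'
#' @param config a `SyntheticConfig`.
#' @param path file path.
#' @return `write_synthetic_config`: `path`, invisibly;
#'   `read_synthetic_config`: a `SyntheticConfig` identical to the one
#'   written.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "SyntheticConfig"))
  plain <- unclass(config)
  plain$features <- lapply(plain$features, unclass)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  feats <- lapply(raw$features, function(f)
    feature_spec(f$name, f$class, beta = f$beta, tau = f$tau,
                 latent_share = f$latent_share, p_in_dhs = f$p_in_dhs,
                 n_peaks = f$n_peaks, scale = f$scale))
  synthetic_config(seed = raw$seed, chrom_length = raw$chrom_length,
                   n_dhs = raw$n_dhs,
                   dhs_length_range = raw$dhs_length_range,
                   latent_mu = raw$latent_mu,
                   latent_sigma = raw$latent_sigma,
                   features = feats, dnase_noise_sd = raw$dnase_noise_sd,
                   bump_frac_range = raw$bump_frac_range,
                   bump_segments = raw$bump_segments,
                   peak_length_range = raw$peak_length_range,
                   background_height = raw$background_height)
}
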