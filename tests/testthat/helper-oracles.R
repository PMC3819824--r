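# Independent brute-force oracles and small fixture builders.
# Everything here works per base or by exhaustive enumeration and never
# calls the code paths it is used to check.

# Per-base signal values of `track` over [start, end) on `chrom`
# (0-based half-open), walking every segment.
brute_signal_vector <- function(track, chrom, start, end) {
  df <- as.data.frame(track)
  df <- df[df$chrom == chrom, , drop = FALSE]
  v <- numeric(end - start)
  for (i in seq_len(nrow(df))) {
    a <- max(df$start[i], start)
    b <- min(df$end[i], end)
    if (a < b) v[(a - start + 1):(b - start)] <- df$value[i]
  }
  v
}

# Per-base membership overlap test on a toy chromosome of length L.
brute_overlaps <- function(q_start, q_end, t_start, t_end, L) {
  occ <- logical(L)
  for (i in seq_along(t_start)) occ[(t_start[i] + 1):t_end[i]] <- TRUE
  vapply(seq_along(q_start),
         function(i) any(occ[(q_start[i] + 1):q_end[i]]), TRUE)
}

# Random non-overlapping signal track on chr "c1" of length L.
random_track <- function(n_seg, L, name = "t") {
  cuts <- sort(sample(0:L, 2 * n_seg, replace = FALSE))
  s <- cuts[seq(1, 2 * n_seg, 2)]
  e <- cuts[seq(2, 2 * n_seg, 2)]
  signal_track(name, rep("c1", n_seg), s, e, runif(n_seg, 0, 10))
}

# Upper-tail enrichment p-value by exhaustive enumeration of all
# possible N-subsets of the M enumerated models.
brute_enrichment_p <- function(feature_names, k, N, feature, x_obs) {
  models <- combn(sort(feature_names), k, simplify = FALSE)
  contains <- vapply(models, function(m) feature %in% m, TRUE)
  draws <- combn(length(models), N)
  counts <- colSums(matrix(contains[draws], nrow = N))
  mean(counts >= x_obs)
}

# Matrix-level synthetic data: latent accessibility a_i drives y and
# each informative column through multiplicative log-normal noise.
# Cheap stand-in for the full track generator in modeling tests.
make_latent_matrix <- function(n, taus, seed, informative = NULL,
                               y_noise = 0.2) {
  if (is.null(informative)) informative <- rep(TRUE, length(taus))
  set.seed(seed)
  a <- rlnorm(n, 2, 0.8)
  X <- vapply(seq_along(taus), function(j) {
    if (informative[j]) a * exp(rnorm(n, 0, taus[j]))
    else rlnorm(n, 2, 0.8)
  }, numeric(n))
  colnames(X) <- sprintf("f%02d", seq_along(taus))
  y <- a * exp(rnorm(n, 0, y_noise))
  feature_matrix(sprintf("r%05d", seq_len(n)), colnames(X), X, y, "max")
}

# Tiny track world shared by several files: two chromosomes, three
# features, five regions; small enough for per-base checking.
toy_world <- function() {
  dhs <- peak_set("DHS", c("c1", "c1", "c1", "c2", "c2"),
                  c(10, 50, 120, 0, 40), c(30, 90, 150, 20, 70))
  dnase <- signal_track("DNase", c("c1", "c1", "c1", "c2"),
                        c(12, 55, 125, 5), c(25, 80, 149, 50),
                        c(4, 9, 2.5, 7))
  tracks <- list(
    fA = signal_track("fA", c("c1", "c1", "c2"), c(0, 60, 10),
                      c(20, 85, 60), c(2, 6, 3)),
    fB = signal_track("fB", "c1", 140, 160, 5),
    fC = signal_track("fC", "c2", 45, 65, 1.5))
  list(dhs = dhs, dnase = dnase, tracks = tracks)
}
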