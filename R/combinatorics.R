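#' Enumerate all k-feature subsets in canonical order
#'
#' Subsets are internally sorted and listed in lexicographic order of
#' the sorted feature names, giving exactly `choose(F, k)` subsets.
#'
#' @param feature_names character vector of F unique names.
#' @param k subset size, `1 <= k <= F`.
#' @return List of character vectors, each of length `k`.
#' @export
enumerate_subsets <- function(feature_names, k) {
  stopifnot(!anyDuplicated(feature_names))
  f <- length(feature_names)
  if (k < 1 || k > f) stop("k must satisfy 1 <= k <= ", f)
  combn(sort(feature_names), k, simplify = FALSE)
}

#' Evaluate every k-feature model by cross-validated prediction power
#'
#' Runs [kfold_cv()] for each subset from [enumerate_subsets()] and for
#' the full feature set, reusing one fold partition for every model so
#' subsets are compared on identical folds. Results carry the relative
#' power R / R_full (not clamped: a subset may beat the full model).
#'
#' @param matrix a `FeatureMatrix`.
#' @param k subset size.
#' @param config a [model_config()].
#' @param folds number of CV folds.
#' @param seed integer seed (fold partition).
#' @return List with `results` (`data.frame`: `features`
#'   (slash-joined), `R`, `relative_power`, sorted by decreasing R,
#'   ties broken lexicographically), `subsets` (list of character
#'   vectors, same order), and `R_full`.
#' @export
evaluate_combinations <- function(matrix, k, config = model_config("lm"),
                                  folds = 10L, seed = 1L) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  subsets <- enumerate_subsets(matrix$feature_names, k)
  fold_assignment <- make_folds(nrow(matrix$X), folds, seed)
  R_full <- kfold_cv(matrix, config = config, folds = fold_assignment)$R
  R <- vapply(subsets, function(fs)
    kfold_cv(matrix, fs, config, folds = fold_assignment)$R, 0)
  key <- vapply(subsets, paste, "", collapse = "/")
  ord <- order(-R, key)
  list(results = data.frame(features = key[ord], R = R[ord],
                            relative_power = R[ord] / R_full,
                            stringsAsFactors = FALSE),
       subsets = subsets[ord],
       R_full = R_full)
}

#' Select combinations exceeding a fraction of the full model's power
#'
#' Keeps combinations with `R > threshold * R_full` -- a strict
#' inequality on R ("more than" the given share of the full model's
#' prediction power).
#'
#' @param combos result of [evaluate_combinations()].
#' @param threshold fraction of `R_full` (default 0.90).
#' @return Same shape as `combos` restricted to the top set.
#' @export
top_combinations <- function(combos, threshold = 0.90) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- combos$results$R > threshold * combos$R_full
  list(results = combos$results[keep, , drop = FALSE],
       subsets = combos$subsets[keep],
       R_full = combos$R_full,
       threshold = threshold)
}

#' Hypergeometric enrichment of features within a top-combination set
#'
#' Null model: the N top combinations are a uniform draw of N models
#' from the M = choose(F, k) enumerated k-feature models, of which
#' K = choose(F-1, k-1) contain any given feature. For each feature the
#' upper-tail probability P(X >= x) of its observed membership count x
#' is reported, together with Benjamini-Hochberg adjusted values;
#' features are flagged at raw p < alpha.
#'
#' @param top result of [top_combinations()] (or any list with a
#'   `subsets` element of equal-size subsets); must be non-empty.
#' @param feature_names the full universe of F feature names.
#' @param k subset size used in the enumeration.
#' @param alpha raw significance threshold (default 0.01).
#' @return `data.frame` with one row per feature: `feature`, `x`, `N`,
#'   `K`, `M`, `p_value`, `p_bh`, `enriched`, sorted by `p_value`.
#' @export
feature_enrichment <- function(top, feature_names, k, alpha = 0.01) {
  subsets <- top$subsets
  if (length(subsets) == 0L) stop("top set is empty")
  if (!all(lengths(subsets) == k)) stop("subsets of mixed size")
  f <- length(feature_names)
  M <- choose(f, k)
  K <- choose(f - 1, k - 1)
  N <- length(subsets)
  members <- unlist(subsets)
  x <- vapply(feature_names, function(fn) sum(members == fn), 0L)
  p <- phyper(x - 1, K, M - K, N, lower.tail = FALSE)
  out <- data.frame(feature = feature_names, x = x, N = N, K = K, M = M,
                    p_value = p, p_bh = p.adjust(p, "BH"),
                    enriched = p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value, out$feature), , drop = FALSE]
}

#' Prediction power as a function of sample size
#'
#' For each sample size, draws `reps` independent region subsamples
#' (each seeded deterministically from the master seed and replicate
#' index), runs [kfold_cv()] on each, and reports the mean and standard
#' deviation of the prediction power R.
#'
#' @param matrix a `FeatureMatrix`.
#' @param sizes integer vector of sample sizes (each >= `folds` and
#'   <= the number of rows).
#' @param reps replicates per size (default 500).
#' @param config a [model_config()].
#' @param folds CV folds.
#' @param seed master seed.
#' @return `data.frame` with columns `size`, `mean_R`, `sd_R`, `reps`.
#' @export
sample_size_curve <- function(matrix, sizes, reps = 500L,
                              config = model_config("lm"), folds = 10L,
                              seed = 1L) {
  stopifnot(inherits(matrix, "FeatureMatrix"), reps >= 1)
  n <- nrow(matrix$X)
  if (any(sizes > n)) stop("sample size exceeds number of regions")
  if (any(sizes < folds)) stop("sample size smaller than fold count")
  rows <- lapply(sizes, function(sz) {
    R <- vapply(seq_len(reps), function(r) {
      sub_seed <- derive_seed(seed, sprintf("size%d_rep%d", sz, r))
      sub <- sample_regions(matrix, sz, sub_seed)
      kfold_cv(sub, config = config, k = folds,
               seed = derive_seed(sub_seed, "folds"))$R
    }, 0)
    data.frame(size = sz, mean_R = mean(R),
               sd_R = if (reps > 1) sd(R) else 0, reps = reps)
  })
  do.call(rbind, rows)
}
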