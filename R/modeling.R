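#' Model configuration for accessibility prediction
#'
#' Defaults for the SVR reproduce the libsvm defaults of the standard R
#' SVR interface: radial-basis kernel, cost 1, epsilon-insensitivity
#' 0.1, gamma = 1/(number of features), with features and target
#' centred/scaled on the training fold (predictions are mapped back to
#' target units). The linear model is ordinary least squares with an
#' intercept and ignores the SVR hyperparameters. No tuning is done
#' inside cross-validation.
#'
#' @param algorithm `"svr"` or `"lm"`.
#' @param cost SVR cost parameter C (> 0).
#' @param epsilon SVR insensitivity width (> 0), in standardized target
#'   units when `standardize = TRUE`.
#' @param gamma RBF kernel width; `NULL` means 1/n_features at fit time.
#' @param standardize centre/scale predictors and target on the
#'   training data (constant columns map to zeros).
#' @param log1p apply `log1p` to predictors and target before fitting
#'   (off by default: signals are modeled untransformed).
#' @param tol SMO stopping tolerance.
#' @param max_iter SMO iteration cap.
#' @return A `ModelConfig` list.
#' @export
model_config <- function(algorithm = c("svr", "lm"), cost = 1.0,
                         epsilon = 0.1, gamma = NULL, standardize = TRUE,
                         log1p = FALSE, tol = 1e-3, max_iter = 1000000L) {
  algorithm <- match.arg(algorithm)
  stopifnot(cost > 0, epsilon > 0, is.null(gamma) || gamma > 0)
  structure(list(algorithm = algorithm, cost = cost, epsilon = epsilon,
                 gamma = gamma, standardize = standardize, log1p = log1p,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "ModelConfig")
}

#' Fit a prediction model (SVR or linear) on training data
#'
#' @param train_X numeric matrix of training features (>= 2 rows).
#' @param train_y numeric target vector.
#' @param config a [model_config()].
#' @return A `chromaccess_model` with a [predict()] method returning
#'   predictions in original target units.
#' @export
fit_model <- function(train_X, train_y, config = model_config()) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) < 2L) stop("need at least 2 training rows")
  if (ncol(train_X) < 1L) stop("need at least 1 feature")
  if (any(!is.finite(train_X)) || any(!is.finite(train_y)))
    stop("non-finite training inputs")
  if (config$log1p) {
    train_X <- log1p(train_X); train_y <- log1p(train_y)
  }
  if (config$standardize) {
    xm <- colMeans(train_X)
    xs <- apply(train_X, 2, sd)
    xs[!is.finite(xs) | xs == 0] <- 1  # constant columns -> zeros
    ym <- mean(train_y)
    ys <- sd(train_y)
    if (!is.finite(ys) || ys == 0) ys <- 1
  } else {
    xm <- rep(0, ncol(train_X)); xs <- rep(1, ncol(train_X))
    ym <- 0; ys <- 1
  }
  Xs <- sweep(sweep(train_X, 2, xm), 2, xs, "/")
  ysc <- (train_y - ym) / ys

  if (config$algorithm == "lm") {
    fit <- stats::lm.fit(cbind(1, Xs), ysc)
    coef <- fit$coefficients
    coef[is.na(coef)] <- 0  # rank deficiency: drop aliased columns
    model <- list(coef = coef)
  } else {
    gamma <- if (is.null(config$gamma)) 1 / ncol(train_X) else config$gamma
    fit <- .svr_smo_fit(Xs, ysc, config$cost, config$epsilon, gamma,
                        config$tol, config$max_iter)
    if (!fit$converged)
      warning("SVR solver hit max_iter before reaching tolerance")
    sv <- which(abs(fit$beta) > 1e-12)
    model <- list(sv_X = Xs[sv, , drop = FALSE], sv_beta = fit$beta[sv],
                  b = fit$b, gamma = gamma, iterations = fit$iterations)
  }
  structure(list(algorithm = config$algorithm, model = model,
                 xm = xm, xs = xs, ym = ym, ys = ys,
                 log1p = config$log1p, n_features = ncol(train_X)),
            class = "chromaccess_model")
}

#' @export
predict.chromaccess_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_features)
    stop("newdata has ", ncol(X), " features; model expects ",
         object$n_features)
  if (object$log1p) X <- log1p(X)
  Xs <- sweep(sweep(X, 2, object$xm), 2, object$xs, "/")
  if (object$algorithm == "lm") {
    p <- drop(cbind(1, Xs) %*% object$model$coef)
  } else {
    m <- object$model
    if (length(m$sv_beta) == 0L) {
      p <- rep(m$b, nrow(Xs))
    } else {
      p <- as.numeric(.svr_rbf_predict(m$sv_X, m$sv_beta, m$b, m$gamma, Xs))
    }
  }
  p <- p * object$ys + object$ym
  if (object$log1p) p <- expm1(p)
  p
}

#' Prediction power: R-squared and R of predicted vs observed
#'
#' The coefficient of determination is the squared Pearson correlation
#' between predictions and observations -- the R-squared of the
#' least-squares line through the predicted-vs-observed scatter -- and
#' the prediction power R is its positive square root. By construction
#' R2 lies in [0, 1] and both quantities are invariant under positive
#' affine transforms of either argument.
#'
#' @param predictions,observed equal-length numeric vectors (>= 3).
#' @return List with elements `R2` and `R`.
#' @export
prediction_power <- function(predictions, observed) {
  if (length(predictions) != length(observed))
    stop("length mismatch")
  if (length(observed) < 3L) stop("need at least 3 points")
  if (sd(observed) == 0) stop("constant observed vector: R undefined")
  if (sd(predictions) == 0) {
    warning("constant predictions: R set to 0")
    return(list(R2 = 0, R = 0))
  }
  r <- cor(predictions, observed)
  list(R2 = r^2, R = sqrt(r^2))
}

#' Random k-fold partition of n rows (sizes differ by at most 1)
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  with_seed(seed, {
    fold <- integer(n)
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
    fold
  })
}

#' k-fold cross-validated prediction of DNase signal
#'
#' Randomly partitions the regions into `k` near-equal folds
#' (deterministic given `seed`), trains on k-1 folds, predicts the
#' held-out fold, pools the out-of-fold predictions across all folds,
#' and computes the prediction power on the pooled scatter.
#'
#' @param matrix a `FeatureMatrix`.
#' @param features subset of feature names to use (default: all).
#' @param config a [model_config()].
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold partition.
#' @param folds optional precomputed fold assignment (overrides
#'   `k`/`seed`); used to compare feature subsets on identical folds.
#' @return A `CVResult`: list with `fold_assignment`, `predictions`,
#'   `observed`, `R2`, `R`.
#' @export
kfold_cv <- function(matrix, features = NULL, config = model_config(),
                     k = 10L, seed = 1L, folds = NULL) {
  stopifnot(inherits(matrix, "FeatureMatrix"))
  if (is.null(features)) features <- matrix$feature_names
  missing <- setdiff(features, matrix$feature_names)
  if (length(missing)) stop("unknown feature(s): ",
                            paste(missing, collapse = ", "))
  n <- nrow(matrix$X)
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  stopifnot(length(folds) == n)
  X <- matrix$X[, features, drop = FALSE]
  y <- matrix$y
  preds <- numeric(n)
  for (f in sort(unique(folds))) {
    test <- folds == f
    fit <- fit_model(X[!test, , drop = FALSE], y[!test], config)
    preds[test] <- predict(fit, X[test, , drop = FALSE])
  }
  pw <- prediction_power(preds, y)
  structure(list(fold_assignment = folds, predictions = preds,
                 observed = y, R2 = pw$R2, R = pw$R),
            class = "CVResult")
}

#' Four-way model comparison: SVR vs linear, max vs avg aggregation
#'
#' Runs 10-fold cross-validation for each feature class (HM-only,
#' TF-only, and HM+TF) under every combination of algorithm (SVR,
#' linear model) and aggregation (max-signal matrix, avg-signal
#' matrix), and tabulates the prediction power R. Both matrices must
#' describe the same regions and features; the same fold partition is
#' used for every cell.
#'
#' @param matrix_max,matrix_avg `FeatureMatrix` objects built with
#'   `max` and `avg` aggregation on the same regions/features.
#' @param classes named character vector mapping each feature name to
#'   `"HM"` or `"TF"`.
#' @param config base [model_config()]; its `algorithm` is overridden.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return `data.frame` with rows `HM`, `TF`, `HM+TF` and columns
#'   `SVR_max`, `LM_max`, `SVR_avg`, `LM_avg`.
#' @export
model_comparison <- function(matrix_max, matrix_avg, classes,
                             config = model_config(), k = 10L, seed = 1L) {
  stopifnot(inherits(matrix_max, "FeatureMatrix"),
            inherits(matrix_avg, "FeatureMatrix"))
  if (!identical(matrix_max$region_ids, matrix_avg$region_ids))
    stop("matrices describe different region sets")
  if (!identical(matrix_max$feature_names, matrix_avg$feature_names))
    stop("matrices describe different feature sets")
  stopifnot(all(matrix_max$feature_names %in% names(classes)))
  sets <- list(
    HM = matrix_max$feature_names[classes[matrix_max$feature_names] == "HM"],
    TF = matrix_max$feature_names[classes[matrix_max$feature_names] == "TF"])
  sets[["HM+TF"]] <- matrix_max$feature_names
  folds <- make_folds(nrow(matrix_max$X), k, seed)
  cell <- function(mat, algo, feats) {
    cfg <- config; cfg$algorithm <- algo
    kfold_cv(mat, feats, cfg, folds = folds)$R
  }
  out <- data.frame(row.names = names(sets))
  for (col in c("SVR_max", "LM_max", "SVR_avg", "LM_avg")) {
    algo <- if (startsWith(col, "SVR")) "svr" else "lm"
    mat <- if (endsWith(col, "max")) matrix_max else matrix_avg
    out[[col]] <- vapply(sets, function(fs) {
      if (length(fs) == 0L) return(NA_real_)
      cell(mat, algo, fs)
    }, 0)
  }
  out
}
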