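# Cross-validated random-forest regression engine shared by the skin-age
# indices (SPA/SMA/SIA) and the microbial SIP predictions. Features are a
# samples x features matrix; ranger runs single-threaded with a fold-derived
# seed so results are exactly reproducible.
.rf_cv <- function(features, target, n_folds, n_trees, seed,
                   transfer_features = NULL) {
  x <- as.matrix(features)
  if (!is.numeric(x) || any(!is.finite(x))) stop("non-finite feature values")
  n <- nrow(x)
  if (length(target) != n) stop("features and target are not row-aligned")
  if (n_folds < 2) stop("n_folds must be >= 2")
  if (n < 2 * n_folds) stop("need at least 2 * n_folds samples")
  colnames(x) <- sprintf("f%05d", seq_len(ncol(x)))
  set.seed(seed)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  oof <- numeric(n)
  r2 <- numeric(n_folds)
  imp <- matrix(0, ncol(x), n_folds,
                dimnames = list(colnames(x), NULL))
  tf <- NULL
  transfer <- if (!is.null(transfer_features)) {
    tf <- as.matrix(transfer_features)
    colnames(tf) <- colnames(x)
    matrix(0, nrow(tf), n_folds)
  } else NULL
  for (k in seq_len(n_folds)) {
    tr <- fold != k
    dat <- data.frame(.y = target[tr], x[tr, , drop = FALSE])
    fit <- ranger::ranger(
      dependent.variable.name = ".y", data = dat,
      num.trees = n_trees, importance = "permutation",
      seed = seed + k, num.threads = 1
    )
    pred <- stats::predict(fit, data.frame(x[!tr, , drop = FALSE]),
                           num.threads = 1)$predictions
    oof[!tr] <- pred
    obs <- target[!tr]
    r2[k] <- 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)
    imp[names(fit$variable.importance), k] <- fit$variable.importance
    if (!is.null(transfer))
      transfer[, k] <- stats::predict(fit, data.frame(tf),
                                      num.threads = 1)$predictions
  }
  list(oof = oof, fold = fold, r2_pct = 100 * r2,
       importance_mean = rowMeans(imp),
       importance_sd = apply(imp, 1, stats::sd),
       transfer = if (!is.null(transfer)) rowMeans(transfer))
}

#' Fit a skin-age index by cross-validated random-forest regression
#'
#' Random-forest regression of chronological age on a feature table (the
#' ten SIPs for the skin phenotype age, species relative abundances for the
#' skin microbiota age, or their concatenation for the integration age).
#' Samples are split into `n_folds` random folds; each sample's index is
#' its out-of-fold prediction. Feature importance is ranger's permutation
#' importance, averaged over folds.
#'
#' @param features Samples x features numeric matrix or data.frame.
#' @param ages Chronological ages (years), row-aligned to `features`.
#' @param n_folds Number of cross-validation folds (default 5).
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed; fixes fold assignment and forests.
#' @return A list with `predicted_age` (out-of-fold, years), `fold`,
#'   `r2_pct` (per-fold held-out R-squared, percent), `mae` (years),
#'   `importance` (data.frame: feature, mean, sd).
#' @export
fit_age_index <- function(features, ages, n_folds = 5, n_trees = 500,
                          seed = 1) {
  cv <- .rf_cv(features, ages, n_folds, n_trees, seed)
  feat_names <- colnames(as.matrix(features))
  if (is.null(feat_names)) feat_names <- names(cv$importance_mean)
  list(predicted_age = cv$oof, fold = cv$fold, r2_pct = cv$r2_pct,
       mae = mean(abs(cv$oof - ages)),
       importance = data.frame(feature = feat_names,
                               mean = unname(cv$importance_mean),
                               sd = unname(cv$importance_sd)))
}

#' Transfer a cross-validated age model to a held-out group
#'
#' Runs the same five-fold cross-validation as [fit_age_index()] on the
#' training subset (e.g., one gender), and in each fold also predicts every
#' transfer sample; a transfer sample's skin age is the mean of its
#' per-fold predictions.
#'
#' @param features Samples x features matrix covering both groups.
#' @param ages Ages for all samples.
#' @param train_mask,transfer_mask Disjoint logical vectors selecting the
#'   training and transfer samples.
#' @inheritParams fit_age_index
#' @return Numeric vector of transfer predictions (years), one per
#'   transfer sample, in mask order; empty if the transfer mask is empty.
#' @export
cross_group_transfer <- function(features, ages, train_mask, transfer_mask,
                                 n_folds = 5, n_trees = 500, seed = 1) {
  x <- as.matrix(features)
  if (any(train_mask & transfer_mask)) stop("masks must be disjoint")
  if (sum(transfer_mask) == 0) return(numeric(0))
  cv <- .rf_cv(x[train_mask, , drop = FALSE], ages[train_mask],
               n_folds, n_trees, seed,
               transfer_features = x[transfer_mask, , drop = FALSE])
  cv$transfer
}

#' Predict a SIP score from microbial species abundances
#'
#' Cross-validated random-forest regression of one SIP on the species
#' relative-abundance table, reporting the normalized mean absolute error
#' (each sample's error divided by its observed score) so accuracy is
#' comparable across SIPs with different units.
#'
#' @param species Samples x species relative-abundance matrix.
#' @param sip_scores Observed scores, all strictly positive.
#' @inheritParams fit_age_index
#' @return A list with `predicted` (out-of-fold scores), `r2_pct`, `mae`,
#'   `normalized_mae`.
#' @export
predict_sip_from_species <- function(species, sip_scores, n_folds = 5,
                                     n_trees = 500, seed = 1) {
  if (any(sip_scores <= 0))
    stop("all observed scores must be > 0: the normalized MAE divides ",
         "each error by its observed value")
  cv <- .rf_cv(species, sip_scores, n_folds, n_trees, seed)
  list(predicted = cv$oof, fold = cv$fold, r2_pct = cv$r2_pct,
       mae = mean(abs(cv$oof - sip_scores)),
       normalized_mae = normalized_mae(cv$oof, sip_scores))
}

#' Normalized mean absolute error
#'
#' `mean(|predicted - observed| / observed)`; requires strictly positive
#' observed values.
#'
#' @param predicted,observed Numeric vectors of equal length.
#' @return Dimensionless non-negative scalar.
#' @export
normalized_mae <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  if (any(observed <= 0)) stop("observed values must be > 0")
  mean(abs(predicted - observed) / observed)
}
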