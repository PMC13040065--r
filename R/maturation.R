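#' Encode confound variables as demeaned numeric columns
#'
#' Two-level confounds (sex, hemisphere) become a single demeaned indicator
#' column; a K-level confound (site) becomes K demeaned indicator columns
#' (the resulting rank deficiency is absorbed by the pseudo-inverse in the
#' projection).  Single-level confounds are dropped with a warning.
#'
#' @param meta data.frame with the confound columns.
#' @param confounds column names to encode.
#' @param centers optional named list of column means from a training split,
#'   to demean new data consistently.
#' @return list with `V` (matrix, columns grouped per confound), `groups`
#'   (confound name per column) and `centers` (for re-application).
#' @export
encode_confounds <- function(meta, confounds = c("sex", "site", "hemisphere"),
                             centers = NULL) {
  cols <- list(); groups <- character(0); ctr_out <- list()
  for (cf in confounds) {
    abort_if(!cf %in% names(meta), paste("missing confound column:", cf))
    x <- as.character(meta[[cf]])
    levs <- if (!is.null(centers)) centers[[cf]]$levels else sort(unique(x))
    if (length(levs) < 2) {
      warning(sprintf("confound '%s' has a single level; dropped", cf))
      next
    }
    if (length(levs) == 2) {
      ind <- matrix(as.numeric(x == levs[2]), ncol = 1,
                    dimnames = list(NULL, paste0(cf, "_", levs[2])))
    } else {
      ind <- sapply(levs, function(l) as.numeric(x == l))
      colnames(ind) <- paste0(cf, "_", levs)
    }
    mu <- if (!is.null(centers)) centers[[cf]]$means else colMeans(ind)
    ind <- sweep(ind, 2, mu)
    cols[[cf]] <- ind
    groups <- c(groups, rep(cf, ncol(ind)))
    ctr_out[[cf]] <- list(levels = levs,
                          means = stats::setNames(mu, colnames(ind)))
  }
  abort_if(length(cols) == 0, "no usable confound columns")
  list(V = do.call(cbind, cols), groups = groups, centers = ctr_out)
}

#' Remove confounds by linear projection
#'
#' Computes the deconfounded feature matrix `X - V V^+ X`, with `V^+` the
#' Moore-Penrose pseudo-inverse of the demeaned confound matrix: a single
#' simultaneous regression-based removal of all confounds.  The residual
#' columns are orthogonal to every confound column, and the operation is
#' idempotent.
#'
#' @param X numeric feature matrix (scans x features).
#' @param V demeaned confound matrix from [encode_confounds()].
#' @param beta optional projection coefficients `V^+ X` estimated on a
#'   training split, to apply to new data.
#' @return list with `X_hat` (deconfounded features) and `beta`.
#' @export
deconfound <- function(X, V, beta = NULL) {
  X <- as.matrix(X); V <- as.matrix(V)
  abort_if(nrow(X) != nrow(V), "feature and confound row counts differ")
  if (is.null(beta)) beta <- pinv(V) %*% X
  list(X_hat = X - V %*% beta, beta = beta)
}

#' Percentage variance explained by a confound
#'
#' For the selected confound columns `V1` (with `Vn` the remaining columns),
#' computes per feature j the percentage of variance the confound would
#' explain acting alone, `%VE_j = 100 |V1 V1^+ X_j|^2 / |X_j|^2`, and the
#' unique variance explained beyond the other confounds,
#' `%UVE_j = 100 (|V V^+ X_j|^2 - |Vn Vn^+ X_j|^2) / |X_j|^2`.  Under
#' mutually orthogonal confounds %UVE equals %VE.  Zero-variance features are
#' reported missing.
#'
#' @param X numeric feature matrix.
#' @param V demeaned confound matrix.
#' @param which_cols column indices (or a `groups` name via `groups`) of the
#'   confound of interest.
#' @param groups optional character vector naming each column's confound, as
#'   returned by [encode_confounds()]; then `which_cols` may be a name.
#' @return data.frame with feature, pct_ve, pct_uve.
#' @export
variance_explained <- function(X, V, which_cols, groups = NULL) {
  X <- as.matrix(X); V <- as.matrix(V)
  if (is.character(which_cols)) {
    abort_if(is.null(groups), "need `groups` to select a confound by name")
    which_cols <- which(groups == which_cols)
  }
  V1 <- V[, which_cols, drop = FALSE]
  Vn <- V[, -which_cols, drop = FALSE]
  proj <- function(M, X) if (ncol(M) == 0) X * 0 else M %*% (pinv(M) %*% X)
  ss <- function(M) colSums(M^2)
  denom <- ss(X)
  ve <- 100 * ss(proj(V1, X)) / denom
  uve <- 100 * (ss(proj(V, X)) - ss(proj(Vn, X))) / denom
  ve[denom < 1e-12] <- NA_real_
  uve[denom < 1e-12] <- NA_real_
  data.frame(feature = colnames(X, do.NULL = FALSE, prefix = "x"),
             pct_ve = ve, pct_uve = uve, row.names = NULL)
}

#' Fit the fetal brain maturation model
#'
#' Random-forest regression of gestational age on the standardised,
#' deconfounded IDPs under subject-level k-fold cross-validation: both scans
#' of a fetus always land in the same fold, and standardisation, confound
#' encoding and projection coefficients are estimated on each training split
#' only, then applied to its test split.  The forest uses 100 trees and
#' `ceiling(max_feature_ratio * n_features)` candidate features per split.
#'
#' @param table IDP data.frame with metadata (fetus_id, ga_weeks and the
#'   confound columns) and the feature columns.
#' @param features feature column names (default the 28 IDPs).
#' @param confounds confound column names to remove.
#' @param n_folds folds (default 3).
#' @param n_trees trees per forest (default 100).
#' @param max_feature_ratio fraction of features tried per split (default
#'   0.15).
#' @param seed integer seed controlling fold assignment and forests.
#' @return a `maturation_model`: per-fold forests and preprocessing, fold ids
#'   per scan, and out-of-fold predictions.
#' @export
fit_maturation_model <- function(table, features = idp_names(),
                                 confounds = c("sex", "site", "hemisphere"),
                                 n_folds = 3L, n_trees = 100L,
                                 max_feature_ratio = 0.15, seed = 1L) {
  abort_if(nrow(table) < 50, "need at least 50 scans")
  fet <- unique(table$fetus_id)
  abort_if(length(fet) < n_folds,
           sprintf("cannot form %d subject-level folds from %d fetuses",
                   n_folds, length(fet)))
  set.seed(seed)
  fold_of_fetus <- stats::setNames(
    sample(rep_len(seq_len(n_folds), length(fet))), fet)
  fold <- unname(fold_of_fetus[table$fetus_id])
  X <- as.matrix(table[, features])
  ga <- table$ga_weeks
  mtry <- ceiling(max_feature_ratio * length(features))

  preds <- rep(NA_real_, nrow(table))
  fits <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- fold != k; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg < 1e-12] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
    enc_tr <- encode_confounds(table[tr, ], confounds)
    enc_te <- encode_confounds(table[te, ], confounds, centers = enc_tr$centers)
    dc_tr <- deconfound(Xtr, enc_tr$V)
    dc_te <- deconfound(Xte, enc_te$V, beta = dc_tr$beta)
    rf <- ranger::ranger(
      x = as.data.frame(dc_tr$X_hat), y = ga[tr],
      num.trees = n_trees, mtry = mtry, importance = "impurity",
      seed = seed + k)
    preds[te] <- predict(rf, data = as.data.frame(dc_te$X_hat))$predictions
    fits[[k]] <- list(forest = rf, mu = mu, sigma = sg,
                      centers = enc_tr$centers, beta = dc_tr$beta,
                      X_test = dc_te$X_hat, test_rows = which(te))
  }
  structure(list(fits = fits, fold = fold, predictions = preds,
                 ga_weeks = ga, fetus_id = table$fetus_id,
                 features = features, confounds = confounds,
                 n_trees = n_trees, mtry = mtry, seed = seed),
            class = "maturation_model")
}

#' Evaluate the maturation model
#'
#' Out-of-fold performance: mean absolute error in days (weeks x 7), Pearson
#' correlation and the intraclass correlation (two-way absolute agreement,
#' single measures) between predicted and chronological gestational age, plus
#' the per-scan brain-age delta (predicted minus chronological, days).
#'
#' @param model a `maturation_model`.
#' @return a `maturation_report` list with mae_days, pearson_r, icc and
#'   `deltas` (data.frame of per-scan deltas).
#' @export
evaluate_maturation <- function(model) {
  abort_if(any(is.na(model$predictions)), "missing out-of-fold predictions")
  pred <- model$predictions
  ga <- model$ga_weeks
  structure(list(
    mae_days = mean(abs(pred - ga)) * 7,
    pearson_r = cor(pred, ga),
    icc = icc_agreement(cbind(pred, ga)),
    deltas = data.frame(fetus_id = model$fetus_id, ga_weeks = ga,
                        predicted_ga = pred,
                        brain_age_delta_days = (pred - ga) * 7)),
    class = "maturation_report")
}

#' @export
print.maturation_report <- function(x, ...) {
  cat(sprintf("Maturation index: MAE %.2f days, R = %.3f, ICC = %.3f (n = %d)\n",
              x$mae_days, x$pearson_r, x$icc, nrow(x$deltas)))
  invisible(x)
}

#' Feature importance of the maturation model
#'
#' Impurity-based importances (averaged over folds, normalised to sum to 1)
#' and held-out permutation importances (mean increase in test MSE when a
#' feature column is permuted), with the ranking by impurity importance.
#'
#' @param model a `maturation_model`.
#' @param n_perm permutations per feature and fold.
#' @return data.frame sorted by decreasing impurity importance, with columns
#'   feature, importance_impurity, importance_permutation.
#' @export
feature_importance <- function(model, n_perm = 3L) {
  p <- length(model$features)
  imp <- rep(0, p)
  perm <- rep(0, p)
  set.seed(model$seed + 1000L)
  for (f in model$fits) {
    ri <- ranger::importance(f$forest)
    imp <- imp + ri / sum(ri)
    Xte <- f$X_test
    yte <- model$ga_weeks[f$test_rows]
    base <- mean((predict(f$forest,
                          data = as.data.frame(Xte))$predictions - yte)^2)
    for (j in seq_len(p)) {
      inc <- 0
      for (r in seq_len(n_perm)) {
        Xp <- Xte
        Xp[, j] <- Xp[sample.int(nrow(Xp)), j]
        mse <- mean((predict(f$forest,
                             data = as.data.frame(Xp))$predictions - yte)^2)
        inc <- inc + (mse - base)
      }
      perm[j] <- perm[j] + inc / n_perm
    }
  }
  imp <- imp / length(model$fits)
  perm <- perm / length(model$fits)
  out <- data.frame(feature = model$features,
                    importance_impurity = imp,
                    importance_permutation = perm)
  out[order(-out$importance_impurity), ]
}
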