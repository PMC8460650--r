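# Cascade deep forest: layers of four heterogeneous base classifiers whose
# class-probability vectors are concatenated with the original features and
# propagated, with validation-driven automatic depth and post hoc
# zero-importance feature pruning.

CLASSIFIER_TYPES <- c("logistic", "xgboost", "random_forest", "extra_trees")

# Layer-index offset separating depth-search fits from final refits in the
# derived seed stream.
REFIT_LAYER_OFFSET <- 1000L

#' Cascade configuration
#'
#' @param max_layers Hard cap on cascade depth (default 20).
#' @param epsilon Minimum validation-AUC improvement over the best previous
#'   layer required to keep growing (default 1e-3, patience 1).
#' @param validation_fraction Share of the training data held out (stratified)
#'   to score layers for the stopping rule (default 0.2).
#' @param oof_folds Folds used to generate out-of-fold class vectors for
#'   training rows (default 3); each base classifier is fitted once per fold
#'   and test-time predictions average the fold models.
#' @param seed Base RNG seed; every stochastic component derives its own seed
#'   from it deterministically.
#' @param classifiers Subset of
#'   `c("logistic", "xgboost", "random_forest", "extra_trees")`, in the fixed
#'   class-vector order. The default full bank emits an 8-dimensional class
#'   vector (4 classifiers x 2 classes).
#' @param num_trees Trees per forest (default 70).
#' @param min_node_size Minimum node size to attempt a split (default 5).
#' @param xgb_nrounds Boosting rounds for the gradient-boosted member
#'   (default 100, the common library default).
#' @param xgb_max_depth,xgb_eta Gradient-boosting depth and learning rate.
#' @param logistic_lambda Ridge penalty of the linear logistic member
#'   (default 1e-2; a small fixed penalty keeps the fit defined when
#'   features outnumber samples).
#' @return A list of class `cascade_config`.
#' @export
cascade_config <- function(max_layers = 20L, epsilon = 1e-3,
                           validation_fraction = 0.2, oof_folds = 3L,
                           seed = 1L, classifiers = CLASSIFIER_TYPES,
                           num_trees = 70L, min_node_size = 5L,
                           xgb_nrounds = 100L, xgb_max_depth = 6L,
                           xgb_eta = 0.3, logistic_lambda = 1e-2) {
  classifiers <- match.arg(classifiers, CLASSIFIER_TYPES, several.ok = TRUE)
  cfg <- list(max_layers = as.integer(max_layers), epsilon = epsilon,
              validation_fraction = validation_fraction,
              oof_folds = as.integer(oof_folds), seed = as.integer(seed),
              classifiers = classifiers,
              num_trees = as.integer(num_trees),
              min_node_size = as.integer(min_node_size),
              xgb_nrounds = as.integer(xgb_nrounds),
              xgb_max_depth = as.integer(xgb_max_depth),
              xgb_eta = xgb_eta, logistic_lambda = logistic_lambda)
  stopifnot(cfg$max_layers >= 1L, cfg$epsilon >= 0,
            cfg$validation_fraction > 0, cfg$validation_fraction < 1,
            cfg$oof_folds >= 2L, length(cfg$classifiers) >= 1L)
  structure(cfg, class = "cascade_config")
}

#' Average per-tree class distributions
#'
#' A forest's class distribution for a sample is the componentwise mean of its
#' trees' (p_positive, p_negative) pairs; e.g. three trees voting
#' (0.3750, 0.6250), (0.5556, 0.4444) and (1.0000, 0.0000) average to
#' (0.6435, 0.3565).
#'
#' @param per_tree A list of length-2 numeric vectors, or a matrix with one
#'   row per tree and columns (p_positive, p_negative).
#' @return Numeric length-2 vector `c(p_positive, p_negative)` summing to 1.
#' @export
average_tree_distributions <- function(per_tree) {
  if (is.list(per_tree)) {
    if (length(per_tree) == 0L) stop("need at least one distribution", call. = FALSE)
    per_tree <- do.call(rbind, per_tree)
  }
  stopifnot(is.matrix(per_tree), ncol(per_tree) == 2L)
  if (nrow(per_tree) == 0L) stop("need at least one distribution", call. = FALSE)
  if (any(per_tree < 0) || any(abs(rowSums(per_tree) - 1) > 1e-6)) {
    stop("each row must be a probability pair summing to 1", call. = FALSE)
  }
  out <- colMeans(per_tree)
  stats::setNames(out, c("p_positive", "p_negative"))
}

#' Augment features with a layer's class vectors
#'
#' Concatenates the *original* layer-0 features with the most recent layer's
#' class vector: a d-dimensional input and a full 4-classifier bank give
#' d + 8 columns (800 -> 808 at the default feature dimensions). The class
#' vector is recomputed at every layer; it never accumulates.
#'
#' @param X Original feature matrix (n x d).
#' @param class_vecs Class-vector matrix (n x 2 * n_classifiers).
#' @return Matrix with `ncol(X) + ncol(class_vecs)` columns.
#' @export
augment_features <- function(X, class_vecs) {
  stopifnot(is.matrix(X), is.matrix(class_vecs))
  if (nrow(X) != nrow(class_vecs)) {
    stop(sprintf("row-count mismatch: %d features rows vs %d class-vector rows",
                 nrow(X), nrow(class_vecs)), call. = FALSE)
  }
  cbind(X, class_vecs)
}

# ---- base classifier bank ---------------------------------------------------

# Fit one base classifier. X: numeric matrix with colnames; y: 0/1 integer.
.fit_base <- function(type, X, y, cfg, seed, want_importance = TRUE) {
  switch(type,
    logistic = {
      fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                            alpha = 0, lambda = cfg$logistic_lambda,
                            standardize = TRUE)
      list(type = type, fit = fit, lambda = cfg$logistic_lambda)
    },
    xgboost = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = cfg$xgb_max_depth,
                      eta = cfg$xgb_eta, tree_method = "hist", nthread = 1,
                      seed = seed),
        data = dtrain, nrounds = cfg$xgb_nrounds, verbose = 0)
      list(type = type, fit = fit, features = colnames(X))
    },
    random_forest = {
      fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                            num.trees = cfg$num_trees,
                            min.node.size = cfg$min_node_size,
                            probability = TRUE,
                            importance = if (want_importance) "impurity" else "none",
                            seed = seed, num.threads = 1)
      list(type = type, fit = fit)
    },
    extra_trees = {
      fit <- ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                            num.trees = cfg$num_trees,
                            min.node.size = cfg$min_node_size,
                            splitrule = "extratrees",
                            probability = TRUE,
                            importance = if (want_importance) "impurity" else "none",
                            seed = seed, num.threads = 1)
      list(type = type, fit = fit)
    },
    stop(sprintf("unknown classifier type '%s'", type), call. = FALSE)
  )
}

# Positive-class probability from one fitted base classifier.
.predict_base <- function(model, X) {
  switch(model$type,
    logistic = as.numeric(stats::predict(model$fit, newx = X, s = model$lambda,
                                         type = "response")),
    xgboost = as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X))),
    random_forest = ,
    extra_trees = {
      p <- stats::predict(model$fit, data = X, num.threads = 1)$predictions
      as.numeric(p[, "1"])
    }
  )
}

# Per-feature importance of one fitted base classifier, as a nonnegative
# vector over the model's input columns. Trees: impurity importance;
# logistic: |coefficient|.
.importance_base <- function(model, feature_names) {
  imp <- stats::setNames(numeric(length(feature_names)), feature_names)
  switch(model$type,
    logistic = {
      beta <- abs(as.numeric(stats::coef(model$fit, s = model$lambda))[-1L])
      imp[] <- beta
    },
    xgboost = {
      tab <- xgboost::xgb.importance(model = model$fit)
      if (nrow(tab) > 0L) imp[tab$Feature] <- tab$Gain
    },
    random_forest = ,
    extra_trees = {
      ri <- ranger::importance(model$fit)
      imp[names(ri)] <- pmax(ri, 0)
    }
  )
  imp
}

# Deterministic fold assignment: n samples into k folds, as equal as possible.
.assign_folds <- function(n, k, seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# Deterministic per-(layer, classifier, fold) seed derived from the base seed.
.derive_seed <- function(base, layer, clf, fold) {
  (base + 104729L * layer + 7919L * clf + 101L * fold) %% .Machine$integer.max
}

# ---- layers -----------------------------------------------------------------

# Fit one cascade layer on (X, y). Returns the fitted layer plus the
# out-of-fold class-vector matrix for the training rows.
.fit_layer <- function(X, y, cfg, layer_index, want_importance = TRUE) {
  n <- nrow(X)
  folds <- .assign_folds(n, cfg$oof_folds, .derive_seed(cfg$seed, layer_index, 0L, 0L))
  nclf <- length(cfg$classifiers)
  oof <- matrix(NA_real_, n, 2L * nclf)
  members <- vector("list", nclf)
  names(members) <- cfg$classifiers
  for (ci in seq_len(nclf)) {
    type <- cfg$classifiers[ci]
    fold_models <- vector("list", cfg$oof_folds)
    for (f in seq_len(cfg$oof_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L) {
        stop("a training fold lost one of the classes; use fewer folds or more data",
             call. = FALSE)
      }
      m <- .fit_base(type, X[tr, , drop = FALSE], y[tr], cfg,
                     .derive_seed(cfg$seed, layer_index, ci, f),
                     want_importance = want_importance)
      fold_models[[f]] <- m
      oof[!tr, 2L * ci - 1L] <- .predict_base(m, X[!tr, , drop = FALSE])
    }
    oof[, 2L * ci] <- 1 - oof[, 2L * ci - 1L]
    members[[ci]] <- fold_models
  }
  layer <- structure(list(members = members, classifiers = cfg$classifiers,
                          input_dim = ncol(X), feature_names = colnames(X)),
                     class = "cascade_layer")
  list(layer = layer, oof = oof)
}

#' Class vectors emitted by a fitted cascade layer
#'
#' For each sample, the fixed-order concatenation of each base classifier's
#' (p_positive, p_negative) pair; with the full 4-classifier bank this is the
#' 8-dimensional class vector. Each classifier's probability is the average
#' over its out-of-fold models.
#'
#' @param layer A fitted `cascade_layer` (from a [fit_cascade()] model).
#' @param X Input matrix with the layer's training dimensionality.
#' @return Matrix of `nrow(X)` rows and `2 * n_classifiers` columns; adjacent
#'   column pairs sum to 1.
#' @export
layer_class_vector <- function(layer, X) {
  if (!inherits(layer, "cascade_layer")) stop("layer is not fitted", call. = FALSE)
  stopifnot(is.matrix(X))
  if (ncol(X) != layer$input_dim) {
    stop(sprintf("X has %d columns but the layer was trained on %d",
                 ncol(X), layer$input_dim), call. = FALSE)
  }
  colnames(X) <- layer$feature_names
  nclf <- length(layer$members)
  out <- matrix(NA_real_, nrow(X), 2L * nclf)
  for (ci in seq_len(nclf)) {
    preds <- vapply(layer$members[[ci]], function(m) .predict_base(m, X),
                    numeric(nrow(X)))
    p <- if (nrow(X) == 1L) mean(preds) else rowMeans(preds)
    out[, 2L * ci - 1L] <- p
    out[, 2L * ci] <- 1 - p
  }
  colnames(out) <- paste0(rep(layer$classifiers, each = 2L), c("_pos", "_neg"))
  out
}

# ---- cascade ----------------------------------------------------------------

#' Fit a cascade deep forest
#'
#' Grows layers of the base-classifier bank. A stratified validation split
#' (`validation_fraction`) scores each layer by AUC; training rows receive
#' out-of-fold class vectors while validation (and later test) rows are scored
#' by the fold-averaged classifiers. Growth stops when a new layer improves
#' validation AUC by less than `epsilon` over the best previous layer or
#' `max_layers` is reached, and the best-scoring prefix of layers is kept.
#' The kept prefix is then refitted on the full training set (fit plus
#' validation rows) with the same out-of-fold machinery, so the final model
#' does not discard the held-out fifth of the data the depth search used.
#' After training, features whose aggregate importance is exactly zero are
#' masked (see [prune_zero_importance()]).
#'
#' @param X Numeric feature matrix (n x d), the pair features.
#' @param y Binary labels (0/1), both classes present.
#' @param config A [cascade_config()].
#' @return A `cascade_model` with elements `layers`, `feature_mask`,
#'   `stopping_record` (per-layer validation AUC and the stop reason),
#'   `importance` and `config`.
#' @export
fit_cascade <- function(X, y, config = cascade_config()) {
  stopifnot(inherits(config, "cascade_config"), is.matrix(X))
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present in y", call. = FALSE)
  if (nrow(X) < config$oof_folds) {
    stop("fewer samples than oof_folds", call. = FALSE)
  }
  if (!all(is.finite(X))) stop("X contains non-finite values", call. = FALSE)
  d <- ncol(X)
  orig_names <- paste0("f", seq_len(d))

  # Stratified validation split for the stopping rule.
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  val_idx <- unlist(lapply(split(seq_along(y), y), function(idx) {
    nval <- max(1L, round(length(idx) * config$validation_fraction))
    sample(idx, nval)
  }), use.names = FALSE)
  fit_idx <- setdiff(seq_along(y), val_idx)
  X_fit <- X[fit_idx, , drop = FALSE]
  X_val <- X[val_idx, , drop = FALSE]
  y_fit <- y[fit_idx]
  y_val <- y[val_idx]

  layers <- list()
  val_auc <- numeric(0)
  prev_fit_cv <- NULL
  prev_val_cv <- NULL
  best <- -Inf
  stop_reason <- "max_layers"
  for (l in seq_len(config$max_layers)) {
    A_fit <- if (l == 1L) X_fit else augment_features(X_fit, prev_fit_cv)
    A_val <- if (l == 1L) X_val else augment_features(X_val, prev_val_cv)
    colnames(A_fit) <- colnames(A_val) <-
      c(orig_names, if (l > 1L) paste0("cv", seq_len(ncol(A_fit) - d)))
    res <- .fit_layer(A_fit, y_fit, config, l, want_importance = FALSE)
    val_cv <- layer_class_vector(res$layer, A_val)
    score <- compute_auc(y_val, rowMeans(val_cv[, seq(1L, ncol(val_cv), by = 2L),
                                                drop = FALSE]))
    layers[[l]] <- res$layer
    val_auc[l] <- score
    if (l > 1L && score < best + config$epsilon) {
      stop_reason <- "no_improvement"
      break
    }
    best <- max(best, score)
    prev_fit_cv <- res$oof
    prev_val_cv <- val_cv
  }
  keep <- which.max(val_auc)

  # Refit the selected depth on all training rows; layer seeds are offset so
  # the refit draws fresh fold assignments.
  colnames(X) <- orig_names
  layers <- vector("list", keep)
  prev_cv <- NULL
  for (l in seq_len(keep)) {
    A <- if (l == 1L) X else augment_features(X, prev_cv)
    colnames(A) <- c(orig_names, if (l > 1L) paste0("cv", seq_len(ncol(A) - d)))
    res <- .fit_layer(A, y, config, l + REFIT_LAYER_OFFSET)
    layers[[l]] <- res$layer
    prev_cv <- res$oof
  }

  model <- structure(list(layers = layers, feature_mask = rep(TRUE, d),
                          importance = NULL,
                          stopping_record = list(val_auc = val_auc,
                                                 kept_layers = keep,
                                                 stop_reason = stop_reason),
                          n_features = d, config = config,
                          schema_version = 1L),
                     class = "cascade_model")
  model$importance <- .aggregate_importance(model)
  model$feature_mask <- prune_zero_importance(model)
  model
}

# Aggregate per-original-feature importance across layers and members: each
# member's importance vector (over the original d features) is renormalized to
# sum 1, then averaged.
.aggregate_importance <- function(model) {
  d <- model$n_features
  acc <- numeric(d)
  cnt <- 0L
  for (layer in model$layers) {
    nm <- layer$feature_names
    for (fold_models in layer$members) {
      per_fold <- vapply(fold_models, .importance_base, numeric(layer$input_dim),
                         feature_names = nm)
      imp <- rowMeans(per_fold)[seq_len(d)]
      s <- sum(imp)
      if (s > 0) imp <- imp / s
      acc <- acc + imp
      cnt <- cnt + 1L
    }
  }
  acc / cnt
}

#' Zero-importance feature mask
#'
#' Importance per original feature is the mean over layers and bank members of
#' each member's renormalized importance vector (impurity importance for the
#' tree members, gain for the boosted member, absolute coefficient for the
#' linear member). Features whose aggregate importance is exactly zero (e.g.
#' constant columns) are dropped; at least one feature is always retained.
#' The mask is applied automatically by [predict.cascade_model()].
#'
#' @param model A fitted `cascade_model`.
#' @return Logical vector of length `d` (TRUE = keep).
#' @export
prune_zero_importance <- function(model) {
  stopifnot(inherits(model, "cascade_model"))
  imp <- if (is.null(model$importance)) .aggregate_importance(model) else model$importance
  mask <- imp > 0
  if (!any(mask)) mask[which.max(imp)] <- TRUE
  mask
}

#' Predict interaction probabilities with a cascade model
#'
#' Propagates samples through every kept layer, re-augmenting the original
#' features with each layer's class vector; the final score is the mean of the
#' last layer's positive-class probabilities. Masked (zero-importance)
#' features are zeroed before propagation, which cannot change the output of
#' any member that assigned them zero importance.
#'
#' @param object A fitted `cascade_model`.
#' @param X Feature matrix with the training dimensionality.
#' @param type `"prob"` for probabilities (default) or `"label"` for hard 0/1
#'   labels at threshold 0.5 (scores exactly 0.5 classify as positive).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`, or integer labels.
#' @export
predict.cascade_model <- function(object, X, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  stopifnot(is.matrix(X))
  if (ncol(X) != object$n_features) {
    stop(sprintf("X has %d columns but the model was trained on %d",
                 ncol(X), object$n_features), call. = FALSE)
  }
  X[, !object$feature_mask] <- 0
  cv <- NULL
  for (l in seq_along(object$layers)) {
    A <- if (l == 1L) X else augment_features(X, cv)
    cv <- layer_class_vector(object$layers[[l]], A)
  }
  p <- rowMeans(cv[, seq(1L, ncol(cv), by = 2L), drop = FALSE])
  if (type == "label") as.integer(p >= 0.5) else as.numeric(p)
}

#' @export
print.cascade_model <- function(x, ...) {
  sr <- x$stopping_record
  cat(sprintf("cascade_model: %d layer(s) over %d features (%d retained)\n",
              length(x$layers), x$n_features, sum(x$feature_mask)))
  cat(sprintf("  bank: %s\n", paste(x$config$classifiers, collapse = ", ")))
  cat(sprintf("  validation AUC by layer: %s (stop: %s)\n",
              paste(sprintf("%.4f", sr$val_auc), collapse = ", "), sr$stop_reason))
  invisible(x)
}

#' Serialize / restore a cascade model
#'
#' Stores the layers, mask, config and a schema version; [load_cascade()]
#' refuses archives written under a different schema.
#'
#' @param model A `cascade_model`.
#' @param path Archive path (RDS).
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cascade_model") || !identical(model$schema_version, 1L)) {
    stop("incompatible cascade model archive", call. = FALSE)
  }
  model
}
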