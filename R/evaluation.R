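# Cold-start and pairwise cross-validation, balanced negative sampling,
# threshold metrics, AUC/AUPR, repeated-run aggregation, and unknown-pair
# ranking.

#' Sample negative (unknown-status) pairs
#'
#' Draws `n` distinct zero entries of the interaction matrix uniformly without
#' replacement; positives can never be drawn. Presumed negatives for training
#' and evaluation are taken from the unknown pairs, matching the usual
#' balanced negative-sampling protocol for sparse interaction data.
#'
#' @param Y Binary interaction matrix.
#' @param n Number of negatives (commonly `sum(Y)` for a balanced set).
#' @param exclude Optional 2-column matrix/data.frame of (row, col) indices to
#'   exclude in addition to the positives.
#' @param seed RNG seed.
#' @return A `data.frame` with integer columns `row` and `col`.
#' @export
sample_negatives <- function(Y, n, exclude = NULL, seed = 1L) {
  stopifnot(is.matrix(Y))
  zero_idx <- which(Y == 0L)
  if (!is.null(exclude) && NROW(exclude) > 0L) {
    exclude <- as.matrix(exclude)
    excl_lin <- (exclude[, 2L] - 1L) * nrow(Y) + exclude[, 1L]
    zero_idx <- setdiff(zero_idx, excl_lin)
  }
  if (n > length(zero_idx)) {
    stop(sprintf("requested %d negatives but only %d eligible unknown pairs exist (deficit %d)",
                 n, length(zero_idx), n - length(zero_idx)), call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  sel <- sample(zero_idx, n)
  data.frame(row = ((sel - 1L) %% nrow(Y)) + 1L,
             col = ((sel - 1L) %/% nrow(Y)) + 1L)
}

# Balanced negatives drawn to mirror the cross-validation scheme: under CV1
# (masked lncRNA rows) each row contributes as many negatives as it has
# positives (capped by its zeros), so test folds stay balanced in the
# cold-start regime; CV2 is the transpose; CV3 samples globally.
.sample_negatives_scheme <- function(Y, scheme, seed) {
  if (scheme == "CV3") return(sample_negatives(Y, sum(Y), seed = seed))
  margin <- if (scheme == "CV1") 1L else 2L
  units <- seq_len(dim(Y)[margin])
  out <- vector("list", length(units))
  for (u in units) {
    Yu <- if (margin == 1L) Y[u, , drop = FALSE] else Y[, u, drop = FALSE]
    npos <- sum(Yu)
    nzero <- length(Yu) - npos
    nneg <- min(npos, nzero)
    if (nneg == 0L) next
    zeros <- which(Yu == 0L)
    old <- .save_rng()
    set.seed((seed + 7L * u) %% .Machine$integer.max)
    sel <- sample(zeros, nneg)
    .restore_rng(old)
    out[[u]] <- if (margin == 1L) data.frame(row = u, col = sel)
                else data.frame(row = sel, col = u)
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Cross-validation splits over an interaction matrix
#'
#' Three schemes: `"CV1"` partitions lncRNA rows into folds (test pairs are
#' all labeled pairs in the masked rows — prediction for entirely new
#' lncRNAs); `"CV2"` does the same over protein columns; `"CV3"` partitions
#' the labeled pairs themselves, stratified by label. Labeled pairs are the
#' positives plus balanced sampled negatives (supplied or sampled internally
#' with the same seed).
#'
#' @param Y Binary interaction matrix.
#' @param scheme `"CV1"`, `"CV2"` or `"CV3"`.
#' @param n_folds Number of folds (default 5).
#' @param seed RNG seed.
#' @param negatives Optional `data.frame(row, col)` of presumed negatives; if
#'   `NULL`, sampled via the scheme-aware balanced sampler.
#' @return A list of folds; each fold is a list with `fold`, `train` and
#'   `test`, the latter two `data.frame(row, col, label)`.
#' @export
make_cv_splits <- function(Y, scheme = c("CV1", "CV2", "CV3"), n_folds = 5L,
                           seed = 1L, negatives = NULL) {
  scheme <- match.arg(scheme)
  n_folds <- as.integer(n_folds)
  stopifnot(is.matrix(Y), n_folds >= 2L)
  if (is.null(negatives)) negatives <- .sample_negatives_scheme(Y, scheme, seed)
  pos <- which(Y == 1L, arr.ind = TRUE)
  pairs <- rbind(
    data.frame(row = as.integer(pos[, 1L]), col = as.integer(pos[, 2L]), label = 1L),
    data.frame(row = negatives$row, col = negatives$col, label = 0L)
  )
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (scheme == "CV1" || scheme == "CV2") {
    margin <- if (scheme == "CV1") "row" else "col"
    n_units <- if (scheme == "CV1") nrow(Y) else ncol(Y)
    if (n_units < n_folds) {
      stop(sprintf("%s needs at least as many %ss as folds", scheme,
                   if (scheme == "CV1") "row" else "column"), call. = FALSE)
    }
    unit_fold <- sample(rep_len(seq_len(n_folds), n_units))
    pair_fold <- unit_fold[pairs[[margin]]]
  } else {
    if (nrow(pairs) < n_folds) stop("fewer labeled pairs than folds", call. = FALSE)
    pair_fold <- integer(nrow(pairs))
    for (lab in c(0L, 1L)) {
      idx <- which(pairs$label == lab)
      pair_fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  }
  lapply(seq_len(n_folds), function(f) {
    list(fold = f,
         train = pairs[pair_fold != f, , drop = FALSE],
         test = pairs[pair_fold == f, , drop = FALSE])
  })
}

#' Threshold classification metrics from a confusion table
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), accuracy =
#' (TP+TN)/(TP+FP+TN+FN), F1 = 2PR/(P+R). Degenerate denominators yield 0
#' with a warning so that fold averages stay defined.
#'
#' @param TP,FP,TN,FN Nonnegative integer counts.
#' @return Named numeric vector `c(precision, recall, accuracy, f1)`.
#' @export
compute_point_metrics <- function(TP, FP, TN, FN) {
  stopifnot(TP >= 0, FP >= 0, TN >= 0, FN >= 0, TP + FP + TN + FN > 0)
  precision <- if (TP + FP == 0) {
    warning("no predicted positives; precision set to 0", call. = FALSE); 0
  } else TP / (TP + FP)
  recall <- if (TP + FN == 0) {
    warning("no actual positives; recall set to 0", call. = FALSE); 0
  } else TP / (TP + FN)
  accuracy <- (TP + TN) / (TP + FP + TN + FN)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, accuracy = accuracy, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outscores a random negative, with ties counted half (midranks).
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, higher = more likely positive.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L)
  nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC requires both classes to be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-wise area under the interpolated-precision envelope: for each distinct
#' score threshold (descending), the PR point (recall, precision) is computed;
#' interpolated precision at recall r is the maximum precision over points
#' with recall >= r, and the area is the sum of recall increments times that
#' envelope. No linear interpolation between PR points is used. With constant
#' scores the AUPR equals the positive prevalence.
#'
#' @param labels Binary 0/1 vector with at least one positive.
#' @param scores Numeric scores.
#' @return AUPR in `[0, 1]`.
#' @export
compute_aupr <- function(labels, scores) {
  labels <- as.integer(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0L, 1L)))
  npos <- sum(labels == 1L)
  if (npos == 0L) stop("AUPR requires at least one positive", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  pred_pos <- seq_along(lab)
  # one PR point per distinct threshold (last index within each tie group)
  thr_end <- which(!duplicated(sc, fromLast = TRUE))
  precision <- tp[thr_end] / pred_pos[thr_end]
  recall <- tp[thr_end] / npos
  # precision envelope: max precision over equal-or-higher recall
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

#' Rank unknown pairs by predicted interaction probability
#'
#' Scores every zero-entry (unknown) pair of the dataset with a trained
#' cascade model, optionally restricted to one lncRNA row or one protein
#' column (the "new entity" case-study protocol), and returns them in
#' descending-score order. Ties are broken lexicographically by
#' (lncrna_id, protein_id); ranks are 1-based.
#'
#' @param model A fitted `cascade_model`.
#' @param dataset An `lpi_dataset`.
#' @param features Pre-computed feature list, as from [featurize_dataset()]
#'   (must match the feature space the model was trained on).
#' @param restrict Optional single lncRNA or protein id.
#' @return `data.frame(lncrna_id, protein_id, score, rank)`.
#' @export
rank_unknown_pairs <- function(model, dataset, features, restrict = NULL) {
  stopifnot(inherits(model, "cascade_model"), inherits(dataset, "lpi_dataset"))
  Y <- dataset$Y
  zero <- which(Y == 0L, arr.ind = TRUE)
  if (!is.null(restrict)) {
    if (restrict %in% rownames(Y)) {
      zero <- zero[zero[, 1L] == match(restrict, rownames(Y)), , drop = FALSE]
    } else if (restrict %in% colnames(Y)) {
      zero <- zero[zero[, 2L] == match(restrict, colnames(Y)), , drop = FALSE]
    } else {
      stop(sprintf("restrict id '%s' not found among lncRNAs or proteins", restrict),
           call. = FALSE)
    }
  }
  if (nrow(zero) == 0L) {
    return(data.frame(lncrna_id = character(0), protein_id = character(0),
                      score = numeric(0), rank = integer(0)))
  }
  X <- pair_features(features, zero[, 1L], zero[, 2L])
  score <- predict(model, X)
  out <- data.frame(lncrna_id = rownames(Y)[zero[, 1L]],
                    protein_id = colnames(Y)[zero[, 2L]],
                    score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$lncrna_id, out$protein_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Fraction of true interactions among the top-N ranked pairs
#'
#' @param ranked A ranked `data.frame` (descending score order) carrying a
#'   binary `label` column, or bare labels in ranked order.
#' @param N Cutoff.
#' @return Percentage in `[0, 100]`.
#' @export
top_n_true_fraction <- function(ranked, N) {
  labels <- if (is.data.frame(ranked)) ranked$label else ranked
  stopifnot(!is.null(labels), N >= 1L)
  if (N > length(labels)) {
    stop(sprintf("N = %d exceeds the ranking length %d", N, length(labels)),
         call. = FALSE)
  }
  100 * sum(labels[seq_len(N)] == 1L) / N
}

#' Featurize a dataset into lncRNA and protein feature matrices
#'
#' lncRNAs get `4^k`-dimensional k-mer composition; proteins get the
#' segment-hash autoencoder embedding (trained on this dataset's proteins).
#'
#' @param dataset An `lpi_dataset`.
#' @param k lncRNA k-mer size (default 4).
#' @param K Protein sliding-window size (default 3).
#' @param vocab_size,M,embedding_dim,epochs,learning_rate Protein embedding
#'   settings (see [protein_featurize()]).
#' @param seed Seed for the autoencoder.
#' @param allow_unknown Accept unknown residues in the protein hash.
#' @return List with `lncrna` (matrix), `protein` (matrix) and `encoder`.
#' @export
featurize_dataset <- function(dataset, k = 4L, K = 3L, vocab_size = 8191L,
                              M = 600L, embedding_dim = 544L, epochs = 100L,
                              learning_rate = 1e-3, seed = 1L,
                              allow_unknown = FALSE) {
  stopifnot(inherits(dataset, "lpi_dataset"))
  L <- kmer_featurize(dataset$lncrnas, k = k)
  pf <- protein_featurize(dataset$proteins, K = K, vocab_size = vocab_size,
                          M = M, embedding_dim = embedding_dim, epochs = epochs,
                          learning_rate = learning_rate, seed = seed,
                          allow_unknown = allow_unknown)
  list(lncrna = L, protein = pf$embeddings, encoder = pf$encoder)
}

#' Pair feature matrix for (row, col) index pairs
#'
#' Concatenates the lncRNA composition vector and the protein embedding for
#' each candidate pair (default total dimension 256 + 544 = 800).
#'
#' @param features Feature list from [featurize_dataset()].
#' @param rows,cols Integer row (lncRNA) and column (protein) indices.
#' @return Numeric matrix, one row per pair.
#' @export
pair_features <- function(features, rows, cols) {
  stopifnot(length(rows) == length(cols))
  X <- cbind(features$lncrna[rows, , drop = FALSE],
             features$protein[cols, , drop = FALSE])
  dimnames(X) <- list(NULL, paste0("f", seq_len(ncol(X))))
  X
}

#' Repeated cross-validation experiment
#'
#' Per repeat: fresh balanced negative sample and fresh splits (seed = base
#' seed + repeat index), a cascade trained per fold, test pairs scored, six
#' metrics (precision, recall, accuracy, F1, AUC, AUPR) computed per fold and
#' averaged over folds. The report carries per-repeat rows plus mean and
#' standard deviation over repeats. Features are computed once (they are
#' unsupervised functions of the sequences).
#'
#' @param dataset An `lpi_dataset`.
#' @param scheme `"CV1"`, `"CV2"` or `"CV3"`.
#' @param n_folds Folds per repeat (default 5).
#' @param repeats Number of repeats (default 20, matching the usual
#'   repeated-run protocol; tests and examples use fewer).
#' @param cascade Cascade settings, a [cascade_config()]; its seed is
#'   re-derived per repeat and fold.
#' @param features Optional pre-computed [featurize_dataset()] output.
#' @param seed Base seed.
#' @param keep_predictions Keep per-fold test predictions in the report.
#' @param ... Passed to [featurize_dataset()] when `features` is `NULL`.
#' @return An `lpi_cv_report`: list with `per_repeat` (data.frame), `summary`
#'   (mean/sd per metric), `scheme`, `n_folds`, `repeats`, `seed` and
#'   optionally `predictions`.
#' @export
run_cv_experiment <- function(dataset, scheme = c("CV1", "CV2", "CV3"),
                              n_folds = 5L, repeats = 20L,
                              cascade = cascade_config(), features = NULL,
                              seed = 1L, keep_predictions = FALSE, ...) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(dataset, "lpi_dataset"), repeats >= 1L)
  if (is.null(features)) {
    features <- featurize_dataset(dataset, seed = seed, ...)
  }
  metric_names <- c("precision", "recall", "accuracy", "f1", "auc", "aupr")
  per_repeat <- matrix(NA_real_, repeats, length(metric_names),
                       dimnames = list(NULL, metric_names))
  predictions <- if (keep_predictions) vector("list", repeats) else NULL
  for (r in seq_len(repeats)) {
    seed_r <- (seed + r) %% .Machine$integer.max
    splits <- make_cv_splits(dataset$Y, scheme, n_folds = n_folds, seed = seed_r)
    fold_metrics <- matrix(NA_real_, length(splits), length(metric_names))
    fold_preds <- if (keep_predictions) vector("list", length(splits)) else NULL
    for (f in seq_along(splits)) {
      sp <- splits[[f]]
      cfg <- cascade
      cfg$seed <- (seed_r + 7919L * f) %% .Machine$integer.max
      X_tr <- pair_features(features, sp$train$row, sp$train$col)
      X_te <- pair_features(features, sp$test$row, sp$test$col)
      model <- fit_cascade(X_tr, sp$train$label, cfg)
      p <- predict(model, X_te)
      y <- sp$test$label
      pred_lab <- as.integer(p >= 0.5)
      TP <- sum(pred_lab == 1L & y == 1L); FP <- sum(pred_lab == 1L & y == 0L)
      TN <- sum(pred_lab == 0L & y == 0L); FN <- sum(pred_lab == 0L & y == 1L)
      pm <- suppressWarnings(compute_point_metrics(TP, FP, TN, FN))
      auc <- if (length(unique(y)) == 2L) compute_auc(y, p) else NA_real_
      aupr <- if (any(y == 1L)) compute_aupr(y, p) else NA_real_
      fold_metrics[f, ] <- c(pm, auc, aupr)
      if (keep_predictions) {
        fold_preds[[f]] <- data.frame(repeat_id = r, fold = f,
                                      row = sp$test$row, col = sp$test$col,
                                      label = y, score = p)
      }
    }
    per_repeat[r, ] <- colMeans(fold_metrics, na.rm = TRUE)
    if (keep_predictions) predictions[[r]] <- do.call(rbind, fold_preds)
  }
  per_repeat <- as.data.frame(per_repeat)
  per_repeat <- cbind(data.frame(repeat_id = seq_len(repeats)), per_repeat)
  summary <- data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(per_repeat[[m]]), numeric(1)),
    sd = vapply(metric_names, function(m) stats::sd(per_repeat[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(list(per_repeat = per_repeat, summary = summary, scheme = scheme,
                 n_folds = n_folds, repeats = repeats, seed = seed,
                 predictions = if (keep_predictions) do.call(rbind, predictions)),
            class = "lpi_cv_report")
}

#' @export
print.lpi_cv_report <- function(x, ...) {
  cat(sprintf("lpi_cv_report: %s, %d folds x %d repeat(s), base seed %d\n",
              x$scheme, x$n_folds, x$repeats, x$seed))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Write a CV report as TSV (per-repeat) plus a JSON summary
#'
#' @param report An `lpi_cv_report`.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_cv_report <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "lpi_cv_report"))
  if (!is.null(tsv_path)) {
    utils::write.table(report$per_repeat, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    means <- stats::setNames(as.list(report$summary$mean), report$summary$metric)
    sds <- stats::setNames(as.list(report$summary$sd), report$summary$metric)
    jsonlite::write_json(
      list(scheme = report$scheme, n_folds = report$n_folds,
           repeats = report$repeats, seed = report$seed,
           mean = means, sd = sds),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
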