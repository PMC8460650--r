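# Shared fixtures and independent oracles used across test files.

# Write a FASTA file from id -> sequence pairs; returns the path.
write_tmp_fasta <- function(ids, seqs, wrap = NULL) {
  path <- tempfile(fileext = ".fa")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- seqs[i]
    if (is.null(wrap)) {
      writeLines(s, con)
    } else {
      starts <- seq(1, nchar(s), by = wrap)
      writeLines(substring(s, starts, pmin(starts + wrap - 1, nchar(s))), con)
    }
  }
  path
}

random_dna <- function(len) paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                                  collapse = "")

# Brute-force dictionary-counting k-mer oracle: enumerate every window into a
# named tally, normalize over counted windows.
oracle_kmer <- function(seq, k) {
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1,
                                  drop = FALSE],
                      1, paste, collapse = ""))
  counts <- stats::setNames(numeric(length(kmers)), kmers)
  L <- nchar(seq)
  if (L >= k) {
    for (i in 1:(L - k + 1)) {
      w <- substr(seq, i, i + k - 1)
      if (w %in% kmers) counts[w] <- counts[w] + 1
    }
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# Brute-force AUC oracle: all positive-negative score comparisons, ties half.
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Brute-force AUPR oracle: sweep every distinct score threshold, compute
# (recall, precision), take the precision envelope, accumulate step areas.
oracle_aupr <- function(labels, scores) {
  npos <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- t(vapply(thresholds, function(th) {
    pred <- scores >= th
    c(recall = sum(labels == 1 & pred) / npos,
      precision = sum(labels == 1 & pred) / sum(pred))
  }, numeric(2)))
  pts <- pts[order(pts[, "recall"]), , drop = FALSE]
  env <- rev(cummax(rev(pts[, "precision"])))
  sum(diff(c(0, pts[, "recall"])) * env)
}

# Polynomial segment-hash oracle, written against the definition rather than
# the implementation's Horner loop.
oracle_hash <- function(segment, vocab_size) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  chars <- strsplit(segment, "")[[1]]
  total <- 0
  for (i in seq_along(chars)) {
    total <- total + (match(chars[i], aa) - 1) * 31^(i - 1)
  }
  total %% vocab_size
}

# Small linearly separable toy set: two Gaussian clouds at +/- mu with unit
# spread, a wide margin when mu = 3.
toy_separable <- function(n = 200, d = 10, mu = 3, seed = 42) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * d), n, d) + outer(ifelse(y == 1, mu, -mu), rep(1, d))
  colnames(X) <- paste0("f", seq_len(d))
  list(X = X, y = y)
}

# Small fast cascade config for unit tests.
tiny_cascade <- function(seed = 1, max_layers = 2L, ...) {
  cascade_config(max_layers = max_layers, oof_folds = 2L, num_trees = 15L,
                 xgb_nrounds = 10L, seed = seed, ...)
}

# Small synthetic dataset + features for pipeline tests (low dims for speed).
tiny_pipeline_fixture <- function(seed = 5, n_lncrnas = 40L, n_proteins = 8L) {
  ds <- generate_dataset(synthetic_spec(
    n_lncrnas = n_lncrnas, n_proteins = n_proteins,
    lncrna_length_range = c(80L, 120L), protein_length_range = c(60L, 90L),
    n_motif_classes = 2L, seed = seed))
  feats <- featurize_dataset(ds, k = 2L, M = 64L, embedding_dim = 16L,
                             epochs = 20L, seed = seed)
  list(dataset = ds, features = feats)
}
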