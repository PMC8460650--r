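#' Sliding-window segmentation of a protein sequence
#'
#' Divides a length-`L` sequence into the `L - K + 1` overlapping substrings
#' of length `K`, in order.
#'
#' @param seq Canonical amino-acid sequence.
#' @param K Window size (default 3).
#' @param id Identifier used in error messages.
#' @return Character vector of `nchar(seq) - K + 1` segments.
#' @export
segment_sequence <- function(seq, K = 3L, id = "<protein>") {
  stopifnot(is.character(seq), length(seq) == 1L)
  K <- as.integer(K)
  L <- nchar(seq)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > L) {
    stop(sprintf("protein '%s': window size K = %d exceeds sequence length %d",
                 id, K, L), call. = FALSE)
  }
  starts <- seq_len(L - K + 1L)
  substring(seq, starts, starts + K - 1L)
}

#' Hash equal-length segments to integers
#'
#' Deterministic polynomial hash `h(s) = (sum_i code(s_i) * 31^i) mod
#' vocab_size`, where `code` is the fixed alphabetical 0-19 index of the
#' amino acid (A, C, D, ..., Y) and 20 encodes the unknown residue `X` when
#' permissive canonicalization is in use.
#'
#' @param segments Character vector of equal-length segments.
#' @param vocab_size Hash modulus (default 8191, prime).
#' @param allow_unknown Accept the `X` unknown code; otherwise any character
#'   outside the 20 standard codes is an error.
#' @return Integer vector of hashes in `[0, vocab_size)`.
#' @export
hash_segments <- function(segments, vocab_size = 8191L, allow_unknown = FALSE) {
  if (length(segments) == 0L) return(integer(0))
  vocab_size <- as.integer(vocab_size)
  if (vocab_size < 2L) stop("vocab_size must be >= 2", call. = FALSE)
  K <- unique(nchar(segments))
  if (length(K) != 1L) stop("segments must all have the same length", call. = FALSE)
  valid <- c(AA_ALPHABET, if (allow_unknown) "X")
  chars <- strsplit(segments, "", fixed = TRUE)
  bad <- setdiff(unique(unlist(chars)), valid)
  if (length(bad) > 0L) {
    stop(sprintf("segment contains invalid amino-acid code(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  codes <- matrix(AA_CODES[unlist(chars)], nrow = K)
  # Horner evaluation from the highest power down, reducing mod vocab_size at
  # each step so doubles never lose integer precision.
  h <- numeric(ncol(codes))
  for (i in K:1) h <- (h * 31 + codes[i, ]) %% vocab_size
  as.integer(h)
}

#' Pad or truncate a hash sequence to fixed length, scaled to [0, 1]
#'
#' Hashes are shifted to `[1, vocab_size]` (so the pad value 0 is reserved)
#' and divided by `vocab_size`. Sequences longer than `M` keep their first `M`
#' values; shorter ones are right-padded with `pad_value`.
#'
#' @param hashes Integer vector of segment hashes in `[0, vocab_size)`.
#' @param M Fixed output length (default 600).
#' @param pad_value Pad value on the scaled axis (default 0).
#' @param vocab_size Hash modulus used to produce `hashes`.
#' @return Numeric vector of length `M` with values in `[0, 1]`.
#' @export
pad_or_truncate <- function(hashes, M = 600L, pad_value = 0, vocab_size = 8191L) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  v <- (as.numeric(hashes) + 1) / vocab_size
  if (length(v) >= M) v[seq_len(M)] else c(v, rep(pad_value, M - length(v)))
}

#' Autoencoder specification
#'
#' Hyperparameters for the protein-embedding autoencoder: a feed-forward
#' encoder-decoder with one tanh hidden layer of width `embedding_dim`
#' (the bottleneck, which becomes the protein feature vector) and a linear
#' output layer, trained full-batch with Adam under squared-error loss.
#'
#' @param input_length Fixed padded input length `M` (default 600).
#' @param embedding_dim Bottleneck width, i.e. protein feature dimension
#'   (default 544, so 256 lncRNA + 544 protein = 800 pair features).
#' @param epochs Training passes (default 100).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed RNG seed for weight initialization.
#' @return A list of class `encoder_spec`.
#' @export
encoder_spec <- function(input_length = 600L, embedding_dim = 544L,
                         epochs = 100L, learning_rate = 1e-3, seed = 1L) {
  spec <- list(input_length = as.integer(input_length),
               embedding_dim = as.integer(embedding_dim),
               epochs = as.integer(epochs),
               learning_rate = learning_rate,
               seed = as.integer(seed))
  with(spec, {
    stopifnot(input_length >= 1L, embedding_dim >= 1L, epochs >= 1L,
              learning_rate > 0)
    if (embedding_dim >= input_length) {
      stop("embedding_dim must be smaller than input_length", call. = FALSE)
    }
  })
  structure(spec, class = "encoder_spec")
}

#' Fit the protein-embedding autoencoder
#'
#' Trains an encoder-decoder to reproduce its input under mean squared error:
#' `h = tanh(X W1 + b1)`, `Xhat = h W2 + b2`. The bottleneck activations `h`
#' are the protein embeddings. Training is full-batch Adam, reproducible under
#' `spec$seed`.
#'
#' @param X Numeric matrix, one fixed-length scaled hash vector per row.
#' @param spec An [encoder_spec()].
#' @return A fitted encoder of class `protein_encoder`, carrying the weights,
#'   the spec and the per-epoch loss history.
#' @export
fit_autoencoder <- function(X, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"), is.matrix(X))
  if (nrow(X) < 2L) stop("autoencoder training needs at least 2 rows", call. = FALSE)
  if (ncol(X) != spec$input_length) {
    stop(sprintf("X has %d columns but spec$input_length is %d",
                 ncol(X), spec$input_length), call. = FALSE)
  }
  if (!all(is.finite(X))) stop("X contains non-finite values", call. = FALSE)

  M <- spec$input_length
  d <- spec$embedding_dim
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed))
  set.seed(spec$seed)
  W1 <- matrix(stats::rnorm(M * d, sd = sqrt(1 / M)), M, d)
  b1 <- numeric(d)
  W2 <- matrix(stats::rnorm(d * M, sd = sqrt(1 / d)), d, M)
  b2 <- numeric(M)

  params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss <- numeric(spec$epochs)
  n <- nrow(X)

  for (ep in seq_len(spec$epochs)) {
    H <- tanh(sweep(X %*% params$W1, 2, params$b1, `+`))
    Xhat <- sweep(H %*% params$W2, 2, params$b2, `+`)
    R <- Xhat - X
    loss[ep] <- mean(R^2)
    dXhat <- 2 * R / length(R)
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(H, dXhat),
      b2 = colSums(dXhat)
    )
    dH <- dXhat %*% t(params$W2)
    dZ <- dH * (1 - H^2)
    grads$W1 <- crossprod(X, dZ)
    grads$b1 <- colSums(dZ)
    for (nm in names(params)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^ep)
      vhat <- v[[nm]] / (1 - beta2^ep)
      params[[nm]] <- params[[nm]] - spec$learning_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(c(params, list(spec = spec, loss = loss)), class = "protein_encoder")
}

#' Reconstruction loss of a fitted encoder on data
#'
#' @param encoder A `protein_encoder`.
#' @param X Numeric matrix with `spec$input_length` columns.
#' @return Mean squared reconstruction error.
#' @export
reconstruction_error <- function(encoder, X) {
  H <- .encode(encoder, X)
  Xhat <- sweep(H %*% encoder$W2, 2, encoder$b2, `+`)
  mean((Xhat - X)^2)
}

.encode <- function(encoder, X) {
  stopifnot(inherits(encoder, "protein_encoder"), is.matrix(X))
  if (ncol(X) != encoder$spec$input_length) {
    stop(sprintf("X has %d columns but the encoder expects %d",
                 ncol(X), encoder$spec$input_length), call. = FALSE)
  }
  tanh(sweep(X %*% encoder$W1, 2, encoder$b1, `+`))
}

#' Embed proteins with a fitted encoder
#'
#' @param encoder A fitted `protein_encoder`.
#' @param X Numeric matrix of fixed-length scaled hash vectors (rows =
#'   proteins).
#' @return Numeric matrix, one `embedding_dim`-vector per input row (rownames
#'   preserved).
#' @export
embed_proteins <- function(encoder, X) {
  H <- .encode(encoder, X)
  dimnames(H) <- list(rownames(X), paste0("e", seq_len(ncol(H))))
  H
}

#' Full protein featurization: segment, hash, pad, embed
#'
#' @param seqs Record `data.frame` (`id`, `sequence`) or character vector of
#'   canonical amino-acid sequences.
#' @param K Sliding-window size (default 3).
#' @param vocab_size Hash modulus (default 8191).
#' @param M Fixed padded length (default 600).
#' @param embedding_dim Bottleneck width (default 544).
#' @param epochs,learning_rate,seed Autoencoder training settings.
#' @param allow_unknown Accept `X` residues in the hash.
#' @return A list with `embeddings` (matrix, rows = proteins) and `encoder`
#'   (the fitted `protein_encoder`).
#' @export
protein_featurize <- function(seqs, K = 3L, vocab_size = 8191L, M = 600L,
                              embedding_dim = 544L, epochs = 100L,
                              learning_rate = 1e-3, seed = 1L,
                              allow_unknown = FALSE) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    seqs <- seqs$sequence
  } else {
    ids <- names(seqs)
  }
  X <- t(mapply(function(s, id) {
    segs <- segment_sequence(s, K, id = if (is.null(id)) "<protein>" else id)
    h <- hash_segments(segs, vocab_size, allow_unknown = allow_unknown)
    pad_or_truncate(h, M = M, vocab_size = vocab_size)
  }, seqs, if (is.null(ids)) vector("list", length(seqs)) else ids))
  rownames(X) <- ids
  spec <- encoder_spec(input_length = M, embedding_dim = embedding_dim,
                       epochs = epochs, learning_rate = learning_rate,
                       seed = seed)
  encoder <- fit_autoencoder(X, spec)
  list(embeddings = embed_proteins(encoder, X), encoder = encoder)
}

# Save/restore the global RNG state so seeded internals do not perturb the
# caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
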