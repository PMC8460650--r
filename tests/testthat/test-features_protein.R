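test_that("segment_sequence yields L - K + 1 ordered overlapping windows", {
  expect_equal(segment_sequence("MKVLAT", K = 3), c("MKV", "KVL", "VLA", "LAT"))
  expect_equal(segment_sequence("MK", K = 2), "MK")
  expect_error(segment_sequence("M", K = 3, id = "p1"), "p1")

  set.seed(2)
  for (i in 1:25) {
    L <- sample(1:60, 1)
    s <- paste(sample(c("A", "C", "D", "M", "K"), L, replace = TRUE), collapse = "")
    K <- sample(1:L, 1)
    expect_length(segment_sequence(s, K), L - K + 1)
  }
})

test_that("hash_segments is deterministic, in range, and matches the oracle", {
  expect_equal(hash_segments("AAA", 8191), 0L)
  expect_equal(hash_segments("ACD", 8191), oracle_hash("ACD", 8191))
  expect_equal(hash_segments(c("MKV", "MKV")), rep(hash_segments("MKV"), 2))

  set.seed(4)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  segs <- replicate(50, paste(sample(aa, 3, replace = TRUE), collapse = ""))
  h <- hash_segments(segs, 8191)
  expect_true(all(h >= 0 & h < 8191))
  expect_equal(h, vapply(segs, oracle_hash, numeric(1), vocab_size = 8191,
                         USE.NAMES = FALSE))

  expect_error(hash_segments("AXB", allow_unknown = FALSE), "invalid")
  expect_silent(hash_segments("AXA", allow_unknown = TRUE))
})

test_that("hash collision rate stays modest at the default vocabulary", {
  set.seed(8)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  segs <- unique(replicate(1000, paste(sample(aa, 3, replace = TRUE), collapse = "")))
  h <- hash_segments(segs, 8191)
  collision_rate <- 1 - length(unique(h)) / length(h)
  expect_lt(collision_rate, 0.5)
})

test_that("pad_or_truncate fixes length and scales hashes into (0, 1]", {
  v <- pad_or_truncate(c(0L, 10L, 8190L, 5L), M = 6, vocab_size = 8191)
  expect_length(v, 6)
  expect_equal(v[1:4], c(1, 11, 8191, 6) / 8191)
  expect_equal(v[5:6], c(0, 0))

  v2 <- pad_or_truncate(0:7, M = 6, vocab_size = 8191)
  expect_equal(v2, (1:6) / 8191)

  v3 <- pad_or_truncate(0:5, M = 6, vocab_size = 8191)
  expect_equal(v3, (1:6) / 8191)
  expect_error(pad_or_truncate(1:3, M = 0), "M must be")
})

test_that("autoencoder training is seeded, shrinks loss, and shapes output", {
  set.seed(21)
  X <- matrix(runif(50 * 32), 50, 32)
  spec <- encoder_spec(input_length = 32, embedding_dim = 16, epochs = 100,
                       seed = 77)
  enc1 <- fit_autoencoder(X, spec)
  enc2 <- fit_autoencoder(X, spec)
  expect_identical(embed_proteins(enc1, X), embed_proteins(enc2, X))
  expect_lt(reconstruction_error(enc1, X), enc1$loss[1])
  expect_true(all(diff(enc1$loss[c(1, 100)]) < 0))
  expect_equal(dim(embed_proteins(enc1, X)), c(50L, 16L))
})

test_that("autoencoder validates its inputs", {
  expect_error(encoder_spec(input_length = 16, embedding_dim = 16), "smaller")
  X <- matrix(1, 1, 32)
  expect_error(fit_autoencoder(X, encoder_spec(32, 8)), "at least 2 rows")
  Xbad <- matrix(c(NA, runif(63)), 2, 32)
  expect_error(fit_autoencoder(Xbad, encoder_spec(32, 8)), "non-finite")
  enc <- fit_autoencoder(matrix(runif(64), 2, 32), encoder_spec(32, 8, epochs = 2))
  expect_error(embed_proteins(enc, matrix(0, 2, 31)), "expects")
})

test_that("identical proteins embed identically; different ones differ", {
  seqs <- c(a = "MKVLATMKVLATMKVLAT", b = "MKVLATMKVLATMKVLAT",
            c = "WWWYYYWWWYYYWWWYYY")
  pf <- protein_featurize(seqs, K = 3, M = 12, embedding_dim = 4, epochs = 10,
                          seed = 3)
  E <- pf$embeddings
  expect_equal(E["a", ], E["b", ])
  expect_false(isTRUE(all.equal(unname(E["a", ]), unname(E["c", ]))))
})

test_that("full protein featurization is a pure function of sequence and seed", {
  seqs <- c(p1 = "MKVLATWYCDE", p2 = "AAAKKKMMMLLL")
  a <- protein_featurize(seqs, K = 3, M = 8, embedding_dim = 3, epochs = 5, seed = 2)
  b <- protein_featurize(seqs, K = 3, M = 8, embedding_dim = 3, epochs = 5, seed = 2)
  expect_identical(a$embeddings, b$embeddings)
})
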