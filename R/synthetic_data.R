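# Seeded synthetic fixtures: FASTA-compatible sequences plus an interaction
# matrix with planted motif-driven signal, so the whole pipeline is testable
# without any external data.

#' Specification for a synthetic interaction dataset
#'
#' Each lncRNA and each protein is assigned a latent compatibility class.
#' A class-specific nucleotide motif is embedded repeatedly in each lncRNA
#' (shifting its 4-mer composition) and a class-specific amino-acid motif in
#' each protein, so both featurizers can in principle recover the class.
#' Interactions arise with probability `interaction_prob_match` when the two
#' classes match and `interaction_prob_mismatch` otherwise, then labels flip
#' with probability `label_noise`.
#'
#' Defaults emulate the shape of curated interaction datasets (hundreds of
#' lncRNAs, tens of proteins, sparse matrix) at desk scale: 150 x 20 with a
#' strong planted signal (0.6 vs 0.02, no noise).
#'
#' @param n_lncrnas,n_proteins Entity counts.
#' @param lncrna_length_range,protein_length_range Inclusive length ranges.
#' @param n_motif_classes Number of latent compatibility classes.
#' @param interaction_prob_match,interaction_prob_mismatch Interaction
#'   probabilities for matching / mismatching classes.
#' @param label_noise Independent flip probability applied to every entry.
#' @param seed RNG seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lncrnas = 150L, n_proteins = 20L,
                           lncrna_length_range = c(200L, 400L),
                           protein_length_range = c(120L, 300L),
                           n_motif_classes = 4L,
                           interaction_prob_match = 0.6,
                           interaction_prob_mismatch = 0.02,
                           label_noise = 0, seed = 1L) {
  spec <- list(n_lncrnas = as.integer(n_lncrnas),
               n_proteins = as.integer(n_proteins),
               lncrna_length_range = as.integer(lncrna_length_range),
               protein_length_range = as.integer(protein_length_range),
               n_motif_classes = as.integer(n_motif_classes),
               interaction_prob_match = interaction_prob_match,
               interaction_prob_mismatch = interaction_prob_mismatch,
               label_noise = label_noise, seed = as.integer(seed))
  probs <- c(spec$interaction_prob_match, spec$interaction_prob_mismatch,
             spec$label_noise)
  if (any(probs < 0) || any(probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(spec$n_lncrnas >= 1L, spec$n_proteins >= 1L,
            spec$n_motif_classes >= 1L,
            length(spec$lncrna_length_range) == 2L,
            length(spec$protein_length_range) == 2L,
            spec$lncrna_length_range[1L] >= 8L,
            spec$protein_length_range[1L] >= 8L,
            diff(spec$lncrna_length_range) >= 0L,
            diff(spec$protein_length_range) >= 0L)
  structure(spec, class = "synthetic_spec")
}

.random_seq <- function(len, alphabet) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Overwrite `motif` into `seq` at `n_copies` random positions (copies may
# overlap; multiplicity scales with sequence length upstream).
.plant_motif <- function(seq, motif, n_copies) {
  L <- nchar(seq)
  w <- nchar(motif)
  if (n_copies < 1L || w > L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  mot <- strsplit(motif, "", fixed = TRUE)[[1L]]
  starts <- sample.int(L - w + 1L, n_copies, replace = TRUE)
  for (s in starts) chars[s:(s + w - 1L)] <- mot
  paste(chars, collapse = "")
}

#' Generate a synthetic dataset with planted interaction signal
#'
#' Fully seeded: the same spec yields an identical dataset. Latent classes
#' are stored in `dataset$meta` (`lncrna_class`, `protein_class`,
#' `lncrna_motifs`, `protein_motifs`) for calibration tests.
#'
#' @param spec A [synthetic_spec()].
#' @return An `lpi_dataset`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(spec$seed)
  C <- spec$n_motif_classes
  # distinct planted motifs per class
  lnc_motifs <- replicate(C, .random_seq(8L, NUC_ALPHABET))
  pro_motifs <- replicate(C, .random_seq(6L, AA_ALPHABET))
  while (anyDuplicated(lnc_motifs)) lnc_motifs <- replicate(C, .random_seq(8L, NUC_ALPHABET))
  while (anyDuplicated(pro_motifs)) pro_motifs <- replicate(C, .random_seq(6L, AA_ALPHABET))

  lnc_class <- sample(rep_len(seq_len(C), spec$n_lncrnas))
  pro_class <- sample(rep_len(seq_len(C), spec$n_proteins))

  lnc_len <- sample(spec$lncrna_length_range[1L]:spec$lncrna_length_range[2L],
                    spec$n_lncrnas, replace = TRUE)
  pro_len <- sample(spec$protein_length_range[1L]:spec$protein_length_range[2L],
                    spec$n_proteins, replace = TRUE)

  lnc_seq <- vapply(seq_len(spec$n_lncrnas), function(i) {
    s <- .random_seq(lnc_len[i], NUC_ALPHABET)
    .plant_motif(s, lnc_motifs[lnc_class[i]], max(1L, lnc_len[i] %/% 40L))
  }, character(1))
  pro_seq <- vapply(seq_len(spec$n_proteins), function(j) {
    s <- .random_seq(pro_len[j], AA_ALPHABET)
    .plant_motif(s, pro_motifs[pro_class[j]], max(1L, pro_len[j] %/% 30L))
  }, character(1))

  lnc_ids <- sprintf("lnc%04d", seq_len(spec$n_lncrnas))
  pro_ids <- sprintf("prot%03d", seq_len(spec$n_proteins))

  match_mat <- outer(lnc_class, pro_class, `==`)
  p <- ifelse(match_mat, spec$interaction_prob_match,
              spec$interaction_prob_mismatch)
  Y <- matrix(as.integer(stats::runif(length(p)) < p), nrow(p), ncol(p))
  if (spec$label_noise > 0) {
    flip <- stats::runif(length(Y)) < spec$label_noise
    Y[flip] <- 1L - Y[flip]
  }
  dimnames(Y) <- list(lnc_ids, pro_ids)
  Y <- structure(Y, class = c("lpi_matrix", class(Y)))

  lpi_dataset(
    data.frame(id = lnc_ids, sequence = lnc_seq, stringsAsFactors = FALSE),
    data.frame(id = pro_ids, sequence = pro_seq, stringsAsFactors = FALSE),
    Y,
    meta = list(spec = spec, lncrna_class = lnc_class, protein_class = pro_class,
                lncrna_motifs = lnc_motifs, protein_motifs = pro_motifs)
  )
}

#' Ready-made worked-example fixtures
#'
#' Returns the canonical three-tree class-distribution example used to
#' illustrate forest probability averaging, and the five published dataset
#' dimension triples (lncRNAs, proteins, known interactions) useful for
#' unknown-pair arithmetic checks.
#'
#' @return A list with `tree_distributions` (3 x 2 matrix of
#'   (p_positive, p_negative) rows) and `dataset_dims` (data.frame with
#'   columns `dataset`, `n_lncrnas`, `n_proteins`, `n_interactions`).
#' @export
worked_example_fixture <- function() {
  list(
    tree_distributions = matrix(c(0.3750, 0.6250,
                                  0.5556, 0.4444,
                                  1.0000, 0.0000),
                                nrow = 3L, byrow = TRUE,
                                dimnames = list(NULL, c("p_positive", "p_negative"))),
    dataset_dims = data.frame(
      dataset = 1:5,
      n_lncrnas = c(935L, 885L, 990L, 109L, 1704L),
      n_proteins = c(59L, 84L, 27L, 35L, 42L),
      n_interactions = c(3479L, 3265L, 4158L, 948L, 22133L)
    )
  )
}
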