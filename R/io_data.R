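#' Canonicalize a biological sequence
#'
#' Upper-cases a sequence and validates it against the declared alphabet.
#' Nucleotide sequences have `U` mapped to `T` (RNA input is accepted);
#' amino-acid sequences must use the 20 standard one-letter codes. With
#' `allow_unknown = TRUE`, characters outside the alphabet are mapped to `N`
#' (nucleotide; k-mer windows containing `N` are later dropped) or `X`
#' (amino acid; hashed to a dedicated unknown code) instead of being rejected.
#'
#' @param seq Character scalar, the raw sequence.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param allow_unknown Map out-of-alphabet characters to `N`/`X` instead of
#'   raising an error.
#' @param id Identifier used in error messages.
#' @return The canonical sequence string.
#' @export
canonicalize_sequence <- function(seq, alphabet = c("nucleotide", "amino-acid"),
                                  allow_unknown = FALSE, id = "<sequence>") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (alphabet == "nucleotide") {
    s <- chartr("U", "T", s)
    valid <- c(NUC_ALPHABET, if (allow_unknown) "N")
    sub_char <- "N"
  } else {
    valid <- c(AA_ALPHABET, if (allow_unknown) "X")
    sub_char <- "X"
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), valid)
  if (length(bad) > 0L) {
    if (!allow_unknown) {
      stop(sprintf("sequence '%s' contains character(s) outside the %s alphabet: %s",
                   id, alphabet, paste(bad, collapse = ", ")), call. = FALSE)
    }
    chars[chars %in% bad] <- sub_char
    s <- paste(chars, collapse = "")
  }
  s
}

#' Read and canonicalize sequences from a FASTA file
#'
#' Standard `>`-header FASTA with possibly wrapped sequence lines. Records are
#' returned in file order, canonicalized for the declared alphabet (see
#' [canonicalize_sequence()]).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"amino-acid"`.
#' @param allow_unknown Passed to [canonicalize_sequence()].
#' @return A `data.frame` with columns `id` and `sequence`, one row per record.
#'   An empty file yields a zero-row frame.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino-acid"),
                       allow_unknown = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("failed to parse FASTA '%s': %s",
                                                   path, conditionMessage(e)), call. = FALSE))
  if (length(set) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  # FASTA descriptions may carry annotations after the first token; the first
  # whitespace-delimited token is the record id.
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop(sprintf("FASTA '%s' contains a record with an empty header", path), call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("FASTA '%s' contains duplicated ids: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  seqs <- as.character(set)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop(sprintf("FASTA '%s': record '%s' has an empty sequence body",
                 path, ids[which(empty)[1L]]), call. = FALSE)
  }
  seqs <- mapply(canonicalize_sequence, seqs, id = ids,
                 MoreArgs = list(alphabet = alphabet, allow_unknown = allow_unknown),
                 USE.NAMES = FALSE)
  data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE)
}

#' Read an interaction edge list
#'
#' Tab-separated file with at least two columns (`lncrna_id`, `protein_id`) and
#' an optional third binary label column. Lines starting with `#` are treated
#' as comments/headers. Duplicate pairs are collapsed with a warning.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame` with columns `lncrna_id`, `protein_id` and, when a
#'   third column is present, `label` (integer 0/1).
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("edge list not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(lncrna_id = character(0), protein_id = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 2L)) {
    stop(sprintf("edge list '%s': line %d has fewer than 2 tab-separated fields",
                 path, lineno[which(nfield < 2L)[1L]]), call. = FALSE)
  }
  edges <- data.frame(
    lncrna_id = vapply(fields, `[`, character(1), 1L),
    protein_id = vapply(fields, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  if (all(nfield >= 3L)) {
    lab <- vapply(fields, `[`, character(1), 3L)
    if (!all(lab %in% c("0", "1"))) {
      stop(sprintf("edge list '%s': third column must be 0/1 labels", path), call. = FALSE)
    }
    edges$label <- as.integer(lab)
  }
  dup <- duplicated(edges[, c("lncrna_id", "protein_id")])
  if (any(dup)) {
    warning(sprintf("edge list '%s': %d duplicate pair(s) collapsed", path, sum(dup)),
            call. = FALSE)
    edges <- edges[!dup, , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

#' Build a binary lncRNA x protein interaction matrix
#'
#' Entry `Y[i, j] = 1` records a known interaction between the i-th lncRNA and
#' the j-th protein; `0` means the pair's status is unknown (not a verified
#' non-interaction). Row and column order follow the record order.
#'
#' @param lncrnas,proteins Sequence record frames (as from [read_fasta()]) or
#'   character vectors of ids.
#' @param edges A two-column `data.frame` (`lncrna_id`, `protein_id`) or a
#'   list of ids as from [read_edge_list()].
#' @return An integer matrix with `dimnames = list(lncrna_ids, protein_ids)`,
#'   of class `lpi_matrix`.
#' @export
build_interaction_matrix <- function(lncrnas, proteins, edges) {
  lnc_ids <- if (is.data.frame(lncrnas)) lncrnas$id else as.character(lncrnas)
  pro_ids <- if (is.data.frame(proteins)) proteins$id else as.character(proteins)
  if (anyDuplicated(lnc_ids)) stop("duplicated lncRNA ids", call. = FALSE)
  if (anyDuplicated(pro_ids)) stop("duplicated protein ids", call. = FALSE)
  Y <- matrix(0L, nrow = length(lnc_ids), ncol = length(pro_ids),
              dimnames = list(lnc_ids, pro_ids))
  if (NROW(edges) > 0L) {
    el <- if (is.data.frame(edges)) edges$lncrna_id else vapply(edges, `[`, character(1), 1L)
    ep <- if (is.data.frame(edges)) edges$protein_id else vapply(edges, `[`, character(1), 2L)
    bad_l <- setdiff(unique(el), lnc_ids)
    if (length(bad_l) > 0L) {
      stop(sprintf("edge references unknown lncRNA id(s): %s",
                   paste(bad_l, collapse = ", ")), call. = FALSE)
    }
    bad_p <- setdiff(unique(ep), pro_ids)
    if (length(bad_p) > 0L) {
      stop(sprintf("edge references unknown protein id(s): %s",
                   paste(bad_p, collapse = ", ")), call. = FALSE)
    }
    Y[cbind(match(el, lnc_ids), match(ep, pro_ids))] <- 1L
  }
  structure(Y, class = c("lpi_matrix", class(Y)))
}

#' Number of unknown (zero) pairs in an interaction matrix
#'
#' @param Y A binary interaction matrix.
#' @return `nrow(Y) * ncol(Y) - sum(Y)`.
#' @export
count_unknown_pairs <- function(Y) {
  stopifnot(is.matrix(Y), all(Y %in% c(0L, 1L)))
  length(Y) - sum(Y)
}

#' Bundle sequences and interactions into a dataset
#'
#' @param lncrnas,proteins Sequence record frames (`id`, `sequence`).
#' @param Y Interaction matrix whose dimnames match the record ids exactly.
#' @param meta Optional list of extra metadata (e.g. latent classes for
#'   synthetic data).
#' @return An object of class `lpi_dataset`.
#' @export
lpi_dataset <- function(lncrnas, proteins, Y, meta = list()) {
  stopifnot(is.data.frame(lncrnas), is.data.frame(proteins), is.matrix(Y))
  if (!identical(rownames(Y), lncrnas$id)) {
    stop("matrix rows do not match lncRNA records", call. = FALSE)
  }
  if (!identical(colnames(Y), proteins$id)) {
    stop("matrix columns do not match protein records", call. = FALSE)
  }
  structure(list(lncrnas = lncrnas, proteins = proteins, Y = Y, meta = meta),
            class = "lpi_dataset")
}

#' @export
print.lpi_dataset <- function(x, ...) {
  cat(sprintf("lpi_dataset: %d lncRNAs x %d proteins, %d known interactions (%d unknown pairs)\n",
              nrow(x$Y), ncol(x$Y), sum(x$Y), count_unknown_pairs(x$Y)))
  invisible(x)
}

#' Write a dataset as FASTA files plus a TSV edge list
#'
#' @param dataset An `lpi_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`lncrna_fasta`, `protein_fasta`,
#'   `edges`).
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "lpi_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(lncrna_fasta = file.path(dir, "lncrnas.fa"),
                protein_fasta = file.path(dir, "proteins.fa"),
                edges = file.path(dir, "interactions.tsv"))
  write_fasta(dataset$lncrnas, paths$lncrna_fasta)
  write_fasta(dataset$proteins, paths$protein_fasta)
  ones <- which(dataset$Y == 1L, arr.ind = TRUE)
  ones <- ones[order(ones[, 1L], ones[, 2L]), , drop = FALSE]
  writeLines(paste(rownames(dataset$Y)[ones[, 1L]],
                   colnames(dataset$Y)[ones[, 2L]], sep = "\t"),
             paths$edges)
  invisible(paths)
}

#' Read a dataset from FASTA files plus an edge list
#'
#' @param lncrna_fasta,protein_fasta FASTA paths.
#' @param edges_path TSV edge list path.
#' @param allow_unknown Passed to [read_fasta()].
#' @return An `lpi_dataset`.
#' @export
read_dataset <- function(lncrna_fasta, protein_fasta, edges_path,
                         allow_unknown = FALSE) {
  lnc <- read_fasta(lncrna_fasta, "nucleotide", allow_unknown = allow_unknown)
  pro <- read_fasta(protein_fasta, "amino-acid", allow_unknown = allow_unknown)
  edges <- read_edge_list(edges_path)
  lpi_dataset(lnc, pro, build_interaction_matrix(lnc, pro, edges))
}

# Minimal FASTA writer (60-column wrap).
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a ranked prediction table as TSV
#'
#' @param ranked A `data.frame` with columns `lncrna_id`, `protein_id`,
#'   `score`, `rank` (as from [rank_unknown_pairs()]).
#' @param path Output path.
#' @export
write_predictions <- function(ranked, path) {
  stopifnot(all(c("lncrna_id", "protein_id", "score", "rank") %in% names(ranked)))
  utils::write.table(ranked, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
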