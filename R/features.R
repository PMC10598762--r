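# k-mer tokenization and count vectorization: the numeric encoding that
# turns barcode sequences into a sparse sample x vocabulary count matrix.

#' Tokenize a sequence into overlapping k-mers
#'
#' Left-to-right windows of width `k` at stride 1: a sequence of length L
#' yields `max(0, L - k + 1)` tokens. Ambiguity codes (N, R, Y, ...) are
#' kept verbatim inside tokens; they simply become rare vocabulary
#' entries.
#'
#' @param sequence A single character string.
#' @param k k-mer size (>= 1).
#' @return Character vector of uppercase tokens (possibly empty).
#' @export
#' @examples
#' kmerize("ACGTACGT", 7)
kmerize <- function(sequence, k) {
  stopifnot(length(sequence) == 1L, k >= 1)
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, 1:(L - k + 1L), k:L)
}

# token lists for many sequences at once
kmerize_all <- function(sequences, k) lapply(sequences, kmerize, k = k)

#' Build a k-mer vocabulary from a training corpus
#'
#' The vocabulary is the lexicographically sorted set of distinct tokens
#' observed in the training corpus only; it is frozen at training time and
#' prediction-time tokens outside it are dropped by [vectorize()].
#'
#' @param token_lists List of token vectors (from [kmerize()]).
#' @return A `kmer_vocab`: list with `k`, `tokens` (sorted), `index`
#'   (named integer positions 1..V).
#' @export
build_vocabulary <- function(token_lists) {
  toks <- unlist(token_lists, use.names = FALSE)
  if (length(toks) == 0L) {
    stop("cannot build a vocabulary from an all-empty corpus")
  }
  tokens <- sort(unique(toks), method = "radix")
  k <- unique(nchar(tokens))
  if (length(k) != 1L) stop("tokens of mixed length in corpus")
  structure(list(k = as.integer(k), tokens = tokens,
                 index = setNames(seq_along(tokens), tokens)),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat("<kmer_vocab> k=", x$k, ", ", length(x$tokens), " tokens\n", sep = "")
  invisible(x)
}

#' Count-vectorize token lists against a fixed vocabulary
#'
#' Entry (i, j) is the number of occurrences of vocabulary token j in
#' sample i. Out-of-vocabulary tokens are silently dropped (the
#' fit-then-transform contract for prediction-time data).
#'
#' @param token_lists List of token vectors.
#' @param vocab A `kmer_vocab`.
#' @return Sparse integer count matrix (`dgCMatrix`), one row per sample,
#'   columns named by vocabulary token.
#' @export
vectorize <- function(token_lists, vocab) {
  stopifnot(inherits(vocab, "kmer_vocab"), length(vocab$tokens) > 0L)
  n <- length(token_lists)
  V <- length(vocab$tokens)
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    j <- match(token_lists[[i]], vocab$tokens)
    j <- j[!is.na(j)]
    if (length(j)) {
      tab <- tabulate(j, nbins = V)
      nz <- which(tab > 0L)
      ii[[i]] <- rep.int(i, length(nz)); jj[[i]] <- nz; xx[[i]] <- tab[nz]
    }
  }
  Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                       j = as.integer(unlist(jj)),
                       x = as.numeric(unlist(xx)), dims = c(n, V),
                       dimnames = list(NULL, vocab$tokens))
}

#' One-call featurization of raw sequences
#'
#' @param sequences Character vector of sequences.
#' @param vocab Either a `kmer_vocab` (transform mode) or `NULL`, in which
#'   case a vocabulary is built from `sequences` (fit mode).
#' @param k k-mer size; required when `vocab` is `NULL`.
#' @return List with `matrix` (sparse counts) and `vocab`.
#' @export
featurize <- function(sequences, vocab = NULL, k = 7L) {
  if (is.null(vocab)) {
    toks <- kmerize_all(sequences, k)
    vocab <- build_vocabulary(toks)
  } else {
    toks <- kmerize_all(sequences, vocab$k)
  }
  list(matrix = vectorize(toks, vocab), vocab = vocab)
}

#' Export a count matrix and vocabulary to disk
#'
#' Writes the sparse count matrix in MatrixMarket format plus a
#' one-token-per-line vocabulary file next to it.
#'
#' @param counts Sparse count matrix from [vectorize()].
#' @param vocab The matching `kmer_vocab`.
#' @param mtx_path Output path for the MatrixMarket file.
#' @param vocab_path Output path for the vocabulary (default: `mtx_path`
#'   with a `.vocab.txt` suffix).
#' @return `mtx_path`, invisibly.
#' @export
write_feature_matrix <- function(counts, vocab, mtx_path,
                                 vocab_path = paste0(mtx_path, ".vocab.txt")) {
  Matrix::writeMM(as(counts, "generalMatrix"), mtx_path)
  writeLines(vocab$tokens, vocab_path)
  invisible(mtx_path)
}
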