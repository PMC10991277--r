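#' One-hot encode an amino-acid sequence
#'
#' Produces an \code{L_max x 20} binary matrix with columns in the canonical
#' alphabetical residue order (A, C, D, ..., Y). Sequences longer than
#' \code{L_max} are truncated at the C-terminus (the N-terminal prefix is
#' kept); shorter ones are zero-padded. The unknown residue \code{"X"}
#' encodes as an all-zero row, keeping the 20-column shape.
#'
#' @param sequence a single amino-acid string over the normalised alphabet.
#' @param L_max maximum encoded length (default 1000 residues).
#' @return matrix of 0/1 with attributes \code{true_length} (residues
#'   actually encoded) and \code{protein_id} (if the input is named).
#' @examples
#' m <- oneHotEncode("ACD", L_max = 5)
#' which(m[1, ] == 1)  # column "A"
#' @export
oneHotEncode <- function(sequence, L_max = 1000L) {
  stopifnot(length(sequence) == 1L, L_max >= 1L)
  if (is.na(sequence) || nchar(sequence) == 0L) stop("empty sequence")
  chars <- strsplit(as.character(sequence), "")[[1]]
  n <- min(length(chars), L_max)
  idx <- match(chars[seq_len(n)], AA_ALPHABET20)
  m <- matrix(0, nrow = L_max, ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET20))
  keep <- which(!is.na(idx))
  if (length(keep)) m[cbind(keep, idx[keep])] <- 1
  attr(m, "true_length") <- n
  attr(m, "protein_id") <- names(sequence)
  m
}

#' Decode a one-hot matrix back to a sequence
#'
#' Inverse of \code{\link{oneHotEncode}} on its image: rows summing to 1
#' decode to their residue, all-zero rows within \code{true_length} decode to
#' the unknown symbol, trailing all-zero padding is dropped.
#'
#' @param m a one-hot matrix from \code{\link{oneHotEncode}}.
#' @param true_length number of encoded residues; defaults to the matrix
#'   attribute, else the last row containing a 1.
#' @return the decoded amino-acid string.
#' @export
oneHotDecode <- function(m, true_length = attr(m, "true_length")) {
  hit <- m == 1
  if (is.null(true_length)) {
    nz <- which(rowSums(hit) > 0)
    true_length <- if (length(nz)) max(nz) else 0L
  }
  if (true_length == 0L) return("")
  res <- rep(AA_UNKNOWN, true_length)
  ij <- which(hit[seq_len(true_length), , drop = FALSE], arr.ind = TRUE)
  res[ij[, 1]] <- AA_ALPHABET20[ij[, 2]]
  paste(res, collapse = "")
}

#' One-hot encode a batch of proteins
#'
#' Stacks per-sequence one-hot matrices in input order into an
#' \code{n x L_max x 20} array, with a stable id-to-row index.
#'
#' @param x a named character vector of sequences, an
#'   \link[Biostrings]{AAStringSet}, or a \linkS4class{ThermoCorpus}.
#' @param L_max maximum encoded length.
#' @param ids optional subset of protein ids to encode (order preserved).
#' @return numeric array with \code{dim = c(n, L_max, 20)},
#'   \code{dimnames[[1]]} the protein ids, and an \code{index} attribute
#'   mapping id to row.
#' @export
encodeBatch <- function(x, L_max = 1000L, ids = NULL) {
  seqs <- asSequenceVector(x)
  if (!is.null(ids)) {
    missing <- setdiff(ids, names(seqs))
    if (length(missing))
      stop("ids not present in sequence source: ",
           paste(head(missing, 5), collapse = ", "))
    seqs <- seqs[ids]
  }
  n <- length(seqs)
  if (n == 0L) stop("empty batch")
  if (any(!nzchar(seqs)))
    stop("empty sequence for protein(s): ",
         paste(head(names(seqs)[!nzchar(seqs)], 5), collapse = ", "))
  arr <- array(0, dim = c(n, L_max, 20L),
               dimnames = list(names(seqs), NULL, AA_ALPHABET20))
  sp <- strsplit(as.character(seqs), "")
  pos_list <- lapply(sp, function(ch) seq_len(min(length(ch), L_max)))
  code_list <- Map(function(ch, pos) match(ch[pos], AA_ALPHABET20), sp, pos_list)
  i <- rep(seq_len(n), lengths(pos_list))
  pos <- unlist(pos_list, use.names = FALSE)
  code <- unlist(code_list, use.names = FALSE)
  ok <- !is.na(code)
  arr[cbind(i[ok], pos[ok], code[ok])] <- 1
  attr(arr, "index") <- stats::setNames(seq_len(n), names(seqs))
  arr
}

# Coerce the supported sequence sources to a named character vector.
asSequenceVector <- function(x) {
  if (methods::is(x, "ThermoCorpus")) {
    s <- as.character(proteins(x))
    names(s) <- S4Vectors::mcols(proteins(x))$protein_id
    s
  } else if (methods::is(x, "AAStringSet")) {
    s <- as.character(x)
    names(s) <- sub("\\s.*$", "", names(x))
    s
  } else if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    x
  } else stop("unsupported sequence source: ", class(x)[1])
}
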