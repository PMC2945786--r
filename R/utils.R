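# Internal k-mer machinery shared by the scan, the controls and the
# generator.  Bases are encoded A=0, C=1, G=2, T=3; a k-mer maps to
# 1 + sum_j code[j] * 4^(k-1-j), i.e. lexicographic rank (1-based).

.BASES <- c("A", "C", "G", "T")

.base_lookup <- local({
  tbl <- rep(NA_integer_, 256L)
  tbl[utf8ToInt("A")] <- 0L
  tbl[utf8ToInt("C")] <- 1L
  tbl[utf8ToInt("G")] <- 2L
  tbl[utf8ToInt("T")] <- 3L
  tbl
})

# Encode equal-length sequences into an L x n matrix of base codes
# (NA for anything outside ACGT, e.g. N or lowercase masking).
.encode_bases <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[[1L]])
  stopifnot(all(nchar(seqs) == L))
  bytes <- utf8ToInt(paste(seqs, collapse = ""))
  matrix(.base_lookup[bytes], nrow = L, ncol = n)
}

# Rolling k-mer ranks: (L-k+1) x n matrix of 1-based k-mer indices,
# NA wherever a window touches a non-ACGT character.
.kmer_codes <- function(seqs, k) {
  B <- .encode_bases(seqs)
  L <- nrow(B)
  if (L < k) stop("sequences shorter than k")
  W <- matrix(0, L - k + 1L, ncol(B))
  for (j in seq_len(k)) W <- 4 * W + B[j:(L - k + j), , drop = FALSE]
  W + 1
}

#' Enumerate all k-mers in lexicographic order
#'
#' @param k word length.
#' @return character vector of length `4^k` (`AAAA...` first).
#' @export
all_kmers <- function(k) {
  stopifnot(k >= 1)
  out <- ""
  for (i in seq_len(k)) out <- as.vector(t(outer(out, .BASES, paste0)))
  out
}

.kmer_index <- function(kmers) {
  codes <- .encode_bases(kmers)
  if (anyNA(codes)) stop("k-mers must be uppercase ACGT")
  as.integer(colSums(codes * 4^(rev(seq_len(nrow(codes))) - 1))) + 1L
}

#' Reverse complement of nucleotide strings
#'
#' @param x character vector over ACGTN.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s)
    intToUtf8(rev(utf8ToInt(s))), character(1), USE.NAMES = FALSE))
}

# Binary presence of every k-mer per sequence: sparse n x 4^k matrix
# with entries 0/1 (an exon counts once however many occurrences).
.presence_matrix <- function(seqs, k) {
  W <- .kmer_codes(seqs, k)
  n <- ncol(W)
  i <- rep(seq_len(n), each = nrow(W))
  j <- as.vector(W)
  keep <- !is.na(j)
  M <- Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                            dims = c(n, 4^k))
  M@x[] <- 1
  M
}

# Count G+C as an integer; NA if the string has any non-ACGT character.
.gc_count <- function(seqs) {
  up <- toupper(seqs)
  n_acgt <- nchar(gsub("[^ACGT]", "", up))
  out <- nchar(gsub("[^GC]", "", up))
  out[n_acgt < nchar(up)] <- NA_integer_
  out
}

.has_ambiguous <- function(seqs) grepl("[^ACGT]", toupper(seqs))
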