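#' D2 and D2* alignment-free similarity and distance
#'
#' The raw D2 statistic is the inner product of two kmer count vectors,
#' `D2 = sum_w X_w * Y_w`. It is self-normalized to a similarity
#' `s = D2 / sqrt(D2(X,X) * D2(Y,Y))` in `[0, 1]` and converted to a
#' dissimilarity `d = 0.5 * (1 - s)` in `[0, 0.5]`.
#'
#' D2* centers each count by its expectation under a zeroth-order
#' (independent-base) background model estimated from each sequence's own
#' base composition: with `m` the total kmer count and `p_w` the product of
#' the base frequencies of the word, the centered count is
#' `X~_w = X_w - m_X p_w` and
#' `D2* = sum_w X~_w Y~_w / sqrt(m_X p_w m_Y p'_w)`,
#' summed over the full 4^k word space. Words unobserved in both sequences
#' contribute `sqrt(m_X p_w m_Y p'_w)`, which under the zeroth-order model
#' sums in closed form to
#' `sqrt(m_X m_Y) * (sum_b sqrt(p_X(b) p_Y(b)))^k`, so the sparse
#' implementation is exact over all 4^k words while touching only observed
#' kmers. D2* is normalized to a distance the same way as D2 (its
#' similarity can be negative, so the distance lies in `[0, 1]`, with 0.5
#' the expectation for unrelated sequences).
#'
#' @param X,Y `kmer_counts` objects with equal `k` and canonical flags.
#' @return `d2_similarity`/`d2star_similarity` return the normalized
#'   similarity; `d2_distance`/`d2star_distance` the corresponding
#'   dissimilarity.
#' @examples
#' x <- count_kmers("ACGTACGTAA", 2)
#' d2_distance(x, x)  # 0
#' @export
d2_similarity <- function(X, Y) {
  check_compatible(X, Y)
  raw <- d2_raw(X, Y)
  den <- sqrt(d2_raw(X, X) * d2_raw(Y, Y))
  if (den == 0) stop("D2 similarity undefined for an empty kmer vector")
  raw / den
}

#' @rdname d2_similarity
#' @export
d2_distance <- function(X, Y) 0.5 * (1 - d2_similarity(X, Y))

d2_raw <- function(X, Y) {
  shared <- intersect(names(X$counts), names(Y$counts))
  sum(as.numeric(X$counts[shared]) * as.numeric(Y$counts[shared]))
}

#' @rdname d2_similarity
#' @export
d2star_similarity <- function(X, Y) {
  check_compatible(X, Y)
  raw <- d2star_raw(X, Y)
  den <- sqrt(d2star_raw(X, X) * d2star_raw(Y, Y))
  if (den == 0) stop("D2* similarity undefined (degenerate background)")
  raw / den
}

#' @rdname d2_similarity
#' @export
d2star_distance <- function(X, Y) 0.5 * (1 - d2star_similarity(X, Y))

# Exact sparse D2* over the full 4^k word space: observed words explicitly,
# the both-unobserved remainder via the closed-form baseline sum.
d2star_raw <- function(X, Y) {
  k <- X$k
  mX <- as.numeric(X$n_kmers_total)
  mY <- as.numeric(Y$n_kmers_total)
  if (mX == 0 || mY == 0) stop("D2* undefined for an empty kmer vector")
  words <- union(names(X$counts), names(Y$counts))
  pX <- word_probs(words, X$base_freqs)
  pY <- word_probs(words, Y$base_freqs)
  if (any(pX == 0) || any(pY == 0))
    stop("background model assigns probability 0 to a counted kmer")
  x <- as.numeric(X$counts[words]); x[is.na(x)] <- 0
  y <- as.numeric(Y$counts[words]); y[is.na(y)] <- 0
  base <- sqrt(mX * pX * mY * pY)
  term <- (x - mX * pX) * (y - mY * pY) / base
  baseline_total <- sqrt(mX * mY) *
    sum(sqrt(as.numeric(X$base_freqs) * as.numeric(Y$base_freqs)))^k
  baseline_total + sum(term - base)
}

word_probs <- function(words, base_freqs) {
  if (length(words) == 0) return(numeric(0))
  mat <- matrix(unlist(strsplit(words, "", fixed = TRUE)),
                nrow = length(words), byrow = TRUE)
  p <- rep(1, length(words))
  for (b in c("A", "C", "G", "T"))
    p <- p * base_freqs[[b]]^rowSums(mat == b)
  p
}

check_compatible <- function(X, Y) {
  stopifnot(inherits(X, "kmer_counts"), inherits(Y, "kmer_counts"))
  if (X$k != Y$k) stop("kmer length mismatch: ", X$k, " vs ", Y$k)
  if (!identical(X$canonical, Y$canonical))
    stop("canonical flag mismatch between kmer vectors")
  invisible(TRUE)
}

#' Pairwise D2/D2* distance matrix over genomes
#'
#' Counts kmers for each sequence and fills the symmetric matrix of
#' pairwise alignment-free distances. `k = 8` is the scale at which full
#' plastomes give well-resolved D2 distances.
#'
#' @param seqs named character vector of sequences (names become labels),
#'   or a data.frame with columns `genome_id` and `seq`.
#' @param k kmer length (default 8).
#' @param canonical canonical kmer counting? (default FALSE, i.e. stranded;
#'   assembled genomes have a defined strand).
#' @param method `"d2"` or `"d2star"`.
#' @param circular count wrap-around windows? (default TRUE).
#' @return symmetric numeric matrix with zero diagonal and the labels as
#'   dimnames.
#' @export
d2_distance_matrix <- function(seqs, k = 8, canonical = FALSE,
                               method = c("d2", "d2star"), circular = TRUE) {
  method <- match.arg(method)
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$genome_id)
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs))
    stop("seqs must carry unique labels")
  vecs <- lapply(seqs, count_kmers, k = k, canonical = canonical,
                 circular = circular)
  n <- length(vecs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  fun <- if (method == "d2") d2_distance else d2star_distance
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- fun(vecs[[i]], vecs[[j]])
  }
  d
}

#' p-distance matrix from a multiple alignment
#'
#' Pairwise proportion of mismatched sites; columns with a gap (`-`) or `N`
#' in either sequence of a pair are excluded from that pair's comparison.
#'
#' @param alignment a [seq_set()] (or data.frame with `id` and `seq`) of
#'   equal-length aligned sequences.
#' @return symmetric numeric matrix of p-distances.
#' @export
p_distance_matrix <- function(alignment) {
  ids <- alignment$id
  seqs <- toupper(alignment$seq)
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned sequences must have equal length")
  ch <- lapply(seqs, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  ok <- lapply(ch, function(x) x != "-" & x != "N")
  n <- length(ch)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    comp <- ok[[i]] & ok[[j]]
    nc <- sum(comp)
    if (nc == 0)
      stop("no comparable sites between ", ids[i], " and ", ids[j])
    d[i, j] <- d[j, i] <- sum(ch[[i]][comp] != ch[[j]][comp]) / nc
  }
  d
}

#' Write a PHYLIP square distance matrix
#'
#' Full symmetric matrix, classic format: taxon count on the first line,
#' then one row per taxon with the label padded to 10 characters (longer
#' labels are kept intact and followed by a space, the common "relaxed"
#' convention).
#'
#' @param d symmetric labeled distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(d, path) {
  labs <- rownames(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               lab <- if (nchar(labs[i]) >= 10) paste0(labs[i], " ")
                      else formatC(labs[i], width = -10)
               paste0(lab, paste(sprintf("%.6f", d[i, ]), collapse = " "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path file written by [write_phylip()] (or whitespace-separated
#'   square PHYLIP matrix with one row per line).
#' @return symmetric labeled distance matrix.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) < n + 1) stop("malformed PHYLIP matrix")
  toks <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  labs <- vapply(toks, `[[`, character(1), 1)
  d <- t(vapply(toks, function(x) as.numeric(x[-1]), numeric(n)))
  dimnames(d) <- list(labs, labs)
  d
}
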