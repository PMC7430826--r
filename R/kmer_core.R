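#' Kmer count vectors
#'
#' [count_kmers()] extracts the kmer count vector of a sequence: every
#' length-`k` window over the alphabet A/C/G/T is counted; windows containing
#' any other character (N, IUPAC ambiguity codes, ...) are skipped. With
#' `canonical = TRUE` each kmer is replaced by the lexicographic minimum of
#' itself and its reverse complement before counting, which makes the vector
#' strand-agnostic (appropriate for shotgun reads of unknown orientation).
#' With `circular = TRUE` the `k - 1` wrap-around windows of a circular
#' molecule (e.g. a plastome) are appended, i.e. extraction runs over
#' `paste0(seq, substr(seq, 1, k - 1))`.
#'
#' The result carries the total kmer count, the source length, and the
#' base composition of the source (A/C/G/T frequencies over unambiguous
#' bases), which the D2* background model consumes.
#'
#' @param seq a single character string.
#' @param k kmer length, between 1 and 31.
#' @param canonical collapse each kmer with its reverse complement?
#' @param circular include wrap-around windows?
#' @return A `kmer_counts` object: list with elements `k`, `canonical`,
#'   `counts` (named integer vector, names are kmer strings),
#'   `n_kmers_total`, `source_len`, `base_freqs`.
#' @examples
#' count_kmers("ACGTACGT", k = 4)
#' count_kmers("TTTT", k = 3, canonical = TRUE)  # counts AAA
#' @export
count_kmers <- function(seq, k, canonical = FALSE, circular = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a positive integer")
  if (k > 31) stop("k must be <= 31")
  seq <- toupper(seq)
  if (circular && nchar(seq) < k)
    stop("circular extraction requires a sequence of length >= k")
  cc <- cpp_kmer_count(seq, as.integer(k), canonical, circular)
  counts <- cc$count
  names(counts) <- cpp_codes_to_strings(cc$hi, cc$lo, as.integer(k))
  kmer_counts(counts, k = as.integer(k), canonical = canonical,
              source_len = nchar(seq), base_freqs = base_composition(seq))
}

#' @describeIn count_kmers Low-level constructor from a named count vector
#'   (used when a vector is specified directly rather than extracted).
#' @param counts named integer vector of positive kmer counts; names must be
#'   length-`k` strings over A/C/G/T.
#' @param source_len length of the originating sequence (0 if unknown).
#' @param base_freqs named numeric vector of A/C/G/T frequencies summing
#'   to 1; defaults to the uniform composition.
#' @export
kmer_counts <- function(counts, k, canonical = FALSE, source_len = 0L,
                        base_freqs = c(A = .25, C = .25, G = .25, T = .25)) {
  counts <- counts[order(names(counts))]
  if (length(counts)) {
    if (any(nchar(names(counts)) != k))
      stop("all kmer names must have length k")
    if (any(grepl("[^ACGT]", names(counts))))
      stop("kmer names must be over the alphabet {A,C,G,T}")
    if (any(counts <= 0)) stop("counts must be positive")
  }
  bf <- base_freqs[c("A", "C", "G", "T")]
  if (anyNA(bf) || abs(sum(bf) - 1) > 1e-9)
    stop("base_freqs must be named A/C/G/T frequencies summing to 1")
  structure(list(k = as.integer(k), canonical = isTRUE(canonical),
                 counts = as.integer(counts) |> setNames(names(counts)),
                 n_kmers_total = sum(counts), source_len = source_len,
                 base_freqs = bf),
            class = "kmer_counts")
}

base_composition <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- c(A = sum(ch == "A"), C = sum(ch == "C"),
         G = sum(ch == "G"), T = sum(ch == "T"))
  tot <- sum(n)
  if (tot == 0) return(c(A = .25, C = .25, G = .25, T = .25))
  n / tot
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf(
    "kmer_counts: k=%d%s, %d distinct kmers, %d total, source %d bp\n",
    x$k, if (x$canonical) " (canonical)" else "", length(x$counts),
    x$n_kmers_total, x$source_len))
  cat(sprintf("base freqs: A=%.3f C=%.3f G=%.3f T=%.3f\n",
              x$base_freqs["A"], x$base_freqs["C"],
              x$base_freqs["G"], x$base_freqs["T"]))
  invisible(x)
}
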