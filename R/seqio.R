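#' Sequence record sets
#'
#' A `seq_set` is the package's lightweight carrier for reads and genomes: a
#' `data.frame` with columns `id` (record identifier), `seq` (uppercase
#' sequence over A/C/G/T/N) and `qual` (per-base Phred quality string,
#' Sanger/Illumina 1.8+ offset-33 encoding; `NA` for FASTA input).
#'
#' @param id character vector of record identifiers.
#' @param seq character vector of sequences (uppercased on construction).
#' @param qual optional character vector of quality strings, same lengths as
#'   `seq`; `NULL` or `NA` entries mean "no qualities".
#' @return A `seq_set` data.frame.
#' @examples
#' seq_set(c("r1", "r2"), c("ACGT", "GGGTT"))
#' @export
seq_set <- function(id, seq, qual = NULL) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (any(!nzchar(seq))) stop("empty sequence in record ",
                              id[which(!nzchar(seq))[1]])
  if (is.null(qual)) qual <- rep(NA_character_, length(seq))
  qual <- as.character(qual)
  if (length(qual) != length(seq)) stop("qual and seq must have equal length")
  bad <- which(!is.na(qual) & nchar(qual) != nchar(seq))
  if (length(bad))
    stop("quality length differs from sequence length in record ", id[bad[1]])
  structure(data.frame(id = id, seq = seq, qual = qual,
                       stringsAsFactors = FALSE),
            class = c("seq_set", "data.frame"))
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set with %d record(s)%s\n", nrow(x),
              if (all(is.na(x$qual))) "" else " (with qualities)"))
  n <- min(nrow(x), 6L)
  if (n > 0) {
    show <- ifelse(nchar(x$seq[seq_len(n)]) > 40,
                   paste0(substr(x$seq[seq_len(n)], 1, 40), "..."),
                   x$seq[seq_len(n)])
    cat(sprintf("  %s  [%d bp]  %s\n", x$id[seq_len(n)],
                nchar(x$seq[seq_len(n)]), show), sep = "")
  }
  if (nrow(x) > n) cat("  ...\n")
  invisible(x)
}

guess_format <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(p))
  if (ext %in% c("fa", "fasta", "fna", "ffn")) return("fasta")
  if (ext %in% c("fq", "fastq")) return("fastq")
  stop("cannot guess sequence format from extension of ", path)
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads plain or gzip-compressed FASTA/FASTQ files into a [seq_set()].
#' Lowercase bases are uppercased; record order is preserved. FASTQ records
#' whose quality string length differs from the sequence length raise a
#' parse error naming the offending record.
#'
#' @param path file path; `.gz` suffix is decompressed transparently.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (guess from extension).
#' @return A [seq_set()].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- guess_format(path)
  if (format == "fasta") {
    x <- Biostrings::readDNAStringSet(path, format = "fasta")
    return(seq_set(names(x), as.character(x)))
  }
  lines <- readLines(gzfile(path))
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(lines) %/% 4L
  hdr <- lines[seq(1L, by = 4L, length.out = n)]
  sq <- lines[seq(2L, by = 4L, length.out = n)]
  plus <- lines[seq(3L, by = 4L, length.out = n)]
  ql <- lines[seq(4L, by = 4L, length.out = n)]
  if (any(substr(hdr, 1, 1) != "@") || any(substr(plus, 1, 1) != "+"))
    stop("malformed FASTQ record framing in ", path)
  id <- sub("\\s.*$", "", substring(hdr, 2))
  bad <- which(nchar(ql) != nchar(sq))
  if (length(bad))
    stop("FASTQ parse error: quality/sequence length mismatch in record ",
         id[bad[1]])
  seq_set(id, sq, ql)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x a [seq_set()]. Writing FASTQ requires qualities on every record.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (guess from extension).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(x, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  gz <- grepl("\\.gz$", path, ignore.case = TRUE)
  if (format == "fasta") {
    s <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
    Biostrings::writeXStringSet(s, path, compress = gz)
  } else {
    if (anyNA(x$qual))
      stop("FASTQ output requires qualities on every record")
    con <- if (gz) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(rbind(paste0("@", x$id), x$seq, "+", x$qual), con)
  }
  invisible(path)
}

#' Filter reads on length and median Phred quality
#'
#' A read passes iff its length is at least `min_len` and the median of its
#' per-base Phred scores is at least `min_median_q` (both comparisons
#' inclusive). The median of an even-length quality vector is the mean of
#' the two central order statistics. Records without qualities (FASTA) are
#' subject to the length rule only. Order is preserved; the filter is
#' idempotent.
#'
#' @param x a [seq_set()].
#' @param min_median_q minimum median Phred score (default 25).
#' @param min_len minimum read length in bp (default 100).
#' @param offset Phred ASCII offset (default 33, Sanger/Illumina 1.8+).
#' @return The filtered [seq_set()].
#' @export
quality_filter <- function(x, min_median_q = 25, min_len = 100, offset = 33) {
  keep <- nchar(x$seq) >= min_len
  hasq <- !is.na(x$qual)
  if (any(hasq & keep)) {
    # quality strings are often shared (e.g. constant simulated qualities);
    # compute the median once per distinct string
    uq <- unique(x$qual[hasq & keep])
    med <- vapply(uq, function(q) median(utf8ToInt(q)) - offset, numeric(1))
    names(med) <- uq
    keep[hasq] <- keep[hasq] & med[x$qual[hasq]] >= min_median_q
  }
  out <- x[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Reverse complement of DNA strings
#'
#' @param x character vector over A/C/G/T/N (case-insensitive).
#' @return character vector of reverse complements (uppercase).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(toupper(x))))
}
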