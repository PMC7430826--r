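#' Call SNPs and indels from a whole-genome alignment
#'
#' Scans the columns of a supplied multi-FASTA alignment once per query and
#' reports differences from the chosen reference in 1-based inclusive
#' reference coordinates (positions count non-gap reference characters, so
#' a deletion printed as 58,399-58,415 has length 17). Maximal runs of
#' query gaps opposite reference bases become one deletion call; maximal
#' runs of reference gaps become one insertion anchored at the preceding
#' reference position (0 when at the alignment start). Mismatched bases are
#' SNPs. Columns where both sequences are gapped are skipped (they belong
#' to other sequences of the alignment); `N` in either sequence is treated
#' as missing data and produces no call. Alignment construction is
#' upstream (e.g. MAFFT); this module never aligns.
#'
#' @param alignment a [seq_set()] (or data.frame with `id`, `seq`) of
#'   equal-length aligned sequences, gaps as `-`.
#' @param ref_id id of the reference sequence.
#' @return A `variant_calls` data.frame: `kind` (`snp`, `deletion`,
#'   `insertion`), `ref_id`, `query_id`, `ref_start`, `ref_end`, `length`,
#'   `ref_allele`, `query_allele` (alleles gap-free), one block of rows per
#'   non-reference sequence, ordered by query then `ref_start`.
#' @export
call_variants <- function(alignment, ref_id) {
  ids <- alignment$id
  seqs <- toupper(alignment$seq)
  if (length(unique(nchar(seqs))) != 1)
    stop("ragged alignment: sequences differ in length")
  ri <- match(ref_id, ids)
  if (is.na(ri)) stop("reference id not in alignment: ", ref_id)
  r <- strsplit(seqs[ri], "", fixed = TRUE)[[1]]
  out <- lapply(setdiff(seq_along(ids), ri), function(qi) {
    q <- strsplit(seqs[qi], "", fixed = TRUE)[[1]]
    pairwise_calls(r, q, ref_id, ids[qi])
  })
  out <- do.call(rbind, out) %||% empty_calls()
  if (is.null(out)) out <- empty_calls()
  rownames(out) <- NULL
  structure(out, class = c("variant_calls", "data.frame"))
}

empty_calls <- function() {
  data.frame(kind = character(), ref_id = character(),
             query_id = character(), ref_start = integer(),
             ref_end = integer(), length = integer(),
             ref_allele = character(), query_allele = character(),
             stringsAsFactors = FALSE)
}

pairwise_calls <- function(r, q, ref_id, query_id) {
  keep <- !(r == "-" & q == "-")  # project onto this pair
  r <- r[keep]; q <- q[keep]
  refpos <- cumsum(r != "-")
  state <- rep("m", length(r))
  state[r == "N" | q == "N"] <- "n"
  both <- r != "-" & q != "-" & r != "N" & q != "N"
  state[both & r != q] <- "s"
  state[r != "-" & q == "-" & r != "N"] <- "d"
  state[r == "-" & q != "-" & q != "N"] <- "i"
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  rows <- list()
  for (u in which(runs$values %in% c("s", "d", "i"))) {
    cols <- starts[u]:ends[u]
    v <- runs$values[u]
    if (v == "s") {
      for (p in cols)
        rows[[length(rows) + 1L]] <- data.frame(
          kind = "snp", ref_id = ref_id, query_id = query_id,
          ref_start = refpos[p], ref_end = refpos[p], length = 1L,
          ref_allele = r[p], query_allele = q[p],
          stringsAsFactors = FALSE)
    } else if (v == "d") {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "deletion", ref_id = ref_id, query_id = query_id,
        ref_start = refpos[cols[1]], ref_end = refpos[cols[length(cols)]],
        length = length(cols),
        ref_allele = paste(r[cols], collapse = ""), query_allele = "",
        stringsAsFactors = FALSE)
    } else {
      anchor <- if (cols[1] == 1L) 0L else refpos[cols[1] - 1L]
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "insertion", ref_id = ref_id, query_id = query_id,
        ref_start = anchor, ref_end = anchor, length = length(cols),
        ref_allele = "", query_allele = paste(q[cols], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows) %||% empty_calls()
}

#' Write / read a variant table
#'
#' Tab-separated, one row per call, stable column order; round-trips
#' through [read_variant_table()].
#'
#' @param calls a `variant_calls` data.frame from [call_variants()].
#' @param path file path.
#' @return `write_variant_table` returns `path` invisibly;
#'   `read_variant_table` returns the `variant_calls` data.frame.
#' @export
write_variant_table <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_variant_table
#' @export
read_variant_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                  colClasses = c(kind = "character", ref_id = "character",
                                 query_id = "character",
                                 ref_start = "integer", ref_end = "integer",
                                 length = "integer",
                                 ref_allele = "character",
                                 query_allele = "character"))
  structure(x, class = c("variant_calls", "data.frame"))
}
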