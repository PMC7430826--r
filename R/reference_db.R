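#' Build a kmer reference database over labeled genomes
#'
#' Each genome contributes its set of distinct kmers (presence, not counts);
#' the database also records the taxon each genome belongs to, so multiple
#' accessions of one species can be pooled at detection time. Genomes are
#' treated as circular by default (plastomes are circular molecules) and
#' kmers are canonicalized by default, since shotgun reads have unknown
#' strand.
#'
#' @param genomes a data.frame with character columns `taxon_id`,
#'   `genome_id` and `seq` (one genome per row); `genome_id` must be unique.
#' @param k kmer length (default 31: at k = 31 the 4^k kmer space makes
#'   chance matches of random sequence vanishingly rare).
#' @param canonical collapse strands? (default `TRUE`).
#' @param circular include wrap-around windows? (default `TRUE`).
#' @return A `kmer_db` object.
#' @examples
#' g <- data.frame(taxon_id = "spA", genome_id = "spA_1",
#'                 seq = "ACGTACGTAGGCTTAG")
#' build_kmer_db(g, k = 4, canonical = FALSE, circular = FALSE)
#' @export
build_kmer_db <- function(genomes, k = 31, canonical = TRUE, circular = TRUE) {
  stopifnot(is.data.frame(genomes),
            all(c("taxon_id", "genome_id", "seq") %in% names(genomes)))
  if (nrow(genomes) == 0) stop("no genomes supplied")
  if (anyDuplicated(genomes$genome_id))
    stop("duplicate genome_id: ",
         genomes$genome_id[duplicated(genomes$genome_id)][1])
  if (any(!nzchar(genomes$seq))) stop("empty genome sequence")
  sets <- lapply(genomes$seq, function(s) {
    cc <- cpp_kmer_count(toupper(s), as.integer(k), canonical, circular)
    list(hi = cc$hi, lo = cc$lo)
  })
  names(sets) <- genomes$genome_id
  structure(list(k = as.integer(k), canonical = canonical,
                 circular = circular,
                 genomes = data.frame(genome_id = genomes$genome_id,
                                      taxon_id = genomes$taxon_id,
                                      stringsAsFactors = FALSE),
                 sets = sets),
            class = "kmer_db")
}

#' @export
print.kmer_db <- function(x, ...) {
  cat(sprintf("kmer_db: k=%d%s%s, %d genome(s) in %d taxon(a)\n", x$k,
              if (x$canonical) ", canonical" else "",
              if (x$circular) ", circular" else "",
              nrow(x$genomes), length(unique(x$genomes$taxon_id))))
  sz <- vapply(x$sets, function(s) length(s$hi), integer(1))
  for (i in seq_len(min(nrow(x$genomes), 10)))
    cat(sprintf("  %s (%s): %d distinct kmers\n", x$genomes$genome_id[i],
                x$genomes$taxon_id[i], sz[i]))
  if (nrow(x$genomes) > 10) cat("  ...\n")
  invisible(x)
}

#' Number of distinct kmers per genome
#' @param db a `kmer_db`.
#' @return named integer vector, one entry per genome.
#' @export
db_set_sizes <- function(db) {
  vapply(db$sets, function(s) length(s$hi), integer(1))
}

#' Inverted kmer index as a data.frame
#'
#' Materializes the kmer -> genome index (one row per kmer/genome pair,
#' kmer decoded to its string form). Intended for inspection and testing
#' on small databases; at k = 31 over full plastomes this is large.
#'
#' @param db a `kmer_db`.
#' @return data.frame with columns `kmer`, `genome_id`.
#' @export
db_index <- function(db) {
  g2t <- match(db$genomes$taxon_id, unique(db$genomes$taxon_id)) - 1L
  m <- cpp_merge_index(unname(db$sets), g2t, length(unique(db$genomes$taxon_id)))
  km <- cpp_codes_to_strings(m$hi, m$lo, db$k)
  n_per <- diff(m$offsets)
  data.frame(kmer = rep(km, n_per),
             genome_id = db$genomes$genome_id[m$gid + 1L],
             stringsAsFactors = FALSE)
}

# Merged CSR index + taxon bookkeeping used by the detection layer.
db_merged <- function(db) {
  taxa <- unique(db$genomes$taxon_id)
  g2t <- match(db$genomes$taxon_id, taxa) - 1L
  m <- cpp_merge_index(unname(db$sets), g2t, length(taxa))
  list(merged = m, taxa = taxa, g2t = g2t)
}

#' Derive a take-one-out database
#'
#' Returns a copy of the database with one genome removed and the index
#' rebuilt, leaving the original untouched. Querying a genome's own reads
#' against a database that omits that genome avoids the circularity of
#' testing assembly reads against their own assembly.
#'
#' @param db a `kmer_db`.
#' @param genome_id the genome to hold out.
#' @return A `kmer_db` without `genome_id`.
#' @export
take_one_out <- function(db, genome_id) {
  i <- match(genome_id, db$genomes$genome_id)
  if (is.na(i)) stop("unknown genome_id: ", genome_id)
  if (nrow(db$genomes) == 1) stop("cannot remove the only genome")
  db$genomes <- db$genomes[-i, , drop = FALSE]
  rownames(db$genomes) <- NULL
  db$sets <- db$sets[db$genomes$genome_id]
  db
}

DB_FORMAT <- "plastidkmer-db"
DB_VERSION <- 1L

#' Save / load a kmer database
#'
#' The on-disk format is plain text: a one-line JSON header (format name,
#' version, `k`, flags, genome/taxon table with per-genome kmer counts)
#' followed by one line per genome holding its sorted 2-bit-packed kmers as
#' fixed-width hexadecimal words. The round trip is bit-exact.
#'
#' @param db a `kmer_db`.
#' @param path file path (a `.gz` suffix compresses transparently).
#' @return `save_kmer_db` returns `path` invisibly; `load_kmer_db` returns
#'   the `kmer_db`.
#' @export
save_kmer_db <- function(db, path) {
  hdr <- jsonlite::toJSON(list(
    format = DB_FORMAT, version = DB_VERSION, k = db$k,
    canonical = db$canonical, circular = db$circular,
    genome_id = db$genomes$genome_id, taxon_id = db$genomes$taxon_id,
    n_kmers = unname(db_set_sizes(db))), auto_unbox = TRUE)
  body <- vapply(db$sets, function(s)
    paste(cpp_codes_to_hex(s$hi, s$lo), collapse = " "), character(1))
  gz <- grepl("\\.gz$", path, ignore.case = TRUE)
  con <- if (gz) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(hdr), unname(body)), con)
  invisible(path)
}

#' @rdname save_kmer_db
#' @param expect_k,expect_canonical optional expectations checked against
#'   the stored header; a mismatch is a format error.
#' @export
load_kmer_db <- function(path, expect_k = NULL, expect_canonical = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(gzfile(path))
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e)
    stop("corrupt database header in ", path, ": ", conditionMessage(e)))
  if (!identical(hdr$format, DB_FORMAT))
    stop("not a ", DB_FORMAT, " file: ", path)
  if (!identical(as.integer(hdr$version), DB_VERSION))
    stop("unsupported database version: ", hdr$version)
  if (!is.null(expect_k) && as.integer(hdr$k) != as.integer(expect_k))
    stop("database k (", hdr$k, ") does not match expected k (", expect_k, ")")
  if (!is.null(expect_canonical) && !identical(isTRUE(hdr$canonical),
                                               isTRUE(expect_canonical)))
    stop("database canonical flag does not match expectation")
  ng <- length(hdr$genome_id)
  if (length(lines) != ng + 1L)
    stop("corrupt database body: expected ", ng, " genome lines")
  sets <- vector("list", ng)
  for (i in seq_len(ng)) {
    hx <- strsplit(lines[i + 1L], " ", fixed = TRUE)[[1]]
    hx <- hx[nzchar(hx)]
    if (length(hx) != hdr$n_kmers[i])
      stop("corrupt database body: kmer count mismatch for genome ",
           hdr$genome_id[i])
    sets[[i]] <- cpp_hex_to_codes(hx)[c("hi", "lo")]
  }
  names(sets) <- hdr$genome_id
  structure(list(k = as.integer(hdr$k), canonical = isTRUE(hdr$canonical),
                 circular = isTRUE(hdr$circular),
                 genomes = data.frame(genome_id = hdr$genome_id,
                                      taxon_id = hdr$taxon_id,
                                      stringsAsFactors = FALSE),
                 sets = sets),
            class = "kmer_db")
}
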