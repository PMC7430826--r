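#' Assign reads to reference genomes by kmer matching
#'
#' Every kmer of every read is looked up in the database; a read's best
#' genome is the one matching the most of its kmers, provided the matched
#' fraction reaches `min_fraction`. Ties are broken by lexicographic
#' `genome_id`, so assignment is deterministic. Reads shorter than `k`
#' contribute zero kmers and stay unassigned.
#'
#' @param reads a [seq_set()] of query reads.
#' @param db a `kmer_db` from [build_kmer_db()].
#' @param min_fraction minimum fraction of a read's kmers that must match
#'   the best genome for the read to be assigned (default 0.5).
#' @return data.frame with one row per read: `read_id`, `n_kmers`,
#'   `best_genome` (`NA` if unassigned) and `best_fraction`; the full
#'   per-read x per-genome matched-kmer count matrix is attached as
#'   attribute `"matches"`.
#' @export
assign_reads <- function(reads, db, min_fraction = 0.5) {
  mr <- match_reads(reads, db)
  assignment_from_matches(mr, reads$id, db, min_fraction)
}

assignment_from_matches <- function(mr, read_ids, db, min_fraction) {
  gi <- db$genomes$genome_id
  ord <- order(gi)  # lexicographic tie-break
  m <- mr$matches[, ord, drop = FALSE]
  best_j <- max.col(m, ties.method = "first")
  best_cnt <- m[cbind(seq_len(nrow(m)), best_j)]
  best_fraction <- ifelse(mr$n_kmers > 0, best_cnt / mr$n_kmers, 0)
  assigned <- best_cnt > 0 & best_fraction >= min_fraction
  out <- data.frame(read_id = read_ids, n_kmers = mr$n_kmers,
                    best_genome = ifelse(assigned, gi[ord][best_j],
                                         NA_character_),
                    best_fraction = best_fraction,
                    stringsAsFactors = FALSE)
  attr(out, "matches") <- mr$matches
  out
}

# Shared kmer-matching core: runs the compiled matcher over the merged
# database index and returns raw per-read and per-taxon tallies.
match_reads <- function(reads, db) {
  if (is.null(db) || nrow(db$genomes) == 0) stop("empty reference database")
  dm <- db_merged(db)
  res <- cpp_match_reads(reads$seq, db$k, db$canonical,
                         dm$merged$hi, dm$merged$lo,
                         dm$merged$offsets, dm$merged$gid,
                         dm$g2t, nrow(db$genomes), length(dm$taxa))
  colnames(res$matches) <- db$genomes$genome_id
  list(n_kmers = res$n_kmers, matches = res$matches,
       taxon_total = setNames(res$taxon_total, dm$taxa),
       taxon_unique = setNames(res$taxon_unique, dm$taxa),
       taxon_set_size = setNames(dm$merged$taxon_set_size, dm$taxa),
       total_kmers = res$total_kmers, taxa = dm$taxa)
}

#' Detect taxa in a read set
#'
#' Classifies a (quality-filtered) read set against the database and issues
#' per-taxon detection calls. Counts from multiple genomes (accessions) of
#' one taxon are pooled: a kmer occurrence matching any accession of a
#' taxon counts once for that taxon. A taxon is *detected* when it has at
#' least `min_reads` assigned reads and at least `min_unique_kmers` distinct
#' matched kmers; it is additionally *supported* when the binomial tail
#' probability of its total matched-kmer count under the chance-match null
#' is below `alpha`. The null match rate per queried kmer is
#' `|taxon kmer set| / 4^k`. A taxon that passes the count thresholds but
#' not the support test is "detected, poorly supported".
#'
#' @param reads a [seq_set()] of query reads (quality filtering is expected
#'   upstream; see [quality_filter()]).
#' @param db a `kmer_db`.
#' @param min_reads minimum assigned reads (default 10).
#' @param min_unique_kmers minimum distinct matched kmers (default 100).
#' @param alpha support significance level (default 1e-6).
#' @param min_fraction per-read assignment threshold, see [assign_reads()].
#' @return A `detection_report`: data.frame with one row per taxon
#'   (`taxon_id`, `assigned_reads`, `total_matched_kmers`,
#'   `unique_matched_kmers`, `support_p`, `detected`, `supported`), sorted
#'   by decreasing `total_matched_kmers`, with attributes `params`,
#'   `total_reads` and `total_kmers`.
#' @export
detect <- function(reads, db, min_reads = 10, min_unique_kmers = 100,
                   alpha = 1e-6, min_fraction = 0.5) {
  params <- list(k = db$k, canonical = db$canonical, min_reads = min_reads,
                 min_unique_kmers = min_unique_kmers, alpha = alpha,
                 min_fraction = min_fraction)
  if (nrow(reads) == 0) {
    taxa <- unique(db$genomes$taxon_id)
    out <- data.frame(taxon_id = taxa, assigned_reads = 0L,
                      total_matched_kmers = 0, unique_matched_kmers = 0,
                      support_p = 1, detected = FALSE, supported = FALSE,
                      stringsAsFactors = FALSE)
    return(structure(out, params = params, total_reads = 0L,
                     total_kmers = 0, class = c("detection_report",
                                                "data.frame")))
  }
  mr <- match_reads(reads, db)
  asg <- assignment_from_matches(mr, reads$id, db, min_fraction)
  taxa <- mr$taxa
  tax_of_genome <- setNames(db$genomes$taxon_id, db$genomes$genome_id)
  assigned_tax <- tax_of_genome[asg$best_genome[!is.na(asg$best_genome)]]
  assigned <- setNames(integer(length(taxa)), taxa)
  tb <- table(assigned_tax)
  assigned[names(tb)] <- as.integer(tb)
  # chance-match null: each queried kmer hits the taxon's kmer set
  # independently with probability |set| / 4^k
  p0 <- mr$taxon_set_size / 4^db$k
  n <- mr$total_kmers
  support_p <- ifelse(mr$taxon_total > 0,
                      pbinom(mr$taxon_total - 1, size = n, prob = p0,
                             lower.tail = FALSE), 1)
  detected <- assigned >= min_reads & mr$taxon_unique >= min_unique_kmers
  supported <- detected & support_p < alpha
  out <- data.frame(taxon_id = taxa, assigned_reads = assigned,
                    total_matched_kmers = mr$taxon_total,
                    unique_matched_kmers = mr$taxon_unique,
                    support_p = support_p, detected = detected,
                    supported = supported, stringsAsFactors = FALSE)
  out <- out[order(-out$total_matched_kmers, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, params = params, total_reads = nrow(reads),
            total_kmers = n, class = c("detection_report", "data.frame"))
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("detection_report: %d read(s), %.0f queried kmer(s)\n",
              attr(x, "total_reads"), attr(x, "total_kmers")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a detection report to TSV or JSON
#'
#' @param report a `detection_report`.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_detection_report <- function(report, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    jsonlite::write_json(list(params = attr(report, "params"),
                              total_reads = attr(report, "total_reads"),
                              per_taxon = as.data.frame(report)),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Spike-in dilution series and limit of detection
#'
#' For each spike fraction and replicate, builds a mixture of the background
#' components plus target reads at that fraction (see [build_mixture()]),
#' runs [detect()], and records whether the target taxon was detected and
#' supported. The limit of detection (LOD) is the smallest fraction at
#' which the target is detected with support in every replicate.
#'
#' @param db a `kmer_db` containing the target taxon.
#' @param background list of background components, each a
#'   `list(label =, reads =, proportion =)` with `reads` a [seq_set()] pool
#'   to sample from; proportions are percentages of the non-spike part.
#' @param target_reads a [seq_set()] pool of target reads to spike in.
#' @param target_taxon the taxon_id of the target in `db`.
#' @param fractions spike fractions in percent (default: the 9-point series
#'   5, 2.5, 1.25, 0.6, 0.3, 0.15, 0.07, 0.03, 0.01).
#' @param total_reads mixture size (default 220000).
#' @param seed base RNG seed; replicate r uses `seed + r - 1`.
#' @param replicates number of replicates per fraction (default 3).
#' @param replace sample pools with replacement? (default FALSE).
#' @param ... further arguments passed to [detect()].
#' @return data.frame with one row per fraction x replicate (`fraction`,
#'   `replicate`, `detected`, `supported`, `assigned_reads`,
#'   `total_matched_kmers`, `unique_matched_kmers`, `support_p`), with the
#'   LOD attached as attribute `"lod"` (`NA` if no fraction qualifies).
#' @export
dilution_series <- function(db, background, target_reads, target_taxon,
                            fractions = c(5, 2.5, 1.25, 0.6, 0.3, 0.15,
                                          0.07, 0.03, 0.01),
                            total_reads = 220000, seed = 1, replicates = 3,
                            replace = FALSE, ...) {
  if (total_reads <= 0) stop("total_reads must be positive")
  if (any(fractions < 0 | fractions >= 100))
    stop("fractions must lie in [0, 100)")
  rows <- vector("list", length(fractions) * replicates)
  i <- 0L
  for (f in fractions) for (r in seq_len(replicates)) {
    spec <- mixture_spec(background,
                         spike = list(label = target_taxon,
                                      reads = target_reads, fraction = f),
                         total_reads = total_reads, seed = seed + r - 1L,
                         replace = replace)
    mix <- build_mixture(spec)
    rep_ <- detect(mix, db, ...)
    row <- rep_[rep_$taxon_id == target_taxon, , drop = FALSE]
    if (nrow(row) == 0)
      stop("target taxon ", target_taxon, " is not in the database")
    i <- i + 1L
    rows[[i]] <- data.frame(fraction = f, replicate = r,
                            detected = row$detected,
                            supported = row$supported,
                            assigned_reads = row$assigned_reads,
                            total_matched_kmers = row$total_matched_kmers,
                            unique_matched_kmers = row$unique_matched_kmers,
                            support_p = row$support_p)
  }
  out <- do.call(rbind, rows)
  attr(out, "lod") <- lod_from_series(out)
  out
}

#' @rdname dilution_series
#' @param series a dilution-series table as returned by [dilution_series()].
#' @export
lod_from_series <- function(series) {
  ok <- tapply(series$supported, series$fraction, all)
  good <- as.numeric(names(ok))[ok]
  if (length(good) == 0) NA_real_ else min(good)
}

#' Take-one-out identification accuracy
#'
#' Pairs each take-one-out database with the read set of the genome it
#' omits, runs [detect()] on each pair, and scores a trial as correct when
#' the true taxon is the top-ranked detected taxon (reports are ranked by
#' total matched kmers). Returns the percentage of correct trials.
#'
#' @param dbs list of `kmer_db` objects, each omitting one accession.
#' @param read_sets list of [seq_set()] read sets, `read_sets[[i]]` holding
#'   reads from the genome omitted in `dbs[[i]]`.
#' @param true_taxon the taxon_id the reads truly belong to.
#' @param ... passed to [detect()].
#' @return percent of trials (0-100) in which `true_taxon` ranked first
#'   among detected taxa, with the per-trial logical vector attached as
#'   attribute `"trials"`.
#' @export
take_one_out_accuracy <- function(dbs, read_sets, true_taxon, ...) {
  if (length(dbs) != length(read_sets))
    stop("dbs and read_sets must have the same length")
  hit <- vapply(seq_along(dbs), function(i) {
    rep_ <- detect(read_sets[[i]], dbs[[i]], ...)
    det <- rep_[rep_$detected, , drop = FALSE]
    nrow(det) > 0 && det$taxon_id[1] == true_taxon
  }, logical(1))
  structure(100 * mean(hit), trials = hit)
}
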