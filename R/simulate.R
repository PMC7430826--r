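#' Simulate an i.i.d. random genome
#'
#' Draws a sequence of independent bases with expected GC content `gc`
#' (AT and GC each split evenly between their two bases). The default GC of
#' 0.37 matches typical plastome composition. Deterministic given `seed`.
#'
#' @param length genome length in bp.
#' @param seed RNG seed.
#' @param gc expected GC fraction, in (0, 1).
#' @return a single character string.
#' @export
simulate_genome <- function(length, seed, gc = 0.37) {
  stopifnot(length > 0, gc > 0, gc < 1)
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
}

#' Mutate a genome, recording ground-truth variants
#'
#' Either plants an explicit list of variants (SNPs, deletions, insertions
#' in 1-based inclusive reference coordinates) or draws random substitutions
#' and indels at the given per-base rates. Returns the mutated sequence, the
#' ground-truth variant table, and the construction-true pairwise alignment
#' of reference and mutant, against which [call_variants()] must recover the
#' planted variants exactly.
#'
#' Explicit variants use the columns `kind` (`"snp"`, `"deletion"`,
#' `"insertion"`), `ref_start`, `ref_end` and, where relevant,
#' `query_allele` (SNP replacement base or inserted bases; insertions are
#' anchored after `ref_start`, with `ref_start == ref_end`).
#'
#' @param genome reference sequence (single string).
#' @param sub_rate per-base substitution probability in `[0, 1)`.
#' @param indel_rate per-base indel initiation probability in `[0, 1)`.
#' @param max_indel maximum random indel length (default 10).
#' @param seed RNG seed (required when any rate is positive).
#' @param variants optional explicit variant data.frame (see Details);
#'   when supplied, the rates are ignored.
#' @return list with elements `seq` (mutated sequence), `variants`
#'   (data.frame of `VariantCall` rows: `kind`, `ref_start`, `ref_end`,
#'   `length`, `ref_allele`, `query_allele`) and `alignment` (character
#'   vector of the two gapped rows, names `ref` and `query`).
#' @export
mutate_genome <- function(genome, sub_rate = 0, indel_rate = 0,
                          max_indel = 10, seed = NULL, variants = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  L <- nchar(genome)
  if (is.null(variants)) {
    if (sub_rate == 0 && indel_rate == 0) {
      variants <- empty_variants()
    } else {
      if (is.null(seed)) stop("seed is required for random mutation")
      variants <- with_seed(seed, random_variant_plan(
        genome, sub_rate, indel_rate, max_indel))
    }
  } else {
    variants <- normalize_variant_plan(genome, variants)
  }
  apply_variant_plan(genome, variants)
}

empty_variants <- function() {
  data.frame(kind = character(), ref_start = integer(), ref_end = integer(),
             length = integer(), ref_allele = character(),
             query_allele = character(), stringsAsFactors = FALSE)
}

other_bases <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")

random_variant_plan <- function(genome, sub_rate, indel_rate, max_indel) {
  L <- nchar(genome)
  ch <- strsplit(genome, "", fixed = TRUE)[[1]]
  indels <- NULL
  occupied <- rep(FALSE, L)
  if (indel_rate > 0) {
    pos <- which(runif(L) < indel_rate)
    if (length(pos)) {
      len <- sample.int(max_indel, length(pos), replace = TRUE)
      del <- runif(length(pos)) < 0.5
      # drop indels overlapping an earlier one (greedy left-to-right)
      keep <- !logical(length(pos))
      last_end <- 0L
      for (i in seq_along(pos)) {
        end_i <- if (del[i]) pos[i] + len[i] - 1L else pos[i]
        if (pos[i] <= last_end || end_i > L) keep[i] <- FALSE
        else last_end <- end_i
      }
      pos <- pos[keep]; len <- len[keep]; del <- del[keep]
      qa <- character(length(pos))
      qa[!del] <- vapply(len[!del], function(l)
        paste(sample(c("A", "C", "G", "T"), l, TRUE), collapse = ""),
        character(1))
      indels <- data.frame(
        kind = ifelse(del, "deletion", "insertion"), ref_start = pos,
        ref_end = ifelse(del, pos + len - 1L, pos), query_allele = qa,
        stringsAsFactors = FALSE)
      for (i in which(del)) occupied[pos[i]:(pos[i] + len[i] - 1L)] <- TRUE
    }
  }
  snps <- NULL
  if (sub_rate > 0) {
    pos <- which(runif(L) < sub_rate & !occupied)
    if (length(pos)) {
      alt <- vapply(strsplit(other_bases[ch[pos]], "", fixed = TRUE),
                    function(b) b[sample.int(3L, 1L)], character(1))
      snps <- data.frame(kind = "snp", ref_start = pos, ref_end = pos,
                         query_allele = unname(alt),
                         stringsAsFactors = FALSE)
    }
  }
  plan <- rbind(indels, snps)
  if (is.null(plan) || nrow(plan) == 0) return(empty_variants())
  normalize_variant_plan(genome, plan[order(plan$ref_start), , drop = FALSE])
}

normalize_variant_plan <- function(genome, variants) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "ref_start") %in% names(v)))
  if (is.null(v$ref_end)) v$ref_end <- v$ref_start
  if (is.null(v$query_allele)) v$query_allele <- ""
  L <- nchar(genome)
  v <- v[order(v$ref_start), , drop = FALSE]
  v$length <- ifelse(v$kind == "insertion", nchar(v$query_allele),
                     v$ref_end - v$ref_start + 1L)
  if (any(v$kind == "snp" & v$length != 1L))
    stop("a snp must have ref_start == ref_end")
  if (any(v$ref_start < 1L | v$ref_end > L | v$ref_end < v$ref_start))
    stop("variant coordinates out of range")
  if (any(v$kind == "insertion" & !nzchar(v$query_allele)))
    stop("insertion requires a non-empty query_allele")
  if (any(v$kind == "snp" & nchar(v$query_allele) != 1L))
    stop("snp requires a single-base query_allele")
  # overlap check over reference footprints
  if (nrow(v) > 1) {
    fs <- v$ref_start
    fe <- ifelse(v$kind == "insertion", v$ref_start, v$ref_end)
    if (any(fs[-1] <= fe[-nrow(v)]))
      stop("overlapping planted variants")
  }
  v$ref_allele <- ifelse(v$kind == "insertion", "",
                         substring(genome, v$ref_start, v$ref_end))
  sub_bad <- v$kind == "snp" & nzchar(v$query_allele) &
    v$query_allele == v$ref_allele
  if (any(sub_bad)) stop("snp query_allele equals the reference base")
  v[c("kind", "ref_start", "ref_end", "length", "ref_allele",
      "query_allele")]
}

apply_variant_plan <- function(genome, v) {
  L <- nchar(genome)
  n <- nrow(v)
  # flanks between consecutive variants, then interleave flank/variant parts
  ins <- v$kind == "insertion"
  pre_end <- ifelse(ins, v$ref_start, v$ref_start - 1L)
  consumed_to <- ifelse(ins, v$ref_start, v$ref_end)  # last ref pos used
  pre_start <- if (n > 0) c(1L, consumed_to[-n] + 1L) else integer(0)
  flank <- if (n > 0) substring(genome, pre_start, pre_end) else genome
  ref_var <- ifelse(v$kind == "insertion", strrep("-", v$length),
                    v$ref_allele)
  qry_var <- ifelse(v$kind == "deletion", strrep("-", v$length),
                    v$query_allele)
  tail_start <- if (n > 0) consumed_to[n] + 1L else 1L
  tail_seq <- if (n > 0) substr(genome, tail_start, L) else ""
  weave <- function(var_parts) {
    out <- character(2L * n + 1L)
    out[seq(1L, by = 2L, length.out = n)] <- flank
    out[seq(2L, by = 2L, length.out = n)] <- var_parts
    out[2L * n + 1L] <- tail_seq
    paste(out, collapse = "")
  }
  ref_aln <- if (n > 0) weave(ref_var) else genome
  qry_aln <- if (n > 0) weave(qry_var) else genome
  list(seq = gsub("-", "", qry_aln, fixed = TRUE), variants = v,
       alignment = c(ref = ref_aln, query = qry_aln))
}

#' Simulate fixed-length shotgun reads from a circular genome
#'
#' Read start positions are uniform over the (circular) genome, strands are
#' random, and substitution errors are i.i.d. at `error_rate`. Each read
#' carries a constant quality string (`quality_char`, default 'F' = Q37,
#' comfortably above the default Q25 filter). Deterministic given `seed`.
#'
#' @param genome template sequence (single string).
#' @param n_reads number of reads.
#' @param read_len read length in bp (default 125).
#' @param error_rate per-base substitution error probability (default 0.002).
#' @param seed RNG seed.
#' @param id_prefix read id prefix (ids are `prefix_000001`, ...).
#' @param quality_char constant quality symbol (offset-33 encoding).
#' @return a [seq_set()] of `n_reads` reads with qualities.
#' @export
simulate_reads <- function(genome, n_reads, read_len = 125,
                           error_rate = 0.002, seed = 1,
                           id_prefix = "read", quality_char = "F") {
  L <- nchar(genome)
  stopifnot(L >= read_len, n_reads >= 0, error_rate >= 0, error_rate < 1)
  if (n_reads == 0) return(seq_set(character(0), character(0)))
  with_seed(seed, {
    doubled <- paste0(genome, substr(genome, 1, read_len - 1))
    start <- sample.int(L, n_reads, replace = TRUE)
    sq <- substring(doubled, start, start + read_len - 1L)
    rev <- runif(n_reads) < 0.5
    if (any(rev)) sq[rev] <- revcomp(sq[rev])
    if (error_rate > 0) {
      n_err <- rbinom(n_reads, read_len, error_rate)
      hit <- which(n_err > 0)
      for (i in hit) {
        ch <- strsplit(sq[i], "", fixed = TRUE)[[1]]
        pos <- sample.int(read_len, n_err[i])
        ch[pos] <- vapply(ch[pos], function(b) {
          alts <- other_bases[[b]] %||% "ACGT"
          substr(alts, s <- sample.int(nchar(alts), 1), s)
        }, character(1))
        sq[i] <- paste(ch, collapse = "")
      }
    }
    seq_set(sprintf("%s_%06d", id_prefix, seq_len(n_reads)), sq,
            rep(strrep(quality_char, read_len), n_reads))
  })
}

#' Mixture designs
#'
#' A `mixture_spec` describes a spiked read mixture: background components
#' with stated proportions (percent; renormalized to fill `100 - fraction`
#' after the spike takes its share) and a spike component at a given
#' fraction. [build_mixture()] realizes the design by sampling each pool
#' without replacement (unless `replace = TRUE`), relabels read ids with
#' their component of origin (`label|original_id`), and shuffles the result
#' deterministically by `seed`.
#'
#' Component counts: the spike gets `round(total_reads * fraction / 100)`
#' reads; the background remainder is split in the stated ratios with
#' largest-remainder rounding, so every component is within one read of its
#' exact share.
#'
#' @param components list of `list(label =, reads =, proportion =)`;
#'   proportions must sum to 100 (a small shortfall such as the classic
#'   30/30/30/3.3/3.3/3.3 design summing to 99.9 is accepted and
#'   renormalized).
#' @param spike `list(label =, reads =, fraction =)`, fraction in percent
#'   (`>= 0`).
#' @param total_reads total mixture size.
#' @param seed RNG seed.
#' @param replace allow sampling pools with replacement?
#' @return `mixture_spec` returns the validated design object;
#'   `build_mixture` returns a shuffled [seq_set()] of `total_reads` reads.
#' @export
mixture_spec <- function(components, spike, total_reads, seed = 1,
                         replace = FALSE) {
  stopifnot(length(components) >= 1, total_reads > 0)
  lab <- vapply(components, `[[`, character(1), "label")
  prop <- vapply(components, function(x) as.numeric(x$proportion), numeric(1))
  if (any(prop < 0)) stop("component proportions must be >= 0")
  if (abs(sum(prop) - 100) > 0.5)
    stop("background proportions must sum to 100 (got ", sum(prop), ")")
  if (anyDuplicated(c(lab, spike$label))) stop("duplicate component labels")
  if (spike$fraction < 0 || spike$fraction >= 100)
    stop("spike fraction must lie in [0, 100)")
  structure(list(components = components, spike = spike,
                 total_reads = as.integer(total_reads),
                 seed = as.integer(seed), replace = isTRUE(replace)),
            class = "mixture_spec")
}

#' @rdname mixture_spec
#' @param spec a `mixture_spec`.
#' @export
build_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  n_spike <- round(spec$total_reads * spec$spike$fraction / 100)
  n_bg <- spec$total_reads - n_spike
  prop <- vapply(spec$components, function(x) as.numeric(x$proportion),
                 numeric(1))
  share <- n_bg * prop / sum(prop)
  n_i <- floor(share)
  rem <- n_bg - sum(n_i)
  if (rem > 0) {
    extra <- order(share - n_i, decreasing = TRUE)[seq_len(rem)]
    n_i[extra] <- n_i[extra] + 1L
  }
  with_seed(spec$seed, {
    parts <- vector("list", length(spec$components) + 1L)
    for (j in seq_along(spec$components)) {
      comp <- spec$components[[j]]
      parts[[j]] <- sample_pool(comp$reads, n_i[j], comp$label, spec$replace)
    }
    parts[[length(parts)]] <- sample_pool(spec$spike$reads, n_spike,
                                          spec$spike$label, spec$replace)
    out <- do.call(rbind, parts)
    out <- out[sample.int(nrow(out)), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("seq_set", "data.frame")
    out
  })
}

sample_pool <- function(pool, n, label, replace) {
  if (n == 0) {
    out <- pool[0, , drop = FALSE]
  } else {
    if (!replace && n > nrow(pool))
      stop("component '", label, "' exhausted: need ", n, " reads, pool has ",
           nrow(pool), " (set replace = TRUE to sample with replacement)")
    out <- pool[sample.int(nrow(pool), n, replace = replace), , drop = FALSE]
  }
  if (nrow(out) > 0) out$id <- paste0(label, "|", out$id)
  out
}

#' Simulate a panel of related plastome-like genomes
#'
#' Generates an ancestral genome and derives from it a nested set of
#' relatives: `n_accessions` conspecific accessions of a target species
#' (mutated at `acc_divergence` each, so pairwise divergence is about twice
#' that), congeneric species at `genus_divergence`, confamilial species at
#' `family_divergence`, and optionally a distant outgroup. Substitution-only
#' mutation keeps all genomes alignable by construction.
#'
#' @param seed RNG seed.
#' @param length genome length (default 150000, plastome scale).
#' @param n_accessions conspecific accessions of the target (default 3).
#' @param n_genus,n_family number of congeneric / confamilial relatives
#'   (defaults 2 and 3).
#' @param acc_divergence per-accession divergence from the species ancestor
#'   (default 5e-4, i.e. pairwise about 0.1%).
#' @param genus_divergence,family_divergence,outgroup_divergence divergence
#'   of relatives from the ancestor (defaults 0.02, 0.10, 0.25).
#' @param outgroup include an outgroup genome? (default TRUE).
#' @param gc expected GC fraction of the ancestor.
#' @return data.frame with columns `taxon_id`, `genome_id`, `seq`. The
#'   target accessions share `taxon_id` `"target_sp"`; every other genome
#'   is its own taxon.
#' @export
simulate_accession_panel <- function(seed, length = 150000,
                                     n_accessions = 3, n_genus = 2,
                                     n_family = 3, acc_divergence = 5e-4,
                                     genus_divergence = 0.02,
                                     family_divergence = 0.10,
                                     outgroup_divergence = 0.25,
                                     outgroup = TRUE, gc = 0.37) {
  anc <- simulate_genome(length, seed = seed, gc = gc)
  rows <- list()
  add <- function(taxon, genome, rate, sub_seed) {
    sq <- if (rate == 0) anc else
      mutate_genome(anc, sub_rate = rate, seed = sub_seed)$seq
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_id = taxon, genome_id = genome, seq = sq,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_accessions))
    add("target_sp", sprintf("target_sp_acc%d", i), acc_divergence,
        seed + 100L + i)
  for (i in seq_len(n_genus))
    add(sprintf("genus_rel%d", i), sprintf("genus_rel%d_g1", i),
        genus_divergence, seed + 200L + i)
  for (i in seq_len(n_family))
    add(sprintf("family_rel%d", i), sprintf("family_rel%d_g1", i),
        family_divergence, seed + 300L + i)
  if (outgroup)
    add("outgroup", "outgroup_g1", outgroup_divergence, seed + 400L)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
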