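test_that("genome simulation is deterministic with controlled composition", {
  g1 <- simulate_genome(158823, seed = 12)
  g2 <- simulate_genome(158823, seed = 12)
  expect_identical(g1, g2)
  expect_equal(nchar(g1), 158823)

  # observed GC within 3 binomial standard errors of the target
  g <- simulate_genome(150000, seed = 13, gc = 0.37)
  gc_obs <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / 150000
  se <- sqrt(0.37 * 0.63 / 150000)
  expect_lt(abs(gc_obs - 0.37), 3 * se)

  # two independent draws differ at about 1 - sum(p^2) of positions
  a <- strsplit(simulate_genome(50000, seed = 14), "")[[1]]
  b <- strsplit(simulate_genome(50000, seed = 15), "")[[1]]
  p <- c(0.315, 0.185, 0.185, 0.315)
  exp_mismatch <- 1 - sum(p^2)
  se <- sqrt(exp_mismatch * (1 - exp_mismatch) / 50000)
  expect_lt(abs(mean(a != b) - exp_mismatch), 3 * se)
})

test_that("mutation honors explicit variant plans and records ground truth", {
  g <- simulate_genome(1000, seed = 16)
  null <- mutate_genome(g)
  expect_identical(null$seq, g)
  expect_equal(nrow(null$variants), 0)

  # plant a 17 bp deletion: printed-style coordinates close over 17 bases
  big <- simulate_genome(60000, seed = 17)
  m <- mutate_genome(big, variants = data.frame(
    kind = "deletion", ref_start = 58399, ref_end = 58415))
  expect_equal(nchar(m$seq), 60000 - 17)
  expect_equal(m$variants$ref_end - m$variants$ref_start + 1, 17)
  expect_equal(m$variants$length, 17)
  expect_identical(m$seq, paste0(substr(big, 1, 58398),
                                 substr(big, 58416, 60000)))

  expect_error(mutate_genome(g, variants = data.frame(
    kind = c("deletion", "snp"), ref_start = c(10, 12),
    ref_end = c(14, 12), query_allele = c("", "A"))), "overlapping")
})

test_that("random substitution counts follow the binomial model", {
  g <- simulate_genome(150000, seed = 18)
  m <- mutate_genome(g, sub_rate = 0.001, seed = 19)
  n_sub <- sum(m$variants$kind == "snp")
  se <- sqrt(150000 * 0.001 * 0.999)
  expect_lt(abs(n_sub - 150), 3 * se)
  # every recorded snp differs from the reference at its position
  expect_true(all(m$variants$ref_allele != m$variants$query_allele))
})

test_that("simulated reads are exact circular substrings when error-free", {
  g <- simulate_genome(5000, seed = 20)
  doubled <- paste0(g, substr(g, 1, 124))
  reads <- simulate_reads(g, 200, error_rate = 0, seed = 21)
  expect_equal(nrow(reads), 200)
  expect_true(all(nchar(reads$seq) == 125))
  hit <- vapply(reads$seq, function(s)
    grepl(s, doubled, fixed = TRUE) || grepl(revcomp(s), doubled,
                                             fixed = TRUE), logical(1))
  expect_true(all(hit))
  expect_equal(nrow(simulate_reads(g, 0, seed = 1)), 0)
})

test_that("read error rate matches the binomial oracle", {
  g <- simulate_genome(5000, seed = 22)
  clean <- simulate_reads(g, 400, error_rate = 0, seed = 23)
  noisy <- simulate_reads(g, 400, error_rate = 0.01, seed = 23)
  # same seed => same positions/strands, so mismatches are pure error
  mm <- sum(vapply(seq_len(400), function(i) {
    a <- strsplit(clean$seq[i], "")[[1]]
    b <- strsplit(noisy$seq[i], "")[[1]]
    sum(a != b)
  }, numeric(1)))
  n <- 400 * 125
  se <- sqrt(n * 0.01 * 0.99)
  expect_lt(abs(mm - n * 0.01), 3 * se)
})

test_that("mixtures honor the design within one read per component", {
  pools <- list(
    list(label = "p1", reads = simulate_reads(random_dna(3000, 30), 40000,
                                              seed = 31, id_prefix = "p1"),
         proportion = 30),
    list(label = "p2", reads = simulate_reads(random_dna(3000, 32), 40000,
                                              seed = 33, id_prefix = "p2"),
         proportion = 30),
    list(label = "p3", reads = simulate_reads(random_dna(3000, 34), 40000,
                                              seed = 35, id_prefix = "p3"),
         proportion = 30),
    list(label = "b1", reads = simulate_reads(random_dna(3000, 36), 5000,
                                              seed = 37, id_prefix = "b1"),
         proportion = 3.3),
    list(label = "b2", reads = simulate_reads(random_dna(3000, 38), 5000,
                                              seed = 39, id_prefix = "b2"),
         proportion = 3.3),
    list(label = "b3", reads = simulate_reads(random_dna(3000, 40), 5000,
                                              seed = 41, id_prefix = "b3"),
         proportion = 3.3))
  spike_pool <- simulate_reads(random_dna(3000, 42), 6000, seed = 43,
                               id_prefix = "sp")
  spec <- mixture_spec(pools, list(label = "target", reads = spike_pool,
                                   fraction = 5),
                       total_reads = 100000, seed = 44)
  mix <- build_mixture(spec)
  expect_equal(nrow(mix), 100000)
  lab <- sub("\\|.*$", "", mix$id)
  tally <- table(lab)
  expect_equal(unname(tally["target"]), round(100000 * 5 / 100))
  shares <- 95000 * c(30, 30, 30, 3.3, 3.3, 3.3) / 99.9
  for (i in seq_along(pools))
    expect_lte(abs(tally[pools[[i]]$label] - shares[i]), 1)

  # spike 0% contains no spike-labeled reads
  spec0 <- mixture_spec(pools, list(label = "target", reads = spike_pool,
                                    fraction = 0),
                        total_reads = 1000, seed = 45)
  expect_false(any(grepl("^target\\|", build_mixture(spec0)$id)))

  # pool exhaustion errors without the replacement flag
  small <- list(list(label = "b1", reads = pools[[4]]$reads,
                     proportion = 100))
  specx <- mixture_spec(small, list(label = "target",
                                    reads = spike_pool, fraction = 0),
                        total_reads = 20000, seed = 46)
  expect_error(build_mixture(specx), "exhausted")
  specr <- mixture_spec(small, list(label = "target",
                                    reads = spike_pool, fraction = 0),
                        total_reads = 20000, seed = 46, replace = TRUE)
  expect_equal(nrow(build_mixture(specr)), 20000)
})

test_that("mixture design validation rejects bad proportions", {
  p <- list(list(label = "a", reads = seq_set("r", strrep("A", 125)),
                 proportion = 50))
  sp <- list(label = "s", reads = seq_set("r", strrep("A", 125)),
             fraction = 1)
  expect_error(mixture_spec(p, sp, total_reads = 10), "sum to 100")
  expect_error(mixture_spec(list(list(label = "a",
                                      reads = seq_set("r", "A"),
                                      proportion = 100)),
                            list(label = "s", reads = seq_set("r", "A"),
                                 fraction = 100),
                            total_reads = 10), "fraction")
  expect_error(mixture_spec(p, sp, total_reads = 0), "total_reads")
})

test_that("the full simulation pipeline is byte-reproducible under a fixed seed", {
  run <- function() {
    g <- simulate_genome(4000, seed = 50)
    pools <- list(list(label = "bg",
                       reads = simulate_reads(random_dna(4000, 51), 2000,
                                              seed = 52, id_prefix = "bg"),
                       proportion = 100))
    tg <- simulate_reads(g, 500, seed = 53, id_prefix = "tg")
    spec <- mixture_spec(pools, list(label = "t", reads = tg, fraction = 2),
                         total_reads = 1000, seed = 54)
    f <- tempfile(fileext = ".fastq")
    write_sequences(build_mixture(spec), f)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(run(), run())
})

test_that("accession panels have the designed nested divergence", {
  panel <- small_panel()
  expect_equal(sum(panel$taxon_id == "target_sp"), 3)
  pdiv <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x != y)
  }
  accs <- panel$seq[panel$taxon_id == "target_sp"]
  expect_lt(pdiv(accs[1], accs[2]), 0.0015)  # conspecific ~0.1%
  gen <- panel$seq[grepl("genus", panel$genome_id)][1]
  expect_gt(pdiv(accs[1], gen), 0.01)
  fam <- panel$seq[grepl("family", panel$genome_id)][1]
  expect_gt(pdiv(accs[1], fam), pdiv(accs[1], gen))
})
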