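# 3-genome toy database over 2 kb genomes at k=11 keeps the brute-force
# oracle cheap while exercising the full matching path.
toy_world <- function(k = 11, canonical = TRUE) {
  genomes <- data.frame(
    taxon_id = c("spA", "spA", "spB"),
    genome_id = c("A1", "A2", "B1"),
    seq = c(random_dna(2000, 21),
            mutate_genome(random_dna(2000, 21), sub_rate = 0.001,
                          seed = 22)$seq,
            random_dna(2000, 23)))
  list(genomes = genomes,
       db = build_kmer_db(genomes, k = k, canonical = canonical))
}

test_that("an error-free read from a genome matches it completely", {
  w <- toy_world()
  reads <- simulate_reads(w$genomes$seq[1], 20, read_len = 125,
                          error_rate = 0, seed = 5)
  asg <- assign_reads(reads, w$db)
  expect_true(all(asg$n_kmers == 125 - 11 + 1))
  expect_true(all(asg$best_fraction == 1))
  expect_true(all(asg$best_genome %in% c("A1", "A2")))
})

test_that("random reads match nothing at high k and stay unassigned", {
  panel <- small_panel()
  db <- build_kmer_db(panel[1:4, ], k = 31)
  rnd <- seq_set(sprintf("r%02d", 1:50),
                 replicate(50, random_dna(125, sample.int(1e6, 1))))
  asg <- assign_reads(rnd, db)
  expect_true(all(is.na(asg$best_genome)))
  expect_true(all(attr(asg, "matches") == 0))
})

test_that("per-genome match counts equal brute-force membership testing", {
  w <- toy_world(k = 11, canonical = TRUE)
  reads <- rbind(simulate_reads(w$genomes$seq[1], 40, seed = 31,
                                error_rate = 0.01),
                 simulate_reads(w$genomes$seq[3], 40, seed = 32,
                                error_rate = 0.01),
                 seq_set("rnd", random_dna(125, 77)))
  class(reads) <- c("seq_set", "data.frame")
  asg <- assign_reads(reads, w$db)
  m <- attr(asg, "matches")
  gsets <- lapply(w$genomes$seq, function(s)
    names(oracle_kmers(s, 11, canonical = TRUE, circular = TRUE)))
  for (i in seq_len(nrow(reads))) {
    rk <- names(oracle_kmers(reads$seq[i], 11, canonical = TRUE))
    rk_all <- oracle_kmers(reads$seq[i], 11, canonical = TRUE)
    for (g in 1:3) {
      expected <- sum(rk_all[names(rk_all) %in% gsets[[g]]])
      expect_equal(unname(m[i, g]), unname(expected))
    }
  }
})

test_that("ties in best-genome choice break lexicographically", {
  s <- random_dna(1000, 8)
  g <- data.frame(taxon_id = c("t2", "t1"), genome_id = c("zz", "aa"),
                  seq = c(s, s))
  db <- build_kmer_db(g, k = 15)
  reads <- simulate_reads(s, 10, error_rate = 0, seed = 9)
  asg <- assign_reads(reads, db)
  expect_true(all(asg$best_genome == "aa"))
})

test_that("detect calls the source taxon and only the source taxon", {
  w <- toy_world()
  reads <- simulate_reads(w$genomes$seq[1], 200, seed = 41)
  rep_ <- detect(reads, w$db)
  expect_s3_class(rep_, "detection_report")
  expect_true(rep_$detected[rep_$taxon_id == "spA"])
  expect_true(rep_$supported[rep_$taxon_id == "spA"])
  expect_false(rep_$detected[rep_$taxon_id == "spB"])
  expect_lte(sum(rep_$assigned_reads), nrow(reads))
  # detected implies the read-count threshold
  expect_true(all(rep_$assigned_reads[rep_$detected] >=
                    attr(rep_, "params")$min_reads))
})

test_that("detect on zero reads reports no detections", {
  w <- toy_world()
  rep_ <- detect(seq_set(character(0), character(0)), w$db)
  expect_equal(attr(rep_, "total_reads"), 0L)
  expect_false(any(rep_$detected))
})

test_that("reads shorter than k contribute zero kmers but count as reads", {
  w <- toy_world(k = 31)
  reads <- seq_set(c("tiny", "ok"),
                   c("ACGTACGT", substr(w$genomes$seq[1], 1, 125)))
  asg <- assign_reads(reads, w$db)
  expect_equal(asg$n_kmers, c(0L, 95L))
  expect_true(is.na(asg$best_genome[1]))
  rep_ <- detect(reads, w$db)
  expect_equal(attr(rep_, "total_reads"), 2L)
})

test_that("match counts are invariant to read order and db serialization", {
  w <- toy_world()
  reads <- simulate_reads(w$genomes$seq[1], 50, seed = 51)
  asg1 <- assign_reads(reads, w$db)
  perm <- plastidkmer:::with_seed(1, sample.int(nrow(reads)))
  shuffled <- reads[perm, ]
  class(shuffled) <- c("seq_set", "data.frame")
  asg2 <- assign_reads(shuffled, w$db)
  expect_equal(attr(asg2, "matches"), attr(asg1, "matches")[perm, ])
  path <- withr::local_tempfile()
  save_kmer_db(w$db, path)
  asg3 <- assign_reads(reads, load_kmer_db(path))
  expect_identical(attr(asg3, "matches"), attr(asg1, "matches"))
})

test_that("spiking more target reads never lowers its matched-kmer total", {
  # k = 21 makes chance matches of unrelated background negligible
  w <- toy_world(k = 21)
  bg <- simulate_reads(random_dna(2000, 61), 2000, seed = 62,
                       id_prefix = "bg")
  tg <- simulate_reads(w$genomes$seq[1], 500, seed = 63, id_prefix = "tg")
  comps <- list(list(label = "bg", reads = bg, proportion = 100))
  totals <- vapply(c(0, 1, 5, 20), function(f) {
    spec <- mixture_spec(comps, list(label = "spA", reads = tg,
                                     fraction = f),
                         total_reads = 1000, seed = 7)
    rep_ <- detect(build_mixture(spec), w$db)
    rep_$total_matched_kmers[rep_$taxon_id == "spA"]
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
  expect_equal(totals[1], 0)
})

test_that("adding an unrelated genome leaves the target's counts unchanged", {
  w <- toy_world()
  reads <- simulate_reads(w$genomes$seq[1], 100, seed = 71)
  before <- detect(reads, w$db)
  g2 <- rbind(w$genomes,
              data.frame(taxon_id = "spC", genome_id = "C1",
                         seq = random_dna(2000, 72)))
  after <- detect(reads, build_kmer_db(g2, k = 11))
  for (col in c("total_matched_kmers", "unique_matched_kmers",
                "assigned_reads"))
    expect_equal(after[after$taxon_id == "spA", col],
                 before[before$taxon_id == "spA", col])
})

test_that("take-one-out accuracy scores trials against the detection reports", {
  panel <- small_panel()
  db <- build_kmer_db(panel, k = 31)
  accs <- panel$genome_id[panel$taxon_id == "target_sp"]
  dbs <- lapply(accs, function(g) take_one_out(db, g))
  sets <- lapply(seq_along(accs), function(i)
    simulate_reads(panel$seq[panel$genome_id == accs[i]], 500,
                   seed = 80 + i, id_prefix = accs[i]))
  acc <- take_one_out_accuracy(dbs, sets, "target_sp")
  expect_equal(as.numeric(acc), 100)
  # recount oracle: accuracy equals the mean of per-trial indicators
  trials <- vapply(seq_along(dbs), function(i) {
    rep_ <- detect(sets[[i]], dbs[[i]])
    det <- rep_[rep_$detected, ]
    nrow(det) > 0 && det$taxon_id[1] == "target_sp"
  }, logical(1))
  expect_equal(as.numeric(acc), 100 * mean(trials))
  expect_equal(attr(acc, "trials"), trials)
  # negative control: an unrelated "true" taxon scores 0
  expect_equal(as.numeric(take_one_out_accuracy(dbs, sets, "genus_rel1")), 0)
  expect_error(take_one_out_accuracy(dbs[1:2], sets, "target_sp"),
               "same length")
})

test_that("dilution series flags the spike and never the absent target", {
  panel <- small_panel()
  db <- build_kmer_db(panel, k = 31)
  bg <- list(list(label = "bg1",
                  reads = simulate_reads(random_dna(20000, 91), 4000,
                                         seed = 92, id_prefix = "bg1"),
                  proportion = 100))
  tg <- simulate_reads(panel$seq[1], 2000, seed = 93, id_prefix = "tg")
  tab <- dilution_series(db, bg, tg, "target_sp", fractions = c(10, 0),
                         total_reads = 2000, seed = 5, replicates = 2)
  expect_true(all(tab$supported[tab$fraction == 10]))
  expect_false(any(tab$detected[tab$fraction == 0]))
  expect_equal(attr(tab, "lod"), 10)
  expect_equal(lod_from_series(tab), 10)
})
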