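# Shared fixtures and independent oracles, built in code at test time.

random_dna <- function(n, seed, alphabet = c("A", "C", "G", "T")) {
  plastidkmer:::with_seed(seed,
    paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

# brute-force kmer enumeration oracle: plain R substring sliding window
oracle_kmers <- function(seq, k, canonical = FALSE, circular = FALSE) {
  if (circular) seq <- paste0(seq, substr(seq, 1, k - 1))
  L <- nchar(seq)
  if (L < k) return(table(character(0)))
  w <- substring(seq, 1:(L - k + 1), k:L)
  w <- w[!grepl("[^ACGT]", w)]
  if (canonical) w <- pmin(w, revcomp(w))
  table(w)
}

# sort-based median oracle
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else mean(x[n / 2 + 0:1])
}

# small nested genome panel shared across detection/phylo tests (cached)
local({
  cache <- new.env()
  small_panel <<- function() {
    if (is.null(cache$panel))
      cache$panel <- simulate_accession_panel(
        4242, length = 20000, n_genus = 2, n_family = 2)
    cache$panel
  }
})

# dense D2* oracle: direct summation over all 4^k words from first
# principles (counts, composition and expectations recomputed in plain R)
dense_d2star <- function(sx, sy, k) {
  words <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1,
                 paste, collapse = "")
  cx <- oracle_kmers(sx, k); cy <- oracle_kmers(sy, k)
  x <- as.numeric(cx[words]); x[is.na(x)] <- 0
  y <- as.numeric(cy[words]); y[is.na(y)] <- 0
  fx <- table(factor(strsplit(sx, "")[[1]], c("A", "C", "G", "T")))
  fy <- table(factor(strsplit(sy, "")[[1]], c("A", "C", "G", "T")))
  px_b <- as.numeric(fx / sum(fx)); py_b <- as.numeric(fy / sum(fy))
  wmat <- do.call(rbind, strsplit(words, ""))
  pw <- function(pb) apply(wmat, 1, function(w)
    prod(pb[match(w, c("A", "C", "G", "T"))]))
  px <- pw(px_b); py <- pw(py_b)
  mx <- sum(x); my <- sum(y)
  num <- function(x, y, px, py, mx, my)
    sum((x - mx * px) * (y - my * py) / sqrt(mx * px * my * py))
  raw <- num(x, y, px, py, mx, my)
  raw / sqrt(num(x, x, px, px, mx, mx) * num(y, y, py, py, my, my))
}

# additive distance matrix from a random binary tree with strictly
# positive branch lengths (ape's rtree + path distances = ground truth)
random_additive_matrix <- function(n_taxa, seed) {
  plastidkmer:::with_seed(seed, {
    tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 2))
    ape::cophenetic.phylo(tr)
  })
}
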