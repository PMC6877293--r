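# Independent brute-force oracles used across test files. These stay naive
# on purpose: simple loops over characters and positions, sharing no code
# with the implementation paths they check.

random_genome <- function(n, gc = 0.5, seed = 1) {
  withr_seed(seed)
  hta_genome(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                          prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                   (1 - gc) / 2)),
                   collapse = ""), id = "oracle")
}

withr_seed <- function(seed) set.seed(seed)

# per-base coverage by explicit counting, circular
brute_coverage <- function(fragments, n) {
  v <- numeric(n)
  for (i in seq_len(nrow(fragments))) {
    for (p in fragments$start[i]:(fragments$end[i] - 1L)) {
      v[(p %% n) + 1L] <- v[(p %% n) + 1L] + 1
    }
  }
  v
}

# windowed k-mer frequency at 1-based position p by substring scanning
brute_kmer_freq <- function(genome, kmer, window, p) {
  ch <- strsplit(genome$sequence, "")[[1]]
  n <- length(ch)
  k <- nchar(kmer)
  h <- (window - 1L) / 2L
  idx <- ((p - 1 - h):(p - 1 + h)) %% n + 1L
  s <- paste(ch[idx], collapse = "")
  cnt <- 0L
  for (i in 1:(window - k + 1L))
    if (substr(s, i, i + k - 1L) == kmer) cnt <- cnt + 1L
  cnt / (window - k + 1L)
}

# dyad-relative class proportion by per-fragment tallying
brute_class_profile <- function(fragments, genome, members, L) {
  ch <- strsplit(genome$sequence, "")[[1]]
  n <- length(ch)
  offs <- seq.int(-(L %/% 2L), (L %/% 2L) - 1L)
  dy <- (fragments$start + fragments$end) %/% 2L
  vapply(offs, function(d) {
    hits <- 0L
    for (i in seq_along(dy)) {
      p1 <- ((dy[i] + d) %% n) + 1L
      p2 <- ((dy[i] + d + 1L) %% n) + 1L
      din <- paste0(ch[p1], ch[p2])
      if (din %in% members) hits <- hits + 1L
    }
    hits / length(dy)
  }, 0)
}
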