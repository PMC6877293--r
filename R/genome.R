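#' Genome object
#'
#' In-memory representation of a (typically circular) genome: an identifier,
#' an uppercase nucleotide sequence over \code{A,C,G,T,N}, and a circularity
#' flag. Archaeal chromosomes such as that of \emph{Thermoplasma acidophilum}
#' are circular, and all window extraction, fragment sampling and coverage
#' routines in this package honour the wrap-around.
#'
#' @param sequence single character string of nucleotides (case-insensitive)
#' @param id genome identifier used as the chromosome name in all outputs
#' @param circular logical; treat the sequence as circular
#' @return an object of class \code{hta_genome}
#' @examples
#' g <- hta_genome("ACGTACGT", id = "toy")
#' genome_length(g)
#' @export
hta_genome <- function(sequence, id = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("genome sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L)
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular)),
            class = "hta_genome")
}

#' @export
print.hta_genome <- function(x, ...) {
  cat(sprintf("<hta_genome> %s: %d bp (%s)\n", x$id, genome_length(x),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Genome length in base pairs
#' @param genome an \code{hta_genome}
#' @export
genome_length <- function(genome) nchar(genome$sequence)

# Integer base codes A=0 C=1 G=2 T=3, NA for N. Cached on the object's
# environmentless list is not possible, so callers reuse the vector.
base_codes <- function(genome) {
  r <- utf8ToInt(genome$sequence)
  code <- rep(NA_integer_, length(r))
  code[r == 65L] <- 0L  # A
  code[r == 67L] <- 1L  # C
  code[r == 71L] <- 2L  # G
  code[r == 84L] <- 3L  # T
  code
}

kmer_to_code <- function(kmer) {
  m <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  b <- m[strsplit(toupper(kmer), "")[[1]]]
  if (anyNA(b)) stop("k-mer must be over {A,C,G,T}: ", kmer)
  as.integer(sum(b * 4L^(rev(seq_along(b)) - 1L)))
}

# Rolling k-mer code at each start position (circular); NA where any of the
# k bases is N. Returned vector has the genome's length.
rolling_kmer_codes <- function(codes, k, circular = TRUE) {
  n <- length(codes)
  if (k > n) stop("k exceeds genome length")
  ext <- if (circular) c(codes, codes[seq_len(k - 1L)]) else codes
  out <- numeric(n + (if (circular) 0L else 1L - k))
  out[] <- 0
  for (j in seq_len(k)) {
    out <- out * 4 + as.numeric(ext[seq.int(j, length.out = length(out))])
  }
  out
}

#' Windowed k-mer frequency track
#'
#' For every position p of the genome, the frequency of \code{kmer} among the
#' k-mer start positions fully contained in the window of \code{window} bp
#' centred at p: count / (window - k + 1). Windows wrap around the origin for
#' circular genomes; windows containing any N base yield NA.
#'
#' This primitive underlies both the k-mer feature matrix of the occupancy
#' model and the planted synthetic occupancy landscapes.
#'
#' @param genome an \code{hta_genome}
#' @param kmer k-mer string, k between 1 and window
#' @param window odd window size in bp
#' @return numeric vector of per-bp frequencies in [0,1] (NA at N windows)
#' @export
kmer_window_frequency <- function(genome, kmer, window) {
  k <- nchar(kmer)
  n <- genome_length(genome)
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and positive")
  if (k > window) stop("k-mer longer than window")
  if (window > n) stop("window exceeds genome length")
  codes <- base_codes(genome)
  kc <- rolling_kmer_codes(codes, k)
  ind <- as.numeric(!is.na(kc) & kc == kmer_to_code(kmer))
  h <- (window - 1L) %/% 2L
  cnt <- window_sum_offset(ind, -h, h - k + 1L)
  freq <- cnt / (window - k + 1L)
  if (anyNA(codes)) {
    n_in_win <- window_sum_offset(as.numeric(is.na(codes)), -h, h)
    freq[n_in_win > 0] <- NA_real_
  }
  freq
}

# Extract the (circular) subsequence covering 1-based positions i..j as base
# codes; j may exceed the genome length.
codes_window <- function(codes, i, j) {
  n <- length(codes)
  codes[circ_index(seq.int(i, j), n)]
}

#' GC fraction of a genome or subsequence
#' @param genome an \code{hta_genome}
#' @export
gc_fraction <- function(genome) {
  codes <- base_codes(genome)
  mean(codes == 1L | codes == 2L, na.rm = TRUE)
}
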