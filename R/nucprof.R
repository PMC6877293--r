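#' Dinucleotide and mononucleotide class membership
#'
#' Classes follow the standard strong/weak and purine/pyrimidine
#' partitions: SS = \{CC,CG,GC,GG\}, WW = \{AA,AT,TA,TT\}, SW/WS their
#' mixed complements; RR = purine-purine \{AA,AG,GA,GG\}, YY =
#' pyrimidine-pyrimidine \{CC,CT,TC,TT\}, RY/YR the mixed purine classes.
#' Mononucleotide classes: mono_GC = \{G,C\}, mono_AT = \{A,T\}.
#'
#' @param name class name: one of "SS","WW","SW","WS","RR","YY","RY","YR",
#'   "mono_AT","mono_GC"
#' @return character vector of member (di)nucleotides
#' @export
dinucleotide_class <- function(name) {
  S <- c("C", "G"); W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  pairs <- function(a, b) as.vector(outer(a, b, paste0))
  switch(name,
         SS = pairs(S, S), WW = pairs(W, W),
         SW = pairs(S, W), WS = pairs(W, S),
         RR = pairs(R, R), YY = pairs(Y, Y),
         RY = pairs(R, Y), YR = pairs(Y, R),
         mono_AT = W, mono_GC = S,
         stop("unknown class: ", name))
}

is_mono_class <- function(name) name %in% c("mono_AT", "mono_GC")

# logical lookup over dinucleotide codes 0..15 (or base codes 0..3)
class_lut <- function(name) {
  members <- dinucleotide_class(name)
  if (is_mono_class(name)) {
    lut <- logical(4)
    lut[vapply(members, kmer_to_code, 0L) + 1L] <- TRUE
  } else {
    lut <- logical(16)
    lut[vapply(members, kmer_to_code, 0L) + 1L] <- TRUE
  }
  lut
}

#' Read filtering ahead of nucleotide profiling
#'
#' Retains fragments that (i) have mean base quality of at least
#' \code{min_mean_quality} (fragments with no quality recorded are
#' retained and counted in the \code{n_no_quality} attribute), (ii)
#' overlap at least one called peak by at least
#' \code{min_peak_overlap_fraction} of their own length, and (iii) are the
#' first occurrence of their exact coordinates (duplicate removal, so
#' profiles are not biased toward highly occupied footprints).
#'
#' @param fragments fragment table
#' @param peaks peak table
#' @param min_mean_quality quality threshold (default 30)
#' @param min_peak_overlap_fraction fraction of the fragment length that
#'   must be covered by a peak (default 0.9)
#' @param deduplicate drop exact coordinate duplicates (default TRUE)
#' @param genome_length_bp genome length (circular overlap handling)
#' @export
filter_reads <- function(fragments, peaks, min_mean_quality = 30,
                         min_peak_overlap_fraction = 0.9,
                         deduplicate = TRUE, genome_length_bp = NULL) {
  stopifnot(min_peak_overlap_fraction > 0, min_peak_overlap_fraction <= 1)
  fr <- fragments
  n_no_quality <- sum(is.na(fr$mean_quality))
  keep_q <- is.na(fr$mean_quality) | fr$mean_quality >= min_mean_quality
  fr <- fr[keep_q, , drop = FALSE]
  if (deduplicate) {
    fr <- fr[!duplicated(fr[, c("chrom", "start", "end")]), , drop = FALSE]
  }
  if (nrow(peaks) == 0L) {
    out <- fr[0, , drop = FALSE]
  } else {
    best <- numeric(nrow(fr))
    ps <- peaks$start; pe <- peaks$end
    for (j in seq_along(ps)) {
      ov <- pmin(fr$end, pe[j]) - pmax(fr$start, ps[j])
      best <- pmax(best, pmax(ov, 0L) / fr$length)
    }
    out <- fr[best >= min_peak_overlap_fraction, , drop = FALSE]
  }
  attr(out, "n_no_quality") <- n_no_quality
  out
}

#' Positional nucleotide-class profile around fragment dyads
#'
#' For fragments of a single length L, the proportion of fragments whose
#' genomic (di)nucleotide at each dyad-relative offset belongs to the
#' class. Offsets run over \code{[-floor(L/2), floor(L/2) - 1]} with the
#' dyad base at offset 0; a dinucleotide at offset d spans genomic
#' positions dyad+d and dyad+d+1 on the reference strand (merged MNase
#' fragments are unstranded, so reference-strand profiles make RR/YY
#' asymmetry a meaningful dyad property).
#'
#' @param fragments fragment table, all of one length (or within
#'   \code{length_range})
#' @param genome \code{hta_genome}
#' @param class_name see \code{\link{dinucleotide_class}}
#' @param length_range optional inclusive range of lengths to pool;
#'   offsets then use the range minimum
#' @return data.frame(offset, proportion, class, n_fragments)
#' @export
positional_class_profile <- function(fragments, genome, class_name,
                                     length_range = NULL) {
  if (!is.null(length_range)) {
    fragments <- fragments[fragments$length >= length_range[1] &
                           fragments$length <= length_range[2], ,
                           drop = FALSE]
    L <- as.integer(length_range[1])
  } else {
    L <- unique(fragments$length)
    if (length(L) != 1L)
      stop("fragments must share one length (or supply length_range)")
  }
  mono <- is_mono_class(class_name)
  if (!mono && L < 2L) stop("dinucleotide profile needs length >= 2")
  if (nrow(fragments) == 0L) stop("no fragments")
  lut <- class_lut(class_name)
  codes <- base_codes(genome)
  n <- length(codes)
  member <- if (mono) {
    ok <- !is.na(codes)
    v <- rep(NA, n); v[ok] <- lut[codes[ok] + 1L]; v
  } else {
    dc <- rolling_kmer_codes(codes, 2L)
    ok <- !is.na(dc)
    v <- rep(NA, n); v[ok] <- lut[dc[ok] + 1L]; v
  }
  dy <- fragment_dyads(fragments)
  offs <- seq.int(-(L %/% 2L), (L %/% 2L) - 1L)
  prop <- vapply(offs, function(d) {
    mean(member[circ_index(dy + d + 1L, n)], na.rm = TRUE)
  }, 0)
  data.frame(offset = offs, proportion = prop, class = class_name,
             n_fragments = nrow(fragments))
}

#' Background class proportion by random region sampling
#'
#' Expected class proportion under the genome's base composition,
#' estimated as the mean class proportion over \code{n} uniformly placed
#' regions of \code{region_size} bp (25,000 regions by default).
#'
#' @param genome \code{hta_genome}
#' @param region_size region size, bp
#' @param class_name see \code{\link{dinucleotide_class}}
#' @param n number of sampled regions
#' @param seed integer seed
#' @export
background_expectation <- function(genome, region_size, class_name,
                                   n = 25000L, seed = 1L) {
  g <- genome_length(genome)
  if (region_size > g) stop("region_size exceeds genome length")
  lut <- class_lut(class_name)
  codes <- base_codes(genome)
  mono <- is_mono_class(class_name)
  member <- if (mono) {
    ok <- !is.na(codes)
    v <- rep(NA, g); v[ok] <- lut[codes[ok] + 1L]; v
  } else {
    dc <- rolling_kmer_codes(codes, 2L)
    ok <- !is.na(dc)
    v <- rep(NA, g); v[ok] <- lut[dc[ok] + 1L]; v
  }
  n_steps <- if (mono) region_size else region_size - 1L
  with_seed(seed, {
    starts <- sample.int(g, n, replace = TRUE) - 1L   # 0-based
    acc <- 0; cnt <- 0
    for (j in seq_len(n_steps) - 1L) {
      vals <- member[circ_index(starts + j + 1L, g)]
      acc <- acc + sum(vals, na.rm = TRUE)
      cnt <- cnt + sum(!is.na(vals))
    }
    acc / cnt
  })
}

#' Mean GC profile around (re-oriented) peak dyads
#'
#' Per-offset mean of the G-or-C indicator across peak windows; windows of
#' flipped peaks are reversed.
#'
#' @param peaks oriented peak table (orientation column respected; "unset"
#'   treated as as_is)
#' @param genome \code{hta_genome}
#' @param flank half-window, bp
#' @return data.frame(offset, gc)
#' @export
peak_gc_profile <- function(peaks, genome, flank) {
  if (nrow(peaks) == 0L) stop("no peaks")
  codes <- base_codes(genome)
  n <- length(codes)
  isgc <- as.numeric(codes == 1L | codes == 2L)
  offs <- seq.int(-flank, flank)
  mat <- matrix(NA_real_, nrow(peaks), length(offs))
  for (i in seq_len(nrow(peaks))) {
    w <- isgc[circ_index(peaks$center[i] + offs + 1L, n)]
    if (identical(peaks$orientation[i], "flipped")) w <- rev(w)
    mat[i, ] <- w
  }
  data.frame(offset = offs, gc = colMeans(mat, na.rm = TRUE))
}

#' Write a positional profile as TSV
#' @param profile data.frame from \code{\link{positional_class_profile}}
#' @param path output file
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
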