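#' Peak-calling configuration
#'
#' Footprint calling follows the nucleR scheme: a low-pass Fourier filter
#' of the (normalized) coverage track, candidate peaks at local maxima of
#' the filtered track, and an empirical height score with threshold 2.5.
#' Width classes mirror the fragment classes: narrow footprints up to
#' 65 bp, broad footprints of 70 bp or more.
#'
#' @param keep_component_fraction fraction of Fourier components retained
#'   by the low-pass filter, in (0, 1]
#' @param score_threshold minimum peak score (standard score of the
#'   filtered peak height against the empirical distribution of the track)
#' @param narrow_max maximum half-height extent of a narrow peak, bp
#' @param broad_min minimum half-height extent of a broad peak, bp
#' @export
peak_call_config <- function(keep_component_fraction = 0.02,
                             score_threshold = 2.5,
                             narrow_max = 65L, broad_min = 70L) {
  stopifnot(keep_component_fraction > 0, keep_component_fraction <= 1,
            is.finite(score_threshold), narrow_max < broad_min)
  structure(list(keep_component_fraction = keep_component_fraction,
                 score_threshold = score_threshold,
                 narrow_max = as.integer(narrow_max),
                 broad_min = as.integer(broad_min)),
            class = "peak_call_config")
}

#' Low-pass Fourier filter of a coverage track
#'
#' Discrete Fourier transform of the circular track; the lowest-frequency
#' \code{keep_component_fraction} of components (plus their symmetric
#' conjugates) are retained, all others zeroed, and the real part of the
#' inverse transform returned. The DC component is always kept, so the
#' track mean is preserved.
#'
#' @param track \code{cov_track} or numeric vector
#' @param keep_component_fraction fraction in (0, 1]
#' @export
fourier_filter <- function(track, keep_component_fraction = 0.02) {
  stopifnot(keep_component_fraction > 0, keep_component_fraction <= 1)
  v <- track_values(track)
  n <- length(v)
  fq <- fft(v)
  cutoff <- floor(keep_component_fraction * n / 2)
  freq <- pmin(0:(n - 1), n - (0:(n - 1)))   # symmetric frequency index
  fq[freq > cutoff] <- 0
  out <- Re(fft(fq, inverse = TRUE)) / n
  if (inherits(track, "cov_track"))
    cov_track(out, genome_id = track$genome_id,
              size_class = track$size_class, normalization = "filtered")
  else out
}

# circular local maxima, leftmost-of-plateau rule
local_maxima_circular <- function(v) {
  n <- length(v)
  prev <- v[c(n, seq_len(n - 1L))]
  nxt <- v[c(seq.int(2L, n), 1L)]
  which(v > prev & v >= nxt)
}

# half-height extent around a candidate maximum (1-based index), circular
half_height_extent <- function(v, i, max_reach) {
  n <- length(v)
  half <- v[i] / 2
  left <- i; right <- i
  for (s in seq_len(max_reach)) {
    j <- circ_index(i - s, n)
    if (v[j] < half) break
    left <- i - s
  }
  for (s in seq_len(max_reach)) {
    j <- circ_index(i + s, n)
    if (v[j] < half) break
    right <- i + s
  }
  c(left, right)
}

#' Detect footprint peaks on a filtered track
#'
#' Candidate centres are local maxima of the low-pass filtered track
#' (leftmost position on plateaus). The peak extent is the contiguous
#' region above half the centre height; the score is the filtered value at
#' the centre expressed as a standard score against the empirical
#' (genome-wide) distribution of the unfiltered track:
#' \code{(filtered[center] - mean(raw)) / sd(raw)}. Peaks scoring below the
#' threshold are discarded; the extent width assigns the narrow/broad
#' class. Detection expects a mean-zero normalized track (the output of
#' \code{\link{normalize_by_input}} or \code{\link{self_normalize}}), for
#' which the half-height extent is well defined.
#'
#' @param filtered_track output of \code{\link{fourier_filter}}
#' @param raw_track the track the filter was applied to
#' @param config \code{\link{peak_call_config}}
#' @param max_extent search limit for the half-height extent, bp
#' @return data.frame(chrom, center, start, end, width, width_class,
#'   score, orientation); coordinates 0-based half-open, center = dyad
#' @export
detect_peaks <- function(filtered_track, raw_track,
                         config = peak_call_config(), max_extent = 1000L) {
  f <- track_values(filtered_track)
  r <- track_values(raw_track)
  if (length(f) != length(r)) stop("filtered and raw tracks differ in length")
  mu <- mean(r); s <- stats::sd(r)
  if (!is.finite(s) || s < 1e-12)
    stop("raw track has zero variance; cannot score peaks")
  n <- length(f)
  cand <- local_maxima_circular(f)
  if (length(cand) == 0L)
    return(empty_peaks())
  score <- (f[cand] - mu) / s
  keep <- score >= config$score_threshold
  cand <- cand[keep]; score <- score[keep]
  if (length(cand) == 0L) return(empty_peaks())
  ext <- t(vapply(cand, function(i) half_height_extent(f, i, max_extent),
                  c(0, 0)))
  width <- ext[, 2] - ext[, 1] + 1L
  cls <- rep(NA_character_, length(cand))
  cls[width <= config$narrow_max] <- "narrow"
  cls[width >= config$broad_min] <- "broad"
  gid <- if (inherits(filtered_track, "cov_track"))
    filtered_track$genome_id else "genome"
  data.frame(chrom = gid,
             center = cand - 1L,                 # 0-based dyad
             start = as.integer(ext[, 1] - 1L),  # may be negative (wrap)
             end = as.integer(ext[, 2]),         # half-open
             width = as.integer(width),
             width_class = cls,
             score = score,
             orientation = "unset",
             stringsAsFactors = FALSE)
}

empty_peaks <- function() {
  data.frame(chrom = character(), center = integer(), start = integer(),
             end = integer(), width = integer(), width_class = character(),
             score = numeric(), orientation = character(),
             stringsAsFactors = FALSE)
}

#' Match peaks between two calls by reciprocal overlap
#'
#' A pair matches when the intersection covers at least
#' \code{min_reciprocal_overlap} of both extents. Candidate pairs are
#' matched greedily in order of decreasing reciprocal overlap, each peak
#' entering at most one pair.
#'
#' @param a,b peak tables from \code{\link{detect_peaks}}
#' @param min_reciprocal_overlap fraction in (0, 1]
#' @return list(matched = data.frame(a, b, overlap), a_only, b_only)
#'   where a/b are row indices into the inputs
#' @export
overlap_peaks <- function(a, b, min_reciprocal_overlap = 0.5) {
  pairs <- NULL
  if (nrow(a) && nrow(b)) {
    ov <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      lo <- pmax(a$start[i], b$start[j])
      hi <- pmin(a$end[i], b$end[j])
      pmax(hi - lo, 0L)
    })
    recd <- ov / outer(a$end - a$start, b$end - b$start, pmax)
    cand <- which(recd >= min_reciprocal_overlap, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(recd[cand], decreasing = TRUE)
      cand <- cand[ord, , drop = FALSE]
      used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_a[i] && !used_b[j]) {
          keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand))
        pairs <- data.frame(a = cand[, 1], b = cand[, 2],
                            overlap = ov[cand])
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(a = integer(), b = integer(), overlap = integer())
  list(matched = pairs,
       a_only = setdiff(seq_len(nrow(a)), pairs$a),
       b_only = setdiff(seq_len(nrow(b)), pairs$b))
}

#' Partition broad peaks into deciles of relative small-fragment coverage
#'
#' Per peak, the statistic is
#' mean(small coverage over the extent) / (mean small + mean large), the
#' relative abundance of small fragments at the footprint. Peaks are ranked
#' by the statistic and split into 10 equal-count groups (decile 1 =
#' lowest relative small-fragment coverage; any remainder is spread from
#' decile 1 upward).
#'
#' @param broad_peaks peak table (at least 10 rows)
#' @param small_track,large_track coverage tracks of the two size classes
#' @return the peak table with columns \code{small_fraction} and
#'   \code{decile} added
#' @export
decile_partition <- function(broad_peaks, small_track, large_track) {
  if (nrow(broad_peaks) < 10L) stop("need at least 10 broad peaks")
  sv <- track_values(small_track); lv <- track_values(large_track)
  n <- length(sv)
  stat <- vapply(seq_len(nrow(broad_peaks)), function(i) {
    idx <- circ_index(seq.int(broad_peaks$start[i] + 1L,
                              broad_peaks$end[i]), n)
    s <- mean(sv[idx]); l <- mean(lv[idx])
    if (s + l <= 0) {
      warning("zero total coverage at peak ", i, "; statistic set to 0")
      return(0)
    }
    s / (s + l)
  }, 0)
  m <- nrow(broad_peaks)
  base <- m %/% 10L; rem <- m %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, rem), rep(0L, 10L - rem))
  decile_by_rank <- rep(seq_len(10L), sizes)
  out <- broad_peaks
  out$small_fraction <- stat
  out$decile <- integer(m)
  out$decile[order(stat)] <- decile_by_rank
  out
}

#' Intergenic enrichment of a peak subset
#'
#' A peak is intergenic when its centre lies outside every gene interval.
#' The enrichment ratio is the intergenic fraction of the query peaks over
#' the intergenic fraction of the genome; the p-value is an upper-tail
#' hypergeometric test drawing the query subset from a population of peaks
#' (successes = intergenic peaks in the population).
#'
#' @param peaks query peak table
#' @param gene_intervals data.frame(start, end), 0-based half-open gene
#'   coordinates
#' @param genome \code{hta_genome} (for the genomic intergenic fraction)
#' @param population optional superset peak table the query was drawn from;
#'   defaults to the query itself
#' @return list(n_query, n_intergenic, ratio, p_value,
#'   genome_intergenic_fraction)
#' @export
intergenic_enrichment <- function(peaks, gene_intervals, genome,
                                  population = NULL) {
  if (nrow(peaks) == 0L) stop("empty peak list")
  n <- genome_length(genome)
  genic <- logical(n)
  for (i in seq_len(nrow(gene_intervals))) {
    idx <- circ_index(seq.int(gene_intervals$start[i] + 1L,
                              gene_intervals$end[i]), n)
    genic[idx] <- TRUE
  }
  is_intergenic <- function(pk) !genic[circ_index(pk$center + 1L, n)]
  population <- population %||% peaks
  k <- sum(is_intergenic(peaks))
  K <- sum(is_intergenic(population))
  N <- nrow(population)
  m <- nrow(peaks)
  frac_genome <- mean(!genic)
  ratio <- (k / m) / frac_genome
  p <- stats::phyper(k - 1L, K, N - K, m, lower.tail = FALSE)
  list(n_query = m, n_intergenic = k, ratio = ratio, p_value = p,
       genome_intergenic_fraction = frac_genome)
}

#' Write peaks as extended BED
#'
#' BED6 plus width_class, score and (when present) decile columns.
#' @param peaks peak table
#' @param path output file
#' @export
write_peaks_bed <- function(peaks, path) {
  dec <- if ("decile" %in% names(peaks)) peaks$decile else ""
  writeLines(sprintf("%s\t%d\t%d\tpeak%d\t%.4f\t.\t%s\t%s",
                     peaks$chrom, pmax(peaks$start, 0L), peaks$end,
                     seq_len(nrow(peaks)), peaks$score, peaks$width_class,
                     as.character(dec)),
             path)
  invisible(path)
}
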