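#' Fragment size-class bounds
#'
#' Protected MNase fragments fall into two classes: small fragments of
#' 40-65 bp (minimal HTa footprints) and large fragments of 70-100 bp
#' (extended footprints). Bounds are inclusive on both ends.
#'
#' @param small,large inclusive length ranges, bp
#' @export
size_class_bounds <- function(small = c(40L, 65L), large = c(70L, 100L)) {
  stopifnot(length(small) == 2L, length(large) == 2L,
            small[1] <= small[2], large[1] <= large[2],
            small[2] < large[1])
  list(small = as.integer(small), large = as.integer(large))
}

size_class_of <- function(lengths, bounds = size_class_bounds()) {
  out <- rep("other", length(lengths))
  out[lengths >= bounds$small[1] & lengths <= bounds$small[2]] <- "small"
  out[lengths >= bounds$large[1] & lengths <= bounds$large[2]] <- "large"
  out
}

select_size_class <- function(fragments, size_class, bounds) {
  if (is.numeric(size_class) && length(size_class) == 2L) {
    keep <- fragments$length >= size_class[1] & fragments$length <= size_class[2]
  } else {
    size_class <- match.arg(size_class, c("all", "small", "large"))
    keep <- switch(size_class,
      all = rep(TRUE, nrow(fragments)),
      small = fragments$length >= bounds$small[1] &
              fragments$length <= bounds$small[2],
      large = fragments$length >= bounds$large[1] &
              fragments$length <= bounds$large[2])
  }
  fragments[keep, , drop = FALSE]
}

#' Fragment-size-resolved coverage
#'
#' Per-base coverage: \code{values[p]} is the number of retained fragments
#' with \code{start <= p < end}. Fragments outside the requested size class
#' are excluded entirely; fragments spanning the origin of a circular genome
#' (end > genome length) wrap.
#'
#' @param fragments fragment table (see \code{\link{fragments_df}})
#' @param genome an \code{hta_genome} (supplies length and circularity)
#' @param size_class "all", "small", "large", or a numeric \code{c(lo, hi)}
#'   length range (inclusive)
#' @param bounds size-class bounds
#' @return a raw \code{cov_track}
#' @export
compute_coverage <- function(fragments, genome, size_class = "all",
                             bounds = size_class_bounds()) {
  n <- genome_length(genome)
  fr <- select_size_class(fragments, size_class, bounds)
  delta <- numeric(n + 1L)
  if (nrow(fr) > 0L) {
    s <- fr$start; e <- fr$end
    if (any(s < 0L | s >= n)) stop("fragment start outside genome")
    if (any(e > 2L * n) || (!genome$circular && any(e > n)))
      stop("fragment end outside genome")
    e1 <- pmin(e, n)
    delta <- delta + tabulate(s + 1L, n + 1L) - tabulate(e1 + 1L, n + 1L)
    wrap <- e > n
    if (any(wrap))
      delta <- delta + tabulate(rep(1L, sum(wrap)), n + 1L) -
        tabulate(e[wrap] - n + 1L, n + 1L)
  }
  lab <- if (is.numeric(size_class)) paste(size_class, collapse = "-")
         else size_class
  cov_track(cumsum(delta)[seq_len(n)], genome_id = genome$id,
            size_class = lab, normalization = "raw")
}

#' RPGC (1x genome coverage) normalization
#'
#' Scales a raw track so that mean coverage over the effective genome size
#' equals 1: values are multiplied by
#' \code{effective_genome_size / sum(values)}. For the \emph{T. acidophilum}
#' assembly the effective genome size is 1,564,906 bp.
#'
#' @param track raw \code{cov_track}
#' @param effective_genome_size effective (mappable) genome size, bp
#' @export
rpgc_normalize <- function(track, effective_genome_size = genome_length_ta()) {
  v <- track_values(track)
  s <- sum(v)
  if (s <= 0) stop("cannot RPGC-normalize an all-zero track")
  cov_track(v * effective_genome_size / s, genome_id = track$genome_id,
            size_class = track$size_class, normalization = "RPGC")
}

#' Effective genome size of the T. acidophilum DSM1728 assembly
#' @export
genome_length_ta <- function() 1564906L

#' Circular running-mean smoothing
#'
#' @param track \code{cov_track} or numeric vector
#' @param window odd window, bp; must not exceed the track length
#' @export
smooth_track <- function(track, window) {
  v <- track_values(track)
  if (window > length(v)) stop("smoothing window exceeds genome length")
  if (window %% 2L != 1L || window < 1L) stop("window must be odd and >= 1")
  out <- running_mean_circular(v, window)
  if (inherits(track, "cov_track"))
    cov_track(out, genome_id = track$genome_id, size_class = track$size_class,
              normalization = track$normalization)
  else out
}

# clamp a smoothing window to the track length, keeping it odd
effective_window <- function(window, n) {
  w <- min(as.integer(window), n)
  if (w %% 2L == 0L) w <- w - 1L
  max(w, 1L)
}

#' Replication-bias removal by input normalization
#'
#' Divides an MNase coverage track by a heavily smoothed copy of the
#' matched sonicated-input track (default 10 kb window), removing the
#' origin-to-terminus copy-number gradient of replicating cells, then
#' converts the ratio to a Z-score (mean 0, sd 1). When the smoothed input
#' contains zeros the function fails loudly; supply \code{pseudocount} to add
#' a constant to the input before smoothing instead.
#'
#' @param mnase raw or RPGC \code{cov_track}
#' @param input matched input track on the same genome
#' @param smooth_window input smoothing window, bp (clamped to the genome)
#' @param pseudocount optional constant added to the input before smoothing
#' @return \code{cov_track} with normalization \code{"input_normalized_z"}
#' @export
normalize_by_input <- function(mnase, input, smooth_window = 10000L,
                               pseudocount = NULL) {
  m <- track_values(mnase); inp <- track_values(input)
  if (length(m) != length(inp)) stop("mnase and input tracks differ in length")
  if (!is.null(pseudocount)) inp <- inp + pseudocount
  w <- effective_window(smooth_window, length(inp))
  sm <- running_mean_circular(inp, w)
  if (any(sm <= 0))
    stop("smoothed input contains zeros; supply a pseudocount ",
         "(argument `pseudocount`) or increase input depth")
  ratio <- m / sm
  z <- zscore_or_zeros(ratio)
  cov_track(z, genome_id = if (inherits(mnase, "cov_track")) mnase$genome_id
                           else "genome",
            size_class = if (inherits(mnase, "cov_track")) mnase$size_class
                         else "all",
            normalization = "input_normalized_z")
}

zscore_or_zeros <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(numeric(length(x)))
  (x - mean(x)) / s
}

#' Self-normalization against a smoothed copy of the same track
#'
#' Used when no sonicated input is available: the track is divided by its
#' own 250 kb smoothed trend and Z-scored. With a smoothing window at or
#' above the genome length this reduces to global-mean normalization.
#'
#' @inheritParams normalize_by_input
#' @param track \code{cov_track} to normalize
#' @export
self_normalize <- function(track, smooth_window = 250000L,
                           pseudocount = NULL) {
  out <- normalize_by_input(track, track, smooth_window = smooth_window,
                            pseudocount = pseudocount)
  out$normalization <- "self_normalized"
  out
}

#' Optional extreme-coverage capping
#'
#' Caps raw per-base values at an upper quantile (used in the source study
#' for the H. volcanii data, thresholded at the last percentile). Off by
#' default throughout the pipeline.
#'
#' @param track raw \code{cov_track}
#' @param cap_percentile upper percentile, e.g. 99
#' @export
cap_coverage <- function(track, cap_percentile = 99) {
  v <- track_values(track)
  cap <- stats::quantile(v, cap_percentile / 100, names = FALSE)
  as_cov_track(pmin(v, cap), template = track,
               normalization = track$normalization)
}

#' Coverage correlation across fragment-length bins
#'
#' Spearman correlation matrix of genome-wide raw (non-RPGC) coverage
#' computed separately for reads in each length bin, at base-pair
#' resolution.
#'
#' @param fragments fragment table
#' @param genome \code{hta_genome}
#' @param length_bins list of inclusive \code{c(lo, hi)} length ranges
#' @return symmetric matrix of Spearman rho (NA rows for empty bins)
#' @export
length_correlation_matrix <- function(fragments, genome, length_bins) {
  if (length(length_bins) < 2L) stop("need at least 2 length bins")
  labs <- vapply(length_bins, function(b) paste(b, collapse = "-"), "")
  covs <- lapply(length_bins, function(b)
    track_values(compute_coverage(fragments, genome, size_class = b)))
  empty <- vapply(covs, function(v) all(v == 0), TRUE)
  if (any(empty))
    warning("empty length bin(s): ", paste(labs[empty], collapse = ","))
  k <- length(covs)
  m <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in i:k) {
    if (!empty[i] && !empty[j])
      m[i, j] <- m[j, i] <- stats::cor(covs[[i]], covs[[j]],
                                       method = "spearman")
  }
  m
}

#' Site-relative coverage aggregation
#'
#' Median (or mean) track value at each offset in [-flank, +flank] across a
#' set of stranded sites (e.g. TSSs); windows of minus-strand sites are
#' reversed so that positive offsets always point downstream.
#'
#' @param track \code{cov_track}
#' @param sites data.frame with columns position (0-based) and strand
#'   ("+"/"-"); unstranded sites (".") are rejected
#' @param flank half-window, bp
#' @param statistic "median" or "mean"
#' @param circular wrap windows around the origin (default); if FALSE,
#'   out-of-genome positions are excluded per site
#' @return data.frame(offset, value, n_sites)
#' @export
aggregate_around_sites <- function(track, sites, flank,
                                   statistic = c("median", "mean"),
                                   circular = TRUE) {
  statistic <- match.arg(statistic)
  if (nrow(sites) == 0L) stop("no sites supplied")
  if (any(sites$strand == "."))
    stop("unstranded sites ('.') cannot be used for oriented aggregation")
  v <- track_values(track)
  n <- length(v)
  offs <- seq.int(-flank, flank)
  mat <- matrix(NA_real_, nrow(sites), length(offs))
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    idx <- p + offs               # 0-based genome positions
    if (circular) {
      mat[i, ] <- v[(idx %% n) + 1L]
    } else {
      ok <- idx >= 0L & idx < n
      mat[i, ok] <- v[idx[ok] + 1L]
    }
    if (sites$strand[i] == "-") mat[i, ] <- rev(mat[i, ])
  }
  fun <- if (statistic == "median") function(x) stats::median(x, na.rm = TRUE)
         else function(x) mean(x, na.rm = TRUE)
  data.frame(offset = offs,
             value = apply(mat, 2L, fun),
             n_sites = colSums(!is.na(mat)))
}
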