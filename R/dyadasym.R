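#' Orient broad peaks by small-fragment dyad asymmetry
#'
#' For each peak, the mean small-fragment coverage left of the dyad (a,
#' over \code{[center - half_width, center)}) and right of it (b, over
#' \code{[center, center + half_width)}) are compared; a peak with
#' \code{a/b < 1} is flagged flipped, so that after re-orientation the
#' small-fragment-rich side always lies on the same side of the dyad.
#' Ties (a = b), and peaks with no small coverage at all, are not flipped;
#' b = 0 with a > 0 gives ratio +Inf (not flipped).
#'
#' @param peaks peak table from \code{\link{detect_peaks}}
#' @param small_track small-fragment \code{cov_track}
#' @param half_width averaging span either side of the dyad, bp; default
#'   half the peak extent
#' @return the peak table with columns a, b, ratio, flipped added and
#'   orientation set to "as_is"/"flipped"
#' @export
orient_peaks <- function(peaks, small_track, half_width = NULL) {
  v <- track_values(small_track)
  n <- length(v)
  m <- nrow(peaks)
  a <- b <- numeric(m)
  for (i in seq_len(m)) {
    hw <- if (is.null(half_width)) max(1L, peaks$width[i] %/% 2L)
          else as.integer(half_width)
    c0 <- peaks$center[i]
    a[i] <- mean(v[circ_index(seq.int(c0 - hw, c0 - 1L) + 1L, n)])
    b[i] <- mean(v[circ_index(seq.int(c0, c0 + hw - 1L) + 1L, n)])
  }
  ratio <- ifelse(b > 0, a / b, ifelse(a > 0, Inf, NA_real_))
  flipped <- !is.na(ratio) & ratio < 1
  out <- peaks
  out$a <- a; out$b <- b; out$ratio <- ratio; out$flipped <- flipped
  out$orientation <- ifelse(flipped, "flipped", "as_is")
  out
}

#' Orient a single peak
#' @inheritParams orient_peaks
#' @param peak one-row peak table (or list with center and width)
#' @export
orient_peak <- function(peak, small_track, half_width = NULL) {
  pk <- as.data.frame(peak)
  orient_peaks(pk, small_track, half_width = half_width)
}

#' Re-oriented aggregate coverage around peak dyads
#'
#' Extracts the \code{[-flank, +flank]} track window around every peak
#' dyad, reverses the windows of flipped peaks, and returns the
#' elementwise mean profile.
#'
#' @param peaks oriented peak table (see \code{\link{orient_peaks}})
#' @param track \code{cov_track} to aggregate
#' @param flank half-window, bp
#' @return data.frame(offset, value)
#' @export
reoriented_aggregate <- function(peaks, track, flank) {
  if (nrow(peaks) == 0L) stop("no peaks to aggregate")
  if (!all(peaks$orientation %in% c("as_is", "flipped")))
    stop("orientations must be set; run orient_peaks() first")
  v <- track_values(track)
  n <- length(v)
  offs <- seq.int(-flank, flank)
  mat <- matrix(NA_real_, nrow(peaks), length(offs))
  for (i in seq_len(nrow(peaks))) {
    w <- v[circ_index(peaks$center[i] + offs + 1L, n)]
    if (peaks$orientation[i] == "flipped") w <- rev(w)
    mat[i, ] <- w
  }
  data.frame(offset = offs, value = colMeans(mat))
}

#' Fragment-length versus position occupancy matrix
#'
#' Counts of fragments, binned by fragment length (rows) and by the signed
#' offset of the fragment dyad from a reference point (columns). Offsets
#' of minus-strand or flipped reference points are sign-reversed. Built
#' from non-normalized fragments; cells are raw counts, so the matrix
#' total equals the number of contributing (in-range) fragment-reference
#' pairs.
#'
#' @param fragments fragment table
#' @param reference_points data.frame with column \code{position} (0-based)
#'   and either \code{strand} ("+"/"-") or \code{orientation}
#'   ("as_is"/"flipped"); a peak table from \code{\link{orient_peaks}}
#'   works directly (its \code{center} is used as position)
#' @param flank maximum absolute offset, bp
#' @param length_range inclusive fragment-length range, within [20, 200]
#' @param genome_length_bp genome length for circular offsets
#' @return integer matrix, rownames = lengths, colnames = offsets
#' @export
length_position_matrix <- function(fragments, reference_points, flank,
                                   length_range = c(20L, 200L),
                                   genome_length_bp) {
  stopifnot(length_range[1] >= 20L, length_range[2] <= 200L)
  pos <- reference_points$position %||% reference_points$center
  revd <- if (!is.null(reference_points$orientation))
    reference_points$orientation == "flipped"
  else if (!is.null(reference_points$strand))
    reference_points$strand == "-"
  else rep(FALSE, length(pos))
  lens <- seq.int(length_range[1], length_range[2])
  offs <- seq.int(-flank, flank)
  m <- matrix(0L, length(lens), length(offs),
              dimnames = list(lens, offs))
  keep <- fragments$length >= length_range[1] &
          fragments$length <= length_range[2]
  fr <- fragments[keep, , drop = FALSE]
  if (nrow(fr) == 0L || length(pos) == 0L) return(m)
  dy <- fragment_dyads(fr)
  n <- genome_length_bp
  for (j in seq_along(pos)) {
    d <- (dy - pos[j]) %% n
    d[d > n / 2] <- d[d > n / 2] - n      # signed circular offset
    if (revd[j]) d <- -d
    inr <- which(abs(d) <= flank)
    if (!length(inr)) next
    li <- fr$length[inr] - length_range[1] + 1L
    oi <- d[inr] + flank + 1L
    for (k in seq_along(inr)) m[li[k], oi[k]] <- m[li[k], oi[k]] + 1L
  }
  m
}

#' Write an orientation table as TSV
#' @param peaks oriented peak table
#' @param path output file
#' @export
write_orientation_tsv <- function(peaks, path) {
  utils::write.table(
    data.frame(peak_id = seq_len(nrow(peaks)), center = peaks$center,
               a = peaks$a, b = peaks$b, ratio = peaks$ratio,
               flipped = peaks$flipped),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a length-position matrix as TSV
#' @param m matrix from \code{\link{length_position_matrix}}
#' @param path output file
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(length = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
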