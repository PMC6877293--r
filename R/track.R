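#' Coverage track
#'
#' A per-base-pair numeric vector aligned to a genome, tagged with the
#' fragment size class it was computed from and its normalization state.
#'
#' @param values numeric vector, one value per genome position
#' @param genome_id chromosome/genome identifier the track is aligned to
#' @param size_class one of \code{"small"}, \code{"large"}, \code{"all"}, or
#'   a custom label such as \code{"70-80"}
#' @param normalization one of \code{"raw"}, \code{"RPGC"},
#'   \code{"input_normalized_z"}, \code{"self_normalized"}, or another label
#'   describing how the values were derived (e.g. \code{"occupancy"},
#'   \code{"predicted"}, \code{"filtered"})
#' @return an object of class \code{cov_track}
#' @export
cov_track <- function(values, genome_id = "genome", size_class = "all",
                      normalization = "raw") {
  stopifnot(is.numeric(values), length(values) > 0L)
  if (normalization == "raw" && any(values < 0, na.rm = TRUE))
    stop("raw coverage values must be non-negative")
  structure(list(values = as.numeric(values), genome_id = genome_id,
                 size_class = size_class, normalization = normalization),
            class = "cov_track")
}

#' @export
print.cov_track <- function(x, ...) {
  v <- x$values
  cat(sprintf("<cov_track> %s [%s, %s]: %d bp, mean %.4g, sd %.4g\n",
              x$genome_id, x$size_class, x$normalization, length(v),
              mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE)))
  invisible(x)
}

#' Extract the per-bp values of a coverage track
#' @param track a \code{cov_track} (a bare numeric vector is passed through)
#' @export
track_values <- function(track) {
  if (inherits(track, "cov_track")) track$values else as.numeric(track)
}

track_length <- function(track) length(track_values(track))

as_cov_track <- function(x, template = NULL, ...) {
  if (inherits(x, "cov_track")) return(x)
  if (!is.null(template))
    cov_track(x, genome_id = template$genome_id,
              size_class = template$size_class, ...)
  else cov_track(x, ...)
}
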