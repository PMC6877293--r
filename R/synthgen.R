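#' Genome specification for the synthetic generator
#'
#' Describes a circular genome with spatially varying GC content as a set of
#' segments tiling \code{[0, length)}, each with its own target GC fraction.
#'
#' @param length genome length, bp
#' @param gc_profile data.frame(start, end, gc) of 0-based half-open
#'   segments tiling the genome; or a single GC fraction applied genome-wide
#' @param circular logical
#' @param seed integer seed
#' @export
genome_spec <- function(length, gc_profile = 0.46, circular = TRUE,
                        seed = 1L) {
  length <- as.integer(length)
  stopifnot(length > 0L)
  if (is.numeric(gc_profile) && !is.data.frame(gc_profile)) {
    stopifnot(length(gc_profile) == 1L)
    gc_profile <- data.frame(start = 0L, end = length, gc = gc_profile)
  }
  gp <- gc_profile[order(gc_profile$start), , drop = FALSE]
  if (any(gp$gc < 0 | gp$gc > 1)) stop("gc fractions must be in [0,1]")
  if (gp$start[1] != 0L || gp$end[nrow(gp)] != length ||
      (nrow(gp) > 1L && any(gp$start[-1] != gp$end[-nrow(gp)])))
    stop("gc_profile segments must tile [0, length) without gaps or overlap")
  structure(list(length = length, gc_profile = gp,
                 circular = isTRUE(circular), seed = as.integer(seed)),
            class = "genome_spec")
}

#' Generate a synthetic genome
#'
#' Bases are drawn i.i.d. within each GC segment with
#' P(G) = P(C) = gc/2 and P(A) = P(T) = (1-gc)/2. Reproducible given the
#' spec's seed.
#'
#' @param spec a \code{\link{genome_spec}}
#' @param id genome identifier
#' @return an \code{hta_genome}
#' @export
generate_genome <- function(spec, id = "synthetic") {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    parts <- vapply(seq_len(nrow(spec$gc_profile)), function(i) {
      seg <- spec$gc_profile[i, ]
      m <- seg$end - seg$start
      p <- c(A = (1 - seg$gc) / 2, C = seg$gc / 2,
             G = seg$gc / 2, T = (1 - seg$gc) / 2)
      paste(sample(names(p), m, replace = TRUE, prob = p), collapse = "")
    }, "")
    hta_genome(paste(parts, collapse = ""), id = id,
               circular = spec$circular)
  })
}

#' Planted k-mer occupancy model
#'
#' Ground-truth generative model for the sequence-encoded occupancy
#' landscape: per-bp occupancy is an affine function of windowed k-mer
#' frequencies, mirroring the structure the k-mer LASSO is meant to
#' recover.
#'
#' @param kmer_weights named numeric vector, names are k-mers (k <= 4)
#' @param window odd window, bp
#' @param intercept baseline occupancy
#' @export
planted_occupancy_model <- function(kmer_weights, window = 51L,
                                    intercept = 0) {
  stopifnot(is.numeric(kmer_weights), !is.null(names(kmer_weights)),
            all(nchar(names(kmer_weights)) <= 4L),
            window %% 2L == 1L, window > 0L)
  if (!all(grepl("^[ACGT]+$", names(kmer_weights))))
    stop("k-mers must be over {A,C,G,T}")
  structure(list(kmer_weights = kmer_weights, window = as.integer(window),
                 intercept = intercept),
            class = "planted_occupancy_model")
}

#' Plant an occupancy landscape on a genome
#'
#' Per-bp value: intercept + sum over k-mers of
#' weight * windowed frequency, computed on circular windows. If any value
#' is negative the whole track is shifted up so its minimum is zero
#' (occupancy is a non-negative sampling intensity).
#'
#' @param genome \code{hta_genome}
#' @param model \code{\link{planted_occupancy_model}}
#' @return \code{cov_track} with normalization \code{"occupancy"}
#' @export
plant_occupancy <- function(genome, model) {
  stopifnot(inherits(model, "planted_occupancy_model"))
  if (model$window > genome_length(genome))
    stop("window exceeds genome length")
  v <- rep(model$intercept, genome_length(genome))
  for (km in names(model$kmer_weights))
    v <- v + model$kmer_weights[[km]] *
      kmer_window_frequency(genome, km, model$window)
  mn <- min(v, na.rm = TRUE)
  if (mn < 0) v <- v - mn
  cov_track(v, genome_id = genome$id, size_class = "all",
            normalization = "occupancy")
}

#' Fragment length-mixture specification
#'
#' The bimodal protected-fragment length distribution: a two-component
#' mixture of discretised Gaussians truncated to [20, 200] bp, with modes
#' near 50 bp (minimal footprints) and 85 bp (extended footprints).
#'
#' @param small_mode,large_mode component modes, bp (within [20, 200])
#' @param small_sd,large_sd component standard deviations, bp
#' @param p_small mixture weight of the small component
#' @param n_fragments number of fragments to emit
#' @param duplicate_rate fraction of emitted fragments that are exact
#'   coordinate copies of other emitted fragments (PCR-duplicate structure)
#' @param seed integer seed
#' @export
fragment_mixture_spec <- function(small_mode = 50L, large_mode = 85L,
                                  small_sd = 5, large_sd = 6,
                                  p_small = 0.45, n_fragments = 1e5,
                                  duplicate_rate = 0.05, seed = 1L) {
  stopifnot(p_small >= 0, p_small <= 1,
            small_mode >= 20, small_mode <= 200,
            large_mode >= 20, large_mode <= 200,
            duplicate_rate >= 0, duplicate_rate < 1)
  structure(list(small_mode = small_mode, large_mode = large_mode,
                 small_sd = small_sd, large_sd = large_sd,
                 p_small = p_small, n_fragments = as.integer(n_fragments),
                 duplicate_rate = duplicate_rate, seed = as.integer(seed)),
            class = "fragment_mixture_spec")
}

#' Replication copy-number gradient specification
#'
#' Exponentially growing cells carry more copies of early-replicating DNA;
#' the per-bp copy-number multiplier decays linearly with circular distance
#' from the origin, from \code{max_ratio} at the origin to 1 at the
#' terminus.
#'
#' @param origin origin position, bp (0-based)
#' @param max_ratio copy number at the origin relative to the terminus
#' @export
replication_gradient_spec <- function(origin, max_ratio = 2) {
  stopifnot(max_ratio >= 1, origin >= 0)
  structure(list(origin = as.integer(origin), max_ratio = max_ratio),
            class = "replication_gradient_spec")
}

#' Copy-number multiplier track of a replication gradient
#' @param gradient \code{\link{replication_gradient_spec}}
#' @param genome_length_bp genome length
#' @export
gradient_multiplier <- function(gradient, genome_length_bp) {
  if (gradient$origin >= genome_length_bp) stop("origin outside genome")
  p <- seq_len(genome_length_bp) - 1L
  d <- abs(p - gradient$origin)
  d <- pmin(d, genome_length_bp - d)       # circular distance
  dmax <- genome_length_bp / 2
  1 + (gradient$max_ratio - 1) * (1 - d / dmax)
}

# draw mixture lengths, discretised + truncated to [20,200]
draw_mixture_lengths <- function(m, mix) {
  comp_small <- runif(m) < mix$p_small
  len <- integer(m)
  len[comp_small] <- round(rnorm(sum(comp_small), mix$small_mode, mix$small_sd))
  len[!comp_small] <- round(rnorm(sum(!comp_small), mix$large_mode, mix$large_sd))
  bad <- which(len < 20L | len > 200L)
  while (length(bad)) {
    redraw_small <- comp_small[bad]
    len[bad[redraw_small]] <- round(rnorm(sum(redraw_small),
                                          mix$small_mode, mix$small_sd))
    len[bad[!redraw_small]] <- round(rnorm(sum(!redraw_small),
                                           mix$large_mode, mix$large_sd))
    bad <- bad[len[bad] < 20L | len[bad] > 200L]
  }
  len
}

#' Sample protected fragments from an occupancy landscape
#'
#' Fragment centres are drawn with probability proportional to
#' occupancy x replication-gradient multiplier; lengths come from the
#' bimodal mixture; a \code{duplicate_rate} fraction of the output are exact
#' coordinate copies of other sampled fragments. Exactly
#' \code{mix$n_fragments} records are returned. Coordinates are 0-based
#' half-open; fragments spanning the origin keep end > genome length.
#'
#' @param occupancy non-negative \code{cov_track} (not all zero)
#' @param mix \code{\link{fragment_mixture_spec}}
#' @param gradient optional \code{\link{replication_gradient_spec}}
#' @param chrom chromosome name for the emitted records
#' @return fragment table (see \code{\link{fragments_df}})
#' @export
sample_fragments <- function(occupancy, mix, gradient = NULL,
                             chrom = NULL) {
  stopifnot(inherits(mix, "fragment_mixture_spec"))
  v <- track_values(occupancy)
  if (any(v < 0, na.rm = TRUE)) stop("occupancy must be non-negative")
  v[is.na(v)] <- 0
  if (all(v == 0)) stop("occupancy is all zero; nothing to sample")
  n <- length(v)
  w <- v
  if (!is.null(gradient)) w <- w * gradient_multiplier(gradient, n)
  chrom <- chrom %||%
    (if (inherits(occupancy, "cov_track")) occupancy$genome_id else "genome")
  with_seed(mix$seed, {
    ntot <- mix$n_fragments
    ndup <- round(mix$duplicate_rate * ntot)
    nfresh <- ntot - ndup
    centers <- sample_prob_int(n, nfresh, w) - 1L      # 0-based
    len <- draw_mixture_lengths(nfresh, mix)
    start <- (centers - len %/% 2L) %% n
    end <- start + len
    if (ndup > 0L) {
      src <- sample.int(nfresh, ndup, replace = TRUE)
      start <- c(start, start[src]); end <- c(end, end[src])
    }
    fragments_df(chrom, start, end)
  })
}

#' Sample broad footprints with edge-aligned small fragments
#'
#' Emulates the nucleation-extension footprint geometry: each nucleation
#' site emits large fragments centred on the site and small fragments whose
#' centres sit at one edge of the large footprint. The site's preferred
#' edge (+1 = right, -1 = left) is chosen once per site and each small
#' fragment lands on it with probability \code{edge_bias}. The per-site
#' preferred edge is recorded in the \code{"truth"} attribute for
#' validation against re-orientation calls.
#'
#' @param nucleation_sites 0-based site positions
#' @param n_per_site number of large (and of small) fragments per site
#' @param small_len,large_len fragment lengths, bp
#' @param edge_bias probability in [0.5, 1] that a small fragment sits on
#'   the site's preferred edge
#' @param genome_length_bp genome length for circular wrapping
#' @param seed integer seed
#' @param chrom chromosome name
#' @return fragment table with attribute \code{truth}
#'   (data.frame(site, preferred_edge))
#' @export
sample_broad_footprints <- function(nucleation_sites, n_per_site,
                                    small_len = 50L, large_len = 84L,
                                    edge_bias = 0.9, genome_length_bp,
                                    seed = 1L, chrom = "synthetic") {
  stopifnot(edge_bias >= 0.5, edge_bias <= 1)
  with_seed(seed, {
    sites <- as.integer(nucleation_sites)
    pref <- sample(c(-1L, 1L), length(sites), replace = TRUE)
    offset <- (large_len - small_len) %/% 2L
    frs <- list()
    for (i in seq_along(sites)) {
      if (n_per_site < 1L) next
      s <- sites[i]
      lc <- rep(s, n_per_site)
      side <- ifelse(runif(n_per_site) < edge_bias, pref[i], -pref[i])
      sc <- s + side * offset
      centers <- c(lc, sc)
      lens <- c(rep(large_len, n_per_site), rep(small_len, n_per_site))
      start <- (centers - lens %/% 2L) %% genome_length_bp
      frs[[i]] <- data.frame(start = start, end = start + lens)
    }
    truth <- data.frame(site = sites, preferred_edge = pref)
    if (length(frs) == 0L) {
      out <- fragments_df(character(), integer(), integer())[0, ]
    } else {
      all <- do.call(rbind, frs)
      out <- fragments_df(chrom, all$start, all$end)
    }
    attr(out, "truth") <- truth
    out
  })
}

#' Write planted-truth sidecar metadata
#' @param truth a truth data.frame (e.g. the \code{truth} attribute of
#'   \code{\link{sample_broad_footprints}})
#' @param path output TSV
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
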