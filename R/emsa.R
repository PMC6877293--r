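#' EMSA oligo-library design
#'
#' A band-shift library is built from a small set of 100 bp backbone
#' sequences, each diversified by eight randomized dinucleotides at defined,
#' non-overlapping positions. Randomized slots are written as \code{NN} in
#' the backbone sequence; all other positions are fixed and used for read
#' assignment.
#'
#' @param backbones data.frame(id, sequence) with \code{NN} at randomized
#'   slots
#' @param randomized_positions list (per backbone) of eight 0-based
#'   dinucleotide start offsets
#' @param planted_affinity named numeric vector of composition-feature
#'   weights used by the pool generator; recognised names:
#'   \code{"intercept"}, \code{"GpC"} (count of the GC dinucleotide step),
#'   \code{"GC_content"} (fraction G+C of the full oligo)
#' @export
emsa_design <- function(backbones, randomized_positions,
                        planted_affinity = c(intercept = 0)) {
  stopifnot(is.data.frame(backbones), all(c("id", "sequence") %in%
                                          names(backbones)),
            length(randomized_positions) == nrow(backbones))
  backbones$sequence <- toupper(backbones$sequence)
  L <- unique(nchar(backbones$sequence))
  if (length(L) != 1L) stop("all backbones must have equal length")
  for (i in seq_len(nrow(backbones))) {
    rp <- sort(as.integer(randomized_positions[[i]]))
    if (length(rp) != 8L) stop("each backbone needs exactly 8 randomized dinucleotides")
    if (any(rp < 0L) || any(rp > L - 2L))
      stop("randomized position outside backbone ", backbones$id[i])
    if (any(diff(rp) < 2L))
      stop("randomized dinucleotides overlap in backbone ", backbones$id[i])
    randomized_positions[[i]] <- rp
    ch <- strsplit(backbones$sequence[i], "")[[1]]
    slot_idx <- as.vector(outer(1:2, rp, function(a, b) a + b))
    if (!all(ch[slot_idx] == "N"))
      stop("backbone ", backbones$id[i],
           " must carry N at randomized positions")
    if (any(ch[-slot_idx] == "N"))
      stop("backbone ", backbones$id[i], " has N outside randomized slots")
  }
  d <- structure(list(backbones = backbones,
                      randomized_positions = randomized_positions,
                      planted_affinity = planted_affinity,
                      oligo_length = L),
                 class = "emsa_design")
  check_design_unambiguous(d)
  d
}

# error if two backbones agree at every position fixed in both
check_design_unambiguous <- function(design) {
  b <- design$backbones
  n <- nrow(b)
  if (n < 2L) return(invisible(TRUE))
  chars <- lapply(b$sequence, function(s) strsplit(s, "")[[1]])
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both_fixed <- chars[[i]] != "N" & chars[[j]] != "N"
    if (all(chars[[i]][both_fixed] == chars[[j]][both_fixed]))
      stop("ambiguous design: backbones ", b$id[i], " and ", b$id[j],
           " are identical at all jointly fixed positions")
  }
  invisible(TRUE)
}

#' Random EMSA design helper
#'
#' Builds a design with \code{n_backbones} random backbones of 100 bp and
#' eight randomized dinucleotide slots at fixed offsets 10, 21, ..., 87.
#'
#' @param n_backbones number of backbones
#' @param gc GC fraction of the fixed backbone positions
#' @param planted_affinity see \code{\link{emsa_design}}
#' @param seed integer seed
#' @export
random_emsa_design <- function(n_backbones = 5L, gc = 0.46,
                               planted_affinity = c(intercept = 0),
                               seed = 1L) {
  slots <- as.integer(10 + 11 * (0:7))
  with_seed(seed, {
    seqs <- vapply(seq_len(n_backbones), function(i) {
      ch <- sample(c("A", "C", "G", "T"), 100, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
      ch[as.vector(outer(1:2, slots, `+`))] <- "N"
      paste(ch, collapse = "")
    }, "")
    emsa_design(data.frame(id = paste0("backbone", seq_len(n_backbones)),
                           sequence = seqs, stringsAsFactors = FALSE),
                rep(list(slots), n_backbones),
                planted_affinity = planted_affinity)
  })
}

count_gpc <- function(seqs) {
  (nchar(seqs) - nchar(gsub("GC", "", seqs, fixed = TRUE))) / 2L
}

gc_content <- function(seqs) {
  (nchar(gsub("[AT]", "", seqs))) / nchar(seqs)
}

emsa_slow_probability <- function(seqs, affinity) {
  eta <- rep(0, length(seqs))
  for (nm in names(affinity)) {
    eta <- eta + affinity[[nm]] * switch(nm,
      intercept = 1,
      GpC = count_gpc(seqs),
      GC_content = gc_content(seqs),
      stop("unknown affinity feature: ", nm))
  }
  stats::plogis(eta)
}

#' Generate a synthetic EMSA read pool
#'
#' Each read is a backbone (chosen uniformly) with its eight randomized
#' dinucleotides filled i.i.d. uniformly over the 16 dinucleotides. The read
#' is assigned to the slow (protein-bound) band with probability
#' logistic(sum of planted affinity x composition features). Exactly
#' \code{n_reads} reads are returned, together with a counts table and the
#' per-read truth (backbone and slow-probability).
#'
#' @param design \code{\link{emsa_design}}
#' @param n_reads number of reads
#' @param seed integer seed
#' @return list(reads = data.frame(sequence, band, backbone, p_slow),
#'   counts = per-(backbone, band) count table)
#' @export
generate_emsa_pool <- function(design, n_reads, seed = 1L) {
  stopifnot(inherits(design, "emsa_design"))
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  with_seed(seed, {
    bidx <- sample.int(nrow(design$backbones), n_reads, replace = TRUE)
    seqs <- character(n_reads)
    for (b in seq_len(nrow(design$backbones))) {
      sel <- which(bidx == b)
      if (!length(sel)) next
      rp <- design$randomized_positions[[b]]
      bb <- design$backbones$sequence[b]
      # fixed blocks between slots (0-based slot starts, slots are 2 bp)
      cuts <- c(0L, as.vector(rbind(rp, rp + 2L)), design$oligo_length)
      blocks <- substring(bb, head(cuts, -1) + 1L, cuts[-1])
      fixed_blocks <- blocks[seq(1, length(blocks), by = 2)]
      parts <- vector("list", length(blocks))
      parts[seq(1, length(blocks), by = 2)] <-
        lapply(fixed_blocks, rep, times = length(sel))
      for (s in seq_along(rp))
        parts[[2L * s]] <- dinucs[sample.int(16L, length(sel),
                                             replace = TRUE)]
      seqs[sel] <- do.call(paste0, parts)
    }
    p <- emsa_slow_probability(seqs, design$planted_affinity)
    band <- ifelse(runif(n_reads) < p, "slow", "fast")
    reads <- data.frame(sequence = seqs, band = band,
                        backbone = design$backbones$id[bidx],
                        p_slow = p, stringsAsFactors = FALSE)
    counts <- as.data.frame(table(backbone = reads$backbone,
                                  band = reads$band),
                            stringsAsFactors = FALSE)
    list(reads = reads, counts = counts)
  })
}

#' Assign EMSA reads to design backbones
#'
#' A read is assigned to the unique backbone whose fixed positions it
#' matches exactly; reads matching no backbone, more than one, or of the
#' wrong length are left unassigned. The eight randomized dinucleotides are
#' extracted for assigned reads.
#'
#' @param sequences character vector of read sequences
#' @param design \code{\link{emsa_design}}
#' @param band optional band label per read (carried through)
#' @return data.frame(sequence, band, backbone, dinucleotides) with
#'   NA backbone for unassigned reads; attribute \code{n_unassigned}
#' @export
assign_reads <- function(sequences, design, band = NA_character_) {
  stopifnot(inherits(design, "emsa_design"))
  sequences <- toupper(sequences)
  n <- length(sequences)
  B <- nrow(design$backbones)
  match_mat <- matrix(FALSE, n, B)
  len_ok <- nchar(sequences) == design$oligo_length
  for (b in seq_len(B)) {
    rp <- design$randomized_positions[[b]]
    cuts <- c(0L, as.vector(rbind(rp, rp + 2L)), design$oligo_length)
    starts <- head(cuts, -1) + 1L; ends <- cuts[-1]
    fixed <- seq(1, length(starts), by = 2)
    bb_fixed <- paste(substring(design$backbones$sequence[b],
                                starts[fixed], ends[fixed]), collapse = "")
    read_fixed <- rep("", n)
    for (f in fixed)
      read_fixed <- paste0(read_fixed,
                           substring(sequences, starts[f], ends[f]))
    match_mat[, b] <- len_ok & read_fixed == bb_fixed
  }
  hits <- rowSums(match_mat)
  assigned <- which(hits == 1L)
  backbone <- rep(NA_character_, n)
  dinucs <- rep(NA_character_, n)
  if (length(assigned)) {
    bsel <- max.col(match_mat[assigned, , drop = FALSE])
    backbone[assigned] <- design$backbones$id[bsel]
    for (b in seq_len(B)) {
      sel <- assigned[bsel == b]
      if (!length(sel)) next
      rp <- design$randomized_positions[[b]]
      dd <- rep("", length(sel))
      for (s in rp) dd <- paste0(dd, substring(sequences[sel], s + 1L, s + 2L))
      dinucs[sel] <- dd
    }
  }
  out <- data.frame(sequence = sequences,
                    band = rep_len(band, n),
                    backbone = backbone, dinucleotides = dinucs,
                    stringsAsFactors = FALSE)
  attr(out, "n_unassigned") <- n - length(assigned)
  out
}

#' P_slow per composition class
#'
#' Groups assigned reads by a composition value (integer-percent G+C
#' content of the full oligo, or GpC dinucleotide count) and reports, per
#' group, the proportion of reads found in the slow (protein-bound) band:
#' \code{p_slow = n_slow / (n_slow + n_fast)}. A per-backbone P_slow table
#' is attached as attribute \code{by_backbone}.
#'
#' @param assigned output of \code{\link{assign_reads}} with band labels in
#'   \{"slow","fast"\}
#' @param composition "GpC_count" or "GC_content"
#' @param exclude_backbones backbone ids dropped before grouping (e.g. an
#'   anomalously behaving AT-rich backbone)
#' @return data.frame(x, n_slow, n_fast, p_slow) sorted by x
#' @export
compute_pslow <- function(assigned, composition = c("GpC_count",
                                                    "GC_content"),
                          exclude_backbones = character()) {
  composition <- match.arg(composition)
  ok <- !is.na(assigned$backbone) &
    !(assigned$backbone %in% exclude_backbones) &
    assigned$band %in% c("slow", "fast")
  d <- assigned[ok, , drop = FALSE]
  if (nrow(d) == 0L) stop("no assigned reads left after exclusion")
  x <- switch(composition,
              GpC_count = count_gpc(d$sequence),
              GC_content = round(100 * gc_content(d$sequence)))
  tab_group <- function(key) {
    slow <- tapply(d$band == "slow", key, sum)
    tot <- tapply(rep(1L, nrow(d)), key, sum)
    data.frame(key = names(tot), n_slow = as.integer(slow),
               n_fast = as.integer(tot - slow),
               p_slow = as.numeric(slow / tot), row.names = NULL,
               stringsAsFactors = FALSE)
  }
  out <- tab_group(x)
  out$key <- as.numeric(out$key)
  names(out)[1] <- "x"
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  bb <- tab_group(d$backbone)
  names(bb)[1] <- "backbone"
  attr(out, "by_backbone") <- bb
  attr(out, "composition") <- composition
  out
}

#' Read-count-weighted Pearson correlation of a P_slow table
#'
#' r between composition value x and p_slow, each group weighted by its
#' total read count, mirroring point-size-weighted correlations of
#' band-sequencing figures.
#'
#' @param table output of \code{\link{compute_pslow}}
#' @param n_boot optional bootstrap resamples (over groups, weighted) for a
#'   95 percent CI; 0 disables
#' @param seed seed for the bootstrap
#' @return correlation (numeric scalar; with attribute \code{ci} if
#'   bootstrapped)
#' @export
weighted_correlation <- function(table, n_boot = 0L, seed = 1L) {
  if (nrow(table) < 3L) stop("need at least 3 composition groups")
  w <- table$n_slow + table$n_fast
  r <- weighted_pearson(table$x, table$p_slow, w)
  if (n_boot > 0L) {
    rs <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(nrow(table), replace = TRUE, prob = w)
      tryCatch(weighted_pearson(table$x[idx], table$p_slow[idx],
                                rep(1, length(idx))),
               error = function(e) NA_real_)
    }, 0))
    attr(r, "ci") <- stats::quantile(rs, c(0.025, 0.975), na.rm = TRUE,
                                     names = FALSE)
  }
  r
}

weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  if (sw <= 0) stop("non-positive total weight")
  xm <- sum(w * x) / sw; ym <- sum(w * y) / sw
  vx <- sum(w * (x - xm)^2); vy <- sum(w * (y - ym)^2)
  if (vx <= 0 || vy <= 0) stop("zero weighted variance")
  sum(w * (x - xm) * (y - ym)) / sqrt(vx * vy)
}

#' Write an EMSA design as TSV
#' @param design \code{\link{emsa_design}}
#' @param path output file
#' @export
write_emsa_design <- function(design, path) {
  off <- vapply(design$randomized_positions, paste, "", collapse = ",")
  utils::write.table(
    data.frame(backbone_id = design$backbones$id,
               sequence = design$backbones$sequence,
               randomized_offsets = off),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an EMSA design from TSV
#' @param path TSV with columns backbone_id, sequence, randomized_offsets
#' @param planted_affinity passed through to \code{\link{emsa_design}}
#' @export
read_emsa_design <- function(path, planted_affinity = c(intercept = 0)) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  emsa_design(data.frame(id = d$backbone_id, sequence = d$sequence,
                         stringsAsFactors = FALSE),
              lapply(strsplit(d$randomized_offsets, ","), as.integer),
              planted_affinity = planted_affinity)
}

#' Write EMSA reads as FASTA (one file per band)
#' @param reads data.frame(sequence, band)
#' @param dir output directory
#' @param prefix file prefix
#' @export
write_emsa_reads_fasta <- function(reads, dir, prefix = "emsa") {
  paths <- character(0)
  for (b in unique(reads$band)) {
    sel <- reads$band == b
    p <- file.path(dir, sprintf("%s_%s.fasta", prefix, b))
    writeLines(paste0(">read", which(sel), "\n", reads$sequence[sel]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read EMSA reads from FASTA files labelled by band
#' @param slow_path,fast_path FASTA files of the slow and fast bands
#' @export
read_emsa_reads_fasta <- function(slow_path, fast_path) {
  rd <- function(p, b) {
    ss <- Biostrings::readDNAStringSet(p)
    data.frame(sequence = as.character(ss), band = b,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rbind(rd(slow_path, "slow"), rd(fast_path, "fast"))
}
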