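#' Read a genome from a FASTA file
#'
#' The first (or named) record becomes an \code{hta_genome}. Parsing is done
#' by Biostrings; the sequence is uppercased.
#'
#' @param path FASTA file
#' @param id optional record name to select; default first record
#' @param circular logical circularity flag to attach
#' @export
read_genome_fasta <- function(path, id = NULL, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  i <- if (is.null(id)) 1L else match(id, names(ss))
  if (is.na(i)) stop("record ", id, " not found in ", path)
  nm <- sub("\\s.*$", "", names(ss)[i])
  hta_genome(as.character(ss[[i]]), id = nm, circular = circular)
}

#' Write a genome as FASTA
#' @param genome an \code{hta_genome}
#' @param path output file
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Construct a fragment table
#'
#' Canonical in-memory representation of mapped protected fragments:
#' 0-based half-open intervals. For circular genomes a fragment spanning the
#' origin keeps \code{end > genome length} and is normalised on write.
#'
#' @param chrom chromosome name(s)
#' @param start,end 0-based half-open coordinates
#' @param mean_quality optional per-fragment mean base quality
#' @return data.frame with columns chrom, start, end, length, mean_quality
#' @export
fragments_df <- function(chrom, start, end, mean_quality = NA_real_) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(start >= end)) stop("fragment start must be < end")
  len <- end - start
  if (any(len < 1L | len > 1000L)) stop("fragment lengths must be in [1,1000]")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             length = len,
             mean_quality = rep_len(as.numeric(mean_quality),
                                    length(start)),
             stringsAsFactors = FALSE)
}

#' Dyad positions of fragments
#'
#' The footprint centre: \code{floor((start+end)/2)}, i.e. the left-of-centre
#' base for even-length fragments. Applied uniformly across the package.
#' @param fragments a fragment table
#' @export
fragment_dyads <- function(fragments) {
  as.integer((fragments$start + fragments$end) %/% 2L)
}

#' Read mapped fragments from a BED file
#'
#' Accepts 3- to 6-column BED. Every line must parse; a malformed line
#' raises an error naming its line number. When a genome is supplied,
#' coordinates are validated against its bounds (for circular genomes the
#' end may extend up to one genome length past the origin).
#'
#' @param path BED file
#' @param genome optional \code{hta_genome} for bounds checking
#' @export
read_fragments_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(fragments_df(character(), integer(), integer())[0, ])
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("malformed BED line ", which(nf < 3L)[1], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("malformed BED line ", bad[1], ": non-integer coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop("invalid interval at BED line ", bad[1], ": start must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    n <- genome_length(genome)
    lim <- if (genome$circular) 2L * n else n
    bad <- which(start >= n | end > lim)
    if (length(bad))
      stop("record at BED line ", bad[1], " (", chrom[bad[1]], ":",
           start[bad[1]], "-", end[bad[1]], ") out of genome bounds")
  }
  fragments_df(chrom, start, end)
}

#' Write fragments as 6-column BED
#'
#' Name column carries the fragment size-class label, score is 0 and strand
#' "." (merged MNase fragments are unstranded). Records extending past the
#' origin of a circular genome are wrapped into two lines.
#'
#' @param fragments fragment table
#' @param path output file
#' @param genome optional genome; required to wrap origin-spanning records
#' @param bounds size-class bounds used for labelling, see
#'   \code{\link{size_class_bounds}}
#' @export
write_fragments_bed <- function(fragments, path, genome = NULL,
                                bounds = size_class_bounds()) {
  cls <- size_class_of(fragments$length, bounds)
  st <- fragments$start; en <- fragments$end; ch <- fragments$chrom
  if (!is.null(genome)) {
    n <- genome_length(genome)
    over <- en > n
    if (any(over)) {
      ch <- c(ch, ch[over]); cls <- c(cls, cls[over])
      st <- c(st, rep(0L, sum(over)))
      en2 <- en; en2[over] <- n
      en <- c(en2, fragments$end[over] - n)
    }
  }
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t.", ch, st, en, cls), path)
  invisible(path)
}

#' Write a coverage track as bedGraph or wiggle
#'
#' Adjacent equal values are run-length merged in bedGraph. Values are
#' printed with enough digits that a round trip reproduces them to 1e-6.
#'
#' @param track a \code{cov_track}
#' @param path output file
#' @param format "bedGraph" or "wiggle"
#' @export
write_track <- function(track, path, format = c("bedGraph", "wiggle")) {
  format <- match.arg(format)
  v <- track_values(track)
  if (length(v) == 0L) stop("cannot write a track of length 0")
  if (format == "bedGraph") {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    lines <- c("track type=bedGraph",
               sprintf("%s\t%d\t%d\t%.10g", track$genome_id, starts, ends,
                       r$values))
  } else {
    lines <- c(sprintf("fixedStep chrom=%s start=1 step=1", track$genome_id),
               sprintf("%.10g", v))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage track
#' @param path bedGraph file
#' @param genome_length_bp total track length (intervals must tile it is not
#'   required; uncovered positions become 0)
#' @param size_class,normalization metadata to attach
#' @export
read_track_bedgraph <- function(path, genome_length_bp, size_class = "all",
                                normalization = "raw") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  lines <- lines[nzchar(lines)]
  v <- numeric(genome_length_bp)
  gid <- "genome"
  if (length(lines)) {
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    if (any(nf != 4L)) stop("malformed bedGraph line ", which(nf != 4L)[1])
    gid <- f[[1]][1]
    st <- as.integer(vapply(f, `[[`, "", 2L))
    en <- as.integer(vapply(f, `[[`, "", 3L))
    val <- as.numeric(vapply(f, `[[`, "", 4L))
    if (anyNA(st) || anyNA(en) || anyNA(val)) stop("malformed bedGraph values")
    if (any(en > genome_length_bp)) stop("bedGraph interval beyond track length")
    for (i in seq_along(st)) v[(st[i] + 1L):en[i]] <- val[i]
  }
  cov_track(v, genome_id = gid, size_class = size_class,
            normalization = normalization)
}

#' Read site annotations (TSS and similar) from BED6 or GFF3
#'
#' Returns point annotations with 0-based positions. For GFF3, a feature on
#' the + strand contributes its start and a feature on the - strand its end
#' coordinate (the 5' end of the feature); GFF's 1-based closed coordinates
#' are converted at this boundary. For BED, the 5' end of the interval is
#' used. Duplicate gene ids are kept with a warning.
#'
#' @param path input file
#' @param format "BED" or "GFF"
#' @param kind annotation kind label (e.g. "TSS", "TES", "ATG")
#' @param feature_type for GFF, restrict to this feature type (default
#'   "gene"; NULL keeps all)
#' @return data.frame(chrom, position, strand, kind, gene_id)
#' @export
read_sites <- function(path, format = c("BED", "GFF"), kind = "TSS",
                       feature_type = "gene") {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), position = integer(),
                      strand = character(), kind = character(),
                      gene_id = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (format == "BED") {
    if (any(nf < 6L))
      stop("malformed BED line ", which(nf < 6L)[1],
           ": 6 columns required for stranded sites")
    chrom <- vapply(f, `[[`, "", 1L)
    start <- as.integer(vapply(f, `[[`, "", 2L))
    end <- as.integer(vapply(f, `[[`, "", 3L))
    gene_id <- vapply(f, `[[`, "", 4L)
    strand <- vapply(f, `[[`, "", 6L)
    pos <- ifelse(strand == "-", end - 1L, start)
  } else {
    if (any(nf < 9L))
      stop("malformed GFF line ", which(nf < 9L)[1], ": 9 columns required")
    type <- vapply(f, `[[`, "", 3L)
    keep <- if (is.null(feature_type)) rep(TRUE, length(f))
            else type == feature_type
    f <- f[keep]
    if (length(f) == 0L) stop("no features of type ", feature_type)
    chrom <- vapply(f, `[[`, "", 1L)
    start1 <- as.integer(vapply(f, `[[`, "", 4L))
    end1 <- as.integer(vapply(f, `[[`, "", 5L))
    strand <- vapply(f, `[[`, "", 7L)
    attrs <- vapply(f, `[[`, "", 9L)
    gene_id <- sub(".*(?:^|;)\\s*(?:ID|gene_id|locus_tag)=([^;]+).*", "\\1",
                   attrs)
    pos <- ifelse(strand == "-", end1 - 1L, start1 - 1L)
  }
  if (!all(strand %in% c("+", "-", ".")))
    stop("invalid strand field: ", strand[!strand %in% c("+", "-", ".")][1])
  if (anyDuplicated(gene_id))
    warning("duplicate gene_id(s): ",
            paste(unique(gene_id[duplicated(gene_id)]), collapse = ","),
            " (all kept)")
  data.frame(chrom = chrom, position = as.integer(pos), strand = strand,
             kind = kind, gene_id = gene_id, stringsAsFactors = FALSE)
}
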