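#' Demo run configuration for the synthetic end-to-end pipeline
#'
#' A compact, fully synthetic dataset exercising every stage: a 20 kb
#' circular genome with a GC gradient, a planted k-mer occupancy
#' landscape, a bimodal fragment pool with a 2:1 replication gradient, a
#' uniform sonicated input, and a small k-mer model fit. Sizes are chosen
#' so a full run takes seconds while every downstream statistic is well
#' populated.
#'
#' @param seed master integer seed; every stage derives its own stream
#' @export
demo_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    genome_length = 20000L,
    gc = 0.46,
    planted = planted_occupancy_model(
      c(GC = 6, TA = -4, CAG = 5), window = 51L, intercept = 1),
    n_fragments = 60000L,
    n_input_fragments = 60000L,
    gradient = replication_gradient_spec(origin = 0L, max_ratio = 2),
    input_smooth_window = 2001L,
    peak_config = peak_call_config(keep_component_fraction = 0.02,
                                   score_threshold = 2.5),
    model_kmers = all_kmers(1:2),
    model_top_n = 10L,
    profile_length = 50L,
    flank = 200L
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Composes the package's stages in order: genome generation, occupancy
#' planting, fragment and input sampling, size-resolved coverage, RPGC and
#' input normalization, Fourier-filtered peak calling, broad-peak
#' re-orientation, dinucleotide profiling, and the k-mer LASSO model with
#' held-out evaluation. All intermediates are written as plain-text files
#' (FASTA/BED/bedGraph/TSV/JSON) under \code{out_dir}, and the run is a
#' pure function of the configuration seed.
#'
#' @param config list from \code{\link{demo_run_config}}
#' @param out_dir output directory (created if needed)
#' @param quiet suppress progress messages
#' @return invisible list with the main in-memory results
#' @export
run_full_analysis <- function(config = demo_run_config(), out_dir,
                              quiet = FALSE) {
  stopifnot(is.list(config), !is.null(config$seed))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage genome: length=%d gc=%.2f seed=%d", config$genome_length,
      config$gc, config$seed)
  gspec <- genome_spec(config$genome_length, config$gc,
                       seed = derive_seed(config$seed, "genome"))
  genome <- generate_genome(gspec)
  write_genome_fasta(genome, file.path(out_dir, "genome.fasta"))

  occupancy <- plant_occupancy(genome, config$planted)
  write_track(occupancy, file.path(out_dir, "occupancy.bedGraph"))

  say("stage fragments: n=%d (+input %d)", config$n_fragments,
      config$n_input_fragments)
  mix <- fragment_mixture_spec(n_fragments = config$n_fragments,
                               seed = derive_seed(config$seed, "fragments"))
  fragments <- sample_fragments(occupancy, mix, gradient = config$gradient)
  write_fragments_bed(fragments, file.path(out_dir, "fragments.bed"),
                      genome = genome)
  flat <- cov_track(rep(1, config$genome_length), genome_id = genome$id)
  imix <- fragment_mixture_spec(small_mode = 150, large_mode = 150,
                                small_sd = 30, large_sd = 30, p_small = 0.5,
                                n_fragments = config$n_input_fragments,
                                duplicate_rate = 0,
                                seed = derive_seed(config$seed, "input"))
  input_fr <- sample_fragments(flat, imix, gradient = config$gradient)
  write_fragments_bed(input_fr, file.path(out_dir, "input.bed"),
                      genome = genome)

  say("stage coverage + normalization")
  cov_all <- compute_coverage(fragments, genome, "all")
  cov_small <- compute_coverage(fragments, genome, "small")
  cov_large <- compute_coverage(fragments, genome, "large")
  cov_input <- compute_coverage(input_fr, genome, "all")
  rpgc <- rpgc_normalize(cov_all,
                         effective_genome_size = config$genome_length)
  write_track(rpgc, file.path(out_dir, "coverage_all_rpgc.bedGraph"))
  norm <- normalize_by_input(cov_all, cov_input,
                             smooth_window = config$input_smooth_window)
  norm_small <- normalize_by_input(cov_small, cov_input,
                                   smooth_window = config$input_smooth_window)
  write_track(norm, file.path(out_dir, "coverage_all_normalized.bedGraph"))

  say("stage peaks: keep_fraction=%.3g threshold=%.2f",
      config$peak_config$keep_component_fraction,
      config$peak_config$score_threshold)
  filt <- fourier_filter(norm, config$peak_config$keep_component_fraction)
  peaks <- detect_peaks(filt, norm, config$peak_config)
  broad <- peaks[!is.na(peaks$width_class) & peaks$width_class == "broad", ,
                 drop = FALSE]
  if (nrow(broad)) {
    broad <- orient_peaks(broad, cov_small)
    write_orientation_tsv(broad, file.path(out_dir, "orientation.tsv"))
    agg <- reoriented_aggregate(broad, cov_small, flank = config$flank)
    write_profile_tsv(agg, file.path(out_dir, "reoriented_small.tsv"))
  }
  write_peaks_bed(peaks, file.path(out_dir, "peaks.bed"))

  say("stage profiles")
  kept <- filter_reads(fragments, peaks,
                       genome_length_bp = config$genome_length)
  prof <- NULL
  modal <- config$profile_length
  frag_L <- kept[kept$length == modal, , drop = FALSE]
  if (nrow(frag_L) >= 10L) {
    prof <- rbind(positional_class_profile(frag_L, genome, "SS"),
                  positional_class_profile(frag_L, genome, "WW"))
    write_profile_tsv(prof, file.path(out_dir, "dinucleotide_profile.tsv"))
  }

  say("stage kmer model: %d candidate kmers, top %d",
      length(config$model_kmers), config$model_top_n)
  sel <- select_features(norm_small, genome, kmers = config$model_kmers,
                         top_n = config$model_top_n)
  model <- fit_lasso(norm_small, genome, sel)
  write_model_json(model, file.path(out_dir, "model.json"))
  pred <- predict_coverage(model, genome)
  rho <- list(
    trained = evaluate_prediction(pred, norm_small, "trained"),
    untrained = evaluate_prediction(pred, norm_small, "untrained"))
  report <- list(
    seed = config$seed,
    n_fragments = nrow(fragments),
    n_peaks = nrow(peaks),
    n_broad = nrow(broad),
    n_narrow = sum(!is.na(peaks$width_class) &
                   peaks$width_class == "narrow"),
    rho_trained = rho$trained,
    rho_untrained = rho$untrained)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: %d peaks (%d broad), rho untrained=%.3f", report$n_peaks,
      report$n_broad, report$rho_untrained)
  invisible(list(genome = genome, occupancy = occupancy,
                 fragments = fragments, peaks = peaks, broad = broad,
                 model = model, prediction = pred, report = report))
}
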