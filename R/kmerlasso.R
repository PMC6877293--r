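#' All k-mers of the given sizes
#' @param ks integer vector of k values (1 to 4)
#' @export
all_kmers <- function(ks = 1:4) {
  stopifnot(all(ks >= 1L), all(ks <= 4L))
  unlist(lapply(ks, function(k) {
    do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                stringsAsFactors = FALSE)[, k:1, drop = FALSE])
  }))
}

#' Display name of a k-mer feature
#'
#' Dinucleotides are reported in XpY notation (the feature "GC", G followed
#' by C, prints as "GpC"), matching field convention.
#' @param kmer k-mer string
#' @export
kmer_display_name <- function(kmer) {
  ifelse(nchar(kmer) == 2L,
         paste0(substr(kmer, 1, 1), "p", substr(kmer, 2, 2)), kmer)
}

#' Default training region: the first third of the genome
#' @param genome_length_bp genome length
#' @return c(start, end), 0-based half-open
#' @export
first_third <- function(genome_length_bp) {
  c(0L, as.integer(floor(genome_length_bp / 3)))
}

# 1-based position indices of a 0-based half-open region, possibly strided
region_positions <- function(region, step = 1L) {
  seq.int(region[1] + 1L, region[2], by = step)
}

#' k-mer feature matrix
#'
#' Per-position windowed k-mer frequencies (see
#' \code{\link{kmer_window_frequency}}) for each (k-mer, window) pair,
#' assembled as a positions x features matrix. Column names are
#' "KMER|wWINDOW". Positions whose window contains N are NA.
#'
#' @param genome \code{hta_genome}
#' @param features data.frame(kmer, window) of feature definitions, or
#'   NULL to cross \code{kmers} with \code{window_sizes}
#' @param kmers,window_sizes used when \code{features} is NULL
#' @param positions optional 1-based positions to restrict rows to
#' @export
kmer_features <- function(genome, features = NULL, kmers = all_kmers(1:4),
                          window_sizes = c(21L, 51L), positions = NULL) {
  if (is.null(features))
    features <- expand.grid(kmer = kmers, window = window_sizes,
                            stringsAsFactors = FALSE)
  n <- genome_length(genome)
  rows <- positions %||% seq_len(n)
  out <- matrix(NA_real_, length(rows), nrow(features))
  colnames(out) <- paste0(features$kmer, "|w", features$window)
  for (i in seq_len(nrow(features))) {
    v <- kmer_window_frequency(genome, features$kmer[i], features$window[i])
    out[, i] <- v[rows]
  }
  out
}

#' Correlation-based feature pre-selection
#'
#' Pearson correlation of every (k-mer, window) feature with the coverage
#' response over the training region; features are ranked by absolute
#' correlation and the top \code{top_n} returned (ties broken by
#' lexicographic k-mer, then smaller window). Constant features get r = 0.
#' Features are computed one at a time, so the full feature matrix is
#' never materialised.
#'
#' @param coverage response \code{cov_track} (normalized)
#' @param genome \code{hta_genome}
#' @param kmers candidate k-mers
#' @param window_sizes candidate windows, bp
#' @param training_region c(start, end) 0-based half-open; default first
#'   third of the genome
#' @param top_n number of features to keep (80 by default)
#' @param step position stride over the training region (1 = every bp)
#' @return data.frame(kmer, window, r) ranked by |r|
#' @export
select_features <- function(coverage, genome, kmers = all_kmers(1:4),
                            window_sizes = c(21L, 51L),
                            training_region = NULL, top_n = 80L,
                            step = 1L) {
  y_all <- track_values(coverage)
  n <- genome_length(genome)
  training_region <- training_region %||% first_third(n)
  pos <- region_positions(training_region, step)
  y <- y_all[pos]
  if (stats::sd(y, na.rm = TRUE) < 1e-12)
    stop("degenerate (zero-variance) response over the training region")
  grid <- expand.grid(kmer = kmers, window = window_sizes,
                      stringsAsFactors = FALSE)
  r <- vapply(seq_len(nrow(grid)), function(i) {
    x <- kmer_window_frequency(genome, grid$kmer[i], grid$window[i])[pos]
    if (stats::sd(x, na.rm = TRUE) < 1e-12) return(0)
    stats::cor(x, y, use = "complete.obs")
  }, 0)
  grid$r <- r
  ord <- order(-abs(grid$r), grid$kmer, grid$window)
  head(grid[ord, , drop = FALSE], top_n)
}

#' Fit the k-mer LASSO occupancy model
#'
#' L1-penalised linear regression of the coverage response on the selected
#' windowed k-mer frequencies over the training region, with 10-fold
#' cross-validation to choose the penalty. Features are standardized
#' internally and coefficients returned on the original scale. The penalty
#' grid is 100 log-spaced values from lambda_max (all weights zero) down
#' to 1e-4 lambda_max; the CV-minimising penalty is selected. CV folds are
#' contiguous genomic blocks of the training region, because adjacent
#' positions are near-duplicates and randomly scattered folds would leak
#' training information into validation folds.
#'
#' @param coverage response \code{cov_track}
#' @param genome \code{hta_genome}
#' @param selected data.frame(kmer, window) from
#'   \code{\link{select_features}}
#' @param training_region c(start, end) 0-based half-open; default first
#'   third
#' @param cv_folds number of contiguous-block folds (default 10)
#' @param lambda optional fixed penalty, bypassing cross-validation
#' @param rule penalty selection rule: \code{"min"} (minimum mean CV
#'   error, the default) or \code{"1se"} (largest penalty within one
#'   standard error of the minimum; more conservative under pure noise)
#' @param step position stride (logged in the model)
#' @return object of class \code{kmer_lasso_model}
#' @export
fit_lasso <- function(coverage, genome, selected, training_region = NULL,
                      cv_folds = 10L, lambda = NULL,
                      rule = c("min", "1se"), step = 1L) {
  rule <- match.arg(rule)
  n <- genome_length(genome)
  training_region <- training_region %||% first_third(n)
  pos <- region_positions(training_region, step)
  y <- track_values(coverage)[pos]
  X <- kmer_features(genome, features = selected, positions = pos)
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) < cv_folds) stop("fewer training positions than folds")
  if (stats::sd(y) < 1e-12) stop("degenerate (zero-variance) response")
  # glmnet requires >= 2 columns; duplicate a lone feature and pool the
  # two (identical) coefficients afterwards
  lone <- ncol(X) == 1L
  if (lone) X <- cbind(X, X)
  if (is.null(lambda)) {
    foldid <- as.integer(ceiling(seq_along(y) / (length(y) / cv_folds)))
    foldid[foldid > cv_folds] <- cv_folds
    cv <- glmnet::cv.glmnet(X, y, alpha = 1, foldid = foldid,
                            nlambda = 100L, lambda.min.ratio = 1e-4,
                            standardize = TRUE)
    s <- if (rule == "min") "lambda.min" else "lambda.1se"
    penalty <- cv[[s]]
    co <- as.matrix(stats::coef(cv, s = s))
  } else {
    grid <- sort(unique(c(lambda, lambda * c(10, 100, 1000))),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = grid,
                          standardize = TRUE, thresh = 1e-12)
    penalty <- lambda
    co <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
  }
  wts <- co[-1, 1]
  if (lone) wts <- sum(wts)
  structure(list(features = selected[, c("kmer", "window")],
                 weights = setNames(wts, colnames(X)[seq_along(wts)]),
                 intercept = co[1, 1],
                 penalty = penalty,
                 cv_folds = if (is.null(lambda)) cv_folds else 0L,
                 training_region = as.integer(training_region),
                 step = as.integer(step)),
            class = "kmer_lasso_model")
}

#' @export
print.kmer_lasso_model <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf(paste0("<kmer_lasso_model> %d features (%d nonzero), ",
                     "intercept %.4g, penalty %.4g\n"),
              length(x$weights), nz, x$intercept, x$penalty))
  top <- sort(abs(x$weights), decreasing = TRUE)
  top <- names(top[top > 0])[seq_len(min(5, nz))]
  if (length(top)) cat("  strongest:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' Predict a coverage track from a fitted k-mer model
#'
#' Per-bp linear prediction intercept + X w over the whole genome (or the
#' supplied feature matrix). Positions whose windows contain N predict NA.
#'
#' @param model \code{kmer_lasso_model}
#' @param genome \code{hta_genome} to predict on
#' @param features optional precomputed feature matrix whose columns match
#'   the model's features
#' @return \code{cov_track} with normalization \code{"predicted"}
#' @export
predict_coverage <- function(model, genome = NULL, features = NULL) {
  if (is.null(features)) {
    if (is.null(genome)) stop("supply a genome or a feature matrix")
    features <- kmer_features(genome, features = model$features)
  }
  need <- paste0(model$features$kmer, "|w", model$features$window)
  if (!all(need %in% colnames(features)))
    stop("feature matrix is missing model features: ",
         paste(setdiff(need, colnames(features)), collapse = ","))
  X <- features[, need, drop = FALSE]
  pred <- as.numeric(X %*% model$weights + model$intercept)
  cov_track(pred, genome_id = if (!is.null(genome)) genome$id else "genome",
            size_class = "all", normalization = "predicted")
}

#' Evaluate predicted against observed coverage
#'
#' Spearman correlation over the non-NA positions of the named region;
#' "untrained" is the complement of the training region.
#'
#' @param predicted,observed \code{cov_track}s on the same genome
#' @param region "all", "trained" or "untrained"
#' @param training_region c(start, end) 0-based half-open
#' @export
evaluate_prediction <- function(predicted, observed,
                                region = c("all", "trained", "untrained"),
                                training_region = NULL) {
  region <- match.arg(region)
  p <- track_values(predicted); o <- track_values(observed)
  if (length(p) != length(o)) stop("track lengths differ")
  n <- length(p)
  training_region <- training_region %||% first_third(n)
  idx <- switch(region,
                all = seq_len(n),
                trained = region_positions(training_region),
                untrained = setdiff(seq_len(n),
                                    region_positions(training_region)))
  ok <- idx[!is.na(p[idx]) & !is.na(o[idx])]
  if (length(ok) < 10L) stop("fewer than 10 usable positions")
  stats::cor(p[ok], o[ok], method = "spearman")
}

#' Serialize a fitted model to JSON
#' @param model \code{kmer_lasso_model}
#' @param path output file
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(features = model$features, weights = unname(model$weights),
         feature_names = kmer_display_name(model$features$kmer),
         intercept = model$intercept, penalty = model$penalty,
         cv_folds = model$cv_folds,
         training_region = model$training_region, step = model$step),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a fitted model from JSON
#' @param path JSON written by \code{\link{write_model_json}}
#' @export
read_model_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.data.frame(j$features)
  structure(list(features = feats,
                 weights = setNames(as.numeric(j$weights),
                                    paste0(feats$kmer, "|w", feats$window)),
                 intercept = as.numeric(j$intercept),
                 penalty = as.numeric(j$penalty),
                 cv_folds = as.integer(j$cv_folds),
                 training_region = as.integer(j$training_region),
                 step = as.integer(j$step)),
            class = "kmer_lasso_model")
}
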