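test_that("coverage counts fragments per base and honours size classes", {
  g <- hta_genome(strrep("A", 200), "g")
  fr <- fragments_df("g", 0L, 50L)
  v <- track_values(compute_coverage(fr, g, "all"))
  expect_equal(v, c(rep(1, 50), rep(0, 150)))
  # length-66 fragment is in neither class (bounds 40-65 / 70-100)
  fr66 <- fragments_df("g", 0L, 66L)
  expect_equal(sum(track_values(compute_coverage(fr66, g, "small"))), 0)
  expect_equal(sum(track_values(compute_coverage(fr66, g, "large"))), 0)
  expect_equal(sum(track_values(compute_coverage(fr66, g, "all"))), 66)
  # boundary lengths stay in class (inclusive bounds)
  fr65 <- fragments_df("g", 0L, 65L)
  expect_equal(sum(track_values(compute_coverage(fr65, g, "small"))), 65)
})

test_that("coverage equals brute-force counting on random circular instances", {
  for (i in 1:20) {
    withr_seed(i)
    n <- sample(500:1000, 1)
    g <- hta_genome(strrep("A", n), "g")
    m <- sample(1:300, 1)
    start <- sample(0:(n - 1), m, replace = TRUE)
    len <- sample(20:120, m, replace = TRUE)
    fr <- fragments_df("g", start, start + len)
    expect_equal(track_values(compute_coverage(fr, g, "all")),
                 brute_coverage(fr, n))
  }
})

test_that("RPGC scales to 1x coverage, is scale-invariant and idempotent", {
  tr <- cov_track(rep(2, 1000), "g")
  expect_equal(track_values(rpgc_normalize(tr, 1000)), rep(1, 1000))
  withr_seed(3)
  tr2 <- cov_track(rpois(1000, 5), "g")
  a <- rpgc_normalize(tr2, 1000)
  b <- rpgc_normalize(cov_track(track_values(tr2) * 2, "g"), 1000)
  expect_equal(track_values(a), track_values(b))
  expect_equal(track_values(rpgc_normalize(a, 1000)), track_values(a),
               tolerance = 1e-9)
  expect_error(rpgc_normalize(cov_track(rep(0, 10), "g")), "all-zero")
})

test_that("circular smoothing preserves the mean and spreads impulses", {
  expect_equal(track_values(smooth_track(cov_track(rep(3, 100), "g"), 11)),
               rep(3, 100))
  imp <- numeric(101); imp[51] <- 1
  sm <- smooth_track(imp, 11)
  expect_equal(sm[46:56], rep(1 / 11, 11))
  expect_equal(sum(sm), 1)
  withr_seed(4)
  x <- runif(500)
  expect_equal(mean(smooth_track(x, 25)), mean(x), tolerance = 1e-9)
  expect_error(smooth_track(x, 501), "exceeds")
  expect_error(smooth_track(x, 10), "odd")
})

test_that("input normalization Z-scores the ratio and guards degeneracy", {
  tr <- cov_track(rep(4, 2000), "g")
  expect_equal(track_values(normalize_by_input(tr, tr, 101)), rep(0, 2000))
  withr_seed(5)
  m <- cov_track(rpois(2000, 10), "g")
  inp <- cov_track(rpois(2000, 10) + 1, "g")
  z <- track_values(normalize_by_input(m, inp, 101))
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(z), 1, tolerance = 1e-9)
  # zeros in smoothed input fail loudly unless a pseudocount is given
  inp0 <- cov_track(rep(0, 2000), "g")
  expect_error(normalize_by_input(m, inp0, 101), "pseudocount")
  expect_silent(normalize_by_input(m, inp0, 101, pseudocount = 1))
})

test_that("input normalization removes a shared multiplicative gradient", {
  n <- 100000L
  grad <- gradient_multiplier(replication_gradient_spec(0, 2), n)
  withr_seed(6)
  m <- cov_track(rpois(n, 10 * grad), "g")
  inp <- cov_track(rpois(n, 10 * grad), "g")
  z <- track_values(normalize_by_input(m, inp, 10001))
  expect_lt(abs(stats::cor(z, grad, method = "spearman")), 0.05)
})

test_that("self-normalization removes slow trends and has a global-mean limit", {
  expect_equal(track_values(self_normalize(cov_track(rep(2, 1001), "g"))),
               rep(0, 1001))
  n <- 100000L
  trend <- 2 + sin(2 * pi * seq_len(n) / n)
  withr_seed(7)
  tr <- cov_track(rnorm(n, 10, 1) * trend, "g")
  z <- track_values(self_normalize(tr, 10001))
  expect_lt(abs(stats::cor(z, trend, method = "spearman")), 0.1)
  # window >= genome length: equivalent to global-mean normalization
  withr_seed(8)
  x <- runif(1001) + 1
  z1 <- track_values(self_normalize(cov_track(x, "g"), 5000))
  z2 <- zval <- (x / mean(x) - mean(x / mean(x))) / stats::sd(x / mean(x))
  expect_equal(z1, z2, tolerance = 1e-9)
})

test_that("length correlation matrix is symmetric with unit diagonal", {
  g <- random_genome(2000, seed = 9)
  withr_seed(9)
  start <- sample(0:1999, 400, replace = TRUE)
  len <- sample(c(45, 50, 85, 90), 400, replace = TRUE)
  fr <- fragments_df("oracle", start, start + len)
  m <- length_correlation_matrix(fr, g, list(c(40, 55), c(80, 95)))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), c(1, 1))
  # identical bins correlate perfectly
  m2 <- length_correlation_matrix(fr, g, list(c(40, 55), c(40, 55)))
  expect_equal(unname(m2[1, 2]), 1)
  # disjoint halves anti-correlate
  frA <- fragments_df("oracle", seq(0, 900, by = 10), seq(50, 950, by = 10))
  frB <- fragments_df("oracle", seq(1000, 1900, by = 10),
                      seq(1090, 1990, by = 10))
  m3 <- length_correlation_matrix(rbind(frA, frB), g,
                                  list(c(45, 55), c(85, 95)))
  expect_lte(m3[1, 2], 0)
  expect_warning(length_correlation_matrix(fr, g,
                                           list(c(40, 55), c(200, 210))),
                 "empty")
})

test_that("site-relative aggregation reverses minus-strand windows", {
  v <- seq(0, 99)
  tr <- cov_track(v, "g")
  s_plus <- data.frame(position = 50L, strand = "+")
  prof <- aggregate_around_sites(tr, s_plus, 5)
  expect_equal(prof$value, v[46:56])
  s_minus <- data.frame(position = 50L, strand = "-")
  prof2 <- aggregate_around_sites(tr, s_minus, 5)
  expect_equal(prof2$value, rev(v[46:56]))
  # constant track -> constant profile
  prof3 <- aggregate_around_sites(cov_track(rep(7, 100), "g"),
                                  rbind(s_plus, s_minus), 10)
  expect_true(all(prof3$value == 7))
  # elementwise median of two opposing ramps
  vv <- c(0:10, rep(0, 89))
  tr2 <- cov_track(vv, "g")
  sites <- data.frame(position = c(5L, 5L), strand = c("+", "-"))
  med <- aggregate_around_sites(tr2, sites, 5, statistic = "median")
  expect_equal(med$value, apply(rbind(vv[1:11], rev(vv[1:11])), 2, median))
})

test_that("aggregation is equivariant under genome rotation", {
  withr_seed(10)
  v <- runif(200)
  sites <- data.frame(position = c(20L, 120L), strand = c("+", "-"))
  base <- aggregate_around_sites(cov_track(v, "g"), sites, 15)
  shift <- 37L
  v2 <- c(v[(shift + 1):200], v[1:shift])   # rotate left by shift
  sites2 <- data.frame(position = (sites$position - shift) %% 200L,
                       strand = sites$strand)
  rot <- aggregate_around_sites(cov_track(v2, "g"), sites2, 15)
  expect_equal(rot$value, base$value)
})
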