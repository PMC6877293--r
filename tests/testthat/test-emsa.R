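test_that("design validation rejects overlaps, misplaced slots and ambiguity", {
  d <- random_emsa_design(3, seed = 1)
  expect_s3_class(d, "emsa_design")
  # overlapping randomized dinucleotides
  bb <- d$backbones[1, , drop = FALSE]
  expect_error(emsa_design(bb, list(c(10, 11, 32, 43, 54, 65, 76, 87))),
               "overlap|exactly 8")
  # ambiguous design: identical fixed positions
  two <- d$backbones[c(1, 1), ]
  two$id <- c("b1", "b2")
  expect_error(emsa_design(two, d$randomized_positions[c(1, 1)],
                           c(intercept = 0)), "ambiguous")
  # design TSV round trip
  tmp <- tempfile(fileext = ".tsv")
  write_emsa_design(d, tmp)
  d2 <- read_emsa_design(tmp)
  expect_identical(d2$backbones$sequence, d$backbones$sequence)
  expect_identical(d2$randomized_positions, d$randomized_positions)
})

test_that("pool generation is seeded, exact-count and band-balanced at null", {
  d <- random_emsa_design(5, planted_affinity = c(intercept = 0), seed = 2)
  pool <- generate_emsa_pool(d, 1e5, seed = 3)
  expect_identical(nrow(pool$reads), 100000L)
  expect_identical(sum(pool$counts$Freq), 100000L)
  # zero affinity -> slow fraction ~ 0.5 within 0.02
  expect_lt(abs(mean(pool$reads$band == "slow") - 0.5), 0.02)
  # determinism
  pool2 <- generate_emsa_pool(d, 1e5, seed = 3)
  expect_identical(pool$reads, pool2$reads)
  # saturating positive GpC affinity: top-GpC reads all slow
  dsat <- random_emsa_design(2, planted_affinity = c(intercept = -50,
                                                     GpC = 100), seed = 4)
  psat <- generate_emsa_pool(dsat, 5000, seed = 5)
  gpc <- (nchar(psat$reads$sequence) -
          nchar(gsub("GC", "", psat$reads$sequence, fixed = TRUE))) / 2
  expect_true(all(psat$reads$band[gpc == max(gpc)] == "slow"))
})

test_that("read assignment is exact-match and round trips the generator", {
  d <- random_emsa_design(5, seed = 6)
  pool <- generate_emsa_pool(d, 5000, seed = 7)
  asn <- assign_reads(pool$reads$sequence, d, band = pool$reads$band)
  expect_identical(attr(asn, "n_unassigned"), 0L)
  expect_identical(asn$backbone, pool$reads$backbone)
  expect_true(all(nchar(asn$dinucleotides) == 16L))
  # one mismatch at a fixed position -> unassigned
  r <- pool$reads$sequence[1]
  fixed_pos <- setdiff(seq_len(100),
                       as.vector(outer(1:2, d$randomized_positions[[1]],
                                       `+`)))
  p <- fixed_pos[1]
  bad <- r
  substr(bad, p, p) <- setdiff(c("A", "C", "G", "T"),
                               substr(r, p, p))[1]
  asn2 <- assign_reads(c(r, bad), d)
  expect_identical(is.na(asn2$backbone), c(FALSE, TRUE))
  expect_identical(attr(asn2, "n_unassigned"), 1L)
})

test_that("P_slow tables count correctly and conserve reads", {
  # hand-count check: 25 slow / 75 fast in one composition group
  d <- random_emsa_design(1, seed = 8)
  pool <- generate_emsa_pool(d, 200, seed = 9)
  seqs <- rep(pool$reads$sequence[1], 100)
  asn <- assign_reads(seqs, d, band = rep(c("slow", "fast"),
                                          times = c(25, 75)))
  tab <- compute_pslow(asn)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$p_slow, 0.25)
  expect_identical(tab$n_slow, 25L)
  # all slow -> p_slow 1 everywhere
  asn2 <- assign_reads(pool$reads$sequence, d, band = "slow")
  expect_true(all(compute_pslow(asn2)$p_slow == 1))
  # conservation: assigned group totals + unassigned = all reads
  d5 <- random_emsa_design(5, seed = 10)
  pool5 <- generate_emsa_pool(d5, 3000, seed = 11)
  seqs5 <- c(pool5$reads$sequence, strrep("A", 100))   # one alien read
  asn5 <- assign_reads(seqs5, d5, band = c(pool5$reads$band, "slow"))
  tab5 <- compute_pslow(asn5)
  expect_identical(sum(tab5$n_slow + tab5$n_fast) +
                     attr(asn5, "n_unassigned"), 3001L)
  # backbone exclusion
  tabx <- compute_pslow(asn5, exclude_backbones = "backbone1")
  bb <- attr(tabx, "by_backbone")
  expect_false("backbone1" %in% bb$backbone)
  expect_error(compute_pslow(asn5,
                             exclude_backbones = d5$backbones$id),
               "no assigned reads")
})

test_that("planted positive GpC affinity yields increasing P_slow", {
  d <- random_emsa_design(5, planted_affinity = c(intercept = -0.5,
                                                  GpC = 0.15), seed = 12)
  pool <- generate_emsa_pool(d, 1e5, seed = 13)
  asn <- assign_reads(pool$reads$sequence, d, band = pool$reads$band)
  tab <- compute_pslow(asn)
  # weighted monotone trend: isotonic fit explains nearly all variation
  w <- tab$n_slow + tab$n_fast
  iso <- stats::isoreg(tab$x, tab$p_slow)
  sse_iso <- sum(w * (iso$yf - tab$p_slow)^2)
  sse_tot <- sum(w * (tab$p_slow - sum(w * tab$p_slow) / sum(w))^2)
  expect_lt(sse_iso / sse_tot, 0.05)
  expect_gt(weighted_correlation(tab), 0)
})

test_that("weighted correlation matches closed forms and equal-weight Pearson", {
  tab <- data.frame(x = 1:6, n_slow = 3:8, n_fast = 7:2)
  tab$p_slow <- 0.1 + 0.05 * tab$x       # exact line, b > 0
  expect_equal(weighted_correlation(tab), 1)
  # equal weights reduce to ordinary Pearson r
  withr_seed(14)
  tab2 <- data.frame(x = 1:10, n_slow = 5L, n_fast = 5L,
                     p_slow = runif(10))
  expect_equal(weighted_correlation(tab2),
               stats::cor(tab2$x, tab2$p_slow))
  # dominant weight: direct evaluation of the weighted formula
  tab3 <- data.frame(x = c(1, 2, 3), n_slow = c(4950, 30, 20),
                     n_fast = c(4950, 30, 20), p_slow = c(0.5, 0.9, 0.1))
  w <- tab3$n_slow + tab3$n_fast
  xm <- sum(w * tab3$x) / sum(w); pm <- sum(w * tab3$p_slow) / sum(w)
  rman <- sum(w * (tab3$x - xm) * (tab3$p_slow - pm)) /
    sqrt(sum(w * (tab3$x - xm)^2) * sum(w * (tab3$p_slow - pm)^2))
  expect_equal(weighted_correlation(tab3), rman)
  expect_error(weighted_correlation(tab[1:2, ]), "at least 3")
  tabc <- data.frame(x = 1:3, n_slow = 1L, n_fast = 1L, p_slow = 0.5)
  expect_error(weighted_correlation(tabc), "zero weighted variance")
})

test_that("replicate pools from one design agree on per-backbone P_slow", {
  d <- random_emsa_design(5, planted_affinity = c(intercept = -0.3,
                                                  GpC = 0.1), seed = 15)
  get_bb <- function(seed) {
    pool <- generate_emsa_pool(d, 1e5, seed = seed)
    asn <- assign_reads(pool$reads$sequence, d, band = pool$reads$band)
    attr(compute_pslow(asn), "by_backbone")
  }
  b1 <- get_bb(16); b2 <- get_bb(17)
  expect_identical(b1$backbone, b2$backbone)
  expect_lt(max(abs(b1$p_slow - b2$p_slow)), 0.05)
})
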