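test_that("dinucleotide classes have exactly the canonical member sets", {
  expect_setequal(dinucleotide_class("SS"), c("CC", "CG", "GC", "GG"))
  expect_setequal(dinucleotide_class("WW"), c("AA", "AT", "TA", "TT"))
  expect_setequal(dinucleotide_class("RR"), c("AA", "AG", "GA", "GG"))
  expect_setequal(dinucleotide_class("YY"), c("CC", "CT", "TC", "TT"))
  expect_setequal(dinucleotide_class("mono_GC"), c("C", "G"))
  expect_setequal(dinucleotide_class("mono_AT"), c("A", "T"))
  # the two partitions each cover all 16 dinucleotides
  expect_setequal(c(dinucleotide_class("SS"), dinucleotide_class("WW"),
                    dinucleotide_class("SW"), dinucleotide_class("WS")),
                  as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)))
  expect_setequal(c(dinucleotide_class("RR"), dinucleotide_class("YY"),
                    dinucleotide_class("RY"), dinucleotide_class("YR")),
                  as.vector(outer(c("A", "C", "G", "T"),
                                  c("A", "C", "G", "T"), paste0)))
  expect_error(dinucleotide_class("XX"), "unknown")
})

test_that("read filtering applies quality, peak-overlap and duplicate rules", {
  pks <- data.frame(chrom = "g", center = 150L, start = 100L, end = 200L,
                    width = 100L, width_class = "broad", score = 3,
                    orientation = "unset")
  # 100 bp fragment overlapping the peak by 89 vs 90 bp
  fr <- fragments_df("g", c(111L, 110L), c(211L, 210L),
                     mean_quality = c(35, 35))
  kept <- filter_reads(fr, pks)
  expect_identical(kept$start, 110L)     # 90-bp overlap kept, 89 removed
  # quality threshold at 30 exactly; missing quality retained but counted
  fr2 <- fragments_df("g", c(120L, 120L, 120L), c(180L, 180L, 180L),
                      mean_quality = c(29.9, 30, NA))
  fr2$start <- c(120L, 121L, 122L); fr2$end <- c(180L, 181L, 182L)
  kept2 <- filter_reads(fr2, pks)
  expect_identical(kept2$start, c(121L, 122L))
  expect_identical(attr(kept2, "n_no_quality"), 1L)
  # exact duplicates collapse to the first occurrence
  fr3 <- fragments_df("g", c(120L, 120L, 125L), c(180L, 180L, 185L),
                      mean_quality = 35)
  expect_identical(nrow(filter_reads(fr3, pks)), 2L)
})

test_that("positional class profiles match a brute-force tally", {
  gG <- hta_genome(strrep("G", 400), "allG")
  fr <- fragments_df("allG", c(100L, 200L), c(150L, 250L))
  pr <- positional_class_profile(fr, gG, "SS")
  expect_true(all(pr$proportion == 1))
  expect_identical(nrow(pr), 50L)        # offsets -25..24
  expect_true(all(positional_class_profile(fr, gG, "WW")$proportion == 0))
  expect_error(positional_class_profile(fragments_df("allG", 0L, 1L), gG,
                                        "SS"), "length >= 2")
  # random instances against the naive oracle
  for (i in 1:10) {
    g <- random_genome(300, seed = 100 + i)
    withr_seed(200 + i)
    start <- sample(0:299, 30, replace = TRUE)
    fr2 <- fragments_df("oracle", start, start + 20L)
    for (cls in c("SS", "RR", "YR")) {
      expect_equal(positional_class_profile(fr2, g, cls)$proportion,
                   brute_class_profile(fr2, g, dinucleotide_class(cls), 20L))
    }
  }
})

test_that("complementary class partitions sum to one at every offset", {
  g <- random_genome(500, seed = 31)
  withr_seed(32)
  start <- sample(0:499, 50, replace = TRUE)
  fr <- fragments_df("oracle", start, start + 30L)
  sw <- Reduce(`+`, lapply(c("SS", "WW", "SW", "WS"), function(cl)
    positional_class_profile(fr, g, cl)$proportion))
  expect_equal(sw, rep(1, 30))
  ry <- Reduce(`+`, lapply(c("RR", "YY", "RY", "YR"), function(cl)
    positional_class_profile(fr, g, cl)$proportion))
  expect_equal(ry, rep(1, 30))
})

test_that("SS/WW profiles are strand-symmetric while RR/YY swap under mirroring", {
  g <- random_genome(400, seed = 41)
  withr_seed(42)
  start <- sample(0:399, 40, replace = TRUE)
  L <- 20L
  fr <- fragments_df("oracle", start, start + L)
  # reverse complement the genome; a fragment [s,e) maps to [n-e, n-s)
  n <- 400L
  comp <- chartr("ACGT", "TGCA", g$sequence)
  grc <- hta_genome(paste(rev(strsplit(comp, "")[[1]]), collapse = ""),
                    "rc")
  frrc <- fragments_df("rc", n - fr$end, n - fr$start)
  # the floor-dyad convention for even-length fragments shifts the mirrored
  # profile by exactly one base relative to plain reversal
  shift1 <- function(p) rev(p)[-1]
  for (cls in c("SS", "WW")) {
    p1 <- positional_class_profile(fr, g, cls)$proportion
    p2 <- positional_class_profile(frrc, grc, cls)$proportion
    expect_equal(p2[-L], shift1(p1))
  }
  prr <- positional_class_profile(fr, g, "RR")$proportion
  pyy <- positional_class_profile(fr, g, "YY")$proportion
  prr_rc <- positional_class_profile(frrc, grc, "RR")$proportion
  pyy_rc <- positional_class_profile(frrc, grc, "YY")$proportion
  expect_equal(prr_rc[-L], shift1(pyy))
  expect_equal(pyy_rc[-L], shift1(prr))
})

test_that("background expectations match composition nulls", {
  gG <- hta_genome(strrep("G", 1000), "allG")
  expect_equal(background_expectation(gG, 50, "SS", n = 100, seed = 1), 1)
  g <- generate_genome(genome_spec(200000, 0.5, seed = 51))
  bg <- background_expectation(g, 100, "SS", n = 25000, seed = 52)
  expect_lt(abs(bg - 0.25), 0.005)
  expect_error(background_expectation(gG, 2000, "SS"), "exceeds")
})

test_that("peak GC profiles average windows with orientation", {
  gG <- hta_genome(strrep("G", 500), "allG")
  pks <- data.frame(chrom = "allG", center = c(100L, 300L), start = 90L,
                    end = 110L, width = 20L, width_class = "broad",
                    score = 3, orientation = c("as_is", "flipped"))
  pr <- peak_gc_profile(pks, gG, 10)
  expect_true(all(pr$gc == 1))
  # single-peak profile equals the window's base indicator (oracle)
  g <- random_genome(500, seed = 61)
  pk <- data.frame(chrom = "oracle", center = 250L, start = 240L,
                   end = 260L, width = 20L, width_class = "broad",
                   score = 3, orientation = "as_is")
  pr2 <- peak_gc_profile(pk, g, 15)
  ch <- strsplit(g$sequence, "")[[1]]
  expect_equal(pr2$gc, as.numeric(ch[236:266] %in% c("G", "C")))
})
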