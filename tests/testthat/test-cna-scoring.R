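toy_model <- function(arms = 4, arm_length_bp = 1e6) {
  generate_arm_model(arms = arms, arm_length_bp = arm_length_bp,
                     n_genes = 2000, seed = 1)
}

test_that("gain/loss thresholding follows strict inequalities", {
  seg <- data.frame(sample = "s1", chrom = "chr1", start = 0, end = 100,
                    value = c(0.5, 0.3, 0.0, -0.3, -0.31, 0.30001))
  out <- threshold_segments(seg)
  expect_equal(out$value, c(0.5, -0.31, 0.30001))
  expect_equal(out$direction, c("gain", "loss", "gain"))
  bad <- data.frame(sample = "s1", chrom = "chr1", start = 10, end = 10,
                    value = 1)
  expect_error(threshold_segments(bad), "end <= start")
  expect_error(threshold_segments(seg, gain_threshold = -0.5,
                                  loss_threshold = 0.5), "below")
})

test_that("arm splitting conserves altered base pairs", {
  gm <- toy_model()
  seg <- data.frame(sample = "s1", chrom = "chr1",
                    start = c(0, 5e5, 9.9e5), end = c(1e6, 1.6e6, 1.2e6),
                    value = 0.5, direction = "gain")
  out <- split_segments_by_arm(seg, gm)
  expect_true(all(out$arm_name %in% gm$arms$arm_name))
  expect_equal(sum(out$end - out$start), sum(seg$end - seg$start))
  # segment confined to one arm is unchanged
  one <- split_segments_by_arm(seg[1, ], gm)
  expect_equal(nrow(one), 1)
  expect_equal(one$start, 0)
  expect_equal(one$end, 1e6)
  # centromere-spanning segment is split into two summing parts
  two <- split_segments_by_arm(seg[2, ], gm)
  expect_equal(nrow(two), 2)
  expect_equal(sum(two$end - two$start), 1.6e6 - 5e5)
  expect_setequal(two$arm_name, c("1p", "1q"))
  # unknown chromosome and out-of-genome segment rejected
  expect_error(split_segments_by_arm(
    data.frame(sample = "s1", chrom = "chrX", start = 0, end = 10,
               value = 1), gm), "not in arm model")
  expect_error(split_segments_by_arm(
    data.frame(sample = "s1", chrom = "chr1", start = 1.9e6, end = 2.5e6,
               value = 1), gm), "outside")
})

test_that("arm splitting matches a brute-force intersection oracle", {
  gm <- generate_arm_model(arms = 10, arm_length_bp = 1e4,
                           n_genes = 100, seed = 2)
  set.seed(42)
  for (rep in 1:20) {
    seg <- random_segment_table(gm, n_segments = 50)
    out <- split_segments_by_arm(seg, gm)
    for (ai in seq_len(nrow(gm$arms))) {
      arm <- gm$arms[ai, ]
      keep <- seg$chrom == arm$chrom
      cs <- pmax(seg$start[keep], arm$start)
      ce <- pmin(seg$end[keep], arm$end)
      expected <- sum(pmax(ce - cs, 0))
      got <- sum(out$end[out$arm_name == arm$arm_name] -
                   out$start[out$arm_name == arm$arm_name])
      expect_equal(got, expected)
    }
  }
})

test_that("broad/focal calls follow the strict 98% rule", {
  gm <- toy_model()
  mk <- function(start, end, value, sample = "s1", chrom = "chr1") {
    data.frame(sample = sample, chrom = chrom, start = start, end = end,
               value = value)
  }
  prep <- function(seg) split_segments_by_arm(threshold_segments(seg), gm)
  # 98.5% of the p arm -> one broad gain
  ev <- call_events(prep(mk(0, 985000, 0.5)), gm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$breadth, "broad")
  expect_equal(ev$direction, "gain")
  expect_equal(ev$arm_fraction, 0.985)
  # exactly 98.0% -> focal (strictly "longer than")
  ev <- call_events(prep(mk(0, 980000, 0.5)), gm)
  expect_equal(ev$breadth, "focal")
  # three disjoint focal losses on one arm totalling 5% -> three focal
  seg <- mk(c(0, 20000, 40000), c(10000, 30000, 50000), -0.6)
  ev <- call_events(prep(seg), gm)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$breadth == "focal"))
  expect_true(all(ev$direction == "loss"))
  # abutting altered runs merge: two halves of an arm -> one broad
  ev <- call_events(prep(mk(c(0, 5e5), c(5e5, 1e6), 0.5)), gm)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$breadth, "broad")
  expect_equal(ev$arm_fraction, 1)
  # gain and loss on the same arm are separate events
  ev <- call_events(prep(rbind(mk(0, 1e6, 0.5), mk(0, 1e6, -0.5))), gm)
  expect_equal(sort(ev$direction), c("gain", "loss"))
  expect_true(all(ev$breadth == "broad"))
  expect_error(call_events(prep(mk(0, 1e4, 0.5)), gm,
                           broad_fraction = 1), "between 0 and 1")
})

test_that("CNA scores implement the printed formulas", {
  gm <- toy_model()  # 4 arms, 2000 genes
  ev <- data.frame(sample = "s1", chrom = "chr1",
                   arm_name = c("1p", "1q", "2p", "2q", "1p"),
                   direction = c("gain", "loss", "gain", "gain", "loss"),
                   breadth = c("broad", "broad", "focal", "focal",
                               "focal"),
                   span_bp = 1, arm_fraction = 0.5)
  expect_equal(unname(broad_cna_score(ev, gm)), 2 / 4)
  expect_equal(unname(focal_cna_score(ev, gm)), 3 / 2000)
  none <- ev[0, ]
  expect_equal(unname(broad_cna_score(none, gm, samples = "s1")), 0)
  expect_equal(unname(focal_cna_score(none, gm, samples = "s1")), 0)
  # focal example from the formula: 5 focal events over 2000 genes
  ev5 <- data.frame(sample = "s1", chrom = "chr1", arm_name = "1p",
                    direction = "gain", breadth = rep("focal", 5),
                    span_bp = 1, arm_fraction = 0.01)
  expect_equal(unname(focal_cna_score(ev5, gm)), 0.0025)
})

test_that("event calls and scores match the brute-force oracle", {
  set.seed(7)
  for (rep in 1:30) {
    n_arms <- sample(c(4, 10, 22, 46), 1)
    gm <- generate_arm_model(arms = n_arms, arm_length_bp = 1e4,
                             n_genes = 500, seed = rep)
    seg <- random_segment_table(gm, n_segments = sample(20:120, 1))
    oracle <- oracle_cna_scores(seg, gm)
    alt <- split_segments_by_arm(threshold_segments(seg), gm)
    ev <- call_events(alt, gm)
    samples <- unique(seg$sample)
    expect_equal(broad_cna_score(ev, gm, samples), oracle$broad_score)
    expect_equal(focal_cna_score(ev, gm, samples), oracle$focal_score)
  }
})

test_that("adding events never decreases the scores", {
  gm <- toy_model()
  ev <- data.frame(sample = "s1", chrom = "chr1", arm_name = "1p",
                   direction = "gain", breadth = "broad", span_bp = 1,
                   arm_fraction = 0.99)
  more <- rbind(ev, within(ev, breadth <- "focal"))
  expect_gte(broad_cna_score(more, gm)[["s1"]],
             broad_cna_score(ev, gm)[["s1"]])
  expect_gte(focal_cna_score(more, gm)[["s1"]],
             focal_cna_score(ev, gm)[["s1"]])
})

test_that("TMB and fusion scores are the printed ratios", {
  expect_equal(tmb_score(0), 0)
  expect_equal(tmb_score(2990), 2990 / 299.029409, tolerance = 1e-12)
  expect_equal(tmb_score(2990), 9.99902, tolerance = 1e-5)
  k <- c(1, 10, 250)
  expect_equal(tmb_score(2 * k), 2 * tmb_score(k), tolerance = 1e-12)
  expect_error(tmb_score(-1), "nonnegative")
  expect_equal(fusion_score(3, 6), 0.5)
  expect_equal(fusion_score(0, 6), 0)
  expect_error(fusion_score(3, 0), "positive")
})

test_that("CNA frequency profile counts overlapping samples per bin", {
  gm <- toy_model()
  alt <- threshold_segments(data.frame(
    sample = c("s1", "s2"), chrom = "chr1",
    start = c(0, 0), end = c(1e5, 5e4), value = c(0.5, -0.5)))
  prof <- cna_frequency_profile(alt, gm, bin_bp = 1e5,
                                samples = c("s1", "s2"))
  expect_true(all(prof$gain_freq >= 0 & prof$gain_freq <= 1))
  first <- prof[prof$chrom == "chr1" & prof$start == 0, ]
  expect_equal(first$gain_freq, 0.5)
  expect_equal(first$loss_freq, 0.5)
  expect_equal(sum(prof$gain_freq > 0), 1)
  # empty input -> all-zero profile (given an explicit cohort)
  zero <- cna_frequency_profile(alt[0, ], gm, 1e5, samples = "s1")
  expect_true(all(zero$gain_freq == 0 & zero$loss_freq == 0))
  expect_error(cna_frequency_profile(alt[0, ], gm, 1e5), "empty cohort")
})

test_that("frequency profile matches per-bin membership oracle", {
  gm <- generate_arm_model(arms = 6, arm_length_bp = 1e4, n_genes = 50,
                           seed = 4)
  set.seed(11)
  seg <- random_segment_table(gm, 60, n_samples = 5)
  alt <- threshold_segments(seg)
  samples <- paste0("s", 1:5)
  prof <- cna_frequency_profile(alt, gm, bin_bp = 2500, samples = samples)
  for (i in sample(nrow(prof), min(20, nrow(prof)))) {
    b <- prof[i, ]
    for (dir in c("gain", "loss")) {
      hit <- vapply(samples, function(s) {
        any(alt$sample == s & alt$direction == dir &
              alt$chrom == b$chrom & alt$start < b$end &
              alt$end > b$start)
      }, logical(1))
      expect_equal(b[[paste0(dir, "_freq")]], mean(hit))
    }
  }
})

test_that("score correlation matrix is symmetric with unit diagonal", {
  panel <- data.frame(sample = paste0("s", 1:10),
                      a = 1:10, b = (1:10) * 2, c = -(1:10),
                      d = rnorm(10))
  m <- score_correlation_matrix(panel)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(m["a", "b"], 1)
  expect_equal(m["a", "c"], -1)
  expect_true(all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
  # constant column undefined, not zero
  panel$e <- 1
  expect_warning(m2 <- score_correlation_matrix(panel), "constant")
  expect_true(is.na(m2["e", "a"]))
  expect_error(score_correlation_matrix(panel[1:2, ]), "3 samples")
})

test_that("1-based inclusive SEG input is converted on read", {
  f <- tempfile(fileext = ".seg")
  writeLines(c("sample\tchrom\tstart\tend\tvalue",
               "s1\tchr1\t1\t100\t0.5"), f)
  seg0 <- read_seg(f, coords = "0half")
  seg1 <- read_seg(f, coords = "1incl")
  expect_equal(seg0$start, 1)
  expect_equal(seg1$start, 0)
  expect_equal(seg1$end, 100)
})
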