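test_that("window entropy follows the Shannon definition", {
  expect_equal(window_entropy(strrep("S", 10)), 0)
  expect_equal(window_entropy("SGSGSGSGSG"), 1)
  expect_equal(window_entropy("ARNDCQEGHILKMFPSTWYV"), log2(20))
  withr::local_seed(2)
  for (i in 1:5) {
    s <- random_record(30)$sequence
    expect_equal(window_entropy(s), oracle_entropy(s), tolerance = 1e-12)
    # permutation invariance
    perm <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(window_entropy(perm), window_entropy(s))
  }
})

test_that("appending a modal residue never raises window entropy", {
  withr::local_seed(12)
  for (i in 1:10) {
    s <- random_record(sample(10:40, 1))$sequence
    tal <- oracle_tally(s)
    modal <- names(tal)[which.max(tal)]
    expect_lte(window_entropy(paste0(s, modal)), window_entropy(s) + 1e-12)
  }
})

test_that("homopolymers are one full low-complexity segment", {
  segs <- scan_low_complexity(protein_record("p", strrep("S", 100)))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 0L)
  expect_equal(segs$end, 100L)
  expect_equal(segs$score, 0)
  expect_equal(segs$dominant_residues, "S")
})

test_that("balanced high-complexity sequences yield no segments", {
  withr::local_seed(8)
  s <- paste(rep(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 5), collapse = "")
  shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
  # verify premise with the exhaustive window-entropy oracle
  p <- scan_params()
  Hs <- sapply(1:(100 - p$window + 1), function(i)
    oracle_entropy(substr(shuffled, i, i + p$window - 1)))
  expect_true(all(Hs > p$k_extend))
  expect_equal(nrow(scan_low_complexity(protein_record("p", shuffled))), 0)
})

test_that("short sequences warn and return empty scans", {
  expect_warning(segs <- scan_low_complexity(protein_record("p", "SSS")),
                 "shorter than window")
  expect_equal(nrow(segs), 0)
  expect_warning(scan_residue_bias(protein_record("p", "SSS"), "S"),
                 "shorter than window")
})

test_that("low-complexity scan equals the brute-force window oracle", {
  withr::local_seed(101)
  p <- scan_params()
  biased <- c(S = 0.35, G = 0.30, A = 0.05, R = 0.05, H = 0.05, Q = 0.05,
              L = 0.05, E = 0.05, K = 0.05)
  prob <- rep(0.001, 20)
  names(prob) <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  prob[names(biased)] <- biased
  for (i in 1:15) {
    n <- sample(25:200, 1)
    # mix of uniform and compositionally biased draws so segments do occur
    rec <- if (i %% 2 == 0) random_record(n) else
      random_record(n, prob = prob / sum(prob))
    segs <- scan_low_complexity(rec, p)
    orc <- oracle_scan_lc(rec$sequence, p)
    expect_equal(segs[, c("start", "end")], orc,
                 ignore_attr = TRUE)
  }
})

test_that("residue-bias scan equals the brute-force oracle with exact tails", {
  withr::local_seed(202)
  p <- scan_params(window = 15, p_threshold = 1e-4)
  prob <- rep(0.02, 20)
  names(prob) <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  prob[c("G", "S")] <- c(0.25, 0.40)
  for (i in 1:15) {
    n <- sample(15:200, 1)
    rec <- if (i %% 2 == 0) random_record(n) else
      random_record(n, prob = prob / sum(prob))
    segs <- scan_residue_bias(rec, "GS", p)
    orc <- oracle_scan_bias(rec$sequence, "GS", p)
    expect_equal(segs[, c("start", "end")], orc, ignore_attr = TRUE)
  }
})

test_that("binomial tails equal exhaustive pmf summation", {
  for (w in c(5, 10, 20)) for (p0 in c(0.05, 0.1, 0.5)) for (k in 0:w) {
    exact <- oracle_binom_tail(k, w, p0)
    impl <- stats::pbinom(k - 1, w, p0, lower.tail = FALSE)
    expect_equal(impl, exact, tolerance = 1e-10)
  }
})

test_that("an all-target window has the closed-form tail p0^w", {
  p <- scan_params(window = 20, p_threshold = 1e-6,
                   background = {
                     b <- rep(0.05, 20)
                     names(b) <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
                     b
                   })
  rec <- protein_record("s", strrep("S", 60))
  segs <- scan_residue_bias(rec, "S", p)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 0L)
  expect_equal(segs$end, 60L)
  # score is -log10 of the best window tail = -log10(0.05^20)
  expect_equal(segs$score, -20 * log10(0.05), tolerance = 1e-6)
  expect_equal(coverage(segs, 60), 1)
  # queried residue absent -> nothing
  expect_equal(nrow(scan_residue_bias(protein_record("g", strrep("G", 60)),
                                      "S", p)), 0)
  # zero background mass is an error
  b0 <- rep(1 / 19, 20)
  names(b0) <- names(p$background)
  b0[["S"]] <- 0
  expect_error(scan_residue_bias(rec, "S",
                                 scan_params(background = b0 / sum(b0))),
               "background mass")
})

test_that("coverage is the union fraction and rejects overlap", {
  expect_equal(coverage(data.frame(start = 0, end = 50), 100), 0.5)
  expect_equal(coverage(data.frame(start = integer(0), end = integer(0)),
                        100), 0)
  expect_equal(coverage(data.frame(start = c(0, 60), end = c(30, 100)), 100),
               0.7)
  expect_error(coverage(data.frame(start = c(0, 20), end = c(30, 50)), 100),
               "overlap")
  expect_error(coverage(data.frame(start = 0, end = 150), 100), "invalid")
})

test_that("stricter tail thresholds never increase coverage", {
  withr::local_seed(77)
  prob <- rep(0.02, 20)
  names(prob) <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  prob[c("G", "S")] <- c(0.2, 0.35)
  rec <- random_record(300, prob = prob / sum(prob))
  covs <- sapply(c(1e-2, 1e-4, 1e-6, 1e-8), function(pt) {
    segs <- scan_residue_bias(rec, "GS", scan_params(p_threshold = pt))
    coverage(segs, 300)
  })
  expect_true(all(diff(covs) <= 1e-12))
})

test_that("segment sets are idempotent under re-merging", {
  withr::local_seed(55)
  prob <- rep(0.02, 20)
  names(prob) <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  prob[c("G", "S")] <- c(0.25, 0.4)
  rec <- random_record(250, prob = prob / sum(prob))
  for (segs in list(scan_residue_bias(rec, "GS"),
                    scan_low_complexity(rec))) {
    if (nrow(segs) < 1) next
    gap_ok <- all(diff(segs$start) > 0)
    expect_true(gap_ok)
    # gaps between retained segments exceed merge_gap (nothing left to merge)
    if (nrow(segs) > 1)
      expect_true(all(segs$start[-1] - segs$end[-nrow(segs)] >
                        scan_params()$merge_gap))
  }
})
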