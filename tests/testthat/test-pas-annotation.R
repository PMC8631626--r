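end_track <- function(counts_at, iv = genomic_interval("chr1", 0, 500, "+")) {
  counts <- numeric(interval_length(iv))
  counts[as.integer(names(counts_at)) - iv$start] <- counts_at
  end_count_track(iv, counts)
}

test_that("peak calling clusters, discards weak clusters, and picks summits", {
  tr <- end_track(c(`100` = 50, `101` = 30, `150` = 5))
  sites <- call_end_peaks(tr, min_count = 10, merge_window = 10)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$summit, 100)
  expect_equal(sites$total_count, 80)
  expect_equal(attr(sites, "discarded_count"), 5)

  # boundary: a single position exactly at min_count is retained
  one <- call_end_peaks(end_track(c(`200` = 10)), min_count = 10)
  expect_equal(nrow(one), 1)

  # all-zero track -> empty
  empty <- call_end_peaks(end_track(c(`200` = 0)), min_count = 1)
  expect_equal(nrow(empty), 0)
})

test_that("summit ties break toward the most 3' position, strand-aware", {
  plus <- end_track(c(`100` = 20, `103` = 20))
  expect_equal(call_end_peaks(plus, min_count = 1, merge_window = 5)$summit, 103)
  minus <- end_track(c(`100` = 20, `103` = 20),
                     genomic_interval("chr1", 0, 500, "-"))
  expect_equal(call_end_peaks(minus, min_count = 1, merge_window = 5)$summit, 100)
})

test_that("peak calling conserves reads and orders sites 5' to 3'", {
  set.seed(13)
  for (k in 1:20) {
    iv <- genomic_interval("chr1", 0, 300, sample(c("+", "-"), 1))
    counts <- rpois(300, 0.3) * rpois(300, 3)
    tr <- end_count_track(iv, counts)
    sites <- call_end_peaks(tr, min_count = 5, merge_window = 4)
    expect_equal(sum(sites$total_count) + attr(sites, "discarded_count"),
                 sum(counts))
    if (nrow(sites) > 1) {
      d <- diff(sites$summit)
      expect_true(all(if (iv$strand == "-") d < 0 else d > 0))
    }
  }
})

test_that("two planted clusters recover their usage fractions", {
  iv <- genomic_interval("chr1", 0, 2000, "+")
  tr <- simulate_end_seq(c(300, 1500), c(0.8, 0.2), n_reads = 10000,
                         interval = iv, jitter_sd = 2, seed = 99)
  sites <- call_end_peaks(tr, min_count = 10, merge_window = 8)
  expect_equal(nrow(sites), 2)
  frac <- sites$total_count / sum(sites$total_count)
  expect_lt(max(abs(frac - c(0.8, 0.2))), 0.03)
  expect_lt(abs(sites$summit[1] - 300), 3)
})

test_that("PAS scanning reproduces the published hexamer calls", {
  # canonical signal at the distal site
  canon <- scan_pas("GGGAAUAAAGGGGGGGGGGC", 20)
  expect_equal(canon$class, "canonical")
  expect_equal(canon$hexamer, "AAUAAA")
  # the weaker proximal signal is a single-mismatch variant
  var <- scan_pas("GGGAUUAAAGGGGGGGGGGC", 20)
  expect_equal(var$class, "variant")
  expect_equal(var$hexamer, "AUUAAA")
  # the mutated proximal site (two mismatches) is no longer a hit
  none <- scan_pas("GGGAUCAAGGGGGGGGGGGC", 20)
  expect_equal(nrow(none), 0)
})

test_that("PAS scanning treats DNA input as RNA and clips short sequences", {
  dna <- scan_pas("GGGAATAAAGGGGGGGGGGC", 20)
  expect_equal(dna$hexamer, "AAUAAA")
  expect_equal(nrow(scan_pas("AAUAA", 5)), 0)
})

test_that("PAS ordering puts canonical first, then variants nearest the cleavage", {
  seq <- paste0("AAUAAA", "CC", "AUUAAA", "CC", "AAUAAA", "CCCCCCCC")
  hits <- scan_pas(seq, nchar(seq), window_upstream = 40)
  expect_equal(hits$class, c("canonical", "canonical", "variant"))
  expect_true(all(diff(hits$offset[hits$class == "canonical"]) > 0))
})

test_that("PAS scanner agrees exactly with the brute-force oracle", {
  set.seed(23)
  for (k in 1:300) {
    n <- sample(10:200, 1)
    s <- random_rna(n)
    cp <- sample(7:n, 1)
    w <- sample(c(10, 25, 40), 1)
    got <- as.data.frame(scan_pas(s, cp, w))
    want <- oracle_pas(s, cp, w)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("G/U-rich scoring matches hand counts and flags missing sequence", {
  pre <- "AAAA"
  expect_equal(scan_gu_rich(paste0(pre, "UGUGUGUGUG"), 5)$score, 1.0)
  expect_true(scan_gu_rich(paste0(pre, "UGUGUGUGUG"), 5)$gu_rich)
  expect_equal(scan_gu_rich(paste0(pre, "ACACACACAC"), 5)$score, 0.0)
  expect_false(scan_gu_rich(paste0(pre, "ACACACACAC"), 5)$gu_rich)
  hand <- scan_gu_rich(paste0(pre, "UGACUGACUG"), 5)
  expect_equal(hand$score, 0.6)  # 6 of 10 G/U
  expect_true(hand$gu_rich)
  off_end <- scan_gu_rich("AAAAA", 4)
  expect_true(is.na(off_end$score))
  expect_equal(off_end$flag, "no_downstream_sequence")
})

test_that("QKI scanning finds the worked bipartite example", {
  hits <- scan_qki_motif("GGAACUAACGGGGGUAAUGG")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$half1_start, 3)   # 0-based offset 2
  expect_equal(hits$half1_seq, "AACUAAC")
  expect_equal(hits$spacer_len, 5)
  expect_equal(hits$half2_seq, "UAAU")
  expect_equal(hits$half2_start, hits$half1_start + 7 + hits$spacer_len)
  expect_equal(nrow(scan_qki_motif("GGGGCGCGGGGGGC")), 0)
})

test_that("shortest-spacer policy takes one closer; exhaustive takes both", {
  # half1 AACUAAC then UAAU at spacers 3 and 9
  seq <- paste0("AACUAAC", "GGG", "UAAU", "GG", "UAAU", "GGG")
  short <- scan_qki_motif(seq)
  expect_equal(nrow(short), 1)
  expect_equal(short$spacer_len, 3)
  exh <- scan_qki_motif(seq, mode = "exhaustive")
  expect_equal(nrow(exh), 2)
  expect_equal(sort(exh$spacer_len), c(3, 9))
})

test_that("exhaustive QKI scanning agrees exactly with the enumeration oracle", {
  set.seed(29)
  for (k in 1:300) {
    n <- sample(15:250, 1)
    # AU-rich alphabet so half-sites actually occur
    s <- paste(sample(c("A", "C", "U", "U", "A", "G"), n, replace = TRUE),
               collapse = "")
    got <- as.data.frame(scan_qki_motif(s, mode = "exhaustive"))[
      , c("half1_start", "spacer_len", "half2_start")]
    want <- oracle_qki_exhaustive(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("scanning is strand-consistent: motif coordinates mirror under reverse complement", {
  set.seed(31)
  for (k in 1:50) {
    n <- sample(30:120, 1)
    s <- random_rna(n)
    expect_equal(reverse_complement(reverse_complement(s)), s)
    # a motif at 1-based [a, b] on one strand appears as its reverse
    # complement at the mirrored coordinates [n - b + 1, n - a + 1]
    planted <- paste0(random_rna(12), "AAUAAA", random_rna(12))
    hit <- scan_pas(planted, nchar(planted) + 1, 40)
    a <- hit$start[hit$hexamer == "AAUAAA"][1]
    expect_false(is.na(a))
    rc <- reverse_complement(planted)
    mirror_start <- nchar(planted) - (a + 5) + 1
    expect_equal(substr(rc, mirror_start, mirror_start + 5), "UUUAUU")
  }
})

test_that("site annotation maps summits into transcript-oriented sequence", {
  iv <- genomic_interval("chr1", 0, 60, "+")
  counts <- numeric(60); counts[30] <- 40  # genomic position 30
  tr <- end_count_track(iv, counts)
  sites <- call_end_peaks(tr, min_count = 1)
  seq <- paste0(random_rna(20), "AAUAAA", random_rna(3),  # PAS at 21..26
                "UGUGUGUGUGUG", random_rna(19))
  seq <- substr(seq, 1, 60)
  ann <- annotate_cleavage_sites(sites, seq, iv)
  expect_equal(ann$seq_pos, 30)
  expect_equal(ann$pas_hexamer, "AAUAAA")
  expect_equal(ann$pas_class, "canonical")
  expect_true(ann$gu_rich)
})
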