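make_track <- function(spec, prox_depth, dist_depth, gap_depth = 0) {
  lo <- min(spec$proximal$start, spec$distal$start)
  hi <- max(spec$proximal$end, spec$distal$end)
  iv <- genomic_interval(spec$proximal$chrom, lo, hi, spec$strand)
  depth <- rep(gap_depth, hi - lo)
  pos0 <- lo + seq_len(hi - lo) - 1
  depth[pos0 >= spec$proximal$start & pos0 < spec$proximal$end] <- prox_depth
  depth[pos0 >= spec$distal$start & pos0 < spec$distal$end] <- dist_depth
  coverage_track(iv, depth)
}

test_that("the distal ratio matches hand-computed values", {
  spec <- toy_spec()
  expect_equal(compute_distal_ratio(make_track(spec, 10, 0), spec)$ratio, 0)
  expect_equal(compute_distal_ratio(make_track(spec, 5, 5), spec)$ratio, 0.5)
  # proximal mean 100 reads/base, distal mean 5 -> 5/105
  expect_equal(compute_distal_ratio(make_track(spec, 100, 5), spec)$ratio,
               5 / 105, tolerance = 1e-12)
})

test_that("zero coverage in both regions yields a missing ratio", {
  spec <- toy_spec()
  sr <- compute_distal_ratio(make_track(spec, 0, 0, gap_depth = 3), spec)
  expect_true(is.na(sr$ratio))
})

test_that("the ratio is exactly scale invariant and bounded", {
  spec <- toy_spec()
  set.seed(3)
  for (k in 1:20) {
    p <- sample(0:200, 1); d <- sample(0:200, 1)
    if (p + d == 0) next
    r1 <- compute_distal_ratio(make_track(spec, p, d), spec)$ratio
    for (c_mult in c(2L, 7L, 100L)) {
      rc <- compute_distal_ratio(make_track(spec, c_mult * p, c_mult * d),
                                 spec)$ratio
      expect_identical(rc, r1)
    }
    expect_gte(r1, 0); expect_lte(r1, 1)
  }
})

test_that("cohort comparison reproduces the exactly-enumerated rank test", {
  # all 20 orderings of 3-vs-3 put {0.05,0.06,0.08} vs {0.02,0.03,0.04} at
  # the extreme: two-sided exact p = 2/20 = 0.1
  cc <- compare_cohorts(c(0.05, 0.06, 0.08), c(0.02, 0.03, 0.04))
  expect_equal(cc$fold_change, 2)
  expect_equal(cc$p_value, 0.1)

  same <- compare_cohorts(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)
})

test_that("swapping cohort labels inverts the fold and keeps the p-value", {
  set.seed(5)
  a <- rbeta(12, 2, 30); b <- rbeta(9, 2, 20)
  ab <- compare_cohorts(a, b); ba <- compare_cohorts(b, a)
  expect_equal(ab$fold_change, 1 / ba$fold_change)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("missing ratios are dropped listwise and empty groups error", {
  cc <- compare_cohorts(c(0.2, NA, 0.3), c(0.1, 0.15))
  expect_equal(cc$n_case, 2)
  expect_error(compare_cohorts(c(NA_real_), c(0.1)), "empty")
})

test_that("a zero control median reports a median difference instead of a fold", {
  cc <- compare_cohorts(c(0.2, 0.3), c(0, 0, 0))
  expect_true(is.na(cc$fold_change))
  expect_equal(cc$median_difference, 0.25)
})

test_that("stratified comparison finds only the stratum with a planted shift", {
  set.seed(21)
  n <- 40
  tab <- data.frame(
    sample_id = sprintf("s%02d", 1:(4 * n)),
    group = rep(c("case", "control"), each = 2 * n),
    genotype = rep(rep(c("MM", "MZ"), each = n), 2))
  ratio <- rbeta(4 * n, 5, 95)
  shifted <- tab$group == "case" & tab$genotype == "MZ"
  ratio[shifted] <- rbeta(sum(shifted), 5, 95) * 2.5
  res <- stratified_compare(data.frame(sample_id = tab$sample_id, ratio = ratio),
                            tab, "genotype")
  wc <- res$within_case
  expect_equal(wc$stratum, "MZ")
  expect_equal(wc$reference, "MM")
  expect_lt(wc$p_value, 0.01)
  per <- res$per_stratum
  expect_lt(per$p_value[per$stratum == "MZ"],
            per$p_value[per$stratum == "MM"])
})

test_that("stratified comparison handles the published genotype imbalance", {
  set.seed(8)
  sizes <- list(MM = c(284, 210), MS = c(20, 14), MZ = c(16, 8), ZZ = c(7, 1))
  rows <- do.call(rbind, lapply(names(sizes), function(g) {
    data.frame(genotype = g,
               group = rep(c("case", "control"), sizes[[g]]))
  }))
  rows$sample_id <- sprintf("s%03d", seq_len(nrow(rows)))
  ratios <- data.frame(sample_id = rows$sample_id,
                       ratio = rbeta(nrow(rows), 5, 95))
  res <- stratified_compare(ratios, rows, "genotype")
  per <- res$per_stratum
  expect_setequal(per$stratum, names(sizes))
  expect_true(per$low_power[per$stratum == "ZZ"])
  expect_false(per$low_power[per$stratum == "MM"])
})

test_that("unknown stratum values collapse to 'other' with a warning", {
  tab <- data.frame(sample_id = c("a", "b", "c", "d"),
                    group = c("case", "case", "control", "control"),
                    genotype = c("MM", "XX", "MM", "XX"))
  ratios <- data.frame(sample_id = tab$sample_id, ratio = c(0.1, 0.2, 0.1, 0.2))
  expect_warning(res <- stratified_compare(ratios, tab, "genotype",
                                           known_levels = c("MM", "MS", "MZ", "ZZ")),
                 "other")
  expect_true("other" %in% res$per_stratum$stratum)
})

test_that("the stage trend test behaves at its boundaries and under permutation", {
  expect_equal(trend_test(c(0.1, 0.2, 0.3, 0.4), c(1, 2, 3, 4))$rho, 1)
  expect_error(trend_test(c(0.1, 0.2, 0.3), c(2, 2, 2)), "distinct")
  deg <- trend_test(rep(0.2, 9), rep(1:3, 3))
  expect_equal(deg$rho, 0); expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)

  # shuffled stages should rarely reach nominal significance
  set.seed(17)
  hits <- 0
  n_perm <- 400
  r <- rbeta(30, 5, 95)
  stages <- rep(0:4, 6)
  for (k in 1:n_perm) {
    tt <- trend_test(r, sample(stages))
    if (tt$p_value < 0.05) hits <- hits + 1
  }
  expect_lt(hits / n_perm, 0.1)
})

test_that("fraction summaries give the nuclear/cytoplasmic fold", {
  fc <- fraction_compare(c(0.4, 0.5, 0.1, 0.1),
                         c("nuclear", "nuclear", "cytoplasmic", "cytoplasmic"))
  expect_equal(fc$nuclear_cytoplasmic_fold, 4.5)
  one <- fraction_compare(c(0.2, 0.2), c("nuclear", "nuclear"))
  expect_true(is.na(one$nuclear_cytoplasmic_fold))
  expect_equal(nrow(one$summary), 1)
  eq <- fraction_compare(c(0.3, 0.3), c("nuclear", "cytoplasmic"))
  expect_equal(eq$nuclear_cytoplasmic_fold, 1)
})

test_that("single-cell ratios use the length-normalized formula per cell", {
  spec <- serpina1_region_spec()  # Lp = 79, Ld = 1602
  counts <- data.frame(proximal = c(5, 5, 1), distal = c(0, 2, 0))
  rownames(counts) <- c("c1", "c2", "c3")
  res <- single_cell_ratios(counts, c("A", "A", "B"), spec,
                            min_total_reads = 1)
  expect_equal(res$cells$ratio[res$cells$cell_id == "c1"], 0)
  expected <- (2 / 1602) / ((2 / 1602) + (5 / 79))
  expect_equal(res$cells$ratio[res$cells$cell_id == "c2"], expected,
               tolerance = 1e-12)
  # hand value quoted for a 1622-base distal segment
  spec2 <- region_spec("toy2",
                       genomic_interval("chr1", 0, 79, "+"),
                       genomic_interval("chr1", 100, 1722, "+"))
  res2 <- single_cell_ratios(data.frame(proximal = 5, distal = 2), "A",
                             spec2, min_total_reads = 1)
  expect_equal(res2$cells$ratio, 0.01911, tolerance = 1e-3)
})

test_that("single-cell filtering excludes cells, warns on empty clusters", {
  counts <- data.frame(proximal = c(5, 1), distal = c(5, 0))
  expect_warning(res <- single_cell_ratios(counts, c("A", "B"),
                                           min_total_reads = 3),
                 "B")
  expect_equal(nrow(res$cells), 1)
  expect_warning(res0 <- single_cell_ratios(counts, c("A", "B"),
                                            min_total_reads = 100),
                 "no cells")
  expect_equal(nrow(res0$cells), 0)
})

test_that("pooled cluster ratios sum counts before normalizing", {
  spec <- toy_spec()  # Lp = 50, Ld = 200
  counts <- data.frame(proximal = c(10, 30), distal = c(20, 20))
  res <- single_cell_ratios(counts, c("A", "A"), spec, min_total_reads = 1)
  dn <- (40 / 200); pn <- (40 / 50)
  expect_equal(res$clusters$pooled_ratio, dn / (dn + pn))
})
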