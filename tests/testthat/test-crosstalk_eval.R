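# Evaluation metrics: reference matching, contamination reports, diversity,
# dissimilarity, rarefaction, filtering and composition correlation.

test_that("match_to_reference applies the one-mismatch rule", {
  ref <- fix_mock(4, len = 50)
  expect_identical(match_to_reference(ref$seq[2], ref), ref$variant_id[2])

  set.seed(11)
  mut1 <- mutate_string(ref$seq[3], 1)
  expect_identical(match_to_reference(mut1, ref), ref$variant_id[3])

  mut3 <- mutate_string(ref$seq[1], 3)
  expect_true(is.na(match_to_reference(mut3, ref)))

  # length-mismatched sequences are spurious
  expect_true(is.na(match_to_reference(substr(ref$seq[1], 1, 30), ref)))
})

test_that("spurious_report counts contaminants and negative controls", {
  ref <- fix_mock(4, len = 50)
  foreign <- strrep("A", 50)
  tab <- matrix(0L, 5, 3,
                dimnames = list(c(ref$seq, foreign),
                                c("mock1", "mock2", "NC1")))
  tab[1:4, "mock1"] <- c(2000L, 300L, 100L, 38L)
  tab[1:4, "mock2"] <- c(2100L, 233L, 80L, 20L)
  tab[foreign, "mock2"] <- 5L

  rep0 <- spurious_report(tab[, , drop = FALSE], ref,
                          negative_control_ids = "NC1")
  lib <- rep0$libraries
  expect_identical(lib$n_spurious[lib$sample_id == "mock1"], 0L)
  expect_identical(lib$n_spurious[lib$sample_id == "mock2"], 1L)
  expect_equal(lib$fraction_spurious_reads[lib$sample_id == "mock2"],
               5 / 2438)
  expect_identical(rep0$negative_controls$n_detected, 0L)

  tab[foreign, "NC1"] <- 2L
  rep1 <- spurious_report(tab, ref, "NC1")
  expect_identical(rep1$negative_controls$n_detected, 1L)

  expect_error(spurious_report(tab, ref, "nope"), "unknown")
})

test_that("observed richness and Chao1 follow the stated formulas", {
  expect_identical(observed_richness(c(5, 1, 1, 2)), 4L)
  expect_equal(chao1(c(5, 1, 1, 2)), 4.5)
  expect_equal(chao1(c(5, 3, 2, 2)), 4)   # no singletons
  expect_identical(observed_richness(numeric(4) + 0), 0L)
  expect_equal(chao1(rep(0, 4)), 0)
  expect_error(chao1(c(1, -1)), "non-negative")

  # chao1 >= observed always; equality iff f1 <= 1; vegan as oracle
  set.seed(21)
  for (i in 1:20) {
    x <- rpois(30, 1.2)
    expect_gte(chao1(x), observed_richness(x))
    f1 <- sum(x == 1)
    if (f1 <= 1) expect_equal(chao1(x), observed_richness(x) + 0)
    expect_equal(chao1(x), unname(vegan::estimateR(x)["S.chao1"]))
  }
})

test_that("bray_curtis is a bounded semimetric with the stated form", {
  expect_equal(bray_curtis(c(2, 1, 0), c(0, 1, 3)), 5 / 7)
  expect_equal(bray_curtis(c(3, 2), c(3, 2)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 5)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(31)
  for (i in 1:15) {
    x <- rpois(10, 3); y <- rpois(10, 3)
    if (sum(x + y) == 0) next
    d <- bray_curtis(x, y)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(y, x))
    expect_equal(d, unname(as.vector(vegan::vegdist(rbind(x, y),
                                                    method = "bray"))))
  }
})

test_that("rarefy subsamples without replacement", {
  x <- c(10, 5, 0, 25)
  expect_identical(rarefy(x, 40, seed = 1), as.integer(x))
  expect_identical(rarefy(x, 0, seed = 1), rep(0L, 4))
  expect_error(rarefy(x, 41), "between 0 and")

  r <- rarefy(x, 20, seed = 3)
  expect_identical(sum(r), 20L)
  expect_true(all(r <= x))
  expect_identical(rarefy(x, 20, seed = 3), r)

  # hypergeometric mean: E[first] = depth/2 for (1000, 1000) at depth 1000
  firsts <- vapply(1:200, function(s) rarefy(c(1000, 1000), 1000, seed = s)[1],
                   integer(1))
  se <- sqrt(1000 * 0.5 * 0.5 * (1000 / 1999)) / sqrt(200)
  expect_lt(abs(mean(firsts) - 500), 4 * se)
})

test_that("abundance_filter uses a strictly-exceeds rule", {
  # column totals 1000 each: 0.30% exceeds in s1, 0.20% never does
  tab <- cbind(s1 = c(3L, 2L, 995L), s2 = c(2L, 2L, 996L))
  rownames(tab) <- c("row_030pct", "row_020pct", "bulk")
  f <- abundance_filter(tab, 0.0025)
  expect_identical(rownames(f), c("row_030pct", "bulk"))

  # exactly at the threshold is dropped
  tab2 <- rbind(at = c(25L, 0L), rest = c(9975L, 100L))
  colnames(tab2) <- c("a", "b")
  expect_false("at" %in% rownames(abundance_filter(tab2, 0.0025)))

  # threshold 0 only drops all-zero rows
  tab3 <- rbind(z = c(0L, 0L), nz = c(1L, 0L))
  colnames(tab3) <- c("a", "b")
  expect_identical(rownames(abundance_filter(tab3, 0)), "nz")
})

test_that("expected_vs_measured correlates log abundances per pool", {
  ref <- fix_mock(6, len = 40)      # 3 species x 2 variants
  # measured exactly proportional to expected -> r = 1
  counts <- round(ref$abundance * 1e5)
  tab <- matrix(as.integer(counts), ncol = 1,
                dimnames = list(ref$seq, "m1"))
  r <- expected_vs_measured(tab, ref, pools = list(p1 = "m1"))
  expect_equal(unname(r$per_pool["p1"]), 1, tolerance = 1e-6)
  expect_equal(r$mean_r, 1, tolerance = 1e-6)

  # reversed ranking on a log-spaced mock -> negative r
  tab_rev <- matrix(as.integer(rev(counts)), ncol = 1,
                    dimnames = list(ref$seq, "m1"))
  r_rev <- expected_vs_measured(tab_rev, ref, pools = list(p1 = "m1"))
  expect_lt(r_rev$mean_r, 0)

  # single detected member -> pool skipped with a warning
  tab_one <- matrix(c(50L, rep(0L, 5)), ncol = 1,
                    dimnames = list(ref$seq, "m1"))
  expect_warning(r_one <- expected_vs_measured(tab_one, ref,
                                               pools = list(p1 = "m1")),
                 "skipped")
  expect_true(is.na(r_one$mean_r))

  # member exclusion removes a species from the correlation
  r_ex <- expected_vs_measured(tab, ref, pools = list(p1 = "m1"),
                               exclude_members = "sp03")
  expect_equal(unname(r_ex$per_pool["p1"]), 1, tolerance = 1e-6)
})

test_that("count tables round-trip through TSV", {
  tab <- cbind(s1 = c(5L, 0L, 2L), s2 = c(1L, 3L, 0L))
  rownames(tab) <- c("ACGT", "TTTT", "GGGG")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tab, tf)
  expect_identical(read_count_table(tf), tab)
})
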