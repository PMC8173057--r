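# Mock-community composition sampling, read construction and injection of
# substitution errors and barcode-swap events.

test_that("simulate_mock_counts draws seeded multinomials", {
  ref <- fix_mock(6)
  m <- simulate_mock_counts(ref, size = 2438, reps = 20, seed = 4)
  expect_identical(dim(m), c(6L, 20L))
  expect_true(all(colSums(m) == 2438))

  # single variant at p = 1
  one <- mock_reference(data.frame(variant_id = "v", species = "s",
                                   seq = "ACGT", abundance = 1))
  expect_equal(as.vector(simulate_mock_counts(one, 50, 3, seed = 1)),
               rep(50, 3))

  # binomial moments for p = (0.5, 0.5)
  half <- mock_reference(data.frame(variant_id = c("a", "b"),
                                    species = c("a", "b"),
                                    seq = c("AAAA", "TTTT"),
                                    abundance = c(0.5, 0.5)))
  mm <- simulate_mock_counts(half, size = 10000, reps = 100, seed = 2)
  expect_lt(abs(mean(mm[1, ]) - 5000), 3 * sqrt(10000 * 0.25))

  expect_identical(simulate_mock_counts(ref, 100, 5, seed = 9),
                   simulate_mock_counts(ref, 100, 5, seed = 9))
})

test_that("mock_reference validates abundances and the synthetic mock is sane", {
  expect_error(mock_reference(data.frame(variant_id = "v", species = "s",
                                         seq = "ACGT", abundance = 0.9)),
               "sum to 1")
  z <- synthetic_zymo_mock(seed = 2, insert_length = 100)
  expect_s3_class(z, "mock_reference")
  expect_equal(sum(z$abundance), 1, tolerance = 1e-12)
  expect_identical(length(unique(z$species)), 8L)
  expect_true(all(nchar(z$seq) == 100))
  # log-ladder: dominant species ~10x the next
  agg <- sort(tapply(z$abundance, z$species, sum), decreasing = TRUE)
  expect_gt(agg[1] / agg[2], 5)

  # FASTA + TSV round trip
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_mock_reference(z, fa, tsv)
  back <- read_mock_reference(fa, tsv)
  expect_identical(back$seq, z$seq)
  expect_equal(back$abundance, z$abundance, tolerance = 1e-9)
})

test_that("build_read_pair composes the construct and round-trips", {
  bs <- fix_barcode_set(6)
  insert <- strrep("ACGGT", 25)
  set.seed(3)
  rp <- build_read_pair(insert, bs$seq[1], bs$seq[2], "UDB_H12", "V4", "A")
  expect_identical(substr(rp$r1, 1, 12), bs$seq[1])
  expect_identical(substr(rp$r1, 13, 28), head_sequences()[["H1"]])
  expect_identical(substr(rp$r2, 1, 12), bs$seq[2])
  expect_identical(substr(rp$r2, 13, 28), head_sequences()[["H2"]])

  rpB <- build_read_pair(insert, bs$seq[1], bs$seq[2], "UDB_H12", "V4", "B")
  expect_identical(substr(rpB$r1, 13, 28), head_sequences()[["H2"]])
  expect_identical(substr(rpB$r2, 13, 28), head_sequences()[["H1"]])

  p <- parse_read_start(rp$r2, "UDB_H12", "rev")
  expect_identical(p$category, "ok")
  expect_identical(p$barcode, bs$seq[2])
  # reverse-side insert is the reverse complement of the template
  expect_identical(substr(rp$r2, p$insert_from, nchar(rp$r2)),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(insert))))

  expect_error(build_read_pair("", bs$seq[1], bs$seq[2]), "non-empty")
})

test_that("inject_errors follows the binomial substitution model", {
  reads <- list(r1 = rep(strrep("ACGT", 25), 50),
                r2 = rep(strrep("TGCA", 25), 50))
  id <- inject_errors(reads, 0, seed = 1)
  expect_identical(id$r1, reads$r1)
  expect_identical(sum(id$n_sub_r1), 0L)

  all_mut <- inject_errors(reads, 1, seed = 1)
  expect_true(all(mapply(function(a, b) hamming(a, b) == nchar(a),
                         all_mut$r1, reads$r1)))

  # 1e5 bases at eps = 0.01: observed substitutions near 1000
  big <- list(r1 = rep(strrep("A", 1000), 50), r2 = rep(strrep("C", 1000), 50))
  got <- inject_errors(big, 0.01, seed = 8)
  n_obs <- sum(got$n_sub_r1) + sum(got$n_sub_r2)
  expect_lt(abs(n_obs - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))
  # manifest edit counts agree with sequence differences
  expect_identical(unname(mapply(hamming, got$r1, big$r1)),
                   got$n_sub_r1)

  expect_error(inject_errors(reads, 1.2), "\\[0, 1\\]")
})

test_that("inject_crosstalk swaps one side to a foreign in-use barcode", {
  sheet <- fix_sheet("UDB_H12", 6, k = 12)
  ref <- fix_mock(4, len = 60)
  cfg0 <- sim_config(sheet, ref, reads_per_sample = 80, seed = 31)
  sim <- simulate_reads(cfg0)

  pairs <- list(r1 = sim$r1, r2 = sim$r2, manifest = sim$manifest)
  same <- inject_crosstalk(pairs, 0, sheet, seed = 2)
  expect_identical(same$r1, sim$r1)
  expect_false(any(same$manifest$swap))

  swapped <- inject_crosstalk(pairs, 1, sheet, seed = 2)
  expect_true(all(swapped$manifest$swap))
  # exactly one side's barcode is foreign, and belongs to another sample
  mf <- swapped$manifest
  for (i in seq_len(20)) {
    row <- match(mf$sample_id[i], sheet$sample_id)
    r1bc <- substr(swapped$r1[i], 1, 12)
    r2bc <- substr(swapped$r2[i], 1, 12)
    own <- if (mf$orientation[i] == "A") c(sheet$bc1_seq[row], sheet$bc2_seq[row])
           else c(sheet$bc2_seq[row], sheet$bc1_seq[row])
    expect_identical(sum(c(r1bc, r2bc) != own), 1L)
    expect_true(mf$swap_bc[i] %in% c(sheet$bc1_seq, sheet$bc2_seq))
    # the replacement differs from the barcode it displaced
    side_own <- if (mf$swap_side[i] == 1L) sheet$bc1_seq[row] else sheet$bc2_seq[row]
    expect_false(mf$swap_bc[i] == side_own)
  }

  one_sample <- sheet[1, ]
  expect_error(inject_crosstalk(pairs, 0.5, one_sample), "at least 2")
})

test_that("simulate_run is reproducible and truth matches the manifest", {
  sheet <- fix_sheet("UDB_H11", 4, k = 10)
  ref <- fix_mock(5, len = 60)
  cfg <- sim_config(sheet, ref, reads_per_sample = 60, error_rate = 0.005,
                    crosstalk_rate = 0.05, seed = 17,
                    blank_samples = "S04")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- simulate_run(cfg, d1)
  p2 <- simulate_run(cfg, d2)
  expect_identical(readLines(gzfile(p1$r1)), readLines(gzfile(p2$r1)))
  expect_identical(readLines(gzfile(p1$r2)), readLines(gzfile(p2$r2)))
  expect_identical(p1$sim$manifest, p2$sim$manifest)

  sim <- p1$sim
  # blank sample emits nothing but stays a truth column
  expect_identical(sum(sim$manifest$sample_id == "S04"), 0L)
  expect_true("S04" %in% colnames(sim$truth))
  expect_identical(sum(sim$truth[, "S04"]), 0L)
  # truth table is exactly the manifest aggregation
  agg <- table(sim$manifest$variant, sim$manifest$sample_id)
  expect_identical(sum(sim$truth), length(sim$r1))
  for (v in rownames(agg)) for (s in colnames(agg)) {
    expect_identical(sim$truth[v, s], as.integer(agg[v, s]))
  }
})
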