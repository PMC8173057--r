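# Mismatch-tolerant matching, read anatomy parsing and end-to-end demux.

test_that("match_barcode tolerates mismatches and rejects ties", {
  bs <- fix_barcode_set(10)
  exact <- match_barcode(bs$seq[3], bs, max_mm = 1)
  expect_identical(exact$status, "matched")
  expect_identical(exact$seq, bs$seq[3])
  expect_identical(exact$mm, 0L)

  # distance-1 mutant is unique when set min distance >= 3 (triangle ineq.)
  expect_gte(distance_profile(bs)$min, 4L)
  set.seed(1)
  mut <- mutate_string(bs$seq[5], 1)
  m <- match_barcode(mut, bs, max_mm = 1)
  expect_identical(m$status, "matched")
  expect_identical(m$seq, bs$seq[5])

  amb <- match_barcode("AATT", barcode_set(c("AAAA", "TTTT")), max_mm = 2)
  expect_identical(amb$status, "ambiguous")

  none <- match_barcode(strrep("A", 12), bs, max_mm = 1)
  expect_true(none$status %in% c("none", "matched")) # depends on set
  expect_identical(match_barcode("AAA", bs, 1)$status, "structural")
})

test_that("no single-substitution error can switch barcodes (min dist >= 3)", {
  bs <- fix_barcode_set(15)
  expect_gte(distance_profile(bs)$min, 3L)
  for (i in seq_len(nrow(bs))) {
    chars <- strsplit(bs$seq[i], "")[[1]]
    for (p in seq_along(chars)) {
      for (b in setdiff(c("A", "C", "G", "T"), chars[p])) {
        mut <- chars
        mut[p] <- b
        m <- match_barcode(paste(mut, collapse = ""), bs, max_mm = 1)
        expect_identical(m$status, "matched")
        expect_identical(m$seq, bs$seq[i])
      }
    }
  }
})

test_that("match_iupac expands degenerate bases", {
  # 515F with C at the Y position and A at the M position
  obs <- "GTGCCAGCAGCCGCGGTAA"
  m <- match_iupac("GTGYCAGCMGCCGCGGTAA", obs, max_mm = 2)
  expect_true(m$ok)
  expect_identical(m$mm, 0L)

  same <- match_iupac("ACGT", "ACGT", 0)
  expect_identical(same$mm, 0L)

  fail <- match_iupac("AC", "TG", 1)
  expect_false(fail$ok)
  expect_identical(fail$mm, 2L)

  expect_error(match_iupac("AXC", "AAC", 1), "invalid IUPAC")
})

test_that("parse_read_start anchors barcode/head/primer and trims", {
  bs <- fix_barcode_set(6)
  insert <- strrep("ACGT", 30)
  rp <- build_read_pair(insert, bs$seq[1], bs$seq[2], "UDB_H12", "V4",
                        orientation = "A")
  p <- parse_read_start(rp$r1, "UDB_H12", "fwd")
  expect_identical(p$category, "ok")
  expect_identical(p$barcode, bs$seq[1])
  expect_identical(p$insert_from, 12L + 16L + 19L + 1L) # insert offset 47
  expect_identical(substr(rp$r1, p$insert_from, nchar(rp$r1)), insert)

  # three substitutions in the head exceed tolerance 2
  bad <- rp$r1
  substr(bad, 13, 15) <- "NNN"
  expect_identical(parse_read_start(bad, "UDB_H12", "fwd")$category,
                   "head_mismatch")

  short <- substr(rp$r1, 1, 40)
  expect_identical(parse_read_start(short, "UDB_H12", "fwd")$category,
                   "structural")
})

test_that("demultiplex_pair round-trips and exposes the CDB crosstalk risk", {
  bs <- fix_barcode_set(12)
  insert <- strrep("TTGCA", 20)

  u12 <- assign_samples("UDB_H12", paste0("s", 1:4), bs, seed = 3)
  dec <- build_decoder(u12)
  set.seed(5)
  rp <- build_read_pair(insert, u12$bc1_seq[1], u12$bc2_seq[1], "UDB_H12")
  out <- demultiplex_pair(rp, dec)
  expect_identical(out$category, "assigned")
  expect_identical(out$sample_id, "s1")
  expect_identical(out$orientation, "A")
  expect_identical(out$insert_fwd, insert)

  # orientation B still decodes
  rpB <- build_read_pair(insert, u12$bc1_seq[1], u12$bc2_seq[1], "UDB_H12",
                         orientation = "B")
  outB <- demultiplex_pair(rpB, dec)
  expect_identical(outB$sample_id, "s1")
  expect_identical(outB$orientation, "B")

  # r2 barcode swapped to another sample's H2 barcode -> invalid_combination
  swapped <- build_read_pair(insert, u12$bc1_seq[1], u12$bc2_seq[2],
                             "UDB_H12")
  expect_identical(demultiplex_pair(swapped, dec)$category,
                   "invalid_combination")

  # on a fully-used CDB sheet the same swap lands in another sample
  bs4 <- barcode_set(bs$seq[1:4])
  cdb <- assign_samples("CDB_H12", paste0("c", 1:12), bs4, seed = 3)
  dcd <- build_decoder(cdb)
  for (i in c(1, 5, 9)) {
    other_bc2 <- setdiff(cdb$bc2_seq, c(cdb$bc2_seq[i], cdb$bc1_seq[i]))[1]
    sw <- build_read_pair(insert, cdb$bc1_seq[i], other_bc2, "CDB_H12")
    res <- demultiplex_pair(sw, dcd)
    expect_identical(res$category, "assigned")
    expect_false(identical(res$sample_id, cdb$sample_id[i]))
    victim <- cdb$sample_id[cdb$bc1_seq == cdb$bc1_seq[i] &
                              cdb$bc2_seq == other_bc2]
    expect_identical(res$sample_id, victim)
  }
})

test_that("SB demux uses both read barcodes", {
  sb <- fix_sheet("SB", 4, k = 12)
  dec <- build_decoder(sb)
  insert <- strrep("GATTACA", 15)
  set.seed(9)
  rp <- build_read_pair(insert, sb$bc1_seq[2], scheme = "SB")
  expect_identical(demultiplex_pair(rp, dec)$sample_id, sb$sample_id[2])

  # disagreeing barcode on the other end -> invalid_combination
  rp2 <- rp
  substr(rp2$r2, 1, 12) <- sb$bc1_seq[3]
  expect_identical(demultiplex_pair(rp2, dec)$category,
                   "invalid_combination")
})

test_that("run_demux writes per-sample FASTQ and conserves categories", {
  sheet <- fix_sheet("UDB_H12", 6, k = 12)
  ref <- fix_mock(5, len = 90)
  outdir <- withr::local_tempdir()
  cfg <- sim_config(sheet, ref, reads_per_sample = 120,
                    error_rate = 0.01, seed = 21,
                    blank_samples = "S06")
  paths <- simulate_run(cfg, file.path(outdir, "sim"))
  stats <- run_demux(paths$r1, paths$r2, sheet,
                     outdir = file.path(outdir, "demux"),
                     write_unassigned = TRUE)
  expect_identical(stats$total, 600L)
  expect_identical(sum(unlist(stats$categories)), stats$total)
  expect_identical(stats$per_sample$S06, 0L)

  # at this error rate nearly everything is still assigned correctly
  asg <- stats$assignments
  ok <- asg$category == "assigned"
  mf <- paths$sim$manifest[match(asg$read_id[ok], paths$sim$manifest$read_id), ]
  expect_identical(asg$sample_id[ok], mf$sample_id)

  # trimmed per-sample FASTQ exists and re-reads
  f <- file.path(outdir, "demux", "S01_R1.fastq.gz")
  expect_true(file.exists(f))
  back <- read_fastq(f)
  expect_identical(length(back$seq), stats$per_sample$S01)
  expect_true(file.exists(file.path(outdir, "demux", "demux_stats.json")))

  # desynchronized input is fatal with a record index
  r2 <- read_fastq(paths$r2)
  trunc <- file.path(outdir, "trunc_R2.fastq.gz")
  write_fastq(r2$id[-1], r2$seq[-1], r2$qual[-1], trunc)
  expect_error(run_demux(paths$r1, trunc, sheet, outdir = NULL),
               "desynchronized")
  shuf <- file.path(outdir, "shuf_R2.fastq.gz")
  write_fastq(rev(r2$id), rev(r2$seq), rev(r2$qual), shuf)
  expect_error(run_demux(paths$r1, shuf, sheet, outdir = NULL),
               "desynchronized pair files at record 1")
})

test_that("error-free simulation demultiplexes losslessly with trimming", {
  for (scheme in c("UDB_H11", "CDB_H12")) {
    k <- if (scheme == "UDB_H11") 20 else 6
    n <- 8
    sheet <- fix_sheet(scheme, n, k = k)
    ref <- fix_mock(4, len = 70)
    cfg <- sim_config(sheet, ref, reads_per_sample = 100, seed = 13)
    sim <- simulate_reads(cfg)
    res <- demux_read_pairs(sim$r1, sim$r2, build_decoder(sheet),
                            demux_params(), sim$q1, sim$q2)
    expect_true(all(res$category == "assigned"))
    expect_identical(res$sample_id, sim$manifest$sample_id)
    # trimmed insert equals the template (forward side)
    tmpl <- ref$seq[match(sim$manifest$variant, ref$variant_id)]
    expect_identical(res$insert_fwd, tmpl)
    expect_identical(res$insert_rev,
                     as.character(Biostrings::reverseComplement(
                       Biostrings::DNAStringSet(tmpl))))
  }
})
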