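# Mismatch-tolerant, orientation-aware demultiplexing of paired-end reads.
#
# Read layout on each end: [barcode][16-nt head][target primer][insert].
# Matching is anchored at position 0 and indel-free (Hamming mode); the
# defaults tolerate 1 barcode mismatch and 2 head/primer mismatches.

DEMUX_CATEGORIES <- c("assigned", "unknown_barcode", "invalid_combination",
                      "head_mismatch", "primer_mismatch", "ambiguous",
                      "structural")

# Progress rank used to merge the two orientation attempts: report the
# category from the orientation that got furthest through the read anatomy.
.CAT_RANK <- c(structural = 0, head_mismatch = 1, primer_mismatch = 2,
               unknown_barcode = 3, ambiguous = 4, invalid_combination = 5,
               assigned = 6)

#' Demultiplexing parameters
#'
#' @param max_mm_barcode Maximum barcode mismatches (default 1).
#' @param max_mm_head Maximum head-sequence mismatches (default 2).
#' @param max_mm_primer Maximum primer mismatches (default 2).
#' @param try_both_orientations Try both read orientations (r1 = forward side
#'   and r1 = reverse side)? Default `TRUE`; dual-head reads from
#'   ligation-based libraries come in both orientations.
#' @return A `demux_params` list.
#' @export
demux_params <- function(max_mm_barcode = 1L, max_mm_head = 2L,
                         max_mm_primer = 2L, try_both_orientations = TRUE) {
  p <- list(max_mm_barcode = as.integer(max_mm_barcode),
            max_mm_head = as.integer(max_mm_head),
            max_mm_primer = as.integer(max_mm_primer),
            try_both_orientations = isTRUE(try_both_orientations))
  if (any(unlist(p[1:3]) < 0L)) {
    stop("mismatch tolerances must be >= 0", call. = FALSE)
  }
  class(p) <- "demux_params"
  p
}

.check_params_vs_set <- function(params, decoder) {
  for (side in c("side1", "side2")) {
    set <- decoder[[side]]
    if (nrow(set) >= 2L) {
      md <- distance_profile(set)$min
      if (params$max_mm_barcode >= ceiling(md / 2)) {
        warning(sprintf(
          "max_mm_barcode=%d may be ambiguous for a set with min distance %d",
          params$max_mm_barcode, md), call. = FALSE)
        break
      }
    }
  }
  invisible(NULL)
}

#' Match an observed barcode against a set with mismatch tolerance
#'
#' Returns the unique set member within `max_mm` mismatches; ties between two
#' or more members are rejected as ambiguous rather than guessed.
#'
#' @param observed Observed barcode string (same length as the set members).
#' @param set A [barcode_set()].
#' @param max_mm Maximum tolerated mismatches.
#' @return List with `status` (`"matched"`, `"none"`, `"ambiguous"` or
#'   `"structural"` for a length mismatch), and for matches `id`, `seq`,
#'   `mm`.
#' @export
match_barcode <- function(observed, set, max_mm = 1L) {
  set <- .as_barcode_set(set)
  observed <- .norm_seq(observed)[1]
  if (nchar(observed) != bc_len(set)) {
    return(list(status = "structural", id = NA_character_,
                seq = NA_character_, mm = NA_integer_))
  }
  d <- .dist_to_set(observed, set$seq)[1, ]
  hit <- which(d <= max_mm)
  if (length(hit) == 0L) {
    list(status = "none", id = NA_character_, seq = NA_character_,
         mm = NA_integer_)
  } else if (length(hit) > 1L) {
    list(status = "ambiguous", id = NA_character_, seq = NA_character_,
         mm = min(d[hit]))
  } else {
    list(status = "matched", id = set$id[hit], seq = set$seq[hit],
         mm = d[hit])
  }
}

#' Count mismatches of an observed string against an IUPAC pattern
#'
#' A position matches if the observed base is in the IUPAC expansion of the
#' pattern base (N matches everything). Anchored, equal length, no indels.
#'
#' @param pattern IUPAC pattern (e.g. a degenerate primer).
#' @param observed Observed DNA string of the same length.
#' @param max_mm Maximum tolerated mismatches.
#' @return List with `ok` (logical) and `mm` (mismatch count).
#' @export
match_iupac <- function(pattern, observed, max_mm = 2L) {
  pattern <- .norm_seq(pattern)
  observed <- .norm_seq(observed)
  if (nchar(pattern) != nchar(observed)) {
    stop("pattern and observed must have equal length", call. = FALSE)
  }
  mm <- .iupac_mm_vec(pattern, observed)
  list(ok = mm <= max_mm, mm = mm)
}

# Vectorized parse of one side's technical sequence on a read vector.
# Returns per-read category ("ok"/"structural"/"head_mismatch"/
# "primer_mismatch"), observed barcode, mismatch counts, insert offset.
.parse_side_vec <- function(reads, bc_length, head_seq, primer_seq, params) {
  n <- length(reads)
  need <- bc_length + HEAD_LEN + nchar(primer_seq)
  cat <- rep("ok", n)
  bc <- rep(NA_character_, n)
  head_mm <- rep(NA_integer_, n)
  primer_mm <- rep(NA_integer_, n)

  ok <- !is.na(reads) & nchar(reads) > need # strict: insert must be non-empty
  cat[!ok] <- "structural"
  if (any(ok)) {
    r <- reads[ok]
    bc_obs <- substr(r, 1L, bc_length)
    head_obs <- substr(r, bc_length + 1L, bc_length + HEAD_LEN)
    primer_obs <- substr(r, bc_length + HEAD_LEN + 1L, need)
    hmm <- .iupac_mm_vec(head_seq, head_obs)
    pmm <- .iupac_mm_vec(primer_seq, primer_obs)
    sub_cat <- rep("ok", length(r))
    sub_cat[hmm > params$max_mm_head] <- "head_mismatch"
    sub_cat[hmm <= params$max_mm_head &
              pmm > params$max_mm_primer] <- "primer_mismatch"
    cat[ok] <- sub_cat
    bc[ok] <- bc_obs
    head_mm[ok] <- hmm
    primer_mm[ok] <- pmm
  }
  list(category = cat, bc = bc, head_mm = head_mm, primer_mm = primer_mm,
       insert_from = need + 1L)
}

#' Parse the technical sequence at a read start
#'
#' Locates barcode (positions 1..L), head (next 16 nt) and primer at the
#' start of a read, anchored and indel-free, and reports the insert offset.
#'
#' @param read Read sequence.
#' @param scheme One of [schemes()].
#' @param side `"fwd"` (H1-side) or `"rev"` (other end).
#' @param params A [demux_params()].
#' @param bc_length Barcode length in nt (default 12).
#' @param primer_pair Primer pair name or list.
#' @return List with `category` (`"ok"`, `"structural"`, `"head_mismatch"` or
#'   `"primer_mismatch"`), `barcode` (observed string), `head_mm`,
#'   `primer_mm`, `insert_from` (1-based position of the first insert base).
#' @export
parse_read_start <- function(read, scheme, side = c("fwd", "rev"),
                             params = demux_params(), bc_length = 12L,
                             primer_pair = "V4") {
  side <- match.arg(side)
  pp <- .as_primer_pair(primer_pair)
  heads <- .scheme_heads(scheme)
  head_seq <- head_sequences()[[heads[[side]]]]
  primer_seq <- if (side == "fwd") pp$fwd else pp$rev
  res <- .parse_side_vec(.norm_seq(read)[1], as.integer(bc_length),
                         head_seq, primer_seq, params)
  list(category = res$category[1], barcode = res$bc[1],
       head_mm = res$head_mm[1], primer_mm = res$primer_mm[1],
       insert_from = res$insert_from)
}

# Match a vector of observed barcodes to a set; returns status plus index.
.match_barcodes_vec <- function(obs, set, max_mm) {
  n <- length(obs)
  status <- rep("none", n)
  idx <- rep(NA_integer_, n)
  ok <- !is.na(obs) & nchar(obs) == bc_len(set) & n > 0L
  if (any(ok)) {
    D <- .dist_to_set(obs[ok], set$seq)
    within <- D <= max_mm
    nhit <- rowSums(within)
    st <- rep("none", sum(ok))
    st[nhit == 1L] <- "matched"
    st[nhit >= 2L] <- "ambiguous"
    ix <- rep(NA_integer_, sum(ok))
    one <- nhit == 1L
    if (any(one)) ix[one] <- max.col(within[one, , drop = FALSE], "first")
    status[ok] <- st
    idx[ok] <- ix
  }
  status[!ok & !is.na(obs)] <- "structural"
  list(status = status, idx = idx)
}

# One orientation attempt over read vectors. reads_f is parsed as the
# forward (H1) side, reads_r as the reverse side.
.attempt_orientation <- function(reads_f, reads_r, decoder, params) {
  heads <- head_sequences()
  hf <- heads[[decoder$heads[["fwd"]]]]
  hr <- heads[[decoder$heads[["rev"]]]]
  pf <- .parse_side_vec(reads_f, decoder$bc_len, hf, decoder$primer_pair$fwd,
                        params)
  pr <- .parse_side_vec(reads_r, decoder$bc_len, hr, decoder$primer_pair$rev,
                        params)
  n <- length(reads_f)
  category <- rep("assigned", n)
  sample_id <- rep(NA_character_, n)
  bc1 <- rep(NA_character_, n)
  bc2 <- rep(NA_character_, n)

  # structural > head > primer; worst failure of the two sides wins
  side_fail <- function(cat_f, cat_r) {
    rank <- c(structural = 0, head_mismatch = 1, primer_mismatch = 2, ok = 99)
    pick <- pmin(rank[cat_f], rank[cat_r])
    names(rank)[match(pick, rank)]
  }
  parse_ok <- pf$category == "ok" & pr$category == "ok"
  bad <- !parse_ok
  if (any(bad)) {
    category[bad] <- side_fail(pf$category[bad], pr$category[bad])
  }

  if (any(parse_ok)) {
    m1 <- .match_barcodes_vec(pf$bc[parse_ok], decoder$side1,
                              params$max_mm_barcode)
    m2 <- .match_barcodes_vec(pr$bc[parse_ok], decoder$side2,
                              params$max_mm_barcode)
    st <- rep("assigned", sum(parse_ok))
    st[m1$status == "none" | m2$status == "none"] <- "unknown_barcode"
    st[(m1$status == "ambiguous" | m2$status == "ambiguous") &
         st != "unknown_barcode"] <- "ambiguous"
    ok2 <- st == "assigned"
    s1 <- rep(NA_character_, sum(parse_ok))
    s2 <- s1
    smp <- s1
    if (any(ok2)) {
      s1[ok2] <- decoder$side1$seq[m1$idx[ok2]]
      s2[ok2] <- decoder$side2$seq[m2$idx[ok2]]
      if (decoder$scheme == "SB") {
        smp[ok2] <- .decode_combination(decoder, s1[ok2], s2[ok2])
        disagree <- ok2 & s1 != s2
        st[disagree] <- "invalid_combination"
        smp[disagree] <- NA_character_
      } else {
        smp[ok2] <- .decode_combination(decoder, s1[ok2], s2[ok2])
        st[ok2 & is.na(smp)] <- "invalid_combination"
      }
    }
    category[parse_ok] <- st
    sample_id[parse_ok] <- smp
    bc1[parse_ok] <- s1
    bc2[parse_ok] <- s2
  }
  category[category == "assigned" & is.na(sample_id)] <- "invalid_combination"

  list(category = category, sample_id = sample_id, bc1 = bc1, bc2 = bc2,
       insert_from_f = pf$insert_from, insert_from_r = pr$insert_from)
}

#' Demultiplex vectors of paired-end reads
#'
#' Vectorized core of the demultiplexer: classifies every read pair into
#' exactly one category and, for assigned pairs, trims barcode + head +
#' primer off both mates. Orientation A reads the first mate as the forward
#' (H1) side; orientation B swaps the mates. If both orientations assign to
#' different samples the pair is rejected as ambiguous; among failures the
#' orientation that progressed furthest determines the reported category.
#'
#' @param r1,r2 Character vectors of mate-1 / mate-2 sequences.
#' @param decoder A [build_decoder()] result.
#' @param params A [demux_params()].
#' @param q1,q2 Optional quality strings, trimmed alongside the sequences.
#' @return A data.frame with one row per pair: `category`, `sample_id`,
#'   `bc1`, `bc2` (matched barcode sequences, forward side first),
#'   `orientation` (`"A"`/`"B"`/`NA`), `insert_fwd`, `insert_rev` (trimmed
#'   inserts in forward-side-first order) and trimmed qualities `qual_fwd`,
#'   `qual_rev` when qualities were given.
#' @export
demux_read_pairs <- function(r1, r2, decoder, params = demux_params(),
                             q1 = NULL, q2 = NULL) {
  stopifnot(inherits(decoder, "bc_decoder"))
  r1 <- .norm_seq(r1)
  r2 <- .norm_seq(r2)
  if (length(r1) != length(r2)) {
    stop("r1 and r2 must have the same number of reads", call. = FALSE)
  }
  n <- length(r1)
  A <- .attempt_orientation(r1, r2, decoder, params)
  use_B <- params$try_both_orientations
  if (use_B) {
    B <- .attempt_orientation(r2, r1, decoder, params)
    a_ass <- A$category == "assigned"
    b_ass <- B$category == "assigned"
    both <- a_ass & b_ass & A$sample_id != B$sample_id
    pick_B <- (!a_ass & b_ass) |
      (!a_ass & !b_ass & .CAT_RANK[B$category] > .CAT_RANK[A$category])
    category <- A$category
    sample_id <- A$sample_id
    bc1 <- A$bc1
    bc2 <- A$bc2
    orientation <- ifelse(A$category == "assigned", "A", NA_character_)
    if (any(pick_B)) {
      category[pick_B] <- B$category[pick_B]
      sample_id[pick_B] <- B$sample_id[pick_B]
      bc1[pick_B] <- B$bc1[pick_B]
      bc2[pick_B] <- B$bc2[pick_B]
      orientation[pick_B] <- ifelse(B$category[pick_B] == "assigned", "B",
                                    NA_character_)
    }
    if (any(both)) {
      category[both] <- "ambiguous"
      sample_id[both] <- NA_character_
      orientation[both] <- NA_character_
    }
    orient_B <- !is.na(orientation) & orientation == "B"
  } else {
    category <- A$category
    sample_id <- A$sample_id
    bc1 <- A$bc1
    bc2 <- A$bc2
    orientation <- ifelse(category == "assigned", "A", NA_character_)
    orient_B <- rep(FALSE, n)
  }

  assigned <- category == "assigned"
  insert_fwd <- rep(NA_character_, n)
  insert_rev <- rep(NA_character_, n)
  from_f <- A$insert_from_f
  from_r <- A$insert_from_r
  fwd_read <- ifelse(orient_B, r2, r1)
  rev_read <- ifelse(orient_B, r1, r2)
  insert_fwd[assigned] <- substr(fwd_read[assigned], from_f, nchar(fwd_read[assigned]))
  insert_rev[assigned] <- substr(rev_read[assigned], from_r, nchar(rev_read[assigned]))

  out <- data.frame(category = category, sample_id = sample_id,
                    bc1 = bc1, bc2 = bc2, orientation = orientation,
                    insert_fwd = insert_fwd, insert_rev = insert_rev,
                    stringsAsFactors = FALSE)
  if (!is.null(q1) && !is.null(q2)) {
    fq <- ifelse(orient_B, q2, q1)
    rq <- ifelse(orient_B, q1, q2)
    out$qual_fwd <- ifelse(assigned, substr(fq, from_f, nchar(fq)),
                           NA_character_)
    out$qual_rev <- ifelse(assigned, substr(rq, from_r, nchar(rq)),
                           NA_character_)
  }
  out
}

#' Demultiplex a single read pair
#'
#' Single-pair convenience wrapper around [demux_read_pairs()].
#'
#' @param rp List with elements `r1`, `r2` (sequences) and optionally `id`,
#'   `q1`, `q2`.
#' @inheritParams demux_read_pairs
#' @return A one-row outcome (list): `category`, `sample_id`, `bc1`, `bc2`,
#'   `orientation`, `insert_fwd`, `insert_rev`.
#' @export
demultiplex_pair <- function(rp, decoder, params = demux_params()) {
  res <- demux_read_pairs(rp$r1, rp$r2, decoder, params,
                          q1 = rp$q1, q2 = rp$q2)
  as.list(res[1, ])
}

#' Run demultiplexing over paired FASTQ files
#'
#' Reads record-synchronized paired FASTQ(.gz) files, assigns every pair to a
#' sample (or failure category), writes two gzip-compressed FASTQ files of
#' trimmed inserts per assigned sample, and returns yield statistics.
#'
#' @param fastq_r1,fastq_r2 Paths to the mate FASTQ(.gz) files.
#' @param sheet A sample sheet (see [assign_samples()]) or a prebuilt
#'   [build_decoder()] object.
#' @param params A [demux_params()].
#' @param outdir Output directory (created if missing); pass `NULL` to skip
#'   writing FASTQ output.
#' @param write_unassigned Also write category-named FASTQ pairs for
#'   unassigned reads?
#' @param stats_files Write `demux_stats.tsv` / `demux_stats.json` into
#'   `outdir`?
#' @return A `demux_stats` list: `total`, `categories` (named counts summing
#'   to `total`), `per_sample` (named assigned counts), `yield`
#'   (assigned/total), plus the per-read `assignments` data.frame.
#' @export
run_demux <- function(fastq_r1, fastq_r2, sheet, params = demux_params(),
                      outdir = NULL, write_unassigned = FALSE,
                      stats_files = !is.null(outdir)) {
  decoder <- if (inherits(sheet, "bc_decoder")) sheet else build_decoder(sheet)
  .check_params_vs_set(params, decoder)
  f1 <- read_fastq(fastq_r1)
  f2 <- read_fastq(fastq_r2)
  if (length(f1$seq) != length(f2$seq)) {
    stop(sprintf("desynchronized pair files: %d vs %d records",
                 length(f1$seq), length(f2$seq)), call. = FALSE)
  }
  id1 <- sub("[/ ].*$", "", f1$id)
  id2 <- sub("[/ ].*$", "", f2$id)
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop(sprintf("desynchronized pair files at record %d: '%s' vs '%s'",
                 bad[1], f1$id[bad[1]], f2$id[bad[1]]), call. = FALSE)
  }

  res <- demux_read_pairs(f1$seq, f2$seq, decoder, params,
                          q1 = f1$qual, q2 = f2$qual)
  res$read_id <- id1

  categories <- table(factor(res$category, levels = DEMUX_CATEGORIES))
  per_sample <- table(factor(res$sample_id[res$category == "assigned"],
                             levels = decoder$samples))
  total <- nrow(res)
  stats <- list(total = total,
                categories = as.list(as.integer(categories)) |>
                  stats::setNames(names(categories)),
                per_sample = as.list(as.integer(per_sample)) |>
                  stats::setNames(names(per_sample)),
                yield = if (total > 0) unname(categories[["assigned"]]) / total else NA_real_)

  if (!is.null(outdir)) {
    if (!dir.exists(outdir) &&
        !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
      stop("cannot create output directory: ", outdir, call. = FALSE)
    }
    asg <- res[res$category == "assigned", , drop = FALSE]
    for (s in unique(asg$sample_id)) {
      rows <- asg[asg$sample_id == s, , drop = FALSE]
      write_fastq(rows$read_id, rows$insert_fwd, rows$qual_fwd,
                  file.path(outdir, paste0(s, "_R1.fastq.gz")))
      write_fastq(rows$read_id, rows$insert_rev, rows$qual_rev,
                  file.path(outdir, paste0(s, "_R2.fastq.gz")))
    }
    if (write_unassigned) {
      una <- res[res$category != "assigned", , drop = FALSE]
      for (cg in unique(una$category)) {
        rows <- which(res$category == cg)
        write_fastq(id1[rows], f1$seq[rows], f1$qual[rows],
                    file.path(outdir, paste0("unassigned_", cg, "_R1.fastq.gz")))
        write_fastq(id2[rows], f2$seq[rows], f2$qual[rows],
                    file.path(outdir, paste0("unassigned_", cg, "_R2.fastq.gz")))
      }
    }
    if (stats_files) {
      st <- data.frame(metric = c("total", paste0("category_", names(categories)),
                                  paste0("sample_", names(per_sample)), "yield"),
                       value = c(total, as.integer(categories),
                                 as.integer(per_sample), stats$yield))
      utils::write.table(st, file.path(outdir, "demux_stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(stats, file.path(outdir, "demux_stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  stats$assignments <- res
  class(stats) <- "demux_stats"
  stats
}

#' @export
print.demux_stats <- function(x, ...) {
  cat(sprintf("<demux_stats> %d read pairs, yield %.4f\n", x$total, x$yield))
  cats <- unlist(x$categories)
  for (nm in names(cats)) {
    if (cats[[nm]] > 0) cat(sprintf("  %-20s %d\n", nm, cats[[nm]]))
  }
  invisible(x)
}

#' Build a sample-by-sequence count table from demultiplexing assignments
#'
#' Exact dereplication of the trimmed forward inserts of assigned read pairs:
#' the synthetic-data stand-in for denoised sequence-variant inference.
#'
#' @param assignments The `assignments` data.frame of [run_demux()] /
#'   [demux_read_pairs()].
#' @param samples Optional sample ids to include as columns (defaults to the
#'   samples seen; pass the full sheet order to keep empty samples, e.g.
#'   negative controls, as all-zero columns).
#' @return Integer matrix, rows = unique insert sequences, columns = samples.
#' @export
count_table <- function(assignments, samples = NULL) {
  asg <- assignments[assignments$category == "assigned", , drop = FALSE]
  if (is.null(samples)) samples <- sort(unique(asg$sample_id))
  seqs <- sort(unique(asg$insert_fwd))
  tab <- table(factor(asg$insert_fwd, levels = seqs),
               factor(asg$sample_id, levels = samples))
  mat <- matrix(as.integer(tab), nrow = length(seqs),
                dimnames = list(seqs, samples))
  mat
}
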