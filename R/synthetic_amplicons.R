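# Ground-truthed simulation of multiplexed two-step-PCR amplicon reads:
# mock-community composition sampling, per-scheme read construction,
# substitution errors and barcode-swap (index hopping) injection. Everything
# is reproducible from one master seed via named RNG substreams.

#' Construct a mock-community reference
#'
#' A mock reference lists the community members with their 16S variant
#' sequences and per-variant relative abundances (per 16S gene, summing
#' to 1). Non-identical intragenomic 16S copies are modelled as separate
#' variants with their own weights; per-variant weights are an input, not a
#' computation.
#'
#' @param variants Data.frame with columns `variant_id`, `species`, `seq`,
#'   `abundance` (relative abundance per 16S gene; renormalized if the sum
#'   deviates by no more than 1e-9, rejected otherwise when
#'   `normalize = FALSE`).
#' @param normalize Renormalize abundances to sum to 1? Default `FALSE`
#'   (abundances must already sum to 1 within 1e-9).
#' @return Object of class `mock_reference`.
#' @export
mock_reference <- function(variants, normalize = FALSE) {
  req <- c("variant_id", "species", "seq", "abundance")
  if (!all(req %in% names(variants))) {
    stop("variants must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  v <- as.data.frame(variants)[req]
  v$seq <- .norm_seq(v$seq)
  v$abundance <- as.numeric(v$abundance)
  if (any(!nzchar(v$seq)) || !all(.is_dna(v$seq))) {
    stop("variant sequences must be non-empty A/C/G/T strings", call. = FALSE)
  }
  if (anyDuplicated(v$variant_id)) {
    stop("variant_id must be unique", call. = FALSE)
  }
  if (any(v$abundance < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  s <- sum(v$abundance)
  if (normalize) {
    if (s <= 0) stop("abundances sum to zero", call. = FALSE)
    v$abundance <- v$abundance / s
  } else if (abs(s - 1) > 1e-9) {
    stop(sprintf("abundances must sum to 1 (got %.12f); use normalize=TRUE",
                 s), call. = FALSE)
  }
  class(v) <- c("mock_reference", "data.frame")
  v
}

#' @export
print.mock_reference <- function(x, ...) {
  cat(sprintf("<mock_reference> %d variants, %d species\n",
              nrow(x), length(unique(x$species))))
  agg <- stats::aggregate(abundance ~ species, as.data.frame(x), sum)
  print(agg[order(-agg$abundance), ], row.names = FALSE)
  invisible(x)
}

#' Synthetic log-ladder mock community (ZymoBIOMICS-Standard-II-like)
#'
#' A SYNTHETIC stand-in for a commercial log-distributed DNA mock standard:
#' eight bacterial members whose genomic-DNA abundances step down tenfold
#' (89.1%, 8.9%, 0.89%, 2 x 0.089%, 0.0089%, 0.00089%, 0.000089%), each with
#' 1-5 distinct 16S variants of random sequence (intragenomic copies differ
#' at a few positions). The variant sequences have no biological meaning;
#' real per-variant reference tables should be loaded with
#' [read_mock_reference()].
#'
#' @param seed Integer seed for the random variant sequences.
#' @param insert_length Length of each simulated 16S variant (nt).
#' @return A [mock_reference()].
#' @export
synthetic_zymo_mock <- function(seed = 1L, insert_length = 250L) {
  species <- c("Listeria_monocytogenes", "Pseudomonas_aeruginosa",
               "Bacillus_subtilis", "Escherichia_coli",
               "Salmonella_enterica", "Lactobacillus_fermentum",
               "Enterococcus_faecalis", "Staphylococcus_aureus")
  abund <- c(89.1, 8.9, 0.89, 0.089, 0.089, 0.0089, 0.00089, 0.000089)
  abund <- abund / sum(abund)
  n_var <- c(5L, 4L, 5L, 3L, 3L, 2L, 2L, 1L)
  .with_substream(seed, "synthetic_zymo_mock", {
    rows <- list()
    for (i in seq_along(species)) {
      base <- paste(sample(DNA_BASES, insert_length, replace = TRUE),
                    collapse = "")
      w <- as.numeric(stats::rmultinom(1, 100L, rep(1, n_var[i])))
      w <- (w + 1) / sum(w + 1)
      for (j in seq_len(n_var[i])) {
        seq <- base
        if (j > 1L) { # operon variants: a few substitutions on the base copy
          pos <- sample.int(insert_length, 3L)
          for (p in pos) {
            substr(seq, p, p) <- sample(setdiff(DNA_BASES,
                                                substr(seq, p, p)), 1L)
          }
        }
        rows[[length(rows) + 1L]] <- data.frame(
          variant_id = sprintf("%s_16S_%d", species[i], j),
          species = species[i], seq = seq,
          abundance = abund[i] * w[j], stringsAsFactors = FALSE)
      }
    }
    mock_reference(do.call(rbind, rows), normalize = TRUE)
  })
}

#' Read / write a mock reference (FASTA + abundance TSV)
#'
#' Variant sequences in FASTA (record names = `variant_id`), abundances in a
#' TSV with columns `variant_id`, `species`, `abundance`.
#'
#' @param fasta,tsv File paths.
#' @return `read_mock_reference` returns a [mock_reference()].
#' @export
read_mock_reference <- function(fasta, tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "species", "abundance") %in% names(ab))) {
    stop("abundance TSV needs columns variant_id, species, abundance",
         call. = FALSE)
  }
  idx <- match(ab$variant_id, names(seqs))
  if (anyNA(idx)) {
    stop("abundance TSV lists variants missing from the FASTA", call. = FALSE)
  }
  ab$seq <- as.character(seqs)[idx]
  mock_reference(ab)
}

#' @rdname read_mock_reference
#' @param ref A [mock_reference()] to write.
#' @export
write_mock_reference <- function(ref, fasta, tsv) {
  x <- Biostrings::DNAStringSet(ref$seq)
  names(x) <- ref$variant_id
  Biostrings::writeXStringSet(x, fasta)
  utils::write.table(
    as.data.frame(ref)[c("variant_id", "species", "abundance")],
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, tsv))
}

#' Multinomial mock-community count simulation
#'
#' Draws replicate library compositions from the reference per-variant
#' probabilities with `stats::rmultinom`: each replicate is one library of
#' `size` read pairs.
#'
#' @param ref A [mock_reference()].
#' @param size Reads per replicate library (default 2438).
#' @param reps Number of replicate libraries (default 100).
#' @param seed Integer seed.
#' @return Integer matrix, rows = variants (named), columns = replicates;
#'   every column sums to `size`.
#' @export
simulate_mock_counts <- function(ref, size = 2438L, reps = 100L, seed = 1L) {
  stopifnot(inherits(ref, "mock_reference"))
  if (size < 0 || reps < 1) {
    stop("size must be >= 0 and reps >= 1", call. = FALSE)
  }
  if (abs(sum(ref$abundance) - 1) > 1e-9) {
    stop("reference abundances must sum to 1", call. = FALSE)
  }
  m <- .with_substream(seed, "simulate_mock_counts",
                       stats::rmultinom(reps, size, ref$abundance))
  rownames(m) <- ref$variant_id
  colnames(m) <- sprintf("rep%03d", seq_len(reps))
  m
}

# Expand IUPAC degenerate positions of `pattern` for n reads, each degenerate
# position resolved uniformly at random (ambient RNG).
.expand_iupac_n <- function(pattern, n) {
  allowed <- .iupac_allowed(pattern)
  deg <- which(lengths(allowed) > 1L)
  out <- rep(pattern, n)
  if (length(deg) == 0L || n == 0L) return(out)
  M <- matrix(rep(strsplit(pattern, "")[[1]], n), nrow = n, byrow = TRUE)
  for (p in deg) {
    M[, p] <- sample(allowed[[p]], n, replace = TRUE)
  }
  apply(M, 1, paste, collapse = "")
}

#' Construct a synthetic barcoded read pair
#'
#' Assembles mate sequences following the construct layout barcode + head +
#' primer + insert: the forward (H1) side carries the sample's first barcode
#' and the forward primer followed by the insert; the reverse side carries
#' the second barcode (the same one for SB), the reverse head and primer,
#' and the reverse complement of the insert. Degenerate primer positions are
#' resolved uniformly at random (ambient RNG; seed via the caller).
#'
#' @param insert Template insert sequence (non-empty).
#' @param bc1_seq,bc2_seq Barcode sequences of the sample (forward / reverse
#'   side; `bc2_seq` ignored for SB).
#' @param scheme One of [schemes()].
#' @param primer_pair Primer pair name or list.
#' @param orientation `"A"` (mate 1 = forward side) or `"B"` (mates swapped).
#' @param qual_char Constant quality character (default `"I"`).
#' @return List with `r1`, `r2`, `q1`, `q2`.
#' @export
build_read_pair <- function(insert, bc1_seq, bc2_seq = bc1_seq,
                            scheme = "UDB_H12", primer_pair = "V4",
                            orientation = c("A", "B"), qual_char = "I") {
  orientation <- match.arg(orientation)
  insert <- .norm_seq(insert)[1]
  if (nchar(insert) < 1L) stop("insert must be non-empty", call. = FALSE)
  scheme <- .norm_scheme(scheme)
  if (scheme == "SB") bc2_seq <- bc1_seq
  pp <- .as_primer_pair(primer_pair)
  heads <- head_sequences()[.scheme_heads(scheme)]
  fwd <- paste0(bc1_seq, heads[[1]], .expand_iupac_n(pp$fwd, 1L), insert)
  rev <- paste0(bc2_seq, heads[[2]], .expand_iupac_n(pp$rev, 1L),
                .revcomp(insert))
  if (orientation == "A") {
    list(r1 = fwd, r2 = rev,
         q1 = strrep(qual_char, nchar(fwd)), q2 = strrep(qual_char, nchar(rev)))
  } else {
    list(r1 = rev, r2 = fwd,
         q1 = strrep(qual_char, nchar(rev)), q2 = strrep(qual_char, nchar(fwd)))
  }
}

# Vectorized per-base substitution; returns list(seqs, n_sub).
.mutate_seqs <- function(seqs, eps) {
  n_sub <- integer(length(seqs))
  if (eps <= 0 || length(seqs) == 0L) return(list(seqs = seqs, n_sub = n_sub))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    k <- stats::rbinom(1L, L, eps)
    if (k == 0L) next
    pos <- sample.int(L, k)
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    seqs[i] <- paste(chars, collapse = "")
    n_sub[i] <- k
  }
  list(seqs = seqs, n_sub = n_sub)
}

#' Inject per-base substitution errors into read pairs
#'
#' Each base is independently substituted to a uniformly chosen different
#' base with probability `epsilon`; non-ACGT bases are left untouched.
#'
#' @param pairs List with character vectors `r1`, `r2`.
#' @param epsilon Per-base substitution probability in \[0, 1\].
#' @param seed Integer seed.
#' @return `pairs` with mutated `r1`, `r2` plus integer vectors `n_sub_r1`,
#'   `n_sub_r2`.
#' @export
inject_errors <- function(pairs, epsilon, seed = 1L) {
  if (epsilon < 0 || epsilon > 1) {
    stop("epsilon must be in [0, 1]", call. = FALSE)
  }
  .with_substream(seed, "inject_errors", {
    m1 <- .mutate_seqs(pairs$r1, epsilon)
    m2 <- .mutate_seqs(pairs$r2, epsilon)
    pairs$r1 <- m1$seqs
    pairs$r2 <- m2$seqs
    pairs$n_sub_r1 <- m1$n_sub
    pairs$n_sub_r2 <- m2$n_sub
    pairs
  })
}

#' Inject exactly n substitutions into each read's barcode region
#'
#' Deterministic error placement for tolerance testing: mutates exactly `n`
#' positions within the first `bc_length` bases of every read.
#'
#' @param reads Character vector of reads.
#' @param bc_length Barcode length (region 1..bc_length is mutated).
#' @param n Substitutions per barcode.
#' @param seed Integer seed.
#' @return Mutated character vector.
#' @export
inject_barcode_errors <- function(reads, bc_length, n = 1L, seed = 1L) {
  if (n > bc_length) stop("n must be <= bc_length", call. = FALSE)
  .with_substream(seed, "inject_barcode_errors", {
    vapply(reads, function(r) {
      chars <- strsplit(r, "", fixed = TRUE)[[1]]
      pos <- sample.int(bc_length, n)
      for (p in pos) {
        chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
      }
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Inject barcode-swap (index hopping) events into read pairs
#'
#' With probability `rho` per read pair, the barcode on one uniformly chosen
#' side is replaced by a barcode used on that side by a different sample
#' (excluding the pair's current barcode sequence), emulating barcode/index
#' hopping between pooled libraries.
#'
#' @param pairs List with `r1`, `r2` (assembled reads) and `manifest`
#'   data.frame carrying at least `sample_id` and `orientation`.
#' @param rho Per-pair swap probability in \[0, 1\].
#' @param sheet The sample sheet the reads were built from (>= 2 samples).
#' @param seed Integer seed.
#' @return `pairs` with modified reads and manifest columns `swap`
#'   (logical), `swap_side` (1 = forward/H1 side, 2 = reverse side),
#'   `swap_bc` (replacement barcode sequence).
#' @export
inject_crosstalk <- function(pairs, rho, sheet, seed = 1L) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  validate_sample_sheet(sheet)
  if (nrow(sheet) < 2L && rho > 0) {
    stop("crosstalk injection requires at least 2 samples", call. = FALSE)
  }
  mf <- pairs$manifest
  n <- length(pairs$r1)
  stopifnot(nrow(mf) == n)
  scheme <- .norm_scheme(unique(sheet$scheme))
  L <- nchar(sheet$bc1_seq[1])

  mf$swap <- logical(n)
  mf$swap_side <- NA_integer_
  mf$swap_bc <- NA_character_
  if (rho > 0 && n > 0L) {
    .with_substream(seed, "inject_crosstalk", {
      ev <- stats::runif(n) < rho
      side <- ifelse(stats::runif(n) < 0.5, 1L, 2L)
      if (scheme == "SB") side <- sample(1:2, n, replace = TRUE)
      for (i in which(ev)) {
        samp <- mf$sample_id[i]
        row <- match(samp, sheet$sample_id)
        own <- if (side[i] == 1L || scheme == "SB") sheet$bc1_seq[row] else sheet$bc2_seq[row]
        others <- sheet$sample_id != samp
        cand <- if (side[i] == 1L || scheme == "SB") {
          unique(sheet$bc1_seq[others])
        } else {
          unique(sheet$bc2_seq[others])
        }
        cand <- setdiff(cand, own)
        if (length(cand) == 0L) next
        newbc <- cand[sample.int(length(cand), 1L)]
        # side 1 sits on r1 in orientation A, on r2 in orientation B
        on_r1 <- (side[i] == 1L) == (mf$orientation[i] == "A")
        if (on_r1) {
          substr(pairs$r1[i], 1L, L) <- newbc
        } else {
          substr(pairs$r2[i], 1L, L) <- newbc
        }
        mf$swap[i] <- TRUE
        mf$swap_side[i] <- side[i]
        mf$swap_bc[i] <- newbc
      }
    })
  }
  pairs$manifest <- mf
  pairs
}

#' Simulation configuration
#'
#' Bundles everything [simulate_reads()] / [simulate_run()] need. Defaults
#' follow the reference mock-simulation conditions: 2438 read pairs per
#' library, error-free reads, no crosstalk.
#'
#' @param sheet A validated sample sheet.
#' @param ref A [mock_reference()] used as template source for every
#'   non-blank sample (override per sample via `sample_refs`).
#' @param reads_per_sample Read pairs per sample (default 2438).
#' @param error_rate Per-base substitution probability (default 0).
#' @param crosstalk_rate Per-pair barcode-swap probability (default 0).
#' @param seed Master seed; all RNG substreams derive from it.
#' @param blank_samples Sample ids that emit zero reads (negative controls).
#' @param sample_refs Named list of per-sample [mock_reference()] overrides.
#' @param orientation `"random"`, `"A"` or `"B"` mate orientation.
#' @param qual_char Constant base-quality character.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sheet, ref, reads_per_sample = 2438L,
                       error_rate = 0, crosstalk_rate = 0, seed = 1L,
                       blank_samples = character(),
                       sample_refs = list(),
                       orientation = c("random", "A", "B"),
                       qual_char = "I") {
  validate_sample_sheet(sheet)
  orientation <- match.arg(orientation)
  if (reads_per_sample < 0) stop("reads_per_sample must be >= 0", call. = FALSE)
  if (error_rate < 0 || error_rate > 1 ||
      crosstalk_rate < 0 || crosstalk_rate > 1) {
    stop("rates must be in [0, 1]", call. = FALSE)
  }
  if (!all(blank_samples %in% sheet$sample_id)) {
    stop("blank_samples must be sample ids of the sheet", call. = FALSE)
  }
  if (length(sample_refs) &&
      !all(names(sample_refs) %in% sheet$sample_id)) {
    stop("sample_refs names must be sample ids of the sheet", call. = FALSE)
  }
  structure(list(sheet = sheet, ref = ref,
                 reads_per_sample = as.integer(reads_per_sample),
                 error_rate = error_rate, crosstalk_rate = crosstalk_rate,
                 seed = as.integer(seed), blank_samples = blank_samples,
                 sample_refs = sample_refs, orientation = orientation,
                 qual_char = qual_char),
            class = "sim_config")
}

#' Simulate a multiplexed amplicon run in memory
#'
#' For every non-blank sample, draws a multinomial composition over its
#' reference variants, assembles barcoded read pairs, injects barcode-swap
#' events and then substitution errors, and shuffles the read order. Blank
#' (negative-control) samples stay on the sheet but emit no reads.
#'
#' @param config A [sim_config()].
#' @return List with `r1`, `r2`, `q1`, `q2` (character vectors),
#'   `manifest` (data.frame: `read_id`, `sample_id`, `variant`,
#'   `orientation`, `swap`, `swap_side`, `swap_bc`, `n_sub_r1`, `n_sub_r2`)
#'   and `truth` (variant x sample integer count matrix over all sheet
#'   samples).
#' @export
simulate_reads <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sheet <- config$sheet
  scheme <- .norm_scheme(unique(sheet$scheme))
  pp <- .as_primer_pair(unique(sheet$primer_pair))
  seed <- config$seed

  sample_id <- character(0)
  variant <- character(0)
  insert <- character(0)
  for (i in seq_len(nrow(sheet))) {
    s <- sheet$sample_id[i]
    if (s %in% config$blank_samples || config$reads_per_sample == 0L) next
    ref <- if (s %in% names(config$sample_refs)) {
      config$sample_refs[[s]]
    } else config$ref
    stopifnot(inherits(ref, "mock_reference"))
    counts <- .with_substream(seed, paste0("composition_", s),
                              stats::rmultinom(1, config$reads_per_sample,
                                               ref$abundance))[, 1]
    v <- rep(ref$variant_id, counts)
    sample_id <- c(sample_id, rep(s, length(v)))
    variant <- c(variant, v)
    insert <- c(insert, rep(ref$seq, counts))
  }
  n <- length(sample_id)

  row <- match(sample_id, sheet$sample_id)
  bc1 <- sheet$bc1_seq[row]
  bc2 <- if (scheme == "SB") bc1 else sheet$bc2_seq[row]
  heads <- head_sequences()[.scheme_heads(scheme)]

  orient <- switch(config$orientation,
                   A = rep("A", n), B = rep("B", n),
                   random = .with_substream(seed, "orientation",
                                            sample(c("A", "B"), n, replace = TRUE)))
  fwd_primers <- .with_substream(seed, "primer_expansion_f",
                                 .expand_iupac_n(pp$fwd, n))
  rev_primers <- .with_substream(seed, "primer_expansion_r",
                                 .expand_iupac_n(pp$rev, n))

  ins_rc <- if (n > 0L) .revcomp(insert) else character(0)
  fwd_read <- paste0(bc1, heads[[1]], fwd_primers, insert)
  rev_read <- paste0(bc2, heads[[2]], rev_primers, ins_rc)
  is_A <- orient == "A"
  r1 <- ifelse(is_A, fwd_read, rev_read)
  r2 <- ifelse(is_A, rev_read, fwd_read)

  manifest <- data.frame(read_id = sprintf("sim_%07d", seq_len(n)),
                         sample_id = sample_id, variant = variant,
                         orientation = orient, stringsAsFactors = FALSE)
  pairs <- list(r1 = r1, r2 = r2, manifest = manifest)
  pairs <- inject_crosstalk(pairs, config$crosstalk_rate, sheet,
                            seed = .substream_seed(seed, "crosstalk"))
  err <- inject_errors(list(r1 = pairs$r1, r2 = pairs$r2),
                       config$error_rate,
                       seed = .substream_seed(seed, "errors"))
  pairs$r1 <- err$r1
  pairs$r2 <- err$r2
  pairs$manifest$n_sub_r1 <- err$n_sub_r1
  pairs$manifest$n_sub_r2 <- err$n_sub_r2

  ord <- .with_substream(seed, "shuffle", sample.int(max(n, 1L)))
  if (n > 0L) {
    pairs$r1 <- pairs$r1[ord]
    pairs$r2 <- pairs$r2[ord]
    pairs$manifest <- pairs$manifest[ord, , drop = FALSE]
    rownames(pairs$manifest) <- NULL
  }
  pairs$q1 <- strrep(config$qual_char, nchar(pairs$r1))
  pairs$q2 <- strrep(config$qual_char, nchar(pairs$r2))

  all_variants <- sort(unique(pairs$manifest$variant))
  truth <- table(factor(pairs$manifest$variant, levels = all_variants),
                 factor(pairs$manifest$sample_id, levels = sheet$sample_id))
  pairs$truth <- matrix(as.integer(truth), nrow = length(all_variants),
                        dimnames = list(all_variants, sheet$sample_id))
  pairs
}

#' Simulate a run and write FASTQ + manifest + truth tables
#'
#' File-writing wrapper around [simulate_reads()]: writes
#' `simulated_R1.fastq.gz`, `simulated_R2.fastq.gz`, `manifest.tsv` and
#' `truth_counts.tsv` into `outdir`. Record-identical across calls with the
#' same config.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the four file paths and the in-memory
#'   simulation (`sim`).
#' @export
simulate_run <- function(config, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  sim <- simulate_reads(config)
  paths <- list(
    r1 = file.path(outdir, "simulated_R1.fastq.gz"),
    r2 = file.path(outdir, "simulated_R2.fastq.gz"),
    manifest = file.path(outdir, "manifest.tsv"),
    truth = file.path(outdir, "truth_counts.tsv"))
  write_fastq(sim$manifest$read_id, sim$r1, sim$q1, paths$r1)
  write_fastq(sim$manifest$read_id, sim$r2, sim$q2, paths$r2)
  utils::write.table(sim$manifest, paths$manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(variant = rownames(sim$truth),
                                sim$truth, check.names = FALSE),
                     paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(sim = sim)))
}
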