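# Barcoding schemes for two-step PCR amplicon multiplexing.
#
# First-step PCR tags the amplicon with one of two constant 16-nt head
# (linker) sequences on each end; the second-step (barcoding) PCR anneals to
# those heads and prepends a sample barcode. Four layouts are supported:
#   SB       - one barcode, H1 head on both ends (classic single barcoding)
#   UDB_H11  - two sample-exclusive barcodes, H1 head on both ends
#   UDB_H12  - two sample-exclusive barcodes, H1 forward / H2 reverse
#   CDB_H12  - combinatorially unique ordered barcode pairs, H1/H2 heads

#' Head (linker) sequences H1 and H2
#'
#' Constant 16-nt sequences placed between barcode and target primer; the
#' barcoding primer anneals to them in the second PCR.
#'
#' @return Named character vector with elements `H1` and `H2`.
#' @export
head_sequences <- function() {
  c(H1 = "GCTATGCGCGAGCTGC", H2 = "TAGCGCACACCTGGTA")
}

HEAD_LEN <- 16L

#' 16S rRNA gene primer pairs
#'
#' The two bundled target-gene primer pairs (IUPAC degenerate bases allowed):
#' 515F/806R for the V4 region and 341F/785R for V3-V4. Any other pair can be
#' supplied to the layout/simulator/demultiplexer functions as a list with
#' elements `name`, `fwd`, `rev`, `region`.
#'
#' @param name Optional pair name (`"V4"` or `"V3-4"`); if omitted, both are
#'   returned.
#' @return A list (or list of lists) with `name`, `fwd`, `rev`, `region`.
#' @export
primer_pairs <- function(name = NULL) {
  pp <- list(
    "V4" = list(name = "V4", fwd = "GTGYCAGCMGCCGCGGTAA",
                rev = "GGACTACNVGGGTWTCTAAT", region = "V4",
                fwd_name = "515F", rev_name = "806R"),
    "V3-4" = list(name = "V3-4", fwd = "CCTACGGGNGGCWGCAG",
                  rev = "GACTACHVGGGTATCTAATCC", region = "V3-4",
                  fwd_name = "341F", rev_name = "785R"))
  if (is.null(name)) return(pp)
  if (!name %in% names(pp)) {
    stop("unknown primer pair: ", name, " (available: ",
         paste(names(pp), collapse = ", "), ")", call. = FALSE)
  }
  pp[[name]]
}

.as_primer_pair <- function(x) {
  if (is.character(x) && length(x) == 1L) return(primer_pairs(x))
  if (is.list(x) && all(c("name", "fwd", "rev") %in% names(x))) return(x)
  stop("primer pair must be a known name or a list(name, fwd, rev)",
       call. = FALSE)
}

#' Supported barcoding schemes
#' @return Character vector of scheme identifiers.
#' @export
schemes <- function() c("SB", "UDB_H11", "UDB_H12", "CDB_H12")

.norm_scheme <- function(scheme) {
  s <- toupper(gsub("-", "_", as.character(scheme)[1]))
  if (!s %in% schemes()) {
    stop("unknown scheme '", scheme, "'; expected one of ",
         paste(schemes(), collapse = ", "), call. = FALSE)
  }
  s
}

# Head ids used on the forward (first) and reverse (second) amplicon end.
.scheme_heads <- function(scheme) {
  switch(.norm_scheme(scheme),
         SB = c(fwd = "H1", rev = "H1"),
         UDB_H11 = c(fwd = "H1", rev = "H1"),
         UDB_H12 = c(fwd = "H1", rev = "H2"),
         CDB_H12 = c(fwd = "H1", rev = "H2"))
}

.is_dual <- function(scheme) .norm_scheme(scheme) != "SB"

#' Multiplexing capacity of a barcoding scheme
#'
#' Number of samples (amplified with the same primer pair) that can be
#' multiplexed into a single amplicon pool with a barcode set of size `k`:
#' `k` for single barcoding, `floor(k/2)` for UDB-H11 (each sample consumes
#' an exclusive pair of barcodes), `k` for UDB-H12 (one exclusive barcode per
#' head side) and `k*(k-1)` for CDB-H12 (ordered pairs of distinct barcodes).
#'
#' @param scheme One of [schemes()] (case/hyphen insensitive).
#' @param k Barcode-set size (non-negative).
#' @return Non-negative integer capacity.
#' @examples
#' capacity("CDB_H12", 548) # 299756
#' @export
capacity <- function(scheme, k) {
  if (length(k) != 1L || is.na(k) || k < 0 || k != floor(k)) {
    stop("k must be a single non-negative integer", call. = FALSE)
  }
  k <- as.numeric(k)
  out <- switch(.norm_scheme(scheme),
                SB = k,
                UDB_H11 = floor(k / 2),
                UDB_H12 = k,
                CDB_H12 = k * (k - 1))
  out
}

#' Total capacity across primer pairs and pool libraries
#'
#' A sequencing run can combine `m` amplicon pool libraries (separated by
#' library indexes), each of which can hold [capacity()] samples for each of
#' `n` distinct target-gene primer pairs.
#'
#' @inheritParams capacity
#' @param n_primer_pairs Number of distinct primer pairs (>= 1).
#' @param m_pools Number of amplicon pool libraries combined (>= 1).
#' @return `capacity(scheme, k) * n_primer_pairs * m_pools`.
#' @export
total_capacity <- function(scheme, k, n_primer_pairs = 1L, m_pools = 1L) {
  if (n_primer_pairs < 1 || m_pools < 1) {
    stop("n_primer_pairs and m_pools must be >= 1", call. = FALSE)
  }
  capacity(scheme, k) * n_primer_pairs * m_pools
}

.new_sample_sheet <- function(df, scheme) {
  rownames(df) <- NULL
  attr(df, "scheme") <- scheme
  class(df) <- c("sample_sheet", "data.frame")
  validate_sample_sheet(df)
  df
}

#' Assign barcodes to samples under a scheme
#'
#' Builds a sample sheet satisfying the scheme's exclusivity invariants.
#' Barcode order is shuffled deterministically from `seed`, then:
#' SB assigns one barcode per sample; UDB-H11 assigns disjoint unordered
#' pairs; UDB-H12 pairs barcode i (H1 side) with barcode i+1 mod k (H2 side),
#' a circular offset that guarantees the two barcodes of a sample differ;
#' CDB-H12 enumerates ordered pairs (i, j), i != j, and takes the first
#' `length(sample_ids)`.
#'
#' @param scheme One of [schemes()].
#' @param sample_ids Unique character vector of sample names.
#' @param barcodes A [barcode_set()] (H1 side for dual-head schemes).
#' @param barcodes2 Optional second [barcode_set()] for the H2 side
#'   (UDB_H12/CDB_H12 only); defaults to `barcodes` with circular-offset
#'   pairing.
#' @param seed Integer seed for the deterministic shuffle.
#' @param primer_pair Primer pair name or list (see [primer_pairs()]).
#' @return A `sample_sheet`: data.frame with columns `sample_id`, `scheme`,
#'   `primer_pair`, `bc1_id`, `bc1_seq`, `bc2_id`, `bc2_seq` (`bc2_*` is `NA`
#'   for SB).
#' @export
assign_samples <- function(scheme, sample_ids, barcodes, barcodes2 = NULL,
                           seed = 1L, primer_pair = "V4") {
  scheme <- .norm_scheme(scheme)
  barcodes <- .as_barcode_set(barcodes)
  pp <- .as_primer_pair(primer_pair)
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique", call. = FALSE)
  }
  n <- length(sample_ids)
  k <- nrow(barcodes)
  cap <- capacity(scheme, k)
  if (!is.null(barcodes2)) {
    barcodes2 <- .as_barcode_set(barcodes2)
    if (bc_len(barcodes2) != bc_len(barcodes)) {
      stop("barcodes and barcodes2 must have the same length", call. = FALSE)
    }
    if (scheme %in% c("SB", "UDB_H11")) {
      stop("barcodes2 only applies to UDB_H12/CDB_H12", call. = FALSE)
    }
    cap <- switch(scheme,
                  UDB_H12 = min(k, nrow(barcodes2)),
                  CDB_H12 = k * nrow(barcodes2))
  }
  if (n > cap) {
    stop(sprintf("capacity exceeded: scheme %s with this barcode set supports %d samples, got %d",
                 scheme, cap, n), call. = FALSE)
  }

  ord <- .with_substream(seed, "assign_samples", sample.int(k))
  b1 <- barcodes[ord, , drop = FALSE]
  if (is.null(barcodes2)) {
    b2 <- b1
    offset <- TRUE
  } else {
    ord2 <- .with_substream(seed, "assign_samples2",
                            sample.int(nrow(barcodes2)))
    b2 <- barcodes2[ord2, , drop = FALSE]
    offset <- FALSE
  }

  idx <- switch(
    scheme,
    SB = cbind(seq_len(n), NA_integer_),
    UDB_H11 = cbind(2L * seq_len(n) - 1L, 2L * seq_len(n)),
    UDB_H12 = {
      i <- seq_len(n)
      j <- if (offset) (i %% nrow(b2)) + 1L else i
      cbind(i, j)
    },
    CDB_H12 = {
      # ordered pairs (i, j): same-sequence pairs excluded
      i <- rep(seq_len(k), each = nrow(b2))
      j <- rep(seq_len(nrow(b2)), times = k)
      keep <- b1$seq[i] != b2$seq[j]
      cbind(i[keep], j[keep])[seq_len(n), , drop = FALSE]
    })

  sb <- scheme == "SB"
  df <- data.frame(
    sample_id = sample_ids,
    scheme = scheme,
    primer_pair = pp$name,
    bc1_id = b1$id[idx[, 1]],
    bc1_seq = b1$seq[idx[, 1]],
    bc2_id = if (sb) NA_character_ else b2$id[idx[, 2]],
    bc2_seq = if (sb) NA_character_ else b2$seq[idx[, 2]],
    stringsAsFactors = FALSE)
  .new_sample_sheet(df, scheme)
}

#' Validate a sample sheet against its scheme's invariants
#'
#' SB: each barcode used by at most one sample. UDB-H11: every barcode
#' appears in at most one sample's pair. UDB-H12: each barcode used at most
#' once per head side; the two barcodes of a sample differ. CDB-H12: ordered
#' pairs unique; the two barcodes of a sample differ.
#'
#' @param sheet A sample sheet data.frame (see [assign_samples()]).
#' @return The sheet, invisibly; stops with a message on violation.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "scheme", "primer_pair",
           "bc1_id", "bc1_seq", "bc2_id", "bc2_seq")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  scheme <- .norm_scheme(unique(sheet$scheme))
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sheet", call. = FALSE)
  }
  lens1 <- nchar(sheet$bc1_seq)
  if (length(unique(lens1)) > 1L) {
    stop("mixed barcode lengths in sheet", call. = FALSE)
  }
  if (scheme == "SB") {
    if (anyDuplicated(sheet$bc1_seq)) {
      stop("SB: a barcode is assigned to more than one sample", call. = FALSE)
    }
  } else if (scheme == "UDB_H11") {
    all_bc <- c(sheet$bc1_seq, sheet$bc2_seq)
    if (anyDuplicated(all_bc)) {
      stop("UDB_H11: a barcode appears in more than one sample's pair",
           call. = FALSE)
    }
  } else if (scheme == "UDB_H12") {
    if (anyDuplicated(sheet$bc1_seq) || anyDuplicated(sheet$bc2_seq)) {
      stop("UDB_H12: a barcode is reused on the same head side", call. = FALSE)
    }
    if (any(sheet$bc1_seq == sheet$bc2_seq)) {
      stop("UDB_H12: a sample uses the same barcode on both sides",
           call. = FALSE)
    }
  } else { # CDB_H12
    key <- paste(sheet$bc1_seq, sheet$bc2_seq, sep = "|")
    if (anyDuplicated(key)) {
      stop("CDB_H12: duplicated ordered barcode pair", call. = FALSE)
    }
    if (any(sheet$bc1_seq == sheet$bc2_seq)) {
      stop("CDB_H12: a sample uses the same barcode on both sides",
           call. = FALSE)
    }
  }
  invisible(sheet)
}

#' @export
print.sample_sheet <- function(x, ...) {
  cat(sprintf("<sample_sheet> scheme %s, %d samples, primer pair %s\n",
              unique(x$scheme), nrow(x),
              paste(unique(x$primer_pair), collapse = ",")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Read / write sample sheets as TSV
#'
#' Tab-separated, UTF-8, with header `sample_id scheme primer_pair bc1_id
#' bc1_seq bc2_id bc2_seq`; `#`-prefixed comment lines are ignored on read.
#'
#' @param path File path.
#' @return `read_sample_sheet` returns a validated `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("bc2_id", "bc2_seq")) {
    if (col %in% names(df)) df[[col]][df[[col]] == ""] <- NA_character_
  }
  .new_sample_sheet(df, .norm_scheme(unique(df$scheme)))
}

#' @rdname read_sample_sheet
#' @param sheet A `sample_sheet` to write.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  out <- as.data.frame(sheet)
  out$bc2_id[is.na(out$bc2_id)] <- ""
  out$bc2_seq[is.na(out$bc2_seq)] <- ""
  utils::write.table(out, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Build a decoder from observed barcode evidence to sample ids
#'
#' The decoder maps the ordered pair of barcodes observed on the (forward,
#' reverse) ends of a read pair to a sample. SB matches the single barcode
#' (both ends carry it). UDB-H11 cannot distinguish ends (both carry head
#' H1), so all four ordered combinations of a sample's two barcodes --
#' including the homo-combinations (a,a) and (b,b) that a two-primer
#' barcoding PCR necessarily produces -- map to that sample. UDB-H12 and
#' CDB-H12 look the ordered (H1-side, H2-side) pair up directly; pairs of
#' known barcodes not present in the sheet decode to "invalid combination".
#'
#' @param sheet A validated sample sheet.
#' @return An object of class `bc_decoder` used by the demultiplexer: holds
#'   the per-side barcode sets and the combination lookup.
#' @export
build_decoder <- function(sheet) {
  validate_sample_sheet(sheet)
  scheme <- .norm_scheme(unique(sheet$scheme))
  if (scheme == "SB") {
    side1 <- barcode_set(sheet$bc1_seq, sheet$bc1_id)
    side2 <- side1
    map <- stats::setNames(sheet$sample_id, sheet$bc1_seq)
  } else if (scheme == "UDB_H11") {
    all_seq <- c(sheet$bc1_seq, sheet$bc2_seq)
    all_id <- c(sheet$bc1_id, sheet$bc2_id)
    side1 <- barcode_set(all_seq, make.unique(all_id))
    side2 <- side1
    a <- sheet$bc1_seq
    b <- sheet$bc2_seq
    keys <- c(paste(a, b, sep = "|"), paste(b, a, sep = "|"),
              paste(a, a, sep = "|"), paste(b, b, sep = "|"))
    map <- stats::setNames(rep(sheet$sample_id, 4L), keys)
  } else {
    u1 <- !duplicated(sheet$bc1_seq)
    u2 <- !duplicated(sheet$bc2_seq)
    side1 <- barcode_set(sheet$bc1_seq[u1], sheet$bc1_id[u1])
    side2 <- barcode_set(sheet$bc2_seq[u2], sheet$bc2_id[u2])
    map <- stats::setNames(sheet$sample_id,
                           paste(sheet$bc1_seq, sheet$bc2_seq, sep = "|"))
  }
  pp <- .as_primer_pair(unique(sheet$primer_pair))
  out <- list(scheme = scheme, heads = .scheme_heads(scheme),
              bc_len = bc_len(side1), side1 = side1, side2 = side2,
              map = map, primer_pair = pp,
              samples = sheet$sample_id)
  class(out) <- "bc_decoder"
  out
}

#' @export
print.bc_decoder <- function(x, ...) {
  cat(sprintf("<bc_decoder> scheme %s: %d samples, %d/%d barcodes on fwd/rev side\n",
              x$scheme, length(x$samples), nrow(x$side1), nrow(x$side2)))
  invisible(x)
}

# Ordered-combination lookup; returns sample_id or NA (invalid combination).
.decode_combination <- function(decoder, seq1, seq2) {
  key <- if (decoder$scheme == "SB") seq1 else paste(seq1, seq2, sep = "|")
  unname(decoder$map[key])
}
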