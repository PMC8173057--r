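#' Construct a barcode set
#'
#' A barcode set is an ordered collection of distinct, equal-length DNA tags
#' used for sample multiplexing. Sets intended for error-tolerant
#' demultiplexing should keep a minimum pairwise Hamming distance of at least
#' 4 so that single sequencing errors cannot convert one barcode into another.
#'
#' @param seqs Character vector of barcode sequences over A/C/G/T
#'   (case-insensitive; normalized to upper case).
#' @param ids Optional character vector of barcode labels; defaults to
#'   `bc001`, `bc002`, ...
#' @return An object of class `barcode_set`: a data.frame with columns `id`
#'   and `seq`, and attribute `bc_len` (the common barcode length).
#' @examples
#' bs <- barcode_set(c("ACGTACGTACGT", "TGCATGCATGCA"))
#' distance_profile(bs)
#' @export
barcode_set <- function(seqs, ids = NULL) {
  seqs <- .norm_seq(seqs)
  if (length(seqs) == 0L) stop("barcode set must not be empty", call. = FALSE)
  if (!all(.is_dna(seqs))) {
    stop("barcode sequences must contain only A/C/G/T", call. = FALSE)
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("all barcodes in a set must have the same length", call. = FALSE)
  }
  if (anyDuplicated(seqs)) {
    stop("barcode sequences must be distinct", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- sprintf("bc%03d", seq_along(seqs))
  } else {
    ids <- as.character(ids)
    if (length(ids) != length(seqs)) {
      stop("ids and seqs must have equal length", call. = FALSE)
    }
    if (anyDuplicated(ids)) stop("barcode ids must be unique", call. = FALSE)
  }
  out <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  attr(out, "bc_len") <- as.integer(L)
  class(out) <- c("barcode_set", "data.frame")
  out
}

#' @export
print.barcode_set <- function(x, ...) {
  cat(sprintf("<barcode_set> %d barcodes of length %d nt\n",
              nrow(x), attr(x, "bc_len")))
  if (nrow(x) >= 2L) {
    dp <- distance_profile(x)
    cat(sprintf("  min Hamming distance %d, median %g\n", dp$min, dp$median))
  }
  invisible(x)
}

.as_barcode_set <- function(x) {
  if (inherits(x, "barcode_set")) return(x)
  if (is.character(x)) return(barcode_set(x))
  if (is.data.frame(x) && all(c("id", "seq") %in% names(x))) {
    return(barcode_set(x$seq, x$id))
  }
  stop("cannot interpret object as a barcode set", call. = FALSE)
}

bc_len <- function(set) attr(set, "bc_len")

#' Hamming distance between equal-length DNA strings
#'
#' Number of positions at which two strings differ. Vectorized elementwise
#' over pairs of equal-length vectors (with the usual recycling of a scalar).
#'
#' @param a,b Character vectors of equal-length strings.
#' @return Integer vector of distances.
#' @examples
#' hamming("AAAA", "TTTT") # 4
#' @export
hamming <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("a and b must have matching lengths", call. = FALSE)
  }
  if (any(nchar(a) != nchar(b))) {
    stop("strings must have equal length for Hamming distance", call. = FALSE)
  }
  if (length(a) == 0L) return(integer())
  vapply(seq_along(a), function(i) {
    sum(utf8ToInt(a[i]) != utf8ToInt(b[i]))
  }, integer(1))
}

#' Pairwise Hamming-distance profile of a barcode set
#'
#' Summarizes all `n*(n-1)/2` unordered pairwise distances: minimum, median
#' and the full histogram. Large minimum distances are what make mismatch-
#' tolerant demultiplexing unambiguous.
#'
#' @param set A [barcode_set()] (or coercible object) of at least 2 barcodes.
#' @return List with elements `min` (integer), `median` (numeric),
#'   `histogram` (named integer table over observed distances), `n_pairs`.
#' @examples
#' distance_profile(barcode_set(c("AAAA", "AATT", "TTTT")))
#' @export
distance_profile <- function(set) {
  set <- .as_barcode_set(set)
  if (nrow(set) < 2L) {
    stop("distance_profile requires at least 2 barcodes", call. = FALSE)
  }
  D <- .pairwise_hamming(set$seq)
  d <- D[upper.tri(D)]
  hist <- table(factor(d, levels = seq(min(d), max(d))))
  list(min = min(d), median = stats::median(d),
       histogram = hist, n_pairs = length(d))
}

#' Per-position base-composition profile of a barcode set
#'
#' Computes, for each barcode position, the frequency of A/C/G/T across the
#' set. A set with near-uniform composition (all frequencies near 0.25) keeps
#' per-cycle base diversity high on the sequencer, which matters because the
#' barcode is read in the first cycles.
#'
#' @param set A [barcode_set()] (or coercible object), non-empty.
#' @return Object of class `composition_profile`: list with `freq` (L x 4
#'   matrix, rows sum to 1) and `uniformity_score` (max |freq - 0.25|, in
#'   \[0, 0.75\]; 0 is perfectly uniform).
#' @examples
#' composition_profile(barcode_set(c("AA", "CC", "GG", "TT")))$uniformity_score
#' @export
composition_profile <- function(set) {
  set <- .as_barcode_set(set)
  M <- .char_mat(set$seq)
  freq <- t(apply(M, 2, function(col) {
    tabulate(factor(col, levels = DNA_BASES), nbins = 4L) / length(col)
  }))
  colnames(freq) <- DNA_BASES
  rownames(freq) <- paste0("pos", seq_len(nrow(freq)))
  out <- list(freq = freq, uniformity_score = max(abs(freq - 0.25)))
  class(out) <- "composition_profile"
  out
}

#' @export
print.composition_profile <- function(x, ...) {
  cat(sprintf("<composition_profile> %d positions, uniformity score %.4f\n",
              nrow(x$freq), x$uniformity_score))
  print(round(x$freq, 3))
  invisible(x)
}

.uniformity_score <- function(seqs) {
  M <- .char_mat(seqs)
  freq <- apply(M, 2, function(col) {
    tabulate(factor(col, levels = DNA_BASES), nbins = 4L) / length(col)
  })
  max(abs(freq - 0.25))
}

#' Select a barcode subset under distance and composition criteria
#'
#' Greedy packing under the minimum pairwise Hamming-distance constraint,
#' followed by local swap refinement that lowers the composition
#' `uniformity_score` while preserving the distance constraint. Candidates are
#' shuffled with the given seed before the greedy pass, so runs are
#' reproducible and ties are broken by post-shuffle order. Distance is a hard
#' constraint; composition uniformity is an objective, not a threshold.
#'
#' @param candidates Candidate pool, a [barcode_set()] or coercible object.
#' @param k Target subset size.
#' @param d_min Minimum allowed pairwise Hamming distance (default 4).
#' @param seed Integer seed controlling the shuffle / tie-breaking.
#' @param uniformity_weight Non-negative weight of the uniformity objective in
#'   swap refinement; 0 disables refinement.
#' @param max_sweeps Maximum refinement sweeps over the selected set.
#' @return A `barcode_set` of size at most `k` whose pairwise minimum distance
#'   is >= `d_min`. If no subset of size `k` was found, the largest subset
#'   found is returned with attribute `flagged = TRUE` and a warning.
#' @examples
#' pool <- random_barcodes(50, 12, seed = 1)
#' sel <- select_barcodes(pool, k = 10, d_min = 4, seed = 1)
#' validate_set(sel, d_min = 4)$pass
#' @export
select_barcodes <- function(candidates, k, d_min = 4L, seed = 1L,
                            uniformity_weight = 1, max_sweeps = 5L) {
  candidates <- .as_barcode_set(candidates)
  L <- bc_len(candidates)
  k <- as.integer(k)
  d_min <- as.integer(d_min)
  if (d_min < 1L) stop("d_min must be >= 1", call. = FALSE)
  if (d_min > L) {
    stop(sprintf("impossible constraint: d_min (%d) exceeds barcode length (%d)",
                 d_min, L), call. = FALSE)
  }
  if (k < 1L || k > nrow(candidates)) {
    stop("k must be between 1 and the candidate pool size", call. = FALSE)
  }

  ord <- .with_substream(seed, "select_barcodes",
                         sample.int(nrow(candidates)))
  seqs <- candidates$seq[ord]
  ids <- candidates$id[ord]
  D <- .pairwise_hamming(seqs)

  # Greedy packing in shuffled order: keep a candidate iff it is >= d_min
  # away from everything already kept.
  chosen <- integer(0)
  for (i in seq_along(seqs)) {
    if (length(chosen) >= k) break
    if (length(chosen) == 0L || all(D[i, chosen] >= d_min)) {
      chosen <- c(chosen, i)
    }
  }

  # Swap refinement: replace a chosen barcode by an unchosen candidate when
  # this keeps the distance constraint and lowers the uniformity score.
  if (uniformity_weight > 0 && length(chosen) >= 2L) {
    pool <- setdiff(seq_along(seqs), chosen)
    best <- .uniformity_score(seqs[chosen])
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (pos in seq_along(chosen)) {
        others <- chosen[-pos]
        for (cand in pool) {
          if (any(D[cand, others] < d_min)) next
          trial <- chosen
          trial[pos] <- cand
          sc <- .uniformity_score(seqs[trial])
          if (sc < best - 1e-12) {
            pool <- c(setdiff(pool, cand), chosen[pos])
            chosen <- trial
            best <- sc
            improved <- TRUE
            break
          }
        }
      }
      if (!improved) break
    }
  }

  chosen <- sort(chosen)
  out <- barcode_set(seqs[chosen], ids[chosen])
  if (nrow(out) < k) {
    warning(sprintf(
      "no subset of size %d at d_min=%d found; returning largest found (%d)",
      k, d_min, nrow(out)), call. = FALSE)
    attr(out, "flagged") <- TRUE
  } else {
    attr(out, "flagged") <- FALSE
  }
  out
}

#' Validate a barcode set against a minimum-distance requirement
#'
#' Report-based check: never throws on a bad set. Fails if any pair of
#' barcodes is closer than `d_min`, if any sequence is duplicated, or if
#' lengths are mixed.
#'
#' @param set Barcode set (or a data.frame/character vector coercible to one;
#'   duplicates and mixed lengths are tolerated here so they can be reported).
#' @param d_min Required minimum pairwise Hamming distance.
#' @return List with `pass` (logical), `offending` (data.frame of offending
#'   pairs: `id_a`, `id_b`, `distance`, `reason`), `min_distance` (NA if
#'   not computable).
#' @export
validate_set <- function(set, d_min = 4L) {
  if (inherits(set, "barcode_set")) {
    ids <- set$id
    seqs <- set$seq
  } else if (is.data.frame(set) && all(c("id", "seq") %in% names(set))) {
    ids <- as.character(set$id)
    seqs <- .norm_seq(set$seq)
  } else {
    seqs <- .norm_seq(set)
    ids <- sprintf("bc%03d", seq_along(seqs))
  }
  off <- data.frame(id_a = character(), id_b = character(),
                    distance = integer(), reason = character(),
                    stringsAsFactors = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1])
    off <- rbind(off, data.frame(
      id_a = ids[1], id_b = ids[bad], distance = NA_integer_,
      reason = "length_mismatch", stringsAsFactors = FALSE))
    return(list(pass = FALSE, offending = off, min_distance = NA_integer_))
  }
  dup <- which(duplicated(seqs))
  for (j in dup) {
    i <- match(seqs[j], seqs)
    off <- rbind(off, data.frame(
      id_a = ids[i], id_b = ids[j], distance = 0L,
      reason = "duplicate", stringsAsFactors = FALSE))
  }
  min_d <- NA_integer_
  if (length(seqs) >= 2L) {
    D <- .pairwise_hamming(seqs)
    ut <- which(upper.tri(D) & D < d_min & D > 0L, arr.ind = TRUE)
    if (nrow(ut) > 0L) {
      off <- rbind(off, data.frame(
        id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
        distance = D[ut], reason = "below_d_min", stringsAsFactors = FALSE))
    }
    min_d <- min(D[upper.tri(D)])
  }
  list(pass = nrow(off) == 0L, offending = off, min_distance = min_d)
}

#' Generate random DNA barcodes
#'
#' Uniform i.i.d. A/C/G/T sequences, deduplicated; mainly a candidate-pool
#' source for [select_barcodes()] and for testing.
#'
#' @param n Number of barcodes.
#' @param len Barcode length in nt.
#' @param seed Integer seed.
#' @return A [barcode_set()].
#' @export
random_barcodes <- function(n, len, seed = 1L) {
  seqs <- .with_substream(seed, "random_barcodes", {
    out <- character(0)
    while (length(out) < n) {
      need <- n - length(out)
      new <- vapply(seq_len(need), function(i) {
        paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      }, character(1))
      out <- unique(c(out, new))
    }
    out
  })
  barcode_set(seqs)
}

#' Read / write barcode lists as TSV
#'
#' Two-column tab-separated format (`id`, `sequence`); a header line is
#' optional on read and `#`-prefixed comment lines are ignored. Sequences are
#' normalized to upper case.
#'
#' @param path File path.
#' @return `read_barcodes` returns a [barcode_set()].
#' @export
read_barcodes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty barcode file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) {
    stop("barcode TSV must have two tab-separated columns (id, sequence)",
         call. = FALSE)
  }
  first <- toupper(trimws(parts[[1]][2]))
  if (!.is_dna(first)) parts <- parts[-1] # header line
  ids <- vapply(parts, `[`, character(1), 1L)
  seqs <- vapply(parts, `[`, character(1), 2L)
  barcode_set(seqs, ids)
}

#' @rdname read_barcodes
#' @param set A [barcode_set()] to write.
#' @export
write_barcodes <- function(set, path) {
  set <- .as_barcode_set(set)
  utils::write.table(
    data.frame(id = set$id, sequence = set$seq),
    file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
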