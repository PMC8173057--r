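# Evaluation metrics for demultiplexed or simulated count data: spurious-
# sequence calling against a mock reference, negative-control contamination,
# alpha diversity, Bray-Curtis dissimilarity, rarefaction, relative-abundance
# filtering and expected-vs-measured correlation.

.check_count_table <- function(table) {
  if (!is.matrix(table) || is.null(rownames(table)) ||
      is.null(colnames(table))) {
    stop("count table must be a matrix with row (sequence) and column (sample) names",
         call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  invisible(table)
}

#' Match sequences to a mock reference with mismatch tolerance
#'
#' A sequence is matched if it is within `max_mm` Hamming mismatches of some
#' reference variant of equal length; length-mismatched sequences are
#' spurious by definition. On ties the closest variant (first on equal
#' distance) is reported.
#'
#' @param seqs Character vector of query sequences.
#' @param ref A [mock_reference()].
#' @param max_mm Maximum tolerated mismatches (default 1).
#' @return Character vector of matched `variant_id`s, `NA` where spurious.
#' @export
match_to_reference <- function(seqs, ref, max_mm = 1L) {
  stopifnot(inherits(ref, "mock_reference"))
  out <- rep(NA_character_, length(seqs))
  if (length(seqs) == 0L) return(out)
  seqs <- .norm_seq(seqs)
  by_len <- split(seq_along(seqs), nchar(seqs))
  ref_len <- nchar(ref$seq)
  for (L in names(by_len)) {
    rset <- which(ref_len == as.integer(L))
    if (length(rset) == 0L) next
    idx <- by_len[[L]]
    D <- .dist_to_set(seqs[idx], ref$seq[rset])
    best <- apply(D, 1, which.min)
    bestd <- D[cbind(seq_along(idx), best)]
    hit <- bestd <= max_mm
    out[idx[hit]] <- ref$variant_id[rset][best[hit]]
  }
  out
}

#' Spurious-sequence and negative-control contamination report
#'
#' For every library (column) that is not a negative control: the number of
#' detected sequences matched to the mock reference, the number of spurious
#' (unmatched) sequences, and the fraction of reads in spurious sequences.
#' For every negative control: the number of detected sequences (all of
#' which are contamination by definition).
#'
#' @param table Count matrix, rows = sequences, columns = samples.
#' @param ref A [mock_reference()].
#' @param negative_control_ids Column names that are PCR negative controls.
#' @param max_mm Reference-matching mismatch tolerance (default 1).
#' @return Object of class `spurious_report`: list with `libraries`
#'   (data.frame: `sample_id`, `n_matched`, `n_spurious`,
#'   `fraction_spurious_reads`) and `negative_controls` (data.frame:
#'   `sample_id`, `n_detected`).
#' @export
spurious_report <- function(table, ref, negative_control_ids = character(),
                            max_mm = 1L) {
  .check_count_table(table)
  if (!all(negative_control_ids %in% colnames(table))) {
    stop("unknown negative-control column id(s): ",
         paste(setdiff(negative_control_ids, colnames(table)), collapse = ", "),
         call. = FALSE)
  }
  matched <- !is.na(match_to_reference(rownames(table), ref, max_mm))
  libs <- setdiff(colnames(table), negative_control_ids)
  lib_df <- do.call(rbind, lapply(libs, function(s) {
    x <- table[, s]
    det <- x > 0
    tot <- sum(x)
    data.frame(sample_id = s,
               n_matched = sum(det & matched),
               n_spurious = sum(det & !matched),
               fraction_spurious_reads = if (tot > 0) sum(x[!matched]) / tot else 0,
               stringsAsFactors = FALSE)
  }))
  nc_df <- do.call(rbind, lapply(negative_control_ids, function(s) {
    data.frame(sample_id = s, n_detected = sum(table[, s] > 0),
               stringsAsFactors = FALSE)
  }))
  if (is.null(lib_df)) lib_df <- data.frame(sample_id = character(),
                                            n_matched = integer(),
                                            n_spurious = integer(),
                                            fraction_spurious_reads = numeric())
  if (is.null(nc_df)) nc_df <- data.frame(sample_id = character(),
                                          n_detected = integer())
  structure(list(libraries = lib_df, negative_controls = nc_df),
            class = "spurious_report")
}

#' @export
print.spurious_report <- function(x, ...) {
  cat("<spurious_report>\n")
  if (nrow(x$libraries)) {
    cat(sprintf("  libraries: %d, total spurious sequences %d\n",
                nrow(x$libraries), sum(x$libraries$n_spurious)))
  }
  if (nrow(x$negative_controls)) {
    cat(sprintf("  negative controls: %d, detected sequences %s\n",
                nrow(x$negative_controls),
                paste(x$negative_controls$n_detected, collapse = ",")))
  }
  invisible(x)
}

#' Observed richness and the Chao1 estimator
#'
#' Observed richness is the number of non-zero entries. Chao1 uses the
#' bias-corrected form `S_obs + f1*(f1-1) / (2*(f2+1))` with `f1` singletons
#' and `f2` doubletons, so it is defined even without doubletons and always
#' `>= S_obs`.
#'
#' @param counts Non-negative integer count vector.
#' @return `observed_richness`: integer; `chao1`: numeric.
#' @examples
#' chao1(c(5, 1, 1, 2)) # 4.5
#' @export
observed_richness <- function(counts) {
  .check_counts_vec(counts)
  sum(counts > 0)
}

.check_counts_vec <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  invisible(counts)
}

#' @rdname observed_richness
#' @export
chao1 <- function(counts) {
  .check_counts_vec(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' `sum(|x - y|) / sum(x + y)`: 0 for identical vectors, 1 for disjoint
#' supports.
#'
#' @param x,y Non-negative numeric vectors of equal length, not both zero.
#' @return Dissimilarity in \[0, 1\].
#' @examples
#' bray_curtis(c(2, 1, 0), c(0, 1, 3)) # 5/7
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (any(x < 0) || any(y < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- sum(x + y)
  if (tot == 0) {
    stop("Bray-Curtis undefined for two all-zero vectors", call. = FALSE)
  }
  sum(abs(x - y)) / tot
}

#' Rarefy a count vector to a fixed depth
#'
#' Random subsampling without replacement (multivariate hypergeometric).
#'
#' @param counts Non-negative integer vector.
#' @param depth Target depth, `<= sum(counts)`.
#' @param seed Integer seed.
#' @return Integer vector of the same length summing to `depth`.
#' @export
rarefy <- function(counts, depth, seed = 1L) {
  .check_counts_vec(counts)
  depth <- as.integer(depth)
  if (depth < 0 || depth > sum(counts)) {
    stop("depth must be between 0 and sum(counts)", call. = FALSE)
  }
  if (depth == sum(counts)) return(as.integer(counts))
  .with_substream(seed, "rarefy", {
    picked <- sample(rep.int(seq_along(counts), counts), depth)
    tabulate(picked, nbins = length(counts))
  })
}

#' Drop sequences that never exceed a relative-abundance threshold
#'
#' A row survives iff its per-sample relative abundance strictly exceeds
#' `threshold` in at least one sample; counts of surviving rows are
#' unchanged. The default 0.25% is the spurious-sequence filter used for
#' batch-effect analysis.
#'
#' @param table Count matrix, rows = sequences, columns = samples.
#' @param threshold Relative-abundance threshold in \[0, 1\] (default
#'   0.0025).
#' @return Filtered count matrix.
#' @export
abundance_filter <- function(table, threshold = 0.0025) {
  .check_count_table(table)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0, 1]", call. = FALSE)
  }
  totals <- colSums(table)
  rel <- sweep(table, 2, pmax(totals, 1), "/")
  keep <- apply(rel, 1, function(r) any(r > threshold))
  table[keep, , drop = FALSE]
}

#' Expected-versus-measured mock-composition correlation
#'
#' Aggregates reference variants into species, sums measured counts of
#' sequences matched (within `max_mm`) to each species across the samples of
#' each pool, and correlates log-transformed measured relative abundances
#' with log expected abundances (Pearson). Members undetected in a pool are
#' excluded from that pool's correlation; pools with fewer than 2 shared
#' members are skipped with a warning. Per-pool coefficients are averaged.
#'
#' @param table Count matrix, rows = sequences, columns = samples.
#' @param ref A [mock_reference()].
#' @param pools Named list: pool name -> character vector of column ids.
#' @param max_mm Reference-matching tolerance (default 1).
#' @param exclude_members Species labels to drop before correlating (e.g.
#'   members suspected to be external contamination).
#' @return List with `per_pool` (named numeric vector of Pearson r) and
#'   `mean_r`.
#' @export
expected_vs_measured <- function(table, ref, pools, max_mm = 1L,
                                 exclude_members = character()) {
  .check_count_table(table)
  stopifnot(inherits(ref, "mock_reference"))
  if (!all(unlist(pools) %in% colnames(table))) {
    stop("pools reference unknown sample columns", call. = FALSE)
  }
  keep <- !(ref$species %in% exclude_members)
  expected <- tapply(ref$abundance[keep], ref$species[keep], sum)
  hit <- match_to_reference(rownames(table), ref, max_mm)
  species <- ref$species[match(hit, ref$variant_id)]

  per_pool <- numeric(0)
  for (pn in names(pools)) {
    cols <- pools[[pn]]
    counts <- rowSums(table[, cols, drop = FALSE])
    sp_counts <- tapply(counts[!is.na(species)], species[!is.na(species)], sum)
    sp_counts <- sp_counts[!(names(sp_counts) %in% exclude_members)]
    shared <- names(sp_counts)[sp_counts > 0]
    shared <- intersect(shared, names(expected)[expected > 0])
    if (length(shared) < 2L) {
      warning(sprintf("pool '%s' skipped: fewer than 2 shared detected members",
                      pn), call. = FALSE)
      next
    }
    meas <- sp_counts[shared] / sum(sp_counts)
    exp_ab <- expected[shared] / sum(expected)
    per_pool[pn] <- stats::cor(log(exp_ab), log(meas), method = "pearson")
  }
  list(per_pool = per_pool,
       mean_r = if (length(per_pool)) mean(per_pool) else NA_real_)
}

#' Read / write count tables as TSV
#'
#' First column `sequence` (row ids), remaining columns samples.
#'
#' @param path File path.
#' @return `read_count_table` returns an integer matrix.
#' @export
read_count_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  .check_count_table(mat)
}

#' @rdname read_count_table
#' @param table Count matrix to write.
#' @export
write_count_table <- function(table, path) {
  .check_count_table(table)
  utils::write.table(data.frame(sequence = rownames(table), table,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
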