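# Internal string/RNG utilities shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# N x L character matrix from equal-length sequences.
.char_mat <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(character(), 0L, 0L))
  L <- nchar(seqs)
  if (length(unique(L)) != 1L) {
    stop("sequences must all have the same length", call. = FALSE)
  }
  matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
         nrow = n, byrow = TRUE)
}

.is_dna <- function(seqs) {
  !grepl("[^ACGT]", seqs)
}

.norm_seq <- function(seqs) {
  toupper(trimws(as.character(seqs)))
}

# Full symmetric pairwise Hamming distance matrix (integer).
.pairwise_hamming <- function(seqs) {
  M <- .char_mat(seqs)
  n <- nrow(M)
  D <- matrix(0L, n, n)
  if (n < 2L) return(D)
  for (i in seq_len(n - 1L)) {
    idx <- (i + 1L):n
    ref <- matrix(M[i, ], length(idx), ncol(M), byrow = TRUE)
    d <- as.integer(rowSums(M[idx, , drop = FALSE] != ref))
    D[i, idx] <- d
    D[idx, i] <- d
  }
  D
}

# Distances of each observed sequence (rows) to each set sequence (cols).
.dist_to_set <- function(obs, set_seqs) {
  Mo <- .char_mat(obs)
  Ms <- .char_mat(set_seqs)
  out <- matrix(NA_integer_, nrow(Mo), nrow(Ms))
  if (nrow(Mo) == 0L || nrow(Ms) == 0L) return(out)
  if (ncol(Mo) != ncol(Ms)) {
    stop("observed and set sequences differ in length", call. = FALSE)
  }
  for (j in seq_len(nrow(Ms))) {
    ref <- matrix(Ms[j, ], nrow(Mo), ncol(Mo), byrow = TRUE)
    out[, j] <- as.integer(rowSums(Mo != ref))
  }
  out
}

# Per-position allowed-base sets for an IUPAC pattern.
.iupac_allowed <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  codes <- Biostrings::IUPAC_CODE_MAP[chars]
  if (anyNA(codes)) {
    bad <- unique(chars[is.na(codes)])
    stop("invalid IUPAC character(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  strsplit(unname(codes), "", fixed = TRUE)
}

# Mismatch counts of equal-length observed strings against one IUPAC pattern.
.iupac_mm_vec <- function(pattern, obs) {
  allowed <- .iupac_allowed(pattern)
  if (length(obs) == 0L) return(integer())
  Mo <- .char_mat(obs)
  if (ncol(Mo) != length(allowed)) {
    stop("observed and pattern differ in length", call. = FALSE)
  }
  mm <- integer(nrow(Mo))
  for (l in seq_along(allowed)) {
    mm <- mm + !(Mo[, l] %in% allowed[[l]])
  }
  mm
}

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Evaluate expr under a named RNG substream derived from a master seed, then
# restore the caller's RNG state. Substreams keep module outputs independently
# reproducible from one master seed.
.with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  sub <- .substream_seed(seed, stream)
  set.seed(sub)
  expr
}

.substream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
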