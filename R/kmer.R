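# Canonical k-mer scan used to choose a rotation point inside single-copy
# territory, so the inverted repeat never straddles the artificial sequence
# start during detection.

#' Detection parameters
#'
#' @param k k-mer size in bp for the single-copy scan.
#' @param step k-mer step in bp.
#' @param min_ir_len minimum inverted-repeat arm length in bp for a genome
#'   to pass the filter; arms strictly shorter are filtered.
#' @param chain_gap maximum gap in bp when chaining collinear exact inverted
#'   matches into one arm (tolerates point divergence between the two
#'   deposited IR copies).
#' @param seed_len exact-match seed length in bp for the inverted-repeat
#'   finder; arms shorter than this are not detectable.
#' @param run_mode rule choosing the rotation point within single-copy
#'   k-mer territory; `"longest-run-midpoint"` (the only implemented rule)
#'   takes the midpoint of the longest maximal run of single-copy k-mer
#'   positions, maximizing distance from the IR boundaries.
#' @return object of class `cpj_params`.
#' @export
detection_params <- function(k = 55L, step = 1L, min_ir_len = 100L,
                             chain_gap = 10L, seed_len = 20L,
                             run_mode = "longest-run-midpoint") {
  k <- as.integer(k); step <- as.integer(step)
  min_ir_len <- as.integer(min_ir_len); chain_gap <- as.integer(chain_gap)
  seed_len <- as.integer(seed_len)
  stopifnot(k >= 2L, step >= 1L, min_ir_len >= 1L, chain_gap >= 0L,
            seed_len >= 2L, run_mode == "longest-run-midpoint")
  structure(list(k = k, step = step, min_ir_len = min_ir_len,
                 chain_gap = chain_gap, seed_len = seed_len,
                 run_mode = run_mode),
            class = "cpj_params")
}

# All windows of the sequence as strings, plus their reverse complements,
# computed in O(1) per window from the reverse complement of the whole
# sequence. Returns list(fwd, rc, valid) where valid flags windows free of
# non-ACGT letters.
sequence_windows <- function(sequence, k, starts) {
  m <- nchar(sequence)
  fwd <- substring(sequence, starts, starts + k - 1L)
  rc_full <- revcomp(sequence)
  rc <- substring(rc_full, m - (starts + k - 1L) + 1L, m - starts + 1L)
  valid <- !grepl("[^ACGT]", fwd)
  list(fwd = fwd, rc = rc, valid = valid)
}

#' Canonical k-mer counts
#'
#' Every window contributes one count keyed by the lexicographically smaller
#' of the k-mer and its reverse complement, so a k-mer and its mirror in the
#' opposite IR arm share one key with count 2. For circular topology windows
#' wrap the origin so every base starts one window. Windows containing
#' non-ACGT letters are excluded.
#'
#' @param sequence nucleotide string.
#' @param k window size in bp.
#' @param step window step in bp.
#' @param topology `"circular"` or `"linear"`.
#' @return named integer vector of counts per canonical k-mer.
#' @export
canonical_kmer_counts <- function(sequence, k, step = 1L,
                                  topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  n <- nchar(sequence)
  if (n < k) stop("sequence (", n, " bp) shorter than k = ", k)
  prof <- kmer_profile(sequence, k, step, topology)
  counts <- table(prof$canon[prof$valid])
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

# Per-window canonical k-mer and validity (internal; shared by the count
# table and the single-copy profile so both agree on window handling).
kmer_profile <- function(sequence, k, step, topology) {
  n <- nchar(sequence)
  if (topology == "circular") {
    ext <- paste0(sequence, substr(sequence, 1L, k - 1L))
    starts <- seq.int(1L, n, by = step)
  } else {
    ext <- sequence
    starts <- seq.int(1L, n - k + 1L, by = step)
  }
  w <- sequence_windows(ext, k, starts)
  canon <- ifelse(w$fwd <= w$rc, w$fwd, w$rc)
  list(starts = starts, canon = canon, valid = w$valid)
}

# Logical vector over window starts: TRUE where the canonical k-mer of the
# window occurs exactly once genome-wide. Invalid (ambiguity-containing)
# windows are never single-copy.
single_copy_profile <- function(sequence, k, topology) {
  prof <- kmer_profile(sequence, k, 1L, topology)
  counts <- table(prof$canon[prof$valid])
  cnt <- as.integer(counts[prof$canon])
  single <- prof$valid & !is.na(cnt) & cnt == 1L
  single
}

#' Choose a rotation point inside single-copy territory
#'
#' Computes the single-copy k-mer profile of the circular genome and returns
#' the 0-based rotation offset placing the new start at the midpoint of the
#' longest maximal run of consecutive single-copy positions (wrap-aware).
#' Starting mid-run keeps the inverted repeat wholly internal to the rotated
#' sequence.
#'
#' @param genome an [annotated_genome()] (circular).
#' @param params [detection_params()].
#' @return 0-based rotation offset.
#' @export
find_rotation_point <- function(genome, params = detection_params()) {
  seq <- if (inherits(genome, "cpj_genome")) genome$sequence else genome
  n <- nchar(seq)
  v <- single_copy_profile(seq, params$k, "circular")
  if (!any(v)) stop("no single-copy region found")
  if (all(v)) {
    run_start <- 1L
    run_len <- n
  } else {
    # Rotate the profile to start just after a FALSE so runs never wrap.
    i0 <- which(!v)[1L]
    w <- v[((seq_len(n) + i0 - 1L) %% n) + 1L]  # w[r] == v at orig (i0 + r - 1) %% n + 1
    r <- rle(w)
    ends <- cumsum(r$lengths)
    starts_rot <- ends - r$lengths + 1L
    true_runs <- which(r$values)
    lens <- r$lengths[true_runs]
    starts_orig <- ((i0 + starts_rot[true_runs] - 1L) %% n) + 1L
    best <- which(lens == max(lens))
    best <- best[which.min(starts_orig[best])]
    run_start <- starts_orig[best]
    run_len <- lens[best]
  }
  mid <- ((run_start - 1L + (run_len - 1L) %/% 2L) %% n) + 1L
  mid - 1L
}
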