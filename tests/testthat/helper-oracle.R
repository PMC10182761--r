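# Independent oracles used to check the k-mer scan and the inverted-repeat
# finder. Implemented from first principles (character vectors, per
# anti-diagonal scans), sharing no code with the package internals.

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force canonical k-mer counts: one window at a time, reverse
# complement by reversing a character vector.
oracle_kmer_counts <- function(seq, k, topology = "linear", step = 1L) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  if (topology == "circular") ch2 <- c(ch, ch[seq_len(k - 1L)]) else ch2 <- ch
  starts <- seq.int(1L, if (topology == "circular") n else n - k + 1L, by = step)
  canon <- vapply(starts, function(i) {
    w <- ch2[i:(i + k - 1L)]
    if (any(!w %in% names(.ORACLE_COMP))) return(NA_character_)
    rc <- rev(unname(.ORACLE_COMP[w]))
    fw <- paste(w, collapse = "")
    rc <- paste(rc, collapse = "")
    if (fw <= rc) fw else rc
  }, character(1L))
  tab <- table(canon[!is.na(canon)])
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

# Brute-force longest non-overlapping inverted pair: scan every
# anti-diagonal of the complement-match matrix, restricted to cells below
# the self-overlap line, and take the longest run (ties: smallest first-arm
# start, then smallest second-arm start). Returns list(arm_1, arm_2,
# length) or NULL.
oracle_longest_inverted_pair <- function(seq) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  comp <- unname(.ORACLE_COMP[ch])
  comp[is.na(comp)] <- "#"
  best <- NULL
  for (cd in 3:(2L * n - 1L)) {
    i_lo <- max(1L, cd - n)
    i_hi <- (cd - 1L) %/% 2L
    if (i_hi < i_lo) next
    i <- i_lo:i_hi
    w <- ch[i] == comp[cd - i]
    if (!any(w)) next
    r <- rle(w)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (kk in which(r$values)) {
      L <- r$lengths[kk]
      a <- i[starts[kk]]
      e <- cd - a
      q <- e - L + 1L
      if (is.null(best) ||
          L > best$length ||
          (L == best$length && (a < best$arm_1[1L] ||
                                (a == best$arm_1[1L] && q < best$arm_2[1L])))) {
        best <- list(arm_1 = c(a, a + L - 1L), arm_2 = c(q, e), length = L)
      }
    }
  }
  best
}

# Random sequence with a planted inverted repeat: arm_2 = revcomp(arm_1),
# arms separated by at least `gap` bases.
plant_inverted_repeat <- function(n, arm_len, gap = 25L) {
  stopifnot(n >= 2L * arm_len + gap + 2L)
  base <- strsplit(rand_dna(n), "")[[1L]]
  p <- sample.int(n - 2L * arm_len - gap + 1L, 1L)
  qlo <- p + arm_len + gap
  qhi <- n - arm_len + 1L
  q <- qlo + sample.int(qhi - qlo + 1L, 1L) - 1L
  arm <- strsplit(rand_dna(arm_len), "")[[1L]]
  rc <- rev(unname(.ORACLE_COMP[arm]))
  base[p:(p + arm_len - 1L)] <- arm
  base[q:(q + arm_len - 1L)] <- rc
  list(seq = paste(base, collapse = ""), arm_1 = c(p, p + arm_len - 1L),
       arm_2 = c(q, q + arm_len - 1L))
}
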