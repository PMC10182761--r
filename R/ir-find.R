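# Native inverted-repeat finder: exact-match seeds on anti-diagonals,
# merged into maximal exact inverted matches, optionally chained across
# small gaps to tolerate point divergence between the deposited IR copies.
#
# A seed is a pair (i, j), i < j, with window(i) equal to the reverse
# complement of window(j). All seeds of one exact inverted match share the
# anti-diagonal c = i + j, with consecutive i, so maximal matches are runs
# of consecutive i within an anti-diagonal group.

# Occurrence cap per seed k-mer; guards against low-complexity blowup.
.SEED_OCC_CAP <- 64L

#' Find the longest inverted repeat of a linear(ized) sequence
#'
#' Returns the maximum-length pair of non-overlapping substrings where one
#' is the exact reverse complement of the other, after chaining collinear
#' exact matches separated by at most `chain_gap` bp on the same
#' anti-diagonal. Ties are broken by the leftmost first-arm start, then the
#' leftmost second-arm start. Palindromic matches that would overlap
#' themselves are truncated to the longest non-overlapping sub-pair.
#'
#' @param sequence nucleotide string without origin wrap (rotate first).
#' @param params [detection_params()]; `seed_len` bounds the shortest
#'   detectable arm, `chain_gap` the tolerated divergence gaps.
#' @return a `cpj_irpair` with `arm_1` (leftmost), `arm_2`, the common arm
#'   `length`, and `mismatch` (total chained gap bases), or `NULL` when no
#'   inverted pair of at least `seed_len` bp exists.
#' @export
find_longest_inverted_repeat <- function(sequence, params = detection_params()) {
  n <- nchar(sequence)
  s <- params$seed_len
  if (n < 2L * s) return(NULL)

  starts <- seq_len(n - s + 1L)
  w <- sequence_windows(sequence, s, starts)

  ok <- which(w$valid)
  if (length(ok) == 0L) return(NULL)
  buckets <- split(ok, w$fwd[ok])
  sizes <- lengths(buckets)
  buckets <- buckets[sizes <= .SEED_OCC_CAP]
  hit <- match(w$rc, names(buckets))
  jj_all <- which(!is.na(hit) & w$valid)
  if (length(jj_all) == 0L) return(NULL)
  reps <- lengths(buckets)[hit[jj_all]]
  jj <- rep.int(jj_all, reps)
  ii <- unlist(buckets[hit[jj_all]], use.names = FALSE)
  keep <- ii < jj
  ii <- ii[keep]; jj <- jj[keep]
  if (length(ii) == 0L) return(NULL)

  groups <- split(ii, ii + jj)
  cand <- list()
  for (nm in names(groups)) {
    c_diag <- as.integer(nm)
    i_sorted <- sort(unique(groups[[nm]]))
    # maximal runs of consecutive i
    brk <- c(0L, which(diff(i_sorted) != 1L), length(i_sorted))
    runs <- Map(function(a, b) i_sorted[(a + 1L):b],
                utils::head(brk, -1L), utils::tail(brk, -1L))
    # each run -> match (p, L); chain runs with base-gap <= chain_gap
    p <- vapply(runs, function(r) r[1L], integer(1L))
    lastseed <- vapply(runs, function(r) r[length(r)], integer(1L))
    L <- lastseed - p + s
    k <- 1L
    while (k <= length(p)) {
      pp <- p[k]; LL <- L[k]; mism <- 0L
      while (k < length(p)) {
        gap <- p[k + 1L] - (pp + LL)
        if (gap >= 1L && gap <= params$chain_gap) {
          mism <- mism + gap
          LL <- (p[k + 1L] + L[k + 1L] - 1L) - pp + 1L
          k <- k + 1L
        } else break
      }
      cand[[length(cand) + 1L]] <- c(p = pp, L = LL, c = c_diag, mism = mism)
      k <- k + 1L
    }
  }
  if (length(cand) == 0L) return(NULL)
  cm <- do.call(rbind, cand)
  p <- cm[, "p"]; L <- cm[, "L"]; mism <- cm[, "mism"]
  e <- cm[, "c"] - p + s - 1L          # second-arm end
  q <- e - L + 1L                      # second-arm start

  # truncate self-overlapping (palindromic) pairs to the longest
  # non-overlapping sub-pair
  ov <- p + L - 1L >= q
  if (any(ov)) {
    Cbase <- p + e                     # base-level anti-diagonal
    Ltr <- (Cbase - 2L * p + 1L) %/% 2L
    L[ov] <- Ltr[ov]
    q[ov] <- e[ov] - L[ov] + 1L
    mism[ov] <- 0L
  }
  valid <- L >= 1L & p + L - 1L < q
  if (!any(valid)) return(NULL)
  p <- p[valid]; L <- L[valid]; q <- q[valid]; e <- e[valid]; mism <- mism[valid]

  best <- order(-L, p, q)[1L]
  ir_pair(c(p[best], p[best] + L[best] - 1L), c(q[best], e[best]),
          L[best], mism[best])
}
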