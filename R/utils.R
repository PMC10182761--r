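# Circular-coordinate helpers shared across the package.
#
# All genome coordinates are 1-based inclusive. An interval with start > end
# wraps through the sequence origin (the convention used by published tetrad
# coordinate tables for records whose linearization starts inside a region).

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps the
#' package working on plain character vectors.
#'
#' @param x single nucleotide string (IUPAC alphabet).
#' @return reverse-complemented string, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Rotate a sequence so that `offset + 1` becomes the first base
#'
#' @param sequence nucleotide string.
#' @param offset 0-based rotation amount, `0 <= offset < nchar(sequence)`.
#' @return rotated string: `rotated[i] == original[(i + offset) mod length]`.
#' @export
rotate_sequence <- function(sequence, offset) {
  n <- nchar(sequence)
  stopifnot(offset >= 0L, offset < n)
  if (offset == 0L) return(sequence)
  paste0(substr(sequence, offset + 1L, n), substr(sequence, 1L, offset))
}

# Length of a circular interval (start > end wraps the origin).
ivl_length <- function(start, end, n) {
  if (start <= end) end - start + 1L else n - start + 1L + end
}

# Is position p inside the (possibly wrapping) interval [start, end]?
pos_in_ivl <- function(p, start, end) {
  if (start <= end) p >= start & p <= end else p >= start | p <= end
}

# Map a position from rotated coordinates back to deposited coordinates.
# offset is the 0-based rotation that was applied (rotated base 1 sits at
# deposited base offset + 1).
pos_to_deposited <- function(pos, offset, n) {
  ((pos - 1L + offset) %% n) + 1L
}

# Map a deposited position into the coordinates of a rotation by `offset`.
pos_from_deposited <- function(pos, offset, n) {
  ((pos - 1L - offset) %% n) + 1L
}

#' Map an interval from rotated back to deposited coordinates
#'
#' Applies the deposited-position formula to both endpoints; the result may
#' wrap the origin (start > end).
#'
#' @param interval length-2 integer vector `c(start, end)` in rotated
#'   coordinates.
#' @param offset the 0-based rotation that produced those coordinates.
#' @param genome_length total sequence length in bp.
#' @return length-2 integer vector in deposited coordinates.
#' @export
map_to_original <- function(interval, offset, genome_length) {
  stopifnot(length(interval) == 2L)
  c(
    pos_to_deposited(interval[1L], offset, genome_length),
    pos_to_deposited(interval[2L], offset, genome_length)
  )
}

# Circular forward distance from position a to position b (0 when a == b).
circ_dist_fwd <- function(a, b, n) (b - a) %% n

# --- logging -----------------------------------------------------------------

.log_levels <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)

cpj_log_level <- function() {
  lvl <- getOption("cpjunctions.log_level", "warn")
  if (!lvl %in% names(.log_levels)) lvl <- "warn"
  lvl
}

# Structured log line: level, accession, stage, message.
cpj_log <- function(level, msg, accession = NA_character_, stage = NA_character_) {
  if (.log_levels[[level]] < .log_levels[[cpj_log_level()]]) return(invisible(NULL))
  parts <- c(toupper(level), accession, stage, msg)
  parts <- parts[!is.na(parts)]
  message(paste(parts, collapse = " | "))
  invisible(NULL)
}

# Locale-stable thousands formatting for figure labels.
format_bp <- function(x) {
  formatC(x, format = "d", big.mark = ",")
}
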