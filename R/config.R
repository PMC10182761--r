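# Two-column tab-separated configuration files: column 1 is a GenBank file
# path, optional column 2 a region string overriding tetrad detection.

#' Parse a tetrad region string
#'
#' Accepts the coordinate convention of published tetrad tables:
#' `"LSC:s-e;IRb:s-e;SSC:s-e;IRa:s-e"` with `;` or `,` between regions,
#' ASCII dash or en-dash between coordinates, and start > end denoting a
#' region that wraps the sequence origin.
#'
#' @param text region string naming all four regions.
#' @param genome_length optional total length in bp; when supplied the
#'   resulting tetrad is validated against it.
#' @return a [tetrad()] (unvalidated when `genome_length` is absent).
#' @export
parse_tetrad_string <- function(text, genome_length = NA) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("–", "-", text)
  parts <- trimws(strsplit(clean, "[;,]")[[1L]])
  parts <- parts[nzchar(parts)]
  ivs <- list()
  for (p in parts) {
    m <- regmatches(p, regexec("^(LSC|IRb|SSC|IRa)\\s*:\\s*(\\d+)\\s*-\\s*(\\d+)$",
                               p, ignore.case = TRUE))[[1L]]
    if (length(m) != 4L) stop("malformed region token '", p, "' in: ", text)
    lab <- c(lsc = "lsc", irb = "irb", ssc = "ssc", ira = "ira")[[tolower(m[2L])]]
    if (!is.null(ivs[[lab]])) stop("duplicate region label '", m[2L], "' in: ", text)
    ivs[[lab]] <- as.integer(m[3:4])
  }
  missing <- setdiff(c("lsc", "irb", "ssc", "ira"), names(ivs))
  if (length(missing) > 0L) {
    stop("region string is missing ", paste(toupper(missing), collapse = ", "),
         ": ", text)
  }
  tetrad(ivs$lsc, ivs$irb, ivs$ssc, ivs$ira, genome_length)
}

#' Parse a two-column configuration file
#'
#' Column 1: path to a GenBank file; optional column 2: a region string
#' (see [parse_tetrad_string()]) overriding tetrad detection for that file.
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path configuration file path.
#' @return list of entries, each `list(gb_path =, custom_tetrad = tetrad or
#'   NULL)`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    cols <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    gb_path <- trimws(cols[1L])
    custom <- NULL
    if (length(cols) >= 2L && nzchar(trimws(cols[2L]))) {
      custom <- tryCatch(
        parse_tetrad_string(trimws(cols[2L])),
        error = function(e) {
          stop("configuration line ", i, ": ", conditionMessage(e), call. = FALSE)
        }
      )
    }
    out[[length(out) + 1L]] <- list(gb_path = gb_path, custom_tetrad = custom)
  }
  out
}
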