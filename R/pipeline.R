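# End-to-end wiring: parse -> (custom tetrad | detect) -> filter ->
# standardize -> junctions -> figure + tables.

#' Detect the inverted-repeat pair of a genome
#'
#' For circular records the genome is first rotated to start inside
#' single-copy territory (so the IR cannot straddle the artificial origin),
#' the longest inverted repeat is found on the rotated sequence, and the
#' arm coordinates are mapped back to the deposited orientation. Linear
#' records are searched as-is (rotation of a linear molecule is
#' meaningless); an arm touching a sequence end is logged as possibly
#' truncated.
#'
#' @param genome an [annotated_genome()].
#' @param params [detection_params()].
#' @return `list(ir = cpj_irpair or NULL, offset = rotation applied)`; arm
#'   coordinates in deposited coordinates (wrap-encoded when applicable).
#' @export
detect_tetrad <- function(genome, params = detection_params()) {
  n <- genome$length
  offset <- 0L
  if (genome$topology == "circular") {
    offset <- find_rotation_point(genome, params)
    cpj_log("debug", sprintf("rotation offset %d", offset),
            accession = genome$accession, stage = "rotate")
  }
  seq_rot <- rotate_sequence(genome$sequence, offset)
  ir_rot <- find_longest_inverted_repeat(seq_rot, params)
  if (is.null(ir_rot)) {
    cpj_log("info", "no inverted repeat found",
            accession = genome$accession, stage = "detect")
    return(list(ir = NULL, offset = offset))
  }
  if (genome$topology == "linear" &&
      (ir_rot$arm_1[1L] == 1L || ir_rot$arm_2[2L] == n)) {
    cpj_log("warn", "IR truncated at sequence end",
            accession = genome$accession, stage = "detect")
  }
  ir <- ir_pair(map_to_original(ir_rot$arm_1, offset, n),
                map_to_original(ir_rot$arm_2, offset, n),
                ir_rot$length, ir_rot$mismatch)
  cpj_log("info",
          sprintf("IR arms %d..%d / %d..%d (%d bp, rotated %d..%d / %d..%d)",
                  ir$arm_1[1L], ir$arm_1[2L], ir$arm_2[1L], ir$arm_2[2L],
                  ir$length, ir_rot$arm_1[1L], ir_rot$arm_1[2L],
                  ir_rot$arm_2[1L], ir_rot$arm_2[2L]),
          accession = genome$accession, stage = "detect")
  list(ir = ir, offset = offset)
}

# Marker for a genome excluded by the filter (not an error).
skip_result <- function(genome, reason) {
  structure(list(accession = genome$accession, reason = reason),
            class = "cpj_skip")
}

#' Process one genome through detection, filtering, and standardization
#'
#' @param genome an [annotated_genome()].
#' @param params [detection_params()].
#' @param custom_tetrad optional [tetrad()] (e.g. from a configuration
#'   file) that bypasses detection; the annotation filter still applies.
#' @return a result list (`genome`, `tetrad` in deposited coordinates,
#'   `group`, `standardized`, `view`) or a `cpj_skip` naming the filter
#'   rule that excluded the genome.
#' @export
process_genome <- function(genome, params = detection_params(),
                           custom_tetrad = NULL) {
  if (!is.null(custom_tetrad)) {
    tet <- tetrad(
      c(custom_tetrad$lsc$start, custom_tetrad$lsc$end),
      c(custom_tetrad$irb$start, custom_tetrad$irb$end),
      c(custom_tetrad$ssc$start, custom_tetrad$ssc$end),
      c(custom_tetrad$ira$start, custom_tetrad$ira$end),
      genome_length = genome$length
    )
    if (length(genome$genes) == 0L) {
      cpj_log("info", "filtered: unannotated", accession = genome$accession,
              stage = "filter")
      return(skip_result(genome, "unannotated"))
    }
  } else {
    det <- tryCatch(detect_tetrad(genome, params), error = function(e) e)
    if (inherits(det, "error")) {
      cpj_log("info", paste("filtered:", conditionMessage(det)),
              accession = genome$accession, stage = "filter")
      return(skip_result(genome, conditionMessage(det)))
    }
    verdict <- passes_filter(genome, det$ir, params)
    if (!verdict$pass) {
      cpj_log("info", paste("filtered:", verdict$reason),
              accession = genome$accession, stage = "filter")
      return(skip_result(genome, verdict$reason))
    }
    tet <- classify_tetrad(det$ir, genome$length)
  }
  group <- classify_start_group(genome, tet)
  cpj_log("info", sprintf("start group %s%s", group$code,
                          if (group$i_flag) " (+i flag)" else ""),
          accession = genome$accession, stage = "group")
  std <- standardize_start(genome, tet)
  view <- genome_view(std$genome, std$tetrad)
  list(genome = genome, tetrad = tet, group = group, standardized = std,
       view = view)
}

#' Run the full junction-diagram pipeline
#'
#' For each input record: parse, detect (or adopt the configuration file's
#' custom junction coordinates), filter, standardize to LSC-first, compute
#' junctions, and add one row to the stacked figure. Filtered genomes are
#' reported and skipped, not fatal; unreadable files are reported per file
#' and the run continues.
#'
#' @param inputs character vector of GenBank file paths.
#' @param config optional path to a two-column configuration file (see
#'   [parse_config()]); entries are processed after `inputs`.
#' @param outdir output directory.
#' @param formats non-empty subset of `c("svg", "pdf", "png")`.
#' @param params [detection_params()].
#' @param prefix output file-name prefix.
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"quiet"`.
#' @return (invisibly) `list(status, n_rendered, skipped, errors, figure,
#'   results, paths)`; `status` is 0 when at least one genome was rendered,
#'   1 otherwise.
#' @export
run_junction_pipeline <- function(inputs = character(0L), config = NULL,
                                  outdir = ".", formats = "svg",
                                  params = detection_params(),
                                  prefix = "cpjunctions",
                                  log_level = "warn") {
  old <- options(cpjunctions.log_level = log_level)
  on.exit(options(old), add = TRUE)
  stopifnot(length(formats) >= 1L, all(formats %in% c("svg", "pdf", "png")))

  entries <- lapply(inputs, function(p) list(gb_path = p, custom_tetrad = NULL))
  if (!is.null(config)) entries <- c(entries, parse_config(config))
  if (length(entries) == 0L) stop("no inputs: give GenBank paths or a config file")

  results <- list()
  skipped <- list()
  errors <- list()
  for (entry in entries) {
    recs <- tryCatch(read_genbank_records(entry$gb_path), error = function(e) e)
    if (inherits(recs, "error")) {
      cpj_log("warn", conditionMessage(recs), stage = "read")
      errors[[length(errors) + 1L]] <-
        list(path = entry$gb_path, message = conditionMessage(recs))
      next
    }
    for (rec in recs) {
      res <- tryCatch(
        process_genome(rec, params, entry$custom_tetrad),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        cpj_log("warn", conditionMessage(res), accession = rec$accession,
                stage = "process")
        errors[[length(errors) + 1L]] <-
          list(path = entry$gb_path, accession = rec$accession,
               message = conditionMessage(res))
      } else if (inherits(res, "cpj_skip")) {
        skipped[[length(skipped) + 1L]] <- res
      } else {
        results[[length(results) + 1L]] <- res
      }
    }
  }

  if (length(results) == 0L) {
    cpj_log("warn", "no genome passed detection and filtering; nothing to draw")
    return(invisible(list(status = 1L, n_rendered = 0L, skipped = skipped,
                          errors = errors, figure = NULL, results = list(),
                          paths = character(0L))))
  }

  fig <- layout_figure(lapply(results, `[[`, "view"))
  paths <- write_figure(fig, outdir, prefix, formats)
  paths["regions"] <- file.path(outdir, paste0(prefix, ".regions.tsv"))
  write_region_table(
    lapply(results, function(r) list(genome = r$genome, tetrad = r$tetrad)),
    paths[["regions"]]
  )
  paths["junctions"] <- file.path(outdir, paste0(prefix, ".junctions.tsv"))
  write_junction_table(
    lapply(results, function(r) list(genome = r$genome,
                                     contexts = r$view$contexts)),
    paths[["junctions"]]
  )
  cpj_log("info", sprintf("rendered %d genome(s), skipped %d, %d error(s)",
                          length(results), length(skipped), length(errors)),
          stage = "summary")
  invisible(list(status = 0L, n_rendered = length(results), skipped = skipped,
                 errors = errors, figure = fig, results = results,
                 paths = paths))
}
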