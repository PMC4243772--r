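# Pipeline orchestration. Stages always execute in one fixed
# hierarchical order; disabled stages are identities:
#   renaming -> translation -> consensus -> RY coding -> third-position
#   exclusion -> concatenation -> informative-site extraction -> output.
# Process chains that contradict this flow (e.g. RY coding before a
# nucleotide-to-amino-acid translation) are rejected at configuration
# time; they require two separate runs.

#' Build and validate a pipeline run configuration
#'
#' @param inputs character vector of alignment files and/or
#'   directories.
#' @param rename_file optional tab-delimited rename map.
#' @param translate optional `"nt2aa"` or `"aa2nt"`.
#' @param consensus_file optional block definition file (see
#'   [parse_block_file()]).
#' @param consensus_method consensus method, see [consensus_column()].
#' @param ry_mode optional `"all"` or `"third"`.
#' @param exclude_third drop every third nucleotide column.
#' @param concat build a supermatrix from all processed inputs.
#' @param informative `"none"`, `"file"`, `"super"` or `"both"`:
#'   extract parsimony-informative sites per infile and/or from the
#'   supermatrix.
#' @param out_formats output formats, subset of `"fasta"`, `"phylip"`,
#'   `"nexus"`.
#' @param mrbayes_block embed a MrBayes block in NEXUS output.
#' @param partitions write a RAxML partition file for the supermatrix.
#' @param fast reduced info report (skip per-fragment listings).
#' @param out_dir output directory.
#' @return validated object of class `"run_config"`.
#' @export
run_config <- function(inputs,
                       rename_file = NULL,
                       translate = NULL,
                       consensus_file = NULL,
                       consensus_method = "mostfreq",
                       ry_mode = NULL,
                       exclude_third = FALSE,
                       concat = FALSE,
                       informative = "none",
                       out_formats = "fasta",
                       mrbayes_block = FALSE,
                       partitions = FALSE,
                       fast = FALSE,
                       out_dir = "phyloconcat_out") {
  if (!length(inputs)) stop("at least one input is required")
  if (!is.null(translate)) {
    translate <- match.arg(translate, c("nt2aa", "aa2nt"))
  }
  if (!is.null(ry_mode)) ry_mode <- match.arg(ry_mode, c("all", "third"))
  consensus_method <- match.arg(consensus_method, CONSENSUS_METHODS)
  informative <- match.arg(informative, c("none", "file", "super", "both"))
  out_formats <- match.arg(tolower(out_formats), OUTPUT_FORMATS,
                           several.ok = TRUE)
  # flow-order guards: these combinations would need the late stage to
  # run before the early one, i.e. two separate runs
  if (isTRUE(exclude_third) && identical(ry_mode, "third")) {
    stop("config error: third-position exclusion and third-position RY ",
         "coding are mutually exclusive in one run")
  }
  if (identical(translate, "nt2aa") &&
      (isTRUE(exclude_third) || !is.null(ry_mode))) {
    stop("config error: RY coding or third-position exclusion cannot be ",
         "combined with nucleotide-to-amino-acid translation in one run; ",
         "run the tool twice")
  }
  if (informative %in% c("super", "both") && !isTRUE(concat)) {
    stop("config error: supermatrix informative-site extraction ",
         "requires concatenation")
  }
  if ((isTRUE(partitions) || isTRUE(mrbayes_block)) && !isTRUE(concat)) {
    stop("config error: partition output requires concatenation")
  }
  structure(
    list(inputs = inputs, rename_file = rename_file, translate = translate,
         consensus_file = consensus_file,
         consensus_method = consensus_method, ry_mode = ry_mode,
         exclude_third = isTRUE(exclude_third), concat = isTRUE(concat),
         informative = informative, out_formats = unique(out_formats),
         mrbayes_block = isTRUE(mrbayes_block),
         partitions = isTRUE(partitions), fast = isTRUE(fast),
         out_dir = out_dir),
    class = "run_config"
  )
}

#' Run the full processing pipeline
#'
#' Reads every input, applies the enabled stages in the fixed flow
#' order and writes the requested outputs plus the info report (and,
#' when structure strings are present, the structure report). Stage
#' warnings are collected rather than raised.
#'
#' @param config a [run_config()].
#' @return object of class `"run_summary"`: list with `files` (named
#'   list of written paths), `warnings`, `n_inputs`, `n_taxa` (per
#'   input), and `supermatrix` (the supermatrix object or `NULL`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", out_dir)
  }
  paths <- resolve_input_order(config$inputs)
  alns <- lapply(paths, read_alignment)
  raw_alns <- alns
  warnings <- character()
  files <- list()

  # 1. renaming
  if (!is.null(config$rename_file)) {
    map <- parse_rename_file(config$rename_file)
    reports <- list()
    for (i in seq_along(alns)) {
      res <- apply_renames(alns[[i]], map)
      alns[[i]] <- res$alignment
      rep_i <- res$report
      rep_i$file <- alns[[i]]$source
      reports[[i]] <- rep_i
    }
    rep_all <- do.call(rbind, reports)
    rename_path <- file.path(out_dir, "rename_report.txt")
    writeLines(c(
      "rename report (old -> new, applied?)",
      paste0(rep_all$old, " -> ", rep_all$new, "  [",
             ifelse(rep_all$applied, "applied", "unused"), "] ",
             rep_all$file)
    ), rename_path)
    files$rename_report <- rename_path
  }

  # 2. translation
  if (identical(config$translate, "nt2aa")) {
    for (i in seq_along(alns)) {
      res <- translate_nt_to_aa(alns[[i]])
      alns[[i]] <- res$alignment
      warnings <- c(warnings, res$warnings)
    }
  } else if (identical(config$translate, "aa2nt")) {
    alns <- lapply(alns, reverse_translate_alignment)
  }

  # 3. consensus of defined blocks
  if (!is.null(config$consensus_file)) {
    blocks <- parse_block_file(config$consensus_file)
    alns <- lapply(alns, build_consensus, blocks = blocks,
                   method = config$consensus_method)
  }

  # 4. RY coding
  if (!is.null(config$ry_mode)) {
    alns <- lapply(alns, ry_encode, mode = config$ry_mode)
  }

  # 5. third-position exclusion
  if (config$exclude_third) {
    alns <- lapply(alns, exclude_third_positions)
  }

  # 6. concatenation
  sm <- NULL
  if (config$concat) {
    sm <- concatenate(alns)
    files$supermatrix <- write_alignment(
      sm, out_dir, formats = config$out_formats,
      mrbayes_block = config$mrbayes_block)
    if (config$partitions) {
      files$partitions_raxml <- write_partitions_raxml(
        sm$partitions, file.path(out_dir, "supermatrix_partitions.txt"))
    }
  } else {
    files$alignments <- unlist(lapply(alns, function(a) {
      write_alignment(a, out_dir, formats = config$out_formats)
    }))
  }

  # 7. parsimony-informative site extraction
  informative_counts <- list()
  if (config$informative %in% c("file", "both")) {
    for (a in alns) {
      res <- extract_informative(a)
      informative_counts[[a$source]] <- length(res$indices)
      if (length(res$indices)) {
        files$informative <- c(files$informative, write_alignment(
          res$alignment, out_dir, formats = config$out_formats,
          base_name = paste0(file_stem(a$source), "_informative")))
      } else {
        warnings <- c(warnings, paste0(a$source,
                      ": no parsimony-informative sites; no file written"))
      }
    }
  }
  if (config$informative %in% c("super", "both")) {
    res <- extract_informative(sm)
    informative_counts[["supermatrix"]] <- length(res$indices)
    if (length(res$indices)) {
      files$informative <- c(files$informative, write_alignment(
        res$alignment, out_dir, formats = config$out_formats,
        base_name = "supermatrix_informative"))
    } else {
      warnings <- c(warnings,
                    "supermatrix: no parsimony-informative sites")
    }
  }

  # 8. reports
  files$info_report <- write_info_report(
    alns, sm, file.path(out_dir, "info_report.txt"), fast = config$fast)
  sr <- write_structure_report(
    alns, sm, file.path(out_dir, "structure_report.txt"))
  if (!is.null(sr)) files$structure_report <- sr

  structure(
    list(files = files, warnings = warnings,
         n_inputs = length(alns),
         n_taxa = vapply(alns, n_records, integer(1L)),
         informative_counts = informative_counts,
         supermatrix = sm),
    class = "run_summary"
  )
}

#' @export
print.run_summary <- function(x, ...) {
  cat("phyloconcat run:", x$n_inputs, "input(s)\n")
  for (f in unlist(x$files)) cat("  wrote:", f, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
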