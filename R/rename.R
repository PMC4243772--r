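# Sequence renaming from a tab-delimited old-name/new-name map.
# Renaming runs before any other processing stage so that downstream
# concatenation matches taxa by their final names.

#' Parse a tab-delimited rename map
#'
#' Each non-blank row holds the old name, one tab, and the new name.
#' Old names must be unique, and no two old names may map to the same
#' new name.
#'
#' @param path path to the rename file.
#' @return named character vector: `names()` are the old names, values
#'   the new names.
#' @export
parse_rename_file <- function(path) {
  if (!file.exists(path)) stop("no such rename file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  old <- character()
  new <- character()
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !nzchar(trimws(parts[1L])) ||
        !nzchar(trimws(parts[2L]))) {
      stop("rename file ", path, ", line ", i,
           ": expected '<old><TAB><new>'")
    }
    old <- c(old, trimws(parts[1L]))
    new <- c(new, trimws(parts[2L]))
  }
  if (anyDuplicated(old)) {
    stop("rename file ", path, ": duplicate old name(s): ",
         paste(unique(old[duplicated(old)]), collapse = ", "))
  }
  if (anyDuplicated(new)) {
    stop("rename file ", path, ": duplicate new name(s): ",
         paste(unique(new[duplicated(new)]), collapse = ", "))
  }
  stats::setNames(new, old)
}

#' Apply a rename map to an alignment
#'
#' Records whose name matches an old name exactly (case-sensitive,
#' whole name) are renamed; all other records and all residues are left
#' untouched. Map entries that match no record are reported as unused.
#'
#' @param aln an [alignment()].
#' @param map named character vector from [parse_rename_file()].
#' @return list with `alignment` (renamed) and `report`, a data frame
#'   with columns `old`, `new`, `applied`.
#' @export
apply_renames <- function(aln, map) {
  if (!length(map)) {
    return(list(alignment = aln,
                report = data.frame(old = character(), new = character(),
                                    applied = logical())))
  }
  hit <- aln$names %in% names(map)
  new_names <- aln$names
  new_names[hit] <- unname(map[aln$names[hit]])
  if (anyDuplicated(new_names)) {
    dup <- unique(new_names[duplicated(new_names)])
    stop("renaming would create duplicate name(s) in ", aln$source, ": ",
         paste(dup, collapse = ", "))
  }
  out <- alignment(new_names, aln$seqs, source = aln$source,
                   types = aln$types)
  report <- data.frame(old = names(map), new = unname(map),
                       applied = names(map) %in% aln$names,
                       stringsAsFactors = FALSE)
  list(alignment = out, report = report)
}
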