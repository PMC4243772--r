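# Dot-bracket secondary-structure parsing (stack matching) and the
# stem/loop position report for infiles and the supermatrix.

#' Parse a dot-bracket structure string
#'
#' Stack matching: each `)` pairs with the most recent unmatched `(`;
#' `.` positions are loops; `-` and `?` are ignored positions that are
#' neither stem nor loop. Pseudoknot bracket alphabets (`[]`, `{}`,
#' `<>`) are rejected. All coordinates are 1-based.
#'
#' @param s dot-bracket string over `(`, `)`, `.`, `-`, `?`.
#' @return object of class `"pairing_table"`: list with `pairs`
#'   (integer matrix, columns `open`/`close`, ordered by `open`),
#'   `loops` (integer vector), `ignored` (integer vector) and `length`
#'   (string length).
#' @examples
#' parse_dot_bracket("((..))")
#' @export
parse_dot_bracket <- function(s) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop("s must be a single non-empty string")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  knots <- chars %in% c("[", "]", "{", "}", "<", ">")
  if (any(knots)) {
    stop("pseudoknot brackets are not supported (position ",
         which(knots)[1L], ")")
  }
  bad <- !chars %in% c("(", ")", ".", "-", "?")
  if (any(bad)) {
    stop("invalid structure character '", chars[which(bad)[1L]],
         "' at position ", which(bad)[1L])
  }
  stack <- integer()
  open <- integer()
  close <- integer()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) {
        stop("unmatched ')' at position ", i)
      }
      open <- c(open, stack[length(stack)])
      close <- c(close, i)
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) {
    stop("unmatched '(' at position ", stack[1L])
  }
  ord <- order(open)
  structure(
    list(pairs = cbind(open = open[ord], close = close[ord]),
         loops = which(chars == "."),
         ignored = which(chars %in% c("-", "?")),
         ignored_chars = chars[chars %in% c("-", "?")],
         length = length(chars)),
    class = "pairing_table"
  )
}

#' Regenerate the dot-bracket string of a pairing table
#'
#' @param pt a `"pairing_table"` from [parse_dot_bracket()].
#' @return the dot-bracket string, with ignored positions restored
#'   verbatim.
#' @export
dot_bracket_string <- function(pt) {
  chars <- rep(".", pt$length)
  chars[pt$pairs[, "open"]] <- "("
  chars[pt$pairs[, "close"]] <- ")"
  chars[pt$ignored] <- pt$ignored_chars
  chars[pt$loops] <- "."
  paste(chars, collapse = "")
}

#' @export
print.pairing_table <- function(x, ...) {
  cat("Pairing table:", nrow(x$pairs), "pairs,",
      length(x$loops), "loop positions,", x$length, "columns\n")
  invisible(x)
}

structure_section <- function(label, name, pt, offset = 0L) {
  pair_lines <- if (nrow(pt$pairs)) {
    paste0("    pair ", pt$pairs[, "open"] + offset, " - ",
           pt$pairs[, "close"] + offset)
  } else {
    "    (no pairs)"
  }
  loop_line <- paste0("    loops: ",
                      if (length(pt$loops)) {
                        paste(pt$loops + offset, collapse = " ")
                      } else "(none)")
  c(paste0("== ", label, " | record: ", name), pair_lines, loop_line, "")
}

#' Write the stem/loop structure report
#'
#' For every secondary-structure record among the inputs, reports the
#' paired (stem) coordinates and the unpaired (loop) positions, and
#' repeats the same for the concatenated supermatrix where the
#' coordinates are shifted by each gene's partition offset. Padding
#' (`.`) inserted for taxa missing a structure gene shows up as loop
#' positions of the pad. Skipped (returns `NULL`) when no structure
#' record exists.
#'
#' @param alignments list of input [alignment()] objects.
#' @param supermatrix optional supermatrix from [concatenate()].
#' @param path output file path.
#' @return `path` invisibly, or `NULL` when there is nothing to report.
#' @export
write_structure_report <- function(alignments, supermatrix = NULL, path) {
  lines <- character()
  found <- FALSE
  for (a in alignments) {
    for (i in which(a$types == "structure")) {
      found <- TRUE
      pt <- parse_dot_bracket(a$seqs[i])
      lines <- c(lines,
                 structure_section(paste0("infile: ", a$source),
                                   a$names[i], pt))
    }
  }
  if (!found) return(invisible(NULL))
  if (!is.null(supermatrix)) {
    sa <- supermatrix$alignment
    for (i in which(sa$types == "structure")) {
      pt <- parse_dot_bracket(sa$seqs[i])
      lines <- c(lines,
                 structure_section("supermatrix", sa$names[i], pt))
    }
  }
  writeLines(c("phyloconcat structure report", "", lines), path)
  invisible(path)
}
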