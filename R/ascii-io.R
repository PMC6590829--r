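#' Read column-oriented ASCII data with attributes
#'
#' Parses the plain-text dialect used throughout the package: a line whose
#' tokens are all numbers is a data row; a line starting with an identifier
#' followed by at least one further token is an attribute (`"temperature
#' 293.15"`); anything else is kept as a comment.  Consecutive data rows form
#' one block; a blank line, or an attribute/comment line appearing after data
#' rows (or an explicit `block` keyword), starts a new block.  Each block
#' together with its preceding attributes and comments becomes one
#' [dataSet()].
#'
#' Attribute values are parsed as numbers where possible: a single numeric
#' token becomes a scalar, several numeric tokens a vector, anything else is
#' stored as the raw remainder string.  The reserved attribute name `.roles`
#' carries the column-role indices (`X Y` or `X Y eY`) and is turned back into
#' the role map instead of a plain attribute; this is how [write_dat()]
#' round-trips roles and how a written one-row vector attribute stays distinct
#' from a one-row data block.
#'
#' @param file path to a text file (ignored when `text` is given).
#' @param text optional character scalar holding the file contents directly.
#' @param columns optional integer vector selecting data columns after
#'   parsing.
#' @param replace optional named character vector of fixed-string replacements
#'   applied to every line before parsing (e.g. `c("," = ".")` for decimal
#'   commas).
#' @param block optional keyword: a line whose first token equals it forces a
#'   new block (the line itself is dropped).
#' @param roles optional role vector (as in [dataSet()]) overriding defaults
#'   and any `.roles` line.
#' @return a [dataCollection()]; empty input (or input without any numeric
#'   row) gives an empty collection.
#' @examples
#' txt <- "q 0.5\n1 0.9\n2 0.7\n\nq 1.0\n1 0.8\n2 0.5\n"
#' dc <- read_dat(text = txt)
#' dc_attr(dc, "q")
#' @export
read_dat <- function(file, text = NULL, columns = NULL, replace = NULL,
                     block = NULL, roles = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1]]
           else readLines(file, warn = FALSE)
  if (!is.null(replace))
    for (k in names(replace))
      lines <- gsub(k, replace[[k]], lines, fixed = TRUE)

  sets <- list()
  attrs <- list(); comments <- character(); rows <- list()
  nc <- NA_integer_; roles_line <- NULL; data_lines <- integer()

  flush <- function() {
    if (length(rows)) {
      mat <- do.call(rbind, rows)
      if (!is.null(columns)) mat <- mat[, columns, drop = FALSE]
      rl <- if (!is.null(roles)) roles
            else if (!is.null(roles_line)) {
              r <- c(X = roles_line[1], Y = roles_line[2])
              if (length(roles_line) >= 3) r <- c(r, eY = roles_line[3])
              r
            } else NULL
      sets[[length(sets) + 1L]] <<- dataSet(mat, attributes = attrs,
                                            comments = comments, roles = rl)
    }
    attrs <<- list(); comments <<- character(); rows <<- list()
    nc <<- NA_integer_; roles_line <<- NULL; data_lines <<- integer()
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    trimmed <- trimws(ln)
    if (!nzchar(trimmed)) {               # blank line ends a block
      if (length(rows)) flush()
      next
    }
    toks <- strsplit(trimmed, "[ \t]+")[[1]]
    nums <- suppressWarnings(as.numeric(toks))
    if (!anyNA(nums)) {                    # data row
      if (!is.na(nc) && length(nums) != nc)
        stop(sprintf(
          "ragged data row at line %d: %d columns, block has %d",
          i, length(nums), nc))
      nc <- length(nums)
      rows[[length(rows) + 1L]] <- nums
      data_lines <- c(data_lines, i)
      next
    }
    if (!is.null(block) && toks[1] == block) { flush(); next }
    if (length(rows)) flush()              # attribute/comment after data
    is_attr <- length(toks) >= 2L &&
      (make.names(toks[1]) == toks[1] || toks[1] == ".roles")
    if (is_attr) {
      rest_tokens <- toks[-1]
      rest_nums <- suppressWarnings(as.numeric(rest_tokens))
      raw <- sub("^[^ \t]+[ \t]+", "", trimmed)
      if (toks[1] == ".roles") {
        roles_line <- as.integer(rest_nums)
      } else if (!anyNA(rest_nums)) {
        attrs[[toks[1]]] <- rest_nums
      } else {
        attrs[[toks[1]]] <- raw
      }
    } else {
      comments <- c(comments,
                    if (startsWith(ln, "# ")) substring(ln, 3)
                    else if (startsWith(ln, "#")) substring(ln, 2)
                    else ln)
    }
  }
  flush()
  dataCollection(sets)
}

#' Write a collection as attribute-preserving ASCII
#'
#' Emits each [dataSet()] as its comments (prefixed `"# "` so they are never
#' re-read as attributes), its attributes as `name value(s)` lines, a reserved
#' `.roles` line recording the column roles, and the numeric rows at full
#' double precision (17 significant digits).  Blocks are separated by one
#' blank line.  `read_dat(write_dat(dc))` reproduces the collection exactly.
#'
#' @param dc a [dataCollection()] or single [dataSet()].
#' @param file path to write to; when `NULL` the text is returned invisibly
#'   only.
#' @return the formatted text, invisibly.
#' @export
write_dat <- function(dc, file = NULL) {
  if (inherits(dc, "dataSet")) dc <- dataCollection(dc)
  stopifnot(inherits(dc, "dataCollection"))
  blocks <- vapply(dc, .format_dataset, character(1))
  txt <- paste(blocks, collapse = "\n")
  if (!is.null(file)) {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(txt, con, sep = "")
  }
  invisible(txt)
}

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x) & !is.nan(x)] <- "NA"
  out
}

.format_dataset <- function(ds) {
  out <- character()
  if (length(ds$comments)) out <- c(out, paste0("# ", ds$comments))
  for (nm in names(ds$attributes)) {
    v <- ds$attributes[[nm]]
    out <- c(out, paste(nm, if (is.character(v)) v
                        else paste(.fmt_num(v), collapse = " ")))
  }
  out <- c(out, paste(".roles", paste(ds$roles, collapse = " ")))
  out <- c(out, apply(ds$data, 1L,
                      function(r) paste(.fmt_num(r), collapse = " ")))
  paste0(paste(out, collapse = "\n"), "\n")
}
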