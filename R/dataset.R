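#' Matrix-like dataset with metadata attributes
#'
#' A `dataSet` couples a numeric matrix (rows are observations, columns are
#' quantities such as momentum transfer, intensity and its uncertainty) with
#' named metadata attributes (temperature, wavevector, concentration, ...),
#' free-text comments and a column-role map assigning the `X`, `Y` and
#' optional `eY` roles to columns.  The roles drive plotting, pruning,
#' interpolation, fitting and smearing; the attributes are picked up
#' automatically as fixed model parameters by [fit_collection()].
#'
#' @param data numeric matrix or vector (a vector is treated as a one-column
#'   matrix); data frames are converted.
#' @param attributes named list of metadata; each element a numeric scalar,
#'   numeric vector or a single character string.  Names must be syntactically
#'   valid identifiers and must not collide with the role names `X`, `Y`, `eY`.
#' @param comments character vector of free-text comment lines.
#' @param roles integer vector with names `X`, `Y` and optionally `eY`, giving
#'   1-based column indices.  Defaults to `X = 1`, `Y = 2` and, when at least
#'   three columns are present, `eY = 3`.
#' @return an object of class `dataSet`.
#' @examples
#' ds <- dataSet(cbind(q = 1:5 / 10, I = exp(-(1:5 / 10))),
#'               attributes = list(temperature = 293.15))
#' ds_x(ds)
#' @export
dataSet <- function(data, attributes = list(), comments = character(),
                    roles = NULL) {
  if (is.data.frame(data)) data <- as.matrix(data)
  if (is.vector(data) && is.numeric(data)) data <- matrix(data, ncol = 1)
  if (!is.matrix(data) || !is.numeric(data))
    stop("'data' must be a numeric matrix")
  if (nrow(data) < 1L) stop("'data' must have at least one row")
  if (is.null(roles)) {
    roles <- c(X = 1L, Y = min(2L, ncol(data)))
    if (ncol(data) >= 3L) roles <- c(roles, eY = 3L)
  }
  dimnames(data) <- NULL
  roles <- .check_roles(roles, ncol(data))
  .check_attributes(attributes)
  structure(list(data = data, attributes = attributes,
                 comments = as.character(comments), roles = roles),
            class = "dataSet")
}

.check_roles <- function(roles, ncol) {
  roles <- vapply(roles, as.integer, integer(1))
  if (!all(names(roles) %in% c("X", "Y", "eY")) ||
      !all(c("X", "Y") %in% names(roles)))
    stop("roles must name X, Y and optionally eY")
  ok <- !is.na(roles)
  if (ncol >= 2L && anyDuplicated(roles[ok]) > 0L)
    stop("role column indices must be distinct")
  if (any(roles[ok] < 1L | roles[ok] > ncol))
    stop("role column index out of range (", ncol, " columns)")
  roles
}

.check_attributes <- function(attributes) {
  if (length(attributes) == 0L) return(invisible(NULL))
  nm <- names(attributes)
  if (is.null(nm) || any(nm == ""))
    stop("all attributes must be named")
  bad <- nm[make.names(nm) != nm]
  if (length(bad))
    stop("attribute names must be valid identifiers: ",
         paste(bad, collapse = ", "))
  if (any(nm %in% c("X", "Y", "eY")))
    stop("attribute names must not collide with role names X/Y/eY")
  invisible(NULL)
}

#' @export
print.dataSet <- function(x, ...) {
  cat(sprintf("dataSet: %d rows x %d columns\n", nrow(x$data), ncol(x$data)))
  r <- x$roles
  cat("  roles: ", paste(sprintf("%s=%d", names(r), r), collapse = ", "), "\n")
  if (length(x$attributes)) {
    cat("  attributes:\n")
    for (nm in names(x$attributes)) {
      v <- x$attributes[[nm]]
      cat("    ", nm, " = ",
          if (is.character(v)) v else paste(signif(v, 6), collapse = " "),
          "\n", sep = "")
    }
  }
  if (length(x$comments))
    cat(sprintf("  %d comment line(s)\n", length(x$comments)))
  invisible(x)
}

#' Role-column accessors
#'
#' Extract the column assigned to the `X`, `Y` or `eY` role of a [dataSet()].
#' `ds_ey` returns `NULL` when no error column is assigned.
#'
#' @param ds a `dataSet`.
#' @return numeric vector (or `NULL` for a missing `eY` role).
#' @export
ds_x <- function(ds) ds$data[, ds$roles[["X"]]]

#' @rdname ds_x
#' @export
ds_y <- function(ds) ds$data[, ds$roles[["Y"]]]

#' @rdname ds_x
#' @export
ds_ey <- function(ds) {
  if (!"eY" %in% names(ds$roles) || is.na(ds$roles[["eY"]])) return(NULL)
  ds$data[, ds$roles[["eY"]]]
}

#' Get or set a metadata attribute of a dataSet
#'
#' @param ds a `dataSet`.
#' @param name attribute name.
#' @param default value returned when the attribute is absent.
#' @param value new attribute value.
#' @export
ds_attr <- function(ds, name, default = NULL) {
  if (name %in% names(ds$attributes)) ds$attributes[[name]] else default
}

#' @rdname ds_attr
#' @export
`ds_attr<-` <- function(ds, name, value) {
  a <- ds$attributes
  a[[name]] <- value
  .check_attributes(a)
  ds$attributes <- a
  ds
}

#' Ordered collection of dataSets
#'
#' A `dataCollection` is an ordered list of [dataSet()] objects, possibly of
#' different shapes.  It is the unit on which attribute filtering and
#' simultaneous fitting operate.
#'
#' @param items a list of `dataSet` objects (or a single `dataSet`).
#' @return an object of class `dataCollection` (a list subclass).
#' @export
dataCollection <- function(items = list()) {
  if (inherits(items, "dataSet")) items <- list(items)
  if (!all(vapply(items, inherits, logical(1), "dataSet")))
    stop("all items must be dataSet objects")
  structure(items, class = c("dataCollection", "list"))
}

#' @export
print.dataCollection <- function(x, ...) {
  cat(sprintf("dataCollection of %d dataSet(s)\n", length(x)))
  for (i in seq_along(x)) {
    ds <- x[[i]]
    an <- names(ds$attributes)
    cat(sprintf("  [%d] %d x %d%s\n", i, nrow(ds$data), ncol(ds$data),
                if (length(an)) paste0("  (", paste(an, collapse = ", "), ")")
                else ""))
  }
  invisible(x)
}

#' @export
`[.dataCollection` <- function(x, i) {
  dataCollection(unclass(x)[i])
}

#' Query an attribute across a collection
#'
#' Returns one value per item; items lacking the attribute yield the missing
#' marker `NA`.
#'
#' @param dc a `dataCollection`.
#' @param name attribute name.
#' @param simplify if `TRUE` (default) scalar numeric values are returned as a
#'   vector, otherwise as a list.
#' @return vector (with `NA` for missing) or list.
#' @export
dc_attr <- function(dc, name, simplify = TRUE) {
  vals <- lapply(dc, function(ds)
    if (name %in% names(ds$attributes)) ds$attributes[[name]] else NA)
  if (simplify && all(vapply(vals, function(v)
    length(v) == 1L && (is.numeric(v) || all(is.na(v))), logical(1))))
    return(unlist(vals))
  vals
}

#' Filter a collection by an attribute predicate
#'
#' Keeps the items for which `predicate` evaluates to `TRUE`.  The predicate
#' receives the attribute list of one `dataSet` (so `function(a) a$q > 1`
#' selects by the `q` attribute).  Items on which the predicate throws (for
#' example because an attribute is missing) are excluded with a warning.
#' Order is preserved and the input is never modified.
#'
#' @param dc a `dataCollection`.
#' @param predicate function of one attribute list returning a single logical.
#' @return the filtered `dataCollection`.
#' @examples
#' dc <- dataCollection(lapply(c(280, 300, 320), function(T)
#'   dataSet(cbind(1:3, 1:3), attributes = list(temperature = T))))
#' length(filter_collection(dc, function(a) a$temperature > 300))
#' @export
filter_collection <- function(dc, predicate) {
  stopifnot(inherits(dc, "dataCollection"), is.function(predicate))
  keep <- vapply(seq_along(dc), function(i) {
    res <- tryCatch(isTRUE(predicate(dc[[i]]$attributes)),
                    error = function(e) {
                      warning(sprintf(
                        "predicate failed on item %d (%s); item excluded",
                        i, conditionMessage(e)), call. = FALSE)
                      FALSE
                    })
    res
  }, logical(1))
  dc[keep]
}
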