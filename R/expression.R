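#' Expression matrix with a cancer/control sample design
#'
#' Container for a nonnegative feature-by-sample abundance table together
#' with a binary group labelling of the samples.  This is the unit of input
#' for all differential expression operations.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Row names are feature identifiers, column names are sample identifiers;
#'   both are required and must be unique.  Entries must be nonnegative and
#'   finite.
#' @param groups Named character vector (or 2-column data frame with columns
#'   `sample_id`, `group`) mapping every sample to `"cancer"` or `"control"`
#'   (case-insensitive).  Both groups must be non-empty.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the numeric matrix) and `groups` (a factor over the samples
#'   with levels `control`, `cancer`).
#' @examples
#' m <- matrix(rpois(20, 50), nrow = 4,
#'             dimnames = list(paste0("f", 1:4), paste0("s", 1:5)))
#' g <- setNames(c("cancer", "cancer", "cancer", "control", "control"),
#'               colnames(m))
#' expr <- expression_matrix(m, g)
#' @export
expression_matrix <- function(values, groups) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (features x samples)",
         call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry feature row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers in `values`", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers in `values`", call. = FALSE)
  if (any(!is.finite(values)))
    stop("`values` contains non-finite entries", call. = FALSE)
  if (any(values < 0))
    stop("`values` contains negative abundances", call. = FALSE)

  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups)))
      stop("groups data frame needs columns `sample_id` and `group`",
           call. = FALSE)
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample_id))
  }
  grp <- tolower(as.character(groups))
  names(grp) <- names(groups)
  bad <- setdiff(unique(grp), c("cancer", "control"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(colnames(values), names(grp))
  if (length(missing))
    stop("sample(s) without a group label: ",
         paste(missing, collapse = ", "), call. = FALSE)
  grp <- grp[colnames(values)]
  grp <- factor(grp, levels = c("control", "cancer"))
  if (any(table(grp) == 0))
    stop("both groups (cancer and control) must be non-empty", call. = FALSE)

  structure(list(values = values, groups = grp),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf(
    "expression_matrix: %d features x %d samples (%d cancer / %d control)\n",
    nrow(x$values), ncol(x$values), tab[["cancer"]], tab[["control"]]))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression table from TSV
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers, tab-separated.
#'
#' @param path Path to the TSV file.
#' @param groups Named character vector or data frame of group labels (see
#'   [expression_matrix()]), typically from [read_groups()].
#' @return An `expression_matrix`.
#' @export
read_expression <- function(path, groups) {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expression table needs a feature column plus >=1 sample column: ",
         path, call. = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, groups)
}

#' Read a sample-to-group mapping from TSV
#'
#' Two-column tab-separated file `sample_id<TAB>group`, group one of
#' cancer/control (case-insensitive).  A header line is tolerated.
#'
#' @param path Path to the TSV file.
#' @return Named character vector mapping sample id to lower-case group.
#' @export
read_groups <- function(path) {
  if (!file.exists(path))
    stop("groups file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("groups file needs two columns: sample_id<TAB>group", call. = FALSE)
  # drop a header row if present
  if (tolower(df[1, 2]) %in% c("group", "label", "condition"))
    df <- df[-1, , drop = FALSE]
  g <- tolower(as.character(df[[2]]))
  names(g) <- as.character(df[[1]])
  bad <- setdiff(unique(g), c("cancer", "control"))
  if (length(bad))
    stop("groups file contains unknown label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  g
}
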