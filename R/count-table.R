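#' Weighted miRNA count table
#'
#' Container for a features x samples matrix of (possibly fractional)
#' weighted counts together with per-sample library sizes. Column sums can
#' never exceed the library size: a read contributes at most total weight 1.
#'
#' @param counts Numeric matrix, features in rows (rownames = miR ids),
#'   samples in columns (colnames = sample ids); non-negative.
#' @param library_sizes Named numeric vector of per-sample totals, aligned
#'   with the columns.
#' @return An object of class `mir_count_table`.
#' @examples
#' mir_count_table(matrix(c(2, 0.5, 0, 0.5), 2, 2,
#'   dimnames = list(c("miR-a", "miR-b"), c("s1", "s2"))),
#'   library_sizes = c(s1 = 10, s2 = 10))
#' @export
mir_count_table <- function(counts, library_sizes) {
  counts <- as.matrix(counts)
  stopifnot(is.numeric(counts), all(counts >= 0),
            !is.null(rownames(counts)), !is.null(colnames(counts)),
            length(library_sizes) == ncol(counts))
  if (is.null(names(library_sizes)))
    names(library_sizes) <- colnames(counts)
  stopifnot(identical(names(library_sizes), colnames(counts)))
  structure(list(counts = counts, library_sizes = library_sizes,
                 normalized = FALSE),
            class = "mir_count_table")
}

#' @export
print.mir_count_table <- function(x, ...) {
  cat("mir_count_table: ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples", if (isTRUE(x$normalized)) " (CPM)", "\n", sep = "")
  cat("library sizes: ",
      paste0(names(x$library_sizes), "=", x$library_sizes, collapse = ", "),
      "\n", sep = "")
  print(utils::head(x$counts))
  if (nrow(x$counts) > 6L) cat("... (", nrow(x$counts) - 6L, " more)\n")
  invisible(x)
}

#' @export
dim.mir_count_table <- function(x) dim(x$counts)

#' @method as.matrix mir_count_table
#' @export
as.matrix.mir_count_table <- function(x, ...) x$counts

#' Depth-normalize a count table to counts per million
#'
#' Scales each sample column by `1e6 / library_size`. By default the
#' library size is the number of mapped reads recorded when the table was
#' built (which may exceed the assigned total when some mapped reads
#' overlap no annotation), so normalized column sums are at most 1e6 and
#' equal 1e6 exactly when every mapped read was assigned.
#'
#' @param table A [mir_count_table].
#' @return A [mir_count_table] with CPM values (`normalized = TRUE`);
#'   library sizes kept as metadata.
#' @examples
#' tab <- mir_count_table(matrix(5, 1, 1, dimnames = list("m", "s")),
#'                        library_sizes = c(s = 1000))
#' depth_normalize(tab)$counts  # 5000 CPM
#' @export
depth_normalize <- function(table) {
  stopifnot(inherits(table, "mir_count_table"))
  if (any(table$library_sizes <= 0))
    stop("depth_normalize: zero library size for sample(s) ",
         paste(names(table$library_sizes)[table$library_sizes <= 0],
               collapse = ", "), call. = FALSE)
  out <- table
  out$counts <- sweep(table$counts, 2L, 1e6 / table$library_sizes, "*")
  out$normalized <- TRUE
  out
}

#' Write a count table as TSV
#'
#' First column `mir_id`, one column per sample, preceded by one
#' `#library_size=<sample>:<n>` comment line per sample.
#'
#' @param table A [mir_count_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "mir_count_table"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("#library_size=%s:%s", names(table$library_sizes),
                     format(table$library_sizes, scientific = FALSE,
                            trim = TRUE)), con)
  df <- data.frame(mir_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a count table written by [write_count_table()]
#'
#' @param path TSV path.
#' @return A [mir_count_table].
#' @export
read_count_table <- function(path) {
  lines <- readLines(path)
  lib_lines <- grep("^#library_size=", lines, value = TRUE)
  kv <- sub("^#library_size=", "", lib_lines)
  libs <- stats::setNames(as.numeric(sub("^[^:]*:", "", kv)),
                          sub(":.*$", "", kv))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1L, drop = FALSE])
  rownames(counts) <- df$mir_id
  mir_count_table(counts, library_sizes = libs[colnames(counts)])
}
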