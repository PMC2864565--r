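#' Construct a validated gene-by-library count matrix
#'
#' The universal input container: a matrix of non-negative integer read counts
#' with genes as rows and libraries as columns, plus a library size per
#' library. Library sizes are stored separately from the counts because the
#' total number of reads for a library may exceed the reads tabulated into
#' genes (for example, when unannotated or multi-mapping reads are excluded
#' from the matrix but still consumed sequencing depth).
#'
#' @param counts numeric matrix of non-negative whole numbers with unique,
#'   non-empty rownames (gene identifiers) and colnames (library identifiers).
#' @param lib_sizes optional numeric vector of library sizes, one per column
#'   (recycled names from `counts` if unnamed). Defaults to the column sums.
#'   Each must be strictly positive; sizes may exceed the column sums.
#' @return An object of class `"count_matrix"`: a list with elements
#'   `counts` (integer-valued matrix) and `lib_sizes` (named numeric vector).
#' @examples
#' m <- matrix(c(10, 100, 0, 20, 100, 5), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("libA", "libB")))
#' x <- count_matrix(m)
#' lib_sizes(x)
#' @export
count_matrix <- function(counts, lib_sizes = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("'counts' must be a numeric matrix")
  if (nrow(counts) == 0L || ncol(counts) == 0L)
    stop("count matrix is empty")
  gid <- rownames(counts)
  lid <- colnames(counts)
  if (is.null(gid) || anyNA(gid) || any(gid == ""))
    stop("count matrix must have gene identifiers as rownames")
  if (is.null(lid) || anyNA(lid) || any(lid == ""))
    stop("count matrix must have library identifiers as colnames")
  if (anyDuplicated(gid))
    stop("duplicate gene identifier(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(lid))
    stop("duplicate library identifier(s): ",
         paste(unique(lid[duplicated(lid)]), collapse = ", "))
  if (anyNA(counts)) stop("counts contain missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != floor(counts)))
    stop("counts must be whole numbers; fractional values are rejected, not rounded")
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max
  cs <- colSums(counts)
  if (is.null(lib_sizes)) {
    lib_sizes <- cs
  } else {
    if (length(lib_sizes) != ncol(counts))
      stop("'lib_sizes' must have one value per library")
    if (anyNA(lib_sizes) || any(lib_sizes <= 0))
      stop("library sizes must be positive")
    lib_sizes <- as.numeric(lib_sizes)
  }
  names(lib_sizes) <- lid
  structure(list(counts = counts, lib_sizes = lib_sizes),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " libraries\n", sep = "")
  cat("libraries: ", paste(colnames(x$counts), collapse = ", "), "\n", sep = "")
  cat("library sizes: ", paste(format(x$lib_sizes, big.mark = ","),
                               collapse = ", "), "\n", sep = "")
  n <- min(5L, nrow(x$counts))
  print(x$counts[seq_len(n), , drop = FALSE])
  if (nrow(x$counts) > n) cat("... (", nrow(x$counts) - n, " more genes)\n", sep = "")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Accessors for count_matrix objects
#'
#' @param x a [count_matrix()] object.
#' @return `gene_ids()` and `library_ids()` return character vectors;
#'   `lib_sizes()` the named numeric vector of library sizes.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname gene_ids
#' @export
library_ids <- function(x) colnames(x$counts)

#' @rdname gene_ids
#' @export
lib_sizes <- function(x) x$lib_sizes

# resolve a library id to a column index, with a useful error
.lib_index <- function(x, id) {
  i <- match(id, colnames(x$counts))
  if (is.na(i)) stop("unknown library id: '", id, "'")
  i
}

#' Read a tab-delimited count matrix
#'
#' Expects a header row of library names and a first column of gene
#' identifiers; every remaining cell must parse as a non-negative whole
#' number. Lines starting with `#` are treated as comments and skipped, so
#' output written by the CLI (which carries `#` metadata headers) reads back
#' directly.
#'
#' @param path path to the file.
#' @param sep field delimiter (default tab).
#' @param lib_sizes optional per-library size overrides (see
#'   [count_matrix()]).
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, sep = "\t", lib_sizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                          check.names = FALSE, comment.char = "#",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("count table needs a gene-id column and at least one library")
  gid <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
  bad <- which(is.na(num) & !is.na(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("cell does not parse as a number at gene '", gid[bad[1L, 1L]],
         "', library '", colnames(m)[bad[1L, 2L]], "': '",
         m[bad[1L, 1L], bad[1L, 2L]], "'")
  if (anyNA(num)) stop("count table contains empty cells")
  if (any(num < 0)) {
    bad <- which(num < 0, arr.ind = TRUE)
    stop("negative count at gene '", gid[bad[1L, 1L]], "', library '",
         colnames(m)[bad[1L, 2L]], "'")
  }
  dimnames(num) <- list(gid, colnames(m))
  count_matrix(num, lib_sizes = lib_sizes)
}

#' Write a count matrix as a tab-delimited table
#'
#' Writes a header row of library names and gene identifiers in the first
#' column (named `gene`), round-trippable by [read_counts()]. Identifiers
#' must not contain the delimiter.
#'
#' @param x a [count_matrix()].
#' @param path output path.
#' @param sep field delimiter.
#' @param header optional character vector of metadata lines, written as
#'   `#`-prefixed comments before the table.
#' @export
write_counts <- function(x, path, sep = "\t", header = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = gene_ids(x), x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table(df, path, sep = sep, header = header)
}

#' Write labelled records as a delimited table
#'
#' Plain-text writer used for all tool outputs: tab-delimited, header row,
#' optional `#`-prefixed metadata lines. Cell values and column names must
#' not contain the delimiter.
#'
#' @param df a data frame (an empty one yields a header-only file).
#' @param path output path, or an open connection (e.g. `stdout()`).
#' @param sep field delimiter.
#' @param header optional character vector of metadata comment lines.
#' @export
write_table <- function(df, path, sep = "\t", header = NULL) {
  df <- as.data.frame(df)
  chk <- vapply(df, function(col) any(grepl(sep, as.character(col), fixed = TRUE)),
                logical(1L))
  if (any(chk) || any(grepl(sep, names(df), fixed = TRUE)))
    stop("values must not contain the field delimiter")
  if (inherits(path, "connection")) {
    con <- path
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
  }
  if (!is.null(header) && length(header))
    writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(NULL)
}

#' Read a gene-list file
#'
#' One identifier per line; blank lines and `#` comments are ignored;
#' duplicates collapse to a set.
#'
#' @param path path to the file.
#' @return Character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  ids <- unique(lines)
  if (length(ids) == 0L) stop("gene list is empty: ", path)
  ids
}

#' Read a two-column gene-length table
#'
#' Tab-delimited, header optional-free format: `gene<TAB>length`, lengths in
#' bases. Lengths are carried for simulation sources that sample the joint
#' count/length distribution; the normalization itself never uses them (gene
#' length is absorbed into per-gene expression).
#'
#' @param path path to the file.
#' @return Named integer vector of lengths (names are gene identifiers).
#' @export
read_gene_lengths <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("gene-length table needs two columns: gene, length")
  len <- as.numeric(df[[2L]])
  if (anyNA(len) || any(len <= 0) || any(len != floor(len)))
    stop("gene lengths must be positive integers")
  if (anyDuplicated(df[[1L]])) stop("duplicate gene identifiers in length table")
  stats::setNames(as.integer(len), df[[1L]])
}
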