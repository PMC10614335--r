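#' Construct a count table
#'
#' The central container of the pipeline: a non-negative integer matrix of
#' read counts, elements in rows and sequenced samples in columns, plus a
#' sample-descriptor table. Sample names follow the grammar
#' \code{library.replicate.bin} (e.g. \code{"NT.1.high"},
#' \code{"anchor.2.day0"}); library names must not contain dots.
#'
#' @param counts integer matrix (elements x samples) with rownames and
#'   colnames, or an object coercible to one. Counts must be whole and
#'   non-negative.
#' @param samples optional data.frame with columns \code{sample},
#'   \code{library}, \code{replicate}, \code{bin}; parsed from the column
#'   names when omitted.
#' @return object of class \code{count_table}: list with \code{counts} and
#'   \code{samples}.
#' @export
count_table <- function(counts, samples = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("count table has no elements", call. = FALSE)
  if (ncol(counts) == 0L) stop("count table has no samples", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry element rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate element_id in count table", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample descriptor in count table", call. = FALSE)
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(samples)) samples <- parse_sample_names(colnames(counts))
  stopifnot(identical(samples$sample, colnames(counts)))
  structure(list(counts = counts, samples = samples), class = "count_table")
}

#' Parse sample descriptors of the form library.replicate.bin
#'
#' @param x character vector of sample names.
#' @return data.frame with columns \code{sample}, \code{library},
#'   \code{replicate}, \code{bin}. Names that do not split into exactly three
#'   fields get NA metadata (they remain usable by name).
#' @export
parse_sample_names <- function(x) {
  parts <- strsplit(x, ".", fixed = TRUE)
  pick <- function(i) vapply(parts, function(p)
    if (length(p) == 3L) p[i] else NA_character_, character(1))
  data.frame(sample = x, library = pick(1), replicate = pick(2),
             bin = pick(3), stringsAsFactors = FALSE)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d elements x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Read / write count tables
#'
#' TSV with an \code{element_id} column followed by one integer column per
#' sample. Round-trips losslessly; column order is preserved.
#'
#' @param path file path.
#' @return \code{read_count_table}: a [count_table()].
#' @export
read_count_table <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  if (!"element_id" %in% names(raw) || ncol(raw) < 2L)
    stop("count table file must have element_id plus >= 1 sample column",
         call. = FALSE)
  mat <- as.matrix(raw[setdiff(names(raw), "element_id")])
  if (any(!grepl("^[0-9]+$", mat)))
    stop("count table contains negative, fractional or non-numeric counts",
         call. = FALSE)
  storage.mode(mat) <- "integer"
  rownames(mat) <- raw$element_id
  count_table(mat)
}

#' @rdname read_count_table
#' @param table a [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  out <- data.frame(element_id = rownames(table$counts),
                    table$counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge count tables column-wise
#'
#' All tables must cover the identical element set (any order); duplicate
#' sample descriptors are rejected.
#'
#' @param ... count tables, or a single list of them.
#' @return merged [count_table()] with elements in the first table's order.
#' @export
merge_count_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && !inherits(tabs[[1]], "count_table"))
    tabs <- tabs[[1]]
  stopifnot(length(tabs) >= 1L, all(vapply(tabs, inherits, logical(1),
                                           "count_table")))
  ref <- rownames(tabs[[1]]$counts)
  for (t in tabs[-1]) {
    ids <- rownames(t$counts)
    if (!setequal(ids, ref)) {
      d1 <- setdiff(ref, ids); d2 <- setdiff(ids, ref)
      stop("element sets differ: missing {",
           paste(utils::head(d1, 5), collapse = ","), "}, extra {",
           paste(utils::head(d2, 5), collapse = ","), "}", call. = FALSE)
    }
  }
  mats <- lapply(tabs, function(t) t$counts[ref, , drop = FALSE])
  merged <- do.call(cbind, mats)
  if (anyDuplicated(colnames(merged)))
    stop("duplicate sample descriptors across tables", call. = FALSE)
  count_table(merged)
}

#' Subset a count table to one screen
#'
#' @param table a [count_table()].
#' @param library library name to keep (the first dot-field of the sample
#'   descriptor).
#' @return a [count_table()] with only that library's samples.
#' @export
subset_library <- function(table, library) {
  stopifnot(inherits(table, "count_table"))
  keep <- table$samples$library %in% library
  if (!any(keep)) stop("no samples for library '", library, "'", call. = FALSE)
  count_table(table$counts[, keep, drop = FALSE],
              table$samples[keep, , drop = FALSE])
}
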