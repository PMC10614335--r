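#' Read layout for guide counting
#'
#' Reads from a dual-guide screen share a constant 5' region (the sequencing
#' primer lands immediately upstream of the variable protospacer); the
#' protospacer follows the constant anchor at a fixed offset. Because the full
#' vector map is not hard-coded, both the constant sequence and the admitted
#' protospacer lengths are configurable.
#'
#' @param anchor5 constant sequence expected 5' of the protospacer. The
#'   protospacer is taken to start immediately after its first occurrence in
#'   the read.
#' @param proto_len integer vector of admitted protospacer lengths
#'   (default 19:20). Longest match wins.
#' @return a \code{read_layout} list.
#' @export
read_layout <- function(anchor5, proto_len = c(19L, 20L)) {
  anchor5 <- check_dna(anchor5, "anchor5")
  stopifnot(length(anchor5) == 1L, all(proto_len >= 1))
  structure(list(anchor5 = anchor5,
                 proto_len = sort(unique(as.integer(proto_len)))),
            class = "read_layout")
}

#' Count guides in sequencing reads by exact match
#'
#' A read is counted for a library element iff the segment immediately
#' following the 5' constant anchor exactly matches that element's
#' protospacer (no mismatch tolerance). Reads without the anchor, or whose
#' post-anchor segment matches no protospacer, are tallied as unmatched.
#' When protospacers of several lengths are admitted, the longest match wins;
#' the uniqueness check makes ties impossible.
#'
#' @param reads character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTQ file (plain or gzip).
#' @param library a \code{dual_library} or a guide library data.frame.
#' @param layout a [read_layout()].
#' @return list with \code{counts} (named integer vector over every library
#'   element, zeros included), \code{unmatched} and \code{n_reads}
#'   (\code{sum(counts) + unmatched == n_reads}).
#' @export
count_guides <- function(reads, library, layout) {
  stopifnot(inherits(layout, "read_layout"))
  lib <- if (inherits(library, "dual_library")) library$elements else library
  lib <- validate_guide_library(lib)
  if (anyDuplicated(lib$protospacer))
    stop("duplicate protospacers in library; counting index requires ",
         "unique protospacers", call. = FALSE)
  reads <- as_read_characters(reads)
  anchor <- layout$anchor5
  pos <- regexpr(anchor, reads, fixed = TRUE)
  start <- as.integer(pos) + nchar(anchor)
  hit <- rep(NA_integer_, length(reads))
  searchable <- which(pos > 0L)
  lens <- sort(intersect(layout$proto_len, nchar(lib$protospacer)),
               decreasing = TRUE)
  for (L in lens) {
    idx <- searchable[is.na(hit[searchable])]
    if (!length(idx)) break
    seg <- substr(reads[idx], start[idx], start[idx] + L - 1L)
    sel <- which(nchar(lib$protospacer) == L)
    m <- match(seg, lib$protospacer[sel])
    found <- !is.na(m)
    hit[idx[found]] <- sel[m[found]]
  }
  counts <- tabulate(hit, nbins = nrow(lib))
  names(counts) <- lib$element_id
  list(counts = counts,
       unmatched = sum(is.na(hit)),
       n_reads = length(reads))
}

as_read_characters <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  check_dna(reads, "reads")
}

#' Synthesize reads from a count column
#'
#' Emits one read per counted molecule, of the form
#' \code{anchor5 + protospacer + tail3}, for exercising [count_guides()] and
#' producing text fixtures. The hU6-primer failsafe of the real protocol
#' (only molecules carrying the fixed guide amplify) is modeled upstream:
#' no fixed-guide-less reads are ever emitted.
#'
#' @param counts named integer vector (element_id -> read count).
#' @param library a \code{dual_library} or guide library data.frame.
#' @param layout a [read_layout()].
#' @param tail3 constant 3' sequence appended after the protospacer.
#' @param shuffle if TRUE, reads are returned in a seeded random order
#'   (uses the current RNG state).
#' @return character vector of reads, named by their source element.
#' @export
synthesize_reads <- function(counts, library, layout, tail3 = "GTTTAAGAGC",
                             shuffle = FALSE) {
  stopifnot(inherits(layout, "read_layout"))
  lib <- if (inherits(library, "dual_library")) library$elements else library
  lib <- validate_guide_library(lib)
  m <- match(names(counts), lib$element_id)
  if (anyNA(m)) stop("counts name elements absent from the library",
                     call. = FALSE)
  reads <- rep(paste0(layout$anchor5, lib$protospacer[m], tail3), counts)
  names(reads) <- rep(names(counts), counts)
  if (shuffle) reads <- reads[sample.int(length(reads))]
  reads
}

#' Write reads to a FASTQ file
#'
#' @param reads character vector of read sequences.
#' @param path output path (ends in .fastq; plain text).
#' @param ids read identifiers (default read_1..n).
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  reads <- check_dna(reads, "reads")
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), reads, "+",
                           strrep("I", nchar(reads))))
  writeLines(lines, path)
  invisible(path)
}
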