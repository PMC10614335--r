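#' Annealing oligos for cloning a fixed guide
#'
#' Dual-guide vectors carry the fixed (anchor) guide in a hU6 cassette that is
#' cloned by ligating a pair of annealed oligos with custom overhangs. The
#' forward oligo is \code{"ATG" + protospacer + "GTTTCAGAGC"}; the reverse
#' oligo is \code{"TTAGCTCTGAAAC" + reverse-complement(protospacer) +
#' "CATGTTT"}.
#'
#' @param protospacer character vector of protospacer sequences (ACGT;
#'   typically 19--20 nt). Lowercase input is uppercased.
#' @return a data.frame with columns \code{protospacer}, \code{forward} and
#'   \code{reverse}, one row per input guide.
#' @examples
#' make_annealing_oligos("GGAGTACGCGTCCGGGCCAA")
#' @export
make_annealing_oligos <- function(protospacer) {
  protospacer <- check_dna(protospacer, "protospacer")
  data.frame(
    protospacer = protospacer,
    forward = paste0("ATG", protospacer, "GTTTCAGAGC"),
    reverse = paste0("TTAGCTCTGAAAC", revcomp(protospacer), "CATGTTT"),
    stringsAsFactors = FALSE
  )
}

#' Recover the protospacer encoded by an oligo pair
#'
#' Inverse of [make_annealing_oligos()]; used to verify oligo orders.
#'
#' @param forward,reverse oligo sequences as produced by
#'   [make_annealing_oligos()].
#' @return character vector of protospacers. Errors if the constant overhangs
#'   are absent or the two oligos disagree.
#' @export
decode_annealing_oligos <- function(forward, reverse) {
  forward <- check_dna(forward, "forward oligo")
  reverse <- check_dna(reverse, "reverse oligo")
  ok_f <- startsWith(forward, "ATG") & endsWith(forward, "GTTTCAGAGC")
  ok_r <- startsWith(reverse, "TTAGCTCTGAAAC") & endsWith(reverse, "CATGTTT")
  if (!all(ok_f & ok_r))
    stop("oligos do not carry the expected constant overhangs", call. = FALSE)
  from_f <- substr(forward, 4L, nchar(forward) - 10L)
  from_r <- substr(reverse, 14L, nchar(reverse) - 7L)
  if (!all(from_f == revcomp(from_r)))
    stop("forward and reverse oligos encode different protospacers",
         call. = FALSE)
  from_f
}

#' Restriction enzymes known to the attrition scan
#'
#' Recognition sequences for the enzymes used to open the dual-guide cloning
#' vector. Both are palindromic, so a single-strand scan suffices for them;
#' user-supplied non-palindromic sites are scanned on both strands by
#' [find_restriction_sites()].
#'
#' @return named character vector of recognition sequences.
#' @export
restriction_enzymes <- function() {
  c(BamHI = "GGATCC", NotI = "GCGGCCGC")
}

#' Find restriction sites in a sequence
#'
#' Reports every exact occurrence of each recognition sequence, including
#' overlapping occurrences. Non-palindromic recognition sequences are also
#' scanned on the reverse strand, with hit positions reported on the forward
#' strand.
#'
#' @param sequence a single DNA string (ACGT).
#' @param enzymes enzyme names from [restriction_enzymes()], or a named
#'   character vector mapping enzyme names to recognition sequences. An
#'   unnamed, unknown enzyme name is a configuration error.
#' @return data.frame with columns \code{enzyme} and \code{start} (0-based
#'   position of the site's leftmost base on the forward strand), ordered by
#'   position then enzyme name.
#' @examples
#' find_restriction_sites("GCGGCCGCGGCCGC", "NotI")
#' @export
find_restriction_sites <- function(sequence, enzymes = c("BamHI", "NotI")) {
  stopifnot(length(sequence) == 1L)
  sequence <- check_dna(sequence, "sequence", allow_empty = TRUE)
  enzymes <- resolve_enzymes(enzymes)
  out <- data.frame(enzyme = character(0), start = integer(0))
  for (nm in names(enzymes)) {
    rec <- enzymes[[nm]]
    hits <- overlapping_starts(sequence, rec)
    rc <- revcomp(rec)
    if (!identical(rc, rec))
      hits <- union(hits, overlapping_starts(sequence, rc))
    if (length(hits))
      out <- rbind(out, data.frame(enzyme = nm, start = as.integer(sort(hits))))
  }
  out <- out[order(out$start, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}

resolve_enzymes <- function(enzymes) {
  builtin <- restriction_enzymes()
  if (is.null(names(enzymes))) names(enzymes) <- enzymes
  recs <- character(length(enzymes))
  for (i in seq_along(enzymes)) {
    nm <- names(enzymes)[i]
    val <- enzymes[[i]]
    if (identical(nm, val) || !nzchar(val) || nm == "") {
      # bare name: must be a known enzyme
      if (!nm %in% names(builtin))
        stop("unknown enzyme '", nm, "': supply a recognition sequence, e.g. ",
             "c(", nm, " = \"GAATTC\")", call. = FALSE)
      recs[i] <- builtin[[nm]]
    } else {
      recs[i] <- check_dna(val, paste0("recognition sequence for ", nm))
    }
  }
  names(recs) <- names(enzymes)
  recs
}

# 0-based start positions of all (overlapping) exact occurrences
overlapping_starts <- function(sequence, pattern) {
  if (nchar(sequence) < nchar(pattern)) return(integer(0))
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Validate a guide library table
#'
#' A guide library is a data.frame with columns \code{element_id} (unique),
#' \code{gene}, \code{protospacer} (19--20 nt ACGT by convention; any
#' non-empty ACGT string is accepted) and \code{is_negative_control}
#' (logical).
#'
#' @param lib data.frame to validate.
#' @return the validated library (protospacers uppercased), invisibly usable.
#' @export
validate_guide_library <- function(lib) {
  need <- c("element_id", "gene", "protospacer", "is_negative_control")
  if (!is.data.frame(lib) || !all(need %in% names(lib)))
    stop("guide library must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(lib) == 0L) stop("guide library is empty", call. = FALSE)
  if (anyDuplicated(lib$element_id))
    stop("duplicate element_id in guide library", call. = FALSE)
  lib$protospacer <- check_dna(lib$protospacer, "protospacer")
  lib$is_negative_control <- as.logical(lib$is_negative_control)
  if (anyNA(lib$is_negative_control))
    stop("is_negative_control must be logical", call. = FALSE)
  lib
}

#' Build a dual-guide library in silico
#'
#' Takes a parent single-guide library, drops every element whose protospacer
#' (embedded in its vector context) contains a restriction site used during
#' cloning, and attaches the fixed anchor guide to the survivors. This mirrors
#' the small attrition (~1\%) incurred when the variable library is
#' restriction-digested into the dual-guide vector.
#'
#' @param parent guide library data.frame (see [validate_guide_library()]).
#' @param fixed_guide protospacer of the anchor guide present in every
#'   element.
#' @param context5,context3 optional flanking vector sequence placed 5' and 3'
#'   of each protospacer before scanning, so junction-spanning sites are
#'   caught. Default empty: the protospacer alone is scanned.
#' @param enzymes as in [find_restriction_sites()].
#' @return list with components \code{library} (a \code{dual_library}:
#'   \code{fixed_guide}, \code{elements}, contexts) and \code{report} (a
#'   \code{build_report}: \code{n_input}, \code{n_lost_restriction},
#'   \code{fraction_lost}, \code{lost_ids}).
#' @export
build_dual_library <- function(parent, fixed_guide, context5 = "",
                               context3 = "", enzymes = c("BamHI", "NotI")) {
  parent <- validate_guide_library(parent)
  fixed_guide <- check_dna(fixed_guide, "fixed_guide")
  context5 <- check_dna(context5, "context5", allow_empty = TRUE)
  context3 <- check_dna(context3, "context3", allow_empty = TRUE)
  stopifnot(length(fixed_guide) == 1L)
  if (nrow(find_restriction_sites(paste0(context5, fixed_guide, context3),
                                  enzymes)) > 0L)
    stop("fixed guide cassette contains a restriction site and would ",
         "self-digest", call. = FALSE)
  cassettes <- paste0(context5, parent$protospacer, context3)
  lost <- vapply(cassettes, function(s)
    nrow(find_restriction_sites(s, enzymes)) > 0L, logical(1),
    USE.NAMES = FALSE)
  report <- structure(list(
    n_input = nrow(parent),
    n_lost_restriction = sum(lost),
    fraction_lost = sum(lost) / nrow(parent),
    lost_ids = parent$element_id[lost]
  ), class = "build_report")
  lib <- structure(list(
    fixed_guide = fixed_guide,
    elements = parent[!lost, , drop = FALSE],
    context5 = context5,
    context3 = context3
  ), class = "dual_library")
  rownames(lib$elements) <- NULL
  list(library = lib, report = report)
}

#' @export
print.build_report <- function(x, ...) {
  cat(sprintf("dual-guide build: %d input elements, %d lost to restriction sites (%.2f%%)\n",
              x$n_input, x$n_lost_restriction, 100 * x$fraction_lost))
  invisible(x)
}

#' @export
print.dual_library <- function(x, ...) {
  cat(sprintf("dual_library: fixed guide %s, %d variable elements\n",
              x$fixed_guide, nrow(x$elements)))
  invisible(x)
}

#' Transformants needed to maintain library coverage
#'
#' @param n_elements number of library elements.
#' @param coverage fold coverage to maintain (e.g. 50 for 50x).
#' @return \code{n_elements * coverage}, as a numeric count.
#' @examples
#' transformants_required(100000, 50)
#' @export
transformants_required <- function(n_elements, coverage) {
  n_elements <- check_count(n_elements, "n_elements")
  coverage <- check_count(coverage, "coverage")
  n_elements * coverage
}

#' Read / write guide library tables
#'
#' Tab-separated tables with header \code{element_id, gene, protospacer,
#' is_negative_control}.
#'
#' @param path file path.
#' @return for \code{read_guide_library}, a validated guide library
#'   data.frame.
#' @export
read_guide_library <- function(path) {
  lib <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_guide_library(lib)
}

#' @rdname read_guide_library
#' @param lib guide library data.frame.
#' @export
write_guide_library <- function(lib, path) {
  lib <- validate_guide_library(lib)
  write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export protospacers as FASTA
#'
#' @param lib guide library data.frame.
#' @param path output FASTA path.
#' @export
write_protospacer_fasta <- function(lib, path) {
  lib <- validate_guide_library(lib)
  seqs <- Biostrings::DNAStringSet(lib$protospacer)
  names(seqs) <- lib$element_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write a build report to disk
#'
#' Emits \code{build_report.json} plus a TSV of the lost elements.
#'
#' @param report a \code{build_report} from [build_dual_library()].
#' @param dir output directory (created if needed).
#' @export
write_build_report <- function(report, dir) {
  stopifnot(inherits(report, "build_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n_input = report$n_input,
         n_lost_restriction = report$n_lost_restriction,
         fraction_lost = report$fraction_lost),
    file.path(dir, "build_report.json"), auto_unbox = TRUE, digits = NA)
  write.table(data.frame(element_id = report$lost_ids),
              file.path(dir, "lost_elements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
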