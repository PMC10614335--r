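#' Configuration for anchored-versus-control screen comparison
#'
#' The three-way interaction framework (synthetic / same-pathway /
#' orthogonal) is qualitative; these thresholds make it operational and are
#' deliberately configurable. \code{min_abs_phenotype} is calibrated against
#' the synthetic generator's default world: the null-gene score scale there
#' is about 0.05 log2 units and the weakest true effect is about 0.27, so
#' the floor sits between them.
#'
#' @param alpha Mann-Whitney significance level (default 0.05).
#' @param min_abs_phenotype minimum absolute phenotype score, log2 units, for
#'   a gene to count as a hit in a screen (default 0.25).
#' @param enhancement_factor tau: relative change in |phenotype| required to
#'   call enhancement or suppression between screens (default 0.3).
#' @return a \code{compare_config} list.
#' @export
compare_config <- function(alpha = 0.05, min_abs_phenotype = 0.25,
                           enhancement_factor = 0.3) {
  check_fraction(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  stopifnot(min_abs_phenotype >= 0, enhancement_factor > 0)
  structure(list(alpha = alpha, min_abs_phenotype = min_abs_phenotype,
                 enhancement_factor = enhancement_factor),
            class = "compare_config")
}

#' Per-gene rank change between two screens
#'
#' @param nt,anchor \code{gene_stats} data.frames (or \code{screen_stats}
#'   objects) from [analyze_screen()] for the non-targeting-anchored and
#'   gene-anchored screens.
#' @return data.frame over the gene intersection with columns \code{gene},
#'   \code{rank_nt}, \code{rank_anchor} and \code{rank_delta} (=
#'   \code{rank_nt - rank_anchor}; positive means the gene moved up, toward
#'   rank 1, in the anchored screen). Genes present in only one screen are
#'   attached as the \code{"missing"} attribute.
#' @export
rank_delta <- function(nt, anchor) {
  nt <- as_gene_stats(nt); anchor <- as_gene_stats(anchor)
  common <- intersect(nt$gene, anchor$gene)
  if (!length(common))
    stop("no genes scored in both screens", call. = FALSE)
  out <- data.frame(
    gene = common,
    rank_nt = nt$rank[match(common, nt$gene)],
    rank_anchor = anchor$rank[match(common, anchor$gene)],
    stringsAsFactors = FALSE
  )
  out$rank_delta <- out$rank_nt - out$rank_anchor
  attr(out, "missing") <- list(
    only_nt = setdiff(nt$gene, common),
    only_anchor = setdiff(anchor$gene, common))
  out
}

as_gene_stats <- function(x) {
  if (inherits(x, "screen_stats")) x <- x$gene_stats
  stopifnot(is.data.frame(x),
            all(c("gene", "phenotype_score", "p_value", "rank") %in% names(x)))
  x
}

#' Classify gene interactions with the anchor
#'
#' A gene is significant in a screen when its Mann-Whitney p-value is at
#' most \code{alpha} and its absolute phenotype score reaches
#' \code{min_abs_phenotype}. With tau = \code{enhancement_factor}, the rules
#' apply in order:
#' \enumerate{
#'   \item synthetic: significant in the anchored screen, same sign, and
#'     enhanced — |anchored phenotype| at least (1 + tau) times the control
#'     phenotype — or not significant in the control screen at all (a factor
#'     fully buffered in the wild type).
#'   \item same_pathway: significant in the control screen but lost or
#'     diminished — not significant in the anchored screen, or |anchored
#'     phenotype| at most (1 - tau) times the control phenotype.
#'   \item orthogonal: significant in both with essentially unchanged
#'     phenotype.
#'   \item null: everything else.
#' }
#'
#' @param df data.frame with columns \code{phenotype_nt}, \code{p_nt},
#'   \code{phenotype_anchor}, \code{p_anchor}.
#' @param config a [compare_config()].
#' @return character vector of categories parallel to \code{df} rows.
#' @export
classify_interactions <- function(df, config = compare_config()) {
  a <- config$alpha; f <- config$min_abs_phenotype
  tau <- config$enhancement_factor
  sig_nt <- df$p_nt <= a & abs(df$phenotype_nt) >= f
  sig_an <- df$p_anchor <= a & abs(df$phenotype_anchor) >= f
  same_sign <- sign(df$phenotype_anchor) == sign(df$phenotype_nt)
  enhanced <- abs(df$phenotype_anchor) >= (1 + tau) * abs(df$phenotype_nt)
  diminished <- abs(df$phenotype_anchor) <= (1 - tau) * abs(df$phenotype_nt)
  unchanged <- abs(df$phenotype_anchor - df$phenotype_nt) <
    tau * pmax(abs(df$phenotype_nt), f)
  out <- rep("null", nrow(df))
  rule1 <- sig_an & ((enhanced & same_sign) | !sig_nt)
  rule2 <- !rule1 & sig_nt & (!sig_an | diminished)
  rule3 <- !rule1 & !rule2 & sig_nt & sig_an & unchanged
  out[rule3] <- "orthogonal"
  out[rule2] <- "same_pathway"
  out[rule1] <- "synthetic"
  out
}

# Expected call for a true category given the anchor's own category;
# used for the confusion matrix on simulated data.
expected_interaction <- function(truth_category, anchor_category) {
  if (anchor_category == "pathway_B_member") {
    map <- c(pathway_A_member = "synthetic", pathway_B_member = "same_pathway")
  } else {
    map <- c(pathway_A_member = "same_pathway", pathway_B_member = "synthetic")
  }
  map <- c(map, stabilizer = "orthogonal", expression_only = "null",
           null = "null")
  unname(map[truth_category])
}

#' Compare an anchored screen against the non-targeting screen
#'
#' Joins the two screens' gene statistics, computes rank deltas, classifies
#' every gene scored in both screens, and summarizes category counts. The
#' anchor gene's own row (the anchor+self double knockdown, expected
#' significant because two guides against one gene deepen its knockdown) is
#' flagged and excluded from the summary and confusion matrix.
#'
#' @param nt,anchor \code{screen_stats} or \code{gene_stats} for the two
#'   screens.
#' @param config a [compare_config()].
#' @param truth optional truth table from a [generate_dataset()] run; when
#'   supplied, a confusion matrix of expected versus called categories is
#'   added to the summary.
#' @param anchor_gene name of the anchored gene (flagged in the output).
#' @return object of class \code{interaction_calls}: list with \code{calls}
#'   (gene, phenotype_nt, p_nt, rank_nt, phenotype_anchor, p_anchor,
#'   rank_anchor, rank_delta, is_anchor, category; ordered by rank_anchor)
#'   and \code{summary} (category counts, and \code{confusion} when truth is
#'   given).
#' @export
compare_screens <- function(nt, anchor, config = compare_config(),
                            truth = NULL, anchor_gene = NULL) {
  nt <- as_gene_stats(nt); anchor <- as_gene_stats(anchor)
  rd <- rank_delta(nt, anchor)
  i_nt <- match(rd$gene, nt$gene); i_an <- match(rd$gene, anchor$gene)
  calls <- data.frame(
    gene = rd$gene,
    phenotype_nt = nt$phenotype_score[i_nt],
    p_nt = nt$p_value[i_nt],
    rank_nt = rd$rank_nt,
    phenotype_anchor = anchor$phenotype_score[i_an],
    p_anchor = anchor$p_value[i_an],
    rank_anchor = rd$rank_anchor,
    rank_delta = rd$rank_delta,
    stringsAsFactors = FALSE
  )
  calls$is_anchor <- !is.null(anchor_gene) & calls$gene %in% anchor_gene
  calls$category <- classify_interactions(
    data.frame(phenotype_nt = calls$phenotype_nt, p_nt = calls$p_nt,
               phenotype_anchor = calls$phenotype_anchor,
               p_anchor = calls$p_anchor), config)
  calls <- calls[order(calls$rank_anchor), , drop = FALSE]
  rownames(calls) <- NULL
  summarized <- calls[!calls$is_anchor, , drop = FALSE]
  counts <- table(factor(summarized$category,
                         levels = c("synthetic", "same_pathway",
                                    "orthogonal", "null")))
  summary <- list(n_genes = nrow(calls), category_counts = counts,
                  missing = attr(rd, "missing"))
  if (!is.null(truth)) {
    anchor_cat <- if (!is.null(anchor_gene) && anchor_gene %in% truth$gene)
      truth$category[match(anchor_gene, truth$gene)] else "pathway_A_member"
    m <- match(summarized$gene, truth$gene)
    expected <- expected_interaction(truth$category[m], anchor_cat)
    lv <- c("synthetic", "same_pathway", "orthogonal", "null")
    summary$confusion <- table(expected = factor(expected, levels = lv),
                               called = factor(summarized$category,
                                               levels = lv))
  }
  structure(list(calls = calls, summary = summary, config = config,
                 anchor_gene = anchor_gene),
            class = "interaction_calls")
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat("interaction_calls:", x$summary$n_genes, "genes\n")
  print(x$summary$category_counts)
  if (!is.null(x$summary$confusion)) {
    cat("confusion (expected x called):\n")
    print(x$summary$confusion)
  }
  invisible(x)
}

#' Write an interaction comparison to disk
#'
#' InteractionCall TSV, summary JSON, and the rank-vs-rank scatter data.
#'
#' @param x an \code{interaction_calls} from [compare_screens()].
#' @param dir output directory.
#' @export
write_compare_report <- function(x, dir) {
  stopifnot(inherits(x, "interaction_calls"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(x$calls, file.path(dir, "interaction_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(x$calls[, c("gene", "rank_nt", "rank_anchor", "category")],
              file.path(dir, "rank_scatter.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  summ <- list(n_genes = x$summary$n_genes,
               category_counts = as.list(x$summary$category_counts),
               anchor_gene = x$anchor_gene)
  if (!is.null(x$summary$confusion))
    summ$confusion <- as.data.frame(x$summary$confusion)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
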