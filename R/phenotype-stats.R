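#' Statistics configuration for screen scoring
#'
#' @param min_count count threshold; a guide must reach it in both members of
#'   the compared sample pair to be scored (default 50, "fewer than 50"
#'   excluded).
#' @param k_strongest number of strongest guides averaged into the gene
#'   phenotype score (default 3).
#' @param pseudocount added to each count before frequencies (default 1).
#' @param discriminant_mode \code{"neglog_product"} (default):
#'   phenotype x -log10(p); \code{"literal_product"}: phenotype x p. See
#'   [discriminant_score()].
#' @param mw_exact_max exact Mann-Whitney enumeration is used when
#'   \code{n * m} is at most this bound (default 100); above it, the normal
#'   approximation with tie and continuity corrections.
#' @param alpha significance level recorded with the run (default 0.05).
#' @param min_abs_phenotype effect floor recorded with the run (default 0.1
#'   log2 units).
#' @return a \code{stats_config} list.
#' @export
stats_config <- function(min_count = 50, k_strongest = 3, pseudocount = 1,
                         discriminant_mode = c("neglog_product",
                                               "literal_product"),
                         mw_exact_max = 100, alpha = 0.05,
                         min_abs_phenotype = 0.1) {
  discriminant_mode <- match.arg(discriminant_mode)
  stopifnot(min_count >= 0, k_strongest >= 1, pseudocount >= 0,
            mw_exact_max >= 1)
  check_fraction(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  structure(list(min_count = min_count, k_strongest = k_strongest,
                 pseudocount = pseudocount,
                 discriminant_mode = discriminant_mode,
                 mw_exact_max = mw_exact_max, alpha = alpha,
                 min_abs_phenotype = min_abs_phenotype),
            class = "stats_config")
}

#' Filter guides on read counts
#'
#' A guide is retained iff its count reaches \code{min_count} in both
#' columns of the compared sample pair (requiring both sides prevents ratio
#' artifacts from one-sided dropout). A count of exactly \code{min_count}
#' is retained.
#'
#' @param table a [count_table()].
#' @param pair character vector of the two sample names being compared.
#' @param min_count threshold (default 50).
#' @return named logical vector over the table's elements.
#' @export
filter_low_counts <- function(table, pair, min_count = 50) {
  stopifnot(inherits(table, "count_table"), length(pair) == 2L)
  missing <- setdiff(pair, colnames(table$counts))
  if (length(missing))
    stop("sample column(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pass <- table$counts[, pair[1]] >= min_count &
    table$counts[, pair[2]] >= min_count
  names(pass) <- rownames(table$counts)
  pass
}

#' Raw guide-level log2 enrichment
#'
#' \code{log2(((high + pc) / total_high) / ((low + pc) / total_low))}, the
#' relative-frequency log ratio with pseudocount. The totals are expected to
#' be pseudocount-adjusted already (column sum over passing elements plus
#' \code{pseudocount * n_passing}); [analyze_screen()] does this.
#'
#' @param high,low counts in the numerator/denominator samples (vectorized).
#' @param total_high,total_low adjusted column totals.
#' @param pseudocount default 1.
#' @return numeric vector of raw log2 enrichments.
#' @export
guide_phenotype <- function(high, low, total_high, total_low,
                            pseudocount = 1) {
  stopifnot(all(total_high > 0), all(total_low > 0))
  log2(((high + pseudocount) / total_high) /
         ((low + pseudocount) / total_low))
}

#' Center guide phenotypes on the non-targeting controls
#'
#' Subtracts the median raw phenotype of the passing non-targeting guides
#' from every element, so the NT median is exactly 0 afterwards.
#'
#' @param raw named numeric vector of raw phenotypes (passing elements).
#' @param is_nt logical vector parallel to \code{raw}.
#' @return centered named numeric vector.
#' @export
normalize_to_controls <- function(raw, is_nt) {
  stopifnot(length(raw) == length(is_nt))
  if (!any(is_nt))
    stop("no passing non-targeting guides: cannot normalize", call. = FALSE)
  raw - median(raw[is_nt])
}

#' Average guide phenotypes across replicates
#'
#' Element-wise mean over the replicates in which the element passed the
#' count filter; an element passing in only one replicate keeps that
#' replicate's value, and an element failing everywhere is dropped.
#'
#' @param reps list of named numeric vectors (one per replicate, passing
#'   elements only).
#' @return list with \code{phenotype} (named means) and \code{n_reps}
#'   (replicates contributing per element).
#' @export
average_replicates <- function(reps) {
  stopifnot(is.list(reps), length(reps) >= 1L)
  ids <- unique(unlist(lapply(reps, names)))
  if (!length(ids))
    stop("no element passes the filter in any replicate", call. = FALSE)
  acc <- rep(0, length(ids)); nrep <- rep(0L, length(ids))
  names(acc) <- names(nrep) <- ids
  for (r in reps) {
    acc[names(r)] <- acc[names(r)] + r
    nrep[names(r)] <- nrep[names(r)] + 1L
  }
  list(phenotype = acc / nrep, n_reps = nrep)
}

#' Gene phenotype score from its guides
#'
#' Signed mean of the \code{k} guides with the largest absolute phenotype
#' (selection by magnitude, not sign); \code{k} is capped at the number of
#' passing guides. A tie at the k-th slot is broken by element_id order, so
#' the score is deterministic.
#'
#' @param phenotypes numeric vector of a gene's passing guide phenotypes.
#' @param k_strongest default 3.
#' @param ids element ids used for tie-breaking (defaults to names or
#'   index order).
#' @return the phenotype score.
#' @export
gene_phenotype <- function(phenotypes, k_strongest = 3, ids = NULL) {
  n <- length(phenotypes)
  if (n == 0L) stop("gene has no passing guides", call. = FALSE)
  if (is.null(ids)) ids <- names(phenotypes) %||% as.character(seq_len(n))
  ord <- order(-abs(phenotypes), ids)
  mean(phenotypes[ord[seq_len(min(k_strongest, n))]])
}

#' Two-sided Mann-Whitney p-value of gene guides versus controls
#'
#' Exact by complete enumeration of all \code{choose(n + m, n)} labelings
#' when \code{n * m <= exact_max} (the two-sided p is twice the smaller tail
#' probability of the U statistic, capped at 1; ties are handled through
#' midranks). Larger samples use the normal approximation with tie
#' correction and continuity correction. The p-value is clamped into
#' (0, 1].
#'
#' @param x gene guide phenotypes (typically 5 values).
#' @param y negative-control phenotypes.
#' @param exact_max enumeration bound on \code{n * m} (default 100).
#' @return two-sided p-value in (0, 1].
#' @export
mw_pvalue <- function(x, y, exact_max = 100) {
  n <- length(x); m <- length(y)
  if (n < 1L || m < 1L) stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (n * m <= exact_max) {
    combs <- utils::combn(n + m, n)
    U_all <- colSums(matrix(r[combs], nrow = n)) - n * (n + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(U_all <= U_obs + eps), mean(U_all >= U_obs - eps))
  } else {
    mu <- n * m / 2
    N <- n + m
    ties <- table(r)
    sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- max(0, abs(U_obs - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * pnorm(-z)
  }
  min(1, max(p, .Machine$double.xmin))
}

#' Discriminant score combining effect size and significance
#'
#' The default mode is \code{phenotype_score * (-log10 p)}: strong,
#' significant genes get large-magnitude scores, which matches ranking genes
#' by volcano-plot extremity. The literal mode \code{phenotype_score * p}
#' reads the alternative convention word for word; it shrinks significant
#' genes toward zero and is retained for comparability, never as the
#' default.
#'
#' @param phenotype_score gene phenotype score(s).
#' @param p_value Mann-Whitney p-value(s) in (0, 1].
#' @param mode \code{"neglog_product"} (default) or
#'   \code{"literal_product"}.
#' @return discriminant score(s).
#' @export
discriminant_score <- function(phenotype_score, p_value,
                               mode = c("neglog_product",
                                        "literal_product")) {
  mode <- match.arg(mode)
  if (any(p_value == 0)) {
    warning("p-value of 0 clamped to machine minimum before log")
    p_value <- pmax(p_value, .Machine$double.xmin)
  }
  stopifnot(all(p_value > 0 & p_value <= 1))
  switch(mode,
         neglog_product = phenotype_score * (-log10(p_value)),
         literal_product = phenotype_score * p_value)
}

#' Rank genes by discriminant score
#'
#' Rank 1 is the lowest (most negative) discriminant. Ties are broken by
#' absolute phenotype score (descending) and then gene name (ascending), so
#' the ranking is a deterministic permutation of 1..n independent of input
#' order.
#'
#' @param discriminant numeric vector of discriminant scores.
#' @param phenotype_score parallel phenotype scores (tie-break).
#' @param gene parallel gene names (final tie-break).
#' @return integer ranks parallel to the input.
#' @export
rank_genes <- function(discriminant, phenotype_score = rep(0, length(discriminant)),
                       gene = as.character(seq_along(discriminant))) {
  ord <- order(discriminant, -abs(phenotype_score), gene)
  ranks <- integer(length(discriminant))
  ranks[ord] <- seq_along(ord)
  ranks
}

#' Growth-screen gamma (fitness per doubling)
#'
#' Runs the same filter / enrichment / NT-centering chain on a
#' day0-versus-day18 column pair and divides by the number of population
#' doublings, yielding a per-element fitness in log2 units per doubling.
#'
#' @param table a [count_table()].
#' @param pair c(day18_sample, day0_sample): enrichment numerator first.
#' @param is_nt named logical vector over the table's elements.
#' @param doublings population doublings between the timepoints (default
#'   10).
#' @param config a [stats_config()].
#' @return named numeric vector of gammas over passing elements.
#' @export
growth_gamma <- function(table, pair, is_nt, doublings = 10,
                         config = stats_config()) {
  check_count(doublings, "doublings")
  phen <- replicate_phenotypes(table, pair, is_nt, config)
  phen / doublings
}

# One replicate's filter -> raw enrichment -> NT centering chain.
replicate_phenotypes <- function(table, pair, is_nt, config) {
  pass <- filter_low_counts(table, pair, config$min_count)
  if (!any(pass)) stop("no element passes the count filter for pair ",
                       paste(pair, collapse = "/"), call. = FALSE)
  ids <- names(pass)[pass]
  hi <- table$counts[ids, pair[1]]
  lo <- table$counts[ids, pair[2]]
  pc <- config$pseudocount
  t_hi <- sum(hi) + pc * length(ids)
  t_lo <- sum(lo) + pc * length(ids)
  raw <- guide_phenotype(hi, lo, t_hi, t_lo, pc)
  names(raw) <- ids
  normalize_to_controls(raw, is_nt[ids])
}

#' Score one screen from counts to ranked gene statistics
#'
#' The full per-screen chain: per replicate, guides are filtered (at least
#' \code{min_count} reads in both compared samples), converted to
#' pseudocounted log2 relative-frequency enrichments, and centered on the
#' non-targeting median; guide phenotypes are then averaged across the
#' replicates in which they passed; per gene, the phenotype score is the
#' signed mean of the \code{k_strongest} largest-magnitude guides, the
#' p-value is a two-sided Mann-Whitney test of all the gene's passing guides
#' against all passing non-targeting guides, and genes are ranked by
#' discriminant score (ascending). Genes with no passing guide are excluded
#' from ranking; genes with fewer than \code{k_strongest} passing guides are
#' scored on what passed and flagged via \code{n_guides_passing}.
#'
#' @param table a [count_table()] holding one screen's samples (use
#'   [subset_library()] or \code{screen} to pick one library out of a
#'   combined table).
#' @param library guide library data.frame mapping elements to genes and
#'   marking non-targeting controls.
#' @param config a [stats_config()].
#' @param mode \code{"facs"} (high vs low bins) or \code{"growth"} (day18 vs
#'   day0, scores in gamma units per doubling).
#' @param screen optional library name to select from a combined table.
#' @param doublings growth-mode doublings (default 10).
#' @return object of class \code{screen_stats}: list with
#'   \code{guide_phenotypes} (element_id, gene, phenotype, n_reps, is_nt),
#'   \code{gene_stats} (gene, phenotype_score, p_value, discriminant, rank,
#'   n_guides_passing; ordered by rank), \code{mode}, \code{config}.
#' @export
analyze_screen <- function(table, library, config = stats_config(),
                           mode = c("facs", "growth"), screen = NULL,
                           doublings = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(table, "count_table"))
  lib <- if (inherits(library, "dual_library")) library$elements else library
  lib <- validate_guide_library(lib)
  if (!is.null(screen)) table <- subset_library(table, screen)
  missing <- setdiff(rownames(table$counts), lib$element_id)
  if (length(missing))
    stop("count table elements absent from library: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  is_nt <- lib$is_negative_control
  names(is_nt) <- lib$element_id

  smp <- table$samples
  num_bin <- if (mode == "facs") "high" else "day18"
  den_bin <- if (mode == "facs") "low" else "day0"
  reps <- unique(smp$replicate[smp$bin %in% c(num_bin, den_bin)])
  reps <- reps[!is.na(reps)]
  if (!length(reps))
    stop("no ", num_bin, "/", den_bin, " sample pairs found", call. = FALSE)
  per_rep <- list()
  for (r in reps) {
    hi <- smp$sample[smp$replicate == r & smp$bin == num_bin]
    lo <- smp$sample[smp$replicate == r & smp$bin == den_bin]
    if (length(hi) != 1L || length(lo) != 1L)
      stop("replicate ", r, " does not have exactly one ", num_bin,
           " and one ", den_bin, " sample", call. = FALSE)
    per_rep[[as.character(r)]] <-
      replicate_phenotypes(table, c(hi, lo), is_nt, config)
  }
  avg <- average_replicates(per_rep)
  phen <- avg$phenotype
  if (mode == "growth") phen <- phen / doublings

  gp <- data.frame(element_id = names(phen),
                   gene = lib$gene[match(names(phen), lib$element_id)],
                   phenotype = unname(phen),
                   n_reps = unname(avg$n_reps[names(phen)]),
                   is_nt = unname(is_nt[names(phen)]),
                   stringsAsFactors = FALSE)
  controls <- gp$phenotype[gp$is_nt]
  if (!length(controls))
    stop("no passing non-targeting guides for the Mann-Whitney reference",
         call. = FALSE)
  genes <- sort(unique(gp$gene[!gp$is_nt]))
  score <- p <- numeric(length(genes)); n_pass <- integer(length(genes))
  for (i in seq_along(genes)) {
    rows <- gp$gene == genes[i]
    score[i] <- gene_phenotype(gp$phenotype[rows], config$k_strongest,
                               gp$element_id[rows])
    p[i] <- mw_pvalue(gp$phenotype[rows], controls, config$mw_exact_max)
    n_pass[i] <- sum(rows)
  }
  disc <- discriminant_score(score, p, config$discriminant_mode)
  gs <- data.frame(gene = genes, phenotype_score = score, p_value = p,
                   discriminant = disc,
                   rank = rank_genes(disc, score, genes),
                   n_guides_passing = n_pass, stringsAsFactors = FALSE)
  gs <- gs[order(gs$rank), , drop = FALSE]
  rownames(gs) <- NULL
  structure(list(guide_phenotypes = gp, gene_stats = gs, mode = mode,
                 config = config), class = "screen_stats")
}

#' @export
print.screen_stats <- function(x, ...) {
  cat(sprintf("screen_stats (%s): %d genes scored, %d guide phenotypes\n",
              x$mode, nrow(x$gene_stats), nrow(x$guide_phenotypes)))
  print(utils::head(x$gene_stats, 5))
  invisible(x)
}

#' Write screen statistics to disk
#'
#' Per-guide phenotype TSV, per-gene stats TSV and a JSON echo of the run
#' configuration.
#'
#' @param stats a \code{screen_stats} from [analyze_screen()].
#' @param dir output directory.
#' @export
write_screen_stats <- function(stats, dir) {
  stopifnot(inherits(stats, "screen_stats"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(stats$guide_phenotypes, file.path(dir, "guide_phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(stats$gene_stats, file.path(dir, "gene_stats.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(unclass(stats$config), list(mode = stats$mode)),
                       file.path(dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
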