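#' Two-pathway redundancy flux model
#'
#' The synthetic reporter is a substrate that can be handled by either of two
#' partially redundant pathways (an EMC-like pathway A and a GET-like pathway
#' B, in the motivating biology: tail-anchored protein insertion into the ER
#' membrane) plus a small background flux. Reporter output is the sum of the
#' three fluxes; knocking down members of one pathway is masked by the other
#' (buffering), while knocking down both collapses output to the background
#' (synthetic phenotype).
#'
#' @param flux_A,flux_B,flux_bg non-negative flux weights; their sum must be
#'   positive. The model is used on the normalized scale, so only ratios
#'   matter.
#' @return a \code{pathway_model} list.
#' @export
pathway_model <- function(flux_A = 0.5, flux_B = 0.5, flux_bg = 0.02) {
  stopifnot(flux_A >= 0, flux_B >= 0, flux_bg >= 0,
            flux_A + flux_B + flux_bg > 0)
  structure(list(flux_A = flux_A, flux_B = flux_B, flux_bg = flux_bg),
            class = "pathway_model")
}

effect_categories <- c("pathway_A_member", "pathway_B_member", "stabilizer",
                       "expression_only", "null")

#' Build a table of true gene effects
#'
#' @param gene character vector of gene names.
#' @param category one of \code{pathway_A_member}, \code{pathway_B_member},
#'   \code{stabilizer}, \code{expression_only}, \code{null}.
#' @param strength effect strength in [0, 1]; must be 0 for \code{null}.
#' @return validated data.frame (a truth table).
#' @export
true_effects <- function(gene, category, strength) {
  stopifnot(all(category %in% effect_categories),
            all(strength >= 0 & strength <= 1),
            all(strength[category == "null"] == 0))
  data.frame(gene = gene, category = category, strength = strength,
             stringsAsFactors = FALSE)
}

#' Expected log2 reporter ratio under the flux model
#'
#' Each knockdown of gene \eqn{g} (strength \eqn{s}, guide efficacy \eqn{e})
#' leaves residual gene activity \eqn{1 - s e}; several guides against the
#' same gene compose multiplicatively, so the combined knockdown is
#' \eqn{k_g = 1 - \prod_i (1 - s e_i)}. A pathway's residual activity is the
#' product over its targeted members of \eqn{1 - k_g}; reporter output is
#' \eqn{F_A a_A + F_B a_B + F_{bg}}, reported as log2 relative to the
#' unperturbed output so that no knockdown gives 0. Stabilizer knockdowns add
#' \eqn{\log_2(1 + s_g k^{(e)}_g)} where \eqn{k^{(e)}_g} is the combined guide
#' efficacy (loss of a degradation factor raises reporter level);
#' \code{expression_only} knockdowns contribute 0 because they scale GFP and
#' RFP alike and cancel in the ratio.
#'
#' The anchor guide, when present, has its efficacy multiplied by the
#' interference factor \code{rho} (the second cassette slightly diminishes
#' the fixed guide's potency), including when the variable guide targets the
#' anchor's own gene (double knockdown of one gene).
#'
#' @param effects data.frame with columns \code{gene}, \code{category},
#'   \code{strength}, \code{efficacy}: the knockdowns delivered by the
#'   variable guide(s). May have zero rows.
#' @param model a [pathway_model()].
#' @param anchor optional list with \code{gene}, \code{category},
#'   \code{strength}, \code{efficacy}, \code{rho}: the fixed-guide knockdown.
#' @return expected log2 reporter ratio (0 = unperturbed).
#' @export
expected_log_ratio <- function(effects, model = pathway_model(),
                               anchor = NULL) {
  stopifnot(inherits(model, "pathway_model"))
  gene <- effects$gene
  category <- effects$category
  strength <- effects$strength
  efficacy <- effects$efficacy
  if (!is.null(anchor)) {
    gene <- c(gene, anchor$gene)
    category <- c(category, anchor$category)
    strength <- c(strength, anchor$strength)
    efficacy <- c(efficacy, anchor$efficacy * (anchor$rho %||% 1))
  }
  stopifnot(all(strength >= 0 & strength <= 1),
            all(efficacy >= 0 & efficacy <= 1))
  act_A <- 1; act_B <- 1; stab <- 0
  for (g in unique(gene)) {
    i <- which(gene == g)
    cat_g <- category[i[1]]
    if (cat_g == "pathway_A_member") {
      act_A <- act_A * prod(1 - strength[i] * efficacy[i])
    } else if (cat_g == "pathway_B_member") {
      act_B <- act_B * prod(1 - strength[i] * efficacy[i])
    } else if (cat_g == "stabilizer") {
      e_comb <- 1 - prod(1 - efficacy[i])
      stab <- stab + log2(1 + strength[i[1]] * e_comb)
    }
    # expression_only and null contribute nothing to the ratio
  }
  total <- model$flux_A + model$flux_B + model$flux_bg
  log2((model$flux_A * act_A + model$flux_B * act_B + model$flux_bg) / total) +
    stab
}

#' Simulation configuration
#'
#' Defaults encode the screen as run: 5 guides per gene, two biological
#' replicates, 30\% tail gates on the reporter ratio, about 1000 cells per
#' element (the coverage maintained during the screen), and sequencing depth
#' of 1000 reads per element per bin.
#'
#' @param n_genes number of genes in the variable library.
#' @param guides_per_gene guides per gene (default 5).
#' @param n_negative_control_guides non-targeting guides (default 250).
#' @param anchor_gene gene targeted by the fixed guide in the anchored
#'   library; default the first pathway-A gene of the scenario.
#' @param anchor_efficacy knockdown efficacy of the fixed guide on its own
#'   (default 0.95: fixed guides are pre-validated to be potent).
#' @param interference_rho multiplier on the fixed guide's efficacy caused by
#'   the second cassette (default 0.8; the effect is real but modest).
#' @param guide_efficacy list describing the per-guide efficacy draw:
#'   \code{list(dist = "beta", shape1 = 8, shape2 = 2)} (mean 0.8), or
#'   \code{list(dist = "ladder", values = c(0.9, 0.8, 0.7, 0.5, 0.3))} for a
#'   deterministic per-gene ladder used in exactly reproducible fixtures.
#' @param cell_noise_sd per-cell Gaussian noise on the log2 reporter ratio
#'   (default 1.0). Tail gates amplify mean shifts: with 30\% gates, noise
#'   much below the typical true shift sorts nearly all hit cells out of the
#'   depleted bin, and the 50-count filter then censors exactly the strong
#'   hits. An sd of 1 log2 unit reproduces the substantial high/low overlap
#'   of real reporter ratio distributions.
#' @param cells_per_element sorted-population coverage per element
#'   (default 1000).
#' @param gate_fraction FACS tail fraction per bin, in (0, 0.5)
#'   (default 0.30).
#' @param read_depth_per_bin total reads sequenced per sorted bin; default
#'   \code{NULL} means 1000 x number of elements.
#' @param n_replicates biological replicates (default 2).
#' @param doublings population doublings between timepoints in growth mode
#'   (default 10).
#' @param seed RNG seed used by [generate_dataset()].
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 100, guides_per_gene = 5,
                       n_negative_control_guides = 250,
                       anchor_gene = NULL, anchor_efficacy = 0.95,
                       interference_rho = 0.8,
                       guide_efficacy = list(dist = "beta", shape1 = 8,
                                             shape2 = 2),
                       cell_noise_sd = 1.0, cells_per_element = 1000,
                       gate_fraction = 0.30, read_depth_per_bin = NULL,
                       n_replicates = 2, doublings = 10, seed = 1) {
  check_count(n_genes, "n_genes")
  check_count(guides_per_gene, "guides_per_gene")
  check_count(n_negative_control_guides, "n_negative_control_guides")
  check_count(n_replicates, "n_replicates")
  check_count(doublings, "doublings")
  check_count(cells_per_element, "cells_per_element")
  check_fraction(anchor_efficacy, "anchor_efficacy")
  check_fraction(interference_rho, "interference_rho", open_lo = TRUE)
  check_fraction(gate_fraction, "gate_fraction", lo = 0, hi = 0.5,
                 open_lo = TRUE, open_hi = TRUE)
  stopifnot(cell_noise_sd >= 0)
  if (!is.null(read_depth_per_bin)) check_count(read_depth_per_bin,
                                                "read_depth_per_bin")
  structure(as.list(environment()), class = "sim_config")
}

#' Scenario: which genes carry which true effects
#'
#' The default scenario mirrors the anchored-screen design: the anchor gene
#' belongs to pathway A; losing pathway-B members is buffered in the control
#' background and synthetic in the anchored background; losing further
#' pathway-A members is masked by the anchor (same pathway); stabilizer loss
#' raises the reporter in both backgrounds; expression-only genes cancel in
#' the ratio and carry no phenotype at all.
#'
#' @param n_pathway_A pathway-A genes, anchor included (default 8).
#' @param n_pathway_B pathway-B genes (default 10).
#' @param n_stabilizer reporter-stabilizing genes (default 5).
#' @param n_expression_only genes affecting GFP and RFP alike (default 5).
#' @param strength_pathway knockdown effect strength of pathway members
#'   (default 0.9: core insertase subunits are strong hits).
#' @param strength_stabilizer stabilizer strength (default 0.5).
#' @param strength_expression expression-only strength (default 0.5; it never
#'   reaches the ratio, but is recorded for completeness).
#' @return a \code{sim_scenario} list.
#' @export
default_scenario <- function(n_pathway_A = 8, n_pathway_B = 10,
                             n_stabilizer = 5, n_expression_only = 5,
                             strength_pathway = 0.9,
                             strength_stabilizer = 0.5,
                             strength_expression = 0.5) {
  structure(as.list(environment()), class = "sim_scenario")
}

#' Scenario with no true effects (null calibration)
#'
#' @return a \code{sim_scenario} with every gene null.
#' @export
null_scenario <- function() {
  default_scenario(n_pathway_A = 0, n_pathway_B = 0, n_stabilizer = 0,
                   n_expression_only = 0)
}

# Assign categories/strengths to n_genes gene names per scenario.
scenario_truth <- function(scenario, genes) {
  n <- length(genes)
  n_special <- scenario$n_pathway_A + scenario$n_pathway_B +
    scenario$n_stabilizer + scenario$n_expression_only
  if (n_special > n)
    stop("scenario requests ", n_special, " special genes but only ", n,
         " genes are simulated", call. = FALSE)
  category <- rep("null", n)
  strength <- rep(0, n)
  i <- 0
  if (scenario$n_pathway_A > 0) {
    category[(i + 1):(i + scenario$n_pathway_A)] <- "pathway_A_member"
    strength[(i + 1):(i + scenario$n_pathway_A)] <- scenario$strength_pathway
    i <- i + scenario$n_pathway_A
  }
  if (scenario$n_pathway_B > 0) {
    category[(i + 1):(i + scenario$n_pathway_B)] <- "pathway_B_member"
    strength[(i + 1):(i + scenario$n_pathway_B)] <- scenario$strength_pathway
    i <- i + scenario$n_pathway_B
  }
  if (scenario$n_stabilizer > 0) {
    category[(i + 1):(i + scenario$n_stabilizer)] <- "stabilizer"
    strength[(i + 1):(i + scenario$n_stabilizer)] <- scenario$strength_stabilizer
    i <- i + scenario$n_stabilizer
  }
  if (scenario$n_expression_only > 0) {
    category[(i + 1):(i + scenario$n_expression_only)] <- "expression_only"
    strength[(i + 1):(i + scenario$n_expression_only)] <- scenario$strength_expression
  }
  true_effects(genes, category, strength)
}

# Random unique ACGT k-mers (uses current RNG state).
random_protospacers <- function(n, width = 20L) {
  repeat {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
            collapse = ""), character(1))
    if (!anyDuplicated(seqs)) return(seqs)
  }
}

# Draw per-guide efficacies per config; NT guides get efficacy 0.
draw_efficacies <- function(lib, config) {
  eff <- numeric(nrow(lib))
  targeting <- !lib$is_negative_control
  spec <- config$guide_efficacy
  if (identical(spec$dist, "beta")) {
    eff[targeting] <- rbeta(sum(targeting), spec$shape1, spec$shape2)
  } else if (identical(spec$dist, "ladder")) {
    genes <- unique(lib$gene[targeting])
    for (g in genes) {
      i <- which(lib$gene == g & targeting)
      eff[i] <- rep_len(spec$values, length(i))
    }
  } else stop("unknown guide efficacy distribution '", spec$dist, "'",
              call. = FALSE)
  eff
}

# Vectorized expected log-ratios for every element of a library.
element_expected_ratios <- function(lib, truth, efficacies, model,
                                    anchor = NULL) {
  missing <- setdiff(unique(lib$gene[!lib$is_negative_control]), truth$gene)
  if (length(missing))
    stop("genes absent from truth table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  m <- match(lib$gene, truth$gene)
  none <- list(gene = character(0), category = character(0),
               strength = numeric(0), efficacy = numeric(0))
  vapply(seq_len(nrow(lib)), function(i) {
    eff <- if (lib$is_negative_control[i]) none else
      list(gene = lib$gene[i], category = truth$category[m[i]],
           strength = truth$strength[m[i]], efficacy = efficacies[[i]])
    expected_log_ratio(eff, model, anchor)
  }, numeric(1))
}

#' Simulate single-cell reporter ratios
#'
#' Each library element contributes \code{cells_per_element} cells whose log2
#' reporter ratio is the element's expected value under the flux model plus
#' Gaussian cell-to-cell noise. Uses the current RNG state; seed externally
#' for reproducibility.
#'
#' @param library a \code{dual_library} or guide library data.frame.
#' @param truth a truth table from [true_effects()]; every targeted library
#'   gene must appear in it.
#' @param config a [sim_config()].
#' @param model a [pathway_model()].
#' @param efficacies per-element guide efficacies (named or in library
#'   order); drawn from the config distribution when NULL.
#' @param anchor optional anchor knockdown, as in [expected_log_ratio()].
#' @return data.frame with columns \code{element_id} and \code{ratio}, one
#'   row per cell.
#' @export
simulate_cells <- function(library, truth, config = sim_config(),
                           model = pathway_model(), efficacies = NULL,
                           anchor = NULL) {
  lib <- if (inherits(library, "dual_library")) library$elements else library
  lib <- validate_guide_library(lib)
  if (is.null(efficacies)) efficacies <- draw_efficacies(lib, config)
  expected <- element_expected_ratios(lib, truth, efficacies, model, anchor)
  n <- config$cells_per_element
  ratio <- rep(expected, each = n)
  if (config$cell_noise_sd > 0)
    ratio <- ratio + rnorm(length(ratio), 0, config$cell_noise_sd)
  data.frame(element_id = rep(lib$element_id, each = n), ratio = ratio,
             stringsAsFactors = FALSE)
}

#' Sort cells into FACS bins by global quantile gates
#'
#' Gates are drawn on the pooled population (a single sorter gate on the
#' mixed library), not per element: the cells with the
#' \code{gate_fraction} highest ratios go to \code{high}, the same number of
#' lowest ratios to \code{low}, everything else is \code{unsorted}. Exactly
#' \code{round(gate_fraction * n)} cells land in each tail; ties are broken
#' by stable input order.
#'
#' @param cells data.frame from [simulate_cells()], or a numeric ratio
#'   vector.
#' @param gate_fraction tail fraction in (0, 0.5).
#' @return factor of \code{"low"}, \code{"unsorted"}, \code{"high"} parallel
#'   to the input cells.
#' @export
simulate_sort <- function(cells, gate_fraction = 0.30) {
  check_fraction(gate_fraction, "gate_fraction", lo = 0, hi = 0.5,
                 open_lo = TRUE, open_hi = TRUE)
  ratio <- if (is.data.frame(cells)) cells$ratio else cells
  n <- length(ratio)
  if (n < 4L) stop("need at least 4 cells to sort", call. = FALSE)
  k <- round(gate_fraction * n)
  ord <- order(ratio, method = "radix")   # radix sort is stable
  bin <- rep("unsorted", n)
  bin[ord[seq_len(k)]] <- "low"
  bin[ord[seq.int(n - k + 1L, n)]] <- "high"
  factor(bin, levels = c("low", "unsorted", "high"))
}

#' Multinomial sequencing of sorted bins
#'
#' Per bin, reads are drawn multinomially with probabilities proportional to
#' each element's cell count in that bin; every column therefore sums to the
#' configured depth exactly.
#'
#' @param bins named list of per-element cell tallies (named integer vectors
#'   over a common element set), one entry per sample; list names become
#'   sample descriptors.
#' @param read_depth_per_bin reads per sample.
#' @return a [count_table()].
#' @export
simulate_counts <- function(bins, read_depth_per_bin) {
  check_count(read_depth_per_bin, "read_depth_per_bin")
  stopifnot(is.list(bins), length(bins) >= 1L, !is.null(names(bins)))
  ids <- names(bins[[1]])
  mat <- matrix(0L, nrow = length(ids), ncol = length(bins),
                dimnames = list(ids, names(bins)))
  for (j in seq_along(bins)) {
    cells <- bins[[j]][ids]
    if (anyNA(cells)) stop("bins cover different element sets", call. = FALSE)
    if (sum(cells) == 0) stop("bin '", names(bins)[j], "' is empty",
                              call. = FALSE)
    mat[, j] <- rmultinom(1, read_depth_per_bin, prob = cells)[, 1]
  }
  count_table(mat)
}

#' Simulate a growth (fitness) screen
#'
#' Day-0 abundances grow for \code{doublings} population doublings at
#' per-element relative fitness \code{fitness} (log2 enrichment per
#' doubling): the day-18 abundance is proportional to
#' \code{day0 * 2^(doublings * fitness)}. Both timepoints are sequenced
#' multinomially at the given depth. Uses the current RNG state.
#'
#' @param library a \code{dual_library} or guide library data.frame.
#' @param fitness named numeric vector (element_id -> fitness per doubling);
#'   elements not named default to 0.
#' @param doublings population doublings between the timepoints.
#' @param read_depth_per_bin reads per timepoint.
#' @param abundance0 optional named day-0 abundances (default uniform).
#' @param prefix sample-name prefix, producing columns
#'   \code{prefix.day0} / \code{prefix.day18}.
#' @return a [count_table()] with \code{day0} and \code{day18} columns.
#' @export
simulate_growth <- function(library, fitness, doublings = 10,
                            read_depth_per_bin = 1e6, abundance0 = NULL,
                            prefix = "growth.1") {
  check_count(doublings, "doublings")
  lib <- if (inherits(library, "dual_library")) library$elements else library
  lib <- validate_guide_library(lib)
  f <- rep(0, nrow(lib)); names(f) <- lib$element_id
  if (!is.null(fitness)) {
    if (anyNA(fitness) || any(!is.finite(fitness)))
      stop("fitness values must be finite", call. = FALSE)
    f[names(fitness)] <- fitness
  }
  a0 <- rep(1, nrow(lib)); names(a0) <- lib$element_id
  if (!is.null(abundance0)) a0[names(abundance0)] <- abundance0
  if (sum(a0) == 0) stop("all day-0 abundances are zero", call. = FALSE)
  a18 <- a0 * 2^(doublings * f)
  bins <- list(a0, a18)
  names(bins) <- paste(prefix, c("day0", "day18"), sep = ".")
  simulate_counts(bins, read_depth_per_bin)
}

#' Generate a paired dual-guide reporter screen dataset
#'
#' Produces the full synthetic experiment: a variable guide library
#' (\code{guides_per_gene} guides per gene plus non-targeting controls) is
#' screened twice, once anchored on a non-targeting fixed guide (\code{NT}
#' library) and once anchored on the anchor gene (\code{anchor} library), in
#' \code{n_replicates} replicates each, with 30\%-tail sorting and
#' multinomial sequencing. The anchor gene also exists as a variable-position
#' gene, so the anchor+self double-knockdown element is present. Ground truth
#' (gene categories, strengths, per-guide efficacies) is returned alongside
#' the counts.
#'
#' @param config a [sim_config()]; \code{config$seed} makes the output
#'   byte-identical across runs.
#' @param scenario a [default_scenario()] / [null_scenario()].
#' @param model a [pathway_model()].
#' @return object of class \code{simulated_screen}: list with \code{counts}
#'   (a [count_table()] holding \code{NT.*} and \code{anchor.*} samples),
#'   \code{truth}, \code{efficacies}, \code{library} (guide table),
#'   \code{anchor_gene}, \code{config}, \code{scenario}, \code{model}.
#' @export
generate_dataset <- function(config = sim_config(),
                             scenario = default_scenario(),
                             model = pathway_model()) {
  stopifnot(inherits(config, "sim_config"), inherits(scenario, "sim_scenario"))
  if (!is.null(config$seed)) set.seed(config$seed)
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  truth <- scenario_truth(scenario, genes)
  anchor_gene <- config$anchor_gene %||% {
    cand <- truth$gene[truth$category == "pathway_A_member"]
    if (length(cand)) cand[1] else NA_character_
  }
  g <- config$guides_per_gene
  lib <- data.frame(
    element_id = c(paste0(rep(genes, each = g), "_", seq_len(g)),
                   sprintf("NTC_%04d", seq_len(config$n_negative_control_guides))),
    gene = c(rep(genes, each = g),
             rep("negative_control", config$n_negative_control_guides)),
    stringsAsFactors = FALSE
  )
  lib$protospacer <- random_protospacers(nrow(lib))
  lib$is_negative_control <- lib$gene == "negative_control"
  efficacies <- draw_efficacies(lib, config)
  names(efficacies) <- lib$element_id

  depth <- config$read_depth_per_bin %||% (1000 * nrow(lib))
  anchor_truth <- if (!is.na(anchor_gene)) {
    i <- match(anchor_gene, truth$gene)
    list(gene = anchor_gene, category = truth$category[i],
         strength = truth$strength[i], efficacy = config$anchor_efficacy,
         rho = config$interference_rho)
  } else NULL

  tabs <- list()
  for (screen in c("NT", "anchor")) {
    anchor <- if (screen == "anchor") anchor_truth else NULL
    expected <- element_expected_ratios(lib, truth, efficacies, model, anchor)
    for (rep_i in seq_len(config$n_replicates)) {
      n <- config$cells_per_element
      ratio <- rep(expected, each = n)
      if (config$cell_noise_sd > 0)
        ratio <- ratio + rnorm(length(ratio), 0, config$cell_noise_sd)
      bin <- simulate_sort(ratio, config$gate_fraction)
      elem <- rep(seq_len(nrow(lib)), each = n)
      tal <- function(which_bin) {
        x <- tabulate(elem[bin == which_bin], nbins = nrow(lib))
        names(x) <- lib$element_id
        x
      }
      bins <- list(tal("high"), tal("low"))
      names(bins) <- paste(screen, rep_i, c("high", "low"), sep = ".")
      tabs[[length(tabs) + 1L]] <- simulate_counts(bins, depth)
    }
  }
  structure(list(
    counts = merge_count_tables(tabs),
    truth = truth,
    efficacies = data.frame(element_id = lib$element_id, gene = lib$gene,
                            efficacy = unname(efficacies),
                            stringsAsFactors = FALSE),
    library = lib,
    anchor_gene = anchor_gene,
    config = config, scenario = scenario, model = model
  ), class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat(sprintf("simulated_screen: %d genes, %d elements, anchor = %s\n",
              x$config$n_genes, nrow(x$library), x$anchor_gene))
  print(x$counts)
  invisible(x)
}

#' Write a simulated screen to disk as plain text
#'
#' Emits the count table, truth table, per-guide efficacies, guide library
#' and a JSON echo of the configuration.
#'
#' @param sim a \code{simulated_screen}.
#' @param dir output directory.
#' @export
write_simulated_screen <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$efficacies, file.path(dir, "efficacies.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_guide_library(sim$library, file.path(dir, "library.tsv"))
  cfg <- sim$config; cfg$guide_efficacy <- as.list(cfg$guide_efficacy)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
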