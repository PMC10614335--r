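# Independent oracles used by the property tests. These deliberately avoid
# the package's code paths: the Mann-Whitney oracle defines U by pairwise
# comparison counting (not rank sums) and enumerates labelings explicitly;
# the restriction oracle is a character-by-character sliding window.

# Two-sided exact Mann-Whitney p by complete enumeration.
oracle_mw <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_stat <- function(a, b) {
    u <- 0
    for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
    u
  }
  u_obs <- u_stat(x, y)
  labelings <- utils::combn(n + m, n)
  u_all <- apply(labelings, 2, function(idx)
    u_stat(pooled[idx], pooled[-idx]))
  lo <- mean(u_all <= u_obs + 1e-9)
  hi <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# Sliding-window scan for exact occurrences of pattern (0-based starts).
oracle_scan <- function(sequence, pattern) {
  L <- nchar(sequence); w <- nchar(pattern)
  if (L < w) return(integer(0))
  starts <- integer(0)
  for (i in seq_len(L - w + 1)) {
    if (substr(sequence, i, i + w - 1) == pattern)
      starts <- c(starts, i - 1L)
  }
  starts
}

# Character-level reverse complement, independent of the package helper.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
          collapse = ""), character(1))
}

# A tiny guide library for I/O and counting tests.
toy_library <- function() {
  data.frame(
    element_id = c("geneA_1", "geneA_2", "geneB_1", "NTC_1"),
    gene = c("geneA", "geneA", "geneB", "negative_control"),
    protospacer = c("ACGTACGTACGTACGTACGT", "TTTTCCCCAAAAGGGGACGT",
                    "GATCGATCGATCGATCGATC", "CCCCGGGGAAAATTTTCGCG"),
    is_negative_control = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# A small, fast simulated world for pipeline tests.
small_config <- function(seed = 42, ...) {
  sim_config(n_genes = 25, n_negative_control_guides = 60,
             cells_per_element = 300, seed = seed, ...)
}

small_scenario <- function() {
  default_scenario(n_pathway_A = 3, n_pathway_B = 3, n_stabilizer = 2,
                   n_expression_only = 2)
}
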