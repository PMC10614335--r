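eff_row <- function(gene, category, strength, efficacy) {
  data.frame(gene = gene, category = category, strength = strength,
             efficacy = efficacy, stringsAsFactors = FALSE)
}
no_eff <- eff_row(character(0), character(0), numeric(0), numeric(0))

test_that("expected_log_ratio reproduces the flux-model closed form", {
  m <- pathway_model(0.5, 0.5, 0)
  expect_equal(expected_log_ratio(no_eff, m), 0)

  # full knockdown of one pathway member halves the flux
  expect_equal(expected_log_ratio(eff_row("a", "pathway_A_member", 1, 1), m),
               -1)

  # synergy: anchor ablates pathway A, variable guide ablates pathway B;
  # only the background flux remains
  m_bg <- pathway_model(0.5, 0.5, 0.02)
  anchor <- list(gene = "anc", category = "pathway_A_member", strength = 1,
                 efficacy = 1, rho = 1)
  got <- expected_log_ratio(eff_row("b", "pathway_B_member", 1, 1), m_bg,
                            anchor = anchor)
  expect_equal(got, log2(0.02 / 1.02))

  # stabilizer knockdown raises the reporter
  expect_equal(expected_log_ratio(eff_row("s", "stabilizer", 0.5, 0.8), m),
               log2(1 + 0.5 * 0.8))

  # expression-only and null knockdowns cancel in the ratio
  expect_equal(expected_log_ratio(eff_row("e", "expression_only", 1, 1), m), 0)
  expect_equal(expected_log_ratio(eff_row("n", "null", 0, 1), m), 0)

  # partial knockdowns compose multiplicatively within a pathway
  two <- rbind(eff_row("a1", "pathway_A_member", 0.9, 0.8),
               eff_row("a2", "pathway_A_member", 0.9, 0.5))
  act_A <- (1 - 0.72) * (1 - 0.45)
  expect_equal(expected_log_ratio(two, m), log2((0.5 * act_A + 0.5) / 1))
})

test_that("anchor interference rho and same-gene composition follow the model", {
  m <- pathway_model(0.5, 0.5, 0.02)
  anchor <- list(gene = "g", category = "pathway_A_member", strength = 0.9,
                 efficacy = 0.95, rho = 0.8)
  # variable guide against the anchor's own gene: residual activity is
  # (1 - s e1)(1 - s e2 rho)
  got <- expected_log_ratio(eff_row("g", "pathway_A_member", 0.9, 0.7), m,
                            anchor = anchor)
  res <- (1 - 0.9 * 0.7) * (1 - 0.9 * 0.95 * 0.8)
  expect_equal(got, log2((0.5 * res + 0.5 + 0.02) / 1.02))
})

test_that("masking: a saturated anchor makes further same-pathway knockdowns inert", {
  m <- pathway_model(0.5, 0.5, 0.02)
  anchor <- list(gene = "anc", category = "pathway_A_member", strength = 1,
                 efficacy = 1, rho = 1)
  base <- expected_log_ratio(no_eff, m, anchor = anchor)
  for (eff in c(0.1, 0.5, 1)) {
    more <- expected_log_ratio(eff_row("a2", "pathway_A_member", 1, eff), m,
                               anchor = anchor)
    expect_identical(more, base)
  }
})

test_that("pathway labels are symmetric", {
  set.seed(11)
  for (i in 1:20) {
    fa <- runif(1); fb <- runif(1); bg <- runif(1, 0, 0.2)
    s <- runif(2); e <- runif(2)
    effA <- rbind(eff_row("x", "pathway_A_member", s[1], e[1]),
                  eff_row("y", "pathway_B_member", s[2], e[2]))
    effB <- rbind(eff_row("x", "pathway_B_member", s[1], e[1]),
                  eff_row("y", "pathway_A_member", s[2], e[2]))
    expect_equal(expected_log_ratio(effA, pathway_model(fa, fb, bg)),
                 expected_log_ratio(effB, pathway_model(fb, fa, bg)))
  }
})

test_that("simulate_cells is exact at zero noise, seeded, and unbiased", {
  lib <- toy_library()
  truth <- true_effects(c("geneA", "geneB"),
                        c("pathway_A_member", "null"), c(0.9, 0))
  cfg <- sim_config(n_genes = 2, cells_per_element = 50, cell_noise_sd = 0,
                    seed = 1)
  eff <- c(0.8, 0.6, 0.5, 0)
  cells <- simulate_cells(lib, truth, cfg, efficacies = eff)
  expect_equal(nrow(cells), 4 * 50)
  # zero noise: every cell of an element sits exactly at its expected ratio
  per_el <- tapply(cells$ratio, cells$element_id, function(x)
    length(unique(x)))
  expect_true(all(per_el == 1))
  m <- pathway_model()
  expect_equal(unique(cells$ratio[cells$element_id == "geneA_1"]),
               expected_log_ratio(eff_row("geneA", "pathway_A_member", 0.9,
                                          0.8), m))
  expect_equal(unique(cells$ratio[cells$element_id == "NTC_1"]), 0)

  # determinism under a fixed seed
  cfg2 <- sim_config(n_genes = 2, cells_per_element = 50, cell_noise_sd = 0.7)
  set.seed(99); a <- simulate_cells(lib, truth, cfg2, efficacies = eff)
  set.seed(99); b <- simulate_cells(lib, truth, cfg2, efficacies = eff)
  expect_identical(a, b)

  # CLT bound on the mean of a null element's cells
  cfg3 <- sim_config(n_genes = 2, cells_per_element = 10000,
                     cell_noise_sd = 1)
  set.seed(7)
  cells3 <- simulate_cells(lib, truth, cfg3, efficacies = eff)
  nt_mean <- mean(cells3$ratio[cells3$element_id == "NTC_1"])
  expect_lt(abs(nt_mean), 3 * 1 / sqrt(10000))

  expect_error(simulate_cells(lib, truth[1, , drop = FALSE], cfg,
                              efficacies = eff), "absent from truth")
})

test_that("simulate_sort applies global quantile gates with stable ties", {
  bins <- simulate_sort(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1), 0.3)
  expect_equal(as.character(bins),
               c("high", "high", "high", "unsorted", "unsorted", "unsorted",
                 "unsorted", "low", "low", "low"))

  # all-equal ratios: configured counts still honored, by input order
  tied <- simulate_sort(rep(1, 10), 0.3)
  expect_equal(sum(tied == "high"), 3)
  expect_equal(sum(tied == "low"), 3)
  expect_equal(which(tied == "low"), 1:3)    # stable: first-come
  expect_equal(which(tied == "high"), 8:10)

  # gate just under 0.5 leaves only the middle sliver unsorted
  x <- seq_len(100)
  g <- simulate_sort(x, 0.49)
  expect_equal(sum(g == "unsorted"), 100 - 2 * round(0.49 * 100))

  expect_error(simulate_sort(c(1, 2, 3), 0.3), "at least 4")
  expect_error(simulate_sort(1:10, 0.5), "gate_fraction")
})

test_that("simulate_counts draws multinomially and conserves depth", {
  one <- simulate_counts(list(s1 = c(a = 5)), 1000)
  expect_equal(unname(one$counts[, 1]), 1000L)

  set.seed(21)
  two <- simulate_counts(list(s1 = c(a = 500, b = 500)), 10000)
  expect_equal(sum(two$counts[, 1]), 10000L)
  # +-3.5 sigma of Binomial(1e4, 0.5)
  expect_gte(two$counts["a", 1], 4650L)
  expect_lte(two$counts["a", 1], 5350L)

  set.seed(22)
  multi <- simulate_counts(list(x = c(a = 1, b = 2, c = 3),
                                y = c(a = 9, b = 0, c = 1)), 5000)
  expect_equal(unname(colSums(multi$counts)), c(5000L, 5000L))
  expect_equal(unname(multi$counts["b", "y"]), 0L)

  expect_error(simulate_counts(list(s = c(a = 0, b = 0)), 100), "empty")
})

test_that("simulate_growth follows 2^(doublings x fitness)", {
  lib <- toy_library()
  # neutral world: day18 frequencies match day0 frequencies within noise
  set.seed(31)
  neutral <- simulate_growth(lib, fitness = NULL, doublings = 10,
                             read_depth_per_bin = 4e5)
  f0 <- neutral$counts[, 1] / sum(neutral$counts[, 1])
  f18 <- neutral$counts[, 2] / sum(neutral$counts[, 2])
  expect_true(all(abs(f0 - f18) < 5 * sqrt(0.25 * 0.75 / 4e5)))

  # one element at fitness -0.1 over 10 doublings halves its relative
  # abundance against the neutral background
  set.seed(32)
  dep <- simulate_growth(lib, fitness = c(geneA_1 = -0.1), doublings = 10,
                         read_depth_per_bin = 1e6)
  ratio0 <- dep$counts["geneA_1", 1] / sum(dep$counts[, 1])
  ratio18 <- dep$counts["geneA_1", 2] / sum(dep$counts[, 2])
  # expected post-renormalization frequency: 0.5/3.5 vs 1/4 at day0
  expect_equal(ratio18 / ratio0, (0.5 / 3.5) / (1 / 4), tolerance = 0.05)

  set.seed(33); a <- simulate_growth(lib, c(geneA_1 = -0.1), 10, 1e5)
  set.seed(33); b <- simulate_growth(lib, c(geneA_1 = -0.1), 10, 1e5)
  expect_identical(a, b)

  expect_error(simulate_growth(lib, c(geneA_1 = Inf), 10, 1e5), "finite")
  expect_error(simulate_growth(lib, NULL, 10, 1e5,
                               abundance0 = c(geneA_1 = 0, geneA_2 = 0,
                                              geneB_1 = 0, NTC_1 = 0)),
               "zero")
})

test_that("generate_dataset emits a reproducible paired screen with truth", {
  cfg <- small_config(seed = 77)
  sim <- generate_dataset(cfg, small_scenario())
  depth <- 1000 * nrow(sim$library)
  expect_equal(unname(colSums(sim$counts$counts)), rep(depth, 8L))
  expect_setequal(unique(sim$counts$samples$library), c("NT", "anchor"))
  expect_equal(nrow(sim$counts$counts), nrow(sim$library))
  # anchor gene is also present as a variable gene (anchor+self element)
  expect_true(sim$anchor_gene %in% sim$library$gene)
  expect_equal(sim$truth$category[match(sim$anchor_gene, sim$truth$gene)],
               "pathway_A_member")

  sim2 <- generate_dataset(small_config(seed = 77), small_scenario())
  expect_identical(sim$counts, sim2$counts)
  expect_identical(sim$efficacies, sim2$efficacies)

  sim3 <- generate_dataset(small_config(seed = 78), small_scenario())
  expect_false(identical(sim$counts, sim3$counts))

  too_many <- default_scenario(n_pathway_A = 20, n_pathway_B = 20)
  expect_error(generate_dataset(small_config(), too_many), "special genes")
})

test_that("pathway-B knockdowns shift more under the anchored background", {
  # closed-form check of the screen design: the anchor (pathway A) uncovers
  # pathway-B phenotypes
  m <- pathway_model()
  anchor <- list(gene = "anc", category = "pathway_A_member", strength = 0.9,
                 efficacy = 0.95, rho = 0.8)
  base_nt <- expected_log_ratio(no_eff, m)
  base_an <- expected_log_ratio(no_eff, m, anchor = anchor)
  for (e in c(0.5, 0.7, 0.9)) {
    b <- eff_row("b", "pathway_B_member", 0.9, e)
    shift_nt <- expected_log_ratio(b, m) - base_nt
    shift_an <- expected_log_ratio(b, m, anchor = anchor) - base_an
    expect_gt(abs(shift_an), abs(shift_nt))
  }
})

test_that("ladder efficacies make fixtures exactly reproducible", {
  cfg <- small_config(seed = 5,
                      guide_efficacy = list(dist = "ladder",
                                            values = c(0.9, 0.8, 0.7, 0.5,
                                                       0.3)))
  sim <- generate_dataset(cfg, small_scenario())
  eff <- sim$efficacies
  g1 <- eff$efficacy[eff$gene == "G0001"]
  expect_equal(g1, c(0.9, 0.8, 0.7, 0.5, 0.3))
  expect_equal(unique(eff$efficacy[eff$gene == "negative_control"]), 0)
})

test_that("simulated screens write to disk as plain text", {
  sim <- generate_dataset(small_config(seed = 3), small_scenario())
  dir <- withr::local_tempdir()
  write_simulated_screen(sim, dir)
  back <- read_count_table(file.path(dir, "counts.tsv"))
  expect_identical(back$counts, sim$counts$counts)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), sim$config$n_genes)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_equal(cfg$seed, 3L)
})
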