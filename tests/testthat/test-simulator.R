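# minimal low-level demography: k modern lineages in one population
one_population <- function(k, lambda = 1) {
  list(branch_end = Inf, branch_parent = -1L,
       leaf_branch = rep(0L, k), leaf_time = rep(0, k),
       admix_time = numeric(), admix_target = integer(),
       admix_dest = integer(), admix_beta = numeric(), lambda = lambda)
}

test_that("pairwise coalescence time is exponential with rate lambda", {
  set.seed(1)
  n <- 20000L
  times <- vapply(seq_len(n), function(i) {
    simulate_gene_tree(one_population(2L))$merges$time[1L]
  }, 0)
  expect_lt(abs(mean(times) - 1), 3 / sqrt(n))  # 3 SE
  set.seed(2)
  t2 <- vapply(seq_len(5000L), function(i) {
    simulate_gene_tree(one_population(2L, lambda = 4))$merges$time[1L]
  }, 0)
  expect_lt(abs(mean(t2) - 0.25), 3 * 0.25 / sqrt(5000))
})

test_that("discordant cherry topologies are equally likely under the null", {
  set.seed(3)
  model <- species_model("S")
  n13 <- 0L
  n23 <- 0L
  for (i in seq_len(20000L)) {
    gt <- simulate_gene_tree(model)
    cl <- c(gt$merges$clade1, gt$merges$clade2)
    # gene tree (((1,3),(2,4)),5) realized iff clades 13 and 24 both form
    if (all(c("13", "24") %in% cl)) n13 <- n13 + 1L
    if (all(c("23", "14") %in% cl)) n23 <- n23 + 1L
  }
  expect_gt(n13 + n23, 50L)
  bt <- stats::binom.test(n13, n13 + n23, 0.5)
  expect_gt(bt$p.value, 0.001)
})

test_that("a zero-proportion gene-flow edge leaves the process untouched", {
  m0 <- species_model("S")
  m1 <- add_gene_flow(m0, "1>3", beta = 0)
  c0 <- simulate_pattern_counts(m0, 5000, seed = 99)
  c1 <- simulate_pattern_counts(m1, 5000, seed = 99)
  expect_identical(as.numeric(c0), as.numeric(c1))
})

test_that("pattern simulation is reproducible under a fixed seed", {
  m <- add_gene_flow(species_model("A"), "4>1")
  a <- simulate_pattern_counts(m, 3000, seed = 123)
  b <- simulate_pattern_counts(m, 3000, seed = 123)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_equal(sum(a), 3000)
})

test_that("mutations fall uniformly on branches and map to patterns", {
  set.seed(4)
  star <- gene_tree(setNames(rep(1, 5), as.character(1:5)))
  pats <- drop_mutations(star, mu = 600)
  expect_true(all(pats %in% pattern_codes()[1:5]))  # singletons only
  gof <- suppressWarnings(stats::chisq.test(table(factor(
    pats, levels = pattern_codes()[1:5]))))
  expect_gt(gof$p.value, 0.001)

  cat12 <- gene_tree(c("12" = 1))
  expect_true(all(drop_mutations(cat12, mu = 50) == "BBAAA"))

  # complement clades polarize to the same pattern
  deep <- gene_tree(c("134" = 1))
  expect_true(all(drop_mutations(deep, mu = 50) == "ABAAB"))

  expect_identical(drop_mutations(star, mu = 1e-9), character())
})

test_that("Poisson mutation counts track mu times tree length", {
  set.seed(12)
  gt <- gene_tree(c("1" = 2, "23" = 3))  # total length 5
  k <- vapply(1:2000, function(i) length(drop_mutations(gt, mu = 0.8)), 0)
  expect_equal(mean(k), 4, tolerance = 3 * 2 / sqrt(2000))
})

test_that("equal probability sets are balanced under the null", {
  cts <- simulate_pattern_counts(species_model("S"), 30000, seed = 21)
  specs <- binomial_specs("S")
  for (i in seq_len(nrow(specs))) {
    nl <- cts[[specs$left[i]]]
    nr <- cts[[specs$right[i]]]
    bt <- stats::binom.test(round(nl), round(nl + nr), 0.5)
    expect_gt(bt$p.value, 0.001)
  }
})

test_that("relabeling the exchangeable cherry leaves the pattern law
          invariant", {
  c1 <- simulate_pattern_counts(species_model("S"), 20000, seed = 31)
  c2 <- simulate_pattern_counts(species_model("S"), 20000, seed = 32)
  # swap taxa 3 and 4 in the second sample
  swap <- vapply(pattern_codes(), function(code) {
    s <- strsplit(code, "")[[1L]][c(1, 2, 4, 3, 5)]
    p <- polarize_site(ifelse(s == "B", "T", "C"))
    if (is.null(p)) code else p
  }, "")
  c2s <- setNames(as.numeric(c2)[match(pattern_codes(), swap)],
                  pattern_codes())
  ct <- suppressWarnings(stats::chisq.test(rbind(as.numeric(c1), c2s)))
  expect_gt(ct$p.value, 0.001)
})

test_that("an ancient tip biases only the statistics using its singletons", {
  m <- species_model("S", sampling_times = c(0, 0.5, 0, 0, 0))
  cts <- simulate_pattern_counts(m, 50000, seed = 41)
  p <- compute_panel(cts, "S", include_singletons = TRUE)
  expect_identical(p$class[p$name == "S5+7"], "+")
  expect_true(all(p$class[1:4] == "0"))
})

test_that("gene-flow scenarios recover their predicted sign signatures", {
  # anchor scenario: 1>3 on tree S at 100,000 patterns
  m <- scenario_model("S", "1>3")
  p <- compute_panel(simulate_pattern_counts(m, 1e5, seed = 51), "S")
  expect_identical(p$class[1:4], c("+", "+", "+", "0"))
  # direction flip: 3>1 zeroes the second statistic instead of the fourth
  m2 <- scenario_model("S", "3>1")
  p2 <- compute_panel(simulate_pattern_counts(m2, 1e5, seed = 52), "S")
  expect_identical(p2$class[1:4], c("+", "0", "+", "+"))
})

test_that("model validation rejects malformed graphs", {
  expect_error(species_model("S", node_times = c("12" = 2, "34" = 1,
                                                 "1234" = 1.5,
                                                 "12345" = 3)),
               "strictly increase")
  expect_error(species_model("S", sampling_times = c(0, -1, 0, 0, 0)))
  expect_error(species_model("S", sampling_times = c(2, 0, 0, 0, 0)),
               "beyond")
  m <- species_model("S")
  expect_error(add_gene_flow(m, "3>3"), "differ")
  expect_error(add_gene_flow(m, "1>3", beta = 1.2), "beta")
  expect_error(add_gene_flow(m, "3>12"), "coexist")
  expect_error(add_gene_flow(m, "7>3"), "no branch")
})
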