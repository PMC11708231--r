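test_that("the preferred statistic inventory is eight plus four plus eight", {
  specs <- binomial_specs()
  expect_equal(nrow(specs), 20L)
  expect_setequal(specs$name[specs$requires_synchronization],
                  c("S7", "S8", "A4", "Q7", "Q8"))
  expect_length(panel_compositions("S"), 8L)
  expect_length(panel_compositions("A"), 4L)
  expect_length(panel_compositions("Q"), 8L)
  expect_length(panel_compositions("S", include_singletons = FALSE), 4L)
  expect_length(panel_compositions("A", include_singletons = FALSE), 3L)
  expect_length(panel_compositions("Q", include_singletons = FALSE), 4L)
})

test_that("composition expansion cancels shared patterns before scaling", {
  cts <- pattern_counts(c(BABAA = 7, BAABA = 3, ABABA = 2))
  lr <- compose("S1+4", cts)  # BAABA appears in S1's right and S4's left
  expect_equal(lr[["nL"]], 7)
  expect_equal(lr[["nR"]], 2)

  cts2 <- pattern_counts(c(BABAA = 5, AAABB = 1, BAABA = 2, AABAB = 2))
  lr2 <- compose("S1-6", cts2)
  expect_equal(lr2[["nL"]], 6)
  expect_equal(lr2[["nR"]], 4)

  set.seed(11)
  for (i in 1:20) {
    cts3 <- rand_counts()
    lr3 <- compose("S3-1", cts3)
    expect_equal(lr3[["nL"]] - lr3[["nR"]],
                 cts3[["BAABA"]] - cts3[["ABBAA"]])
  }
  expect_error(parse_composition("X1-2"), "cannot parse")
  expect_error(parse_composition("A1-7"), "no binomial statistic")
})

test_that("classification follows the two-sided normal threshold", {
  expect_equal(z_critical(0.01), 2.576, tolerance = 1e-3)
  zero <- evaluate_statistic("S1", pattern_counts())
  expect_identical(zero$class, "0")
  expect_equal(zero$scaled, 0)

  r <- evaluate_statistic("S5", pattern_counts(c(BAAAB = 5000, ABAAB = 4000)))
  expect_equal(r$Z, 1000 / sqrt(9000), tolerance = 1e-9)
  expect_identical(r$class, "+")

  r2 <- evaluate_statistic("S5", pattern_counts(c(BAAAB = 6, ABAAB = 4)))
  expect_equal(r2$Z, 2 / sqrt(10), tolerance = 1e-9)
  expect_identical(r2$class, "0")
})

test_that("published value/interval/Z triples satisfy the scaling and Wald
          formulas", {
  # (scaled value, 99% Wald radius, Z) rows from the published tree-S run
  triples <- rbind(c(0.388, 0.015, 63.44), c(0.290, 0.016, 44.82),
                   c(0.157, 0.018, 23.07), c(0.058, 0.005, 30.48),
                   c(0.610, 0.011, 121.1), c(0.089, 0.017, 13.87))
  for (i in seq_len(nrow(triples))) {
    s <- triples[i, 1]; rad <- triples[i, 2]; z <- triples[i, 3]
    # radius = 2.576 * sqrt(4 nL nR / T^3) with s = (nL-nR)/T, z = s sqrt(T)
    expect_lt(abs(2.576 * sqrt(1 - s^2) * s / z - rad), 1.5e-3)
  }
})

test_that("panels have the fixed shape and order", {
  cts <- pattern_counts()
  pS <- compute_panel(cts, "S")
  expect_identical(pS$name, c("S1-6", "S2-6", "S3-5", "S4-5", "S5+7",
                              "S6+8", "S3+4-5+7", "S1+2-6+8"))
  expect_true(all(pS$class == "0"))
  pA <- compute_panel(cts, "A", include_singletons = TRUE)
  expect_identical(pA$name, c("A1-2", "A1-3", "A2-3", "A1+2-3+4"))
  pQn <- compute_panel(cts, "Q", include_singletons = FALSE)
  expect_identical(pQn$name, c("Q1-6", "Q2-6", "Q3-5", "Q4-5"))
})

test_that("linear relations among binomials hold on every count vector", {
  set.seed(5)
  un <- function(comp, cts) {
    lr <- compose(comp, cts)
    lr[["nL"]] - lr[["nR"]]
  }
  for (i in 1:200) {
    cts <- rand_counts()
    expect_equal(un("S1", cts) + un("S4", cts),
                 un("S2", cts) + un("S3", cts))
    expect_equal(un("Q1", cts) + un("Q4", cts),
                 un("Q2", cts) + un("Q3", cts))
  }
})

test_that("scaled statistics stay in [-1, 1] with congruent signs", {
  set.seed(6)
  for (i in 1:50) {
    cts <- rand_counts()
    for (tree in c("S", "A", "Q")) {
      p <- compute_panel(cts, tree)
      expect_true(all(p$scaled >= -1 & p$scaled <= 1))
      expect_equal(sign(p$scaled), sign(p$unscaled))
      expect_equal(sign(p$Z), sign(p$unscaled))
    }
  }
})

# DFOIL written out directly from its pattern groups, independent of the
# composition machinery
dfoil_oracle <- function(cts) {
  n <- function(p) cts[[p]]
  scaled <- function(L, R) {
    if (L + R == 0) return(0)
    (L - R) / (L + R)
  }
  c(DFO = scaled(n("BABAA") + n("ABABA") + n("AAABB") + n("AAABA"),
                 n("BAABA") + n("ABBAA") + n("AABAB") + n("AABAA")),
    DIL = scaled(n("ABBAA") + n("BAABA") + n("AAABB") + n("AAABA"),
                 n("ABABA") + n("BABAA") + n("AABAB") + n("AABAA")),
    DFI = scaled(n("BABAA") + n("ABABA") + n("ABAAB") + n("ABAAA"),
                 n("ABBAA") + n("BAABA") + n("BAAAB") + n("BAAAA")),
    DOL = scaled(n("BAABA") + n("ABBAA") + n("ABAAB") + n("ABAAA"),
                 n("ABABA") + n("BABAA") + n("BAAAB") + n("BAAAA")))
}

test_that("DFOIL compositions agree with their second printed form and an
          independent oracle", {
  set.seed(8)
  for (i in 1:200) {
    cts <- rand_counts()
    a <- dfoil_panel(cts)
    b <- dfoil_panel(cts, alternate = TRUE)
    expect_equal(a$scaled, b$scaled, tolerance = 1e-12)
    expect_equal(a$nL, b$nL)
    expect_equal(setNames(a$scaled, a$name), dfoil_oracle(cts),
                 tolerance = 1e-12)
  }
  sym <- pattern_counts(setNames(rep(4, 15), pattern_codes()))
  expect_true(all(dfoil_panel(sym)$scaled == 0))
})

test_that("Partitioned D equals its signed binomial expansions", {
  d <- partitioned_d(pattern_counts(c(BAAAB = 3, ABAAB = 1)))
  expect_equal(d$scaled[d$name == "D12"], 0.5)
  d1 <- partitioned_d(pattern_counts(c(BABAA = 4, ABBAA = 1)))
  expect_equal(d1$scaled[d1$name == "D1"], -0.6)
  sym <- pattern_counts(setNames(rep(2, 15), pattern_codes()))
  expect_true(all(partitioned_d(sym)$scaled == 0))
  set.seed(9)
  for (i in 1:50) {
    cts <- rand_counts()
    d <- partitioned_d(cts)
    expect_equal(d$scaled[1], evaluate_statistic("S5", cts)$scaled)
    expect_equal(d$scaled[2], -evaluate_statistic("S3", cts)$scaled)
    expect_equal(d$scaled[3], -evaluate_statistic("S4", cts)$scaled)
  }
})

# classic four-taxon D by direct allele-split counting on raw sites
quartet_d <- function(sites, taxa, pair13, pair24) {
  al <- as.matrix(sites[, 2L + taxa])
  n_baba <- 0; n_abba <- 0
  for (i in seq_len(nrow(al))) {
    a <- al[i, ]
    u <- unique(a)
    if (length(u) != 2L) next
    split <- which(a == u[1L])
    if (setequal(split, pair13) || setequal(split, setdiff(1:4, pair13))) {
      n_baba <- n_baba + 1
    } else if (setequal(split, pair24) ||
               setequal(split, setdiff(1:4, pair24))) {
      n_abba <- n_abba + 1
    }
  }
  if (n_baba + n_abba == 0) return(0)
  (n_baba - n_abba) / (n_baba + n_abba)
}

test_that("dropping one ingroup population reduces the panel to classic D", {
  set.seed(10)
  for (i in 1:20) {
    al <- matrix(sample(c("C", "T"), 5L * 60L, replace = TRUE), ncol = 5L)
    sites <- data.frame(chrom = "c", pos = 1:60, t1 = al[, 1], t2 = al[, 2],
                        t3 = al[, 3], t4 = al[, 4], t5 = al[, 5],
                        stringsAsFactors = FALSE)
    cts <- count_patterns(sites, mode = "haploid")
    p <- compute_panel(cts, "S", include_singletons = FALSE)
    # drop 4: D over (1,2,3,5) compares 13|25 with 23|15 splits
    expect_equal(p$scaled[p$name == "S3-5"],
                 quartet_d(sites, c(1, 2, 3, 5), c(1, 3), c(2, 3)))
    # drop 3: D over (1,2,4,5)
    expect_equal(p$scaled[p$name == "S4-5"],
                 quartet_d(sites, c(1, 2, 4, 5), c(1, 3), c(2, 3)))
    # drop 2: D over (1,3,4,5) compares 13|45 with 14|35 splits
    expect_equal(p$scaled[p$name == "S1-6"],
                 quartet_d(sites, c(1, 3, 4, 5), c(1, 2), c(1, 3)))
    # drop 1: D over (2,3,4,5) compares 23|45 with 24|35 splits
    expect_equal(p$scaled[p$name == "S2-6"],
                 quartet_d(sites, c(2, 3, 4, 5), c(1, 2), c(1, 3)))
  }
})
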