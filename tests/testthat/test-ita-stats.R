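test_that("Spearman rho matches the rank-then-Pearson oracle, ties included", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    x <- sample(round(rnorm(n), 1))   # rounding forces ties
    y <- round(rnorm(n), 1)
    got <- spearman(x, y)
    expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(got$p,
                 suppressWarnings(cor.test(x, y, method = "spearman",
                                           exact = FALSE)$p.value),
                 tolerance = 1e-9)
  }
  # perfect anti-monotone relation
  x <- 1:10
  expect_equal(spearman(x, exp(-x))$rho, -1)
  expect_equal(spearman(x, exp(-x))$p, 0)
  # constant vector: undefined, flagged as NA for exclusion
  expect_true(is.na(spearman(x, rep(2, 10))$rho))
  expect_error(spearman(1:5, 1:6), "equal length")

  # matrix form agrees with the scalar form entry-wise
  X <- matrix(rnorm(4 * 15), 4)
  Y <- matrix(rnorm(6 * 15), 6)
  m <- spearman_matrix(X, Y)
  expect_equal(m$rho[2, 3], spearman(X[2, ], Y[3, ])$rho)
  expect_equal(m$p[4, 6], spearman(X[4, ], Y[6, ])$p)
})

test_that("BH adjustment equals the quadratic step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)                 # single p unchanged
  expect_equal(bh_adjust(rep(0.01, 10)), rep(0.01, 10))
  set.seed(8)
  for (i in 1:10) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- runif(25)
  perm <- sample(25)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("anti-correlation counting uses strict thresholds on both axes", {
  rho <- c(-0.3, -0.5, -0.31, -0.9, 0.4, NA)
  fdr <- c(0.01, 0.049, 0.05, 0.2, 0.01, 0.01)
  # -0.3 exactly fails; fdr 0.05 exactly fails; NA never counts
  expect_identical(count_anticorrelated(rho, fdr), 1L)
  expect_identical(count_anticorrelated(rho, fdr, rho_max = -0.29, fdr_max = 0.3),
                   4L)
})

test_that("adjusted ITA identities: zero background, equal fractions, hub-TF sign", {
  expect_equal(adjusted_ita(10, 100, 0, 1000), 10)
  expect_equal(adjusted_ita(10, 100, 100, 1000), 0)
  expect_equal(adjusted_ita(1, 1, 300, 1000), 0.7)
  # one anti-correlated real target among several predicted, with a large
  # transitively anti-correlated background: negative despite m_tar = 1
  expect_lt(adjusted_ita(1, 5, 800, 1000), 0)
  # linear in m_tar and m_nontar
  expect_equal(adjusted_ita(4, 10, 5, 50) - adjusted_ita(3, 10, 5, 50), 1)
  expect_equal(adjusted_ita(4, 10, 6, 50) - adjusted_ita(4, 10, 5, 50), -10 / 50)
  expect_error(adjusted_ita(1, 2, 0, 0), "n_nontar")
  expect_error(adjusted_ita(3, 2, 0, 10), "0 <= m <= n")
})

test_that("one-sided Fisher p is the hypergeometric upper tail", {
  expect_equal(fisher_one_sided(0, 10, 3, 50), 1)    # X >= 0 is certain
  expect_equal(fisher_one_sided(3, 10, 10, 100), oracle_fisher(3, 10, 10, 100),
               tolerance = 1e-14)
  # agreement with stats::fisher.test's one-sided alternative
  ft <- fisher.test(matrix(c(5, 7, 4, 84), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(fisher_one_sided(5, 12, 4, 88), ft$p.value, tolerance = 1e-12)
  # monotone non-increasing in m_tar at fixed margins
  p <- fisher_one_sided(0:13, 20, 13 - (0:13), 80)
  expect_true(all(diff(p) <= 1e-14))
  expect_error(fisher_one_sided(3, 2, 0, 10), "negative cell")
})

test_that("signed log transform is odd and hits the anchor values", {
  expect_identical(signed_log(0), 0)
  expect_equal(signed_log(c(1, -1)), c(1, -1))
  expect_equal(signed_log(c(3, -3)), c(2, -2))
  y <- rnorm(50, sd = 20)
  expect_equal(signed_log(-y), -signed_log(y))
})

# Deterministic 2-isomiR fixture whose correlation structure is planted
# directly in the expression values: targets of isoA are strictly
# decreasing in isoA, non-targets are noise.
make_profile_fixture <- function() {
  n <- 20
  set.seed(99)
  samples <- sprintf("s%02d", 1:n)
  isoA <- 1:n + 0.1 * rnorm(n)
  isoB <- rnorm(n)
  iso_expr <- rbind("isoA|0" = isoA, "isoB|0" = isoB)
  colnames(iso_expr) <- samples
  tx <- rbind(
    T1 = -isoA + 0.01 * rnorm(n),   # true anti-correlated target of isoA
    T2 = -isoA + 0.01 * rnorm(n),
    T3 = rnorm(n),                  # inert target
    N1 = rnorm(n), N2 = rnorm(n), N3 = rnorm(n), N4 = rnorm(n)
  )
  colnames(tx) <- samples
  interactions <- data.frame(
    isomir = c("isoA|0", "isoA|0", "isoA|0", "isoB|0"),
    transcript_id = c("T1", "T2", "T3", "T3"),
    window_start = 0L, seed_type = c("8mer", "6mer", "other", "6mer"),
    region = c("3UTR", "CDS", "3UTR", "3UTR"), source = "internal",
    stringsAsFactors = FALSE
  )
  nontargets <- list("isoA|0" = c("N1", "N2", "N3", "N4"),
                     "isoB|0" = c("N1", "N2", "N3", "N4"))
  groups <- data.frame(sample_id = samples, group = "g1",
                       stringsAsFactors = FALSE)
  list(iso = iso_expr, tx = tx, interactions = interactions,
       nontargets = nontargets, groups = groups)
}

test_that("ITA records are consistent with manual counts on the correlation table", {
  fx <- make_profile_fixture()
  prof <- compute_ita_profile(fx$iso, fx$tx, fx$groups, fx$interactions,
                              fx$nontargets)
  expect_identical(names(prof$ita),
                   c("isomir", "group", "stratum", "n_tar", "m_tar",
                     "n_nontar", "m_nontar", "ita", "background_ita",
                     "adjusted_ita", "adjusted_ita_signed_log",
                     "fisher_p", "fisher_fdr"))
  co <- prof$correlations
  for (iso in c("isoA|0", "isoB|0")) {
    rec <- prof$ita[prof$ita$isomir == iso, ]
    tar <- co[co$isomir == iso & co$role == "target", ]
    non <- co[co$isomir == iso & co$role == "nontarget", ]
    expect_identical(rec$n_tar, nrow(tar))
    expect_identical(rec$n_nontar, nrow(non))
    expect_identical(rec$m_tar, sum(tar$rho < -0.3 & tar$fdr < 0.05))
    expect_identical(rec$m_nontar, sum(non$rho < -0.3 & non$fdr < 0.05))
    expect_equal(rec$adjusted_ita,
                 rec$m_tar - rec$n_tar * rec$m_nontar / rec$n_nontar)
    expect_equal(rec$fisher_p, fisher_one_sided(rec$m_tar, rec$n_tar,
                                                rec$m_nontar, rec$n_nontar))
  }
  recA <- prof$ita[prof$ita$isomir == "isoA|0", ]
  expect_identical(recA$m_tar, 2L)          # T1, T2 planted anti-correlations
  expect_gt(recA$adjusted_ita, 0)
  # correlation FDR is one joint family per group (targets and non-targets)
  expect_equal(co$fdr, bh_adjust(co$p))
  # Fisher FDR is BH across isomiRs within the group
  expect_equal(prof$ita$fisher_fdr, bh_adjust(prof$ita$fisher_p))
})

test_that("stratified ITA splits targets by site label at pair granularity", {
  fx <- make_profile_fixture()
  prof <- compute_ita_profile(fx$iso, fx$tx, fx$groups, fx$interactions,
                              fx$nontargets, strata = "seed_type")
  recA <- prof$ita[prof$ita$isomir == "isoA|0", ]
  expect_setequal(recA$stratum, c("8mer", "6mer", "other"))
  expect_identical(recA$n_tar[recA$stratum == "8mer"], 1L)   # T1
  expect_identical(recA$m_tar[recA$stratum == "8mer"], 1L)
  expect_identical(recA$n_tar[recA$stratum == "other"], 1L)  # T3, inert
  expect_identical(recA$m_tar[recA$stratum == "other"], 0L)
  # the non-target background is shared across strata
  expect_identical(unique(recA$n_nontar), 4L)
})

test_that("small groups are skipped with a warning and constants are excluded", {
  fx <- make_profile_fixture()
  groups2 <- fx$groups
  groups2$group[1:2] <- "tiny"
  expect_warning(
    prof <- compute_ita_profile(fx$iso, fx$tx, groups2, fx$interactions,
                                fx$nontargets, min_group_size = 5),
    "tiny"
  )
  expect_identical(unique(prof$ita$group), "g1")

  tx2 <- fx$tx
  tx2["N1", ] <- 3                          # constant vector
  expect_message(
    prof2 <- compute_ita_profile(fx$iso, tx2, fx$groups, fx$interactions,
                                 fx$nontargets),
    "constant"
  )
  expect_identical(unique(prof2$ita$n_nontar), 3L)
})

test_that("active-set report flags by Fisher FDR and compares groups", {
  ita <- data.frame(
    isomir = rep(c("a|0", "b|0", "c|0"), 2),
    group = rep(c("g1", "g2"), each = 3),
    stratum = "pooled",
    fisher_fdr = c(0.01, 0.2, 0.01, 0.01, 0.2, 0.01),
    stringsAsFactors = FALSE
  )
  rep1 <- report_active_sets(ita)
  expect_identical(rep1$active$g1, c("a|0", "c|0"))
  expect_equal(rep1$jaccard$jaccard, 1)     # identical activity patterns
  ita$fisher_fdr[4:6] <- c(0.2, 0.01, 0.2)
  rep2 <- report_active_sets(ita)
  expect_equal(rep2$jaccard$jaccard, 0)     # disjoint active sets
  expect_error(report_active_sets(ita[ita$group == "g1", ]), "2 groups")
})
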