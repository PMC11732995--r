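test_that("SMA fit: exact proportionality, symmetry, independence limit", {
  x <- 1:20
  f <- sma_fit(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 0)
  expect_equal(f$r2, 1)

  set.seed(1)
  a <- rnorm(500); b <- 3 - 0.5 * a + rnorm(500)
  fab <- sma_fit(a, b); fba <- sma_fit(b, a)
  expect_equal(fab$r2, cor(a, b)^2, tolerance = 1e-12)
  expect_equal(fab$slope * fba$slope, 1, tolerance = 1e-12)
  expect_equal(fab$r2, fba$r2)
  # slope magnitude is the sd ratio regardless of correlation strength
  expect_equal(abs(fab$slope), sd(b) / sd(a), tolerance = 1e-12)

  set.seed(2)
  big <- sma_fit(rnorm(1e4), rnorm(1e4))
  expect_lt(big$r2, 0.01)

  expect_error(sma_fit(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(sma_fit(1:2, 2:3), ">= 3")
})

make_blue_fixture <- function(n_genotypes = 30, conds, seed = 5,
                              trait = "Seedyield") {
  set.seed(seed)
  g <- rnorm(n_genotypes, 80, 6)
  rows <- lapply(seq_along(conds), function(i) {
    tibble::tibble(genotype = sprintf("G%02d", 1:n_genotypes),
                   condition = conds[i], trait = trait,
                   blue = g + rnorm(1, 0, 5) +
                     rnorm(n_genotypes, 0, 4),
                   fallback = "none")
  })
  out <- dplyr::bind_rows(rows)
  cbind(split_condition_key(out$condition)[, c("year", "location",
                                               "management")], out)
}

test_that("pairwise consistency yields C(k,2) pairs and pairwise-complete n", {
  conds <- condition_key(rep(2015:2017, each = 3),
                         rep(c("GGE", "HAN", "KAL"), 3), "HN_WF_RF")
  bt <- make_blue_fixture(conds = conds)
  pairs <- pairwise_consistency(bt, "Seedyield")
  expect_equal(nrow(pairs), choose(9, 2))
  expect_true(all(pairs$n == 30))
  # drop one genotype from one condition: its pairs lose one observation
  bt2 <- bt[!(bt$condition == conds[1] & bt$genotype == "G01"), ]
  p2 <- pairwise_consistency(bt2, "Seedyield")
  touched <- p2$condition_a == conds[1] | p2$condition_b == conds[1]
  expect_true(all(p2$n[touched] == 29))
  expect_true(all(p2$n[!touched] == 30))
  # r2 equals squared Pearson correlation of the shared BLUEs
  a <- bt$blue[bt$condition == conds[1]]
  b <- bt$blue[bt$condition == conds[2]]
  expect_equal(pairs$r2_sma[1], cor(a, b)^2, tolerance = 1e-12)
})

test_that("two conditions give exactly one pair", {
  bt <- make_blue_fixture(conds = condition_key(2015:2016, "GGE",
                                                "HN_WF_RF"))
  expect_equal(nrow(pairwise_consistency(bt, "Seedyield")), 1L)
})

test_that("grouping keeps pairs agreeing on every fixed factor", {
  conds <- condition_key(rep(2015:2016, each = 4),
                         rep(c("GGE", "HAN"), each = 2, times = 2),
                         rep(c("HN_WF_RF", "LN_NF_RF"), 4))
  bt <- make_blue_fixture(conds = conds, seed = 6)
  pairs <- pairwise_consistency(bt, "Seedyield")
  pooled <- group_pairs(pairs)
  expect_true(all(pooled$level == "all"))
  expect_equal(nrow(pooled), nrow(pairs))

  by_m <- group_pairs(pairs, "management")
  # within one management: 4 conditions -> 6 pairs, two managements
  expect_equal(nrow(by_m), 12L)
  expect_setequal(unique(by_m$level), c("HN_WF_RF", "LN_NF_RF"))
  # a mixed-management pair is dropped from that grouping
  a <- split_condition_key(pairs$condition_a)$management
  b <- split_condition_key(pairs$condition_b)$management
  expect_equal(sum(a == b), nrow(by_m))

  # double grouping keys on the level combination; pairs differ in the
  # remaining factor only
  by_ml <- group_pairs(pairs, c("management", "location"))
  expect_equal(nrow(by_ml), 4L)  # 2 mgmt x 2 loc, one year-pair each
  expect_setequal(unique(by_ml$level),
                  c("HN_WF_RF-GGE", "HN_WF_RF-HAN",
                    "LN_NF_RF-GGE", "LN_NF_RF-HAN"))

  # grouped multisets are subsets of the pooled multiset, no double count
  expect_lte(nrow(by_m), nrow(pairs))
  expect_true(all(by_m$r2_sma %in% pairs$r2_sma))
})

test_that("ANOVA gate and Fisher LSD letters behave on constructed groups", {
  # identical groups: gate closed, shared letter
  same <- list(a = c(0.4, 0.5, 0.45), b = c(0.4, 0.5, 0.45))
  res <- anova_lsd(same)
  expect_gt(res$anova_p, 0.05)
  expect_identical(unname(res$letters), c("a", "a"))

  # separated groups: closed-form F oracle and distinct letters
  g1 <- rep(0, 4); g2 <- rep(10, 4)
  # one-way F computed from first principles
  gm <- mean(c(g1, g2))
  ssb <- 4 * (mean(g1) - gm)^2 + 4 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  expect_equal(ssw, 0)
  sep <- anova_lsd(list(lo = g1 + rnorm(4, 0, 1e-3),
                        hi = g2 + rnorm(4, 0, 1e-3)))
  expect_lt(sep$anova_p, 1e-6)
  expect_setequal(unname(sep$letters), c("a", "b"))
  expect_identical(names(sort(sep$letters)), c("hi", "lo"))  # "a" = top mean

  # overlapping middle group: a / ab / b, verified against pairwise-t oracle
  set.seed(18)
  lo <- rnorm(8, 0, 1); mid <- rnorm(8, 1.1, 1); hi <- rnorm(8, 2.2, 1)
  res3 <- anova_lsd(list(lo = lo, mid = mid, hi = hi))
  y <- c(lo, mid, hi)
  g <- rep(c("lo", "mid", "hi"), each = 8)
  mse <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / (24 - 3)
  pair_p <- function(u, v) {
    t <- (mean(u) - mean(v)) / sqrt(mse * (1 / 8 + 1 / 8))
    2 * pt(-abs(t), 21)
  }
  expect_lt(pair_p(lo, hi), 0.05)
  expect_gt(pair_p(lo, mid), 0.05)
  expect_gt(pair_p(mid, hi), 0.05)
  expect_identical(res3$letters[["hi"]], "a")
  expect_identical(res3$letters[["mid"]], "ab")
  expect_identical(res3$letters[["lo"]], "b")
})

test_that("levels with < 2 values are excluded with a warning", {
  expect_warning(res <- anova_lsd(list(a = c(1, 2), b = c(4, 5),
                                       c = 3)),
                 "excluded")
  expect_length(res$letters, 2L)
})

test_that("summarise_consistency reports max/mean/min and letters", {
  conds <- condition_key(rep(2015:2017, each = 2), rep(c("GGE", "HAN"), 3),
                         "HN_WF_RF")
  bt <- make_blue_fixture(conds = conds, seed = 8)
  pairs <- pairwise_consistency(bt, "Seedyield")
  sm <- suppressWarnings(summarise_consistency(group_pairs(pairs, "year")))
  expect_true(all(sm$max >= sm$mean & sm$mean >= sm$min))
  expect_equal(sum(sm$n_pairs), 3L)  # one within-year pair per year
})
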