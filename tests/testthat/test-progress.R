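make_bp_fixture <- function(slope = 0.37, n = 50, noise = 0, seed = 1,
                            condition = "2015/HAN/HN_WF_RF") {
  set.seed(seed)
  ry <- sample(1963:2013, n, replace = TRUE)
  list(blue = tibble::tibble(
    genotype = sprintf("G%03d", 1:n), year = 2015L, location = "HAN",
    management = "HN_WF_RF", condition = condition, trait = "Seedyield",
    blue = 10 + slope * ry + rnorm(n, 0, noise), fallback = "none"),
    meta = tibble::tibble(genotype = sprintf("G%03d", 1:n),
                          release_year = ry))
}

test_that("noise-free linear BLUEs recover the slope exactly", {
  fx <- make_bp_fixture(slope = 0.37)
  bp <- estimate_bp(fx$blue, fx$meta, "Seedyield", "2015/HAN/HN_WF_RF")
  expect_equal(bp$bp, 0.37, tolerance = 1e-12)
  expect_equal(bp$r2, 1, tolerance = 1e-12)
})

test_that("permuting release years against BLUEs kills the slope", {
  fx <- make_bp_fixture(slope = 0.5, n = 400, noise = 0.1, seed = 2)
  set.seed(3)
  fx$meta$release_year <- sample(fx$meta$release_year)
  bp <- estimate_bp(fx$blue, fx$meta, "Seedyield", "2015/HAN/HN_WF_RF")
  expect_lt(abs(bp$bp), 0.05)
  expect_gt(bp$p_value, 0.001)
})

test_that("BP is scale-equivariant in BLUEs and shift-invariant in years", {
  fx <- make_bp_fixture(slope = 0.2, noise = 1, seed = 4)
  b0 <- estimate_bp(fx$blue, fx$meta, "Seedyield", "2015/HAN/HN_WF_RF")
  fx2 <- fx; fx2$blue$blue <- fx2$blue$blue * 3
  b1 <- estimate_bp(fx2$blue, fx2$meta, "Seedyield", "2015/HAN/HN_WF_RF")
  expect_equal(b1$bp, 3 * b0$bp, tolerance = 1e-12)
  fx3 <- fx; fx3$meta$release_year <- fx3$meta$release_year + 100L
  b2 <- estimate_bp(fx3$blue, fx3$meta, "Seedyield", "2015/HAN/HN_WF_RF")
  expect_equal(b2$bp, b0$bp, tolerance = 1e-10)
})

test_that("degenerate panels error", {
  fx <- make_bp_fixture(n = 10)
  fx$meta$release_year <- 1990L
  expect_error(estimate_bp(fx$blue, fx$meta, "Seedyield",
                           "2015/HAN/HN_WF_RF"), "release years equal")
  expect_error(estimate_bp(fx$blue[1:2, ], fx$meta, "Seedyield",
                           "2015/HAN/HN_WF_RF"), ">= 3")
})

# condition-level BP fixture for the multi-linear decomposition
make_bp_condition_table <- function(n_cond = 24, seed = 10,
                                    beta = c(TGW = 2, Harvest_Index_bio = 50,
                                             Straw = 0.5,
                                             Grain_per_spike_bio = 1,
                                             Spike_number_bio = -0.02),
                                    intercept = 0.1, noise = 0) {
  set.seed(seed)
  conds <- condition_key(rep(2015:2017, length.out = n_cond),
                         rep(c("GGE", "HAN", "KAL", "KIE"),
                             length.out = n_cond),
                         rep(c("HN_WF_RF", "HN_NF_RF", "LN_NF_RF"),
                             each = 8, length.out = n_cond))
  conds <- make.unique(conds)  # guard: fixture must have distinct keys
  stopifnot(!anyDuplicated(conds))
  X <- sapply(names(beta), function(tr) rnorm(n_cond, 0, 1))
  y <- intercept + X %*% beta + rnorm(n_cond, 0, noise)
  long <- rbind(
    data.frame(condition = conds, trait = "Seedyield", bp = as.vector(y)),
    do.call(rbind, lapply(names(beta), function(tr) {
      data.frame(condition = conds, trait = tr, bp = X[, tr])
    })))
  long$p_value <- 0.01; long$r2 <- 0.9; long$n <- 100
  tibble::as_tibble(long)
}

test_that("exact linear combination is recovered with R2 = 1", {
  bp <- make_bp_condition_table()
  fit <- bp_regression(bp)
  all_lv <- fit[fit$level == "all", ]
  expect_equal(all_lv$r2_full[1], 1, tolerance = 1e-10)
  expect_equal(all_lv$estimate[all_lv$term == "TGW"], 2, tolerance = 1e-8)
  expect_equal(all_lv$estimate[all_lv$term == "Harvest_Index_bio"], 50,
               tolerance = 1e-8)
  expect_equal(all_lv$estimate[all_lv$term == "(Intercept)"], 0.1,
               tolerance = 1e-8)
})

test_that("constant regressor is dropped with a warning", {
  bp <- make_bp_condition_table()
  bp$bp[bp$trait == "Straw"] <- 1
  expect_warning(fit <- bp_regression(bp), "constant regressor")
  expect_false("Straw" %in% fit$term)
  expect_true("TGW" %in% fit$term)
})

test_that("grouping levels partition the pooled condition set", {
  bp <- make_bp_condition_table(n_cond = 24, noise = 0.5)
  fit <- bp_regression(bp, grouping = "management")
  lv <- setdiff(unique(fit$level), "all")
  n_all <- fit$n_conditions[fit$level == "all"][1]
  n_lv <- vapply(lv, function(l) fit$n_conditions[fit$level == l][1], 1)
  expect_equal(sum(n_lv), n_all)
})

test_that("independent regressors give a small R2 consistent with the
           F reference", {
  r2s <- replicate(40, {
    bp <- make_bp_condition_table(n_cond = 40, beta = c(
      TGW = 0, Harvest_Index_bio = 0, Straw = 0, Grain_per_spike_bio = 0,
      Spike_number_bio = 0), noise = 1, seed = sample.int(1e6, 1))
    fit <- bp_regression(bp)
    fit$r2_full[fit$level == "all"][1]
  })
  # under the null, R2 ~ Beta(p/2, (n-p-1)/2): p = 5, n = 40
  expect_lt(mean(r2s), qbeta(0.99, 5 / 2, 34 / 2))
  ks <- suppressWarnings(ks.test(r2s, function(q) pbeta(q, 5 / 2, 34 / 2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("bp_table collects per-cell estimates and skips bad cells", {
  fx <- make_bp_fixture(slope = 0.3, noise = 2, seed = 6)
  b2 <- fx$blue
  b2$condition <- "2016/KIE/HN_WF_RF"
  b2$year <- 2016L; b2$location <- "KIE"
  bt <- rbind(fx$blue, b2)
  out <- bp_table(bt, fx$meta)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$condition, c("2015/HAN/HN_WF_RF", "2016/KIE/HN_WF_RF"))
})
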