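test_that("nine indices match the brute-force oracle on a 5x4 fixture", {
  x <- rand_matrix(5, 4, seed = 123)
  got <- stability_indices(x)
  want <- stability_oracle(x)
  for (col in names(want)) {
    expect_equal(got[[col]], want[[col]], tolerance = 1e-10,
                 ignore_attr = TRUE, label = col)
  }
})

test_that("purely additive matrix has no interaction signal", {
  a <- seq(40, 58, length.out = 10)
  c_ <- seq(-4, 10, length.out = 8)
  x <- outer(a, c_, `+`)
  rownames(x) <- sprintf("g%02d", 1:10)
  st <- stability_indices(x)
  expect_equal(st$W_i, rep(0, 10), tolerance = 1e-18)
  expect_equal(st$s2_di, rep(0, 10), tolerance = 1e-18)
  expect_equal(st$S_i4, rep(0, 10), tolerance = 1e-18)
  expect_equal(st$b_i, rep(1, 10), tolerance = 1e-12)
  expect_equal(st$r2_i, rep(1, 10), tolerance = 1e-12)
  expect_equal(st$D2_i, rep(0, 10), tolerance = 1e-16)
})

test_that("a genotype best in every environment has zero superiority", {
  x <- rand_matrix(6, 5, seed = 7)
  x[3, ] <- apply(x, 2, max) + 5
  st <- stability_indices(x)
  expect_equal(st$P_i[3], 0)
  expect_true(all(st$P_i[-3] > 0))
})

test_that("algebraic identities hold on random matrices", {
  for (s in 1:100) {
    x <- rand_matrix(20, 10, seed = 1000 + s)
    st <- stability_indices(x)
    G <- 20; E <- 10
    inter_ss <- sum((x - rowMeans(x) -
                       rep(colMeans(x), each = G) + mean(x))^2)
    expect_equal(sum(st$W_i), inter_ss, tolerance = 1e-9)
    expect_equal(mean(st$b_i), 1, tolerance = 1e-9)
    expect_equal(mean(st$sigma2_i), inter_ss / ((G - 1) * (E - 1)),
                 tolerance = 1e-9)
  }
})

test_that("location shift changes nothing; scaling acts quadratically or
           not at all", {
  x <- rand_matrix(12, 6, seed = 55)
  st <- stability_indices(x)
  st_shift <- stability_indices(x + 13)
  for (col in setdiff(names(st), "genotype")) {
    expect_equal(st_shift[[col]], st[[col]], tolerance = 1e-9, label = col)
  }
  cc <- 2.5
  st_scale <- stability_indices(x * cc)
  for (col in c("W_i", "s2_di", "S2_xi", "D2_i", "P_i", "sigma2_i")) {
    expect_equal(st_scale[[col]], cc^2 * st[[col]], tolerance = 1e-8,
                 label = col)
  }
  for (col in c("b_i", "r2_i", "S_i4")) {
    expect_equal(st_scale[[col]], st[[col]], tolerance = 1e-9, label = col)
  }
})

test_that("direction metadata: the erratic genotype scores less stable on
           every smaller-is-stabler index", {
  set.seed(9)
  E <- 12
  e <- rnorm(E, 0, 5)
  x <- rbind(stable = 50 + e + rnorm(E, 0, 0.1),
             erratic = 50 + e + rnorm(E, 0, 8),
             filler1 = 48 + e + rnorm(E, 0, 1),
             filler2 = 52 + e + rnorm(E, 0, 1))
  st <- stability_indices(x)
  dir <- si_direction()
  smaller <- dir$index[dir$stable_when == "smaller"]
  expect_setequal(smaller, c("s2_di", "W_i", "sigma2_i", "D2_i", "P_i",
                             "S2_xi", "S_i4"))
  i_stable <- which(st$genotype == "stable")
  i_erratic <- which(st$genotype == "erratic")
  for (col in setdiff(smaller, "P_i")) {
    expect_lt(st[[col]][i_stable], st[[col]][i_erratic])
  }
  expect_equal(nrow(dir), 9L)
})

test_that("trait matrix drops exactly the incomplete genotypes", {
  conds <- condition_key(2015:2018, "HAN", "HN_WF_RF")
  bt <- expand.grid(genotype = sprintf("G%02d", 1:6), condition = conds,
                    stringsAsFactors = FALSE)
  set.seed(4)
  bt$trait <- "Seedyield"
  bt$blue <- rnorm(nrow(bt), 80, 5)
  bt <- tibble::as_tibble(bt)
  m0 <- suppressMessages(build_trait_matrix(bt, "Seedyield"))
  expect_equal(dim(m0), c(6L, 4L))
  expect_identical(rownames(m0), sort(unique(bt$genotype)))
  bt2 <- bt[!(bt$genotype == "G03" & bt$condition == conds[2]), ]
  expect_message(m1 <- build_trait_matrix(bt2, "Seedyield"), "1 genotype")
  expect_identical(rownames(m1), setdiff(rownames(m0), "G03"))
  expect_error(build_trait_matrix(bt[bt$condition %in% conds[1:2], ],
                                  "Seedyield"), ">= 3 conditions")
})

test_that("minimal sizes: E = 2 leaves s2_di undefined, G = 2 errors", {
  x <- rand_matrix(4, 2, seed = 2)
  st <- stability_indices(x)
  expect_true(all(is.na(st$s2_di)))
  expect_true(all(is.finite(st$W_i)))
  expect_error(stability_indices(rand_matrix(2, 5, seed = 2)), "G >= 3")
})

test_that("TFI regressor: mean mode equals a direct column mean", {
  conds <- condition_key(2015:2017, "HAN", "HN_WF_RF")
  bt <- expand.grid(genotype = sprintf("G%02d", 1:5), condition = conds,
                    stringsAsFactors = FALSE)
  set.seed(12)
  bt$trait <- "TFI"
  bt$blue <- runif(nrow(bt), 0, 40)
  bt <- tibble::as_tibble(bt)
  v <- tfi_regressor(bt, genotypes = sprintf("G%02d", 1:5))
  direct <- tapply(bt$blue, bt$genotype, mean)
  expect_equal(as.numeric(v), as.numeric(direct[names(v)]),
               tolerance = 1e-12)

  # constant TFI everywhere -> constant regressor
  bt$blue <- 5
  v5 <- tfi_regressor(bt, genotypes = sprintf("G%02d", 1:5))
  expect_true(all(v5 == 5))

  # SI mode on an additive TFI matrix with ecovalence -> all zeros
  add <- expand.grid(genotype = sprintf("G%02d", 1:5), condition = conds,
                     stringsAsFactors = FALSE)
  add$trait <- "TFI"
  add$blue <- as.numeric(factor(add$genotype)) * 2 +
    as.numeric(factor(add$condition))
  v0 <- tfi_regressor(tibble::as_tibble(add),
                      genotypes = sprintf("G%02d", 1:5),
                      mode = "si_of_tfi", si_name = "W_i")
  expect_equal(unname(v0), rep(0, 5), tolerance = 1e-18)
})

test_that("stability-of-yield regression recovers an exact combination", {
  set.seed(20)
  n <- 60
  tabs <- list()
  for (tr in c("TGW", "Harvest_Index_bio", "Straw")) {
    tabs[[tr]] <- tibble::tibble(genotype = sprintf("G%03d", 1:n),
                                 W_i = runif(n, 0, 10))
  }
  tfi <- setNames(runif(n, 0, 30), sprintf("G%03d", 1:n))
  resp <- tibble::tibble(
    genotype = sprintf("G%03d", 1:n),
    W_i = 1 + 2 * tabs$TGW$W_i + 0.5 * tabs$Harvest_Index_bio$W_i -
      1.5 * tabs$Straw$W_i + 0.1 * tfi)
  tabs$Seedyield <- resp
  fit <- si_regression(tabs, "W_i", tfi = tfi)
  expect_equal(fit$r2_full[1], 1, tolerance = 1e-10)
  expect_equal(fit$estimate[fit$term == "TGW"], 2, tolerance = 1e-8)
  expect_equal(fit$estimate[fit$term == "TFI"], 0.1, tolerance = 1e-8)
  expect_equal(fit$estimate[fit$term == "(Intercept)"], 1,
               tolerance = 1e-8)
})

test_that("permuted response gives a null-consistent R2 across the nine
           indices", {
  set.seed(30)
  n <- 100
  mk <- function() {
    x <- rand_matrix(n, 8, seed = sample.int(1e6, 1))
    stability_indices(x)
  }
  tabs <- list(Seedyield = mk(), TGW = mk(), Harvest_Index_bio = mk())
  fits <- lapply(si_direction()$index, function(si) {
    si_regression(tabs, si)
  })
  expect_length(fits, 9L)
  r2 <- vapply(fits, function(f) f$r2_full[1], 1)
  # p = 2 regressors, n = 100: null 99th percentile of R2
  expect_lt(max(r2), qbeta(0.999, 2 / 2, 97 / 2))
})
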