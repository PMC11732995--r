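# Independent oracles, written as plain elementwise loops so they share no
# code path with the vectorized implementations they check.

# nine stability indices by direct summation
stability_oracle <- function(x) {
  G <- nrow(x); E <- ncol(x)
  xi <- numeric(G); for (i in 1:G) xi[i] <- mean(x[i, ])
  xj <- numeric(E); for (j in 1:E) xj[j] <- mean(x[, j])
  xg <- mean(x)
  e <- xj - xg
  see <- sum(e^2)
  b <- s2d <- r2 <- W <- D2 <- P <- S2x <- S4 <- numeric(G)
  for (i in 1:G) {
    num <- 0
    for (j in 1:E) num <- num + (x[i, j] - xi[i]) * e[j]
    b[i] <- num / see
  }
  bmin <- min(b)
  Mj <- numeric(E); for (j in 1:E) Mj[j] <- max(x[, j])
  rk <- matrix(0, G, E)
  for (j in 1:E) rk[, j] <- rank(x[, j] - xi + xg)
  for (i in 1:G) {
    ssd <- ssw <- ssD <- ssP <- ssrow <- 0
    for (j in 1:E) {
      ssd <- ssd + (x[i, j] - xi[i] - b[i] * e[j])^2
      ssw <- ssw + (x[i, j] - xi[i] - xj[j] + xg)^2
      ssD <- ssD + (x[i, j] - xi[i] - bmin * e[j])^2
      ssP <- ssP + (x[i, j] - Mj[j])^2
      ssrow <- ssrow + (x[i, j] - xi[i])^2
    }
    s2d[i] <- ssd / (E - 2)
    W[i] <- ssw
    D2[i] <- ssD
    P[i] <- ssP / (2 * E)
    S2x[i] <- ssrow / (E - 1)
    r2[i] <- b[i]^2 * see / ssrow
    mr <- mean(rk[i, ])
    s4 <- 0
    for (j in 1:E) s4 <- s4 + (rk[i, j] - mr)^2
    S4[i] <- s4 / (E - 1)
  }
  sig2 <- numeric(G)
  for (i in 1:G) {
    sig2[i] <- (G * (G - 1) * W[i] - sum(W)) / ((G - 1) * (G - 2) * (E - 1))
  }
  data.frame(b_i = b, s2_di = s2d, r2_i = r2, W_i = W, sigma2_i = sig2,
             D2_i = D2, P_i = P, S2_xi = S2x, S_i4 = S4)
}

# LMG by brute-force averaging of sequential R2 gains over all orderings
lmg_perm_oracle <- function(y, X) {
  X <- as.data.frame(X)
  p <- ncol(X)
  r2_of <- function(cols) {
    if (!length(cols)) return(0)
    summary(lm(y ~ ., data = X[, cols, drop = FALSE]))$r.squared
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  shares <- setNames(numeric(p), names(X))
  all_p <- perms(seq_len(p))
  for (ord in all_p) {
    for (k in seq_len(p)) {
      before <- ord[seq_len(which(ord == k) - 1)]
      shares[k] <- shares[k] + r2_of(c(before, k)) - r2_of(before)
    }
  }
  shares / length(all_p)
}

# a reproducible random G x E matrix with named rows/cols
rand_matrix <- function(G, E, seed) {
  set.seed(seed)
  matrix(rnorm(G * E, 50, 10), G, E,
         dimnames = list(sprintf("g%02d", 1:G), sprintf("e%02d", 1:E)))
}

# 30-plot single-condition toy table with three planted QC violations:
# one TGW of 85 g, one negative yield, one harvest index far above its
# condition mean
make_toy_qc_table <- function() {
  set.seed(99)
  n <- 30
  hi <- rnorm(n, 0.5, 0.015)
  hi[7] <- mean(hi[-7]) + 8 * sd(hi[-7])
  tgw <- rnorm(n, 45, 2); tgw[3] <- 85
  gy <- rnorm(n, 80, 5); gy[12] <- -4
  base <- data.frame(genotype = sprintf("G%02d", 1:n), release_year = 1990L,
                     year = 2015L, location = "HAN",
                     management = "HN_WF_RF",
                     replicate = 1L, row = 1:n, col = 1L)
  as_plot_records(rbind(
    cbind(base, trait = "TGW", value = tgw),
    cbind(base, trait = "Seedyield", value = gy),
    cbind(base, trait = "Harvest_Index_bio", value = hi)))
}
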