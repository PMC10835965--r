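# Independent oracles used to validate the package's statistics. These are
# deliberately naive implementations (term-by-term summation, series
# expansions, explicit enumeration) kept separate from the code paths they
# check.

# upper-tail binomial P[X >= x] by term-by-term log-space summation
oracle_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  k <- x:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# chi-square survival for even df via the closed-form Poisson series:
# P[X > x] = exp(-x/2) * sum_{j=0}^{df/2-1} (x/2)^j / j!
oracle_chisq_sf_even <- function(x, df) {
  stopifnot(df %% 2 == 0)
  j <- 0:(df / 2 - 1)
  sum(exp(-x / 2 + j * log(x / 2) - lfactorial(j)))
}

# Benjamini-Hochberg by explicit step-up enumeration
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force reimplementation of the full assignment decision rule
oracle_assign <- function(guide_counts, library, alpha = 0.001,
                          umi_floor = 3) {
  m <- as.matrix(guide_counts)
  prop <- library$proportion / sum(library$proportion)
  names(prop) <- library$guide_id
  n_family <- nrow(library)
  out <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (j in seq_len(ncol(m))) {
    n_c <- sum(m[, j])
    if (n_c == 0) next
    for (i in seq_len(nrow(m))) {
      x <- m[i, j]
      if (x == 0) next
      p <- oracle_binom_tail(x, n_c, prop[rownames(m)[i]])
      out[i, j] <- (min(1, p * n_family) < alpha) && (x > umi_floor)
    }
  }
  out
}

# maximum-likelihood fit of the two-part model by a generic optimizer,
# maximizing the same penalized objective as the package (ridge 1e-6 on
# the logistic guide coefficients; Gaussian part by profile likelihood)
oracle_hurdle_lr <- function(X_full, X_red, pen_full, pen_red, y, v,
                             lambda = 1e-6) {
  nll_logit <- function(beta, X, pen) {
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -(sum(y * log(mu) + (1 - y) * log(1 - mu)) -
        0.5 * lambda * sum(beta[pen]^2))
  }
  fit_logit <- function(X, pen) {
    o <- stats::optim(numeric(ncol(X)), nll_logit, X = X, pen = pen,
                      method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
    -o$value
  }
  idx <- which(y == 1)
  rss <- function(X) {
    f <- stats::lm.fit(X[idx, , drop = FALSE], v[idx])
    sum(f$residuals^2)
  }
  lr_disc <- 2 * (fit_logit(X_full, pen_full) - fit_logit(X_red, pen_red))
  lr_cont <- length(idx) * log(rss(X_red) / rss(X_full))
  c(disc = lr_disc, cont = lr_cont)
}

# textbook (normal-approximation, tie-corrected) rank-sum statistic
oracle_ranksum_z <- function(x1, x2) {
  x <- c(x1, x2)
  n1 <- length(x1); n2 <- length(x2); n <- n1 + n2
  r <- rank(x)
  w <- sum(r[seq_len(n1)])
  e <- n1 * (n + 1) / 2
  ties <- table(x)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  (w - e) / sqrt(v)
}
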