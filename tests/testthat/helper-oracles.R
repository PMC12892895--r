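# Independent reference implementations used as oracles. These are written
# straight from the published formulas / definitions and share no code with
# the package internals they check.

# --- TMM: doubly trimmed, precision-weighted mean of M-values -------------
oracle_tmm <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- vapply(seq_len(ncol(counts)),
               function(j) stats::quantile(counts[, j], 0.75), numeric(1)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  one_factor <- function(j) {
    obs <- as.numeric(counts[, j])
    rf <- as.numeric(counts[, ref])
    nO <- lib[j]
    nR <- lib[ref]
    M <- log2((obs / nO) / (rf / nR))
    A <- (log2(obs / nO) + log2(rf / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - rf) / (nR * rf) # binomial asymptotic var
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; v <- v[fin]
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

# --- AUC: exhaustive pairwise Mann-Whitney comparison ---------------------
oracle_auc <- function(scores, is_case) {
  pos <- scores[is_case]
  neg <- scores[!is_case]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# --- Benjamini-Hochberg step-up, from the definition ----------------------
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  adj <- p[ord] * m / seq_len(m)
  # enforce monotonicity from the largest rank downwards
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  q[ord] <- pmin(adj, 1)
  q
}

# --- two-sided Fisher exact p by hypergeometric enumeration ---------------
oracle_fisher2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- L1-penalized logistic regression by IRLS + coordinate descent --------
# Minimizes (1/n) sum[log(1+exp(eta)) - y*eta] + lambda*||beta_std||_1 with
# predictors standardized by their 1/n-variance SD (glmnet's convention),
# then back-transforms to the original scale.
oracle_lasso_logistic <- function(x, y, lambda, n_outer = 200, tol = 1e-12) {
  n <- nrow(x)
  xm <- colMeans(x)
  xs <- sqrt(colMeans(x^2) - xm^2)
  xstd <- sweep(sweep(x, 2, xm), 2, xs, "/")
  b0 <- stats::qlogis(mean(y))
  beta <- rep(0, ncol(x))
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (outer in seq_len(n_outer)) {
    beta_old_outer <- c(b0, beta)
    eta <- as.numeric(b0 + xstd %*% beta)
    pr <- 1 / (1 + exp(-eta))
    w <- pmax(pr * (1 - pr), 1e-9)
    z <- eta + (y - pr) / w
    for (inner in seq_len(1000)) {
      maxdelta <- 0
      r <- z - b0 - as.numeric(xstd %*% beta)
      new_b0 <- b0 + sum(w * r) / sum(w)
      maxdelta <- max(maxdelta, abs(new_b0 - b0))
      r <- r - (new_b0 - b0)
      b0 <- new_b0
      for (j in seq_len(ncol(x))) {
        xj <- xstd[, j]
        num <- sum(w * xj * r) / n + sum(w * xj^2) * beta[j] / n
        new_bj <- soft(num, lambda) / (sum(w * xj^2) / n)
        if (new_bj != beta[j]) {
          r <- r - xj * (new_bj - beta[j])
          maxdelta <- max(maxdelta, abs(new_bj - beta[j]))
          beta[j] <- new_bj
        }
      }
      if (maxdelta < tol) break
    }
    if (max(abs(c(b0, beta) - beta_old_outer)) < 1e-10) break
  }
  list(intercept = b0 - sum(beta * xm / xs), beta = beta / xs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- greedy caliper matching by explicit scan -----------------------------
oracle_greedy_match <- function(lp_case, lp_ctrl, caliper_abs) {
  used <- character(0)
  pairs <- list()
  for (cid in names(sort(lp_case, decreasing = TRUE))) {
    best <- NA_character_
    best_d <- Inf
    for (kid in sort(setdiff(names(lp_ctrl), used))) {
      d <- abs(lp_ctrl[kid] - lp_case[cid])
      if (d <= caliper_abs && d < best_d) {
        best <- kid
        best_d <- d
      }
    }
    if (!is.na(best)) {
      used <- c(used, best)
      pairs[[cid]] <- best
    }
  }
  pairs
}
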