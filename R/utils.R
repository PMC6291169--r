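# Internal helpers: seeding, validation, fast mass OLS.

# Deterministically derive a 32-bit sub-seed from a base seed and a stage tag.
# Keeps per-stage RNG streams reproducible without reusing the same seed.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_oscdev <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    stop_oscdev("'%s' must be a single finite number in [%g, %g]", name, lo, hi)
  x
}

# OLS of each column of Y (n x m) on design X (n x k); returns beta, se, t, p
# for the coefficient in column `which` of X. Vectorised across responses.
mass_ols <- function(Y, X, which = 2L) {
  Y <- as.matrix(Y)
  n <- nrow(X); k <- ncol(X)
  if (nrow(Y) != n) stop_oscdev("design and response row counts differ")
  if (n <= k) stop_oscdev("need more observations (%d) than regressors (%d)", n, k)
  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop_oscdev("rank-deficient design; collinear columns: %s",
                paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, Y)                       # k x m
  res <- Y - X %*% coefs
  df <- n - k
  sigma2 <- colSums(res^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))[which]
  beta <- coefs[which, ]
  se <- sqrt(sigma2 * xtx_inv_diag)
  # responses that are (numerically) perfectly fit carry no evidence:
  # report beta 0, p 1 rather than a 0/0 t statistic
  scale2 <- colMeans(Y^2) + 1e-300
  degenerate <- sigma2 <= scale2 * 1e-20
  tval <- ifelse(se > 0, beta / se, 0)
  pval <- 2 * pt(-abs(tval), df)
  if (any(degenerate)) {
    zero_beta <- degenerate & abs(beta) < sqrt(scale2) * 1e-8
    beta[zero_beta] <- 0
    tval[zero_beta] <- 0
    pval[zero_beta] <- 1
  }
  list(beta = beta, se = se, t = tval, p = pval, df = df)
}

# Upper-triangle (i < j) index pairs for an n x n symmetric matrix.
# Column-major order, i.e. the same order as m[upper.tri(m)].
ut_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx
}

# Flatten symmetric matrices (list or 3d array [i, j, subject]) into a
# subjects x edges matrix following ut_pairs() order.
edges_from_matrices <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3L) {
    n <- dim(mats)[1]
    idx <- upper.tri(diag(n))
    t(apply(mats, 3, function(m) m[idx]))
  } else {
    n <- nrow(mats[[1]])
    idx <- upper.tri(diag(n))
    do.call(rbind, lapply(mats, function(m) m[idx]))
  }
}
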