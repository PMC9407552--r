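# Independent oracle implementations used to cross-check the package.
# These are deliberately naive (loops, lm, enumeration) and share no code
# with the implementations they verify.

# PLS1 by NIPALS on mean-centered data; returns slope vector and intercept.
nipals_pls1 <- function(X, y, A) {
  X <- as.matrix(X)
  xm <- colMeans(X); ym <- mean(y)
  E <- sweep(X, 2, xm); f <- y - ym
  W <- NULL; P <- NULL; Q <- numeric(0)
  for (a in seq_len(A)) {
    w <- crossprod(E, f); w <- w / sqrt(sum(w^2))
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    q <- sum(f * t) / sum(t^2)
    E <- E - t %*% t(p)
    f <- f - q * t
    W <- cbind(W, w); P <- cbind(P, p); Q <- c(Q, q)
  }
  B <- W %*% solve(crossprod(P, W), Q)
  list(coefficients = as.vector(B), intercept = ym - sum(xm * B))
}

# Savitzky-Golay by explicit per-window polynomial least squares (truncated
# windows at the edges), evaluated at the target point.
naive_savgol_row <- function(x, frame, order) {
  K <- length(x)
  h <- (frame - 1) %/% 2
  out <- numeric(K)
  for (j in seq_len(K)) {
    win <- max(1, j - h):min(K, j + h)
    z <- win - j
    deg <- min(order, length(win) - 1)
    fit <- stats::lm(x[win] ~ stats::poly(z, deg, raw = TRUE))
    out[j] <- unname(stats::predict(fit, data.frame(z = 0)))
  }
  out
}

# SPXY by direct loops: normalized joint distances, lexicographic-first
# max pair, then max-min growth with lowest-index tie-breaking. Operates in
# canonical (sorted id) order like the implementation under test.
naive_spxy_order <- function(X, y, n_cal) {
  n <- nrow(X)
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    dx[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    dy[i, j] <- abs(y[i] - y[j])
  }
  d <- 0
  if (max(dx) > 0) d <- d + dx / max(dx)
  if (max(dy) > 0) d <- d + dy / max(dy)
  best <- -Inf; pair <- c(1L, 2L)
  for (j in 1:(n - 1)) for (i in (j + 1):n) {
    if (d[j, i] > best) { best <- d[j, i]; pair <- c(j, i) }
  }
  sel <- pair
  while (length(sel) < n_cal) {
    best <- -Inf; nxt <- NA
    for (c in setdiff(1:n, sel)) {
      m <- min(d[c, sel])
      if (m > best) { best <- m; nxt <- c }
    }
    sel <- c(sel, nxt)
  }
  sel
}

# One SPA chain by repeated least-squares residual projection (qr-based),
# on the column-centered matrix.
naive_spa_chain <- function(X, start, n_max) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  chain <- start
  for (step in seq_len(n_max - 1)) {
    S <- Xc[, chain, drop = FALSE]
    best <- -1; nxt <- NA
    for (c in seq_len(ncol(Xc))) {
      if (c %in% chain) next
      res <- stats::lm.fit(S, Xc[, c])$residuals
      if (sum(res^2) > best + 1e-12) { best <- sum(res^2); nxt <- c }
    }
    chain <- c(chain, nxt)
  }
  chain
}

# Random spectra-like matrix and response.
rand_problem <- function(n, p, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), y = rnorm(n))
}

# Small spectra_set around random data.
rand_spectra <- function(n, p, seed, wl = seq(500, by = 2, length.out = p)) {
  set.seed(seed)
  spectra_set(wl, matrix(abs(rnorm(n * p, 1, 0.2)), n, p),
              sprintf("S%02d", seq_len(n)))
}
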