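# Independent brute-force implementations used as oracles. These are kept
# deliberately naive (explicit loops, no shared code with the package) so
# they exercise the formulas, not the implementation under test.

oracle_descriptors <- function(s, f, s_prev = NULL) {
  N <- length(s)
  tot <- 0
  for (k in 1:N) tot <- tot + s[k]
  p <- numeric(N)
  for (k in 1:N) p[k] <- s[k] / tot
  mu <- 0
  for (k in 1:N) mu <- mu + f[k] * p[k]
  v <- 0
  for (k in 1:N) v <- v + (f[k] - mu)^2 * p[k]
  spread <- sqrt(v)
  if (spread > 1e-12) {
    m3 <- 0; m4 <- 0
    for (k in 1:N) {
      m3 <- m3 + (f[k] - mu)^3 * p[k]
      m4 <- m4 + (f[k] - mu)^4 * p[k]
    }
    skew <- m3 / spread^3
    kurt <- m4 / spread^4
  } else {
    skew <- 0; kurt <- 0
  }
  ent <- 0
  for (k in 1:N) if (p[k] > 0) ent <- ent - p[k] * log(p[k])
  ent <- if (N > 1) ent / log(N) else 0
  gm <- 1
  for (k in 1:N) gm <- gm * s[k]^(1 / N)
  flat <- gm / (tot / N)
  crest <- max(s) / (tot / N)
  flux <- 0
  if (!is.null(s_prev)) {
    for (k in 1:N) flux <- flux + (s[k] - s_prev[k])^2
    flux <- sqrt(flux)
  }
  fbar <- mean(f); sbar <- tot / N
  num <- 0; den <- 0
  for (k in 1:N) {
    num <- num + (f[k] - fbar) * (s[k] - sbar)
    den <- den + (f[k] - fbar)^2
  }
  slope <- num / den
  dn <- 0; dd <- 0
  for (k in 2:N) {
    dn <- dn + (s[k] - s[1]) / (k - 1)
    dd <- dd + s[k]
  }
  decrease <- if (dd > 0) dn / dd else 0
  cum <- 0; roll <- f[N]
  for (k in 1:N) {
    cum <- cum + p[k]
    if (cum >= 0.95 - 1e-12) { roll <- f[k]; break }
  }
  c(centroid = mu, spread = spread, skewness = skew, kurtosis = kurt,
    entropy = ent, flatness = flat, crest = crest, flux = flux,
    slope = slope, decrease = decrease, rolloff = roll)
}

# Exact best rank-d affine reconstruction error via truncated SVD of the
# centered data (a linear autoencoder with biases realizes exactly this
# model class).
oracle_rank_d_mse <- function(X, d) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  Xd <- sv$u[, 1:d, drop = FALSE] %*% diag(sv$d[1:d], d) %*%
    t(sv$v[, 1:d, drop = FALSE])
  mean((Xc - Xd)^2)
}

# Plugin mutual information computed from an explicit contingency loop.
oracle_mi <- function(x, y) {
  n <- length(x)
  ux <- unique(x); uy <- unique(y)
  mi <- 0
  for (a in ux) for (b in uy) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) mi <- mi + pxy * log2(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
  }
  mi
}
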