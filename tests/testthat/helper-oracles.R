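# Independent brute-force oracles used to pin down expected values.
# These deliberately re-derive each quantity from its definition with
# plain loops, separate from the package's implementations.

oracle_kendall <- function(x, y) {
  n <- length(x)
  P <- Q <- Tx <- Uy <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) next      # tied in both: excluded from T and U
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Uy <- Uy + 1
    else if (sign(dx) == sign(dy)) P <- P + 1
    else Q <- Q + 1
  }
  (P - Q) / sqrt((P + Q + Tx) * (P + Q + Uy))
}

oracle_js <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + 0.5 * p[i] * log2(p[i] / m[i])
    if (q[i] > 0) s <- s + 0.5 * q[i] * log2(q[i] / m[i])
  }
  s
}

oracle_ssim <- function(x, y, L) {
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  (2 * mx * my + C1) * (2 * cxy + C2) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
}

oracle_ch <- function(X, labels) {
  cl <- unique(labels); k <- length(cl); n <- nrow(X)
  gc_ <- colMeans(X)
  bcss <- 0; wcss <- 0
  for (c in cl) {
    sub <- X[labels == c, , drop = FALSE]
    ci <- colMeans(sub)
    bcss <- bcss + nrow(sub) * sum((ci - gc_)^2)
    for (r in seq_len(nrow(sub))) wcss <- wcss + sum((sub[r, ] - ci)^2)
  }
  (bcss / (k - 1)) / (wcss / (n - k))
}

oracle_weighted_f1 <- function(yt, yp) {
  s <- 0
  for (c in unique(yt)) {
    tp <- sum(yt == c & yp == c); fp <- sum(yt != c & yp == c)
    fn <- sum(yt == c & yp != c)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    s <- s + f1 * sum(yt == c) / length(yt)
  }
  s
}

# One EM iteration of coordinate-space CPD written straight from the
# update equations (init W = 0, posterior, linear solve, variance).
oracle_cpd_step <- function(X, Y, beta, lambda, w = 0) {
  M <- nrow(Y); N <- nrow(X); D <- ncol(Y)
  sigma2 <- 0
  for (m in 1:M) for (n in 1:N) sigma2 <- sigma2 + sum((X[n, ] - Y[m, ])^2)
  sigma2 <- sigma2 / (D * M * N)
  G <- matrix(0, M, M)
  for (i in 1:M) for (j in 1:M)
    G[i, j] <- exp(-sum((Y[i, ] - Y[j, ])^2) / (2 * beta^2))
  P <- matrix(0, M, N)
  for (n in 1:N) {
    num <- vapply(1:M, function(m)
      exp(-sum((X[n, ] - Y[m, ])^2) / (2 * sigma2)), 0)
    cc <- (2 * pi * sigma2)^(D / 2) * w / (1 - w) * M / N
    P[, n] <- num / (sum(num) + cc)
  }
  P1 <- rowSums(P)
  A <- G + lambda * sigma2 * diag(1 / P1)
  rhs <- diag(1 / P1) %*% P %*% X - Y
  W <- solve(A, rhs)
  TY <- Y + G %*% W
  Np <- sum(P)
  s2 <- (sum(diag(t(X) %*% diag(colSums(P)) %*% X)) -
           2 * sum(diag(t(P %*% X) %*% TY)) +
           sum(diag(t(TY) %*% diag(P1) %*% TY))) / (Np * D)
  list(P = P, W = W, sigma2 = s2)
}

oracle_weighted_average <- function(W, X) {
  out <- matrix(0, nrow(W), ncol(X))
  for (i in seq_len(nrow(W))) {
    num <- rep(0, ncol(X)); den <- 0
    for (j in seq_len(ncol(W))) {
      num <- num + W[i, j] * X[j, ]
      den <- den + W[i, j]
    }
    out[i, ] <- num / den
  }
  out
}

# Small deterministic slide for I/O-level tests.
tiny_slide <- function(n = 6, g = 10, seed = 42, patches = FALSE) {
  set.seed(seed)
  counts <- matrix(rpois(n * g, 5), n, g)
  coords <- cbind(runif(n, 0, 500), runif(n, 0, 500))
  p <- if (patches)
    lapply(seq_len(n), function(i) array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3)))
  else NULL
  spot_slide(sprintf("BC%02d", seq_len(n)), coords, counts,
             sprintf("G%02d", seq_len(g)), p)
}
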