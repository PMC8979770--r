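# Independent straight-line reference implementations used as oracles.
# Deliberately written with explicit loops from the defining formulas and
# sharing no code with the package.

oracle_kernel <- function(X, alpha, K) {
  n <- nrow(X)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  dbar <- numeric(n)
  for (i in 1:n) dbar[i] <- mean(sort(d[i, -i])[1:K])
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    eps <- (dbar[i] + dbar[j] + d[i, j]) / 3
    W[i, j] <- exp(-d[i, j]^2 / (alpha * eps^2))
  }
  (W + t(W)) / 2
}

oracle_P <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in 1:n) {
    s <- sum(W[i, -i])
    for (j in 1:n) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * s)
  }
  P
}

oracle_S <- function(W, K) {
  n <- nrow(W)
  S <- matrix(0, n, n)
  for (i in 1:n) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(w, decreasing = TRUE)[1:K]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

# full fusion from raw feature matrices
oracle_snf <- function(X_list, alpha, K, Tt) {
  m <- length(X_list)
  Ws <- lapply(X_list, oracle_kernel, alpha = alpha, K = K)
  Ps <- lapply(Ws, oracle_P)
  Ss <- lapply(Ws, oracle_S, K = K)
  if (m == 1) return(Ps[[1]])
  n <- nrow(Ps[[1]])
  for (t in 1:Tt) {
    Pn <- vector("list", m)
    for (h in 1:m) {
      avg <- matrix(0, n, n)
      for (k in setdiff(1:m, h)) avg <- avg + Ps[[k]]
      avg <- avg / (m - 1)
      M <- Ss[[h]] %*% avg %*% t(Ss[[h]])
      M <- (M + t(M)) / 2
      P2 <- matrix(0, n, n)
      for (i in 1:n) {
        s <- sum(M[i, -i])
        for (j in 1:n) P2[i, j] <- if (i == j) 0.5 else M[i, j] / (2 * s)
      }
      Pn[[h]] <- P2
    }
    Ps <- Pn
  }
  fused <- matrix(0, n, n)
  for (h in 1:m) fused <- fused + Ps[[h]]
  fused <- fused / m
  (fused + t(fused)) / 2
}

# GAT layer from its defining equations (single head, LeakyReLU 0.2 additive
# attention with the 8*tanh(e/8) logit bound, softmax over the
# neighbourhood, no dropout)
oracle_gat <- function(X, adj, W, a_src, a_dst, act = c("elu", "linear")) {
  act <- match.arg(act)
  n <- nrow(X)
  H <- X %*% W
  out <- matrix(0, n, ncol(W))
  for (i in 1:n) {
    nb <- which(adj[i, ] == 1)
    e <- numeric(length(nb))
    for (t in seq_along(nb)) {
      raw <- sum(a_src * H[i, ]) + sum(a_dst * H[nb[t], ])
      lk <- if (raw > 0) raw else 0.2 * raw
      e[t] <- 8 * tanh(lk / 8)
    }
    al <- exp(e - max(e))
    al <- al / sum(al)
    for (t in seq_along(nb)) out[i, ] <- out[i, ] + al[t] * H[nb[t], ]
  }
  if (act == "elu") ifelse(out > 0, out, exp(out) - 1) else out
}

# mean silhouette width from its definition
oracle_silhouette <- function(X, labels) {
  n <- nrow(X)
  d <- as.matrix(dist(X))
  s <- numeric(n)
  for (i in 1:n) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- Inf
    for (g in setdiff(unique(labels), labels[i]))
      b <- min(b, mean(d[i, labels == g]))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# two-group log-rank chi-square from the at-risk tables
oracle_logrank_2group <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  tev <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tev) {
    at <- time >= t
    n_t <- sum(at)
    n1 <- sum(at & group == g1)
    d_t <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n_t - d_t) * n1 * (n_t - n1) / (n_t^2 * (n_t - 1))
  }
  chisq <- (O1 - E1)^2 / V
  -log10(max(pchisq(chisq, df = 1, lower.tail = FALSE), 1e-300))
}

# Harrell's C by exhaustive enumeration of comparable pairs
oracle_cindex <- function(time, event, risk) {
  num <- den <- 0
  n <- length(time)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    sh <- if (time[i] < time[j]) i else j
    lo <- if (time[i] < time[j]) j else i
    if (event[sh] != 1) next                     # shorter time censored: not comparable
    den <- den + 1
    if (risk[sh] > risk[lo]) num <- num + 1
    else if (risk[sh] == risk[lo]) num <- num + 0.5
  }
  num / den
}

# Kaplan-Meier survival by the product-limit formula
oracle_km <- function(time, event) {
  tev <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = tev, surv = NA_real_)
  for (r in seq_along(tev)) {
    n_t <- sum(time >= tev[r])
    d_t <- sum(time == tev[r] & event == 1)
    s <- s * (1 - d_t / n_t)
    out$surv[r] <- s
  }
  out
}
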