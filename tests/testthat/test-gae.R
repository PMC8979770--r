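tiny_graph <- function(n = 7, K = 3, seed = 11) {
  set.seed(seed)
  W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 1
  build_graph(toy_fused(multigatae:::renormalize_P(W)), K)
}

test_that("a GAT layer reduces to neighbourhood averaging at zero attention", {
  g <- tiny_graph()
  X <- toy_matrix(7, 4, seed = 1)
  W <- matrix(0.3, 4, 3)
  par <- list(W = W, a_src = rep(0, 3), a_dst = rep(0, 3))
  out <- gat_layer(X, g, par, activation = "linear")
  H <- X %*% W
  for (i in 1:7) {
    nb <- g$dst[g$src == i]
    expect_equal(out$out[i, ], colMeans(H[nb, , drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("attention coefficients are a softmax over each neighbourhood", {
  g <- tiny_graph(seed = 4)
  set.seed(2)
  par <- list(W = matrix(rnorm(4 * 3), 4, 3), a_src = rnorm(3), a_dst = rnorm(3))
  out <- gat_layer(toy_matrix(7, 4, seed = 3), g, par)
  sums <- tapply(out$alpha, g$src, sum)
  expect_true(all(abs(sums - 1) < 1e-8))
})

test_that("a GAT layer matches the straight-line equation oracle", {
  # fixed 3-node graph, hand-set small weights
  W <- matrix(c(0.5, 0.4, 0.3,
                0.4, 0.5, 0.2,
                0.3, 0.2, 0.5), 3, 3, byrow = TRUE)
  g <- build_graph(toy_fused(W), 2)
  X <- matrix(c(0.1, -0.2, 0.3, 0.5, -0.4, 0.2), 3, 2)
  par <- list(W = matrix(c(0.2, -0.1, 0.3, 0.15, -0.25, 0.05), 2, 3),
              a_src = c(0.1, -0.2, 0.3), a_dst = c(-0.15, 0.25, 0.1))
  for (act in c("elu", "linear")) {
    mine <- gat_layer(X, g, par, activation = act)$out
    ref <- oracle_gat(X, g$target, par$W, par$a_src, par$a_dst, act = act)
    expect_equal(mine, ref, tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("encoding is deterministic in evaluation mode and seeded in training mode", {
  g <- tiny_graph()
  cfg <- gae_config(hidden_dims = c(6, 3), attn_dim = 4, seed = 2)
  set.seed(2)
  st <- init_encoder_state(5, g$n, cfg)
  X <- toy_matrix(7, 5, seed = 6)
  z1 <- encode_omics(X, g, st$omics[[1]], cfg)$Z
  z2 <- encode_omics(X, g, st$omics[[1]], cfg)$Z
  expect_identical(z1, z2)
  # training mode consumes the RNG but is reproducible under the same seed
  set.seed(77)
  zt1 <- encode_omics(X, g, st$omics[[1]], cfg, training = TRUE)$Z
  set.seed(77)
  zt2 <- encode_omics(X, g, st$omics[[1]], cfg, training = TRUE)$Z
  expect_identical(zt1, zt2)
  expect_false(identical(z1, zt1))
})

test_that("omics-level attention weights form a softmax with the stated degeneracies", {
  g <- tiny_graph()
  set.seed(3)
  Z1 <- matrix(rnorm(7 * 3), 7, 3)
  Z2 <- matrix(rnorm(7 * 3), 7, 3)

  # single omics bypass
  e1 <- omics_attention(list(Z1), g)
  expect_identical(e1$Z_final, Z1)
  expect_identical(e1$beta, 1)

  # v = 0 makes all scores equal: beta uniform, fusion = arithmetic mean
  attn0 <- list(v = rep(0, 4), Wz = matrix(rnorm(12), 3, 4),
                Wa = matrix(rnorm(28), 7, 4))
  e0 <- omics_attention(list(Z1, Z2), g, attn0)
  expect_equal(e0$beta, c(0.5, 0.5))
  expect_equal(e0$Z_final, (Z1 + Z2) / 2, tolerance = 1e-12)

  # general parameters match a direct evaluation of the scoring formula
  attn <- list(v = c(0.2, -0.1, 0.3, 0.05), Wz = matrix(rnorm(12), 3, 4),
               Wa = matrix(rnorm(28), 7, 4))
  e <- omics_attention(list(Z1, Z2), g, attn)
  w <- sapply(list(Z1, Z2), function(Z)
    mean(tanh(Z %*% attn$Wz + g$target %*% attn$Wa) %*% attn$v))
  beta_ref <- exp(w - max(w)); beta_ref <- beta_ref / sum(beta_ref)
  expect_equal(e$beta, beta_ref, tolerance = 1e-10)
  expect_equal(sum(e$beta), 1, tolerance = 1e-8)
  expect_equal(e$Z_final, beta_ref[1] * Z1 + beta_ref[2] * Z2, tolerance = 1e-12)
})

test_that("the inner-product decoder is a symmetric sigmoid bilinear form", {
  Z0 <- matrix(0, 4, 2)
  expect_true(all(decode(Z0) == 0.5))
  Z <- rbind(c(1, 0), c(0, 1))
  A <- decode(Z)
  expect_equal(A[1, 2], 0.5)
  expect_equal(A[1, 1], 1 / (1 + exp(-1)), tolerance = 1e-10)
  set.seed(5)
  Zr <- matrix(rnorm(12), 6, 2)
  Ar <- decode(Zr)
  expect_lt(max(abs(Ar - t(Ar))), 1e-12)
  expect_true(all(Ar > 0 & Ar < 1))
})

test_that("analytic gradients match central differences", {
  g <- tiny_graph()
  Xs <- list(toy_matrix(7, 5, seed = 8), toy_matrix(7, 4, seed = 9))
  cfg <- gae_config(hidden_dims = c(6, 3), attn_dim = 4, dropout = 0, seed = 2)
  set.seed(2)
  state <- init_encoder_state(c(5, 4), g$n, cfg)
  # undo the small-scale output init: O(1) parameters keep the central
  # differences well conditioned
  for (i in 1:2) state$omics[[i]]$L2$W <- 10 * state$omics[[i]]$L2$W
  A <- g$target
  pw <- (length(A) - sum(A)) / sum(A)
  lossfn <- function(st) {
    fw <- multigatae:::gae_forward(Xs, g, st, cfg, training = FALSE)
    multigatae:::recon_loss(fw$emb$Z_final, A, pw)
  }
  fw <- multigatae:::gae_forward(Xs, g, state, cfg, training = FALSE)
  gr <- multigatae:::gae_backward(fw, g, state, cfg, A, pw)
  h <- 1e-6
  set.seed(30)
  rel_errs <- c()
  for (om in 1:2) for (L in c("L1", "L2")) for (leaf in c("W", "a_src", "a_dst")) {
    p <- state$omics[[om]][[L]][[leaf]]
    gv <- gr$omics[[om]][[L]][[leaf]]
    for (i in sample(length(p), min(3, length(p)))) {
      s2 <- state
      s2$omics[[om]][[L]][[leaf]][i] <- p[i] + h
      lp <- lossfn(s2)
      s2$omics[[om]][[L]][[leaf]][i] <- p[i] - h
      lm <- lossfn(s2)
      num <- (lp - lm) / (2 * h)
      rel_errs <- c(rel_errs, abs(num - gv[i]) / max(1e-8, abs(num) + abs(gv[i])))
    }
  }
  for (leaf in c("v", "Wz", "Wa")) {
    p <- state$attn[[leaf]]
    gv <- gr$attn[[leaf]]
    for (i in sample(length(p), min(4, length(p)))) {
      s2 <- state
      s2$attn[[leaf]][i] <- p[i] + h
      lp <- lossfn(s2)
      s2$attn[[leaf]][i] <- p[i] - h
      lm <- lossfn(s2)
      num <- (lp - lm) / (2 * h)
      rel_errs <- c(rel_errs, abs(num - gv[i]) / max(1e-8, abs(num) + abs(gv[i])))
    }
  }
  # central differences are inexact where a perturbation crosses a
  # LeakyReLU/ELU kink or a softmax max switch: tolerate isolated outliers
  # but demand near machine-precision agreement almost everywhere
  expect_gte(mean(rel_errs < 1e-5), 0.95)
  expect_lt(max(rel_errs), 1e-2)
  expect_lt(stats::median(rel_errs), 1e-7)
})

test_that("training is seed-reproducible and keeps both attention levels normalised", {
  g <- tiny_graph(n = 12, K = 4, seed = 21)
  Xs <- list(toy_matrix(12, 6, seed = 22), toy_matrix(12, 5, seed = 23))
  cfg <- gae_config(hidden_dims = c(8, 4), attn_dim = 4, epochs = 30, seed = 5)
  tr1 <- gae_train(Xs, g, cfg)
  tr2 <- gae_train(Xs, g, cfg)
  expect_identical(tr1$loss_trajectory, tr2$loss_trajectory)
  expect_identical(tr1$embedding$Z_final, tr2$embedding$Z_final)
  expect_true(all(is.finite(tr1$loss_trajectory$loss)))
  # per-omics beta rows sum to 1 throughout training
  bsum <- rowSums(as.matrix(tr1$loss_trajectory[, c("beta_1", "beta_2")]))
  expect_true(all(abs(bsum - 1) < 1e-8))
  # per-node attention rows sum to 1 at the trained parameters
  fw <- multigatae:::gae_forward(Xs, g, tr1$state, cfg, training = FALSE)
  for (en in fw$enc) {
    sums <- tapply(en$l1$alpha, g$src, sum)
    expect_true(all(abs(sums - 1) < 1e-8))
  }
})

test_that("identical omics layers get near-uniform fusion weights", {
  g <- tiny_graph(n = 15, K = 5, seed = 31)
  X <- toy_matrix(15, 8, seed = 32)
  cfg <- gae_config(hidden_dims = c(10, 4), attn_dim = 4, epochs = 60, seed = 3)
  tr <- gae_train(list(X, X, X), g, cfg)
  expect_lt(max(abs(tr$embedding$beta - 1 / 3)), 0.1)
})

test_that("embeddings are permutation-equivariant at fixed parameters", {
  n <- 10
  set.seed(41)
  W <- matrix(runif(n * n), n, n); W <- (W + t(W)) / 2; diag(W) <- 1
  fused <- toy_fused(multigatae:::renormalize_P(W))
  g <- build_graph(fused, 4)
  X <- toy_matrix(n, 6, seed = 42)
  cfg <- gae_config(hidden_dims = c(6, 3), attn_dim = 4, seed = 2)
  set.seed(2)
  st <- init_encoder_state(6, n, cfg)
  Z <- encode_omics(X, g, st$omics[[1]], cfg)$Z
  perm <- sample(n)
  gp <- build_graph(toy_fused(multigatae:::renormalize_P(W[perm, perm]),
                              ids = rownames(W)[perm]), 4)
  Zp <- encode_omics(X[perm, ], gp, st$omics[[1]], cfg)$Z
  expect_equal(Zp, Z[perm, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("training reduces reconstruction loss on a structured cohort", {
  spec <- synthetic_spec(n_samples = 60, k_true = 3, n_features = c(40, 40),
                         n_informative = 12, omics_informative = c(TRUE, TRUE),
                         missing_rate = 0, seed = 13)
  coh <- generate_cohort(spec)
  pre <- lapply(coh$omics, preprocess_omics)
  al <- align_samples(pre, coh$clinical)
  fused <- fuse_omics(al$omics, snf_config(K_neighbors = 15))
  g <- build_graph(fused, 18)
  cfg <- gae_config(epochs = 150, seed = 13)
  tr <- gae_train(al$omics, g, cfg)
  l <- tr$loss_trajectory$loss
  expect_lt(l[length(l)], 0.5 * l[1])
})

test_that("the fused embedding recovers subtypes and beats any single-omics run", {
  # moderate signal split across three layers: the fused embedding should
  # recover the partition while each single-layer embedding does worse
  spec <- synthetic_spec(n_samples = 120, k_true = 3, n_features = c(60, 60, 60),
                         n_informative = 15, signal_shift = 1.3,
                         omics_informative = c(TRUE, TRUE, TRUE),
                         missing_rate = 0, seed = 17)
  coh <- generate_cohort(spec)
  pre <- lapply(coh$omics, preprocess_omics)
  al <- align_samples(pre, coh$clinical)
  truth <- coh$true_labels[rownames(al$omics[[1]])]
  emb_ari <- function(ms, seed) {
    fused <- fuse_omics(ms)
    g <- build_graph(fused, 40)
    tr <- gae_train(ms, g, gae_config(epochs = 200, seed = seed))
    mclust::adjustedRandIndex(kmeans_cluster(tr$embedding$Z_final, 3,
                                             seed = 1), truth)
  }
  ari_multi <- emb_ari(al$omics, 17)
  ari_single <- vapply(1:3, function(h) emb_ari(al$omics[h], 17), numeric(1))
  expect_gte(ari_multi, 0.9)
  expect_true(all(ari_single < ari_multi))
})
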