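#' Graph autoencoder configuration
#'
#' Defaults follow the method's tuned choices where stated (2 encoder layers,
#' learning rate 0.01, dropout 0.5); widths, attention dimension and the
#' epoch budget are package defaults.
#'
#' @param hidden_dims Integer vector of length 2: widths of the two encoder
#'   layers (nonlinear then linear output). The second entry is the embedding
#'   dimension.
#' @param attn_dim Width of the omics-level attention projection.
#' @param lr Adam learning rate.
#' @param dropout Dropout probability on the normalised attention
#'   coefficients during training (as in standard GAT implementations).
#' @param epochs Number of training epochs.
#' @param warmup_epochs Linear learning-rate warmup length: the step size
#'   ramps from `lr/warmup_epochs` up to `lr` over the first
#'   `warmup_epochs` epochs, then stays at `lr`. Protects the quadratic
#'   inner-product decoder from the large coherent first steps that
#'   otherwise saturate the attention softmax.
#' @param use_sym_norm If `TRUE`, attention coefficients are additionally
#'   multiplied by the symmetric normalisation
#'   \eqn{\tilde D^{-1/2}\tilde A \tilde D^{-1/2}} edge weights (the printed
#'   hybrid propagation rule); default `FALSE` uses pure masked GAT
#'   aggregation.
#' @param leaky_slope Negative slope of the LeakyReLU in the attention
#'   mechanism.
#' @param att_clip Soft bound on attention logits (`att_clip * tanh(e /
#'   att_clip)`), preventing one-hot softmax saturation during training.
#' @param seed Integer seed governing parameter initialisation and dropout.
#' @return A `gae_config` list.
#' @export
gae_config <- function(hidden_dims = c(256L, 64L), attn_dim = 32L, lr = 0.01,
                       dropout = 0.5, epochs = 300L, warmup_epochs = 50L,
                       use_sym_norm = FALSE, leaky_slope = 0.2, att_clip = 8,
                       seed = 1L) {
  stopifnot(length(hidden_dims) == 2, all(hidden_dims >= 1), lr > 0,
            dropout >= 0, dropout < 1, epochs >= 1, warmup_epochs >= 1,
            attn_dim >= 1)
  structure(list(hidden_dims = as.integer(hidden_dims),
                 attn_dim = as.integer(attn_dim), lr = lr, dropout = dropout,
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 use_sym_norm = isTRUE(use_sym_norm),
                 leaky_slope = leaky_slope, att_clip = att_clip,
                 seed = as.integer(seed)),
            class = "gae_config")
}

glorot <- function(nr, nc) {
  l <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

#' Initialise encoder parameters
#'
#' One two-layer GAT encoder per omics plus (for m > 1) the omics-level
#' attention parameters `v`, `Wz`, `Wa`. Uses the current RNG state; seed
#' before calling for reproducibility.
#'
#' @param input_dims Integer vector of per-omics feature counts.
#' @param n Number of samples (rows of the graph).
#' @param cfg A [gae_config()].
#' @return An `encoder_state` list: `omics` (per-omics layer parameters) and
#'   `attn` (`NULL` for a single omics).
#' @export
init_encoder_state <- function(input_dims, n, cfg = gae_config()) {
  h1 <- cfg$hidden_dims[1]; h2 <- cfg$hidden_dims[2]; a <- cfg$attn_dim
  omics <- lapply(input_dims, function(p) {
    list(
      L1 = list(W = glorot(p, h1), a_src = glorot(h1, 1)[, 1], a_dst = glorot(h1, 1)[, 1]),
      # small-scale output layer: the decoder starts near sigmoid(0) = 1/2,
      # so the first recorded loss is close to the balanced baseline (exact
      # zero is a saddle of the quadratic decoder)
      L2 = list(W = 0.1 * glorot(h1, h2), a_src = glorot(h2, 1)[, 1], a_dst = glorot(h2, 1)[, 1])
    )
  })
  attn <- NULL
  if (length(input_dims) > 1) {
    attn <- list(v = glorot(a, 1)[, 1], Wz = glorot(h2, a), Wa = glorot(n, a))
  }
  structure(list(omics = omics, attn = attn), class = "encoder_state")
}

# per-source-node index groups for the edge softmax, cached on the graph
edge_groups <- function(g) {
  if (is.null(g$groups_src))
    g$groups_src <- split(seq_along(g$src), factor(g$src, levels = seq_len(g$n)))
  g
}

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

#' Single graph-attention layer
#'
#' Computes masked additive attention over the graph's edges,
#' \eqn{e_{ij} = \mathrm{LeakyReLU}(a_{src}^\top W x_i + a_{dst}^\top W x_j)},
#' normalises per node with a softmax over the neighbourhood (self-loop
#' included), and aggregates
#' \eqn{out_i = \sigma(\sum_j \alpha_{ij} W x_j)}.
#'
#' @param x Numeric n x p node-feature matrix, row-aligned with `g`.
#' @param g A [build_graph()] `graph_spec`.
#' @param params Layer parameters: list with `W` (p x h), `a_src`, `a_dst`
#'   (length-h attention vectors).
#' @param activation `"elu"` or `"linear"`.
#' @param use_sym_norm See [gae_config()].
#' @param leaky_slope LeakyReLU negative slope.
#' @param att_dropout Dropout probability on the normalised attention
#'   coefficients (active only with `training = TRUE`); dropped coefficients
#'   are zeroed and the survivors rescaled by 1/(1-p), the usual inverted
#'   scheme.
#' @param training Enable attention dropout (consumes the RNG stream).
#' @param layer_id Label used in error messages.
#' @return List with `out` (n x h) and `alpha` (per-edge attention, summing
#'   to 1 over each node's neighbourhood), plus cached intermediates for the
#'   backward pass.
#' @export
gat_layer <- function(x, g, params, activation = c("elu", "linear"),
                      use_sym_norm = FALSE, leaky_slope = 0.2,
                      att_dropout = 0, training = FALSE, att_clip = 8,
                      layer_id = "") {
  activation <- match.arg(activation)
  if (ncol(x) != nrow(params$W))
    stop(sprintf("gat_layer%s: feature width %d does not match W input dim %d",
                 layer_id, ncol(x), nrow(params$W)))
  g <- edge_groups(g)
  src <- g$src; dst <- g$dst
  H <- x %*% params$W
  as_n <- drop(H %*% params$a_src)
  ad_n <- drop(H %*% params$a_dst)
  eraw <- as_n[src] + ad_n[dst]
  e <- ifelse(eraw > 0, eraw, leaky_slope * eraw)
  # soft-bound the logits so the neighbourhood softmax cannot saturate
  # one-hot as the hidden scale grows (keeps gradients alive)
  e <- att_clip * tanh(e / att_clip)
  mx <- vapply(g$groups_src, function(ix) max(e[ix]), numeric(1))
  ex <- exp(e - mx[src])
  denom <- rowsum(ex, src)[, 1]
  alpha <- ex / denom[src]
  cscale <- if (use_sym_norm) g$deg_norm[src] * g$deg_norm[dst] else 1
  keep <- if (training && att_dropout > 0) {
    (stats::runif(length(alpha)) >= att_dropout) / (1 - att_dropout)
  } else 1
  coef <- alpha * cscale * keep
  pre <- rowsum(coef * H[dst, , drop = FALSE], src)
  out <- if (activation == "elu") elu(pre) else pre
  if (!all(is.finite(out)))
    stop(sprintf("gat_layer%s: non-finite activations", layer_id))
  list(out = out, alpha = alpha,
       cache = list(x = x, H = H, eraw = eraw, e = e, alpha = alpha,
                    cscale = cscale, keep = keep, coef = coef, pre = pre,
                    out = out, activation = activation,
                    use_sym_norm = use_sym_norm, leaky_slope = leaky_slope,
                    att_clip = att_clip))
}

# analytic backward pass of gat_layer; returns gradients wrt inputs/params
gat_backward <- function(dOut, cache, params, g) {
  g <- edge_groups(g)
  src <- g$src; dst <- g$dst
  dPre <- if (cache$activation == "elu") {
    dOut * ifelse(cache$pre > 0, 1, cache$out + 1)
  } else dOut
  H <- cache$H
  dCoef <- rowSums(dPre[src, , drop = FALSE] * H[dst, , drop = FALSE])
  dAlpha <- dCoef * cache$cscale * cache$keep
  dH <- rowsum(cache$coef * dPre[src, , drop = FALSE], dst)
  Ssum <- rowsum(cache$alpha * dAlpha, src)[, 1]
  dE <- cache$alpha * (dAlpha - Ssum[src])
  dE <- dE * (1 - (cache$e / cache$att_clip)^2)      # tanh bound
  dEraw <- dE * ifelse(cache$eraw > 0, 1, cache$leaky_slope)
  dAs <- rowsum(dEraw, src)[, 1]        # dL/d(a_src . h_i) per node
  dAd <- rowsum(dEraw, dst)[, 1]
  da_src <- drop(crossprod(H, dAs))
  da_dst <- drop(crossprod(H, dAd))
  dH <- dH + outer(dAs, params$a_src) + outer(dAd, params$a_dst)
  list(dX = dH %*% t(params$W),
       dW = crossprod(cache$x, dH),
       da_src = da_src, da_dst = da_dst)
}

#' Encode one omics layer into an embedding
#'
#' Applies the two stacked graph-attention layers (ELU then linear output).
#' Dropout on layer inputs is active in training mode only; evaluation mode
#' is deterministic.
#'
#' @param x Preprocessed [omics_matrix()] (or numeric matrix) row-aligned
#'   with `g`.
#' @param g A [build_graph()] `graph_spec`.
#' @param params Per-omics slice of an [init_encoder_state()] (`L1`, `L2`).
#' @param cfg A [gae_config()].
#' @param training Enable dropout (uses the current RNG state).
#' @return List with `Z` (n x d embedding) and per-layer caches.
#' @export
encode_omics <- function(x, g, params, cfg = gae_config(), training = FALSE) {
  x <- unclass(x)
  if (nrow(x) != g$n) stop("encode_omics: sample rows do not match graph size")
  l1 <- gat_layer(x, g, params$L1, "elu", cfg$use_sym_norm, cfg$leaky_slope,
                  att_dropout = cfg$dropout, training = training,
                  att_clip = cfg$att_clip, layer_id = "[1]")
  l2 <- gat_layer(l1$out, g, params$L2, "linear", cfg$use_sym_norm, cfg$leaky_slope,
                  att_dropout = cfg$dropout, training = training,
                  att_clip = cfg$att_clip, layer_id = "[2]")
  list(Z = l2$out, l1 = l1, l2 = l2)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Omics-level attention fusion
#'
#' Scores each omics embedding by
#' \eqn{w^i = \mathrm{mean}_r\, v^\top \tanh(Z^i W_z + \tilde A W_a)_r},
#' normalises the scores with a softmax into weights \eqn{\beta}, and returns
#' \eqn{Z_{final} = \sum_i \beta_i Z^i}. A single omics bypasses the
#' mechanism with \eqn{\beta = 1}.
#'
#' @param Zs List of n x d per-omics embeddings.
#' @param g A [build_graph()] `graph_spec` (its binary target adjacency is
#'   the \eqn{\tilde A} entering the scores).
#' @param attn Attention parameters `v`, `Wz`, `Wa` (the `attn` slot of an
#'   [init_encoder_state()]); ignored for a single omics.
#' @param sample_ids Optional sample IDs attached to the result.
#' @return An `omics_embedding` list: `Z_final`, `beta`, `Z_per_omics`,
#'   `sample_ids`, plus cached score intermediates.
#' @export
omics_attention <- function(Zs, g, attn = NULL, sample_ids = g$sample_ids) {
  m <- length(Zs)
  stopifnot(m >= 1)
  if (m == 1) {
    emb <- list(Z_final = Zs[[1]], beta = 1, Z_per_omics = Zs,
                sample_ids = sample_ids, M = NULL, AWa = NULL)
    class(emb) <- "omics_embedding"
    return(emb)
  }
  if (is.null(attn)) stop("omics_attention: attention parameters required for m > 1")
  A <- g$target
  AWa <- A %*% attn$Wa
  M <- lapply(Zs, function(Z) tanh(Z %*% attn$Wz + AWa))
  w <- vapply(M, function(Mi) mean(Mi %*% attn$v), numeric(1))
  beta <- softmax(w)
  Zf <- Reduce(`+`, Map(function(b, Z) b * Z, beta, Zs))
  structure(list(Z_final = Zf, beta = beta, Z_per_omics = Zs,
                 sample_ids = sample_ids, M = M, AWa = AWa),
            class = "omics_embedding")
}

#' @export
print.omics_embedding <- function(x, ...) {
  cat(sprintf("<omics_embedding> %d samples x %d dims, %d omics, beta = %s\n",
              nrow(x$Z_final), ncol(x$Z_final), length(x$Z_per_omics),
              paste(signif(x$beta, 3), collapse = ", ")))
  invisible(x)
}

#' Inner-product decoder
#'
#' Reconstructs the adjacency as
#' \eqn{\hat A = \mathrm{sigmoid}(Z_{final} Z_{final}^\top)}: symmetric,
#' entries in (0, 1).
#'
#' @param emb An [omics_attention()] embedding, or a plain n x d matrix.
#' @return The n x n reconstructed adjacency.
#' @export
decode <- function(emb) {
  Z <- if (inherits(emb, "omics_embedding")) emb$Z_final else emb
  1 / (1 + exp(-(Z %*% t(Z))))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# positive-reweighted BCE between logits theta = Z Z^T and binary target A
recon_loss <- function(Zf, A, pos_w) {
  theta <- Zf %*% t(Zf)
  L <- pos_w * A * softplus(-theta) + (1 - A) * softplus(theta)
  mean(L)
}

recon_loss_grad_Z <- function(Zf, A, pos_w) {
  theta <- Zf %*% t(Zf)
  sig <- 1 / (1 + exp(-theta))
  G <- ((pos_w * A + (1 - A)) * sig - pos_w * A) / length(A)
  (G + t(G)) %*% Zf                    # G symmetric by construction, kept explicit
}

# full forward pass; training mode consumes RNG for dropout
gae_forward <- function(Xs, g, state, cfg, training = FALSE) {
  enc <- lapply(seq_along(Xs), function(i)
    encode_omics(Xs[[i]], g, state$omics[[i]], cfg, training = training))
  Zs <- lapply(enc, `[[`, "Z")
  emb <- omics_attention(Zs, g, state$attn)
  list(enc = enc, emb = emb)
}

# analytic gradients of recon_loss wrt every parameter in `state`
gae_backward <- function(fw, g, state, cfg, A, pos_w) {
  emb <- fw$emb
  m <- length(fw$enc)
  dZf <- recon_loss_grad_Z(emb$Z_final, A, pos_w)
  dZs <- vector("list", m)
  dattn <- NULL
  if (m == 1) {
    dZs[[1]] <- dZf
  } else {
    at <- state$attn
    beta <- emb$beta
    dbeta <- vapply(seq_len(m), function(i) sum(dZf * emb$Z_per_omics[[i]]), numeric(1))
    dw <- beta * (dbeta - sum(beta * dbeta))
    n <- g$n
    dv <- numeric(length(at$v))
    dWz <- matrix(0, nrow(at$Wz), ncol(at$Wz))
    dWa <- matrix(0, nrow(at$Wa), ncol(at$Wa))
    for (i in seq_len(m)) {
      dZs[[i]] <- beta[i] * dZf
      dsi <- dw[i] / n                          # each node's score weighted equally
      Mi <- emb$M[[i]]
      dv <- dv + dsi * colSums(Mi)
      dU <- sweep(1 - Mi^2, 2, at$v * dsi, `*`) # dM_r = dsi * v; dU = dM * (1 - M^2)
      dWz <- dWz + crossprod(emb$Z_per_omics[[i]], dU)
      dZs[[i]] <- dZs[[i]] + dU %*% t(at$Wz)
      dWa <- dWa + crossprod(A, dU)
    }
    dattn <- list(v = dv, Wz = dWz, Wa = dWa)
  }
  domics <- vector("list", m)
  for (i in seq_len(m)) {
    en <- fw$enc[[i]]
    b2 <- gat_backward(dZs[[i]], en$l2$cache, state$omics[[i]]$L2, g)
    b1 <- gat_backward(b2$dX, en$l1$cache, state$omics[[i]]$L1, g)
    domics[[i]] <- list(
      L1 = list(W = b1$dW, a_src = b1$da_src, a_dst = b1$da_dst),
      L2 = list(W = b2$dW, a_src = b2$da_src, a_dst = b2$da_dst))
  }
  list(omics = domics, attn = dattn)
}

# Adam over a nested list of numeric arrays
adam_init <- function(p) {
  if (is.list(p)) lapply(p, adam_init) else array(0, dim = if (is.null(dim(p))) length(p) else dim(p))
}

adam_step <- function(p, grad, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-4) {
  if (is.list(p)) {
    out <- Map(adam_step, p, grad, m, v, MoreArgs = list(lr = lr, t = t, b1 = b1, b2 = b2, eps = eps))
    return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                v = lapply(out, `[[`, "v")))
  }
  m <- b1 * m + (1 - b1) * grad
  v <- b2 * v + (1 - b2) * grad^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train the graph autoencoder
#'
#' Minimises the positive-class-reweighted binary cross-entropy between the
#' decoded adjacency and the graph's binary target with Adam. All randomness
#' (initialisation, dropout) is governed by `cfg$seed`; two runs with the
#' same inputs and seed give bit-identical trajectories.
#'
#' @param Xs List of preprocessed, sample-aligned omics matrices.
#' @param g A [build_graph()] `graph_spec`.
#' @param cfg A [gae_config()].
#' @param verbose Print the loss every 50 epochs.
#' @return List with `state` (trained [init_encoder_state()]), `embedding`
#'   (evaluation-mode [omics_attention()] result at the final parameters),
#'   and `loss_trajectory` (data.frame: epoch, loss, one beta column per
#'   omics).
#' @export
gae_train <- function(Xs, g, cfg = gae_config(), verbose = FALSE) {
  Xs <- lapply(Xs, unclass)
  stopifnot(length(Xs) >= 1)
  for (X in Xs) if (nrow(X) != g$n) stop("gae_train: omics rows do not match graph")
  set.seed(cfg$seed)
  g <- edge_groups(g)
  state <- init_encoder_state(vapply(Xs, ncol, integer(1)), g$n, cfg)
  A <- g$target
  npos <- sum(A)
  pos_w <- (length(A) - npos) / npos
  am <- adam_init(state)
  av <- adam_init(state)
  m <- length(Xs)
  losses <- numeric(cfg$epochs)
  betas <- matrix(NA_real_, cfg$epochs, m)
  for (ep in seq_len(cfg$epochs)) {
    lr_ep <- cfg$lr * min(1, ep / cfg$warmup_epochs)
    fw <- gae_forward(Xs, g, state, cfg, training = TRUE)
    loss <- recon_loss(fw$emb$Z_final, A, pos_w)
    if (!is.finite(loss)) stop("gae_train: non-finite loss at epoch ", ep)
    losses[ep] <- loss
    betas[ep, ] <- fw$emb$beta
    gr <- gae_backward(fw, g, state, cfg, A, pos_w)
    upd <- adam_step(state[c("omics", "attn")[c(TRUE, m > 1)]],
                     gr[c("omics", "attn")[c(TRUE, m > 1)]],
                     am[c("omics", "attn")[c(TRUE, m > 1)]],
                     av[c("omics", "attn")[c(TRUE, m > 1)]],
                     lr = lr_ep, t = ep)
    state$omics <- upd$p$omics
    am$omics <- upd$m$omics
    av$omics <- upd$v$omics
    if (m > 1) {
      state$attn <- upd$p$attn
      am$attn <- upd$m$attn
      av$attn <- upd$v$attn
    }
    if (verbose && ep %% 50 == 0)
      message(sprintf("epoch %d: loss %.5f", ep, loss))
  }
  fw <- gae_forward(Xs, g, state, cfg, training = FALSE)
  traj <- data.frame(epoch = seq_len(cfg$epochs), loss = losses)
  traj[paste0("beta_", seq_len(m))] <- betas
  list(state = state, embedding = fw$emb, loss_trajectory = traj)
}
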