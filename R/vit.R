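## Small vision transformer, implemented from scratch in base R with
## hand-derived backpropagation. Desk-scale geometry: the input image is cut
## into non-overlapping patch tokens, linearly embedded with a learned
## positional embedding, passed through pre-LayerNorm transformer blocks
## (multi-head self-attention + ReLU MLP, both residual), mean-pooled and
## read out by a 2-logit softmax head. Gradients are verified against finite
## differences in the test suite.

## image (s x s x 3, values in [0,1]) -> token matrix N x (p*p*3), row-major
## over the patch grid
vit_tokenize <- function(arr, patch) {
  s <- dim(arr)[1]
  np <- s %/% patch
  toks <- matrix(0, np * np, patch * patch * 3L)
  k <- 0L
  for (i in seq_len(np)) {
    rows <- ((i - 1L) * patch + 1L):(i * patch)
    for (j in seq_len(np)) {
      k <- k + 1L
      cols <- ((j - 1L) * patch + 1L):(j * patch)
      toks[k, ] <- as.vector(arr[rows, cols, ])
    }
  }
  toks
}

vit_init <- function(cfg) {
  P <- cfg$patch^2 * 3L; D <- cfg$d_model; M <- cfg$mlp_hidden
  N <- (cfg$input_size %/% cfg$patch)^2
  rmat <- function(a, b, sc) matrix(rnorm(a * b, 0, sc), a, b)
  params <- list(We = rmat(P, D, sqrt(2 / P)), be = numeric(D),
                 pos = rmat(N, D, 0.02),
                 Wh = rmat(D, 2L, sqrt(2 / D)), bh = numeric(2L),
                 lnf_g = rep(1, D), lnf_b = numeric(D))
  for (l in seq_len(cfg$n_layers)) {
    params[[paste0("ln1_g", l)]] <- rep(1, D)
    params[[paste0("ln1_b", l)]] <- numeric(D)
    params[[paste0("Wq", l)]] <- rmat(D, D, sqrt(2 / D))
    params[[paste0("Wk", l)]] <- rmat(D, D, sqrt(2 / D))
    params[[paste0("Wv", l)]] <- rmat(D, D, sqrt(2 / D))
    params[[paste0("Wo", l)]] <- rmat(D, D, sqrt(2 / D))
    params[[paste0("ln2_g", l)]] <- rep(1, D)
    params[[paste0("ln2_b", l)]] <- numeric(D)
    params[[paste0("W1", l)]] <- rmat(D, M, sqrt(2 / D))
    params[[paste0("b1", l)]] <- numeric(M)
    params[[paste0("W2", l)]] <- rmat(M, D, sqrt(2 / M))
    params[[paste0("b2", l)]] <- numeric(D)
  }
  params
}

## row-wise layernorm; returns list(y, xhat, istd)
ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  istd <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * istd
  list(y = sweep(xhat, 2, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, istd = istd)
}

## backward through layernorm; dy -> list(dX, dg, db)
ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat; istd <- cache$istd
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- (dxhat - m1 - xhat * m2) * istd
  list(dX = dX, dg = dg, db = db)
}

softmax_rows <- function(S) {
  e <- exp(S - apply(S, 1, max))
  e / rowSums(e)
}

## forward pass over a batch; toks: (B*N) x P stacked row-major per sample
vit_forward <- function(params, toks, cfg, B, keep_cache = TRUE) {
  N <- (cfg$input_size %/% cfg$patch)^2
  D <- cfg$d_model; H <- cfg$n_heads; dh <- D %/% H
  X <- toks %*% params$We + rep(params$be, each = nrow(toks)) +
    params$pos[rep(seq_len(N), times = B), ]
  cache <- list(toks = toks, layers = vector("list", cfg$n_layers))
  for (l in seq_len(cfg$n_layers)) {
    p <- function(nm) params[[paste0(nm, l)]]
    lc <- list(X_in = X)
    c1 <- ln_fwd(X, p("ln1_g"), p("ln1_b"))
    Q <- c1$y %*% p("Wq"); K <- c1$y %*% p("Wk"); V <- c1$y %*% p("Wv")
    O <- matrix(0, nrow(X), D)
    Plist <- vector("list", B * H)
    for (b in seq_len(B)) {
      idx <- ((b - 1L) * N + 1L):(b * N)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[idx, cols, drop = FALSE], K[idx, cols, drop = FALSE]) / sqrt(dh)
        Pm <- softmax_rows(S)
        O[idx, cols] <- Pm %*% V[idx, cols, drop = FALSE]
        Plist[[(b - 1L) * H + h]] <- Pm
      }
    }
    A <- O %*% p("Wo")
    X <- X + A
    c2 <- ln_fwd(X, p("ln2_g"), p("ln2_b"))
    Z1 <- c2$y %*% p("W1") + rep(p("b1"), each = nrow(X))
    R <- pmax(Z1, 0)
    Mo <- R %*% p("W2") + rep(p("b2"), each = nrow(X))
    lc <- c(lc, list(c1 = c1, Q = Q, K = K, V = V, O = O, Plist = Plist,
                     X_att = X, c2 = c2, Z1 = Z1, R = R))
    X <- X + Mo
    if (keep_cache) cache$layers[[l]] <- lc
  }
  cf <- ln_fwd(X, params$lnf_g, params$lnf_b)
  Fmat <- cf$y
  pool <- matrix(0, B, D)
  for (b in seq_len(B)) {
    idx <- ((b - 1L) * N + 1L):(b * N)
    pool[b, ] <- colMeans(Fmat[idx, , drop = FALSE])
  }
  logits <- pool %*% params$Wh + rep(params$bh, each = B)
  probs <- softmax_rows(logits)
  out <- list(probs = probs, logits = logits)
  if (keep_cache) {
    out$cache <- c(cache, list(X_final = X, cf = cf, pool = pool))
  }
  out
}

## cross-entropy loss + full backward; y in {0,1}
vit_loss_grad <- function(params, toks, y, cfg) {
  B <- length(y)
  N <- (cfg$input_size %/% cfg$patch)^2
  D <- cfg$d_model; H <- cfg$n_heads; dh <- D %/% H
  fw <- vit_forward(params, toks, cfg, B, keep_cache = TRUE)
  probs <- fw$probs
  loss <- -mean(log(pmax(probs[cbind(seq_len(B), y + 1L)], 1e-12)))
  grads <- lapply(params, function(p) p * 0)
  dlogits <- probs
  dlogits[cbind(seq_len(B), y + 1L)] <- dlogits[cbind(seq_len(B), y + 1L)] - 1
  dlogits <- dlogits / B
  cache <- fw$cache
  grads$Wh <- crossprod(cache$pool, dlogits)
  grads$bh <- colSums(dlogits)
  dpool <- dlogits %*% t(params$Wh)
  dF <- matrix(0, B * N, D)
  for (b in seq_len(B)) {
    idx <- ((b - 1L) * N + 1L):(b * N)
    dF[idx, ] <- matrix(dpool[b, ] / N, N, D, byrow = TRUE)
  }
  lb <- ln_bwd(dF, cache$cf, params$lnf_g)
  grads$lnf_g <- lb$dg; grads$lnf_b <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg$n_layers))) {
    p <- function(nm) params[[paste0(nm, l)]]
    lc <- cache$layers[[l]]
    ## MLP branch: X_out = X_att + relu(LN2(X_att) W1 + b1) W2 + b2
    dMo <- dX
    grads[[paste0("W2", l)]] <- crossprod(lc$R, dMo)
    grads[[paste0("b2", l)]] <- colSums(dMo)
    dR <- dMo %*% t(p("W2"))
    dZ1 <- dR * (lc$Z1 > 0)
    grads[[paste0("W1", l)]] <- crossprod(lc$c2$y, dZ1)
    grads[[paste0("b1", l)]] <- colSums(dZ1)
    dH2 <- dZ1 %*% t(p("W1"))
    lb2 <- ln_bwd(dH2, lc$c2, p("ln2_g"))
    grads[[paste0("ln2_g", l)]] <- lb2$dg
    grads[[paste0("ln2_b", l)]] <- lb2$db
    dX_att <- dX + lb2$dX
    ## attention branch: X_att = X_in + (O Wo)
    dA <- dX_att
    grads[[paste0("Wo", l)]] <- crossprod(lc$O, dA)
    dO <- dA %*% t(p("Wo"))
    dQ <- matrix(0, nrow(dO), D); dK <- dQ; dV <- dQ
    B_here <- nrow(dO) %/% N
    for (b in seq_len(B_here)) {
      idx <- ((b - 1L) * N + 1L):(b * N)
      for (h in seq_len(H)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        Pm <- lc$Plist[[(b - 1L) * H + h]]
        dOb <- dO[idx, cols, drop = FALSE]
        Vb <- lc$V[idx, cols, drop = FALSE]
        dP <- tcrossprod(dOb, Vb)
        dV[idx, cols] <- crossprod(Pm, dOb)
        dS <- Pm * (dP - rowSums(dP * Pm))
        dQ[idx, cols] <- dS %*% lc$K[idx, cols, drop = FALSE] / sqrt(dh)
        dK[idx, cols] <- crossprod(dS, lc$Q[idx, cols, drop = FALSE]) / sqrt(dh)
      }
    }
    grads[[paste0("Wq", l)]] <- crossprod(lc$c1$y, dQ)
    grads[[paste0("Wk", l)]] <- crossprod(lc$c1$y, dK)
    grads[[paste0("Wv", l)]] <- crossprod(lc$c1$y, dV)
    dH1 <- dQ %*% t(p("Wq")) + dK %*% t(p("Wk")) + dV %*% t(p("Wv"))
    lb1 <- ln_bwd(dH1, lc$c1, p("ln1_g"))
    grads[[paste0("ln1_g", l)]] <- lb1$dg
    grads[[paste0("ln1_b", l)]] <- lb1$db
    dX <- dX_att + lb1$dX
  }
  ## embedding
  grads$We <- crossprod(cache$toks, dX)
  grads$be <- colSums(dX)
  Bn <- nrow(dX) %/% N
  dpos <- matrix(0, N, D)
  for (b in seq_len(Bn)) {
    idx <- ((b - 1L) * N + 1L):(b * N)
    dpos <- dpos + dX[idx, , drop = FALSE]
  }
  grads$pos <- dpos
  list(loss = loss, grads = grads)
}

## Adam update in place over the parameter list
adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

vit_fit <- function(toks_list, y, cfg) {
  set.seed(cfg$seed)
  params <- vit_init(cfg)
  st <- list(t = 0L,
             m = lapply(params, function(p) p * 0),
             v = lapply(params, function(p) p * 0))
  n <- length(y)
  bs <- min(cfg$batch_size, n)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = bs)) {
      sel <- ord[start:min(start + bs - 1L, n)]
      toks <- do.call(rbind, toks_list[sel])
      lg <- vit_loss_grad(params, toks, y[sel], cfg)
      up <- adam_step(params, lg$grads, st, cfg$learning_rate)
      params <- up$params; st <- up$st
    }
  }
  params
}

vit_predict <- function(params, toks_list, cfg, chunk = 64L) {
  n <- length(toks_list)
  if (n == 0L) return(numeric())
  scores <- numeric(n)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    toks <- do.call(rbind, toks_list[sel])
    fw <- vit_forward(params, toks, cfg, length(sel), keep_cache = FALSE)
    scores[sel] <- fw$probs[, 2L]
  }
  scores
}
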