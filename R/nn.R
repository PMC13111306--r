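# Internal neural-network primitives for the curvature-map encoder.
# Everything is plain double-precision base R with hand-written backward
# passes; gradients are verified against central differences in the tests.

# --- convolution via im2col ------------------------------------------------

# precompute the im2col gather indices for a 3x3, stride-2, pad-1 conv
convPlan <- function(inSize, kernel = 3, stride = 2, pad = 1) {
  outSize <- (inSize + 2 * pad - kernel) %/% stride + 1L
  padSize <- inSize + 2 * pad
  P <- outSize * outSize
  idx <- matrix(0L, P, kernel * kernel)
  q <- 0L
  for (kw in seq_len(kernel)) for (kh in seq_len(kernel)) {
    q <- q + 1L
    oh <- rep(seq_len(outSize), times = outSize)
    ow <- rep(seq_len(outSize), each = outSize)
    ih <- (oh - 1L) * stride + kh
    iw <- (ow - 1L) * stride + kw
    idx[, q] <- ih + (iw - 1L) * padSize
  }
  list(inSize = inSize, outSize = outSize, padSize = padSize,
       kernel = kernel, pad = pad, idx = idx)
}

# x: inSize x inSize x Cin array -> list(out = P x Cout, cache)
convForward <- function(x, W, b, plan) {
  cin <- dim(x)[3]
  ps <- plan$padSize
  K <- plan$kernel^2
  Xcol <- matrix(0, nrow(plan$idx), K * cin)
  for (c in seq_len(cin)) {
    padc <- matrix(0, ps, ps)
    padc[(plan$pad + 1):(plan$pad + plan$inSize),
         (plan$pad + 1):(plan$pad + plan$inSize)] <- x[, , c]
    Xcol[, ((c - 1) * K + 1):(c * K)] <- padc[plan$idx]
  }
  out <- sweep(Xcol %*% W, 2, b, `+`)
  list(out = out, Xcol = Xcol)
}

convBackward <- function(dOut, W, cache, plan, cin) {
  ps <- plan$padSize
  K <- plan$kernel^2
  dW <- crossprod(cache$Xcol, dOut)
  db <- colSums(dOut)
  dXcol <- tcrossprod(dOut, W)
  dx <- array(0, dim = c(plan$inSize, plan$inSize, cin))
  keep <- (plan$pad + 1):(plan$pad + plan$inSize)
  for (c in seq_len(cin)) {
    dpad <- matrix(0, ps, ps)
    for (q in seq_len(K)) {
      ii <- plan$idx[, q]
      dpad[ii] <- dpad[ii] + dXcol[, (c - 1) * K + q]
    }
    dx[, , c] <- dpad[keep, keep]
  }
  list(dx = dx, dW = dW, db = db)
}

# --- patch embedding -------------------------------------------------------

patchPlan <- function(gridSize, patch, channels) {
  nP <- gridSize %/% patch           # patches per side
  T <- nP * nP
  pd <- patch * patch * channels
  idx <- matrix(0L, T, pd)
  t <- 0L
  for (pw in seq_len(nP)) for (ph in seq_len(nP)) {
    t <- t + 1L
    j <- 0L
    for (c in seq_len(channels)) for (kw in seq_len(patch)) for (kh in seq_len(patch)) {
      j <- j + 1L
      ih <- (ph - 1L) * patch + kh
      iw <- (pw - 1L) * patch + kw
      idx[t, j] <- ih + (iw - 1L) * gridSize + (c - 1L) * gridSize * gridSize
    }
  }
  list(T = T, pd = pd, idx = idx, dims = c(gridSize, gridSize, channels))
}

patchForward <- function(x, plan) matrix(x[plan$idx], plan$T, plan$pd)

patchBackward <- function(dTok, plan) {
  dx <- array(0, dim = plan$dims)
  dx[plan$idx] <- dTok        # patch indices are disjoint
  dx
}

# --- layer norm (per token over the feature dim) ---------------------------

lnForward <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  out <- sweep(xhat * matrix(g, nrow(X), length(g), byrow = TRUE), 2, b, `+`)
  list(out = out, xhat = xhat, istd = istd)
}

lnBackward <- function(dOut, g, cache) {
  xhat <- cache$xhat; istd <- cache$istd
  D <- ncol(dOut)
  dg <- colSums(dOut * xhat)
  db <- colSums(dOut)
  dxhat <- dOut * matrix(g, nrow(dOut), D, byrow = TRUE)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * istd
  list(dx = dx, dg = dg, db = db)
}

# --- softmax ---------------------------------------------------------------

softmaxRows <- function(S) {
  m <- apply(S, 1, max)
  E <- exp(S - m)
  E / rowSums(E)
}

softmaxBackwardRows <- function(dA, A) A * (dA - rowSums(dA * A))

# --- multi-head self-attention --------------------------------------------

mhaForward <- function(X, p, pre, heads) {
  D <- ncol(X); dh <- D %/% heads
  Q <- sweep(X %*% p[[paste0(pre, "_Wq")]], 2, p[[paste0(pre, "_bq")]], `+`)
  K <- sweep(X %*% p[[paste0(pre, "_Wk")]], 2, p[[paste0(pre, "_bk")]], `+`)
  V <- sweep(X %*% p[[paste0(pre, "_Wv")]], 2, p[[paste0(pre, "_bv")]], `+`)
  As <- vector("list", heads); Os <- matrix(0, nrow(X), D)
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    A <- softmaxRows(S)
    As[[h]] <- A
    Os[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  out <- sweep(Os %*% p[[paste0(pre, "_Wo")]], 2, p[[paste0(pre, "_bo")]], `+`)
  list(out = out, Q = Q, K = K, V = V, A = As, O = Os)
}

mhaBackward <- function(dOut, X, p, pre, heads, cache, grads) {
  D <- ncol(X); dh <- D %/% heads
  grads[[paste0(pre, "_Wo")]] <- grads[[paste0(pre, "_Wo")]] +
    crossprod(cache$O, dOut)
  grads[[paste0(pre, "_bo")]] <- grads[[paste0(pre, "_bo")]] + colSums(dOut)
  dO <- tcrossprod(dOut, p[[paste0(pre, "_Wo")]])
  dQ <- matrix(0, nrow(X), D); dK <- dQ; dV <- dQ
  for (h in seq_len(heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    A <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dS <- softmaxBackwardRows(dA, A) / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  dX <- matrix(0, nrow(X), D)
  for (nm in c("q", "k", "v")) {
    dM <- switch(nm, q = dQ, k = dK, v = dV)
    W <- p[[paste0(pre, "_W", nm)]]
    grads[[paste0(pre, "_W", nm)]] <- grads[[paste0(pre, "_W", nm)]] +
      crossprod(X, dM)
    grads[[paste0(pre, "_b", nm)]] <- grads[[paste0(pre, "_b", nm)]] + colSums(dM)
    dX <- dX + tcrossprod(dM, W)
  }
  list(dX = dX, grads = grads)
}

# --- full encoder forward / backward --------------------------------------

initEncoderParams <- function(cfg) {
  rn <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  D <- cfg$dim; H <- cfg$mlpDim; heads <- cfg$heads
  c1 <- cfg$convChannels[1]; c2 <- cfg$convChannels[2]
  p <- list(
    conv1_W = rn(9, c1, 9), conv1_b = numeric(c1),
    conv2_W = rn(9 * c1, c2, 9 * c1), conv2_b = numeric(c2),
    patch_W = rn(cfg$patchDim, D, cfg$patchDim), patch_b = numeric(D),
    pos = matrix(stats::rnorm(cfg$nTokens * D, 0, 0.02), cfg$nTokens, D))
  for (l in seq_len(cfg$blocks)) {
    pre <- paste0("blk", l)
    p[[paste0(pre, "_ln1_g")]] <- rep(1, D)
    p[[paste0(pre, "_ln1_b")]] <- numeric(D)
    for (nm in c("q", "k", "v", "o")) {
      p[[paste0(pre, "_W", nm)]] <- rn(D, D, D)
      p[[paste0(pre, "_b", nm)]] <- numeric(D)
    }
    p[[paste0(pre, "_ln2_g")]] <- rep(1, D)
    p[[paste0(pre, "_ln2_b")]] <- numeric(D)
    p[[paste0(pre, "_mlp_W1")]] <- rn(D, H, D)
    p[[paste0(pre, "_mlp_b1")]] <- numeric(H)
    p[[paste0(pre, "_mlp_W2")]] <- rn(H, D, H)
    p[[paste0(pre, "_mlp_b2")]] <- numeric(D)
  }
  p$lnf_g <- rep(1, D); p$lnf_b <- numeric(D)
  p$proj_W <- rn(D, D, D); p$proj_b <- numeric(D)
  p$node_E <- matrix(stats::rnorm(2 * D, 0, 0.5), 2, D)
  p
}

encoderPlans <- function(cfg) {
  p1 <- convPlan(cfg$gridSize)
  p2 <- convPlan(p1$outSize)
  pp <- patchPlan(p2$outSize, cfg$patch, cfg$convChannels[2])
  list(conv1 = p1, conv2 = p2, patch = pp)
}

# x: gridSize x gridSize normalized map -> list(z = unit embedding, cache)
encForward <- function(x, p, cfg, plans) {
  cache <- list()
  a0 <- array(x, dim = c(cfg$gridSize, cfg$gridSize, 1))
  cv1 <- convForward(a0, p$conv1_W, p$conv1_b, plans$conv1)
  h1 <- pmax(cv1$out, 0)
  a1 <- array(h1, dim = c(plans$conv1$outSize, plans$conv1$outSize,
                          cfg$convChannels[1]))
  cv2 <- convForward(a1, p$conv2_W, p$conv2_b, plans$conv2)
  h2 <- pmax(cv2$out, 0)
  a2 <- array(h2, dim = c(plans$conv2$outSize, plans$conv2$outSize,
                          cfg$convChannels[2]))
  tok <- patchForward(a2, plans$patch)
  X0 <- sweep(tok %*% p$patch_W, 2, p$patch_b, `+`) + p$pos
  X <- X0
  for (l in seq_len(cfg$blocks)) {
    pre <- paste0("blk", l)
    ln1 <- lnForward(X, p[[paste0(pre, "_ln1_g")]], p[[paste0(pre, "_ln1_b")]])
    att <- mhaForward(ln1$out, p, pre, cfg$heads)
    X1 <- X + att$out
    ln2 <- lnForward(X1, p[[paste0(pre, "_ln2_g")]], p[[paste0(pre, "_ln2_b")]])
    Hpre <- sweep(ln2$out %*% p[[paste0(pre, "_mlp_W1")]], 2,
                  p[[paste0(pre, "_mlp_b1")]], `+`)
    Hact <- pmax(Hpre, 0)
    M <- sweep(Hact %*% p[[paste0(pre, "_mlp_W2")]], 2,
               p[[paste0(pre, "_mlp_b2")]], `+`)
    X2 <- X1 + M
    cache[[pre]] <- list(Xin = X, ln1 = ln1, att = att, X1 = X1, ln2 = ln2,
                         Hpre = Hpre, Hact = Hact)
    X <- X2
  }
  lnf <- lnForward(X, p$lnf_g, p$lnf_b)
  pooled <- colMeans(lnf$out)
  proj <- as.numeric(pooled %*% p$proj_W) + p$proj_b
  nrm <- sqrt(sum(proj^2))
  z <- proj / nrm
  cache$front <- list(cv1 = cv1, h1 = h1, cv2 = cv2, h2 = h2, tok = tok)
  cache$back <- list(Xlast = X, lnf = lnf, pooled = pooled, proj = proj,
                     nrm = nrm, z = z)
  list(z = z, cache = cache)
}

# dz: gradient wrt the unit embedding; accumulates into `grads`
encBackward <- function(dz, p, cfg, plans, cache, grads) {
  bk <- cache$back
  # through L2 normalization
  dproj <- (dz - bk$z * sum(dz * bk$z)) / bk$nrm
  grads$proj_W <- grads$proj_W + outer(bk$pooled, dproj)
  grads$proj_b <- grads$proj_b + dproj
  dpooled <- as.numeric(p$proj_W %*% dproj)
  T <- cfg$nTokens
  dLnfOut <- matrix(dpooled / T, T, cfg$dim, byrow = TRUE)
  lb <- lnBackward(dLnfOut, p$lnf_g, bk$lnf)
  grads$lnf_g <- grads$lnf_g + lb$dg
  grads$lnf_b <- grads$lnf_b + lb$db
  dX <- lb$dx
  for (l in rev(seq_len(cfg$blocks))) {
    pre <- paste0("blk", l)
    cc <- cache[[pre]]
    # MLP branch
    dM <- dX
    grads[[paste0(pre, "_mlp_W2")]] <- grads[[paste0(pre, "_mlp_W2")]] +
      crossprod(cc$Hact, dM)
    grads[[paste0(pre, "_mlp_b2")]] <- grads[[paste0(pre, "_mlp_b2")]] + colSums(dM)
    dH <- tcrossprod(dM, p[[paste0(pre, "_mlp_W2")]]) * (cc$Hpre > 0)
    grads[[paste0(pre, "_mlp_W1")]] <- grads[[paste0(pre, "_mlp_W1")]] +
      crossprod(cc$ln2$out, dH)
    grads[[paste0(pre, "_mlp_b1")]] <- grads[[paste0(pre, "_mlp_b1")]] + colSums(dH)
    dLn2Out <- tcrossprod(dH, p[[paste0(pre, "_mlp_W1")]])
    lb2 <- lnBackward(dLn2Out, p[[paste0(pre, "_ln2_g")]], cc$ln2)
    grads[[paste0(pre, "_ln2_g")]] <- grads[[paste0(pre, "_ln2_g")]] + lb2$dg
    grads[[paste0(pre, "_ln2_b")]] <- grads[[paste0(pre, "_ln2_b")]] + lb2$db
    dX1 <- dX + lb2$dx
    # attention branch
    mb <- mhaBackward(dX1, cc$ln1$out, p, pre, cfg$heads, cc$att, grads)
    grads <- mb$grads
    lb1 <- lnBackward(mb$dX, p[[paste0(pre, "_ln1_g")]], cc$ln1)
    grads[[paste0(pre, "_ln1_g")]] <- grads[[paste0(pre, "_ln1_g")]] + lb1$dg
    grads[[paste0(pre, "_ln1_b")]] <- grads[[paste0(pre, "_ln1_b")]] + lb1$db
    dX <- dX1 + lb1$dx
  }
  grads$pos <- grads$pos + dX
  fr <- cache$front
  grads$patch_W <- grads$patch_W + crossprod(fr$tok, dX)
  grads$patch_b <- grads$patch_b + colSums(dX)
  dTok <- tcrossprod(dX, p$patch_W)
  dA2 <- patchBackward(dTok, plans$patch)
  dH2 <- matrix(dA2, nrow = nrow(fr$h2)) * (fr$cv2$out > 0)
  cb2 <- convBackward(dH2, p$conv2_W, fr$cv2, plans$conv2, cfg$convChannels[1])
  grads$conv2_W <- grads$conv2_W + cb2$dW
  grads$conv2_b <- grads$conv2_b + cb2$db
  dH1 <- matrix(cb2$dx, nrow = nrow(fr$h1)) * (fr$cv1$out > 0)
  cb1 <- convBackward(dH1, p$conv1_W, fr$cv1, plans$conv1, 1L)
  grads$conv1_W <- grads$conv1_W + cb1$dW
  grads$conv1_b <- grads$conv1_b + cb1$db
  grads
}

zeroLike <- function(p) lapply(p, function(w) w * 0)

# --- symmetric InfoNCE between map embeddings and node embeddings ----------

# Z: B x D unit embeddings; E: 2 x D raw node table; y: class index 1/2.
# Returns loss plus gradients wrt Z and E.
infoNCE <- function(Z, E, y, temperature) {
  nrmE <- sqrt(rowSums(E^2))
  Nn <- E / nrmE
  S <- tcrossprod(Z, Nn) / temperature
  B <- nrow(Z)
  A <- softmaxRows(S)                     # map -> node direction
  Lmn <- -mean(log(pmax(A[cbind(seq_len(B), y)], 1e-300)))
  dS <- (A - (col(S) == y)) / B
  present <- sort(unique(y))
  Lnm <- 0
  for (c in present) {
    sc <- S[, c]
    lse <- max(sc) + log(sum(exp(sc - max(sc))))
    pos <- which(y == c)
    Lnm <- Lnm - mean(sc[pos] - lse)
    soft <- exp(sc - lse)
    add <- soft
    add[pos] <- add[pos] - 1 / length(pos)
    dS[, c] <- dS[, c] + add / length(present)
  }
  Lnm <- Lnm / length(present)
  loss <- (Lmn + Lnm) / 2
  dS <- dS / 2
  dZ <- (dS %*% Nn) / temperature
  dNn <- crossprod(dS, Z) / temperature
  dE <- (dNn - Nn * rowSums(dNn * Nn)) / nrmE
  list(loss = loss, dZ = dZ, dE = dE)
}
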