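# Attention stages. All variants map a per-channel sequence (T, N, d) to a
# sequence of the same shape, plus retrievable attention weights:
#   self     - learned Q/K/V projections, scaled dot-product, row softmax
#              (or the projection-free form when self_projection = FALSE)
#   mha      - h parallel heads of width floor(d/h), concatenated, re-projected
#   cross    - queries from one channel, keys/values from the feature-wise
#              concatenation of the other two channels
#   temporal - scalar score per timestep against the final hidden state,
#              softmax over T; output scaled so pooling yields the classical
#              context vector
#   channel  - squeeze-and-excitation gate: global average, two-layer
#              bottleneck, sigmoid feature scaling

attn_init <- function(variant, d, cfg) {
  switch(variant,
    self = if (cfg$self_projection)
      list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d))
    else list(),
    mha = {
      h <- cfg$mha_heads
      dh <- max(1L, d %/% h)
      heads <- lapply(seq_len(h), function(i)
        list(Wq = glorot(d, dh), Wk = glorot(d, dh), Wv = glorot(d, dh)))
      names(heads) <- paste0("h", seq_len(h))
      c(heads, list(Wo = glorot(h * dh, d)))
    },
    cross = list(Wq = glorot(d, d), Wk = glorot(2 * d, d), Wv = glorot(2 * d, d)),
    temporal = list(),
    channel = {
      r <- max(1L, d %/% 4L)
      list(W2 = glorot(d, r), b2 = numeric(r), W1 = glorot(r, d), b1 = numeric(d))
    },
    stop("unknown attention variant: ", variant, call. = FALSE))
}

# scaled dot-product attention for one window, given Q, K, V (T x dk each)
sdp_forward <- function(Q, K, V, dk) {
  A <- softmax_rows(Q %*% t(K) / sqrt(dk))
  list(O = A %*% V, A = A)
}

sdp_backward <- function(dO, Q, K, V, A, dk) {
  dV <- crossprod(A, dO)
  dA <- dO %*% t(V)
  dS <- softmax_rows_backward(dA, A) / sqrt(dk)
  list(dQ = dS %*% K, dK = crossprod(dS, Q), dV = dV)
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# Xs: list of 3 arrays (T, N, d). Returns outputs, caches and (optionally)
# per-channel attention weights: (N, T, T) for self/mha/cross, (N, T) for
# temporal, (N, d) gates for channel.
att_forward <- function(Xs, P, cfg, return_weights = FALSE) {
  variant <- cfg$attention_variant
  T <- dim(Xs[[1]])[1]; N <- dim(Xs[[1]])[2]; d <- dim(Xs[[1]])[3]
  outs <- vector("list", 3)
  caches <- vector("list", 3)
  weights <- if (return_weights) vector("list", 3) else NULL

  if (variant == "self") {
    proj <- isTRUE(cfg$self_projection)
    dummy <- matrix(0, 1, 1)
    for (c in 1:3) {
      Xc <- aperm(Xs[[c]], c(1, 3, 2))               # (T, d, N)
      p <- P[[c]]
      res <- self_attn_forward_cpp(Xc,
                                   if (proj) p$Wq else dummy,
                                   if (proj) p$Wk else dummy,
                                   if (proj) p$Wv else dummy, proj)
      outs[[c]] <- aperm(res$O, c(1, 3, 2))
      caches[[c]] <- list(Xc = Xc, A = res$A)
      if (return_weights) weights[[c]] <- aperm(res$A, c(3, 1, 2))
    }
    return(list(out = outs,
                cache = list(variant = variant, ch = caches, cfg = cfg,
                             P = P, dims = c(T, N, d)),
                weights = weights))
  }

  if (variant == "channel") {
    for (c in 1:3) {
      X <- Xs[[c]]; p <- P[[c]]
      Z <- colMeans(X, dims = 1)                       # N x d
      A1 <- sweep(Z %*% p$W2, 2, p$b2, "+")
      H1 <- A1 * (A1 > 0)
      G <- sigmoid(sweep(H1 %*% p$W1, 2, p$b1, "+"))   # N x d gates
      Gx <- array(rep(G, each = T), c(T, N, d))
      outs[[c]] <- X * Gx
      caches[[c]] <- list(X = X, Z = Z, A1 = A1, H1 = H1, G = G, p = p)
      if (return_weights) weights[[c]] <- G
    }
    return(list(out = outs, cache = list(variant = variant, ch = caches),
                weights = weights))
  }

  for (c in 1:3) {
    X <- Xs[[c]]
    p <- P[[c]]
    Ws <- if (return_weights && variant != "temporal") array(0, c(N, T, T))
          else if (return_weights) array(0, c(N, T))
    per_win <- vector("list", N)
    O <- array(0, dim(X))
    for (n in seq_len(N)) {
      Xn <- matrix(X[, n, ], T, d)
      if (variant == "mha") {
        h <- cfg$mha_heads; dh <- ncol(p$h1$Wq)
        heads <- vector("list", h)
        Ocat <- matrix(0, T, h * dh)
        Aavg <- matrix(0, T, T)
        for (i in seq_len(h)) {
          ph <- p[[paste0("h", i)]]
          Q <- Xn %*% ph$Wq; K <- Xn %*% ph$Wk; V <- Xn %*% ph$Wv
          s <- sdp_forward(Q, K, V, dh)
          Ocat[, ((i - 1) * dh + 1):(i * dh)] <- s$O
          heads[[i]] <- list(Q = Q, K = K, V = V, A = s$A)
          Aavg <- Aavg + s$A / h
        }
        s <- list(O = Ocat %*% p$Wo, A = Aavg)
        per_win[[n]] <- list(Xn = Xn, heads = heads, Ocat = Ocat)
      } else if (variant == "cross") {
        others <- setdiff(1:3, c)
        Xo <- cbind(matrix(Xs[[others[1]]][, n, ], T, d),
                    matrix(Xs[[others[2]]][, n, ], T, d))
        Q <- Xn %*% p$Wq; K <- Xo %*% p$Wk; V <- Xo %*% p$Wv
        s <- sdp_forward(Q, K, V, d)
        per_win[[n]] <- list(Xn = Xn, Xo = Xo, Q = Q, K = K, V = V, A = s$A,
                             others = others)
      } else if (variant == "temporal") {
        q <- Xn[T, ]
        sc <- as.numeric(Xn %*% q) / sqrt(d)
        a <- as.numeric(softmax_rows(matrix(sc, 1)))
        s <- list(O = T * a * Xn, A = a)
        per_win[[n]] <- list(Xn = Xn, a = a, q = q)
      }
      O[, n, ] <- s$O
      if (return_weights) {
        if (variant == "temporal") Ws[n, ] <- s$A else Ws[n, , ] <- s$A
      }
    }
    outs[[c]] <- O
    caches[[c]] <- per_win
    if (return_weights) weights[[c]] <- Ws
  }
  list(out = outs, cache = list(variant = variant, ch = caches, cfg = cfg,
                                P = P, dims = c(T, N, d)),
       weights = weights)
}

att_backward <- function(dYs, cache) {
  variant <- cache$variant
  if (variant == "self") {
    proj <- isTRUE(cache$cfg$self_projection)
    dummy <- matrix(0, 1, 1)
    dXs <- vector("list", 3); grads <- vector("list", 3)
    for (c in 1:3) {
      cc <- cache$ch[[c]]
      p <- cache$P[[c]]
      bk <- self_attn_backward_cpp(cc$Xc,
                                   if (proj) p$Wq else dummy,
                                   if (proj) p$Wk else dummy,
                                   if (proj) p$Wv else dummy,
                                   cc$A, aperm(dYs[[c]], c(1, 3, 2)), proj)
      dXs[[c]] <- aperm(bk$dX, c(1, 3, 2))
      grads[[c]] <- if (proj) list(Wq = bk$dWq, Wk = bk$dWk, Wv = bk$dWv)
                    else list()
    }
    return(list(dXs = dXs, grads = grads))
  }
  if (variant == "channel") {
    dXs <- vector("list", 3); grads <- vector("list", 3)
    for (c in 1:3) {
      cc <- cache$ch[[c]]
      X <- cc$X; T <- dim(X)[1]; N <- dim(X)[2]; d <- dim(X)[3]
      dY <- dYs[[c]]
      Gx <- array(rep(cc$G, each = T), c(T, N, d))
      dX <- dY * Gx
      dG <- apply(dY * X, c(2, 3), sum)                  # N x d
      dA2 <- dG * cc$G * (1 - cc$G)
      dH1 <- dA2 %*% t(cc$p$W1)
      dA1 <- dH1 * (cc$A1 > 0)
      dZ <- dA1 %*% t(cc$p$W2)
      dX <- dX + array(rep(dZ / T, each = T), c(T, N, d))
      dXs[[c]] <- dX
      grads[[c]] <- list(W2 = crossprod(cc$Z, dA1), b2 = colSums(dA1),
                         W1 = crossprod(cc$H1, dA2), b1 = colSums(dA2))
    }
    return(list(dXs = dXs, grads = grads))
  }

  cfg <- cache$cfg
  dims <- cache$dims; T <- dims[1]; N <- dims[2]; d <- dims[3]
  P <- cache$P
  dXs <- lapply(1:3, function(c) array(0, c(T, N, d)))
  grads <- lapply(1:3, function(c)
    if (is.list(P[[c]]) && length(P[[c]])) zero_like(P[[c]]) else list())

  for (c in 1:3) {
    per_win <- cache$ch[[c]]
    p <- P[[c]]
    for (n in seq_len(N)) {
      w <- per_win[[n]]
      dO <- matrix(dYs[[c]][, n, ], T, d)
      if (variant == "mha") {
        h <- cfg$mha_heads; dh <- ncol(p$h1$Wq)
        dOcat <- dO %*% t(p$Wo)
        grads[[c]]$Wo <- grads[[c]]$Wo + crossprod(w$Ocat, dO)
        dXn <- matrix(0, T, d)
        for (i in seq_len(h)) {
          hd <- w$heads[[i]]
          ph <- p[[paste0("h", i)]]
          dOi <- dOcat[, ((i - 1) * dh + 1):(i * dh), drop = FALSE]
          g <- sdp_backward(dOi, hd$Q, hd$K, hd$V, hd$A, dh)
          key <- paste0("h", i)
          grads[[c]][[key]]$Wq <- grads[[c]][[key]]$Wq + crossprod(w$Xn, g$dQ)
          grads[[c]][[key]]$Wk <- grads[[c]][[key]]$Wk + crossprod(w$Xn, g$dK)
          grads[[c]][[key]]$Wv <- grads[[c]][[key]]$Wv + crossprod(w$Xn, g$dV)
          dXn <- dXn + g$dQ %*% t(ph$Wq) + g$dK %*% t(ph$Wk) + g$dV %*% t(ph$Wv)
        }
        dXs[[c]][, n, ] <- dXs[[c]][, n, ] + dXn
      } else if (variant == "cross") {
        g <- sdp_backward(dO, w$Q, w$K, w$V, w$A, d)
        grads[[c]]$Wq <- grads[[c]]$Wq + crossprod(w$Xn, g$dQ)
        grads[[c]]$Wk <- grads[[c]]$Wk + crossprod(w$Xo, g$dK)
        grads[[c]]$Wv <- grads[[c]]$Wv + crossprod(w$Xo, g$dV)
        dXs[[c]][, n, ] <- dXs[[c]][, n, ] + g$dQ %*% t(p$Wq)
        dXo <- g$dK %*% t(p$Wk) + g$dV %*% t(p$Wv)
        o1 <- w$others[1]; o2 <- w$others[2]
        dXs[[o1]][, n, ] <- dXs[[o1]][, n, ] + dXo[, 1:d, drop = FALSE]
        dXs[[o2]][, n, ] <- dXs[[o2]][, n, ] + dXo[, (d + 1):(2 * d), drop = FALSE]
      } else if (variant == "temporal") {
        a <- w$a; Xn <- w$Xn; q <- w$q
        dX <- T * a * dO                       # row-scaled
        da <- T * rowSums(dO * Xn)
        ds <- a * (da - sum(a * da))
        dX <- dX + outer(ds, q) / sqrt(d)
        dq <- as.numeric(crossprod(Xn, ds)) / sqrt(d)
        dX[T, ] <- dX[T, ] + dq
        dXs[[c]][, n, ] <- dXs[[c]][, n, ] + dX
      }
    }
  }
  list(dXs = dXs, grads = grads)
}
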