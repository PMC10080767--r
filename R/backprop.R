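## Hand-derived reverse-mode gradients for the three-tier attention
## network. The derivation mirrors the forward pass in attention-model.R
## exactly: classifier -> level attention -> relation attention ->
## per-head neighbour attention. Validated against central finite
## differences in the test suite.

## gradient of the class-weighted cross-entropy w.r.t. the logits
loss_grad_logits <- function(logits, labels, mask, class_weights) {
  n <- nrow(logits)
  G <- matrix(0, n, 2L)
  y <- labels[mask]
  L <- logits[mask, , drop = FALSE]
  m <- pmax(L[, 1], L[, 2])
  P <- exp(L - m)
  P <- P / rowSums(P)
  Y <- cbind(1 - y, y)
  w <- class_weights[y + 1L]
  G[mask, ] <- (w / sum(w)) * (P - Y)
  G
}

## full backward pass; returns a flat grad list mirroring params$par
mhamfd_backward <- function(cache, params, logits, labels, mask,
                            class_weights = c(1, 1)) {
  par <- params$par; dims <- params$dims; levels <- params$levels
  n <- nrow(cache$H); d <- dims$d; K <- dims$K; dh <- dims$dh
  slope <- dims$leaky_slope
  grads <- lapply(par, function(p) array(0, dim = dim(p) %||% length(p)))
  grads <- lapply(grads, function(g) if (length(dim(g)) == 1L) as.vector(g) else g)
  names(grads) <- names(par)

  dlogits <- loss_grad_logits(logits, labels, mask, class_weights)
  if (!is.null(par$Wc)) {
    grads$Wc <- t(cache$H) %*% dlogits
    dH <- dlogits %*% t(par$Wc)
  } else {
    hd <- cache$head
    grads$Wc2 <- t(hd$Ha) %*% dlogits
    dHa <- dlogits %*% t(par$Wc2)
    dhp <- dHa * elu_grad_from_pre(hd$hp)
    grads$Wc1 <- t(cache$H) %*% dhp
    grads$bc1 <- colSums(dhp)
    dH <- dhp %*% t(par$Wc1)
  }

  ## hierarchical tier
  lev_names <- names(cache$x_lev)
  gamma <- cache$gamma
  dgamma <- vapply(lev_names, function(m) sum(dH * cache$x_lev[[m]]), 0)
  dlambda <- gamma * (dgamma - sum(gamma * dgamma))
  dx_lev <- list()
  for (mi in seq_along(lev_names)) {
    m <- lev_names[mi]
    dxm <- gamma[mi] * dH
    t1 <- cache$t1[[m]]
    coef <- dlambda[mi] / n
    dpre1 <- (coef * matrix(par$q1, n, dims$datt, byrow = TRUE)) * (1 - t1^2)
    grads$W1 <- grads$W1 + t(cache$x_lev[[m]]) %*% dpre1
    grads$b1 <- grads$b1 + colSums(dpre1)
    grads$q1 <- grads$q1 + coef * colSums(t1)
    dxm <- dxm + dpre1 %*% t(par$W1)
    dx_lev[[m]] <- dxm
  }

  ## inter-relation tier (softmax within each level)
  beta <- cache$beta
  dx_rel <- list()
  for (lv in sort(unique(levels))) {
    rels <- names(levels)[levels == lv]
    dxm <- dx_lev[[as.character(lv)]]
    dbeta <- vapply(rels, function(r) sum(dxm * cache$x_rel[[r]]), 0)
    b <- beta[rels]
    domega <- b * (dbeta - sum(b * dbeta))
    for (ri in seq_along(rels)) {
      r <- rels[ri]
      dxr <- b[ri] * dxm
      t0 <- cache$t0[[r]]
      coef <- domega[ri] / n
      dpre0 <- (coef * matrix(par$q0, n, dims$datt, byrow = TRUE)) * (1 - t0^2)
      grads$W0 <- grads$W0 + t(cache$x_rel[[r]]) %*% dpre0
      grads$b0 <- grads$b0 + colSums(dpre0)
      grads$q0 <- grads$q0 + coef * colSums(t0)
      dxr <- dxr + dpre0 %*% t(par$W0)
      dx_rel[[r]] <- dxr
    }
  }

  ## intra-relation tier (compiled kernel, all heads of one relation)
  Xd <- cache$Xd
  for (rel in names(levels)) {
    rc <- cache$rel[[rel]]
    g <- .intra_bwd(dx_rel[[rel]], rc$Z, Xd,
                    par[[paste0("a1.", rel)]], par[[paste0("a2.", rel)]],
                    rc$alpha, rc$pre, rc$spos,
                    rc$alphad, rc$dmask,
                    1 - dims$dropout, slope)
    grads[[paste0("W.", rel)]] <- g$gW
    grads[[paste0("a1.", rel)]] <- g$ga1
    grads[[paste0("a2.", rel)]] <- g$ga2
  }
  grads
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## one Adam step with decoupled-from-loss L2 (classic Adam: decay added to
## the gradient of every weight, never to biases)
adam_step <- function(par, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bias_names <- c("b0", "b1", "bc1")
  for (nm in names(par)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && !(nm %in% bias_names)) g <- g + weight_decay * par[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = state)
}

adam_init <- function(par) {
  zero <- lapply(par, function(p) p * 0)
  list(t = 0L, m = zero, v = zero)
}
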