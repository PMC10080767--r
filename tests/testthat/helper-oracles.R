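# Independent oracles used across the test files. Deliberately written
# as plain nested loops, sharing no code with the package internals.

# claims table from parallel vectors, for hand-built fixtures
make_claims <- function(p, t, d, m, lab = NULL) {
  if (is.null(lab)) lab <- rep(NA_integer_, length(p))
  mhamfd:::new_claims(p, as.Date(t), d, m, lab)
}

# brute-force O(n^2 v^2) pairwise-visit scan for one set of shared types
oracle_adjacency <- function(claims, shared) {
  patients <- unique(claims$patient_id)
  # same visit dedup rule as the graph builder
  key <- paste(claims$patient_id, format(claims$visit_date), claims$department_id,
               vapply(claims$medicine_ids, function(m) paste(sort(m), collapse = "|"), ""))
  cl <- claims[!duplicated(key), ]
  n <- length(patients)
  A <- matrix(FALSE, n, n, dimnames = list(patients, patients))
  for (i in seq_len(nrow(cl))) {
    for (j in seq_len(nrow(cl))) {
      pi <- cl$patient_id[i]; pj <- cl$patient_id[j]
      if (pi == pj) next
      ok <- TRUE
      if ("D" %in% shared && cl$department_id[i] != cl$department_id[j]) ok <- FALSE
      if (ok && "T" %in% shared && cl$visit_date[i] != cl$visit_date[j]) ok <- FALSE
      if (ok && "M" %in% shared &&
          length(intersect(cl$medicine_ids[[i]], cl$medicine_ids[[j]])) == 0L) ok <- FALSE
      if (ok) A[pi, pj] <- TRUE
    }
  }
  A
}

# random small claim population for property tests (independent of the
# package's simulator)
random_claims <- function(n_patients, max_visits = 5L, n_dep = 4L,
                          n_dates = 6L, n_med = 5L) {
  p <- character(); t <- character(); d <- character(); m <- list()
  for (i in seq_len(n_patients)) {
    nv <- sample(max_visits, 1L)
    for (v in seq_len(nv)) {
      p <- c(p, sprintf("p%02d", i))
      t <- c(t, format(as.Date("2018-03-01") + sample(n_dates, 1L)))
      d <- c(d, sprintf("d%d", sample(n_dep, 1L)))
      m <- c(m, list(sample(sprintf("m%d", seq_len(n_med)),
                            sample(0:3, 1L))))
    }
  }
  make_claims(p, t, d, m)
}

# plain-loop dense forward pass: scores -> masked softmax -> weighted sum
# per head, then relation/level attention and classifier
oracle_forward <- function(X, masks, params) {
  par <- params$par; dims <- params$dims; levels <- params$levels
  n <- nrow(X); K <- dims$K; dh <- dims$dh
  lrelu <- function(x) ifelse(x > 0, x, dims$leaky_slope * x)
  elu_ <- function(x) ifelse(x > 0, x, exp(x) - 1)
  x_rel <- list()
  for (rel in names(levels)) {
    W <- par[[paste0("W.", rel)]]
    a1 <- par[[paste0("a1.", rel)]]; a2 <- par[[paste0("a2.", rel)]]
    mask <- masks[[rel]]
    out <- matrix(0, n, K * dh)
    for (k in seq_len(K)) {
      Wk <- W[, ((k - 1) * dh + 1):(k * dh), drop = FALSE]
      Z <- X %*% Wk
      for (i in seq_len(n)) {
        att <- which(mask[i, ])
        e <- vapply(att, function(j)
          lrelu(sum(a1[, k] * Z[i, ]) + sum(a2[, k] * Z[j, ])), 0)
        a <- exp(e - max(e)); a <- a / sum(a)
        agg <- rep(0, dh)
        for (jj in seq_along(att)) agg <- agg + a[jj] * Z[att[jj], ]
        out[i, ((k - 1) * dh + 1):(k * dh)] <- elu_(agg)
      }
    }
    x_rel[[rel]] <- out
  }
  score_of <- function(x, W, b, q) {
    s <- 0
    for (i in seq_len(nrow(x))) s <- s + sum(q * tanh(drop(t(W) %*% x[i, ]) + b))
    s / nrow(x)
  }
  x_lev <- list(); beta_all <- c()
  for (lv in sort(unique(levels))) {
    rels <- names(levels)[levels == lv]
    om <- vapply(rels, function(r) score_of(x_rel[[r]], par$W0, par$b0, par$q0), 0)
    b <- exp(om - max(om)); b <- b / sum(b)
    xm <- matrix(0, n, dims$d)
    for (ri in seq_along(rels)) xm <- xm + b[ri] * x_rel[[rels[ri]]]
    x_lev[[as.character(lv)]] <- xm
    beta_all <- c(beta_all, stats::setNames(b, rels))
  }
  lam <- vapply(x_lev, function(xm) score_of(xm, par$W1, par$b1, par$q1), 0)
  g <- exp(lam - max(lam)); g <- g / sum(g)
  H <- matrix(0, n, dims$d)
  for (mi in seq_along(x_lev)) H <- H + g[mi] * x_lev[[mi]]
  logits <- if (!is.null(par$Wc)) H %*% par$Wc else {
    Ha <- t(apply(H, 1, function(r) {
      z <- drop(t(par$Wc1) %*% r) + par$bc1
      ifelse(z > 0, z, exp(z) - 1)
    }))
    Ha %*% par$Wc2
  }
  list(H = H, logits = logits, beta = beta_all, gamma = unname(g))
}

# tiny deterministic fixture shared by several model tests
model_fixture <- function(n_feat = 4, seed = 7) {
  sim <- simulate_claims(n_fraud = 4, n_normal = 6, ring_size = 2,
                         n_departments = 3, n_dates = 10, n_medicines = 6,
                         co_visits_per_ring = 2,
                         background_visits_per_patient = 2,
                         medicines_per_visit = 2, seed = seed)
  X <- simulate_features(sim$labels, k = n_feat, seed = seed)
  g <- build_hetero_graph(sim$claims, X)
  adjs <- build_all_relation_graphs(g)
  ctrl <- mhamfd_control(embed_dim = 8, heads = 2, att_dim = 6)
  params <- init_params(n_feat, lapply(adjs, `[[`, "path"), ctrl, seed = seed)
  list(sim = sim, X = g$features, g = g, adjs = adjs, ctrl = ctrl,
       params = params, labels = unname(g$labels),
       masks = mhamfd:::attention_masks(adjs))
}
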