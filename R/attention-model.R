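## Three-tier attention network over behavioural-relationship graphs.
## Tier 1 (intra-relation): multi-head neighbour attention within one
## relation graph. Tier 2 (inter-relation): attention over the relation
## embeddings of one level. Tier 3 (hierarchical): attention over the
## level embeddings. A classification head (linear or one-hidden-layer
## MLP) maps the final embedding H to fraud/non-fraud logits. Gradients are hand-derived in R/backprop.R.

leaky_relu <- function(x, slope = 0.2) pmax(x, 0) + slope * pmin(x, 0)
elu <- function(x) pmax(x, 0) + expm1(pmin(x, 0))
elu_grad_from_pre <- function(pre) {
  g <- exp(pmin(pre, 0))
  g[pre > 0] <- 1
  g
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Model hyper-parameters and training control
#'
#' Collects every tunable of the attention network and its training loop.
#' The defaults are the reference settings of the architecture: Adam with
#' learning rate 0.005, 8 attention heads, 64-dimensional embeddings,
#' 128-dimensional attention vectors, L2 weight decay 0.001, dropout 0.6
#' and early-stopping patience 50.
#'
#' @param embed_dim Patient embedding dimension d (divisible by `heads`).
#' @param att_dim Dimension of the inter/hierarchical attention space.
#' @param heads Number of intra-relation attention heads K.
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient, applied by the optimiser to all
#'   weight matrices and attention vectors but not to biases.
#' @param dropout Drop probability applied to input features and to the
#'   attention coefficients during training.
#' @param patience Early stopping: training halts when validation loss has
#'   not reached a new minimum and validation accuracy has not reached a
#'   new maximum for this many consecutive epochs.
#' @param max_epochs Hard cap on training epochs.
#' @param split_ratio Length-3 positive weights for train:validation:test.
#' @param class_weights `"auto"` (default: plain cross-entropy when the
#'   training classes are roughly balanced, inverse-frequency weights
#'   normalised to mean 1 when the minority class falls below 20%),
#'   `"inverse"`, `"none"`, or a numeric length-2 vector (non-fraud,
#'   fraud).
#' @param classifier_hidden Width of the classification head's hidden
#'   layer (ELU); `0` uses a plain linear map from the embedding to the
#'   two class logits.
#' @param max_level Highest behavioural-relationship level used (1..3).
#' @param leaky_slope Negative slope of the LeakyReLU in the neighbour
#'   attention scorer.
#' @param max_neighbors Optional per-patient neighbour cap (see
#'   [cap_neighbors()]); `Inf` keeps every neighbour.
#' @param verbose Print per-epoch progress during training.
#' @return A list of class `mhamfd_control`.
#' @export
mhamfd_control <- function(embed_dim = 64L, att_dim = 128L, heads = 8L,
                           learning_rate = 0.005, weight_decay = 0.001,
                           dropout = 0.6, patience = 50L, max_epochs = 500L,
                           split_ratio = c(3, 1, 1),
                           class_weights = "auto", classifier_hidden = 64L,
                           max_level = 3L,
                           leaky_slope = 0.2, max_neighbors = Inf,
                           verbose = FALSE) {
  stopifnot(embed_dim >= 1, heads >= 1, embed_dim %% heads == 0,
            att_dim >= 1, learning_rate > 0, weight_decay >= 0,
            dropout >= 0, dropout < 1, patience >= 1, max_epochs >= 1,
            length(split_ratio) == 3, all(split_ratio > 0),
            classifier_hidden >= 0, max_level %in% 1:3)
  structure(list(embed_dim = as.integer(embed_dim),
                 att_dim = as.integer(att_dim), heads = as.integer(heads),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 dropout = dropout, patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 split_ratio = split_ratio, class_weights = class_weights,
                 classifier_hidden = as.integer(classifier_hidden),
                 max_level = as.integer(max_level),
                 leaky_slope = leaky_slope, max_neighbors = max_neighbors,
                 verbose = isTRUE(verbose)),
            class = "mhamfd_control")
}

#' Initialise model parameters
#'
#' Glorot-uniform initialisation for all weight matrices and attention
#' vectors, zeros for biases, deterministic under `seed`. Per relation and
#' head there is a projection matrix (`k_in` to `d/K`) and a length
#' `2 d/K` pair-scoring vector; the inter and hierarchical tiers each have
#' a weight matrix (`d` to `att_dim`), bias and attention vector, and the
#' classification head is either linear (`d x 2`) or a one-hidden-layer
#' MLP (`d -> classifier_hidden -> 2`, ELU), per the control.
#'
#' @param k_in Input feature dimension.
#' @param relations Either a list of `relation_path` objects or a named
#'   integer vector of levels (names = relation names).
#' @param control A [mhamfd_control()] list (dims and heads are read from
#'   it).
#' @param seed Integer RNG seed.
#' @return A list of class `mhamfd_params`: `par` (named flat list of
#'   arrays), `dims`, and `levels` (named integer vector per relation).
#' @export
init_params <- function(k_in, relations, control = mhamfd_control(), seed = 1L) {
  stopifnot(k_in >= 1)
  d <- control$embed_dim; K <- control$heads; datt <- control$att_dim
  if (d %% K != 0) stop("embed_dim must be divisible by heads")
  dh <- d %/% K
  if (is.list(relations)) {
    levels <- vapply(relations, `[[`, 0L, "level")
    names(levels) <- vapply(relations, `[[`, "", "name")
  } else {
    levels <- relations
  }
  set.seed(as.integer(seed))
  par <- list()
  for (rel in names(levels)) {
    # heads stored side by side: columns ((k-1)*dh+1):(k*dh) belong to head k
    par[[paste0("W.", rel)]] <- do.call(cbind, replicate(K, glorot(k_in, dh),
                                                         simplify = FALSE))
    par[[paste0("a1.", rel)]] <- glorot(dh, K)
    par[[paste0("a2.", rel)]] <- glorot(dh, K)
  }
  par$W0 <- glorot(d, datt); par$b0 <- numeric(datt); par$q0 <- drop(glorot(datt, 1))
  par$W1 <- glorot(d, datt); par$b1 <- numeric(datt); par$q1 <- drop(glorot(datt, 1))
  if (control$classifier_hidden > 0L) {
    h <- control$classifier_hidden
    par$Wc1 <- glorot(d, h); par$bc1 <- numeric(h); par$Wc2 <- glorot(h, 2L)
  } else {
    par$Wc <- glorot(d, 2L)
  }
  structure(list(par = par,
                 dims = list(k_in = as.integer(k_in), d = d, K = K,
                             dh = dh, datt = datt,
                             leaky_slope = control$leaky_slope,
                             dropout = control$dropout),
                 levels = levels),
            class = "mhamfd_params")
}

## logical n x n attended-set masks (neighbours plus self) per relation,
## with the -Inf/0 additive masks precomputed as an attribute
attention_masks <- function(adjs) {
  masks <- lapply(adjs, function(a) {
    M <- adjacency_matrix(a)
    diag(M) <- TRUE
    M
  })
  names(masks) <- names(adjs)
  attr(masks, "imasks") <- lapply(masks, function(M) {
    storage.mode(M) <- "integer"
    M
  })
  masks
}

## row-wise softmax of a masked score matrix; off-mask entries get weight 0
masked_softmax <- function(S, mask) {
  S[!mask] <- -Inf
  n <- nrow(S)
  m <- S[cbind(seq_len(n), max.col(S, ties.method = "first"))]
  P <- exp(S - m)
  P[!mask] <- 0
  P / rowSums(P)
}

## one relation, all heads; thin wrapper over the compiled kernel.
## Returns x (n x d), Z, and cube caches alpha/pre/spos (+ alphad, dmask
## when training; E when keep_E).
intra_forward <- function(Xd, mask, W, a1, a2, dims, training,
                          keep_E = TRUE, imask = NULL) {
  if (is.null(imask)) {
    imask <- mask
    storage.mode(imask) <- "integer"
  }
  .intra_fwd(Xd, W, a1, a2, imask, training,
             1 - dims$dropout, dims$leaky_slope, keep_E)
}

## relation-weighting score shared by the inter and hierarchical tiers:
## omega = mean_i q' tanh(W' x_i + b)
att_score <- function(x, W, b, q) {
  t_ <- tanh(sweep(x %*% W, 2L, b, "+"))
  list(score = mean(t_ %*% q), t = t_)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Full forward pass of the attention network
#'
#' Composes the three aggregation tiers and the linear classifier:
#' neighbour attention within every relation graph, relation attention
#' within each level, level attention across levels, then fraud logits.
#'
#' @param X Numeric feature matrix (patients x k).
#' @param adjs Named list of `relation_adjacency` objects (e.g. from
#'   [build_all_relation_graphs()]), or precomputed logical masks with an
#'   attribute-free named list passed through `masks`.
#' @param params A `mhamfd_params` object.
#' @param training Apply dropout (to features and attention coefficients)?
#'   Uses the current RNG stream.
#' @param keep_cache Retain intermediate quantities needed for the
#'   backward pass (internal use; large).
#' @param masks Optional precomputed attended-set masks (overrides
#'   `adjs`).
#' @param report Build the `attention_report` (set `FALSE` inside the
#'   training loop to save memory)?
#' @return A list: `H` (n x d final embeddings), `logits` (n x 2),
#'   `report` (an `attention_report`, see [attention_report()]), and
#'   `cache` (if requested).
#' @export
mhamfd_forward <- function(X, adjs, params, training = FALSE,
                           keep_cache = FALSE, masks = NULL, report = TRUE) {
  stopifnot(inherits(params, "mhamfd_params"))
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  if (is.null(masks)) masks <- attention_masks(adjs)
  levels <- params$levels
  stopifnot(all(names(levels) %in% names(masks)))
  dims <- params$dims; par <- params$par
  n <- nrow(X)
  keep <- 1 - dims$dropout
  drop_fn <- function(M) {
    dm <- matrix(stats::runif(length(M)) < keep, nrow(M), ncol(M))
    (M * dm) / keep
  }
  Xd <- if (training && dims$dropout > 0) drop_fn(X) else X

  imasks <- attr(masks, "imasks")
  rel_cache <- list(); x_rel <- list()
  for (rel in names(levels)) {
    fw <- intra_forward(Xd, masks[[rel]], par[[paste0("W.", rel)]],
                        par[[paste0("a1.", rel)]], par[[paste0("a2.", rel)]],
                        dims, training && dims$dropout > 0,
                        keep_E = report, imask = imasks[[rel]])
    x_rel[[rel]] <- fw$x
    rel_cache[[rel]] <- fw
  }

  lev_present <- sort(unique(levels))
  omega <- stats::setNames(numeric(length(levels)), names(levels))
  beta <- stats::setNames(numeric(length(levels)), names(levels))
  x_lev <- list(); t0 <- list()
  for (lv in lev_present) {
    rels <- names(levels)[levels == lv]
    sc <- lapply(x_rel[rels], att_score, W = par$W0, b = par$b0, q = par$q0)
    omega[rels] <- vapply(sc, `[[`, 0, "score")
    beta[rels] <- softmax_vec(omega[rels])
    xm <- matrix(0, n, dims$d)
    for (rel in rels) xm <- xm + beta[rel] * x_rel[[rel]]
    x_lev[[as.character(lv)]] <- xm
    t0[rels] <- lapply(sc, `[[`, "t")
  }

  sc1 <- lapply(x_lev, att_score, W = par$W1, b = par$b1, q = par$q1)
  lambda <- vapply(sc1, `[[`, 0, "score")
  gamma <- softmax_vec(lambda)
  H <- matrix(0, n, dims$d)
  for (m in seq_along(x_lev)) H <- H + gamma[m] * x_lev[[m]]
  head_cache <- NULL
  if (!is.null(par$Wc)) {
    logits <- H %*% par$Wc
  } else {
    hp <- sweep(H %*% par$Wc1, 2L, par$bc1, "+")
    Ha <- elu(hp)
    logits <- Ha %*% par$Wc2
    head_cache <- list(hp = hp, Ha = Ha)
  }
  rownames(H) <- rownames(logits) <- rownames(X)

  rpt <- if (report) attention_report(rel_cache, masks, levels, omega, beta,
                                      lambda, gamma)
  out <- list(H = H, logits = logits, report = rpt)
  if (keep_cache)
    out$cache <- list(Xd = Xd, rel = rel_cache, x_rel = x_rel,
                      x_lev = x_lev, t0 = t0, head = head_cache,
                      t1 = lapply(sc1, `[[`, "t"),
                      omega = omega, beta = beta, lambda = lambda,
                      gamma = gamma, H = H, masks = masks,
                      training = training)
  out
}

#' Assemble an attention report
#'
#' Gathers every attention quantity of one forward pass: per relation the
#' head-averaged pre-softmax neighbour scores E and coefficients alpha
#' (off-mask entries `NA` resp. 0), per level the relation scores omega
#' and weights beta, and the level scores lambda and weights gamma.
#'
#' @param rel_cache,masks,levels,omega,beta,lambda,gamma Internal pieces
#'   of a forward pass.
#' @return A list of class `attention_report`.
#' @keywords internal
attention_report <- function(rel_cache, masks, levels, omega, beta,
                             lambda, gamma) {
  alpha <- list(); E <- list()
  for (rel in names(rel_cache)) {
    rc <- rel_cache[[rel]]
    K <- dim(rc$alpha)[3]
    am <- rowSums(rc$alpha, dims = 2) / K
    em <- rowSums(rc$E, dims = 2) / K
    em[!masks[[rel]]] <- NA_real_
    alpha[[rel]] <- am
    E[[rel]] <- em
  }
  lev_present <- sort(unique(levels))
  beta_by_level <- lapply(lev_present, function(lv) beta[names(levels)[levels == lv]])
  names(beta_by_level) <- paste0("level", lev_present)
  names(gamma) <- names(lambda) <- paste0("level", lev_present)
  structure(list(alpha = alpha, E = E, omega = omega,
                 beta = beta, beta_by_level = beta_by_level,
                 lambda = lambda, gamma = gamma, levels = levels),
            class = "attention_report")
}

#' @export
print.attention_report <- function(x, digits = 3, ...) {
  cat("Attention weights\n")
  cat("  levels (gamma): ",
      paste(sprintf("%s=%.*f", names(x$gamma), digits, x$gamma),
            collapse = "  "), "\n")
  for (lv in names(x$beta_by_level)) {
    b <- x$beta_by_level[[lv]]
    cat(sprintf("  %s relations (beta): %s\n", lv,
                paste(sprintf("%s=%.*f", names(b), digits, b), collapse = "  ")))
  }
  invisible(x)
}

#' Serialise an attention report as JSON
#'
#' Writes the two interpretability summaries of a fitted model: the
#' attention value per level of behavioural relationship (gamma) and the
#' attention value per behavioural relationship within its level (beta).
#'
#' @param report An `attention_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_attention_json <- function(report, path) {
  jsonlite::write_json(
    list(level_attention = as.list(report$gamma),
         relation_attention = lapply(report$beta_by_level, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Intra-relation aggregation for a single relation
#'
#' Multi-head neighbour attention over one behavioural-relationship
#' graph. For each head, pair scores are a LeakyReLU (slope
#' `leaky_slope`) of a learned linear function of the projected target
#' and neighbour features; the scores are softmax-normalised over the
#' attended set (the patient's neighbours plus itself) and used to
#' average the projected neighbour features, followed by an ELU. Head
#' outputs are concatenated.
#'
#' @param X Feature matrix (patients x k).
#' @param adj A `relation_adjacency` whose patients match `rownames(X)`
#'   (or positional order).
#' @param params A `mhamfd_params` containing this relation.
#' @param training Apply dropout.
#' @return A list: `x` (n x d relation embedding), `alpha` (list of
#'   per-head coefficient matrices).
#' @export
intra_aggregate <- function(X, adj, params, training = FALSE) {
  rel <- adj$path$name
  if (!paste0("W.", rel) %in% names(params$par))
    stop("no parameters for relation ", rel)
  if (any(!is.finite(X))) stop("feature matrix contains non-finite values")
  mask <- attention_masks(list(adj))[[1L]]
  dims <- params$dims
  keep <- 1 - dims$dropout
  Xd <- if (training && dims$dropout > 0) {
    dm <- matrix(stats::runif(length(X)) < keep, nrow(X), ncol(X))
    (X * dm) / keep
  } else X
  fw <- intra_forward(Xd, mask, params$par[[paste0("W.", rel)]],
                      params$par[[paste0("a1.", rel)]],
                      params$par[[paste0("a2.", rel)]],
                      dims, training && dims$dropout > 0)
  K <- dim(fw$alpha)[3]
  list(x = fw$x, alpha = lapply(seq_len(K), function(k) fw$alpha[, , k]))
}

#' Inter-relation aggregation within one level
#'
#' Scores each relation embedding by the mean over patients of
#' `q0' tanh(W0 x + b0)`, softmax-normalises the scores into relation
#' weights beta, and returns the beta-weighted sum as the level
#' embedding.
#'
#' @param xs List of relation embedding matrices (same shape).
#' @param params A `mhamfd_params`.
#' @return A list: `x_m` (level embedding), `beta` (weights, sum 1),
#'   `omega` (raw scores).
#' @export
inter_aggregate <- function(xs, params) {
  stopifnot(length(xs) >= 1)
  shp <- vapply(xs, dim, integer(2))
  if (any(shp != shp[, 1])) stop("relation embeddings differ in shape")
  sc <- lapply(xs, att_score, W = params$par$W0, b = params$par$b0,
               q = params$par$q0)
  omega <- vapply(sc, `[[`, 0, "score")
  beta <- softmax_vec(omega)
  x_m <- Reduce(`+`, Map(`*`, as.list(beta), xs))
  list(x_m = x_m, beta = beta, omega = omega)
}

#' Hierarchical aggregation across levels
#'
#' Same attention form as [inter_aggregate()] with the level parameters
#' (`W1`, `b1`, `q1`): level embeddings are scored, softmax-normalised
#' into level weights gamma, and summed into the final embedding H.
#'
#' @param xs List of level embedding matrices.
#' @param params A `mhamfd_params`.
#' @return A list: `H`, `gamma`, `lambda` (raw scores).
#' @export
hierar_aggregate <- function(xs, params) {
  stopifnot(length(xs) >= 1)
  shp <- vapply(xs, dim, integer(2))
  if (any(shp != shp[, 1])) stop("level embeddings differ in shape")
  sc <- lapply(xs, att_score, W = params$par$W1, b = params$par$b1,
               q = params$par$q1)
  lambda <- vapply(sc, `[[`, 0, "score")
  gamma <- softmax_vec(lambda)
  H <- Reduce(`+`, Map(`*`, as.list(gamma), xs))
  list(H = H, gamma = gamma, lambda = lambda)
}

#' Class-weighted cross-entropy loss
#'
#' Mean class-weighted cross-entropy of the softmaxed logits over the
#' labelled nodes in `mask` (a weighted mean: each node contributes with
#' the weight of its class, normalised by the total weight). The L2
#' penalty is applied by the optimiser as weight decay, not here.
#'
#' @param logits n x 2 matrix (columns: non-fraud, fraud).
#' @param labels Integer vector (0/1, `NA` allowed off-mask).
#' @param mask Integer indices of the labelled nodes to score.
#' @param class_weights Length-2 positive weights (non-fraud, fraud).
#' @return Scalar loss.
#' @export
loss_fn <- function(logits, labels, mask, class_weights = c(1, 1)) {
  if (length(mask) == 0L) stop("empty mask: no labelled nodes to score")
  stopifnot(length(class_weights) == 2, all(class_weights > 0))
  y <- labels[mask]
  if (any(is.na(y))) stop("mask points at unlabelled nodes")
  L <- logits[mask, , drop = FALSE]
  m <- pmax(L[, 1], L[, 2])
  logZ <- m + log(exp(L[, 1] - m) + exp(L[, 2] - m))
  nll <- logZ - ifelse(y == 1L, L[, 2], L[, 1])
  w <- class_weights[y + 1L]
  sum(w * nll) / sum(w)
}
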