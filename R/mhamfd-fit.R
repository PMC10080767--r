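#' Fit the hierarchical-attention fraud detection model
#'
#' End-to-end fit from a claims table: builds the attributed
#' heterogeneous information network, materialises the patient--patient
#' behavioural-relationship graphs up to `control$max_level`, splits the
#' labelled patients into stratified train/validation/test sets, trains
#' the three-tier attention network semi-supervised (all structure and
#' features visible, only training labels drive the loss) with Adam and
#' early stopping, and evaluates every split.
#'
#' @param claims A claims table from [read_claims()] or
#'   [simulate_claims()]; label column may be partially `NA`.
#' @param features Optional numeric feature matrix, one row per patient;
#'   `NULL` uses [structural_features()].
#' @param control A [mhamfd_control()] with hyper-parameters.
#' @param split Optional precomputed split from [split_nodes()];
#'   `NULL` draws one from `control$split_ratio` with `seed`.
#' @param seed Integer seed governing the split, parameter
#'   initialisation and dropout.
#' @return An object of class `mhamfd`. Key components: `metrics`
#'   (train/val/test [evaluate()] results), `report` (the
#'   `attention_report` of the fitted model), `embeddings` (final H),
#'   `prob` (fitted fraud probabilities), `history`, `split`, `graph`,
#'   `adjacencies`, `params`.
#' @examples
#' sim <- simulate_claims(n_fraud = 12, n_normal = 24, ring_size = 4,
#'                        n_departments = 8, n_dates = 30, n_medicines = 20,
#'                        seed = 7)
#' X <- simulate_features(sim$labels, k = 4, seed = 7)
#' fit <- mhamfd(sim$claims, X,
#'               control = mhamfd_control(embed_dim = 8, heads = 2,
#'                                        att_dim = 8, max_epochs = 5,
#'                                        patience = 5),
#'               seed = 7)
#' print(fit)
#' @export
mhamfd <- function(claims, features = NULL, control = mhamfd_control(),
                   split = NULL, seed = 1L) {
  stopifnot(inherits(control, "mhamfd_control"))
  g <- build_hetero_graph(claims, features)
  adjs <- build_all_relation_graphs(g, control$max_level)
  if (is.finite(control$max_neighbors))
    adjs <- lapply(adjs, cap_neighbors,
                   max_neighbors = control$max_neighbors, seed = seed)
  labels <- unname(g$labels)
  if (is.null(split))
    split <- split_nodes(labels, control$split_ratio, seed = seed)
  X <- g$features

  tr <- train_model(X, adjs, labels, control, split, seed = seed)
  fw <- mhamfd_forward(X, adjs, tr$params, training = FALSE)
  prob <- exp(fw$logits - apply(fw$logits, 1, max))
  prob <- prob[, 2] / rowSums(prob)
  names(prob) <- g$patients

  metrics <- lapply(split, function(m) evaluate(fw$logits, labels, m))

  structure(list(call = match.call(), control = control, seed = seed,
                 graph = g, adjacencies = adjs, split = split,
                 labels = stats::setNames(labels, g$patients),
                 params = tr$params, history = tr$history,
                 best_epoch = tr$best_epoch, epochs_run = tr$epochs_run,
                 class_weights = tr$class_weights,
                 embeddings = fw$H, logits = fw$logits, prob = prob,
                 report = fw$report, metrics = metrics),
            class = "mhamfd")
}

#' @export
print.mhamfd <- function(x, digits = 4, ...) {
  s <- graph_summary(x$graph)
  cat("Hierarchical-attention fraud detection model\n")
  cat(sprintf("  %d patients (%d fraud / %d non-fraud / %d unlabelled), %d relations\n",
              s$nodes["P"], s$labels["fraud"], s$labels["non_fraud"],
              s$labels["unlabelled"], length(x$adjacencies)))
  cat(sprintf("  trained %d epochs (best at %d), class weights %.2f/%.2f\n",
              x$epochs_run, x$best_epoch,
              x$class_weights[1], x$class_weights[2]))
  m <- x$metrics$test
  cat(sprintf("  test: f1 %.*f  accuracy %.*f  precision %.*f  recall %.*f\n",
              digits, m$f1, digits, m$accuracy, digits, m$precision,
              digits, m$recall))
  cat("  level attention (gamma): ",
      paste(sprintf("%s=%.3f", names(x$report$gamma), x$report$gamma),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.mhamfd <- function(object, ...) {
  structure(list(graph = graph_summary(object$graph),
                 control = object$control,
                 metrics = object$metrics,
                 report = object$report,
                 history = object$history,
                 best_epoch = object$best_epoch,
                 epochs_run = object$epochs_run,
                 class_weights = object$class_weights),
            class = "summary.mhamfd")
}

#' @export
print.summary.mhamfd <- function(x, ...) {
  cat("== Graph ==\n"); print(x$graph)
  cat(sprintf("\n== Training ==\n%d epochs run, best validation epoch %d\n",
              x$epochs_run, x$best_epoch))
  cat("\n== Metrics ==\n")
  for (nm in names(x$metrics)) {
    cat(nm, ": ", sep = ""); print(x$metrics[[nm]])
  }
  cat("\n== Attention ==\n"); print(x$report)
  invisible(x)
}

#' Attention weights of a fitted model
#'
#' The interpretable coefficients of the model: the level attention
#' weights gamma and the within-level relation attention weights beta
#' (and, optionally, the classifier matrix).
#'
#' @param object A fitted `mhamfd`.
#' @param what `"attention"` (default) or `"classifier"`.
#' @param ... Unused.
#' @return For `"attention"`, a list with `gamma` and `beta_by_level`;
#'   for `"classifier"`, the classification head parameters (a `d x 2`
#'   matrix, or the list `Wc1`, `bc1`, `Wc2` for the MLP head).
#' @export
coef.mhamfd <- function(object, what = c("attention", "classifier"), ...) {
  what <- match.arg(what)
  if (what == "classifier") {
    p <- object$params$par
    return(if (!is.null(p$Wc)) p$Wc else p[c("Wc1", "bc1", "Wc2")])
  }
  list(gamma = object$report$gamma,
       beta_by_level = object$report$beta_by_level)
}

#' Predictions from a fitted model
#'
#' The model is transductive: every patient of the fitted graph already
#' has an embedding and a fraud probability, which this method exposes.
#'
#' @param object A fitted `mhamfd`.
#' @param type `"prob"` (fraud probability), `"class"` (0/1 at 0.5),
#'   `"logits"` or `"embedding"`.
#' @param patients Optional character vector restricting the output.
#' @param ... Unused.
#' @return A named vector (prob/class), or a matrix (logits/embedding).
#' @export
predict.mhamfd <- function(object, type = c("prob", "class", "logits",
                                            "embedding"),
                           patients = NULL, ...) {
  type <- match.arg(type)
  sel <- patients %||% object$graph$patients
  bad <- setdiff(sel, object$graph$patients)
  if (length(bad) > 0L)
    stop("unknown patient(s): ", paste(bad, collapse = ", "),
         " (the model is transductive; refit with their claims included)")
  switch(type,
         prob = object$prob[sel],
         class = stats::setNames(as.integer(object$prob[sel] > 0.5), sel),
         logits = object$logits[match(sel, object$graph$patients), , drop = FALSE],
         embedding = object$embeddings[match(sel, object$graph$patients), , drop = FALSE])
}

#' @export
fitted.mhamfd <- function(object, ...) object$prob

#' Residuals of a fitted model
#'
#' Response residuals `label - fitted fraud probability` for the
#' labelled patients (`NA` for unlabelled ones).
#'
#' @param object A fitted `mhamfd`.
#' @param ... Unused.
#' @return A named numeric vector over all patients.
#' @export
residuals.mhamfd <- function(object, ...) {
  object$labels - object$prob
}

#' Simulate labels from the fitted probabilities
#'
#' Draws Bernoulli fraud labels for every patient from the fitted fraud
#' probabilities, as a parametric-bootstrap device.
#'
#' @param object A fitted `mhamfd`.
#' @param nsim Number of simulated label vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of 0/1 labels, rownames =
#'   patient ids.
#' @export
simulate.mhamfd <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$prob)
  out <- as.data.frame(replicate(nsim, stats::rbinom(n, 1L, object$prob)))
  rownames(out) <- names(object$prob)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plots for a fitted model
#'
#' Two base-graphics panels: the training and validation loss history
#' (with the best validation epoch marked) and a barplot of the
#' attention weights per level and per relation.
#'
#' @param x A fitted `mhamfd`.
#' @param which Subset of `c(1, 2)`: 1 = history, 2 = attention.
#' @param ... Passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.mhamfd <- function(x, which = c(1, 2), ...) {
  if (length(which) > 1L) {
    op <- graphics::par(mfrow = c(1, length(which)))
    on.exit(graphics::par(op))
  }
  if (1 %in% which) {
    h <- x$history
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = 1, col = c("grey40", "firebrick"),
                      xlab = "epoch", ylab = "loss",
                      main = "training history", ...)
    graphics::abline(v = x$best_epoch, lty = 3)
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("grey40", "firebrick"), bty = "n")
  }
  if (2 %in% which) {
    w <- c(x$report$gamma, x$report$beta)
    graphics::barplot(w, las = 2, col = c(rep("grey30", length(x$report$gamma)),
                                          rep("steelblue", length(x$report$beta))),
                      ylab = "attention weight",
                      main = "level (dark) and relation attention", ...)
  }
  invisible(x)
}

#' Fraud-lift table of a fitted model
#'
#' Convenience wrapper around [fraud_lift_analysis()] using the fitted
#' model's relation graphs and labels.
#'
#' @param object A fitted `mhamfd`.
#' @return A `lift_table`.
#' @export
lift.mhamfd <- function(object) {
  fraud_lift_analysis(object$adjacencies, object$labels)
}

#' Features-only logistic baseline
#'
#' Fits `glm(label ~ features)` on the training split and evaluates on
#' the test split, mirroring the graph model's metric conventions. This
#' quantifies how much label signal the attributes alone carry, i.e. the
#' reference the structural model must beat.
#'
#' @param X Feature matrix.
#' @param labels Integer labels.
#' @param split A [split_nodes()] list.
#' @return An `mhamfd_metrics` for the test split.
#' @export
baseline_logistic <- function(X, labels, split) {
  df <- data.frame(y = labels, X)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df[split$train, ],
                                     family = stats::binomial()))
  p <- suppressWarnings(stats::predict(fit, newdata = df, type = "response"))
  logits <- cbind(log(pmax(1 - p, 1e-12)), log(pmax(p, 1e-12)))
  suppressWarnings(evaluate(logits, labels, split$test))
}
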