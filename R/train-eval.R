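#' Stratified train/validation/test node split
#'
#' Randomly partitions the labelled nodes into train, validation and test
#' sets in the given proportions, stratified by class so each split keeps
#' the overall fraud ratio (up to rounding by largest remainder).
#' Unlabelled nodes belong to no split but remain visible to the model
#' (transductive setting).
#'
#' @param labels Integer vector, 1 = fraud, 0 = non-fraud, `NA` =
#'   unlabelled.
#' @param ratio Length-3 positive weights, e.g. `c(3, 1, 1)`.
#' @param seed Integer seed.
#' @return A list of integer index vectors `train`, `val`, `test`
#'   (disjoint, union = labelled nodes).
#' @export
split_nodes <- function(labels, ratio = c(3, 1, 1), seed = 1L) {
  stopifnot(length(ratio) == 3, all(ratio > 0))
  if (sum(labels == 1L, na.rm = TRUE) < 1L || sum(labels == 0L, na.rm = TRUE) < 1L)
    stop("need at least one labelled node of each class")
  set.seed(as.integer(seed))
  frac <- ratio / sum(ratio)
  out <- list(train = integer(), val = integer(), test = integer())
  for (cls in c(0L, 1L)) {
    idx <- which(!is.na(labels) & labels == cls)
    idx <- sample(idx)
    n <- length(idx)
    sizes <- floor(frac * n)
    rem <- frac * n - sizes
    short <- n - sum(sizes)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      sizes[add] <- sizes[add] + 1L
    }
    if (any(sizes == 0L))
      stop("class ", cls, " would be absent from a split at ratio ",
           paste(ratio, collapse = ":"), "; use a coarser ratio or more labels")
    ends <- cumsum(sizes)
    out$train <- c(out$train, idx[seq_len(sizes[1])])
    out$val <- c(out$val, idx[(ends[1] + 1L):ends[2]])
    out$test <- c(out$test, idx[(ends[2] + 1L):ends[3]])
  }
  lapply(out, sort)
}

inverse_class_weights <- function(y) {
  f <- c(mean(y == 0L), mean(y == 1L))
  w <- 1 / f
  2 * w / sum(w)  # normalise to mean 1
}

resolve_class_weights <- function(mode, y_train) {
  if (is.numeric(mode)) {
    stopifnot(length(mode) == 2, all(mode > 0))
    return(mode)
  }
  switch(mode,
         inverse = inverse_class_weights(y_train),
         none = c(1, 1),
         # plain cross-entropy in the balanced regime, inverse-frequency
         # weights once the minority class drops below 20% of the labels
         auto = if (min(mean(y_train == 1L), mean(y_train == 0L)) < 0.2)
           inverse_class_weights(y_train) else c(1, 1),
         stop("unknown class_weights mode: ", mode))
}

#' Train the attention network
#'
#' Full-batch semi-supervised training: Adam with L2 weight decay, loss
#' on the training nodes only, validation loss and accuracy recorded
#' every epoch. Training stops early when validation loss has not reached
#' a new minimum and validation accuracy has not reached a new maximum
#' for `patience` consecutive epochs; the returned parameters are those
#' of the epoch with the lowest validation loss (earliest on ties).
#' Reported train/validation losses are computed without dropout at the
#' current parameters.
#'
#' @param X Feature matrix (patients x k).
#' @param adjs Named list of `relation_adjacency` objects.
#' @param labels Integer label vector aligned with `rownames(X)`.
#' @param control A [mhamfd_control()].
#' @param split A list from [split_nodes()].
#' @param seed Integer seed (parameter init and dropout).
#' @return A list: `params` (best-epoch `mhamfd_params`), `history`
#'   (data.frame epoch/train_loss/val_loss/val_acc), `best_epoch`,
#'   `epochs_run`, `class_weights`.
#' @export
train_model <- function(X, adjs, labels, control = mhamfd_control(),
                        split, seed = 1L) {
  stopifnot(inherits(control, "mhamfd_control"))
  paths <- lapply(adjs, `[[`, "path")
  params <- init_params(ncol(X), paths, control, seed = seed)
  masks <- attention_masks(adjs)
  cw <- resolve_class_weights(control$class_weights, labels[split$train])

  state <- adam_init(params$par)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), val_acc = numeric())
  best <- list(loss = Inf, acc = -Inf, par = params$par, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(control$max_epochs)) {
    fw <- mhamfd_forward(X, adjs, params, training = TRUE,
                         keep_cache = TRUE, masks = masks, report = FALSE)
    tr_loss_drop <- loss_fn(fw$logits, labels, split$train, cw)
    if (!is.finite(tr_loss_drop))
      stop("training diverged (non-finite loss) at epoch ", epoch)
    grads <- mhamfd_backward(fw$cache, params, fw$logits, labels,
                             split$train, cw)
    upd <- adam_step(params$par, grads, state, control$learning_rate,
                     control$weight_decay)
    params$par <- upd$par; state <- upd$state

    ev <- mhamfd_forward(X, adjs, params, training = FALSE,
                         masks = masks, report = FALSE)
    tr_loss <- loss_fn(ev$logits, labels, split$train, cw)
    val_loss <- loss_fn(ev$logits, labels, split$val, cw)
    pred <- as.integer(ev$logits[, 2] > ev$logits[, 1])
    val_acc <- mean(pred[split$val] == labels[split$val])
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = val_loss, val_acc = val_acc))
    improved <- FALSE
    if (val_loss < best$loss) {
      best$loss <- val_loss; best$par <- params$par; best$epoch <- epoch
      improved <- TRUE
    }
    if (val_acc > best$acc) {
      best$acc <- val_acc
      improved <- TRUE
    }
    stall <- if (improved) 0L else stall + 1L
    if (control$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  acc %.3f",
                      epoch, tr_loss, val_loss, val_acc))
    if (stall >= control$patience) break
  }
  params$par <- best$par
  list(params = params, history = hist, best_epoch = best$epoch,
       epochs_run = nrow(hist), class_weights = cw)
}

#' Classification metrics on a node subset
#'
#' Argmax predictions with fraud as the positive class. Precision with
#' zero predicted positives (and recall with zero actual positives) are
#' reported as 0 with a warning.
#'
#' @param logits n x 2 logit matrix (columns non-fraud, fraud).
#' @param labels Integer labels.
#' @param mask Integer indices to evaluate on.
#' @return A list of class `mhamfd_metrics`: `accuracy`, `precision`,
#'   `recall`, `f1` and `confusion` (tp, fp, fn, tn).
#' @export
evaluate <- function(logits, labels, mask) {
  if (length(mask) == 0L) stop("empty mask")
  y <- labels[mask]
  pred <- as.integer(logits[mask, 2] > logits[mask, 1])
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  if (length(unique(y)) < 2L)
    warning("mask contains a single class; some metrics are degenerate")
  if (tp + fp == 0L) {
    warning("no predicted positives; precision reported as 0")
    precision <- 0
  } else precision <- tp / (tp + fp)
  if (tp + fn == 0L) {
    warning("no actual positives; recall reported as 0")
    recall <- 0
  } else recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(accuracy = (tp + tn) / length(y), precision = precision,
                 recall = recall, f1 = f1,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn)),
            class = "mhamfd_metrics")
}

#' @export
print.mhamfd_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("accuracy %.*f  precision %.*f  recall %.*f  f1 %.*f\n",
              digits, x$accuracy, digits, x$precision,
              digits, x$recall, digits, x$f1))
  cat(sprintf("confusion: tp=%d fp=%d fn=%d tn=%d\n",
              x$confusion["tp"], x$confusion["fp"],
              x$confusion["fn"], x$confusion["tn"]))
  invisible(x)
}

#' Fraud-lift analysis by fraudulent-neighbour count
#'
#' For each behavioural relationship, labelled patients are grouped by
#' how many of their neighbours are labelled fraudulent (buckets 0, 1, 2
#' and 3+). Each group's fraud rate is reported together with its lift
#' over the zero-fraud-neighbour group; when the zero group is empty the
#' overall fraud rate is used as reference and flagged in the `ref`
#' column.
#'
#' @param adjs Named list of `relation_adjacency` objects.
#' @param labels Named integer label vector (names = patient ids).
#' @return A data.frame of class `lift_table`: `path`, `bucket`, `n`,
#'   `fraud_rate`, `lift`, `ref`.
#' @export
fraud_lift_analysis <- function(adjs, labels) {
  if (sum(labels == 1L, na.rm = TRUE) < 1L)
    stop("need at least one labelled fraud node")
  fraud_ids <- names(labels)[!is.na(labels) & labels == 1L]
  labelled <- names(labels)[!is.na(labels)]
  rows <- list()
  for (rel in names(adjs)) {
    adj <- adjs[[rel]]
    counts <- vapply(labelled, function(p)
      sum(adj$neighbors[[p]] %in% fraud_ids), 0L)
    bucket <- cut(counts, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
                  labels = c("0", "1", "2", "3+"))
    y <- labels[labelled]
    overall <- mean(y == 1L)
    tab <- lapply(levels(bucket), function(b) {
      in_b <- bucket == b
      data.frame(path = rel, bucket = b, n = sum(in_b),
                 fraud_rate = if (any(in_b)) mean(y[in_b] == 1L) else NA_real_,
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tab)
    zero_rate <- tab$fraud_rate[tab$bucket == "0"]
    if (!is.na(zero_rate) && tab$n[tab$bucket == "0"] > 0L && zero_rate > 0) {
      tab$lift <- tab$fraud_rate / zero_rate
      tab$ref <- "zero_group"
    } else {
      tab$lift <- tab$fraud_rate / overall
      tab$ref <- "overall"
    }
    rows[[rel]] <- tab
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lift_table", "data.frame")
  out
}

#' @export
print.lift_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$fraud_rate <- round(df$fraud_rate, digits)
  df$lift <- round(df$lift, digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
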