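# Class-imbalance strategies, the training loop, the 2:1:1 weighted
# ensemble, and the binary-classification metrics suite.

#' Construct a labeled sample set
#'
#' @param windows Integer matrix (N x 31) of window index encodings.
#' @param features Numeric matrix (N x 2340).
#' @param labels 0/1 vector of length N.
#' @return A `labeled_set` list.
#' @export
labeled_set <- function(windows, features, labels) {
  stopifnot(nrow(windows) == nrow(features), nrow(features) == length(labels),
            all(labels %in% c(0, 1)))
  structure(list(windows = windows, features = features,
                 labels = as.numeric(labels)), class = "labeled_set")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("<labeled_set> %d samples (%d positive / %d negative)\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

subset_set <- function(set, idx) {
  labeled_set(set$windows[idx, , drop = FALSE],
              set$features[idx, , drop = FALSE], set$labels[idx])
}

#' Random undersampling of the majority class
#'
#' Keeps every positive sample and draws, without replacement, an equal
#' number of negatives.
#'
#' @param set A [labeled_set()].
#' @param seed Integer seed.
#' @return A balanced `labeled_set`.
#' @export
undersample <- function(set, seed = 1) {
  pos <- which(set$labels == 1); neg <- which(set$labels == 0)
  if (!length(pos) || !length(neg)) abort("need at least one sample of each class")
  if (length(pos) > length(neg)) {
    abort(sprintf("cannot undersample: %d positives exceed %d negatives",
                  length(pos), length(neg)))
  }
  set.seed(seed)
  keep <- sort(c(pos, sample(neg, length(pos))))
  subset_set(set, keep)
}

#' Per-sample weights for weighted oversampling
#'
#' Each sample's weight is inversely proportional to its class frequency;
#' weights are normalised to sum to 1, so each class carries half the total
#' mass.
#'
#' @param labels 0/1 vector.
#' @return Numeric weights summing to 1.
#' @export
oversample_weights <- function(labels) {
  freq <- table(factor(labels, levels = c(0, 1))) / length(labels)
  if (any(freq == 0)) abort("both classes must be present")
  w <- 1 / as.numeric(freq[as.character(labels)])
  w / sum(w)
}

#' Class weights for a class-weighted loss
#'
#' `w_pos / w_neg = freq_neg / freq_pos`, scaled so `w_neg = 1`.
#'
#' @param labels 0/1 vector.
#' @return Named numeric vector `c(w_pos, w_neg)`.
#' @export
class_loss_weights <- function(labels) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (!n_pos || !n_neg) abort("both classes must be present")
  c(w_pos = n_neg / n_pos, w_neg = 1)
}

minority_knn <- function(Xmin, k) {
  n <- nrow(Xmin)
  d2 <- outer(rowSums(Xmin^2), rowSums(Xmin^2), "+") - 2 * tcrossprod(Xmin)
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

make_synthetic_rows <- function(set, seed_idx, k_nn, n_new, pick_seed_rows) {
  # pick_seed_rows: integer vector (length n_new) of minority-row indices
  gaps <- runif(n_new)
  nbr_pick <- sample.int(ncol(k_nn), n_new, replace = TRUE)
  Xmin <- set$features[seed_idx, , drop = FALSE]
  new_feat <- matrix(0, n_new, ncol(set$features))
  for (r in seq_len(n_new)) {
    a <- pick_seed_rows[r]
    b <- k_nn[a, nbr_pick[r]]
    new_feat[r, ] <- Xmin[a, ] + gaps[r] * (Xmin[b, ] - Xmin[a, ])
  }
  new_win <- set$windows[seed_idx[pick_seed_rows], , drop = FALSE]
  list(features = new_feat, windows = new_win)
}

#' SMOTE-style oversampling on the continuous feature block
#'
#' Synthetic minority samples are drawn uniformly on segments between a
#' minority sample and one of its `k` nearest minority neighbours (Euclidean
#' distance over the 2340-wide feature block).  The discrete window indices
#' of a synthetic sample are copied from its seed minority sample.  The
#' minority count is raised to the majority count.
#'
#' @param set A [labeled_set()].
#' @param k Number of minority neighbours (default 5).
#' @param seed Integer seed.
#' @return An augmented, balanced `labeled_set`.
#' @export
smote_like <- function(set, k = 5, seed = 1) {
  pos <- which(set$labels == 1); neg <- which(set$labels == 0)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- setdiff(seq_along(set$labels), minority)
  if (length(minority) < k + 1) {
    abort(sprintf("SMOTE needs at least k+1 = %d minority samples, found %d",
                  k + 1, length(minority)))
  }
  n_new <- length(majority) - length(minority)
  if (n_new <= 0) return(set)
  set.seed(seed)
  knn <- minority_knn(set$features[minority, , drop = FALSE], k)
  pick <- sample.int(length(minority), n_new, replace = TRUE)
  syn <- make_synthetic_rows(set, minority, knn, n_new, pick)
  labeled_set(rbind(set$windows, syn$windows),
              rbind(set$features, syn$features),
              c(set$labels, rep(set$labels[minority[1]], n_new)))
}

#' ADASYN-style oversampling on the continuous feature block
#'
#' Like [smote_like()], but the number of synthetics generated around each
#' minority sample is proportional to the fraction of majority-class samples
#' among its `k` nearest neighbours in the full set, prioritising
#' hard-to-learn minority samples.
#'
#' @inheritParams smote_like
#' @return An augmented, balanced `labeled_set`.
#' @export
adasyn_like <- function(set, k = 5, seed = 1) {
  pos <- which(set$labels == 1); neg <- which(set$labels == 0)
  minority <- if (length(pos) <= length(neg)) pos else neg
  majority <- setdiff(seq_along(set$labels), minority)
  if (length(minority) < k + 1) {
    abort(sprintf("ADASYN needs at least k+1 = %d minority samples, found %d",
                  k + 1, length(minority)))
  }
  n_new <- length(majority) - length(minority)
  if (n_new <= 0) return(set)
  set.seed(seed)
  X <- set$features
  # hardness: majority fraction among the k nearest neighbours in the full set
  Xmin <- X[minority, , drop = FALSE]
  d2 <- outer(rowSums(Xmin^2), rowSums(X^2), "+") - 2 * tcrossprod(Xmin, X)
  d2[cbind(seq_along(minority), minority)] <- Inf
  is_majority <- seq_along(set$labels) %in% majority
  r <- apply(d2, 1, function(row) mean(is_majority[order(row)[seq_len(k)]]))
  if (sum(r) == 0) r <- rep(1, length(r))
  alloc <- floor(r / sum(r) * n_new)
  short <- n_new - sum(alloc)
  if (short > 0) {
    extra <- order(r / sum(r) * n_new - alloc, decreasing = TRUE)[seq_len(short)]
    alloc[extra] <- alloc[extra] + 1
  }
  knn <- minority_knn(Xmin, k)
  pick <- rep(seq_along(minority), alloc)
  syn <- make_synthetic_rows(set, minority, knn, n_new, pick)
  out <- labeled_set(rbind(set$windows, syn$windows),
                     rbind(set$features, syn$features),
                     c(set$labels, rep(set$labels[minority[1]], n_new)))
  attr(out, "alloc") <- alloc
  out
}

weighted_bce_grad <- function(logits, y, w) {
  p <- 1 / (1 + exp(-logits))
  sw <- sum(w)
  loss <- sum(w * (log1p(exp(-abs(logits))) + pmax(logits, 0) - y * logits)) / sw
  list(loss = loss, dz = w * (p - y) / sw)
}

#' Train one network under an imbalance strategy
#'
#' Adam on (optionally class-weighted) binary cross-entropy.  `ru`
#' undersamples once up front; `wo` resamples each epoch with
#' [oversample_weights()]; `cwl` weights the loss with
#' [class_loss_weights()]; `smote` / `adasyn` augment the set once up front.
#' All randomness (sampling, shuffling, dropout) flows from `seed`; on one
#' CPU the loss trajectory is bit-reproducible.
#'
#' @param set A [labeled_set()].
#' @param strategy One of `"ru"`, `"wo"`, `"cwl"`, `"smote"`, `"adasyn"`.
#' @param config A [net_config()]; `lr` and `batch_size` are taken from it.
#' @param seed Integer seed.
#' @param epochs Training epochs (default: the per-strategy value in
#'   `config$epochs`); 0 returns the freshly initialised net unchanged.
#' @param verbose Print the per-epoch loss?
#' @return A trained `glycobind_net` with `strategy_tag` and
#'   `loss_trajectory` filled in.
#' @export
train_net <- function(set, strategy = c("ru", "wo", "cwl", "smote", "adasyn"),
                      config = net_config(), seed = 1, epochs = NULL,
                      verbose = FALSE) {
  strategy <- match.arg(strategy)
  if (length(unique(set$labels)) < 2) abort("degenerate labels: need both classes")
  epochs <- epochs %||% unname(config$epochs[strategy])
  net <- net_init(config, seed = seed)
  net$strategy_tag <- toupper(strategy)
  if (epochs == 0) return(net)

  train_set <- switch(strategy,
    ru = undersample(set, seed = seed),
    smote = smote_like(set, seed = seed),
    adasyn = adasyn_like(set, seed = seed),
    set)
  w_class <- if (strategy == "cwl") class_loss_weights(set$labels) else c(w_pos = 1, w_neg = 1)
  samp_w <- if (strategy == "wo") oversample_weights(set$labels) else NULL

  set.seed(seed)
  opt <- adam_init(net$params)
  N <- length(train_set$labels)
  bs <- config$batch_size
  traj <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    idx <- if (strategy == "wo") {
      sample.int(N, N, replace = TRUE, prob = samp_w)
    } else sample.int(N)
    ep_loss <- 0; nb <- 0
    for (s in seq(1, N, by = bs)) {
      e <- min(N, s + bs - 1)
      bi <- idx[s:e]
      y <- train_set$labels[bi]
      w <- ifelse(y == 1, w_class["w_pos"], w_class["w_neg"])
      fwd <- net_forward_full(net, train_set$windows[bi, , drop = FALSE],
                              train_set$features[bi, , drop = FALSE],
                              training = TRUE, want_cache = TRUE)
      net$bn_state <- fwd$net$bn_state
      lg <- weighted_bce_grad(fwd$logits, y, w)
      if (!is.finite(lg$loss)) {
        abort(sprintf("training diverged (non-finite loss) at epoch %d; last finite losses: %s",
                      ep, paste(round(tail(traj[seq_len(ep - 1)], 3), 4), collapse = ", ")))
      }
      grads <- net_backward_full(net, fwd$cache, lg$dz)
      upd <- adam_step(net$params, grads, opt, lr = config$lr)
      net$params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    traj[ep] <- ep_loss / nb
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, traj[ep]))
  }
  net$loss_trajectory <- traj
  net
}

#' Combine three component probabilities with 2:1:1 weights
#'
#' `(2 * p_ru + p_wo + p_cwl) / 4`: the undersampling model carries twice
#' the weight of the other two.
#'
#' @param p_ru,p_wo,p_cwl Probability vectors of equal length.
#' @return The ensemble probability vector.
#' @export
ensemble_predict <- function(p_ru, p_wo, p_cwl) {
  (2 * p_ru + p_wo + p_cwl) / 4
}

#' Train the three-component weighted ensemble
#'
#' Trains the undersampling, weighted-oversampling, and class-weighted-loss
#' models and wires them through [ensemble_predict()].
#'
#' @param set A [labeled_set()].
#' @param config A [net_config()].
#' @param seeds Integer seeds, one per component (recycled from the first).
#' @param epochs Optional epoch override applied to every component.
#' @param verbose Print training progress?
#' @return An `ensemble_model`: components `m_ru`, `m_wo`, `m_cwl`, weights
#'   `c(2, 1, 1)/4`.
#' @export
build_ensemble <- function(set, config = net_config(), seeds = c(1, 2, 3),
                           epochs = NULL, verbose = FALSE) {
  seeds <- rep_len(seeds, 3)
  structure(list(
    m_ru = train_net(set, "ru", config, seed = seeds[1], epochs = epochs, verbose = verbose),
    m_wo = train_net(set, "wo", config, seed = seeds[2], epochs = epochs, verbose = verbose),
    m_cwl = train_net(set, "cwl", config, seed = seeds[3], epochs = epochs, verbose = verbose),
    weights = c(ru = 2, wo = 1, cwl = 1) / 4), class = "ensemble_model")
}

#' Predict with a fitted ensemble
#' @param object An `ensemble_model`.
#' @param windows,features Prediction inputs (see [predict_net()]).
#' @param ... Unused.
#' @return Probability vector.
#' @export
predict.ensemble_model <- function(object, windows, features, ...) {
  ensemble_predict(predict_net(object$m_ru, windows, features),
                   predict_net(object$m_wo, windows, features),
                   predict_net(object$m_cwl, windows, features))
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> components RU/WO/CWL with weights 2:1:1\n")
  invisible(x)
}

roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # one point per unique threshold
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y)[keep]; fp <- cumsum(1 - y)[keep]
  P <- sum(y); N <- length(y) - P
  list(tpr = c(0, tp / P), fpr = c(0, fp / N),
       tp = c(0, tp), fp = c(0, fp), P = P, N = N)
}

auc_trapezoid <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

aupr_step <- function(scores, labels) {
  r <- roc_points(scores, labels)
  rec <- r$tp / r$P
  prec <- ifelse(r$tp + r$fp > 0, r$tp / (r$tp + r$fp), 1)
  # step-wise interpolation: precision held at the value reached at the
  # higher-recall end of each segment
  sum(diff(rec) * prec[-1])
}

#' Evaluate predicted probabilities against binary labels
#'
#' Confusion counts at `threshold`, then sensitivity, specificity, balanced
#' accuracy, accuracy, precision, F1, MCC, and threshold-free AUC
#' (trapezoidal) and AUPR (step-wise precision interpolation).  With
#' single-class labels AUC/AUPR are `NaN` with a warning; an MCC
#' denominator of zero yields 0 by convention.
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param labels 0/1 vector.
#' @param threshold Decision threshold (default 0.5; a prediction equal to
#'   the threshold counts as positive).
#' @return A `metrics_report` (named list; see [tidy.metrics_report()]).
#' @export
evaluate_predictions <- function(probabilities, labels, threshold = 0.5) {
  stopifnot(length(probabilities) == length(labels))
  labels <- as.numeric(labels)
  pred <- as.numeric(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NaN
  sp <- if (tn + fp > 0) tn / (tn + fp) else NaN
  prec <- if (tp + fp > 0) tp / (tp + fp) else NaN
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NaN
  acc <- (tp + tn) / length(labels)
  denom <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  if (length(unique(labels)) < 2) {
    warn("single-class labels: AUC and AUPR are undefined (NaN)")
    auc <- aupr <- NaN
  } else {
    auc <- auc_trapezoid(probabilities, labels)
    aupr <- aupr_step(probabilities, labels)
  }
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 SN = sn, SP = sp, BACC = (sn + sp) / 2, ACC = acc,
                 PREC = prec, F1 = f1, MCC = mcc, AUC = auc, AUPR = aupr,
                 threshold = threshold, n = length(labels)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d @ threshold %.2f\n", x$n, x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  cat(sprintf("  SN %.3f  SP %.3f  BACC %.3f  ACC %.3f\n", x$SN, x$SP, x$BACC, x$ACC))
  cat(sprintf("  PREC %.3f  F1 %.3f  MCC %.3f  AUC %.3f  AUPR %.3f\n",
              x$PREC, x$F1, x$MCC, x$AUC, x$AUPR))
  invisible(x)
}

#' Save / load fitted models
#'
#' Plain RDS serialisation with the configuration embedded; `load_model`
#' restores predictions exactly.
#'
#' @param model A `glycobind_net` or `ensemble_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
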