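# Group-level feature selection: Yeo-Johnson preprocessing, greedy
# incremental feature-group selection (IFS) with the Occam tie rule, and the
# two bespoke group scores used to rank feature groups after RFE and
# Elastic Net fits.

yj_transform <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) < 1e-12) {
    out[pos] <- log1p(x[pos])
  } else {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  }
  if (abs(lambda - 2) < 1e-12) {
    out[!pos] <- -log1p(-x[!pos])
  } else {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  }
  out
}

yj_inverse <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) < 1e-12) {
    out[pos] <- expm1(y[pos])
  } else {
    out[pos] <- (y[pos] * lambda + 1)^(1 / lambda) - 1
  }
  if (abs(lambda - 2) < 1e-12) {
    out[!pos] <- -expm1(-y[!pos])
  } else {
    out[!pos] <- 1 - (1 - (2 - lambda) * y[!pos])^(1 / (2 - lambda))
  }
  out
}

yj_loglik <- function(x, lambda) {
  z <- yj_transform(x, lambda)
  s2 <- mean((z - mean(z))^2)
  if (s2 <= 0) return(-Inf)
  n <- length(x)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit a per-column Yeo-Johnson transform and apply it
#'
#' Each column's power parameter lambda is estimated by maximum likelihood
#' on the fitting rows only, then the transform is applied to all rows.
#' Constant columns are passed through unchanged (lambda = 1) with a
#' warning.
#'
#' @param matrix Numeric matrix with finite entries.
#' @param fit_rows Row indices used for lambda estimation (default: all).
#' @return List with `transformed` (matrix) and `lambda` (per-column vector);
#'   class `yeo_johnson`.
#' @export
yeo_johnson_fit_apply <- function(matrix, fit_rows = seq_len(nrow(matrix))) {
  matrix <- as.matrix(matrix)
  if (!all(is.finite(matrix))) abort("Yeo-Johnson input must be finite")
  p <- ncol(matrix)
  lambda <- numeric(p)
  out <- matrix
  for (j in seq_len(p)) {
    xf <- matrix[fit_rows, j]
    if (sd(xf) < 1e-12) {
      warn(sprintf("column %d is constant; Yeo-Johnson left it unchanged", j))
      lambda[j] <- 1
      next
    }
    lambda[j] <- optimize(function(l) yj_loglik(xf, l),
                          interval = c(-5, 5), maximum = TRUE)$maximum
    out[, j] <- yj_transform(matrix[, j], lambda[j])
  }
  structure(list(transformed = out, lambda = lambda), class = "yeo_johnson")
}

#' Invert a fitted Yeo-Johnson transform
#' @param fit A `yeo_johnson` object.
#' @param transformed Matrix on the transformed scale (defaults to the
#'   fitted one).
#' @return Matrix on the original scale.
#' @export
yeo_johnson_invert <- function(fit, transformed = fit$transformed) {
  out <- as.matrix(transformed)
  for (j in seq_len(ncol(out))) out[, j] <- yj_inverse(out[, j], fit$lambda[j])
  out
}

#' Define feature groups over a combined design matrix
#' @param widths Named integer vector of group widths, in column order.
#' @return Tibble with `name`, `width`, and the column index range.
#' @export
feature_groups <- function(widths) {
  stopifnot(all(widths > 0), !is.null(names(widths)))
  ends <- cumsum(widths)
  tibble(name = names(widths), width = as.integer(widths),
         from = c(1L, head(ends, -1) + 1L), to = as.integer(ends))
}

f1_score <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

stratified_folds <- function(labels, folds, seed) {
  withr_seed <- function(expr) { old <- .Random.seed %||% NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed); expr }
  fold_of <- integer(length(labels))
  withr_seed({
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

#' Cross-validated F1 scorer over feature-group combinations
#'
#' Builds the `score_fn` consumed by [ifs_greedy()]: given a set of group
#' names it subsets the design matrix to those columns and returns the
#' stratified k-fold CV F1 of the supplied learner.
#'
#' @param design Numeric design matrix.
#' @param labels 0/1 vector.
#' @param groups Tibble from [feature_groups()].
#' @param learner List with `fit(X, y)` and `predict(model, X)` (the latter
#'   returning 0/1); default is a logistic regression.
#' @param folds Number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return Function `character vector of group names -> CV F1`.
#' @export
cv_group_scorer <- function(design, labels, groups, learner = logistic_learner(),
                            folds = 10, seed = 1) {
  if (length(unique(labels)) < 2) abort("degenerate labels: only one class present")
  fold_of <- stratified_folds(labels, folds, seed)
  function(group_names) {
    g <- groups[groups$name %in% group_names, , drop = FALSE]
    cols <- unlist(lapply(seq_len(nrow(g)), function(i) g$from[i]:g$to[i]))
    X <- design[, cols, drop = FALSE]
    scores <- vapply(seq_len(folds), function(k) {
      tr <- fold_of != k
      model <- learner$fit(X[tr, , drop = FALSE], labels[tr])
      pred <- learner$predict(model, X[!tr, , drop = FALSE])
      f1_score(labels[!tr], pred)
    }, numeric(1))
    mean(scores)
  }
}

#' Plug-in learners for feature selection
#'
#' `logistic_learner` wraps `glm(family = binomial)`;
#' `svm_learner` wraps `e1071::svm` (if installed).
#' @return A list with `fit` and `predict` closures.
#' @export
logistic_learner <- function() {
  list(
    fit = function(X, y) {
      df <- as.data.frame(X); df$.y <- y
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    predict = function(model, X) {
      as.integer(stats::predict(model, newdata = as.data.frame(X), type = "response") >= 0.5)
    })
}

#' @rdname logistic_learner
#' @export
svm_learner <- function() {
  if (!requireNamespace("e1071", quietly = TRUE)) abort("e1071 not installed")
  list(
    fit = function(X, y) e1071::svm(X, factor(y)),
    predict = function(model, X) as.integer(as.character(stats::predict(model, X))))
}

#' Greedy incremental feature-group selection
#'
#' Starts from the single best-scoring group, then repeatedly adds the group
#' whose inclusion maximises the score, stopping when no addition strictly
#' improves it.  On ties the smaller set is preferred (Occam's razor), so a
#' tying addition never happens.
#'
#' @param group_names Candidate group names.
#' @param score_fn Function mapping a character vector of group names to a
#'   scalar score (e.g. from [cv_group_scorer()], or any oracle).
#' @return A `selection_result`: list with `chosen_groups` (ordered) and
#'   `trace` (tibble of per-step candidates and scores).
#' @export
ifs_greedy <- function(group_names, score_fn) {
  if (!length(group_names)) abort("no candidate feature groups")
  trace <- list()
  singles <- vapply(group_names, function(g) score_fn(g), numeric(1))
  best_i <- which.max(singles)          # ties: first in candidate order
  chosen <- group_names[best_i]
  best <- singles[best_i]
  trace[[1]] <- tibble(step = 1L, candidate = group_names, score = unname(singles),
                       chosen = group_names == group_names[best_i])
  step <- 1L
  repeat {
    remaining <- setdiff(group_names, chosen)
    if (!length(remaining)) break
    scores <- vapply(remaining, function(g) score_fn(c(chosen, g)), numeric(1))
    cand_i <- which.max(scores)
    step <- step + 1L
    improved <- scores[cand_i] > best   # strict: tie keeps the smaller set
    trace[[step]] <- tibble(step = step, candidate = remaining,
                            score = unname(scores),
                            chosen = improved & seq_along(remaining) == cand_i)
    if (!improved) break
    chosen <- c(chosen, remaining[cand_i])
    best <- scores[cand_i]
  }
  structure(list(chosen_groups = chosen, best_score = unname(best),
                 trace = bind_rows(trace)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", paste(x$chosen_groups, collapse = " + "),
      sprintf(" (score %.4f)\n", x$best_score))
  invisible(x)
}

#' Group score after recursive feature elimination
#'
#' `count_in_top100 / sqrt(group_width)`: the number of the group's features
#' ranked in the global top 100, normalised by the square root of the group
#' width so large groups are not over-penalised.
#'
#' @param count_in_top100 Features of the group within the top 100.
#' @param group_width Total features in the group.
#' @return Scalar score.
#' @export
rfe_group_score <- function(count_in_top100, group_width) {
  stopifnot(group_width >= 1, count_in_top100 >= 0,
            count_in_top100 <= min(100, group_width))
  count_in_top100 / sqrt(group_width)
}

#' Group score after an Elastic Net fit
#'
#' `n_g / (n_s * sqrt(f_g))` where `n_g` is the number of the group's
#' features with non-zero coefficients, `n_s` the total number of selected
#' features, and `f_g` the group width.
#'
#' @param n_g Selected features from the group.
#' @param n_s Total selected features (>= 1).
#' @param f_g Total features in the group.
#' @return Scalar score.
#' @export
enet_group_score <- function(n_g, n_s, f_g) {
  stopifnot(n_s >= 1, f_g >= 1, n_g >= 0, n_g <= min(n_s, f_g))
  n_g / (n_s * sqrt(f_g))
}

#' Rank feature groups through an Elastic Net fit
#'
#' Convenience wrapper: fits `glmnet` (alpha = 0.5) at a single penalty,
#' counts non-zero coefficients per group, and scores each group with
#' [enet_group_score()].
#'
#' @param design Numeric design matrix.
#' @param labels 0/1 vector.
#' @param groups Tibble from [feature_groups()].
#' @param lambda Penalty (default: `lambda.min` from an internal
#'   cross-validated path would be costly; a small fixed value is used).
#' @return Tibble of groups with `n_selected` and `score`, best first.
#' @export
enet_group_rank <- function(design, labels, groups, lambda = 0.01) {
  if (!requireNamespace("glmnet", quietly = TRUE)) abort("glmnet not installed")
  fit <- glmnet::glmnet(design, labels, family = "binomial", alpha = 0.5,
                        lambda = lambda)
  beta <- as.numeric(fit$beta)
  n_s <- max(1L, sum(beta != 0))
  res <- groups
  res$n_selected <- vapply(seq_len(nrow(groups)), function(i) {
    sum(beta[groups$from[i]:groups$to[i]] != 0)
  }, numeric(1))
  res$score <- mapply(enet_group_score, res$n_selected, n_s, res$width)
  arrange(res, dplyr::desc(.data$score))
}
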