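small_set <- function(n_pos = 30, n_neg = 120, d = 3, seed = 5) {
  synth_labeled_set(n_pos, n_neg, d = d, seed = seed)
}

test_that("undersampling keeps all positives, balances, and is seed-deterministic", {
  s <- small_set()
  u <- undersample(s, seed = 2)
  expect_equal(sum(u$labels == 1), 30)
  expect_equal(sum(u$labels == 0), 30)
  # every positive sample's identity preserved
  pos_rows <- s$features[s$labels == 1, ]
  expect_equal(u$features[u$labels == 1, ], pos_rows)
  expect_equal(undersample(s, seed = 2)$features, u$features)
  # balanced input passes through as the same multiset
  b <- synth_labeled_set(20, 20, seed = 3)
  ub <- undersample(b, seed = 1)
  expect_equal(dim(ub$features), dim(b$features))
  expect_equal(sort(rowSums(ub$features)), sort(rowSums(b$features)))
  swapped <- labeled_set(b$windows, b$features, 1 - b$labels)
  expect_error(undersample(small_set(40, 10), 1), "exceed")
})

test_that("oversampling weights are inverse class frequencies summing to one", {
  y <- c(rep(1, 10), rep(0, 90))
  w <- oversample_weights(y)
  expect_equal(sum(w), 1)
  expect_equal(w[y == 1][1] / w[y == 0][1], 9)
  wb <- oversample_weights(rep(c(0, 1), 25))
  expect_true(all(abs(wb - wb[1]) < 1e-12))
  expect_true(all(w > 0))
})

test_that("class loss weights follow the inverse frequency ratio", {
  expect_equal(class_loss_weights(c(rep(1, 10), rep(0, 90))),
               c(w_pos = 9, w_neg = 1))
  expect_equal(class_loss_weights(rep(c(0, 1), 10)), c(w_pos = 1, w_neg = 1))
  expect_error(class_loss_weights(rep(1, 5)), "both classes")
})

test_that("SMOTE-like synthetics interpolate minority neighbours and balance classes", {
  s <- small_set(n_pos = 25, n_neg = 100, seed = 8)
  sm <- smote_like(s, k = 5, seed = 3)
  expect_equal(sum(sm$labels == 1), sum(sm$labels == 0))
  n0 <- length(s$labels)
  syn <- sm$features[(n0 + 1):length(sm$labels), , drop = FALSE]
  syn_win <- sm$windows[(n0 + 1):length(sm$labels), , drop = FALSE]
  minority <- which(s$labels == 1)
  Xmin <- s$features[minority, , drop = FALSE]
  knn <- glycobind:::minority_knn(Xmin, 5)
  # each synthetic row is a convex combination of a minority sample and one
  # of its k nearest minority neighbours, and carries its seed's windows
  for (r in seq_len(nrow(syn))) {
    on_segment <- FALSE; windows_ok <- FALSE
    for (a in seq_len(nrow(Xmin))) {
      dirs <- Xmin[knn[a, ], , drop = FALSE] - matrix(Xmin[a, ], 5, ncol(Xmin), byrow = TRUE)
      resid <- syn[r, ] - Xmin[a, ]
      for (b in 1:5) {
        dd <- dirs[b, ]
        u <- sum(resid * dd) / sum(dd * dd)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((resid - u * dd)^2)) < 1e-6) {
          on_segment <- TRUE
          if (identical(syn_win[r, ], s$windows[minority[a], ])) windows_ok <- TRUE
        }
      }
    }
    expect_true(on_segment)    # convex combination of a minority pair
    expect_true(windows_ok)    # windows inherited from a valid seed sample
  }
  expect_error(smote_like(small_set(4, 50), k = 5), "k\\+1")
})

test_that("ADASYN-like allocation prioritises minority samples near the majority", {
  # two minority clusters: one isolated, one inside the majority cloud
  set.seed(6)
  n_feat <- 2340
  iso <- matrix(rnorm(10 * n_feat, mean = 30), 10, n_feat)
  hard <- matrix(rnorm(10 * n_feat, mean = 0), 10, n_feat)
  maj <- matrix(rnorm(60 * n_feat, mean = 0), 60, n_feat)
  feats <- rbind(iso, hard, maj)
  wins <- matrix(sample(0:20, 80 * 31, TRUE), 80, 31)
  s <- labeled_set(wins, feats, c(rep(1, 20), rep(0, 60)))
  ad <- adasyn_like(s, k = 5, seed = 2)
  expect_equal(sum(ad$labels == 1), sum(ad$labels == 0))
  alloc <- attr(ad, "alloc")
  expect_gt(sum(alloc[11:20]), sum(alloc[1:10]))   # hard cluster gets more
})

test_that("the ensemble rule is the exact 2:1:1 weighted average", {
  expect_equal(ensemble_predict(1, 0, 0), 0.5)
  expect_equal(ensemble_predict(0.3, 0.3, 0.3), 0.3)
  expect_equal(ensemble_predict(0.8, 0.6, 0.4), 0.65)
  g <- seq(0, 1, by = 0.1)
  grid <- expand.grid(p1 = g, p2 = g, p3 = g)
  got <- ensemble_predict(grid$p1, grid$p2, grid$p3)
  expect_equal(got, (2 * grid$p1 + grid$p2 + grid$p3) / 4)
  # convexity: bounded by component extremes
  expect_true(all(got >= pmin(grid$p1, grid$p2, grid$p3) - 1e-12))
  expect_true(all(got <= pmax(grid$p1, grid$p2, grid$p3) + 1e-12))
})

test_that("metric formulas match hand arithmetic on a fixed confusion table", {
  # TP=2 FP=1 TN=3 FN=4
  prob <- c(0.9, 0.9, 0.1, 0.1, 0.1, 0.1, 0.8, 0.2, 0.2, 0.2)
  lab <- c(1, 1, 1, 1, 1, 1, 0, 0, 0, 0)
  m <- evaluate_predictions(prob, lab)
  expect_equal(c(m$TP, m$FP, m$TN, m$FN), c(2, 1, 3, 4))
  expect_equal(m$PREC, 2 / 3)
  expect_equal(m$SN, 1 / 3)
  expect_equal(m$SP, 3 / 4)
  expect_equal(m$BACC, 13 / 24)
  expect_equal(m$F1, 4 / 9)
  expect_equal(m$ACC, 0.5)
  expect_equal(m$MCC, (2 * 3 - 1 * 4) / sqrt(6 * 3 * 4 * 7))
  expect_equal(m$BACC, (m$SN + m$SP) / 2)
})

test_that("perfect predictions score 1 on every headline metric", {
  lab <- rep(c(0, 1), 20)
  m <- evaluate_predictions(ifelse(lab == 1, 0.95, 0.05), lab)
  for (k in c("SN", "SP", "BACC", "ACC", "PREC", "F1", "MCC", "AUC", "AUPR")) {
    expect_equal(m[[k]], 1)
  }
})

test_that("evaluation matches brute-force counting and the Mann-Whitney AUC", {
  set.seed(19)
  n <- 10000
  prob <- runif(n)
  lab <- rbinom(n, 1, 0.2)
  m <- evaluate_predictions(prob, lab)
  o <- oracle_metrics(prob, lab)
  for (k in names(o)) expect_equal(m[[k]], o[[k]])
  expect_equal(m$AUC, oracle_auc_mw(prob, lab), tolerance = 1e-9)
  skip_if_not_installed("pROC")
  expect_equal(m$AUC,
               as.numeric(pROC::auc(pROC::roc(lab, prob, quiet = TRUE,
                                              direction = "<",
                                              levels = c(0, 1)))),
               tolerance = 1e-9)
})

test_that("degenerate evaluation inputs follow the stated conventions", {
  expect_warning(m <- evaluate_predictions(c(0.2, 0.8), c(1, 1)), "single-class")
  expect_true(is.nan(m$AUC) && is.nan(m$AUPR))
  # all predictions on one side: MCC denominator zero -> 0
  m2 <- evaluate_predictions(c(0.9, 0.9, 0.9), c(1, 0, 1))
  expect_equal(m2$MCC, 0)
})

test_that("training is seed-reproducible and zero epochs returns the initial net", {
  s <- small_set(20, 60, seed = 2)
  cfg <- net_config_desk()
  n0 <- train_net(s, "cwl", cfg, seed = 4, epochs = 0)
  expect_equal(n0$params, net_init(cfg, seed = 4)$params)
  expect_length(n0$loss_trajectory, 0)
  n1 <- train_net(s, "ru", cfg, seed = 4, epochs = 2)
  n2 <- train_net(s, "ru", cfg, seed = 4, epochs = 2)
  expect_identical(n1$loss_trajectory, n2$loss_trajectory)
  expect_identical(n1$params, n2$params)
  expect_equal(n1$strategy_tag, "RU")
})

test_that("a separable problem is learned quickly by each loss-based strategy", {
  s <- small_set(60, 240, d = 4, seed = 9)
  cfg <- net_config_desk()
  for (strat in c("ru", "cwl")) {
    net <- train_net(s, strat, cfg, seed = 3, epochs = 4)
    p <- predict_net(net, s$windows, s$features)
    expect_gte(evaluate_predictions(p, s$labels)$AUC, 0.95)
  }
})

test_that("model serialisation round-trips predictions exactly", {
  s <- small_set(15, 45, seed = 1)
  cfg <- net_config_desk()
  ens <- build_ensemble(s, cfg, seeds = 4:6, epochs = 1)
  p1 <- predict(ens, s$windows, s$features)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(ens, f)
  expect_identical(predict(load_model(f), s$windows, s$features), p1)
  # ensemble output bounded by component extremes
  pr <- predict_net(ens$m_ru, s$windows, s$features)
  pw <- predict_net(ens$m_wo, s$windows, s$features)
  pc <- predict_net(ens$m_cwl, s$windows, s$features)
  expect_true(all(p1 <= pmax(pr, pw, pc) + 1e-12))
  expect_true(all(p1 >= pmin(pr, pw, pc) - 1e-12))
})

test_that("tidiers summarise fitted objects as tibbles", {
  s <- small_set(10, 30, seed = 2)
  net <- train_net(s, "ru", net_config_desk(), seed = 1, epochs = 1)
  td <- tidy(net)
  expect_s3_class(td, "tbl_df")
  expect_true("emb" %in% td$parameter)
  gl <- glance(net)
  expect_equal(gl$strategy, "RU")
  expect_equal(gl$epochs, 1L)
  m <- evaluate_predictions(runif(50), rbinom(50, 1, 0.4))
  expect_equal(nrow(tidy(m)), 9)
  crv <- prediction_curves(runif(50), rbinom(50, 1, 0.4))
  pl <- ggplot2::autoplot(crv)
  expect_s3_class(pl, "ggplot")
  expect_s3_class(ggplot2::autoplot(net), "ggplot")
})
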