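# The two-branch network: a residual-convolutional branch over 31-position
# residue-window index encodings and a feed-forward branch over the
# 2340-wide per-residue feature vector, fused by a small head ending in a
# sigmoid unit.

#' Network architecture configuration
#'
#' Defaults follow the published hyperparameter table of the final model:
#' kernel-3 / pad-1 / stride-1 conv1d with 10 output channels, kernel-2 max
#' pooling, three residual blocks with concatenation skips, 2340-wide FNN
#' input, dropout 0.5, Adam with initial learning rate 1e-5 and batch size
#' 2048.  `head_hidden` (width of the penultimate fused layer, unstated in
#' the published configuration) defaults to 128.
#'
#' @param window_len,alphabet_size,embed_dim ResNet-branch input geometry.
#' @param conv_filters,conv_kernel,conv_padding,conv_stride,conv_dilation,pool_kernel
#'   Convolution / pooling constants.
#' @param n_blocks Number of residual blocks.
#' @param resnet_out Width of the ResNet branch's final linear output.
#' @param fnn_in,fnn_hidden1,fnn_hidden2 FNN-branch widths.
#' @param head_hidden Fused-head hidden width.
#' @param dropout Dropout probability after linear layers.
#' @param lr,batch_size Training defaults.
#' @param epochs Named per-strategy epoch defaults.
#' @return A `net_config` list.
#' @export
net_config <- function(window_len = 31, alphabet_size = 21, embed_dim = 21,
                       conv_filters = 10, conv_kernel = 3, conv_padding = 1,
                       conv_stride = 1, conv_dilation = 1, pool_kernel = 2,
                       n_blocks = 3, resnet_out = 32,
                       fnn_in = 2340, fnn_hidden1 = 512, fnn_hidden2 = 256,
                       head_hidden = 128, dropout = 0.5,
                       lr = 1e-5, batch_size = 2048,
                       epochs = c(ru = 180, wo = 100, cwl = 325,
                                  smote = 100, adasyn = 100)) {
  cfg <- as.list(environment())
  stopifnot(all(vapply(cfg[!(names(cfg) %in% "epochs")], function(x) x > 0, logical(1))))
  if (cfg$conv_kernel != 3 || cfg$conv_padding != 1 || cfg$conv_stride != 1 ||
      cfg$conv_dilation != 1 || cfg$pool_kernel != 2) {
    abort("only kernel 3 / padding 1 / stride 1 / dilation 1 convolutions with kernel-2 pooling are implemented")
  }
  structure(cfg, class = "net_config")
}

#' Desk-scale training profile
#'
#' The shipped defaults mirror the published full-scale configuration; for
#' synthetic desk-scale data (thousands of samples, a handful of epochs) a
#' larger step size and small batches are appropriate.  This helper returns
#' the same architecture with `lr = 1e-3` and `batch_size = 64`.
#'
#' @param ... Overrides passed on to [net_config()].
#' @export
net_config_desk <- function(...) net_config(lr = 1e-3, batch_size = 64, ...)

block_channels <- function(cfg) {
  c_in <- cfg$embed_dim
  sizes <- list()
  for (b in seq_len(cfg$n_blocks)) {
    sizes[[b]] <- c(inp = c_in, out = c_in + cfg$conv_filters)
    c_in <- c_in + cfg$conv_filters
  }
  sizes
}

resnet_flat_width <- function(cfg) {
  T <- cfg$window_len
  for (b in seq_len(cfg$n_blocks)) T <- T %/% 2
  ch <- block_channels(cfg)
  unname(ch[[cfg$n_blocks]]["out"]) * T
}

#' Initialise network parameters
#'
#' He-scaled Gaussian weights, zero biases, unit batch-norm gains; the
#' 21 x 21 window-embedding lookup table is trainable and initialised to
#' standard normal scaled by 0.1.
#'
#' @param config A [net_config()].
#' @param seed Integer seed (all initialisation randomness flows from it).
#' @return A `glycobind_net`: list with `config`, `params`, `bn_state`,
#'   `strategy_tag`.
#' @export
net_init <- function(config = net_config(), seed = 1) {
  set.seed(seed)
  P <- list()
  S <- list()
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  add_bn <- function(name, width) {
    P[[paste0(name, "_gamma")]] <<- rep(1, width)
    P[[paste0(name, "_beta")]] <<- rep(0, width)
    S[[paste0(name, "_mean")]] <<- rep(0, width)
    S[[paste0(name, "_var")]] <<- rep(1, width)
  }
  P$emb <- matrix(rnorm(config$alphabet_size * config$embed_dim, sd = 0.1),
                  config$alphabet_size, config$embed_dim)
  for (b in seq_len(config$n_blocks)) {
    cin <- block_channels(config)[[b]]["inp"]
    f <- config$conv_filters
    P[[paste0("conv", b, "a_W")]] <- he(3 * cin, f)
    P[[paste0("conv", b, "a_b")]] <- rep(0, f)
    add_bn(paste0("bn", b, "a"), f)
    P[[paste0("conv", b, "b_W")]] <- he(3 * f, f)
    P[[paste0("conv", b, "b_b")]] <- rep(0, f)
    add_bn(paste0("bn", b, "b"), f)
  }
  flat <- resnet_flat_width(config)
  P$res_W <- he(flat, config$resnet_out); P$res_b <- rep(0, config$resnet_out)
  add_bn("bn_res", config$resnet_out)
  P$fnn1_W <- he(config$fnn_in, config$fnn_hidden1); P$fnn1_b <- rep(0, config$fnn_hidden1)
  add_bn("bn_f1", config$fnn_hidden1)
  P$fnn2_W <- he(config$fnn_hidden1, config$fnn_hidden2); P$fnn2_b <- rep(0, config$fnn_hidden2)
  add_bn("bn_f2", config$fnn_hidden2)
  P$head1_W <- he(config$resnet_out + config$fnn_hidden2, config$head_hidden)
  P$head1_b <- rep(0, config$head_hidden)
  add_bn("bn_h1", config$head_hidden)
  P$head2_W <- he(config$head_hidden, 1); P$head2_b <- rep(0, 1)
  structure(list(config = config, params = P, bn_state = S,
                 strategy_tag = NA_character_, loss_trajectory = numeric(0)),
            class = "glycobind_net")
}

#' @export
print.glycobind_net <- function(x, ...) {
  cat(sprintf("<glycobind_net> %s parameters, strategy %s, %d epochs trained\n",
              format(net_n_params(x), big.mark = ","),
              x$strategy_tag, length(x$loss_trajectory)))
  invisible(x)
}

#' Total trainable parameter count
#' @param net A `glycobind_net`.
#' @return Integer.
#' @export
net_n_params <- function(net) sum(vapply(net$params, length, integer(1)))

# forward through one residual block (+ its trailing max-pool);
# returns output, new T, cache, possibly updated bn_state
res_block_forward <- function(X, net, b, B, T, training, trace = NULL) {
  P <- net$params; S <- net$bn_state
  cin <- ncol(X)
  cache <- list(cin = cin, T = T)
  cv1 <- conv1d_forward(X, P[[paste0("conv", b, "a_W")]], P[[paste0("conv", b, "a_b")]], B, T)
  bn1 <- bn_forward(cv1$out, P[[paste0("bn", b, "a_gamma")]], P[[paste0("bn", b, "a_beta")]],
                    S[[paste0("bn", b, "a_mean")]], S[[paste0("bn", b, "a_var")]], training)
  r1 <- relu_forward(bn1$out)
  cv2 <- conv1d_forward(r1$out, P[[paste0("conv", b, "b_W")]], P[[paste0("conv", b, "b_b")]], B, T)
  bn2 <- bn_forward(cv2$out, P[[paste0("bn", b, "b_gamma")]], P[[paste0("bn", b, "b_beta")]],
                    S[[paste0("bn", b, "b_mean")]], S[[paste0("bn", b, "b_var")]], training)
  r2 <- relu_forward(bn2$out)
  cat_out <- cbind(X, r2$out)
  if (!is.null(trace)) trace(sprintf("block%d", b), ncol(cat_out), T)
  pool <- maxpool2_forward(cat_out, B, T)
  if (!is.null(trace)) trace(sprintf("pool%d", b), ncol(cat_out), T %/% 2)
  S[[paste0("bn", b, "a_mean")]] <- bn1$rmean; S[[paste0("bn", b, "a_var")]] <- bn1$rvar
  S[[paste0("bn", b, "b_mean")]] <- bn2$rmean; S[[paste0("bn", b, "b_var")]] <- bn2$rvar
  cache <- c(cache, list(cv1 = cv1, bn1 = bn1, r1 = r1, cv2 = cv2, bn2 = bn2,
                         r2 = r2, pool = pool))
  list(out = pool$out, T = T %/% 2, cache = cache, bn_state = S)
}

res_block_backward <- function(dY, net, b, cache, B) {
  P <- net$params
  T <- cache$T; cin <- cache$cin
  dcat <- maxpool2_backward(dY, cache$pool, cin + net$config$conv_filters)
  dskip <- dcat[, seq_len(cin), drop = FALSE]
  dr2 <- dcat[, (cin + 1):ncol(dcat), drop = FALSE]
  G <- list()
  d <- dr2 * cache$r2$mask
  bb <- bn_backward(d, cache$bn2, P[[paste0("bn", b, "b_gamma")]])
  G[[paste0("bn", b, "b_gamma")]] <- bb$dgamma; G[[paste0("bn", b, "b_beta")]] <- bb$dbeta
  cb <- conv1d_backward(bb$dX, cache$cv2, P[[paste0("conv", b, "b_W")]], B, T,
                        net$config$conv_filters)
  G[[paste0("conv", b, "b_W")]] <- cb$dW; G[[paste0("conv", b, "b_b")]] <- cb$db
  d <- cb$dX * cache$r1$mask
  ba <- bn_backward(d, cache$bn1, P[[paste0("bn", b, "a_gamma")]])
  G[[paste0("bn", b, "a_gamma")]] <- ba$dgamma; G[[paste0("bn", b, "a_beta")]] <- ba$dbeta
  ca <- conv1d_backward(ba$dX, cache$cv1, P[[paste0("conv", b, "a_W")]], B, T, cin)
  G[[paste0("conv", b, "a_W")]] <- ca$dW; G[[paste0("conv", b, "a_b")]] <- ca$db
  list(dX = dskip + ca$dX, grads = G)
}

flatten_ct <- function(X, B, T) {
  C <- ncol(X)
  M <- matrix(0, B, C * T)
  for (t in seq_len(T)) M[, (seq_len(C) - 1) * T + t] <- X[((t - 1) * B + 1):(t * B), ]
  M
}

unflatten_ct <- function(M, B, T, C) {
  X <- matrix(0, B * T, C)
  for (t in seq_len(T)) X[((t - 1) * B + 1):(t * B), ] <- M[, (seq_len(C) - 1) * T + t]
  X
}

net_forward_full <- function(net, windows, features, training = FALSE,
                             want_cache = FALSE, want_trace = FALSE) {
  cfg <- net$config
  P <- net$params; B <- nrow(windows)
  if (!is.null(features) && nrow(features) != B) abort("batch mismatch between windows and features")
  if (!is.null(features) && ncol(features) != cfg$fnn_in) {
    abort(sprintf("feature width mismatch: expected %d, got %d", cfg$fnn_in, ncol(features)))
  }
  if (ncol(windows) != cfg$window_len) {
    abort(sprintf("window length mismatch: expected %d, got %d", cfg$window_len, ncol(windows)))
  }
  tr <- list()
  trace_fn <- if (want_trace) function(nm, C, T) tr[[nm]] <<- c(channels = C, positions = T) else NULL
  cache <- list()

  emb <- embedding_forward(windows, P$emb, B, cfg$window_len)
  if (want_trace) { tr[["embedding"]] <- c(channels = ncol(P$emb), positions = cfg$window_len) }
  X <- emb$out; T <- cfg$window_len
  blocks <- list()
  for (b in seq_len(cfg$n_blocks)) {
    rb <- res_block_forward(X, net, b, B, T, training, trace = trace_fn)
    net$bn_state <- rb$bn_state
    blocks[[b]] <- rb$cache
    X <- rb$out; T <- rb$T
  }
  C_last <- ncol(X)
  flat <- flatten_ct(X, B, T)
  lr_ <- linear_forward(flat, P$res_W, P$res_b)
  bnr <- bn_forward(lr_$out, P$bn_res_gamma, P$bn_res_beta,
                    net$bn_state$bn_res_mean, net$bn_state$bn_res_var, training)
  net$bn_state$bn_res_mean <- bnr$rmean; net$bn_state$bn_res_var <- bnr$rvar
  dor <- dropout_forward(bnr$out, cfg$dropout, training)
  rr <- relu_forward(dor$out)
  r_out <- rr$out
  if (want_trace) tr[["resnet_linear"]] <- c(channels = ncol(r_out), positions = 1)

  if (is.null(features)) {  # branch-only forward
    return(list(resnet_out = r_out, trace = tr, net = net))
  }

  l1 <- linear_forward(features, P$fnn1_W, P$fnn1_b)
  bf1 <- bn_forward(l1$out, P$bn_f1_gamma, P$bn_f1_beta,
                    net$bn_state$bn_f1_mean, net$bn_state$bn_f1_var, training)
  net$bn_state$bn_f1_mean <- bf1$rmean; net$bn_state$bn_f1_var <- bf1$rvar
  df1 <- dropout_forward(bf1$out, cfg$dropout, training)
  rf1 <- relu_forward(df1$out)
  l2 <- linear_forward(rf1$out, P$fnn2_W, P$fnn2_b)
  bf2 <- bn_forward(l2$out, P$bn_f2_gamma, P$bn_f2_beta,
                    net$bn_state$bn_f2_mean, net$bn_state$bn_f2_var, training)
  net$bn_state$bn_f2_mean <- bf2$rmean; net$bn_state$bn_f2_var <- bf2$rvar
  df2 <- dropout_forward(bf2$out, cfg$dropout, training)
  rf2 <- relu_forward(df2$out)
  f_out <- rf2$out

  H <- cbind(r_out, f_out)
  h1 <- linear_forward(H, P$head1_W, P$head1_b)
  bh1 <- bn_forward(h1$out, P$bn_h1_gamma, P$bn_h1_beta,
                    net$bn_state$bn_h1_mean, net$bn_state$bn_h1_var, training)
  net$bn_state$bn_h1_mean <- bh1$rmean; net$bn_state$bn_h1_var <- bh1$rvar
  dh1 <- dropout_forward(bh1$out, cfg$dropout, training)
  rh1 <- relu_forward(dh1$out)
  h2 <- linear_forward(rh1$out, P$head2_W, P$head2_b)
  z <- as.numeric(h2$out)

  out <- list(logits = z, prob = 1 / (1 + exp(-z)), trace = tr, net = net)
  if (want_cache) {
    out$cache <- list(emb = emb, blocks = blocks, C_last = C_last, T_last = T,
                      flat = flat, lr_ = lr_, bnr = bnr, dor = dor, rr = rr,
                      l1 = l1, bf1 = bf1, df1 = df1, rf1 = rf1,
                      l2 = l2, bf2 = bf2, df2 = df2, rf2 = rf2,
                      h1 = h1, bh1 = bh1, dh1 = dh1, rh1 = rh1, B = B)
  }
  out
}

net_backward_full <- function(net, cache, dz) {
  cfg <- net$config; P <- net$params; B <- cache$B
  G <- list()
  dh2 <- matrix(dz, ncol = 1)
  lb2 <- linear_backward(dh2, cache$h2 %||% list(X = cache$rh1$out), P$head2_W)
  G$head2_W <- lb2$dW; G$head2_b <- lb2$db
  d <- lb2$dX * cache$rh1$mask
  if (!is.null(cache$dh1$mask)) d <- d * cache$dh1$mask
  bh <- bn_backward(d, cache$bh1, P$bn_h1_gamma)
  G$bn_h1_gamma <- bh$dgamma; G$bn_h1_beta <- bh$dbeta
  lh1 <- linear_backward(bh$dX, cache$h1, P$head1_W)
  G$head1_W <- lh1$dW; G$head1_b <- lh1$db
  dr <- lh1$dX[, seq_len(cfg$resnet_out), drop = FALSE]
  df <- lh1$dX[, (cfg$resnet_out + 1):ncol(lh1$dX), drop = FALSE]

  # FNN branch
  d <- df * cache$rf2$mask
  if (!is.null(cache$df2$mask)) d <- d * cache$df2$mask
  b2 <- bn_backward(d, cache$bf2, P$bn_f2_gamma)
  G$bn_f2_gamma <- b2$dgamma; G$bn_f2_beta <- b2$dbeta
  l2 <- linear_backward(b2$dX, cache$l2, P$fnn2_W)
  G$fnn2_W <- l2$dW; G$fnn2_b <- l2$db
  d <- l2$dX * cache$rf1$mask
  if (!is.null(cache$df1$mask)) d <- d * cache$df1$mask
  b1 <- bn_backward(d, cache$bf1, P$bn_f1_gamma)
  G$bn_f1_gamma <- b1$dgamma; G$bn_f1_beta <- b1$dbeta
  l1 <- linear_backward(b1$dX, cache$l1, P$fnn1_W)
  G$fnn1_W <- l1$dW; G$fnn1_b <- l1$db

  # ResNet branch
  d <- dr * cache$rr$mask
  if (!is.null(cache$dor$mask)) d <- d * cache$dor$mask
  br <- bn_backward(d, cache$bnr, P$bn_res_gamma)
  G$bn_res_gamma <- br$dgamma; G$bn_res_beta <- br$dbeta
  lres <- linear_backward(br$dX, cache$lr_, P$res_W)
  G$res_W <- lres$dW; G$res_b <- lres$db
  dX <- unflatten_ct(lres$dX, B, cache$T_last, cache$C_last)
  for (b in rev(seq_len(cfg$n_blocks))) {
    rb <- res_block_backward(dX, net, b, cache$blocks[[b]], B)
    G <- c(G, rb$grads)
    dX <- rb$dX
  }
  G$emb <- embedding_backward(dX, cache$emb, cfg$alphabet_size)
  G
}

#' Forward pass of the residual-convolutional branch
#'
#' Embedding lookup (31 -> 31 x 21), three residual blocks with
#' concatenation skips and kernel-2 max pooling (channels 21 -> 31 -> 41 ->
#' 51; positions 31 -> 15 -> 7 -> 3), flatten, and a linear layer to the
#' 32-wide branch output.
#'
#' @param net A `glycobind_net`.
#' @param windows Integer matrix (B x 31) of indices in `[0, 20]`.
#' @param trace Record the (channels, positions) shape after every stage?
#' @return B x 32 matrix; with `trace = TRUE`, a `shape_trace` attribute
#'   (named list of `c(channels, positions)`) is attached.
#' @export
resnet_branch_forward <- function(net, windows, trace = FALSE) {
  res <- net_forward_full(net, windows, features = NULL, training = FALSE,
                          want_trace = trace)
  out <- res$resnet_out
  if (trace) attr(out, "shape_trace") <- res$trace
  out
}

#' Forward pass of the feed-forward branch
#'
#' Two linear layers (2340 -> 512 -> 256), each followed by batch
#' normalisation, dropout (inactive in this evaluation-mode pass) and ReLU.
#'
#' @param net A `glycobind_net`.
#' @param features Numeric matrix (B x 2340).
#' @return B x 256 matrix.
#' @export
fnn_branch_forward <- function(net, features) {
  cfg <- net$config; P <- net$params
  if (ncol(features) != cfg$fnn_in) {
    abort(sprintf("feature width mismatch: expected %d, got %d", cfg$fnn_in, ncol(features)))
  }
  l1 <- linear_forward(features, P$fnn1_W, P$fnn1_b)
  b1 <- bn_forward(l1$out, P$bn_f1_gamma, P$bn_f1_beta,
                   net$bn_state$bn_f1_mean, net$bn_state$bn_f1_var, FALSE)
  r1 <- relu_forward(b1$out)
  l2 <- linear_forward(r1$out, P$fnn2_W, P$fnn2_b)
  b2 <- bn_forward(l2$out, P$bn_f2_gamma, P$bn_f2_beta,
                   net$bn_state$bn_f2_mean, net$bn_state$bn_f2_var, FALSE)
  relu_forward(b2$out)$out
}

#' Full evaluation-mode forward pass
#'
#' @param net A `glycobind_net`.
#' @param windows Integer matrix (B x 31).
#' @param features Numeric matrix (B x 2340).
#' @param batch Evaluation mini-batch size (memory bound only).
#' @return Numeric vector of B probabilities in (0, 1).
#' @export
predict_net <- function(net, windows, features, batch = 4096) {
  B <- nrow(windows)
  out <- numeric(B)
  for (s in seq(1, B, by = batch)) {
    e <- min(B, s + batch - 1)
    out[s:e] <- net_forward_full(net, windows[s:e, , drop = FALSE],
                                 features[s:e, , drop = FALSE],
                                 training = FALSE)$prob
  }
  out
}

#' Record the architecture shape trace
#'
#' Runs a forward pass of the ResNet branch on a valid batch and returns the
#' observed tensor shapes stage by stage.
#'
#' @param net A `glycobind_net` (default: freshly initialised).
#' @param batch Batch size for the probe.
#' @return Tibble with `stage`, `channels`, `positions`.
#' @export
net_shape_trace <- function(net = net_init(net_config(), seed = 1), batch = 4) {
  win <- matrix(sample(0:20, batch * net$config$window_len, replace = TRUE),
                batch, net$config$window_len)
  out <- resnet_branch_forward(net, win, trace = TRUE)
  tr <- attr(out, "shape_trace")
  tibble(stage = names(tr),
         channels = vapply(tr, `[[`, numeric(1), "channels"),
         positions = vapply(tr, `[[`, numeric(1), "positions"))
}
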