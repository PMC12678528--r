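#' Deep baseline configuration
#'
#' Reduced-scale replicas of the two nonlinear reference pipelines: a
#' two-layer recurrent LSTM (tanh activations in both recurrent layers)
#' with a linear head, and a committee of feed-forward networks (three
#' dense layers: tanh, tanh, linear) whose predictions are averaged.
#' Defaults keep training CPU-friendly; results are comparison
#' scaffolding, not the package's core method.
#'
#' @param variant `"ffn"` or `"lstm"`.
#' @param hidden Hidden width (per layer).
#' @param n_committee Number of committee members (ffn only; default 5).
#' @param window Sequence window length in samples (lstm only).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param seed RNG seed; member k trains with a seed derived from it.
#' @param init `"xavier"` (default) or `"zero"` weight initialization.
#' @export
dl_config <- function(variant = c("ffn", "lstm"), hidden = NULL,
                      n_committee = 5, window = 64, epochs = 30,
                      batch_size = 256, learning_rate = 0.01, seed = 1,
                      init = c("xavier", "zero")) {
  variant <- match.arg(variant)
  init <- match.arg(init)
  hidden <- hidden %||% if (variant == "ffn") 32L else 64L
  if (n_committee < 1 || hidden < 1 || window < 1 || epochs < 0 ||
      batch_size < 1)
    wmlr_stop("dl_config sizes must be positive (n_committee >= 1)",
              "wmlr_config_error")
  list(variant = variant, hidden = as.integer(hidden),
       n_committee = as.integer(n_committee), window = as.integer(window),
       epochs = as.integer(epochs), batch_size = as.integer(batch_size),
       learning_rate = learning_rate, seed = as.integer(seed), init = init)
}

# --- Adam optimizer over a flat list of parameter matrices ------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(params)) {
    state$m[[k]] <- b1 * state$m[[k]] + (1 - b1) * grads[[k]]
    state$v[[k]] <- b2 * state$v[[k]] + (1 - b2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - b1^state$t)
    vhat <- state$v[[k]] / (1 - b2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# --- Feed-forward network ---------------------------------------------------

ffn_init <- function(p, h, q, init) {
  sc <- function(fan) if (init == "zero") 0 else sqrt(1 / fan)
  list(W1 = matrix(stats::rnorm(h * p, 0, sc(p)), h, p), b1 = numeric(h),
       W2 = matrix(stats::rnorm(h * h, 0, sc(h)), h, h), b2 = numeric(h),
       W3 = matrix(stats::rnorm(q * h, 0, sc(h)), q, h), b3 = numeric(q))
}

ffn_forward <- function(par, X) {
  H1 <- tanh(X %*% t(par$W1) + matrix(par$b1, nrow(X), length(par$b1),
                                      byrow = TRUE))
  H2 <- tanh(H1 %*% t(par$W2) + matrix(par$b2, nrow(X), length(par$b2),
                                       byrow = TRUE))
  out <- H2 %*% t(par$W3) + matrix(par$b3, nrow(X), length(par$b3),
                                   byrow = TRUE)
  list(H1 = H1, H2 = H2, out = out)
}

ffn_grads <- function(par, X, Y, fw) {
  n <- nrow(X)
  dOut <- 2 * (fw$out - Y) / (n * ncol(Y))        # d mean squared error
  dH2 <- (dOut %*% par$W3) * (1 - fw$H2^2)
  dH1 <- (dH2 %*% par$W2) * (1 - fw$H1^2)
  list(W1 = crossprod(dH1, X), b1 = colSums(dH1),
       W2 = crossprod(dH2, fw$H1), b2 = colSums(dH2),
       W3 = crossprod(dOut, fw$H2), b3 = colSums(dOut))
}

train_ffn_member <- function(Xs, Ys, config, seed) {
  n <- nrow(Xs)
  with_seed(seed, {
    par <- ffn_init(ncol(Xs), config$hidden, ncol(Ys), config$init)
    opt <- adam_new(par)
    losses <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- perm[s:min(s + config$batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]; Yb <- Ys[idx, , drop = FALSE]
        fw <- ffn_forward(par, Xb)
        gr <- ffn_grads(par, Xb, Yb, fw)
        st <- adam_step(par, gr, opt, config$learning_rate)
        par <- st$params; opt <- st$state
      }
      losses[ep] <- mean((ffn_forward(par, Xs)$out - Ys)^2)
      if (!is.finite(losses[ep]))
        wmlr_stop(sprintf("FFN training diverged at epoch %d", ep),
                  "wmlr_divergence_error")
    }
    list(par = par, loss = losses)
  })
}

# --- 2-layer LSTM with linear head ------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_init <- function(p, h, q, init) {
  sc <- function(fan) if (init == "zero") 0 else sqrt(1 / fan)
  layer <- function(pin) list(Wx = matrix(stats::rnorm(pin * 4 * h, 0, sc(pin)),
                                          pin, 4 * h),
                              Wh = matrix(stats::rnorm(h * 4 * h, 0, sc(h)),
                                          h, 4 * h),
                              b = numeric(4 * h))
  list(l1 = layer(p), l2 = layer(h),
       Why = matrix(stats::rnorm(h * q, 0, sc(h)), h, q), by = numeric(q))
}

# forward one layer over a window batch; X is a list of B x pin matrices
lstm_layer_forward <- function(lay, xs, h) {
  B <- nrow(xs[[1]]); Tn <- length(xs)
  H <- matrix(0, B, h); Cc <- matrix(0, B, h)
  cache <- vector("list", Tn)
  hs <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    a <- xs[[t]] %*% lay$Wx + H %*% lay$Wh +
      matrix(lay$b, B, 4 * h, byrow = TRUE)
    i <- sigmoid(a[, 1:h, drop = FALSE])
    f <- sigmoid(a[, (h + 1):(2 * h), drop = FALSE])
    o <- sigmoid(a[, (2 * h + 1):(3 * h), drop = FALSE])
    g <- tanh(a[, (3 * h + 1):(4 * h), drop = FALSE])
    Cprev <- Cc
    Cc <- f * Cprev + i * g
    tc <- tanh(Cc)
    Hprev <- H
    H <- o * tc
    cache[[t]] <- list(i = i, f = f, o = o, g = g, C = Cc, Cprev = Cprev,
                       tc = tc, Hprev = Hprev, x = xs[[t]])
    hs[[t]] <- H
  }
  list(hs = hs, cache = cache)
}

lstm_layer_backward <- function(lay, cache, dhs, h) {
  Tn <- length(cache); B <- nrow(dhs[[1]])
  dWx <- lay$Wx * 0; dWh <- lay$Wh * 0; db <- lay$b * 0
  dH <- matrix(0, B, h); dC <- matrix(0, B, h)
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dH
    do <- dh * cc$tc
    dC <- dC + dh * cc$o * (1 - cc$tc^2)
    di <- dC * cc$g; df <- dC * cc$Cprev; dg <- dC * cc$i
    da <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                do * cc$o * (1 - cc$o),
                dg * (1 - cc$g^2))
    dWx <- dWx + crossprod(cc$x, da)
    dWh <- dWh + crossprod(cc$Hprev, da)
    db <- db + colSums(da)
    dxs[[t]] <- da %*% t(lay$Wx)
    dH <- da %*% t(lay$Wh)
    dC <- dC * cc$f
  }
  list(dWx = dWx, dWh = dWh, db = db, dxs = dxs)
}

lstm_forward <- function(par, xs, h) {
  f1 <- lstm_layer_forward(par$l1, xs, h)
  f2 <- lstm_layer_forward(par$l2, f1$hs, h)
  outs <- lapply(f2$hs, function(H)
    H %*% par$Why + matrix(par$by, nrow(H), length(par$by), byrow = TRUE))
  list(f1 = f1, f2 = f2, outs = outs)
}

train_lstm <- function(Xs, Ys, config, seed) {
  W <- config$window
  n <- nrow(Xs); nw <- n %/% W
  if (nw < 1) wmlr_stop("dataset shorter than one window",
                        "wmlr_shape_error")
  h <- config$hidden
  # window w occupies rows (w-1)*W + 1 .. w*W; time-major slice lists
  xs_all <- lapply(seq_len(W), function(t)
    Xs[(seq_len(nw) - 1L) * W + t, , drop = FALSE])
  ys_all <- lapply(seq_len(W), function(t)
    Ys[(seq_len(nw) - 1L) * W + t, , drop = FALSE])
  with_seed(seed, {
    par <- lstm_init(ncol(Xs), h, ncol(Ys), config$init)
    opt <- list(t = 0L)  # Adam state built lazily from the flat param list
    losses <- numeric(config$epochs)
    nbatch <- max(1L, config$batch_size %/% W)  # windows per minibatch
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(nw)
      for (s in seq(1L, nw, by = nbatch)) {
        wsel <- perm[s:min(s + nbatch - 1L, nw)]
        xs <- lapply(xs_all, function(M) M[wsel, , drop = FALSE])
        ys <- lapply(ys_all, function(M) M[wsel, , drop = FALSE])
        fw <- lstm_forward(par, xs, h)
        B <- length(wsel)
        scale <- B * W * ncol(Ys)
        douts <- Map(function(o, y) 2 * (o - y) / scale, fw$outs, ys)
        dWhy <- Reduce(`+`, Map(function(H, dO) crossprod(H, dO),
                                fw$f2$hs, douts))
        dby <- Reduce(`+`, lapply(douts, colSums))
        dh2 <- lapply(douts, function(dO) dO %*% t(par$Why))
        b2 <- lstm_layer_backward(par$l2, fw$f2$cache, dh2, h)
        b1 <- lstm_layer_backward(par$l1, fw$f1$cache, b2$dxs, h)
        gr <- list(l1 = list(Wx = b1$dWx, Wh = b1$dWh, b = b1$db),
                   l2 = list(Wx = b2$dWx, Wh = b2$dWh, b = b2$db),
                   Why = dWhy, by = dby)
        flatp <- list(l1.Wx = par$l1$Wx, l1.Wh = par$l1$Wh, l1.b = par$l1$b,
                      l2.Wx = par$l2$Wx, l2.Wh = par$l2$Wh, l2.b = par$l2$b,
                      Why = par$Why, by = par$by)
        flatg <- list(l1.Wx = gr$l1$Wx, l1.Wh = gr$l1$Wh, l1.b = gr$l1$b,
                      l2.Wx = gr$l2$Wx, l2.Wh = gr$l2$Wh, l2.b = gr$l2$b,
                      Why = gr$Why, by = gr$by)
        if (opt$t == 0L) opt <- adam_new(flatp)
        st <- adam_step(flatp, flatg, opt, config$learning_rate)
        opt <- st$state
        par <- list(l1 = list(Wx = st$params$l1.Wx, Wh = st$params$l1.Wh,
                              b = st$params$l1.b),
                    l2 = list(Wx = st$params$l2.Wx, Wh = st$params$l2.Wh,
                              b = st$params$l2.b),
                    Why = st$params$Why, by = st$params$by)
      }
      fw <- lstm_forward(par, xs_all, h)
      err <- Map(function(o, y) o - y, fw$outs, ys_all)
      losses[ep] <- mean(vapply(err, function(e) mean(e^2), numeric(1)))
      if (!is.finite(losses[ep]))
        wmlr_stop(sprintf("LSTM training diverged at epoch %d", ep),
                  "wmlr_divergence_error")
    }
    list(par = par, loss = losses)
  })
}

#' Train a deep baseline
#'
#' Channels are standardized by training statistics (stored so
#' predictions return raw millivolts). The FFN variant trains
#' `n_committee` members on identical data with member-specific seeds and
#' averages their predictions; the LSTM variant trains one two-layer
#' recurrent model over non-overlapping windows. Training uses
#' backpropagation with the Adam update; the per-epoch loss sequence is
#' recorded.
#'
#' @param X,Y Observations x channels matrices (inputs, targets, mV).
#' @param config A [dl_config()].
#' @return A `dl_model`.
#' @export
train_dl <- function(X, Y, config = dl_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!nrow(X) || nrow(X) != nrow(Y))
    wmlr_stop("X and Y must be nonempty with equal rows", "wmlr_shape_error")
  input_names <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  output_names <- colnames(Y) %||% paste0("y", seq_len(ncol(Y)))
  xm <- colMeans(X); ym <- colMeans(Y)
  xs <- apply(X, 2, stats::sd); ys <- apply(Y, 2, stats::sd)
  xs[xs == 0 | !is.finite(xs)] <- 1; ys[ys == 0 | !is.finite(ys)] <- 1
  Xs <- sweep(sweep(X, 2, xm), 2, xs, "/")
  Ys <- sweep(sweep(Y, 2, ym), 2, ys, "/")
  members <- if (config$variant == "ffn") {
    lapply(seq_len(config$n_committee), function(k)
      train_ffn_member(Xs, Ys, config, derive_seed(config$seed, k)))
  } else {
    list(train_lstm(Xs, Ys, config, config$seed))
  }
  structure(list(variant = config$variant, config = config,
                 members = members,
                 loss = lapply(members, `[[`, "loss"),
                 input_names = input_names, output_names = output_names,
                 scaling = list(x_center = xm, x_scale = xs,
                                y_center = ym, y_scale = ys)),
            class = "dl_model")
}

#' Predict from a deep baseline
#'
#' Committee output is the unweighted mean of member outputs; results are
#' in raw millivolts, one row per input sample.
#'
#' @param model A `dl_model` from [train_dl()].
#' @param X Input matrix with the training channel count.
#' @export
predict_dl <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$input_names))
    wmlr_stop("input channel count does not match the trained model",
              "wmlr_shape_error")
  sc <- model$scaling
  Xs <- sweep(sweep(X, 2, sc$x_center), 2, sc$x_scale, "/")
  preds <- lapply(model$members, function(mb) {
    if (model$variant == "ffn") {
      ffn_forward(mb$par, Xs)$out
    } else {
      W <- model$config$window
      n <- nrow(Xs)
      pad <- (W - n %% W) %% W
      Xp <- rbind(Xs, matrix(0, pad, ncol(Xs)))
      nw <- nrow(Xp) %/% W
      xs <- lapply(seq_len(W), function(t)
        Xp[(seq_len(nw) - 1L) * W + t, , drop = FALSE])
      fw <- lstm_forward(mb$par, xs, model$config$hidden)
      out <- matrix(0, nrow(Xp), length(model$output_names))
      for (t in seq_len(W)) out[(seq_len(nw) - 1L) * W + t, ] <- fw$outs[[t]]
      out[seq_len(n), , drop = FALSE]
    }
  })
  Ys <- Reduce(`+`, preds) / length(preds)
  Yhat <- sweep(sweep(Ys, 2, sc$y_scale, "*"), 2, sc$y_center, "+")
  colnames(Yhat) <- model$output_names
  Yhat
}

#' @export
predict.dl_model <- function(object, X, ...) predict_dl(object, X)

#' @export
print.dl_model <- function(x, ...) {
  cat(sprintf("<dl_model> %s: %d member(s), hidden %d\n", x$variant,
              length(x$members), x$config$hidden))
  invisible(x)
}
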