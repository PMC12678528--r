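#' Linear lead transform y = A x + C
#'
#' A `linear_lead_model` maps input channel samples to output lead samples
#' per time point: `y = A x + C` with coefficient matrix `A`
#' (outputs x inputs) and intercept vector `C`. `A` and `C` are always
#' stored in raw millivolt units; `scaling_state` records any internal
#' standardization used during fitting so that predictions are invariant
#' to that choice.
#'
#' @name linear_lead_model
NULL

new_linear_model <- function(A, C, input_names, output_names,
                             scaling_state = NULL, fitter = "ols",
                             meta = list()) {
  A <- as.matrix(A)
  dimnames(A) <- list(output_names, input_names)
  names(C) <- output_names
  structure(list(A = A, C = C, input_names = input_names,
                 output_names = output_names,
                 scaling_state = scaling_state, fitter = fitter,
                 meta = meta),
            class = "linear_lead_model")
}

#' @export
print.linear_lead_model <- function(x, ...) {
  cat(sprintf("<linear_lead_model> (%s): %d inputs -> %d outputs\n",
              x$fitter, length(x$input_names), length(x$output_names)))
  invisible(x)
}

check_xy <- function(X, Y, input_names, output_names) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y))
    wmlr_stop("X and Y observation counts differ", "wmlr_shape_error")
  input_names <- input_names %||% colnames(X) %||%
    paste0("x", seq_len(ncol(X)))
  output_names <- output_names %||% colnames(Y) %||%
    paste0("y", seq_len(ncol(Y)))
  if (length(input_names) != ncol(X) || length(output_names) != ncol(Y))
    wmlr_stop("channel name lists do not match matrix dimensions",
              "wmlr_shape_error")
  if (nrow(X) < ncol(X) + 1L)
    wmlr_stop("need at least n_inputs + 1 observations", "wmlr_shape_error")
  list(X = X, Y = Y, input_names = input_names, output_names = output_names)
}

#' Closed-form least-squares fit of the lead transform
#'
#' Returns the minimizer of `||Y - (X A' + C)||^2` via SVD; for a
#' rank-deficient design the minimum-norm solution is returned with a
#' warning. This is the closed-form anchor the SGD fitter is checked
#' against.
#'
#' @param X Observations x input channels matrix.
#' @param Y Observations x output channels matrix.
#' @param input_names,output_names Channel labels (default: column names).
#' @return A [linear_lead_model].
#' @export
fit_ols <- function(X, Y, input_names = NULL, output_names = NULL) {
  d <- check_xy(X, Y, input_names, output_names)
  xm <- colMeans(d$X); ym <- colMeans(d$Y)
  Xc <- sweep(d$X, 2, xm); Yc <- sweep(d$Y, 2, ym)
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  r <- sum(sv$d > tol)
  if (r < ncol(Xc))
    warning("rank-deficient design: returning minimum-norm solution",
            call. = FALSE)
  dinv <- c(1 / sv$d[seq_len(r)], rep(0, ncol(Xc) - r))
  At <- sv$v %*% (dinv * (t(sv$u) %*% Yc))   # p x q
  A <- t(At)
  C <- as.numeric(ym - A %*% xm)
  new_linear_model(A, C, d$input_names, d$output_names, fitter = "ols")
}

#' SGD hyperparameters
#'
#' @param learning_rate Step size on standardized channels.
#' @param epochs Maximum passes over the data.
#' @param batch_size Minibatch size (mean-gradient updates).
#' @param seed RNG seed controlling batch shuffling (deterministic fits).
#' @param tol Early-stop threshold on epoch-loss improvement.
#' @export
sgd_config <- function(learning_rate = 0.05, epochs = 300, batch_size = 1024,
                       seed = 1, tol = 1e-12) {
  list(learning_rate = learning_rate, epochs = epochs,
       batch_size = batch_size, seed = seed, tol = tol)
}

#' Fit the lead transform by minibatch stochastic gradient descent
#'
#' Channels are centered and scaled by their training statistics, the
#' model is trained by mean-gradient minibatch SGD from a zero
#' initialization, and the coefficients are mapped back to raw millivolts
#' (so for a rank-deficient design SGD, like [fit_ols()], converges to the
#' minimum-norm solution). Deterministic given `hyper$seed`.
#'
#' @inheritParams fit_ols
#' @param hyper An [sgd_config()].
#' @return A [linear_lead_model] with recorded loss history in `meta`.
#' @export
fit_sgd <- function(X, Y, hyper = sgd_config(), input_names = NULL,
                    output_names = NULL) {
  d <- check_xy(X, Y, input_names, output_names)
  n <- nrow(d$X)
  xm <- colMeans(d$X); ym <- colMeans(d$Y)
  xs <- apply(d$X, 2, stats::sd); ys <- apply(d$Y, 2, stats::sd)
  xs[xs == 0] <- 1; ys[ys == 0] <- 1
  Xs <- sweep(sweep(d$X, 2, xm), 2, xs, "/")
  Ys <- sweep(sweep(d$Y, 2, ym), 2, ys, "/")
  p <- ncol(Xs); q <- ncol(Ys)
  A <- matrix(0, q, p); C <- numeric(q)
  lr <- hyper$learning_rate
  losses <- numeric(0)
  prev <- Inf
  with_seed(hyper$seed, {
    for (ep in seq_len(hyper$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = hyper$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + hyper$batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]
        E <- Xb %*% t(A) + matrix(C, length(idx), q, byrow = TRUE) -
          Ys[idx, , drop = FALSE]
        A <- A - lr * crossprod(E, Xb) / length(idx)
        C <- C - lr * colMeans(E)
      }
      R <- Xs %*% t(A) + matrix(C, n, q, byrow = TRUE) - Ys
      loss <- mean(R^2)
      # standardized channels start at loss ~ 1; an exploding loss means
      # the step size exceeds the stability limit
      if (!is.finite(loss) || loss > 1e8)
        wmlr_stop(sprintf("SGD diverged (exploding loss at epoch %d); reduce the learning rate", ep),
                  "wmlr_divergence_error")
      losses <- c(losses, loss)
      improvement <- prev - loss
      if (improvement >= 0 && improvement < hyper$tol) break
      prev <- min(prev, loss)
    }
  })
  A_raw <- (ys * A) * matrix(1 / xs, q, p, byrow = TRUE)
  C_raw <- as.numeric(ym + ys * C - A_raw %*% xm)
  new_linear_model(A_raw, C_raw, d$input_names, d$output_names,
                   scaling_state = list(x_center = xm, x_scale = xs,
                                        y_center = ym, y_scale = ys),
                   fitter = "sgd",
                   meta = list(hyper = hyper, loss = losses,
                               epochs_run = length(losses)))
}

#' Standardized coefficient matrix of a fitted model
#'
#' Expresses `A` on unit-variance channels (`A_std[i, j] = A[i, j] *
#' x_scale[j] / y_scale[i]`), using the model's stored scaling state or
#' supplied scales. Used to compare fitters independent of channel units.
#'
#' @param model A [linear_lead_model].
#' @param x_scale,y_scale Channel scales; default from `scaling_state`.
#' @export
standardized_coefs <- function(model, x_scale = NULL, y_scale = NULL) {
  x_scale <- x_scale %||% model$scaling_state$x_scale
  y_scale <- y_scale %||% model$scaling_state$y_scale
  if (is.null(x_scale) || is.null(y_scale))
    wmlr_stop("no scaling state available; supply x_scale and y_scale",
              "wmlr_value_error")
  sweep(sweep(model$A, 2, x_scale, "*"), 1, y_scale, "/")
}

#' Predict output leads from input channels
#'
#' `Yhat = X A' + C`, per sample, in raw millivolts. Column names of `X`
#' must match the model's input names in order; no silent reordering.
#'
#' @param object A [linear_lead_model].
#' @param X Observations x input channels matrix.
#' @param ... Unused.
#' @export
predict.linear_lead_model <- function(object, X, ...) {
  X <- as.matrix(X)
  if (is.null(colnames(X)) || !identical(colnames(X), object$input_names))
    wmlr_stop("input channel names/order do not match the model",
              "wmlr_alignment_error")
  Yhat <- X %*% t(object$A) +
    matrix(object$C, nrow(X), length(object$C), byrow = TRUE)
  colnames(Yhat) <- object$output_names
  Yhat
}

#' Derive the four limb leads from leads I and II
#'
#' Einthoven's law and the Goldberger augmented-lead identities:
#' `III = II - I`, `aVR = -(I + II)/2`, `aVL = I - II/2`, `aVF = II - I/2`,
#' exact per sample.
#'
#' @param lead_i,lead_ii Equal-length sample vectors (mV).
#' @return Matrix with columns `III`, `aVR`, `aVL`, `aVF`.
#' @export
derive_limb_leads <- function(lead_i, lead_ii) {
  if (length(lead_i) != length(lead_ii))
    wmlr_stop("leads I and II have different lengths", "wmlr_shape_error")
  cbind(III = lead_ii - lead_i,
        aVR = -(lead_i + lead_ii) / 2,
        aVL = lead_i - lead_ii / 2,
        aVF = lead_ii - lead_i / 2)
}

#' Model serialization
#'
#' Flat JSON holding `A`, `C`, channel names, scaling state, fitter and
#' fit metadata.
#'
#' @param model A [linear_lead_model].
#' @param path Output JSON path.
#' @export
save_model <- function(model, path) {
  obj <- list(A = unclass(model$A), C = unname(model$C),
              input_names = model$input_names,
              output_names = model$output_names,
              scaling_state = lapply(model$scaling_state, unname),
              fitter = model$fitter, meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_linear_model(obj$A, obj$C, obj$input_names, obj$output_names,
                   scaling_state = obj$scaling_state,
                   fitter = obj$fitter, meta = obj$meta)
}

#' Construct a reconstruction pipeline
#'
#' Variants mirror the five studied configurations:
#' * `p1` -- linear transform on raw leads I, II, V2 (outputs V1, V3,
#'   V4, V5, V6);
#' * `p2` -- linear transform on raw leads I, II, V3 (outputs V1, V2,
#'   V4, V5, V6);
#' * `wmlr` -- linear transform on the six-channel wave-masked augmented
#'   input (outputs as p2);
#' * `lstm`, `ffn` -- deep baselines on raw I, II, V3 (outputs as p2).
#'
#' The returned object bundles an input builder, a model fitter and the
#' output lead list, so every variant is interchangeable in
#' [cross_validate()].
#'
#' @param variant One of `"p1"`, `"p2"`, `"wmlr"`, `"lstm"`, `"ffn"`.
#' @param fitter `"ols"` or `"sgd"` for the linear variants.
#' @param sgd An [sgd_config()] used when `fitter = "sgd"`.
#' @param dl A [dl_config()] for the deep variants.
#' @param wave_leads Wave-to-lead mapping for the masked channels.
#' @return A `recon_pipeline` object.
#' @export
make_pipeline <- function(variant = c("p2", "p1", "wmlr", "lstm", "ffn"),
                          fitter = c("sgd", "ols"), sgd = sgd_config(),
                          dl = NULL,
                          wave_leads = c(P = "II", QRS = "V3", T = "I")) {
  if (!is.character(variant) || !(variant[1] %in% c("p1", "p2", "wmlr", "lstm", "ffn")))
    wmlr_stop(sprintf("unknown pipeline variant '%s'", variant[1]),
              "wmlr_config_error")
  variant <- variant[1]
  fitter <- match.arg(fitter)
  input_names <- switch(variant,
                        p1 = c("I", "II", "V2"),
                        p2 = , lstm = , ffn = c("I", "II", "V3"),
                        wmlr = AUGMENTED_CHANNELS)
  output_names <- if (variant == "p1") c("V1", "V3", "V4", "V5", "V6")
                  else c("V1", "V2", "V4", "V5", "V6")
  if (variant %in% c("lstm", "ffn") && is.null(dl))
    dl <- dl_config(variant = variant)
  build_input <- function(entry) {
    rec <- entry$record %||% entry
    if (variant == "wmlr") {
      if (is.null(entry$fiducials))
        wmlr_stop("wmlr pipeline needs fiducials for each record",
                  "wmlr_validation_error")
      build_augmented_input(rec, entry$fiducials,
                            wave_leads = wave_leads)$channels
    } else {
      miss <- setdiff(input_names, rec$lead_names)
      if (length(miss))
        wmlr_stop(paste("record lacks input lead(s):",
                        paste(miss, collapse = ", ")), "wmlr_lead_error")
      rec$samples[, input_names, drop = FALSE]
    }
  }
  build_output <- function(entry) {
    rec <- entry$record %||% entry
    miss <- setdiff(output_names, rec$lead_names)
    if (length(miss))
      wmlr_stop(paste("record lacks output lead(s):",
                      paste(miss, collapse = ", ")), "wmlr_lead_error")
    rec$samples[, output_names, drop = FALSE]
  }
  fit <- function(X, Y) {
    if (variant %in% c("lstm", "ffn"))
      train_dl(X, Y, config = dl)
    else if (fitter == "ols")
      fit_ols(X, Y, input_names, output_names)
    else
      fit_sgd(X, Y, hyper = sgd, input_names = input_names,
              output_names = output_names)
  }
  structure(list(variant = variant, fitter = fitter,
                 input_names = input_names, output_names = output_names,
                 build_input = build_input, build_output = build_output,
                 fit = fit, sgd = sgd, dl = dl, wave_leads = wave_leads),
            class = "recon_pipeline")
}

#' @export
print.recon_pipeline <- function(x, ...) {
  cat(sprintf("<recon_pipeline> %s: [%s] -> [%s]\n", x$variant,
              paste(x$input_names, collapse = ","),
              paste(x$output_names, collapse = ",")))
  invisible(x)
}
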