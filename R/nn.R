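# Minimal feed-forward / convolutional network engine.
#
# Tensor conventions: convolutional stages use arrays dim c(H, W, C, N)
# (H = statistic rows, W = positional intervals, C = channels, N = batch);
# fully connected stages use matrices dim c(d, N). Convolutions are stride-1
# with odd kernels and "same" zero padding, implemented by im2col gather with
# indices precomputed at build time. All layers are pure functions of
# (params, input) except batch-norm running statistics, which nn_forward
# returns in the updated net.

new_layer <- function(type, params = list(), ...) {
  c(list(type = type, params = params), list(...))
}

init_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

conv_idx <- function(H, W, C, kh, kw) {
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  Hp <- H + 2L * ph; Wp <- W + 2L * pw
  off <- as.vector(outer(0:(kh - 1L),
                         outer(0:(kw - 1L), 0:(C - 1L), function(dw, cc) Hp * dw + Hp * Wp * cc),
                         "+"))                                  # kh*kw*C offsets, dh fastest
  start <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))  # H*W starts, ho fastest
  list(idx = as.vector(outer(off, start, "+")), ph = ph, pw = pw, Hp = Hp, Wp = Wp)
}

#' Build a network from a layer specification
#'
#' @param spec list of layer specs, e.g. `list(list("conv", kh = 1, kw = 5,
#'   cout = 8), list("relu"), list("pool", kh = 1, kw = 4), list("flatten"),
#'   list("fc", out = 64), ...)`. Supported types: `conv`, `pool` (max),
#'   `relu`, `flatten`, `fc`, `bnorm`, `dropout`, `rnn`, `res_save`,
#'   `res_add_relu` (residual skip pair sharing an `id`).
#' @param input_shape `c(H, W, C)` for convolutional input or a scalar for
#'   vector input.
#' @return a `nn_net` list with `layers` and `out_shape`. Parameters are
#'   drawn from the current RNG state (seed before calling for
#'   reproducibility).
#' @export
nn_build <- function(spec, input_shape) {
  layers <- vector("list", length(spec))
  shape <- input_shape
  for (i in seq_along(spec)) {
    sp <- spec[[i]]
    type <- sp[[1]]
    if (type == "conv") {
      stopifnot(length(shape) == 3)
      H <- shape[1]; W <- shape[2]; C <- shape[3]
      kh <- sp$kh; kw <- sp$kw; cout <- sp$cout
      fan <- kh * kw * C
      layers[[i]] <- new_layer("conv",
        params = list(W = init_mat(cout, fan, sqrt(2 / fan)), b = numeric(cout)),
        kh = kh, kw = kw, cin = C, cout = cout, H = H, Wd = W,
        im = conv_idx(H, W, C, kh, kw))
      shape <- c(H, W, cout)
    } else if (type == "pool") {
      H <- shape[1]; W <- shape[2]
      if (sp$kh > 1 && H %% sp$kh != 0) stop("pool: height ", H, " not divisible by ", sp$kh)
      if (sp$kw > 1 && W %% sp$kw != 0) stop("pool: width ", W, " not divisible by ", sp$kw)
      layers[[i]] <- new_layer("pool", kh = sp$kh, kw = sp$kw, in_shape = shape)
      shape <- c(H %/% sp$kh, W %/% sp$kw, shape[3])
    } else if (type == "relu") {
      layers[[i]] <- new_layer("relu")
    } else if (type == "flatten") {
      layers[[i]] <- new_layer("flatten", in_shape = shape)
      shape <- prod(shape)
    } else if (type == "fc") {
      stopifnot(length(shape) == 1)
      layers[[i]] <- new_layer("fc",
        params = list(W = init_mat(sp$out, shape, sqrt(2 / shape)),
                      b = numeric(sp$out)))
      shape <- sp$out
    } else if (type == "bnorm") {
      d <- shape
      layers[[i]] <- new_layer("bnorm",
        params = list(gamma = rep(1, d), beta = numeric(d)),
        run_mean = numeric(d), run_var = rep(1, d), momentum = 0.9, eps = 1e-5)
    } else if (type == "dropout") {
      layers[[i]] <- new_layer("dropout", rate = sp$rate)
    } else if (type == "rnn") {
      stopifnot(length(shape) == 3)
      H <- shape[1]; hid <- sp$hidden
      layers[[i]] <- new_layer("rnn",
        params = list(Wx = init_mat(hid, H, sqrt(1 / H)),
                      Wh = init_mat(hid, hid, sqrt(1 / hid)),
                      b = numeric(hid)),
        hidden = hid, in_shape = shape)
      shape <- hid
    } else if (type == "res_save") {
      layers[[i]] <- new_layer("res_save", id = sp$id)
    } else if (type == "res_add_relu") {
      layers[[i]] <- new_layer("res_add_relu", id = sp$id)
    } else stop("unknown layer type: ", type)
  }
  structure(list(layers = layers, out_shape = shape), class = "nn_net")
}

pool_axis_fwd <- function(x, k, axis) {
  d <- dim(x)
  if (axis == 2) { x <- aperm(x, c(2, 1, 3, 4)); d <- dim(x) }
  R <- prod(d) %/% k
  M <- matrix(x, k, R)
  ii <- max.col(t(M), ties.method = "first")
  out <- array(M[cbind(ii, seq_len(R))], c(d[1] %/% k, d[2], d[3], d[4]))
  if (axis == 2) out <- aperm(out, c(2, 1, 3, 4))
  list(out = out, ii = ii, d = d)
}

pool_axis_bwd <- function(dout, cache, k, axis) {
  if (axis == 2) dout <- aperm(dout, c(2, 1, 3, 4))
  R <- length(cache$ii)
  dM <- matrix(0, k, R)
  dM[cbind(cache$ii, seq_len(R))] <- as.vector(dout)
  dx <- array(dM, cache$d)
  if (axis == 2) dx <- aperm(dx, c(2, 1, 3, 4))
  dx
}

#' Forward pass
#'
#' @param net a [nn_build()] network.
#' @param x input array `(H, W, C, N)` or matrix `(d, N)`.
#' @param train logical; enables batch-statistics batch-norm and dropout
#'   (dropout draws from the current RNG stream).
#' @return list `out`, `caches`, `net` (with updated batch-norm running
#'   statistics when `train`).
#' @export
nn_forward <- function(net, x, train = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      P <- ly$params; im <- ly$im
      d <- dim(x); N <- d[4]
      xp <- array(0, c(im$Hp, im$Wp, ly$cin, N))
      xp[im$ph + seq_len(d[1]), im$pw + seq_len(d[2]), , ] <- x
      dim(xp) <- c(im$Hp * im$Wp * ly$cin, N)
      Xc <- xp[im$idx, , drop = FALSE]
      dim(Xc) <- c(ly$kh * ly$kw * ly$cin, ly$H * ly$Wd * N)
      Y <- P$W %*% Xc + P$b
      x <- aperm(array(Y, c(ly$cout, ly$H, ly$Wd, N)), c(2, 3, 1, 4))
      caches[[i]] <- list(Xc = Xc, N = N)
    } else if (ly$type == "pool") {
      cc <- list()
      if (ly$kw > 1) {
        pf <- pool_axis_fwd(x, ly$kw, 2L)
        x <- pf$out
        cc$w <- list(ii = pf$ii, d = pf$d, k = ly$kw, ax = 2L)
      }
      if (ly$kh > 1) {
        pf <- pool_axis_fwd(x, ly$kh, 1L)
        x <- pf$out
        cc$h <- list(ii = pf$ii, d = pf$d, k = ly$kh, ax = 1L)
      }
      caches[[i]] <- cc
    } else if (ly$type == "relu") {
      mask <- x > 0
      x <- x * mask
      caches[[i]] <- mask
    } else if (ly$type == "flatten") {
      N <- dim(x)[4]
      caches[[i]] <- dim(x)
      dim(x) <- c(prod(dim(x)) / N, N)
    } else if (ly$type == "fc") {
      caches[[i]] <- x
      x <- ly$params$W %*% x + ly$params$b
    } else if (ly$type == "bnorm") {
      P <- ly$params
      if (train) {
        mu <- rowMeans(x); v <- rowMeans((x - mu)^2)
        net$layers[[i]]$run_mean <- ly$momentum * ly$run_mean + (1 - ly$momentum) * mu
        net$layers[[i]]$run_var <- ly$momentum * ly$run_var + (1 - ly$momentum) * v
      } else { mu <- ly$run_mean; v <- ly$run_var }
      xhat <- (x - mu) / sqrt(v + ly$eps)
      caches[[i]] <- list(xhat = xhat, x = x, mu = mu, v = v, train = train)
      x <- P$gamma * xhat + P$beta
    } else if (ly$type == "dropout") {
      if (train && ly$rate > 0) {
        keep <- 1 - ly$rate
        mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
        x <- x * mask
        caches[[i]] <- mask
      } else caches[[i]] <- NULL
    } else if (ly$type == "rnn") {
      P <- ly$params
      d <- dim(x); W <- d[2]; N <- d[4]
      xs <- array(x, c(d[1], W, N))          # C assumed 1
      h <- matrix(0, ly$hidden, N)
      hs <- vector("list", W)
      for (t in seq_len(W)) {
        h <- tanh(P$Wx %*% xs[, t, , drop = TRUE] + P$Wh %*% h + P$b)
        if (N == 1L) h <- matrix(h, ly$hidden, 1L)
        hs[[t]] <- h
      }
      caches[[i]] <- list(xs = xs, hs = hs, d = d)
      x <- h
    } else if (ly$type == "res_save") {
      caches[[i]] <- x                       # value re-used at the matching add
    } else if (ly$type == "res_add_relu") {
      saved <- NULL
      for (j in seq_len(i - 1)) {
        lj <- net$layers[[j]]
        if (lj$type == "res_save" && lj$id == ly$id) saved <- caches[[j]]
      }
      pre <- x + saved
      mask <- pre > 0
      x <- pre * mask
      caches[[i]] <- mask
    }
  }
  list(out = x, caches = caches, net = net)
}

#' Backward pass
#'
#' @param net network used in the forward pass.
#' @param caches caches from [nn_forward()].
#' @param dout gradient of the loss w.r.t. the network output.
#' @return list `dx` (gradient at the input) and `grads` (per-layer list
#'   mirroring each layer's `params`).
#' @export
nn_backward <- function(net, caches, dout) {
  grads <- vector("list", length(net$layers))
  res_d <- list()                            # id -> pending skip gradient
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    if (ly$type == "conv") {
      cc <- caches[[i]]; N <- cc$N; im <- ly$im
      dY <- aperm(dout, c(3, 1, 2, 4))
      dim(dY) <- c(ly$cout, ly$H * ly$Wd * N)
      grads[[i]] <- list(W = tcrossprod(dY, cc$Xc), b = rowSums(dY))
      dXc <- crossprod(ly$params$W, dY)
      dim(dXc) <- c(length(im$idx), N)
      rs <- rowsum(dXc, im$idx)
      dxp <- matrix(0, im$Hp * im$Wp * ly$cin, N)
      dxp[as.integer(rownames(rs)), ] <- rs
      dim(dxp) <- c(im$Hp, im$Wp, ly$cin, N)
      dout <- dxp[im$ph + seq_len(ly$H), im$pw + seq_len(ly$Wd), , , drop = FALSE]
    } else if (ly$type == "pool") {
      cc <- caches[[i]]
      if (!is.null(cc$h)) dout <- pool_axis_bwd(dout, cc$h, cc$h$k, 1L)
      if (!is.null(cc$w)) dout <- pool_axis_bwd(dout, cc$w, cc$w$k, 2L)
    } else if (ly$type == "relu") {
      dout <- dout * caches[[i]]
    } else if (ly$type == "flatten") {
      dim(dout) <- caches[[i]]
    } else if (ly$type == "fc") {
      x <- caches[[i]]
      grads[[i]] <- list(W = tcrossprod(dout, x), b = rowSums(dout))
      dout <- crossprod(ly$params$W, dout)
    } else if (ly$type == "bnorm") {
      cc <- caches[[i]]; P <- ly$params
      Nn <- ncol(cc$x)
      inv <- 1 / sqrt(cc$v + ly$eps)
      dxhat <- dout * P$gamma
      grads[[i]] <- list(gamma = rowSums(dout * cc$xhat), beta = rowSums(dout))
      if (cc$train) {
        # batch statistics are functions of x
        xc <- cc$x - cc$mu
        dv <- rowSums(dxhat * xc) * (-0.5) * inv^3
        dmu <- -rowSums(dxhat) * inv + dv * rowMeans(-2 * xc)
        dout <- dxhat * inv + dv * 2 * xc / Nn + dmu / Nn
      } else {
        # running statistics are constants
        dout <- dxhat * inv
      }
    } else if (ly$type == "dropout") {
      if (!is.null(caches[[i]])) dout <- dout * caches[[i]]
    } else if (ly$type == "rnn") {
      cc <- caches[[i]]; P <- ly$params
      W <- cc$d[2]; N <- cc$d[4]
      dWx <- 0 * P$Wx; dWh <- 0 * P$Wh; db <- 0 * P$b
      dxs <- array(0, dim(cc$xs))
      dh <- dout
      for (t in rev(seq_len(W))) {
        ht <- cc$hs[[t]]
        da <- dh * (1 - ht^2)
        xt <- matrix(cc$xs[, t, ], cc$d[1], N)
        hprev <- if (t > 1) cc$hs[[t - 1]] else matrix(0, ly$hidden, N)
        dWx <- dWx + tcrossprod(da, xt)
        dWh <- dWh + tcrossprod(da, hprev)
        db <- db + rowSums(da)
        dxs[, t, ] <- crossprod(P$Wx, da)
        dh <- crossprod(P$Wh, da)
      }
      grads[[i]] <- list(Wx = dWx, Wh = dWh, b = db)
      dout <- array(dxs, cc$d)
    } else if (ly$type == "res_save") {
      pend <- res_d[[as.character(ly$id)]]
      if (!is.null(pend)) dout <- dout + pend
    } else if (ly$type == "res_add_relu") {
      dout <- dout * caches[[i]]
      res_d[[as.character(ly$id)]] <- dout
    }
  }
  list(dx = dout, grads = grads)
}

#' Softmax cross-entropy head
#' @param logits `(K, N)` matrix; `y` integer class labels in `1..K`.
#' @return list `loss`, `probs`, `dlogits` (already divided by N).
#' @export
softmax_ce <- function(logits, y) {
  z <- logits - apply(logits, 2, max)[col(logits)]
  ez <- exp(z)
  p <- ez / colSums(ez)[col(ez)]
  N <- ncol(p)
  loss <- -mean(log(pmax(p[cbind(y, seq_len(N))], 1e-12)))
  d <- p
  d[cbind(y, seq_len(N))] <- d[cbind(y, seq_len(N))] - 1
  list(loss = loss, probs = p, dlogits = d / N)
}

#' Sigmoid binary cross-entropy head
#' @param logits `(1, N)` matrix; `d` 0/1 domain labels.
#' @return list `loss`, `probs`, `dlogits`.
#' @export
sigmoid_bce <- function(logits, d) {
  p <- 1 / (1 + exp(-logits))
  N <- length(d)
  loss <- -mean(d * log(pmax(p, 1e-12)) + (1 - d) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, probs = p, dlogits = (p - matrix(d, 1)) / N)
}

#' Gradient reversal
#'
#' Forward pass is the identity; the backward contract multiplies the
#' incoming sensitivity by `-lambda`, turning the discriminator's descent
#' direction into an ascent direction for the feature extractor.
#' @param x any numeric array (returned unchanged).
#' @export
grad_reverse <- function(x) x

#' @rdname grad_reverse
#' @param g upstream gradient.
#' @param lambda adversarial weight.
#' @export
grad_reverse_backward <- function(g, lambda) -lambda * g

#' Adam optimizer state for a network
#' @param net a `nn_net`.
#' @return opaque state list.
#' @export
adam_init <- function(net) {
  lapply(net$layers, function(ly) {
    if (!length(ly$params)) return(NULL)
    lapply(ly$params, function(p) list(m = 0 * p, v = 0 * p))
  })
}

#' One Adam update
#'
#' @param net network; `grads` from [nn_backward()]; `state` from
#'   [adam_init()]; `t` step counter (1-based).
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @return list `net`, `state`.
#' @export
adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    if (is.null(grads[[i]])) next
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      net$layers[[i]]$params[[nm]] <- net$layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(net = net, state = state)
}
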