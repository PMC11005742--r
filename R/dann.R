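#' Model configuration
#'
#' Architecture and optimization settings for the domain-adversarial sweep
#' classifier. The feature extractor follows the published design: a (1,5)
#' convolution with (1,4) pooling scanning each statistic's positional
#' series, a (3,1) convolution with (2,1) pooling mixing statistics at fixed
#' position, then two residual bottleneck modules (1x1 reduce, (3,1) conv,
#' 1x1 expand; channel reduction factor 4). The classifier has 4 fully
#' connected layers (batch-norm after the first two, ReLU then softmax,
#' dropout); the discriminator has 3 fully connected layers (no dropout, so
#' that a lambda = 0 run is step-identical to plain supervised training).
#'
#' @param lambda adversarial weight (the published setting fixes it at 1).
#' @param M deep-ensemble size (default 5).
#' @param arch feature extractor: `"rowcol"` (the (1,n)/(m,1)-kernel 2D CNN),
#'   `"cnn2d"` (generic (3,3)-kernel 2D CNN), `"cnn1d"` (1D CNN over
#'   positions with statistics as channels), `"rnn"`.
#' @param conv_channels channels of the two convolution stages.
#' @param fc_classifier hidden widths of the first three classifier layers.
#' @param fc_discriminator hidden widths of the two discriminator hidden
#'   layers.
#' @param dropout classifier dropout rate (default 0.5).
#' @param lr,batch_size,epochs,patience optimization settings (Adam,
#'   early stopping on validation loss).
#' @param seed integer seed for initialization and batching.
#' @return a `dann_config` list.
#' @export
dann_config <- function(lambda = 1, M = 5L, arch = "rowcol",
                        conv_channels = c(8L, 16L),
                        fc_classifier = c(128L, 64L, 32L),
                        fc_discriminator = c(64L, 32L),
                        dropout = 0.5, lr = 1e-3, batch_size = 64L,
                        epochs = 40L, patience = 10L, seed = 1L) {
  stopifnot(lambda >= 0, M >= 1)
  structure(list(lambda = lambda, M = as.integer(M), arch = arch,
                 conv_channels = conv_channels, fc_classifier = fc_classifier,
                 fc_discriminator = fc_discriminator, dropout = dropout,
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)), class = "dann_config")
}

extractor_spec <- function(arch, nstat, m, channels) {
  c1 <- channels[1]; c2 <- channels[2]
  if (arch == "rowcol") {
    red <- max(1L, c2 %/% 4L)
    list(list("conv", kh = 1L, kw = 5L, cout = c1), list("relu"),
         list("pool", kh = 1L, kw = 4L),
         list("conv", kh = 3L, kw = 1L, cout = c2), list("relu"),
         list("pool", kh = 2L, kw = 1L),
         list("res_save", id = 1L),
         list("conv", kh = 1L, kw = 1L, cout = red), list("relu"),
         list("conv", kh = 3L, kw = 1L, cout = red), list("relu"),
         list("conv", kh = 1L, kw = 1L, cout = c2),
         list("res_add_relu", id = 1L),
         list("res_save", id = 2L),
         list("conv", kh = 1L, kw = 1L, cout = red), list("relu"),
         list("conv", kh = 3L, kw = 1L, cout = red), list("relu"),
         list("conv", kh = 1L, kw = 1L, cout = c2),
         list("res_add_relu", id = 2L),
         list("flatten"))
  } else if (arch == "cnn2d") {
    list(list("conv", kh = 3L, kw = 3L, cout = c1), list("relu"),
         list("pool", kh = 2L, kw = 2L),
         list("conv", kh = 3L, kw = 3L, cout = c2), list("relu"),
         list("pool", kh = 2L, kw = 2L),
         list("flatten"))
  } else if (arch == "cnn1d") {
    # input reshaped to (1, m, nstat): statistics become channels
    list(list("conv", kh = 1L, kw = 5L, cout = 2L * c1), list("relu"),
         list("pool", kh = 1L, kw = 4L),
         list("conv", kh = 1L, kw = 3L, cout = 2L * c2), list("relu"),
         list("pool", kh = 1L, kw = 2L),
         list("flatten"))
  } else if (arch == "rnn") {
    list(list("rnn", hidden = 64L))
  } else stop("unknown architecture: ", arch)
}

extractor_input_shape <- function(arch, nstat, m) {
  if (arch == "cnn1d") c(1L, m, nstat) else c(nstat, m, 1L)
}

reshape_input <- function(x, arch) {
  # x: (nstat, m, N) feature array -> network input (H, W, C, N)
  d <- dim(x)
  if (arch == "cnn1d") aperm(array(x, c(d[1], d[2], d[3], 1L)), c(4, 2, 1, 3))
  else array(x, c(d[1], d[2], 1L, d[3]))
}

#' Build a domain-adversarial sweep classifier
#'
#' @param nstat number of statistic rows (40 for the default registry).
#' @param m positional intervals of the feature grid.
#' @param config a [dann_config()]. Initialization is seeded from
#'   `config$seed`; two builds with the same seed are identical.
#' @return a `dann_model` with `extractor`, `classifier`, `discriminator`
#'   networks and the config.
#' @export
dann_build <- function(nstat, m, config = dann_config()) {
  set.seed(config$seed)
  ext <- nn_build(extractor_spec(config$arch, nstat, m, config$conv_channels),
                  extractor_input_shape(config$arch, nstat, m))
  emb <- ext$out_shape
  fcc <- config$fc_classifier
  cls <- nn_build(list(
    list("fc", out = fcc[1]), list("bnorm"), list("relu"),
    list("dropout", rate = config$dropout),
    list("fc", out = fcc[2]), list("bnorm"), list("relu"),
    list("dropout", rate = config$dropout),
    list("fc", out = fcc[3]), list("relu"),
    list("fc", out = 5L)), emb)
  fcd <- config$fc_discriminator
  dsc <- nn_build(list(
    list("fc", out = fcd[1]), list("relu"),
    list("fc", out = fcd[2]), list("relu"),
    list("fc", out = 1L)), emb)
  structure(list(extractor = ext, classifier = cls, discriminator = dsc,
                 config = config, classes = sweep_classes()),
            class = "dann_model")
}

#' Adversarial objective and gradients on one batch
#'
#' Computes the transductive objective
#' `E = (1/n) sum_source L_y - lambda (1/N) sum_all L_d`
#' (5-class cross-entropy classifier loss on labeled source cases, binary
#' cross-entropy domain loss on all cases, source = 0 / target = 1) and the
#' backpropagated gradients. The discriminator path reaches the extractor
#' through gradient reversal, so the extractor gradient equals `dL_y/dtheta_f
#' - lambda dL_d/dtheta_f` while the discriminator gradient is `+dL_d/
#' dtheta_d` (its own descent direction).
#'
#' @param model a `dann_model`.
#' @param xs source input array `(H, W, C, n)`; `ys` integer labels `1..5`.
#' @param xt target input array (unlabeled) or `NULL` for supervised-only.
#' @param lambda adversarial weight.
#' @param train forward in training mode (batch-norm batch statistics,
#'   dropout).
#' @return list `total`, `loss_y`, `loss_d`, `grads` (per sub-network),
#'   `model` (updated batch-norm state), `probs`.
#' @export
dann_loss <- function(model, xs, ys, xt = NULL, lambda = model$config$lambda,
                      train = TRUE) {
  n <- dim(xs)[4]
  if (n == 0L) stop("empty source batch")
  x_all <- if (is.null(xt)) xs else {
    d <- dim(xs)
    arr <- array(0, c(d[1:3], n + dim(xt)[4]))
    arr[, , , seq_len(n)] <- xs
    arr[, , , n + seq_len(dim(xt)[4])] <- xt
    arr
  }
  N <- dim(x_all)[4]
  fe <- nn_forward(model$extractor, x_all, train)
  model$extractor <- fe$net
  emb <- fe$out                               # (demb, N)
  fc <- nn_forward(model$classifier, emb[, seq_len(n), drop = FALSE], train)
  model$classifier <- fc$net
  ce <- softmax_ce(fc$out, ys)
  bc <- nn_backward(model$classifier, fc$caches, ce$dlogits)
  demb <- matrix(0, nrow(emb), N)
  demb[, seq_len(n)] <- bc$dx

  loss_d <- NA_real_
  gd <- NULL
  if (!is.null(model$discriminator) && !is.null(xt)) {
    dlab <- c(rep(0, n), rep(1, N - n))
    fd <- nn_forward(model$discriminator, grad_reverse(emb), train)
    bce <- sigmoid_bce(fd$out, dlab)
    loss_d <- bce$loss
    bd <- nn_backward(model$discriminator, fd$caches, bce$dlogits)
    gd <- bd$grads
    demb <- demb + grad_reverse_backward(bd$dx, lambda)
  }
  be <- nn_backward(model$extractor, fe$caches, demb)
  total <- ce$loss - ifelse(is.na(loss_d), 0, lambda * loss_d)
  list(total = total, loss_y = ce$loss, loss_d = loss_d,
       grads = list(extractor = be$grads, classifier = bc$grads,
                    discriminator = gd),
       model = model, probs = ce$probs)
}

#' Train a sweep classifier transductively
#'
#' Minimizes the adversarial objective by Adam over mini-batches that pair
#' each labeled source batch with an equal-sized unlabeled target batch.
#' With `lambda = 0` (or `target = NULL`) this reduces exactly to plain
#' supervised training; setting `update_discriminator = FALSE` additionally
#' freezes the discriminator without changing the RNG stream, so the two
#' runs produce identical extractor/classifier trajectories.
#'
#' @param x source feature array `(nstat, m, N)` (standardized).
#' @param y factor or integer labels (5 classes).
#' @param target optional unlabeled target feature array `(nstat, m, Nt)`.
#' @param config a [dann_config()].
#' @param val optional list `x`, `y` for validation-based checkpointing and
#'   early stopping (falls back to training loss when absent).
#' @param update_discriminator train the discriminator (default TRUE when a
#'   target is given).
#' @param verbose print per-epoch losses.
#' @return a trained `dann_model`; `$log` holds per-epoch `loss_y`,
#'   `loss_d`, `val_acc`.
#' @export
dann_train <- function(x, y, target = NULL, config = dann_config(),
                       val = NULL, update_discriminator = !is.null(target),
                       verbose = FALSE) {
  if (is.factor(y)) y <- as.integer(y)
  nstat <- dim(x)[1]; m <- dim(x)[2]; N <- dim(x)[3]
  model <- dann_build(nstat, m, config)
  xs_all <- reshape_input(x, config$arch)
  xt_all <- if (!is.null(target)) reshape_input(target, config$arch)
  states <- list(extractor = adam_init(model$extractor),
                 classifier = adam_init(model$classifier),
                 discriminator = adam_init(model$discriminator))
  step <- 0L
  best <- list(metric = Inf, model = model)
  bad_epochs <- 0L
  log <- data.frame()
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(N)
    nb <- ceiling(N / config$batch_size)
    ep_ly <- 0; ep_ld <- 0
    for (b in seq_len(nb)) {
      idx <- perm[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, N)]
      tgt <- NULL
      if (!is.null(xt_all)) {
        tidx <- sample.int(dim(xt_all)[4], length(idx), replace = TRUE)
        tgt <- xt_all[, , , tidx, drop = FALSE]
      }
      res <- dann_loss(model, xs_all[, , , idx, drop = FALSE], y[idx], tgt,
                       lambda = config$lambda, train = TRUE)
      model <- res$model
      step <- step + 1L
      up <- adam_step(model$extractor, res$grads$extractor,
                      states$extractor, step, lr = config$lr)
      model$extractor <- up$net; states$extractor <- up$state
      up <- adam_step(model$classifier, res$grads$classifier,
                      states$classifier, step, lr = config$lr)
      model$classifier <- up$net; states$classifier <- up$state
      if (update_discriminator && !is.null(res$grads$discriminator)) {
        up <- adam_step(model$discriminator, res$grads$discriminator,
                        states$discriminator, step, lr = config$lr)
        model$discriminator <- up$net; states$discriminator <- up$state
      }
      ep_ly <- ep_ly + res$loss_y
      ep_ld <- ep_ld + ifelse(is.na(res$loss_d), 0, res$loss_d)
      if (!is.finite(res$loss_y)) {
        warning("non-finite loss at epoch ", epoch, "; stopping at last checkpoint")
        model <- best$model
        model$log <- log
        return(model)
      }
    }
    val_acc <- NA_real_
    metric <- ep_ly / nb
    if (!is.null(val)) {
      pr <- dann_predict(model, val$x)
      yv <- if (is.factor(val$y)) as.integer(val$y) else val$y
      val_acc <- mean(max.col(t(pr$probs)) == yv)
      vl <- -mean(log(pmax(pr$probs[cbind(yv, seq_along(yv))], 1e-12)))
      metric <- vl
    }
    log <- rbind(log, data.frame(epoch = epoch, loss_y = ep_ly / nb,
                                 loss_d = ep_ld / nb, val_acc = val_acc))
    if (verbose)
      message(sprintf("epoch %d  L_y %.4f  L_d %.4f  val_acc %s", epoch,
                      ep_ly / nb, ep_ld / nb, format(val_acc, digits = 3)))
    if (metric < best$metric - 1e-6) {
      best <- list(metric = metric, model = model)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$patience) break
    }
  }
  model <- best$model
  model$log <- log
  model
}

#' Predict class probabilities and domain scores
#'
#' @param model a trained `dann_model`.
#' @param x feature array `(nstat, m, N)` standardized with the training
#'   scale.
#' @param batch_size forward batch size.
#' @return list `probs` (5 x N, columns on the simplex), `domain` (length-N
#'   discriminator outputs; source-like data scores below 0.5), `embedding`
#'   (demb x N).
#' @export
dann_predict <- function(model, x, batch_size = 256L) {
  xin <- reshape_input(x, model$config$arch)
  N <- dim(xin)[4]
  probs <- matrix(0, 5, N); dom <- numeric(N)
  emb_out <- NULL
  for (b in seq_len(ceiling(N / batch_size))) {
    idx <- ((b - 1L) * batch_size + 1L):min(b * batch_size, N)
    fe <- nn_forward(model$extractor, xin[, , , idx, drop = FALSE], train = FALSE)
    fc <- nn_forward(model$classifier, fe$out, train = FALSE)
    z <- fc$out - apply(fc$out, 2, max)[col(fc$out)]
    p <- exp(z); probs[, idx] <- p / colSums(p)[col(p)]
    if (!is.null(model$discriminator)) {
      fd <- nn_forward(model$discriminator, fe$out, train = FALSE)
      dom[idx] <- 1 / (1 + exp(-as.vector(fd$out)))
    }
    if (is.null(emb_out)) emb_out <- matrix(0, nrow(fe$out), N)
    emb_out[, idx] <- fe$out
  }
  rownames(probs) <- model$classes
  list(probs = probs, domain = dom, embedding = emb_out)
}

#' Train a deep ensemble
#'
#' `M` models with independent random initializations (seeds
#' `config$seed + 0..M-1`), each trained on the same data.
#'
#' @inheritParams dann_train
#' @return list of `dann_model` of length `config$M`.
#' @export
dann_train_ensemble <- function(x, y, target = NULL, config = dann_config(),
                                val = NULL, verbose = FALSE) {
  lapply(seq_len(config$M), function(mi) {
    cfg <- config
    cfg$seed <- config$seed + mi - 1L
    set.seed(cfg$seed)
    dann_train(x, y, target, cfg, val, verbose = verbose)
  })
}

#' Ensemble prediction (mean of member distributions)
#'
#' `p(y|x) = M^-1 sum_m p_m(y|x)`; the domain score is likewise the member
#' mean.
#'
#' @param models list of trained `dann_model` sharing one class order.
#' @param x feature array `(nstat, m, N)`.
#' @return list `probs` (5 x N ensemble mean), `member_probs` (list),
#'   `domain` (mean discriminator output).
#' @export
ensemble_predict <- function(models, x) {
  stopifnot(length(models) >= 1)
  cls <- lapply(models, `[[`, "classes")
  if (!all(vapply(cls, identical, logical(1), cls[[1]])))
    stop("ensemble members disagree on class ordering")
  preds <- lapply(models, dann_predict, x = x)
  probs <- Reduce(`+`, lapply(preds, `[[`, "probs")) / length(models)
  dom <- Reduce(`+`, lapply(preds, `[[`, "domain")) / length(models)
  list(probs = probs, member_probs = lapply(preds, `[[`, "probs"), domain = dom)
}

#' Mean maximum-class-probability confidence
#'
#' @param probs 5 x N probability matrix (or list with `probs`).
#' @return mean over cases of the maximum class probability.
#' @export
prediction_confidence <- function(probs) {
  if (is.list(probs)) probs <- probs$probs
  stopifnot(ncol(probs) >= 1)
  mean(apply(probs, 2, max))
}

#' smoothGrad saliency map
#'
#' Mean absolute gradient of the predicted-class score (the pre-softmax
#' activation, the standard saliency target: probability gradients vanish
#' once the classifier saturates) w.r.t. the input, averaged over
#' `n_samples` Gaussian-perturbed copies of the input. With `noise_sd = 0,
#' n_samples = 1` this is the plain gradient magnitude.
#'
#' @param model trained `dann_model`.
#' @param x single feature matrix `(nstat, m)`.
#' @param noise_sd Gaussian noise SD on the standardized input scale
#'   (default 0.1).
#' @param n_samples number of perturbed copies (default 25).
#' @param seed RNG seed for the noise draws.
#' @return `(nstat, m)` saliency grid.
#' @export
smoothgrad_saliency <- function(model, x, noise_sd = 0.1, n_samples = 25L,
                                seed = 1L) {
  set.seed(as.integer(seed))
  d <- dim(x)
  acc <- matrix(0, d[1], d[2])
  for (s in seq_len(n_samples)) {
    noisy <- x + if (noise_sd > 0) matrix(stats::rnorm(length(x), 0, noise_sd),
                                          d[1], d[2]) else 0
    xin <- reshape_input(array(noisy, c(d, 1L)), model$config$arch)
    fe <- nn_forward(model$extractor, xin, train = FALSE)
    fc <- nn_forward(model$classifier, fe$out, train = FALSE)
    cstar <- which.max(fc$out[, 1])
    bc <- nn_backward(model$classifier, fc$caches,
                      matrix(as.numeric(seq_len(5) == cstar), 5, 1))
    be <- nn_backward(model$extractor, fe$caches, bc$dx)
    g <- be$dx
    if (model$config$arch == "cnn1d") g <- aperm(g, c(3, 2, 1, 4))
    acc <- acc + abs(matrix(g, d[1], d[2]))
  }
  acc / n_samples
}
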