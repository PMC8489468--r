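# The denoising image filter (DNIF): a U-Net-style encoder-decoder trained
# to regress a clinical-standard averaged image from one noisy
# single-acquisition image. Convolution primitives live in src/convops.cpp;
# the network wiring, He initialization, max-norm constraint, losses and the
# Adam loop are implemented here.

#' Architecture configuration for the denoising network
#'
#' @param depth number of resolution levels (encoder levels including the
#'   bottleneck), >= 2. Default 4.
#' @param base_channels channels of the first level; doubled per level.
#' @param kernel_size odd convolution kernel size (default 3).
#' @param max_weight_norm maximum L2 norm of the weights incident to each
#'   hidden unit (each convolution filter); enforced after every optimizer
#'   update. Default 3.
#' @param input_shape (rows, cols) the network is intended for. Inputs whose
#'   sides are not divisible by `2^(depth-1)` are reflect-padded at run time,
#'   but each side must be at least `2^(depth-1)` pixels.
#' @return a `dnif_config`.
#' @export
model_config <- function(depth = 4L, base_channels = 16L, kernel_size = 3L,
                         max_weight_norm = 3.0, input_shape = c(64L, 64L)) {
  depth <- as.integer(depth)
  stopifnot(depth >= 2L, base_channels >= 1L, kernel_size %% 2 == 1,
            max_weight_norm > 0, length(input_shape) == 2L)
  div <- 2L^(depth - 1L)
  if (any(input_shape < div))
    stop("input_shape ", paste(input_shape, collapse = "x"),
         " incompatible with depth ", depth,
         ": each side must be >= (and is padded to a multiple of) ", div)
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 kernel_size = as.integer(kernel_size),
                 max_weight_norm = max_weight_norm,
                 input_shape = as.integer(input_shape)),
            class = "dnif_config")
}

#' Training configuration
#'
#' Defaults follow the published recipe: Adam with learning rate 0.001,
#' batch size 36, 15 epochs, MAE cost function; the combined MAE/SSIM loss
#' uses weight `alpha = 0.7` on the MAE term.
#'
#' @param loss one of `"mae"`, `"mse"`, `"mae_ssim"`.
#' @param alpha weight of the MAE term in the combined loss, in \[0, 1\].
#' @param learning_rate Adam step size.
#' @param batch_size images per optimizer step.
#' @param epochs passes over the training set.
#' @param seed integer seed controlling initialization order and shuffling.
#' @return a `dnif_train_config`.
#' @export
train_config <- function(loss = c("mae", "mse", "mae_ssim"), alpha = 0.7,
                         learning_rate = 0.001, batch_size = 36L,
                         epochs = 15L, seed = 1L) {
  loss <- match.arg(loss)
  stopifnot(alpha >= 0, alpha <= 1, learning_rate > 0, batch_size >= 1,
            epochs >= 1)
  structure(list(loss = loss, alpha = alpha, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "dnif_train_config")
}

he_init <- function(nout, nin, fan_in) {
  matrix(rnorm(nout * nin, 0, sqrt(2 / fan_in)), nout, nin)
}

unet_channels <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

#' Build an untrained denoising network
#'
#' Canonical U-Net layout: per encoder level two `k x k` convolutions with
#' ReLU then 2x2 max pooling; a two-convolution bottleneck; per decoder
#' level a 2x2 transposed convolution, concatenation with the matching
#' encoder skip, and two convolutions; a final linear 1x1 convolution to one
#' channel. Weights are He-normal initialized; every hidden layer carries a
#' max-norm constraint on the incoming weights of each filter.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the weight draws.
#' @return a `dnif_model` with `config`, `params`, `training_history`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "dnif_config"))
  set.seed(as.integer(seed))
  D <- config$depth
  k <- config$kernel_size
  ch <- unet_channels(config)
  params <- list()
  conv_layer <- function(cin, cout, ks = k) {
    fan <- cin * ks * ks
    list(W = he_init(cout, fan, fan), b = rep(0, cout), k = ks)
  }
  for (l in seq_len(D)) {
    cin <- if (l == 1L) 1L else ch[l - 1L]
    params[[paste0("enc", l, "c1")]] <- conv_layer(cin, ch[l])
    params[[paste0("enc", l, "c2")]] <- conv_layer(ch[l], ch[l])
  }
  for (l in seq_len(D - 1L)) {
    fan <- ch[l + 1L] * 4L
    params[[paste0("up", l)]] <- list(W = he_init(ch[l], fan, fan),
                                      b = rep(0, ch[l]), k = 2L)
    params[[paste0("dec", l, "c1")]] <- conv_layer(2L * ch[l], ch[l])
    params[[paste0("dec", l, "c2")]] <- conv_layer(ch[l], ch[l])
  }
  params[["outc"]] <- conv_layer(ch[1L], 1L, ks = 1L)
  model <- structure(list(config = config, params = params,
                          training_history = numeric(0)),
                     class = "dnif_model")
  apply_max_norm(model)
}

hidden_layer_names <- function(model) {
  setdiff(names(model$params), "outc")
}

# project each filter's incoming-weight vector onto the max-norm ball
apply_max_norm <- function(model) {
  mx <- model$config$max_weight_norm
  for (nm in hidden_layer_names(model)) {
    W <- model$params[[nm]]$W
    nrm <- sqrt(rowSums(W * W))
    over <- nrm > mx
    if (any(over)) {
      W[over, ] <- W[over, , drop = FALSE] * (mx / nrm[over])
      model$params[[nm]]$W <- W
    }
  }
  model
}

#' Total number of trainable parameters
#' @param model a `dnif_model`.
#' @return integer parameter count (a pure function of the configuration).
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), 0))
}

as_cube <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L))

relu <- function(a) {
  a[a < 0] <- 0
  a
}

unet_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  D <- model$config$depth
  cache <- if (keep_cache) list(acts = list(), pool = list()) else NULL
  conv_act <- function(nm, inp) {
    a <- relu(cpp_conv2d_fwd(inp, p[[nm]]$W, p[[nm]]$b, p[[nm]]$k))
    if (keep_cache) cache$acts[[nm]] <<- list(x = inp, a = a)
    a
  }
  cur <- as_cube(x)
  skips <- vector("list", D - 1L)
  for (l in seq_len(D - 1L)) {
    cur <- conv_act(paste0("enc", l, "c1"), cur)
    cur <- conv_act(paste0("enc", l, "c2"), cur)
    skips[[l]] <- cur
    pl <- cpp_maxpool_fwd(cur)
    if (keep_cache) cache$pool[[l]] <- list(idx = pl$idx, dim = dim(cur))
    cur <- pl$y
  }
  cur <- conv_act(paste0("enc", D, "c1"), cur)
  cur <- conv_act(paste0("enc", D, "c2"), cur)
  for (l in rev(seq_len(D - 1L))) {
    nm <- paste0("up", l)
    u <- relu(cpp_upconv_fwd(cur, p[[nm]]$W, p[[nm]]$b))
    if (keep_cache) cache$acts[[nm]] <- list(x = cur, a = u)
    cur <- array(c(skips[[l]], u),
                 dim = c(dim(u)[1], dim(u)[2], dim(skips[[l]])[3] + dim(u)[3]))
    cur <- conv_act(paste0("dec", l, "c1"), cur)
    cur <- conv_act(paste0("dec", l, "c2"), cur)
  }
  y <- cpp_conv2d_fwd(cur, p$outc$W, p$outc$b, 1L)
  if (keep_cache) cache$acts[["outc"]] <- list(x = cur)
  list(y = matrix(y, dim(y)[1], dim(y)[2]), cache = cache)
}

# backward pass: dy is the gradient of the loss wrt the output image
unet_backward <- function(model, cache, dy) {
  p <- model$params
  D <- model$config$depth
  grads <- list()
  conv_back <- function(nm, dpost) {
    cc <- cache$acts[[nm]]
    dpre <- dpost * (cc$a > 0)
    bw <- cpp_conv2d_bwd(cc$x, p[[nm]]$W, p[[nm]]$k, dpre)
    grads[[nm]] <<- list(W = bw$dW, b = as.numeric(bw$db))
    bw$dx
  }
  bw <- cpp_conv2d_bwd(cache$acts$outc$x, p$outc$W, 1L, as_cube(dy))
  grads[["outc"]] <- list(W = bw$dW, b = as.numeric(bw$db))
  dcur <- bw$dx
  dskips <- vector("list", D - 1L)
  for (l in seq_len(D - 1L)) {
    dcur <- conv_back(paste0("dec", l, "c2"), dcur)
    dcur <- conv_back(paste0("dec", l, "c1"), dcur)
    cs <- dim(dcur)[3] / 2L
    dskips[[l]] <- dcur[, , seq_len(cs), drop = FALSE]
    du <- dcur[, , cs + seq_len(cs), drop = FALSE]
    nm <- paste0("up", l)
    cc <- cache$acts[[nm]]
    du <- du * (cc$a > 0)
    bw <- cpp_upconv_bwd(cc$x, p[[nm]]$W, du)
    grads[[nm]] <- list(W = bw$dW, b = as.numeric(bw$db))
    dcur <- bw$dx
  }
  dcur <- conv_back(paste0("enc", D, "c2"), dcur)
  dcur <- conv_back(paste0("enc", D, "c1"), dcur)
  for (l in rev(seq_len(D - 1L))) {
    pl <- cache$pool[[l]]
    da <- cpp_maxpool_bwd(pl$idx, dcur, pl$dim[1], pl$dim[2]) + dskips[[l]]
    da <- conv_back(paste0("enc", l, "c2"), da)
    dcur <- conv_back(paste0("enc", l, "c1"), da)
  }
  grads
}

#' Training losses
#'
#' `loss_mae` and `loss_mse` are the pixel-mean absolute and squared errors.
#' `loss_mae_ssim` is the convex combination
#' `alpha * MAE + (1 - alpha) * (1 - SSIM)`: the structural term enters as a
#' dissimilarity so the loss decreases as similarity increases.
#'
#' @param pred,target numeric matrices of identical shape.
#' @param alpha weight of the MAE term, in \[0, 1\] (default 0.7).
#' @return non-negative scalar.
#' @export
loss_mae <- function(pred, target) {
  stopifnot(all(dim(pred) == dim(target)))
  mean(abs(pred - target))
}

#' @rdname loss_mae
#' @export
loss_mse <- function(pred, target) {
  stopifnot(all(dim(pred) == dim(target)))
  mean((pred - target)^2)
}

#' @rdname loss_mae
#' @export
loss_mae_ssim <- function(pred, target, alpha = 0.7) {
  stopifnot(all(dim(pred) == dim(target)), alpha >= 0, alpha <= 1)
  alpha * loss_mae(pred, target) +
    (1 - alpha) * (1 - ssim(pred, target, data_range = 1.0))
}

loss_value_and_grad <- function(pred, target, cfg) {
  n <- length(pred)
  switch(cfg$loss,
    mae = list(value = loss_mae(pred, target),
               grad = sign(pred - target) / n),
    mse = list(value = loss_mse(pred, target),
               grad = 2 * (pred - target) / n),
    mae_ssim = list(
      value = loss_mae_ssim(pred, target, cfg$alpha),
      grad = cfg$alpha * sign(pred - target) / n -
        (1 - cfg$alpha) * ssim_grad(pred, target, data_range = 1.0)))
}

check_normalized <- function(imgs, what) {
  mx <- max(vapply(imgs, max, 0))
  if (!is.finite(mx) || mx > 1 + 1e-6)
    stop(what, " must be normalized to [0, 1] (max found: ", mx, ")")
  invisible(TRUE)
}

#' Train the denoising network
#'
#' Minimizes the configured loss over (noisy single-acquisition image,
#' clinical-standard target) pairs with Adam; the max-norm constraint is
#' re-applied after every update. All b-values and directions are pooled
#' into one dataset — a single network serves every b-value.
#'
#' @param model a `dnif_model`.
#' @param pairs list of `list(x = , y = )` matrices, both normalized to
#'   \[0, 1\] and sharing a common shape.
#' @param cfg a [train_config()].
#' @return the trained model; `training_history` holds the mean training
#'   loss of each epoch.
#' @export
train_dnif <- function(model, pairs, cfg) {
  stopifnot(inherits(model, "dnif_model"), inherits(cfg, "dnif_train_config"),
            length(pairs) >= 1L)
  check_normalized(lapply(pairs, `[[`, "x"), "input images")
  check_normalized(lapply(pairs, `[[`, "y"), "target images")
  p <- model$params
  adam_m <- lapply(p, function(q) list(W = q$W * 0, b = q$b * 0))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  set.seed(cfg$seed)
  history <- numeric(cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(length(pairs))
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      gacc <- NULL
      bloss <- 0
      for (i in bt) {
        fw <- unet_forward(model, pairs[[i]]$x, keep_cache = TRUE)
        lv <- loss_value_and_grad(fw$y, pairs[[i]]$y, cfg)
        bloss <- bloss + lv$value
        g <- unet_backward(model, fw$cache, lv$grad)
        gacc <- if (is.null(gacc)) g else
          Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), gacc, g)
      }
      nb <- length(bt)
      t <- t + 1L
      for (nm in names(model$params)) {
        for (fld in c("W", "b")) {
          g <- gacc[[nm]][[fld]] / nb
          adam_m[[nm]][[fld]] <- b1 * adam_m[[nm]][[fld]] + (1 - b1) * g
          adam_v[[nm]][[fld]] <- b2 * adam_v[[nm]][[fld]] + (1 - b2) * g^2
          mh <- adam_m[[nm]][[fld]] / (1 - b1^t)
          vh <- adam_v[[nm]][[fld]] / (1 - b2^t)
          model$params[[nm]][[fld]] <- model$params[[nm]][[fld]] -
            cfg$learning_rate * mh / (sqrt(vh) + eps)
        }
      }
      model <- apply_max_norm(model)
      ep_loss <- ep_loss + bloss
    }
    history[epoch] <- ep_loss / length(pairs)
  }
  model$training_history <- c(model$training_history, history)
  model$train_config <- cfg
  model
}

pad_to_multiple <- function(img, mult) {
  d <- dim(img)
  pad <- (mult - d %% mult) %% mult
  if (all(pad == 0)) return(list(img = img, crop = NULL))
  top <- floor(pad[1] / 2); bot <- pad[1] - top
  lef <- floor(pad[2] / 2); rig <- pad[2] - lef
  ri <- c(rev(seq_len(top) + 1L), seq_len(d[1]),
          d[1] - seq_len(bot))
  ci <- c(rev(seq_len(lef) + 1L), seq_len(d[2]),
          d[2] - seq_len(rig))
  list(img = img[ri, ci, drop = FALSE],
       crop = list(r = top + seq_len(d[1]), c = lef + seq_len(d[2])))
}

#' Apply the denoising network to one image
#'
#' The image must be normalized to \[0, 1\]. Sides that are not divisible by
#' `2^(depth-1)` are reflect-padded symmetrically before the forward pass and
#' the padding is cropped from the output, so the result has the input shape.
#' Inference is deterministic.
#'
#' @param model a (typically trained) `dnif_model`.
#' @param img numeric matrix in \[0, 1\]; NaN/NA values are rejected.
#' @return denoised matrix of the same shape.
#' @export
denoise <- function(model, img) {
  stopifnot(inherits(model, "dnif_model"), is.matrix(img))
  if (anyNA(img) || any(!is.finite(img)))
    stop("input image contains NA/NaN/Inf values")
  check_normalized(list(img), "input image")
  mult <- 2L^(model$config$depth - 1L)
  if (any(dim(img) < mult))
    stop("image ", paste(dim(img), collapse = "x"), " too small for depth ",
         model$config$depth, " (needs >= ", mult, " per side)")
  pd <- pad_to_multiple(img, mult)
  y <- unet_forward(model, pd$img)$y
  if (!is.null(pd$crop)) y <- y[pd$crop$r, pd$crop$c, drop = FALSE]
  y
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture configuration, the weights, and
#' the training history. The file is a run-time artifact (RDS).
#'
#' @param model a `dnif_model`.
#' @param path checkpoint file path.
#' @return `load_dnif` returns the model; `save_dnif` the path, invisibly.
#' @export
save_dnif <- function(model, path) {
  stopifnot(inherits(model, "dnif_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_dnif
#' @export
load_dnif <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dnif_model"))
  model
}
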