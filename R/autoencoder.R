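# Convolutional autoencoders (RED-CNN and Unet style) trained
# unsupervised on a single prior image; penultimate-layer activations
# serve as per-pixel features for the kernel matrix. Networks are small
# static graphs of conv / ReLU / add / bilinear-resize nodes; the conv
# forward/backward passes run through compiled im2col + GEMM.

#' Autoencoder specification
#'
#' @param architecture `"redcnn"` (5x5 convolutions, width 60, additive
#'   skip connections, ~7e5 parameters) or `"unet"` (3x3 convolutions,
#'   stride-2 downsampling, bilinear upsampling, additive skips,
#'   12-channel penultimate layer, ~3.4e5 parameters).
#' @param epochs Training epochs (default 300).
#' @param lr Adam learning rate; defaults to 1e-4 for RED-CNN and 1e-2
#'   for Unet.
#' @param seed Seed for the deterministic weight initialization.
#' @param width Hidden width for RED-CNN (default 60).
#' @param widths Per-scale widths for Unet (default c(16, 32, 64, 96)).
#' @param feature_layer Layer selector for [extract_cnn_features()];
#'   `"penultimate"` (default) or a node id.
#' @return An `autoencoder_spec` list.
#' @export
autoencoder_spec <- function(architecture = c("unet", "redcnn"),
                             epochs = 300L, lr = NULL, seed = 0L,
                             width = 60L, widths = c(16L, 32L, 64L, 96L),
                             feature_layer = "penultimate") {
  architecture <- match.arg(architecture)
  if (is.null(lr)) lr <- if (architecture == "redcnn") 1e-4 else 1e-2
  structure(list(architecture = architecture, epochs = as.integer(epochs),
                 lr = lr, seed = as.integer(seed), width = as.integer(width),
                 widths = as.integer(widths), feature_layer = feature_layer),
            class = "autoencoder_spec")
}

# --- graph construction -------------------------------------------------

.net_new <- function() {
  list(nodes = list(), params = list())
}

.net_add <- function(net, op, in1 = NA_integer_, in2 = NA_integer_,
                     pidx = NA_integer_, k = NA_integer_,
                     stride = NA_integer_, pad = NA_integer_,
                     ref = NA_integer_) {
  net$nodes[[length(net$nodes) + 1L]] <-
    list(op = op, in1 = in1, in2 = in2, pidx = pidx, k = k,
         stride = stride, pad = pad, ref = ref)
  net
}

.net_conv <- function(net, from, in_ch, out_ch, k, stride = 1L,
                      relu = TRUE, norm = FALSE) {
  pidx <- length(net$params) + 1L
  net$params[[pidx]] <- list(kind = "conv", in_ch = in_ch, out_ch = out_ch,
                             k = k, W = NULL, b = NULL)
  net <- .net_add(net, "conv", in1 = from, pidx = pidx, k = k,
                  stride = stride, pad = (k - 1L) %/% 2L)
  last <- length(net$nodes)
  if (norm) {
    nidx <- length(net$params) + 1L
    net$params[[nidx]] <- list(kind = "inorm", out_ch = out_ch,
                               W = NULL, b = NULL)
    net <- .net_add(net, "inorm", in1 = last, pidx = nidx)
    last <- length(net$nodes)
  }
  conv_id <- last
  if (relu) {
    net <- .net_add(net, "relu", in1 = last)
    list(net = net, id = length(net$nodes), conv = conv_id)
  } else list(net = net, id = conv_id, conv = conv_id)
}

.build_redcnn <- function(width) {
  w <- width
  net <- .net_add(.net_new(), "input"); x <- 1L
  r <- .net_conv(net, x, 1L, w, 5L); net <- r$net; e1 <- r$id
  r <- .net_conv(net, e1, w, w, 5L); net <- r$net; e2 <- r$id
  r <- .net_conv(net, e2, w, w, 5L); net <- r$net; e3 <- r$id
  r <- .net_conv(net, e3, w, w, 5L); net <- r$net; e4 <- r$id
  r <- .net_conv(net, e4, w, w, 5L); net <- r$net; e5 <- r$id
  r <- .net_conv(net, e5, w, w, 5L, relu = FALSE); net <- r$net
  net <- .net_add(net, "add", in1 = r$id, in2 = e4)
  net <- .net_add(net, "relu", in1 = length(net$nodes)); d5 <- length(net$nodes)
  r <- .net_conv(net, d5, w, w, 5L); net <- r$net; d4 <- r$id
  r <- .net_conv(net, d4, w, w, 5L, relu = FALSE); net <- r$net
  net <- .net_add(net, "add", in1 = r$id, in2 = e2)
  net <- .net_add(net, "relu", in1 = length(net$nodes)); d3 <- length(net$nodes)
  r <- .net_conv(net, d3, w, w, 5L); net <- r$net; d2 <- r$id
  r <- .net_conv(net, d2, w, 1L, 5L, relu = FALSE); net <- r$net
  net <- .net_add(net, "add", in1 = r$id, in2 = x)
  list(net = net, out = length(net$nodes), feature = d2)
}

.build_unet <- function(widths) {
  c1 <- widths[1]; c2 <- widths[2]; c3 <- widths[3]; c4 <- widths[4]
  net <- .net_add(.net_new(), "input"); x <- 1L
  # per-channel (instance) normalization in every hidden convolution
  # stabilizes training at the large Unet learning rate and keeps the
  # ReLU feature channels responsive
  r <- .net_conv(net, x, 1L, c1, 3L, norm = TRUE); net <- r$net; e1 <- r$id
  r <- .net_conv(net, e1, c1, c2, 3L, stride = 2L, norm = TRUE); net <- r$net
  r <- .net_conv(net, r$id, c2, c2, 3L, norm = TRUE); net <- r$net; e2 <- r$id
  r <- .net_conv(net, e2, c2, c3, 3L, stride = 2L, norm = TRUE); net <- r$net
  r <- .net_conv(net, r$id, c3, c3, 3L, norm = TRUE); net <- r$net; e3 <- r$id
  r <- .net_conv(net, e3, c3, c4, 3L, stride = 2L, norm = TRUE); net <- r$net
  r <- .net_conv(net, r$id, c4, c4, 3L, norm = TRUE); net <- r$net; bt <- r$id

  up <- function(net, from, skip, cin, cout) {
    net <- .net_add(net, "resize", in1 = from, ref = skip)
    r <- .net_conv(net, length(net$nodes), cin, cout, 3L, norm = TRUE)
    net <- r$net
    net <- .net_add(net, "add", in1 = r$id, in2 = skip)
    r <- .net_conv(net, length(net$nodes), cout, cout, 3L, norm = TRUE)
    r
  }
  r <- up(net, bt, e3, c4, c3); net <- r$net
  r <- up(net, r$id, e2, c3, c2); net <- r$net
  r <- up(net, r$id, e1, c2, c1); net <- r$net
  r <- .net_conv(net, r$id, c1, 12L, 3L, norm = TRUE); net <- r$net; p <- r$id
  r <- .net_conv(net, p, 12L, 1L, 3L, relu = FALSE); net <- r$net
  list(net = net, out = r$id, feature = p)
}

#' Build an autoencoder model
#'
#' Constructs the network graph and deterministically initializes the
#' weights (He normal) from the spec's seed.
#'
#' @param spec An [autoencoder_spec()].
#' @return An `autoencoder_model` list with fields `spec`, `nodes`,
#'   `params`, `out_node`, `feature_node`, `n_parameters`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "autoencoder_spec"))
  g <- if (spec$architecture == "redcnn") .build_redcnn(spec$width)
       else .build_unet(spec$widths)
  net <- g$net
  net$params <- .with_seed(spec$seed, {
    lapply(net$params, function(p) {
      if (p$kind == "inorm") {
        p$W <- matrix(1, p$out_ch, 1L)   # per-channel scale
        p$b <- numeric(p$out_ch)         # per-channel shift
      } else {
        fan_in <- p$k * p$k * p$in_ch
        p$W <- matrix(stats::rnorm(fan_in * p$out_ch) * sqrt(2 / fan_in),
                      fan_in, p$out_ch)
        # small positive bias keeps plain conv+ReLU units responsive
        p$b <- rep(0.1, p$out_ch)
      }
      p
    })
  })
  n_par <- sum(vapply(net$params, function(p) length(p$W) + length(p$b), 0))
  structure(list(spec = spec, nodes = net$nodes, params = net$params,
                 out_node = g$out, feature_node = g$feature,
                 n_parameters = n_par),
            class = "autoencoder_model")
}

#' Number of trainable parameters
#' @param model An `autoencoder_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) model$n_parameters

# --- bilinear resize ---------------------------------------------------

.resize_cache <- new.env(parent = emptyenv())

.resize_1d <- function(n_in, n_out) {
  key <- paste0(n_in, ">", n_out)
  if (!is.null(.resize_cache[[key]])) return(.resize_cache[[key]])
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- pmin(floor(src), n_in - 1)
  w1 <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  M <- Matrix::sparseMatrix(
    i = rep(seq_len(n_out), 2L),
    j = c(i0 + 1, i1 + 1),
    x = c(1 - w1, w1),
    dims = c(n_out, n_in))
  .resize_cache[[key]] <- M
  M
}

.resize_fwd <- function(a, h2, w2) {
  d <- dim(a)
  Ry <- .resize_1d(d[1], h2); Rx <- .resize_1d(d[2], w2)
  out <- array(0, c(h2, w2, d[3]))
  for (c in seq_len(d[3]))
    out[, , c] <- as.matrix(Ry %*% a[, , c] %*% Matrix::t(Rx))
  out
}

.resize_bwd <- function(g, h1, w1) {
  d <- dim(g)
  Ry <- .resize_1d(h1, d[1]); Rx <- .resize_1d(w1, d[2])
  out <- array(0, c(h1, w1, d[3]))
  for (c in seq_len(d[3]))
    out[, , c] <- as.matrix(Matrix::t(Ry) %*% g[, , c] %*% Rx)
  out
}

# --- instance normalization --------------------------------------------

# per-channel normalization over the spatial dimensions of the single
# image, with learned scale gamma and shift beta
.inorm_fwd <- function(a, gamma, beta, eps = 1e-5) {
  d <- dim(a); n <- d[1] * d[2]
  M <- matrix(a, n, d[3])
  mu <- colMeans(M)
  v <- colMeans(M^2) - mu^2
  xhat <- sweep(M, 2, mu, "-")
  xhat <- sweep(xhat, 2, sqrt(v + eps), "/")
  out <- sweep(sweep(xhat, 2, as.numeric(gamma), "*"), 2, beta, "+")
  list(out = array(out, d), xhat = xhat, v = v)
}

.inorm_bwd <- function(a, gamma, g, eps = 1e-5) {
  d <- dim(a); n <- d[1] * d[2]
  fw <- .inorm_fwd(a, gamma, numeric(d[3]), eps)
  G <- matrix(g, n, d[3])
  dgamma <- matrix(colSums(G * fw$xhat), d[3], 1L)
  dbeta <- colSums(G)
  dxhat <- sweep(G, 2, as.numeric(gamma), "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * fw$xhat)
  dx <- sweep(dxhat, 2, m1, "-") - sweep(fw$xhat, 2, m2, "*")
  dx <- sweep(dx, 2, sqrt(fw$v + eps), "/")
  list(dgamma = dgamma, dbeta = dbeta, dx = array(dx, d))
}

# --- forward / backward ------------------------------------------------

.net_forward <- function(model, x_arr) {
  acts <- vector("list", length(model$nodes))
  for (id in seq_along(model$nodes)) {
    nd <- model$nodes[[id]]
    acts[[id]] <- switch(nd$op,
      input = x_arr,
      conv = {
        p <- model$params[[nd$pidx]]
        nn_conv_forward(acts[[nd$in1]], p$W, p$b, nd$k, nd$stride, nd$pad)$out
      },
      relu = pmax(acts[[nd$in1]], 0),
      inorm = {
        p <- model$params[[nd$pidx]]
        .inorm_fwd(acts[[nd$in1]], p$W, p$b)$out
      },
      add = acts[[nd$in1]] + acts[[nd$in2]],
      resize = {
        tgt <- dim(acts[[nd$ref]])
        .resize_fwd(acts[[nd$in1]], tgt[1], tgt[2])
      },
      stop("unknown op"))
  }
  acts
}

.net_backward <- function(model, acts, dout) {
  n <- length(model$nodes)
  grads <- vector("list", n)
  pgrads <- lapply(model$params, function(p)
    list(dW = matrix(0, nrow(p$W), ncol(p$W)), db = numeric(length(p$b))))
  grads[[model$out_node]] <- dout
  acc <- function(cur, g) if (is.null(cur)) g else cur + g
  for (id in rev(seq_len(n))) {
    g <- grads[[id]]
    if (is.null(g)) next
    nd <- model$nodes[[id]]
    if (nd$op == "conv") {
      p <- model$params[[nd$pidx]]
      bk <- nn_conv_backward(acts[[nd$in1]], p$W, g, nd$k, nd$stride, nd$pad)
      pgrads[[nd$pidx]]$dW <- pgrads[[nd$pidx]]$dW + bk$dW
      pgrads[[nd$pidx]]$db <- pgrads[[nd$pidx]]$db + as.numeric(bk$db)
      grads[[nd$in1]] <- acc(grads[[nd$in1]], bk$dx)
    } else if (nd$op == "relu") {
      grads[[nd$in1]] <- acc(grads[[nd$in1]], g * (acts[[id]] > 0))
    } else if (nd$op == "inorm") {
      p <- model$params[[nd$pidx]]
      bk <- .inorm_bwd(acts[[nd$in1]], p$W, g)
      pgrads[[nd$pidx]]$dW <- pgrads[[nd$pidx]]$dW + bk$dgamma
      pgrads[[nd$pidx]]$db <- pgrads[[nd$pidx]]$db + bk$dbeta
      grads[[nd$in1]] <- acc(grads[[nd$in1]], bk$dx)
    } else if (nd$op == "add") {
      grads[[nd$in1]] <- acc(grads[[nd$in1]], g)
      grads[[nd$in2]] <- acc(grads[[nd$in2]], g)
    } else if (nd$op == "resize") {
      d1 <- dim(acts[[nd$in1]])
      grads[[nd$in1]] <- acc(grads[[nd$in1]], .resize_bwd(g, d1[1], d1[2]))
    }
  }
  pgrads
}

.normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}

#' Train an autoencoder on a single image
#'
#' Minimizes the reconstruction loss `||x - phi(theta; x)||^2` with Adam
#' (full-image gradient per epoch). The image is internally scaled to
#' [0, 1]. Training is deterministic: the only randomness is the weight
#' initialization from the spec's seed.
#'
#' @param model An [build_model()] result.
#' @param x Prior image (matrix), typically the X-ray CT.
#' @param epochs,lr Override the spec's epochs / learning rate.
#' @param seed If non-NULL, reinitializes the weights from this seed
#'   before training.
#' @return List: `model` (trained), `trace` (per-epoch loss vector).
#' @export
train_autoencoder <- function(model, x, epochs = NULL, lr = NULL,
                              seed = NULL) {
  stopifnot(inherits(model, "autoencoder_model"))
  if (!is.null(seed)) {
    sp <- model$spec; sp$seed <- as.integer(seed)
    model <- build_model(sp)
  }
  if (is.null(epochs)) epochs <- model$spec$epochs
  if (is.null(lr)) lr <- model$spec$lr
  x01 <- .normalize01(x)
  x_arr <- array(x01, c(nrow(x), ncol(x), 1L))

  mstate <- lapply(model$params, function(p)
    list(mW = matrix(0, nrow(p$W), ncol(p$W)), vW = matrix(0, nrow(p$W), ncol(p$W)),
         mb = numeric(length(p$b)), vb = numeric(length(p$b))))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    acts <- .net_forward(model, x_arr)
    out <- acts[[model$out_node]]
    resid <- out - x_arr
    loss <- sum(resid^2)
    if (!is.finite(loss))
      stop("autoencoder training diverged (loss is not finite) at learning rate ",
           lr)
    trace[ep] <- loss
    pg <- .net_backward(model, acts, 2 * resid)
    for (q in seq_along(model$params)) {
      st <- mstate[[q]]; p <- model$params[[q]]; g <- pg[[q]]
      st$mW <- b1 * st$mW + (1 - b1) * g$dW
      st$vW <- b2 * st$vW + (1 - b2) * g$dW^2
      st$mb <- b1 * st$mb + (1 - b1) * g$db
      st$vb <- b2 * st$vb + (1 - b2) * g$db^2
      bc1 <- 1 - b1^ep; bc2 <- 1 - b2^ep
      p$W <- p$W - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
      p$b <- p$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
      mstate[[q]] <- st; model$params[[q]] <- p
    }
  }
  list(model = model, trace = trace)
}

#' Extract CNN features from a trained autoencoder
#'
#' Runs a forward pass on the (internally [0, 1]-scaled) image and
#' returns the selected layer's activation as a per-pixel feature map.
#' Only layers whose spatial size equals the input qualify; the default
#' is the penultimate layer (12 channels for the Unet, 60 for RED-CNN).
#'
#' @param model A trained `autoencoder_model`.
#' @param x Image to extract features from.
#' @param layer `"penultimate"` or a node id.
#' @return A `feature_map` with `kind = "cnn"`.
#' @export
extract_cnn_features <- function(model, x, layer = "penultimate") {
  stopifnot(inherits(model, "autoencoder_model"))
  node <- if (identical(layer, "penultimate")) model$feature_node
          else as.integer(layer)
  if (is.na(node) || node < 1L || node > length(model$nodes))
    stop("invalid feature layer selector")
  x_arr <- array(.normalize01(x), c(nrow(x), ncol(x), 1L))
  acts <- .net_forward(model, x_arr)
  a <- acts[[node]]
  if (dim(a)[1] != nrow(x) || dim(a)[2] != ncol(x))
    stop("selected layer does not preserve the input spatial size")
  F <- matrix(a, nrow(x) * ncol(x), dim(a)[3])
  structure(list(features = F, kind = "cnn", normalized = FALSE),
            class = "feature_map")
}
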