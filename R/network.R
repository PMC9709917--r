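# The spherical graph CNN: four polynomial graph-convolution layers (each
# followed by batch normalization, ReLU and 4:1 max pooling), global
# average pooling over the 12 base pixels, and a fully connected head —
# softmax classifier or linear 256-d embedder. Forward, backprop and Adam
# are implemented directly on R matrices; batches are stored in
# [n_pix, batch, channels] layout so the sparse Laplacian applies to a
# single matrix view without copying.

#' Network configuration
#'
#' @param head `"classifier"` (softmax over `n_classes`) or `"embedder"`
#'   (linear 256-d descriptor).
#' @param n_classes Classifier output size (default 3).
#' @param channels Channels per convolution layer.
#' @param embedding Embedding width after global average pooling.
#' @param K Polynomial filter order (K = 3 means 4 terms, k = 0..3).
#' @param n_side Input map resolution (default 16).
#' @param k Graph neighbours per pixel (default 20).
#' @param in_channels Input channels (9 feature maps).
#' @param pool Layer pooling: `"max"` (standard architecture) or
#'   `"average"`.
#' @return A `network_config` list.
#' @export
network_config <- function(head = c("classifier", "embedder"),
                           n_classes = 3L, channels = c(32, 64, 128, 256),
                           embedding = 256L, K = 3L, n_side = 16L,
                           k = 20L, in_channels = 9L,
                           pool = c("max", "average")) {
  head <- match.arg(head)
  pool <- match.arg(pool)
  stopifnot(length(channels) >= 1, K >= 0)
  structure(list(head = head, n_classes = as.integer(n_classes),
    channels = as.integer(channels), embedding = as.integer(embedding),
    K = as.integer(K), n_side = as.integer(n_side), k = as.integer(k),
    in_channels = as.integer(in_channels), pool = pool),
    class = "network_config")
}

#' Initialize a network
#'
#' Glorot-style initialization; the k-th polynomial coefficient is scaled
#' by an estimate of `|L|^-k` (monomial filters of the unscaled Laplacian
#' would otherwise explode at initialization).
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for reproducible initialization.
#' @param graphs Optional prebuilt [sphere_graph_hierarchy()].
#' @return Object of class `sphere_network` (weights + graphs + config).
#' @export
network_init <- function(cfg, seed = 1L, graphs = NULL) {
  set.seed(seed)
  n_layers <- length(cfg$channels)
  if (is.null(graphs)) {
    graphs <- sphere_graph_hierarchy(cfg$n_side, n_layers, cfg$k)
  }
  layers <- vector("list", n_layers)
  cin <- cfg$in_channels
  for (l in seq_len(n_layers)) {
    cout <- cfg$channels[l]
    lnorm <- max(Matrix::rowSums(abs(graphs[[l]]$laplacian)))
    a <- array(0, c(cfg$K + 1, cin, cout))
    sd0 <- sqrt(2 / ((cfg$K + 1) * cin + cout))
    for (k in 0:cfg$K) {
      a[k + 1, , ] <- matrix(stats::rnorm(cin * cout, sd = sd0 / lnorm^k),
        cin, cout)
    }
    layers[[l]] <- list(
      a = a,
      gamma = rep(1, cout), beta = rep(0, cout),
      run_mean = rep(0, cout), run_var = rep(1, cout))
    cin <- cout
  }
  out_dim <- if (cfg$head == "classifier") cfg$n_classes else cfg$embedding
  fc <- list(
    W = matrix(stats::rnorm(cfg$embedding * out_dim,
      sd = sqrt(2 / (cfg$embedding + out_dim))), cfg$embedding, out_dim),
    b = rep(0, out_dim))
  structure(list(cfg = cfg, graphs = graphs, layers = layers, fc = fc,
                 bn_momentum = 0.9, bn_eps = 1e-5),
            class = "sphere_network")
}

# ---- forward pass ----------------------------------------------------

# x: array [n_pix, B, C]; applies L to the (n_pix) x (B*C) matrix view
lap_apply <- function(L, x) {
  d <- dim(x)
  array(as.matrix(L %*% matrix(x, d[1], d[2] * d[3])), d)
}

conv_forward <- function(x, graph, a) {
  d <- dim(x)
  K <- dim(a)[1] - 1L
  cout <- dim(a)[3]
  Tk <- x
  Ts <- vector("list", K + 1)
  Ts[[1]] <- Tk
  y <- array(matrix(Tk, d[1] * d[2], d[3]) %*%
    matrix(a[1, , ], d[3], cout), c(d[1], d[2], cout))
  for (k in seq_len(K)) {
    Tk <- lap_apply(graph$laplacian, Tk)
    Ts[[k + 1]] <- Tk
    y <- y + array(matrix(Tk, d[1] * d[2], d[3]) %*%
      matrix(a[k + 1, , ], d[3], cout), c(d[1], d[2], cout))
  }
  list(y = y, Ts = Ts)
}

bn_forward <- function(x, layer, training, eps) {
  d <- dim(x)
  xm <- matrix(x, d[1] * d[2], d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    va <- colMeans(xc^2)
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
    xc <- sweep(xm, 2, mu)
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  list(y = array(y, d), xhat = xhat, istd = istd, mu = mu, va = va)
}

maxpool_forward <- function(x, mode = "max") {
  d <- dim(x)
  n4 <- d[1] %/% 4L
  xr <- matrix(array(x, c(4, n4 * d[2] * d[3])), 4)
  if (mode == "average") {
    return(list(y = array(colMeans(xr), c(n4, d[2], d[3])), argmax = NULL,
                in_dim = d))
  }
  am <- max.col(t(xr), ties.method = "first")
  mx <- xr[cbind(am, seq_len(ncol(xr)))]
  list(y = array(mx, c(n4, d[2], d[3])), argmax = am, in_dim = d)
}

#' Forward pass of the spherical network
#'
#' @param net A `sphere_network`.
#' @param x Input batch: `spherical_maps`, a list of them, or an array
#'   `[n_pix, B, 9]`.
#' @param training Use batch statistics in batch norm (and keep the
#'   caches needed for backprop).
#' @return List with `out` (`B x n_classes` softmax probabilities or
#'   `B x 256` descriptors), `embedding` (`B x 256` pre-head features) and,
#'   when `training`, the layer caches.
#' @export
network_forward <- function(net, x, training = FALSE) {
  x <- as_input_array(x, net$cfg)
  caches <- vector("list", length(net$layers))
  for (l in seq_along(net$layers)) {
    cf <- conv_forward(x, net$graphs[[l]], net$layers[[l]]$a)
    bf <- bn_forward(cf$y, net$layers[[l]], training, net$bn_eps)
    relu_mask <- bf$y > 0
    xr <- bf$y * relu_mask
    pf <- maxpool_forward(xr, net$cfg$pool %||% "max")
    caches[[l]] <- list(conv = cf, bn = bf, relu = relu_mask, pool = pf)
    x <- pf$y
  }
  if (any(!is.finite(x))) stop("non-finite activations after layer ",
    length(net$layers))
  d <- dim(x)
  h <- matrix(colMeans(matrix(x, d[1], d[2] * d[3])), d[2], d[3])  # B x C
  z <- sweep(h %*% net$fc$W, 2, net$fc$b, `+`)
  out <- if (net$cfg$head == "classifier") softmax(z) else z
  res <- list(out = out, embedding = h, logits = z)
  if (training) res$caches <- c(caches, list(gap_dim = d))
  res
}

as_input_array <- function(x, cfg) {
  if (inherits(x, "spherical_maps")) x <- list(x)
  if (is.list(x) && !is.array(x)) {
    n_pix <- ncol(x[[1]]$channels)
    B <- length(x)
    arr <- array(0, c(n_pix, B, nrow(x[[1]]$channels)))
    for (b in seq_len(B)) arr[, b, ] <- t(x[[b]]$channels)
    return(arr)
  }
  x
}

#' Softmax over rows
#'
#' Numerically stable: `p_i = exp(z_i - max z) / sum_j exp(z_j - max z)`.
#'
#' @param z Numeric vector or matrix (rows are observations).
#' @return Probabilities of the same shape, rows summing to 1.
#' @export
softmax <- function(z) {
  vec_in <- is.null(dim(z))
  if (vec_in) z <- matrix(z, 1)
  zs <- z - apply(z, 1, max)
  e <- exp(zs)
  p <- e / rowSums(e)
  if (vec_in) p <- drop(p)
  p
}

#' Cross-entropy loss
#'
#' Mean over the batch of `-sum_i y_i log p_i` (natural log). Zero
#' predicted probability at the true class is clamped at 1e-12 with a
#' warning.
#'
#' @param p Predicted probabilities (vector or `B x C` matrix).
#' @param y One-hot truth of the same shape, or integer class labels.
#' @return Scalar loss.
#' @export
cross_entropy <- function(p, y) {
  if (is.null(dim(p))) p <- matrix(p, 1)
  if (is.null(dim(y))) {
    if (length(y) == nrow(p)) {
      Y <- matrix(0, nrow(p), ncol(p))
      Y[cbind(seq_len(nrow(p)), as.integer(y))] <- 1
      y <- Y
    } else {
      y <- matrix(y, 1)
    }
  }
  pt <- rowSums(p * y)
  if (any(pt <= 0)) {
    warning("zero predicted probability at the true class; clamping")
    pt <- pmax(pt, 1e-12)
  }
  mean(-log(pt))
}

#' Contrastive (margin) loss for descriptor pairs
#'
#' `L = y d^2 + (1 - y) max(0, m - d)^2` with `d` the Euclidean distance
#' between the two descriptors; similar pairs (y = 1) are pulled together,
#' dissimilar pairs pushed beyond the margin.
#'
#' @param f1,f2 Descriptor vectors or `B x d` matrices.
#' @param y Pair labels (1 similar, 0 dissimilar).
#' @param m Margin (default 1).
#' @return Mean loss over the batch.
#' @export
contrastive_loss <- function(f1, f2, y, m = 1.0) {
  if (is.null(dim(f1))) f1 <- matrix(f1, 1)
  if (is.null(dim(f2))) f2 <- matrix(f2, 1)
  d <- sqrt(rowSums((f1 - f2)^2))
  mean(y * d^2 + (1 - y) * pmax(0, m - d)^2)
}

# ---- backward pass ---------------------------------------------------

# dz: B x out_dim gradient at the FC output; returns parameter grads and
# runs the chain back through the trunk
network_backward <- function(net, fwd, dz) {
  caches <- fwd$caches
  gap_dim <- caches[[length(caches)]]
  caches <- caches[-length(caches)]
  h <- fwd$embedding
  grads <- list(fc = list(W = t(h) %*% dz, b = colSums(dz)))
  dh <- dz %*% t(net$fc$W)                # B x C
  # undo global average pool: spread over n_pix_last pixels
  n_last <- gap_dim[1]
  dx <- array(0, gap_dim)
  for (c in seq_len(gap_dim[3])) {
    dx[, , c] <- matrix(dh[, c] / n_last, n_last, gap_dim[2], byrow = TRUE)
  }
  grads$layers <- vector("list", length(net$layers))
  for (l in rev(seq_along(net$layers))) {
    cache <- caches[[l]]
    # pool backward
    pd <- cache$pool$in_dim
    n4 <- pd[1] %/% 4L
    if (is.null(cache$pool$argmax)) {        # average pooling
      dxr <- matrix(rep(as.vector(dx) / 4, each = 4), 4)
    } else {
      dxr <- matrix(0, 4, n4 * pd[2] * pd[3])
      dxr[cbind(cache$pool$argmax, seq_len(ncol(dxr)))] <- as.vector(dx)
    }
    dx <- array(dxr, pd)
    # relu
    dx <- dx * cache$relu
    # batch norm backward (batch statistics)
    d <- dim(dx)
    n <- d[1] * d[2]
    dym <- matrix(dx, n, d[3])
    xhat <- cache$bn$xhat
    dgamma <- colSums(dym * xhat)
    dbeta <- colSums(dym)
    dxhat <- sweep(dym, 2, net$layers[[l]]$gamma, `*`)
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
    dxm <- sweep(t1 - t2, 2, cache$bn$istd, `*`)
    dx <- array(dxm, d)
    # conv backward
    Ts <- cache$conv$Ts
    K <- length(Ts) - 1L
    cin <- dim(Ts[[1]])[3]
    cout <- d[3]
    da <- array(0, c(K + 1, cin, cout))
    dmat <- matrix(dx, d[1] * d[2], cout)
    for (k in 0:K) {
      da[k + 1, , ] <- t(matrix(Ts[[k + 1]], d[1] * d[2], cin)) %*% dmat
    }
    a <- net$layers[[l]]$a
    G <- array(dmat %*% t(matrix(a[K + 1, , ], cin, cout)),
               c(d[1], d[2], cin))
    if (K >= 1) {
      for (k in (K - 1):0) {
        G <- lap_apply(net$graphs[[l]]$laplacian, G) +
          array(dmat %*% t(matrix(a[k + 1, , ], cin, cout)),
                c(d[1], d[2], cin))
      }
    }
    grads$layers[[l]] <- list(a = da, gamma = dgamma, beta = dbeta)
    dx <- G
  }
  grads
}

# update running BN statistics from a training-mode forward
bn_update_running <- function(net, fwd) {
  for (l in seq_along(net$layers)) {
    bf <- fwd$caches[[l]]$bn
    mom <- net$bn_momentum
    net$layers[[l]]$run_mean <- mom * net$layers[[l]]$run_mean +
      (1 - mom) * bf$mu
    net$layers[[l]]$run_var <- mom * net$layers[[l]]$run_var +
      (1 - mom) * bf$va
  }
  net
}

#' Calibrate batch-norm statistics on reference inputs
#'
#' Runs one training-mode forward pass and sets the running batch-norm
#' statistics to the batch statistics of `x`. Useful before inference
#' with an untrained or freshly loaded network.
#'
#' @param net A `sphere_network`.
#' @param x Input batch (see [network_forward()]).
#' @return The calibrated network.
#' @export
calibrate_network <- function(net, x) {
  fw <- network_forward(net, x, training = TRUE)
  mom <- net$bn_momentum
  net$bn_momentum <- 0
  net <- bn_update_running(net, fw)
  net$bn_momentum <- mom
  net
}

# ---- Adam ------------------------------------------------------------

adam_state <- function(net) {
  zero_like <- function(p) {
    if (is.list(p)) lapply(p, zero_like) else p * 0
  }
  list(m = zero_like(network_params(net)),
       v = zero_like(network_params(net)), t = 0L)
}

network_params <- function(net) {
  c(lapply(net$layers, function(l) l[c("a", "gamma", "beta")]),
    list(fc = net$fc))
}

network_set_params <- function(net, params) {
  nl <- length(net$layers)
  for (l in seq_len(nl)) {
    net$layers[[l]]$a <- params[[l]]$a
    net$layers[[l]]$gamma <- params[[l]]$gamma
    net$layers[[l]]$beta <- params[[l]]$beta
  }
  net$fc <- params$fc
  net
}

grads_as_params <- function(grads) {
  c(grads$layers, list(fc = grads$fc))
}

adam_step <- function(net, state, grads, lr, betas = c(0.9, 0.999),
                      weight_decay = 0, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  params <- network_params(net)
  g <- grads_as_params(grads)
  walk <- function(p, gr, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, gr, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    if (weight_decay > 0) gr <- gr + weight_decay * p
    m <- b1 * m + (1 - b1) * gr
    v <- b2 * v + (1 - b2) * gr^2
    mhat <- m / (1 - b1^state$t)
    vhat <- v / (1 - b2^state$t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- Map(walk, params, g, state$m, state$v)
  params <- lapply(out, `[[`, "p")
  state$m <- lapply(out, `[[`, "m")
  state$v <- lapply(out, `[[`, "v")
  list(net = network_set_params(net, params), state = state)
}

# ---- serialization ---------------------------------------------------

#' Save network weights
#'
#' Writes a single JSON archive with a manifest (config, layer shapes,
#' n_side schedule) and all parameter values; [load_network()] restores it
#' bit-for-bit (up to double-precision decimal round-trip).
#'
#' @param net A `sphere_network`.
#' @param file Output path.
#' @export
save_network <- function(net, file) {
  enc <- function(x) list(dim = dim(x) %||% length(x), values = as.vector(x))
  obj <- list(
    manifest = list(
      package = "pocketsphere",
      config = unclass(net$cfg),
      n_side_schedule = vapply(net$graphs, `[[`, numeric(1), "n_side"),
      n_layers = length(net$layers)),
    layers = lapply(net$layers, function(l) lapply(l, enc)),
    fc = lapply(net$fc, enc))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load network weights saved by [save_network()]
#' @param file Path to the JSON archive.
#' @return A `sphere_network` (graphs rebuilt from the manifest).
#' @export
load_network <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE,
    simplifyDataFrame = FALSE)
  cfg <- do.call(network_config, obj$manifest$config[
    c("head", "n_classes", "channels", "embedding", "K", "n_side", "k",
      "in_channels")])
  net <- network_init(cfg, seed = 0L)
  dec <- function(e) {
    v <- e$values
    if (length(e$dim) > 1) array(v, e$dim) else as.numeric(v)
  }
  for (l in seq_along(net$layers)) {
    for (nm in names(net$layers[[l]])) {
      net$layers[[l]][[nm]] <- dec(obj$layers[[l]][[nm]])
    }
  }
  net$fc$W <- dec(obj$fc$W)
  net$fc$b <- dec(obj$fc$b)
  net
}

#' Pocket descriptors from a trained embedder
#'
#' @param net A `sphere_network` with the embedder head.
#' @param maps A `spherical_maps` object or list of them.
#' @return `B x 256` matrix of descriptors.
#' @export
pocket_descriptor <- function(net, maps) {
  network_forward(net, maps, training = FALSE)$out
}
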