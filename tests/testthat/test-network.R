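# Small-configuration checks of the network heads, losses and training
# mechanics; gradients are validated against finite differences.

tiny_cfg <- function(head = "classifier") {
  network_config(head, n_classes = 3, channels = c(3, 4), embedding = 4,
    n_side = 4, k = 8)
}

test_that("classifier probabilities normalize and embedder is 256-d", {
  net <- network_init(tiny_cfg(), seed = 2)
  x <- array(rnorm(192 * 2 * 9), c(192, 2, 9))
  fw <- network_forward(net, x, training = TRUE)
  expect_equal(dim(fw$out), c(2, 3))
  expect_equal(rowSums(fw$out), c(1, 1), tolerance = 1e-6)
  # full-size embedder emits the standard 256-long descriptor
  full <- network_init(network_config("embedder"), seed = 1)
  g <- healpix_grid(16)
  maps <- structure(list(channels = matrix(rnorm(9 * 3072), 9, 3072,
    dimnames = list(MAP_CHANNELS, NULL)), miss_mask = integer(3072),
    n_side = 16L), class = "spherical_maps")
  d <- network_forward(full, maps)$out
  expect_equal(length(d), 256)
})

test_that("softmax and cross-entropy follow their closed forms", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  expect_lt(max(abs(softmax(c(1, 2, 3)) - softmax(c(1, 2, 3) + 100))),
    1e-12)
  expect_equal(cross_entropy(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(cross_entropy(rep(1 / 3, 3), c(0, 1, 0)), log(3))
  set.seed(1)
  p <- softmax(matrix(rnorm(15), 5, 3))
  y <- diag(3)[sample(3, 5, replace = TRUE), ]
  expect_gte(cross_entropy(p, y), 0)
  expect_warning(cross_entropy(c(0, 1), c(1, 0)), "clamping")
})

test_that("contrastive loss matches the margin hinge closed form", {
  f <- rnorm(8)
  expect_equal(contrastive_loss(f, f, 1), 0)
  f2 <- f + c(2, rep(0, 7))          # d = 2 >= m
  expect_equal(contrastive_loss(f, f2, 0, m = 1), 0)
  f3 <- f + c(0.5, rep(0, 7))        # d = 0.5, m = 1
  expect_equal(contrastive_loss(f, f3, 0, m = 1), 0.25)
  expect_equal(contrastive_loss(f, f3, 1, m = 1), 0.25)  # y=1 -> d^2
})

test_that("backpropagation matches finite differences everywhere", {
  cfg <- tiny_cfg()
  net <- network_init(cfg, seed = 2)
  set.seed(5)
  x <- array(rnorm(192 * 2 * 9, sd = 0.5), c(192, 2, 9))
  Y <- rbind(c(1, 0, 0), c(0, 0, 1))
  lossfun <- function(n) {
    cross_entropy(network_forward(n, x, training = TRUE)$out, Y)
  }
  fw <- network_forward(net, x, training = TRUE)
  gr <- pocketsphere:::network_backward(net, fw, (fw$out - Y) / 2)
  eps <- 1e-6
  probe <- function(get, set, analytic) {
    num <- (lossfun(set(net, get(net) + eps)) -
            lossfun(set(net, get(net) - eps))) / (2 * eps)
    expect_equal(analytic, num, tolerance = 1e-4)
  }
  probe(function(n) n$layers[[1]]$a[2, 3, 2],
        function(n, v) { n$layers[[1]]$a[2, 3, 2] <- v; n },
        gr$layers[[1]]$a[2, 3, 2])
  probe(function(n) n$layers[[2]]$a[4, 1, 2],
        function(n, v) { n$layers[[2]]$a[4, 1, 2] <- v; n },
        gr$layers[[2]]$a[4, 1, 2])
  probe(function(n) n$layers[[1]]$gamma[2],
        function(n, v) { n$layers[[1]]$gamma[2] <- v; n },
        gr$layers[[1]]$gamma[2])
  probe(function(n) n$layers[[2]]$beta[3],
        function(n, v) { n$layers[[2]]$beta[3] <- v; n },
        gr$layers[[2]]$beta[3])
  probe(function(n) n$fc$W[2, 1],
        function(n, v) { n$fc$W[2, 1] <- v; n },
        gr$fc$W[2, 1])
  probe(function(n) n$fc$b[3],
        function(n, v) { n$fc$b[3] <- v; n },
        gr$fc$b[3])
})

test_that("the forward pass is invariant to permutations within 4-blocks", {
  cfg <- tiny_cfg()
  net <- network_init(cfg, seed = 3)
  set.seed(6)
  x <- array(rnorm(192 * 9), c(192, 1, 9))
  base <- network_forward(net, x, training = TRUE)$out
  # permute pixels within bottom-level 4-blocks only: since layer-1
  # convolution is followed by max pooling, permutations commute with the
  # pooled path when conv weights at k>0 are zeroed
  net0 <- net
  for (l in seq_along(net0$layers)) {
    net0$layers[[l]]$a[2:4, , ] <- 0
  }
  base0 <- network_forward(net0, x, training = TRUE)$out
  set.seed(7)
  perm <- as.vector(vapply(seq(1, 192, by = 4),
    function(s) s - 1 + sample(4), numeric(4)))
  xp <- x[perm, , , drop = FALSE]
  out_p <- network_forward(net0, xp, training = TRUE)$out
  expect_equal(out_p, base0, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(base, base0)))  # sanity: k>0 terms matter
})

test_that("non-finite activations are reported with the layer name", {
  net <- network_init(tiny_cfg(), seed = 2)
  net$layers[[2]]$a[1, 1, 1] <- Inf
  x <- array(rnorm(192 * 9), c(192, 1, 9))
  expect_error(network_forward(net, x, training = TRUE), "layer")
})

test_that("weights round-trip through the JSON archive", {
  net <- network_init(tiny_cfg("embedder"), seed = 9)
  f <- tempfile(fileext = ".json")
  save_network(net, f)
  back <- load_network(f)
  expect_equal(back$layers, net$layers)
  expect_equal(back$fc, net$fc)
  x <- array(rnorm(192 * 9), c(192, 1, 9))
  expect_equal(network_forward(back, x)$out, network_forward(net, x)$out)
})
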