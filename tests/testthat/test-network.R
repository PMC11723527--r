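# A very small custom architecture used where full presets would be wasteful.
mini_cfg <- function() {
  network_config("tiny",
                 blocks = data.frame(filters = 4L, dilation = c(2L, 1L),
                                     n_conv = 2L),
                 proj_filters = 4L, n_dropout_layers = 1L)
}

# Examples for training tests: small two-domain proteins.
mini_examples <- function(n = 4L, seed = 50L) {
  lapply(seq_len(n), function(i) {
    spec <- synthetic_spec(domain_sizes = c(60L, 50L),
                           seed = derive_seed_for_test(seed, i))
    prot <- make_protein(spec)
    hits <- make_hits(prot$truth, "both", seed = i)
    list(features = featurize(prot$model, prot$pae, hits),
         truth = prot$truth, cluster_id = sprintf("c%d", i))
  })
}
derive_seed_for_test <- function(seed, i) seed * 31 + i * 7

test_that("preset layer counts match their configuration", {
  full <- build_network(network_config("full"))
  cl <- count_layers(full)
  expect_equal(unname(cl["conv"]), 48L)
  expect_equal(unname(cl["dropout"]), 15L)
  expect_equal(full$cfg$dropout_ratio, 0.15)
  expect_equal(length(full$blocks), 12L)

  tiny <- build_network(network_config("tiny"))
  expect_equal(unname(count_layers(tiny)["conv"]), 8L)
  expect_equal(unname(count_layers(tiny)["dropout"]), 2L)

  expect_error(network_config("tiny", n_dropout_layers = 20L),
               "too many dropout layers")
})

test_that("forward output is a probability map on any spatial size", {
  net <- build_network(network_config("tiny"), seed = 2)
  x <- array(runif(40 * 40 * 24), dim = c(40, 40, 24))
  p <- net_forward(net, x)$p
  expect_equal(dim(p), c(40, 40))
  expect_true(all(p >= 0 & p <= 1))   # class-1 softmax output; class-0 = 1-p
})

test_that("a tiny network processes a full 500x500 crop", {
  net <- build_network(network_config("tiny"), seed = 2)
  x <- array(runif(500 * 500 * 24, 0, 10), dim = c(500, 500, 24))
  t0 <- Sys.time()
  p <- net_forward(net, x)$p
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  expect_equal(dim(p), c(500, 500))
  expect_true(all(is.finite(p)))
  expect_lt(elapsed, 30)
})

test_that("masked BCE matches closed forms and a scalar-loop oracle", {
  t <- matrix(rbinom(100, 1, 0.5), 10, 10)
  expect_lt(masked_bce_loss(t, t), 1e-6)
  expect_equal(masked_bce_loss(matrix(0.5, 10, 10), t), log(2),
               tolerance = 1e-12)
  set.seed(4)
  p <- matrix(runif(100), 10, 10)
  mask <- matrix(runif(100) > 0.3, 10, 10)
  acc <- 0; n <- 0
  for (i in 1:10) for (j in 1:10) {
    if (!mask[i, j]) next
    acc <- acc - (t[i, j] * log(p[i, j]) + (1 - t[i, j]) * log(1 - p[i, j]))
    n <- n + 1
  }
  expect_equal(masked_bce_loss(p, t, mask), acc / n)
})

test_that("target matrices encode same-domain membership", {
  spec <- crop_spec(list(c(1L, 200L)))
  one <- target_matrix(list(1:200), spec)
  expect_true(all(one$target[1:200, 1:200] == 1))
  expect_true(all(one$mask[1:200, 1:200]))
  expect_false(any(one$mask[201:500, ]))
  expect_true(all(one$target[201:500, ] == 0))

  two <- target_matrix(list(1:100, 101:200), spec)
  expect_true(all(two$target[1:100, 1:100] == 1))
  expect_true(all(two$target[101:200, 101:200] == 1))
  expect_true(all(two$target[1:100, 101:200] == 0))

  disc <- target_matrix(list(c(1:50, 151:200)), spec)
  expect_equal(disc$target[10, 160], 1)
  expect_equal(disc$target[10, 100], 0)   # 100 in no domain
})

test_that("padded pixels never influence the training loss", {
  ex <- mini_examples(1)[[1]]
  spec <- crop_spec(list(c(1L, ex$features$L)), pad_left = 40L)
  crop <- extract_crop(ex$features, spec)
  tg <- target_matrix(ex$truth, spec)
  net <- build_network(mini_cfg(), seed = 3)
  loss_of <- function(crop_x) {
    v <- which(!is.na(spec$pos_map))
    p <- net_forward(net, crop_x[v, v, , drop = FALSE])$p
    masked_bce_loss(p, tg$target[v, v])
  }
  base <- loss_of(crop$x)
  perturbed <- crop$x
  perturbed[1:40, , ] <- 99        # left padding
  perturbed[, 460:500, ] <- -7     # right padding
  expect_identical(loss_of(perturbed), base)
})

test_that("cluster split holds out whole clusters deterministically", {
  ex <- lapply(1:200, function(i)
    list(cluster_id = sprintf("cl%03d", ((i - 1) %% 100) + 1)))
  sp <- split_by_cluster(ex, frac = 0.05, seed = 3)
  val_cl <- unique(vapply(sp$validation, `[[`, "", "cluster_id"))
  train_cl <- unique(vapply(sp$train, `[[`, "", "cluster_id"))
  expect_length(val_cl, 5L)
  expect_length(intersect(val_cl, train_cl), 0L)
  expect_equal(length(sp$train) + length(sp$validation), 200L)

  sp2 <- split_by_cluster(ex, frac = 0.05, seed = 3)
  expect_identical(sp, sp2)

  expect_error(split_by_cluster(list(list(cluster_id = "only")), 0.05, 1),
               "at least two clusters")
})

test_that("zero-epoch training changes nothing and logs nothing", {
  ex <- mini_examples(2)
  tr <- train_network(ex, mini_cfg(), train_config(epochs = 0, seed = 5,
                                                   validation_cluster_fraction = 0.5))
  ref <- build_network(mini_cfg(), seed = 5)
  expect_equal(domainseg:::get_params(tr$net), domainseg:::get_params(ref))
  expect_equal(nrow(tr$log), 0L)
})

test_that("training is seed-deterministic and reduces the loss", {
  ex <- mini_examples(4)
  cfg <- train_config(epochs = 3, validation_cluster_fraction = 0.3,
                      seed = 11, learning_rate = 3e-3)
  tr1 <- train_network(ex, mini_cfg(), cfg)
  tr2 <- train_network(ex, mini_cfg(), cfg)
  expect_identical(tr1$log, tr2$log)
  expect_identical(domainseg:::get_params(tr1$net),
                   domainseg:::get_params(tr2$net))
  expect_equal(nrow(tr1$log), 3L)
  expect_lt(min(tr1$log$train_loss), tr1$log$train_loss[1])
  expect_lt(min(tr1$log$train_loss), log(2))  # beats the 0.5 baseline
})

test_that("analytic gradients match finite differences", {
  set.seed(42)
  cfg <- network_config("tiny",
                        blocks = data.frame(filters = 3L, dilation = c(2L, 1L),
                                            n_conv = 2L),
                        proj_filters = 3L, n_dropout_layers = 0L)
  net <- build_network(cfg, seed = 3)
  H <- 8
  x <- array(runif(H * H * 24), dim = c(H, H, 24))
  t <- matrix(rbinom(H * H, 1, 0.5), H, H)
  fw <- net_forward(net, x, train = TRUE)
  d <- (fw$p - t) / length(t)
  gz <- array(0, dim = c(H, H, 2)); gz[, , 1] <- -d; gz[, , 2] <- d
  gr <- domainseg:::net_backward(net, fw$cache, gz)
  p <- domainseg:::get_params(net)
  eps <- 1e-5
  loss_at <- function(pp) {
    fw <- net_forward(domainseg:::set_params(net, pp), x)
    masked_bce_loss(fw$p, t)
  }
  for (nm in names(p)) {
    idx <- sample(length(p[[nm]]), min(3L, length(p[[nm]])))
    for (i in idx) {
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- loss_at(p2)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- loss_at(p2)
      num <- (up - dn) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("per-protein prediction is symmetric, bounded and stub-transparent", {
  ex <- mini_examples(1)[[1]]
  L <- ex$features$L
  # identity stub: thresholded raw distance channel
  stub <- function(x) (x[, , 1] < 15) + 0
  p <- predict_protein(ex$features, stub)
  want <- (ex$features$distance < 15) + 0
  want <- (want + t(want)) / 2
  expect_equal(p, want)

  net <- build_network(mini_cfg(), seed = 9)
  p2 <- predict_protein(ex$features, net)
  expect_equal(dim(p2), c(L, L))
  expect_equal(p2, t(p2))
  expect_true(all(p2 >= 0 & p2 <= 1))
})

test_that("checkpoints round trip through a single file", {
  ex <- mini_examples(2)
  tr <- train_network(ex, mini_cfg(),
                      train_config(epochs = 1, seed = 2,
                                   validation_cluster_fraction = 0.5))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(tr, path)
  back <- load_checkpoint(path)
  expect_equal(domainseg:::get_params(back$net),
               domainseg:::get_params(tr$net))
  expect_equal(back$log, tr$log)
  x <- array(runif(20 * 20 * 24), dim = c(20, 20, 24))
  expect_equal(net_forward(back$net, x)$p, net_forward(tr$net, x)$p)
})
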