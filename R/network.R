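# Residual dilated convolutional network mapping 24 input channels to
# per-pixel two-class (same-domain / different-domain) probabilities.
#
# The network semantics are "masked": activations are zero at non-valid
# (padding) pixels at every layer, so the forward pass may be restricted to
# the valid bounding box of a crop without changing any valid-pixel output.
# Because crop segments are placed consecutively after the left pad, the
# valid region of every crop is one contiguous square block.

#' Network architecture configuration
#'
#' The trunk is a stack of residual blocks of dilated 3x3 convolutions,
#' preceded by a 1x1 projection of the 24 input channels and followed by a
#' 1x1 two-class softmax head. Filters and dilation decrease from early to
#' late blocks so early layers see broad context and late layers local
#' detail. Dropout layers are interleaved after every
#' `floor(n_conv / (n_dropout + 1))`-th trunk convolution.
#'
#' The `"full"` preset has a 64-filter projection and 12 blocks of 4
#' convolutions (48 convolutional layers; filters 64/48/32/16 and dilations
#' 8/4/2/1 by block quartile) with 15 dropout layers. The `"tiny"` preset
#' (8-filter projection, 4 blocks of 2 convolutions, 2 dropout layers) is
#' for CPU-scale experiments and tests.
#'
#' @param scale `"full"` or `"tiny"`.
#' @param dropout_ratio dropout probability (default 0.15).
#' @param in_channels input channel count (default 24).
#' @param blocks optional custom schedule: data.frame with columns
#'   `filters`, `dilation`, `n_conv` (one row per residual block).
#' @param proj_filters optional custom projection width.
#' @param n_dropout_layers optional custom dropout layer count.
#' @return a `network_config`.
#' @export
network_config <- function(scale = c("full", "tiny"), dropout_ratio = 0.15,
                           in_channels = 24L, blocks = NULL,
                           proj_filters = NULL, n_dropout_layers = NULL) {
  scale <- match.arg(scale)
  if (is.null(blocks)) {
    blocks <- if (scale == "full")
      data.frame(filters = rep(c(64L, 48L, 32L, 16L), each = 3L),
                 dilation = rep(c(8L, 4L, 2L, 1L), each = 3L),
                 n_conv = 4L)
    else
      data.frame(filters = 8L, dilation = c(4L, 2L, 1L, 1L), n_conv = 2L)
  }
  if (is.null(proj_filters))
    proj_filters <- if (scale == "full") 64L else 8L
  n_conv <- sum(blocks$n_conv)
  if (is.null(n_dropout_layers))
    n_dropout_layers <- if (scale == "full") 15L else 2L
  stopifnot(n_conv >= 2L, dropout_ratio >= 0, dropout_ratio < 1,
            all(blocks$dilation >= 1L))
  if (any(diff(blocks$dilation) > 0L))
    stop("dilations must be non-increasing across blocks")
  spacing <- n_conv %/% (n_dropout_layers + 1L)
  if (n_dropout_layers > 0L && spacing < 1L)
    stop("too many dropout layers for ", n_conv, " convolutional layers")
  dropout_after <- if (n_dropout_layers > 0L)
    spacing * seq_len(n_dropout_layers) else integer(0)
  structure(list(scale = scale, blocks = blocks,
                 proj_filters = as.integer(proj_filters),
                 in_channels = as.integer(in_channels),
                 n_conv_layers = as.integer(n_conv),
                 n_dropout_layers = as.integer(n_dropout_layers),
                 dropout_ratio = dropout_ratio,
                 dropout_after = as.integer(dropout_after)),
            class = "network_config")
}

he_init <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        dim = c(k, k, cin, cout))
}

#' Instantiate the network
#'
#' @param cfg a [network_config].
#' @param seed RNG seed for weight initialization (default 1).
#' @return a `dilated_cnn` object holding the configuration and all
#'   parameter arrays.
#' @export
build_network <- function(cfg = network_config("full"), seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(as.integer(seed %% 2147483647))
  net <- list(cfg = cfg)
  net$proj <- list(W = he_init(1L, cfg$in_channels, cfg$proj_filters),
                   b = numeric(cfg$proj_filters))
  blocks <- list()
  cin <- cfg$proj_filters
  conv_idx <- 0L
  for (k in seq_len(nrow(cfg$blocks))) {
    f <- cfg$blocks$filters[k]
    d <- cfg$blocks$dilation[k]
    convs <- list()
    ci <- cin
    for (j in seq_len(cfg$blocks$n_conv[k])) {
      conv_idx <- conv_idx + 1L
      convs[[j]] <- list(W = he_init(3L, ci, f), b = numeric(f),
                         dilation = d,
                         dropout_after = conv_idx %in% cfg$dropout_after)
      ci <- f
    }
    skip <- if (cin != f)
      list(W = he_init(1L, cin, f), b = numeric(f)) else NULL
    blocks[[k]] <- list(convs = convs, skip = skip, filters = f)
    cin <- f
  }
  net$blocks <- blocks
  net$head <- list(W = he_init(1L, cin, 2L), b = numeric(2L))
  class(net) <- "dilated_cnn"
  net
}

#' Layer-count introspection
#'
#' @param net a `dilated_cnn`.
#' @return named integer vector with counts of trunk convolutional layers
#'   (`conv`), dropout layers (`dropout`), input projection layers
#'   (`projection`), skip projections (`skip`) and softmax heads (`head`).
#' @export
count_layers <- function(net) {
  stopifnot(inherits(net, "dilated_cnn"))
  n_conv <- sum(vapply(net$blocks, function(b) length(b$convs), 1L))
  n_drop <- sum(vapply(net$blocks, function(b)
    sum(vapply(b$convs, `[[`, FALSE, "dropout_after")), 1L))
  n_skip <- sum(vapply(net$blocks, function(b) !is.null(b$skip), FALSE))
  c(conv = n_conv, dropout = n_drop, projection = 1L, skip = n_skip,
    head = 1L)
}

#' @export
print.dilated_cnn <- function(x, ...) {
  cl <- count_layers(x)
  cat(sprintf("dilated_cnn (%s): %d conv layers in %d residual blocks, %d dropout layers (ratio %.2f)\n",
              x$cfg$scale, cl["conv"], length(x$blocks), cl["dropout"],
              x$cfg$dropout_ratio))
  invisible(x)
}

# Fixed per-channel input squashing: distances and PAE (unbounded, in
# Angstrom) are mapped into [0,1) by d/(d+s); position and evidence
# channels are already bounded.
normalize_channels <- function(x) {
  x[, , 1L] <- x[, , 1L] / (x[, , 1L] + 15)
  x[, , 2L] <- x[, , 2L] / (x[, , 2L] + 10)
  x
}

#' Forward pass
#'
#' @param net a `dilated_cnn`.
#' @param x input array H x W x C (any spatial size; typically a crop or its
#'   valid bounding box).
#' @param train logical; when TRUE dropout is active (consumes the R RNG
#'   stream) and layer caches for backprop are retained.
#' @return list with `p` (H x W same-domain probability, class-1 softmax
#'   output) and, when `train`, `cache`.
#' @export
net_forward <- function(net, x, train = FALSE) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == net$cfg$in_channels)
  ratio <- net$cfg$dropout_ratio
  xn <- normalize_channels(x)
  cache <- if (train) list(xn = xn) else NULL
  pre <- .conv2d_fwd(xn, net$proj$W, net$proj$b, 1L)
  h <- pre * (pre > 0)
  if (train) cache$proj_pre <- pre
  bcaches <- list()
  for (k in seq_along(net$blocks)) {
    blk <- net$blocks[[k]]
    inp <- h
    a <- inp
    bc <- list(inp = inp, conv_in = list(), pre = list(), drop = list())
    nj <- length(blk$convs)
    for (j in seq_len(nj)) {
      cv <- blk$convs[[j]]
      if (train) bc$conv_in[[j]] <- a
      a <- .conv2d_fwd(a, cv$W, cv$b, cv$dilation)
      if (train) bc$pre[[j]] <- a
      if (j < nj) a <- a * (a > 0)
      if (cv$dropout_after && train) {
        m <- array((stats::runif(length(a)) >= ratio) / (1 - ratio),
                   dim = dim(a))
        a <- a * m
        bc$drop[[j]] <- m
      }
    }
    skip <- if (is.null(blk$skip)) inp
            else .conv2d_fwd(inp, blk$skip$W, blk$skip$b, 1L)
    s <- a + skip
    h <- s * (s > 0)
    if (train) { bc$s <- s; bcaches[[k]] <- bc }
  }
  logits <- .conv2d_fwd(h, net$head$W, net$head$b, 1L)
  p <- 1 / (1 + exp(logits[, , 1L] - logits[, , 2L]))
  if (train) { cache$head_in <- h; cache$bcaches <- bcaches }
  list(p = p, cache = cache)
}

# Backward pass. gz: H x W x 2 gradient w.r.t. the head logits.
# Returns a named list of gradient arrays matching get_params().
net_backward <- function(net, cache, gz) {
  grads <- list()
  bw <- .conv2d_bwd(cache$head_in, net$head$W, gz, 1L)
  grads[["head.W"]] <- bw$gw; grads[["head.b"]] <- bw$gb
  g <- bw$gx
  for (k in rev(seq_along(net$blocks))) {
    blk <- net$blocks[[k]]
    bc <- cache$bcaches[[k]]
    gs <- g * (bc$s > 0)
    # skip path
    if (is.null(blk$skip)) {
      g_inp <- gs
    } else {
      bws <- .conv2d_bwd(bc$inp, blk$skip$W, gs, 1L)
      grads[[paste0("b", k, ".skip.W")]] <- bws$gw
      grads[[paste0("b", k, ".skip.b")]] <- bws$gb
      g_inp <- bws$gx
    }
    # main path
    ga <- gs
    nj <- length(blk$convs)
    for (j in rev(seq_len(nj))) {
      cv <- blk$convs[[j]]
      if (cv$dropout_after && length(bc$drop) >= j && !is.null(bc$drop[[j]]))
        ga <- ga * bc$drop[[j]]
      if (j < nj) ga <- ga * (bc$pre[[j]] > 0)
      bwc <- .conv2d_bwd(bc$conv_in[[j]], cv$W, ga, cv$dilation)
      grads[[paste0("b", k, ".c", j, ".W")]] <- bwc$gw
      grads[[paste0("b", k, ".c", j, ".b")]] <- bwc$gb
      ga <- bwc$gx
    }
    g <- g_inp + ga
  }
  g <- g * (cache$proj_pre > 0)
  bwp <- .conv2d_bwd(cache$xn, net$proj$W, g, 1L)
  grads[["proj.W"]] <- bwp$gw; grads[["proj.b"]] <- bwp$gb
  grads
}

get_params <- function(net) {
  p <- list("proj.W" = net$proj$W, "proj.b" = net$proj$b)
  for (k in seq_along(net$blocks)) {
    blk <- net$blocks[[k]]
    for (j in seq_along(blk$convs)) {
      p[[paste0("b", k, ".c", j, ".W")]] <- blk$convs[[j]]$W
      p[[paste0("b", k, ".c", j, ".b")]] <- blk$convs[[j]]$b
    }
    if (!is.null(blk$skip)) {
      p[[paste0("b", k, ".skip.W")]] <- blk$skip$W
      p[[paste0("b", k, ".skip.b")]] <- blk$skip$b
    }
  }
  p[["head.W"]] <- net$head$W; p[["head.b"]] <- net$head$b
  p
}

set_params <- function(net, p) {
  net$proj$W <- p[["proj.W"]]; net$proj$b <- p[["proj.b"]]
  for (k in seq_along(net$blocks)) {
    for (j in seq_along(net$blocks[[k]]$convs)) {
      net$blocks[[k]]$convs[[j]]$W <- p[[paste0("b", k, ".c", j, ".W")]]
      net$blocks[[k]]$convs[[j]]$b <- p[[paste0("b", k, ".c", j, ".b")]]
    }
    if (!is.null(net$blocks[[k]]$skip)) {
      net$blocks[[k]]$skip$W <- p[[paste0("b", k, ".skip.W")]]
      net$blocks[[k]]$skip$b <- p[[paste0("b", k, ".skip.b")]]
    }
  }
  net$head$W <- p[["head.W"]]; net$head$b <- p[["head.b"]]
  net
}

#' Masked binary cross-entropy
#'
#' Mean over masked-in pixels of `-(t log p + (1-t) log(1-p))`, with
#' probabilities clipped to `[1e-7, 1 - 1e-7]`.
#'
#' @param pred,target numeric arrays of equal shape (probabilities and 0/1
#'   targets).
#' @param mask logical array of the same shape (default: all pixels).
#' @return scalar loss.
#' @export
masked_bce_loss <- function(pred, target, mask = NULL) {
  stopifnot(length(pred) == length(target))
  if (is.null(mask)) mask <- rep(TRUE, length(pred))
  p <- pmin(pmax(pred[mask], 1e-7), 1 - 1e-7)
  t <- target[mask]
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Binary same-domain target for a crop
#'
#' Pixel (i, j) is 1 iff both residues are assigned to the same reference
#' domain; residues in no domain are 0 against everything; padded pixels
#' are masked out.
#'
#' @param domains a [domain_set] (or plain list of residue-index vectors).
#' @param spec a [crop_spec].
#' @return list with `target` (0/1 matrix) and `mask` (logical matrix),
#'   both `crop_size` x `crop_size`.
#' @export
target_matrix <- function(domains, spec) {
  doms <- if (inherits(domains, "domain_set")) domains$domains else domains
  cs <- spec$crop_size
  v <- which(!is.na(spec$pos_map))
  res <- spec$pos_map[v]
  dom_id <- rep(0L, max(res, unlist(doms), 0L))
  for (d in seq_along(doms)) dom_id[doms[[d]]] <- d
  ids <- dom_id[res]
  tm <- outer(ids, ids, "==") & (ids > 0)
  target <- matrix(0, cs, cs)
  target[v, v] <- tm + 0
  mask <- matrix(FALSE, cs, cs)
  mask[v, v] <- TRUE
  list(target = target, mask = mask)
}

#' Training configuration
#'
#' @param epochs number of epochs (default 30).
#' @param validation_cluster_fraction fraction of clusters held out for
#'   validation (default 0.05).
#' @param seed run seed; per-epoch crop seeds are derived from it.
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size examples per parameter update (default 1).
#' @param patience optional early-stopping patience in epochs on the
#'   validation loss (default `Inf`, i.e. off: the epoch cap governs).
#' @return a `train_config`.
#' @export
train_config <- function(epochs = 30L, validation_cluster_fraction = 0.05,
                         seed = 1L, learning_rate = 1e-3, batch_size = 1L,
                         patience = Inf) {
  stopifnot(epochs >= 0, validation_cluster_fraction > 0,
            validation_cluster_fraction < 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 validation_cluster_fraction = validation_cluster_fraction,
                 seed = as.integer(seed), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), patience = patience),
            class = "train_config")
}

#' Split training examples by homology cluster
#'
#' Whole clusters are held out for validation until at least `frac` of the
#' clusters are on the validation side; no cluster straddles the split.
#'
#' @param examples list of examples, each carrying a `cluster_id` element.
#' @param frac fraction of clusters to hold out.
#' @param seed RNG seed (deterministic split).
#' @return list with `train` and `validation` example lists.
#' @export
split_by_cluster <- function(examples, frac, seed = 1L) {
  ids <- vapply(examples, `[[`, "", "cluster_id")
  clusters <- sort(unique(ids))
  if (length(clusters) < 2L)
    stop("need at least two clusters to split")
  set.seed(as.integer(seed %% 2147483647))
  perm <- sample(clusters)
  n_hold <- ceiling(frac * length(clusters))
  val_clusters <- perm[seq_len(n_hold)]
  list(train = examples[!ids %in% val_clusters],
       validation = examples[ids %in% val_clusters])
}

# Slice a crop (and its target) to the valid bounding box. Valid pixels of
# every crop_spec form one contiguous block, so this is exact under the
# masked network semantics.
crop_box <- function(crop) {
  v <- which(!is.na(crop$spec$pos_map))
  list(x = crop$x[v, v, , drop = FALSE], v = v)
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the network
#'
#' Examples carry precomputed feature sets and reference domains. Crops are
#' re-sampled every epoch with a fresh seed derived from the run seed, so
#' successive epochs see slightly different inputs. Optimization is Adam on
#' a per-crop masked binary cross-entropy.
#'
#' @param examples list of training examples; each a list with `features`
#'   (from [featurize] or compatible), `truth` (a [domain_set] or list of
#'   residue sets) and `cluster_id`.
#' @param net_cfg a [network_config].
#' @param train_cfg a [train_config].
#' @return list with `net` (trained `dilated_cnn`), `log` (data.frame with
#'   per-epoch `epoch`, `train_loss`, `val_loss`) and `split` (the cluster
#'   split used).
#' @export
train_network <- function(examples, net_cfg = network_config("tiny"),
                          train_cfg = train_config()) {
  split <- split_by_cluster(examples, train_cfg$validation_cluster_fraction,
                            seed = train_cfg$seed)
  net <- build_network(net_cfg, seed = train_cfg$seed)
  params <- get_params(net)
  state <- adam_init(params)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  if (train_cfg$epochs == 0L)
    return(list(net = net, log = log, split = split))
  best_val <- Inf; since_best <- 0L
  for (epoch in seq_len(train_cfg$epochs)) {
    epoch_seed <- derive_seed(train_cfg$seed, epoch)
    losses <- numeric(0)
    for (i in seq_along(split$train)) {
      ex <- split$train[[i]]
      specs <- make_training_crops(ex$features$L,
                                   seed = derive_seed(epoch_seed, i))
      for (spec in specs) {
        crop <- extract_crop(ex$features, spec)
        box <- crop_box(crop)
        tg <- target_matrix(ex$truth, spec)
        tbox <- tg$target[box$v, box$v]
        net <- set_params(net, params)
        fw <- net_forward(net, box$x, train = TRUE)
        n <- length(tbox)
        loss <- masked_bce_loss(fw$p, tbox)
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", epoch)
        losses <- c(losses, loss)
        d <- (fw$p - tbox) / n
        gz <- array(0, dim = c(dim(fw$p), 2L))
        gz[, , 1L] <- -d
        gz[, , 2L] <- d
        grads <- net_backward(net, fw$cache, gz)
        upd <- adam_step(params, grads, state, train_cfg$learning_rate)
        params <- upd$params; state <- upd$state
      }
    }
    net <- set_params(net, params)
    val_loss <- if (length(split$validation))
      mean(vapply(split$validation, function(ex)
        validation_loss(net, ex), 0)) else NA_real_
    log <- rbind(log, data.frame(epoch = epoch,
                                 train_loss = mean(losses),
                                 val_loss = val_loss))
    if (is.finite(train_cfg$patience) && !is.na(val_loss)) {
      if (val_loss < best_val - 1e-6) { best_val <- val_loss; since_best <- 0L }
      else since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }
  list(net = set_params(net, params), log = log, split = split)
}

# Deterministic validation loss: one zero-pad crop for short chains, the
# systematic inference crops otherwise.
validation_loss <- function(net, ex) {
  L <- ex$features$L
  specs <- if (L <= CROP_SIZE) list(crop_spec(list(c(1L, L))))
           else make_inference_crops(L)
  mean(vapply(specs, function(spec) {
    crop <- extract_crop(ex$features, spec)
    box <- crop_box(crop)
    tg <- target_matrix(ex$truth, spec)
    fw <- net_forward(net, box$x, train = FALSE)
    masked_bce_loss(fw$p, tg$target[box$v, box$v])
  }, 0))
}

#' Predict the same-domain probability matrix for one protein
#'
#' Short chains (L <= 500) run through a single zero-pad crop; longer
#' chains through the systematic inference crops, with per-pair averaging
#' over covering crops. The output is symmetrized.
#'
#' @param features a `feature_set` from [featurize].
#' @param net a trained `dilated_cnn`, or (for testing plumbing) a function
#'   `x -> H x W matrix` applied to each crop's valid box.
#' @return L x L symmetric matrix of same-domain probabilities.
#' @export
predict_protein <- function(features, net) {
  L <- features$L
  specs <- if (L <= CROP_SIZE) list(crop_spec(list(c(1L, L))))
           else make_inference_crops(L)
  outputs <- lapply(specs, function(spec) {
    crop <- extract_crop(features, spec)
    box <- crop_box(crop)
    pbox <- if (is.function(net)) net(box$x)
            else net_forward(net, box$x, train = FALSE)$p
    out <- matrix(0, spec$crop_size, spec$crop_size)
    out[box$v, box$v] <- pbox
    out
  })
  assemble_probability(outputs, specs, L)
}

#' Save / load a network checkpoint
#'
#' Single-file RDS container holding the configuration, parameters and the
#' training log.
#'
#' @param trained result of [train_network] (or a list with `net`, `log`).
#' @param path checkpoint path.
#' @export
save_checkpoint <- function(trained, path) {
  saveRDS(list(cfg = trained$net$cfg, params = get_params(trained$net),
               log = trained$log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns a list with `net` and `log`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  net <- build_network(ck$cfg, seed = 1L)
  list(net = set_params(net, ck$params), log = ck$log)
}
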