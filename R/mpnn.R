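# Message-passing embedding network and triplet-loss training, implemented
# directly on (sparse) matrix operations. A batch of graphs is processed as
# one block-diagonal system: node features are stacked, message passing is a
# sparse adjacency product, and per-graph readout is a sparse sum-pooling
# product, which keeps the whole forward/backward pass vectorized.
#
# Layer t:   H_t = relu(H_{t-1} W_self + (A H_{t-1}) W_nbr + (B E) W_edge + b)
# Readout:   z   = (S H_T) W_out + b_out
# with A the symmetric adjacency, B the node-edge incidence and S the
# graph-sum pooling matrix. Sum pooling and neighbour sums make the
# embedding exactly invariant to atom reordering.

#' Initialize an embedding network
#'
#' @param node_dim,edge_dim input feature dimensions (defaults match
#'   [featurize()]).
#' @param hidden hidden width.
#' @param steps number of message-passing steps.
#' @param embedding_dim output embedding dimension.
#' @param rng_seed seed for weight initialization.
#' @return an `mpnn_model` (list of parameter matrices + config).
#' @export
mpnn_init <- function(node_dim = .node_feature_dim(),
                      edge_dim = .edge_feature_dim(),
                      hidden = 48L, steps = 3L, embedding_dim = 16L,
                      rng_seed = 42L) {
  set.seed(rng_seed)
  glorot <- function(nin, nout) {
    r <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -r, r), nin, nout)
  }
  params <- list(W_in = glorot(node_dim, hidden), b_in = numeric(hidden))
  for (t in seq_len(steps)) {
    params[[paste0("W_self", t)]] <- glorot(hidden, hidden)
    params[[paste0("W_nbr", t)]] <- glorot(hidden, hidden)
    params[[paste0("W_edge", t)]] <- glorot(edge_dim, hidden)
    params[[paste0("b", t)]] <- numeric(hidden)
  }
  params$W_out <- glorot(hidden, embedding_dim)
  params$b_out <- numeric(embedding_dim)
  structure(list(
    params = params,
    config = list(node_dim = node_dim, edge_dim = edge_dim, hidden = hidden,
                  steps = steps, embedding_dim = embedding_dim,
                  rng_seed = rng_seed)
  ), class = "mpnn_model")
}

#' @export
print.mpnn_model <- function(x, ...) {
  cfg <- x$config
  cat("mpnn_model:", cfg$steps, "message-passing steps, hidden", cfg$hidden,
      "-> embedding", cfg$embedding_dim, "\n")
  invisible(x)
}

# stack a list of mol_graphs into one block system
.batch_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) g$n, integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  N <- sum(ns)
  X <- do.call(rbind, lapply(graphs, function(g) g$node_x))
  E <- do.call(rbind, lapply(graphs, function(g) g$edge_x))
  e1 <- unlist(lapply(seq_along(graphs), function(i) {
    graphs[[i]]$edges[, 1] + offs[i]
  }), use.names = FALSE)
  e2 <- unlist(lapply(seq_along(graphs), function(i) {
    graphs[[i]]$edges[, 2] + offs[i]
  }), use.names = FALSE)
  M <- length(e1)
  A <- Matrix::sparseMatrix(i = c(e1, e2), j = c(e2, e1), x = 1,
                            dims = c(N, N))
  B <- if (M > 0) {
    Matrix::sparseMatrix(i = c(e1, e2), j = c(seq_len(M), seq_len(M)), x = 1,
                         dims = c(N, M))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), dims = c(N, 0L))
  }
  S <- Matrix::sparseMatrix(
    i = rep(seq_along(graphs), ns), j = seq_len(N), x = 1,
    dims = c(length(graphs), N)
  )
  if (is.null(E) || nrow(E) == 0) E <- matrix(0, 0, .edge_feature_dim())
  list(X = X, E = E, A = A, B = B, S = S, N = N, M = M)
}

.mpnn_forward <- function(model, batch) {
  p <- model$params
  steps <- model$config$steps
  cache <- list(batch = batch)
  P0 <- sweep(batch$X %*% p$W_in, 2, p$b_in, "+")
  H <- pmax(P0, 0)
  cache$P0 <- P0
  cache$H <- list(H)
  BE <- as.matrix(batch$B %*% batch$E) # N x edge_dim, constant across layers
  cache$BE <- BE
  for (t in seq_len(steps)) {
    AH <- as.matrix(batch$A %*% H)
    P <- H %*% p[[paste0("W_self", t)]] + AH %*% p[[paste0("W_nbr", t)]] +
      BE %*% p[[paste0("W_edge", t)]]
    P <- sweep(P, 2, p[[paste0("b", t)]], "+")
    cache[[paste0("AH", t)]] <- AH
    cache[[paste0("P", t)]] <- P
    H <- pmax(P, 0)
    cache$H[[t + 1]] <- H
  }
  SH <- as.matrix(batch$S %*% H)
  Z <- sweep(SH %*% p$W_out, 2, p$b_out, "+")
  cache$SH <- SH
  list(Z = Z, cache = cache)
}

.mpnn_backward <- function(model, cache, dZ) {
  p <- model$params
  steps <- model$config$steps
  grads <- list()
  grads$W_out <- crossprod(cache$SH, dZ)
  grads$b_out <- colSums(dZ)
  dH <- as.matrix(Matrix::crossprod(cache$batch$S, dZ %*% t(p$W_out)))
  for (t in rev(seq_len(steps))) {
    dP <- dH * (cache[[paste0("P", t)]] > 0)
    Hprev <- cache$H[[t]]
    grads[[paste0("W_self", t)]] <- crossprod(Hprev, dP)
    grads[[paste0("W_nbr", t)]] <- crossprod(cache[[paste0("AH", t)]], dP)
    grads[[paste0("W_edge", t)]] <- crossprod(cache$BE, dP)
    grads[[paste0("b", t)]] <- colSums(dP)
    dH <- dP %*% t(p[[paste0("W_self", t)]]) +
      as.matrix(cache$batch$A %*% (dP %*% t(p[[paste0("W_nbr", t)]])))
  }
  dP0 <- dH * (cache$P0 > 0)
  grads$W_in <- crossprod(cache$batch$X, dP0)
  grads$b_in <- colSums(dP0)
  grads
}

#' Embed molecular graphs
#'
#' Deterministic inference (no ablation): maps each graph to a real vector
#' of length `embedding_dim`.
#'
#' @param model an `mpnn_model`.
#' @param graphs list of `mol_graph`s (or a character vector of SMILES,
#'   featurized on the fly).
#' @return numeric matrix, one embedding row per graph.
#' @export
embed_graphs <- function(model, graphs) {
  if (is.character(graphs)) graphs <- featurize(graphs)
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  if (length(graphs) == 0) {
    return(matrix(0, 0, model$config$embedding_dim))
  }
  nd <- ncol(graphs[[1]]$node_x)
  if (nd != model$config$node_dim) {
    stop("feature schema mismatch: graph has ", nd, " node features, model expects ",
         model$config$node_dim)
  }
  fw <- .mpnn_forward(model, .batch_graphs(graphs))
  fw$Z
}

#' Triplet margin loss
#'
#' `max(0, d(a, p) - d(a, n) + margin)` with Euclidean distances, averaged
#' over rows when matrices are supplied.
#'
#' @param anchor,positive,negative embedding vectors (or matrices with one
#'   embedding per row).
#' @param margin positive margin.
#' @return mean loss (non-negative scalar).
#' @export
triplet_margin_loss <- function(anchor, positive, negative, margin = 1.0) {
  stopifnot(margin > 0)
  a <- rbind(anchor); p <- rbind(positive); n <- rbind(negative)
  if (ncol(a) != ncol(p) || ncol(a) != ncol(n)) {
    stop("embedding length mismatch")
  }
  dap <- sqrt(rowSums((a - p)^2))
  dan <- sqrt(rowSums((a - n)^2))
  mean(pmax(0, dap - dan + margin))
}

# loss + gradient wrt the stacked embedding matrix Z (rows: the batch's
# anchors, then positives, then negatives)
.triplet_loss_grad <- function(Z, nt, margin) {
  za <- Z[seq_len(nt), , drop = FALSE]
  zp <- Z[nt + seq_len(nt), , drop = FALSE]
  zn <- Z[2 * nt + seq_len(nt), , drop = FALSE]
  vap <- za - zp
  van <- za - zn
  dap <- sqrt(rowSums(vap^2))
  dan <- sqrt(rowSums(van^2))
  li <- dap - dan + margin
  active <- li > 0
  loss <- mean(pmax(li, 0))
  dZ <- matrix(0, nrow(Z), ncol(Z))
  if (any(active)) {
    w <- as.numeric(active) / nt
    uap <- vap / pmax(dap, 1e-12)
    uan <- van / pmax(dan, 1e-12)
    dZ[seq_len(nt), ] <- w * (uap - uan)
    dZ[nt + seq_len(nt), ] <- -w * uap
    dZ[2 * nt + seq_len(nt), ] <- w * uan
  }
  list(loss = loss, dZ = dZ)
}

#' Training configuration for the embedder
#'
#' @param batch_size triplets per optimization step.
#' @param learning_rate Adam learning rate.
#' @param margin triplet margin.
#' @param early_stopping_patience epochs without validation improvement
#'   before stopping.
#' @param max_epochs hard epoch cap.
#' @param validation_fraction fraction of training triplets held out for
#'   early stopping.
#' @param rng_seed master seed (shuffling, ablation, validation split).
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 1e-3,
                         margin = 1.0, early_stopping_patience = 25L,
                         max_epochs = 500L, validation_fraction = 0.1,
                         rng_seed = 42L) {
  stopifnot(batch_size >= 1, margin > 0, early_stopping_patience >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, margin = margin,
                 early_stopping_patience = as.integer(early_stopping_patience),
                 max_epochs = as.integer(max_epochs),
                 validation_fraction = validation_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Ablation configuration
#'
#' @param node_drop_prob,edge_drop_prob independent drop probabilities
#'   applied to each training graph.
#' @return an `ablation_config` list.
#' @export
ablation_config <- function(node_drop_prob = 0.01, edge_drop_prob = 0.05) {
  stopifnot(node_drop_prob >= 0, node_drop_prob < 1,
            edge_drop_prob >= 0, edge_drop_prob < 1)
  structure(list(node_drop_prob = node_drop_prob,
                 edge_drop_prob = edge_drop_prob),
            class = "ablation_config")
}

.adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the embedding network with the triplet margin loss
#'
#' One shared-parameter network embeds anchor, positive and negative of each
#' triplet; the mean batch triplet margin loss is minimized by Adam.
#' Training stops when the validation loss has not improved for
#' `early_stopping_patience` epochs (or at `max_epochs`); the best-validation
#' parameters are kept. All randomness (validation split, shuffling,
#' ablation) derives from the configured seed.
#'
#' @param triplets data.frame with `anchor`, `positive`, `negative` SMILES
#'   columns (as produced by [sample_triplets()]).
#' @param cfg a [train_config()].
#' @param ablation an [ablation_config()].
#' @param model optionally, a pre-initialized `mpnn_model` to continue from.
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained `mpnn_model`) and `log` (data.frame of
#'   per-epoch train/validation losses; attribute `config` records all
#'   hyperparameters).
#' @export
train_embedder <- function(triplets, cfg = train_config(),
                           ablation = ablation_config(),
                           model = NULL, verbose = FALSE) {
  if (nrow(triplets) == 0) stop("empty triplet stream")
  smiles <- unique(c(triplets$anchor, triplets$positive, triplets$negative))
  graphs <- featurize(smiles)
  names(graphs) <- smiles
  if (is.null(model)) model <- mpnn_init(rng_seed = cfg$rng_seed)
  set.seed(cfg$rng_seed)
  n <- nrow(triplets)
  n_val <- max(1L, round(n * cfg$validation_fraction))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) stop("no training triplets left after validation split")
  val_batch <- .batch_graphs(c(graphs[triplets$anchor[val_idx]],
                               graphs[triplets$positive[val_idx]],
                               graphs[triplets$negative[val_idx]]))
  state <- .adam_state(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(tr_idx)
    nb <- ceiling(length(ord) / cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      rows <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                     length(ord))]
      nt <- length(rows)
      gl <- c(graphs[triplets$anchor[rows]],
              graphs[triplets$positive[rows]],
              graphs[triplets$negative[rows]])
      if (ablation$node_drop_prob > 0 || ablation$edge_drop_prob > 0) {
        gl <- lapply(gl, ablate, node_drop_prob = ablation$node_drop_prob,
                     edge_drop_prob = ablation$edge_drop_prob)
      }
      batch <- .batch_graphs(gl)
      fw <- .mpnn_forward(model, batch)
      lg <- .triplet_loss_grad(fw$Z, nt, cfg$margin)
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", epoch, ", batch ", b)
      }
      ep_loss <- ep_loss + lg$loss * nt
      grads <- .mpnn_backward(model, fw$cache, lg$dZ)
      upd <- .adam_step(model$params, grads, state, cfg$learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    ep_loss <- ep_loss / length(ord)
    vz <- .mpnn_forward(model, val_batch)$Z
    vl <- .triplet_loss_grad(vz, n_val, cfg$margin)$loss
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss,
                                 val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, ep_loss, vl))
    }
    if (vl < best$loss - 1e-9) {
      best <- list(loss = vl, params = model$params, epoch = epoch)
    } else if (epoch - best$epoch >= cfg$early_stopping_patience) {
      break
    }
  }
  model$params <- best$params
  attr(log, "config") <- list(train = unclass(cfg), ablation = unclass(ablation),
                              architecture = model$config,
                              best_epoch = best$epoch)
  list(model = model, log = log)
}

#' Save / load an embedding model as JSON
#'
#' @param model an `mpnn_model`.
#' @param path file path.
#' @return `load_model` returns the restored `mpnn_model`.
#' @export
save_model <- function(model, path) {
  obj <- list(config = model$config,
              params = lapply(model$params, function(p) {
                if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
                else list(dim = NULL, data = as.numeric(p))
              }))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim) == 2) {
      matrix(p$data, p$dim[1], p$dim[2])
    } else as.numeric(p$data)
  })
  cfg <- obj$config
  structure(list(params = params,
                 config = lapply(cfg, function(x) x)),
            class = "mpnn_model")
}
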