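#' Configuration of the structure-conditioned autoregressive model
#'
#' A compact generative model over alignment columns conditioned on a
#' k-nearest-neighbor contact graph. Each column carries a learned absolute
#' positional encoding; each graph edge carries Gaussian radial-basis
#' activations of the inter-nucleotide distance (16 functions spanning
#' 0-20 Angstroms by default) concatenated with a sinusoidal relative
#' position encoding. Columns are predicted autoregressively over the
#' 6-symbol alphabet \{A,U,C,G,-,X\}; sequence information flows only along
#' causally admissible edges (j < i). Training uses label smoothing and
#' edge dropout.
#'
#' @param k neighbors per node in the contact graph.
#' @param rbf_count number of radial basis functions.
#' @param rbf_span numeric length-2 span of the RBF centers, Angstroms.
#' @param abs_pos_features width of the learned absolute positional encoding.
#' @param relpos_features width of the sinusoidal relative position encoding
#'   (even).
#' @param dropout edge dropout rate during training.
#' @param label_smoothing label smoothing rate for the training loss.
#' @param alphabet output symbols; gap is a predictable symbol.
#' @return a `gnn_config` list.
#' @export
gnn_config <- function(k = 50, rbf_count = 16, rbf_span = c(0, 20),
                       abs_pos_features = 16, relpos_features = 16,
                       dropout = 0.10, label_smoothing = 0.10,
                       alphabet = c("A", "U", "C", "G", "-", "X")) {
  stopifnot(k >= 0, rbf_count >= 1, length(rbf_span) == 2,
            rbf_span[2] > rbf_span[1], relpos_features %% 2 == 0,
            dropout >= 0, dropout < 1, label_smoothing >= 0,
            label_smoothing < 1)
  structure(list(k = as.integer(k), rbf_count = as.integer(rbf_count),
                 rbf_span = rbf_span,
                 abs_pos_features = as.integer(abs_pos_features),
                 relpos_features = as.integer(relpos_features),
                 dropout = dropout, label_smoothing = label_smoothing,
                 alphabet = alphabet),
            class = "gnn_config")
}

rbf_centers <- function(cfg) {
  seq(cfg$rbf_span[1], cfg$rbf_span[2], length.out = cfg$rbf_count)
}

rbf_activations <- function(d, cfg) {
  centers <- rbf_centers(cfg)
  width <- diff(centers[1:2]) # width = center spacing
  exp(-outer(d, centers, "-")^2 / (2 * width^2))
}

relpos_encoding <- function(delta, n_feat) {
  half <- n_feat / 2
  freqs <- 10000^(-(seq_len(half) - 1) / half)
  ang <- outer(delta, freqs)
  cbind(sin(ang), cos(ang))
}

#' Graph feature bundle from a distance matrix
#'
#' Selects the k-nearest-neighbor edges and attaches per-edge features:
#' Gaussian RBF activations of the edge distance concatenated with the
#' sinusoidal encoding of the index offset j - i. Masked positions are
#' excluded from neighbor selection.
#'
#' @param dm a `distance_matrix` (or square matrix, Angstroms).
#' @param cfg a [gnn_config()].
#' @return list with `edges` (tibble i, j, distance), `features` (edge by
#'   feature matrix, RBF then relative position) and `n_nodes`.
#' @export
build_graph_features <- function(dm, cfg = gnn_config()) {
  dm <- as_distance_matrix(dm)
  n <- nrow(dm$D)
  if (cfg$k == 0) {
    edges <- tibble(i = integer(), j = integer(), distance = double())
    return(list(edges = edges,
                features = matrix(0, 0, cfg$rbf_count + cfg$relpos_features),
                n_nodes = n))
  }
  cm <- contact_map(dm, "knn", k = cfg$k)
  idx <- which(cm$M == 1, arr.ind = TRUE)
  edges <- tibble(i = idx[, 1], j = idx[, 2],
                  distance = dm$D[idx])
  feats <- cbind(rbf_activations(edges$distance, cfg),
                 relpos_encoding(edges$j - edges$i, cfg$relpos_features))
  list(edges = edges, features = feats, n_nodes = n)
}

#' Initialize a structure-conditioned autoregressive model
#'
#' @param cfg a [gnn_config()].
#' @param dm a `distance_matrix` over the family's (projected) columns, or a
#'   pre-built [build_graph_features()] bundle.
#' @param rng_seed integer seed for parameter initialization.
#' @return an object of class `rna_gnn`.
#' @export
init_rna_gnn <- function(cfg, dm, rng_seed = 0) {
  graph <- if (is.list(dm) && !inherits(dm, "distance_matrix") &&
               all(c("edges", "features", "n_nodes") %in% names(dm))) {
    dm
  } else {
    build_graph_features(dm, cfg)
  }
  L <- graph$n_nodes
  S <- length(cfg$alphabet)
  p <- cfg$abs_pos_features
  fe <- ncol(graph$features)
  causal <- graph$edges$j < graph$edges$i
  params <- withr::with_seed(rng_seed, list(
    pos = matrix(rnorm(L * p, sd = 0.1), L, p),
    w_bias = matrix(rnorm(p * S, sd = 0.1), p, S),
    w_gate = rnorm(fe, sd = 0.1),
    coupling = matrix(0, S, S)))
  structure(list(cfg = cfg, n_columns = L,
                 edges = graph$edges[causal, , drop = FALSE],
                 edge_features = graph$features[causal, , drop = FALSE],
                 all_edges = graph$edges,
                 params = params,
                 meta = list(checkpoint_id = rlang::hash(params),
                             parent_id = NULL)),
            class = "rna_gnn")
}

#' @export
print.rna_gnn <- function(x, ...) {
  cat(sprintf(
    "<rna_gnn> %d columns, %d causal edges (k = %d), alphabet {%s}\n",
    x$n_columns, nrow(x$edges), x$cfg$k, paste(x$cfg$alphabet, collapse = ",")))
  invisible(x)
}

# rows of symbols -> integer matrix over the model alphabet
gnn_encode_rows <- function(model, rows) {
  if (inherits(rows, "aligned_family")) rows <- unname(rows$rows)
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  if (ncol(m) != model$n_columns) {
    abort(sprintf("family width %d does not match the graph size %d",
                  ncol(m), model$n_columns))
  }
  m[m == "N"] <- "X"
  im <- matrix(match(m, model$cfg$alphabet), nrow(m), ncol(m))
  if (anyNA(im)) abort("symbols outside the model alphabet")
  im
}

# gate vector (one scalar per causal edge), optionally with edge dropout
gnn_gates <- function(model, dropout_mask = NULL) {
  g <- as.vector(model$edge_features %*% model$params$w_gate)
  if (!is.null(dropout_mask)) g <- g * dropout_mask
  g
}

# forward: logits array R x L x S; caches for backward
gnn_forward <- function(model, sym, dropout_mask = NULL) {
  p <- model$params
  S <- length(model$cfg$alphabet)
  R <- nrow(sym); L <- model$n_columns
  g <- gnn_gates(model, dropout_mask)
  Gs <- Matrix::sparseMatrix(i = model$edges$j, j = model$edges$i,
                             x = g, dims = c(L, L))
  bias <- p$pos %*% p$w_bias # L x S
  logits <- array(0, c(R, L, S))
  Y <- vector("list", S)
  for (c0 in seq_len(S)) {
    Yc <- matrix(p$coupling[sym, c0], R, L)
    Y[[c0]] <- Yc
    logits[, , c0] <- as.matrix(Yc %*% Gs) +
      matrix(bias[, c0], R, L, byrow = TRUE)
  }
  list(logits = logits, Y = Y, Gs = Gs, g = g)
}

# slice-wise softmax over the class dimension of an R x L x S logit array
softmax3 <- function(a) {
  S <- dim(a)[3]
  mx <- a[, , 1]
  for (c0 in seq_len(S)[-1]) mx <- pmax(mx, a[, , c0])
  Z <- 0
  for (c0 in seq_len(S)) { a[, , c0] <- exp(a[, , c0] - mx); Z <- Z + a[, , c0] }
  for (c0 in seq_len(S)) a[, , c0] <- a[, , c0] / Z
  a
}

true_index3 <- function(sym) {
  R <- nrow(sym); L <- ncol(sym)
  cbind(rep(seq_len(R), L), rep(seq_len(L), each = R), as.vector(sym))
}

gnn_loss_grads <- function(model, sym, fw, label_smoothing,
                           dropout_mask = NULL) {
  cfg <- model$cfg; p <- model$params
  S <- length(cfg$alphabet)
  R <- nrow(sym); L <- model$n_columns
  probs <- softmax3(fw$logits)
  n <- R * L
  lp_true <- log(probs[true_index3(sym)])
  nll <- -mean(lp_true)
  eps <- label_smoothing
  dlog <- probs
  # smoothed target: (1-eps) one-hot + eps/S
  dlog <- dlog - eps / S
  ti <- true_index3(sym)
  dlog[ti] <- dlog[ti] - (1 - eps)
  dlog <- dlog / n
  dB <- apply(dlog, c(2, 3), sum) # L x S
  dpos <- dB %*% t(p$w_bias)
  dw_bias <- crossprod(p$pos, dB)
  Gt <- Matrix::t(fw$Gs)
  dcoupling <- matrix(0, S, S)
  dGmat <- matrix(0, L, L)
  for (c0 in seq_len(S)) {
    dZc <- dlog[, , c0]
    dYc <- as.matrix(dZc %*% Gt)
    acc <- rowsum(as.vector(dYc), group = as.vector(sym))
    dcoupling[as.integer(rownames(acc)), c0] <- acc
    dGmat <- dGmat + crossprod(fw$Y[[c0]], dZc)
  }
  dg <- dGmat[cbind(model$edges$j, model$edges$i)]
  if (!is.null(dropout_mask)) dg <- dg * dropout_mask
  dw_gate <- as.vector(crossprod(model$edge_features, dg))
  list(nll = nll,
       grads = list(pos = dpos, w_bias = dw_bias, w_gate = dw_gate,
                    coupling = dcoupling))
}

# mean NLL per column (no label smoothing) for evaluation
gnn_eval_nll <- function(model, sym) {
  fw <- gnn_forward(model, sym)
  probs <- softmax3(fw$logits)
  -mean(log(probs[true_index3(sym)]))
}

#' Train a structure-conditioned autoregressive model
#'
#' Cross-entropy over alignment columns with label smoothing and edge
#' dropout, AdamW updates, periodic validation (plain cross-entropy) and
#' early stopping; the best-validation checkpoint is returned.
#'
#' @param model an [init_rna_gnn()] model.
#' @param train_rows,val_rows aligned rows: an [aligned_family()] or a
#'   character vector of equal-width strings over the model alphabet.
#' @param cfg a [train_config()].
#' @param quiet suppress progress messages?
#' @return list with `model` and `report` (iteration, train_nll, val_nll,
#'   perplexity).
#' @export
train_gnn <- function(model, train_rows, val_rows, cfg = train_config(),
                      quiet = TRUE) {
  sym_tr <- gnn_encode_rows(model, train_rows)
  sym_va <- gnn_encode_rows(model, val_rows)
  if (nrow(sym_tr) == 0) abort("empty training set")
  params <- model$params
  state <- adamw_init(params)
  best <- list(nll = Inf, params = params)
  since_best <- 0L; rows <- list(); run_loss <- c()
  n_edges <- nrow(model$edges)
  withr::with_seed(cfg$rng_seed, {
    iter <- 0L
    while (iter < cfg$max_iters) {
      iter <- iter + 1L
      pick <- sample.int(nrow(sym_tr), min(cfg$batch_size, nrow(sym_tr)))
      model$params <- params
      mask <- if (model$cfg$dropout > 0 && n_edges > 0) {
        (runif(n_edges) >= model$cfg$dropout) / (1 - model$cfg$dropout)
      } else NULL
      fw <- gnn_forward(model, sym_tr[pick, , drop = FALSE], mask)
      bk <- gnn_loss_grads(model, sym_tr[pick, , drop = FALSE], fw,
                           model$cfg$label_smoothing, mask)
      grads <- clip_global_norm(bk$grads, cfg$grad_clip)
      upd <- adamw_step(params, grads, state, lr = lr_at(iter, cfg),
                        beta1 = cfg$beta1, beta2 = cfg$beta2,
                        weight_decay = cfg$weight_decay)
      params <- upd$params; state <- upd$state
      run_loss <- c(run_loss, bk$nll)
      if (iter %% cfg$eval_interval == 0 || iter == cfg$max_iters) {
        model$params <- params
        vnll <- gnn_eval_nll(model, sym_va)
        rows[[length(rows) + 1L]] <- tibble(
          iteration = iter, train_nll = mean(run_loss), val_nll = vnll,
          perplexity = exp(vnll))
        run_loss <- c()
        if (!quiet) message(sprintf("iter %d: val ppl %.3f", iter, exp(vnll)))
        if (vnll < best$nll - 1e-5) {
          best <- list(nll = vnll, params = params); since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$early_stop_patience) break
        }
      }
    }
  })
  model$params <- best$params
  model$meta$checkpoint_id <- rlang::hash(best$params)
  report <- dplyr::bind_rows(rows)
  class(report) <- c("lm_train_report", class(report))
  list(model = model, report = report)
}

#' Sample aligned rows from a structure-conditioned model
#'
#' Columns are generated left to right; each column's logits combine the
#' learned positional bias with gated couplings from already-generated
#' neighbor columns. The first `length(seed_columns)` columns are fixed to
#' the seed.
#'
#' @param model a trained `rna_gnn`.
#' @param n_sequences rows to sample.
#' @param seed_columns character vector (or string) of seed symbols for the
#'   leading columns; may be empty.
#' @param temperature logit divisor > 0.
#' @param rng_seed integer seed.
#' @return tibble with `id` and aligned `seq` columns (width = graph size).
#' @export
generate_gnn <- function(model, n_sequences, seed_columns = character(),
                         temperature = 0.5, rng_seed = 0) {
  if (temperature <= 0) abort("temperature must be > 0")
  if (length(seed_columns) == 1 && nchar(seed_columns[1]) > 1) {
    seed_columns <- seq_chars(seed_columns[1])
  }
  s0 <- length(seed_columns)
  L <- model$n_columns; S <- length(model$cfg$alphabet)
  stopifnot(s0 <= L)
  p <- model$params
  bias <- p$pos %*% p$w_bias
  g <- gnn_gates(model)
  edge_by_target <- split(seq_len(nrow(model$edges)), model$edges$i)
  sym <- matrix(0L, n_sequences, L)
  if (s0 > 0) {
    seed_idx <- match(seed_columns, model$cfg$alphabet)
    if (anyNA(seed_idx)) abort("seed symbols outside the model alphabet")
    sym[, seq_len(s0)] <- matrix(seed_idx, n_sequences, s0, byrow = TRUE)
  }
  withr::with_seed(rng_seed, {
    for (i in seq_len(L)) {
      if (i <= s0) next
      lg <- matrix(bias[i, ], n_sequences, S, byrow = TRUE)
      for (e in edge_by_target[[as.character(i)]] %||% integer()) {
        j <- model$edges$j[e]
        lg <- lg + g[e] * p$coupling[sym[, j], , drop = FALSE]
      }
      lg <- lg / temperature
      lg <- lg - matrixStats::rowMaxs(lg)
      pr <- exp(lg); pr <- pr / rowSums(pr)
      sym[, i] <- vapply(seq_len(n_sequences), function(r) {
        sample.int(S, 1L, prob = pr[r, ])
      }, 0L)
    }
  })
  seqs <- apply(sym, 1, function(z) {
    paste(model$cfg$alphabet[z], collapse = "")
  })
  tibble(id = sprintf("gnn%04d", seq_len(n_sequences)), seq = seqs)
}

#' Log-probability of aligned rows under a structure-conditioned model
#'
#' Teacher-forced sum of per-column log-probabilities (all columns,
#' gap included as a symbol). Deterministic; no dropout.
#'
#' @param model a trained `rna_gnn`.
#' @param rows aligned rows (strings of the graph width).
#' @return numeric vector, one natural-log probability per row.
#' @export
gnn_log_probability <- function(model, rows) {
  sym <- gnn_encode_rows(model, rows)
  fw <- gnn_forward(model, sym)
  probs <- softmax3(fw$logits)
  rowSums(matrix(log(probs[true_index3(sym)]), nrow(sym), model$n_columns))
}

#' One-row summary of a fitted structure-conditioned model
#' @param x an `rna_gnn`.
#' @param ... unused.
#' @return tibble with graph and parameter-count columns.
#' @export
glance.rna_gnn <- function(x, ...) {
  tibble(n_columns = x$n_columns, k = x$cfg$k,
         n_causal_edges = nrow(x$edges),
         n_parameters = sum(vapply(x$params, length, 0L)),
         checkpoint_id = x$meta$checkpoint_id)
}
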