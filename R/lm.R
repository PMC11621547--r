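#' Configuration of the decoder-only RNA language model
#'
#' A compact GPT-style causal transformer over n-gram tokens, with rotary
#' position encoding applied inside every attention layer (`rope_mode =
#' "per_layer"`, the default) or in the first layer only (`"overall"`), and
#' root-mean-square normalization in the transformer blocks. The full-scale
#' recipe uses a 384-token context, 18 layers, 6 heads and width 300; tests
#' and examples use much smaller settings.
#'
#' @param context_window maximum tokens attended to (>= 2).
#' @param n_layers number of transformer blocks.
#' @param n_heads attention heads; must divide `d_embed`, and the per-head
#'   width must be even for the rotary encoding.
#' @param d_embed embedding width.
#' @param dropout dropout rate on block outputs during training.
#' @param rope_mode `"per_layer"` or `"overall"`.
#' @return an `lm_config` list.
#' @export
lm_config <- function(context_window = 384, n_layers = 18, n_heads = 6,
                      d_embed = 300, dropout = 0,
                      rope_mode = c("per_layer", "overall")) {
  rope_mode <- match.arg(rope_mode)
  if (context_window < 2) abort("context_window must be at least 2")
  if (d_embed %% n_heads != 0) {
    abort(sprintf("d_embed (%d) must be divisible by n_heads (%d)",
                  d_embed, n_heads))
  }
  if ((d_embed / n_heads) %% 2 != 0) {
    abort("per-head width must be even for rotary position encoding")
  }
  structure(list(context_window = as.integer(context_window),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 d_embed = as.integer(d_embed),
                 dropout = dropout, rope_mode = rope_mode, norm = "rms"),
            class = "lm_config")
}

#' Initialize an RNA language model
#'
#' Parameters are drawn N(0, 0.02) (residual projections scaled by
#' 1/sqrt(2 * n_layers)); the output head is weight-tied to the token
#' embedding. Initialization is deterministic under `rng_seed`.
#'
#' @param cfg an [lm_config()].
#' @param spec a [build_vocab()] tokenizer; the model's vocabulary.
#' @param rng_seed integer seed.
#' @return an object of class `rna_lm`.
#' @export
init_rna_lm <- function(cfg, spec, rng_seed = 0) {
  stopifnot(inherits(cfg, "lm_config"), inherits(spec, "tok_spec"))
  d <- cfg$d_embed; V <- spec$vocab_size; L <- cfg$n_layers
  params <- withr::with_seed(rng_seed, {
    p <- list(wte = matrix(rnorm(V * d, sd = 0.02), V, d))
    res_sd <- 0.02 / sqrt(2 * L)
    for (l in seq_len(L)) {
      p[[paste0("l", l, ".w_qkv")]]  <- matrix(rnorm(d * 3 * d, sd = 0.02), d, 3 * d)
      p[[paste0("l", l, ".w_o")]]    <- matrix(rnorm(d * d, sd = res_sd), d, d)
      p[[paste0("l", l, ".g1")]]     <- rep(1, d)
      p[[paste0("l", l, ".w_fc")]]   <- matrix(rnorm(d * 4 * d, sd = 0.02), d, 4 * d)
      p[[paste0("l", l, ".w_proj")]] <- matrix(rnorm(4 * d * d, sd = res_sd), 4 * d, d)
      p[[paste0("l", l, ".g2")]]     <- rep(1, d)
    }
    p$gf <- rep(1, d)
    p
  })
  structure(list(cfg = cfg, spec = spec, params = params,
                 meta = list(checkpoint_id = rlang::hash(params),
                             parent_id = NULL, train_ids = NULL,
                             val_ids = NULL)),
            class = "rna_lm")
}

#' @export
print.rna_lm <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<rna_lm> %d layers, %d heads, width %d, context %d, vocab %d (%s tokens); %s parameters\n",
    x$cfg$n_layers, x$cfg$n_heads, x$cfg$d_embed, x$cfg$context_window,
    x$spec$vocab_size, paste0(x$spec$n, "-gram"), format(n_par, big.mark = ",")))
  invisible(x)
}

## ---- internals: forward / backward ----------------------------------------

rms_eps <- 1e-6

rope_tables <- function(T, head_dim) {
  half <- head_dim / 2
  freqs <- 10000^(-(2 * (seq_len(half) - 1)) / head_dim)
  ang <- outer(seq_len(T) - 1, freqs) # T x half
  list(cos = cos(ang), sin = sin(ang))
}

rope_apply <- function(x, tab) { # x: T x head_dim
  half <- ncol(x) / 2
  od <- seq(1, ncol(x), by = 2); ev <- od + 1
  y <- x
  y[, od] <- x[, od] * tab$cos - x[, ev] * tab$sin
  y[, ev] <- x[, od] * tab$sin + x[, ev] * tab$cos
  y
}

rope_unapply <- function(dy, tab) { # gradient through the rotation
  half <- ncol(dy) / 2
  od <- seq(1, ncol(dy), by = 2); ev <- od + 1
  dx <- dy
  dx[, od] <- dy[, od] * tab$cos + dy[, ev] * tab$sin
  dx[, ev] <- -dy[, od] * tab$sin + dy[, ev] * tab$cos
  dx
}

rmsnorm_fwd <- function(x, g) {
  r <- sqrt(rowMeans(x * x) + rms_eps)
  xhat <- x / r
  list(y = sweep(xhat, 2, g, "*"), xhat = xhat, r = r)
}

rmsnorm_bwd <- function(dy, x, g, cache) {
  gdy <- sweep(dy, 2, g, "*")
  dg <- colSums(dy * cache$xhat)
  d <- ncol(x)
  dx <- gdy / cache$r - x * (rowSums(gdy * x) / (d * cache$r^3))
  list(dx = dx, dg = dg)
}

# GELU in its sigmoid approximation x * sigmoid(1.702 x): one exp per call
# instead of the Gaussian cdf/pdf pair, at negligible accuracy cost
gelu_fwd <- function(x) x / (1 + exp(-1.702 * x))
gelu_bwd <- function(dy, x) {
  s <- 1 / (1 + exp(-1.702 * x))
  dy * (s + 1.702 * x * s * (1 - s))
}

# Forward pass over a batch. ids, targets: B x T 0-based integer matrices;
# targets may be NULL. Flattened row index r = (b-1)*T + t.
# want: "loss" (training; returns caches), "logprobs" (per-position target
# log-probabilities), "last_logits" (logits at the final position of each row).
lm_forward <- function(model, ids, targets = NULL, want = "loss",
                       dropout_rng = NULL) {
  cfg <- model$cfg; p <- model$params
  B <- nrow(ids); T <- ncol(ids)
  if (T > cfg$context_window) abort("batch longer than the context window")
  d <- cfg$d_embed; H <- cfg$n_heads; hd <- d / H
  flat <- as.vector(t(ids)) # b-major
  X <- p$wte[flat + 1L, , drop = FALSE]
  rope <- rope_tables(T, hd)
  neg_mask <- matrix(0, T, T)
  neg_mask[upper.tri(neg_mask)] <- -Inf

  caches <- vector("list", cfg$n_layers)
  idx_b <- function(b) ((b - 1L) * T + 1L):(b * T)

  for (l in seq_len(cfg$n_layers)) {
    use_rope <- cfg$rope_mode == "per_layer" || l == 1L
    nm <- function(s) p[[paste0("l", l, ".", s)]]
    n1 <- rmsnorm_fwd(X, nm("g1"))
    qkv <- n1$y %*% nm("w_qkv")
    O <- matrix(0, B * T, d)
    att <- vector("list", B)
    for (b in seq_len(B)) {
      rb <- idx_b(b)
      attb <- vector("list", H)
      for (h in seq_len(H)) {
        ch <- ((h - 1L) * hd + 1L):(h * hd)
        q <- qkv[rb, ch, drop = FALSE]
        k <- qkv[rb, d + ch, drop = FALSE]
        v <- qkv[rb, 2L * d + ch, drop = FALSE]
        if (use_rope) { q <- rope_apply(q, rope); k <- rope_apply(k, rope) }
        s <- tcrossprod(q, k) / sqrt(hd) + neg_mask
        s <- s - matrixStats::rowMaxs(s)
        e <- exp(s)
        P <- e / rowSums(e)
        O[rb, ch] <- P %*% v
        attb[[h]] <- list(P = P, q = q, k = k, v = v)
      }
      att[[b]] <- attb
    }
    att_out <- O %*% nm("w_o")
    X1 <- X + att_out
    n2 <- rmsnorm_fwd(X1, nm("g2"))
    fc_in <- n2$y %*% nm("w_fc")
    fc_act <- gelu_fwd(fc_in)
    mlp_out <- fc_act %*% nm("w_proj")
    X2 <- X1 + mlp_out
    caches[[l]] <- list(X = X, n1 = n1, qkv = qkv, att = att, O = O,
                        X1 = X1, n2 = n2, fc_in = fc_in, fc_act = fc_act,
                        use_rope = use_rope)
    X <- X2
  }

  nf <- rmsnorm_fwd(X, p$gf)
  if (want == "last_logits") {
    last_rows <- seq_len(B) * T
    return(nf$y[last_rows, , drop = FALSE] %*% t(p$wte))
  }
  logits <- nf$y %*% t(p$wte)
  mx <- matrixStats::rowMaxs(logits)
  lse <- mx + log(rowSums(exp(logits - mx)))
  tflat <- as.vector(t(targets))
  valid <- tflat != model$spec$pad_id & !is.na(tflat)
  logp_t <- logits[cbind(seq_along(tflat), tflat + 1L)] - lse
  if (want == "logprobs") {
    lp <- matrix(ifelse(valid, logp_t, 0), B, T, byrow = TRUE)
    return(list(logprobs = lp, valid = matrix(valid, B, T, byrow = TRUE)))
  }
  n_valid <- sum(valid)
  loss <- -sum(logp_t[valid]) / n_valid
  list(loss = loss, n_valid = n_valid,
       state = list(caches = caches, nf = nf, logits = logits, lse = lse,
                    tflat = tflat, valid = valid, flat = flat,
                    rope = rope, B = B, T = T))
}

lm_backward <- function(model, st) {
  cfg <- model$cfg; p <- model$params
  B <- st$B; T <- st$T
  d <- cfg$d_embed; H <- cfg$n_heads; hd <- d / H
  caches <- st$caches
  grads <- vector("list", length(p))
  names(grads) <- names(p)

  probs <- exp(st$logits - st$lse)
  dlogits <- probs
  dlogits[cbind(seq_along(st$tflat), st$tflat + 1L)] <-
    dlogits[cbind(seq_along(st$tflat), st$tflat + 1L)] - 1
  dlogits[!st$valid, ] <- 0
  dlogits <- dlogits / sum(st$valid)

  grads$wte <- crossprod(dlogits, st$nf$y) # head side of the tied embedding
  dF <- dlogits %*% p$wte
  # reconstruct the last block's output (input of the final rmsnorm)
  cl <- caches[[cfg$n_layers]]
  X_final <- cl$X1 + cl$fc_act %*% p[[paste0("l", cfg$n_layers, ".w_proj")]]
  rn <- rmsnorm_bwd(dF, X_final, p$gf, st$nf)
  grads$gf <- rn$dg
  dX <- rn$dx

  idx_b <- function(b) ((b - 1L) * T + 1L):(b * T)
  for (l in rev(seq_len(cfg$n_layers))) {
    ca <- caches[[l]]
    nm <- function(s) p[[paste0("l", l, ".", s)]]
    gn <- function(s) paste0("l", l, ".", s)
    # mlp
    dmlp_out <- dX
    grads[[gn("w_proj")]] <- crossprod(ca$fc_act, dmlp_out)
    dfc_act <- dmlp_out %*% t(nm("w_proj"))
    dfc_in <- gelu_bwd(dfc_act, ca$fc_in)
    grads[[gn("w_fc")]] <- crossprod(ca$n2$y, dfc_in)
    dn2y <- dfc_in %*% t(nm("w_fc"))
    rn2 <- rmsnorm_bwd(dn2y, ca$X1, nm("g2"), ca$n2)
    grads[[gn("g2")]] <- rn2$dg
    dX1 <- dX + rn2$dx
    # attention
    datt_out <- dX1
    grads[[gn("w_o")]] <- crossprod(ca$O, datt_out)
    dO <- datt_out %*% t(nm("w_o"))
    dqkv <- matrix(0, B * T, 3 * d)
    for (b in seq_len(B)) {
      rb <- idx_b(b)
      for (h in seq_len(H)) {
        ch <- ((h - 1L) * hd + 1L):(h * hd)
        a <- ca$att[[b]][[h]]
        dOb <- dO[rb, ch, drop = FALSE]
        dP <- tcrossprod(dOb, a$v)
        dv <- crossprod(a$P, dOb)
        dS <- a$P * (dP - rowSums(dP * a$P))
        dq <- (dS %*% a$k) / sqrt(hd)
        dk <- (crossprod(dS, a$q)) / sqrt(hd)
        if (ca$use_rope) {
          dq <- rope_unapply(dq, st$rope)
          dk <- rope_unapply(dk, st$rope)
        }
        dqkv[rb, ch] <- dq
        dqkv[rb, d + ch] <- dk
        dqkv[rb, 2L * d + ch] <- dv
      }
    }
    grads[[gn("w_qkv")]] <- crossprod(ca$n1$y, dqkv)
    dn1y <- dqkv %*% t(nm("w_qkv"))
    rn1 <- rmsnorm_bwd(dn1y, ca$X, nm("g1"), ca$n1)
    grads[[gn("g1")]] <- rn1$dg
    dX <- dX1 + rn1$dx
  }
  # embedding side of the tied weight
  agg <- rowsum(dX, group = st$flat)
  rows <- as.integer(rownames(agg)) + 1L
  grads$wte[rows, ] <- grads$wte[rows, ] + agg
  grads
}

## ---- batching and evaluation ----------------------------------------------

# sample a training batch: left-aligned, PAD-tailed, random crops for
# sequences longer than the window
make_batch <- function(tokens, batch_size, W, pad_id) {
  pick <- sample.int(length(tokens), batch_size, replace = TRUE)
  ids <- matrix(pad_id, batch_size, W + 1L)
  for (r in seq_len(batch_size)) {
    tk <- tokens[[pick[r]]]
    if (length(tk) <= W + 1L) {
      ids[r, seq_along(tk)] <- tk
    } else {
      s <- sample.int(length(tk) - W, 1L)
      ids[r, ] <- tk[s:(s + W)]
    }
  }
  list(inputs = ids[, 1:W, drop = FALSE],
       targets = ids[, 2:(W + 1L), drop = FALSE])
}

# split token vectors into windows of at most W+1 tokens with stride W, so
# every target token is predicted exactly once
chunk_tokens <- function(tokens, W) {
  chunks <- list(); owner <- integer()
  for (i in seq_along(tokens)) {
    tk <- tokens[[i]]
    s <- 1L
    while (s < length(tk)) {
      e <- min(s + W, length(tk))
      chunks[[length(chunks) + 1L]] <- tk[s:e]
      owner <- c(owner, i)
      s <- e # windows overlap by one token: last input becomes next first
    }
  }
  list(chunks = chunks, owner = owner)
}

# mean NLL per non-PAD token over a token-vector list (teacher forced)
evaluate_nll <- function(model, tokens, batch_size = 32) {
  W <- model$cfg$context_window
  pad <- model$spec$pad_id
  cs <- chunk_tokens(tokens, W)
  total <- 0; count <- 0L
  i <- 1L
  while (i <= length(cs$chunks)) {
    grp <- cs$chunks[i:min(i + batch_size - 1L, length(cs$chunks))]
    Tm <- max(vapply(grp, length, 0L))
    ids <- matrix(pad, length(grp), Tm)
    for (r in seq_along(grp)) ids[r, seq_along(grp[[r]])] <- grp[[r]]
    fw <- lm_forward(model, ids[, -ncol(ids), drop = FALSE],
                     ids[, -1, drop = FALSE], want = "logprobs")
    total <- total - sum(fw$logprobs[fw$valid])
    count <- count + sum(fw$valid)
    i <- i + batch_size
  }
  total / count
}

## ---- training ---------------------------------------------------------------

#' Train an RNA language model
#'
#' Next-token cross-entropy on non-PAD positions with AdamW, a decaying
#' learning rate, periodic validation evaluation and early stopping; the
#' best-validation checkpoint is returned. Batches are left-aligned and
#' PAD-tailed; sequences longer than the context window are trained on
#' random crops and evaluated on non-overlapping windows.
#'
#' @param model an [init_rna_lm()] model.
#' @param train_tokens,val_tokens named lists of encoded token vectors
#'   ([encode_dataset()]).
#' @param cfg a [train_config()].
#' @param quiet suppress progress messages?
#' @return list with `model` (best checkpoint) and `report`, a tibble with
#'   one row per evaluation: iteration, train_nll, val_nll, perplexity.
#' @export
train_lm <- function(model, train_tokens, val_tokens, cfg = train_config(),
                     quiet = TRUE) {
  if (length(train_tokens) == 0 || length(val_tokens) == 0) {
    abort("empty token dataset")
  }
  vmax <- max(unlist(train_tokens, use.names = FALSE))
  if (vmax >= model$spec$vocab_size) abort("token ids exceed the model vocabulary")
  W <- model$cfg$context_window
  pad <- model$spec$pad_id
  params <- model$params
  state <- adamw_init(params)
  best <- list(nll = Inf, params = params)
  since_best <- 0L
  rows <- list()
  run_loss <- c()
  withr::with_seed(cfg$rng_seed, {
    iter <- 0L
    while (iter < cfg$max_iters) {
      iter <- iter + 1L
      bt <- make_batch(train_tokens, cfg$batch_size, W, pad)
      model$params <- params
      fw <- lm_forward(model, bt$inputs, bt$targets, want = "loss")
      grads <- lm_backward(model, fw$state)
      grads <- clip_global_norm(grads, cfg$grad_clip)
      upd <- adamw_step(params, grads, state, lr = lr_at(iter, cfg),
                        beta1 = cfg$beta1, beta2 = cfg$beta2,
                        weight_decay = cfg$weight_decay)
      params <- upd$params; state <- upd$state
      run_loss <- c(run_loss, fw$loss)
      if (iter %% cfg$eval_interval == 0 || iter == cfg$max_iters) {
        model$params <- params
        vnll <- evaluate_nll(model, val_tokens)
        rows[[length(rows) + 1L]] <- tibble(
          iteration = iter, train_nll = mean(run_loss), val_nll = vnll,
          perplexity = exp(vnll))
        run_loss <- c()
        if (!quiet) {
          message(sprintf("iter %d: train %.4f val %.4f (ppl %.3f)",
                          iter, rows[[length(rows)]]$train_nll, vnll, exp(vnll)))
        }
        if (vnll < best$nll - 1e-5) {
          best <- list(nll = vnll, params = params)
          since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$early_stop_patience) break
        }
      }
    }
  })
  model$params <- best$params
  model$meta$checkpoint_id <- rlang::hash(best$params)
  model$meta$train_ids <- names(train_tokens)
  model$meta$val_ids <- names(val_tokens)
  report <- dplyr::bind_rows(rows)
  class(report) <- c("lm_train_report", class(report))
  list(model = model, report = report)
}

#' Finetune a trained RNA language model
#'
#' Identical training contract to [train_lm()], started from an existing
#' checkpoint (typically: pretrain on the full family, finetune on the
#' hyperthermophile subset). Provenance (the parent checkpoint id) is
#' recorded, and sequences that belonged to the parent's validation split but
#' appear in the finetuning training set trigger a warning, since the
#' finetuning split should respect the pretraining partition.
#'
#' @inheritParams train_lm
#' @return list with `model` and `report` as in [train_lm()].
#' @export
finetune_lm <- function(model, train_tokens, val_tokens, cfg = train_config(),
                        quiet = TRUE) {
  parent <- model$meta$checkpoint_id
  leaked <- intersect(names(train_tokens), model$meta$val_ids)
  if (length(leaked) > 0) {
    warn(sprintf(
      "%d finetuning training sequence(s) were in the pretraining validation set (e.g. %s)",
      length(leaked), leaked[1]))
  }
  if (cfg$max_iters == 0) {
    rep0 <- tibble(iteration = integer(), train_nll = double(),
                   val_nll = double(), perplexity = double())
    model$meta$parent_id <- parent
    return(list(model = model, report = rep0))
  }
  out <- train_lm(model, train_tokens, val_tokens, cfg, quiet = quiet)
  out$model$meta$parent_id <- parent
  out
}

## ---- model-agnostic scoring and generation --------------------------------

#' Logits of the next token given a batch of prefixes
#'
#' S3 generic used by [sequence_log_probability()] and [generate_sequences()]
#' so that alternative sequence models (e.g. the exact first-order
#' [markov_model()]) share the scoring and sampling code paths.
#'
#' @param model a sequence model.
#' @param ids B x T matrix of 0-based token ids.
#' @param positions `"last"` for next-token logits at the final position,
#'   `"all"` for a list `(logprobs, valid)` of per-position target
#'   log-probabilities (requires `targets`).
#' @param targets B x T matrix of target ids when `positions = "all"`.
#' @return see `positions`.
#' @export
model_logits <- function(model, ids, positions = "last", targets = NULL) {
  UseMethod("model_logits")
}

#' @export
model_logits.rna_lm <- function(model, ids, positions = "last", targets = NULL) {
  if (positions == "last") {
    lm_forward(model, ids, want = "last_logits")
  } else {
    lm_forward(model, ids, targets, want = "logprobs")
  }
}

model_context <- function(model) UseMethod("model_context")
#' @export
model_context.rna_lm <- function(model) model$cfg$context_window
#' @export
model_context.default <- function(model) .Machine$integer.max

model_vocab <- function(model) UseMethod("model_vocab")
#' @export
model_vocab.default <- function(model) model$spec

#' Log-probability of sequences under an autoregressive model
#'
#' Teacher-forced sum of log p(token | prefix) over body and EOS tokens,
#' conditioning from BOS on. Sequences longer than the context window are
#' evaluated on non-overlapping windows (stride = context window, one-token
#' overlap so each token is predicted once); the result then carries
#' attribute `windowed = TRUE`. Deterministic: no dropout is applied.
#'
#' @param model an `rna_lm` (or any model providing [model_logits()]).
#' @param seqs character vector of RNA sequences.
#' @param batch_size sequences scored per forward pass.
#' @return numeric vector of log-probabilities (natural log), one per input.
#' @export
sequence_log_probability <- function(model, seqs, batch_size = 64) {
  spec <- model_vocab(model)
  W <- as.numeric(model_context(model))
  tokens <- lapply(seqs, function(s) encode(s, spec)$ids)
  cs <- chunk_tokens(tokens, min(W, max(vapply(tokens, length, 0L))))
  out <- numeric(length(seqs))
  windowed <- any(vapply(tokens, length, 0L) > W + 1)
  i <- 1L
  while (i <= length(cs$chunks)) {
    take <- i:min(i + batch_size - 1L, length(cs$chunks))
    grp <- cs$chunks[take]
    Tm <- max(vapply(grp, length, 0L))
    ids <- matrix(spec$pad_id, length(grp), Tm)
    for (r in seq_along(grp)) ids[r, seq_along(grp[[r]])] <- grp[[r]]
    fw <- model_logits(model, ids[, -ncol(ids), drop = FALSE],
                       positions = "all",
                       targets = ids[, -1, drop = FALSE])
    contrib <- rowSums(fw$logprobs * fw$valid)
    for (r in seq_along(grp)) {
      out[cs$owner[take[r]]] <- out[cs$owner[take[r]]] + contrib[r]
    }
    i <- i + batch_size
  }
  if (windowed) attr(out, "windowed") <- TRUE
  out
}

#' Generation settings
#'
#' @param seed_prefix nucleotide string seeding every generated sequence
#'   (length >= the tokenizer n-gram size).
#' @param temperature logit divisor T > 0 before softmax sampling; low values
#'   sharpen toward greedy decoding.
#' @param n_sequences number of sequences to sample.
#' @param max_nucleotides stop length (including the seed).
#' @param rng_seed integer seed; generation is bit-reproducible under it.
#' @return a `generation_config` list.
#' @export
generation_config <- function(seed_prefix, temperature = 0.5,
                              n_sequences = 1, max_nucleotides = 500,
                              rng_seed = 0) {
  if (temperature <= 0) abort("temperature must be > 0")
  stopifnot(n_sequences >= 1, max_nucleotides > nchar(seed_prefix))
  structure(list(seed_prefix = seed_prefix, temperature = temperature,
                 n_sequences = as.integer(n_sequences),
                 max_nucleotides = as.integer(max_nucleotides),
                 rng_seed = rng_seed),
            class = "generation_config")
}

# Incremental decoding with per-layer key/value caches. Valid while the
# prefix fits the context window (positions are absolute within it).
# step_fn(pr) -> B-vector of sampled 0-based ids; returns the id matrix.
lm_generate_cached <- function(model, ids0, max_body, step_sampler) {
  cfg <- model$cfg; p <- model$params
  d <- cfg$d_embed; H <- cfg$n_heads; hd <- d / H; L <- cfg$n_layers
  B <- nrow(ids0)
  rope <- rope_tables(cfg$context_window, hd)
  # caches[[l]][[h]]$K / $V: lists over positions of B x hd matrices
  caches <- lapply(seq_len(L), function(l) {
    lapply(seq_len(H), function(h) list(K = list(), V = list()))
  })
  ids <- ids0
  step_forward <- function(tok_ids, t) {
    X <- p$wte[tok_ids + 1L, , drop = FALSE] # B x d
    for (l in seq_len(L)) {
      use_rope <- cfg$rope_mode == "per_layer" || l == 1L
      nm <- function(s) p[[paste0("l", l, ".", s)]]
      n1 <- rmsnorm_fwd(X, nm("g1"))
      qkv <- n1$y %*% nm("w_qkv")
      O <- matrix(0, B, d)
      tab_t <- list(cos = rope$cos[t, , drop = FALSE],
                    sin = rope$sin[t, , drop = FALSE])
      rot1 <- function(x) { # rotate a B x hd block at position t
        od <- seq(1, hd, by = 2); ev <- od + 1
        y <- x
        co <- rep(tab_t$cos, each = B); si <- rep(tab_t$sin, each = B)
        y[, od] <- x[, od] * co - x[, ev] * si
        y[, ev] <- x[, od] * si + x[, ev] * co
        y
      }
      for (h in seq_len(H)) {
        ch <- ((h - 1L) * hd + 1L):(h * hd)
        q <- qkv[, ch, drop = FALSE]
        k <- qkv[, d + ch, drop = FALSE]
        v <- qkv[, 2L * d + ch, drop = FALSE]
        if (use_rope) { q <- rot1(q); k <- rot1(k) }
        caches[[l]][[h]]$K[[t]] <<- k
        caches[[l]][[h]]$V[[t]] <<- v
        Ks <- caches[[l]][[h]]$K; Vs <- caches[[l]][[h]]$V
        sc <- matrix(0, B, t)
        for (tau in seq_len(t)) sc[, tau] <- rowSums(q * Ks[[tau]])
        sc <- sc / sqrt(hd)
        sc <- sc - matrixStats::rowMaxs(sc)
        w <- exp(sc); w <- w / rowSums(w)
        o <- matrix(0, B, hd)
        for (tau in seq_len(t)) o <- o + w[, tau] * Vs[[tau]]
        O[, ch] <- o
      }
      X <- X + O %*% nm("w_o")
      n2 <- rmsnorm_fwd(X, nm("g2"))
      X <- X + gelu_fwd(n2$y %*% nm("w_fc")) %*% nm("w_proj")
    }
    rmsnorm_fwd(X, p$gf)$y %*% t(p$wte)
  }
  # prime the cache on the seed prefix
  lg <- NULL
  for (t in seq_len(ncol(ids0))) lg <- step_forward(ids0[, t], t)
  while ((ncol(ids) - 1L) < max_body) {
    nxt <- step_sampler(lg)
    ids <- cbind(ids, nxt)
    if (attr(nxt, "all_done") %||% FALSE) break
    if (ncol(ids) >= model$cfg$context_window) break
    lg <- step_forward(nxt, ncol(ids))
  }
  ids
}

#' Sample sequences from an autoregressive model
#'
#' Temperature-scaled softmax sampling over the full vocabulary (no top-k or
#' nucleus truncation), seeded with a nucleotide prefix. Sampling stops at
#' EOS or at `max_nucleotides`; when the prefix outgrows the context window
#' the most recent window of tokens conditions the next draw.
#' Overlap-inconsistent adjacent tokens are resolved by the [decode()] policy
#' (first-character reconstruction) and counted per sequence.
#'
#' @param model an `rna_lm` or any model providing [model_logits()].
#' @param gcfg a [generation_config()].
#' @return tibble with columns `id`, `seq`, `n_inconsistent`; every `seq`
#'   begins with the seed prefix.
#' @export
generate_sequences <- function(model, gcfg) {
  stopifnot(inherits(gcfg, "generation_config"))
  spec <- model_vocab(model)
  W <- model_context(model)
  seed_ids <- encode(gcfg$seed_prefix, spec)$ids
  seed_ids <- seed_ids[-length(seed_ids)] # drop EOS; keep BOS + body
  B <- gcfg$n_sequences
  max_body <- gcfg$max_nucleotides - spec$n + 1L
  ids <- matrix(rep(seed_ids, each = B), B, length(seed_ids))
  alive <- rep(TRUE, B)
  banned <- c(spec$bos_id, spec$pad_id) + 1L
  sampler <- function(lg) {
    lg[, banned] <- -Inf
    lg <- lg / gcfg$temperature
    lg <- lg - matrixStats::rowMaxs(lg)
    pr <- exp(lg); pr <- pr / rowSums(pr)
    nxt <- integer(B)
    for (r in seq_len(B)) {
      nxt[r] <- if (alive[r]) {
        sample.int(ncol(pr), 1L, prob = pr[r, ]) - 1L
      } else spec$pad_id
    }
    alive <<- alive & nxt != spec$eos_id
    attr(nxt, "all_done") <- !any(alive)
    nxt
  }
  withr::with_seed(gcfg$rng_seed, {
    if (inherits(model, "rna_lm") && max_body + 1L <= W) {
      # incremental decoding with key/value caches
      ids <- lm_generate_cached(model, ids, max_body, sampler)
    } else {
      while (any(alive) && (ncol(ids) - 1L) < max_body) {
        t0 <- max(1L, ncol(ids) - W + 1L)
        lg <- model_logits(model, ids[, t0:ncol(ids), drop = FALSE],
                           positions = "last")
        ids <- cbind(ids, sampler(lg))
      }
    }
  })
  seqs <- character(B); inc <- integer(B)
  for (r in seq_len(B)) {
    dec <- decode(ids[r, ], spec)
    # the first generated tokens overlap the seed tail; the seed itself is
    # authoritative there, disagreements are already in the count
    seqs[r] <- paste0(gcfg$seed_prefix,
                      substring(dec$seq, nchar(gcfg$seed_prefix) + 1L))
    inc[r] <- dec$inconsistencies
  }
  tibble(id = sprintf("gen%04d", seq_len(B)), seq = seqs,
         n_inconsistent = inc)
}

## ---- broom-style methods ----------------------------------------------------

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy the evaluation trace of a training run
#' @param x an `lm_train_report` (from [train_lm()] or [train_gnn()]).
#' @param ... unused.
#' @return the evaluation tibble.
#' @export
tidy.lm_train_report <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a fitted language model
#' @param x an `rna_lm`.
#' @param ... unused.
#' @return tibble with architecture and checkpoint columns.
#' @export
glance.rna_lm <- function(x, ...) {
  tibble(n_layers = x$cfg$n_layers, n_heads = x$cfg$n_heads,
         d_embed = x$cfg$d_embed, context_window = x$cfg$context_window,
         vocab_size = x$spec$vocab_size, ngram = x$spec$n,
         n_parameters = sum(vapply(x$params, length, 0L)),
         checkpoint_id = x$meta$checkpoint_id,
         parent_id = x$meta$parent_id %||% NA_character_)
}

#' First-order Markov sequence model
#'
#' An exact autoregressive model whose next-token distribution depends only
#' on the current token. Shares the [sequence_log_probability()] and
#' [generate_sequences()] code paths with the transformer and serves as a
#' closed-form reference: its sequence probabilities can be enumerated by
#' hand. A matrix with identical rows is a context-independent (unigram)
#' model, the calibration case in which multi-mutation ddlogP scores are
#' exactly additive.
#'
#' @param spec a [build_vocab()] tokenizer.
#' @param trans V x V row-stochastic matrix of next-token probabilities
#'   (rows/columns in vocabulary id order, including specials).
#' @return an object of class `markov_lm`.
#' @export
markov_model <- function(spec, trans) {
  stopifnot(nrow(trans) == spec$vocab_size, ncol(trans) == spec$vocab_size)
  if (any(abs(rowSums(trans) - 1) > 1e-8)) abort("transition rows must sum to 1")
  structure(list(spec = spec, trans = trans), class = "markov_lm")
}

#' @export
model_logits.markov_lm <- function(model, ids, positions = "last",
                                   targets = NULL) {
  logt <- log(model$trans)
  if (positions == "last") {
    return(logt[ids[, ncol(ids)] + 1L, , drop = FALSE])
  }
  B <- nrow(ids); T <- ncol(ids)
  valid <- targets != model$spec$pad_id
  lp <- matrix(0, B, T)
  lp[valid] <- logt[cbind(ids[valid] + 1L, targets[valid] + 1L)]
  list(logprobs = lp, valid = valid)
}
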