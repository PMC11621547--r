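test_that("model initialization is deterministic and validates its config", {
  spec <- build_vocab(3)
  m1 <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 4)
  m2 <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 4)
  expect_identical(m1$params, m2$params)
  m3 <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 5)
  expect_false(identical(m1$params, m3$params))
  expect_error(lm_config(n_heads = 4, d_embed = 30), "divisible")
  expect_error(lm_config(context_window = 1), "at least 2")
  # forward smoke on a minimal batch
  ids <- matrix(encode("ACGUA", spec)$ids[1:4], 1)
  lg <- rnaforge:::lm_forward(m1, ids, want = "last_logits")
  expect_equal(dim(lg), c(1, spec$vocab_size))
  expect_true(all(is.finite(lg)))
})

test_that("analytic gradients agree with finite differences", {
  spec <- build_vocab(2)
  m <- init_rna_lm(lm_config(context_window = 8, n_layers = 2, n_heads = 2,
                             d_embed = 8), spec, rng_seed = 1)
  set.seed(2)
  ids <- matrix(sample(0:15, 12, replace = TRUE), 2, 6)
  tg <- cbind(ids[, 2:6], c(spec$eos_id, spec$pad_id))
  fw <- rnaforge:::lm_forward(m, ids, tg)
  gr <- rnaforge:::lm_backward(m, fw$state)
  eps <- 1e-6
  for (nm in c("wte", "l1.w_qkv", "l1.w_o", "l2.w_fc", "l2.g2", "gf")) {
    p <- m$params[[nm]]
    for (ii in sample(length(p), 3)) {
      mp <- m; mp$params[[nm]][ii] <- p[ii] + eps
      mm <- m; mm$params[[nm]][ii] <- p[ii] - eps
      num <- (rnaforge:::lm_forward(mp, ids, tg)$loss -
              rnaforge:::lm_forward(mm, ids, tg)$loss) / (2 * eps)
      expect_equal(gr[[nm]][ii], num, tolerance = 1e-3)
    }
  }
})

test_that("a uniform-logit model has perplexity exactly the vocabulary size", {
  for (n in c(1, 3)) {
    spec <- build_vocab(n)
    m <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 0)
    m$params <- lapply(m$params, function(p) p * 0) # all-zero: uniform logits
    toks <- encode_dataset(rand_rna_set(5, 30, seed = n), spec)
    nll <- rnaforge:::evaluate_nll(m, toks)
    expect_equal(perplexity_from_nll(nll), spec$vocab_size, tolerance = 1e-10)
  }
})

test_that("PAD positions are excluded from the loss", {
  spec <- build_vocab(3)
  m <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 3)
  ids <- encode(rand_rna(20, seed = 1), spec)$ids
  unpadded <- matrix(ids[-length(ids)], 1)
  tg1 <- matrix(ids[-1], 1)
  k <- length(ids)
  padded <- matrix(c(ids[-length(ids)], rep(spec$pad_id, 10)), 1)
  tg2 <- matrix(c(ids[-1], rep(spec$pad_id, 10)), 1)
  l1 <- rnaforge:::lm_forward(m, unpadded, tg1)$loss
  l2 <- rnaforge:::lm_forward(m, padded, tg2)$loss
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("training memorizes a deterministic corpus to near-certainty", {
  spec <- build_vocab(3)
  s <- rand_rna(40, seed = 6)
  toks <- encode_dataset(setNames(rep(s, 200), paste0("c", 1:200)), spec)
  m <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 0)
  out <- train_lm(m, toks, toks[1:5], fast_train_cfg(300))
  expect_lt(min(out$report$perplexity), 1.1) # zero-entropy corpus
  expect_equal(tail(out$report$perplexity, 1),
               exp(tail(out$report$val_nll, 1)))
})

test_that("sequence log-probabilities match the Markov chain closed form", {
  spec <- build_vocab(1)
  set.seed(8)
  cond <- matrix(runif(16, 0.05, 1), 4, 4)
  cond <- cond / rowSums(cond)
  trans <- markov_trans(cond, p_eos = 0.15)
  mk <- markov_model(spec, trans)
  seqs <- vapply(1:6, function(i) rand_rna(sample(3:12, 1)), "")
  got <- sequence_log_probability(mk, seqs)
  want <- vapply(seqs, function(s) chain_logp(s, trans), 0)
  expect_equal(as.numeric(got), unname(want), tolerance = 1e-10)
})

test_that("windowed evaluation sums log-probabilities across context chunks", {
  spec <- build_vocab(3)
  m <- init_rna_lm(lm_config(context_window = 16, n_layers = 2, n_heads = 2,
                             d_embed = 16), spec, rng_seed = 2)
  s <- rand_rna(60, seed = 9) # far beyond the 16-token window
  lp <- sequence_log_probability(m, s)
  expect_true(isTRUE(attr(lp, "windowed")))
  # independent accumulation over the same non-overlapping windows
  ids <- encode(s, spec)$ids
  total <- 0; start <- 1
  while (start < length(ids)) {
    stop_at <- min(start + 16, length(ids))
    w <- ids[start:stop_at]
    fw <- rnaforge:::lm_forward(m, matrix(w[-length(w)], 1),
                                matrix(w[-1], 1), want = "logprobs")
    total <- total + sum(fw$logprobs[fw$valid])
    start <- stop_at
  }
  expect_equal(as.numeric(lp), total, tolerance = 1e-10)
})

test_that("generation respects seed, determinism, and the greedy limit", {
  spec <- build_vocab(3)
  m <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 7)
  gc1 <- generation_config("ACGUACGU", temperature = 0.7, n_sequences = 4,
                           max_nucleotides = 30, rng_seed = 11)
  g1 <- generate_sequences(m, gc1)
  g2 <- generate_sequences(m, gc1)
  expect_identical(g1, g2) # bit-reproducible
  expect_true(all(startsWith(g1$seq, "ACGUACGU")))
  expect_error(generation_config("ACGU", temperature = 0), "> 0")

  # near-zero temperature equals argmax decoding
  cold <- generate_sequences(m, generation_config("ACGUACGU",
    temperature = 1e-8, n_sequences = 2, max_nucleotides = 20, rng_seed = 1))
  expect_equal(cold$seq[1], cold$seq[2])
  ids <- encode("ACGUACGU", spec)$ids
  ids <- matrix(ids[-length(ids)], 1)
  banned <- c(spec$bos_id, spec$pad_id) + 1L
  while (ncol(ids) - 1 < 20 - 3 + 1) {
    lg <- rnaforge:::model_logits(m, ids, positions = "last")
    lg[, banned] <- -Inf
    nxt <- which.max(lg[1, ]) - 1L
    if (nxt == spec$eos_id) { ids <- cbind(ids, nxt); break }
    ids <- cbind(ids, nxt)
  }
  greedy <- decode(ids[1, ], spec)$seq
  greedy <- paste0("ACGUACGU", substring(greedy, 9))
  expect_equal(cold$seq[1], greedy)
})

test_that("sampling reproduces Markov transition frequencies within 3 sigma", {
  spec <- build_vocab(1)
  cond <- matrix(c(.7, .1, .1, .1,
                   .1, .7, .1, .1,
                   .25, .25, .25, .25,
                   .4, .3, .2, .1), 4, 4, byrow = TRUE)
  trans <- markov_trans(cond, p_eos = 0)
  mk <- markov_model(spec, trans)
  n <- 4000
  g <- generate_sequences(mk, generation_config("A", temperature = 1,
    n_sequences = n, max_nucleotides = 3, rng_seed = 13))
  second <- substr(g$seq, 2, 2) # transition out of the seeded A
  for (b in 1:4) {
    p <- cond[1, b]
    phat <- mean(second == c("A", "C", "G", "U")[b])
    expect_lt(abs(phat - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("finetuning records provenance and guards the data partition", {
  spec <- build_vocab(3)
  toks <- encode_dataset(rand_rna_set(20, 25, seed = 3), spec)
  m <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 0)
  base <- train_lm(m, toks[1:15], toks[16:20], fast_train_cfg(30, eval_every = 30))
  # zero-iteration finetune returns the parent unchanged
  ft0 <- finetune_lm(base$model, toks[1:5], toks[16:20],
                     fast_train_cfg(0))
  expect_identical(ft0$model$params, base$model$params)
  expect_equal(ft0$model$meta$parent_id, base$model$meta$checkpoint_id)
  # a finetune-train sequence from the parent validation split warns
  expect_warning(
    finetune_lm(base$model, toks[16:17], toks[18:20],
                fast_train_cfg(10, eval_every = 10)),
    "validation")
})

test_that("tidy and glance expose training traces and model summaries", {
  spec <- build_vocab(2)
  toks <- encode_dataset(rand_rna_set(10, 20, seed = 4), spec)
  m <- init_rna_lm(tiny_lm_cfg(), spec, rng_seed = 0)
  out <- train_lm(m, toks, toks[1:2], fast_train_cfg(20, eval_every = 10))
  td <- tidy(out$report)
  expect_true(all(c("iteration", "train_nll", "val_nll", "perplexity")
                  %in% names(td)))
  gl <- glance(out$model)
  expect_equal(gl$ngram, 2)
  expect_equal(gl$vocab_size, 19)
})
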