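# Shared fixtures and independent brute-force oracles used across tests.

rand_rna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

rand_rna_set <- function(n, len, seed = 0) {
  set.seed(seed)
  setNames(vapply(seq_len(n), function(i) rand_rna(len), ""),
           paste0("r", seq_len(n)))
}

## ---- first-order Markov chain reference -----------------------------------

# transition matrix over the n=1 vocabulary (A,C,G,U,BOS,EOS,PAD):
# cond is a 4x4 row-stochastic matrix of nucleotide transitions.
markov_trans <- function(cond, p_eos = 0.1, init = rep(0.25, 4)) {
  V <- 7L
  tr <- matrix(0, V, V)
  tr[1:4, 1:4] <- (1 - p_eos) * cond
  tr[1:4, 6] <- p_eos          # -> EOS
  tr[5, 1:4] <- init           # BOS -> first nucleotide
  tr[6, 7] <- 1; tr[7, 7] <- 1 # EOS/PAD absorb into PAD
  tr
}

# closed-form chain log-probability of a full sequence (body + EOS),
# computed directly from the transition matrix
chain_logp <- function(seq, trans) {
  nts <- c("A", "C", "G", "U")
  idx <- match(strsplit(seq, "")[[1]], nts)
  states <- c(5L, idx) # BOS then nucleotides
  lp <- 0
  for (k in seq_len(length(states) - 1)) {
    lp <- lp + log(trans[states[k], states[k + 1]])
  }
  lp + log(trans[states[length(states)], 6L]) # EOS
}

## ---- brute-force oracles ---------------------------------------------------

bf_noncanonical <- function(row, pairs) {
  ch <- strsplit(row, "")[[1]]
  canon <- c("GC", "CG", "AU", "UA", "GU", "UG")
  num <- 0L; den <- 0L
  for (r in seq_len(nrow(pairs))) {
    a <- ch[pairs$i[r]]; b <- ch[pairs$j[r]]
    if (a %in% c("A", "C", "G", "U") && b %in% c("A", "C", "G", "U")) {
      den <- den + 1L
      if (!paste0(a, b) %in% canon) num <- num + 1L
    }
  }
  if (den == 0) 0 else num / den
}

bf_cutoff_map <- function(D, d) {
  n <- nrow(D)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && D[i, j] < d) M[i, j] <- 1
  }
  M
}

bf_knn_map <- function(D, k) {
  n <- nrow(D)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cand <- setdiff(seq_len(n), i)
    cand <- cand[is.finite(D[i, cand])]
    ord <- cand[order(D[i, cand], cand)]
    M[i, utils::head(ord, k)] <- 1
  }
  M
}

bf_corr <- function(A, B) sum(A * B) / sqrt(sum(A^2) * sum(B^2))

bf_jsd <- function(p, q) {
  h <- function(x) { x <- x[x > 0]; -sum(x * log2(x)) }
  h((p + q) / 2) - (h(p) + h(q)) / 2
}

# all-pairs single-linkage components at an identity threshold: the
# reference for greedy clustering on fixtures with well-separated groups
bf_identity_components <- function(seqs, threshold) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (pairwise_identity(seqs[i], seqs[j]) >= threshold) {
      parent[find(i)] <- find(j)
    }
  }
  length(unique(vapply(seq_len(n), find, 0L)))
}

# a family in four well-separated identity groups
identity_group_fixture <- function(per_group = 5, len = 60, seed = 42) {
  set.seed(seed)
  bases <- vapply(1:4, function(i) rand_rna(len), "")
  out <- character(0)
  for (g in 1:4) {
    for (m in seq_len(per_group)) {
      ch <- strsplit(bases[g], "")[[1]]
      pos <- sample(len, 2)
      ch[pos] <- sample(c("A", "C", "G", "U"), 2, replace = TRUE)
      out <- c(out, paste(ch, collapse = ""))
    }
  }
  setNames(out, paste0("g", rep(1:4, each = per_group), "_", seq_along(out)))
}

# tiny training run shared by LM tests
tiny_lm_cfg <- function(context = 48, d = 32) {
  lm_config(context_window = context, n_layers = 2, n_heads = 2, d_embed = d)
}

fast_train_cfg <- function(iters, lr = 2e-3, bs = 8, eval_every = 50,
                           patience = 10, seed = 0) {
  train_config(lr_start = lr, lr_end = lr / 10, decay_iters = iters,
               max_iters = iters, batch_size = bs,
               eval_interval = eval_every, early_stop_patience = patience,
               rng_seed = seed)
}
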