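# AdamW optimizer over a flat named list of numeric arrays, plus the
# learning-rate schedules used for model training.

adamw_init <- function(params) {
  list(step = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

# decoupled weight decay on matrix-shaped parameters only (gains are 1-D)
adamw_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.998,
                       eps = 1e-8, weight_decay = 0.01) {
  state$step <- state$step + 1L
  t <- state$step
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    if (!is.null(dim(params[[nm]])) && weight_decay > 0) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

# lr_start -> lr_end over decay_iters, then constant at lr_end
lr_at <- function(iter, cfg) {
  frac <- min(iter / max(cfg$decay_iters, 1), 1)
  if (cfg$schedule == "cosine") {
    cfg$lr_end + (cfg$lr_start - cfg$lr_end) * 0.5 * (1 + cos(pi * frac))
  } else {
    cfg$lr_start + (cfg$lr_end - cfg$lr_start) * frac
  }
}

clip_global_norm <- function(grads, max_norm) {
  if (is.null(max_norm) || max_norm <= 0) return(grads)
  total <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
  if (total > max_norm) grads <- lapply(grads, function(g) g * (max_norm / total))
  grads
}

#' Training configuration for the autoregressive models
#'
#' Defaults follow the full-scale recipe (AdamW with beta2 = 0.998, batch 18,
#' learning rate decayed from 5e-5 to 5e-6 over 100,000 iterations, early
#' stopping on validation loss); small-model runs typically raise the
#' learning rate and lower `max_iters`.
#'
#' @param lr_start,lr_end initial and final learning rate.
#' @param decay_iters iterations over which the rate decays.
#' @param schedule `"linear"` (default) or `"cosine"` decay.
#' @param beta1,beta2 AdamW moment coefficients.
#' @param weight_decay decoupled weight decay on matrix parameters.
#' @param batch_size sequences per iteration.
#' @param max_iters training iteration budget.
#' @param eval_interval iterations between validation evaluations.
#' @param early_stop_patience evaluations without improvement before stopping.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param rng_seed seed controlling batch sampling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(lr_start = 5e-5, lr_end = 5e-6, decay_iters = 100000,
                         schedule = c("linear", "cosine"),
                         beta1 = 0.9, beta2 = 0.998, weight_decay = 0.01,
                         batch_size = 18, max_iters = 2000,
                         eval_interval = 50, early_stop_patience = 6,
                         grad_clip = 1.0, rng_seed = 0) {
  schedule <- match.arg(schedule)
  stopifnot(lr_end <= lr_start, batch_size >= 1, max_iters >= 0,
            eval_interval >= 1, beta2 > 0, beta2 < 1)
  structure(list(lr_start = lr_start, lr_end = lr_end,
                 decay_iters = decay_iters, schedule = schedule,
                 beta1 = beta1, beta2 = beta2, weight_decay = weight_decay,
                 batch_size = batch_size, max_iters = max_iters,
                 eval_interval = eval_interval,
                 early_stop_patience = early_stop_patience,
                 grad_clip = grad_clip, rng_seed = rng_seed),
            class = "train_config")
}
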