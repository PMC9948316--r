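# Training engine: cyclic decayed learning-rate schedule, token-count
# batching, Adam, and the negative log-likelihood training loop.

#' Learning-rate scheduler configuration
#'
#' Cyclic decayed schedule: within each cycle the rate ramps linearly from
#' the floor to the peak over the warmup, then decays geometrically back
#' to the floor at the cycle end, and jumps to the ramp again. The
#' \code{constant_factor} of the related Noam-style parameterization is
#' retained for provenance but the schedule is driven directly by its
#' printed endpoints.
#'
#' @param peak_lr maximum rate (default 0.001).
#' @param floor_lr minimum rate (default 3.9e-12).
#' @param warmup_steps ramp length in steps (default 5000).
#' @param cycle_steps cycle period in steps (default 25000).
#' @param constant_factor retained scale constant (default 5).
#' @return object of class \code{sched_config}.
#' @export
sched_config <- function(peak_lr = 0.001, floor_lr = 3.9e-12,
                         warmup_steps = 5000L, cycle_steps = 25000L,
                         constant_factor = 5) {
  stopifnot(floor_lr > 0, floor_lr < peak_lr, warmup_steps < cycle_steps)
  structure(list(peak_lr = peak_lr, floor_lr = floor_lr,
                 warmup_steps = as.integer(warmup_steps),
                 cycle_steps = as.integer(cycle_steps),
                 constant_factor = constant_factor),
            class = "sched_config")
}

#' Learning rate at a step
#'
#' Periodic with period \code{cycle_steps}; attains \code{peak_lr} exactly
#' at the warmup end of each cycle and \code{floor_lr} exactly at the
#' cycle end.
#'
#' @param step integer step(s), >= 1.
#' @param cfg a \code{\link{sched_config}}.
#' @return numeric learning rate(s).
#' @export
lr_at <- function(step, cfg) {
  if (any(step < 1)) stop("step must be >= 1")
  s <- ((step - 1) %% cfg$cycle_steps) + 1
  ramp <- cfg$floor_lr + (cfg$peak_lr - cfg$floor_lr) * s / cfg$warmup_steps
  decay <- cfg$peak_lr *
    (cfg$floor_lr / cfg$peak_lr)^((s - cfg$warmup_steps) /
                                  (cfg$cycle_steps - cfg$warmup_steps))
  ifelse(s <= cfg$warmup_steps, ramp, decay)
}

#' Training configuration
#'
#' @param tokens_per_batch token budget per batch (default 8000): a batch
#'   of n pairs with maximum source length Ls and maximum target length Lt
#'   satisfies (Ls + Lt) * n <= tokens_per_batch.
#' @param max_steps optimizer updates to run (default 500000).
#' @param checkpoint_every snapshot/evaluation period (default 25000).
#' @param seed run seed covering shuffling, dropout and initialization.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(tokens_per_batch = 8000L, max_steps = 500000L,
                         checkpoint_every = 25000L, seed = 1L) {
  stopifnot(tokens_per_batch >= 1, max_steps >= 0)
  structure(list(tokens_per_batch = as.integer(tokens_per_batch),
                 max_steps = as.integer(max_steps),
                 checkpoint_every = as.integer(checkpoint_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Pack translation pairs into token-budgeted batches
#'
#' Pairs are bucketed by source length, packed greedily so that the
#' footprint (max source length + max target length + 1 for the shifted
#' target) times the pair count stays within the budget, and the batch
#' order is shuffled with the given seed.
#'
#' @param pairs list of pairs: each \code{list(src = integer indices,
#'   tgt = integer indices without specials, id = string)}.
#' @param tokens_per_batch token budget.
#' @param seed shuffle seed.
#' @return list of batches: \code{src}, \code{tgt_in}, \code{tgt_out}
#'   integer matrices (PAD-right) plus \code{ids}.
#' @export
make_batches <- function(pairs, tokens_per_batch, seed = 1L) {
  if (length(pairs) == 0) return(list())
  slen <- vapply(pairs, function(p) length(p$src), integer(1))
  tlen <- vapply(pairs, function(p) length(p$tgt), integer(1))
  foot <- slen + tlen + 1L  # +1: bos/eos shift on the target side
  too_big <- which(foot > tokens_per_batch)
  if (length(too_big)) {
    stop(sprintf("pair '%s' (%d tokens) exceeds the batch budget %d",
                 pairs[[too_big[1]]]$id, foot[too_big[1]], tokens_per_batch))
  }
  ord <- order(slen, tlen)
  batches <- list()
  cur <- integer(0); cur_s <- 0L; cur_t <- 0L
  flush <- function() {
    if (length(cur) == 0) return(invisible(NULL))
    batches[[length(batches) + 1L]] <<- build_batch(pairs[cur])
    cur <<- integer(0); cur_s <<- 0L; cur_t <<- 0L
    invisible(NULL)
  }
  for (i in ord) {
    ns <- max(cur_s, slen[i]); nt <- max(cur_t, tlen[i] + 1L)
    if (length(cur) > 0 && (ns + nt) * (length(cur) + 1L) > tokens_per_batch) {
      flush()
      ns <- slen[i]; nt <- tlen[i] + 1L
    }
    cur <- c(cur, i); cur_s <- ns; cur_t <- nt
  }
  flush()
  set.seed(seed)
  batches[sample.int(length(batches))]
}

build_batch <- function(plist) {
  B <- length(plist)
  Ls <- max(vapply(plist, function(p) length(p$src), integer(1)))
  Lt <- max(vapply(plist, function(p) length(p$tgt), integer(1))) + 1L
  src <- matrix(PAD_IDX, B, Ls)
  tin <- matrix(PAD_IDX, B, Lt)
  tout <- matrix(PAD_IDX, B, Lt)
  for (b in seq_len(B)) {
    s <- plist[[b]]$src; t <- plist[[b]]$tgt
    src[b, seq_along(s)] <- s
    full <- c(BOS_IDX, t, EOS_IDX)
    tin[b, seq_len(length(full) - 1L)] <- full[-length(full)]
    tout[b, seq_len(length(full) - 1L)] <- full[-1L]
  }
  list(src = src, tgt_in = tin, tgt_out = tout,
       ids = vapply(plist, function(p) as.character(p$id %||% ""), character(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Adam update; moments live in `state`, and the parameter buffers are
# updated in place by the C++ kernel -- the training loop owns a private
# deep copy of the parameter list, so this never leaks outside it
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- grads[[nm]] * 0
      state$v[[nm]] <- grads[[nm]] * 0
    }
  }
  adam_update_cpp(params, state$m, state$v, grads, names(grads), lr,
                  beta1, beta2, eps, 1 - beta1^state$t, 1 - beta2^state$t)
  list(params = params, state = state)
}

#' Train a transformer translator
#'
#' Optimizes mean per-token negative log-likelihood (padding excluded)
#' with Adam under the cyclic decayed schedule. Deterministic for a fixed
#' seed: two runs produce identical loss traces.
#'
#' @param model a \code{transformer} from \code{\link{init_transformer}}.
#' @param pairs encoded translation pairs (see \code{\link{make_batches}}).
#' @param train_cfg a \code{\link{train_config}}.
#' @param sched_cfg a \code{\link{sched_config}}.
#' @param checkpoint_dir optional directory for periodic RDS snapshots.
#' @param eval_hook optional \code{function(model, step)} called every
#'   \code{checkpoint_every} steps.
#' @param verbose print a progress line every 200 steps.
#' @return list with the trained \code{model}, a \code{history}
#'   data.frame (step, lr, loss) and the final \code{state}.
#' @export
train_translator <- function(model, pairs, train_cfg, sched_cfg,
                             checkpoint_dir = NULL, eval_hook = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(train_cfg, "train_config"),
            inherits(sched_cfg, "sched_config"))
  set.seed(train_cfg$seed)
  # private deep copy: the Adam kernel updates these buffers in place
  model$params <- lapply(model$params, function(x) x + 0)
  state <- list(t = 0L, m = list(), v = list())
  hist_step <- integer(0); hist_lr <- numeric(0); hist_loss <- numeric(0)
  step <- 0L; epoch <- 0L
  while (step < train_cfg$max_steps) {
    epoch <- epoch + 1L
    batches <- make_batches(pairs, train_cfg$tokens_per_batch,
                            seed = train_cfg$seed + epoch)
    for (ba in batches) {
      if (step >= train_cfg$max_steps) break
      step <- step + 1L
      lr <- lr_at(step, sched_cfg)
      fwd <- transformer_forward(model, ba, train = TRUE, need_cache = TRUE)
      if (!is.finite(fwd$loss)) {
        stop(sprintf("non-finite loss %.4g at step %d (lr %.3g)",
                     fwd$loss, step, lr))
      }
      bwd <- transformer_backward(model, ba, fwd)
      up <- adam_step(model$params, bwd$grads, state, lr)
      model$params <- up$params; state <- up$state
      hist_step <- c(hist_step, step)
      hist_lr <- c(hist_lr, lr)
      hist_loss <- c(hist_loss, fwd$loss)
      if (verbose && step %% 200L == 0L) {
        message(sprintf("step %6d  lr %.3g  loss %.4f", step, lr, fwd$loss))
      }
      if (step %% train_cfg$checkpoint_every == 0L) {
        if (!is.null(checkpoint_dir)) {
          dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
          saveRDS(model, file.path(checkpoint_dir,
                                   sprintf("step%06d.rds", step)))
        }
        if (!is.null(eval_hook)) eval_hook(model, step)
      }
    }
    if (length(batches) == 0) break
  }
  list(model = model,
       history = data.frame(step = hist_step, lr = hist_lr, loss = hist_loss),
       state = state)
}
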