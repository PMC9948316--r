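# Attribution of predictions to source fingerprint features: integrated
# gradients over source-feature embeddings, and cross-attention maps.

#' Integrated-gradients attribution matrix
#'
#' For each target position t, the attribution of source token i is
#' \deqn{(x_i - x'_i) \cdot \frac{1}{m}\sum_{k=1}^{m}
#'   \partial F_t(x' + (k/m)(x - x')) / \partial x_i}
#' summed over embedding dimensions, where \eqn{F_t} is the
#' teacher-forced log-probability of the target token at position t and
#' \eqn{x'} the padding-token ("absent feature") baseline embedding.
#' Row sums approximate \eqn{F_t(x) - F_t(x')} (completeness).
#'
#' @param model a \code{transformer}.
#' @param src_vocab,tgt_vocab vocabularies.
#' @param src_tokens source fingerprint tokens.
#' @param tgt_tokens target tokens (the model's own prediction or a
#'   provided reference).
#' @param m_steps number of path steps (default 64).
#' @return object of class \code{attribution_matrix}: list with
#'   \code{scores} (targets x sources, signed), token labels,
#'   \code{method}, \code{ig_steps}, \code{baseline} and
#'   \code{completeness} (per-row endpoint differences).
#' @export
integrated_gradients <- function(model, src_vocab, tgt_vocab, src_tokens,
                                 tgt_tokens, m_steps = 64L) {
  stopifnot(m_steps >= 1)
  d <- model$cfg$d_model
  src <- encode_tokens(src_vocab, src_tokens)
  tgt <- encode_tokens(tgt_vocab, tgt_tokens)
  Ls <- length(src); Lt <- length(tgt)
  full <- c(BOS_IDX, tgt, EOS_IDX)
  batch <- list(src = matrix(src, 1), tgt_in = matrix(full[-length(full)], 1),
                tgt_out = NULL)
  x <- model$params$src_emb[src, , drop = FALSE] * sqrt(d)
  xb <- matrix(model$params$src_emb[PAD_IDX, ] * sqrt(d), Ls, d, byrow = TRUE)
  diff <- x - xb
  # rows of logp correspond to tgt_in positions; position t predicts
  # full[t+1]; take t = 1..Lt so F_t is the log-prob of tgt token t
  V <- vocab_size(tgt_vocab)
  grad_sum <- array(0, dim = c(Lt, Ls, d))
  for (k in seq_len(m_steps)) {
    xa <- xb + (k / m_steps) * diff
    fwd <- transformer_forward(model, batch, train = FALSE, need_cache = TRUE,
                               src_embed_override = xa)
    for (t in seq_len(Lt)) {
      seed <- matrix(0, length(full) - 1L, V)
      seed[t, full[t + 1L]] <- 1
      bwd <- transformer_backward(model, batch, fwd, dlogp_seed = seed)
      grad_sum[t, , ] <- grad_sum[t, , ] + bwd$d_src_embed
    }
  }
  scores <- matrix(0, Lt, Ls, dimnames = list(tgt_tokens, src_tokens))
  for (t in seq_len(Lt)) {
    scores[t, ] <- rowSums(diff * grad_sum[t, , ] / m_steps)
  }
  if (any(!is.finite(scores))) stop("non-finite integrated gradients")
  f_at <- function(xe) {
    fwd <- transformer_forward(model, batch, train = FALSE,
                               src_embed_override = xe)
    vapply(seq_len(Lt), function(t) fwd$logp[t, full[t + 1L]], numeric(1))
  }
  completeness <- f_at(x) - f_at(xb)
  structure(list(scores = scores, src_tokens = src_tokens,
                 tgt_tokens = tgt_tokens, method = "integrated_gradients",
                 ig_steps = as.integer(m_steps), baseline = "pad",
                 completeness = completeness),
            class = "attribution_matrix")
}

#' Cross-attention attribution matrix
#'
#' Teacher-forced forward pass with attention capture; cross-attention
#' weights are aggregated over decoder layers and heads (default: final
#' layer, mean over heads). Every row is a softmax distribution over
#' source tokens and sums to 1.
#'
#' @param model a \code{transformer}.
#' @param src_vocab,tgt_vocab vocabularies.
#' @param src_tokens,tgt_tokens token sequences as in
#'   \code{\link{integrated_gradients}}.
#' @param layer_agg \code{"last"} or a layer index.
#' @param head_agg \code{"mean"} or a head index.
#' @return an \code{attribution_matrix} with non-negative scores.
#' @export
attention_map <- function(model, src_vocab, tgt_vocab, src_tokens,
                          tgt_tokens, layer_agg = "last", head_agg = "mean") {
  src <- encode_tokens(src_vocab, src_tokens)
  tgt <- encode_tokens(tgt_vocab, tgt_tokens)
  Lt <- length(tgt)
  full <- c(BOS_IDX, tgt, EOS_IDX)
  batch <- list(src = matrix(src, 1), tgt_in = matrix(full[-length(full)], 1),
                tgt_out = NULL)
  fwd <- transformer_forward(model, batch, train = FALSE,
                             capture_attention = TRUE)
  l <- if (identical(layer_agg, "last")) model$cfg$n_layers else as.integer(layer_agg)
  maps <- fwd$attn[[l]][[1]]   # per-head Lt_in x Ls matrices
  M <- if (identical(head_agg, "mean")) {
    Reduce(`+`, maps) / length(maps)
  } else maps[[as.integer(head_agg)]]
  M <- M[seq_len(Lt), , drop = FALSE]
  dimnames(M) <- list(tgt_tokens, src_tokens)
  structure(list(scores = M, src_tokens = src_tokens,
                 tgt_tokens = tgt_tokens, method = "attention",
                 layer = l, head = head_agg),
            class = "attribution_matrix")
}

#' @export
print.attribution_matrix <- function(x, ...) {
  cat(sprintf("%s attribution matrix: %d target x %d source tokens\n",
              x$method, nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$completeness)) {
    res <- abs(rowSums(x$scores) - x$completeness)
    cat(sprintf("  max completeness residual: %.4g\n", max(res)))
  }
  invisible(x)
}

#' Write an attribution matrix as a labelled TSV file
#' @param x an \code{attribution_matrix}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_attribution_tsv <- function(x, path) {
  df <- as.data.frame(x$scores)
  names(df) <- x$src_tokens
  utils::write.table(cbind(target = x$tgt_tokens, df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
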