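# Beam-search decoding of fingerprint token sequences into molecular
# strings, and batched prediction records.

#' Translate one fingerprint token sequence (top-1)
#'
#' Beam search over target tokens with end-token termination and a length
#' cap; \code{beam_size = 1} is exactly greedy argmax decoding. Returns
#' the single highest log-probability completed hypothesis, detokenized.
#' If no hypothesis terminates within \code{max_len} the best truncated
#' hypothesis is returned flagged incomplete.
#'
#' @param model a \code{transformer}.
#' @param src_vocab,tgt_vocab vocabularies.
#' @param src_tokens character vector of source fingerprint tokens
#'   (unknowns map to the unknown index).
#' @param beam_size beam width (default 5).
#' @param max_len decoded length cap (default 256).
#' @param length_normalize divide hypothesis scores by length when
#'   ranking (default FALSE).
#' @return list with \code{text}, \code{tokens}, \code{logp},
#'   \code{completed}.
#' @export
translate_top1 <- function(model, src_vocab, tgt_vocab, src_tokens,
                           beam_size = 5L, max_len = 256L,
                           length_normalize = FALSE) {
  if (length(src_tokens) == 0) stop("empty source sequence")
  src <- encode_tokens(src_vocab, src_tokens)
  src <- src[seq_len(min(length(src), model$cfg$max_len_src))]
  max_len <- min(max_len, model$cfg$max_len_tgt - 1L)
  beams <- list(list(seq = BOS_IDX, logp = 0, done = FALSE))
  completed <- list()
  for (pos in seq_len(max_len)) {
    active <- Filter(function(b) !b$done, beams)
    if (length(active) == 0) break
    B <- length(active)
    Lt <- max(vapply(active, function(b) length(b$seq), integer(1)))
    tin <- matrix(PAD_IDX, B, Lt)
    for (b in seq_len(B)) tin[b, seq_along(active[[b]]$seq)] <- active[[b]]$seq
    batch <- list(src = matrix(src, B, length(src), byrow = TRUE),
                  tgt_in = tin, tgt_out = NULL)
    fwd <- transformer_forward(model, batch, train = FALSE)
    cand <- list()
    for (b in seq_len(B)) {
      row <- (b - 1L) * Lt + length(active[[b]]$seq)
      lp <- fwd$logp[row, ]
      lp[PAD_IDX] <- -Inf; lp[BOS_IDX] <- -Inf
      top <- order(lp, decreasing = TRUE)[seq_len(min(beam_size, length(lp)))]
      for (k in top) {
        cand[[length(cand) + 1L]] <- list(
          seq = c(active[[b]]$seq, k),
          logp = active[[b]]$logp + lp[k],
          done = (k == EOS_IDX))
      }
    }
    score <- vapply(cand, function(c_)
      c_$logp / if (length_normalize) length(c_$seq) else 1, numeric(1))
    cand <- cand[order(score, decreasing = TRUE)]
    beams <- utils::head(cand, beam_size)
    for (b in beams) if (b$done) completed[[length(completed) + 1L]] <- b
    if (length(completed) >= beam_size) break
  }
  pick_from <- if (length(completed)) completed else beams
  sc <- vapply(pick_from, function(b)
    b$logp / if (length_normalize) length(b$seq) else 1, numeric(1))
  best <- pick_from[[which.max(sc)]]
  toks <- decode_indices(tgt_vocab, best$seq)
  list(text = paste(toks, collapse = ""), tokens = toks, logp = best$logp,
       completed = length(completed) > 0)
}

#' Translate a batch of fingerprint token sequences
#'
#' Order-preserving; each record carries validity and the primary
#' Tanimoto score under the sparse radius-1 circular fingerprint (AEs),
#' set to 0 for invalid predictions. Per-record failures are recorded,
#' not propagated.
#'
#' @param model a \code{transformer}.
#' @param src_vocab,tgt_vocab vocabularies.
#' @param srcs list of character token vectors.
#' @param ground_truth character vector of reference strings (same
#'   representation as the decoder output).
#' @param representation \code{"SMILES"} or \code{"SELFIES"}.
#' @param ids optional record identifiers.
#' @param beam_size,max_len,length_normalize decoding controls.
#' @return data.frame of prediction records: \code{id},
#'   \code{ground_truth}, \code{prediction}, \code{representation},
#'   \code{valid}, \code{tc_primary}.
#' @export
translate_batch <- function(model, src_vocab, tgt_vocab, srcs, ground_truth,
                            representation = c("SMILES", "SELFIES"),
                            ids = NULL, beam_size = 5L, max_len = 256L,
                            length_normalize = FALSE) {
  representation <- match.arg(representation)
  n <- length(srcs)
  stopifnot(length(ground_truth) == n)
  if (is.null(ids)) ids <- sprintf("P%06d", seq_len(n))
  if (n == 0) {
    return(data.frame(id = character(0), ground_truth = character(0),
                      prediction = character(0), representation = character(0),
                      valid = logical(0), tc_primary = numeric(0),
                      stringsAsFactors = FALSE))
  }
  preds <- character(n); valid <- logical(n); tcp <- numeric(n)
  completed <- logical(n)
  for (i in seq_len(n)) {
    r <- tryCatch(
      translate_top1(model, src_vocab, tgt_vocab, srcs[[i]],
                     beam_size = beam_size, max_len = max_len,
                     length_normalize = length_normalize),
      error = function(e) list(text = "", completed = FALSE))
    preds[i] <- r$text
    completed[i] <- isTRUE(r$completed)
  }
  valid <- completed & is_valid_molstring(preds, representation)
  for (i in seq_len(n)) {
    tcp[i] <- if (!valid[i]) 0 else prediction_tanimoto(
      preds[i], ground_truth[i], representation, "AEs")
  }
  data.frame(id = ids, ground_truth = ground_truth, prediction = preds,
             representation = representation, valid = valid,
             tc_primary = tcp, stringsAsFactors = FALSE)
}

# Tanimoto between prediction and ground truth given the string
# representation; SELFIES records are decoded to molecules first
prediction_tanimoto <- function(pred, gt, representation, spec_name) {
  ps <- if (representation == "SELFIES") selfies_decode(pred) else pred
  gs <- if (representation == "SELFIES") selfies_decode(gt) else gt
  out <- tryCatch(tanimoto_smiles(ps, gs, spec_name), error = function(e) 0)
  if (!is.finite(out)) 0 else out
}
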