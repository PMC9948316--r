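# The central modelling interface: fit a fingerprint-to-molecule
# translator on a molecule corpus and use it through the standard S3
# generics (print, summary, predict, coef, plot, logLik).

#' Fit a fingerprint-to-molecule translator
#'
#' Featurizes each training molecule under one registry fingerprint into
#' an ordered feature-token sentence, tokenizes the molecular strings
#' (atom-wise SMILES or SELFIES units), builds source/target
#' vocabularies, and trains a transformer encoder-decoder by teacher
#' forcing under the cyclic decayed learning-rate schedule.
#'
#' @param records molecule-record data.frame
#'   (\code{\link{molecule_records}} / \code{\link{generate_molecules}}).
#' @param spec fingerprint name from the registry (default
#'   \code{"ECFP4"}).
#' @param representation target string representation: \code{"SMILES"}
#'   (default) or \code{"SELFIES"}.
#' @param model_cfg a \code{\link{model_config}} (vocabulary sizes are
#'   filled in automatically).
#' @param train_cfg a \code{\link{train_config}}.
#' @param sched_cfg a \code{\link{sched_config}}.
#' @param checkpoint_dir optional directory for periodic snapshots.
#' @param eval_hook optional \code{function(model, step)} checkpoint
#'   callback.
#' @param verbose print training progress.
#' @return object of class \code{fp_translator}.
#' @export
fp_translator <- function(records, spec = "ECFP4",
                          representation = c("SMILES", "SELFIES"),
                          model_cfg = model_config(),
                          train_cfg = train_config(),
                          sched_cfg = sched_config(),
                          checkpoint_dir = NULL, eval_hook = NULL,
                          verbose = FALSE) {
  representation <- match.arg(representation)
  stopifnot(is.data.frame(records), nrow(records) > 0)
  fspec <- fingerprint_spec(spec)
  src_seqs <- lapply(records$smiles, function(s) featurize(s, fspec)$tokens)
  tgt_strings <- if (representation == "SMILES") {
    records$smiles
  } else {
    vapply(records$smiles, selfies_encode, character(1), USE.NAMES = FALSE)
  }
  tgt_seqs <- lapply(tgt_strings, function(s) {
    if (representation == "SMILES") tokenize_smiles(s) else tokenize_selfies(s)
  })
  src_vocab <- build_vocab(src_seqs)
  tgt_vocab <- build_vocab(tgt_seqs)
  model_cfg$src_vocab_size <- vocab_size(src_vocab)
  model_cfg$tgt_vocab_size <- vocab_size(tgt_vocab)
  pairs <- lapply(seq_along(src_seqs), function(i) {
    list(src = encode_tokens(src_vocab, src_seqs[[i]]),
         tgt = encode_tokens(tgt_vocab, tgt_seqs[[i]]),
         id = records$id[i])
  })
  model <- init_transformer(model_cfg, seed = train_cfg$seed)
  run <- train_translator(model, pairs, train_cfg, sched_cfg,
                          checkpoint_dir = checkpoint_dir,
                          eval_hook = eval_hook, verbose = verbose)
  structure(list(model = run$model, src_vocab = src_vocab,
                 tgt_vocab = tgt_vocab, spec = fspec,
                 representation = representation,
                 history = run$history, n_train = nrow(records),
                 train_cfg = train_cfg, sched_cfg = sched_cfg,
                 call = match.call()),
            class = "fp_translator")
}

#' @export
print.fp_translator <- function(x, ...) {
  cat("Fingerprint-to-molecule translator\n")
  cat(sprintf("  source fingerprint: %s (%s, %s)\n", x$spec$name,
              x$spec$family,
              if (identical(x$spec$n_bits, "sparse")) "sparse"
              else sprintf("%d bits", x$spec$n_bits)))
  cat(sprintf("  target: %s  |  vocabulary %d -> %d tokens\n",
              x$representation, vocab_size(x$src_vocab),
              vocab_size(x$tgt_vocab)))
  cat(sprintf("  transformer: %d layers, %d heads, d_model %d (%s parameters)\n",
              x$model$cfg$n_layers, x$model$cfg$n_heads, x$model$cfg$d_model,
              format(count_parameters(x$model), big.mark = ",")))
  if (nrow(x$history)) {
    cat(sprintf("  trained %d steps on %d molecules; final loss %.4f\n",
                max(x$history$step), x$n_train,
                x$history$loss[nrow(x$history)]))
  }
  invisible(x)
}

#' @export
summary.fp_translator <- function(object, ...) {
  h <- object$history
  out <- list(spec = object$spec$name,
              representation = object$representation,
              n_train = object$n_train,
              n_parameters = count_parameters(object$model),
              steps = if (nrow(h)) max(h$step) else 0L,
              final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
              min_loss = if (nrow(h)) min(h$loss) else NA_real_)
  class(out) <- "summary.fp_translator"
  out
}

#' @export
print.summary.fp_translator <- function(x, ...) {
  cat(sprintf(
    "fp_translator: %s -> %s | %d molecules | %s parameters | %d steps | final loss %.4f (min %.4f)\n",
    x$spec, x$representation, x$n_train,
    format(x$n_parameters, big.mark = ","), x$steps, x$final_loss, x$min_loss))
  invisible(x)
}

#' Predict molecular strings from molecules or token sequences
#'
#' Featurizes \code{newdata} under the fitted source fingerprint and
#' beam-decodes top-1 molecular strings.
#'
#' @param object a fitted \code{fp_translator}.
#' @param newdata molecule-record data.frame, character vector of SMILES,
#'   or list of raw fingerprint token vectors.
#' @param beam_size,max_len,length_normalize decoding controls.
#' @param ... unused.
#' @return prediction-record data.frame (see
#'   \code{\link{translate_batch}}).
#' @export
predict.fp_translator <- function(object, newdata, beam_size = 5L,
                                  max_len = 256L, length_normalize = FALSE,
                                  ...) {
  if (is.character(newdata)) {
    newdata <- data.frame(id = sprintf("Q%06d", seq_along(newdata)),
                          smiles = newdata, stringsAsFactors = FALSE)
  }
  if (is.data.frame(newdata)) {
    srcs <- lapply(newdata$smiles, function(s)
      featurize(s, object$spec)$tokens)
    gt <- if (object$representation == "SMILES") newdata$smiles else
      vapply(newdata$smiles, selfies_encode, character(1), USE.NAMES = FALSE)
    ids <- newdata$id
  } else {
    srcs <- newdata
    gt <- rep(NA_character_, length(srcs))
    ids <- sprintf("Q%06d", seq_along(srcs))
  }
  translate_batch(object$model, object$src_vocab, object$tgt_vocab,
                  srcs, gt, representation = object$representation,
                  ids = ids, beam_size = beam_size, max_len = max_len,
                  length_normalize = length_normalize)
}

#' @export
coef.fp_translator <- function(object, ...) object$model$params

#' @export
logLik.fp_translator <- function(object, ...) {
  h <- object$history
  val <- if (nrow(h)) -h$loss[nrow(h)] else NA_real_
  structure(val, df = count_parameters(object$model), class = "logLik")
}

#' Plot the training loss and learning-rate trace
#' @param x a fitted \code{fp_translator}.
#' @param ... passed to \code{plot}.
#' @export
plot.fp_translator <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$step, h$loss, type = "l", xlab = "step",
                 ylab = "NLL loss", ...)
  graphics::plot(h$step, h$lr, type = "l", xlab = "step",
                 ylab = "learning rate", log = "y")
  invisible(x)
}

# --- checkpoints -----------------------------------------------------------

config_hash <- function(cfg) {
  fnv1a31(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA))
}

#' Save a fitted translator checkpoint
#'
#' Single-file archive holding the model configuration (as JSON), the
#' weights, the vocabularies and a config hash validated on load.
#'
#' @param object a \code{fp_translator} (or raw \code{transformer}).
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
save_translator <- function(object, path) {
  cfg_json <- jsonlite::toJSON(unclass(object$model$cfg), auto_unbox = TRUE,
                               digits = NA)
  saveRDS(list(cfg_json = as.character(cfg_json),
               hash = config_hash(object$model$cfg),
               params = object$model$params,
               src_vocab = object$src_vocab$tokens,
               tgt_vocab = object$tgt_vocab$tokens,
               spec_name = object$spec$name,
               representation = object$representation,
               history = object$history,
               n_train = object$n_train),
          path)
  invisible(path)
}

#' Load a translator checkpoint
#'
#' @param path file written by \code{\link{save_translator}}.
#' @return a \code{fp_translator}.
#' @export
load_translator <- function(path) {
  x <- readRDS(path)
  cfg <- do.call(model_config, jsonlite::fromJSON(x$cfg_json))
  if (!identical(config_hash(cfg), x$hash)) {
    stop("checkpoint config hash mismatch: ", path)
  }
  model <- init_transformer(cfg, seed = 0L)
  model$params <- x$params
  mk_vocab <- function(toks) structure(
    list(tokens = toks, index = stats::setNames(seq_along(toks), toks)),
    class = "vocabulary")
  structure(list(model = model, src_vocab = mk_vocab(x$src_vocab),
                 tgt_vocab = mk_vocab(x$tgt_vocab),
                 spec = fingerprint_spec(x$spec_name),
                 representation = x$representation,
                 history = x$history, n_train = x$n_train,
                 call = NULL),
            class = "fp_translator")
}
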