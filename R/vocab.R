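# Token vocabularies with reserved special indices. Index order is fixed:
# 1 <pad>, 2 <bos>, 3 <eos>, 4 <unk>, then corpus tokens by decreasing
# frequency (ties broken lexicographically).

SPECIAL_TOKENS <- c("<pad>", "<bos>", "<eos>", "<unk>")

#' Build a vocabulary from token sequences
#'
#' @param sequences list of character token vectors.
#' @return object of class \code{vocabulary}: list with \code{tokens}
#'   (index -> token, specials first) and \code{index} (token -> index).
#' @export
build_vocab <- function(sequences) {
  stopifnot(length(sequences) > 0)
  tab <- table(unlist(sequences))
  toks <- names(tab)[order(-as.integer(tab), names(tab), method = "radix")]
  toks <- setdiff(toks, SPECIAL_TOKENS)
  all <- c(SPECIAL_TOKENS, toks)
  idx <- stats::setNames(seq_along(all), all)
  structure(list(tokens = all, index = idx), class = "vocabulary")
}

#' Vocabulary size (specials included)
#' @param vocab a \code{vocabulary}.
#' @return integer.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Encode tokens as integer indices
#'
#' Unseen tokens map to the unknown index.
#'
#' @param vocab a \code{vocabulary}.
#' @param tokens character vector.
#' @return integer vector.
#' @export
encode_tokens <- function(vocab, tokens) {
  if (length(tokens) == 0) return(integer(0))
  i <- unname(vocab$index[tokens])
  i[is.na(i)] <- UNK_IDX
  as.integer(i)
}

#' Decode integer indices to tokens (specials dropped)
#' @param vocab a \code{vocabulary}.
#' @param idx integer vector.
#' @return character vector.
#' @export
decode_indices <- function(vocab, idx) {
  toks <- vocab$tokens[idx]
  toks[!toks %in% SPECIAL_TOKENS]
}

#' Save a vocabulary as JSON
#' @param vocab a \code{vocabulary}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
save_vocab <- function(vocab, path) {
  jsonlite::write_json(list(tokens = vocab$tokens), path, auto_unbox = FALSE)
  invisible(path)
}

#' Load a vocabulary from JSON
#' @param path JSON path written by \code{\link{save_vocab}}.
#' @return a \code{vocabulary}.
#' @export
load_vocab <- function(path) {
  toks <- as.character(jsonlite::read_json(path, simplifyVector = TRUE)$tokens)
  stopifnot(identical(toks[1:4], SPECIAL_TOKENS))
  structure(list(tokens = toks,
                 index = stats::setNames(seq_along(toks), toks)),
            class = "vocabulary")
}
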