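# 32-bit FNV-1a over character keys; all sparse fingerprint feature IDs
# derive from this, so featurization is deterministic across platforms.
# Arithmetic is done in doubles (exact below 2^53) to avoid R's integer
# overflow-to-NA semantics.

#' Hash a character key to a non-negative 31-bit integer
#'
#' Deterministic FNV-1a hash used for all sparse fingerprint feature
#' identifiers. Results lie in \code{[0, 2^31)} so they are always
#' representable as R integers.
#'
#' @param key character vector of keys.
#' @return integer vector of non-negative feature identifiers.
#' @keywords internal
fnv1a31 <- function(key) {
  p <- 16777619
  vapply(key, function(k) {
    h <- 2166136261
    for (b in utf8ToInt(k)) {
      lo8 <- h %% 256
      h <- h - lo8 + bitwXor(as.integer(lo8), bitwAnd(b, 255L))
      hi <- ((h %/% 65536) * p) %% 65536
      lo <- (h %% 65536) * p
      h <- (hi * 65536 + lo) %% 4294967296
    }
    as.integer(h %% 2147483648)
  }, integer(1), USE.NAMES = FALSE)
}

# fold sparse ids into [0, n_bits)
fold_bits <- function(ids, n_bits) sort(unique(ids %% as.integer(n_bits)))
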