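# Evaluation suite: Tanimoto exactness, top-1 accuracy breakdown,
# fingerprint-bias matrix, similarity significance thresholds, and the
# stereo-error profile.

# canonical molecule strings behind a prediction record table
record_molecule_smiles <- function(records) {
  selfies <- records$representation == "SELFIES"
  pred <- records$prediction; gt <- records$ground_truth
  if (any(selfies)) {
    pred[selfies] <- vapply(pred[selfies], function(s)
      tryCatch(selfies_decode(s), error = function(e) NA_character_),
      character(1), USE.NAMES = FALSE)
    gt[selfies] <- vapply(gt[selfies], function(s)
      tryCatch(selfies_decode(s), error = function(e) NA_character_),
      character(1), USE.NAMES = FALSE)
  }
  list(pred = pred, gt = gt)
}

#' Tanimoto exactness of a prediction set
#'
#' Percentage of predictions whose Tanimoto coefficient with the ground
#' truth equals 1 under the chosen metric fingerprint. Invalid
#' predictions count in the denominator only.
#'
#' @param records prediction-record data.frame from
#'   \code{\link{translate_batch}}.
#' @param metric_spec one of \code{metric_fingerprint_names()}.
#' @return percentage in [0, 100].
#' @export
tanimoto_exactness <- function(records, metric_spec = "AEs") {
  if (nrow(records) == 0) stop("empty record set")
  ms <- record_molecule_smiles(records)
  exact <- 0L
  for (i in seq_len(nrow(records))) {
    if (!records$valid[i] || is.na(ms$pred[i])) next
    tc <- tryCatch(tanimoto_smiles(ms$pred[i], ms$gt[i], metric_spec),
                   error = function(e) 0)
    if (tc >= 1 - 1e-12) exact <- exact + 1L
  }
  100 * exact / nrow(records)
}

#' Breakdown of top-1 accuracy
#'
#' Classifies every prediction by the first matching rule: Invalid;
#' not-exact (primary Tanimoto < 1 under the sparse radius-1 circular
#' fingerprint); String exact (raw strings equal); Non-canonical
#' (stereo-preserving canonical forms equal); Stereo (stereo-stripped
#' canonical forms equal); Others. Reports category percentages, the
#' Tanimoto-exact total, and the mean Tanimoto score with invalid
#' predictions contributing 0.
#'
#' @param records prediction-record data.frame.
#' @return object of class \code{breakdown_report}.
#' @export
breakdown <- function(records) {
  n <- nrow(records)
  stopifnot(n > 0)
  ms <- record_molecule_smiles(records)
  cls <- character(n)
  tc <- numeric(n)
  for (i in seq_len(n)) {
    if (!records$valid[i] || is.na(ms$pred[i])) {
      cls[i] <- "invalid"; tc[i] <- 0
      next
    }
    tc[i] <- tryCatch(tanimoto_smiles(ms$pred[i], ms$gt[i], "AEs"),
                      error = function(e) 0)
    if (tc[i] < 1 - 1e-12) { cls[i] <- "not_exact"; next }
    if (identical(records$prediction[i], records$ground_truth[i])) {
      cls[i] <- "string_exact"; next
    }
    pc <- canonicalize_smiles(ms$pred[i]); gc_ <- canonicalize_smiles(ms$gt[i])
    if (!is.na(pc) && !is.na(gc_) && pc == gc_) { cls[i] <- "noncanonical"; next }
    ps <- canonicalize_smiles(ms$pred[i], keep_stereo = FALSE)
    gs <- canonicalize_smiles(ms$gt[i], keep_stereo = FALSE)
    if (!is.na(ps) && !is.na(gs) && ps == gs) { cls[i] <- "stereo"; next }
    cls[i] <- "others"
  }
  pct <- function(k) 100 * sum(cls == k) / n
  structure(list(
    n_total = n,
    pct_tc_exact = pct("string_exact") + pct("noncanonical") +
      pct("stereo") + pct("others"),
    pct_string_exact = pct("string_exact"),
    pct_stereo = pct("stereo"),
    pct_noncanonical = pct("noncanonical"),
    pct_others = pct("others"),
    pct_invalid = pct("invalid"),
    mean_tc = mean(tc),
    classes = cls
  ), class = "breakdown_report")
}

#' @export
print.breakdown_report <- function(x, ...) {
  cat(sprintf("Breakdown of top-1 accuracy (n = %d)\n", x$n_total))
  cat(sprintf("  Tc = 1.0        %6.1f%%\n", x$pct_tc_exact))
  cat(sprintf("    String exact  %6.1f%%\n", x$pct_string_exact))
  cat(sprintf("    Stereo        %6.1f%%\n", x$pct_stereo))
  cat(sprintf("    Non-canonical %6.1f%%\n", x$pct_noncanonical))
  cat(sprintf("    Others        %6.1f%%\n", x$pct_others))
  cat(sprintf("  Invalid         %6.1f%%\n", x$pct_invalid))
  cat(sprintf("  Mean Tc          %6.3f\n", x$mean_tc))
  invisible(x)
}

#' Fingerprint-bias matrix
#'
#' One row per model (source fingerprint), one column per metric
#' fingerprint (the 13 registry featurizers plus explicit-bit ECFP2* and
#' ECFP4*); cells are Tanimoto-exactness percentages.
#'
#' @param per_model_records named list of prediction-record data.frames.
#' @return numeric matrix (models x 15 metrics).
#' @export
bias_matrix <- function(per_model_records) {
  stopifnot(length(per_model_records) >= 1)
  mets <- metric_fingerprint_names()
  out <- matrix(NA_real_, length(per_model_records), length(mets),
                dimnames = list(names(per_model_records), mets))
  for (r in seq_along(per_model_records)) {
    for (c_ in seq_along(mets)) {
      out[r, c_] <- tanimoto_exactness(per_model_records[[r]], mets[c_])
    }
  }
  out
}

#' Similarity significance threshold for a fingerprint
#'
#' Samples random unordered molecule pairs (no self-pairs) from a corpus,
#' computes their Tanimoto similarity under the fingerprint, and returns
#' the empirical (1 - p) quantile: the similarity value exceeded by only
#' a fraction p of random pairs.
#'
#' @param corpus molecule-record data.frame (>= 2 molecules).
#' @param spec_name one of \code{metric_fingerprint_names()}.
#' @param p significance level (default 0.01).
#' @param n_pairs number of sampled pairs (default 1000).
#' @param seed sampling seed.
#' @return object of class \code{significance_threshold}: list with
#'   \code{spec_name}, \code{p_value}, \code{tc_threshold},
#'   \code{n_pairs}, \code{seed}, \code{similarities}.
#' @export
significance_threshold <- function(corpus, spec_name, p = 0.01,
                                   n_pairs = 1000L, seed = 1L) {
  n <- nrow(corpus)
  if (n < 2) stop("corpus must contain at least 2 molecules")
  stopifnot(p > 0, p <= 1)
  set.seed(seed)
  i <- sample.int(n, n_pairs, replace = TRUE)
  j <- sample.int(n - 1L, n_pairs, replace = TRUE)
  j <- ifelse(j >= i, j + 1L, j)
  sims <- vapply(seq_len(n_pairs), function(k)
    tanimoto_smiles(corpus$smiles[i[k]], corpus$smiles[j[k]], spec_name),
    numeric(1))
  sorted <- sort(sims)
  idx <- max(1L, as.integer(ceiling((1 - p) * n_pairs)))
  structure(list(spec_name = spec_name, p_value = p,
                 tc_threshold = sorted[idx], n_pairs = as.integer(n_pairs),
                 seed = as.integer(seed), similarities = sims),
            class = "significance_threshold")
}

#' @export
print.significance_threshold <- function(x, ...) {
  cat(sprintf("Tc threshold (%s, p = %g, %d pairs): %.4f\n",
              x$spec_name, x$p_value, x$n_pairs, x$tc_threshold))
  invisible(x)
}

#' Stereo-error profile of the Stereo breakdown category
#'
#' Partitions the records whose stereo-stripped canonical forms match
#' into: \code{missing} (prediction carries no stereo annotation while
#' the ground truth does), \code{spurious} (the converse),
#' \code{reversed} (the canonical strings align mark-for-mark on the
#' same skeleton and at least one descriptor is opposite -- the
#' cis/trans or clockwise/anti-clockwise reversal case), and
#' \code{mixed} (stereo present on both sides but not alignable
#' positionally).
#'
#' @param records prediction-record data.frame.
#' @return named integer vector of counts.
#' @export
stereo_error_profile <- function(records) {
  br <- breakdown(records)
  idx <- which(br$classes == "stereo")
  out <- c(reversed = 0L, missing = 0L, spurious = 0L, mixed = 0L)
  if (length(idx) == 0) return(out)
  ms <- record_molecule_smiles(records[idx, , drop = FALSE])
  for (k in seq_along(idx)) {
    pc <- canonicalize_smiles(ms$pred[k]); gc_ <- canonicalize_smiles(ms$gt[k])
    pm <- stereo_marks(pc); gm <- stereo_marks(gc_)
    if (length(pm$marks) == 0 && length(gm$marks) > 0) {
      out["missing"] <- out["missing"] + 1L
    } else if (length(pm$marks) > 0 && length(gm$marks) == 0) {
      out["spurious"] <- out["spurious"] + 1L
    } else if (identical(pm$skeleton, gm$skeleton) &&
               identical(pm$pos, gm$pos) &&
               any(pm$marks != gm$marks)) {
      out["reversed"] <- out["reversed"] + 1L
    } else {
      out["mixed"] <- out["mixed"] + 1L
    }
  }
  out
}

# split a SMILES string into its stereo-free skeleton plus the stereo
# descriptors (@, @@, /, \) anchored at skeleton positions
stereo_marks <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  skel <- character(0)
  pos <- integer(0); marks <- character(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "@") {
      if (i < length(chars) && chars[i + 1L] == "@") {
        marks <- c(marks, "@@"); i <- i + 2L
      } else {
        marks <- c(marks, "@"); i <- i + 1L
      }
      pos <- c(pos, length(skel))
    } else if (ch == "/" || ch == "\\") {
      marks <- c(marks, ch); pos <- c(pos, length(skel))
      i <- i + 1L
    } else {
      skel <- c(skel, ch); i <- i + 1L
    }
  }
  list(skeleton = paste(skel, collapse = ""), pos = pos, marks = marks)
}
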