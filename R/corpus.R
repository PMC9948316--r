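# Synthetic drug-like corpus: generation by random SELFIES sampling +
# robust decoding, heavy-atom filtering, stereo enrichment toward a target
# fraction, atom-type diversity selection, and train/test splitting.

#' Corpus generation configuration
#'
#' @param n_molecules number of unique molecules to generate.
#' @param heavy_atom_cap inclusive upper bound on non-hydrogen atoms
#'   (default 50, the small/medium drug-like regime).
#' @param stereo_fraction_target fraction of molecules that should carry
#'   stereochemistry after canonicalization (default 0.3).
#' @param min_heavy_atoms lower bound on heavy atoms; tiny fragments below
#'   this are rejected as not drug-like (default 5).
#' @param max_generation_attempts cap on decode attempts before giving up.
#' @param seed RNG seed for the whole generation run.
#' @return object of class \code{corpus_config}.
#' @export
corpus_config <- function(n_molecules, heavy_atom_cap = 50L,
                          stereo_fraction_target = 0.3,
                          min_heavy_atoms = 5L,
                          max_generation_attempts = max(50L * n_molecules, 1000L),
                          seed = 1L) {
  stopifnot(n_molecules >= 0,
            heavy_atom_cap >= 1,
            stereo_fraction_target >= 0, stereo_fraction_target <= 1,
            max_generation_attempts >= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 heavy_atom_cap = as.integer(heavy_atom_cap),
                 stereo_fraction_target = stereo_fraction_target,
                 min_heavy_atoms = as.integer(min_heavy_atoms),
                 max_generation_attempts = as.integer(max_generation_attempts),
                 seed = as.integer(seed)),
            class = "corpus_config")
}

#' Generate a synthetic drug-like molecule corpus
#'
#' Samples random token sequences in the robust SELFIES-style alphabet and
#' decodes them, which guarantees chemical validity without an external
#' compound database; this corpus is a synthetic stand-in for a large
#' public compound collection. Unassigned stereocenters are randomly fixed
#' molecule-by-molecule until the stereo fraction approaches the target.
#' Deterministic for a fixed config seed.
#'
#' @param config a \code{\link{corpus_config}}.
#' @return data.frame of molecule records (see
#'   \code{\link{molecule_records}}), exactly \code{n_molecules} rows,
#'   unique by canonical SMILES.
#' @export
generate_molecules <- function(config) {
  stopifnot(inherits(config, "corpus_config"))
  n <- config$n_molecules
  if (n == 0) {
    return(data.frame(id = character(0), smiles = character(0),
                      heavy_atoms = integer(0), has_stereo = logical(0),
                      stringsAsFactors = FALSE))
  }
  set.seed(config$seed)
  seen <- new.env(parent = emptyenv())
  out_smiles <- character(0)
  out_stereo <- logical(0)
  attempts <- 0L
  while (length(out_smiles) < n) {
    if (attempts >= config$max_generation_attempts) {
      stop(sprintf(
        "corpus generation exhausted %d attempts with %d/%d molecules",
        attempts, length(out_smiles), n))
    }
    attempts <- attempts + 1L
    ntok <- sample(6:42, 1)
    smi <- selfies_decode(sample_selfies_tokens(ntok))
    can <- canonicalize_smiles(smi)
    if (is.na(can)) next
    ha <- count_heavy_atoms(can)
    if (ha > config$heavy_atom_cap || ha < config$min_heavy_atoms) next
    if (!is.null(seen[[can]])) next
    st <- grepl("[@/\\\\]", can)
    frac_now <- if (length(out_stereo)) mean(out_stereo) else 0
    if (!st && frac_now < config$stereo_fraction_target) {
      enriched <- enrich_stereo(can)
      if (!is.na(enriched)) { can2 <- enriched
        if (is.null(seen[[can2]])) { can <- can2; st <- TRUE }
      }
    }
    if (!is.null(seen[[can]])) next
    seen[[can]] <- TRUE
    out_smiles <- c(out_smiles, can)
    out_stereo <- c(out_stereo, st)
  }
  data.frame(
    id = sprintf("M%06d", seq_len(n)),
    smiles = out_smiles,
    heavy_atoms = vapply(out_smiles, count_heavy_atoms, integer(1), USE.NAMES = FALSE),
    has_stereo = out_stereo,
    stringsAsFactors = FALSE
  )
}

# try to fix random stereocenters on a molecule; returns canonical SMILES
# with stereo annotations, or NA if none could be realized
enrich_stereo <- function(can_smiles, tries = 8L) {
  g <- tryCatch(mol_graph(can_smiles), error = function(e) NULL)
  if (is.null(g)) return(NA_character_)
  atoms <- g$atoms; bonds <- g$bonds
  tet <- which(atoms$elem == "C" & !atoms$aromatic & atoms$chiral == "" &
                 atoms$degree >= 3L & atoms$nh <= 1L)
  dbl <- which(bonds$order == 2L &
                 atoms$elem[bonds$a1] == "C" & atoms$elem[bonds$a2] == "C" &
                 !atoms$aromatic[bonds$a1] & !atoms$aromatic[bonds$a2])
  cand <- c(paste0("t", tet), paste0("d", dbl))
  if (length(cand) == 0) return(NA_character_)
  for (k in seq_len(tries)) {
    pick <- sample(cand, 1)
    a2 <- atoms; b2 <- bonds
    if (substr(pick, 1, 1) == "t") {
      i <- as.integer(substr(pick, 2, 10))
      a2$chiral[i] <- sample(c("@", "@@"), 1)
    } else {
      bi <- as.integer(substr(pick, 2, 10))
      i <- bonds$a1[bi]; j <- bonds$a2[bi]
      si <- which((b2$a1 == i | b2$a2 == i) & b2$order == 1L)
      sj <- which((b2$a1 == j | b2$a2 == j) & b2$order == 1L)
      if (length(si) == 0 || length(sj) == 0) next
      b2$dir[si[1]] <- "/"
      b2$dir[sj[1]] <- sample(c("/", "\\"), 1)
    }
    smi2 <- tryCatch(write_smiles(a2, b2), error = function(e) NA_character_)
    if (is.na(smi2)) next
    can2 <- canonicalize_smiles(smi2)
    if (!is.na(can2) && grepl("[@/\\\\]", can2)) return(can2)
  }
  NA_character_
}

#' Filter molecule records by heavy-atom count
#'
#' Keeps exactly the records with \code{heavy_atoms <= cap} (inclusive
#' bound), preserving input order.
#'
#' @param mols molecule-record data.frame.
#' @param cap inclusive heavy-atom maximum (>= 1).
#' @return filtered data.frame.
#' @export
filter_by_heavy_atoms <- function(mols, cap) {
  stopifnot(cap >= 1)
  mols[mols$heavy_atoms <= cap, , drop = FALSE]
}

#' Greedy atom-type diversity selection
#'
#' Selects up to \code{budget} candidate molecules maximizing coverage of
#' radius-0 sparse circular features (atom types): at each step the
#' candidate contributing the most features not yet covered by the base
#' set plus previous selections is taken; ties break by input order;
#' selection stops early once no candidate adds a new feature.
#'
#' @param candidates candidate molecule-record data.frame.
#' @param base base molecule-record data.frame whose atom types are
#'   already covered.
#' @param budget maximum number of candidates to select (>= 0).
#' @return the selected subset of \code{candidates} (possibly empty).
#' @export
select_diverse_by_atom_types <- function(candidates, base, budget) {
  stopifnot(budget >= 0)
  if (budget == 0 || nrow(candidates) == 0) {
    return(candidates[integer(0), , drop = FALSE])
  }
  feats <- lapply(candidates$smiles, atom_type_features)
  covered <- unique(unlist(lapply(base$smiles, atom_type_features)))
  chosen <- integer(0)
  remaining <- seq_len(nrow(candidates))
  while (length(chosen) < budget && length(remaining) > 0) {
    gains <- vapply(remaining, function(i) length(setdiff(feats[[i]], covered)),
                    integer(1))
    if (max(gains) == 0L) break
    pick <- remaining[which.max(gains)]   # which.max takes the first tie
    chosen <- c(chosen, pick)
    covered <- union(covered, feats[[pick]])
    remaining <- setdiff(remaining, pick)
  }
  candidates[chosen, , drop = FALSE]
}

# radius-0 sparse circular features = atom types
atom_type_features <- function(smiles) {
  g <- mol_graph(smiles)
  unique(morgan_ids(g, radius = 0L)[[1]])
}

#' Split a corpus into train and test partitions
#'
#' Uniform random split without replacement, deterministic per seed. The
#' partitions are disjoint by canonical SMILES provided the input is
#' (as produced by \code{\link{generate_molecules}}) duplicate-free.
#'
#' @param mols molecule-record data.frame.
#' @param test_size number of molecules to hold out (0..nrow).
#' @param seed RNG seed for the split.
#' @return list of class \code{corpus_split} with elements \code{train},
#'   \code{test}, \code{seed}.
#' @export
split_corpus <- function(mols, test_size, seed = 1L) {
  n <- nrow(mols)
  if (test_size < 0 || test_size > n) {
    stop(sprintf("test_size must be in [0, %d]", n))
  }
  set.seed(seed)
  idx <- if (test_size > 0) sample.int(n, test_size) else integer(0)
  structure(list(train = mols[setdiff(seq_len(n), idx), , drop = FALSE],
                 test = mols[idx, , drop = FALSE],
                 seed = as.integer(seed)),
            class = "corpus_split")
}

#' Read a SMILES file
#'
#' One record per line, \code{SMILES<TAB>ID}; the ID column is optional.
#'
#' @param path file path.
#' @return data.frame with columns \code{smiles} and \code{id}.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(
    smiles = vapply(parts, `[`, character(1), 1),
    id = vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("M%06d", i),
      character(1)),
    stringsAsFactors = FALSE
  )
}

#' Write a SMILES file
#'
#' @param mols data.frame with \code{smiles} and \code{id} columns.
#' @param path file path.
#' @return invisibly, \code{path}.
#' @export
write_smiles_file <- function(mols, path) {
  writeLines(paste0(mols$smiles, "\t", mols$id), path)
  invisible(path)
}

#' Write a corpus manifest (config, counts, seed) as JSON
#'
#' @param config the \code{\link{corpus_config}} used.
#' @param mols the generated molecule records.
#' @param path output JSON path.
#' @return invisibly, \code{path}.
#' @export
write_corpus_manifest <- function(config, mols, path) {
  jsonlite::write_json(list(
    config = unclass(config),
    n_generated = nrow(mols),
    stereo_fraction = if (nrow(mols)) mean(mols$has_stereo) else 0,
    heavy_atom_range = if (nrow(mols)) range(mols$heavy_atoms) else integer(0)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
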