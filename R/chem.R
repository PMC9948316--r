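# Chemistry kernel: canonicalization, validity and molecular graphs.
# Chemical perception (aromaticity, canonical ordering, stereo sanity) is
# delegated to OpenBabel via ChemmineOB/ChemmineR; SMILES syntax handling
# lives in parse.R.

#' Canonicalize SMILES strings
#'
#' Produces the canonical isomeric SMILES form using the OpenBabel
#' canonicalizer, so that Kekule variants and alternative atom enumerations
#' of the same molecule map to a single string. Stereo annotations are
#' removed before canonicalization when \code{keep_stereo = FALSE}.
#'
#' @param smiles character vector of SMILES strings.
#' @param keep_stereo keep stereochemical annotations? Default \code{TRUE}.
#' @return character vector of canonical SMILES; \code{NA} for strings the
#'   kernel cannot parse.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("OCC", "C1=CC=CC=C1"))
#' }
#' @export
canonicalize_smiles <- function(smiles, keep_stereo = TRUE) {
  if (length(smiles) == 0) return(character(0))
  s <- as.character(smiles)
  if (!keep_stereo) s <- strip_stereo_marks(s)
  out <- rep(NA_character_, length(s))
  ok <- !is.na(s) & nzchar(s) & vapply(s, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  if (any(ok)) out[ok] <- ob_canonical(s[ok])
  out
}

# batch conversion through OpenBabel; returns NA where OB drops a record
ob_canonical <- function(s) {
  ids <- sprintf("fp2mol%06d", seq_along(s))
  src <- paste(paste0(s, "\t", ids), collapse = "\n")
  raw <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = src)),
    error = function(e) ""
  )
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  out <- rep(NA_character_, length(s))
  if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    got_id <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[2]) else "", character(1))
    got_smi <- vapply(parts, function(p) trimws(p[1]), character(1))
    m <- match(got_id, ids)
    keep <- !is.na(m) & nzchar(got_smi)
    out[m[keep]] <- got_smi[keep]
  }
  out
}

# remove stereo annotations at the string level: tetrahedral tags inside
# bracket atoms and directional bond marks; brackets that become redundant
# are resolved by the canonicalizer afterwards
strip_stereo_marks <- function(s) {
  s <- gsub("@", "", s, fixed = TRUE)
  s <- gsub("/", "", s, fixed = TRUE)
  gsub("\\", "", s, fixed = TRUE)
}

#' Test chemical validity of molecular strings
#'
#' A SMILES string is valid when it passes syntactic checks (balanced
#' brackets and parentheses, matched ring-closure digits, recognizable
#' atoms) and the chemistry kernel parses it into a molecule. A SELFIES
#' string is valid when it decodes to a molecule; by construction of the
#' robust decoder this holds for every sequence of vocabulary tokens.
#'
#' @param s character vector of molecular strings.
#' @param representation \code{"SMILES"} or \code{"SELFIES"}.
#' @return logical vector.
#' @export
is_valid_molstring <- function(s, representation = c("SMILES", "SELFIES")) {
  representation <- match.arg(representation)
  if (length(s) == 0) return(logical(0))
  if (representation == "SELFIES") {
    smi <- vapply(s, function(x) {
      tryCatch(selfies_decode(x), error = function(e) NA_character_)
    }, character(1), USE.NAMES = FALSE)
    ok <- !is.na(smi) & nzchar(smi)
    ok[ok] <- is_valid_molstring(smi[ok], "SMILES")
    return(ok)
  }
  out <- rep(FALSE, length(s))
  ok <- !is.na(s) & nzchar(s) &
    vapply(s, smiles_syntax_ok, logical(1), USE.NAMES = FALSE)
  if (any(ok)) out[ok] <- !is.na(ob_canonical(s[ok]))
  out
}

#' Construct molecule records from SMILES
#'
#' Canonicalizes each input and derives per-molecule properties. Records
#' that fail to parse are dropped with a warning.
#'
#' @param smiles character vector of SMILES strings.
#' @param id optional character vector of identifiers (default M000001...).
#' @return data.frame with columns \code{id}, \code{smiles} (canonical
#'   isomeric SMILES), \code{heavy_atoms}, \code{has_stereo}.
#' @export
molecule_records <- function(smiles, id = NULL) {
  if (is.null(id)) id <- sprintf("M%06d", seq_along(smiles))
  stopifnot(length(id) == length(smiles))
  can <- canonicalize_smiles(smiles)
  bad <- is.na(can)
  if (any(bad)) {
    warning(sprintf("dropping %d unparseable record(s): %s", sum(bad),
                    paste(utils::head(id[bad], 5), collapse = ", ")))
  }
  can <- can[!bad]; id <- id[!bad]
  data.frame(
    id = id,
    smiles = can,
    heavy_atoms = vapply(can, count_heavy_atoms, integer(1), USE.NAMES = FALSE),
    has_stereo = grepl("[@/\\\\]", can),
    stringsAsFactors = FALSE
  )
}

#' Count non-hydrogen atoms in a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return integer heavy-atom count.
#' @export
count_heavy_atoms <- function(smiles) {
  p <- parse_smiles(smiles)
  sum(p$atoms$elem != "H")
}

# --- molecular graph -------------------------------------------------------

# cache of parsed graphs keyed by SMILES (session-local)
.graph_cache <- new.env(parent = emptyenv())

#' Build a molecular graph from a SMILES string
#'
#' Parses the string, then aligns kekulized bond orders from the chemistry
#' kernel so that aromatic input yields definite single/double orders.
#' The returned graph drives all fingerprint featurizers.
#'
#' @param smiles a single SMILES string.
#' @param cache reuse a session-local cache keyed by the input string?
#' @return list with \code{atoms} (data.frame: elem, aromatic, charge, nh,
#'   degree, in_ring), \code{bonds} (data.frame: a1, a2, order, aromatic)
#'   and \code{dist} (topological distance matrix).
#' @export
mol_graph <- function(smiles, cache = TRUE) {
  if (cache && !is.null(g <- .graph_cache[[smiles]])) return(g)
  p <- parse_smiles(smiles)
  atoms <- p$atoms
  bonds <- p$bonds
  n <- nrow(atoms)
  if (nrow(bonds) > 0 && any(bonds$order == 0L)) {
    # aromatic bonds: take kekulized orders from the kernel's SDF output,
    # whose atom order matches SMILES atom order
    ko <- kekulized_orders(smiles, n)
    for (i in which(bonds$order == 0L)) {
      key <- paste(sort(c(bonds$a1[i], bonds$a2[i])), collapse = "-")
      o <- ko[[key]]
      bonds$order[i] <- if (is.null(o)) 1L else o
    }
  }
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    for (i in seq_len(nrow(bonds))) {
      bsum[bonds$a1[i]] <- bsum[bonds$a1[i]] + bonds$order[i]
      bsum[bonds$a2[i]] <- bsum[bonds$a2[i]] + bonds$order[i]
    }
  }
  nh <- integer(n)
  for (i in seq_len(n)) {
    nh[i] <- if (!is.na(atoms$hcount[i])) atoms$hcount[i] else
      implicit_h(atoms$elem[i], atoms$charge[i], bsum[i])
  }
  atoms$nh <- nh
  atoms$degree <- deg
  g_ig <- igraph::graph_from_data_frame(
    d = if (nrow(bonds)) bonds[, c("a1", "a2")] else data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE, vertices = data.frame(name = seq_len(n))
  )
  atoms$in_ring <- ring_membership(g_ig, n)
  dist <- igraph::distances(g_ig)
  dist <- dist[order(as.integer(rownames(dist))), order(as.integer(colnames(dist))), drop = FALSE]
  g <- list(atoms = atoms, bonds = bonds, dist = dist, smiles = smiles)
  if (cache) .graph_cache[[smiles]] <- g
  g
}

# kekulized bond orders keyed "i-j" (i<j), from the SDF connection table
kekulized_orders <- function(smiles, n_expected) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))
  bb <- ChemmineR::bondblock(sdf[[1]])
  ab <- ChemmineR::atomblock(sdf[[1]])
  if (nrow(ab) < n_expected) stop("kekulization failed for: ", smiles)
  out <- list()
  for (i in seq_len(nrow(bb))) {
    a1 <- as.integer(bb[i, 1]); a2 <- as.integer(bb[i, 2])
    key <- paste(sort(c(a1, a2)), collapse = "-")
    out[[key]] <- as.integer(bb[i, 3])
  }
  out
}

# atoms flagged in a cycle via igraph girth-free approach: an atom is in a
# ring iff removing it does not disconnect each pair of its neighbors, or
# simpler: edge is a bridge test
ring_membership <- function(g_ig, n) {
  if (igraph::ecount(g_ig) == 0) return(rep(FALSE, n))
  bridges <- igraph::bridges(g_ig)
  ring_edges <- setdiff(seq_len(igraph::ecount(g_ig)), as.integer(bridges))
  inring <- rep(FALSE, n)
  if (length(ring_edges)) {
    ends <- igraph::ends(g_ig, ring_edges, names = TRUE)
    inring[as.integer(ends)] <- TRUE
  }
  inring
}

# default-valence implicit hydrogen count for organic-subset atoms
implicit_h <- function(elem, charge, bond_sum) {
  vals <- switch(elem,
    C = 4L, N = c(3L, 5L), O = 2L, S = c(2L, 4L, 6L), P = c(3L, 5L),
    F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L,
    return(0L))
  # charge adjustment: cations gain a bonding slot, anions lose one
  v <- vals + as.integer(charge)
  v <- v[v >= bond_sum]
  if (length(v) == 0) return(0L)
  as.integer(max(0, min(v) - bond_sum))
}

#' Clear the session-local molecular graph cache
#' @return invisibly, the number of entries removed.
#' @export
clear_graph_cache <- function() {
  n <- length(ls(.graph_cache))
  rm(list = ls(.graph_cache), envir = .graph_cache)
  invisible(n)
}
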