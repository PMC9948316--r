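# The thirteen fingerprint featurizers and set-Tanimoto similarity.
# All featurizers operate on the kekulized molecular graph from
# mol_graph(); sparse feature identifiers come from the package-local
# 31-bit FNV hash, hashed variants fold them into the registry bit size.
# Presence-only (set) semantics throughout.

#' The fingerprint registry
#'
#' Exactly thirteen featurizers in five families, with fixed parameters:
#' MACCS (166 predefined keys), Avalon-style paths and feature classes
#' (512 bits), hashed atom pairs (2048 bits, path lengths 1-6), the
#' path-based fingerprint with branched (RDK4) or linear-only (RDK4-L)
#' subgraphs of 2-4 bonds (2048 bits), topological torsions over 4 bonded
#' atoms (sparse, and hashed to 2048), and circular fingerprints: sparse
#' atom environments of radius 1 (AEs), hashed radius 0/1/2 (ECFP0/2/4),
#' and pharmacophoric feature-class variants (FCFP2/4).
#'
#' @return list of \code{fingerprint_spec} objects, in registry order.
#' @export
fingerprint_registry <- function() {
  sp <- function(name, family, hashed, n_bits, params = list()) {
    structure(list(name = name, family = family, hashed = hashed,
                   n_bits = n_bits, params = params),
              class = "fingerprint_spec")
  }
  list(
    sp("MACCS",  "predefined",         TRUE,  166L),
    sp("Avalon", "paths-and-features", TRUE,  512L),
    sp("HashAP", "path-based",         TRUE,  2048L, list(minLength = 1L, maxLength = 6L)),
    sp("RDK4",   "path-based",         TRUE,  2048L, list(minPath = 2L, maxPath = 4L, branched = TRUE)),
    sp("RDK4-L", "path-based",         TRUE,  2048L, list(minPath = 2L, maxPath = 4L, branched = FALSE)),
    sp("TT",     "4-atom-paths",       FALSE, "sparse"),
    sp("HashTT", "4-atom-paths",       TRUE,  2048L),
    sp("AEs",    "circular",           FALSE, "sparse", list(radius = 1L)),
    sp("ECFP0",  "circular",           TRUE,  2048L, list(radius = 0L)),
    sp("ECFP2",  "circular",           TRUE,  2048L, list(radius = 1L)),
    sp("ECFP4",  "circular",           TRUE,  2048L, list(radius = 2L)),
    sp("FCFP2",  "circular",           TRUE,  2048L, list(radius = 1L, feature_invariants = TRUE)),
    sp("FCFP4",  "circular",           TRUE,  2048L, list(radius = 2L, feature_invariants = TRUE))
  )
}

#' Look up one fingerprint spec by name
#' @param name one of the 13 registry names.
#' @return a \code{fingerprint_spec}.
#' @export
fingerprint_spec <- function(name) {
  reg <- fingerprint_registry()
  hit <- Filter(function(s) s$name == name, reg)
  if (length(hit) == 0) stop("unknown fingerprint spec: ", name)
  hit[[1]]
}

# the 15 metric variants: 13 specs + explicit-bit circular sets
METRIC_FP_NAMES <- c("MACCS", "Avalon", "HashAP", "RDK4", "RDK4-L", "TT",
                     "HashTT", "AEs", "ECFP0", "ECFP2", "ECFP4", "FCFP2",
                     "FCFP4", "ECFP2*", "ECFP4*")

#' Names of the 15 similarity-metric fingerprints
#'
#' The 13 registry featurizers plus the explicit-bit (unhashed) variants
#' ECFP2* and ECFP4* of the corresponding circular fingerprints.
#'
#' @return character vector of length 15.
#' @export
metric_fingerprint_names <- function() METRIC_FP_NAMES

# --- invariants ------------------------------------------------------------

# Daylight-style atom invariant for ECFP/AEs
ecfp_invariant <- function(g) {
  a <- g$atoms
  paste(a$elem, a$degree, a$nh, a$charge, as.integer(a$in_ring),
        as.integer(a$aromatic), sep = ",")
}

# pharmacophoric feature classes for FCFP: donor, acceptor, aromatic,
# halogen, basic N, acidic O
fcfp_invariant <- function(g) {
  a <- g$atoms
  n <- nrow(a)
  carbonyl_c <- rep(FALSE, n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      b <- g$bonds[i, ]
      if (b$order == 2L) {
        if (a$elem[b$a1] == "C" && a$elem[b$a2] == "O") carbonyl_c[b$a1] <- TRUE
        if (a$elem[b$a2] == "C" && a$elem[b$a1] == "O") carbonyl_c[b$a2] <- TRUE
      }
    }
  }
  adj_carbonyl <- rep(FALSE, n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      b <- g$bonds[i, ]
      if (carbonyl_c[b$a1]) adj_carbonyl[b$a2] <- TRUE
      if (carbonyl_c[b$a2]) adj_carbonyl[b$a1] <- TRUE
    }
  }
  donor <- a$elem %in% c("N", "O") & a$nh >= 1L
  acceptor <- a$elem %in% c("N", "O") & a$charge <= 0L
  halogen <- a$elem %in% c("F", "Cl", "Br", "I")
  basic <- a$elem == "N" & a$charge >= 0L & !a$aromatic & !adj_carbonyl
  acidic <- a$elem == "O" & (a$charge < 0L | (a$nh >= 1L & adj_carbonyl))
  paste(as.integer(donor), as.integer(acceptor), as.integer(a$aromatic),
        as.integer(halogen), as.integer(basic), as.integer(acidic), sep = ",")
}

# Carhart-style atom type for atom pairs / torsions: element, pi bonds,
# heavy-neighbor count less the k path neighbors
pi_counts <- function(g) {
  n <- nrow(g$atoms)
  np <- integer(n)
  if (nrow(g$bonds)) {
    for (i in seq_len(nrow(g$bonds))) {
      b <- g$bonds[i, ]
      add <- max(0L, b$order - 1L)
      np[b$a1] <- np[b$a1] + add
      np[b$a2] <- np[b$a2] + add
    }
  }
  np
}

carhart_type <- function(g, i, k) {
  paste0(g$atoms$elem[i], ".", pi_counts(g)[i], ".",
         max(0L, g$atoms$degree[i] - k))
}

# --- circular (Morgan) -----------------------------------------------------

# per-radius environment identifiers; returns list radius -> integer vector
# (per atom) of environment ids
morgan_ids <- function(g, radius, invariant = ecfp_invariant) {
  n <- nrow(g$atoms)
  ids <- fnv1a31(paste0("M0|", invariant(g)))
  out <- list(ids)
  if (radius >= 1L && n > 0) {
    nb <- vector("list", n)
    if (nrow(g$bonds)) {
      for (i in seq_len(nrow(g$bonds))) {
        b <- g$bonds[i, ]
        nb[[b$a1]] <- c(nb[[b$a1]], list(c(b$order, b$a2)))
        nb[[b$a2]] <- c(nb[[b$a2]], list(c(b$order, b$a1)))
      }
    }
    for (r in seq_len(radius)) {
      prev <- out[[r]]
      nxt <- integer(n)
      for (i in seq_len(n)) {
        if (length(nb[[i]]) == 0) {
          # an isolated atom's wider environment is its radius-0 environment
          nxt[i] <- prev[i]
          next
        }
        pairs <- vapply(nb[[i]], function(e) sprintf("%d:%d", e[1], prev[e[2]]),
                        character(1))
        key <- paste0("M", r, "|", prev[i], "|",
                      paste(sort(pairs), collapse = ";"))
        nxt[i] <- fnv1a31(key)
      }
      out[[r + 1L]] <- nxt
    }
  }
  out
}

morgan_set <- function(g, radius, invariant = ecfp_invariant) {
  sort(unique(unlist(morgan_ids(g, radius, invariant))))
}

# --- torsions and atom pairs ----------------------------------------------

torsion_set <- function(g) {
  bonds <- g$bonds
  if (nrow(bonds) == 0) return(integer(0))
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
  }
  keys <- character(0)
  for (i in seq_len(nrow(bonds))) {
    b <- bonds$a1[i]; c_ <- bonds$a2[i]
    for (a in setdiff(adj[[b]], c_)) {
      for (d in setdiff(adj[[c_]], c(b, a))) {
        t <- c(carhart_type(g, a, 1L), carhart_type(g, b, 2L),
               carhart_type(g, c_, 2L), carhart_type(g, d, 1L))
        fwd <- paste(t, collapse = "|")
        rev <- paste(rev(t), collapse = "|")
        keys <- c(keys, paste0("TT|", min(fwd, rev)))
      }
    }
  }
  if (length(keys) == 0) return(integer(0))
  sort(unique(fnv1a31(unique(keys))))
}

atom_pair_set <- function(g, min_len = 1L, max_len = 6L) {
  n <- nrow(g$atoms)
  if (n < 2) return(integer(0))
  keys <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- g$dist[i, j]
      if (is.finite(d) && d >= min_len && d <= max_len) {
        ti <- carhart_type(g, i, 1L); tj <- carhart_type(g, j, 1L)
        pr <- sort(c(ti, tj))
        keys <- c(keys, sprintf("AP|%s|%s|%d", pr[1], pr[2], d))
      }
    }
  }
  if (length(keys) == 0) return(integer(0))
  sort(unique(fnv1a31(unique(keys))))
}

# --- path-based ------------------------------------------------------------

# connected bond subgraphs with n_bonds in [min_path, max_path]; branched
# or linear-only; canonical labels are permutation-invariant
path_subgraph_set <- function(g, min_path = 2L, max_path = 4L, branched = TRUE) {
  bonds <- g$bonds
  nb <- nrow(bonds)
  if (nb == 0) return(integer(0))
  elem <- g$atoms$elem
  if (!branched) {
    keys <- linear_path_keys(g, min_path, max_path)
  } else {
    # grow connected edge sets, dedupe by sorted edge index key
    incident <- vector("list", nrow(g$atoms))
    for (i in seq_len(nb)) {
      incident[[bonds$a1[i]]] <- c(incident[[bonds$a1[i]]], i)
      incident[[bonds$a2[i]]] <- c(incident[[bonds$a2[i]]], i)
    }
    seen <- new.env(parent = emptyenv())
    result <- new.env(parent = emptyenv())
    grow <- function(edge_set, atom_set) {
      key <- paste(sort(edge_set), collapse = ",")
      if (!is.null(seen[[key]])) return(invisible(NULL))
      seen[[key]] <- TRUE
      ne <- length(edge_set)
      if (ne >= min_path) result[[key]] <- edge_set
      if (ne >= max_path) return(invisible(NULL))
      cand <- setdiff(unique(unlist(incident[atom_set])), edge_set)
      for (e in cand) grow(c(edge_set, e),
                           unique(c(atom_set, bonds$a1[e], bonds$a2[e])))
      invisible(NULL)
    }
    for (e in seq_len(nb)) grow(e, c(bonds$a1[e], bonds$a2[e]))
    keys <- vapply(ls(result), function(k) subgraph_label(g, result[[k]]),
                   character(1), USE.NAMES = FALSE)
  }
  if (length(keys) == 0) return(integer(0))
  sort(unique(fnv1a31(unique(keys))))
}

# canonical-ish label: sorted multiset of edge descriptors plus the sorted
# within-subgraph degree sequence (relabeling-invariant)
subgraph_label <- function(g, edge_set) {
  bonds <- g$bonds[edge_set, , drop = FALSE]
  elem <- g$atoms$elem
  ed <- vapply(seq_len(nrow(bonds)), function(i) {
    e1 <- elem[bonds$a1[i]]; e2 <- elem[bonds$a2[i]]
    p <- sort(c(e1, e2))
    sprintf("%s-%s:%d", p[1], p[2], bonds$order[i])
  }, character(1))
  atoms <- unique(c(bonds$a1, bonds$a2))
  degs <- vapply(atoms, function(a) sum(bonds$a1 == a | bonds$a2 == a), integer(1))
  paste0("SG|", paste(sort(ed), collapse = ";"), "|",
         paste(sort(degs), collapse = ","))
}

linear_path_keys <- function(g, min_path, max_path) {
  bonds <- g$bonds
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  bidx <- list()
  for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], bonds$a2[i])
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], bonds$a1[i])
    bidx[[paste(sort(c(bonds$a1[i], bonds$a2[i])), collapse = "-")]] <- bonds$order[i]
  }
  elem <- g$atoms$elem
  keys <- character(0)
  walk <- function(path) {
    nbnd <- length(path) - 1L
    if (nbnd >= min_path) {
      lab <- path_label(path, elem, bidx)
      keys <<- c(keys, lab)
    }
    if (nbnd >= max_path) return(invisible(NULL))
    last <- path[length(path)]
    for (v in adj[[last]]) if (!(v %in% path)) walk(c(path, v))
    invisible(NULL)
  }
  for (s in seq_len(n)) walk(s)
  unique(keys)
}

path_label <- function(path, elem, bidx) {
  seg <- function(p) {
    parts <- character(0)
    for (i in seq_len(length(p) - 1L)) {
      o <- bidx[[paste(sort(c(p[i], p[i + 1L])), collapse = "-")]]
      parts <- c(parts, elem[p[i]], as.character(o))
    }
    paste0(paste(parts, collapse = ""), elem[p[length(p)]])
  }
  fwd <- seg(path); rev_ <- seg(rev(path))
  paste0("LP|", min(fwd, rev_))
}

# --- MACCS-inspired keys ---------------------------------------------------

# 166-position substructure key set. Positions are fixed; a documented
# subset of graph predicates is implemented (element presence, ring sizes,
# common functional groups, size and charge features); the remaining
# positions never fire, so vocabularies are corpus-derived.
maccs_set <- function(g) {
  a <- g$atoms; b <- g$bonds
  elem <- a$elem
  has_bond <- function(e1, e2, o) {
    if (nrow(b) == 0) return(FALSE)
    any((elem[b$a1] == e1 & elem[b$a2] == e2 & b$order == o) |
        (elem[b$a1] == e2 & elem[b$a2] == e1 & b$order == o))
  }
  ring_sizes <- graph_ring_sizes(g)
  keys <- integer(0)
  on <- function(pos, cond) if (isTRUE(cond)) keys <<- c(keys, pos)
  on(7L,  any(ring_sizes == 3))
  on(13L, any(ring_sizes == 4))
  on(22L, any(ring_sizes == 5))
  on(26L, any(ring_sizes == 6))
  on(29L, any(ring_sizes == 7))
  on(35L, any(ring_sizes >= 8))
  on(40L, length(ring_sizes) >= 2)
  on(44L, any(elem == "P"))
  on(48L, any(elem == "S"))
  on(52L, any(elem == "N"))
  on(56L, any(elem == "O"))
  on(60L, any(elem == "F"))
  on(64L, any(elem == "Cl"))
  on(68L, any(elem == "Br"))
  on(72L, any(elem == "I"))
  on(76L, sum(elem %in% c("F", "Cl", "Br", "I")) >= 2)
  on(80L, any(a$charge > 0))
  on(84L, any(a$charge < 0))
  on(88L, any(a$aromatic))
  on(92L, any(a$elem == "N" & a$in_ring))
  on(96L, any(a$elem == "O" & a$in_ring))
  on(100L, any(a$elem == "S" & a$in_ring))
  on(104L, has_bond("C", "O", 2L))
  on(108L, has_bond("C", "N", 2L))
  on(112L, has_bond("C", "N", 3L))
  on(116L, has_bond("C", "C", 3L))
  on(120L, has_bond("C", "C", 2L))
  on(124L, has_bond("N", "O", 1L) || has_bond("N", "O", 2L))
  on(128L, has_bond("S", "O", 2L))
  on(132L, any(elem == "O" & a$nh >= 1L))
  on(136L, any(elem == "N" & a$nh >= 2L))
  on(140L, any(elem == "N" & a$nh == 1L))
  on(144L, any(elem == "C" & a$degree >= 4L))
  on(148L, any(elem == "N" & a$degree >= 3L))
  on(150L, carboxyl_present(g))
  on(152L, amide_present(g))
  on(154L, ether_present(g))
  on(156L, sum(elem == "C" & a$nh >= 3L) >= 1)
  on(158L, sum(elem == "C" & a$nh >= 3L) >= 2)
  on(160L, sum(elem == "O") >= 2)
  on(161L, sum(elem == "N") >= 2)
  on(162L, nrow(a) >= 10)
  on(163L, nrow(a) >= 20)
  on(164L, nrow(a) >= 30)
  on(165L, any(a$in_ring))
  sort(unique(keys))
}

# size of the smallest cycle through each ring (non-bridge) edge: the
# shortest path between its endpoints with the edge removed, plus one
graph_ring_sizes <- function(g) {
  if (nrow(g$bonds) == 0) return(integer(0))
  ig <- igraph::graph_from_data_frame(g$bonds[, c("a1", "a2")],
                                      directed = FALSE,
                                      vertices = data.frame(name = seq_len(nrow(g$atoms))))
  bridges <- as.integer(igraph::bridges(ig))
  ring_edges <- setdiff(seq_len(igraph::ecount(ig)), bridges)
  sizes <- integer(0)
  for (e in ring_edges) {
    ends <- igraph::ends(ig, e, names = FALSE)
    g2 <- igraph::delete_edges(ig, e)
    d <- igraph::distances(g2, v = ends[1], to = ends[2])[1, 1]
    if (is.finite(d)) sizes <- c(sizes, as.integer(d) + 1L)
  }
  sort(unique(sizes))
}

carboxyl_present <- function(g) {
  a <- g$atoms; b <- g$bonds
  if (nrow(b) == 0) return(FALSE)
  for (i in which(a$elem == "C")) {
    nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    ords <- c(b$order[b$a1 == i], b$order[b$a2 == i])
    os <- a$elem[nb] == "O"
    if (sum(os) >= 2 && any(ords[os] == 2L) &&
        any(ords[os] == 1L & (a$nh[nb[os]] >= 1L | a$charge[nb[os]] < 0L))) {
      return(TRUE)
    }
  }
  FALSE
}

amide_present <- function(g) {
  a <- g$atoms; b <- g$bonds
  if (nrow(b) == 0) return(FALSE)
  for (i in which(a$elem == "C")) {
    nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    ords <- c(b$order[b$a1 == i], b$order[b$a2 == i])
    if (any(a$elem[nb] == "O" & ords == 2L) && any(a$elem[nb] == "N" & ords == 1L)) {
      return(TRUE)
    }
  }
  FALSE
}

ether_present <- function(g) {
  a <- g$atoms; b <- g$bonds
  for (i in which(a$elem == "O" & a$nh == 0L & a$charge == 0L)) {
    nb <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    if (length(nb) == 2 && all(a$elem[nb] == "C")) return(TRUE)
  }
  FALSE
}

# --- Avalon-style paths and feature classes --------------------------------

avalon_set <- function(g, n_bits = 512L) {
  keys <- character(0)
  a <- g$atoms
  keys <- c(keys, paste0("AV.at|", ecfp_invariant(g)))
  if (nrow(g$bonds)) {
    elem <- a$elem
    keys <- c(keys, vapply(seq_len(nrow(g$bonds)), function(i) {
      p <- sort(c(elem[g$bonds$a1[i]], elem[g$bonds$a2[i]]))
      sprintf("AV.bd|%s-%s:%d", p[1], p[2], g$bonds$order[i])
    }, character(1)))
  }
  keys <- c(keys, paste0("AV.", linear_path_keys(g, 2L, 3L)))
  rs <- graph_ring_sizes(g)
  keys <- c(keys, sprintf("AV.ring|%d", rs))
  keys <- c(keys, sprintf("AV.deg|%s%d", a$elem, a$degree))
  fold_bits(fnv1a31(unique(keys)), n_bits)
}

# --- public featurization surface ------------------------------------------

#' Compute a fingerprint feature set for similarity
#'
#' Returns the set of integer feature identifiers of a molecule under one
#' of the 15 metric fingerprints (13 registry specs plus the explicit-bit
#' circular variants \code{ECFP2*} and \code{ECFP4*}).
#'
#' @param smiles a single SMILES string (or a molecule-record row).
#' @param spec_name one of \code{metric_fingerprint_names()}.
#' @return object of class \code{feature_set}: list with \code{spec_name}
#'   and sorted integer \code{features}.
#' @export
to_feature_set <- function(smiles, spec_name) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles[1]
  if (!spec_name %in% METRIC_FP_NAMES) stop("unknown spec name: ", spec_name)
  g <- mol_graph(smiles)
  feats <- switch(spec_name,
    "MACCS" = maccs_set(g),
    "Avalon" = avalon_set(g),
    "HashAP" = fold_bits(atom_pair_set(g), 2048L),
    "RDK4" = fold_bits(path_subgraph_set(g, branched = TRUE), 2048L),
    "RDK4-L" = fold_bits(path_subgraph_set(g, branched = FALSE), 2048L),
    "TT" = torsion_set(g),
    "HashTT" = fold_bits(torsion_set(g), 2048L),
    "AEs" = morgan_set(g, 1L),
    "ECFP0" = fold_bits(morgan_set(g, 0L), 2048L),
    "ECFP2" = fold_bits(morgan_set(g, 1L), 2048L),
    "ECFP4" = fold_bits(morgan_set(g, 2L), 2048L),
    "FCFP2" = fold_bits(morgan_set(g, 1L, fcfp_invariant), 2048L),
    "FCFP4" = fold_bits(morgan_set(g, 2L, fcfp_invariant), 2048L),
    "ECFP2*" = morgan_set(g, 1L),
    "ECFP4*" = morgan_set(g, 2L)
  )
  structure(list(spec_name = spec_name, features = as.integer(feats)),
            class = "feature_set")
}

#' Featurize a molecule into a fingerprint token sequence
#'
#' The model-facing "sentence": feature identifiers rendered as decimal
#' strings, sorted ascending by numeric value, presence-only (duplicates
#' removed). For hashed specs every token value lies in
#' \code{[0, n_bits)}.
#'
#' @param mol a molecule-record row (or a SMILES string).
#' @param spec a \code{fingerprint_spec} or registry name.
#' @return object of class \code{feature_token_sequence}: list with
#'   \code{spec_name} and character \code{tokens}.
#' @export
featurize <- function(mol, spec) {
  if (is.character(spec)) spec <- fingerprint_spec(spec)
  smiles <- if (is.data.frame(mol)) mol$smiles[1] else mol
  fs <- to_feature_set(smiles, spec$name)
  structure(list(spec_name = spec$name,
                 tokens = as.character(sort(unique(fs$features)))),
            class = "feature_token_sequence")
}

#' Tanimoto similarity between two feature sets
#'
#' \code{|A intersect B| / |A union B|}; defined as 1 when both sets are
#' empty. The two sets must come from the same fingerprint.
#'
#' @param a,b \code{feature_set} objects of the same \code{spec_name}.
#' @return similarity in \code{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  if (!identical(a$spec_name, b$spec_name)) {
    stop("tanimoto requires matching fingerprint specs: ",
         a$spec_name, " vs ", b$spec_name)
  }
  if (length(a$features) == 0 && length(b$features) == 0) return(1.0)
  inter <- length(intersect(a$features, b$features))
  inter / (length(a$features) + length(b$features) - inter)
}

#' Tanimoto similarity between two molecules under a named fingerprint
#'
#' @param smiles_a,smiles_b SMILES strings.
#' @param spec_name one of \code{metric_fingerprint_names()}.
#' @return similarity in \code{[0, 1]}.
#' @export
tanimoto_smiles <- function(smiles_a, smiles_b, spec_name = "AEs") {
  tanimoto(to_feature_set(smiles_a, spec_name),
           to_feature_set(smiles_b, spec_name))
}
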