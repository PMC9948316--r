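# SMILES syntax layer: a structural parser (atoms/bonds/ring closures with
# stereo annotations preserved), the atom-wise tokenizer used for model
# targets, and a SMILES writer used by the SELFIES codec. Syntax only --
# chemical perception stays in chem.R.

ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

#' Parse a SMILES string into atoms and bonds
#'
#' Purely syntactic parse preserving stereo annotations: bracket atoms,
#' organic-subset atoms (aromatic lowercase included), bond symbols,
#' directional marks, branches and ring closures (including \code{\%nn}).
#' Aromatic and colon bonds get order 0, to be kekulized by
#' \code{\link{mol_graph}}.
#'
#' @param s a single SMILES string.
#' @return list with data.frames \code{atoms} (elem, aromatic, charge,
#'   hcount, chiral) and \code{bonds} (a1, a2, order, dir) in input order.
#' @export
parse_smiles <- function(s) {
  if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s)) {
    stop("parse_smiles expects one non-empty string")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- list(); bonds <- list()
  stack <- integer(0)        # branch stack of atom indices
  prev <- 0L                 # index of previous atom (0 = none)
  pend_order <- NA_integer_  # bond symbol seen since last atom
  pend_dir <- ""
  ring <- list()             # open ring closures: num -> list(atom, order, dir)
  i <- 1L
  new_atom <- function(elem, aromatic, charge, hcount, chiral) {
    atoms[[length(atoms) + 1L]] <<- list(elem = elem, aromatic = aromatic,
                                         charge = charge, hcount = hcount,
                                         chiral = chiral)
    length(atoms)
  }
  add_bond <- function(a1, a2, order, dir) {
    bonds[[length(bonds) + 1L]] <<- list(a1 = a1, a2 = a2, order = order, dir = dir)
  }
  attach_atom <- function(idx, aromatic) {
    if (prev > 0L) {
      o <- pend_order
      if (is.na(o)) {
        o <- if (aromatic && atoms[[prev]]$aromatic) 0L else 1L
      }
      add_bond(prev, idx, o, pend_dir)
    }
    prev <<- idx
    pend_order <<- NA_integer_; pend_dir <<- ""
  }
  close_or_open_ring <- function(num) {
    if (prev == 0L) stop("ring closure before any atom")
    key <- as.character(num)
    if (is.null(ring[[key]])) {
      ring[[key]] <<- list(atom = prev, order = pend_order, dir = pend_dir)
    } else {
      op <- ring[[key]]
      if (op$atom == prev) stop("ring closure to self")
      o <- pend_order
      if (is.na(o)) o <- op$order
      if (is.na(o)) {
        o <- if (atoms[[op$atom]]$aromatic && atoms[[prev]]$aromatic) 0L else 1L
      }
      d <- if (nzchar(pend_dir)) pend_dir else op$dir
      add_bond(op$atom, prev, o, d)
      ring[[key]] <<- NULL
    }
    pend_order <<- NA_integer_; pend_dir <<- ""
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unbalanced '[' in SMILES")
      body <- substr(s, i + 1L, j - 1L)
      a <- parse_bracket_atom(body)
      idx <- new_atom(a$elem, a$aromatic, a$charge, a$hcount, a$chiral)
      attach_atom(idx, a$aromatic)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      idx <- new_atom(paste0(ch, chars[i + 1L]), FALSE, 0L, NA_integer_, "")
      attach_atom(idx, FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      idx <- new_atom(ch, FALSE, 0L, NA_integer_, "")
      attach_atom(idx, FALSE)
      i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- new_atom(toupper(ch), TRUE, 0L, NA_integer_, "")
      attach_atom(idx, TRUE)
      i <- i + 1L
    } else if (ch == "-") { pend_order <- 1L; i <- i + 1L
    } else if (ch == "=") { pend_order <- 2L; i <- i + 1L
    } else if (ch == "#") { pend_order <- 3L; i <- i + 1L
    } else if (ch == ":") { pend_order <- 0L; i <- i + 1L
    } else if (ch == "/") { pend_dir <- "/"; i <- i + 1L
    } else if (ch == "\\") { pend_dir <- "\\"; i <- i + 1L
    } else if (ch == "(") {
      if (prev == 0L) stop("branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unbalanced ')' in SMILES")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      close_or_open_ring(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(s, i + 1L, i + 2L))) {
        stop("malformed %nn ring closure")
      }
      close_or_open_ring(as.integer(substr(s, i + 1L, i + 2L)))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- 0L; pend_order <- NA_integer_; pend_dir <- ""
      i <- i + 1L
    } else {
      stop(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(stack) > 0) stop("unbalanced '(' in SMILES")
  if (length(ring) > 0) stop("unmatched ring closure(s)")
  if (length(atoms) == 0) stop("no atoms in SMILES")
  atoms_df <- data.frame(
    elem = vapply(atoms, `[[`, character(1), "elem"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    hcount = vapply(atoms, `[[`, integer(1), "hcount"),
    chiral = vapply(atoms, `[[`, character(1), "chiral"),
    stringsAsFactors = FALSE
  )
  bonds_df <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, `[[`, integer(1), "a1"),
    a2 = vapply(bonds, `[[`, integer(1), "a2"),
    order = vapply(bonds, `[[`, integer(1), "order"),
    dir = vapply(bonds, `[[`, character(1), "dir"),
    stringsAsFactors = FALSE
  ) else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                    dir = character(0), stringsAsFactors = FALSE)
  list(atoms = atoms_df, bonds = bonds_df)
}

parse_bracket_atom <- function(body) {
  m <- regexec("^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H([0-9]*))?(\\+{1,2}|-{1,2}|[+-][0-9]+)?(:[0-9]+)?$",
               body)
  g <- regmatches(body, m)[[1]]
  if (length(g) == 0) stop("malformed bracket atom: [", body, "]")
  sym <- g[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  elem <- if (aromatic) paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, 2)) else sym
  chiral <- g[4]
  hcount <- if (nzchar(g[5])) { if (nzchar(g[6])) as.integer(g[6]) else 1L } else 0L
  charge <- 0L
  cg <- g[7]
  if (nzchar(cg)) {
    charge <- if (cg %in% c("+", "++", "-", "--")) {
      as.integer(nchar(cg)) * (if (substr(cg, 1, 1) == "+") 1L else -1L)
    } else as.integer(cg)
  }
  list(elem = elem, aromatic = aromatic, charge = charge,
       hcount = hcount, chiral = chiral)
}

# quick syntactic acceptability used by validity checks
smiles_syntax_ok <- function(s) {
  !inherits(tryCatch(parse_smiles(s), error = function(e) e), "error")
}

SMILES_TOKEN_RE <- paste0(
  "(\\[[^]]*\\]|Br|Cl|%[0-9]{2}|[BCNOPSFI]|[bcnops]|",
  "[-=#$:/\\\\().+*]|[0-9]|@)"
)

#' Tokenize a SMILES string atom-wise
#'
#' Standard chemistry segmentation: bracket atoms are single tokens, as are
#' two-letter halogens (Cl, Br) and \code{\%nn} ring closures; every other
#' character is its own token. Concatenating the tokens reproduces the
#' input exactly.
#'
#' @param s a single SMILES string.
#' @return character vector of tokens.
#' @examples
#' tokenize_smiles("c1ccccc1")
#' @export
tokenize_smiles <- function(s) {
  stopifnot(is.character(s), length(s) == 1, nzchar(s))
  if (lengths(regmatches(s, gregexpr("[", s, fixed = TRUE))) !=
      lengths(regmatches(s, gregexpr("]", s, fixed = TRUE)))) {
    stop("unbalanced square brackets in SMILES")
  }
  toks <- regmatches(s, gregexpr(SMILES_TOKEN_RE, s, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != s) {
    stop("SMILES contains untokenizable characters: ", s)
  }
  toks
}

#' Tokenize a SELFIES string
#'
#' One token per bracket-enclosed unit; characters outside brackets are an
#' error. The empty string yields an empty sequence.
#'
#' @param s a single SELFIES string.
#' @return character vector of tokens.
#' @export
tokenize_selfies <- function(s) {
  stopifnot(is.character(s), length(s) == 1)
  if (!nzchar(s)) return(character(0))
  toks <- regmatches(s, gregexpr("\\[[^]]*\\]", s, perl = TRUE))[[1]]
  if (paste(toks, collapse = "") != s) {
    stop("stray characters outside SELFIES brackets")
  }
  toks
}

# --- SMILES writer ---------------------------------------------------------

# Write a SMILES string from an explicit structure. `atoms`: data.frame with
# elem, charge, chiral, nh; `bonds`: data.frame with a1, a2, order (1/2/3),
# dir. Neighbor order follows bond insertion order; ring-closure digits are
# emitted immediately after the opening atom.
write_smiles <- function(atoms, bonds) {
  n <- nrow(atoms)
  if (n == 0) return("")
  adj <- vector("list", n)
  if (nrow(bonds)) {
    for (i in seq_len(nrow(bonds))) {
      adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], list(list(nb = bonds$a2[i], b = i)))
      adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], list(list(nb = bonds$a1[i], b = i)))
    }
  }
  visited <- rep(FALSE, n)
  used_bond <- rep(FALSE, max(1, nrow(bonds)))
  ring_at <- vector("list", n)   # per-atom ring digit annotations
  ring_no <- 0L
  # pass 1: classify edges by DFS, assign ring numbers
  tree_children <- vector("list", n)
  order_visit <- integer(0)
  dfs1 <- function(u) {
    visited[u] <<- TRUE
    order_visit <<- c(order_visit, u)
    for (e in adj[[u]]) {
      if (used_bond[e$b]) next
      v <- e$nb
      if (!visited[v]) {
        used_bond[e$b] <<- TRUE
        tree_children[[u]] <<- c(tree_children[[u]], list(e))
        dfs1(v)
      } else {
        used_bond[e$b] <<- TRUE
        ring_no <<- ring_no + 1L
        dig <- if (ring_no <= 9L) as.character(ring_no) else sprintf("%%%02d", ring_no)
        # opening at the earlier-visited atom v, closing at u
        ring_at[[v]] <<- c(ring_at[[v]], list(list(dig = dig, bond = e$b, role = "open")))
        ring_at[[u]] <<- c(ring_at[[u]], list(list(dig = dig, bond = e$b, role = "close")))
      }
    }
  }
  roots <- c()
  for (r in seq_len(n)) if (!visited[r]) { roots <- c(roots, r); dfs1(r) }
  bond_sym <- function(b, with_dir = TRUE) {
    o <- bonds$order[b]
    sym <- if (o == 2L) "=" else if (o == 3L) "#" else ""
    if (with_dir && nzchar(bonds$dir[b])) sym <- paste0(sym, bonds$dir[b])
    sym
  }
  atom_token <- function(u) {
    e <- atoms$elem[u]; ch <- atoms$charge[u]; st <- atoms$chiral[u]
    nh <- atoms$nh[u]
    plain <- e %in% ORGANIC_SUBSET && ch == 0L && !nzchar(st)
    if (plain) return(e)
    hs <- if (nh == 1L) "H" else if (nh > 1L) paste0("H", nh) else ""
    cs <- if (ch > 0L) { if (ch == 1L) "+" else paste0("+", ch) }
          else if (ch < 0L) { if (ch == -1L) "-" else as.character(ch) } else ""
    paste0("[", e, st, hs, cs, "]")
  }
  build <- function(u) {
    out <- atom_token(u)
    for (r in ring_at[[u]]) {
      pre <- if (r$role == "close") bond_sym(r$bond) else ""
      out <- paste0(out, pre, r$dig)
    }
    kids <- tree_children[[u]]
    nk <- length(kids)
    if (nk > 0) {
      for (k in seq_len(nk)) {
        e <- kids[[k]]
        seg <- paste0(bond_sym(e$b), build(e$nb))
        out <- if (k < nk) paste0(out, "(", seg, ")") else paste0(out, seg)
      }
    }
    out
  }
  paste(vapply(roots, build, character(1)), collapse = ".")
}
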