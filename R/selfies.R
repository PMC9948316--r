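# Robust bracket-token molecular string codec (SELFIES-style). Every
# sequence of alphabet tokens decodes to a chemically valid molecule: a
# valence state machine caps bond orders, skips impossible branch/ring
# instructions, and implicit hydrogens absorb leftover valence. Used both
# as the SELFIES target representation and as the synthetic-corpus
# generator's sampling space.

selfies_atom_cores <- function() {
  # core, element, charge, chiral tag, valence capacity
  list(
    list(core = "C",   elem = "C",  charge = 0L,  chiral = "",   cap = 4L),
    list(core = "N",   elem = "N",  charge = 0L,  chiral = "",   cap = 3L),
    list(core = "O",   elem = "O",  charge = 0L,  chiral = "",   cap = 2L),
    list(core = "S",   elem = "S",  charge = 0L,  chiral = "",   cap = 2L),
    list(core = "P",   elem = "P",  charge = 0L,  chiral = "",   cap = 3L),
    list(core = "F",   elem = "F",  charge = 0L,  chiral = "",   cap = 1L),
    list(core = "Cl",  elem = "Cl", charge = 0L,  chiral = "",   cap = 1L),
    list(core = "Br",  elem = "Br", charge = 0L,  chiral = "",   cap = 1L),
    list(core = "N+1", elem = "N",  charge = 1L,  chiral = "",   cap = 4L),
    list(core = "O-1", elem = "O",  charge = -1L, chiral = "",   cap = 1L),
    list(core = "C@",  elem = "C",  charge = 0L,  chiral = "@",  cap = 4L),
    list(core = "C@@", elem = "C",  charge = 0L,  chiral = "@@", cap = 4L)
  )
}

#' The SELFIES-style token alphabet
#'
#' Atom tokens combine an optional bond prefix (\code{=}, \code{#},
#' \code{/}, \code{\\}) with an atom core (organic-subset elements, charged
#' nitrogen/oxygen, tetrahedral-tagged carbon), plus branch and ring
#' tokens. Any sequence drawn from this alphabet decodes to a valid
#' molecule.
#'
#' @return character vector of tokens, in fixed registry order.
#' @export
selfies_alphabet <- function() {
  cores <- selfies_atom_cores()
  toks <- character(0)
  for (a in cores) {
    toks <- c(toks, paste0("[", a$core, "]"))
    if (a$cap >= 2 && !nzchar(a$chiral)) toks <- c(toks, paste0("[=", a$core, "]"))
    if (a$cap >= 3 && !nzchar(a$chiral) && a$elem %in% c("C", "N"))
      toks <- c(toks, paste0("[#", a$core, "]"))
    if (!nzchar(a$chiral))
      toks <- c(toks, paste0("[/", a$core, "]"), paste0("[\\", a$core, "]"))
  }
  c(toks, "[Branch1]", "[=Branch1]", "[Branch2]", "[Ring1]", "[=Ring1]", "[Ring2]")
}

# token -> 0..15 index value (overloaded index alphabet, position mod 16)
selfies_index_value <- function(token) {
  ab <- selfies_alphabet()
  pos <- match(token, ab)
  if (is.na(pos)) 0L else (pos - 1L) %% 16L
}

# first alphabet token whose index value is v (encoder side)
selfies_index_token <- function(v) {
  ab <- selfies_alphabet()
  ab[which(((seq_along(ab) - 1L) %% 16L) == v)[1]]
}

parse_atom_token <- function(token) {
  m <- regexec("^\\[([=#/\\\\]?)(C@@|C@|Cl|Br|N\\+1|O-1|[CNOSPF])\\]$", token)
  g <- regmatches(token, m)[[1]]
  if (length(g) == 0) return(NULL)
  core <- g[3]
  spec <- Filter(function(a) a$core == core, selfies_atom_cores())[[1]]
  order <- switch(g[2], "=" = 2L, "#" = 3L, 1L)
  dir <- if (g[2] %in% c("/", "\\")) g[2] else ""
  list(elem = spec$elem, charge = spec$charge, chiral = spec$chiral,
       cap = spec$cap, order = order, dir = dir)
}

#' Decode a SELFIES-style string to SMILES
#'
#' Robust derivation: bond orders are capped by the remaining valence of
#' both partners, branches and rings that cannot be realized are skipped,
#' and derivation of a chain stops when the current atom's valence is
#' exhausted. The result is always a valid SMILES string (empty only if the
#' sequence contains no atom token).
#'
#' @param s a SELFIES string or a character vector of tokens.
#' @return a single SMILES string.
#' @export
selfies_decode <- function(s) {
  tokens <- if (length(s) == 1 && (grepl("][", s, fixed = TRUE) || grepl("^\\[.*\\]$", s) || !nzchar(s)))
    tokenize_selfies(s) else as.character(s)
  st <- new.env(parent = emptyenv())
  st$atoms <- list(); st$bonds <- list(); st$fv <- integer(0)
  derive_selfies(tokens, st, cur = 0L, first_order = NA_integer_)
  n <- length(st$atoms)
  if (n == 0) return("")
  atoms <- data.frame(
    elem = vapply(st$atoms, `[[`, character(1), "elem"),
    charge = vapply(st$atoms, `[[`, integer(1), "charge"),
    chiral = vapply(st$atoms, `[[`, character(1), "chiral"),
    nh = pmax(0L, st$fv),
    stringsAsFactors = FALSE
  )
  # plain organic atoms take default implicit H; explicit nh only matters
  # for bracket atoms (charged or chiral), where nh = leftover valence
  bonds <- if (length(st$bonds)) data.frame(
    a1 = vapply(st$bonds, `[[`, integer(1), "a1"),
    a2 = vapply(st$bonds, `[[`, integer(1), "a2"),
    order = vapply(st$bonds, `[[`, integer(1), "order"),
    dir = vapply(st$bonds, `[[`, character(1), "dir"),
    stringsAsFactors = FALSE
  ) else data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
                    dir = character(0), stringsAsFactors = FALSE)
  write_smiles(atoms, bonds)
}

# core derivation loop; mutates st; returns invisibly
derive_selfies <- function(tokens, st, cur, first_order) {
  i <- 1L
  n <- length(tokens)
  take_index <- function() {
    if (i > n) return(NA_integer_)
    v <- selfies_index_value(tokens[i]); i <<- i + 1L
    v
  }
  while (i <= n) {
    tok <- tokens[i]
    at <- parse_atom_token(tok)
    if (!is.null(at)) {
      i <- i + 1L
      if (cur == 0L) {
        st$atoms[[length(st$atoms) + 1L]] <- at
        st$fv <- c(st$fv, at$cap)
        cur <- length(st$atoms)
      } else {
        if (st$fv[cur] <= 0L) break
        b <- at$order
        if (!is.na(first_order)) { b <- max(b, first_order) }
        b <- min(b, st$fv[cur], at$cap)
        st$atoms[[length(st$atoms) + 1L]] <- at
        st$fv <- c(st$fv, at$cap)
        new <- length(st$atoms)
        st$bonds[[length(st$bonds) + 1L]] <-
          list(a1 = cur, a2 = new, order = b, dir = at$dir)
        st$fv[cur] <- st$fv[cur] - b
        st$fv[new] <- st$fv[new] - b
        cur <- new
      }
      first_order <- NA_integer_
    } else if (tok %in% c("[Branch1]", "[=Branch1]", "[Branch2]")) {
      i <- i + 1L
      k <- if (tok == "[Branch2]") 2L else 1L
      vs <- integer(0)
      for (kk in seq_len(k)) { v <- take_index(); if (!is.na(v)) vs <- c(vs, v) }
      if (length(vs) < k) break
      L <- if (k == 1L) vs[1] + 1L else 16L * vs[1] + vs[2] + 1L
      L <- min(L, n - i + 1L)
      if (L >= 1L && cur > 0L && st$fv[cur] >= 2L) {
        bo <- if (tok == "[=Branch1]") 2L else NA_integer_
        sub <- tokens[i:(i + L - 1L)]
        # branch derivation starts attached to the current atom
        st_sub_cur <- cur
        derive_branch(sub, st, st_sub_cur, bo)
      }
      i <- i + max(0L, L)
    } else if (tok %in% c("[Ring1]", "[=Ring1]", "[Ring2]")) {
      i <- i + 1L
      k <- if (tok == "[Ring2]") 2L else 1L
      vs <- integer(0)
      for (kk in seq_len(k)) { v <- take_index(); if (!is.na(v)) vs <- c(vs, v) }
      if (length(vs) < k) break
      off <- if (k == 1L) vs[1] + 1L else 16L * vs[1] + vs[2] + 1L
      if (cur > 0L) {
        tgt <- cur - off
        if (tgt >= 1L) {
          dup <- any(vapply(st$bonds, function(b)
            (b$a1 == tgt && b$a2 == cur) || (b$a1 == cur && b$a2 == tgt), logical(1)))
          bo <- if (tok == "[=Ring1]") 2L else 1L
          b <- min(bo, st$fv[cur], st$fv[tgt])
          if (!dup && b >= 1L) {
            st$bonds[[length(st$bonds) + 1L]] <-
              list(a1 = tgt, a2 = cur, order = b, dir = "")
            st$fv[cur] <- st$fv[cur] - b
            st$fv[tgt] <- st$fv[tgt] - b
          }
        }
      }
    } else {
      # unknown/index token in derivation position: skip (robustness)
      i <- i + 1L
    }
  }
  invisible(NULL)
}

derive_branch <- function(tokens, st, cur, first_order) {
  derive_selfies(tokens, st, cur = cur, first_order = first_order)
}

#' Encode a SMILES string as a SELFIES-style string
#'
#' Kekulizes the molecule, walks its parse tree depth-first and emits atom,
#' branch and ring tokens. Only molecules within the codec alphabet
#' (C, N, O, S, P, F, Cl, Br; charges on N+/O-; tetrahedral tags on carbon)
#' are encodable. Decoding the result reconstructs an equivalent molecule.
#'
#' @param smiles a single SMILES string.
#' @return a SELFIES string.
#' @export
selfies_encode <- function(smiles) {
  g <- mol_graph(smiles)
  atoms <- g$atoms; bonds <- g$bonds
  ok_core <- function(i) {
    e <- atoms$elem[i]; ch <- atoms$charge[i]; st <- atoms$chiral[i]
    if (nzchar(st) && e != "C") return(FALSE)
    if (ch == 0L) return(e %in% c("C", "N", "O", "S", "P", "F", "Cl", "Br"))
    (e == "N" && ch == 1L) || (e == "O" && ch == -1L)
  }
  if (!all(vapply(seq_len(nrow(atoms)), ok_core, logical(1)))) {
    stop("molecule outside the SELFIES codec alphabet: ", smiles)
  }
  n <- nrow(atoms)
  adj <- vector("list", n)
  if (nrow(bonds)) for (i in seq_len(nrow(bonds))) {
    adj[[bonds$a1[i]]] <- c(adj[[bonds$a1[i]]], list(list(nb = bonds$a2[i], b = i)))
    adj[[bonds$a2[i]]] <- c(adj[[bonds$a2[i]]], list(list(nb = bonds$a1[i], b = i)))
  }
  visited <- rep(FALSE, n)
  used <- rep(FALSE, max(1, nrow(bonds)))
  pos <- integer(n)          # creation order position
  counter <- 0L
  atom_core <- function(i) {
    e <- atoms$elem[i]; ch <- atoms$charge[i]; st <- atoms$chiral[i]
    if (nzchar(st)) paste0("C", st)
    else if (ch == 1L) "N+1"
    else if (ch == -1L) "O-1"
    else e
  }
  atom_tok <- function(i, order, dir) {
    pre <- if (order == 2L) "=" else if (order == 3L) "#" else if (nzchar(dir)) dir else ""
    core <- atom_core(i)
    tok <- paste0("[", pre, core, "]")
    if (!(tok %in% selfies_alphabet())) tok <- paste0("[", core, "]")
    tok
  }
  index_toks <- function(v, k) {
    if (k == 1L) selfies_index_token(v)
    else c(selfies_index_token(v %/% 16L), selfies_index_token(v %% 16L))
  }
  # pass 1: DFS classifies tree vs ring-closure edges and fixes visit order
  tree_kids <- vector("list", n)
  ring_close <- vector("list", n)   # at the later-visited atom
  dfs1 <- function(u) {
    visited[u] <<- TRUE
    counter <<- counter + 1L
    pos[u] <<- counter
    for (e in adj[[u]]) {
      if (used[e$b]) next
      v <- e$nb
      if (!visited[v]) {
        used[e$b] <<- TRUE
        tree_kids[[u]] <<- c(tree_kids[[u]], list(e))
        dfs1(v)
      } else {
        used[e$b] <<- TRUE
        ring_close[[u]] <<- c(ring_close[[u]], list(list(open = v, b = e$b)))
      }
    }
  }
  # pass 2: emit tokens; decode creates atoms in this same order, so ring
  # offsets are measured in visit positions
  emit <- function(u, in_order, in_dir) {
    out <- atom_tok(u, in_order, in_dir)
    for (r in ring_close[[u]]) {
      off <- pos[u] - pos[r$open] - 1L
      o <- bonds$order[r$b]
      rt <- if (off <= 15L) {
        c(if (o >= 2L) "[=Ring1]" else "[Ring1]", index_toks(off, 1L))
      } else {
        c("[Ring2]", index_toks(min(off, 255L), 2L))
      }
      out <- c(out, rt)
    }
    kids <- tree_kids[[u]]
    nk <- length(kids)
    for (k in seq_len(nk)) {
      e <- kids[[k]]
      sub <- emit(e$nb, bonds$order[e$b], bonds$dir[e$b])
      if (k < nk) {
        L <- length(sub)
        btok <- if (bonds$order[e$b] >= 2L) "[=Branch1]" else "[Branch1]"
        if (L <= 16L) {
          out <- c(out, btok, index_toks(L - 1L, 1L), sub)
        } else {
          out <- c(out, "[Branch2]", index_toks(min(L - 1L, 255L), 2L), sub)
        }
      } else {
        out <- c(out, sub)
      }
    }
    out
  }
  dfs1(1L)
  if (any(!visited)) stop("disconnected molecules are not encodable")
  paste(emit(1L, 1L, ""), collapse = "")
}

#' Sample random SELFIES token sequences
#'
#' Draws token sequences from the codec alphabet with atom-heavy weights
#' (a carbon-rich organic distribution with occasional branches, rings,
#' heteroatoms, charges and stereo tags). The first token is always an
#' atom token, so every sampled sequence decodes to a non-empty molecule.
#' Randomness comes from R's RNG; seed with \code{set.seed}.
#'
#' @param n_tokens integer length of the sequence.
#' @return character vector of tokens.
#' @export
sample_selfies_tokens <- function(n_tokens) {
  ab <- selfies_alphabet()
  w <- rep(1, length(ab))
  names(w) <- ab
  w["[C]"] <- 30; w["[=C]"] <- 4; w["[N]"] <- 5; w["[O]"] <- 6
  w["[=O]"] <- 3; w["[S]"] <- 1.5; w["[F]"] <- 1.5
  w["[Branch1]"] <- 8; w["[Ring1]"] <- 6; w["[=Branch1]"] <- 2
  w["[C@]"] <- 1.2; w["[C@@]"] <- 1.2
  first <- sample(c("[C]", "[N]", "[O]"), 1, prob = c(0.8, 0.1, 0.1))
  if (n_tokens <= 1L) return(first)
  c(first, sample(ab, n_tokens - 1L, replace = TRUE, prob = w))
}
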