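#' Read a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms (charge, explicit hydrogens,
#' tetrahedral `@`/`@@` tags, atom-map numbers), ring closures (including
#' `%nn`), branches, directional bonds and dot-separated components.
#' Implicit hydrogen counts are resolved at parse time, so a `mol_graph`
#' always carries total hydrogen counts.
#'
#' Tetrahedral tags are normalised to a neighbour order sorted by atom index
#' (implicit hydrogen first), so parity survives later atom reordering.
#'
#' @param smiles a single SMILES string.
#' @return A [mol_graph()].
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop("parse_smiles() expects a single SMILES string", call. = FALSE)
  }
  s <- trimws(smiles)
  if (s == "") stop("empty SMILES", call. = FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  np <- length(ch)

  atoms <- list()   # each: list(symbol, charge, hcount (NA = implicit), aromatic, chiral, map)
  nbrs  <- list()   # SMILES-order neighbour lists (0 = implicit H placeholder)
  bonds_u <- integer(); bonds_v <- integer()
  bonds_order <- character(); bonds_dir <- character()

  prev <- NA_integer_
  stack <- integer()
  pend_order <- ""      # pending explicit bond symbol
  pend_dir <- ""
  rings <- list()       # digit -> list(atom, order, dir, slot)

  two_letter <- c("Cl", "Br", "Si", "Se", "Sn", "Mg", "Zn", "Cu", "Na", "Li", "Al")
  organic <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

  add_atom <- function(symbol, charge, hcount, aromatic, chiral, map) {
    atoms[[length(atoms) + 1L]] <<- list(symbol = symbol, charge = charge,
                                         hcount = hcount, aromatic = aromatic,
                                         chiral = chiral, map = map)
    nbrs[[length(atoms)]] <<- integer()
    length(atoms)
  }
  add_bond <- function(u, v, order, dir, u_slot = NA_integer_) {
    bonds_u <<- c(bonds_u, u); bonds_v <<- c(bonds_v, v)
    bonds_order <<- c(bonds_order, order); bonds_dir <<- c(bonds_dir, dir)
    # neighbour bookkeeping (slot: pre-reserved ring position on u)
    if (is.na(u_slot)) nbrs[[u]] <<- c(nbrs[[u]], v) else nbrs[[u]][u_slot] <<- v
    nbrs[[v]] <<- c(nbrs[[v]], u)
  }
  connect <- function(idx) {
    if (!is.na(prev)) {
      arom_pair <- atoms[[prev]]$aromatic && atoms[[idx]]$aromatic
      ord <- if (pend_order == "") {
        if (arom_pair) "aromatic" else "single"
      } else pend_order
      add_bond(prev, idx, ord, pend_dir)
    }
    prev <<- idx
    pend_order <<- ""; pend_dir <<- ""
  }
  ring_digit <- function(d) {
    key <- as.character(d)
    if (is.null(rings[[key]])) {
      # reserve the neighbour slot now so chirality order is correct
      nbrs[[prev]] <<- c(nbrs[[prev]], -d)
      rings[[key]] <<- list(atom = prev, order = pend_order, dir = pend_dir,
                            slot = length(nbrs[[prev]]))
    } else {
      op <- rings[[key]]
      ord <- if (pend_order != "") pend_order else op$order
      if (op$order != "" && pend_order != "" && op$order != pend_order) {
        stop("ring closure bond order mismatch in ", smiles, call. = FALSE)
      }
      if (ord == "") {
        arom_pair <- atoms[[op$atom]]$aromatic && atoms[[prev]]$aromatic
        ord <- if (arom_pair) "aromatic" else "single"
      }
      dir <- if (op$dir != "") op$dir else flip_dir(pend_dir)
      add_bond(op$atom, prev, ord, dir, u_slot = op$slot)
      rings[[key]] <<- NULL
    }
    pend_order <<- ""; pend_dir <<- ""
  }

  i <- 1L
  while (i <= np) {
    c1 <- ch[i]
    if (c1 == " ") { i <- i + 1L; next }
    if (c1 == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (c1 == ")") {
      if (!length(stack)) stop("unbalanced ')' in ", smiles, call. = FALSE)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (c1 == ".") { prev <- NA_integer_; pend_order <- ""; pend_dir <- ""; i <- i + 1L; next }
    if (c1 %in% c("-", "=", "#", ":", "~")) {
      pend_order <- switch(c1, "-" = "single", "=" = "double",
                           "#" = "triple", ":" = "aromatic", "~" = "single")
      i <- i + 1L; next
    }
    if (c1 == "/") { pend_dir <- "up"; pend_order <- "single"; i <- i + 1L; next }
    if (c1 == "\\") { pend_dir <- "down"; pend_order <- "single"; i <- i + 1L; next }
    if (grepl("[0-9]", c1)) { ring_digit(as.integer(c1)); i <- i + 1L; next }
    if (c1 == "%") {
      if (i + 2L > np) stop("truncated %nn ring closure in ", smiles, call. = FALSE)
      ring_digit(as.integer(paste0(ch[i + 1L], ch[i + 2L])))
      i <- i + 3L; next
    }
    if (c1 == "[") {
      j <- i + 1L
      while (j <= np && ch[j] != "]") j <- j + 1L
      if (j > np) stop("unclosed bracket atom in ", smiles, call. = FALSE)
      body <- paste(ch[(i + 1L):(j - 1L)], collapse = "")
      at <- parse_bracket_atom(body, smiles)
      idx <- add_atom(at$symbol, at$charge, at$hcount, at$aromatic, at$chiral, at$map)
      connect(idx)
      if (at$hcount > 0L && at$chiral != "") {
        # implicit-H placeholder occupies the position right after the
        # preceding atom (or first position when the atom opens a chain)
        pos <- length(nbrs[[idx]]) + 1L   # == 1 at chain start, 2 otherwise
        nbrs[[idx]] <- append(nbrs[[idx]], 0L, after = pos - 1L)
      }
      i <- j + 1L; next
    }
    # organic-subset atom (possibly two-letter, possibly aromatic lowercase)
    sym2 <- if (i < np) paste0(c1, ch[i + 1L]) else ""
    if (sym2 %in% c("Cl", "Br")) {
      idx <- add_atom(sym2, 0L, NA_integer_, FALSE, "", 0L)
      connect(idx); i <- i + 2L; next
    }
    if (c1 %in% organic) {
      idx <- add_atom(c1, 0L, NA_integer_, FALSE, "", 0L)
      connect(idx); i <- i + 1L; next
    }
    if (c1 %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(c1), 0L, NA_integer_, TRUE, "", 0L)
      connect(idx); i <- i + 1L; next
    }
    stop(sprintf("unexpected character '%s' in SMILES '%s'", c1, smiles),
         call. = FALSE)
  }
  if (length(rings)) stop("unclosed ring bond in ", smiles, call. = FALSE)
  if (length(stack)) stop("unbalanced '(' in ", smiles, call. = FALSE)
  if (!length(atoms)) stop("empty SMILES", call. = FALSE)

  adf <- data.frame(
    symbol = vapply(atoms, `[[`, "", "symbol"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    hcount = vapply(atoms, `[[`, NA_integer_, "hcount"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    chiral = vapply(atoms, `[[`, "", "chiral"),
    map = vapply(atoms, `[[`, 0L, "map"),
    stringsAsFactors = FALSE
  )
  bdf <- data.frame(u = bonds_u, v = bonds_v, order = bonds_order,
                    dir = bonds_dir, stringsAsFactors = FALSE)

  # an unannotated bond between two aromatic atoms defaults to aromatic, but
  # aromatic bonds only exist inside rings: demote acyclic ones (the biaryl
  # link bond that canonical writers emit without an explicit '-') to single
  if (any(bdf$order == "aromatic")) {
    gtmp <- structure(list(atoms = adf, bonds = bdf), class = "mol_graph")
    demote <- bdf$order == "aromatic" & !bonds_in_ring(gtmp)
    bdf$order[demote] <- "single"
  }

  # resolve implicit hydrogens for organic-subset atoms
  bs <- numeric(nrow(adf))
  if (nrow(bdf)) {
    val <- bond_order_value(bdf$order)
    for (k in seq_len(nrow(bdf))) {
      bs[bdf$u[k]] <- bs[bdf$u[k]] + val[k]
      bs[bdf$v[k]] <- bs[bdf$v[k]] + val[k]
    }
  }
  for (a in which(is.na(adf$hcount))) {
    adf$hcount[a] <- implicit_h_fill(adf$symbol[a], adf$charge[a], bs[a])
  }

  # normalise chirality to sorted neighbour order (0 = implicit H first)
  for (a in which(adf$chiral != "")) {
    ord <- nbrs[[a]]
    if (any(ord < 0L)) stop("internal: unresolved ring slot", call. = FALSE)
    if (length(ord) < 3L) { adf$chiral[a] <- ""; next }
    perm <- order(ord)
    if (permutation_parity(perm) == -1L) {
      adf$chiral[a] <- if (adf$chiral[a] == "@") "@@" else "@"
    }
  }
  mol_graph(adf, bdf)
}

parse_bracket_atom <- function(body, smiles) {
  pat <- paste0(
    "^([0-9]*)",
    "(Cl|Br|Si|Se|Sn|Mg|Zn|Cu|Na|Li|Al|Fe|[A-IK-PR-Z][a-z]?|se|as|[bcnops])",
    "(@@|@)?(H[0-9]*)?([+-][0-9]*)?(:[0-9]+)?$")
  mm <- regexec(pat, body)
  if (mm[[1]][1] == -1L) {
    stop(sprintf("cannot parse bracket atom '[%s]' in '%s'", body, smiles),
         call. = FALSE)
  }
  parts <- regmatches(body, mm)[[1]]
  sym <- parts[3]
  aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
  symbol <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
  } else sym
  chiral <- parts[4]
  hpart <- parts[5]
  hcount <- if (hpart == "") 0L else if (hpart == "H") 1L
  else as.integer(substring(hpart, 2))
  cpart <- parts[6]
  charge <- if (cpart == "") 0L
  else if (cpart == "+") 1L
  else if (cpart == "-") -1L
  else {
    mag <- as.integer(substring(cpart, 2))
    if (substr(cpart, 1, 1) == "+") mag else -mag
  }
  mpart <- parts[7]
  map <- if (mpart == "") 0L else as.integer(substring(mpart, 2))
  list(symbol = symbol, charge = charge, hcount = hcount,
       aromatic = aromatic, chiral = chiral, map = map)
}

permutation_parity <- function(perm) {
  inv <- 0L
  k <- length(perm)
  for (i in seq_len(k - 1L)) {
    inv <- inv + sum(perm[(i + 1L):k] < perm[i])
  }
  if (inv %% 2L == 0L) 1L else -1L
}


#' Write a molecular graph as a SMILES string
#'
#' Emits every atom in bracket form with its explicit hydrogen count, so the
#' output is unambiguous and round-trips through [parse_smiles()] and through
#' OpenBabel without valence reinterpretation. Atoms are traversed in index
#' order (depth-first within components), so the string is a deterministic
#' function of the graph; it is not canonical — see [canonical_smiles()].
#'
#' @param g a [mol_graph()].
#' @param keep_maps write atom-map numbers (default `TRUE`).
#' @return A SMILES string.
#' @export
write_smiles <- function(g, keep_maps = TRUE) {
  n <- n_atoms(g)
  if (n == 0L) return("")
  m <- n_bonds(g)
  adj <- vector("list", n)
  if (m) {
    for (i in seq_len(m)) {
      adj[[g$bonds$u[i]]] <- c(adj[[g$bonds$u[i]]], i)
      adj[[g$bonds$v[i]]] <- c(adj[[g$bonds$v[i]]], i)
    }
  }
  other_end <- function(bi, a) if (g$bonds$u[bi] == a) g$bonds$v[bi] else g$bonds$u[bi]

  ## pass 1: DFS tree (children per atom, ascending index) + ring bonds
  roots <- integer()
  parent_bond <- rep(NA_integer_, n)
  children <- lapply(seq_len(n), function(i) integer())
  ring_open <- lapply(seq_len(n), function(i) integer())
  ring_close <- lapply(seq_len(n), function(i) integer())
  seen_atom <- logical(n)
  seen_bond <- logical(max(m, 1L))
  dfs <- function(a) {
    seen_atom[a] <<- TRUE
    inc <- adj[[a]]
    if (length(inc) > 1L) inc <- inc[order(vapply(inc, other_end, 0L, a = a))]
    for (bi in inc) {
      if (seen_bond[bi]) next
      b <- other_end(bi, a)
      if (seen_atom[b]) {
        seen_bond[bi] <<- TRUE
        ring_open[[b]] <<- c(ring_open[[b]], bi)
        ring_close[[a]] <<- c(ring_close[[a]], bi)
      } else {
        seen_bond[bi] <<- TRUE
        parent_bond[b] <<- bi
        children[[a]] <<- c(children[[a]], bi)
        dfs(b)
      }
    }
  }
  for (r in seq_len(n)) if (!seen_atom[r]) { roots <- c(roots, r); dfs(r) }
  roots <- unique(roots[seen_atom[roots]])
  roots <- roots[!duplicated(roots)]

  ring_digit_of <- integer(max(m, 1L))
  next_digit <- 0L

  bond_char <- function(bi, from) {
    b <- g$bonds[bi, ]
    if (b$dir != "") {
      d <- if (b$u == from) b$dir else flip_dir(b$dir)
      return(if (d == "up") "/" else "\\")
    }
    switch(b$order,
      double = "=", triple = "#", aromatic = "",
      single = {
        other <- other_end(bi, from)
        if (g$atoms$aromatic[from] && g$atoms$aromatic[other]) "-" else ""
      })
  }

  atom_token <- function(a, chiral_tag) {
    at <- g$atoms[a, ]
    sym <- if (at$aromatic) tolower(at$symbol) else at$symbol
    h <- if (at$hcount == 0L) "" else if (at$hcount == 1L) "H" else paste0("H", at$hcount)
    q <- if (at$charge == 0L) ""
    else if (at$charge == 1L) "+" else if (at$charge == -1L) "-"
    else if (at$charge > 0L) paste0("+", at$charge) else as.character(at$charge)
    mp <- if (keep_maps && at$map > 0L) paste0(":", at$map) else ""
    paste0("[", sym, chiral_tag, h, q, mp, "]")
  }

  emit <- function(a) {
    pb <- parent_bond[a]
    write_order <- integer()
    if (!is.na(pb)) write_order <- c(write_order, other_end(pb, a))
    if (g$atoms$hcount[a] > 0L && g$atoms$chiral[a] != "") {
      write_order <- c(write_order, 0L)
    }
    ring_tokens <- ""
    for (bi in ring_open[[a]]) {
      next_digit <<- next_digit + 1L
      ring_digit_of[bi] <<- next_digit
      d <- next_digit
      dtok <- if (d > 9L) sprintf("%%%02d", d) else as.character(d)
      ring_tokens <- paste0(ring_tokens, bond_char(bi, a), dtok)
      write_order <- c(write_order, other_end(bi, a))
    }
    for (bi in ring_close[[a]]) {
      d <- ring_digit_of[bi]
      dtok <- if (d > 9L) sprintf("%%%02d", d) else as.character(d)
      ring_tokens <- paste0(ring_tokens, dtok)
      write_order <- c(write_order, other_end(bi, a))
    }
    for (bi in children[[a]]) write_order <- c(write_order, other_end(bi, a))

    chiral_tag <- ""
    if (g$atoms$chiral[a] != "" && length(write_order) >= 3L) {
      tag <- g$atoms$chiral[a]
      if (permutation_parity(order(write_order)) == -1L) {
        tag <- if (tag == "@") "@@" else "@"
      }
      chiral_tag <- tag
    }
    out <- paste0(atom_token(a, chiral_tag), ring_tokens)
    kids <- children[[a]]
    nk <- length(kids)
    if (nk) {
      sub <- character(nk)
      for (k in seq_len(nk)) {
        bi <- kids[k]
        frag <- paste0(bond_char(bi, a), emit(other_end(bi, a)))
        sub[k] <- if (k < nk) paste0("(", frag, ")") else frag
      }
      out <- paste0(out, paste(sub, collapse = ""))
    }
    out
  }

  paste(vapply(roots, emit, ""), collapse = ".")
}
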