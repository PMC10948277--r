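#' Attributed molecular graphs
#'
#' A `mol_graph` is the universal substrate of the package: a light-weight
#' attributed graph with atoms (element, formal charge, total hydrogen count,
#' aromatic flag, chirality tag, atom-map number) and bonds (endpoints, order,
#' directional/stereo annotation). Atom indices are contiguous `1..n`; bonds
#' are stored once per unordered pair with `u < v`, and bond row order is the
#' frozen bond enumeration used for entity indexing.
#'
#' @param atoms data frame with columns `symbol`, `charge`, `hcount`,
#'   `aromatic`, `chiral`, `map`.
#' @param bonds data frame with columns `u`, `v`, `order`
#'   (one of `"single"`, `"double"`, `"triple"`, `"aromatic"`) and `dir`
#'   (`""`, `"up"`, `"down"`; direction is relative to `u -> v`).
#' @return An object of class `mol_graph`.
#' @export
mol_graph <- function(atoms, bonds = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("symbol", "charge", "hcount", "aromatic", "chiral", "map")
  for (col in setdiff(need, names(atoms))) {
    atoms[[col]] <- switch(col,
      charge = 0L, hcount = 0L, map = 0L,
      aromatic = FALSE, chiral = "", symbol = stop("atoms need a symbol column")
    )
  }
  atoms <- atoms[need]
  atoms$charge <- as.integer(atoms$charge)
  atoms$hcount <- as.integer(atoms$hcount)
  atoms$map <- as.integer(atoms$map)
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(u = integer(), v = integer(),
                        order = character(), dir = character(),
                        stringsAsFactors = FALSE)
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$dir)) bonds$dir <- rep("", nrow(bonds))
    swap <- bonds$u > bonds$v
    if (any(swap)) {
      tmp <- bonds$u[swap]; bonds$u[swap] <- bonds$v[swap]; bonds$v[swap] <- tmp
      bonds$dir[swap] <- flip_dir(bonds$dir[swap])
    }
    bonds <- bonds[c("u", "v", "order", "dir")]
    bonds$u <- as.integer(bonds$u); bonds$v <- as.integer(bonds$v)
  }
  g <- structure(list(atoms = atoms, bonds = bonds), class = "mol_graph")
  validate_mol_graph(g)
  g
}

flip_dir <- function(d) {
  out <- d
  out[d == "up"] <- "down"
  out[d == "down"] <- "up"
  out
}

validate_mol_graph <- function(g) {
  n <- nrow(g$atoms); b <- g$bonds
  if (nrow(b)) {
    if (any(b$u < 1L | b$v > n | b$u == b$v)) {
      stop("mol_graph: bond references an invalid atom", call. = FALSE)
    }
    if (anyDuplicated(paste(b$u, b$v))) {
      stop("mol_graph: duplicate bond between an atom pair", call. = FALSE)
    }
    if (!all(b$order %in% c("single", "double", "triple", "aromatic"))) {
      stop("mol_graph: unknown bond order", call. = FALSE)
    }
  }
  invisible(g)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d atoms, %d bonds: %s\n",
              n_atoms(x), n_bonds(x), write_smiles(x)))
  invisible(x)
}

#' @rdname mol_graph
#' @param g a `mol_graph`.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' @rdname mol_graph
#' @export
n_bonds <- function(g) nrow(g$bonds)

bond_order_value <- function(order) {
  unname(c(single = 1, double = 2, triple = 3, aromatic = 1.5)[order])
}

# Sum of bond orders incident to each atom (aromatic counts 1.5).
atom_bond_sums <- function(g) {
  s <- numeric(n_atoms(g))
  if (nrow(g$bonds)) {
    val <- bond_order_value(g$bonds$order)
    for (i in seq_len(nrow(g$bonds))) {
      s[g$bonds$u[i]] <- s[g$bonds$u[i]] + val[i]
      s[g$bonds$v[i]] <- s[g$bonds$v[i]] + val[i]
    }
  }
  s
}

# Standard valences of the organic subset plus common hetero elements.
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4, Se = c(2, 4, 6)
)

# Elements with a lone pair gain bonding capacity when positively charged;
# carbon/boron lose it. Negative charge always removes capacity.
effective_valences <- function(symbol, charge) {
  v <- .default_valences[[symbol]]
  if (is.null(v)) return(NULL)
  if (charge > 0) {
    if (symbol %in% c("N", "O", "P", "S", "F", "Cl", "Br", "I", "Se")) {
      v <- v + charge
    } else {
      v <- v - charge
    }
  } else if (charge < 0) {
    v <- v + charge
  }
  v[v >= 0]
}

# Hydrogen count a neutral-valence fill would assign: smallest allowed
# valence >= the (ceiling of the) bond-order sum, or zero when exceeded.
implicit_h_fill <- function(symbol, charge, bond_sum) {
  v <- effective_valences(symbol, charge)
  if (is.null(v) || !length(v)) return(0L)
  need <- ceiling(bond_sum - 1e-9)
  ok <- v[v >= need]
  if (!length(ok)) return(0L)
  as.integer(ok[1] - need)
}

# Largest valence the element/charge supports; used to reject edits that
# would overflow an atom even before hydrogens are reassigned.
max_valence <- function(symbol, charge) {
  v <- effective_valences(symbol, charge)
  if (is.null(v) || !length(v)) return(Inf)
  max(v)
}

#' @importFrom igraph graph_from_data_frame components girth make_empty_graph
mol_igraph <- function(g) {
  n <- n_atoms(g)
  if (n == 0L) return(igraph::make_empty_graph(0, directed = FALSE))
  if (nrow(g$bonds)) {
    igraph::graph_from_data_frame(g$bonds[, c("u", "v")], directed = FALSE,
                                  vertices = data.frame(name = seq_len(n)))
  } else {
    igraph::make_empty_graph(n, directed = FALSE)
  }
}

# Logical vector: is each bond part of a ring?  A bond lies on a cycle iff
# its endpoints stay connected after the bond is removed.
bonds_in_ring <- function(g) {
  m <- n_bonds(g)
  if (m == 0L) return(logical(0))
  ig <- mol_igraph(g)
  out <- logical(m)
  for (i in seq_len(m)) {
    ig2 <- igraph::delete_edges(ig, i)
    memb <- igraph::components(ig2)$membership
    out[i] <- memb[g$bonds$u[i]] == memb[g$bonds$v[i]]
  }
  out
}

atoms_in_ring <- function(g) {
  inring <- logical(n_atoms(g))
  br <- bonds_in_ring(g)
  if (any(br)) {
    inring[unique(c(g$bonds$u[br], g$bonds$v[br]))] <- TRUE
  }
  inring
}

atom_degrees <- function(g) {
  d <- integer(n_atoms(g))
  if (nrow(g$bonds)) {
    t1 <- tabulate(g$bonds$u, nbins = n_atoms(g))
    t2 <- tabulate(g$bonds$v, nbins = n_atoms(g))
    d <- t1 + t2
  }
  d
}

# Connected components as a list of atom-index vectors.
mol_components <- function(g) {
  if (n_atoms(g) == 0L) return(list())
  memb <- igraph::components(mol_igraph(g))$membership
  split(seq_len(n_atoms(g)), memb)
}

# Induced subgraph on a set of atoms; returns the subgraph and the map from
# old to new atom indices.
induced_subgraph_mol <- function(g, atoms_keep) {
  atoms_keep <- sort(unique(as.integer(atoms_keep)))
  idx_map <- integer(n_atoms(g))
  idx_map[atoms_keep] <- seq_along(atoms_keep)
  b <- g$bonds
  keep <- b$u %in% atoms_keep & b$v %in% atoms_keep
  b <- b[keep, , drop = FALSE]
  if (nrow(b)) {
    b$u <- idx_map[b$u]; b$v <- idx_map[b$v]
  }
  list(graph = mol_graph(g$atoms[atoms_keep, , drop = FALSE], b),
       old2new = idx_map, kept = atoms_keep)
}

find_bond <- function(g, u, v) {
  lo <- min(u, v); hi <- max(u, v)
  w <- which(g$bonds$u == lo & g$bonds$v == hi)
  if (length(w)) w[1] else NA_integer_
}

heavy_formula <- function(g) {
  tab <- table(g$atoms$symbol)
  paste(sprintf("%s%d", names(tab), as.integer(tab)), collapse = "")
}
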