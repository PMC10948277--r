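#' Parse an atom-mapped reaction record
#'
#' A record is one line `reactants>>product` in atom-mapped SMILES, with an
#' optional tab-separated reaction-class column (an integer 1-10). Multiple
#' reactants are dot-separated. Every product atom must carry a map number,
#' each occurring on exactly one reactant atom; reactant-only atoms may be
#' unmapped (motif atoms typically are).
#'
#' @param record a single text line.
#' @return A `reaction` object: list with `product` (a [mol_graph()]),
#'   `reactants` (list of `mol_graph`), and `reaction_class`
#'   (integer or `NA`).
#' @export
parse_reaction <- function(record) {
  stopifnot(is.character(record), length(record) == 1L)
  fields <- strsplit(trimws(record), "\t", fixed = TRUE)[[1]]
  rxn_smi <- fields[1]
  rclass <- NA_integer_
  if (length(fields) >= 2L && grepl("^[0-9]+$", fields[2])) {
    rclass <- as.integer(fields[2])
    if (rclass < 1L || rclass > 10L) {
      stop(sprintf("reaction class out of range 1-10 in record '%s'", record),
           call. = FALSE)
    }
  }
  sides <- strsplit(rxn_smi, ">>", fixed = TRUE)[[1]]
  if (length(sides) != 2L || !nzchar(trimws(sides[2]))) {
    stop(sprintf("record is not 'reactants>>product': '%s'", record),
         call. = FALSE)
  }
  if (!nzchar(trimws(sides[1]))) {
    stop(sprintf("empty reactant side in record '%s'", record), call. = FALSE)
  }
  product <- tryCatch(parse_smiles(sides[2]), error = function(e) {
    stop(sprintf("unparsable product in record '%s': %s", record,
                 conditionMessage(e)), call. = FALSE)
  })
  reactants <- lapply(strsplit(sides[1], ".", fixed = TRUE)[[1]], function(s) {
    tryCatch(parse_smiles(s), error = function(e) {
      stop(sprintf("unparsable reactant '%s' in record '%s': %s", s, record,
                   conditionMessage(e)), call. = FALSE)
    })
  })
  rxn <- structure(list(product = product, reactants = reactants,
                        reaction_class = rclass), class = "reaction")
  validate_reaction_mapping(rxn, record)
  rxn
}

validate_reaction_mapping <- function(rxn, record = "<reaction>") {
  pmap <- rxn$product$atoms$map
  if (any(pmap <= 0L)) {
    stop(sprintf("mapping error: unmapped product atom in '%s'", record),
         call. = FALSE)
  }
  if (anyDuplicated(pmap)) {
    stop(sprintf("mapping error: duplicated product map number in '%s'", record),
         call. = FALSE)
  }
  rmap <- unlist(lapply(rxn$reactants, function(g) g$atoms$map))
  rmap <- rmap[rmap > 0L]
  if (anyDuplicated(rmap)) {
    stop(sprintf("mapping error: duplicated reactant map number in '%s'", record),
         call. = FALSE)
  }
  missing <- setdiff(pmap, rmap)
  if (length(missing)) {
    stop(sprintf("mapping error: product map(s) %s absent from reactants in '%s'",
                 paste(missing, collapse = ","), record), call. = FALSE)
  }
  invisible(rxn)
}

#' @export
print.reaction <- function(x, ...) {
  cat(sprintf("<reaction> %d reactant(s) >> product (%d atoms)%s\n",
              length(x$reactants), n_atoms(x$product),
              if (is.na(x$reaction_class)) "" else
                sprintf(", class %d", x$reaction_class)))
  invisible(x)
}

#' Normalize a reaction to canonical product atom order and mapping
#'
#' Benchmark reaction sets carry an ordering shortcut: the atom mapped "1"
#' tends to sit in the reaction center, which leaks the answer to a model
#' that sees map-derived indices. This reorders the product's atoms to the
#' canonical SMILES output order, reassigns map numbers `1..n` in that order,
#' and translates the reactant maps accordingly; the result is chemically
#' identical but its numbering carries no information about the reaction.
#' The product's bond enumeration is frozen from the canonical form, making
#' all downstream entity indices reproducible.
#'
#' @param rxn a `reaction`.
#' @return A `reaction` with normalized mapping.
#' @export
remove_dataset_shortcut <- function(rxn) {
  validate_reaction_mapping(rxn)
  p_tagged <- rxn$product
  p_tagged$atoms$map <- seq_len(n_atoms(p_tagged))
  can <- canonical_smiles(p_tagged, keep_maps = TRUE)
  finish_shortcut_removal(rxn, can)
}

finish_shortcut_removal <- function(rxn, can) {
  p <- rxn$product
  old_maps <- p$atoms$map
  p_new <- parse_smiles(can)
  if (n_atoms(p_new) != n_atoms(p) ||
      !identical(sort(p_new$atoms$map), seq_len(n_atoms(p)))) {
    stop("canonicalization did not preserve the product atom set", call. = FALSE)
  }
  # p_new atom k corresponds to original atom p_new$atoms$map[k]
  orig_of_new <- p_new$atoms$map
  new_of_orig <- integer(length(orig_of_new))
  new_of_orig[orig_of_new] <- seq_along(orig_of_new)
  p_new$atoms$map <- seq_len(n_atoms(p_new))
  # translate reactant maps: old product map -> new map
  translate <- integer(0)
  translate[old_maps] <- new_of_orig
  reactants <- lapply(rxn$reactants, function(g) {
    mm <- g$atoms$map
    keep <- mm > 0L & mm %in% old_maps
    g$atoms$map[!keep] <- 0L
    g$atoms$map[keep] <- translate[mm[keep]]
    g
  })
  structure(list(product = p_new, reactants = reactants,
                 reaction_class = rxn$reaction_class), class = "reaction")
}

#' Entity indices of a molecular graph
#'
#' Bonds and atoms share one index space: bond entities occupy `0..m-1` in
#' bond enumeration order, atom entities occupy `m..m+n-1` (atom index plus
#' `m`). Values are 0-based to match the path/token serialization.
#'
#' @param g a [mol_graph()].
#' @return Integer vector of length `m + n` (the values `0..m+n-1`), with a
#'   `kind` attribute (`"bond"`/`"atom"`).
#' @export
index_entities <- function(g) {
  m <- n_bonds(g); n <- n_atoms(g)
  idx <- seq_len(m + n) - 1L
  attr(idx, "kind") <- rep(c("bond", "atom"), c(m, n))
  idx
}

entity_kind <- function(value, m) ifelse(value < m, "bond", "atom")
entity_atom <- function(value, m) as.integer(value - m + 1L)  # 1-based atom
entity_bond <- function(value) as.integer(value + 1L)         # 1-based bond row

# ---- featurization ------------------------------------------------------

.feat_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                    "Si", "Se", "Sn", "Mg", "Zn", "Cu")
.feat_stereo <- c("none", "up", "down", "cis", "trans", "any")

#' Featurizer layout
#'
#' Returns the fixed layout of the atom and bond feature vectors, recorded in
#' vocabulary files and checkpoints so artifacts are self-describing.
#' Atom features (45): element one-hot over 16 symbols plus "other" (17),
#' degree 0-5 (6), formal charge -2..+2 (5), total hydrogens 0-4 (5),
#' chirality none/@/@@/other (4), hybridization s/sp/sp2/sp3/other (5),
#' aromatic (1), in-ring (1), radical placeholder (1). A 10-wide one-hot of
#' the reaction class is appended when the class is supplied (55).
#' Bond features (12): order one-hot (4), conjugation (1), in-ring (1),
#' stereo/direction one-hot (6).
#'
#' @return A list describing the layout.
#' @export
featurizer_layout <- function() {
  list(
    version = 1L,
    atom_width = 45L, atom_width_with_class = 55L,
    bond_width = 12L, bond_type_onehot_width = 4L, class_width = 10L,
    elements = .feat_elements,
    stereo = .feat_stereo
  )
}

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (!is.na(i)) v[i] <- 1
  v
}

#' Fixed-width featurization of a molecular graph
#'
#' @param g a [mol_graph()].
#' @param reaction_class optional integer 1-10; when given, a 10-wide one-hot
#'   is appended to every atom vector.
#' @return List with `atom_features` (n x 45 or n x 55 matrix),
#'   `bond_features` (m x 12 matrix) and `bond_type_onehot` (m x 4 matrix
#'   over none/single/double/triple; aromatic bonds fall outside the edit
#'   type classes and get an all-zero row).
#' @export
featurize <- function(g, reaction_class = NULL) {
  n <- n_atoms(g); m <- n_bonds(g)
  if (!is.null(reaction_class)) {
    stopifnot(length(reaction_class) == 1L)
    if (is.na(reaction_class)) reaction_class <- NULL
  }
  if (!is.null(reaction_class) &&
      (reaction_class < 1L || reaction_class > 10L)) {
    stop("reaction_class must be in 1..10", call. = FALSE)
  }
  deg <- atom_degrees(g)
  inring_a <- atoms_in_ring(g)
  inring_b <- bonds_in_ring(g)
  # crude hybridization proxy from incident bond orders
  hyb <- rep("sp3", n)
  if (m) {
    for (i in seq_len(m)) {
      o <- g$bonds$order[i]
      for (a in c(g$bonds$u[i], g$bonds$v[i])) {
        if (o == "triple") hyb[a] <- "sp"
        else if (o %in% c("double", "aromatic") && hyb[a] != "sp") hyb[a] <- "sp2"
      }
    }
  }
  hyb[deg == 0L & g$atoms$hcount == 0L] <- "s"

  atom_row <- function(a) {
    at <- g$atoms[a, ]
    el <- c(one_hot(at$symbol, .feat_elements),
            as.numeric(!at$symbol %in% .feat_elements))
    c(el,
      one_hot(min(deg[a], 5L), 0:5),
      one_hot(max(-2L, min(2L, at$charge)), -2:2),
      one_hot(min(at$hcount, 4L), 0:4),
      one_hot(if (at$chiral %in% c("", "@", "@@")) at$chiral else "other",
              c("", "@", "@@", "other")),
      one_hot(hyb[a], c("s", "sp", "sp2", "sp3", "other")),
      as.numeric(at$aromatic),
      as.numeric(inring_a[a]),
      0)  # radical electrons: not modelled
  }
  A <- if (n) t(vapply(seq_len(n), atom_row, numeric(45))) else
    matrix(0, 0, 45)
  if (!is.null(reaction_class)) {
    cls <- matrix(rep(one_hot(as.integer(reaction_class), 1:10), each = n), n, 10)
    A <- cbind(A, cls)
  }

  bond_row <- function(i) {
    b <- g$bonds[i, ]
    conj <- b$order %in% c("aromatic", "double", "triple") ||
      (hyb[b$u] %in% c("sp", "sp2") && hyb[b$v] %in% c("sp", "sp2"))
    stereo <- if (b$dir == "") "none" else b$dir
    c(one_hot(b$order, c("single", "double", "triple", "aromatic")),
      as.numeric(conj),
      as.numeric(inring_b[i]),
      one_hot(stereo, .feat_stereo))
  }
  B <- if (m) t(vapply(seq_len(m), bond_row, numeric(12))) else matrix(0, 0, 12)
  Bt <- if (m) t(vapply(seq_len(m), function(i)
    one_hot(g$bonds$order[i], c("none", "single", "double", "triple")),
    numeric(4))) else matrix(0, 0, 4)

  list(atom_features = A, bond_features = B, bond_type_onehot = Bt)
}

#' Read reaction records from a file
#'
#' One atom-mapped reaction SMILES per line, optional tab-separated class
#' column. Lines that are empty or start with `#` are skipped.
#'
#' @param path file path.
#' @return List of `reaction` objects.
#' @export
read_reactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, parse_reaction)
}

#' @rdname remove_dataset_shortcut
#' @param rxns list of `reaction` objects.
#' @details `normalize_reactions()` applies the same normalization to a list
#'   of reactions with a single batched canonicalization pass.
#' @export
normalize_reactions <- function(rxns) {
  if (!length(rxns)) return(rxns)
  tagged <- lapply(rxns, function(rxn) {
    p <- rxn$product
    p$atoms$map <- seq_len(n_atoms(p))
    p
  })
  cans <- canonical_smiles(tagged, keep_maps = TRUE)
  out <- lapply(seq_along(rxns), function(i) {
    finish_shortcut_removal(rxns[[i]], cans[i])
  })
  names(out) <- names(rxns)
  out
}
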