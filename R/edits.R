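# Edit derivation: compare mapped product and reactant graphs and express the
# reaction center as bond edits (order changes, removals) and atom edits
# (hydrogen-count / formal-charge changes).

# map number -> (reactant index, atom index) lookup table
reactant_atom_table <- function(rxn) {
  out <- list()
  for (ri in seq_along(rxn$reactants)) {
    g <- rxn$reactants[[ri]]
    mm <- g$atoms$map
    for (ai in which(mm > 0L)) {
      out[[as.character(mm[ai])]] <- c(ri = ri, ai = ai)
    }
  }
  out
}

unsupported_reaction <- function(msg) {
  stop(errorCondition(msg, class = c("retromotif_unsupported", "error")))
}

#' Derive the Edit sequence of a mapped reaction
#'
#' Compares the product against the reactants atom-by-atom through the
#' mapping and emits the reaction center as transformation tokens: bond
#' edits for mapped bonds whose order differs (removal is the new type
#' "none"), and atom edits for mapped atoms whose hydrogen count or formal
#' charge cannot be recovered by valence refilling at the edit sites. The
#' endpoints of edited bonds and all atom-edit atoms are the attachment
#' atoms where motifs will be added.
#'
#' Bond formation between two mapped atoms (a bond present in the reactants
#' but not in the product) and aromaticity changes across the arrow have no
#' entity in the product index space and raise an `retromotif_unsupported`
#' condition; such records are skipped during preprocessing.
#'
#' @param rxn a `reaction` (ideally after [remove_dataset_shortcut()]).
#' @return List with `edits` (list of tokens, ordered by ascending entity
#'   index), `labels` (0/1 over the `m+n` entities), `attachments`
#'   (product atom indices, sorted), and `pinned` (atom indices whose
#'   hydrogen count is set explicitly by an atom edit).
#' @export
derive_edits <- function(rxn) {
  validate_reaction_mapping(rxn)
  p <- rxn$product
  m <- n_bonds(p); n <- n_atoms(p)
  rat <- reactant_atom_table(rxn)
  pmap <- p$atoms$map

  r_bondsums <- lapply(rxn$reactants, atom_bond_sums)

  # --- bond edits ---------------------------------------------------------
  edits <- list()
  bond_edit_endpoints <- integer()
  for (bi in seq_len(m)) {
    u <- p$bonds$u[bi]; v <- p$bonds$v[bi]
    loc_u <- rat[[as.character(pmap[u])]]
    loc_v <- rat[[as.character(pmap[v])]]
    r_order <- "none"
    if (loc_u["ri"] == loc_v["ri"]) {
      g <- rxn$reactants[[loc_u["ri"]]]
      rb <- find_bond(g, loc_u["ai"], loc_v["ai"])
      if (!is.na(rb)) r_order <- g$bonds$order[rb]
    }
    p_order <- p$bonds$order[bi]
    if (p_order == r_order) next
    if (p_order == "aromatic" || r_order == "aromatic") {
      unsupported_reaction("aromatic bond change across the reaction arrow")
    }
    edits[[length(edits) + 1L]] <- list(
      kind = "bond", entity = bi - 1L, new_order = r_order)
    bond_edit_endpoints <- c(bond_edit_endpoints, u, v)
  }

  # bond formation check: reactant bond between two product-mapped atoms
  # that are not bonded in the product
  pm_pos <- integer(); pm_pos[pmap] <- seq_len(n)
  for (ri in seq_along(rxn$reactants)) {
    g <- rxn$reactants[[ri]]
    mm <- g$atoms$map
    if (!nrow(g$bonds)) next
    for (bi in seq_len(nrow(g$bonds))) {
      mu <- mm[g$bonds$u[bi]]; mv <- mm[g$bonds$v[bi]]
      if (mu > 0L && mv > 0L && mu %in% pmap && mv %in% pmap) {
        if (is.na(find_bond(p, pm_pos[mu], pm_pos[mv]))) {
          unsupported_reaction("bond formation between mapped atoms in the retro direction")
        }
      }
    }
  }

  # --- atom edits ---------------------------------------------------------
  touched0 <- unique(bond_edit_endpoints)
  atom_edit_atoms <- integer()
  pinned <- integer()
  for (a in seq_len(n)) {
    loc <- rat[[as.character(pmap[a])]]
    g <- rxn$reactants[[loc["ri"]]]
    ra <- loc["ai"]
    if (g$atoms$symbol[ra] != p$atoms$symbol[a]) {
      stop(sprintf("mapping error: element mismatch at map %d", pmap[a]),
           call. = FALSE)
    }
    r_h <- g$atoms$hcount[ra]; r_q <- g$atoms$charge[ra]
    p_h <- p$atoms$hcount[a]; p_q <- p$atoms$charge[a]
    dq <- r_q - p_q
    nb_u <- g$bonds$u[g$bonds$v == ra]; nb_v <- g$bonds$v[g$bonds$u == ra]
    nbr <- c(nb_u, nb_v)
    has_extra <- length(nbr) > 0L &&
      any(g$atoms$map[nbr] == 0L | !g$atoms$map[nbr] %in% pmap)
    attach_needed <- (a %in% touched0) || has_extra
    expected_h <- if (attach_needed) {
      implicit_h_fill(g$atoms$symbol[ra], r_q, r_bondsums[[loc["ri"]]][ra])
    } else p_h
    need <- dq != 0L || expected_h != r_h ||
      (has_extra && !(a %in% touched0))
    if (need) {
      edits[[length(edits) + 1L]] <- list(
        kind = "atom", entity = m + a - 1L,
        dH = r_h - p_h, dq = dq)
      atom_edit_atoms <- c(atom_edit_atoms, a)
      pinned <- c(pinned, a)
    }
  }

  if (length(edits)) {
    edits <- edits[order(vapply(edits, `[[`, 0L, "entity"))]
  }
  labels <- integer(m + n)
  for (e in edits) labels[e$entity + 1L] <- 1L
  attachments <- sort(unique(c(touched0, atom_edit_atoms)))
  list(edits = edits, labels = labels, attachments = attachments,
       pinned = sort(unique(pinned)))
}
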