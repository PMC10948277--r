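# Motif extraction: decompose the non-synthon part of each reactant into
# motifs. Rule 1 breaks reactant bonds that connect synthon atoms to
# leaving-group atoms, keeping a copy of the synthon-side atom inside the
# motif as its interface atom. Rule 2 breaks bonds whose two endpoints lie
# in separate rings (a biphenyl-type linker bond). Rule 3 breaks bonds where
# one endpoint is a ring atom and the other is a branch atom of degree > 1.
# Rules 2-3 are applied to a fixed point; each cut keeps the parent-side
# endpoint as the child's interface and marks it as a new interface on the
# parent, so parents expose the attachment sites of their children.

new_motif <- function(graph, interfaces, key = NA_character_) {
  structure(list(graph = graph, interfaces = as.integer(interfaces),
                 key = key), class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("<motif> %s (%d interface%s)\n",
              if (is.na(x$key)) write_smiles(x$graph) else x$key,
              length(x$interfaces),
              if (length(x$interfaces) == 1L) "" else "s"))
  invisible(x)
}

# copy atom `a` of graph `g` as a detached interface atom row
interface_copy_row <- function(g, a) {
  row <- g$atoms[a, , drop = FALSE]
  row$chiral <- ""
  row$map <- 0L
  row
}

# clear aromatic flags on atoms with no incident aromatic bond (interface
# copies of ring atoms end up outside any aromatic system)
fix_aromatic_flags <- function(g) {
  has_ar <- logical(n_atoms(g))
  if (nrow(g$bonds)) {
    ar <- g$bonds$order == "aromatic"
    has_ar[unique(c(g$bonds$u[ar], g$bonds$v[ar]))] <- TRUE
  }
  g$atoms$aromatic <- g$atoms$aromatic & has_ar
  g
}

#' Extract the motifs of a mapped reaction
#'
#' Identifies, per reactant, the atoms that are not part of any synthon
#' (atoms whose map number does not occur in the product) and decomposes
#' them into motifs under the three cutting rules. Attachment atoms whose
#' reactant atom has no leaving-group neighbours yield a single-atom motif
#' (just the interface copy): the vocabulary entry that completes an
#' attachment with hydrogens only.
#'
#' @param rxn a `reaction`.
#' @param synthon_atoms map numbers identifying synthon atoms; defaults to
#'   all product map numbers.
#' @param attachment_maps map numbers of the attachment atoms (from
#'   [derive_edits()]); used to create terminal single-atom motifs. May be
#'   empty, in which case only leaving-group motifs are returned.
#' @return List of motif occurrences; each has `motif` (with canonically
#'   ordered interfaces and a canonical key), `q` (which interface merges
#'   with the attachment), `parent` (0 = synthon group, else the index of
#'   the parent occurrence), `attach_map` (product map number, parent == 0)
#'   or `parent_atom` (atom index within the parent motif's graph).
#' @export
extract_motifs <- function(rxn, synthon_atoms = NULL,
                           attachment_maps = integer(), finalize = TRUE) {
  pmap <- rxn$product$atoms$map
  if (is.null(synthon_atoms)) synthon_atoms <- pmap
  if (!all(synthon_atoms %in% pmap)) {
    stop("mapping error: synthon_atoms must be product map numbers",
         call. = FALSE)
  }
  occs <- list()   # occurrence skeletons; keys/canonical order fixed at the end

  for (ri in seq_along(rxn$reactants)) {
    g <- rxn$reactants[[ri]]
    mm <- g$atoms$map
    is_syn <- mm > 0L & mm %in% synthon_atoms
    extra <- which(!is_syn)
    syn <- which(is_syn)

    # terminal single-atom motifs at attachments with no leaving group here
    for (a in syn) {
      if (!mm[a] %in% attachment_maps) next
      nbr <- c(g$bonds$u[g$bonds$v == a], g$bonds$v[g$bonds$u == a])
      if (!any(nbr %in% extra)) {
        tg <- fix_aromatic_flags(mol_graph(interface_copy_row(g, a), NULL))
        occs[[length(occs) + 1L]] <- list(
          graph = tg, interfaces = 1L, parent = 0L,
          attach_map = mm[a], parent_atom = NA_integer_)
      }
    }
    if (!length(extra)) next

    memb <- igraph::components(mol_igraph(g))$membership
    sub_extra <- induced_subgraph_mol(g, extra)
    ememb <- if (n_atoms(sub_extra$graph)) {
      igraph::components(mol_igraph(sub_extra$graph))$membership
    } else integer()
    for (cid in unique(ememb)) {
      comp <- sub_extra$kept[ememb == cid]
      # boundary synthon atoms bonded to this component
      bu <- g$bonds$u; bv <- g$bonds$v
      touching <- unique(c(bu[bv %in% comp & is_syn[bu]],
                           bv[bu %in% comp & is_syn[bv]]))
      if (length(touching) == 0L) {
        unsupported_reaction(
          "reactant fragment with no connection to any synthon (spectator)")
      }
      if (length(touching) > 1L) {
        unsupported_reaction(
          "leaving group bridges multiple synthon atoms")
      }
      s <- touching
      sub <- induced_subgraph_mol(g, c(comp, s))
      cg <- sub$graph
      ci <- sub$old2new[s]
      cg$atoms[ci, ] <- interface_copy_row(g, s)
      # the interface copy keeps only its bonds into the motif component;
      # bonds from s to other synthon atoms were dropped by the induction
      occs[[length(occs) + 1L]] <- list(
        graph = fix_aromatic_flags(cg), interfaces = ci, parent = 0L,
        attach_map = mm[s], parent_atom = NA_integer_)
    }
  }

  occs <- cut_motifs_to_fixed_point(occs)
  if (finalize) finalize_motif_occurrences(occs) else occs
}

# Batched finalization of several occurrence lists (one per reaction):
# flattens, runs the two OpenBabel passes once, and unflattens.
finalize_motif_sets <- function(occ_sets) {
  lens <- vapply(occ_sets, length, 0L)
  flat <- finalize_motif_occurrences(unlist(occ_sets, recursive = FALSE))
  split_at <- rep(seq_along(lens), lens)
  out <- vector("list", length(occ_sets))
  for (i in seq_along(out)) out[[i]] <- flat[split_at == i]
  out
}

# Apply rules 2-3 iteratively. `occs` entries gain children appended to the
# list; parent/parent_atom link children to the occurrence they hang off.
cut_motifs_to_fixed_point <- function(occs) {
  j <- 1L
  while (j <= length(occs)) {
    repeat {
      oc <- occs[[j]]
      g <- oc$graph
      m <- n_bonds(g)
      if (!m) break
      ring_b <- bonds_in_ring(g)
      ring_a <- atoms_in_ring(g)
      deg <- atom_degrees(g)
      cut <- NA_integer_
      for (bi in seq_len(m)) {
        if (ring_b[bi]) next
        u <- g$bonds$u[bi]; v <- g$bonds$v[bi]
        if ((ring_a[u] && ring_a[v]) ||
            (ring_a[u] && !ring_a[v] && deg[v] > 1L) ||
            (ring_a[v] && !ring_a[u] && deg[u] > 1L)) { cut <- bi; break }
      }
      if (is.na(cut)) break
      u <- g$bonds$u[cut]; v <- g$bonds$v[cut]
      cut_order <- g$bonds$order[cut]
      g2 <- g
      g2$bonds <- g2$bonds[-cut, , drop = FALSE]
      memb <- igraph::components(mol_igraph(g2))$membership
      anchor <- oc$interfaces[1]
      parent_side <- which(memb == memb[anchor])
      child_side <- which(memb != memb[anchor])
      pe <- if (u %in% parent_side) u else v   # parent-side endpoint
      ce <- if (pe == u) v else u

      child_sub <- induced_subgraph_mol(g2, c(child_side, pe))
      cgraph <- child_sub$graph
      cidx <- child_sub$old2new[pe]
      cgraph$atoms[cidx, ] <- interface_copy_row(g, pe)
      # restore the cut bond between the interface copy and the child atom
      cgraph$bonds <- rbind(cgraph$bonds, data.frame(
        u = min(cidx, child_sub$old2new[ce]),
        v = max(cidx, child_sub$old2new[ce]),
        order = cut_order, dir = "", stringsAsFactors = FALSE))
      cgraph <- mol_graph(cgraph$atoms, cgraph$bonds)

      parent_sub <- induced_subgraph_mol(g2, parent_side)
      pgraph <- fix_aromatic_flags(parent_sub$graph)
      new_ifaces <- parent_sub$old2new[oc$interfaces]
      if (any(new_ifaces == 0L)) {
        unsupported_reaction("motif cut would displace an existing interface")
      }
      pe_new <- parent_sub$old2new[pe]
      if (!pe_new %in% new_ifaces) new_ifaces <- c(new_ifaces, pe_new)

      # re-index links of existing children of this occurrence
      for (k in seq_along(occs)) {
        if (identical(occs[[k]]$parent, j)) {
          occs[[k]]$parent_atom <- parent_sub$old2new[occs[[k]]$parent_atom]
        }
      }
      occs[[j]]$graph <- pgraph
      occs[[j]]$interfaces <- new_ifaces
      occs[[length(occs) + 1L]] <- list(
        graph = fix_aromatic_flags(cgraph), interfaces = cidx, parent = j,
        attach_map = NA_integer_, parent_atom = pe_new)
    }
    j <- j + 1L
  }
  occs
}

# Canonical interface order and canonical keys for a list of occurrences;
# OpenBabel calls are batched across all occurrences.
finalize_motif_occurrences <- function(occs) {
  if (!length(occs)) return(list())
  # pass 1: canonical atom ranks (tag atoms by index, canonicalize, read back)
  tagged <- lapply(occs, function(oc) {
    g <- oc$graph
    g$atoms$map <- seq_len(n_atoms(g))
    g
  })
  can1 <- canonical_smiles(tagged, keep_maps = TRUE)
  out <- vector("list", length(occs))
  keyed <- vector("list", length(occs))
  for (i in seq_along(occs)) {
    oc <- occs[[i]]
    back <- parse_smiles(can1[i])
    rank <- integer(n_atoms(oc$graph))
    rank[back$atoms$map] <- seq_len(n_atoms(back))
    merge_iface <- oc$interfaces[1]
    ifaces <- oc$interfaces[order(rank[oc$interfaces])]
    kg <- oc$graph
    kg$atoms$map <- 0L
    kg$atoms$map[ifaces] <- seq_along(ifaces)
    keyed[[i]] <- kg
    out[[i]] <- list(oc = oc, ifaces = ifaces,
                     q = match(merge_iface, ifaces))
  }
  keys <- canonical_smiles(keyed, keep_maps = TRUE)
  lapply(seq_along(out), function(i) {
    oc <- out[[i]]$oc
    list(motif = new_motif(oc$graph, out[[i]]$ifaces, keys[i]),
         q = out[[i]]$q,
         parent = oc$parent,
         attach_map = oc$attach_map,
         parent_atom = oc$parent_atom)
  })
}

#' Reconstruct a motif from its canonical key
#'
#' The canonical key is a canonical SMILES in which interface atoms carry
#' map numbers `1..K` in canonical order; parsing it recovers the motif
#' graph and its interface list exactly.
#'
#' @param key a canonical motif key.
#' @return A `motif`.
#' @export
motif_from_key <- function(key) {
  g <- parse_smiles(key)
  ifaces <- which(g$atoms$map > 0L)[order(g$atoms$map[g$atoms$map > 0L])]
  if (!length(ifaces)) stop("motif key carries no interface atoms", call. = FALSE)
  g$atoms$map <- 0L
  new_motif(g, ifaces, key)
}
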