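# Editable molecular graphs: the execution engine for transformation paths.
# Bond/atom edits are applied in the Edit phase; motifs are grafted in the
# AddingMotif phase; hydrogen counts at edit sites are refilled at the end.

chemistry_error <- function(msg) {
  stop(errorCondition(msg, class = c("retromotif_chemistry", "error")))
}
state_error <- function(msg) {
  stop(errorCondition(msg, class = c("retromotif_state", "error")))
}

#' Start editing a product graph
#'
#' Creates an editable state around a product molecular graph. The state
#' tracks the phase (`edit` -> `adding_motif` -> `done`), the attachment
#' queue, which atoms have open valence (hydrogens refilled at the end) and
#' which have pinned hydrogen counts (set explicitly by an atom edit).
#'
#' During the Edit phase removed bonds are kept as rows with order `"none"`
#' so that bond entity indices keep referring to the product's bond
#' enumeration; the rows are dropped when the phase ends.
#'
#' @param product a [mol_graph()].
#' @return An `editable_graph`.
#' @export
new_editable_graph <- function(product) {
  structure(list(
    graph = product,
    m0 = n_bonds(product),         # product bond count: entity offset
    n0 = n_atoms(product),
    phase = "edit",
    queue = integer(),             # atom indices (current graph)
    promoted = integer(),          # queue atoms added by motifs
    open = integer(),              # atoms whose H is refilled at the end
    pinned = integer(),            # atoms with explicit H from atom edits
    synthon = NULL                 # frozen at finish_edit()
  ), class = "editable_graph")
}

#' @export
print.editable_graph <- function(x, ...) {
  cat(sprintf("<editable_graph> phase=%s, %d atoms, queue [%s]\n",
              x$phase, n_atoms(x$graph), paste(x$queue, collapse = " ")))
  invisible(x)
}

# current graph with "none"-order bond rows removed (for encoding/output)
graph_view <- function(st) {
  g <- st$graph
  keep <- g$bonds$order != "none"
  if (!all(keep)) g$bonds <- g$bonds[keep, , drop = FALSE]
  g
}

editable_bond_sums <- function(g) {
  s <- numeric(n_atoms(g))
  if (nrow(g$bonds)) {
    ord <- g$bonds$order
    val <- ifelse(ord == "none", 0, bond_order_value(ord))
    for (i in seq_len(nrow(g$bonds))) {
      s[g$bonds$u[i]] <- s[g$bonds$u[i]] + val[i]
      s[g$bonds$v[i]] <- s[g$bonds$v[i]] + val[i]
    }
  }
  s
}

check_max_valence <- function(st, atoms) {
  bs <- editable_bond_sums(st$graph)
  for (a in atoms) {
    at <- st$graph$atoms[a, ]
    floor_h <- if (a %in% st$pinned) at$hcount else 0
    if (ceiling(bs[a] - 1e-9) + floor_h > max_valence(at$symbol, at$charge)) {
      chemistry_error(sprintf(
        "valence overflow at atom %d (%s, bond sum %.1f)", a, at$symbol, bs[a]))
    }
  }
  invisible(TRUE)
}

#' Apply a bond or atom edit
#'
#' Bond entities are retyped to `new_state$new_order` (`"none"` removes the
#' bond); atom entities receive `new_state$dH` hydrogens and
#' `new_state$dq` charge, pinning the hydrogen count. Affected atoms join
#' the attachment queue.
#'
#' @param st an `editable_graph` in phase `"edit"`.
#' @param entity 0-based entity index in the product index space.
#' @param new_state for a bond: `list(new_order=)`; for an atom:
#'   `list(dH=, dq=)`.
#' @return The updated `editable_graph`.
#' @export
apply_edit <- function(st, entity, new_state) {
  if (st$phase != "edit") state_error("apply_edit outside the Edit phase")
  m <- st$m0
  if (entity < 0L || entity >= m + st$n0) {
    stop(sprintf("entity index %d outside [0, %d)", entity, m + st$n0),
         call. = FALSE)
  }
  if (entity < m) {
    bi <- entity + 1L
    b <- st$graph$bonds[bi, ]
    new_order <- new_state$new_order
    if (is.null(new_order) ||
        !new_order %in% c("none", "single", "double", "triple")) {
      stop("bond edit needs new_order in none/single/double/triple",
           call. = FALSE)
    }
    if (identical(b$order, new_order)) {
      chemistry_error(sprintf("no-op bond edit: bond %d already '%s'",
                              entity, new_order))
    }
    if (b$order == "aromatic") {
      chemistry_error("editing an aromatic bond is not supported")
    }
    st$graph$bonds$order[bi] <- new_order
    st$graph$bonds$dir[bi] <- ""
    touched <- c(b$u, b$v)
    check_max_valence(st, touched)
    st$open <- union(st$open, setdiff(touched, st$pinned))
    st$queue <- c(st$queue, setdiff(touched, st$queue))
  } else {
    a <- entity - m + 1L
    dH <- new_state$dH %||% 0L
    dq <- new_state$dq %||% 0L
    at <- st$graph$atoms[a, ]
    new_h <- at$hcount + dH
    if (new_h < 0L) chemistry_error(sprintf("negative hydrogen count at atom %d", a))
    st$graph$atoms$hcount[a] <- new_h
    st$graph$atoms$charge[a] <- at$charge + dq
    st$pinned <- union(st$pinned, a)
    st$open <- setdiff(st$open, a)
    check_max_valence(st, a)
    st$queue <- c(st$queue, setdiff(a, st$queue))
  }
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' End the Edit phase
#'
#' Drops removed bonds, sorts the attachment queue ascending by atom index
#' (= ascending entity index), freezes the synthon graph, and moves to the
#' AddingMotif phase — or directly to `done` when there are no attachments.
#'
#' @param st an `editable_graph` in phase `"edit"`.
#' @return The updated `editable_graph`.
#' @export
finish_edit <- function(st) {
  if (st$phase != "edit") state_error("finish_edit outside the Edit phase")
  keep <- st$graph$bonds$order != "none"
  st$graph$bonds <- st$graph$bonds[keep, , drop = FALSE]
  st$queue <- sort(st$queue)
  st$synthon <- sanitized_graph(st)
  st$phase <- if (length(st$queue)) "adding_motif" else "done"
  st
}

#' Attach a motif at the front attachment atom
#'
#' Grafts the motif by identifying its interface atom `interface` with the
#' attachment atom: the merged atom keeps the synthon atom's identity and
#' gains the motif-side bonds. Remaining interface atoms of the motif are
#' promoted to attachment atoms and served depth-first (pushed to the front
#' of the queue, in the motif's canonical interface order).
#'
#' @param st an `editable_graph` in phase `"adding_motif"`.
#' @param attachment atom index; must equal the queue front.
#' @param motif a `motif`.
#' @param interface 1-based index into the motif's interface list.
#' @return The updated `editable_graph`.
#' @export
attach_motif <- function(st, attachment, motif, interface = 1L) {
  if (st$phase != "adding_motif") {
    state_error("attach_motif outside the AddingMotif phase")
  }
  if (!length(st$queue)) state_error("attach_motif with an empty queue")
  if (attachment != st$queue[1]) {
    state_error(sprintf("attachment %d is not the queue front (%d)",
                        attachment, st$queue[1]))
  }
  if (interface < 1L || interface > length(motif$interfaces)) {
    stop(sprintf("interface index %d invalid for a motif with %d interface(s)",
                 interface, length(motif$interfaces)), call. = FALSE)
  }
  mg <- motif$graph
  ia <- motif$interfaces[interface]
  if (mg$atoms$symbol[ia] != st$graph$atoms$symbol[attachment]) {
    chemistry_error(sprintf(
      "merge error: interface atom is %s but attachment atom %d is %s",
      mg$atoms$symbol[ia], attachment, st$graph$atoms$symbol[attachment]))
  }
  n_old <- n_atoms(st$graph)
  keep <- setdiff(seq_len(n_atoms(mg)), ia)
  new_idx <- integer(n_atoms(mg))
  new_idx[keep] <- n_old + seq_along(keep)
  new_idx[ia] <- attachment
  if (length(keep)) {
    add_atoms <- mg$atoms[keep, , drop = FALSE]
    add_atoms$map <- 0L
    st$graph$atoms <- rbind(st$graph$atoms, add_atoms)
  }
  if (nrow(mg$bonds)) {
    nb <- mg$bonds
    nb$u <- new_idx[nb$u]; nb$v <- new_idx[nb$v]
    swap <- nb$u > nb$v
    if (any(swap)) {
      tmp <- nb$u[swap]; nb$u[swap] <- nb$v[swap]; nb$v[swap] <- tmp
      nb$dir[swap] <- flip_dir(nb$dir[swap])
    }
    st$graph$bonds <- rbind(st$graph$bonds, nb)
  }
  check_max_valence(st, attachment)
  st$queue <- st$queue[-1]
  rest <- motif$interfaces[-interface]
  if (length(rest)) {
    promoted <- new_idx[rest]
    st$queue <- c(promoted, st$queue)
    st$promoted <- c(st$promoted, promoted)
  }
  if (!length(st$queue)) st$phase <- "done"
  st
}

# Refill hydrogens at open (edit-touched, unpinned) atoms and return the
# finished graph. Motif-contributed atoms keep their stored hydrogen counts:
# those came from the reactants with the attachment bond already present.
sanitized_graph <- function(st) {
  g <- graph_view(st)
  bs <- atom_bond_sums(g)
  for (a in intersect(st$open, seq_len(n_atoms(g)))) {
    at <- g$atoms[a, ]
    g$atoms$hcount[a] <- implicit_h_fill(at$symbol, at$charge, bs[a])
    # an edit can destroy a stereocenter's neighbourhood; drop stale tags
    if (at$chiral != "" && atom_degrees(g)[a] + g$atoms$hcount[a] < 4L) {
      g$atoms$chiral[a] <- ""
    }
  }
  g
}

#' Execute a transformation path on a product graph
#'
#' Runs a full token sequence (`Edit`*, `FinishEdit`, `AddingMotif`*) against
#' a product and returns the resulting reactants as canonical, map-free
#' SMILES, ordered by descending heavy-atom count (ties broken
#' lexicographically). Any step failure is rethrown with the step index.
#'
#' @param product a [mol_graph()].
#' @param tokens list of target tokens; each is a list with `action` and, for
#'   `Edit`, `entity` + state fields, for `AddingMotif`, `motif_id` (resolved
#'   through `vocab`) or a `motif` object, plus `interface`.
#' @param vocab a `motif_vocabulary`, required when tokens carry motif ids.
#' @return Character vector of reactant canonical SMILES.
#' @export
apply_path <- function(product, tokens, vocab = NULL) {
  st <- new_editable_graph(product)
  for (k in seq_along(tokens)) {
    tok <- tokens[[k]]
    st <- tryCatch(switch(tok$action,
      Start = st,
      Edit = apply_edit(st, tok$entity,
                        tok[intersect(names(tok), c("new_order", "dH", "dq"))]),
      FinishEdit = finish_edit(st),
      AddingMotif = {
        mot <- if (!is.null(tok[["motif"]])) tok[["motif"]] else {
          if (is.null(vocab)) stop("tokens carry motif ids but no vocab given",
                                   call. = FALSE)
          vocab_motif(vocab, tok$motif_id)
        }
        attach_motif(st, st$queue[1], mot, tok$interface %||% 1L)
      },
      stop(sprintf("unknown action '%s'", tok$action), call. = FALSE)
    ), error = function(e) {
      stop(sprintf("apply_path failed at step %d (%s): %s",
                   k, tok$action, conditionMessage(e)), call. = FALSE)
    })
  }
  if (st$phase == "edit") st <- finish_edit(st)
  if (st$phase != "done") {
    state_error(sprintf("path ended with %d unserved attachment(s)",
                        length(st$queue)))
  }
  final <- sanitized_graph(st)
  comps <- mol_components(final)
  graphs <- lapply(comps, function(ix) induced_subgraph_mol(final, ix)$graph)
  smis <- canonical_smiles(graphs, keep_maps = FALSE)
  sizes <- vapply(graphs, n_atoms, 0L)
  smis[order(-sizes, smis, method = "radix")]
}
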