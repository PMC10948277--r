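# Transformation-path construction: Edit tokens from derive_edits(), a
# junction tree over synthons and motifs, and its depth-first linearization
# into aligned input/target token sequences.

#' Build the junction tree of a reaction
#'
#' The synthon group is the root; motif occurrences are nodes; each edge
#' records the attachment (a product atom for top-level motifs, a promoted
#' interface atom of the parent motif otherwise), the motif, and the
#' interface index that merges with the attachment.
#'
#' @param rxn a normalized `reaction`.
#' @param edits result of [derive_edits()] for `rxn`.
#' @param occs result of [extract_motifs()] for `rxn`.
#' @return A `junction_tree`: list with `attachments` (product atom indices,
#'   ascending) and `nodes` (the occurrences, with `attach_atom` resolved to
#'   product atom indices for top-level nodes).
#' @export
build_junction_tree <- function(rxn, edits, occs) {
  pmap <- rxn$product$atoms$map
  pos <- integer(max(pmap)); pos[pmap] <- seq_along(pmap)
  nodes <- lapply(occs, function(oc) {
    if (oc$parent == 0L) oc$attach_atom <- pos[oc$attach_map]
    oc
  })
  # every attachment must be covered by exactly one top-level node
  top_at <- vapply(nodes, function(nd)
    if (nd$parent == 0L) nd$attach_atom else NA_integer_, 0L)
  for (a in edits$attachments) {
    hits <- sum(top_at == a, na.rm = TRUE)
    if (hits != 1L) {
      unsupported_reaction(sprintf(
        "attachment atom %d covered by %d motifs (expected exactly 1)", a, hits))
    }
  }
  extra <- stats::na.omit(top_at)[!stats::na.omit(top_at) %in% edits$attachments]
  if (length(extra)) {
    unsupported_reaction(sprintf(
      "motif attached at non-attachment atom %d", extra[1]))
  }
  structure(list(attachments = sort(edits$attachments), nodes = nodes),
            class = "junction_tree")
}

#' @export
print.junction_tree <- function(x, ...) {
  cat(sprintf("<junction_tree> %d attachment(s), %d motif node(s)\n",
              length(x$attachments), length(x$nodes)))
  invisible(x)
}

#' Linearize a junction tree into AddingMotif token pairs
#'
#' Replays the decoder's attachment-queue discipline: the product attachment
#' atoms are served in ascending entity order; when an attached motif has
#' further interfaces, those are promoted to attachment atoms and served
#' depth-first before the remaining siblings, in the motif's canonical
#' interface order.
#'
#' @param tree a `junction_tree`.
#' @return List of steps, each `list(input=, target=)`: the input token
#'   carries the attachment (`attach_kind`, `attach_entity`), the target
#'   carries the motif key and interface index.
#' @export
linearize <- function(tree) {
  nodes <- tree$nodes
  used <- logical(length(nodes))
  # queue entries: list(kind = "product"/"promoted", atom = product atom,
  #                     occ = parent occurrence, patom = parent-graph atom)
  queue <- lapply(tree$attachments, function(a) list(kind = "product", atom = a))
  steps <- list()
  while (length(queue)) {
    front <- queue[[1]]; queue <- queue[-1]
    cand <- which(!used & vapply(nodes, function(nd) {
      if (front$kind == "product") {
        nd$parent == 0L && nd$attach_atom == front$atom
      } else {
        nd$parent == front$occ && identical(nd$parent_atom, front$patom)
      }
    }, FALSE))
    if (length(cand) != 1L) {
      unsupported_reaction(sprintf(
        "queue attachment has %d covering motif(s)", length(cand)))
    }
    j <- cand
    used[j] <- TRUE
    nd <- nodes[[j]]
    steps[[length(steps) + 1L]] <- list(
      input = list(
        attach_kind = front$kind,
        attach_entity = if (front$kind == "product") front$atom else NA_integer_),
      target = list(key = nd$motif$key, interface = nd$q,
                    n_interfaces = length(nd$motif$interfaces)))
    rest <- setdiff(seq_along(nd$motif$interfaces), nd$q)
    if (length(rest)) {
      promos <- lapply(rest, function(k) list(
        kind = "promoted", occ = j, patom = nd$motif$interfaces[k]))
      queue <- c(promos, queue)
    }
  }
  if (!all(used)) {
    unsupported_reaction("junction tree has unreachable motif nodes")
  }
  steps
}

#' Build the transformation paths of a set of reactions
#'
#' Corpus-level path construction with batched canonicalization: one
#' OpenBabel pass normalizes all products, two passes key all motifs, one
#' pass canonicalizes all ground-truth reactants. Reactions that cannot be
#' expressed as edit + motif paths are returned as condition objects in the
#' output list (inspect with `inherits(x, "condition")`).
#'
#' @param reactions list of `reaction` objects (or a file path).
#' @param vocab a `motif_vocabulary`.
#' @param normalize run [remove_dataset_shortcut()] first (default).
#' @return List parallel to `reactions`: `transformation_path` objects, or
#'   the condition under which a reaction was rejected.
#' @export
prepare_paths <- function(reactions, vocab, normalize = TRUE) {
  if (is.character(reactions)) reactions <- read_reactions(reactions)
  if (normalize) reactions <- normalize_reactions(reactions)
  stage1 <- lapply(reactions, function(r) {
    tryCatch({
      de <- derive_edits(r)
      am <- r$product$atoms$map[de$attachments]
      occs <- extract_motifs(r, attachment_maps = am, finalize = FALSE)
      list(r = r, de = de, occs = occs)
    }, error = function(e) e)
  })
  ok <- !vapply(stage1, inherits, TRUE, "condition")
  fins <- finalize_motif_sets(lapply(stage1[ok], `[[`, "occs"))
  # ground-truth reactants, batched
  all_react <- unlist(lapply(stage1[ok], function(s) s$r$reactants),
                      recursive = FALSE)
  truth_flat <- if (length(all_react)) {
    canonical_smiles(all_react, keep_maps = FALSE)
  } else character()
  n_react <- vapply(stage1[ok], function(s) length(s$r$reactants), 0L)
  truth_grp <- split(truth_flat, rep(seq_along(n_react), n_react))

  out <- vector("list", length(reactions))
  j <- 0L
  for (i in seq_along(reactions)) {
    if (!ok[i]) { out[[i]] <- stage1[[i]]; next }
    j <- j + 1L
    s <- stage1[[i]]
    sizes <- vapply(s$r$reactants, n_atoms, 0L)
    truth <- truth_grp[[j]][order(-sizes, truth_grp[[j]], method = "radix")]
    out[[i]] <- tryCatch(
      assemble_path(s$r, s$de, fins[[j]], vocab, truth),
      error = function(e) e)
  }
  names(out) <- names(reactions)
  out
}

#' Build the transformation path of one reaction
#'
#' Derives the Edit tokens (ascending entity order), the motif occurrences
#' and junction tree, and linearizes everything into aligned input and
#' target token sequences: `Start` + previous-step tokens on the input side,
#' `Edit`*/`FinishEdit`/`AddingMotif`* on the target side. Applying the
#' target tokens to the product ([apply_path()]) reproduces the reactants.
#'
#' @param rxn a `reaction`.
#' @param vocab a `motif_vocabulary` covering the reaction's motifs.
#' @param normalize run [remove_dataset_shortcut()] first (default).
#' @return A `transformation_path`: `input_tokens`, `target_tokens`,
#'   `labels`, `reaction` (the normalized reaction), and
#'   `reactants_canonical` (map-free truth, in [apply_path()] order).
#' @export
build_path <- function(rxn, vocab, normalize = TRUE) {
  r <- if (normalize) remove_dataset_shortcut(rxn) else rxn
  de <- derive_edits(r)
  am <- r$product$atoms$map[de$attachments]
  occs <- extract_motifs(r, attachment_maps = am)
  smis <- canonical_smiles(r$reactants, keep_maps = FALSE)
  sizes <- vapply(r$reactants, n_atoms, 0L)
  assemble_path(r, de, occs, vocab, smis[order(-sizes, smis, method = "radix")])
}

assemble_path <- function(r, de, occs, vocab, truth) {
  tree <- build_junction_tree(r, de, occs)
  add_steps <- linearize(tree)

  m <- n_bonds(r$product)
  targets <- list()
  inputs <- list(list(action = "Start"))
  tclasses <- type_classes(vocab)

  for (e in de$edits) {
    tok <- if (e$kind == "bond") {
      list(action = "Edit", entity = e$entity, new_order = e$new_order,
           type_class = match(e$new_order, tclasses))
    } else {
      tc <- match(sprintf("a:%d,%d", e$dH, e$dq), tclasses)
      if (is.na(tc)) {
        unsupported_reaction(sprintf(
          "atom-change state (%+d H, %+d q) not in the vocabulary", e$dH, e$dq))
      }
      list(action = "Edit", entity = e$entity, dH = e$dH, dq = e$dq,
           type_class = tc)
    }
    targets[[length(targets) + 1L]] <- tok
  }
  targets[[length(targets) + 1L]] <- list(action = "FinishEdit")

  for (s in add_steps) {
    id <- vocab_lookup(vocab, s$target$key)
    if (is.na(id)) {
      stop(sprintf("coverage error: motif '%s' missing from the vocabulary",
                   s$target$key), call. = FALSE)
    }
    targets[[length(targets) + 1L]] <- list(
      action = "AddingMotif", motif_id = id, interface = s$target$interface,
      n_interfaces = s$target$n_interfaces)
  }

  # align inputs: input t carries the realized token of step t-1, plus the
  # attachment being completed on AddingMotif steps
  for (t in seq_along(targets)[-1]) {
    prev <- targets[[t - 1]]
    cur <- targets[[t]]
    inp <- list(action = prev$action)
    if (prev$action == "Edit") {
      inp$entity <- prev$entity
      inp$type_class <- prev$type_class
    }
    if (cur$action == "AddingMotif") {
      s <- add_steps[[t - 1L - length(de$edits)]]   # steps after FinishEdit
      inp$attach_kind <- s$input$attach_kind
      inp$attach_entity <- if (s$input$attach_kind == "product") {
        m + s$input$attach_entity - 1L
      } else NA_integer_
      if (prev$action == "AddingMotif") {
        inp$prev_motif_id <- prev$motif_id
        inp$prev_interface <- prev$interface
        inp$prev_multi <- prev$n_interfaces > 1L
      }
    }
    inputs[[t]] <- inp
  }

  structure(list(
    input_tokens = inputs,
    target_tokens = targets,
    labels = de$labels,
    reaction = r,
    tree = tree,
    reactants_canonical = truth
  ), class = "transformation_path")
}

#' Round-trip check of transformation paths
#'
#' Applies each path\'s target tokens to its product and compares the
#' resulting reactant set with the ground truth; canonicalization is
#' batched across all paths.
#'
#' @param paths list of `transformation_path`.
#' @param vocab the `motif_vocabulary` the paths were built against.
#' @return Logical vector: exact reactant-multiset match per path.
#' @export
path_roundtrip <- function(paths, vocab) {
  graph_sets <- lapply(paths, function(p) {
    st <- new_editable_graph(p$reaction$product)
    for (tok in p$target_tokens) {
      st <- switch(tok$action,
        Edit = apply_edit(st, tok$entity,
                          tok[intersect(names(tok), c("new_order", "dH", "dq"))]),
        FinishEdit = finish_edit(st),
        AddingMotif = attach_motif(st, st$queue[1],
                                   vocab_motif(vocab, tok$motif_id),
                                   tok$interface))
    }
    if (st$phase == "edit") st <- finish_edit(st)
    final <- sanitized_graph(st)
    lapply(mol_components(final), function(ix)
      induced_subgraph_mol(final, ix)$graph)
  })
  lens <- vapply(graph_sets, length, 0L)
  flat <- unlist(graph_sets, recursive = FALSE)
  smis <- canonical_smiles(flat, keep_maps = FALSE)
  grp <- split(smis, rep(seq_along(lens), lens))
  sizes <- split(vapply(flat, n_atoms, 0L), rep(seq_along(lens), lens))
  vapply(seq_along(paths), function(i) {
    got <- grp[[i]][order(-sizes[[i]], grp[[i]], method = "radix")]
    identical(got, paths[[i]]$reactants_canonical)
  }, TRUE)
}

#' @export
print.transformation_path <- function(x, ...) {
  acts <- vapply(x$target_tokens, `[[`, "", "action")
  cat(sprintf("<transformation_path> %s\n", paste(acts, collapse = " ")))
  invisible(x)
}

#' Serialize transformation paths to JSON records
#'
#' One JSON object per reaction: tokens, labels, the normalized reaction
#' SMILES and the ground-truth reactants. [load_paths()] restores them
#' (re-parsing the reaction and resolving motif ids against the vocabulary).
#'
#' @param paths list of `transformation_path`.
#' @param path output file.
#' @export
save_paths <- function(paths, path) {
  recs <- lapply(paths, function(p) list(
    rxn_smiles = paste0(
      paste(vapply(p$reaction$reactants, write_smiles, ""), collapse = "."),
      ">>", write_smiles(p$reaction$product)),
    reaction_class = p$reaction$reaction_class,
    input_tokens = p$input_tokens,
    target_tokens = p$target_tokens,
    labels = p$labels,
    reactants_canonical = p$reactants_canonical
  ))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_paths
#' @export
load_paths <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(recs, function(rec) {
    rxn <- parse_reaction(if (is.null(rec$reaction_class) ||
                              is.na(rec$reaction_class %||% NA)) {
      rec$rxn_smiles
    } else paste0(rec$rxn_smiles, "\t", rec$reaction_class))
    fix_tok <- function(tok) {
      for (f in c("entity", "type_class", "motif_id", "interface",
                  "n_interfaces", "attach_entity", "prev_motif_id",
                  "prev_interface", "dH", "dq")) {
        v <- tok[[f]]
        if (!is.null(v) && length(v) == 1L && !is.na(suppressWarnings(as.integer(v)))) {
          tok[[f]] <- as.integer(v)
        } else if (!is.null(v) && is.na(v %||% NA)) {
          tok[[f]] <- NA_integer_
        }
      }
      tok
    }
    structure(list(
      input_tokens = lapply(rec$input_tokens, fix_tok),
      target_tokens = lapply(rec$target_tokens, fix_tok),
      labels = as.integer(unlist(rec$labels)),
      reaction = rxn,
      reactants_canonical = as.character(unlist(rec$reactants_canonical))
    ), class = "transformation_path")
  })
}

# target tokens in the form apply_path() executes (bond edits carry
# new_order, atom edits carry dH/dq, motifs resolved through the vocab)
path_exec_tokens <- function(p) p$target_tokens
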