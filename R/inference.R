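# Beam-search decoding of products into ranked reactant sets, and the
# Top-k canonical-SMILES evaluation metric.

#' Beam search over transformation paths
#'
#' Decodes a product graph autoregressively: at each step every live
#' hypothesis expands over the factored heads (action + entity + type in the
#' Edit phase; motif + interface in the AddingMotif phase), scoring each
#' candidate token by the sum of its head log-probabilities; the global
#' top-`k` hypotheses by cumulative log-likelihood survive. Expansions whose
#' graph operation fails a chemistry check (valence overflow, interface
#' element mismatch, no-op edit) are pruned. A hypothesis finishes when all
#' attachments have been served; scores are raw log-likelihood sums (no
#' length normalization).
#'
#' @param product a [mol_graph()] (atom maps ignored). For results
#'   consistent with training, pass a canonical-order product
#'   (see [predict_reactants()]).
#' @param model a `retro_model` or `retro_fit`.
#' @param vocab the `motif_vocabulary`.
#' @param k beam width (>= 1).
#' @param max_len token cap per path.
#' @param reaction_class class label for class-conditioned models.
#' @return List of finished hypotheses, sorted by descending
#'   log-likelihood: each has `tokens`, `log_likelihood`, `state`
#'   (the final `editable_graph`).
#' @export
beam_search <- function(product, model, vocab, k = 5L, max_len = 30L,
                        reaction_class = NULL) {
  if (inherits(model, "retro_fit")) model <- model$model
  stopifnot(k >= 1L)
  if (!identical(model$vocab_hash, vocab_hash(vocab))) {
    stop("model and vocabulary do not match", call. = FALSE)
  }
  enc <- encode_graph(model, product, reaction_class)
  m0 <- n_bonds(product); n0 <- n_atoms(product)
  n_type <- model$n_type
  tclasses <- c("none", "single", "double", "triple")
  iface_counts <- vapply(vocab$motifs, function(m) length(m$interfaces), 0L)
  # per-motif interface elements, for element pre-filtering
  iface_syms <- lapply(vocab$motifs, function(m) m$graph$atoms$symbol[m$interfaces])

  st0 <- new_editable_graph(product)
  hyp0 <- list(st = st0, dec = decoder_init(model, enc),
               hsyn = synthon_embedding(model, graph_view(st0), reaction_class),
               logp = 0, tokens = list(), finished = FALSE)
  expand <- function(hyp) {
    ds <- decode_step(model, enc, hyp$dec)
    cands <- enumerate_candidates(hyp, ds, model, vocab, m0, n_type,
                                  iface_counts, iface_syms)
    out <- list()
    for (cd in cands) {
      new_hyp <- tryCatch(
        advance_hypothesis(hyp, cd, ds, model, enc, vocab, m0, n0,
                           reaction_class),
        retromotif_chemistry = function(e) NULL,
        retromotif_state = function(e) NULL)
      if (!is.null(new_hyp)) out[[length(out) + 1L]] <- new_hyp
    }
    out
  }
  beam_core(hyp0, expand, k, max_len)
}

# Generic breadth-limited best-first search: at every step each live
# hypothesis expands, and the global top-k of (finished + expanded) by
# cumulative log-likelihood survive. Independent of the molecular machinery
# so it can be exercised with hand-built expanders.
beam_core <- function(init, expand, k, max_len) {
  live <- list(init)
  finished <- list()
  for (step in seq_len(max_len)) {
    if (!length(live)) break
    pool <- finished
    for (hyp in live) {
      for (h2 in expand(hyp)) pool[[length(pool) + 1L]] <- h2
    }
    if (!length(pool)) break
    ord <- order(vapply(pool, `[[`, 0, "logp"), decreasing = TRUE)
    pool <- pool[ord[seq_len(min(k, length(pool)))]]
    finished <- Filter(function(h) h$finished, pool)
    live <- Filter(function(h) !h$finished, pool)
  }
  finished[order(vapply(finished, `[[`, 0, "logp"), decreasing = TRUE)]
}

# Exhaustive depth-first enumeration over the same expander interface: the
# brute-force oracle for beam_core on small path spaces.
enumerate_paths <- function(init, expand, max_len) {
  out <- list()
  recurse <- function(hyp, depth) {
    if (hyp$finished) { out[[length(out) + 1L]] <<- hyp; return(invisible()) }
    if (depth >= max_len) return(invisible())
    for (h2 in expand(hyp)) recurse(h2, depth + 1L)
  }
  recurse(init, 0L)
  out[order(vapply(out, `[[`, 0, "logp"), decreasing = TRUE)]
}

enumerate_candidates <- function(hyp, ds, model, vocab, m0, n_type,
                                 iface_counts, iface_syms) {
  st <- hyp$st
  cands <- list()
  if (st$phase == "edit") {
    cands[[1L]] <- list(action = "FinishEdit", logp = ds$act_logp[2])
    nE <- m0 + st$n0
    lp_edit <- ds$act_logp[1]
    for (i in seq_len(nE)) {
      classes <- if (i <= m0) seq_len(4L) else setdiff(seq_len(n_type), 1:4)
      for (cc in classes) {
        cands[[length(cands) + 1L]] <- list(
          action = "Edit", entity = i - 1L, type_class = cc,
          logp = lp_edit + log(ds$edit_scores[i] + 1e-12) + ds$type_logp[i, cc])
      }
    }
  } else if (st$phase == "adding_motif") {
    att_sym <- st$graph$atoms$symbol[st$queue[1]]
    lp_add <- ds$act_logp[3]
    for (z in seq_along(vocab$motifs)) {
      qs <- which(iface_syms[[z]] == att_sym)
      for (q in qs) {
        cands[[length(cands) + 1L]] <- list(
          action = "AddingMotif", motif_id = z, interface = q,
          logp = lp_add + ds$motif_logp[z] + ds$ifc_logp[q])
      }
    }
  }
  cands
}

advance_hypothesis <- function(hyp, cd, ds, model, enc, vocab, m0, n0,
                               reaction_class) {
  st <- hyp$st
  tclasses4 <- c("none", "single", "double", "triple")
  new_st <- switch(cd$action,
    Edit = {
      state <- if (cd$entity < m0) {
        list(new_order = tclasses4[cd$type_class])
      } else {
        ac <- (if (inherits(vocab, "motif_vocabulary")) vocab$atom_changes)
        row <- cd$type_class - 4L
        list(dH = ac$dH[row], dq = ac$dq[row])
      }
      apply_edit(st, cd$entity, state)
    },
    FinishEdit = finish_edit(st),
    AddingMotif = attach_motif(st, st$queue[1],
                               vocab_motif(vocab, cd$motif_id), cd$interface))
  tokens <- c(hyp$tokens, list(cd[setdiff(names(cd), "logp")]))
  fin <- new_st$phase == "done"
  out <- list(st = new_st, logp = hyp$logp + cd$logp, tokens = tokens,
              finished = fin)
  if (fin) return(out)
  # synthon embedding: recomputed after each edit, frozen at FinishEdit
  hsyn <- if (cd$action == "Edit") {
    synthon_embedding(model, graph_view(new_st), reaction_class)
  } else if (cd$action == "FinishEdit") {
    synthon_embedding(model, new_st$synthon, reaction_class)
  } else hyp$hsyn
  out$hsyn <- hsyn
  # input token for the next step mirrors the training-side alignment
  tok <- list(action = cd$action)
  dists <- list(pa = ds$pa)
  if (cd$action == "Edit") {
    tok$entity <- cd$entity
    dists$ptype <- exp(ds$type_logp[cd$entity + 1L, ])
  } else {
    nxt <- new_st$queue[1]
    if (cd$action == "AddingMotif" &&
        length(vocab_motif(vocab, cd$motif_id)$interfaces) > 1L) {
      tok$prev_multi <- TRUE
      dists$pmot <- ds$pmot
      dists$pifc <- ds$pifc
    } else if (nxt <= n0) {
      tok$attach_kind <- "product"
      tok$attach_entity <- m0 + nxt - 1L
    } else {
      tok$attach_kind <- "promoted"
    }
  }
  x <- next_input_vec(model$params, tok, dists, enc$entities, hsyn)$x
  out$dec <- list(u = ds$state$u, x = x)
  out
}

# canonical reactant-set string of a finished hypothesis
hypothesis_graphs <- function(hyp) {
  final <- sanitized_graph(hyp$st)
  lapply(mol_components(final), function(ix)
    induced_subgraph_mol(final, ix)$graph)
}

#' Predict reactants for a product SMILES
#'
#' Parses and canonically reorders the product (atom maps are unnecessary
#' and ignored), runs [beam_search()], converts every finished hypothesis
#' into canonical map-free reactant SMILES, and merges duplicate reactant
#' sets keeping the best score.
#'
#' @param smiles a product SMILES string.
#' @param model a `retro_model` or `retro_fit`.
#' @param vocab the `motif_vocabulary`.
#' @param k beam width; at most `k` ranked predictions are returned.
#' @param reaction_class class label for class-conditioned models.
#' @param max_len token cap per path.
#' @return A tibble with `rank`, `reactants` (dot-joined canonical SMILES,
#'   largest component first) and `log_likelihood`, sorted by rank.
#' @export
predict_reactants <- function(smiles, model, vocab, k = 5L,
                              reaction_class = NULL, max_len = 30L) {
  g <- tryCatch(parse_smiles(smiles), error = function(e) {
    stop(sprintf("invalid product SMILES '%s': %s", smiles,
                 conditionMessage(e)), call. = FALSE)
  })
  g$atoms$map <- 0L
  # canonical atom order, as in training after shortcut removal
  g$atoms$map <- seq_len(n_atoms(g))
  g <- parse_smiles(canonical_smiles(g, keep_maps = TRUE))
  g$atoms$map <- 0L
  hyps <- beam_search(g, model, vocab, k = k, max_len = max_len,
                      reaction_class = reaction_class)
  if (!length(hyps)) {
    warning("beam search found no valid finished hypothesis")
    return(tibble::tibble(rank = integer(), reactants = character(),
                          log_likelihood = numeric()))
  }
  gsets <- lapply(hyps, hypothesis_graphs)
  lens <- vapply(gsets, length, 0L)
  flat <- unlist(gsets, recursive = FALSE)
  smis <- canonical_smiles(flat, keep_maps = FALSE)
  grp <- split(smis, rep(seq_along(lens), lens))
  sizes <- split(vapply(flat, n_atoms, 0L), rep(seq_along(lens), lens))
  strs <- vapply(seq_along(hyps), function(i)
    paste(grp[[i]][order(-sizes[[i]], grp[[i]], method = "radix")], collapse = "."), "")
  scores <- vapply(hyps, `[[`, 0, "logp")
  keep <- !duplicated(strs)
  out <- tibble::tibble(reactants = strs[keep],
                        log_likelihood = scores[keep])
  out <- out[order(-out$log_likelihood), ]
  out$rank <- seq_len(nrow(out))
  out[, c("rank", "reactants", "log_likelihood")]
}

#' Canonical reactant-set string
#'
#' Canonicalizes each dot-separated component map-free and joins them
#' largest-first (ties lexicographic) — the normal form used by the Top-k
#' metric on both prediction and ground-truth sides.
#'
#' @param smiles character vector of (multi-component) SMILES.
#' @return Character vector of normalized reactant-set strings.
#' @export
canonical_reactant_set <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)
  lens <- vapply(parts, length, 0L)
  gs <- lapply(unlist(parts), parse_smiles)
  for (i in seq_along(gs)) gs[[i]]$atoms$map <- 0L
  can <- canonical_smiles(gs, keep_maps = FALSE)
  sizes <- vapply(gs, n_atoms, 0L)
  grp <- split(seq_along(can), rep(seq_along(lens), lens))
  unname(vapply(grp, function(ix)
    paste(can[ix][order(-sizes[ix], can[ix], method = "radix")], collapse = "."), ""))
}

#' Top-k accuracy of ranked reactant predictions
#'
#' The fraction of records whose ground-truth reactant set (order-insensitive
#' multiset comparison in canonical map-free SMILES) appears among the top-k
#' ranked predictions.
#'
#' @param predictions tibble with columns `input_id`, `rank`, `reactants`.
#' @param truth tibble with columns `input_id`, `reactants` (one row per
#'   record), or a character vector named by input id.
#' @param ks the k values to report.
#' @param canonicalize re-normalize both sides with
#'   [canonical_reactant_set()] (set `FALSE` if already normalized).
#' @return A tibble with columns `k` and `accuracy` (non-decreasing in `k`).
#' @export
topk_accuracy <- function(predictions, truth, ks = c(1L, 3L, 5L, 10L),
                          canonicalize = TRUE) {
  if (!is.data.frame(truth)) {
    truth <- tibble::tibble(input_id = names(truth),
                            reactants = unname(truth))
  }
  preds <- tibble::as_tibble(predictions)
  if (canonicalize) {
    preds$reactants <- canonical_reactant_set(preds$reactants)
    truth$reactants <- canonical_reactant_set(truth$reactants)
  }
  ids <- unique(truth$input_id)
  hit_rank <- vapply(ids, function(id) {
    tr <- truth$reactants[truth$input_id == id][1]
    pr <- preds[preds$input_id == id, ]
    w <- which(pr$reactants == tr)
    if (length(w)) min(pr$rank[w]) else Inf
  }, 0)
  tibble::tibble(k = as.integer(ks),
                 accuracy = vapply(ks, function(k) mean(hit_rank <= k), 0))
}
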