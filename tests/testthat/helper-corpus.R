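# Shared fixtures, built once per test run and memoized.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

toy_records <- function() c(
  ester    = "[CH3:5][C:4](=[O:6])O.[OH:3][CH2:2][CH3:1]>>[CH3:1][CH2:2][O:3][C:4]([CH3:5])=[O:6]",
  identity = "[CH3:1][OH:2]>>[CH3:1][OH:2]",
  tosyl    = "[CH3:1][CH2:2]OS(=O)(=O)c1ccc(C)cc1.[NH2:3][CH3:4]>>[CH3:1][CH2:2][NH:3][CH3:4]",
  biphenyl = "[CH3:1][C:2](=[O:3])Oc1ccc(-c2ccccc2)cc1.[OH:4][CH3:5]>>[CH3:1][C:2](=[O:3])[O:4][CH3:5]",
  quat     = "[CH3:1][N:2]([CH3:3])[CH3:4].[CH3:5]I>>[CH3:1][N+:2]([CH3:3])([CH3:4])[CH3:5]"
)

toy_reactions <- function() memo("toy_rxns", lapply(toy_records(), parse_reaction))

toy_vocab <- function() memo("toy_vocab", build_vocabulary(toy_reactions()))

toy_paths <- function() memo("toy_paths", {
  prepare_paths(toy_reactions(), toy_vocab())
})

small_corpus <- function() memo("small_corpus", {
  recs <- generate_fixtures(12, seed = 7)
  rxns <- lapply(recs, parse_reaction)
  vocab <- build_vocabulary(rxns)
  paths <- prepare_paths(rxns, vocab)
  list(recs = recs, rxns = rxns, vocab = vocab, paths = paths)
})

# tiny randomly initialized model over the toy vocabulary
tiny_model <- function(D = 8L, L = 1L, heads = 2L, seed = 3L) {
  new_model(toy_vocab(), model_config(D = D, L = L, heads = heads, seed = seed))
}

# synthon embeddings entering each input step of a path (teacher forcing)
hsyn_steps <- function(model, path, vocab) {
  st <- new_editable_graph(path$reaction$product)
  N <- length(path$target_tokens)
  out <- vector("list", N)
  cur <- retromotif:::synthon_embedding(model, retromotif:::graph_view(st))
  for (t in seq_len(N)) {
    out[[t]] <- cur
    tok <- path$target_tokens[[t]]
    st <- switch(tok$action,
      Edit = apply_edit(st, tok$entity,
                        tok[intersect(names(tok), c("new_order", "dH", "dq"))]),
      FinishEdit = finish_edit(st),
      AddingMotif = attach_motif(st, st$queue[1],
                                 vocab_motif(vocab, tok$motif_id),
                                 tok$interface))
    if (tok$action == "Edit") {
      cur <- retromotif:::synthon_embedding(model, retromotif:::graph_view(st))
    }
    if (tok$action == "FinishEdit") {
      cur <- retromotif:::synthon_embedding(model, st$synthon)
    }
  }
  out
}

# reorder atoms of a molecular graph by `perm` (atom i moves to position
# perm[i]); used for permutation-invariance checks
permute_mol <- function(g, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  atoms <- g$atoms[inv, , drop = FALSE]
  rownames(atoms) <- NULL
  b <- g$bonds
  if (nrow(b)) {
    b$u <- perm[b$u]; b$v <- perm[b$v]
  }
  # chiral tags are normalised to ascending neighbour index (implicit H
  # first); relabelling can change that order, flipping the parity
  for (anew in which(atoms$chiral != "")) {
    aold <- perm_inv_lookup(inv, anew)
    nb_old <- sort(c(g$bonds$v[g$bonds$u == aold], g$bonds$u[g$bonds$v == aold]))
    seq_old <- c(if (g$atoms$hcount[aold] > 0L) 0L, nb_old)
    seq_new <- ifelse(seq_old == 0L, 0L, perm[pmax(seq_old, 1L)])
    if (retromotif:::permutation_parity(order(seq_new)) == -1L) {
      atoms$chiral[anew] <- if (atoms$chiral[anew] == "@") "@@" else "@"
    }
  }
  mol_graph(atoms, b)
}

perm_inv_lookup <- function(inv, anew) inv[anew]


# independent greedy decoder: full candidate enumeration at each step, keep
# the locally best child only (the oracle for beam width 1)
greedy_decode_oracle <- function(model, vocab, g, max_len = 8L) {
  enc <- encode_graph(model, g)
  m0 <- n_bonds(g); n0 <- n_atoms(g)
  iface_syms <- lapply(vocab$motifs, function(m) m$graph$atoms$symbol[m$interfaces])
  st0 <- new_editable_graph(g)
  init <- list(st = st0, dec = decoder_init(model, enc),
               hsyn = retromotif:::synthon_embedding(model, retromotif:::graph_view(st0)),
               logp = 0, tokens = list(), finished = FALSE)
  hyp <- init
  for (step in seq_len(max_len)) {
    if (hyp$finished) break
    ds <- decode_step(model, enc, hyp$dec)
    cands <- retromotif:::enumerate_candidates(hyp, ds, model, vocab, m0,
                                               model$n_type, NULL, iface_syms)
    kids <- list()
    for (cd in cands) {
      h2 <- tryCatch(
        retromotif:::advance_hypothesis(hyp, cd, ds, model, enc, vocab, m0,
                                        n0, NULL),
        error = function(e) NULL)
      if (!is.null(h2)) kids[[length(kids) + 1L]] <- h2
    }
    if (!length(kids)) return(NULL)
    hyp <- kids[[which.max(vapply(kids, `[[`, 0, "logp"))]]
  }
  hyp
}
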