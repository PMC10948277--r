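test_that("bond removal disconnects and hydrogens refill at open sites", {
  g <- parse_smiles("CC(=O)OCC")      # ester; bond 3 is C(=O)-O in this order
  st <- new_editable_graph(g)
  bi <- retromotif:::find_bond(g, 2L, 4L)     # carbonyl C - ester O
  st <- apply_edit(st, bi - 1L, list(new_order = "none"))
  st <- finish_edit(st)
  final <- retromotif:::sanitized_graph(st)
  comps <- retromotif:::mol_components(final)
  expect_length(comps, 2L)            # two connected components (via traversal)
  smis <- sort(canonical_smiles(lapply(comps, function(ix)
    retromotif:::induced_subgraph_mol(final, ix)$graph)))
  expect_identical(smis, sort(c("CC=O", "CCO")))
})

test_that("bond retype rebalances hydrogen counts by valence", {
  g <- parse_smiles("CC")
  st <- new_editable_graph(g)
  st <- apply_edit(st, 0L, list(new_order = "double"))
  st <- finish_edit(st)
  out <- retromotif:::sanitized_graph(st)
  expect_identical(canonical_smiles(out), "C=C")
  expect_identical(out$atoms$hcount, c(2L, 2L))
})

test_that("invalid edits are rejected", {
  g <- parse_smiles("CC")
  st <- new_editable_graph(g)
  expect_error(apply_edit(st, 5L, list(new_order = "none")), "outside")
  expect_error(apply_edit(st, 0L, list(new_order = "single")), "no-op")
  # overflowing carbon valence is a chemistry error
  g2 <- parse_smiles("C(C)(C)(C)C")
  st2 <- new_editable_graph(g2)
  expect_error(apply_edit(st2, 0L, list(new_order = "triple")), "valence")
})

test_that("finish_edit sorts the queue and freezes the synthon", {
  g <- parse_smiles("CC(=O)OCC")
  st <- new_editable_graph(g)
  st0 <- finish_edit(st)
  expect_identical(st0$phase, "done")          # empty queue: nothing to add
  st <- new_editable_graph(g)
  st <- apply_edit(st, retromotif:::find_bond(g, 2L, 4L) - 1L,
                   list(new_order = "none"))
  st <- finish_edit(st)
  expect_identical(st$phase, "adding_motif")
  expect_identical(st$queue, sort(st$queue))
  expect_s3_class(st$synthon, "mol_graph")
})

test_that("motif attachment merges the interface with the attachment atom", {
  # acid-chloride completion: synthon CC(=O)* + chlorine motif -> CC(=O)Cl
  g <- parse_smiles("CC(=O)OC")
  st <- new_editable_graph(g)
  st <- apply_edit(st, retromotif:::find_bond(g, 2L, 4L) - 1L,
                   list(new_order = "none"))
  st <- finish_edit(st)
  cl <- retromotif:::motif_from_key(canonical_smiles(parse_smiles("Cl[CH0:1]"),
                                                     keep_maps = TRUE))
  att <- st$queue[1]
  n_before <- n_atoms(st$graph)
  st <- attach_motif(st, att, cl, 1L)
  expect_identical(n_atoms(st$graph), n_before + 1L)   # interface merged
  # element mismatch is a merge error
  st2 <- new_editable_graph(g)
  st2 <- apply_edit(st2, retromotif:::find_bond(g, 2L, 4L) - 1L,
                    list(new_order = "none"))
  st2 <- finish_edit(st2)
  o_motif <- retromotif:::motif_from_key(
    canonical_smiles(parse_smiles("C[OH0:1]"), keep_maps = TRUE))
  front <- st2$queue[1]
  if (st2$graph$atoms$symbol[front] == "C") {
    expect_error(attach_motif(st2, front, o_motif, 1L), "merge error")
  }
  # attaching outside the adding phase is a state error
  expect_error(attach_motif(new_editable_graph(g), 1L, cl, 1L), "phase")
})

test_that("multi-interface motifs grow the queue (promotion)", {
  p <- toy_paths()[["tosyl"]]
  v <- toy_vocab()
  st <- new_editable_graph(p$reaction$product)
  for (tok in p$target_tokens) {
    if (tok$action == "Edit") {
      st <- apply_edit(st, tok$entity,
                       tok[intersect(names(tok), c("new_order", "dH", "dq"))])
    } else if (tok$action == "FinishEdit") {
      st <- finish_edit(st)
      q0 <- length(st$queue)
    } else {
      mot <- vocab_motif(v, tok$motif_id)
      before <- length(st$queue)
      st <- attach_motif(st, st$queue[1], mot, tok$interface)
      if (length(mot$interfaces) > 1L) {
        expect_identical(length(st$queue), before)   # -1 served, +1 promoted
        expect_true(st$queue[1] %in% st$promoted)
      }
    }
  }
  expect_identical(st$phase, "done")
})

test_that("the identity path returns the product unchanged", {
  g <- parse_smiles("CC(=O)OCC")
  out <- apply_path(g, list(list(action = "Start"), list(action = "FinishEdit")))
  expect_identical(out, canonical_smiles(g))
})

test_that("step errors propagate with the step index", {
  g <- parse_smiles("CC")
  bad <- list(list(action = "Edit", entity = 0L, new_order = "single"))
  expect_error(apply_path(g, bad), "step 1")
})

test_that("heavy atoms are conserved through a full path", {
  sc <- small_corpus()
  for (p in sc$paths[1:6]) {
    prod <- p$reaction$product
    st <- new_editable_graph(prod)
    added <- 0L
    for (tok in p$target_tokens) {
      if (tok$action == "Edit") {
        st <- apply_edit(st, tok$entity,
                         tok[intersect(names(tok), c("new_order", "dH", "dq"))])
      } else if (tok$action == "FinishEdit") st <- finish_edit(st)
      else {
        mot <- vocab_motif(sc$vocab, tok$motif_id)
        added <- added + n_atoms(mot$graph) - 1L     # one merge per attach
        st <- attach_motif(st, st$queue[1], mot, tok$interface)
      }
    }
    expect_identical(n_atoms(st$graph), n_atoms(prod) + added)
  }
})
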