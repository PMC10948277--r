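# Expected motif keys computed independently: the motif graphs are written
# out by hand as mapped SMILES (map numbers marking interface atoms) and
# canonicalized directly, without going through extract_motifs().
hand_key <- function(mapped_smiles) canonical_smiles(parse_smiles(mapped_smiles),
                                                     keep_maps = TRUE)

test_that("rule 1 keeps an interface copy of the attachment atom", {
  r <- remove_dataset_shortcut(toy_reactions()[["ester"]])
  de <- derive_edits(r)
  occs <- extract_motifs(r, attachment_maps = r$product$atoms$map[de$attachments])
  keys <- sort(vapply(occs, function(o) o$motif$key, ""))
  # acid side: hydroxyl + carbonyl-carbon interface; alcohol side: hydrogen
  # completion = bare interface copy of the ester oxygen
  expect_identical(keys, sort(c(hand_key("[C:1]O"), hand_key("[OH:1]"))))
  # interface retains element/charge/hydrogens of the copied atom
  acid <- occs[[which(vapply(occs, function(o) o$motif$key, "") == hand_key("[C:1]O"))]]
  ia <- acid$motif$interfaces[1]
  expect_identical(acid$motif$graph$atoms$symbol[ia], "C")
  expect_identical(acid$motif$graph$atoms$hcount[ia], 0L)
})

test_that("reactants identical to synthons yield no leaving-group motifs", {
  r <- remove_dataset_shortcut(toy_reactions()[["identity"]])
  expect_length(extract_motifs(r, attachment_maps = integer()), 0L)
})

test_that("rule 2 splits bonds bridging separate rings", {
  r <- remove_dataset_shortcut(toy_reactions()[["biphenyl"]])
  de <- derive_edits(r)
  occs <- extract_motifs(r, attachment_maps = r$product$atoms$map[de$attachments])
  # the biphenyl leaving group must arrive as two single-ring motifs
  n_ring_atoms <- vapply(occs, function(o)
    sum(retromotif:::atoms_in_ring(o$motif$graph)), 0L)
  expect_true(all(n_ring_atoms <= 6))
  expect_identical(sum(n_ring_atoms == 6), 2L)
  # and no stored motif keeps a bond joining two distinct rings
  for (o in occs) {
    g <- o$motif$graph
    if (!nrow(g$bonds)) next
    rb <- retromotif:::bonds_in_ring(g)
    ra <- retromotif:::atoms_in_ring(g)
    expect_false(any(!rb & ra[g$bonds$u] & ra[g$bonds$v]))
  }
})

test_that("rule 3 exposes a second interface on the parent motif", {
  r <- remove_dataset_shortcut(toy_reactions()[["tosyl"]])
  de <- derive_edits(r)
  occs <- extract_motifs(r, attachment_maps = r$product$atoms$map[de$attachments])
  nif <- vapply(occs, function(o) length(o$motif$interfaces), 0L)
  expect_true(any(nif == 2L))        # O-SO2 parent: carbon + sulfur interfaces
  kids <- occs[vapply(occs, function(o) o$parent > 0L, TRUE)]
  expect_length(kids, 1L)            # the tolyl ring, child of the sulfonate
  expect_identical(kids[[1]]$motif$key, hand_key("Cc1ccc(cc1)[S:1]"))
  # rule 2/3 closure on every stored motif
  for (o in occs) {
    g <- o$motif$graph
    if (!nrow(g$bonds)) next
    rb <- retromotif:::bonds_in_ring(g)
    ra <- retromotif:::atoms_in_ring(g)
    deg <- retromotif:::atom_degrees(g)
    viol <- !rb & ((ra[g$bonds$u] & !ra[g$bonds$v] & deg[g$bonds$v] > 1L) |
                   (ra[g$bonds$v] & !ra[g$bonds$u] & deg[g$bonds$u] > 1L))
    expect_false(any(viol))
  }
})

test_that("vocabulary content is deterministic and order independent", {
  rxns <- toy_reactions()
  v1 <- build_vocabulary(rxns)
  v2 <- build_vocabulary(rev(rxns))
  expect_identical(v1$keys, v2$keys)
  expect_identical(sort(v1$freq), sort(v2$freq))
  expect_identical(build_vocabulary(list())$keys, character())
  # distinct canonical keys define |Z|
  expect_identical(length(v1$keys), length(unique(v1$keys)))
})

test_that("vocabulary files round-trip exactly and reject bad input", {
  v <- toy_vocab()
  f <- withr::local_tempfile(fileext = ".json")
  save_vocabulary(v, f)
  v2 <- load_vocabulary(f)
  expect_identical(v2$keys, v$keys)
  expect_identical(v2$atom_changes, v$atom_changes)
  expect_identical(retromotif:::vocab_hash(v2), retromotif:::vocab_hash(v))
  for (i in seq_along(v$keys)) {
    expect_identical(v2$motifs[[i]]$interfaces, v$motifs[[i]]$interfaces)
    expect_identical(canonical_smiles(v2$motifs[[i]]$graph),
                     canonical_smiles(v$motifs[[i]]$graph))
  }
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(readLines(f), collapse = ""), 1, 40), bad)
  expect_error(load_vocabulary(bad), "vocabulary")
})

test_that("motif atoms account exactly for the reactant atoms", {
  for (p in small_corpus()$paths[1:8]) {
    r <- p$reaction
    de <- derive_edits(r)
    occs <- extract_motifs(r, attachment_maps = r$product$atoms$map[de$attachments])
    reactant_heavy <- sort(unlist(lapply(r$reactants, function(g) g$atoms$symbol)))
    motif_extra <- unlist(lapply(occs, function(o) {
      # only the merge interface is a duplicated copy; other interfaces are
      # real reactant atoms exposed as future attachment sites
      o$motif$graph$atoms$symbol[-o$motif$interfaces[o$q]]
    }))
    # child motifs whose interface copies a parent-motif atom duplicate it;
    # parent-level interfaces copy synthon atoms
    synthon_heavy <- r$product$atoms$symbol
    expect_identical(sort(c(synthon_heavy, motif_extra)), reactant_heavy)
  }
})
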