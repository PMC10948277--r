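test_that("parse_reaction validates structure and mapping", {
  r <- parse_reaction("[CH3:1][OH:2]>>[CH3:1][OH:2]")
  expect_length(r$reactants, 1L)
  expect_identical(n_atoms(r$product), 2L)

  r2 <- parse_reaction(toy_records()[["ester"]])
  expect_length(r2$reactants, 2L)
  # brute force: product map multiset equals matched reactant maps
  rmaps <- unlist(lapply(r2$reactants, function(g) g$atoms$map))
  expect_setequal(r2$product$atoms$map, rmaps[rmaps > 0])

  expect_error(parse_reaction("[CH3:1][O:2][CH3:3]>>"), "reactants>>product")
  expect_error(parse_reaction("[CH3:1]O>>[CH3:1][OH:2]"), "mapping error")
  expect_error(parse_reaction("[CH3:1][OH:1]>>[CH3:1][OH:1]"), "duplicated")
  r3 <- parse_reaction(paste0(toy_records()[["ester"]], "\t3"))
  expect_identical(r3$reaction_class, 3L)
})

test_that("shortcut removal canonicalizes order and is permutation invariant", {
  base <- parse_reaction(toy_records()[["ester"]])
  norm <- remove_dataset_shortcut(base)
  expect_identical(norm$product$atoms$map, seq_len(n_atoms(norm$product)))
  # chemically identical
  expect_identical(canonical_smiles(norm$product), canonical_smiles(base$product))
  # idempotent
  ref <- canonical_smiles(norm$product, keep_maps = TRUE)
  expect_identical(canonical_smiles(remove_dataset_shortcut(norm)$product,
                                    keep_maps = TRUE), ref)
  # invariant under 10 random re-mappings
  set.seed(9)
  for (i in 1:10) {
    pm <- sample(50, 6)
    s <- sprintf(
      "[CH3:%d][C:%d](=[O:%d])O.[OH:%d][CH2:%d][CH3:%d]>>[CH3:%d][CH2:%d][O:%d][C:%d]([CH3:%d])=[O:%d]",
      pm[5], pm[4], pm[6], pm[3], pm[2], pm[1],
      pm[1], pm[2], pm[3], pm[4], pm[5], pm[6])
    out <- remove_dataset_shortcut(parse_reaction(s))
    expect_identical(canonical_smiles(out$product, keep_maps = TRUE), ref)
    got <- lapply(out$reactants, function(g) sort(g$atoms$map[g$atoms$map > 0]))
    want <- lapply(norm$reactants, function(g) sort(g$atoms$map[g$atoms$map > 0]))
    expect_identical(got, want)
  }
  # batched normalization agrees with the per-reaction path
  batch <- normalize_reactions(list(base, base))
  expect_identical(canonical_smiles(batch[[1]]$product, keep_maps = TRUE), ref)
})

test_that("entity indexing offsets atoms by the bond count", {
  g <- parse_smiles("CCO")           # n = 3, m = 2
  ix <- index_entities(g)
  expect_identical(as.integer(ix), 0:4)
  expect_identical(attr(ix, "kind"), rep(c("bond", "atom"), c(2, 3)))
  g1 <- parse_smiles("C")
  expect_identical(as.integer(index_entities(g1)), 0L)
  benz <- parse_smiles("c1ccccc1")   # n = 6, m = 6
  ixb <- index_entities(benz)
  expect_identical(as.integer(ixb)[attr(ixb, "kind") == "atom"], 6:11)
  # bijection onto [0, m+n)
  for (p in small_corpus()$paths[1:4]) {
    g <- p$reaction$product
    expect_identical(sort(as.integer(index_entities(g))),
                     0:(n_bonds(g) + n_atoms(g) - 1L))
  }
})

test_that("featurizer widths are exact and values well-formed", {
  g <- parse_smiles("CCO")
  fs <- featurize(g)
  expect_identical(dim(fs$atom_features), c(3L, 45L))
  expect_identical(dim(fs$bond_features), c(2L, 12L))
  expect_identical(dim(fs$bond_type_onehot), c(2L, 4L))
  expect_true(all(rowSums(fs$bond_type_onehot) == 1))
  expect_true(all(is.finite(fs$atom_features)))
  fs2 <- featurize(g, reaction_class = 3)
  expect_identical(ncol(fs2$atom_features), 55L)
  expect_identical(sum(fs2$atom_features[, 46:55]), 3 * 1)
  expect_identical(which(fs2$atom_features[1, 46:55] == 1), 3L)
  # no bonds -> empty bond table
  fs3 <- featurize(parse_smiles("C"))
  expect_identical(nrow(fs3$bond_features), 0L)
  # element outside the supported set maps to the "other" slot, no error
  fs4 <- featurize(parse_smiles("[Te]"))
  expect_identical(fs4$atom_features[1, 17], 1)
  expect_error(featurize(g, reaction_class = 11), "1..10")
})
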