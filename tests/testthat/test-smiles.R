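test_that("parse/write round-trips are stable across molecule classes", {
  panel <- c("CC(=O)OCC", "c1ccccc1-c1ccccc1", "C[N+](C)(C)C.[I-]",
             "OS(=O)(=O)c1ccc(C)cc1", "C1CC2CCC1CC2", "F/C=C/Cl",
             "[CH3:2][C@@H](N)[OH:5]", "Brc1ccncc1", "O=[N+]([O-])c1ccccc1")
  for (s in panel) {
    g <- parse_smiles(s)
    w <- write_smiles(g)
    g2 <- parse_smiles(w)
    expect_identical(write_smiles(g2), w, info = s)
    expect_identical(g2$atoms$symbol, g$atoms$symbol, info = s)
    expect_identical(g2$atoms$hcount, g$atoms$hcount, info = s)
  }
})

test_that("implicit hydrogen counts follow standard valences", {
  expect_identical(parse_smiles("CCO")$atoms$hcount, c(3L, 2L, 1L))
  expect_identical(parse_smiles("C=C")$atoms$hcount, c(2L, 2L))
  expect_identical(parse_smiles("c1ccccc1")$atoms$hcount, rep(1L, 6))
  expect_identical(parse_smiles("c1ccncc1")$atoms$hcount,
                   c(1L, 1L, 1L, 0L, 1L, 1L))
  # bracket atoms carry explicit hydrogens only
  expect_identical(parse_smiles("[CH2]")$atoms$hcount, 2L)
  expect_identical(parse_smiles("[N+](C)(C)(C)C")$atoms$hcount[1], 0L)
})

test_that("canonicalization is invariant to atom order", {
  g <- parse_smiles("CC(=O)OCC")
  ref <- canonical_smiles(g)
  set.seed(42)
  perms <- replicate(20, sample(n_atoms(g)), simplify = FALSE)
  outs <- canonical_smiles(lapply(perms, function(p) permute_mol(g, p)))
  expect_identical(unique(outs), ref)
})

test_that("canonical SMILES agree with OpenBabel run on the raw string", {
  for (s in c("OCC", "CCO", "c1ccccc1C(=O)Cl", "C[C@H](N)O")) {
    expect_identical(canonical_smiles(parse_smiles(s)), ob_canonical(s),
                     info = s)
  }
})

test_that("map handling: keep_maps retains maps, default strips them", {
  g <- parse_smiles("[CH3:1][OH:2]")
  expect_false(grepl(":", canonical_smiles(g)))
  expect_true(grepl(":1", canonical_smiles(g, keep_maps = TRUE)))
})

test_that("tetrahedral tags survive reordering and flip correctly", {
  a <- canonical_smiles(parse_smiles("C[C@H](N)O"))
  b <- canonical_smiles(parse_smiles("C[C@@H](N)O"))
  expect_false(identical(a, b))
  # same stereocenter written from a different atom order
  g <- parse_smiles("C[C@H](N)O")
  for (i in 1:5) {
    set.seed(i)
    expect_identical(canonical_smiles(permute_mol(g, sample(n_atoms(g)))), a)
  }
})

test_that("malformed SMILES are rejected with informative errors", {
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(C"), "unbalanced")
  expect_error(parse_smiles("[Qx]"), "bracket atom")
  expect_error(parse_smiles(""), "empty")
})
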