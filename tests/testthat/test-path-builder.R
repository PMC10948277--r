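test_that("derive_edits identifies the reaction center", {
  # identity: nothing changes
  r0 <- remove_dataset_shortcut(toy_reactions()[["identity"]])
  de0 <- derive_edits(r0)
  expect_length(de0$edits, 0L)
  expect_identical(de0$labels, integer(n_bonds(r0$product) + n_atoms(r0$product)))

  # ester: brute-force comparison of mapped bond sets says exactly one bond
  # (the C-O ester bond) differs, removed on the reactant side
  r <- remove_dataset_shortcut(toy_reactions()[["ester"]])
  de <- derive_edits(r)
  bond_edits <- Filter(function(e) e$kind == "bond", de$edits)
  expect_length(bond_edits, 1L)
  expect_identical(bond_edits[[1]]$new_order, "none")
  bi <- bond_edits[[1]]$entity + 1L
  ends <- sort(c(r$product$bonds$u[bi], r$product$bonds$v[bi]))
  expect_setequal(r$product$atoms$symbol[ends], c("C", "O"))
  expect_identical(de$attachments, ends)

  # quaternization: one bond edit plus one charge-type atom edit
  rq <- remove_dataset_shortcut(toy_reactions()[["quat"]])
  dq <- derive_edits(rq)
  kinds <- vapply(dq$edits, `[[`, "", "kind")
  expect_setequal(kinds, c("bond", "atom"))
  at <- dq$edits[[which(kinds == "atom")]]
  expect_identical(c(at$dH, at$dq), c(0L, -1L))

  # labels flag exactly the edit objects
  for (p in toy_paths()) {
    d <- derive_edits(p$reaction)
    expect_identical(which(d$labels == 1L) - 1L,
                     vapply(d$edits, `[[`, 0L, "entity"))
  }
})

test_that("edit tokens are ordered by ascending entity index", {
  for (p in small_corpus()$paths) {
    ents <- vapply(Filter(function(t) t$action == "Edit", p$target_tokens),
                   `[[`, 0L, "entity")
    expect_identical(ents, sort(ents))
  }
})

test_that("junction-tree linearization follows the queue discipline", {
  # root-only tree: identity reaction
  p0 <- toy_paths()[["identity"]]
  expect_identical(vapply(p0$target_tokens, `[[`, "", "action"), "FinishEdit")

  # two independent attachments are served in ascending entity order
  pe <- toy_paths()[["ester"]]
  adds <- Filter(function(t) !is.null(t$attach_entity) || identical(t$action, "AddingMotif"),
                 pe$input_tokens)
  ents <- vapply(pe$input_tokens, function(t) t$attach_entity %||% NA_integer_, 0L)
  ents <- ents[!is.na(ents)]
  expect_identical(ents, sort(ents))

  # depth-first: the promoted interface is served immediately after the
  # multi-interface motif that exposed it, before any remaining siblings
  pt <- toy_paths()[["tosyl"]]
  acts <- vapply(pt$target_tokens, `[[`, "", "action")
  adds <- which(acts == "AddingMotif")
  multi <- adds[vapply(pt$target_tokens[adds], function(t)
    t$n_interfaces > 1L, TRUE)]
  expect_length(multi, 1L)
  nxt <- pt$input_tokens[[multi + 1L]]
  expect_identical(nxt$attach_kind, "promoted")
})

test_that("paths have the Start/Edit*/FinishEdit/AddingMotif* phase shape", {
  for (p in c(toy_paths(), small_corpus()$paths)) {
    acts <- vapply(p$target_tokens, `[[`, "", "action")
    expect_identical(sum(acts == "FinishEdit"), 1L)
    fe <- which(acts == "FinishEdit")
    if (fe > 1L) expect_true(all(acts[1:(fe - 1L)] == "Edit"))
    if (fe < length(acts)) {
      expect_true(all(acts[(fe + 1L):length(acts)] == "AddingMotif"))
    }
    expect_identical(p$input_tokens[[1]]$action, "Start")
    expect_length(p$input_tokens, length(p$target_tokens))
  }
})

test_that("path construction is deterministic and vocabulary-coverage checked", {
  v <- toy_vocab()
  r <- toy_reactions()[["tosyl"]]
  p1 <- build_path(r, v)
  p2 <- build_path(r, v)
  expect_identical(p1$target_tokens, p2$target_tokens)
  expect_identical(p1$input_tokens, p2$input_tokens)
  # a vocabulary missing the needed motifs is a coverage error
  v_small <- build_vocabulary(toy_reactions()["identity"])
  expect_error(build_path(r, v_small), "coverage|vocabulary")
})

test_that("path files round-trip through JSON", {
  paths <- toy_paths()[c("ester", "tosyl")]
  f <- withr::local_tempfile(fileext = ".json")
  save_paths(paths, f)
  back <- load_paths(f)
  for (i in seq_along(paths)) {
    expect_identical(back[[i]]$target_tokens, paths[[i]]$target_tokens)
    expect_identical(back[[i]]$labels, paths[[i]]$labels)
    expect_identical(back[[i]]$reactants_canonical,
                     paths[[i]]$reactants_canonical)
  }
})

test_that("build_path then apply_path reproduces the reactants", {
  sc <- small_corpus()
  expect_true(all(vapply(sc$paths, inherits, TRUE, "transformation_path")))
  rt <- path_roundtrip(sc$paths, sc$vocab)
  expect_identical(mean(rt), 1)
})
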