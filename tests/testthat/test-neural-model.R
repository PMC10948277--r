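test_that("encoder output shapes follow the entity index space", {
  model <- tiny_model()
  for (s in c("C", "CC(=O)OCC", "c1ccccc1C")) {
    g <- parse_smiles(s)
    enc <- encode_graph(model, g)
    expect_identical(nrow(enc$entities), n_bonds(g) + n_atoms(g))
    expect_identical(ncol(enc$entities), model$cfg$D)
    expect_length(enc$hG, model$cfg$D)
    expect_true(all(is.finite(enc$entities)), info = s)
    expect_true(all(is.finite(enc$hG)), info = s)
  }
})

test_that("graph embedding is permutation invariant, entities equivariant", {
  model <- tiny_model(D = 16L)
  g <- parse_smiles("CC(=O)OCc1ccccc1")
  enc <- encode_graph(model, g)
  set.seed(21)
  for (i in 1:4) {
    perm <- sample(n_atoms(g))
    gp <- permute_mol(g, perm)
    encp <- encode_graph(model, gp)
    expect_lt(max(abs(enc$hG - encp$hG)), 1e-5)
    # atom entities are permuted rows of the original
    m <- n_bonds(g)
    a0 <- enc$entities[m + seq_len(n_atoms(g)), ]
    a1 <- encp$entities[m + seq_len(n_atoms(g)), ]
    expect_lt(max(abs(a0 - a1[perm, , drop = FALSE])), 1e-5)
  }
})

test_that("decoding is deterministic and heads are normalized", {
  model <- tiny_model()
  g <- parse_smiles("CC(=O)OCC")
  enc <- encode_graph(model, g)
  ds1 <- decode_step(model, enc, decoder_init(model, enc))
  ds2 <- decode_step(model, enc, decoder_init(model, enc))
  expect_identical(ds1$pa, ds2$pa)
  expect_identical(ds1$edit_scores, ds2$edit_scores)
  expect_lt(abs(sum(ds1$pa) - 1), 1e-6)
  expect_lt(abs(sum(exp(ds1$motif_logp)) - 1), 1e-6)
  expect_lt(abs(sum(exp(ds1$ifc_logp)) - 1), 1e-6)
  expect_true(all(apply(ds1$type_logp, 1, function(r) abs(sum(exp(r)) - 1) < 1e-6)))
  expect_true(all(ds1$edit_scores > 0 & ds1$edit_scores < 1))
})

test_that("tied edit scores resolve to the lowest entity index", {
  model <- tiny_model()
  # zeroing the score head makes every entity score identical
  for (nm in c("tgt.W1", "tgt.b1", "tgt.W2", "tgt.b2")) {
    model$params[[nm]][] <- 0
  }
  g <- parse_smiles("CCO")
  enc <- encode_graph(model, g)
  ds <- decode_step(model, enc, decoder_init(model, enc))
  expect_identical(length(unique(ds$edit_scores)), 1L)
  expect_identical(which.max(ds$edit_scores), 1L)
})

test_that("next_input has width D on every branch and is linear in params", {
  model <- tiny_model()
  D <- model$cfg$D
  g <- parse_smiles("CC(=O)OCC")
  enc <- encode_graph(model, g)
  dists <- list(pa = rep(1 / 3, 3),
                ptype = rep(1 / model$n_type, model$n_type),
                pmot = rep(1 / model$n_motif, model$n_motif),
                pifc = rep(1 / model$max_q, model$max_q))
  hsyn <- enc$hG
  toks <- list(
    list(action = "Edit", entity = 0L),
    list(action = "FinishEdit", attach_kind = "product", attach_entity = 5L),
    list(action = "AddingMotif", attach_kind = "promoted"),
    list(action = "AddingMotif", prev_multi = TRUE)
  )
  for (tok in toks) {
    expect_length(next_input(model, enc, tok, dists, hsyn), D)
  }
  # with all contributing parameters at zero the input reduces to hsyn
  m0 <- model
  for (nm in c("fp.W", "fp.b", "fb.W", "fb.b", "fz.W", "fz.b", "fq.W", "fq.b",
               "se.W", "se.b", "sa.W", "sa.b", "vatt")) {
    m0$params[[nm]][] <- 0
  }
  for (tok in toks) {
    expect_equal(next_input(m0, enc, tok, dists, hsyn), hsyn, tolerance = 1e-12)
  }
})

test_that("loss matches closed forms in degenerate settings", {
  # uniform action logits give cross-entropy log(3) per step
  model <- tiny_model()
  for (nm in c("act.W1", "act.b1", "act.W2", "act.b2")) model$params[[nm]][] <- 0
  p0 <- toy_paths()[["identity"]]          # single FinishEdit step
  pd <- retromotif:::prep_path_data(p0, toy_vocab())
  ps <- retromotif:::path_pass(model, pd, with_grads = FALSE)
  expect_equal(ps$loss, log(3), tolerance = 1e-10)
})

test_that("teacher-forced likelihood factorizes over the per-step heads", {
  # the training forward and the inference-side decode_step must assign the
  # same log-probabilities to the realized tokens
  model <- tiny_model(D = 16L)
  vocab <- toy_vocab()
  p <- toy_paths()[["tosyl"]]
  pd <- retromotif:::prep_path_data(p, vocab)
  ps <- retromotif:::path_pass(model, pd, with_grads = FALSE)
  enc <- encode_graph(model, p$reaction$product)
  hs <- hsyn_steps(model, p, vocab)
  state <- decoder_init(model, enc)
  for (t in seq_along(p$target_tokens)) {
    ds <- decode_step(model, enc, state)
    st <- ps$fwd$steps[[t]]
    tgt <- p$target_tokens[[t]]
    expect_equal(ds$pa, st$ce_a$probs, tolerance = 1e-10)
    if (tgt$action == "Edit") {
      expect_equal(sigmoid_vec <- ds$edit_scores,
                   as.vector(1 / (1 + exp(-st$tg$Y))), tolerance = 1e-10)
      expect_equal(exp(ds$type_logp[tgt$entity + 1L, ]), st$ce_y$probs,
                   tolerance = 1e-10)
    } else if (tgt$action == "AddingMotif") {
      expect_equal(exp(ds$motif_logp), st$ce_m$probs, tolerance = 1e-10)
      expect_equal(exp(ds$ifc_logp), st$ce_q$probs, tolerance = 1e-10)
    }
    if (t < length(p$target_tokens)) {
      x <- next_input(model, enc, p$input_tokens[[t + 1L]], st$dists, hs[[t + 1L]])
      state <- list(u = ds$state$u, x = x)
    }
  }
})

test_that("analytic gradients match finite differences of the objective", {
  model <- tiny_model(D = 8L)
  vocab <- toy_vocab()
  p1 <- toy_paths()[["tosyl"]]
  hs <- hsyn_steps(model, p1, vocab)
  enc0 <- encode_graph(model, p1$reaction$product, want_cache = TRUE)
  fwd0 <- retromotif:::path_forward(model, p1, enc0, hs)
  base_dists <- lapply(fwd0$steps, function(s) s$dists)
  base_entities <- enc0$entities
  gr <- retromotif:::path_backward(model, p1, enc0, fwd0)

  # the objective under the package's stop-gradient policy: distributions,
  # entity rows recycled into inputs, and synthon embeddings held constant
  loss_sg <- function(params) {
    m2 <- model; m2$params <- params
    p <- params; D <- m2$cfg$D
    enc <- encode_graph(m2, p1$reaction$product, want_cache = TRUE)
    targets <- p1$target_tokens; inputs <- p1$input_tokens
    N <- length(targets); nE <- enc$m + enc$n
    u <- retromotif:::lin_f(enc$hG, p[["sG.W"]], p[["sG.b"]])
    x <- numeric(D); total <- 0
    for (t in seq_len(N)) {
      gru <- retromotif:::gru_f(x, u, p, "dec."); u <- gru$h
      psi <- c(enc$hG, u)
      tgt <- targets[[t]]
      act <- retromotif:::mlp2_f(psi, p[["act.W1"]], p[["act.b1"]],
                                 p[["act.W2"]], p[["act.b2"]])
      total <- total +
        retromotif:::softmax_ce(act$y, match(tgt$action, retromotif:::ACTIONS))$loss
      if (tgt$action == "Edit") {
        Xt <- cbind(matrix(psi, nE, 2 * D, byrow = TRUE), enc$entities)
        tg <- retromotif:::mmlp2_f(Xt, p[["tgt.W1"]], p[["tgt.b1"]],
                                   p[["tgt.W2"]], p[["tgt.b2"]])
        yv <- numeric(nE); yv[tgt$entity + 1] <- 1
        total <- total + retromotif:::bce_logits(as.vector(tg$Y), yv)$loss
        ty <- retromotif:::mlp2_f(c(psi, enc$entities[tgt$entity + 1, ]),
                                  p[["typ.W1"]], p[["typ.b1"]],
                                  p[["typ.W2"]], p[["typ.b2"]])
        total <- total + retromotif:::softmax_ce(ty$y, tgt$type_class)$loss
      } else if (tgt$action == "AddingMotif") {
        mo <- retromotif:::mlp2_f(psi, p[["mot.W1"]], p[["mot.b1"]],
                                  p[["mot.W2"]], p[["mot.b2"]])
        total <- total + retromotif:::softmax_ce(mo$y, tgt$motif_id)$loss
        fzv <- retromotif:::lin_f(base_dists[[t]]$pmot, p[["fz.W"]], p[["fz.b"]])
        fc <- retromotif:::mlp2_f(c(psi, fzv), p[["ifc.W1"]], p[["ifc.b1"]],
                                  p[["ifc.W2"]], p[["ifc.b2"]])
        total <- total + retromotif:::softmax_ce(fc$y, tgt$interface)$loss
      }
      if (t < N) {
        x <- retromotif:::next_input_vec(p, inputs[[t + 1]], base_dists[[t]],
                                         base_entities, hs[[t + 1]])$x
      }
    }
    total / N
  }
  expect_equal(loss_sg(model$params), fwd0$loss, tolerance = 1e-12)
  set.seed(11)
  eps <- 1e-5
  for (nm in sample(names(model$params), 20)) {
    g_an <- gr[[nm]]
    if (is.null(g_an)) g_an <- model$params[[nm]] * 0
    i <- sample(length(model$params[[nm]]), 1)
    pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - eps
    g_num <- (loss_sg(pp) - loss_sg(pm)) / (2 * eps)
    expect_lt(abs(g_num - g_an[i]) / max(abs(g_num), abs(g_an[i]), 1e-6),
              1e-3)
  }
})

test_that("every head receives gradient on a batch with all token kinds", {
  model <- tiny_model(D = 8L)
  vocab <- toy_vocab()
  fams <- c("act", "tgt", "typ", "mot", "ifc", "dec", "sG", "ent", "ro",
            "emb", "bond", "fp", "se", "fb", "sa", "fz", "fq")
  seen <- setNames(rep(FALSE, length(fams)), fams)
  for (p in toy_paths()[c("tosyl", "ester")]) {
    pd <- retromotif:::prep_path_data(p, vocab)
    ps <- retromotif:::path_pass(model, pd, with_grads = TRUE)
    for (nm in names(ps$grads)) {
      fam <- sub("[.].*$", "", sub("^l[0-9]+[.].*$", "emb", nm))
      if (fam %in% fams && any(ps$grads[[nm]] != 0)) seen[fam] <- TRUE
    }
  }
  expect_true(all(seen))
})
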