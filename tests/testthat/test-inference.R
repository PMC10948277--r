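# A hand-built search space with explicit probability tables: a three-step
# process where each step offers choices "a" (p = 0.6), "b" (p = 0.3) and
# "c" (p = 0.1, terminal). Prefix scores are monotone in the final score, so
# beam search must agree with exhaustive enumeration at every width.
toy_expander <- function(depth_cap = 3L) {
  probs <- c(a = 0.6, b = 0.3, c = 0.1)
  function(hyp) {
    d <- length(hyp$tokens)
    lapply(names(probs), function(ch) {
      list(tokens = c(hyp$tokens, ch),
           logp = hyp$logp + log(probs[[ch]]),
           finished = ch == "c" || d + 1L >= depth_cap)
    })
  }
}

toy_init <- list(tokens = character(), logp = 0, finished = FALSE)

sig <- function(hyps) vapply(hyps, function(h)
  paste(paste(h$tokens, collapse = ""), sprintf("%.10f", h$logp)), "")

test_that("beam equals exhaustive enumeration on a hand-built model", {
  expand <- toy_expander()
  full <- retromotif:::enumerate_paths(toy_init, expand, max_len = 3L)
  expect_length(full, 15L)   # 12 depth-3 leaves + 'c', 'ac', 'bc'
  for (k in c(1L, 2L, 5L)) {
    bm <- retromotif:::beam_core(toy_init, expand, k, max_len = 3L)
    expect_identical(sig(bm), sig(full)[seq_len(length(bm))])
    expect_lte(length(bm), k)
  }
  # beam as wide as the whole path space returns the exact full ranking
  bm_all <- retromotif:::beam_core(toy_init, expand, 15L, max_len = 3L)
  expect_identical(sig(bm_all), sig(full))
})

test_that("beam scores are sorted and never worsen with wider beams", {
  expand <- toy_expander(4L)
  prev_best <- -Inf
  for (k in 1:4) {
    bm <- retromotif:::beam_core(toy_init, expand, k, max_len = 4L)
    scores <- vapply(bm, `[[`, 0, "logp")
    expect_identical(scores, sort(scores, decreasing = TRUE))
    expect_gte(scores[1], prev_best)
    prev_best <- scores[1]
  }
})

test_that("beam width 1 reproduces greedy decoding on a real model", {
  model <- tiny_model(D = 8L, seed = 6L)
  vocab <- toy_vocab()
  g <- parse_smiles("CC(=O)OC")
  b1 <- beam_search(g, model, vocab, k = 1L, max_len = 8L)
  expect_length(b1, 1L)
  greedy <- greedy_decode_oracle(model, vocab, g, max_len = 8L)
  expect_true(greedy$finished)
  expect_equal(b1[[1]]$logp, greedy$logp, tolerance = 1e-10)
  expect_identical(b1[[1]]$tokens, greedy$tokens)
})

test_that("beam matches exhaustive enumeration on a small molecular space", {
  model <- tiny_model(D = 8L, seed = 9L)
  vocab <- toy_vocab()
  g <- parse_smiles("CO")
  enc <- encode_graph(model, g)
  st0 <- new_editable_graph(g)
  init <- list(st = st0, dec = decoder_init(model, enc),
               hsyn = retromotif:::synthon_embedding(model, retromotif:::graph_view(st0)),
               logp = 0, tokens = list(), finished = FALSE)
  m0 <- n_bonds(g); n0 <- n_atoms(g)
  iface_syms <- lapply(vocab$motifs, function(m) m$graph$atoms$symbol[m$interfaces])
  expand <- function(hyp) {
    ds <- decode_step(model, enc, hyp$dec)
    cands <- retromotif:::enumerate_candidates(hyp, ds, model, vocab, m0,
                                               model$n_type, NULL, iface_syms)
    out <- list()
    for (cd in cands) {
      h2 <- tryCatch(
        retromotif:::advance_hypothesis(hyp, cd, ds, model, enc, vocab, m0,
                                        n0, NULL),
        error = function(e) NULL)
      if (!is.null(h2)) out[[length(out) + 1L]] <- h2
    }
    out
  }
  full <- retromotif:::enumerate_paths(init, expand, max_len = 4L)
  expect_gt(length(full), 3L)
  # width large enough to cover every live partial hypothesis at any depth,
  # so no branch is ever pruned and beam must equal the exhaustive ranking
  big <- retromotif:::beam_core(init, expand, 500L, max_len = 4L)
  expect_equal(vapply(big, `[[`, 0, "logp"),
               vapply(full, `[[`, 0, "logp"), tolerance = 1e-10)
})

test_that("predictions are ranked, deduplicated, and capped at k", {
  model <- tiny_model(D = 8L, seed = 6L)
  vocab <- toy_vocab()
  pr <- predict_reactants("CC(=O)OC", model, vocab, k = 6L, max_len = 8L)
  expect_lte(nrow(pr), 6L)
  expect_identical(pr$rank, seq_len(nrow(pr)))
  expect_identical(pr$log_likelihood, sort(pr$log_likelihood, decreasing = TRUE))
  expect_identical(anyDuplicated(pr$reactants), 0L)
  expect_error(predict_reactants("not a smiles((", model, vocab), "invalid")
})

test_that("Top-k accuracy matches hand-computed fractions and is monotone", {
  preds <- tibble::tibble(
    input_id = c(1, 1, 2, 2, 3, 3, 4),
    rank = c(1, 2, 1, 2, 1, 2, 1),
    reactants = c("CCO", "CC=O", "CC=O.CCO", "OCC", "C", "CC", "O")
  )
  truth <- tibble::tibble(
    input_id = 1:4,
    reactants = c("OCC",            # hit at rank 1 (canonical form of CCO)
                  "CCO.CC=O",       # hit at rank 1 after set normalization
                  "CC",             # hit at rank 2
                  "N")              # never hit
  )
  tk <- topk_accuracy(preds, truth, ks = c(1, 2, 3))
  expect_equal(tk$accuracy, c(2 / 4, 3 / 4, 3 / 4))
  expect_true(all(diff(tk$accuracy) >= 0))
  # truth at rank 2: top-1 misses, top-3 hits
  tk2 <- topk_accuracy(preds[preds$input_id == 3, ],
                       truth[truth$input_id == 3, ], ks = c(1, 3))
  expect_equal(tk2$accuracy, c(0, 1))
})

test_that("reactant-set normalization orders components deterministically", {
  out <- canonical_reactant_set(c("OCC.C", "C.CCO"))
  expect_identical(out[1], out[2])
  expect_identical(out[1], "CCO.C")   # larger component first
})
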