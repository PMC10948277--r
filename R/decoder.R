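# GRU decoder with five prediction heads. Training runs teacher-forced over
# aligned input/target token sequences; the total loss is binary
# cross-entropy on per-entity edit scores plus cross-entropies on action,
# type, motif and interface predictions, averaged per step.
#
# Gradient policy: the decoder is differentiated end-to-end through the GRU,
# the heads, the product-graph entity embeddings used for edit scoring and
# type conditioning (Eq-level conditioning), the graph embedding and the
# readout/encoder. The predicted distributions and entity/synthon embeddings
# that are recycled into the *next step's input* are treated as constants
# (stop-gradient): truncating these secondary paths keeps backpropagation
# through time local while leaving every parameter reachable through a
# primary path.

ACTIONS <- c("Edit", "FinishEdit", "AddingMotif")

# input embedding for one step; dists are the previous step's predicted
# distributions (constants), e_prev/e_att are entity embeddings (constants),
# hsyn is the current synthon embedding (constant). Returns the vector and
# a cache for parameter gradients.
next_input_vec <- function(p, tok, dists, enc_entities, hsyn) {
  pieces <- list()
  x <- lin_f(dists$pa, p[["fp.W"]], p[["fp.b"]])
  pieces$pa <- dists$pa
  if (tok$action == "Edit") {
    e <- enc_entities[tok$entity + 1L, ]
    x <- x + lin_f(e, p[["se.W"]], p[["se.b"]])
    x <- x + lin_f(dists$ptype, p[["fb.W"]], p[["fb.b"]])
    pieces$se_in <- e
    pieces$ptype <- dists$ptype
  } else if (isTRUE(tok$prev_multi)) {
    x <- x + lin_f(dists$pmot, p[["fz.W"]], p[["fz.b"]])
    x <- x + lin_f(dists$pifc, p[["fq.W"]], p[["fq.b"]])
    pieces$pmot <- dists$pmot
    pieces$pifc <- dists$pifc
  } else {
    e <- if (identical(tok$attach_kind, "product")) {
      enc_entities[tok$attach_entity + 1L, ]
    } else p[["vatt"]]
    x <- x + lin_f(e, p[["sa.W"]], p[["sa.b"]])
    pieces$sa_in <- e
    pieces$vatt_used <- !identical(tok$attach_kind, "product")
  }
  x <- x + hsyn
  list(x = x, cache = pieces)
}

next_input_backward <- function(p, cache, dx, grads) {
  gfp <- lin_b(cache$pa, p[["fp.W"]], dx)
  grads <- acc_grad(grads, "fp.W", gfp$dW)
  grads <- acc_grad(grads, "fp.b", gfp$db)
  if (!is.null(cache$se_in)) {
    gse <- lin_b(cache$se_in, p[["se.W"]], dx)
    grads <- acc_grad(grads, "se.W", gse$dW)
    grads <- acc_grad(grads, "se.b", gse$db)
    gfb <- lin_b(cache$ptype, p[["fb.W"]], dx)
    grads <- acc_grad(grads, "fb.W", gfb$dW)
    grads <- acc_grad(grads, "fb.b", gfb$db)
  } else if (!is.null(cache$pmot)) {
    gfz <- lin_b(cache$pmot, p[["fz.W"]], dx)
    grads <- acc_grad(grads, "fz.W", gfz$dW)
    grads <- acc_grad(grads, "fz.b", gfz$db)
    gfq <- lin_b(cache$pifc, p[["fq.W"]], dx)
    grads <- acc_grad(grads, "fq.W", gfq$dW)
    grads <- acc_grad(grads, "fq.b", gfq$db)
  } else if (!is.null(cache$sa_in)) {
    gsa <- lin_b(cache$sa_in, p[["sa.W"]], dx)
    grads <- acc_grad(grads, "sa.W", gsa$dW)
    grads <- acc_grad(grads, "sa.b", gsa$db)
    if (isTRUE(cache$vatt_used)) grads <- acc_grad(grads, "vatt", gsa$dx)
  }
  grads
}

# teacher-forced forward + loss over one path. `enc` comes from
# encode_graph(..., want_cache = TRUE); `hsyn_by_step[[t]]` is the synthon
# embedding entering input t (constant).
path_forward <- function(model, path, enc, hsyn_by_step, frozen_x = NULL) {
  p <- model$params
  D <- model$cfg$D
  targets <- path$target_tokens
  inputs <- path$input_tokens
  N <- length(targets)
  nE <- enc$m + enc$n

  u <- lin_f(enc$hG, p[["sG.W"]], p[["sG.b"]])
  x <- numeric(D)
  steps <- vector("list", N)
  total <- 0
  n_tok_correct <- 0L
  for (t in seq_len(N)) {
    gru <- gru_f(x, u, p, "dec.")
    u <- gru$h
    psi <- c(enc$hG, u)
    tgt <- targets[[t]]
    act_idx <- match(tgt$action, ACTIONS)
    act <- mlp2_f(psi, p[["act.W1"]], p[["act.b1"]], p[["act.W2"]], p[["act.b2"]])
    ce_a <- softmax_ce(act$y, act_idx)
    loss_t <- ce_a$loss
    correct <- which.max(act$y) == act_idx
    st <- list(gru = gru, psi = psi, act = act, ce_a = ce_a, tgt = tgt,
               dists = list(pa = ce_a$probs))
    if (tgt$action == "Edit") {
      Xt <- cbind(matrix(psi, nE, 2L * D, byrow = TRUE), enc$entities)
      tg <- mmlp2_f(Xt, p[["tgt.W1"]], p[["tgt.b1"]], p[["tgt.W2"]], p[["tgt.b2"]])
      yv <- numeric(nE); yv[tgt$entity + 1L] <- 1
      bce <- bce_logits(as.vector(tg$Y), yv)
      loss_t <- loss_t + bce$loss
      e_true <- enc$entities[tgt$entity + 1L, ]
      ty <- mlp2_f(c(psi, e_true), p[["typ.W1"]], p[["typ.b1"]],
                   p[["typ.W2"]], p[["typ.b2"]])
      ce_y <- softmax_ce(ty$y, tgt$type_class)
      loss_t <- loss_t + ce_y$loss
      correct <- correct && which.max(as.vector(tg$Y)) == tgt$entity + 1L &&
        which.max(ty$y) == tgt$type_class
      st$tg <- tg; st$bce <- bce; st$ty <- ty; st$ce_y <- ce_y
      st$dists$ptype <- ce_y$probs
    } else if (tgt$action == "AddingMotif") {
      mo <- mlp2_f(psi, p[["mot.W1"]], p[["mot.b1"]], p[["mot.W2"]], p[["mot.b2"]])
      ce_m <- softmax_ce(mo$y, tgt$motif_id)
      loss_t <- loss_t + ce_m$loss
      fzv <- lin_f(ce_m$probs, p[["fz.W"]], p[["fz.b"]])   # stop-grad on probs
      fc <- mlp2_f(c(psi, fzv), p[["ifc.W1"]], p[["ifc.b1"]],
                   p[["ifc.W2"]], p[["ifc.b2"]])
      ce_q <- softmax_ce(fc$y, tgt$interface)
      loss_t <- loss_t + ce_q$loss
      correct <- correct && which.max(mo$y) == tgt$motif_id &&
        which.max(fc$y) == tgt$interface
      st$mo <- mo; st$ce_m <- ce_m; st$fzv <- fzv; st$fc <- fc; st$ce_q <- ce_q
      st$dists$pmot <- ce_m$probs
      st$dists$pifc <- ce_q$probs
    }
    total <- total + loss_t
    n_tok_correct <- n_tok_correct + correct
    if (t < N) {
      if (is.null(frozen_x)) {
        ni <- next_input_vec(p, inputs[[t + 1L]], st$dists, enc$entities,
                             hsyn_by_step[[t + 1L]])
        x <- ni$x
        st$ni <- ni
      } else {
        x <- frozen_x[[t + 1L]]
      }
    }
    steps[[t]] <- st
  }
  list(loss = total / N, steps = steps, N = N,
       token_acc = n_tok_correct / N)
}

# backward companion of path_forward; returns flat gradient list (includes
# encoder gradients through entities, hG and readout).
path_backward <- function(model, path, enc, fwd) {
  p <- model$params
  cfg <- model$cfg
  D <- cfg$D
  N <- fwd$N
  nE <- enc$m + enc$n
  grads <- list()
  dEnt <- matrix(0, nE, D)
  dhG <- numeric(D)
  du_next <- numeric(D)     # gradient flowing into u_t from step t+1
  dx_next <- numeric(D)     # gradient flowing into x_{t+1}
  scale <- 1 / N
  for (t in rev(seq_len(N))) {
    st <- fwd$steps[[t]]
    dpsi <- numeric(2L * D)
    # next-input construction at this step feeds x_{t+1}
    if (t < N) {
      grads <- next_input_backward(p, st$ni$cache, dx_next, grads)
    }
    if (st$tgt$action == "Edit") {
      gty <- mlp2_b(st$ty, p[["typ.W1"]], p[["typ.W2"]], st$ce_y$dlogits * scale)
      grads <- acc_grads(grads, list("typ.W1" = gty$dW1, "typ.b1" = gty$db1,
                                     "typ.W2" = gty$dW2, "typ.b2" = gty$db2))
      dpsi <- dpsi + gty$dx[1:(2L * D)]
      dEnt[st$tgt$entity + 1L, ] <- dEnt[st$tgt$entity + 1L, ] +
        gty$dx[(2L * D + 1L):(3L * D)]
      gtg <- mmlp2_b(st$tg, p[["tgt.W1"]], p[["tgt.W2"]],
                     matrix(st$bce$dlogits * scale, ncol = 1))
      grads <- acc_grads(grads, list("tgt.W1" = gtg$dW1, "tgt.b1" = gtg$db1,
                                     "tgt.W2" = gtg$dW2, "tgt.b2" = gtg$db2))
      dpsi <- dpsi + colSums(gtg$dX[, 1:(2L * D), drop = FALSE])
      dEnt <- dEnt + gtg$dX[, (2L * D + 1L):(3L * D), drop = FALSE]
    } else if (st$tgt$action == "AddingMotif") {
      gfc <- mlp2_b(st$fc, p[["ifc.W1"]], p[["ifc.W2"]], st$ce_q$dlogits * scale)
      grads <- acc_grads(grads, list("ifc.W1" = gfc$dW1, "ifc.b1" = gfc$db1,
                                     "ifc.W2" = gfc$dW2, "ifc.b2" = gfc$db2))
      dpsi <- dpsi + gfc$dx[1:(2L * D)]
      # fzv path: gradient to fz parameters (probs are constants)
      dfzv <- gfc$dx[(2L * D + 1L):(3L * D)]
      gfz <- lin_b(st$ce_m$probs, p[["fz.W"]], dfzv)
      grads <- acc_grad(grads, "fz.W", gfz$dW)
      grads <- acc_grad(grads, "fz.b", gfz$db)
      gmo <- mlp2_b(st$mo, p[["mot.W1"]], p[["mot.W2"]], st$ce_m$dlogits * scale)
      grads <- acc_grads(grads, list("mot.W1" = gmo$dW1, "mot.b1" = gmo$db1,
                                     "mot.W2" = gmo$dW2, "mot.b2" = gmo$db2))
      dpsi <- dpsi + gmo$dx
    }
    gact <- mlp2_b(st$act, p[["act.W1"]], p[["act.W2"]], st$ce_a$dlogits * scale)
    grads <- acc_grads(grads, list("act.W1" = gact$dW1, "act.b1" = gact$db1,
                                   "act.W2" = gact$dW2, "act.b2" = gact$db2))
    dpsi <- dpsi + gact$dx
    dhG <- dhG + dpsi[1:D]
    du <- dpsi[(D + 1L):(2L * D)] + du_next
    gb <- gru_b(st$gru, p, "dec.", du, grads)
    grads <- gb$grads
    du_next <- gb$dh
    dx_next <- gb$dx
  }
  # initial hidden state sigma_G(hG); x_1 = 0 absorbs its gradient
  gsG <- lin_b(enc$hG, p[["sG.W"]], du_next)
  grads <- acc_grad(grads, "sG.W", gsG$dW)
  grads <- acc_grad(grads, "sG.b", gsG$db)
  dhG <- dhG + gsG$dx

  eb <- entity_backward(p, enc$cache$ent, dEnt)
  grads <- acc_grads(grads, eb$grads)
  rb <- readout_backward(p, enc$cache$ro, dhG)
  grads <- acc_grads(grads, rb$grads)
  genc <- encoder_backward(p, cfg, enc$cache$enc, eb$dh + rb$dh)
  grads <- acc_grads(grads, genc)
  grads
}

#' One decoding step (inference view)
#'
#' Advances the GRU on an input embedding and evaluates the prediction
#' heads: action logits, per-entity edit scores, per-entity type logits
#' (the type head conditioned on each entity), motif logits, and interface
#' logits conditioned on the predicted motif distribution.
#'
#' @param model a `retro_model`.
#' @param enc output of [encode_graph()] for the product.
#' @param state list with `u` (GRU hidden) and `x` (input embedding); use
#'   [decoder_init()] for step 1.
#' @return List with `state` (updated), `pa` (action probabilities),
#'   `edit_scores`, `type_logp` ((m+n) x n_type log-probabilities),
#'   `motif_logp`, `ifc_logp`, and the raw `psi`.
#' @export
decode_step <- function(model, enc, state) {
  p <- model$params
  D <- model$cfg$D
  gru <- gru_f(state$x, state$u, p, "dec.")
  u <- gru$h
  psi <- c(enc$hG, u)
  nE <- enc$m + enc$n
  act <- mlp2_f(psi, p[["act.W1"]], p[["act.b1"]], p[["act.W2"]], p[["act.b2"]])
  pa <- softmax(act$y)
  Xt <- cbind(matrix(psi, nE, 2L * D, byrow = TRUE), enc$entities)
  sc <- sigmoid(as.vector(mmlp2_f(Xt, p[["tgt.W1"]], p[["tgt.b1"]],
                                  p[["tgt.W2"]], p[["tgt.b2"]])$Y))
  tyY <- mmlp2_f(Xt, p[["typ.W1"]], p[["typ.b1"]], p[["typ.W2"]], p[["typ.b2"]])$Y
  type_logp <- t(apply(tyY, 1, log_softmax))
  mo <- mlp2_f(psi, p[["mot.W1"]], p[["mot.b1"]], p[["mot.W2"]], p[["mot.b2"]])
  pmot <- softmax(mo$y)
  fzv <- lin_f(pmot, p[["fz.W"]], p[["fz.b"]])
  fc <- mlp2_f(c(psi, fzv), p[["ifc.W1"]], p[["ifc.b1"]],
               p[["ifc.W2"]], p[["ifc.b2"]])
  list(state = list(u = u, x = state$x),
       pa = pa, act_logp = log_softmax(act$y),
       edit_scores = sc,
       type_logp = type_logp,
       motif_logp = log_softmax(mo$y), pmot = pmot,
       ifc_logp = log_softmax(fc$y), pifc = softmax(fc$y),
       psi = psi)
}

#' @rdname decode_step
#' @export
decoder_init <- function(model, enc) {
  list(u = lin_f(enc$hG, model$params[["sG.W"]], model$params[["sG.b"]]),
       x = numeric(model$cfg$D))
}

#' @rdname decode_step
#' @param token the realized input token for the next step (see
#'   `transformation_path` input tokens).
#' @param dists the previous step's predicted distributions
#'   (`pa`, and `ptype` / `pmot` + `pifc` as applicable).
#' @param hsyn current synthon embedding.
#' @export
next_input <- function(model, enc, token, dists, hsyn) {
  next_input_vec(model$params, token, dists, enc$entities, hsyn)$x
}

# synthon embedding of an editable state (forward only)
synthon_embedding <- function(model, g, reaction_class = NULL) {
  enc <- encode_graph(model, g, reaction_class)
  enc$hG
}
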