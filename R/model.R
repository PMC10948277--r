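# Model definition: an L-layer graph transformer encoder over atoms with
# edge-feature-biased multi-head attention, entity embeddings from a shared
# bond MLP, a gated-attention readout, and (in decoder.R) a GRU decoder with
# five prediction heads. All parameters live in one flat named list so the
# optimizer, checkpointing and the finite-difference gradient checker can
# treat the model uniformly.

#' Model configuration
#'
#' @param D embedding width (default 256; the compact test-scale setting in
#'   this package's own experiments is 64).
#' @param L number of graph-transformer layers (default 4).
#' @param heads attention heads; must divide `D`.
#' @param ffn_mult width multiplier of the feed-forward block.
#' @param use_class condition atom features on the 10-class reaction type.
#' @param seed initialization seed.
#' @return A config list.
#' @export
model_config <- function(D = 256L, L = 4L, heads = 8L, ffn_mult = 2L,
                         use_class = FALSE, seed = 1L) {
  stopifnot(D %% heads == 0L)
  list(D = as.integer(D), L = as.integer(L), heads = as.integer(heads),
       ffn_mult = as.integer(ffn_mult), use_class = isTRUE(use_class),
       seed = as.integer(seed))
}

rnorm_mat <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)

#' Initialize a model against a vocabulary
#'
#' @param vocab a `motif_vocabulary`.
#' @param cfg a [model_config()].
#' @return A `retro_model`: config, flat parameter list, and the vocabulary
#'   hash + featurizer layout it is bound to.
#' @export
new_model <- function(vocab, cfg = model_config()) {
  D <- cfg$D
  atom_in <- 45L + if (cfg$use_class) 10L else 0L
  n_type <- length(type_classes(vocab))
  n_motif <- length(vocab$keys)
  max_q <- max(vocab$max_interfaces, 1L)
  p <- list()
  withr::with_seed(cfg$seed, {
    gl <- function(nr, nc) rnorm_mat(nr, nc, 1 / sqrt(nr))
    p[["emb.W"]] <- gl(atom_in, D); p[["emb.b"]] <- numeric(D)
    p[["bond.W"]] <- gl(12L, D);    p[["bond.b"]] <- numeric(D)
    for (l in seq_len(cfg$L)) {
      pre <- sprintf("l%d.", l)
      for (nm in c("Wq", "Wk", "Wv", "Wo", "We")) p[[paste0(pre, nm)]] <- gl(D, D)
      p[[paste0(pre, "ln1g")]] <- rep(1, D); p[[paste0(pre, "ln1b")]] <- numeric(D)
      p[[paste0(pre, "ln2g")]] <- rep(1, D); p[[paste0(pre, "ln2b")]] <- numeric(D)
      Dw <- D * cfg$ffn_mult
      p[[paste0(pre, "W1")]] <- gl(D, Dw); p[[paste0(pre, "b1")]] <- numeric(Dw)
      p[[paste0(pre, "W2")]] <- gl(Dw, D); p[[paste0(pre, "b2")]] <- numeric(D)
    }
    p[["ent.W1"]] <- gl(2L * D, D); p[["ent.b1"]] <- numeric(D)
    p[["ent.W2"]] <- gl(D, D);      p[["ent.b2"]] <- numeric(D)
    p[["ro.Wg1"]] <- gl(D, D); p[["ro.bg1"]] <- numeric(D)
    p[["ro.wg2"]] <- gl(D, 1L); p[["ro.bg2"]] <- numeric(1L)
    p[["ro.Wp"]] <- gl(D, D); p[["ro.bp"]] <- numeric(D)
    p[["sG.W"]] <- gl(D, D); p[["sG.b"]] <- numeric(D)
    for (nm in c("Wz", "Uz", "Wr", "Ur", "Wh", "Uh")) {
      p[[paste0("dec.", nm)]] <- gl(D, D)
    }
    for (nm in c("bz", "br", "bh")) p[[paste0("dec.", nm)]] <- numeric(D)
    head2 <- function(pre, din, dout) {
      p[[paste0(pre, ".W1")]] <<- gl(din, D); p[[paste0(pre, ".b1")]] <<- numeric(D)
      p[[paste0(pre, ".W2")]] <<- gl(D, dout); p[[paste0(pre, ".b2")]] <<- numeric(dout)
    }
    head2("act", 2L * D, 3L)
    head2("tgt", 3L * D, 1L)
    head2("typ", 3L * D, n_type)
    head2("mot", 2L * D, n_motif)
    head2("ifc", 2L * D + D, max_q)
    p[["se.W"]] <- gl(D, D); p[["se.b"]] <- numeric(D)
    p[["sa.W"]] <- gl(D, D); p[["sa.b"]] <- numeric(D)
    p[["fp.W"]] <- gl(3L, D); p[["fp.b"]] <- numeric(D)
    p[["fb.W"]] <- gl(n_type, D); p[["fb.b"]] <- numeric(D)
    p[["fz.W"]] <- gl(n_motif, D); p[["fz.b"]] <- numeric(D)
    p[["fq.W"]] <- gl(max_q, D); p[["fq.b"]] <- numeric(D)
    p[["vatt"]] <- stats::rnorm(D, sd = 0.1)
  })
  structure(list(cfg = cfg, params = p,
                 n_type = n_type, n_motif = n_motif, max_q = max_q,
                 vocab_hash = vocab_hash(vocab),
                 layout = featurizer_layout()),
            class = "retro_model")
}

#' @export
print.retro_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, 0L))
  cat(sprintf(
    "<retro_model> D=%d L=%d heads=%d | %d type / %d motif / %d interface classes | %s parameters\n",
    x$cfg$D, x$cfg$L, x$cfg$heads, x$n_type, x$n_motif, x$max_q,
    format(np, big.mark = ",")))
  invisible(x)
}

# ---- encoder -------------------------------------------------------------

#' Encode a molecular graph
#'
#' Runs the graph-transformer encoder: atom embeddings are refined by
#' edge-biased multi-head self-attention over bonded neighbours (plus a
#' self-loop), entity embeddings are derived for every bond
#' (`MLP(h_u || h_v)`) and atom (`MLP(h_u || h_u)`), and the graph
#' embedding is a gated-attention readout over atoms.
#'
#' @param model a `retro_model`.
#' @param g a [mol_graph()].
#' @param reaction_class optional class 1-10 (models built with
#'   `use_class = TRUE` require it).
#' @param want_cache keep intermediates for the backward pass.
#' @return List with `h` (n x D atom embeddings), `entities`
#'   ((m+n) x D entity embeddings, bonds first), `hG` (graph embedding),
#'   and `cache` when requested.
#' @export
encode_graph <- function(model, g, reaction_class = NULL, want_cache = FALSE) {
  p <- model$params
  cfg <- model$cfg
  if (cfg$use_class && is.null(reaction_class)) {
    stop("model was built with use_class = TRUE; reaction_class is required",
         call. = FALSE)
  }
  fs <- featurize(g, if (cfg$use_class) reaction_class else NULL)
  enc <- encoder_forward(p, cfg, fs$atom_features, fs$bond_features, g$bonds)
  ent <- entity_forward(p, enc$h, g$bonds)
  ro <- readout_forward(p, enc$h)
  out <- list(h = enc$h, entities = ent$E, hG = ro$hG,
              m = n_bonds(g), n = n_atoms(g))
  if (want_cache) out$cache <- list(enc = enc, ent = ent, ro = ro, g = g)
  out
}

encoder_forward <- function(p, cfg, X, B, bonds) {
  n <- nrow(X); m <- nrow(B)
  D <- cfg$D; H <- cfg$heads; Dh <- D %/% H
  s <- sqrt(Dh)
  h <- mlin_f(X, p[["emb.W"]], p[["emb.b"]])
  G <- if (m) mlin_f(B, p[["bond.W"]], p[["bond.b"]]) else
    matrix(0, 0, D)
  mask <- diag(n) > 0
  if (m) for (i in seq_len(m)) {
    mask[bonds$u[i], bonds$v[i]] <- TRUE
    mask[bonds$v[i], bonds$u[i]] <- TRUE
  }
  layers <- vector("list", cfg$L)
  for (l in seq_len(cfg$L)) {
    pre <- sprintf("l%d.", l)
    Q <- h %*% p[[paste0(pre, "Wq")]]
    K <- h %*% p[[paste0(pre, "Wk")]]
    V <- h %*% p[[paste0(pre, "Wv")]]
    E <- if (m) G %*% p[[paste0(pre, "We")]] else matrix(0, 0, D)
    Ocat <- matrix(0, n, D)
    Ah <- vector("list", H)
    for (hd in seq_len(H)) {
      ix <- ((hd - 1L) * Dh + 1L):(hd * Dh)
      S <- (Q[, ix, drop = FALSE] %*% t(K[, ix, drop = FALSE])) / s
      if (m) for (i in seq_len(m)) {
        u <- bonds$u[i]; v <- bonds$v[i]
        qe_u <- sum(Q[u, ix] * E[i, ix]) / s
        qe_v <- sum(Q[v, ix] * E[i, ix]) / s
        S[u, v] <- S[u, v] + qe_u
        S[v, u] <- S[v, u] + qe_v
      }
      S[!mask] <- -1e30
      A <- row_softmax(S)
      Ah[[hd]] <- A
      Ocat[, ix] <- A %*% V[, ix, drop = FALSE]
    }
    O <- Ocat %*% p[[paste0(pre, "Wo")]]
    R1 <- h + O
    ln1 <- layernorm_f(R1, p[[paste0(pre, "ln1g")]], p[[paste0(pre, "ln1b")]])
    h1 <- ln1$Y
    ffA <- mlin_f(h1, p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    ffH <- mish(ffA)
    Fo <- mlin_f(ffH, p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    R2 <- h1 + Fo
    ln2 <- layernorm_f(R2, p[[paste0(pre, "ln2g")]], p[[paste0(pre, "ln2b")]])
    layers[[l]] <- list(h_in = h, Q = Q, K = K, V = V, E = E, Ah = Ah,
                        Ocat = Ocat, ln1 = ln1, h1 = h1, ffA = ffA, ffH = ffH,
                        ln2 = ln2)
    h <- ln2$Y
  }
  list(h = h, X = X, B = B, G = G, bonds = bonds, mask = mask, layers = layers,
       n = n, m = m)
}

encoder_backward <- function(p, cfg, cache, dh) {
  n <- cache$n; m <- cache$m
  D <- cfg$D; H <- cfg$heads; Dh <- D %/% H
  s <- sqrt(Dh)
  bonds <- cache$bonds; mask <- cache$mask
  grads <- list()
  dG <- matrix(0, max(m, 0L), D)
  for (l in rev(seq_len(cfg$L))) {
    pre <- sprintf("l%d.", l)
    lc <- cache$layers[[l]]
    g2 <- layernorm_b(lc$ln2, p[[paste0(pre, "ln2g")]], dh)
    grads <- acc_grad(grads, paste0(pre, "ln2g"), g2$dg)
    grads <- acc_grad(grads, paste0(pre, "ln2b"), g2$db)
    dR2 <- g2$dX
    dh1 <- dR2
    gF2 <- mlin_b(lc$ffH, p[[paste0(pre, "W2")]], dR2)
    grads <- acc_grad(grads, paste0(pre, "W2"), gF2$dW)
    grads <- acc_grad(grads, paste0(pre, "b2"), gF2$db)
    dffA <- gF2$dX * dmish(lc$ffA)
    gF1 <- mlin_b(lc$h1, p[[paste0(pre, "W1")]], dffA)
    grads <- acc_grad(grads, paste0(pre, "W1"), gF1$dW)
    grads <- acc_grad(grads, paste0(pre, "b1"), gF1$db)
    dh1 <- dh1 + gF1$dX
    g1 <- layernorm_b(lc$ln1, p[[paste0(pre, "ln1g")]], dh1)
    grads <- acc_grad(grads, paste0(pre, "ln1g"), g1$dg)
    grads <- acc_grad(grads, paste0(pre, "ln1b"), g1$db)
    dR1 <- g1$dX
    dh_in <- dR1
    dO <- dR1
    grads <- acc_grad(grads, paste0(pre, "Wo"), t(lc$Ocat) %*% dO)
    dOcat <- dO %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, n, D); dK <- matrix(0, n, D); dV <- matrix(0, n, D)
    dE <- matrix(0, max(m, 0L), D)
    for (hd in seq_len(H)) {
      ix <- ((hd - 1L) * Dh + 1L):(hd * Dh)
      A <- lc$Ah[[hd]]
      dOh <- dOcat[, ix, drop = FALSE]
      dA <- dOh %*% t(lc$V[, ix, drop = FALSE])
      dV[, ix] <- dV[, ix] + t(A) %*% dOh
      dS <- A * (dA - rowSums(dA * A))
      dS[!mask] <- 0
      dQ[, ix] <- dQ[, ix] + (dS %*% lc$K[, ix, drop = FALSE]) / s
      dK[, ix] <- dK[, ix] + (t(dS) %*% lc$Q[, ix, drop = FALSE]) / s
      if (m) for (i in seq_len(m)) {
        u <- bonds$u[i]; v <- bonds$v[i]
        dQ[u, ix] <- dQ[u, ix] + dS[u, v] * lc$E[i, ix] / s
        dE[i, ix] <- dE[i, ix] + dS[u, v] * lc$Q[u, ix] / s
        dQ[v, ix] <- dQ[v, ix] + dS[v, u] * lc$E[i, ix] / s
        dE[i, ix] <- dE[i, ix] + dS[v, u] * lc$Q[v, ix] / s
      }
    }
    grads <- acc_grad(grads, paste0(pre, "Wq"), t(lc$h_in) %*% dQ)
    grads <- acc_grad(grads, paste0(pre, "Wk"), t(lc$h_in) %*% dK)
    grads <- acc_grad(grads, paste0(pre, "Wv"), t(lc$h_in) %*% dV)
    dh_in <- dh_in + dQ %*% t(p[[paste0(pre, "Wq")]]) +
      dK %*% t(p[[paste0(pre, "Wk")]]) + dV %*% t(p[[paste0(pre, "Wv")]])
    if (m) {
      grads <- acc_grad(grads, paste0(pre, "We"), t(cache$G) %*% dE)
      dG <- dG + dE %*% t(p[[paste0(pre, "We")]])
    }
    dh <- dh_in
  }
  if (m) {
    gB <- mlin_b(cache$B, p[["bond.W"]], dG)
    grads <- acc_grad(grads, "bond.W", gB$dW)
    grads <- acc_grad(grads, "bond.b", gB$db)
  }
  gX <- mlin_b(cache$X, p[["emb.W"]], dh)
  grads <- acc_grad(grads, "emb.W", gX$dW)
  grads <- acc_grad(grads, "emb.b", gX$db)
  grads
}

# entity embeddings: bonds (rows 1..m) then atoms (rows m+1..m+n)
entity_forward <- function(p, h, bonds) {
  n <- nrow(h); m <- nrow(bonds)
  if (m) {
    Xb <- cbind(h[bonds$u, , drop = FALSE], h[bonds$v, , drop = FALSE])
  } else Xb <- matrix(0, 0, 2L * ncol(h))
  Xa <- cbind(h, h)
  X <- rbind(Xb, Xa)
  mm <- mmlp2_f(X, p[["ent.W1"]], p[["ent.b1"]], p[["ent.W2"]], p[["ent.b2"]])
  list(E = mm$Y, cache = mm, bonds = bonds, n = n, m = m)
}

entity_backward <- function(p, ec, dE) {
  gb <- mmlp2_b(ec$cache, p[["ent.W1"]], p[["ent.W2"]], dE)
  grads <- list("ent.W1" = gb$dW1, "ent.b1" = gb$db1,
                "ent.W2" = gb$dW2, "ent.b2" = gb$db2)
  D <- ncol(gb$dX) / 2L
  n <- ec$n; m <- ec$m
  dh <- matrix(0, n, D)
  if (m) {
    for (i in seq_len(m)) {
      dh[ec$bonds$u[i], ] <- dh[ec$bonds$u[i], ] + gb$dX[i, 1:D]
      dh[ec$bonds$v[i], ] <- dh[ec$bonds$v[i], ] + gb$dX[i, D + (1:D)]
    }
  }
  dh <- dh + gb$dX[m + seq_len(n), 1:D, drop = FALSE] +
    gb$dX[m + seq_len(n), D + (1:D), drop = FALSE]
  list(dh = dh, grads = grads)
}

# gated attention readout over atoms
readout_forward <- function(p, h) {
  sc <- mmlp2_f(h, p[["ro.Wg1"]], p[["ro.bg1"]], p[["ro.wg2"]], p[["ro.bg2"]])
  alpha <- softmax(as.vector(sc$Y))
  P <- mlin_f(h, p[["ro.Wp"]], p[["ro.bp"]])
  hG <- as.vector(t(P) %*% alpha)
  list(hG = hG, alpha = alpha, P = P, sc = sc, h = h)
}

readout_backward <- function(p, rc, dhG) {
  alpha <- rc$alpha
  dP <- outer(alpha, dhG)
  dalpha <- as.vector(rc$P %*% dhG)
  gP <- mlin_b(rc$h, p[["ro.Wp"]], dP)
  ds <- alpha * (dalpha - sum(dalpha * alpha))
  gs <- mmlp2_b(rc$sc, p[["ro.Wg1"]], p[["ro.wg2"]], matrix(ds, ncol = 1))
  grads <- list("ro.Wp" = gP$dW, "ro.bp" = gP$db,
                "ro.Wg1" = gs$dW1, "ro.bg1" = gs$db1,
                "ro.wg2" = gs$dW2, "ro.bg2" = gs$db2)
  list(dh = gP$dX + gs$dX, grads = grads)
}
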