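# Dense numeric building blocks with hand-written backward passes. All
# forward functions return caches sufficient for their backward companions;
# gradients are accumulated into a flat named list by the callers.

mish <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  x * tanh(sp)
}

dmish <- function(x) {
  sp <- ifelse(x > 20, x, log1p(exp(pmin(x, 20))))
  t <- tanh(sp)
  sg <- 1 / (1 + exp(-x))
  t + x * (1 - t^2) * sg
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

log_softmax <- function(x) {
  m <- max(x)
  x - m - log(sum(exp(x - m)))
}

row_softmax <- function(X) {
  mx <- apply(X, 1, max)
  Z <- exp(X - mx)
  Z / rowSums(Z)
}

# y = x W + b for a row vector x (returned as plain vector)
lin_f <- function(x, W, b = NULL) {
  y <- as.vector(x %*% W)
  if (!is.null(b)) y <- y + b
  y
}

# backward of lin_f: returns list(dx, dW, db)
lin_b <- function(x, W, dy) {
  list(dx = as.vector(W %*% dy), dW = outer(as.vector(x), dy), db = dy)
}

# matrix-batched version: Y = X W + b (rows are samples)
mlin_f <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- sweep(Y, 2, b, "+")
  Y
}

mlin_b <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = t(X) %*% dY, db = colSums(dY))
}

# two-layer perceptron with a Mish hidden layer (vector input)
mlp2_f <- function(x, W1, b1, W2, b2) {
  a <- lin_f(x, W1, b1)
  h <- mish(a)
  y <- lin_f(h, W2, b2)
  list(y = y, a = a, h = h, x = x)
}

mlp2_b <- function(cache, W1, W2, dy) {
  g2 <- lin_b(cache$h, W2, dy)
  dh <- g2$dx
  da <- dh * dmish(cache$a)
  g1 <- lin_b(cache$x, W1, da)
  list(dx = g1$dx, dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db)
}

# matrix-batched two-layer Mish perceptron
mmlp2_f <- function(X, W1, b1, W2, b2) {
  A <- mlin_f(X, W1, b1)
  H <- mish(A)
  Y <- mlin_f(H, W2, b2)
  list(Y = Y, A = A, H = H, X = X)
}

mmlp2_b <- function(cache, W1, W2, dY) {
  g2 <- mlin_b(cache$H, W2, dY)
  dA <- g2$dX * dmish(cache$A)
  g1 <- mlin_b(cache$X, W1, dA)
  list(dX = g1$dX, dW1 = g1$dW, db1 = g1$db, dW2 = g2$dW, db2 = g2$db)
}

# row-wise layer normalization with learned gain/bias
layernorm_f <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  va <- rowMeans(Xc^2)
  sd_inv <- 1 / sqrt(va + eps)
  Xh <- Xc * sd_inv
  Y <- sweep(Xh, 2, g, "*")
  Y <- sweep(Y, 2, b, "+")
  list(Y = Y, Xh = Xh, sd_inv = sd_inv)
}

layernorm_b <- function(cache, g, dY) {
  Xh <- cache$Xh; sd_inv <- cache$sd_inv
  D <- ncol(Xh)
  dXh <- sweep(dY, 2, g, "*")
  # dX = (dXh - mean(dXh) - Xh * mean(dXh * Xh)) * sd_inv
  m1 <- rowMeans(dXh)
  m2 <- rowMeans(dXh * Xh)
  dX <- (dXh - m1 - Xh * m2) * sd_inv
  list(dX = dX, dg = colSums(dY * Xh), db = colSums(dY))
}

# GRU cell (vector state)
gru_f <- function(x, h, p, pre) {
  z_a <- lin_f(x, p[[paste0(pre, "Wz")]]) + lin_f(h, p[[paste0(pre, "Uz")]]) +
    p[[paste0(pre, "bz")]]
  r_a <- lin_f(x, p[[paste0(pre, "Wr")]]) + lin_f(h, p[[paste0(pre, "Ur")]]) +
    p[[paste0(pre, "br")]]
  z <- sigmoid(z_a); r <- sigmoid(r_a)
  hh_a <- lin_f(x, p[[paste0(pre, "Wh")]]) +
    lin_f(r * h, p[[paste0(pre, "Uh")]]) + p[[paste0(pre, "bh")]]
  hh <- tanh(hh_a)
  hn <- (1 - z) * h + z * hh
  list(h = hn, x = x, hprev = h, z = z, r = r, hh = hh)
}

gru_b <- function(cache, p, pre, dh, grads) {
  z <- cache$z; r <- cache$r; hh <- cache$hh
  h <- cache$hprev; x <- cache$x
  dz <- dh * (hh - h)
  dhh <- dh * z
  dhprev <- dh * (1 - z)
  dhh_a <- dhh * (1 - hh^2)
  gU <- lin_b(r * h, p[[paste0(pre, "Uh")]], dhh_a)
  gW <- lin_b(x, p[[paste0(pre, "Wh")]], dhh_a)
  drh <- gU$dx
  dr <- drh * h
  dhprev <- dhprev + drh * r
  dz_a <- dz * z * (1 - z)
  dr_a <- dr * r * (1 - r)
  gUz <- lin_b(h, p[[paste0(pre, "Uz")]], dz_a)
  gWz <- lin_b(x, p[[paste0(pre, "Wz")]], dz_a)
  gUr <- lin_b(h, p[[paste0(pre, "Ur")]], dr_a)
  gWr <- lin_b(x, p[[paste0(pre, "Wr")]], dr_a)
  grads <- acc_grad(grads, paste0(pre, "Wh"), gW$dW)
  grads <- acc_grad(grads, paste0(pre, "Uh"), gU$dW)
  grads <- acc_grad(grads, paste0(pre, "bh"), dhh_a)
  grads <- acc_grad(grads, paste0(pre, "Wz"), gWz$dW)
  grads <- acc_grad(grads, paste0(pre, "Uz"), gUz$dW)
  grads <- acc_grad(grads, paste0(pre, "bz"), dz_a)
  grads <- acc_grad(grads, paste0(pre, "Wr"), gWr$dW)
  grads <- acc_grad(grads, paste0(pre, "Ur"), gUr$dW)
  grads <- acc_grad(grads, paste0(pre, "br"), dr_a)
  dx <- gW$dx + gWz$dx + gWr$dx
  dhprev <- dhprev + gUz$dx + gUr$dx
  list(dx = dx, dh = dhprev, grads = grads)
}

acc_grad <- function(grads, name, g) {
  cur <- grads[[name]]
  grads[[name]] <- if (is.null(cur)) g else cur + g
  grads
}

acc_grads <- function(grads, named) {
  for (nm in names(named)) grads <- acc_grad(grads, nm, named[[nm]])
  grads
}

# softmax cross-entropy: returns loss, probs and dlogits
softmax_ce <- function(logits, target) {
  lp <- log_softmax(logits)
  p <- exp(lp)
  d <- p
  d[target] <- d[target] - 1
  list(loss = -lp[target], probs = p, dlogits = d)
}

# elementwise binary cross-entropy from logits, mean over elements
bce_logits <- function(logits, y) {
  p <- sigmoid(logits)
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  list(loss = loss, probs = p, dlogits = (p - y) / length(y))
}

# Adam optimizer step over flat parameter/gradient lists
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  # global gradient-norm clipping
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

new_adam_state <- function() list(t = 0L, m = list(), v = list())
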