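# Teacher-forced training: full-batch Adam over transformation paths, with
# per-epoch loss/accuracy history, checkpointing, and validation metrics.

# tensors (features + bonds) for the product and every synthon state a path
# visits; computed once, re-encoded with current parameters each epoch
prep_path_data <- function(path, vocab, use_class = FALSE) {
  r <- path$reaction
  cls <- if (use_class) r$reaction_class else NULL
  if (use_class && is.na(r$reaction_class %||% NA)) {
    stop("use_class = TRUE but a reaction has no class label", call. = FALSE)
  }
  tensors <- function(g) {
    fs <- featurize(g, cls)
    list(X = fs$atom_features, B = fs$bond_features, bonds = g$bonds,
         n = n_atoms(g), m = n_bonds(g))
  }
  st <- new_editable_graph(r$product)
  nE <- sum(vapply(path$target_tokens, function(t) t$action == "Edit", TRUE))
  # synthon states: after 0..nE edits (Edit-phase inputs use the working
  # view with open valences), plus the sanitized frozen synthon that every
  # AddingMotif-phase input sees
  syn <- vector("list", nE + 2L)
  syn[[1L]] <- tensors(graph_view(st))
  j <- 0L
  for (tok in path$target_tokens) {
    if (tok$action != "Edit") break
    st <- apply_edit(st, tok$entity,
                     tok[intersect(names(tok), c("new_order", "dH", "dq"))])
    j <- j + 1L
    syn[[j + 1L]] <- tensors(graph_view(st))
  }
  st <- finish_edit(st)
  syn[[nE + 2L]] <- tensors(st$synthon)
  N <- length(path$target_tokens)
  sidx <- ifelse(seq_len(N) - 1L <= nE, pmax(seq_len(N) - 1L, 0L) + 1L,
                 nE + 2L)            # synthon index per input step
  list(product = tensors(r$product), syn = syn, sidx = sidx,
       path = path, N = N)
}

encode_tensors <- function(model, tens, want_cache = FALSE, entities = TRUE) {
  p <- model$params
  enc <- encoder_forward(p, model$cfg, tens$X, tens$B, tens$bonds)
  ro <- readout_forward(p, enc$h)
  out <- list(h = enc$h, hG = ro$hG, m = tens$m, n = tens$n)
  if (entities) {
    ent <- entity_forward(p, enc$h, tens$bonds)
    out$entities <- ent$E
    if (want_cache) out$cache <- list(enc = enc, ent = ent, ro = ro)
  } else if (want_cache) {
    out$cache <- list(enc = enc, ro = ro)
  }
  out
}

# forward (+ optional backward) over one prepared path with current params
path_pass <- function(model, pd, with_grads = TRUE) {
  enc <- encode_tensors(model, pd$product, want_cache = with_grads)
  hsyn_cache <- lapply(unique(pd$sidx), function(j) {
    encode_tensors(model, pd$syn[[j]], entities = FALSE)$hG
  })
  names(hsyn_cache) <- as.character(unique(pd$sidx))
  hsyn_by_step <- lapply(pd$sidx, function(j) hsyn_cache[[as.character(j)]])
  fwd <- path_forward(model, pd$path, enc, hsyn_by_step)
  out <- list(loss = fwd$loss, token_acc = fwd$token_acc,
              exact = fwd$token_acc == 1, fwd = fwd, enc = enc)
  if (with_grads) out$grads <- path_backward(model, pd$path, enc, fwd)
  out
}

#' Train the encoder-decoder on transformation paths
#'
#' Full-batch teacher-forced training with Adam and global gradient-norm
#' clipping. Training is deterministic given the configuration seed (which
#' also fixes the initialization). Stops early once every training path is
#' predicted exactly and the mean loss is below `target_loss` (a confidence
#' margin that keeps beam decoding on-path), or after `epochs`.
#'
#' @param paths list of `transformation_path` (see [prepare_paths()]).
#' @param vocab the `motif_vocabulary`.
#' @param cfg a [model_config()].
#' @param epochs maximum epochs.
#' @param lr Adam learning rate.
#' @param clip global gradient-norm clip.
#' @param target_loss early-stop loss threshold (with 100% token accuracy).
#' @param verbose print progress every 25 epochs.
#' @return A `retro_fit`: the trained `retro_model`, a `history` tibble
#'   (epoch, loss, token accuracy, exact-match rate), and the config.
#' @export
train_model <- function(paths, vocab, cfg = model_config(D = 64L, L = 2L,
                                                         heads = 4L),
                        epochs = 300L, lr = 2e-3, clip = 5,
                        target_loss = 0.1, verbose = FALSE) {
  paths <- Filter(function(p) inherits(p, "transformation_path"), paths)
  if (!length(paths)) stop("no usable transformation paths", call. = FALSE)
  model <- new_model(vocab, cfg)
  data <- lapply(paths, prep_path_data, vocab = vocab,
                 use_class = cfg$use_class)
  opt <- new_adam_state()
  hist <- vector("list", epochs)
  np <- length(data)
  for (ep in seq_len(epochs)) {
    total <- list()
    loss <- 0; acc_sum <- 0; n_exact <- 0L
    for (pd in data) {
      ps <- path_pass(model, pd, with_grads = TRUE)
      loss <- loss + ps$loss / np
      acc_sum <- acc_sum + ps$token_acc
      n_exact <- n_exact + ps$exact
      for (nm in names(ps$grads)) {
        total <- acc_grad(total, nm, ps$grads[[nm]] / np)
      }
    }
    exact <- n_exact / np
    acc <- acc_sum / np
    hist[[ep]] <- data.frame(epoch = ep, loss = loss, token_acc = acc,
                             exact_match = exact)
    if (verbose && (ep %% 25L == 0L || ep == 1L)) {
      message(sprintf("epoch %4d  loss %.4f  token acc %.3f  exact %.3f",
                      ep, loss, acc, exact))
    }
    # metrics describe the current parameters: stop before updating so the
    # returned model is the one that satisfied the criterion
    if (n_exact == np && loss < target_loss) break
    upd <- adam_step(model$params, total, opt, lr = lr, clip = clip)
    model$params <- upd$params
    opt <- upd$state
  }
  history <- tibble::as_tibble(do.call(rbind, hist[!vapply(hist, is.null, TRUE)]))
  structure(list(model = model, history = history, cfg = cfg,
                 n_paths = np), class = "retro_fit")
}

#' @export
print.retro_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<retro_fit> %d paths, %d epochs | final loss %.4f, token acc %.3f, exact %.3f\n",
    x$n_paths, nrow(x$history), last$loss, last$token_acc, last$exact_match))
  invisible(x)
}

#' Teacher-forced validation metrics
#'
#' @param model a `retro_model` (or `retro_fit`).
#' @param paths list of `transformation_path`.
#' @param vocab the vocabulary the model was trained against.
#' @return A one-row tibble: mean loss, token accuracy, per-head accuracies
#'   (action, entity, type, motif, interface) and the full-path exact-match
#'   rate, all in `[0, 1]`.
#' @export
validate_model <- function(model, paths, vocab) {
  if (inherits(model, "retro_fit")) model <- model$model
  paths <- Filter(function(p) inherits(p, "transformation_path"), paths)
  data <- lapply(paths, prep_path_data, vocab = vocab,
                 use_class = model$cfg$use_class)
  agg <- c(action = 0, entity = 0, type = 0, motif = 0, interface = 0)
  cnt <- agg
  loss <- 0; acc_sum <- 0; n_exact <- 0L
  for (pd in data) {
    ps <- path_pass(model, pd, with_grads = FALSE)
    loss <- loss + ps$loss / length(data)
    acc_sum <- acc_sum + ps$token_acc
    n_exact <- n_exact + ps$exact
    for (st in ps$fwd$steps) {
      aok <- which.max(st$ce_a$probs) == match(st$tgt$action, ACTIONS)
      agg["action"] <- agg["action"] + aok; cnt["action"] <- cnt["action"] + 1
      if (st$tgt$action == "Edit") {
        agg["entity"] <- agg["entity"] +
          (which.max(as.vector(st$tg$Y)) == st$tgt$entity + 1L)
        cnt["entity"] <- cnt["entity"] + 1
        agg["type"] <- agg["type"] + (which.max(st$ce_y$probs) == st$tgt$type_class)
        cnt["type"] <- cnt["type"] + 1
      } else if (st$tgt$action == "AddingMotif") {
        agg["motif"] <- agg["motif"] + (which.max(st$ce_m$probs) == st$tgt$motif_id)
        cnt["motif"] <- cnt["motif"] + 1
        agg["interface"] <- agg["interface"] +
          (which.max(st$ce_q$probs) == st$tgt$interface)
        cnt["interface"] <- cnt["interface"] + 1
      }
    }
  }
  accs <- ifelse(cnt > 0, agg / cnt, NA_real_)
  tibble::tibble(
    loss = loss, token_acc = acc_sum / length(data),
    exact_match = n_exact / length(data),
    acc_action = accs["action"], acc_entity = accs["entity"],
    acc_type = accs["type"], acc_motif = accs["motif"],
    acc_interface = accs["interface"]
  )
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the parameters, configuration, featurizer layout
#' and the hash of the vocabulary the model was built against; loading
#' refuses a mismatched vocabulary.
#'
#' @param model a `retro_model` or `retro_fit`.
#' @param path file path (RDS).
#' @param vocab vocabulary to validate against on load.
#' @return `load_checkpoint()` returns the `retro_model`.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "retro_fit")) model <- model$model
  saveRDS(list(schema = "retromotif-checkpoint", version = 1L,
               cfg = model$cfg, params = model$params,
               n_type = model$n_type, n_motif = model$n_motif,
               max_q = model$max_q,
               vocab_hash = model$vocab_hash, layout = model$layout), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, vocab) {
  obj <- readRDS(path)
  if (!identical(obj$schema, "retromotif-checkpoint")) {
    stop("not a retromotif checkpoint", call. = FALSE)
  }
  if (!identical(obj$vocab_hash, vocab_hash(vocab))) {
    stop("checkpoint was trained against a different vocabulary", call. = FALSE)
  }
  structure(list(cfg = obj$cfg, params = obj$params, n_type = obj$n_type,
                 n_motif = obj$n_motif, max_q = obj$max_q,
                 vocab_hash = obj$vocab_hash, layout = obj$layout),
            class = "retro_model")
}

#' Training-curve plot
#'
#' @param object a `retro_fit`.
#' @param ... unused.
#' @return A ggplot object (loss and exact-match rate per epoch).
#' @export
autoplot.retro_fit <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  h <- object$history
  long <- rbind(
    data.frame(epoch = h$epoch, value = h$loss, metric = "loss"),
    data.frame(epoch = h$epoch, value = h$exact_match, metric = "exact match")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}
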