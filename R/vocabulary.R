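#' Build a motif vocabulary from training reactions
#'
#' Normalizes each reaction ([remove_dataset_shortcut()]), derives its edits
#' and motifs, and collects the distinct motif canonical keys. Ids are
#' assigned by lexicographic key order, so the vocabulary is independent of
#' the input order. Atom-edit states (hydrogen/charge deltas) observed in
#' the training set are collected alongside: they extend the four bond-type
#' classes of the type prediction head. Reactions whose edits or motifs
#' cannot be derived are skipped and counted.
#'
#' @param reactions list of `reaction` objects (or a file path understood by
#'   [read_reactions()]).
#' @param normalize run [remove_dataset_shortcut()] on each reaction first.
#' @return A `motif_vocabulary`: `keys` (lexicographically sorted canonical
#'   keys; position = id), `freq` (occurrence counts), `max_interfaces`,
#'   `atom_changes` (data frame `dH`, `dq`), `skipped` (named counts of
#'   skip reasons), and the featurizer `layout`.
#' @export
build_vocabulary <- function(reactions, normalize = TRUE) {
  if (is.character(reactions)) reactions <- read_reactions(reactions)
  if (normalize && length(reactions)) {
    reactions <- normalize_reactions(reactions)
  }
  stage1 <- lapply(reactions, function(r) {
    tryCatch({
      de <- derive_edits(r)
      am <- r$product$atoms$map[de$attachments]
      occs <- extract_motifs(r, attachment_maps = am, finalize = FALSE)
      list(occs = occs, edits = de$edits)
    }, error = function(e) e)
  })
  ok <- !vapply(stage1, inherits, TRUE, "condition")
  skipped <- c()
  for (e in stage1[!ok]) {
    msg <- conditionMessage(e)
    skipped[msg] <- (if (msg %in% names(skipped)) skipped[msg] else 0L) + 1L
  }
  fins <- finalize_motif_sets(lapply(stage1[ok], `[[`, "occs"))

  counts <- new.env(parent = emptyenv())
  ac <- new.env(parent = emptyenv())
  for (occs in fins) {
    for (oc in occs) {
      k <- oc$motif$key
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  for (s in stage1[ok]) {
    for (e in s$edits) {
      if (e$kind == "atom") ac[[sprintf("%d,%d", e$dH, e$dq)]] <- TRUE
    }
  }
  keys <- sort(ls(counts), method = "radix")
  freq <- vapply(keys, function(k) counts[[k]], 0L, USE.NAMES = FALSE)
  motifs <- lapply(keys, motif_from_key)
  acs <- ls(ac)
  atom_changes <- if (length(acs)) {
    parts <- do.call(rbind, strsplit(sort(acs, method = "radix"), ","))
    data.frame(dH = as.integer(parts[, 1]), dq = as.integer(parts[, 2]))
  } else data.frame(dH = integer(), dq = integer())
  structure(list(
    version = 1L,
    keys = keys, freq = freq, motifs = motifs,
    max_interfaces = if (length(motifs)) {
      max(vapply(motifs, function(m) length(m$interfaces), 0L))
    } else 1L,
    atom_changes = atom_changes,
    n_reactions = sum(ok),
    skipped = skipped,
    layout = featurizer_layout()
  ), class = "motif_vocabulary")
}

#' @export
print.motif_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<motif_vocabulary> |Z| = %d (from %d reactions, %d skipped), %d atom-change class(es)\n",
    length(x$keys), x$n_reactions, sum(x$skipped), nrow(x$atom_changes)))
  invisible(x)
}

#' @rdname build_vocabulary
#' @param vocab a `motif_vocabulary`.
#' @param key a canonical motif key.
#' @return `vocab_lookup()`: the 1-based motif id, or `NA` if absent.
#' @export
vocab_lookup <- function(vocab, key) match(key, vocab$keys)

#' @rdname build_vocabulary
#' @param id 1-based motif id.
#' @return `vocab_motif()`: the `motif` for an id.
#' @export
vocab_motif <- function(vocab, id) {
  if (is.na(id) || id < 1L || id > length(vocab$keys)) {
    stop(sprintf("motif id %s outside the vocabulary (|Z| = %d)",
                 id, length(vocab$keys)), call. = FALSE)
  }
  vocab$motifs[[id]]
}

# type-head classes: 4 bond classes then the atom-change classes
type_classes <- function(vocab) {
  c("none", "single", "double", "triple",
    if (nrow(vocab$atom_changes)) {
      sprintf("a:%d,%d", vocab$atom_changes$dH, vocab$atom_changes$dq)
    })
}

#' Save / load a motif vocabulary
#'
#' The vocabulary is serialized as versioned JSON carrying the canonical
#' keys (which encode the motif graphs and interface orderings exactly),
#' frequencies, atom-change classes and the featurizer layout. Loading
#' reconstructs motif ids, graphs, and interface orderings identically.
#'
#' @param vocab a `motif_vocabulary`.
#' @param path file path.
#' @return `load_vocabulary()` returns the `motif_vocabulary`.
#' @export
save_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "motif_vocabulary"))
  obj <- list(
    schema = "retromotif-vocabulary",
    version = vocab$version,
    keys = vocab$keys,
    freq = vocab$freq,
    atom_changes = vocab$atom_changes,
    n_reactions = vocab$n_reactions,
    skipped = as.list(vocab$skipped),
    layout = vocab$layout
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
    stop(sprintf("cannot read vocabulary file '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!identical(obj$schema, "retromotif-vocabulary")) {
    stop("not a retromotif vocabulary file (schema tag missing)", call. = FALSE)
  }
  if (!identical(as.integer(obj$version), 1L)) {
    stop(sprintf("unsupported vocabulary schema version '%s' (expected 1)",
                 obj$version), call. = FALSE)
  }
  keys <- as.character(obj$keys %||% character())
  motifs <- lapply(keys, motif_from_key)
  ac <- obj$atom_changes
  atom_changes <- if (!is.null(ac) && length(ac) && NROW(ac)) {
    data.frame(dH = as.integer(ac$dH), dq = as.integer(ac$dq))
  } else data.frame(dH = integer(), dq = integer())
  structure(list(
    version = 1L,
    keys = keys,
    freq = as.integer(obj$freq %||% integer()),
    motifs = motifs,
    max_interfaces = if (length(motifs)) {
      max(vapply(motifs, function(m) length(m$interfaces), 0L))
    } else 1L,
    atom_changes = atom_changes,
    n_reactions = as.integer(obj$n_reactions %||% 0L),
    skipped = unlist(obj$skipped) %||% c(),
    layout = obj$layout
  ), class = "motif_vocabulary")
}

# stable content hash used to couple checkpoints to a vocabulary
vocab_hash <- function(vocab) {
  txt <- paste(c(vocab$keys, type_classes(vocab)), collapse = "|")
  # small rolling hash; stability matters, cryptographic strength does not
  h <- 0
  for (v in utf8ToInt(txt)) h <- (h * 131 + v) %% 2147483647
  sprintf("%d-%d", length(vocab$keys), h)
}
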