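#' Canonical SMILES via OpenBabel
#'
#' Canonicalization is delegated to OpenBabel's canonical SMILES writer,
#' which this package treats as the canonical-ranking engine (its atom
#' ranking is independent of atom-map numbers, which the package relies on
#' when re-mapping reactions). Calls are batched: one `obabel` process per
#' vector of inputs.
#'
#' @param smiles character vector of SMILES strings.
#' @param keep_maps keep atom-map numbers in the output (`-xa`).
#' @return Character vector of canonical SMILES, same length and order.
#' @export
ob_canonical <- function(smiles, keep_maps = FALSE) {
  if (!length(smiles)) return(character())
  stopifnot(is.character(smiles))
  obabel <- Sys.which("obabel")
  if (obabel == "") stop("OpenBabel ('obabel') not found on PATH", call. = FALSE)
  fin <- tempfile(fileext = ".smi"); fout <- tempfile(fileext = ".smi")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  # carry the input position in the title so skipped records are detectable
  writeLines(paste(smiles, seq_along(smiles)), fin)
  args <- c(fin, "-osmi", "-xc", if (keep_maps) "-xa", "-O", fout)
  suppressWarnings(system2(obabel, args, stdout = FALSE, stderr = FALSE))
  out_lines <- if (file.exists(fout)) readLines(fout, warn = FALSE) else character()
  res <- rep(NA_character_, length(smiles))
  if (length(out_lines)) {
    parts <- strsplit(out_lines, "[ \t]+")
    for (p in parts) {
      if (length(p) >= 2L) {
        idx <- suppressWarnings(as.integer(p[length(p)]))
        if (!is.na(idx) && idx >= 1L && idx <= length(res)) res[idx] <- p[1]
      }
    }
  }
  if (anyNA(res)) {
    bad <- which(is.na(res))
    stop(sprintf("OpenBabel could not canonicalize %d record(s); first: '%s'",
                 length(bad), smiles[bad[1]]), call. = FALSE)
  }
  res
}

#' Canonical SMILES of molecular graphs
#'
#' Writes each graph with [write_smiles()] and canonicalizes through
#' OpenBabel. With `keep_maps = FALSE`, atom-map numbers are stripped before
#' canonicalization so the output carries no mapping tokens.
#'
#' @param gs a `mol_graph` or a list of them.
#' @param keep_maps retain atom-map numbers.
#' @return Character vector of canonical SMILES.
#' @export
canonical_smiles <- function(gs, keep_maps = FALSE) {
  if (inherits(gs, "mol_graph")) gs <- list(gs)
  raw <- vapply(gs, write_smiles, "", keep_maps = keep_maps)
  ob_canonical(raw, keep_maps = keep_maps)
}
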