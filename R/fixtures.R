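# Synthetic atom-mapped reactions, built forward: reactants are constructed
# by attaching leaving-group molecules to fragment cores, the product by
# joining the cores across the reaction center. Ground-truth edits, motifs
# and paths therefore exist by construction, which makes the generator the
# round-trip oracle for every other module.

# join two graphs with a single bond a1-a2 (each side loses one hydrogen
# unless allow_charge, in which case a hydrogen-free site gains +1 charge)
join_graphs <- function(g1, a1, g2, a2, charge_site2 = FALSE) {
  off <- n_atoms(g1)
  atoms <- rbind(g1$atoms, g2$atoms)
  b2 <- g2$bonds
  if (nrow(b2)) { b2$u <- b2$u + off; b2$v <- b2$v + off }
  bonds <- rbind(g1$bonds, b2,
                 data.frame(u = a1, v = a2 + off, order = "single", dir = "",
                            stringsAsFactors = FALSE))
  g <- mol_graph(atoms, bonds)
  drop_h <- function(g, a, charge_ok) {
    if (g$atoms$hcount[a] > 0L) {
      g$atoms$hcount[a] <- g$atoms$hcount[a] - 1L
    } else if (charge_ok) {
      g$atoms$charge[a] <- g$atoms$charge[a] + 1L
    } else {
      stop("join site has no hydrogen to give up", call. = FALSE)
    }
    g
  }
  g <- drop_h(g, a1, FALSE)
  g <- drop_h(g, a2 + off, charge_site2)
  attr(g, "offset") <- off
  g
}

.fixture_pools <- function() {
  frag <- function(smiles, site, site2 = NA_integer_) {
    list(g = parse_smiles(smiles), site = site, site2 = site2)
  }
  list(
    # fragment cores; `site` (and optional `site2`) are H-bearing join atoms
    left = list(
      frag("CC=O", 2L),            # acetyl
      frag("CCC", 2L),             # sec-propyl
      frag("c1ccccc1", 1L),        # phenyl
      frag("CC(C)C", 2L),          # isobutyl CH
      frag("CC=O", 1L),            # acetaldehyde methyl side
      frag("CCCC", 2L),            # sec-butyl
      frag("Cc1ccccc1", 1L),       # benzyl methyl
      frag("CC(=O)C", 4L),         # acetone methyl
      frag("C=CC", 3L),            # allyl
      frag("CC#N", 1L),            # acetonitrile methyl
      frag("COC", 1L),             # methoxymethyl
      frag("c1ccncc1", 2L)         # pyridyl
    ),
    right = list(
      frag("OC", 1L),              # methanol O
      frag("NCC", 1L, 3L),         # ethylamine N (+ terminal CH3 as 2nd site)
      frag("CCO", 3L, 1L),         # ethanol O (+ CH3)
      frag("C1CCCCC1", 1L),        # cyclohexane CH
      frag("NC", 1L),              # methylamine N
      frag("OCC(C)C", 1L, 4L),     # isobutanol O (+ methyl)
      frag("C1CCOC1", 2L),         # tetrahydrofuranyl CH
      frag("NCc1ccccc1", 1L, 4L)   # benzylamine N (+ ring CH)
    ),
    # leaving-group molecules (NULL = hydrogen completion / terminal motif);
    # atom 1 is always the bonding atom
    lg = list(
      NULL,
      list(g = parse_smiles("O"), a = 1L),                         # hydroxyl
      list(g = parse_smiles("Cl"), a = 1L),
      list(g = parse_smiles("Br"), a = 1L),
      list(g = parse_smiles("OC"), a = 1L),                        # methoxy
      list(g = parse_smiles("OS(=O)(=O)c1ccc(C)cc1"), a = 1L),     # tosylate
      list(g = parse_smiles("Oc1ccc(-c2ccccc2)cc1"), a = 1L)       # biphenylyl ether
    )
  )
}

# attach a leaving group (or nothing) to a reactant core
complete_fragment <- function(fr, lg) {
  if (is.null(lg)) return(fr$g)
  join_graphs(fr$g, fr$site, lg$g, lg$a)
}

#' Generate synthetic atom-mapped reactions
#'
#' Builds reactions forward from hand-written fragment and leaving-group
#' pools: one or two single-bond reaction centers per product, leaving
#' groups drawn from a pool that includes hydrogen-only completions, a
#' sulfonate ester (which the cutting rules split into a two-interface
#' motif plus a ring motif) and a biaryl ether (rule-2 material), plus an
#' amine-quaternization template that exercises charge-type atom edits.
#' Product atoms are mapped `1..n` in a random order (the numbering carries
#' no reaction-center information only after [remove_dataset_shortcut()],
#' mimicking the benchmark's shortcut); leaving-group atoms are unmapped.
#'
#' @param n_reactions number of reactions.
#' @param seed RNG seed; the output is a deterministic function of it.
#' @param p_two_center probability of a second reaction center.
#' @param p_quat probability of the quaternization (atom-edit) template.
#' @param with_class attach a random reaction-class label 1-10.
#' @return Character vector of reaction records (`reactants>>product`, plus
#'   a tab-separated class column when `with_class`).
#' @export
generate_fixtures <- function(n_reactions, seed = 7L, p_two_center = 0.3,
                              p_quat = 0.2, with_class = FALSE) {
  if (n_reactions == 0L) return(character())
  pools <- .fixture_pools()
  out <- character(0)
  withr::with_seed(seed, {
    seen <- character(0)
    rounds <- 0L
    while (length(out) < n_reactions && rounds < 60L) {
      rounds <- rounds + 1L
      want <- n_reactions - length(out)
      cand <- character(want)
      for (i in seq_len(want)) {
        cand[i] <- if (stats::runif(1) < p_quat) {
          fixture_quat(pools)
        } else {
          fixture_join(pools, two_center = stats::runif(1) < p_two_center)
        }
      }
      # one product, one reactant set: duplicate products would make the
      # teacher-forced target ambiguous, so repeats are rejected
      keys <- ob_canonical(vapply(cand, function(rec) {
        g <- parse_smiles(strsplit(rec, ">>", fixed = TRUE)[[1]][2])
        g$atoms$map <- 0L
        write_smiles(g)
      }, ""))
      for (i in seq_along(cand)) {
        if (keys[i] %in% seen) next
        seen <- c(seen, keys[i])
        rec <- cand[i]
        if (with_class) rec <- paste0(rec, "\t", sample.int(10L, 1L))
        out <- c(out, rec)
        if (length(out) == n_reactions) break
      }
    }
  })
  if (length(out) < n_reactions) {
    stop("fixture pools exhausted before reaching the requested count",
         call. = FALSE)
  }
  out
}

# map product atoms 1..n in random order, propagate to reactant synthon
# atoms through `syn_map` (list of reactant-atom-index vectors aligned with
# product-atom-index vectors), and emit the record
emit_fixture <- function(product, reactants, prod_atoms_of) {
  n <- n_atoms(product)
  perm <- sample.int(n)
  product$atoms$map <- perm
  for (k in seq_along(reactants)) {
    pa <- prod_atoms_of[[k]]
    reactants[[k]]$atoms$map <- 0L
    reactants[[k]]$atoms$map[seq_along(pa)] <- ifelse(is.na(pa), 0L, perm[pa])
  }
  reactants <- reactants[sample.int(length(reactants))]
  paste0(paste(vapply(reactants, write_smiles, ""), collapse = "."),
         ">>", write_smiles(product))
}

fixture_join <- function(pools, two_center = FALSE) {
  fl <- pools$left[[sample.int(length(pools$left), 1L)]]
  fr <- pools$right[[sample.int(length(pools$right), 1L)]]
  product <- join_graphs(fl$g, fl$site, fr$g, fr$site)
  off_r <- attr(product, "offset")
  # reactant cores and the product atoms their leading atoms correspond to
  # heteroatom sites complete with hydrogen only (alcohol/amine chemistry);
  # carbon sites draw from the whole leaving-group pool
  lgs <- pools$lg
  draw_lg <- function(fr) {
    if (fr$g$atoms$symbol[fr$site] != "C") return(NULL)
    lgs[[sample.int(length(lgs), 1L)]]
  }
  lg1 <- draw_lg(fl)
  lg2 <- draw_lg(fr)
  r1 <- complete_fragment(fl, lg1)
  r2 <- complete_fragment(fr, lg2)
  reactants <- list(r1, r2)
  prod_atoms_of <- list(
    c(seq_len(n_atoms(fl$g)), rep(NA_integer_, n_atoms(r1) - n_atoms(fl$g))),
    c(off_r + seq_len(n_atoms(fr$g)), rep(NA_integer_, n_atoms(r2) - n_atoms(fr$g)))
  )
  if (two_center && !is.na(fr$site2)) {
    fx <- pools$left[[sample.int(length(pools$left), 1L)]]
    prod2 <- join_graphs(product, off_r + fr$site2, fx$g, fx$site)
    off_x <- attr(prod2, "offset")
    product <- prod2
    lg3 <- draw_lg(fx)
    r3 <- complete_fragment(fx, lg3)
    # second site on the middle core now carries one less hydrogen in the
    # product; its reactant copy keeps the hydrogen (refilled at apply time)
    reactants[[3]] <- r3
    prod_atoms_of[[3]] <- c(off_x + seq_len(n_atoms(fx$g)),
                            rep(NA_integer_, n_atoms(r3) - n_atoms(fx$g)))
  }
  emit_fixture(product, reactants, prod_atoms_of)
}

fixture_quat <- function(pools) {
  alk <- list(
    list(g = parse_smiles("CC"), site = 1L),
    list(g = parse_smiles("CCC"), site = 1L),
    list(g = parse_smiles("CC(C)C"), site = 2L),
    list(g = parse_smiles("CCCC"), site = 1L),
    list(g = parse_smiles("CCOCC"), site = 1L),
    list(g = parse_smiles("Cc1ccccc1"), site = 1L)
  )[[sample.int(6L, 1L)]]
  amine <- parse_smiles("CN(C)C")
  product <- join_graphs(alk$g, alk$site, amine, 2L, charge_site2 = TRUE)
  off <- attr(product, "offset")
  hal <- list(g = parse_smiles(sample(c("I", "Br"), 1L)), a = 1L)
  r1 <- join_graphs(alk$g, alk$site, hal$g, hal$a)
  reactants <- list(r1, amine)
  prod_atoms_of <- list(
    c(seq_len(n_atoms(alk$g)), rep(NA_integer_, n_atoms(r1) - n_atoms(alk$g))),
    off + seq_len(n_atoms(amine))
  )
  emit_fixture(product, reactants, prod_atoms_of)
}
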