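# Shared fixtures, built in code at test time. Heavier objects are created
# lazily and cached for the whole run.

# (+)-epi-isozizaene, the stereochemistry worked example: a C15H24 tricyclic
# sesquiterpene on the zizaane (tricyclo[6.2.1.0^{1,5}]undecane) skeleton,
# reconstructed to match its published decomposition behaviour.
EIZ_SMILES <- "CC1=C2CC[C@@H]3CC[C@@]2(C3)C(C)(C)[C@@H]1C"

# small named library: acyclic molecules (oracle-friendly), one enantiomer
# pair, an aromatic and a charged species for parser coverage
fixture_smiles <- c(
  water = "O",
  hydroxylamine = "NO",
  ethanol = "CCO",
  propane = "CCC",
  isobutane = "CC(C)C",
  butanol2_R = "C[C@H](O)CC",
  butanol2_S = "C[C@@H](O)CC",
  alaninol = "C[C@@H](N)CO",
  thiol = "CC(S)CC",
  chloro = "CC(Cl)CCC",
  diol = "OCC(O)CO",
  amine = "CCNCC" ,
  ketone = "CC(=O)CC",
  acid = "CC(=O)O",
  ester = "CC(=O)OC",
  nitrile = "CC#N",
  alkene = "CC=CC",
  branched = "CC(C)(C)CC",
  aminoacid = "NC(C)C(=O)O",
  thioether = "CSCC"
)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fixture_table <- function() {
  cached("fixture_table",
         compound_table(names(fixture_smiles), unname(fixture_smiles)))
}

small_corpus <- function() {
  cached("small_corpus",
         generate_corpus(n_molecules = 15, n_reactions = 150, noise_sd = 1,
                         seed = 11))
}

# ---- independent fragmentation oracle -------------------------------------
# Bond graph parsed with ChemmineR/OpenBabel (a different toolkit from the
# implementation backend); environments classified by a hand-rolled rooted
# Weisfeiler-Lehman-style signature built by walking the bond graph. For
# acyclic neutral molecules the radius-1 signature classes coincide exactly
# with induced-subgraph isomorphism classes.
oracle_graph <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_.*$", "", rownames(ab))
  n <- length(sym)
  nb <- vector("list", n)
  if (nrow(bb) > 0) {
    for (r in seq_len(nrow(bb))) {
      a <- bb[r, 1]; b <- bb[r, 2]; o <- bb[r, 3]
      nb[[a]] <- rbind(nb[[a]], c(b, o))
      nb[[b]] <- rbind(nb[[b]], c(a, o))
    }
  }
  list(sym = sym, nb = nb, n = n)
}

oracle_signatures <- function(smiles, radius) {
  g <- oracle_graph(smiles)
  wl_round <- function(sig) {
    vapply(seq_len(g$n), function(i) {
      if (is.null(g$nb[[i]])) return(paste0(g$sym[i], "|"))
      parts <- sort(paste0(g$nb[[i]][, 2], ":", sig[g$nb[[i]][, 1]]))
      paste0(g$sym[i], "|", paste(parts, collapse = ","))
    }, character(1))
  }
  sig <- g$sym
  for (k in seq_len(radius)) sig <- wl_round(sig)
  sig
}

# radius-1 environment classes up to *unrooted* subgraph isomorphism: a
# degree-1 atom's environment is a single edge whose root is not recoverable
# from the subgraph, so such atoms are classified by the unordered edge label
oracle_classes_r1 <- function(smiles) {
  g <- oracle_graph(smiles)
  rooted <- oracle_signatures(smiles, 1)
  deg <- vapply(g$nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  out <- rooted
  for (i in which(deg == 1)) {
    j <- g$nb[[i]][1, 1]; o <- g$nb[[i]][1, 2]
    out[i] <- paste0("edge|", o, "|", paste(sort(c(g$sym[i], g$sym[j])), collapse = "-"))
  }
  out
}

# the set of fixture molecules safe for the oracle comparison (acyclic,
# neutral, single bonds resolvable by OpenBabel)
oracle_smiles <- fixture_smiles[!names(fixture_smiles) %in% c("water")]

expect_same_partition <- function(a, b) {
  expect_equal(length(a), length(b))
  tab <- table(a, b)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
}

expect_refines <- function(fine, coarse) {
  tab <- table(fine, coarse)
  expect_true(all(rowSums(tab > 0) == 1))
}

# random fixture molecule set from the template grammar (deterministic)
random_fixture_molecules <- function(n, seed = 99) {
  withr::with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      cand <- moietherm:::template_molecule()
      if (!cand %in% out) out <- c(out, cand)
    }
    out
  })
}
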