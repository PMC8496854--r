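test_that("the sesquiterpene worked example yields 7 stereo moieties and 5 without", {
  with_st <- decompose(EIZ_SMILES, radius = 1, stereo = TRUE)
  without <- decompose(EIZ_SMILES, radius = 1, stereo = FALSE)
  expect_equal(nrow(with_st), 7L)
  expect_equal(nrow(without), 5L)
  # the chiral methine moiety of the worked example and its achiral collapse
  expect_true(any(grepl("C@@H", with_st$key, fixed = TRUE)))
  expect_true("CC(C)C" %in% without$key)
  expect_equal(sum(with_st$count), 15L)
  expect_equal(sum(without$count), 15L)
})

test_that("atom environments honour radius, stereo stripping and truncation", {
  # water has no neighbours beyond itself: radius-2 environment truncates
  expect_equal(atom_environment("O", 1, radius = 2), "O")
  # a stereocentre keeps its marker with stereo on and loses it with stereo off
  idx <- which(vapply(seq_len(4), function(i)
    grepl("@", atom_environment("C[C@@H](O)CC", i, radius = 1)), logical(1)))[1]
  expect_match(atom_environment("C[C@@H](O)CC", idx, radius = 1), "@", fixed = TRUE)
  expect_false(grepl("@", atom_environment("C[C@@H](O)CC", idx, radius = 1,
                                           stereo = FALSE), fixed = TRUE))
  expect_error(atom_environment("O", 2, radius = 1), class = "mt_input_error")
  expect_error(atom_environment("CCO", 1, radius = 0), class = "mt_input_error")
  expect_error(atom_environment("CCO", 1, radius = 3), class = "mt_input_error")
})

test_that("hydroxylamine decomposes with counts summing to its two heavy atoms", {
  mv <- decompose("NO", radius = 1)
  expect_equal(sum(mv$count), 2L)
  # both atoms see the whole (unrooted) two-atom fragment as their environment
  expect_equal(nrow(mv), 1L)
  expect_equal(mv$key, "NO")
})

test_that("moiety counts conserve the heavy-atom count in every mode", {
  tab <- fixture_table()
  for (i in seq_len(nrow(tab))) {
    for (r in list(1, 2, c(1, 2))) {
      for (st in c(TRUE, FALSE)) {
        mv <- decompose(tab$canonical_smiles[i], radius = r, stereo = st)
        for (rr in r) {
          expect_equal(sum(mv$count[mv$radius == rr]), tab$heavy_atom_count[i],
                       info = paste(tab$compound_id[i], rr, st))
        }
      }
    }
  }
})

test_that("the stereo-aware partition refines the stereo-free partition", {
  for (smi in c(EIZ_SMILES, unname(fixture_smiles))) {
    for (r in c(1, 2)) {
      envs_on <- moietherm:::mt_environments(smi, r, TRUE)[[1]][[as.character(r)]]
      envs_off <- moietherm:::mt_environments(smi, r, FALSE)[[1]][[as.character(r)]]
      # atoms sharing a stereo-aware key always share the stereo-free key
      expect_refines(envs_on, envs_off)
      expect_lte(length(unique(envs_off)), length(unique(envs_on)))
    }
  }
})

test_that("environment classes agree with an independent bond-graph walk", {
  # radius 1 on acyclic molecules: implementation keys and the hand-rolled
  # rooted signature induce the same atom partition
  for (smi in unname(oracle_smiles)) {
    impl <- moietherm:::mt_environments(smi, 1, FALSE)[[1]][["1"]]
    orac <- oracle_classes_r1(smi)
    expect_same_partition(impl, orac)
    # radius 2: the rooted signature is at least as fine as the unrooted
    # canonical-fragment key
    impl2 <- moietherm:::mt_environments(smi, 2, FALSE)[[1]][["2"]]
    orac2 <- oracle_signatures(smi, 2)
    expect_refines(orac2, impl2)
  }
})

test_that("incidence matrices are assembled deterministically", {
  w <- compound_table("W", "O")
  G1 <- build_incidence(w, radii = 1)
  expect_equal(dim(G1), c(1L, 1L))
  expect_equal(unname(G1[1, 1]), 1L)

  # identical structures under two IDs give identical rows
  two <- compound_table(c("A", "B"), c("CCO", "CCO"))
  G2 <- build_incidence(two, radii = c(1, 2))
  expect_equal(unname(G2["A", ]), unname(G2["B", ]))

  # combined radii concatenate the per-radius matrices
  tab <- fixture_table()
  G12 <- build_incidence(tab, radii = c(1, 2))
  Ga <- build_incidence(tab, radii = 1)
  Gb <- build_incidence(tab, radii = 2)
  expect_equal(ncol(G12), ncol(Ga) + ncol(Gb))
  expect_equal(unclass(G12)[, colnames(Ga)], unclass(Ga)[, ])
  # per-radius row sums equal heavy-atom counts
  expect_equal(unname(rowSums(G12[, colnames(Ga)])), as.numeric(tab$heavy_atom_count))
  expect_equal(unname(rowSums(G12[, colnames(Gb)])), as.numeric(tab$heavy_atom_count))
})

test_that("incidence column count matches the oracle's distinct-environment count", {
  lib <- compound_table(names(oracle_smiles), unname(oracle_smiles))
  G <- build_incidence(lib, radii = 1, stereo = FALSE)
  orac <- unique(unlist(lapply(unname(oracle_smiles), oracle_classes_r1)))
  expect_equal(ncol(G), length(orac))
})

test_that("moiety-change vectors are antisymmetric and respect mass balance", {
  tab <- fixture_table()
  G <- build_incidence(tab, radii = c(1, 2))
  # identity reaction cancels exactly
  rxn_id <- stats::setNames(c(-1, 1), c("ethanol", "ethanol"))
  expect_true(all(moiety_change(stats::setNames(0, "ethanol")[0], G) == 0))
  x0 <- moiety_change(stats::setNames(c(-1, 1), c("water", "water")), G)
  expect_true(all(x0 == 0))

  rxn <- stats::setNames(c(-1, -2, 1, 1), c("ethanol", "water", "propane", "diol"))
  x <- moiety_change(rxn, G)
  xr <- moiety_change(stats::setNames(-as.numeric(rxn), names(rxn)), G)
  expect_equal(x, -xr)

  # heavy atoms are conserved per radius: the signed total equals the
  # stoichiometry-weighted heavy-atom change
  parts <- moiety_label_parts(colnames(G))
  for (rr in c(1, 2)) {
    expected <- sum(as.numeric(rxn) *
                      tab[names(rxn), "heavy_atom_count"])
    expect_equal(sum(x[parts$radius == rr]), expected)
  }

  # the enantiomer interconversion: zero change without stereo, nonzero with
  Gs <- build_incidence(tab, radii = c(1, 2), stereo = TRUE)
  Gn <- build_incidence(tab, radii = c(1, 2), stereo = FALSE)
  epi <- stats::setNames(c(-1, 1), c("butanol2_R", "butanol2_S"))
  expect_true(any(moiety_change(epi, Gs) != 0))
  expect_true(all(moiety_change(epi, Gn) == 0))

  expect_error(moiety_change(stats::setNames(1, "nope"), G),
               class = "mt_input_error")
})

test_that("fragment re-canonicalization is idempotent and fixes stereo-free keys", {
  G <- build_incidence(fixture_table(), radii = c(1, 2))
  keys <- moiety_label_parts(colnames(G))$key
  once <- moietherm:::mt_canonical_fragment(keys)
  ok <- !is.na(once)
  expect_gt(mean(ok), 0.9)
  twice <- moietherm:::mt_canonical_fragment(once[ok])
  expect_equal(twice, once[ok])
  # keys without parent-context stereo tags are fixed points
  plain <- ok & !grepl("@", keys, fixed = TRUE)
  expect_equal(once[plain], keys[plain])
})

test_that("incidence serialization round-trips through TSV + JSON sidecar", {
  G <- build_incidence(fixture_table(), radii = 1)
  tf <- tempfile(fileext = ".tsv")
  write_incidence(G, tf)
  back <- utils::read.delim(tf, check.names = FALSE)
  expect_equal(nrow(back), nrow(G))
  expect_equal(as.matrix(back[, -1]), unclass(G), ignore_attr = TRUE)
  meta <- jsonlite::fromJSON(paste0(tf, ".json"))
  expect_equal(meta$n_moieties, ncol(G))
  expect_equal(meta$toolkit, "rdkit")
})
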