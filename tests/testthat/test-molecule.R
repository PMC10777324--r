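test_that("V2000 parsing fills atoms, bonds and implicit hydrogens", {
  mol <- parse_molfile(mol_ethanol())
  expect_equal(nrow(mol$atoms), 3)
  expect_equal(nrow(mol$bonds), 2)
  expect_equal(mol$atoms$implicit_h, c(3L, 2L, 1L))
  benz <- parse_molfile(mol_benzene())
  expect_equal(nrow(benz$atoms), 6)
  expect_true(all(benz$atoms$implicit_h == 1L))
  bad <- mol_ethanol()
  bad[4] <- " xx yy  0  0  0  0  0  0  0  0999 V2000"
  expect_error(parse_molfile(bad), "counts")
  v3 <- sub("V2000", "V3000", mol_ethanol()[4])
  expect_error(parse_molfile(c(mol_ethanol()[1:3], v3)), "V3000")
})

test_that("molecular formulas follow Hill order", {
  expect_equal(molecular_formula(parse_molfile(mol_ethanol())), "C2H6O")
  expect_equal(molecular_formula(parse_molfile(mol_benzene())), "C6H6")
  expect_equal(molecular_formula(parse_molfile(mol_water())), "H2O")
  expect_equal(molecular_formula(parse_molfile(mol_dimethoxybenzene())),
               "C8H10O2")
})

test_that("canonical keys are invariant under 100 random renumberings", {
  mols <- list(mol_ethanol(), mol_benzene(), mol_dimethoxybenzene(),
               mol_butan2ol(1L))
  set.seed(123)
  for (lines in mols) {
    ref <- canonical_key(parse_molfile(lines))
    n <- nrow(parse_molfile(lines)$atoms)
    for (k in 1:100) {
      perm <- sample(n)
      key <- canonical_key(parse_molfile(renumber_molfile(lines, perm)))
      expect_identical(key, ref)
    }
  }
})

test_that("canonical keys separate isomers and enantiomers", {
  expect_false(canonical_key(parse_molfile(mol_ethanol())) ==
                 canonical_key(parse_molfile(mol_dimethyl_ether())))
  r <- parse_molfile(mol_butan2ol(1L))
  s <- parse_molfile(mol_butan2ol(2L))
  expect_false(canonical_key(r, stereo = TRUE) ==
                 canonical_key(s, stereo = TRUE))
  expect_identical(canonical_key(r, stereo = FALSE),
                   canonical_key(s, stereo = FALSE))
  # Kekule forms of benzene compare equal
  expect_identical(canonical_key(parse_molfile(mol_benzene(0))),
                   canonical_key(parse_molfile(mol_benzene(1))))
})

test_that("answers grade as correct / wrong constitution / wrong stereo", {
  sol <- parse_molfile(mol_ethanol())
  shuffled <- parse_molfile(renumber_molfile(mol_ethanol(), c(3L, 1L, 2L)))
  expect_equal(check_answer(shuffled, sol), "correct")
  expect_equal(check_answer(parse_molfile(mol_dimethyl_ether()), sol),
               "wrong_constitution")
  r <- parse_molfile(mol_butan2ol(1L))
  s <- parse_molfile(mol_butan2ol(2L))
  expect_equal(check_answer(r, s, stereo = TRUE), "wrong_stereo")
  expect_equal(check_answer(r, s, stereo = FALSE), "correct")
})

test_that("hydrogen classes partition all hydrogens", {
  for (lines in list(mol_ethanol(), mol_benzene(), mol_dimethoxybenzene(),
                     mol_butan2ol(1L), mol_water())) {
    mol <- parse_molfile(lines)
    cls <- equivalent_hydrogens(mol)
    total <- sum(vapply(cls, function(cl) nrow(cl$positions), numeric(1)))
    formula <- molecular_formula(mol)
    h <- as.integer(sub(".*H(\\d+).*", "\\1", formula))
    expect_equal(total, h)
    # classes are disjoint
    keys <- unlist(lapply(cls, function(cl)
      paste(cl$positions$atom, cl$positions$h)))
    expect_equal(anyDuplicated(keys), 0)
  }
})

test_that("hydrogen equivalence matches the brute-force automorphism oracle", {
  for (lines in list(mol_ethanol(), mol_benzene(), mol_dimethoxybenzene(),
                     mol_butan2ol(0L))) {
    mol <- parse_molfile(lines)
    orbits <- brute_force_h_orbits(mol)
    cls <- equivalent_hydrogens(mol)
    # heavy atoms carrying hydrogens grouped per class must coincide with
    # the oracle orbit partition
    for (cl in cls) {
      heavy <- unique(cl$positions$atom)
      expect_length(unique(orbits[heavy]), 1)
    }
    carriers <- which(mol$atoms$implicit_h > 0)
    expected_classes <- length(unique(orbits[carriers]))
    observed <- length(unique(vapply(cls, function(cl)
      orbits[cl$positions$atom[1]], numeric(1))))
    expect_equal(observed, expected_classes)
  }
})

test_that("specific topicity calls match chemistry", {
  benz <- equivalent_hydrogens(parse_molfile(mol_benzene()))
  expect_length(benz, 1)
  expect_equal(nrow(benz[[1]]$positions), 6)
  eth <- equivalent_hydrogens(parse_molfile(mol_ethanol()))
  expect_length(eth, 3)
  dmb <- equivalent_hydrogens(parse_molfile(mol_dimethoxybenzene()))
  sizes <- sort(vapply(dmb, function(cl) nrow(cl$positions), numeric(1)))
  expect_equal(sizes, c(4, 6))
  # 2-butanol: the C3 methylene splits into two diastereotopic classes
  but <- equivalent_hydrogens(parse_molfile(mol_butan2ol(1L)))
  dia <- Filter(function(cl) cl$topicity == "diastereotopic", but)
  expect_length(dia, 2)
  expect_true(all(vapply(dia, function(cl) nrow(cl$positions), numeric(1)) == 1))
  # without the stereocenter flag the same methylene stays one class
  but0 <- equivalent_hydrogens(parse_molfile(mol_butan2ol(0L)))
  expect_length(Filter(function(cl) cl$topicity == "diastereotopic", but0), 0)
})

test_that("refinement orbits never split true orbits", {
  for (lines in list(mol_ethanol(), mol_benzene(), mol_dimethoxybenzene())) {
    mol <- parse_molfile(lines)
    adj <- nmrkit:::adjacency_list(mol)
    cols <- nmrkit:::refine_colors(
      adj, as.integer(factor(nmrkit:::atom_invariants(mol))))
    orbits <- brute_force_h_orbits(mol)
    # same true orbit implies same refined color
    for (o in unique(orbits)) {
      mem <- which(orbits == o)
      expect_length(unique(cols[mem]), 1)
    }
  }
})
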