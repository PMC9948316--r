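# Chemistry kernel: canonicalization, validity, molecular graphs.

test_that("canonicalization is idempotent and merges equivalent writings", {
  panel <- fixture_panel()
  can <- canonicalize_smiles(panel)
  expect_false(anyNA(can))
  expect_identical(canonicalize_smiles(can), can)
  # Kekule and aromatic writings of benzene collapse
  expect_identical(canonicalize_smiles("C1=CC=CC=C1"),
                   canonicalize_smiles("c1ccccc1"))
  # alternative atom enumerations collapse
  expect_identical(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_identical(canonicalize_smiles("CC(C)O"), canonicalize_smiles("OC(C)C"))
})

test_that("stereo stripping removes all stereo and commutes with writing", {
  expect_identical(canonicalize_smiles("C/C=C/C", keep_stereo = FALSE),
                   canonicalize_smiles("C/C=C\\C", keep_stereo = FALSE))
  expect_identical(canonicalize_smiles("C[C@@H](N)C(=O)O", keep_stereo = FALSE),
                   canonicalize_smiles("C[C@H](N)C(=O)O", keep_stereo = FALSE))
  expect_false(grepl("[@/\\\\]",
                     canonicalize_smiles("C[C@@H](N)/C=C/C", keep_stereo = FALSE)))
})

test_that("validity detects syntactic and structural breakage", {
  expect_false(is_valid_molstring("C(("))
  expect_false(is_valid_molstring("C1CC"))      # unmatched ring bond
  expect_false(is_valid_molstring("C]["))
  expect_true(is_valid_molstring("CCO"))
  expect_true(is_valid_molstring("c1ccccc1"))
  expect_identical(is_valid_molstring(character(0)), logical(0))
})

test_that("heavy-atom counts ignore hydrogens and count every other atom", {
  expect_identical(count_heavy_atoms("C"), 1L)
  expect_identical(count_heavy_atoms("CCO"), 3L)
  expect_identical(count_heavy_atoms("c1ccccc1CC(=O)[O-]"), 10L)
  expect_identical(count_heavy_atoms("[NH4+]"), 1L)
})

test_that("molecule records satisfy their invariants", {
  rec <- molecule_records(c("OCC", "c1ccccc1", "C[C@@H](N)C(=O)O"))
  expect_identical(nrow(rec), 3L)
  # canonical SMILES re-canonicalizes to itself
  expect_identical(canonicalize_smiles(rec$smiles), rec$smiles)
  expect_identical(rec$heavy_atoms,
                   vapply(rec$smiles, count_heavy_atoms, integer(1),
                          USE.NAMES = FALSE))
  expect_identical(rec$has_stereo, grepl("[@/\\\\]", rec$smiles))
  expect_warning(molecule_records(c("CCO", "C((")), "dropping")
})

test_that("molecular graphs carry kekulized orders and ring flags", {
  g <- mol_graph("c1ccncc1C(=O)O")
  expect_identical(nrow(g$atoms), 9L)
  # aromatic ring kekulized into alternating single/double
  ring_orders <- g$bonds$order[g$atoms$aromatic[g$bonds$a1] &
                               g$atoms$aromatic[g$bonds$a2]]
  expect_setequal(unique(ring_orders), c(1L, 2L))
  expect_true(all(g$atoms$in_ring[g$atoms$aromatic]))
  expect_false(any(g$atoms$in_ring[!g$atoms$aromatic]))
  # pyridine nitrogen has no hydrogen, ring carbons have one
  expect_identical(g$atoms$nh[g$atoms$elem == "N"], 0L)
  # distances are graph distances
  expect_equal(max(g$dist), 5)
})
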