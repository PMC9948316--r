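# Fingerprint featurizers: registry contract, feature ranges, torsion
# path semantics, and Tanimoto properties.

test_that("the registry holds exactly the 13 featurizers with fixed parameters", {
  reg <- fingerprint_registry()
  expect_length(reg, 13L)
  names_ <- vapply(reg, `[[`, character(1), "name")
  expect_identical(names_, c("MACCS", "Avalon", "HashAP", "RDK4", "RDK4-L",
                             "TT", "HashTT", "AEs", "ECFP0", "ECFP2",
                             "ECFP4", "FCFP2", "FCFP4"))
  expect_false(anyDuplicated(names_) > 0)
  expect_identical(fingerprint_spec("MACCS")$n_bits, 166L)
  expect_identical(fingerprint_spec("Avalon")$n_bits, 512L)
  for (nm in c("HashAP", "RDK4", "RDK4-L", "HashTT", "ECFP0", "ECFP2",
               "ECFP4", "FCFP2", "FCFP4")) {
    expect_identical(fingerprint_spec(nm)$n_bits, 2048L)
  }
  expect_identical(fingerprint_spec("TT")$n_bits, "sparse")
  expect_identical(fingerprint_spec("AEs")$n_bits, "sparse")
  expect_identical(fingerprint_spec("HashAP")$params$minLength, 1L)
  expect_identical(fingerprint_spec("HashAP")$params$maxLength, 6L)
  expect_identical(fingerprint_spec("RDK4")$params$minPath, 2L)
  expect_identical(fingerprint_spec("RDK4")$params$maxPath, 4L)
  expect_true(fingerprint_spec("RDK4")$params$branched)
  expect_false(fingerprint_spec("RDK4-L")$params$branched)
  expect_error(fingerprint_spec("nope"), "unknown")
  expect_length(metric_fingerprint_names(), 15L)
})

test_that("hashed featurizers emit tokens inside their bit range, sorted", {
  panel <- fixture_panel()
  for (spec in fingerprint_registry()) {
    for (s in panel) {
      ft <- featurize(s, spec)
      vals <- as.numeric(ft$tokens)
      expect_false(is.unsorted(vals, strictly = TRUE))
      if (is.numeric(spec$n_bits)) {
        expect_true(all(vals >= 0 & vals < spec$n_bits),
                    label = sprintf("%s within [0,%d)", spec$name, spec$n_bits))
      }
    }
  }
})

test_that("topological torsions require four bonded atoms", {
  # brute-force 4-atom simple path enumeration as the oracle
  count_paths4 <- function(smiles) {
    g <- mol_graph(smiles)
    n <- nrow(g$atoms)
    if (nrow(g$bonds) == 0) return(0L)
    adj <- lapply(seq_len(n), function(i)
      c(g$bonds$a2[g$bonds$a1 == i], g$bonds$a1[g$bonds$a2 == i]))
    cnt <- 0L
    for (a in seq_len(n)) for (b in adj[[a]]) for (c_ in setdiff(adj[[b]], a))
      for (d in setdiff(adj[[c_]], c(a, b))) cnt <- cnt + 1L
    cnt / 2L
  }
  expect_identical(length(to_feature_set("CCC", "TT")$features), 0L)
  expect_identical(length(to_feature_set("CCCC", "TT")$features), 1L)
  expect_identical(count_paths4("CCC"), 0)
  expect_identical(count_paths4("CCCC"), 1)
  # every molecule with no 4-atom path has an empty torsion set
  for (s in c("C", "CC", "CC(C)C", "CO")) {
    has_path <- count_paths4(s) > 0
    expect_identical(length(to_feature_set(s, "TT")$features) > 0, has_path)
  }
})

test_that("a single heavy atom yields one atom environment", {
  expect_length(to_feature_set("C", "AEs")$features, 1L)
  expect_length(to_feature_set("O", "AEs")$features, 1L)
})

test_that("feature sets are deterministic", {
  for (nm in c("AEs", "ECFP4", "MACCS", "TT", "HashAP")) {
    expect_identical(to_feature_set("CC(=O)Oc1ccccc1C(=O)O", nm),
                     to_feature_set("CC(=O)Oc1ccccc1C(=O)O", nm))
  }
  expect_identical(to_feature_set("CCO", "ECFP2*"),
                   to_feature_set("CCO", "ECFP2*"))
  expect_error(to_feature_set("CCO", "ECFP8"), "unknown")
})

test_that("Tanimoto: identity, symmetry, range, and the set formula", {
  panel <- fixture_panel()
  for (nm in metric_fingerprint_names()) {
    for (s in panel) {
      expect_equal(tanimoto_smiles(s, s, nm), 1.0)
    }
    x <- tanimoto_smiles(panel[1], panel[3], nm)
    y <- tanimoto_smiles(panel[3], panel[1], nm)
    expect_equal(x, y)
    expect_true(x >= 0 && x <= 1)
  }
  fs <- function(v) structure(list(spec_name = "toy", features = v),
                              class = "feature_set")
  expect_equal(tanimoto(fs(c(1L, 2L, 3L)), fs(c(2L, 3L, 4L))), 0.5)
  expect_equal(tanimoto(fs(c(1L, 2L)), fs(c(3L, 4L))), 0)
  expect_equal(tanimoto(fs(integer(0)), fs(integer(0))), 1.0)
  bad <- structure(list(spec_name = "other", features = 1L),
                   class = "feature_set")
  expect_error(tanimoto(fs(1L), bad), "matching")
})
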