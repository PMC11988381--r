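test_that("parse_smiles builds sane molecular graphs and rejects bad input", {
  m <- parse_smiles("CCO")
  expect_equal(nrow(m$atoms), 3L)
  expect_equal(nrow(m$bonds), 2L)
  expect_equal(sort(m$atoms$element), c("C", "C", "O"))
  expect_equal(m$atoms$n_h, c(3L, 2L, 1L))

  pfoa <- parse_smiles("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
  expect_equal(sum(pfoa$atoms$element == "C"), 8L)
  expect_equal(sum(pfoa$atoms$element == "F"), 15L)

  expect_error(parse_smiles("C("), class = "edcscreen_parse_error")
  expect_error(parse_smiles(""), class = "edcscreen_parse_error")
})

test_that("longest fluorinated chain follows the carbon-with-fluorine rule", {
  expect_equal(longest_fluorinated_chain(parse_smiles("CCO")), 0L)
  expect_equal(longest_fluorinated_chain(parse_smiles("FC(F)(F)F")), 1L)
  # the carboxyl carbon bears no fluorine and breaks the chain
  pfoa <- parse_smiles("OC(=O)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)C(F)(F)F")
  expect_equal(longest_fluorinated_chain(pfoa), 7L)
  # fluorinated aromatic carbons qualify
  expect_equal(longest_fluorinated_chain(parse_smiles("Fc1c(F)cccc1")), 2L)
  # branched: the longest simple path runs through the branch point
  branched <- parse_smiles("FC(F)(F)C(F)(C(F)(F)F)C(F)(F)F")
  expect_equal(longest_fluorinated_chain(branched), 3L)
  # an unfluorinated branch point disconnects its CF3 arms
  neo <- parse_smiles("FC(F)(F)C(C(F)(F)F)(C(F)(F)F)C(F)(F)F")
  expect_equal(longest_fluorinated_chain(neo), 1L)
})

test_that("fully fluorinated linear alkanes have chain length equal to carbon count", {
  for (n in c(1L, 2L, 5L, 12L, 26L)) {
    smi <- edcscreen:::perfluoro_chain(n)
    expect_equal(longest_fluorinated_chain(parse_smiles(smi)), n,
                 info = paste("n =", n))
  }
})

test_that("chain length matches an exhaustive simple-path oracle on random graphs", {
  skip_if_not_installed("igraph")
  withr::local_seed(420)
  for (k in 1:200) {
    mol <- random_molecule(sample(3:30, 1))
    expect_equal(longest_fluorinated_chain(mol),
                 oracle_longest_fluorinated_chain(mol),
                 info = paste("case", k))
    expect_lte(longest_fluorinated_chain(mol), sum(mol$atoms$element == "C"))
  }
})

test_that("functional-group detection applies precedence", {
  fg <- function(s) detect_functional_groups(parse_smiles(s))
  expect_setequal(fg("c1ccccc1"), "phenyl")
  expect_setequal(fg("OC(=O)C(F)(F)F"), c("carboxylic acid", "halide"))
  expect_setequal(fg("NC(=O)N"), "urea")
  expect_setequal(fg("CNC(=O)OC"), "carbamate")
  expect_setequal(fg("CC(=O)OC(C)=O"), "anhydride")
  expect_setequal(fg("CS(=O)(=O)O"), "sulfonic acid")
  # an alcohol elsewhere in an acid-bearing molecule still reports
  expect_setequal(fg("OCC(=O)O"), c("carboxylic acid", "alcohol"))
})

test_that("functional-group detection is invariant to SMILES rewriting", {
  pairs <- list(
    c("OC(=O)C", "CC(O)=O"),
    c("c1ccccc1C", "Cc1ccccc1"),
    c("CCOC(=O)C(F)(F)F", "FC(F)(F)C(=O)OCC"),
    c("NC(=O)NCC", "CCNC(N)=O")
  )
  for (p in pairs) {
    expect_setequal(detect_functional_groups(parse_smiles(p[1])),
                    detect_functional_groups(parse_smiles(p[2])))
  }
})

test_that("hydrophobicity descriptors are deterministic with known anchors", {
  eth <- compute_hydrophobicity_descriptors(parse_smiles("CCO"))
  expect_equal(eth$tpsa, 20.23, tolerance = 1e-6)
  expect_equal(compute_hydrophobicity_descriptors(parse_smiles("c1ccccc1"))$tpsa, 0)
  # perfluorocarbons and hydrocarbons carry no N/O/S polar area
  expect_equal(compute_hydrophobicity_descriptors(parse_smiles("FC(F)(F)C(F)(F)F"))$tpsa, 0)
  again <- compute_hydrophobicity_descriptors(parse_smiles("CCO"))
  expect_identical(eth, again)
  expect_gte(eth$tpsa, 0)
})

test_that("molecular-weight filter is inclusive at both bounds and monotone", {
  rec <- data.frame(cas_id = letters[1:5],
                    mol_weight = c(174.9, 175.0, 500, 1000.0, 1000.1))
  kept <- filter_by_molecular_weight(rec, 175, 1000)
  expect_equal(kept$cas_id, c("b", "c", "d"))
  # widening the window never removes a record
  wider <- filter_by_molecular_weight(rec, 100, 1100)
  expect_true(all(kept$cas_id %in% wider$cas_id))
  expect_error(filter_by_molecular_weight(rec, 10, 5),
               class = "edcscreen_domain_error")
})

test_that("annotate_compounds discards unparsable SMILES and annotates the rest", {
  rec <- data.frame(cas_id = c("ok1", "bad", "ok2"),
                    smiles = c("OC(=O)C(F)(F)C(F)(F)F", "C(", "CCO"),
                    stringsAsFactors = FALSE)
  expect_message(ann <- annotate_compounds(rec), "discarding 1")
  expect_equal(ann$cas_id, c("ok1", "ok2"))
  expect_equal(attr(ann, "n_discarded"), 1L)
  expect_equal(ann$fluorinated_chain_length, c(2L, 0L))
  expect_true(all(ann$mol_weight > 0))
  expect_true(grepl("carboxylic acid", ann$functional_groups[1]))
})
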