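test_that("the contact cutoff is inclusive and respects planted distances", {
  tc <- generate_toy_complex(c(4.0, 4.99, 5.0, 5.01), seed = 11)
  ct <- contacts_within_cutoff(tc$receptor, tc$pose, 5.0)
  expect_equal(ct$resno, 1:3)
  expect_equal(ct$min_distance, c(4.0, 4.99, 5.0), tolerance = 1e-9)
  # at 5.1 A the fourth residue joins
  expect_equal(nrow(contacts_within_cutoff(tc$receptor, tc$pose, 5.1)), 4L)
  # coincident atoms are contacts even at cutoff 0
  tc0 <- generate_toy_complex(0, seed = 12)
  expect_equal(contacts_within_cutoff(tc0$receptor, tc0$pose, 0)$min_distance, 0)
})

test_that("contacts match an all-pairs brute-force scan on random complexes", {
  for (seed in 1:100) {
    cx <- generate_random_complex(n_residues = 12L, atoms_per_residue = 2L,
                                  n_ligand_atoms = 4L, box = 8, seed = seed)
    got <- contacts_as_keyed(contacts_within_cutoff(cx$receptor, cx$pose, 5.0))
    want <- oracle_contacts(cx$receptor, cx$pose, 5.0)
    expect_equal(got$key, want$key, info = paste("seed", seed))
    expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
  }
})

test_that("contact sets are monotone in the cutoff", {
  for (seed in c(5, 17, 23)) {
    cx <- generate_random_complex(seed = seed)
    inner <- contacts_within_cutoff(cx$receptor, cx$pose, 4.5)
    outer <- contacts_within_cutoff(cx$receptor, cx$pose, 5.0)
    expect_true(all(paste(inner$chain, inner$resno) %in%
                      paste(outer$chain, outer$resno)))
  }
})

test_that("empty structures are rejected", {
  tc <- generate_toy_complex(3, seed = 1)
  empty <- structure_model(data.frame(resid = character(), resno = integer(),
                                      x = numeric(), y = numeric(), z = numeric()))
  expect_error(contacts_within_cutoff(empty, tc$pose),
               class = "edcscreen_empty_structure_error")
})

test_that("residue frequencies count each residue once per pose", {
  one <- data.frame(resid = c("LEU", "LEU", "PHE"), resno = c(10L, 10L, 20L),
                    chain = "A", min_distance = c(3, 4, 2))
  prof <- aggregate_residue_frequencies(list(p1 = one))
  # LEU touched twice at the atom level but is one residue: 50/50
  expect_equal(prof$pct[prof$resid == "LEU"], 50)
  expect_equal(prof$pct[prof$resid == "PHE"], 50)

  many <- rep(list(data.frame(resid = "LEU", resno = 1L, chain = "A",
                              min_distance = 3)), 15)
  names(many) <- sprintf("p%02d", 1:15)
  prof15 <- aggregate_residue_frequencies(many)
  expect_equal(prof15$pct, 100)
  expect_equal(prof15$count, 15L)
  expect_equal(attr(prof15, "n"), 15L)
})

test_that("planted type counts give matching percentages and order invariance", {
  mk <- function(resids) data.frame(resid = resids, resno = seq_along(resids),
                                    chain = "A", min_distance = 3)
  lists <- list(a = mk(c("LEU", "LEU", "PHE")), b = mk(c("LEU", "ILE")),
                c = mk("PHE"))
  prof <- aggregate_residue_frequencies(lists)
  expect_equal(prof$count[match(c("ILE", "LEU", "PHE"), prof$resid)],
               c(1L, 3L, 2L))
  expect_equal(sum(prof$pct), 100)
  shuffled <- aggregate_residue_frequencies(lists[c(3, 1, 2)])
  expect_equal(prof[order(prof$resid), c("resid", "count", "pct")],
               shuffled[order(shuffled$resid), c("resid", "count", "pct")],
               ignore_attr = TRUE)
})

test_that("FASTA export maps residues in residue-number order and flags odd input", {
  cl <- list(cmpdA = data.frame(resid = c("PHE", "LEU"), resno = c(215L, 210L),
                                chain = "A", min_distance = c(4, 3)))
  fa <- export_contacts_fasta(cl, "CAR")
  expect_equal(fa, c(">CAR|cmpdA", "LF"))

  three <- list(
    c1 = data.frame(resid = "LEU", resno = 1L, chain = "A", min_distance = 3),
    c2 = data.frame(resid = "MET", resno = 2L, chain = "A", min_distance = 3),
    c3 = data.frame(resid = "TRP", resno = 3L, chain = "A", min_distance = 3))
  fa3 <- export_contacts_fasta(three, "PXR")
  headers <- fa3[seq(1, 6, by = 2)]
  expect_equal(length(unique(headers)), 3L)

  expect_error(export_contacts_fasta(list(x = data.frame()), "AR"),
               class = "edcscreen_empty_structure_error")
  odd <- list(x = data.frame(resid = "XYZ", resno = 1L, chain = "A",
                             min_distance = 2))
  expect_error(export_contacts_fasta(odd, "AR"),
               class = "edcscreen_unknown_residue_error")
})
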