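test_that("molfile parsing yields hydrogen-suppressed, kekulized graphs", {
  co2 <- read_molfile(co2_molfile())
  expect_equal(n_atoms(co2), 3L)
  expect_equal(n_bonds(co2), 2L)
  expect_equal(bond_labels(co2), rep("C-O:double", 2))

  met <- read_molfile(methane_molfile())
  expect_equal(n_atoms(met), 1L)
  expect_equal(n_bonds(met), 0L)
  expect_equal(unclass(molecular_formula(met))[c("C", "H")], c(C = 1L, H = 4L))

  benz <- read_molfile(benzene_aromatic_molfile())
  expect_equal(n_bonds(benz), 6L)
  expect_equal(sort(table(bond_labels(benz))),
               sort(c("C-C:single" = 3L, "C-C:double" = 3L)),
               ignore_attr = TRUE)
  expect_setequal(names(table(bond_labels(benz))),
                  c("C-C:single", "C-C:double"))
})

test_that("malformed and unsupported molfiles fail with useful errors", {
  bad <- sub("  3  2", "garbage", co2_molfile(), fixed = TRUE)
  expect_error(read_molfile(bad), "counts line \\(line 4\\)")
  v3 <- sub("0999 V2000", "0999 V3000", co2_molfile(), fixed = TRUE)
  expect_error(read_molfile(v3), "V3000")
  # two disconnected ethane skeletons in one record
  multi <- paste(c("two components", "  test", "",
                   "  4  2  0  0  0  0  0  0  0  0999 V2000",
                   rep("    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0", 4),
                   "  1  2  1  0", "  3  4  1  0", "M  END"), collapse = "\n")
  expect_error(read_molfile(multi), "not connected|multi-component")
})

test_that("SDF streams parse record-wise, skipping corrupt entries", {
  g1 <- chain_graph(2)
  g2 <- read_molfile(co2_molfile())
  sdf <- paste(c(write_molfile(g1), "$$$$", "corrupt record", "$$$$",
                 write_molfile(g2), "$$$$"), collapse = "\n")
  expect_message(out <- read_sdf(sdf), "skipping SDF record 2")
  expect_length(out, 2L)
  expect_equal(canonical_code(out[[2]]), canonical_code(g2))
  expect_length(read_sdf(""), 0L)
})

test_that("SMILES input matches molfile normalization", {
  expect_equal(bond_labels(read_smiles("O=C=O")), rep("C-O:double", 2))
  expect_equal(bond_labels(read_smiles("CC")), "C-C:single")
  benz <- read_smiles("c1ccccc1")
  expect_equal(sort(bond_labels(benz)),
               sort(rep(c("C-C:single", "C-C:double"), each = 3)))
  expect_error(read_smiles("not(a(smiles"), "invalid SMILES")
})

test_that("formulas count suppressed hydrogens and masses follow standard weights", {
  co2 <- read_molfile(co2_molfile())
  expect_equal(unclass(molecular_formula(co2)), c(C = 1L, O = 2L),
               ignore_attr = TRUE)
  eth <- read_smiles("CC")
  expect_equal(unclass(molecular_formula(eth)), c(C = 2L, H = 6L),
               ignore_attr = TRUE)
  expect_equal(round(average_mass(c(C = 1, O = 2)), 1), 44.0)
  expect_equal(average_mass(character(0)), 0)
  expect_error(average_mass(c(Xx = 2)), "Xx")
  # additivity over disjoint union
  f1 <- c(C = 3, H = 8); f2 <- c(N = 2, O = 1)
  expect_equal(average_mass(c(f1, f2)), average_mass(f1) + average_mass(f2))
})

test_that("the bundled paclitaxel structure has the literature formula and mass", {
  tx <- read_molfile(system.file("extdata", "taxol.mol",
                                 package = "massembly"))
  f <- molecular_formula(tx)
  expect_equal(unclass(f), c(C = 47L, H = 51L, N = 1L, O = 14L),
               ignore_attr = TRUE)
  expect_equal(round(average_mass(f), 1), 853.9)
})

test_that("diastereomer counts are powers of two", {
  expect_equal(diastereomer_count(11), 2048)
  expect_equal(diastereomer_count(0), 1)
  expect_equal(diastereomer_count(3), 8)
  expect_error(diastereomer_count(-1), "non-negative")
})

test_that("canonical codes are permutation-invariant and label-sensitive", {
  set.seed(101)
  for (g in list(read_smiles("c1ccccc1"), read_smiles("CC(C)C(=O)O"),
                 chain_graph(5))) {
    code <- canonical_code(g)
    for (i in 1:40) {
      expect_identical(canonical_code(permute_atoms(g)), code)
    }
  }
  expect_false(canonical_code(read_smiles("O=C=O")) ==
                 canonical_code(read_smiles("S=C=S")))
  expect_false(canonical_code(chain_graph(3, order = "single")) ==
                 canonical_code(chain_graph(3, order = "double")))
})

test_that("molfile writing round-trips to an isomorphic graph", {
  for (smi in c("O=C=O", "c1ccccc1", "CC(C)C(=O)O", "C1CC1")) {
    g <- read_smiles(smi)
    rt <- read_molfile(write_molfile(g))
    expect_identical(canonical_code(rt), canonical_code(g))
    expect_equal(n_bonds(rt), n_bonds(g))
  }
})

test_that("mol_graph validates its invariants", {
  expect_error(mol_graph(data.frame(element = c("C", "C")),
                         data.frame(a1 = 1, a2 = 1, order = "single")),
               "distinct")
  expect_error(mol_graph(data.frame(element = c("C", "C")),
                         data.frame(a1 = c(1, 1), a2 = c(2, 2),
                                    order = c("single", "double"))),
               "duplicate bond")
  expect_error(mol_graph(data.frame(element = c("C", "C")),
                         data.frame(a1 = 1, a2 = 3, order = "single")),
               "non-existent")
  expect_error(mol_graph(data.frame(element = "Zz"), NULL), "Zz")
})
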