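test_that("split-branch base cases follow the recursion's conventions", {
  one <- chain_graph(1)
  expect_equal(split_branch_ma(one)$ma, 1L)
  expect_equal(split_branch_ma(one, convention = "joins")$ma, 0L)
  atom <- mol_graph(data.frame(element = "C"), NULL)
  expect_warning(r0 <- split_branch_ma(atom), "zero-bond")
  expect_equal(r0$ma, 0L)
})

test_that("split-branch reproduces hand-checked small molecules", {
  expect_equal(split_branch_ma(read_molfile(co2_molfile()))$ma, 2L)
  expect_equal(split_branch_ma(chain_graph(3))$ma, 3L)  # no doubling helps
  expect_equal(split_branch_ma(chain_graph(4))$ma, 3L)  # {2-bond path x2}
  for (k in 1:4)
    expect_equal(split_branch_ma(chain_graph(2^k))$ma, k + 1L)
  expect_equal(split_branch_ma(read_smiles("c1ccccc1"))$ma, 4L)
})

test_that("duplicate class enumeration finds all repeated shapes", {
  co2 <- read_molfile(co2_molfile())
  cls <- enumerate_duplicate_classes(co2)
  expect_length(cls, 1L)
  expect_equal(cls[[1]]$size, 1L)
  expect_equal(cls[[1]]$multiplicity, 2L)

  benz <- read_smiles("c1ccccc1")
  cls <- enumerate_duplicate_classes(benz)
  # 2-bond single+double path x3, C-C single x3, C=C double x3
  expect_equal(vapply(cls, `[[`, 0L, "size"), c(2L, 1L, 1L))
  expect_equal(vapply(cls, `[[`, 0L, "multiplicity"), c(3L, 3L, 3L))
  # copies within a class are pairwise edge-disjoint
  for (cl in cls) {
    edges <- unlist(cl$packing)
    expect_equal(anyDuplicated(edges), 0L)
  }
})

test_that("the chosen partition minimizes the assembly cost", {
  # all bond labels distinct: forced all-singleton partition, MA = bonds
  g <- mol_graph(data.frame(element = c("C", "N", "O", "S")),
                 data.frame(a1 = 1:3, a2 = 2:4, order = "single"))
  p <- choose_partition(g)
  expect_equal(p$cost, 3L)
  expect_length(p$classes, 0L)
  expect_length(p$singletons, 3L)

  p4 <- choose_partition(chain_graph(4))
  expect_length(p4$classes, 1L)
  expect_equal(p4$classes[[1]]$size, 2L)
  expect_equal(p4$classes[[1]]$multiplicity, 2L)
  expect_equal(p4$cost, 3L)
})

test_that("exact search realizes the shortest-pathway definition", {
  expect_equal(exact_ma(chain_graph(1)), 1L)
  tri <- mol_graph(data.frame(element = rep("C", 3)),
                   data.frame(a1 = c(1, 2, 1), a2 = c(2, 3, 3),
                              order = "single"))
  expect_equal(exact_ma(tri), 3L)
  expect_equal(exact_ma(chain_graph(8)), 4L)  # doubling pathway
  expect_error(exact_ma(chain_graph(9)), "limited to 8")
})

test_that("assembly index respects structural bounds on a random corpus", {
  fx <- fixture_manifest(n_random = 40, max_bonds = 8, chains = 0:3,
                         seed = 23)
  for (g in fx$graphs) {
    m <- n_bonds(g)
    ma <- split_branch_ma(g)$ma
    expect_gte(ma, 1L)
    expect_lte(ma, m)
    expect_gte(ma, ceiling(log2(m)) + 1L)
    expect_equal(split_branch_ma(g, convention = "joins")$ma, ma - 1L)
  }
})

test_that("the index is invariant under atom reindexing and re-runs", {
  set.seed(31)
  for (rep in 1:10) {
    g <- make_random_molecule(sample(2:9, 1))
    ref <- split_branch_ma(g)$ma
    for (i in 1:4)
      expect_equal(split_branch_ma(permute_atoms(g))$ma, ref)
  }
  g <- read_smiles("CC(C)C(=O)O")
  r1 <- split_branch_ma(g); r2 <- split_branch_ma(g)
  expect_identical(r1$ma, r2$ma)
  expect_identical(r1$partition_tree$cost, r2$partition_tree$cost)
  expect_identical(lapply(r1$partition_tree$classes, `[[`, "copies"),
                   lapply(r2$partition_tree$classes, `[[`, "copies"))
})

test_that("the timeout guard degrades to the naive bond count", {
  g <- make_random_molecule(24, seed = 5, duplication_bias = 0.9)
  expect_warning(r <- split_branch_ma(g, timeout = 1e-4), "timed out")
  expect_true(r$partial)
  expect_equal(r$ma, n_bonds(g))
})

test_that("the mass-bin survey normalizes frequencies within bins", {
  g <- read_smiles("CC(C)C(=O)O")
  sv <- survey_ma_vs_mass(rep(list(g), 10))
  expect_equal(nrow(sv), 1L)
  expect_equal(sv$frequency, 1.0)
  expect_equal(sv$count, 10L)

  fx <- fixture_manifest(n_random = 25, max_bonds = 8, chains = 0:3,
                         seed = 7)
  sv2 <- survey_ma_vs_mass(fx$graphs)
  sums <- tapply(sv2$frequency, sv2$bin_low, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))
  # survey agrees with the manifest's recorded indices
  hand <- table(fx$manifest$ma)
  expect_equal(sum(sv2$count), length(fx$graphs))
  expect_equal(tapply(sv2$count, sv2$ma, sum)[names(hand)],
               as.array(hand), ignore_attr = TRUE)

  expect_equal(nrow(survey_ma_vs_mass(list())), 0L)
})
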