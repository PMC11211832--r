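test_that("putative cores match the exhaustive single-cut enumeration oracle", {
  cases <- c("Cc1ccccc1", "Cc1ccc(-c2ccccc2)cc1", "CC(=O)Nc1ccc(O)cc1",
             "c1ccc2[nH]ccc2c1", "OCc1ccncc1")
  for (s in cases) {
    g <- parse_smiles(s)
    got <- sort(vapply(enumerate_putative_cores(g, max_cores = 50),
                       function(c) c$smiles, character(1)))
    oracle <- brute_force_cores(g)$smiles
    expect_identical(got, oracle, label = s)
  }
})

test_that("core enumeration handles ring-free and single-ring edge cases", {
  expect_length(enumerate_putative_cores(parse_smiles("CCCCCC")), 0L)
  benz <- enumerate_putative_cores(parse_smiles("c1ccccc1"))
  expect_length(benz, 1L)
  expect_identical(benz[[1]]$smiles, "c1ccccc1")
  expect_equal(benz[[1]]$node_indices, 1:6)

  tol <- enumerate_putative_cores(parse_smiles("Cc1ccccc1"))
  expect_true("c1ccccc1" %in% vapply(tol, function(c) c$smiles, character(1)))

  bm <- enumerate_putative_cores(parse_smiles("Cc1ccc(-c2ccccc2)cc1"))
  smis <- vapply(bm, function(c) c$smiles, character(1))
  expect_equal(length(smis), 3L)  # biphenyl, toluene part, bare benzene
  expect_true(to_canonical_smiles(parse_smiles("c1ccc(-c2ccccc2)cc1")) %in% smis)
  # deterministic priority: larger cores first
  sizes <- vapply(bm, function(c) length(c$node_indices), integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("core cap keeps the largest cores and reports the total", {
  g <- parse_smiles("Cc1ccc(-c2ccccc2)cc1")
  capped <- enumerate_putative_cores(g, max_cores = 1L)
  expect_length(capped, 1L)
  expect_equal(attr(capped, "total_cores"), 3L)
  expect_equal(capped[[1]]$smiles,
               enumerate_putative_cores(g, max_cores = 10L)[[1]]$smiles)
})

test_that("identify_rgroups partitions the periphery, one linker atom each", {
  g <- parse_smiles("Cc1ccccc1")
  core <- enumerate_putative_cores(g)[[1]]
  rgs <- identify_rgroups(g, core)
  expect_length(rgs, 1L)
  expect_equal(rgs[[1]]$peripheral, 1L)
  expect_true(rgs[[1]]$linker_node %in% core$node_indices)

  expect_length(identify_rgroups(parse_smiles("c1ccccc1"), 1:6), 0L)
  expect_error(identify_rgroups(g, c(1L, 99L)), "not a subset")

  # three substituents: pairwise-disjoint groups covering all non-core atoms
  m <- parse_smiles("Cc1cc(O)cc(N)c1")
  core3 <- Filter(function(c) c$smiles == "c1ccccc1",
                  enumerate_putative_cores(m))[[1]]
  rgs3 <- identify_rgroups(m, core3)
  expect_length(rgs3, 3L)
  periph <- unlist(lapply(rgs3, function(r) r$peripheral))
  expect_equal(sort(periph), setdiff(seq_len(n_atoms(m)), core3$node_indices))
  expect_equal(anyDuplicated(periph), 0L)
  # independent oracle: connected components of the non-core subgraph
  ig <- igraph::induced_subgraph(molrgr:::.as_igraph(m),
                                 setdiff(seq_len(n_atoms(m)),
                                         core3$node_indices))
  expect_equal(length(rgs3), igraph::components(ig)$no)
})

test_that("enumerate_decompositions follows the 2^n - 1 count law", {
  m <- parse_smiles("Cc1cc(O)cc(N)c1")
  core <- Filter(function(c) c$smiles == "c1ccccc1",
                 enumerate_putative_cores(m))[[1]]
  expect_length(enumerate_decompositions(m, core), 7L)  # n = 3

  g1 <- parse_smiles("Cc1ccccc1")
  expect_length(enumerate_decompositions(g1, enumerate_putative_cores(g1)[[1]]), 1L)

  m4 <- parse_smiles("Cc1c(O)cc(N)cc1F")
  core4 <- Filter(function(c) c$smiles == "c1ccccc1",
                  enumerate_putative_cores(m4, max_cores = 20L))[[1]]
  expect_length(enumerate_decompositions(m4, core4), 15L)  # n = 4

  expect_length(enumerate_decompositions(parse_smiles("c1ccccc1"),
                                         enumerate_putative_cores(parse_smiles("c1ccccc1"))[[1]]),
                0L)
})

test_that("decoupling toluene's methyl yields the expected masked pieces", {
  g <- parse_smiles("Cc1ccccc1")
  core <- enumerate_putative_cores(g)[[1]]
  d <- enumerate_decompositions(g, core)[[1]]
  q <- d$query_template
  expect_equal(n_atoms(q), 6L)
  expect_equal(sum(q$atoms$masked), 1L)
  expect_false(any(q$bonds$masked))          # core ring bonds keep attributes
  expect_true(all(q$bonds$order == "aromatic"))
  frag <- d$fragments[[1]]
  expect_equal(n_atoms(frag), 2L)
  expect_true(frag$atoms$masked[1])
  expect_true(frag$bonds$masked[1])
  expect_identical(d$rgroup_smiles, "*C")
  expect_equal(d$site_pairs[[1]][["fragment"]], 1L)
})

test_that("decoupling all groups masks one query node per distinct linker atom", {
  m <- parse_smiles("Cc1cc(O)cc(N)c1")
  core <- Filter(function(c) c$smiles == "c1ccccc1",
                 enumerate_putative_cores(m))[[1]]
  ds <- enumerate_decompositions(m, core)
  d_all <- ds[[length(ds)]]
  expect_length(d_all$fragments, 3L)
  expect_equal(sum(d_all$query_template$atoms$masked), 3L)
  # heavy-atom conservation: query + fragments - duplicated copies = molecule
  for (d in ds) {
    n_frag <- sum(vapply(d$fragments, n_atoms, integer(1)))
    expect_equal(n_atoms(d$query_template) + n_frag - length(d$fragments),
                 n_atoms(m))
    elems <- c(d$query_template$atoms$element[!d$query_template$atoms$masked],
               unlist(lapply(d$fragments, function(f)
                 f$atoms$element[!f$atoms$masked])))
    masked_q <- sum(d$query_template$atoms$masked)
    expect_equal(sort(c(elems,
                        m$atoms$element[vapply(d$rgroups, function(r)
                          r$linker_node, integer(1))[seq_len(masked_q)]])),
                 sort(m$atoms$element))
  }
})

test_that("reattach restores the parent molecule and builds new ones", {
  g <- parse_smiles("Cc1ccccc1")
  core <- enumerate_putative_cores(g)[[1]]
  d <- enumerate_decompositions(g, core)[[1]]
  back <- reattach(d$query_template, d$fragments[[1]],
                   c(d$site_pairs[[1]][["query"]], 1L),
                   fill = "restore-original")
  expect_s3_class(back, "molgraph")
  expect_identical(to_canonical_smiles(back), to_canonical_smiles(g))

  # attach a hydroxyl to the masked ring carbon -> phenol
  phen <- reattach(d$query_template, parse_smiles("*O"),
                   c(d$site_pairs[[1]][["query"]], 1L), fill = "default")
  expect_identical(to_canonical_smiles(phen), "Oc1ccccc1")

  # impossible valence -> rejection signal, not an error
  q2 <- mask_joint(parse_smiles("FC(F)(F)C"), 2L)
  bad <- reattach(q2, parse_smiles("*C(F)(F)F"), c(2L, 1L), fill = "default")
  expect_s3_class(bad, "invalid_product")
  expect_false(bad$valid)

  expect_error(reattach(d$query_template, d$fragments[[1]], c(2L, 1L)),
               "not a masked linker")
})

test_that("round trips reproduce the parent for every corpus decomposition", {
  corp <- small_corpus()
  ok <- vapply(corp$instances, function(x) {
    m <- reattach_all(x$decomposition, fill = "restore-original")
    !inherits(m, "invalid_product") &&
      identical(to_canonical_smiles(m), x$molecule_smiles)
  }, logical(1))
  expect_true(all(ok))
})

test_that("decomposition masks exactly the decoupled joints", {
  corp <- small_corpus()
  for (x in corp$instances[seq(1, length(corp$instances), by = 7)]) {
    d <- x$decomposition
    gd <- molrgr:::.decomposed_view(d)$graph
    n_sites <- length(d$fragments)
    n_linkers <- length(unique(vapply(d$rgroups, function(r) r$linker_node,
                                      integer(1))))
    expect_equal(sum(gd$atoms$masked), n_linkers + n_sites)
    expect_equal(sum(gd$bonds$masked), n_sites)
  }
})
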