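test_that("build_instances applies the core cap and emits all decompositions", {
  # the benzene core of a 3-substituent fixture contributes 2^3 - 1 = 7
  # instances; every other (molecule, core) pair contributes 2^n - 1 as well
  m3 <- "Cc1cc(O)cc(N)c1"
  inst <- build_instances(list(parse_smiles(m3)), max_cores = 10L)
  per_core <- table(vapply(inst, function(x) x$core$smiles, character(1)))
  expect_equal(unname(per_core[["c1ccccc1"]]), 7L)
  n_rg <- vapply(inst, function(x) length(x$rgroup_smiles), integer(1))
  expect_true(all(n_rg >= 1L))
  for (cs in names(per_core)) {
    ns <- n_rg[vapply(inst, function(x) x$core$smiles, character(1)) == cs]
    expect_equal(unname(per_core[[cs]]), 2L^max(ns) - 1L, label = cs)
  }

  expect_length(build_instances(list(parse_smiles("CCCCCC"))), 0L)

  # 15 unique cores at cap 10 -> the molecule is dropped entirely
  m4 <- parse_smiles("Cc1c(O)cc(N)cc1F")
  expect_equal(attr(enumerate_putative_cores(m4, 20L), "total_cores"), 15L)
  expect_length(build_instances(list(m4), max_cores = 10L), 0L)
  expect_gt(length(build_instances(list(m4), max_cores = 15L)), 0L)
})

test_that("occurrence counts equal an independent recount", {
  # counts are taken over the full instance set, before the commonness filter
  fx <- small_fixtures()
  inst <- build_instances(lapply(fx, function(r) r$graph))
  rec <- collect_rgroup_records(inst)
  recount <- table(unlist(lapply(inst, function(x) x$rgroup_smiles)))
  expect_setequal(rec$fragment_smiles, names(recount))
  for (s in names(recount)) {
    expect_equal(rec$occurrence_count[rec$fragment_smiles == s],
                 unname(as.integer(recount[s])), label = s)
  }
})

test_that("commonness uses a strict empirical-percentile threshold", {
  mk <- function(counts) {
    structure(data.frame(fragment_smiles = if (length(counts) > 0)
                           sprintf("*C%d", seq_along(counts)) else character(0),
                         occurrence_count = counts,
                         is_common = logical(length(counts)),
                         stringsAsFactors = FALSE),
              class = c("rgroup_records", "data.frame"))
  }
  # constant distribution: nothing strictly exceeds the percentile
  r <- tag_common_rgroups(mk(rep(1L, 10000L)), 99.99)
  expect_false(any(r$is_common))

  # 9999 singletons + one heavy hitter: only the heavy hitter is common
  counts <- c(rep(1L, 9999L), 10000L)
  thr <- unname(quantile(counts, 0.9999, type = 7))  # interpolation oracle
  r2 <- tag_common_rgroups(mk(counts), 99.99)
  expect_identical(r2$is_common, counts > thr)
  expect_equal(sum(r2$is_common), 1L)
  expect_true(r2$is_common[r2$occurrence_count == 10000L])

  # low percentile: everything above the minimum is common
  r3 <- tag_common_rgroups(mk(c(1L, 2L, 3L, 4L)), 1e-9)
  expect_identical(r3$is_common, c(FALSE, TRUE, TRUE, TRUE))

  expect_error(tag_common_rgroups(mk(integer(0))), "empty")
  expect_error(tag_common_rgroups(mk(1:3), 0), "percentile")
  expect_error(tag_common_rgroups(mk(1:3), 100), "percentile")
})

test_that("instance filtering removes strict majorities of common fragments", {
  mk_inst <- function(frs) structure(list(rgroup_smiles = frs),
                                     class = "corpus_instance")
  rec <- structure(data.frame(fragment_smiles = c("*C", "*O", "*N"),
                              occurrence_count = c(5L, 100L, 1L),
                              is_common = c(FALSE, TRUE, FALSE),
                              stringsAsFactors = FALSE),
                   class = c("rgroup_records", "data.frame"))
  inst <- list(mk_inst(c("*C", "*O")),        # ratio 0.5 -> kept
               mk_inst(c("*O", "*O", "*C")),  # ratio 2/3 -> removed
               mk_inst("*C"),                 # 0 common  -> kept
               mk_inst("*O"))                 # ratio 1   -> removed
  kept <- filter_instances(inst, rec)
  expect_length(kept, 2L)
  expect_identical(kept[[1]]$rgroup_smiles, c("*C", "*O"))
})

test_that("condition vectors flag the expected functional groups", {
  catalog <- load_fg_catalog()
  expect_equal(attr(catalog, "F"), 87L)
  cv <- condition_vector(c("*O", "*C(=O)O", "*OC", "*C(F)(F)F"), catalog)
  expect_equal(dim(cv), c(4L, 87L))
  expect_equal(unname(cv[1, "hydroxyl"]), 1L)
  expect_equal(unname(cv[1, "carboxylic_acid"]), 0L)
  expect_equal(unname(cv[2, "carboxylic_acid"]), 1L)
  expect_equal(unname(cv[2, "carbonyl"]), 1L)
  expect_equal(unname(cv[3, "hydroxyl"]), 0L)
  expect_equal(unname(cv[3, "methoxy"]), 1L)
  expect_equal(unname(cv[4, "trifluoromethyl"]), 1L)
  expect_equal(unname(cv[4, "fluoro"]), 1L)
})

test_that("condition vectors are invariant to fragment atom ordering", {
  pairs <- list(c("*C(=O)O", "*C(O)=O"),
                c("*c1ccccc1", "*c1ccccc1"),
                c("*OC", "*OC"),
                c("*N(C)C", "*N(C)C"))
  # also via graph-level reordering through canonical form
  for (p in pairs) {
    expect_equal(condition_vector(p[1]), condition_vector(p[2]))
  }
  v1 <- condition_vector("*C(=O)N")
  v2 <- condition_vector(to_canonical_smiles(parse_smiles("N(C(*)=O)")))
  expect_equal(v1, v2)
})

test_that("an empty catalog is a configuration error", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("name\tsmarts", tmp)
  expect_error(load_fg_catalog(tmp), "configuration error")
})

test_that("splits are molecule-level, seeded and leakage-free", {
  corp <- small_corpus()
  by_mol <- split(vapply(corp$instances, function(x) x$split, character(1)),
                  vapply(corp$instances, function(x) x$mol_id, integer(1)))
  expect_true(all(vapply(by_mol, function(s) length(unique(s)) == 1L,
                         logical(1))))
  fx <- small_fixtures()
  corp2 <- build_corpus(lapply(fx, function(r) r$graph), seed = 7)
  expect_identical(vapply(corp$instances, function(x) x$split, character(1)),
                   vapply(corp2$instances, function(x) x$split, character(1)))
})

test_that("corpus serialization round-trips byte-identically", {
  corp <- small_corpus()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  serialize_corpus(corp, d1)
  corp2 <- read_corpus(d1)
  serialize_corpus(corp2, d2)
  for (f in c("instances.jsonl", "rgroups.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  expect_equal(length(corp2$instances), length(corp$instances))
  expect_identical(corp2$records$fragment_smiles, corp$records$fragment_smiles)
  expect_identical(attr(corp2$records, "condition"),
                   attr(corp$records, "condition"))
})

test_that("the validator passes a built corpus and catches planted violations", {
  corp <- small_corpus()
  expect_length(validate_corpus(corp), 0L)
  broken <- corp
  broken$records$is_common[which.max(broken$records$occurrence_count)] <-
    !broken$records$is_common[which.max(broken$records$occurrence_count)]
  expect_gt(length(validate_corpus(broken)), 0L)
})
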