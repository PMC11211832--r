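test_that("libraries deduplicate fragments and embed deterministically", {
  ck <- toy_checkpoint()
  lib <- toy_library()
  expect_equal(length(lib$smiles), nrow(small_corpus()$records))
  expect_equal(nrow(lib$embeddings), length(lib$smiles))
  expect_equal(anyDuplicated(lib$smiles), 0L)

  lib2 <- build_library(small_corpus()$records, ck)
  expect_identical(lib$embeddings, lib2$embeddings)

  dup <- build_library(c("*C", "*O", "*C"), ck)
  expect_equal(length(dup$smiles), 2L)

  # a fragment the chemistry layer rejects is skipped with a warning
  expect_warning(
    lib3 <- build_library(c("*C", "*C(C)(C)(C)(C)C"), ck),
    "skipping")
  expect_equal(length(lib3$smiles), 1L)
  expect_identical(lib3$skipped, "*C(C)(C)(C)(C)C")
})

test_that("retrieve ranks by inner product with stable tie-breaking", {
  ck <- toy_checkpoint()
  lib <- toy_library()
  corp <- small_corpus()
  d <- corp$instances[[1]]$decomposition
  site <- d$site_pairs[[1]][["query"]]
  cond <- rep(0L, 87L)  # Cond-None ablation input is accepted
  res <- retrieve(d$query_template, site, cond, lib, ck, K = 5L)
  expect_s3_class(res, "retrieval_result")
  expect_equal(nrow(res$ranked), 5L)
  expect_true(all(diff(res$ranked$score) <= 1e-12))
  expect_equal(anyDuplicated(res$ranked$rgroup_id), 0L)

  # oracle: exhaustive inner-product ranking
  H <- encode(d$query_template, ck)
  zc <- project_query(H[site, ], cond, ck)
  sc <- as.vector(lib$embeddings %*% zc)
  expect_equal(res$ranked$rgroup_id,
               order(-sc, seq_along(sc))[1:5])

  # K beyond the library returns everything
  resN <- retrieve(d$query_template, site, cond, lib, ck, K = 10000L)
  expect_equal(nrow(resN$ranked), length(lib$smiles))

  unmasked <- which(!d$query_template$atoms$masked)[1]
  expect_error(retrieve(d$query_template, unmasked, cond, lib, ck),
               "masked linker")
})

test_that("MRR and recall match hand-computed values and a two-loop oracle", {
  mk <- function(frs) data.frame(rank = seq_along(frs), fragment_smiles = frs,
                                 stringsAsFactors = FALSE)
  # best ranks 2 and 4 -> MRR = (1/2 + 1/4)/2 = 0.375
  res <- list(mk(c("a", "T1", "b", "c")), mk(c("x", "y", "z", "T2", "w")))
  m <- evaluate_retrieval(res, list("T1", "T2"), K_list = c(1, 2, 4))
  expect_equal(unname(m["MRR"]), 0.375)
  expect_equal(unname(m[c("R@1", "R@2", "R@4")]), c(0, 0.5, 1))

  # perfect retrieval
  m2 <- evaluate_retrieval(list(mk(c("T", "a"))), list("T"), K_list = c(5, 50))
  expect_equal(unname(m2), c(1, 1, 1))

  # absent truth contributes zero everywhere
  m3 <- evaluate_retrieval(list(mk(c("a", "b"))), list("T"), K_list = 5)
  expect_equal(unname(m3), c(0, 0))

  # multiple truths use the best rank
  m4 <- evaluate_retrieval(list(mk(c("a", "T1", "T2"))), list(c("T1", "T2")),
                           K_list = 2)
  expect_equal(unname(m4["MRR"]), 0.5)

  # two-loop oracle on random rank assignments
  set.seed(31)
  ids <- sprintf("f%02d", 1:30)
  for (rep in 1:5) {
    res5 <- lapply(1:8, function(i) mk(sample(ids, 20)))
    tr5 <- lapply(1:8, function(i) sample(ids, 2))
    got <- evaluate_retrieval(res5, tr5, K_list = c(3, 10))
    mrr <- 0; r3 <- 0; r10 <- 0
    for (i in 1:8) {
      best <- Inf
      for (k in seq_len(nrow(res5[[i]]))) {
        if (res5[[i]]$fragment_smiles[k] %in% tr5[[i]]) { best <- k; break }
      }
      if (is.finite(best)) mrr <- mrr + 1 / best
      r3 <- r3 + (best <= 3); r10 <- r10 + (best <= 10)
    }
    expect_equal(unname(got), c(mrr, r3, r10) / 8, tolerance = 1e-12)
  }

  expect_error(evaluate_retrieval(res, list("T1", character(0))),
               "ground truth")
})

test_that("baselines behave as specified", {
  lib <- toy_library()
  N <- length(lib$smiles)
  pop <- baseline_rankings("popularity", lib, n_queries = 4, K = N)
  expect_identical(pop[[1]], pop[[4]])
  expect_true(all(diff(lib$counts[pop[[1]]$rgroup_id]) <= 0))
  # a query whose truth is the most frequent fragment scores MRR 1
  top <- pop[[1]]$fragment_smiles[1]
  expect_equal(unname(evaluate_retrieval(pop[1], list(top), 5)["MRR"]), 1)

  r1 <- baseline_rankings("random", lib, n_queries = 3, K = 5, seed = 9)
  r2 <- baseline_rankings("random", lib, n_queries = 3, K = 5, seed = 9)
  expect_identical(r1, r2)
  expect_false(identical(r1[[1]]$rgroup_id, r1[[2]]$rgroup_id) &&
                 identical(r1[[2]]$rgroup_id, r1[[3]]$rgroup_id))

  # closed form: single-truth R@K for the random baseline is K/N
  K <- 5
  hits <- 0
  n_trials <- 400
  for (s in 1:n_trials) {
    rr <- baseline_rankings("random", lib, n_queries = 1, K = K, seed = s)
    truth <- lib$smiles[1 + (s %% N)]
    hits <- hits + (evaluate_retrieval(rr, list(truth), K)[[paste0("R@", K)]])
  }
  p_hat <- hits / n_trials
  p_exp <- K / N
  se <- sqrt(p_exp * (1 - p_exp) / n_trials)
  expect_lt(abs(p_hat - p_exp), 4 * se + 1e-9)
})

test_that("swapping condition vectors changes the ranking signal", {
  ck <- toy_checkpoint()
  lib <- toy_library()
  corp <- small_corpus()
  d <- corp$instances[[2]]$decomposition
  site <- d$site_pairs[[1]][["query"]]
  cond_a <- attr(corp$records, "condition")[1, ]
  cond_b <- 1L - cond_a
  ra <- retrieve(d$query_template, site, cond_a, lib, ck, K = 5L)
  rb <- retrieve(d$query_template, site, cond_b, lib, ck, K = 5L)
  expect_false(identical(ra$ranked$score, rb$ranked$score))
})
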