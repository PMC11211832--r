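test_that("model initialization is seeded and dimensioned by the config", {
  m1 <- init_rgr_model(encoder_config(num_layers = 2, hidden_dim = 8), seed = 3)
  m2 <- init_rgr_model(encoder_config(num_layers = 2, hidden_dim = 8), seed = 3)
  expect_identical(m1$params, m2$params)
  m3 <- init_rgr_model(encoder_config(num_layers = 2, hidden_dim = 8), seed = 4)
  expect_false(identical(m1$params, m3$params))

  # query head consumes d + F inputs: 387 at the published defaults
  md <- init_rgr_model(encoder_config(), seed = 1)
  expect_equal(nrow(md$params$query_W1), 300L + 87L)
  expect_equal(nrow(md$params$query_W1), 387L)
  expect_equal(ncol(md$params$graph_W2), 300L)
})

test_that("encode returns one d-vector per node, deterministically", {
  model <- tiny_model()
  g <- parse_smiles("CCO")
  H <- encode(g, model)
  expect_equal(dim(H), c(3L, 8L))
  expect_identical(H, encode(g, model))
  expect_equal(dim(encode(parse_smiles("C"), model)), c(1L, 8L))
  expect_error(encode(structure(list(node_features = matrix(integer(0), 0, 5),
                                     edge_features = matrix(integer(0), 0, 2),
                                     edge_index = matrix(integer(0), 0, 2)),
                                class = "list"), model), "empty graph")
})

test_that("message passing respects components and symmetry", {
  model <- tiny_model()
  # benzene: all atoms are equivalent -> identical rows
  Hb <- encode(parse_smiles("c1ccccc1"), model)
  expect_lt(max(abs(sweep(Hb, 2, Hb[1, ]))), 1e-10)

  # two-component graph: component A unchanged when component B is replaced
  gA <- parse_smiles("CCO")
  gAB1 <- parse_smiles("CCO.c1ccccc1")
  gAB2 <- parse_smiles("CCO.CC(=O)N")
  H1 <- encode(gAB1, model)
  H2 <- encode(gAB2, model)
  expect_equal(H1[1:3, ], H2[1:3, ], tolerance = 1e-12)
  expect_equal(H1[1:3, ], encode(gA, model), tolerance = 1e-12)
})

test_that("encode is permutation-equivariant", {
  model <- tiny_model()
  set.seed(9)
  for (s in c("CC(=O)Nc1ccc(O)cc1", "FC(F)(F)c1ccncc1", "CN1CCCC1")) {
    g <- parse_smiles(s)
    p <- sample(n_atoms(g))
    g2 <- permute_molgraph(g, p)
    H <- encode(g, model)
    H2 <- encode(g2, model)
    expect_equal(H2, H[p, , drop = FALSE], tolerance = 1e-10, label = s)
  }
})

test_that("graph projection pools before the head and ignores node order", {
  model <- tiny_model()
  g <- parse_smiles("CC(=O)O")
  H <- encode(g, model)
  z <- project_graph(H, model)
  expect_length(z, 8L)
  expect_equal(project_graph(H[sample(nrow(H)), ], model), z,
               tolerance = 1e-12)
  # constant rows pool to the row itself before the head
  hrow <- matrix(rnorm(8), 1)
  Hc <- hrow[rep(1, 5), ]
  zc <- project_graph(Hc, model)
  expect_equal(zc, project_graph(hrow, model), tolerance = 1e-12)
  expect_true(attr(project_graph(H, model, stopgrad = TRUE), "stopgrad"))
})

test_that("linker-pair projection is symmetric in the masked pair", {
  model <- tiny_model()
  m_i <- rnorm(8); q_i <- rnorm(8); r_i <- rnorm(8)
  z1 <- project_linker_pair(m_i, q_i, r_i, model)
  z2 <- project_linker_pair(m_i, r_i, q_i, model)
  expect_equal(z1$z_p, z2$z_p, tolerance = 1e-12)
  expect_true(attr(z1$z_p, "stopgrad"))
  # zero pair projects the head at zero
  z0 <- project_linker_pair(m_i, rep(0, 8), rep(0, 8), model)
  direct <- molrgr:::.val(molrgr:::.forward_head(NULL, model, "node",
    molrgr:::tp_const(NULL, matrix(0, 1, 8))))
  expect_equal(unname(as.vector(z0$z_p)), as.vector(direct), tolerance = 1e-12)
  expect_error(project_linker_pair(m_i[1:3], q_i, r_i, model), "length d")
})

test_that("query projection validates the condition width and uses it", {
  model <- tiny_model()
  q <- rnorm(8)
  c0 <- rep(0L, 87L)
  z0 <- project_query(q, c0, model)
  expect_length(z0, 8L)
  c1 <- c0; c1[5] <- 1L
  expect_false(isTRUE(all.equal(project_query(q, c1, model), z0)))
  expect_error(project_query(q, rep(0L, 10L), model), "dimension error")
  # all-one conditions accepted too
  expect_length(project_query(q, rep(1L, 87L), model), 8L)
})

test_that("isomorphic fragments get identical R-group projections", {
  model <- tiny_model()
  f1 <- parse_smiles("*C(=O)O")
  f2 <- parse_smiles("*C(O)=O")
  z1 <- project_rgroup(encode(f1, model), model)
  z2 <- project_rgroup(encode(f2, model), model)
  expect_equal(z1, z2, tolerance = 1e-10)
  # single-node pooling is the row itself
  h <- matrix(rnorm(8), 1)
  expect_equal(project_rgroup(h, model),
               project_rgroup(h[c(1, 1), ], model), tolerance = 1e-12)
})

test_that("one shared encoder and shared heads produce all projections", {
  model <- tiny_model()
  corp <- small_corpus()
  prep <- molrgr:::.prepare_instances(corp$instances[1:4], corp$records)
  tape <- molrgr:::.new_tape()
  out <- molrgr:::.batch_forward(prep, model, loss_config(),
                                 attr(corp$records, "condition"),
                                 training = FALSE, tape = tape)
  molrgr:::backward(tape, out$L)
  grads <- molrgr:::.tape_grads(tape)
  # weight sharing: the single encoder parameter set accumulates gradient
  # from both the original and the decomposed forward passes, and the node
  # head from every linker site; parameter identity is by name in one list.
  expect_true("emb_element" %in% names(grads))
  expect_true("node_W1" %in% names(grads))
  expect_true("graph_W1" %in% names(grads))
  expect_true(all(c("query_W1", "rgroup_W1") %in% names(grads)))
})

test_that("stop-gradient branches assign the encoder zero credit", {
  model <- tiny_model()
  corp <- small_corpus()
  prep <- molrgr:::.prepare_instances(corp$instances[1:4], corp$records)
  cond <- attr(corp$records, "condition")

  # perturbing encoder weights changes the detached projections' values...
  out1 <- molrgr:::.batch_forward(prep, model, loss_config(), cond)
  model2 <- model
  model2$params$emb_element <- model2$params$emb_element + 0.05
  out2 <- molrgr:::.batch_forward(prep, model2, loss_config(), cond)
  expect_gt(max(abs(out1$z_GD - out2$z_GD)), 0)
  expect_gt(max(abs(out1$z_p - out2$z_p)), 0)

  # ...but a loss fed only by detached branches backpropagates nothing
  tape <- molrgr:::.new_tape()
  pack <- molrgr:::.pack_graphs(lapply(prep, function(x) x$fD))
  H <- molrgr:::.forward_gnn(tape, model, pack, training = FALSE)
  detached <- molrgr:::tp_const(tape, molrgr:::.val(H))
  loss <- molrgr:::tp_info_nce(tape, detached,
                               molrgr:::tp_const(tape, molrgr:::.val(H) + 1),
                               0.5)
  molrgr:::backward(tape, loss)
  expect_length(molrgr:::.tape_grads(tape), 0L)
})

test_that("checkpoints refuse mismatched schemas on load", {
  ck <- toy_checkpoint()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  reloaded <- load_checkpoint(path)
  expect_s3_class(reloaded, "rgr_checkpoint")
  expect_identical(molrgr:::.as_model(reloaded)$params$graph_W1,
                   molrgr:::.as_model(ck)$params$graph_W1)

  bad <- ck
  bad$model$catalog_checksum <- "0000"
  path2 <- tempfile(fileext = ".rds")
  save_checkpoint(bad, path2)
  expect_error(load_checkpoint(path2), "catalog checksum")

  bad2 <- ck
  bad2$model$vocab$node$element <- c("X", bad2$model$vocab$node$element)
  path3 <- tempfile(fileext = ".rds")
  save_checkpoint(bad2, path3)
  expect_error(load_checkpoint(path3), "vocabulary schema")
})
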