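# Shared fixtures and oracles for the suite. Everything is generated in code;
# expensive objects are built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .cache, inherits = FALSE)) {
    assign(key, force(expr), .cache)
  }
  get(key, .cache, inherits = FALSE)
}

small_fixtures <- function() cached("fx20", generate_fixtures(count = 20, seed = 7))

small_corpus <- function() cached("corp20", {
  fx <- small_fixtures()
  build_corpus(lapply(fx, function(r) r$graph), seed = 7)
})

tiny_model <- function() cached("model8", {
  init_rgr_model(encoder_config(num_layers = 2, hidden_dim = 8), seed = 3)
})

# A lightly trained checkpoint on a small corpus (shared by retrieval and
# lead-optimization tests; a few epochs are enough for deterministic,
# non-degenerate embeddings).
toy_checkpoint <- function() cached("ck_toy", {
  pretrain(small_corpus(),
           config = encoder_config(num_layers = 2, hidden_dim = 16),
           train_cfg = train_config(batch_size = 64, max_epochs = 3,
                                    patience = 10, seed = 1))
})

toy_library <- function() cached("lib_toy", {
  build_library(small_corpus()$records, toy_checkpoint())
})

# Independent brute-force core enumerator: every subset of cuttable bonds
# (acyclic, single, unmasked) is cut; every connected ring-containing
# component that is not the improper full molecule is a candidate core.
brute_force_cores <- function(g) {
  ring <- molrgr:::.ring_bond_flags(n_atoms(g), g$bonds)
  cuttable <- which(!ring & g$bonds$order == "single" & !g$bonds$masked)
  found <- character(0)
  sets <- list()
  for (mask in 0:(2^length(cuttable) - 1)) {
    cut <- cuttable[bitwAnd(mask, bitwShiftL(1, seq_along(cuttable) - 1)) != 0]
    keep_bonds <- setdiff(seq_len(n_bonds(g)), cut)
    ig <- igraph::make_empty_graph(n_atoms(g), directed = FALSE)
    if (length(keep_bonds) > 0)
      ig <- igraph::add_edges(ig, rbind(g$bonds$from[keep_bonds],
                                        g$bonds$to[keep_bonds]))
    comp <- igraph::components(ig)$membership
    for (ci in unique(comp)) {
      nodes <- which(comp == ci)
      if (length(nodes) == n_atoms(g) && length(cuttable) > 0) next
      sub_bonds <- g$bonds$from %in% nodes & g$bonds$to %in% nodes
      if (!any(ring[sub_bonds])) next
      smi <- to_canonical_smiles(molrgr:::.subgraph(g, nodes))
      if (!smi %in% found) {
        found <- c(found, smi)
        sets[[length(sets) + 1]] <- nodes
      }
    }
  }
  list(smiles = sort(found), sets = sets)
}

# Random atom relabeling of a molgraph (oracle for permutation invariance).
permute_molgraph <- function(g, perm) {
  inv <- order(perm)
  g2 <- g
  g2$atoms <- g$atoms[perm, , drop = FALSE]
  g2$bonds$from <- inv[g$bonds$from]
  g2$bonds$to <- inv[g$bonds$to]
  sw <- g2$bonds$from > g2$bonds$to
  tmp <- g2$bonds$from[sw]
  g2$bonds$from[sw] <- g2$bonds$to[sw]
  g2$bonds$to[sw] <- tmp
  rownames(g2$atoms) <- NULL
  g2
}

# 100+ drug-like SMILES assembled from the generator plus hand-picked
# standards (round-trip fixture set).
druglike_smiles <- function() cached("druglike", {
  base <- c("CCO", "c1ccccc1", "Cc1ccccc1", "CC(=O)Nc1ccc(O)cc1",
            "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccc2[nH]ccc2c1",
            "OC(=O)c1ccccc1OC(C)=O", "Clc1ccccc1", "c1ccncc1",
            "C1CCNCC1", "O=C(N)c1ccncc1", "FC(F)(F)c1ccc(N)cc1",
            "CN1CCC[C@H]1c1cccnc1", "O=S(=O)(N)c1ccccc1")
  fx <- generate_fixtures(count = 90, seed = 13)
  unique(c(base, vapply(fx, function(r) r$smiles, character(1))))
})
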