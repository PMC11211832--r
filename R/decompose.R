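#' Putative cores, R-groups and masked decompositions
#'
#' A molecule is decomposed under the "single molecule - multiple scaffolds"
#' paradigm: a putative core is any connected, ring-containing remainder
#' obtainable by cutting one or more acyclic single non-ring bonds (fused ring
#' systems are never split); the peripheral substructures hanging off a core
#' are its R-groups, each sharing one linker atom with the core. Decoupling a
#' subset of R-groups duplicates each shared linker atom into the fragment and
#' masks both copies plus the copy's bond into the fragment, yielding a query
#' template and decoupled fragments whose masked linker joints can later be
#' re-attached.
#'
#' @name decompose
NULL

# Condensed bridge tree: contract every bond that cannot be cut (ring bonds
# and non-single bridges); remaining bonds form a tree over super-nodes.
.bridge_tree <- function(g) {
  n <- n_atoms(g)
  ring_bond <- .ring_bond_flags(n, g$bonds)
  cuttable <- !ring_bond & g$bonds$order == "single" & !g$bonds$masked
  contracted <- igraph::make_empty_graph(n, directed = FALSE)
  if (any(!cuttable)) {
    keep <- which(!cuttable)
    contracted <- igraph::add_edges(contracted,
                                    rbind(g$bonds$from[keep], g$bonds$to[keep]))
  }
  member <- igraph::components(contracted)$membership
  k <- max(member)
  ring_atom <- rep(FALSE, n)
  if (any(ring_bond)) {
    rb <- which(ring_bond)
    ring_atom[unique(c(g$bonds$from[rb], g$bonds$to[rb]))] <- TRUE
  }
  super_has_ring <- vapply(seq_len(k), function(s) any(ring_atom[member == s]),
                           logical(1))
  cut_idx <- which(cuttable)
  tree_edges <- if (length(cut_idx) > 0L) {
    cbind(member[g$bonds$from[cut_idx]], member[g$bonds$to[cut_idx]])
  } else matrix(integer(0), 0L, 2L)
  list(member = member, n_super = k, super_has_ring = super_has_ring,
       tree_edges = tree_edges, cut_bonds = cut_idx)
}

# Enumerate connected subtrees (as sorted super-node id vectors) of the bridge
# tree, up to `limit` unique subtrees.
.connected_subtrees <- function(n_super, tree_edges, limit = 2048L) {
  adj <- vector("list", n_super)
  if (nrow(tree_edges) > 0L) {
    for (k in seq_len(nrow(tree_edges))) {
      a <- tree_edges[k, 1]; b <- tree_edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- new.env(parent = emptyenv())
  out <- list()
  queue <- lapply(seq_len(n_super), function(i) i)
  for (q in queue) assign(paste(q, collapse = ","), TRUE, envir = seen)
  truncated <- FALSE
  while (length(queue) > 0L) {
    s <- queue[[1L]]; queue[[1L]] <- NULL
    out[[length(out) + 1L]] <- s
    if (length(out) >= limit) { truncated <- TRUE; break }
    nbrs <- setdiff(unique(unlist(adj[s])), s)
    for (nb in nbrs) {
      s2 <- sort(c(s, nb))
      key <- paste(s2, collapse = ",")
      if (!exists(key, envir = seen, inherits = FALSE)) {
        assign(key, TRUE, envir = seen)
        queue[[length(queue) + 1L]] <- s2
      }
    }
  }
  attr(out, "truncated") <- truncated
  out
}

#' Enumerate the putative cores of a molecule
#'
#' A candidate core is a connected, ring-containing induced subgraph whose
#' boundary consists only of acyclic single bonds (so it is obtainable by
#' removing one or more maximal peripheral branches). Candidates are
#' deduplicated by canonical SMILES and returned in deterministic priority
#' order: larger cores first, ties broken by canonical SMILES. The full
#' molecule itself only qualifies when it is a single ring system carrying no
#' substituents. Acyclic molecules have no cores.
#'
#' @param molecule A `molgraph`.
#' @param max_cores Keep at most this many cores (default 10). The attribute
#'   `"total_cores"` on the result records the number of unique cores found
#'   before capping, so callers can drop molecules exceeding the cap.
#' @return A list of `putative_core` objects (possibly empty), each with
#'   `node_indices`, `core_id` and `smiles`.
#' @export
enumerate_putative_cores <- function(molecule, max_cores = 10L) {
  stopifnot(inherits(molecule, "molgraph"), max_cores >= 1L)
  bt <- .bridge_tree(molecule)
  if (!any(bt$super_has_ring)) {
    out <- list()
    attr(out, "total_cores") <- 0L
    return(out)
  }
  subtrees <- .connected_subtrees(bt$n_super, bt$tree_edges)
  full <- bt$n_super
  cands <- list()
  for (s in subtrees) {
    if (!any(bt$super_has_ring[s])) next
    if (length(s) == full && full > 1L) next
    cands[[length(cands) + 1L]] <- sort(which(bt$member %in% s))
  }
  if (length(cands) == 0L) {
    out <- list()
    attr(out, "total_cores") <- 0L
    return(out)
  }
  smiles <- vapply(cands, function(nodes)
    to_canonical_smiles(.subgraph(molecule, nodes)), character(1))
  keep <- !duplicated(smiles)
  cands <- cands[keep]; smiles <- smiles[keep]
  sizes <- lengths(cands)
  ord <- order(-sizes, smiles)
  cands <- cands[ord]; smiles <- smiles[ord]
  total <- length(cands)
  if (attr(subtrees, "truncated")) total <- max_cores + 1L
  ncap <- min(length(cands), max_cores)
  out <- lapply(seq_len(ncap), function(j) {
    structure(list(node_indices = cands[[j]], core_id = j,
                   smiles = smiles[j]),
              class = "putative_core")
  })
  attr(out, "total_cores") <- total
  out
}

#' @export
print.putative_core <- function(x, ...) {
  cat(sprintf("<putative_core #%d> %d atoms: %s\n", x$core_id,
              length(x$node_indices), x$smiles))
  invisible(x)
}

#' Identify the R-groups of a molecule relative to a putative core
#'
#' Each maximal connected peripheral component attached to the core is one
#' R-group; every non-core atom belongs to exactly one R-group, and each
#' R-group records the linker atom it shares with the core (the core-side
#' attachment atom) plus the single bond crossing the boundary.
#'
#' @param molecule A `molgraph`.
#' @param core A `putative_core` of `molecule` (or an integer vector of core
#'   node indices).
#' @return A list of `rgroup` objects ordered by linker atom id (ties by the
#'   smallest peripheral atom id). Empty when the core covers the molecule.
#' @export
identify_rgroups <- function(molecule, core) {
  core_nodes <- if (inherits(core, "putative_core")) core$node_indices
    else sort(unique(as.integer(core)))
  if (any(core_nodes < 1L | core_nodes > n_atoms(molecule)))
    stop("argument error: core nodes are not a subset of the molecule")
  periph <- setdiff(seq_len(n_atoms(molecule)), core_nodes)
  if (length(periph) == 0L) return(list())
  sub <- igraph::induced_subgraph(.as_igraph(molecule), periph)
  member <- igraph::components(sub)$membership
  groups <- lapply(seq_len(max(member)), function(ci) periph[member == ci])

  rgs <- lapply(groups, function(comp) {
    crossing <- which((molecule$bonds$from %in% comp) !=
                        (molecule$bonds$to %in% comp))
    crossing <- crossing[molecule$bonds$from[crossing] %in% core_nodes |
                           molecule$bonds$to[crossing] %in% core_nodes]
    if (length(crossing) != 1L)
      stop("argument error: peripheral component attaches to the core ",
           "through ", length(crossing), " bonds (expected exactly 1)")
    b <- molecule$bonds[crossing, ]
    linker <- if (b$from %in% core_nodes) b$from else b$to
    first_atom <- if (b$from %in% core_nodes) b$to else b$from
    structure(list(node_indices = sort(c(comp, linker)), peripheral = sort(comp),
                   linker_node = linker, linker_edge = crossing,
                   first_atom = first_atom),
              class = "rgroup")
  })
  ord <- order(vapply(rgs, function(r) r$linker_node, integer(1)),
               vapply(rgs, function(r) min(r$peripheral), integer(1)))
  rgs[ord]
}

#' @export
print.rgroup <- function(x, ...) {
  cat(sprintf("<rgroup> %d peripheral atoms, linker atom %d\n",
              length(x$peripheral), x$linker_node))
  invisible(x)
}

#' Decouple a subset of R-groups from a core
#'
#' Builds one masked decomposition: the query template is the molecule minus
#' the subset's peripheral atoms with each affected linker atom masked (and
#' nothing else -- its remaining core bonds keep their attributes); each
#' decoupled fragment consists of the R-group atoms plus a duplicated copy of
#' its linker atom, with the copy and the copy's bond into the fragment
#' masked. R-groups outside the subset remain intact and unmasked in the
#' query template.
#'
#' @param molecule A `molgraph`.
#' @param core A `putative_core` (or core node indices).
#' @param subset Non-empty list of `rgroup` objects from
#'   [identify_rgroups()], pairwise disjoint.
#' @return A `decomposition` with `query_template`, `fragments` (the masked
#'   linker copy is always atom 1 of a fragment), `site_pairs` (one
#'   `c(query, fragment)` index pair per fragment), `rgroup_smiles` (canonical
#'   fragment SMILES) and `subset_id` (filled by
#'   [enumerate_decompositions()]).
#' @export
decouple_subset <- function(molecule, core, subset) {
  if (length(subset) == 0L) stop("argument error: empty R-group subset")
  periph_all <- unlist(lapply(subset, function(r) r$peripheral))
  if (anyDuplicated(periph_all))
    stop("argument error: overlapping R-groups in subset")

  query_nodes <- setdiff(seq_len(n_atoms(molecule)), periph_all)
  qmap <- integer(n_atoms(molecule))
  qmap[query_nodes] <- seq_along(query_nodes)
  query <- .subgraph(molecule, query_nodes, recompute_h = FALSE)
  for (rg in subset) query <- mask_joint(query, qmap[rg$linker_node])

  fragments <- vector("list", length(subset))
  site_pairs <- vector("list", length(subset))
  rsmiles <- character(length(subset))
  for (i in seq_along(subset)) {
    rg <- subset[[i]]
    fragments[[i]] <- .build_fragment(molecule, rg)
    site_pairs[[i]] <- c(query = qmap[rg$linker_node], fragment = 1L)
    rsmiles[i] <- to_canonical_smiles(fragments[[i]])
  }

  structure(list(molecule = molecule, core = core, rgroups = subset,
                 query_template = query, fragments = fragments,
                 site_pairs = site_pairs, rgroup_smiles = rsmiles,
                 subset_id = NA_integer_),
            class = "decomposition")
}

# Decoupled fragment of one R-group: its atoms plus a duplicated, masked copy
# of the linker atom (always atom 1), whose bond into the fragment is masked.
.build_fragment <- function(molecule, rg) {
  periph <- rg$peripheral
  fmap <- integer(n_atoms(molecule))
  fmap[periph] <- seq_along(periph) + 1L
  at <- rbind(molecule$atoms[rg$linker_node, , drop = FALSE],
              molecule$atoms[periph, , drop = FALSE])
  keep <- molecule$bonds$from %in% periph & molecule$bonds$to %in% periph
  bd <- molecule$bonds[keep, , drop = FALSE]
  if (nrow(bd) > 0L) {
    bd$from <- fmap[bd$from]; bd$to <- fmap[bd$to]
    sw <- bd$from > bd$to
    tmp <- bd$from[sw]; bd$from[sw] <- bd$to[sw]; bd$to[sw] <- tmp
  } else bd <- .empty_bonds()
  cut <- molecule$bonds[rg$linker_edge, , drop = FALSE]
  bd <- rbind(data.frame(from = 1L, to = fmap[rg$first_atom],
                         order = cut$order, stereo = cut$stereo,
                         masked = TRUE, stringsAsFactors = FALSE), bd)
  frag <- .new_molgraph(at, bd)
  frag$atoms$masked[1L] <- TRUE
  frag
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition k=%s> query %d atoms, %d decoupled fragment%s: %s\n",
              ifelse(is.na(x$subset_id), "?", x$subset_id),
              n_atoms(x$query_template), length(x$fragments),
              if (length(x$fragments) == 1L) "" else "s",
              paste(x$rgroup_smiles, collapse = " ")))
  invisible(x)
}

#' Enumerate all masked decompositions of a molecule over one core
#'
#' One decomposition per non-empty subset of the core's R-groups: a molecule
#' whose core carries `n` R-groups yields exactly `2^n - 1` decompositions.
#' Subset order is deterministic: binary counting over R-groups sorted by
#' linker atom id, so `subset_id = k` decouples R-group `t` iff bit `t-1` of
#' `k` is set.
#'
#' @inheritParams decouple_subset
#' @return List of `decomposition` objects (empty when the core has no
#'   R-groups).
#' @export
enumerate_decompositions <- function(molecule, core) {
  rgs <- identify_rgroups(molecule, core)
  n <- length(rgs)
  if (n == 0L) return(list())
  if (n > 12L)
    stop("argument error: ", n, " R-groups would enumerate ", 2^n - 1,
         " decompositions; refusing above n = 12")
  out <- vector("list", 2^n - 1L)
  for (k in seq_len(2^n - 1L)) {
    sel <- which(bitwAnd(k, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    d <- decouple_subset(molecule, core, rgs[sel])
    d$subset_id <- k
    out[[k]] <- d
  }
  out
}

#' Re-attach a decoupled fragment onto a query template
#'
#' Merges the fragment's masked linker copy onto the query's masked linker
#' node, unmasks the joint and fills in node and edge attributes. With
#' `fill = "restore-original"` the stored original attributes are restored
#' (round trips reproduce the parent molecule exactly). With
#' `fill = "default"` -- used for retrieved foreign fragments -- the query
#' node keeps its stored attributes when it has them (falling back to a
#' carbon atom otherwise), the joint bond becomes a plain single bond, and
#' the hydrogen count is re-derived from the remaining valence. The result is
#' sanitized; a chemically impossible product is returned as an
#' `invalid_product` signal, not an error.
#'
#' @param query_template A `molgraph` with a masked linker node.
#' @param fragment A `molgraph` whose masked linker copy is `site_pair[2]`.
#' @param site_pair Integer pair `c(query_node, fragment_node)`; both must be
#'   masked linker nodes.
#' @param fill `"default"` or `"restore-original"`.
#' @return A `molgraph`, or an object of class `invalid_product` with fields
#'   `valid = FALSE` and `reason`.
#' @export
reattach <- function(query_template, fragment, site_pair,
                     fill = c("default", "restore-original")) {
  fill <- match.arg(fill)
  qnode <- as.integer(site_pair[1]); fnode <- as.integer(site_pair[2])
  if (qnode < 1L || qnode > n_atoms(query_template) ||
      !query_template$atoms$masked[qnode])
    stop("argument error: query node ", qnode, " is not a masked linker node")
  if (fnode < 1L || fnode > n_atoms(fragment) ||
      !fragment$atoms$masked[fnode])
    stop("argument error: fragment node ", fnode, " is not a masked linker node")
  g <- .merge_fragment(query_template, qnode, fragment, fnode, fill)
  .finalize_joint(g, qnode, fill)
}

# Merge fragment onto g at qnode, dropping the fragment's copy atom fnode.
# Joint bonds (formerly incident to the copy) are unmasked and filled.
.merge_fragment <- function(g, qnode, fragment, fnode, fill) {
  nf <- n_atoms(fragment)
  keep <- setdiff(seq_len(nf), fnode)
  fmap <- integer(nf)
  fmap[keep] <- n_atoms(g) + seq_along(keep)
  fmap[fnode] <- qnode
  at <- rbind(g$atoms, fragment$atoms[keep, , drop = FALSE])
  fb <- fragment$bonds
  if (nrow(fb) > 0L) {
    joint <- fb$from == fnode | fb$to == fnode
    fb$from <- fmap[fb$from]; fb$to <- fmap[fb$to]
    sw <- fb$from > fb$to
    tmp <- fb$from[sw]; fb$from[sw] <- fb$to[sw]; fb$to[sw] <- tmp
    if (fill == "default") {
      fb$order[joint & fb$masked] <- "single"
      fb$stereo[joint & fb$masked] <- "none"
    }
    fb$masked[joint] <- FALSE
  }
  bd <- rbind(g$bonds, fb)
  .new_molgraph(at, bd, fragment_ids = NULL)
}

# Unmask the joint atom, fill attributes, recompute its hydrogen count when
# attributes were inferred, and sanitize.
.finalize_joint <- function(g, qnode, fill) {
  a <- g$atoms[qnode, ]
  if (fill == "default" && a$element == "*") {
    g$atoms$element[qnode] <- "C"
    g$atoms$charge[qnode] <- 0L
    g$atoms$aromatic[qnode] <- FALSE
    g$atoms$chirality[qnode] <- "none"
  }
  g$atoms$masked[qnode] <- FALSE
  if (fill == "default") {
    bsum <- .bond_order_sums(n_atoms(g), g$bonds)[qnode]
    dv <- .default_valences[[g$atoms$element[qnode]]]
    if (!is.null(dv)) {
      s <- ceiling(bsum)
      fit <- dv[dv >= s]
      g$atoms$hcount[qnode] <- if (length(fit) == 0L) 0L
        else as.integer(fit[1L] - s)
    }
  }
  ok <- tryCatch({ sanitize_molgraph(g); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) {
    return(structure(list(valid = FALSE, reason = ok),
                     class = "invalid_product"))
  }
  g
}

#' @export
print.invalid_product <- function(x, ...) {
  cat("<invalid product>", x$reason, "\n")
  invisible(x)
}

#' Re-attach every decoupled fragment of a decomposition
#'
#' Merges all fragments back onto the query template over their recorded site
#' pairs. Fragments sharing a linker atom are merged before the joint atom is
#' unmasked, so multi-branch joints round-trip correctly.
#'
#' @param decomposition A `decomposition`.
#' @param fill Attribute fill policy, see [reattach()].
#' @return A `molgraph` or an `invalid_product`.
#' @export
reattach_all <- function(decomposition,
                         fill = c("restore-original", "default")) {
  fill <- match.arg(fill)
  g <- decomposition$query_template
  qnodes <- vapply(decomposition$site_pairs, function(p) p[[1]], integer(1))
  for (i in seq_along(decomposition$fragments)) {
    g <- .merge_fragment(g, qnodes[i], decomposition$fragments[[i]],
                         decomposition$site_pairs[[i]][[2]], fill)
  }
  for (q in unique(qnodes)) {
    g <- .finalize_joint(g, q, fill)
    if (inherits(g, "invalid_product")) return(g)
  }
  g
}

# Disjoint decomposed view G_D = query template + fragments, with bookkeeping
# for the encoder: per-fragment node spans and (query_row, fragment_row)
# linker pairs in the packed index space.
.decomposed_view <- function(decomp) {
  gd <- .disjoint_union(c(list(decomp$query_template), decomp$fragments))
  offs <- attr(gd, "offsets")
  pairs <- t(vapply(seq_along(decomp$fragments), function(i) {
    c(q = decomp$site_pairs[[i]][[1]],
      r = offs[i + 1L] + decomp$site_pairs[[i]][[2]])
  }, integer(2)))
  frag_rows <- lapply(seq_along(decomp$fragments), function(i) {
    offs[i + 1L] + seq_len(n_atoms(decomp$fragments[[i]]))
  })
  list(graph = gd, linker_pairs = pairs, frag_rows = frag_rows)
}
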