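#' Molecular graphs with maskable attributes
#'
#' A `molgraph` is an undirected simple graph over heavy atoms. Atoms carry
#' element, formal charge, aromatic flag, chirality tag, hydrogen count and a
#' mask flag; bonds carry order, stereo tag and a mask flag. Masked entities
#' keep their stored attributes (so round trips can restore them) but are
#' rendered as the `MASK` sentinel by [featurize()] and as wildcard `*` atoms
#' by the SMILES writer. A graph may be disconnected: the decomposed view of a
#' molecule holds the query template and the decoupled R-group fragments as
#' disjoint components, tracked in `fragment_ids`.
#'
#' @name molgraph
NULL

#' Number of atoms / bonds in a molecular graph
#' @param g A `molgraph`.
#' @return Integer count.
#' @export
n_atoms <- function(g) nrow(g$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(g) nrow(g$bonds)

#' @export
print.molgraph <- function(x, ...) {
  nm <- sum(x$atoms$masked)
  nb <- sum(x$bonds$masked)
  comp <- molgraph_components(x)
  cat(sprintf("<molgraph> %d atoms (%d masked), %d bonds (%d masked), %d component%s\n",
              n_atoms(x), nm, n_bonds(x), nb, max(comp, 0L),
              if (max(comp, 0L) == 1L) "" else "s"))
  if (!is.null(x$source_smiles)) cat("  source:", x$source_smiles, "\n")
  invisible(x)
}

.new_molgraph <- function(atoms, bonds, source_smiles = NULL,
                          fragment_ids = NULL) {
  rownames(atoms) <- NULL
  rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds, source_smiles = source_smiles,
                 fragment_ids = fragment_ids),
            class = "molgraph")
}

.empty_bonds <- function() {
  data.frame(from = integer(0), to = integer(0), order = character(0),
             stereo = character(0), masked = logical(0),
             stringsAsFactors = FALSE)
}

#' Validate the chemistry of a molecular graph
#'
#' Checks that every unmasked atom's total valence (bond orders plus hydrogen
#' count, aromatic bonds counting 1.5 with a lone-pair allowance for aromatic
#' heteroatoms) does not exceed the maximum permitted valence for its element
#' and formal charge. Masked atoms and wildcard attachment points are exempt.
#'
#' @param g A `molgraph`.
#' @param context Optional string naming the molecule in error messages.
#' @return `TRUE` invisibly, or an error describing the violation.
#' @export
sanitize_molgraph <- function(g, context = NULL) {
  ctx <- if (is.null(context)) "" else paste0(" in '", context, "'")
  bsum_hi <- .bond_order_sums(n_atoms(g), g$bonds)
  # Donor variant: aromatic bonds count 1 (pyrrole-type lone-pair donors).
  bonds_lo <- g$bonds
  bonds_lo$order[bonds_lo$order == "aromatic"] <- "single"
  bsum_lo <- .bond_order_sums(n_atoms(g), bonds_lo)
  for (v in seq_len(n_atoms(g))) {
    if (g$atoms$masked[v] || g$atoms$element[v] == "*") next
    vmax <- .max_valence(g$atoms$element[v], g$atoms$charge[v])
    if (is.null(vmax)) next
    tot_hi <- ceiling(bsum_hi[v]) + g$atoms$hcount[v]
    tot_lo <- floor(bsum_lo[v]) + g$atoms$hcount[v]
    ok <- tot_hi <= vmax || (g$atoms$aromatic[v] && tot_lo <= vmax)
    if (!ok) {
      stop("sanitization error", ctx, ": atom ", v, " (", g$atoms$element[v],
           ") has valence ", tot_hi, " > permitted ", vmax)
    }
  }
  invisible(TRUE)
}

#' Mask a linker joint (an atom and selected incident bonds)
#'
#' Returns a copy of the graph with the mask flag set on the given atom and on
#' the listed bonds, which must be incident to it. Stored attribute values are
#' retained (for round-trip restoration) but every consumer that reads
#' attributes -- [featurize()], the SMILES writer -- sees the `MASK` sentinel.
#' Masking an already-masked entity is a no-op, so the operation is
#' idempotent. Topology is unchanged.
#'
#' @param g A `molgraph`.
#' @param node_index Atom id to mask (1-based).
#' @param edge_indices Integer ids of bonds to mask (rows of `g$bonds`), all
#'   incident to `node_index`. May be empty.
#' @return A new `molgraph`.
#' @export
mask_joint <- function(g, node_index, edge_indices = integer(0)) {
  node_index <- as.integer(node_index)
  edge_indices <- as.integer(edge_indices)
  if (length(node_index) != 1L || is.na(node_index) ||
      node_index < 1L || node_index > n_atoms(g)) {
    stop("argument error: node_index ", node_index, " not in graph")
  }
  if (length(edge_indices) > 0L) {
    if (any(edge_indices < 1L | edge_indices > n_bonds(g)))
      stop("argument error: edge index out of range")
    inc <- g$bonds$from[edge_indices] == node_index |
      g$bonds$to[edge_indices] == node_index
    if (!all(inc))
      stop("argument error: edge ", edge_indices[!inc][1L],
           " is not incident to node ", node_index)
  }
  g$atoms$masked[node_index] <- TRUE
  if (length(edge_indices) > 0L) g$bonds$masked[edge_indices] <- TRUE
  g
}

#' Featurize a molecular graph into integer-coded matrices
#'
#' Encodes every atom and bond attribute against the fixed vocabularies of
#' [attribute_vocabularies()]. Masked atoms and bonds map to the sentinel id
#' (the final index) of every attribute; unmasked entities never do. Bonds are
#' expanded to both directions for message passing: directed edge `2k-1` is
#' `from -> to` of bond `k` and edge `2k` its reverse.
#'
#' @param g A `molgraph`.
#' @return A list with `node_features` (n x 5 integer matrix), `edge_features`
#'   (2E x 2 integer matrix), `edge_index` (2E x 2, columns `src`, `dst`),
#'   `sentinel` ids per attribute and `vocab` (the vocabularies used).
#' @export
featurize <- function(g) {
  v <- attribute_vocabularies()
  n <- n_atoms(g)
  code <- function(values, vocab, attr_name) {
    idx <- match(values, vocab)
    if (attr_name == "element") idx[is.na(idx)] <- match("other", vocab)
    if (anyNA(idx)) {
      bad <- unique(values[is.na(idx)])
      stop("encoding error: attribute '", attr_name,
           "' value outside vocabulary: ", paste(bad, collapse = ", "))
    }
    idx
  }
  hc <- pmin(pmax(g$atoms$hcount, 0L), 4L)
  nf <- cbind(
    element   = code(g$atoms$element, v$node$element, "element"),
    charge    = code(as.character(g$atoms$charge), v$node$charge, "charge"),
    aromatic  = code(as.character(g$atoms$aromatic), v$node$aromatic, "aromatic"),
    chirality = code(g$atoms$chirality, v$node$chirality, "chirality"),
    hcount    = code(as.character(hc), v$node$hcount, "hcount")
  )
  sent_node <- vapply(v$node, length, integer(1))
  if (any(g$atoms$masked)) {
    nf[g$atoms$masked, ] <- matrix(sent_node, sum(g$atoms$masked), 5L,
                                   byrow = TRUE)
  }

  ne <- n_bonds(g)
  if (ne > 0L) {
    eo <- code(g$bonds$order, v$edge$order, "order")
    es <- code(g$bonds$stereo, v$edge$stereo, "stereo")
    eo[g$bonds$masked] <- length(v$edge$order)
    es[g$bonds$masked] <- length(v$edge$stereo)
    ef <- cbind(order = rep(eo, each = 2L), stereo = rep(es, each = 2L))
    ei <- matrix(0L, 2L * ne, 2L, dimnames = list(NULL, c("src", "dst")))
    ei[seq(1L, 2L * ne, by = 2L), ] <- cbind(g$bonds$from, g$bonds$to)
    ei[seq(2L, 2L * ne, by = 2L), ] <- cbind(g$bonds$to, g$bonds$from)
  } else {
    ef <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("order", "stereo")))
    ei <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("src", "dst")))
  }
  list(node_features = nf, edge_features = ef, edge_index = ei,
       sentinel = v$sentinel, vocab = v)
}

# Graph utilities ------------------------------------------------------------

.as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n_atoms(g), directed = FALSE)
  if (n_bonds(g) > 0L) ig <- igraph::add_edges(ig, rbind(g$bonds$from, g$bonds$to))
  ig
}

#' Connected-component labels of a molecular graph
#' @param g A `molgraph`.
#' @return Integer vector of component ids, one per atom.
#' @export
molgraph_components <- function(g) {
  if (n_atoms(g) == 0L) return(integer(0))
  igraph::components(.as_igraph(g))$membership
}

# Degrees (heavy-atom neighbors) per atom.
.degrees <- function(g) {
  d <- integer(n_atoms(g))
  if (n_bonds(g) > 0L) {
    t1 <- tabulate(g$bonds$from, nbins = n_atoms(g))
    t2 <- tabulate(g$bonds$to, nbins = n_atoms(g))
    d <- t1 + t2
  }
  d
}

# Induced subgraph on `nodes` (kept in ascending order). When recompute_h is
# TRUE, hydrogen counts of boundary atoms absorb the removed bond orders so
# the subgraph stands alone as a molecule.
.subgraph <- function(g, nodes, recompute_h = TRUE) {
  nodes <- sort(unique(as.integer(nodes)))
  if (any(nodes < 1L | nodes > n_atoms(g)))
    stop("argument error: subgraph nodes out of range")
  map <- integer(n_atoms(g)); map[nodes] <- seq_along(nodes)
  at <- g$atoms[nodes, , drop = FALSE]
  keep <- g$bonds$from %in% nodes & g$bonds$to %in% nodes
  bd <- g$bonds[keep, , drop = FALSE]
  if (recompute_h) {
    cut <- g$bonds[(g$bonds$from %in% nodes) != (g$bonds$to %in% nodes), ,
                   drop = FALSE]
    if (nrow(cut) > 0L) {
      w <- c(single = 1, double = 2, triple = 3, aromatic = 1)
      for (k in seq_len(nrow(cut))) {
        end <- if (cut$from[k] %in% nodes) cut$from[k] else cut$to[k]
        at$hcount[map[end]] <- at$hcount[map[end]] + as.integer(w[cut$order[k]])
      }
    }
  }
  if (nrow(bd) > 0L) {
    bd$from <- map[bd$from]; bd$to <- map[bd$to]
    sw <- bd$from > bd$to
    tmp <- bd$from[sw]; bd$from[sw] <- bd$to[sw]; bd$to[sw] <- tmp
  } else bd <- .empty_bonds()
  .new_molgraph(at, bd)
}

# Disjoint union of molgraphs; returns graph plus per-input node offsets.
.disjoint_union <- function(graphs) {
  offs <- cumsum(c(0L, vapply(graphs, n_atoms, integer(1))))
  at <- do.call(rbind, lapply(graphs, function(g) g$atoms))
  bds <- lapply(seq_along(graphs), function(i) {
    b <- graphs[[i]]$bonds
    if (nrow(b) > 0L) { b$from <- b$from + offs[i]; b$to <- b$to + offs[i] }
    b
  })
  bd <- do.call(rbind, bds)
  if (is.null(bd) || nrow(bd) == 0L) bd <- .empty_bonds()
  frag <- rep(seq_along(graphs), vapply(graphs, n_atoms, integer(1)))
  g <- .new_molgraph(at, bd, fragment_ids = frag)
  attr(g, "offsets") <- offs[seq_along(graphs)]
  g
}
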