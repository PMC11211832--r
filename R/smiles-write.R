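#' Render and canonicalize molecular graphs as SMILES
#'
#' The writer renders masked atoms as wildcard `*` atoms and masked bonds as
#' unspecified bonds next to them (the `* ~` display convention for fragment
#' attachment points). Canonicalization of valid unmasked molecules and of
#' fragments whose masked atoms sit outside aromatic rings is delegated to
#' OpenBabel; graphs with masked atoms inside aromatic rings (query templates)
#' use an internal Morgan-refinement canonical ordering, since aromatic rings
#' containing a wildcard member cannot be kekulized by standard toolkits.
#' Stereochemistry is not emitted: canonical forms are constitution-only.
#'
#' Two graphs equal up to isomorphism yield identical canonical strings, and
#' `parse_smiles(to_canonical_smiles(g))` is graph-isomorphic to `g`.
#'
#' @param g A `molgraph` (may be disconnected; components are canonicalized
#'   separately and joined with `.` in sorted order).
#' @return A single SMILES string.
#' @examples
#' to_canonical_smiles(parse_smiles("OCC"))  # "CCO"
#' @export
to_canonical_smiles <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  if (!any(g$atoms$masked) && !any(g$bonds$masked)) {
    sanitize_molgraph(g)
  }
  comp <- molgraph_components(g)
  pieces <- vapply(seq_len(max(comp)), function(ci) {
    sub <- .subgraph(g, which(comp == ci), recompute_h = FALSE)
    .canonical_component(sub)
  }, character(1))
  paste(sort(pieces), collapse = ".")
}

.canonical_component <- function(sub) {
  masked_atoms <- which(sub$atoms$masked)
  arom_adjacent <- FALSE
  if (length(masked_atoms) > 0L && n_bonds(sub) > 0L) {
    inc <- sub$bonds$from %in% masked_atoms | sub$bonds$to %in% masked_atoms
    arom_adjacent <- any(sub$bonds$order[inc] == "aromatic")
  }
  if (!arom_adjacent) {
    smi <- .write_smiles(sub)
    out <- tryCatch(.ob_canonical(smi), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  # Internal canonical ordering (masked aromatic-ring members, or OB failure).
  .write_smiles(sub, ranks = .canonical_ranks(sub))
}

.ob_canonical <- function(smi) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", smi)
  out <- trimws(out)
  if (!nzchar(out)) stop("canonicalization error for '", smi, "'")
  out
}

# SMILES writer ---------------------------------------------------------------

# Write a connected molgraph as SMILES. `ranks`, when given, fixes the root
# (lowest rank) and the neighbor visiting order.
.write_smiles <- function(g, ranks = NULL) {
  n <- n_atoms(g)
  if (n == 0L) stop("argument error: empty graph")
  if (is.null(ranks)) ranks <- seq_len(n)
  adj <- vector("list", n)
  for (k in seq_len(n_bonds(g))) {
    a <- g$bonds$from[k]; b <- g$bonds$to[k]
    adj[[a]] <- c(adj[[a]], list(list(nb = b, bond = k)))
    adj[[b]] <- c(adj[[b]], list(list(nb = a, bond = k)))
  }
  for (v in seq_len(n)) {
    if (length(adj[[v]]) > 1L) {
      ord <- order(vapply(adj[[v]], function(e) ranks[e$nb], numeric(1)))
      adj[[v]] <- adj[[v]][ord]
    }
  }

  visited <- rep(FALSE, n)
  bond_used <- rep(FALSE, max(n_bonds(g), 1L))
  ring_bonds <- vector("list", n)   # per atom: list of (digit, bond)
  digit_free <- rep(TRUE, 99L)

  # First pass: find back edges (ring closures) via DFS.
  order_visit <- integer(0)
  stack <- list(list(v = which.min(ranks), parent_bond = NA_integer_))
  back_edges <- integer(0)
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- top$v
    if (visited[v]) next
    visited[v] <- TRUE
    order_visit <- c(order_visit, v)
    if (!is.na(top$parent_bond)) bond_used[top$parent_bond] <- TRUE
    es <- adj[[v]]
    for (e in rev(es)) {
      if (!visited[e$nb]) {
        stack[[length(stack) + 1L]] <- list(v = e$nb, parent_bond = e$bond)
      } else if (!bond_used[e$bond]) {
        bond_used[e$bond] <- TRUE
        back_edges <- c(back_edges, e$bond)
      }
    }
  }
  if (!all(visited)) stop("argument error: graph is not connected")

  # Assign ring-closure digits.
  rc_of_bond <- list()
  for (bk in back_edges) {
    d <- which(digit_free)[1L]
    digit_free[d] <- FALSE   # digits kept unique per molecule (simple, valid)
    rc_of_bond[[as.character(bk)]] <- d
    for (end in c(g$bonds$from[bk], g$bonds$to[bk])) {
      ring_bonds[[end]] <- c(ring_bonds[[end]],
                             list(list(digit = d, bond = bk)))
    }
  }

  # Second pass: recursive emission.
  visited2 <- rep(FALSE, n)
  emit_atom <- function(v) .atom_token(g, v)
  bond_sym <- function(bk, vfrom) {
    b <- g$bonds[bk, ]
    if (b$masked) {
      adj_star <- g$atoms$masked[b$from] || g$atoms$masked[b$to]
      return(if (adj_star) "" else "~")
    }
    switch(b$order,
      single = {
        both_arom <- g$atoms$aromatic[b$from] && g$atoms$aromatic[b$to]
        star_adj <- g$atoms$masked[b$from] || g$atoms$masked[b$to]
        if (both_arom || star_adj) "-" else ""
      },
      double = "=",
      triple = "#",
      aromatic = {
        star_adj <- g$atoms$masked[b$from] || g$atoms$masked[b$to]
        both_arom <- g$atoms$aromatic[b$from] && g$atoms$aromatic[b$to]
        if (star_adj || !both_arom) ":" else ""
      })
  }

  write_atom <- function(v, in_bond) {
    visited2[v] <<- TRUE
    out <- character(0)
    if (!is.na(in_bond)) out <- c(out, bond_sym(in_bond, v))
    out <- c(out, emit_atom(v))
    for (rb in ring_bonds[[v]]) {
      out <- c(out, bond_sym(rb$bond, v),
               if (rb$digit > 9L) paste0("%", sprintf("%02d", rb$digit))
               else as.character(rb$digit))
    }
    children <- Filter(function(e) !visited2[e$nb] && !(e$bond %in% back_edges),
                       adj[[v]])
    if (length(children) > 0L) {
      for (i in seq_along(children)) {
        e <- children[[i]]
        if (visited2[e$nb]) next
        piece <- write_atom(e$nb, e$bond)
        if (i < length(children)) piece <- c("(", piece, ")")
        out <- c(out, piece)
      }
    }
    out
  }

  root <- which.min(ranks)
  paste(write_atom(root, NA_integer_), collapse = "")
}

.atom_token <- function(g, v) {
  a <- g$atoms[v, ]
  if (a$masked || a$element == "*") return("*")
  sym <- a$element
  aromatic_ok <- a$aromatic && tolower(sym) %in% .aromatic_organic
  shown <- if (aromatic_ok) tolower(sym) else sym
  # Decide whether the bare organic-subset token reproduces the stored hcount.
  bare_ok <- sym %in% .organic_subset && a$charge == 0L && !is.na(a$hcount) &&
    (!a$aromatic || aromatic_ok)
  if (bare_ok) {
    bsum <- 0
    w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
    inc <- g$bonds$from == v | g$bonds$to == v
    if (any(inc)) {
      ords <- g$bonds$order[inc]
      ords[g$bonds$masked[inc]] <- "single"
      bsum <- sum(w[ords])
    }
    dv <- .default_valences[[sym]]
    if (a$aromatic) dv <- dv[1L]
    s <- ceiling(bsum)
    fit <- dv[dv >= s]
    implied <- if (length(fit) == 0L) 0L else as.integer(fit[1L] - s)
    if (implied == a$hcount) return(shown)
  }
  h <- if (is.na(a$hcount) || a$hcount == 0L) ""
    else if (a$hcount == 1L) "H" else paste0("H", a$hcount)
  chg <- if (a$charge == 0L) ""
    else if (a$charge == 1L) "+" else if (a$charge == -1L) "-"
    else sprintf("%+d", a$charge)
  paste0("[", shown, h, chg, "]")
}

# Canonical ranking -----------------------------------------------------------

# Morgan/Weisfeiler-Lehman style iterative refinement with deterministic orbit
# tie-breaking. Masked atoms sort first so fragment strings start at their
# attachment point. Returns a permutation-invariant rank per atom (1..n,
# all distinct) for automorphism-refinable graphs.
.canonical_ranks <- function(g) {
  n <- n_atoms(g)
  deg <- .degrees(g)
  key <- paste(ifelse(g$atoms$masked, 0L, 1L), g$atoms$element,
               g$atoms$charge, g$atoms$aromatic, g$atoms$hcount, deg,
               sep = "|")
  ranks <- match(key, sort(unique(key)))

  bclass <- ifelse(g$bonds$masked, "m", paste(g$bonds$order, g$bonds$stereo))
  nbrs <- vector("list", n)
  for (k in seq_len(n_bonds(g))) {
    a <- g$bonds$from[k]; b <- g$bonds$to[k]
    nbrs[[a]] <- c(nbrs[[a]], list(c(bclass[k], b)))
    nbrs[[b]] <- c(nbrs[[b]], list(c(bclass[k], a)))
  }

  refine <- function(ranks) {
    repeat {
      # zero-padded ranks keep lexicographic order equal to numeric order, so
      # class numbering is stable across iterations and the loop converges
      key2 <- vapply(seq_len(n), function(v) {
        ns <- vapply(nbrs[[v]], function(e)
          paste0(e[1], ":", sprintf("%05d", ranks[as.integer(e[2])])),
          character(1))
        paste(sprintf("%05d", ranks[v]), paste(sort(ns), collapse = ","),
              sep = "#")
      }, character(1))
      new_ranks <- match(key2, sort(unique(key2)))
      if (identical(new_ranks, ranks)) return(ranks)
      ranks <- new_ranks
    }
  }
  ranks <- refine(ranks)
  while (max(tabulate(ranks)) > 1L) {
    tab <- tabulate(ranks)
    r0 <- which(tab > 1L)[1L]
    v0 <- which(ranks == r0)[1L]
    # Promote one member of the first tied orbit, shift the rest up, re-refine.
    bump <- ranks >= r0 & seq_len(n) != v0
    ranks[bump] <- ranks[bump] + 1L
    ranks[v0] <- r0
    ranks <- match(ranks, sort(unique(ranks)))
    ranks <- refine(ranks)
  }
  ranks
}

# Graph identity up to isomorphism, via canonical SMILES.
.same_molecule <- function(g1, g2) {
  identical(to_canonical_smiles(g1), to_canonical_smiles(g2))
}
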