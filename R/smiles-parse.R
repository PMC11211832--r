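#' Parse a SMILES string into a molecular graph
#'
#' Builds the heavy-atom graph (hydrogens implicit) with chemical attributes
#' populated and no masking. Aromaticity is taken from the SMILES aromatic
#' (lowercase) notation; unspecified bonds between two aromatic atoms inside a
#' ring are resolved to aromatic bonds, all other unspecified bonds to single
#' bonds. Wildcard `*` atoms are parsed as masked linker nodes (attachment
#' points), as are their unspecified incident bonds.
#'
#' Implicit hydrogen counts are derived from the standard valence of each
#' organic-subset atom; bracket atoms use their explicit H count. A valence
#' check rejects impossible molecules (e.g. pentavalent carbon).
#'
#' @param smiles A single non-empty SMILES string.
#' @return A `molgraph` object.
#' @examples
#' g <- parse_smiles("CCO")
#' n_atoms(g)
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("parse error: 'smiles' must be a single non-empty string")
  }
  smiles <- trimws(smiles)
  toks <- .tokenize_smiles(smiles)

  atoms <- list()
  bonds <- list()
  prev_stack <- integer(0)   # branch stack
  prev <- NA_integer_
  pending_bond <- NULL       # bond symbol awaiting next atom
  ring_open <- list()        # ring-closure number -> list(atom, bond)

  add_bond <- function(a, b, sym) {
    if (a == b) stop("parse error in '", smiles, "': self bond")
    bonds[[length(bonds) + 1L]] <<- list(from = a, to = b, sym = sym)
  }

  for (tk in toks) {
    if (tk$type == "atom") {
      idx <- length(atoms) + 1L
      atoms[[idx]] <- tk$atom
      if (!is.na(prev)) {
        sym <- if (is.null(pending_bond)) "" else pending_bond
        add_bond(prev, idx, sym)
      }
      pending_bond <- NULL
      prev <- idx
    } else if (tk$type == "bond") {
      pending_bond <- tk$sym
    } else if (tk$type == "open") {
      prev_stack <- c(prev_stack, prev)
    } else if (tk$type == "close") {
      if (length(prev_stack) == 0L)
        stop("parse error in '", smiles, "': unbalanced ')'")
      prev <- prev_stack[length(prev_stack)]
      prev_stack <- prev_stack[-length(prev_stack)]
    } else if (tk$type == "ring") {
      key <- as.character(tk$num)
      if (is.na(prev)) stop("parse error in '", smiles, "': ring bond before atom")
      if (is.null(ring_open[[key]])) {
        ring_open[[key]] <- list(atom = prev,
                                 sym = if (is.null(pending_bond)) "" else pending_bond)
      } else {
        op <- ring_open[[key]]
        sym <- if (!is.null(pending_bond)) pending_bond else op$sym
        add_bond(op$atom, prev, sym)
        ring_open[[key]] <- NULL
      }
      pending_bond <- NULL
    } else if (tk$type == "dot") {
      prev <- NA_integer_
      pending_bond <- NULL
    }
  }
  if (length(prev_stack) > 0L)
    stop("parse error in '", smiles, "': unbalanced '('")
  open_rings <- names(ring_open)[!vapply(ring_open, is.null, logical(1))]
  if (length(open_rings) > 0L)
    stop("parse error in '", smiles, "': unclosed ring bond ", open_rings[1L])
  if (length(atoms) == 0L)
    stop("parse error in '", smiles, "': no atoms")

  at <- data.frame(
    element   = vapply(atoms, function(a) a$element, character(1)),
    charge    = vapply(atoms, function(a) a$charge, integer(1)),
    aromatic  = vapply(atoms, function(a) a$aromatic, logical(1)),
    chirality = vapply(atoms, function(a) a$chirality, character(1)),
    hcount    = vapply(atoms, function(a) a$hcount, integer(1)),
    masked    = vapply(atoms, function(a) a$masked, logical(1)),
    stringsAsFactors = FALSE
  )
  h_explicit <- vapply(atoms, function(a) a$h_explicit, logical(1))

  if (length(bonds) > 0L) {
    bd <- data.frame(
      from = vapply(bonds, function(b) min(b$from, b$to), integer(1)),
      to   = vapply(bonds, function(b) max(b$from, b$to), integer(1)),
      sym  = vapply(bonds, function(b) b$sym, character(1)),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(bd[, c("from", "to")]))
      stop("parse error in '", smiles, "': duplicate bond")
  } else {
    bd <- data.frame(from = integer(0), to = integer(0), sym = character(0),
                     stringsAsFactors = FALSE)
  }

  g <- .resolve_bonds(at, bd, h_explicit, smiles)
  sanitize_molgraph(g, context = smiles)
  g
}

# Tokenizer ------------------------------------------------------------------

.tokenize_smiles <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  push <- function(t) toks[[length(toks) + 1L]] <<- t
  two_char <- c("Cl", "Br")

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("parse error in '", s, "': unterminated '['")
      body <- substr(s, i + 1L, j - 1L)
      push(list(type = "atom", atom = .parse_bracket_atom(body, s)))
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% two_char) {
      push(list(type = "atom", atom = .plain_atom(paste0(ch, chars[i + 1L]), FALSE)))
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      push(list(type = "atom", atom = .plain_atom(ch, FALSE)))
      i <- i + 1L
    } else if (ch %in% .aromatic_organic) {
      push(list(type = "atom", atom = .plain_atom(toupper(ch), TRUE)))
      i <- i + 1L
    } else if (ch == "*") {
      push(list(type = "atom", atom = .star_atom()))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~", "/", "\\")) {
      push(list(type = "bond", sym = ch))
      i <- i + 1L
    } else if (ch == "(") {
      push(list(type = "open")); i <- i + 1L
    } else if (ch == ")") {
      push(list(type = "close")); i <- i + 1L
    } else if (grepl("^[0-9]$", ch)) {
      push(list(type = "ring", num = as.integer(ch))); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("parse error in '", s, "': bad '%' ring closure")
      push(list(type = "ring", num = as.integer(substr(s, i + 1L, i + 2L))))
      i <- i + 3L
    } else if (ch == ".") {
      push(list(type = "dot")); i <- i + 1L
    } else {
      stop("parse error in '", s, "': unexpected character '", ch, "'")
    }
  }
  toks
}

.plain_atom <- function(element, aromatic) {
  list(element = element, charge = 0L, aromatic = aromatic,
       chirality = "none", hcount = NA_integer_, h_explicit = FALSE,
       masked = FALSE)
}

.star_atom <- function() {
  list(element = "*", charge = 0L, aromatic = FALSE, chirality = "none",
       hcount = 0L, h_explicit = TRUE, masked = TRUE)
}

.parse_bracket_atom <- function(body, context) {
  rx <- "^([0-9]*)([A-Za-z][a-z]?|\\*)(@{1,2}|@TH[12])?(H[0-9]*)?([+-][0-9]*|\\+{2,}|-{2,})?(:[0-9]+)?$"
  m <- regmatches(body, regexec(rx, body))[[1]]
  if (length(m) == 0L)
    stop("parse error in '", context, "': bad bracket atom [", body, "]")
  sym <- m[3]
  if (sym == "*") {
    a <- .star_atom()
    return(a)
  }
  aromatic <- sym %in% .aromatic_organic || sym %in% c("se", "as")
  element <- if (aromatic) {
    paste0(toupper(substr(sym, 1, 1)), substr(sym, 2, nchar(sym)))
  } else sym
  chir <- m[4]
  chirality <- if (is.na(chir) || chir == "") "none"
    else if (chir == "@") "CCW" else if (chir == "@@") "CW" else "other"
  hpart <- m[5]
  hcount <- if (is.na(hpart) || hpart == "") 0L
    else if (hpart == "H") 1L else as.integer(substr(hpart, 2, nchar(hpart)))
  cpart <- m[6]
  charge <- 0L
  if (!is.na(cpart) && cpart != "") {
    if (grepl("^\\+\\+*$", cpart)) charge <- nchar(cpart)
    else if (grepl("^--*$", cpart)) charge <- -nchar(cpart)
    else charge <- as.integer(paste0(substr(cpart, 1, 1), "1")) *
        as.integer(substr(cpart, 2, nchar(cpart)))
  }
  list(element = element, charge = as.integer(charge), aromatic = aromatic,
       chirality = chirality, hcount = hcount, h_explicit = TRUE,
       masked = FALSE)
}

# Bond resolution and implicit hydrogens -------------------------------------

# Resolve unspecified bond symbols to concrete orders, derive implicit
# hydrogen counts, and assemble the molgraph object.
.resolve_bonds <- function(at, bd, h_explicit, smiles) {
  n <- nrow(at)
  order <- character(nrow(bd))
  stereo <- rep("none", nrow(bd))
  masked <- rep(FALSE, nrow(bd))
  in_ring <- .ring_bond_flags(n, bd)

  for (k in seq_len(nrow(bd))) {
    sym <- bd$sym[k]
    a <- bd$from[k]; b <- bd$to[k]
    if (sym == "" ) {
      if (at$masked[a] || at$masked[b]) {
        order[k] <- "single"; masked[k] <- TRUE
      } else if (at$aromatic[a] && at$aromatic[b] && in_ring[k]) {
        order[k] <- "aromatic"
      } else order[k] <- "single"
    } else if (sym == "-") order[k] <- "single"
    else if (sym == "=") order[k] <- "double"
    else if (sym == "#") order[k] <- "triple"
    else if (sym == ":") order[k] <- "aromatic"
    else if (sym == "~") { order[k] <- "single"; masked[k] <- TRUE }
    else if (sym %in% c("/", "\\")) { order[k] <- "single"; stereo[k] <- "any" }
  }

  bonds <- data.frame(from = bd$from, to = bd$to, order = order,
                      stereo = stereo, masked = masked,
                      stringsAsFactors = FALSE)

  # Implicit hydrogens for organic-subset atoms without explicit H.
  bsum <- .bond_order_sums(n, bonds)
  for (v in seq_len(n)) {
    if (h_explicit[v]) next
    dv <- .default_valences[[at$element[v]]]
    if (is.null(dv)) { at$hcount[v] <- 0L; next }
    # aromatic atoms never use hypervalent states for implicit hydrogens
    if (at$aromatic[v]) dv <- dv[1L]
    s <- ceiling(bsum[v])
    fit <- dv[dv >= s]
    at$hcount[v] <- if (length(fit) == 0L) 0L else as.integer(fit[1L] - s)
  }

  structure(
    list(atoms = at, bonds = bonds, source_smiles = smiles,
         fragment_ids = NULL),
    class = "molgraph"
  )
}

# Sum of bond orders per atom; aromatic counts 1.5.
.bond_order_sums <- function(n, bonds) {
  w <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  s <- numeric(n)
  if (nrow(bonds) > 0L) {
    ww <- unname(w[bonds$order])
    for (k in seq_len(nrow(bonds))) {
      s[bonds$from[k]] <- s[bonds$from[k]] + ww[k]
      s[bonds$to[k]] <- s[bonds$to[k]] + ww[k]
    }
  }
  s
}

# TRUE for bonds participating in a ring (non-bridge edges).
.ring_bond_flags <- function(n, bd) {
  if (nrow(bd) == 0L) return(logical(0))
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  ig <- igraph::add_edges(ig, rbind(bd$from, bd$to))
  br <- igraph::bridges(ig)
  flags <- rep(TRUE, nrow(bd))
  flags[as.integer(br)] <- FALSE
  flags
}
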