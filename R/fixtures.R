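#' Synthetic core + substituent molecule generator
#'
#' Generates drug-like test molecules with known ground-truth decompositions
#' by attaching sampled one-attachment-point substituents to sampled
#' substitutable positions of ring-system cores. Because the construction
#' record (core atoms, attachment positions, fragment SMILES) is emitted with
#' every molecule, every downstream stage -- decomposition, corpus building,
#' pretraining, retrieval -- can be tested without any external corpus. The
#' generator emulates the compositional structure of drug-like screening
#' molecules (one scaffold, a handful of small substituents); it does not
#' emulate their full size distribution, stereochemistry or charge states.
#'
#' @param count Number of molecules.
#' @param seed Integer seed; the same spec and seed always reproduce the same
#'   molecules.
#' @param cores Character vector of ring-system core SMILES.
#' @param substituents Character vector of fragment SMILES, each with exactly
#'   one `*` attachment point.
#' @param n_subs_range Integer `c(min, max)` number of substituents per
#'   molecule.
#' @param max_retries Resampling attempts per molecule before erroring.
#' @return A list of records: `smiles` (canonical), `graph` (the built
#'   `molgraph`), `core_atoms` (ground-truth construction core indices into
#'   `graph`), `rgroups` (data.frame with `fragment_smiles` and
#'   `linker_node`).
#' @examples
#' fx <- generate_fixtures(count = 3, seed = 7)
#' fx[[1]]$smiles
#' @export
generate_fixtures <- function(count = 100L, seed = 7L,
                              cores = default_fixture_cores(),
                              substituents = default_fixture_substituents(),
                              n_subs_range = c(1L, 3L),
                              max_retries = 20L) {
  stopifnot(count >= 1L, n_subs_range[1] >= 1L,
            n_subs_range[2] >= n_subs_range[1])
  bad <- substituents[vapply(substituents, function(s)
    lengths(regmatches(s, gregexpr("*", s, fixed = TRUE))) != 1L, logical(1))]
  if (length(bad) > 0L)
    stop("argument error: substituents must have exactly one '*': ",
         paste(bad, collapse = ", "))

  core_graphs <- lapply(cores, parse_smiles)
  sub_graphs <- lapply(substituents, parse_smiles)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  out <- vector("list", count)
  for (i in seq_len(count)) {
    rec <- NULL
    for (try in seq_len(max_retries)) {
      ci <- sample.int(length(cores), 1L)
      core <- core_graphs[[ci]]
      open_pos <- which(core$atoms$hcount >= 1L &
                          core$atoms$element %in% c("C", "N"))
      ks <- seq(n_subs_range[1], n_subs_range[2])
      k <- ks[sample.int(length(ks), 1L)]
      if (length(open_pos) < k) next
      pos <- sort(sample(open_pos, k))
      si <- sample.int(length(substituents), k, replace = TRUE)
      built <- tryCatch(
        .assemble_fixture(core, pos, sub_graphs[si], substituents[si]),
        error = function(e) NULL)
      if (!is.null(built)) { rec <- built; break }
    }
    if (is.null(rec))
      stop("fixture generation failed after ", max_retries,
           " retries (unsatisfiable valence)")
    out[[i]] <- rec
  }
  out
}

#' Default fixture building blocks
#'
#' Cores span single aromatic rings, an aromatic heterocycle, a saturated
#' heterocycle, a fused system and a two-ring-system assembly; substituents
#' span acyclic and ring-like R-groups and exercise the functional-group
#' catalog (hydroxyl, amine, halogens, carboxyl, amide, ether, CF3, phenyl).
#'
#' @return Character vector of SMILES.
#' @export
default_fixture_cores <- function() {
  c("c1ccccc1",            # benzene
    "c1ccncc1",            # pyridine
    "C1CCNCC1",            # piperidine
    "c1ccc2[nH]ccc2c1",    # indole
    "c1ccc(-c2ccccc2)cc1") # biphenyl
}

#' @rdname default_fixture_cores
#' @export
default_fixture_substituents <- function() {
  c("*C", "*O", "*N", "*F", "*Cl",
    "*C(=O)O", "*C(=O)N", "*OC", "*C(F)(F)F", "*c1ccccc1")
}

# Attach substituent graphs (each with masked * as atom to drop) to core
# positions by single bonds; returns the construction record.
.assemble_fixture <- function(core, positions, subs, sub_smiles) {
  g <- core
  core_n <- n_atoms(core)
  rg_linker <- integer(length(positions))
  for (i in seq_along(positions)) {
    frag <- subs[[i]]
    star <- which(frag$atoms$masked | frag$atoms$element == "*")
    if (length(star) != 1L) stop("argument error: substituent needs one '*'")
    anchor <- c(frag$bonds$from[frag$bonds$from == star | frag$bonds$to == star],
                frag$bonds$to[frag$bonds$from == star | frag$bonds$to == star])
    anchor <- setdiff(unique(anchor), star)[1L]
    keep <- setdiff(seq_len(n_atoms(frag)), star)
    fmap <- integer(n_atoms(frag))
    fmap[keep] <- n_atoms(g) + seq_along(keep)
    at <- frag$atoms[keep, , drop = FALSE]
    fb <- frag$bonds[!(frag$bonds$from == star | frag$bonds$to == star), ,
                     drop = FALSE]
    if (nrow(fb) > 0L) {
      fb$from <- fmap[fb$from]; fb$to <- fmap[fb$to]
    } else fb <- .empty_bonds()
    pos <- positions[i]
    newb <- data.frame(from = pos, to = fmap[anchor], order = "single",
                       stereo = "none", masked = FALSE,
                       stringsAsFactors = FALSE)
    at2 <- rbind(g$atoms, at)
    at2$hcount[pos] <- at2$hcount[pos] - 1L
    if (at2$hcount[pos] < 0L) stop("valence exhausted at position ", pos)
    g <- .new_molgraph(at2, rbind(g$bonds, fb, newb))
    rg_linker[i] <- pos
  }
  sanitize_molgraph(g)
  smi <- to_canonical_smiles(g)
  list(smiles = smi, graph = g,
       core_atoms = seq_len(core_n),
       rgroups = data.frame(fragment_smiles = vapply(seq_along(subs),
                              function(i) .ob_canonical(sub_smiles[i]),
                              character(1)),
                            linker_node = rg_linker,
                            stringsAsFactors = FALSE))
}
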