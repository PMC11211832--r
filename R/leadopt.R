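#' Lead optimization by R-group retrieval and re-attachment
#'
#' Decomposes a reference molecule at a chosen R-group site, retrieves
#' candidate replacement fragments from an embedding library, re-attaches
#' each candidate with the default attribute fill, keeps the chemically valid
#' products and scores drug-likeness (QED, higher is better) and synthetic
#' accessibility (SAscore, lower is easier). A product counts as "improved"
#' when its QED is strictly higher AND its SAscore strictly lower than the
#' reference (the conjunctive reading).
#'
#' @name leadopt
NULL

#' Score molecules with QED and SAscore
#'
#' Batch bridge to the published QED and synthetic-accessibility
#' implementations of the installed RDKit toolkit (invoked through
#' `python`); one subprocess scores the whole batch.
#'
#' @param smiles Character vector of molecule SMILES.
#' @param python Python executable (default `"python"` on the PATH).
#' @return Data.frame with columns `smiles`, `qed`, `sascore` (NA where the
#'   toolkit cannot parse a product).
#' @export
chem_scores <- function(smiles, python = "python") {
  script <- system.file("python", "chem_scores.py", package = "molrgr")
  if (!nzchar(script)) stop("configuration error: scoring script not found")
  out <- suppressWarnings(
    system2(python, shQuote(script), input = smiles, stdout = TRUE,
            stderr = FALSE))
  if (length(out) == 0L)
    stop("scoring error: python scoring bridge produced no output")
  parts <- strsplit(out, "\t", fixed = TRUE)
  df <- data.frame(smiles = vapply(parts, `[`, "", 1L),
                   qed = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L))),
                   sascore = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3L))),
                   stringsAsFactors = FALSE)
  df[match(smiles, df$smiles), , drop = FALSE]
}

#' Run the lead-optimization pipeline at one R-group site
#'
#' @param reference A `molgraph` (or SMILES) of the reference molecule.
#' @param site_rgroup_smiles Canonical fragment SMILES identifying which
#'   R-group of which enumerated core to replace (the first core carrying a
#'   matching R-group is used).
#' @param library An `rgroup_library`.
#' @param checkpoint The pretraining checkpoint behind the library.
#' @param condition Optional condition vector for the query (defaults to the
#'   condition vector of the replaced fragment).
#' @param K Number of candidates to retrieve (default 1000).
#' @param python Python executable for scoring.
#' @return A `leadopt_report`: reference scores, candidate table
#'   (`product_smiles`, `qed`, `sascore`, `rank`, `valid`),
#'   `proportion_valid` and `proportion_improved` (among valid products).
#' @export
optimize <- function(reference, site_rgroup_smiles, library, checkpoint,
                     condition = NULL, K = 1000L, python = "python") {
  model <- .as_model(checkpoint)
  if (is.character(reference)) reference <- parse_smiles(reference)
  found <- NULL
  for (core in enumerate_putative_cores(reference)) {
    rgs <- identify_rgroups(reference, core)
    for (i in seq_along(rgs)) {
      fs <- to_canonical_smiles(.build_fragment(reference, rgs[[i]]))
      if (identical(fs, site_rgroup_smiles)) { found <- list(core = core, rg = rgs[[i]]); break }
    }
    if (!is.null(found)) break
  }
  if (is.null(found))
    stop("argument error: no enumerated core carries the R-group ",
         site_rgroup_smiles)
  decomp <- decouple_subset(reference, found$core, list(found$rg))
  if (is.null(condition)) {
    condition <- as.vector(condition_vector(site_rgroup_smiles))
  }
  site <- decomp$site_pairs[[1]][["query"]]
  res <- retrieve(decomp$query_template, site, condition, library, model,
                  K = K)

  products <- character(nrow(res$ranked))
  valid <- logical(nrow(res$ranked))
  for (i in seq_len(nrow(res$ranked))) {
    frag <- tryCatch(parse_smiles(res$ranked$fragment_smiles[i]),
                     error = function(e) NULL)
    if (is.null(frag)) { valid[i] <- FALSE; next }
    star <- which(frag$atoms$masked)
    if (length(star) != 1L) { valid[i] <- FALSE; next }
    prod <- reattach(decomp$query_template, frag, c(site, star),
                     fill = "default")
    if (inherits(prod, "invalid_product")) { valid[i] <- FALSE; next }
    ps <- tryCatch(to_canonical_smiles(prod), error = function(e) NULL)
    if (is.null(ps)) { valid[i] <- FALSE; next }
    products[i] <- ps
    valid[i] <- TRUE
  }

  ref_smiles <- to_canonical_smiles(reference)
  sc <- chem_scores(c(ref_smiles, products[valid]), python = python)
  ref_sc <- sc[1L, ]
  cand <- data.frame(product_smiles = products,
                     qed = NA_real_, sascore = NA_real_,
                     rank = res$ranked$rank, valid = valid,
                     stringsAsFactors = FALSE)
  if (any(valid)) {
    m <- match(products[valid], sc$smiles)
    cand$qed[valid] <- sc$qed[m]
    cand$sascore[valid] <- sc$sascore[m]
  }
  # products the scoring toolkit rejects are not valid molecules either
  cand$valid <- cand$valid & !is.na(cand$qed) & !is.na(cand$sascore)
  improved <- cand$valid & cand$qed > ref_sc$qed & cand$sascore < ref_sc$sascore
  structure(list(reference_smiles = ref_smiles,
                 reference_qed = ref_sc$qed,
                 reference_sascore = ref_sc$sascore,
                 site_rgroup_smiles = site_rgroup_smiles,
                 candidates_requested = K,
                 candidates = cand,
                 proportion_valid = mean(cand$valid),
                 proportion_improved = if (any(cand$valid))
                   sum(improved) / sum(cand$valid) else 0),
            class = "leadopt_report")
}

#' @export
print.leadopt_report <- function(x, ...) {
  cat(sprintf("<leadopt_report> %s (QED %.3f, SA %.2f), replacing %s\n",
              x$reference_smiles, x$reference_qed, x$reference_sascore,
              x$site_rgroup_smiles))
  cat(sprintf("  %d candidates: %.1f%% valid, %.1f%% improved (QED up & SA down)\n",
              nrow(x$candidates), 100 * x$proportion_valid,
              100 * x$proportion_improved))
  invisible(x)
}

#' Color molecule atoms by the first principal component of their embeddings
#'
#' Extracts node representations from the pretrained encoder, projects them
#' onto the first principal component, and min-max normalizes to [0, 1].
#' The sign is fixed by making the highest-degree atom's centered score
#' non-negative (ties broken by atom index), so the coloring is deterministic
#' and invariant to atom input ordering. Molecules whose atoms all embed
#' identically (or a single atom) get the constant 0.5.
#'
#' @param molecule A `molgraph` or SMILES.
#' @param checkpoint An `rgr_checkpoint` or `rgr_model`.
#' @return Numeric vector in [0, 1], one value per atom.
#' @export
color_nodes_by_pca <- function(molecule, checkpoint) {
  model <- .as_model(checkpoint)
  if (is.character(molecule)) molecule <- parse_smiles(molecule)
  H <- encode(molecule, model)
  if (nrow(H) == 1L) return(0.5)
  s <- as.vector(stats::prcomp(H, center = TRUE, scale. = FALSE)$x[, 1L])
  if (max(abs(s)) < 1e-12) return(rep(0.5, nrow(H)))
  deg <- .degrees(molecule)
  anchor <- which.max(deg)
  if (s[anchor] < 0) s <- -s
  (s - min(s)) / (max(s) - min(s))
}
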