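#' R-group embedding library and conditioned retrieval
#'
#' The library holds one embedding per unique R-group fragment, computed by
#' the pretrained encoder and the R-group projection head. A conditioned
#' query -- the projection of a masked query linker node concatenated with a
#' functional-group condition vector -- is answered by exhaustive
#' inner-product search over the library (the library sizes handled here do
#' not need an approximate index; ranking is exact).
#'
#' @name retrieval
NULL

#' Build an R-group embedding library
#'
#' Fragments are deduplicated by canonical SMILES, parsed (the `*` atom
#' becomes the masked linker copy), encoded in deterministic order and
#' projected by the R-group head. Fragments that fail to parse are skipped
#' with a warning and listed in the `skipped` field.
#'
#' @param records An `rgroup_records` data.frame (or a character vector of
#'   fragment SMILES; occurrence counts then default to 1).
#' @param checkpoint An `rgr_checkpoint` or `rgr_model`.
#' @return An `rgroup_library`: `smiles`, `counts`, `condition` matrix,
#'   `embeddings` (N x d), `skipped`, and provenance.
#' @export
build_library <- function(records, checkpoint) {
  model <- .as_model(checkpoint)
  if (is.character(records)) {
    records <- data.frame(fragment_smiles = records, occurrence_count = 1L,
                          stringsAsFactors = FALSE)
  }
  dup <- duplicated(records$fragment_smiles)
  records <- records[!dup, , drop = FALSE]
  cond <- attr(records, "condition")
  if (!is.null(cond)) cond <- cond[!dup, , drop = FALSE]
  ord <- order(records$fragment_smiles)
  records <- records[ord, , drop = FALSE]
  if (!is.null(cond)) cond <- cond[ord, , drop = FALSE]

  smiles <- records$fragment_smiles
  emb <- matrix(NA_real_, length(smiles), model$config$hidden_dim)
  skipped <- character(0)
  for (i in seq_along(smiles)) {
    g <- tryCatch(parse_smiles(smiles[i]), error = function(e) NULL)
    if (is.null(g)) {
      warning("skipping unparsable fragment: ", smiles[i])
      skipped <- c(skipped, smiles[i])
      next
    }
    H <- encode(g, model)
    emb[i, ] <- project_rgroup(H, model)
  }
  keep <- !is.na(emb[, 1L])
  if (is.null(cond)) cond <- condition_vector(smiles[keep])
  else cond <- cond[keep, , drop = FALSE]
  structure(list(smiles = smiles[keep],
                 counts = records$occurrence_count[keep],
                 condition = cond,
                 embeddings = emb[keep, , drop = FALSE],
                 skipped = skipped,
                 catalog_checksum = model$catalog_checksum),
            class = "rgroup_library")
}

#' @export
print.rgroup_library <- function(x, ...) {
  cat(sprintf("<rgroup_library> %d fragments, d = %d\n",
              length(x$smiles), ncol(x$embeddings)))
  invisible(x)
}

#' Retrieve candidate R-groups for a masked query linker site
#'
#' Encodes the query template, projects the masked linker node concatenated
#' with the condition vector into the co-embedding space, and ranks the
#' library by raw inner product (descending; ties broken by library id for a
#' stable ranking).
#'
#' @param query_template A `molgraph` with at least one masked linker node.
#' @param site Node index of the masked linker to query.
#' @param condition 0/1 condition vector of length F (all-zero and all-one
#'   are valid ablation inputs).
#' @param library An `rgroup_library`.
#' @param checkpoint The checkpoint used to build the library.
#' @param K Number of candidates (default 1000); capped at the library size.
#' @return A `retrieval_result`: `ranked` data.frame (`rank`, `rgroup_id`,
#'   `fragment_smiles`, `score`) plus the query metadata.
#' @export
retrieve <- function(query_template, site, condition, library, checkpoint,
                     K = 1000L) {
  model <- .as_model(checkpoint)
  site <- as.integer(site)
  if (K < 1L) stop("argument error: K must be >= 1")
  if (site < 1L || site > n_atoms(query_template) ||
      !query_template$atoms$masked[site])
    stop("argument error: site ", site, " is not a masked linker node")
  H <- encode(query_template, model)
  z_C <- project_query(H[site, ], condition, model)
  scores <- as.vector(library$embeddings %*% z_C)
  ord <- order(-scores, seq_along(scores))
  k <- min(K, length(scores))
  sel <- ord[seq_len(k)]
  structure(list(ranked = data.frame(rank = seq_len(k), rgroup_id = sel,
                                     fragment_smiles = library$smiles[sel],
                                     score = scores[sel],
                                     stringsAsFactors = FALSE),
                 site = site, K = K, condition = condition),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> site %d, top %d of %d requested\n",
              x$site, nrow(x$ranked), x$K))
  print(utils::head(x$ranked, 5L))
  invisible(x)
}

#' Evaluate ranked retrievals with MRR and recall at K
#'
#' MRR uses the best (lowest) rank of any ground-truth fragment per query;
#' R\\@K is the fraction of queries with at least one ground truth ranked at
#' or above K. Ground truths absent from a ranked list contribute reciprocal
#' rank 0 and miss every recall cutoff.
#'
#' @param results List of `retrieval_result`s (or plain data.frames with a
#'   `fragment_smiles` column in rank order).
#' @param truths List (one per query) of ground-truth fragment SMILES.
#' @param K_list Recall cutoffs (default 5, 10, 50, 100).
#' @return Named numeric vector: `MRR` and one `R@K` entry per cutoff.
#' @export
evaluate_retrieval <- function(results, truths, K_list = c(5L, 10L, 50L, 100L)) {
  stopifnot(length(results) == length(truths))
  if (any(lengths(truths) == 0L))
    stop("argument error: every query needs at least one ground truth")
  best_rank <- vapply(seq_along(results), function(i) {
    r <- results[[i]]
    ranked <- if (inherits(r, "retrieval_result")) r$ranked else r
    hits <- which(ranked$fragment_smiles %in% truths[[i]])
    if (length(hits) == 0L) Inf else min(ranked$rank[hits])
  }, numeric(1))
  out <- c(MRR = mean(ifelse(is.finite(best_rank), 1 / best_rank, 0)))
  for (K in K_list) out[[paste0("R@", K)]] <- mean(best_rank <= K)
  out
}

#' Naive retrieval baselines
#'
#' `random` draws a seeded uniform sample of library fragments without
#' replacement, independently per query; `popularity` gives every query the
#' identical list of the most frequent fragments (occurrence-count
#' descending, ties broken by canonical SMILES).
#'
#' @param kind `"random"` or `"popularity"`.
#' @param library An `rgroup_library` (with `counts` for popularity).
#' @param n_queries Number of queries to produce rankings for.
#' @param K Ranking depth.
#' @param seed Seed for the random baseline.
#' @return List of `n_queries` data.frames in [evaluate_retrieval()] format.
#' @export
baseline_rankings <- function(kind = c("random", "popularity"), library,
                              n_queries, K = 1000L, seed = 1L) {
  kind <- match.arg(kind)
  N <- length(library$smiles)
  k <- min(K, N)
  if (kind == "popularity") {
    ord <- order(-library$counts, library$smiles)[seq_len(k)]
    one <- data.frame(rank = seq_len(k), rgroup_id = ord,
                      fragment_smiles = library$smiles[ord],
                      score = as.numeric(library$counts[ord]),
                      stringsAsFactors = FALSE)
    return(replicate(n_queries, one, simplify = FALSE))
  }
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lapply(seq_len(n_queries), function(i) {
    sel <- sample.int(N, k)
    data.frame(rank = seq_len(k), rgroup_id = sel,
               fragment_smiles = library$smiles[sel], score = 0,
               stringsAsFactors = FALSE)
  })
}
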