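#' Pretraining corpus construction
#'
#' Builds the pretraining dataset from a set of molecules: every decomposition
#' of every surviving (molecule, core) pair becomes one corpus instance.
#' Molecules with more putative cores than the cap are dropped entirely.
#' R-group fragments are deduplicated by canonical SMILES into records
#' carrying occurrence counts and functional-group condition vectors; records
#' above the commonness percentile are flagged and instances dominated by
#' common R-groups are removed.
#'
#' @name corpus
NULL

#' Load the functional-group SMARTS catalog
#'
#' The shipped catalog defines the `F = 87` bit positions of every R-group
#' condition vector; each row is a named SMARTS pattern. The md5 checksum of
#' the catalog file is recorded in corpora and model checkpoints so that
#' embeddings and condition vectors are never mixed across catalog versions.
#'
#' @param path Path to a tab-separated catalog (columns `name`, `smarts`).
#'   Defaults to the catalog shipped with the package.
#' @return A data.frame with class `fg_catalog` and attributes `checksum` and
#'   `F` (number of bits).
#' @export
load_fg_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_groups.tsv", package = "molrgr")
  }
  if (!nzchar(path) || !file.exists(path))
    stop("configuration error: functional-group catalog not found")
  cat0 <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "smarts") %in% names(cat0)) || nrow(cat0) == 0L)
    stop("configuration error: catalog must have columns name, smarts")
  structure(cat0, class = c("fg_catalog", "data.frame"),
            checksum = unname(tools::md5sum(path)), F = nrow(cat0))
}

#' Compute the functional-group condition vector of an R-group fragment
#'
#' Bit `f` is 1 iff SMARTS pattern `f` of the catalog matches the fragment.
#' Matching is performed on the `*`-bearing fragment SMILES; the wildcard
#' attachment atom occupies a connection slot but can never itself match an
#' element-specific pattern atom, so the vector depends only on the fragment's
#' own chemistry and is invariant to SMILES atom ordering.
#'
#' @param fragment_smiles Character vector of fragment SMILES (each with one
#'   `*` attachment point).
#' @param catalog An `fg_catalog`; its length defines the configured F.
#' @return A 0/1 integer matrix with one row per fragment and F columns.
#' @export
condition_vector <- function(fragment_smiles, catalog = load_fg_catalog()) {
  if (!inherits(catalog, "fg_catalog") || nrow(catalog) == 0L)
    stop("configuration error: empty or invalid functional-group catalog")
  frag <- vapply(fragment_smiles, function(s) {
    g <- parse_smiles(s)   # validates the fragment
    s
  }, character(1))
  blob <- paste(frag, collapse = "\n")
  bits <- matrix(0L, length(frag), nrow(catalog),
                 dimnames = list(NULL, catalog$name))
  for (j in seq_len(nrow(catalog))) {
    counts <- ChemmineOB::forEachMol("SMILES", blob, function(mol)
      ChemmineOB::smartsSearch_OB(list(m = mol), catalog$smarts[j],
                                  uniqueMatches = TRUE))
    bits[, j] <- as.integer(unlist(counts) > 0)
  }
  bits
}

#' Build pretraining instances from molecules
#'
#' Enumerates putative cores per molecule, drops molecules whose unique core
#' count exceeds `max_cores`, and emits every masked decomposition of every
#' surviving (molecule, core) pair. Acyclic molecules and cores without
#' R-groups contribute nothing.
#'
#' @param molecules List of `molgraph` objects (or character SMILES).
#' @param max_cores Core-count cap (default 10); molecules exceeding it are
#'   excluded entirely.
#' @return A list of `corpus_instance` objects, each with `mol_id`,
#'   `molecule_smiles`, `core`, `decomposition`, `rgroup_smiles` and `split`
#'   (unset until [split_and_serialize()]).
#' @export
build_instances <- function(molecules, max_cores = 10L) {
  stopifnot(max_cores >= 1L)
  if (is.character(molecules)) molecules <- lapply(molecules, parse_smiles)
  out <- list()
  for (i in seq_along(molecules)) {
    m <- molecules[[i]]
    cores <- enumerate_putative_cores(m, max_cores = max_cores)
    if (attr(cores, "total_cores") > max_cores) next
    msmi <- to_canonical_smiles(m)
    for (core in cores) {
      decomps <- enumerate_decompositions(m, core)
      for (d in decomps) {
        out[[length(out) + 1L]] <- structure(
          list(mol_id = i, molecule_smiles = msmi, core = core,
               decomposition = d, rgroup_smiles = d$rgroup_smiles,
               split = NA_character_),
          class = "corpus_instance")
      }
    }
  }
  out
}

#' Collect deduplicated R-group records with occurrence counts
#'
#' @param instances List of `corpus_instance`s.
#' @param catalog An `fg_catalog` used for condition vectors.
#' @return A data.frame (class `rgroup_records`) with columns
#'   `fragment_smiles`, `occurrence_count`, `is_common` (initially `FALSE`)
#'   and a `condition` matrix attribute (one row per record).
#' @export
collect_rgroup_records <- function(instances, catalog = load_fg_catalog()) {
  if (length(instances) == 0L) stop("argument error: no instances")
  all_smiles <- unlist(lapply(instances, function(x) x$rgroup_smiles))
  tab <- table(all_smiles)
  rec <- data.frame(fragment_smiles = names(tab),
                    occurrence_count = as.integer(tab),
                    is_common = FALSE, stringsAsFactors = FALSE)
  rec <- rec[order(rec$fragment_smiles), , drop = FALSE]
  rownames(rec) <- NULL
  cond <- condition_vector(rec$fragment_smiles, catalog)
  structure(rec, class = c("rgroup_records", "data.frame"),
            condition = cond, catalog_checksum = attr(catalog, "checksum"))
}

#' Flag common R-groups above an occurrence percentile
#'
#' `is_common` is set iff a record's occurrence count strictly exceeds the
#' empirical percentile (linear interpolation) of the deduplicated counts.
#' At the default 99.99th percentile this isolates the heavy right tail of
#' the skewed occurrence distribution (hydroxyl-like fragments).
#'
#' @param records An `rgroup_records` data.frame.
#' @param percentile Percentile in (0, 100); default 99.99.
#' @return The records with `is_common` updated; the threshold is stored in
#'   the `"threshold"` attribute.
#' @export
tag_common_rgroups <- function(records, percentile = 99.99) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("argument error: empty record list")
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 100)
    stop("argument error: percentile must be in (0, 100)")
  thr <- unname(stats::quantile(records$occurrence_count, percentile / 100,
                                type = 7))
  records$is_common <- records$occurrence_count > thr
  attr(records, "threshold") <- thr
  attr(records, "percentile") <- percentile
  records
}

#' Remove instances dominated by common R-groups
#'
#' An instance is removed iff strictly more than half of its decoupled masked
#' R-groups are common ones; an instance with exactly half common fragments
#' is kept.
#'
#' @param instances List of `corpus_instance`s.
#' @param records An `rgroup_records` with `is_common` tagged.
#' @return The filtered instance list.
#' @export
filter_instances <- function(instances, records) {
  common <- records$fragment_smiles[records$is_common]
  keep <- vapply(instances, function(x) {
    k <- length(x$rgroup_smiles)
    if (k == 0L) return(TRUE)
    sum(x$rgroup_smiles %in% common) / k <= 0.5
  }, logical(1))
  instances[keep]
}

#' Build a full pretraining corpus from molecules
#'
#' Runs [build_instances()], [collect_rgroup_records()],
#' [tag_common_rgroups()] and [filter_instances()], then assigns seeded
#' molecule-level train/valid/test splits (all instances of one molecule
#' share a split, preventing leakage between splits).
#'
#' @param molecules List of `molgraph`s or SMILES.
#' @param max_cores Core-count cap (default 10).
#' @param common_percentile Commonness percentile (default 99.99).
#' @param ratios Train/valid/test ratios summing to 1 (default 0.8/0.1/0.1).
#' @param seed Integer seed for the split shuffle.
#' @param catalog Functional-group catalog.
#' @return An `rgr_corpus`: list with `instances`, `records` and `manifest`.
#' @export
build_corpus <- function(molecules, max_cores = 10L, common_percentile = 99.99,
                         ratios = c(0.8, 0.1, 0.1), seed = 7L,
                         catalog = load_fg_catalog()) {
  instances <- build_instances(molecules, max_cores = max_cores)
  if (length(instances) == 0L)
    stop("configuration error: no corpus instances (no decomposable molecules)")
  records <- collect_rgroup_records(instances, catalog)
  records <- tag_common_rgroups(records, common_percentile)
  instances <- filter_instances(instances, records)
  instances <- .assign_splits(instances, ratios, seed)
  manifest <- list(
    n_molecules = length(unique(vapply(instances, function(x) x$mol_id,
                                       integer(1)))),
    n_instances = length(instances),
    n_rgroups = nrow(records),
    max_cores = max_cores,
    common_percentile = common_percentile,
    ratios = ratios, seed = seed,
    catalog_checksum = attr(catalog, "checksum"),
    F = attr(catalog, "F")
  )
  structure(list(instances = instances, records = records,
                 manifest = manifest), class = "rgr_corpus")
}

#' @export
print.rgr_corpus <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<rgr_corpus> %d instances / %d molecules / %d unique R-groups (F = %d)\n",
              m$n_instances, m$n_molecules, m$n_rgroups, m$F))
  spl <- table(vapply(x$instances, function(i) i$split, character(1)))
  cat("  splits:", paste(names(spl), spl, sep = "=", collapse = " "), "\n")
  invisible(x)
}

.assign_splits <- function(instances, ratios, seed) {
  if (abs(sum(ratios) - 1) > 1e-8)
    stop("argument error: split ratios must sum to 1")
  mol_ids <- sort(unique(vapply(instances, function(x) x$mol_id, integer(1))))
  nm <- length(mol_ids)
  # seeded shuffle without disturbing the caller's RNG state
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  shuffled <- sample(mol_ids)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  n_train <- round(ratios[1] * nm)
  n_valid <- round(ratios[2] * nm)
  n_valid <- min(n_valid, nm - n_train)
  split_of <- stats::setNames(rep("test", nm), shuffled)
  if (n_train > 0L) split_of[as.character(shuffled[seq_len(n_train)])] <- "train"
  if (n_valid > 0L) split_of[as.character(shuffled[n_train + seq_len(n_valid)])] <- "valid"
  for (i in seq_along(instances)) {
    instances[[i]]$split <- unname(split_of[as.character(instances[[i]]$mol_id)])
  }
  instances
}

#' Serialize a corpus to disk and read it back
#'
#' Writes `instances.jsonl` (one JSON record per instance: canonical molecule
#' SMILES, core atom indices in canonical parse order, core/query SMILES,
#' subset id, decoupled fragment SMILES, split), `rgroups.tsv` (fragment
#' SMILES, count, commonness flag, condition bits as a 0/1 string) and
#' `manifest.json`. Serialization is deterministic: the same corpus always
#' produces byte-identical files, and [read_corpus()] reconstructs the
#' decompositions by re-decomposing each molecule at its recorded core and
#' subset, so `serialize(read(serialize(x)))` is byte-identical too.
#'
#' @param corpus An `rgr_corpus`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
serialize_corpus <- function(corpus, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "instances.jsonl"), "w")
  on.exit(close(con), add = TRUE)
  for (x in corpus$instances) {
    # Record core atoms and decoupled linker atoms in the canonical parse
    # order of molecule_smiles so reconstruction is representation-independent.
    g <- x$decomposition$molecule
    canon_mol <- parse_smiles(x$molecule_smiles)
    rg_ranks <- .canonical_ranks(g)
    rc_ranks <- .canonical_ranks(canon_mol)
    to_canon <- function(nodes) match(rg_ranks[nodes], rc_ranks)
    core_atoms <- sort(to_canon(x$core$node_indices))
    decoupled <- lapply(seq_along(x$decomposition$rgroups), function(i) {
      list(linker = to_canon(x$decomposition$rgroups[[i]]$linker_node),
           fragment_smiles = x$rgroup_smiles[i])
    })
    ord <- order(vapply(decoupled, function(d) d$linker, integer(1)),
                 vapply(decoupled, function(d) d$fragment_smiles, character(1)))
    decoupled <- decoupled[ord]
    rec <- list(molecule_smiles = x$molecule_smiles,
                core_atoms = core_atoms,
                core_smiles = x$core$smiles,
                query_smiles = to_canonical_smiles(x$decomposition$query_template),
                decoupled = decoupled,
                split = x$split)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  rec <- corpus$records
  cond <- attr(rec, "condition")
  tsv <- data.frame(fragment_smiles = rec$fragment_smiles,
                    occurrence_count = rec$occurrence_count,
                    is_common = as.integer(rec$is_common),
                    condition_bits = apply(cond, 1, paste, collapse = ""),
                    stringsAsFactors = FALSE)
  utils::write.table(tsv, file.path(out_dir, "rgroups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(jsonlite::toJSON(corpus$manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' @rdname serialize_corpus
#' @param dir Directory previously written by [serialize_corpus()].
#' @param catalog Functional-group catalog (must match the manifest checksum).
#' @export
read_corpus <- function(dir, catalog = load_fg_catalog()) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  if (!identical(unname(manifest$catalog_checksum),
                 unname(attr(catalog, "checksum"))))
    stop("configuration error: catalog checksum mismatch")
  lines <- readLines(file.path(dir, "instances.jsonl"))
  mol_cache <- new.env(parent = emptyenv())
  instances <- vector("list", length(lines))
  mol_ids <- new.env(parent = emptyenv())
  next_id <- 0L
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i])
    key <- rec$molecule_smiles
    if (!exists(key, mol_ids, inherits = FALSE)) {
      next_id <- next_id + 1L
      assign(key, next_id, mol_ids)
      assign(key, parse_smiles(key), mol_cache)
    }
    m <- get(key, mol_cache)
    core <- structure(list(node_indices = sort(as.integer(rec$core_atoms)),
                           core_id = NA_integer_, smiles = rec$core_smiles),
                      class = "putative_core")
    rgs <- identify_rgroups(m, core)
    dec <- rec$decoupled
    if (is.data.frame(dec)) {
      dec <- lapply(seq_len(nrow(dec)), function(r) as.list(dec[r, ]))
    }
    rg_linkers <- vapply(rgs, function(r) r$linker_node, integer(1))
    rg_frag_smiles <- vapply(rgs, function(r)
      to_canonical_smiles(.build_fragment(m, r)), character(1))
    sel <- integer(0)
    for (item in dec) {
      cand <- setdiff(which(rg_linkers == as.integer(item$linker) &
                              rg_frag_smiles == item$fragment_smiles), sel)
      if (length(cand) == 0L)
        stop("internal error: decoupled R-group not found on reload")
      sel <- c(sel, cand[1L])
    }
    sel <- sort(sel)
    d <- decouple_subset(m, core, rgs[sel])
    d$subset_id <- sum(2L^(sel - 1L))
    instances[[i]] <- structure(
      list(mol_id = get(key, mol_ids), molecule_smiles = key, core = core,
           decomposition = d, rgroup_smiles = d$rgroup_smiles,
           split = rec$split),
      class = "corpus_instance")
  }
  tsv <- utils::read.delim(file.path(dir, "rgroups.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(fragment_smiles = "character",
                                          occurrence_count = "integer",
                                          is_common = "integer",
                                          condition_bits = "character"))
  cond <- do.call(rbind, lapply(strsplit(tsv$condition_bits, ""),
                                as.integer))
  colnames(cond) <- catalog$name
  records <- structure(
    data.frame(fragment_smiles = tsv$fragment_smiles,
               occurrence_count = tsv$occurrence_count,
               is_common = as.logical(tsv$is_common),
               stringsAsFactors = FALSE),
    class = c("rgroup_records", "data.frame"),
    condition = cond, catalog_checksum = manifest$catalog_checksum)
  manifest$ratios <- as.numeric(manifest$ratios)
  structure(list(instances = instances, records = records,
                 manifest = manifest), class = "rgr_corpus")
}

#' Validate corpus invariants
#'
#' Independent validator pass: re-enumerates cores to confirm no surviving
#' molecule violates the core cap, recomputes occurrence counts from scratch,
#' re-applies the percentile rule, and checks the strict ">half common"
#' removal rule plus resolvability of every fragment SMILES.
#'
#' @param corpus An `rgr_corpus`.
#' @return A list of violation strings (empty when the corpus is valid).
#' @export
validate_corpus <- function(corpus) {
  violations <- character(0)
  inst <- corpus$instances
  rec <- corpus$records
  recount <- table(unlist(lapply(inst, function(x) x$rgroup_smiles)))
  missing <- setdiff(names(recount), rec$fragment_smiles)
  if (length(missing) > 0L)
    violations <- c(violations, paste("fragment not in record table:",
                                      missing))
  thr <- stats::quantile(rec$occurrence_count,
                         corpus$manifest$common_percentile / 100, type = 7)
  bad_tag <- rec$fragment_smiles[rec$is_common != (rec$occurrence_count > thr)]
  if (length(bad_tag) > 0L)
    violations <- c(violations, paste("commonness tag wrong:", bad_tag))
  common <- rec$fragment_smiles[rec$is_common]
  for (x in inst) {
    k <- length(x$rgroup_smiles)
    if (k > 0L && sum(x$rgroup_smiles %in% common) / k > 0.5)
      violations <- c(violations,
                      paste("instance kept despite >half common fragments:",
                            x$molecule_smiles))
  }
  mols <- unique(vapply(inst, function(x) x$molecule_smiles, character(1)))
  for (ms in mols) {
    cores <- enumerate_putative_cores(parse_smiles(ms),
                                      max_cores = corpus$manifest$max_cores)
    if (attr(cores, "total_cores") > corpus$manifest$max_cores)
      violations <- c(violations, paste("molecule exceeds core cap:", ms))
  }
  violations
}
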