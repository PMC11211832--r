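#' Loss and training configuration
#'
#' Temperatures follow the pretraining objective: `tau1 = 0.01` for the
#' graph-level contrastive term, `tau2 = 0.05` for the masked linker-node
#' term and `tau3 = 0.01` for the conditioned R-group retrieval term. The
#' per-term weights default to 1 each; setting a weight to 0 ablates the
#' term (e.g. `weights = c(1, 1, 0)` turns off the retrieval objective).
#'
#' @param tau1,tau2,tau3 Positive temperature scalars.
#' @param weights Numeric length-3 multipliers for the three loss terms.
#' @return A `loss_config` list.
#' @export
loss_config <- function(tau1 = 0.01, tau2 = 0.05, tau3 = 0.01,
                        weights = c(1, 1, 1)) {
  stopifnot(tau1 > 0, tau2 > 0, tau3 > 0, length(weights) == 3L)
  structure(list(tau1 = tau1, tau2 = tau2, tau3 = tau3, weights = weights),
            class = "loss_config")
}

#' @rdname loss_config
#' @param batch_size Instances per pretraining batch (the reference protocol
#'   uses 512; scale down for small corpora).
#' @param lr Adam learning rate (reference pretraining uses 0.001).
#' @param max_epochs Maximum epochs (reference protocol: 100).
#' @param patience Early-stopping patience in epochs on the validation loss.
#' @param seed Integer seed controlling initialization and batch order.
#' @export
train_config <- function(batch_size = 512L, lr = 1e-3, max_epochs = 100L,
                         patience = 10L, seed = 1L) {
  stopifnot(batch_size >= 1L, lr > 0, max_epochs >= 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

# Precompute featurizations and index bookkeeping for one corpus instance.
.prepare_instance <- function(inst, records) {
  d <- inst$decomposition
  if (length(d$fragments) == 0L) return(NULL)
  dv <- .decomposed_view(d)
  cond_idx <- match(inst$rgroup_smiles, records$fragment_smiles)
  list(fM = featurize(d$molecule),
       fD = featurize(dv$graph),
       m_rows = vapply(d$rgroups, function(r) r$linker_node, integer(1)),
       q_rows = dv$linker_pairs[, "q"],
       r_rows = dv$linker_pairs[, "r"],
       frag_rows = dv$frag_rows,
       cond_idx = cond_idx,
       rgroup_smiles = inst$rgroup_smiles,
       split = inst$split)
}

.prepare_instances <- function(instances, records) {
  prep <- lapply(instances, .prepare_instance, records = records)
  drop <- vapply(prep, is.null, logical(1))
  if (any(drop))
    warning(sum(drop), " instance(s) without decoupled fragments excluded")
  prep[!drop]
}

# Forward pass over a batch of prepared instances. Returns loss nodes and the
# projection values. The decomposed-view graph projection and the summed
# masked-linker projection are computed value-only (stop-gradient branches).
.batch_forward <- function(prep, model, loss_cfg, cond_matrix,
                           training = FALSE, tape = NULL) {
  B1 <- length(prep)
  packM <- .pack_graphs(lapply(prep, function(x) x$fM))
  packD <- .pack_graphs(lapply(prep, function(x) x$fD))
  HM <- .forward_gnn(tape, model, packM, training = training)
  HD <- .forward_gnn(tape, model, packD, training = training)

  # graph-level pair: z_GM (grad) vs z_GD (stop-gradient)
  z_GM <- .forward_head(tape, model, "graph",
                        tp_segment_mean(tape, HM, packM$graph_id, B1))
  pooledD <- .val(tp_segment_mean(NULL, tp_const(NULL, .val(HD)),
                                  packD$graph_id, B1))
  z_GD <- tp_const(tape, .val(.forward_head(NULL, model, "graph",
                                            tp_const(NULL, pooledD))))

  # per-site global row indices
  m_glob <- unlist(lapply(seq_len(B1), function(i)
    packM$offsets[i] + prep[[i]]$m_rows))
  q_glob <- unlist(lapply(seq_len(B1), function(i)
    packD$offsets[i] + prep[[i]]$q_rows))
  r_glob <- unlist(lapply(seq_len(B1), function(i)
    packD$offsets[i] + prep[[i]]$r_rows))
  B2 <- length(m_glob)

  z_m <- .forward_head(tape, model, "node", tp_gather(tape, HM, m_glob))
  HDv <- .val(HD)
  z_p <- tp_const(tape, .val(.forward_head(NULL, model, "node",
    tp_const(NULL, HDv[q_glob, , drop = FALSE] +
               HDv[r_glob, , drop = FALSE]))))

  cond <- do.call(rbind, lapply(prep, function(x)
    cond_matrix[x$cond_idx, , drop = FALSE]))
  z_C <- .forward_head(tape, model, "query",
                       tp_concat_const(tape, tp_gather(tape, HD, q_glob),
                                       cond))
  frag_rows_all <- unlist(lapply(seq_len(B1), function(i)
    lapply(prep[[i]]$frag_rows, function(rw) packD$offsets[i] + rw)),
    use.names = FALSE)
  frag_group <- rep(seq_len(B2), unlist(lapply(prep, function(x)
    lengths(x$frag_rows)), use.names = FALSE))
  z_R <- .forward_head(tape, model, "rgroup",
                       tp_segment_mean(tape,
                                       tp_gather(tape, HD, frag_rows_all),
                                       frag_group, B2))

  L1 <- tp_info_nce(tape, z_GM, z_GD, loss_cfg$tau1)
  L2 <- tp_info_nce(tape, z_m, z_p, loss_cfg$tau2)
  L3 <- tp_info_nce(tape, z_C, z_R, loss_cfg$tau3)
  w <- loss_cfg$weights
  L <- tp_add(tape, tp_add(tape, tp_scale(tape, L1, w[1]),
                           tp_scale(tape, L2, w[2])),
              tp_scale(tape, L3, w[3]))
  list(L = L, L1 = .val(L1), L2 = .val(L2), L3 = .val(L3),
       B1 = B1, B2 = B2, B3 = B2,
       z_GM = .val(z_GM), z_GD = .val(z_GD), z_m = .val(z_m),
       z_p = .val(z_p), z_C = .val(z_C), z_R = .val(z_R))
}

#' Masked graph contrastive + R-group retrieval loss over a batch
#'
#' Computes the three pooled InfoNCE terms for a batch of corpus instances:
#' `L1` aligns each molecule's graph projection with its decomposed view
#' (B1 pairs, temperature `tau1`, decomposed branch detached), `L2` aligns
#' every original linker node with the sum of its masked linker pair (all B2
#' linker sites in the batch pooled as mutual in-batch negatives, `tau2`,
#' masked branch detached), and `L3` aligns every conditioned query linker
#' projection with its decoupled R-group projection (B3 pairs, `tau3`). The
#' total is the weighted sum `L = L1 + L2 + L3`.
#'
#' @param instances List of `corpus_instance`s (a batch).
#' @param model An `rgr_model` or `rgr_checkpoint`.
#' @param records `rgroup_records` of the corpus (condition vectors).
#' @param loss_cfg A [loss_config()].
#' @return Named numeric vector `c(L, L1, L2, L3)` with attributes `B1`,
#'   `B2`, `B3`.
#' @export
mgcl_rgr_loss <- function(instances, model, records,
                          loss_cfg = loss_config()) {
  model <- .as_model(model)
  prep <- .prepare_instances(instances, records)
  if (length(prep) == 0L) stop("argument error: no usable instances")
  out <- .batch_forward(prep, model, loss_cfg, attr(records, "condition"),
                        training = FALSE, tape = NULL)
  structure(c(L = .val(out$L), L1 = out$L1, L2 = out$L2, L3 = out$L3),
            B1 = out$B1, B2 = out$B2, B3 = out$B3)
}

.bn_snapshot <- function(model) {
  lapply(stats::setNames(nm = ls(model$bn_state)), function(l) {
    st <- get(l, model$bn_state)
    list(mean = st$mean, var = st$var)
  })
}

.bn_restore <- function(model, snap) {
  for (l in names(snap)) {
    st <- get(l, model$bn_state)
    st$mean <- snap[[l]]$mean
    st$var <- snap[[l]]$var
  }
  invisible(model)
}

#' Pretrain the encoder with the dual InfoNCE objective
#'
#' Mini-batch Adam training over the corpus's train split with per-epoch
#' validation, early stopping on the validation total loss, and retention of
#' the best-validation parameters. Fully seeded: two runs with the same
#' corpus, configs and seed produce identical loss curves.
#'
#' @param corpus An `rgr_corpus` with train/valid splits.
#' @param config An [encoder_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param init Optional `rgr_checkpoint` to resume from.
#' @param verbose Print per-epoch losses.
#' @return An `rgr_checkpoint`: the best model, the per-epoch `history`
#'   data.frame (train/valid total and per-term losses) and the configs.
#' @export
pretrain <- function(corpus, config = encoder_config(),
                     loss_cfg = loss_config(), train_cfg = train_config(),
                     init = NULL, verbose = FALSE) {
  splits <- vapply(corpus$instances, function(x) x$split, character(1))
  if (!any(splits == "train") || !any(splits == "valid"))
    stop("configuration error: corpus needs non-empty train and valid splits")
  records <- corpus$records
  cond <- attr(records, "condition")
  prep_train <- .prepare_instances(corpus$instances[splits == "train"], records)
  prep_valid <- .prepare_instances(corpus$instances[splits == "valid"], records)

  model <- if (is.null(init)) init_rgr_model(config, seed = train_cfg$seed)
    else .as_model(init)

  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(train_cfg$seed + 1L)

  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, bn = .bn_snapshot(model),
               epoch = 0L)
  va0 <- .eval_split(prep_valid, model, loss_cfg, cond, train_cfg$batch_size)
  hist <- list(data.frame(epoch = 0L, train_L = NA_real_, train_L1 = NA_real_,
                          train_L2 = NA_real_, train_L3 = NA_real_,
                          valid_L = va0[1], valid_L1 = va0[2],
                          valid_L2 = va0[3], valid_L3 = va0[4]))
  if (verbose) message(sprintf("epoch   0  valid %.4f (untrained)", va0[1]))
  bad <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample(length(prep_train))
    nb <- ceiling(length(ord) / train_cfg$batch_size)
    tr <- c(L = 0, L1 = 0, L2 = 0, L3 = 0)
    for (b in seq_len(nb)) {
      sel <- ord[((b - 1L) * train_cfg$batch_size + 1L):
                   min(b * train_cfg$batch_size, length(ord))]
      tape <- .new_tape()
      out <- .batch_forward(prep_train[sel], model, loss_cfg, cond,
                            training = TRUE, tape = tape)
      backward(tape, out$L)
      grads <- .tape_grads(tape)
      stepped <- adam_step(model$params, grads, opt, lr = train_cfg$lr)
      model$params <- stepped$params
      opt <- stepped$state
      tr <- tr + c(.val(out$L), out$L1, out$L2, out$L3) * length(sel)
    }
    tr <- tr / length(prep_train)
    va <- .eval_split(prep_valid, model, loss_cfg, cond,
                      train_cfg$batch_size)
    hist[[epoch + 1L]] <- data.frame(epoch = epoch,
                                train_L = tr[1], train_L1 = tr[2],
                                train_L2 = tr[3], train_L3 = tr[4],
                                valid_L = va[1], valid_L1 = va[2],
                                valid_L2 = va[3], valid_L3 = va[4])
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  valid %.4f", epoch, tr[1], va[1]))
    if (va[1] < best$loss - 1e-9) {
      best <- list(loss = va[1], params = model$params,
                   bn = .bn_snapshot(model), epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= train_cfg$patience) break
    }
  }
  model$params <- best$params
  .bn_restore(model, best$bn)
  history <- do.call(rbind, hist)
  rownames(history) <- NULL
  structure(list(model = model, history = history, loss_cfg = loss_cfg,
                 train_cfg = train_cfg, best_epoch = best$epoch,
                 corpus_manifest = corpus$manifest),
            class = "rgr_checkpoint")
}

.eval_split <- function(prep, model, loss_cfg, cond, batch_size) {
  nb <- ceiling(length(prep) / batch_size)
  acc <- c(0, 0, 0, 0)
  for (b in seq_len(nb)) {
    sel <- ((b - 1L) * batch_size + 1L):min(b * batch_size, length(prep))
    out <- .batch_forward(prep[sel], model, loss_cfg, cond,
                          training = FALSE, tape = NULL)
    acc <- acc + c(.val(out$L), out$L1, out$L2, out$L3) * length(sel)
  }
  acc / length(prep)
}

#' @export
print.rgr_checkpoint <- function(x, ...) {
  cat(sprintf("<rgr_checkpoint> best epoch %d (valid loss %.4f), %d epochs run\n",
              x$best_epoch, min(x$history$valid_L), nrow(x$history)))
  invisible(x)
}

#' Save / load a pretraining checkpoint
#'
#' Checkpoints store the weights, encoder configuration, attribute-vocabulary
#' schema and functional-group catalog checksum. Loading refuses checkpoints
#' whose schema or catalog does not match the current package, so embeddings
#' are never mixed across incompatible featurizations.
#'
#' @param checkpoint An `rgr_checkpoint` or `rgr_model`.
#' @param path File path.
#' @return `load_checkpoint` returns the checkpoint.
#' @export
save_checkpoint <- function(checkpoint, path) {
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param catalog Functional-group catalog to validate against.
#' @export
load_checkpoint <- function(path, catalog = load_fg_catalog()) {
  ck <- readRDS(path)
  model <- .as_model(ck)
  if (!identical(unname(model$catalog_checksum),
                 unname(attr(catalog, "checksum"))))
    stop("configuration error: checkpoint catalog checksum mismatch")
  if (!identical(model$vocab, attribute_vocabularies()))
    stop("configuration error: checkpoint vocabulary schema mismatch")
  ck
}
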