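#' Generic scaffold of a molecule
#'
#' The ring systems plus the linker atoms connecting them, obtained by
#' iteratively pruning terminal (degree-1) atoms. Acyclic molecules have an
#' empty scaffold and are grouped together by the scaffold split.
#'
#' @param g A `molgraph` or SMILES string.
#' @return Canonical scaffold SMILES (`""` for acyclic molecules).
#' @export
generic_scaffold <- function(g) {
  if (is.character(g)) g <- parse_smiles(g)
  keep <- rep(TRUE, n_atoms(g))
  repeat {
    deg <- integer(n_atoms(g))
    bsel <- g$bonds$from %in% which(keep) & g$bonds$to %in% which(keep)
    if (any(bsel)) {
      deg <- tabulate(g$bonds$from[bsel], n_atoms(g)) +
        tabulate(g$bonds$to[bsel], n_atoms(g))
    }
    terminal <- keep & deg <= 1L
    ring_atoms <- integer(0)
    if (!any(terminal)) break
    keep[terminal] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) return("")
  to_canonical_smiles(.subgraph(g, which(keep)))
}

#' Deterministic scaffold split
#'
#' Groups molecules by [generic_scaffold()], orders the groups largest first
#' (ties by scaffold string), and fills the train, then validation, then test
#' partitions to the requested ratios. Molecules sharing a scaffold never
#' cross partitions, so test scaffolds are unseen during training.
#'
#' @param smiles Character vector of molecule SMILES.
#' @param ratios Train/valid/test ratios summing to 1 (default 0.8/0.1/0.1).
#' @return Character vector in `{"train","valid","test"}` per molecule.
#' @export
scaffold_split <- function(smiles, ratios = c(0.8, 0.1, 0.1)) {
  if (abs(sum(ratios) - 1) > 1e-8)
    stop("argument error: ratios must sum to 1")
  scaf <- vapply(smiles, function(s)
    tryCatch(generic_scaffold(s), error = function(e) ""), character(1))
  groups <- split(seq_along(smiles), scaf)
  ord <- order(-lengths(groups), names(groups))
  groups <- groups[ord]
  n <- length(smiles)
  n_train <- floor(ratios[1] * n)
  n_valid <- floor(ratios[2] * n)
  out <- character(n)
  assigned <- 0L
  for (gset in groups) {
    lab <- if (assigned < n_train) "train"
      else if (assigned < n_train + n_valid) "valid" else "test"
    out[gset] <- lab
    assigned <- assigned + length(gset)
  }
  out
}

#' Fine-tune a pretrained encoder for property prediction
#'
#' Loads the pretrained graph encoder, adds a linear task prediction head on
#' the mean-pooled graph representation (with dropout during training), and
#' fine-tunes end-to-end with Adam. The dataset is partitioned 8:1:1 by the
#' deterministic scaffold split; missing labels are masked from the loss.
#' Classification reports AUROC averaged over tasks, regression RMSE; the
#' experiment is repeated over `seeds` and summarized as mean and standard
#' deviation.
#'
#' @param checkpoint An `rgr_checkpoint` (pretrained weights) or `rgr_model`.
#' @param data A data.frame (or CSV path) with a SMILES column and one or
#'   more label columns. Classification labels are 0/1 (NA allowed).
#' @param task `"classification"` or `"regression"`.
#' @param smiles_col Name of the SMILES column (default `"smiles"`).
#' @param train_cfg A [train_config()]; the protocol defaults here are batch
#'   size 32 and learning rate 1e-4.
#' @param dropout Dropout rate on the pooled representation (default 0.3).
#' @param seeds Integer vector of seeds (one fine-tuning run each).
#' @param ratios Scaffold-split ratios.
#' @param verbose Print per-epoch validation metrics.
#' @return List with `per_seed` (data.frame of test metrics), `mean`, `sd`
#'   and the split sizes.
#' @export
finetune_property <- function(checkpoint, data,
                              task = c("classification", "regression"),
                              smiles_col = "smiles",
                              train_cfg = train_config(batch_size = 32L,
                                                       lr = 1e-4,
                                                       max_epochs = 20L,
                                                       patience = 5L),
                              dropout = 0.3, seeds = 1:5,
                              ratios = c(0.8, 0.1, 0.1), verbose = FALSE) {
  task <- match.arg(task)
  if (is.character(data)) data <- utils::read.csv(data, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(data))
    stop("argument error: no column '", smiles_col, "' in dataset")
  label_cols <- setdiff(names(data), smiles_col)
  if (length(label_cols) == 0L) stop("argument error: no label columns")
  Y <- as.matrix(data[, label_cols, drop = FALSE])
  storage.mode(Y) <- "double"

  feats <- lapply(data[[smiles_col]], function(s) featurize(parse_smiles(s)))
  split <- scaffold_split(data[[smiles_col]], ratios)
  idx <- list(train = which(split == "train"), valid = which(split == "valid"),
              test = which(split == "test"))
  if (length(idx$train) == 0L || length(idx$valid) == 0L ||
      length(idx$test) == 0L)
    stop("configuration error: a scaffold-split partition is empty")

  base_model <- .as_model(checkpoint)
  per_seed <- lapply(seeds, function(sd0) {
    .finetune_one(base_model, feats, Y, idx, task, train_cfg, dropout, sd0,
                  verbose)
  })
  metrics <- vapply(per_seed, function(x) x$metric, numeric(1))
  list(per_seed = data.frame(seed = seeds, metric = metrics),
       mean = mean(metrics, na.rm = TRUE),
       sd = stats::sd(metrics, na.rm = TRUE),
       metric = if (task == "classification") "AUROC" else "RMSE",
       split_sizes = lengths(idx))
}

.finetune_one <- function(base_model, feats, Y, idx, task, train_cfg,
                          dropout, seed, verbose) {
  model <- base_model
  model$bn_state <- local({ e <- new.env(parent = emptyenv())
    for (l in ls(base_model$bn_state)) {
      st0 <- get(l, base_model$bn_state)
      st <- new.env(parent = emptyenv())
      st$mean <- st0$mean; st$var <- st0$var
      assign(l, st, e)
    }
    e })
  d <- model$config$hidden_dim
  ntask <- ncol(Y)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  model$params$task_W <- .glorot(d, ntask)
  model$params$task_b <- matrix(0, 1L, ntask)
  opt <- adam_init(model$params)
  best <- list(metric = if (task == "classification") -Inf else Inf,
               params = model$params, bn = .bn_snapshot(model))
  bad <- 0L
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample(idx$train)
    nb <- ceiling(length(ord) / train_cfg$batch_size)
    for (b in seq_len(nb)) {
      sel <- ord[((b - 1L) * train_cfg$batch_size + 1L):
                   min(b * train_cfg$batch_size, length(ord))]
      tape <- .new_tape()
      logits <- .predict_head(tape, model, feats[sel], dropout, TRUE)
      loss <- if (task == "classification") {
        tp_bce_masked(tape, logits, Y[sel, , drop = FALSE])
      } else {
        tp_mse_masked(tape, logits, Y[sel, , drop = FALSE])
      }
      backward(tape, loss)
      stepped <- adam_step(model$params, .tape_grads(tape), opt,
                           lr = train_cfg$lr)
      model$params <- stepped$params
      opt <- stepped$state
    }
    vm <- .eval_metric(model, feats, Y, idx$valid, task, train_cfg$batch_size)
    if (verbose) message(sprintf("epoch %d valid %s %.4f", epoch,
                                 if (task == "classification") "AUROC" else "RMSE",
                                 vm))
    improved <- if (task == "classification") !is.na(vm) && vm > best$metric
      else !is.na(vm) && vm < best$metric
    if (improved) {
      best <- list(metric = vm, params = model$params, bn = .bn_snapshot(model))
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= train_cfg$patience) break
    }
  }
  model$params <- best$params
  .bn_restore(model, best$bn)
  list(metric = .eval_metric(model, feats, Y, idx$test, task,
                             train_cfg$batch_size),
       model = model)
}

.predict_head <- function(tape, model, feats, dropout, training) {
  pack <- .pack_graphs(feats)
  H <- .forward_gnn(tape, model, pack, training = training)
  pooled <- tp_segment_mean(tape, H, pack$graph_id, length(feats))
  pooled <- tp_dropout(tape, pooled, dropout, training)
  tp_addbias(tape, tp_matmul(tape, pooled, .param_node(tape, model$params, "task_W")),
             .param_node(tape, model$params, "task_b"))
}

.eval_metric <- function(model, feats, Y, sel, task, batch_size) {
  preds <- matrix(NA_real_, length(sel), ncol(Y))
  nb <- ceiling(length(sel) / batch_size)
  for (b in seq_len(nb)) {
    rows <- sel[((b - 1L) * batch_size + 1L):min(b * batch_size, length(sel))]
    preds[match(rows, sel), ] <- .val(.predict_head(NULL, model, feats[rows],
                                                    0, FALSE))
  }
  ys <- Y[sel, , drop = FALSE]
  if (task == "regression") {
    return(sqrt(mean((preds - ys)^2, na.rm = TRUE)))
  }
  aucs <- vapply(seq_len(ncol(ys)), function(t) {
    ok <- !is.na(ys[, t])
    if (length(unique(ys[ok, t])) < 2L) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(ys[ok, t], preds[ok, t], quiet = TRUE,
                                   direction = "<", levels = c(0, 1))))
  }, numeric(1))
  if (all(is.na(aucs))) NA_real_ else mean(aucs, na.rm = TRUE)
}
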