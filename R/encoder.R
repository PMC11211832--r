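#' Encoder and projection-head configuration
#'
#' The shared graph encoder is a graph isomorphism network (GIN) with
#' `num_layers` message-passing layers and hidden width `hidden_dim` (the
#' embedding dimension d, default 300). Edge attributes are embedded and
#' added to messages; each layer applies a two-layer MLP followed by batch
#' normalization, with ReLU between layers. The four projection heads (graph,
#' node, conditioned query, R-group) are two-layer MLPs of width d with
#' LeakyReLU activation; the query head consumes the node projection
#' concatenated with the length-F functional-group condition vector, i.e. a
#' `d + F` input (387 at the defaults d = 300, F = 87).
#'
#' @param num_layers Number of GIN layers (default 5).
#' @param hidden_dim Embedding dimension d (default 300).
#' @param cond_dim Condition-vector length F (default 87, the catalog size).
#' @param leaky_slope Negative slope of the heads' LeakyReLU (default 0.01).
#' @param bn_momentum Running-statistics momentum of batch normalization.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(num_layers = 5L, hidden_dim = 300L, cond_dim = 87L,
                           leaky_slope = 0.01, bn_momentum = 0.1) {
  stopifnot(num_layers >= 1L, hidden_dim > 0L, cond_dim >= 0L)
  structure(list(num_layers = as.integer(num_layers),
                 hidden_dim = as.integer(hidden_dim),
                 cond_dim = as.integer(cond_dim),
                 leaky_slope = leaky_slope, bn_momentum = bn_momentum),
            class = "encoder_config")
}

.glorot <- function(nin, nout) {
  a <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -a, a), nin, nout)
}

#' Initialize an encoder + heads model with seeded random weights
#'
#' @param config An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @param catalog Functional-group catalog whose size must equal `cond_dim`
#'   and whose checksum is stored for compatibility checks.
#' @return An `rgr_model`: parameters, batch-norm state, config, vocabulary
#'   schema and catalog checksum.
#' @export
init_rgr_model <- function(config = encoder_config(), seed = 1L,
                           catalog = load_fg_catalog()) {
  if (attr(catalog, "F") != config$cond_dim)
    stop("configuration error: catalog size ", attr(catalog, "F"),
         " != configured condition dimension ", config$cond_dim)
  vocab <- attribute_vocabularies()
  d <- config$hidden_dim
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  p <- list()
  for (k in names(vocab$node)) {
    p[[paste0("emb_", k)]] <- matrix(stats::rnorm(length(vocab$node[[k]]) * d,
                                                  sd = 0.1),
                                     length(vocab$node[[k]]), d)
  }
  for (l in seq_len(config$num_layers)) {
    p[[sprintf("edge_order_%d", l)]] <-
      matrix(stats::rnorm(length(vocab$edge$order) * d, sd = 0.1),
             length(vocab$edge$order), d)
    p[[sprintf("edge_stereo_%d", l)]] <-
      matrix(stats::rnorm(length(vocab$edge$stereo) * d, sd = 0.1),
             length(vocab$edge$stereo), d)
    p[[sprintf("gin_W1_%d", l)]] <- .glorot(d, d)
    p[[sprintf("gin_b1_%d", l)]] <- matrix(0, 1L, d)
    p[[sprintf("gin_W2_%d", l)]] <- .glorot(d, d)
    p[[sprintf("gin_b2_%d", l)]] <- matrix(0, 1L, d)
    p[[sprintf("bn_gamma_%d", l)]] <- matrix(1, 1L, d)
    p[[sprintf("bn_beta_%d", l)]] <- matrix(0, 1L, d)
  }
  for (h in c("graph", "node", "rgroup")) {
    p[[paste0(h, "_W1")]] <- .glorot(d, d)
    p[[paste0(h, "_b1")]] <- matrix(0, 1L, d)
    p[[paste0(h, "_W2")]] <- .glorot(d, d)
    p[[paste0(h, "_b2")]] <- matrix(0, 1L, d)
  }
  p[["query_W1"]] <- .glorot(d + config$cond_dim, d)
  p[["query_b1"]] <- matrix(0, 1L, d)
  p[["query_W2"]] <- .glorot(d, d)
  p[["query_b2"]] <- matrix(0, 1L, d)

  bn_state <- new.env(parent = emptyenv())
  for (l in seq_len(config$num_layers)) {
    st <- new.env(parent = emptyenv())
    st$mean <- rep(0, d); st$var <- rep(1, d)
    assign(as.character(l), st, envir = bn_state)
  }
  structure(list(params = p, bn_state = bn_state, config = config,
                 vocab = vocab, catalog_checksum = attr(catalog, "checksum"),
                 version = "1"),
            class = "rgr_model")
}

#' @export
print.rgr_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<rgr_model> %d GIN layers, d = %d, F = %d, %s parameters\n",
              x$config$num_layers, x$config$hidden_dim, x$config$cond_dim,
              format(np, big.mark = ",")))
  invisible(x)
}

# Pack featurized graphs into one disjoint batch for the encoder.
.pack_graphs <- function(feats) {
  nn <- vapply(feats, function(f) nrow(f$node_features), integer(1))
  offs <- cumsum(c(0L, nn))
  nf <- do.call(rbind, lapply(feats, function(f) f$node_features))
  ef <- do.call(rbind, lapply(feats, function(f) f$edge_features))
  ei <- do.call(rbind, lapply(seq_along(feats), function(i)
    feats[[i]]$edge_index + offs[i]))
  gid <- rep(seq_along(feats), nn)
  list(node_features = nf, edge_features = ef, edge_index = ei,
       graph_id = gid, offsets = offs[seq_along(feats)],
       n_graphs = length(feats))
}

# GIN forward over a packed batch; returns the node-representation tape node.
.forward_gnn <- function(tape, model, pack, training = FALSE) {
  p <- model$params
  cfg <- model$config
  nf <- pack$node_features
  N <- nrow(nf)
  # sum the five attribute embeddings
  h <- NULL
  emb_names <- c("emb_element", "emb_charge", "emb_aromatic", "emb_chirality",
                 "emb_hcount")
  for (k in seq_along(emb_names)) {
    e <- tp_gather(tape, .param_node(tape, p, emb_names[k]), nf[, k])
    h <- if (is.null(h)) e else tp_add(tape, h, e)
  }
  src <- pack$edge_index[, 1L]; dst <- pack$edge_index[, 2L]
  for (l in seq_len(cfg$num_layers)) {
    if (nrow(pack$edge_features) > 0L) {
      e <- tp_add(tape,
        tp_gather(tape, .param_node(tape, p, sprintf("edge_order_%d", l)),
                  pack$edge_features[, 1L]),
        tp_gather(tape, .param_node(tape, p, sprintf("edge_stereo_%d", l)),
                  pack$edge_features[, 2L]))
      msg <- tp_relu(tape, tp_add(tape, tp_gather(tape, h, src), e))
      agg <- tp_add(tape, tp_scatter_sum(tape, msg, dst, N), h)
    } else {
      agg <- h
    }
    z <- tp_addbias(tape, tp_matmul(tape, agg,
                                    .param_node(tape, p, sprintf("gin_W1_%d", l))),
                    .param_node(tape, p, sprintf("gin_b1_%d", l)))
    z <- tp_relu(tape, z)
    z <- tp_addbias(tape, tp_matmul(tape, z,
                                    .param_node(tape, p, sprintf("gin_W2_%d", l))),
                    .param_node(tape, p, sprintf("gin_b2_%d", l)))
    st <- get(as.character(l), envir = model$bn_state)
    z <- tp_batchnorm(tape, z, .param_node(tape, p, sprintf("bn_gamma_%d", l)),
                      .param_node(tape, p, sprintf("bn_beta_%d", l)),
                      st, training = training, momentum = cfg$bn_momentum)
    h <- if (l < cfg$num_layers) tp_relu(tape, z) else z
  }
  h
}

# Parameter nodes are cached per tape so each parameter matrix has exactly
# one node (gradient accumulation point) per forward pass.
.param_node <- function(tape, params, name) {
  if (is.null(tape)) return(tp_const(NULL, params[[name]]))
  if (is.null(tape$pcache)) tape$pcache <- new.env(parent = emptyenv())
  if (!exists(name, tape$pcache, inherits = FALSE)) {
    assign(name, .tp_node(tape, params[[name]]), tape$pcache)
  }
  get(name, tape$pcache, inherits = FALSE)
}

# Two-layer LeakyReLU projection head.
.forward_head <- function(tape, model, prefix, x) {
  p <- model$params
  s <- model$config$leaky_slope
  z <- tp_addbias(tape, tp_matmul(tape, x, .param_node(tape, p, paste0(prefix, "_W1"))),
                  .param_node(tape, p, paste0(prefix, "_b1")))
  z <- tp_lrelu(tape, z, s)
  tp_addbias(tape, tp_matmul(tape, z, .param_node(tape, p, paste0(prefix, "_W2"))),
             .param_node(tape, p, paste0(prefix, "_b2")))
}

# Collect parameter gradients accumulated on a tape.
.tape_grads <- function(tape) {
  if (is.null(tape$pcache)) return(list())
  out <- list()
  for (name in ls(tape$pcache)) {
    nd <- get(name, tape$pcache, inherits = FALSE)
    if (!is.null(nd$grad)) out[[name]] <- nd$grad
  }
  out
}

#' Encode a molecular graph into node representations
#'
#' Runs the shared GIN encoder over the (possibly disconnected) graph in
#' inference mode. Message passing is confined to connected components, so
#' the representations of one component are unaffected by the others.
#'
#' @param graph A `molgraph` (or a list returned by [featurize()]).
#' @param model An `rgr_model` (or an `rgr_checkpoint`).
#' @return A numeric matrix H with one d-dimensional row per node.
#' @export
encode <- function(graph, model) {
  model <- .as_model(model)
  f <- if (inherits(graph, "molgraph")) featurize(graph) else graph
  if (nrow(f$node_features) == 0L) stop("argument error: empty graph")
  pack <- .pack_graphs(list(f))
  .val(.forward_gnn(NULL, model, pack, training = FALSE))
}

.as_model <- function(m) {
  if (inherits(m, "rgr_checkpoint")) m$model else m
}

#' Graph-level projection
#'
#' Mean-pools node representations over all nodes and applies the graph
#' projection head. With `stopgrad = TRUE` (the decomposed-view branch) the
#' result is detached: during training it contributes no gradient to the
#' encoder.
#'
#' @param H Node-representation matrix from [encode()].
#' @param model An `rgr_model` or checkpoint.
#' @param stopgrad Logical; detach the projection from the encoder.
#' @return A d-vector.
#' @export
project_graph <- function(H, model, stopgrad = FALSE) {
  model <- .as_model(model)
  pooled <- matrix(colMeans(H), 1L)
  z <- .val(.forward_head(NULL, model, "graph", tp_const(NULL, pooled)))
  structure(as.vector(z), stopgrad = stopgrad)
}

#' Linker-node projections for the node-level contrastive pair
#'
#' `z_m` projects the unmasked linker-node row of the original molecule;
#' `z_p` projects the vector-wise sum of the masked linker pair (query-side
#' row plus fragment-side row) and is the detached branch during training.
#' The sum makes `z_p` symmetric in its two inputs.
#'
#' @param m_i d-vector: linker-node row of the original molecule's H.
#' @param q_i,r_i d-vectors: masked linker rows of the decomposed view.
#' @param model An `rgr_model` or checkpoint.
#' @return List with `z_m` and `z_p` (both d-vectors).
#' @export
project_linker_pair <- function(m_i, q_i, r_i, model) {
  model <- .as_model(model)
  d <- model$config$hidden_dim
  if (length(m_i) != d || length(q_i) != d || length(r_i) != d)
    stop("argument error: linker vectors must have length d = ", d)
  zm <- .val(.forward_head(NULL, model, "node",
                           tp_const(NULL, matrix(m_i, 1L))))
  zp <- .val(.forward_head(NULL, model, "node",
                           tp_const(NULL, matrix(q_i + r_i, 1L))))
  list(z_m = as.vector(zm), z_p = structure(as.vector(zp), stopgrad = TRUE))
}

#' Conditioned query projection
#'
#' Concatenates a masked query linker-node representation with a
#' functional-group condition bit vector and applies the query projection
#' head (input width d + F).
#'
#' @param q_i d-vector: masked query linker-node row.
#' @param c_R 0/1 vector of length F (all-zero and all-one vectors are
#'   accepted; they are the Cond-None / Cond-All ablation inputs).
#' @param model An `rgr_model` or checkpoint.
#' @return A d-vector `z_C`.
#' @export
project_query <- function(q_i, c_R, model) {
  model <- .as_model(model)
  d <- model$config$hidden_dim
  if (length(q_i) != d)
    stop("argument error: q_i must have length d = ", d)
  if (length(c_R) != model$config$cond_dim)
    stop("dimension error: condition vector has length ", length(c_R),
         ", expected F = ", model$config$cond_dim)
  x <- matrix(c(q_i, as.numeric(c_R)), 1L)
  as.vector(.val(.forward_head(NULL, model, "query", tp_const(NULL, x))))
}

#' R-group fragment projection
#'
#' Mean-pools the node representations of one decoupled fragment (masked
#' linker copy included) and applies the R-group projection head.
#'
#' @param H_R Node-representation matrix covering exactly one fragment.
#' @param model An `rgr_model` or checkpoint.
#' @return A d-vector `z_R`.
#' @export
project_rgroup <- function(H_R, model) {
  model <- .as_model(model)
  pooled <- matrix(colMeans(H_R), 1L)
  as.vector(.val(.forward_head(NULL, model, "rgroup", tp_const(NULL, pooled))))
}
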