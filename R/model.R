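# Full model assembly: initialization, the three-block encoder and the
# autoregressive sequence decoder (teacher-forced logits).

#' Initialize a sequence-design model
#'
#' @param config a [model_config].
#' @param feat a [feature_config] (its `m` must equal `config$m`).
#' @param variant `"full"` (ligand-aware) or `"protein_only"` (ablation with
#'   the ligand featurization and protein-ligand encoder removed).
#' @param seed integer RNG seed for weight initialization.
#' @return object of class `pocket_model` with elements `params`, `config`,
#'   `feat`, `variant`.
#' @export
init_model <- function(config = model_config(), feat = feature_config(),
                       variant = c("full", "protein_only"), seed = 1L) {
  variant <- match.arg(variant)
  if (feat$m != config$m) feat$m <- config$m
  shapes <- .param_shapes(config, feat, variant)
  params <- .init_params(shapes, seed)
  structure(list(params = params, config = config, feat = feat,
                 variant = variant, seed = seed),
            class = "pocket_model")
}

#' @export
print.pocket_model <- function(x, ...) {
  cat(sprintf("pocket_model (%s): m=%d, %.2fM parameters\n", x$variant,
              x$config$m,
              sum(vapply(x$params, length, 1L)) / 1e6))
  invisible(x)
}

# wrap every parameter as a named autograd leaf (training mode)
.wrap_params <- function(params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- ag_leaf(params[[nm]], nm)
  out
}

#' Run the encoder on featurized inputs
#'
#' Three protein encoder layers over the K-NN residue graph; for the full
#' variant, `num_ctx_layers` alternating atom-graph and protein-ligand-graph
#' updates whose output is merged into the node states through a residual
#' LayerNorm branch.
#'
#' @param model a `pocket_model` (or packer stack via `P`/`prefix`).
#' @param features a `pocket_features` bundle from [featurize()].
#' @param training enable dropout.
#' @param P optional parameter list override (autograd nodes during training).
#' @param prefix parameter-name prefix (used by the packer's twin stacks).
#' @return list with `h_V` `[L x m]`, `e` `[(L K) x m]`, `e_idx`, `features`.
#' @export
model_encode <- function(model, features, training = FALSE, P = NULL,
                         prefix = "") {
  if (is.null(P)) P <- model$params
  cfg <- model$config
  L <- features$L
  K <- features$K_eff
  M <- features$M
  full <- identical(model$variant, "full") || identical(model$variant, "packer")
  pg <- function(nm) paste0(prefix, nm)

  pos16 <- .lin(P, pg("pos_enc"), features$pos_onehot)
  e <- ag_concat(pos16, features$rbf_edges)
  e <- .norm(P, pg("norm_edges"), .lin(P, pg("edge_embed"), e, bias = FALSE))
  e <- .lin(P, pg("W_e"), e)

  v <- matrix(0, L, cfg$m)
  for (l in seq_len(cfg$num_enc_layers)) {
    upd <- enc_layer(P, pg(sprintf("enc%d", l)), v, e, features$e_idx,
                     features$mask, features$mask_attend, cfg, training)
    v <- upd$v; e <- upd$e
  }

  if (full) {
    t64 <- .lin(P, pg("type_linear"), features$ctx_onehot)
    v_in <- ag_concat(features$ctx_rbf, t64, features$ctx_angles)
    v_y <- .norm(P, pg("norm_nodes"), .lin(P, pg("node_down"), v_in))
    y_nodes <- .norm(P, pg("norm_y_nodes"),
                     .lin(P, pg("y_nodes_embed"), features$ctx_onehot,
                          bias = FALSE))
    y_edges <- .norm(P, pg("norm_y_edges"),
                     .lin(P, pg("y_edges_embed"), features$yedges_rbf,
                          bias = FALSE))
    v_c <- .lin(P, pg("W_c"), v)
    v_y <- .lin(P, pg("W_v"), v_y)
    y_nodes <- .lin(P, pg("W_nodes_y"), y_nodes)
    y_edges <- .lin(P, pg("W_edges_y"), y_edges)
    for (l in seq_len(cfg$num_ctx_layers)) {
      y_nodes <- context_dec_layer(P, pg(sprintf("ctxy%d", l)), y_nodes,
                                   y_edges, M, features$Y_m_flat,
                                   features$Ym_edges, cfg, training)
      ctx_edges <- ag_concat(v_y, y_nodes)
      v_c <- dec_layer(P, pg(sprintf("ctx%d", l)), v_c, ctx_edges, B = M,
                       mask = features$mask, mask_attend = features$Y_m_flat,
                       cfg = cfg, training = training)
    }
    v_c <- ag_matmul(v_c, P[[paste0(pg("V_C"), ".W")]])
    v <- ag_add(v, .norm(P, pg("V_C_norm"),
                         ag_dropout(v_c, cfg$dropout_p, training)))
  }
  list(h_V = v, e = e, e_idx = features$e_idx, features = features)
}

# ranks: step at which each position is decoded (ties allowed for tied
# groups); position i may attend to j iff rank[j] < rank[i]
.causal_mask_flat <- function(e_idx, rank) {
  L <- nrow(e_idx); K <- ncol(e_idx)
  i_flat <- rep(seq_len(L), each = K)
  j_flat <- as.vector(t(e_idx))
  as.numeric(rank[j_flat] < rank[i_flat])
}

#' Decoding order to rank vector
#' @param decoding_order integer permutation of `1:L` (positions in visit
#'   order).
#' @return integer `[L]`: `rank[p]` = step at which position `p` is decoded.
#' @export
order_to_rank <- function(decoding_order) {
  L <- length(decoding_order)
  if (!identical(sort(decoding_order), seq_len(L)))
    stop("decoding_order must be a permutation of 1:L")
  rank <- integer(L)
  rank[decoding_order] <- seq_len(L)
  rank
}

#' Teacher-forced decoder: per-position logits and log-probabilities
#'
#' Position `i` attends to the sequence tokens of neighbors decoded before it
#' under the given order; not-yet-decoded neighbor slots fall back to
#' encoder-only features (sequence embedding zeroed).
#'
#' @param model a `pocket_model`.
#' @param encoded output of [model_encode()].
#' @param S integer token sequence `[L]`.
#' @param decoding_order permutation of `1:L`, or `rank` given directly.
#' @param rank optional precomputed rank vector (overrides
#'   `decoding_order`; ties allowed for tied groups).
#' @param training enable dropout.
#' @param P parameter override (training).
#' @return list with `logits` and `log_probs`, both `[L x 21]`.
#' @export
decode_logits <- function(model, encoded, S, decoding_order = NULL,
                          rank = NULL, training = FALSE, P = NULL) {
  if (is.null(P)) P <- model$params
  cfg <- model$config
  e_idx <- encoded$e_idx
  L <- nrow(e_idx); K <- ncol(e_idx)
  if (is.null(rank)) {
    if (is.null(decoding_order)) stop("supply decoding_order or rank")
    rank <- order_to_rank(decoding_order)
  }
  stopifnot(length(S) == L, all(S >= 1 & S <= cfg$alphabet_size))
  j_flat <- as.vector(t(e_idx))
  ca <- .causal_mask_flat(e_idx, rank)

  h_S <- ag_gather(P[["W_s.W"]], S)                   # [L x m] embedding
  h_S_j <- ag_gather(h_S, j_flat)
  e <- encoded$e
  h_V <- encoded$h_V
  h_V_enc_j <- ag_gather(h_V, j_flat)
  zeros <- matrix(0, L * K, cfg$m)
  # encoder-only fallback features for not-yet-decoded neighbors
  h_EXV <- ag_concat(e, zeros, h_V_enc_j)
  h_EXV_fw <- ag_mulconst(h_EXV, 1 - ca)
  h_ES <- ag_concat(e, h_S_j)
  mask <- encoded$features$mask
  mask_attend <- encoded$features$mask_attend
  for (l in seq_len(cfg$num_dec_layers)) {
    h_V_j <- ag_gather(h_V, j_flat)
    h_ESV <- ag_concat(h_ES, h_V_j)
    h_ESV <- ag_add(ag_mulconst(h_ESV, ca), h_EXV_fw)
    h_V <- dec_layer(P, sprintf("dec%d", l), h_V, h_ESV, B = K,
                     mask = mask, mask_attend = mask_attend,
                     cfg = cfg, training = training)
  }
  logits <- .lin(P, "W_out", h_V)
  list(logits = logits, log_probs = ag_logsoftmax(logits))
}
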