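# Parameter store construction and the three message-passing layer types.
#
# All layer functions run on plain matrices (eval mode) or autograd nodes
# (training) transparently; parameters are looked up in a named list `P`
# whose entries are arrays or `ag_node`s.

#' Model configuration
#'
#' @param m hidden width.
#' @param num_enc_layers protein encoder layers.
#' @param num_ctx_layers protein-ligand encoder blocks.
#' @param num_dec_layers sequence decoder layers.
#' @param dropout_p dropout probability (training only).
#' @param msg_scale message-sum scaling constant `s`.
#' @param ffn_width position-wise feed-forward hidden width (4 m by default).
#' @param alphabet_size sequence alphabet size.
#' @return list of class `model_config`.
#' @export
model_config <- function(m = 128L, num_enc_layers = 3L, num_ctx_layers = 2L,
                         num_dec_layers = 3L, dropout_p = 0.1,
                         msg_scale = 30.0, ffn_width = 4L * m,
                         alphabet_size = 21L) {
  stopifnot(m >= 1, num_enc_layers >= 1, num_dec_layers >= 1,
            msg_scale > 0, dropout_p >= 0, dropout_p < 1)
  structure(list(m = as.integer(m),
                 num_enc_layers = as.integer(num_enc_layers),
                 num_ctx_layers = as.integer(num_ctx_layers),
                 num_dec_layers = as.integer(num_dec_layers),
                 dropout_p = dropout_p, msg_scale = msg_scale,
                 ffn_width = as.integer(ffn_width),
                 alphabet_size = as.integer(alphabet_size)),
            class = "model_config")
}

# shape table: list(name = c(dims...)); `variant` controls which branches exist
.param_shapes <- function(config, feat, variant = c("full", "protein_only")) {
  variant <- match.arg(variant)
  m <- config$m; r <- feat$r; A <- config$alphabet_size
  ff <- config$ffn_width
  pe_w <- 2L * feat$max_offset + 2L
  sh <- list()
  add <- function(sh, name, dims) { sh[[name]] <- dims; sh }
  lin <- function(sh, name, din, dout, bias = TRUE) {
    sh <- add(sh, paste0(name, ".W"), c(din, dout))
    if (bias) sh <- add(sh, paste0(name, ".b"), dout)
    sh
  }
  norm <- function(sh, name) {
    sh <- add(sh, paste0(name, ".g"), m)
    add(sh, paste0(name, ".b"), m)
  }
  enc_layer <- function(sh, pre) {
    sh <- lin(sh, paste0(pre, ".W1"), 3L * m, m)
    sh <- lin(sh, paste0(pre, ".W2"), m, m)
    sh <- lin(sh, paste0(pre, ".W3"), m, m)
    sh <- lin(sh, paste0(pre, ".W11"), 3L * m, m)
    sh <- lin(sh, paste0(pre, ".W12"), m, m)
    sh <- lin(sh, paste0(pre, ".W13"), m, m)
    sh <- norm(sh, paste0(pre, ".norm1"))
    sh <- norm(sh, paste0(pre, ".norm2"))
    sh <- norm(sh, paste0(pre, ".norm3"))
    sh <- lin(sh, paste0(pre, ".ffn_in"), m, ff)
    lin(sh, paste0(pre, ".ffn_out"), ff, m)
  }
  dec_layer <- function(sh, pre, num_in) {
    sh <- lin(sh, paste0(pre, ".W1"), m + num_in, m)
    sh <- lin(sh, paste0(pre, ".W2"), m, m)
    sh <- lin(sh, paste0(pre, ".W3"), m, m)
    sh <- norm(sh, paste0(pre, ".norm1"))
    sh <- norm(sh, paste0(pre, ".norm2"))
    sh <- lin(sh, paste0(pre, ".ffn_in"), m, ff)
    lin(sh, paste0(pre, ".ffn_out"), ff, m)
  }
  encode_block <- function(sh, pre) {
    sh <- lin(sh, paste0(pre, "pos_enc"), pe_w, 16L)
    sh <- lin(sh, paste0(pre, "edge_embed"), 16L + 25L * r, m, bias = FALSE)
    sh <- norm(sh, paste0(pre, "norm_edges"))
    sh <- lin(sh, paste0(pre, "W_e"), m, m)
    for (l in seq_len(config$num_enc_layers))
      sh <- enc_layer(sh, sprintf("%senc%d", pre, l))
    if (variant == "full") {
      sh <- lin(sh, paste0(pre, "type_linear"), 147L, 64L)
      sh <- lin(sh, paste0(pre, "node_down"), 5L * r + 64L + 4L, m)
      sh <- norm(sh, paste0(pre, "norm_nodes"))
      sh <- lin(sh, paste0(pre, "y_nodes_embed"), 147L, m, bias = FALSE)
      sh <- norm(sh, paste0(pre, "norm_y_nodes"))
      sh <- lin(sh, paste0(pre, "y_edges_embed"), r, m, bias = FALSE)
      sh <- norm(sh, paste0(pre, "norm_y_edges"))
      sh <- lin(sh, paste0(pre, "W_v"), m, m)
      sh <- lin(sh, paste0(pre, "W_c"), m, m)
      sh <- lin(sh, paste0(pre, "W_nodes_y"), m, m)
      sh <- lin(sh, paste0(pre, "W_edges_y"), m, m)
      sh <- lin(sh, paste0(pre, "V_C"), m, m, bias = FALSE)
      sh <- norm(sh, paste0(pre, "V_C_norm"))
      for (l in seq_len(config$num_ctx_layers)) {
        sh <- dec_layer(sh, sprintf("%sctxy%d", pre, l), m)       # atom graph
        sh <- dec_layer(sh, sprintf("%sctx%d", pre, l), 2L * m)   # protein-ligand
      }
    }
    sh
  }
  sh <- encode_block(sh, "")
  sh <- add(sh, "W_s.W", c(A, m))
  for (l in seq_len(config$num_dec_layers))
    sh <- dec_layer(sh, sprintf("dec%d", l), 3L * m)
  sh <- lin(sh, "W_out", m, A)
  sh
}

# packer shapes: two independent encoder stacks + sequence-aware decoder +
# torsion head (4 chis x 3 components x {mean, concentration, mixing logit})
.packer_shapes <- function(config, feat, variant = "full") {
  m <- config$m; A <- config$alphabet_size
  base <- function(pre) {
    cfg <- config
    sh <- list()
    # reuse .param_shapes encode machinery by building a full table and
    # keeping only the encoder entries, prefixed
    all <- .param_shapes(cfg, feat, variant)
    keep <- !grepl("^(W_s\\.|dec[0-9]+\\.|W_out\\.)", names(all))
    out <- all[keep]
    names(out) <- paste0(pre, names(out))
    out
  }
  sh <- c(base("a."), base("b."))
  sh[["W_s.W"]] <- c(A, m)
  ff <- config$ffn_width
  for (l in seq_len(config$num_dec_layers)) {
    pre <- sprintf("dec%d", l)
    sh[[paste0(pre, ".W1.W")]] <- c(4L * m, m); sh[[paste0(pre, ".W1.b")]] <- m
    sh[[paste0(pre, ".W2.W")]] <- c(m, m); sh[[paste0(pre, ".W2.b")]] <- m
    sh[[paste0(pre, ".W3.W")]] <- c(m, m); sh[[paste0(pre, ".W3.b")]] <- m
    sh[[paste0(pre, ".norm1.g")]] <- m; sh[[paste0(pre, ".norm1.b")]] <- m
    sh[[paste0(pre, ".norm2.g")]] <- m; sh[[paste0(pre, ".norm2.b")]] <- m
    sh[[paste0(pre, ".ffn_in.W")]] <- c(m, ff); sh[[paste0(pre, ".ffn_in.b")]] <- ff
    sh[[paste0(pre, ".ffn_out.W")]] <- c(ff, m); sh[[paste0(pre, ".ffn_out.b")]] <- m
  }
  sh[["W_torsion.W"]] <- c(m, 36L); sh[["W_torsion.b"]] <- 36L
  sh
}

# Xavier-uniform for weight matrices, zeros for biases, ones/zeros for norms
.init_params <- function(shapes, seed = 1L) {
  set.seed(seed)
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    if (grepl("\\.W$", nm) && length(d) == 2) {
      lim <- sqrt(6 / (d[1] + d[2]))
      out[[nm]] <- matrix(stats::runif(prod(d), -lim, lim), d[1], d[2])
    } else if (grepl("\\.g$", nm)) {
      out[[nm]] <- rep(1, d)
    } else {
      out[[nm]] <- rep(0, d)       # biases and norm betas
    }
  }
  out
}

#' Count trainable parameters of the architecture
#'
#' @param config a [model_config].
#' @param feat a [feature_config].
#' @param variant `"full"` (ligand-aware), `"protein_only"` (ligand
#'   featurization and protein-ligand encoder removed) or `"packer"`.
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(config = model_config(),
                             feat = feature_config(),
                             variant = c("full", "protein_only", "packer")) {
  variant <- match.arg(variant)
  sh <- if (variant == "packer") .packer_shapes(config, feat)
        else .param_shapes(config, feat, variant)
  sum(vapply(sh, prod, numeric(1)))
}

## ---- layer forward functions ----------------------------------------------

.lin <- function(P, name, x, bias = TRUE) {
  y <- ag_matmul(x, P[[paste0(name, ".W")]])
  if (bias) y <- ag_addbias(y, P[[paste0(name, ".b")]])
  y
}

.norm <- function(P, name, x) {
  ag_layernorm(x, P[[paste0(name, ".g")]], P[[paste0(name, ".b")]])
}

.ffn <- function(P, pre, x) {
  .lin(P, paste0(pre, ".ffn_out"), ag_gelu(.lin(P, paste0(pre, ".ffn_in"), x)))
}

#' Encoder layer: update nodes and edges on the protein graph
#'
#' Messages are a 3-layer MLP of `(v_i, v_j, e_ij)` summed over neighbors and
#' scaled by `1/s`; node update is residual + LayerNorm followed by a
#' position-wise FFN; the edge update repeats the message pattern without an
#' FFN. Masked residues contribute zero messages and carry zero node states.
#'
#' @param P parameter list; `pre` layer name prefix.
#' @param v node states `[L x m]`; `e` edge states `[(L K) x m]`.
#' @param e_idx neighbor indices `[L x K]`.
#' @param mask,mask_attend residue validity and per-edge source validity.
#' @param cfg a [model_config]; `training` enables dropout.
#' @return list `(v, e)`.
#' @keywords internal
#' @export
enc_layer <- function(P, pre, v, e, e_idx, mask, mask_attend, cfg,
                      training = FALSE) {
  L <- nrow(e_idx); K <- ncol(e_idx)
  i_flat <- rep(seq_len(L), each = K)
  j_flat <- as.vector(t(e_idx))
  p <- cfg$dropout_p; s <- cfg$msg_scale
  vi <- ag_gather(v, i_flat)
  vj <- ag_gather(v, j_flat)
  q <- ag_concat(vi, vj, e)
  q <- .lin(P, paste0(pre, ".W3"),
            ag_gelu(.lin(P, paste0(pre, ".W2"),
                         ag_gelu(.lin(P, paste0(pre, ".W1"), q)))))
  q <- ag_mulconst(q, mask_attend)
  dh <- ag_scale(ag_sumblocks(q, L, K), 1 / s)
  v <- .norm(P, paste0(pre, ".norm1"), ag_add(v, ag_dropout(dh, p, training)))
  dh <- .ffn(P, pre, v)
  v <- .norm(P, paste0(pre, ".norm2"), ag_add(v, ag_dropout(dh, p, training)))
  v <- ag_mulconst(v, mask)
  vi <- ag_gather(v, i_flat)
  vj <- ag_gather(v, j_flat)
  q <- ag_concat(vi, vj, e)
  q <- .lin(P, paste0(pre, ".W13"),
            ag_gelu(.lin(P, paste0(pre, ".W12"),
                         ag_gelu(.lin(P, paste0(pre, ".W11"), q)))))
  e <- .norm(P, paste0(pre, ".norm3"), ag_add(e, ag_dropout(q, p, training)))
  list(v = v, e = e)
}

#' Decoder layer: node-only update from packed edge features
#'
#' Generic over the neighbor dimension: `edges` holds `B` packed neighbor
#' features per node (row `(i-1) B + k`), messages are MLP of `(v_i, e_ik)`.
#'
#' @param v `[L x m]`; `edges` `[(L B) x w]`.
#' @param B neighbors per node.
#' @param mask node validity (length L); `mask_attend` per-edge validity
#'   (length L B) or NULL.
#' @return updated `v`.
#' @keywords internal
#' @export
dec_layer <- function(P, pre, v, edges, B, mask, mask_attend, cfg,
                      training = FALSE) {
  L <- nrow(ag_value(v))
  p <- cfg$dropout_p; s <- cfg$msg_scale
  vi <- ag_gather(v, rep(seq_len(L), each = B))
  q <- ag_concat(vi, edges)
  q <- .lin(P, paste0(pre, ".W3"),
            ag_gelu(.lin(P, paste0(pre, ".W2"),
                         ag_gelu(.lin(P, paste0(pre, ".W1"), q)))))
  if (!is.null(mask_attend)) q <- ag_mulconst(q, mask_attend)
  dh <- ag_scale(ag_sumblocks(q, L, B), 1 / s)
  v <- .norm(P, paste0(pre, ".norm1"), ag_add(v, ag_dropout(dh, p, training)))
  dh <- .ffn(P, pre, v)
  v <- .norm(P, paste0(pre, ".norm2"), ag_add(v, ag_dropout(dh, p, training)))
  if (!is.null(mask)) v <- ag_mulconst(v, mask)
  v
}

#' Context (atom-graph) layer: per-residue fully connected atom updates
#'
#' Nodes are the `M` context atoms of each residue (`[(L M) x m]`), edges the
#' `M x M` atom-atom features (`[(L M M) x m]`); masked atoms are excluded
#' from sums and carry zero states.
#'
#' @return updated atom node states `[(L M) x m]`.
#' @keywords internal
#' @export
context_dec_layer <- function(P, pre, v, edges, M, Y_m_flat, Ym_edges, cfg,
                              training = FALSE) {
  dec_layer(P, pre, v, edges, B = M, mask = Y_m_flat,
            mask_attend = Ym_edges, cfg = cfg, training = training)
}
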