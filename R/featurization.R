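# Invariant featurization of a backbone plus context atoms into the three
# graphs consumed by the network: a K-nearest-neighbor protein graph with 25
# atom-pair RBF channels per edge, a per-residue fully connected ligand-atom
# graph, and the protein-ligand graph (per-residue M nearest context atoms).

#' Featurization configuration
#'
#' @param K protein nearest neighbors per residue.
#' @param M context atoms per residue.
#' @param r number of radial basis functions.
#' @param m hidden width of learned projections.
#' @param max_offset cap on residue-index offsets in positional encodings.
#' @param noise_level Gaussian coordinate noise standard deviation, Angstrom.
#' @param rbf_min,rbf_max RBF center range, Angstrom.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(K = 32L, M = 25L, r = 16L, m = 128L,
                           max_offset = 32L, noise_level = 0.1,
                           rbf_min = 2, rbf_max = 22) {
  stopifnot(K >= 1, M >= 1, r >= 1, m >= 1, noise_level >= 0,
            rbf_max > rbf_min)
  structure(list(K = as.integer(K), M = as.integer(M), r = as.integer(r),
                 m = as.integer(m), max_offset = as.integer(max_offset),
                 noise_level = noise_level, rbf_min = rbf_min,
                 rbf_max = rbf_max),
            class = "feature_config")
}

#' Gaussian radial basis encoding of distances
#'
#' `r` Gaussians with centers evenly spaced on `[rbf_min, rbf_max]` and
#' width `sigma = (rbf_max - rbf_min) / r`.
#'
#' @param d numeric vector of distances (>= 0), Angstrom.
#' @param config a [feature_config].
#' @return numeric matrix `[length(d) x r]`.
#' @export
rbf_encode <- function(d, config = feature_config()) {
  centers <- seq(config$rbf_min, config$rbf_max, length.out = config$r)
  sigma <- (config$rbf_max - config$rbf_min) / config$r
  exp(-((outer(d, centers, "-")) / sigma)^2)
}

#' Relative-position encoding indices and one-hot
#'
#' Same-chain residue pairs encode `clip(offset + max_offset, 0, 2 max_offset)`;
#' cross-chain pairs map to the dedicated index `2 max_offset + 1` regardless
#' of offset. Width is `2 max_offset + 2`; a learned linear layer in the model
#' projects the one-hot to 16 channels.
#'
#' @param offset integer matrix/vector of index differences `i - j`.
#' @param same_chain 0/1 of the same shape.
#' @param max_offset clipping bound.
#' @return list with `index` (0-based category per entry) and `onehot`
#'   (`[n x (2 max_offset + 2)]`).
#' @export
positional_encoding <- function(offset, same_chain, max_offset = 32L) {
  off <- as.numeric(offset)
  sc <- as.numeric(same_chain)
  d <- sc * pmin(pmax(off + max_offset, 0), 2 * max_offset)
  f <- (1 - sc) * (2 * max_offset + 1)
  g <- as.integer(d + f)
  width <- 2L * max_offset + 2L
  onehot <- matrix(0, length(g), width)
  onehot[cbind(seq_along(g), g + 1L)] <- 1
  list(index = g, onehot = onehot)
}

# backbone with NA rows replaced by zeros (masked residues are inert anyway)
.clean_backbone <- function(structure) {
  bb <- structure$backbone
  bb[!is.finite(bb)] <- 0
  bb
}

#' K-nearest-neighbor protein graph
#'
#' Neighbors by CA-CA distance (self included), ties broken by lower residue
#' index; `K` is capped at `L`.
#'
#' @param structure a [protein_structure].
#' @param config a [feature_config].
#' @return list with `e_idx` (`[L x K_eff]` 1-based), `K_eff`, and the raw
#'   edge features `rbf_edges` (`[(L K_eff) x 25 r]`, edge (i,k) at row
#'   `(i-1) K_eff + k`), `pos_onehot` (`[(L K_eff) x (2 max_offset + 2)]`),
#'   `offset` and `same_chain` matrices.
#' @export
build_protein_graph <- function(structure, config = feature_config()) {
  bb <- .clean_backbone(structure)
  L <- dim(bb)[1]
  K <- min(config$K, L)
  ca <- bb[, 2, , drop = FALSE]; dim(ca) <- c(L, 3)
  d2 <- outer(rowSums(ca^2), rowSums(ca^2), "+") - 2 * tcrossprod(ca)
  d2[d2 < 0] <- 0
  e_idx <- matrix(0L, L, K)
  for (i in seq_len(L)) {
    e_idx[i, ] <- order(d2[i, ], seq_len(L))[seq_len(K)]
  }
  i_flat <- rep(seq_len(L), each = K)
  j_flat <- as.vector(t(e_idx))

  n <- bb[, 1, ]; cam <- bb[, 2, ]; cm <- bb[, 3, ]; o <- bb[, 4, ]
  if (L == 1) { n <- rbind(n); cam <- rbind(cam); cm <- rbind(cm); o <- rbind(o) }
  cb <- virtual_cbeta(n, cam, cm)
  atoms <- list(n, cam, cm, o, cb)
  blocks <- vector("list", 25L)
  bi <- 0L
  for (a in 1:5) {
    for (b in 1:5) {
      bi <- bi + 1L
      dv <- sqrt(rowSums((atoms[[a]][i_flat, , drop = FALSE] -
                          atoms[[b]][j_flat, , drop = FALSE])^2))
      blocks[[bi]] <- rbf_encode(dv, config)
    }
  }
  rbf_edges <- do.call(cbind, blocks)

  offset <- matrix(structure$residue_index[i_flat] -
                   structure$residue_index[j_flat], L, K, byrow = TRUE)
  same_chain <- matrix(as.numeric(structure$chain_labels[i_flat] ==
                                  structure$chain_labels[j_flat]),
                       L, K, byrow = TRUE)
  pe <- positional_encoding(as.vector(t(offset)), as.vector(t(same_chain)),
                            config$max_offset)
  list(e_idx = e_idx, K_eff = K, rbf_edges = rbf_edges,
       pos_onehot = pe$onehot, offset = offset, same_chain = same_chain)
}

#' Select the M nearest context atoms per residue
#'
#' Distances from each residue's virtual C-beta; unmasked slots are sorted by
#' ascending distance, missing slots are mask-zero.
#'
#' @param structure a [protein_structure].
#' @param context a [context_atoms].
#' @param config a [feature_config].
#' @return list of class `residue_context` with `Y` (`[L x M x 3]`),
#'   `Y_m` (`[L x M]` 0/1) and `Y_t` (`[L x M]` atomic numbers, 0 at masked
#'   slots).
#' @export
select_context_atoms <- function(structure, context, config = feature_config()) {
  bb <- .clean_backbone(structure)
  L <- dim(bb)[1]
  M <- config$M
  Y <- array(0, c(L, M, 3))
  Y_m <- matrix(0, L, M)
  Y_t <- matrix(0L, L, M)
  na <- nrow(context$coords)
  if (na > 0) {
    n <- bb[, 1, ]; cam <- bb[, 2, ]; cm <- bb[, 3, ]
    if (L == 1) { n <- rbind(n); cam <- rbind(cam); cm <- rbind(cm) }
    cb <- virtual_cbeta(n, cam, cm)
    take <- min(M, na)
    for (i in seq_len(L)) {
      dv <- sqrt(colSums((t(context$coords) - cb[i, ])^2))
      ord <- order(dv, seq_len(na))[seq_len(take)]
      Y[i, seq_len(take), ] <- context$coords[ord, , drop = FALSE]
      Y_m[i, seq_len(take)] <- 1
      Y_t[i, seq_len(take)] <- context$element[ord]
    }
  }
  structure(list(Y = Y, Y_m = Y_m, Y_t = Y_t, M = M),
            class = "residue_context")
}

# one-hot of element identity (120) + group (19) + period (8) = 147 channels
.element_onehot <- function(Y_t_flat) {
  n <- length(Y_t_flat)
  out <- matrix(0, n, 147)
  live <- which(Y_t_flat >= 1L)
  if (length(live)) {
    z <- pmin(as.integer(Y_t_flat[live]), 118L)
    gp <- element_group_period(z)
    out[cbind(live, pmin(z, 120L))] <- 1
    out[cbind(live, 120L + gp$group + 1L)] <- 1          # groups 0..18
    out[cbind(live, 139L + pmin(gp$period, 8L))] <- 1    # periods 1..8
  }
  out
}

# sin/cos of azimuth and polar angle of each context atom in the residue's
# orthonormal N-CA-C frame (origin CA); zero for masked slots
.context_angles <- function(n, ca, c, Y, Y_m) {
  L <- nrow(ca); M <- dim(Y)[2]
  e1 <- .vunit(n - ca)
  e3 <- .vunit(.vcross(n - ca, c - ca))
  e2 <- .vcross(e3, e1)
  out <- matrix(0, L * M, 4)
  for (i in seq_len(L)) {
    for (j in seq_len(M)) {
      if (Y_m[i, j] == 0) next
      d <- Y[i, j, ] - ca[i, ]
      nd <- sqrt(sum(d^2))
      if (nd < 1e-9) next
      x <- sum(d * e1[i, ]); y <- sum(d * e2[i, ]); z <- sum(d * e3[i, ])
      az <- atan2(y, x)
      pol <- acos(max(-1, min(1, z / nd)))
      out[(i - 1) * M + j, ] <- c(sin(az), cos(az), sin(pol), cos(pol))
    }
  }
  out
}

#' Raw context features (ligand-graph and protein-ligand-graph inputs)
#'
#' @param structure a [protein_structure].
#' @param residue_context output of [select_context_atoms()].
#' @param config a [feature_config].
#' @return list with `ctx_rbf` (`[(L M) x 5 r]`, N/CA/C/O/virtual-CB to atom
#'   distances), `ctx_onehot` (`[(L M) x 147]` element/group/period),
#'   `ctx_angles` (`[(L M) x 4]`), `yedges_rbf` (`[(L M M) x r]`, atom-atom
#'   distances with row (i,j,k) at `((i-1) M + j - 1) M + k`), plus the flat
#'   masks `Y_m_flat` and `Ym_edges`.
#' @export
context_features <- function(structure, residue_context,
                             config = feature_config()) {
  bb <- .clean_backbone(structure)
  L <- dim(bb)[1]
  M <- residue_context$M
  Y <- residue_context$Y
  Y_m <- residue_context$Y_m
  n <- bb[, 1, ]; cam <- bb[, 2, ]; cm <- bb[, 3, ]; o <- bb[, 4, ]
  if (L == 1) { n <- rbind(n); cam <- rbind(cam); cm <- rbind(cm); o <- rbind(o) }
  cb <- virtual_cbeta(n, cam, cm)
  atoms <- list(n, cam, cm, o, cb)
  Yf <- matrix(aperm(Y, c(2, 1, 3)), L * M, 3)   # row (i,j) = (i-1)*M + j
  i_of <- rep(seq_len(L), each = M)
  blocks <- lapply(atoms, function(a) {
    dv <- sqrt(rowSums((a[i_of, , drop = FALSE] - Yf)^2))
    rbf_encode(dv, config)
  })
  ctx_rbf <- do.call(cbind, blocks)
  ctx_onehot <- .element_onehot(as.vector(t(residue_context$Y_t)))
  ctx_angles <- .context_angles(n, cam, cm, Y, Y_m)

  # atom-atom distances within each residue's context set
  jj <- rep(seq_len(M), each = M)
  kk <- rep(seq_len(M), times = M)
  yer <- matrix(0, L * M * M, config$r)
  for (i in seq_len(L)) {
    Yi <- matrix(Y[i, , ], M, 3)
    dv <- sqrt(rowSums((Yi[jj, , drop = FALSE] - Yi[kk, , drop = FALSE])^2))
    yer[((i - 1) * M * M) + seq_len(M * M), ] <- rbf_encode(dv, config)
  }
  Y_m_flat <- as.vector(t(Y_m))
  Ym_edges <- numeric(L * M * M)
  for (i in seq_len(L)) {
    mi <- Y_m[i, ]
    Ym_edges[((i - 1) * M * M) + seq_len(M * M)] <- mi[jj] * mi[kk]
  }
  list(ctx_rbf = ctx_rbf, ctx_onehot = ctx_onehot, ctx_angles = ctx_angles,
       yedges_rbf = yer, Y_m_flat = Y_m_flat, Ym_edges = Ym_edges)
}

#' Add i.i.d. Gaussian noise to all coordinates
#'
#' Training-time augmentation (0.1 Angstrom by default in the training
#' configuration); `noise_level = 0` returns the inputs unchanged.
#'
#' @param structure a [protein_structure].
#' @param context a [context_atoms].
#' @param noise_level standard deviation, Angstrom.
#' @param rng_seed optional integer seed.
#' @return list with noised `structure` and `context` copies.
#' @export
add_coordinate_noise <- function(structure, context, noise_level,
                                 rng_seed = NULL) {
  stopifnot(noise_level >= 0)
  if (noise_level == 0) return(list(structure = structure, context = context))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  bb <- structure$backbone
  fin <- is.finite(bb)
  bb[fin] <- bb[fin] + stats::rnorm(sum(fin), 0, noise_level)
  structure$backbone <- bb
  if (length(context$element)) {
    context$coords <- context$coords +
      matrix(stats::rnorm(length(context$coords), 0, noise_level),
             nrow(context$coords), 3)
  }
  list(structure = structure, context = context)
}

#' Full raw featurization bundle
#'
#' Convenience wrapper running [build_protein_graph()],
#' [select_context_atoms()] and [context_features()]; the learned projections
#' (positional-encoding linear, edge/node embeddings) live in the model.
#'
#' @param structure a [protein_structure].
#' @param context a [context_atoms] (may be empty).
#' @param config a [feature_config].
#' @return list of class `pocket_features`.
#' @export
featurize <- function(structure, context = context_atoms(),
                      config = feature_config()) {
  g <- build_protein_graph(structure, config)
  rc <- select_context_atoms(structure, context, config)
  cf <- context_features(structure, rc, config)
  L <- length(structure$sequence)
  mask <- as.numeric(structure$residue_mask)
  j_flat <- as.vector(t(g$e_idx))
  mask_attend <- mask[rep(seq_len(L), each = g$K_eff)] * mask[j_flat]
  structure(c(g, cf,
              list(residue_context = rc, L = L, M = rc$M, mask = mask,
                   mask_attend = mask_attend, config = config)),
            class = "pocket_features")
}
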