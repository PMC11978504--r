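# Sidechain packing head: twin encoder stacks, a sequence-aware decoder and a
# von Mises (circular normal) mixture over each of the four chi angles
# (3 components x {mean, concentration, mixing logit} = 36 raw outputs per
# residue). Chi angles are decoded stage by stage (all chi1, then chi2, ...);
# atoms placed by earlier stages re-enter as protein_sidechain context.

#' Initialize a sidechain-packing model
#'
#' @param config a [model_config].
#' @param feat a [feature_config].
#' @param seed integer initialization seed.
#' @return object of class `pocket_packer`.
#' @export
init_packer <- function(config = model_config(), feat = feature_config(),
                        seed = 1L) {
  if (feat$m != config$m) feat$m <- config$m
  shapes <- .packer_shapes(config, feat)
  params <- .init_params(shapes, seed)
  structure(list(params = params, config = config, feat = feat,
                 variant = "packer", seed = seed),
            class = "pocket_packer")
}

#' @export
print.pocket_packer <- function(x, ...) {
  cat(sprintf("pocket_packer: m=%d, %.2fM parameters\n", x$config$m,
              sum(vapply(x$params, length, 1L)) / 1e6))
  invisible(x)
}

# raw forward: torsion head outputs [L x 36]
.packer_forward <- function(packer, features, S, rank, training = FALSE,
                            P = NULL) {
  if (is.null(P)) P <- packer$params
  cfg <- packer$config
  stub <- list(config = cfg, variant = "packer", feat = packer$feat)
  enc_a <- model_encode(stub, features, training, P = P, prefix = "a.")
  enc_b <- model_encode(stub, features, training, P = P, prefix = "b.")
  e_idx <- features$e_idx
  L <- nrow(e_idx); K <- ncol(e_idx)
  j_flat <- as.vector(t(e_idx))
  ca <- .causal_mask_flat(e_idx, rank)
  h_S <- ag_gather(P[["W_s.W"]], S)
  h_S_j <- ag_gather(h_S, j_flat)
  h_V <- enc_a$h_V
  enc_fallback <- ag_mulconst(
    ag_concat(enc_a$e, matrix(0, L * K, cfg$m), ag_gather(enc_a$h_V, j_flat)),
    1 - ca)
  for (l in seq_len(cfg$num_dec_layers)) {
    h_V_j <- ag_gather(h_V, j_flat)
    edges <- ag_concat(enc_b$e, h_S_j, h_V_j)
    edges <- ag_add(ag_mulconst(edges, ca), enc_fallback)
    h_V <- dec_layer(P, sprintf("dec%d", l), h_V, edges, B = K,
                     mask = features$mask,
                     mask_attend = features$mask_attend,
                     cfg = cfg, training = training)
  }
  .lin(P, "W_torsion", h_V)
}

#' Predict per-residue chi-angle mixture distributions
#'
#' The 36 raw outputs per residue reshape to `[4 chis x 3 components x 3]`
#' (mean, raw concentration, mixing logit); concentrations are floored via
#' `0.1 + softplus`, means wrapped to `(-pi, pi]`.
#'
#' @param packer a `pocket_packer`.
#' @param structure a [protein_structure].
#' @param sequence integer tokens `[L]` (the designed/assigned sequence).
#' @param context a [context_atoms].
#' @param rank optional decoding-rank vector (default: random permutation
#'   seeded by `rng_seed`).
#' @param rng_seed integer seed for the decoding order.
#' @return object of class `torsion_mixture`: arrays `mean`, `concentration`,
#'   `mix_logits`, each `[L x 4 x 3]`, plus `chi_mask` `[L x 4]`.
#' @export
predict_torsion_distribution <- function(packer, structure, sequence,
                                         context = context_atoms(),
                                         rank = NULL, rng_seed = 1L) {
  L <- length(sequence)
  features <- featurize(structure, context, packer$feat)
  if (is.null(rank)) {
    set.seed(rng_seed)
    rank <- order_to_rank(sample.int(L))
  }
  raw <- ag_value(.packer_forward(packer, features, sequence, rank))
  torsion_mixture_from_raw(raw, sequence)
}

#' Build a torsion mixture from raw head outputs
#' @param raw numeric `[L x 36]`.
#' @param sequence integer tokens (for the per-residue chi validity mask).
#' @return a `torsion_mixture`.
#' @export
torsion_mixture_from_raw <- function(raw, sequence) {
  L <- nrow(raw)
  # columns of `raw` are chi-major: for chi k, component c, parameter p
  # (mean, raw concentration, mixing logit) at column ((k-1)*3+(c-1))*3+p
  mean <- array(0, c(L, 4, 3)); conc <- array(0, c(L, 4, 3))
  mixl <- array(0, c(L, 4, 3))
  for (k in 1:4) for (cc in 1:3) {
    base <- ((k - 1) * 3 + (cc - 1)) * 3
    mean[, k, cc] <- wrap_angle(raw[, base + 1])
    conc[, k, cc] <- 0.1 + .softplus(raw[, base + 2])
    mixl[, k, cc] <- raw[, base + 3]
  }
  nchi <- chi_count(sequence)
  chi_mask <- outer(nchi, 1:4, ">=")
  structure(list(mean = mean, concentration = conc, mix_logits = mixl,
                 chi_mask = chi_mask),
            class = "torsion_mixture")
}

.softplus <- function(x) {
  # overflow-safe log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' von Mises mixture density on the circle
#'
#' @param mixture a `torsion_mixture`.
#' @param i residue row; `k` chi index (1-4).
#' @param x angles (radians) at which to evaluate.
#' @return density values (integrates to 1 over any 2 pi window).
#' @export
torsion_density <- function(mixture, i, k, x) {
  mu <- mixture$mean[i, k, ]
  kap <- mixture$concentration[i, k, ]
  w <- exp(mixture$mix_logits[i, k, ] - max(mixture$mix_logits[i, k, ]))
  w <- w / sum(w)
  out <- numeric(length(x))
  for (cc in 1:3) {
    logI0 <- log(besselI(kap[cc], 0, expon.scaled = TRUE)) + kap[cc]
    out <- out + w[cc] * exp(kap[cc] * cos(x - mu[cc]) - log(2 * pi) - logI0)
  }
  out
}

#' Negative log-likelihood of observed chi angles under a torsion mixture
#'
#' Invariant to 2 pi shifts of the observations.
#'
#' @param mixture a `torsion_mixture`.
#' @param chis numeric `[L x 4]` observed angles (radians; NA ignored).
#' @return numeric `[L x 4]` per-chi NLL (NA where unobserved or invalid).
#' @export
torsion_nll <- function(mixture, chis) {
  L <- dim(mixture$mean)[1]
  out <- matrix(NA_real_, L, 4)
  for (i in seq_len(L)) for (k in 1:4) {
    if (!mixture$chi_mask[i, k] || is.na(chis[i, k])) next
    mu <- mixture$mean[i, k, ]
    kap <- mixture$concentration[i, k, ]
    ml <- mixture$mix_logits[i, k, ]
    lw <- ml - (max(ml) + log(sum(exp(ml - max(ml)))))
    logI0 <- log(besselI(kap, 0, expon.scaled = TRUE)) + kap
    comp <- lw + kap * cos(chis[i, k] - mu) - log(2 * pi) - logI0
    mx <- max(comp)
    out[i, k] <- -(mx + log(sum(exp(comp - mx))))
  }
  out
}

#' Sample from a von Mises distribution (Best-Fisher rejection)
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration (> 0).
#' @return numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  wrap_angle(out + mu)
}

# one chi draw (or mode) from a residue's stage-k mixture
.draw_chi <- function(mixture, i, k, mode) {
  w <- exp(mixture$mix_logits[i, k, ] - max(mixture$mix_logits[i, k, ]))
  w <- w / sum(w)
  if (mode == "mode") {
    mixture$mean[i, k, which.max(w)]
  } else {
    cc <- sample.int(3, 1, prob = w)
    rvonmises(1, mixture$mean[i, k, cc], mixture$concentration[i, k, cc])
  }
}

#' Decode full sidechain conformations stage by stage
#'
#' Four stages: all chi1 angles are decoded first, then chi2, chi3, chi4.
#' After each stage the newly placed sidechain atoms join the context set
#' (category `protein_sidechain`), context atoms are re-selected, and the
#' next stage is predicted conditioned on them. `mode = "mode"` takes the
#' highest-weight component mean; `mode = "sample"` draws from the mixture.
#'
#' @param packer a `pocket_packer`.
#' @param structure a [protein_structure].
#' @param sequence integer tokens.
#' @param context a [context_atoms] (ligand atoms; may be empty).
#' @param mode `"sample"` or `"mode"`.
#' @param rng_seed integer seed.
#' @return list of class `chi_set`: `chi` `[L x 4]` radians (NA where the
#'   residue has fewer chis), `chi_log_prob` `[L x 4]` (mixture log density
#'   at the emitted angle), `coords` `[L x 14 x 3]` full-atom coordinates.
#' @export
decode_sidechains <- function(packer, structure, sequence,
                              context = context_atoms(),
                              mode = c("sample", "mode"), rng_seed = 1L) {
  mode <- match.arg(mode)
  set.seed(rng_seed)
  L <- length(sequence)
  rank <- order_to_rank(sample.int(L))
  chis <- matrix(NA_real_, L, 4)
  nchi <- chi_count(sequence)
  coords <- array(NA_real_, c(L, 14, 3))
  chi_lp <- matrix(NA_real_, L, 4)

  place_all <- function() {
    for (i in seq_len(L)) {
      if (!structure$residue_mask[i]) next
      coords[i, , ] <<- chis_to_coords(sequence[i], structure$backbone[i, , ],
                                       chis[i, ])
    }
  }
  place_all()

  for (k in 1:4) {
    if (!any(nchi >= k)) next
    ctx_k <- concat_context(context, .placed_sidechain_context(sequence, coords))
    features <- featurize(structure, ctx_k, packer$feat)
    raw <- ag_value(.packer_forward(packer, features, sequence, rank))
    mixture <- torsion_mixture_from_raw(raw, sequence)
    for (i in seq_len(L)) {
      if (nchi[i] < k || !structure$residue_mask[i]) next
      chi <- .draw_chi(mixture, i, k, mode)
      chis[i, k] <- chi
      chi_lp[i, k] <- log(torsion_density(mixture, i, k, chi))
    }
    place_all()
  }
  structure(list(chi = chis, chi_log_prob = chi_lp, coords = coords,
                 chi_mask = outer(nchi, 1:4, ">="), sequence = sequence),
            class = "chi_set")
}

# already-placed sidechain atoms (beyond CB slot 5 onward incl. CB) as context
.placed_sidechain_context <- function(sequence, coords) {
  rows <- list()
  L <- dim(coords)[1]
  for (i in seq_len(L)) {
    nm <- atom14_names(sequence[i])
    if (length(nm) < 5) next
    for (a in 5:length(nm)) {
      xyz <- coords[i, a, ]
      if (all(is.finite(xyz))) {
        el <- element_number(substr(gsub("[0-9]", "", nm[a]), 1, 1))
        rows[[length(rows) + 1L]] <- c(xyz, el)
      }
    }
  }
  if (!length(rows)) return(context_atoms())
  mat <- do.call(rbind, rows)
  context_atoms(mat[, 1:3, drop = FALSE], mat[, 4],
                rep("protein_sidechain", nrow(mat)))
}
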