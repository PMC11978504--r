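# Shared test helpers: tiny models, tiny structures, independent oracles.

tiny_model_config <- function(m = 8L) {
  model_config(m = m, ffn_width = 4L * m, dropout_p = 0)
}

tiny_feature_config <- function(m = 8L, K = 4L, M = 3L) {
  feature_config(K = K, M = M, m = m)
}

tiny_fixture <- function(L = 10L, seed = 3L, ligand = list(
                           n_atoms = 3L, element = c("ZN", "C", "O"),
                           radius = 3, attach_residue = max(1L, L %/% 2L))) {
  spec <- fixture_spec(chain_length = L, rng_seed = seed, ligand = ligand)
  s <- make_backbone(spec)
  ctx <- make_context(spec, s)
  list(structure = s, context = ctx, spec = spec)
}

tiny_model <- function(variant = "full", m = 8L, seed = 2L, K = 4L, M = 3L) {
  init_model(tiny_model_config(m), tiny_feature_config(m, K, M), variant,
             seed = seed)
}

# minimal hand-built PDB text: n_res alanine-like residues + optional extras
make_pdb_lines <- function(residues, hetatoms = character(0)) {
  lines <- character(0)
  serial <- 0L
  for (r in seq_along(residues)) {
    res <- residues[[r]]
    for (a in seq_along(res$atoms)) {
      serial <- serial + 1L
      nm <- res$atoms[a]
      namef <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, namef, res$altloc %||% " ", res$resname, res$chain %||% "A",
        res$resseq, res$icode %||% " ",
        res$xyz[a, 1], res$xyz[a, 2], res$xyz[a, 3],
        res$occ %||% 1.0, 0.0,
        if (!is.null(res$elements)) res$elements[a] else substr(nm, 1, 1)))
    }
  }
  c(lines, hetatoms, "END")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a chemically sane two-residue backbone atom table
two_residue_atoms <- function() {
  bb1 <- rbind(c(0, 0, 0), c(1.458, 0, 0), c(2.009, 1.42, 0), c(1.40, 2.42, 0))
  bb2 <- rbind(c(3.32, 1.54, 0), c(4.31, 2.45, 0.3), c(5.66, 1.81, 0.5),
               c(6.66, 2.5, 0.6))
  list(list(atoms = c("N", "CA", "C", "O"), resname = "ALA", resseq = 1,
            xyz = bb1),
       list(atoms = c("N", "CA", "C", "O"), resname = "GLY", resseq = 2,
            xyz = bb2))
}

hetatm_line <- function(serial, name, resname, resseq, xyz, element,
                        chain = "B", occ = 1.0) {
  namef <- if (nchar(name) < 4 && nchar(element) == 1) sprintf(" %-3s", name)
           else sprintf("%-4s", name)
  sprintf("HETATM%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namef, " ", resname, chain, resseq, " ",
          xyz[1], xyz[2], xyz[3], occ, 0.0, toupper(element))
}

# independent NeRF used as a forward-kinematics oracle (distinct from the
# package implementation: rotation-matrix construction instead of frame math)
oracle_place <- function(a, b, c, bond, angle, dihedral) {
  u <- (c - b); u <- u / sqrt(sum(u^2))
  v <- (a - b); v <- v - sum(v * u) * u
  v <- v / sqrt(sum(v^2))
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  # dihedral 0 is cis to `a` (+v); positive dihedral rotates toward -w,
  # matching the IUPAC sign convention of dihedral_angle()
  d <- -cos(angle) * u + sin(angle) * (cos(dihedral) * v -
                                       sin(dihedral) * w)
  c + bond * d
}

# scalar-loop oracle for a full encoder layer (node + FFN + edge update),
# written with explicit loops, independent of the package's matrix code
oracle_enc_layer <- function(P, pre, v, e, e_idx, mask, mask_attend, cfg) {
  m <- ncol(v); L <- nrow(v); K <- ncol(e_idx)
  gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
  lnorm <- function(x, g, b) {
    mu <- mean(x); g * (x - mu) / sqrt(mean((x - mu)^2) + 1e-5) + b
  }
  lin <- function(x, nm) as.numeric(x %*% P[[paste0(nm, ".W")]] +
                                    P[[paste0(nm, ".b")]])
  pass <- function(vv, w1, w2, w3) {
    out <- matrix(0, L, m)
    for (i in seq_len(L)) for (k in seq_len(K)) {
      j <- e_idx[i, k]
      q <- c(vv[i, ], vv[j, ], e[(i - 1) * K + k, ])
      q <- gelu(lin(q, paste0(pre, ".", w1)))
      q <- gelu(lin(q, paste0(pre, ".", w2)))
      q <- lin(q, paste0(pre, ".", w3)) * mask_attend[(i - 1) * K + k]
      out[i, ] <- out[i, ] + q / cfg$msg_scale
    }
    out
  }
  dh <- pass(v, "W1", "W2", "W3")
  v2 <- t(vapply(seq_len(L), function(i) {
    lnorm(v[i, ] + dh[i, ], P[[paste0(pre, ".norm1.g")]],
          P[[paste0(pre, ".norm1.b")]])
  }, numeric(m)))
  v3 <- t(vapply(seq_len(L), function(i) {
    h <- gelu(lin(v2[i, ], paste0(pre, ".ffn_in")))
    lnorm(v2[i, ] + lin(h, paste0(pre, ".ffn_out")),
          P[[paste0(pre, ".norm2.g")]], P[[paste0(pre, ".norm2.b")]])
  }, numeric(m)))
  v3 <- v3 * mask
  e2 <- e
  for (i in seq_len(L)) for (k in seq_len(K)) {
    j <- e_idx[i, k]
    row <- (i - 1) * K + k
    q <- c(v3[i, ], v3[j, ], e[row, ])
    q <- gelu(lin(q, paste0(pre, ".W11")))
    q <- gelu(lin(q, paste0(pre, ".W12")))
    q <- lin(q, paste0(pre, ".W13"))
    e2[row, ] <- lnorm(e[row, ] + q, P[[paste0(pre, ".norm3.g")]],
                       P[[paste0(pre, ".norm3.b")]])
  }
  list(v = v3, e = e2)
}

# scalar-loop oracle for the message MLP + node update of a decoder-type
# layer (independent of the package's matrix implementation)
oracle_dec_layer <- function(P, pre, v, edges, B, mask, mask_attend, cfg) {
  m <- ncol(v)
  L <- nrow(v)
  s <- cfg$msg_scale
  gelu <- function(x) 0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
  lnorm <- function(x, g, b) {
    mu <- mean(x); sd2 <- mean((x - mu)^2)
    g * (x - mu) / sqrt(sd2 + 1e-5) + b
  }
  lin <- function(x, W, b) as.numeric(x %*% W + b)
  out <- v
  for (i in seq_len(L)) {
    dh <- rep(0, m)
    for (k in seq_len(B)) {
      row <- (i - 1) * B + k
      q <- c(v[i, ], edges[row, ])
      q <- gelu(lin(q, P[[paste0(pre, ".W1.W")]], P[[paste0(pre, ".W1.b")]]))
      q <- gelu(lin(q, P[[paste0(pre, ".W2.W")]], P[[paste0(pre, ".W2.b")]]))
      q <- lin(q, P[[paste0(pre, ".W3.W")]], P[[paste0(pre, ".W3.b")]])
      if (!is.null(mask_attend)) q <- q * mask_attend[row]
      dh <- dh + q / s
    }
    x <- lnorm(v[i, ] + dh, P[[paste0(pre, ".norm1.g")]],
               P[[paste0(pre, ".norm1.b")]])
    f <- lin(x, P[[paste0(pre, ".ffn_in.W")]], P[[paste0(pre, ".ffn_in.b")]])
    f <- lin(gelu(f), P[[paste0(pre, ".ffn_out.W")]],
             P[[paste0(pre, ".ffn_out.b")]])
    x <- lnorm(x + f, P[[paste0(pre, ".norm2.g")]],
               P[[paste0(pre, ".norm2.b")]])
    out[i, ] <- x * mask[i]
  }
  out
}
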