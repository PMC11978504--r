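# Synthetic fixtures: idealized backbones built from textbook dihedral
# presets, ligand atom clouds, and planted-rule datasets where sequence
# identity at some positions is a deterministic function of ligand proximity.

#' Fixture specification
#'
#' @param n_chains number of chains.
#' @param chain_length residues per chain.
#' @param ss secondary-structure preset: `"helix"` (phi -57, psi -47),
#'   `"strand"` (phi -119, psi 113) or `"mixed"` (random per-residue choice).
#' @param ligand list(n_atoms, element, radius, attach_residue) or NULL.
#' @param rng_seed integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_chains = 1L, chain_length = 20L, ss = "helix",
                         ligand = NULL, rng_seed = 1L) {
  stopifnot(n_chains >= 1, chain_length >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length), ss = ss,
                 ligand = ligand, rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

.SS_DIHEDRALS <- list(helix = c(phi = -57, psi = -47),
                      strand = c(phi = -119, psi = 113))

# ideal backbone internal coordinates (Engh-Huber-like)
.BB_GEOM <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
                 ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                 ang_ca_c_o = 120.1)

#' Build an idealized multi-chain backbone
#'
#' Sequential NeRF construction with ideal bond geometry and preset
#' phi/psi dihedrals (omega fixed at 180 degrees); consecutive CA-CA
#' distances come out at ~3.8 Angstrom. Chains are translated apart by
#' 40 Angstrom. The sequence is initialized to all-alanine.
#'
#' @param spec a [fixture_spec].
#' @return a [protein_structure].
#' @export
make_backbone <- function(spec = fixture_spec()) {
  set.seed(spec$rng_seed)
  g <- .BB_GEOM
  d2r <- pi / 180
  Lc <- spec$chain_length
  nch <- spec$n_chains
  total <- Lc * nch
  bb <- array(NA_real_, c(total, 4, 3))
  chain_labels <- rep(seq_len(nch), each = Lc)
  residue_index <- rep(seq_len(Lc), nch)
  for (ch in seq_len(nch)) {
    phi <- numeric(Lc); psi <- numeric(Lc)
    for (i in seq_len(Lc)) {
      pick <- if (identical(spec$ss, "mixed")) {
        sample(c("helix", "strand"), 1)
      } else spec$ss
      dh <- .SS_DIHEDRALS[[pick]]
      if (is.null(dh)) stop("unknown secondary-structure preset: ", spec$ss)
      phi[i] <- dh["phi"] * d2r; psi[i] <- dh["psi"] * d2r
    }
    offset <- c((ch - 1) * 40, 0, 0)
    N <- offset
    CA <- offset + c(g$n_ca, 0, 0)
    C <- place_atom(offset + c(0, 1, 0), N, CA, g$ca_c,
                    g$ang_n_ca_c * d2r, 77 * d2r)
    for (i in seq_len(Lc)) {
      row <- (ch - 1) * Lc + i
      bb[row, 1, ] <- N; bb[row, 2, ] <- CA; bb[row, 3, ] <- C
      bb[row, 4, ] <- place_atom(N, CA, C, g$c_o, g$ang_ca_c_o * d2r,
                                 psi[i] + pi)
      if (i < Lc) {
        N2 <- place_atom(N, CA, C, g$c_n, g$ang_ca_c_n * d2r, psi[i])
        CA2 <- place_atom(CA, C, N2, g$n_ca, g$ang_c_n_ca * d2r, pi)
        C2 <- place_atom(C, N2, CA2, g$ca_c, g$ang_n_ca_c * d2r, phi[i + 1])
        N <- N2; CA <- CA2; C <- C2
      }
    }
  }
  protein_structure(bb, residue_index, chain_labels,
                    rep(1L, total), rep(TRUE, total),
                    chain_ids = LETTERS[chain_labels])
}

#' Place a synthetic ligand near a backbone
#'
#' Metals are single atoms at the stated radius from the attach residue's
#' virtual C-beta; molecules are connected random clouds with 1.5 Angstrom
#' steps starting from that point.
#'
#' @param spec a [fixture_spec] whose `ligand` field holds
#'   `list(n_atoms, element, radius, attach_residue)`; element is a symbol
#'   or atomic number, recycled over atoms.
#' @param backbone a [protein_structure] from [make_backbone()].
#' @return a [context_atoms] (empty when the spec has no ligand).
#' @export
make_context <- function(spec, backbone) {
  lg <- spec$ligand
  if (is.null(lg) || (lg$n_atoms %||% 0) < 1) return(context_atoms())
  set.seed(spec$rng_seed + 1L)
  el <- lg$element
  if (is.character(el)) el <- element_number(el)
  el <- rep(as.integer(el), length.out = lg$n_atoms)
  at <- lg$attach_residue %||% sample.int(length(backbone$sequence), 1)
  cb <- virtual_cbeta(backbone$backbone[at, 1, ], backbone$backbone[at, 2, ],
                      backbone$backbone[at, 3, ])
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  coords <- matrix(0, lg$n_atoms, 3)
  coords[1, ] <- cb + (lg$radius %||% 3) * dir
  if (lg$n_atoms > 1) {
    for (a in 2:lg$n_atoms) {
      step <- stats::rnorm(3); step <- 1.5 * step / sqrt(sum(step^2))
      coords[a, ] <- coords[a - 1, ] + step
    }
  }
  category <- if (lg$n_atoms == 1 && is_metal_element(el[1])) "metal"
              else "small_molecule"
  context_atoms(coords, el, rep(category, lg$n_atoms))
}

#' Planted sequence rule
#'
#' Residues whose virtual C-beta lies within `trigger_radius` of any trigger
#' atom receive `forced_token`; all other positions draw from the background
#' distribution (optionally conditioned on spatial neighbor count via
#' `background_fn`).
#'
#' @param trigger_element element symbol or atomic number.
#' @param trigger_radius Angstrom (> 0).
#' @param forced_token integer token (default histidine).
#' @param background_tokens,background_probs background distribution.
#' @param background_fn optional `function(neighbor_count)` returning a
#'   probability vector over `background_tokens`.
#' @return list of class `planted_rule`.
#' @export
planted_rule <- function(trigger_element = "ZN", trigger_radius = 6.0,
                         forced_token = one_to_tokens("H"),
                         background_tokens = one_to_tokens(c("A", "L", "S", "E")),
                         background_probs = c(0.4, 0.3, 0.2, 0.1),
                         background_fn = NULL) {
  stopifnot(trigger_radius > 0,
            abs(sum(background_probs) - 1) < 1e-9,
            length(background_tokens) == length(background_probs))
  if (is.character(trigger_element)) trigger_element <- element_number(trigger_element)
  structure(list(trigger_element = as.integer(trigger_element),
                 trigger_radius = trigger_radius,
                 forced_token = as.integer(forced_token),
                 background_tokens = as.integer(background_tokens),
                 background_probs = background_probs,
                 background_fn = background_fn),
            class = "planted_rule")
}

# apply a planted rule to one structure + context; returns sequence + triggers
.apply_rule <- function(structure, context, rule) {
  L <- length(structure$sequence)
  bb <- structure$backbone
  cb <- virtual_cbeta(bb[, 1, ], bb[, 2, ], bb[, 3, ])
  trig <- which(context$element == rule$trigger_element)
  positions <- integer(0)
  if (length(trig) && rule$trigger_radius > 0) {
    tc <- context$coords[trig, , drop = FALSE]
    dmin <- sqrt(pmax(0, outer(rowSums(cb^2), rowSums(tc^2), "+") -
                        2 * tcrossprod(cb, tc)))
    dmin <- apply(matrix(dmin, nrow = L), 1, min)
    positions <- which(dmin <= rule$trigger_radius)
  }
  S <- integer(L)
  if (!is.null(rule$background_fn)) {
    ca <- matrix(bb[, 2, ], L, 3)
    dmat <- as.matrix(stats::dist(ca))
    ncount <- rowSums(dmat < 10) - 1L
    for (i in seq_len(L)) {
      pr <- rule$background_fn(ncount[i])
      S[i] <- sample(rule$background_tokens, 1, prob = pr)
    }
  } else {
    S <- sample(rule$background_tokens, L, replace = TRUE,
                prob = rule$background_probs)
  }
  S[positions] <- rule$forced_token
  list(sequence = S, trigger_positions = positions)
}

#' Generate a labelled planted-rule dataset
#'
#' Each entry is an idealized helix with one trigger atom placed near a
#' random residue; sequences are assigned by the rule. The train/held-out
#' split is by structure.
#'
#' @param n_structures total structures.
#' @param rule a [planted_rule].
#' @param seed integer seed.
#' @param chain_length residues per structure.
#' @param holdout_fraction share of structures held out.
#' @param placement_radius distance of the trigger atom from the chosen
#'   residue's virtual C-beta, Angstrom.
#' @return list with `train`, `test` (lists of entries carrying `structure`,
#'   `context`, `trigger_positions`, `id`) and `rule`.
#' @export
make_planted_dataset <- function(n_structures = 100L, rule = planted_rule(),
                                 seed = 1L, chain_length = 60L,
                                 holdout_fraction = 0.2,
                                 placement_radius = 2.5) {
  set.seed(seed)
  entries <- vector("list", n_structures)
  for (s in seq_len(n_structures)) {
    sseed <- seed + 1000L * s
    spec <- fixture_spec(chain_length = chain_length, ss = "helix",
                         rng_seed = sseed)
    str <- make_backbone(spec)
    set.seed(sseed + 1L)
    attach <- sample.int(chain_length, 1)
    spec$ligand <- list(n_atoms = 1L, element = rule$trigger_element,
                        radius = placement_radius, attach_residue = attach)
    ctx <- make_context(spec, str)
    set.seed(sseed + 2L)
    lab <- .apply_rule(str, ctx, rule)
    str$sequence <- lab$sequence
    entries[[s]] <- list(structure = str, context = ctx,
                         trigger_positions = lab$trigger_positions,
                         id = sprintf("planted_%03d", s))
  }
  n_test <- max(1L, round(holdout_fraction * n_structures))
  test_idx <- seq_len(n_test)                       # deterministic split
  list(train = entries[-test_idx], test = entries[test_idx], rule = rule)
}

#' Write a fixture structure (plus context) as a PDB file
#'
#' @param structure a [protein_structure].
#' @param context a [context_atoms].
#' @param path output path.
#' @return invisible `path`.
#' @export
write_fixture_pdb <- function(structure, context, path) {
  write_structure(structure, sidechain_coords = NULL, path = path,
                  context = context)
}
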