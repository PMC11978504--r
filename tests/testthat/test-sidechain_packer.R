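# Torsion mixtures, chi geometry round-trips, staged decoding.

tiny_packer <- function(seed = 3L, m = 8L) {
  init_packer(tiny_model_config(m), tiny_feature_config(m), seed = seed)
}

test_that("torsion head: concentration floor, wrapped means, normalization", {
  raw <- matrix(stats::rnorm(2 * 36, sd = 3), 2, 36)
  raw[1, 2] <- -1e9                      # raw concentration channel, chi1 comp1
  mix <- torsion_mixture_from_raw(raw, one_to_tokens(c("K", "S")))
  expect_equal(mix$concentration[1, 1, 1], 0.1)          # softplus saturates
  expect_true(all(mix$concentration > 0.1 - 1e-12))
  expect_true(all(mix$mean > -pi & mix$mean <= pi))
  expect_identical(unname(mix$chi_mask[1, ]), rep(TRUE, 4))      # LYS: 4 chis
  expect_identical(unname(mix$chi_mask[2, ]), c(TRUE, FALSE, FALSE, FALSE))

  # 1024-point quadrature: density integrates to 1 on the circle
  xs <- seq(-pi, pi, length.out = 1025)[-1025]
  for (k in 1:4) {
    dens <- torsion_density(mix, 1, k, xs)
    expect_equal(sum(dens) * 2 * pi / 1024, 1, tolerance = 1e-6)
  }
})

test_that("torsion_nll: minimum at a dominant mean, 2pi invariance, quadrature", {
  raw <- matrix(0, 1, 36)
  raw[1, 1] <- 1.2          # chi1 comp1 mean
  raw[1, 2] <- 5            # high concentration
  raw[1, 3] <- 10           # dominant mixing logit
  mix <- torsion_mixture_from_raw(raw, one_to_tokens("K"))
  grid <- seq(-pi, pi, length.out = 181)
  nlls <- vapply(grid, function(x) {
    torsion_nll(mix, matrix(c(x, NA, NA, NA), 1, 4))[1, 1]
  }, numeric(1))
  expect_equal(grid[which.min(nlls)], mix$mean[1, 1, 1], tolerance = 0.05)
  obs <- matrix(c(0.7, NA, NA, NA), 1, 4)
  obs2 <- obs; obs2[1, 1] <- 0.7 + 2 * pi
  expect_equal(torsion_nll(mix, obs)[1, 1], torsion_nll(mix, obs2)[1, 1],
               tolerance = 1e-9)
  # NLL matches the quadrature-normalized density directly
  dens <- torsion_density(mix, 1, 1, 0.7)
  expect_equal(torsion_nll(mix, obs)[1, 1], -log(dens), tolerance = 1e-9)
})

test_that("chi place-then-measure round-trips to 1e-6 rad for all residues", {
  fx <- tiny_fixture(L = 3, ligand = NULL)
  bb <- fx$structure$backbone[2, , ]
  for (one in c("S", "C", "T", "V", "I", "L", "M", "D", "N", "E", "Q",
                "K", "R", "H", "F", "Y", "W", "P")) {
    tok <- one_to_tokens(one)
    nchi <- chi_count(tok)
    set.seed(match(one, LETTERS))
    chis <- stats::runif(nchi, -pi, pi)
    c14 <- chis_to_coords(tok, bb, chis)
    got <- measure_chis(tok, c14)
    expect_equal(got[seq_len(nchi)], chis, tolerance = 1e-6,
                 label = paste("chi round-trip", one))
  }
})

test_that("reconstructed bonds match the ideal table within 0.01 A", {
  fx <- tiny_fixture(L = 2, ligand = NULL)
  bb <- fx$structure$backbone[1, , ]
  for (one in c("L", "K", "W", "Y", "R")) {
    tok <- one_to_tokens(one)
    chis <- stats::runif(chi_count(tok), -pi, pi)
    c14 <- chis_to_coords(tok, bb, chis)
    nm <- atom14_names(tok)
    tab <- ideal_bond_table(tok)
    for (row in seq_len(nrow(tab))) {
      a <- c14[match(tab$atom[row], nm), ]
      parent <- tab$parent[row]
      p <- if (parent %in% nm) c14[match(parent, nm), ] else bb[match(parent, c("N","CA","C","O")), ]
      expect_lt(abs(sqrt(sum((a - p)^2)) - tab$length[row]), 0.01)
    }
  }
})

test_that("LEU chi geometry matches an independent forward-kinematics oracle", {
  fx <- tiny_fixture(L = 2, ligand = NULL)
  bb <- fx$structure$backbone[1, , ]
  tok <- one_to_tokens("L")
  chis <- c(-60, 180) * pi / 180
  c14 <- chis_to_coords(tok, bb, chis)
  nm <- atom14_names(tok)
  # oracle: place CB, CG, CD1 with an independent NeRF implementation
  cb <- oracle_place(bb[3, ], bb[1, ], bb[2, ], 1.530, 110.4 * pi / 180,
                     122.6 * pi / 180)
  cg <- oracle_place(bb[1, ], bb[2, ], cb, 1.530, 116.3 * pi / 180, chis[1])
  cd1 <- oracle_place(bb[2, ], cb, cg, 1.521, 110.7 * pi / 180, chis[2])
  expect_equal(c14[match("CB", nm), ], cb, tolerance = 1e-6)
  expect_equal(c14[match("CG", nm), ], cg, tolerance = 1e-6)
  expect_equal(c14[match("CD1", nm), ], cd1, tolerance = 1e-6)
  # rotating the backbone rotates the sidechain identically
  tr <- random_rigid_transform(seed = 7)
  bb2 <- apply_rigid_transform(bb, tr)
  c14b <- chis_to_coords(tok, bb2, chis)
  live <- apply(is.finite(c14), 1, all)
  expect_equal(c14b[live, ], apply_rigid_transform(c14[live, ], tr),
               tolerance = 1e-8)
})

test_that("CB placement agrees with the virtual C-beta direction", {
  fx <- tiny_fixture(L = 3, ligand = NULL)
  bb <- fx$structure$backbone[2, , ]
  c14 <- chis_to_coords(one_to_tokens("A"), bb)
  vcb <- as.numeric(virtual_cbeta(bb[1, ], bb[2, ], bb[3, ]))
  expect_lt(sqrt(sum((c14[5, ] - vcb)^2)), 0.25)
})

test_that("decode_sidechains: chi-count table, staged feedback, sampling", {
  fx <- tiny_fixture(L = 5, seed = 8)
  pk <- tiny_packer()
  # all-GLY: nothing decoded
  gly <- rep(one_to_tokens("G"), 5)
  cs <- decode_sidechains(pk, fx$structure, gly, fx$context, mode = "mode")
  expect_true(all(is.na(cs$chi)))
  expect_true(all(is.na(cs$coords[, 5:14, ])))
  # SER decodes chi1 only
  ser <- rep(one_to_tokens("S"), 5)
  cs2 <- decode_sidechains(pk, fx$structure, ser, fx$context, mode = "mode")
  expect_true(all(is.finite(cs2$chi[, 1])))
  expect_true(all(is.na(cs2$chi[, 2:4])))
  # mixed sequence: valid chis finite, log-probs finite, geometry present
  mix <- one_to_tokens(c("K", "L", "F", "S", "R"))
  cs3 <- decode_sidechains(pk, fx$structure, mix, fx$context, mode = "sample",
                           rng_seed = 2)
  nchi <- chi_count(mix)
  for (i in 1:5) {
    expect_true(all(is.finite(cs3$chi[i, seq_len(nchi[i])])))
    expect_true(all(is.finite(cs3$chi_log_prob[i, seq_len(nchi[i])])))
  }
  # seeded determinism
  cs4 <- decode_sidechains(pk, fx$structure, mix, fx$context, mode = "sample",
                           rng_seed = 2)
  expect_identical(cs3$chi, cs4$chi)
})

test_that("sampled chi1 falls in the high-density support of its mixture", {
  # Monte-Carlo oracle: draws stay above the mixture's 1% density quantile
  set.seed(10)
  raw <- matrix(stats::rnorm(36, sd = 2), 1, 36)
  mixx <- torsion_mixture_from_raw(raw, one_to_tokens("S"))
  xs <- seq(-pi, pi, length.out = 1024)
  dens <- torsion_density(mixx, 1, 1, xs)
  q01 <- stats::quantile(dens, 0.01)
  draws <- vapply(1:1000, function(i) pocketdesign:::.draw_chi(mixx, 1, 1, "sample"),
                  numeric(1))
  d_at <- torsion_density(mixx, 1, 1, draws)
  expect_gt(mean(d_at >= q01), 0.95)
})

test_that("stage causality: neighbor chi1 atoms steer later-stage mixtures", {
  fx <- tiny_fixture(L = 4, seed = 6, ligand = NULL)
  pk <- tiny_packer()
  mixseq <- rep(one_to_tokens("K"), 4)
  rank <- order_to_rank(1:4)
  # place residue 2's gamma atoms at two different chi1 values and feed them
  # back as protein_sidechain context, as the staged decoder does
  ctx_of <- function(chi1) {
    coords <- array(NA_real_, c(4, 14, 3))
    coords[2, , ] <- chis_to_coords(mixseq[2], fx$structure$backbone[2, , ],
                                    c(chi1, NA, NA, NA))
    pocketdesign:::.placed_sidechain_context(mixseq, coords)
  }
  mix_a <- predict_torsion_distribution(pk, fx$structure, mixseq,
                                        ctx_of(-pi / 3), rank = rank)
  mix_b <- predict_torsion_distribution(pk, fx$structure, mixseq,
                                        ctx_of(+pi / 3), rank = rank)
  expect_false(isTRUE(all.equal(mix_a$mean[1, 2, ], mix_b$mean[1, 2, ])))
  # stage-1 chi values equal the stage-1 mixture read-out: chi1 never sees
  # any chi2 information because no later-stage atoms exist yet
  cs <- decode_sidechains(pk, fx$structure, mixseq, context_atoms(),
                          mode = "mode", rng_seed = 1)
  set.seed(1)
  rank1 <- order_to_rank(sample.int(4))
  # stage-1 context = the chi-independent CB atoms already placed
  coords0 <- array(NA_real_, c(4, 14, 3))
  for (i in 1:4) coords0[i, , ] <- chis_to_coords(mixseq[i],
                                                  fx$structure$backbone[i, , ])
  ctx1 <- pocketdesign:::.placed_sidechain_context(mixseq, coords0)
  mix1 <- predict_torsion_distribution(pk, fx$structure, mixseq,
                                       ctx1, rank = rank1)
  for (i in 1:4) {
    w <- mix1$mix_logits[i, 1, ]
    expect_equal(cs$chi[i, 1], mix1$mean[i, 1, which.max(w)],
                 tolerance = 1e-9)
  }
})

test_that("von Mises sampler matches its distribution moments", {
  set.seed(4)
  mu <- 1.1; kap <- 5
  draws <- rvonmises(4000, mu, kap)
  # circular mean near mu; mean resultant length near I1/I0(kappa)
  cm <- atan2(mean(sin(draws)), mean(cos(draws)))
  expect_lt(abs(atan2(sin(cm - mu), cos(cm - mu))), 0.05)
  R <- sqrt(mean(sin(draws))^2 + mean(cos(draws))^2)
  expect_lt(abs(R - besselI(kap, 1) / besselI(kap, 0)), 0.03)
})
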