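# Virtual C-beta, RBF, graph construction, context selection, invariances.

test_that("virtual C-beta: degenerate collapse, ideal length, equivariance", {
  p <- c(1.2, -0.3, 2.0)
  expect_equal(as.numeric(virtual_cbeta(p, p, p)), p)

  # ideal alanine backbone: independent evaluation of the printed formula
  n <- c(0, 0, 0); ca <- c(1.458, 0, 0)
  c_ <- ca + 1.525 * c(cos(pi - 111.2 * pi / 180), sin(pi - 111.2 * pi / 180), 0)
  b <- ca - n; cc <- c_ - ca
  cr <- c(b[2] * cc[3] - b[3] * cc[2], b[3] * cc[1] - b[1] * cc[3],
          b[1] * cc[2] - b[2] * cc[1])
  expected <- -0.5827 * cr + 0.5680 * b - 0.5407 * cc + ca
  got <- as.numeric(virtual_cbeta(n, ca, c_))
  expect_equal(got, expected)
  expect_true(abs(sqrt(sum((got - ca)^2)) - 1.5) < 0.1)

  tr <- random_rigid_transform(seed = 4)
  got2 <- as.numeric(virtual_cbeta(
    apply_rigid_transform(rbind(n), tr), apply_rigid_transform(rbind(ca), tr),
    apply_rigid_transform(rbind(c_), tr)))
  expect_equal(got2, as.numeric(apply_rigid_transform(rbind(got), tr)),
               tolerance = 1e-10)
})

test_that("RBF encoding peaks at centers and vanishes far out", {
  cfg <- feature_config()
  centers <- seq(cfg$rbf_min, cfg$rbf_max, length.out = cfg$r)
  at_center <- rbf_encode(centers[5], cfg)
  expect_identical(which.max(at_center), 5L)
  expect_equal(max(at_center), 1)
  expect_true(all(rbf_encode(200, cfg) < 1e-10))
  # scalar re-evaluation oracle at a mid-range distance
  d <- 7.3
  sigma <- (cfg$rbf_max - cfg$rbf_min) / cfg$r
  expect_equal(as.numeric(rbf_encode(d, cfg)),
               exp(-((d - centers) / sigma)^2))
})

test_that("positional encoding indices match the clip/offset arithmetic", {
  pe <- positional_encoding(0, 1)
  expect_identical(pe$index, 32L)
  expect_identical(which(pe$onehot[1, ] == 1), 33L)   # 0-based 32
  expect_identical(positional_encoding(17, 0)$index, 65L)
  expect_identical(positional_encoding(-500, 0)$index, 65L)
  expect_identical(positional_encoding(100, 1)$index, 64L)
  expect_identical(positional_encoding(-100, 1)$index, 0L)
  expect_identical(positional_encoding(-5, 1)$index, 27L)
})

test_that("protein graph: neighbor counts and brute-force top-k agreement", {
  fx <- tiny_fixture(L = 40, ligand = NULL)
  g <- build_protein_graph(fx$structure, feature_config(K = 32))
  expect_identical(dim(g$e_idx), c(40L, 32L))

  one <- tiny_fixture(L = 1, ligand = NULL)
  g1 <- build_protein_graph(one$structure, feature_config(K = 32))
  expect_identical(g1$e_idx, matrix(1L, 1, 1))        # self-neighbor fallback

  # O(L^2) oracle on a random backbone
  set.seed(8)
  L <- 20
  bb <- array(stats::rnorm(L * 4 * 3, sd = 5), c(L, 4, 3))
  s <- protein_structure(bb, 1:L, rep(1L, L), rep(1L, L), rep(TRUE, L))
  K <- 6L
  g2 <- build_protein_graph(s, feature_config(K = K))
  ca <- matrix(bb[, 2, ], L, 3)
  for (i in seq_len(L)) {
    d <- sqrt(colSums((t(ca) - ca[i, ])^2))
    expect_identical(g2$e_idx[i, ], order(d, seq_len(L))[seq_len(K)])
  }
})

test_that("context selection matches a brute-force sort and pads with mask", {
  fx <- tiny_fixture(L = 8, ligand = NULL)
  set.seed(9)
  na <- 30
  coords <- matrix(stats::rnorm(na * 3, sd = 8), na, 3)
  ctx <- context_atoms(coords, sample(5:30, na, TRUE),
                       rep("small_molecule", na))
  cfg <- feature_config(K = 4, M = 10)
  rc <- select_context_atoms(fx$structure, ctx, cfg)
  bb <- fx$structure$backbone
  cb <- virtual_cbeta(bb[, 1, ], bb[, 2, ], bb[, 3, ])
  for (i in 1:8) {
    d <- sqrt(colSums((t(coords) - cb[i, ])^2))
    ord <- order(d, seq_len(na))[1:10]
    expect_equal(matrix(rc$Y[i, , ], 10, 3), coords[ord, ])
    expect_identical(rc$Y_t[i, ], ctx$element[ord])
  }
  expect_true(all(rc$Y_m == 1))

  few <- context_atoms(coords[1:3, ], ctx$element[1:3], ctx$category[1:3])
  rc2 <- select_context_atoms(fx$structure, few, feature_config(M = 25))
  expect_identical(unname(rowSums(rc2$Y_m)), rep(3, 8))

  rc0 <- select_context_atoms(fx$structure, context_atoms(), cfg)
  expect_true(all(rc0$Y_m == 0))
})

test_that("element one-hot: Zn maps to group 12, period 4; widths sum to 147", {
  gp <- element_group_period(element_number("ZN"))
  expect_identical(gp$group, 12L)
  expect_identical(gp$period, 4L)
  gp2 <- element_group_period(c(1, 6, 26, 53))
  expect_identical(gp2$group, c(1L, 14L, 8L, 17L))
  expect_identical(gp2$period, c(1L, 2L, 4L, 5L))

  fx <- tiny_fixture(L = 4)
  rc <- select_context_atoms(fx$structure, fx$context, tiny_feature_config())
  cf <- context_features(fx$structure, rc, tiny_feature_config())
  expect_identical(ncol(cf$ctx_onehot), 147L)
  expect_identical(ncol(cf$ctx_rbf), 5L * 16L)
  expect_identical(ncol(cf$ctx_angles), 4L)
  live <- cf$Y_m_flat == 1
  expect_true(all(rowSums(cf$ctx_onehot[live, , drop = FALSE]) == 3))
  expect_true(all(rowSums(cf$ctx_onehot[!live, , drop = FALSE]) == 0))
})

test_that("coordinate noise: identity at 0, seeded, calibrated std", {
  fx <- tiny_fixture(L = 5)
  out0 <- add_coordinate_noise(fx$structure, fx$context, 0)
  expect_identical(out0$structure$backbone, fx$structure$backbone)
  a <- add_coordinate_noise(fx$structure, fx$context, 0.1, rng_seed = 7)
  b <- add_coordinate_noise(fx$structure, fx$context, 0.1, rng_seed = 7)
  expect_identical(a$structure$backbone, b$structure$backbone)
  expect_false(identical(a$structure$backbone, fx$structure$backbone))
  # Monte-Carlo: empirical std over many draws within 3 sigma of estimator
  set.seed(1)
  n_draw <- 1e5
  big <- protein_structure(array(0, c(n_draw %/% 12 , 4, 3)),
                           seq_len(n_draw %/% 12), rep(1L, n_draw %/% 12),
                           rep(1L, n_draw %/% 12), rep(TRUE, n_draw %/% 12))
  noised <- add_coordinate_noise(big, context_atoms(), 0.1, rng_seed = 2)
  devs <- as.numeric(noised$structure$backbone)
  se <- 0.1 / sqrt(2 * (length(devs) - 1))
  expect_lt(abs(stats::sd(devs) - 0.1), 3 * se)
})

test_that("features are invariant to rigid transforms and storage order", {
  fx <- tiny_fixture(L = 12, seed = 5)
  # jitter breaks the ideal helix's exact neighbor-distance ties
  fx[c("structure", "context")] <-
    add_coordinate_noise(fx$structure, fx$context, 0.2, rng_seed = 72)
  cfg <- tiny_feature_config()
  f1 <- featurize(fx$structure, fx$context, cfg)
  tr <- random_rigid_transform(seed = 11)
  s2 <- fx$structure
  for (a in 1:4) s2$backbone[, a, ] <- apply_rigid_transform(s2$backbone[, a, ], tr)
  ctx2 <- fx$context
  ctx2$coords <- apply_rigid_transform(ctx2$coords, tr)
  f2 <- featurize(s2, ctx2, cfg)
  expect_identical(f1$e_idx, f2$e_idx)
  expect_equal(f1$rbf_edges, f2$rbf_edges, tolerance = 1e-6)
  expect_equal(f1$ctx_rbf, f2$ctx_rbf, tolerance = 1e-6)
  expect_equal(f1$ctx_angles, f2$ctx_angles, tolerance = 1e-6)
  expect_equal(f1$yedges_rbf, f2$yedges_rbf, tolerance = 1e-6)

  # permuting context-atom storage leaves the selection identical
  set.seed(3)
  perm <- sample(length(fx$context$element))
  ctx3 <- context_atoms(fx$context$coords[perm, ], fx$context$element[perm],
                        fx$context$category[perm])
  rc1 <- select_context_atoms(fx$structure, fx$context, cfg)
  rc3 <- select_context_atoms(fx$structure, ctx3, cfg)
  expect_equal(rc1$Y, rc3$Y)
  expect_identical(rc1$Y_t, rc3$Y_t)
})
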