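# Primitive layers, message-passing layers vs scalar oracles, encoder
# contracts, parameter counts, gradient flow.

test_that("gelu, layer_norm and dropout follow their contracts", {
  expect_identical(ag_gelu(matrix(0, 1, 1))[1, 1], 0)
  x <- matrix(seq(-3, 3, length.out = 12), 3, 4)
  # reflection identity of the tanh approximation: gelu(x) - x = gelu(-x)
  expect_equal(ag_gelu(x) - x, ag_gelu(-x), tolerance = 1e-12)

  g <- stats::runif(4); b <- stats::rnorm(4)
  const <- matrix(5, 2, 4)
  ln <- ag_layernorm(const, g, b)
  expect_equal(ln, matrix(b, 2, 4, byrow = TRUE), tolerance = 1e-12)

  set.seed(1)
  xx <- matrix(stats::rnorm(20), 4, 5)
  expect_identical(ag_dropout(xx, 0.5, training = FALSE), xx)
  dr <- ag_dropout(xx, 0.5, training = TRUE)
  expect_true(any(dr == 0) || !identical(dr, xx))
})

test_that("ffn applies Linear-GELU-Linear with the exact printed shapes", {
  cfg <- tiny_model_config(m = 4L)
  mod <- tiny_model(m = 4L)
  expect_identical(dim(mod$params[["enc1.ffn_in.W"]]), c(4L, 16L))
  expect_identical(dim(mod$params[["enc1.ffn_out.W"]]), c(16L, 4L))
  big <- model_config()
  expect_identical(big$ffn_width, 512L)
})

test_that("dec_layer matches a scalar oracle on a 2-residue m=2 instance", {
  m <- 2L
  cfg <- model_config(m = m, ffn_width = 4L, dropout_p = 0)
  set.seed(21)
  shapes <- pocketdesign:::.param_shapes(cfg, feature_config(m = m, K = 2, M = 2),
                                         "protein_only")
  P <- pocketdesign:::.init_params(shapes, seed = 13)
  v <- matrix(stats::rnorm(4), 2, m)
  edges <- matrix(stats::rnorm(2 * 2 * 3 * m), 4, 3 * m)
  mask <- c(1, 1); mask_attend <- rep(1, 4)
  got <- dec_layer(P, "dec1", v, edges, B = 2L, mask, mask_attend, cfg)
  want <- oracle_dec_layer(P, "dec1", v, edges, 2L, mask, mask_attend, cfg)
  expect_equal(got, want, tolerance = 1e-6)
  # masked neighbor messages are exactly zero: zeroing the mask equals
  # zeroing those edge rows entirely
  ma2 <- c(1, 0, 1, 1)
  got2 <- dec_layer(P, "dec1", v, edges, B = 2L, mask, ma2, cfg)
  edges_z <- edges; edges_z[2, ] <- 1e6           # garbage in masked slot
  got3 <- dec_layer(P, "dec1", v, edges_z, B = 2L, mask, ma2, cfg)
  expect_equal(got2, got3, tolerance = 1e-8)
})

test_that("enc_layer matches a scalar oracle on a 2-residue m=2 instance", {
  m <- 2L
  cfg <- model_config(m = m, ffn_width = 4L, dropout_p = 0)
  shapes <- pocketdesign:::.param_shapes(cfg, feature_config(m = m, K = 2, M = 2),
                                         "protein_only")
  P <- pocketdesign:::.init_params(shapes, seed = 14)
  set.seed(22)
  v <- matrix(stats::rnorm(4), 2, m)
  e <- matrix(stats::rnorm(8), 4, m)
  e_idx <- rbind(c(1L, 2L), c(2L, 1L))
  mask <- c(1, 1); mask_attend <- rep(1, 4)
  got <- enc_layer(P, "enc1", v, e, e_idx, mask, mask_attend, cfg)
  want <- oracle_enc_layer(P, "enc1", v, e, e_idx, mask, mask_attend, cfg)
  expect_equal(got$v, want$v, tolerance = 1e-6)
  expect_equal(got$e, want$e, tolerance = 1e-6)
  # zero-weight limit: with all weights and norm gains zeroed the layer
  # output collapses to the norm offsets (betas), i.e. zero here
  P0 <- lapply(P, function(x) x * 0)
  z <- enc_layer(P0, "enc1", v, e, e_idx, mask, mask_attend, cfg)
  expect_true(all(z$v == 0))
  expect_true(all(z$e == 0))
  # single residue with only a self-edge: one-term message sum stays finite
  g1 <- enc_layer(P, "enc1", v[1, , drop = FALSE], e[1, , drop = FALSE],
                  matrix(1L, 1, 1), 1, 1, cfg)
  expect_true(all(is.finite(g1$v)))
})

test_that("context_dec_layer: permutation equivariance and single-atom case", {
  m <- 4L
  cfg <- model_config(m = m, ffn_width = 8L, dropout_p = 0)
  shapes <- pocketdesign:::.param_shapes(cfg, feature_config(m = m, K = 2, M = 3),
                                         "full")
  P <- pocketdesign:::.init_params(shapes, seed = 15)
  L <- 2L; M <- 3L
  set.seed(30)
  v <- matrix(stats::rnorm(L * M * m), L * M, m)
  e <- matrix(stats::rnorm(L * M * M * m), L * M * M, m)
  ym <- rep(1, L * M); yme <- rep(1, L * M * M)
  out <- context_dec_layer(P, "ctxy1", v, e, M, ym, yme, cfg)

  # permute atoms within residue 1 -> outputs permute identically
  perm <- c(3L, 1L, 2L)
  v2 <- v; v2[1:3, ] <- v[perm, ]
  e2 <- e
  for (j in 1:3) for (k in 1:3) {
    e2[(j - 1) * 3 + k, ] <- e[(perm[j] - 1) * 3 + perm[k], ]
  }
  out2 <- context_dec_layer(P, "ctxy1", v2, e2, M, ym, yme, cfg)
  expect_equal(out2[1:3, ], out[perm, ], tolerance = 1e-8)

  # M = 1: a single self-message changes the node state deterministically
  v1 <- matrix(stats::rnorm(m), 1, m)
  e1 <- matrix(stats::rnorm(m), 1, m)
  o1 <- context_dec_layer(P, "ctxy1", v1, e1, 1L, 1, 1, cfg)
  expect_true(all(is.finite(o1)))
  # all-masked context: update reduces to the residual/FFN path of zeros
  oz <- context_dec_layer(P, "ctxy1", v1, e1, 1L, 0, 0, cfg)
  expect_true(all(oz == 0))                        # node mask zeroes output
})

test_that("parameter counts match the printed architecture sizes", {
  full <- count_parameters(model_config(), feature_config(), "full")
  prot <- count_parameters(model_config(), feature_config(), "protein_only")
  expect_equal(round(full / 1e6, 2), 2.62)
  expect_equal(round(prot / 1e6, 2), 1.66)
  # doubling m roughly quadruples the dominant quadratic terms
  big <- count_parameters(model_config(m = 256L, ffn_width = 1024L),
                          feature_config(m = 256L), "full")
  expect_gt(big, full)
  expect_gt(big / full, 3)
  expect_lt(big / full, 4.2)
  # initialized store matches the declared count
  mod <- tiny_model()
  expect_identical(sum(vapply(mod$params, length, 1L)),
                   as.integer(count_parameters(tiny_model_config(),
                                               tiny_feature_config(), "full")))
})

test_that("encode: masked-context contract and eval determinism", {
  fx <- tiny_fixture(L = 6)
  mod <- tiny_model()
  f_ctx <- featurize(fx$structure, fx$context, mod$feat)
  f_empty <- featurize(fx$structure, context_atoms(), mod$feat)
  # with all context masked, outputs are invariant to ContextAtoms content:
  # an empty context and a garbage-but-masked context agree
  f_garbage <- f_empty
  f_garbage$ctx_rbf <- matrix(stats::rnorm(length(f_empty$ctx_rbf)),
                              nrow(f_empty$ctx_rbf))
  e1 <- model_encode(mod, f_empty)
  e2 <- model_encode(mod, f_garbage)
  expect_equal(e1$h_V, e2$h_V, tolerance = 1e-8)
  # deterministic in eval mode
  e3 <- model_encode(mod, f_ctx)
  e4 <- model_encode(mod, f_ctx)
  expect_identical(e3$h_V, e4$h_V)
  # finiteness across sizes
  for (L in c(1L, 5L, 30L)) {
    fxL <- tiny_fixture(L = L, ligand = if (L > 2)
      list(n_atoms = 2L, element = "ZN", radius = 3, attach_residue = 1L)
      else NULL)
    fL <- featurize(fxL$structure, fxL$context, mod$feat)
    eL <- model_encode(mod, fL)
    expect_true(all(is.finite(eL$h_V)))
  }
})

test_that("gradients flow to every declared parameter", {
  fx <- tiny_fixture(L = 8)
  mod <- tiny_model()
  f <- featurize(fx$structure, fx$context, mod$feat)
  ag_tape_start()
  P <- pocketdesign:::.wrap_params(mod$params)
  enc <- model_encode(mod, f, training = TRUE, P = P)
  dec <- decode_logits(mod, enc, fx$structure$sequence,
                       decoding_order = sample(8), training = TRUE, P = P)
  loss <- sequence_loss(dec$log_probs, fx$structure$sequence, f$mask)
  g <- ag_backward(loss)
  ag_tape_stop()
  expect_setequal(names(g), names(mod$params))
  dead <- names(g)[vapply(g, function(x) all(x == 0), logical(1))]
  expect_identical(dead, character(0))
})

test_that("checkpoints round-trip with strict shape validation", {
  mod <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(mod, path)
  back <- load_checkpoint(path)
  expect_identical(back$variant, "full")
  expect_equal(back$params, mod$params)
  # corrupt one shape -> load fails
  bad <- readRDS(path)
  bad[["W_out.W"]] <- bad[["W_out.W"]][, 1:5]
  saveRDS(bad, path)
  expect_error(load_checkpoint(path), "shape mismatch")
})
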