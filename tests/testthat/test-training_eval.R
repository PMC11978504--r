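# Losses, augmentation, training determinism, metrics.

test_that("sequence_loss: perfect, uniform and hand-computed cases", {
  L <- 3L
  S <- c(2L, 5L, 9L)
  perfect <- matrix(log(1e-12), L, 21)
  perfect[cbind(1:L, S)] <- 0
  expect_equal(sequence_loss(perfect, S, rep(1, L)), 0)
  uniform <- matrix(log(1 / 21), L, 21)
  expect_equal(sequence_loss(uniform, S, rep(1, L)), log(21))
  set.seed(2)
  lp <- matrix(log(stats::runif(L * 21)), L, 21)
  lp <- lp - log(rowSums(exp(lp)))
  mask <- c(1, 0, 1)
  hand <- -(lp[1, S[1]] + lp[3, S[3]]) / 2
  expect_equal(sequence_loss(lp, S, mask), hand)
})

test_that("loss at initialization is near ln(21) for a random model", {
  fx <- tiny_fixture(L = 12)
  mod <- tiny_model(seed = 42)
  f <- featurize(fx$structure, fx$context, mod$feat)
  enc <- model_encode(mod, f)
  dec <- decode_logits(mod, enc, fx$structure$sequence,
                       decoding_order = sample(12))
  loss <- sequence_loss(dec$log_probs, fx$structure$sequence, f$mask)
  expect_lt(abs(loss - log(21)), 0.75)
})

test_that("sidechain-context augmentation respects its fraction contract", {
  fx <- tiny_fixture(L = 10, ligand = NULL)
  s <- fx$structure
  # give every residue a fake sidechain atom
  s$sidechain_atoms <- data.frame(residue = 1:10, name = "CB",
                                  x = s$backbone[, 2, 1] + 1,
                                  y = s$backbone[, 2, 2],
                                  z = s$backbone[, 2, 3],
                                  element = 6L)
  entry <- list(structure = s, context = context_atoms())
  set.seed(1)
  out0 <- augment_sidechain_context(list(entry), c(0, 0))
  expect_length(out0[[1]]$donated, 0L)
  expect_identical(nrow(out0[[1]]$context$coords), 0L)
  out1 <- augment_sidechain_context(list(entry), c(1, 1))
  expect_length(out1[[1]]$donated, 10L)
  expect_identical(unique(out1[[1]]$context$category), "protein_sidechain")
  # Monte-Carlo: selected counts match the binomial expectation
  set.seed(7)
  counts <- replicate(1000, {
    length(augment_sidechain_context(list(entry), c(0.3, 0.3))[[1]]$donated)
  })
  expect_lt(abs(mean(counts) - 3), 3 * sqrt(10 * 0.3 * 0.7 / 1000) + 0.05)
})

test_that("dataset filter applies resolution and length rules", {
  fx <- tiny_fixture(L = 5, ligand = NULL)
  good <- list(structure = fx$structure, context = context_atoms())
  bad_res <- good; bad_res$structure$resolution <- 4.2
  good$structure$resolution <- 2.0
  no_meta <- list(structure = tiny_fixture(L = 5, ligand = NULL)$structure,
                  context = context_atoms())
  expect_warning(kept <- filter_dataset(list(good, bad_res, no_meta),
                                        3.5, 6000L), "resolution")
  expect_length(kept, 2L)
  long <- good
  expect_length(filter_dataset(list(good), 3.5, max_length = 5L), 0L)
})

test_that("cluster tables read as id -> cluster", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\t1", "b\t1", "c\t2"), f)
  tab <- read_cluster_table(f)
  expect_identical(tab$id, c("a", "b", "c"))
  expect_identical(tab$cluster, c(1L, 1L, 2L))
})

test_that("training: loss decreases on overfit, equal seeds reproduce", {
  fx <- tiny_fixture(L = 10, seed = 4)
  entry <- list(structure = fx$structure, context = fx$context)
  mod <- tiny_model()
  tc <- train_config(steps = 12L, batch_tokens = 10L, rng_seed = 3,
                     noise_level = 0, lr = 2e-3,
                     sidechain_context_fraction = c(0, 0))
  out1 <- train_model(mod, list(entry), tc)
  out2 <- train_model(mod, list(entry), tc)
  expect_identical(out1$losses, out2$losses)
  expect_lt(mean(tail(out1$losses, 3)), mean(head(out1$losses, 3)))
  expect_error(train_model(mod, list(), tc), "empty")
  # resumable: two 6-step runs with a carried state match one 12-step run
  tc6 <- tc; tc6$steps <- 6L
  a <- train_model(mod, list(entry), tc6)
  expect_identical(a$opt_state$t, 6L)
})

test_that("context shell membership at the 4.9/5.1 A boundary", {
  fx <- tiny_fixture(L = 3, ligand = NULL)
  s <- fx$structure
  cb <- virtual_cbeta(s$backbone[2, 1, ], s$backbone[2, 2, ], s$backbone[2, 3, ])
  near <- context_atoms(rbind(as.numeric(cb) + c(4.9, 0, 0)), 30L, "metal")
  far <- context_atoms(rbind(as.numeric(cb) + c(5.1, 0, 0)), 30L, "metal")
  expect_true(2L %in% context_shell_residues(s, near, 5.0))
  expect_false(2L %in% context_shell_residues(s, far, 5.0))
  expect_identical(context_shell_residues(s, context_atoms(), 5.0), integer(0))

  # brute-force O(n^2) oracle on a random fixture with sidechain coords
  set.seed(11)
  fx2 <- tiny_fixture(L = 12, seed = 11)
  sc <- array(NA_real_, c(12, 14, 3))
  for (i in 1:12) sc[i, , ] <- chis_to_coords(one_to_tokens("L"),
                                              fx2$structure$backbone[i, , ],
                                              stats::runif(2, -pi, pi))
  got <- context_shell_residues(fx2$structure, fx2$context, 5.0, sc)
  want <- integer(0)
  for (i in 1:12) {
    hit <- FALSE
    for (a in 5:14) {
      if (any(!is.finite(sc[i, a, ]))) next
      for (j in seq_along(fx2$context$element)) {
        if (sqrt(sum((sc[i, a, ] - fx2$context$coords[j, ])^2)) <= 5.0)
          hit <- TRUE
      }
    }
    if (hit) want <- c(want, i)
  }
  expect_identical(got, want)
})

test_that("sequence recovery arithmetic and medians", {
  native <- c(1L, 2L, 3L, 4L)
  expect_equal(sequence_recovery(list(native), native), 1.0)
  half <- c(1L, 2L, 9L, 9L)
  expect_equal(sequence_recovery(list(half), native), 0.5)
  expect_equal(sequence_recovery(list(native, half), native, positions = 1:4),
               0.75)
  expect_equal(stats::median(c(0.2, 0.6, 0.9)), 0.6)
  expect_true(is.na(sequence_recovery(list(native), native, integer(0))))
})

test_that("chi recovery: wraparound, 180-degree symmetry, hand counts", {
  d2r <- pi / 180
  seqs <- one_to_tokens(c("K", "F", "S"))
  pred <- matrix(NA_real_, 3, 4)
  nat <- matrix(NA_real_, 3, 4)
  pred[1, 1:4] <- c(359, 20, 100, -50) * d2r
  nat[1, 1:4] <- c(1, 25, 150, -49) * d2r      # chi1 in (wrap), chi2 out? 5 deg -> in
  pred[2, 1:2] <- c(30, 95) * d2r
  nat[2, 1:2] <- c(31, -85) * d2r              # PHE chi2: 180-symmetric hit
  pred[3, 1] <- 10 * d2r; nat[3, 1] <- 40 * d2r
  out <- chi_recovery(pred, nat, seqs, threshold_deg = 10)
  # hand-enumerated: chi1 hits = {K (2 deg), F (1 deg)}, miss = {S};
  # chi2 hits = {K (5 deg), F (symmetric 0)}; chi3 miss; chi4 hit
  expect_identical(out$counts, c(3L, 2L, 1L, 1L))
  expect_equal(out$per_chi, c(2 / 3, 1, 0, 1))
  expect_equal(out$overall, 5 / 7)
})

test_that("confidence calibration: perfect, constant and rank oracle", {
  expect_equal(confidence_calibration(c(10, 20, 30), c(0.1, 0.2, 0.3))$correlation, 1)
  flag <- confidence_calibration(c(5, 5, 5), c(0.1, 0.2, 0.3))
  expect_true(flag$constant)
  expect_true(is.na(flag$correlation))
  set.seed(9)
  conf <- stats::runif(20, 0, 100)
  rec <- stats::runif(20)
  got <- confidence_calibration(conf, rec)
  expect_equal(got$correlation, stats::cor(rank(conf), rank(rec)),
               tolerance = 1e-9)
})
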