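# Desk-scale training: Adam, categorical cross-entropy on teacher-forced
# log-probabilities under random decoding orders, token-budget batching,
# per-step coordinate noise, and the sidechain-context augmentation.

#' Training configuration
#'
#' @param steps optimizer steps.
#' @param lr learning rate (fixed; `warmup_steps > 0` ramps linearly).
#' @param adam_beta1,adam_beta2,adam_eps Adam moments/epsilon.
#' @param batch_tokens residue-token budget per batch.
#' @param noise_level coordinate noise std, Angstrom.
#' @param sidechain_context_fraction length-2 range; per batch a fraction is
#'   drawn uniformly and that share of residues donate their sidechain atoms
#'   as context (identities remain prediction targets).
#' @param rng_seed integer seed.
#' @param resolution_cutoff,max_length dataset filters (Angstrom, residues).
#' @param warmup_steps linear learning-rate warmup steps (0 = fixed rate).
#' @return list of class `train_config`.
#' @export
train_config <- function(steps = 100L, lr = 1e-3,
                         adam_beta1 = 0.9, adam_beta2 = 0.98,
                         adam_eps = 1e-9, batch_tokens = 6000L,
                         noise_level = 0.1,
                         sidechain_context_fraction = c(0.02, 0.04),
                         rng_seed = 1L, resolution_cutoff = 3.5,
                         max_length = 6000L, warmup_steps = 0L) {
  stopifnot(steps >= 1, all(sidechain_context_fraction >= 0),
            all(sidechain_context_fraction <= 1))
  structure(list(steps = as.integer(steps), lr = lr,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 adam_eps = adam_eps, batch_tokens = as.integer(batch_tokens),
                 noise_level = noise_level,
                 sidechain_context_fraction = sidechain_context_fraction,
                 rng_seed = as.integer(rng_seed),
                 resolution_cutoff = resolution_cutoff,
                 max_length = as.integer(max_length),
                 warmup_steps = as.integer(warmup_steps)),
            class = "train_config")
}

#' Masked categorical cross-entropy sequence loss
#'
#' Mean negative log-probability of the true tokens over valid residues.
#' Accepts plain matrices or autograd nodes (for training).
#'
#' @param log_probs `[L x 21]` log-probabilities (node or matrix).
#' @param S integer true tokens.
#' @param residue_mask logical/0-1 vector.
#' @return scalar (1x1 node during training).
#' @export
sequence_loss <- function(log_probs, S, residue_mask) {
  L <- length(S)
  w <- as.numeric(residue_mask)
  picked <- ag_pick(log_probs, seq_len(L), S)
  out <- ag_scale(ag_wmean(picked, w), -1)
  if (is_ag_node(out)) out else as.numeric(out)
}

#' Donate sidechain atoms of a random residue fraction as context
#'
#' @param batch list of entries `list(structure, context, ...)`.
#' @param fraction_range length-2 numeric range; one fraction drawn per call.
#' @return the batch with augmented `context` and a `donated` index vector
#'   per entry.
#' @export
augment_sidechain_context <- function(batch, fraction_range = c(0.02, 0.04)) {
  frac <- if (diff(range(fraction_range)) == 0) fraction_range[1]
          else stats::runif(1, fraction_range[1], fraction_range[2])
  lapply(batch, function(entry) {
    sc <- entry$structure$sidechain_atoms
    if (is.null(sc) || frac <= 0) { entry$donated <- integer(0); return(entry) }
    candidates <- unique(sc$residue)
    pick <- candidates[stats::runif(length(candidates)) < frac]
    if (frac >= 1) pick <- candidates
    entry$donated <- pick
    if (length(pick)) {
      entry$context <- concat_context(
        entry$context, protein_sidechain_context(entry$structure, pick))
    }
    entry
  })
}

#' Filter a dataset on resolution and length metadata
#'
#' @param entries list of entries with `structure` elements.
#' @param resolution_cutoff keep entries with resolution <= cutoff; entries
#'   without resolution metadata are kept with a warning.
#' @param max_length keep entries shorter than this.
#' @return filtered list.
#' @export
filter_dataset <- function(entries, resolution_cutoff = 3.5,
                           max_length = 6000L) {
  keep <- vapply(entries, function(e) {
    L <- length(e$structure$sequence)
    if (L >= max_length) return(FALSE)
    res <- e$structure$resolution
    if (is.null(res) || is.na(res)) return(NA)
    res <= resolution_cutoff
  }, logical(1))
  if (anyNA(keep)) {
    warning(sum(is.na(keep)), " entries lack resolution metadata; kept")
    keep[is.na(keep)] <- TRUE
  }
  entries[keep]
}

#' Read a precomputed cluster-assignment table (id TAB cluster)
#' @param path TSV path with two columns, no header required.
#' @return data.frame with columns `id`, `cluster`.
#' @export
read_cluster_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab)[1:2] <- c("id", "cluster")
  tab[, 1:2]
}

## ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## ---- training loop ---------------------------------------------------------

#' Train a sequence-design model
#'
#' Token-budget batching over the dataset (cluster-aware sampling when
#' entries carry a `cluster` field: one entry per sampled cluster), per-step
#' Gaussian coordinate noise, teacher forcing under a fresh random decoding
#' order per structure, Adam updates. Fully seeded and resumable via the
#' returned optimizer state.
#'
#' @param model a `pocket_model`.
#' @param dataset non-empty list of entries `list(structure, context,
#'   id = ..., cluster = ...)`.
#' @param config a [train_config].
#' @param opt_state optional optimizer state from a previous call (resume).
#' @param verbose print progress.
#' @return list with `model` (updated weights), `losses` (per-step mean
#'   token NLL), `opt_state`.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        opt_state = NULL, verbose = FALSE) {
  if (!length(dataset)) stop("empty dataset")
  set.seed(config$rng_seed)
  params <- model$params
  opt <- opt_state %||% adam_init(params)
  losses <- numeric(config$steps)
  clusters <- vapply(dataset, function(e) as.character(e$cluster %||% NA),
                     character(1))
  use_clusters <- !anyNA(clusters)
  aug_on <- max(config$sidechain_context_fraction) > 0 &&
    any(vapply(dataset, function(e) !is.null(e$structure$sidechain_atoms),
               logical(1)))

  for (step in seq_len(config$steps)) {
    # assemble a batch under the token budget (always at least one entry)
    batch <- list()
    tok <- 0L
    repeat {
      idx <- if (use_clusters) {
        cl <- sample(unique(clusters), 1)
        sample(which(clusters == cl), 1)
      } else sample.int(length(dataset), 1)
      entry <- dataset[[idx]]
      Lx <- length(entry$structure$sequence)
      if (length(batch) && tok + Lx > config$batch_tokens) break
      batch[[length(batch) + 1L]] <- entry
      tok <- tok + Lx
      if (tok >= config$batch_tokens) break
    }
    if (aug_on) batch <- augment_sidechain_context(
      batch, config$sidechain_context_fraction)

    grads_total <- NULL
    tok_total <- 0
    loss_total <- 0
    for (entry in batch) {
      noised <- add_coordinate_noise(entry$structure, entry$context,
                                     config$noise_level)
      feats <- featurize(noised$structure, noised$context, model$feat)
      L <- feats$L
      ag_tape_start()
      P <- .wrap_params(params)
      enc <- model_encode(model, feats, training = TRUE, P = P)
      dec <- decode_logits(model, enc, entry$structure$sequence,
                           decoding_order = sample.int(L),
                           training = TRUE, P = P)
      loss <- sequence_loss(dec$log_probs, entry$structure$sequence,
                            feats$mask)
      g <- ag_backward(loss)
      lval <- ag_value(loss)[1, 1]
      ag_tape_stop()
      ntok <- sum(feats$mask)
      loss_total <- loss_total + lval * ntok
      tok_total <- tok_total + ntok
      if (is.null(grads_total)) {
        grads_total <- lapply(g, function(x) x * ntok)
      } else {
        for (nm in names(g)) grads_total[[nm]] <- grads_total[[nm]] + g[[nm]] * ntok
      }
    }
    for (nm in names(grads_total)) grads_total[[nm]] <- grads_total[[nm]] / tok_total
    lr <- config$lr
    if (config$warmup_steps > 0 && step <= config$warmup_steps)
      lr <- lr * step / config$warmup_steps
    upd <- adam_step(params, grads_total, opt, lr,
                     config$adam_beta1, config$adam_beta2, config$adam_eps)
    params <- upd$params
    opt <- upd$state
    losses[step] <- loss_total / tok_total
    if (verbose && (step %% 10 == 0 || step == 1))
      message(sprintf("step %d/%d loss %.4f", step, config$steps, losses[step]))
  }
  model$params <- params
  list(model = model, losses = losses, opt_state = opt)
}
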