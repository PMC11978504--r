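# Autoregressive sequence sampling under a random decoding order, with
# temperature, per-position bias, fixed positions and tied (symmetric)
# position groups; teacher-forced sequence scoring.

#' Design request
#'
#' @param temperature sampling temperature `T > 0`.
#' @param bias optional `[L x 21]` additive logit bias.
#' @param fixed_positions optional two-column matrix / data.frame
#'   `(position, token)`: those positions emit the given token with
#'   probability 1.
#' @param tied_groups optional list of disjoint integer position vectors;
#'   members of a group are decoded together from the average of their
#'   probability vectors and receive identical tokens.
#' @param n_designs number of sequences to sample.
#' @param rng_seed integer seed.
#' @param omit_unknown exclude the unknown token from sampling (default TRUE;
#'   implemented as a large negative bias).
#' @return list of class `design_request`.
#' @export
design_request <- function(temperature = 0.1, bias = NULL,
                           fixed_positions = NULL, tied_groups = NULL,
                           n_designs = 1L, rng_seed = 1L,
                           omit_unknown = TRUE) {
  stopifnot(temperature > 0, n_designs >= 1)
  if (!is.null(tied_groups)) {
    all_pos <- unlist(tied_groups)
    if (anyDuplicated(all_pos)) stop("tied groups must be disjoint")
  }
  structure(list(temperature = temperature, bias = bias,
                 fixed_positions = fixed_positions,
                 tied_groups = tied_groups,
                 n_designs = as.integer(n_designs),
                 rng_seed = as.integer(rng_seed),
                 omit_unknown = omit_unknown),
            class = "design_request")
}

.effective_bias <- function(request, L, A) {
  bias <- request$bias
  if (is.null(bias)) bias <- matrix(0, L, A)
  stopifnot(nrow(bias) == L, ncol(bias) == A)
  if (isTRUE(request$omit_unknown)) bias[, A] <- bias[, A] - 1e9
  bias
}

.sample_token <- function(p) {
  sample.int(length(p), 1L, prob = p)
}

#' Sample one designed sequence
#'
#' Positions are visited in a uniformly random permutation; each position is
#' drawn from `softmax((logits + bias) / T)`. Fixed positions emit their token
#' with probability 1; tied groups are decoded at their earliest slot from
#' the average of the members' probability vectors. Confidence is
#' `100 x` the mean (untempered) model probability of the emitted token over
#' designable (non-fixed) positions.
#'
#' @param model a `pocket_model`.
#' @param encoded output of [model_encode()].
#' @param request a [design_request] (its `rng_seed` is used only via
#'   [design_sequences()]; call `set.seed` yourself when using this directly).
#' @return list of class `design_result`: `sequence`, `sequence_string`,
#'   `log_probs` `[L x 21]` (untempered), `decoding_order`, `rank`,
#'   `confidence`, `temperature`, `step_probs` (per-step tempered sampling
#'   probability of the emitted token).
#' @export
sample_sequence <- function(model, encoded, request = design_request()) {
  A <- model$config$alphabet_size
  L <- encoded$features$L
  Tt <- request$temperature
  bias <- .effective_bias(request, L, A)
  order <- sample.int(L)

  fixed <- rep(NA_integer_, L)
  if (!is.null(request$fixed_positions)) {
    fp <- as.matrix(request$fixed_positions)
    stopifnot(all(fp[, 1] >= 1 & fp[, 1] <= L))
    fixed[fp[, 1]] <- as.integer(fp[, 2])
  }
  group_of <- rep(NA_integer_, L)
  if (!is.null(request$tied_groups)) {
    for (gi in seq_along(request$tied_groups))
      group_of[request$tied_groups[[gi]]] <- gi
  }

  # ranks: tied members collapse onto the earliest member's slot
  rank <- order_to_rank(order)
  if (!is.null(request$tied_groups)) {
    for (g in request$tied_groups) rank[g] <- min(rank[g])
  }

  S <- rep(A, L)                       # filler token; causally never read
  step_probs <- rep(NA_real_, L)
  done <- rep(FALSE, L)
  for (pos in order) {
    if (done[pos]) next
    grp <- if (!is.na(group_of[pos])) request$tied_groups[[group_of[pos]]] else pos
    if (!is.na(fixed[pos])) {
      S[grp] <- fixed[pos]
      step_probs[grp] <- 1
      done[grp] <- TRUE
      next
    }
    dec <- decode_logits(model, encoded, S, rank = rank)
    logit_rows <- ag_value(dec$logits)[grp, , drop = FALSE]
    pr <- exp(sweep((logit_rows + bias[grp, , drop = FALSE]) / Tt, 1,
                    apply((logit_rows + bias[grp, , drop = FALSE]) / Tt, 1, max)))
    pr <- pr / rowSums(pr)
    pbar <- colMeans(pr)
    tok <- .sample_token(pbar)
    S[grp] <- tok
    step_probs[grp] <- pbar[tok]
    done[grp] <- TRUE
  }

  final <- decode_logits(model, encoded, S, rank = rank)
  lp <- ag_value(final$log_probs)
  designable <- is.na(fixed) & encoded$features$mask > 0
  conf <- 100 * mean(exp(lp[cbind(which(designable), S[designable])]))
  structure(list(sequence = S,
                 sequence_string = paste(tokens_to_one(S), collapse = ""),
                 log_probs = lp, decoding_order = order, rank = rank,
                 confidence = conf, temperature = Tt,
                 step_probs = step_probs),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat(sprintf("design_result: %s (confidence %.1f, T=%.3g)\n",
              x$sequence_string, x$confidence, x$temperature))
  invisible(x)
}

#' Sample multiple designs (seeded)
#'
#' @param model a `pocket_model`.
#' @param encoded output of [model_encode()].
#' @param request a [design_request]; `n_designs` and `rng_seed` are honored.
#' @return list of `design_result`s.
#' @export
design_sequences <- function(model, encoded, request = design_request()) {
  set.seed(request$rng_seed)
  out <- vector("list", request$n_designs)
  for (d in seq_len(request$n_designs)) {
    out[[d]] <- sample_sequence(model, encoded, request)
    out[[d]]$id <- sprintf("design_%d", d)
  }
  out
}

#' Greedy (T -> 0) redesign: argmax of (logits + bias) at every step
#'
#' @inheritParams sample_sequence
#' @return a `design_result`.
#' @export
greedy_sequence <- function(model, encoded, request = design_request()) {
  A <- model$config$alphabet_size
  L <- encoded$features$L
  bias <- .effective_bias(request, L, A)
  order <- sample.int(L)
  rank <- order_to_rank(order)
  S <- rep(A, L)
  for (pos in order) {
    dec <- decode_logits(model, encoded, S, rank = rank)
    row <- ag_value(dec$logits)[pos, ] + bias[pos, ]
    S[pos] <- which.max(row)
  }
  final <- decode_logits(model, encoded, S, rank = rank)
  lp <- ag_value(final$log_probs)
  designable <- encoded$features$mask > 0
  conf <- 100 * mean(exp(lp[cbind(which(designable), S[designable])]))
  structure(list(sequence = S,
                 sequence_string = paste(tokens_to_one(S), collapse = ""),
                 log_probs = lp, decoding_order = order, rank = rank,
                 confidence = conf, temperature = 0,
                 step_probs = rep(NA_real_, L)),
            class = "design_result")
}

#' Teacher-forced score of a sequence under random decoding orders
#'
#' @param model a `pocket_model`.
#' @param encoded output of [model_encode()].
#' @param S integer token sequence.
#' @param n_orders number of random decoding orders to average.
#' @param rng_seed integer seed.
#' @return list with `per_position` (mean log-probability per position, <= 0)
#'   and `mean` (overall masked mean).
#' @export
score_sequence <- function(model, encoded, S, n_orders = 1L, rng_seed = 1L) {
  set.seed(rng_seed)
  L <- encoded$features$L
  acc <- numeric(L)
  for (o in seq_len(n_orders)) {
    order <- sample.int(L)
    dec <- decode_logits(model, encoded, S, decoding_order = order)
    lp <- ag_value(dec$log_probs)
    acc <- acc + lp[cbind(seq_len(L), S)]
  }
  per_pos <- acc / n_orders
  mask <- encoded$features$mask > 0
  list(per_position = per_pos, mean = mean(per_pos[mask]))
}
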