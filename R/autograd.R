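# Minimal tape-based reverse-mode autograd on numeric matrices.
#
# Every op accepts either plain matrices or `ag_node` environments. When no
# argument is a node the op computes eagerly and returns a plain matrix, so
# eval-mode forward passes carry zero tape overhead. When recording, nodes are
# appended to the active tape and `ag_backward()` walks it in reverse.
#
# Conventions: all activations are 2-D matrices (rows = entities, columns =
# channels); higher-rank tensors are stored with a documented row layout
# (e.g. edge (i,k) lives at row (i-1)*K + k).

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

#' Start recording an autograd tape
#' @return invisible NULL.
#' @keywords internal
#' @export
ag_tape_start <- function() {
  .ag$recording <- TRUE
  .ag$tape <- vector("list", 4096L)
  .ag$n <- 0L
  invisible(NULL)
}

#' Stop recording and drop the tape
#' @keywords internal
#' @export
ag_tape_stop <- function() {
  .ag$recording <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

is_ag_node <- function(x) inherits(x, "ag_node")

ag_value <- function(x) if (is_ag_node(x)) x$val else x

#' Create a leaf (parameter) node
#' @param val numeric array.
#' @param name parameter name used to collect gradients.
#' @keywords internal
#' @export
ag_leaf <- function(val, name = NULL) {
  stopifnot(.ag$recording)
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- NULL
  node$backfn <- NULL
  node$name <- name
  class(node) <- "ag_node"
  .ag$n <- .ag$n + 1L
  if (.ag$n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[.ag$n]] <- node
  node
}

# internal: build a node from computed val, node parents and a backward fn.
# backfn(g, node) must return a list of gradients aligned with `parents`.
ag_make <- function(val, parents, backfn) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$name <- NULL
  class(node) <- "ag_node"
  .ag$n <- .ag$n + 1L
  if (.ag$n > length(.ag$tape)) .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  .ag$tape[[.ag$n]] <- node
  node
}

ag_any_node <- function(...) {
  args <- list(...)
  for (a in args) if (is_ag_node(a)) return(TRUE)
  FALSE
}

#' Run backward pass from a scalar loss node
#'
#' @param loss an `ag_node` holding a 1x1 value.
#' @return named list of gradients for every leaf created with a `name`.
#' @keywords internal
#' @export
ag_backward <- function(loss) {
  stopifnot(is_ag_node(loss), length(loss$val) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in rev(seq_len(.ag$n))) {
    node <- .ag$tape[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad, node)
    ps <- node$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.null(p) || is.null(gs[[j]])) next
      p$grad <- if (is.null(p$grad)) gs[[j]] else p$grad + gs[[j]]
    }
  }
  out <- list()
  for (i in seq_len(.ag$n)) {
    node <- .ag$tape[[i]]
    if (!is.null(node$name)) {
      out[[node$name]] <- if (is.null(node$grad)) array(0, dim(node$val)) else node$grad
    }
  }
  out
}

## ---- ops -------------------------------------------------------------------

#' Matrix product `x %*% w`
#' @param x `[n x p]`, `w` `[p x q]`; either may be a node.
#' @keywords internal
#' @export
ag_matmul <- function(x, w) {
  xv <- ag_value(x); wv <- ag_value(w)
  val <- xv %*% wv
  if (!ag_any_node(x, w)) return(val)
  px <- if (is_ag_node(x)) x else NULL
  pw <- if (is_ag_node(w)) w else NULL
  ag_make(val, list(px, pw), function(g, node) {
    list(if (!is.null(px)) g %*% t(wv) else NULL,
         if (!is.null(pw)) crossprod(xv, g) else NULL)
  })
}

#' Add a bias row-vector to every row
#' @keywords internal
#' @export
ag_addbias <- function(x, b) {
  xv <- ag_value(x); bv <- ag_value(b)
  val <- xv + matrix(bv, nrow(xv), length(bv), byrow = TRUE)
  if (!ag_any_node(x, b)) return(val)
  px <- if (is_ag_node(x)) x else NULL
  pb <- if (is_ag_node(b)) b else NULL
  ag_make(val, list(px, pb), function(g, node) {
    list(if (!is.null(px)) g else NULL,
         if (!is.null(pb)) colSums(g) else NULL)
  })
}

#' Elementwise addition of equal-shape arrays
#' @keywords internal
#' @export
ag_add <- function(x, y) {
  val <- ag_value(x) + ag_value(y)
  if (!ag_any_node(x, y)) return(val)
  px <- if (is_ag_node(x)) x else NULL
  py <- if (is_ag_node(y)) y else NULL
  ag_make(val, list(px, py), function(g, node) {
    list(if (!is.null(px)) g else NULL, if (!is.null(py)) g else NULL)
  })
}

#' Multiply by a constant scalar
#' @keywords internal
#' @export
ag_scale <- function(x, s) {
  val <- ag_value(x) * s
  if (!is_ag_node(x)) return(val)
  ag_make(val, list(x), function(g, node) list(g * s))
}

#' Elementwise multiply by a constant mask/matrix (same shape or row vector)
#'
#' `m` must be a plain numeric: either a matrix of the same shape as `x` or a
#' vector of length `nrow(x)` (row-wise scaling via column-major recycling).
#' @keywords internal
#' @export
ag_mulconst <- function(x, m) {
  xv <- ag_value(x)
  val <- xv * m
  if (!is_ag_node(x)) return(val)
  ag_make(val, list(x), function(g, node) list(g * m))
}

#' GELU nonlinearity (tanh approximation with sqrt(2/pi))
#' @keywords internal
#' @export
ag_gelu <- function(x) {
  xv <- ag_value(x)
  c0 <- sqrt(2 / pi)
  u <- c0 * (xv + 0.044715 * xv^3)
  th <- tanh(u)
  val <- 0.5 * xv * (1 + th)
  if (!is_ag_node(x)) return(val)
  ag_make(val, list(x), function(g, node) {
    du <- c0 * (1 + 3 * 0.044715 * xv^2)
    list(g * (0.5 * (1 + th) + 0.5 * xv * (1 - th^2) * du))
  })
}

#' Layer normalization over rows with affine parameters
#'
#' Per-row mean/variance normalization, `eps = 1e-5`, then `gamma * xhat + beta`.
#' @keywords internal
#' @export
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- ag_value(x); gv <- ag_value(gamma); bv <- ag_value(beta)
  n <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  gmat <- matrix(gv, nrow(xv), n, byrow = TRUE)
  val <- xhat * gmat + matrix(bv, nrow(xv), n, byrow = TRUE)
  if (!ag_any_node(x, gamma, beta)) return(val)
  px <- if (is_ag_node(x)) x else NULL
  pg <- if (is_ag_node(gamma)) gamma else NULL
  pb <- if (is_ag_node(beta)) beta else NULL
  ag_make(val, list(px, pg, pb), function(g, node) {
    gx <- NULL
    if (!is.null(px)) {
      gh <- g * gmat
      m1 <- rowMeans(gh)
      m2 <- rowMeans(gh * xhat)
      gx <- inv * (gh - m1 - xhat * m2)
    }
    list(gx,
         if (!is.null(pg)) colSums(g * xhat) else NULL,
         if (!is.null(pb)) colSums(g) else NULL)
  })
}

#' Inverted dropout with a precomputed keep mask
#'
#' Caller draws the mask so that RNG usage stays explicit and seedable.
#' @param mask plain 0/1 matrix of `x`'s shape (already divided by keep prob
#'   upstream or raw 0/1 — see `scale`).
#' @keywords internal
#' @export
ag_dropout <- function(x, p, training = FALSE) {
  if (!training || p <= 0) return(x)
  xv <- ag_value(x)
  keep <- matrix(stats::rbinom(length(xv), 1L, 1 - p), nrow(xv), ncol(xv)) / (1 - p)
  ag_mulconst(x, keep)
}

#' Concatenate matrices column-wise
#' @param ... matrices or nodes with equal row counts.
#' @keywords internal
#' @export
ag_concat <- function(...) {
  args <- list(...)
  vals <- lapply(args, ag_value)
  val <- do.call(cbind, vals)
  if (!Reduce(`|`, lapply(args, is_ag_node))) return(val)
  widths <- vapply(vals, ncol, 1L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  parents <- lapply(args, function(a) if (is_ag_node(a)) a else NULL)
  ag_make(val, parents, function(g, node) {
    lapply(seq_along(parents), function(j) {
      if (is.null(parents[[j]])) NULL else g[, starts[j]:ends[j], drop = FALSE]
    })
  })
}

#' Gather rows by index (with scatter-add backward)
#' @keywords internal
#' @export
ag_gather <- function(x, idx) {
  xv <- ag_value(x)
  val <- xv[idx, , drop = FALSE]
  if (!is_ag_node(x)) return(val)
  nr <- nrow(xv)
  ag_make(val, list(x), function(g, node) {
    gg <- rowsum(g, group = idx, reorder = FALSE)
    rows <- as.integer(rownames(gg))
    out <- matrix(0, nr, ncol(g))
    out[rows, ] <- gg
    list(out)
  })
}

#' Sum contiguous row blocks of fixed size
#'
#' Rows are grouped as `rep(seq_len(nblocks), each = blocksize)`; returns one
#' row per block.
#' @keywords internal
#' @export
ag_sumblocks <- function(x, nblocks, blocksize) {
  xv <- ag_value(x)
  grp <- rep(seq_len(nblocks), each = blocksize)
  val <- rowsum(xv, group = grp, reorder = FALSE)
  dimnames(val) <- NULL
  if (!is_ag_node(x)) return(val)
  ag_make(val, list(x), function(g, node) list(g[grp, , drop = FALSE]))
}

#' Row-wise log-softmax
#' @keywords internal
#' @export
ag_logsoftmax <- function(x) {
  xv <- ag_value(x)
  mx <- apply(xv, 1, max)
  z <- xv - mx
  lse <- log(rowSums(exp(z)))
  val <- z - lse
  if (!is_ag_node(x)) return(val)
  ag_make(val, list(x), function(g, node) {
    list(g - exp(val) * rowSums(g))
  })
}

#' Pick one entry per selected row: `x[cbind(rows, cols)]` as an n x 1 node
#' @keywords internal
#' @export
ag_pick <- function(x, rows, cols) {
  xv <- ag_value(x)
  val <- matrix(xv[cbind(rows, cols)], ncol = 1)
  if (!is_ag_node(x)) return(val)
  dm <- dim(xv)
  ag_make(val, list(x), function(g, node) {
    out <- matrix(0, dm[1], dm[2])
    # accumulate in case of repeated (row, col) pairs
    for (i in seq_along(rows)) out[rows[i], cols[i]] <- out[rows[i], cols[i]] + g[i, 1]
    list(out)
  })
}

#' Weighted mean reduced to a 1x1 scalar node
#' @param w plain non-negative weights of `x`'s length (matrix or vector).
#' @keywords internal
#' @export
ag_wmean <- function(x, w) {
  xv <- ag_value(x)
  sw <- sum(w)
  stopifnot(sw > 0)
  val <- matrix(sum(xv * w) / sw, 1, 1)
  if (!is_ag_node(x)) return(val)
  ag_make(val, list(x), function(g, node) {
    list(array(g[1, 1] * w / sw, dim = dim(xv)))
  })
}
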