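# Posterior probabilities of ancestral presence and of per-branch gain/loss
# events, by the up-down algorithm: the pruning (inward) pass conditions on
# the data below each node, the outward pass brings in the rest of the tree,
# and their product on every branch yields the joint parent/child state
# posterior from which event probabilities are read off.

# One category's node/branch posteriors for a batch of patterns.
# Returns list of [npat x n] matrices: pres, gain, loss, plus loglik vector.
.updown_category <- function(tree, leaf01, g, l) {
  dp <- .down_pass(tree, leaf01, g, l)
  npat <- nrow(leaf01)
  n <- tree$n
  L0 <- dp$L0; L1 <- dp$L1
  pres <- matrix(0, npat, n)
  gain <- matrix(0, npat, n)
  loss <- matrix(0, npat, n)
  U0 <- matrix(0, npat, n)
  U1 <- matrix(0, npat, n)
  # origin-to-root branch: parent is the origin, fixed absent
  j0 <- (1 - g[1]) * L0[, 1]
  j1 <- g[1] * L1[, 1]
  z <- j0 + j1
  pres[, 1] <- j1 / z
  gain[, 1] <- j1 / z       # a "gain at the root" is a gain on this branch
  U0[, 1] <- 1 - g[1]
  U1[, 1] <- g[1]
  for (v in seq_len(n)) {
    cs <- tree$children[[v]]
    k <- length(cs)
    if (k == 0L) next
    m0 <- vector("list", k)
    m1 <- vector("list", k)
    for (i in seq_len(k)) {
      c <- cs[i]
      m0[[i]] <- (1 - g[c]) * L0[, c] + g[c] * L1[, c]
      m1[[i]] <- l[c] * L0[, c] + (1 - l[c]) * L1[, c]
    }
    # product over siblings via prefix/suffix products (no division, so
    # structurally-zero messages from (near-)deterministic branches are safe)
    pre0 <- pre1 <- rep.int(1, npat)
    left0 <- left1 <- vector("list", k)
    for (i in seq_len(k)) {
      left0[[i]] <- pre0; left1[[i]] <- pre1
      pre0 <- pre0 * m0[[i]]; pre1 <- pre1 * m1[[i]]
    }
    suf0 <- suf1 <- rep.int(1, npat)
    for (i in k:1) {
      c <- cs[i]
      A0 <- U0[, v] * left0[[i]] * suf0
      A1 <- U1[, v] * left1[[i]] * suf1
      j00 <- A0 * (1 - g[c]) * L0[, c]
      j01 <- A0 * g[c] * L1[, c]
      j10 <- A1 * l[c] * L0[, c]
      j11 <- A1 * (1 - l[c]) * L1[, c]
      z <- j00 + j01 + j10 + j11
      gain[, c] <- j01 / z
      loss[, c] <- j10 / z
      pres[, c] <- (j01 + j11) / z
      u0 <- A0 * (1 - g[c]) + A1 * l[c]
      u1 <- A0 * g[c] + A1 * (1 - l[c])
      s <- u0 + u1
      s[s == 0] <- 1
      U0[, c] <- u0 / s
      U1[, c] <- u1 / s
      suf0 <- suf0 * m0[[i]]; suf1 <- suf1 * m1[[i]]
    }
  }
  list(pres = pres, gain = gain, loss = loss, loglik = dp$loglik)
}

# batched posteriors over a pattern matrix [npat x nleaf]; category-mixed
.posterior_engine <- function(tree, leaf01, model) {
  cats <- .category_probs(model)
  w <- vapply(cats, `[[`, 0, "w")
  per <- lapply(cats, function(cc) .updown_category(tree, leaf01, cc$g, cc$l))
  ll <- matrix(vapply(per, `[[`, numeric(nrow(leaf01)), "loglik"),
               nrow = nrow(leaf01), ncol = length(per))
  mix <- .mix_loglik(ll, w)
  cat_post <- exp(ll + rep(log(w), each = nrow(ll)) - mix)
  pres <- gain <- loss <- matrix(0, nrow(leaf01), tree$n)
  for (c in seq_along(per)) {
    pres <- pres + cat_post[, c] * per[[c]]$pres
    gain <- gain + cat_post[, c] * per[[c]]$gain
    loss <- loss + cat_post[, c] * per[[c]]$loss
  }
  loglik <- mix
  if (model$condition_on_observed)
    loglik <- loglik - log(-expm1(.empty_loglik(tree, cats)))
  list(pres = pres, gain = gain, loss = loss,
       category_posterior = cat_post, loglik = loglik)
}

#' Posterior presence and event probabilities for one family
#'
#' @param pattern named 0/1 vector over the tree's leaves.
#' @param tree a [cogevo_tree()].
#' @param model a [gainloss_model()].
#' @return Object of class `family_posterior`: `node_presence`,
#'   `branch_gain`, `branch_loss` (numeric vectors indexed by node id, the
#'   root branch at position 1), `category_posterior`, `loglik`.
#' @export
posteriors <- function(pattern, tree, model) {
  leaf01 <- .pattern_row(pattern, tree)
  r <- .posterior_engine(tree, leaf01, model)
  structure(list(node_presence = r$pres[1, ], branch_gain = r$gain[1, ],
                 branch_loss = r$loss[1, ],
                 category_posterior = r$category_posterior[1, ],
                 loglik = r$loglik[1]),
            class = "family_posterior")
}

#' Posteriors for every family of a presence matrix
#'
#' Identical patterns are collapsed internally and the results expanded, so
#' cost scales with the number of distinct phyletic patterns.
#'
#' @param matrix presence matrix (families x genomes).
#' @param tree a [cogevo_tree()].
#' @param model a [gainloss_model()].
#' @return Object of class `gainloss_posteriors` with matrices
#'   `node_presence`, `branch_gain`, `branch_loss` (families x branches),
#'   `category_posterior`, vector `loglik`, and `family_ids`.
#' @export
compute_posteriors <- function(matrix, tree, model) {
  matrix <- .align_matrix(matrix, tree)
  key <- apply(matrix, 1, paste, collapse = "")
  uk <- !duplicated(key)
  um <- matrix(as.numeric(matrix[uk, , drop = FALSE]), nrow = sum(uk))
  idx <- match(key, key[uk])
  r <- .posterior_engine(tree, um, model)
  structure(list(tree = tree,
                 node_presence = r$pres[idx, , drop = FALSE],
                 branch_gain = r$gain[idx, , drop = FALSE],
                 branch_loss = r$loss[idx, , drop = FALSE],
                 category_posterior = r$category_posterior[idx, , drop = FALSE],
                 loglik = r$loglik[idx],
                 family_ids = rownames(matrix)),
            class = "gainloss_posteriors")
}

#' @export
print.gainloss_posteriors <- function(x, ...) {
  cat(sprintf("gainloss_posteriors: %d families x %d branches; total loglik %.3f\n",
              length(x$family_ids), ncol(x$node_presence), sum(x$loglik)))
  invisible(x)
}

#' Exhaustive-enumeration posteriors (testing oracle)
#'
#' Computes the identical contract to [posteriors()] by summing over every
#' complete assignment of ancestral states (origin fixed absent).  Cost is
#' exponential in the number of internal nodes; refuses trees with more than
#' 14 nodes.
#'
#' @inheritParams posteriors
#' @return A `family_posterior`.
#' @export
brute_force_posteriors <- function(pattern, tree, model) {
  if (tree$n > 14) stop("brute force refused: tree has more than 14 nodes")
  leaf01 <- .pattern_row(pattern, tree)[1, ]
  n <- tree$n
  free <- which(!tree$is_leaf)
  nfree <- length(free)
  states <- matrix(0, max(2^nfree, 1), n)
  states[, tree$is_leaf] <- rep(leaf01[tree$leaf_index[tree$is_leaf]],
                                each = nrow(states))
  if (nfree > 0) {
    grid <- as.matrix(expand.grid(rep(list(0:1), nfree)))
    states[, free] <- grid
  }
  cats <- .category_probs(model)
  w <- vapply(cats, `[[`, 0, "w")
  Lc <- numeric(length(cats))
  pres_c <- gain_c <- loss_c <- matrix(0, length(cats), n)
  L_empty_c <- numeric(length(cats))
  for (ci in seq_along(cats)) {
    g <- cats[[ci]]$g; l <- cats[[ci]]$l
    pr <- rep.int(1, nrow(states))
    for (v in seq_len(n)) {
      ps <- if (v == 1L) rep(0, nrow(states)) else states[, tree$parent[v]]
      sv <- states[, v]
      pv <- ifelse(ps == 0, ifelse(sv == 1, g[v], 1 - g[v]),
                   ifelse(sv == 0, l[v], 1 - l[v]))
      pr <- pr * pv
    }
    Lc[ci] <- sum(pr)
    for (v in seq_len(n)) {
      ps <- if (v == 1L) rep(0, nrow(states)) else states[, tree$parent[v]]
      pres_c[ci, v] <- sum(pr[states[, v] == 1])
      gain_c[ci, v] <- sum(pr[ps == 0 & states[, v] == 1])
      loss_c[ci, v] <- sum(pr[ps == 1 & states[, v] == 0])
    }
    # all-absent likelihood for the observability correction, enumerated too
    est <- states
    est[, tree$is_leaf] <- 0
    est <- est[!duplicated(est), , drop = FALSE]
    pr0 <- rep.int(1, nrow(est))
    for (v in seq_len(n)) {
      ps <- if (v == 1L) rep(0, nrow(est)) else est[, tree$parent[v]]
      sv <- est[, v]
      pr0 <- pr0 * ifelse(ps == 0, ifelse(sv == 1, g[v], 1 - g[v]),
                          ifelse(sv == 0, l[v], 1 - l[v]))
    }
    L_empty_c[ci] <- sum(pr0)
  }
  L <- sum(w * Lc)
  cat_post <- w * Lc / L
  loglik <- log(L)
  if (model$condition_on_observed)
    loglik <- loglik - log(1 - sum(w * L_empty_c))
  structure(list(
    node_presence = colSums((w * Lc / L) * pres_c / ifelse(Lc > 0, Lc, 1)),
    branch_gain = colSums((w * Lc / L) * gain_c / ifelse(Lc > 0, Lc, 1)),
    branch_loss = colSums((w * Lc / L) * loss_c / ifelse(Lc > 0, Lc, 1)),
    category_posterior = cat_post, loglik = loglik),
    class = "family_posterior")
}
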