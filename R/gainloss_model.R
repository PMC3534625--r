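# Branch-specific two-state gain/loss model with a 2-category family rate
# mixture.  Each branch b (the root's origin branch included) carries a gain
# probability g_b and loss probability l_b for the reference category
# (multiplier 1).  Category c rescales the underlying intensities:
#   gamma_b = -log(1 - g_b),  g_b^(c) = 1 - exp(-m_c * gamma_b)
# and likewise for losses.  The state at the origin (above the root) is
# fixed absent, so presence anywhere must be explained by at least one gain.

.P_CLIP <- c(1e-6, 1 - 1e-6)

.clip_prob <- function(p) pmin(pmax(p, .P_CLIP[1]), .P_CLIP[2])

#' Construct a gain/loss model on a tree
#'
#' @param tree a [cogevo_tree()].
#' @param gain,loss numeric vectors of per-branch gain and loss
#'   probabilities (length `n_branches(tree)`, indexed by child node;
#'   entry 1 is the origin-to-root branch).  Scalars are recycled.
#' @param m2 rate multiplier of the second family category (the first is
#'   fixed at 1); set `w2 = 0` for a single-category model.
#' @param w2 mixture weight of the second category, in `[0,1)`.
#' @param condition_on_observed correct the likelihood for the fact that
#'   families absent from every genome can never be observed, by dividing by
#'   `1 - P(all-absent pattern)`.
#' @return Object of class `gainloss_model`.
#' @export
gainloss_model <- function(tree, gain, loss, m2 = 1, w2 = 0,
                           condition_on_observed = TRUE) {
  n <- tree$n
  gain <- rep_len(as.numeric(gain), n)
  loss <- rep_len(as.numeric(loss), n)
  if (any(gain < 0 | gain > 1 | loss < 0 | loss > 1))
    stop("gain/loss probabilities must lie in [0,1]")
  if (m2 <= 0) stop("m2 must be positive")
  if (w2 < 0 || w2 >= 1) stop("w2 must lie in [0,1)")
  structure(list(tree = tree, gain = gain, loss = loss, m2 = m2, w2 = w2,
                 condition_on_observed = condition_on_observed,
                 loglik = NA_real_, converged = NA),
            class = "gainloss_model")
}

#' @export
print.gainloss_model <- function(x, ...) {
  cat(sprintf(paste0("gainloss_model: %d branches; categories w=(%.3f, %.3f),",
                     " m=(1, %.3f); condition_on_observed=%s\n"),
              x$tree$n, 1 - x$w2, x$w2, x$m2, x$condition_on_observed))
  if (!is.na(x$loglik))
    cat(sprintf("  fitted: loglik %.3f, converged %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Two-state transition matrix of one branch
#'
#' Rows are the parent state (absent, present), columns the child state;
#' rows sum to one: `[[1-g, g], [l, 1-l]]`.
#'
#' @param g gain probability (0 to 1).
#' @param l loss probability (0 to 1).
#' @return 2x2 numeric matrix with dimnames `absent`/`present`.
#' @export
branch_matrix <- function(g, l) {
  if (any(c(g, l) < 0) || any(c(g, l) > 1))
    stop("g and l must lie in [0,1]")
  matrix(c(1 - g, l, g, 1 - l), 2, 2,
         dimnames = list(c("absent", "present"), c("absent", "present")))
}

# per-category branch probabilities; returns list of (g, l) vectors
.category_probs <- function(model) {
  gam <- -log1p(-.clip_prob(model$gain))
  lam <- -log1p(-.clip_prob(model$loss))
  mult <- c(1, model$m2)
  w <- c(1 - model$w2, model$w2)
  keep <- w > 0
  lapply(which(keep), function(c)
    list(g = .clip_prob(-expm1(-mult[c] * gam)),
         l = .clip_prob(-expm1(-mult[c] * lam)),
         w = w[c]))
}

# -- pruning (down) pass, vectorized over patterns ---------------------------
# leaf01: matrix [n_patterns x n_leaves], columns in leaf-index order.
# g, l: per-branch probability vectors.  Returns per-pattern log-likelihood
# and the scaled conditional likelihood matrices needed by the up pass.
.down_pass <- function(tree, leaf01, g, l) {
  npat <- nrow(leaf01)
  n <- tree$n
  L0 <- matrix(0, npat, n)
  L1 <- matrix(0, npat, n)
  logsc <- numeric(npat)
  for (v in n:1) {
    if (tree$is_leaf[v]) {
      x <- leaf01[, tree$leaf_index[v]]
      L0[, v] <- 1 - x
      L1[, v] <- x
    } else {
      a0 <- rep.int(1, npat)
      a1 <- rep.int(1, npat)
      for (c in tree$children[[v]]) {
        a0 <- a0 * ((1 - g[c]) * L0[, c] + g[c] * L1[, c])
        a1 <- a1 * (l[c] * L0[, c] + (1 - l[c]) * L1[, c])
      }
      s <- pmax(a0, a1)
      s[s == 0] <- 1
      L0[, v] <- a0 / s
      L1[, v] <- a1 / s
      logsc <- logsc + log(s)
    }
  }
  lik_root <- (1 - g[1]) * L0[, 1] + g[1] * L1[, 1]
  list(L0 = L0, L1 = L1,
       loglik = ifelse(lik_root > 0, log(lik_root) + logsc, -Inf))
}

# per-pattern, per-category log-likelihoods; returns matrix [npat x ncat]
.pattern_logliks <- function(tree, leaf01, cats) {
  matrix(vapply(cats, function(cc) .down_pass(tree, leaf01, cc$g, cc$l)$loglik,
                numeric(nrow(leaf01))),
         nrow = nrow(leaf01), ncol = length(cats))
}

# log(sum_c w_c exp(ll_c)) row-wise, stably
.mix_loglik <- function(ll, w) {
  ll <- ll + rep(log(w), each = nrow(ll))
  m <- do.call(pmax, c(as.data.frame(ll), list(-Inf)))
  res <- m + log(rowSums(exp(ll - m)))
  res[!is.finite(m)] <- -Inf
  res
}

# mixture log-likelihood of the all-absent pattern (unconditioned)
.empty_loglik <- function(tree, cats) {
  empty <- matrix(0, 1, sum(tree$is_leaf))
  ll <- .pattern_logliks(tree, empty, cats)
  .mix_loglik(ll, vapply(cats, `[[`, 0, "w"))
}

#' Log-likelihood of one family's phyletic pattern
#'
#' Computed by the pruning algorithm over the two states with the origin
#' fixed absent and the origin-to-root branch applied, mixed over the rate
#' categories.  With `condition_on_observed` the likelihood is divided by
#' the probability that the family is present in at least one genome.
#'
#' @param pattern named 0/1 vector over the tree's leaves (names matched to
#'   leaf names; an unnamed vector must already be in leaf order).
#' @param tree a [cogevo_tree()].
#' @param model a [gainloss_model()].
#' @return Log-likelihood (scalar).
#' @export
family_loglik <- function(pattern, tree, model) {
  leaf01 <- .pattern_row(pattern, tree)
  cats <- .category_probs(model)
  w <- vapply(cats, `[[`, 0, "w")
  ll <- .mix_loglik(.pattern_logliks(tree, leaf01, cats), w)
  if (model$condition_on_observed)
    ll <- ll - log(-expm1(.empty_loglik(tree, cats)))
  as.numeric(ll)
}

.pattern_row <- function(pattern, tree) {
  ln <- leaf_names(tree)
  if (!is.null(names(pattern))) {
    if (!setequal(names(pattern), ln))
      stop("pattern names do not match the tree's leaves")
    pattern <- pattern[ln]
  } else if (length(pattern) != length(ln)) {
    stop("pattern length does not match the number of leaves")
  }
  if (any(!pattern %in% c(0, 1))) stop("pattern values must be 0/1")
  matrix(as.numeric(pattern), 1, length(ln))
}
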