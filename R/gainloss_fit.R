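# Maximum-likelihood fitting of the gain/loss model.
#
# The E-step machinery does double duty.  One up-down pass per category
# yields the expected per-branch gains, losses and parent-state occupancies
# plus category responsibilities; conditioning on observability is handled
# by augmenting the sample with n * P(empty) / (1 - P(empty)) fractional
# "ghost" families carrying the all-absent pattern (truncated-data EM).
# Those same expected counts are the exact score of the conditional
# log-likelihood (the observed-data score equals the posterior-expected
# complete-data score), so the quasi-Newton stage runs L-BFGS with analytic
# gradients at one E-pass per iteration.  A short EM warm-up precedes it:
# EM is monotone and robust far from the optimum, while L-BFGS traverses
# the nearly flat ridge -- root presence traded against secondary gains --
# on which plain EM crawls.

.THETA_BOUNDS <- c(-16, 4)
.GAMMA_MAX <- 20

.unpack_theta <- function(theta, n, two_cat) {
  gam <- exp(theta[seq_len(n)])
  lam <- exp(theta[n + seq_len(n)])
  m2 <- if (two_cat) exp(theta[2 * n + 1]) else 1
  w2 <- if (two_cat) plogis(theta[2 * n + 2]) else 0
  list(gain = .clip_prob(-expm1(-gam)), loss = .clip_prob(-expm1(-lam)),
       m2 = m2, w2 = w2)
}

.pack_theta <- function(par, two_cat) {
  th <- c(log(pmax(-log1p(-par$gain), 1e-12)),
          log(pmax(-log1p(-par$loss), 1e-12)))
  if (two_cat) th <- c(th, log(par$m2), qlogis(min(max(par$w2, 1e-6), 1 - 1e-6)))
  pmin(pmax(th, .THETA_BOUNDS[1]), .THETA_BOUNDS[2])
}

# conditional (or plain) data log-likelihood for collapsed patterns
.data_loglik <- function(tree, leaf01, wt, model) {
  cats <- .category_probs(model)
  ll <- .mix_loglik(.pattern_logliks(tree, leaf01, cats),
                    vapply(cats, `[[`, 0, "w"))
  if (model$condition_on_observed)
    ll <- ll - log(-expm1(.empty_loglik(tree, cats)))
  sum(wt * ll)
}

# Ghost-augmented expected sufficient statistics.  Returns the conditional
# log-likelihood and, per category (rows) and branch (columns): expected
# gains G, losses Lo, parent-absent occupancy N0, parent-present N1, plus
# the responsibility-weighted family totals per category.
.suff_stats <- function(tree, leaf01, wt, par, condition, two_cat) {
  n <- tree$n
  nfam <- sum(wt)
  mult <- c(1, par$m2)
  w <- if (two_cat) c(1 - par$w2, par$w2) else 1
  ncat <- length(w)
  gam <- -log1p(-.clip_prob(par$gain))
  lam <- -log1p(-.clip_prob(par$loss))
  aug <- rbind(leaf01, 0)          # last row: the all-absent ghost pattern
  ig <- nrow(aug)
  up <- vector("list", ncat)
  llmat <- matrix(0, ig, ncat)
  for (j in seq_len(ncat)) {
    g <- .clip_prob(-expm1(-mult[j] * gam))
    l <- .clip_prob(-expm1(-mult[j] * lam))
    up[[j]] <- .updown_category(tree, aug, g, l)
    llmat[, j] <- up[[j]]$loglik
  }
  mix <- .mix_loglik(llmat, w)
  resp <- exp(llmat + rep(log(w), each = ig) - mix)
  P0 <- exp(mix[ig])
  ghost <- if (condition) nfam * P0 / (1 - P0) else 0
  wt_aug <- c(wt, ghost)
  ll <- sum(wt * mix[-ig]) - (if (condition) nfam * log(1 - P0) else 0)
  G <- Lo <- N0 <- N1 <- matrix(0, ncat, n)
  for (j in seq_len(ncat)) {
    wj <- wt_aug * resp[, j]
    tw <- sum(wj)
    for (v in seq_len(n)) {
      pp <- if (v == 1L) 0 else up[[j]]$pres[, tree$parent[v]]
      ppw <- sum(wj * pp)
      N0[j, v] <- tw - ppw
      N1[j, v] <- ppw
      G[j, v] <- sum(wj * up[[j]]$gain[, v])
      Lo[j, v] <- sum(wj * up[[j]]$loss[, v])
    }
  }
  list(ll = ll, G = G, Lo = Lo, N0 = N0, N1 = N1,
       cat_tot = colSums(wt_aug * resp), wt_tot = sum(wt_aug),
       gam = gam, lam = lam, mult = mult)
}

# analytic gradient of the conditional log-likelihood on theta scale
.theta_gradient <- function(st, par, n, two_cat) {
  mult <- st$mult
  ncat <- nrow(st$G)
  ggam <- glam <- numeric(n)
  gm2 <- 0
  for (j in seq_len(ncat)) {
    m <- mult[j]
    pg <- pmin(pmax(-expm1(-m * st$gam), 1e-12), 1 - 1e-12)
    pl <- pmin(pmax(-expm1(-m * st$lam), 1e-12), 1 - 1e-12)
    eg <- exp(-m * st$gam)
    el <- exp(-m * st$lam)
    ggam <- ggam + st$G[j, ] * m * eg / pg - (st$N0[j, ] - st$G[j, ]) * m
    glam <- glam + st$Lo[j, ] * m * el / pl - (st$N1[j, ] - st$Lo[j, ]) * m
    if (j == 2) {
      gm2 <- sum(st$G[2, ] * st$gam * eg / pg - (st$N0[2, ] - st$G[2, ]) * st$gam) +
        sum(st$Lo[2, ] * st$lam * el / pl - (st$N1[2, ] - st$Lo[2, ]) * st$lam)
    }
  }
  gr <- c(ggam * st$gam, glam * st$lam)   # chain rule for theta = log(rate)
  if (two_cat) {
    w2 <- par$w2
    gpsi <- st$cat_tot[2] - w2 * st$wt_tot
    gr <- c(gr, gm2 * par$m2, gpsi)
  }
  gr
}

# one EM iteration (generalized M-step: 1-D solves per branch, then m2, w2)
.em_step <- function(tree, leaf01, wt, par, condition, two_cat) {
  n <- tree$n
  st <- .suff_stats(tree, leaf01, wt, par, condition, two_cat)
  mm <- st$mult[seq_len(nrow(st$G))]
  opt1d <- function(E, N, fallback) {
    f <- function(x) {
      p <- pmin(pmax(-expm1(-mm * x), 1e-12), 1 - 1e-12)
      sum(E * log(p) + (N - E) * log1p(-p))
    }
    if (sum(E) <= 1e-12) return(1e-9)
    if (sum(N - E) <= 1e-12) return(.GAMMA_MAX)
    optimize(f, c(1e-9, .GAMMA_MAX), maximum = TRUE, tol = 1e-10)$maximum
  }
  gam_new <- vapply(seq_len(n), function(v)
    opt1d(st$G[, v], st$N0[, v], st$gam[v]), 0)
  lam_new <- vapply(seq_len(n), function(v) {
    if (sum(st$N1[, v]) < 1e-12) return(st$lam[v])  # e.g. the origin branch
    opt1d(st$Lo[, v], st$N1[, v], st$lam[v])
  }, 0)
  par$gain <- .clip_prob(-expm1(-gam_new))
  par$loss <- .clip_prob(-expm1(-lam_new))
  if (two_cat) {
    par$w2 <- min(max(st$cat_tot[2] / st$wt_tot, 1e-4), 1 - 1e-4)
    fm <- function(logm) {
      m2 <- exp(logm)
      g2 <- pmin(pmax(-expm1(-m2 * gam_new), 1e-12), 1 - 1e-12)
      l2 <- pmin(pmax(-expm1(-m2 * lam_new), 1e-12), 1 - 1e-12)
      sum(st$G[2, ] * log(g2) + (st$N0[2, ] - st$G[2, ]) * log1p(-g2) +
            st$Lo[2, ] * log(l2) + (st$N1[2, ] - st$Lo[2, ]) * log1p(-l2))
    }
    par$m2 <- exp(optimize(fm, c(log(1e-3), log(100)), maximum = TRUE,
                           tol = 1e-8)$maximum)
  }
  par
}

#' Fit the branch-specific gain/loss model by maximum likelihood
#'
#' Maximizes the summed per-family log-likelihood (optionally conditioned
#' on families being observable, i.e. present in at least one genome) over
#' per-branch gain and loss probabilities plus the two-category rate
#' mixture.  Optimization starts from a deterministic sparse initialization
#' (secondary gains 0.02, root gain 0.5, losses 0.3) with a monotone EM
#' warm-up -- the observability correction implemented as truncated-data EM
#' -- and finishes with L-BFGS on log-intensity/logit-transformed
#' parameters using analytic gradients derived from the same expected event
#' counts.  The default tolerance is deliberately tight: the likelihood
#' surface has a nearly flat ridge trading root presence against secondary
#' gains, and walking that ridge to its optimum matters more than the final
#' likelihood digits suggest (see the methods vignette).
#'
#' @param matrix presence matrix (families x genomes).
#' @param tree a [cogevo_tree()] whose leaves match the matrix columns.
#' @param n_categories 1 or 2 family rate categories.
#' @param condition_on_observed divide each family likelihood by the
#'   probability of a non-empty pattern (recommended whenever all-absent
#'   families are unobservable, which is always the case for real data).
#' @param em_iter EM warm-up iterations per round.
#' @param rounds maximal number of EM + L-BFGS rounds.
#' @param tol convergence tolerance, log-likelihood units per family.
#' @param init optional named list overriding initial `gain`, `loss`, `m2`,
#'   `w2`.
#' @return A fitted [gainloss_model()] with `loglik` and `converged` set.
#' @export
fit_model <- function(matrix, tree, n_categories = 2,
                      condition_on_observed = TRUE,
                      em_iter = 100, rounds = 6, tol = 1e-8, init = NULL) {
  stopifnot(n_categories %in% 1:2)
  matrix <- .align_matrix(matrix, tree)
  nfam <- nrow(matrix)
  if (nfam == 0) stop("empty presence matrix")
  if (nfam < 50)
    warning("fewer than 50 families; branch-specific rates will be noisy")
  if (all(matrix == 1))
    warning("every family is ubiquitous; loss probabilities are not identifiable")
  key <- apply(matrix, 1, paste, collapse = "")
  uk <- !duplicated(key)
  leaf01 <- matrix(as.numeric(matrix[uk, , drop = FALSE]), nrow = sum(uk))
  wt <- as.numeric(table(factor(key, levels = key[uk])))
  n <- tree$n
  two_cat <- n_categories == 2

  par <- list(gain = c(0.5, rep(0.02, n - 1)), loss = rep(0.3, n),
              m2 = if (two_cat) 3 else 1, w2 = if (two_cat) 0.5 else 0)
  if (!is.null(init)) par[names(init)] <- init

  mk <- function(p) gainloss_model(tree, p$gain, p$loss, m2 = p$m2, w2 = p$w2,
                                   condition_on_observed = condition_on_observed)
  negll <- function(theta) {
    p <- .unpack_theta(theta, n, two_cat)
    v <- -.data_loglik(tree, leaf01, wt, mk(p))
    if (!is.finite(v)) 1e10 else v
  }
  neggr <- function(theta) {
    p <- .unpack_theta(theta, n, two_cat)
    st <- .suff_stats(tree, leaf01, wt, p, condition_on_observed, two_cat)
    -.theta_gradient(st, p, n, two_cat)
  }

  ll <- .data_loglik(tree, leaf01, wt, mk(par))
  converged <- FALSE
  for (round in seq_len(rounds)) {
    ll_round <- ll
    for (it in seq_len(em_iter)) {
      par_new <- .em_step(tree, leaf01, wt, par, condition_on_observed, two_cat)
      ll_new <- .data_loglik(tree, leaf01, wt, mk(par_new))
      if (ll_new >= ll) par <- par_new
      delta <- ll_new - ll
      ll <- max(ll, ll_new)
      if (abs(delta) < tol * nfam) break
    }
    fit <- tryCatch(
      optim(.pack_theta(par, two_cat), negll, neggr, method = "L-BFGS-B",
            lower = .THETA_BOUNDS[1], upper = .THETA_BOUNDS[2],
            control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && -fit$value > ll) {
      par <- .unpack_theta(fit$par, n, two_cat)
      ll <- -fit$value
    }
    if (ll - ll_round < tol * nfam) { converged <- TRUE; break }
  }

  model <- mk(par)
  model$loglik <- ll
  model$converged <- converged
  if (!converged)
    warning("optimization did not reach tolerance within ", rounds, " rounds")
  model
}
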