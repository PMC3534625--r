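# Commonality distribution of a pangenome and its decomposition into
# exponential components: the rapidly decaying "cloud" of rare families,
# the intermediate "shell", and the nearly ubiquitous "core" whose
# component rises toward k = G.  Component sizes are the sums (integrals)
# of each exponential over k = 1..G.

#' Commonality histogram of a presence matrix
#'
#' @param matrix presence matrix (families x genomes).
#' @return Object of class `commonality_histogram`: `G` (number of
#'   genomes) and `counts`, a length-`G` integer vector where `counts[k]`
#'   is the number of families present in exactly `k` genomes (families
#'   present nowhere are excluded).
#' @export
commonality_histogram <- function(matrix) {
  if (nrow(matrix) == 0) stop("empty presence matrix")
  G <- ncol(matrix)
  k <- rowSums(matrix)
  counts <- tabulate(k[k > 0], nbins = G)
  structure(list(G = G, counts = counts), class = "commonality_histogram")
}

#' @export
print.commonality_histogram <- function(x, ...) {
  cat(sprintf("commonality_histogram: G=%d genomes, %d families\n",
              x$G, sum(x$counts)))
  invisible(x)
}

.mixture_mu <- function(a, b, k) {
  mu <- rep(0, length(k))
  for (i in seq_along(a)) mu <- mu + a[i] * exp(b[i] * k)
  mu
}

# Poisson deviance between counts y and intensities mu (y may be real)
.poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-12)
  term <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(mu - y + term)
}

#' Fit a mixture of exponentials to a commonality histogram
#'
#' Minimizes the Poisson deviance between `counts(k)` and
#' `sum_i a_i * exp(b_i * k)` over `k = 1..G` (counts are counts, so a
#' Poisson objective avoids the zero-count pathologies of least squares on
#' logs).  Optimization is L-BFGS-B on `(log a_i, b_i)` with exponents
#' bounded to `|b| <= 2` (steeper than e^2-fold change per genome is not
#' identifiable from integer k), multistarted from log-linear fits anchored
#' on contiguous thirds of the k range plus seeded jitter.
#'
#' @param hist a [commonality_histogram()].
#' @param n_components number of exponential components (3 for the
#'   cloud/shell/core decomposition).
#' @param n_starts number of multistart initializations.
#' @param seed RNG seed for the start jitter.
#' @return Object of class `exp_mixture_fit`: data frame `components`
#'   (`a`, `b`, `size`, labels for 3 components), `objective`, `converged`,
#'   `G`.  Components are ordered by increasing exponent `b`, so component
#'   1 is the fastest-decaying ("cloud" when `n_components = 3`, then
#'   "shell", then "core").
#' @export
fit_exponential_mixture <- function(hist, n_components = 3, n_starts = 20,
                                    seed = 1) {
  stopifnot(inherits(hist, "commonality_histogram"))
  k <- seq_len(hist$G)
  y <- hist$counts
  if (sum(y > 0) < 2 * n_components)
    stop("need at least ", 2 * n_components, " nonzero histogram bins")
  nc <- n_components

  obj <- function(theta) {
    a <- exp(theta[seq_len(nc)])
    b <- theta[nc + seq_len(nc)]
    v <- .poisson_deviance(y, .mixture_mu(a, b, k))
    if (!is.finite(v)) 1e12 else v
  }

  # anchor starts: log-linear fit on each contiguous third of the support
  support <- which(y > 0)
  pieces <- if (nc == 1) list(support)
  else split(support, cut(seq_along(support), nc, labels = FALSE))
  anchors <- lapply(pieces, function(ix) {
    kk <- k[ix]; yy <- y[ix]
    if (length(ix) >= 2 && sd(kk) > 0) {
      f <- lm(log(pmax(yy, 0.5)) ~ kk)
      c(a = exp(unname(coef(f)[1])), b = max(-2, min(2, unname(coef(f)[2]))))
    } else c(a = max(yy, 1), b = 0)
  })
  theta_anchor <- c(log(vapply(anchors, `[`, 0, "a")),
                    vapply(anchors, `[`, 0, "b"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- theta_anchor
    if (s > 1) th0 <- th0 + rnorm(length(th0), 0, c(rep(1, nc), rep(0.3, nc)))
    th0[nc + seq_len(nc)] <- pmax(-2, pmin(2, th0[nc + seq_len(nc)]))
    f <- tryCatch(
      optim(th0, obj, method = "L-BFGS-B",
            lower = c(rep(-20, nc), rep(-2, nc)),
            upper = c(rep(40, nc), rep(2, nc)),
            control = list(maxit = 1000)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) stop("all optimization starts failed")
  a <- exp(best$par[seq_len(nc)])
  b <- best$par[nc + seq_len(nc)]
  o <- order(b)
  a <- a[o]; b <- b[o]
  sizes <- vapply(seq_len(nc), function(i) sum(a[i] * exp(b[i] * k)), 0)
  labels <- if (nc == 3) c("cloud", "shell", "core")
  else paste0("component", seq_len(nc))
  structure(list(
    components = data.frame(component = labels, a = a, b = b, size = sizes),
    objective = best$value, converged = best$convergence == 0, G = hist$G),
    class = "exp_mixture_fit")
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  cat(sprintf("exp_mixture_fit: deviance %.4g, converged %s\n",
              x$objective, x$converged))
  print(x$components, row.names = FALSE)
  invisible(x)
}

#' Component sizes (integrals) of a fitted exponential mixture
#'
#' `S_i = sum_{k=1..G} a_i * exp(b_i * k)`, reported exactly and rounded to
#' two significant figures (the usual reporting convention for pangenome
#' component sizes).
#'
#' @param fit an [fit_exponential_mixture()] result, or a data frame with
#'   columns `a` and `b`.
#' @param G number of genomes (taken from the fit when available).
#' @return Data frame: `component`, `size`, `size_2sf`.
#' @export
component_sizes <- function(fit, G = NULL) {
  comp <- if (inherits(fit, "exp_mixture_fit")) fit$components else fit
  if (is.null(G)) G <- fit$G
  k <- seq_len(G)
  sz <- vapply(seq_len(nrow(comp)),
               function(i) sum(comp$a[i] * exp(comp$b[i] * k)), 0)
  lab <- if ("component" %in% names(comp)) comp$component
  else paste0("component", seq_len(nrow(comp)))
  data.frame(component = lab, size = sz, size_2sf = signif(sz, 2))
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
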