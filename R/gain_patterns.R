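# Likely-gain patterns and the downstream statistics of gene gain:
# pattern frequency tables, gains-per-family distributions, multi-gain
# branch correlations, and the two-gain pair-exchange analysis with a
# product-of-gains Poisson null.

#' Likely-gain pattern of one family
#'
#' Branches whose posterior gain probability strictly exceeds the threshold
#' are marked as likely gains; the total posterior gain is summed over all
#' branches regardless of the threshold.
#'
#' @param post a `family_posterior` (from [posteriors()]), or a numeric
#'   vector of per-branch gain posteriors.
#' @param threshold gain-probability threshold (strict `>`).
#' @param family_id optional id carried through.
#' @return Object of class `gain_pattern`: `family`, `likely_gain_branches`
#'   (integer branch ids), `total_posterior_gain`, `class` (one of
#'   `"zero-gain"`, `"single-gain"`, `"multi-gain"`).
#' @export
likely_gains <- function(post, threshold = 0.5, family_id = NA_character_) {
  bg <- if (inherits(post, "family_posterior")) post$branch_gain else as.numeric(post)
  set <- which(bg > threshold)
  cls <- if (length(set) == 0) "zero-gain"
  else if (length(set) == 1) "single-gain" else "multi-gain"
  structure(list(family = family_id, likely_gain_branches = set,
                 total_posterior_gain = sum(bg), class = cls),
            class = "gain_pattern")
}

#' Likely-gain patterns for every family of a posterior batch
#'
#' @param post a [compute_posteriors()] result.
#' @param threshold gain-probability threshold (strict `>`).
#' @return List of [likely_gains()] patterns, one per family.
#' @export
gain_patterns <- function(post, threshold = 0.5) {
  stopifnot(inherits(post, "gainloss_posteriors"))
  lapply(seq_along(post$family_ids), function(i)
    likely_gains(post$branch_gain[i, ], threshold, post$family_ids[i]))
}

#' Distinct phyletic patterns and their uniqueness
#'
#' @param matrix presence matrix.
#' @return List: `n_distinct`, `n_unique` (patterns occurring once),
#'   `unique_pct` (integer percent), `frequency` (data frame of pattern
#'   string and count, most frequent first).
#' @export
phyletic_pattern_table <- function(matrix) {
  if (nrow(matrix) == 0) stop("empty presence matrix")
  key <- apply(matrix, 1, paste, collapse = "")
  tab <- table(key)
  freq <- data.frame(pattern = names(tab), count = as.integer(tab))
  freq <- freq[order(-freq$count, freq$pattern), , drop = FALSE]
  rownames(freq) <- NULL
  n_distinct <- nrow(freq)
  n_unique <- sum(freq$count == 1)
  list(n_distinct = n_distinct, n_unique = n_unique,
       unique_pct = pattern_unique_pct(n_unique, n_distinct),
       frequency = freq)
}

#' Percent of distinct patterns that are unique
#'
#' @param n_unique patterns seen exactly once.
#' @param n_distinct distinct patterns.
#' @return Integer percent (rounded).
#' @export
pattern_unique_pct <- function(n_unique, n_distinct) {
  round(100 * n_unique / n_distinct)
}

#' Ubiquitous families, optionally excluding one genome
#'
#' @param matrix presence matrix.
#' @param excluded_genome genome id; also count families present in every
#'   genome except exactly this one.
#' @return List: `ubiquitous` and (when requested) `ubiquitous_excluding`.
#' @export
ubiquity_counts <- function(matrix, excluded_genome = NULL) {
  G <- ncol(matrix)
  rs <- rowSums(matrix)
  out <- list(ubiquitous = sum(rs == G))
  if (!is.null(excluded_genome)) {
    if (!excluded_genome %in% colnames(matrix))
      stop("unknown genome id: ", excluded_genome)
    out$ubiquitous_excluding <-
      sum(rs == G - 1 & matrix[, excluded_genome] == 0)
  }
  out
}

#' Distribution of gains per family
#'
#' Discrete histogram of likely-gain counts, kernel-smoothed density of the
#' total posterior gain (Gaussian kernel, Silverman's bandwidth), an
#' exponential decay rate fitted by least squares on the log histogram over
#' counts >= 1 (zero-count bins skipped), and the single-gain fraction
#' among families with at least one likely gain.
#'
#' @param patterns list of [likely_gains()] patterns.
#' @return List: `histogram` (data frame `n_gains`, `count`, including the
#'   zero-gain bin), `density` (a [stats::density()] object or `NULL`),
#'   `decay_rate` (`NA` if the fit is degenerate), `single_gain_fraction`.
#' @export
gain_count_distribution <- function(patterns) {
  ng <- vapply(patterns, function(p) length(p$likely_gain_branches), 0L)
  tot <- vapply(patterns, `[[`, 0, "total_posterior_gain")
  hist <- data.frame(n_gains = 0:max(ng),
                     count = tabulate(ng + 1L, nbins = max(ng) + 1L))
  pos <- hist[hist$n_gains >= 1 & hist$count > 0, , drop = FALSE]
  decay <- NA_real_
  if (nrow(pos) >= 2 && length(patterns) >= 10) {
    f <- lm(log(count) ~ n_gains, data = pos)
    decay <- -unname(coef(f)[2])
  }
  dens <- if (length(tot) >= 2 && sd(tot) > 0) density(tot, bw = "nrd0") else NULL
  with_gain <- sum(ng >= 1)
  list(histogram = hist, density = dens, decay_rate = decay,
       single_gain_fraction = if (with_gain > 0) sum(ng == 1) / with_gain else NA_real_)
}

.spearman <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), n - 2))
}

#' Per-branch multi-gain statistics and their correlation with total gains
#'
#' For every branch: the total posterior gains summed over all families,
#' and the posterior gains summed over multi-gain families only (families
#' whose total posterior gain exceeds 1.5).  Spearman correlation (average
#' ranks, large-sample t p-value) between the two vectors is reported for
#' all branches and for internal (non-leaf) branches separately.
#'
#' @param post a [compute_posteriors()] result.
#' @param multi_threshold total-posterior-gain threshold defining
#'   multi-gain families (strict `>`).
#' @return List: `per_branch` data frame (`branch`, `total_gains`,
#'   `multigain_gains`, `is_internal`), `all` and `internal` each with
#'   `rho` and `p`.
#' @export
multigain_branch_stats <- function(post, multi_threshold = 1.5) {
  stopifnot(inherits(post, "gainloss_posteriors"))
  if (ncol(post$branch_gain) < 5) stop("need at least 5 branches")
  tot <- colSums(post$branch_gain)
  multi <- rowSums(post$branch_gain) > multi_threshold
  mg <- colSums(post$branch_gain[multi, , drop = FALSE])
  internal <- !post$tree$is_leaf
  per <- data.frame(branch = seq_along(tot), total_gains = tot,
                    multigain_gains = mg, is_internal = internal)
  list(per_branch = per,
       all = .spearman(tot, mg),
       internal = .spearman(tot[internal], mg[internal]))
}

#' Observed two-gain branch pairs
#'
#' Families with exactly two likely gains, neither on the origin-to-root
#' branch (gains in the last common ancestor are the default state, not
#' exchange), counted as unordered branch pairs -- the raw material of the
#' within-domain gene-exchange analysis.
#'
#' @param patterns list of [likely_gains()] patterns.
#' @param root_branch branch id of the origin-to-root branch (1 in this
#'   package's preorder numbering).
#' @return Object of class `pair_exchange_table`: `N2`, `observed` (data
#'   frame `branch_i`, `branch_j`, `observed` with `branch_i < branch_j`).
#' @export
two_gain_pairs <- function(patterns, root_branch = 1L) {
  sel <- Filter(function(p) length(p$likely_gain_branches) == 2 &&
                  !root_branch %in% p$likely_gain_branches, patterns)
  if (length(sel) == 0) {
    obs <- data.frame(branch_i = integer(0), branch_j = integer(0),
                      observed = integer(0))
  } else {
    pr <- t(vapply(sel, function(p) sort(p$likely_gain_branches), integer(2)))
    key <- paste(pr[, 1], pr[, 2], sep = "-")
    tab <- table(key)
    parts <- do.call(rbind, strsplit(names(tab), "-", fixed = TRUE))
    obs <- data.frame(branch_i = as.integer(parts[, 1]),
                      branch_j = as.integer(parts[, 2]),
                      observed = as.integer(tab))
    obs <- obs[order(obs$branch_i, obs$branch_j), , drop = FALSE]
    rownames(obs) <- NULL
  }
  structure(list(N2 = length(sel), observed = obs),
            class = "pair_exchange_table")
}

#' Expected two-gain pair counts under the product-of-gains null
#'
#' Under a null of independent exchange, the expected count of pair (i, j)
#' is proportional to the product of the branches' total gains:
#' `expected(i,j) = N2 * g_i * g_j / sum_{k<l} g_k * g_l` over branches with
#' positive totals (root branch excluded).  Expected counts sum to `N2`.
#' Each observed pair receives an upper-tail Poisson p-value, and the
#' Spearman correlation between observed and expected is reported over
#' pairs observed more than once.
#'
#' @param table a [two_gain_pairs()] result.
#' @param branch_gain_totals per-branch total posterior gains (full-length
#'   vector indexed by branch id).
#' @param root_branch branch id excluded from the null.
#' @return The table with `expected` (all-pairs data frame: `branch_i`,
#'   `branch_j`, `expected`), the observed table gaining `expected`, `p`
#'   and `bh_q` columns, and `spearman` (`rho`, `p`, over pairs with
#'   observed > 1).
#' @export
expected_pair_counts <- function(table, branch_gain_totals, root_branch = 1L) {
  stopifnot(inherits(table, "pair_exchange_table"))
  g <- branch_gain_totals
  g[root_branch] <- 0
  br <- which(g > 0)
  if (length(br) < 2) stop("need at least two branches with positive gain totals")
  pairs <- t(combn(br, 2))
  prod <- g[pairs[, 1]] * g[pairs[, 2]]
  expected <- table$N2 * prod / sum(prod)
  exp_df <- data.frame(branch_i = pairs[, 1], branch_j = pairs[, 2],
                       expected = expected)
  obs <- table$observed
  key <- function(d) paste(d$branch_i, d$branch_j, sep = "-")
  m <- match(key(obs), key(exp_df))
  obs$expected <- exp_df$expected[m]
  obs$p <- mapply(poisson_upper_pvalue, obs$observed, pmax(obs$expected, 1e-300))
  obs$bh_q <- stats::p.adjust(obs$p, method = "BH")
  gt1 <- obs$observed > 1
  sp <- if (sum(gt1) >= 2 && all(obs$observed[gt1] == obs$expected[gt1]))
    list(rho = 1, p = 0)  # identical vectors are perfectly concordant
  else if (sum(gt1) >= 3) .spearman(obs$observed[gt1], obs$expected[gt1])
  else list(rho = NA_real_, p = NA_real_)
  table$expected <- exp_df
  table$observed <- obs
  table$spearman <- sp
  table
}

#' Upper-tail Poisson p-value
#'
#' `P(X >= observed)` for `X ~ Poisson(expected)`, computed exactly via the
#' regularized gamma function (no normal approximation).
#'
#' @param observed non-negative integer count.
#' @param expected positive Poisson mean.
#' @return Probability in (0, 1].
#' @export
poisson_upper_pvalue <- function(observed, expected) {
  if (observed < 0) stop("observed count must be non-negative")
  if (expected <= 0) stop("expected must be positive")
  if (observed == 0) return(1)
  ppois(observed - 1, expected, lower.tail = FALSE)
}
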