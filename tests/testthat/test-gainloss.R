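test_that("branch_matrix is the two-state transition matrix", {
  expect_equal(unname(branch_matrix(0, 0)), diag(2))
  expect_equal(unname(branch_matrix(1, 1)),
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(unname(branch_matrix(0.3, 0.1)),
               matrix(c(0.7, 0.1, 0.3, 0.9), 2, 2))
  expect_true(all(rowSums(branch_matrix(0.42, 0.17)) == 1))
  expect_error(branch_matrix(1.2, 0), "0,1")
})

test_that("single-leaf likelihoods reduce to the origin-branch probability", {
  tr <- read_newick("A;")
  m <- gainloss_model(tr, gain = 0.37, loss = 0.2,
                      condition_on_observed = FALSE)
  expect_equal(family_loglik(c(A = 1), tr, m), log(0.37), tolerance = 1e-9)
  expect_equal(family_loglik(c(A = 0), tr, m), log(1 - 0.37), tolerance = 1e-9)

  bf <- brute_force_posteriors(c(A = 1), tr, m)
  expect_equal(bf$node_presence[1], 1)
  expect_equal(bf$branch_gain[1], 1)
})

test_that("two-leaf likelihood equals the exhaustive two-term sum", {
  tr <- read_newick("(A:1,B:1):1;")
  g <- c(0.3, 0.2, 0.4); l <- c(0.1, 0.25, 0.35)
  m <- gainloss_model(tr, g, l, condition_on_observed = FALSE)
  # enumerate the root state by hand
  term <- function(r) {
    (if (r == 0) 1 - g[1] else g[1]) *
      (if (r == 0) g[2] else 1 - l[2]) *
      (if (r == 0) 1 - g[3] else l[3])
  }
  expect_equal(family_loglik(c(A = 1, B = 0), tr, m),
               log(term(0) + term(1)), tolerance = 1e-12)
})

test_that("hand enumeration of g=l=0.5 on a two-leaf tree matches posteriors", {
  tr <- read_newick("(A,B);")
  m <- gainloss_model(tr, 0.5, 0.5, condition_on_observed = FALSE)
  p <- posteriors(c(A = 1, B = 0), tr, m)
  # four root/origin configurations, all transition probs 0.5:
  # every complete assignment has probability 0.5^3; root state is
  # equally likely present or absent given one presence and one absence
  expect_equal(p$node_presence[1], 0.5, tolerance = 1e-4)
  expect_equal(p$branch_gain[1], 0.5, tolerance = 1e-4)
  expect_equal(p$loglik, log(0.25), tolerance = 1e-4)
})

test_that("pruning and up-down agree with exhaustive enumeration", {
  set.seed(2024)
  worst <- 0
  for (i in 1:200) {
    tr <- rand_tree(sample(2:6, 1))
    m <- rand_model(tr)
    pat <- rand_pattern(tr)
    p1 <- posteriors(pat, tr, m)
    p2 <- brute_force_posteriors(pat, tr, m)
    scale <- max(1, abs(p2$loglik))
    worst <- max(worst,
                 abs(p1$loglik - p2$loglik) / scale,
                 abs(family_loglik(pat, tr, m) - p2$loglik) / scale,
                 abs(p1$node_presence - p2$node_presence),
                 abs(p1$branch_gain - p2$branch_gain),
                 abs(p1$branch_loss - p2$branch_loss),
                 abs(p1$category_posterior - p2$category_posterior))
  }
  expect_lt(worst, 1e-10)
})

test_that("posterior invariants hold: event bounds, leaf match, marginal consistency", {
  set.seed(77)
  for (i in 1:20) {
    tr <- rand_tree(sample(3:8, 1))
    m <- rand_model(tr)
    pat <- rand_pattern(tr)
    p <- posteriors(pat, tr, m)
    expect_true(all(p$branch_gain + p$branch_loss <= 1 + 1e-12))
    # gain on b needs the parent absent and the child present
    for (v in seq_len(tr$n)) {
      pp <- if (v == 1) 0 else p$node_presence[tr$parent[v]]
      expect_lte(p$branch_gain[v], 1 - pp + 1e-10)
      expect_lte(p$branch_gain[v], p$node_presence[v] + 1e-10)
      expect_lte(p$branch_loss[v], pp + 1e-10)
    }
    leaves <- which(tr$is_leaf)
    expect_equal(unname(p$node_presence[leaves]),
                 unname(pat[tr$name[leaves]]), tolerance = 1e-9)
  }
})

test_that("a deterministic model yields deterministic event posteriors", {
  tr <- read_newick("((A,B),C);")
  # gains certain at the root, then faithful transmission
  m <- gainloss_model(tr, gain = c(1, 0, 0, 0, 0), loss = 0,
                      condition_on_observed = FALSE)
  p <- posteriors(c(A = 1, B = 1, C = 1), tr, m)
  expect_equal(unname(p$branch_gain), c(1, 0, 0, 0, 0), tolerance = 1e-4)
  expect_equal(unname(p$node_presence), rep(1, 5), tolerance = 1e-4)
  expect_equal(sum(p$branch_loss), 0, tolerance = 1e-4)
})

test_that("the all-absent pattern has near-zero presence and matches enumeration", {
  set.seed(31)
  tr <- rand_tree(4)
  m <- gainloss_model(tr, runif(tr$n, 0.01, 0.1), runif(tr$n, 0.2, 0.6),
                      condition_on_observed = FALSE)
  pat <- setNames(rep(0, 4), leaf_names(tr))
  p1 <- posteriors(pat, tr, m)
  p2 <- brute_force_posteriors(pat, tr, m)
  expect_true(all(p1$node_presence < 0.2))
  expect_equal(p1$branch_gain, p2$branch_gain, tolerance = 1e-10)
})

test_that("brute force refuses oversized trees", {
  tr <- balanced_tree(16)
  m <- gainloss_model(tr, 0.1, 0.1)
  expect_error(
    brute_force_posteriors(setNames(rep(1, 16), leaf_names(tr)), tr, m),
    "refuse")
})

test_that("conditioning on observability rescales the likelihood correctly", {
  set.seed(55)
  tr <- rand_tree(4)
  g <- runif(tr$n, 0.05, 0.4); l <- runif(tr$n, 0.1, 0.6)
  m_raw <- gainloss_model(tr, g, l, m2 = 2, w2 = 0.3,
                          condition_on_observed = FALSE)
  m_cond <- gainloss_model(tr, g, l, m2 = 2, w2 = 0.3,
                           condition_on_observed = TRUE)
  pat <- setNames(c(1, 0, 1, 0), leaf_names(tr))
  empty <- setNames(rep(0, 4), leaf_names(tr))
  l_empty <- exp(family_loglik(empty, tr, m_raw))
  expect_equal(family_loglik(pat, tr, m_cond),
               family_loglik(pat, tr, m_raw) - log(1 - l_empty),
               tolerance = 1e-10)
  # event posteriors are conditional on the observed pattern either way
  expect_equal(posteriors(pat, tr, m_cond)$branch_gain,
               posteriors(pat, tr, m_raw)$branch_gain, tolerance = 1e-12)
})

test_that("fitting an all-ones matrix drives parameters to their bounds", {
  tr <- balanced_tree(4)
  m <- matrix(1L, 60, 4, dimnames = list(sprintf("f%02d", 1:60),
                                         leaf_names(tr)))
  expect_warning(fit <- fit_model(m, tr, n_categories = 1), "ubiquitous")
  expect_gt(fit$gain[1], 0.99)          # root gain at the upper clip
  expect_lt(max(fit$loss[-1]), 0.01)    # losses at the lower clip
})

test_that("a single-category fit on category-free data reaches the generating loglik", {
  tr <- balanced_tree(8)
  gen <- gainloss_model(tr, gain = c(0.6, rep(0.02, tr$n - 1)),
                        loss = c(0, rep(0.25, tr$n - 1)),
                        condition_on_observed = TRUE)
  sim <- simulate_presence(tr, gen, 2000, seed = 17)
  fit <- fit_model(sim$matrix, tr, n_categories = 1)
  ll_gen <- sum(compute_posteriors(sim$matrix, tr, gen)$loglik)
  expect_gt(fit$loglik, ll_gen - 2)
  expect_true(fit$converged)
})

test_that("expected_events sums event posteriors per branch and family", {
  tr <- balanced_tree(4)
  gen <- gainloss_model(tr, gain = c(0.7, rep(0.05, tr$n - 1)),
                        loss = c(0, rep(0.2, tr$n - 1)))
  sim <- simulate_presence(tr, gen, 50, seed = 3)
  post <- compute_posteriors(sim$matrix, tr, gen)
  ev <- expected_events(post)
  expect_equal(sum(ev$per_branch$expected_gains),
               sum(ev$per_family$total_gains), tolerance = 1e-9)
  expect_true(all(ev$per_branch$expected_gains <= nrow(sim$matrix)))
  expect_equal(ev$per_branch$expected_gains, colSums(post$branch_gain))
})

test_that("ancestral_sizes sums posteriors and applies a strict threshold", {
  m <- matrix(0.25, 8, 3)
  s <- ancestral_sizes(m, threshold = 0.9)
  expect_equal(s$expected_families, rep(2, 3))

  m2 <- rbind(matrix(1, 3, 2), matrix(0.9, 2, 2))
  s2 <- ancestral_sizes(m2, threshold = 0.9)
  expect_equal(s2$expected_families[1], 3 + 1.8)
  expect_equal(s2$high_confidence[1], 3)  # 0.9 is excluded (strict >)
})

test_that("summary_table reproduces the published archaeal and bacterial cells", {
  a <- summary_table(17680, 74690, 10335)
  v <- setNames(a$value, a$statistic)
  expect_equal(v[["gains/family"]], 1.71)
  expect_equal(v[["acquisitions/family"]], 0.71)
  expect_equal(v[["losses/family"]], 7.23)
  expect_equal(v[["loss/gain ratio"]], 4.22)

  b <- summary_table(7769, 32355, 4149)
  vb <- setNames(b$value, b$statistic)
  expect_equal(vb[["gains/family"]], 1.87)
  expect_equal(vb[["acquisitions/family"]], 0.87)
  expect_equal(vb[["losses/family"]], 7.80)
  expect_equal(vb[["loss/gain ratio"]], 4.16)

  z <- summary_table(100, 0, 100)
  vz <- setNames(z$value, z$statistic)
  expect_equal(vz[["acquisitions/family"]], 0)
  expect_equal(vz[["loss/gain ratio"]], 0)
})

test_that("genome-size extrapolation applies the paralogy ratio at 2 significant figures", {
  expect_equal(extrapolate_genome_size(1725, 1.5), 2600)
  expect_equal(extrapolate_genome_size(1000, 1.5), 1500)
})
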