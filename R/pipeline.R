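# Stage-composition functions: each reads/writes the plain TSV formats the
# individual modules use, so stages can be rerun or swapped independently.

#' Benchmark conditions for gain/loss parameter recovery
#'
#' A fixed 16-leaf balanced tree with a heterogeneous two-category model:
#' the root (origin) branch carries a high gain probability (0.7),
#' secondary gains are rare (0.001-0.004, cycling so no two branches are
#' equal), loss is depth-structured -- light on internal branches (0.05)
#' and heavy on terminal branches (0.155-0.255) -- and the category mixture
#' (w2 = 0.3, m2 = 2) makes 30% of families evolve twice as fast.  The loss
#' levels put the expected loss/gain event-count ratio of observable
#' families at 4, the four-fold excess of losses over gains that
#' genome-scale reconstructions typically recover, while the low deep-branch
#' loss keeps ancestral presence at the root strongly identified (heavy
#' deep loss would let secondary-gain explanations mimic the data; see the
#' methods vignette).
#'
#' @return List with `tree` and generating `model`.
#' @export
recovery_benchmark <- function() {
  tree <- balanced_tree(16)
  n <- tree$n
  gain <- rep(c(0.001, 0.002, 0.004), length.out = n)
  loss <- rep(0.05, n)
  loss[tree$is_leaf] <- rep(c(0.155, 0.205, 0.255),
                            length.out = sum(tree$is_leaf))
  gain[1] <- 0.7
  loss[1] <- 0
  model <- gainloss_model(tree, gain, loss, m2 = 2, w2 = 0.3,
                          condition_on_observed = TRUE)
  list(tree = tree, model = model)
}

#' Run the simulation stage, writing the dataset bundle as TSV/Newick
#'
#' @param tree a [cogevo_tree()].
#' @param model a [gainloss_model()].
#' @param n_families families to simulate.
#' @param seed RNG seed.
#' @param out_dir output directory (created).
#' @return Invisibly, the [simulate_presence()] result.
#' @export
run_simulation <- function(tree, model, n_families, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_presence(tree, model, n_families, seed)
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
  write_tsv(sim$matrix, file.path(out_dir, "matrix.tsv"), seed, "presence matrix")
  write_tsv(sim$truth$states, file.path(out_dir, "truth_states.tsv"), seed,
            "true node states")
  ev <- data.frame(family = rep(rownames(sim$truth$gain_events),
                                times = ncol(sim$truth$gain_events) * 2),
                   branch = rep(rep(seq_len(ncol(sim$truth$gain_events)),
                                    each = nrow(sim$truth$gain_events)), 2),
                   event = rep(c("gain", "loss"),
                               each = length(sim$truth$gain_events)),
                   occurred = c(as.integer(sim$truth$gain_events),
                                as.integer(sim$truth$loss_events)))
  write_tsv(ev[ev$occurred == 1, c("family", "branch", "event")],
            file.path(out_dir, "truth_events.tsv"), seed, "true events")
  invisible(sim)
}

#' Run the clustering stage from TSV inputs
#'
#' @param hits_path,genemap_path hit-table and gene-map TSVs
#'   ([read_hit_table()]).
#' @param out_dir output directory.
#' @param merge also merge complementary-pattern clusters.
#' @param overlap_max,link_score_min see [merge_complementary()].
#' @return Invisibly, the final `ortholog_clusters`.
#' @export
run_clustering <- function(hits_path, genemap_path, out_dir,
                           merge = FALSE, overlap_max = 0.2,
                           link_score_min = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ht <- read_hit_table(hits_path, genemap_path)
  cs <- triangle_clusters(symmetric_best_hits(best_hits(ht)), ht$genome)
  if (merge) cs <- merge_complementary(cs, ht, overlap_max, link_score_min)
  rows <- do.call(rbind, lapply(names(cs$clusters), function(id)
    data.frame(cluster = id, gene = cs$clusters[[id]],
               genome = unname(cs$gene2genome[cs$clusters[[id]]]))))
  if (is.null(rows))
    rows <- data.frame(cluster = character(0), gene = character(0),
                       genome = character(0))
  write_tsv(rows, file.path(out_dir, "clusters.tsv"), what = "ortholog clusters")
  cov <- genome_coverage(cs)
  write_tsv(data.frame(genome = c(names(cov$per_genome), "overall"),
                       fraction_assigned = c(cov$per_genome, cov$overall)),
            file.path(out_dir, "coverage.tsv"), what = "genome coverage")
  invisible(cs)
}

#' Run the commonality stage
#'
#' @param matrix presence matrix or TSV path.
#' @param out_dir output directory.
#' @param n_components exponential components to fit.
#' @param seed multistart seed.
#' @return Invisibly, the [fit_exponential_mixture()] result.
#' @export
run_commonality <- function(matrix, out_dir, n_components = 3, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(matrix)) matrix <- read_matrix(matrix)
  h <- commonality_histogram(matrix)
  fit <- fit_exponential_mixture(h, n_components, seed = seed)
  write_tsv(data.frame(k = seq_len(h$G), count = h$counts),
            file.path(out_dir, "commonality.tsv"), seed, "commonality histogram")
  write_tsv(fit$components, file.path(out_dir, "mixture_fit.tsv"), seed,
            "exponential mixture fit")
  invisible(fit)
}

#' Run the gain/loss reconstruction stage
#'
#' Fits the model, computes posteriors for every family, and writes the
#' model, node/event posterior tables and the headline summary.
#'
#' @param matrix presence matrix or TSV path.
#' @param tree a [cogevo_tree()] or Newick file path.
#' @param out_dir output directory.
#' @param n_categories,condition_on_observed passed to [fit_model()].
#' @return Invisibly, list(model, posteriors, sizes, events, summary).
#' @export
run_reconstruction <- function(matrix, tree, out_dir, n_categories = 2,
                               condition_on_observed = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(matrix)) matrix <- read_matrix(matrix)
  if (is.character(tree)) tree <- read_newick(tree, file = TRUE)
  vp <- validate_pair(tree, matrix, strict = TRUE)
  model <- fit_model(matrix, tree, n_categories, condition_on_observed)
  post <- compute_posteriors(matrix, tree, model)
  sizes <- ancestral_sizes(post)
  events <- expected_events(post)
  summ <- summary_table(events$per_family$total_gains,
                        events$per_family$total_losses, nrow(matrix))
  write_tsv(data.frame(branch = seq_len(tree$n), gain = model$gain,
                       loss = model$loss),
            file.path(out_dir, "model.tsv"), what = "fitted gain/loss model")
  np <- data.frame(family = rep(post$family_ids, times = tree$n),
                   node = rep(seq_len(tree$n), each = length(post$family_ids)),
                   presence = as.numeric(post$node_presence))
  write_tsv(np, file.path(out_dir, "node_posteriors.tsv"),
            what = "node presence posteriors")
  ep <- data.frame(family = rep(post$family_ids, times = tree$n),
                   branch = rep(seq_len(tree$n), each = length(post$family_ids)),
                   gain = as.numeric(post$branch_gain),
                   loss = as.numeric(post$branch_loss))
  write_tsv(ep, file.path(out_dir, "event_posteriors.tsv"),
            what = "event posteriors")
  write_tsv(sizes, file.path(out_dir, "ancestral_sizes.tsv"),
            what = "ancestral sizes")
  write_tsv(summ, file.path(out_dir, "summary.tsv"), what = "summary statistics")
  invisible(list(model = model, posteriors = post, sizes = sizes,
                 events = events, summary = summ))
}

#' Run the gain-pattern statistics stage
#'
#' @param post a [compute_posteriors()] result (e.g. from
#'   [run_reconstruction()]).
#' @param out_dir output directory.
#' @param gain_threshold likely-gain posterior threshold.
#' @return Invisibly, list(patterns, distribution, multigain, pairs).
#' @export
run_patterns <- function(post, out_dir, gain_threshold = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pats <- gain_patterns(post, gain_threshold)
  dist <- gain_count_distribution(pats)
  mg <- multigain_branch_stats(post)
  pt <- two_gain_pairs(pats)
  pt <- tryCatch(
    expected_pair_counts(pt, colSums(post$branch_gain)),
    error = function(e) pt)
  pat_df <- data.frame(
    family = vapply(pats, function(p) p$family, ""),
    class = vapply(pats, function(p) p$class, ""),
    branches = vapply(pats, function(p)
      paste(p$likely_gain_branches, collapse = ","), ""),
    total_posterior_gain = vapply(pats, `[[`, 0, "total_posterior_gain"))
  write_tsv(pat_df, file.path(out_dir, "gain_patterns.tsv"),
            what = "likely-gain patterns")
  write_tsv(dist$histogram, file.path(out_dir, "gain_histogram.tsv"),
            what = "gains-per-family histogram")
  if (nrow(pt$observed))
    write_tsv(pt$observed, file.path(out_dir, "pair_table.tsv"),
              what = "two-gain pair table")
  invisible(list(patterns = pats, distribution = dist, multigain = mg,
                 pairs = pt))
}
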