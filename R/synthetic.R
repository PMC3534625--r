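# Synthetic-data generators with recorded ground truth: presence matrices
# evolved under a gain/loss model, commonality histograms from exponential
# mixtures, and similarity hit tables with planted ortholog groups.

#' Balanced bifurcating tree
#'
#' @param n_leaves power of two.
#' @param brlen branch length written on every branch.
#' @return A [cogevo_tree()] with leaves `t01..tN`.
#' @export
balanced_tree <- function(n_leaves, brlen = 1) {
  stopifnot(n_leaves >= 2, bitwAnd(n_leaves, n_leaves - 1L) == 0)
  build <- function(lo, hi) {
    if (lo == hi) return(sprintf("t%02d:%g", lo, brlen))
    mid <- (lo + hi - 1L) %/% 2L
    sprintf("(%s,%s):%g", build(lo, mid), build(mid + 1L, hi), brlen)
  }
  read_newick(paste0(build(1L, n_leaves), ";"))
}

#' Evolve presence/absence patterns along a tree
#'
#' Each family draws a rate category from the model's mixture, then evolves
#' from the absent origin state down every branch (the origin-to-root
#' branch first) with the category's transition probabilities.  With
#' `condition_nonempty`, families absent from every leaf are redrawn by
#' rejection and the rejection count reported.
#'
#' @param tree a [cogevo_tree()].
#' @param model a [gainloss_model()].
#' @param n_families number of families to emit.
#' @param seed RNG seed (integer).
#' @param condition_nonempty redraw all-absent families.
#' @return List: `matrix` (presence matrix, families `fam00001..`), `truth`
#'   (class `simulation_truth`: `states` families x nodes, `gain_events`,
#'   `loss_events` logical matrices, `category`, `rejections`, `seed`,
#'   `model`).
#' @export
simulate_presence <- function(tree, model, n_families, seed,
                              condition_nonempty = TRUE) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- tree$n
  cats <- .category_probs(model)
  gmat <- t(vapply(cats, `[[`, numeric(n), "g"))  # [ncat x n]
  lmat <- t(vapply(cats, `[[`, numeric(n), "l"))
  w <- vapply(cats, `[[`, 0, "w")
  leafcols <- which(tree$is_leaf)

  draw <- function(nf) {
    cat <- sample.int(length(w), nf, replace = TRUE, prob = w)
    st <- matrix(0L, nf, n)
    gain <- matrix(FALSE, nf, n)
    loss <- matrix(FALSE, nf, n)
    for (v in seq_len(n)) {
      ps <- if (v == 1L) rep.int(0L, nf) else st[, tree$parent[v]]
      u <- runif(nf)
      gv <- gmat[cat, v]
      lv <- lmat[cat, v]
      sv <- ifelse(ps == 0L, as.integer(u < gv), as.integer(u >= lv))
      st[, v] <- sv
      gain[, v] <- ps == 0L & sv == 1L
      loss[, v] <- ps == 1L & sv == 0L
    }
    list(cat = cat, st = st, gain = gain, loss = loss)
  }

  d <- draw(n_families)
  rejections <- 0L
  if (condition_nonempty) {
    repeat {
      empty <- rowSums(d$st[, leafcols, drop = FALSE]) == 0
      if (!any(empty)) break
      rejections <- rejections + sum(empty)
      if (rejections > 1000 * n_families)
        stop("rejection rate above 99.9%: the model almost never produces ",
             "observable families")
      r <- draw(sum(empty))
      d$cat[empty] <- r$cat
      d$st[empty, ] <- r$st
      d$gain[empty, ] <- r$gain
      d$loss[empty, ] <- r$loss
    }
  }
  fam <- sprintf("fam%05d", seq_len(n_families))
  m <- d$st[, leafcols, drop = FALSE]
  dimnames(m) <- list(fam, tree$name[leafcols])
  rownames(d$st) <- rownames(d$gain) <- rownames(d$loss) <- fam
  truth <- structure(list(states = d$st, gain_events = d$gain,
                          loss_events = d$loss, category = d$cat,
                          rejections = rejections, seed = seed, model = model),
                     class = "simulation_truth")
  list(matrix = m, truth = truth)
}

#' Draw a commonality histogram from an exponential mixture
#'
#' `counts[k] ~ Poisson(sum_i a_i * exp(b_i * k))`, independently per k.
#'
#' @param components data frame or list with vectors `a` (positive) and
#'   `b`; an empty component set yields an all-zero histogram.
#' @param G number of genomes.
#' @param seed RNG seed.
#' @return A [commonality_histogram()]-classed object.
#' @export
simulate_commonality <- function(components, G, seed) {
  a <- components$a
  b <- components$b
  if (length(a) && any(a <= 0)) stop("amplitudes must be positive")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mu <- .mixture_mu(a, b, seq_len(G))
  structure(list(G = G, counts = rpois(G, mu)),
            class = "commonality_histogram")
}

#' Simulate an all-vs-all hit table with planted ortholog groups
#'
#' Each planted group places one gene in each of `group_size` genomes; all
#' its cross-genome pairs receive scores from the high distribution,
#' `pmax(min_high, Normal(mu_high, sd_high))`.  Background hits appear
#' between random cross-genome non-group pairs at `background_rate` per
#' ordered pair, with scores `pmin(bg_cap, Exponential(mean bg_mean))` --
#' so `min_high > bg_cap` gives strictly disjoint score supports.  Both
#' directions of every hit are emitted.
#'
#' @param n_genomes number of genomes (`G01..`).
#' @param n_groups number of planted ortholog groups.
#' @param group_size genomes per group (>= 3 for triangle recovery),
#'   recycled.
#' @param n_background_genes extra unclustered genes per genome.
#' @param background_rate probability a background ordered pair is hit.
#' @param min_high,mu_high,sd_high high (within-group) score parameters.
#' @param bg_cap,bg_mean background score cap and mean.
#' @param seed RNG seed.
#' @return List: `hits` (a [hit_table()]), `true_clusters` (named list of
#'   gene-id vectors).
#' @export
simulate_hit_table <- function(n_genomes, n_groups, group_size = 3,
                               n_background_genes = 2,
                               background_rate = 0.01,
                               min_high = 120, mu_high = 150, sd_high = 10,
                               bg_cap = 60, bg_mean = 25, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genomes <- sprintf("G%02d", seq_len(n_genomes))
  group_size <- rep_len(group_size, n_groups)
  stopifnot(all(group_size <= n_genomes))
  gene2genome <- character(0)
  true_clusters <- vector("list", n_groups)
  q <- character(0); s <- character(0); sc <- numeric(0)
  for (gi in seq_len(n_groups)) {
    gset <- sort(sample(genomes, group_size[gi]))
    ids <- sprintf("%s_grp%03d", gset, gi)
    gene2genome[ids] <- gset
    true_clusters[[gi]] <- ids
    pr <- t(combn(ids, 2))
    hs <- pmax(min_high, rnorm(nrow(pr), mu_high, sd_high))
    q <- c(q, pr[, 1], pr[, 2]); s <- c(s, pr[, 2], pr[, 1]); sc <- c(sc, hs, hs)
  }
  names(true_clusters) <- sprintf("group_%03d", seq_len(n_groups))
  if (n_background_genes > 0) {
    bg_ids <- as.vector(outer(genomes, seq_len(n_background_genes),
                              function(g, i) sprintf("%s_bg%02d", g, i)))
    gene2genome[bg_ids] <- substr(bg_ids, 1, 3)
  }
  all_genes <- names(gene2genome)
  if (background_rate > 0 && length(all_genes) > 1) {
    pr <- t(combn(sort(all_genes), 2))
    cross <- gene2genome[pr[, 1]] != gene2genome[pr[, 2]]
    ingroup <- rep(FALSE, nrow(pr))
    for (cl in true_clusters)
      ingroup <- ingroup | (pr[, 1] %in% cl & pr[, 2] %in% cl)
    cand <- which(cross & !ingroup)
    hit <- cand[runif(length(cand)) < background_rate]
    if (length(hit)) {
      bs <- pmin(bg_cap, rexp(length(hit), 1 / bg_mean))
      q <- c(q, pr[hit, 1], pr[hit, 2])
      s <- c(s, pr[hit, 2], pr[hit, 1])
      sc <- c(sc, bs, bs)
    }
  }
  ht <- hit_table(data.frame(query = q, subject = s, score = sc), gene2genome)
  list(hits = ht, true_clusters = true_clusters)
}
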