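# Shared helpers: random tree/model/pattern generators for property tests.

rand_tree <- function(n_leaves, with_lengths = TRUE) {
  labs <- paste0("L", seq_len(n_leaves))
  build <- function(ls) {
    bl <- if (with_lengths) sprintf(":%.3f", runif(1, 0.1, 2)) else ""
    if (length(ls) == 1) return(paste0(ls, bl))
    k <- sample(seq_len(length(ls) - 1), 1)
    paste0("(", build(ls[1:k]), ",", build(ls[-(1:k)]), ")", bl)
  }
  read_newick(paste0(build(labs), ";"))
}

rand_model <- function(tree, two_cat = TRUE, condition = NA) {
  if (is.na(condition)) condition <- sample(c(TRUE, FALSE), 1)
  gainloss_model(tree,
                 gain = runif(tree$n, 0.05, 0.9),
                 loss = runif(tree$n, 0.05, 0.9),
                 m2 = if (two_cat) runif(1, 0.5, 5) else 1,
                 w2 = if (two_cat) runif(1, 0, 0.8) else 0,
                 condition_on_observed = condition)
}

rand_pattern <- function(tree) {
  setNames(sample(0:1, sum(tree$is_leaf), replace = TRUE), leaf_names(tree))
}

# small presence matrix from explicit rows
pm <- function(rows, genomes, families = sprintf("f%02d", seq_along(rows))) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(families, genomes)
  storage.mode(m) <- "integer"
  m
}
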