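#' @importFrom stats optim setNames rpois runif rnorm rexp plogis qlogis
#'   ppois density cor pt complete.cases quantile lm coef sd
#' @importFrom utils read.delim write.table head combn
NULL

#' Rooted phylogeny with an origin branch
#'
#' A `cogevo_tree` stores a rooted (possibly multifurcating) phylogeny as
#' parallel vectors in preorder: node 1 is the root and every node's parent
#' precedes it.  Every node, including the root, owns exactly one branch --
#' the branch connecting it to its parent; the root's branch descends from an
#' implicit "origin" outside the tree.  Branch count therefore equals node
#' count (2n - 1 for a strictly bifurcating tree with n leaves).
#'
#' @param parent integer vector, `parent[i]` is the parent node of node `i`
#'   (0 for the root).
#' @param name character vector of node names; leaf names must be non-empty
#'   and unique, internal names may be `""`.
#' @param brlen numeric vector of branch lengths (`NA` when absent); entry 1
#'   is the origin-to-root branch.
#' @return An object of class `cogevo_tree` with elements `n`, `parent`,
#'   `children`, `name`, `brlen`, `is_leaf`, `leaf_index` (position of each
#'   leaf in `leaf_names()` order, `NA` for internal nodes).
#' @export
cogevo_tree <- function(parent, name, brlen = rep(NA_real_, length(parent))) {
  parent <- as.integer(parent)
  n <- length(parent)
  stopifnot(length(name) == n, length(brlen) == n)
  if (sum(parent == 0L) != 1L || parent[1] != 0L)
    stop("exactly one root expected, at node 1")
  if (any(parent[-1] >= seq_len(n)[-1] | parent[-1] < 1L))
    stop("nodes must be in preorder: parent index < node index")
  children <- vector("list", n)
  for (v in seq_len(n)[-1]) children[[parent[v]]] <- c(children[[parent[v]]], v)
  is_leaf <- lengths(children) == 0L
  lf <- name[is_leaf]
  if (any(!nzchar(lf)) || anyNA(lf)) stop("leaf names must be non-empty")
  if (anyDuplicated(lf)) {
    stop("duplicate leaf names: ", paste(unique(lf[duplicated(lf)]), collapse = ", "))
  }
  leaf_index <- rep(NA_integer_, n)
  leaf_index[is_leaf] <- seq_len(sum(is_leaf))
  structure(
    list(n = n, parent = parent, children = children, name = as.character(name),
         brlen = as.numeric(brlen), is_leaf = is_leaf, leaf_index = leaf_index),
    class = "cogevo_tree"
  )
}

#' @export
print.cogevo_tree <- function(x, ...) {
  cat(sprintf("cogevo_tree: %d nodes (%d leaves), %d branches incl. origin branch\n",
              x$n, sum(x$is_leaf), x$n))
  invisible(x)
}

#' Leaf names of a tree
#'
#' @param tree a [cogevo_tree()].
#' @return Character vector of leaf names in leaf-index order.
#' @export
leaf_names <- function(tree) tree$name[tree$is_leaf]

#' Number of branches (including the origin-to-root branch)
#'
#' @param tree a [cogevo_tree()].
#' @return Integer; equals the node count.
#' @export
n_branches <- function(tree) tree$n

# Check parenthesis balance, reporting 1-based character offset of the fault.
.check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  opens <- integer(0)
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") { depth <- depth + 1L; opens <- c(opens, i) }
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("Newick parse error: unmatched ')' at character ", i)
      opens <- opens[-length(opens)]
    }
  }
  if (depth > 0L)
    stop("Newick parse error: unmatched '(' at character ", opens[1])
  invisible(TRUE)
}

# Convert an ape "phylo" object (+ optional root edge) to cogevo_tree,
# assigning preorder integer ids deterministically.
.from_ape <- function(phy) {
  ntip <- length(phy$tip.label)
  ntot <- ntip + phy$Nnode
  kids <- vector("list", ntot)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], phy$edge[i, 2])
  }
  elen <- rep(NA_real_, ntot)
  if (!is.null(phy$edge.length)) elen[phy$edge[, 2]] <- phy$edge.length
  aname <- character(ntot)
  aname[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) aname[ntip + seq_len(phy$Nnode)] <- phy$node.label
  root_ape <- ntip + 1L
  # iterative preorder DFS, children in edge-matrix order
  ord <- integer(ntot)
  stack <- root_ape
  k <- 0L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- v
    if (!is.null(kids[[v]])) stack <- c(stack, rev(kids[[v]]))
  }
  newid <- integer(ntot)
  newid[ord] <- seq_len(ntot)
  parent <- integer(ntot)
  parent[1] <- 0L
  for (v in seq_len(ntot)) {
    for (c in kids[[v]]) parent[newid[c]] <- newid[v]
  }
  brlen <- elen[ord]
  if (!is.null(phy$root.edge)) brlen[1] <- phy$root.edge
  cogevo_tree(parent, aname[ord], brlen)
}

#' Read a rooted phylogeny from Newick text
#'
#' Accepts the standard Newick dialect (branch lengths, internal labels,
#' quoted names, multifurcations).  Internal nodes without labels keep their
#' deterministic preorder integer ids, so posterior tables are comparable
#' across runs.  A trailing root branch length (`...)R:0.1;`) is stored as
#' the origin-to-root branch length.
#'
#' @param text Newick string, or a file path when `file = TRUE`.
#' @param file read `text` as a path instead of literal Newick.
#' @return A [cogevo_tree()].
#' @export
read_newick <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  text <- trimws(text)
  .check_parens(text)
  body <- sub(";\\s*$", "", text)
  if (!grepl("[(,]", body)) {
    # single-leaf tree: root is the leaf
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    nm <- gsub("^'|'$", "", trimws(parts[1]))
    if (!nzchar(nm)) stop("Newick parse error: empty single-leaf tree")
    bl <- if (length(parts) > 1) as.numeric(parts[2]) else NA_real_
    return(cogevo_tree(0L, nm, bl))
  }
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: unparseable input")
  .from_ape(phy)
}

.quote_label <- function(x) {
  ifelse(grepl("[ ()\\[\\]:;,']", x), paste0("'", gsub("'", "''", x), "'"), x)
}

#' Write a phylogeny as Newick text
#'
#' Branch lengths are written to 10 significant digits; the origin-to-root
#' branch (if it has a length) is written as a trailing root edge, so
#' `read_newick(write_newick(tree))` round-trips topology, names and lengths.
#'
#' @param tree a [cogevo_tree()].
#' @return Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  fmt <- function(v) {
    lab <- .quote_label(tree$name[v])
    s <- if (tree$is_leaf[v]) lab
    else paste0("(", paste(vapply(tree$children[[v]], fmt, ""), collapse = ","), ")", lab)
    if (!is.na(tree$brlen[v]))
      s <- paste0(s, ":", format(tree$brlen[v], digits = 10))
    s
  }
  paste0(fmt(1L), ";")
}

#' Prune a tree to a subset of leaves
#'
#' Drops all leaves outside `keep`; internal nodes left with a single child
#' are suppressed and their branch lengths summed onto the surviving branch
#' (a unary root is suppressed the same way, its length folded into the new
#' origin-to-root branch), keeping the tree in the form the gain/loss model
#' expects.
#'
#' @param tree a [cogevo_tree()].
#' @param keep character vector of leaf names to retain.
#' @return A pruned [cogevo_tree()].
#' @export
prune_tree <- function(tree, keep) {
  stopifnot(all(keep %in% leaf_names(tree)), length(keep) >= 1)
  # returns list(name, brlen, children=list of such) or NULL if subtree empty
  build <- function(v) {
    if (tree$is_leaf[v]) {
      if (tree$name[v] %in% keep)
        return(list(name = tree$name[v], brlen = tree$brlen[v], children = list()))
      return(NULL)
    }
    ch <- Filter(Negate(is.null), lapply(tree$children[[v]], build))
    if (length(ch) == 0L) return(NULL)
    if (length(ch) == 1L) {  # unary: suppress, sum lengths
      one <- ch[[1]]
      bl <- if (is.na(tree$brlen[v]) && is.na(one$brlen)) NA_real_
      else sum(c(tree$brlen[v], one$brlen), na.rm = TRUE)
      one$brlen <- bl
      return(one)
    }
    list(name = tree$name[v], brlen = tree$brlen[v], children = ch)
  }
  r <- build(1L)
  if (is.null(r)) stop("pruning removed every leaf")
  parent <- integer(0); name <- character(0); brlen <- numeric(0)
  emit <- function(node, pid) {
    parent <<- c(parent, pid)
    name <<- c(name, node$name)
    brlen <<- c(brlen, node$brlen)
    my <- length(parent)
    for (c in node$children) emit(c, my)
  }
  emit(r, 0L)
  cogevo_tree(parent, name, brlen)
}

# leaves below each node, as leaf_index values; list of integer vectors
.clade_leaves <- function(tree) {
  out <- vector("list", tree$n)
  for (v in tree$n:1) {
    out[[v]] <- if (tree$is_leaf[v]) tree$leaf_index[v]
    else unlist(out[tree$children[[v]]], use.names = FALSE)
  }
  out
}
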