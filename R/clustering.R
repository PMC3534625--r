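# COG-style ortholog clustering from an all-vs-all similarity table:
# genome-specific best hits -> symmetric (bidirectional) best-hit pairs ->
# triangles spanning three genomes -> merge of triangles sharing an edge ->
# optional merging of clusters with complementary phyletic patterns.

#' Build a hit table
#'
#' @param hits data frame with columns `query`, `subject`, `score`
#'   (non-negative).  Self hits (`query == subject`) are dropped with a
#'   message.
#' @param gene2genome named character vector mapping gene id to genome id;
#'   every gene appearing in `hits` must be present.
#' @return Object of class `hit_table`.
#' @export
hit_table <- function(hits, gene2genome) {
  stopifnot(all(c("query", "subject", "score") %in% names(hits)))
  hits <- data.frame(query = as.character(hits$query),
                     subject = as.character(hits$subject),
                     score = as.numeric(hits$score))
  if (any(hits$score < 0)) stop("negative scores are not allowed")
  self <- hits$query == hits$subject
  if (any(self)) {
    message("dropped ", sum(self), " self hits")
    hits <- hits[!self, , drop = FALSE]
  }
  genes <- unique(c(hits$query, hits$subject))
  missing <- setdiff(genes, names(gene2genome))
  if (length(missing))
    stop("genes missing from gene->genome map: ",
         paste(head(missing, 5), collapse = ", "))
  structure(list(hits = hits, genome = gene2genome), class = "hit_table")
}

#' Read a hit table and gene map from TSV files
#'
#' The hit file is either 3 columns (query, subject, score) or 12-column
#' BLAST tabular output, in which case the bit score (column 12) is used.
#'
#' @param hits_path hit TSV path.
#' @param genemap_path two-column TSV (gene id, genome id), no header
#'   required.
#' @return A [hit_table()].
#' @export
read_hit_table <- function(hits_path, genemap_path) {
  h <- read.delim(hits_path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  h <- if (ncol(h) >= 12) data.frame(query = h[[1]], subject = h[[2]], score = h[[12]])
  else if (ncol(h) >= 3) data.frame(query = h[[1]], subject = h[[2]], score = h[[3]])
  else stop("hit table needs 3 or 12 columns")
  gm <- read.delim(genemap_path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  hit_table(h, setNames(as.character(gm[[2]]), as.character(gm[[1]])))
}

#' Genome-specific best hits
#'
#' For each query gene and each foreign genome it hits, the single
#' highest-scoring subject; score ties are broken by the lexicographically
#' smallest subject id so results are deterministic.  Within-genome hits are
#' ignored.
#'
#' @param ht a [hit_table()].
#' @return Data frame with columns `query`, `target_genome`, `subject`,
#'   `score`.
#' @export
best_hits <- function(ht) {
  stopifnot(inherits(ht, "hit_table"))
  h <- ht$hits
  h$qg <- unname(ht$genome[h$query])
  h$sg <- unname(ht$genome[h$subject])
  h <- h[h$qg != h$sg, , drop = FALSE]
  if (nrow(h) == 0)
    return(data.frame(query = character(0), target_genome = character(0),
                      subject = character(0), score = numeric(0)))
  o <- order(h$query, h$sg, -h$score, h$subject)
  h <- h[o, , drop = FALSE]
  keep <- !duplicated(paste(h$query, h$sg, sep = "\r"))
  data.frame(query = h$query[keep], target_genome = h$sg[keep],
             subject = h$subject[keep], score = h$score[keep])
}

#' Symmetric (bidirectional) best-hit pairs
#'
#' A pair \{x, y\} is kept when x is y's best hit in x's genome and y is
#' x's best hit in y's genome.
#'
#' @param best output of [best_hits()].
#' @return Data frame of unordered pairs: `gene1`, `gene2` (gene1 < gene2),
#'   `score` (mean of the two directed best-hit scores).
#' @export
symmetric_best_hits <- function(best) {
  if (nrow(best) == 0)
    return(data.frame(gene1 = character(0), gene2 = character(0),
                      score = numeric(0)))
  fwd <- paste(best$query, best$subject, sep = "\r")
  rev <- paste(best$subject, best$query, sep = "\r")
  mutual <- fwd %in% rev
  b <- best[mutual, , drop = FALSE]
  g1 <- pmin(b$query, b$subject)
  g2 <- pmax(b$query, b$subject)
  key <- paste(g1, g2, sep = "\r")
  agg <- tapply(b$score, key, mean)
  first <- !duplicated(key)
  ord <- order(key[first])
  data.frame(gene1 = g1[first][ord], gene2 = g2[first][ord],
             score = as.numeric(agg[key[first]][ord]))
}

#' Triangle-seeded ortholog clusters
#'
#' Enumerates all 3-cliques of the symmetric-best-hit graph whose members
#' lie in three distinct genomes, then transitively merges triangles that
#' share an edge; each connected component of this triangle-overlap graph is
#' one cluster.  A gene belonging to triangles of more than one component
#' (possible through promiscuous vertex sharing) is assigned to the
#' component in which it participates in most triangles, ties to the lowest
#' cluster id, keeping clusters disjoint.  Genes in no triangle are
#' unassigned.
#'
#' @param bbh output of [symmetric_best_hits()].
#' @param gene2genome named gene -> genome map.
#' @return Object of class `ortholog_clusters`: list of `clusters` (named
#'   list of gene-id vectors), `unassigned`, and the `gene2genome` map.
#' @export
triangle_clusters <- function(bbh, gene2genome) {
  empty <- structure(list(clusters = list(), unassigned = character(0),
                          gene2genome = gene2genome),
                     class = "ortholog_clusters")
  if (nrow(bbh) == 0) return(empty)
  verts <- sort(unique(c(bbh$gene1, bbh$gene2)))
  g <- igraph::graph_from_data_frame(bbh[, c("gene1", "gene2")],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  tri <- igraph::triangles(g)
  if (length(tri) == 0) return(within_unassigned(empty, verts))
  tri <- matrix(igraph::V(g)$name[tri], ncol = 3, byrow = TRUE)
  tri <- t(apply(tri, 1, sort))
  ok <- apply(tri, 1, function(r) length(unique(gene2genome[r])) == 3)
  tri <- tri[ok, , drop = FALSE]
  if (nrow(tri) == 0) return(within_unassigned(empty, verts))
  # union-find over triangles keyed by shared edges
  parent <- seq_len(nrow(tri))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  edge_of <- function(a, b) paste(a, b, sep = "\r")
  ekeys <- rbind(edge_of(tri[, 1], tri[, 2]),
                 edge_of(tri[, 1], tri[, 3]),
                 edge_of(tri[, 2], tri[, 3]))
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(tri))) {
    for (k in ekeys[, i]) {
      j <- seen[[k]]
      if (is.null(j)) assign(k, i, envir = seen)
      else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
    }
  }
  comp <- vapply(seq_len(nrow(tri)), find, 0L)
  comp_ids <- sort(unique(comp))
  # deterministic cluster numbering: by smallest gene id in the component
  comp_genes <- lapply(comp_ids, function(c) sort(unique(as.vector(tri[comp == c, ]))))
  ord <- order(vapply(comp_genes, `[`, "", 1))
  comp_ids <- comp_ids[ord]; comp_genes <- comp_genes[ord]
  # disambiguate genes present in several components: most triangles wins
  gene_comp <- list()
  for (ci in seq_along(comp_ids)) {
    tsub <- tri[comp == comp_ids[ci], , drop = FALSE]
    cnt <- table(as.vector(tsub))
    for (gn in names(cnt)) {
      prev <- gene_comp[[gn]]
      if (is.null(prev) || cnt[[gn]] > prev[2]) gene_comp[[gn]] <- c(ci, cnt[[gn]])
    }
  }
  assign_to <- vapply(gene_comp, `[`, 0, 1)
  clusters <- lapply(seq_along(comp_ids), function(ci)
    sort(names(assign_to)[assign_to == ci]))
  clusters <- clusters[lengths(clusters) > 0]
  names(clusters) <- sprintf("cluster_%04d", seq_along(clusters))
  all_genes <- names(gene2genome)
  structure(list(clusters = clusters,
                 unassigned = setdiff(all_genes, unlist(clusters)),
                 gene2genome = gene2genome),
            class = "ortholog_clusters")
}

within_unassigned <- function(cs, verts) {
  cs$unassigned <- names(cs$gene2genome)
  cs
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat(sprintf("ortholog_clusters: %d clusters, %d genes assigned, %d unassigned\n",
              length(x$clusters), length(unlist(x$clusters)),
              length(x$unassigned)))
  invisible(x)
}

#' Phyletic pattern (genome set) of each cluster
#'
#' @param cs an [triangle_clusters()] result.
#' @return Named list of sorted genome-id vectors.
#' @export
cluster_patterns <- function(cs) {
  lapply(cs$clusters, function(g) sort(unique(unname(cs$gene2genome[g]))))
}

#' Merge clusters with complementary phyletic patterns
#'
#' Two clusters merge when the genomes they share, as a fraction of the
#' smaller cluster's genome set, do not exceed `overlap_max`, and the mean
#' of the per-gene best cross-cluster hit scores is at least
#' `link_score_min`.  Applied iteratively, strongest link first, until no
#' pair qualifies.
#'
#' @param cs an `ortholog_clusters` object.
#' @param ht the [hit_table()] supplying cross-cluster similarities.
#' @param overlap_max maximal allowed shared-genome fraction (default 0.2).
#' @param link_score_min minimal mean cross-cluster best-hit score; default
#'   is the 90th percentile of scores of hits that are not symmetric best
#'   hits (background similarity level).
#' @return A merged `ortholog_clusters` object.
#' @export
merge_complementary <- function(cs, ht, overlap_max = 0.2,
                                link_score_min = NULL) {
  if (is.null(link_score_min)) {
    bbh <- symmetric_best_hits(best_hits(ht))
    inbbh <- paste(pmin(ht$hits$query, ht$hits$subject),
                   pmax(ht$hits$query, ht$hits$subject), sep = "\r") %in%
      paste(bbh$gene1, bbh$gene2, sep = "\r")
    bg <- ht$hits$score[!inbbh]
    link_score_min <- if (length(bg)) as.numeric(quantile(bg, 0.9)) else 0
  }
  link_score <- function(a, b) {
    h <- ht$hits
    ab <- h[(h$query %in% a & h$subject %in% b) |
              (h$query %in% b & h$subject %in% a), , drop = FALSE]
    if (nrow(ab) == 0) return(-Inf)
    best_per_query <- tapply(ab$score, ab$query, max)
    mean(best_per_query)
  }
  repeat {
    pats <- cluster_patterns(cs)
    ids <- names(cs$clusters)
    if (length(ids) < 2) break
    best <- NULL
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        pi <- pats[[i]]; pj <- pats[[j]]
        ov <- length(intersect(pi, pj)) / min(length(pi), length(pj))
        if (ov > overlap_max) next
        sc <- link_score(cs$clusters[[i]], cs$clusters[[j]])
        if (sc < link_score_min) next
        if (is.null(best) || sc > best$sc) best <- list(i = i, j = j, sc = sc)
      }
    }
    if (is.null(best)) break
    cs$clusters[[best$i]] <- sort(c(cs$clusters[[best$i]], cs$clusters[[best$j]]))
    cs$clusters[[best$j]] <- NULL
  }
  names(cs$clusters) <- sprintf("cluster_%04d", seq_along(cs$clusters))
  cs
}

#' Fraction of genes assigned to clusters, per genome and overall
#'
#' @param cs an `ortholog_clusters` object.
#' @return List with `per_genome` (named numeric vector) and `overall`.
#' @export
genome_coverage <- function(cs) {
  all_genes <- names(cs$gene2genome)
  assigned <- unlist(cs$clusters, use.names = FALSE)
  per <- tapply(all_genes %in% assigned, unname(cs$gene2genome[all_genes]), mean)
  list(per_genome = setNames(as.numeric(per), names(per)),
       overall = if (length(all_genes)) mean(all_genes %in% assigned) else 0)
}

#' Cluster-derived presence matrix
#'
#' One row per cluster, one column per genome, 1 when the cluster contains
#' at least one gene from the genome.
#'
#' @param cs an `ortholog_clusters` object.
#' @return Binary integer matrix.
#' @export
clusters_to_matrix <- function(cs) {
  genomes <- sort(unique(unname(cs$gene2genome)))
  m <- matrix(0L, length(cs$clusters), length(genomes),
              dimnames = list(names(cs$clusters), genomes))
  for (i in seq_along(cs$clusters))
    m[i, unique(unname(cs$gene2genome[cs$clusters[[i]]]))] <- 1L
  m
}
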