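# Presence/absence matrix IO and tree/matrix consistency checks.
#
# A presence matrix is a plain integer matrix with values in {0,1}, rownames
# = family ids, colnames = genome ids.  Paralogs are collapsed: a family is
# scored 1 in a genome when it has at least one member there.

#' Read a binary presence/absence matrix from TSV
#'
#' Expects a header row of genome ids and a first column of family ids.
#' Comment lines starting with `#` are skipped.  Cell values greater than 1
#' (paralog counts) are binarized with a warning, since downstream analyses
#' work on binary phyletic patterns.
#'
#' @param path TSV file path, or literal text via `text =` semantics of
#'   [utils::read.delim()] when `is_text = TRUE`.
#' @param is_text treat `path` as the file contents.
#' @param drop_empty drop all-zero family rows (reported via message).
#' @return Integer matrix (families x genomes) with values in \{0,1\}.
#' @export
read_matrix <- function(path, is_text = FALSE, drop_empty = FALSE) {
  df <- if (is_text)
    read.delim(text = path, check.names = FALSE, comment.char = "#",
               stringsAsFactors = FALSE)
  else
    read.delim(path, check.names = FALSE, comment.char = "#",
               stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix needs a family-id column plus >=1 genome column")
  fam <- as.character(df[[1]])
  if (anyDuplicated(fam))
    stop("duplicate family id: ", fam[duplicated(fam)][1])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row %d, column '%s'", bad, names(vals)[j]))
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  if (any(m < 0)) stop("negative cell values are not allowed")
  if (any(m > 1)) {
    warning(sum(m > 1), " cells with counts >1 binarized (paralogs collapsed)")
    m[m > 1] <- 1
  }
  storage.mode(m) <- "integer"
  rownames(m) <- fam
  if (drop_empty) {
    empty <- rowSums(m) == 0
    if (any(empty)) {
      message("dropping ", sum(empty), " all-zero families")
      m <- m[!empty, , drop = FALSE]
    }
  }
  m
}

#' Write a presence matrix (or any table) as TSV with a provenance header
#'
#' @param m matrix or data.frame.
#' @param path output file.
#' @param seed optional seed to record in the provenance line.
#' @param what short description for the provenance line.
#' @export
write_tsv <- function(m, path, seed = NULL, what = "table") {
  hdr <- sprintf("# cogevo %s | %s%s",
                 as.character(utils::packageVersion("cogevo")), what,
                 if (is.null(seed)) "" else sprintf(" | seed=%d", seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (is.matrix(m)) {
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Check that a tree and a presence matrix describe the same genomes
#'
#' @param tree a [cogevo_tree()].
#' @param matrix presence matrix (genomes in columns).
#' @param strict raise an error on any mismatch instead of reporting.
#' @param prune if `TRUE` and the only mismatch is extra tree leaves, prune
#'   the tree to the intersection (suppressing unary nodes).
#' @return List with `ok`, `missing_from_tree` (genomes absent from the
#'   tree), `missing_from_matrix` (leaves absent from the matrix), and the
#'   possibly pruned `tree` and column-reduced `matrix`.
#' @export
validate_pair <- function(tree, matrix, strict = FALSE, prune = FALSE) {
  g <- colnames(matrix)
  l <- leaf_names(tree)
  miss_tree <- setdiff(g, l)
  miss_mat <- setdiff(l, g)
  ok <- length(miss_tree) == 0 && length(miss_mat) == 0
  if (!ok && strict)
    stop("tree/matrix mismatch; missing from tree: [",
         paste(miss_tree, collapse = ", "), "]; missing from matrix: [",
         paste(miss_mat, collapse = ", "), "]")
  if (!ok && prune) {
    common <- intersect(l, g)
    if (length(common) == 0) stop("tree and matrix share no genomes")
    tree <- prune_tree(tree, common)
    matrix <- matrix[, leaf_names(tree), drop = FALSE]
    ok <- length(setdiff(colnames(matrix), leaf_names(tree))) == 0
  }
  list(ok = ok, missing_from_tree = miss_tree, missing_from_matrix = miss_mat,
       tree = tree, matrix = matrix)
}

# order matrix columns to the tree's leaf order; errors if sets differ
.align_matrix <- function(matrix, tree) {
  l <- leaf_names(tree)
  if (!setequal(colnames(matrix), l))
    stop("matrix genomes do not match tree leaves; run validate_pair()")
  matrix[, l, drop = FALSE]
}
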