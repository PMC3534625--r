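# Summaries over family posteriors: ancestral genome sizes, per-branch
# expected event counts, and the headline gain/loss statistics table.

#' Expected and high-confidence ancestral family counts
#'
#' The expected number of families at a node is the sum over families of the
#' posterior presence probability (so 8 families each with posterior 0.25
#' contribute an expected 2 families); the high-confidence count uses a
#' strict `> threshold` rule.
#'
#' @param post a [compute_posteriors()] result, or a numeric matrix of
#'   presence posteriors (families x nodes).
#' @param threshold posterior probability above which presence counts as
#'   high-confidence (strict inequality).
#' @return Data frame with one row per node: `node`, `expected_families`,
#'   `high_confidence`.
#' @export
ancestral_sizes <- function(post, threshold = 0.9) {
  m <- if (inherits(post, "gainloss_posteriors")) post$node_presence else as.matrix(post)
  data.frame(node = seq_len(ncol(m)),
             expected_families = colSums(m),
             high_confidence = colSums(m > threshold))
}

#' Expected gain and loss event counts
#'
#' @param post a [compute_posteriors()] result.
#' @return List with `per_branch` (data frame: branch, expected_gains,
#'   expected_losses; branch 1 is the origin-to-root branch) and
#'   `per_family` (data frame: family, total_gains, total_losses).
#' @export
expected_events <- function(post) {
  stopifnot(inherits(post, "gainloss_posteriors"))
  list(per_branch = data.frame(branch = seq_len(ncol(post$branch_gain)),
                               expected_gains = colSums(post$branch_gain),
                               expected_losses = colSums(post$branch_loss)),
       per_family = data.frame(family = post$family_ids,
                               total_gains = rowSums(post$branch_gain),
                               total_losses = rowSums(post$branch_loss)))
}

#' Headline gain/loss summary statistics
#'
#' Reports total gains and losses, per-family rates, secondary acquisitions
#' per family (`(gains - n) / n`, i.e. gains beyond the one default gain in
#' the last common ancestor), the loss/gain ratio, and -- when per-family
#' totals are supplied -- the percentage of families whose total expected
#' gain count is below 1.5 ("single-gain" families).  Rates are rounded to
#' 2 decimals and percentages to integers, matching the conventional
#' reporting precision.
#'
#' @param gains per-family expected gain totals, or a single grand total.
#' @param losses per-family expected loss totals, or a single grand total.
#' @param n_families number of families.
#' @return Data frame with columns `statistic` and `value`.
#' @export
summary_table <- function(gains, losses, n_families) {
  gt <- sum(gains)
  lt <- sum(losses)
  single <- if (length(gains) > 1)
    round(100 * mean(gains < 1.5)) else NA_real_
  vals <- c(
    families = n_families,
    gains = gt,
    `gains/family` = round(gt / n_families, 2),
    `acquisitions/family` = round((gt - n_families) / n_families, 2),
    losses = lt,
    `losses/family` = round(lt / n_families, 2),
    `loss/gain ratio` = if (gt > 0) round(lt / gt, 2) else NA_real_,
    `single-gain (<1.5) %` = single
  )
  data.frame(statistic = names(vals), value = unname(vals))
}

#' Extrapolate an ancestral genome size from a family count
#'
#' Extant genomes carry on average about 1.5 genes per detected family
#' (paralogy); multiplying an ancestral expected family count by this ratio
#' and rounding to two significant figures gives a crude ancestral gene
#' count.
#'
#' @param expected_families ancestral expected family count.
#' @param genes_per_family extant genes-to-families ratio.
#' @return Gene count rounded to 2 significant figures.
#' @export
extrapolate_genome_size <- function(expected_families, genes_per_family = 1.5) {
  signif(expected_families * genes_per_family, 2)
}
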