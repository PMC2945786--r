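# Tissue-bias analysis: tissue-specific gene sets from an expression
# matrix, a matched-control permutation test for enrichment/depletion
# of a motif pair's host genes across tissues, and a binomial
# concordance test against an RNA-binding protein's expression
# profile.

#' Tissue-specific gene sets
#'
#' Gene g is specific to tissue t when `expr[g, t]` exceeds the
#' gene's median expression across all tissues by more than two
#' standard deviations (per-gene median and sd, strict inequality).
#'
#' @param expr numeric matrix, genes x tissues, with row and column
#'   names; no missing values (rows with gaps are dropped with a
#'   warning).
#' @return logical matrix of the same shape (`TRUE` = specific).
#' @export
tissue_specific_sets <- function(expr) {
  if (ncol(expr) < 2L) stop("need at least two tissues")
  bad <- apply(expr, 1L, anyNA)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with missing values dropped")
    expr <- expr[!bad, , drop = FALSE]
  }
  med <- apply(expr, 1L, stats::median)
  sdv <- apply(expr, 1L, stats::sd)
  expr > med + 2 * sdv
}

#' Permutation test for tissue bias of a motif pair's host genes
#'
#' The genes whose exons carry the pair define the per-tissue
#' fraction of tissue-specifically expressed genes, `F_E`.  Each of
#' `iterations` control draws collects the same number of exons not
#' carrying the pair, with every control gene matched to a pair gene
#' of the same exon count (nearest count when no exact match exists),
#' giving `F_C`.  The enrichment p-value per tissue is the fraction
#' of iterations with `F_C >= F_E` and the depletion p-value the
#' fraction with `F_C <= F_E`; both use the add-one rule
#' `(count + 1) / (iterations + 1)` so no reported p is zero.
#'
#' @param pair list or one-row data.frame with `motif_u`, `motif_d`.
#' @param corpus the corpus.
#' @param pairing the [region_pairing()] scanned.
#' @param gene_map data.frame `exon_id`, `gene_id`, `exon_count`
#'   (number of exons of the gene).
#' @param expr genes x tissues expression matrix (rownames =
#'   gene_id).
#' @param iterations permutation count (default 10000).
#' @param seed RNG seed.
#' @param cutoff per-tissue significance cutoff (default 0.001).
#' @return object of class `tissue_bias`: `F_E`, `p_enrich`,
#'   `p_deplete` (per tissue), `enriched` / `depleted` tissue labels
#'   at the cutoff, `n_genes`, `iterations`.
#' @export
pair_tissue_bias <- function(pair, corpus, pairing, gene_map, expr,
                             iterations = 10000L, seed = 1L,
                             cutoff = 0.001) {
  up <- extract_region(corpus, pairing$upstream)
  dn <- extract_region(corpus, pairing$downstream)
  carrier <- grepl(pair$motif_u[[1L]], up, fixed = TRUE) &
    grepl(pair$motif_d[[1L]], dn, fixed = TRUE)
  if (!any(carrier)) stop("no exon carries the pair")
  spec <- tissue_specific_sets(expr)
  gm <- gene_map[match(corpus$exon_id, gene_map$exon_id), , drop = FALSE]
  usable <- !is.na(gm$gene_id) & gm$gene_id %in% rownames(spec)
  carrier <- carrier & usable

  pair_genes <- unique(gm$gene_id[carrier])
  S <- spec[pair_genes, , drop = FALSE]
  F_E <- colMeans(S)

  # control pool: exons not carrying the pair, from genes without it
  pool <- which(usable & !gm$gene_id %in% pair_genes)
  if (!length(pool)) stop("no eligible control exons")
  pool_genes <- gm$gene_id[pool]
  pool_counts <- gm$exon_count[pool]
  # one representative exon row per pool gene (sampling genes via
  # exon-count matching; drawing an exon identifies its gene)
  want <- gm$exon_count[carrier][match(pair_genes, gm$gene_id[carrier])]
  avail <- sort(unique(pool_counts))
  target <- vapply(want, function(w) avail[which.min(abs(avail - w))],
                   numeric(1))
  by_count <- split(seq_along(pool), pool_counts)

  rng <- .substream(seed, "tissue_bias")
  spec_pool <- spec[pool_genes, , drop = FALSE]
  n_tis <- ncol(spec)
  ge <- integer(n_tis); le <- integer(n_tis)
  counts_tab <- table(factor(target, levels = avail))
  m <- length(pair_genes)
  for (it in seq_len(iterations)) {
    draw <- integer(0)
    for (cnt in names(counts_tab)) {
      need <- counts_tab[[cnt]]
      if (need == 0L) next
      cls <- by_count[[cnt]]
      pick <- if (length(cls) >= need)
        cls[rng$sample_int(length(cls), need)]
      else cls[rng$sample_int(length(cls), need, replace = TRUE)]
      draw <- c(draw, pick)
    }
    F_C <- colMeans(spec_pool[draw, , drop = FALSE])
    ge <- ge + (F_C >= F_E)
    le <- le + (F_C <= F_E)
  }
  p_enrich <- (ge + 1) / (iterations + 1)
  p_deplete <- (le + 1) / (iterations + 1)
  names(p_enrich) <- names(p_deplete) <- colnames(expr)
  structure(list(motif_u = pair$motif_u[[1L]],
                 motif_d = pair$motif_d[[1L]],
                 F_E = F_E, p_enrich = p_enrich, p_deplete = p_deplete,
                 enriched = colnames(expr)[p_enrich <= cutoff],
                 depleted = colnames(expr)[p_deplete <= cutoff],
                 cutoff = cutoff, n_genes = m,
                 iterations = iterations),
            class = "tissue_bias")
}

#' @export
print.tissue_bias <- function(x, ...) {
  cat(sprintf("<tissue_bias> %s/%s: %d host genes, %d iterations\n",
              x$motif_u, x$motif_d, x$n_genes, x$iterations))
  cat(sprintf("  enriched tissues (p <= %g): %s\n", x$cutoff,
              if (length(x$enriched)) paste(x$enriched, collapse = ", ")
              else "none"))
  cat(sprintf("  depleted tissues (p <= %g): %s\n", x$cutoff,
              if (length(x$depleted)) paste(x$depleted, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Binomial concordance with an RNA-binding protein's profile
#'
#' Over the tissues significant for the pair, a tissue is concordant
#' when the protein's expression deviates from its own cross-tissue
#' median in the matching direction: above the median in
#' pair-enriched tissues, below it in pair-depleted ones.  Returns a
#' one-sided binomial p-value for the concordant count at success
#' probability 0.5.
#'
#' @param bias a [pair_tissue_bias()] result with at least one
#'   significant tissue.
#' @param rbp_profile named numeric vector: the protein's expression
#'   per tissue (names matching the expression matrix columns).
#' @return list with `p_value`, `concordant`, `n_significant`;
#'   `flagged = TRUE` (and `p_value = NA`) when no tissue is
#'   significant.
#' @export
concordance_binomial <- function(bias, rbp_profile) {
  stopifnot(inherits(bias, "tissue_bias"))
  med <- stats::median(rbp_profile)
  conc <- c(rbp_profile[bias$enriched] > med,
            rbp_profile[bias$depleted] < med)
  n <- length(conc)
  if (n == 0L)
    return(list(p_value = NA_real_, concordant = 0L, n_significant = 0L,
                flagged = TRUE))
  x <- sum(conc)
  list(p_value = stats::pbinom(x - 1L, n, 0.5, lower.tail = FALSE),
       concordant = x, n_significant = n, flagged = FALSE)
}
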