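#' Pairwise LD (R-squared) between SNP dosages
#'
#' Squared Pearson correlation of dosage vectors; the matching LD
#' statistic for a dosage-based data model.
#'
#' @param genotypes dosage matrix.
#' @param snp_subset optional character vector of SNPs to restrict to.
#' @return symmetric R-squared matrix with unit diagonal.
#' @export
pairwise_r2 <- function(genotypes, snp_subset = NULL) {
  G <- if (is.null(snp_subset)) genotypes
       else genotypes[, snp_subset, drop = FALSE]
  if (ncol(G) < 2) stop("need >= 2 SNPs for pairwise LD")
  sds <- apply(G, 2, stats::sd)
  if (any(sds == 0))
    stop("constant dosage for SNP(s): ",
         paste(colnames(G)[sds == 0], collapse = ", "))
  stats::cor(G)^2
}

#' LD blocks by single-linkage clustering of 1 - R-squared
#'
#' Hierarchical clustering with single linkage ("friends of friends")
#' on the distance \eqn{1 - R^2}, cut at height `cut` (default 0.4), so
#' that blocks are the connected components of the graph joining SNP
#' pairs with \eqn{R^2} strictly greater than `1 - cut` (0.6 at the
#' default). Each member of a multi-SNP block has \eqn{R^2 > 0.6} with at
#' least one other member and \eqn{R^2 \le 0.6} with every SNP outside
#' its block; singleton blocks are permitted.
#'
#' @param r2 symmetric R-squared matrix from [pairwise_r2()].
#' @param cut tree cut height (default 0.4). Distances exactly at the cut
#'   do not join.
#' @return list of class `ld_blocks`: `assignment` (data.frame `snp`,
#'   `block`), `members` (list of SNP vectors per block).
#' @export
single_linkage_blocks <- function(r2, cut = 0.4) {
  if (!is.matrix(r2) || nrow(r2) != ncol(r2))
    stop("r2 must be a square matrix")
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 must be symmetric")
  snps <- rownames(r2)
  if (is.null(snps)) snps <- paste0("snp", seq_len(nrow(r2)))
  if (nrow(r2) == 1) {
    block <- 1L
  } else {
    d <- stats::as.dist(1 - r2)
    hc <- stats::hclust(d, method = "single")
    # cutree joins merges at height <= h; the block definition requires
    # strict R^2 > 1 - cut, i.e. distance strictly < cut
    block <- unname(stats::cutree(hc, h = cut - 1e-9))
  }
  # renumber blocks in order of first appearance for stable output
  block <- match(block, unique(block))
  assignment <- data.frame(snp = snps, block = block)
  members <- split(snps, block)
  structure(list(assignment = assignment, members = members),
            class = "ld_blocks")
}

#' Aggregate significant SNP-flux calls to risk locus-flux pairs
#'
#' Collapses SNP-level significant calls to distinct (LD block, reaction)
#' combinations, counting member SNPs and summarizing the direction of
#' interaction within each locus-flux pair.
#'
#' @param calls data.frame from [call_pairs()] (needs `snp`, `reaction`,
#'   `call`, `direction`).
#' @param blocks a [single_linkage_blocks()] result covering every called
#'   SNP.
#' @return data.frame: `block`, `reaction`, `n_snps`, `direction`
#'   (`amplification`, `buffering` or `mixed`), `min_fdr_interaction`
#'   when available.
#' @export
aggregate_locus_flux_pairs <- function(calls, blocks) {
  stopifnot(inherits(blocks, "ld_blocks"))
  sig <- calls[!is.na(calls$call) & calls$call == "significant", ,
               drop = FALSE]
  if (nrow(sig) == 0)
    return(data.frame(block = integer(0), reaction = character(0),
                      n_snps = integer(0), direction = character(0)))
  idx <- match(sig$snp, blocks$assignment$snp)
  if (anyNA(idx))
    stop("SNP(s) without an LD block assignment: ",
         paste(unique(sig$snp[is.na(idx)]), collapse = ", "))
  sig$block <- blocks$assignment$block[idx]
  key <- interaction(sig$block, sig$reaction, drop = TRUE)
  rows <- lapply(split(sig, key), function(g) {
    dirs <- unique(g$direction)
    data.frame(
      block = g$block[1], reaction = g$reaction[1],
      n_snps = length(unique(g$snp)),
      direction = if (length(dirs) == 1) dirs else "mixed",
      min_fdr_interaction = if (!is.null(g$fdr_interaction))
        min(g$fdr_interaction) else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$block, out$reaction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
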