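# Gene-region windowing, lead-variant selection, and greedy LD clumping.
#
# A gene region is the annotated gene interval extended by a flank (default
# 200 kb each side, floored at position 1). Variants falling in several
# windows belong to all of them. Instrument pruning follows the usual
# greedy clump: take the most significant remaining variant, discard
# everything correlated with it at r^2 >= the threshold, repeat.

#' Assign variants to flanked gene regions
#'
#' @param dataset A `gwas_dataset` (needs `chrom` and `pos`).
#' @param annotation Tibble with `gene_symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param flank Flank added to each side of the gene, in base pairs
#'   (default 200000). Window start is floored at 1.
#' @return Tibble with one row per gene: `gene_symbol`, `chrom`,
#'   `window_start`, `window_end`, `variant_ids` (list column) and
#'   `n_variants`. Attribute `unassigned` holds ids of variants in no
#'   window. Window boundaries are inclusive.
#' @export
assign_regions <- function(dataset, annotation, flank = 200000) {
  if (is.null(annotation) || nrow(annotation) == 0) {
    abort_usage("annotation must be non-empty")
  }
  d <- as_tibble(dataset)
  assigned <- rep(FALSE, nrow(d))
  out <- vector("list", nrow(annotation))
  for (g in seq_len(nrow(annotation))) {
    ws <- max(1, annotation$start[g] - flank)
    we <- annotation$end[g] + flank
    hit <- !is.na(d$chrom) & d$chrom == annotation$chrom[g] &
      !is.na(d$pos) & d$pos >= ws & d$pos <= we
    assigned <- assigned | hit
    out[[g]] <- tibble(
      gene_symbol = annotation$gene_symbol[g],
      chrom = annotation$chrom[g],
      window_start = ws,
      window_end = we,
      variant_ids = list(d$variant_id[hit]),
      n_variants = sum(hit)
    )
  }
  res <- list_rbind(out)
  structure(res, unassigned = d$variant_id[!assigned])
}

#' Lead variant of a region
#'
#' The member with the smallest p-value; ties broken by smaller position,
#' then lexicographically smaller variant id.
#'
#' @param dataset A `gwas_dataset`.
#' @param variant_ids Character vector of region member ids (non-empty, all
#'   present in `dataset`).
#' @return The lead `variant_id` (length-1 character).
#' @export
lead_variant <- function(dataset, variant_ids) {
  if (length(variant_ids) == 0) {
    abort_usage("region has no member variants")
  }
  d <- as_tibble(dataset)
  idx <- match(variant_ids, d$variant_id)
  if (anyNA(idx)) {
    abort_data(paste0(
      "variant(s) absent from dataset: ",
      paste(head(variant_ids[is.na(idx)], 5L), collapse = ", ")
    ))
  }
  sub <- d[idx, ]
  if (all(is.na(sub$pval))) {
    abort_usage("no member has a p-value")
  }
  ord <- order(sub$pval, sub$pos, sub$variant_id)
  sub$variant_id[ord[1]]
}

#' Greedy LD clumping
#'
#' Optionally filters to `pval <= p_max`, then repeatedly retains the most
#' significant remaining variant (ties as in [lead_variant()]) and removes
#' all remaining variants with squared correlation `r^2 >= r2_max` against
#' it. Retained variants are returned in retention order and are pairwise
#' below the threshold.
#'
#' @param dataset A `gwas_dataset`.
#' @param variant_ids Candidate variant ids.
#' @param ld An [ld_matrix()] covering all candidates.
#' @param r2_max Removal threshold on r-squared; retained pairs satisfy
#'   `r^2 < r2_max`. Default 0.1.
#' @param p_max Optional p-value filter applied before clumping (`NULL` for
#'   none).
#' @return Character vector of retained variant ids, in retention order.
#' @export
greedy_clump <- function(dataset, variant_ids, ld, r2_max = 0.1,
                         p_max = NULL) {
  if (length(variant_ids) == 0) {
    return(character(0))
  }
  missing_ld <- setdiff(variant_ids, rownames(ld))
  if (length(missing_ld) > 0) {
    abort_data(paste0(
      "variant(s) absent from LD matrix: ",
      paste(head(missing_ld, 5L), collapse = ", ")
    ))
  }
  d <- as_tibble(dataset)
  idx <- match(variant_ids, d$variant_id)
  if (anyNA(idx)) {
    abort_data(paste0(
      "variant(s) absent from dataset: ",
      paste(head(variant_ids[is.na(idx)], 5L), collapse = ", ")
    ))
  }
  sub <- d[idx, c("variant_id", "pos", "pval")]
  if (!is.null(p_max)) {
    sub <- sub[!is.na(sub$pval) & sub$pval <= p_max, ]
  }
  if (nrow(sub) == 0) {
    return(character(0))
  }
  sub <- sub[order(sub$pval, sub$pos, sub$variant_id), ]
  remaining <- sub$variant_id
  r2 <- unclass(ld)[remaining, remaining, drop = FALSE]^2
  retained <- character(0)
  while (length(remaining) > 0) {
    top <- remaining[1]
    retained <- c(retained, top)
    keep <- r2[top, remaining] < r2_max
    keep[remaining == top] <- FALSE
    remaining <- remaining[keep]
  }
  retained
}
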