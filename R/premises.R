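# The four instrument-validity premises.
#
# 1. Biological relevance: the region's gene encodes a protein directly
#    involved in ketone production or utilization.
# 2. Cross-trait consistency: the lead variant associates with all three
#    primary ketone bodies (acetone, acetoacetate, beta-hydroxybutyrate).
# 3. No horizontal pleiotropy: no catalogued genome-wide-significant trait
#    association for the region, other than whitelisted vertical traits.
# 4. Positive controls: the region's instruments associate with at least
#    one trait with a trial-established response to ketone supplementation.

#' Default panel of ketone-metabolism genes
#'
#' Genes encoding the enzymes and transporters of ketone body production
#' and utilization (hepatic ketogenesis, peripheral ketolysis), plus the
#' acetone-metabolizing CYP2E1.
#'
#' @return Character vector of gene symbols.
#' @export
ketone_gene_panel <- function() {
  c("ACAT1", "ACAT2", "HMGCS2", "HMGCL", "BDH1", "SLC2A4", "AACS", "OXCT1",
    "CYP2E1")
}

new_premise_verdict <- function(status, evidence = tibble(),
                                reason = NA_character_) {
  stopifnot(status %in% c("pass", "fail", "not_evaluated"))
  structure(
    list(status = status, evidence = as_tibble(evidence), reason = reason),
    class = "premise_verdict"
  )
}

verdict_not_evaluated <- function(reason = "short_circuited") {
  new_premise_verdict("not_evaluated", tibble(), reason)
}

#' @export
print.premise_verdict <- function(x, ...) {
  cat(sprintf("<premise_verdict> %s%s\n", x$status,
              if (!is.na(x$reason)) paste0(" (", x$reason, ")") else ""))
  if (nrow(x$evidence) > 0) print(x$evidence, ...)
  invisible(x)
}

#' Symbol for a premise status
#'
#' `pass` renders as a check mark, `fail` as a multiplication sign,
#' `not_evaluated` as a dash.
#'
#' @param status Character vector of statuses.
#' @return Character vector of symbols.
#' @export
status_symbol <- function(status) {
  unname(c(pass = "✓", fail = "×", not_evaluated = "-")[status])
}

#' Premise 1: biological relevance of the gene region
#'
#' @param gene_symbol The region's gene symbol.
#' @param relevant_genes Non-empty character vector of ketone-relevant
#'   genes; defaults to [ketone_gene_panel()]. Matching is
#'   case-insensitive.
#' @return A `premise_verdict`.
#' @export
premise_biological <- function(gene_symbol,
                               relevant_genes = ketone_gene_panel()) {
  if (length(relevant_genes) == 0) {
    abort_config("relevant_genes must be non-empty")
  }
  hit <- toupper(gene_symbol) %in% toupper(relevant_genes)
  new_premise_verdict(
    if (hit) "pass" else "fail",
    evidence = tibble(gene_symbol = gene_symbol, relevant = hit),
    reason = if (hit) NA_character_ else "gene_not_ketone_relevant"
  )
}

#' Premise 2: consistency across the three primary ketone bodies
#'
#' The lead variant must be present and associated below `p_threshold` in
#' each of the three ketone GWAS. A variant missing from a dataset fails
#' (with reason `missing`) rather than erroring.
#'
#' @param lead_id Lead variant id.
#' @param ketone_datasets Named list of exactly three `gwas_dataset`
#'   objects (acetone, acetoacetate, beta-hydroxybutyrate).
#' @param p_threshold Association threshold, default `1e-4` (strict `<`).
#' @param require_sign_concordance If `TRUE`, additionally require the same
#'   effect direction in all three datasets (off by default; only
#'   meaningful when the datasets share an effect-allele frame).
#' @return A `premise_verdict`; the evidence lists per-trait beta, se and
#'   p.
#' @export
premise_consistency <- function(lead_id, ketone_datasets, p_threshold = 1e-4,
                                require_sign_concordance = FALSE) {
  if (length(ketone_datasets) != 3) {
    abort_usage("exactly three ketone datasets are required")
  }
  ev <- list_rbind(imap(ketone_datasets, function(ds, nm) {
    d <- as_tibble(ds)
    i <- match(lead_id, d$variant_id)
    if (is.na(i)) {
      tibble(trait = nm, present = FALSE, beta = NA_real_, se = NA_real_,
             pval = NA_real_)
    } else {
      tibble(trait = nm, present = TRUE, beta = d$beta[i], se = d$se[i],
             pval = d$pval[i])
    }
  }))
  ev$below_threshold <- ev$present & !is.na(ev$pval) & ev$pval < p_threshold
  reason <- NA_character_
  if (!all(ev$present)) {
    reason <- "missing"
  } else if (!all(ev$below_threshold)) {
    reason <- "above_threshold"
  } else if (require_sign_concordance &&
             length(unique(sign(ev$beta))) != 1L) {
    reason <- "sign_discordant"
  }
  new_premise_verdict(
    if (is.na(reason)) "pass" else "fail",
    evidence = mutate(ev, variant_id = lead_id),
    reason = reason
  )
}

#' Premise 3: no horizontal pleiotropy from the catalogue screen
#'
#' Flags every catalogued trait associated with the region (matched by gene
#' symbol or by member variant id) below `p_threshold`. The premise passes
#' when every flagged trait is on the vertical-pleiotropy whitelist (traits
#' judged to lie on the ketone pathway itself); with the default empty
#' whitelist any flagged trait fails the premise.
#'
#' @param gene_symbol The region's gene symbol.
#' @param variant_ids The region's member variant ids.
#' @param catalogue A trait-association catalogue tibble
#'   (see [read_trait_catalogue()]).
#' @param p_threshold Flagging threshold, default `5e-8` (strict `<`).
#' @param vertical_whitelist Character vector of trait names treated as
#'   vertical pleiotropy (case-insensitive); default empty.
#' @return A `premise_verdict`; the evidence lists flagged traits with
#'   their whitelist status.
#' @export
premise_pleiotropy <- function(gene_symbol, variant_ids, catalogue,
                               p_threshold = 5e-8,
                               vertical_whitelist = character()) {
  cat_tbl <- as_tibble(catalogue)
  hit <- (!is.na(cat_tbl$gene_symbol) &
            toupper(cat_tbl$gene_symbol) == toupper(gene_symbol)) |
    (!is.na(cat_tbl$variant_id) & cat_tbl$variant_id %in% variant_ids)
  flagged <- cat_tbl[hit & !is.na(cat_tbl$pval) & cat_tbl$pval < p_threshold, ]
  flagged <- flagged[order(flagged$pval), ]
  flagged <- flagged[!duplicated(tolower(flagged$trait)), ]
  vertical <- tolower(flagged$trait) %in% tolower(vertical_whitelist)
  ev <- tibble(
    trait = flagged$trait,
    pval = flagged$pval,
    vertical = vertical
  )
  pass <- all(vertical)
  new_premise_verdict(
    if (pass) "pass" else "fail",
    evidence = ev,
    reason = if (pass) NA_character_ else "horizontal_pleiotropy_flagged"
  )
}

#' Premise 4: association with at least one positive control
#'
#' For each control outcome, estimates the effect of the instrumented
#' exposure with the inverse-variance weighted method (two or more
#' variants) or the ratio method (single variant). The premise passes when
#' any control association has `p < alpha` (two-sided).
#'
#' @param instruments Named list of `harmonized_set` objects, one per
#'   control outcome (exposure harmonized to that control).
#' @param alpha Significance level, default 0.05.
#' @param ivw_model IVW model for multi-variant sets (see [mr_ivw()]).
#' @return A `premise_verdict`; the evidence carries one row per control
#'   with the method used, estimate, CI and p.
#' @export
premise_positive_controls <- function(instruments, alpha = 0.05,
                                      ivw_model = "mre") {
  if (length(instruments) == 0) {
    abort_usage("at least one control outcome is required")
  }
  if (is.null(names(instruments)) || any(names(instruments) == "")) {
    names(instruments) <- paste0("control_", seq_along(instruments))
  }
  ev <- list_rbind(imap(instruments, function(hs, nm) {
    j <- nrow(hs)
    if (j == 0) {
      return(tibble(
        control = nm, method = NA_character_, n_variants = 0L,
        beta = NA_real_, se = NA_real_, ci_low = NA_real_,
        ci_high = NA_real_, pval = NA_real_
      ))
    }
    est <- if (j == 1) mr_ratio(hs) else mr_ivw(hs, model = ivw_model)
    tibble(
      control = nm, method = est$method, n_variants = j,
      beta = est$beta, se = est$se, ci_low = est$ci_low,
      ci_high = est$ci_high, pval = est$pval
    )
  }))
  if (all(ev$n_variants == 0)) {
    return(new_premise_verdict("fail", ev, "no_instruments"))
  }
  pass <- any(!is.na(ev$pval) & ev$pval < alpha)
  new_premise_verdict(
    if (pass) "pass" else "fail",
    evidence = ev,
    reason = if (pass) NA_character_ else "no_control_association"
  )
}
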