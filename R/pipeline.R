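# The stepwise instrument-selection pipeline.
#
# Biologically-driven strategy: discover candidate gene regions from the
# acetone GWAS at a permissive threshold, then evaluate the four validity
# premises per region. A failure at premise 1 or 2 short-circuits the rest
# (they are reported as not-evaluated); once premises 1-2 pass, premises 3
# and 4 are evaluated independently of each other, so a pleiotropy failure
# still reports the positive-control result alongside it. Overall validity
# requires all four passes.
#
# Agnostic strategy: per ketone body, take the genome-wide significant lead
# variant of every gene region and run IVW, weighted median and MR-Egger
# against each control outcome.

#' Pipeline configuration
#'
#' Thresholds, gene panel and policies for both strategies. Defaults follow
#' the framework's standard choices: candidate discovery below
#' `p = 5e-6` (deliberately sub-genome-wide, so biologically relevant but
#' sub-threshold regions are not overlooked), genome-wide significance
#' `5e-8` for instruments and the catalogue screen, ketone-body consistency
#' at `1e-4`, clumping at `r^2 < 0.1`, gene windows of +/- 200 kb, and a
#' two-sided 0.05 level for the positive controls.
#'
#' @param relevant_genes Gene panel for premise 1.
#' @param vertical_whitelist Traits treated as vertical pleiotropy in
#'   premise 3 (default empty: most conservative).
#' @param p_discovery Candidate-region discovery threshold (strict `<`).
#' @param p_genomewide Genome-wide threshold for instruments and the
#'   catalogue screen.
#' @param p_consistency Premise-2 threshold.
#' @param r2_max Clumping threshold on r-squared.
#' @param flank Gene-region flank in base pairs.
#' @param alpha Premise-4 significance level.
#' @param require_sign_concordance Premise-2 direction flag.
#' @param ivw_model IVW model used throughout (`"mre"` or `"fe"`).
#' @param harmonization A [harmonization_policy()].
#' @param n_boot,seed Bootstrap size and seed for the weighted median in
#'   the agnostic strategy.
#' @return A list of class `premise_config`.
#' @export
premise_config <- function(relevant_genes = ketone_gene_panel(),
                           vertical_whitelist = character(),
                           p_discovery = 5e-6,
                           p_genomewide = 5e-8,
                           p_consistency = 1e-4,
                           r2_max = 0.1,
                           flank = 200000,
                           alpha = 0.05,
                           require_sign_concordance = FALSE,
                           ivw_model = "mre",
                           harmonization = harmonization_policy(),
                           n_boot = 1000,
                           seed = 1L) {
  structure(
    list(
      relevant_genes = relevant_genes,
      vertical_whitelist = vertical_whitelist,
      p_discovery = p_discovery,
      p_genomewide = p_genomewide,
      p_consistency = p_consistency,
      r2_max = r2_max,
      flank = flank,
      alpha = alpha,
      require_sign_concordance = require_sign_concordance,
      ivw_model = ivw_model,
      harmonization = harmonization,
      n_boot = n_boot,
      seed = seed
    ),
    class = "premise_config"
  )
}

check_bundle <- function(bundle) {
  required <- c("discovery", "ketones", "controls", "annotation", "ld",
                "catalogue")
  missing_parts <- setdiff(required, names(bundle))
  if (length(missing_parts) > 0) {
    abort_config(paste0(
      "bundle lacks component(s): ", paste(missing_parts, collapse = ", ")
    ))
  }
  if (length(bundle$ketones) != 3) {
    abort_config("bundle$ketones must hold exactly three datasets")
  }
  if (length(bundle$controls) == 0) {
    abort_config("bundle$controls must hold at least one dataset")
  }
  invisible(bundle)
}

#' Discover candidate gene regions from a discovery GWAS
#'
#' Regions whose flanked window contains at least one variant below the
#' discovery threshold.
#'
#' @param dataset Discovery `gwas_dataset` (acetone).
#' @param annotation Gene annotation tibble.
#' @param p_discovery Discovery threshold (strict `<`), default `5e-6`.
#' @param flank Window flank in base pairs.
#' @return The [assign_regions()] tibble restricted to discovered regions,
#'   with an added `min_pval` column. Attribute `unassigned_significant`
#'   lists sub-threshold variants falling in no window.
#' @export
discover_candidate_regions <- function(dataset, annotation,
                                       p_discovery = 5e-6, flank = 200000) {
  regions <- assign_regions(dataset, annotation, flank = flank)
  d <- as_tibble(dataset)
  min_p <- map_dbl(regions$variant_ids, function(ids) {
    if (length(ids) == 0) return(NA_real_)
    suppressWarnings(min(d$pval[match(ids, d$variant_id)], na.rm = TRUE))
  })
  regions$min_pval <- min_p
  hit <- !is.na(min_p) & min_p < p_discovery
  unassigned <- attr(regions, "unassigned", exact = TRUE)
  un_sig <- unassigned[
    d$pval[match(unassigned, d$variant_id)] < p_discovery
  ]
  structure(regions[hit, ], unassigned_significant = un_sig[!is.na(un_sig)])
}

#' Run the biologically-driven premise pipeline
#'
#' For every discovery dataset and every candidate region: premise 1
#' (biological relevance); if passed, premise 2 (ketone-body consistency of
#' the lead variant); if passed, the region's genome-wide significant
#' variants are clumped and premises 3 (catalogue pleiotropy screen) and 4
#' (positive controls, instruments harmonized per control) are evaluated
#' independently. Verdicts after the first premise-1/2 failure are
#' not-evaluated.
#'
#' @param bundle A list with components `discovery` (named list of acetone
#'   `gwas_dataset`s), `ketones` (named list of three ketone datasets),
#'   `controls` (named list of control-outcome datasets), `annotation`,
#'   `ld` (named list of [ld_matrix()] per gene), `catalogue`.
#' @param config A [premise_config()].
#' @return A tibble of class `premise_matrix`, one row per (source, region)
#'   sorted by source then genomic position, with status columns
#'   `biological`, `consistent`, `no_pleiotropy`, `positive_control`, the
#'   rendered `pattern`, instrument ids, and a `verdicts` list column of
#'   the four `premise_verdict` objects. Attribute `stepwise` counts the
#'   regions surviving each premise per source.
#' @export
run_biological_pipeline <- function(bundle, config = premise_config()) {
  check_bundle(bundle)
  rows <- list()
  stepwise <- list()
  for (src in names(bundle$discovery)) {
    src_rows_list <- list()
    ds <- bundle$discovery[[src]]
    regions <- discover_candidate_regions(
      ds, bundle$annotation, p_discovery = config$p_discovery,
      flank = config$flank
    )
    for (g in seq_len(nrow(regions))) {
      gene <- regions$gene_symbol[g]
      members <- regions$variant_ids[[g]]
      p1 <- premise_biological(gene, config$relevant_genes)
      p2 <- p3 <- p4 <- verdict_not_evaluated()
      lead <- NA_character_
      instruments <- character(0)
      if (p1$status == "pass") {
        lead <- lead_variant(ds, members)
        p2 <- premise_consistency(
          lead, bundle$ketones, p_threshold = config$p_consistency,
          require_sign_concordance = config$require_sign_concordance
        )
      }
      if (p1$status == "pass" && p2$status == "pass") {
        d <- as_tibble(ds)
        gws <- members[d$pval[match(members, d$variant_id)] <
                         config$p_genomewide]
        gws <- gws[!is.na(gws)]
        if (is.null(bundle$ld[[gene]])) {
          abort_config(paste0("bundle$ld lacks a matrix for gene ", gene))
        }
        instruments <- greedy_clump(
          ds, gws, bundle$ld[[gene]], r2_max = config$r2_max
        )
        p3 <- premise_pleiotropy(
          gene, members, bundle$catalogue,
          p_threshold = config$p_genomewide,
          vertical_whitelist = config$vertical_whitelist
        )
        p4 <- if (length(instruments) == 0) {
          new_premise_verdict("fail", tibble(),
                              "no_genomewide_significant_instruments")
        } else {
          hs <- map(bundle$controls, function(ctrl) {
            harmonize_set(ds, ctrl, instruments,
                          policy = config$harmonization)
          })
          premise_positive_controls(hs, alpha = config$alpha,
                                    ivw_model = config$ivw_model)
        }
      }
      statuses <- c(p1$status, p2$status, p3$status, p4$status)
      src_rows_list[[length(src_rows_list) + 1L]] <- tibble(
        source = src,
        gene_symbol = gene,
        chrom = regions$chrom[g],
        window_start = regions$window_start[g],
        window_end = regions$window_end[g],
        lead_variant = lead,
        n_instruments = length(instruments),
        instruments = list(instruments),
        biological = statuses[1],
        consistent = statuses[2],
        no_pleiotropy = statuses[3],
        positive_control = statuses[4],
        pattern = paste(status_symbol(statuses), collapse = ""),
        all_four = all(statuses == "pass"),
        verdicts = list(list(biological = p1, consistent = p2,
                             no_pleiotropy = p3, positive_control = p4))
      )
    }
    src_rows <- list_rbind(src_rows_list)
    has_rows <- nrow(src_rows) > 0
    stepwise[[length(stepwise) + 1L]] <- tibble(
      source = src,
      n_candidate = nrow(regions),
      n_biological = if (has_rows) sum(src_rows$biological == "pass") else 0L,
      n_consistent = if (has_rows) {
        sum(src_rows$biological == "pass" & src_rows$consistent == "pass")
      } else 0L,
      n_no_pleiotropy = if (has_rows) {
        sum(src_rows$biological == "pass" & src_rows$consistent == "pass" &
              src_rows$no_pleiotropy == "pass")
      } else 0L,
      n_all_four = if (has_rows) sum(src_rows$all_four) else 0L
    )
    rows <- c(rows, src_rows_list)
  }
  out <- if (length(rows) > 0) {
    arrange(list_rbind(rows), .data$source, .data$chrom, .data$window_start,
            .data$gene_symbol)
  } else {
    tibble(
      source = character(0), gene_symbol = character(0), chrom = character(0),
      window_start = numeric(0), window_end = numeric(0),
      lead_variant = character(0), n_instruments = integer(0),
      instruments = list(), biological = character(0),
      consistent = character(0), no_pleiotropy = character(0),
      positive_control = character(0), pattern = character(0),
      all_four = logical(0), verdicts = list()
    )
  }
  structure(
    out,
    stepwise = list_rbind(stepwise),
    class = c("premise_matrix", class(tibble()))
  )
}

#' @export
print.premise_matrix <- function(x, ...) {
  cat(render_premise_matrix(x, style = "text"))
  invisible(x)
}

#' Render a premise matrix as text
#'
#' Deterministic renderings of the verdict matrix using the symbols
#' from [status_symbol()]: a check mark for a satisfied premise, a
#' multiplication sign for a failed one, and a dash where a premise was not
#' investigated.
#'
#' @param x A `premise_matrix`.
#' @param style `"text"` for an aligned human-readable table, `"tsv"` for
#'   tab-delimited records.
#' @return A single character string (with trailing newline).
#' @export
render_premise_matrix <- function(x, style = c("text", "tsv")) {
  style <- match.arg(style)
  tb <- as_tibble(x)
  tb <- arrange(tb, .data$source, .data$chrom, .data$window_start,
                .data$gene_symbol)
  secondary <- map_chr(seq_len(nrow(tb)), function(i) {
    ids <- setdiff(tb$instruments[[i]], tb$lead_variant[i])
    if (length(ids) == 0) "" else paste(ids, collapse = ",")
  })
  flat <- tibble(
    source = tb$source,
    gene = tb$gene_symbol,
    lead_variant = ifelse(is.na(tb$lead_variant), "", tb$lead_variant),
    secondary_variants = secondary,
    biological = status_symbol(tb$biological),
    consistent = status_symbol(tb$consistent),
    no_pleiotropy = status_symbol(tb$no_pleiotropy),
    positive_control = status_symbol(tb$positive_control),
    pattern = tb$pattern
  )
  header <- names(flat)
  lines <- c(
    paste(header, collapse = "\t"),
    map_chr(seq_len(nrow(flat)), function(i) {
      paste(as.character(unlist(flat[i, ])), collapse = "\t")
    })
  )
  if (style == "text") {
    mat <- rbind(header, as.matrix(flat))
    widths <- apply(nchar(mat), 2, max)
    lines <- apply(mat, 1, function(r) {
      paste(mapply(formatC, r, width = -widths), collapse = "  ")
    })
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Run the agnostic instrument-selection strategy
#'
#' Per ketone body: genome-wide significant variants, one lead per gene
#' region, harmonized to each control outcome; then the inverse-variance
#' weighted, weighted median and MR-Egger methods where their
#' instrument-count preconditions hold (a single variant falls back to the
#' ratio method; the two-sample estimators needing three instruments are
#' recorded as skipped below that).
#'
#' @inheritParams run_biological_pipeline
#' @return A tibble of class `agnostic_result`: one row per (exposure,
#'   outcome, method) with `n_variants`, the estimate block, `status`
#'   (`"ok"`, `"skipped"`, or `"no_instruments"`) and `note`.
#' @export
run_agnostic_pipeline <- function(bundle, config = premise_config()) {
  check_bundle(bundle)
  rows <- list()
  for (kt in names(bundle$ketones)) {
    ds <- bundle$ketones[[kt]]
    regions <- assign_regions(ds, bundle$annotation, flank = config$flank)
    d <- as_tibble(ds)
    leads <- character(0)
    for (g in seq_len(nrow(regions))) {
      members <- regions$variant_ids[[g]]
      if (length(members) == 0) next
      lead <- lead_variant(ds, members)
      if (d$pval[match(lead, d$variant_id)] < config$p_genomewide) {
        leads <- c(leads, lead)
      }
    }
    leads <- unique(leads)
    for (ctrl in names(bundle$controls)) {
      if (length(leads) == 0) {
        rows[[length(rows) + 1L]] <- tibble(
          exposure = kt, outcome = ctrl, method = NA_character_,
          n_variants = 0L, beta = NA_real_, se = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
          status = "no_instruments", note = "no genome-wide significant leads"
        )
        next
      }
      hs <- harmonize_set(ds, bundle$controls[[ctrl]], leads,
                          policy = config$harmonization)
      j <- nrow(hs)
      add <- function(est, method, status = "ok", note = NA_character_) {
        tibble(
          exposure = kt, outcome = ctrl, method = method, n_variants = j,
          beta = if (is.null(est)) NA_real_ else est$beta,
          se = if (is.null(est)) NA_real_ else est$se,
          ci_low = if (is.null(est)) NA_real_ else est$ci_low,
          ci_high = if (is.null(est)) NA_real_ else est$ci_high,
          pval = if (is.null(est)) NA_real_ else est$pval,
          status = status, note = note
        )
      }
      if (j == 0) {
        rows[[length(rows) + 1L]] <- tibble(
          exposure = kt, outcome = ctrl, method = NA_character_,
          n_variants = 0L, beta = NA_real_, se = NA_real_,
          ci_low = NA_real_, ci_high = NA_real_, pval = NA_real_,
          status = "no_instruments",
          note = "all instruments dropped in harmonization"
        )
        next
      }
      if (j == 1) {
        rows[[length(rows) + 1L]] <- add(mr_ratio(hs), "ratio")
      } else {
        est <- mr_ivw(hs, model = config$ivw_model)
        rows[[length(rows) + 1L]] <- add(est, est$method)
      }
      if (j >= 3) {
        rows[[length(rows) + 1L]] <- add(
          mr_weighted_median(hs, n_boot = config$n_boot, seed = config$seed),
          "weighted_median"
        )
        rows[[length(rows) + 1L]] <- tryCatch(
          add(mr_egger(hs), "egger"),
          ketomr_domain_error = function(e) {
            add(NULL, "egger", "skipped", conditionMessage(e))
          }
        )
      } else {
        rows[[length(rows) + 1L]] <- add(
          NULL, "weighted_median", "skipped", "fewer than 3 variants"
        )
        rows[[length(rows) + 1L]] <- add(
          NULL, "egger", "skipped", "fewer than 3 variants"
        )
      }
    }
  }
  structure(
    list_rbind(rows),
    class = c("agnostic_result", class(tibble()))
  )
}
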