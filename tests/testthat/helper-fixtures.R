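# Deterministic fixtures built in code.

assoc_row <- function(variant_id, chrom = "1", pos = 1000000,
                      effect_allele = "A", other_allele = "G",
                      beta = 0.1, se = 0.01, eaf = 0.3,
                      pval = NULL, n = 100000) {
  tibble::tibble(
    variant_id = variant_id, chrom = chrom, pos = pos,
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se,
    pval = if (!is.null(pval)) pval else if (se > 0) {
      ketomr::wald_pvalue(beta, se)
    } else NA_real_,
    n = n
  )
}

tiny_dataset <- function(rows, trait_name = "trait") {
  ketomr::gwas_dataset(dplyr::bind_rows(rows), trait_name = trait_name)
}

# A hand-built noise-free bundle emulating a canonical verdict table for five reference regions:
# one variant per gene region (two for OXCT1), exact p-values, identity LD.
# Expected patterns: CYP2E1 acetone-only; SLC2A4 blood-pressure pleiotropy
# but control association; HMGCS2 clean but no control association; OXCT1
# all four premises; LPL biologically irrelevant.
table_fixture_bundle <- function() {
  genes <- tibble::tibble(
    gene_symbol = c("CYP2E1", "SLC2A4", "HMGCS2", "OXCT1", "LPL"),
    chrom = c("10", "17", "1", "5", "8"),
    start = 1000000, end = 1010000
  )
  v <- function(id, chrom, pos, beta, se = 0.005) {
    assoc_row(id, chrom = chrom, pos = pos, beta = beta, se = se)
  }
  # Strong acetone association everywhere (p << 5e-8).
  acetone_rows <- list(
    v("rs_cyp", "10", 1005000, 0.10),
    v("rs_slc", "17", 1005000, 0.11),
    v("rs_hmg", "1", 1005000, 0.09),
    v("rs_oxc1", "5", 1005000, 0.12),
    v("rs_oxc2", "5", 1006000, 0.08),
    v("rs_lpl", "8", 1005000, 0.10)
  )
  acetone <- tiny_dataset(acetone_rows, "acetone")
  # Other ketone bodies: CYP2E1 null (p > 0.05), everything else strong.
  other_rows <- lapply(acetone_rows, function(r) {
    r$beta <- if (r$variant_id == "rs_cyp") 0.001 else 0.8 * r$beta
    r$pval <- ketomr::wald_pvalue(r$beta, r$se)
    r
  })
  acetoacetate <- tiny_dataset(other_rows, "acetoacetate")
  bhb <- tiny_dataset(other_rows, "beta_hydroxybutyrate")
  # Control: association for SLC2A4 and OXCT1 instruments, null for the
  # others (HMGCS2 in particular).
  ctrl_beta <- function(id) {
    if (id %in% c("rs_slc", "rs_oxc1", "rs_oxc2")) 0.05 else 0.0001
  }
  ctrl_rows <- lapply(acetone_rows, function(r) {
    r$beta <- ctrl_beta(r$variant_id)
    r$se <- 0.01
    r$pval <- ketomr::wald_pvalue(r$beta, r$se)
    r
  })
  control <- tiny_dataset(ctrl_rows, "cognitive_performance")
  ld <- lapply(stats::setNames(genes$gene_symbol, genes$gene_symbol),
               function(g) {
    ids <- switch(g,
      CYP2E1 = "rs_cyp", SLC2A4 = "rs_slc", HMGCS2 = "rs_hmg",
      OXCT1 = c("rs_oxc1", "rs_oxc2"), LPL = "rs_lpl"
    )
    ketomr::ld_matrix(diag(length(ids)), ids)
  })
  catalogue <- tibble::tibble(
    variant_id = c(NA_character_, NA_character_),
    gene_symbol = c("SLC2A4", "OXCT1"),
    trait = c("systolic blood pressure", "weak trait"),
    pval = c(1e-12, 1e-6)
  )
  list(
    discovery = list(karjalainen = acetone),
    ketones = list(acetone = acetone, acetoacetate = acetoacetate,
                   beta_hydroxybutyrate = bhb),
    controls = list(cognitive_performance = control),
    annotation = genes,
    ld = ld,
    catalogue = catalogue
  )
}

# Compare a premise matrix against a scenario truth table; TRUE when every
# discovered region matches its expected pattern in every source and no
# undiscovered region appears.
matrix_matches_truth <- function(pm, truth) {
  pm <- tibble::as_tibble(pm)
  for (i in seq_len(nrow(truth))) {
    g <- truth$gene_symbol[i]
    rows <- pm[pm$gene_symbol == g, ]
    if (!truth$discovered[i]) {
      if (nrow(rows) > 0) return(FALSE)
      next
    }
    if (nrow(rows) != length(unique(pm$source))) return(FALSE)
    if (!all(rows$pattern == truth$pattern[i])) return(FALSE)
  }
  extra <- setdiff(pm$gene_symbol, truth$gene_symbol)
  length(extra) == 0
}
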