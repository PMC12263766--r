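# Synthetic GWAS-summary-statistic bundles with known truth.
#
# The generator emulates the statistical structure of the real data
# sources: two acetone discovery GWAS with independent noise (a
# Karjalainen-style meta-analysis and a UK-Biobank-style study), three
# correlated ketone-body traits sharing regional genetics through trait
# loadings, control-outcome GWAS from non-overlapping samples, AR(1) LD
# with LD-correlated estimation noise, scrambled allele encodings between
# studies, and per-region archetypes engineered to fail exactly one
# validity premise.
#
# Model: true per-allele joint exposure effects gamma_j ~ N(0, tau^2) on
# causal variants, else 0. Marginal (GWAS-scale) effects are R %*% gamma,
# propagating signal to LD partners as for standardized genotypes. Ketone
# trait k has marginal effect lambda_k * (R gamma); a control has
# beta_c * (R gamma) + R alpha, with alpha the direct (horizontally
# pleiotropic) outcome effect. Observed estimates are multivariate normal
# around the marginal effects with per-variant SE 1/sqrt(2 f (1-f) n) and
# cross-variant noise correlation equal to the LD r (shared estimation
# sample). Pleiotropic alpha is drawn relative to the exposure-increasing
# allele (alpha_j = sign(gamma_j) * N(mu, sigma^2)), the frame in which
# directional pleiotropy is defined.

.archetypes <- c("valid", "no_biology", "inconsistent", "pleiotropic", "null")

#' Default archetype regions
#'
#' Five gene regions, each an archetype: OXCT1 (valid instrument region),
#' LPL (associated but biologically irrelevant), CYP2E1 (acetone-only
#' signal), SLC2A4 (ketone-consistent but horizontally pleiotropic via
#' blood pressure), GALNT2 (no signal at all). Causal-variant counts mirror
#' the reported instrument sets: several independent signals at OXCT1, a
#' single signal at SLC2A4. A single causal variant in the pleiotropic
#' region also keeps its direct outcome effect proportional across LD
#' partners, which is what lets a single-signal pleiotropic locus show a
#' clean (if confounded) control association.
#'
#' @return Tibble with `gene_symbol`, `archetype`, `chrom`, `n_variants`,
#'   `n_causal`.
#' @export
ketone_archetype_regions <- function() {
  tibble(
    gene_symbol = c("OXCT1", "LPL", "CYP2E1", "SLC2A4", "GALNT2"),
    archetype = c("valid", "no_biology", "inconsistent", "pleiotropic",
                  "null"),
    chrom = c("5", "8", "10", "17", "1"),
    n_variants = 20L,
    n_causal = c(4L, 3L, 3L, 1L, 0L)
  )
}

#' Synthetic scenario
#'
#' Study conditions for [generate_bundle()]. Defaults emulate the real data
#' sources: sample sizes of the published acetone, acetoacetate,
#' beta-hydroxybutyrate, cognitive-performance, two-hour-glucose and
#' insulin-fold-change GWAS; lead-variant effect sizes typical of NMR
#' metabolite loci (`tau = 0.1` SD per allele); strongly correlated ketone
#' measures (loadings 1 / 0.9 / 0.8); and control effects with the
#' directions reported for ketone supplementation (better cognition, lower
#' two-hour glucose and insulin response).
#'
#' @param regions Tibble with `gene_symbol`, `archetype` (one of `valid`,
#'   `no_biology`, `inconsistent`, `pleiotropic`, `null`), `chrom`,
#'   `n_variants`, `n_causal`.
#' @param tau SD of true per-allele joint exposure effects (trait SD units).
#' @param gamma_floor Smallest admissible causal effect magnitude; causal
#'   effects are drawn from N(0, tau^2) truncated to `|gamma| >=
#'   gamma_floor`. Non-null archetype regions represent loci that were
#'   discovered in the source GWAS, so their effects must be detectable
#'   there (0.03 SD per allele is the genome-wide-significance
#'   detectability floor at the published ketone GWAS sample sizes);
#'   undetectable loci are represented by the `null` archetype. Set to 0
#'   for an untruncated draw.
#' @param lambda Named loadings of the three ketone bodies on the shared
#'   regional genetics (acetone first; it is the instrumented exposure).
#' @param beta_controls Named true causal effects of the exposure on each
#'   control outcome.
#' @param mu_alpha,sigma_alpha Mean and SD of the direct outcome effect per
#'   causal variant in pleiotropic regions (exposure-increasing-allele
#'   frame).
#' @param rho AR(1) LD decay parameter, in `[0, 1)`.
#' @param eaf_range Effect-allele-frequency range (uniform draw).
#' @param n_karjalainen Sample size of the meta-analysis-style acetone
#'   discovery GWAS.
#' @param n_ketones Named sample sizes of the three UK-Biobank-style ketone
#'   GWAS (the acetone one doubles as the second discovery study).
#' @param n_controls Named sample sizes of the control-outcome GWAS; names
#'   must match `beta_controls`.
#' @param prob_palindromic Fraction of variants given palindromic (A/T or
#'   C/G) allele pairs.
#' @param prob_swap,prob_strand_flip Per-variant probabilities that a
#'   non-reference study encodes the variant with swapped alleles /
#'   opposite strand.
#' @return A list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    regions = ketone_archetype_regions(),
    tau = 0.1,
    gamma_floor = 0.03,
    lambda = c(acetone = 1, acetoacetate = 0.9, beta_hydroxybutyrate = 0.8),
    beta_controls = c(cognitive_performance = 0.10,
                      two_hour_glucose = -0.20,
                      insulin_fold_change = -0.15),
    mu_alpha = 0.05,
    sigma_alpha = 0.01,
    rho = 0.6,
    eaf_range = c(0.1, 0.9),
    n_karjalainen = 130311,
    n_ketones = c(acetone = 115075, acetoacetate = 115075,
                  beta_hydroxybutyrate = 113595),
    n_controls = c(cognitive_performance = 257828,
                   two_hour_glucose = 63396,
                   insulin_fold_change = 53334),
    prob_palindromic = 0.15,
    prob_swap = 0.3,
    prob_strand_flip = 0.1) {
  regions <- as_tibble(regions)
  stopifnot(all(c("gene_symbol", "archetype", "chrom", "n_variants",
                  "n_causal") %in% names(regions)))
  if (!all(regions$archetype %in% .archetypes)) {
    abort_domain(paste0(
      "unknown archetype(s): ",
      paste(setdiff(regions$archetype, .archetypes), collapse = ", ")
    ))
  }
  if (any(regions$n_causal > regions$n_variants)) {
    abort_domain("n_causal must not exceed n_variants")
  }
  if (any(regions$archetype != "null" & regions$n_causal < 1)) {
    abort_domain("non-null archetypes need n_causal >= 1")
  }
  if (tau <= 0) abort_domain("tau must be positive")
  if (gamma_floor < 0) abort_domain("gamma_floor must be non-negative")
  if (rho < 0 || rho >= 1) abort_domain("rho must lie in [0, 1)")
  stopifnot(
    length(lambda) == 3, !is.null(names(lambda)),
    identical(sort(names(beta_controls)), sort(names(n_controls))),
    length(n_ketones) == 3,
    eaf_range[1] > 0, eaf_range[2] < 1, eaf_range[1] <= eaf_range[2]
  )
  structure(
    list(
      regions = regions, tau = tau, gamma_floor = gamma_floor,
      lambda = lambda,
      beta_controls = beta_controls, mu_alpha = mu_alpha,
      sigma_alpha = sigma_alpha, rho = rho, eaf_range = eaf_range,
      n_karjalainen = n_karjalainen, n_ketones = n_ketones,
      n_controls = n_controls, prob_palindromic = prob_palindromic,
      prob_swap = prob_swap, prob_strand_flip = prob_strand_flip
    ),
    class = "synthetic_scenario"
  )
}

#' AR(1) LD matrix
#'
#' `r(j, k) = rho^|j - k|`, positive definite by construction for
#' `rho` in `[0, 1)`.
#'
#' @param n_variants Matrix dimension.
#' @param rho Decay parameter in `[0, 1)`.
#' @param variant_ids Optional ids (defaults to `v1..vn`).
#' @return An [ld_matrix()].
#' @export
generate_ld_matrix <- function(n_variants, rho,
                               variant_ids = paste0("v", seq_len(n_variants))) {
  if (rho < 0 || rho >= 1) {
    abort_domain("rho must lie in [0, 1)")
  }
  idx <- seq_len(n_variants)
  r <- rho^abs(outer(idx, idx, "-"))
  ld_matrix(r, variant_ids)
}

#' Expected premise outcomes for a scenario
#'
#' The archetype-to-verdict mapping: `valid` passes all four premises;
#' `no_biology` fails premise 1 (2-4 not evaluated); `inconsistent` fails
#' premise 2 (3-4 not evaluated); `pleiotropic` fails premise 3 while its
#' strong direct outcome effect makes premise 4 pass; `null` regions are
#' never discovered.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Tibble with `gene_symbol`, `archetype`, `discovered` and the
#'   four expected premise statuses plus the rendered `pattern` (`NA` for
#'   undiscovered regions).
#' @export
scenario_truth <- function(scenario) {
  map_row <- function(archetype) {
    switch(archetype,
      valid = c("pass", "pass", "pass", "pass"),
      no_biology = c("fail", "not_evaluated", "not_evaluated",
                     "not_evaluated"),
      inconsistent = c("pass", "fail", "not_evaluated", "not_evaluated"),
      pleiotropic = c("pass", "pass", "fail", "pass"),
      null = rep(NA_character_, 4)
    )
  }
  rows <- map(seq_len(nrow(scenario$regions)), function(i) {
    a <- scenario$regions$archetype[i]
    s <- map_row(a)
    tibble(
      gene_symbol = scenario$regions$gene_symbol[i],
      archetype = a,
      discovered = a != "null",
      biological = s[1], consistent = s[2], no_pleiotropy = s[3],
      positive_control = s[4],
      pattern = if (a == "null") NA_character_ else {
        paste(status_symbol(s), collapse = "")
      }
    )
  })
  list_rbind(rows)
}

# Magnitude-truncated normal: |x| >= floor, sign symmetric, scale tau.
# Inverse-CDF draw on the half-normal tail.
rtruncnorm_mag <- function(n, tau, floor) {
  v0 <- 2 * pnorm(floor / tau) - 1
  mag <- tau * qnorm((1 + runif(n, v0, 1)) / 2)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

.palindromic_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
.nonpalindromic_pairs <- list(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)

#' Generate a synthetic GWAS bundle with known truth
#'
#' Draws one realization of the scenario: per-region effects, per-study
#' observed summary statistics, allele encodings, an annotation, per-region
#' LD matrices, and a trait-association catalogue in which pleiotropic
#' regions carry a genome-wide-significant blood-pressure record. The two
#' acetone discovery studies share the true effects but have independent
#' estimation noise; the UK-Biobank-style acetone dataset serves as both
#' the second discovery study and the agnostic exposure. Bit-for-bit
#' reproducible given the seed (the global RNG state is untouched).
#'
#' @param scenario A [synthetic_scenario()].
#' @param seed Integer seed.
#' @return A list with `bundle` (components `discovery`, `ketones`,
#'   `controls`, `annotation`, `ld`, `catalogue`, ready for
#'   [run_biological_pipeline()]), `truth` (the [scenario_truth()] table
#'   with per-region causal variant ids attached) and `scenario`.
#' @export
generate_bundle <- function(scenario = synthetic_scenario(), seed = 1L) {
  withr::with_seed(seed, generate_bundle_impl(scenario))
}

generate_bundle_impl <- function(scenario) {
  regions <- scenario$regions
  ctrl_names <- names(scenario$n_controls)
  study_names <- c("karjalainen_acetone", "borges_acetone", "acetoacetate",
                   "beta_hydroxybutyrate", ctrl_names)
  study_n <- c(
    scenario$n_karjalainen,
    scenario$n_ketones[["acetone"]],
    scenario$n_ketones[["acetoacetate"]],
    scenario$n_ketones[["beta_hydroxybutyrate"]],
    unname(scenario$n_controls[ctrl_names])
  )
  per_study <- setNames(
    map(study_names, function(nm) list()), study_names
  )
  ld_list <- list()
  catalogue <- list()
  causal_ids <- list()

  for (i in seq_len(nrow(regions))) {
    gene <- regions$gene_symbol[i]
    archetype <- regions$archetype[i]
    n_v <- regions$n_variants[i]
    n_c <- regions$n_causal[i]
    gene_start <- 1000000
    gene_end <- 1050000
    pos <- sort(sample((gene_start - 150000):(gene_end + 150000), n_v))
    ids <- sprintf("rs%d", i * 100000 + seq_len(n_v))
    f <- runif(n_v, scenario$eaf_range[1], scenario$eaf_range[2])
    ld <- generate_ld_matrix(n_v, scenario$rho, ids)
    r <- unclass(ld)
    chol_u <- chol(r)

    gamma <- numeric(n_v)
    alpha <- numeric(n_v)
    if (archetype != "null" && n_c > 0) {
      causal <- sort(sample.int(n_v, n_c))
      gamma[causal] <- rtruncnorm_mag(n_c, scenario$tau,
                                      scenario$gamma_floor)
      if (archetype == "pleiotropic") {
        alpha[causal] <- sign(gamma[causal]) *
          rnorm(n_c, scenario$mu_alpha, scenario$sigma_alpha)
      }
      causal_ids[[gene]] <- ids[causal]
    } else {
      causal_ids[[gene]] <- character(0)
    }
    m <- drop(r %*% gamma)
    m_alpha <- drop(r %*% alpha)

    mean_for <- function(study) {
      if (archetype == "null") return(numeric(n_v))
      if (study %in% c("karjalainen_acetone", "borges_acetone")) {
        return(scenario$lambda[["acetone"]] * m)
      }
      if (study == "acetoacetate") {
        if (archetype == "inconsistent") return(numeric(n_v))
        return(scenario$lambda[["acetoacetate"]] * m)
      }
      if (study == "beta_hydroxybutyrate") {
        if (archetype == "inconsistent") return(numeric(n_v))
        return(scenario$lambda[["beta_hydroxybutyrate"]] * m)
      }
      scenario$beta_controls[[study]] * m + m_alpha
    }

    base_pairs <- map(seq_len(n_v), function(j) {
      if (runif(1) < scenario$prob_palindromic) {
        .palindromic_pairs[[sample.int(4L, 1L)]]
      } else {
        .nonpalindromic_pairs[[sample.int(8L, 1L)]]
      }
    })
    a1 <- map_chr(base_pairs, 1)
    a2 <- map_chr(base_pairs, 2)

    for (s in seq_along(study_names)) {
      study <- study_names[s]
      n_sample <- study_n[s]
      se <- 1 / sqrt(2 * f * (1 - f) * n_sample)
      noise <- drop(crossprod(chol_u, rnorm(n_v)))
      beta_hat <- mean_for(study) + se * noise
      ea <- a1
      oa <- a2
      eaf <- f
      if (s > 1L) {
        strand <- runif(n_v) < scenario$prob_strand_flip
        ea[strand] <- .complement(ea[strand])
        oa[strand] <- .complement(oa[strand])
        swap <- runif(n_v) < scenario$prob_swap
        tmp <- ea[swap]
        ea[swap] <- oa[swap]
        oa[swap] <- tmp
        beta_hat[swap] <- -beta_hat[swap]
        eaf[swap] <- 1 - eaf[swap]
      }
      per_study[[study]][[i]] <- tibble(
        variant_id = ids,
        chrom = regions$chrom[i],
        pos = pos,
        effect_allele = ea,
        other_allele = oa,
        eaf = eaf,
        beta = beta_hat,
        se = se,
        pval = wald_pvalue(beta_hat, se),
        n = n_sample
      )
    }

    ld_list[[gene]] <- ld
    if (archetype == "pleiotropic") {
      top <- causal[which.max(abs(gamma[causal]))]
      catalogue[[length(catalogue) + 1L]] <- tibble(
        variant_id = ids[top], gene_symbol = gene,
        trait = "systolic blood pressure", pval = 1e-12
      )
    }
    if (archetype == "valid") {
      catalogue[[length(catalogue) + 1L]] <- tibble(
        variant_id = NA_character_, gene_symbol = gene,
        trait = "serum metabolite ratio", pval = 1e-6
      )
    }
  }

  make_ds <- function(study, trait_name, ancestry) {
    gwas_dataset(
      list_rbind(per_study[[study]]),
      trait_name = trait_name, trait_units = "SD units", ancestry = ancestry
    )
  }
  karjalainen <- make_ds("karjalainen_acetone", "acetone (Karjalainen-style)",
                         "mixed")
  borges_acetone <- make_ds("borges_acetone", "acetone (UKB-style)",
                            "European")
  ketones <- list(
    acetone = borges_acetone,
    acetoacetate = make_ds("acetoacetate", "acetoacetate", "European"),
    beta_hydroxybutyrate = make_ds("beta_hydroxybutyrate",
                                   "beta-hydroxybutyrate", "European")
  )
  controls <- setNames(
    map(ctrl_names, function(nm) make_ds(nm, nm, "European")), ctrl_names
  )
  annotation <- tibble(
    gene_symbol = regions$gene_symbol,
    chrom = regions$chrom,
    start = 1000000,
    end = 1050000
  )
  truth <- scenario_truth(scenario)
  truth$causal_ids <- unname(causal_ids[truth$gene_symbol])

  list(
    bundle = list(
      discovery = list(karjalainen = karjalainen, borges = borges_acetone),
      ketones = ketones,
      controls = controls,
      annotation = annotation,
      ld = ld_list,
      catalogue = list_rbind(c(
        list(tibble(variant_id = character(0), gene_symbol = character(0),
                    trait = character(0), pval = numeric(0))),
        catalogue
      ))
    ),
    truth = truth,
    scenario = scenario
  )
}

#' Write a bundle to a directory of plain-text files
#'
#' Emits every dataset as a tab-delimited summary-statistics file, the
#' annotation as BED, per-gene LD matrices, the catalogue, an optional
#' truth table, and a `manifest.tsv` tying them together for
#' [read_bundle()].
#'
#' @param bundle A bundle as produced by [generate_bundle()]`$bundle`.
#' @param dir Output directory (created if needed).
#' @param truth Optional truth tibble, written as `truth.tsv` (list columns
#'   are flattened to comma-separated strings).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(ds, role, name) {
    file <- paste0(role, "_", name, ".tsv")
    write_gwas_table(ds, file.path(dir, file))
    info <- trait_info(ds)
    manifest[[length(manifest) + 1L]] <<- tibble(
      role = role, name = name, trait_name = info$trait_name,
      trait_units = info$trait_units, ancestry = info$ancestry, file = file
    )
  }
  for (nm in names(bundle$discovery)) emit(bundle$discovery[[nm]],
                                           "discovery", nm)
  for (nm in names(bundle$ketones)) emit(bundle$ketones[[nm]], "ketone", nm)
  for (nm in names(bundle$controls)) emit(bundle$controls[[nm]], "control", nm)
  write_gene_annotation(bundle$annotation, file.path(dir, "annotation.bed"))
  for (gene in names(bundle$ld)) {
    write_ld_matrix(bundle$ld[[gene]], file.path(dir, paste0("ld_", gene,
                                                             ".tsv")))
  }
  write_trait_catalogue(bundle$catalogue, file.path(dir, "catalogue.tsv"))
  if (!is.null(truth)) {
    flat <- truth
    if (!is.null(flat$causal_ids)) {
      flat$causal_ids <- map_chr(flat$causal_ids, paste, collapse = ",")
    }
    readr::write_tsv(flat, file.path(dir, "truth.tsv"), progress = FALSE)
  }
  readr::write_tsv(list_rbind(manifest), file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#'
#' @param dir Bundle directory containing `manifest.tsv`.
#' @return A bundle list with the same components as
#'   [generate_bundle()]`$bundle`.
#' @export
read_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest_path)) {
    abort_config(paste0("no manifest.tsv in ", dir))
  }
  manifest <- readr::read_tsv(manifest_path, show_col_types = FALSE,
                              progress = FALSE)
  load_role <- function(role) {
    part <- manifest[manifest$role == role, ]
    setNames(
      map(seq_len(nrow(part)), function(i) {
        read_gwas_table(
          file.path(dir, part$file[i]),
          trait_name = part$trait_name[i],
          trait_units = part$trait_units[i],
          ancestry = part$ancestry[i]
        )
      }),
      part$name
    )
  }
  ld_files <- list.files(dir, pattern = "^ld_.*\\.tsv$")
  ld <- setNames(
    map(ld_files, function(fl) read_ld_matrix(file.path(dir, fl))),
    sub("^ld_(.*)\\.tsv$", "\\1", ld_files)
  )
  list(
    discovery = load_role("discovery"),
    ketones = load_role("ketone"),
    controls = load_role("control"),
    annotation = read_gene_annotation(file.path(dir, "annotation.bed")),
    ld = ld,
    catalogue = read_trait_catalogue(file.path(dir, "catalogue.tsv"))
  )
}
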