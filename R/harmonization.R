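# Effect-allele harmonization for two-sample MR.
#
# Exposure and outcome association records for the same variant may encode
# the effect allele differently: same alleles, swapped alleles, opposite
# strand, or both. Harmonization places the outcome association on the
# exposure's effect-allele frame. Palindromic variants (A/T, C/G) cannot be
# resolved from allele labels alone; orientation is inferred from allele
# frequencies when both are available and informative, otherwise the
# variant is dropped.

.complement <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(a1, a2) {
  nchar(a1) == 1 & nchar(a2) == 1 & a2 == .complement(a1)
}

#' Harmonization policy
#'
#' @param palindromic How to treat palindromic variants: `"infer"` (default)
#'   keeps them when both EAFs are present and outside the ambiguity window,
#'   inferring orientation from frequency agreement; `"drop"` always drops
#'   them.
#' @param ambiguity_window Closed EAF interval within which frequency gives
#'   no usable orientation signal. Default `c(0.42, 0.58)`, a common
#'   conservative choice.
#' @return A list of class `harmonization_policy`.
#' @export
harmonization_policy <- function(palindromic = c("infer", "drop"),
                                 ambiguity_window = c(0.42, 0.58)) {
  palindromic <- match.arg(palindromic)
  stopifnot(length(ambiguity_window) == 2, ambiguity_window[1] <= ambiguity_window[2])
  structure(
    list(palindromic = palindromic, ambiguity_window = ambiguity_window),
    class = "harmonization_policy"
  )
}

# Resolve one variant's allele configuration.
# Returns list(action, flip (logical: outcome beta sign flips),
#              strand (logical), reason).
resolve_alleles <- function(e1, e2, o1, o2, eaf_x, eaf_y, policy) {
  out <- function(action, flip = FALSE, strand = FALSE, reason = NA_character_) {
    list(action = action, flip = flip, strand = strand, reason = reason)
  }
  indel <- nchar(e1) > 1 || nchar(e2) > 1 || nchar(o1) > 1 || nchar(o2) > 1
  if (indel) {
    # Indel alleles are compared literally; no strand complement attempted.
    if (o1 == e1 && o2 == e2) return(out("kept"))
    if (o1 == e2 && o2 == e1) return(out("flipped", flip = TRUE))
    return(out("dropped", reason = "allele_mismatch"))
  }
  if (is_palindromic(e1, e2)) {
    if (!(o1 %in% c(e1, e2)) || !(o2 %in% c(e1, e2)) || o1 == o2) {
      return(out("dropped", reason = "allele_mismatch"))
    }
    if (policy$palindromic == "drop") {
      return(out("dropped", reason = "palindromic_ambiguous"))
    }
    # Nominal alignment by label, then frequency check: for a palindromic
    # pair, a strand flip is indistinguishable from an allele swap by label.
    flip <- o1 != e1
    eafy <- if (flip) 1 - eaf_y else eaf_y
    w <- policy$ambiguity_window
    ambiguous <- function(f) is.na(f) || (f >= w[1] && f <= w[2])
    if (ambiguous(eaf_x) || ambiguous(eafy)) {
      return(out("dropped", reason = "palindromic_ambiguous"))
    }
    if ((eaf_x < 0.5) != (eafy < 0.5)) flip <- !flip
    return(out(if (flip) "flipped" else "kept", flip = flip))
  }
  c1 <- .complement(e1)
  c2 <- .complement(e2)
  if (o1 == e1 && o2 == e2) return(out("kept"))
  if (o1 == e2 && o2 == e1) return(out("flipped", flip = TRUE))
  if (o1 == c1 && o2 == c2) return(out("strand_flipped", strand = TRUE))
  if (o1 == c2 && o2 == c1) return(out("flipped", flip = TRUE, strand = TRUE))
  out("dropped", reason = "allele_mismatch")
}

#' Harmonize one exposure/outcome variant pair
#'
#' Places the outcome association on the exposure's effect-allele frame.
#' Standard errors are never changed; a sign flip negates the outcome beta
#' and reflects the outcome EAF.
#'
#' @param exposure,outcome One-row data frames (or lists) with fields
#'   `variant_id`, `effect_allele`, `other_allele`, `beta`, `se` and
#'   optionally `eaf`; both must describe the same `variant_id`.
#' @param policy A [harmonization_policy()].
#' @return One-row tibble with `variant_id`, exposure and outcome
#'   beta/se/eaf on the common frame, `action` (one of `kept`, `flipped`,
#'   `strand_flipped`, `dropped`) and `drop_reason` (`NA` unless dropped).
#' @export
harmonize_variant <- function(exposure, outcome,
                              policy = harmonization_policy()) {
  if (exposure$variant_id != outcome$variant_id) {
    abort_usage("exposure and outcome rows describe different variants")
  }
  eaf_x <- if (!is.null(exposure$eaf)) exposure$eaf else NA_real_
  eaf_y <- if (!is.null(outcome$eaf)) outcome$eaf else NA_real_
  res <- resolve_alleles(
    exposure$effect_allele, exposure$other_allele,
    outcome$effect_allele, outcome$other_allele,
    eaf_x, eaf_y, policy
  )
  dropped <- res$action == "dropped"
  tibble(
    variant_id = exposure$variant_id,
    effect_allele = exposure$effect_allele,
    other_allele = exposure$other_allele,
    exposure_beta = exposure$beta,
    exposure_se = exposure$se,
    exposure_eaf = eaf_x,
    outcome_beta = if (dropped) NA_real_ else {
      if (res$flip) -outcome$beta else outcome$beta
    },
    outcome_se = if (dropped) NA_real_ else outcome$se,
    outcome_eaf = if (dropped) NA_real_ else {
      if (res$flip) 1 - eaf_y else eaf_y
    },
    action = res$action,
    drop_reason = res$reason
  )
}

#' Harmonize an instrument set across two GWAS datasets
#'
#' For each requested variant, pairs the exposure and outcome associations
#' and reconciles their allele frames. Variants absent from the outcome (or
#' exposure) dataset, with irreconcilable alleles, or palindromic without
#' usable frequency information are dropped; every requested id is accounted
#' for either in the kept set or the drop log.
#'
#' @param exposure,outcome `gwas_dataset` objects.
#' @param variant_ids Character vector of instrument variant ids (non-empty).
#' @param policy A [harmonization_policy()].
#' @return A tibble of class `harmonized_set` with the kept pairs ordered by
#'   (chrom, pos): `variant_id`, `chrom`, `pos`, alleles on the exposure
#'   frame, `exposure_beta`, `exposure_se`, `exposure_eaf`, `outcome_beta`,
#'   `outcome_se`, `outcome_eaf`, `action`. Attributes: `drop_log` (tibble
#'   of `variant_id`, `reason`), `exposure_trait`, `outcome_trait`.
#' @export
harmonize_set <- function(exposure, outcome, variant_ids,
                          policy = harmonization_policy()) {
  if (length(variant_ids) == 0) {
    abort_usage("variant_ids must be non-empty")
  }
  if (anyDuplicated(variant_ids)) {
    abort_usage("variant_ids must be unique")
  }
  ex <- as_tibble(exposure)
  ox <- as_tibble(outcome)
  ex_idx <- match(variant_ids, ex$variant_id)
  ox_idx <- match(variant_ids, ox$variant_id)

  rows <- vector("list", length(variant_ids))
  drops <- list()
  for (i in seq_along(variant_ids)) {
    id <- variant_ids[i]
    if (is.na(ex_idx[i])) {
      drops[[length(drops) + 1L]] <- tibble(variant_id = id,
                                            reason = "missing_in_exposure")
      next
    }
    if (is.na(ox_idx[i])) {
      drops[[length(drops) + 1L]] <- tibble(variant_id = id,
                                            reason = "missing_in_outcome")
      next
    }
    e <- ex[ex_idx[i], ]
    o <- ox[ox_idx[i], ]
    h <- harmonize_variant(e, o, policy)
    if (h$action == "dropped") {
      drops[[length(drops) + 1L]] <- tibble(variant_id = id,
                                            reason = h$drop_reason)
      next
    }
    h$chrom <- e$chrom
    h$pos <- e$pos
    rows[[i]] <- h
  }
  kept <- list_rbind(compact(rows))
  if (nrow(kept) > 0) {
    kept <- arrange(
      select(kept, "variant_id", "chrom", "pos", "effect_allele",
             "other_allele", "exposure_beta", "exposure_se", "exposure_eaf",
             "outcome_beta", "outcome_se", "outcome_eaf", "action"),
      .data$chrom, .data$pos, .data$variant_id
    )
  } else {
    kept <- tibble(
      variant_id = character(0), chrom = character(0), pos = numeric(0),
      effect_allele = character(0), other_allele = character(0),
      exposure_beta = numeric(0), exposure_se = numeric(0),
      exposure_eaf = numeric(0), outcome_beta = numeric(0),
      outcome_se = numeric(0), outcome_eaf = numeric(0), action = character(0)
    )
  }
  structure(
    kept,
    drop_log = list_rbind(c(
      list(tibble(variant_id = character(0), reason = character(0))), drops
    )),
    exposure_trait = attr(exposure, "trait_name", exact = TRUE) %||% "exposure",
    outcome_trait = attr(outcome, "trait_name", exact = TRUE) %||% "outcome",
    class = c("harmonized_set", class(tibble()))
  )
}

#' Drop log of a harmonized instrument set
#' @param x A `harmonized_set`.
#' @return Tibble with `variant_id`, `reason`, one row per dropped variant.
#' @export
drop_log <- function(x) {
  attr(x, "drop_log", exact = TRUE) %||%
    tibble(variant_id = character(0), reason = character(0))
}

#' Write a harmonization drop log
#' @param x A `harmonized_set`.
#' @param path Output path (tab-delimited `variant_id`, `reason`).
#' @return `path`, invisibly.
#' @export
write_drop_log <- function(x, path) {
  readr::write_tsv(drop_log(x), path, progress = FALSE)
  invisible(path)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf(
    "<harmonized_set> %s -> %s: %d kept, %d dropped\n",
    attr(x, "exposure_trait"), attr(x, "outcome_trait"),
    nrow(x), nrow(drop_log(x))
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
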