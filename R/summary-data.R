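# GWAS summary-statistic containers and file adapters.
#
# A "gwas_dataset" is a tibble of per-variant association records for one
# trait (one row per variant: alleles, effect size, SE, p-value, EAF, N)
# carrying the trait's metadata as attributes. All betas are per copy of the
# effect allele; for NMR metabolite GWAS the trait is in SD units.

.canonical_columns <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

#' Construct a GWAS summary-statistics dataset
#'
#' Validates a data frame of per-variant association statistics and attaches
#' trait metadata. Rows violating the per-variant invariants (non-positive
#' SE, p-value outside (0, 1], EAF outside (0, 1), malformed or identical
#' alleles) are rejected with row-numbered diagnostics; missing p-values are
#' filled in from `beta`/`se` via [wald_pvalue()], and missing SEs from
#' `beta`/`pval`.
#'
#' @param x Data frame with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta` and at least one of `se`, `pval`; optionally
#'   `chrom`, `pos`, `eaf`, `n`.
#' @param trait_name,trait_units,ancestry Trait metadata stored as
#'   attributes.
#' @param strict If `TRUE`, any invalid row aborts instead of being dropped.
#' @return A tibble of class `gwas_dataset`, one row per valid variant,
#'   ordered as given, with attributes `trait_name`, `trait_units`,
#'   `ancestry` and `rejected` (a tibble of dropped rows with reasons).
#' @export
gwas_dataset <- function(x, trait_name = "trait", trait_units = "SD units",
                         ancestry = NA_character_, strict = FALSE) {
  x <- as_tibble(x)
  required <- c("variant_id", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort_config(paste0(
      "missing required column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (!any(c("se", "pval") %in% names(x))) {
    abort_config("need at least one of columns 'se' or 'pval'")
  }
  for (col in setdiff(.canonical_columns, names(x))) {
    x[[col]] <- if (col %in% c("variant_id", "chrom", "effect_allele",
                               "other_allele")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  x <- x[, .canonical_columns]
  x$variant_id <- as.character(x$variant_id)
  x$chrom <- as.character(x$chrom)
  x$effect_allele <- toupper(as.character(x$effect_allele))
  x$other_allele <- toupper(as.character(x$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    x[[col]] <- as.numeric(x[[col]])
  }

  # Fill the derivable column before validation: p from beta/se when absent,
  # se from beta/p when absent. Stored p-values are kept as given.
  derive_p <- is.na(x$pval) & !is.na(x$se) & x$se > 0 & !is.na(x$beta)
  x$pval[derive_p] <- wald_pvalue(x$beta[derive_p], x$se[derive_p])
  derive_se <- is.na(x$se) & !is.na(x$pval) & x$pval > 0 & x$pval <= 1 &
    !is.na(x$beta) & x$beta != 0
  x$se[derive_se] <- abs(x$beta[derive_se] / qnorm(x$pval[derive_se] / 2))

  reason <- association_problems(x)
  bad <- !is.na(reason)
  if (any(bad)) {
    rejected <- mutate(x[bad, ], row = which(bad), reason = reason[bad])
    if (strict) {
      abort_data(paste0(
        "invalid association row(s): ",
        paste0("row ", rejected$row, " (", rejected$reason, ")",
               collapse = "; ")
      ))
    }
    warn(paste0(
      "dropped ", sum(bad), " invalid association row(s): ",
      paste0("row ", head(rejected$row, 5L), " (",
             head(rejected$reason, 5L), ")", collapse = "; "),
      if (sum(bad) > 5L) " ..." else ""
    ))
    x <- x[!bad, ]
  } else {
    rejected <- mutate(x[0, ], row = integer(0), reason = character(0))
  }

  dup <- unique(x$variant_id[duplicated(x$variant_id)])
  if (length(dup) > 0) {
    abort_data(paste0(
      "duplicate variant_id: ", paste(head(dup, 5L), collapse = ", ")
    ))
  }

  structure(
    x,
    trait_name = trait_name,
    trait_units = trait_units,
    ancestry = ancestry,
    rejected = rejected,
    class = c("gwas_dataset", class(tibble()))
  )
}

# Vector of per-row failure reasons (NA where the row is valid).
association_problems <- function(x) {
  reason <- rep(NA_character_, nrow(x))
  flag <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, why, reason)
  }
  allele_ok <- function(a) !is.na(a) & nchar(a) >= 1 & grepl("^[ACGT]+$", a)
  reason <- flag(is.na(x$variant_id) | x$variant_id == "", "missing_variant_id")
  reason <- flag(!allele_ok(x$effect_allele) | !allele_ok(x$other_allele),
                 "invalid_alleles")
  reason <- flag(x$effect_allele == x$other_allele, "identical_alleles")
  reason <- flag(is.na(x$beta), "missing_beta")
  reason <- flag(is.na(x$se) | x$se <= 0, "nonpositive_se")
  reason <- flag(is.na(x$pval) | x$pval <= 0 | x$pval > 1, "pval_out_of_range")
  reason <- flag(!is.na(x$eaf) & (x$eaf <= 0 | x$eaf >= 1), "eaf_out_of_range")
  reason <- flag(!is.na(x$n) & x$n <= 0, "nonpositive_n")
  reason
}

#' @export
print.gwas_dataset <- function(x, ...) {
  cat(sprintf(
    "<gwas_dataset> trait: %s (%s), ancestry: %s, %d variants\n",
    attr(x, "trait_name"), attr(x, "trait_units"),
    attr(x, "ancestry") %||% NA, nrow(x)
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Trait metadata of a GWAS dataset
#' @param x A `gwas_dataset`.
#' @return A one-row tibble with `trait_name`, `trait_units`, `ancestry`,
#'   `n_variants`.
#' @export
trait_info <- function(x) {
  tibble(
    trait_name = attr(x, "trait_name"),
    trait_units = attr(x, "trait_units"),
    ancestry = attr(x, "ancestry"),
    n_variants = nrow(x)
  )
}

#' Two-sided Wald p-value from an effect estimate and its standard error
#'
#' `p = 2 * Phi(-|beta/se|)`, clipped below at the smallest positive
#' representable double so a p-value is never exactly zero.
#'
#' @param beta,se Numeric vectors (recycled); `se` must be positive.
#' @return Numeric vector of p-values in (0, 1].
#' @export
wald_pvalue <- function(beta, se) {
  if (any(is.na(se)) || any(se <= 0)) {
    abort_domain("se must be positive")
  }
  pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-delimited (optionally gzipped) summary-statistics file,
#' renames columns to the canonical scheme via `column_map`, and validates
#' through [gwas_dataset()].
#'
#' @param path File path; `.gz` is handled transparently.
#' @param column_map Named character vector mapping canonical names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pval`, `n`) to the file's column names. `NULL` means the
#'   file already uses canonical names.
#' @inheritParams gwas_dataset
#' @return A `gwas_dataset`.
#' @export
read_gwas_table <- function(path, column_map = NULL, trait_name = "trait",
                            trait_units = "SD units",
                            ancestry = NA_character_, strict = FALSE) {
  if (!file.exists(path)) {
    abort_config(paste0("file not found: ", path))
  }
  # Columns are read as character and converted with base R's strtod-based
  # parser: extreme p-values (denormal range) survive a write/read cycle
  # bit-for-bit, which the fast type-guessing parser does not guarantee.
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(column_map)) {
    missing_file_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_file_cols) > 0) {
      abort_config(paste0(
        "column_map names file column(s) absent from ", path, ": ",
        paste(missing_file_cols, collapse = ", ")
      ))
    }
    raw <- rename(raw, !!!setNames(unname(column_map), names(column_map)))
  }
  gwas_dataset(raw, trait_name = trait_name, trait_units = trait_units,
               ancestry = ancestry, strict = strict)
}

#' Write GWAS summary statistics to a tab-delimited file
#' @param x A `gwas_dataset` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_table <- function(x, path) {
  readr::write_tsv(as_tibble(x)[, .canonical_columns], path, progress = FALSE)
  invisible(path)
}

#' Read a BED gene annotation
#'
#' BED input is 0-based half-open; coordinates are converted to the 1-based
#' inclusive representation used throughout the package. Overlapping genes
#' are retained as-is (no merging).
#'
#' @param path Path to a headerless BED file with columns chrom, start, end,
#'   name.
#' @return Tibble with `gene_symbol`, `chrom`, `start`, `end`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("file not found: ", path))
  }
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "gene_symbol"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), gene_symbol = readr::col_character()
    ),
    progress = FALSE
  )
  ann <- tibble(
    gene_symbol = raw$gene_symbol,
    chrom = raw$chrom,
    start = raw$start + 1,
    end = raw$end
  )
  if (any(ann$start > ann$end)) {
    bad <- ann$gene_symbol[ann$start > ann$end]
    abort_data(paste0("start > end for: ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(ann$gene_symbol)) {
    abort_data("duplicate gene_symbol in annotation")
  }
  ann
}

#' Write a gene annotation as BED
#' @param annotation Tibble with `gene_symbol`, `chrom`, `start`, `end`
#'   (1-based inclusive); written as 0-based half-open BED.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  out <- tibble(
    chrom = annotation$chrom,
    start = annotation$start - 1,
    end = annotation$end,
    gene_symbol = annotation$gene_symbol
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Construct an LD matrix
#'
#' Pairwise LD correlations (r, not r-squared) between variants. The matrix
#' is symmetrized by averaging when asymmetric within `tol`, and the
#' diagonal is forced to exactly 1.
#'
#' @param r Square numeric matrix of correlations.
#' @param variant_ids Character vector of variant ids, one per row/column.
#' @param tol Largest tolerated asymmetry / bound overshoot (default 1e-8).
#' @return A matrix of class `ld_matrix` with `variant_ids` as dimnames.
#' @export
ld_matrix <- function(r, variant_ids, tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) {
    abort_data("LD matrix must be square")
  }
  if (length(variant_ids) != nrow(r)) {
    abort_data("variant_ids length must equal LD matrix dimension")
  }
  if (anyDuplicated(variant_ids)) {
    abort_data("duplicate variant_ids in LD matrix")
  }
  if (any(abs(r) > 1 + tol)) {
    abort_data("LD correlations must satisfy |r| <= 1")
  }
  if (max(abs(r - t(r))) > tol) {
    abort_data("LD matrix is asymmetric beyond tolerance")
  }
  r <- (r + t(r)) / 2
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' Read a tab-delimited LD matrix
#'
#' Expects a square matrix whose first row and first column hold variant
#' ids.
#'
#' @param path File path.
#' @inheritParams ld_matrix
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, tol = 1e-8) {
  if (!file.exists(path)) {
    abort_config(paste0("file not found: ", path))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(raw[[1]])
  r <- as.matrix(raw[, -1, drop = FALSE])
  if (!identical(colnames(r), ids)) {
    abort_data("LD matrix row and column variant ids disagree")
  }
  storage.mode(r) <- "double"
  ld_matrix(r, ids, tol = tol)
}

#' Write an LD matrix
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- dplyr::bind_cols(
    tibble(variant_id = rownames(ld)),
    as_tibble(unclass(ld))
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a trait-association catalogue
#'
#' Tab-delimited records of previously reported trait associations,
#' GWAS-Catalogue style: `variant_id`, `gene_symbol`, `trait`, `pval`.
#' Either of `variant_id`/`gene_symbol` may be empty on a given record.
#'
#' @param path File path.
#' @return Tibble with those four columns.
#' @export
read_trait_catalogue <- function(path) {
  if (!file.exists(path)) {
    abort_config(paste0("file not found: ", path))
  }
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      variant_id = readr::col_character(),
      gene_symbol = readr::col_character(),
      trait = readr::col_character(),
      pval = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(!is.na(raw$pval) & (raw$pval <= 0 | raw$pval > 1))) {
    abort_data("catalogue pval outside (0, 1]")
  }
  raw
}

#' Write a trait-association catalogue
#' @param catalogue Tibble with `variant_id`, `gene_symbol`, `trait`, `pval`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_catalogue <- function(catalogue, path) {
  readr::write_tsv(
    catalogue[, c("variant_id", "gene_symbol", "trait", "pval")],
    path, progress = FALSE
  )
  invisible(path)
}
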