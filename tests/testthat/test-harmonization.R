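test_that("every non-palindromic allele configuration resolves per the truth table", {
  pairs <- list(
    c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
    c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
  )
  comp <- function(a) chartr("ACGT", "TGCA", a)
  # Hand-built truth table: how the outcome encodes the variant -> expected
  # action and whether the outcome beta sign flips.
  transforms <- list(
    identical = list(f = function(p) p, action = "kept", flip = FALSE),
    swapped = list(f = function(p) rev(p), action = "flipped", flip = TRUE),
    strand = list(f = function(p) comp(p), action = "strand_flipped",
                  flip = FALSE),
    strand_swapped = list(f = function(p) rev(comp(p)), action = "flipped",
                          flip = TRUE)
  )
  for (p in pairs) {
    for (nm in names(transforms)) {
      tr <- transforms[[nm]]
      oalleles <- tr$f(p)
      e <- assoc_row("rs1", effect_allele = p[1], other_allele = p[2],
                     beta = 0.10, eaf = 0.3)
      o <- assoc_row("rs1", effect_allele = oalleles[1],
                     other_allele = oalleles[2], beta = -0.05,
                     eaf = if (tr$flip) 0.7 else 0.3)
      h <- harmonize_variant(e, o)
      expect_equal(h$action, tr$action,
                   label = paste(p[1], p[2], nm, "action"))
      expect_equal(h$outcome_beta, if (tr$flip) 0.05 else -0.05,
                   label = paste(p[1], p[2], nm, "beta"))
      expect_equal(h$outcome_eaf, 0.3, label = paste(p[1], p[2], nm, "eaf"))
      expect_identical(h$outcome_se, o$se)
    }
  }
  # Irreconcilable alleles drop.
  e <- assoc_row("rs1", effect_allele = "A", other_allele = "G")
  o <- assoc_row("rs1", effect_allele = "A", other_allele = "C")
  h <- harmonize_variant(e, o)
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "allele_mismatch")
})

test_that("palindromic variants use frequency inference or drop", {
  pal <- function(ea_x, oa_x, eaf_x, ea_y, oa_y, eaf_y, beta_y = -0.05,
                  policy = harmonization_policy()) {
    harmonize_variant(
      assoc_row("rs1", effect_allele = ea_x, other_allele = oa_x,
                eaf = eaf_x, beta = 0.1),
      assoc_row("rs1", effect_allele = ea_y, other_allele = oa_y,
                eaf = eaf_y, beta = beta_y),
      policy
    )
  }
  # Mid-frequency: ambiguous regardless of labels.
  h <- pal("A", "T", 0.5, "A", "T", 0.5)
  expect_equal(h$action, "dropped")
  expect_equal(h$drop_reason, "palindromic_ambiguous")
  # Window boundaries are inclusive.
  expect_equal(pal("A", "T", 0.42, "A", "T", 0.42)$action, "dropped")
  expect_equal(pal("C", "G", 0.58, "C", "G", 0.58)$action, "dropped")
  # Missing EAF on either side: dropped under the default policy.
  expect_equal(pal("A", "T", NA, "A", "T", 0.2)$action, "dropped")
  expect_equal(pal("A", "T", 0.2, "A", "T", NA)$action, "dropped")
  # Informative agreeing frequencies: kept as-is.
  h <- pal("A", "T", 0.2, "A", "T", 0.2)
  expect_equal(h$action, "kept")
  expect_equal(h$outcome_beta, -0.05)
  # Same labels but mirrored frequency: the outcome is on the other strand
  # frame; beta flips.
  h <- pal("C", "G", 0.2, "C", "G", 0.8)
  expect_equal(h$action, "flipped")
  expect_equal(h$outcome_beta, 0.05)
  expect_equal(h$outcome_eaf, 0.2)
  # Swapped labels with mirrored frequency: nominal swap confirmed.
  h <- pal("A", "T", 0.2, "T", "A", 0.8)
  expect_equal(h$action, "flipped")
  expect_equal(h$outcome_beta, 0.05)
  # Swapped labels but matching frequency: swap cancelled by strand flip.
  h <- pal("A", "T", 0.2, "T", "A", 0.2)
  expect_equal(h$action, "kept")
  expect_equal(h$outcome_beta, -0.05)
  # The drop-always policy never keeps a palindrome.
  h <- pal("A", "T", 0.2, "A", "T", 0.2,
           policy = harmonization_policy(palindromic = "drop"))
  expect_equal(h$action, "dropped")
})

test_that("indel alleles are compared literally with no complementing", {
  e <- assoc_row("rs1", effect_allele = "AT", other_allele = "A", beta = 0.1)
  o_swap <- assoc_row("rs1", effect_allele = "A", other_allele = "AT",
                      beta = -0.05)
  h <- harmonize_variant(e, o_swap)
  expect_equal(h$action, "flipped")
  expect_equal(h$outcome_beta, 0.05)
  # The literal complement of an indel is not considered a match.
  o_comp <- assoc_row("rs1", effect_allele = "TA", other_allele = "T",
                      beta = -0.05)
  expect_equal(harmonize_variant(e, o_comp)$drop_reason, "allele_mismatch")
})

test_that("harmonization is idempotent and SEs are never touched", {
  e <- assoc_row("rs1", effect_allele = "A", other_allele = "G", beta = 0.1,
                 se = 0.011, eaf = 0.3)
  o <- assoc_row("rs1", effect_allele = "G", other_allele = "A",
                 beta = -0.05, se = 0.023, eaf = 0.7)
  h1 <- harmonize_variant(e, o)
  expect_equal(h1$action, "flipped")
  expect_identical(h1$outcome_se, 0.023)
  # Re-harmonizing the already-aligned pair changes nothing.
  o2 <- o
  o2$effect_allele <- h1$effect_allele
  o2$other_allele <- h1$other_allele
  o2$beta <- h1$outcome_beta
  o2$eaf <- h1$outcome_eaf
  h2 <- harmonize_variant(e, o2)
  expect_equal(h2$action, "kept")
  expect_equal(h2$outcome_beta, h1$outcome_beta)
  expect_equal(h2$outcome_eaf, h1$outcome_eaf)
})

test_that("harmonize_set keeps, flips and logs as expected", {
  exposure <- tiny_dataset(list(
    assoc_row("rs1", pos = 100, effect_allele = "A", other_allele = "G",
              beta = 0.10),
    assoc_row("rs2", pos = 200, effect_allele = "C", other_allele = "T",
              beta = 0.12),
    assoc_row("rs3", pos = 300, effect_allele = "A", other_allele = "T",
              beta = 0.08, eaf = 0.5),
    assoc_row("rs4", pos = 400, effect_allele = "G", other_allele = "T",
              beta = 0.05)
  ), "exposure")
  outcome <- tiny_dataset(list(
    assoc_row("rs1", pos = 100, effect_allele = "G", other_allele = "A",
              beta = -0.05, eaf = 0.7),
    assoc_row("rs2", pos = 200, effect_allele = "C", other_allele = "T",
              beta = 0.02),
    assoc_row("rs3", pos = 300, effect_allele = "A", other_allele = "T",
              beta = 0.01, eaf = 0.5)
  ), "outcome")
  hs <- harmonize_set(exposure, outcome, c("rs1", "rs2", "rs3", "rs4"))
  expect_s3_class(hs, "harmonized_set")
  expect_equal(hs$variant_id, c("rs1", "rs2"))
  expect_equal(hs$action, c("flipped", "kept"))
  expect_equal(hs$outcome_beta, c(0.05, 0.02))
  log <- drop_log(hs)
  expect_equal(nrow(log), 2)
  expect_equal(log$reason[log$variant_id == "rs3"], "palindromic_ambiguous")
  expect_equal(log$reason[log$variant_id == "rs4"], "missing_in_outcome")
  # Every requested id is accounted for.
  expect_setequal(c(hs$variant_id, log$variant_id),
                  c("rs1", "rs2", "rs3", "rs4"))
  expect_error(harmonize_set(exposure, outcome, character(0)),
               class = "ketomr_usage_error")
})

test_that("a dataset harmonized against itself keeps everything unflipped", {
  ds <- tiny_dataset(list(
    assoc_row("rs1", pos = 100, effect_allele = "A", other_allele = "G"),
    assoc_row("rs2", pos = 200, effect_allele = "C", other_allele = "T")
  ))
  hs <- harmonize_set(ds, ds, c("rs1", "rs2"))
  expect_equal(hs$action, c("kept", "kept"))
  expect_equal(hs$outcome_beta, hs$exposure_beta)
  expect_equal(nrow(drop_log(hs)), 0)
})

test_that("complementing both studies leaves kept betas unchanged", {
  set.seed(42)
  comp <- function(a) chartr("ACGT", "TGCA", a)
  mk <- function(flipper = identity) {
    rows <- lapply(1:6, function(i) {
      pair <- list(c("A", "G"), c("C", "T"), c("G", "T"), c("A", "C"),
                   c("T", "C"), c("G", "A"))[[i]]
      assoc_row(paste0("rs", i), pos = i * 100,
                effect_allele = flipper(pair[1]),
                other_allele = flipper(pair[2]),
                beta = 0.05 * i, eaf = 0.1 + 0.05 * i)
    })
    tiny_dataset(rows)
  }
  plainx <- mk()
  plainy <- mk()
  compx <- mk(comp)
  compy <- mk(comp)
  ids <- paste0("rs", 1:6)
  h_plain <- harmonize_set(plainx, plainy, ids)
  h_comp <- harmonize_set(compx, compy, ids)
  expect_equal(h_comp$outcome_beta, h_plain$outcome_beta)
  expect_equal(h_comp$exposure_beta, h_plain$exposure_beta)
})

test_that("MR estimates are invariant to a joint effect-allele swap", {
  set.seed(11)
  base <- lapply(1:5, function(i) {
    assoc_row(paste0("rs", i), pos = i * 100, effect_allele = "A",
              other_allele = "G", beta = rnorm(1, 0.1, 0.02),
              se = 0.01, eaf = 0.3)
  })
  outc <- lapply(base, function(r) {
    r$beta <- 0.3 * r$beta + rnorm(1, 0, 0.01)
    r$se <- 0.02
    r
  })
  swap_one <- function(rows, id) {
    lapply(rows, function(r) {
      if (r$variant_id == id) {
        tmp <- r$effect_allele
        r$effect_allele <- r$other_allele
        r$other_allele <- tmp
        r$beta <- -r$beta
        r$eaf <- 1 - r$eaf
      }
      r
    })
  }
  ids <- paste0("rs", 1:5)
  h0 <- harmonize_set(tiny_dataset(base), tiny_dataset(outc), ids)
  h1 <- harmonize_set(tiny_dataset(swap_one(base, "rs3")),
                      tiny_dataset(swap_one(outc, "rs3")), ids)
  for (fit in list(mr_ivw, mr_egger)) {
    e0 <- fit(h0)
    e1 <- fit(h1)
    expect_equal(e1$beta, e0$beta, tolerance = 1e-12)
    expect_equal(e1$se, e0$se, tolerance = 1e-12)
  }
  w0 <- mr_weighted_median(h0, n_boot = 50, seed = 9)
  w1 <- mr_weighted_median(h1, n_boot = 50, seed = 9)
  expect_equal(w1$beta, w0$beta, tolerance = 1e-12)
})

test_that("drop logs can be written out", {
  exposure <- tiny_dataset(list(assoc_row("rs1")))
  outcome <- tiny_dataset(list(assoc_row("rs_other")))
  hs <- harmonize_set(exposure, outcome, "rs1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_drop_log(hs, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$reason, "missing_in_outcome")
})
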