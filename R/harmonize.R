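.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.isPalindromic <- function(ea, oa) .COMPLEMENT[ea] == oa

#' Harmonize exposure instruments with outcome associations
#'
#' Aligns each instrument's outcome association to the exposure's effect
#' allele, the step that makes two-sample Wald ratios meaningful when the
#' two GWAS report different alleles or strands. Non-palindromic variants
#' are aligned by allele letters (directly or via the strand complement);
#' when the outcome's effect allele is the exposure's other allele, the
#' outcome beta is negated and its EAF complemented. Palindromic variants
#' (A/T or G/C) match by letters on either strand, so letters cannot
#' resolve them: under `"infer_by_eaf"` the allele frequencies on the two
#' sides are compared to 0.5 and the orientation that makes them agree is
#' chosen, unless either frequency is missing or sits within
#' `eafAmbiguityBand` of 0.5, in which case the variant is dropped; under
#' `"drop"` all palindromic variants are dropped. Instruments absent from
#' the outcome study are dropped with a warning.
#'
#' @param exposure an [InstrumentSet] (or [GwasAssociations]) of exposure
#'   instruments.
#' @param outcome a [GwasAssociations] of outcome associations.
#' @param palindromicPolicy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eafAmbiguityBand half-width around 0.5 within which an EAF is
#'   considered uninformative for strand inference (default 0.08).
#' @return a [HarmonizedPairs]; dropped rows are retained with their
#'   reason, and `x@log` counts each decision.
#' @export
harmonize <- function(exposure, outcome,
                      palindromicPolicy = c("infer_by_eaf", "drop"),
                      eafAmbiguityBand = 0.08) {
  stopifnot(is(exposure, "GwasAssociations"), is(outcome, "GwasAssociations"))
  palindromicPolicy <- match.arg(palindromicPolicy)
  if (!is.numeric(eafAmbiguityBand) || eafAmbiguityBand < 0 ||
      eafAmbiguityBand >= 0.5)
    mrStop("eafAmbiguityBand must lie in [0, 0.5)", "ivwMR_config_error")

  ex <- exposure@table
  out <- outcome@table
  if (anyDuplicated(out$rsid))
    out <- out[!duplicated(out$rsid), , drop = FALSE]
  rownames(out) <- out$rsid

  n <- nrow(ex)
  res <- data.frame(
    rsid = ex$rsid,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_exposure = ex$beta, se_exposure = ex$se, eaf_exposure = ex$eaf,
    beta_outcome = NA_real_, se_outcome = NA_real_, eaf_outcome = NA_real_,
    flip_applied = FALSE, palindromic = FALSE,
    resolution = "dropped", reason = NA_character_,
    stringsAsFactors = FALSE
  )

  counts <- c(direct = 0L, flipped = 0L, eaf_inferred = 0L,
              dropped_absent = 0L, dropped_palindromic = 0L,
              dropped_ambiguous_eaf = 0L, dropped_missing_eaf = 0L,
              dropped_allele_mismatch = 0L)

  for (i in seq_len(n)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    pal <- unname(.isPalindromic(ea, oa))
    res$palindromic[i] <- pal

    o <- out[match(ex$rsid[i], out$rsid), ]
    if (is.na(o$rsid)) {
      res$reason[i] <- "absent_from_outcome"
      counts["dropped_absent"] <- counts["dropped_absent"] + 1L
      next
    }
    b <- o$beta; s <- o$se; f <- o$eaf
    oea <- o$effect_allele; ooa <- o$other_allele
    flips <- 0L  # net effect-allele swaps applied to the outcome record

    if (pal) {
      ## letters match on either strand; orientation must come from EAF
      if (!setequal(c(oea, ooa), c(ea, oa))) {
        res$reason[i] <- "allele_mismatch"
        counts["dropped_allele_mismatch"] <- counts["dropped_allele_mismatch"] + 1L
        next
      }
      if (palindromicPolicy == "drop") {
        res$reason[i] <- "palindromic"
        counts["dropped_palindromic"] <- counts["dropped_palindromic"] + 1L
        next
      }
      fe <- ex$eaf[i]
      if (is.na(fe) || is.na(f)) {
        res$reason[i] <- "palindromic_missing_eaf"
        counts["dropped_missing_eaf"] <- counts["dropped_missing_eaf"] + 1L
        next
      }
      if (oea != ea) { b <- -b; f <- 1 - f; flips <- flips + 1L }
      if (abs(fe - 0.5) <= eafAmbiguityBand ||
          abs(f - 0.5) <= eafAmbiguityBand) {
        res$reason[i] <- "palindromic_ambiguous_eaf"
        counts["dropped_ambiguous_eaf"] <- counts["dropped_ambiguous_eaf"] + 1L
        next
      }
      if ((fe < 0.5) != (f < 0.5)) {
        ## frequencies disagree: the outcome is on the other strand,
        ## where this allele letter labels the complementary allele
        b <- -b; f <- 1 - f; flips <- flips + 1L
      }
      res$resolution[i] <- "eaf_inferred"
      counts["eaf_inferred"] <- counts["eaf_inferred"] + 1L
    } else {
      cea <- unname(.COMPLEMENT[ea]); coa <- unname(.COMPLEMENT[oa])
      if (oea == ea && ooa == oa) {
        res$resolution[i] <- "direct"
      } else if (oea == oa && ooa == ea) {
        b <- -b; if (!is.na(f)) f <- 1 - f; flips <- 1L
        res$resolution[i] <- "flipped"
      } else if (oea == cea && ooa == coa) {
        ## reported on the other strand, same allele orientation
        res$resolution[i] <- "direct"
      } else if (oea == coa && ooa == cea) {
        b <- -b; if (!is.na(f)) f <- 1 - f; flips <- 1L
        res$resolution[i] <- "flipped"
      } else {
        res$reason[i] <- "allele_mismatch"
        counts["dropped_allele_mismatch"] <- counts["dropped_allele_mismatch"] + 1L
        next
      }
      counts[res$resolution[i]] <- counts[res$resolution[i]] + 1L
    }
    res$beta_outcome[i] <- b
    res$se_outcome[i] <- s
    res$eaf_outcome[i] <- f
    res$flip_applied[i] <- (flips %% 2L) == 1L
  }

  if (counts["dropped_absent"] > 0L)
    mrWarn(sprintf("%d instrument(s) absent from outcome associations",
                   counts[["dropped_absent"]]),
           "ivwMR_absent_instruments_warning")

  new("HarmonizedPairs",
      exposureTrait = exposure@trait, outcomeTrait = outcome@trait,
      scale = outcome@scale, pairs = res, log = counts)
}

#' View the harmonized outcome side as a GwasAssociations
#'
#' Re-expresses the (kept) harmonized outcome associations as a
#' [GwasAssociations] on the exposure's alleles — useful for audits and for
#' verifying that harmonization is involution-safe.
#'
#' @param pairs a [HarmonizedPairs].
#' @return a [GwasAssociations] on the outcome trait.
#' @export
harmonizedOutcome <- function(pairs) {
  stopifnot(is(pairs, "HarmonizedPairs"))
  kept <- keptPairs(pairs)
  tab <- data.frame(
    rsid = kept$rsid, chromosome = NA_character_,
    effect_allele = kept$effect_allele, other_allele = kept$other_allele,
    beta = kept$beta_outcome, se = kept$se_outcome, eaf = kept$eaf_outcome,
    pvalue = NA_real_, n = NA_real_, stringsAsFactors = FALSE
  )
  new("GwasAssociations", trait = pairs@outcomeTrait, scale = pairs@scale,
      unitLabel = "", table = tab,
      provenance = list(source = "harmonizedOutcome", n_read = nrow(tab),
                        n_kept = nrow(tab), n_skipped = 0L))
}
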