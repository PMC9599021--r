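# Unit chain shared by all assays: the extract holds `sampleMass` g of tissue
# in `extractVolume` mL of 80% ethanol; the read cuvette concentration times
# the dilution factor gives the extract concentration.

# molar extinction coefficient (L mol^-1 cm^-1) and molar mass (g mol^-1)
# of cyanidin-3-glucoside; 1 cm path length assumed.
.TAC_EPSILON <- 26900
.TAC_MW <- 449.2

.FW_UNITS <- c(TPC = "mg GAE/100 g FW", TFC = "mg RE/100 g FW",
               TAC = "mg cyan-3-G/100 g FW", FRAP = "umol TE/g FW",
               ABTS = "umol TE/g FW")
.DW_UNITS <- c(TPC = "mg GAE/g DW", TFC = "mg RE/g DW",
               TAC = "mg cyan-3-G/g DW", FRAP = "umol TE/g DW",
               ABTS = "umol TE/g DW")

#' Default per-assay dilution factors
#'
#' The working dilutions used when a record does not carry its own factor:
#' the pH-differential anthocyanin assay mixes 0.2 mL sample into 1.8 mL
#' buffer (10x), and extracts are read at a 10x dilution in the TPC, FRAP
#' and ABTS assays so that typical berry extracts fall inside the calibrated
#' range; flavonoid extracts are read neat.
#'
#' @return named numeric vector over assays.
#' @export
defaultDilutionFactors <- function() {
  c(TPC = 10, TFC = 1, TAC = 10, FRAP = 10, ABTS = 10)
}

#' Default calibration curves
#'
#' Plausible instrument responses for the four standards, used by the
#' simulator and as fallbacks when no fitted curves are supplied:
#' gallic acid 10-300 ug/mL (absorbance at 760 nm), rutin 50-1000 ug/mL
#' (510 nm), Trolox 0.05-1 mM for FRAP (593 nm) and Trolox 0.05-1 mM for
#' ABTS, where the signal is percent inhibition of the blank at 734 nm.
#'
#' @return named list of [CalibrationCurve-class] objects with elements
#'   \code{gallic_acid}, \code{rutin}, \code{trolox_frap}, \code{trolox_abts}.
#' @export
defaultCurves <- function() {
  list(
    gallic_acid = calibrationCurve(0.005, 0.010, c(10, 300), "gallic acid"),
    rutin = calibrationCurve(0.0012, 0.005, c(50, 1000), "rutin"),
    trolox_frap = calibrationCurve(0.90, 0.020, c(0.05, 1), "Trolox (FRAP)"),
    trolox_abts = calibrationCurve(80, 2, c(0.05, 1), "Trolox (ABTS)")
  )
}

.check_ctx <- function(sampleMass, extractVolume) {
  if (!is.finite(sampleMass) || sampleMass <= 0)
    stop("'sampleMass' must be > 0 (g)")
  if (!is.finite(extractVolume) || extractVolume <= 0)
    stop("'extractVolume' must be > 0 (mL)")
}

#' Quantify a Folin-type assay reading (TPC or TFC)
#'
#' Converts one absorbance reading into mg of standard equivalents per
#' 100 g of tissue: the curve is inverted to ug/mL in the cuvette,
#' multiplied by the dilution factor to give the extract concentration,
#' scaled by the extract volume to the mass of equivalents in the whole
#' extract, and expressed per 100 g of the extracted sample mass.
#'
#' @param absorbance reading (vectorised over replicates).
#' @param curve [CalibrationCurve-class] of the standard (gallic acid for
#'   TPC, rutin for TFC), in ug/mL.
#' @param dilutionFactor dimensionless >= 1.
#' @param sampleMass g of tissue extracted (berries: 5).
#' @param extractVolume mL of final extract (30).
#' @param warn pass through range warnings from [predictConcentration()].
#' @return mg equivalents per 100 g fresh weight.
#' @export
quantifyFolin <- function(absorbance, curve, dilutionFactor = 1,
                          sampleMass = 5, extractVolume = 30, warn = TRUE) {
  .check_ctx(sampleMass, extractVolume)
  if (any(dilutionFactor < 1)) stop("'dilutionFactor' must be >= 1")
  conc <- predictConcentration(curve, absorbance, warn = warn)   # ug/mL read
  ug <- conc * dilutionFactor * extractVolume                    # ug in extract
  ug * (100 / sampleMass) / 1000                                 # mg / 100 g
}

#' Quantify monomeric anthocyanins by the pH-differential method
#'
#' The anthocyanin absorbance is
#' \eqn{A = (A_{510} - A_{700})_{pH 1.0} - (A_{510} - A_{700})_{pH 4.5}};
#' the cyanidin-3-glucoside concentration in the read cuvette is
#' \eqn{A \cdot MW \cdot 1000 / \epsilon} mg/L with \eqn{MW = 449.2} and
#' \eqn{\epsilon = 26900} (1 cm path), multiplied by the dilution factor and
#' rebased to mg per 100 g of sample. A negative differential absorbance
#' (possible for near-colourless samples under noise) is clamped to zero
#' with a warning.
#'
#' @param a510Acid,a700Acid readings at pH 1.0.
#' @param a510Neutral,a700Neutral readings at pH 4.5.
#' @param dilutionFactor,sampleMass,extractVolume see [quantifyFolin()].
#' @return mg cyanidin-3-glucoside equivalents per 100 g fresh weight.
#' @export
quantifyTAC <- function(a510Acid, a700Acid, a510Neutral, a700Neutral,
                        dilutionFactor = 10, sampleMass = 5,
                        extractVolume = 30) {
  .check_ctx(sampleMass, extractVolume)
  readings <- list(a510Acid, a700Acid, a510Neutral, a700Neutral)
  if (any(vapply(readings, function(r) any(!is.finite(r)), logical(1))))
    stop("all four pH-differential readings are required")
  A <- (a510Acid - a700Acid) - (a510Neutral - a700Neutral)
  if (any(A < 0)) {
    warning("negative differential absorbance clamped to 0")
    A <- pmax(A, 0)
  }
  mgL <- A * .TAC_MW * 1000 * dilutionFactor / .TAC_EPSILON  # mg/L in extract
  mgL * (extractVolume / 1000) * (100 / sampleMass)          # mg / 100 g
}

#' Quantify ferric reducing antioxidant power (FRAP)
#'
#' Inverse prediction from a Trolox curve in mM at 593 nm, times the
#' dilution factor, gives the extract Trolox-equivalent concentration in
#' umol/mL; scaling by extract volume and sample mass yields umol TE per g.
#'
#' @inheritParams quantifyFolin
#' @param curve Trolox [CalibrationCurve-class] in mM.
#' @return umol Trolox equivalents per g fresh weight.
#' @export
quantifyFRAP <- function(absorbance, curve, dilutionFactor = 10,
                         sampleMass = 5, extractVolume = 30, warn = TRUE) {
  .check_ctx(sampleMass, extractVolume)
  concmM <- predictConcentration(curve, absorbance, warn = warn)  # mM read
  concmM * dilutionFactor * extractVolume / sampleMass            # umol/g
}

#' Percent inhibition of the ABTS blank
#'
#' @param aSample,aBlank absorbance of sample and blank at 734 nm.
#' @return percent inhibition \eqn{(A_b - A_s)/A_b \times 100}.
#' @export
abtsInhibition <- function(aSample, aBlank) {
  if (any(aBlank <= 0)) stop("blank absorbance must be > 0")
  (aBlank - aSample) / aBlank * 100
}

#' Quantify ABTS radical-scavenging capacity
#'
#' Percent inhibition of the blank absorbance is converted to a Trolox
#' equivalent concentration through a Trolox inhibition curve (percent
#' inhibition vs mM), then scaled like FRAP. Records whose inhibition
#' falls outside the 20-80\% working window are flagged (attribute
#' \code{"flag"}), not rejected; a blank away from the nominal
#' 0.70 +/- 0.02 raises a configuration warning.
#'
#' @param aSample,aBlank absorbance at 734 nm.
#' @param curve Trolox inhibition [CalibrationCurve-class]
#'   (signal = percent inhibition, concentration in mM).
#' @inheritParams quantifyFolin
#' @return umol Trolox equivalents per g fresh weight, with attribute
#'   \code{flag}: character vector, \code{""} or
#'   \code{"inhibition_out_of_range"} per element.
#' @export
quantifyABTS <- function(aSample, aBlank, curve, dilutionFactor = 10,
                         sampleMass = 5, extractVolume = 30, warn = TRUE) {
  .check_ctx(sampleMass, extractVolume)
  if (any(abs(aBlank - 0.70) > 0.02))
    warning("ABTS blank absorbance outside 0.70 +/- 0.02 at 734 nm: check working solution")
  inh <- abtsInhibition(aSample, aBlank)
  flag <- ifelse(inh < 20 | inh > 80, "inhibition_out_of_range", "")
  concmM <- predictConcentration(curve, inh, warn = warn)
  value <- concmM * dilutionFactor * extractVolume / sampleMass
  attr(value, "flag") <- flag
  value
}

#' Rebase a fresh-weight value to dry weight
#'
#' Per-100-g-FW concentrations (TPC, TFC, TAC) become mg per g DW; per-g-FW
#' activities (FRAP, ABTS) become umol per g DW.
#'
#' @param value fresh-weight value.
#' @param dryMatterFraction fraction of dry matter in the fresh tissue,
#'   strictly inside (0, 1).
#' @param per100g whether \code{value} is expressed per 100 g (TRUE for
#'   TPC/TFC/TAC) or per g (FRAP/ABTS).
#' @return the dry-weight value per g DW.
#' @examples
#' fwToDw(352.7, 0.184)  # 19.17 mg/g DW
#' @export
fwToDw <- function(value, dryMatterFraction, per100g = TRUE) {
  if (any(!is.finite(dryMatterFraction)) ||
      any(dryMatterFraction <= 0) || any(dryMatterFraction >= 1))
    stop("'dryMatterFraction' must lie strictly inside (0, 1)")
  perg <- if (per100g) value / 100 else value
  perg / dryMatterFraction
}

#' Quantify a table of absorbance records
#'
#' Table-level driver over the per-assay quantification functions. The
#' absorbance table is in long format with one row per reading; readings of
#' multi-reading assays (TAC, ABTS) are matched within genotype x assay x
#' replicate by \code{reading_name}.
#'
#' @param absorbance data frame with columns \code{genotype}, \code{assay}
#'   (TPC/TFC/TAC/FRAP/ABTS), \code{replicate}, \code{reading_name},
#'   \code{value}, and optionally \code{dilution_factor}. Reading names:
#'   \code{A760} (TPC), \code{A510} (TFC), \code{A510_pH1}, \code{A700_pH1},
#'   \code{A510_pH45}, \code{A700_pH45} (TAC), \code{A593} (FRAP),
#'   \code{A734_sample}, \code{A734_blank} (ABTS).
#' @param context data frame with columns \code{genotype},
#'   \code{sample_mass_g}, \code{extract_volume_ml} and optionally
#'   \code{dry_matter_fraction}; a single row is recycled for all genotypes.
#' @param curves named list of curves as in [defaultCurves()].
#' @param dilutionFactors fallback per-assay factors when the table has no
#'   \code{dilution_factor} column, as in [defaultDilutionFactors()].
#' @param basis \code{"FW"} or \code{"DW"}; DW requires
#'   \code{dry_matter_fraction} in \code{context}.
#' @return data frame: genotype, assay, replicate, value, units, basis, flags.
#' @export
quantifyAssays <- function(absorbance, context,
                           curves = defaultCurves(),
                           dilutionFactors = defaultDilutionFactors(),
                           basis = c("FW", "DW")) {
  basis <- match.arg(basis)
  need <- c("genotype", "assay", "replicate", "reading_name", "value")
  miss <- setdiff(need, names(absorbance))
  if (length(miss))
    stop("absorbance table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"dilution_factor" %in% names(absorbance))
    absorbance$dilution_factor <- unname(dilutionFactors[as.character(absorbance$assay)])
  if (!all(c("genotype", "sample_mass_g", "extract_volume_ml") %in% names(context)))
    stop("context table needs columns genotype, sample_mass_g, extract_volume_ml")
  ctx <- context[match(absorbance$genotype, context$genotype), , drop = FALSE]
  if (nrow(context) == 1L) ctx[] <- context[rep(1L, nrow(absorbance)), ]
  if (anyNA(ctx$sample_mass_g))
    stop("genotype(s) missing from context table: ",
         paste(unique(absorbance$genotype[is.na(ctx$sample_mass_g)]), collapse = ", "))

  key <- interaction(absorbance$genotype, absorbance$assay,
                     absorbance$replicate, drop = TRUE)
  out <- lapply(split(seq_len(nrow(absorbance)), key), function(i) {
    rec <- absorbance[i, , drop = FALSE]
    assay <- as.character(rec$assay[1L])
    g <- as.character(rec$genotype[1L])
    rep_ <- rec$replicate[1L]
    df <- rec$dilution_factor[1L]
    sm <- ctx$sample_mass_g[i[1L]]
    ev <- ctx$extract_volume_ml[i[1L]]
    r <- setNames(rec$value, rec$reading_name)
    flag <- ""
    value <- switch(assay,
      TPC = quantifyFolin(r[["A760"]], curves$gallic_acid, df, sm, ev),
      TFC = quantifyFolin(r[["A510"]], curves$rutin, df, sm, ev),
      TAC = quantifyTAC(r[["A510_pH1"]], r[["A700_pH1"]],
                        r[["A510_pH45"]], r[["A700_pH45"]], df, sm, ev),
      FRAP = quantifyFRAP(r[["A593"]], curves$trolox_frap, df, sm, ev),
      ABTS = {
        v <- quantifyABTS(r[["A734_sample"]], r[["A734_blank"]],
                          curves$trolox_abts, df, sm, ev)
        flag <- attr(v, "flag")
        as.numeric(v)
      },
      stop("unknown assay kind: ", assay)
    )
    data.frame(genotype = g, assay = assay, replicate = rep_,
               value = unname(value), units = unname(.FW_UNITS[assay]),
               basis = "FW", flags = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (basis == "DW") {
    if (!"dry_matter_fraction" %in% names(context))
      stop("DW basis requires 'dry_matter_fraction' in the context table")
    dm <- context$dry_matter_fraction[match(out$genotype, context$genotype)]
    per100 <- out$assay %in% c("TPC", "TFC", "TAC")
    out$value <- fwToDw(out$value, dm, per100g = FALSE) *
      ifelse(per100, 1 / 100, 1)
    out$units <- unname(.DW_UNITS[out$assay])
    out$basis <- "DW"
  }
  out[order(out$genotype, out$assay, out$replicate), ]
}
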