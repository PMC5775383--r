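#' Lipid mixture
#'
#' A liposome lipid composition: component names, molar fractions and net
#' elementary charge per molecule, together with the total lipid molarity.
#' The default mixture is EPC/DOTAP/DOPE 50/25/25 mol% at 25 mM total lipid;
#' only DOTAP carries charge (+1), EPC and DOPE are net-neutral zwitterions.
#'
#' @slot components data.frame with columns name, molarFraction, charge.
#' @slot totalConcentration total lipid concentration, mM.
#' @export
setClass("LipidMix",
  representation(components = "data.frame", totalConcentration = "numeric"))

setValidity("LipidMix", function(object) {
  msg <- character()
  cmp <- object@components
  if (!all(c("name", "molarFraction", "charge") %in% names(cmp)))
    msg <- c(msg, "components needs columns name, molarFraction, charge")
  else {
    if (abs(sum(cmp$molarFraction) - 1) > 1e-9)
      msg <- c(msg, "molar fractions must sum to 1")
    if (any(cmp$molarFraction < 0))
      msg <- c(msg, "molar fractions must be non-negative")
    if (any(cmp$charge != round(cmp$charge)))
      msg <- c(msg, "charges must be integer elementary charges")
  }
  if (object@totalConcentration < 0)
    msg <- c(msg, "totalConcentration must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn LipidMix-class Construct a lipid mixture.
#' @param name,molarFraction,charge parallel component vectors.
#' @param totalConcentration total lipid concentration, mM.
#' @export
lipidMix <- function(name = c("EPC", "DOTAP", "DOPE"),
                     molarFraction = c(0.50, 0.25, 0.25),
                     charge = c(0L, 1L, 0L),
                     totalConcentration = 25) {
  new("LipidMix",
      components = data.frame(name = name, molarFraction = molarFraction,
                              charge = as.integer(charge)),
      totalConcentration = totalConcentration)
}

#' Cationic lipid concentration of a mixture
#'
#' Sum of molar fraction x positive charge over positively charged
#' components, times the total lipid concentration. For the default mixture
#' this is the DOTAP molarity.
#'
#' @param mix a [LipidMix-class].
#' @return cationic charge concentration, mM (of elementary positive charge).
#' @export
cationicConcentration <- function(mix) {
  stopifnot(is(mix, "LipidMix"))
  cmp <- mix@components
  pos <- cmp$charge > 0
  sum(cmp$molarFraction[pos] * cmp$charge[pos]) * mix@totalConcentration
}

#' Hydrodynamic focusing flows
#'
#' Center (lipid/ethanol) and side (aqueous) volumetric flow rates of the
#' focusing junction used for liposome synthesis. Defaults are 11 uL/min
#' center and two 55 uL/min side streams.
#'
#' @slot centerFlow center stream, uL/min.
#' @slot sideFlows side streams, uL/min.
#' @export
setClass("FocusingFlows",
  representation(centerFlow = "numeric", sideFlows = "numeric"))

setValidity("FocusingFlows", function(object) {
  fl <- c(object@centerFlow, object@sideFlows)
  msg <- character()
  if (any(fl < 0)) msg <- c(msg, "flows must be non-negative")
  if (sum(fl) <= 0) msg <- c(msg, "at least one flow must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn FocusingFlows-class Construct focusing flows.
#' @param centerFlow center stream, uL/min.
#' @param sideFlows numeric vector of side streams, uL/min.
#' @export
focusingFlows <- function(centerFlow = 11, sideFlows = c(55, 55)) {
  new("FocusingFlows", centerFlow = centerFlow, sideFlows = sideFlows)
}

#' Dilution of a lipid mixture by hydrodynamic focusing
#'
#' At steady state the lipid stream is diluted by the volumetric flow
#' fraction it contributes: every concentration is scaled by
#' centerFlow / (centerFlow + sum(sideFlows)); molar fractions are
#' unchanged. With the default 11 and 2 x 55 uL/min flows, 25 mM total lipid
#' becomes 25 x 11/121 = 2.27 mM.
#'
#' @param mix a [LipidMix-class].
#' @param flows a [FocusingFlows-class].
#' @return the diluted [LipidMix-class].
#' @export
focusingDilution <- function(mix, flows = focusingFlows()) {
  stopifnot(is(mix, "LipidMix"), is(flows, "FocusingFlows"))
  total <- flows@centerFlow + sum(flows@sideFlows)
  stopIf(total <= 0, "all flows are zero: dilution undefined")
  out <- mix
  out@totalConcentration <- mix@totalConcentration * flows@centerFlow / total
  out
}

# cationic charge molarity of the default mixture after focusing dilution
.defaultCationic <- function()
  cationicConcentration(focusingDilution(lipidMix()))

#' Lipoplex preparation recipe
#'
#' Inputs of the molar charge ratio R+/-: the plasmid DNA mass complexed,
#' the volume of (diluted) liposome suspension added, the final mixture
#' volume, the mean nucleotide molecular mass per DNA negative charge, and
#' the cationic charge molarity of the liposome suspension.
#'
#' @slot pdnaMass plasmid DNA mass, ug.
#' @slot liposomeVolume liposome suspension volume, uL.
#' @slot finalVolume final lipoplex mixture volume, uL.
#' @slot nucleotideMw mean nucleotide mass per negative charge, g/mol
#'   (330 g/mol, the standard per-nucleotide convention for N/P-type ratios).
#' @slot cationicConcentration cationic charge concentration of the liposome
#'   suspension, mM.
#' @export
setClass("LipoplexRecipe",
  representation(pdnaMass = "numeric", liposomeVolume = "numeric",
                 finalVolume = "numeric", nucleotideMw = "numeric",
                 cationicConcentration = "numeric"))

setValidity("LipoplexRecipe", function(object) {
  msg <- character()
  if (object@pdnaMass < 0) msg <- c(msg, "pdnaMass must be >= 0")
  if (object@liposomeVolume < 0) msg <- c(msg, "liposomeVolume must be >= 0")
  if (object@finalVolume <= 0) msg <- c(msg, "finalVolume must be > 0")
  if (object@nucleotideMw <= 0) msg <- c(msg, "nucleotideMw must be > 0")
  if (object@cationicConcentration < 0)
    msg <- c(msg, "cationicConcentration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn LipoplexRecipe-class Construct a recipe. Defaults follow the
#'   on-chip protocol: 0.07 ug pDNA complexed with focusing-diluted
#'   EPC/DOTAP/DOPE liposomes in a 4 uL final mixture.
#' @param pdnaMass pDNA mass, ug.
#' @param liposomeVolume liposome suspension volume, uL.
#' @param finalVolume final mixture volume, uL.
#' @param nucleotideMw g/mol per DNA negative charge.
#' @param cationicConcentration mM; defaults to the focusing-diluted default
#'   mixture (0.568 mM).
#' @export
lipoplexRecipe <- function(liposomeVolume = 2, pdnaMass = 0.07,
                           finalVolume = 4, nucleotideMw = 330,
                           cationicConcentration = NULL) {
  if (is.null(cationicConcentration))
    cationicConcentration <- .defaultCationic()
  new("LipoplexRecipe", pdnaMass = pdnaMass, liposomeVolume = liposomeVolume,
      finalVolume = finalVolume, nucleotideMw = nucleotideMw,
      cationicConcentration = cationicConcentration)
}

#' Molar charge ratio R+/- of a lipoplex recipe
#'
#' Ratio of positive charges contributed by the cationic lipid to negative
#' charges contributed by DNA phosphates:
#' R = (cationic mM x liposome uL) / (pDNA ug / nucleotide g/mol x 1000),
#' both sides in nanomoles of charge. The computed value is snapped to the
#' nearest of the nominal ratios used experimentally ({1.5, 3, 5}) when it
#' lies within 20\% of it; otherwise the nominal slot is NA.
#'
#' @param recipe a [LipoplexRecipe-class].
#' @param nominalSet candidate nominal ratios.
#' @param snapTolerance relative window for snapping.
#' @return list with elements \code{rPlusMinus} (the computed ratio) and
#'   \code{nominal} (snapped value or NA).
#' @examples
#' chargeRatio(lipoplexRecipe(liposomeVolume = 2))   # ~5.36, nominal 5
#' chargeRatio(lipoplexRecipe(liposomeVolume = 0.5)) # ~1.34, nominal 1.5
#' @export
chargeRatio <- function(recipe, nominalSet = c(1.5, 3, 5),
                        snapTolerance = 0.2) {
  stopifnot(is(recipe, "LipoplexRecipe"))
  stopIf(recipe@pdnaMass <= 0, "pdnaMass must be > 0: charge ratio undefined")
  posNmol <- recipe@cationicConcentration * recipe@liposomeVolume
  negNmol <- recipe@pdnaMass / recipe@nucleotideMw * 1000
  r <- posNmol / negNmol
  nominal <- NA_real_
  if (r > 0 && length(nominalSet)) {
    i <- which.min(abs(r - nominalSet))
    if (abs(r - nominalSet[i]) / nominalSet[i] <= snapTolerance)
      nominal <- nominalSet[i]
  }
  list(rPlusMinus = r, nominal = nominal)
}

#' Expected lipoplex dose per droplet
#'
#' Expected number of lipoplex particles in one trapped droplet, assuming
#' the particles are diluted into the loading mixture and partitioned
#' proportionally to volume:
#' count = concentration x (lipoplexVolume / totalMixVolume) x dropletVolume.
#' With the protocol midpoint concentration 6e7 particles/uL, 4 uL of
#' lipoplexes in a 104 uL loading mixture and 2 nL droplets, the dose is
#' about 4.6e3, i.e. on the order of 1e4 lipoplexes per anchor.
#'
#' @param particleConcentration particles per uL of lipoplex suspension.
#' @param lipoplexVolume volume of lipoplex suspension in the mix, uL.
#' @param totalMixVolume total loading mixture volume, uL.
#' @param dropletVolumeNl droplet volume, nL.
#' @return list with \code{count} and \code{nearestPowerOfTen}.
#' @export
lipoplexesPerDroplet <- function(particleConcentration = 6e7,
                                 lipoplexVolume = 4,
                                 totalMixVolume = 104,
                                 dropletVolumeNl = 2) {
  assertScalarNumber(particleConcentration, "particleConcentration", 0)
  assertScalarNumber(lipoplexVolume, "lipoplexVolume", 0, strict = TRUE)
  assertScalarNumber(totalMixVolume, "totalMixVolume", 0, strict = TRUE)
  assertScalarNumber(dropletVolumeNl, "dropletVolumeNl", 0, strict = TRUE)
  count <- particleConcentration * (lipoplexVolume / totalMixVolume) *
    dropletVolumeNl * 1e-3
  list(count = count,
       nearestPowerOfTen = if (count > 0) 10^round(log10(count)) else 0)
}

setMethod("show", "LipidMix", function(object) {
  cat(sprintf("LipidMix: %.4g mM total\n", object@totalConcentration))
  print(object@components, row.names = FALSE)
})

setMethod("show", "LipoplexRecipe", function(object) {
  cat(sprintf(
    "LipoplexRecipe: %.3g ug pDNA + %.3g uL liposomes (%.4g mM cationic) in %.3g uL\n",
    object@pdnaMass, object@liposomeVolume, object@cationicConcentration,
    object@finalVolume))
})
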