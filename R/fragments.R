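#' @include mass.R
NULL

#' Fragment rule table
#'
#' Which structure-specific fragment kinds are legal for each lipid class
#' and polarity. The table is shipped as an editable plain-text config
#' (`extdata/fragment_rules.tsv`) so further classes can be added without
#' code changes.
#'
#' @return data.frame with columns `lipid_class`, `polarity`, `kind`,
#'   `adduct`.
#' @export
fragmentRules <- function() .milkCache$fragmentRules

.ruleAllowed <- function(lipidClass, polarity, kind = NULL) {
  r <- fragmentRules()
  hit <- r$lipid_class == lipidClass & r$polarity == polarity
  if (!is.null(kind)) hit <- hit & r$kind == kind
  any(hit)
}

.phosphocholineIonMz <- function() {
  ionMz(elementalFormula(C = 5, H = 15, N = 1, O = 4, P = 1), +1L)
}

#' Neutral-loss fragments of an ammoniated TAG species
#'
#' Collision-induced dissociation of [M+NH4]+ TAG ions ejects each fatty
#' acyl as the free acid together with ammonia, leaving a DAG-like
#' fragment ion. For every *distinct* FA moiety the fragment m/z is
#' `precursor m/z - mass(FA free acid) - mass(NH3)`.
#'
#' @param species Molecular-level TAG annotation
#'   ([LipidAnnotation-class] or string).
#' @return data.frame with one row per distinct FA: `fa` (label like
#'   `"FA 16:0"`), `fragmentMz`, `multiplicity` (1-3 esterified
#'   positions), and `precursorMz` as an attribute-free extra column.
#' @examples
#' tagNeutralLossFragments("TAG 16:0-18:1-18:1")
#' @export
tagNeutralLossFragments <- function(species) {
  if (is.character(species)) species <- parseAnnotation(species)
  stopifnot(is(species, "LipidAnnotation"))
  if (species@lipidClass != "TAG" || species@level != "molecular")
    stop("neutral-loss prediction needs a molecular-level TAG species",
         call. = FALSE)
  precursorMz <- monoisotopicMz(elementalComposition(species), "+NH4")
  m <- species@moieties
  key <- paste(m$carbons, m$doubleBonds, sep = ":")
  keep <- !duplicated(key)
  mult <- as.vector(table(key)[key[keep]])
  nh3 <- monoisotopicMass(.AMMONIA)
  faMass <- vapply(which(keep), function(k)
    monoisotopicMass(acylFormula(m$carbons[k], m$doubleBonds[k])), 0)
  out <- data.frame(
    fa = .faLabel(m$carbons[keep], m$doubleBonds[keep]),
    fragmentMz = precursorMz - faMass - nh3,
    multiplicity = mult,
    precursorMz = precursorMz,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Class- and polarity-specific fragments of glycerophospholipids, PC and SM
#'
#' Positive mode (PC and SM, any annotation level): the phosphocholine
#' headgroup fragment at m/z 184.0733 plus the residual (unfragmented)
#' precursor ion, which carries the exact precursor mass into the MS/MS
#' spectrum and disambiguates isobaric PC/SM candidates sharing one
#' isolation step. Negative mode (molecular-level PE, PI, PS and PC as
#' formate adduct): the fatty acyl carboxylate anion of each distinct FA;
#' PS additionally shows the neutral loss of the serine headgroup
#' (precursor - 87.0320).
#'
#' @param species [LipidAnnotation-class] or shorthand string.
#' @param polarity `"+"` or `"-"`.
#' @return data.frame with columns `label`, `fragmentMz`, `multiplicity`,
#'   `precursorMz`.
#' @examples
#' gplFragments("PE 17:0-14:1", "-")
#' gplFragments("PC 34:1", "+")
#' @export
gplFragments <- function(species, polarity) {
  if (is.character(species)) species <- parseAnnotation(species)
  stopifnot(is(species, "LipidAnnotation"))
  cls <- species@lipidClass
  if (!polarity %in% c("+", "-"))
    stop("polarity must be '+' or '-'", call. = FALSE)
  if (!.ruleAllowed(cls, polarity))
    stop(sprintf("no fragment rule for %s in %s mode", cls, polarity),
         call. = FALSE)

  if (polarity == "+") {
    # PC / SM headgroup route
    precursorMz <- monoisotopicMz(elementalComposition(species), "+H")
    return(data.frame(
      label = c("headgroup", "precursor"),
      fragmentMz = c(.phosphocholineIonMz(), precursorMz),
      multiplicity = 1L,
      precursorMz = precursorMz,
      stringsAsFactors = FALSE))
  }

  if (species@level != "molecular")
    stop(sprintf("negative-mode FA fragments need a molecular-level %s species",
                 cls), call. = FALSE)
  adduct <- .classAdduct(cls, "-")
  precursorMz <- monoisotopicMz(elementalComposition(species), adduct)
  m <- species@moieties[!species@moieties$isLcb, , drop = FALSE]
  key <- paste(m$carbons, m$doubleBonds, sep = ":")
  keep <- !duplicated(key)
  mult <- as.vector(table(key)[key[keep]])
  anionMz <- vapply(which(keep), function(k)
    monoisotopicMz(acylFormula(m$carbons[k], m$doubleBonds[k]), "-H"), 0)
  out <- data.frame(
    label = .faLabel(m$carbons[keep], m$doubleBonds[keep]),
    fragmentMz = anionMz,
    multiplicity = mult,
    precursorMz = precursorMz,
    stringsAsFactors = FALSE)
  if (cls == "PS" && .ruleAllowed("PS", "-", "serine-loss")) {
    out <- rbind(out, data.frame(
      label = "NL serine",
      fragmentMz = precursorMz - monoisotopicMass(.SERINE_LOSS),
      multiplicity = 1L,
      precursorMz = precursorMz,
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
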