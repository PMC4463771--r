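#' @include annotation.R
NULL

.ELEMENTS <- c("C", "H", "N", "O", "P")

#' Build an elemental formula
#'
#' Formulas are plain named numeric vectors over C, H, N, O, P; negative
#' counts are only meaningful as intermediate differences.
#'
#' @param C,H,N,O,P Atom counts.
#' @return Named numeric vector of length 5.
#' @examples
#' elementalFormula(C = 5, H = 15, N = 1, O = 4, P = 1)  # phosphocholine ion
#' @export
elementalFormula <- function(C = 0, H = 0, N = 0, O = 0, P = 0) {
  c(C = C, H = H, N = N, O = O, P = P)
}

.fadd <- function(a, b, mult = 1) {
  out <- elementalFormula()
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + mult * b
  out
}

.WATER <- elementalFormula(H = 2, O = 1)
.AMMONIA <- elementalFormula(N = 1, H = 3)
.GLYCEROL <- elementalFormula(C = 3, H = 8, O = 3)
# glycerophospho-X backbones (neutral, free of acyls)
.BACKBONES <- list(
  PC = elementalFormula(C = 8, H = 20, N = 1, O = 6, P = 1),
  PE = elementalFormula(C = 5, H = 14, N = 1, O = 6, P = 1),
  PS = elementalFormula(C = 6, H = 14, N = 1, O = 8, P = 1),
  PI = elementalFormula(C = 9, H = 19, O = 11, P = 1)
)
.PHOSPHOCHOLINE <- elementalFormula(C = 5, H = 14, N = 1, O = 4, P = 1)
.SERINE_LOSS <- elementalFormula(C = 3, H = 5, N = 1, O = 2)

#' Elemental formula of a fatty acyl as free acid
#'
#' @param carbons,doubleBonds Chain length and number of double bonds.
#' @return CnH(2n-2d)O2 as a formula vector.
#' @export
acylFormula <- function(carbons, doubleBonds) {
  elementalFormula(C = carbons, H = 2 * carbons - 2 * doubleBonds, O = 2)
}

# sphingoid long-chain base: CcH(2c+3-2d)N(OH)h
.lcbFormula <- function(carbons, doubleBonds, hydroxyls = 2) {
  elementalFormula(C = carbons, H = 2 * carbons + 3 - 2 * doubleBonds,
                   N = 1, O = hydroxyls)
}

#' Neutral elemental composition of a lipid annotation
#'
#' Assembles backbone + headgroup + acyl chains minus one water per
#' ester/amide bond. The lipid class fixes the backbone, so a sum-level
#' annotation is sufficient for every supported class (for SM the LCB/FA
#' split does not change the formula given the `;2` dihydroxy base).
#'
#' @param annotation [LipidAnnotation-class] or shorthand string.
#' @return Named numeric formula vector (neutral molecule).
#' @examples
#' elementalComposition("TAG 52:2")   # C55 H102 O6
#' elementalComposition("PC 34:1")    # C42 H82 N O8 P
#' @export
elementalComposition <- function(annotation) {
  if (is.character(annotation)) annotation <- parseAnnotation(annotation)
  stopifnot(is(annotation, "LipidAnnotation"))
  cls <- annotation@lipidClass
  sc <- annotation@sumCarbons
  sd <- annotation@sumDoubleBonds
  acylSum <- function(nChains) {
    elementalFormula(C = sc, H = 2 * sc - 2 * sd, O = 2 * nChains)
  }
  if (cls == "FA") return(acylFormula(sc, sd))
  if (cls == "TAG") {
    f <- .fadd(.GLYCEROL, acylSum(3))
    return(.fadd(f, .WATER, mult = -3))
  }
  if (cls %in% .GPL_CLASSES) {
    f <- .fadd(.BACKBONES[[cls]], acylSum(2))
    return(.fadd(f, .WATER, mult = -2))
  }
  if (cls == "SM") {
    oh <- if (annotation@sumHydroxyls > 0) annotation@sumHydroxyls else 2L
    # combined LCB + amide FA, before bond formation
    chains <- elementalFormula(C = sc, H = 2 * sc + 3 - 2 * sd, N = 1,
                               O = oh + 2)
    f <- .fadd(chains, .PHOSPHOCHOLINE)
    return(.fadd(f, .WATER, mult = -2))  # amide + phosphoester
  }
  stop(sprintf("unsupported lipid class '%s'", cls), call. = FALSE)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Named numeric formula vector (see [elementalFormula()]).
#' @return Mass in u, summed from the packaged element mass table.
#' @export
monoisotopicMass <- function(formula) {
  masses <- elementMasses()
  if (!all(names(formula) %in% names(masses)))
    stop("formula contains unsupported elements", call. = FALSE)
  sum(formula * masses[names(formula)])
}

.ADDUCTS <- list(
  "+H"    = list(delta = elementalFormula(H = 1), charge = +1L),
  "+NH4"  = list(delta = elementalFormula(N = 1, H = 4), charge = +1L),
  "-H"    = list(delta = elementalFormula(H = -1), charge = -1L),
  "+HCOO" = list(delta = elementalFormula(C = 1, H = 1, O = 2), charge = -1L)
)

#' Supported ionization adducts
#'
#' @return Character vector of adduct names.
#' @export
adductNames <- function() names(.ADDUCTS)

#' m/z of a pre-formed ion
#'
#' Subtracts one electron mass per positive charge (adds per negative).
#'
#' @param formula Elemental formula of the ion (charge carriers included).
#' @param charge Signed integer charge; magnitude must be 1 and non-zero.
#' @return m/z value.
#' @examples
#' ionMz(elementalFormula(C = 5, H = 15, N = 1, O = 4, P = 1), +1)  # 184.0733
#' @export
ionMz <- function(formula, charge) {
  charge <- as.integer(charge)
  if (charge == 0L)
    stop("no m/z is defined for a neutral (charge 0)", call. = FALSE)
  if (abs(charge) != 1L)
    stop("only singly charged ions are supported", call. = FALSE)
  (monoisotopicMass(formula) - charge * electronMass()) / abs(charge)
}

#' m/z of a neutral molecule under an adduct
#'
#' @param formula Neutral elemental formula.
#' @param adduct One of `"+H"`, `"+NH4"`, `"-H"`, `"+HCOO"`.
#' @return m/z including the electron-mass correction.
#' @examples
#' monoisotopicMz(elementalComposition("TAG 52:2"), "+NH4")  # 876.802
#' @export
monoisotopicMz <- function(formula, adduct) {
  if (!adduct %in% names(.ADDUCTS))
    stop(sprintf("unknown adduct '%s'", adduct), call. = FALSE)
  a <- .ADDUCTS[[adduct]]
  ionMz(.fadd(formula, a$delta), a$charge)
}

#' Default adduct used per lipid class and polarity
#'
#' TAG ionizes as the ammonium adduct in positive mode; PC and SM as
#' protonated species for headgroup detection and PC as the formate adduct
#' for negative-mode fatty acyl fragments; PE, PS and PI as deprotonated
#' species.
#'
#' @return data.frame with columns `lipidClass`, `polarity`, `adduct`.
#' @export
defaultClassAdducts <- function() {
  data.frame(
    lipidClass = c("TAG", "PC", "SM", "PC", "PE", "PS", "PI"),
    polarity   = c("+", "+", "+", "-", "-", "-", "-"),
    adduct     = c("+NH4", "+H", "+H", "+HCOO", "-H", "-H", "-H"),
    stringsAsFactors = FALSE)
}

.classAdduct <- function(lipidClass, polarity) {
  tab <- defaultClassAdducts()
  hit <- tab$adduct[tab$lipidClass == lipidClass & tab$polarity == polarity]
  if (length(hit) != 1)
    stop(sprintf("no default adduct for %s in %s mode", lipidClass, polarity),
         call. = FALSE)
  hit
}

#' Fatty acyl pools
#'
#' `tagFaPool()` spans 4-20 carbons with 0-5 double bonds (the range
#' observed for TAG moieties in milk); `gplFaPool()` spans 12-22 carbons
#' (no short-chain glycerophospholipid moieties are observed). Double
#' bonds are additionally capped at carbons/2.
#'
#' @param carbons,doubleBonds Integer vectors spanning the pool.
#' @return data.frame with columns `carbons`, `doubleBonds`.
#' @export
faPool <- function(carbons, doubleBonds = 0:5) {
  pool <- expand.grid(carbons = as.integer(carbons),
                      doubleBonds = as.integer(doubleBonds))
  pool <- pool[pool$doubleBonds <= pool$carbons %/% 2, ]
  pool <- pool[order(pool$carbons, pool$doubleBonds), ]
  rownames(pool) <- NULL
  pool
}

#' @rdname faPool
#' @export
tagFaPool <- function() faPool(4:20, 0:5)

#' @rdname faPool
#' @export
gplFaPool <- function() faPool(12:22, 0:5)

.faLabel <- function(carbons, doubleBonds) {
  sprintf("FA %d:%d", carbons, doubleBonds)
}

#' Enumerate candidate molecular species from a fatty acyl pool
#'
#' Builds all acyl multisets (size 3 for TAG, size 2 for
#' glycerophospholipids, one fixed LCB plus one FA for SM) whose default
#' adduct m/z falls inside `mzRange`. Output is deduplicated and ordered
#' by class, then m/z.
#'
#' @param pool Fatty acyl pool data.frame (see [faPool()]).
#' @param classes Character vector of lipid classes to enumerate.
#' @param mzRange Numeric length-2 precursor m/z interval (default the
#'   400-1000 acquisition range); use `c(0, Inf)` for no bound.
#' @param lcb Length-2 integer vector (carbons, double bonds) of the
#'   dihydroxy long-chain base used for SM.
#' @return data.frame with columns `species`, `lipidClass`, `adduct`,
#'   `polarity`, `mz`.
#' @examples
#' enumerateCandidates(faPool(c(16, 18), c(0, 1)), "TAG", c(0, Inf))
#' @export
enumerateCandidates <- function(pool, classes, mzRange = c(400, 1000),
                                lcb = c(18L, 1L)) {
  if (length(classes) == 0 || nrow(pool) == 0)
    return(data.frame(species = character(), lipidClass = character(),
                      adduct = character(), polarity = character(),
                      mz = numeric()))
  bad <- setdiff(classes, setdiff(.LIPID_CLASSES, "FA"))
  if (length(bad))
    stop(sprintf("cannot enumerate class '%s'", bad[1]), call. = FALSE)
  n <- nrow(pool)
  faMass <- monoisotopicMass(elementalFormula(O = 2)) +
    pool$carbons * monoisotopicMass(elementalFormula(C = 1, H = 2)) -
    pool$doubleBonds * monoisotopicMass(elementalFormula(H = 2))
  labs <- .faLabel(pool$carbons, pool$doubleBonds)
  glycerolMass <- monoisotopicMass(.GLYCEROL)
  waterMass <- monoisotopicMass(.WATER)

  adductShift <- function(adduct) {
    a <- .ADDUCTS[[adduct]]
    monoisotopicMass(a$delta) - a$charge * electronMass()
  }
  out <- list()

  pairIdx <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  i <- pairIdx[, "row"]; j <- pairIdx[, "col"]

  for (cls in unique(classes)) {
    if (cls == "TAG") {
      reps <- n - j + 1L
      ii <- rep(i, reps); jj <- rep(j, reps)
      kk <- unlist(lapply(j, function(x) seq(x, n)), use.names = FALSE)
      mass <- glycerolMass + faMass[ii] + faMass[jj] + faMass[kk] -
        3 * waterMass
      mz <- mass + adductShift("+NH4")
      keep <- mz >= mzRange[1] & mz <= mzRange[2]
      if (any(keep)) {
        sp <- paste("TAG", paste(sub("^FA ", "", labs[ii[keep]]),
                                 sub("^FA ", "", labs[jj[keep]]),
                                 sub("^FA ", "", labs[kk[keep]]), sep = "-"))
        out[[cls]] <- data.frame(species = sp, lipidClass = cls,
                                 adduct = "+NH4", polarity = "+",
                                 mz = mz[keep], stringsAsFactors = FALSE)
      }
    } else if (cls %in% .GPL_CLASSES) {
      adduct <- .classAdduct(cls, "-")
      backboneMass <- monoisotopicMass(.BACKBONES[[cls]])
      mass <- backboneMass + faMass[i] + faMass[j] - 2 * waterMass
      mz <- mass + adductShift(adduct)
      keep <- mz >= mzRange[1] & mz <= mzRange[2]
      if (any(keep)) {
        sp <- paste(cls, paste(sub("^FA ", "", labs[i[keep]]),
                               sub("^FA ", "", labs[j[keep]]), sep = "-"))
        out[[cls]] <- data.frame(species = sp, lipidClass = cls,
                                 adduct = adduct, polarity = "-",
                                 mz = mz[keep], stringsAsFactors = FALSE)
      }
    } else if (cls == "SM") {
      lcbMass <- monoisotopicMass(.lcbFormula(lcb[1], lcb[2]))
      mass <- lcbMass + faMass + monoisotopicMass(.PHOSPHOCHOLINE) -
        2 * waterMass
      mz <- mass + adductShift("+H")
      keep <- mz >= mzRange[1] & mz <= mzRange[2]
      if (any(keep)) {
        sp <- sprintf("SM %d:%d;2/%d:%d", lcb[1], lcb[2],
                      pool$carbons[keep], pool$doubleBonds[keep])
        out[[cls]] <- data.frame(species = sp, lipidClass = cls,
                                 adduct = "+H", polarity = "+",
                                 mz = mz[keep], stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(species = character(), lipidClass = character(),
                      adduct = character(), polarity = character(),
                      mz = numeric()))
  res <- res[!duplicated(res$species), ]
  res <- res[order(res$lipidClass, res$mz), ]
  rownames(res) <- NULL
  res
}
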