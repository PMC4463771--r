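#' @include AllClasses.R
NULL

.parseMoietyToken <- function(token, context) {
  m <- regmatches(token, regexec("^([0-9]+):([0-9]+)(;([0-9]+))?$", token))[[1]]
  if (length(m) == 0)
    stop(sprintf("malformed moiety token '%s' in '%s' (expected carbons:doubleBonds)",
                 token, context), call. = FALSE)
  carbons <- as.integer(m[2])
  db <- as.integer(m[3])
  oh <- if (nzchar(m[5])) as.integer(m[5]) else 0L
  if (carbons < 2L)
    stop(sprintf("moiety '%s': carbons must be >= 2", token), call. = FALSE)
  if (db > carbons %/% 2)
    stop(sprintf("moiety '%s': too many double bonds for %d carbons",
                 token, carbons), call. = FALSE)
  c(carbons = carbons, doubleBonds = db, hydroxyls = oh)
}

.newAnnotation <- function(lipidClass, level, sumCarbons, sumDoubleBonds,
                           sumHydroxyls = 0L, moieties = NULL) {
  if (is.null(moieties))
    moieties <- data.frame(carbons = integer(), doubleBonds = integer(),
                           hydroxyls = integer(), isLcb = logical())
  new("LipidAnnotation", lipidClass = lipidClass, level = level,
      sumCarbons = as.integer(sumCarbons),
      sumDoubleBonds = as.integer(sumDoubleBonds),
      sumHydroxyls = as.integer(sumHydroxyls), moieties = moieties)
}

#' Parse a shorthand lipid annotation
#'
#' Understands sum-composition names (`"TAG 52:2"`, `"SM 34:1;2"`),
#' molecular-species names with `-`-separated fatty acyl moieties
#' (`"PC 16:0-18:1"`, `"TAG 4:0-16:0-16:0"`; an en-dash is accepted as
#' well), sphingomyelin with an explicit long-chain base
#' (`"SM 18:1;2/17:0"`, where `;2` marks a dihydroxy base), and free fatty
#' acids (`"FA 16:0"`). The moiety separator does not encode sn-positions.
#'
#' @param text A single non-empty annotation string.
#' @return A [LipidAnnotation-class] object; `formatAnnotation()` round-trips
#'   it (emitting plain hyphens).
#' @examples
#' parseAnnotation("TAG 52:2")
#' parseAnnotation("PC 16:0-18:1")
#' parseAnnotation("SM 18:1;2/17:0")
#' @export
parseAnnotation <- function(text) {
  if (!is.character(text) || length(text) != 1 || !nzchar(trimws(text)))
    stop("annotation must be a single non-empty string", call. = FALSE)
  s <- trimws(gsub("–", "-", text))
  sp <- regexpr(" ", s, fixed = TRUE)
  if (sp < 0)
    stop(sprintf("malformed annotation '%s': missing composition after class", s),
         call. = FALSE)
  cls <- substr(s, 1L, sp - 1L)
  rest <- trimws(substr(s, sp + 1L, nchar(s)))
  if (!cls %in% .LIPID_CLASSES)
    stop(sprintf("unknown lipid class '%s' in '%s'", cls, s), call. = FALSE)

  if (cls == "SM" && grepl("/", rest, fixed = TRUE)) {
    parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed SM annotation '%s': expected LCB/FA", s),
           call. = FALSE)
    lcb <- .parseMoietyToken(parts[1], s)
    if (lcb["hydroxyls"] < 1L)
      stop(sprintf("SM long-chain base '%s' must state its hydroxyls (e.g. 18:1;2)",
                   parts[1]), call. = FALSE)
    fa <- .parseMoietyToken(parts[2], s)
    m <- data.frame(carbons = c(lcb["carbons"], fa["carbons"]),
                    doubleBonds = c(lcb["doubleBonds"], fa["doubleBonds"]),
                    hydroxyls = c(lcb["hydroxyls"], 0L),
                    isLcb = c(TRUE, FALSE), row.names = NULL)
    return(.newAnnotation("SM", "molecular", sum(m$carbons),
                          sum(m$doubleBonds), lcb["hydroxyls"], m))
  }

  if (grepl("-", rest, fixed = TRUE)) {
    tokens <- strsplit(rest, "-", fixed = TRUE)[[1]]
    expected <- switch(cls, TAG = 3L, PC = 2L, PE = 2L, PS = 2L, PI = 2L,
                       SM = NA_integer_, FA = 1L)
    if (is.na(expected))
      stop(sprintf("SM molecular species use LCB/FA notation, not '-' ('%s')", s),
           call. = FALSE)
    if (length(tokens) != expected)
      stop(sprintf("%s needs %d moieties, got %d in '%s'",
                   cls, expected, length(tokens), s), call. = FALSE)
    parsed <- lapply(tokens, .parseMoietyToken, context = s)
    m <- data.frame(carbons = vapply(parsed, `[[`, 0, "carbons"),
                    doubleBonds = vapply(parsed, `[[`, 0, "doubleBonds"),
                    hydroxyls = 0L, isLcb = FALSE)
    return(.newAnnotation(cls, "molecular", sum(m$carbons), sum(m$doubleBonds),
                          0L, m))
  }

  tok <- .parseMoietyToken(rest, s)
  if (cls == "FA") {
    m <- data.frame(carbons = tok["carbons"], doubleBonds = tok["doubleBonds"],
                    hydroxyls = 0L, isLcb = FALSE, row.names = NULL)
    return(.newAnnotation("FA", "molecular", tok["carbons"],
                          tok["doubleBonds"], 0L, m))
  }
  if (cls == "SM") {
    if (tok["hydroxyls"] < 1L)
      stop(sprintf("SM sum composition must state LCB hydroxyls (e.g. 'SM 34:1;2'), got '%s'", s),
           call. = FALSE)
  } else if (tok["hydroxyls"] != 0L) {
    stop(sprintf("hydroxyl count is only meaningful for SM ('%s')", s),
         call. = FALSE)
  }
  .newAnnotation(cls, "sum", tok["carbons"], tok["doubleBonds"],
                 tok["hydroxyls"])
}

.formatMoiety <- function(carbons, doubleBonds, hydroxyls = 0L) {
  base <- sprintf("%d:%d", carbons, doubleBonds)
  if (hydroxyls > 0L) paste0(base, ";", hydroxyls) else base
}

#' Format a LipidAnnotation back to shorthand text
#'
#' Inverse of [parseAnnotation()]; always emits plain hyphens.
#'
#' @param annotation A [LipidAnnotation-class] object.
#' @return A single string.
#' @examples
#' formatAnnotation(parseAnnotation("PC 16:0–18:1"))
#' @export
formatAnnotation <- function(annotation) {
  stopifnot(is(annotation, "LipidAnnotation"))
  cls <- annotation@lipidClass
  if (annotation@level == "sum") {
    return(paste(cls, .formatMoiety(annotation@sumCarbons,
                                    annotation@sumDoubleBonds,
                                    annotation@sumHydroxyls)))
  }
  m <- annotation@moieties
  if (cls == "SM") {
    lcb <- m[m$isLcb, ]
    fa <- m[!m$isLcb, ]
    return(paste0("SM ", .formatMoiety(lcb$carbons, lcb$doubleBonds,
                                       lcb$hydroxyls),
                  "/", .formatMoiety(fa$carbons, fa$doubleBonds)))
  }
  paste(cls, paste(mapply(.formatMoiety, m$carbons, m$doubleBonds),
                   collapse = "-"))
}

#' @describeIn parseAnnotation Lipid class accessor.
#' @param annotation A [LipidAnnotation-class] object.
#' @export
lipidClass <- function(annotation) annotation@lipidClass

#' @describeIn parseAnnotation Annotation level accessor ("sum" or
#'   "molecular").
#' @export
annotationLevel <- function(annotation) annotation@level

#' @describeIn parseAnnotation Sum composition accessor, a named integer
#'   vector with elements `carbons`, `doubleBonds`, `hydroxyls`.
#' @export
sumComposition <- function(annotation) {
  c(carbons = annotation@sumCarbons, doubleBonds = annotation@sumDoubleBonds,
    hydroxyls = annotation@sumHydroxyls)
}

#' @describeIn parseAnnotation Moieties accessor (data.frame; zero rows at
#'   sum level).
#' @export
moieties <- function(annotation) annotation@moieties

setMethod("show", "LipidAnnotation", function(object) {
  cat(sprintf("LipidAnnotation: %s [%s level]\n", formatAnnotation(object),
              object@level))
  invisible(NULL)
})
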