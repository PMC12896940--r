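#' Ovarian structure taxonomy
#'
#' The stereological reading of an ovarian cross section assigns every grid
#' point to one of 19 cellular-structure categories. Twelve of these are the
#' main germline cells (oogonia through atretic oocytes); the remaining seven
#' are somatic or technical categories (lysis, blood vessel, intercellular
#' space, gonadal wall, connective tissue, unnatural emptiness, undetermined)
#' that absorb points not landing on a follicle.
#'
#' `structureCodes()` returns the 19 canonical code strings in taxonomy
#' order; `germlineCodes()` returns the 12 germline codes.
#' `resolveStructureCodes()` maps user-supplied codes onto the canonical set,
#' resolving the two historical alias spellings (`"aoA"` for `"oaA"`,
#' `"aoB"` for `"aoB"`'s canonical `"oaB"`); unknown codes are an error,
#' never silently dropped.
#'
#' @param codes character vector of structure codes, canonical or aliased.
#' @return `structureCodes()` and `germlineCodes()` return character
#'   vectors; `resolveStructureCodes()` returns `codes` with every element
#'   replaced by its canonical spelling.
#' @examples
#' structureCodes()
#' resolveStructureCodes(c("aoA", "po1"))
#' @export
structureCodes <- function() {
  c("og", "po1", "po2", "cao", "vit1", "vit2", "vit3", "pho", "ho",
    "POF", "oaA", "oaB", "L", "cs", "ei", "pg", "tc", "v", "i")
}

#' @rdname structureCodes
#' @export
germlineCodes <- function() {
  c("og", "po1", "po2", "cao", "vit1", "vit2", "vit3", "pho", "ho",
    "POF", "oaA", "oaB")
}

.STRUCTURE_ALIASES <- c(aoA = "oaA", aoB = "oaB")

#' @rdname structureCodes
#' @export
resolveStructureCodes <- function(codes) {
  codes <- as.character(codes)
  hit <- codes %in% names(.STRUCTURE_ALIASES)
  codes[hit] <- .STRUCTURE_ALIASES[codes[hit]]
  bad <- setdiff(unique(codes), structureCodes())
  if (length(bad))
    stop("unknown structure code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  codes
}

#' @rdname structureCodes
#' @param x character vector of codes (canonical; aliases are resolved first).
#' @export
isGermline <- function(x) resolveStructureCodes(x) %in% germlineCodes()

# Phase and stage label sets used throughout.
.PHASES <- c("A", "B", "C", "D", "E")
.STAGES <- c("1", "2", "3", "4")

#' @rdname structureCodes
#' @export
maturityPhases <- function() .PHASES

#' @rdname structureCodes
#' @export
macroscopicStages <- function() .STAGES
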