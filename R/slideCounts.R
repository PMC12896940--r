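#' Construct a SlideCountSet
#'
#' Builds a [SlideCountSet-class] from a hit-count matrix (or a named vector
#' for a single slide). Structure codes may be given in any order, may use
#' the alias spellings (`"aoA"`/`"aoB"`), and may omit structures that
#' received no points: rows are reordered, aliases resolved and missing
#' structures filled with zeros. Unknown codes are an error.
#'
#' @param hits integer matrix, structures x slides (rownames = structure
#'   codes, colnames = slide ids), or a named integer vector for one slide.
#' @param totalPoints per-slide total grid points; defaults to the column
#'   sums of `hits`. A mismatch between supplied totals and column sums is
#'   an inconsistency error naming the slide.
#' @param slideId,fishId,ovary,position per-slide metadata, recycled to the
#'   number of slides. Defaults: `colnames(hits)`, `fishId = slideId`,
#'   ventral ovary (`"V"`) at the median position (2) — the designated
#'   staging section.
#' @param expectedRange length-2 numeric; totals outside it raise a warning
#'   (not an error). The grid design uses 500-600 points per slide.
#' @return a [SlideCountSet-class].
#' @examples
#' scs <- SlideCountSet(c(po1 = 300, po2 = 150, tc = 50), slideId = "s1")
#' fractionEstimates(scs)[c("po1", "po2", "tc"), ]
#' @export
SlideCountSet <- function(hits, totalPoints = NULL,
                          slideId = colnames(hits), fishId = slideId,
                          ovary = "V", position = 2,
                          expectedRange = c(500, 600)) {
  if (is.vector(hits)) hits <- matrix(hits, ncol = 1L,
                                      dimnames = list(names(hits), NULL))
  if (is.null(rownames(hits)))
    stop("'hits' must have structure codes as rownames", call. = FALSE)
  rownames(hits) <- resolveStructureCodes(rownames(hits))
  if (any(duplicated(rownames(hits))))
    stop("duplicated structure rows after alias resolution", call. = FALSE)
  full <- matrix(0L, nrow = 19L, ncol = ncol(hits),
                 dimnames = list(structureCodes(), colnames(hits)))
  full[rownames(hits), ] <- as.integer(round(hits))
  if (is.null(slideId))
    slideId <- sprintf("slide_%03d", seq_len(ncol(full)))
  colnames(full) <- slideId
  sums <- colSums(full)
  if (is.null(totalPoints)) {
    totalPoints <- sums
  } else {
    totalPoints <- rep(as.integer(totalPoints), length.out = ncol(full))
    if (any(totalPoints <= 0))
      stop("invalid slide: total_points must be positive", call. = FALSE)
    bad <- which(sums != totalPoints)
    if (length(bad))
      stop("hit counts do not sum to total_points for slide(s): ",
           paste(slideId[bad], collapse = ", "), call. = FALSE)
  }
  if (any(totalPoints <= 0))
    stop("invalid slide: total_points must be positive", call. = FALSE)
  out <- which(totalPoints < expectedRange[1] | totalPoints > expectedRange[2])
  if (length(out))
    warning("total_points outside expected range [",
            expectedRange[1], ", ", expectedRange[2], "] for slide(s): ",
            paste(slideId[out], collapse = ", "), call. = FALSE)
  cd <- DataFrame(slide_id = slideId,
                  fish_id = rep(as.character(fishId), length.out = ncol(full)),
                  ovary = rep(as.character(ovary), length.out = ncol(full)),
                  position = rep(as.integer(position), length.out = ncol(full)),
                  total_points = as.integer(totalPoints))
  new("SlideCountSet",
      SummarizedExperiment(assays = list(hits = full), colData = cd))
}

#' Point-count area-fraction estimates
#'
#' The stereological fraction estimator: a grid of 500-600 equidistant
#' points is overlaid on the ovarian section, and the area fraction of each
#' structure is estimated by the percentage of grid points hitting it,
#' \deqn{\mathrm{fract\_estim} = (100 / \mathrm{total\_points}) \times
#'   \mathrm{hit\_points}.}
#' Fractions are reported for all 19 structures (absent structures yield 0)
#' and sum to 100 per slide.
#'
#' @param x a [SlideCountSet-class], or a named numeric vector of hit counts
#'   for a single slide.
#' @param totalPoints for the vector method, the total number of grid
#'   points; defaults to `sum(x)`.
#' @param ... unused.
#' @return For a `SlideCountSet`, a 19 x n numeric matrix of percentages
#'   (rows = structures, columns = slides); for a vector, a named numeric
#'   vector over the 19 canonical codes.
#' @examples
#' fractionEstimates(c(po1 = 100, tc = 400))[["po1"]]  # 20
#' @rdname fractionEstimates
#' @export
setMethod("fractionEstimates", "SlideCountSet", function(x, ...) {
  tp <- colData(x)$total_points
  f <- sweep(hitCounts(x), 2L, tp, function(h, n) 100 * h / n)
  colnames(f) <- colData(x)$slide_id
  f
})

#' @rdname fractionEstimates
#' @export
setMethod("fractionEstimates", "numeric", function(x, totalPoints = sum(x), ...) {
  if (length(totalPoints) != 1L || totalPoints <= 0)
    stop("invalid slide: total_points must be a single positive number",
         call. = FALSE)
  v <- stats::setNames(numeric(19L), structureCodes())
  if (length(x)) {
    names(x) <- resolveStructureCodes(names(x))
    if (any(x < 0)) stop("negative hit counts", call. = FALSE)
    if (sum(x) != totalPoints)
      stop("hit counts do not sum to total_points", call. = FALSE)
    v[names(x)] <- v[names(x)] + unname(100 * x / totalPoints)
  }
  v
})

#' Germline hit counts
#'
#' Restriction of a slide's hit counts to the 12 main germline cell
#' categories (oogonia through beta-atretic oocytes). Together with the 7
#' somatic/technical categories these partition the grid, so germline plus
#' non-germline hits always sum to `total_points`.
#'
#' @param x a [SlideCountSet-class].
#' @return integer matrix, 12 germline structures x slides.
#' @rdname germlineCounts
#' @export
setMethod("germlineCounts", "SlideCountSet", function(x) {
  hitCounts(x)[germlineCodes(), , drop = FALSE]
})

# ---- CSV readers / writers --------------------------------------------------

#' Read and write slide-count tables
#'
#' Counts tables are UTF-8 CSV with a header row. The long format has one
#' row per (slide, structure) with columns `slide_id, fish_id, ovary,
#' position, structure, hit_points, total_points`; zero rows may be omitted.
#' The wide format has one row per slide with one column per structure code
#' plus the same metadata columns. `readCountsCSV()` auto-detects the
#' format, resolves structure-code aliases and validates row by row;
#' `writeCountsCSV()` writes the long format (zero rows omitted).
#'
#' @param path file path.
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @param expectedRange passed to [SlideCountSet()].
#' @return `readCountsCSV()` returns a [SlideCountSet-class];
#'   `writeCountsCSV()` invisibly returns `path`.
#' @export
readCountsCSV <- function(path, format = c("auto", "long", "wide"),
                          expectedRange = c(500, 600)) {
  format <- match.arg(format)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "auto")
    format <- if ("structure" %in% colnames(df)) "long" else "wide"
  if (format == "long") {
    need <- c("slide_id", "structure", "hit_points", "total_points")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
      stop("counts CSV lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    bad <- which(df$hit_points < 0 | df$hit_points != round(df$hit_points))
    if (length(bad))
      stop("invalid hit_points at row(s) ", paste(bad + 1L, collapse = ", "),
           " of ", path, call. = FALSE)
    df$structure <- resolveStructureCodes(df$structure)
    slides <- unique(df$slide_id)
    hits <- matrix(0L, 19L, length(slides),
                   dimnames = list(structureCodes(), slides))
    idx <- cbind(match(df$structure, structureCodes()),
                 match(df$slide_id, slides))
    if (anyDuplicated(idx))
      stop("duplicated (slide, structure) rows in ", path, call. = FALSE)
    hits[idx] <- as.integer(df$hit_points)
    meta <- df[!duplicated(df$slide_id), , drop = FALSE]
    meta <- meta[match(slides, meta$slide_id), ]
  } else {
    codes <- intersect(c(structureCodes(), names(.STRUCTURE_ALIASES)),
                       colnames(df))
    if (!length(codes))
      stop("wide counts CSV has no structure columns", call. = FALSE)
    hits <- t(as.matrix(df[, codes, drop = FALSE]))
    colnames(hits) <- df$slide_id
    meta <- df
  }
  SlideCountSet(hits,
                totalPoints = meta$total_points,
                slideId = meta$slide_id,
                fishId = if ("fish_id" %in% colnames(meta)) meta$fish_id
                         else meta$slide_id,
                ovary = if ("ovary" %in% colnames(meta)) meta$ovary else "V",
                position = if ("position" %in% colnames(meta)) meta$position
                           else 2L,
                expectedRange = expectedRange)
}

#' @rdname readCountsCSV
#' @param x a [SlideCountSet-class].
#' @export
writeCountsCSV <- function(x, path) {
  h <- hitCounts(x)
  cd <- as.data.frame(colData(x))
  long <- data.frame(
    slide_id = rep(cd$slide_id, each = nrow(h)),
    fish_id = rep(cd$fish_id, each = nrow(h)),
    ovary = rep(cd$ovary, each = nrow(h)),
    position = rep(cd$position, each = nrow(h)),
    structure = rep(rownames(h), ncol(h)),
    hit_points = as.vector(h),
    total_points = rep(cd$total_points, each = nrow(h)))
  long <- long[long$hit_points > 0, , drop = FALSE]
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
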