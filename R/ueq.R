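#' Default UEQ item map
#'
#' The 26-item User Experience Questionnaire scores six scales:
#' attractiveness (6 items), perspicuity, efficiency, dependability,
#' stimulation and novelty (4 items each). Items are interleaved across
#' scales in the questionnaire and half of them are reverse-keyed. The item
#' wording is instrument-specific; the map ships as editable data -- scoring
#' depends only on each item's scale membership and polarity, and any map
#' with the (6, 4, 4, 4, 4, 4) structure is accepted.
#'
#' @return `data.frame` with columns `item` (1-26), `scale`, `reversed`.
#' @export
ueq_item_map <- function() {
  scale <- character(26)
  scale[c(1, 12, 14, 16, 24, 25)] <- "attractiveness"
  scale[c(2, 4, 13, 21)] <- "perspicuity"
  scale[c(9, 20, 22, 23)] <- "efficiency"
  scale[c(8, 11, 17, 19)] <- "dependability"
  scale[c(5, 6, 7, 18)] <- "stimulation"
  scale[c(3, 10, 15, 26)] <- "novelty"
  data.frame(item = 1:26, scale = scale,
             reversed = (1:26) %% 2 == 1)
}

ueq_scale_names <- c("attractiveness", "perspicuity", "efficiency",
                     "dependability", "stimulation", "novelty")

validate_item_map <- function(item_map) {
  stopifnot(nrow(item_map) == 26,
            all(sort(item_map$item) == 1:26),
            all(item_map$scale %in% ueq_scale_names))
  sizes <- table(factor(item_map$scale, levels = ueq_scale_names))
  if (!all(sizes == c(6, 4, 4, 4, 4, 4)))
    stop("item map must assign 6/4/4/4/4/4 items to the six scales")
  invisible(item_map)
}

#' Score a UEQ response
#'
#' Each answer on the 1-7 scale is recoded to \[-3, +3\] (normal polarity:
#' `answer - 4`; reversed: `4 - answer`); a scale is the mean of its
#' recoded items. A scale with fewer than half of its items answered is
#' returned as `NA`. The pragmatic-quality index averages perspicuity,
#' efficiency and dependability; hedonic quality averages stimulation and
#' novelty.
#'
#' @param answers numeric vector of 26 answers in 1-7 (in item order;
#'   `NA` = unanswered), or a `data.frame`/matrix with 26 such columns (one
#'   row per respondent).
#' @param item_map item-to-scale map, see [ueq_item_map()].
#' @return `data.frame` with the six scale means, `pragmatic` and `hedonic`.
#' @export
#' @examples
#' score_ueq(rep(4, 26)) # all scales 0
score_ueq <- function(answers, item_map = ueq_item_map()) {
  validate_item_map(item_map)
  if (is.vector(answers)) answers <- matrix(answers, nrow = 1)
  answers <- as.matrix(answers)
  stopifnot(ncol(answers) == 26)
  if (any(!is.na(answers) & (answers < 1 | answers > 7 |
                             answers != round(answers))))
    stop("answers must be integers in 1..7")
  item_map <- item_map[order(item_map$item), ]
  rec <- sweep(answers, 2, 4)                     # answer - 4
  rev_cols <- which(item_map$reversed)
  rec[, rev_cols] <- -rec[, rev_cols]             # 4 - answer
  out <- as.data.frame(lapply(ueq_scale_names, function(sc) {
    cols <- which(item_map$scale == sc)
    vals <- rec[, cols, drop = FALSE]
    answered <- rowSums(!is.na(vals))
    m <- rowMeans(vals, na.rm = TRUE)
    m[answered < length(cols) / 2] <- NA
    m
  }))
  names(out) <- ueq_scale_names
  out$pragmatic <- rowMeans(out[c("perspicuity", "efficiency", "dependability")])
  out$hedonic <- rowMeans(out[c("stimulation", "novelty")])
  out
}

#' Default UEQ benchmark table
#'
#' Reads the benchmark configuration shipped with the package
#' (`inst/extdata/ueq_benchmark.csv`): per scale, the lower thresholds of
#' the excellent / good / above-average / below-average bands, derived from
#' a reference distribution of software evaluations. The file is editable
#' configuration, not an asserted constant.
#'
#' @param path optional path to an alternative benchmark CSV.
#' @return `data.frame` with `scale` and the four threshold columns.
#' @export
ueq_benchmark <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ueq_benchmark.csv", package = "cctrial")
  bm <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("scale", "excellent", "good", "above_average", "below_average")
  missing_cols <- setdiff(needed, names(bm))
  if (length(missing_cols))
    stop("malformed benchmark: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  thr <- as.matrix(bm[, needed[-1]])
  bad <- which(apply(thr, 1, function(r) any(diff(r) >= 0)))
  if (length(bad))
    stop("malformed benchmark: thresholds not strictly decreasing in row(s) ",
         paste(bad, collapse = ", "), " (line ",
         paste(bad + 1, collapse = ", "), " of the file)")
  bm
}

#' Classify UEQ scales against a benchmark
#'
#' A scale lands in the highest band whose threshold it strictly exceeds
#' ("better than" the reference share); a value exactly at a threshold falls
#' to the band below.
#'
#' @param scales one-row result of [score_ueq()] (or any named list of scale
#'   values).
#' @param benchmark benchmark table, see [ueq_benchmark()].
#' @return `data.frame` with `scale`, `value`, `category`.
#' @export
classify_benchmark <- function(scales, benchmark = ueq_benchmark()) {
  bands <- c("excellent", "good", "above average", "below average", "poor")
  rows <- lapply(intersect(ueq_scale_names, names(scales)), function(sc) {
    v <- scales[[sc]][1]
    b <- benchmark[benchmark$scale == sc, ]
    if (nrow(b) != 1) stop("benchmark has no row for scale ", sc)
    thr <- as.numeric(b[c("excellent", "good", "above_average", "below_average")])
    cat_idx <- match(TRUE, v > thr, nomatch = 5)
    data.frame(scale = sc, value = v, category = bands[cat_idx])
  })
  do.call(rbind, rows)
}

#' Group comparison of UEQ scales from summary statistics
#'
#' Delegates to [cohen_d_independent()] per scale and attaches the
#' conventional interpretation band.
#'
#' @param summaries `data.frame` with columns `scale`, `mean1`, `sd1`,
#'   `n1`, `mean2`, `sd2`, `n2`.
#' @return `data.frame` with `scale`, `cohen_d`, `band`.
#' @export
compare_groups <- function(summaries) {
  stopifnot(all(c("scale", "mean1", "sd1", "n1", "mean2", "sd2", "n2") %in%
                  names(summaries)))
  d <- mapply(cohen_d_independent, summaries$mean1, summaries$sd1,
              summaries$n1, summaries$mean2, summaries$sd2, summaries$n2)
  data.frame(scale = summaries$scale, cohen_d = d,
             band = effect_size_band(d, "cohen_d"))
}
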