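#' Map a membranous-staining proportion to a core score
#'
#' The per-core IHC score is the proportion of tumor cells with membranous
#' staining binned on a zero-to-ten scale: 0 maps to score 0 and each
#' subsequent decile (1-10%, 11-20%, ..., 91-100%) to scores 1 through 10,
#' i.e. \code{ceiling(pct / 10)} for positive proportions. Fractional
#' percentages are allowed; scores are always integers.
#'
#' @param pct percentage(s) in [0, 100].
#' @return integer score(s) in 0..10.
#' @examples
#' proportion_to_score(c(0, 10, 10.5, 55, 100))  # 0 1 2 6 10
#' @export
proportion_to_score <- function(pct) {
  if (any(is.na(pct)) || !is.numeric(pct))
    stop("`pct` must be numeric with no missing values")
  if (any(pct < 0 | pct > 100))
    stop("percentages must lie in [0, 100]")
  as.integer(ifelse(pct == 0, 0L, ceiling(pct / 10)))
}

#' Aggregate duplicate cores to a per-site IHC score
#'
#' Each (case, marker, site) is represented by up to two replicate cores
#' scored 0-10; the site-level IHC score is their sum on a 0-20 scale. When
#' only one core is available the score is doubled to stay on the 0-20 scale
#' and flagged as imputed so downstream analyses can exclude it; when no
#' core is available the value is missing.
#'
#' @param cores data frame with columns \code{case_id}, \code{marker},
#'   \code{site} (\code{"Pr"} or \code{"LN"}), \code{replicate} (1 or 2) and
#'   \code{score} (integer 0-10). Missing cores are simply absent rows (or
#'   rows with \code{NA} score).
#' @return data frame with one row per observed (case, marker, site):
#'   \code{case_id}, \code{marker}, \code{site}, \code{value} (0-20 or
#'   \code{NA}) and \code{imputed}.
#' @export
aggregate_cores <- function(cores) {
  req <- c("case_id", "marker", "site", "replicate", "score")
  if (!all(req %in% names(cores)))
    stop("`cores` must have columns: ", paste(req, collapse = ", "))
  sc <- cores$score
  if (any(!is.na(sc) & (sc < 0 | sc > 10 | sc != floor(sc))))
    stop("core scores must be integers in 0..10")
  key <- interaction(cores$case_id, cores$marker, cores$site, drop = TRUE)
  if (any(table(key) > 2))
    stop("more than two replicate cores for some (case, marker, site)")
  agg <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) c(NA_integer_, NA) else
      if (length(v) == 1) c(2L * v, TRUE) else c(sum(v), FALSE)
  }
  out <- do.call(rbind, lapply(split(seq_along(key), key), function(i) {
    a <- agg(cores$score[i])
    data.frame(case_id = cores$case_id[i[1]],
               marker = cores$marker[i[1]],
               site = cores$site[i[1]],
               value = as.integer(a[1]),
               imputed = as.logical(a[2]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$case_id, out$marker, out$site), , drop = FALSE]
}

#' Marker-specific band scheme on the 0-20 IHC score
#'
#' Bands classify the 0-20 site-level IHC score into strong/homogeneous
#' (\code{++}), moderate (\code{+}) and weak/negative (\code{-}) staining.
#' Defaults: CDH17 ++ 18-20, + 9-17, - 0-8; CLDN18 ++ 14-20, + 6-13,
#' - 0-5; CLDN7 ++ 12-20, + 8-11, - 0-7. The CLDN18 and CLDN7 negative
#' bands are derived as complements of the stated \code{+}/\code{++}
#' ranges within 0-20 and flagged as such in the scheme metadata.
#'
#' @param bands named list (one element per marker, names matched
#'   case-insensitively) of lists with integer vectors \code{"++"},
#'   \code{"+"}, \code{"-"} of \code{c(lo, hi)} bounds. The three intervals
#'   of each marker must partition 0..20.
#' @return An object of class \code{"band_scheme"}.
#' @export
band_scheme <- function(bands = list(
    CDH17  = list(`++` = c(18, 20), `+` = c(9, 17), `-` = c(0, 8)),
    CLDN18 = list(`++` = c(14, 20), `+` = c(6, 13), `-` = c(0, 5)),
    CLDN7  = list(`++` = c(12, 20), `+` = c(8, 11), `-` = c(0, 7)))) {
  for (m in names(bands)) {
    b <- bands[[m]]
    if (!setequal(names(b), c("++", "+", "-")))
      stop("marker ", m, ": bands must be named '++', '+', '-'")
    covered <- sort(as.integer(unlist(
      lapply(b, function(iv) seq(iv[1], iv[2])))))
    if (!identical(covered, 0:20))
      stop("marker ", m, ": band intervals must partition 0..20 ",
           "with no gaps or overlaps")
  }
  derived <- c(CLDN18 = "'-' range derived as complement of printed bands",
               CLDN7 = "'-' range derived as complement of printed bands")
  structure(list(bands = stats::setNames(bands, norm_label(names(bands))),
                 marker_names = stats::setNames(names(bands),
                                                norm_label(names(bands))),
                 derived_notes = derived),
            class = "band_scheme")
}

#' Band label for an IHC score
#'
#' @param marker marker id (case-insensitive).
#' @param value integer IHC score(s) 0-20; \code{NA} yields \code{NA}.
#' @param scheme a \code{\link{band_scheme}}.
#' @return character vector of band labels \code{"++"}, \code{"+"},
#'   \code{"-"} (or \code{NA} for missing values).
#' @examples
#' band("CDH17", c(20, 17, 8))  # "++" "+" "-"
#' @export
band <- function(marker, value, scheme = band_scheme()) {
  stopifnot(inherits(scheme, "band_scheme"))
  m <- norm_label(marker)
  if (length(m) != 1 || !m %in% names(scheme$bands))
    stop("no band scheme for marker: ", marker)
  ok <- !is.na(value)
  if (any(value[ok] < 0 | value[ok] > 20 | value[ok] != floor(value[ok])))
    stop("IHC scores must be integers in 0..20")
  b <- scheme$bands[[m]]
  out <- rep(NA_character_, length(value))
  for (lab in c("++", "+", "-")) {
    iv <- b[[lab]]
    out[ok & value >= iv[1] & value <= iv[2]] <- lab
  }
  out
}

#' Classify a case into an expression subgroup from its CDH17/CLDN18 bands
#'
#' The three subgroups partition cases by their joint CDH17/CLDN18 staining
#' pattern of the primary lesion: Group 1 is strong homogeneous CDH17 with
#' absent-to-moderate CLDN18 (\code{CDH17 ++ / CLDN18 + or -}); Group 2 is
#' both strong (\code{++/++}) or both moderate (\code{+/+}); Group 3 is weak
#' or negative CDH17 with any CLDN18 (\code{- / any}). The remaining
#' combinations (\code{CDH17 +} with \code{CLDN18 ++} or \code{-}) fall
#' outside the rules and are returned as \code{"unclassified"}. Missing
#' bands yield \code{NA}.
#'
#' @param cdh17_band,cldn18_band band labels (\code{"++"}, \code{"+"},
#'   \code{"-"}), recycled to common length.
#' @return character vector with values \code{"Group1"}, \code{"Group2"},
#'   \code{"Group3"}, \code{"unclassified"} or \code{NA}.
#' @examples
#' classify_group("++", "-")   # Group1
#' classify_group("+", "++")   # unclassified
#' @export
classify_group <- function(cdh17_band, cldn18_band) {
  n <- max(length(cdh17_band), length(cldn18_band))
  a <- rep_len(as.character(cdh17_band), n)
  b <- rep_len(as.character(cldn18_band), n)
  valid <- c("++", "+", "-")
  if (any(!is.na(a) & !a %in% valid) || any(!is.na(b) & !b %in% valid))
    stop("bands must be one of '++', '+', '-'")
  out <- rep(NA_character_, n)
  ok <- !is.na(a) & !is.na(b)
  out[ok & a == "++" & b %in% c("+", "-")] <- "Group1"
  out[ok & ((a == "++" & b == "++") | (a == "+" & b == "+"))] <- "Group2"
  out[ok & a == "-"] <- "Group3"
  out[ok & is.na(out)] <- "unclassified"
  out
}

#' Classify cases from aggregated primary-lesion IHC scores
#'
#' Convenience wrapper: takes the output of \code{\link{aggregate_cores}},
#' keeps primary-lesion (\code{Pr}) scores for CDH17 and CLDN18, applies the
#' band scheme and the subgroup rules.
#'
#' @param ihc data frame as returned by \code{\link{aggregate_cores}}.
#' @param scheme a \code{\link{band_scheme}}.
#' @param site which site's scores to classify on (default \code{"Pr"}).
#' @return data frame: \code{case_id}, \code{cdh17}, \code{cldn18} (scores),
#'   \code{cdh17_band}, \code{cldn18_band}, \code{group}.
#' @export
classify_cases <- function(ihc, scheme = band_scheme(), site = "Pr") {
  sub <- ihc[norm_label(ihc$site) == norm_label(site), , drop = FALSE]
  get <- function(marker) {
    s <- sub[norm_label(sub$marker) == norm_label(marker), , drop = FALSE]
    stats::setNames(s$value, s$case_id)
  }
  cdh <- get("CDH17"); cld <- get("CLDN18")
  cases <- sort(unique(sub$case_id))
  cdh <- cdh[match(cases, names(cdh))]
  cld <- cld[match(cases, names(cld))]
  data.frame(case_id = cases,
             cdh17 = as.integer(cdh),
             cldn18 = as.integer(cld),
             cdh17_band = band("CDH17", as.integer(cdh), scheme),
             cldn18_band = band("CLDN18", as.integer(cld), scheme),
             group = classify_group(band("CDH17", as.integer(cdh), scheme),
                                    band("CLDN18", as.integer(cld), scheme)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Whole-section staining category from a 0-10 score
#'
#' Whole tissue sections are categorized on a four-level scale from the
#' 0-10 proportion score: Category 1 (strongly positive) for scores 8-10,
#' Category 2 (moderately positive) for 5-7, Category 3 (weakly positive)
#' for 1-4 and Category 4 (negative/absent) for 0.
#'
#' @param score integer score(s) in 0..10.
#' @return integer category index in 1..4.
#' @examples
#' category(c(9, 6, 2, 0))  # 1 2 3 4
#' @export
category <- function(score) {
  if (any(is.na(score)) ||
      any(score < 0 | score > 10 | score != floor(score)))
    stop("scores must be integers in 0..10")
  ifelse(score >= 8, 1L, ifelse(score >= 5, 2L, ifelse(score >= 1, 3L, 4L)))
}

#' Whole-section staining profile
#'
#' The total cancer area of the primary lesion is divided into 10 regions,
#' each scored 0-10 and categorized; each metastatic node is categorized
#' individually from its own score.
#'
#' @param region_scores exactly 10 integer scores (0-10) for the primary
#'   lesion regions.
#' @param node_scores integer scores (0-10) for metastatic nodes (may be
#'   empty).
#' @return list with \code{region_categories} (10 values in 1..4) and
#'   \code{node_categories}.
#' @export
whole_section_profile <- function(region_scores, node_scores = integer(0)) {
  if (length(region_scores) != 10)
    stop("exactly 10 primary-lesion region scores are required")
  list(region_categories = category(region_scores),
       node_categories = if (length(node_scores)) category(node_scores)
                         else integer(0))
}
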