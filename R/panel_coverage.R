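#' Positive/negative marker calls from a numeric score table
#'
#' Converts a cases-by-markers score table into boolean calls under either a
#' per-marker numeric threshold (call positive when score >= threshold,
#' mirroring the inclusive floor of the expression screen) or a band rule
#' (call positive when the IHC band is not negative). Missing scores yield
#' missing calls.
#'
#' @param scores numeric matrix or data frame, cases in rows (row names =
#'   case ids), markers in columns.
#' @param rule either a named numeric vector of per-marker thresholds (a
#'   single unnamed value is recycled to all markers), or a
#'   \code{\link{band_scheme}}, in which case a call is positive when
#'   \code{\link{band}} assigns \code{"+"} or \code{"++"}.
#' @return logical matrix of calls (may contain \code{NA}).
#' @export
calls_from_scores <- function(scores, rule) {
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)))
    rownames(scores) <- paste0("case", seq_len(nrow(scores)))
  if (is.null(colnames(scores)))
    stop("`scores` must have marker column names")
  markers <- colnames(scores)
  if (inherits(rule, "band_scheme")) {
    unknown <- setdiff(norm_label(markers), names(rule$bands))
    if (length(unknown))
      stop("no band scheme for marker(s): ", paste(unknown, collapse = ", "))
    calls <- vapply(markers, function(m) {
      b <- band(m, scores[, m], scheme = rule)
      as.logical(b %in% c("+", "++") & !is.na(b))
    }, logical(nrow(scores)))
    calls <- matrix(calls, nrow = nrow(scores),
                    dimnames = dimnames(scores))
    calls[is.na(scores)] <- NA
  } else if (is.numeric(rule)) {
    if (is.null(names(rule))) {
      if (length(rule) != 1)
        stop("unnamed numeric rule must be a single threshold")
      rule <- stats::setNames(rep(rule, length(markers)), markers)
    }
    names(rule) <- norm_label(names(rule))
    missing_rule <- setdiff(norm_label(markers), names(rule))
    if (length(missing_rule))
      stop("no threshold for marker(s): ",
           paste(missing_rule, collapse = ", "))
    extra <- setdiff(names(rule), norm_label(markers))
    if (length(extra))
      stop("rule names unknown markers: ", paste(extra, collapse = ", "))
    thr <- rule[norm_label(markers)]
    calls <- sweep(scores, 2, thr, FUN = ">=")
  } else {
    stop("`rule` must be a numeric threshold vector or a band_scheme")
  }
  calls
}

#' Panel coverage of a set of marker calls
#'
#' A case is covered when it is positive for at least one marker of the
#' panel; missing calls are treated as negative (a missing core cannot serve
#' as evidence of positivity). Pattern counts enumerate all 2^|panel|
#' joint positivity patterns.
#'
#' @param calls logical case-by-marker matrix, as from
#'   \code{\link{calls_from_scores}}.
#' @param panel character vector of marker ids (subset of the columns).
#' @return An object of class \code{"panel_coverage"}: list with
#'   \code{panel}, \code{covered}, \code{total}, \code{fraction},
#'   \code{percent} (one decimal, half away from zero) and
#'   \code{pattern_counts} (named integer vector, names like
#'   \code{"A+/B-"}).
#' @export
coverage <- function(calls, panel = colnames(calls)) {
  calls <- as.matrix(calls)
  if (!length(panel)) stop("panel must contain at least one marker")
  hit <- match(norm_label(panel), norm_label(colnames(calls)))
  if (anyNA(hit))
    stop("panel markers not in call table: ",
         paste(panel[is.na(hit)], collapse = ", "))
  sub <- calls[, hit, drop = FALSE]
  sub[is.na(sub)] <- FALSE
  covered <- sum(rowSums(sub) > 0)
  total <- nrow(sub)
  pat <- apply(sub, 1, function(r)
    paste0(panel, ifelse(r, "+", "-"), collapse = "/"))
  # enumerate all 2^p patterns so absent ones appear with count 0
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(panel)))[,
    rev(seq_along(panel)), drop = FALSE]
  lev <- apply(grid, 1, function(r)
    paste0(panel, ifelse(r, "+", "-"), collapse = "/"))
  counts <- table(factor(pat, levels = lev))
  structure(list(panel = as.character(panel),
                 covered = covered,
                 total = total,
                 fraction = covered / total,
                 percent = coverage_percent(covered, total),
                 pattern_counts = c(counts)),
            class = "panel_coverage")
}

#' @export
print.panel_coverage <- function(x, ...) {
  cat(sprintf("panel {%s}: %d / %d cases covered (%.1f%%)\n",
              paste(x$panel, collapse = ", "), x$covered, x$total,
              x$percent))
  invisible(x)
}

#' Coverage count as a printed percentage
#'
#' Expresses \code{covered/total} as a percentage rounded half away from
#' zero, the convention that reproduces the printed figures 40/56 = 71.4,
#' 50/56 = 89.3 and 98/106 = 92.5.
#'
#' @param covered,total non-negative counts, \code{covered <= total},
#'   \code{total > 0}.
#' @param digits decimal places (default 1).
#' @export
coverage_percent <- function(covered, total, digits = 1) {
  if (any(total <= 0)) stop("total must be positive")
  if (any(covered < 0) || any(covered > total))
    stop("covered must lie in [0, total]")
  round_half_away(100 * covered / total, digits)
}

# round half away from zero (base round() is round-half-even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Greedy minimal covering panel
#'
#' Greedy set cover over markers: at each step, add the marker covering the
#' most still-uncovered cases, breaking ties by lexicographic marker id.
#' Stops when all cases are covered, no marker adds coverage, or
#' \code{max_size} is reached.
#'
#' @param calls logical case-by-marker matrix.
#' @param max_size maximum panel size (default: all markers).
#' @return list with \code{panel} (ordered marker ids) and \code{trace}
#'   (data frame: \code{marker}, \code{gain}, \code{covered},
#'   \code{fraction} after each addition).
#' @export
best_panel_greedy <- function(calls, max_size = ncol(calls)) {
  calls <- as.matrix(calls)
  stopifnot(max_size >= 1)
  calls[is.na(calls)] <- FALSE
  markers <- sort(colnames(calls))
  uncovered <- rep(TRUE, nrow(calls))
  panel <- character(0)
  trace <- data.frame(marker = character(0), gain = integer(0),
                      covered = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  while (length(panel) < max_size && any(uncovered)) {
    cand <- setdiff(markers, panel)
    if (!length(cand)) break
    gains <- vapply(cand, function(m) sum(calls[uncovered, m]), integer(1))
    if (max(gains) == 0) break
    pick <- cand[which.max(gains)]  # cand is sorted: ties -> smallest id
    uncovered <- uncovered & !calls[, pick]
    panel <- c(panel, pick)
    trace <- rbind(trace, data.frame(
      marker = pick, gain = max(gains),
      covered = sum(!uncovered),
      fraction = sum(!uncovered) / nrow(calls),
      stringsAsFactors = FALSE))
  }
  list(panel = panel, trace = trace)
}
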