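#' Expression matrix with tissue-class labels
#'
#' Container for a probes-by-samples matrix of non-negative signal scores
#' (MAS5-style "Genechip scores") together with a tissue-class label per
#' sample. The tissue class is either \code{"tumor"} or the name of a normal
#' tissue (e.g. \code{"esophagus"}); labels are matched case-insensitively
#' after trimming whitespace, but stored verbatim.
#'
#' @param values numeric matrix, probes in rows and samples in columns, with
#'   unique row and column names and all entries \code{>= 0}.
#' @param tissue_class character vector of per-sample labels, either named by
#'   sample id or in column order of \code{values}.
#' @return An object of class \code{"expression_matrix"}: a list with
#'   elements \code{values} and \code{tissue_class} (named by sample id).
#' @export
expression_matrix <- function(values, tissue_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (probes x samples)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (any(values < 0, na.rm = TRUE))
    stop("expression scores must be non-negative")
  if (length(tissue_class) != ncol(values))
    stop("`tissue_class` must have one label per sample")
  if (!is.null(names(tissue_class))) {
    if (!setequal(names(tissue_class), colnames(values)))
      stop("names of `tissue_class` do not match sample ids")
    tissue_class <- tissue_class[colnames(values)]
  } else {
    names(tissue_class) <- colnames(values)
  }
  structure(list(values = values, tissue_class = as.character(tissue_class)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d probes x %d samples (%d tumor)\n",
              nrow(x$values), ncol(x$values),
              sum(norm_label(x$tissue_class) == "tumor")))
  invisible(x)
}

# canonical form for tissue/marker labels: trimmed, lower case
norm_label <- function(x) tolower(trimws(as.character(x)))

#' Screening thresholds for the candidate-marker screen
#'
#' Bundles the selection rule of the expression screen: a probe is selected
#' when its maximum over a panel of normal tissues is strictly below
#' \code{normal_ceiling} and its \code{tumor_rank_k}-th largest tumor value is
#' at least \code{tumor_floor}. The default normal panel is the ten tissues
#' whose expression would confound in-vivo detection of nodal metastases;
#' stomach, colon and small intestine are excluded entirely because the
#' markers of interest are physiologically expressed there.
#'
#' @param normal_ceiling score; normal-panel maximum must be strictly below
#'   this (default 150).
#' @param tumor_floor score; the k-th largest tumor value must be at least
#'   this (default 500).
#' @param tumor_rank_k 1-based rank of the tumor order statistic, counted
#'   from the top with duplicates retained (default 40).
#' @param normal_panel tissue labels included in the normal maximum.
#' @param excluded_tissues tissue labels ignored entirely by the screen.
#' @return An object of class \code{"screen_thresholds"}.
#' @export
screen_thresholds <- function(normal_ceiling = 150,
                              tumor_floor = 500,
                              tumor_rank_k = 40,
                              normal_panel = c("esophagus", "pancreas",
                                               "spleen", "adipose",
                                               "lymph node", "artery", "vein",
                                               "peripheral blood cells",
                                               "monocyte", "macrophage"),
                              excluded_tissues = c("stomach", "colon",
                                                   "small intestine")) {
  stopifnot(is.numeric(normal_ceiling), length(normal_ceiling) == 1,
            is.numeric(tumor_floor), length(tumor_floor) == 1,
            is.numeric(tumor_rank_k), length(tumor_rank_k) == 1,
            tumor_rank_k >= 1, tumor_rank_k == as.integer(tumor_rank_k))
  panel <- norm_label(normal_panel)
  excl <- norm_label(excluded_tissues)
  if ("tumor" %in% c(panel, excl))
    stop("'tumor' cannot appear in the normal panel or excluded tissues")
  if (length(intersect(panel, excl)))
    stop("normal panel and excluded tissues overlap: ",
         paste(intersect(panel, excl), collapse = ", "))
  structure(list(normal_ceiling = normal_ceiling,
                 tumor_floor = tumor_floor,
                 tumor_rank_k = as.integer(tumor_rank_k),
                 normal_panel = panel,
                 excluded_tissues = excl),
            class = "screen_thresholds")
}

# column index helpers; warn once about tissue labels outside the vocabulary
screen_sample_sets <- function(x, thresholds, warn_unknown = TRUE) {
  cls <- norm_label(x$tissue_class)
  known <- c("tumor", thresholds$normal_panel, thresholds$excluded_tissues)
  unknown <- setdiff(unique(cls), known)
  if (warn_unknown && length(unknown))
    warning("ignoring samples with tissue classes outside the screen ",
            "vocabulary: ", paste(unknown, collapse = ", "), call. = FALSE)
  list(panel = which(cls %in% thresholds$normal_panel),
       tumor = which(cls == "tumor"))
}

#' Maximum expression over the normal-tissue panel
#'
#' @param x an \code{\link{expression_matrix}}.
#' @param probe probe id.
#' @param thresholds a \code{\link{screen_thresholds}} object; only its
#'   panel definitions are used.
#' @return The maximum score of \code{probe} over samples whose tissue class
#'   is in the normal panel. Excluded tissues and tumor samples never
#'   contribute.
#' @export
normal_max <- function(x, probe, thresholds = screen_thresholds()) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!probe %in% rownames(x$values)) stop("unknown probe: ", probe)
  idx <- screen_sample_sets(x, thresholds)$panel
  if (!length(idx)) stop("no samples fall in the normal panel")
  max(x$values[probe, idx])
}

#' k-th largest tumor expression value
#'
#' The k-th value from the top among tumor samples, with duplicates counted
#' (descending sort, 1-based position \code{k}).
#'
#' @inheritParams normal_max
#' @param k 1-based rank from the top.
#' @export
tumor_order_stat <- function(x, probe, k) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!probe %in% rownames(x$values)) stop("unknown probe: ", probe)
  tum <- which(norm_label(x$tissue_class) == "tumor")
  if (!length(tum)) stop("matrix contains no tumor samples")
  if (k < 1 || k > length(tum))
    stop("k must be between 1 and the number of tumor samples (",
         length(tum), ")")
  unname(sort(x$values[probe, tum], decreasing = TRUE)[k])
}

#' Order-statistic screen for tumor-enriched probes
#'
#' For every probe, computes the normal-panel maximum and the k-th largest
#' tumor value, then selects probes with normal maximum strictly below the
#' ceiling and tumor order statistic at or above the floor.
#'
#' @inheritParams normal_max
#' @return An object of class \code{"screen_result"}: a list with
#'   \code{table} (data frame with one row per probe: \code{probe_id},
#'   \code{normal_max}, \code{tumor_kth}, \code{pass_normal},
#'   \code{pass_tumor}, \code{selected}), \code{selected_probes} (sorted by
#'   probe id) and the \code{thresholds} used.
#' @examples
#' vals <- rbind(good = c(100, 900, 800, 700),
#'               leaky = c(600, 900, 800, 700))
#' colnames(vals) <- c("n1", "t1", "t2", "t3")
#' m <- expression_matrix(vals, c("esophagus", "tumor", "tumor", "tumor"))
#' screen(m, screen_thresholds(tumor_rank_k = 2))$selected_probes
#' @export
screen <- function(x, thresholds = screen_thresholds()) {
  stopifnot(inherits(x, "expression_matrix"),
            inherits(thresholds, "screen_thresholds"))
  sets <- screen_sample_sets(x, thresholds)
  if (!length(sets$tumor)) stop("matrix contains no tumor samples")
  if (!length(sets$panel)) stop("no samples fall in the normal panel")
  k <- thresholds$tumor_rank_k
  if (k > length(sets$tumor))
    stop("tumor_rank_k (", k, ") exceeds the number of tumor samples (",
         length(sets$tumor), ")")
  nmax <- apply(x$values[, sets$panel, drop = FALSE], 1, max)
  kth <- apply(x$values[, sets$tumor, drop = FALSE], 1,
               function(v) sort(v, decreasing = TRUE)[k])
  pass_n <- nmax < thresholds$normal_ceiling
  pass_t <- kth >= thresholds$tumor_floor
  tab <- data.frame(probe_id = rownames(x$values),
                    normal_max = unname(nmax),
                    tumor_kth = unname(kth),
                    pass_normal = unname(pass_n),
                    pass_tumor = unname(pass_t),
                    selected = unname(pass_n & pass_t),
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 selected_probes = sort(tab$probe_id[tab$selected]),
                 thresholds = thresholds),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  n <- nrow(x$table)
  cat(sprintf(paste0(
    "screen_result: %d / %d probes selected\n",
    "  normal max < %g (panel of %d tissues): %d pass\n",
    "  tumor rank-%d value >= %g: %d pass\n"),
    sum(x$table$selected), n,
    x$thresholds$normal_ceiling, length(x$thresholds$normal_panel),
    sum(x$table$pass_normal),
    x$thresholds$tumor_rank_k, x$thresholds$tumor_floor,
    sum(x$table$pass_tumor)))
  if (length(x$selected_probes))
    cat("  selected:", paste(x$selected_probes, collapse = ", "), "\n")
  invisible(x)
}

#' Scatter-plot table of screen statistics
#'
#' One row per probe with the two screen axes (normal-panel maximum, tumor
#' order statistic) and the selection flag; suitable for plotting or TSV
#' export.
#'
#' @param result a \code{\link{screen}} result.
#' @return data frame with columns \code{probe_id}, \code{normal_max},
#'   \code{tumor_kth}, \code{selected}.
#' @export
scatter_table <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  result$table[, c("probe_id", "normal_max", "tumor_kth", "selected")]
}
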