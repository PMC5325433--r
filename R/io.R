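#' @name gcpanel-io
#' @title Readers and writers for the pipeline's file formats
#'
#' @description
#' All writers prepend a single provenance comment line
#' (\code{# gcpanel <version> | seed=<seed>}); all readers skip
#' \code{#}-comment lines, so every writer/reader pair round-trips with
#' full fidelity. Formats: expression matrices as TSV (first column
#' \code{probe_id}, one column per sample) with a sample sheet CSV
#' (\code{sample_id,tissue_class}); core scores as CSV
#' (\code{case_id,marker,site,replicate,score}); clinical tables as CSV
#' (\code{case_id,time,event,group,...}); summaries as JSON.
NULL

provenance_line <- function(seed = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("gcpanel")),
                  error = function(e) "dev")
  paste0("# gcpanel ", ver,
         if (!is.null(seed)) paste0(" | seed=", seed) else "")
}

write_with_header <- function(df, path, sep, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_line(seed), con)
  utils::write.table(df, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname gcpanel-io
#' @param x an \code{\link{expression_matrix}}.
#' @param path,sample_sheet_path output/input file paths.
#' @param seed optional seed recorded in the provenance header.
#' @export
write_expression_tsv <- function(x, path, sample_sheet_path = NULL,
                                 seed = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(probe_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_with_header(df, path, sep = "\t", seed = seed)
  if (!is.null(sample_sheet_path))
    write_with_header(
      data.frame(sample_id = colnames(x$values),
                 tissue_class = unname(x$tissue_class),
                 stringsAsFactors = FALSE),
      sample_sheet_path, sep = ",", seed = seed)
  invisible(path)
}

#' @rdname gcpanel-io
#' @export
read_expression_tsv <- function(path, sample_sheet_path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id")
    stop(path, ": first column must be 'probe_id'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$probe_id
  ss <- utils::read.csv(sample_sheet_path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue_class") %in% names(ss)))
    stop(sample_sheet_path,
         ": needs columns 'sample_id' and 'tissue_class'")
  missing_samples <- setdiff(colnames(vals), ss$sample_id)
  if (length(missing_samples))
    stop(sample_sheet_path, ": no tissue class for sample(s): ",
         paste(missing_samples, collapse = ", "))
  expression_matrix(vals,
                    stats::setNames(ss$tissue_class, ss$sample_id)[
                      colnames(vals)])
}

#' @rdname gcpanel-io
#' @param cores a core-score data frame
#'   (\code{case_id,marker,site,replicate,score}).
#' @export
write_core_scores <- function(cores, path, seed = NULL) {
  req <- c("case_id", "marker", "site", "replicate", "score")
  stopifnot(all(req %in% names(cores)))
  write_with_header(cores[, req], path, sep = ",", seed = seed)
}

#' @rdname gcpanel-io
#' @export
read_core_scores <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  req <- c("case_id", "marker", "site", "replicate", "score")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!is.na(df$score) &
                 (df$score < 0 | df$score > 10 | df$score != floor(df$score)))
  if (length(bad))
    stop(path, ": invalid score at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (scores must be integers 0..10)")
  df
}

#' @rdname gcpanel-io
#' @param clinical a clinical data frame with at least
#'   \code{case_id,time,event}.
#' @export
write_clinical <- function(clinical, path, seed = NULL) {
  stopifnot(all(c("case_id", "time", "event") %in% names(clinical)))
  write_with_header(clinical, path, sep = ",", seed = seed)
}

#' @rdname gcpanel-io
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  miss <- setdiff(c("case_id", "time", "event"), names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  check_surv(df$time, df$event)
  df
}

#' @rdname gcpanel-io
#' @param object any list-like summary object.
#' @export
write_json_summary <- function(object, path, seed = NULL) {
  object$provenance <- list(
    package = "gcpanel",
    version = tryCatch(as.character(utils::packageVersion("gcpanel")),
                       error = function(e) "dev"),
    seed = seed)
  jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' End-to-end TMA marker report
#'
#' Chains the pipeline stages on a core-score table (and, optionally, a
#' clinical table): core aggregation, band assignment and subgroup
#' classification, CDH17+CLDN18 panel coverage over the classifiable
#' cases, two-way clustering of the site-level IHC scores, and (when
#' survival data are supplied) a Gehan-Wilcoxon comparison of the
#' subgroups.
#'
#' @param cores core-score data frame
#'   (\code{case_id,marker,site,replicate,score}).
#' @param clinical optional clinical data frame
#'   (\code{case_id,time,event}); its cases are matched to the classified
#'   subgroups by \code{case_id}.
#' @param scheme a \code{\link{band_scheme}}.
#' @return list with \code{classification}, \code{group_sizes},
#'   \code{coverage} (classifiable-case coverage: covered = cases in
#'   Groups 1-3), \code{clustering} (two-way cluster of the score matrix)
#'   and, when clinical data are given, \code{survival} (the Gehan test)
#'   and \code{km} (per-group curves).
#' @export
marker_report <- function(cores, clinical = NULL, scheme = band_scheme()) {
  ihc <- aggregate_cores(cores)
  cls <- classify_cases(ihc, scheme = scheme)
  grp <- cls$group[!is.na(cls$group)]
  group_sizes <- table(factor(grp, levels = c("Group1", "Group2", "Group3",
                                              "unclassified")))
  covered <- sum(grp != "unclassified")
  total <- length(grp)
  cov <- list(covered = covered, total = total,
              fraction = covered / total,
              percent = coverage_percent(covered, total))

  # site-level score matrix: cases x (marker, site); imputed values kept
  key <- paste(ihc$marker, ihc$site, sep = "_")
  cases <- sort(unique(ihc$case_id))
  mat <- matrix(NA_real_, length(cases), length(unique(key)),
                dimnames = list(cases, sort(unique(key))))
  for (r in seq_len(nrow(ihc)))
    mat[ihc$case_id[r], paste(ihc$marker[r], ihc$site[r], sep = "_")] <-
      ihc$value[r]
  clustering <- two_way_cluster(mat)

  out <- list(classification = cls,
              group_sizes = c(group_sizes),
              coverage = cov,
              clustering = clustering)
  if (!is.null(clinical)) {
    sub <- data.frame(case_id = cls$case_id, subgroup = cls$group,
                      stringsAsFactors = FALSE)
    merged <- merge(clinical, sub, by = "case_id")
    merged <- merged[!is.na(merged$subgroup) &
                       merged$subgroup != "unclassified", , drop = FALSE]
    if (length(unique(merged$subgroup)) >= 2) {
      out$survival <- gehan_wilcoxon_test(merged$time, merged$event,
                                          merged$subgroup)
      out$km <- km_estimate(merged$time, merged$event, merged$subgroup)
    }
  }
  out
}
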