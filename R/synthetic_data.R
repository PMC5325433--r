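#' Configuration for the synthetic expression fixture
#'
#' Describes a probes-by-samples expression fixture with the statistical
#' structure the marker screen assumes: positive, right-skewed (log-normal)
#' background signal; a panel of normal tissues (one sample each); a block
#' of tumor samples; a small set of planted tumor-enriched probes that pass
#' the screen by construction; and decoy probes that each violate exactly
#' one screen criterion (normal-leaky: expressed in a panel tissue;
#' tumor-weak: never reaches the tumor floor; tumor-rare: strong in too few
#' tumors).
#'
#' @param n_probes total probes (default 10000).
#' @param n_tumors tumor samples (default 56).
#' @param normal_tissue_names one normal sample is generated per name;
#'   defaults to the ten-tissue screening panel plus stomach, colon and
#'   small intestine.
#' @param n_planted_markers probes planted to pass the screen (default 3).
#' @param decoy_counts named counts for \code{normal_leaky},
#'   \code{tumor_weak}, \code{tumor_rare}.
#' @param background_log_mean,background_log_sd log-normal parameters of
#'   the background signal (defaults \code{log(50)} and 1).
#' @param seed integer seed.
#' @return object of class \code{"expression_fixture_config"}.
#' @export
expression_fixture_config <- function(
    n_probes = 10000, n_tumors = 56,
    normal_tissue_names = c("esophagus", "pancreas", "spleen", "adipose",
                            "lymph node", "artery", "vein",
                            "peripheral blood cells", "monocyte",
                            "macrophage", "stomach", "colon",
                            "small intestine"),
    n_planted_markers = 3,
    decoy_counts = c(normal_leaky = 5, tumor_weak = 5, tumor_rare = 5),
    background_log_mean = log(50), background_log_sd = 1,
    seed = 1L) {
  stopifnot(n_probes >= 1, n_tumors >= 1, n_planted_markers >= 0,
            background_log_sd > 0, length(normal_tissue_names) >= 1)
  dc <- c(normal_leaky = 0, tumor_weak = 0, tumor_rare = 0)
  dc[names(decoy_counts)] <- decoy_counts
  if (any(dc < 0)) stop("decoy counts must be non-negative")
  if (n_planted_markers + sum(dc) > n_probes)
    stop("planted markers (", n_planted_markers, ") plus decoys (",
         sum(dc), ") exceed n_probes (", n_probes, ")")
  structure(list(n_probes = as.integer(n_probes),
                 n_tumors = as.integer(n_tumors),
                 normal_tissue_names = normal_tissue_names,
                 n_planted_markers = as.integer(n_planted_markers),
                 decoy_counts = dc,
                 background_log_mean = background_log_mean,
                 background_log_sd = background_log_sd,
                 seed = as.integer(seed)),
            class = "expression_fixture_config")
}

#' Generate a synthetic expression matrix with planted screen hits
#'
#' Identical seeds yield identical matrices. Exactly
#' \code{n_planted_markers} probes satisfy the default screen by
#' construction (normal-panel values uniform on [1, 100]; at least
#' \code{tumor_rank_k} tumor values at or above 600); decoys violate their
#' designated criterion; all remaining probes carry log-normal background
#' signal, post-checked (and damped if needed) so no background probe
#' passes the screen.
#'
#' @param config an \code{\link{expression_fixture_config}}.
#' @param thresholds the \code{\link{screen_thresholds}} the plant must
#'   satisfy (defaults match the screen defaults).
#' @return an \code{\link{expression_matrix}} with attributes
#'   \code{"roles"} (per-probe: background / planted / decoy class) and
#'   \code{"planted_probes"}.
#' @export
generate_expression_fixture <- function(config = expression_fixture_config(),
                                        thresholds = screen_thresholds()) {
  stopifnot(inherits(config, "expression_fixture_config"))
  k <- thresholds$tumor_rank_k
  if (k > config$n_tumors)
    stop("tumor_rank_k exceeds n_tumors in the fixture config")
  withr::with_seed(config$seed, {
    n_norm <- length(config$normal_tissue_names)
    n_samp <- n_norm + config$n_tumors
    probe_ids <- sprintf("P%05d", seq_len(config$n_probes))
    sample_ids <- c(make.names(config$normal_tissue_names, unique = TRUE),
                    sprintf("GC%03d", seq_len(config$n_tumors)))
    tissue <- c(config$normal_tissue_names,
                rep("tumor", config$n_tumors))
    vals <- matrix(stats::rlnorm(config$n_probes * n_samp,
                                 config$background_log_mean,
                                 config$background_log_sd),
                   nrow = config$n_probes,
                   dimnames = list(probe_ids, sample_ids))

    roles <- rep("background", config$n_probes)
    n_special <- config$n_planted_markers + sum(config$decoy_counts)
    special <- sample(config$n_probes, n_special)
    role_vec <- c(rep("planted", config$n_planted_markers),
                  rep(names(config$decoy_counts),
                      times = config$decoy_counts))
    roles[special] <- role_vec

    cls <- norm_label(tissue[seq_len(n_norm)])
    panel_cols <- which(cls %in% thresholds$normal_panel)
    excl_cols <- which(cls %in% thresholds$excluded_tissues)
    tumor_cols <- n_norm + seq_len(config$n_tumors)

    fill_probe <- function(i, role) {
      panel_v <- stats::runif(length(panel_cols), 1, 100)
      excl_v <- stats::runif(length(excl_cols), 200, 8000)
      if (role == "normal_leaky") {
        leak <- sample(seq_along(panel_v), 1)
        panel_v[leak] <- stats::runif(1, 300, 3000)
      }
      n_high <- switch(role,
        planted = sample(k:config$n_tumors, 1),
        normal_leaky = sample(k:config$n_tumors, 1),
        tumor_weak = 0L,
        tumor_rare = min(k - 1L, max(1L, k %/% 4L)))
      tum_v <- stats::runif(config$n_tumors, 1, 400)
      if (n_high > 0)
        tum_v[sample(config$n_tumors, n_high)] <- stats::runif(n_high,
                                                               600, 8000)
      vals[i, panel_cols] <<- panel_v
      vals[i, excl_cols] <<- excl_v
      vals[i, tumor_cols] <<- tum_v
    }
    for (j in seq_along(special)) fill_probe(special[j], role_vec[j])

    # ensure no background probe slips through the screen by chance
    bg <- which(roles == "background")
    if (length(bg) && length(panel_cols)) {
      nmax <- apply(vals[bg, panel_cols, drop = FALSE], 1, max)
      kth <- apply(vals[bg, tumor_cols, drop = FALSE], 1,
                   function(v) sort(v, decreasing = TRUE)[k])
      slip <- bg[nmax < thresholds$normal_ceiling &
                   kth >= thresholds$tumor_floor]
      for (i in slip)
        vals[i, tumor_cols] <- vals[i, tumor_cols] *
          (0.98 * thresholds$tumor_floor /
             sort(vals[i, tumor_cols], decreasing = TRUE)[k])
    }

    em <- expression_matrix(vals, tissue)
    attr(em, "roles") <- stats::setNames(roles, probe_ids)
    attr(em, "planted_probes") <- sort(probe_ids[roles == "planted"])
    em
  })
}

#' Configuration for the synthetic TMA core-score fixture
#'
#' Emulates a tissue-microarray scoring table: per case, duplicate
#' primary-lesion (Pr) and nodal (LN) cores for each of CDH17, CLDN18 and
#' CLDN7, scored 0-10, with a latent subgroup per case. The primary-lesion
#' aggregate of each case is drawn uniformly inside its latent group's
#' score region of the subgroup rules, so the band/classify pipeline
#' recovers the latent labels exactly.
#'
#' @param n_cases number of cases (default 106).
#' @param group_proportions non-negative weights over Group1, Group2,
#'   Group3, unclassified (default 30/30/38/8, normalized).
#' @param replicate_noise maximum absolute core-to-core score difference
#'   (integer 0..10, default 2).
#' @param missing_ln_core_rate probability that an individual LN core is
#'   missing (nodal cores without a cancer component; default 0.1).
#' @param seed integer seed.
#' @export
tma_fixture_config <- function(n_cases = 106,
                               group_proportions = c(Group1 = 30,
                                                     Group2 = 30,
                                                     Group3 = 38,
                                                     unclassified = 8),
                               replicate_noise = 2,
                               missing_ln_core_rate = 0.1,
                               seed = 1L) {
  stopifnot(n_cases >= 1, length(group_proportions) == 4,
            replicate_noise >= 0, replicate_noise <= 10,
            replicate_noise == floor(replicate_noise),
            missing_ln_core_rate >= 0, missing_ln_core_rate <= 1)
  if (any(group_proportions < 0) || sum(group_proportions) <= 0)
    stop("group proportions must be non-negative and sum to a positive value")
  gp <- group_proportions / sum(group_proportions)
  if (is.null(names(gp)))
    names(gp) <- c("Group1", "Group2", "Group3", "unclassified")
  structure(list(n_cases = as.integer(n_cases), group_proportions = gp,
                 replicate_noise = as.integer(replicate_noise),
                 missing_ln_core_rate = missing_ln_core_rate,
                 seed = as.integer(seed)),
            class = "tma_fixture_config")
}

# feasible replicate split of an aggregate V into (a, V - a), both 0..10,
# |difference| <= noise; uniform over the feasible set
split_aggregate <- function(v, noise) {
  lo <- max(0, v - 10, ceiling((v - noise) / 2))
  hi <- min(10, v, floor((v + noise) / 2))
  a <- if (lo >= hi) lo else sample(lo:hi, 1)
  c(a, v - a)
}

# uniform integer draw from a range; with zero replicate noise only even
# aggregates admit an exact duplicate-core split, so odd values are dropped
draw_in <- function(rng, noise) {
  if (noise == 0) rng <- rng[rng %% 2 == 0]
  if (length(rng) == 1) rng else sample(rng, 1)
}

# draw from a latent group's (CDH17, CLDN18) score region
latent_box_draw <- function(group, noise) {
  switch(group,
    Group1 = c(draw_in(18:20, noise), draw_in(0:13, noise)),
    Group2 = if (stats::runif(1) < 0.5)
      c(draw_in(18:20, noise), draw_in(14:20, noise))
    else
      c(draw_in(9:17, noise), draw_in(6:13, noise)),
    Group3 = c(draw_in(0:8, noise), draw_in(0:20, noise)),
    unclassified = c(draw_in(9:17, noise),
                     if (stats::runif(1) < 7 / 13) draw_in(14:20, noise)
                     else draw_in(0:5, noise)),
    stop("unknown latent group: ", group))
}

#' Generate a synthetic TMA core-score table
#'
#' @param config a \code{\link{tma_fixture_config}}.
#' @return list with \code{cores} (data frame: \code{case_id},
#'   \code{marker}, \code{site}, \code{replicate}, \code{score}) and
#'   \code{latent_groups} (data frame: \code{case_id}, \code{group}).
#' @export
generate_tma_fixture <- function(config = tma_fixture_config()) {
  stopifnot(inherits(config, "tma_fixture_config"))
  withr::with_seed(config$seed, {
    case_ids <- sprintf("case%03d", seq_len(config$n_cases))
    groups <- sample(names(config$group_proportions), config$n_cases,
                     replace = TRUE, prob = config$group_proportions)
    rows <- vector("list", config$n_cases)
    for (i in seq_len(config$n_cases)) {
      box <- latent_box_draw(groups[i], config$replicate_noise)
      agg <- c(CDH17 = box[1], CLDN18 = box[2],
               CLDN7 = draw_in(0:20, config$replicate_noise))
      case_rows <- list()
      for (m in names(agg)) {
        pr <- split_aggregate(agg[[m]], config$replicate_noise)
        ln_total <- max(0, min(20, agg[[m]] + sample(-2:2, 1)))
        if (config$replicate_noise == 0) ln_total <- ln_total - ln_total %% 2
        ln <- split_aggregate(ln_total, config$replicate_noise)
        df <- data.frame(case_id = case_ids[i], marker = m,
                         site = rep(c("Pr", "LN"), each = 2),
                         replicate = c(1L, 2L, 1L, 2L),
                         score = as.integer(c(pr, ln)),
                         stringsAsFactors = FALSE)
        drop_ln <- df$site == "LN" &
          stats::runif(4) < config$missing_ln_core_rate
        case_rows[[m]] <- df[!drop_ln, , drop = FALSE]
      }
      rows[[i]] <- do.call(rbind, case_rows)
    }
    cores <- do.call(rbind, rows)
    rownames(cores) <- NULL
    list(cores = cores,
         latent_groups = data.frame(case_id = case_ids, group = groups,
                                    stringsAsFactors = FALSE))
  })
}

#' Configuration for the synthetic survival fixture
#'
#' Exponential event times per group, independent exponential censoring
#' and administrative censoring at \code{max_followup}.
#'
#' @param group_hazards named exponential event rates per day, one per
#'   group label. The defaults give the better-prognosis group roughly a
#'   third the hazard of the others over a ten-year horizon.
#' @param censor_rate exponential rate of independent censoring (0 = none).
#' @param max_followup administrative censoring horizon in days.
#' @param seed integer seed.
#' @export
survival_fixture_config <- function(
    group_hazards = c(Group1 = 2e-4, Group2 = 6e-4, Group3 = 6e-4,
                      unclassified = 5e-4),
    censor_rate = 2e-4, max_followup = 3650, seed = 1L) {
  stopifnot(length(group_hazards) >= 1, all(group_hazards > 0),
            censor_rate >= 0, max_followup > 0)
  if (is.null(names(group_hazards)))
    stop("group_hazards must be named by group label")
  structure(list(group_hazards = group_hazards,
                 censor_rate = censor_rate,
                 max_followup = max_followup, seed = as.integer(seed)),
            class = "survival_fixture_config")
}

#' Generate synthetic survival records for labelled cases
#'
#' @param config a \code{\link{survival_fixture_config}}.
#' @param group_labels one group label per case; every label must have a
#'   hazard in the config.
#' @param case_ids optional case identifiers (default \code{case001}...).
#' @return data frame: \code{case_id}, \code{time} (days), \code{event}
#'   (1 = death from disease, 0 = censored), \code{group}.
#' @export
generate_survival_fixture <- function(config = survival_fixture_config(),
                                      group_labels,
                                      case_ids = NULL) {
  stopifnot(inherits(config, "survival_fixture_config"))
  unknown <- setdiff(unique(group_labels), names(config$group_hazards))
  if (length(unknown))
    stop("no hazard for group label(s): ", paste(unknown, collapse = ", "))
  n <- length(group_labels)
  if (is.null(case_ids)) case_ids <- sprintf("case%03d", seq_len(n))
  withr::with_seed(config$seed, {
    ev <- stats::rexp(n, rate = config$group_hazards[group_labels])
    cen <- if (config$censor_rate > 0)
      stats::rexp(n, rate = config$censor_rate) else rep(Inf, n)
    cen <- pmin(cen, config$max_followup)
    data.frame(case_id = case_ids,
               time = pmin(ev, cen),
               event = as.integer(ev <= cen),
               group = as.character(group_labels),
               stringsAsFactors = FALSE)
  })
}
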