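#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via \code{\link[survival]{survfit}}; censored
#' times reduce the risk set without producing steps. Survival is the time
#' from surgery to death from the primary disease; patients alive at last
#' follow-up (or dying of other causes, under the cause-specific
#' convention) are censored.
#'
#' @param time positive follow-up times (days).
#' @param event event indicator, 1 = death from disease, 0 = censored.
#' @param group optional group labels; one curve per group.
#' @return data frame with columns \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{surv} and (when grouped)
#'   \code{group}.
#' @export
km_estimate <- function(time, event, group = NULL) {
  check_surv(time, event)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  } else {
    g <- as.factor(group)
    fit <- survival::survfit(survival::Surv(time, event) ~ g)
    out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv,
                      group = rep(sub("^g=", "", names(fit$strata)),
                                  fit$strata))
  }
  out
}

check_surv <- function(time, event) {
  if (any(is.na(time)) || any(time <= 0))
    stop("survival times must be positive and non-missing")
  if (!all(event %in% c(0, 1)))
    stop("event indicator must be 0 (censored) or 1 (event)")
  invisible(TRUE)
}

# lightweight test-result container shared by the categorical/survival tests
gc_test <- function(statistic, p_value, method, n, ...) {
  structure(c(list(statistic = unname(statistic),
                   p_value = unname(p_value),
                   method = method, n = n), list(...)),
            class = "gc_test")
}

#' @export
print.gc_test <- function(x, ...) {
  cat(x$method, "\n  statistic =", format(x$statistic),
      " p =", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Gehan generalized Wilcoxon test for survival differences
#'
#' Weighted log-rank test comparing two or more survival curves. The
#' default Gehan-Breslow variant weights each event time by the total
#' number at risk, emphasizing early differences; the Peto-Prentice
#' variant (weights = modified left-continuous survival estimate) is
#' available via \code{weights}. The p-value comes from a chi-square
#' approximation with \code{groups - 1} degrees of freedom, or from exact
#' permutation enumeration of group assignments when the total sample size
#' is at most 12 (or \code{exact = TRUE}).
#'
#' @param time,event as in \code{\link{km_estimate}}.
#' @param group group labels (at least two non-empty groups).
#' @param weights \code{"gehan"} (number at risk) or \code{"peto"}.
#' @param exact force (\code{TRUE}) or suppress (\code{FALSE}) exact
#'   permutation; default \code{NULL} enumerates when total n <= 12.
#' @return a \code{gc_test} with the chi-square statistic, p-value, degrees
#'   of freedom and per-group sizes; \code{p_permutation} when computed.
#' @export
gehan_wilcoxon_test <- function(time, event, group,
                                weights = c("gehan", "peto"),
                                exact = NULL) {
  weights <- match.arg(weights)
  check_surv(time, event)
  g <- as.factor(group)
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) == 0)) stop("all groups must be non-empty")
  obs <- weighted_logrank_chi2(time, event, g, weights)
  n_tot <- length(time)
  do_exact <- isTRUE(exact) || (is.null(exact) && n_tot <= 12)
  p_perm <- NULL
  if (do_exact) {
    perms <- multiset_permutations(as.integer(g))
    stats <- vapply(perms, function(idx)
      weighted_logrank_chi2(time, event,
                            factor(levels(g)[idx], levels = levels(g)),
                            weights)$chi2,
      numeric(1))
    p_perm <- mean(stats >= obs$chi2 - 1e-12)
  }
  gc_test(obs$chi2,
          if (!is.null(p_perm)) p_perm else
            stats::pchisq(obs$chi2, df = obs$df, lower.tail = FALSE),
          method = sprintf("%s weighted log-rank (%s)",
                           if (weights == "gehan")
                             "Gehan-Breslow generalized Wilcoxon"
                           else "Peto-Prentice",
                           if (!is.null(p_perm)) "exact permutation"
                           else "chi-square approximation"),
          n = as.integer(table(g)), df = obs$df,
          p_chisq = stats::pchisq(obs$chi2, df = obs$df,
                                  lower.tail = FALSE),
          p_permutation = p_perm)
}

# core weighted log-rank machinery shared by approximation and permutation
weighted_logrank_chi2 <- function(time, event, g, weights) {
  G <- nlevels(g)
  ut <- sort(unique(time[event == 1]))
  U <- numeric(G)
  V <- matrix(0, G, G)
  if (weights == "peto") {
    # left-continuous modified survival estimate S~(t) = prod(1 - d/(n+1))
    allt <- sort(unique(time))
    s_mod <- stats::setNames(numeric(length(allt)), allt)
    s <- 1
    for (i in seq_along(allt)) {
      s_mod[i] <- s  # value just before allt[i]
      n_i <- sum(time >= allt[i])
      d_i <- sum(time == allt[i] & event == 1)
      s <- s * (1 - d_i / (n_i + 1))
    }
  }
  for (t in ut) {
    at_risk <- time >= t
    n_i <- sum(at_risk)
    d_i <- sum(time == t & event == 1)
    n_gi <- tabulate(g[at_risk], nbins = G)
    d_gi <- tabulate(g[time == t & event == 1], nbins = G)
    w <- if (weights == "gehan") n_i else s_mod[as.character(t)]
    U <- U + w * (d_gi - n_gi * d_i / n_i)
    if (n_i >= 2) {
      # multivariate hypergeometric: Var(d_g) = w^2 h (diag(p) - pp')
      h <- d_i * (n_i - d_i) / (n_i - 1)
      p_g <- n_gi / n_i
      V <- V + w^2 * h * (diag(p_g, G) - tcrossprod(p_g))
    }
  }
  keep <- seq_len(G - 1)
  Vk <- V[keep, keep, drop = FALSE]
  chi2 <- tryCatch(
    drop(t(U[keep]) %*% solve(Vk, U[keep])),
    error = function(e) drop(t(U[keep]) %*% pseudo_inverse(Vk) %*% U[keep]))
  if (!is.finite(chi2) || chi2 < 0) chi2 <- 0
  list(chi2 = chi2, df = G - 1, U = U, V = V)
}

pseudo_inverse <- function(m, tol = 1e-10) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# all distinct permutations of a small multiset (indices into levels)
multiset_permutations <- function(x) {
  out <- list()
  recurse <- function(prefix, remaining) {
    if (!length(remaining)) {
      out[[length(out) + 1]] <<- prefix
      return()
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      recurse(c(prefix, v), remaining[-i])
    }
  }
  recurse(integer(0), sort(x))
  out
}

#' Cox proportional hazards fits mirroring a univariate/multivariate table
#'
#' Thin wrapper around \code{\link[survival]{coxph}} with Breslow tie
#' handling (Efron available), convergence tolerance 1e-8 and at most 50
#' Newton-Raphson iterations. Ordinal three-level covariates are expected
#' to be numerically coded 0/1/2 so each hazard ratio is per level step.
#' Non-convergence or separation raises a diagnostic error rather than
#' returning silent output.
#'
#' @param records data frame containing \code{time}, \code{event} and
#'   covariate columns.
#' @param variables character vector of covariate column names
#'   (numeric-coded).
#' @param univariate fit each variable in its own model (\code{TRUE}) or
#'   one joint model (\code{FALSE}).
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @param time_col,event_col column names for time and event.
#' @return object of class \code{"cox_result"}: list with \code{table}
#'   (variable, coef, hr, ci_low, ci_high, se, p), \code{loglik},
#'   \code{n}, \code{n_event}, \code{univariate}, \code{ties},
#'   \code{iterations}.
#' @export
cox_fit <- function(records, variables, univariate = FALSE,
                    ties = c("breslow", "efron"),
                    time_col = "time", event_col = "event") {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(c(time_col, event_col, variables), names(records))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  check_surv(records[[time_col]], records[[event_col]])
  if (sum(records[[event_col]]) < 1) stop("need at least one event")
  for (v in variables)
    if (!is.numeric(records[[v]]))
      stop("covariate '", v, "' must be numeric-coded")

  fit_one <- function(vars) {
    f <- stats::as.formula(paste0(
      "survival::Surv(", time_col, ", ", event_col, ") ~ ",
      paste(vars, collapse = " + ")))
    wrns <- character(0)
    fit <- withCallingHandlers(
      survival::coxph(f, data = records, ties = ties,
                      control = survival::coxph.control(eps = 1e-8,
                                                        iter.max = 50)),
      warning = function(w) {
        wrns <<- c(wrns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    bad <- grepl("converge|infinite|singular", wrns)
    if (any(bad))
      stop("Cox fit failed for [", paste(vars, collapse = ", "),
           "]: ", wrns[bad][1], call. = FALSE)
    s <- summary(fit)
    list(table = data.frame(variable = rownames(s$coefficients),
                            coef = s$coefficients[, "coef"],
                            hr = s$conf.int[, "exp(coef)"],
                            ci_low = s$conf.int[, "lower .95"],
                            ci_high = s$conf.int[, "upper .95"],
                            se = s$coefficients[, "se(coef)"],
                            p = s$coefficients[, "Pr(>|z|)"],
                            stringsAsFactors = FALSE, row.names = NULL),
         loglik = fit$loglik[2], iter = fit$iter)
  }

  if (univariate) {
    tab <- do.call(rbind, lapply(variables,
                                 function(v) fit_one(v)$table))
    loglik <- NA_real_
    iters <- NA_integer_
  } else {
    joint <- fit_one(variables)
    tab <- joint$table
    loglik <- joint$loglik
    iters <- joint$iter
  }
  structure(list(table = tab, loglik = loglik,
                 n = nrow(records), n_event = sum(records[[event_col]]),
                 univariate = univariate, ties = ties,
                 iterations = iters),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties, %s): n = %d, events = %d\n",
              x$ties, if (x$univariate) "univariate" else "multivariate",
              x$n, x$n_event))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value as the sum of hypergeometric probabilities of tables
#' (with the same margins) no more probable than the observed one, via
#' \code{\link[stats]{fisher.test}}.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return a \code{gc_test}; the statistic is the conditional MLE odds
#'   ratio.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)))
    stop("`table` must be 2 x 2")
  if (any(table < 0) || any(table != floor(table)))
    stop("counts must be non-negative integers")
  ft <- stats::fisher.test(table)
  gc_test(ft$estimate, ft$p.value, method = "Fisher's exact test (2x2)",
          n = sum(table))
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Pearson statistic with \code{(r-1)(c-1)} degrees of freedom. When any
#' expected count falls below \code{min_expected} the asymptotic p-value is
#' flagged and a seeded Monte-Carlo exact p-value (conditional on the
#' margins) is attached.
#'
#' @param table r x c matrix of non-negative integer counts with positive
#'   margins.
#' @param min_expected expected-count threshold triggering the Monte-Carlo
#'   p-value (default 5).
#' @param monte_carlo_B number of Monte-Carlo tables (default 1e5).
#' @param seed integer seed for the Monte-Carlo draw (local to the call).
#' @return a \code{gc_test} with \code{df}, \code{low_expected} flag and,
#'   when flagged, \code{p_monte_carlo}.
#' @export
chi_square_rxc <- function(table, min_expected = 5, monte_carlo_B = 1e5,
                           seed = 1L) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != floor(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all row and column margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  flagged <- any(ct$expected < min_expected)
  p_mc <- NULL
  if (flagged) {
    p_mc <- withr::with_seed(seed, suppressWarnings(
      stats::chisq.test(table, simulate.p.value = TRUE,
                        B = monte_carlo_B))$p.value)
  }
  gc_test(ct$statistic, ct$p.value,
          method = "Pearson chi-square",
          n = sum(table), df = unname(ct$parameter),
          low_expected = flagged, p_monte_carlo = p_mc)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The statistic is
#' \code{U = #\{(i, j): x_i > y_j\} + 0.5 #\{ties\}}. The p-value is exact
#' (full enumeration of group assignments, valid under ties) when
#' \code{n1 + n2 <= 12} or \code{exact = TRUE}; otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact force or suppress exact enumeration; \code{NULL} (default)
#'   enumerates when the pooled size is at most 12.
#' @return a \code{gc_test} with the U statistic and a two-sided p-value.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  pooled <- c(x, y)
  u_of <- function(xs, ys) {
    r <- rank(c(xs, ys))
    sum(r[seq_along(xs)]) - length(xs) * (length(xs) + 1) / 2
  }
  U <- u_of(x, y)
  mu <- n1 * n2 / 2
  do_exact <- isTRUE(exact) || (is.null(exact) && n <= 12)
  if (do_exact) {
    combos <- utils::combn(n, n1)
    us <- apply(combos, 2, function(idx)
      u_of(pooled[idx], pooled[-idx]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "Mann-Whitney U (exact enumeration)"
  } else {
    r <- rank(pooled)
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "Mann-Whitney U (normal approximation, tie/continuity corrected)"
  }
  gc_test(U, p, method = method, n = c(n1, n2))
}
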