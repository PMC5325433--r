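# Independent oracles used across the suite. Each deliberately recomputes
# its quantity by a different route than the package (brute-force loops,
# exhaustive enumeration, closed forms).

# brute-force double-loop screen filter over an expression_matrix
brute_force_screen <- function(em, thr) {
  cls <- tolower(trimws(em$tissue_class))
  panel_cols <- which(cls %in% thr$normal_panel)
  tumor_cols <- which(cls == "tumor")
  selected <- character(0)
  for (p in rownames(em$values)) {
    nm <- -Inf
    for (j in panel_cols) nm <- max(nm, em$values[p, j])
    tum <- em$values[p, tumor_cols]
    kth <- rev(sort(tum))[thr$tumor_rank_k]
    if (nm < thr$normal_ceiling && kth >= thr$tumor_floor)
      selected <- c(selected, p)
  }
  sort(selected)
}

# naive UPGMA: at every step, inter-cluster distances are re-averaged from
# the ORIGINAL matrix over all member pairs (no Lance-Williams update)
naive_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(1, 2); bestd <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < bestd) { bestd <- dij; best <- c(i, j) }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# exhaustive hypergeometric enumeration for a 2x2 two-sided Fisher p
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
  obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact Mann-Whitney by pair counting over all group assignments
mw_enum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  pooled <- c(x, y)
  u_pairs <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- n1 * length(y) / 2
  obs <- u_pairs(x, y)
  us <- apply(utils::combn(n, n1), 2,
              function(idx) u_pairs(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  nc2 <- comb2(sum(tab))
  expected <- si * sj / nc2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)  # e.g. both partitions all-singletons
  (sij - expected) / denom
}

# small random expression matrix with an assortment of tissue classes
random_expression_matrix <- function(n_probes, n_norm = 6, n_tumor = 10,
                                     max_score = 2000) {
  panel <- c("esophagus", "pancreas", "spleen", "adipose", "lymph node",
             "artery")
  tissues <- c(panel[seq_len(n_norm)], rep("tumor", n_tumor))
  vals <- matrix(stats::runif(n_probes * length(tissues), 0, max_score),
                 nrow = n_probes,
                 dimnames = list(sprintf("pr%03d", seq_len(n_probes)),
                                 sprintf("s%02d", seq_along(tissues))))
  expression_matrix(vals, tissues)
}
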