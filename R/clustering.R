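#' Screen metrics for differences across dominant symbiont types
#'
#' Univariate screen over every metric column: Shapiro-Wilk on the
#' group-centered residuals decides between one-way ANOVA (normality not
#' rejected at alpha 0.05) and Kruskal-Wallis; metrics with p < 0.05 are
#' kept. This is a screen, not inference: no multiplicity correction is
#' applied. Constant metrics, and metrics with fewer than two groups of at
#' least `min_group` samples, are dropped with a reason.
#'
#' @param wide Samples x metrics matrix (e.g. [cubes_to_wide()]).
#' @param groups Factor of group labels (dominant symbiont types), one per
#'   row of `wide`.
#' @param alpha Keep threshold.
#' @param min_group Minimum samples per group for a group to count.
#' @return Data.frame: metric, test ("ANOVA"/"Kruskal-Wallis"/NA), p_value,
#'   kept, reason.
#' @export
screen_metrics <- function(wide, groups, alpha = 0.05, min_group = 3L) {
  groups <- factor(groups)
  stopifnot(nrow(wide) == length(groups))
  tab <- table(groups)
  if (sum(tab >= min_group) < 2L) {
    stop("need at least 2 groups with >= ", min_group, " samples")
  }
  res <- lapply(colnames(wide), function(m) {
    x <- wide[, m]
    ok <- is.finite(x)
    g <- droplevels(groups[ok])
    x <- x[ok]
    row <- data.frame(metric = m, test = NA_character_, p_value = NA_real_,
                      kept = FALSE, reason = "")
    small <- names(which(table(g) < 2L))
    if (length(small)) {
      keep <- !(g %in% small)
      x <- x[keep]
      g <- droplevels(g[keep])
    }
    if (nlevels(g) < 2L) {
      row$reason <- "fewer than 2 usable groups"
      return(row)
    }
    if (stats::sd(x) == 0) {
      row$reason <- "constant metric"
      return(row)
    }
    resid <- x - stats::ave(x, g)
    sw_p <- tryCatch(stats::shapiro.test(resid)$p.value, error = function(e) 0)
    if (sw_p >= 0.05) {
      row$test <- "ANOVA"
      row$p_value <- stats::anova(stats::aov(x ~ g))[["Pr(>F)"]][1]
    } else {
      row$test <- "Kruskal-Wallis"
      row$p_value <- stats::kruskal.test(x, g)$p.value
    }
    row$kept <- is.finite(row$p_value) && row$p_value < alpha
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Z-score a metrics x samples matrix by metric
#'
#' Each row (metric) is centered and scaled to mean 0, SD 1; missing values
#' are ignored in the moments and retained as missing.
#'
#' @param mat Metrics x samples numeric matrix.
#' @return Matrix of the same shape.
#' @export
zscore_matrix <- function(mat) {
  mu <- rowMeans(mat, na.rm = TRUE)
  sd <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sd)) || any(sd == 0)) {
    stop("zero-variance metric row(s); screen before Z-scoring: ",
         paste(utils::head(rownames(mat)[!is.finite(sd) | sd == 0]),
               collapse = ", "))
  }
  (mat - mu) / sd
}

# internal: the sample-id sets of every internal node of an hclust tree
hclust_node_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    members <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else sets[[k]]
    }))
    sets[[i]] <- sort(members)
  }
  lapply(sets, function(s) hc$labels[s])
}

# correlation distance between sample columns; the pairwise-complete path
# is only taken when missing values are actually present
cor_dist <- function(mat) {
  cc <- if (anyNA(mat)) {
    stats::cor(mat, use = "pairwise.complete.obs")
  } else {
    stats::cor(mat)
  }
  stats::as.dist(1 - cc)
}

#' Hierarchical clustering with multiscale bootstrap support
#'
#' Clusters samples (columns) by average-linkage agglomeration on
#' 1 - Pearson correlation distance between their metric vectors, and
#' attaches per-node support from a multiscale bootstrap over metric
#' resampling: metrics are resampled with replacement at relative sizes
#' `scales` (0.5-1.4), the per-scale bootstrap probability of each original
#' node is recorded, and the approximately-unbiased (AU) p-value is
#' obtained from the signed-distance/curvature fit
#' `qnorm(1 - BP_r) = v sqrt(r) + c / sqrt(r)`, giving
#' `AU = 1 - pnorm(v - c)`.
#'
#' Samples with more than `max_missing` missing metrics are excluded with a
#' warning.
#'
#' @param zmat Metrics x samples matrix (typically Z-scored).
#' @param n_boot Total bootstrap iterations, split evenly across scales.
#' @param scales Relative resampling sizes.
#' @param seed Seed making the bootstrap deterministic.
#' @param max_missing Missingness tolerance per sample.
#' @return Object of class `boot_dendrogram`: `hclust`, per-node data.frame
#'   (`members`, `au`, `bp`), scales, counts.
#' @export
bootstrap_cluster <- function(zmat, n_boot = 1000L,
                              scales = seq(0.5, 1.4, by = 0.1),
                              seed = 1L, max_missing = 0.2) {
  stopifnot(ncol(zmat) >= 3L, n_boot >= 100L)
  frac_na <- colMeans(is.na(zmat))
  if (any(frac_na > max_missing)) {
    warning("excluding ", sum(frac_na > max_missing),
            " sample(s) with > ", 100 * max_missing, "% missing metrics: ",
            paste(colnames(zmat)[frac_na > max_missing], collapse = ", "))
    zmat <- zmat[, frac_na <= max_missing, drop = FALSE]
  }
  set.seed(as.integer(seed))
  hc <- stats::hclust(cor_dist(zmat), method = "average")
  sets <- hclust_node_sets(hc)
  keys <- vapply(sets, paste, "", collapse = "\r")
  p <- nrow(zmat)
  per_scale <- max(1L, floor(n_boot / length(scales)))
  bp <- matrix(0, nrow = length(keys), ncol = length(scales))
  for (si in seq_along(scales)) {
    m <- max(2L, round(scales[si] * p))
    hits <- numeric(length(keys))
    for (b in seq_len(per_scale)) {
      idx <- sample.int(p, m, replace = TRUE)
      hcb <- stats::hclust(cor_dist(zmat[idx, , drop = FALSE]),
                           method = "average")
      kb <- vapply(hclust_node_sets(hcb), paste, "", collapse = "\r")
      hits <- hits + (keys %in% kb)
    }
    bp[, si] <- hits / per_scale
  }
  nb <- per_scale
  au <- bp_at_1 <- numeric(length(keys))
  for (i in seq_along(keys)) {
    # saturated nodes: recovered in (almost) every replicate at every
    # scale, or in none -- the signed-distance fit is degenerate there
    if (all(bp[i, ] >= 1 - 0.5 / nb)) {
      au[i] <- bp_at_1[i] <- 1
      next
    }
    if (all(bp[i, ] <= 0.5 / nb)) {
      au[i] <- bp_at_1[i] <- 0
      next
    }
    b <- pmin(pmax(bp[i, ], 0.5 / nb), 1 - 0.5 / nb)
    z <- stats::qnorm(1 - b)
    w <- nb * stats::dnorm(z)^2 / (b * (1 - b))
    X <- cbind(sqrt(scales), 1 / sqrt(scales))
    cf <- tryCatch(
      stats::lm.wfit(X, z, w)$coefficients,
      error = function(e) c(NA_real_, NA_real_)
    )
    if (anyNA(cf)) {
      au[i] <- bp_at_1[i] <- mean(bp[i, scales == 1])
    } else {
      au[i] <- 1 - stats::pnorm(cf[1] - cf[2])
      bp_at_1[i] <- 1 - stats::pnorm(cf[1] + cf[2])
    }
  }
  # the root always appears; report it with full support
  nodes <- data.frame(node = seq_along(keys),
                      size = lengths(sets),
                      au = au, bp = bp_at_1,
                      bp_raw = bp[, which.min(abs(scales - 1))])
  structure(list(hclust = hc, nodes = nodes, members = sets,
                 scales = scales, n_boot_per_scale = per_scale,
                 seed = as.integer(seed)),
            class = "boot_dendrogram")
}

#' @export
print.boot_dendrogram <- function(x, ...) {
  cat("Bootstrap dendrogram:", length(x$hclust$labels), "samples,",
      x$n_boot_per_scale * length(x$scales), "bootstrap iterations over",
      length(x$scales), "scales\n")
  top <- x$nodes[order(-x$nodes$size), ][1:min(5, nrow(x$nodes)), ]
  cat("  largest nodes (size: AU):",
      paste(sprintf("%d: %.2f", top$size, top$au), collapse = ", "), "\n")
  invisible(x)
}

#' Plot a bootstrap dendrogram with AU support
#'
#' @param x A [bootstrap_cluster()] result.
#' @param ... Passed to [plot.hclust()].
#' @export
plot.boot_dendrogram <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

#' Cut a dendrogram into k phenotypes
#'
#' Cuts at the height yielding exactly `k` groups (the k largest clustering
#' groups) and relabels phenotypes by decreasing size, ties broken by the
#' first sample id in the cluster.
#'
#' @param dend A [bootstrap_cluster()] result or an `hclust`.
#' @param k Number of phenotypes.
#' @return Object of class `phenotype_assignment`: data.frame
#'   (`sample_id`, `phenotype`) plus the dendrogram.
#' @export
cut_phenotypes <- function(dend, k = 4L) {
  hc <- if (inherits(dend, "boot_dendrogram")) dend$hclust else dend
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$labels)
  if (k > n) stop("k exceeds the number of samples (", n, ")")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  first_id <- vapply(names(sizes), function(g) {
    min(names(raw)[raw == as.integer(g)])
  }, "")
  ord <- order(-as.integer(sizes), first_id)
  relabel <- stats::setNames(seq_len(k), names(sizes)[ord])
  pheno <- unname(relabel[as.character(raw)])
  structure(list(
    assignment = data.frame(sample_id = names(raw), phenotype = pheno),
    k = k,
    dendrogram = if (inherits(dend, "boot_dendrogram")) dend else NULL,
    hclust = hc),
    class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  cat("Phenotype assignment: k =", x$k, "\n")
  print(table(phenotype = x$assignment$phenotype))
  invisible(x)
}

#' Rank metrics driving phenotype separation
#'
#' Scores every metric by its one-way between-phenotype F statistic on the
#' (Z-scored) values and aggregates by metric family (the metric name
#' component of `metric_wavelength_timepoint`), reporting the median family
#' F. When no metric reaches p < 0.05 the ranking is flagged uninformative.
#'
#' @param zmat Metrics x samples matrix.
#' @param assignment A [cut_phenotypes()] result (or a factor of labels
#'   aligned with `zmat` columns).
#' @return List with `metrics` (per-metric F and p, ranked) and `families`
#'   (family, median_F, n, rank), plus `informative`.
#' @export
rank_driver_metrics <- function(zmat, assignment) {
  g <- if (inherits(assignment, "phenotype_assignment")) {
    a <- assignment$assignment
    factor(a$phenotype[match(colnames(zmat), a$sample_id)])
  } else {
    factor(assignment)
  }
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 phenotypes")
  f_of <- function(x) {
    ok <- is.finite(x)
    gg <- droplevels(g[ok])
    if (nlevels(gg) < 2L || stats::sd(x[ok]) == 0) return(c(NA, NA))
    a <- stats::anova(stats::aov(x[ok] ~ gg))
    c(a[["F value"]][1], a[["Pr(>F)"]][1])
  }
  fs <- t(apply(zmat, 1L, f_of))
  metrics <- data.frame(metric = rownames(zmat), F = fs[, 1], p = fs[, 2])
  metrics <- metrics[order(-metrics$F), ]
  rownames(metrics) <- NULL
  fam <- sub("_.*$", "", metrics$metric)
  med <- tapply(metrics$F, fam, stats::median, na.rm = TRUE)
  families <- data.frame(family = names(med), median_F = as.numeric(med),
                         n = as.integer(table(fam)[names(med)]))
  families <- families[order(-families$median_F), ]
  families$rank <- seq_len(nrow(families))
  rownames(families) <- NULL
  list(metrics = metrics, families = families,
       informative = any(metrics$p < 0.05, na.rm = TRUE))
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b Two label vectors of equal length.
#' @return The Hubert-Arabie adjusted Rand index.
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Export a bootstrap dendrogram as Newick with node support
#'
#' Internal nodes carry their AU support (as a 0-100 label) in the Newick
#' node-label position.
#'
#' @param dend A [bootstrap_cluster()] result.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  stopifnot(inherits(dend, "boot_dendrogram"))
  phy <- ape::as.phylo(dend$hclust)
  # ape orders internal nodes; map via member sets
  phy$node.label <- rep("", phy$Nnode)
  tip_sets <- lapply(seq_len(phy$Nnode) + length(phy$tip.label),
                     function(nd) {
    sort(phy$tip.label[unlist(phangorn_desc(phy, nd))])
  })
  keys_hc <- vapply(dend$members, paste, "", collapse = "\r")
  keys_phy <- vapply(tip_sets, paste, "", collapse = "\r")
  m <- match(keys_phy, keys_hc)
  phy$node.label[!is.na(m)] <-
    sprintf("%.0f", 100 * dend$nodes$au[m[!is.na(m)]])
  ape::write.tree(phy, file = path)
  invisible(path)
}

# tips descending from a node (small recursive helper; avoids a phangorn
# dependency for one traversal)
phangorn_desc <- function(phy, node) {
  nt <- length(phy$tip.label)
  if (node <= nt) return(node)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_desc, phy = phy))
}
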