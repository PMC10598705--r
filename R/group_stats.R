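#' Compare metric trajectories across phenotypes or wavelengths
#'
#' For each metric x wavelength (phenotype factor) or metric x phenotype
#' (wavelength factor), fits the repeated-measures linear mixed model
#' `value ~ group + timepoint + (1 | fragment)` by REML (timepoint as a
#' categorical fixed effect, a random intercept per fragment) and tests all
#' pairwise group contrasts with Bonferroni adjustment within the family.
#' A singular or failed fit falls back to a two-stage comparison of
#' per-fragment means (pairwise Welch t tests, Bonferroni), flagged in the
#' output.
#'
#' @param cubes List of `metric_cube` objects (one per fragment).
#' @param assignment A [cut_phenotypes()] result or a data.frame
#'   (`sample_id`, `phenotype`).
#' @param factor Contrast factor: `"phenotype"` (spectral profiles pooled
#'   within wavelength) or `"wavelength"` (within phenotype).
#' @param metrics Metric families to test (default all 8).
#' @param alpha Significance level applied to adjusted p-values.
#' @return Data.frame of class `contrast_table`: metric, stratum, pair,
#'   estimate, p_adjusted, significant, family_size, method.
#' @export
compare_profiles <- function(cubes, assignment,
                             factor = c("phenotype", "wavelength"),
                             metrics = metric_names(), alpha = 0.05) {
  factor <- match.arg(factor)
  if (inherits(assignment, "phenotype_assignment")) {
    assignment <- assignment$assignment
  }
  tidy <- do.call(rbind, lapply(cubes, cube_to_tidy))
  tidy$phenotype <- assignment$phenotype[match(tidy$sample_id,
                                               assignment$sample_id)]
  tidy <- tidy[!is.na(tidy$phenotype) & tidy$metric %in% metrics, ]
  tidy$phenotype <- base::factor(tidy$phenotype)
  tidy$wavelength_nm <- base::factor(tidy$wavelength_nm)
  tidy$timepoint <- base::factor(tidy$timepoint_index)
  grp_col <- if (factor == "phenotype") "phenotype" else "wavelength_nm"
  strat_col <- if (factor == "phenotype") "wavelength_nm" else "phenotype"
  strata <- split(tidy, list(tidy$metric, tidy[[strat_col]]), drop = TRUE)
  out <- lapply(strata, function(d) {
    d$group <- droplevels(d[[grp_col]])
    d$fragment <- base::factor(d$sample_id)
    d <- d[is.finite(d$value), ]
    tab <- table(unique(d[, c("fragment", "group")])$group)
    if (sum(tab >= 3L) < 2L) return(NULL)
    contrast_mixed(d, metric = d$metric[1],
                   stratum = as.character(d[[strat_col]][1]), alpha = alpha)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("contrast_table", "data.frame")
  res
}

# fit one stratum's mixed model and extract Bonferroni-adjusted pairwise
# group contrasts, with the two-stage fallback
contrast_mixed <- function(d, metric, stratum, alpha = 0.05) {
  pairs_of <- function(lv) {
    utils::combn(lv, 2L, paste, collapse = " - ")
  }
  fallback <- function() {
    agg <- stats::aggregate(value ~ fragment + group, d, mean)
    lv <- levels(droplevels(agg$group))
    cmb <- utils::combn(lv, 2L)
    est <- p <- numeric(ncol(cmb))
    for (j in seq_len(ncol(cmb))) {
      x <- agg$value[agg$group == cmb[1, j]]
      y <- agg$value[agg$group == cmb[2, j]]
      est[j] <- mean(x) - mean(y)
      p[j] <- if (stats::sd(c(x, y)) == 0) 1 else
        tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
    }
    padj <- pmin(p * ncol(cmb), 1)
    data.frame(metric = metric, stratum = stratum,
               pair = pairs_of(lv)[seq_len(ncol(cmb))],
               estimate = est, p_adjusted = padj,
               significant = is.finite(padj) & padj < alpha,
               family_size = ncol(cmb), method = "two-stage fallback")
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      value ~ group + timepoint + (1 | fragment), data = d)),
    error = function(e) NULL)
  if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) return(fallback())
  gl <- tryCatch(
    summary(multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey")),
            test = multcomp::adjusted("bonferroni")),
    error = function(e) NULL)
  if (is.null(gl)) return(fallback())
  est <- as.numeric(gl$test$coefficients)
  padj <- as.numeric(gl$test$pvalues)
  data.frame(metric = metric, stratum = stratum,
             pair = names(gl$test$coefficients),
             estimate = est, p_adjusted = padj,
             significant = padj < alpha,
             family_size = length(est), method = "lmm")
}

#' Compare cellular traits across phenotypes
#'
#' Per trait: Shapiro-Wilk on group-centered residuals gates between
#' one-way ANOVA with Tukey HSD and Kruskal-Wallis with Bonferroni-adjusted
#' pairwise Wilcoxon tests; a compact letter display is computed from the
#' pairwise significance graph (phenotypes sharing a letter are pairwise
#' non-significant). Constant traits are skipped with a warning.
#'
#' @param traits Data.frame with `sample_id` and numeric trait columns.
#' @param assignment A [cut_phenotypes()] result or data.frame
#'   (`sample_id`, `phenotype`).
#' @param trait_cols Trait columns to test (default: all numeric except
#'   ids).
#' @param alpha Significance level.
#' @return List of class `trait_comparison`: `tests` (trait, test,
#'   p_value), `pairwise` (trait, pair, p_adjusted, significant), `letters`
#'   (trait x phenotype compact letter display).
#' @export
compare_cellular_traits <- function(traits, assignment, trait_cols = NULL,
                                    alpha = 0.05) {
  if (inherits(assignment, "phenotype_assignment")) {
    assignment <- assignment$assignment
  }
  g <- factor(assignment$phenotype[match(traits$sample_id,
                                         assignment$sample_id)])
  keep <- !is.na(g)
  traits <- traits[keep, ]
  g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least 2 phenotypes")
  if (any(table(g) < 3L)) {
    stop("every phenotype needs at least 3 samples for trait comparison")
  }
  if (is.null(trait_cols)) {
    trait_cols <- setdiff(names(traits)[vapply(traits, is.numeric,
                                               logical(1))],
                          c("fragment", "seed"))
  }
  tests <- pairwise <- NULL
  letters_mat <- NULL
  for (tr in trait_cols) {
    x <- traits[[tr]]
    if (stats::sd(x, na.rm = TRUE) == 0) {
      warning("skipping constant trait: ", tr)
      next
    }
    resid <- x - stats::ave(x, g, FUN = function(v) mean(v, na.rm = TRUE))
    sw_p <- tryCatch(stats::shapiro.test(resid)$p.value, error = function(e) 0)
    lv <- levels(g)
    cmb <- utils::combn(lv, 2L)
    pairnm <- apply(cmb, 2L, paste, collapse = "-")
    if (sw_p >= 0.05) {
      fit <- stats::aov(x ~ g)
      tests <- rbind(tests, data.frame(
        trait = tr, test = "ANOVA+Tukey",
        p_value = stats::anova(fit)[["Pr(>F)"]][1]))
      tk <- stats::TukeyHSD(fit)$g
      p_adj <- tk[match(paste(cmb[2, ], cmb[1, ], sep = "-"),
                        rownames(tk)), "p adj"]
    } else {
      kw <- stats::kruskal.test(x, g)
      tests <- rbind(tests, data.frame(
        trait = tr, test = "Kruskal-Wallis+Bonferroni",
        p_value = kw$p.value))
      pw <- stats::pairwise.wilcox.test(x, g, p.adjust.method = "bonferroni",
                                        exact = FALSE)$p.value
      look <- function(r, c) {
        if (r %in% rownames(pw) && c %in% colnames(pw)) pw[r, c] else NA_real_
      }
      p_adj <- vapply(seq_len(ncol(cmb)), function(j) {
        a <- cmb[1, j]; b <- cmb[2, j]
        v <- c(look(b, a), look(a, b))
        if (any(is.finite(v))) v[is.finite(v)][1] else NA_real_
      }, numeric(1))
    }
    pairwise <- rbind(pairwise, data.frame(
      trait = tr, pair = pairnm, p_adjusted = p_adj,
      significant = is.finite(p_adj) & p_adj < alpha))
    sig <- matrix(FALSE, nlevels(g), nlevels(g),
                  dimnames = list(lv, lv))
    for (j in seq_len(ncol(cmb))) {
      s <- is.finite(p_adj[j]) && p_adj[j] < alpha
      sig[cmb[1, j], cmb[2, j]] <- sig[cmb[2, j], cmb[1, j]] <- s
    }
    letters_mat <- rbind(letters_mat, cld_letters(sig))
    rownames(letters_mat)[nrow(letters_mat)] <- tr
  }
  structure(list(tests = tests, pairwise = pairwise,
                 letters = letters_mat, phenotypes = levels(g)),
            class = "trait_comparison")
}

#' @export
print.trait_comparison <- function(x, ...) {
  cat("Cellular trait comparison across", length(x$phenotypes),
      "phenotypes\n")
  print(x$tests, row.names = FALSE)
  cat("compact letter display:\n")
  print(x$letters)
  invisible(x)
}

# compact letter display by insert-and-absorb on the pairwise significance
# matrix: start from one letter covering everything and split it at every
# significant pair, so groups share a letter iff no significant difference
# separates them along the way
cld_letters <- function(sig) {
  lv <- rownames(sig)
  cols <- list(lv)
  absorb <- function(cols) {
    keep <- rep(TRUE, length(cols))
    for (i in seq_along(cols)) {
      for (j in seq_along(cols)) {
        if (i == j || !keep[i] || !keep[j]) next
        sub <- all(cols[[i]] %in% cols[[j]])
        proper <- sub && !all(cols[[j]] %in% cols[[i]])
        if (proper || (sub && j < i)) keep[i] <- FALSE
      }
    }
    cols[keep]
  }
  pairs <- which(upper.tri(sig) & sig, arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    a <- lv[pairs[k, 1]]
    b <- lv[pairs[k, 2]]
    nxt <- list()
    for (cl in cols) {
      if (a %in% cl && b %in% cl) {
        nxt <- c(nxt, list(setdiff(cl, a)), list(setdiff(cl, b)))
      } else {
        nxt <- c(nxt, list(cl))
      }
    }
    cols <- absorb(nxt)
  }
  out <- vapply(lv, function(g) {
    paste(letters[which(vapply(cols, function(cl) g %in% cl, logical(1)))],
          collapse = "")
  }, "")
  matrix(out, nrow = 1, dimnames = list(NULL, lv))
}
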