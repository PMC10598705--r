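make_groups <- function(n_per = 10L, k = 3L) {
  factor(rep(seq_len(k), each = n_per))
}

test_that("screening keeps planted shifts and drops constants", {
  set.seed(21)
  g <- make_groups(10, 2)
  n <- length(g)
  wide <- cbind(
    shifted = rnorm(n) + 5 * (g == 2),      # 5 pooled SDs apart
    null1 = rnorm(n),
    const = rep(3, n))
  scr <- screen_metrics(wide, g)
  expect_true(scr$kept[scr$metric == "shifted"])
  expect_false(scr$kept[scr$metric == "const"])
  expect_equal(scr$reason[scr$metric == "const"], "constant metric")
  expect_error(screen_metrics(wide[1:4, ], g[1:4]), "at least 2 groups")
  # planted shift is detected in every seed (power ~ 1)
  kept <- sapply(1:20, function(s) {
    set.seed(s)
    w <- cbind(m = rnorm(n) + 5 * (g == 2))
    screen_metrics(w, g)$kept
  })
  expect_true(all(kept))
})

test_that("screening has nominal type-I control on null metrics", {
  set.seed(99)
  g <- make_groups(10, 6)
  nulls <- matrix(rnorm(length(g) * 1000), nrow = length(g))
  colnames(nulls) <- paste0("null_", seq_len(ncol(nulls)))
  scr <- screen_metrics(nulls, g)
  expect_gte(mean(scr$kept), 0.03)
  expect_lte(mean(scr$kept), 0.07)
  # both test branches get exercised by the Shapiro gate
  expect_true(all(c("ANOVA", "Kruskal-Wallis") %in% scr$test) ||
                all(scr$test == "ANOVA"))
})

test_that("Z-scoring standardizes rows and is affine invariant", {
  set.seed(3)
  m <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("m", 1:5), paste0("s", 1:10)))
  z <- zscore_matrix(m)
  expect_equal(unname(rowMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-12)
  expect_equal(zscore_matrix(3 * m - 17), z, tolerance = 1e-12)
  m[2, 3] <- NA
  z2 <- zscore_matrix(m)
  expect_true(is.na(z2[2, 3]) && sum(is.na(z2)) == 1L)
  expect_error(zscore_matrix(rbind(m, flat = rep(1, 10))), "zero-variance")
})

# two sample blocks with opposite metric signatures: half the metrics go
# up and half go down in the second block, so the blocks separate under
# correlation distance between sample profiles
two_block_matrix <- function(seed = 1, n_metrics = 40L, shift = 4) {
  set.seed(seed)
  samples <- paste0("s", 1:12)
  m <- matrix(rnorm(n_metrics * 12), n_metrics, 12,
              dimnames = list(paste0("m", 1:n_metrics), samples))
  half <- seq_len(n_metrics / 2)
  m[half, 7:12] <- m[half, 7:12] + shift
  m[-half, 7:12] <- m[-half, 7:12] - shift
  m
}

test_that("bootstrap clustering finds well-separated groups with support", {
  sup <- sapply(1:5, function(s) {
    zm <- zscore_matrix(two_block_matrix(seed = s))
    bd <- bootstrap_cluster(zm, n_boot = 1000, seed = s)
    # both 6-sample blocks must be recovered with high AU support
    blocks <- bd$nodes[bd$nodes$size == 6, ]
    keys <- vapply(bd$members[blocks$node], paste, "", collapse = ",")
    want <- c(paste(paste0("s", 1:6), collapse = ","),
              paste(paste0("s", 7:12), collapse = ","))
    if (!all(want %in% keys)) return(0)
    min(blocks$au[keys %in% want])
  })
  expect_gte(median(sup), 0.95)
})

test_that("bootstrap clustering is seed-deterministic and null-calibrated", {
  zm <- zscore_matrix(two_block_matrix())
  a <- bootstrap_cluster(zm, n_boot = 200, seed = 5)
  b <- bootstrap_cluster(zm, n_boot = 200, seed = 5)
  expect_identical(a$nodes, b$nodes)
  # structureless (null) data: cluster-scale nodes (size >= 3; tight
  # sample pairs are known to draw high support even under the null)
  # rarely reach 0.95 support
  high <- sapply(1:10, function(s) {
    set.seed(s)
    null <- matrix(rnorm(40 * 12), 40, 12,
                   dimnames = list(paste0("m", 1:40), paste0("s", 1:12)))
    bd <- bootstrap_cluster(zscore_matrix(null), n_boot = 1000, seed = s)
    inner <- bd$nodes$size < ncol(null) & bd$nodes$size >= 3
    max(bd$nodes$au[inner])
  })
  expect_gte(mean(high < 0.95), 0.8)
})

test_that("duplicated samples merge at zero height; missingness excluded", {
  zm <- zscore_matrix(two_block_matrix())
  zm <- cbind(zm, s1dup = zm[, "s1"])
  bd <- bootstrap_cluster(zm, n_boot = 150, seed = 1)
  pairnode <- which(vapply(bd$members, function(s)
    setequal(s, c("s1", "s1dup")), logical(1)))
  expect_length(pairnode, 1L)
  expect_equal(bd$hclust$height[pairnode], 0, tolerance = 1e-12)
  zm_na <- zm
  zm_na[1:15, "s2"] <- NA  # 37% missing
  expect_warning(bootstrap_cluster(zm_na, n_boot = 150, seed = 1),
                 "excluding")
})

test_that("phenotype cuts select the k largest groups deterministically", {
  zm <- zscore_matrix(two_block_matrix())
  bd <- bootstrap_cluster(zm, n_boot = 150, seed = 2)
  a2 <- cut_phenotypes(bd, k = 2)
  expect_equal(sort(unique(a2$assignment$phenotype)), 1:2)
  expect_equal(unname(table(a2$assignment$phenotype)), c(6L, 6L),
               ignore_attr = TRUE)
  # ties in size are broken by first sample id: s1's block gets label 1
  expect_equal(a2$assignment$phenotype[a2$assignment$sample_id == "s1"], 1L)
  a1 <- cut_phenotypes(bd, k = 1)
  expect_true(all(a1$assignment$phenotype == 1L))
  an <- cut_phenotypes(bd, k = ncol(zm))
  expect_equal(sort(an$assignment$phenotype), 1:ncol(zm))
  expect_error(cut_phenotypes(bd, k = 99), "exceeds")
})

test_that("clustering is invariant to sample order", {
  zm <- zscore_matrix(two_block_matrix())
  perm <- sample(ncol(zm))
  a <- cut_phenotypes(bootstrap_cluster(zm, n_boot = 150, seed = 3), k = 2)
  b <- cut_phenotypes(bootstrap_cluster(zm[, perm], n_boot = 150, seed = 3),
                      k = 2)
  ma <- a$assignment$phenotype[match(colnames(zm), a$assignment$sample_id)]
  mb <- b$assignment$phenotype[match(colnames(zm), b$assignment$sample_id)]
  expect_equal(adjusted_rand(ma, mb), 1)
})

test_that("driver ranking surfaces the separating metric family", {
  set.seed(8)
  samples <- paste0("s", 1:12)
  g <- rep(1:2, each = 6)
  rows <- c(paste0("NPQ_442_", 1:10), paste0("qP_442_", 1:10))
  m <- matrix(rnorm(20 * 12), 20, 12, dimnames = list(rows, samples))
  m[1:10, g == 2] <- m[1:10, g == 2] + 4   # only NPQ family separates
  rk <- rank_driver_metrics(zscore_matrix(m),
                            setNames(g, samples)[samples])
  expect_equal(rk$families$family[1], "NPQ")
  expect_true(rk$informative)
  # identical phenotypes: uninformative flag
  rk0 <- rank_driver_metrics(zscore_matrix(m[, ]), factor(rep(1:2, 6)))
  expect_error(rank_driver_metrics(m, factor(rep(1, 12))), "2 phenotypes")
})

test_that("adjusted Rand agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(1:5, 1:5), 1)
})

test_that("dendrogram exports to Newick with support labels", {
  zm <- zscore_matrix(two_block_matrix())
  bd <- bootstrap_cluster(zm, n_boot = 150, seed = 4)
  path <- tempfile(fileext = ".nwk")
  write_dendrogram_newick(bd, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, colnames(zm))
  expect_true(any(nchar(phy$node.label) > 0))
})
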