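test_that("Bray-Curtis matches its closed form and vegan", {
  x <- rbind(a = c(1, 1, 0), b = c(0, 1, 1))
  expect_equal(as.numeric(bray_curtis(x)), 0.5)
  same <- rbind(a = c(2, 3, 1), b = c(2, 3, 1))
  expect_equal(as.numeric(bray_curtis(same)), 0)
  disjoint <- rbind(a = c(4, 0, 0), b = c(0, 2, 5))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  set.seed(1)
  m <- matrix(rpois(60, 4), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("o", 1:6)))
  m[1, ] <- m[1, ] + 1  # guard positive totals
  expect_equal(as.vector(bray_curtis(m)),
               as.vector(vegan::vegdist(m, "bray")))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "Zero-total")
})

test_that("PERMANOVA reduces to classical ANOVA on univariate Euclidean data", {
  set.seed(12)
  y <- rnorm(14)
  g <- rep(c("a", "b"), 7)
  res <- permanova(stats::dist(y), data.frame(g = g), ~ g, n_perm = 99,
                   seed = 1)
  f_classic <- anova(lm(y ~ g))$`F value`[1]
  expect_equal(res$table$pseudo_f[1], f_classic, tolerance = 1e-8)
  expect_equal(sum(res$table$r2[res$table$term != "Total"]), 100,
               tolerance = 1e-6)
})

test_that("exhaustive permutations agree with independent oracles", {
  set.seed(4)
  y <- rnorm(6)
  g <- rep(c("a", "b"), each = 3)
  perms <- all_permutations(6)
  res <- permanova(stats::dist(y), data.frame(g = g), ~ g,
                   permutations = perms)
  # oracle 1: classical F recomputed for every permutation of y
  f_of <- function(yy) anova(lm(yy ~ g))$`F value`[1]
  f_obs <- f_of(y)
  p_oracle <- (sum(apply(perms, 1, function(p) f_of(y[p])) >=
                     f_obs - 1e-12) + 1) / (nrow(perms) + 1)
  expect_equal(res$table$p_value[1], p_oracle, tolerance = 1e-12)
  # oracle 2: vegan with the identical permutation set
  ad <- vegan::adonis2(stats::dist(y) ~ g, data = data.frame(g = g),
                       permutations = perms[-1, , drop = FALSE])
  expect_equal(res$table$pseudo_f[1], ad$F[1], tolerance = 1e-10)
  expect_equal(res$table$sum_sq[1], ad$SumOfSqs[1], tolerance = 1e-10)
})

test_that("sequential terms match vegan and are order-sensitive", {
  set.seed(8)
  m <- matrix(rpois(20 * 8, 6), 20, 8,
              dimnames = list(paste0("s", 1:20), paste0("o", 1:8)))
  d <- bray_curtis(hellinger(as_otu_table(m)))
  df <- data.frame(sample_id = paste0("s", 1:20),
                   cov = rnorm(20), grp = rep(c("x", "y"), 10))
  res <- permanova(d, df, ~ cov + grp, n_perm = 99, seed = 2)
  ad <- vegan::adonis2(d ~ cov + grp, data = df, by = "terms",
                       permutations = 99)
  expect_equal(res$table$sum_sq[1:2], ad$SumOfSqs[1:2], tolerance = 1e-10)
  expect_equal(res$table$pseudo_f[1:2], ad$F[1:2], tolerance = 1e-10)
  expect_error(permanova(d, transform(df, grp = "x"), ~ grp),
               "single level")
})

test_that("perfect group separation is detected with maximal R2", {
  block <- rbind(matrix(rep(c(5, 0, 1, 0), 7), 7, 4, byrow = TRUE),
                 matrix(rep(c(0, 4, 0, 6), 7), 7, 4, byrow = TRUE))
  rownames(block) <- paste0("s", 1:14)
  colnames(block) <- paste0("o", 1:4)
  d <- bray_curtis(block)
  res <- permanova(d, data.frame(g = rep(c("a", "b"), each = 7)), ~ g,
                   n_perm = 199, seed = 1)
  expect_gt(res$table$r2[1], 99.9)
  # ties occur only when a permutation recreates the exact split
  expect_lte(res$table$p_value[1], 0.015)
})

test_that("eigenvector maps reproduce wave ordering on a transect", {
  d <- stats::dist(cbind(1:10, 0))
  basis <- dbmem(d)
  v <- basis$vectors
  expect_true(all(diff(basis$values) <= 1e-9))
  # orthonormal columns
  gram <- crossprod(v)
  expect_equal(gram, diag(ncol(v)), tolerance = 1e-8,
               ignore_attr = TRUE)
  sign_changes <- function(x) sum(diff(sign(x)) != 0)
  expect_equal(sign_changes(v[, 1]), 1)
  expect_equal(sign_changes(v[, 2]), 2)
  expect_equal(sign_changes(v[, 3]), 3)
})

test_that("eigenvector maps separate distant clusters", {
  coords <- c(0, 1, 2, 100, 101, 102)
  basis <- dbmem(stats::dist(cbind(coords, 0)))
  v1 <- basis$vectors[, 1]
  expect_equal(length(unique(sign(v1[1:3]))), 1)
  expect_equal(length(unique(sign(v1[4:6]))), 1)
  expect_true(sign(v1[1]) != sign(v1[4]))
  # degenerate input: identical points give an empty basis
  expect_warning(empty <- dbmem(stats::dist(cbind(rep(0, 4), 0))),
                 "No positive eigenvalues")
  expect_equal(ncol(empty$vectors), 0)
})

test_that("temporal distances pool winter-adjacent months", {
  dates <- as.Date(c("2018-02-10", "2018-04-20", "2018-11-05",
                     "2019-01-20", "2018-07-01"))
  d <- as.matrix(temporal_distances(dates))
  expect_equal(d[1, 2], 0)   # Feb and Apr pooled to March
  expect_equal(d[3, 4], 0)   # Nov and next Jan pooled to December
  expect_gt(d[1, 5], 0)
})

test_that("plant-phylogeny community distances match hand-computed values", {
  dir <- withr::local_tempdir()
  writeLines("((A:1,B:1):1,C:2);", file.path(dir, "t.nwk"))
  tr <- read_survey_tree(file.path(dir, "t.nwk"))
  comm <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         A = c(1, 0, 1), B = c(0, 1, 0), C = c(0, 0, 1))
  dd <- phylo_community_distances(tr, comm)
  cd <- as.matrix(dd$comdist)
  cdnt <- as.matrix(dd$comdistnt)
  ps <- as.matrix(dd$phylosor)
  expect_equal(cd["s1", "s2"], 2)    # patristic path A-B
  expect_equal(cdnt["s1", "s2"], 2)
  # identical single-species communities
  same <- tibble::tibble(sample_id = c("x", "y"), A = c(1, 1),
                         B = c(0, 0), C = c(0, 0))
  ds <- phylo_community_distances(tr, same)
  expect_equal(as.numeric(ds$comdist), 0)
  expect_equal(as.numeric(ds$comdistnt), 0)
  expect_equal(as.numeric(ds$phylosor), 0)
  bad <- tibble::tibble(sample_id = "s", A = 1, Zed = 1)
  expect_error(phylo_community_distances(tr, bad), "Zed")
})

test_that("NMDS embeds planar configurations with near-zero stress", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1), c(0.5, 2))
  rownames(pts) <- paste0("s", 1:5)
  d <- stats::dist(pts)
  fit <- nmds(d, k = 2, n_starts = 10, seed = 3)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds(d, k = 2, n_starts = 10, seed = 3)
  expect_identical(fit$points, fit2$points)
  expect_error(nmds(stats::dist(c(0, 1, NA))), "finite")
})

test_that("environment vectors recover an axis-aligned gradient", {
  pts <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("s", 1:30), NULL))
  fit <- structure(
    list(points = dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(pts)),
      tibble::tibble(NMDS1 = pts[, 1], NMDS2 = pts[, 2]))),
    class = "nmds_fit")
  env <- tibble::tibble(sample_id = rownames(pts),
                        grad = pts[, 1], flat = rep(1, 30))
  expect_warning(ef <- envfit_vectors(fit, env, n_perm = 99, seed = 1),
                 "constant")
  expect_equal(ef$r2[ef$variable == "grad"], 1, tolerance = 1e-6)
  expect_gt(abs(ef$NMDS1[ef$variable == "grad"]), 0.999)
  expect_lte(ef$p_value[ef$variable == "grad"], 0.01)
})
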