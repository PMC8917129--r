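test_that("Bray-Curtis reproduces worked examples and vegan", {
  x <- rbind(s1 = c(2, 2, 0), s2 = c(0, 2, 2), s3 = c(2, 2, 0))
  colnames(x) <- c("a", "b", "c")
  d <- as.matrix(bray_curtis(x))
  expect_equal(d["s1", "s2"], 0.5)
  expect_equal(d["s1", "s3"], 0)
  disj <- rbind(s1 = c(3, 0), s2 = c(0, 7))
  expect_equal(as.matrix(bray_curtis(disj))["s1", "s2"], 1)
  skip_if_not_installed("vegan")
  t1 <- tiny_table(seed = 2, n = 8, p = 6)
  expect_equal(as.matrix(bray_curtis(t1)),
               as.matrix(vegan::vegdist(t1, "bray")), tolerance = 1e-12)
})

test_that("unweighted UniFrac matches hand computation on a star tree", {
  tr <- star_tree(c("l1", "l2", "l3"))
  tab <- rbind(A = c(l1 = 1, l2 = 1, l3 = 0),
               B = c(l1 = 0, l2 = 1, l3 = 1))
  expect_equal(as.matrix(unweighted_unifrac(tab, tr))["A", "B"], 2 / 3)
  # identical presence vectors
  same <- rbind(A = c(l1 = 1, l2 = 3, l3 = 0), B = c(l1 = 5, l2 = 1, l3 = 0))
  expect_equal(as.matrix(unweighted_unifrac(same, tr))["A", "B"], 0)
  # disjoint leaf sets
  dis <- rbind(A = c(l1 = 1, l2 = 0, l3 = 0), B = c(l1 = 0, l2 = 0, l3 = 2))
  expect_equal(as.matrix(unweighted_unifrac(dis, tr))["A", "B"], 1)
  bad <- rbind(A = c(l1 = 1, lX = 1))
  colnames(bad) <- c("l1", "lX")
  expect_error(unweighted_unifrac(bad, tr), "lX")
})

test_that("weighted UniFrac closed forms and invariances hold", {
  tr2 <- star_tree(c("l1", "l2"))
  tab <- rbind(A = c(l1 = 4, l2 = 0), B = c(l1 = 0, l2 = 9))
  expect_equal(as.matrix(weighted_unifrac(tab, tr2, normalized = TRUE))["A", "B"], 1)
  same <- rbind(A = c(l1 = 2, l2 = 6), B = c(l1 = 1, l2 = 3))
  expect_equal(as.matrix(weighted_unifrac(same, tr2))["A", "B"], 0)
  # scaling one sample leaves relative abundances unchanged
  t1 <- tiny_table(seed = 3, n = 4, p = 5)
  tr5 <- ape::rcoal(5, tip.label = colnames(t1))
  d1 <- as.matrix(weighted_unifrac(t1, tr5))
  t2 <- t1; t2[2, ] <- t2[2, ] * 13
  expect_equal(as.matrix(weighted_unifrac(t2, tr5)), d1, tolerance = 1e-12)
  expect_error(weighted_unifrac(rbind(t1, zero = rep(0, 5)), tr5), "zero")
})

test_that("UniFrac agrees with the phyloseq implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(7)
  tr <- ape::rcoal(8, tip.label = paste0("a", 1:8))
  cnt <- matrix(rpois(48, 15), 6, 8,
                dimnames = list(paste0("s", 1:6), paste0("a", 1:8)))
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(cnt, taxa_are_rows = FALSE), phyloseq::phy_tree(tr))
  expect_equal(as.matrix(unweighted_unifrac(cnt, tr)),
               as.matrix(phyloseq::UniFrac(ps, weighted = FALSE)),
               tolerance = 1e-9)
  expect_equal(as.matrix(weighted_unifrac(cnt, tr, normalized = TRUE)),
               as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = TRUE)),
               tolerance = 1e-9)
  expect_equal(as.matrix(weighted_unifrac(cnt, tr, normalized = FALSE)),
               as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = FALSE)),
               tolerance = 1e-9)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # collinear points at 0, 3, 4: one informative axis
  pts <- c(0, 3, 4)
  dm <- as.matrix(dist(pts)); dimnames(dm) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(dm)
  expect_equal(sum(ord$eigenvalues > 1e-9), 1)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)
  # regular simplex: n-1 equal eigenvalues
  n <- 5
  simplex <- matrix(1, n, n) - diag(n)
  dimnames(simplex) <- list(paste0("s", 1:n), paste0("s", 1:n))
  os <- pcoa(simplex)
  pos <- os$eigenvalues[os$eigenvalues > 1e-9]
  expect_length(pos, n - 1)
  expect_lt(diff(range(pos)), 1e-9)
  # Euclidean input: no meaningful negative eigenvalue
  t1 <- tiny_table(seed = 4, n = 7, p = 4)
  de <- as.matrix(dist(t1))
  expect_gt(min(pcoa(de)$eigenvalues), -1e-9 * max(abs(de)))
  expect_error(pcoa(dm[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA statistic matches vegan and classical 1-D ANOVA", {
  skip_if_not_installed("vegan")
  t1 <- tiny_table(seed = 6, n = 12, p = 5)
  g <- rep(c("A", "B", "C"), each = 4)
  d <- bray_curtis(t1)
  mine <- permanova(d, g, n_permutations = 999, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g, permutations = 99)
  expect_equal(mine$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$effect_size, ref$R2[1], tolerance = 1e-10)
  # Euclidean distance on 1-D data: pseudo-F equals the ANOVA F
  v <- c(1.2, 0.8, 1.5, 3.3, 2.9, 3.8)
  gv <- rep(c("x", "y"), each = 3)
  dm <- as.matrix(dist(v)); dimnames(dm) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expect_equal(permanova(dm, gv, 999, seed = 1)$statistic,
               anova_oneway(v, gv)$statistic, tolerance = 1e-10)
})

test_that("PERMANOVA separates structure and degrades gracefully", {
  set.seed(9)
  cloud <- rbind(matrix(rnorm(40), 10, 4), matrix(rnorm(40, 6), 10, 4))
  rownames(cloud) <- paste0("s", 1:20)
  d <- as.matrix(dist(cloud))
  g <- rep(c("A", "B"), each = 10)
  r <- permanova(d, g, n_permutations = 999, seed = 2)
  expect_gt(r$effect_size, 0.5)
  expect_lte(r$p_value, 0.001)
  # all-zero distances: degenerate
  z <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  dz <- permanova(z, rep(c("A", "B"), 2), 999, seed = 1)
  expect_true(dz$degenerate)
  expect_equal(dz$p_value, 1)
  expect_error(permanova(d, c("A", rep("B", 19)), 999), "size")
})

test_that("exhaustive PERMANOVA and ANOSIM match an independent enumeration", {
  skip_if_not_installed("vegan")
  set.seed(10)
  for (labels in list(rep(c("A", "B"), each = 3),
                      c("A", "A", "B", "B", "B"),
                      rep(c("A", "B", "C"), 2),
                      c(rep("A", 3), rep("B", 4)))) {
    n <- length(labels)
    t1 <- tiny_table(seed = n, n = n, p = 4)
    d <- bray_curtis(t1)
    perms <- oracle_label_perms(labels)
    # oracle statistics via vegan on every distinct arrangement
    f_or <- apply(perms, 1, function(gg)
      vegan::adonis2(stats::as.dist(d) ~ gg, permutations = 0)$F[1])
    r_or <- apply(perms, 1, function(gg)
      vegan::anosim(stats::as.dist(d), gg, permutations = 0)$statistic)
    f_obs <- vegan::adonis2(stats::as.dist(d) ~ labels, permutations = 0)$F[1]
    r_obs <- vegan::anosim(stats::as.dist(d), labels,
                           permutations = 0)$statistic
    mine_f <- permanova(d, labels, exhaustive = TRUE)
    mine_r <- anosim(d, labels, exhaustive = TRUE)
    expect_equal(mine_f$p_value, mean(f_or >= f_obs - 1e-12))
    expect_equal(mine_r$p_value, mean(r_or >= r_obs - 1e-12))
    # sampled p within 3 Monte-Carlo standard errors of the exhaustive p
    ps <- permanova(d, labels, n_permutations = 999, seed = 3)$p_value
    se <- sqrt(mine_f$p_value * (1 - mine_f$p_value) / 999)
    expect_lt(abs(ps - mine_f$p_value), 3 * se + 2 / 999)
  }
})

test_that("ANOSIM equals 1 under complete separation and matches vegan", {
  # all between-distances exceed all within-distances
  sep <- rbind(matrix(rnorm(12, 0, 0.01), 4, 3),
               matrix(rnorm(12, 5, 0.01), 4, 3))
  rownames(sep) <- paste0("s", 1:8)
  d <- as.matrix(dist(sep))
  g <- rep(c("A", "B"), each = 4)
  expect_equal(anosim(d, g, 999, seed = 1)$statistic, 1)
  skip_if_not_installed("vegan")
  t1 <- tiny_table(seed = 12, n = 10, p = 6)
  g2 <- rep(c("A", "B"), 5)
  expect_equal(anosim(bray_curtis(t1), g2, 999, seed = 1)$statistic,
               unname(vegan::anosim(stats::as.dist(bray_curtis(t1)), g2,
                                    permutations = 99)$statistic),
               tolerance = 1e-10)
  # the mean of R over all distinct labelings is exactly zero
  t8 <- tiny_table(seed = 44, n = 8, p = 5)
  d8 <- bray_curtis(t8)
  lab8 <- rep(c("A", "B"), each = 4)
  rs <- apply(oracle_label_perms(lab8), 1, function(gg)
    anosim(d8, gg, n_permutations = 99, seed = 1)$statistic)
  expect_equal(mean(rs), 0, tolerance = 1e-10)
})

test_that("PERMDISP detects dispersion differences and matches vegan's F", {
  skip_if_not_installed("vegan")
  set.seed(15)
  tight <- matrix(rnorm(30, sd = 1), 10, 3)
  wide <- matrix(rnorm(30, sd = 5), 10, 3)
  m <- rbind(tight, wide); rownames(m) <- paste0("s", 1:20)
  d <- as.matrix(dist(m)); g <- rep(c("A", "B"), each = 10)
  r <- permdisp(d, g, n_permutations = 999, seed = 4)
  expect_lte(r$p_value, 0.01)
  bd <- vegan::betadisper(stats::as.dist(d), g, type = "centroid")
  expect_equal(r$statistic, stats::anova(bd)$`F value`[1], tolerance = 1e-8)
  # mirror-image groups share their dispersion pattern
  mir <- rbind(tight, tight + 100); rownames(mir) <- paste0("s", 1:20)
  rm <- permdisp(as.matrix(dist(mir)), g, n_permutations = 999, seed = 4)
  expect_gt(rm$p_value, 0.2)
  expect_lt(rm$statistic, 1e-10)
})

test_that("distance outputs are symmetric with zero diagonal", {
  t1 <- tiny_table(seed = 20, n = 6, p = 5)
  tr <- ape::rcoal(5, tip.label = colnames(t1))
  for (d in list(bray_curtis(t1), weighted_unifrac(t1, tr),
                 unweighted_unifrac(t1, tr))) {
    m <- as.matrix(d)
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
    expect_true(all(m <= 1 + 1e-12))
  }
  # permutation equivariance under sample reordering
  ord <- c(3, 1, 2, 6, 5, 4)
  expect_equal(as.matrix(bray_curtis(t1[ord, ])),
               as.matrix(bray_curtis(t1))[ord, ord])
})
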