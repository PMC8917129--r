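test_that("marker tests route by residual normality and detect planted shifts", {
  ds <- simulate_experiment(simulation_config(seed = 17))
  mt <- marker_treatment_tests(ds$enzyme_table)
  expect_equal(nrow(mt$tests), 22)  # 11 tissue/marker combos x 2 strata
  # planted fungicide increase of head LDH: omnibus significant in both strata
  for (s in c("CL", "MD")) {
    row <- mt$tests[mt$tests$tissue == "head" & mt$tests$marker == "LDH" &
                      mt$tests$stratum == s, ]
    expect_lt(row$p_value, 0.05)
    ph <- mt$posthoc[[paste("head", "LDH", s, sep = ".")]]
    fung_ctrl <- ph[(ph$group_a == "Control" & ph$group_b == "Fungicide") |
                      (ph$group_a == "Fungicide" & ph$group_b == "Control"), ]
    expect_lt(fung_ctrl$adjusted_p, 0.05)
  }
  # a missing treatment cell is reported by name
  broken <- ds$enzyme_table[!(ds$enzyme_table$tissue == "head" &
                                ds$enzyme_table$marker == "GST" &
                                ds$enzyme_table$colonization == "CL" &
                                ds$enzyme_table$treatment == "Mix"), ]
  expect_error(marker_treatment_tests(broken), "Mix")
})

test_that("null markers are significant at roughly the nominal rate", {
  cfg <- simulation_config(seed = 27,
                           enzyme_effect_map = data.frame(
                             tissue = character(), marker = character(),
                             colonization = character(),
                             treatment = character(), shift = numeric()))
  ds <- simulate_experiment(cfg)
  mt <- marker_treatment_tests(ds$enzyme_table)
  # 22 null omnibus tests: expect about 5% rejections (binomial slack)
  expect_lte(sum(mt$tests$p_value < 0.05), qbinom(0.999, 22, 0.05) + 1)
})

test_that("a constant marker exercises the degenerate path", {
  tab <- expand.grid(tissue = "midgut", marker = "ALP",
                     colonization = c("CL", "MD"),
                     treatment = c("Control", "T1", "T2"),
                     replicate = 1:4, stringsAsFactors = FALSE)
  tab$activity <- 5
  mt <- suppressWarnings(marker_treatment_tests(tab))
  expect_true(all(mt$tests$p_value == 1))
})

test_that("colonization contrasts recover the planted midgut GST difference", {
  ds <- simulate_experiment(simulation_config(seed = 18))
  cc <- colonization_contrast(ds$enzyme_table)
  row <- cc[cc$tissue == "midgut" & cc$marker == "GST" &
              cc$pesticide == "Control", ]
  expect_lt(row$p_value, 0.05)
  expect_gt(row$estimate, 0)  # higher in CL
  # identical strata: p = 1
  tab <- expand.grid(tissue = "head", marker = "GST",
                     colonization = c("CL", "MD"),
                     treatment = "Control", replicate = 1:5,
                     stringsAsFactors = FALSE)
  tab$activity <- rep(c(1, 2, 3, 4, 5), each = 2)
  same <- suppressWarnings(colonization_contrast(tab))
  expect_equal(same$p_value, 1)
  # estimate flips sign when stratum labels swap
  tab2 <- ds$enzyme_table
  tab2$colonization <- ifelse(tab2$colonization == "CL", "MD", "CL")
  cc2 <- colonization_contrast(tab2)
  key <- paste(cc$tissue, cc$marker, cc$pesticide)
  key2 <- paste(cc2$tissue, cc2$marker, cc2$pesticide)
  expect_equal(cc$estimate, -cc2$estimate[match(key, key2)])
  expect_equal(cc$p_value, cc2$p_value[match(key, key2)], tolerance = 1e-9)
})

test_that("control normalization maps the reference column to zero", {
  m <- matrix(c(1, 2, 1.5, 3, 2, 5), 2, 3,
              dimnames = list(c("GST.h", "LDH.m"),
                              c("CL.Control", "CL.Mix", "MD.Control")))
  nm <- control_normalize(m)
  expect_equal(unname(nm[, "CL.Control"]), c(0, 0))
  expect_equal(nm["GST.h", "CL.Mix"], 0.5)
  # doubling a row's raw means leaves normalized values unchanged
  m2 <- m; m2["GST.h", ] <- m["GST.h", ] * 2
  expect_equal(control_normalize(m2), nm)
  m3 <- m; m3["LDH.m", "CL.Control"] <- 0
  expect_error(control_normalize(m3), "LDH.m")
  expect_error(control_normalize(m, control_column = "nope"), "not found")
})

test_that("UPGMA reproduces the worked three-point example", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  # embed exactly: cluster rows of a matrix whose Euclidean distances are d
  dn <- beegut:::upgma_from_dist(d)
  expect_equal(dn$heights, c(1, 2))
  expect_equal(dn$newick, "((A:1,B:1):1,C:2);")
  expect_equal(dn$order, c("A", "B", "C"))
})

test_that("UPGMA recovers ultrametric distances and matches hclust heights", {
  # an ultrametric tree's cophenetic matrix must be reproduced exactly
  tr <- ape::read.tree(text = "((a:1,b:1):2,(c:2.5,d:2.5):0.5);")
  cm <- ape::cophenetic.phylo(tr)
  dn <- beegut:::upgma_from_dist(cm)
  back <- ape::cophenetic.phylo(ape::read.tree(text = dn$newick))
  expect_equal(back[rownames(cm), colnames(cm)], cm, tolerance = 1e-9)
  set.seed(60)
  m <- matrix(rnorm(35), 7, 5, dimnames = list(letters[1:7], NULL))
  u <- upgma_cluster(m, "rows")
  h <- stats::hclust(stats::dist(m), method = "average")
  expect_equal(sort(u$merges$distance), sort(h$height), tolerance = 1e-12)
  # monotone heights, invariance to row order
  expect_true(all(diff(u$merges$height) >= -1e-12))
  u2 <- upgma_cluster(m[sample(7), ], "rows")
  expect_equal(u2$newick, u$newick)
  # duplicate rows merge first at height 0
  md <- rbind(x = c(1, 2), y = c(1, 2), z = c(9, 9))
  ud <- upgma_cluster(md, "rows")
  expect_equal(ud$merges$height[1], 0)
  expect_setequal(c(ud$merges$a[1], ud$merges$b[1]), c("x", "y"))
})

test_that("heatmap rendering writes a file honoring dendrogram order", {
  ds <- simulate_experiment(small_sim(seed = 21))
  norm <- control_normalize(marker_matrix(ds$enzyme_table))
  rd <- upgma_cluster(norm, "rows"); cd <- upgma_cluster(norm, "columns")
  f <- file.path(tempdir(), "hm.png")
  out <- render_heatmap(norm, rd, cd, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  expect_identical(out$row_order, rd$order)
  expect_identical(out$col_order, cd$order)
  # all-zero matrix renders without error (uniform center color)
  z <- norm * 0
  expect_no_error(render_heatmap(z, file = file.path(tempdir(), "hm0.png")))
})
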