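# Physiological-marker statistics with normality routing, the
# control-normalized marker matrix, UPGMA clustering and its heatmap.

marker_residuals <- function(values, groups) {
  unlist(lapply(split(values, groups), function(v) v - mean(v)),
         use.names = FALSE)
}

#' Treatment-effect tests per tissue, marker and colonization stratum
#'
#' Within each (tissue, marker, stratum), residuals from the treatment
#' means are routed by a Shapiro-Wilk test: parametric data get a one-way
#' ANOVA with Tukey HSD post hoc, nonparametric data a Kruskal-Wallis test
#' with Dunn's post hoc (Benjamini-Hochberg).
#'
#' @param enzyme_table data frame `tissue`, `marker`, `colonization`,
#'   `treatment`, `replicate`, `activity`.
#' @param alpha significance level of the normality routing.
#' @return list with `tests` (one row per tissue/marker/stratum: `route`,
#'   `method`, `statistic`, `p_value`) and `posthoc` (named list of
#'   posthoc tables keyed `tissue.marker.stratum`).
#' @export
marker_treatment_tests <- function(enzyme_table, alpha = 0.05) {
  need <- c("tissue", "marker", "colonization", "treatment", "activity")
  stopifnot(all(need %in% names(enzyme_table)))
  key <- interaction(enzyme_table$tissue, enzyme_table$marker,
                     enzyme_table$colonization, drop = TRUE)
  all_trt <- unique(enzyme_table$treatment)
  rows <- list(); posthoc <- list()
  for (k in levels(key)) {
    d <- enzyme_table[key == k, ]
    missing <- setdiff(all_trt, unique(d$treatment))
    if (length(missing))
      stop("missing treatment level(s) for ", k, ": ",
           paste(missing, collapse = ", "))
    res <- marker_residuals(d$activity, d$treatment)
    route <- if (stats::sd(res) == 0) "nonparametric"
             else normality_route(res, alpha)
    if (route == "parametric") {
      t1 <- anova_oneway(d$activity, d$treatment)
      ph <- tukey_hsd(d$activity, d$treatment)
    } else {
      t1 <- kruskal_wallis(d$activity, d$treatment)
      ph <- dunn_test(d$activity, d$treatment)
    }
    rows[[k]] <- data.frame(
      tissue = d$tissue[1], marker = d$marker[1],
      stratum = d$colonization[1], route = route, method = t1$method,
      statistic = t1$statistic, p_value = t1$p_value,
      stringsAsFactors = FALSE)
    posthoc[[k]] <- ph
  }
  tests <- do.call(rbind, rows); rownames(tests) <- NULL
  list(tests = tests, posthoc = posthoc)
}

#' CL-versus-MD contrast per tissue, marker and pesticide
#'
#' Two-group comparison of enzyme activities between colonization strata
#' under the same pesticide treatment: the parametric route uses the
#' two-group ANOVA (equivalent to a pooled t test) and the nonparametric
#' route the Wilcoxon rank sum test, with the same Shapiro-Wilk routing as
#' the omnibus tests.
#'
#' @inheritParams marker_treatment_tests
#' @return data frame with one row per (tissue, marker, pesticide):
#'   `route`, `method`, `estimate` (CL mean - MD mean), `statistic`,
#'   `p_value`.
#' @export
colonization_contrast <- function(enzyme_table, alpha = 0.05) {
  key <- interaction(enzyme_table$tissue, enzyme_table$marker,
                     enzyme_table$treatment, drop = TRUE)
  rows <- list()
  for (k in levels(key)) {
    d <- enzyme_table[key == k, ]
    strata <- sort(unique(d$colonization))
    if (length(strata) != 2)
      stop("both colonization strata required for ", k)
    res <- marker_residuals(d$activity, d$colonization)
    route <- if (stats::sd(res) == 0) "nonparametric"
             else normality_route(res, alpha)
    a <- d$activity[d$colonization == strata[1]]
    b <- d$activity[d$colonization == strata[2]]
    if (route == "parametric") t1 <- anova_oneway(d$activity, d$colonization)
    else t1 <- wilcoxon_rank_sum(a, b)
    rows[[k]] <- data.frame(
      tissue = d$tissue[1], marker = d$marker[1],
      pesticide = d$treatment[1], route = route, method = t1$method,
      estimate = mean(a) - mean(b), statistic = t1$statistic,
      p_value = t1$p_value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  out
}

#' Mean activity matrix: (tissue, marker) rows x (stratum.treatment) columns
#'
#' @inheritParams marker_treatment_tests
#' @return numeric matrix of treatment means; rownames `marker.tissue`,
#'   colnames `stratum.treatment` (e.g. `CL.Control`).
#' @export
marker_matrix <- function(enzyme_table) {
  rows <- interaction(enzyme_table$marker, enzyme_table$tissue, drop = TRUE)
  cols <- interaction(enzyme_table$colonization, enzyme_table$treatment,
                      drop = TRUE)
  m <- tapply(enzyme_table$activity, list(rows, cols), mean)
  if (any(is.na(m))) stop("missing tissue/marker/treatment cells")
  m
}

#' Normalize treatment means to the rate of variation versus the control
#'
#' Each entry becomes `(mean_treatment - mean_control) / mean_control` per
#' row, so the control column maps to 0, increases are positive and
#' decreases negative.
#'
#' @param m marker matrix from [marker_matrix()].
#' @param control_column column used as reference (default `"CL.Control"`).
#' @param mode `"relative"` (default, `(t - c)/c`) or `"ratio"` (`t/c`).
#' @export
control_normalize <- function(m, control_column = "CL.Control",
                              mode = c("relative", "ratio")) {
  mode <- match.arg(mode)
  if (!control_column %in% colnames(m))
    stop("control column not found: ", control_column)
  ctrl <- m[, control_column]
  if (any(ctrl == 0))
    stop("zero control mean in row(s): ",
         paste(rownames(m)[ctrl == 0], collapse = ", "))
  if (mode == "relative") sweep(sweep(m, 1, ctrl), 1, ctrl, "/")
  else sweep(m, 1, ctrl, "/")
}

# ---- UPGMA ------------------------------------------------------------------

#' UPGMA (average-linkage) hierarchical clustering
#'
#' Agglomerates items by unweighted average inter-cluster distance over the
#' Euclidean distances of the matrix rows or columns. Merge heights are the
#' ultrametric node heights (half the average distance at merge), so the
#' dendrogram reproduces ultrametric input distances exactly. Ties are
#' broken by lexicographic label order, making the result independent of
#' input row order.
#'
#' @param m numeric matrix.
#' @param axis cluster `"rows"` or `"columns"`.
#' @return `beegut_dendrogram` list: `merges` (data frame of the merge
#'   sequence), `heights`, `labels`, `order` (leaf order), `newick`.
#' @export
upgma_cluster <- function(m, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2) stop("need at least 2 items to cluster")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("item", seq_len(nrow(m)))
  d <- as.matrix(stats::dist(m))
  dimnames(d) <- list(labels, labels)
  upgma_from_dist(d)
}

upgma_from_dist <- function(d) {
  labels <- rownames(d)
  active <- labels
  size <- stats::setNames(rep(1, length(labels)), labels)
  newick <- stats::setNames(labels, labels)
  height <- stats::setNames(rep(0, length(labels)), labels)
  merges <- list()
  leaf_order <- stats::setNames(as.list(labels), labels)
  while (length(active) > 1) {
    sub <- d[active, active, drop = FALSE]
    diag(sub) <- Inf
    mn <- min(sub)
    # lexicographically smallest tied pair
    cand <- which(sub <= mn + 1e-12, arr.ind = TRUE)
    pairs <- t(apply(cand, 1, function(ij)
      sort(c(active[ij[1]], active[ij[2]]))))
    key <- paste(pairs[, 1], pairs[, 2])
    best <- pairs[order(key)[1], ]
    a <- best[1]; b <- best[2]
    h <- d[a, b] / 2
    new_lab <- a  # cluster inherits its smallest member label
    merges[[length(merges) + 1]] <- data.frame(
      a = a, b = b, distance = d[a, b], height = h,
      stringsAsFactors = FALSE)
    bl_a <- h - height[a]; bl_b <- h - height[b]
    newick[new_lab] <- sprintf("(%s:%.10g,%s:%.10g)", newick[a], bl_a,
                               newick[b], bl_b)
    leaf_order[[new_lab]] <- c(leaf_order[[a]], leaf_order[[b]])
    # UPGMA update: size-weighted average distance
    others <- setdiff(active, c(a, b))
    for (o in others)
      d[new_lab, o] <- d[o, new_lab] <-
        (size[a] * d[a, o] + size[b] * d[b, o]) / (size[a] + size[b])
    size[new_lab] <- size[a] + size[b]
    height[new_lab] <- h
    active <- c(others, new_lab)
  }
  merges <- do.call(rbind, merges)
  structure(list(merges = merges, heights = merges$height,
                 labels = labels, order = leaf_order[[active]],
                 newick = paste0(newick[active], ";")),
            class = "beegut_dendrogram")
}

#' @export
print.beegut_dendrogram <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$labels), "items\n ", x$newick, "\n")
  invisible(x)
}

#' Render the control-normalized marker heatmap
#'
#' Draws the normalized marker matrix with a green-black-red diverging
#' scale centered at 0 (green = decrease, red = increase versus the
#' colonized control) and rows/columns ordered by their UPGMA dendrograms.
#'
#' @param norm normalized marker matrix.
#' @param row_dend,col_dend `beegut_dendrogram`s for rows and columns
#'   (computed from `norm` when `NULL`).
#' @param file output PNG path.
#' @return invisibly, a list with `file`, `row_order`, `col_order`.
#' @export
render_heatmap <- function(norm, row_dend = NULL, col_dend = NULL, file) {
  if (is.null(row_dend)) row_dend <- upgma_cluster(norm, "rows")
  if (is.null(col_dend)) col_dend <- upgma_cluster(norm, "columns")
  m <- norm[row_dend$order, col_dend$order, drop = FALSE]
  lim <- max(abs(m), 1e-9)
  pal <- grDevices::colorRampPalette(c("green3", "black", "red2"))(101)
  grDevices::png(file, width = 900, height = 700)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(8, 10, 2, 2))  # settings die with the device
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)), t(m),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.9)
  graphics::axis(2, seq_len(nrow(m)), rownames(m), las = 2, cex.axis = 0.9)
  graphics::box()
  invisible(list(file = file, row_order = row_dend$order,
                 col_order = col_dend$order))
}
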