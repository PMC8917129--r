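# Community dissimilarities, principal coordinates, and permutational
# multivariate statistics, computed from first principles.

new_dist <- function(m, metric) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  d <- stats::as.dist(m)
  attr(d, "metric") <- metric
  d
}

dist_matrix <- function(d) {
  m <- as.matrix(d)
  if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric")
  m
}

#' Bray-Curtis dissimilarity
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over an absolute-abundance
#' (or count) table.
#'
#' @param table samples x ASVs nonnegative matrix.
#' @return a `dist` with attribute `metric = "bray-curtis"`.
#' @export
bray_curtis <- function(table) {
  if (any(table < 0)) stop("negative abundances")
  n <- nrow(table)
  m <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(table[i, ] + table[j, ])
      if (denom == 0)
        stop("undefined Bray-Curtis for all-zero samples: ",
             rownames(table)[i], ", ", rownames(table)[j])
      m[i, j] <- m[j, i] <- sum(abs(table[i, ] - table[j, ])) / denom
    }
  }
  new_dist(m, "bray-curtis")
}

# postorder edge x tip membership of a rooted tree
edge_tip_membership <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  desc <- matrix(FALSE, nnode, ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    desc[p, ] <- desc[p, ] | desc[ch, ]
  }
  list(membership = desc[tr$edge[, 2], , drop = FALSE],
       lengths = tr$edge.length, tips = tr$tip.label, tree = tr)
}

check_tree_cover <- function(table, tree) {
  missing <- setdiff(colnames(table), tree$tip.label)
  if (length(missing))
    stop("ASV(s) missing from the tree: ",
         paste(utils::head(missing, 5), collapse = ", "))
}

#' Unweighted UniFrac distance
#'
#' Fraction of branch length unique to either sample's leaf set over the
#' branch length spanned by their union.
#'
#' @param table samples x ASVs matrix (presence is `> 0`).
#' @param tree rooted `phylo` whose tips cover the table's ASVs.
#' @export
unweighted_unifrac <- function(table, tree) {
  check_tree_cover(table, tree)
  et <- edge_tip_membership(tree)
  pres <- (table > 0)[, et$tips[et$tips %in% colnames(table)], drop = FALSE]
  A <- matrix(0, nrow(table), length(et$tips),
              dimnames = list(rownames(table), et$tips))
  A[, colnames(pres)] <- pres
  # edge x sample: does any tip under the edge occur in the sample?
  P <- (et$membership %*% t(A)) > 0
  n <- nrow(table)
  m <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      uni <- sum(et$lengths[xor(P[, i], P[, j])])
      tot <- sum(et$lengths[P[, i] | P[, j]])
      m[i, j] <- m[j, i] <- if (tot == 0) 0 else uni / tot
    }
  }
  new_dist(m, "unweighted-unifrac")
}

#' Weighted UniFrac distance
#'
#' `sum_e L_e |p_A(e) - p_B(e)|` over branches, where `p(e)` is the relative
#' abundance of the subtree below branch `e`. When `normalized`, the raw
#' distance is divided by the abundance-weighted maximum attainable
#' distance `sum_tips depth_tip (p_A(tip) + p_B(tip))`, bounding it to [0, 1].
#'
#' @inheritParams unweighted_unifrac
#' @param normalized logical; default `TRUE`.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  check_tree_cover(table, tree)
  if (any(rowSums(table) == 0))
    stop("zero-abundance sample(s): ",
         paste(rownames(table)[rowSums(table) == 0], collapse = ", "))
  et <- edge_tip_membership(tree)
  A <- matrix(0, nrow(table), length(et$tips),
              dimnames = list(rownames(table), et$tips))
  A[, colnames(table)] <- table
  rel <- sweep(A, 1, rowSums(A), "/")
  # edge x sample subtree relative abundance
  P <- et$membership %*% t(rel)
  depth <- ape::node.depth.edgelength(et$tree)[seq_along(et$tips)]
  names(depth) <- et$tips
  n <- nrow(table)
  m <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sum(et$lengths * abs(P[, i] - P[, j]))
      if (normalized) {
        dmax <- sum(depth * (rel[i, et$tips] + rel[j, et$tips]))
        d <- if (dmax == 0) 0 else d / dmax
      }
      m[i, j] <- m[j, i] <- d
    }
  }
  new_dist(m, paste0(if (normalized) "normalized-", "weighted-unifrac"))
}

#' Principal coordinate analysis
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are built from positive eigenvalues; negative eigenvalues
#' (non-Euclidean input) are reported.
#'
#' @param dm a `dist` or symmetric matrix.
#' @return `beegut_pcoa` list: `eigenvalues` (descending), `coordinates`
#'   (positive axes), `negative_coordinates` (axes for negative
#'   eigenvalues, scaled by `sqrt(-lambda)`), `proportion_explained`.
#' @export
pcoa <- function(dm) {
  m <- dist_matrix(dm)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 samples for ordination")
  a <- -0.5 * m^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  neg <- e$values < -tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  ncoords <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  rownames(coords) <- rownames(ncoords) <- rownames(m)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(eigenvalues = e$values,
                 coordinates = coords,
                 negative_coordinates = ncoords,
                 proportion_explained =
                   e$values[pos] / sum(e$values[pos])),
            class = "beegut_pcoa")
}

# ---- permutation machinery --------------------------------------------------

new_permtest <- function(method, statistic, p_value, n_permutations,
                         seed = NULL, effect_size = NULL, degenerate = FALSE) {
  structure(list(method = method, statistic = unname(statistic),
                 effect_size = effect_size, n_permutations = n_permutations,
                 p_value = p_value, seed = seed, degenerate = degenerate),
            class = "beegut_permtest")
}

#' @export
print.beegut_permtest <- function(x, ...) {
  cat(toupper(x$method), ": statistic =", format(x$statistic, digits = 5),
      if (!is.null(x$effect_size))
        paste0(" R2 = ", format(x$effect_size, digits = 4)),
      "\n  p =", format(x$p_value, digits = 4),
      " (", x$n_permutations, "permutations)\n")
  invisible(x)
}

# all distinct orderings of a label multiset (n! / prod(n_g!)) rows
multiset_perms <- function(x) {
  x <- as.character(x)
  out <- new.env()
  out$rows <- vector("list", 0)
  rec <- function(remaining, acc) {
    if (!length(remaining)) {
      out$rows[[length(out$rows) + 1]] <- acc
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      rec(remaining[-i], c(acc, v))
    }
  }
  rec(sort(x), character(0))
  do.call(rbind, out$rows)
}

check_grouping <- function(dm_n, grouping, min_size = 2L) {
  grouping <- as.character(grouping)
  if (length(grouping) != dm_n)
    stop("grouping length does not match the distance matrix")
  tab <- table(grouping)
  if (length(tab) < 2) stop("need at least two groups")
  if (any(tab < min_size))
    stop("group(s) of size < ", min_size, ": ",
         paste(names(tab)[tab < min_size], collapse = ", "))
  grouping
}

permanova_f <- function(d2, grouping) {
  n <- nrow(d2)
  groups <- unique(grouping)
  k <- length(groups)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (g in groups) {
    idx <- which(grouping == g)
    ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_b <- ss_t - ss_w
  list(f = (ss_b / (k - 1)) / (ss_w / (n - k)),
       r2 = if (ss_t > 0) ss_b / ss_t else NA_real_,
       ss_t = ss_t)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Pseudo-F partitioning of distance-matrix variance among groups (the
#' ADONIS test), computed directly from squared inter-point distances via
#' the Gower identity. The p value counts the observed arrangement among
#' the permutations: `p = (1 + #{F* >= F}) / (1 + B)`. With
#' `exhaustive = TRUE` all distinct label arrangements are enumerated and
#' the p value is the exact proportion with `F* >= F`.
#'
#' @param dm a `dist` or symmetric matrix.
#' @param grouping group labels per sample.
#' @param n_permutations number of random permutations (>= 99).
#' @param seed RNG seed recorded in the result.
#' @param exhaustive enumerate all distinct label arrangements.
#' @export
permanova <- function(dm, grouping, n_permutations = 999, seed = NULL,
                      exhaustive = FALSE) {
  m <- dist_matrix(dm)
  grouping <- check_grouping(nrow(m), grouping)
  if (!exhaustive && n_permutations < 99)
    stop("n_permutations must be at least 99")
  d2 <- m^2
  if (all(d2 == 0))
    return(new_permtest("permanova", NA_real_, 1, 0, seed,
                        degenerate = TRUE))
  obs <- permanova_f(d2, grouping)
  eps <- 1e-12
  if (exhaustive) {
    perms <- multiset_perms(grouping)
    fs <- apply(perms, 1, function(g) permanova_f(d2, g)$f)
    p <- mean(fs >= obs$f - eps)
    return(new_permtest("permanova", obs$f, p, nrow(perms), seed,
                        effect_size = obs$r2))
  }
  if (!is.null(seed)) set.seed(seed)
  fs <- replicate(n_permutations,
                  permanova_f(d2, sample(grouping))$f)
  p <- (1 + sum(fs >= obs$f - eps)) / (1 + n_permutations)
  new_permtest("permanova", obs$f, p, n_permutations, seed,
               effect_size = obs$r2)
}

anosim_r <- function(rk, between) {
  m <- length(rk)
  (mean(rk[between]) - mean(rk[!between])) / (m / 2)
}

#' Analysis of similarities
#'
#' Rank-based comparison of between- versus within-group distances:
#' `R = (rbar_between - rbar_within) / (M / 2)` with `M = n(n-1)/2` ranks
#' over all pairwise distances. R near 1 indicates strong separation.
#'
#' @inheritParams permanova
#' @export
anosim <- function(dm, grouping, n_permutations = 999, seed = NULL,
                   exhaustive = FALSE) {
  m <- dist_matrix(dm)
  grouping <- check_grouping(nrow(m), grouping)
  rk <- rank(stats::as.dist(m))
  pair_idx <- which(upper.tri(m), arr.ind = TRUE)
  # as.dist stores the lower triangle column-wise: (i > j) ordered by column
  lowidx <- which(lower.tri(m), arr.ind = TRUE)
  between_for <- function(g)
    g[lowidx[, 1]] != g[lowidx[, 2]]
  obs <- anosim_r(rk, between_for(grouping))
  eps <- 1e-12
  if (exhaustive) {
    perms <- multiset_perms(grouping)
    rs <- apply(perms, 1, function(g) anosim_r(rk, between_for(g)))
    p <- mean(rs >= obs - eps)
    return(new_permtest("anosim", obs, p, nrow(perms), seed))
  }
  if (!is.null(seed)) set.seed(seed)
  rs <- replicate(n_permutations, anosim_r(rk, between_for(sample(grouping))))
  p <- (1 + sum(rs >= obs - eps)) / (1 + n_permutations)
  new_permtest("anosim", obs, p, n_permutations, seed)
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the samples by principal coordinates keeping real and imaginary
#' axes, computes each sample's distance to its group centroid with the
#' negative-eigenvalue contribution subtracted (Anderson's correction),
#' then tests equality of mean dispersion with a one-way F whose null
#' distribution is obtained by permuting the distances-to-centroid across
#' groups.
#'
#' @inheritParams permanova
#' @export
permdisp <- function(dm, grouping, n_permutations = 999, seed = NULL) {
  m <- dist_matrix(dm)
  grouping <- check_grouping(nrow(m), grouping)
  ord <- pcoa(m)
  cp <- ord$coordinates
  cn <- ord$negative_coordinates
  z2 <- numeric(nrow(m))
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    ctr_p <- colMeans(cp[idx, , drop = FALSE])
    dp <- rowSums(sweep(cp[idx, , drop = FALSE], 2, ctr_p)^2)
    dn <- 0
    if (ncol(cn) > 0) {
      ctr_n <- colMeans(cn[idx, , drop = FALSE])
      dn <- rowSums(sweep(cn[idx, , drop = FALSE], 2, ctr_n)^2)
    }
    z2[idx] <- dp - dn
  }
  if (any(z2 < 0)) {
    warning("negative squared centroid distances clipped at 0")
    z2 <- pmax(z2, 0)
  }
  z <- sqrt(z2)
  obs <- anova_oneway(z, grouping)
  if (isTRUE(obs$degenerate) && !is.finite(obs$statistic))
    return(new_permtest("permdisp", NA_real_, 1, 0, seed, degenerate = TRUE))
  if (!is.null(seed)) set.seed(seed)
  fstat <- function(v) {
    ss <- anova_ss(v, grouping)
    if (ss$ssw <= 0) Inf else
      (ss$ssb / (ss$k - 1)) / (ss$ssw / (ss$n - ss$k))
  }
  fs <- replicate(n_permutations, fstat(sample(z)))
  p <- (1 + sum(fs >= obs$statistic - 1e-12)) / (1 + n_permutations)
  new_permtest("permdisp", obs$statistic, p, n_permutations, seed)
}
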