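# Per-ASV permutation ANOVA on absolute abundances: omnibus F and per-level
# t statistics vs the control, randomization p values, Tukey post hoc with
# Bonferroni adjustment, and Venn partitioning across colonization strata.

# group indicator utilities shared by the vectorized permutation engine
group_design <- function(treatments) {
  lev <- unique(treatments)
  G <- t(vapply(lev, function(l) as.numeric(treatments == l),
                numeric(length(treatments))))
  rownames(G) <- lev
  list(G = G, lev = lev)
}

# F and treatment-vs-control t statistics for every column of V (n x B)
perm_stats <- function(V, G, n_g, control_idx) {
  n <- nrow(V); k <- nrow(G)
  sums <- G %*% V                       # k x B group sums
  means <- sums / n_g
  grand <- colSums(V) / n
  ssb <- colSums(n_g * (sweep(means, 2, grand))^2)
  sst <- colSums(V^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  mse <- ssw / (n - k)
  f <- (ssb / (k - 1)) / mse
  tmat <- NULL
  if (!is.na(control_idx)) {
    se <- sqrt(outer(1 / n_g + 1 / n_g[control_idx], mse))
    tmat <- sweep(means, 2, means[control_idx, ]) / se
    tmat <- tmat[-control_idx, , drop = FALSE]
  }
  list(f = f, t = tmat)
}

#' Permutation ANOVA for one ASV
#'
#' The observed omnibus F (identical to [anova_oneway()]) and the per-level
#' t statistics of each treatment against the control are recomputed on
#' `n_permutations` random reshufflings of the abundance values. The
#' omnibus p is the proportion of permuted F values greater than or equal
#' to the observed one (the study's randomization rule; it can be exactly
#' 0). Per-level p values use `|t|` by default (`tail = "two-sided"`) or
#' the raw `t >= t_obs` proportion in the one-sided mode.
#'
#' @param abundances numeric absolute abundances for one ASV.
#' @param treatments factor of pesticide treatments (>= 2 levels, >= 3
#'   samples each).
#' @param n_permutations randomizations (default 10000).
#' @param seed RNG seed.
#' @param control reference level for the per-level t statistics.
#' @param tail `"two-sided"` or `"one-sided"` per-level rule.
#' @param exhaustive enumerate all value permutations (small n only).
#' @param alpha significance level for the `significant` flag.
#' @return an `asv_test` list: `statistic` (F), `p_value`, `t_values`,
#'   `t_p_values`, `n_permutations`, `seed`, `significant`.
#' @export
permutation_anova_asv <- function(abundances, treatments,
                                  n_permutations = 10000, seed = NULL,
                                  control = "Control",
                                  tail = c("two-sided", "one-sided"),
                                  exhaustive = FALSE, alpha = 0.05) {
  tail <- match.arg(tail)
  treatments <- as.character(treatments)
  stopifnot(length(abundances) == length(treatments))
  tab <- table(treatments)
  if (length(tab) < 2) stop("need at least two treatments")
  if (any(tab < 3)) stop("need at least 3 samples per treatment")
  n <- length(abundances)
  gd <- group_design(treatments)
  n_g <- as.numeric(table(factor(treatments, levels = gd$lev)))
  control_idx <- match(control, gd$lev)
  if (stats::sd(abundances) == 0) {
    res <- list(statistic = NA_real_, p_value = 1,
                t_values = NULL, t_p_values = NULL,
                n_permutations = 0, seed = seed, degenerate = TRUE,
                significant = FALSE)
    class(res) <- "asv_test"
    return(res)
  }
  obs <- perm_stats(matrix(abundances, ncol = 1), gd$G, n_g, control_idx)
  if (exhaustive) {
    idx <- all_permutations(n)
    V <- matrix(abundances[idx], nrow = n)
  } else {
    if (!is.null(seed)) set.seed(seed)
    V <- vapply(seq_len(n_permutations),
                function(i) abundances[sample.int(n)], numeric(n))
  }
  per <- perm_stats(V, gd$G, n_g, control_idx)
  eps <- 1e-12
  p_f <- mean(per$f >= obs$f[1] - eps)
  t_p <- NULL
  if (!is.na(control_idx)) {
    t_obs <- obs$t[, 1]
    t_p <- vapply(seq_along(t_obs), function(r) {
      if (tail == "two-sided") mean(abs(per$t[r, ]) >= abs(t_obs[r]) - eps)
      else mean(per$t[r, ] >= t_obs[r] - eps)
    }, numeric(1))
    names(t_p) <- rownames(obs$t)
  }
  res <- list(statistic = obs$f[1], p_value = p_f,
              t_values = if (!is.na(control_idx)) obs$t[, 1],
              t_p_values = t_p,
              n_permutations = ncol(V), seed = seed,
              degenerate = FALSE, significant = p_f < alpha)
  class(res) <- "asv_test"
  res
}

#' @export
print.asv_test <- function(x, ...) {
  cat("permutation ANOVA: F =", format(x$statistic, digits = 5),
      " p =", format(x$p_value, digits = 4),
      " (", x$n_permutations, "randomizations)\n")
  invisible(x)
}

# all n! permutation index matrix (n x n!) -- small n only
all_permutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v))
    do.call(cbind, lapply(seq_along(v), function(i)
      rbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

# deterministic 32-bit seed from a master seed and an ASV id
derive_seed <- function(master, id) {
  h <- sum(utf8ToInt(id) * (seq_along(utf8ToInt(id)) %% 7 + 1))
  as.integer((as.numeric(master) * 10007 + h * 31) %% 2147483647)
}

#' Per-ASV permutation ANOVA across a stratum table
#'
#' Runs [permutation_anova_asv()] for every ASV present in at least
#' `prevalence_floor` of the stratum's samples, separately within each
#' colonization stratum. Samples are sorted by name and per-ASV seeds are
#' derived deterministically from `(seed, asv)`, so results do not depend
#' on input row order.
#'
#' @param abs_table samples x ASVs absolute-abundance matrix.
#' @param metadata data frame with `sample`, `colonization`, `pesticide`.
#' @param n_permutations randomizations per ASV.
#' @param seed master seed.
#' @param prevalence_floor minimal fraction of samples with the ASV present.
#' @param control reference treatment level.
#' @param alpha significance level.
#' @return data frame with one row per (stratum, ASV): `asv`, `stratum`,
#'   `F`, `p_perm`, `significant`, prefixed per-contrast p columns; the
#'   full records are attached as attribute `"records"`.
#' @export
run_all_asvs <- function(abs_table, metadata, n_permutations = 10000,
                         seed = 1L, prevalence_floor = 0.25,
                         control = "Control", alpha = 0.05) {
  stopifnot(all(c("sample", "colonization", "pesticide") %in% names(metadata)))
  out <- list(); records <- list()
  for (stratum in sort(unique(stats::na.omit(metadata$colonization)))) {
    meta_s <- metadata[!is.na(metadata$colonization) &
                         metadata$colonization == stratum, ]
    samples <- sort(intersect(meta_s$sample, rownames(abs_table)))
    if (!length(samples)) stop("no samples for stratum ", stratum)
    tab <- abs_table[samples, , drop = FALSE]
    trt <- meta_s$pesticide[match(samples, meta_s$sample)]
    prev <- colMeans(tab > 0)
    for (asv in colnames(tab)[prev >= prevalence_floor]) {
      r <- permutation_anova_asv(tab[, asv], trt,
                                 n_permutations = n_permutations,
                                 seed = derive_seed(seed, paste0(stratum, asv)),
                                 control = control, alpha = alpha)
      records[[paste(stratum, asv)]] <- r
      row <- data.frame(asv = asv, stratum = stratum,
                        F = r$statistic, p_perm = r$p_value,
                        significant = r$significant,
                        stringsAsFactors = FALSE)
      if (!is.null(r$t_p_values))
        for (nm in names(r$t_p_values))
          row[[paste0("p_t_", nm)]] <- r$t_p_values[[nm]]
      out[[paste(stratum, asv)]] <- row
    }
  }
  res <- do.call(rbind, lapply(out, function(d) {
    # harmonize columns across strata (treatment sets can differ)
    d
  }))
  rownames(res) <- NULL
  attr(res, "records") <- records
  attr(res, "prevalence_floor") <- prevalence_floor
  res
}

#' Tukey post hoc contrasts with Bonferroni adjustment
#'
#' All pairwise Tukey HSD comparisons for one ASV, Bonferroni-adjusted
#' across the pairs; the treatment-versus-control contrasts are flagged in
#' the `vs_control` column.
#'
#' @inheritParams permutation_anova_asv
#' @export
posthoc_vs_control <- function(abundances, treatments, control = "Control") {
  ph <- tukey_hsd(abundances, treatments)
  ph$adjusted_p <- pmin(1, adjust_p(ph$raw_p, "bonferroni"))
  ph$adjust_method <- "tukey+bonferroni"
  ph$vs_control <- ph$group_a == control | ph$group_b == control
  ph
}

#' Venn partition of significant ASVs between strata
#'
#' @param sig_CL,sig_MD character vectors of significant ASV ids.
#' @return list with the sets and counts `CL_only`, `MD_only`, `shared`,
#'   `total`.
#' @export
venn_partition <- function(sig_CL, sig_MD) {
  sig_CL <- unique(as.character(sig_CL))
  sig_MD <- unique(as.character(sig_MD))
  shared <- intersect(sig_CL, sig_MD)
  list(set_CL = sig_CL, set_MD = sig_MD, shared_set = shared,
       counts = c(CL_only = length(setdiff(sig_CL, sig_MD)),
                  MD_only = length(setdiff(sig_MD, sig_CL)),
                  shared = length(shared),
                  total = length(union(sig_CL, sig_MD))))
}
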