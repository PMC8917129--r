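# ASV filtering: organellar/eukaryotic removal and reagent-contaminant
# identification against blank extractions (prevalence + frequency, "either").

#' Remove organellar and eukaryotic ASVs
#'
#' Drops every ASV whose lineage contains "Mitochondria" or "Chloroplast" at
#' any rank, or whose domain is "Eukaryota" (case-insensitive). ASVs missing
#' from the taxonomy are retained with a warning.
#'
#' @param asv_counts samples x ASVs matrix.
#' @param taxonomy data frame with column `asv` and rank columns (the first
#'   rank column is taken as the domain).
#' @return list with `counts` (filtered matrix) and `removed` (ASV ids).
#' @export
taxonomy_filter <- function(asv_counts, taxonomy) {
  stopifnot("asv" %in% names(taxonomy))
  asvs <- colnames(asv_counts)
  missing <- setdiff(asvs, taxonomy$asv)
  if (length(missing))
    warning(length(missing), " ASV(s) without taxonomy retained: ",
            paste(utils::head(missing, 5), collapse = ", "))
  tx <- taxonomy[match(asvs, taxonomy$asv), , drop = FALSE]
  ranks <- tx[, setdiff(names(tx), "asv"), drop = FALSE]
  lineage <- apply(ranks, 1, function(r) paste(r, collapse = ";"))
  domain <- as.character(ranks[[1]])
  bad <- !is.na(tx$asv) &
    (grepl("mitochondria|chloroplast", lineage, ignore.case = TRUE) |
       grepl("^eukaryota$", trimws(domain), ignore.case = TRUE))
  list(counts = asv_counts[, !bad, drop = FALSE],
       removed = asvs[bad])
}

#' Prevalence score for contaminant identification
#'
#' For each ASV, builds the 2x2 presence/absence table of blanks (plus
#' negative controls) versus true samples and scores over-representation in
#' blanks with a one-sided Fisher exact test. Small p indicates a likely
#' reagent contaminant.
#'
#' @param asv_counts samples x ASVs matrix (blanks included).
#' @param is_blank logical per sample (reference class).
#' @return named numeric vector of one-sided p values per ASV.
#' @export
prevalence_method <- function(asv_counts, is_blank) {
  stopifnot(length(is_blank) == nrow(asv_counts))
  if (!any(is_blank) || !any(!is_blank))
    stop("need at least one blank and one true sample")
  pres <- asv_counts > 0
  nb <- sum(is_blank); ns <- sum(!is_blank)
  vapply(colnames(asv_counts), function(a) {
    pb <- sum(pres[is_blank, a]); ps <- sum(pres[!is_blank, a])
    if (pb + ps == 0) return(1)
    tab <- matrix(c(pb, nb - pb, ps, ns - ps), nrow = 2)
    stats::fisher.test(tab, alternative = "greater")$p.value
  }, numeric(1))
}

#' Frequency score for contaminant identification
#'
#' Reagent contaminants enter extractions at a level independent of the
#' input DNA, so their relative abundance varies inversely with the total
#' bacterial load. The score is the one-sided p value of the Spearman
#' correlation between an ASV's relative abundance and log10 load
#' (alternative: negative correlation), computed over the true samples in
#' which the ASV is present. ASVs present in fewer than `min_present`
#' samples receive the neutral score 0.5.
#'
#' When cohorts with systematically different community compositions and
#' loads are mixed (here: CL versus MD bees), a cross-cohort correlation
#' can mimic the contamination signature for genuine community members; an
#' optional `strata` factor therefore restricts the correlation to within
#' strata, combining the per-stratum one-sided p values by Stouffer's
#' weighted-z method.
#'
#' @param asv_counts samples x ASVs matrix of true (non-blank) samples.
#' @param loads named positive totals (e.g. normalized 16S copies) for the
#'   rows of `asv_counts`.
#' @param min_present minimal number of samples with the ASV present.
#' @param strata optional per-sample stratum labels (e.g. colonization).
#' @return named numeric vector of scores per ASV.
#' @export
frequency_method <- function(asv_counts, loads, min_present = 5L,
                             strata = NULL) {
  if (!is.null(names(loads))) loads <- loads[rownames(asv_counts)]
  stopifnot(length(loads) == nrow(asv_counts), all(loads > 0))
  if (is.null(strata)) strata <- rep("all", nrow(asv_counts))
  stopifnot(length(strata) == nrow(asv_counts))
  tot <- rowSums(asv_counts)
  keep <- tot > 0
  rel <- sweep(asv_counts[keep, , drop = FALSE], 1, tot[keep], "/")
  lload <- log10(loads[keep])
  strata <- as.character(strata)[keep]
  one_p <- function(x, l) {
    if (length(x) < min_present) return(NA_real_)
    if (stats::sd(x) == 0 || stats::sd(l) == 0) return(NA_real_)
    suppressWarnings(stats::cor.test(l, x, method = "spearman",
                                     alternative = "less")$p.value)
  }
  vapply(colnames(rel), function(a) {
    ps <- ns <- numeric(0)
    for (s in unique(strata)) {
      idx <- strata == s & rel[, a] > 0
      p <- one_p(rel[idx, a], lload[idx])
      if (!is.na(p)) { ps <- c(ps, p); ns <- c(ns, sum(idx)) }
    }
    if (!length(ps)) return(0.5)
    # Stouffer weighted combination of the one-sided per-stratum p values
    z <- stats::qnorm(pmin(pmax(ps, 1e-15), 1 - 1e-15))
    stats::pnorm(sum(sqrt(ns) * z) / sqrt(sum(ns)))
  }, numeric(1))
}

#' Combine prevalence and frequency calls ("either" rule)
#'
#' Flags an ASV as a contaminant when its prevalence p OR its frequency
#' score falls strictly below `threshold`.
#'
#' @param prevalence_p,frequency_score named vectors over the same ASVs.
#' @param threshold classification threshold (default 0.1).
#' @return data frame `asv`, `prevalence_p`, `frequency_score`,
#'   `flagged_by`, `is_contaminant`.
#' @export
combine_either <- function(prevalence_p, frequency_score, threshold = 0.1) {
  asvs <- names(prevalence_p)
  stopifnot(!is.null(asvs), setequal(asvs, names(frequency_score)))
  frequency_score <- frequency_score[asvs]
  by_prev <- prevalence_p < threshold
  by_freq <- frequency_score < threshold
  flagged_by <- mapply(function(p, f) {
    paste(c(if (p) "prevalence", if (f) "frequency"), collapse = "+")
  }, by_prev, by_freq)
  data.frame(asv = asvs,
             prevalence_p = unname(prevalence_p),
             frequency_score = unname(frequency_score),
             flagged_by = unname(flagged_by),
             is_contaminant = unname(by_prev | by_freq),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Remove flagged contaminants and drop blank samples
#'
#' @param asv_counts samples x ASVs matrix.
#' @param calls output of [combine_either()].
#' @param is_blank logical per sample; blank rows are dropped.
#' @return filtered matrix of true samples x retained ASVs.
#' @export
remove_contaminants <- function(asv_counts, calls, is_blank = NULL) {
  drop_asv <- calls$asv[calls$is_contaminant]
  keep <- setdiff(colnames(asv_counts), drop_asv)
  out <- asv_counts[, keep, drop = FALSE]
  if (!is.null(is_blank)) out <- out[!is_blank, , drop = FALSE]
  out
}
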