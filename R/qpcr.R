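# qPCR absolute quantification: Cq -> copies via plasmid standard curves,
# actin normalization, cells-per-gut conversion.

#' Aggregate replicate Cq values
#'
#' Collapses replicate quantification cycles to per-(sample, gene) means.
#' A replicate spread above `spread_warn` cycles triggers a warning but the
#' mean is still returned; samples with no finite replicate are dropped.
#'
#' @param cq_table data frame with columns `sample`, `gene`, `cq`
#'   (a `replicate` column is allowed and ignored).
#' @param spread_warn maximal acceptable max-min replicate spread, in cycles.
#' @return data frame `sample`, `gene`, `cq` (mean), `spread`, `n_reps`.
#' @export
aggregate_cq <- function(cq_table, spread_warn = 1) {
  stopifnot(all(c("sample", "gene", "cq") %in% names(cq_table)))
  cq_table <- cq_table[is.finite(cq_table$cq), , drop = FALSE]
  if (!nrow(cq_table)) stop("no finite Cq replicates")
  key <- interaction(cq_table$sample, cq_table$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(cq_table, key), function(d) {
    data.frame(sample = d$sample[1], gene = d$gene[1],
               cq = mean(d$cq), spread = diff(range(d$cq)),
               n_reps = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  bad <- agg$spread > spread_warn
  if (any(bad))
    warning(sum(bad), " sample/gene combinations with replicate spread > ",
            spread_warn, " cycles: ",
            paste(utils::head(agg$sample[bad], 5), collapse = ", "))
  agg
}

#' Fit a qPCR standard curve
#'
#' Least-squares regression of Cq on log10(plasmid copies) over a serial
#' dilution series. The amplification efficiency is `E = 10^(-1/slope)`;
#' perfect doubling chemistry gives E = 2 (slope -3.3219).
#'
#' @param dilutions data frame with columns `copies` (> 0) and `cq`;
#'   at least 3 distinct copy levels.
#' @param gene optional gene label carried into the result.
#' @return object of class `standard_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `gene`.
#' @export
fit_standard_curve <- function(dilutions, gene = NA_character_) {
  stopifnot(all(c("copies", "cq") %in% names(dilutions)))
  if (any(dilutions$copies <= 0)) stop("copies must be positive")
  if (length(unique(dilutions$copies)) < 3L)
    stop("need at least 3 distinct copy levels")
  fit <- stats::lm(cq ~ log10(copies), data = dilutions)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve slope must be negative (Cq decreases with copies)")
  sst <- sum((dilutions$cq - mean(dilutions$cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  sc <- list(slope = slope,
             intercept = unname(stats::coef(fit)[1]),
             efficiency = 10^(-1 / slope),
             r_squared = r2,
             gene = gene)
  if (sc$efficiency <= 1 || sc$efficiency > 2.2)
    warning("amplification efficiency ", round(sc$efficiency, 3),
            " outside the sanity band (1, 2.2]")
  class(sc) <- "standard_curve"
  sc
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("qPCR standard curve", if (!is.na(x$gene)) paste0("(", x$gene, ")"),
      "\n  slope =", round(x$slope, 4),
      " intercept =", round(x$intercept, 3),
      " E =", round(x$efficiency, 4),
      " R^2 =", round(x$r_squared, 5), "\n")
  invisible(x)
}

#' Raw copy number from a Cq value
#'
#' Inverts the standard-curve relation: `n = E^(intercept - cq)`.
#'
#' @param curve a `standard_curve`.
#' @param cq quantification cycle(s).
#' @export
raw_copies <- function(curve, cq) {
  stopifnot(inherits(curve, "standard_curve"), all(is.finite(cq)))
  curve$efficiency^(curve$intercept - cq)
}

#' Cq predicted for a copy number (standard-curve forward relation)
#'
#' @inheritParams raw_copies
#' @param copies positive copy number(s).
#' @export
cq_from_copies <- function(curve, copies) {
  stopifnot(inherits(curve, "standard_curve"), all(copies > 0))
  curve$intercept - log(copies) / log(curve$efficiency)
}

#' Actin-normalized bacterial loads per gut
#'
#' Per-microliter raw copies are scaled by the DNA elution volume to whole-gut
#' copies, then 16S copies are normalized by dividing by the sample's actin
#' copies and multiplying by the median actin copies across samples (removing
#' gut-size and extraction-efficiency variation), and finally divided by
#' `loci_per_cell` 16S loci to give bacterial cells per gut.
#'
#' @param raw_loads data frame with columns `sample`, `raw_16S`, `raw_actin`
#'   (copies per microliter of DNA extract).
#' @param elution_volume DNA elution volume in microliters (default 50).
#' @param loci_per_cell mean 16S rRNA gene copies per bacterial cell.
#' @return data frame `sample`, `raw_16S`, `raw_actin`, `copies_per_gut`,
#'   `normalized_16S`, `cells_per_gut`. Samples without a positive actin
#'   signal are excluded with a message.
#' @export
normalize_loads <- function(raw_loads, elution_volume = 50, loci_per_cell = 4) {
  stopifnot(all(c("sample", "raw_16S", "raw_actin") %in% names(raw_loads)))
  ok <- is.finite(raw_loads$raw_actin) & raw_loads$raw_actin > 0 &
    is.finite(raw_loads$raw_16S)
  if (any(!ok))
    message("excluding ", sum(!ok), " sample(s) without a valid actin signal: ",
            paste(utils::head(raw_loads$sample[!ok], 5), collapse = ", "))
  d <- raw_loads[ok, , drop = FALSE]
  if (!nrow(d)) stop("no samples with valid 16S and actin measurements")
  copies_gut <- d$raw_16S * elution_volume
  actin_gut <- d$raw_actin * elution_volume
  med_actin <- stats::median(actin_gut)
  normalized <- copies_gut / actin_gut * med_actin
  data.frame(sample = d$sample,
             raw_16S = d$raw_16S, raw_actin = d$raw_actin,
             copies_per_gut = copies_gut,
             normalized_16S = normalized,
             cells_per_gut = normalized / loci_per_cell,
             stringsAsFactors = FALSE)
}

#' Compare bacterial loads between colonization groups
#'
#' Wilcoxon rank sum test of cells per gut between colonized (CL) and
#' microbiota-depleted (MD) bees, plus the CL/MD ratio of median loads.
#'
#' @param cells_per_gut numeric loads.
#' @param colonization labels with exactly two levels (reference order:
#'   the first sorted level is the numerator if `numerator` is missing).
#' @param numerator label used as ratio numerator (default `"CL"` if present).
#' @return a `beegut_test` with `ratio_of_medians` in the result.
#' @export
compare_loads <- function(cells_per_gut, colonization, numerator = NULL) {
  colonization <- as.character(colonization)
  lev <- sort(unique(colonization))
  if (length(lev) != 2L) stop("expected exactly two colonization levels")
  if (is.null(numerator)) numerator <- if ("CL" %in% lev) "CL" else lev[1]
  denom <- setdiff(lev, numerator)
  xa <- cells_per_gut[colonization == numerator]
  xb <- cells_per_gut[colonization == denom]
  res <- wilcoxon_rank_sum(xa, xb)
  res$ratio_of_medians <- stats::median(xa) / stats::median(xb)
  res$groups <- c(numerator, denom)
  res
}

#' Full qPCR quantification chain
#'
#' Fits per-gene standard curves from the dilution series, aggregates
#' replicate Cq values, converts them to raw copies, and returns
#' actin-normalized loads per gut.
#'
#' @param dilution_series data frame `gene`, `copies`, `cq`.
#' @param cq_table data frame `sample`, `gene`, `replicate`, `cq`.
#' @param elution_volume DNA elution volume in microliters.
#' @param loci_per_cell 16S loci per bacterial cell.
#' @return output of [normalize_loads()], with the fitted curves attached
#'   as attribute `"curves"`.
#' @export
quantify_loads <- function(dilution_series, cq_table, elution_volume = 50,
                           loci_per_cell = 4) {
  curves <- lapply(split(dilution_series, dilution_series$gene),
                   function(d) fit_standard_curve(d, d$gene[1]))
  if (!all(c("16S", "actin") %in% names(curves)))
    stop("dilution series must cover genes 16S and actin")
  agg <- aggregate_cq(cq_table)
  raw <- lapply(c(`16S` = "16S", actin = "actin"), function(g) {
    a <- agg[agg$gene == g, ]
    stats::setNames(raw_copies(curves[[g]], a$cq), a$sample)
  })
  samples <- intersect(names(raw$`16S`), names(raw$actin))
  loads <- normalize_loads(
    data.frame(sample = samples, raw_16S = raw$`16S`[samples],
               raw_actin = raw$actin[samples], stringsAsFactors = FALSE),
    elution_volume = elution_volume, loci_per_cell = loci_per_cell)
  attr(loads, "curves") <- curves
  loads
}
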