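# Absolute-abundance ASV table: amplicon proportions x qPCR loads.

#' Convert counts to per-sample proportions
#'
#' @param asv_counts samples x ASVs nonnegative matrix. Samples with zero
#'   total count are excluded with a message.
#' @return matrix of row-proportions (rows sum to 1).
#' @export
to_proportions <- function(asv_counts) {
  tot <- rowSums(asv_counts)
  if (any(tot == 0)) {
    message("excluding ", sum(tot == 0), " zero-count sample(s): ",
            paste(utils::head(rownames(asv_counts)[tot == 0], 5),
                  collapse = ", "))
    asv_counts <- asv_counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(asv_counts)) stop("no samples with positive counts")
  sweep(asv_counts, 1, tot, "/")
}

#' Scale proportions by per-sample bacterial load
#'
#' Builds the absolute-abundance table: each sample's ASV proportions are
#' multiplied by its qPCR-measured load (normalized 16S copies for ASV-level
#' statistics, cells for load plots). Each row then sums to the sample's
#' load.
#'
#' @param proportions samples x ASVs proportion matrix.
#' @param loads named numeric vector of per-sample loads. Samples without a
#'   load are excluded with a message; a zero load yields an all-zero row.
#' @return samples x ASVs matrix of estimated copy numbers, with attribute
#'   `"loads"` recording the loads used.
#' @export
scale_by_load <- function(proportions, loads) {
  stopifnot(!is.null(names(loads)), !is.null(rownames(proportions)))
  have <- rownames(proportions) %in% names(loads)
  if (any(!have))
    message("excluding ", sum(!have), " sample(s) without a load: ",
            paste(utils::head(rownames(proportions)[!have], 5),
                  collapse = ", "))
  pr <- proportions[have, , drop = FALSE]
  if (!nrow(pr)) stop("no samples with matching loads")
  l <- loads[rownames(pr)]
  if (any(l == 0))
    message(sum(l == 0), " sample(s) with zero load yield all-zero rows")
  out <- pr * l
  attr(out, "loads") <- l
  out
}
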