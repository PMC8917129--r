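# End-to-end orchestration: simulate/read -> qPCR -> filtering -> absolute
# abundance -> community ecology -> per-ASV tests -> physiology -> survival.

#' Pipeline configuration
#'
#' @param output_dir directory for all outputs.
#' @param simulate if `TRUE` generate data with [simulate_experiment()];
#'   otherwise read a dataset from `input_dir`.
#' @param sim a [simulation_config()] (when `simulate`).
#' @param input_dir directory of input tables (when `simulate = FALSE`).
#' @param seed master seed for all permutation stages.
#' @param n_permutations permutations for community-level tests.
#' @param asv_permutations randomizations per ASV.
#' @param alpha significance level.
#' @param contaminant_threshold "either"-rule threshold.
#' @param prevalence_floor per-ASV prevalence floor for testing.
#' @param stages subset of
#'   `c("qpcr", "filter", "abundance", "ecology", "asvtest", "physiology",
#'   "survival", "cluster")` to run.
#' @export
pipeline_config <- function(output_dir,
                            simulate = TRUE,
                            sim = simulation_config(),
                            input_dir = NULL,
                            seed = 1L,
                            n_permutations = 999,
                            asv_permutations = 2000,
                            alpha = 0.05,
                            contaminant_threshold = 0.1,
                            prevalence_floor = 0.25,
                            stages = c("qpcr", "filter", "abundance",
                                       "ecology", "asvtest", "physiology",
                                       "survival", "cluster")) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_permutations < 99) stop("n_permutations must be at least 99")
  if (!simulate && (is.null(input_dir) || !dir.exists(input_dir)))
    stop("input_dir must exist when simulate = FALSE")
  cfg <- as.list(environment())
  class(cfg) <- "beegut_pipeline_config"
  cfg
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log_path, append = TRUE)
  message(msg)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order and writes every output table to
#' `config$output_dir`. Re-running with the same config reproduces all
#' numeric outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `manifest` (named file paths), `results`
#'   (key statistics) and the in-memory intermediates.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "beegut_pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$output_dir, "run.log")
  cat("", file = logf)
  manifest <- c(); results <- list()
  stage_on <- function(s) s %in% config$stages

  if (config$simulate) {
    log_line(logf, "simulate: seed ", config$sim$seed)
    ds <- simulate_experiment(config$sim)
    manifest <- c(manifest, write_dataset(ds, file.path(config$output_dir,
                                                        "simulated_input")))
  } else {
    log_line(logf, "reading inputs from ", config$input_dir)
    ds <- read_dataset(config$input_dir)
  }
  meta <- ds$metadata
  gut <- meta$sample[!meta$is_blank]

  loads <- NULL
  if (stage_on("qpcr")) {
    log_line(logf, "qpcr: fitting standard curves")
    loads <- quantify_loads(ds$dilution_series, ds$cq_table,
                            elution_volume = if (!is.null(ds$config))
                              ds$config$elution_volume else 50)
    manifest["loads"] <- write_tsv(loads,
                                   file.path(config$output_dir, "loads.tsv"))
    cmp <- compare_loads(loads$cells_per_gut,
                         meta$colonization[match(loads$sample, meta$sample)])
    results$load_ratio_CL_MD <- cmp$ratio_of_medians
    results$load_wilcoxon_p <- cmp$p_value
    log_line(logf, "qpcr: CL/MD median ratio ",
             round(cmp$ratio_of_medians, 3))
  }

  counts <- ds$asv_counts
  if (stage_on("filter")) {
    tf <- taxonomy_filter(counts, ds$taxonomy)
    log_line(logf, "filter: removed ", length(tf$removed),
             " organellar/eukaryotic ASVs")
    prev <- prevalence_method(tf$counts, meta$is_blank[match(
      rownames(tf$counts), meta$sample)])
    load_vec <- stats::setNames(loads$normalized_16S, loads$sample)
    freq_rows <- rownames(tf$counts)[rownames(tf$counts) %in% gut &
                                       rownames(tf$counts) %in%
                                       names(load_vec)]
    freq <- frequency_method(tf$counts[freq_rows, , drop = FALSE], load_vec,
                             strata = meta$colonization[match(freq_rows,
                                                              meta$sample)])
    calls <- combine_either(prev, freq, config$contaminant_threshold)
    manifest["contaminants"] <- write_tsv(
      calls, file.path(config$output_dir, "contaminants.tsv"))
    counts <- remove_contaminants(tf$counts, calls,
                                  meta$is_blank[match(rownames(tf$counts),
                                                      meta$sample)])
    results$n_contaminants_flagged <- sum(calls$is_contaminant)
    log_line(logf, "filter: flagged ", sum(calls$is_contaminant),
             " contaminant ASVs")
  } else {
    counts <- counts[rownames(counts) %in% gut, , drop = FALSE]
  }

  abs_tab <- NULL
  if (stage_on("abundance")) {
    props <- to_proportions(counts)
    load_vec <- stats::setNames(loads$normalized_16S, loads$sample)
    abs_tab <- scale_by_load(props, load_vec)
    manifest["abs_abund"] <- write_tsv(
      data.frame(sample = rownames(abs_tab), abs_tab, check.names = FALSE),
      file.path(config$output_dir, "abs_abund.tsv"))
    log_line(logf, "abundance: ", nrow(abs_tab), " x ", ncol(abs_tab),
             " absolute table")
  }

  if (stage_on("ecology") && !is.null(abs_tab)) {
    col_of <- meta$colonization[match(rownames(abs_tab), meta$sample)]
    trt_of <- meta$pesticide[match(rownames(abs_tab), meta$sample)]
    bc <- bray_curtis(abs_tab)
    wuf <- weighted_unifrac(abs_tab, ds$tree)
    uuf <- unweighted_unifrac(abs_tab, ds$tree)
    for (nm in c("bray_curtis", "weighted_unifrac", "unweighted_unifrac")) {
      dmat <- as.matrix(switch(nm, bray_curtis = bc,
                               weighted_unifrac = wuf,
                               unweighted_unifrac = uuf))
      manifest[nm] <- write_tsv(
        data.frame(sample = rownames(dmat), dmat, check.names = FALSE),
        file.path(config$output_dir, paste0(nm, ".tsv")))
    }
    ord <- pcoa(bc)
    manifest["pcoa"] <- write_tsv(
      data.frame(sample = rownames(ord$coordinates),
                 ord$coordinates[, 1:min(4, ncol(ord$coordinates))],
                 check.names = FALSE),
      file.path(config$output_dir, "pcoa.tsv"))
    eco <- list(
      adonis_colonization_bc =
        permanova(bc, col_of, config$n_permutations, config$seed),
      anosim_colonization_wuf =
        anosim(wuf, col_of, config$n_permutations, config$seed + 1),
      anosim_colonization_uuf =
        anosim(uuf, col_of, config$n_permutations, config$seed + 2))
    for (s in unique(col_of)) {
      idx <- col_of == s
      sub <- as.matrix(bc)[idx, idx]
      eco[[paste0("adonis_pesticide_", s)]] <-
        permanova(sub, trt_of[idx], config$n_permutations, config$seed + 3)
      eco[[paste0("permdisp_pesticide_", s)]] <-
        permdisp(sub, trt_of[idx], config$n_permutations, config$seed + 4)
    }
    results$ecology <- lapply(eco, function(x)
      list(method = x$method, statistic = x$statistic,
           effect_size = x$effect_size, p_value = x$p_value))
    manifest["ecology_tests"] <- file.path(config$output_dir, "ecology.json")
    jsonlite::write_json(results$ecology, manifest[["ecology_tests"]],
                         auto_unbox = TRUE, digits = NA)
    log_line(logf, "ecology: colonization PERMANOVA R2 ",
             round(eco$adonis_colonization_bc$effect_size, 3))
  }

  if (stage_on("asvtest") && !is.null(abs_tab)) {
    tests <- run_all_asvs(abs_tab, meta,
                          n_permutations = config$asv_permutations,
                          seed = config$seed,
                          prevalence_floor = config$prevalence_floor,
                          alpha = config$alpha)
    manifest["asv_tests"] <- write_tsv(
      tests, file.path(config$output_dir, "asv_tests.tsv"))
    sig <- split(tests$asv[tests$significant], tests$stratum[tests$significant])
    venn <- venn_partition(sig[["CL"]] %||% character(),
                           sig[["MD"]] %||% character())
    manifest["venn"] <- file.path(config$output_dir, "venn.json")
    jsonlite::write_json(venn, manifest[["venn"]], auto_unbox = TRUE,
                         digits = NA)
    results$venn_counts <- as.list(venn$counts)
    log_line(logf, "asvtest: ", sum(tests$significant),
             " significant ASV records")
  }

  if (stage_on("physiology")) {
    mt <- marker_treatment_tests(ds$enzyme_table, config$alpha)
    cc <- colonization_contrast(ds$enzyme_table, config$alpha)
    manifest["physiology_tests"] <- write_tsv(
      mt$tests, file.path(config$output_dir, "physiology_tests.tsv"))
    manifest["colonization_contrasts"] <- write_tsv(
      cc, file.path(config$output_dir, "colonization_contrasts.tsv"))
    results$physiology <- list(
      n_significant_marker_tests = sum(mt$tests$p_value < config$alpha),
      n_significant_contrasts = sum(cc$p_value < config$alpha))
    if (stage_on("cluster")) {
      mm <- marker_matrix(ds$enzyme_table)
      norm <- control_normalize(mm)
      manifest["normalized_matrix"] <- write_tsv(
        data.frame(row = rownames(norm), norm, check.names = FALSE),
        file.path(config$output_dir, "normalized_matrix.tsv"))
      rd <- upgma_cluster(norm, "rows")
      cd <- upgma_cluster(norm, "columns")
      writeLines(rd$newick, file.path(config$output_dir, "rows.nwk"))
      writeLines(cd$newick, file.path(config$output_dir, "columns.nwk"))
      manifest["rows_dendrogram"] <- file.path(config$output_dir, "rows.nwk")
      manifest["columns_dendrogram"] <- file.path(config$output_dir,
                                                  "columns.nwk")
      hm <- render_heatmap(norm, rd, cd,
                           file.path(config$output_dir, "heatmap.png"))
      manifest["heatmap"] <- hm$file
      log_line(logf, "cluster: column leaf order ",
               paste(cd$order, collapse = " "))
    }
  }

  if (stage_on("survival")) {
    sl <- ds$survival_log
    grp_of <- paste(sl$colonization, sl$pesticide, sep = ".")
    km_rows <- list(); ev_rows <- list()
    for (cage in unique(sl$cage)) {
      s <- sl[sl$cage == cage, ]
      s <- s[order(s$day), ]
      n0 <- s$alive[1] + s$deaths[1]
      km <- kaplan_meier(s$deaths, n0)
      km$cage <- cage
      km_rows[[cage]] <- km
      ev <- expand_events(s$deaths, n0)
      ev$cage <- cage
      ev$group <- paste(s$colonization[1], s$pesticide[1], sep = ".")
      ev_rows[[cage]] <- ev
    }
    km_all <- do.call(rbind, km_rows)
    ev_all <- do.call(rbind, ev_rows)
    manifest["km_curves"] <- write_tsv(
      km_all, file.path(config$output_dir, "km_curves.tsv"))
    lr <- logrank(ev_all$time, ev_all$status, ev_all$group)
    manifest["logrank"] <- file.path(config$output_dir, "logrank.json")
    jsonlite::write_json(list(statistic = lr$statistic, df = lr$df,
                              p_value = lr$p_value),
                         manifest[["logrank"]], auto_unbox = TRUE,
                         digits = NA)
    results$logrank_p <- lr$p_value
    cs <- consumption_series(ds$feeder_log, survival_log = sl)
    manifest["consumption"] <- write_tsv(
      cs, file.path(config$output_dir, "consumption.tsv"))
    trt_map <- stats::setNames(paste(sl$colonization, sl$pesticide,
                                     sep = "."), sl$cage)
    trt_map <- trt_map[!duplicated(names(trt_map))]
    kw <- compare_consumption(cs, trt_map)
    results$consumption_kw_p <- kw$p_value
    log_line(logf, "survival: log-rank p ", round(lr$p_value, 3),
             ", consumption KW p ", round(kw$p_value, 3))
  }

  results$seed <- config$seed
  manifest["results"] <- file.path(config$output_dir, "results.json")
  jsonlite::write_json(results, manifest[["results"]], auto_unbox = TRUE,
                       digits = NA)
  log_line(logf, "done: ", length(manifest), " outputs")
  invisible(list(manifest = manifest, results = results, dataset = ds,
                 abs_table = abs_tab, loads = loads))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a directory of pipeline input files
#'
#' Schema and cross-reference checks for every input table: required
#' columns, label agreement between the counts table, metadata, Cq table
#' and tree leaves. Report-only; never throws on bad content.
#'
#' @param directory input directory as produced by [write_dataset()].
#' @return data frame `check`, `ok`, `detail`.
#' @export
validate_inputs <- function(directory) {
  row_of <- function(check, ok, detail = "") data.frame(
    check = check, ok = ok, detail = detail, stringsAsFactors = FALSE)
  out <- list()
  ds <- tryCatch(read_dataset(directory), error = function(e) e)
  if (inherits(ds, "error"))
    return(row_of("read", FALSE, conditionMessage(ds)))
  out[[1]] <- row_of("read", TRUE)
  need_meta <- c("sample", "colonization", "pesticide", "cage", "is_blank")
  out[[2]] <- row_of("metadata columns",
                  all(need_meta %in% names(ds$metadata)),
                  paste(setdiff(need_meta, names(ds$metadata)),
                        collapse = ", "))
  extra <- setdiff(rownames(ds$asv_counts), ds$metadata$sample)
  out[[3]] <- row_of("counts samples in metadata", !length(extra),
                  paste(utils::head(extra, 5), collapse = ", "))
  no_tree <- setdiff(colnames(ds$asv_counts), ds$tree$tip.label)
  out[[4]] <- row_of("ASVs covered by tree", !length(no_tree),
                  paste(utils::head(no_tree, 5), collapse = ", "))
  no_tax <- setdiff(colnames(ds$asv_counts), ds$taxonomy$asv)
  out[[5]] <- row_of("ASVs covered by taxonomy", !length(no_tax),
                  paste(utils::head(no_tax, 5), collapse = ", "))
  gut <- ds$metadata$sample[!ds$metadata$is_blank]
  no_cq <- setdiff(gut, ds$cq_table$sample)
  out[[6]] <- row_of("gut samples with Cq data", !length(no_cq),
                  paste(utils::head(no_cq, 5), collapse = ", "))
  out[[7]] <- row_of("counts nonnegative", all(ds$asv_counts >= 0))
  neg_surv <- any(ds$survival_log$alive < 0 | ds$survival_log$deaths < 0)
  out[[8]] <- row_of("survival counts nonnegative", !neg_surv)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
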