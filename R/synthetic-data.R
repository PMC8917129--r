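# In-silico replica of a 2 colonization x 5 pesticide factorial cage study:
# ASV counts, taxonomy, phylogeny, qPCR Cq values, blanks, enzyme activities,
# survival and feeder logs, plus the generating ground truth.

core_genus_weights <- c("Lactobacillus Firm-5" = 0.28,
                        "Gilliamella"          = 0.22,
                        "Snodgrassella"        = 0.15,
                        "Lactobacillus Firm-4" = 0.12,
                        "Bifidobacterium"      = 0.12,
                        "Frischella"           = 0.05)

opportunist_genera <- c("Fructobacillus", "Arsenophonus", "Acinetobacter",
                        "Pseudomonas", "Enterobacter", "Klebsiella",
                        "Bombella", "Apilactobacillus")

contaminant_genera <- c("Ralstonia", "Sphingomonas", "Burkholderia",
                        "Methylobacterium", "Cutibacterium", "Bradyrhizobium")

#' Configuration of the synthetic cage experiment
#'
#' Defaults emulate the study design: 2 colonization levels (CL = colonized,
#' MD = microbiota-depleted) x 5 pesticide treatments x 4 cages of 30 bees,
#' 16 dissected guts per treatment combination (160 gut samples), 16 blank
#' extractions, and 7 pooled physiology replicates per treatment and tissue.
#' Bacterial loads are lognormal with the CL mean three-fold the MD mean;
#' read counts are Dirichlet-multinomial at Poisson depth; reagent
#' contaminants enter every sample at a load-independent absolute level.
#'
#' @param seed integer RNG seed; the same config yields a bit-identical
#'   dataset.
#' @param colonization_levels,pesticide_treatments factor labels.
#' @param cages_per_treatment,bees_per_cage,guts_per_treatment,n_blanks
#'   design counts (guts are spread evenly across cages).
#' @param n_core_asvs,n_opportunist_asvs,n_contaminant_asvs,n_organelle_asvs
#'   community sizes; organellar ASVs exercise the taxonomy filter.
#' @param mean_load_MD mean true bacterial cells per gut in MD bees.
#' @param load_ratio_CL_MD fold increase of the CL mean load over MD.
#' @param load_cv coefficient of variation of the lognormal loads.
#' @param dirichlet_concentration concentration of the within-group
#'   composition Dirichlet; larger = less compositional noise.
#' @param sequencing_depth_mean,blank_depth_mean Poisson mean reads/sample.
#' @param contaminant_mean_copies mean absolute 16S copies contributed by
#'   each contaminant ASV per extraction, independent of the true load.
#' @param effect_map data frame (`asv`, `colonization`, `treatment`, `fold`)
#'   of multiplicative treatment effects on expected absolute abundance.
#' @param enzyme_effect_map data frame (`tissue`, `marker`, `colonization`,
#'   `treatment`, `shift`) of relative shifts of enzyme means versus the
#'   stratum control.
#' @param physiology_reps pooled samples per treatment/tissue/marker.
#' @param exposure_days days of chronic exposure (survival horizon).
#' @param daily_hazard per-day death probability (single value or named by
#'   pesticide treatment).
#' @param consumption_mean,consumption_sd per-bee daily syrup intake (g).
#' @param evaporation_mean,evaporation_sd daily feeder evaporation (g).
#' @param elution_volume DNA elution volume (uL).
#' @param cq_noise_sd replicate Cq noise (cycles); triplicates are emitted.
#' @param enzyme_cv coefficient of variation of enzyme activities.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              colonization_levels = c("CL", "MD"),
                              pesticide_treatments = c("Control", "Insecticide",
                                                       "Herbicide", "Fungicide",
                                                       "Mix"),
                              cages_per_treatment = 4L,
                              bees_per_cage = 30L,
                              guts_per_treatment = 16L,
                              n_blanks = 16L,
                              n_core_asvs = 12L,
                              n_opportunist_asvs = 20L,
                              n_contaminant_asvs = 6L,
                              n_organelle_asvs = 2L,
                              mean_load_MD = 3e7,
                              load_ratio_CL_MD = 3,
                              load_cv = 0.5,
                              dirichlet_concentration = 100,
                              sequencing_depth_mean = 40000,
                              blank_depth_mean = 2000,
                              contaminant_mean_copies = 2e5,
                              effect_map = NULL,
                              enzyme_effect_map = NULL,
                              physiology_reps = 7L,
                              exposure_days = 5L,
                              daily_hazard = 0.008,
                              consumption_mean = 0.045,
                              consumption_sd = 0.006,
                              evaporation_mean = 0.08,
                              evaporation_sd = 0.015,
                              elution_volume = 50,
                              cq_noise_sd = 0.15,
                              enzyme_cv = 0.12) {
  if (is.null(effect_map)) effect_map <- default_effect_map()
  if (is.null(enzyme_effect_map)) enzyme_effect_map <- default_enzyme_effects()
  cfg <- as.list(environment())
  counts <- c("cages_per_treatment", "bees_per_cage", "guts_per_treatment",
              "n_blanks", "n_core_asvs", "n_opportunist_asvs",
              "n_contaminant_asvs", "physiology_reps", "exposure_days")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop(nm, " must be at least 1")
  if (cfg$load_ratio_CL_MD <= 0) stop("load_ratio_CL_MD must be positive")
  if (cfg$dirichlet_concentration <= 0)
    stop("dirichlet_concentration must be positive")
  if (anyDuplicated(cfg$pesticide_treatments))
    stop("pesticide treatment labels must be unique")
  if (cfg$sequencing_depth_mean <= 0) stop("sequencing depth must be positive")
  if (any(cfg$daily_hazard < 0 | cfg$daily_hazard > 1))
    stop("daily_hazard must lie in [0, 1]")
  class(cfg) <- "simulation_config"
  cfg
}

# five low-abundance opportunists (about 0.5-1.5% of the MD community) are
# increased under one pesticide treatment each; the fold per target is
# calibrated so that the planted shift is about five within-group standard
# deviations (compositional CV grows as ASV weight shrinks: for weight w at
# concentration c, CV ~ sqrt((1-w)/(w(1+c))), compounded with the load CV),
# while total loads stay essentially unchanged (< 5% mean shift)
default_effect_map <- function() {
  data.frame(
    asv = c("Opp11", "Opp12", "Opp13", "Opp14", "Opp15"),
    colonization = "MD",
    treatment = c("Insecticide", "Herbicide", "Fungicide", "Mix",
                  "Fungicide"),
    fold = c(6, 6, 7, 7, 9),
    stringsAsFactors = FALSE)
}

default_enzyme_effects <- function() {
  data.frame(
    tissue = c("head", "head", "head", "head",
               "midgut", "midgut", "midgut", "midgut"),
    marker = c("LDH", "LDH", "LDH", "LDH", "GST", "GST", "GST", "GST"),
    colonization = c("CL", "MD", "MD", "MD", "CL", "MD", "MD", "MD"),
    treatment = c("Fungicide", "Fungicide", "Herbicide", "Mix",
                  "Fungicide", "Fungicide", "Herbicide", "Mix"),
    shift = c(0.5, 0.6, 0.35, 0.6, -0.3, 0.35, 0.3, 0.4),
    stringsAsFactors = FALSE)
}

# tissue x marker baseline activities (mU/mg protein) for the 11 valid
# combinations; midgut GST is elevated 1.4x in CL bees.
enzyme_baselines <- function() {
  d <- rbind(
    data.frame(tissue = c("head", "abdomen", "midgut"), marker = "GST",
               mean = c(55, 48, 60)),
    data.frame(tissue = c("head", "abdomen", "midgut"), marker = "G6PDH",
               mean = c(30, 26, 34)),
    data.frame(tissue = c("head", "abdomen", "midgut"), marker = "LDH",
               mean = c(82, 75, 70)),
    data.frame(tissue = "midgut", marker = c("ALP", "POx"),
               mean = c(120, 15)))
  d$cl_mult <- ifelse(d$tissue == "midgut" & d$marker == "GST", 1.4, 1)
  d
}

rdirichlet1 <- function(alpha) {
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos], rate = 1)
  g / sum(g)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

build_taxonomy <- function(asv_ids, kind, genus) {
  domain <- ifelse(kind == "organelle" & genus == "Eukaryota_host",
                   "Eukaryota", "Bacteria")
  fam <- ifelse(genus == "Mitochondria_host", "Mitochondria", paste0(genus, "aceae"))
  ord <- ifelse(genus == "Chloroplast_plant", "Chloroplast", "Unassigned_order")
  data.frame(asv = asv_ids, domain = domain, phylum = "Unassigned_phylum",
             class = "Unassigned_class", order = ord, family = fam,
             genus = genus, stringsAsFactors = FALSE)
}

#' Simulate the full cage experiment
#'
#' Generates every table the analysis pipeline consumes, together with the
#' generating ground truth (`truth`): true cells per gut, true read-level
#' proportions, the contaminant ASV set and the planted effect maps.
#'
#' @param config a [simulation_config()].
#' @return a `synthetic_dataset` list with elements `asv_counts` (samples x
#'   ASVs integer matrix), `taxonomy`, `tree` (ape `phylo`), `metadata`,
#'   `cq_table`, `dilution_series`, `enzyme_table`, `survival_log`,
#'   `feeder_log`, `truth`, `config`.
#' @export
simulate_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cfg <- config

  ## ---- ASV universe ----
  core_ids <- sprintf("Core%02d", seq_len(cfg$n_core_asvs))
  opp_ids <- sprintf("Opp%02d", seq_len(cfg$n_opportunist_asvs))
  con_ids <- sprintf("Contam%02d", seq_len(cfg$n_contaminant_asvs))
  org_ids <- if (cfg$n_organelle_asvs > 0)
    sprintf("Org%02d", seq_len(cfg$n_organelle_asvs)) else character()
  asv_ids <- c(core_ids, opp_ids, con_ids, org_ids)

  core_genus <- rep(names(core_genus_weights),
                    length.out = cfg$n_core_asvs)
  opp_genus <- rep(opportunist_genera, length.out = cfg$n_opportunist_asvs)
  con_genus <- rep(contaminant_genera, length.out = cfg$n_contaminant_asvs)
  org_genus <- rep(c("Chloroplast_plant", "Mitochondria_host"),
                   length.out = cfg$n_organelle_asvs)
  taxonomy <- rbind(build_taxonomy(core_ids, "core", core_genus),
                    build_taxonomy(opp_ids, "opportunist", opp_genus),
                    build_taxonomy(con_ids, "contaminant", con_genus),
                    if (length(org_ids))
                      build_taxonomy(org_ids, "organelle", org_genus))

  ## core weights: genus budget split geometrically within genus
  core_w <- numeric(cfg$n_core_asvs)
  for (gn in unique(core_genus)) {
    idx <- which(core_genus == gn)
    shares <- 0.6^(seq_along(idx) - 1)
    core_w[idx] <- core_genus_weights[[gn]] * shares / sum(shares)
  }
  opp_w <- 0.75^(seq_len(cfg$n_opportunist_asvs) - 1)
  opp_w <- opp_w / sum(opp_w)

  base_w <- list(
    CL = c(core_w / sum(core_w) * 0.92, opp_w * 0.08,
           rep(0, length(con_ids) + length(org_ids))),
    MD = c(rep(0, length(core_ids)), opp_w,
           rep(0, length(con_ids) + length(org_ids))))
  for (s in names(base_w)) names(base_w[[s]]) <- asv_ids

  ## ---- design layout ----
  strata <- cfg$colonization_levels
  treatments <- cfg$pesticide_treatments
  design <- expand.grid(colonization = strata, pesticide = treatments,
                        stringsAsFactors = FALSE)
  guts_per_cage <- cfg$guts_per_treatment / cfg$cages_per_treatment

  meta <- list(); rows <- list(); truth_load <- c(); truth_prop <- list()
  loci <- 4
  mean_load <- c(CL = cfg$mean_load_MD * cfg$load_ratio_CL_MD,
                 MD = cfg$mean_load_MD)
  if (!all(strata %in% names(mean_load)))
    mean_load <- stats::setNames(rep(cfg$mean_load_MD, length(strata)), strata)

  measured_16S <- c(); actin_gut <- c()
  for (d in seq_len(nrow(design))) {
    col <- design$colonization[d]; trt <- design$pesticide[d]
    w0 <- base_w[[col]]
    w <- w0
    em <- cfg$effect_map
    hit <- em$colonization == col & em$treatment == trt
    for (i in which(hit)) {
      if (em$asv[i] %in% names(w)) w[em$asv[i]] <- w[em$asv[i]] * em$fold[i]
    }
    load_adj <- sum(w) / sum(w0)
    for (g in seq_len(cfg$guts_per_treatment)) {
      cage <- ((g - 1) %/% guts_per_cage) + 1
      id <- sprintf("%s_%s_c%d_g%02d", col, trt, cage, g)
      L <- rlnorm_mean_cv(1, mean_load[[col]] * load_adj, cfg$load_cv)
      p_comm <- rdirichlet1(cfg$dirichlet_concentration * w / sum(w))
      abs_copies <- stats::setNames(p_comm * L * loci, asv_ids)
      con_copies <- rlnorm_mean_cv(length(con_ids),
                                   cfg$contaminant_mean_copies, 0.5)
      org_copies <- if (length(org_ids))
        rlnorm_mean_cv(length(org_ids), 0.005 * mean_load[[col]] * loci, 0.5)
        else numeric()
      abs_copies[con_ids] <- con_copies
      if (length(org_ids)) abs_copies[org_ids] <- org_copies
      pr <- abs_copies / sum(abs_copies)
      depth <- stats::rpois(1, cfg$sequencing_depth_mean)
      reads <- stats::rmultinom(1, depth, pr)[, 1]
      rows[[id]] <- reads
      truth_load[id] <- L
      truth_prop[[id]] <- pr
      measured_16S[id] <- sum(abs_copies)
      meta[[id]] <- data.frame(sample = id, colonization = col,
                               pesticide = trt,
                               cage = sprintf("%s_%s_c%d", col, trt, cage),
                               is_blank = FALSE, stringsAsFactors = FALSE)
    }
  }

  ## blanks: contaminants only
  for (b in seq_len(cfg$n_blanks)) {
    id <- sprintf("Blank_%02d", b)
    abs_copies <- stats::setNames(numeric(length(asv_ids)), asv_ids)
    abs_copies[con_ids] <- rlnorm_mean_cv(length(con_ids),
                                          cfg$contaminant_mean_copies, 0.5)
    pr <- abs_copies / sum(abs_copies)
    depth <- stats::rpois(1, cfg$blank_depth_mean)
    rows[[id]] <- stats::rmultinom(1, depth, pr)[, 1]
    truth_prop[[id]] <- pr
    meta[[id]] <- data.frame(sample = id, colonization = NA_character_,
                             pesticide = NA_character_, cage = NA_character_,
                             is_blank = TRUE, stringsAsFactors = FALSE)
  }

  asv_counts <- do.call(rbind, rows)
  dimnames(asv_counts) <- list(names(rows), asv_ids)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL

  ## ---- tree over all ASVs ----
  tree <- ape::rcoal(length(asv_ids), tip.label = sample(asv_ids))

  ## ---- qPCR ----
  curves <- list(`16S` = list(slope = -3.4, intercept = 37),
                 actin = list(slope = -3.35, intercept = 35))
  eff <- function(cv) 10^(-1 / cv$slope)
  gut_samples <- metadata$sample[!metadata$is_blank]
  extraction_eff <- rlnorm_mean_cv(length(gut_samples), 1, 0.2)
  names(extraction_eff) <- gut_samples
  actin_per_gut <- 1e6 * extraction_eff
  meas_16S <- measured_16S[gut_samples] * extraction_eff

  cq_rows <- list()
  for (s in gut_samples) {
    for (gene in c("16S", "actin")) {
      cv <- curves[[gene]]
      per_ul <- if (gene == "16S") meas_16S[[s]] else actin_per_gut[[s]]
      per_ul <- per_ul / cfg$elution_volume
      cq0 <- cv$intercept - log(per_ul) / log(eff(cv))
      cq_rows[[paste(s, gene)]] <- data.frame(
        sample = s, gene = gene, replicate = 1:3,
        cq = cq0 + stats::rnorm(3, 0, cfg$cq_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  cq_table <- do.call(rbind, cq_rows); rownames(cq_table) <- NULL

  dil_rows <- list()
  for (gene in c("16S", "actin")) {
    cv <- curves[[gene]]
    copies <- 10^(2:8)
    for (rep in 1:3) {
      dil_rows[[paste(gene, rep)]] <- data.frame(
        gene = gene, copies = copies, replicate = rep,
        cq = cv$intercept - log(copies) / log(eff(cv)) +
          stats::rnorm(length(copies), 0, cfg$cq_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  dilution_series <- do.call(rbind, dil_rows); rownames(dilution_series) <- NULL

  ## ---- enzymes ----
  base <- enzyme_baselines()
  enz_rows <- list(); enz_truth <- list()
  for (i in seq_len(nrow(base))) {
    for (col in strata) {
      for (trt in treatments) {
        mu <- base$mean[i] * (if (col == "CL") base$cl_mult[i] else 1)
        ee <- cfg$enzyme_effect_map
        hit <- ee$tissue == base$tissue[i] & ee$marker == base$marker[i] &
          ee$colonization == col & ee$treatment == trt
        if (any(hit)) mu <- mu * (1 + sum(ee$shift[hit]))
        act <- stats::rnorm(cfg$physiology_reps, mu, cfg$enzyme_cv * mu)
        enz_rows[[length(enz_rows) + 1]] <- data.frame(
          tissue = base$tissue[i], marker = base$marker[i],
          colonization = col, treatment = trt,
          replicate = seq_len(cfg$physiology_reps),
          activity = pmax(act, 1e-6), stringsAsFactors = FALSE)
        enz_truth[[length(enz_truth) + 1]] <- data.frame(
          tissue = base$tissue[i], marker = base$marker[i],
          colonization = col, treatment = trt, true_mean = mu,
          stringsAsFactors = FALSE)
      }
    }
  }
  enzyme_table <- do.call(rbind, enz_rows); rownames(enzyme_table) <- NULL

  ## ---- survival & feeder ----
  hazard <- cfg$daily_hazard
  if (is.null(names(hazard)))
    hazard <- stats::setNames(rep(hazard[1], length(treatments)), treatments)
  surv_rows <- list(); feed_rows <- list()
  for (d in seq_len(nrow(design))) {
    col <- design$colonization[d]; trt <- design$pesticide[d]
    for (cg in seq_len(cfg$cages_per_treatment)) {
      cage <- sprintf("%s_%s_c%d", col, trt, cg)
      alive <- cfg$bees_per_cage
      for (day in seq_len(cfg$exposure_days)) {
        deaths <- stats::rbinom(1, alive, hazard[[trt]])
        alive_start <- alive
        alive <- alive - deaths
        surv_rows[[paste(cage, day)]] <- data.frame(
          cage = cage, colonization = col, pesticide = trt, day = day,
          deaths = deaths, alive = alive, stringsAsFactors = FALSE)
        per_bee <- max(stats::rnorm(1, cfg$consumption_mean,
                                    cfg$consumption_sd), 1e-4)
        evap <- max(stats::rnorm(1, cfg$evaporation_mean,
                                 cfg$evaporation_sd), 0)
        feed_rows[[paste(cage, day)]] <- data.frame(
          cage = cage, colonization = col, pesticide = trt, day = day,
          role = "feeder", mass_change = alive_start * per_bee + evap,
          stringsAsFactors = FALSE)
      }
    }
  }
  for (ec in 1:3) {
    for (day in seq_len(cfg$exposure_days)) {
      feed_rows[[paste("evap", ec, day)]] <- data.frame(
        cage = sprintf("EvapCtrl_%d", ec), colonization = NA_character_,
        pesticide = NA_character_, day = day, role = "evaporation",
        mass_change = max(stats::rnorm(1, cfg$evaporation_mean,
                                       cfg$evaporation_sd), 0),
        stringsAsFactors = FALSE)
    }
  }
  survival_log <- do.call(rbind, surv_rows); rownames(survival_log) <- NULL
  feeder_log <- do.call(rbind, feed_rows); rownames(feeder_log) <- NULL

  truth <- list(true_cells_per_gut = truth_load,
                true_proportions = do.call(rbind, truth_prop),
                true_contaminants = con_ids,
                true_effect_map = cfg$effect_map,
                true_enzyme_means = do.call(rbind, enz_truth))
  colnames(truth$true_proportions) <- asv_ids

  ds <- list(asv_counts = asv_counts, taxonomy = taxonomy, tree = tree,
             metadata = metadata, cq_table = cq_table,
             dilution_series = dilution_series, enzyme_table = enzyme_table,
             survival_log = survival_log, feeder_log = feeder_log,
             truth = truth, config = cfg)
  class(ds) <- "synthetic_dataset"
  ds
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic cage-experiment dataset:",
      sum(!x$metadata$is_blank), "gut samples,",
      sum(x$metadata$is_blank), "blanks,",
      ncol(x$asv_counts), "ASVs\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `asv_counts.tsv`, `taxonomy.tsv`, `metadata.tsv`, `tree.nwk`,
#' `cq.csv`, `dilutions.csv`, `enzymes.tsv`, `survival.csv`, `feeder.csv`
#' and `truth.json` into `directory`.
#'
#' @param ds a `synthetic_dataset`.
#' @param directory output directory (created if absent).
#' @return invisibly, a named character vector of the files written.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(directory, name)
  counts_df <- data.frame(sample = rownames(ds$asv_counts),
                          ds$asv_counts, check.names = FALSE)
  utils::write.table(counts_df, f("asv_counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$taxonomy, f("taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$metadata, f("metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ape::write.tree(ds$tree, f("tree.nwk"))
  utils::write.csv(ds$cq_table, f("cq.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$dilution_series, f("dilutions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(ds$enzyme_table, f("enzymes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(ds$survival_log, f("survival.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$feeder_log, f("feeder.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- ds$truth
  truth$true_cells_per_gut <- as.list(ds$truth$true_cells_per_gut)
  tp_df <- data.frame(
    sample = rownames(ds$truth$true_proportions),
    as.data.frame(ds$truth$true_proportions), check.names = FALSE)
  rownames(tp_df) <- NULL
  truth$true_proportions <- tp_df
  jsonlite::write_json(truth, f("truth.json"), digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  manifest <- c(asv_counts = f("asv_counts.tsv"), taxonomy = f("taxonomy.tsv"),
                metadata = f("metadata.tsv"), tree = f("tree.nwk"),
                cq = f("cq.csv"), dilutions = f("dilutions.csv"),
                enzymes = f("enzymes.tsv"), survival = f("survival.csv"),
                feeder = f("feeder.csv"), truth = f("truth.json"))
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory directory holding the ten files.
#' @return a `synthetic_dataset`-shaped list (without `config`).
#' @export
read_dataset <- function(directory) {
  f <- function(name) {
    p <- file.path(directory, name)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  counts_df <- utils::read.delim(f("asv_counts.tsv"), check.names = FALSE)
  asv_counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(asv_counts) <- counts_df$sample
  truth <- jsonlite::read_json(f("truth.json"), simplifyVector = TRUE)
  if (!is.null(truth$true_proportions)) {
    tp <- as.data.frame(truth$true_proportions, check.names = FALSE)
    keep <- setdiff(names(tp), c("sample", "_row"))
    m <- as.matrix(tp[, keep, drop = FALSE])
    rownames(m) <- tp$sample
    truth$true_proportions <- m
  }
  truth$true_cells_per_gut <- unlist(truth$true_cells_per_gut)
  meta <- utils::read.delim(f("metadata.tsv"))
  meta$is_blank <- as.logical(meta$is_blank)
  ds <- list(asv_counts = asv_counts,
             taxonomy = utils::read.delim(f("taxonomy.tsv")),
             metadata = meta,
             tree = ape::read.tree(f("tree.nwk")),
             cq_table = utils::read.csv(f("cq.csv"), check.names = FALSE),
             dilution_series = utils::read.csv(f("dilutions.csv")),
             enzyme_table = utils::read.delim(f("enzymes.tsv")),
             survival_log = utils::read.csv(f("survival.csv")),
             feeder_log = utils::read.csv(f("feeder.csv")),
             truth = truth)
  class(ds) <- "synthetic_dataset"
  ds
}
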