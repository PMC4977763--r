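#' Pipeline configuration
#'
#' Defaults encode the workflow's standard operating point: genome-wide
#' significance 1e-8, 500 kb selection windows called at the 99th percentile,
#' phasing frequency threshold 0.95 with at least 4 homozygous dogs, and
#' stepwise inclusion/exclusion alpha 0.05. All randomness flows from the
#' single top-level `seed` via per-stage derived seeds. The configuration
#' round-trips losslessly through its YAML file representation
#' ([read_pipeline_config()] / [write_pipeline_config()]).
#'
#' @param simulation list of [sim_config()] arguments (used when `input` is
#'   NULL).
#' @param input optional list `genotype_path`, `breed_path`,
#'   `stereotype_path` to analyse existing files instead of simulating.
#' @param traits trait names to scan (NULL = all in the stereotype table).
#' @param gwas_threshold inclusive genome-wide significance cutoff.
#' @param window_size,percentile selection-scan windowing and region calling.
#' @param phasing_threshold,min_homozygotes haplotype-block rule.
#' @param prediction list: `markers` (NULL = use discovered GWAS peaks),
#'   `alpha`, `criterion`, `tolerance`, `window`, `n_perm`, `test_breeds`
#'   (NULL = a derived-seed random third of breeds).
#' @param out_dir output directory.
#' @param seed top-level integer seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = list(), input = NULL, traits = NULL,
                            gwas_threshold = 1e-8, window_size = 5e5,
                            percentile = 99, phasing_threshold = 0.95,
                            min_homozygotes = 4L, prediction = list(),
                            out_dir = "breedscan_out", seed = 1L) {
  stopifnot(gwas_threshold > 0, gwas_threshold < 1,
            phasing_threshold > 0, phasing_threshold <= 1,
            percentile > 50, percentile < 100, min_homozygotes >= 1)
  pred <- utils::modifyList(
    list(alpha = 0.05, criterion = "half_sd",
         tolerance = 0.5, window = 0L, n_perm = 500L),
    prediction[!vapply(prediction, is.null, logical(1))])
  for (key in c("markers", "test_breeds"))
    if (!key %in% names(pred)) pred[key] <- list(NULL)
  structure(list(simulation = simulation, input = input, traits = traits,
                 gwas_threshold = gwas_threshold, window_size = window_size,
                 percentile = percentile,
                 phasing_threshold = phasing_threshold,
                 min_homozygotes = as.integer(min_homozygotes),
                 prediction = pred, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation$causal_loci)) {
    raw$simulation$causal_loci <- lapply(raw$simulation$causal_loci,
      function(cl) causal_locus(cl$chrom, cl$position, cl$risk_breeds,
                                cl$sweep_flank_bp,
                                unlist(cl$effect_weights), id = cl$id))
  }
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  # yaml drops names on atomic vectors; store effect weights as a map
  raw$simulation$causal_loci <- lapply(raw$simulation$causal_loci,
    function(cl) {
      cl <- unclass(cl)
      cl$effect_weights <- as.list(cl$effect_weights)
      cl
    })
  yaml::write_yaml(raw, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_seed <- function(seed, stage) {
  # small fixed offsets keep every derived seed well under 2^31
  seed + c(simulate = 0L, gwas = 101L, selscan = 202L, haplomap = 303L,
           predict = 404L)[[stage]]
}

#' Run the full mapping pipeline
#'
#' Executes simulate/load -> trait PCA -> LMM GWAS per trait -> selection
#' scan -> haplotype fine-mapping at the GWAS peaks -> breed-frequency
#' stereotype prediction, writing per-stage TSV outputs and a JSON manifest
#' (package version, seed, config hash, per-stage row counts) into
#' `config$out_dir`. A stage failure halts the run with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "breedscan",
                   version = as.character(utils::packageVersion("breedscan")),
                   seed = config$seed, stages = list())
  cfg_path <- file.path(config$out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  t_start <- Sys.time()

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    message(sprintf("[breedscan] stage %s ...", name))
    out <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("[breedscan] stage %s done (%.1fs)", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  # --- data ---------------------------------------------------------------
  data <- run_stage("data", function() {
    if (!is.null(config$input)) {
      ds <- read_plink_text(config$input$genotype_path,
                            config$input$breed_path)
      st <- read_stereotypes(config$input$stereotype_path)
      list(dataset = ds, stereotypes = st, truth = NULL)
    } else {
      sim_args <- utils::modifyList(config$simulation,
                                    list(seed = stage_seed(config$seed,
                                                           "simulate")))
      cfg <- do.call(sim_config, sim_args)
      ds <- simulate_breed_genotypes(cfg)
      st <- simulate_stereotypes(ds, cfg)
      write_plink_text(ds, file.path(config$out_dir, "simulated"))
      write_stereotypes(st, file.path(config$out_dir, "stereotypes.tsv"))
      list(dataset = ds, stereotypes = st, truth = attr(ds, "truth"))
    }
  })
  ds <- data$dataset; st <- data$stereotypes
  manifest$stages$data <- list(individuals = length(ds$individuals),
                               snps = nrow(ds$snp_map),
                               breeds = length(unique(dataset_breeds(ds))),
                               traits = length(st$traits))
  traits <- config$traits %||% st$traits

  # --- pca ----------------------------------------------------------------
  pca <- run_stage("pca", function() {
    p <- pca_traits(st)
    write_tsv(data.frame(trait = rownames(p$loadings), p$loadings),
              file.path(config$out_dir, "pca_loadings.tsv"))
    write_tsv(data.frame(breed = rownames(p$scores), p$scores),
              file.path(config$out_dir, "pca_scores.tsv"))
    p
  })
  manifest$stages$pca <- list(
    components = length(pca$explained_variance),
    pc1_fraction = round(pca$explained_variance[1], 4))

  # --- gwas ---------------------------------------------------------------
  gwas <- run_stage("gwas", function() {
    K <- centered_grm(ds)
    policy <- significance_policy(config$gwas_threshold)
    res <- list()
    for (tr in traits) {
      y <- assign_breed_means(ds, st, tr)
      rec <- lmm_lrt_scan(ds, y, K)
      write_tsv(rec, file.path(config$out_dir,
                               paste0("gwas_", tr, ".tsv")))
      write_tsv(data.frame(chrom = rec$chrom, pos = rec$pos,
                           neg_log10_p = -log10(rec$p_value)),
                file.path(config$out_dir, paste0("manhattan_", tr, ".tsv")))
      res[[tr]] <- list(records = rec, hits = significant_hits(rec, policy))
    }
    res
  })
  manifest$stages$gwas <- list(
    traits_scanned = length(traits),
    snps_tested = nrow(ds$snp_map),
    significant_hits = sum(vapply(gwas, function(g) nrow(g$hits),
                                  numeric(1))))

  # --- selscan ------------------------------------------------------------
  scan <- run_stage("selscan", function() {
    sc <- selection_scan(ds, config$window_size, config$percentile)
    for (stat in c("di", "si")) {
      regs <- do.call(rbind, lapply(names(sc$regions[[stat]]), function(b) {
        r <- sc$regions[[stat]][[b]]
        if (!nrow(r)) return(NULL)
        cbind(breed = b, r)
      }))
      if (is.null(regs))
        regs <- data.frame(breed = character(0), chrom = integer(0),
                           start = numeric(0), end = numeric(0),
                           n_windows = integer(0), extreme = numeric(0))
      write_tsv(regs, file.path(config$out_dir,
                                paste0("regions_", stat, ".tsv")))
    }
    sc
  })
  manifest$stages$selscan <- list(
    windows = nrow(scan$windows),
    di_regions = sum(vapply(scan$regions$di, nrow, numeric(1))),
    si_regions = sum(vapply(scan$regions$si, nrow, numeric(1))))

  # --- haplomap -----------------------------------------------------------
  peaks <- unique(do.call(rbind, lapply(names(gwas), function(tr) {
    h <- gwas[[tr]]$hits
    if (!nrow(h)) return(NULL)
    data.frame(trait = tr, snp = h$snp[1], chrom = h$chrom[1],
               pos = h$pos[1], stringsAsFactors = FALSE)
  })))
  haplo <- run_stage("haplomap", function() {
    calls <- list(); blocks_out <- NULL
    if (!is.null(peaks)) for (i in seq_len(nrow(peaks))) {
      for (al in c("A", "B")) {
        bl <- lapply(unique(dataset_breeds(ds)), function(b)
          phased_block(ds, b, peaks$snp[i], al,
                       freq_threshold = config$phasing_threshold,
                       min_homozygotes = config$min_homozygotes))
        bl <- Filter(Negate(is.null), bl)
        if (!length(bl)) next
        blocks_out <- rbind(blocks_out, do.call(rbind, lapply(bl, function(x)
          data.frame(trait = peaks$trait[i], peak_snp = x$peak_snp,
                     allele = x$allele, breed = x$breed, chrom = x$chrom,
                     start = x$start, end = x$end,
                     length_kb = block_length_kb(x),
                     n_homozygotes = x$n_homozygotes, n_snps = x$n_snps))))
        ov <- cross_breed_overlap(bl)
        if (isTRUE(ov$empty)) next
        mi <- map_intervals(ov, scan$regions, ov$breeds, peaks$pos[i],
                            window_size = config$window_size,
                            label = paste0(peaks$trait[i], ":",
                                           peaks$snp[i], ":", al))
        calls[[mi$label]] <- mi
      }
    }
    if (is.null(blocks_out))
      blocks_out <- data.frame(trait = character(0), peak_snp = character(0),
                               allele = character(0), breed = character(0),
                               chrom = integer(0), start = numeric(0),
                               end = numeric(0), length_kb = numeric(0),
                               n_homozygotes = integer(0), n_snps = integer(0))
    write_tsv(blocks_out, file.path(config$out_dir, "phased_blocks.tsv"))
    calls_df <- do.call(rbind, lapply(calls, function(x)
      data.frame(locus = x$label, chrom = x$chrom,
                 max_start = x$max_interval[1], max_end = x$max_interval[2],
                 max_kb = diff(x$max_interval) / 1000,
                 min_start = x$min_interval[1], min_end = x$min_interval[2],
                 min_kb = diff(x$min_interval) / 1000,
                 min_source = x$min_source,
                 breeds = paste(x$supporting_breeds, collapse = ","))))
    if (is.null(calls_df))
      calls_df <- data.frame(locus = character(0))
    write_tsv(calls_df, file.path(config$out_dir, "map_intervals.tsv"))
    list(blocks = blocks_out, calls = calls)
  })
  manifest$stages$haplomap <- list(peaks = if (is.null(peaks)) 0L
                                           else nrow(peaks),
                                   blocks = nrow(haplo$blocks),
                                   interval_calls = length(haplo$calls))

  # --- predict ------------------------------------------------------------
  pred <- run_stage("predict", function() {
    markers <- config$prediction$markers %||%
      (if (!is.null(peaks)) unique(peaks$snp) else character(0))
    if (!length(markers)) return(list(skipped = "no markers available"))
    breeds <- sort(unique(dataset_breeds(ds)))
    test_breeds <- config$prediction$test_breeds
    if (is.null(test_breeds)) {
      set.seed(stage_seed(config$seed, "predict"))
      test_breeds <- sort(sample(breeds, max(1, round(length(breeds) / 3))))
    }
    train_breeds <- setdiff(breeds, test_breeds)
    Xall <- breed_allele_frequencies(ds, markers)
    obs <- st$values[match(breeds, st$breeds), , drop = FALSE]
    predicted <- matrix(NA_real_, length(test_breeds), length(traits),
                        dimnames = list(test_breeds, traits))
    coefs <- NULL
    for (tr in traits) {
      mod <- stepwise_fit(Xall[train_breeds, , drop = FALSE],
                          obs[train_breeds, tr],
                          alpha = config$prediction$alpha, trait = tr)
      predicted[, tr] <- predict_breeds(mod,
                                        Xall[test_breeds, , drop = FALSE])
      if (length(mod$selected))
        coefs <- rbind(coefs, data.frame(trait = tr, marker = mod$selected,
                                         coefficient = mod$coefficients))
    }
    sm <- success_matrix(predicted, obs[test_breeds, traits, drop = FALSE],
                         config$prediction$criterion,
                         config$prediction$tolerance,
                         config$prediction$window)
    pc <- permutation_chance(predicted,
                             obs[test_breeds, traits, drop = FALSE],
                             config$prediction$criterion,
                             config$prediction$tolerance,
                             config$prediction$window,
                             n_perm = config$prediction$n_perm,
                             seed = stage_seed(config$seed, "predict"))
    if (is.null(coefs)) coefs <- data.frame(trait = character(0),
                                            marker = character(0),
                                            coefficient = numeric(0))
    write_tsv(coefs, file.path(config$out_dir, "prediction_models.tsv"))
    write_tsv(data.frame(breed = rownames(predicted), predicted),
              file.path(config$out_dir, "predictions.tsv"))
    write_tsv(data.frame(breed = rownames(sm$success), sm$success * 1L,
                         total = sm$row_totals),
              file.path(config$out_dir, "success_matrix.tsv"))
    list(success = sm, chance = pc, test_breeds = test_breeds,
         markers = markers)
  })
  manifest$stages$predict <- if (!is.null(pred$skipped))
    list(skipped = pred$skipped)
  else list(markers = length(pred$markers),
            test_breeds = length(pred$test_breeds),
            success_rate = round(pred$success$success_rate, 4),
            chance_rate = round(pred$chance$chance_rate, 4),
            permutation_p = round(pred$chance$p_value, 6))

  manifest$elapsed_seconds <- round(as.numeric(
    difftime(Sys.time(), t_start, units = "secs")), 3)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
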