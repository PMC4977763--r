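#' Simulation configuration
#'
#' Describes a breed-structured genotype + stereotype simulation. Breeds
#' diverge from a common ancestral population under the Balding-Nichols model
#' (beta-distributed breed allele frequencies around an ancestral frequency,
#' with per-breed divergence `F`). Selective sweeps are planted at causal loci
#' by near-fixing the risk allele in the designated carrier breeds and forcing
#' all their chromosomes to inherit one founder haplotype across the sweep
#' flank, with a small per-SNP leak rate so blocks decay realistically at
#' their edges. These distributional choices are generative stand-ins: real
#' array cohorts provide no generative model, and none of linkage
#' disequilibrium decay, recombination maps or coalescent noise is emulated.
#'
#' @param n_breeds number of breeds.
#' @param dogs_per_breed individuals per breed.
#' @param n_snps_per_chrom SNPs simulated per chromosome.
#' @param chrom_lengths base-pair length of each chromosome (vector; the
#'   chromosome ids are `1..length(chrom_lengths)`).
#' @param breed_divergence_F Balding-Nichols divergence in `[0, 1)`, scalar or
#'   one value per breed.
#' @param causal_loci list of [causal_locus()] specifications.
#' @param trait_noise_sd SD of the breed-level stereotype noise, on the trait
#'   scale (traits are linear in breed risk-allele frequencies, so a unit of
#'   trait corresponds to a unit of allele frequency under weight 1).
#' @param missing_rate fraction of genotype calls set missing, in `[0, 1)`.
#' @param seed integer RNG seed; the same config and seed reproduce the
#'   simulation exactly.
#' @param anc_freq_range range of the Uniform ancestral allele frequency
#'   (default 0.05-0.95, avoiding rare-allele degeneracy).
#' @param sweep_fixation risk-allele frequency forced in carrier breeds at a
#'   causal SNP (default 0.975, i.e. near-fixed).
#' @param sweep_background_freq ancestral frequency of the risk allele at a
#'   causal SNP (default 0.1): the planted variant is a derived allele driven
#'   near fixation only in the carrier breeds and segregating at low
#'   frequency elsewhere, the classic sweep signature.
#' @param sweep_leak per-SNP probability that a carrier chromosome escapes the
#'   founder haplotype inside the sweep flank (default 0.02).
#' @param clip_range stereotype scores are clipped to this range
#'   (default `c(0, Inf)`; nonnegative like questionnaire scores).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_breeds = 12, dogs_per_breed = 12,
                       n_snps_per_chrom = 400,
                       chrom_lengths = rep(12e6, 5),
                       breed_divergence_F = 0.2,
                       causal_loci = list(),
                       trait_noise_sd = 0.1,
                       missing_rate = 0.01,
                       seed = 1L,
                       anc_freq_range = c(0.05, 0.95),
                       sweep_fixation = 0.975,
                       sweep_background_freq = 0.1,
                       sweep_leak = 0.02,
                       clip_range = c(0, Inf)) {
  cfg <- list(n_breeds = as.integer(n_breeds),
              dogs_per_breed = as.integer(dogs_per_breed),
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              chrom_lengths = as.numeric(chrom_lengths),
              breed_divergence_F = breed_divergence_F,
              causal_loci = causal_loci,
              trait_noise_sd = trait_noise_sd,
              missing_rate = missing_rate,
              seed = as.integer(seed),
              anc_freq_range = anc_freq_range,
              sweep_fixation = sweep_fixation,
              sweep_background_freq = sweep_background_freq,
              sweep_leak = sweep_leak,
              clip_range = clip_range)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_breeds >= 1, cfg$dogs_per_breed >= 1,
            cfg$n_snps_per_chrom >= 1, all(cfg$chrom_lengths > 0))
  F <- cfg$breed_divergence_F
  if (!all(F >= 0 & F < 1)) stop("breed_divergence_F must be in [0, 1)")
  if (!(length(F) %in% c(1L, cfg$n_breeds)))
    stop("breed_divergence_F must be scalar or one value per breed")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (cfg$trait_noise_sd < 0) stop("trait_noise_sd must be >= 0")
  breeds <- sim_breed_ids(cfg$n_breeds)
  for (cl in cfg$causal_loci) {
    if (!inherits(cl, "causal_locus")) stop("causal_loci entries must be causal_locus()")
    if (cl$chrom < 1 || cl$chrom > length(cfg$chrom_lengths) ||
        cl$position < 1 || cl$position > cfg$chrom_lengths[cl$chrom])
      stop("causal locus '", cl$id, "' lies outside the simulated map")
    if (!all(cl$risk_breeds %in% breeds))
      stop("causal locus '", cl$id, "' names unknown risk breeds: ",
           paste(setdiff(cl$risk_breeds, breeds), collapse = ", "))
  }
  invisible(cfg)
}

#' Causal locus specification
#'
#' @param chrom chromosome index (1-based into `chrom_lengths`).
#' @param position 1-based bp position of the causal SNP; a SNP is placed at
#'   exactly this position in the simulated map.
#' @param risk_breeds breed codes carrying the sweep (see [sim_breed_ids()]).
#' @param sweep_flank_bp half-width of the low-diversity founder-haplotype
#'   flank around the causal SNP (>= 0).
#' @param effect_weights named numeric vector, trait name -> effect on the
#'   breed stereotype per unit risk-allele frequency.
#' @param id locus label.
#' @return a `causal_locus` list.
#' @export
causal_locus <- function(chrom, position, risk_breeds, sweep_flank_bp,
                         effect_weights, id = NULL) {
  stopifnot(sweep_flank_bp >= 0)
  if (is.null(id)) id <- sprintf("locus_%d_%d", chrom, position)
  if (length(effect_weights) && is.null(names(effect_weights)))
    stop("effect_weights must be named by trait")
  structure(list(id = id, chrom = as.integer(chrom),
                 position = as.numeric(position),
                 risk_breeds = as.character(risk_breeds),
                 sweep_flank_bp = as.numeric(sweep_flank_bp),
                 effect_weights = effect_weights),
            class = "causal_locus")
}

#' Breed codes used by the simulator
#' @param n number of breeds.
#' @return character vector `BR01`, `BR02`, ...
#' @export
sim_breed_ids <- function(n) sprintf("BR%02d", seq_len(n))

#' Simulate breed-structured genotypes
#'
#' Draws an ancestral allele frequency per SNP from
#' `Uniform(anc_freq_range)`, per-breed frequencies from the Balding-Nichols
#' beta distribution with that breed's divergence `F`, and individual
#' genotypes as `Binomial(2, breed frequency)`. At each causal locus the risk
#' breeds are set near-fixed for the risk allele and every SNP within
#' `sweep_flank_bp` is copied from a shared founder haplotype (per-SNP escape
#' probability `sweep_leak`), injecting the long homozygous flanks of a
#' selective sweep. Missing calls are then applied uniformly at
#' `missing_rate`, and each SNP's dosage is oriented to the cohort minor
#' allele. The planted truth (causal SNP ids, risk alleles, sweep intervals)
#' is attached as `attr(, "truth")`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_dataset()] with a `truth` attribute (data.frame: locus
#'   id, snp id, chromosome, position, risk allele code, sweep interval,
#'   comma-separated risk breeds).
#' @export
simulate_breed_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_chrom <- length(config$chrom_lengths)
  breeds <- sim_breed_ids(config$n_breeds)
  Fb <- rep(config$breed_divergence_F, length.out = config$n_breeds)
  n_ind <- config$n_breeds * config$dogs_per_breed
  ind <- sprintf("%s_d%02d", rep(breeds, each = config$dogs_per_breed),
                 rep(seq_len(config$dogs_per_breed), config$n_breeds))
  breed_of <- stats::setNames(rep(breeds, each = config$dogs_per_breed), ind)
  ind_breed_idx <- rep(seq_len(config$n_breeds), each = config$dogs_per_breed)

  # positions: causal positions are always present in the map
  map_list <- vector("list", n_chrom)
  for (ch in seq_len(n_chrom)) {
    causal_pos <- vapply(Filter(function(cl) cl$chrom == ch, config$causal_loci),
                         `[[`, numeric(1), "position")
    n_free <- config$n_snps_per_chrom - length(causal_pos)
    if (n_free < 0) stop("more causal loci than SNPs on chromosome ", ch)
    pos <- sort(unique(c(causal_pos,
                         sample.int(config$chrom_lengths[ch], n_free))))
    while (length(pos) < config$n_snps_per_chrom) {
      pos <- sort(unique(c(pos, sample.int(
        config$chrom_lengths[ch], config$n_snps_per_chrom - length(pos)))))
    }
    map_list[[ch]] <- data.frame(
      snp = sprintf("c%d_%d", ch, pos), chrom = ch, pos = pos,
      stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, map_list)
  m <- nrow(map)

  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, m, replace = TRUE)]
  der <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))

  p_anc <- stats::runif(m, config$anc_freq_range[1], config$anc_freq_range[2])
  for (cl in config$causal_loci) {
    j <- which(map$chrom == cl$chrom & map$pos == cl$position)
    p_anc[j] <- config$sweep_background_freq
  }
  # breed frequencies: Balding-Nichols beta(p(1-F)/F, (1-p)(1-F)/F)
  freq <- matrix(0, config$n_breeds, m)
  for (b in seq_len(config$n_breeds)) {
    if (Fb[b] == 0) {
      freq[b, ] <- p_anc
    } else {
      a <- (1 - Fb[b]) / Fb[b]
      freq[b, ] <- stats::rbeta(m, p_anc * a, (1 - p_anc) * a)
    }
  }

  truth <- NULL
  for (cl in config$causal_loci) {
    j <- which(map$chrom == cl$chrom & map$pos == cl$position)
    stopifnot(length(j) == 1L)
    freq[match(cl$risk_breeds, breeds), j] <- config$sweep_fixation
    truth <- rbind(truth, data.frame(
      locus = cl$id, snp = map$snp[j], chrom = cl$chrom,
      pos = cl$position, risk_allele = der[j],
      sweep_start = max(1, cl$position - cl$sweep_flank_bp),
      sweep_end = min(config$chrom_lengths[cl$chrom],
                      cl$position + cl$sweep_flank_bp),
      risk_breeds = paste(cl$risk_breeds, collapse = ","),
      stringsAsFactors = FALSE))
  }

  # genotypes count the derived allele at this stage
  g <- matrix(stats::rbinom(n_ind * m, 2L, freq[ind_breed_idx, ]),
              n_ind, m)

  # founder-haplotype sweeps
  for (cl in config$causal_loci) {
    flank <- which(map$chrom == cl$chrom &
                   abs(map$pos - cl$position) <= cl$sweep_flank_bp)
    founder <- stats::rbinom(length(flank), 1L, p_anc[flank])
    founder[map$pos[flank] == cl$position] <- 1L  # founder carries risk allele
    rows <- which(ind_breed_idx %in% match(cl$risk_breeds, breeds))
    nf <- length(flank); nr <- length(rows)
    bg <- freq[ind_breed_idx[rows], flank, drop = FALSE]
    fo <- matrix(founder, nr, nf, byrow = TRUE)
    copy <- function() {
      esc <- matrix(stats::runif(nr * nf) < config$sweep_leak, nr, nf)
      out <- fo
      out[esc] <- stats::rbinom(sum(esc), 1L, bg[esc])
      out
    }
    g[rows, flank] <- copy() + copy()
  }

  if (config$missing_rate > 0) {
    g[stats::runif(n_ind * m) < config$missing_rate] <- NA_integer_
  }

  # orient to cohort minor allele; ties go to the lexicographically smaller
  # code and never-observed alleles get the PLINK placeholder "0", matching
  # the reader's convention so write/read round-trips are exact
  n_obs <- colSums(!is.na(g))
  c_der <- colSums(g, na.rm = TRUE)
  c_ref <- 2 * n_obs - c_der
  a1 <- der; a2 <- ref
  flip <- c_der > c_ref | (c_der == c_ref & ref < der)
  a1[flip] <- ref[flip]; a2[flip] <- der[flip]
  g[, flip] <- 2 - g[, flip, drop = FALSE]
  mono_der <- c_der == 0 & n_obs > 0    # derived never seen
  mono_ref <- c_ref == 0 & n_obs > 0    # reference never seen
  a1[mono_der] <- "0"; a2[mono_der] <- ref[mono_der]
  a1[mono_ref] <- "0"; a2[mono_ref] <- der[mono_ref]
  a1[n_obs == 0] <- "0"; a2[n_obs == 0] <- "0"
  map$allele1 <- a1
  map$allele2 <- a2
  rownames(map) <- NULL
  dimnames(g) <- list(ind, map$snp)

  ds <- genotype_dataset(ind, breed_of, map, g)
  if (!is.null(truth)) rownames(truth) <- NULL
  attr(ds, "truth") <- truth
  ds
}

#' Simulate breed stereotype scores
#'
#' Breed trait value = sum over causal loci of
#' `effect_weight * breed risk-allele frequency` + `Normal(0, trait_noise_sd)`
#' noise, clipped to `config$clip_range`. Every one of the nine C-BARQ traits
#' receives a value; traits with no causal weight are pure noise.
#'
#' @param dataset a [genotype_dataset()] produced by
#'   [simulate_breed_genotypes()] with the same `config`.
#' @param config the [sim_config()] used for the dataset.
#' @param traits trait names (default [cbarq_traits()]).
#' @return a [stereotype_table()].
#' @export
simulate_stereotypes <- function(dataset, config, traits = cbarq_traits()) {
  set.seed(config$seed + 1013L)
  breeds <- sort(unique(dataset_breeds(dataset)))
  vals <- matrix(stats::rnorm(length(breeds) * length(traits),
                              0, config$trait_noise_sd),
                 length(breeds), length(traits),
                 dimnames = list(breeds, traits))
  truth <- attr(dataset, "truth")
  for (i in seq_along(config$causal_loci)) {
    cl <- config$causal_loci[[i]]
    tr <- truth[truth$locus == cl$id, ]
    f <- risk_allele_frequency(dataset, tr$snp, tr$risk_allele)[breeds]
    for (t in names(cl$effect_weights)) {
      if (!t %in% traits) stop("effect weight names unknown trait: ", t)
      vals[, t] <- vals[, t] + cl$effect_weights[[t]] * f
    }
  }
  vals <- pmin(pmax(vals, config$clip_range[1]), config$clip_range[2])
  stereotype_table(breeds, vals, allow_negative = any(vals < 0))
}

#' Per-breed frequency of a named allele at one SNP
#'
#' Missing genotypes are excluded from the denominator.
#' @param dataset a `GenotypeDataset`.
#' @param snp SNP id.
#' @param allele allele code; must be one of the SNP's two alleles.
#' @return named numeric vector, one frequency per breed.
#' @export
risk_allele_frequency <- function(dataset, snp, allele) {
  j <- match(snp, dataset$snp_map$snp)
  if (is.na(j)) stop("unknown SNP: ", snp)
  g <- dataset$genotypes[, j]
  if (allele == dataset$snp_map$allele2[j]) g <- 2 - g
  else if (allele != dataset$snp_map$allele1[j])
    stop("allele ", allele, " is not an allele of ", snp)
  br <- dataset_breeds(dataset)
  cnt <- tapply(g, br, function(x) sum(x, na.rm = TRUE))
  den <- tapply(g, br, function(x) 2 * sum(!is.na(x)))
  out <- stats::setNames(as.numeric(cnt / den), names(cnt))
  out[den == 0] <- NA_real_
  out
}

#' Canned test fixture with planted truth
#'
#' A small, fully reproducible instance of the simulator's default study
#' conditions: 12 breeds of 12 dogs, 5 chromosomes of 12 Mb with 400 SNPs
#' each, Balding-Nichols divergence F = 0.2, and one planted sweep (1 Mb
#' flanks, risk allele near-fixed in 3 carrier breeds) whose risk-allele
#' frequency drives two stereotype traits (weights 1.0 and 0.8) over breed
#' noise SD 0.1.
#'
#' @param seed integer seed.
#' @param n_causal 0 or 1 planted causal loci (0 gives a null fixture).
#' @return list with elements `dataset`, `stereotypes`, `truth` (data.frame of
#'   the planted causal loci), and `config`.
#' @export
make_fixture <- function(seed = 1L, n_causal = 1L) {
  loci <- list()
  if (n_causal >= 1L) {
    loci <- list(causal_locus(
      chrom = 3, position = 6e6, risk_breeds = sim_breed_ids(12)[1:3],
      sweep_flank_bp = 1e6,
      effect_weights = c(stranger_directed_aggression = 1.0,
                         stranger_oriented_fear = 0.8)))
  }
  cfg <- sim_config(causal_loci = loci, seed = seed)
  ds <- simulate_breed_genotypes(cfg)
  st <- simulate_stereotypes(ds, cfg)
  list(dataset = ds, stereotypes = st,
       truth = attr(ds, "truth"), config = cfg)
}

#' Canned prediction-study fixture
#'
#' A larger panel shaped for the breed-frequency prediction workflow: 24
#' breeds of 8 dogs, 3 chromosomes of 10 Mb with 250 SNPs each, and two
#' planted sweeps whose risk-allele frequencies drive all nine stereotype
#' traits (weights 0.6-1.0, breed noise SD 0.1). Carrier breeds of both loci
#' are present in the training and in the held-out thirds, as in a real
#' cross-panel prediction where the mapped alleles segregate on both sides.
#' The candidate marker set is the two causal SNPs plus five random null
#' SNPs, echoing a small handful of discovery markers.
#'
#' @param seed integer seed.
#' @param n_null_markers null SNPs added to the candidate set (default 5).
#' @return list with `dataset`, `stereotypes`, `truth`, `config`, `markers`,
#'   `train_breeds`, `test_breeds`.
#' @export
make_prediction_fixture <- function(seed = 1L, n_null_markers = 5L) {
  b <- sim_breed_ids(24)
  loci <- list(
    causal_locus(1, 5e6, b[c(1, 2, 3, 17, 18)], 8e5,
                 c(stranger_directed_aggression = 1.0,
                   owner_directed_aggression = 0.7,
                   stranger_oriented_fear = 0.9, dog_rivalry = 0.6)),
    causal_locus(2, 3e6, b[c(5, 6, 19, 20)], 8e5,
                 c(dog_directed_aggression = 0.8, nonsocial_fear = 1.0,
                   touch_sensitivity = 0.6, dog_oriented_fear = 0.9,
                   separation_related_anxiety = 0.7)))
  cfg <- sim_config(n_breeds = 24, dogs_per_breed = 8,
                    n_snps_per_chrom = 250, chrom_lengths = rep(10e6, 3),
                    causal_loci = loci, seed = seed)
  ds <- simulate_breed_genotypes(cfg)
  st <- simulate_stereotypes(ds, cfg)
  truth <- attr(ds, "truth")
  set.seed(seed + 2027L)
  markers <- c(truth$snp,
               sample(setdiff(ds$snp_map$snp, truth$snp), n_null_markers))
  list(dataset = ds, stereotypes = st, truth = truth, config = cfg,
       markers = markers, train_breeds = b[1:16], test_breeds = b[17:24])
}
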