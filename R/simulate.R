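#' Simulation configuration for the synthetic caribou-like study
#'
#' Bundles every knob of the synthetic-data generator: an admixed cohort of
#' diploid individuals genotyped at biallelic SNPs (Balding--Nichols
#' divergence between ancestral populations), a liability-scale migration
#' phenotype with both ancestry and sparse causal-locus effects, and daily
#' GPS tracks for migrant and resident animals.
#'
#' Defaults emulate the study design the pipeline targets: ~190 individuals
#' drawn from 2 ancestral populations, ~28K SNPs, per-individual admixture
#' proportions from a symmetric Dirichlet, a minority of causal loci, and
#' one-fix-per-day year-long tracks with a ~50 km seasonal range separation.
#'
#' @param n_individuals number of diploid individuals
#' @param n_snps number of biallelic SNPs
#' @param k_true number of ancestral populations
#' @param fst_divergence Balding--Nichols divergence per population, in (0,1);
#'   recycled to length `k_true`
#' @param q_alpha symmetric Dirichlet concentration for admixture proportions
#' @param n_causal number of causal SNPs on the migration liability
#' @param causal_effect liability-scale effect per alternate allele
#' @param ancestry_effect liability-scale coefficient on the first ("north")
#'   ancestry proportion
#' @param intercept liability-scale baseline
#' @param migration_distance_km separation of seasonal range centers (km)
#' @param departure_day,return_day day-of-year means of spring departure and
#'   autumn return
#' @param transition_sd_days jitter (sd, days) of departure/return timing
#' @param transition_scale_days logistic time scale (days) of the range switch
#' @param step_sd_km daily positional noise (sd, km) around the active center
#' @param n_years monitoring years per animal
#' @param missing_fix_rate fraction of days without a fix, in [0,1)
#' @param io_beta_migrant,io_beta_resident Beta shape pairs for directly
#'   simulated overlap indices of migrants and residents
#' @param seed RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_individuals = 190L, n_snps = 28000L, k_true = 2L,
                       fst_divergence = 0.15, q_alpha = 0.5,
                       n_causal = 50L, causal_effect = 0.15,
                       ancestry_effect = 1.8, intercept = -0.9,
                       migration_distance_km = 50, departure_day = 150,
                       return_day = 290, transition_sd_days = 5,
                       transition_scale_days = 5, step_sd_km = 5,
                       n_years = 1L, missing_fix_rate = 0,
                       io_beta_migrant = c(2, 8), io_beta_resident = c(8, 2),
                       seed = 1L) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps), k_true = as.integer(k_true),
              fst_divergence = rep_len(fst_divergence, k_true),
              q_alpha = q_alpha, n_causal = as.integer(n_causal),
              causal_effect = causal_effect, ancestry_effect = ancestry_effect,
              intercept = intercept,
              migration_distance_km = migration_distance_km,
              departure_day = departure_day, return_day = return_day,
              transition_sd_days = transition_sd_days,
              transition_scale_days = transition_scale_days,
              step_sd_km = step_sd_km, n_years = as.integer(n_years),
              missing_fix_rate = missing_fix_rate,
              io_beta_migrant = io_beta_migrant,
              io_beta_resident = io_beta_resident,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_individuals", "n_snps", "k_true", "n_causal", "n_years")
  for (nm in counts)
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L)
      stopf("configuration error: %s must be a count >= 1", nm)
  if (any(!is.finite(cfg$fst_divergence)) ||
      any(cfg$fst_divergence <= 0) || any(cfg$fst_divergence >= 1))
    stopf("configuration error: fst_divergence must lie in (0,1)")
  if (cfg$missing_fix_rate < 0 || cfg$missing_fix_rate >= 1)
    stopf("configuration error: missing_fix_rate must lie in [0,1)")
  if (cfg$migration_distance_km <= 0)
    stopf("configuration error: migration_distance_km must be > 0")
  invisible(cfg)
}

#' Draw ancestral allele frequencies under the Balding--Nichols model
#'
#' For each locus a base frequency p ~ Uniform(0.05, 0.95) is drawn, and
#' population k receives a frequency from
#' Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k), so the divergence parameter F_k is
#' the expected Weir--Cockerham F_ST between that population and the base --
#' a known target for the downstream estimator.
#'
#' @param n_snps number of loci
#' @param k_true number of populations
#' @param fst_divergence divergence per population (recycled)
#' @param seed RNG seed
#' @return a `k_true` x `n_snps` matrix of frequencies in (0,1), with the
#'   base frequencies attached as attribute `"base_freq"`
#' @export
simulate_ancestral_freqs <- function(n_snps, k_true, fst_divergence, seed = 1L) {
  if (n_snps < 1) stopf("configuration error: n_snps must be >= 1")
  fst <- rep_len(fst_divergence, k_true)
  if (any(!is.finite(fst)) || any(fst <= 0) || any(fst >= 1))
    stopf("configuration error: fst_divergence values must lie in (0,1)")
  set.seed(seed)
  p <- runif(n_snps, 0.05, 0.95)
  F <- matrix(NA_real_, k_true, n_snps)
  for (k in seq_len(k_true)) {
    a <- p * (1 - fst[k]) / fst[k]
    b <- (1 - p) * (1 - fst[k]) / fst[k]
    F[k, ] <- rbeta(n_snps, a, b)
  }
  # guard against numerically fixed loci
  F <- pmin(pmax(F, 1e-6), 1 - 1e-6)
  attr(F, "base_freq") <- p
  F
}

#' Draw admixture proportions from a symmetric Dirichlet
#'
#' @param n_individuals number of individuals
#' @param k_true number of ancestral populations
#' @param q_alpha symmetric Dirichlet concentration
#' @param seed RNG seed
#' @return an `n_individuals` x `k_true` matrix with rows summing to 1
#' @export
simulate_admixture_q <- function(n_individuals, k_true, q_alpha = 0.5, seed = 1L) {
  set.seed(seed)
  rdirichlet(n_individuals, rep(q_alpha, k_true))
}

#' Sample genotypes given ancestral frequencies and admixture proportions
#'
#' Genotype of individual i at locus j is Binomial(2, pi_ij) with
#' pi_ij = sum_k Q_ik F_kj -- the standard admixture sampling model matched
#' by the likelihood the admixture fitter maximises.
#'
#' @param F k x m ancestral frequency matrix
#' @param Q n x k admixture proportion matrix (rows sum to 1)
#' @param seed RNG seed
#' @return a `genotype_matrix` (see [genotype_matrix()]) with no missing calls
#' @export
simulate_genotypes <- function(F, Q, seed = 1L) {
  if (ncol(Q) != nrow(F))
    stopf("input error: Q has %d columns but F has %d rows", ncol(Q), nrow(F))
  if (any(abs(rowSums(Q) - 1) > 1e-8))
    stopf("input error: Q rows must sum to 1")
  set.seed(seed)
  pi <- Q %*% F
  n <- nrow(Q); m <- ncol(F)
  g <- matrix(rbinom(n * m, 2L, pi), n, m)
  ids <- sprintf("ind_%03d", seq_len(n))
  # contiguous blocks of loci per synthetic contig, positions increasing,
  # so column j of the matrix is column j of F
  per_chrom <- ceiling(m / 10)
  chrom_idx <- ((seq_len(m) - 1L) %/% per_chrom) + 1L
  pos_within <- ave(seq_len(m), chrom_idx, FUN = seq_along)
  loci <- data.frame(chrom = sprintf("chr%d", chrom_idx),
                     pos = 1000L * pos_within,
                     id = sprintf("snp_%05d", seq_len(m)),
                     ref = "A", alt = "T", stringsAsFactors = FALSE)
  genotype_matrix(g, loci, ids)
}

#' Simulate migration phenotypes on the liability scale
#'
#' Liability l_i = intercept + ancestry_effect * Q_i1 +
#' sum_c effect_c * (g_ic - 2 f_c), with causal dosages centered at their
#' sample mean so the intercept controls cohort prevalence; the migrant
#' indicator is Bernoulli(logistic(l_i)). A directly simulated
#' overlap index (IO) is drawn from Beta(2,8) for migrants and Beta(8,2) for
#' residents (means 0.2 / 0.8), mirroring range overlap being low for
#' migrants; the movement module can also derive IO from the simulated tracks.
#'
#' @param geno a `genotype_matrix`
#' @param Q admixture proportions (column 1 = "north" ancestry)
#' @param config a [sim_config()]
#' @param causal_idx indices of causal loci (defaults drawn reproducibly)
#' @param seed RNG seed
#' @return list with `status` (0/1 migrant), `io`, `liability`, `causal_idx`,
#'   `causal_effects`
#' @export
simulate_phenotypes <- function(geno, Q, config, causal_idx = NULL, seed = 1L) {
  g <- geno$g
  set.seed(seed)
  if (is.null(causal_idx))
    causal_idx <- sort(sample.int(ncol(g), min(config$n_causal, ncol(g))))
  if (any(causal_idx < 1L | causal_idx > ncol(g)) || anyDuplicated(causal_idx))
    stopf("input error: causal indices must be unique and within the locus range")
  eff <- rep_len(config$causal_effect, length(causal_idx))
  gc <- g[, causal_idx, drop = FALSE]
  gc <- sweep(gc, 2, colMeans(gc, na.rm = TRUE))
  liab <- config$intercept + config$ancestry_effect * Q[, 1L] +
    as.vector(gc %*% eff)
  status <- rbinom(length(liab), 1L, plogis(liab))
  io <- ifelse(status == 1L,
               rbeta(length(liab), config$io_beta_migrant[1], config$io_beta_migrant[2]),
               rbeta(length(liab), config$io_beta_resident[1], config$io_beta_resident[2]))
  list(status = status, io = io, liability = liab,
       causal_idx = causal_idx, causal_effects = eff)
}

#' Simulate a daily GPS track for one animal
#'
#' Daily positions are the active seasonal center plus isotropic Gaussian
#' noise. Residents hold one center; migrants move between a winter center at
#' the origin and a summer center `migration_distance_km` due north, switching
#' along a logistic schedule around jittered departure and return days (the
#' schedule guarantees more than 30 days on the second range under the default
#' timing). Fixes are daily at 12:00 UTC, starting 1 January, with days
#' dropped independently at `missing_fix_rate`.
#'
#' @param status `"migrant"` or `"resident"` (or 1/0)
#' @param config a [sim_config()]
#' @param animal_id id string for the track
#' @param seed RNG seed
#' @param start_year first calendar year of monitoring
#' @return a `telemetry_track`
#' @export
simulate_track <- function(status, config, animal_id = "animal_1", seed = 1L,
                           start_year = 2018L) {
  validate_sim_config(config)
  migrant <- if (is.character(status)) status == "migrant" else as.logical(status)
  set.seed(seed)
  t0 <- as.Date(sprintf("%d-01-01", start_year))
  days <- seq(t0, by = "day", length.out = 365L * config$n_years)
  nt <- length(days)
  d <- config$migration_distance_km
  if (migrant) {
    doy <- as.POSIXlt(days)$yday + 1
    yr <- as.POSIXlt(days)$year
    w <- numeric(nt)
    for (y in unique(yr)) {
      sel <- yr == y
      dep <- rnorm(1, config$departure_day, config$transition_sd_days)
      ret <- rnorm(1, config$return_day, config$transition_sd_days)
      s <- config$transition_scale_days
      w[sel] <- plogis((doy[sel] - dep) / s) * (1 - plogis((doy[sel] - ret) / s))
    }
    cx <- rep(0, nt); cy <- w * d
  } else {
    cx <- rep(0, nt); cy <- rep(0, nt)
  }
  x <- cx + rnorm(nt, 0, config$step_sd_km)
  y <- cy + rnorm(nt, 0, config$step_sd_km)
  keep <- runif(nt) >= config$missing_fix_rate
  ts <- as.POSIXct(paste(days, "12:00:00"), tz = "UTC")
  telemetry_track(animal_id,
                  data.frame(timestamp = ts[keep], x = x[keep], y = y[keep]),
                  crs = "synthetic-plane-km")
}

#' Simulate a full synthetic study in memory
#'
#' Draws ancestral frequencies, admixture proportions, genotypes, migration
#' phenotypes and one GPS track per animal, and returns everything together
#' with the ground truth needed by the tests.
#'
#' @param config a [sim_config()]
#' @return list with `geno`, `Q`, `F`, `phenotypes`, `tracks`, `truth`
#' @export
simulate_dataset <- function(config = sim_config()) {
  validate_sim_config(config)
  F <- simulate_ancestral_freqs(config$n_snps, config$k_true,
                                config$fst_divergence,
                                seed = derive_seed(config$seed, "freqs"))
  Q <- simulate_admixture_q(config$n_individuals, config$k_true, config$q_alpha,
                            seed = derive_seed(config$seed, "admixture"))
  geno <- simulate_genotypes(F, Q, seed = derive_seed(config$seed, "genotypes"))
  phen <- simulate_phenotypes(geno, Q, config,
                              seed = derive_seed(config$seed, "phenotypes"))
  tracks <- lapply(seq_len(config$n_individuals), function(i) {
    simulate_track(phen$status[i], config, animal_id = geno$ids[i],
                   seed = derive_seed(config$seed, paste0("track", i)))
  })
  names(tracks) <- geno$ids
  truth <- data.frame(animal_id = geno$ids, Q, migrant = phen$status,
                      io = phen$io, check.names = FALSE)
  names(truth)[2:(1 + config$k_true)] <- paste0("Q", seq_len(config$k_true))
  list(geno = geno, Q = Q, F = F, phenotypes = phen, tracks = tracks,
       truth = truth, config = config)
}

#' Write a synthetic fixture set to disk
#'
#' Writes a VCF v4.2 (GT only), a telemetry CSV in the pipeline's input
#' schema, a ground-truth TSV and a YAML echo of the configuration. Output is
#' byte-identical across runs at a fixed seed.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return invisibly, the list of file paths written
#' @export
write_fixture_set <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stopf("I/O failure: cannot create directory %s", dir)
  sim <- simulate_dataset(config)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                telemetry = file.path(dir, "telemetry.csv"),
                truth = file.path(dir, "truth.tsv"),
                config = file.path(dir, "config.yaml"))
  write_vcf(sim$geno, paths$vcf)
  tel <- do.call(rbind, lapply(sim$tracks, function(tr) {
    data.frame(animal_id = tr$animal_id,
               timestamp = format(tr$fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
               x_km = tr$fixes$x, y_km = tr$fixes$y, crs = tr$crs)
  }))
  write.csv(tel, paths$telemetry, row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$causal_idx <- paste(sim$phenotypes$causal_idx, collapse = ",")
  write.table(truth, paths$truth, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(yaml::as.yaml(unclass(config)), paths$config)
  invisible(paths)
}
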