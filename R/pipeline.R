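#' Default pipeline configuration
#'
#' All thresholds default to the values the analysis is built around:
#' call rate 0.90, MAF 0.05, HWE 0.001, LD pruning 50/5/0.5, individual
#' missingness 0.85, residence bound 30 days, 95% isopleths, 30 locations
#' per season, 5-fold CV over K, Bonferroni alpha 0.05, 2 kb promoters.
#'
#' @param ... overrides of the defaults
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    telemetry = NULL, vcf = NULL, gene_table = NULL, out_dir = "migragen_out",
    call_rate = 0.90, maf = 0.05, hwe_p = 0.001,
    ld_window = 50L, ld_step = 5L, ld_r2 = 0.5,
    max_missingness = 0.85,
    min_locations = 30L, isopleth_level = 0.95, max_gap_days = 1L,
    n_candidate_days = 60L, candidate_step = 5L,
    k_range = 1:4, cv_folds = 5L,
    bonferroni_alpha = 0.05, promoter_bp = 2000L,
    seed = 1L)
  ov <- list(...)
  bad_range <- function(x, lo, hi) !is.null(x) && (x < lo || x > hi)
  cfg[names(ov)] <- ov
  if (bad_range(cfg$call_rate, 0, 1) || bad_range(cfg$maf, 0, 0.5) ||
      bad_range(cfg$isopleth_level, 0, 1))
    stopf("configuration error: threshold out of range")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file; keys as in [pipeline_config()]
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_stage <- function(obj, dir, name) {
  path <- file.path(dir, name)
  if (is.data.frame(obj))
    write.table(obj, path, sep = "\t", row.names = FALSE, quote = FALSE)
  else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  path
}

stage_manifest <- function(dir, inputs, config) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(unlist(inputs))) else list()
  jsonlite::write_json(list(inputs = hashes, config = unclass(config),
                            files = list.files(dir)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Stages run in order telemetry -> movement -> popgen -> association ->
#' ancestry; each writes its TSVs/JSON and a manifest with input hashes into
#' a subdirectory of `config$out_dir`. Rerunning with unchanged inputs and
#' seed is byte-identical. A missing gene table skips annotation with a
#' warning; a stage failure halts with the stage name.
#'
#' @param config a `pipeline_config` (or path to its YAML)
#' @return invisibly, a list of per-stage results
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  ## telemetry + movement
  res$movement <- stage("movement", {
    tracks <- lapply(read_telemetry(config$telemetry), thin_daily)
    sdir <- file.path(out, "movement")
    dir.create(sdir, showWarnings = FALSE)
    io_screen <- screen_for_io(tracks, config$min_locations)
    write_stage(io_screen, sdir, "io_screen.tsv")
    io_rows <- list()
    for (tr in tracks) {
      el <- io_screen[io_screen$animal_id == tr$animal_id & io_screen$eligible, ]
      if (!nrow(el)) next
      ios <- vapply(el$season_year, function(y) {
        se <- assign_seasons(as.Date(tr$fixes$timestamp, tz = "UTC"))
        s <- tr$fixes[which(se$season == "summer" & se$season_year == y), c("x", "y")]
        w <- tr$fixes[which(se$season == "winter" & se$season_year == y), c("x", "y")]
        seasonal_overlap(s, w, config$isopleth_level)$io
      }, numeric(1))
      io_rows[[tr$animal_id]] <- data.frame(animal_id = tr$animal_id,
                                            io = mean(ios), n_years = length(ios))
    }
    io_tab <- do.call(rbind, io_rows)
    write_stage(io_tab, sdir, "io.tsv")
    cls <- classify_cohort(tracks, config$max_gap_days,
                           config$n_candidate_days, config$candidate_step)
    write_stage(cls, sdir, "classification.tsv")
    stage_manifest(sdir, config$telemetry, config)
    list(io = io_tab, classification = cls)
  })

  ## popgen
  res$popgen <- stage("popgen", {
    geno <- read_vcf(config$vcf)
    sdir <- file.path(out, "popgen")
    dir.create(sdir, showWarnings = FALSE)
    ind <- apply_individual_filters(geno, config$max_missingness)
    loc <- apply_locus_filters(ind$geno, config$call_rate, config$maf,
                               hwe_p = NULL)
    keep_ld <- ld_prune(loc$geno, config$ld_window, config$ld_step, config$ld_r2)
    ld_set <- subset_geno(loc$geno, j = keep_ld)           # relatedness set
    hwe <- apply_locus_filters(ld_set, call_rate = 0, maf = 0,
                               hwe_p = config$hwe_p)
    neutral <- hwe$geno                                     # structure set
    report <- rbind(ind$report, loc$report,
                    data.frame(rule = "ld_prune", threshold = config$ld_r2,
                               n_before = ncol(loc$geno$g),
                               n_removed = ncol(loc$geno$g) - length(keep_ld),
                               n_after = length(keep_ld)),
                    hwe$report[hwe$report$rule == "hwe", ])
    write_stage(report, sdir, "filter_report.tsv")
    K <- compute_grm(ld_set)
    pca <- pca_genotypes(neutral)
    cv <- cross_validate_k(neutral, config$k_range, config$cv_folds,
                           seed = derive_seed(config$seed, "cv"))
    adm <- fit_admixture(neutral, cv$selected_k,
                         seed = derive_seed(config$seed, "admixture"))
    cl <- assign_clusters(adm)
    qt <- data.frame(animal_id = neutral$ids, adm$Q, cluster = cl$cluster)
    write_stage(qt, sdir, "admixture_q.tsv")
    write_stage(data.frame(animal_id = neutral$ids,
                           pca$vectors[, 1:min(5, ncol(pca$vectors))]),
                sdir, "pca_eigenvectors.tsv")
    fst <- if (length(unique(cl$cluster)) >= 2 && all(table(cl$cluster) >= 2))
      fst_between(neutral, cl$cluster, n_boot = 1000L,
                  seed = derive_seed(config$seed, "fst")) else NULL
    if (!is.null(fst))
      write_stage(list(fst = fst$estimate, ci = fst$ci, method = fst$method),
                  sdir, "fst.json")
    stage_manifest(sdir, config$vcf, config)
    list(geno_neutral = neutral, geno_ld = ld_set, grm = K, pca = pca,
         cv = cv, admixture = adm, clusters = cl, fst = fst,
         filter_report = report)
  })

  ## association
  res$assoc <- stage("association", {
    sdir <- file.path(out, "assoc")
    dir.create(sdir, showWarnings = FALSE)
    mv <- res$movement; pg <- res$popgen
    cls <- mv$classification
    keep <- cls$class %in% c("migrant", "resident")
    pheno <- data.frame(animal_id = cls$animal_id[keep],
                        nsd_class = as.integer(cls$class[keep] == "migrant"))
    pheno <- merge(pheno, mv$io, by = "animal_id", all.x = TRUE)
    common <- intersect(pheno$animal_id, pg$geno_ld$ids)
    pheno <- pheno[match(common, pheno$animal_id), ]
    gidx <- match(common, pg$geno_ld$ids)
    gsub <- subset_geno(pg$geno_ld, i = gidx)
    Ksub <- pg$grm[gidx, gidx]
    scans <- list()
    for (ph in c("io", "nsd_class")) {
      y <- pheno[[ph]]
      ok <- !is.na(y)
      if (sum(ok) < 10 || sd(y[ok]) == 0) next
      scan <- association_scan(subset_geno(gsub, i = which(ok)), y[ok],
                               Ksub[ok, ok], alpha = config$bonferroni_alpha)
      if (!is.null(config$gene_table)) {
        genes <- read.delim(config$gene_table, stringsAsFactors = FALSE)
        scan$results$annotation <- annotate_snps(scan$results, genes,
                                                 config$promoter_bp)
      } else warnf("no gene table supplied; annotation stage skipped")
      write_stage(scan$results, sdir, paste0("assoc_", ph, ".tsv"))
      scans[[ph]] <- scan
    }
    write_stage(lapply(scans, `[[`, "lambda_gc"), sdir, "lambda_gc.json")
    stage_manifest(sdir, c(config$telemetry, config$vcf), config)
    scans
  })

  ## ancestry regressions
  res$ancestry <- stage("ancestry", {
    sdir <- file.path(out, "ancestry")
    dir.create(sdir, showWarnings = FALSE)
    pg <- res$popgen; mv <- res$movement
    qtab <- data.frame(animal_id = pg$geno_neutral$ids, q = pg$admixture$Q[, 1])
    io <- merge(mv$io, qtab, by = "animal_id")
    rows <- list()
    if (nrow(io) >= 3 && sd(io$q) > 0)
      rows$io <- regress_io_on_q(io$io, io$q)
    cls <- mv$classification
    st <- merge(data.frame(animal_id = cls$animal_id,
                           status = as.integer(cls$class == "migrant"))[
                             cls$class %in% c("migrant", "resident"), ],
                qtab, by = "animal_id")
    if (length(unique(st$status)) == 2 && sd(st$q) > 0)
      rows$status <- suppressWarnings(regress_migrant_on_q(st$status, st$q))
    tab <- do.call(rbind, rows)
    write_stage(tab, sdir, "ancestry_regressions.tsv")
    stage_manifest(sdir, character(), config)
    tab
  })
  invisible(res)
}
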