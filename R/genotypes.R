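#' Construct a genotype matrix container
#'
#' Individuals x loci dosages of the alternate allele in {0, 1, 2, NA}, with
#' per-locus metadata. This is the container every popgen and association
#' stage consumes.
#'
#' @param g integer matrix, individuals x loci, values 0/1/2/NA
#' @param loci data.frame with columns chrom, pos, id, ref, alt
#' @param ids character vector of individual ids
#' @return an object of class `genotype_matrix`
#' @export
genotype_matrix <- function(g, loci = NULL, ids = NULL) {
  g <- as.matrix(g)
  if (!all(g %in% c(0L, 1L, 2L, NA)))
    stopf("input error: genotypes must be 0, 1, 2 or missing")
  if (is.null(ids)) ids <- rownames(g) %||% sprintf("ind_%03d", seq_len(nrow(g)))
  if (is.null(loci))
    loci <- data.frame(chrom = "chr1", pos = seq_len(ncol(g)),
                       id = sprintf("snp_%05d", seq_len(ncol(g))),
                       ref = "A", alt = "T", stringsAsFactors = FALSE)
  if (nrow(loci) != ncol(g))
    stopf("input error: loci table has %d rows for %d loci", nrow(loci), ncol(g))
  if (any(loci$pos < 0)) stopf("input error: negative positions")
  dimnames(g) <- list(ids, loci$id)
  structure(list(g = g, loci = loci, ids = ids), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d loci (%.2f%% missing)\n",
              nrow(x$g), ncol(x$g), 100 * mean(is.na(x$g))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$g)

#' Per-locus minor allele frequency
#'
#' The alternate-allele frequency folded to [0, 0.5]; missing calls are
#' excluded per locus.
#'
#' @param geno a `genotype_matrix` or plain dosage matrix
#' @return numeric vector of MAFs
#' @export
locus_maf <- function(geno) {
  g <- if (inherits(geno, "genotype_matrix")) geno$g else geno
  f <- colMeans(g, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Per-locus alternate allele frequency
#' @param geno a `genotype_matrix` or matrix
#' @return numeric vector of alternate-allele frequencies
#' @export
locus_freq <- function(geno) {
  g <- if (inherits(geno, "genotype_matrix")) geno$g else geno
  colMeans(g, na.rm = TRUE) / 2
}

subset_geno <- function(geno, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(geno$g))
  if (is.null(j)) j <- seq_len(ncol(geno$g))
  genotype_matrix(geno$g[i, j, drop = FALSE], geno$loci[j, , drop = FALSE],
                  geno$ids[i])
}

#' Read a VCF into a genotype matrix
#'
#' Parses the GT field of a biallelic-SNP VCF to 0/1/2 dosages; multiallelic
#' records are skipped with a warning; sample order is preserved.
#'
#' @param path VCF file (v4.2, uncompressed or gzipped)
#' @return a `genotype_matrix`
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi))
    warnf("skipping %d multiallelic record(s)", sum(multi))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  core <- gsub("\\|", "/", gt)
  g <- matrix(NA_integer_, nrow(core), ncol(core))
  g[core == "0/0"] <- 0L
  g[core == "0/1" | core == "1/0"] <- 1L
  g[core == "1/1"] <- 2L
  bad <- !is.na(core) & is.na(g) & core != "./."
  if (any(bad)) warnf("unparseable GT values treated as missing: %d", sum(bad))
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                 paste0(fix$CHROM, "_", fix$POS), fix$ID),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  genotype_matrix(t(g), loci, colnames(gt))
}

#' Write a genotype matrix as a minimal VCF v4.2
#'
#' GT-only biallelic records on the stored contigs; deterministic output so
#' fixture sets are byte-identical across runs.
#'
#' @param geno a `genotype_matrix`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_vcf <- function(geno, path) {
  g <- geno$g; loci <- geno$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", unique(loci$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$ids), collapse = "\t")), con)
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gt[ok] <- code[g[ok] + 1L]
  rows <- paste(loci$chrom, loci$pos, loci$id, loci$ref, loci$alt,
                ".", "PASS", ".", "GT", sep = "\t")
  body <- paste(rows, apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a plain 0/1/2 dosage TSV as a genotype matrix
#'
#' Alternate input to VCF: a TSV with individuals in rows (first column
#' `animal_id` or row names) and loci in columns.
#'
#' @param path TSV file
#' @return a `genotype_matrix`
#' @export
read_geno_tsv <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  idcol <- which(names(d) %in% c("animal_id", "id", "individual"))[1]
  if (!is.na(idcol)) {
    ids <- as.character(d[[idcol]])
    d <- d[, -idcol, drop = FALSE]
  } else ids <- rownames(d)
  genotype_matrix(as.matrix(d), ids = ids)
}

#' Exact test for Hardy--Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value is the total probability of heterozygote configurations no more
#' probable than the observed one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts
#' @return p-value in (0, 1]
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) return(NA_real_)
  n_a <- 2 * n_hom_alt + n_het          # alternate allele count
  n_rare <- min(n_a, 2 * n - n_a)
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(het = h | n, n_rare) up to a constant:
  #   h*log(2) - lgamma terms of the three genotype counts
  lp <- vapply(hets, function(h) {
    hom_rare <- (n_rare - h) / 2
    hom_common <- n - h - hom_rare
    h * log(2) - lgamma(h + 1) - lgamma(hom_rare + 1) - lgamma(hom_common + 1)
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-10)]))
}

#' Apply per-locus quality filters
#'
#' Filters are applied in order: call rate (keep >= `call_rate`), minor
#' allele frequency (keep strictly > `maf`), and optionally the
#' Hardy--Weinberg exact test (keep p >= `hwe_p`). MAF is computed on the
#' current (individual-filtered) matrix.
#'
#' @param geno a `genotype_matrix`
#' @param call_rate minimum fraction of genotyped individuals
#' @param maf strict lower bound on minor allele frequency
#' @param hwe_p minimum HWE exact-test p-value, or `NULL` to skip
#' @return list with the filtered `geno` and a `report` data.frame
#'   (rule, threshold, n_before, n_removed, n_after)
#' @export
apply_locus_filters <- function(geno, call_rate = 0.90, maf = 0.05,
                                hwe_p = NULL) {
  report <- data.frame(rule = character(), threshold = numeric(),
                       n_before = integer(), n_removed = integer(),
                       n_after = integer(), stringsAsFactors = FALSE)
  add <- function(rule, thr, keep) {
    report[nrow(report) + 1L, ] <<-
      list(rule, thr, length(keep), sum(!keep), sum(keep))
  }
  cr <- colMeans(!is.na(geno$g))
  keep <- cr >= call_rate
  add("call_rate", call_rate, keep)
  geno <- subset_geno(geno, j = which(keep))

  mafs <- locus_maf(geno)
  keep <- mafs > maf
  add("maf", maf, keep)
  geno <- subset_geno(geno, j = which(keep))

  if (!is.null(hwe_p)) {
    p <- apply(geno$g, 2, function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_real_)
      hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    })
    keep <- !is.na(p) & p >= hwe_p
    add("hwe", hwe_p, keep)
    geno <- subset_geno(geno, j = which(keep))
  }
  if (ncol(geno$g) == 0) warnf("all loci removed by filters")
  list(geno = geno, report = report)
}

#' Remove individuals with excessive missingness
#'
#' Individuals with missingness strictly greater than `max_missingness`
#' are removed (a per-individual coverage rule would need read data and is
#' out of scope here).
#'
#' @param geno a `genotype_matrix`
#' @param max_missingness inclusive upper bound on the fraction missing
#' @return list with filtered `geno` and a `report` data.frame
#' @export
apply_individual_filters <- function(geno, max_missingness = 0.85) {
  miss <- rowMeans(is.na(geno$g))
  keep <- miss <= max_missingness
  report <- data.frame(rule = "individual_missingness",
                       threshold = max_missingness,
                       n_before = length(keep), n_removed = sum(!keep),
                       n_after = sum(keep), stringsAsFactors = FALSE)
  list(geno = subset_geno(geno, i = which(keep)), report = report)
}

#' Prune loci in linkage disequilibrium
#'
#' Sliding window of `window` loci advancing by `step`; within each window,
#' for any pair with squared genotype correlation above `r2` the locus with
#' the lower MAF is removed (ties: the later position). Deterministic and
#' order-stable.
#'
#' @param geno a `genotype_matrix`, loci ordered by chrom/pos
#' @param window window size in loci
#' @param step window advance in loci
#' @param r2 r-squared threshold
#' @return integer vector of retained locus indices
#' @export
ld_prune <- function(geno, window = 50L, step = 5L, r2 = 0.5) {
  g <- geno$g
  m <- ncol(g)
  if (m <= 1) return(seq_len(m))
  # mean-impute for correlation; constant columns get r = 0
  gi <- apply(g, 2, function(x) {
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  })
  mafs <- locus_maf(geno)
  removed <- logical(m)
  starts <- seq(1L, max(1L, m - 1L), by = step)
  for (s in starts) {
    idx <- s:min(s + window - 1L, m)
    idx <- idx[!removed[idx]]
    if (length(idx) < 2) next
    cc <- suppressWarnings(cor(gi[, idx, drop = FALSE]))
    cc[is.na(cc)] <- 0
    cc2 <- cc^2
    diag(cc2) <- 0
    while (TRUE) {
      hit <- which(cc2 > r2, arr.ind = TRUE)
      if (!nrow(hit)) break
      hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
      a <- idx[hit[1, 1]]; b <- idx[hit[1, 2]]
      drop_locus <- if (mafs[a] < mafs[b]) a
        else if (mafs[b] < mafs[a]) b
        else max(a, b)                      # tie: later position
      removed[drop_locus] <- TRUE
      kpos <- which(idx == drop_locus)
      cc2[kpos, ] <- 0; cc2[, kpos] <- 0
    }
  }
  which(!removed)
}
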