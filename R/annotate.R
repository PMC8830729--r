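#' Annotate SNPs against a gene table
#'
#' Categories: `exon` (inside an exon interval), `intron` (inside a gene
#' body otherwise), `promoter` (within 2,000 bp upstream of a gene start,
#' strand-aware), else `intergenic`; overlaps resolve exon > intron >
#' promoter. The gene table uses 0-based half-open coordinates; SNP
#' positions are 1-based (VCF convention) and are converted internally.
#'
#' @param loci data.frame with columns `chrom`, `pos` (1-based)
#' @param genes BED-like data.frame: `chrom`, `start`, `end` (0-based
#'   half-open), `strand` ("+"/"-"), `gene_name`, `feature` ("gene" or
#'   "exon"); exon rows are sub-intervals of their gene
#' @param promoter_bp upstream window (default 2000, inclusive)
#' @return character vector of annotations, one per locus, with the matched
#'   gene as attribute `"gene"`
#' @export
annotate_snps <- function(loci, genes, promoter_bp = 2000L) {
  need <- c("chrom", "start", "end", "strand", "gene_name", "feature")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stopf("schema error: gene table missing %s",
                          paste(miss, collapse = ", "))
  if (is.unsorted(order(genes$chrom, genes$start))) {
    warnf("gene table unsorted; sorting internally")
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  ex <- genes[genes$feature == "exon", , drop = FALSE]
  gb <- genes[genes$feature != "exon", , drop = FALSE]
  n <- nrow(loci)
  out <- rep("intergenic", n)
  gene_of <- rep(NA_character_, n)
  p0 <- loci$pos - 1L                    # 0-based coordinate of the SNP base
  for (i in seq_len(n)) {
    ch <- loci$chrom[i]
    inexon <- ex$chrom == ch & ex$start <= p0[i] & p0[i] < ex$end
    ingene <- gb$chrom == ch & gb$start <= p0[i] & p0[i] < gb$end
    if (any(inexon)) {
      out[i] <- "exon"; gene_of[i] <- ex$gene_name[which(inexon)[1]]
    } else if (any(ingene)) {
      out[i] <- "intron"; gene_of[i] <- gb$gene_name[which(ingene)[1]]
    } else {
      gch <- gb[gb$chrom == ch, , drop = FALSE]
      if (nrow(gch)) {
        updist <- ifelse(gch$strand == "-", p0[i] - gch$end + 1L,
                         gch$start - p0[i])
        prom <- updist > 0L & updist <= promoter_bp
        if (any(prom)) {
          out[i] <- "promoter"
          gene_of[i] <- gch$gene_name[which(prom)[1]]
        }
      }
    }
  }
  attr(out, "gene") <- gene_of
  out
}
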