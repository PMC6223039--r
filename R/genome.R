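#' Genome table of chromosome sizes (and optional gene counts)
#'
#' @param chrom unique chromosome names.
#' @param size chromosome sizes in bp, > 0.
#' @param gene_count optional per-chromosome gene counts (weights for the
#'   gene-density null).
#' @return A data.frame of class `genome_table`.
#' @export
genome_table <- function(chrom, size, gene_count = NULL) {
  chrom <- as.character(chrom)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (any(size <= 0)) stop("chromosome sizes must be > 0")
  df <- data.frame(chrom = chrom, size = as.numeric(size),
                   stringsAsFactors = FALSE)
  if (!is.null(gene_count)) df$gene_count <- as.numeric(gene_count)
  class(df) <- c("genome_table", "data.frame")
  df
}

#' Mouse (mm10) chromosome sizes
#'
#' Reference chromosome lengths of the GRCm38/mm10 assembly, the genome the
#' HSC peak analyses are defined on. Embedded so that mouse-scale enrichment
#' simulations run without any download.
#'
#' @param include_x include chrX (default `TRUE`).
#' @param include_y include chrY (default `FALSE`: an all-female design has
#'   no Y-linked intervals).
#' @return A [genome_table()].
#' @export
mouse_chrom_sizes <- function(include_x = TRUE, include_y = FALSE) {
  chrom <- paste0("chr", c(1:19, "X", "Y"))
  size <- c(195471971, 182113224, 160039680, 156508116, 151834684,
            149736546, 145441459, 129401213, 124595110, 130694993,
            122082543, 120129022, 120421639, 124902244, 104043685,
            98207768, 94987271, 90702639, 61431566, 171031299, 91744698)
  keep <- rep(TRUE, length(chrom))
  if (!include_x) keep[chrom == "chrX"] <- FALSE
  if (!include_y) keep[chrom == "chrY"] <- FALSE
  genome_table(chrom[keep], size[keep])
}
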