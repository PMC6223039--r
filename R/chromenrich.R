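# Chromosome-level enrichment statistics for peak sets: observed vs expected
# counts under size- or gene-density-proportional nulls, goodness of fit,
# differential-peak overlap logic, and midpoint-based region annotation.

#' Peak table
#'
#' Genomic intervals in 0-based half-open (BED) convention with an optional
#' `direction` column (`"gain"` / `"loss"`). Rows are sorted by (chrom,
#' start).
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`, `direction`.
#' @return A data.frame of class `peak_table`.
#' @export
peak_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (nrow(df) && any(df$start >= df$end))
    stop("all peaks must satisfy start < end (0-based half-open)")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("peak_table", "data.frame")
  df
}

.as_granges <- function(peaks, levels = unique(peaks$chrom)) {
  GenomicRanges::GRanges(
    seqnames = factor(peaks$chrom, levels = levels),
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Observed peak counts per chromosome
#'
#' @param peaks a [peak_table()].
#' @param genome a [genome_table()]; every peak chromosome must appear in it.
#' @return Named integer vector over the genome's chromosomes (zeros
#'   included), summing to `nrow(peaks)`.
#' @export
count_peaks_per_chrom <- function(peaks, genome) {
  stopifnot(inherits(genome, "genome_table"))
  unknown <- setdiff(unique(peaks$chrom), genome$chrom)
  if (length(unknown))
    stop("peaks on chromosomes absent from the genome table: ",
         paste(unknown, collapse = ", "))
  tab <- table(factor(peaks$chrom, levels = genome$chrom))
  setNames(as.integer(tab), genome$chrom)
}

#' Expected peak counts under a weight-proportional null
#'
#' Distributes `total` over chromosomes proportionally to positive weights
#' (chromosome sizes for the size null, gene counts for the gene-density
#' null). Expected counts are real-valued and sum to `total` exactly.
#'
#' @param total total number of peaks (>= 0).
#' @param weights named positive weights per chromosome.
#' @return Named numeric vector of expected counts.
#' @export
expected_counts <- function(total, weights) {
  if (total < 0) stop("total must be >= 0")
  if (any(weights <= 0)) stop("all weights must be > 0")
  total * weights / sum(weights)
}

#' Goodness of fit of observed vs expected chromosome counts
#'
#' Pearson's X^2 = sum (obs - exp)^2 / exp with either the asymptotic
#' chi-square p-value (df = k - 1) or an exact Monte-Carlo p-value from
#' multinomial resampling under the null weights, p = (1 + #\{X^2_sim >=
#' X^2_obs\}) / (1 + n_sim). The `auto` method switches to Monte-Carlo
#' whenever any expected count falls below 5, where the chi-square
#' approximation is unreliable (e.g. ~118 peaks spread over ~20 mouse
#' chromosomes).
#'
#' @param observed named integer counts.
#' @param expected named expected counts on the same keys, summing to the
#'   same total (1e-6 relative tolerance).
#' @param method `"auto"`, `"chi-square"` or `"monte-carlo"`.
#' @param n_sim Monte-Carlo replicates (default 10000).
#' @param seed seed for the Monte-Carlo draw.
#' @return A list of class `gof_test`: `statistic`, `df`, `p_value`,
#'   `method`.
#' @export
goodness_of_fit <- function(observed, expected,
                            method = c("auto", "chi-square", "monte-carlo"),
                            n_sim = 10000L, seed = NULL) {
  method <- match.arg(method)
  if (!setequal(names(observed), names(expected)) ||
      is.null(names(observed)))
    stop("observed and expected must be named over the same chromosomes")
  expected <- expected[names(observed)]
  total <- sum(observed)
  if (abs(sum(expected) - total) > 1e-6 * max(1, total))
    stop("expected counts must sum to the observed total")
  if (any(expected == 0 & observed > 0))
    stop("zero expected count with nonzero observed count: weights must cover all observed chromosomes")
  keep <- expected > 0
  x2 <- sum((observed[keep] - expected[keep])^2 / expected[keep])
  k <- sum(keep)
  if (method == "auto")
    method <- if (any(expected[keep] < 5)) "monte-carlo" else "chi-square"
  if (method == "chi-square") {
    p <- pchisq(x2, df = k - 1, lower.tail = FALSE)
  } else {
    prob <- expected[keep] / total
    sims <- with_seed(seed, rmultinom(n_sim, size = total, prob = prob))
    x2_sim <- colSums((sims - expected[keep])^2 / expected[keep])
    p <- (1 + sum(x2_sim >= x2)) / (1 + n_sim)
  }
  structure(list(statistic = x2, df = k - 1L, p_value = p, method = method,
                 n_sim = if (method == "monte-carlo") n_sim else NA_integer_),
            class = "gof_test")
}

#' @export
print.gof_test <- function(x, ...) {
  cat(sprintf("goodness of fit: X^2 = %.3f, df = %d, p = %.4g (%s)\n",
              x$statistic, x$df, x$p_value, x$method))
  invisible(x)
}

#' Chromosomal enrichment of a peak set
#'
#' Observed per-chromosome counts against the expectation proportional to
#' chromosome size (`weights = "size"`) or gene count (`weights = "genes"`),
#' with per-chromosome enrichment scores (observed / expected) and a
#' goodness-of-fit test.
#'
#' @param peaks a [peak_table()].
#' @param genome a [genome_table()] (with `gene_count` for the gene null).
#' @param weights `"size"` or `"genes"`.
#' @param method,n_sim,seed passed to [goodness_of_fit()].
#' @return A list of class `chrom_enrichment` with a per-chromosome
#'   data.frame (`table`) and the test (`test`).
#' @export
chrom_enrichment <- function(peaks, genome, weights = c("size", "genes"),
                             method = "auto", n_sim = 10000L, seed = NULL) {
  weights <- match.arg(weights)
  w <- switch(weights, size = genome$size, genes = genome$gene_count)
  if (is.null(w) || any(is.na(w)))
    stop("genome table lacks the requested weights")
  w <- setNames(w, genome$chrom)
  obs <- count_peaks_per_chrom(peaks, genome)
  exp_ <- expected_counts(sum(obs), w)
  test <- goodness_of_fit(obs, exp_, method = method, n_sim = n_sim,
                          seed = seed)
  tab <- data.frame(chrom = genome$chrom, observed = as.integer(obs),
                    expected = as.numeric(exp_),
                    enrichment_score = as.numeric(obs / exp_),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, test = test, weights = weights),
            class = "chrom_enrichment")
}

#' @export
print.chrom_enrichment <- function(x, ...) {
  top <- x$table[order(-x$table$enrichment_score), ][1:min(5, nrow(x$table)), ]
  cat(sprintf("chromosomal enrichment (%s null):\n", x$weights))
  print(top, row.names = FALSE)
  print(x$test)
  invisible(x)
}

#' Overlap of two differential peak sets with direction concordance
#'
#' Counts how many peaks of `a` overlap any peak of `b` by at least
#' `min_overlap_bp`, and how many of those share the direction of change
#' with their partner (the first overlapping `b` peak in coordinate order).
#' Each `a` peak is counted once.
#'
#' @param a,b [peak_table()]s with a `direction` column.
#' @param min_overlap_bp minimum shared bp (default 1).
#' @return A list of class `overlap_result`: `n_a`, `n_b`, `n_overlap`,
#'   `n_same_direction`.
#' @export
differential_overlap <- function(a, b, min_overlap_bp = 1L) {
  for (tb in list(a, b))
    if (is.null(tb$direction) || anyNA(tb$direction))
      stop("both peak tables must carry a complete 'direction' column")
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(structure(list(n_a = nrow(a), n_b = nrow(b), n_overlap = 0L,
                          n_same_direction = 0L), class = "overlap_result"))
  }
  lev <- union(unique(a$chrom), unique(b$chrom))
  hits <- GenomicRanges::findOverlaps(.as_granges(a, lev), .as_granges(b, lev),
                                      minoverlap = min_overlap_bp)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  # first partner in coordinate order: b is sorted, so the smallest subject
  # index per query is the first in coordinate order
  first <- tapply(sh, qh, min)
  qa <- as.integer(names(first))
  n_overlap <- length(qa)
  n_same <- sum(a$direction[qa] == b$direction[as.integer(first)])
  structure(list(n_a = nrow(a), n_b = nrow(b), n_overlap = n_overlap,
                 n_same_direction = as.integer(n_same)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("overlap: %d of %d peaks overlap (vs %d), %d with the same direction\n",
              x$n_overlap, x$n_a, x$n_b, x$n_same_direction))
  invisible(x)
}

#' Annotate peaks by genomic category
#'
#' Assigns each peak, by its midpoint, exactly one category with precedence
#' TSS > promoter > gene body > intergenic. The TSS window is +/-
#' `tss_halfwidth` bp around the transcription start (txStart on the +
#' strand, txEnd on the -), the promoter extends `promoter_width` bp
#' upstream of it, and the gene body is the tx interval.
#'
#' @param peaks a [peak_table()].
#' @param genes data.frame with columns `chrom`, `txStart`, `txEnd`,
#'   `strand` (0-based half-open, like BED).
#' @param promoter_width upstream promoter extent in bp (default 1000).
#' @param tss_halfwidth TSS half-window in bp (default 100).
#' @return Named integer vector of counts over `c("TSS", "promoter",
#'   "gene_body", "intergenic")`, summing to `nrow(peaks)`.
#' @export
annotate_peaks <- function(peaks, genes, promoter_width = 1000L,
                           tss_halfwidth = 100L) {
  stopifnot(all(c("chrom", "txStart", "txEnd", "strand") %in% names(genes)))
  cats <- c("TSS", "promoter", "gene_body", "intergenic")
  if (nrow(peaks) == 0L)
    return(setNames(integer(4), cats))
  mid <- peaks$start + (peaks$end - peaks$start) %/% 2L  # 0-based midpoint
  midg <- GenomicRanges::GRanges(peaks$chrom,
                                 IRanges::IRanges(mid + 1L, mid + 1L))
  plus <- genes$strand != "-"
  tss0 <- ifelse(plus, genes$txStart, genes$txEnd - 1L)  # 0-based TSS base
  tss_r <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, tss0 - tss_halfwidth + 1L),
                     tss0 + tss_halfwidth + 1L))
  prom_start0 <- ifelse(plus, genes$txStart - promoter_width, genes$txEnd)
  prom_end0 <- ifelse(plus, genes$txStart, genes$txEnd + promoter_width)
  prom_r <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1L, prom_start0 + 1L), pmax(1L, prom_end0)))
  body_r <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$txStart + 1L, genes$txEnd))
  assign_cat <- rep("intergenic", nrow(peaks))
  in_body <- GenomicRanges::countOverlaps(midg, body_r) > 0
  in_prom <- GenomicRanges::countOverlaps(midg, prom_r) > 0
  in_tss <- GenomicRanges::countOverlaps(midg, tss_r) > 0
  assign_cat[in_body] <- "gene_body"
  assign_cat[in_prom] <- "promoter"
  assign_cat[in_tss] <- "TSS"
  setNames(as.integer(table(factor(assign_cat, levels = cats))), cats)
}
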