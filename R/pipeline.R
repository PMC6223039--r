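# Cohort orchestration: per-cell quantification, group statistics matching
# the reporting conventions (mean + 1 SEM over biological repeats, paired t
# or ANOVA with Bonferroni-gated post tests), CSV reports.

#' Quantification configuration
#'
#' Names the channels of a stack and collects the tunable measurement
#' parameters. Every threshold default is overridable here.
#'
#' @param dapi name of the nuclear (DAPI) channel; required downstream.
#' @param mark name of the histone-mark channel, or `NULL`.
#' @param paint name of the chromosome-paint channel, or `NULL`.
#' @param tau polarity threshold (default 0.7).
#' @param d_prox homolog proximity threshold in um (default 2.0).
#' @param invagination_cutoff solidity cutoff (default 0.92).
#' @param shell_depth peripherality shell depth in um (default 0.5).
#' @param min_nucleus_volume,min_territory_volume object size floors (um^3).
#' @param n_directions polarity lattice size (default 200).
#' @return A list of class `quantify_config`.
#' @export
quantify_config <- function(dapi = "dapi", mark = "mark", paint = "paint",
                            tau = 0.7, d_prox = 2.0,
                            invagination_cutoff = 0.92, shell_depth = 0.5,
                            min_nucleus_volume = 20,
                            min_territory_volume = 0.5,
                            n_directions = 200L) {
  structure(list(dapi = dapi, mark = mark, paint = paint, tau = tau,
                 d_prox = d_prox, invagination_cutoff = invagination_cutoff,
                 shell_depth = shell_depth,
                 min_nucleus_volume = min_nucleus_volume,
                 min_territory_volume = min_territory_volume,
                 n_directions = as.integer(n_directions)),
            class = "quantify_config")
}

#' Quantify one cell
#'
#' Runs segmentation, morphometry, polarity, territory and co-localization
#' measurements on one multi-channel stack. A failure in one measurement
#' records `NA` for its fields (with the reason in the `errors` field)
#' rather than aborting, so a cohort run survives corrupted cells.
#'
#' @param stack a [multichannel_volume()].
#' @param config a [quantify_config()]; the DAPI channel must exist.
#' @param cell_id,group,repeat_id identifiers carried into the record.
#' @return A list of class `cell_record`; `as.data.frame()` yields the
#'   per-cell CSV row.
#' @export
quantify_cell <- function(stack, config = quantify_config(),
                          cell_id = "cell", group = NA_character_,
                          repeat_id = NA_integer_) {
  stopifnot(inherits(stack, "multichannel_volume"),
            inherits(config, "quantify_config"))
  if (!config$dapi %in% stack$channels)
    stop(sprintf("missing DAPI channel '%s'", config$dapi))
  rec <- list(cell_id = cell_id, group = group, repeat_id = repeat_id,
              errors = character(0))
  fail <- function(step, e) {
    rec$errors <<- c(rec$errors, sprintf("%s: %s", step, conditionMessage(e)))
    NULL
  }
  nucleus <- tryCatch(
    segment_nucleus(stack$data[[config$dapi]], stack$grid,
                    min_volume = config$min_nucleus_volume,
                    cell_id = cell_id),
    error = function(e) fail("segmentation", e))
  rec$nucleus <- nucleus
  rec$morphometry <- if (!is.null(nucleus)) tryCatch({
    chans <- stack$data[setdiff(stack$channels, config$dapi)]
    morphometry(nucleus, channels = if (length(chans)) chans else NULL,
                peripherality_channel =
                  if (!is.null(config$mark) && config$mark %in% names(chans))
                    config$mark else NULL,
                invagination_cutoff = config$invagination_cutoff,
                shell_depth = config$shell_depth)
  }, error = function(e) fail("morphometry", e))
  if (!is.null(nucleus) && !is.null(config$mark) &&
      config$mark %in% stack$channels) {
    rec$polarity <- tryCatch(
      epipolarity_score(stack$data[[config$mark]], nucleus,
                        n_directions = config$n_directions),
      error = function(e) fail("polarity", e))
  }
  if (!is.null(nucleus) && !is.null(config$paint) &&
      config$paint %in% stack$channels) {
    terrs <- tryCatch(
      detect_territories(stack$data[[config$paint]], nucleus,
                         min_volume = config$min_territory_volume,
                         channel_name = config$paint),
      error = function(e) fail("territories", e))
    if (!is.null(terrs)) {
      rec$homologs <- classify_proximity(terrs, d_prox = config$d_prox)
      if (length(terrs) >= 1L && !is.null(config$mark) &&
          config$mark %in% stack$channels) {
        rec$colocalization <- tryCatch(
          colocalization_volume(stack$data[[config$mark]], terrs[[1]],
                                nucleus = nucleus),
          error = function(e) fail("colocalization", e))
      }
    }
  }
  class(rec) <- "cell_record"
  rec
}

#' @export
as.data.frame.cell_record <- function(x, ...) {
  m <- x$morphometry
  h <- x$homologs
  p <- x$polarity
  co <- x$colocalization
  data.frame(
    cell_id = x$cell_id, group = x$group, repeat_id = x$repeat_id,
    volume_um3 = if (!is.null(m)) m$volume else NA_real_,
    nsf = if (!is.null(m)) m$nsf else NA_real_,
    solidity = if (!is.null(m)) m$solidity else NA_real_,
    invaginated = if (!is.null(m)) m$invaginated else NA,
    peripherality = if (!is.null(m)) m$peripherality else NA_real_,
    polarity_score = if (!is.null(p)) p$score else NA_real_,
    polar = if (!is.null(p)) classify_polar(p$score) else NA,
    n_objects = if (!is.null(h)) h$n_objects else NA_integer_,
    distance_um = if (!is.null(h)) h$distance else NA_real_,
    proximal = if (!is.null(h)) h$proximal else NA,
    overlap_um3 = if (!is.null(co)) co$overlap_volume else NA_real_,
    overlap_fraction = if (!is.null(co)) co$overlap_fraction_of_territory
      else NA_real_,
    n_errors = length(x$errors),
    stringsAsFactors = FALSE)
}

#' Compare group means
#'
#' Mean + SEM per group with the significance test matching the design: a
#' paired t-test for two groups with a shared repeat structure, otherwise
#' one-way ANOVA; pairwise Bonferroni-adjusted t-tests are computed only
#' when the overall p-value is below 0.05 (the Bonferroni gate), otherwise
#' the pairwise table is empty.
#'
#' @param values numeric measurements.
#' @param group group label per value (2 or more groups).
#' @param repeat_id optional biological repeat per value; when given, tests
#'   run on per-repeat means (repeat = unit of replication).
#' @param design `"auto"` (paired t for two groups with matching repeats,
#'   else ANOVA), `"paired"`, or `"anova"`.
#' @return A list of class `group_comparison`: `summary` (per-group mean,
#'   SEM, n), `test`, `p_value`, `pairwise` (possibly empty data.frame of
#'   Bonferroni-adjusted p-values).
#' @export
compare_groups <- function(values, group, repeat_id = NULL,
                           design = c("auto", "paired", "anova")) {
  design <- match.arg(design)
  keep <- is.finite(values)
  values <- values[keep]
  group <- as.character(group)[keep]
  if (!is.null(repeat_id)) repeat_id <- repeat_id[keep]
  groups <- unique(group)
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (min(table(group)) < 2L) stop("each group needs at least 2 observations")

  # analysis units: per-repeat means when a repeat structure is given
  if (!is.null(repeat_id)) {
    agg <- aggregate(values, by = list(group = group, rep = repeat_id), mean)
    u_val <- agg$x; u_grp <- agg$group; u_rep <- agg$rep
  } else {
    u_val <- values; u_grp <- group; u_rep <- NULL
  }
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- u_val[u_grp == g]
    data.frame(group = g, mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  paired_ok <- length(groups) == 2L && !is.null(u_rep) &&
    setequal(u_rep[u_grp == groups[1]], u_rep[u_grp == groups[2]]) &&
    length(u_val[u_grp == groups[1]]) >= 2L
  if (design == "paired" && !paired_ok)
    stop("paired design requires two groups with an equal repeat structure")
  use_paired <- design == "paired" || (design == "auto" && paired_ok)
  if (use_paired) {
    o1 <- order(u_rep[u_grp == groups[1]])
    o2 <- order(u_rep[u_grp == groups[2]])
    tt <- t.test(u_val[u_grp == groups[1]][o1],
                 u_val[u_grp == groups[2]][o2], paired = TRUE)
    test_name <- "paired-t"
    p_overall <- tt$p.value
  } else {
    fit <- aov(u_val ~ factor(u_grp))
    p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
    if (is.null(p_overall) || !length(p_overall)) p_overall <- NA_real_
    test_name <- "one-way ANOVA"
  }
  pairwise <- data.frame(group1 = character(), group2 = character(),
                         p_adj = numeric(), stringsAsFactors = FALSE)
  if (is.finite(p_overall) && p_overall < 0.05 && length(groups) > 2L) {
    combs <- utils::combn(groups, 2)
    m <- ncol(combs)
    for (j in seq_len(m)) {
      g1 <- combs[1, j]; g2 <- combs[2, j]
      p_raw <- t.test(u_val[u_grp == g1], u_val[u_grp == g2])$p.value
      pairwise <- rbind(pairwise, data.frame(
        group1 = g1, group2 = g2, p_adj = min(1, m * p_raw),
        stringsAsFactors = FALSE))
    }
  }
  structure(list(summary = summ, test = test_name, p_value = p_overall,
                 pairwise = pairwise),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison (%s): overall p = %.4g\n", x$test, x$p_value))
  print(x$summary, row.names = FALSE)
  if (nrow(x$pairwise)) {
    cat("pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' Run a cohort end to end
#'
#' Quantifies every cell of a simulated cohort (a [cohort_config()]) or a
#' directory of TIFF scenes written by [simulate_cohort()], writes the
#' per-cell table, the per-group summary, the group comparisons, and a run
#' log. Outputs are deterministic for a fixed cohort seed.
#'
#' @param cohort a [cohort_config()] or a directory path.
#' @param config a [quantify_config()].
#' @param out_dir output directory for `cells.csv`, `summary.csv`,
#'   `comparisons.csv`, `run.log`; `NULL` skips writing.
#' @return Invisibly, a list with `cells` (data.frame), `comparisons`
#'   (named list of [compare_groups()] results), and `summary`.
#' @export
run_cohort <- function(cohort, config = quantify_config(), out_dir = NULL) {
  log_lines <- c(sprintf("nucarch %s cohort run",
                         as.character(utils::packageVersion("nucarch"))))
  if (inherits(cohort, "cohort_config")) {
    sim <- simulate_cohort(cohort)
    scenes <- sim$scenes
    meta <- sim$truth
    log_lines <- c(log_lines,
                   sprintf("simulated cohort: %d groups x %d cells, seed %d",
                           length(cohort$groups), cohort$n_cells, cohort$seed))
  } else if (is.character(cohort) && dir.exists(cohort)) {
    paths <- sort(list.files(cohort, pattern = "\\.tif$", full.names = TRUE))
    if (length(paths) == 0L) stop("empty cohort: no TIFF scenes found")
    scenes <- lapply(paths, read_scene)
    ids <- sub("\\.tif$", "", basename(paths))
    names(scenes) <- ids
    gt_path <- file.path(cohort, "ground_truth.csv")
    meta <- if (file.exists(gt_path)) read.csv(gt_path, stringsAsFactors = FALSE)
      else data.frame(cell_id = ids,
                      group = sub("_[0-9]+$", "", ids),
                      repeat_id = 1L, stringsAsFactors = FALSE)
  } else stop("empty cohort: need a cohort_config or an existing directory")
  if (length(scenes) == 0L) stop("empty cohort")

  rows <- list()
  for (cid in names(scenes)) {
    sc <- scenes[[cid]]
    if (is.character(sc)) sc <- read_scene(sc)
    mrow <- meta[meta$cell_id == cid, , drop = FALSE]
    rec <- quantify_cell(sc, config, cell_id = cid,
                         group = if (nrow(mrow)) mrow$group[1] else NA,
                         repeat_id = if (nrow(mrow)) mrow$repeat_id[1] else NA)
    if (length(rec$errors))
      log_lines <- c(log_lines, sprintf("WARNING cell %s: %s", cid,
                                        paste(rec$errors, collapse = "; ")))
    else
      log_lines <- c(log_lines, sprintf("INFO cell %s quantified", cid))
    rows[[cid]] <- as.data.frame(rec)
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL

  metrics <- c("volume_um3", "nsf", "solidity", "polarity_score",
               "distance_um", "peripherality")
  comparisons <- list()
  for (mtr in metrics) {
    v <- cells[[mtr]]
    ok <- is.finite(v) & !is.na(cells$group)
    if (length(unique(cells$group[ok])) >= 2L &&
        min(table(cells$group[ok])) >= 2L) {
      comparisons[[mtr]] <- tryCatch(
        compare_groups(v[ok], cells$group[ok], cells$repeat_id[ok]),
        error = function(e) NULL)
    }
  }
  summ <- do.call(rbind, lapply(names(comparisons), function(mtr) {
    s <- comparisons[[mtr]]$summary
    s$metric <- mtr
    s$p_overall <- comparisons[[mtr]]$p_value
    s
  }))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write.csv(cells, file.path(out_dir, "cells.csv"), row.names = FALSE)
    if (!is.null(summ))
      write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
    comp_rows <- do.call(rbind, lapply(names(comparisons), function(mtr) {
      data.frame(metric = mtr, test = comparisons[[mtr]]$test,
                 p_value = comparisons[[mtr]]$p_value,
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(comp_rows))
      write.csv(comp_rows, file.path(out_dir, "comparisons.csv"),
                row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  invisible(list(cells = cells, comparisons = comparisons, summary = summ))
}
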