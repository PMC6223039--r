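# File I/O: multi-channel TIFF stacks with YAML sidecars, BED-like interval
# tables, chrom.sizes.

#' Write a multi-channel volume as a 16-bit TIFF stack
#'
#' Slices are written channel-major (all z-planes of channel 1, then channel
#' 2, ...). Grid geometry and channel names go into a YAML sidecar
#' (`<path>.yml`) because baseline TIFF has no standard slot for 3-axis
#' physical spacing.
#'
#' @param vol a [multichannel_volume()] with integer intensities in
#'   `[0, 65535]`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(vol, path) {
  stopifnot(inherits(vol, "multichannel_volume"))
  d <- vol$grid$shape
  slices <- list()
  for (nm in vol$channels) {
    a <- vol$data[[nm]] / 65535
    for (z in seq_len(d[1]))
      slices[[length(slices) + 1L]] <- matrix(a[z, , ], nrow = d[2], ncol = d[3])
  }
  tiff::writeTIFF(slices, path, bits.per.sample = 16L, compression = "none")
  side <- list(channels = as.list(vol$channels),
               shape = as.list(as.integer(d)),
               spacing_um = as.list(vol$grid$spacing))
  yaml::write_yaml(side, paste0(path, ".yml"))
  invisible(path)
}

#' Read a multi-channel TIFF stack written by [write_scene()]
#'
#' @param path TIFF path; the sidecar `<path>.yml` supplies channel names
#'   and voxel spacing. `spacing` overrides the sidecar (or supplies it when
#'   the sidecar is absent, in which case all slices are read as one channel
#'   named `"ch1"` unless `channels` is given).
#' @param spacing optional numeric length-3 (dz, dy, dx) override in um.
#' @param channels optional channel-name override.
#' @return A [multichannel_volume()].
#' @export
read_scene <- function(path, spacing = NULL, channels = NULL) {
  slices <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  side_path <- paste0(path, ".yml")
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    if (is.null(channels)) channels <- unlist(side$channels)
    if (is.null(spacing)) spacing <- unlist(side$spacing_um)
  }
  if (is.null(spacing))
    stop("no sidecar found; voxel spacing must be supplied")
  if (is.null(channels)) channels <- "ch1"
  n_ch <- length(channels)
  nz <- length(slices) / n_ch
  if (nz != round(nz))
    stop("slice count is not a multiple of the channel count")
  d <- c(as.integer(nz), dim(slices[[1]])[1], dim(slices[[1]])[2])
  grid <- grid_spec(d, spacing)
  data <- list()
  k <- 0L
  for (nm in channels) {
    a <- array(0, d)
    for (z in seq_len(d[1])) {
      k <- k + 1L
      a[z, , ] <- slices[[k]]
    }
    data[[nm]] <- a
  }
  multichannel_volume(data, grid)
}

#' Read a BED-like interval table
#'
#' Accepts 3-6 column BED (chrom, start, end, name, score, strand) plus an
#' optional 7th `direction` column. With `direction_from_score = TRUE` the
#' sign of the score column supplies the direction (`gain` for positive,
#' `loss` for negative).
#'
#' @param path file path (plain text, tab-separated, no header).
#' @param direction_from_score derive the direction label from the score sign.
#' @return A [peak_table()].
#' @export
read_bed <- function(path, direction_from_score = FALSE) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  cols <- c("chrom", "start", "end", "name", "score", "strand", "direction")
  names(df) <- cols[seq_len(min(ncol(df), length(cols)))]
  if (direction_from_score) {
    if (is.null(df$score)) stop("no score column to derive directions from")
    df$direction <- ifelse(df$score >= 0, "gain", "loss")
  }
  peak_table(df)
}

#' Write a peak table as BED
#'
#' Columns beyond (chrom, start, end) that are present -- name, score,
#' strand, direction -- are appended in that order.
#'
#' @param peaks a [peak_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  df <- as.data.frame(peaks)
  keep <- intersect(c("chrom", "start", "end", "name", "score", "strand",
                      "direction"), names(df))
  write.table(df[keep], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chrom.sizes file
#'
#' Two-column tab-separated text: chromosome name, size in bp. A third
#' column, when present, is taken as a per-chromosome gene count.
#'
#' @param path file path.
#' @return A [genome_table()].
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  genome_table(chrom = df[[1]], size = df[[2]],
               gene_count = if (ncol(df) >= 3) df[[3]] else NULL)
}
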