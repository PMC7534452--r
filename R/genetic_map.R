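#' Construct a genetic map
#'
#' A genetic map is a data frame with one row per marker and columns
#' `chrom`, `marker`, `pos_bp` (1-based physical position, strictly
#' increasing within a chromosome) and `pos_cM` (non-decreasing within a
#' chromosome, each chromosome starting at 0 for estimated maps).
#'
#' @param chrom Chromosome name per marker.
#' @param marker Marker identifier (unique).
#' @param pos_bp Physical position, 1-based bp.
#' @param pos_cM Genetic position, cM.
#' @return A data frame of class `genetic_map`.
#' @export
genetic_map <- function(chrom, marker, pos_bp, pos_cM) {
  m <- data.frame(chrom = as.character(chrom), marker = as.character(marker),
                  pos_bp = as.numeric(pos_bp), pos_cM = as.numeric(pos_cM),
                  stringsAsFactors = FALSE)
  validate_genetic_map(m)
  class(m) <- c("genetic_map", "data.frame")
  m
}

validate_genetic_map <- function(m) {
  stopifnot(all(c("chrom", "marker", "pos_bp", "pos_cM") %in% names(m)))
  if (anyDuplicated(m$marker)) stop("duplicate marker ids in map")
  if (!all(is.finite(m$pos_bp)) || !all(is.finite(m$pos_cM)))
    stop("non-finite map positions")
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    bp <- m$pos_bp[i]; cm <- m$pos_cM[i]
    # identical bp allowed only through stable marker-id order upstream
    if (is.unsorted(bp)) stop("physical positions not sorted on chromosome ", ch)
    if (is.unsorted(cm)) stop("genetic positions not sorted on chromosome ", ch)
  }
  invisible(m)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map:", length(unique(x$chrom)), "chromosome(s),",
      nrow(x), "markers,", sprintf("%.1f cM total\n", map_metrics(x)$overall_length_cM))
  invisible(x)
}

#' Map summary metrics
#'
#' Computes, over all adjacent marker intervals across chromosomes, the
#' overall map length (sum of chromosome lengths), the average and maximum
#' interval lengths, and the marker count. Chromosomes with a single marker
#' contribute to `n_markers` but not to interval statistics.
#'
#' @param map A `genetic_map`.
#' @return A list with `overall_length_cM`, `avg_interval_cM`,
#'   `max_interval_cM` and `n_markers`.
#' @export
map_metrics <- function(map) {
  validate_genetic_map(map)
  lens <- numeric(0)
  total <- 0
  for (ch in unique(map$chrom)) {
    cm <- map$pos_cM[map$chrom == ch]
    if (length(cm) >= 2) {
      iv <- diff(cm)
      lens <- c(lens, iv)
      total <- total + (max(cm) - min(cm))
    }
  }
  list(overall_length_cM = total,
       avg_interval_cM = if (length(lens)) mean(lens) else NA_real_,
       max_interval_cM = if (length(lens)) max(lens) else NA_real_,
       n_markers = nrow(map))
}

#' Read and write maps as TSV
#'
#' The on-disk format has columns `chrom`, `marker`, `bp`, `cM` and
#' round-trips losslessly.
#'
#' @param map A `genetic_map`.
#' @param path File path.
#' @return `read_map_tsv` returns a `genetic_map`; `write_map_tsv` returns
#'   the path invisibly.
#' @export
write_map_tsv <- function(map, path) {
  validate_genetic_map(map)
  df <- data.frame(chrom = map$chrom, marker = map$marker,
                   bp = map$pos_bp, cM = map$pos_cM)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "marker", "bp", "cM") %in% names(df)))
  genetic_map(df$chrom, df$marker, df$bp, df$cM)
}
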