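#' Crossover model
#'
#' Crossovers are placed as a Poisson process on the genetic (cM) scale, so
#' the expected crossover count per gamete per chromosome equals the map
#' length in Morgans and there is no interference. The map function is used
#' only for distance/recombination-fraction conversion, not for placing
#' crossovers.
#'
#' @param map_function "kosambi" (default) or "haldane".
#' @return A list of class `crossover_model`.
#' @export
crossover_model <- function(map_function = c("kosambi", "haldane")) {
  structure(list(map_function = match.arg(map_function), interference = "none"),
            class = "crossover_model")
}

# A haplotype mosaic over one chromosome: segment right endpoints (cM, last
# equals the chromosome length) and the founder origin of each segment.
hap_const <- function(origin, length_cM) {
  list(ends = length_cM, origin = as.integer(origin))
}

hap_at <- function(hap, pos_cM) {
  hap$origin[findInterval(pos_cM, hap$ends, left.open = TRUE) + 1L]
}

recombine <- function(hapA, hapB, xo, start) {
  L <- hapA$ends[length(hapA$ends)]
  bounds <- c(0, xo, L)
  use_A <- rep(c(start == 1L, start != 1L), length.out = length(bounds) - 1L)
  ends <- numeric(0); orig <- integer(0)
  for (s in seq_along(use_A)) {
    lo <- bounds[s]; hi <- bounds[s + 1L]
    if (hi <= lo) next
    h <- if (use_A[s]) hapA else hapB
    i1 <- findInterval(lo, h$ends) + 1L
    i2 <- findInterval(hi, h$ends, left.open = TRUE) + 1L
    seg <- i1:i2
    ends <- c(ends, pmin(h$ends[seg], hi))
    orig <- c(orig, h$origin[seg])
  }
  keep <- if (length(orig) > 1L) c(orig[-1L] != orig[-length(orig)], TRUE) else TRUE
  list(ends = ends[keep], origin = orig[keep])
}

#' Simulate one gamete from a pair of parental haplotypes
#'
#' Draws a Poisson(length_cM / 100) number of crossovers uniformly on the
#' chromosome's genetic length and returns the resulting mosaic of the two
#' parental haplotypes. A 0-cM chromosome yields one parental haplotype
#' unchanged (never a crossover).
#'
#' @param hapA,hapB Parental haplotype mosaics (lists with `ends`, `origin`),
#'   e.g. from `hap_const()`.
#' @param length_cM Chromosome genetic length in cM.
#' @return A haplotype mosaic.
#' @export
simulate_gamete <- function(hapA, hapB, length_cM) {
  if (length_cM <= 0) {
    h <- if (stats::runif(1) < 0.5) hapA else hapB
    return(h)
  }
  n_co <- stats::rpois(1L, length_cM / 100)
  xo <- if (n_co > 0L) sort(stats::runif(n_co, 0, length_cM)) else numeric(0)
  start <- if (stats::runif(1) < 0.5) 1L else 2L
  recombine(hapA, hapB, xo, start)
}

# Breed one selfing lineage from the F1 and return its final pair of
# haplotypes per chromosome. generations = t gives an F_t individual
# (t - 1 rounds of selfing after the F1).
breed_lineage <- function(chrom_lens, generations) {
  haps <- lapply(chrom_lens, function(L)
    list(hap_const(1L, L), hap_const(2L, L)))
  for (g in seq_len(generations - 1L)) {
    haps <- lapply(haps, function(h) {
      list(simulate_gamete(h[[1L]], h[[2L]], h[[1L]]$ends[length(h[[1L]]$ends)]),
           simulate_gamete(h[[1L]], h[[2L]], h[[2L]]$ends[length(h[[2L]]$ends)]))
    })
  }
  haps
}

# Evaluate founder-origin genotype codes at given cM positions.
# Origins: 1 = recurrent parent, 2 = alternate parent.
lineage_genotype <- function(haps, pos_by_chrom) {
  unlist(lapply(seq_along(haps), function(ci) {
    oA <- hap_at(haps[[ci]][[1L]], pos_by_chrom[[ci]])
    oB <- hap_at(haps[[ci]][[2L]], pos_by_chrom[[ci]])
    code <- integer(length(oA))
    code[oA != oB] <- GENO_HET
    code[oA == oB & oA == 2L] <- GENO_ALT
    code
  }), use.names = FALSE)
}

#' Simulate founder-origin genotypes for a selfing RIL population
#'
#' Low-level engine behind [breed_ril_population()]: each line is an
#' independent F1-self, single-seed-descent lineage carried to generation
#' `generations`, and genotype codes (REF = recurrent-parent origin,
#' ALT = alternate origin, HET) are read off at the supplied cM positions.
#'
#' @param pos_by_chrom List of numeric vectors of marker cM positions, one
#'   per chromosome.
#' @param chrom_lens Numeric vector of chromosome genetic lengths (cM).
#' @param n_lines Number of lines (> 0).
#' @param generations Selfing generation, >= 2 (8 for F8 RILs).
#' @param seed Integer seed.
#' @return Integer matrix n_lines x total markers of genotype codes.
#' @export
sim_ril_genotypes <- function(pos_by_chrom, chrom_lens, n_lines,
                              generations = 8L, seed = 1L) {
  stopifnot(n_lines > 0, generations >= 2, length(pos_by_chrom) == length(chrom_lens))
  set.seed(seed)
  n_mark <- sum(lengths(pos_by_chrom))
  geno <- matrix(NA_integer_, n_lines, n_mark)
  for (i in seq_len(n_lines)) {
    haps <- breed_lineage(chrom_lens, generations)
    geno[i, ] <- lineage_genotype(haps, pos_by_chrom)
  }
  geno
}

#' Breed an F8 RIL population from a founder panel
#'
#' Simulates `n_lines` independent single-seed-descent lineages of the cross
#' recurrent x `alt_parent` and genotypes them, in founder-origin codes, at
#' every dense SNP of the panel. The returned population's `truth` slot
#' holds this complete founder-origin matrix (and its map) for downstream
#' oracle comparisons; the `geno` slot starts out identical and is
#' subsequently thinned and degraded by [apply_gbs_observation_model()].
#'
#' @param panel A `founder_panel`.
#' @param alt_parent Alternate founder id (a column of `panel$alt`).
#' @param n_lines Number of RILs (> 0).
#' @param generations Selfing generation (default 8).
#' @param seed Integer seed.
#' @param name Population name.
#' @return An object of class `ril_population`: list with `name`,
#'   `alt_parent`, `generation`, `geno` (lines x markers integer codes),
#'   `map` (a `genetic_map`) and `truth` (list with the full founder-origin
#'   `geno` and its `map`).
#' @export
breed_ril_population <- function(panel, alt_parent, n_lines, generations = 8L,
                                 seed = 1L, name = alt_parent) {
  stopifnot(inherits(panel, "founder_panel"))
  if (!alt_parent %in% colnames(panel$alt))
    stop("alt_parent not in panel: ", alt_parent)
  dense_map <- panel_dense_map(panel)
  chroms <- panel$chromosomes$chrom
  pos_by_chrom <- lapply(chroms, function(ch) dense_map$pos_cM[dense_map$chrom == ch])
  geno <- sim_ril_genotypes(pos_by_chrom, panel$chromosomes$length_cM,
                            n_lines, generations, seed)
  dimnames(geno) <- list(paste0(name, "_L", seq_len(n_lines)), dense_map$marker)
  structure(list(name = name, alt_parent = alt_parent,
                 generation = as.integer(generations),
                 geno = geno, map = dense_map,
                 truth = list(geno = geno, map = dense_map)),
            class = "ril_population")
}

#' @export
print.ril_population <- function(x, ...) {
  cat("RIL population", x$name, sprintf("(F%d, alt parent %s):", x$generation,
      x$alt_parent), nrow(x$geno), "lines x", ncol(x$geno), "markers;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Dense SNPs polymorphic in a given cross
#'
#' A SNP can be discovered by GBS in a biparental cross only if the two
#' parents differ there, i.e. the alternate parent carries ALT.
#'
#' @param panel A `founder_panel`.
#' @param alt_parent Alternate founder id.
#' @return Character vector of polymorphic dense SNP ids.
#' @export
polymorphic_snps <- function(panel, alt_parent) {
  if (!alt_parent %in% colnames(panel$alt)) stop("unknown founder: ", alt_parent)
  panel$snps$id[panel$alt[, alt_parent]]
}
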