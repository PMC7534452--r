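#' Simulate a dense founder SNP panel
#'
#' Builds the founder haplotypes of a NAM design: one recurrent parent
#' (REF at every SNP by construction) plus `k_alternates` alternate
#' founders, genotyped at a dense panel of biallelic SNPs on a shared
#' physical coordinate system, in the role a dense genome-wide SNP
#' dataset plays for a real NAM panel. Each SNP is ALT in at least one
#' alternate founder; the number of alternates sharing the ALT state is
#' drawn from `alt_sharing_profile`.
#'
#' @param k_alternates Number of alternate founders (>= 1).
#' @param chrom_spec Data frame (or list coercible to one) with columns
#'   `length_bp` and `length_cM`, one row per chromosome; optional column
#'   `chrom` with names (default "Chr1", ...).
#' @param snp_density SNPs per Mb (> 0).
#' @param alt_sharing_profile Numeric vector of length `k_alternates`;
#'   element q is the (unnormalised) probability that a SNP is ALT in
#'   exactly q alternates. Default is a U-shaped site-frequency-like
#'   profile, 1 / (q (k + 1 - q)), putting comparable mass on
#'   population-private and universally shared SNPs.
#' @param seed Integer seed; the builder is deterministic given it.
#' @return An object of class `founder_panel`: list with `founder_ids`
#'   (recurrent parent first), `chromosomes` (chrom, length_bp, length_cM),
#'   `snps` (chrom, pos_bp, id) and `alt`, an n_snp x k logical matrix that
#'   is TRUE where the alternate founder carries the ALT allele.
#' @export
build_founder_panel <- function(k_alternates, chrom_spec, snp_density = 50,
                                alt_sharing_profile = NULL, seed = 1L) {
  stopifnot(k_alternates >= 1, snp_density > 0)
  chrom_spec <- as.data.frame(chrom_spec)
  stopifnot(all(c("length_bp", "length_cM") %in% names(chrom_spec)))
  if (any(chrom_spec$length_bp <= 0) || any(chrom_spec$length_cM < 0))
    stop("zero-length chromosome")
  if (is.null(chrom_spec$chrom))
    chrom_spec$chrom <- paste0("Chr", seq_len(nrow(chrom_spec)))
  if (is.null(alt_sharing_profile)) {
    q <- seq_len(k_alternates)
    alt_sharing_profile <- 1 / (q * (k_alternates + 1 - q))
  }
  stopifnot(length(alt_sharing_profile) == k_alternates,
            all(alt_sharing_profile >= 0), sum(alt_sharing_profile) > 0)
  prof <- alt_sharing_profile / sum(alt_sharing_profile)

  set.seed(seed)
  snps <- do.call(rbind, lapply(seq_len(nrow(chrom_spec)), function(i) {
    len <- chrom_spec$length_bp[i]
    n <- max(1L, round(len / 1e6 * snp_density))
    pos <- sort(sample.int(len, n, replace = FALSE))
    data.frame(chrom = chrom_spec$chrom[i], pos_bp = pos,
               stringsAsFactors = FALSE)
  }))
  snps$id <- paste0(snps$chrom, "_", snps$pos_bp)
  n_snp <- nrow(snps)

  share <- sample.int(k_alternates, n_snp, replace = TRUE, prob = prof)
  alt <- matrix(FALSE, n_snp, k_alternates)
  for (q in unique(share)) {
    idx <- which(share == q)
    if (q == k_alternates) {
      alt[idx, ] <- TRUE
    } else {
      for (i in idx) alt[i, sample.int(k_alternates, q)] <- TRUE
    }
  }
  founder_ids <- c("recurrent", paste0("alt", seq_len(k_alternates)))
  colnames(alt) <- founder_ids[-1]

  structure(list(founder_ids = founder_ids,
                 chromosomes = chrom_spec[, c("chrom", "length_bp", "length_cM")],
                 snps = snps, alt = alt),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("Founder panel:", length(x$founder_ids) - 1, "alternate founders,",
      nrow(x$snps), "dense SNPs on", nrow(x$chromosomes), "chromosome(s)\n")
  invisible(x)
}

#' Dense-SNP genetic positions by linear interpolation
#'
#' Dense SNP cM positions are obtained from the chromosome's physical and
#' genetic lengths assuming a uniform recombination landscape (pos_cM =
#' pos_bp / length_bp * length_cM).
#'
#' @param panel A `founder_panel`.
#' @return A `genetic_map` over the dense SNPs.
#' @export
panel_dense_map <- function(panel) {
  chr <- panel$chromosomes
  idx <- match(panel$snps$chrom, chr$chrom)
  cm <- panel$snps$pos_bp / chr$length_bp[idx] * chr$length_cM[idx]
  genetic_map(panel$snps$chrom, panel$snps$id, panel$snps$pos_bp, cm)
}

#' Founder allele at each dense SNP
#'
#' @param panel A `founder_panel`.
#' @param founder Founder id (or "recurrent").
#' @return Integer vector over dense SNPs: `GENO_REF` or `GENO_ALT`.
#' @export
founder_alleles <- function(panel, founder) {
  if (founder == "recurrent") return(rep(GENO_REF, nrow(panel$snps)))
  if (!founder %in% colnames(panel$alt)) stop("unknown founder: ", founder)
  ifelse(panel$alt[, founder], GENO_ALT, GENO_REF)
}
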