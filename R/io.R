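#' Write and read the genotype CSV dialect
#'
#' The on-disk layout (one file per RIL population) is: row 1 marker ids
#' (first cell = "id"), row 2 chromosome, row 3 cM position, row 4 bp
#' position; subsequent rows give the line id followed by genotype codes
#' "A" (REF), "B" (ALT), "H" (heterozygous) or "-" (missing). Round-trips
#' losslessly.
#'
#' @param pop A `ril_population`.
#' @param path File path.
#' @param name,alt_parent,generation Metadata for the population read back
#'   (the CSV stores genotypes and map only).
#' @return `read_genotype_csv` returns a `ril_population`;
#'   `write_genotype_csv` returns the path invisibly.
#' @export
write_genotype_csv <- function(pop, path) {
  stopifnot(inherits(pop, "ril_population"))
  m <- pop$map
  header <- rbind(c("id", m$marker),
                  c("chrom", m$chrom),
                  c("cM", format(m$pos_cM, digits = 12, trim = TRUE, scientific = FALSE)),
                  c("bp", format(m$pos_bp, trim = TRUE, scientific = FALSE)))
  body <- cbind(rownames(pop$geno),
                matrix(geno_to_letter(pop$geno), nrow(pop$geno)))
  utils::write.table(rbind(header, body), path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_csv
#' @export
read_genotype_csv <- function(path, name = basename(path),
                              alt_parent = NA_character_, generation = 8L) {
  lines <- readLines(path)
  if (length(lines) < 5) stop("genotype CSV needs 4 header rows and >= 1 line row")
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol_exp <- length(cells[[1L]])
  bad <- which(lengths(cells) != ncol_exp)
  if (length(bad)) stop("inconsistent column count at row ", bad[1L])
  markers <- cells[[1L]][-1L]
  chrom <- cells[[2L]][-1L]
  has_bp <- length(cells) >= 4 && cells[[4L]][1L] == "bp"
  cm <- suppressWarnings(as.numeric(cells[[3L]][-1L]))
  if (anyNA(cm)) stop("non-numeric cM at row 3, column ",
                      which(is.na(cm))[1L] + 1L)
  if (has_bp) {
    bp <- suppressWarnings(as.numeric(cells[[4L]][-1L]))
    if (anyNA(bp)) stop("non-numeric bp at row 4, column ",
                        which(is.na(bp))[1L] + 1L)
    first_line <- 5L
  } else {
    bp <- round(cm * 1e4) + 1  # placeholder physical order when bp absent
    first_line <- 4L
  }
  body <- cells[first_line:length(cells)]
  line_ids <- vapply(body, `[[`, "", 1L)
  geno <- matrix(NA_integer_, length(body), length(markers),
                 dimnames = list(line_ids, markers))
  for (i in seq_along(body)) {
    codes <- body[[i]][-1L]
    bad <- which(!codes %in% GENO_LETTERS)
    if (length(bad))
      stop("unknown genotype code '", codes[bad[1L]], "' at row ",
           first_line + i - 1L, ", column ", bad[1L] + 1L)
    geno[i, ] <- letter_to_geno(codes)
  }
  map <- genetic_map(chrom, markers, bp, cm)
  structure(list(name = name, alt_parent = alt_parent,
                 generation = as.integer(generation),
                 geno = geno, map = map),
            class = "ril_population")
}

#' Write founder-panel dense SNPs as a minimal VCF
#'
#' One sample column per founder (recurrent first), REF allele "A", ALT
#' allele "T" (placeholder bases; the panel stores allele states, not
#' nucleotides), genotypes 0/0 or 1/1.
#'
#' @param panel A `founder_panel`.
#' @param path Output path (uncompressed .vcf).
#' @return The path, invisibly.
#' @export
write_parental_vcf <- function(panel, path) {
  gts <- cbind("0/0",
               ifelse(panel$alt, "1/1", "0/0"))
  colnames(gts) <- panel$founder_ids
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$founder_ids), collapse = "\t"))
  body <- paste(panel$snps$chrom, panel$snps$pos_bp, panel$snps$id, "A", "T",
                ".", "PASS", ".", "GT",
                apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read parental SNP states from a VCF
#'
#' Accepts biallelic SNP records with genotypes 0/0, 1/1 (or |-separated)
#' and ./.; multiallelic or heterozygous records are skipped with a
#' warning. The recurrent-parent sample (all-REF) must be present.
#'
#' @param path VCF path.
#' @param recurrent Sample name of the recurrent parent (default
#'   "recurrent").
#' @param chrom_spec Optional chromosome spec; reconstructed from the
#'   observed positions when absent.
#' @return A `founder_panel` slice (ALT states are NA where a founder's
#'   call is missing, excluding it from sharing counts).
#' @export
read_parental_vcf <- function(path, recurrent = "recurrent", chrom_spec = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!recurrent %in% colnames(gt)) stop("missing recurrent-parent sample '", recurrent, "'")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  gt_code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA, length(g))
    out[g == "0/0"] <- FALSE
    out[g == "1/1"] <- TRUE
    attr(out, "het") <- !is.na(g) & !(g %in% c("0/0", "1/1", "./."))
    out
  }
  codes <- apply(gt, 2L, gt_code, simplify = FALSE)
  het_any <- Reduce(`|`, lapply(codes, attr, "het"))
  drop <- multi | het_any
  if (any(drop)) warning(sum(drop), " multiallelic/heterozygous record(s) skipped")
  keep <- !drop
  alt <- do.call(cbind, codes)[keep, , drop = FALSE]
  alt <- alt[, setdiff(colnames(gt), recurrent), drop = FALSE]
  snps <- data.frame(chrom = fix[keep, "CHROM"],
                     pos_bp = as.numeric(fix[keep, "POS"]),
                     id = ifelse(is.na(fix[keep, "ID"]) | fix[keep, "ID"] == ".",
                                 paste0(fix[keep, "CHROM"], "_", fix[keep, "POS"]),
                                 fix[keep, "ID"]),
                     stringsAsFactors = FALSE)
  if (is.null(chrom_spec)) {
    chrom_spec <- do.call(rbind, lapply(split(snps$pos_bp, snps$chrom), function(p)
      data.frame(length_bp = max(p) + 1, length_cM = (max(p) + 1) / 2.5e5)))
    chrom_spec$chrom <- rownames(chrom_spec)
  }
  structure(list(founder_ids = c(recurrent, colnames(alt)),
                 chromosomes = as.data.frame(chrom_spec)[, c("chrom", "length_bp", "length_cM")],
                 snps = snps, alt = alt),
            class = "founder_panel")
}

#' Read a run configuration from JSON
#'
#' Known keys: `seed`, `n_pops`, `lines_per_pop`, `gbs_markers`,
#' `missing_rate`, `geno_error_rate`, `snp_density`, `epsilon`,
#' `threshold`, `n_perm`, `n_reps`, `min_shared`, `pves`, `p_threshold`,
#' `paths`. Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return Named list of validated parameters.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("seed", "n_pops", "lines_per_pop", "gbs_markers", "missing_rate",
             "geno_error_rate", "snp_density", "epsilon", "threshold",
             "n_perm", "n_reps", "min_shared", "pves", "p_threshold", "paths")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config key(s): ", paste(extra, collapse = ", "))
  rng <- list(epsilon = c(0, 0.5), threshold = c(0.5, 1), missing_rate = c(0, 1),
              geno_error_rate = c(0, 1), p_threshold = c(0, 1))
  for (k in names(rng)) if (!is.null(cfg[[k]]))
    if (any(cfg[[k]] < rng[[k]][1]) || any(cfg[[k]] > rng[[k]][2]))
      stop("config key '", k, "' out of range")
  cfg
}
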