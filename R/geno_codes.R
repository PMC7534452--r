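#' Genotype codes
#'
#' Genotypes are stored as integer matrices (lines x markers) using the codes
#' `GENO_REF` (0, homozygous for the recurrent-parent state), `GENO_ALT`
#' (1, homozygous for the alternate state), `GENO_HET` (2, heterozygous) and
#' `NA` for a missing call. Within a biparental RIL population the codes are
#' founder-origin symbols (REF = recurrent parent, ALT = the population's
#' alternate parent); in the dense projected matrices they are allele symbols
#' on the shared reference coordinate system.
#'
#' @name geno-codes
#' @aliases GENO_REF GENO_ALT GENO_HET
NULL

#' @export
GENO_REF <- 0L
#' @export
GENO_ALT <- 1L
#' @export
GENO_HET <- 2L

# letters used by the genotype CSV dialect
GENO_LETTERS <- c("A", "B", "H", "-")

#' Convert between integer genotype codes and CSV letters
#'
#' The genotype CSV dialect writes `GENO_REF` as "A", `GENO_ALT` as "B",
#' `GENO_HET` as "H" and a missing call as "-".
#'
#' @param g Integer genotype codes (see [geno-codes]).
#' @param ch Character codes in {"A", "B", "H", "-"}.
#' @return `geno_to_letter` a character vector; `letter_to_geno` an integer
#'   vector with `NA` for "-".
#' @export
geno_to_letter <- function(g) {
  out <- rep("-", length(g))
  out[!is.na(g) & g == GENO_REF] <- "A"
  out[!is.na(g) & g == GENO_ALT] <- "B"
  out[!is.na(g) & g == GENO_HET] <- "H"
  out
}

#' @rdname geno_to_letter
#' @export
letter_to_geno <- function(ch) {
  out <- rep(NA_integer_, length(ch))
  out[ch == "A"] <- GENO_REF
  out[ch == "B"] <- GENO_ALT
  out[ch == "H"] <- GENO_HET
  bad <- !(ch %in% GENO_LETTERS)
  if (any(bad)) stop("unknown genotype code(s): ", paste(unique(ch[bad]), collapse = ", "))
  out
}

#' Is a genotype call an informative homozygote?
#'
#' @param g Integer genotype codes (see [geno-codes]); vector or matrix.
#' @return Logical of the same shape: TRUE for `GENO_REF`/`GENO_ALT`,
#'   FALSE for `GENO_HET` and missing calls.
#' @export
is_hom <- function(g) !is.na(g) & (g == GENO_REF | g == GENO_ALT)

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
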