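test_that("fill-in obeys the flank rules and never alters observed calls", {
  map <- genetic_map(rep("c1", 5), paste0("m", 1:5), 1:5 * 1e5, 0:4)
  g <- rbind(c(0L, NA, 0L, 1L, 1L),    # run flanked REF/REF -> filled
             c(0L, NA, 1L, NA, 1L),    # breakpoint run stays; ALT run filled
             c(NA, 1L, 1L, 1L, NA),    # chromosome-end runs stay
             c(0L, NA, 2L, NA, 1L))    # HET flank never anchors a fill
  f <- fill_in_missing(g, map)
  expect_equal(f$geno[1, ], c(0L, 0L, 0L, 1L, 1L), ignore_attr = TRUE)
  expect_true(is.na(f$geno[2, 2]))          # REF/ALT breakpoint run stays
  expect_equal(f$geno[2, 4], 1L, ignore_attr = TRUE)  # ALT/ALT run filled
  expect_true(is.na(f$geno[3, 1]) && is.na(f$geno[3, 5]))
  expect_true(all(is.na(f$geno[4, c(2, 4)])))
  # observed calls untouched; origin marks exactly the filled cells
  obs <- !is.na(g)
  expect_identical(f$geno[obs], g[obs])
  expect_identical(which(f$origin == 1L), which(is.na(g) & !is.na(f$geno)))
  expect_lte(f$report$missing_fraction_after, f$report$missing_fraction_before)

  # two chromosomes: a run spanning the boundary is two end-runs, not filled
  map2 <- genetic_map(c("c1", "c1", "c2", "c2"), paste0("m", 1:4),
                      c(1e5, 2e5, 1e5, 2e5), c(0, 1, 0, 1))
  g2 <- matrix(c(0L, NA, NA, 0L), 1)
  expect_true(all(is.na(fill_in_missing(g2, map2)$geno[1, 2:3])))
})

test_that("forward-backward posteriors equal exhaustive path enumeration", {
  set.seed(91)
  d <- c(2, 5, 1, 8)   # cM between 5 markers
  map <- genetic_map(rep("c1", 5), paste0("m", 1:5), 1:5 * 1e5, cumsum(c(0, d)))
  states <- c(GENO_REF, GENO_ALT, GENO_HET, NA)
  for (trial in 1:12) {
    obs <- sample(states, 5, replace = TRUE, prob = c(.4, .4, .1, .1))
    gp <- genotype_probabilities(matrix(obs, 1), map, epsilon = 0.02)
    oracle <- enum_posteriors(obs, d, epsilon = 0.02)
    got <- cbind(gp$pREF[1, ], gp$pALT[1, ], gp$pHET[1, ])
    expect_equal(unname(got), unname(oracle), tolerance = 1e-10)
  }
  # single observed marker, epsilon = 0: certainty
  m1 <- genetic_map("c1", "m1", 1e5, 0)
  gp1 <- genotype_probabilities(matrix(GENO_REF), m1, epsilon = 0)
  expect_equal(gp1$pREF[1, 1], 1)
  # all missing: stationary distribution everywhere
  gpm <- genotype_probabilities(matrix(NA_integer_, 1, 5), map, epsilon = 0.01)
  h <- 0.5^7
  expect_equal(unname(gpm$pHET[1, ]), rep(h, 5), tolerance = 1e-12)
  expect_equal(unname(gpm$pREF[1, ]), rep((1 - h) / 2, 5), tolerance = 1e-12)
  expect_error(genotype_probabilities(matrix(7L), m1), "unknown genotype state")
})

test_that("low-confidence filled calls revert to missing", {
  map <- genetic_map(rep("c1", 3), paste0("m", 1:3), 1:3 * 1e5, c(0, 20, 40))
  # wide intervals: a filled middle call has posterior < 0.99 when the
  # posterior is computed from the observed (pre-fill) calls
  g <- matrix(c(0L, NA, 0L), 1)
  f <- fill_in_missing(g, map)
  expect_equal(f$geno[1, 2], 0L, ignore_attr = TRUE)
  probs <- genotype_probabilities(g, map, epsilon = 0.01)
  expect_lt(probs$pREF[1, 2], 0.99)
  f2 <- filter_low_confidence(f, probs, threshold = 0.99)
  expect_true(is.na(f2$geno[1, 2]))
  expect_equal(f2$report$n_removed_low_confidence, 1L)

  # tight intervals: fill survives the 99% filter
  map_t <- genetic_map(rep("c1", 3), paste0("m", 1:3), 1:3 * 1e5, c(0, 0.3, 0.6))
  ft <- fill_in_missing(g, map_t)
  pt <- genotype_probabilities(g, map_t, epsilon = 0.01)
  expect_gt(pt$pREF[1, 2], 0.99)
  ft2 <- filter_low_confidence(ft, pt, threshold = 0.99)
  expect_equal(ft2$geno[1, 2], 0L, ignore_attr = TRUE)

  # threshold = 1 with epsilon > 0 reverts every filled cell
  fall <- filter_low_confidence(ft, pt, threshold = 1)
  expect_true(all(is.na(fall$geno[fall$origin == 1L])))
  expect_equal(sum(fall$origin == 1L), 0L)
})

test_that("fill-in plus filter drives study-scale missingness to a few percent", {
  fx <- make_pop(n_lines = 150, seed = 101, snp_density = 25)
  poly <- polymorphic_snps(fx$founders, fx$alt)
  pop <- apply_gbs_observation_model(fx$pop, poly, missing_rate = 0.216,
                                     geno_error_rate = 0, seed = 5)
  before <- mean(is.na(pop$geno))
  f <- fill_in_missing(pop$geno, pop$map)
  probs <- genotype_probabilities(pop$geno, pop$map, epsilon = 0.01)
  f <- filter_low_confidence(f, probs)
  after <- mean(is.na(f$geno))
  expect_gt(before, 0.19)
  expect_lt(after, 0.05)
  # filled calls agree with the simulated truth almost everywhere
  tru <- fx$pop$truth$geno[, poly]
  filled <- f$origin == 1L
  expect_gt(mean(f$geno[filled] == tru[filled]), 0.995)
})

test_that("dense projection follows the anchoring rules", {
  # hand-built panel: one chromosome, dense SNPs every 0.5 Mb
  fp <- list(founder_ids = c("recurrent", "altA"),
             chromosomes = data.frame(chrom = "c1", length_bp = 4e6, length_cM = 20),
             snps = data.frame(chrom = "c1", pos_bp = seq(5e5, 3.5e6, 5e5),
                               id = paste0("s", 1:7)),
             alt = matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE), 7, 1,
                          dimnames = list(NULL, "altA")))
  class(fp) <- "founder_panel"
  # GBS anchors at 1 Mb (s2) and 2 Mb (s4), plus 3 Mb (s6)
  gmap <- genetic_map(rep("c1", 3), c("g1", "g2", "g3"), c(1e6, 2e6, 3e6), c(5, 10, 15))
  g <- rbind(c(1L, 1L, 0L),   # ALT interval then breakpoint interval
             c(0L, 0L, 0L),   # all-REF intervals
             c(1L, 2L, 1L),   # HET call ignored, not an anchor
             c(NA, 1L, 1L))   # leading overhang
  pop <- as_pop(g, gmap, alt_parent = "altA")
  pr <- impute_parental_snps(pop, fp)
  # line 1: s3 (1.5 Mb) inside ALT-ALT interval -> alternate's allele = REF there
  expect_equal(pr$geno[1, "s3"], GENO_REF, ignore_attr = TRUE)
  # line 1: s5 (2.5 Mb) inside ALT-REF interval -> missing
  expect_true(is.na(pr$geno[1, "s5"]))
  # line 2: REF-anchored interiors take REF
  expect_equal(unname(pr$geno[2, c("s3", "s5")]), c(GENO_REF, GENO_REF))
  # line 3: the HET at g2 is ignored, so g1-g3 is one ALT-ALT interval and
  # interior SNPs take the alternate parent's allele (REF at s3, ALT at s5)
  expect_equal(unname(pr$geno[3, c("s3", "s5")]), c(GENO_REF, GENO_ALT))
  # s4 sits on the ignored HET call and is projected like any interior SNP
  expect_equal(pr$geno[3, "s4"], GENO_ALT, ignore_attr = TRUE)
  expect_equal(pr$origin[3, "s4"], 2L, ignore_attr = TRUE)
  # line 4: overhang before first anchor missing; s5 in ALT-ALT filled ALT
  expect_true(is.na(pr$geno[4, "s1"]))
  expect_equal(pr$geno[4, "s5"], GENO_ALT, ignore_attr = TRUE)
  # colocated dense SNP takes the anchor's implied state (s2 at 1 Mb)
  expect_equal(pr$geno[2, "s2"], GENO_REF, ignore_attr = TRUE)
  expect_equal(pr$geno[1, "s2"], GENO_ALT, ignore_attr = TRUE)
  # ends beyond the last anchor are missing
  expect_true(is.na(pr$geno[1, "s7"]))
})

test_that("projected-call error stays below the double-crossover bound", {
  fx <- make_pop(n_lines = 150, seed = 111, snp_density = 25)
  poly <- polymorphic_snps(fx$founders, fx$alt)
  set.seed(6)
  mk <- sort(sample(poly, round(length(poly) * 0.6)))
  pop <- apply_gbs_observation_model(fx$pop, mk, missing_rate = 0.2,
                                     geno_error_rate = 0, seed = 7)
  f <- fill_in_missing(pop$geno, pop$map)
  probs <- genotype_probabilities(f$geno, pop$map, epsilon = 0.01)
  f <- filter_low_confidence(f, probs)
  pop$geno <- f$geno
  pr <- impute_parental_snps(pop, fx$founders)
  # truth in allele space: founder-origin mosaic through the alt founder's alleles
  tru_orig <- fx$pop$truth$geno
  da <- founder_alleles(fx$founders, fx$alt)
  tru_allele <- tru_orig
  for (j in seq_len(ncol(tru_allele))) {
    a <- tru_orig[, j]
    tru_allele[, j] <- ifelse(a == GENO_ALT, da[j],
                              ifelse(a == GENO_REF, GENO_REF, GENO_HET))
  }
  proj <- pr$origin == 2L & !is.na(pr$geno)
  proj[is.na(proj)] <- FALSE
  expect_gt(sum(proj), 1e4)
  # where the truth is homozygous, a wrong projection needs a double
  # crossover inside the anchored interval; anchored intervals here are
  # well under 2 cM on average, so (d/100)^2 is ~1e-4 — allow generous slack
  hom_t <- is_hom(tru_allele) & proj
  err_hom <- mean(pr$geno[hom_t] != tru_allele[hom_t])
  expect_lt(err_hom, double_crossover_error_rate(2))
  # the remaining raw mismatch is residual F8 heterozygosity in the truth
  err_all <- mean(pr$geno[proj] != tru_allele[proj])
  frac_het <- mean(tru_allele[proj] == GENO_HET)
  expect_lt(abs(err_all - frac_het), 1e-3)
})

test_that("double-crossover error model reproduces its closed form", {
  expect_equal(double_crossover_error_rate(0), 0)
  expect_equal(100 * double_crossover_error_rate(0.4), 0.0016)
  expect_equal(100 * double_crossover_error_rate(13.9), 1.9321)
  expect_equal(double_crossover_error_rate(10, method = "kosambi"),
               (tanh(0.2) / 2)^2)
  expect_error(double_crossover_error_rate(-1), ">= 0")
})

test_that("error correction reverts singleton errors, spares breakpoints", {
  # 11 markers, 1 cM apart; line 1 has a singleton error at marker 6,
  # line 2 has a genuine breakpoint between markers 5 and 6, line 3 is
  # clean REF throughout
  m <- 11L
  map <- genetic_map(rep("Chr1", m), paste0("m", 1:m),
                     seq(1e5, by = 1e5, length.out = m), 0:(m - 1))
  g <- rbind(rep(GENO_REF, m), c(rep(GENO_REF, 5), rep(GENO_ALT, 6)),
             rep(GENO_REF, m))
  g[1, 6] <- GENO_ALT
  res <- correct_genotype_errors(g, map, epsilon = 0.01)
  expect_identical(res$n_reverted, 1L)
  expect_true(is.na(res$geno[1, 6]))
  # everything else untouched, including both sides of the breakpoint
  expect_identical(res$geno[2, ], g[2, ])
  expect_identical(res$geno[3, ], g[3, ])

  # correction de-inflates map estimation: errors planted into truth
  # genotypes push the estimated length up; the screen pulls it back
  spec <- data.frame(chrom = "Chr1", length_bp = 10e6, length_cM = 60)
  fp <- build_founder_panel(2, spec, snp_density = 10, seed = 11)
  pop <- breed_ril_population(fp, colnames(fp$alt)[1], 250, seed = 12)
  pop$geno <- pop$truth$geno
  set.seed(13)
  err <- sample(length(pop$geno), round(0.004 * length(pop$geno)))
  pop$geno[err] <- ifelse(pop$geno[err] == GENO_REF, GENO_ALT, GENO_REF)
  gen_len <- max(pop$map$pos_cM)
  len_raw <- max(estimate_map(pop)$pos_cM)
  pop$geno <- correct_genotype_errors(pop$geno, pop$map)$geno
  len_cor <- max(estimate_map(pop)$pos_cM)
  expect_gt(len_raw / gen_len, 1.1)          # errors inflate
  expect_lt(abs(len_cor / gen_len - 1), 0.08) # screen restores
})
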