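# hand-built two-population fixture shared by the merge/collapse/joint-map
# blocks: one 4 Mb chromosome, 6 dense SNPs, founders altA (all ALT) and
# altB (ALT at SNPs 1-3,6 only)
assoc_fixture <- function() {
  fp <- structure(list(
    founder_ids = c("recurrent", "altA", "altB"),
    chromosomes = data.frame(chrom = "c1", length_bp = 4e6, length_cM = 40),
    snps = data.frame(chrom = "c1", pos_bp = seq(5e5, 3e6, 5e5),
                      id = paste0("s", 1:6)),
    alt = cbind(altA = rep(TRUE, 6),
                altB = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))),
    class = "founder_panel")
  gm <- genetic_map(rep("c1", 2), c("g1", "g2"), c(1e6, 3e6), c(10, 30))
  popA <- as_pop(matrix(c(0L, 1L, 0L, 1L), 2, 2), gm, name = "A", alt_parent = "altA")
  popB <- as_pop(matrix(c(1L, 0L, 1L, 0L, 1L, 0L), 3, 2), gm, name = "B",
                 alt_parent = "altB")
  dA <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, NA, 1L, 0L, 1L), 2, 5,
               dimnames = list(c("L1", "L2"), paste0("s", 1:5)))
  dB <- matrix(1L, 3, 4, dimnames = list(paste0("L", 1:3),
                                         c("s1", "s2", "s3", "s6")))
  list(fp = fp, pops = list(popA, popB), dense = list(dA, dB))
}

test_that("merging populations aligns lines on the SNP union", {
  fx <- assoc_fixture()
  np <- merge_populations(fx$pops, fx$dense, fx$fp)
  expect_s3_class(np, "nam_panel")
  expect_equal(dim(np$geno), c(5L, 6L))
  expect_equal(colnames(np$geno), paste0("s", 1:6))
  expect_equal(rownames(np$geno), c("A:L1", "A:L2", "B:L1", "B:L2", "B:L3"))
  # population B never typed s4/s5: missing there; A never typed s6
  expect_true(all(is.na(np$geno[3:5, c("s4", "s5")])))
  expect_true(all(is.na(np$geno[1:2, "s6"])))
  # values carried through unchanged
  expect_equal(unname(np$geno[1:2, "s1"]), c(0L, 1L))
  expect_equal(as.character(np$population_of_line), rep(c("A", "B"), c(2, 3)))
  expect_output(print(np), "2 populations")
  expect_error(merge_populations(fx$pops[1], fx$dense[1], fx$fp), ">= 2")
})

test_that("perfect-LD collapse keeps one SNP per identical run and reconstructs", {
  fx <- assoc_fixture()
  g <- cbind(s1 = c(0L, 1L, 0L, NA, 1L),
             s2 = c(0L, 1L, 0L, NA, 1L),   # identical to s1 -> collapsed
             s3 = c(0L, 1L, 0L, 0L, 1L),   # same states, different NA pattern
             s4 = c(0L, 1L, 0L, 0L, 1L),   # identical to s3 -> collapsed
             s5 = c(1L, 1L, 0L, 0L, 1L),
             s6 = c(1L, 1L, 0L, 0L, 1L))   # identical to s5 -> collapsed
  rownames(g) <- paste0("L", 1:5)
  np <- merge_populations(fx$pops, fx$dense, fx$fp)
  np$geno <- g
  red <- collapse_perfect_ld(np)
  expect_equal(colnames(red$geno), c("s1", "s3", "s5"))
  rep_of <- attr(red, "representative")
  expect_equal(unname(rep_of[c("s2", "s4", "s6")]), c("s1", "s3", "s5"))
  # exact reconstruction of every collapsed column
  for (j in colnames(g))
    expect_identical(unname(g[, j]), unname(red$geno[, rep_of[j]]))
  # idempotent
  red2 <- collapse_perfect_ld(red)
  expect_identical(red2$geno, red$geno)

  # identical columns on different chromosomes are never collapsed
  np2 <- np
  np2$map$chrom <- c(rep("c1", 3), rep("c2", 3))
  np2$geno <- g[, c(1, 2, 3, 3, 5, 5)]
  colnames(np2$geno) <- paste0("s", 1:6)
  red3 <- collapse_perfect_ld(np2)
  expect_true(all(c("s4", "s5") %in% colnames(red3$geno)))
})

test_that("joint map keeps widely shared SNPs and blanks monomorphic populations", {
  fx <- assoc_fixture()
  np <- merge_populations(fx$pops, fx$dense, fx$fp)
  expect_equal(alt_share_count(np, paste0("s", 1:6)), c(2, 2, 2, 1, 1, 2),
               ignore_attr = TRUE)
  expect_error(alt_share_count(np, "nope"), "unknown SNP")
  jm <- build_joint_map(np, min_shared = 2L)
  expect_false(jm$empty)
  expect_equal(colnames(jm$geno), c("s1", "s2", "s3", "s6"))
  expect_true(all(jm$share >= 2))
  # population B is polymorphic at all retained SNPs here, so no recoding;
  # drop altB's ALT state at s2 and the B lines must blank out there
  fx2 <- fx; fx2$fp$alt["s2" == fx2$fp$snps$id, "altB"] <- FALSE
  np2 <- merge_populations(fx2$pops, fx2$dense, fx2$fp)
  jm2 <- build_joint_map(np2, min_shared = 1L)
  b_lines <- np2$population_of_line == "B"
  expect_true(all(is.na(jm2$geno[b_lines, "s2"])))
  expect_false(anyNA(jm2$geno[!b_lines, "s2"]))
  # estimated positions: one per retained SNP, starting at 0, nondecreasing
  expect_equal(nrow(jm$map), 4)
  expect_equal(min(jm$map$pos_cM), 0)
  expect_false(is.unsorted(jm$map$pos_cM))
  expect_warning(jme <- build_joint_map(np, min_shared = 3L), "no SNP")
  expect_true(jme$empty)
})

test_that("kinship matches its closed form and separates populations", {
  # complete data: K = Xc Xc' / p exactly
  set.seed(61)
  g <- matrix(sample(c(GENO_REF, GENO_ALT), 8 * 20, replace = TRUE), 8, 20)
  K <- kinship_matrix(g)
  Xc <- scale(g, scale = FALSE)
  expect_equal(K, tcrossprod(Xc) / 20, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(K, t(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # HET counts 0.5 and mean-imputation uses the SNP mean
  g2 <- cbind(c(0L, 1L, 2L), c(0L, 1L, NA))
  K2 <- kinship_matrix(g2)
  X2 <- cbind(c(0, 1, 0.5), c(0, 1, 0.5))
  X2c <- scale(X2, scale = FALSE)
  expect_equal(K2, tcrossprod(X2c) / 2, ignore_attr = TRUE)

  # two diverged populations: mean within-population kinship exceeds
  # cross-population kinship
  set.seed(62)
  n <- 40; p <- 300
  f1 <- rbeta(p, 2, 2); f2 <- pmin(pmax(f1 + rnorm(p, 0, 0.25), 0.02), 0.98)
  gg <- rbind(matrix(rbinom(n / 2 * p, 1, rep(f1, each = n / 2)), n / 2, p),
              matrix(rbinom(n / 2 * p, 1, rep(f2, each = n / 2)), n / 2, p))
  Kp <- kinship_matrix(gg)
  blk <- rep(1:2, each = n / 2)
  off <- row(Kp) != col(Kp)
  within <- mean(Kp[off & outer(blk, blk, "==")])
  cross <- mean(Kp[off & outer(blk, blk, "!=")])
  expect_gt(within, cross)
})

test_that("with identity kinship the mixed-model LRT reduces to OLS", {
  set.seed(63)
  n <- 60
  snp <- sample(c(GENO_REF, GENO_ALT), n, replace = TRUE)
  x <- as.numeric(snp == GENO_ALT)
  y <- 0.8 * x + rnorm(n)
  res <- lmm_lrt(y, snp, K = diag(n))
  # ML LRT for the linear model: n log(RSS0 / RSS1)
  rss0 <- sum(resid(lm(y ~ 1))^2); rss1 <- sum(resid(lm(y ~ x))^2)
  expect_equal(res$lrt_stat, n * log(rss0 / rss1), tolerance = 1e-6)
  expect_equal(res$beta_hat, unname(coef(lm(y ~ x))[2]), tolerance = 1e-6)
  expect_equal(res$n, n)
  # precomputed eigendecomposition gives the identical fit
  eig <- eigen(diag(n), symmetric = TRUE)
  res2 <- lmm_lrt(y, snp, eig = eig)
  expect_equal(res2$lrt_stat, res$lrt_stat, tolerance = 1e-10)
  # missing phenotype/SNP lines are dropped (eig must then mismatch)
  snp_na <- snp; snp_na[1:5] <- NA_integer_
  expect_error(lmm_lrt(y, snp_na, eig = eig), "does not match")
  res3 <- lmm_lrt(y, snp_na, K = diag(n))
  expect_equal(res3$n, n - 5L)
  expect_error(lmm_lrt(y, rep(GENO_REF, n), K = diag(n)), "monomorphic")
})

test_that("kinship correction deflates structure-confounded associations", {
  set.seed(64)
  n <- 120; p <- 400
  blk <- rep(1:2, each = n / 2)
  f <- cbind(rbeta(p, 0.8, 0.8), rbeta(p, 0.8, 0.8))
  gg <- t(vapply(blk, function(b) rbinom(p, 1, f[, b]), numeric(p)))
  storage.mode(gg) <- "integer"
  K <- kinship_matrix(gg)
  y <- 1.5 * (blk == 1) + rnorm(n)          # pure population-mean phenotype
  # a strongly differentiated, non-causal SNP
  j <- which.max(abs(f[, 1] - f[, 2]) * (pmin(colMeans(gg), 1 - colMeans(gg)) > 0.1))
  snp <- gg[, j]
  x <- as.numeric(snp)
  p_ols <- summary(lm(y ~ x))$coefficients[2, 4]
  res <- lmm_lrt(y, snp, K = K)
  expect_lt(p_ols, 1e-6)                    # naive test is badly confounded
  expect_false(res$detected)                # mixed model absorbs the structure
  expect_gt(res$p_value / p_ols, 50)        # orders-of-magnitude deflation
})

test_that("detection boundary is inclusive at the threshold", {
  expect_true(detect_association(1e-4))
  expect_false(detect_association(1.0001e-4))
  expect_true(detect_association(1e-9))
  # chi-square quantile at the threshold: LRT boundary 15.137
  expect_equal(qchisq(1e-4, 1, lower.tail = FALSE), 15.137, tolerance = 1e-4)
  expect_error(detect_association(0), "> 0")
  expect_error(detect_association(1.5), "<= 1")
})
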