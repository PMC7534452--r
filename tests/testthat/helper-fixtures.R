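# shared fixtures and independent oracles for the test suite

# small two-chromosome founder panel + populations, cached per session
tiny_chrom_spec <- function() {
  data.frame(chrom = c("Chr1", "Chr2"),
             length_bp = c(12e6, 9e6),
             length_cM = c(70, 55))
}

make_pop <- function(n_lines = 60, seed = 11, chrom_spec = tiny_chrom_spec(),
                     snp_density = 15, n_alt = 3, which_alt = 1) {
  fp <- build_founder_panel(n_alt, chrom_spec, snp_density, seed = seed)
  alt <- colnames(fp$alt)[which_alt]
  pop <- breed_ril_population(fp, alt, n_lines, seed = seed + 1)
  list(founders = fp, pop = pop, alt = alt)
}

# a ril_population built directly from a genotype matrix + map
as_pop <- function(geno, map, name = "fix", alt_parent = "altX") {
  if (is.null(colnames(geno))) colnames(geno) <- map$marker
  if (is.null(rownames(geno))) rownames(geno) <- paste0("L", seq_len(nrow(geno)))
  structure(list(name = name, alt_parent = alt_parent, generation = 8L,
                 geno = geno, map = map),
            class = "ril_population")
}

# brute-force HMM posterior by exhaustive path enumeration: the independent
# oracle for genotype_probabilities() on short chromosomes
enum_posteriors <- function(obs, d_cM, epsilon, generation = 8L,
                            map_function = "kosambi") {
  m <- length(obs)
  h <- 0.5^(generation - 1)
  pi0 <- c((1 - h) / 2, (1 - h) / 2, h)
  Tm <- lapply(d_cM, function(d) {
    r <- if (map_function == "kosambi") tanh(d / 50) / 2 else (1 - exp(-d / 50)) / 2
    R <- 2 * r / (1 + 2 * r)
    rbind(c((1 - h) * (1 - R), (1 - h) * R, h),
          c((1 - h) * R, (1 - h) * (1 - R), h),
          c((1 - h) / 2, (1 - h) / 2, h))
  })
  em <- function(state, o) {
    if (is.na(o)) return(1)
    if (o == state - 1L) 1 - epsilon else epsilon / 2
  }
  paths <- as.matrix(expand.grid(rep(list(1:3), m)))
  probs <- apply(paths, 1L, function(s) {
    p <- pi0[s[1L]] * em(s[1L], obs[1L])
    if (m > 1) for (k in 2:m)
      p <- p * Tm[[k - 1L]][s[k - 1L], s[k]] * em(s[k], obs[k])
    p
  })
  probs <- probs / sum(probs)
  post <- sapply(1:m, function(k)
    sapply(1:3, function(st) sum(probs[paths[, k] == st])))
  t(post)  # m x 3: REF, ALT, HET
}

# binomial 3*SE band check
expect_within_3se <- function(observed, expected, n, label = NULL) {
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  expect_lt(abs(observed - expected), 3 * se + 1e-12, label = label)
}
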