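test_that("gamete counts follow the unambiguous-contribution rule", {
  G <- rbind(c(0L, 0L), c(1L, 1L), c(0L, 2L))
  expect_equal(gamete_counts(G, 1, 2),
               c(n00 = 3L, n01 = 1L, n10 = 0L, n11 = 2L))
  # all double-het rows contribute nothing
  G22 <- matrix(2L, 4, 2)
  expect_equal(sum(gamete_counts(G22, 1, 2)), 0L)
  expect_equal(gamete_counts(rbind(c(0L, 0L)), 1, 2),
               c(n00 = 2L, n01 = 0L, n10 = 0L, n11 = 0L))
  # missing disqualifies the individual at this pair
  Gna <- rbind(c(0L, NA), c(1L, 1L))
  expect_equal(gamete_counts(Gna, 1, 2),
               c(n00 = 0L, n01 = 0L, n10 = 0L, n11 = 2L))
  expect_error(gamete_counts(G, 1, 5), "out of range")
  expect_error(gamete_counts(G, 2, 2), "distinct")
  # equals the naive oracle on random matrices
  for (seed in 1:5) {
    G <- random_genotypes(15, 12, p_missing = 0.1, seed = seed)
    s <- 1 + (seed %% 11); t <- 1 + ((seed + 5) %% 11)
    if (s == t) t <- t %% 11 + 1
    expect_equal(gamete_counts(G, s, t), naive_gamete_counts(G, s, t))
  }
})

test_that("LD sign is the sign of D with the CIS tie", {
  expect_equal(ld_sign(c(5, 0, 0, 5)), "CIS")
  expect_equal(ld_sign(c(0, 5, 5, 0)), "TRANS")
  expect_equal(ld_sign(c(2, 3, 3, 2)), "TRANS")  # D = 4 - 9 = -5
  expect_equal(ld_sign(c(0, 0, 0, 0)), "CIS")    # tie -> CIS
  expect_error(ld_sign(c(1, 2, 3)), "four")
})

test_that("initial phasing copies homozygotes, imputes and chains hets", {
  # all-homozygous input: both haplotypes equal the allele expansion
  G <- rbind(c(0L, 1L, 0L), c(1L, 1L, 0L))
  H <- initial_phase(G)
  expect_equal(H$h1, G)
  expect_equal(H$h2, G)

  # one individual, one het site: canonical orientation
  H1 <- initial_phase(rbind(c(0L, 2L, 1L)))
  expect_equal(H1$h1[1, ], c(0L, 0L, 1L))
  expect_equal(H1$h2[1, ], c(0L, 1L, 1L))

  # CIS chain: hom rows 00,00,11,11 give D > 0 at the (1,2) pair
  G2 <- rbind(c(2L, 2L), c(0L, 0L), c(0L, 0L), c(1L, 1L), c(1L, 1L))
  H2 <- initial_phase(G2)
  expect_equal(H2$h1[1, ], c(0L, 0L))
  expect_equal(H2$h2[1, ], c(1L, 1L))

  # missing sites take the column major allele on both haplotypes + mask
  G3 <- rbind(c(NA, 1L), c(0L, 1L), c(0L, 1L))
  H3 <- initial_phase(G3)
  expect_equal(H3$h1[1, 1], 0L)
  expect_equal(H3$h2[1, 1], 0L)
  expect_true(H3$imputed[1, 1])
  expect_false(any(H3$imputed[-1, ]))

  # complementarity on random inputs
  for (seed in 1:5) {
    G <- random_genotypes(10, 30, p_missing = 0.05, seed = seed)
    expect_true(check_complementarity(initial_phase(G), G))
  }
})

test_that("window support and candidate weight match brute-force counting", {
  expect_equal(window_support("01", list("01", "01", "11")), 2L)
  expect_equal(window_support("01", list()), 0L)
  expect_error(window_support("01", list("011")), "lengths differ")

  withr_seed(42)
  for (rep in 1:5) {
    pool <- lapply(1:20, function(i) rbinom(6, 1, 0.5))
    frag <- pool[[sample(20, 1)]]
    expect_equal(window_support(frag, pool), naive_support(frag, pool))
  }

  # candidate_weight: empty pool at n = 1; symmetric in fragment order;
  # equals an independent recount
  G <- random_genotypes(8, 12, seed = 7)
  H <- random_phasing(G, 7)
  w <- c(3L, 8L)
  fragA <- H$h1[2, w[1]:w[2]]; fragB <- H$h2[2, w[1]:w[2]]
  expect_equal(candidate_weight(2, list(fragA, fragB), w, H),
               candidate_weight(2, list(fragB, fragA), w, H))
  pool <- list()
  for (j in setdiff(1:8, 2))
    pool <- c(pool, list(H$h1[j, w[1]:w[2]]), list(H$h2[j, w[1]:w[2]]))
  expect_equal(candidate_weight(2, list(fragA, fragB), w, H),
               naive_support(fragA, pool) + naive_support(fragB, pool))
  H1 <- phased_set(matrix(c(0L, 1L), 1), matrix(c(1L, 0L), 1))
  expect_equal(candidate_weight(1, list(c(0L, 1L), c(1L, 0L)), c(1L, 2L), H1),
               0L)
})

test_that("orientation refinement fixes a planted suffix flip and is idempotent", {
  withr_seed(9)
  m <- 30
  A <- rbinom(m, 1, 0.5); B <- 1L - A
  h1 <- matrix(rep(A, 10), nrow = 10, byrow = TRUE)
  h2 <- matrix(rep(B, 10), nrow = 10, byrow = TRUE)
  h1[10, 15:m] <- B[15:m]; h2[10, 15:m] <- A[15:m]
  G <- genotypes_from_haplotypes(phased_set(h1, h2))
  cfg <- core_config(l_min = 8, l_max = 16)
  H1 <- refine_orientation(phased_set(h1, h2), G, cfg)
  expect_true(all(H1$h1[10, ] == A) || all(H1$h1[10, ] == B))
  # idempotence on the converged configuration
  H2 <- refine_orientation(H1, G, cfg)
  expect_identical(H1$h1, H2$h1)
  expect_identical(H1$h2, H2$h2)

  # n = 1: nothing to support, nothing changes
  Gs <- rbind(c(2L, 0L, 2L, 2L))
  Hs <- initial_phase(Gs)
  Hr <- refine_orientation(Hs, Gs, core_config(l_min = 2, l_max = 4))
  expect_identical(Hr$h1, Hs$h1)

  # refinement only permutes alleles within pairs: column multisets fixed
  for (seed in 1:4) {
    pop <- coalescent_population(seed, N = 20, theta = 15)
    H0 <- initial_phase(pop$genotypes)
    HR <- refine_orientation(H0, pop$genotypes, core_config())
    expect_true(check_complementarity(HR, pop$genotypes))
    expect_equal(HR$h1 + HR$h2, H0$h1 + H0$h2)
  }
})

test_that("parsimony polishing consolidates pairs and never adds haplotypes", {
  # already-optimal input is untouched
  h <- matrix(rep(c(0L, 1L), 3), 3, 2, byrow = TRUE)
  G <- genotypes_from_haplotypes(phased_set(h, h))
  Hsame <- parsimony_refine(phased_set(h, h), G, core_config())
  expect_identical(Hsame$h1, h)

  # hand-enumerated two-site example: three all-het individuals, two phased
  # ("01","10") and one ("00","11"); flipping the third's suffix takes the
  # pool from 4 distinct haplotypes to 2
  G3 <- matrix(2L, 3, 2)
  h1 <- rbind(c(0L, 1L), c(0L, 1L), c(0L, 0L))
  h2 <- rbind(c(1L, 0L), c(1L, 0L), c(1L, 1L))
  expect_equal(distinct_haplotypes(phased_set(h1, h2)), 4L)
  Hp <- parsimony_refine(phased_set(h1, h2), G3, core_config())
  expect_equal(distinct_haplotypes(Hp), 2L)
  expect_equal(sort(c(paste(Hp$h1[3, ], collapse = ""),
                      paste(Hp$h2[3, ], collapse = ""))), c("01", "10"))

  # monotone on random fixtures, complementarity preserved
  for (seed in 1:5) {
    G <- random_genotypes(8, 25, seed = seed)
    H0 <- random_phasing(G, seed + 1)
    HP <- parsimony_refine(H0, G, core_config())
    expect_lte(distinct_haplotypes(HP), distinct_haplotypes(H0))
    expect_true(check_complementarity(HP, G))
    expect_equal(HP$h1 + HP$h2, H0$h1 + H0$h2)
  }
})

test_that("distinct haplotype counting equals the set-cardinality oracle", {
  expect_equal(distinct_haplotypes(
    phased_set(matrix(c(0L, 1L), 1), matrix(c(1L, 0L), 1))), 2L)
  h <- matrix(c(0L, 1L), 1)
  expect_equal(distinct_haplotypes(phased_set(h, h)), 1L)
  for (seed in 1:5) {
    G <- random_genotypes(10, 8, seed = seed)
    H <- random_phasing(G, seed)
    rows <- unique(c(apply(H$h1, 1, paste, collapse = ""),
                     apply(H$h2, 1, paste, collapse = "")))
    expect_equal(distinct_haplotypes(H), length(rows))
  }
})

test_that("phase_segment runs the three phases deterministically", {
  # all-homozygous segment is trivially phased
  G <- rbind(c(0L, 1L), c(1L, 0L))
  H <- phase_segment(G)
  expect_equal(H$h1, G)

  # identical genotype rows give identical pairs (up to within-pair order)
  pop <- founder_population(3, n = 12, m = 60)
  G2 <- rbind(pop$genotypes, pop$genotypes[1, ])
  H2 <- phase_segment(G2)
  n <- nrow(G2)
  pair_str <- function(H, i) sort(c(paste(H$h1[i, ], collapse = ""),
                                    paste(H$h2[i, ], collapse = "")))
  expect_equal(pair_str(H2, 1), pair_str(H2, n))

  # determinism: identical input + config -> bit-identical result
  G3 <- coalescent_population(5, N = 15, theta = 15)$genotypes
  Ha <- phase_segment(G3, core_config(seed = 11))
  Hb <- phase_segment(G3, core_config(seed = 11))
  expect_identical(Ha, Hb)

  # complementarity holds after every stage
  H0 <- initial_phase(G3)
  HR <- refine_orientation(H0, G3, core_config())
  HP <- parsimony_refine(HR, G3, core_config())
  for (H in list(H0, HR, HP)) expect_true(check_complementarity(H, G3))
})

test_that("low-diversity panels are recovered exactly", {
  # pure founder populations: <= 4 founders, n >= 10, m <= 200
  for (seed in 1:5) {
    pop <- founder_population(seed, n = 40, m = 200, n_founders = 4)
    H <- phase_segment(pop$genotypes, core_config())
    expect_equal(switch_error_rate(pop$truth, H)$ser, 0)
  }
})
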