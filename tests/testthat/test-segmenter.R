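test_that("segment plans partition sites with the short-tail merge rule", {
  p <- plan_segments(2500, 1000)
  expect_equal(p$start, c(1L, 1001L))
  expect_equal(p$end, c(1000L, 2500L))

  p3 <- plan_segments(3000, 1000)
  expect_equal(nrow(p3), 3L)
  expect_equal(p3$end, c(1000L, 2000L, 3000L))

  expect_equal(plan_segments(800, 1000)$end, 800L)
  expect_error(plan_segments(5000, 500), "force")
  expect_equal(nrow(plan_segments(5000, 500, force = TRUE)), 10L)

  # partition invariants over a range of sizes
  for (m in c(1, 999, 1000, 1001, 1999, 2000, 2001, 4500, 10000)) {
    p <- plan_segments(m, 1000)
    expect_equal(p$start[1], 1L)
    expect_equal(p$end[nrow(p)], m)
    if (nrow(p) > 1) {
      expect_equal(p$start[-1], head(p$end, -1) + 1L)
      expect_true(all(p$end - p$start + 1L >= 1000L))
    }
    # at most one interval longer than s, and it stays below s + 1000
    len <- p$end - p$start + 1L
    expect_lte(sum(len > 1000L), 1L)
    expect_true(all(len < 2000L))
  }
})

test_that("junction cases classify by het availability", {
  lmax <- 8L
  hetful <- rep(c(0L, 2L), 10)
  expect_equal(classify_case(hetful, hetful, lmax), "NORMAL")
  # left segment entirely het-free
  expect_equal(classify_case(rep(0L, 20), hetful, lmax), "CASE3")
  expect_equal(classify_case(hetful, rep(1L, 20), lmax), "CASE3")
  # hets exist but only outside the scope window on both sides
  far_left <- c(2L, rep(0L, 19))           # het 19 sites from the junction
  far_right <- c(rep(0L, 19), 2L)
  expect_equal(classify_case(far_left, far_right, lmax), "CASE2")
  expect_equal(classify_case(far_left, hetful, lmax), "CASE1")
  expect_equal(classify_case(hetful, far_right, lmax), "CASE1")
})

test_that("junction merging picks one of the two pairings and matches the oracle", {
  # the merged result is exactly the left pair extended by one of the two
  # right haplotypes, for every individual
  withr_seed(21)
  pop <- founder_population(21, n = 12, m = 40)
  plan <- plan_segments(40, 20, force = TRUE)
  cfg <- core_config(l_min = 4, l_max = 8)
  Hl <- phase_segment(pop$genotypes[, 1:20], cfg)
  Hr <- phase_segment(pop$genotypes[, 21:40], cfg)
  out <- merge_junction(Hl, Hr, pop$genotypes, 1, plan, cfg)
  for (i in 1:12) {
    straight <- c(Hl$h1[i, ], Hr$h1[i, ])
    cross <- c(Hl$h1[i, ], Hr$h2[i, ])
    expect_true(identical(out$merged$h1[i, ], straight) ||
                identical(out$merged$h1[i, ], cross))
  }
  # merged result restricted to the left segment equals the left phasing
  expect_identical(out$merged$h1[, 1:20], Hl$h1)

  # NORMAL decisions equal the exhaustive two-pairing oracle
  for (i in which(out$decisions$case == "NORMAL" & !out$decisions$fallback)) {
    expect_equal(out$decisions$choice[i],
                 naive_junction_choice(Hl, Hr, pop$genotypes, i, 1, plan, cfg))
  }

  # CASE3 choices are reproducible across runs with the same seed
  Gq <- cbind(matrix(0L, 6, 20), random_genotypes(6, 20, seed = 3))
  Hq1 <- phase_segment(Gq[, 1:20], cfg)
  Hq2 <- phase_segment(Gq[, 21:40], cfg)
  o1 <- merge_junction(Hq1, Hq2, Gq, 1, plan, cfg)
  o2 <- merge_junction(Hq1, Hq2, Gq, 1, plan, cfg)
  expect_true(all(o1$decisions$case == "CASE3"))
  expect_identical(o1$decisions$choice, o2$decisions$choice)
})

test_that("merging folds segments into a complementary whole", {
  # a single segment is the identity
  G1 <- random_genotypes(5, 30, seed = 2)
  plan1 <- plan_segments(30, 1000)
  H1 <- phase_segment(G1)
  expect_identical(merge_all(list(H1), G1, plan1)$h1, H1$h1)

  # identical individuals across k segments: junction decisions must keep
  # every individual consistent with every other, so the merged result has
  # zero switch errors against any one individual's phasing
  withr_seed(8)
  A <- rbinom(60, 1, 0.5); B <- 1L - A
  h1 <- matrix(rep(A, 8), 8, byrow = TRUE)
  h2 <- matrix(rep(B, 8), 8, byrow = TRUE)
  G <- genotypes_from_haplotypes(phased_set(h1, h2))
  plan <- plan_segments(60, 20, force = TRUE)
  cfg <- core_config(l_min = 4, l_max = 8)
  segs <- lapply(seq_len(nrow(plan)), function(f)
    phase_segment(G[, plan$start[f]:plan$end[f], drop = FALSE], cfg))
  H <- merge_all(segs, G, plan, cfg)
  ref <- phased_set(matrix(rep(H$h1[1, ], 8), 8, byrow = TRUE),
                    matrix(rep(H$h2[1, ], 8), 8, byrow = TRUE))
  expect_equal(switch_error_rate(ref, H)$ser, 0)
  expect_true(check_complementarity(H, G))

  # complementarity of the full result on random fixtures
  for (seed in 4:6) {
    pop <- coalescent_population(seed, N = 12, theta = 30)
    m <- ncol(pop$genotypes)
    plan <- plan_segments(m, max(20, m %/% 3), force = TRUE)
    segs <- lapply(seq_len(nrow(plan)), function(f)
      phase_segment(pop$genotypes[, plan$start[f]:plan$end[f], drop = FALSE],
                    cfg))
    H <- merge_all(segs, pop$genotypes, plan, cfg)
    expect_true(check_complementarity(H, pop$genotypes))
  }
})

test_that("the pipeline is parallel-deterministic and segment-consistent", {
  pop <- coalescent_population(13, N = 15, theta = 60)
  G <- pop$genotypes
  cfg <- core_config(seed = 5)
  H1 <- run_pipeline(G, s = max(1000, ncol(G)), cfg = cfg, threads = 1)
  # m <= s: the pipeline is phase_segment alone
  expect_identical(H1$h1,
                   phase_segment(G, {cfg2 <- cfg
                     cfg2$seed <- segphase:::cpp_derive_seed(cfg$seed, 1L)
                     cfg2})$h1)

  # threads > 1 must be bit-identical to serial
  Gm <- do.call(cbind, lapply(1:4, function(i)
    coalescent_population(20 + i, N = 15, theta = 60)$genotypes))
  plan_s <- ceiling(ncol(Gm) / 3)
  Hs <- run_pipeline(Gm, s = plan_s, cfg = cfg, threads = 1, force = TRUE)
  Hp <- run_pipeline(Gm, s = plan_s, cfg = cfg, threads = 4, force = TRUE)
  expect_identical(Hs$h1, Hp$h1)
  expect_identical(Hs$h2, Hp$h2)
  expect_identical(attr(Hs, "decisions")$choice, attr(Hp, "decisions")$choice)

  # CASE3 junctions are rare on coalescent-style data
  dec <- attr(Hs, "decisions")
  expect_lt(mean(dec$case == "CASE3"), 0.01)
})
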