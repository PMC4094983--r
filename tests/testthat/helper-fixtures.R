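# Fixture generators and naive reference implementations used as
# independent oracles across the suite. Everything is seeded and built in
# code; no fixture files.

# random genotype matrix with optional missing calls
random_genotypes <- function(n, m, p_het = 0.3, p_missing = 0, seed = 1) {
  withr_seed(seed)
  G <- matrix(sample(0:2, n * m, replace = TRUE,
                     prob = c((1 - p_het) / 2, (1 - p_het) / 2, p_het)),
              n, m)
  if (p_missing > 0) G[matrix(runif(n * m) < p_missing, n, m)] <- NA_integer_
  storage.mode(G) <- "integer"
  G
}

# a random valid phasing of a genotype matrix
random_phasing <- function(G, seed = 1) {
  withr_seed(seed)
  n <- nrow(G); m <- ncol(G)
  h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
  imp <- is.na(G)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    g <- G[i, j]
    if (is.na(g)) { h1[i, j] <- 0L; h2[i, j] <- 0L }
    else if (g == 0L) { h1[i, j] <- 0L; h2[i, j] <- 0L }
    else if (g == 1L) { h1[i, j] <- 1L; h2[i, j] <- 1L }
    else { a <- sample(0:1, 1); h1[i, j] <- a; h2[i, j] <- 1L - a }
  }
  phased_set(h1, h2, imp)
}

# population of pure founder pairs (low-diversity panel)
founder_population <- function(seed, n = 40, m = 200, n_founders = 4) {
  withr_seed(seed)
  founders <- matrix(rbinom(n_founders * m, 1, 0.5), n_founders, m)
  f1 <- sample(n_founders, n, replace = TRUE)
  f2 <- sample(n_founders, n, replace = TRUE)
  truth <- phased_set(founders[f1, , drop = FALSE],
                      founders[f2, , drop = FALSE])
  list(truth = truth, genotypes = genotypes_from_haplotypes(truth),
       founders = founders)
}

# coalescent truth + genotypes via one block
coalescent_population <- function(seed, N = 30, theta = 20, missing = 0) {
  withr_seed(seed)
  B <- simulate_block(2 * N, theta)
  truth <- phased_set(B[seq(1, 2 * N, 2), , drop = FALSE],
                      B[seq(2, 2 * N, 2), , drop = FALSE])
  G <- genotypes_from_haplotypes(truth)
  if (missing > 0) G <- inject_missing(G, missing)
  list(truth = truth, genotypes = G)
}

withr_seed <- function(seed) {
  set.seed(seed)
  invisible(NULL)
}

# ---- naive oracles -------------------------------------------------------

naive_gamete_counts <- function(G, s, t) {
  out <- c(n00 = 0L, n01 = 0L, n10 = 0L, n11 = 0L)
  for (i in seq_len(nrow(G))) {
    a <- G[i, s]; b <- G[i, t]
    if (is.na(a) || is.na(b)) next
    if (a == 2L && b == 2L) next
    if (a != 2L && b != 2L) {
      key <- paste0("n", a, b); out[key] <- out[key] + 2L
    } else if (a != 2L) {
      out[paste0("n", a, 0L)] <- out[paste0("n", a, 0L)] + 1L
      out[paste0("n", a, 1L)] <- out[paste0("n", a, 1L)] + 1L
    } else {
      out[paste0("n", 0L, b)] <- out[paste0("n", 0L, b)] + 1L
      out[paste0("n", 1L, b)] <- out[paste0("n", 1L, b)] + 1L
    }
  }
  out
}

naive_support <- function(fragment, pool_rows) {
  sum(vapply(pool_rows, function(p) identical(as.integer(p),
                                              as.integer(fragment)),
             logical(1)))
}

# brute-force switch errors: try both truth labelings, count orientation
# flips, take the minimum
naive_switch_errors <- function(true_pair, inf_pair, exclude = NULL) {
  t1 <- true_pair[[1]]; t2 <- true_pair[[2]]
  i1 <- inf_pair[[1]]
  keep <- if (is.null(exclude)) rep(TRUE, length(t1)) else !exclude
  het <- keep & (t1 + t2) == 1L
  if (sum(het) < 2) return(0L)
  count_flips <- function(ref) {
    o <- as.integer(i1[het] != ref[het])
    sum(diff(o) != 0L)
  }
  min(count_flips(t1), count_flips(t2))
}

# exhaustive junction oracle: evaluates both pairings at every valid
# placement of an l_max window across the junction, straight pool
naive_junction_choice <- function(H_f, H_f1, G, i, f, plan, cfg) {
  e <- plan$end[f]; start_f <- plan$start[f]
  end_g <- plan$end[f + 1]
  lmax <- cfg$l_max
  n <- nrow(G)
  hets <- function(ii, lo, hi) {
    w <- which(!is.na(G[ii, lo:hi]) & G[ii, lo:hi] == 2L)
    if (length(w)) lo + w - 1L else integer(0)
  }
  best_s <- -1; best_c <- -1
  for (a in seq(max(start_f, e - lmax + 2L), min(e, end_g - lmax + 1L))) {
    b <- a + lmax - 1L
    if (a > e || b <= e) next
    hl <- hets(i, a, e); hr <- hets(i, e + 1L, b)
    if (length(hl) == 0 || length(hr) == 0) next
    frag <- function(ii, which_l, which_r) {
      lcols <- (a - start_f + 1L):(e - start_f + 1L)
      rcols <- 1L:(b - e)
      c(if (which_l == 1) H_f$h1[ii, lcols] else H_f$h2[ii, lcols],
        if (which_r == 1) H_f1$h1[ii, rcols] else H_f1$h2[ii, rcols])
    }
    pool <- list()
    for (j in setdiff(seq_len(n), i))
      pool <- c(pool, list(frag(j, 1, 1)), list(frag(j, 2, 2)))
    ws <- naive_support(frag(i, 1, 1), pool) + naive_support(frag(i, 2, 2), pool)
    wc <- naive_support(frag(i, 1, 2), pool) + naive_support(frag(i, 2, 1), pool)
    if (ws > best_s) best_s <- ws
    if (wc > best_c) best_c <- wc
  }
  if (best_s < 0 && best_c < 0) return(NULL)  # no valid placement
  if (best_c > best_s) "CROSS" else "STRAIGHT"
}
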