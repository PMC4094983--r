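# Synthetic truth generator: neutral-coalescent haplotype blocks (infinite
# sites, no intra-block recombination) concatenated to a target SNP count,
# consecutive pairing into diploid genotypes, optional missing-data
# injection, and random pairing of externally supplied haplotype panels.

#' Simulation parameters
#'
#' @param N number of diploid genotypes to simulate.
#' @param M target SNP count.
#' @param theta per-block population mutation parameter (default 5.0).
#' @param rho recombination parameter of the emulated datasets; recorded for
#'   provenance. Blocks are mutually independent, which acts as free
#'   recombination between blocks; intra-block recombination is not
#'   simulated (feed genuine `ms` output through [read_ms()] when exact
#'   replication is needed).
#' @param block_sites nominal sequence length per block (default 2501);
#'   recorded for provenance, the realised column count per block is its
#'   segregating-site count.
#' @param missing_rate per-cell probability of replacing a genotype call
#'   with missing.
#' @param seed integer seed; all generator randomness flows from it.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(N, M, theta = 5.0, rho = 100, block_sites = 2501L,
                       missing_rate = 0, seed = 1L) {
  N <- as.integer(N); M <- as.integer(M)
  if (is.na(N) || N < 1L || is.na(M) || M < 1L)
    stop("need N >= 1 and M >= 1", call. = FALSE)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  structure(list(N = N, M = M, theta = theta, rho = rho,
                 block_sites = as.integer(block_sites),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_params")
}

#' Simulate one coalescent haplotype block
#'
#' Standard neutral coalescent without recombination under the
#' infinite-sites model: exponential coalescence waiting times at rate
#' `choose(j, 2)` (time in units of 2N generations) and
#' `Poisson(theta / 2 * total branch length)` mutations, one column per
#' mutation, ordered by a uniform mutation position. Every column is
#' polymorphic. Uses the current R RNG state.
#'
#' @param n_hap number of haplotypes (>= 2).
#' @param theta mutation parameter.
#' @return integer matrix (`n_hap` rows) over \{0, 1\} with a `positions`
#'   attribute; `theta = 0` gives zero columns.
#' @export
simulate_block <- function(n_hap, theta) {
  n_hap <- as.integer(n_hap)
  if (is.na(n_hap) || n_hap < 2L) stop("n_hap must be >= 2", call. = FALSE)
  if (theta < 0) stop("theta must be >= 0", call. = FALSE)
  cpp_simulate_block(n_hap, theta)
}

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a truth/genotype dataset
#'
#' Concatenates independent coalescent blocks of `2 * N` haplotypes until at
#' least `M` columns exist, trims to exactly `M`, pairs haplotypes
#' `(2i - 1, 2i)` into genotype `i` and injects missing calls at
#' `missing_rate`. Deterministic given `p$seed`.
#'
#' @param p a [sim_params()].
#' @return list with `truth` (a [phased_set()]), `genotypes` (matrix with
#'   missing as `NA`) and `n_blocks` (number of blocks used).
#' @export
simulate_dataset <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (p$theta == 0) stop("theta = 0 cannot produce segregating sites",
                         call. = FALSE)
  with_preserved_seed(p$seed, {
    n_hap <- 2L * p$N
    mats <- list(); tot <- 0L
    while (tot < p$M) {
      B <- cpp_simulate_block(n_hap, p$theta)
      if (ncol(B) > 0L) {
        mats[[length(mats) + 1L]] <- B
        tot <- tot + ncol(B)
      }
    }
    H <- do.call(cbind, mats)[, seq_len(p$M), drop = FALSE]
    h1 <- H[seq(1L, n_hap, 2L), , drop = FALSE]
    h2 <- H[seq(2L, n_hap, 2L), , drop = FALSE]
    truth <- phased_set(h1, h2)
    G <- implied_genotypes(truth)
    if (p$missing_rate > 0) G <- inject_missing(G, p$missing_rate)
    list(truth = truth, genotypes = G, n_blocks = length(mats))
  })
}

#' Randomly pair haplotypes into genotypes
#'
#' Samples `2 * n_pairs` rows without replacement from a haplotype panel and
#' pairs them consecutively, emulating the construction of genotype
#' datasets from reference haplotype panels. Uses the current RNG state.
#'
#' @param haps haplotype matrix over \{0, 1\} (one haplotype per row).
#' @param n_pairs number of diploid genotypes to form.
#' @return list with `truth` (a [phased_set()]) and `genotypes`.
#' @export
pair_random <- function(haps, n_pairs) {
  stopifnot(is.matrix(haps))
  n_pairs <- as.integer(n_pairs)
  if (nrow(haps) < 2L * n_pairs)
    stop("need at least 2 * n_pairs haplotype rows", call. = FALSE)
  pick <- sample.int(nrow(haps), 2L * n_pairs)
  h1 <- haps[pick[seq(1L, 2L * n_pairs, 2L)], , drop = FALSE]
  h2 <- haps[pick[seq(2L, 2L * n_pairs, 2L)], , drop = FALSE]
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  truth <- phased_set(h1, h2)
  list(truth = truth, genotypes = implied_genotypes(truth))
}

#' Inject missing genotype calls
#'
#' Each cell is independently replaced by missing (`NA`) with probability
#' `rate`. Uses the current RNG state.
#'
#' @param G genotype matrix.
#' @param rate missing probability in `[0, 1)`.
#' @return genotype matrix with missing cells.
#' @export
inject_missing <- function(G, rate) {
  G <- validate_genotypes(G)
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(G)
  drop <- matrix(runif(length(G)) < rate, nrow(G), ncol(G))
  G[drop] <- NA_integer_
  G
}
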