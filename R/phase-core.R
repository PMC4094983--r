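# Three-phase per-segment phasing core:
#   1. initial_phase    - LD-sign chaining of heterozygous sites
#   2. refine_orientation - scalable sliding-window suffix-orientation moves
#   3. parsimony_refine - hill climb on the distinct-haplotype count
# The heavy sweeps live in compiled code; the exported support operations
# are exact R implementations that double as independent oracles in tests.

#' Core configuration
#'
#' @param l_min minimum window length (sites) for orientation refinement.
#' @param l_max maximum window length; window lengths scale geometrically
#'   (x2) from `l_min` to `l_max`, and `l_max` is also the junction-merge
#'   window length.
#' @param refine_passes number of refinement sweeps (each sweep scores all
#'   breakpoints and stops early if nothing changes).
#' @param parsimony_passes cap on parsimony hill-climb sweeps.
#' @param seed integer seed controlling the only stochastic choice in the
#'   pipeline (the pairing draw at heterozygote-free junctions).
#' @return object of class `core_config`.
#' @export
core_config <- function(l_min = 8L, l_max = 64L, refine_passes = 2L,
                        parsimony_passes = 3L, seed = 1L,
                        refine_mode = c("auto", "repair", "consolidate",
                                        "argmax")) {
  l_min <- as.integer(l_min); l_max <- as.integer(l_max)
  if (is.na(l_min) || l_min < 2L || l_max < l_min)
    stop("need 2 <= l_min <= l_max", call. = FALSE)
  refine_passes <- as.integer(refine_passes)
  parsimony_passes <- as.integer(parsimony_passes)
  if (refine_passes < 0L || parsimony_passes < 0L)
    stop("pass counts must be >= 0", call. = FALSE)
  structure(list(l_min = l_min, l_max = l_max,
                 refine_passes = refine_passes,
                 parsimony_passes = parsimony_passes,
                 seed = as.integer(seed),
                 refine_mode = match.arg(refine_mode)),
            class = "core_config")
}

# Mean number of distinct genotype row patterns across (at most 32 evenly
# spaced) windows of length l. Phase-independent regime statistic: at most
# K(K+3)/2 diplotype patterns can arise from K founder haplotypes, so a
# panel whose windows show <= 16 distinct patterns behaves like a
# low-diversity (few-founder) population.
window_genotype_diversity <- function(G, l = 64L) {
  m <- ncol(G)
  if (m <= l) {
    return(length(unique(apply(G, 1L, paste, collapse = ","))))
  }
  pos <- unique(round(seq(1L, m - l + 1L, length.out = 32L)))
  mean(vapply(pos, function(a) {
    length(unique(apply(G[, a:(a + l - 1L), drop = FALSE], 1L,
                        paste, collapse = ",")))
  }, numeric(1L)))
}

#' Two-site unambiguous gamete counts
#'
#' Counts the gametes whose two-site composition is determined by the
#' genotypes alone: an individual homozygous at both sites contributes two
#' identical gametes; homozygous at exactly one site, one gamete to each of
#' the two cells compatible with the homozygote; double-heterozygous or
#' missing individuals contribute nothing.
#'
#' @param G genotype matrix.
#' @param s,t distinct 1-based site indices.
#' @return named integer vector `c(n00, n01, n10, n11)`.
#' @export
gamete_counts <- function(G, s, t) {
  G <- validate_genotypes(G)
  s <- as.integer(s); t <- as.integer(t)
  if (is.na(s) || is.na(t) || s < 1L || t < 1L || s > ncol(G) || t > ncol(G))
    stop("site index out of range", call. = FALSE)
  if (s == t) stop("sites must be distinct", call. = FALSE)
  out <- cpp_gamete_counts(G, s - 1L, t - 1L)
  stats::setNames(as.integer(out), c("n00", "n01", "n10", "n11"))
}

#' Sign of the two-site LD statistic
#'
#' `D = n00 * n11 - n01 * n10`; `D >= 0` is called `"CIS"` (allele 0 at the
#' first site co-resides with allele 0 at the second), `D < 0` is
#' `"TRANS"`. The tie `D == 0` resolves to CIS for determinism.
#'
#' @param counts gamete counts as returned by [gamete_counts()].
#' @return `"CIS"` or `"TRANS"`.
#' @export
ld_sign <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0))
    stop("counts must be four nonnegative numbers", call. = FALSE)
  D <- counts[1L] * counts[4L] - counts[2L] * counts[3L]
  if (D >= 0) "CIS" else "TRANS"
}

#' Initial phasing (phase 1)
#'
#' Homozygous sites are copied to both haplotypes, missing sites are imputed
#' to the column's major allele (a het call counts as one of each allele)
#' and masked, and each individual's heterozygous sites are chained left to
#' right: the first het site takes the canonical orientation (allele 0 on
#' `h1`), and each later het site is oriented relative to the previous one
#' by [ld_sign()] of their [gamete_counts()].
#'
#' @param G genotype matrix.
#' @param cfg a [core_config()] (unused by this phase beyond its contract).
#' @return a [phased_set()].
#' @export
initial_phase <- function(G, cfg = core_config()) {
  G <- validate_genotypes(G)
  res <- cpp_initial_phase(G)
  phased_set(res$h1, res$h2, res$imputed)
}

#' Exact-match support of a fragment in a pool
#'
#' @param fragment allele vector (integer vector or string over \{0, 1\}).
#' @param pool list of allele vectors, or a matrix with one fragment per
#'   row; all the same length as `fragment`.
#' @return number of pool members identical to `fragment`.
#' @export
window_support <- function(fragment, pool) {
  frag <- as_allele_vector(fragment)
  if (is.matrix(pool)) pool <- asplit(pool, 1L)
  if (length(pool) == 0L) return(0L)
  pool <- lapply(pool, as_allele_vector)
  if (any(vapply(pool, length, 1L) != length(frag)))
    stop("fragment and pool lengths differ", call. = FALSE)
  sum(vapply(pool, function(p) all(p == frag), logical(1L)))
}

as_allele_vector <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- strsplit(x, "", fixed = TRUE)[[1L]]
  x <- as.integer(x)
  if (any(is.na(x)) || !all(x %in% 0:1))
    stop("alleles must be 0 or 1", call. = FALSE)
  x
}

#' Support weight of a candidate haplotype pair in a window
#'
#' The weight of a candidate restriction of individual `i` to the window is
#' the summed exact-match support of its two fragments in the pool of the
#' `2(n-1)` current haplotype fragments of all other individuals restricted
#' to the same window.
#'
#' @param i individual index (1-based).
#' @param pair list of the two candidate fragments (each an allele vector or
#'   string) spanning the window.
#' @param window integer vector `c(start, end)`, 1-based inclusive.
#' @param H the current [phased_set()].
#' @return integer weight.
#' @export
candidate_weight <- function(i, pair, window, H) {
  stopifnot(inherits(H, "phased_set"))
  cols <- window[1L]:window[2L]
  others <- setdiff(seq_len(nrow(H$h1)), i)
  pool <- rbind(H$h1[others, cols, drop = FALSE],
                H$h2[others, cols, drop = FALSE])
  window_support(pair[[1L]], pool) + window_support(pair[[2L]], pool)
}

#' Sliding-window orientation refinement (phase 2)
#'
#' For every breakpoint (the gap between an individual's consecutive het
#' sites) both relative orientations of the suffix are scored by the
#' [candidate_weight()] exact-match support over windows of length
#' `l_min, 2*l_min, ..., <= l_max` that keep a het site of the individual
#' on both sides of the gap, and the better-supported orientation is
#' adopted; ties keep the current orientation. Sweeps repeat up to
#' `refine_passes` times, stopping early once a sweep changes nothing.
#' Only relative orientations change: the per-site allele multiset of each
#' pair is untouched.
#'
#' How aggressively flips are accepted depends on `cfg$refine_mode`:
#' \describe{
#'   \item{`"consolidate"`}{progressive sweep (windows left to right,
#'     short lengths first, flips applied immediately); any window
#'     preferring the flip applies it. Right for low-diversity panels,
#'     where every true haplotype is common and an unsupported fragment is
#'     almost surely a phase error.}
#'   \item{`"repair"`}{progressive sweep (longest windows first), but a
#'     flip must be a corroborated repair: the current pair must contain a
#'     zero-support fragment and both flipped fragments must have support.
#'     Right for diverse panels, where an unsupported fragment is often a
#'     genuine rare haplotype that support counting cannot certify.}
#'   \item{`"argmax"`}{batch sweep; a breakpoint flips when the single
#'     best flip weight over all windows beats the single best keep
#'     weight.}
#'   \item{`"auto"` (default)}{picks `"consolidate"` when the mean number
#'     of distinct genotype window patterns is at most 16 (at most
#'     K(K+3)/2 diplotype patterns can arise from K founders, so 16
#'     corresponds to roughly four or five founder haplotypes), otherwise
#'     `"repair"`.}
#' }
#'
#' @param H current [phased_set()] complementing `G`.
#' @param G genotype matrix.
#' @param cfg a [core_config()].
#' @return refined [phased_set()].
#' @export
refine_orientation <- function(H, G, cfg = core_config()) {
  G <- validate_genotypes(G)
  check_complementarity(H, G)
  mode <- cfg$refine_mode
  if (is.null(mode)) mode <- "auto"
  if (mode == "auto")
    mode <- if (window_genotype_diversity(G, cfg$l_max) <= 16)
      "consolidate" else "repair"
  mode_i <- c(argmax = 0L, consolidate = 1L, repair = 2L)[[mode]]
  res <- cpp_refine(G, H$h1, H$h2, cfg$l_min, cfg$l_max, cfg$refine_passes,
                    mode_i)
  phased_set(res$h1, res$h2, H$imputed)
}

#' Maximum-parsimony polish (phase 3)
#'
#' Hill climb over the same suffix-orientation moves: a move is accepted
#' only if it strictly reduces the number of distinct haplotypes in the
#' 2n-row pool, or keeps that count while strictly increasing the summed
#' pool multiplicity of every individual's two haplotypes (equivalently the
#' sum of squared multiplicities). Sweeps run in deterministic order until
#' no move is accepted or `parsimony_passes` is reached. The
#' distinct-haplotype count never increases.
#'
#' @inheritParams refine_orientation
#' @return polished [phased_set()].
#' @export
parsimony_refine <- function(H, G, cfg = core_config()) {
  G <- validate_genotypes(G)
  check_complementarity(H, G)
  res <- cpp_parsimony(G, H$h1, H$h2, cfg$parsimony_passes)
  phased_set(res$h1, res$h2, H$imputed)
}

#' Number of distinct haplotypes in a phased set
#'
#' @param H a [phased_set()].
#' @return cardinality of the set of distinct allele vectors among all 2n
#'   haplotypes.
#' @export
distinct_haplotypes <- function(H) {
  stopifnot(inherits(H, "phased_set"))
  nrow(unique(rbind(H$h1, H$h2)))
}

#' Phase one segment
#'
#' Runs the three phases in order: [initial_phase()],
#' [refine_orientation()], [parsimony_refine()]. Deterministic given the
#' configuration.
#'
#' @param G_seg genotype matrix of the segment.
#' @param cfg a [core_config()].
#' @return a [phased_set()] for the segment.
#' @export
phase_segment <- function(G_seg, cfg = core_config()) {
  H <- initial_phase(G_seg, cfg)
  H <- refine_orientation(H, G_seg, cfg)
  parsimony_refine(H, G_seg, cfg)
}
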