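# Accuracy metrics against truth haplotypes: switch error rate (SER) and
# individual error rate (IER). Imputed (originally missing) sites are
# excluded from both metrics.

as_pair <- function(pair) {
  a <- as_allele_vector(pair[[1L]])
  b <- as_allele_vector(pair[[2L]])
  if (length(a) != length(b)) stop("pair lengths differ", call. = FALSE)
  list(a, b)
}

#' Switch errors for one individual
#'
#' Counts flips in the relative orientation of consecutive heterozygous
#' sites between an inferred haplotype pair and the truth. The orientation
#' is anchored at the first het site (equivalently, the truth labeling
#' minimising errors is chosen). Individuals with fewer than two het sites
#' have zero switch errors.
#'
#' @param true_pair,inferred_pair lists of two haplotype vectors (integer
#'   vectors or strings over \{0, 1\}) complementing the same genotype.
#' @param exclude optional logical vector of sites to ignore (imputed
#'   sites).
#' @return integer switch error count.
#' @export
switch_errors_individual <- function(true_pair, inferred_pair,
                                     exclude = NULL) {
  tp <- as_pair(true_pair); ip <- as_pair(inferred_pair)
  if (length(tp[[1L]]) != length(ip[[1L]]))
    stop("pair lengths differ", call. = FALSE)
  keep <- if (is.null(exclude)) rep(TRUE, length(tp[[1L]])) else !exclude
  gt <- tp[[1L]] + tp[[2L]]
  gi <- ip[[1L]] + ip[[2L]]
  if (any(gt[keep] != gi[keep]))
    stop("pairs do not complement the same genotype", call. = FALSE)
  het <- keep & gt == 1L
  if (sum(het) < 2L) return(0L)
  o <- as.integer(ip[[1L]][het] != tp[[1L]][het])
  sum(diff(o) != 0L)
}

eval_full <- function(H_true, H_inf, denominator = "het") {
  stopifnot(inherits(H_true, "phased_set"), inherits(H_inf, "phased_set"))
  if (!all(dim(H_true$h1) == dim(H_inf$h1)))
    stop("phased sets have different dimensions", call. = FALSE)
  n <- nrow(H_true$h1)
  excl <- H_true$imputed | H_inf$imputed
  gt <- H_true$h1 + H_true$h2
  gi <- H_inf$h1 + H_inf$h2
  if (any((gt != gi)[!excl]))
    stop("phased sets do not share the same underlying genotypes",
         call. = FALSE)
  het <- gt == 1L & !excl
  o <- (H_inf$h1 != H_true$h1)
  switches <- integer(n)
  wrong <- logical(n)
  for (i in seq_len(n)) {
    hi <- which(het[i, ])
    if (length(hi) == 0L) next
    oi <- o[i, hi]
    wrong[i] <- !all(oi == oi[1L])
    if (length(hi) >= 2L) switches[i] <- sum(diff(oi) != 0L)
  }
  het_i <- rowSums(het)
  denom <- if (denominator == "het") sum(het_i) else sum(pmax(het_i - 1L, 0L))
  structure(list(switch_errors = sum(switches),
                 het_loci = sum(het_i),
                 incorrect_individuals = sum(wrong),
                 n = n,
                 ser = if (denom > 0L) sum(switches) / denom else 0,
                 ier = sum(wrong) / n,
                 denominator = denominator,
                 per_individual = data.frame(individual = seq_len(n),
                                             switches = switches,
                                             het = het_i,
                                             incorrect = wrong)),
            class = "phase_eval")
}

#' @export
#' @method print phase_eval
print.phase_eval <- function(x, ...) {
  cat(sprintf(
    "<phase_eval> n = %d | switch errors = %d / %d het loci | SER = %.5f | IER = %.4f\n",
    x$n, x$switch_errors, x$het_loci, x$ser, x$ier))
  invisible(x)
}

#' Switch error rate
#'
#' `SER = (total switch errors) / (total heterozygous loci)`, summed over
#' individuals. The default denominator is the total het-locus count; the
#' `"het-1"` convention (het count minus one per individual) is also
#' available. Invariant to within-pair label swaps on either side; imputed
#' sites are excluded.
#'
#' @param H_true,H_inf truth and inferred [phased_set()]s over the same
#'   genotypes.
#' @param denominator `"het"` (default) or `"het-1"`.
#' @return object of class `phase_eval` with fields `switch_errors`,
#'   `het_loci`, `incorrect_individuals`, `n`, `ser`, `ier`.
#' @export
switch_error_rate <- function(H_true, H_inf,
                              denominator = c("het", "het-1")) {
  eval_full(H_true, H_inf, match.arg(denominator))
}

#' Individual error rate
#'
#' Fraction of individuals whose inferred pair differs from the truth pair
#' under both labelings (non-imputed sites only). Any individual with at
#' least one switch error counts as incorrect.
#'
#' @inheritParams switch_error_rate
#' @return object of class `phase_eval` (see [switch_error_rate()]).
#' @export
individual_error_rate <- function(H_true, H_inf,
                                  denominator = c("het", "het-1")) {
  eval_full(H_true, H_inf, match.arg(denominator))
}
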