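# Divide-and-conquer orchestration: segment planning, per-segment phasing,
# junction merging with the weight-based sliding window and the three
# heterozygote-free boundary cases, and the (optionally parallel) pipeline.

#' Plan segments
#'
#' Partitions `[1, m]` into consecutive intervals of nominal size `s`. A
#' final remainder shorter than 1,000 sites is merged into the penultimate
#' interval; an input shorter than `s` yields a single interval. Segment
#' sizes below 1,000 hurt phasing accuracy near segment edges, so `s < 1000`
#' is refused unless `force = TRUE`.
#'
#' @param m number of sites.
#' @param s nominal segment size (default 1000).
#' @param force allow `s < 1000` (expert use).
#' @return data frame of class `segment_plan` with columns `segment`,
#'   `start`, `end` (1-based, inclusive) and attribute `s`.
#' @export
plan_segments <- function(m, s = 1000L, force = FALSE) {
  m <- as.integer(m); s <- as.integer(s)
  if (is.na(m) || m < 1L) stop("m must be >= 1", call. = FALSE)
  if (is.na(s) || s < 1L) stop("s must be >= 1", call. = FALSE)
  if (s < 1000L && !force)
    stop("segment size below 1000 sites degrades accuracy; use force = TRUE to override",
         call. = FALSE)
  k <- m %/% s
  if (k == 0L) {
    ends <- m
  } else {
    ends <- seq.int(s, by = s, length.out = k)
    rem <- m - k * s
    if (rem > 0L) {
      if (rem < 1000L) ends[k] <- m else ends <- c(ends, m)
    }
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  plan <- data.frame(segment = seq_along(starts), start = starts,
                     end = as.integer(ends))
  attr(plan, "s") <- s
  class(plan) <- c("segment_plan", "data.frame")
  plan
}

#' Classify a junction for one individual
#'
#' The scope window around a junction covers the last `l_max - 1` sites of
#' the left segment and the first `l_max - 1` sites of the right segment.
#' Classification (checked in this order):
#' \describe{
#'   \item{CASE3}{at least one side has no het site anywhere in its segment}
#'   \item{CASE2}{neither side has a het site inside the scope window}
#'   \item{CASE1}{exactly one side has no het site inside the scope window}
#'   \item{NORMAL}{both sides have hets inside the scope window}
#' }
#'
#' @param g_left,g_right the individual's genotype vectors on the left and
#'   right segment.
#' @param l_max maximum window length.
#' @return one of `"NORMAL"`, `"CASE1"`, `"CASE2"`, `"CASE3"`.
#' @export
classify_case <- function(g_left, g_right, l_max = 64L) {
  hl <- !is.na(g_left) & g_left == 2L
  hr <- !is.na(g_right) & g_right == 2L
  if (!any(hl) || !any(hr)) return("CASE3")
  wl <- any(tail(hl, l_max - 1L))
  wr <- any(head(hr, l_max - 1L))
  if (!wl && !wr) return("CASE2")
  if (xor(wl, wr)) return("CASE1")
  "NORMAL"
}

# Row-wise string collapse of a 0/1 matrix.
row_strings <- function(M) {
  if (ncol(M) == 0L) return(rep("", nrow(M)))
  do.call(paste0, lapply(seq_len(ncol(M)), function(j) M[, j]))
}

#' Merge the results of two adjacent segments
#'
#' Determines, per individual, whether the right segment's haplotype pair is
#' concatenated STRAIGHT (`h1-h1`, `h2-h2`) or CROSS (`h1-h2`, `h2-h1`)
#' onto the left segment's pair.
#'
#' NORMAL individuals are decided by sliding a window of length `l_max`
#' across the junction (every placement covering at least one site of each
#' segment, clipped to the segments); placements whose window lacks a het
#' site of the individual on either side are skipped, the rest score both
#' pairings by [candidate_weight()] against all other individuals' current
#' (straight) fragments, and the single best weight wins, ties going to
#' STRAIGHT. CASE1/CASE2 individuals fall back to the two-site LD rule
#' between the last het of the left segment and the first het of the right
#' segment; CASE3 individuals (one side entirely het-free) take a seeded
#' random choice keyed by `(seed, junction, individual)`. NORMAL
#' individuals with no scoreable placement use the CASE1/CASE2 fallback and
#' are flagged.
#'
#' @param H_f,H_f1 [phased_set()]s of segments `f` and `f + 1`.
#' @param G full genotype matrix (original coordinates).
#' @param f index of the left segment in `plan`.
#' @param plan a [plan_segments()] result.
#' @param cfg a [core_config()]; `cfg$seed` keys the CASE3 draws.
#' @return list with `decisions` (data frame: `individual`, `choice`,
#'   `case`, `best_weight`, `fallback`) and `merged` (a [phased_set()] over
#'   both segments).
#' @export
merge_junction <- function(H_f, H_f1, G, f, plan, cfg = core_config(),
                           .het = NULL) {
  if (is.null(.het)) G <- validate_genotypes(G)
  start_f <- plan$start[f]; e <- plan$end[f]
  start_g <- plan$start[f + 1L]; end_g <- plan$end[f + 1L]
  stopifnot(start_g == e + 1L)
  n <- nrow(H_f$h1)
  lmax <- cfg$l_max

  Gl <- G[, start_f:e, drop = FALSE]
  Gr <- G[, start_g:end_g, drop = FALSE]
  cases <- vapply(seq_len(n), function(i)
    classify_case(Gl[i, ], Gr[i, ], lmax), character(1L))

  # scoring region around the junction, clipped to the two segments
  lo <- max(start_f, e - lmax + 2L)
  hi <- min(end_g, e + lmax - 1L)
  leftIdx <- (lo - start_f + 1L):(e - start_f + 1L)
  rightIdx <- seq_len(hi - e)
  SA <- row_strings(cbind(H_f$h1[, leftIdx, drop = FALSE],
                          H_f1$h1[, rightIdx, drop = FALSE]))
  SB <- row_strings(cbind(H_f$h2[, leftIdx, drop = FALSE],
                          H_f1$h2[, rightIdx, drop = FALSE]))
  CA <- row_strings(cbind(H_f$h1[, leftIdx, drop = FALSE],
                          H_f1$h2[, rightIdx, drop = FALSE]))
  CB <- row_strings(cbind(H_f$h2[, leftIdx, drop = FALSE],
                          H_f1$h1[, rightIdx, drop = FALSE]))

  # nearest hets to the junction inside the scoring region, per individual
  het <- if (is.null(.het)) !is.na(G) & G == 2L else .het
  maxHetLeft <- vapply(seq_len(n), function(i) {
    w <- which(het[i, lo:e]); if (length(w)) lo + max(w) - 1L else -Inf
  }, numeric(1L))
  minHetRight <- vapply(seq_len(n), function(i) {
    w <- which(het[i, (e + 1L):hi]); if (length(w)) e + min(w) else Inf
  }, numeric(1L))

  bestS <- rep(-1, n); bestC <- rep(-1, n)
  a_range <- seq.int(max(lo, e - lmax + 2L), min(e, hi - lmax + 1L))
  if (length(a_range) > 0L && a_range[1L] <= a_range[length(a_range)]) {
    for (a in a_range) {
      st <- a - lo + 1L
      fsa <- substr(SA, st, st + lmax - 1L)
      fsb <- substr(SB, st, st + lmax - 1L)
      valid <- maxHetLeft >= a & minHetRight <= a + lmax - 1L
      if (!any(valid)) next
      tb <- table(c(fsa, fsb))
      cnt <- function(x) as.integer(tb[x])
      fca <- substr(CA, st, st + lmax - 1L)
      fcb <- substr(CB, st, st + lmax - 1L)
      wS <- cnt(fsa) + cnt(fsb) - 2L - 2L * (fsa == fsb)
      lk <- function(x) { v <- cnt(x); v[is.na(v)] <- 0L; v }
      wC <- lk(fca) - (fca == fsa) - (fca == fsb) +
            lk(fcb) - (fcb == fsa) - (fcb == fsb)
      upd <- valid & wS > bestS
      bestS[upd] <- wS[upd]
      updc <- valid & wC > bestC
      bestC[updc] <- wC[updc]
    }
  }

  # LD fallback between the last het of f and the first het of f+1
  ld_choice <- function(i) {
    wl <- which(het[i, start_f:e])
    wr <- which(het[i, start_g:end_g])
    if (length(wl) == 0L || length(wr) == 0L) return("STRAIGHT")
    p <- start_f + max(wl) - 1L
    q <- e + min(wr)
    cnt <- cpp_gamete_counts(G, p - 1L, q - 1L)
    cis <- cnt[[1L]] * cnt[[4L]] - cnt[[2L]] * cnt[[3L]] >= 0
    x <- H_f$h1[i, p - start_f + 1L]
    y <- H_f1$h1[i, q - e]
    if (cis == (x == y)) "STRAIGHT" else "CROSS"
  }

  choice <- character(n); weight <- rep(NA_real_, n); fallback <- logical(n)
  for (i in seq_len(n)) {
    if (cases[i] == "CASE3") {
      choice[i] <- if (cpp_case3_bit(cfg$seed, f, i) == 0L) "STRAIGHT" else "CROSS"
    } else if (cases[i] %in% c("CASE1", "CASE2")) {
      choice[i] <- ld_choice(i)
    } else {
      if (bestS[i] < 0 && bestC[i] < 0) {
        choice[i] <- ld_choice(i)
        fallback[i] <- TRUE
      } else {
        choice[i] <- if (bestC[i] > bestS[i]) "CROSS" else "STRAIGHT"
        weight[i] <- max(bestS[i], bestC[i])
      }
    }
  }

  r1 <- H_f1$h1; r2 <- H_f1$h2
  sw <- choice == "CROSS"
  if (any(sw)) {
    tmp <- r1[sw, , drop = FALSE]
    r1[sw, ] <- r2[sw, , drop = FALSE]
    r2[sw, ] <- tmp
  }
  merged <- phased_set(cbind(H_f$h1, r1), cbind(H_f$h2, r2),
                       cbind(H_f$imputed, H_f1$imputed))
  decisions <- data.frame(individual = seq_len(n), junction = f,
                          choice = choice, case = cases,
                          best_weight = weight, fallback = fallback)
  list(decisions = decisions, merged = merged)
}

#' Merge all segment results
#'
#' Left-to-right fold of [merge_junction()]: CROSS decisions swap the right
#' segment's pair labels before concatenation. The output covers all sites
#' and complements `G`.
#'
#' @param segment_results list of [phased_set()]s, one per plan interval.
#' @param G full genotype matrix.
#' @param plan a [plan_segments()] result.
#' @param cfg a [core_config()].
#' @return a [phased_set()] with attribute `decisions` (all junction
#'   decisions).
#' @export
merge_all <- function(segment_results, G, plan, cfg = core_config()) {
  k <- nrow(plan)
  if (length(segment_results) != k)
    stop("one segment result per plan interval required", call. = FALSE)
  segs <- segment_results
  decisions <- vector("list", max(k - 1L, 0L))
  if (k > 1L) {
    het <- !is.na(G) & G == 2L
    for (f in seq_len(k - 1L)) {
      out <- merge_junction(segs[[f]], segs[[f + 1L]], G, f, plan, cfg,
                            .het = het)
      sw <- out$decisions$choice == "CROSS"
      if (any(sw)) {
        tmp <- segs[[f + 1L]]$h1[sw, , drop = FALSE]
        segs[[f + 1L]]$h1[sw, ] <- segs[[f + 1L]]$h2[sw, , drop = FALSE]
        segs[[f + 1L]]$h2[sw, ] <- tmp
      }
      decisions[[f]] <- out$decisions
    }
  }
  H <- phased_set(do.call(cbind, lapply(segs, `[[`, "h1")),
                  do.call(cbind, lapply(segs, `[[`, "h2")),
                  do.call(cbind, lapply(segs, `[[`, "imputed")))
  attr(H, "decisions") <- if (k > 1L) do.call(rbind, decisions) else NULL
  H
}

#' Phase a genotype matrix end to end
#'
#' Plans segments, phases each segment independently with the three-phase
#' core (optionally across workers) and merges adjacent results. For a given
#' seed the output is identical for any number of threads: per-segment seeds
#' are derived deterministically from the master seed and the segment index,
#' and junction draws are keyed by (seed, junction, individual).
#'
#' @param G genotype matrix (individuals x sites, codes 0/1/2/NA).
#' @param s segment size in sites (default 1000; values below 1000 need
#'   `force = TRUE`).
#' @param cfg a [core_config()].
#' @param threads number of forked workers for segment phasing.
#' @param force allow `s < 1000`.
#' @return a [phased_set()] covering all sites, with attributes `plan` and
#'   `decisions`.
#' @export
run_pipeline <- function(G, s = 1000L, cfg = core_config(), threads = 1L,
                         force = FALSE) {
  G <- validate_genotypes(G)
  plan <- plan_segments(ncol(G), s, force = force)
  phase_one <- function(f) {
    cfg_f <- cfg
    cfg_f$seed <- cpp_derive_seed(cfg$seed, f)
    phase_segment(G[, plan$start[f]:plan$end[f], drop = FALSE], cfg_f)
  }
  idx <- seq_len(nrow(plan))
  if (threads > 1L && .Platform$OS.type == "unix") {
    segs <- parallel::mclapply(idx, phase_one, mc.cores = threads)
    bad <- vapply(segs, inherits, logical(1L), "try-error")
    if (any(bad)) stop("segment phasing failed: ", segs[[which(bad)[1L]]],
                       call. = FALSE)
  } else {
    segs <- lapply(idx, phase_one)
  }
  H <- merge_all(segs, G, plan, cfg)
  attr(H, "plan") <- plan
  H
}

#' @rdname run_pipeline
#' @export
phase_genotypes <- run_pipeline
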