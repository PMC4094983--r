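# Genotype and haplotype containers plus readers/writers for the plain-text
# matrix dialect, Hudson ms output and minimal diploid VCF.
#
# A genotype matrix is an integer matrix with one individual per row and one
# SNP site per column, coded 0 (homozygous major), 1 (homozygous minor),
# 2 (heterozygous) and NA (missing, '?' on disk).

#' Validate a genotype matrix
#'
#' Checks that `G` is a non-empty integer matrix over the codes
#' \{0, 1, 2, NA\}.
#'
#' @param G matrix to validate.
#' @return `G`, invisibly coerced to integer storage.
#' @export
validate_genotypes <- function(G) {
  if (!is.matrix(G)) stop("genotypes must be a matrix", call. = FALSE)
  if (nrow(G) < 1L || ncol(G) < 1L)
    stop("genotype matrix must have at least one row and one column",
         call. = FALSE)
  storage.mode(G) <- "integer"
  bad <- !(G %in% c(0L, 1L, 2L) | is.na(G))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("illegal genotype code at row %d, site %d", w[1L], w[2L]),
         call. = FALSE)
  }
  invisible(G)
}

#' Phased haplotype set
#'
#' Container for a phased population: for each individual an ordered pair of
#' haplotype vectors over \{0, 1\}, plus a logical mask of sites whose
#' genotype call was missing and therefore imputed.
#'
#' @param h1,h2 integer matrices (individuals x sites) over \{0, 1\}; row i
#'   of `h1` and `h2` is individual i's haplotype pair.
#' @param imputed logical matrix of the same dimension marking imputed
#'   sites; defaults to all `FALSE`.
#' @return an object of class `phased_set`.
#' @export
phased_set <- function(h1, h2, imputed = NULL) {
  if (!is.matrix(h1) || !is.matrix(h2) || !all(dim(h1) == dim(h2)))
    stop("h1 and h2 must be matrices of identical dimension", call. = FALSE)
  if (nrow(h1) < 1L || ncol(h1) < 1L)
    stop("phased set must not be empty", call. = FALSE)
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"
  if (any(is.na(h1)) || any(is.na(h2)) ||
      !all(h1 %in% 0:1) || !all(h2 %in% 0:1))
    stop("haplotype alleles must be 0 or 1", call. = FALSE)
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(h1), ncol(h1))
  } else if (!is.logical(imputed) || !all(dim(imputed) == dim(h1))) {
    stop("imputed mask must be a logical matrix matching h1", call. = FALSE)
  }
  structure(list(h1 = h1, h2 = h2, imputed = imputed), class = "phased_set")
}

#' @export
#' @method print phased_set
print.phased_set <- function(x, ...) {
  cat(sprintf("<phased_set> %d individuals x %d sites (%d imputed cells)\n",
              nrow(x$h1), ncol(x$h1), sum(x$imputed)))
  invisible(x)
}

#' @export
#' @method dim phased_set
dim.phased_set <- function(x) dim(x$h1)

# Genotypes implied by a phased set: per site 0+0 -> 0, 1+1 -> 1, else 2.
implied_genotypes <- function(ps) {
  G <- ps$h1 + ps$h2
  G[G == 2L] <- 99L
  G[G == 1L] <- 2L
  G[G == 99L] <- 1L
  G
}

#' Check that a phased set complements a genotype matrix
#'
#' At every non-missing site the unordered allele pair must reproduce the
#' genotype code: 0 -> \{0,0\}, 1 -> \{1,1\}, 2 -> \{0,1\}; missing sites
#' must be flagged in the imputed mask.
#'
#' @param ps a [phased_set()].
#' @param G genotype matrix.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
check_complementarity <- function(ps, G) {
  G <- validate_genotypes(G)
  if (!all(dim(ps$h1) == dim(G)))
    stop("phased set and genotype matrix dimensions differ", call. = FALSE)
  imp <- implied_genotypes(ps)
  obs <- !is.na(G)
  if (any(imp[obs] != G[obs])) {
    bad <- which(obs & imp != G, arr.ind = TRUE)[1L, ]
    stop(sprintf("complementarity violated at row %d, site %d",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (any(is.na(G) & !ps$imputed))
    stop("missing genotype site not flagged as imputed", call. = FALSE)
  invisible(TRUE)
}

#' Read a plain-text genotype matrix
#'
#' One individual per row, no header, symbols `0`, `1`, `2`, `?`;
#' whitespace between symbols is tolerated.
#'
#' @param path file to read.
#' @return validated integer genotype matrix (missing as `NA`).
#' @export
read_genotype_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty genotype file: ", path, call. = FALSE)
  lines <- gsub("[ \t]", "", lines)
  widths <- nchar(lines)
  if (length(unique(widths)) != 1L) {
    off <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged genotype matrix: line %d has %d sites, expected %d",
                 off, widths[off], widths[1L]), call. = FALSE)
  }
  chars <- strsplit(lines, "", fixed = TRUE)
  bad <- lapply(chars, function(x) which(!x %in% c("0", "1", "2", "?")))
  ibad <- which(vapply(bad, length, 1L) > 0L)
  if (length(ibad) > 0L) {
    i <- ibad[1L]; j <- bad[[i]][1L]
    stop(sprintf("illegal symbol '%s' at line %d, position %d",
                 chars[[i]][j], i, j), call. = FALSE)
  }
  G <- do.call(rbind, lapply(chars, function(x) {
    x[x == "?"] <- NA_character_
    as.integer(x)
  }))
  validate_genotypes(G)
  G
}

#' Write a plain-text genotype matrix
#'
#' Inverse of [read_genotype_table()]: one individual per row, `?` for
#' missing.
#'
#' @param path output file.
#' @param G genotype matrix.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(path, G) {
  G <- validate_genotypes(G)
  ch <- matrix(as.character(G), nrow(G), ncol(G))
  ch[is.na(ch)] <- "?"
  writeLines(apply(ch, 1L, paste, collapse = ""), path)
  invisible(path)
}

#' Write phased haplotypes
#'
#' Writes 2n lines over \{0, 1\}; lines 2i-1 and 2i are individual i's
#' haplotype pair. Reading the file back with [read_haplotypes()]
#' reproduces the input (the imputed mask is not serialised).
#'
#' @param path output file.
#' @param phased a [phased_set()].
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(path, phased) {
  if (!inherits(phased, "phased_set"))
    stop("phased must be a phased_set", call. = FALSE)
  n <- nrow(phased$h1)
  out <- character(2L * n)
  out[seq(1L, 2L * n, 2L)] <- apply(phased$h1, 1L, paste, collapse = "")
  out[seq(2L, 2L * n, 2L)] <- apply(phased$h2, 1L, paste, collapse = "")
  writeLines(out, path)
  invisible(path)
}

#' Read phased haplotypes
#'
#' @param path file with 2n lines over \{0, 1\} as written by
#'   [write_haplotypes()].
#' @return a [phased_set()] with an all-`FALSE` imputed mask.
#' @export
read_haplotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || length(lines) %% 2L != 0L)
    stop("haplotype file must contain an even, positive number of rows",
         call. = FALSE)
  if (any(grepl("[^01]", lines)))
    stop("haplotype rows may contain only 0 and 1", call. = FALSE)
  M <- do.call(rbind, lapply(strsplit(lines, "", fixed = TRUE), as.integer))
  phased_set(M[seq(1L, nrow(M), 2L), , drop = FALSE],
             M[seq(2L, nrow(M), 2L), , drop = FALSE])
}

#' Parse Hudson ms output
#'
#' Parses the textual output dialect of Hudson's `ms` coalescent simulator:
#' replicates are delimited by `//` lines, each followed by a
#' `segsites:` header, a `positions:` header (when segsites > 0) and one
#' haplotype row per sample. Positions are fractional coordinates on
#' `[0, 1]`; they are retained for provenance but not used by phasing,
#' which is index-based.
#'
#' @param text character vector of lines, or a single string.
#' @return list of replicates, each a list with elements `segsites`,
#'   `positions` and `haplotypes` (integer matrix, samples x segsites).
#' @export
parse_ms <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE))
    text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  starts <- which(trimws(text) == "//")
  if (length(starts) == 0L)
    stop("not ms output: no '//' replicate delimiter found", call. = FALSE)
  ends <- c(starts[-1L] - 1L, length(text))
  lapply(seq_along(starts), function(b) {
    block <- text[seq(starts[b] + 1L, ends[b])]
    block <- block[nzchar(trimws(block))]
    seg_i <- grep("^segsites:", trimws(block))
    if (length(seg_i) == 0L)
      stop("ms replicate missing 'segsites:' header", call. = FALSE)
    segsites <- as.integer(sub("^segsites:\\s*", "", trimws(block[seg_i[1L]])))
    if (is.na(segsites) || segsites < 0L)
      stop("unparseable segsites header", call. = FALSE)
    if (segsites == 0L)
      return(list(segsites = 0L, positions = numeric(0),
                  haplotypes = matrix(integer(0), 0L, 0L)))
    pos_i <- grep("^positions:", trimws(block))
    if (length(pos_i) == 0L)
      stop("ms replicate missing 'positions:' header", call. = FALSE)
    positions <- as.numeric(strsplit(
      sub("^positions:\\s*", "", trimws(block[pos_i[1L]])), "\\s+")[[1L]])
    if (length(positions) != segsites || any(diff(positions) <= 0))
      stop("ms positions must be strictly increasing and match segsites",
           call. = FALSE)
    rows <- trimws(block[seq(pos_i[1L] + 1L, length(block))])
    rows <- rows[grepl("^[01]+$", rows)]
    if (length(rows) == 0L || any(nchar(rows) != segsites))
      stop("ms haplotype rows must all have 'segsites' columns",
           call. = FALSE)
    haps <- do.call(rbind, lapply(strsplit(rows, "", fixed = TRUE),
                                  as.integer))
    list(segsites = segsites, positions = positions, haplotypes = haps)
  })
}

#' Read an ms output file
#'
#' @param path path to an `ms` output file.
#' @return see [parse_ms()].
#' @export
read_ms <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_ms(readLines(path, warn = FALSE))
}

#' Read genotypes from a minimal diploid VCF
#'
#' Ingests biallelic SNP records with diploid GT fields from a single
#' chromosome: `0/0 -> 0`, `1/1 -> 1`, `0/1` and `1/0` (phased or not)
#' `-> 2`, `./. -> NA`. Multiallelic records are an error under
#' `strict = TRUE` and are skipped otherwise. Haploid or polyploid GT
#' fields are always an error. Sites are ordered by position.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @param strict reject multiallelic records instead of skipping them.
#' @return integer genotype matrix, individuals x sites, with site
#'   positions in the column names.
#' @export
read_vcf_genotypes <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (is.null(dim(fix)) || nrow(fix) == 0L)
    stop("VCF contains no records", call. = FALSE)
  if (length(unique(fix[, "CHROM"])) > 1L)
    stop("multi-chromosome VCF: split by chromosome before phasing",
         call. = FALSE)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    if (strict)
      stop(sprintf("multiallelic record at %s:%s", fix[multi, "CHROM"][1L],
                   fix[multi, "POS"][1L]), call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- !multi
  gt <- gt[keep, , drop = FALSE]
  pos <- as.integer(fix[keep, "POS"])
  o <- order(pos)
  gt <- gt[o, , drop = FALSE]
  pos <- pos[o]
  code_one <- function(g) {
    if (is.na(g) || g == "." ) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1L]]
    if (length(alleles) != 2L)
      stop(sprintf("non-diploid GT '%s'", g), call. = FALSE)
    if (all(alleles == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(alleles))
    if (any(is.na(a)) || any(a > 1L))
      stop(sprintf("unsupported GT '%s' (only biallelic diploid calls)", g),
           call. = FALSE)
    if (a[1L] == 0L && a[2L] == 0L) 0L
    else if (a[1L] == 1L && a[2L] == 1L) 1L
    else 2L
  }
  G <- t(matrix(vapply(gt, code_one, integer(1L)), nrow = nrow(gt)))
  colnames(G) <- pos
  validate_genotypes(G)
  G
}

#' Collapse haplotype pairs into genotypes
#'
#' Per site: alleles (0,0) -> 0, (1,1) -> 1, mixed -> 2. Never produces
#' missing calls.
#'
#' @param pairs a [phased_set()], or a list of pairs, each pair a list or
#'   character vector of two equal-length haplotypes (integer vectors or
#'   strings over \{0, 1\}).
#' @return integer genotype matrix with one row per pair.
#' @export
genotypes_from_haplotypes <- function(pairs) {
  if (inherits(pairs, "phased_set")) return(implied_genotypes(pairs))
  as_hap <- function(x) {
    if (is.character(x) && length(x) == 1L)
      x <- as.integer(strsplit(x, "", fixed = TRUE)[[1L]])
    x <- as.integer(x)
    if (any(is.na(x)) || !all(x %in% 0:1))
      stop("haplotype alleles must be 0 or 1", call. = FALSE)
    x
  }
  rows <- lapply(pairs, function(p) {
    a <- as_hap(p[[1L]]); b <- as_hap(p[[2L]])
    if (length(a) != length(b))
      stop("haplotype pair lengths differ", call. = FALSE)
    g <- a + b
    g[g == 2L] <- 99L; g[g == 1L] <- 2L; g[g == 99L] <- 1L
    g
  })
  if (length(unique(vapply(rows, length, 1L))) != 1L)
    stop("all haplotype pairs must have the same length", call. = FALSE)
  do.call(rbind, rows)
}
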