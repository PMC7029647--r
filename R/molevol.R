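# Codon-aware alignment, NG86 Ka/Ks, Ks-peak dating and selection-bias tests.
#
# The Ka/Ks engine is NG86-style counting: synonymous/nonsynonymous site
# fractions per codon position, per-codon differences averaged over
# equal-weight minimal mutational pathways, and a Jukes-Cantor multiple-hit
# correction. Full codon-frequency/transition-weighting machinery (YN00) is
# deliberately out of scope; the counting contract is pinned by an
# exhaustive pathway-enumeration oracle in the test suite.

.CODON_TABLE <- local({
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  stops <- codons[code == "*"]
  sense <- setdiff(codons, stops)
  bases <- c("A", "C", "G", "T")
  # per-codon synonymous site count: at each position, the fraction of the
  # 3 possible substitutions that preserve the amino acid; substitutions to
  # stop codons count as nonsynonymous so that S + N = 3 per codon
  syn_sites <- stats::setNames(numeric(length(sense)), sense)
  for (cd in sense) {
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cd, p, p))) {
        alt <- cd
        substr(alt, p, p) <- b
        if (code[[alt]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    syn_sites[cd] <- s
  }
  list(code = code, sense = sense, stops = stops, syn_sites = syn_sites)
})

.codon_path_cache <- new.env(hash = TRUE, parent = emptyenv())

# Average synonymous/nonsynonymous difference counts over all orderings of
# the differing positions between two sense codons. Pathways passing through
# a stop codon are excluded; if every pathway is blocked, all are used.
# Memoized: at most 61 x 61 distinct codon pairs.
.codon_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .codon_path_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- .CODON_TABLE
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  d <- length(pos)
  if (d == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1L) list(pos) else {
    do.call(c, lapply(seq_len(d), function(i) {
      rest <- pos[-i]
      if (length(rest) == 1L) list(c(pos[i], rest))
      else list(c(pos[i], rest[1L], rest[2L]), c(pos[i], rest[2L], rest[1L]))
    }))
  }
  path_counts <- list()
  for (pm in perms) {
    cur <- c1
    syn <- 0
    nonsyn <- 0
    blocked <- FALSE
    for (p in pm) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (tab$code[[nxt]] == "*" && nxt != c2) {
        blocked <- TRUE
        break
      }
      if (tab$code[[nxt]] == "*" || tab$code[[cur]] == "*") {
        # step involving a stop endpoint (only if c2 itself is a stop,
        # which callers exclude); count as nonsynonymous
        nonsyn <- nonsyn + 1
      } else if (tab$code[[nxt]] == tab$code[[cur]]) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    if (!blocked) {
      path_counts[[length(path_counts) + 1L]] <- c(syn, nonsyn)
    }
  }
  if (!length(path_counts)) {
    # all pathways blocked by stops: fall back to using every ordering,
    # counting the stop-intermediate steps as nonsynonymous
    for (pm in perms) {
      cur <- c1
      syn <- 0
      nonsyn <- 0
      for (p in pm) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        aa1 <- tab$code[[cur]]
        aa2 <- tab$code[[nxt]]
        if (aa1 == aa2 && aa1 != "*") syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      path_counts[[length(path_counts) + 1L]] <- c(syn, nonsyn)
    }
  }
  m <- do.call(rbind, path_counts)
  out <- c(syn = mean(m[, 1L]), nonsyn = mean(m[, 2L]))
  .codon_path_cache[[key]] <- out
  out
}

#' Codon-aware pairwise alignment of two CDS
#'
#' The CDS are translated (universal code), the proteins aligned globally
#' (BLOSUM62, affine gaps), and the alignment back-translated to codons.
#' Columns containing a gap or a stop codon in either sequence are dropped.
#'
#' @param cds1,cds2 CDS sequences (lengths multiples of 3).
#' @return List of class `codon_alignment`: `codons1`, `codons2` (character
#'   vectors of aligned codons) and `n_codons`.
#' @export
align_codons <- function(cds1, cds2) {
  if (nchar(cds1) %% 3L != 0L || nchar(cds2) %% 3L != 0L) {
    stop("CDS length must be a multiple of 3")
  }
  split_codons <- function(x) {
    substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  }
  co1 <- split_codons(toupper(cds1))
  co2 <- split_codons(toupper(cds2))
  tab <- .CODON_TABLE
  aa <- function(co) paste(ifelse(co %in% names(tab$code),
                                  unname(tab$code[co]), "X"), collapse = "")
  p1 <- aa(co1)
  p2 <- aa(co2)
  if (!nzchar(gsub("[*X]", "", p1)) || !nzchar(gsub("[*X]", "", p2))) {
    stop("CDS not translatable (stop codons throughout)")
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p1), Biostrings::AAString(p2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  s1 <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  i1 <- 0L
  i2 <- 0L
  k1 <- character()
  k2 <- character()
  for (k in seq_along(s1)) {
    g1 <- s1[k] == "-"
    g2 <- s2[k] == "-"
    if (!g1) i1 <- i1 + 1L
    if (!g2) i2 <- i2 + 1L
    if (g1 || g2) next
    c1 <- co1[i1]
    c2 <- co2[i2]
    if (c1 %in% tab$stops || c2 %in% tab$stops) next
    if (!(c1 %in% tab$sense) || !(c2 %in% tab$sense)) next
    k1 <- c(k1, c1)
    k2 <- c(k2, c2)
  }
  out <- list(codons1 = k1, codons2 = k2, n_codons = length(k1))
  class(out) <- "codon_alignment"
  out
}

#' NG86-style Ka/Ks from a codon alignment
#'
#' Synonymous (S) and nonsynonymous (N) site counts are averaged over the
#' two sequences; per-codon differences are averaged over equal-weight
#' minimal mutational pathways; proportions are corrected for multiple hits
#' with the Jukes-Cantor formula d = -(3/4) ln(1 - 4p/3). A proportion at
#' or above 0.75 is flagged saturated (correction undefined) and the
#' corresponding rate is `NA`. omega = Ka/Ks is defined only when Ks > 0.
#'
#' @param alignment A `codon_alignment` (or a list with `codons1`,
#'   `codons2`).
#' @return List of class `kaks_result`: `ka`, `ks`, `omega`, `S`, `N`,
#'   `Sd`, `Nd`, `n_codons`, `saturated`, `omega_undefined`.
#' @export
kaks <- function(alignment) {
  co1 <- alignment$codons1
  co2 <- alignment$codons2
  if (!length(co1)) stop("empty codon alignment")
  tab <- .CODON_TABLE
  s1 <- tab$syn_sites[co1]
  s2 <- tab$syn_sites[co2]
  S <- sum((s1 + s2) / 2)
  N <- 3 * length(co1) - S
  diffs <- vapply(seq_along(co1), function(i) {
    .codon_path_counts(co1[i], co2[i])
  }, numeric(2L))
  Sd <- sum(diffs[1L, ])
  Nd <- sum(diffs[2L, ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ks <- jc(pS)
  ka <- jc(pN)
  saturated <- is.na(ks) || is.na(ka)
  omega_undefined <- !saturated && ks == 0
  out <- list(ka = ka, ks = ks,
              omega = if (saturated || omega_undefined) NA_real_ else ka / ks,
              S = S, N = N, Sd = Sd, Nd = Nd, n_codons = length(co1),
              saturated = saturated, omega_undefined = omega_undefined)
  class(out) <- "kaks_result"
  out
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Ka = %s, Ks = %s, omega = %s (S = %.2f, N = %.2f, %d codons)\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$omega, digits = 4), x$S, x$N, x$n_codons))
  if (x$saturated) cat("  flag: saturated (p >= 0.75)\n")
  if (x$omega_undefined) cat("  flag: omega undefined (Ks = 0)\n")
  invisible(x)
}

#' Ka/Ks for a table of gene pairs
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param cds Named character vector of CDS sequences covering all genes.
#' @return Data frame: `gene_a`, `gene_b`, `ka`, `ks`, `omega`,
#'   `n_codons`, `saturated`.
#' @export
kaks_pairs <- function(pairs, cds) {
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    al <- align_codons(cds[[pairs$gene_a[i]]], cds[[pairs$gene_b[i]]])
    k <- if (al$n_codons) kaks(al) else
      list(ka = NA_real_, ks = NA_real_, omega = NA_real_,
           n_codons = 0L, saturated = TRUE)
    out[[i]] <- data.frame(gene_a = pairs$gene_a[i],
                           gene_b = pairs$gene_b[i],
                           ka = k$ka, ks = k$ks, omega = k$omega,
                           n_codons = k$n_codons,
                           saturated = k$saturated)
  }
  do.call(rbind, out)
}

#' Mode of a Ks distribution by kernel density estimation
#'
#' Gaussian KDE with the Silverman rule-of-thumb bandwidth, evaluated on a
#' 512-point grid over [0, 99th percentile]; the argmax is returned, ties
#' broken toward the smaller Ks. Saturated/non-finite values must be
#' excluded upstream.
#'
#' @param ks Numeric vector of Ks values.
#' @param min_n Minimum number of finite values required (default 30).
#' @param n_grid Grid size (default 512).
#' @return The peak Ks (numeric scalar), with the bandwidth in
#'   `attr(, "bandwidth")`.
#' @export
ks_peak <- function(ks, min_n = 30L, n_grid = 512L) {
  ks <- ks[is.finite(ks)]
  if (length(ks) < min_n) {
    stop("need at least ", min_n, " finite Ks values (got ", length(ks), ")")
  }
  if (diff(range(ks)) == 0) {
    out <- ks[1L]
    attr(out, "bandwidth") <- 0
    return(out)
  }
  hi <- stats::quantile(ks, 0.99, names = FALSE)
  d <- stats::density(ks, bw = "nrd0", from = 0, to = hi, n = n_grid)
  peak <- d$x[which.max(d$y)]  # which.max takes the first (smaller) tie
  attr(peak, "bandwidth") <- d$bw
  peak
}

#' Molecular-clock divergence time from a Ks peak
#'
#' T = peak Ks / (2 m), with m substitutions per site per year. Lineages
#' with accelerated silent-substitution rates can be accommodated through
#' `rate_multiplier` (effective rate m x multiplier); deep events dated
#' under a different clock regime should not be forced through this formula.
#'
#' @param peak_ks Ks peak (substitutions per synonymous site).
#' @param m Substitution rate per site per year (default 8.12e-9).
#' @param rate_multiplier Optional rate acceleration factor (default 1).
#' @return Divergence time in years.
#' @export
divergence_time <- function(peak_ks, m = 8.12e-9, rate_multiplier = 1) {
  stopifnot(m > 0, rate_multiplier > 0, peak_ks >= 0)
  peak_ks / (2 * m * rate_multiplier)
}

#' Compare two omega (Ka/Ks) distributions
#'
#' Two-sided Wilcoxon rank-sum test (exact for small samples without ties,
#' normal approximation with tie correction otherwise) plus a permutation
#' test on the absolute difference of medians with the add-one estimate
#' p = (#{|stat_perm| >= |stat_obs|} + 1) / (n_perm + 1).
#'
#' @param omega1,omega2 Numeric vectors (non-finite values excluded).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draw (default 1).
#' @return List: `median_1`, `median_2`, `wilcoxon_p`, `permutation_p`,
#'   `n_1`, `n_2`.
#' @export
selection_bias_test <- function(omega1, omega2, n_perm = 10000L, seed = 1L) {
  omega1 <- omega1[is.finite(omega1)]
  omega2 <- omega2[is.finite(omega2)]
  if (!length(omega1) || !length(omega2)) stop("empty omega set")
  n1 <- length(omega1)
  n2 <- length(omega2)
  if (length(unique(c(omega1, omega2))) == 1L) {
    return(list(median_1 = omega1[1L], median_2 = omega2[1L],
                wilcoxon_p = 1, permutation_p = 1, n_1 = n1, n_2 = n2))
  }
  ties <- anyDuplicated(c(omega1, omega2)) > 0L
  wp <- stats::wilcox.test(omega1, omega2, alternative = "two.sided",
                           exact = (!ties && n1 <= 25L && n2 <= 25L),
                           correct = TRUE)$p.value
  obs <- abs(stats::median(omega1) - stats::median(omega2))
  pp <- .with_seed(.op_seed(seed, "permutation"), {
    pool <- c(omega1, omega2)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n1 + n2, n1)
      stat <- abs(stats::median(pool[idx]) - stats::median(pool[-idx]))
      if (stat >= obs) hits <- hits + 1L
    }
    (hits + 1) / (n_perm + 1)
  })
  list(median_1 = stats::median(omega1), median_2 = stats::median(omega2),
       wilcoxon_p = wp, permutation_p = pp, n_1 = n1, n_2 = n2)
}
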