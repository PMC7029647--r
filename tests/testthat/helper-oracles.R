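# Independent oracles and small fixture builders shared across test files.

# --- brute-force collinear chaining ----------------------------------------
# Maximum-scoring collinear chain by subset enumeration (n <= ~15), over both
# orientations, with the same gap constraint as the chained implementation.
bf_best_chain_score <- function(r1, r2, score, max_gap) {
  n <- length(r1)
  best <- 0
  check <- function(idx, flip) {
    rr2 <- if (flip) -r2[idx] else r2[idx]
    o <- order(r1[idx])
    a <- r1[idx][o]
    b <- rr2[o]
    if (any(diff(a) <= 0) || any(diff(b) <= 0)) return(NA_real_)
    if (any(diff(a) > max_gap + 1) || any(diff(b) > max_gap + 1)) {
      return(NA_real_)
    }
    sum(score[idx])
  }
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    for (flip in c(FALSE, TRUE)) {
      s <- check(idx, flip)
      if (!is.na(s) && s > best) best <- s
    }
  }
  best
}

# --- NG86 pathway enumeration ----------------------------------------------
# Recursive, structurally independent of the package's iterative version:
# walks every ordering of the differing positions depth-first.
GENCODE <- Biostrings::GENETIC_CODE
SENSE_CODONS <- names(GENCODE)[GENCODE != "*"]

oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    for (b in bases) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (GENCODE[[alt]] == GENCODE[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

oracle_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  walk <- function(cur, remaining, allow_stops) {
    if (!length(remaining)) return(list(c(0, 0)))
    res <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!allow_stops && GENCODE[[nxt]] == "*" && nxt != c2) next
      step <- if (GENCODE[[nxt]] == GENCODE[[cur]] &&
                    GENCODE[[cur]] != "*") c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(remaining, p), allow_stops)) {
        res[[length(res) + 1]] <- step + tail
      }
    }
    res
  }
  paths <- walk(c1, pos, allow_stops = FALSE)
  if (!length(paths)) paths <- walk(c1, pos, allow_stops = TRUE)
  m <- do.call(rbind, paths)
  colMeans(m)
}

# --- exact Wilcoxon rank-sum null ------------------------------------------
# Two-sided p by full enumeration of group assignments (no ties assumed).
oracle_wilcoxon_p <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pool), nx)
  stats <- apply(combs, 2, function(idx) {
    sum(r[idx]) - nx * (nx + 1) / 2
  })
  p_le <- mean(stats <= obs)
  p_ge <- mean(stats >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# --- brute-force flag remapping --------------------------------------------
# Every position where `flag` matches with at most max_mm substitutions.
oracle_flag_scan <- function(flag, reference, max_mm = 2) {
  fl <- strsplit(flag, "")[[1]]
  k <- length(fl)
  out <- list()
  for (ch in names(reference)) {
    x <- strsplit(reference[[ch]], "")[[1]]
    for (s in seq_len(length(x) - k + 1)) {
      mm <- sum(x[s:(s + k - 1)] != fl)
      if (mm <= max_mm) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, pos = s,
                                             mismatches = mm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# --- fixtures ---------------------------------------------------------------
tiny_map <- function(n) {
  data.frame(gene_a = sprintf("A%04d", seq_len(n)),
             gene_b = sprintf("B%04d", seq_len(n)))
}

# grid homoeolog map with identical coordinates on both subgenomes
grid_map <- function(chrom_a = "A01", chrom_b = "B01", n = 50,
                     spacing = 5000) {
  starts <- seq(1000, by = spacing, length.out = n)
  data.frame(gene_a = sprintf("%sG%04d", chrom_a, seq_len(n)),
             chrom_a = chrom_a, start_a = starts, end_a = starts + 1200,
             gene_b = sprintf("%sG%04d", chrom_b, seq_len(n)),
             chrom_b = chrom_b, start_b = starts, end_b = starts + 1200)
}

random_dna_str <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

default_expr_spec <- function(n_biased_pairs = 0L, bias_factor = 4,
                              dispersion = 0.05) {
  list(n_biased_pairs = n_biased_pairs, bias_factor = bias_factor,
       dispersion = dispersion, stages = 4L, replicates = 3L,
       mean_count = 500)
}
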