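# Homoeolog expression bias: RPKM normalization, per-stage tests, dominance
# classification, DEG calling, and integration with the SV partition.

#' RPKM normalization
#'
#' RPKM = count x 1e9 / (library_total x gene_length). A gene is flagged
#' expressed in a sample when RPKM > 0.1 (strict).
#'
#' @param counts Integer matrix, genes x samples.
#' @param gene_lengths Named bp vector covering `rownames(counts)`.
#' @param lib_totals Library totals per sample; column sums by default.
#' @param samples Optional sample metadata (`sample`, `stage`,
#'   `replicate`).
#' @return List of class `expression_matrix`: `counts`, `rpkm`,
#'   `expressed`, `gene_lengths`, `lib_totals`, `samples`.
#' @export
rpkm <- function(counts, gene_lengths, lib_totals = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(lib_totals)) lib_totals <- colSums(counts)
  if (any(lib_totals <= 0)) stop("zero library total")
  gl <- gene_lengths[rownames(counts)]
  if (anyNA(gl) || any(gl <= 0)) stop("missing or non-positive gene length")
  r <- counts * 1e9 / outer(as.numeric(gl), as.numeric(lib_totals))
  out <- list(counts = counts, rpkm = r, expressed = r > 0.1,
              gene_lengths = gl, lib_totals = lib_totals, samples = samples)
  class(out) <- "expression_matrix"
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix: %d genes x %d samples (RPKM normalized)\n",
              nrow(x$rpkm), ncol(x$rpkm)))
  cat(sprintf("  expressed (RPKM > 0.1): %.1f%% of entries\n",
              100 * mean(x$expressed)))
  invisible(x)
}

#' Welch t-test on log2 RPKM between the two copies of a pair at one stage
#'
#' Both replicate vectors are log2-transformed after adding `pseudocount`.
#' When both groups are constant and equal the p-value is 1 by convention;
#' constant but unequal groups give p = 0.
#'
#' @param a,b Replicate RPKM vectors for copy A and copy B.
#' @param pseudocount Added before log2 (default 0.01).
#' @return List: `fc` (mean RPKM A / mean RPKM B), `log2fc`, `p`.
#' @export
stage_test <- function(a, b, pseudocount = 0.01) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 replicates per copy")
  la <- log2(a + pseudocount)
  lb <- log2(b + pseudocount)
  fc <- mean(a) / mean(b)
  if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
    p <- if (mean(la) == mean(lb)) 1 else 0
  } else {
    p <- stats::t.test(la, lb)$p.value
  }
  list(fc = fc, log2fc = mean(la) - mean(lb), p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Adjusted values (FDR).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify homoeolog expression dominance for one pair
#'
#' Dominant toward the higher-expressed copy iff some stage shows fold
#' change > `fc_threshold` (or < 1/`fc_threshold`) at FDR <
#' `fdr_threshold`, and the fold-change direction is consistent in every
#' other stage where both copies are expressed (same sign, or |log2FC|
#' below `consistency_eps` for flat stages). Conflicting significant
#' directions or an inconsistent stage give neutral.
#'
#' @param fc,fdr,log2fc Per-stage vectors (equal length).
#' @param both_expressed Per-stage logical: both copies expressed
#'   (RPKM > 0.1); defaults to all `TRUE`.
#' @param fc_threshold,fdr_threshold Dominance cutoffs (defaults 2, 0.01).
#' @param consistency_eps |log2FC| below which a stage counts as flat
#'   (default 0.25).
#' @return `"A-dominant"`, `"B-dominant"` or `"neutral"`.
#' @export
classify_dominance <- function(fc, fdr, log2fc,
                               both_expressed = rep(TRUE, length(fc)),
                               fc_threshold = 2, fdr_threshold = 0.01,
                               consistency_eps = 0.25) {
  sig <- which(fdr < fdr_threshold &
                 (fc > fc_threshold | fc < 1 / fc_threshold))
  if (!length(sig)) return("neutral")
  dir <- sign(log2fc[sig])
  if (length(unique(dir)) > 1L) return("neutral")
  dir <- dir[1L]
  others <- setdiff(seq_along(fc), sig)
  others <- others[both_expressed[others]]
  ok <- all(sign(log2fc[others]) == dir |
              abs(log2fc[others]) < consistency_eps)
  if (!ok) return("neutral")
  if (dir > 0) "A-dominant" else "B-dominant"
}

#' Per-stage homoeolog bias testing and dominance classification
#'
#' For every homoeolog pair and stage, the two copies' replicate RPKM are
#' compared ([stage_test()]); p-values are BH-adjusted per stage across
#' pairs (each stage is its own FDR family); pairs are then classified
#' with [classify_dominance()].
#'
#' @param expr An `expression_matrix` (with `samples` metadata) from
#'   [rpkm()].
#' @param pairs Homoeolog pairs (`gene_a`, `gene_b`).
#' @param fc_threshold,fdr_threshold,consistency_eps,pseudocount
#'   See [classify_dominance()] and [stage_test()].
#' @return Data frame of class `bias_calls`: `pair_id`, `gene_a`, `gene_b`,
#'   per-stage `fc_s*`, `log2fc_s*`, `fdr_s*`, and `class`.
#' @export
homoeolog_bias <- function(expr, pairs, fc_threshold = 2,
                           fdr_threshold = 0.01, consistency_eps = 0.25,
                           pseudocount = 0.01) {
  stopifnot(inherits(expr, "expression_matrix"), !is.null(expr$samples))
  samples <- expr$samples
  stages <- sort(unique(samples$stage))
  n_pairs <- nrow(pairs)
  fc <- log2fc <- pval <- both_ex <-
    matrix(NA_real_, n_pairs, length(stages))
  for (s in seq_along(stages)) {
    cols <- which(samples$stage == stages[s])
    ra <- expr$rpkm[pairs$gene_a, cols, drop = FALSE]
    rb <- expr$rpkm[pairs$gene_b, cols, drop = FALSE]
    for (i in seq_len(n_pairs)) {
      st <- stage_test(ra[i, ], rb[i, ], pseudocount)
      fc[i, s] <- st$fc
      log2fc[i, s] <- st$log2fc
      pval[i, s] <- st$p
    }
    both_ex[, s] <- rowMeans(ra) > 0.1 & rowMeans(rb) > 0.1
  }
  fdr <- apply(pval, 2L, bh_adjust)
  if (n_pairs == 1L) fdr <- matrix(fdr, 1L)
  cls <- vapply(seq_len(n_pairs), function(i) {
    classify_dominance(fc[i, ], fdr[i, ], log2fc[i, ],
                       both_expressed = both_ex[i, ] > 0,
                       fc_threshold = fc_threshold,
                       fdr_threshold = fdr_threshold,
                       consistency_eps = consistency_eps)
  }, character(1L))
  out <- data.frame(pair_id = pairs$gene_a, gene_a = pairs$gene_a,
                    gene_b = pairs$gene_b)
  for (s in seq_along(stages)) {
    out[[sprintf("fc_s%d", stages[s])]] <- fc[, s]
    out[[sprintf("log2fc_s%d", stages[s])]] <- log2fc[, s]
    out[[sprintf("fdr_s%d", stages[s])]] <- fdr[, s]
  }
  out$class <- cls
  class(out) <- c("bias_calls", "data.frame")
  out
}

#' Call differentially expressed genes between two replicate groups
#'
#' DEG iff fold change > `fc_threshold` or < 1/`fc_threshold` and BH FDR <
#' `fdr_threshold` (Welch t-test on log2 RPKM across genes).
#'
#' @param x1,x2 RPKM matrices (genes x replicates) for the two groups,
#'   same row order.
#' @param fc_threshold,fdr_threshold Cutoffs (defaults 2 and 0.05).
#' @param pseudocount Added before log2 (default 0.01).
#' @return Data frame: `gene_id`, `fc`, `log2fc`, `p`, `fdr`, `deg`.
#' @export
deg_call <- function(x1, x2, fc_threshold = 2, fdr_threshold = 0.05,
                     pseudocount = 0.01) {
  stopifnot(nrow(x1) == nrow(x2))
  res <- lapply(seq_len(nrow(x1)), function(i) {
    stage_test(x1[i, ], x2[i, ], pseudocount)
  })
  fc <- vapply(res, `[[`, numeric(1L), "fc")
  p <- vapply(res, `[[`, numeric(1L), "p")
  fdr <- bh_adjust(p)
  data.frame(gene_id = rownames(x1), fc = fc,
             log2fc = vapply(res, `[[`, numeric(1L), "log2fc"),
             p = p, fdr = fdr,
             deg = (fc > fc_threshold | fc < 1 / fc_threshold) &
               fdr < fdr_threshold)
}

#' Compare homoeolog expression divergence between SV groups
#'
#' Per stage, the |log2FC| distributions of SV-carrying pairs (`sv_nonsv`)
#' and `unaffected` pairs are compared by a two-sided Wilcoxon rank-sum
#' test. If the partition carries an `sv_type` column, per-type rows
#' (deletion / insertion vs unaffected) are appended.
#'
#' @param partition Output of [partition_homoeologs()] (optionally with an
#'   `sv_type` column for the per-type split).
#' @param bias A `bias_calls` table from [homoeolog_bias()] covering the
#'   partitioned pairs.
#' @return Data frame: `group`, `stage`, `n_sv`, `n_unaffected`,
#'   `median_sv`, `median_unaffected`, `wilcoxon_p`.
#' @export
sv_expression_integration <- function(partition, bias) {
  m <- match(partition$gene_a, bias$pair_id)
  if (anyNA(m)) stop("partition pairs missing from bias table")
  stages <- as.integer(sub("^fc_s", "",
                           grep("^fc_s", names(bias), value = TRUE)))
  grab <- function(rows, s) {
    abs(bias[[sprintf("log2fc_s%d", s)]][m[rows]])
  }
  sv_rows <- which(partition$group == "sv_nonsv")
  un_rows <- which(partition$group == "unaffected")
  if (!length(sv_rows)) stop("SV_nonSV group is empty")
  if (!length(un_rows)) stop("unaffected group is empty")
  mk <- function(label, rows) {
    do.call(rbind, lapply(stages, function(s) {
      x <- grab(rows, s)
      y <- grab(un_rows, s)
      data.frame(group = label, stage = s, n_sv = length(x),
                 n_unaffected = length(y),
                 median_sv = stats::median(x),
                 median_unaffected = stats::median(y),
                 wilcoxon_p = stats::wilcox.test(x, y,
                                                 alternative = "two.sided",
                                                 exact = FALSE)$p.value)
    }))
  }
  out <- mk("sv_nonsv", sv_rows)
  if ("sv_type" %in% names(partition)) {
    for (tp in c("deletion", "insertion")) {
      rows <- which(partition$group == "sv_nonsv" &
                      partition$sv_type == tp)
      if (length(rows)) out <- rbind(out, mk(tp, rows))
    }
  }
  rownames(out) <- NULL
  out
}
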