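# Collinear synteny blocks and homoeolog pairing.
#
# Anchors (reciprocal protein hits) are chained into collinear blocks by
# dynamic programming per chromosome pair and orientation; gene pairs inside
# retained blocks become syntenic orthologs (tetraploid vs ancestor) or
# homoeolog pairs (A vs B subgenome).

#' Assign ordinal gene ranks along each chromosome
#'
#' Rank is the gene's ordinal position by start coordinate; ties are broken
#' by gene id for determinism.
#'
#' @param genes Gene-model data frame (`gene_id`, `chrom`, `start`, ...).
#' @return `genes` with a `rank` column added.
#' @export
gene_ranks <- function(genes) {
  o <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[o, ]
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = seq_along)
  rownames(genes) <- NULL
  genes
}

#' Load anchors from a 12-column tabular protein hit file
#'
#' Standard blast-tab dialect: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore. Hits at or above
#' the E-value cutoff are dropped; at most `top_k` hits per query are kept,
#' ranked by bitscore.
#'
#' @param path Hit-table path (TSV, no header).
#' @param evalue_cutoff Exclusive E-value cutoff (default 1e-5; a hit is
#'   kept only if `evalue < evalue_cutoff`).
#' @param top_k Hits retained per query (default 5).
#' @return Data frame of anchors: `gene1`, `gene2`, `score` (bitscore),
#'   `evalue`.
#' @export
load_anchors <- function(path, evalue_cutoff = 1e-5, top_k = 5L) {
  stopifnot(evalue_cutoff > 0)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      score = numeric(), evalue = numeric()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 12L)
  if (length(bad)) {
    stop("malformed hit-table row at line ", bad[1L], ": expected 12 columns")
  }
  an <- data.frame(
    gene1 = vapply(f, `[`, character(1L), 1L),
    gene2 = vapply(f, `[`, character(1L), 2L),
    score = as.numeric(vapply(f, `[`, character(1L), 12L)),
    evalue = as.numeric(vapply(f, `[`, character(1L), 11L))
  )
  if (anyNA(an$score) || anyNA(an$evalue)) {
    stop("malformed hit-table row at line ",
         which(is.na(an$score) | is.na(an$evalue))[1L])
  }
  an <- an[an$evalue < evalue_cutoff, , drop = FALSE]
  an <- an[order(an$gene1, -an$score, an$gene2), , drop = FALSE]
  keep <- stats::ave(seq_len(nrow(an)), an$gene1,
                     FUN = seq_along) <= top_k
  an <- an[keep, , drop = FALSE]
  rownames(an) <- NULL
  an
}

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY*X", "")[[1L]]

.protein_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Compute anchors by all-vs-all protein alignment
#'
#' Desk-scale substitute for an external aligner: candidate pairs sharing at
#' least `min_shared_kmers` amino-acid k-mers are aligned globally
#' (Needleman-Wunsch, BLOSUM62, affine gaps) and kept when the alignment
#' score reaches `min_score`. The default score threshold is calibrated so
#' that shuffled (unrelated) length-100 proteins produce anchors at a rate
#' below 1 percent.
#'
#' @param prot1,prot2 Named character vectors of amino-acid sequences.
#' @param k K-mer size for the prefilter (default 5).
#' @param min_shared_kmers Minimum shared k-mers to attempt alignment
#'   (default 2).
#' @param min_score Minimum global alignment score (default 50).
#' @param top_k Hits retained per query gene (default 5).
#' @param self Set `TRUE` for a self-comparison; trivial self-pairs are
#'   excluded.
#' @return Data frame of anchors: `gene1`, `gene2`, `score`, `evalue`
#'   (`NA`; scores are raw).
#' @export
compute_anchors <- function(prot1, prot2, k = 5L, min_shared_kmers = 2L,
                            min_score = 50, top_k = 5L, self = FALSE) {
  ok <- function(p) all(strsplit(paste(p, collapse = ""), "")[[1L]] %in%
                          .AA_ALPHABET)
  if (!ok(prot1) || !ok(prot2)) {
    stop("non-amino-acid symbols in protein input")
  }
  # k-mer index over prot2
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(prot2)) {
    for (km in .protein_kmers(prot2[[j]], k)) {
      idx[[km]] <- c(idx[[km]], j)
    }
  }
  sub_mat <- "BLOSUM62"
  out <- list()
  for (i in seq_along(prot1)) {
    hits <- unlist(lapply(.protein_kmers(prot1[[i]], k),
                          function(km) idx[[km]]), use.names = FALSE)
    if (!length(hits)) next
    tab <- table(hits)
    cand <- as.integer(names(tab)[tab >= min_shared_kmers])
    if (self) cand <- cand[names(prot2)[cand] != names(prot1)[i]]
    if (!length(cand)) next
    sc <- vapply(cand, function(j) {
      Biostrings::pairwiseAlignment(
        Biostrings::AAString(prot1[[i]]), Biostrings::AAString(prot2[[j]]),
        substitutionMatrix = sub_mat, gapOpening = 10, gapExtension = 0.5,
        type = "global", scoreOnly = TRUE)
    }, numeric(1L))
    keep <- which(sc >= min_score)
    if (!length(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      gene1 = names(prot1)[i], gene2 = names(prot2)[cand[keep]],
      score = sc[keep], evalue = NA_real_)
  }
  if (!length(out)) {
    return(data.frame(gene1 = character(), gene2 = character(),
                      score = numeric(), evalue = numeric()))
  }
  an <- do.call(rbind, out)
  an <- an[order(an$gene1, -an$score, an$gene2), ]
  keep <- stats::ave(seq_len(nrow(an)), an$gene1, FUN = seq_along) <= top_k
  an <- an[keep, , drop = FALSE]
  rownames(an) <- NULL
  an
}

# Max-weight collinear chain by O(n^2) DP. `r1`, `r2` are anchor ranks (r2
# already flipped for minus orientation); both must strictly increase along a
# chain with rank gaps of at most `max_gap` genes on each side.
.best_chain <- function(r1, r2, score, max_gap) {
  n <- length(r1)
  o <- order(r1, r2)
  r1 <- r1[o]; r2 <- r2[o]; score <- score[o]
  dp <- score
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (r1[j] < r1[i] && r2[j] < r2[i] &&
          r1[i] - r1[j] <= max_gap + 1L && r2[i] - r2[j] <= max_gap + 1L) {
        cand <- dp[j] + score[i]
        if (cand > dp[i]) {
          dp[i] <- cand
          prev[i] <- j
        }
      }
    }
  }
  best <- which.max(dp)
  chain <- integer()
  at <- best
  while (!is.na(at)) {
    chain <- c(at, chain)
    at <- prev[at]
  }
  list(members = o[chain], score = dp[best])
}

#' Chain anchors into collinear synteny blocks
#'
#' Per chromosome pair and orientation, a maximum-scoring collinear chain is
#' extracted by dynamic programming (gene ranks strictly increasing on side
#' 1, and increasing / decreasing on side 2 for + / - orientation, with rank
#' gaps of at most `max_gap_genes` on either side); its anchors are removed
#' and extraction repeats until no chain with `min_pairs` anchors remains.
#' Each anchor is therefore assigned to at most one block.
#'
#' @param anchors Anchor data frame (`gene1`, `gene2`, `score`).
#' @param genes1,genes2 Gene models for the two sides (ranks computed via
#'   [gene_ranks()] if absent).
#' @param max_gap_genes Maximum rank gap bridged within a chain
#'   (default 25).
#' @param min_pairs Minimum anchors per retained block, inclusive
#'   (default 5).
#' @return List of class `synteny_blocks`: each element has `block_id`,
#'   `chrom1`, `chrom2`, `orientation`, `score`, `anchors` (data frame
#'   `gene1`, `gene2`, `score`, `rank1`, `rank2`).
#' @export
chain_blocks <- function(anchors, genes1, genes2, max_gap_genes = 25L,
                         min_pairs = 5L) {
  if (!"rank" %in% names(genes1)) genes1 <- gene_ranks(genes1)
  if (!"rank" %in% names(genes2)) genes2 <- gene_ranks(genes2)
  m1 <- match(anchors$gene1, genes1$gene_id)
  m2 <- match(anchors$gene2, genes2$gene_id)
  if (anyNA(m1) || anyNA(m2)) {
    stop("anchors reference genes missing from the gene models")
  }
  a <- data.frame(gene1 = anchors$gene1, gene2 = anchors$gene2,
                  score = anchors$score,
                  chrom1 = genes1$chrom[m1], chrom2 = genes2$chrom[m2],
                  rank1 = genes1$rank[m1], rank2 = genes2$rank[m2])
  blocks <- list()
  pair_keys <- sort(unique(paste(a$chrom1, a$chrom2, sep = "\r")))
  for (key in pair_keys) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    sub <- a[a$chrom1 == parts[1L] & a$chrom2 == parts[2L], , drop = FALSE]
    repeat {
      if (nrow(sub) < min_pairs) break
      plus <- .best_chain(sub$rank1, sub$rank2, sub$score, max_gap_genes)
      minus <- .best_chain(sub$rank1, -sub$rank2, sub$score, max_gap_genes)
      use_plus <- plus$score > minus$score ||
        (plus$score == minus$score &&
           length(plus$members) >= length(minus$members))
      ch <- if (use_plus) plus else minus
      if (length(ch$members) < min_pairs) break
      blocks[[length(blocks) + 1L]] <- list(
        chrom1 = parts[1L], chrom2 = parts[2L],
        orientation = if (use_plus) "+" else "-",
        score = ch$score,
        anchors = sub[ch$members,
                      c("gene1", "gene2", "score", "rank1", "rank2")]
      )
      sub <- sub[-ch$members, , drop = FALSE]
    }
  }
  # deterministic ids: order by score desc, then size desc, then chrom pair
  if (length(blocks)) {
    o <- order(-vapply(blocks, `[[`, numeric(1L), "score"),
               -vapply(blocks, function(b) nrow(b$anchors), integer(1L)),
               vapply(blocks, `[[`, character(1L), "chrom1"),
               vapply(blocks, `[[`, character(1L), "chrom2"))
    blocks <- blocks[o]
    for (i in seq_along(blocks)) {
      blocks[[i]]$block_id <- sprintf("blk%04d", i)
    }
  }
  class(blocks) <- "synteny_blocks"
  blocks
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("%d synteny block(s)\n", length(x)))
  for (b in x) {
    cat(sprintf("  %s: %s ~ %s (%s), %d pairs, score %.0f\n", b$block_id,
                b$chrom1, b$chrom2, b$orientation, nrow(b$anchors), b$score))
  }
  invisible(x)
}

#' Derive one-to-one homoeolog pairs from synteny blocks
#'
#' All anchor pairs inside retained blocks become candidate homoeolog
#' pairs; a one-to-one assignment is enforced by keeping the
#' highest-scoring pair per gene (ties broken by block size, then ids).
#'
#' @param blocks A `synteny_blocks` object from an A-vs-B comparison.
#' @return Data frame: `gene_a`, `gene_b`, `block_id`, `score`.
#' @export
homoeolog_pairs <- function(blocks) {
  if (!length(blocks)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      block_id = character(), score = numeric()))
  }
  cand <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(gene_a = b$anchors$gene1, gene_b = b$anchors$gene2,
               block_id = b$block_id, score = b$anchors$score,
               block_size = nrow(b$anchors))
  }))
  cand <- cand[order(-cand$score, -cand$block_size, cand$gene_a,
                     cand$gene_b), ]
  used_a <- character()
  used_b <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$gene_a[i] %in% used_a) && !(cand$gene_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$gene_a[i])
      used_b <- c(used_b, cand$gene_b[i])
    }
  }
  out <- cand[keep, c("gene_a", "gene_b", "block_id", "score")]
  rownames(out) <- NULL
  out
}

#' Paralog pairs from internal (self) synteny
#'
#' Runs the anchor and chaining machinery on a proteome against itself
#' (self-hits excluded; mirrored anchors collapsed by keeping the side with
#' the smaller chromosome/rank) and returns the gene pairs of internal
#' blocks with at least `min_genes` collinear genes — the input for a
#' Ks-based whole-genome-duplication scan.
#'
#' @param prot Named character vector of protein sequences.
#' @param genes Gene models covering `names(prot)`.
#' @param min_genes Minimum collinear genes per internal block, inclusive
#'   (default 5).
#' @param anchors Optional precomputed anchor table (e.g. from
#'   [load_anchors()]); computed with [compute_anchors()] when `NULL`.
#' @param max_gap_genes Maximum rank gap within a chain (default 25).
#' @param ... Passed to [compute_anchors()].
#' @return Data frame: `gene_a`, `gene_b`, `block_id`.
#' @export
self_synteny <- function(prot, genes, min_genes = 5L, anchors = NULL,
                         max_gap_genes = 25L, ...) {
  genes <- gene_ranks(genes)
  if (is.null(anchors)) {
    anchors <- compute_anchors(prot, prot, self = TRUE, ...)
  }
  anchors <- anchors[anchors$gene1 != anchors$gene2, , drop = FALSE]
  # collapse mirrored anchors: keep (smaller chrom, rank) as side 1
  m1 <- match(anchors$gene1, genes$gene_id)
  m2 <- match(anchors$gene2, genes$gene_id)
  key1 <- paste(genes$chrom[m1], sprintf("%06d", genes$rank[m1]))
  key2 <- paste(genes$chrom[m2], sprintf("%06d", genes$rank[m2]))
  flip <- key1 > key2
  g1 <- ifelse(flip, anchors$gene2, anchors$gene1)
  g2 <- ifelse(flip, anchors$gene1, anchors$gene2)
  anchors <- data.frame(gene1 = g1, gene2 = g2, score = anchors$score)
  anchors <- anchors[!duplicated(paste(anchors$gene1, anchors$gene2)), ]
  blocks <- chain_blocks(anchors, genes, genes,
                         max_gap_genes = max_gap_genes,
                         min_pairs = min_genes)
  if (!length(blocks)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      block_id = character()))
  }
  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(gene_a = b$anchors$gene1, gene_b = b$anchors$gene2,
               block_id = b$block_id)
  }))
  rownames(out) <- NULL
  out
}
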