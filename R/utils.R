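# Internal helpers shared across modules.

# Derive a per-operation seed from the user seed so that re-running one stage
# does not depend on how many random draws earlier stages consumed.
# Kept below 2^31 - 1 (R integers are 32-bit).
.op_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(op) * seq_along(utf8ToInt(op)))
  as.integer((abs(seed) * 7919 + h) %% (.Machine$integer.max - 1L)) + 1L
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute each site independently with probability `rate`, always to a
# different base, so the realized pairwise difference rate equals `rate`.
.mutate_dna <- function(seq, rate) {
  if (rate <= 0) return(seq)
  bases <- c("A", "C", "G", "T")
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(x)) < rate)
  if (length(hit)) {
    cur <- match(x[hit], bases)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    x[hit] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  paste(x, collapse = "")
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector or a [Biostrings::DNAStringSet] /
#'   [Biostrings::AAStringSet].
#' @param path Output path. Lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @param type `"DNA"` or `"AA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

# --- minimal GFF3 for gene/mRNA/CDS grids -----------------------------------
# The simulator emits single-CDS gene models; a hand-rolled three-feature
# writer keeps the dependency footprint down (rtracklayer's GFF3 export would
# need full GRanges metadata plumbing for the Parent hierarchy).

#' Write gene models as GFF3
#'
#' One `gene`, one `mRNA` and one `CDS` feature per gene model (the simulator
#' produces single-exon CDS genes). Coordinates written 1-based inclusive.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open internally), `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- g$start + 1L  # to 1-based inclusive
    e <- g$end
    writeLines(c(
      sprintf("%s\talloscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, s, e, g$strand, g$gene_id),
      sprintf("%s\talloscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
              g$chrom, s, e, g$strand, g$gene_id, g$gene_id),
      sprintf("%s\talloscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
              g$chrom, s, e, g$strand, g$gene_id, g$gene_id)
    ), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Reads `gene` features only and returns 0-based half-open coordinates.
#'
#' @param path GFF3 path.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) != 9L)
  if (length(bad)) {
    stop("malformed GFF3 row at line ", bad[1L])
  }
  f <- f[vapply(f, function(x) x[3L] == "gene", logical(1L))]
  if (!length(f)) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character()))
  }
  data.frame(
    gene_id = vapply(f, function(x) sub("^ID=([^;]+).*$", "\\1", x[9L]),
                     character(1L)),
    chrom = vapply(f, `[`, character(1L), 1L),
    start = as.integer(vapply(f, `[`, character(1L), 4L)) - 1L,
    end = as.integer(vapply(f, `[`, character(1L), 5L)),
    strand = vapply(f, `[`, character(1L), 7L)
  )
}

# --- minimal SAM text I/O ----------------------------------------------------
# Rsamtools reads BAM only; the simulator's evidence is plain SAM text (the
# deliverable must stay text), so the record table is (de)serialized here.

#' Write alignment records as SAM text
#'
#' @param records Data frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based), `mapq`, `cigar`, `seq`.
#' @param path Output path.
#' @param chrom_lengths Named vector of reference lengths for the `@SQ`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, chrom_lengths) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(chrom_lengths)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm,
                       as.integer(chrom_lengths[[nm]])), con)
  }
  if (nrow(records)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                       records$qname, as.integer(records$flag),
                       records$rname, as.integer(records$pos),
                       as.integer(records$mapq), records$cigar,
                       records$seq), con)
  }
  invisible(path)
}

#' Read SAM text into an alignment-record table
#'
#' @param path SAM path.
#' @return Data frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(),
                      mapq = integer(), cigar = character(),
                      seq = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 11L)
  if (length(bad)) stop("malformed SAM row at line ", bad[1L])
  data.frame(
    qname = vapply(f, `[`, character(1L), 1L),
    flag = as.integer(vapply(f, `[`, character(1L), 2L)),
    rname = vapply(f, `[`, character(1L), 3L),
    pos = as.integer(vapply(f, `[`, character(1L), 4L)),
    mapq = as.integer(vapply(f, `[`, character(1L), 5L)),
    cigar = vapply(f, `[`, character(1L), 6L),
    seq = vapply(f, `[`, character(1L), 10L)
  )
}

#' Parse a CIGAR string
#'
#' @param cigar CIGAR string (ops restricted to M, I, D, S).
#' @return Data frame with columns `op` and `len`.
#' @export
parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDS])", cigar)[[1L]]
  if (m[1L] == -1L) stop("unparseable CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("(\\d+)([MIDS])", cigar))[[1L]]
  data.frame(
    op = sub("\\d+", "", toks),
    len = as.integer(sub("[MIDS]", "", toks))
  )
}
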