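#' Simulate a pair of diverged diploid ancestor genomes
#'
#' Builds two diploid genomes (A and B) standing in for the progenitors of an
#' allotetraploid. Genes sit on a regular grid at identical coordinates in
#' both genomes; coding regions are filled with random sense codons so Ka/Ks
#' truth stays computable. Genome B is genome A with i.i.d. per-site
#' substitutions at rate `ancestor_divergence` (substitutions hit synonymous
#' and nonsynonymous positions uniformly; indels appear only as explicit SV
#' implants downstream).
#'
#' @param config A [sim_config()].
#' @param sequences If `FALSE`, only gene models and the ortholog map are
#'   produced (coordinate-level world; used for large depth-only
#'   simulations where materializing 10s of Mb of sequence is pointless).
#' @return A list of class `ancestor_sim` with elements `genomeA`, `genomeB`
#'   (named character vectors of chromosome sequences, or `NULL`), `genesA`,
#'   `genesB` (gene-model data frames, 0-based half-open), `ortholog_map`
#'   (columns `gene_a`, `gene_b`) and `chrom_lengths`.
#' @export
simulate_ancestors <- function(config, sequences = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.op_seed(config$seed, "ancestors"), {
    n_chr <- config$n_chromosomes
    len <- config$chromosome_length
    spacing <- config$gene_spacing
    offset <- 1000L

    genomeA <- if (sequences) character(n_chr) else NULL
    genomeB <- if (sequences) character(n_chr) else NULL
    genes <- vector("list", n_chr)

    for (ci in seq_len(n_chr)) {
      starts <- seq(offset, len - config$cds_length_range[2L] - 500L,
                    by = spacing)
      n_codons <- sample(seq(config$cds_length_range[1L] %/% 3L,
                             config$cds_length_range[2L] %/% 3L),
                         length(starts), replace = TRUE)
      cds_len <- n_codons * 3L
      strand <- sample(c("+", "-"), length(starts), replace = TRUE)
      genes[[ci]] <- data.frame(
        idx = seq_along(starts),
        chrom_idx = ci,
        start = as.integer(starts),
        end = as.integer(starts + cds_len),
        strand = strand
      )
      if (sequences) {
        seqA <- .random_dna(len)
        # overwrite gene bodies with sense codons (no stops)
        for (gi in seq_along(starts)) {
          cod <- paste(sample(.SENSE_CODONS, n_codons[gi], replace = TRUE),
                       collapse = "")
          substr(seqA, starts[gi] + 1L, starts[gi] + cds_len[gi]) <- cod
        }
        genomeA[ci] <- seqA
        genomeB[ci] <- .mutate_dna(seqA, config$ancestor_divergence)
      }
    }

    mk_genes <- function(sub) {
      do.call(rbind, lapply(genes, function(g) {
        data.frame(
          gene_id = sprintf("%sG%04d", .chrom_name(sub, g$chrom_idx), g$idx),
          chrom = .chrom_name(sub, g$chrom_idx),
          start = g$start, end = g$end, strand = g$strand
        )
      }))
    }
    genesA <- mk_genes("A")
    genesB <- mk_genes("B")
    chromsA <- .chrom_name("A", seq_len(n_chr))
    chromsB <- .chrom_name("B", seq_len(n_chr))
    if (sequences) {
      names(genomeA) <- chromsA
      names(genomeB) <- chromsB
    }
    chrom_lengths <- stats::setNames(rep(len, 2L * n_chr),
                                     c(chromsA, chromsB))
    out <- list(genomeA = genomeA, genomeB = genomeB,
                genesA = genesA, genesB = genesB,
                ortholog_map = data.frame(gene_a = genesA$gene_id,
                                          gene_b = genesB$gene_id),
                chrom_lengths = chrom_lengths)
    class(out) <- "ancestor_sim"
    out
  })
}

.SENSE_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

#' Simulate the allotetraploid genome with implanted HSEs and SVs
#'
#' Starting from the two ancestors, each subgenome accrues half of
#' `tetraploid_extra_divergence` on its own branch, then homoeologous
#' sequence exchanges overwrite the replaced interval with the donor
#' subgenome's homoeologous sequence, and structural variants are recorded
#' against the tetraploid-as-reference (the resequenced sample carrying them
#' is realized later as read evidence, not as a second FASTA). Insertion
#' donor loci are drawn per the requested origin class: within 10 kb of the
#' breakpoint (tandem), distal on the same chromosome (intra), or on another
#' chromosome (inter), which makes origin-classification truth exact.
#'
#' @param ancestors Output of [simulate_ancestors()].
#' @param config The same [sim_config()].
#' @return A list of class `tetraploid_sim` with elements `genome` (named
#'   character vector over all subgenome chromosomes, or `NULL` in the
#'   coordinate-only world), `genes` (combined gene models with a
#'   `subgenome` column), `truth` (class `alloscan_truth`) and `config`.
#' @export
simulate_tetraploid <- function(ancestors, config) {
  stopifnot(inherits(ancestors, "ancestor_sim"), inherits(config, "sim_config"))
  .with_seed(.op_seed(config$seed, "tetraploid"), {
    has_seq <- !is.null(ancestors$genomeA)
    genome <- NULL
    if (has_seq) {
      half <- config$tetraploid_extra_divergence / 2
      subA <- vapply(ancestors$genomeA, .mutate_dna, character(1L), half)
      subB <- vapply(ancestors$genomeB, .mutate_dna, character(1L), half)
      genome <- c(subA, subB)
    }

    genesA <- ancestors$genesA
    genesB <- ancestors$genesB
    genes <- rbind(cbind(genesA, subgenome = "A"),
                   cbind(genesB, subgenome = "B"))

    # --- implant bookkeeping + overlap validation ---------------------------
    other <- c(A = "B", B = "A")
    hse <- config$hse_spec
    hse_truth <- data.frame(donor = character(), donor_chrom = character(),
                            donor_start = integer(), donor_end = integer(),
                            replaced_chrom = character(),
                            replaced_start = integer(),
                            replaced_end = integer(), length = integer())
    if (!is.null(hse) && nrow(hse)) {
      hse_truth <- data.frame(
        donor = hse$donor,
        donor_chrom = .chrom_name(hse$donor, hse$chrom),
        donor_start = as.integer(hse$start),
        donor_end = as.integer(hse$start + hse$length),
        replaced_chrom = .chrom_name(other[hse$donor], hse$chrom),
        replaced_start = as.integer(hse$start),
        replaced_end = as.integer(hse$start + hse$length),
        length = as.integer(hse$length)
      )
    }

    sv <- config$sv_spec
    sv_truth <- data.frame(sv_id = character(), type = character(),
                           chrom = character(), pos = integer(),
                           pos2 = integer(), size = integer(),
                           origin = character(), donor_chrom = character(),
                           donor_pos = integer())
    if (!is.null(sv) && nrow(sv)) {
      chrom <- .chrom_name(sv$subgenome, sv$chrom)
      pos2 <- ifelse(sv$type == "deletion",
                     as.integer(sv$pos + sv$size), NA_integer_)
      donor_chrom <- rep(NA_character_, nrow(sv))
      donor_pos <- rep(NA_integer_, nrow(sv))
      n_chr <- config$n_chromosomes
      len <- config$chromosome_length
      for (i in seq_len(nrow(sv))) {
        if (sv$type[i] != "insertion") next
        sz <- sv$size[i]
        if (sv$origin[i] == "tandem") {
          donor_chrom[i] <- chrom[i]
          donor_pos[i] <- as.integer(sv$pos[i] +
            sample(seq(500L, 8000L), 1L))
        } else if (sv$origin[i] == "intra") {
          donor_chrom[i] <- chrom[i]
          lo <- (sv$pos[i] + 50000L) %% (len - sz - 50000L)
          donor_pos[i] <- as.integer(lo + sample.int(20000L, 1L))
          # keep the donor well beyond the 10 kb tandem window
          if (abs(donor_pos[i] - sv$pos[i]) <= 20000L) {
            donor_pos[i] <- as.integer((sv$pos[i] + len %/% 2L) %%
                                         (len - sz - 1000L)) + 500L
          }
        } else {  # inter
          oc <- if (n_chr > 1L) (sv$chrom[i] %% n_chr) + 1L else sv$chrom[i]
          osub <- if (n_chr > 1L) sv$subgenome[i] else other[sv$subgenome[i]]
          donor_chrom[i] <- .chrom_name(osub, oc)
          donor_pos[i] <- sample(seq(10000L, len - sz - 10000L), 1L)
        }
      }
      sv_truth <- data.frame(
        sv_id = sprintf("sv%03d", seq_len(nrow(sv))),
        type = sv$type, chrom = chrom, pos = as.integer(sv$pos),
        pos2 = pos2, size = as.integer(sv$size), origin = sv$origin,
        donor_chrom = donor_chrom, donor_pos = donor_pos
      )
      if (any(sv$pos < 1L | sv$pos + sv$size > config$chromosome_length)) {
        stop("SV implant outside chromosome bounds")
      }
    }

    .check_implant_overlaps(hse_truth, sv_truth)

    # --- apply HSEs to sequence --------------------------------------------
    if (has_seq && nrow(hse_truth)) {
      for (i in seq_len(nrow(hse_truth))) {
        h <- hse_truth[i, ]
        donor_seq <- substr(genome[[h$donor_chrom]],
                            h$donor_start + 1L, h$donor_end)
        substr(genome[[h$replaced_chrom]],
               h$replaced_start + 1L, h$replaced_end) <- donor_seq
      }
    }

    map <- data.frame(
      gene_a = genesA$gene_id, chrom_a = genesA$chrom,
      start_a = genesA$start, end_a = genesA$end,
      gene_b = genesB$gene_id, chrom_b = genesB$chrom,
      start_b = genesB$start, end_b = genesB$end
    )

    truth <- list(hse = hse_truth, sv = sv_truth, homoeolog_map = map,
                  bias = NULL, chrom_lengths = ancestors$chrom_lengths)
    class(truth) <- "alloscan_truth"
    out <- list(genome = genome, genes = genes, truth = truth,
                config = config)
    class(out) <- "tetraploid_sim"
    out
  })
}

# Implants must not overlap one another (per chromosome).
.check_implant_overlaps <- function(hse_truth, sv_truth) {
  iv <- rbind(
    if (nrow(hse_truth)) data.frame(
      chrom = c(hse_truth$donor_chrom, hse_truth$replaced_chrom),
      start = c(hse_truth$donor_start, hse_truth$replaced_start),
      end = c(hse_truth$donor_end, hse_truth$replaced_end)
    ),
    if (nrow(sv_truth)) data.frame(
      chrom = sv_truth$chrom,
      start = sv_truth$pos - 1L,
      end = ifelse(sv_truth$type == "deletion",
                   sv_truth$pos2 - 1L, sv_truth$pos)
    )
  )
  if (is.null(iv) || nrow(iv) < 2L) return(invisible(TRUE))
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start[-1L] < x$end[-nrow(x)])) {
      stop("overlapping implants on ", ch)
    }
  }
  invisible(TRUE)
}

#' @export
print.alloscan_truth <- function(x, ...) {
  cat("Synthetic truth set\n")
  cat(sprintf("  HSEs: %d (%s bp total)\n", nrow(x$hse),
              format(sum(x$hse$length), big.mark = ",")))
  cat(sprintf("  SVs:  %d (%d deletions, %d insertions)\n", nrow(x$sv),
              sum(x$sv$type == "deletion"), sum(x$sv$type == "insertion")))
  cat(sprintf("  homoeolog pairs: %d\n", nrow(x$homoeolog_map)))
  if (!is.null(x$bias)) {
    cat(sprintf("  expression-biased pairs: %d\n",
                sum(x$bias$direction != "none")))
  }
  invisible(x)
}

#' @export
print.tetraploid_sim <- function(x, ...) {
  cat("Simulated allotetraploid\n")
  cat(sprintf("  chromosomes: %s\n",
              paste(names(x$truth$chrom_lengths), collapse = ", ")))
  cat(sprintf("  sequences materialized: %s\n",
              if (is.null(x$genome)) "no (coordinate-only)" else "yes"))
  print(x$truth)
  invisible(x)
}

#' Extract CDS sequences for a set of gene models
#'
#' Strand-aware (minus-strand CDS are reverse-complemented).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param genes Gene-model data frame (0-based half-open).
#' @return Named character vector of CDS sequences.
#' @export
extract_cds <- function(genome, genes) {
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    s <- substr(genome[[g$chrom]], g$start + 1L, g$end)
    if (g$strand == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    out[i] <- s
  }
  names(out) <- genes$gene_id
  out
}

#' Translate CDS sequences to proteins
#'
#' @param cds Named character vector of CDS sequences (lengths multiples
#'   of 3).
#' @return Named character vector of amino-acid sequences (universal code;
#'   internal stops rendered as `*`).
#' @export
translate_cds <- function(cds) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cds),
                                           if.fuzzy.codon = "X"))
  names(aa) <- names(cds)
  aa
}
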