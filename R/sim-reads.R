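#' Simulate soft-clipped read evidence for implanted SVs
#'
#' Realizes the resequenced sample carrying the implanted SVs as alignment
#' records against the tetraploid reference. Every SV breakpoint receives
#' `sv_support` soft-clipped records whose clipped subsequence ("flag") is
#' copied from the true donor locus: for insertions the flag carries the
#' inserted sequence (itself copied from the tandem / intra / inter donor
#' locus recorded in the truth set), for deletions the flag carries the
#' sequence across the deleted segment. Sides alternate between 3' clips
#' (`<m>M<s>S`, read runs off the left junction) and 5' clips (`<s>S<m>M`).
#' Background records are fully matched, except a configurable fraction
#' given short (< 10 bp) terminal clips to exercise the confident-clip
#' filter.
#'
#' @param tetraploid A `tetraploid_sim` with materialized sequences.
#' @param config The [sim_config()].
#' @return Data frame of SAM-style records (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`); serialize with [write_sam()].
#' @export
simulate_clipped_reads <- function(tetraploid, config) {
  stopifnot(inherits(tetraploid, "tetraploid_sim"))
  if (is.null(tetraploid$genome)) {
    stop("simulate_clipped_reads needs materialized sequences")
  }
  clip <- config$sv_clip_len
  rl <- config$read_length
  if (rl <= clip) stop("read_length must exceed sv_clip_len")
  genome <- tetraploid$genome
  sv <- tetraploid$truth$sv
  .with_seed(.op_seed(config$seed, "reads"), {
    recs <- list()
    ref <- function(ch, from, to) substr(genome[[ch]], from, to)

    emit_junction <- function(sv_id, ch, junction, left_flag, right_flag) {
      # left_flag: clipped sequence seen past the junction by reads entering
      # from the left (3' clip); right_flag: clipped sequence seen by reads
      # entering from the right (5' clip).
      n <- config$sv_support
      side3 <- rep(c(TRUE, FALSE), length.out = n)
      out <- vector("list", n)
      for (i in seq_len(n)) {
        m <- rl - clip - sample.int(40L, 1L)  # jitter aligned length
        if (side3[i]) {
          pos <- junction - m
          aligned <- ref(ch, pos, junction - 1L)
          out[[i]] <- data.frame(
            qname = sprintf("%s_3p_%02d", sv_id, i), flag = 0L, rname = ch,
            pos = pos, mapq = 60L,
            cigar = sprintf("%dM%dS", m, clip),
            seq = paste0(aligned, left_flag)
          )
        } else {
          pos <- junction
          aligned <- ref(ch, pos, pos + m - 1L)
          out[[i]] <- data.frame(
            qname = sprintf("%s_5p_%02d", sv_id, i), flag = 0L, rname = ch,
            pos = pos, mapq = 60L,
            cigar = sprintf("%dS%dM", clip, m),
            seq = paste0(right_flag, aligned)
          )
        }
      }
      do.call(rbind, out)
    }

    for (i in seq_len(nrow(sv))) {
      s <- sv[i, ]
      if (s$type == "insertion") {
        if (s$size < clip) {
          stop("insertion ", s$sv_id, " smaller than sv_clip_len")
        }
        ins <- ref(s$donor_chrom, s$donor_pos, s$donor_pos + s$size - 1L)
        recs[[length(recs) + 1L]] <- emit_junction(
          s$sv_id, s$chrom, s$pos,
          left_flag = substr(ins, 1L, clip),
          right_flag = substr(ins, s$size - clip + 1L, s$size)
        )
      } else {  # deletion: junctions at pos (left) and pos2 (right)
        recs[[length(recs) + 1L]] <- emit_junction(
          paste0(s$sv_id, "L"), s$chrom, s$pos,
          left_flag = ref(s$chrom, s$pos2, s$pos2 + clip - 1L),
          right_flag = ref(s$chrom, s$pos - clip, s$pos - 1L)
        )
        recs[[length(recs) + 1L]] <- emit_junction(
          paste0(s$sv_id, "R"), s$chrom, s$pos2,
          left_flag = ref(s$chrom, s$pos2, s$pos2 + clip - 1L),
          right_flag = ref(s$chrom, s$pos - clip, s$pos - 1L)
        )
      }
    }

    # background: fully matched records, some with sub-threshold clips
    for (ch in names(genome)) {
      n <- config$background_reads
      if (n < 1L) next
      len <- nchar(genome[[ch]])
      pos <- sample.int(len - rl, n)
      noisy <- stats::runif(n) < config$clip_noise_frac
      bg <- vector("list", n)
      for (j in seq_len(n)) {
        sq <- ref(ch, pos[j], pos[j] + rl - 1L)
        if (noisy[j]) {
          sclip <- sample.int(9L, 1L)
          sq <- paste0(substr(sq, 1L, rl - sclip), .random_dna(sclip))
          cig <- sprintf("%dM%dS", rl - sclip, sclip)
        } else {
          cig <- sprintf("%dM", rl)
        }
        bg[[j]] <- data.frame(qname = sprintf("bg_%s_%04d", ch, j),
                              flag = 0L, rname = ch, pos = pos[j],
                              mapq = 60L, cigar = cig, seq = sq)
      }
      recs[[length(recs) + 1L]] <- do.call(rbind, bg)
    }
    out <- do.call(rbind, recs)
    if (is.null(out)) {
      out <- data.frame(qname = character(), flag = integer(),
                        rname = character(), pos = integer(),
                        mapq = integer(), cigar = character(),
                        seq = character())
    }
    rownames(out) <- NULL
    out
  })
}
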