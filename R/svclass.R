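# Structural-variant confirmation and classification from soft-clip evidence.
#
# Candidate SVs (from an external caller; BreakDancer-style TSV dialect) are
# confirmed by soft-clipped reads near their breakpoints, size-filtered, and
# insertions are traced to their donor locus by remapping the clipped
# subsequence ("flag") end-to-end against the reference.

#' Read a BreakDancer-style candidate SV table
#'
#' Lenient TSV parser: header lines starting with `#` are skipped; the
#' columns `chrom1`, `pos1`, `chrom2`, `pos2`, `type`, `size`, `score` are
#' mapped (by name if a header row is present, else by position); unknown
#' columns are preserved.
#'
#' @param path TSV path.
#' @return Data frame of `sv_candidate` rows: `sv_id`, `type` (lower case),
#'   `chrom`, `pos`, `pos2`, `size`, `score`, plus any extra columns.
#' @export
read_sv_candidates <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  has_header <- length(lines) && grepl("chrom1", lines[1L], fixed = TRUE)
  df <- utils::read.table(text = lines, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) {
    names(df)[seq_len(min(7L, ncol(df)))] <-
      c("chrom1", "pos1", "chrom2", "pos2", "type", "size",
        "score")[seq_len(min(7L, ncol(df)))]
  }
  type <- tolower(df$type)
  type[type %in% c("del")] <- "deletion"
  type[type %in% c("ins")] <- "insertion"
  type[type %in% c("inv")] <- "inversion"
  type[type %in% c("ctx", "itx")] <- "translocation"
  out <- data.frame(sv_id = sprintf("sv%03d", seq_len(nrow(df))),
                    type = type, chrom = df$chrom1,
                    pos = as.integer(df$pos1),
                    pos2 = as.integer(df$pos2),
                    size = as.integer(df$size),
                    score = df$score)
  extra <- setdiff(names(df), c("chrom1", "pos1", "chrom2", "pos2",
                                "type", "size", "score"))
  if (length(extra)) out <- cbind(out, df[, extra, drop = FALSE])
  out
}

#' Candidate table for implanted SVs
#'
#' Builds the candidate-caller input contract directly from a simulation
#' truth set, so the confirmation stage can be exercised without an
#' external caller.
#'
#' @param truth An `alloscan_truth`.
#' @return Candidate data frame in the [read_sv_candidates()] layout.
#' @export
sv_candidates_from_truth <- function(truth) {
  sv <- truth$sv
  data.frame(sv_id = sv$sv_id, type = sv$type, chrom = sv$chrom,
             pos = sv$pos,
             pos2 = ifelse(is.na(sv$pos2), sv$pos, sv$pos2),
             size = sv$size, score = 99)
}

#' Harvest confident soft-clip evidence near a breakpoint
#'
#' Soft-clipped records whose clip junction lies within `window` bp of the
#' breakpoint and whose clip is longer than `min_clip` bp (strict) are
#' returned with the clipped subsequence ("flag") and its side: `5p` for a
#' leading clip (`<s>S<m>M`), `3p` for a trailing clip (`<m>M<s>S`). The
#' junction of a leading clip is the mapped start; of a trailing clip, the
#' mapped end + 1.
#'
#' @param alignments Alignment-record table (see [read_sam()]).
#' @param chrom,breakpoint Breakpoint position (1-based).
#' @param window Distance window around the breakpoint in bp (default 300,
#'   two-sided).
#' @param min_clip Strict minimum clip length in bp (default 10; a clip is
#'   confident only if longer).
#' @return Data frame: `read_id`, `side`, `clip_len`, `flag_seq`,
#'   `junction`.
#' @export
harvest_clips <- function(alignments, chrom, breakpoint, window = 300L,
                          min_clip = 10L) {
  empty <- data.frame(read_id = character(), side = character(),
                      clip_len = integer(), flag_seq = character(),
                      junction = integer())
  if (is.null(alignments) || !nrow(alignments)) return(empty)
  al <- alignments[alignments$rname == chrom &
                     grepl("S", alignments$cigar, fixed = TRUE), ,
                   drop = FALSE]
  if (!nrow(al)) return(empty)
  out <- list()
  for (i in seq_len(nrow(al))) {
    cg <- parse_cigar(al$cigar[i])
    qlen <- sum(cg$len[cg$op %in% c("M", "I", "S")])
    if (qlen != nchar(al$seq[i])) {
      stop("CIGAR/sequence length mismatch for read ", al$qname[i])
    }
    rlen <- sum(cg$len[cg$op %in% c("M", "D")])
    n <- nrow(cg)
    if (cg$op[1L] == "S") {
      junction <- al$pos[i]
      if (abs(junction - breakpoint) <= window && cg$len[1L] > min_clip) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = al$qname[i], side = "5p", clip_len = cg$len[1L],
          flag_seq = substr(al$seq[i], 1L, cg$len[1L]),
          junction = junction)
      }
    }
    if (cg$op[n] == "S") {
      junction <- al$pos[i] + rlen
      if (abs(junction - breakpoint) <= window && cg$len[n] > min_clip) {
        out[[length(out) + 1L]] <- data.frame(
          read_id = al$qname[i], side = "3p", clip_len = cg$len[n],
          flag_seq = substr(al$seq[i], nchar(al$seq[i]) - cg$len[n] + 1L,
                            nchar(al$seq[i])),
          junction = junction)
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Confirm a candidate SV from soft-clip support
#'
#' A breakpoint passes when supported by more than `min_support` confident
#' clips (strict). Deletions (and other two-breakpoint SVs) pass when at
#' least one breakpoint passes by default; set `require_both = TRUE` for
#' the strict mode demanding both.
#'
#' @param candidate One row of a candidate table (see
#'   [read_sv_candidates()]).
#' @param alignments Alignment records used as evidence.
#' @param min_support Strict minimum confident-clip count (default 5).
#' @param require_both Require both breakpoints to pass for
#'   two-breakpoint SVs (default `FALSE`).
#' @param window,min_clip Passed to [harvest_clips()].
#' @return List of class `confident_sv`: candidate fields plus
#'   `n_confident_clips` (per breakpoint), `evidence` (clip table), and
#'   `status` (`confident` or `rejected_support`).
#' @export
confirm_sv <- function(candidate, alignments, min_support = 5L,
                       require_both = FALSE, window = 300L, min_clip = 10L) {
  bps <- candidate$pos
  if (candidate$type %in% c("deletion", "inversion", "translocation") &&
      !is.na(candidate$pos2) && candidate$pos2 != candidate$pos) {
    bps <- c(bps, candidate$pos2)
  }
  ev <- lapply(bps, function(bp) {
    harvest_clips(alignments, candidate$chrom, bp, window, min_clip)
  })
  counts <- vapply(ev, nrow, integer(1L))
  pass <- counts > min_support
  ok <- if (require_both) all(pass) else any(pass)
  out <- list(sv_id = candidate$sv_id, type = candidate$type,
              chrom = candidate$chrom, pos = candidate$pos,
              pos2 = candidate$pos2, size = candidate$size,
              breakpoints = bps, n_confident_clips = counts,
              evidence = do.call(rbind, ev),
              status = if (ok) "confident" else "rejected_support",
              origin = NA_character_, donor_chrom = NA_character_,
              donor_pos = NA_integer_)
  class(out) <- "confident_sv"
  out
}

#' Apply the deletion/insertion size gate
#'
#' Deletions and insertions smaller than `min_size` or larger than
#' `max_size` are discarded (`rejected_size`); other SV types pass through
#' unfiltered.
#'
#' @param sv A `confident_sv`.
#' @param min_size,max_size Inclusive retention bounds in bp (defaults 5
#'   and 10000).
#' @return The `confident_sv`, with `status` possibly set to
#'   `rejected_size`.
#' @export
size_filter <- function(sv, min_size = 5L, max_size = 10000L) {
  stopifnot(inherits(sv, "confident_sv"))
  if (sv$type %in% c("deletion", "insertion") &&
      (sv$size < min_size || sv$size > max_size)) {
    sv$status <- "rejected_size"
  }
  sv
}

#' @export
print.confident_sv <- function(x, ...) {
  cat(sprintf("%s %s at %s:%d (size %d bp): %s; clips per breakpoint: %s\n",
              x$sv_id, x$type, x$chrom, x$pos, x$size, x$status,
              paste(x$n_confident_clips, collapse = "/")))
  if (!is.na(x$origin)) {
    cat(sprintf("  origin: %s (donor %s:%d)\n", x$origin,
                x$donor_chrom, x$donor_pos))
  }
  invisible(x)
}

# End-to-end flag remapping: all reference loci where `flag` matches with at
# most `max_mismatch` substitutions (no indels), on the forward strand,
# with the mismatch count per locus (best-alignment ranking downstream:
# homoeologous near-copies match with more mismatches than the true donor).
.map_flag <- function(flag, reference, max_mismatch = 2L) {
  pat <- Biostrings::DNAString(flag)
  out <- list()
  for (ch in names(reference)) {
    subj <- Biostrings::DNAString(reference[[ch]])
    m <- Biostrings::matchPattern(pat, subj,
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    if (length(m)) {
      nm <- Biostrings::neditAt(pat, subj, at = Biostrings::start(m),
                                with.indels = FALSE)
      out[[length(out) + 1L]] <- data.frame(chrom = ch,
                                            pos = Biostrings::start(m),
                                            mismatches = nm)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

#' Classify an insertion's origin from its flag sequences
#'
#' Flags (clipped subsequences) of at least `min_flag` bp are remapped
#' end-to-end against the reference (substitution-only matching with at
#' most `max_mismatch` mismatches). If any flag matches within
#' `tandem_window` bp of the breakpoint the insertion is tandem. Otherwise
#' a 5' flag and a 3' flag both matching one other locus on the same
#' chromosome at most `pair_window` bp apart resolve the donor: intra if
#' that chromosome is the breakpoint's, inter otherwise. With no
#' consistent match the origin is unresolved.
#'
#' @param sv A confirmed insertion (`confident_sv`).
#' @param reference Named character vector of reference chromosome
#'   sequences.
#' @param tandem_window,pair_window Distance windows in bp (defaults
#'   10000, inclusive).
#' @param max_mismatch Mismatches tolerated in flag remapping (default 2).
#' @param min_flag Minimum flag length remapped (default 15).
#' @return The `confident_sv` with `origin` (`tandem` / `intra` / `inter` /
#'   `unresolved`), `donor_chrom` and `donor_pos` filled when resolved.
#' @export
classify_insertion <- function(sv, reference, tandem_window = 10000L,
                               pair_window = 10000L, max_mismatch = 2L,
                               min_flag = 15L) {
  stopifnot(inherits(sv, "confident_sv"), sv$type == "insertion")
  ev <- sv$evidence
  ev <- ev[nchar(ev$flag_seq) >= min_flag, , drop = FALSE]
  sv$origin <- "unresolved"
  if (is.null(ev) || !nrow(ev)) return(sv)
  if (!sv$chrom %in% names(reference)) {
    stop("reference is missing chromosome ", sv$chrom)
  }
  hits <- lapply(unique(ev$flag_seq), .map_flag, reference = reference,
                 max_mismatch = max_mismatch)
  names(hits) <- unique(ev$flag_seq)

  # tandem: any flag hit within tandem_window of the breakpoint
  for (fs in names(hits)) {
    h <- hits[[fs]]
    near <- h[h$chrom == sv$chrom &
                abs(h$pos - sv$pos) <= tandem_window, , drop = FALSE]
    if (nrow(near)) {
      best <- near[which.min(abs(near$pos - sv$pos)), ]
      sv$origin <- "tandem"
      sv$donor_chrom <- best$chrom
      sv$donor_pos <- best$pos
      return(sv)
    }
  }

  # paired flags: one 5' and one 3' flag matching the same chromosome
  # within pair_window of each other; candidates ranked by total mismatch
  # count (best end-to-end alignment), then by flag-to-flag distance
  f5 <- unique(ev$flag_seq[ev$side == "5p"])
  f3 <- unique(ev$flag_seq[ev$side == "3p"])
  best <- NULL
  for (a in f3) for (b in f5) {
    ha <- hits[[a]]
    hb <- hits[[b]]
    for (ca in unique(ha$chrom)) {
      ia <- which(ha$chrom == ca)
      ib <- which(hb$chrom == ca)
      if (!length(ia) || !length(ib)) next
      for (x in ia) for (y in ib) {
        d <- abs(ha$pos[x] - hb$pos[y])
        if (d > pair_window) next
        # rank: fewest mismatches; then the breakpoint's own chromosome
        # (a homoeologous near-copy of a same-chromosome donor can match
        # the flags equally well); then smallest flag-to-flag distance
        cand <- list(chrom = ca, pos = min(ha$pos[x], hb$pos[y]),
                     dist = d, own = ca == sv$chrom,
                     mm = ha$mismatches[x] + hb$mismatches[y])
        better <- is.null(best) || cand$mm < best$mm ||
          (cand$mm == best$mm && cand$own && !best$own) ||
          (cand$mm == best$mm && cand$own == best$own &&
             cand$dist < best$dist)
        if (better) best <- cand
      }
    }
  }
  if (!is.null(best)) {
    sv$origin <- if (best$chrom == sv$chrom) "intra" else "inter"
    sv$donor_chrom <- best$chrom
    sv$donor_pos <- best$pos
  }
  sv
}

#' Confirm, size-filter and classify a full candidate table
#'
#' @param candidates Candidate data frame (see [read_sv_candidates()]).
#' @param alignments Alignment records.
#' @param reference Reference sequences (needed to classify insertions;
#'   optional).
#' @param ... Passed to [confirm_sv()], [size_filter()] and
#'   [classify_insertion()].
#' @param min_support,window,min_clip,min_size,max_size,tandem_window,pair_window
#'   Stage parameters (see the stage functions).
#' @return List of `confident_sv` objects, plus a `summary` attribute
#'   (data frame of `sv_id`, `type`, `status`, `origin`).
#' @export
classify_svs <- function(candidates, alignments, reference = NULL,
                         min_support = 5L, window = 300L, min_clip = 10L,
                         min_size = 5L, max_size = 10000L,
                         tandem_window = 10000L, pair_window = 10000L, ...) {
  out <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    sv <- confirm_sv(candidates[i, ], alignments, min_support,
                     window = window, min_clip = min_clip)
    sv <- size_filter(sv, min_size, max_size)
    if (sv$status == "confident" && sv$type == "insertion" &&
        !is.null(reference)) {
      sv <- classify_insertion(sv, reference, tandem_window, pair_window,
                               ...)
    }
    out[[i]] <- sv
  }
  names(out) <- candidates$sv_id
  attr(out, "summary") <- data.frame(
    sv_id = vapply(out, `[[`, character(1L), "sv_id"),
    type = vapply(out, `[[`, character(1L), "type"),
    status = vapply(out, `[[`, character(1L), "status"),
    origin = vapply(out, `[[`, character(1L), "origin")
  )
  out
}

#' Annotate genes with overlapping SVs and build an upstream-distance profile
#'
#' A gene is hit when a confident SV overlaps its gene body or its
#' strand-aware upstream window of `upstream_bp`. The profile counts SVs in
#' distance bins upstream of gene starts, alongside a matched
#' random-interval control (same number of intervals, uniform positions,
#' fixed seed) so enrichment near genes is visible.
#'
#' @param svs Output of [classify_svs()] (or a list of `confident_sv`);
#'   only `confident` SVs annotate.
#' @param genes Gene-model data frame (0-based half-open, with `strand`).
#' @param chrom_lengths Named chromosome lengths (for the random control).
#' @param upstream_bp Upstream window in bp (default 2000).
#' @param profile_max,profile_bin Profile reach and bin width in bp
#'   (defaults 5000 and 500).
#' @param seed Seed for the random control (default 1).
#' @return List: `annotations` (data frame `gene_id`, `region`
#'   (`upstream` / `gene_body` / `none`), `sv_ids`) and `profile`
#'   (data frame `bin_start`, `bin_end`, `gene_count`, `control_count`).
#' @export
annotate_genes <- function(svs, genes, chrom_lengths = NULL,
                           upstream_bp = 2000L, profile_max = 5000L,
                           profile_bin = 500L, seed = 1L) {
  conf <- Filter(function(s) s$status == "confident", svs)
  sv_df <- if (length(conf)) {
    data.frame(
      sv_id = vapply(conf, `[[`, character(1L), "sv_id"),
      chrom = vapply(conf, `[[`, character(1L), "chrom"),
      start = vapply(conf, function(s) s$pos - 1L, integer(1L)),
      end = vapply(conf, function(s) {
        if (s$type == "deletion" && !is.na(s$pos2)) s$pos2 - 1L else s$pos
      }, integer(1L)),
      type = vapply(conf, `[[`, character(1L), "type")
    )
  } else {
    data.frame(sv_id = character(), chrom = character(), start = integer(),
               end = integer(), type = character())
  }

  up_start <- ifelse(genes$strand == "+", genes$start - upstream_bp,
                     genes$end)
  up_end <- ifelse(genes$strand == "+", genes$start,
                   genes$end + upstream_bp)
  region <- rep("none", nrow(genes))
  sv_ids <- rep("", nrow(genes))
  if (nrow(sv_df)) {
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      si <- which(sv_df$chrom == ch)
      if (!length(si)) next
      svr <- IRanges::IRanges(start = sv_df$start[si] + 1L,
                              end = pmax(sv_df$end[si], sv_df$start[si] + 1L))
      body <- IRanges::IRanges(start = genes$start[gi] + 1L,
                               end = genes$end[gi])
      up <- IRanges::IRanges(start = up_start[gi] + 1L, end = up_end[gi])
      hit_body <- IRanges::findOverlaps(body, svr)
      hit_up <- IRanges::findOverlaps(up, svr)
      for (k in seq_along(gi)) {
        b <- S4Vectors::subjectHits(hit_body)[
          S4Vectors::queryHits(hit_body) == k]
        u <- S4Vectors::subjectHits(hit_up)[
          S4Vectors::queryHits(hit_up) == k]
        ids <- unique(sv_df$sv_id[si][c(b, u)])
        if (length(b)) {
          region[gi[k]] <- "gene_body"
        } else if (length(u)) {
          region[gi[k]] <- "upstream"
        }
        if (length(ids)) sv_ids[gi[k]] <- paste(ids, collapse = ",")
      }
    }
  }
  annotations <- data.frame(gene_id = genes$gene_id, region = region,
                            sv_ids = sv_ids)

  # upstream-distance profile: SV midpoint distance upstream of gene start
  bins <- seq(0L, profile_max, by = profile_bin)
  count_profile <- function(starts_bp, chroms, strands) {
    cnt <- integer(length(bins) - 1L)
    if (!nrow(sv_df)) return(cnt)
    mid <- (sv_df$start + sv_df$end) / 2
    for (g in seq_along(starts_bp)) {
      si <- which(sv_df$chrom == chroms[g])
      if (!length(si)) next
      d <- if (strands[g] == "+") starts_bp[g] - mid[si]
      else mid[si] - starts_bp[g]
      d <- d[d >= 0 & d < profile_max]
      if (length(d)) {
        cnt <- cnt + tabulate(findInterval(d, bins), length(bins) - 1L)
      }
    }
    cnt
  }
  gene_start_bp <- ifelse(genes$strand == "+", genes$start, genes$end)
  gene_cnt <- count_profile(gene_start_bp, genes$chrom, genes$strand)
  control_cnt <- integer(length(bins) - 1L)
  if (!is.null(chrom_lengths)) {
    control_cnt <- .with_seed(.op_seed(seed, "sv_profile_control"), {
      ch <- sample(names(chrom_lengths), nrow(genes), replace = TRUE)
      pos <- vapply(ch, function(c2) {
        sample.int(chrom_lengths[[c2]], 1L)
      }, integer(1L))
      count_profile(pos, ch, sample(c("+", "-"), nrow(genes),
                                    replace = TRUE))
    })
  }
  profile <- data.frame(bin_start = bins[-length(bins)],
                        bin_end = bins[-1L],
                        gene_count = gene_cnt,
                        control_count = control_cnt)
  list(annotations = annotations, profile = profile)
}

#' Partition homoeolog pairs by SV status
#'
#' Exhaustive, mutually exclusive partition: pairs with exactly one SV-hit
#' copy are `sv_nonsv` (SV side labeled), pairs with both copies hit are
#' `both_sv`, pairs with neither are `unaffected`.
#'
#' @param pairs Homoeolog pairs (`gene_a`, `gene_b`).
#' @param annotations Gene annotations from [annotate_genes()].
#' @return Data frame: `gene_a`, `gene_b`, `group`, `sv_side` (`A`, `B` or
#'   `NA`).
#' @export
partition_homoeologs <- function(pairs, annotations) {
  look <- stats::setNames(annotations$region, annotations$gene_id)
  miss <- setdiff(c(pairs$gene_a, pairs$gene_b), names(look))
  if (length(miss)) {
    stop("gene(s) missing annotation: ", paste(utils::head(miss, 3L),
                                               collapse = ", "))
  }
  hit_a <- look[pairs$gene_a] != "none"
  hit_b <- look[pairs$gene_b] != "none"
  group <- ifelse(hit_a & hit_b, "both_sv",
                  ifelse(hit_a | hit_b, "sv_nonsv", "unaffected"))
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             group = group,
             sv_side = ifelse(group == "sv_nonsv",
                              ifelse(hit_a, "A", "B"), NA_character_))
}
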