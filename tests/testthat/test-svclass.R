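# Soft-clip harvesting, SV confirmation, size gating, insertion origin
# classification, gene annotation and homoeolog partitioning.

mk_read <- function(qname, chrom, pos, cigar, seq) {
  data.frame(qname = qname, flag = 0L, rname = chrom, pos = pos,
             mapq = 60L, cigar = cigar, seq = seq)
}

# n soft-clipped reads (3' side) whose clip junction sits at `junction`
clip_reads <- function(n, chrom, junction, clip = 20L, m = 80L,
                       prefix = "r") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    mk_read(sprintf("%s%02d", prefix, i), chrom, junction - m,
            sprintf("%dM%dS", m, clip),
            paste(rep("A", m + clip), collapse = ""))
  }))
}

test_that("harvest_clips applies the distance window and strict clip minimum", {
  reads <- rbind(
    mk_read("in20", "c1", 900, "80M20S", strrep("A", 100)),   # junction 980
    mk_read("clip8", "c1", 920, "92M8S", strrep("A", 100)),   # clip too short
    mk_read("far", "c1", 200, "80M20S", strrep("A", 100)),    # junction 280
    mk_read("lead", "c1", 1050, "30S70M", strrep("C", 100)),  # 5' clip
    mk_read("full", "c1", 950, "100M", strrep("G", 100))
  )
  ev <- harvest_clips(reads, "c1", 1000)
  expect_setequal(ev$read_id, c("in20", "lead"))
  expect_equal(ev$side[ev$read_id == "in20"], "3p")
  expect_equal(ev$side[ev$read_id == "lead"], "5p")
  expect_equal(nchar(ev$flag_seq[ev$read_id == "lead"]), 30)
  # clip of exactly 10 bp is not confident (strict > 10)
  r10 <- mk_read("c10", "c1", 950, "90M10S", strrep("A", 100))
  expect_equal(nrow(harvest_clips(r10, "c1", 1000)), 0)
  # no records near the breakpoint
  expect_equal(nrow(harvest_clips(reads, "c1", 99000)), 0)
  # inconsistent CIGAR caught
  bad <- mk_read("bad", "c1", 950, "90M20S", strrep("A", 100))
  expect_error(harvest_clips(bad, "c1", 1000), "mismatch")
})

test_that("confirm_sv requires strictly more than min_support confident clips", {
  cand <- data.frame(sv_id = "sv001", type = "insertion", chrom = "c1",
                     pos = 1000L, pos2 = NA_integer_, size = 100L,
                     score = 99)
  expect_equal(confirm_sv(cand, clip_reads(7, "c1", 1000))$status,
               "confident")
  expect_equal(confirm_sv(cand, clip_reads(5, "c1", 1000))$status,
               "rejected_support")
  expect_equal(confirm_sv(cand, clip_reads(0, "c1", 1000))$status,
               "rejected_support")

  # two-breakpoint SV: one passing breakpoint suffices by default,
  # strict mode requires both
  del <- data.frame(sv_id = "sv002", type = "deletion", chrom = "c1",
                    pos = 1000L, pos2 = 5000L, size = 4000L, score = 99)
  reads <- rbind(clip_reads(8, "c1", 1000, prefix = "l"),
                 clip_reads(2, "c1", 5000, prefix = "r"))
  expect_equal(confirm_sv(del, reads)$status, "confident")
  expect_equal(confirm_sv(del, reads, require_both = TRUE)$status,
               "rejected_support")
  expect_equal(confirm_sv(del, reads)$n_confident_clips, c(8, 2))
})

test_that("the size gate keeps 5 bp - 10 kb deletions/insertions only", {
  mk_sv <- function(type, size) {
    cand <- data.frame(sv_id = "s", type = type, chrom = "c1", pos = 1000L,
                       pos2 = NA_integer_, size = as.integer(size),
                       score = 1)
    confirm_sv(cand, clip_reads(8, "c1", 1000))
  }
  expect_equal(size_filter(mk_sv("deletion", 3))$status, "rejected_size")
  expect_equal(size_filter(mk_sv("insertion", 12000))$status,
               "rejected_size")
  expect_equal(size_filter(mk_sv("deletion", 275))$status, "confident")
  expect_equal(size_filter(mk_sv("deletion", 5))$status, "confident")
  expect_equal(size_filter(mk_sv("insertion", 10000))$status, "confident")
  # inversions are exempt from the gate
  expect_equal(size_filter(mk_sv("inversion", 50000))$status, "confident")
})

test_that("flag remapping matches a brute-force scan", {
  ref <- c(c1 = random_dna_str(20000, 61), c2 = random_dna_str(20000, 62))
  flag0 <- substr(ref[["c1"]], 5001, 5030)
  flag2 <- flag0
  substr(flag2, 3, 3) <- if (substr(flag2, 3, 3) == "A") "C" else "A"
  substr(flag2, 17, 17) <- if (substr(flag2, 17, 17) == "G") "T" else "G"
  for (fl in c(flag0, flag2)) {
    got <- alloscan:::.map_flag(fl, ref, max_mismatch = 2)
    want <- oracle_flag_scan(fl, ref, max_mm = 2)
    got <- got[order(got$chrom, got$pos), ]
    want <- want[order(want$chrom, want$pos), ]
    expect_equal(got$chrom, want$chrom)
    expect_equal(got$pos, want$pos)
    expect_equal(got$mismatches, want$mismatches)
  }
})

test_that("insertion origin classification resolves tandem, intra and inter donors", {
  ref <- c(c1 = random_dna_str(60000, 71), c2 = random_dna_str(60000, 72))
  bp <- 5000L
  mk_ins <- function(flag3, flag5) {
    m <- 80L
    reads <- rbind(
      mk_read("a1", "c1", bp - m, sprintf("%dM%dS", m, nchar(flag3)),
              paste0(substr(ref[["c1"]], bp - m, bp - 1), flag3)),
      mk_read("a2", "c1", bp, sprintf("%dS%dM", nchar(flag5), m),
              paste0(flag5, substr(ref[["c1"]], bp, bp + m - 1)))
    )
    reads <- rbind(reads, reads, reads, reads)  # 8 records
    reads$qname <- sprintf("r%02d", seq_len(nrow(reads)))
    cand <- data.frame(sv_id = "svX", type = "insertion", chrom = "c1",
                       pos = bp, pos2 = NA_integer_, size = 200L,
                       score = 9)
    confirm_sv(cand, reads)
  }
  # tandem: donor 500 bp downstream of the breakpoint
  ins <- substr(ref[["c1"]], bp + 500, bp + 699)
  sv <- classify_insertion(mk_ins(substr(ins, 1, 20),
                                  substr(ins, 181, 200)), ref)
  expect_equal(sv$origin, "tandem")
  expect_lte(abs(sv$donor_pos - bp), 10000)
  # intra: donor 40 kb away on the same chromosome (flags 160 bp apart)
  ins <- substr(ref[["c1"]], 45000, 45199)
  sv <- classify_insertion(mk_ins(substr(ins, 1, 20),
                                  substr(ins, 181, 200)), ref)
  expect_equal(sv$origin, "intra")
  expect_equal(sv$donor_chrom, "c1")
  expect_equal(sv$donor_pos, 45000)
  # inter: donor on the other chromosome, flag loci 1 kb apart
  flag3 <- substr(ref[["c2"]], 30000, 30019)
  flag5 <- substr(ref[["c2"]], 31000, 31019)
  sv <- classify_insertion(mk_ins(flag3, flag5), ref)
  expect_equal(sv$origin, "inter")
  expect_equal(sv$donor_chrom, "c2")
  # no consistent match: unresolved
  sv <- classify_insertion(mk_ins(random_dna_str(20, 99),
                                  random_dna_str(20, 98)), ref)
  expect_equal(sv$origin, "unresolved")
  # missing chromosome in the reference
  svX <- mk_ins(substr(ins, 1, 20), substr(ins, 181, 200))
  svX$chrom <- "chrZ"
  expect_error(classify_insertion(svX, ref), "missing chromosome")
})

test_that("gene annotation is strand-aware and the random profile is flat", {
  genes <- data.frame(
    gene_id = c("gp", "gm", "gfar"),
    chrom = "c1",
    start = c(10000L, 30000L, 50000L),
    end = c(11000L, 31000L, 51000L),
    strand = c("+", "-", "+")
  )
  mk_sv_at <- function(id, pos, size = 50L, type = "deletion") {
    s <- list(sv_id = id, type = type, chrom = "c1", pos = pos,
              pos2 = pos + size, size = size, breakpoints = pos,
              n_confident_clips = 8L, evidence = NULL,
              status = "confident", origin = NA_character_,
              donor_chrom = NA_character_, donor_pos = NA_integer_)
    class(s) <- "confident_sv"
    s
  }
  svs <- list(
    mk_sv_at("up_plus", 9500L),      # 500 bp upstream of gp (+)
    mk_sv_at("up_minus", 31400L),    # 400 bp upstream of gm (-)
    mk_sv_at("body", 50500L),        # inside gfar
    mk_sv_at("far", 44000L)          # 5 kb upstream of gfar: no hit
  )
  ann <- annotate_genes(svs, genes, chrom_lengths = c(c1 = 60000))
  a <- ann$annotations
  expect_equal(a$region[a$gene_id == "gp"], "upstream")
  expect_equal(a$region[a$gene_id == "gm"], "upstream")
  expect_equal(a$region[a$gene_id == "gfar"], "gene_body")
  expect_true(grepl("body", a$sv_ids[a$gene_id == "gfar"]))
  # the two upstream SVs enter the profile; the gene-body SV lies
  # downstream of the start and the far SV is outside the 5 kb reach
  expect_equal(sum(ann$profile$gene_count), 2)

  # uniform random SVs near-uniform profile: totals of gene and control
  # profiles agree within a factor of ~2 at matched interval counts
  set.seed(3)
  genes_many <- data.frame(gene_id = sprintf("g%03d", 1:100), chrom = "c1",
                           start = sort(sample.int(900000, 100)),
                           end = 0, strand = "+")
  genes_many$end <- genes_many$start + 1000L
  rnd <- lapply(1:200, function(i) {
    mk_sv_at(sprintf("r%03d", i), sample.int(950000, 1))
  })
  pr <- annotate_genes(rnd, genes_many,
                       chrom_lengths = c(c1 = 1000000))$profile
  expect_gt(sum(pr$control_count), 0)
  expect_lt(abs(log2((sum(pr$gene_count) + 1) /
                       (sum(pr$control_count) + 1))), 1)
})

test_that("homoeolog partition is exhaustive and labels the SV side", {
  pairs <- data.frame(gene_a = c("a1", "a2", "a3", "a4"),
                      gene_b = c("b1", "b2", "b3", "b4"))
  ann <- data.frame(
    gene_id = c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
    region = c("upstream", "none", "gene_body", "none",
               "none", "gene_body", "gene_body", "none"),
    sv_ids = ""
  )
  part <- partition_homoeologs(pairs, ann)
  expect_equal(part$group, c("sv_nonsv", "sv_nonsv", "both_sv",
                             "unaffected"))
  expect_equal(part$sv_side, c("A", "B", NA, NA))
  expect_equal(nrow(part), nrow(pairs))  # partition completeness
  expect_error(partition_homoeologs(
    data.frame(gene_a = "zz", gene_b = "b1"), ann), "zz")
})

test_that("candidate SV tables round-trip through the BreakDancer dialect", {
  p <- tempfile()
  writeLines(c("#comment",
               "c1\t100\tc1\t400\tDEL\t300\t99\textra",
               "c2\t500\tc2\t500\tINS\t80\t88\tmore"), p)
  sv <- read_sv_candidates(p)
  expect_equal(sv$type, c("deletion", "insertion"))
  expect_equal(sv$pos, c(100L, 500L))
  expect_equal(sv$size, c(300L, 80L))
  expect_equal(ncol(sv), 8)  # unknown column preserved
})

test_that("filter monotonicity: raising min_support never adds confident SVs", {
  cand <- data.frame(sv_id = "sv001", type = "insertion", chrom = "c1",
                     pos = 1000L, pos2 = NA_integer_, size = 100L,
                     score = 1)
  reads <- clip_reads(7, "c1", 1000)
  n_conf <- vapply(c(2, 5, 6, 7, 10), function(ms) {
    as.integer(confirm_sv(cand, reads, min_support = ms)$status ==
                 "confident")
  }, integer(1))
  expect_true(all(diff(n_conf) <= 0))
})
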