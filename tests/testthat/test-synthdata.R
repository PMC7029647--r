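# Synthetic allotetraploid generator: determinism, implant construction,
# depth model, read evidence and expression truth.

test_that("ancestor simulation is deterministic and respects the divergence rate", {
  cfg <- sim_config(seed = 7, n_chromosomes = 1, chromosome_length = 1e5,
                    gene_spacing = 2000, cds_length_range = c(300L, 900L))
  a1 <- simulate_ancestors(cfg)
  a2 <- simulate_ancestors(cfg)
  expect_identical(a1$genomeA, a2$genomeA)
  expect_identical(a1$genomeB, a2$genomeB)
  f1 <- tempfile(fileext = ".fa")
  f2 <- tempfile(fileext = ".fa")
  write_fasta(a1$genomeA, f1)
  write_fasta(a2$genomeA, f2)
  expect_identical(readLines(f1), readLines(f2))

  # zero rate: orthologous CDS identical
  cfg0 <- sim_config(seed = 7, n_chromosomes = 1, chromosome_length = 5e4,
                     ancestor_divergence = 0)
  a0 <- simulate_ancestors(cfg0)
  expect_identical(unname(a0$genomeA), unname(a0$genomeB))

  # rate recovery by direct counting over ~300 orthologs at divergence 0.04
  cfgd <- sim_config(seed = 11, n_chromosomes = 1, chromosome_length = 3e5,
                     gene_spacing = 1000, cds_length_range = c(300L, 900L),
                     ancestor_divergence = 0.04)
  ad <- simulate_ancestors(cfgd)
  cdsA <- extract_cds(ad$genomeA, ad$genesA)
  cdsB <- extract_cds(ad$genomeB, ad$genesB)
  diffs <- mapply(function(x, y) {
    mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, cdsA, cdsB)
  expect_lt(abs(mean(diffs) - 0.04), 0.005)
})

test_that("config validation rejects bad CDS lengths, implants and SV sizes", {
  expect_error(sim_config(cds_length_range = c(300L, 1000L)),
               "multiple")
  expect_error(sim_config(hse_spec = data.frame(donor = "A", chrom = 1,
                                                start = 0, length = 5000)),
               "window")
  expect_error(sim_config(sv_spec = data.frame(type = "deletion",
                                               subgenome = "A", chrom = 1,
                                               pos = 100, size = -5)),
               "positive")
  expect_error(sim_config(sv_spec = data.frame(type = "insertion",
                                               subgenome = "A", chrom = 1,
                                               pos = 100, size = 50,
                                               origin = "weird")),
               "origin")
})

test_that("HSE implants copy the donor sequence over the replaced interval", {
  hse <- data.frame(donor = "A", chrom = 1, start = 50000, length = 30000)
  cfg <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 2e5,
                    hse_spec = hse)
  tet <- simulate_tetraploid(simulate_ancestors(cfg), cfg)
  t <- tet$truth$hse[1, ]
  donor <- substr(tet$genome[[t$donor_chrom]], t$donor_start + 1, t$donor_end)
  repl <- substr(tet$genome[[t$replaced_chrom]], t$replaced_start + 1,
                 t$replaced_end)
  expect_identical(donor, repl)
  expect_equal(sum(tet$truth$hse$length),
               sum(tet$truth$hse$donor_end - tet$truth$hse$donor_start))

  # empty implant specs with no extra divergence: tetraploid == ancestors
  cfg0 <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 5e4,
                     tetraploid_extra_divergence = 0)
  anc <- simulate_ancestors(cfg0)
  tet0 <- simulate_tetraploid(anc, cfg0)
  expect_identical(unname(tet0$genome[["A01"]]), unname(anc$genomeA[["A01"]]))
  expect_identical(unname(tet0$genome[["B01"]]), unname(anc$genomeB[["B01"]]))
  expect_equal(nrow(tet0$truth$hse), 0)
  expect_equal(nrow(tet0$truth$sv), 0)

  # overlapping implants rejected
  hse2 <- data.frame(donor = c("A", "B"), chrom = 1,
                     start = c(50000, 60000), length = c(30000, 30000))
  cfg2 <- sim_config(seed = 3, n_chromosomes = 1, chromosome_length = 2e5,
                     hse_spec = hse2)
  expect_error(simulate_tetraploid(simulate_ancestors(cfg2, FALSE), cfg2),
               "overlap")
})

test_that("deletion implants in an exon shorten the gene in truth", {
  # a 275 bp deletion placed inside a gene body is recorded breakpoint-exact
  cfg <- sim_config(seed = 5, n_chromosomes = 1, chromosome_length = 1e5,
                    sv_spec = data.frame(type = "deletion", subgenome = "A",
                                         chrom = 1, pos = 1201, size = 275,
                                         origin = NA))
  tet <- simulate_tetraploid(simulate_ancestors(cfg), cfg)
  sv <- tet$truth$sv
  expect_equal(sv$pos2 - sv$pos, 275)
  g <- tet$genes[tet$genes$subgenome == "A", ][1, ]
  expect_true(sv$pos > g$start & sv$pos2 <= g$end)  # inside the first CDS
})

test_that("window depth follows the copy-number model", {
  # 10 implants of 1 Mb on a 30 Mb chromosome: ~1000 donor-interior windows
  hse <- data.frame(donor = "A", chrom = 1,
                    start = 1e6 + (0:9) * 2.8e6, length = 1e6)
  cfg <- sim_config(seed = 13, n_chromosomes = 1, chromosome_length = 3e7,
                    hse_spec = hse)
  tet <- simulate_tetraploid(simulate_ancestors(cfg, sequences = FALSE), cfg)
  d <- simulate_depth(tet$truth, cfg)
  t <- tet$truth$hse
  inside <- function(w, chrom_col, s_col, e_col) {
    hit <- rep(FALSE, nrow(w))
    for (i in seq_len(nrow(t))) {
      hit <- hit | (w$chrom == t[[chrom_col]][i] &
                      w$start >= t[[s_col]][i] & w$end <= t[[e_col]][i])
    }
    hit
  }
  donor <- d[inside(d, "donor_chrom", "donor_start", "donor_end"), ]
  repl <- d[inside(d, "replaced_chrom", "replaced_start", "replaced_end"), ]
  norm <- d[d$chrom == "A01" &
              !inside(d, "donor_chrom", "donor_start", "donor_end"), ]
  # Poisson means 60 / 0 / 30; sample means within 3 SE
  expect_lt(abs(mean(donor$depth) - 60), 3 * sqrt(60 / nrow(donor)))
  expect_true(all(repl$depth == 0))
  expect_lt(abs(mean(norm$depth) - 30), 3 * sqrt(30 / nrow(norm)))
  # windows tile the chromosomes exactly
  expect_equal(sum(d$end - d$start), sum(tet$truth$chrom_lengths))
  expect_identical(simulate_depth(tet$truth, cfg), d)  # deterministic
})

test_that("clipped-read records are valid SAM with exact per-breakpoint support", {
  sv <- data.frame(type = c("insertion", "deletion"),
                   subgenome = c("A", "A"), chrom = c(1, 1),
                   pos = c(30000, 60000), size = c(200, 300),
                   origin = c("tandem", NA))
  cfg <- sim_config(seed = 9, n_chromosomes = 1, chromosome_length = 1e5,
                    sv_spec = sv, sv_support = 7L)
  tet <- simulate_tetraploid(simulate_ancestors(cfg), cfg)
  reads <- simulate_clipped_reads(tet, cfg)
  # CIGAR query lengths match sequence lengths on every record
  for (i in seq_len(nrow(reads))) {
    cg <- parse_cigar(reads$cigar[i])
    expect_equal(sum(cg$len[cg$op %in% c("M", "I", "S")]),
                 nchar(reads$seq[i]))
  }
  # support parameter 7: exactly 7 clipped records per breakpoint
  ins <- reads[startsWith(reads$qname, "sv001_"), ]
  expect_equal(nrow(ins), 7)
  expect_true(all(grepl("S", ins$cigar)))
  expect_equal(sum(startsWith(reads$qname, "sv002L_")), 7)
  expect_equal(sum(startsWith(reads$qname, "sv002R_")), 7)
  # tandem insertion: the flag sequence occurs within 10 kb of the breakpoint
  flag <- substr(ins$seq[1], nchar(ins$seq[1]) - 19, nchar(ins$seq[1]))
  hit <- gregexpr(flag, tet$genome[["A01"]], fixed = TRUE)[[1]]
  expect_true(any(abs(hit - 30000) <= 10000))
  # round trip through SAM text
  p <- tempfile(fileext = ".sam")
  write_sam(reads, p, tet$truth$chrom_lengths)
  back <- read_sam(p)
  expect_equal(back$cigar, reads$cigar)
  expect_equal(back$pos, reads$pos)

  # no SVs: no clipped records beyond the configured background noise
  cfg0 <- sim_config(seed = 9, n_chromosomes = 1, chromosome_length = 1e5,
                     clip_noise_frac = 0)
  tet0 <- simulate_tetraploid(simulate_ancestors(cfg0), cfg0)
  reads0 <- simulate_clipped_reads(tet0, cfg0)
  expect_false(any(grepl("S", reads0$cigar)))
})

test_that("expression simulation implants the requested bias ratio", {
  map <- tiny_map(400)
  es <- simulate_expression(map, default_expr_spec(n_biased_pairs = 200),
                            seed = 2)
  es2 <- simulate_expression(map, default_expr_spec(n_biased_pairs = 200),
                             seed = 2)
  expect_identical(es$counts, es2$counts)
  expect_equal(sum(es$bias_truth$direction != "none"), 200)

  ex <- rpkm(es$counts, es$gene_lengths, samples = es$samples)
  ratio <- vapply(seq_len(nrow(map)), function(i) {
    mean(ex$rpkm[map$gene_a[i], ]) / mean(ex$rpkm[map$gene_b[i], ])
  }, numeric(1))
  a_biased <- es$bias_truth$direction == "A"
  none <- es$bias_truth$direction == "none"
  expect_lt(abs(mean(ratio[a_biased]) - 4), 0.4)
  expect_lt(abs(mean(ratio[none]) - 1), 0.1)

  # bias factor 1 everywhere: truth carries no biased pairs
  es1 <- simulate_expression(tiny_map(50),
                             default_expr_spec(n_biased_pairs = 50,
                                               bias_factor = 1), seed = 2)
  expect_true(all(es1$bias_truth$factor == 1))
})

test_that("unbiased pairs reject the log-ratio null at about the nominal rate", {
  # generator calibration: pooled over 3 seeds x 1000 pairs, one-sample t on
  # the 12 per-sample log-ratios; tolerance +/- 2 SE at 1000 pairs
  map <- tiny_map(1000)
  rates <- vapply(c(101, 102, 103), function(sd) {
    es <- simulate_expression(map, default_expr_spec(), seed = sd)
    ex <- rpkm(es$counts, es$gene_lengths, samples = es$samples)
    lr <- log2(ex$rpkm[map$gene_a, ] + 0.01) -
      log2(ex$rpkm[map$gene_b, ] + 0.01)
    mean(apply(lr, 1, function(x) stats::t.test(x)$p.value) < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 2 * sqrt(0.05 * 0.95 / 1000))
})
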