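# Anchor loading, computed anchors, collinear chaining and homoeolog pairing.

test_that("load_anchors parses the 12-column dialect and applies the cutoff", {
  rows <- c(
    "g1\th1\t98.5\t200\t3\t0\t1\t200\t1\t200\t1e-50\t380",
    "g1\th2\t90.0\t200\t20\t0\t1\t200\t1\t200\t1e-20\t250",
    "g2\th3\t95.0\t150\t7\t0\t1\t150\t1\t150\t1e-3\t90"
  )
  p <- tempfile()
  writeLines(rows, p)
  an <- load_anchors(p)
  # the 1e-3 row is dropped by the strict < 1e-5 cutoff
  expect_equal(nrow(an), 2)
  expect_equal(an$gene1, c("g1", "g1"))
  expect_equal(an$score[1], 380)
  expect_equal(an$evalue[2], 1e-20)

  # top_k per query, ranked by score
  an1 <- load_anchors(p, top_k = 1)
  expect_equal(nrow(an1), 1)
  expect_equal(an1$gene2, "h1")

  writeLines(character(), p)
  expect_equal(nrow(load_anchors(p)), 0)

  writeLines(c(rows[1], "g9\tonly\tthree"), p)
  expect_error(load_anchors(p), "line 2")
})

test_that("compute_anchors finds self-matches and rejects unrelated sequences", {
  prots <- vapply(1:8, function(i) random_protein(120, 100 + i),
                  character(1))
  names(prots) <- sprintf("p%02d", 1:8)
  an <- compute_anchors(prots, prots)
  # each gene's top anchor is itself
  top <- do.call(rbind, lapply(split(an, an$gene1), function(d) {
    d[which.max(d$score), ]
  }))
  expect_equal(top$gene2, top$gene1)

  # score symmetry
  a12 <- compute_anchors(prots[1], prots[2], min_shared_kmers = 0,
                         min_score = -1e6)
  a21 <- compute_anchors(prots[2], prots[1], min_shared_kmers = 0,
                         min_score = -1e6)
  expect_equal(a12$score, a21$score)

  # unrelated random length-100 proteins: false-anchor rate < 1%
  set.seed(9)
  q <- vapply(1:20, function(i) random_protein(100, 200 + i), character(1))
  s <- vapply(1:20, function(i) random_protein(100, 300 + i), character(1))
  names(q) <- sprintf("q%02d", 1:20)
  names(s) <- sprintf("s%02d", 1:20)
  an0 <- compute_anchors(q, s)
  expect_lt(nrow(an0) / (length(q) * length(s)), 0.01)

  expect_error(compute_anchors(c(x = "MK1V"), c(y = "MKV")),
               "amino-acid")
})

test_that("chain_blocks recovers collinear chains and matches brute force", {
  mk_genes <- function(ids, chrom) {
    data.frame(gene_id = ids, chrom = chrom,
               start = seq_along(ids) * 1000,
               end = seq_along(ids) * 1000 + 500, strand = "+")
  }
  g1 <- mk_genes(sprintf("a%02d", 1:10), "c1")
  g2 <- mk_genes(sprintf("b%02d", 1:10), "c2")

  # 10 perfectly collinear anchors: one + block of size 10
  an <- data.frame(gene1 = g1$gene_id, gene2 = g2$gene_id, score = 100)
  bl <- chain_blocks(an, g1, g2)
  expect_length(bl, 1)
  expect_equal(nrow(bl[[1]]$anchors), 10)
  expect_equal(bl[[1]]$orientation, "+")

  # 4 collinear anchors with min_pairs = 5: no block
  expect_length(chain_blocks(an[1:4, ], g1, g2), 0)

  # 7 anchors reversed on side 2: one - block
  an7 <- data.frame(gene1 = g1$gene_id[1:7], gene2 = rev(g2$gene_id[1:7]),
                    score = 50)
  bl7 <- chain_blocks(an7, g1, g2)
  expect_length(bl7, 1)
  expect_equal(bl7[[1]]$orientation, "-")
  expect_equal(nrow(bl7[[1]]$anchors), 7)

  # rank-gap constraint: a jump of > max_gap_genes breaks the chain
  g1b <- mk_genes(sprintf("a%02d", 1:40), "c1")
  g2b <- mk_genes(sprintf("b%02d", 1:40), "c2")
  idx <- c(1:5, 36:40)  # gap of 30 ranks in the middle
  anb <- data.frame(gene1 = g1b$gene_id[idx], gene2 = g2b$gene_id[idx],
                    score = 10)
  expect_length(chain_blocks(anb, g1b, g2b, max_gap_genes = 25,
                             min_pairs = 6), 0)
  expect_length(chain_blocks(anb, g1b, g2b, max_gap_genes = 40,
                             min_pairs = 6), 1)

  # equivalence with exhaustive search on random instances (<= 12 anchors)
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(5:12, 1)
    r1 <- sample(1:20, n)
    r2 <- sample(1:20, n)
    sc <- sample(1:50, n, replace = TRUE)
    gg1 <- mk_genes(sprintf("x%02d", 1:20), "c1")
    gg2 <- mk_genes(sprintf("y%02d", 1:20), "c2")
    ani <- data.frame(gene1 = sprintf("x%02d", r1),
                      gene2 = sprintf("y%02d", r2), score = sc)
    bi <- chain_blocks(ani, gg1, gg2, max_gap_genes = 6, min_pairs = 1)
    got <- if (length(bi)) bi[[1]]$score else 0
    expect_equal(got, bf_best_chain_score(r1, r2, sc, max_gap = 6))
  }
})

test_that("homoeolog pairing is one-to-one and achieves full recall on a clean world", {
  # gene appearing in two blocks ends up in exactly one pair
  blocks <- list(
    list(block_id = "blk0001", chrom1 = "c1", chrom2 = "c2",
         orientation = "+", score = 500,
         anchors = data.frame(gene1 = c("a1", "a2", "a3"),
                              gene2 = c("b1", "b2", "b3"),
                              score = c(100, 90, 80),
                              rank1 = 1:3, rank2 = 1:3)),
    list(block_id = "blk0002", chrom1 = "c1", chrom2 = "c3",
         orientation = "+", score = 100,
         anchors = data.frame(gene1 = "a1", gene2 = "d1", score = 60,
                              rank1 = 1, rank2 = 1))
  )
  class(blocks) <- "synteny_blocks"
  hp <- homoeolog_pairs(blocks)
  expect_equal(sum(hp$gene_a == "a1"), 1)
  expect_equal(hp$gene_b[hp$gene_a == "a1"], "b1")
  expect_false(any(duplicated(hp$gene_a)))
  expect_false(any(duplicated(hp$gene_b)))
  expect_equal(nrow(homoeolog_pairs(structure(list(),
                                              class = "synteny_blocks"))), 0)

  # simulated tetraploid, no rearrangement: recall/precision vs truth
  cfg <- sim_config(seed = 17, n_chromosomes = 1, chromosome_length = 2e5)
  tet <- simulate_tetraploid(simulate_ancestors(cfg), cfg)
  ga <- tet$genes[tet$genes$subgenome == "A", ]
  gb <- tet$genes[tet$genes$subgenome == "B", ]
  pa <- translate_cds(extract_cds(tet$genome, ga))
  pb <- translate_cds(extract_cds(tet$genome, gb))
  hp2 <- homoeolog_pairs(chain_blocks(compute_anchors(pa, pb), ga, gb))
  truth_keys <- paste(tet$truth$homoeolog_map$gene_a,
                      tet$truth$homoeolog_map$gene_b)
  called_keys <- paste(hp2$gene_a, hp2$gene_b)
  recall <- mean(truth_keys %in% called_keys)
  precision <- mean(called_keys %in% truth_keys)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("self-synteny finds internal duplications and nothing else", {
  # 12 unique proteins on c1; their copies on c2: one internal block
  base <- vapply(1:12, function(i) random_protein(150, 400 + i),
                 character(1))
  prot <- c(base, base)
  names(prot) <- c(sprintf("u%02d", 1:12), sprintf("v%02d", 1:12))
  genes <- data.frame(gene_id = names(prot),
                      chrom = rep(c("c1", "c2"), each = 12),
                      start = rep(seq_len(12) * 1000, 2),
                      end = rep(seq_len(12) * 1000 + 500, 2),
                      strand = "+")
  par <- self_synteny(prot, genes)
  expect_gte(nrow(par), 12)
  expect_true(all(paste0("u", substr(par$gene_a, 2, 3)) == par$gene_a))

  # min_genes enforced: 4 duplicated genes cannot form a block
  par4 <- self_synteny(prot[c(1:4, 13:16)], genes[c(1:4, 13:16), ],
                       min_genes = 5)
  expect_equal(nrow(par4), 0)

  # genome without duplication: no internal blocks
  solo <- vapply(1:10, function(i) random_protein(150, 500 + i),
                 character(1))
  names(solo) <- sprintf("w%02d", 1:10)
  genes_solo <- data.frame(gene_id = names(solo), chrom = "c1",
                           start = seq_len(10) * 1000,
                           end = seq_len(10) * 1000 + 500, strand = "+")
  expect_equal(nrow(self_synteny(solo, genes_solo)), 0)
})

test_that("gene ranks increase along chromosomes with deterministic ties", {
  g <- data.frame(gene_id = c("b", "a", "c"), chrom = "c1",
                  start = c(100, 100, 50), end = c(200, 200, 80),
                  strand = "+")
  r <- gene_ranks(g)
  expect_equal(r$gene_id[order(r$rank)], c("c", "a", "b"))
})
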