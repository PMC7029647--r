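# Orchestration: a flat validated config, per-stage runners over a shared
# state, and a one-shot end-to-end demo on synthetic data with truth scoring.

.PIPELINE_DEFAULTS <- list(
  seed = 1L,
  outdir = NULL,
  # simulation
  n_chromosomes = 2L,
  chromosome_length = 500000L,
  gene_spacing = 5000L,
  depth_mean = 30,
  # hse
  window_size = 10000L,
  double_low = 1.5,
  double_high = 4.0,
  deleted_max = 0.25,
  max_gap_windows = 5L,
  min_span_windows = 8L,
  min_reciprocal_overlap = 0.5,
  # synteny
  evalue_cutoff = 1e-5,
  top_k = 5L,
  max_gap_genes = 25L,
  min_pairs = 5L,
  anchor_min_score = 50,
  # sv
  min_support = 5L,
  min_clip = 10L,
  clip_window = 300L,
  min_size = 5L,
  max_size = 10000L,
  tandem_window = 10000L,
  pair_window = 10000L,
  upstream_bp = 2000L,
  # molevol
  clock_rate = 8.12e-9,
  n_perm = 10000L,
  # expression
  fc_threshold = 2,
  fdr_threshold = 0.01,
  deg_fdr = 0.05,
  consistency_eps = 0.25,
  pseudocount = 0.01,
  n_biased_pairs = 40L,
  bias_factor = 4,
  dispersion = 0.05
)

#' Build a validated pipeline configuration
#'
#' Flat key = value configuration covering every stage parameter, with
#' defaults equal to the method's stated values where the method states
#' them. Unknown keys are rejected.
#'
#' @param ... Overrides for any default (see `alloscan:::.PIPELINE_DEFAULTS`
#'   for the full key list).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  unknown <- setdiff(names(args), names(.PIPELINE_DEFAULTS))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(.PIPELINE_DEFAULTS, args)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run one pipeline stage over a shared state
#'
#' Stages: `simulate` (build the synthetic world), `synteny`, `hse`, `sv`,
#' `kaks`, `expr`, `report`. Each stage reads its inputs from `state`
#' (an environment), writes artifacts under `config$outdir` when set, and
#' stores results back into `state`. Missing inputs raise an error.
#'
#' @param name Stage name.
#' @param config A [pipeline_config()].
#' @param state Environment carrying the pipeline state (created if
#'   missing).
#' @return `state`, invisibly.
#' @export
run_stage <- function(name = c("simulate", "synteny", "hse", "sv", "kaks",
                               "expr", "report"),
                      config = pipeline_config(), state = new.env()) {
  name <- match.arg(name)
  need <- function(what) {
    if (!exists(what, envir = state, inherits = FALSE)) {
      stop("stage '", name, "' needs '", what,
           "'; run the producing stage first")
    }
    get(what, envir = state)
  }
  art <- function(fn, file) {
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      fn(file.path(config$outdir, file))
    }
  }
  msg <- function(...) message("[", name, "] ", sprintf(...))

  if (name == "simulate") {
    len <- config$chromosome_length
    if (len < 3e5 || config$n_chromosomes < 2L) {
      stop("the demo simulation needs chromosome_length >= 3e5 and ",
           ">= 2 chromosomes per subgenome")
    }
    hse_len <- max(8L * config$window_size, min(100000L, round(len * 0.2)))
    hse_spec <- data.frame(
      donor = c("A", "B"),
      chrom = c(1L, 2L),
      start = c(round(len * 0.3), round(len * 0.55)),
      length = hse_len
    )
    # deletions/insertions placed on the gene grid so some hit gene bodies
    # or upstream windows (gene starts sit at 1000 + k * gene_spacing)
    gs <- config$gene_spacing
    sv_spec <- data.frame(
      type = c("deletion", "deletion", "insertion", "insertion",
               "insertion", "deletion"),
      subgenome = c("A", "A", "A", "B", "B", "B"),
      chrom = c(1L, 1L, 2L, 1L, 2L, 2L),
      pos = c(1100L + 4L * gs, 500L + 8L * gs, 1200L + 6L * gs,
              1150L + 10L * gs, 1100L + 14L * gs, 1050L + 18L * gs),
      size = c(275L, 120L, 300L, 250L, 200L, 500L),
      origin = c(NA, NA, "tandem", "intra", "inter", NA)
    )
    cfg <- sim_config(
      seed = config$seed,
      n_chromosomes = config$n_chromosomes,
      chromosome_length = len,
      gene_spacing = gs,
      depth_mean = config$depth_mean,
      window_size = config$window_size,
      hse_spec = hse_spec,
      sv_spec = sv_spec,
      expr_spec = list(n_biased_pairs = config$n_biased_pairs,
                       bias_factor = config$bias_factor,
                       dispersion = config$dispersion,
                       stages = 4L, replicates = 3L, mean_count = 500)
    )
    anc <- simulate_ancestors(cfg)
    tet <- simulate_tetraploid(anc, cfg)
    state$sim_cfg <- cfg
    state$ancestors <- anc
    state$tetraploid <- tet
    state$depth <- simulate_depth(tet$truth, cfg)
    state$reads <- simulate_clipped_reads(tet, cfg)
    state$expr_sim <- simulate_expression(tet$truth$homoeolog_map,
                                          cfg$expr_spec, cfg$seed)
    art(function(p) write_fasta(tet$genome, p), "tetraploid.fa")
    art(function(p) write_gff3(tet$genes, p), "genes.gff3")
    art(function(p) write_depth_tsv(state$depth, p), "depth.tsv")
    art(function(p) write_sam(state$reads, p, tet$truth$chrom_lengths),
        "reads.sam")
    art(function(p) write_counts_tsv(state$expr_sim, p), "counts.tsv")
    msg("world ready: %d genes, %d HSEs, %d SVs, %d homoeolog pairs",
        nrow(tet$genes), nrow(tet$truth$hse), nrow(tet$truth$sv),
        nrow(tet$truth$homoeolog_map))
  } else if (name == "synteny") {
    tet <- need("tetraploid")
    genes <- tet$genes
    ga <- genes[genes$subgenome == "A", ]
    gb <- genes[genes$subgenome == "B", ]
    prot_a <- translate_cds(extract_cds(tet$genome, ga))
    prot_b <- translate_cds(extract_cds(tet$genome, gb))
    anchors <- compute_anchors(prot_a, prot_b, top_k = config$top_k,
                               min_score = config$anchor_min_score)
    blocks <- chain_blocks(anchors, ga, gb,
                           max_gap_genes = config$max_gap_genes,
                           min_pairs = config$min_pairs)
    state$pairs <- homoeolog_pairs(blocks)
    msg("%d anchors -> %d blocks -> %d homoeolog pairs",
        nrow(anchors), length(blocks), nrow(state$pairs))
    art(function(p) utils::write.table(state$pairs, p, sep = "\t",
                                       quote = FALSE, row.names = FALSE),
        "homoeolog_pairs.tsv")
  } else if (name == "hse") {
    depth <- need("depth")
    tet <- need("tetraploid")
    res <- detect_hse(depth, tet$truth$homoeolog_map,
                      window_size = config$window_size,
                      double_low = config$double_low,
                      double_high = config$double_high,
                      deleted_max = config$deleted_max,
                      max_gap_windows = config$max_gap_windows,
                      min_span_windows = config$min_span_windows,
                      min_reciprocal_overlap = config$min_reciprocal_overlap)
    state$hse <- res
    msg("%d windows -> %d HSE call(s), %d unpaired candidate(s)",
        nrow(res$windows), nrow(res$hse), nrow(res$unpaired))
    art(function(p) write_hse_bed(res$hse, p), "hse.bed")
    art(function(p) utils::write.table(res$summary, p, sep = "\t",
                                       quote = FALSE, row.names = FALSE),
        "hse_summary.tsv")
  } else if (name == "sv") {
    tet <- need("tetraploid")
    reads <- need("reads")
    cands <- sv_candidates_from_truth(tet$truth)
    svs <- classify_svs(cands, reads, tet$genome,
                        min_support = config$min_support,
                        window = config$clip_window,
                        min_clip = config$min_clip,
                        min_size = config$min_size,
                        max_size = config$max_size,
                        tandem_window = config$tandem_window,
                        pair_window = config$pair_window)
    ann <- annotate_genes(svs, tet$genes, tet$truth$chrom_lengths,
                          upstream_bp = config$upstream_bp,
                          seed = config$seed)
    state$svs <- svs
    state$sv_annotations <- ann
    n_in <- nrow(cands)
    n_conf <- sum(attr(svs, "summary")$status == "confident")
    msg("candidates in: %d, confident out: %d", n_in, n_conf)
    art(function(p) utils::write.table(attr(svs, "summary"), p, sep = "\t",
                                       quote = FALSE, row.names = FALSE),
        "sv_confident.tsv")
    art(function(p) utils::write.table(ann$profile, p, sep = "\t",
                                       quote = FALSE, row.names = FALSE),
        "sv_profile.tsv")
  } else if (name == "kaks") {
    tet <- need("tetraploid")
    pairs <- need("pairs")
    cds <- extract_cds(tet$genome, tet$genes)
    kk <- kaks_pairs(pairs, cds)
    state$kaks <- kk
    usable <- kk$ks[!kk$saturated & is.finite(kk$ks)]
    state$ks_peak <- ks_peak(usable)
    state$divergence_mya <- divergence_time(state$ks_peak,
                                            m = config$clock_rate) / 1e6
    msg("Ks peak %.4f -> divergence %.2f MYA over %d pairs",
        state$ks_peak, state$divergence_mya, length(usable))
    art(function(p) utils::write.table(kk, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), "kaks.tsv")
  } else if (name == "expr") {
    es <- need("expr_sim")
    pairs <- need("pairs")
    expr <- rpkm(es$counts, es$gene_lengths, samples = es$samples)
    bias <- homoeolog_bias(expr, pairs,
                           fc_threshold = config$fc_threshold,
                           fdr_threshold = config$fdr_threshold,
                           consistency_eps = config$consistency_eps,
                           pseudocount = config$pseudocount)
    state$expr <- expr
    state$bias <- bias
    msg("pairs tested: %d; dominant: %d", nrow(bias),
        sum(bias$class != "neutral"))
    art(function(p) utils::write.table(bias, p, sep = "\t", quote = FALSE,
                                       row.names = FALSE), "bias_calls.tsv")
    if (exists("sv_annotations", envir = state, inherits = FALSE)) {
      part <- partition_homoeologs(pairs, state$sv_annotations$annotations)
      state$partition <- part
      if (any(part$group == "sv_nonsv") && any(part$group == "unaffected")) {
        state$integration <- sv_expression_integration(part, bias)
        art(function(p) utils::write.table(state$integration, p, sep = "\t",
                                           quote = FALSE, row.names = FALSE),
            "sv_expression.tsv")
      }
    }
  } else if (name == "report") {
    tet <- need("tetraploid")
    rep <- .demo_report(state, config)
    state$report <- rep
    art(function(p) writeLines(rep$markdown, p), "report.md")
    msg("HSE recall %.2f; SV accuracy %.2f; dominance accuracy %.2f",
        rep$hse_recall, rep$sv_accuracy, rep$dominance_accuracy)
  }
  invisible(state)
}

# Truth-recovery scoring for the demo report.
.demo_report <- function(state, config) {
  truth <- state$tetraploid$truth
  # HSE recall: every truth implant recovered with matching direction
  hse <- state$hse$hse
  hits <- 0L
  for (i in seq_len(nrow(truth$hse))) {
    t <- truth$hse[i, ]
    ok <- any(hse$donor_chrom == t$donor_chrom &
                hse$direction == paste0(t$donor, ">",
                                        c(A = "B", B = "A")[t$donor]) &
                pmin(hse$donor_end, t$donor_end) -
                  pmax(hse$donor_start, t$donor_start) >
                0.5 * t$length)
    if (ok) hits <- hits + 1L
  }
  hse_recall <- if (nrow(truth$hse)) hits / nrow(truth$hse) else NA_real_
  # SV: confirmation + origin accuracy
  sv_sum <- attr(state$svs, "summary")
  m <- match(sv_sum$sv_id, truth$sv$sv_id)
  conf_ok <- sv_sum$status == "confident"
  ins <- which(truth$sv$type[m] == "insertion")
  origin_ok <- sv_sum$origin[ins] == truth$sv$origin[m][ins]
  sv_accuracy <- mean(c(conf_ok, origin_ok))
  # dominance confusion matrix vs truth
  bt <- state$expr_sim$bias_truth
  bias <- state$bias
  mm <- match(bias$pair_id, bt$pair_id)
  truth_class <- ifelse(bt$direction[mm] == "A", "A-dominant",
                        ifelse(bt$direction[mm] == "B", "B-dominant",
                               "neutral"))
  confusion <- table(truth = truth_class, called = bias$class)
  dominance_accuracy <- mean(truth_class == bias$class)
  md <- c(
    "# alloscan demo report",
    "",
    sprintf("- seed: %d", config$seed),
    sprintf("- HSE recall vs truth: %.3f (%d/%d implants)", hse_recall,
            hits, nrow(truth$hse)),
    sprintf("- SV confirmation + origin accuracy: %.3f", sv_accuracy),
    sprintf("- Ks peak: %.4f -> divergence %.2f MYA",
            state$ks_peak, state$divergence_mya),
    sprintf("- homoeolog pairs: %d called / %d truth", nrow(state$pairs),
            nrow(truth$homoeolog_map)),
    sprintf("- dominance accuracy: %.3f", dominance_accuracy),
    "",
    "## Dominance confusion matrix (truth x called)",
    utils::capture.output(print(confusion))
  )
  list(markdown = md, hse_recall = hse_recall, sv_accuracy = sv_accuracy,
       dominance_accuracy = dominance_accuracy, confusion = confusion)
}

#' Run the full demo pipeline on synthetic data
#'
#' simulate -> synteny -> hse -> sv -> kaks -> expr -> report, on a small
#' synthetic allotetraploid with implanted HSEs, SVs and expression bias;
#' the report scores every detector against the generator's truth.
#'
#' @param seed Master seed.
#' @param outdir Optional artifact directory (FASTA/GFF3/SAM/TSV/BED plus
#'   `report.md`).
#' @param config Optional [pipeline_config()]; `seed`/`outdir` override its
#'   entries.
#' @return The pipeline state environment, invisibly; the report is in
#'   `state$report`.
#' @export
run_demo <- function(seed = 1L, outdir = NULL, config = NULL) {
  if (is.null(config)) config <- pipeline_config()
  config$seed <- as.integer(seed)
  config$outdir <- outdir
  state <- new.env()
  for (stage in c("simulate", "synteny", "hse", "sv", "kaks", "expr",
                  "report")) {
    run_stage(stage, config, state)
  }
  invisible(state)
}
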