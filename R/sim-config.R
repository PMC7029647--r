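#' Simulation configuration for the synthetic allotetraploid
#'
#' Describes the world the generator builds: two diploid ancestors (A and B)
#' with genes on a regular grid, an allotetraploid carrying both subgenomes
#' with extra post-polyploidy divergence, implanted homoeologous sequence
#' exchanges (HSEs), implanted structural variants (SVs) with soft-clip
#' evidence, and negative-binomial homoeolog expression across 4 pod
#' developmental stages x 3 replicates.
#'
#' Defaults mirror the data regime of a tetraploid peanut-style system:
#' ancestor synonymous divergence near the 0.036 Ks peak observed between
#' the A- and B-genome diploids, an extra 0.008 substitutions/site accrued
#' after polyploid formation (subgenome Ks peak near 0.044), 30x sequencing
#' depth, 150 bp reads, and 8 supporting soft-clipped reads of 20 bp clips
#' per implanted SV breakpoint.
#'
#' @param seed Integer master seed; every generator operation derives its own
#'   stream from it, so identical configs give byte-identical outputs.
#' @param n_chromosomes Chromosomes per subgenome.
#' @param chromosome_length Chromosome length in bp.
#' @param gene_spacing Distance between consecutive gene starts in bp.
#' @param cds_length_range Two-element range of CDS lengths in bp; both ends
#'   must be multiples of 3.
#' @param ancestor_divergence Per-site substitution rate separating the two
#'   diploid ancestors.
#' @param tetraploid_extra_divergence Additional per-site divergence accrued
#'   between the subgenomes after polyploid formation (split evenly between
#'   the two subgenome branches).
#' @param hse_spec Data frame of HSE implants: columns `donor` ("A" or "B"),
#'   `chrom` (chromosome index), `start` (bp, 0-based), `length` (bp).
#'   Direction is donor to the other subgenome.
#' @param sv_spec Data frame of SV implants: columns `type` ("deletion" or
#'   "insertion"), `subgenome`, `chrom` (index), `pos` (bp, 1-based
#'   breakpoint), `size` (bp), `origin` ("tandem", "intra" or "inter" for
#'   insertions, NA for deletions).
#' @param depth_mean Expected read depth per copy (reads/site).
#' @param window_size Depth window width in bp (10 kb default).
#' @param read_length Simulated read length in bp.
#' @param sv_support Soft-clipped reads generated per SV breakpoint.
#' @param sv_clip_len Soft-clip length of the supporting reads in bp.
#' @param background_reads Fully matched background records per chromosome.
#' @param clip_noise_frac Fraction of background records given short
#'   (< 10 bp) terminal clips, to exercise the confident-clip filter.
#' @param expr_spec List with `n_biased_pairs`, `bias_factor`, `dispersion`,
#'   `stages`, `replicates`, and `mean_count` (baseline negative-binomial
#'   mean per kb of gene model).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 1e6,
                       gene_spacing = 5000,
                       cds_length_range = c(300L, 1500L),
                       ancestor_divergence = 0.036,
                       tetraploid_extra_divergence = 0.008,
                       hse_spec = NULL,
                       sv_spec = NULL,
                       depth_mean = 30,
                       window_size = 10000,
                       read_length = 150L,
                       sv_support = 8L,
                       sv_clip_len = 20L,
                       background_reads = 200L,
                       clip_noise_frac = 0.05,
                       expr_spec = list(n_biased_pairs = 0L,
                                        bias_factor = 4,
                                        dispersion = 0.05,
                                        stages = 4L,
                                        replicates = 3L,
                                        mean_count = 500)) {
  if (any(cds_length_range %% 3L != 0L)) {
    stop("cds_length_range must contain multiples of 3")
  }
  if (cds_length_range[1L] > cds_length_range[2L]) {
    stop("cds_length_range must be non-decreasing")
  }
  if (depth_mean <= 0) stop("depth_mean must be positive")
  if (ancestor_divergence < 0 || tetraploid_extra_divergence < 0) {
    stop("divergence rates must be non-negative")
  }
  if (!is.null(hse_spec)) {
    hse_spec <- as.data.frame(hse_spec)
    need <- c("donor", "chrom", "start", "length")
    if (!all(need %in% names(hse_spec))) {
      stop("hse_spec needs columns: ", paste(need, collapse = ", "))
    }
    if (!all(hse_spec$donor %in% c("A", "B"))) {
      stop("hse_spec$donor must be 'A' or 'B'")
    }
    if (any(hse_spec$length < window_size)) {
      stop("HSE implants must span at least one depth window (",
           window_size, " bp)")
    }
    if (any(hse_spec$start < 0 |
            hse_spec$start + hse_spec$length > chromosome_length)) {
      stop("HSE implant outside chromosome bounds")
    }
  }
  if (!is.null(sv_spec)) {
    sv_spec <- as.data.frame(sv_spec)
    need <- c("type", "subgenome", "chrom", "pos", "size")
    if (!all(need %in% names(sv_spec))) {
      stop("sv_spec needs columns: ", paste(need, collapse = ", "))
    }
    if (is.null(sv_spec$origin)) sv_spec$origin <- NA_character_
    if (!all(sv_spec$type %in% c("deletion", "insertion"))) {
      stop("sv_spec$type must be 'deletion' or 'insertion'")
    }
    if (any(sv_spec$size <= 0)) stop("SV sizes must be positive")
    ins <- sv_spec$type == "insertion"
    if (any(ins & !sv_spec$origin %in% c("tandem", "intra", "inter"))) {
      stop("insertion origin must be 'tandem', 'intra' or 'inter'")
    }
  }
  stopifnot(expr_spec$dispersion > 0,
            expr_spec$bias_factor > 0,
            expr_spec$stages >= 1L,
            expr_spec$replicates >= 2L)
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              gene_spacing = as.integer(gene_spacing),
              cds_length_range = as.integer(cds_length_range),
              ancestor_divergence = ancestor_divergence,
              tetraploid_extra_divergence = tetraploid_extra_divergence,
              hse_spec = hse_spec,
              sv_spec = sv_spec,
              depth_mean = depth_mean,
              window_size = as.integer(window_size),
              read_length = as.integer(read_length),
              sv_support = as.integer(sv_support),
              sv_clip_len = as.integer(sv_clip_len),
              background_reads = as.integer(background_reads),
              clip_noise_frac = clip_noise_frac,
              expr_spec = expr_spec)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic allotetraploid configuration\n")
  cat(sprintf("  %d chromosome(s)/subgenome x %s bp, genes every %s bp\n",
              x$n_chromosomes, format(x$chromosome_length, big.mark = ","),
              format(x$gene_spacing, big.mark = ",")))
  cat(sprintf("  divergence: ancestors %.3f, post-polyploidy extra %.3f\n",
              x$ancestor_divergence, x$tetraploid_extra_divergence))
  cat(sprintf("  implants: %d HSE(s), %d SV(s); depth %gx, seed %d\n",
              if (is.null(x$hse_spec)) 0L else nrow(x$hse_spec),
              if (is.null(x$sv_spec)) 0L else nrow(x$sv_spec),
              x$depth_mean, x$seed))
  invisible(x)
}

.chrom_name <- function(subgenome, idx) sprintf("%s%02d", subgenome, idx)
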