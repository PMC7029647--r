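#' Simulate homoeolog expression counts with known bias truth
#'
#' Draws negative-binomial read counts for both copies of each homoeolog
#' pair across developmental stages and replicates. A chosen subset of pairs
#' is biased: the dominant copy's mean is `bias_factor` times its partner's
#' in every stage (the biological signature of homoeolog expression
#' dominance); unbiased pairs have ratio 1. Both copies share per-pair
#' baseline expression and per-stage multipliers, so the only systematic
#' between-copy difference is the implanted bias.
#'
#' @param map Homoeolog map: data frame with columns `gene_a`, `gene_b`
#'   (coordinates optional; if `end_a`/`start_a` etc. are present, gene
#'   lengths are taken from them).
#' @param expr_spec List as in [sim_config()] (`n_biased_pairs`,
#'   `bias_factor`, `dispersion`, `stages`, `replicates`, `mean_count`).
#' @param seed Integer seed.
#' @return List of class `expr_sim`: `counts` (genes x samples integer
#'   matrix), `samples` (data frame with `sample`, `stage`, `replicate`),
#'   `gene_lengths` (named bp vector), `bias_truth` (data frame `pair_id`,
#'   `gene_a`, `gene_b`, `direction` in {A, B, none}, `factor`).
#' @export
simulate_expression <- function(map, expr_spec, seed = 1L) {
  stopifnot(is.data.frame(map), all(c("gene_a", "gene_b") %in% names(map)))
  es <- expr_spec
  stopifnot(es$dispersion > 0, es$replicates >= 2L)
  .with_seed(.op_seed(seed, "expression"), {
    n_pairs <- nrow(map)
    n_biased <- min(es$n_biased_pairs, n_pairs)
    stages <- es$stages
    reps <- es$replicates

    if (all(c("start_a", "end_a", "start_b", "end_b") %in% names(map))) {
      len_a <- map$end_a - map$start_a
      len_b <- map$end_b - map$start_b
    } else {
      len_a <- sample(seq(900L, 1500L), n_pairs, replace = TRUE)
      len_b <- sample(seq(900L, 1500L), n_pairs, replace = TRUE)
    }

    biased <- sort(sample.int(n_pairs, n_biased))
    direction <- rep("none", n_pairs)
    direction[biased] <- sample(c("A", "B"), n_biased, replace = TRUE)

    base <- stats::rlnorm(n_pairs, meanlog = log(es$mean_count), sdlog = 0.8)
    stage_mult <- matrix(stats::rlnorm(n_pairs * stages, 0, 0.2),
                         n_pairs, stages)

    samples <- data.frame(
      sample = as.vector(t(outer(seq_len(stages), seq_len(reps),
                                 function(s, r) sprintf("s%dr%d", s, r)))),
      stage = rep(seq_len(stages), each = reps),
      replicate = rep(seq_len(reps), times = stages)
    )
    n_samp <- nrow(samples)

    counts <- matrix(0L, nrow = 2L * n_pairs, ncol = n_samp,
                     dimnames = list(c(map$gene_a, map$gene_b),
                                     samples$sample))
    size <- 1 / es$dispersion
    for (p in seq_len(n_pairs)) {
      fa <- if (direction[p] == "A") es$bias_factor else 1
      fb <- if (direction[p] == "B") es$bias_factor else 1
      for (s in seq_len(stages)) {
        mu <- base[p] * stage_mult[p, s]
        cols <- which(samples$stage == s)
        counts[p, cols] <-
          stats::rnbinom(reps, mu = mu * fa * len_a[p] / 1000, size = size)
        counts[n_pairs + p, cols] <-
          stats::rnbinom(reps, mu = mu * fb * len_b[p] / 1000, size = size)
      }
    }

    out <- list(
      counts = counts,
      samples = samples,
      gene_lengths = stats::setNames(c(len_a, len_b),
                                     c(map$gene_a, map$gene_b)),
      bias_truth = data.frame(pair_id = map$gene_a,
                              gene_a = map$gene_a, gene_b = map$gene_b,
                              direction = direction,
                              factor = ifelse(direction == "none", 1,
                                              es$bias_factor))
    )
    class(out) <- "expr_sim"
    out
  })
}

#' Write a simulated count matrix as TSV
#'
#' @param expr An `expr_sim` from [simulate_expression()].
#' @param path Output path; header row carries sample names (`s<stage>r<rep>`).
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$counts),
                   length = expr$gene_lengths[rownames(expr$counts)],
                   expr$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
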