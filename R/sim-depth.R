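#' Simulate windowed read depth over the combined ancestor reference
#'
#' Emulates mapping tetraploid reads onto the combined progenitor reference:
#' each nonoverlapping window's depth is Poisson with mean
#' `depth_mean x copy_number`, where copy number is 2 inside HSE donor
#' intervals, 0 inside replaced intervals and 1 elsewhere. Windows that
#' partially overlap an implant get the overlap-weighted mean, so boundary
#' windows carry intermediate signal, as real data would.
#'
#' @param truth An `alloscan_truth` (from [simulate_tetraploid()]), used for
#'   chromosome lengths and HSE intervals.
#' @param config The [sim_config()].
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open window bounds) and `depth` (mean reads/site in the window).
#' @export
simulate_depth <- function(truth, config) {
  stopifnot(inherits(truth, "alloscan_truth"), inherits(config, "sim_config"))
  .with_seed(.op_seed(config$seed, "depth"), {
    ws <- config$window_size
    out <- vector("list", length(truth$chrom_lengths))
    for (k in seq_along(truth$chrom_lengths)) {
      ch <- names(truth$chrom_lengths)[k]
      len <- truth$chrom_lengths[[k]]
      starts <- seq(0L, len - 1L, by = ws)
      ends <- pmin(starts + ws, len)
      cn <- rep(1, length(starts))
      h <- truth$hse
      if (nrow(h)) {
        add_overlap <- function(iv_start, iv_end, delta) {
          ov <- pmax(0, pmin(ends, iv_end) - pmax(starts, iv_start))
          cn <<- cn + delta * ov / (ends - starts)
        }
        for (i in which(h$donor_chrom == ch)) {
          add_overlap(h$donor_start[i], h$donor_end[i], +1)
        }
        for (i in which(h$replaced_chrom == ch)) {
          add_overlap(h$replaced_start[i], h$replaced_end[i], -1)
        }
      }
      depth <- stats::rpois(length(starts), config$depth_mean * cn)
      out[[k]] <- data.frame(chrom = ch, start = starts, end = ends,
                             depth = depth)
    }
    do.call(rbind, out)
  })
}

#' Write a depth-window table as TSV
#'
#' @param depth Data frame from [simulate_depth()] or [window_depth()].
#' @param path Output path. Columns: chrom, start, end (0-based half-open),
#'   depth.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(depth, path) {
  utils::write.table(depth[, c("chrom", "start", "end", "depth")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a depth TSV (per-window or per-base)
#'
#' Per-window files carry columns `chrom`, `start`, `end`, `depth`
#' (0-based half-open); per-base files carry `chrom`, `pos` (1-based),
#' `depth`.
#'
#' @param path TSV path.
#' @return Data frame in the dialect found in the file.
#' @export
read_depth_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
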