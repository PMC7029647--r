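# Homoeologous sequence exchange (HSE) detection from windowed read depth.
#
# An HSE replaces a chromosomal segment with its homoeologous counterpart;
# against the combined progenitor reference the donor segment shows doubled
# coverage and the replaced segment little or none. Detection therefore runs:
# window the depth -> classify windows by depth ratio -> link runs ->
# pair double runs with deleted runs on the homoeologous chromosome.

#' Compute depth ratios over nonoverlapping windows
#'
#' Accepts a per-window table (`chrom`, `start`, `end`, `depth`; 0-based
#' half-open) or a per-base table (`chrom`, `pos` 1-based, `depth`). The
#' genome mean depth is estimated in two passes: windows with ratio > 10
#' after the first pass (collapsed repeats) are excluded and the mean
#' re-estimated. The last window of a chromosome may be truncated; its mean
#' is computed over its true width.
#'
#' @param depth Depth data frame in either dialect.
#' @param window_size Window width in bp (default 10 kb).
#' @return Data frame of class `depth_windows`: `chrom`, `window_index`
#'   (1-based per chromosome), `start`, `end`, `depth`, `ratio`, `state`
#'   (`NA` until [classify_windows()]); genome mean depth in
#'   `attr(, "genome_mean")`.
#' @export
window_depth <- function(depth, window_size = 10000L) {
  if (!nrow(depth)) stop("empty depth input")
  if (all(c("start", "end", "depth") %in% names(depth))) {
    w <- depth[, c("chrom", "start", "end", "depth")]
  } else if (all(c("pos", "depth") %in% names(depth))) {
    w <- do.call(rbind, lapply(split(depth, depth$chrom), function(d) {
      win <- (d$pos - 1L) %/% window_size
      agg <- tapply(d$depth, win, mean)
      idx <- as.integer(names(agg))
      len <- tapply(d$pos, win, max)  # chromosome length proxy
      data.frame(chrom = d$chrom[1L], start = idx * window_size,
                 end = pmin((idx + 1L) * window_size,
                            as.integer(max(len))),
                 depth = as.numeric(agg))
    }))
    rownames(w) <- NULL
  } else {
    stop("depth input needs columns (chrom,start,end,depth) or ",
         "(chrom,pos,depth)")
  }
  if (any(w$depth < 0)) stop("negative depth values")
  w <- w[order(w$chrom, w$start), ]
  w$window_index <- stats::ave(w$start, w$chrom,
                               FUN = seq_along)
  gm <- mean(w$depth)
  keep <- w$depth / gm <= 10
  gm <- mean(w$depth[keep])
  w$ratio <- w$depth / gm
  w$state <- NA_character_
  w <- w[, c("chrom", "window_index", "start", "end", "depth", "ratio",
             "state")]
  rownames(w) <- NULL
  attr(w, "genome_mean") <- gm
  class(w) <- c("depth_windows", "data.frame")
  w
}

#' Classify depth windows into double / deleted / normal coverage states
#'
#' A window whose depth ratio lies in `[double_low, double_high]` relative
#' to the genome mean is called `double` (candidate HSE donor); ratio at or
#' below `deleted_max` is called `deleted` (candidate replaced segment);
#' everything else is `normal`.
#'
#' @param windows Output of [window_depth()].
#' @param double_low,double_high Inclusive ratio bounds for the double
#'   state (defaults 1.5 and 4).
#' @param deleted_max Inclusive upper ratio bound for the deleted state
#'   (default 0.25; the source method leaves this cutoff unstated).
#' @return `windows` with the `state` column filled.
#' @export
classify_windows <- function(windows, double_low = 1.5, double_high = 4.0,
                             deleted_max = 0.25) {
  if (!(deleted_max < double_low && double_low < double_high)) {
    stop("thresholds must satisfy deleted_max < double_low < double_high")
  }
  r <- windows$ratio
  windows$state <- ifelse(r >= double_low & r <= double_high, "double",
                          ifelse(r <= deleted_max, "deleted", "normal"))
  windows
}

#' Link classified windows into candidate runs
#'
#' Maximal runs of the target state are formed per chromosome; runs
#' separated by at most `max_gap_windows` non-target windows are merged
#' (gap windows count toward the span), and runs spanning fewer than
#' `min_span_windows` windows are discarded.
#'
#' @param windows Classified windows (from [classify_windows()]).
#' @param state Target state, `"double"` or `"deleted"`.
#' @param max_gap_windows Maximum number of intervening non-target windows
#'   bridged when linking (default 5).
#' @param min_span_windows Minimum run span in windows, inclusive
#'   (default 8, i.e. 80 kb at 10 kb windows).
#' @return Data frame of runs: `chrom`, `first_window`, `last_window`,
#'   `start`, `end` (bp, 0-based half-open), `span_windows`, `n_state`
#'   (target windows in the run), `mean_ratio` (over target windows).
#' @export
link_runs <- function(windows, state = c("double", "deleted"),
                      max_gap_windows = 5L, min_span_windows = 8L) {
  state <- match.arg(state)
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, ]
    w <- w[order(w$window_index), ]
    idx <- which(w$state == state)
    if (!length(idx)) next
    brk <- c(0L, which(diff(idx) > max_gap_windows + 1L), length(idx))
    for (k in seq_len(length(brk) - 1L)) {
      members <- idx[(brk[k] + 1L):brk[k + 1L]]
      span <- members[length(members)] - members[1L] + 1L
      if (span < min_span_windows) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        first_window = w$window_index[members[1L]],
        last_window = w$window_index[members[length(members)]],
        start = w$start[members[1L]],
        end = w$end[members[length(members)]],
        span_windows = span,
        n_state = length(members),
        mean_ratio = mean(w$ratio[members])
      )
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), first_window = integer(),
                      last_window = integer(), start = integer(),
                      end = integer(), span_windows = integer(),
                      n_state = integer(), mean_ratio = numeric()))
  }
  do.call(rbind, out)
}

# Project an interval from one subgenome onto the other by linear
# interpolation between flanking homoeolog anchor midpoints. Returns NA
# coordinates when no flanking anchors exist on both sides.
.project_interval <- function(chrom, start, end, map) {
  a_side <- map$chrom_a == chrom
  b_side <- map$chrom_b == chrom
  if (any(a_side)) {
    m <- map[a_side, ]
    from_mid <- (m$start_a + m$end_a) / 2
    to_mid <- (m$start_b + m$end_b) / 2
    target_chrom <- names(sort(table(m$chrom_b), decreasing = TRUE))[1L]
  } else if (any(b_side)) {
    m <- map[b_side, ]
    from_mid <- (m$start_b + m$end_b) / 2
    to_mid <- (m$start_a + m$end_a) / 2
    target_chrom <- names(sort(table(m$chrom_a), decreasing = TRUE))[1L]
  } else {
    return(NULL)
  }
  o <- order(from_mid)
  from_mid <- from_mid[o]
  to_mid <- to_mid[o]
  p <- stats::approx(from_mid, to_mid, xout = c(start, end), rule = 1)$y
  if (anyNA(p)) {
    # allow limited extrapolation with the slope of the nearest two anchors
    n <- length(from_mid)
    if (n >= 2L) {
      slope_lo <- (to_mid[2L] - to_mid[1L]) / (from_mid[2L] - from_mid[1L])
      slope_hi <- (to_mid[n] - to_mid[n - 1L]) /
        (from_mid[n] - from_mid[n - 1L])
      fill <- function(x) {
        if (x < from_mid[1L]) to_mid[1L] + (x - from_mid[1L]) * slope_lo
        else if (x > from_mid[n]) to_mid[n] + (x - from_mid[n]) * slope_hi
        else stats::approx(from_mid, to_mid, xout = x)$y
      }
      p <- vapply(c(start, end), fill, numeric(1L))
    } else {
      return(list(chrom = target_chrom, start = NA_real_, end = NA_real_))
    }
  }
  list(chrom = target_chrom, start = min(p), end = max(p))
}

#' Pair double-coverage runs with homoeologous deleted runs into HSE calls
#'
#' Each double run is projected onto the other subgenome via the homoeolog
#' map (linear interpolation between flanking anchor midpoints). A projected
#' interval that reciprocally overlaps a deleted run by at least
#' `min_reciprocal_overlap` (in both directions) yields a directed HSE
#' (donor subgenome is the double run's). Double runs without a matching
#' deleted run are returned as unpaired candidates; runs whose projection is
#' undefined are flagged, not dropped.
#'
#' @param double_runs,deleted_runs Run tables from [link_runs()], typically
#'   double runs on one subgenome and deleted runs on the other.
#' @param map Homoeolog map with columns `gene_a`, `chrom_a`, `start_a`,
#'   `end_a`, `gene_b`, `chrom_b`, `start_b`, `end_b`.
#' @param min_reciprocal_overlap Minimum reciprocal overlap fraction
#'   (default 0.5).
#' @param subgenome_of Function mapping a chromosome name to its subgenome
#'   label; the default reads the leading letter (chromosomes named
#'   `A01`, `B01`, ...).
#' @return List with `hse` (data frame: `direction`, `donor_chrom`,
#'   `donor_start`, `donor_end`, `replaced_chrom`, `replaced_start`,
#'   `replaced_end`, `n_windows`, `length`, `donor_ratio`,
#'   `replaced_ratio`) and `unpaired` (double runs with a `reason` column:
#'   `no_deleted_overlap` or `unprojectable`).
#' @export
pair_hse <- function(double_runs, deleted_runs, map,
                     min_reciprocal_overlap = 0.5,
                     subgenome_of = function(ch) substr(ch, 1L, 1L)) {
  hse <- list()
  unpaired <- list()
  for (i in seq_len(nrow(double_runs))) {
    run <- double_runs[i, ]
    proj <- .project_interval(run$chrom, run$start, run$end, map)
    if (is.null(proj) || anyNA(c(proj$start, proj$end))) {
      unpaired[[length(unpaired) + 1L]] <-
        cbind(run, reason = "unprojectable")
      next
    }
    cand <- deleted_runs[deleted_runs$chrom == proj$chrom, , drop = FALSE]
    hit <- NULL
    for (j in seq_len(nrow(cand))) {
      ov <- min(proj$end, cand$end[j]) - max(proj$start, cand$start[j])
      if (ov <= 0) next
      if (ov / (proj$end - proj$start) >= min_reciprocal_overlap &&
          ov / (cand$end[j] - cand$start[j]) >= min_reciprocal_overlap) {
        hit <- cand[j, ]
        break
      }
    }
    if (is.null(hit)) {
      unpaired[[length(unpaired) + 1L]] <-
        cbind(run, reason = "no_deleted_overlap")
      next
    }
    # Refine donor boundaries with the deleted-run evidence: gap-linking can
    # drag a double run past the true edge over a stray high-depth window,
    # while the homoeologous deletion edge is far less noisy; the reported
    # donor segment is the intersection of the double run with the deleted
    # run projected back onto the donor chromosome.
    back <- .project_interval(hit$chrom, hit$start, hit$end, map)
    d_start <- run$start
    d_end <- run$end
    if (!is.null(back) && !anyNA(c(back$start, back$end)) &&
        back$chrom == run$chrom) {
      rs <- max(run$start, round(back$start))
      re <- min(run$end, round(back$end))
      if (re > rs) {
        d_start <- rs
        d_end <- re
      }
    }
    hse[[length(hse) + 1L]] <- data.frame(
      direction = paste0(subgenome_of(run$chrom), ">",
                         subgenome_of(hit$chrom)),
      donor_chrom = run$chrom, donor_start = d_start,
      donor_end = d_end,
      replaced_chrom = hit$chrom, replaced_start = hit$start,
      replaced_end = hit$end,
      n_windows = run$span_windows,
      length = d_end - d_start,
      donor_ratio = run$mean_ratio,
      replaced_ratio = hit$mean_ratio
    )
  }
  empty_run <- double_runs[0, ]
  list(
    hse = if (length(hse)) do.call(rbind, hse) else data.frame(
      direction = character(), donor_chrom = character(),
      donor_start = integer(), donor_end = integer(),
      replaced_chrom = character(), replaced_start = integer(),
      replaced_end = integer(), n_windows = integer(), length = integer(),
      donor_ratio = numeric(), replaced_ratio = numeric()),
    unpaired = if (length(unpaired)) do.call(rbind, unpaired) else
      cbind(empty_run, reason = character())
  )
}

#' Summarize HSE calls per direction
#'
#' @param hse HSE table from [pair_hse()].
#' @param subgenome_sizes Named vector of total bp per subgenome
#'   (names `A`, `B`).
#' @return Data frame with rows `A>B`, `B>A` and `total`: `n`, `total_bp`
#'   (donor segment bp) and `ratio_pct` (HSE bp as a percentage of the
#'   replaced subgenome's size; the total row uses the whole genome).
#' @export
hse_summary <- function(hse, subgenome_sizes) {
  stopifnot(all(c("A", "B") %in% names(subgenome_sizes)))
  dirs <- c("A>B", "B>A")
  rows <- lapply(dirs, function(d) {
    x <- hse[hse$direction == d, , drop = FALSE]
    replaced <- substr(d, 3L, 3L)
    bp <- sum(x$length)
    data.frame(direction = d, n = nrow(x), total_bp = bp,
               ratio_pct = 100 * bp / subgenome_sizes[[replaced]])
  })
  tot_bp <- sum(hse$length)
  rows[[3L]] <- data.frame(direction = "total", n = nrow(hse),
                           total_bp = tot_bp,
                           ratio_pct = 100 * tot_bp / sum(subgenome_sizes))
  do.call(rbind, rows)
}

#' Run the full HSE detector on a depth table
#'
#' Convenience wrapper: [window_depth()] -> [classify_windows()] ->
#' [link_runs()] on both states and both subgenomes -> [pair_hse()] in both
#' directions -> [hse_summary()].
#'
#' @param depth Depth data frame (see [window_depth()]).
#' @param map Homoeolog map (see [pair_hse()]).
#' @param window_size,double_low,double_high,deleted_max,max_gap_windows,min_span_windows,min_reciprocal_overlap
#'   Stage parameters, passed through.
#' @param subgenome_of Chromosome-to-subgenome mapping function.
#' @return List with `windows`, `hse`, `unpaired`, `summary`.
#' @export
detect_hse <- function(depth, map, window_size = 10000L,
                       double_low = 1.5, double_high = 4.0,
                       deleted_max = 0.25, max_gap_windows = 5L,
                       min_span_windows = 8L, min_reciprocal_overlap = 0.5,
                       subgenome_of = function(ch) substr(ch, 1L, 1L)) {
  w <- window_depth(depth, window_size)
  w <- classify_windows(w, double_low, double_high, deleted_max)
  doubles <- link_runs(w, "double", max_gap_windows, min_span_windows)
  deleted <- link_runs(w, "deleted", max_gap_windows, min_span_windows)
  paired <- pair_hse(doubles, deleted, map, min_reciprocal_overlap,
                     subgenome_of)
  sizes <- tapply(w$end - w$start, subgenome_of(w$chrom), sum)
  list(windows = w, hse = paired$hse, unpaired = paired$unpaired,
       summary = hse_summary(paired$hse, sizes))
}

#' Write HSE segments as BED
#'
#' BED (0-based half-open) of donor segments, direction in the name field.
#'
#' @param hse HSE table from [pair_hse()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hse_bed <- function(hse, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# HSE donor segments; coordinates 0-based half-open", con)
  if (nrow(hse)) {
    writeLines(sprintf("%s\t%d\t%d\t%s", hse$donor_chrom,
                       as.integer(hse$donor_start),
                       as.integer(hse$donor_end), hse$direction), con)
  }
  invisible(path)
}
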