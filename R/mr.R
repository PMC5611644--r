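# Methylated-region (MR) calling: tile the genome into non-overlapping
# fixed-width windows, score each window against a context-specific level
# threshold, and merge threshold-passing runs into MRs.

#' Context-specific MR level thresholds
#'
#' Windows are scored methylated when their pooled level reaches at least
#' 40% (CG), 20% (CHG) or 10% (CHH); the comparison is inclusive.
#' @return named numeric vector.
#' @export
mr_thresholds <- function() c(CG = 0.40, CHG = 0.20, CHH = 0.10)

#' Tile a methylome into non-overlapping windows
#'
#' Windows tile each chromosome from coordinate 0; every covered cytosine of
#' the requested context falls in exactly one window (half-open intervals,
#' so a site at position `window_size` belongs to the second window). The
#' window level is the coverage-weighted pooled ratio
#' `sum(n_meth) / sum(n_meth + n_unmeth)`, not the mean of per-site levels.
#'
#' @param m a [methylome()].
#' @param context one of `CG`, `CHG`, `CHH`.
#' @param window_size window width in bp (default 100).
#' @param chrom_lengths optional named vector; when given, every window of
#'   each chromosome is emitted (empty ones with `n_sites = 0` and `NA`
#'   level), otherwise only windows containing covered sites.
#' @return data.frame `chrom`, `start`, `end`, `context`, `n_sites`,
#'   `sum_meth`, `sum_unmeth`, `level`.
#' @export
tile_windows <- function(m, context, window_size = 100L,
                         chrom_lengths = NULL) {
  .check_context(context)
  if (window_size <= 0) stop("window_size must be positive")
  ctx <- context
  dt <- data.table::as.data.table(unclass(m))
  dt <- dt[dt$context == ctx & dt$n_meth + dt$n_unmeth > 0]
  agg <- dt[, win := pos %/% as.integer(window_size)][
    , .(n_sites = .N, sum_meth = sum(n_meth), sum_unmeth = sum(n_unmeth)),
    by = .(chrom, win)]
  if (!is.null(chrom_lengths)) {
    grid <- data.table::rbindlist(lapply(names(chrom_lengths), function(ch) {
      nwin <- ceiling(chrom_lengths[[ch]] / window_size)
      data.table::data.table(chrom = ch, win = seq_len(nwin) - 1L)
    }))
    agg <- agg[grid, on = c("chrom", "win")]
    agg[is.na(n_sites), `:=`(n_sites = 0L, sum_meth = 0L, sum_unmeth = 0L)]
  }
  data.table::setorder(agg, chrom, win)
  out <- data.frame(
    chrom = agg$chrom,
    start = agg$win * as.integer(window_size),
    end = (agg$win + 1L) * as.integer(window_size),
    context = ctx,
    n_sites = agg$n_sites,
    sum_meth = agg$sum_meth,
    sum_unmeth = agg$sum_unmeth)
  tot <- out$sum_meth + out$sum_unmeth
  out$level <- ifelse(tot > 0, out$sum_meth / tot, NA_real_)
  out
}

#' Score windows as methylated against context thresholds
#'
#' A window is methylated when its level is at least the threshold for its
#' context (inclusive). Windows with undefined level, or with fewer covered
#' sites than `min_sites`, are left unscored (`NA`): they are neither
#' methylated nor unmethylated and count toward merge gaps only.
#'
#' @param windows output of [tile_windows()].
#' @param thresholds named per-context level thresholds.
#' @param min_sites minimum covered sites for a window to be scored
#'   (default 1; the DMR caller applies its own >= 4-site rule).
#' @return `windows` with a logical `methylated` column.
#' @export
score_windows <- function(windows, thresholds = mr_thresholds(),
                          min_sites = 1L) {
  .check_context(windows$context)
  thr <- thresholds[windows$context]
  if (anyNA(thr)) stop("thresholds must cover every context present")
  flag <- windows$level >= thr
  flag[is.na(windows$level) | windows$n_sites < min_sites] <- NA
  windows$methylated <- flag
  windows
}

#' Merge methylated windows into MRs
#'
#' Maximal runs of methylated windows become one MR; up to
#' `max_gap_windows` consecutive non-methylated or unscored windows may be
#' bridged. Window positions are taken from coordinates, so absent (empty)
#' windows count toward the gap budget too. The MR level is the
#' coverage-weighted pooled level over member methylated windows only.
#'
#' @param windows scored windows ([score_windows()]), one context.
#' @param max_gap_windows intervening non-methylated windows allowed inside
#'   one MR (default 0: only adjacent methylated windows merge).
#' @return data.frame `chrom`, `start`, `end`, `context`, `n_windows`,
#'   `level`, `length`.
#' @export
merge_mrs <- function(windows, max_gap_windows = 0L) {
  if (is.null(windows$methylated)) stop("windows must be scored first")
  if (length(unique(windows$context)) > 1) {
    stop("merge_mrs expects windows of a single context")
  }
  meth <- windows[!is.na(windows$methylated) & windows$methylated, ,
                  drop = FALSE]
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      n_windows = integer(), level = numeric(),
                      length = integer())
  if (nrow(meth) == 0) return(empty)
  ws <- meth$end[1] - meth$start[1]
  dt <- data.table::as.data.table(meth)
  data.table::setorder(dt, chrom, start)
  dt[, bin_idx := start %/% ws]
  # a new run starts when the window-index gap exceeds the budget or the
  # chromosome changes
  brk <- if (nrow(dt) > 1) {
    (diff(dt$bin_idx) - 1L > max_gap_windows) |
      (dt$chrom[-1] != dt$chrom[-nrow(dt)])
  } else logical(0)
  dt[, run_id := cumsum(c(1L, brk))]
  mrs <- dt[, .(chrom = chrom[1], start = min(start), end = max(end),
                context = context[1], n_windows = .N,
                level = sum(sum_meth) / sum(sum_meth + sum_unmeth)),
            by = run_id][, run_id := NULL]
  mrs[, `:=`(length = end - start)]
  data.table::setorder(mrs, chrom, start)
  as.data.frame(mrs)
}

#' Call MRs from a methylome in one step
#'
#' Convenience wrapper: [tile_windows()] then [score_windows()] then
#' [merge_mrs()]; the stage label of the methylome is attached as a column.
#'
#' @inheritParams tile_windows
#' @inheritParams score_windows
#' @inheritParams merge_mrs
#' @return MR data.frame with a `stage` column.
#' @export
call_mrs <- function(m, context, window_size = 100L,
                     thresholds = mr_thresholds(), min_sites = 1L,
                     max_gap_windows = 0L, chrom_lengths = NULL) {
  w <- tile_windows(m, context, window_size, chrom_lengths)
  w <- score_windows(w, thresholds, min_sites)
  mrs <- merge_mrs(w, max_gap_windows)
  if (nrow(mrs)) mrs$stage <- attr(m, "stage") else mrs$stage <- character(0)
  mrs
}

#' Summarise MR length and level distributions
#'
#' Groups regions by any of `stage` and `context` present and reports the
#' count plus quartiles of region length and methylation level.
#'
#' @param regions MR (or DMR) data.frame with `length` and `level` columns.
#' @return data.frame, one row per group.
#' @export
summarize_mrs <- function(regions) {
  by_cols <- intersect(c("stage", "context"), names(regions))
  dt <- data.table::as.data.table(regions)
  if (nrow(dt) == 0) {
    return(data.frame(n = integer(0)))
  }
  out <- dt[, {
    lq <- quantile(length, c(0, .25, .5, .75, 1), names = FALSE)
    vq <- quantile(level, c(0, .25, .5, .75, 1), names = FALSE)
    .(n = .N,
      length_min = lq[1], length_q25 = lq[2], length_median = lq[3],
      length_q75 = lq[4], length_max = lq[5],
      level_min = vq[1], level_q25 = vq[2], level_median = vq[3],
      level_q75 = vq[4], level_max = vq[5])
  }, by = by_cols]
  as.data.frame(out)
}
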