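# Differentially methylated region (DMR) calling between two stages or
# genotypes: 100-bp bin tiling over sites covered in both samples, per-bin
# two-sided Fisher exact test on pooled C/T counts, Benjamini-Hochberg FDR,
# absolute-difference thresholds, and gap-tolerant same-direction merging.

#' DMR calling thresholds
#'
#' Defaults: absolute pooled-level difference of 0.4 (CG) or 0.2 (CHG, CHH);
#' Benjamini-Hochberg FDR < 0.01 on two-sided Fisher exact tests; at least 4
#' cytosines per 100-bp bin, each covered by 10--100 reads in both samples;
#' merging bridges a gap of one window.
#'
#' @param diff named per-context absolute difference thresholds.
#' @param fdr BH-adjusted significance cutoff (strict `<`).
#' @param min_sites minimum passing cytosines per bin (bins with fewer are
#'   dropped, so 3-site bins are never tested).
#' @param min_cov,max_cov per-site coverage bounds, applied in both samples.
#' @param merge_gap_windows non-significant bins bridgeable when merging.
#' @param bin_size bin width in bp.
#' @return a validated `dmr_thresholds` list.
#' @export
dmr_thresholds <- function(diff = c(CG = 0.40, CHG = 0.20, CHH = 0.20),
                           fdr = 0.01, min_sites = 4L, min_cov = 10L,
                           max_cov = 100L, merge_gap_windows = 1L,
                           bin_size = 100L) {
  stopifnot(all(diff > 0), all(diff <= 1), fdr > 0, fdr <= 1,
            min_sites >= 1, min_cov >= 0, min_cov <= max_cov,
            merge_gap_windows >= 0, bin_size > 0)
  if (!all(CONTEXTS %in% names(diff))) {
    stop("diff thresholds must name CG, CHG and CHH")
  }
  structure(list(diff = diff, fdr = fdr, min_sites = as.integer(min_sites),
                 min_cov = as.integer(min_cov), max_cov = as.integer(max_cov),
                 merge_gap_windows = as.integer(merge_gap_windows),
                 bin_size = as.integer(bin_size)),
            class = "dmr_thresholds")
}

#' Two-sided Fisher exact test for 2x2 count tables (vectorised)
#'
#' For each table `(a_meth, a_unmeth; b_meth, b_unmeth)`, conditions on the
#' margins and sums the hypergeometric point probabilities of all tables at
#' most as probable as the observed one (the standard sum-of-small-p
#' two-sided rule, with a 1e-7 relative guard against floating-point ties).
#' Exact — no continuity or large-sample approximation.
#'
#' @param a_meth,a_unmeth,b_meth,b_unmeth non-negative integer vectors.
#' @return two-sided p-values. A table with an all-zero row yields p = 1
#'   (with a warning): no evidence either way.
#' @export
fisher_exact_2x2 <- function(a_meth, a_unmeth, b_meth, b_unmeth) {
  n <- length(a_meth)
  stopifnot(length(a_unmeth) == n, length(b_meth) == n, length(b_unmeth) == n)
  if (any(c(a_meth, a_unmeth, b_meth, b_unmeth) < 0)) {
    stop("counts must be non-negative")
  }
  drawn <- a_meth + a_unmeth          # sample-A margin
  white <- a_meth + b_meth            # methylated margin
  black <- a_unmeth + b_unmeth
  p <- rep(1, n)
  degenerate <- drawn == 0 | (b_meth + b_unmeth) == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " table(s) with an empty sample; p set to 1")
  }
  live <- which(!degenerate)
  if (!length(live)) return(p)
  lo <- pmax(0L, drawn[live] - black[live])
  hi <- pmin(drawn[live], white[live])
  dobs <- dhyper(a_meth[live], white[live], black[live], drawn[live])
  counts <- hi - lo + 1L
  idx <- rep(seq_along(live), counts)
  k <- sequence(counts, from = lo)
  d <- dhyper(k, white[live][idx], black[live][idx], drawn[live][idx])
  keep <- d <= dobs[idx] * (1 + 1e-7)
  sums <- rowsum(d * keep, idx)
  p[live] <- pmin(1, as.numeric(sums))
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment `q_(i) = min_{j>=i} m p_(j) / j`, capped at 1,
#' returned in input order (wraps [stats::p.adjust()] after validating the
#' input).
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted q-values, same order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  p.adjust(p, method = "BH")
}

#' Build per-bin two-sample comparisons
#'
#' Joins two stage methylomes on `(chrom, pos, strand)` for one context; a
#' cytosine passes only if its coverage lies in `[min_cov, max_cov]` in
#' *both* samples. Passing sites are pooled into `bin_size` bins; bins with
#' fewer than `min_sites` passing cytosines are dropped. Each retained bin
#' gets pooled levels, their difference (`a - b`), a two-sided Fisher exact
#' p-value on the pooled counts (one 2x2 table per bin) and a BH q-value
#' computed across all retained bins genome-wide.
#'
#' @param m_a,m_b two [methylome()] objects on the same reference.
#' @param context `CG`, `CHG` or `CHH`.
#' @param thresholds a [dmr_thresholds()].
#' @return data.frame, one row per retained bin: `chrom`, `start`, `end`,
#'   `context`, `n_sites_passing`, `a_meth`, `a_unmeth`, `b_meth`,
#'   `b_unmeth`, `level_a`, `level_b`, `diff`, `p_value`, `q_value`.
#' @export
build_bins <- function(m_a, m_b, context, thresholds = dmr_thresholds()) {
  .check_context(context)
  ctx <- context
  th <- thresholds
  a <- data.table::as.data.table(unclass(m_a))
  b <- data.table::as.data.table(unclass(m_b))
  a <- a[a$context == ctx]
  b <- b[b$context == ctx]
  if (nrow(a) && nrow(b) && !length(intersect(unique(a$chrom), unique(b$chrom)))) {
    stop("methylomes share no chromosome: are they on the same reference?")
  }
  data.table::setnames(b, c("n_meth", "n_unmeth"), c("bm", "bu"))
  j <- merge(a, b[, .(chrom, pos, strand, bm, bu)],
             by = c("chrom", "pos", "strand"))
  j[, `:=`(cov_a = n_meth + n_unmeth, cov_b = bm + bu)]
  j <- j[cov_a >= th$min_cov & cov_a <= th$max_cov &
           cov_b >= th$min_cov & cov_b <= th$max_cov]
  j[, win := pos %/% th$bin_size]
  bins <- j[, .(n_sites_passing = .N,
                a_meth = sum(n_meth), a_unmeth = sum(n_unmeth),
                b_meth = sum(bm), b_unmeth = sum(bu)),
            by = .(chrom, win)]
  bins <- bins[n_sites_passing >= th$min_sites]
  data.table::setorder(bins, chrom, win)
  out <- data.frame(
    chrom = bins$chrom,
    start = bins$win * th$bin_size,
    end = (bins$win + 1L) * th$bin_size,
    context = rep(ctx, nrow(bins)),
    n_sites_passing = bins$n_sites_passing,
    a_meth = bins$a_meth, a_unmeth = bins$a_unmeth,
    b_meth = bins$b_meth, b_unmeth = bins$b_unmeth)
  out$level_a <- out$a_meth / (out$a_meth + out$a_unmeth)
  out$level_b <- out$b_meth / (out$b_meth + out$b_unmeth)
  out$diff <- out$level_a - out$level_b
  if (nrow(out)) {
    out$p_value <- fisher_exact_2x2(out$a_meth, out$a_unmeth,
                                    out$b_meth, out$b_unmeth)
    out$q_value <- bh_adjust(out$p_value)
  } else {
    out$p_value <- numeric(0)
    out$q_value <- numeric(0)
  }
  out
}

#' Select significant bins
#'
#' A bin is selected iff its absolute pooled-level difference reaches the
#' context threshold (inclusive) *and* its BH q-value is below `fdr`
#' (strict). Direction is `hyper` when sample A is more methylated than
#' sample B, `hypo` otherwise.
#'
#' @param bins output of [build_bins()].
#' @param thresholds a [dmr_thresholds()].
#' @return the selected rows with a `direction` column.
#' @export
call_dmr_bins <- function(bins, thresholds = dmr_thresholds()) {
  thr <- thresholds$diff[bins$context]
  sel <- abs(bins$diff) >= thr & bins$q_value < thresholds$fdr
  out <- bins[sel, , drop = FALSE]
  out$direction <- ifelse(out$diff > 0, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Merge significant bins into DMRs
#'
#' Runs of same-direction significant bins on one chromosome merge into one
#' DMR; up to `merge_gap_windows` intervening non-significant bins may be
#' bridged (the default 1 merges regions within 100 bp of each other).
#' Hyper and hypo bins never merge together. The DMR mean difference is the
#' site-count-weighted mean of member-bin differences.
#'
#' @param sig_bins output of [call_dmr_bins()] (one context).
#' @param merge_gap_windows gap budget in bins.
#' @param bin_size bin width used to build the bins.
#' @return data.frame `chrom`, `start`, `end`, `context`, `direction`,
#'   `n_bins`, `n_sites`, `mean_diff`, `length`.
#' @export
merge_dmrs <- function(sig_bins, merge_gap_windows = 1L, bin_size = 100L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      n_bins = integer(), n_sites = integer(),
                      mean_diff = numeric(), length = integer())
  if (nrow(sig_bins) == 0) return(empty)
  if (length(unique(sig_bins$context)) > 1) {
    stop("merge_dmrs expects bins of a single context")
  }
  res <- lapply(c("hyper", "hypo"), function(dir) {
    dt <- data.table::as.data.table(sig_bins[sig_bins$direction == dir, ,
                                             drop = FALSE])
    if (nrow(dt) == 0) return(NULL)
    data.table::setorder(dt, chrom, start)
    dt[, bin_idx := start %/% as.integer(bin_size)]
    brk <- if (nrow(dt) > 1) {
      (diff(dt$bin_idx) - 1L > merge_gap_windows) |
        (dt$chrom[-1] != dt$chrom[-nrow(dt)])
    } else logical(0)
    dt[, run_id := cumsum(c(1L, brk))]
    dt[, .(chrom = chrom[1], start = min(start), end = max(end),
           context = context[1], direction = dir, n_bins = .N,
           n_sites = sum(n_sites_passing),
           mean_diff = sum(diff * n_sites_passing) / sum(n_sites_passing)),
       by = run_id][, run_id := NULL]
  })
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  if (nrow(out) == 0) return(empty)
  out[, `:=`(length = end - start)]
  data.table::setorder(out, chrom, start)
  as.data.frame(out)
}

#' Associate regions with overlapping annotations
#'
#' A region is associated with every annotation interval it overlaps by at
#' least 1 bp (half-open intervals: abutting does not overlap). Regions
#' touching nothing are labelled `intergenic`.
#'
#' @param regions DMR or MR data.frame (`chrom`, `start`, `end`).
#' @param annotations data.frame as from [read_annotations()] (gene/TE
#'   intervals with `id`).
#' @return `regions` with an `annotation` column (comma-separated ids or
#'   `"intergenic"`).
#' @export
associate_annotations <- function(regions, annotations) {
  regions$annotation <- rep("intergenic", nrow(regions))
  if (nrow(regions) == 0 || nrow(annotations) == 0) return(regions)
  hits <- .overlap_hits(regions, annotations)
  if (nrow(hits)) {
    ids <- hits[, .(annotation = paste(annotations$id[subject], collapse = ",")),
                by = .(query)]
    regions$annotation[ids$query] <- ids$annotation
  }
  regions
}

#' Call DMRs between two stages in one step
#'
#' [build_bins()] then [call_dmr_bins()] then [merge_dmrs()], optionally
#' followed by [associate_annotations()]. An optional consensus mode
#' re-runs the comparison against further replicate sample pairs and keeps
#' only bins significant in all of them before merging.
#'
#' @inheritParams build_bins
#' @param annotations optional annotation data.frame.
#' @param replicates optional list of further `list(a = , b = )` methylome
#'   pairs for consensus calling; a bin must be selected in the main
#'   comparison and every replicate comparison to survive.
#' @return DMR data.frame; the bin-level table is attached as
#'   `attr(, "bins")`.
#' @export
call_dmrs <- function(m_a, m_b, context, thresholds = dmr_thresholds(),
                      annotations = NULL, replicates = NULL) {
  bins <- build_bins(m_a, m_b, context, thresholds)
  sig <- call_dmr_bins(bins, thresholds)
  if (!is.null(replicates)) {
    keys <- paste(sig$chrom, sig$start, sig$direction)
    for (rp in replicates) {
      rb <- call_dmr_bins(build_bins(rp$a, rp$b, context, thresholds),
                          thresholds)
      keys <- intersect(keys, paste(rb$chrom, rb$start, rb$direction))
    }
    sig <- sig[paste(sig$chrom, sig$start, sig$direction) %in% keys, ,
               drop = FALSE]
  }
  dmrs <- merge_dmrs(sig, thresholds$merge_gap_windows, thresholds$bin_size)
  if (!is.null(annotations)) dmrs <- associate_annotations(dmrs, annotations)
  attr(dmrs, "bins") <- bins
  dmrs
}
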