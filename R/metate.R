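# End-aligned meta-TE methylation profiles by TE length class, and
# relative-position histograms of sites or region midpoints over TEs.

#' Group TEs into length classes
#'
#' Default classes: shorter than 1 kb, 1--2 kb, and 2 kb or longer.
#'
#' @param tes TE annotation data.frame (`chrom`, `start`, `end`, ...).
#' @param boundaries strictly increasing class boundaries in bp.
#' @return `tes` with a `length_class` factor (all classes kept as levels,
#'   so empty classes are representable).
#' @export
classify_tes <- function(tes, boundaries = c(1000L, 2000L)) {
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be strictly increasing")
  }
  len <- tes$end - tes$start
  brks <- c(0, boundaries, Inf)
  labs <- character(length(brks) - 1)
  labs[1] <- sprintf("<%gkb", boundaries[1] / 1000)
  labs[length(labs)] <- sprintf(">=%gkb", boundaries[length(boundaries)] / 1000)
  if (length(labs) > 2) {
    labs[2:(length(labs) - 1)] <- sprintf(
      "%g-%gkb", boundaries[-length(boundaries)] / 1000, boundaries[-1] / 1000)
  }
  tes$length_class <- cut(len, breaks = brks, labels = labs, right = FALSE)
  tes
}

#' End-aligned meta-TE methylation profile
#'
#' TE ends of one length class are aligned and pooled methylation is
#' averaged in fixed-width intervals: `flank / bin` bins on each side of the
#' TE, and an interior budget of `floor(min_length / 2 / bin)` bins per
#' side, indexed from each border toward the middle, so bins never overlap
#' within the shortest TE of the class (longer TEs simply leave their middle
#' unprofiled). Minus-strand TEs are mirrored so bin 1 is always the 5'
#' border; TEs without strand (`.`) are treated as plus strand. Sites
#' falling in overlapping flanks of nearby TEs contribute to each.
#'
#' @param m a [methylome()].
#' @param tes TEs of one length class.
#' @param context `CG`, `CHG` or `CHH`.
#' @param flank flanking distance profiled on each side (bp).
#' @param bin interval width (bp).
#' @return data.frame with one row per bin: `side` (`flank5`, `body5`,
#'   `body3`, `flank3`), `bin` (1-based, counted toward the TE for flanks
#'   and from the border inward for body bins), `offset_bp` (signed distance
#'   of the bin start from the nearest TE border), `position` (1..n plotting
#'   index across the whole axis), `mean_level` (pooled; `NA` when no sites
#'   contribute), `n_sites` (site-TE incidences) and `n_reads` (pooled read
#'   count behind the bin mean).
#' @export
build_meta_profile <- function(m, tes, context, flank = 4000L, bin = 10L) {
  .check_context(context)
  if (flank <= 0 || bin <= 0) stop("flank and bin must be positive")
  if (nrow(tes) == 0) stop("TE class is empty")
  ctx <- context
  lens <- tes$end - tes$start
  budget <- floor(min(lens) / 2 / bin)          # interior bins per side
  nf <- as.integer(flank %/% bin)               # flank bins per side
  sites <- data.frame(chrom = m$chrom, pos = m$pos, n_meth = m$n_meth,
                      n_unmeth = m$n_unmeth)[m$context == ctx &
                                               m$n_meth + m$n_unmeth > 0, ]
  ext <- data.frame(chrom = tes$chrom, start = pmax(0L, tes$start - flank),
                    end = tes$end + flank)
  hits <- .overlap_hits(data.frame(chrom = sites$chrom, start = sites$pos,
                                   end = sites$pos + 1L), ext)
  grid <- data.table::data.table(
    side = rep(c("flank5", "body5", "body3", "flank3"),
               c(nf, budget, budget, nf)),
    bin = c(seq_len(nf), seq_len(budget), rev(seq_len(budget)), seq_len(nf)))
  grid[, position := seq_len(.N)]
  grid$offset_bp <- c(-rev(seq_len(nf)) * bin,            # flank5
                      (seq_len(budget) - 1L) * bin,       # body5 (from 5' border)
                      -(rev(seq_len(budget))) * bin,      # body3 (to 3' border)
                      (seq_len(nf) - 1L) * bin)           # flank3
  if (nrow(hits) == 0) {
    grid[, `:=`(mean_level = NA_real_, n_sites = 0L, n_reads = 0L)]
    out <- as.data.frame(grid)
    attr(out, "interior_bins_per_side") <- budget
    return(out)
  }
  p <- sites$pos[hits$query]
  s <- tes$start[hits$subject]
  e <- tes$end[hits$subject]
  str <- tes$strand[hits$subject] %||% rep("+", nrow(hits))
  str[!str %in% c("+", "-")] <- "+"
  # mirror minus-strand TEs: reflect the position within [s - flank, e + flank)
  p5 <- ifelse(str == "-", s + e - 1L - p, p)   # 5'-anchored coordinate
  inc <- data.table::data.table(p = p5, s = s, e = e,
                                nm = sites$n_meth[hits$query],
                                nu = sites$n_unmeth[hits$query])
  assign_side <- function(dt) {
    side <- rep(NA_character_, nrow(dt))
    b <- rep(NA_integer_, nrow(dt))
    up <- dt$p < dt$s & dt$p >= dt$s - flank
    side[up] <- "flank5"
    b[up] <- ((dt$p[up] - (dt$s[up] - flank)) %/% bin) + 1L
    dn <- dt$p >= dt$e & dt$p < dt$e + flank
    side[dn] <- "flank3"
    b[dn] <- ((dt$p[dn] - dt$e[dn]) %/% bin) + 1L
    inside <- dt$p >= dt$s & dt$p < dt$e
    d5 <- (dt$p - dt$s) %/% bin + 1L
    d3 <- (dt$e - 1L - dt$p) %/% bin + 1L
    b5 <- inside & d5 <= budget
    side[b5] <- "body5"; b[b5] <- d5[b5]
    b3 <- inside & !b5 & d3 <= budget
    side[b3] <- "body3"; b[b3] <- d3[b3]
    list(side = side, bin = b)
  }
  ab <- assign_side(inc)
  inc[, `:=`(side = ab$side, bin = ab$bin)]
  inc <- inc[!is.na(side)]
  agg <- inc[, .(mean_level = sum(nm) / sum(nm + nu), n_sites = .N,
                 n_reads = sum(nm + nu)),
             by = .(side, bin)]
  out <- merge(grid, agg, by = c("side", "bin"), all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L, n_reads = 0L)]
  data.table::setorder(out, position)
  out <- as.data.frame(out)
  attr(out, "interior_bins_per_side") <- budget
  out
}

#' Relative positions of sites or midpoints over their features
#'
#' Scales each item's position to `[0, 1]` within its feature (`(x - start)
#' / (end - start)`), mirroring minus-strand features so 0 is always the 5'
#' end, and bins the occurrences.
#'
#' @param features interval data.frame with `id` (and optionally `strand`).
#' @param items data.frame with `feature_id` and either `pos` (a site) or
#'   `start`/`end` (a region whose midpoint is used).
#' @param n_bins histogram bins over `[0, 1]`.
#' @return list with `positions` (numeric vector, one per item) and
#'   `histogram` (data.frame `bin_lo`, `bin_hi`, `count`; counts sum to the
#'   number of items).
#' @export
relative_positions <- function(features, items, n_bins = 20L) {
  fi <- match(items$feature_id, features$id)
  if (anyNA(fi)) stop("unknown feature_id in items")
  x <- if (!is.null(items$pos)) items$pos else
    (items$start + items$end) / 2
  s <- features$start[fi]
  e <- features$end[fi]
  if (any(x < s | x > e)) {
    stop("site or midpoint outside its feature")
  }
  rel <- (x - s) / (e - s)
  str <- features$strand[fi] %||% rep("+", length(fi))
  rel <- ifelse(str == "-", 1 - rel, rel)
  br <- seq(0, 1, length.out = n_bins + 1)
  cuts <- pmin(pmax(findInterval(rel, br, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(cuts, nbins = n_bins)
  list(positions = rel,
       histogram = data.frame(bin_lo = br[-length(br)], bin_hi = br[-1],
                              count = counts))
}
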