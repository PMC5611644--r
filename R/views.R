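# Chromosome-scale stage comparisons, saturated-CHH-site catalogues, and
# the DMR methylation heat matrix with deterministic clustering order.

#' Chromosome-scale stage ratio profile
#'
#' Pools methylation counts of one context into large windows (default
#' 100 kb) for two stages and reports the per-window ratio
#' `level_a / (level_b + pseudocount)` (or the difference `level_a -
#' level_b` with `mode = "difference"`), plus a least-squares polynomial
#' trend over window midpoints. Degree 1 is a literal regression line;
#' the default degree 3 can follow a pericentromeric bump.
#'
#' @param m_a,m_b two [methylome()] objects.
#' @param context `CG`, `CHG` or `CHH`.
#' @param window window width in bp (default 1e5).
#' @param pseudocount added to the denominator level in ratio mode.
#' @param degree polynomial degree of the trend (reduced automatically when
#'   there are too few windows).
#' @param mode `"ratio"` or `"difference"`.
#' @param chrom_lengths optional named chromosome lengths for full tiling.
#' @return data.frame `chrom`, `start`, `end`, `level_a`, `level_b`,
#'   `value`, `trend`.
#' @export
chrom_profile <- function(m_a, m_b, context, window = 100000L,
                          pseudocount = 0.001, degree = 3L,
                          mode = c("ratio", "difference"),
                          chrom_lengths = NULL) {
  mode <- match.arg(mode)
  wa <- tile_windows(m_a, context, window, chrom_lengths)
  wb <- tile_windows(m_b, context, window, chrom_lengths)
  if (!is.null(chrom_lengths) && any(window > unlist(chrom_lengths))) {
    warning("window larger than a chromosome: single window emitted")
  }
  key <- c("chrom", "start", "end")
  j <- merge(wa[, c(key, "level")], wb[, c(key, "level")], by = key,
             all = TRUE, suffixes = c("_a", "_b"))
  j <- j[order(j$chrom, j$start), , drop = FALSE]
  j$value <- if (mode == "ratio") {
    j$level_a / (j$level_b + pseudocount)
  } else {
    j$level_a - j$level_b
  }
  j$trend <- NA_real_
  for (ch in unique(j$chrom)) {
    ok <- j$chrom == ch & !is.na(j$value)
    n <- sum(ok)
    if (n >= 2) {
      deg <- min(degree, n - 1)
      mid <- (j$start[ok] + j$end[ok]) / 2
      fit <- lm(j$value[ok] ~ poly(mid, deg))
      j$trend[ok] <- as.numeric(predict(fit))
    }
  }
  rownames(j) <- NULL
  j
}

#' Catalogue saturated CHH sites
#'
#' Saturated sites are individual CHH cytosines whose every covering read
#' reports methylation (level exactly 1, i.e. `n_unmeth = 0`) with coverage
#' of at least `min_cov`. Optionally associates each site with the TE(s) it
#' falls in.
#'
#' @param m a [methylome()].
#' @param min_cov minimum coverage for a site to be trusted as saturated
#'   (default 5; a 100% level on one or two reads is not evidence of
#'   saturation).
#' @param tes optional TE annotation data.frame for association.
#' @return data.frame `chrom`, `pos`, `strand`, `coverage`, `te_id`
#'   (comma-separated or `NA`).
#' @export
find_saturated_chh <- function(m, min_cov = 5L, tes = NULL) {
  if (min_cov < 1) stop("min_cov must be >= 1")
  sel <- m$context == "CHH" & m$n_unmeth == 0L & m$n_meth >= min_cov
  out <- data.frame(chrom = m$chrom[sel], pos = m$pos[sel],
                    strand = m$strand[sel], coverage = m$n_meth[sel],
                    te_id = NA_character_)
  if (!is.null(tes) && nrow(tes) && nrow(out)) {
    hits <- .overlap_hits(data.frame(chrom = out$chrom, start = out$pos,
                                     end = out$pos + 1L), tes)
    if (nrow(hits)) {
      ids <- hits[, .(te_id = paste(tes$id[subject], collapse = ",")),
                  by = .(query)]
      out$te_id[ids$query] <- ids$te_id
    }
  }
  rownames(out) <- NULL
  out
}

#' DMR methylation heat matrix across stages
#'
#' One row per DMR, one column per stage x context; each cell is the
#' unweighted mean of per-site levels of covered cytosines of that context
#' overlapping the DMR (deliberately not the pooled ratio: every covered
#' cytosine contributes equally). Rows with any undefined cell — a DMR with
#' no covered cytosine of some context in some stage — are dropped and
#' counted in `attr(, "n_dropped")`.
#'
#' @param dmrs DMR data.frame (`chrom`, `start`, `end`).
#' @param stage_methylomes named list of [methylome()] objects (>= 2).
#' @param contexts contexts to include as column groups.
#' @return numeric matrix with columns `<stage>.<context>`, rownames
#'   `chrom:start-end`; attributes `n_dropped` and `dmrs` (the kept rows).
#' @export
build_heat_matrix <- function(dmrs, stage_methylomes,
                              contexts = c("CG", "CHG", "CHH")) {
  if (nrow(dmrs) == 0) stop("no DMRs supplied")
  if (length(stage_methylomes) < 2) stop("need at least two stages")
  .check_context(contexts)
  cols <- as.vector(outer(names(stage_methylomes), contexts, paste, sep = "."))
  mat <- matrix(NA_real_, nrow = nrow(dmrs), ncol = length(cols),
                dimnames = list(paste0(dmrs$chrom, ":", dmrs$start, "-",
                                       dmrs$end), cols))
  reg <- data.frame(chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end)
  for (st in names(stage_methylomes)) {
    m <- stage_methylomes[[st]]
    covd <- m$n_meth + m$n_unmeth > 0
    for (ctx in contexts) {
      sel <- covd & m$context == ctx
      pts <- data.frame(chrom = m$chrom[sel], start = m$pos[sel],
                        end = m$pos[sel] + 1L)
      lev <- m$n_meth[sel] / (m$n_meth[sel] + m$n_unmeth[sel])
      hits <- .overlap_hits(pts, reg)
      if (nrow(hits)) {
        means <- hits[, .(v = mean(lev[query])), by = .(subject)]
        mat[means$subject, paste0(st, ".", ctx)] <- means$v
      }
    }
  }
  keep <- !apply(is.na(mat), 1, any)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("every DMR lacks coverage in some stage/context")
  if (n_dropped > 0) {
    message(sprintf("build_heat_matrix: %d of %d DMRs dropped (uncovered in >=1 stage)",
                    n_dropped, nrow(dmrs)))
  }
  out <- mat[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "dmrs") <- dmrs[keep, , drop = FALSE]
  out
}

#' Deterministic row order by complete-linkage clustering on CG columns
#'
#' Rows are clustered by complete-linkage agglomeration with Manhattan
#' distance computed on the CG columns only; the other contexts follow the
#' same permutation. The leaf order is made deterministic: at every merge
#' the child subtrees are ordered by size (smaller first) and ties are
#' broken by the lexicographically smallest member row of each subtree, so
#' permuting the input rows leaves the ordered matrix content unchanged
#' (when rows are distinct; duplicated rows are interchangeable anyway).
#'
#' @param mat heat matrix from [build_heat_matrix()] (or any numeric matrix).
#' @param use_pattern regular expression selecting the anchor columns
#'   (default: columns ending in `.CG`; when nothing matches, all columns
#'   are used).
#' @return integer vector: row indices in display order.
#' @export
cluster_rows <- function(mat, use_pattern = "\\.CG$") {
  anchor_cols <- grep(use_pattern, colnames(mat) %||% character(0))
  cg <- if (length(anchor_cols)) mat[, anchor_cols, drop = FALSE] else mat
  if (anyNA(cg)) stop("anchor (CG) columns contain NA; filter rows first")
  n <- nrow(cg)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(cg, method = "manhattan"),
                      method = "complete")
  members <- vector("list", n - 1)
  reps <- vector("list", n - 1)   # lexicographically smallest member row
  get <- function(idx) {
    if (idx < 0) list(members = -idx, rep = cg[-idx, ]) else
      list(members = members[[idx]], rep = reps[[idx]])
  }
  for (i in seq_len(n - 1)) {
    l <- get(hc$merge[i, 1])
    r <- get(hc$merge[i, 2])
    swap <- FALSE
    if (length(l$members) != length(r$members)) {
      swap <- length(l$members) > length(r$members)
    } else {
      swap <- .lex_cmp(l$rep, r$rep) > 0
    }
    if (swap) { tmp <- l; l <- r; r <- tmp }
    members[[i]] <- c(l$members, r$members)
    reps[[i]] <- if (.lex_cmp(l$rep, r$rep) <= 0) l$rep else r$rep
  }
  members[[n - 1]]
}

#' Order a heat matrix by [cluster_rows()]
#' @param mat heat matrix.
#' @inheritParams cluster_rows
#' @return the matrix with rows permuted into display order.
#' @export
order_heat_matrix <- function(mat, use_pattern = "\\.CG$") {
  mat[cluster_rows(mat, use_pattern), , drop = FALSE]
}
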