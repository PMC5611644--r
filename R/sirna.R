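# Small-RNA size-class selection and library-normalised abundance (RPM)
# over region sets, with a two-sample location test for group comparisons.

#' Select a small-RNA size class
#'
#' @param reads data.frame with a `length` column (nt).
#' @param size_class `"24"` (24 nt) or `"21-22"` (21--22 nt).
#' @return the reads of that class.
#' @export
select_size_class <- function(reads, size_class = c("24", "21-22")) {
  size_class <- match.arg(size_class)
  keep <- if (size_class == "24") reads$length == 24L else
    reads$length %in% c(21L, 22L)
  reads[keep, , drop = FALSE]
}

#' Reads-per-million abundance over regions
#'
#' Counts reads overlapping each region by at least 1 bp (each read counts
#' once per region it overlaps; half-open intervals, so an abutting read
#' does not count) and normalises by the total mapped library size — all
#' mapped reads, not the size-class subtotal.
#'
#' @param reads read data.frame (`chrom`, `start`, `end`).
#' @param regions region data.frame (`chrom`, `start`, `end`).
#' @param library_total total mapped reads in the library.
#' @return `regions` with `raw_count` and `rpm` columns.
#' @export
quantify_regions <- function(reads, regions, library_total) {
  if (library_total <= 0) stop("library_total must be positive")
  regions$raw_count <- rep(0L, nrow(regions))
  if (nrow(regions) == 0) return(regions)
  if (nrow(reads)) {
    hits <- .overlap_hits(reads, regions)
    if (nrow(hits)) {
      cnt <- hits[, .N, by = .(subject)]
      regions$raw_count[cnt$subject] <- cnt$N
    }
  }
  regions$rpm <- regions$raw_count * 1e6 / library_total
  regions
}

#' Two-sample comparison of region abundances
#'
#' Two-sided Student's t-test (pooled variance by default; Welch with
#' `var_equal = FALSE`) on RPM values, with box-plot-style group summaries.
#'
#' @param rpm_a,rpm_b numeric RPM vectors, or data.frames with an `rpm`
#'   column (as from [quantify_regions()]). Each group needs at least two
#'   values.
#' @param var_equal pool variances (classical Student's t)?
#' @return list with `t`, `df`, `p_value`, and a `summary` data.frame of
#'   per-group n, mean, quartiles.
#' @export
compare_groups <- function(rpm_a, rpm_b, var_equal = TRUE) {
  take <- function(x) if (is.data.frame(x)) x$rpm else as.numeric(x)
  a <- take(rpm_a); b <- take(rpm_b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least two values (variance undefined otherwise)")
  }
  tt <- t.test(a, b, var.equal = var_equal)
  summ <- do.call(rbind, lapply(list(a = a, b = b), function(x) {
    q <- quantile(x, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(n = length(x), mean = mean(x), min = q[1], q25 = q[2],
               median = q[3], q75 = q[4], max = q[5])
  }))
  summ$group <- c("a", "b")
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, summary = summ)
}
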