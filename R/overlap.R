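# Annotation-set overlap: Venn counts, representation factor (observed /
# expected overlap under independence) and hypergeometric significance.

#' Annotation id sets touched by two region lists
#'
#' Collects the distinct annotation ids associated with each region list
#' (via [associate_annotations()]), restricted to the universe of
#' annotations of the compared kind.
#'
#' @param regions_a,regions_b region data.frames with an `annotation`
#'   column.
#' @param universe_annotations annotation data.frame defining the universe
#'   (all annotations of the queried kind, e.g. every TE model).
#' @return list `set_a`, `set_b` (character id vectors), `n_universe`.
#' @export
annotation_sets <- function(regions_a, regions_b, universe_annotations) {
  if (nrow(universe_annotations) == 0) stop("annotation universe is empty")
  universe <- unique(universe_annotations$id)
  touched <- function(regions) {
    if (is.null(regions$annotation)) {
      stop("regions must carry an 'annotation' column; ",
           "run associate_annotations() first")
    }
    ids <- unlist(strsplit(regions$annotation, ",", fixed = TRUE))
    intersect(unique(ids[ids != "intergenic"]), universe)
  }
  list(set_a = touched(regions_a), set_b = touched(regions_b),
       n_universe = length(universe))
}

#' Representation factor with hypergeometric significance
#'
#' `rf = n_overlap / expected` where `expected = n_set1 * n_set2 /
#' n_universe` is the overlap expected if the two sets were drawn
#' independently from the universe. RF > 1 means the overlap is higher than
#' random, RF < 1 lower. Significance is the one-sided hypergeometric tail
#' matched to the direction: `P(X >= n_overlap)` when RF >= 1, `P(X <=
#' n_overlap)` otherwise, with `X ~ Hypergeom(n_universe, n_set1, n_set2)`.
#'
#' @param n_universe universe size.
#' @param n_set1,n_set2 set sizes.
#' @param n_overlap observed intersection size.
#' @return list of class `overlap_result`: the four inputs plus `expected`,
#'   `rf`, `p_value`.
#' @export
representation_factor <- function(n_universe, n_set1, n_set2, n_overlap) {
  stopifnot(n_universe >= 1, n_set1 >= 0, n_set2 >= 0, n_overlap >= 0,
            n_set1 <= n_universe, n_set2 <= n_universe)
  if (n_overlap > min(n_set1, n_set2)) {
    stop("n_overlap exceeds the smaller set")
  }
  if (n_overlap < n_set1 + n_set2 - n_universe) {
    stop("n_overlap below the minimum forced by the universe size")
  }
  expected <- n_set1 * n_set2 / n_universe
  rf <- if (expected > 0) n_overlap / expected else NA_real_
  p <- if (is.na(rf) || rf >= 1) {
    phyper(n_overlap - 1, n_set1, n_universe - n_set1, n_set2,
           lower.tail = FALSE)
  } else {
    phyper(n_overlap, n_set1, n_universe - n_set1, n_set2)
  }
  structure(list(n_universe = n_universe, n_set1 = n_set1, n_set2 = n_set2,
                 n_overlap = n_overlap, expected = expected, rf = rf,
                 p_value = p),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of (%d x %d) in universe %d; expected %.3f, RF = %.3f, p = %.3g\n",
    x$n_overlap, x$n_set1, x$n_set2, x$n_universe, x$expected, x$rf,
    x$p_value))
  invisible(x)
}

#' Overlap enrichment between two annotated region lists
#'
#' Convenience wrapper: [annotation_sets()] then [representation_factor()]
#' on the id-set sizes.
#'
#' @inheritParams annotation_sets
#' @return an `overlap_result`.
#' @export
overlap_test <- function(regions_a, regions_b, universe_annotations) {
  s <- annotation_sets(regions_a, regions_b, universe_annotations)
  representation_factor(s$n_universe, length(s$set_a), length(s$set_b),
                        length(intersect(s$set_a, s$set_b)))
}

#' Two- or three-set Venn counts over annotation ids
#'
#' @param sets named list of 2 or 3 character id vectors.
#' @return data.frame of region membership patterns and counts.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) %in% c(2L, 3L))
  ids <- unique(unlist(sets))
  member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(r) paste(ifelse(r, "1", "0"),
                                                collapse = ""))
  tab <- table(pattern)
  data.frame(pattern = names(tab), count = as.integer(tab))
}
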