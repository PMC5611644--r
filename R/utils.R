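# Internal helpers: coordinate conversion, seeding, validation.

CONTEXTS <- c("CG", "CHG", "CHH")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Convert an internal 0-based half-open interval table to GRanges (1-based
# closed) for overlap machinery only; never exposed to callers.
#' @noRd
.as_gr <- function(df, strand = NULL) {
  s <- if (is.null(strand)) "*" else ifelse(strand %in% c("+", "-"), strand, "*")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = s
  )
}

# Point positions (0-based) to width-1 GRanges.
#' @noRd
.pos_gr <- function(chrom, pos) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, pos + 1L))
}

# Overlap hits (>= 1 bp) between two 0-based half-open interval tables.
# Returns a data.table(query, subject).
#' @noRd
.overlap_hits <- function(query, subject) {
  h <- GenomicRanges::findOverlaps(.as_gr(query), .as_gr(subject))
  data.table::data.table(
    query = S4Vectors::queryHits(h),
    subject = S4Vectors::subjectHits(h)
  )
}

# Stable 31-bit hash of a string mixed with the master seed, so each labelled
# substream (stage, genome, sirna, ...) draws independently and adding one
# stream never perturbs another.
#' @noRd
.substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 2147483647
  as.integer((h + (seed %% 2147483647) * 10007) %% 2147483647)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @noRd
.check_context <- function(context) {
  if (!all(context %in% CONTEXTS)) {
    bad <- setdiff(unique(context), CONTEXTS)
    stop("unknown methylation context: ", paste(bad, collapse = ", "),
         " (expected CG, CHG or CHH)", call. = FALSE)
  }
  invisible(context)
}

# Lexicographic comparison of two numeric vectors: -1, 0 or 1.
#' @noRd
.lex_cmp <- function(x, y) {
  n <- min(length(x), length(y))
  for (i in seq_len(n)) {
    if (x[i] < y[i]) return(-1L)
    if (x[i] > y[i]) return(1L)
  }
  sign(length(x) - length(y))
}
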