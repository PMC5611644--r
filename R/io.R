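# Readers/writers for cytosine reports, annotations, small-RNA tables and
# region (BED6) output, plus the stage_methylome constructor.
#
# Internal convention: all intervals are 0-based half-open; per-cytosine
# positions are stored 0-based. 1-based formats (cytosine report, GFF3) are
# converted here, at the I/O boundary, and nowhere else.

#' Construct a stage methylome from per-cytosine counts
#'
#' A stage methylome is a data.frame of per-cytosine methylation calls for
#' one developmental stage (or genotype), with columns `chrom`, `pos`
#' (0-based), `strand` (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `n_meth` and
#' `n_unmeth` (read counts supporting methylated C and converted T), sorted
#' by `(chrom, pos)`. Strands are kept separate; symmetric CG collapsing is
#' not performed, so counts stay auditable against the input report.
#'
#' @param df data.frame with the columns above (`pos` 0-based).
#' @param stage stage label, e.g. `"mature_embryo"`.
#' @return A `stage_methylome` (data.frame) sorted by `(chrom, pos)`.
#' @export
methylome <- function(df, stage = NA_character_) {
  req <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  dt <- data.table::as.data.table(df)[, req, with = FALSE]
  dt[, `:=`(chrom = as.character(chrom), pos = as.integer(pos),
            strand = as.character(strand), context = as.character(context),
            n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth))]
  .check_context(dt$context)
  if (!all(dt$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(dt$n_meth < 0L) || any(dt$n_unmeth < 0L)) {
    stop("read counts must be non-negative")
  }
  if (anyDuplicated(dt, by = c("chrom", "pos", "strand"))) {
    d <- dt[duplicated(dt, by = c("chrom", "pos", "strand"))][1]
    stop(sprintf("duplicate cytosine record at %s:%d(%s)",
                 d$chrom, d$pos, d$strand))
  }
  data.table::setorder(dt, chrom, pos, strand)
  out <- as.data.frame(dt)
  class(out) <- c("stage_methylome", "data.frame")
  attr(out, "stage") <- stage
  out
}

#' Read a Bismark-style cytosine report
#'
#' Parses a tab-separated cytosine report with columns chromosome, position
#' (1-based), strand, methylated count, unmethylated count, context (and an
#' optional trinucleotide column, which is ignored). Positions are converted
#' to the package's 0-based convention.
#'
#' @param path path to the TSV file.
#' @param min_coverage minimum read coverage (`n_meth + n_unmeth`) for a
#'   record to be kept; default 1 drops uncovered positions. Stage-specific
#'   coverage filters (e.g. the DMR caller's 10--100x gate) are applied by
#'   the callers, not here.
#' @param stage stage label attached to the result.
#' @return A [methylome()] object.
#' @export
read_cytosine_report <- function(path, min_coverage = 1L, stage = NA_character_) {
  if (min_coverage < 0) stop("min_coverage must be >= 0")
  raw <- data.table::fread(path, header = FALSE, sep = "\t",
                           colClasses = "character", fill = TRUE)
  if (nrow(raw) == 0) return(methylome(data.frame(
    chrom = character(), pos = integer(), strand = character(),
    context = character(), n_meth = integer(), n_unmeth = integer()),
    stage = stage))
  if (ncol(raw) < 6) stop("cytosine report needs >= 6 tab-separated columns")
  pos1 <- suppressWarnings(as.integer(raw[[2]]))
  nm <- suppressWarnings(as.integer(raw[[4]]))
  nu <- suppressWarnings(as.integer(raw[[5]]))
  bad <- which(is.na(pos1) | is.na(nm) | is.na(nu) | raw[[1]] == "" |
                 nm < 0 | nu < 0 | pos1 < 1)
  if (length(bad)) {
    stop(sprintf("malformed cytosine-report line %d in %s", bad[1], path))
  }
  ctx <- raw[[6]]
  badctx <- which(!ctx %in% CONTEXTS)
  if (length(badctx)) {
    stop(sprintf("unknown context '%s' at line %d in %s",
                 ctx[badctx[1]], badctx[1], path))
  }
  badstr <- which(!raw[[3]] %in% c("+", "-"))
  if (length(badstr)) {
    stop(sprintf("invalid strand '%s' at line %d in %s",
                 raw[[3]][badstr[1]], badstr[1], path))
  }
  df <- data.frame(chrom = raw[[1]], pos = pos1 - 1L, strand = raw[[3]],
                   context = ctx, n_meth = nm, n_unmeth = nu)
  df <- df[df$n_meth + df$n_unmeth >= min_coverage, , drop = FALSE]
  message(sprintf("read_cytosine_report: %d records kept from %s", nrow(df), path))
  methylome(df, stage = stage)
}

#' Write a stage methylome as a cytosine report
#'
#' Inverse of [read_cytosine_report()]: writes the 1-based six-column TSV
#' dialect, so read -> write -> read round-trips losslessly.
#'
#' @param m a [methylome()] object.
#' @param path output path.
#' @export
write_cytosine_report <- function(m, path) {
  dt <- data.table::data.table(m$chrom, m$pos + 1L, m$strand,
                               m$n_meth, m$n_unmeth, m$context)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene/TE/pericentromere annotations from BED or GFF3
#'
#' BED input (0-based half-open) is taken as-is; GFF3 (1-based inclusive) is
#' converted to the internal 0-based half-open convention. The feature kind
#' (gene, TE, pericentromere, ...) is supplied by the caller, not inferred.
#'
#' @param path `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @param kind label recorded in the `kind` column (e.g. `"TE"`).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `kind`, `id`, `strand`, sorted within each chromosome.
#' @export
read_annotations <- function(path, kind = "other") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0(kind, "_", seq_along(gr))
  } else if (ext %in% c("gff", "gff3", "gtf")) {
    gr <- rtracklayer::import(path, format = if (ext == "gtf") "GTF" else "GFF3")
    ids <- as.character(gr$ID %||% gr$Name %||% paste0(kind, "_", seq_along(gr)))
    ids[is.na(ids)] <- paste0(kind, "_", which(is.na(ids)))
  } else {
    stop("unknown annotation format: .", ext, " (expected BED or GFF3)")
  }
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    kind = kind,
    id = ids,
    strand = as.character(GenomicRanges::strand(gr))
  )
  if (any(out$end <= out$start)) {
    i <- which(out$end <= out$start)[1]
    stop(sprintf("empty or inverted interval %s:[%d,%d) in %s",
                 out$chrom[i], out$start[i], out$end[i], path))
  }
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("read_annotations: %d %s intervals from %s",
                  nrow(out), kind, path))
  out
}

#' Write annotation intervals as BED6 (internal convention is already BED's)
#' @param annotations data.frame as from [read_annotations()].
#' @param path output path.
#' @export
write_annotations <- function(annotations, path) {
  st <- annotations$strand %||% rep(".", nrow(annotations))
  st[!st %in% c("+", "-")] <- "."
  dt <- data.table::data.table(annotations$chrom, annotations$start,
                               annotations$end, annotations$id, 0L, st)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write MRs or DMRs as BED6
#'
#' The name column encodes context plus direction (`CHH_hyper`, `CG_MR`,
#' ...); the score is the mean absolute methylation difference (DMRs) or
#' mean level (MRs) scaled by 1000 and capped at 1000, per the BED score
#' convention.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `context`, and
#'   either `direction` + `mean_diff` (DMRs) or `level` (MRs).
#' @param path output path.
#' @export
write_regions <- function(regions, path) {
  if (nrow(regions) == 0) {
    file.create(path)
    return(invisible(path))
  }
  name <- if (!is.null(regions$direction)) {
    paste0(regions$context, "_", regions$direction)
  } else {
    paste0(regions$context, "_MR")
  }
  val <- if (!is.null(regions$mean_diff)) abs(regions$mean_diff) else
    regions$level %||% rep(0, nrow(regions))
  score <- pmin(1000L, as.integer(round(val * 1000)))
  dt <- data.table::data.table(regions$chrom, regions$start, regions$end,
                               name, score, ".")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED6 region file written by [write_regions()]
#' @param path BED6 path.
#' @return data.frame with `chrom`, `start`, `end`, `context`, `direction`
#'   (`NA` for MRs), `score`.
#' @export
read_regions <- function(path) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      score = integer())
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (nrow(dt) == 0) return(empty)
  parts <- data.table::tstrsplit(dt[[4]], "_", fixed = TRUE)
  data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
             end = as.integer(dt[[3]]),
             context = as.character(parts[[1]]),
             direction = ifelse(parts[[2]] == "MR", NA_character_,
                                as.character(parts[[2]])),
             score = as.integer(dt[[5]]))
}

#' Read a small-RNA read table
#'
#' Accepts a BED3-like TSV (`chrom`, `start`, `end`, 0-based half-open);
#' read length is `end - start`. Reads outside the 18--30-nt small-RNA range
#' are dropped at read-in.
#'
#' @param path TSV/BED path.
#' @param length_range inclusive length bounds kept, default `c(18, 30)`.
#' @return data.frame `chrom`, `start`, `end`, `length`.
#' @export
read_sirna_reads <- function(path, length_range = c(18L, 30L)) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop("small-RNA table needs >= 3 columns")
  out <- data.frame(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
                    end = as.integer(dt[[3]]))
  if (any(out$end <= out$start)) stop("small-RNA read with end <= start")
  out$length <- out$end - out$start
  kept <- out$length >= length_range[1] & out$length <= length_range[2]
  message(sprintf("read_sirna_reads: %d/%d reads in [%d,%d] nt",
                  sum(kept), nrow(out), length_range[1], length_range[2]))
  out[kept, , drop = FALSE]
}

#' Write a small-RNA read table (BED3)
#' @param reads data.frame `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_sirna_reads <- function(reads, path) {
  data.table::fwrite(reads[, c("chrom", "start", "end")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Coverage and methylation level helpers
#'
#' `site_coverage()` is `n_meth + n_unmeth`; `site_level()` is
#' `n_meth / coverage`, `NaN` where coverage is zero.
#'
#' @param m a [methylome()] object.
#' @return numeric vector, one value per record.
#' @export
site_coverage <- function(m) m$n_meth + m$n_unmeth

#' @rdname site_coverage
#' @export
site_level <- function(m) m$n_meth / (m$n_meth + m$n_unmeth)

#' @export
print.stage_methylome <- function(x, ...) {
  cat(sprintf("stage_methylome '%s': %d cytosines on %d chromosome(s)\n",
              attr(x, "stage"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) {
    tab <- table(x$context)
    cat("  contexts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}
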