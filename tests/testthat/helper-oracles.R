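# Independent oracles used to freeze/verify expected values. These share no
# code with the implementation paths they check: point probabilities come
# from lchoose(), not dhyper(); BH selection is the classical step-up rule,
# not p.adjust().

# Two-sided Fisher exact p for table (a, b; c, d) by direct hypergeometric
# enumeration: sum the point probabilities of every table with the same
# margins that is at most as probable as the observed one.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(r1 + r2, c1)
  probs <- exp(logp)
  obs <- probs[match(a, xs)]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Vectorised version for exhaustive sweeps.
fisher_oracle_vec <- function(a, b, c, d) {
  mapply(fisher_oracle, a, b, c, d)
}

# Classical BH step-up selection: reject the i smallest p-values where i is
# the largest index with p_(i) <= i * alpha / m. Returns a logical vector in
# input order.
stepup_select <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * alpha / m)
  sel <- logical(m)
  if (length(ok)) sel[o[seq_len(max(ok))]] <- TRUE
  sel
}

# Hypergeometric tail probabilities by enumeration over the whole support.
hyper_tail_oracle <- function(k, N, n1, n2, upper = TRUE) {
  xs <- max(0, n1 + n2 - N):min(n1, n2)
  probs <- exp(lchoose(n1, xs) + lchoose(N - n1, n2 - xs) - lchoose(N, n2))
  if (upper) sum(probs[xs >= k]) else sum(probs[xs <= k])
}

# Small hand-built methylome: positions 0-based.
make_methylome <- function(pos, n_meth, n_unmeth, context = "CHH",
                           chrom = "Chr1", strand = "+", stage = "test") {
  n <- length(pos)
  methylome(data.frame(
    chrom = rep_len(chrom, n), pos = pos, strand = rep_len(strand, n),
    context = rep_len(context, n), n_meth = n_meth, n_unmeth = n_unmeth),
    stage = stage)
}

# A two-stage null/planted configuration on a featureless chromosome:
# uniform background methylation, optionally with planted DMRs.
flat_two_stage_config <- function(seed, chrom_length, p_chh = 0.1,
                                  planted = NULL, coverage_mean = 20) {
  prof <- rbind(CG = rep(0.5, 4), CHG = rep(0.2, 4), CHH = rep(p_chh, 4))
  colnames(prof) <- c("te_edge", "te_interior", "gene_body", "background")
  sim_config(seed = seed, n_chroms = 1, chrom_length = chrom_length,
             pericentromere_fraction = 0, n_tes = 0, n_genes = 0,
             coverage_mean = coverage_mean,
             stage_profiles = list(stage_a = prof, stage_b = prof),
             peri_chh_boost = c(stage_a = 0),
             planted_dmrs = planted, n_saturated = 0,
             saturated_stage = "none")
}

# Random non-overlapping intervals with lengths in [len_lo, len_hi].
random_intervals <- function(n, chrom_length, len_lo, len_hi, seed,
                             chrom = "Chr1") {
  set.seed(seed)
  lens <- sample(len_lo:len_hi, n, replace = TRUE)
  gap <- floor((chrom_length - sum(lens)) / (n + 1))
  stopifnot(gap > 0)
  starts <- cumsum(c(sample(gap, 1), lens[-n] + sample(gap, n - 1, replace = TRUE)))
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(starts + lens))
}

# Base-pair overlap between two interval sets on one chromosome.
bp_overlap <- function(a, b) {
  cov <- rep(FALSE, max(a$end, b$end))
  for (i in seq_len(nrow(b))) cov[(b$start[i] + 1):b$end[i]] <- TRUE
  tot <- 0L
  for (i in seq_len(nrow(a))) tot <- tot + sum(cov[(a$start[i] + 1):a$end[i]])
  tot
}
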