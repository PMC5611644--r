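# Seeded synthetic-data generator: genome layout (TEs, genes,
# pericentromere), per-stage methylomes with compartment-specific true
# methylation probabilities, planted DMRs and saturated CHH sites, and
# siRNA reads enriched over planted targets. Every draw happens inside a
# labelled substream derived from the master seed, so outputs are
# bit-reproducible and adding a stage never changes another stage's data.

#' Default per-stage true methylation probabilities
#'
#' One matrix per stage, contexts (CG/CHG/CHH) x compartments (`te_edge`,
#' `te_interior`, `gene_body`, `background`). The defaults encode the
#' qualitative developmental dynamics the package targets: CG on TEs high
#' and stable at every stage; CHH on TEs low (~10%) in seedlings, the level
#' typically observed there, intermediate in early embryos and strongly
#' elevated (with fully methylated sites) in mature embryos, concentrated at
#' TE edges where RdDM acts; CHG intermediate and mildly dynamic.
#'
#' @return named list of 3x4 matrices.
#' @export
default_stage_profiles <- function() {
  mk <- function(cg, chg, chh) {
    m <- rbind(CG = cg, CHG = chg, CHH = chh)
    colnames(m) <- c("te_edge", "te_interior", "gene_body", "background")
    m
  }
  list(
    early_embryo  = mk(c(0.85, 0.85, 0.20, 0.05),
                       c(0.40, 0.40, 0.05, 0.02),
                       c(0.25, 0.25, 0.03, 0.02)),
    mature_embryo = mk(c(0.85, 0.85, 0.20, 0.05),
                       c(0.50, 0.50, 0.05, 0.02),
                       c(0.60, 0.45, 0.05, 0.03)),
    seedling_4d   = mk(c(0.85, 0.85, 0.20, 0.05),
                       c(0.35, 0.35, 0.05, 0.02),
                       c(0.10, 0.08, 0.02, 0.02)),
    seedling_10d  = mk(c(0.85, 0.85, 0.20, 0.05),
                       c(0.35, 0.35, 0.05, 0.02),
                       c(0.12, 0.10, 0.02, 0.02))
  )
}

#' Simulation configuration
#'
#' Defines a synthetic multi-stage bisulfite experiment: genome layout,
#' sequencing depth, per-stage/context/compartment true methylation
#' probabilities, planted DMRs and planted saturated CHH sites. The seed
#' fully determines every output.
#'
#' @param seed master integer seed.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param pericentromere_fraction fraction of each chromosome, centred at
#'   its midpoint, that is pericentromeric (TE-dense).
#' @param n_tes TEs per chromosome; `peri_te_fraction` of them fall inside
#'   the pericentromere, making it at least 3x denser than the arms at the
#'   defaults.
#' @param te_length_range,gene_length_range feature length bounds (bp).
#' @param n_genes genes per chromosome (chromosome arms only).
#' @param te_edge_width bp at each TE end treated as the `te_edge`
#'   compartment (canonical RdDM territory); the rest is `te_interior`.
#' @param coverage_mean expected reads per cytosine; coverage is Poisson
#'   with this mean, floored at 1.
#' @param cytosine_density cytosines per bp (both strands pooled).
#' @param context_weights relative genome frequency of CG/CHG/CHH sites;
#'   default puts CHH about five times more frequent than CG, as in a plant
#'   genome.
#' @param stage_profiles per-stage probability matrices, see
#'   [default_stage_profiles()].
#' @param peri_chh_boost named per-stage additive boost to CHH probabilities
#'   of TE compartments inside the pericentromere (early embryos gain CHH
#'   first in pericentromeric TE interiors).
#' @param planted_dmrs data.frame (`chrom`, `start`, `end`, `context`,
#'   `stage_a`, `stage_b`, `base_level`, `diff`): inside the interval the
#'   true probability is `base_level + diff` in `stage_a` and `base_level`
#'   in `stage_b`, overriding compartment profiles in those two stages only.
#' @param n_saturated number of CHH sites planted at true probability 1.0 in
#'   `saturated_stage` (preferring TE-edge sites).
#' @param saturated_stage stage carrying the saturated sites.
#' @param peri_te_fraction fraction of TEs placed inside the pericentromere.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1000000L,
                       pericentromere_fraction = 0.2,
                       n_tes = 80L,
                       te_length_range = c(500L, 6000L),
                       n_genes = 150L,
                       gene_length_range = c(1000L, 4000L),
                       te_edge_width = 200L,
                       coverage_mean = 20,
                       cytosine_density = 0.125,
                       context_weights = c(CG = 1, CHG = 1.5, CHH = 5),
                       stage_profiles = default_stage_profiles(),
                       peri_chh_boost = c(early_embryo = 0.10),
                       planted_dmrs = NULL,
                       n_saturated = 200L,
                       saturated_stage = "mature_embryo",
                       peri_te_fraction = 0.7) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              pericentromere_fraction = pericentromere_fraction,
              n_tes = as.integer(n_tes), te_length_range = as.integer(te_length_range),
              n_genes = as.integer(n_genes),
              gene_length_range = as.integer(gene_length_range),
              te_edge_width = as.integer(te_edge_width),
              coverage_mean = coverage_mean,
              cytosine_density = cytosine_density,
              context_weights = context_weights,
              stage_profiles = stage_profiles,
              peri_chh_boost = peri_chh_boost,
              planted_dmrs = planted_dmrs,
              n_saturated = as.integer(n_saturated),
              saturated_stage = saturated_stage,
              peri_te_fraction = peri_te_fraction)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(cfg$seed >= 0, cfg$n_chroms >= 1, cfg$chrom_length > 0,
            cfg$pericentromere_fraction >= 0, cfg$pericentromere_fraction < 1,
            cfg$coverage_mean > 0, cfg$cytosine_density > 0,
            cfg$cytosine_density <= 1,
            all(cfg$context_weights >= 0), sum(cfg$context_weights) > 0,
            cfg$peri_te_fraction >= 0, cfg$peri_te_fraction <= 1)
  for (st in names(cfg$stage_profiles)) {
    p <- cfg$stage_profiles[[st]]
    if (!all(rownames(p) == CONTEXTS)) stop("profile rows must be CG, CHG, CHH")
    if (any(p < 0) || any(p > 1)) stop("stage profile probabilities must be in [0,1]")
  }
  if (!is.null(cfg$planted_dmrs)) {
    pd <- cfg$planted_dmrs
    req <- c("chrom", "start", "end", "context", "stage_a", "stage_b",
             "base_level", "diff")
    if (!all(req %in% names(pd))) {
      stop("planted_dmrs needs columns: ", paste(req, collapse = ", "))
    }
    .check_context(pd$context)
    lv <- c(pd$base_level, pd$base_level + pd$diff)
    if (any(lv < 0) || any(lv > 1)) {
      stop("planted DMR levels (base_level, base_level + diff) must stay in [0,1]")
    }
    if (any(pd$start >= pd$end)) stop("planted DMR intervals must satisfy start < end")
    # same context + stage pair must not overlap
    key <- paste(pd$context, pd$stage_a, pd$stage_b)
    for (k in unique(key)) {
      sub <- pd[key == k, ]
      sub <- sub[order(sub$chrom, sub$start), ]
      same <- which(sub$chrom[-1] == sub$chrom[-nrow(sub)] &
                      sub$start[-1] < sub$end[-nrow(sub)])
      if (length(same)) stop("planted DMRs overlap for ", k)
    }
  }
  cfg
}

# Place k features of the given lengths without overlap inside [lo, hi),
# uniformly over admissible layouts (draw the free space split).
#' @noRd
.place_features <- function(lo, hi, lengths) {
  k <- length(lengths)
  if (k == 0) return(integer(0))
  total <- sum(lengths)
  free <- (hi - lo) - total
  if (free < 0) {
    stop("configuration error: requested features do not fit in the region")
  }
  cuts <- sort(sample.int(free + 1L, k, replace = TRUE) - 1L)
  starts <- lo + cuts + cumsum(c(0L, lengths[-k]))
  starts
}

#' Simulate genome layout and cytosine positions
#'
#' Lays out, per chromosome: a centred pericentromere, non-overlapping TEs
#' (denser inside the pericentromere), non-overlapping genes on the arms,
#' and cytosine sites with strand and context drawn at the configured
#' density (CHH most frequent). Planted saturated-CHH positions are chosen
#' here (TE-edge CHH sites preferred) so they are stable across stages.
#'
#' @param config a [sim_config()].
#' @return list with `annotations` (genes + TEs + pericentromere intervals),
#'   `sites` (chrom, pos, strand, context), `chrom_lengths` (named), and
#'   `saturated_sites`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream_seed(config$seed, "genome"), {
    chroms <- paste0("Chr", seq_len(config$n_chroms))
    len <- config$chrom_length
    annos <- list(); sites <- list()
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      peri_half <- floor(len * config$pericentromere_fraction / 2)
      mid <- len %/% 2L
      peri <- c(mid - peri_half, mid + peri_half)
      n_peri_te <- round(config$n_tes * config$peri_te_fraction)
      n_arm_te <- config$n_tes - n_peri_te
      te_len <- function(n) if (n > 0)
        sample(config$te_length_range[1]:config$te_length_range[2], n,
               replace = TRUE) else integer(0)
      gene_len <- function(n) if (n > 0)
        sample(config$gene_length_range[1]:config$gene_length_range[2], n,
               replace = TRUE) else integer(0)
      # pericentromeric TEs
      pl <- te_len(n_peri_te)
      peri_starts <- .place_features(peri[1], peri[2], pl)
      # arm features: arm TEs + genes share the two arms, split by count
      arm_te_l <- te_len(n_arm_te)
      gene_l <- gene_len(config$n_genes)
      arm_feats <- data.table::data.table(
        len2 = c(arm_te_l, gene_l),
        is_te = rep(c(TRUE, FALSE), c(length(arm_te_l), length(gene_l))))
      if (nrow(arm_feats)) {
        arm_feats <- arm_feats[sample.int(nrow(arm_feats)), ]
        n_left <- rbinom(1, nrow(arm_feats), peri[1] / (peri[1] + (len - peri[2])))
        left <- head(seq_len(nrow(arm_feats)), n_left)
        right <- setdiff(seq_len(nrow(arm_feats)), left)
        s_left <- .place_features(0L, peri[1], arm_feats$len2[left])
        s_right <- .place_features(peri[2], len, arm_feats$len2[right])
        arm_feats$start <- NA_integer_
        arm_feats$start[left] <- s_left
        arm_feats$start[right] <- s_right
      }
      te_starts <- c(peri_starts,
                     if (nrow(arm_feats)) arm_feats$start[arm_feats$is_te]
                     else integer(0))
      te_lengths <- c(pl,
                      if (nrow(arm_feats)) arm_feats$len2[arm_feats$is_te]
                      else integer(0))
      te_df <- data.frame(
        chrom = rep(ch, length(te_starts)), start = te_starts,
        end = te_starts + te_lengths, kind = rep("TE", length(te_starts)),
        id = rep(NA_character_, length(te_starts)),
        strand = sample(c("+", "-"), length(te_starts), replace = TRUE))
      ge_df <- if (nrow(arm_feats) && any(!arm_feats$is_te)) data.frame(
        chrom = ch, start = arm_feats$start[!arm_feats$is_te],
        end = arm_feats$start[!arm_feats$is_te] + arm_feats$len2[!arm_feats$is_te],
        kind = "gene", id = NA_character_,
        strand = sample(c("+", "-"), sum(!arm_feats$is_te), replace = TRUE))
      else NULL
      peri_df <- if (peri_half > 0) data.frame(
        chrom = ch, start = peri[1], end = peri[2], kind = "pericentromere",
        id = paste0(ch, "_peri"), strand = ".") else NULL
      an <- rbind(te_df, ge_df, peri_df)
      an <- an[order(an$start, an$end), , drop = FALSE]
      annos[[ci]] <- an
      # cytosine sites
      n_sites <- round(len * config$cytosine_density)
      pos <- sort(sample.int(len, n_sites)) - 1L
      w <- config$context_weights / sum(config$context_weights)
      sites[[ci]] <- data.frame(
        chrom = ch, pos = pos,
        strand = sample(c("+", "-"), n_sites, replace = TRUE),
        context = sample(CONTEXTS, n_sites, replace = TRUE,
                         prob = w[CONTEXTS]))
    }
    annotations <- do.call(rbind, annos)
    annotations$id[annotations$kind == "TE"] <-
      paste0("TE", seq_len(sum(annotations$kind == "TE")))
    annotations$id[annotations$kind == "gene"] <-
      paste0("G", seq_len(sum(annotations$kind == "gene")))
    rownames(annotations) <- NULL
    sites <- do.call(rbind, sites)
    rownames(sites) <- NULL
    # planted saturated CHH sites: prefer CHH sites in TE edges
    sat <- NULL
    if (config$n_saturated > 0) {
      tes <- annotations[annotations$kind == "TE", , drop = FALSE]
      edges <- rbind(
        data.frame(chrom = tes$chrom, start = tes$start,
                   end = pmin(tes$end, tes$start + config$te_edge_width)),
        data.frame(chrom = tes$chrom,
                   start = pmax(tes$start, tes$end - config$te_edge_width),
                   end = tes$end))
      chh <- sites[sites$context == "CHH", , drop = FALSE]
      hit <- .overlap_hits(data.frame(chrom = chh$chrom, start = chh$pos,
                                      end = chh$pos + 1L), edges)
      cand <- unique(hit$query)
      if (length(cand) < config$n_saturated) {
        # fall back to any CHH site inside a TE
        hit2 <- .overlap_hits(data.frame(chrom = chh$chrom, start = chh$pos,
                                         end = chh$pos + 1L), tes)
        cand <- unique(c(cand, hit2$query))
      }
      take <- sort(cand[sample.int(length(cand),
                                   min(config$n_saturated, length(cand)))])
      sat <- chh[take, c("chrom", "pos", "strand"), drop = FALSE]
      rownames(sat) <- NULL
    }
    list(annotations = annotations, sites = sites,
         chrom_lengths = setNames(rep(len, length(chroms)), chroms),
         saturated_sites = sat)
  })
}

# Compartment of each site: te_edge > te_interior > gene_body > background.
#' @noRd
.site_compartments <- function(sites, annotations, te_edge_width) {
  comp <- rep("background", nrow(sites))
  pts <- data.frame(chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L)
  genes <- annotations[annotations$kind == "gene", , drop = FALSE]
  if (nrow(genes)) comp[unique(.overlap_hits(pts, genes)$query)] <- "gene_body"
  tes <- annotations[annotations$kind == "TE", , drop = FALSE]
  if (nrow(tes)) {
    comp[unique(.overlap_hits(pts, tes)$query)] <- "te_interior"
    edges <- rbind(
      data.frame(chrom = tes$chrom, start = tes$start,
                 end = pmin(tes$end, tes$start + te_edge_width)),
      data.frame(chrom = tes$chrom,
                 start = pmax(tes$start, tes$end - te_edge_width),
                 end = tes$end))
    comp[unique(.overlap_hits(pts, edges)$query)] <- "te_edge"
  }
  comp
}

#' Simulate one stage's methylome
#'
#' Each cytosine's true methylation probability is looked up by (context,
#' compartment, stage), boosted in pericentromeric TE compartments where
#' configured, then overridden by planted DMRs (in their two stages) and by
#' planted saturated CHH sites (probability exactly 1 in the saturated
#' stage). Coverage is Poisson(`coverage_mean`) floored at 1; methylated
#' counts are Binomial(coverage, p).
#'
#' @param config a [sim_config()].
#' @param stage stage label, must be a name of `config$stage_profiles`.
#' @param genome result of [simulate_genome()].
#' @return a [methylome()] for the stage.
#' @export
simulate_stage <- function(config, stage, genome) {
  stopifnot(inherits(config, "sim_config"))
  if (!stage %in% names(config$stage_profiles)) {
    stop("unknown stage '", stage, "'; configured stages: ",
         paste(names(config$stage_profiles), collapse = ", "))
  }
  sites <- genome$sites
  comp <- .site_compartments(sites, genome$annotations, config$te_edge_width)
  prof <- config$stage_profiles[[stage]]
  p <- prof[cbind(match(sites$context, CONTEXTS), match(comp, colnames(prof)))]
  # pericentromeric CHH boost for TE compartments
  boost <- config$peri_chh_boost[stage]
  if (!is.na(boost) && boost != 0) {
    peri <- genome$annotations[genome$annotations$kind == "pericentromere", ,
                               drop = FALSE]
    if (nrow(peri)) {
      pts <- data.frame(chrom = sites$chrom, start = sites$pos,
                        end = sites$pos + 1L)
      in_peri <- unique(.overlap_hits(pts, peri)$query)
      sel <- intersect(in_peri, which(sites$context == "CHH" &
                                        comp %in% c("te_edge", "te_interior")))
      p[sel] <- pmin(1, p[sel] + boost)
    }
  }
  # planted DMR overrides
  pd <- config$planted_dmrs
  if (!is.null(pd)) {
    pts <- data.frame(chrom = sites$chrom, start = sites$pos,
                      end = sites$pos + 1L)
    for (i in seq_len(nrow(pd))) {
      if (!stage %in% c(pd$stage_a[i], pd$stage_b[i])) next
      hit <- .overlap_hits(pts, pd[i, c("chrom", "start", "end")])
      sel <- hit$query[sites$context[hit$query] == pd$context[i]]
      p[sel] <- if (stage == pd$stage_a[i]) pd$base_level[i] + pd$diff[i] else
        pd$base_level[i]
    }
  }
  # planted saturated CHH sites
  if (!is.null(genome$saturated_sites) && identical(stage, config$saturated_stage)) {
    key <- paste(sites$chrom, sites$pos, sites$strand)
    p[key %in% paste(genome$saturated_sites$chrom, genome$saturated_sites$pos,
                     genome$saturated_sites$strand)] <- 1
  }
  .with_seed(.substream_seed(config$seed, paste0("stage:", stage)), {
    cov <- pmax(1L, rpois(nrow(sites), config$coverage_mean))
    nm <- rbinom(nrow(sites), cov, p)
    methylome(data.frame(chrom = sites$chrom, pos = sites$pos,
                         strand = sites$strand, context = sites$context,
                         n_meth = nm, n_unmeth = cov - nm),
              stage = stage)
  })
}

#' Simulate a small-RNA library
#'
#' Generates 24-nt reads whose per-bp start rate is `enrichment_fold` times
#' higher inside the target intervals (by default the planted CHH-hyper DMR
#' intervals of the truth table) than elsewhere, plus a fraction of 21--22-nt
#' reads scattered uniformly. The returned object carries the library total
#' (all simulated mapped reads) for RPM normalisation.
#'
#' @param config a [sim_config()].
#' @param genome result of [simulate_genome()].
#' @param targets data.frame of enriched intervals (`chrom`, `start`,
#'   `end`); may be empty for a uniform library.
#' @param n_reads total mapped library size.
#' @param enrichment_fold per-bp rate ratio target vs background for 24-nt
#'   reads; the default 10 gives a clearly detectable RdDM-like signal.
#' @param frac_21_22 fraction of the library that is 21--22 nt.
#' @return data.frame `chrom`, `start`, `end`, `length` with attribute
#'   `library_total`.
#' @export
simulate_sirnas <- function(config, genome, targets,
                            n_reads = 200000L, enrichment_fold = 10,
                            frac_21_22 = 0.3) {
  stopifnot(enrichment_fold >= 1, frac_21_22 >= 0, frac_21_22 <= 1)
  .with_seed(.substream_seed(config$seed, "sirna"), {
    chroms <- names(genome$chrom_lengths)
    lens <- as.numeric(genome$chrom_lengths)
    total_bp <- sum(lens)
    n24 <- round(n_reads * (1 - frac_21_22))
    n2122 <- n_reads - n24
    tg <- if (!is.null(targets) && nrow(targets)) {
      data.frame(chrom = targets$chrom, start = targets$start, end = targets$end)
    } else data.frame(chrom = character(), start = integer(), end = integer())
    target_bp <- sum(tg$end - tg$start)
    # The background component is uniform over the whole genome (targets
    # included), so the extra target mass is (fold - 1) x target_bp: the
    # per-bp start rate inside targets is then exactly fold times the rate
    # outside.
    w_extra <- target_bp * (enrichment_fold - 1)
    w_bg <- total_bp
    k_target <- rbinom(1, n24, if (w_extra + w_bg > 0)
      w_extra / (w_extra + w_bg) else 0)
    k_bg <- n24 - k_target
    draw_uniform <- function(n, rlen) {
      ci <- sample.int(length(chroms), n, replace = TRUE, prob = lens)
      st <- floor(runif(n) * (lens[ci] - rlen))
      data.frame(chrom = chroms[ci], start = as.integer(st),
                 end = as.integer(st + rlen))
    }
    out <- list()
    if (k_target > 0) {
      widths <- tg$end - tg$start
      ti <- sample.int(nrow(tg), k_target, replace = TRUE, prob = widths)
      st <- tg$start[ti] + floor(runif(k_target) * pmax(1, widths[ti] - 24L))
      out$t24 <- data.frame(chrom = tg$chrom[ti], start = as.integer(st),
                            end = as.integer(st + 24L))
    }
    if (k_bg > 0) out$b24 <- draw_uniform(k_bg, 24L)
    r24 <- do.call(rbind, out)
    if (!is.null(r24)) r24$length <- 24L
    r2122 <- NULL
    if (n2122 > 0) {
      rl <- sample(c(21L, 22L), n2122, replace = TRUE)
      r2122 <- draw_uniform(n2122, rl)
      r2122$length <- rl
    }
    reads <- rbind(r24, r2122)
    reads <- reads[order(reads$chrom, reads$start), , drop = FALSE]
    rownames(reads) <- NULL
    attr(reads, "library_total") <- n_reads
    reads
  })
}

#' Run the whole generator and assemble the truth table
#'
#' Simulates the genome, one methylome per configured stage, and a
#' small-RNA library enriched over the planted mature-embryo CHH-hyper
#' intervals (falling back to TE edges when no DMRs are planted). The truth
#' table records what was planted: DMR intervals with signed true
#' difference, saturated-CHH positions, and the expected-MR intervals (TEs
#' whose configured probabilities clear the MR thresholds) per stage and
#' context.
#'
#' @param config a [sim_config()].
#' @param sirna_reads,sirna_fold,sirna_frac_21_22 passed to
#'   [simulate_sirnas()].
#' @return list with `genome`, `methylomes` (named by stage), `sirna`,
#'   `truth`, `config`.
#' @export
simulate_experiment <- function(config = sim_config(), sirna_reads = 200000L,
                                sirna_fold = 10, sirna_frac_21_22 = 0.3) {
  genome <- simulate_genome(config)
  stages <- names(config$stage_profiles)
  methylomes <- lapply(stages, function(st) simulate_stage(config, st, genome))
  names(methylomes) <- stages
  # truth: expected MRs = TEs whose configured TE probabilities clear the
  # MR threshold for the context at that stage
  thr <- c(CG = 0.40, CHG = 0.20, CHH = 0.10)
  tes <- genome$annotations[genome$annotations$kind == "TE", , drop = FALSE]
  exp_mrs <- list()
  for (st in stages) {
    prof <- config$stage_profiles[[st]]
    for (ctx in CONTEXTS) {
      if (min(prof[ctx, c("te_edge", "te_interior")]) >= thr[ctx] + 0.05) {
        exp_mrs[[paste(st, ctx)]] <- data.frame(
          stage = st, context = ctx, chrom = tes$chrom,
          start = tes$start, end = tes$end, id = tes$id)
      }
    }
  }
  pd <- config$planted_dmrs
  targets <- if (!is.null(pd)) {
    hyper <- pd[pd$diff > 0 & pd$context == "CHH" &
                  pd$stage_a == config$saturated_stage, , drop = FALSE]
    if (nrow(hyper)) hyper else pd[pd$diff > 0, , drop = FALSE]
  } else NULL
  if (is.null(targets) || nrow(targets) == 0) {
    targets <- data.frame(chrom = tes$chrom, start = tes$start,
                          end = pmin(tes$end, tes$start + config$te_edge_width))
  }
  sirna <- simulate_sirnas(config, genome, targets, n_reads = sirna_reads,
                           enrichment_fold = sirna_fold,
                           frac_21_22 = sirna_frac_21_22)
  truth <- list(
    planted_dmrs = pd,
    saturated_sites = genome$saturated_sites,
    expected_mrs = if (length(exp_mrs)) do.call(rbind, exp_mrs) else NULL,
    sirna_targets = targets
  )
  list(genome = genome, methylomes = methylomes, sirna = sirna,
       truth = truth, config = config)
}
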