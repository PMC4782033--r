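#' Synthetic scenario configuration
#'
#' Describes a fully synthetic study: a genome with planted perfect
#' tri-nucleotide tracts (foreground "disease" loci and background
#' loci), a gene model placing every locus in a known genic region, and
#' per-(assay, cell type) epigenetic maps in which each repeat is
#' covered according to its category's matching rule with a configurable
#' probability.  Ground truth (labels, match indicators, intended
#' distances) is recorded in a manifest so recovery can be verified
#' end to end.
#'
#' Repeats are laid out on a fixed grid of 13 kb slots, one repeat per
#' slot, so that marks placed for one repeat can never match or become
#' the nearest mark of another.  Non-matching repeats receive one
#' "distal" mark at a controlled center-to-center distance drawn
#' log-uniformly from 1.5-5 kb; for foreground loci that distance is
#' multiplied by `proximity_shift` (floored at 350 bp so a distal mark
#' can never satisfy any matching rule), which plants the proximity
#' effect probed by the distance test.
#'
#' @param seed Integer seed; the generator is deterministic given the
#'   full configuration.
#' @param n_chromosomes Number of chromosomes.
#' @param n_da_repeats,n_bg_repeats Foreground / background repeat
#'   counts.
#' @param unit_class_mix Named weights over canonical class labels
#'   (default: uniform over all 10 classes).
#' @param unit_count_range Range of planted unit counts; the lower bound
#'   must reach `min_units` so every planted tract is recoverable.
#' @param region_mix Named weights over `exon`, `intron`, `utr5`,
#'   `utr3`.
#' @param assays Assay names (subset of [assay_metadata()]).
#' @param n_cell_types Cell types per assay.
#' @param match_prob_da,match_prob_bg Per-(assay, cell type) probability
#'   that a map covers a foreground / background repeat per its matching
#'   rule.
#' @param proximity_shift Multiplicative factor applied to foreground
#'   distal-mark distances (1 = no proximity effect).
#' @param decoys_per_map Decoy intervals per map placed far from every
#'   repeat.
#' @param min_units Scanner threshold the scenario is built for.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 1L, n_chromosomes = 2L,
                            n_da_repeats = 12L, n_bg_repeats = 500L,
                            unit_class_mix = NULL,
                            unit_count_range = c(6L, 20L),
                            region_mix = c(exon = 1, intron = 1,
                                           utr5 = 1, utr3 = 1),
                            assays = c("H3K4me3", "DNAm", "DNase"),
                            n_cell_types = 20L,
                            match_prob_da = 0.5, match_prob_bg = 0.5,
                            proximity_shift = 1,
                            decoys_per_map = 10L,
                            min_units = 6L) {
  classes <- unit_classes()
  if (is.null(unit_class_mix)) {
    unit_class_mix <- stats::setNames(rep(1, nrow(classes)),
                                      classes$label)
  }
  stopifnot(all(names(unit_class_mix) %in% classes$label),
            all(unit_class_mix >= 0), sum(unit_class_mix) > 0,
            match_prob_da >= 0, match_prob_da <= 1,
            match_prob_bg >= 0, match_prob_bg <= 1,
            proximity_shift > 0,
            all(names(region_mix) %in% .REGIONS),
            unit_count_range[1] >= min_units,
            unit_count_range[2] >= unit_count_range[1],
            n_da_repeats >= 1, n_bg_repeats >= 1, n_cell_types >= 1)
  md <- assay_metadata()
  if (!all(assays %in% md$assay)) {
    stop("unknown assay(s): ",
         paste(setdiff(assays, md$assay), collapse = ", "))
  }
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    n_da_repeats = as.integer(n_da_repeats),
    n_bg_repeats = as.integer(n_bg_repeats),
    unit_class_mix = unit_class_mix,
    unit_count_range = as.integer(unit_count_range),
    region_mix = region_mix, assays = assays,
    n_cell_types = as.integer(n_cell_types),
    match_prob_da = match_prob_da, match_prob_bg = match_prob_bg,
    proximity_shift = proximity_shift,
    decoys_per_map = as.integer(decoys_per_map),
    min_units = as.integer(min_units),
    slot_width = 13000L), class = "scenario_config")
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# mutate one base (outside protected spans) in each offending tract
.break_tracts <- function(s, tracts, protected) {
  for (i in seq_len(nrow(tracts))) {
    pos <- (tracts$start[i] + tracts$end[i]) %/% 2L + 1L  # 1-based
    cand <- seq.int(tracts$start[i] + 1L, tracts$end[i])
    if (nrow(protected) > 0L) {
      inside <- vapply(cand, function(p)
        any(p > protected$start & p <= protected$end), logical(1))
      cand <- cand[!inside]
    }
    if (length(cand) == 0L) next
    pos <- cand[ceiling(length(cand) / 2)]
    s[pos] <- .DNA_BASES[(match(s[pos], .DNA_BASES) %% 4L) + 1L]
  }
  s
}

.place_transcript <- function(id, chrom, rs, re, region, strand) {
  if (region == "exon") {
    tx <- c(rs - 1000L, re + 1000L); cds <- c(rs - 300L, re + 300L)
    es <- tx[1]; ee <- tx[2]
  } else if (region == "intron") {
    tx <- c(rs - 800L, re + 700L); cds <- c(rs - 750L, re + 650L)
    es <- c(rs - 800L, re + 500L); ee <- c(rs - 600L, re + 700L)
  } else {
    tx <- c(rs - 500L, re + 500L); es <- tx[1]; ee <- tx[2]
    downstream <- c(re + 100L, re + 400L)
    upstream <- c(rs - 400L, rs - 100L)
    cds <- if ((region == "utr5") == (strand == "+"))
      downstream else upstream
  }
  tibble::tibble(name = id, chrom = chrom, strand = strand,
                 tx_start = tx[1], tx_end = tx[2],
                 cds_start = cds[1], cds_end = cds[2],
                 exon_starts = list(as.integer(es)),
                 exon_ends = list(as.integer(ee)))
}

#' Generate a synthetic scenario
#'
#' Builds the genome, gene model, repeat loci, per-cell-type epigenetic
#' maps and ground-truth manifest described by a [scenario_config()].
#' Deterministic given the configuration; when `dir` is supplied all
#' artifacts are also written in the dialects the pipeline reads
#' (FASTA, gene-model TSV, repeat BEDs, per-map BEDs plus a map
#' manifest, and manifest TSVs).
#'
#' @param cfg A [scenario_config()].
#' @param dir Optional output directory.
#' @return List with `cfg`, `genome` (named character vector of
#'   chromosome sequences), `gene_model`, `loci` (annotated repeat
#'   tibble, foreground and background), `maps` (flat list of
#'   `epi_map`), and `manifest` (list of `loci` and `matches` tibbles).
#' @export
generate_scenario <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  .with_seed(cfg$seed, {
    md <- assay_metadata()
    classes <- unit_classes()
    total <- cfg$n_da_repeats + cfg$n_bg_repeats
    spc <- ceiling(total / cfg$n_chromosomes)  # slots per chromosome
    W <- cfg$slot_width
    chrom_len <- (spc + 1L) * W
    chroms <- paste0("chr", seq_len(cfg$n_chromosomes))

    # per-locus design
    source <- sample(c(rep("disease", cfg$n_da_repeats),
                       rep("background", cfg$n_bg_repeats)))
    lab <- sample(names(cfg$unit_class_mix), total, replace = TRUE,
                  prob = cfg$unit_class_mix)
    members <- strsplit(classes$members[match(
      lab, classes$label)], ",", fixed = TRUE)
    unit <- vapply(members, function(m) m[sample.int(length(m), 1)],
                   character(1))
    units <- sample(seq(cfg$unit_count_range[1], cfg$unit_count_range[2]),
                    total, replace = TRUE)
    region <- sample(names(cfg$region_mix), total, replace = TRUE,
                     prob = cfg$region_mix)
    strand <- sample(c("+", "-"), total, replace = TRUE)
    idx <- seq_len(total) - 1L
    chrom <- chroms[idx %/% spc + 1L]
    slot <- idx %% spc
    center <- slot * W + W %/% 2L + sample(-200:200, total, replace = TRUE)
    rs <- center
    re <- rs + 3L * units

    loci <- tibble::tibble(
      locus_id = sprintf("L%04d", seq_len(total)),
      chrom = chrom, start = rs, end = re,
      unit_class = lab, unit_count = units, source = source,
      unit = unit, region = region,
      exon = region == "exon", intron = region == "intron",
      utr5 = region == "utr5", utr3 = region == "utr3")

    # genome: random background cleaned of accidental tracts, then
    # planted tracts with flank breaks so each tract is exactly maximal
    genome <- stats::setNames(vector("list", cfg$n_chromosomes), chroms)
    for (ch in chroms) {
      s <- sample(.DNA_BASES, chrom_len, replace = TRUE)
      mine <- loci[loci$chrom == ch, ]
      none <- mine[0, c("start", "end")]
      for (iter in 1:20) {
        found <- scan_sequence(paste(s, collapse = ""), ch,
                               scan_config(cfg$min_units))
        if (nrow(found) == 0L) break
        if (iter == 20L) stop("could not clean accidental tracts on ", ch)
        s <- .break_tracts(s, found, none)
      }
      for (i in seq_len(nrow(mine))) {
        a <- mine$start[i]; u <- mine$unit_count[i]
        tract <- strsplit(strrep(mine$unit[i], u), "")[[1]]
        s[(a + 1L):(a + 3L * u)] <- tract
        # break period-3 continuation at both flanks
        s[a] <- sample(setdiff(.DNA_BASES, s[a + 3L]), 1)
        s[a + 3L * u + 1L] <- sample(setdiff(.DNA_BASES, s[a + 3L * u - 2L]), 1)
      }
      for (iter in 1:20) {
        found <- scan_sequence(paste(s, collapse = ""), ch,
                               scan_config(cfg$min_units))
        extra <- found[!paste(found$start, found$end) %in%
                         paste(mine$start, mine$end), ]
        if (nrow(extra) == 0L) break
        if (iter == 20L) stop("could not isolate planted tracts on ", ch)
        s <- .break_tracts(s, extra, mine[, c("start", "end")])
      }
      found <- scan_sequence(paste(s, collapse = ""), ch,
                             scan_config(cfg$min_units))
      if (!identical(paste(found$start, found$end, found$unit_class),
                     paste(mine$start, mine$end, mine$unit_class))) {
        stop("planted tract verification failed on ", ch)
      }
      genome[[ch]] <- paste(s, collapse = "")
    }
    genome <- unlist(genome)

    gene_model <- do.call(rbind, lapply(seq_len(total), function(i) {
      .place_transcript(paste0("TX_", loci$locus_id[i]), loci$chrom[i],
                        loci$start[i], loci$end[i], loci$region[i],
                        strand[i])
    }))

    # epigenetic maps with planted match indicators and distal marks
    p_match <- ifelse(loci$source == "disease", cfg$match_prob_da,
                      cfg$match_prob_bg)
    cts <- sprintf("CT%03d", seq_len(cfg$n_cell_types))
    maps <- list()
    match_rows <- list()
    lc <- (loci$start + loci$end) %/% 2L
    for (assay in cfg$assays) {
      category <- md$category[md$assay == assay]
      for (ct in cts) {
        hit <- stats::rbinom(total, 1L, p_match) == 1L
        # matched repeats: interval satisfying the category rule
        if (category == "histone_broad") {
          st_m <- loci$start - 100L - sample(0:300, total, replace = TRUE)
          en_m <- loci$start + 10L + sample(0:190, total, replace = TRUE)
        } else if (category == "dnam_cpg") {
          gap <- sample(0:180, total, replace = TRUE)
          en_m <- loci$start - gap
          st_m <- en_m - 2L
        } else {
          st_m <- lc - 50L - sample(0:100, total, replace = TRUE)
          en_m <- lc + 50L + sample(0:100, total, replace = TRUE)
        }
        # unmatched repeats: one distal mark at a controlled distance
        base_d <- round(10^stats::runif(total, log10(1500), log10(5000)))
        d <- ifelse(loci$source == "disease",
                    pmax(350, round(base_d * cfg$proximity_shift)),
                    base_d)
        side <- sample(c(-1L, 1L), total, replace = TRUE)
        c_dist <- lc + side * as.integer(d)
        iv <- tibble::tibble(
          chrom = loci$chrom,
          start = ifelse(hit, st_m, c_dist - 100L),
          end = ifelse(hit, en_m, c_dist + 100L))
        # decoys far from every repeat (first bases of random slots)
        if (cfg$decoys_per_map > 0L) {
          dch <- sample(chroms, cfg$decoys_per_map, replace = TRUE)
          dpos <- sample.int(spc, cfg$decoys_per_map, replace = TRUE) - 1L
          off <- sample(0:350, cfg$decoys_per_map, replace = TRUE)
          iv <- rbind(iv, tibble::tibble(chrom = dch,
                                         start = dpos * W + off,
                                         end = dpos * W + off + 150L))
        }
        maps[[paste(assay, ct, sep = "_")]] <-
          epi_map(iv, assay, ct, category, md)
        match_rows[[length(match_rows) + 1L]] <- tibble::tibble(
          locus_id = loci$locus_id, assay = assay, cell_type = ct,
          match = hit, distance = ifelse(hit, NA_real_, d))
      }
    }
    manifest <- list(loci = loci,
                     matches = do.call(rbind, match_rows))
    scenario <- list(cfg = cfg, genome = genome, gene_model = gene_model,
                     loci = loci[, c(.loci_core_cols, "locus_id",
                                     .REGIONS)],
                     maps = maps, manifest = manifest)
    if (!is.null(dir)) .write_scenario(scenario, dir)
    scenario
  })
}

.write_scenario <- function(scenario, dir) {
  dir.create(file.path(dir, "maps"), showWarnings = FALSE,
             recursive = TRUE)
  dna <- Biostrings::DNAStringSet(scenario$genome)
  Biostrings::writeXStringSet(dna, file.path(dir, "genome.fa"))
  write_gene_model(scenario$gene_model, file.path(dir, "gene_model.tsv"))
  loci <- scenario$loci
  write_tnr_bed(loci[loci$source == "disease", ],
                file.path(dir, "da_tnr.bed"))
  write_tnr_bed(loci[loci$source == "background", ],
                file.path(dir, "bg_tnr.bed"))
  rows <- lapply(names(scenario$maps), function(nm) {
    m <- scenario$maps[[nm]]
    p <- file.path("maps", paste0(nm, ".bed"))
    utils::write.table(m$intervals, file.path(dir, p), sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    data.frame(assay = m$assay, cell_type = m$cell_type,
               category = m$category, path = p)
  })
  utils::write.table(do.call(rbind, rows),
                     file.path(dir, "map_manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  file.copy(system.file("extdata", "assay_metadata.tsv",
                        package = "tnrenrich"),
            file.path(dir, "assay_metadata.tsv"), overwrite = TRUE)
  utils::write.table(scenario$manifest$loci,
                     file.path(dir, "manifest_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(scenario$manifest$matches,
                     file.path(dir, "manifest_matches.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Recovery metrics against planted effects
#'
#' Compares enrichment results computed on a synthetic scenario with the
#' scenario's ground truth: per-assay rejection rates for the grouped
#' Fisher tests (type-I error under null configurations, power under
#' planted effects), and the distribution of proximity-test left-tail
#' areas for foreground versus held-out background loci.
#'
#' @param scenario A [generate_scenario()] result.
#' @param m1 Optional [m1_run()] output (or several assays bound
#'   together) computed on the scenario's maps.
#' @param m3_da,m3_bg Optional [run_m3_analysis()] outputs for
#'   foreground and held-out background loci.
#' @param alpha Significance threshold.
#' @return List with tibbles `m1` and `m3` (whichever inputs were
#'   given).
#' @export
spike_report <- function(scenario, m1 = NULL, m3_da = NULL,
                         m3_bg = NULL, alpha = 0.05) {
  cfg <- scenario$cfg
  out <- list()
  if (!is.null(m1)) {
    known <- c(cfg$assays, "Any active", "Any repressive")
    if (!all(m1$assay %in% known)) {
      stop("m1 results mention assays absent from the scenario")
    }
    expected <- if (cfg$match_prob_da > cfg$match_prob_bg) "over"
      else if (cfg$match_prob_da < cfg$match_prob_bg) "under" else "none"
    rows <- lapply(split(m1, m1$assay), function(d) {
      sig <- d$p_value <= alpha
      tibble::tibble(assay = d$assay[1], n_tests = nrow(d),
                     rejection_rate = mean(sig),
                     rate_over = mean(sig & d$direction == "over"),
                     rate_under = mean(sig & d$direction == "under"),
                     expected_effect = expected)
    })
    out$m1 <- do.call(rbind, rows)
    rownames(out$m1) <- NULL
  }
  if (!is.null(m3_da) || !is.null(m3_bg)) {
    stats_for <- function(d, src) {
      if (is.null(d)) return(NULL)
      if (!all(c("p_left", "locus") %in% names(d))) {
        stop("m3 results must come from run_m3_analysis()")
      }
      tibble::tibble(source = src, n = nrow(d),
                     median_p_left = stats::median(d$p_left),
                     frac_significant = mean(d$p_left <= alpha))
    }
    out$m3 <- rbind(stats_for(m3_da, "disease"),
                    stats_for(m3_bg, "background"))
  }
  out
}
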