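# Binding archetypes planted by the simulator. Occupancy tiers are per
# factor x cell type channel; together with the accessibility state they
# define eight distinct binding patterns across the four profiled
# channels (NOTCH/RBPJ x RGC/IPC). The fusion/Dam-only ratio cancels
# accessibility by construction, so archetypes sharing a binding pattern
# are separated by intensity tier: archetype 8 (constitutive RBPJ sites
# that lose accessibility upon RGC -> IPC differentiation while bound at
# full occupancy in RGCs) vs archetype 5 (RBPJ-only in RGCs at tier
# 0.5); archetypes 2/6/7 (NOTCH+RBPJ in both cell types) differ by tier
# 0.7/1.0/0.4. Archetype 3 sites (IPC-specific RBPJ) are closed in
# RGCs, where they are unbound.
tada_archetypes <- function() {
  data.frame(
    archetype = 1:8,
    notch_rgc = c(1.0, 0.7, 0.0, 1.0, 0.0, 1.0, 0.4, 0.0),
    rbpj_rgc  = c(0.0, 0.7, 0.0, 1.0, 0.5, 1.0, 0.4, 1.0),
    notch_ipc = c(0.0, 0.7, 0.0, 0.0, 0.0, 1.0, 0.4, 0.0),
    rbpj_ipc  = c(0.0, 0.7, 0.8, 0.0, 0.0, 1.0, 0.4, 0.0),
    reduced_rgc = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    reduced_ipc = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    description = c("NOTCH-only RGC", "NOTCH+RBPJ both (mid tier)",
                    "RBPJ-only IPC, closed in RGC", "NOTCH+RBPJ RGC-only",
                    "RBPJ-only RGC", "constitutive NOTCH+RBPJ (near RGC genes)",
                    "NOTCH+RBPJ both (low tier)",
                    "constitutive RBPJ RGC, accessibility lost in IPC"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults define the standard simulated study: a 2 x 1 Mb genome with
#' GATC motifs planted at exponential spacing, 400 planted binding sites
#' spread over 8 archetypes, 300 genes, 3 replicates per sample at 5e5
#' reads, a 6-fold binding effect, accessibility states open = 1 and
#' reduced = 0.3, and DE tables in which genes nearest to constitutive
#' (archetype 6) sites are RGC-specific with probability 0.8 against a
#' 0.1 background rate.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length (bp).
#' @param gatc_spacing Mean planted GATC spacing (bp, exponential gaps;
#'   must be >= 8).
#' @param n_genes Total genes.
#' @param n_sites Planted binding sites (split evenly over chromosomes).
#' @param archetype_props Proportions of the 8 archetypes (sum to 1).
#' @param beta Binding effect: fold-increase of expected methylation at a
#'   fully occupied site (> 1).
#' @param acc_open,acc_reduced Accessibility multipliers.
#' @param replicates Replicates per sample.
#' @param depth Reads per replicate.
#' @param depth_jitter_sd Log-normal sd of the per-replicate depth factor.
#' @param p_adjacent Probability that the gene nearest an archetype-6 site
#'   is RGC-specific.
#' @param p_background Background RGC-specific rate for all other genes.
#' @param de_effect_mean,de_effect_sd Effect-size distribution of
#'   RGC-specific genes (log fold-change RGC vs IPC).
#' @param site_widths Allowed site widths (bp; multiples of `bin_width`).
#' @param min_site_gap Minimum gap between planted sites (bp).
#' @param bin_width Analysis bin width the sites are aligned to.
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2L, chrom_length = 1e6, gatc_spacing = 256,
                       n_genes = 300L, n_sites = 400L,
                       archetype_props = rep(1 / 8, 8),
                       beta = 6, acc_open = 1, acc_reduced = 0.3,
                       replicates = 3L, depth = 5e5,
                       depth_jitter_sd = 0.1,
                       p_adjacent = 0.8, p_background = 0.1,
                       de_effect_mean = 2, de_effect_sd = 0.5,
                       site_widths = c(900L, 1200L, 1500L),
                       min_site_gap = 2000L, bin_width = 300L,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (gatc_spacing < 8) stop("GATC spacing below 8 bp is not supported")
  stopifnot(abs(sum(archetype_props) - 1) < 1e-9, beta > 1,
            all(site_widths %% bin_width == 0))
  structure(as.list(environment()), class = "sim_config")
}

# deterministic archetype allocation: floor of proportions, remainder to
# the largest fractional parts, so every archetype is used at defaults
allocate_archetypes <- function(n, props) {
  base <- floor(props * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- props * n - base
    base[order(-frac)[seq_len(rem)]] <- base[order(-frac)[seq_len(rem)]] + 1
  }
  rep(seq_along(props), times = base)
}

#' Simulate a TaDa ground-truth genome
#'
#' Generates random chromosome sequences with GATC motifs planted at
#' exponential gaps, plants non-overlapping binding sites (delimited by
#' GATC motifs at both edges and aligned to the analysis bin grid, so
#' that ground truth is unambiguous at the caller's native resolution),
#' places genes (one near each archetype-6 site plus uniform background
#' genes) and precomputes per-fragment occupancy and accessibility.
#' Everything is deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `tada_truth`: `genome` (DNAStringSet), `frags`
#'   (GATC fragments), `sites` (`GRanges` with `archetype`), `genes`
#'   (data frame), `arch6_genes` (gene ids nearest to archetype-6 sites),
#'   `occupancy` (fragment x channel matrix), `accessibility` (fragment x
#'   cell type matrix), `config`.
#' @export
simulate_tada <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  arch <- tada_archetypes()
  L <- as.integer(config$chrom_length)
  bw <- config$bin_width
  chroms <- paste0("chr", seq_len(config$n_chroms))
  per_chrom <- diff(round(seq(0, config$n_sites,
                              length.out = config$n_chroms + 1)))
  site_list <- list()
  seqs <- character(config$n_chroms)
  for (ci in seq_len(config$n_chroms)) {
    n <- per_chrom[ci]
    widths <- sample(config$site_widths, n, replace = TRUE)
    need <- sum(widths) + (n + 1L) * config$min_site_gap
    if (need > L) stop("chromosome too short for the requested sites")
    slack <- L - need
    extra <- floor(slack * {
      u <- stats::runif(n + 1L)
      cumsum(u) / sum(u)
    })
    extra <- diff(c(0, extra))
    starts0 <- integer(n)
    cur <- config$min_site_gap + extra[1L]
    for (i in seq_len(n)) {
      starts0[i] <- (cur %/% bw) * bw    # snap to the analysis grid
      cur <- starts0[i] + widths[i] + config$min_site_gap + extra[i + 1L]
    }
    site_list[[ci]] <- GenomicRanges::GRanges(
      chroms[ci], IRanges::IRanges(starts0 + 1L, starts0 + widths))
    # chromosome sequence with planted GATC motifs
    letters <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    gaps <- pmax(4, ceiling(stats::rexp(ceiling(2 * L / config$gatc_spacing),
                                        1 / config$gatc_spacing)))
    motif_pos <- cumsum(gaps)
    motif_pos <- motif_pos[motif_pos <= L - 3L]
    edge_pos <- c(starts0 + 1L, starts0 + widths + 1L)  # 1-based motif starts
    edge_pos <- edge_pos[edge_pos <= L - 3L]
    for (p in list(motif_pos, edge_pos)) {
      letters[p] <- "G"; letters[p + 1L] <- "A"
      letters[p + 2L] <- "T"; letters[p + 3L] <- "C"
    }
    seqs[ci] <- paste(letters, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  sites <- suppressWarnings(do.call(c, site_list))
  seqlen <- genome_seqlengths(genome)
  GenomeInfoDb::seqlengths(sites) <- seqlen[GenomeInfoDb::seqlevels(sites)]
  labels <- allocate_archetypes(length(sites), config$archetype_props)
  S4Vectors::mcols(sites)$archetype <- sample(labels)   # shuffle placement
  S4Vectors::mcols(sites)$site_id <- sprintf("site_%04d", seq_along(sites))
  # genes: one anchored near each archetype-6 site, the rest uniform
  sites6 <- sites[S4Vectors::mcols(sites)$archetype == 6L]
  anchor_tss0 <- BiocGenerics::end(sites6) +
    sample(300:1500, length(sites6), replace = TRUE)
  anchor_chrom <- as.character(GenomeInfoDb::seqnames(sites6))
  n_bg <- config$n_genes - length(sites6)
  if (n_bg < 0) stop("n_genes smaller than the number of archetype-6 sites")
  bg_chrom <- sample(chroms, n_bg, replace = TRUE)
  bg_tss0 <- 1L + floor(stats::runif(n_bg) * (seqlen[bg_chrom] - 2L))
  genes <- data.frame(
    chrom = c(anchor_chrom, bg_chrom),
    tss = as.integer(c(anchor_tss0, bg_tss0)),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  ord <- order(genes$chrom, genes$tss)
  genes <- genes[ord, , drop = FALSE]
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes$gene_name <- genes$gene_id
  genes$biotype <- "protein_coding"
  rownames(genes) <- NULL
  # which gene is nearest to each archetype-6 site (the DE-truth anchors)
  assoc6 <- nearest_tss(sites6, genes)
  arch6_genes <- unique(assoc6$gene_id)
  frags <- gatc_fragments(scan_gatc_sites(genome), seqlen)
  # per-fragment occupancy per channel and accessibility per cell type
  channels <- c("notch_rgc", "rbpj_rgc", "notch_ipc", "rbpj_ipc")
  occupancy <- matrix(0, length(frags), 4L,
                      dimnames = list(NULL, channels))
  accessibility <- matrix(config$acc_open, length(frags), 2L,
                          dimnames = list(NULL, c("RGC", "IPC")))
  hits <- GenomicRanges::findOverlaps(frags, sites)
  fr <- S4Vectors::queryHits(hits)
  st <- S4Vectors::subjectHits(hits)
  frac <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(frags)[fr], IRanges::ranges(sites)[st])) /
    IRanges::width(frags)[fr]
  a <- S4Vectors::mcols(sites)$archetype[st]
  for (ch in channels) {
    occupancy[cbind(fr, match(ch, channels))] <- frac * arch[[ch]][a]
  }
  accessibility[fr, "RGC"] <- ifelse(arch$reduced_rgc[a],
                                     config$acc_reduced, config$acc_open)
  accessibility[fr, "IPC"] <- ifelse(arch$reduced_ipc[a],
                                     config$acc_reduced, config$acc_open)
  structure(list(genome = genome, frags = frags, sites = sites,
                 genes = genes, arch6_genes = arch6_genes,
                 occupancy = occupancy, accessibility = accessibility,
                 config = config),
            class = "tada_truth")
}

#' Simulate DamID reads for one sample
#'
#' Expected reads per GATC fragment are proportional to fragment length
#' x accessibility(cell type) x (1 + (beta - 1) x occupancy) for
#' Dam-fusion samples (occupancy term absent for Dam-only), scaled to the
#' requested depth with a per-replicate log-normal factor; observed
#' counts are independent Poisson draws. Read 5' positions sit at GATC
#' fragment boundaries (DamID amplicons span GATC to GATC), alternating
#' between the two fragment ends with matching strand.
#'
#' @param truth A `tada_truth`.
#' @param factor `"Notch"`, `"RBPJ"` or `"Dam"` (untethered Dam-only).
#' @param cell_type `"RGC"` or `"IPC"`.
#' @param replicate Replicate number (label only).
#' @param seed Integer seed for this sample.
#' @param depth Reads (defaults to the config depth).
#' @return Width-1 read `GRanges` with strand, sorted;
#'   `metadata()$sample_id` carries `<factor>_<cell_type>_rep<k>`.
#' @export
simulate_damid_reads <- function(truth, factor, cell_type, replicate = 1L,
                                 seed, depth = NULL) {
  stopifnot(inherits(truth, "tada_truth"),
            cell_type %in% c("RGC", "IPC"))
  if (!factor %in% c("Notch", "RBPJ", "Dam")) {
    stop("unknown construct factor: ", factor)
  }
  cfg <- truth$config
  if (is.null(depth)) depth <- cfg$depth
  frags <- truth$frags
  w <- IRanges::width(frags) * truth$accessibility[, cell_type]
  if (factor != "Dam") {
    ch <- paste0(tolower(factor), "_", tolower(cell_type))
    w <- w * (1 + (cfg$beta - 1) * truth$occupancy[, ch])
  }
  set.seed(seed)
  jitter <- exp(stats::rnorm(1, 0, cfg$depth_jitter_sd))
  counts <- stats::rpois(length(w), w / sum(w) * depth * jitter)
  idx <- rep(seq_along(w), counts)
  within <- sequence(counts)
  at_start <- within %% 2L == 1L
  pos <- ifelse(at_start, BiocGenerics::start(frags)[idx],
                BiocGenerics::end(frags)[idx])
  reads <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(frags)[idx],
    IRanges::IRanges(pos, width = 1L),
    strand = ifelse(at_start, "+", "-"))
  GenomeInfoDb::seqlengths(reads) <- GenomeInfoDb::seqlengths(frags)
  reads <- sort(reads, ignore.strand = TRUE)
  S4Vectors::metadata(reads)$sample_id <-
    sprintf("%s_%s_rep%d", factor, cell_type, replicate)
  reads
}

#' Simulate a differential-expression table
#'
#' Genes nearest to archetype-6 (constitutive-binding) sites are
#' RGC-specific with probability `p_adjacent`; all other genes with the
#' background probability. RGC-specific genes draw effect ~
#' Normal(de_effect_mean, de_effect_sd) and q = 10^-Uniform(5, 20); null
#' genes draw effect ~ Normal(0, 0.3) and q ~ Uniform(0.1, 1).
#'
#' @param truth A `tada_truth`.
#' @param seed Integer seed.
#' @param p_adjacent Override of the config adjacency probability (set it
#'   to `p_background` for a null/decoy table).
#' @param p_background Override of the background rate.
#' @return Data frame `gene_id`, `effect`, `q`, `rgc_specific` (the DE
#'   ground truth), deterministic given the seed.
#' @export
simulate_de_table <- function(truth, seed, p_adjacent = NULL,
                              p_background = NULL) {
  stopifnot(inherits(truth, "tada_truth"))
  cfg <- truth$config
  if (is.null(p_adjacent)) p_adjacent <- cfg$p_adjacent
  if (is.null(p_background)) p_background <- cfg$p_background
  set.seed(seed)
  genes <- truth$genes
  anchored <- genes$gene_id %in% truth$arch6_genes
  prob <- ifelse(anchored, p_adjacent, p_background)
  rgc <- stats::runif(nrow(genes)) < prob
  effect <- ifelse(rgc,
                   stats::rnorm(nrow(genes), cfg$de_effect_mean,
                                cfg$de_effect_sd),
                   stats::rnorm(nrow(genes), 0, 0.3))
  q <- ifelse(rgc, 10^-stats::runif(nrow(genes), 5, 20),
              stats::runif(nrow(genes), 0.1, 1))
  data.frame(gene_id = genes$gene_id, effect = effect, q = q,
             rgc_specific = rgc, stringsAsFactors = FALSE)
}

#' Simulate a complete TaDa experiment
#'
#' Ground truth plus reads for every sample (NOTCH and RBPJ fusions and
#' Dam-only, in RGCs and IPCs, `replicates` each) and a DE table, all
#' deterministic given the config seed (per-sample seeds are derived from
#' it).
#'
#' @param config A [sim_config()].
#' @return List of class `tada_sim`: `truth`, `reads` (named list of read
#'   `GRanges`), `de`.
#' @export
simulate_experiment <- function(config) {
  truth <- simulate_tada(config)
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      factor = c("Notch", "RBPJ", "Dam"),
                      cell_type = c("RGC", "IPC"),
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(config$seed + 1, nrow(grid) + 1L)
  reads <- lapply(seq_len(nrow(grid)), function(i) {
    simulate_damid_reads(truth, grid$factor[i], grid$cell_type[i],
                         grid$replicate[i], seed = seeds[i])
  })
  names(reads) <- sprintf("%s_%s_rep%d", grid$factor, grid$cell_type,
                          grid$replicate)
  de <- simulate_de_table(truth, seed = seeds[nrow(grid) + 1L])
  structure(list(truth = truth, reads = reads, de = de), class = "tada_sim")
}

#' Write a simulated experiment to disk
#'
#' Emits genome FASTA, per-sample reads as BED6, the ground truth as JSON
#' (sites, archetypes, genes, DE truth, config) and the DE table as TSV.
#'
#' @param sim A `tada_sim` from [simulate_experiment()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(sim$truth$genome,
                              file.path(out_dir, "genome.fa"))
  for (nm in names(sim$reads)) {
    write_bed(sim$reads[[nm]], file.path(out_dir, paste0(nm, ".bed")),
              names = rep(nm, length(sim$reads[[nm]])),
              scores = rep(0, length(sim$reads[[nm]])))
  }
  write_tsv(sim$de, file.path(out_dir, "de_table.tsv"))
  sites <- sim$truth$sites
  truth_json <- list(
    config = unclass(sim$truth$config),
    sites = data.frame(
      chrom = as.character(GenomeInfoDb::seqnames(sites)),
      start = BiocGenerics::start(sites) - 1L,
      end = BiocGenerics::end(sites),
      archetype = S4Vectors::mcols(sites)$archetype,
      site_id = S4Vectors::mcols(sites)$site_id),
    genes = sim$truth$genes,
    arch6_genes = sim$truth$arch6_genes)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
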