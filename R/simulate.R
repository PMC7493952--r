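#' Configuration for the synthetic mechanoresponse genome
#'
#' Builds the parameter set for the synthetic-data generator.  Defaults
#' describe a desk-scale genome carrying the signal structure the analysis
#' assumes: super-enhancers (SEs) made of clustered Gaussian-bump
#' constituent enhancers whose polarization theta (fraction of SE H3K27ac
#' mass in the dominant constituent) drops under force and drops further
#' when EZH2 levels are preserved during force (oeEZH2), an H3K27me3 block
#' domain abutting exactly one side of each SE, H3K27me3 promoter domains
#' over strongly upregulated genes, typical enhancers populating the bulk of
#' the ROSE rank curve, Poisson read sampling, and an expression table whose
#' absolute expression differences (AED) come from a weak/strong
#' two-component mixture.
#'
#' @param genome_length Bases on the single synthetic chromosome.
#' @param chrom Chromosome name.
#' @param n_genes Number of genes.
#' @param n_ses Number of super-enhancers.
#' @param k_range Range (min, max) of constituents per SE, sampled uniformly.
#' @param theta_range Control-condition polarization range; theta is drawn
#'   uniformly then clamped to `[1/k, 1]`.
#' @param delta_force,delta_oe Reduction of theta under force alone and
#'   under force with compensated EZH2 (oeEZH2).
#' @param ac_attenuation Multiplier on total SE H3K27ac mass under
#'   force + oeEZH2.
#' @param se_mass Expected total H3K27ac read depth summed over one SE.
#' @param sigma_constituent Gaussian sd of a constituent enhancer (bases).
#' @param constituent_gap_range Range of spacing between adjacent
#'   constituent centers (bases).
#' @param hillock_amp_frac,sigma_hillock Amplitude (fraction of the dominant
#'   constituent's height) and sd of the low, wide H3K27ac hillocks that
#'   appear between constituents under force.
#' @param me3_flank_width,me3_flank_amp Width (bases) and expected depth of
#'   the H3K27me3 block domain abutting one side of each SE.
#' @param n_typical,typical_mass_range Number of typical (non-super)
#'   enhancers and the range of their total H3K27ac mass.
#' @param prom_ac_mass,prom_ac_sigma Promoter H3K27ac bump mass and sd.
#' @param prom_me3_width,prom_me3_amp H3K27me3 promoter-domain width and
#'   expected depth over strongly upregulated genes.
#' @param prom_me3_force_factor Fold change of the promoter H3K27me3 domain
#'   under force.
#' @param oe_prom_flatten_sigma_factor,oe_prom_flatten_mass_factor Widening
#'   and attenuation of promoter H3K27ac at weakly regulated genes under
#'   force + oeEZH2.
#' @param bg_chip,bg_input Uniform background expected depth for ChIP and
#'   input libraries.
#' @param feature_min_gap Stitch-safety margin: minimum separation between
#'   an SE footprint and any other feature (bases); kept above the ROSE
#'   stitch distance so distinct features never merge with an SE by
#'   construction.
#' @param library_size Total mappable reads recorded per library.
#' @param group_counts Named counts for the four differentially expressed
#'   gene groups; remaining genes are unchanged.
#' @param weak_lfc_mean,weak_lfc_sd,strong_lfc_mean,strong_lfc_sd Parameters
#'   of the weak and strong |log2 fold change| components.
#' @param fpkm_meanlog,fpkm_sdlog Log-normal baseline FPKM parameters.
#' @param fpkm_noise_sd Log-normal replicate noise sd (log scale).
#' @return A list of class `sepol_config`.
#' @export
synthetic_config <- function(genome_length = 1e7,
                             chrom = "chrS",
                             n_genes = 1000,
                             n_ses = 60,
                             k_range = c(3, 8),
                             theta_range = c(0.55, 0.85),
                             delta_force = 0.15,
                             delta_oe = 0.30,
                             ac_attenuation = 0.7,
                             se_mass = 5e4,
                             sigma_constituent = 500,
                             constituent_gap_range = c(2500, 6000),
                             hillock_amp_frac = 0.10,
                             sigma_hillock = 2000,
                             me3_flank_width = 30000,
                             me3_flank_amp = 2.0,
                             n_typical = 300,
                             typical_mass_range = c(1000, 6000),
                             prom_ac_mass = 1500,
                             prom_ac_sigma = 300,
                             prom_me3_width = 10000,
                             prom_me3_amp = 1.5,
                             prom_me3_force_factor = 1.3,
                             oe_prom_flatten_sigma_factor = 3,
                             oe_prom_flatten_mass_factor = 0.8,
                             bg_chip = 0.5,
                             bg_input = 1.0,
                             feature_min_gap = 16000,
                             library_size = 2e7,
                             group_counts = c(strong_up = 237, weak_up = 249,
                                              strong_down = 85,
                                              weak_down = 388),
                             weak_lfc_mean = 0.7, weak_lfc_sd = 0.2,
                             strong_lfc_mean = 2.0, strong_lfc_sd = 0.4,
                             fpkm_meanlog = 3, fpkm_sdlog = 1,
                             fpkm_noise_sd = 0.1) {
  cfg <- as.list(environment())
  stopifnot(genome_length > 0, n_genes >= 0, n_ses >= 0,
            k_range[1] >= 2, k_range[2] >= k_range[1],
            theta_range[1] > 0, theta_range[2] <= 1,
            delta_force >= 0, delta_oe >= 0,
            ac_attenuation > 0, ac_attenuation <= 1,
            se_mass > 0, sigma_constituent > 0,
            me3_flank_width > 0, library_size > 0,
            sum(group_counts) <= n_genes,
            all(c("strong_up", "weak_up", "strong_down", "weak_down") %in%
                  names(group_counts)))
  class(cfg) <- "sepol_config"
  cfg
}

.sepol_conditions <- c("control", "force", "force_oeEZH2")
.sepol_marks <- c("H3K27ac", "H3K27me3", "input")

## Deterministic per-stage seed derivation from a root seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 100000L) * 10007 + offset * 97 + 1) %%
    2147483629L
}

#' AED boundary between the weak and strong mixture components
#'
#' The planted weak/strong boundary is the crossing point of the two
#' component densities between their means; the ecdf-difference curve for a
#' two-component up/down mixture peaks there in expectation.
#'
#' @param config A [synthetic_config()].
#' @return The boundary in log2 units.
#' @export
aed_mixture_boundary <- function(config) {
  f <- function(t) {
    dnorm(t, config$weak_lfc_mean, config$weak_lfc_sd) -
      dnorm(t, config$strong_lfc_mean, config$strong_lfc_sd)
  }
  stats::uniroot(f, c(config$weak_lfc_mean, config$strong_lfc_mean))$root
}

## Rejection-sample non-overlapping feature footprints on [1, L].
## `blocked` is an IRanges of already-occupied intervals; internally a
## sorted start/end pair of vectors is maintained for speed.
.place_features <- function(widths, L, blocked, min_gap, max_tries = 2000) {
  blocked <- IRanges::reduce(blocked)
  bs <- IRanges::start(blocked)
  be <- IRanges::end(blocked)
  overlaps <- function(a, b) {
    ## any sorted disjoint [bs, be] intersecting [a, b]?
    i <- findInterval(b, bs)
    i >= 1 && be[i] >= a
  }
  placed_start <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(runif(1, 1, L - w))
      if (length(bs) == 0 ||
          !overlaps(max(1, s - min_gap), min(L, s + w + min_gap))) {
        placed_start[i] <- s
        j <- findInterval(s, bs)
        bs <- append(bs, s, after = j)
        be <- append(be, s + w - 1L, after = j)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("capacity error: could not place feature of width ", w,
           " on genome of length ", L)
  }
  list(start = placed_start,
       blocked = IRanges::IRanges(bs, be))
}

#' Generate the synthetic genome layout and truth manifest
#'
#' Places super-enhancers (with their one-sided H3K27me3 flank domains),
#' typical enhancers and gene TSSs on the genome without overlap, draws
#' per-SE polarization and per-gene expression-group labels, and returns a
#' ground-truth manifest that every generated signal feature traces back to.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed; identical (config, seed) pairs give identical
#'   output.
#' @return A list with elements `manifest` (lists `se`, `genes`,
#'   `enhancers`, scalar `aed_boundary`), `tss` (a TSS
#'   [GenomicRanges::GRanges]), `seqlengths`, and `config`.
#' @export
generate_genome_and_genes <- function(config, seed = 1) {
  stopifnot(is(config, "sepol_config"))
  withr::with_seed(derive_seed(seed, 1L), {
    L <- config$genome_length
    sig <- config$sigma_constituent
    ## --- super-enhancers -------------------------------------------------
    k <- sample(seq(config$k_range[1], config$k_range[2]),
                config$n_ses, replace = TRUE)
    gaps <- lapply(k, function(ki)
      runif(ki - 1, config$constituent_gap_range[1],
            config$constituent_gap_range[2]))
    span <- vapply(gaps, sum, numeric(1))
    me3_side <- sample(c("left", "right"), config$n_ses, replace = TRUE)
    ## footprint = me3 flank + SE body (+2*sigma margins each side)
    body_w <- round(span + 4 * sig)
    foot_w <- body_w + config$me3_flank_width
    pl <- .place_features(foot_w, L, IRanges::IRanges(), config$feature_min_gap)
    se_start <- ifelse(me3_side == "left",
                       pl$start + config$me3_flank_width, pl$start)
    se_end <- se_start + body_w                      # half-open, 0-based
    theta <- pmin(1, pmax(1 / k, runif(config$n_ses, config$theta_range[1],
                                       config$theta_range[2])))
    dominant <- vapply(k, function(ki) sample.int(ki, 1), integer(1))
    centers <- lapply(seq_len(config$n_ses), function(i)
      se_start[i] + 2 * sig + c(0, cumsum(gaps[[i]])))
    se <- data.frame(
      se_id = sprintf("SE%03d", seq_len(config$n_ses)),
      chrom = rep(config$chrom, config$n_ses),
      start = as.integer(se_start), end = as.integer(se_end),
      k = k, dominant = dominant,
      theta_control = theta,
      theta_force = pmax(1 / k, theta - config$delta_force),
      theta_force_oeEZH2 = pmax(1 / k, theta - config$delta_oe),
      me3_side = me3_side,
      stringsAsFactors = FALSE)
    se$centers <- I(centers)
    ## --- typical enhancers ----------------------------------------------
    ## SE footprints expanded by the stitch-safety margin block everything
    ## else; typical enhancers and genes then only need small mutual gaps.
    se_zone <- pl$blocked + config$feature_min_gap
    enh <- NULL
    blocked <- se_zone
    if (config$n_typical > 0) {
      pe <- .place_features(rep(round(6 * sig), config$n_typical), L,
                            blocked, 1000)
      blocked <- pe$blocked
      enh <- data.frame(
        enh_id = sprintf("E%04d", seq_len(config$n_typical)),
        chrom = config$chrom,
        center = as.integer(pe$start + 3 * sig),
        mass = runif(config$n_typical, config$typical_mass_range[1],
                     config$typical_mass_range[2]),
        stringsAsFactors = FALSE)
    }
    ## --- genes -----------------------------------------------------------
    gc <- config$group_counts
    n_unch <- config$n_genes - sum(gc)
    group <- sample(rep(c(names(gc), "unchanged"), c(gc, n_unch)))
    pg <- .place_features(rep(2L, config$n_genes), L, blocked, 1000)
    tss_pos <- pg$start                               # 0-based
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    lfc_mag <- numeric(config$n_genes)
    weak <- group %in% c("weak_up", "weak_down")
    strong <- group %in% c("strong_up", "strong_down")
    lfc_mag[weak] <- abs(rnorm(sum(weak), config$weak_lfc_mean,
                               config$weak_lfc_sd))
    lfc_mag[strong] <- abs(rnorm(sum(strong), config$strong_lfc_mean,
                                 config$strong_lfc_sd))
    sign <- ifelse(grepl("down", group), -1, ifelse(group == "unchanged",
                                                    0, 1))
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(config$n_genes)),
      chrom = rep(config$chrom, config$n_genes),
      tss = as.integer(tss_pos), strand = strand,
      group = group, true_log2fc = sign * lfc_mag,
      promoter_me3 = group == "strong_up",
      stringsAsFactors = FALSE)
    tss <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$tss + 1, width = 1),
                                  strand = genes$strand)
    names(tss) <- genes$gene_id
    tss$gene_id <- genes$gene_id
    manifest <- list(se = se, genes = genes, enhancers = enh,
                     aed_boundary = aed_mixture_boundary(config))
    list(manifest = manifest, tss = tss,
         seqlengths = stats::setNames(L, config$chrom), config = config)
  })
}

## Expected-depth contribution of `mass` worth of a Gaussian bump centered
## at `center` (0-based): a list of positions `x` and added values `v`.
## Contributions are returned rather than applied so the caller can
## accumulate into its own lambda vector in place (passing the full vector
## through a function would copy it on every feature).
.bump_profile <- function(center, mass, sigma, L) {
  lo <- max(1, floor(center - 5 * sigma))
  hi <- min(L, ceiling(center + 5 * sigma))
  if (hi < lo) return(list(x = integer(0), v = numeric(0)))
  x <- lo:hi
  list(x = x, v = mass * dnorm(x - 0.5, center, sigma))
}

.block_profile <- function(start0, end0, amp, L) {
  lo <- max(1, start0 + 1)
  hi <- min(L, end0)
  if (hi < lo) return(list(x = integer(0), v = numeric(0)))
  x <- lo:hi
  list(x = x, v = rep(amp, length(x)))
}

## Expected H3K27ac profile of one SE under a condition, scaled so that it
## integrates to the configured (possibly attenuated) SE mass.
.se_ac_profile <- function(se_row, condition, config, L) {
  theta <- switch(condition,
                  control = se_row$theta_control,
                  force = se_row$theta_force,
                  force_oeEZH2 = se_row$theta_force_oeEZH2)
  mass <- config$se_mass *
    if (condition == "force_oeEZH2") config$ac_attenuation else 1
  centers <- se_row$centers[[1]]
  k <- se_row$k
  w <- rep((1 - theta) / (k - 1), k)
  w[se_row$dominant] <- theta
  lo <- max(1, se_row$start - 10 * config$sigma_constituent)
  hi <- min(L, se_row$end + 10 * config$sigma_constituent)
  x <- lo:hi
  prof <- numeric(length(x))
  for (j in seq_len(k))
    prof <- prof + w[j] * dnorm(x - 0.5, centers[j],
                                config$sigma_constituent)
  if (condition %in% c("force", "force_oeEZH2") && k >= 2) {
    dom_height <- w[se_row$dominant] / (config$sigma_constituent *
                                          sqrt(2 * pi))
    ## hillock amplitude scales with the condition's polarization loss:
    ## inter-constituent fill-in is strongest when EZH2 is preserved
    delta <- if (condition == "force") config$delta_force else
      config$delta_oe
    sev <- if (config$delta_force > 0) delta / config$delta_force else 1
    mids <- (centers[-1] + centers[-k]) / 2
    for (m in mids)
      prof <- prof + sev * config$hillock_amp_frac * dom_height *
        exp(-(x - 0.5 - m)^2 / (2 * config$sigma_hillock^2))
  }
  list(x = x, v = prof * (mass / sum(prof)))
}

#' Generate one synthetic ChIP-seq coverage library
#'
#' Builds the expected per-base depth for the requested mark and condition
#' (uniform background plus Gaussian-bump enhancers and rectangular
#' H3K27me3 domains as laid out in the manifest) and draws realized depth
#' from a Poisson at each base.
#'
#' @param config A [synthetic_config()].
#' @param manifest Manifest from [generate_genome_and_genes()].
#' @param condition One of `"control"`, `"force"`, `"force_oeEZH2"`.
#' @param mark One of `"H3K27ac"`, `"H3K27me3"`, `"input"`.
#' @param replicate Replicate index (only changes the noise seed and label).
#' @param seed Integer seed.
#' @return A [CoverageTrack()].
#' @export
generate_coverage_library <- function(config, manifest, condition, mark,
                                      replicate = 1, seed = 1) {
  stopifnot(is(config, "sepol_config"))
  if (!mark %in% .sepol_marks) stop("unknown mark: ", mark)
  if (!condition %in% .sepol_conditions) stop("unknown condition: ",
                                              condition)
  L <- config$genome_length
  off <- 100L * match(condition, .sepol_conditions) +
    10L * match(mark, .sepol_marks) + as.integer(replicate)
  withr::with_seed(derive_seed(seed, off), {
    lambda <- rep(if (mark == "input") config$bg_input else config$bg_chip,
                  L)
    se <- manifest$se
    genes <- manifest$genes
    ## contributions are accumulated in this frame so `lambda` keeps a
    ## reference count of one and subassignment stays in place
    if (mark == "H3K27ac") {
      for (i in seq_len(nrow(se))) {
        p <- .se_ac_profile(se[i, ], condition, config, L)
        lambda[p$x] <- lambda[p$x] + p$v
      }
      if (!is.null(manifest$enhancers))
        for (i in seq_len(nrow(manifest$enhancers))) {
          p <- .bump_profile(manifest$enhancers$center[i],
                             manifest$enhancers$mass[i],
                             config$sigma_constituent, L)
          lambda[p$x] <- lambda[p$x] + p$v
        }
      flat <- condition == "force_oeEZH2" &
        genes$group %in% c("weak_up", "weak_down")
      for (i in seq_len(nrow(genes))) {
        sg <- config$prom_ac_sigma *
          if (flat[i]) config$oe_prom_flatten_sigma_factor else 1
        ms <- config$prom_ac_mass *
          if (flat[i]) config$oe_prom_flatten_mass_factor else 1
        p <- .bump_profile(genes$tss[i], ms, sg, L)
        lambda[p$x] <- lambda[p$x] + p$v
      }
    } else if (mark == "H3K27me3") {
      for (i in seq_len(nrow(se))) {
        p <- if (se$me3_side[i] == "left")
          .block_profile(se$start[i] - config$me3_flank_width,
                         se$start[i], config$me3_flank_amp, L)
        else
          .block_profile(se$end[i], se$end[i] + config$me3_flank_width,
                         config$me3_flank_amp, L)
        lambda[p$x] <- lambda[p$x] + p$v
      }
      amp <- config$prom_me3_amp *
        if (condition %in% c("force", "force_oeEZH2"))
          config$prom_me3_force_factor else 1
      half <- config$prom_me3_width / 2
      pm <- genes[genes$promoter_me3, , drop = FALSE]
      for (i in seq_len(nrow(pm))) {
        p <- .block_profile(round(pm$tss[i] - half),
                            round(pm$tss[i] + half), amp, L)
        lambda[p$x] <- lambda[p$x] + p$v
      }
    }
    counts <- rpois(L, lambda)
    cov <- stats::setNames(list(S4Vectors::Rle(counts)), config$chrom)
    CoverageTrack(cov, library_size = config$library_size,
                  label = if (mark == "input")
                    sprintf("input_rep%d", replicate)
                  else sprintf("%s_%s_rep%d", mark, condition, replicate))
  })
}

#' Generate a synthetic expression table
#'
#' Per-replicate FPKM is baseline x 2^(+/- log2FC / 2) x log-normal noise,
#' so the expected AED of a planted gene equals |true log2FC|.  All planted
#' differentially expressed genes carry `significant = TRUE`.
#'
#' @inheritParams generate_coverage_library
#' @param n_replicates Replicates per condition.
#' @return A data.frame with columns `gene_id`,
#'   `fpkm_ctrl_rep*`, `fpkm_stress_rep*`, `significant`, `group`
#'   (truth label, for recovery tests).
#' @export
generate_expression_table <- function(config, manifest, seed = 1,
                                      n_replicates = 2) {
  stopifnot(is(config, "sepol_config"))
  genes <- manifest$genes
  withr::with_seed(derive_seed(seed, 7L), {
    n <- nrow(genes)
    base <- rlnorm(n, config$fpkm_meanlog, config$fpkm_sdlog)
    out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
    for (r in seq_len(n_replicates))
      out[[sprintf("fpkm_ctrl_rep%d", r)]] <-
        base * 2^(-genes$true_log2fc / 2) *
        rlnorm(n, 0, config$fpkm_noise_sd)
    for (r in seq_len(n_replicates))
      out[[sprintf("fpkm_stress_rep%d", r)]] <-
        base * 2^(genes$true_log2fc / 2) *
        rlnorm(n, 0, config$fpkm_noise_sd)
    out$significant <- genes$group != "unchanged"
    out$group <- genes$group
    out
  })
}

#' Run the full synthetic generator
#'
#' Convenience wrapper: genome layout, the coverage libraries the analysis
#' consumes, and the expression table, all from one root seed.
#'
#' @param config A [synthetic_config()].
#' @param seed Root integer seed.
#' @param marks Marks to simulate coverage for.
#' @param conditions Conditions to simulate.
#' @param n_replicates ChIP replicates per (mark, condition).
#' @param n_input Number of input libraries.
#' @return A list with `genome` (see [generate_genome_and_genes()]),
#'   `tracks` (named list of [CoverageTrack()]s, names like
#'   `H3K27ac_force_rep1`, `input_rep2`), and `expression`.
#' @export
simulate_study <- function(config = synthetic_config(), seed = 1,
                           marks = c("H3K27ac", "H3K27me3"),
                           conditions = .sepol_conditions,
                           n_replicates = 1, n_input = 2) {
  genome <- generate_genome_and_genes(config, seed)
  tracks <- list()
  for (mk in marks)
    for (cd in conditions)
      for (r in seq_len(n_replicates)) {
        nm <- sprintf("%s_%s_rep%d", mk, cd, r)
        tracks[[nm]] <- generate_coverage_library(config, genome$manifest,
                                                  cd, mk, r, seed)
      }
  for (r in seq_len(n_input))
    tracks[[sprintf("input_rep%d", r)]] <-
      generate_coverage_library(config, genome$manifest, "control",
                                "input", r, seed)
  list(genome = genome, tracks = tracks,
       expression = generate_expression_table(config, genome$manifest,
                                              seed))
}

#' Truth SE coordinates as GRanges
#'
#' @param manifest Manifest from [generate_genome_and_genes()].
#' @return [GenomicRanges::GRanges] of the planted SE bodies, named by
#'   `se_id`.
#' @export
manifest_se_granges <- function(manifest) {
  se <- manifest$se
  gr <- GenomicRanges::GRanges(se$chrom,
                               IRanges::IRanges(se$start + 1, se$end))
  names(gr) <- se$se_id
  gr$se_id <- se$se_id
  gr$me3_side <- se$me3_side
  gr
}
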