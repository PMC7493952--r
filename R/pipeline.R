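#' Run the full synthetic analysis pipeline
#'
#' End-to-end orchestration on synthetic data: simulate the study
#' (genome, coverage libraries, expression), partition differentially
#' expressed genes by AED, call super-enhancers per condition, orient them
#' against flanking H3K27me3, compute SE entropy deltas with input-library
#' and matched-length random backgrounds, and contrast promoter entropies
#' per gene group.  Every stage derives its seed from the single root seed,
#' so a rerun with the same config and seed reproduces identical tables.
#'
#' @param config A [synthetic_config()].
#' @param outdir Output directory (created if needed); `NULL` skips all
#'   file output and just returns results.
#' @param seed Root integer seed.
#' @param stages Character subset of
#'   `c("partition", "se", "polarity", "entropy", "promoter")`; stages with
#'   unmet dependencies raise an error naming the missing stage.
#' @param write_tracks Also write each coverage library as bedGraph
#'   (large; off by default).
#' @return A list with elements `sim`, `partition`, `se_sets`, `oriented`,
#'   `entropy`, `promoter`, and `artifacts` (relative paths of files
#'   written).
#' @export
run_pipeline <- function(config = synthetic_config(), outdir = NULL,
                         seed = 1,
                         stages = c("partition", "se", "polarity",
                                    "entropy", "promoter"),
                         write_tracks = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if ("promoter" %in% stages && !"partition" %in% stages)
    stop("dependency error: stage 'promoter' needs stage 'partition'")
  if (any(c("polarity", "entropy") %in% stages) && !"se" %in% stages)
    stop("dependency error: stages 'polarity'/'entropy' need stage 'se'")
  artifacts <- character(0)
  emit <- function(obj, name, writer = write_results_table) {
    if (!is.null(outdir)) {
      writer(obj, file.path(outdir, name))
      artifacts <<- c(artifacts, name)
    }
  }
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)

  sim <- simulate_study(config, seed = seed)
  manifest <- sim$genome$manifest
  tss <- sim$genome$tss
  if (!is.null(outdir)) {
    emit(manifest$se[, setdiff(names(manifest$se), "centers")],
         "truth_se.tsv")
    emit(manifest$genes, "truth_genes.tsv")
    emit(sim$expression, "expression.tsv")
    if (write_tracks)
      for (nm in names(sim$tracks))
        emit(sim$tracks[[nm]], paste0(nm, ".bedGraph"), write_bedgraph)
  }

  res <- list(sim = sim)

  if ("partition" %in% stages) {
    part <- partition_expression(sim$expression)
    res$partition <- part
    emit(part$records, "partition_records.tsv")
    emit(part$curve, "ecdf_difference_curve.tsv")
    if (!is.null(outdir)) {
      jsonlite::write_json(
        list(t_star = part$t_star, max_d = part$max_d,
             counts = as.list(part$counts),
             percentages = as.list(part$percentages),
             ks_d = part$ks$statistic, ks_p = part$ks$p_value),
        file.path(outdir, "partition_summary.json"),
        auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, "partition_summary.json")
    }
  }

  if ("se" %in% stages) {
    se_sets <- list()
    input1 <- sim$tracks$input_rep1
    for (cd in c("control", "force", "force_oeEZH2")) {
      ac <- sim$tracks[[sprintf("H3K27ac_%s_rep1", cd)]]
      peaks <- call_peaks_naive(ac)
      se_sets[[cd]] <- call_super_enhancers(peaks, ac, input1)
    }
    res$se_sets <- se_sets
    res$overlap <- se_set_overlap(lapply(se_sets,
                                         function(x) x[x$is_super]))
    if (!is.null(outdir))
      for (cd in names(se_sets)) {
        g <- se_sets[[cd]]
        g$name <- sprintf("%s_region%04d", cd, seq_along(g))
        emit(g, sprintf("stitched_%s.bed", cd), write_bed)
        emit(g[g$is_super], sprintf("se_%s.bed", cd), write_bed)
      }
  }

  if ("polarity" %in% stages) {
    me3 <- sim$tracks$H3K27me3_control_rep1
    oriented <- lapply(res$se_sets, function(g)
      orient_ses(g[g$is_super], me3))
    res$oriented <- oriented
    res$binned <- lapply(oriented, function(g)
      binned_se_matrix(g, sim$tracks$H3K27ac_control_rep1))
    if (!is.null(outdir))
      for (cd in names(oriented))
        emit(as.data.frame(oriented[[cd]]),
             sprintf("oriented_se_%s.tsv", cd))
  }

  if ("entropy" %in% stages) {
    ses_ctrl <- res$oriented[["control"]] %||%
      res$se_sets$control[res$se_sets$control$is_super]
    ses_ctrl <- GenomicRanges::granges(ses_ctrl)
    names(ses_ctrl) <- paste0("SE", seq_along(ses_ctrl))
    bg <- matched_background_regions(ses_ctrl, sim$genome$seqlengths,
                                     seed = seed)
    trk <- sim$tracks
    deltas <- list(
      background = entropy_deltas(trk$input_rep2, trk$input_rep1,
                                  ses_ctrl, "input2-input1"),
      force = entropy_deltas(trk$H3K27ac_force_rep1,
                             trk$H3K27ac_control_rep1, ses_ctrl,
                             "H3K27ac force-control"),
      force_oeEZH2 = entropy_deltas(trk$H3K27ac_force_oeEZH2_rep1,
                                    trk$H3K27ac_control_rep1, ses_ctrl,
                                    "H3K27ac forceOE-control"),
      me3_force = entropy_deltas(trk$H3K27me3_force_rep1,
                                 trk$H3K27me3_control_rep1, ses_ctrl,
                                 "H3K27me3 force-control"),
      force_bg_regions = entropy_deltas(trk$H3K27ac_force_rep1,
                                        trk$H3K27ac_control_rep1, bg,
                                        "H3K27ac force-control (bg)"))
    res$entropy <- list(
      deltas = deltas,
      report = delta_ecdf_report(lapply(deltas,
                                        function(x) x$deltas$delta),
                                 control = "background", paired = TRUE),
      background_regions = bg)
    if (!is.null(outdir)) {
      emit(do.call(rbind, lapply(deltas, `[[`, "deltas")),
           "entropy_deltas.tsv")
      jsonlite::write_json(lapply(deltas, `[[`, "summary"),
                           file.path(outdir, "entropy_summaries.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, "entropy_summaries.json")
    }
  }

  if ("promoter" %in% stages) {
    groups <- stats::setNames(res$partition$records$subgroup,
                              res$partition$records$gene_id)
    groups <- groups[groups != "unchanged"]
    res$promoter <- promoter_entropy_contrast(
      sim$tracks$H3K27ac_control_rep1, sim$tracks$H3K27ac_force_rep1,
      sim$tracks$H3K27ac_force_oeEZH2_rep1, tss, groups)
    emit(res$promoter$per_gene, "promoter_entropy.tsv")
    emit(res$promoter$per_group, "promoter_entropy_groups.tsv")
  }

  if (!is.null(outdir)) {
    jsonlite::write_json(list(seed = seed, artifacts = artifacts,
                              config = config[lengths(config) > 0]),
                         file.path(outdir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res$artifacts <- artifacts
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
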