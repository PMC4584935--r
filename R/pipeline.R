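# End-to-end pipeline: simulate (or load) -> summarize -> ordinate -> titv
# -> ibs -> network -> enrich, with a manifest and a markdown report.

.stage_names <- c("simulate", "summarize", "ordinate", "titv", "ibs",
                  "network", "enrich")

#' Run the full exome-pattern pipeline on a synthetic cohort
#'
#' Executes all analysis stages in dependency order on a simulated cohort,
#' writes each stage's tabular outputs plus a run manifest under `out_dir`,
#' and returns the result bundle. With a fixed config and seed, all
#' analytic outputs are identical across runs (the manifest carries the
#' only timestamps).
#'
#' @param config A `cohort_config` (or a YAML file readable as one:
#'   top-level keys matching [cohort_config()] arguments).
#' @param out_dir Output directory; `NULL` keeps everything in memory.
#' @param stages Character subset of
#'   `c("simulate","summarize","ordinate","titv","ibs","network","enrich")`;
#'   `simulate` is always run.
#' @param nmds_dims Embedding dimensionality (default 4, the N-1 maximum
#'   for five samples).
#' @param distance Distance for the affection matrices (default
#'   `"jaccard"`).
#' @return A `pipeline_bundle` list with one element per executed stage
#'   plus `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         stages = .stage_names, nmds_dims = 4,
                         distance = "jaccard") {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- do.call(cohort_config, yaml::read_yaml(config))
  stages <- unique(c("simulate", match.arg(stages, .stage_names,
                                           several.ok = TRUE)))
  bundle <- list()
  timings <- c()
  run_stage <- function(name, fn) {
    if (!name %in% stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      .stopf("stage '%s' failed: %s (earlier outputs kept)", name,
             conditionMessage(e)))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    bundle[[name]] <<- res
    message(sprintf("stage %-9s done in %.2fs", name, timings[[name]]))
    invisible(NULL)
  }

  run_stage("simulate", function() simulate_cohort(config))
  sim <- bundle$simulate
  tumors <- sim$callsets[config$tumors]
  controls <- sim$callsets[config$controls]

  run_stage("summarize", function()
    summarize_callsets(sim$callsets, catalog = sim$known_catalog))

  run_stage("ordinate", function() {
    lapply(c(SNV = "SNV", INDEL = "INDEL"), function(st) {
      gs <- lapply(sim$callsets, build_gene_sets, stratum = st)
      m <- build_affection_matrix(gs)
      d <- binary_distance(m, distance)
      k <- min(nmds_dims, nrow(m) - 1)
      ord <- suppressWarnings(nmds(d, k = k, seed = config$seed))
      hc <- hierarchical_cluster(d)
      venn <- set_intersections(gs)
      list(gene_sets = gs, matrix = m, distance = d, nmds = ord,
           clustering = hc, intersections = venn)
    })
  })

  run_stage("titv", function() {
    res <- lapply(sim$callsets, stratified_titv_test,
                  catalog = sim$known_catalog)
    pooled_v <- do.call(rbind, lapply(sim$callsets, `[[`, "variants"))
    pooled <- stratified_titv_test(
      sample_callset("pooled", "control", pooled_v), sim$known_catalog)
    c(res, list(pooled = pooled))
  })

  run_stage("ibs", function() {
    r <- infer_ibs_somatic(tumors, controls, sim$somatic_catalog)
    list(result = r, report = ibs_stage_report(r))
  })

  run_stage("network", function() {
    query <- lapply(sim$callsets, function(cs) {
      union(build_gene_sets(cs, "SNV")$genes, build_gene_sets(cs, "INDEL")$genes)
    })
    tumor_nets <- lapply(config$tumors, function(s)
      build_subnetwork(query[[s]], sim$network, mode = "plus_bridges"))
    names(tumor_nets) <- config$tumors
    cent <- lapply(tumor_nets, centrality)
    lcf <- vapply(names(sim$callsets), function(s) {
      g <- build_subnetwork(query[[s]], sim$network, mode = "direct")
      suppressMessages(largest_component_fraction(g, query[[s]]))
    }, numeric(1))
    overlap <- network_overlap(tumor_nets[[1]], tumor_nets[[2]])
    # nonsynonymous-vs-synonymous hub adjacency contrast over tumor SNVs
    tv <- do.call(rbind, lapply(tumors, `[[`, "variants"))
    exonic_snv <- tv[tv$var_class == "SNV" & tv$region == "exonic" &
                       !is.na(tv$exonic_function), ]
    ns_genes <- .split_genes(exonic_snv$genes[exonic_snv$exonic_function == "nonsynonymous"])
    syn_genes <- setdiff(
      .split_genes(exonic_snv$genes[exonic_snv$exonic_function == "synonymous"]),
      ns_genes)
    contrast <- tryCatch(
      suppressWarnings(hub_interaction_contrast(config$hub_gene, ns_genes,
                                                syn_genes, sim$network)),
      error = function(e) NULL)
    list(tumor_networks = tumor_nets, centrality = cent,
         largest_component_pct = lcf, overlap = overlap,
         hub_contrast = contrast)
  })

  run_stage("enrich", function() {
    universe <- sort(unique(unlist(lapply(sim$callsets, function(cs)
      union(build_gene_sets(cs, "SNV")$genes,
            build_gene_sets(cs, "INDEL")$genes)))))
    res <- lapply(sim$callsets, function(cs) {
      gs <- build_gene_sets(cs, "INDEL")
      if (!length(gs$genes)) return(NULL)
      suppressWarnings(enrich_gene_set(gs$genes, sim$annotations, universe))
    })
    list(universe_size = length(universe), per_sample = res)
  })

  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("exopattern")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = unclass(config),
    stages = names(timings),
    stage_seconds = as.list(timings),
    timestamp = format(Sys.time(), tz = "UTC"))
  class(bundle) <- "pipeline_bundle"

  if (!is.null(out_dir)) .write_bundle(bundle, out_dir)
  bundle
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) write.table(df, file.path(out_dir, name),
                                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$simulate))
    write_cohort(bundle$simulate, file.path(out_dir, "cohort"))
  if (!is.null(bundle$summarize)) wt(bundle$summarize, "class_counts.tsv")
  if (!is.null(bundle$ordinate)) {
    for (st in names(bundle$ordinate)) {
      o <- bundle$ordinate[[st]]
      pts <- data.frame(sample = rownames(o$nmds$points), o$nmds$points)
      f <- file.path(out_dir, sprintf("nmds_%s.tsv", st))
      write.table(pts, f, sep = "\t", quote = FALSE, row.names = FALSE)
      cat(sprintf("# stress1\t%.8g\n", o$nmds$stress), file = f, append = TRUE)
      writeLines(o$clustering$newick,
                 file.path(out_dir, sprintf("dendrogram_%s.nwk", st)))
      wt(o$intersections, sprintf("intersections_%s.tsv", st))
    }
  }
  if (!is.null(bundle$titv)) {
    rows <- do.call(rbind, lapply(names(bundle$titv), function(s) {
      t <- bundle$titv[[s]]
      data.frame(sample = s,
                 novel_ti = t$novel$transitions, novel_tv = t$novel$transversions,
                 novel_fraction = t$novel$fraction,
                 known_ti = t$known$transitions, known_tv = t$known$transversions,
                 known_fraction = t$known$fraction,
                 fisher_p = t$fisher$p_two_sided)
    }))
    wt(rows, "titv.tsv")
  }
  if (!is.null(bundle$ibs)) {
    wt(bundle$ibs$report, "ibs_stages.tsv")
    writeLines(bundle$ibs$result$variant_keys, file.path(out_dir, "ibs_keys.txt"))
  }
  if (!is.null(bundle$network)) {
    for (s in names(bundle$network$centrality))
      wt(bundle$network$centrality[[s]], sprintf("centrality_%s.tsv", s))
    wt(data.frame(sample = names(bundle$network$largest_component_pct),
                  largest_component_pct = bundle$network$largest_component_pct),
       "largest_component.tsv")
  }
  if (!is.null(bundle$enrich)) {
    for (s in names(bundle$enrich$per_sample)) {
      if (!is.null(bundle$enrich$per_sample[[s]]))
        wt(bundle$enrich$per_sample[[s]], sprintf("enrichment_%s.tsv", s))
    }
  }
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(make_report(bundle), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Render a pipeline bundle as a markdown report
#'
#' @param bundle A `pipeline_bundle` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
make_report <- function(bundle) {
  out <- c("# Exome variant pattern report", "")
  skipped <- function(name) c(sprintf("## %s", name), "", "_stage skipped_", "")
  if (is.null(bundle$summarize)) out <- c(out, skipped("Variant class counts"))
  else {
    s <- bundle$summarize
    out <- c(out, "## Variant class counts", "",
             paste(utils::capture.output(print(s, row.names = FALSE)), collapse = "\n"), "")
  }
  if (is.null(bundle$titv)) out <- c(out, skipped("Transition/transversion signature"))
  else {
    out <- c(out, "## Transition/transversion signature", "")
    for (s in names(bundle$titv)) {
      t <- bundle$titv[[s]]
      out <- c(out, sprintf(
        "- %s: novel Ti fraction %.3f, known %.3f, Fisher p = %.3g",
        s, t$novel$fraction, t$known$fraction, t$fisher$p_two_sided))
    }
    out <- c(out, "")
  }
  if (is.null(bundle$ibs)) out <- c(out, skipped("IBS somatic inference"))
  else {
    r <- bundle$ibs$report
    out <- c(out, "## IBS somatic inference", "",
             paste(sprintf("- %s: %d", r$stage, r$count), collapse = "\n"), "")
  }
  if (is.null(bundle$ordinate)) out <- c(out, skipped("Ordination"))
  else {
    out <- c(out, "## Ordination", "")
    for (st in names(bundle$ordinate)) {
      o <- bundle$ordinate[[st]]
      dim1 <- o$nmds$points[, 1]
      split <- names(dim1)[dim1 > stats::median(dim1)]
      out <- c(out, sprintf("- %s: stress-1 = %.4g; dimension-1 upper half: %s",
                            st, o$nmds$stress, paste(split, collapse = ", ")))
    }
    out <- c(out, "")
  }
  if (is.null(bundle$network)) out <- c(out, skipped("Network centrality"))
  else {
    out <- c(out, "## Network centrality (top 10 by degree)", "")
    for (s in names(bundle$network$centrality)) {
      cr <- bundle$network$centrality[[s]]
      top <- head(cr$node[order(cr$degree_rank)], 10)
      out <- c(out, sprintf("- %s: %s", s, paste(top, collapse = ", ")))
    }
    lcf <- bundle$network$largest_component_pct
    out <- c(out, "",
             sprintf("Largest-component percentage per sample: %s",
                     paste(sprintf("%s=%.1f%%", names(lcf), lcf), collapse = ", ")),
             "")
  }
  if (is.null(bundle$enrich)) out <- c(out, skipped("Enrichment"))
  else {
    out <- c(out, "## Significant INDEL gene-set terms", "")
    for (s in names(bundle$enrich$per_sample)) {
      e <- bundle$enrich$per_sample[[s]]
      sig <- if (is.null(e)) character() else e$term[e$significant]
      out <- c(out, sprintf("- %s: %s", s,
                            if (length(sig)) paste(sig, collapse = ", ") else "none"))
    }
    out <- c(out, "")
  }
  out
}
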