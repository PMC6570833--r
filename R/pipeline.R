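#' Pipeline configuration
#'
#' Collects every setting of the end-to-end workflow. Paths are checked at
#' validation time; contrasts must reference group labels present in the
#' genotype file.
#'
#' @param genotypes path of the genotype TSV (see [read_genotypes()]).
#' @param interactions path of the interaction TSV.
#' @param gmt path of the gene-set GMT file.
#' @param contrasts list of `c(case, control)` label pairs.
#' @param out_dir output directory (created if absent).
#' @param qc list of QC thresholds: `max_snp_missing_rate`, `min_maf`,
#'   `min_hwe_p`.
#' @param alpha significance cutoff on the raw p-value.
#' @param min_score interaction confidence threshold.
#' @param caps a [shell_caps()] list.
#' @param weights a [score_weights()] list.
#' @param mcl a [mcl_params()] list.
#' @param top_seeds seed pathways per contrast (default 10).
#' @param min_jaccard pathway-scaffold edge threshold.
#' @param min_snps contrasts with fewer significant SNPs are skipped past
#'   the association stage (default 2).
#' @param seed integer seed recorded in the run log.
#' @param alias_table optional gene-to-protein alias table (data.frame or
#'   named vector).
#' @param annotation optional SNP annotation TSV
#'   (see [read_snp_annotation()]) supplying the locus carried by each SNP.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genotypes, interactions, gmt, contrasts, out_dir,
                            qc = list(max_snp_missing_rate = 0.05,
                                      min_maf = 0.01, min_hwe_p = 1e-6),
                            alpha = 0.05, min_score = 0.400,
                            caps = shell_caps(), weights = score_weights(),
                            mcl = mcl_params(), top_seeds = 10,
                            min_jaccard = 0.05, min_snps = 2, seed = 1,
                            alias_table = NULL, annotation = NULL) {
  for (p in c(genotypes, interactions, gmt, annotation))
    if (!file.exists(p)) gp_stop("missing input file: ", p)
  if (!length(contrasts)) gp_stop("no contrasts configured")
  cfg <- list(genotypes = genotypes, interactions = interactions, gmt = gmt,
              contrasts = contrasts, out_dir = out_dir, qc = qc,
              alpha = alpha, min_score = min_score, caps = caps,
              weights = weights, mcl = mcl, top_seeds = top_seeds,
              min_jaccard = min_jaccard, min_snps = min_snps, seed = seed,
              alias_table = alias_table, annotation = annotation)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Paths inside the file are resolved relative to the file's directory.
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  pipeline_config(
    genotypes = resolve(y$genotypes), interactions = resolve(y$interactions),
    gmt = resolve(y$gmt), contrasts = y$contrasts,
    out_dir = y$out_dir %||% file.path(base, "pipeline_out"),
    qc = y$qc %||% list(max_snp_missing_rate = 0.05, min_maf = 0.01,
                        min_hwe_p = 1e-6),
    alpha = y$alpha %||% 0.05, min_score = y$min_score %||% 0.400,
    caps = do.call(shell_caps, y$caps %||% list()),
    weights = do.call(score_weights, y$weights %||% list()),
    mcl = do.call(mcl_params, y$mcl %||% list()),
    top_seeds = y$top_seeds %||% 10,
    min_jaccard = y$min_jaccard %||% 0.05,
    min_snps = y$min_snps %||% 2, seed = y$seed %||% 1,
    annotation = if (is.null(y$annotation)) NULL else resolve(y$annotation))
}

#' Run the end-to-end workflow
#'
#' For every configured case/control contrast: QC + allelic association
#' (association table TSV and significant-gene list), the pathway-first
#' route (seed-pathway enrichment, complementary pathway network,
#' edge-betweenness communities) and the protein-first route (capped shell
#' expansion of the protein-association network, centralities and combined
#' ranks, Markov clusters, centrality-ranked pathways). Afterwards:
#' pairwise SNP-set comparisons across contrasts, a per-contrast
#' method-consensus merge, and the disease-disease network over the merged
#' pathway profiles. Every written file is listed in a JSON manifest with
#' its MD5 hash; a run log records the seed, thresholds and record counts.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly: list with `files` (data.frame `name`,
#'   `path`, `md5`), `skipped`, `log`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(); logs <- character()
  note <- function(fmt, ...) logs <<- c(logs, sprintf(fmt, ...))
  emit <- function(name, path) files[[name]] <<- path
  save_tsv <- function(obj, name) {
    path <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    write.table(as.data.frame(obj), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(name, path)
    path
  }
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      marker <- file.path(cfg$out_dir, "FAILED")
      writeLines(paste0(label, ": ", conditionMessage(e)), marker)
      gp_stop("pipeline stage '", label, "' failed: ", conditionMessage(e))
    })
  }
  note("seed: %d", cfg$seed)
  note("alpha: %g; min_score: %g; top_seeds: %d; min_jaccard: %g",
       cfg$alpha, cfg$min_score, cfg$top_seeds, cfg$min_jaccard)

  geno <- stage("read_genotypes", read_genotypes(cfg$genotypes))
  if (!is.null(cfg$annotation))
    geno <- stage("annotate_genotypes",
                  annotate_genotypes(geno, read_snp_annotation(cfg$annotation)))
  inter <- stage("read_interactions",
                 read_interactions(cfg$interactions, cfg$min_score))
  db <- stage("read_gmt", read_gmt(cfg$gmt))
  note("inputs: %d samples x %d SNPs; %d interactions; %d gene sets",
       length(geno$samples), nrow(geno$snps), nrow(inter), length(db))
  scaffold <- stage("pathway_graph", pathway_graph(db, cfg$min_jaccard))

  snp_sets <- list(); m1_paths <- list(); m2_paths <- list()
  skipped <- character()
  for (ct in cfg$contrasts) {
    case <- ct[[1]]; ctrl <- ct[[2]]
    label <- paste0(case, "_vs_", ctrl)
    qc <- stage(paste0(label, ":qc"), qc_filter(
      geno, ctrl, cfg$qc$max_snp_missing_rate, cfg$qc$min_maf,
      cfg$qc$min_hwe_p))
    save_tsv(qc$report, paste0(label, ".qc"))
    assoc <- stage(paste0(label, ":association"), run_association(
      geno, case, ctrl, alpha = cfg$alpha, snps = qc$kept))
    save_tsv(assoc, paste0(label, ".assoc"))
    snp_sets[[case]] <- assoc$snp_id
    genes <- unique(assoc$locus[!is.na(assoc$locus)])
    if (length(genes) == 0) genes <- assoc$snp_id
    writeLines(genes, gl_path <- file.path(cfg$out_dir,
                                           paste0(label, ".genes.txt")))
    emit(paste0(label, ".genes"), gl_path)
    note("%s: %d SNPs kept by QC, %d significant, %d genes",
         label, length(qc$kept), nrow(assoc), length(genes))
    if (nrow(assoc) < cfg$min_snps) {
      warning("contrast ", label, " has fewer than ", cfg$min_snps,
              " significant SNPs; downstream stages skipped", call. = FALSE)
      skipped <- c(skipped, label)
      next
    }

    # Method 1: pathway-first route
    m1 <- tryCatch({
      seeds_tab <- enrich_sets(genes, db, top = cfg$top_seeds)
      save_tsv(seeds_tab, paste0(label, ".m1.seed_pathways"))
      comp <- complementary_network(seeds_tab$set_id, scaffold)
      save_tsv(comp$nodes, paste0(label, ".m1.pathway_nodes"))
      save_tsv(comp$edges, paste0(label, ".m1.pathway_edges"))
      pg <- ppa_graph(data.frame(node = comp$nodes$pathway,
                                 role = comp$nodes$role),
                      data.frame(from = comp$edges$from, to = comp$edges$to,
                                 confidence = comp$edges$weight))
      comm <- edge_betweenness_communities(pg)
      save_tsv(data.frame(pathway = names(comm$membership),
                          cluster = comm$membership),
               paste0(label, ".m1.communities"))
      comp$nodes$pathway
    }, gwaspathnet_error = function(e) {
      note("%s: pathway-first route skipped (%s)", label,
           conditionMessage(e))
      NULL
    })
    if (!is.null(m1)) m1_paths[[case]] <- m1

    # Method 2: protein-first route
    m2 <- tryCatch({
      prots <- map_genes_to_proteins(genes, cfg$alias_table)
      net <- expand_seed_network(inter, prots, cfg$caps, cfg$min_score)
      save_tsv(net$edges, paste0(label, ".m2.network_edges"))
      save_tsv(net$nodes, paste0(label, ".m2.network_nodes"))
      ranks <- rank_nodes(combined_score(net, cfg$weights))
      save_tsv(ranks, paste0(label, ".m2.ranked_proteins"))
      clu <- mcl_cluster(net, cfg$mcl)
      save_tsv(data.frame(node = names(clu$membership),
                          cluster = clu$membership),
               paste0(label, ".m2.clusters"))
      pr <- pathway_rank(db, setNames(ranks$combined, ranks$node))
      save_tsv(pr, paste0(label, ".m2.ranked_pathways"))
      note("%s: network %d nodes / %d edges, %d clusters, %d pathways",
           label, nrow(net$nodes), nrow(net$edges), clu$n_clusters, nrow(pr))
      pr$set_id
    }, gwaspathnet_error = function(e) {
      note("%s: protein-first route skipped (%s)", label,
           conditionMessage(e))
      NULL
    })
    if (!is.null(m2)) m2_paths[[case]] <- m2

    if (!is.null(m1) && !is.null(m2)) {
      mm <- merge_methods(m1, m2)
      save_tsv(data.frame(
        pathway = c(mm$common, mm$only_m1, mm$only_m2),
        region = rep(c("common", "only_m1", "only_m2"),
                     c(length(mm$common), length(mm$only_m1),
                       length(mm$only_m2)))),
        paste0(label, ".methods_merge"))
    }
  }

  # cross-contrast SNP comparisons, pairwise
  cases <- names(snp_sets)
  if (length(cases) >= 2) {
    for (pr in combn(cases, 2, simplify = FALSE)) {
      reg <- venn_regions(snp_sets[pr])
      save_tsv(data.frame(region = names(reg), n = lengths(reg),
                          members = vapply(reg, paste, "", collapse = ",")),
               paste0("venn.", pr[1], "_", pr[2]))
    }
  }

  # disease-disease network over merged pathway profiles
  profiles <- lapply(union(names(m1_paths), names(m2_paths)), function(case) {
    union(m1_paths[[case]], m2_paths[[case]])
  })
  names(profiles) <- union(names(m1_paths), names(m2_paths))
  profiles <- profiles[lengths(profiles) > 0]
  if (length(profiles) >= 2) {
    dd <- disease_network(profiles)
    save_tsv(dd$edges, "disease_network_edges")
    save_tsv(dd$nodes, "disease_network_nodes")
  }

  log_path <- file.path(cfg$out_dir, "run.log")
  writeLines(logs, log_path)
  emit("run.log", log_path)
  paths <- unlist(files)
  manifest <- list(
    files = data.frame(name = names(paths), path = unname(paths),
                       md5 = unname(tools::md5sum(paths)),
                       row.names = NULL),
    skipped = skipped, seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
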