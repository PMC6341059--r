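#' Default analysis configuration
#'
#' A nested list with one block per analysis stage; values can be overridden
#' by `modifyList()` or by the YAML file consumed by [read_config()].
#'
#' @param seed Master seed used by every stochastic stage.
#' @return Named list of parameter blocks.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    autosomes_only = TRUE,
    simulate = TRUE,              # generate the inputs with synth_params()
    synth = list(),               # overrides for synth_params()
    inputs = list(),              # external paths when simulate = FALSE
    caller = list(b = 200, q_max = 0.01, min_sep = 2),
    ice = list(max_iter = 200, tol = 1e-5),
    # the bundled synthetic genome plants 50 kb compartment blocks and
    # 40-75 kb TADs, so both analyses run at the map resolution; on real
    # 5 kb data the conventional choice is working_res = 1e5
    compartments = list(working_res = 5000),
    tads = list(w = 3, working_res = 5000),
    loops = list(upstream = 2000, downstream = 200),
    enrichment = list(fold = 5, pseudocount = 1),
    expression = list(min_total = 10),
    trans_sim = list(repetitions = 10000),
    shells = list(n_shells = 5, threshold = 500),
    structures = list(S = 200)
  )
}

#' Read / write the YAML analysis configuration
#' @param path YAML file.
#' @return Config list merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  utils::modifyList(cfg, user)
}

#' @rdname read_config
#' @param config Config list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(config)
}

stage_banner <- function(name) {
  message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
}

#' Run the full comparative analysis
#'
#' Executes, per condition: ICE balancing, distance-decay fitting, cis and
#' trans interaction calling, compartment tracks, TAD calling with majority
#' compartment labels; then across conditions: organ-enriched gene
#' designation, per-gene interaction counts with the log2-ratio rank-sum
#' test, compartment fractions and expression comparisons, anchor feature
#' annotation, the compartment-switch table with switch-stratified
#' expression, promoter-TES loops with gene-set enrichment, the trans overlap
#' table with Fisher test and random-gene simulation, A/B bridge
#' classification, and structure-population shell/neighbor profiles. Every
#' table is written as TSV under `out_dir` together with a JSON manifest.
#'
#' @param config From [default_config()] / [read_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with every computed object.
#' @export
run_full_analysis <- function(config = default_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)
  stage <- "setup"
  result <- tryCatch({
    run_stages(config, out_dir)
  }, error = function(e) {
    writeLines(paste("failed:", conditionMessage(e)), fail_marker)
    stop("pipeline aborted: ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}

run_stages <- function(config, out_dir) {
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  stage_banner("inputs")
  if (isTRUE(config$simulate)) {
    sp <- do.call(synth_params, c(list(seed = config$seed), config$synth))
    fixture <- make_fixture_genome(sp)
    mapX <- simulate_contact_map(fixture, "X")
    mapY <- simulate_contact_map(fixture, "Y")
    expr_raw <- simulate_expression_counts(fixture)
    genes <- fixture$genes
  } else {
    inp <- config$inputs
    mapX <- read_contact_map(inp$matrixX, inp$binsX, config$autosomes_only)
    mapY <- read_contact_map(inp$matrixY, inp$binsY, config$autosomes_only)
    genes <- read_gene_table(inp$genes, inp$gene_dialect %||% "tsv",
                             config$autosomes_only)
    cts <- as.matrix(read.table(inp$expression, header = TRUE, sep = "\t",
                                row.names = 1))
    expr_raw <- expression_table(cts, inp$expression_organs)
    fixture <- NULL
  }

  stage_banner("balancing")
  mapX <- ice_normalize(mapX, config$ice$max_iter, config$ice$tol)
  mapY <- ice_normalize(mapY, config$ice$max_iter, config$ice$tol)

  stage_banner("interaction calling")
  cp <- caller_params(config$caller$b, config$caller$q_max,
                      config$caller$min_sep)
  decayX <- fit_distance_decay(mapX, cp$b, cp$min_sep)
  decayY <- fit_distance_decay(mapY, cp$b, cp$min_sep)
  cisX <- call_cis_interactions(mapX, decayX, cp)
  cisY <- call_cis_interactions(mapY, decayY, cp)
  transX <- call_trans_interactions(mapX, cp)
  transY <- call_trans_interactions(mapY, cp)
  write_bedpe(cisX, file.path(out_dir, "cis_X.bedpe"))
  write_bedpe(cisY, file.path(out_dir, "cis_Y.bedpe"))
  write_bedpe(transX, file.path(out_dir, "trans_X.bedpe"))
  write_bedpe(transY, file.path(out_dir, "trans_Y.bedpe"))

  stage_banner("compartments")
  wres <- config$compartments$working_res
  trackX <- compartment_track(mapX, genes, wres)
  trackY <- compartment_track(mapY, genes, wres)
  write_compartment_track(trackX, file.path(out_dir, "eigen_X.bedgraph"),
                          file.path(out_dir, "compartments_X.bed"))
  write_compartment_track(trackY, file.path(out_dir, "eigen_Y.bedgraph"),
                          file.path(out_dir, "compartments_Y.bed"))
  sw <- compartment_switch(trackX, trackY)
  write_switch_table(sw, file.path(out_dir, "switch_bins.tsv"))
  tsv(data.frame(category = names(sw$percent), count = sw$counts,
                 percent = sw$percent), "switch_summary.tsv")

  stage_banner("TADs")
  tp <- tad_params(config$tads$w, config$tads$working_res)
  tadmapX <- ice_normalize(aggregate_contact_map(mapX, tp$working_res),
                           config$ice$max_iter, config$ice$tol)
  tadmapY <- ice_normalize(aggregate_contact_map(mapY, tp$working_res),
                           config$ice$max_iter, config$ice$tol)
  tadsX <- majority_compartment(call_tads(binsignal(tadmapX, tp$w), tp), trackX)
  tadsY <- majority_compartment(call_tads(binsignal(tadmapY, tp$w), tp), trackY)
  write_tads(tadsX, file.path(out_dir, "tads_X.tsv"))
  write_tads(tadsY, file.path(out_dir, "tads_Y.tsv"))

  stage_banner("expression and organ sets")
  expr <- normalize_expression(expr_raw, config$expression$min_total)
  ep <- enrichment_params(config$enrichment$fold, config$enrichment$pseudocount)
  sets <- designate_enriched(expr$normalized, ep)
  names(sets) <- paste0("set", names(sets))
  write_gmt(sets, file.path(out_dir, "organ_sets.gmt"))

  stage_banner("gene interaction ratios")
  cntX <- interactions_at_genes(cisX, genes)
  cntY <- interactions_at_genes(cisY, genes)
  ratio <- log2_ratio_by_geneset(cntX, cntY, sets$setX, sets$setY,
                                 ep$pseudocount)
  tsv(data.frame(gene = names(ratio$ratio), countX = cntX, countY = cntY,
                 log2_ratio = ratio$ratio), "gene_interaction_counts.tsv")
  tsv(data.frame(statistic = "ranksum_p_setX_vs_setY", value = ratio$p),
      "gene_ratio_test.tsv")

  stage_banner("compartment fractions and expression")
  gcX <- gene_compartment(genes, trackX)
  gcY <- gene_compartment(genes, trackY)
  frac <- rbind(
    data.frame(condition = "X", set = "setX",
               t(compartment_fractions(gcX, sets$setX))),
    data.frame(condition = "X", set = "setY",
               t(compartment_fractions(gcX, sets$setY))),
    data.frame(condition = "Y", set = "setX",
               t(compartment_fractions(gcY, sets$setX))),
    data.frame(condition = "Y", set = "setY",
               t(compartment_fractions(gcY, sets$setY))))
  tsv(frac, "compartment_fractions.tsv")
  groupsAB <- list(
    setX_A = list(genes = intersect(sets$setX, names(gcX)[gcX == "A" & !is.na(gcX)]),
                  organ = "X"),
    setX_B = list(genes = intersect(sets$setX, names(gcX)[gcX == "B" & !is.na(gcX)]),
                  organ = "X"),
    setY_A = list(genes = intersect(sets$setY, names(gcY)[gcY == "A" & !is.na(gcY)]),
                  organ = "Y"),
    setY_B = list(genes = intersect(sets$setY, names(gcY)[gcY == "B" & !is.na(gcY)]),
                  organ = "Y"))
  cmp_expr <- expression_by_group(expr, groupsAB)
  tsv(cmp_expr$summary, "expression_by_compartment_summary.tsv")
  tsv(cmp_expr$tests, "expression_by_compartment_tests.tsv")

  stage_banner("anchor features")
  lp <- loop_params(config$loops$upstream, config$loops$downstream)
  feat <- rbind(cbind(condition = "X", annotate_anchor_features(cisX, genes, lp)),
                cbind(condition = "Y", annotate_anchor_features(cisY, genes, lp)))
  tsv(feat, "anchor_features.tsv")

  stage_banner("switch-stratified expression")
  switched_AB <- names(gcX)[!is.na(gcX) & !is.na(gcY) & gcX == "A" & gcY == "B"]
  switched_BA <- names(gcX)[!is.na(gcX) & !is.na(gcY) & gcX == "B" & gcY == "A"]
  sw_groups <- list(
    AtoB_in_X = list(genes = switched_AB, organ = "X"),
    AtoB_in_Y = list(genes = switched_AB, organ = "Y"),
    BtoA_in_X = list(genes = switched_BA, organ = "X"),
    BtoA_in_Y = list(genes = switched_BA, organ = "Y"))
  sw_expr <- expression_by_group(expr, sw_groups)
  tsv(sw_expr$summary, "switch_expression_summary.tsv")
  tsv(sw_expr$tests, "switch_expression_tests.tsv")

  stage_banner("promoter-TES loops")
  loopsX <- promoter_tes_loops(cisX, genes, lp)
  loopsY <- promoter_tes_loops(cisY, genes, lp)
  universe <- genes$genes$id
  enr <- rbind(
    cbind(condition = "X",
          geneset_enrichment(loopsX, sets, universe)),
    cbind(condition = "Y",
          geneset_enrichment(loopsY, sets, universe)))
  tsv(data.frame(condition = c(rep("X", length(loopsX)),
                               rep("Y", length(loopsY))),
                 gene = c(loopsX, loopsY)), "loop_genes.tsv")
  tsv(enr, "loop_enrichment.tsv")

  stage_banner("trans statistics")
  ttab <- trans_overlap_table(transX, transY, sets$setX, sets$setY, genes)
  tfish <- fisher_exact(ttab)
  sim <- random_gene_simulation(transX, transY, length(sets$setX),
                                length(sets$setY), genes,
                                trans_sim_params(config$trans_sim$repetitions,
                                                 config$seed))
  tsv(data.frame(condition = rownames(ttab), ttab,
                 check.names = FALSE), "trans_overlap.tsv")
  tsv(data.frame(statistic = c("fisher_p", "odds_ratio",
                               "sim_fisher_p", "sim_repetitions"),
                 value = c(tfish$p, tfish$odds_ratio, sim$fisher$p,
                           sim$repetitions)), "trans_tests.tsv")
  tsv(data.frame(condition = rownames(sim$median_table), sim$median_table,
                 check.names = FALSE), "trans_sim_median.tsv")

  stage_banner("bridges")
  brX <- classify_bridges(transX, trackX)
  brY <- classify_bridges(transY, trackY)
  tsv(data.frame(condition = c("X", "Y"),
                 AA = c(brX$counts["AA"], brY$counts["AA"]),
                 BB = c(brX$counts["BB"], brY$counts["BB"]),
                 AB = c(brX$counts["AB"], brY$counts["AB"]),
                 AB_fraction = c(brX$fractions["AB"], brY$fractions["AB"]),
                 excluded = c(brX$excluded, brY$excluded)), "bridges.tsv")

  stage_banner("structures")
  shp <- shell_params(config$shells$n_shells, config$shells$threshold)
  if (isTRUE(config$simulate)) {
    popX <- simulate_structure_population(fixture, tadsX,
                                          config$structures$S)
    popY <- simulate_structure_population(fixture, tadsY,
                                          config$structures$S)
  } else {
    popX <- read_structure_population(config$inputs$structuresX, tadsX,
                                      config$inputs$R_nuc)
    popY <- read_structure_population(config$inputs$structuresY, tadsY,
                                      config$inputs$R_nuc)
  }
  profX <- shell_localization_profile(popX, tadsX$label, shp)
  profY <- shell_localization_profile(popY, tadsY$label, shp)
  write_shell_profile(profX, file.path(out_dir, "shell_profile_X.tsv"))
  write_shell_profile(profY, file.path(out_dir, "shell_profile_Y.tsv"))
  nbX <- trans_neighbor_composition(popX, tadsX$label, shp)
  nbY <- trans_neighbor_composition(popY, tadsY$label, shp)
  tsv(rbind(cbind(condition = "X", nbX$composition),
            cbind(condition = "Y", nbY$composition)),
      "trans_neighbor_composition.tsv")
  gshX <- gene_shell_profile(popX, genes, sets, shp)
  write_shell_profile(gshX, file.path(out_dir, "gene_shell_profile_X.tsv"))
  gshY <- gene_shell_profile(popY, genes, sets, shp)
  write_shell_profile(gshY, file.path(out_dir, "gene_shell_profile_Y.tsv"))
  tsv(radial_profile_table(popX), "radial_positions_X.tsv")
  tsv(radial_profile_table(popY), "radial_positions_Y.tsv")

  stage_banner("manifest")
  manifest <- list(package = "chromarch",
                   version = as.character(utils::packageVersion("chromarch")),
                   seed = config$seed,
                   config = config,
                   n_cis_X = nrow(cisX$records), n_cis_Y = nrow(cisY$records),
                   n_trans_X = nrow(transX$records),
                   n_trans_Y = nrow(transY$records))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(mapX = mapX, mapY = mapY, cisX = cisX, cisY = cisY,
                 transX = transX, transY = transY, trackX = trackX,
                 trackY = trackY, switch = sw, tadsX = tadsX, tadsY = tadsY,
                 expr = expr, sets = sets, counts = list(X = cntX, Y = cntY),
                 ratio = ratio, fractions = frac, anchor_features = feat,
                 loops = list(X = loopsX, Y = loopsY), enrichment = enr,
                 trans_table = ttab, trans_fisher = tfish, trans_sim = sim,
                 bridges = list(X = brX, Y = brY),
                 pops = list(X = popX, Y = popY),
                 shell_profiles = list(X = profX, Y = profY),
                 neighbors = list(X = nbX, Y = nbY)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
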