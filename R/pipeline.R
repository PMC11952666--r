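.pipeline_schema <- function() list(
  seed = "integer",
  out_dir = "character",
  simdata = names(formals(sim_config)),
  preprocess = c("already_log2", "imputation", "min_nonmissing_per_group"),
  diffabund = c("mode", "fdr_cut", "p_cut", "sd_multiple", "sd_method",
                "n_perm"),
  kinases = c("top_n", "ranking_key", "w", "n_rounds", "lambda",
              "stable_fraction", "pca_screen"),
  comodules = c("min_size", "merge_cut", "powers", "r2_target",
                "max_mean_k", "mm_cut", "ps_cut", "max_missing"),
  enrich = c("gmt", "n_perm", "min_size", "max_size", "p_cut", "q_cut")
)

#' Validate a pipeline configuration
#'
#' Flat two-level structure: top-level keys `seed`, `out_dir` and one
#' section per stage. Unknown keys raise an error naming the key.
#'
#' @param config nested list, or path to a YAML file.
#' @return the validated config (with defaults filled in).
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  schema <- .pipeline_schema()
  bad <- setdiff(names(config), names(schema))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (section in intersect(names(config), names(schema))) {
    if (section %in% c("seed", "out_dir")) next
    extra <- setdiff(names(config[[section]]), schema[[section]])
    if (length(extra)) {
      stop("unknown config key(s) in section '", section, "': ",
           paste(extra, collapse = ", "))
    }
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$out_dir)) stop("config must set out_dir")
  config
}

.stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(paste0("stage ", name, " failed: ", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes, in order: data simulation, preprocessing, protein and
#' phosphosite differential abundance, protein-level normalization,
#' kinase-substrate scoring and activity inference, signed co-expression
#' modules, and (when a GMT is configured) over-representation of the
#' differential proteins. Every stage writes its TSV outputs plus a
#' `.prov.json` provenance sidecar into `out_dir`; a run summary is
#' written as `summary.json` and returned.
#'
#' @param config nested list or YAML path, see [validate_config()].
#' @return list of class `pipeline_result` with the per-stage results and
#'   the summary.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(out_dir, "FAILED"))
  seed <- as.integer(config$seed)

  ## --- simulate -----------------------------------------------------------
  study <- .stage("simdata", out_dir, {
    cfg <- do.call(sim_config, c(config$simdata,
                                 if (is.null(config$simdata$seed))
                                   list(seed = seed)))
    study <- simulate_study(cfg)
    write_intensity_tsv(study$proteome$matrix,
                        file.path(out_dir, "proteome.tsv"))
    write_tsv(study$proteome$metadata, file.path(out_dir, "metadata.tsv"))
    write_intensity_tsv(study$phospho$matrix,
                        file.path(out_dir, "phospho.tsv"))
    write_tsv(study$phospho$site_table, file.path(out_dir, "sites.tsv"))
    write_tsv(study$phospho$annotation, file.path(out_dir, "annotation.tsv"))
    write_pssm_tsv(study$kinase_models, file.path(out_dir, "pssm.tsv"))
    jsonlite::write_json(
      list(de_labels = as.list(study$proteome$truth$de_labels),
           kinase_shifts = as.list(study$phospho$truth$kinase_shifts),
           module_labels = as.list(study$proteome$truth$module_labels),
           substrate_map = study$phospho$truth$substrate_map),
      file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE)
    for (f in c("proteome.tsv", "phospho.tsv", "metadata.tsv", "sites.tsv",
                "annotation.tsv", "pssm.tsv")) {
      write_provenance(file.path(out_dir, f), "simdata", unclass(cfg))
    }
    study
  })
  groups <- factor(study$proteome$metadata$group,
                   levels = c("control", "mutant"))
  trait <- study$proteome$metadata$trait

  ## --- preprocess ---------------------------------------------------------
  pp <- config$preprocess
  prot <- .stage("preprocess", out_dir, {
    do.call(preprocess, c(list(x = study$proteome$matrix, groups = groups,
                               already_log2 = TRUE), pp[names(pp) != "already_log2"]))
  })
  phos <- .stage("preprocess", out_dir, {
    do.call(preprocess, c(list(x = study$phospho$matrix, groups = groups,
                               already_log2 = TRUE), pp[names(pp) != "already_log2"]))
  })

  ## --- differential abundance --------------------------------------------
  da_cfg <- config$diffabund
  spec <- threshold_spec(
    fdr_cut = da_cfg$fdr_cut %||% 0.05, p_cut = da_cfg$p_cut %||% 0.05,
    sd_multiple = da_cfg$sd_multiple %||% 2,
    mode = da_cfg$mode %||% "fdr_and_fc"
  )
  n_perm <- da_cfg$n_perm %||% 200L
  sd_method <- da_cfg$sd_method %||% "gaussian"
  da_prot <- .stage("diffabund", out_dir, {
    r <- diff_abundance(prot, groups, spec, sd_method = sd_method,
                        run_permutation = TRUE, n_perm = n_perm, seed = seed)
    write_tsv(r$stats, file.path(out_dir, "protein_stats.tsv"))
    write_provenance(file.path(out_dir, "protein_stats.tsv"), "diffabund",
                     c(unclass(spec), list(sd_method = sd_method,
                                           n_perm = n_perm, seed = seed)),
                     file.path(out_dir, "proteome.tsv"))
    r
  })
  da_phos <- .stage("diffabund", out_dir, {
    r <- diff_abundance(phos, groups, spec, sd_method = sd_method,
                        run_permutation = TRUE, n_perm = n_perm, seed = seed)
    write_tsv(r$stats, file.path(out_dir, "phospho_stats.tsv"))
    write_provenance(file.path(out_dir, "phospho_stats.tsv"), "diffabund",
                     c(unclass(spec), list(sd_method = sd_method,
                                           n_perm = n_perm, seed = seed)),
                     file.path(out_dir, "phospho.tsv"))
    r
  })

  ## --- kinases ------------------------------------------------------------
  kin_cfg <- config$kinases
  kin <- .stage("kinases", out_dir, {
    norm <- normalize_site_by_protein(phos, prot, study$phospho$site_table,
                                      groups)
    scores <- kinase_substrate_score(
      norm$diff_matrix, study$phospho$site_table, study$kinase_models,
      study$phospho$annotation, w = kin_cfg$w %||% 0.5,
      n_rounds = kin_cfg$n_rounds %||% 50L, seed = seed,
      lambda = kin_cfg$lambda %||% 0.01
    )
    top_n <- kin_cfg$top_n %||% 400L
    key <- kin_cfg$ranking_key %||% "pu_probability"
    act <- do.call(rbind, lapply(names(study$kinase_models), function(k) {
      subs <- rank_top_substrates(scores, k, n = top_n, key = key)
      kinase_activity(norm$stats, subs, kinase = k)
    }))
    write_tsv(scores, file.path(out_dir, "substrate_scores.tsv"))
    write_tsv(act, file.path(out_dir, "kinase_activity.tsv"))
    write_tsv(norm$stats, file.path(out_dir, "site_norm_stats.tsv"))
    for (f in c("substrate_scores.tsv", "kinase_activity.tsv",
                "site_norm_stats.tsv")) {
      write_provenance(file.path(out_dir, f), "kinases",
                       list(top_n = top_n, ranking_key = key,
                            w = kin_cfg$w %||% 0.5,
                            n_rounds = kin_cfg$n_rounds %||% 50L,
                            seed = seed),
                       file.path(out_dir, c("phospho.tsv", "proteome.tsv")))
    }
    list(norm = norm, scores = scores, activity = act)
  })

  ## --- co-expression modules ----------------------------------------------
  cm_cfg <- config$comodules
  cm <- .stage("comodules", out_dir, {
    r <- build_coexpression(
      prot, trait,
      powers = cm_cfg$powers %||% 1:20,
      r2_target = cm_cfg$r2_target %||% 0.85,
      max_mean_k = cm_cfg$max_mean_k %||% 100,
      min_size = cm_cfg$min_size %||% 50L,
      merge_cut = cm_cfg$merge_cut %||% 0.25,
      mm_cut = cm_cfg$mm_cut %||% 0.8,
      ps_cut = cm_cfg$ps_cut %||% 0.5,
      max_missing = cm_cfg$max_missing %||% 0.2
    )
    write_tsv(r$membership, file.path(out_dir, "module_membership.tsv"))
    write_tsv(r$trait_stats, file.path(out_dir, "module_trait.tsv"))
    write_tsv(r$scan$table, file.path(out_dir, "soft_threshold_scan.tsv"))
    me <- data.frame(module = rownames(r$modules$eigengenes),
                     r$modules$eigengenes, check.names = FALSE)
    write_tsv(me, file.path(out_dir, "eigengenes.tsv"))
    for (f in c("module_membership.tsv", "module_trait.tsv",
                "soft_threshold_scan.tsv", "eigengenes.tsv")) {
      write_provenance(file.path(out_dir, f), "comodules",
                       c(r$params, list(power = r$power)),
                       file.path(out_dir, "proteome.tsv"))
    }
    r
  })

  ## --- enrichment (optional) ----------------------------------------------
  enr <- NULL
  if (!is.null(config$enrich$gmt)) {
    enr <- .stage("enrich", out_dir, {
      sets <- read_gmt(config$enrich$gmt)
      universe <- da_prot$stats$feature_id
      query <- da_prot$stats$feature_id[da_prot$stats$call != "null"]
      ora <- ora_test(query, sets, universe,
                      p_cut = config$enrich$p_cut %||% 0.05,
                      q_cut = config$enrich$q_cut %||% 0.05)
      ranking <- stats::setNames(da_prot$stats$log2fc,
                                 da_prot$stats$feature_id)
      gsea <- gsea_score(ranking, sets,
                         n_perm = config$enrich$n_perm %||% 1000L,
                         seed = seed,
                         min_size = config$enrich$min_size %||% 10L,
                         max_size = config$enrich$max_size %||% 500L)
      write_tsv(ora, file.path(out_dir, "ora.tsv"))
      write_tsv(gsea, file.path(out_dir, "gsea.tsv"))
      for (f in c("ora.tsv", "gsea.tsv")) {
        write_provenance(file.path(out_dir, f), "enrich",
                         c(config$enrich, list(seed = seed)),
                         file.path(out_dir, "protein_stats.tsv"))
      }
      list(ora = ora, gsea = gsea)
    })
  }

  summary <- list(
    seed = seed,
    proteins = da_prot$summary[c("n_up", "n_down", "n_detected")],
    protein_sd_hat = da_prot$sd_hat,
    protein_perm_fdr = da_prot$permutation$fdr_est,
    phosphosites = da_phos$summary[c("n_up", "n_down", "n_detected")],
    phospho_sd_hat = da_phos$sd_hat,
    kinase_directions = stats::setNames(kin$activity$direction,
                                        kin$activity$kinase),
    chosen_power = cm$power,
    n_modules = length(cm$modules$sizes),
    top_module_trait_r = if (nrow(cm$trait_stats)) {
      cm$trait_stats$r[which.max(abs(cm$trait_stats$r))]
    } else NA_real_,
    top_enrichment = if (!is.null(enr) && nrow(enr$ora)) {
      utils::head(enr$ora$term[enr$ora$significant], 5L)
    } else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  structure(list(study = study, protein = da_prot, phospho = da_phos,
                 kinases = kin, comodules = cm, enrichment = enr,
                 summary = summary),
            class = "pipeline_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
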