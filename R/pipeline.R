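#' Read and validate a run configuration
#'
#' The configuration is a YAML file (or an equivalent list) with blocks
#' `inputs` (paths to the three TPM tables, the ortholog triples, and
#' optionally divergence, interactions, obo and annotations files),
#' `species` (three blocks with `name`, `days_to_anthesis`,
#' `divergence_my`), `thresholds` (`expression_filter` 2, `top_fraction`
#' 0.01, `enrichment_alpha` 0.01, `node_size` 10, `n_permutations` 1000),
#' plus `pseudocount`, `profile_scale` (`log` or `raw`), `seed` and
#' `outdir`. Relative input paths are resolved against the config file's
#' directory.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return validated config list.
#' @export
readRunConfig <- function(config) {
  base <- "."
  if (is.character(config)) {
    base <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path")
  defaults <- list(expression_filter = 2, top_fraction = 0.01,
                   enrichment_alpha = 0.01, node_size = 10,
                   n_permutations = 1000)
  config$thresholds <- modifyList(defaults, config$thresholds %||% list())
  config$pseudocount <- config$pseudocount %||% 1
  config$profile_scale <- config$profile_scale %||% "log"
  config$seed <- config$seed %||% 1L
  config$outdir <- config$outdir %||% "results"
  if (is.null(config$species) || length(config$species) != 3L) {
    stop("config must define exactly three species blocks")
  }
  for (sp in config$species) {
    if (is.null(sp$name) || is.null(sp$days_to_anthesis) ||
        is.null(sp$divergence_my)) {
      stop("each species block needs name, days_to_anthesis, divergence_my")
    }
  }
  th <- config$thresholds
  if (th$top_fraction <= 0 || th$top_fraction > 1 ||
      th$enrichment_alpha <= 0 || th$enrichment_alpha > 1 ||
      th$node_size < 1 || th$n_permutations < 1) {
    stop("thresholds out of range")
  }
  if (is.null(config$inputs$tpm) || length(config$inputs$tpm) != 3L) {
    stop("config must list three TPM tables under inputs$tpm")
  }
  if (is.null(config$inputs$triples)) {
    stop("config must name the ortholog triple table under inputs$triples")
  }
  resolve <- function(p) {
    ifelse(is.na(p) | grepl("^/", p), p, file.path(base, p))
  }
  for (key in c("triples", "divergence", "interactions", "obo",
                "annotations")) {
    if (!is.null(config$inputs[[key]])) {
      config$inputs[[key]] <- resolve(config$inputs[[key]])
    }
  }
  config$inputs$tpm <- resolve(unlist(config$inputs$tpm))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the LED analysis pipeline end-to-end
#'
#' Executes: expression ingestion and filtering, profile construction, LED
#' computation, per-generation scaling, pairwise distribution tests,
#' genic-property correlations and Poisson regression, primary-tissue
#' enrichment of the top LED fraction, and (when GO inputs are configured)
#' rank-based GO enrichment. All outputs are written as TSV into `outdir`
#' together with a run manifest; a rerun with identical config and inputs
#' reproduces identical files.
#'
#' @param config a config list or YAML path (see [readRunConfig()]).
#' @param outdir overrides the config's output directory when non-NULL.
#' @return invisibly, a list with every intermediate result (led table,
#'   scales, test tables, enrichment tables, manifest).
#' @export
runPipeline <- function(config, outdir = NULL) {
  config <- readRunConfig(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  seed <- as.integer(config$seed)
  sp_names <- vapply(config$species, `[[`, character(1L), "name")

  tables <- .stage("read_expression", {
    tabs <- vector("list", 3L)
    tiss <- NULL
    for (k in 1:3) {
      tabs[[k]] <- readTpmTable(config$inputs$tpm[k], sp_names[k],
                                tissues = tiss)
      if (k == 1L) tiss <- tissues(tabs[[1L]])
    }
    tabs
  })
  triples <- .stage("read_triples", readOrthologTriples(config$inputs$triples))

  led <- .stage("led", .ledTable(
    tables, triples, threshold = th$expression_filter,
    pseudocount = config$pseudocount, scale = config$profile_scale
  ))
  writeTsv(led, file.path(outdir, "led.tsv"))

  scales <- .stage("generation_scaling", branchScale(
    sp_names,
    vapply(config$species, `[[`, numeric(1L), "days_to_anthesis"),
    vapply(config$species, `[[`, numeric(1L), "divergence_my")
  ))
  led_pg <- scalePerGeneration(led, scales)
  names(led_pg) <- c("led_pg_x", "led_pg_y", "led_pg_z")
  writeTsv(cbind(led["triple_id"], led_pg),
           file.path(outdir, "led_per_generation.tsv"))

  dist_tests <- .stage("distribution_tests", {
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    rows <- list()
    for (sc in c("led", "led_per_generation")) {
      cols <- if (sc == "led") led[c("led_x", "led_y", "led_z")] else led_pg
      for (i in seq_along(pairs)) {
        pr <- pairs[[i]]
        res <- permutationTestMedianDiff(
          cols[[pr[1L]]], cols[[pr[2L]]], n_perm = th$n_permutations,
          seed = deriveSeed(seed, 10L + i + ifelse(sc == "led", 0L, 3L))
        )
        rows[[length(rows) + 1L]] <- data.frame(
          scale = sc, species_a = sp_names[pr[1L]], species_b = sp_names[pr[2L]],
          observed_stat = res$observed_stat, p_value = res$p_value,
          n_permutations = res$n_permutations
        )
      }
    }
    do.call(rbind, rows)
  })
  writeTsv(dist_tests, file.path(outdir, "distribution_tests.tsv"))

  divergence <- if (!is.null(config$inputs$divergence)) {
    .stage("read_divergence", readDivergenceTable(config$inputs$divergence))
  }
  interactions <- if (!is.null(config$inputs$interactions)) {
    .stage("read_interactions", readInteractions(config$inputs$interactions))
  }

  gene_cols <- c("gene_x", "gene_y", "gene_z")
  led_cols <- c("led_x", "led_y", "led_z")
  ## divergence/interaction tables legitimately cover all three species'
  ## genes; the per-species join would message about the other two thirds
  correlates <- .stage("correlates", suppressMessages(lapply(1:3, function(k) {
    genes <- led[[gene_cols[k]]]
    genicCorrelates(
      genes,
      tau = tissueSpecificity(tables[[k]], genes,
                              pseudocount = config$pseudocount),
      primary = primaryTissues(tables[[k]], genes),
      divergence = divergence, interactions = interactions
    )
  })))

  cor_tab <- .stage("correlations", {
    props <- c("tau", "tree_branch_length", "ka", "ka_ks")
    rows <- list()
    for (k in 1:3) {
      for (prop in intersect(props, names(correlates[[k]]))) {
        for (m in c("pearson", "spearman")) {
          v <- correlates[[k]][[prop]]
          if (sum(complete.cases(v, led[[led_cols[k]]])) < 3L) next
          res <- correlationTest(led[[led_cols[k]]], v, method = m)
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp_names[k], property = prop, method = m,
            r = res$r, t_stat = res$t_stat, p_value = res$p_value, n = res$n
          )
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  if (!is.null(cor_tab)) writeTsv(cor_tab, file.path(outdir, "correlations.tsv"))

  poisson_tab <- if (!is.null(interactions)) .stage("poisson", {
    rows <- lapply(1:3, function(k) {
      cc <- complete.cases(correlates[[k]]$interaction_count)
      fit <- fitPoissonRegression(correlates[[k]]$interaction_count[cc],
                                  led[[led_cols[k]]][cc])
      data.frame(species = sp_names[k], beta0 = fit$beta0, beta1 = fit$beta1,
                 se1 = fit$se1, wald_p = fit$wald_p,
                 residual_deviance = fit$residual_deviance, gof_p = fit$gof_p,
                 converged = fit$converged, n = fit$n)
    })
    do.call(rbind, rows)
  })
  if (!is.null(poisson_tab)) {
    writeTsv(poisson_tab, file.path(outdir, "poisson.tsv"))
  }

  tissue_tab <- .stage("tissue_enrichment", {
    rows <- lapply(1:3, function(k) {
      scores <- setNames(led[[led_cols[k]]], led[[gene_cols[k]]])
      top <- selectTopFraction(scores, th$top_fraction)
      primary <- correlates[[k]]$primary_tissue
      names(primary) <- correlates[[k]]$gene
      enr <- tissueEnrichment(primary[top], primary,
                              tissues = tissues(tables[[k]]))
      cbind(species = sp_names[k], n_top = length(top), enr$table,
            chi2_stat = enr$statistic, chi2_df = enr$df, chi2_p = enr$p_value)
    })
    do.call(rbind, rows)
  })
  writeTsv(tissue_tab, file.path(outdir, "tissue_enrichment.tsv"))

  go_tab <- NULL
  if (!is.null(config$inputs$obo) && !is.null(config$inputs$annotations)) {
    go_tab <- .stage("go_enrichment", {
      dag <- parseOboSubset(config$inputs$obo)
      ann <- propagateAnnotations(dag, readAnnotations(config$inputs$annotations))
      scores <- unlist(lapply(1:3, function(k) {
        setNames(led[[led_cols[k]]], led[[gene_cols[k]]])
      }))
      ann <- ann[ann$gene %in% names(scores), , drop = FALSE]
      attr(ann, "propagated") <- TRUE
      res <- ksEnrichment(dag, ann, scores, node_size = th$node_size)
      res$significant <- res$p_value < th$enrichment_alpha
      res
    })
    writeTsv(go_tab, file.path(outdir, "go_enrichment.tsv"))
  }

  manifest <- list(
    package = as.character(packageVersion("LEDtools")),
    seed = seed,
    species = as.list(sp_names),
    thresholds = th,
    counts = list(
      triples_in = nrow(triples),
      triples_failing_filter = as.list(attr(led, "dropped")),
      triples_retained = nrow(led),
      top_fraction_size = ceiling(th$top_fraction * nrow(led)),
      go_terms_tested = if (!is.null(go_tab)) nrow(go_tab) else 0L,
      go_terms_significant = if (!is.null(go_tab)) sum(go_tab$significant) else 0L
    )
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(
    config = config, tables = tables, led = led, led_per_generation = led_pg,
    scales = scales, distribution_tests = dist_tests,
    correlates = correlates, correlations = cor_tab, poisson = poisson_tab,
    tissue_enrichment = tissue_tab, go_enrichment = go_tab,
    manifest = manifest
  ))
}
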