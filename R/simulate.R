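#' Configuration for the three-species expression simulator
#'
#' The generator emulates the statistical structure the LED analysis
#' assumes: per gene, an ancestral log2-expression vector over tissues;
#' independent Gaussian drift along each lineage with per-tissue standard
#' deviation sqrt(branch_length), so squared profile distance grows roughly
#' linearly with branch length; and, for a small fraction of genes, a large
#' single-tissue, single-lineage expression shift.
#'
#' @param n_genes number of ortholog triples; default 11142 (the scale of a
#'   grass 1:1:1 ortholog set).
#' @param tissues tissue names; default the nine tissues of the grass
#'   expression atlas design (leaf, inflorescence stages, anther, pistil,
#'   seed stages, embryo, endosperm).
#' @param species three species identifiers (lineages x, y, z).
#' @param branch_lengths per-lineage drift variances (per tissue, log2
#'   scale); default c(0.25, 0.25, 0.30), mirroring two sister lineages and
#'   a slightly older outgroup.
#' @param shift_fraction fraction of genes receiving a planted
#'   lineage-specific shift; default 0.01.
#' @param shift_magnitude size of the planted shift in log2 units; default 5
#'   (a 32-fold single-tissue change, 10 drift SDs at the default branch
#'   lengths).
#' @param shift_lineage_weights probabilities of assigning a shift to each
#'   lineage; must sum to 1.
#' @param shift_tissue tissue receiving the shift, or `"random"` to pick a
#'   tissue per gene; default `"anther"`.
#' @param baseline_mean per-tissue mean ancestral log2 expression (scalar or
#'   length-T); default 5.
#' @param baseline_sd SD of ancestral log2 expression across genes; default 2.
#' @param noise_sd SD of additive measurement noise on the TPM scale;
#'   default 0.1.
#' @param seed integer seed; all simulator randomness derives from it.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_genes = 11142,
                             tissues = c("leaf", "early_inflorescence",
                                         "emerging_inflorescence", "anther",
                                         "pistil", "seed_5dap", "seed_10dap",
                                         "embryo", "endosperm"),
                             species = c("species_x", "species_y", "species_z"),
                             branch_lengths = c(0.25, 0.25, 0.30),
                             shift_fraction = 0.01,
                             shift_magnitude = 5,
                             shift_lineage_weights = rep(1 / 3, 3),
                             shift_tissue = "anther",
                             baseline_mean = 5,
                             baseline_sd = 2,
                             noise_sd = 0.1,
                             seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), tissues = as.character(tissues),
    species = as.character(species), branch_lengths = branch_lengths,
    shift_fraction = shift_fraction, shift_magnitude = shift_magnitude,
    shift_lineage_weights = shift_lineage_weights,
    shift_tissue = shift_tissue,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    noise_sd = noise_sd, seed = as.integer(seed)
  )
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (length(cfg$tissues) < 2L || anyDuplicated(cfg$tissues)) {
    stop("tissues must be >= 2 unique names")
  }
  if (length(cfg$species) != 3L || anyDuplicated(cfg$species)) {
    stop("exactly three distinct species are required")
  }
  if (length(cfg$branch_lengths) != 3L || any(cfg$branch_lengths <= 0)) {
    stop("branch_lengths must be three positive values")
  }
  if (cfg$shift_fraction < 0 || cfg$shift_fraction >= 1) {
    stop("shift_fraction must be in [0, 1)")
  }
  if (cfg$shift_magnitude <= 0) stop("shift_magnitude must be positive")
  if (length(cfg$shift_lineage_weights) != 3L ||
      any(cfg$shift_lineage_weights < 0) ||
      abs(sum(cfg$shift_lineage_weights) - 1) > 1e-9) {
    stop("shift_lineage_weights must be three probabilities summing to 1")
  }
  if (!identical(cfg$shift_tissue, "random") &&
      !cfg$shift_tissue %in% cfg$tissues) {
    stop("shift_tissue must be one of the tissues or 'random'")
  }
  if (!length(cfg$baseline_mean) %in% c(1L, length(cfg$tissues))) {
    stop("baseline_mean must be scalar or one value per tissue")
  }
  if (cfg$baseline_sd <= 0 || cfg$noise_sd < 0) {
    stop("baseline_sd must be positive and noise_sd non-negative")
  }
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate three-species tissue expression with planted shifts
#'
#' See [simulationConfig()] for the generative model. Log2 expression is
#' back-transformed to TPM as 2^v - 1, measurement noise is added on the TPM
#' scale, and values are floored at 0. Deterministic given the config seed.
#'
#' @param cfg a `SimulationConfig`.
#' @return list with `tables` (list of three [TissueExpressionSet-class], in
#'   species x/y/z order), `triples` (data.frame `triple_id`, `gene_x`,
#'   `gene_y`, `gene_z`) and `truth` (data.frame per triple: `shifted`,
#'   `shift_lineage`, `shift_tissue`, `shift_magnitude`, and realized drift
#'   norms `drift_norm_x/y/z` on the log2 scale).
#' @export
simulateTripletExpression <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  n <- cfg$n_genes
  T <- length(cfg$tissues)
  bmean <- rep(cfg$baseline_mean, length.out = T)
  prefixes <- c("gx", "gy", "gz")
  withSeed(cfg$seed, {
    anc <- sweep(matrix(rnorm(n * T, 0, cfg$baseline_sd), n, T), 2L, bmean, "+")
    shifted <- runif(n) < cfg$shift_fraction
    lineage <- sample.int(3L, n, replace = TRUE,
                          prob = cfg$shift_lineage_weights)
    tissue_idx <- if (identical(cfg$shift_tissue, "random")) {
      sample.int(T, n, replace = TRUE)
    } else {
      rep(match(cfg$shift_tissue, cfg$tissues), n)
    }
    tables <- vector("list", 3L)
    drift_norms <- matrix(NA_real_, n, 3L)
    for (k in 1:3) {
      drift <- matrix(rnorm(n * T, 0, sqrt(cfg$branch_lengths[k])), n, T)
      drift_norms[, k] <- sqrt(rowSums(drift^2))
      v <- anc + drift
      hit <- which(shifted & lineage == k)
      v[cbind(hit, tissue_idx[hit])] <-
        v[cbind(hit, tissue_idx[hit])] + cfg$shift_magnitude
      tpm <- 2^v - 1
      if (cfg$noise_sd > 0) {
        tpm <- tpm + matrix(rnorm(n * T, 0, cfg$noise_sd), n, T)
      }
      tpm <- pmax(tpm, 0)
      dimnames(tpm) <- list(sprintf("%s%05d", prefixes[k], seq_len(n)),
                            cfg$tissues)
      tables[[k]] <- TissueExpressionSet(tpm, cfg$species[k])
    }
    triples <- data.frame(
      triple_id = sprintf("og%05d", seq_len(n)),
      gene_x = rownames(tables[[1L]]),
      gene_y = rownames(tables[[2L]]),
      gene_z = rownames(tables[[3L]])
    )
    truth <- data.frame(
      triple_id = triples$triple_id,
      shifted = shifted,
      shift_lineage = ifelse(shifted, cfg$species[lineage], NA_character_),
      shift_tissue = ifelse(shifted, cfg$tissues[tissue_idx], NA_character_),
      shift_magnitude = ifelse(shifted, cfg$shift_magnitude, 0),
      drift_norm_x = drift_norms[, 1L],
      drift_norm_y = drift_norms[, 2L],
      drift_norm_z = drift_norms[, 3L]
    )
    list(tables = tables, triples = triples, truth = truth)
  })
}

#' Simulate per-gene sequence divergence and interaction counts
#'
#' Divergence measures (gene-tree branch length, Ka, Ka/Ks) are drawn with
#' mean increasing linearly in a gene's normalized LED (slope
#' `divergence_slope`) times lognormal noise; interaction counts are Poisson
#' with log-mean `beta[1] + beta[2] * normalized LED`. LED is normalized to
#' its within-species quantile, (rank - 0.5) / n, so the planted
#' coefficients act on a [0, 1] predictor regardless of the right-skewed LED
#' scale and are recoverable by regression. One row per gene of each
#' species.
#'
#' @param led data.frame with columns `gene_x/y/z` and `led_x/y/z` (as
#'   produced by the pipeline's LED stage).
#' @param beta length-2 numeric, Poisson log-link intercept and slope;
#'   default c(0.5, -1.0).
#' @param divergence_slope slope of the divergence means in normalized LED;
#'   default 0.5.
#' @param seed integer seed.
#' @return list with `divergence` (gene, branch_length, ka, ka_ks) and
#'   `interactions` (gene, n_partners).
#' @export
simulateCorrelates <- function(led, beta = c(0.5, -1.0),
                               divergence_slope = 0.5, seed = 1) {
  need <- c("gene_x", "gene_y", "gene_z", "led_x", "led_y", "led_z")
  if (!all(need %in% names(led))) {
    stop("'led' must carry gene_x/y/z and led_x/y/z columns")
  }
  if (anyNA(led[, c("led_x", "led_y", "led_z")])) {
    stop("LED missing for some genes")
  }
  withSeed(seed, {
    res <- lapply(1:3, function(k) {
      genes <- led[[c("gene_x", "gene_y", "gene_z")[k]]]
      l <- led[[c("led_x", "led_y", "led_z")[k]]]
      nled <- (rank(l, ties.method = "average") - 0.5) / length(l)
      n <- length(genes)
      noise <- function() exp(rnorm(n, 0, 0.3))
      list(
        divergence = data.frame(
          gene = genes,
          branch_length = (0.2 + divergence_slope * nled) * noise(),
          ka = (0.05 + divergence_slope * nled) * noise(),
          ka_ks = pmin((0.2 + divergence_slope * nled) * noise(), 5)
        ),
        interactions = data.frame(
          gene = genes,
          n_partners = rpois(n, exp(beta[1L] + beta[2L] * nled))
        )
      )
    })
    list(
      divergence = do.call(rbind, lapply(res, `[[`, "divergence")),
      interactions = do.call(rbind, lapply(res, `[[`, "interactions"))
    )
  })
}

#' Simulate a small GO DAG with a planted enriched term
#'
#' Builds a three-level DAG (one root per namespace, three mid-level terms
#' per root, leaf terms below). One planted biological-process leaf
#' annotates exactly the top-scoring genes; background leaves annotate
#' uniform random gene sets of size 10-50. Direct annotations sit on leaves
#' only.
#'
#' @param scores named numeric vector gene -> score; its names are the gene
#'   universe.
#' @param n_background_terms number of background leaf terms; default 100.
#' @param planted_term_size number of top-scoring genes annotated to the
#'   planted term; default 20. With 0 no term is planted (background-only
#'   DAG, e.g. for null calibration).
#' @param seed integer seed.
#' @return list with `dag` ([GoDag-class]), `annotations` (direct,
#'   unpropagated) and `planted_term` (the planted term id).
#' @export
simulateGo <- function(scores, n_background_terms = 100,
                       planted_term_size = 20, seed = 1) {
  genes <- names(scores)
  if (is.null(genes)) stop("'scores' must be a named vector")
  if (planted_term_size > length(genes)) {
    stop("planted_term_size exceeds the number of genes")
  }
  stopifnot(planted_term_size >= 0)
  namespaces <- c("biological_process", "molecular_function",
                  "cellular_component")
  next_id <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      sprintf("GO:%07d", i)
    }
  })
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list()
  add_term <- function(name, ns, parent_ids) {
    id <- next_id()
    ids <<- c(ids, id); nms <<- c(nms, name); nss <<- c(nss, ns)
    parents[[id]] <<- parent_ids
    id
  }
  roots <- vapply(namespaces, function(ns) add_term(ns, ns, character(0)),
                  character(1L))
  mids <- lapply(namespaces, function(ns) {
    vapply(1:3, function(j) {
      add_term(sprintf("%s_branch_%d", ns, j), ns, roots[[ns]])
    }, character(1L))
  })
  names(mids) <- namespaces
  withSeed(seed, {
    if (planted_term_size > 0) {
      planted <- add_term("planted_top_scoring_set", "biological_process",
                          sample(mids$biological_process, 1L))
      ann_gene <- selectTopFraction(scores, planted_term_size / length(scores))
      # selectTopFraction ceiling can overshoot by rounding; take exactly k
      ann_gene <- ann_gene[seq_len(planted_term_size)]
      ann_term <- rep(planted, planted_term_size)
    } else {
      planted <- NA_character_
      ann_gene <- character(0)
      ann_term <- character(0)
    }
    for (b in seq_len(n_background_terms)) {
      ns <- namespaces[(b - 1L) %% 3L + 1L]
      id <- add_term(sprintf("background_%03d", b), ns, sample(mids[[ns]], 1L))
      size <- sample(10:50, 1L)
      ann_gene <- c(ann_gene, sample(genes, size))
      ann_term <- c(ann_term, rep(id, size))
    }
    dag <- new("GoDag",
               terms = data.frame(id = ids, name = nms, namespace = nss),
               parents = parents)
    ann <- unique(data.frame(gene = ann_gene, term = ann_term))
    rownames(ann) <- NULL
    attr(ann, "propagated") <- FALSE
    list(dag = dag, annotations = ann, planted_term = planted)
  })
}

## Serialize a GoDag to minimal OBO.
.writeObo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (i in seq_len(nrow(dag@terms))) {
    pp <- dag@parents[[dag@terms$id[i]]]
    writeLines(c(
      "",
      "[Term]",
      paste0("id: ", dag@terms$id[i]),
      paste0("name: ", dag@terms$name[i]),
      paste0("namespace: ", dag@terms$namespace[i]),
      if (length(pp)) paste0("is_a: ", pp)
    ), con)
  }
  invisible(path)
}

#' Write a complete simulated input bundle to a directory
#'
#' Generates expression tables, ortholog triples, a truth table, correlated
#' divergence and interaction tables, a GO DAG with annotations, and a ready
#' run configuration (`config.yaml`) pointing at them, so [runPipeline()]
#' can be exercised end-to-end. LED is computed internally (with default
#' thresholds) to drive the correlate and GO simulators.
#'
#' @param cfg a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @param beta,divergence_slope passed to [simulateCorrelates()].
#' @param n_background_terms,planted_term_size passed to [simulateGo()].
#' @return invisibly, a named list of written paths plus the `truth` table
#'   and `planted_term`.
#' @export
writeSimulatedBundle <- function(cfg, dir, beta = c(0.5, -1.0),
                                 divergence_slope = 0.5,
                                 n_background_terms = 100,
                                 planted_term_size = 20) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateTripletExpression(cfg)
  paths <- list()
  for (k in 1:3) {
    tab <- sim$tables[[k]]
    df <- data.frame(gene = rownames(tab), tpm(tab), check.names = FALSE)
    p <- file.path(dir, sprintf("tpm_%s.tsv", species(tab)))
    writeTsv(df, p)
    paths[[sprintf("tpm_%d", k)]] <- p
  }
  writeTsv(sim$triples, paths$triples <- file.path(dir, "triples.tsv"))
  writeTsv(sim$truth, paths$truth <- file.path(dir, "truth.tsv"))

  led <- .ledTable(sim$tables, sim$triples)
  corr <- simulateCorrelates(led, beta = beta,
                             divergence_slope = divergence_slope,
                             seed = deriveSeed(cfg$seed, 2L))
  writeTsv(corr$divergence, paths$divergence <- file.path(dir, "divergence.tsv"))
  writeTsv(corr$interactions,
           paths$interactions <- file.path(dir, "interactions.tsv"))

  scores <- c(
    setNames(led$led_x, led$gene_x),
    setNames(led$led_y, led$gene_y),
    setNames(led$led_z, led$gene_z)
  )
  go <- simulateGo(scores, n_background_terms = n_background_terms,
                   planted_term_size = planted_term_size,
                   seed = deriveSeed(cfg$seed, 3L))
  .writeObo(go$dag, paths$obo <- file.path(dir, "go.obo"))
  writeTsv(go$annotations,
           paths$annotations <- file.path(dir, "annotations.tsv"))

  config <- list(
    inputs = list(
      tpm = sprintf("tpm_%s.tsv", cfg$species),
      triples = "triples.tsv",
      divergence = "divergence.tsv",
      interactions = "interactions.tsv",
      obo = "go.obo",
      annotations = "annotations.tsv"
    ),
    species = list(
      list(name = cfg$species[1L], days_to_anthesis = 35, divergence_my = 50),
      list(name = cfg$species[2L], days_to_anthesis = 65, divergence_my = 50),
      list(name = cfg$species[3L], days_to_anthesis = 75, divergence_my = 60)
    ),
    thresholds = list(
      expression_filter = 2, top_fraction = 0.01, enrichment_alpha = 0.01,
      node_size = 10, n_permutations = 1000
    ),
    pseudocount = 1, profile_scale = "log",
    seed = cfg$seed, outdir = "results"
  )
  yaml::write_yaml(config, paths$config <- file.path(dir, "config.yaml"))
  out <- c(paths, list(truth_table = sim$truth, planted_term = go$planted_term))
  invisible(out)
}

## Filter, align, profile and decompose: the LED table used both by the
## bundle writer and the pipeline's core stage.
.ledTable <- function(tables, triples, threshold = 2, pseudocount = 1,
                      scale = "log") {
  retained <- lapply(tables, filterExpressed, threshold = threshold)
  universe <- lapply(tables, rownames)
  al <- alignTriples(triples, retained, universe)
  tr <- al$triples
  if (!nrow(tr)) stop("no triple passed the expression filter in all species")
  px <- makeProfiles(tables[[1L]], tr$gene_x, pseudocount, scale)
  py <- makeProfiles(tables[[2L]], tr$gene_y, pseudocount, scale)
  pz <- makeProfiles(tables[[3L]], tr$gene_z, pseudocount, scale)
  d <- pairwiseProfileDistances(px, py, pz)
  led <- computeLED(d)
  out <- cbind(tr, d, led)
  attr(out, "dropped") <- al$dropped
  rownames(out) <- NULL
  out
}
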