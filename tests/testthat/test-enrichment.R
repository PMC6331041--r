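writeObo <- function(lines) {
  p <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", lines), p)
  p
}

test_that("the OBO parser builds the DAG and skips obsolete terms", {
  p <- writeObo(c(
    "", "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "", "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
    "is_a: GO:1 ! a",
    "", "[Term]", "id: GO:3", "name: c", "namespace: biological_process",
    "is_a: GO:2",
    "", "[Term]", "id: GO:4", "name: dead",
    "namespace: biological_process", "is_obsolete: true"
  ))
  dag <- parseOboSubset(p)
  expect_equal(nrow(dag@terms), 3)
  expect_equal(length(unlist(dag@parents)), 2)
  expect_false("GO:4" %in% dag@terms$id)
})

test_that("the OBO parser rejects cycles and dangling targets", {
  cyc <- writeObo(c(
    "", "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "is_a: GO:2",
    "", "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
    "is_a: GO:1"
  ))
  expect_error(parseOboSubset(cyc), "cycle")

  dang <- writeObo(c(
    "", "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "is_a: GO:9"
  ))
  expect_error(parseOboSubset(dang), "GO:9")
})

test_that("non-is_a relationships are ignored with a note", {
  p <- writeObo(c(
    "", "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "", "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
    "is_a: GO:1", "relationship: part_of GO:1"
  ))
  expect_message(dag <- parseOboSubset(p), "ignored 1")
  expect_equal(length(unlist(dag@parents)), 1)
})

test_that("annotation propagation closes over ancestors and is idempotent", {
  dag <- chainDag()
  direct <- data.frame(gene = "g1", term = "GO:0000003")
  prop <- propagateAnnotations(dag, direct)
  expect_setequal(prop$term[prop$gene == "g1"],
                  c("GO:0000003", "GO:0000002", "GO:0000001"))
  prop2 <- propagateAnnotations(dag, prop)
  expect_setequal(paste(prop2$gene, prop2$term), paste(prop$gene, prop$term))
  expect_error(propagateAnnotations(dag, data.frame(gene = "g", term = "GO:9")),
               "unknown term")
})

test_that("propagation matches a transitive-closure matrix oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 8
    ids <- sprintf("T%02d", 1:n)
    # edges only toward lower indices: acyclic by construction
    parents <- setNames(lapply(1:n, function(i) {
      if (i == 1) character(0) else ids[sample(1:(i - 1), min(sample(0:2, 1), i - 1))]
    }), ids)
    dag <- new("GoDag",
               terms = data.frame(id = ids, name = ids,
                                  namespace = "molecular_function"),
               parents = parents)
    # boolean reachability oracle
    A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
    for (i in ids) A[i, parents[[i]]] <- TRUE
    R <- A
    for (k in 1:n) R <- R | (R %*% A > 0)
    direct <- data.frame(gene = "g1", term = ids[n])
    prop <- propagateAnnotations(dag, direct)
    expect_setequal(prop$term, c(ids[n], ids[R[ids[n], ]]))
  }
})

test_that("parent terms annotate at least as many genes as their children", {
  set.seed(62)
  scores <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  go <- simulateGo(scores, n_background_terms = 30, planted_term_size = 15,
                   seed = 3)
  prop <- propagateAnnotations(go$dag, go$annotations)
  counts <- table(prop$term)
  for (child in names(go$dag@parents)) {
    for (parent in go$dag@parents[[child]]) {
      nc <- ifelse(child %in% names(counts), counts[[child]], 0)
      np <- ifelse(parent %in% names(counts), counts[[parent]], 0)
      expect_gte(np, nc)
    }
  }
})

test_that("a planted top-scoring term dominates the enrichment ranking", {
  set.seed(63)
  scores <- setNames(rnorm(1000), sprintf("g%04d", 1:1000))
  go <- simulateGo(scores, n_background_terms = 50, planted_term_size = 20,
                   seed = 4)
  prop <- propagateAnnotations(go$dag, go$annotations)
  res <- ksEnrichment(go$dag, prop, scores)
  expect_identical(res$term[1], go$planted_term)
  expect_lt(res$p_value[1], 1e-3)
})

test_that("terms below the node-size threshold are not tested", {
  dag <- chainDag()
  genes <- sprintf("g%02d", 1:60)
  scores <- setNames(seq_along(genes), genes)
  direct <- rbind(
    data.frame(gene = genes[1:9], term = "GO:0000003"),   # 9 genes: too small
    data.frame(gene = genes[10:40], term = "GO:0000004")
  )
  prop <- propagateAnnotations(dag, direct)
  res <- ksEnrichment(dag, prop, scores, node_size = 10)
  expect_false("GO:0000003" %in% res$term)
  expect_true("GO:0000004" %in% res$term)

  # unpropagated annotations and missing scores are contract violations
  expect_error(ksEnrichment(dag, direct, scores), "propagated")
  expect_error(ksEnrichment(dag, prop, scores[-1]), "score missing")
})

test_that("elim equals classic when no term reaches the elimination cutoff", {
  set.seed(64)
  scores <- setNames(rnorm(300), sprintf("g%03d", 1:300))
  go <- simulateGo(scores, n_background_terms = 25, planted_term_size = 12,
                   seed = 5)
  prop <- propagateAnnotations(go$dag, go$annotations)
  cls <- ksEnrichment(go$dag, prop, scores, algorithm = "classic")
  elim <- ksEnrichment(go$dag, prop, scores, algorithm = "elim",
                       alpha_elim = 0)
  expect_equal(elim[, setdiff(names(elim), "algorithm")],
               cls[, setdiff(names(cls), "algorithm")])
})

test_that("elim removes significant children's genes from ancestors", {
  # mid term annotates exactly the leaf's genes plus none of its own:
  # once the leaf is eliminated the mid term loses its signal
  dag <- chainDag()
  genes <- sprintf("g%03d", 1:200)
  scores <- setNames(rev(seq_along(genes)), genes)  # g001 highest
  direct <- data.frame(gene = genes[1:15], term = "GO:0000003")
  prop <- propagateAnnotations(dag, direct)
  cls <- ksEnrichment(dag, prop, scores, algorithm = "classic")
  elim <- ksEnrichment(dag, prop, scores, algorithm = "elim",
                       alpha_elim = 0.01)
  p_cls_mid <- cls$p_value[cls$term == "GO:0000002"]
  p_elim_mid <- elim$p_value[elim$term == "GO:0000002"]
  expect_lt(p_cls_mid, 0.01)   # inherits the leaf's signal
  expect_equal(p_elim_mid, 1)  # signal removed with the leaf's genes
})

test_that("filterSignificant applies a strict cutoff in p order", {
  rows <- data.frame(term = c("a", "b", "c"),
                     p_value = c(0.05, 0.001, 0.01))
  out <- filterSignificant(rows, alpha = 0.01)
  expect_identical(out$term, "b")
  expect_equal(nrow(filterSignificant(rows[0, ])), 0)
})
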