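write_orthogroups <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

test_that("parseOrthogroups reads the Orthogroups.tsv dialect", {
  p <- write_orthogroups(c(
    "Orthogroup\tgA\tgB\tgC",
    "OG1\tgA|p1, gA|p2\t\tgC|p1",
    "OG2\tgA|p3\t\t",
    "OG3\tgA|p4\tgB|p1, gB|p2\tgC|p2"))
  cl <- parseOrthogroups(p)
  expect_s4_class(cl, "OrthologClusters")
  expect_equal(length(cl), 3L)
  expect_equal(unname(lengths(members(cl))), c(3L, 1L, 4L))
  # whitespace trimmed, empty cells skipped
  expect_setequal(members(cl)[["OG1"]], c("gA|p1", "gA|p2", "gC|p1"))
})

test_that("parseOrthogroups enforces uniqueness", {
  dup_cluster <- write_orthogroups(c("Orthogroup\tgA", "OG1\tgA|p1", "OG1\tgA|p2"))
  expect_error(parseOrthogroups(dup_cluster), "duplicate cluster id: OG1")
  dup_member <- write_orthogroups(c("Orthogroup\tgA\tgB",
                                    "OG1\tgA|p1\t", "OG2\tgA|p1\tgB|p1"))
  expect_error(parseOrthogroups(dup_member), "gA\\|p1")
})

test_that("multiclass filter keeps exactly the >= 2-class clusters", {
  genome_tbl <- data.frame(
    genome_id = c("gP", "gM", "gT", "gX"),
    species = paste("sp", 1:4),
    ogt_celsius = c(10, 35, 60, 45))  # gX excluded
  prot <- data.frame(
    protein_id = c("gP|a", "gM|a", "gM|b", "gT|a", "gT|b", "gX|a"),
    genome_id = c("gP", "gM", "gM", "gT", "gT", "gX"),
    sequence = rep("MKLVA", 6))
  corpus <- OGTpred:::makeCorpus(genome_tbl, prot)
  mk <- function(lst) methods::new("OrthologClusters",
                                   members = IRanges::CharacterList(lst))
  cl <- mk(list(OG_multi = c("gP|a", "gT|a"),   # psychrophilic + thermophilic
                OG_mono = c("gM|a", "gM|b"),    # mesophilic only
                # the only second-class member comes from an excluded genome
                OG_excl = c("gT|b", "gX|a")))
  kept <- filterMulticlassClusters(cl, corpus)
  # OG_excl counts only the thermophilic member -> one class -> dropped
  expect_setequal(clusterIds(kept), "OG_multi")
  # unresolvable member ids error
  bad <- mk(list(OG_bad = c("gP|a", "nope|z")))
  expect_error(filterMulticlassClusters(bad, corpus), "nope\\|z")
})

test_that("makeSplit partitions clusters round-robin and is deterministic", {
  gen <- small_generated()
  retained <- filterMulticlassClusters(gen$clusters, gen$corpus)
  k <- 3L
  sp1 <- makeSplit(retained, gen$corpus, k = k, seed = 42)
  sp2 <- makeSplit(retained, gen$corpus, k = k, seed = 42)
  expect_identical(foldOfCluster(sp1), foldOfCluster(sp2))
  foc <- foldOfCluster(sp1)
  # every retained cluster in exactly one fold; sizes differ by at most 1
  expect_setequal(names(foc), clusterIds(retained))
  expect_lte(diff(range(table(factor(foc, levels = 0:(k - 1L))))), 1)
  # no homology leakage: cluster members share a fold
  fop <- foldOfProtein(sp1)
  for (cid in clusterIds(retained)) {
    mem <- intersect(members(retained)[[cid]], names(fop))
    expect_equal(length(unique(fop[mem])), 1L)
  }
})

test_that("train and test pools partition the labelled proteins", {
  gen <- small_generated()
  retained <- filterMulticlassClusters(gen$clusters, gen$corpus)
  sp <- makeSplit(retained, gen$corpus, k = 4L, seed = 9)
  info <- proteinInfo(gen$corpus)
  labelled <- info$protein_id[!is.na(info$label_celsius)]
  expect_length(intersect(trainIds(sp), testIds(sp)), 0)
  expect_setequal(c(trainIds(sp), testIds(sp)), labelled)
  # set-difference oracle for the test pool
  in_retained <- intersect(unlist(members(retained), use.names = FALSE), labelled)
  expect_setequal(testIds(sp), setdiff(labelled, in_retained))
})

test_that("makeSplit refuses fewer clusters than folds", {
  gen <- small_generated()
  retained <- filterMulticlassClusters(gen$clusters, gen$corpus)
  expect_error(makeSplit(retained, gen$corpus, k = length(retained) + 1L),
               "fewer clusters")
})

test_that("each fold holds exactly one cluster when k equals cluster count", {
  gen <- small_generated()
  retained <- filterMulticlassClusters(gen$clusters, gen$corpus)
  k <- length(retained)
  sp <- makeSplit(retained, gen$corpus, k = k, seed = 5)
  expect_equal(sort(unname(foldOfCluster(sp))), 0:(k - 1L))
})

test_that("protein-level split reuses the pool but breaks clusters", {
  gen <- small_generated()
  retained <- filterMulticlassClusters(gen$clusters, gen$corpus)
  sp <- makeSplit(retained, gen$corpus, k = 3L, seed = 7)
  leaky <- makeProteinSplit(sp, seed = 7)
  expect_identical(sort(trainIds(leaky)), sort(trainIds(sp)))
  expect_identical(sort(testIds(leaky)), sort(testIds(sp)))
  fop <- foldOfProtein(leaky)
  broken <- vapply(clusterIds(retained), function(cid) {
    mem <- intersect(members(retained)[[cid]], names(fop))
    length(unique(fop[mem])) > 1L
  }, TRUE)
  expect_true(any(broken))
})

test_that("split plans serialise to JSON", {
  gen <- small_generated()
  retained <- filterMulticlassClusters(gen$clusters, gen$corpus)
  sp <- makeSplit(retained, gen$corpus, k = 3L, seed = 1)
  p <- tempfile(fileext = ".json")
  writeSplitPlan(sp, p)
  js <- jsonlite::read_json(p)
  expect_equal(js$k, 3L)
  expect_equal(length(js$fold_clusters), 3L)
  expect_setequal(unlist(js$fold_clusters), clusterIds(retained))
})
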