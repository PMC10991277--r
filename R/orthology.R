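#' Parse an OrthoFinder-style Orthogroups.tsv table
#'
#' First column: cluster (orthogroup) id; remaining columns: comma-separated
#' protein ids, one column per genome; header row present. Ids are
#' whitespace-trimmed and empty cells skipped.
#'
#' @param path path to the TSV file.
#' @return an \linkS4class{OrthologClusters}.
#' @export
parseOrthogroups <- function(path) {
  tbl <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (ncol(tbl) < 2) stop("orthogroup table needs an id column plus genome columns")
  ids <- trimws(tbl[[1]])
  if (anyDuplicated(ids))
    stop("duplicate cluster id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  member_lists <- lapply(seq_len(nrow(tbl)), function(i) {
    cells <- unlist(tbl[i, -1], use.names = FALSE)
    m <- trimws(unlist(strsplit(cells[!is.na(cells) & nzchar(trimws(cells))], ",")))
    m[nzchar(m)]
  })
  names(member_lists) <- ids
  keep <- lengths(member_lists) > 0
  if (any(!keep))
    log_msg(sum(!keep), " empty orthogroup row(s) skipped")
  cl <- IRanges::CharacterList(member_lists[keep])
  all_members <- unlist(cl, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- unique(all_members[duplicated(all_members)])
    stop("protein id(s) appear in more than one cluster: ",
         paste(head(dup, 10), collapse = ", "))
  }
  methods::new("OrthologClusters", members = cl)
}

#' @rdname OrthologClusters-class
#' @export
setMethod("clusterIds", "OrthologClusters", function(x) names(x@members))

#' @rdname OrthologClusters-class
#' @export
setMethod("members", "OrthologClusters", function(x) x@members)

#' @rdname OrthologClusters-class
#' @export
setMethod("length", "OrthologClusters", function(x) length(x@members))

setMethod("show", "OrthologClusters", function(object) {
  cat("OrthologClusters:", length(object@members), "clusters,",
      sum(lengths(object@members)), "member proteins\n")
})

# Temperature classes represented among a cluster's members; members of
# excluded-class genomes contribute nothing.
classesPresent <- function(clusters, corpus) {
  g <- genomes(corpus)
  m <- S4Vectors::mcols(proteins(corpus))
  cls_of_protein <- g$temp_class[match(m$genome_id, g$genome_id)]
  names(cls_of_protein) <- m$protein_id
  lapply(as.list(members(clusters)), function(ids) {
    cls <- cls_of_protein[ids]
    if (any(is.na(cls)))
      stop("cluster member(s) absent from corpus: ",
           paste(head(ids[is.na(cls)], 5), collapse = ", "))
    setdiff(unique(cls), "excluded")
  })
}

#' Keep clusters spanning at least two temperature classes
#'
#' Only clusters whose members come from two or more of the psychrophilic /
#' mesophilic / thermophilic classes are informative for training: a cluster
#' confined to one class tells the model nothing about thermal adaptation.
#' Members of excluded-class genomes do not contribute a class. Output order
#' is stable, sorted by cluster id.
#'
#' @param clusters an \linkS4class{OrthologClusters}.
#' @param corpus the \linkS4class{ThermoCorpus} the members resolve in.
#' @return an \linkS4class{OrthologClusters} with the retained clusters.
#' @export
filterMulticlassClusters <- function(clusters, corpus) {
  present <- classesPresent(clusters, corpus)
  keep <- names(present)[vapply(present, length, 1L) >= 2L]
  keep <- sort(keep)
  methods::new("OrthologClusters", members = members(clusters)[keep])
}

#' Build a cluster-respecting cross-validation split
#'
#' Retained clusters are sorted lexicographically, shuffled by a seeded RNG,
#' and assigned round-robin to \code{k} folds, so all proteins sharing a
#' cluster land in the same fold (no homology leakage). Labelled proteins of
#' the retained clusters form the train/validation pool; every other labelled
#' protein (singleton-class clusters and unclustered proteins) goes to the
#' held-out test set.
#'
#' @param clusters retained clusters (see \code{\link{filterMulticlassClusters}}).
#' @param corpus the \linkS4class{ThermoCorpus}.
#' @param k integer fold count (>= 2).
#' @param seed integer seed for the shuffle.
#' @return a \linkS4class{SplitPlan}.
#' @export
makeSplit <- function(clusters, corpus, k = 10L, seed = 1L) {
  k <- as.integer(k); seed <- as.integer(seed)
  if (k < 2L) stop("k must be >= 2")
  ids <- sort(clusterIds(clusters))
  if (length(ids) < k)
    stop("fewer clusters (", length(ids), ") than folds (", k, ")")
  shuffled <- with_seed(seed, sample(ids))
  fold_of_cluster <- stats::setNames(as.integer((seq_along(shuffled) - 1L) %% k),
                                     shuffled)

  info <- proteinInfo(corpus)
  labelled <- info$protein_id[!is.na(info$label_celsius)]
  mem <- members(clusters)
  member_ids <- unlist(mem, use.names = FALSE)
  cluster_of_member <- rep(names(mem), lengths(mem))
  in_pool <- member_ids[member_ids %in% labelled]
  fold_of_protein <- fold_of_cluster[cluster_of_member[match(in_pool, member_ids)]]
  names(fold_of_protein) <- in_pool
  test_ids <- setdiff(labelled, in_pool)

  methods::new("SplitPlan", level = "cluster", k = k, seed = seed,
               fold_of_cluster = fold_of_cluster,
               fold_of_protein = fold_of_protein,
               train_ids = in_pool, test_ids = test_ids)
}

#' Deliberately leaky protein-level split (negative control)
#'
#' Reassigns the same train pool to folds at the protein level, ignoring
#' cluster membership, so homologous near-duplicates straddle fold
#' boundaries. Used to demonstrate that cluster-level splitting suppresses
#' homology leakage: a model validated on a leaky split reports an inflated
#' correlation.
#'
#' @param split a cluster-level \linkS4class{SplitPlan}.
#' @param seed integer seed for the protein shuffle.
#' @return a protein-level \linkS4class{SplitPlan} over the same pools.
#' @export
makeProteinSplit <- function(split, seed = split@seed) {
  ids <- sort(split@train_ids)
  shuffled <- with_seed(as.integer(seed), sample(ids))
  fold <- stats::setNames(as.integer((seq_along(shuffled) - 1L) %% split@k), shuffled)
  methods::new("SplitPlan", level = "protein", k = split@k,
               seed = as.integer(seed), fold_of_cluster = integer(),
               fold_of_protein = fold, train_ids = split@train_ids,
               test_ids = split@test_ids)
}

#' @rdname SplitPlan-class
#' @export
setMethod("foldOfCluster", "SplitPlan", function(x) x@fold_of_cluster)

#' @rdname SplitPlan-class
#' @export
setMethod("foldOfProtein", "SplitPlan", function(x) x@fold_of_protein)

#' @rdname SplitPlan-class
#' @export
setMethod("trainIds", "SplitPlan", function(x) x@train_ids)

#' @rdname SplitPlan-class
#' @export
setMethod("testIds", "SplitPlan", function(x) x@test_ids)

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan (", object@level, "-level): k = ", object@k,
      ", seed = ", object@seed, "\n", sep = "")
  cat("  train/validation pool:", length(object@train_ids),
      "proteins | test pool:", length(object@test_ids), "proteins\n")
})

#' Write a split plan as JSON
#'
#' Serialises seed, k, per-fold cluster ids and the test pool so a training
#' run is fully reconstructible.
#'
#' @param split a \linkS4class{SplitPlan}.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeSplitPlan <- function(split, path) {
  foc <- foldOfCluster(split)
  per_fold <- lapply(0:(split@k - 1L), function(f) names(foc)[foc == f])
  jsonlite::write_json(
    list(level = split@level, k = split@k, seed = split@seed,
         fold_clusters = per_fold,
         fold_of_protein = as.list(foldOfProtein(split)),
         test_ids = testIds(split)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
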