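#' ThermoCorpus: a temperature-labelled protein corpus
#'
#' Container tying together genome metadata (species, optimal growth
#' temperature in degrees Celsius and the derived temperature class) and the
#' protein sequences drawn from those genomes. Proteins of genomes whose OGT
#' falls outside the three class bands are retained but carry no regression
#' label (\code{NA}), so they can still be scored by a trained model.
#'
#' @slot genomes data.frame with columns \code{genome_id}, \code{species},
#'   \code{ogt_celsius}, \code{temp_class}.
#' @slot proteins \link[Biostrings]{AAStringSet} named by protein id, with
#'   \code{mcols} columns \code{protein_id}, \code{genome_id},
#'   \code{label_celsius} (NA when unlabelled).
#' @slot provenance character vector logging the input files and
#'   normalisation decisions behind the object.
#'
#' @export
setClass("ThermoCorpus",
  representation(genomes = "data.frame",
                 proteins = "AAStringSet",
                 provenance = "character"))

setValidity("ThermoCorpus", function(object) {
  msgs <- character()
  g <- object@genomes
  need <- c("genome_id", "species", "ogt_celsius", "temp_class")
  if (!all(need %in% names(g)))
    msgs <- c(msgs, paste("genomes must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(g$genome_id))
      msgs <- c(msgs, "duplicate genome_id in genomes")
    if (any(!is.finite(g$ogt_celsius)))
      msgs <- c(msgs, "non-finite ogt_celsius")
    if (!all(g$temp_class %in% TEMP_CLASSES))
      msgs <- c(msgs, "temp_class outside the allowed set")
  }
  m <- S4Vectors::mcols(object@proteins)
  if (is.null(m) || !all(c("protein_id", "genome_id", "label_celsius") %in% names(m)))
    msgs <- c(msgs, "proteins mcols must have protein_id, genome_id, label_celsius")
  else {
    if (anyDuplicated(m$protein_id))
      msgs <- c(msgs, "duplicate protein_id in corpus")
    bad <- setdiff(unique(m$genome_id), g$genome_id)
    if (length(bad))
      msgs <- c(msgs, paste("proteins reference unknown genomes:",
                            paste(head(bad, 5), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' OrthologClusters: orthogroup membership
#'
#' One character vector of member protein ids per cluster, named by cluster id.
#' The cluster is the unit of cross-validation splitting: homologous proteins
#' are never separated across folds.
#'
#' @slot members \link[IRanges]{CharacterList} named by cluster id.
#' @export
setClass("OrthologClusters",
  representation(members = "CharacterList"))

setValidity("OrthologClusters", function(object) {
  msgs <- character()
  ids <- names(object@members)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "cluster ids must be unique and non-NULL")
  if (any(lengths(object@members) == 0))
    msgs <- c(msgs, "clusters must have at least one member")
  all_members <- unlist(object@members, use.names = FALSE)
  if (anyDuplicated(all_members)) {
    dup <- unique(all_members[duplicated(all_members)])
    msgs <- c(msgs, paste("protein ids present in more than one cluster:",
                          paste(head(dup, 5), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' SplitPlan: a cluster-respecting cross-validation partition
#'
#' Maps every retained ortholog cluster (or, for the leakage negative control,
#' every training protein) to one of \code{k} folds, and records the
#' train/validation pool versus the held-out test pool. Labelled proteins
#' outside the retained clusters form the test set.
#'
#' @slot level "cluster" for the homology-aware split, "protein" for the
#'   deliberately leaky negative-control split.
#' @slot k integer fold count.
#' @slot seed integer seed the shuffle was drawn from.
#' @slot fold_of_cluster named integer vector, cluster id -> fold in 0..k-1
#'   (empty for protein-level splits).
#' @slot fold_of_protein named integer vector over the train pool.
#' @slot train_ids,test_ids disjoint character vectors of labelled protein ids.
#' @export
setClass("SplitPlan",
  representation(level = "character", k = "integer", seed = "integer",
                 fold_of_cluster = "integer", fold_of_protein = "integer",
                 train_ids = "character", test_ids = "character"))

setValidity("SplitPlan", function(object) {
  msgs <- character()
  if (!object@level %in% c("cluster", "protein"))
    msgs <- c(msgs, "level must be 'cluster' or 'protein'")
  if (object@k < 2L) msgs <- c(msgs, "k must be >= 2")
  if (length(intersect(object@train_ids, object@test_ids)))
    msgs <- c(msgs, "train and test protein sets overlap")
  f <- object@fold_of_protein
  if (!setequal(names(f), object@train_ids))
    msgs <- c(msgs, "fold_of_protein must cover exactly the train pool")
  if (length(f) && (min(f) < 0L || max(f) >= object@k))
    msgs <- c(msgs, "fold indices out of range")
  if (length(msgs)) msgs else TRUE
})

#' ModelConfig: hyperparameters of the convolutional regressor
#'
#' Defaults follow the tuned architecture (kernel size 18, 256 neurons used as
#' both convolution filter count and dense width, dropout 0.3, at most 100
#' epochs with batches of 32, Adam with AMSGRAD); pooling window, learning
#' rate and early-stopping patience are exposed knobs.
#'
#' @export
setClass("ModelConfig",
  representation(kernel_size = "integer", n_neurons = "integer",
                 dropout_rate = "numeric", max_epochs = "integer",
                 batch_size = "integer", pool_size = "integer",
                 learning_rate = "numeric", amsgrad = "logical",
                 early_stop_patience = "integer", normalize_labels = "logical",
                 seed = "integer"))

setValidity("ModelConfig", function(object) {
  msgs <- character()
  if (object@kernel_size < 1L) msgs <- c(msgs, "kernel_size must be >= 1")
  if (object@n_neurons < 1L) msgs <- c(msgs, "n_neurons must be >= 1")
  if (object@dropout_rate < 0 || object@dropout_rate >= 1)
    msgs <- c(msgs, "dropout_rate must be in [0, 1)")
  if (object@batch_size < 1L) msgs <- c(msgs, "batch_size must be >= 1")
  if (object@pool_size < 1L) msgs <- c(msgs, "pool_size must be >= 1")
  if (object@max_epochs < 1L) msgs <- c(msgs, "max_epochs must be >= 1")
  if (object@learning_rate <= 0) msgs <- c(msgs, "learning_rate must be > 0")
  if (object@early_stop_patience < 1L) msgs <- c(msgs, "early_stop_patience must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' OptTempCNN: the (possibly trained) convolutional regressor
#'
#' @slot config \linkS4class{ModelConfig}.
#' @slot L_max integer input length the one-hot matrices are padded/truncated to.
#' @slot weights list of weight matrices/vectors (see \code{\link{buildModel}}).
#' @slot trained logical.
#' @slot history data.frame of per-epoch training and validation loss (in the
#'   optimised label scale: degrees C squared, or z-score units squared when
#'   label standardisation is on).
#' @slot stopped_epoch integer epoch training stopped at (0 if untrained).
#' @slot label_center,label_scale affine map from the internal training scale
#'   back to degrees Celsius (identity unless the config standardises labels).
#' @export
setClass("OptTempCNN",
  representation(config = "ModelConfig", L_max = "integer", weights = "list",
                 trained = "logical", history = "data.frame",
                 stopped_epoch = "integer", label_center = "numeric",
                 label_scale = "numeric"))

#' GridSearchResult: grid search over kernel size and neuron count
#'
#' @slot tried data.frame (kernel_size, n_neurons, validation_r, status).
#' @slot best \linkS4class{ModelConfig} attaining the maximum validation r,
#'   ties broken by smaller kernel then fewer neurons.
#' @export
setClass("GridSearchResult",
  representation(tried = "data.frame", best = "ModelConfig"))

#' MiningResult: ranked, temperature-annotated enzyme candidates
#'
#' @slot ranked data.frame (rank, protein_id, predicted_temp, temp_bin,
#'   full_seq_evalue) sorted by predicted temperature, descending.
#' @slot bin_fractions named numeric of length 3 summing to 1.
#' @slot thresholds numeric c(t_low, t_high) in degrees Celsius.
#' @export
setClass("MiningResult",
  representation(ranked = "data.frame", bin_fractions = "numeric",
                 thresholds = "numeric"))

setValidity("MiningResult", function(object) {
  msgs <- character()
  if (length(object@bin_fractions) != 3L)
    msgs <- c(msgs, "bin_fractions must have length 3")
  else if (abs(sum(object@bin_fractions) - 1) > 1e-9)
    msgs <- c(msgs, "bin_fractions must sum to 1")
  if (length(object@thresholds) != 2L || object@thresholds[1] >= object@thresholds[2])
    msgs <- c(msgs, "thresholds must satisfy t_low < t_high")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticSpec: study conditions for the synthetic corpus generator
#'
#' Defaults are the desk-scale study conditions: six genomes per temperature
#' class, 200 proteins per genome, compositional enrichment of E/L/V/Y in hot
#' genomes and D/H/M/Q/S/T in cold genomes at strength 0.8, 3 degrees Celsius
#' of generation-temperature jitter, ortholog families sharing 90% of sites.
#'
#' @export
setClass("SyntheticSpec",
  representation(n_genomes_per_class = "integer", proteins_per_genome = "integer",
                 families = "integer", family_span = "integer",
                 length_range = "integer", hot_enriched = "character",
                 cold_enriched = "character", enrichment_strength = "numeric",
                 label_noise_sd = "numeric", substitution_rate = "numeric",
                 paralog_rate = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (length(intersect(object@hot_enriched, object@cold_enriched)))
    msgs <- c(msgs, "hot_enriched and cold_enriched must be disjoint")
  if (!all(c(object@hot_enriched, object@cold_enriched) %in% AA_ALPHABET20))
    msgs <- c(msgs, "enriched sets must be standard amino acids")
  if (object@enrichment_strength < 0 || object@enrichment_strength > 1)
    msgs <- c(msgs, "enrichment_strength must be in [0, 1]")
  if (object@substitution_rate < 0 || object@substitution_rate > 1)
    msgs <- c(msgs, "substitution_rate must be in [0, 1]")
  if (object@paralog_rate < 0 || object@paralog_rate > 1)
    msgs <- c(msgs, "paralog_rate must be in [0, 1]")
  if (length(object@family_span) != 2L || object@family_span[1] < 2L ||
      object@family_span[1] > object@family_span[2])
    msgs <- c(msgs, "family_span must be c(min, max) with 2 <= min <= max")
  if (object@family_span[2] > 3L * object@n_genomes_per_class)
    msgs <- c(msgs, "family_span exceeds the total genome count")
  if (length(object@length_range) != 2L || object@length_range[1] < 1L ||
      object@length_range[1] > object@length_range[2])
    msgs <- c(msgs, "length_range must be c(min, max) with 1 <= min <= max")
  if (object@label_noise_sd < 0) msgs <- c(msgs, "label_noise_sd must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' CVEvaluation: per-fold and aggregate evaluation report
#'
#' @slot per_fold data.frame (fold, split, n, pearson_r, mae_celsius).
#' @slot summary data.frame (split, mean_r, sd_r, mean_mae, sd_mae).
#' @slot test data.frame one row (n, pearson_r, mae_celsius) for the held-out
#'   pool scored by the fold-model ensemble mean.
#' @export
setClass("CVEvaluation",
  representation(per_fold = "data.frame", summary = "data.frame",
                 test = "data.frame"))
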