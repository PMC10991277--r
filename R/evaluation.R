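#' Pearson product-moment correlation
#'
#' Standard Pearson r between predicted and observed values. A constant
#' vector makes the correlation undefined; that is signalled as \code{NA}
#' with a warning, deliberately distinct from 0, so sign analyses are never
#' corrupted by silent zeros.
#'
#' @param pred,obs numeric vectors of equal length >= 2.
#' @return Pearson r in [-1, 1], or NA when undefined.
#' @export
pearsonR <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 2L) stop("need at least 2 pairs")
  if (sd(pred) == 0 || sd(obs) == 0) {
    warning("correlation undefined for a constant vector")
    return(NA_real_)
  }
  cor(pred, obs)
}

#' Mean absolute error in degrees Celsius
#' @param pred,obs numeric vectors of equal length >= 1.
#' @return mean of absolute differences.
#' @export
maeCelsius <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch")
  if (length(pred) < 1L) stop("empty input")
  mean(abs(pred - obs))
}

#' Genome-level prediction averages
#'
#' Averages per-protein predictions within each genome (unweighted arithmetic
#' mean) to obtain the genome's predicted optimal temperature, paired with
#' the experimentally known OGT. Genomes with no contributing predictions are
#' omitted with a logged warning.
#'
#' @param predictions numeric vector of per-protein predicted temperatures,
#'   named by protein id.
#' @param corpus the \linkS4class{ThermoCorpus} the proteins resolve in.
#' @return data.frame (genome_id, optTem_pre, optTem_exp, n_proteins).
#' @export
genomeAverage <- function(predictions, corpus) {
  if (is.null(names(predictions))) stop("predictions must be named by protein id")
  info <- proteinInfo(corpus)
  gid <- info$genome_id[match(names(predictions), info$protein_id)]
  if (any(is.na(gid)))
    stop("predictions for unknown protein(s): ",
         paste(head(names(predictions)[is.na(gid)], 5), collapse = ", "))
  means <- tapply(predictions, gid, mean)
  counts <- tapply(predictions, gid, length)
  g <- genomes(corpus)
  absent <- setdiff(g$genome_id, names(means))
  if (length(absent))
    log_msg(length(absent), " genome(s) had no predictions and were omitted")
  data.frame(genome_id = names(means),
             optTem_pre = as.numeric(means),
             optTem_exp = g$ogt_celsius[match(names(means), g$genome_id)],
             n_proteins = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Amino-acid frequency versus thermophilicity
#'
#' For each of the 20 standard residues, correlates its per-protein frequency
#' (count divided by sequence length, unknown residues excluded from both
#' numerator and denominator) with the protein's temperature label across all
#' labelled proteins. Undefined correlations (constant frequency) are
#' reported as \code{NA}, with their count in the \code{n_undefined}
#' attribute. P-values are two-sided correlation-test p-values with no
#' multiple-testing correction (none is applied upstream either).
#'
#' @param corpus a labelled \linkS4class{ThermoCorpus}.
#' @param level \code{"protein"} (default) correlates per-protein frequencies
#'   with protein labels; \code{"genome"} pools frequencies per genome first.
#' @return data.frame (amino_acid, pearson_r, p_value, n), 20 rows.
#' @export
aaFrequencyCorrelation <- function(corpus, level = c("protein", "genome")) {
  level <- match.arg(level)
  info <- proteinInfo(corpus)
  keep <- !is.na(info$label_celsius)
  if (sum(keep) < 2L) stop("need at least 2 labelled proteins")
  aa <- proteins(corpus)[keep]
  lab <- info$label_celsius[keep]
  counts <- Biostrings::letterFrequency(aa, letters = AA_ALPHABET20)
  n_std <- rowSums(counts)
  ok <- n_std > 0
  if (any(!ok)) {
    log_msg(sum(!ok), " protein(s) of only unknown residues dropped from the ",
            "frequency analysis")
    counts <- counts[ok, , drop = FALSE]; lab <- lab[ok]; n_std <- n_std[ok]
  }
  freq <- counts / n_std
  if (level == "genome") {
    gid <- info$genome_id[keep][ok]
    freq <- apply(freq, 2, function(f) tapply(f, gid, mean))
    lab <- tapply(lab, gid, mean)[rownames(freq)]
  }
  if (length(unique(lab)) < 2L) stop("labels are constant; correlation undefined")
  res <- lapply(AA_ALPHABET20, function(a) {
    f <- freq[, a]
    if (sd(f) == 0)
      return(data.frame(amino_acid = a, pearson_r = NA_real_,
                        p_value = NA_real_, n = length(f)))
    if (length(f) < 3L)  # r is defined at n = 2 but the t-test is not
      return(data.frame(amino_acid = a, pearson_r = cor(f, lab),
                        p_value = NA_real_, n = length(f)))
    ct <- cor.test(f, lab)
    data.frame(amino_acid = a, pearson_r = unname(ct$estimate),
               p_value = ct$p.value, n = length(f))
  })
  out <- do.call(rbind, res)
  attr(out, "n_undefined") <- sum(is.na(out$pearson_r))
  out
}

# Predict for a set of proteins with either a trained model or a stub function.
predictWith <- function(model, corpus, ids) {
  seqs <- asSequenceVector(corpus)[ids]
  predictOptTemp(model, seqs)
}

#' Evaluate cross-validation fold models
#'
#' Scores each fold model on its own training and validation proteins
#' (Pearson r and MAE), summarises mean and standard deviation across folds,
#' and scores the held-out test pool. By default test-pool proteins are
#' scored by the mean of all fold models' predictions (ensemble mean);
#' \code{ensemble = FALSE} reports the per-model test metrics' mean instead.
#'
#' @param models list of length \code{k}: fold models (element \code{f+1} is
#'   the model validated on fold \code{f}); each a trained
#'   \linkS4class{OptTempCNN} or a prediction function.
#' @param split a \linkS4class{SplitPlan}.
#' @param corpus the \linkS4class{ThermoCorpus}.
#' @param ensemble logical, see above.
#' @return a \linkS4class{CVEvaluation}.
#' @export
evaluateCV <- function(models, split, corpus, ensemble = TRUE) {
  k <- split@k
  if (length(models) != k)
    stop("need one model per fold: got ", length(models), " for k = ", k)
  fop <- foldOfProtein(split)
  info <- proteinInfo(corpus)
  lab <- stats::setNames(info$label_celsius, info$protein_id)

  rows <- list()
  for (f in 0:(k - 1L)) {
    m <- models[[f + 1L]]
    if (is.null(m)) stop("missing model for fold ", f)
    val_ids <- names(fop)[fop == f]
    tr_ids <- names(fop)[fop != f]
    for (part in c("train", "validation")) {
      ids <- if (part == "train") tr_ids else val_ids
      pred <- predictWith(m, corpus, ids)
      rows[[length(rows) + 1L]] <- data.frame(
        fold = f, split = part, n = length(ids),
        pearson_r = suppressWarnings(pearsonR(pred, lab[ids])),
        mae_celsius = maeCelsius(pred, lab[ids]))
    }
  }
  per_fold <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(c("train", "validation"), function(part) {
    x <- per_fold[per_fold$split == part, ]
    data.frame(split = part, mean_r = mean(x$pearson_r), sd_r = sd(x$pearson_r),
               mean_mae = mean(x$mae_celsius), sd_mae = sd(x$mae_celsius))
  }))

  te <- testIds(split)
  if (length(te)) {
    preds <- vapply(models, function(m) predictWith(m, corpus, te),
                    numeric(length(te)))
    if (ensemble) {
      ens <- rowMeans(preds)
      test <- data.frame(n = length(te),
                         pearson_r = suppressWarnings(pearsonR(ens, lab[te])),
                         mae_celsius = maeCelsius(ens, lab[te]))
    } else {
      rs <- apply(preds, 2, function(p) suppressWarnings(pearsonR(p, lab[te])))
      maes <- apply(preds, 2, function(p) maeCelsius(p, lab[te]))
      test <- data.frame(n = length(te), pearson_r = mean(rs),
                         mae_celsius = mean(maes))
    }
  } else {
    test <- data.frame(n = 0L, pearson_r = NA_real_, mae_celsius = NA_real_)
  }
  methods::new("CVEvaluation", per_fold = per_fold, summary = summ, test = test)
}

setMethod("show", "CVEvaluation", function(object) {
  cat("CVEvaluation over", length(unique(object@per_fold$fold)), "folds\n")
  print(object@summary, row.names = FALSE)
  cat("test pool:\n")
  print(object@test, row.names = FALSE)
})

#' Write an evaluation report as TSV and JSON
#' @param evaluation a \linkS4class{CVEvaluation}.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
writeEvaluation <- function(evaluation, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(evaluation@per_fold, file.path(dir, "per_fold.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(per_fold = evaluation@per_fold,
                            summary = evaluation@summary,
                            test = evaluation@test),
                       file.path(dir, "evaluation.json"), digits = NA)
  invisible(dir)
}
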