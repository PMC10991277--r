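#' Parse a HMMER3 hmmsearch --tblout table
#'
#' Reads the per-target tabular output of \code{hmmsearch --tblout}:
#' whitespace-delimited data lines with 18 fixed fields followed by a free
#'-text description, \code{#} comment lines ignored. The target name becomes
#' the protein id and the query accession (falling back to the query name
#' when the accession is \code{"-"}) the Pfam id; the full-sequence E-value
#' and bit score are kept.
#'
#' @param path path to the tblout file.
#' @return data.frame (protein_id, pfam_id, full_seq_evalue, full_seq_score),
#'   zero rows (with a warning) for a file with no data lines.
#' @export
parseHmmsearchTblout <- function(path) {
  lines <- readLines(path)
  data <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(), pfam_id = character(),
                      full_seq_evalue = numeric(), full_seq_score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(data) == 0L) {
    warning("no data lines in tblout file: ", path)
    return(empty)
  }
  line_no <- match(data, lines)
  rows <- lapply(seq_along(data), function(i) {
    f <- strsplit(trimws(data[i]), "[[:space:]]+")[[1]]
    if (length(f) < 18L)
      stop("malformed tblout data line ", line_no[i], ": expected >= 18 fields, got ",
           length(f))
    ev <- suppressWarnings(as.numeric(f[5]))
    sc <- suppressWarnings(as.numeric(f[6]))
    if (is.na(ev) || is.na(sc) || ev < 0)
      stop("malformed tblout data line ", line_no[i],
           ": bad E-value or score ('", f[5], "', '", f[6], "')")
    data.frame(protein_id = f[1],
               pfam_id = if (f[4] == "-") f[3] else f[4],
               full_seq_evalue = ev, full_seq_score = sc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Filter and deduplicate domain hits
#'
#' Keeps hits at or below the E-value cutoff, one row per protein (the best,
#' i.e. smallest, E-value wins). The upstream screen prints no cutoff; the
#' conventional domain-screen default of 1e-5 is used and logged.
#'
#' @param hits data.frame from \code{\link{parseHmmsearchTblout}}.
#' @param evalue_max E-value cutoff (> 0); \code{Inf} keeps everything.
#' @return filtered, deduplicated data.frame ordered by E-value.
#' @export
filterHits <- function(hits, evalue_max = 1e-5) {
  if (!is.numeric(evalue_max) || evalue_max <= 0) stop("evalue_max must be > 0")
  log_msg("filtering domain hits at E-value <= ", format(evalue_max))
  kept <- hits[hits$full_seq_evalue <= evalue_max, , drop = FALSE]
  kept <- kept[order(kept$full_seq_evalue, kept$protein_id), , drop = FALSE]
  kept <- kept[!duplicated(kept$protein_id), , drop = FALSE]
  rownames(kept) <- NULL
  kept
}

#' Mine candidate thermophilic enzymes from domain hits
#'
#' Predicts an optimal temperature for every hit protein, ranks descending by
#' prediction (ties broken by ascending protein id), and bins each candidate:
#' psychrophilic below \code{t_low}, thermophilic above \code{t_high},
#' mesophilic in between. Thresholds default to the training-class
#' boundaries (20, 50) degrees Celsius.
#'
#' @param hits filtered hits (see \code{\link{filterHits}}).
#' @param sequences sequence source every hit resolves in: an
#'   \link[Biostrings]{AAStringSet}, named character vector or
#'   \linkS4class{ThermoCorpus}.
#' @param model trained \linkS4class{OptTempCNN} or a prediction function.
#' @param t_low,t_high binning thresholds, \code{t_low < t_high}.
#' @return a \linkS4class{MiningResult}.
#' @export
mineCandidates <- function(hits, sequences, model, t_low = 20, t_high = 50) {
  if (t_low >= t_high) stop("t_low must be < t_high")
  if (nrow(hits) == 0L) stop("no hits to mine")
  seqs <- asSequenceVector(sequences)
  missing <- setdiff(hits$protein_id, names(seqs))
  if (length(missing))
    stop("hit protein id(s) not in the sequence source: ",
         paste(head(missing, 10), collapse = ", "))
  pred <- predictOptTemp(model, seqs[hits$protein_id])
  bin <- ifelse(pred < t_low, "psychrophilic",
                ifelse(pred > t_high, "thermophilic", "mesophilic"))
  ord <- order(-pred, hits$protein_id)
  ranked <- data.frame(rank = seq_along(ord),
                       protein_id = hits$protein_id[ord],
                       predicted_temp = as.numeric(pred[ord]),
                       temp_bin = bin[ord],
                       full_seq_evalue = hits$full_seq_evalue[ord],
                       stringsAsFactors = FALSE, row.names = NULL)
  fr <- table(factor(bin, levels = c("psychrophilic", "mesophilic",
                                     "thermophilic"))) / length(bin)
  methods::new("MiningResult", ranked = ranked,
               bin_fractions = stats::setNames(as.numeric(fr), names(fr)),
               thresholds = c(t_low = t_low, t_high = t_high))
}

setMethod("show", "MiningResult", function(object) {
  cat("MiningResult:", nrow(object@ranked), "candidates; bins (psy/mes/the):",
      paste(sprintf("%.1f%%", 100 * object@bin_fractions), collapse = "/"), "\n")
  if (nrow(object@ranked))
    cat("  top candidate:", object@ranked$protein_id[1], "at",
        sprintf("%.1f", object@ranked$predicted_temp[1]), "degrees C\n")
})

#' Export top mining candidates
#'
#' Writes the top-\code{n} candidates as FASTA (rank and predicted
#' temperature carried in the description) and the full ranked table as TSV.
#' Requesting more candidates than exist exports everything with a warning.
#'
#' @param result a \linkS4class{MiningResult}.
#' @param top_n number of candidates to export (>= 1).
#' @param sequences the sequence source the candidates resolve in.
#' @param fasta_path,tsv_path output paths.
#' @return invisibly, the exported subset of the ranked table.
#' @export
exportCandidates <- function(result, top_n, sequences, fasta_path, tsv_path) {
  if (top_n < 1L) stop("top_n must be >= 1")
  ranked <- result@ranked
  if (top_n > nrow(ranked)) {
    warning("top_n = ", top_n, " exceeds the ", nrow(ranked),
            "-candidate table; exporting all")
    top_n <- nrow(ranked)
  }
  top <- ranked[seq_len(top_n), , drop = FALSE]
  seqs <- asSequenceVector(sequences)[top$protein_id]
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- sprintf("%s rank=%d predicted_temp=%.2f", top$protein_id,
                        top$rank, top$predicted_temp)
  Biostrings::writeXStringSet(out, fasta_path)
  write.table(top, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(top)
}
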