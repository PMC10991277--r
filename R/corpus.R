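#' Assign a temperature class from an optimal growth temperature
#'
#' Organisms are classed by their optimal growth temperature (OGT):
#' psychrophilic below 20 degrees C, mesophilic strictly between 30 and 40,
#' thermophilic above 50. The inequalities are strict, so the boundary values
#' 20/30/40/50 and the gap bands [20,30] and [40,50] are "excluded": genomes
#' there contribute no regression label.
#'
#' @param ogt_celsius numeric vector of optimal growth temperatures (degrees C).
#' @return factor with levels psychrophilic, mesophilic, thermophilic, excluded.
#' @examples
#' assignTempClass(c(15, 35, 55, 20, 45))
#' @export
assignTempClass <- function(ogt_celsius) {
  if (!is.numeric(ogt_celsius) || any(!is.finite(ogt_celsius)))
    stop("ogt_celsius must be finite numeric (invalid metadata)")
  cls <- rep("excluded", length(ogt_celsius))
  cls[ogt_celsius < 20] <- "psychrophilic"
  cls[ogt_celsius > 30 & ogt_celsius < 40] <- "mesophilic"
  cls[ogt_celsius > 50] <- "thermophilic"
  factor(cls, levels = TEMP_CLASSES)
}

# Normalise a raw amino-acid string onto the closed 21-letter alphabet:
# uppercase, then every character outside the 20 standard residues becomes
# the single unknown symbol "X" (covers B, J, O, U, Z, X, '*', gaps, ...).
normalizeResidues <- function(seqs) {
  up <- toupper(seqs)
  gsub(sprintf("[^%s]", paste(AA_ALPHABET20, collapse = "")), AA_UNKNOWN, up)
}

# Default FASTA-record-id -> genome-id rule: the text before the first '|'.
defaultGenomeOfRecord <- function(record_ids) {
  sub("\\|.*$", "", record_ids)
}

#' Load a temperature-labelled protein corpus
#'
#' Reads one or more amino-acid FASTA files plus a tab-separated metadata
#' table (columns \code{genome_id}, \code{species}, \code{ogt_celsius}),
#' assigns each genome its temperature class, and stamps every protein of a
#' non-excluded genome with its genome's OGT as regression label. Proteins of
#' excluded genomes are kept, unlabelled, so they can still be scored later.
#' Non-standard residues are normalised to \code{"X"} at load time.
#'
#' @param fasta_paths character vector of FASTA file paths.
#' @param metadata_path path to the metadata TSV (header row required).
#' @param genome_map optional data.frame (\code{record_id}, \code{genome_id})
#'   overriding the default rule that the genome id is the text before the
#'   first \code{"|"} in the FASTA record id.
#' @return a \linkS4class{ThermoCorpus}.
#' @export
loadCorpus <- function(fasta_paths, metadata_path, genome_map = NULL) {
  meta <- read.delim(metadata_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("genome_id", "species", "ogt_celsius")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  meta$genome_id <- as.character(meta$genome_id)
  if (anyDuplicated(meta$genome_id))
    stop("duplicate genome_id in metadata")
  meta$temp_class <- as.character(assignTempClass(meta$ogt_celsius))

  seq_chunks <- lapply(fasta_paths, function(p) {
    x <- Biostrings::readAAStringSet(p)
    if (length(x) == 0) stop("empty FASTA: ", p)
    x
  })
  aa <- do.call(c, seq_chunks)
  record_ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(record_ids))
    stop("duplicate protein ids across FASTA inputs: ",
         paste(head(unique(record_ids[duplicated(record_ids)]), 5), collapse = ", "))

  if (is.null(genome_map)) {
    gid <- defaultGenomeOfRecord(record_ids)
  } else {
    gid <- genome_map$genome_id[match(record_ids, genome_map$record_id)]
    if (any(is.na(gid)))
      stop("records missing from genome_map: ",
           paste(head(record_ids[is.na(gid)], 5), collapse = ", "))
    gid <- as.character(gid)
  }
  unknown <- setdiff(unique(gid), meta$genome_id)
  if (length(unknown)) {
    offending <- record_ids[gid %in% unknown]
    stop("FASTA records reference genomes absent from metadata: ",
         paste(head(offending, 10), collapse = ", "))
  }

  raw <- as.character(aa)
  norm <- normalizeResidues(raw)
  n_changed <- sum(norm != toupper(raw))
  if (n_changed > 0)
    log_msg(n_changed, " sequence(s) had non-standard residues normalised to '",
            AA_UNKNOWN, "'")
  if (any(nchar(norm) == 0)) stop("zero-length sequence in FASTA input")

  prot <- Biostrings::AAStringSet(norm)
  names(prot) <- record_ids
  midx <- match(gid, meta$genome_id)
  label <- ifelse(meta$temp_class[midx] == "excluded", NA_real_,
                  meta$ogt_celsius[midx])
  S4Vectors::mcols(prot) <- S4Vectors::DataFrame(
    protein_id = record_ids, genome_id = gid, label_celsius = label)

  prov <- c(paste("fasta:", fasta_paths), paste("metadata:", metadata_path),
            paste("residues_normalised:", n_changed))
  methods::new("ThermoCorpus", genomes = meta[, c(need, "temp_class")],
               proteins = prot, provenance = prov)
}

#' Build a corpus from in-memory tables (used by the synthetic generator)
#' @param genomes data.frame with genome_id, species, ogt_celsius.
#' @param protein_tbl data.frame with protein_id, genome_id, sequence.
#' @param provenance character log lines.
#' @return a \linkS4class{ThermoCorpus}.
#' @keywords internal
makeCorpus <- function(genomes, protein_tbl, provenance = "in-memory") {
  genomes$genome_id <- as.character(genomes$genome_id)
  genomes$temp_class <- as.character(assignTempClass(genomes$ogt_celsius))
  prot <- Biostrings::AAStringSet(normalizeResidues(protein_tbl$sequence))
  names(prot) <- protein_tbl$protein_id
  midx <- match(protein_tbl$genome_id, genomes$genome_id)
  if (any(is.na(midx)))
    stop("proteins reference unknown genomes: ",
         paste(head(protein_tbl$protein_id[is.na(midx)], 5), collapse = ", "))
  label <- ifelse(genomes$temp_class[midx] == "excluded", NA_real_,
                  genomes$ogt_celsius[midx])
  S4Vectors::mcols(prot) <- S4Vectors::DataFrame(
    protein_id = as.character(protein_tbl$protein_id),
    genome_id = as.character(protein_tbl$genome_id),
    label_celsius = label)
  methods::new("ThermoCorpus",
               genomes = genomes[, c("genome_id", "species", "ogt_celsius", "temp_class")],
               proteins = prot, provenance = provenance)
}

#' @rdname ThermoCorpus-class
#' @export
setMethod("genomes", "ThermoCorpus", function(x) x@genomes)

#' @rdname ThermoCorpus-class
#' @export
setMethod("proteins", "ThermoCorpus", function(x) x@proteins)

#' @rdname ThermoCorpus-class
#' @export
setMethod("provenance", "ThermoCorpus", function(x) x@provenance)

#' Protein metadata of a corpus as a data.frame
#' @param corpus a \linkS4class{ThermoCorpus}.
#' @return data.frame (protein_id, genome_id, label_celsius, width).
#' @export
proteinInfo <- function(corpus) {
  m <- S4Vectors::mcols(corpus@proteins)
  data.frame(protein_id = m$protein_id, genome_id = m$genome_id,
             label_celsius = m$label_celsius,
             width = Biostrings::width(corpus@proteins),
             stringsAsFactors = FALSE)
}

#' Per-class genome and protein counts
#'
#' Tabulates how many genomes and proteins fall in each temperature class.
#' Labelled proteins are partitioned by their genome's class; proteins of
#' excluded genomes are counted in the \code{excluded} row (unlabelled).
#'
#' @param corpus a \linkS4class{ThermoCorpus}.
#' @return data.frame (temp_class, n_genomes, n_proteins) with one row per
#'   class, zero-filled.
#' @export
corpusSummary <- function(corpus) {
  g <- corpus@genomes
  m <- S4Vectors::mcols(corpus@proteins)
  pclass <- g$temp_class[match(m$genome_id, g$genome_id)]
  data.frame(
    temp_class = TEMP_CLASSES,
    n_genomes = as.integer(table(factor(g$temp_class, levels = TEMP_CLASSES))),
    n_proteins = as.integer(table(factor(pclass, levels = TEMP_CLASSES))),
    stringsAsFactors = FALSE)
}

#' Write a corpus summary as TSV and JSON
#' @param corpus a \linkS4class{ThermoCorpus}.
#' @param dir output directory (created if missing).
#' @return invisibly, the summary data.frame.
#' @export
writeCorpusSummary <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- corpusSummary(corpus)
  write.table(s, file.path(dir, "corpus_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(s, file.path(dir, "corpus_summary.json"), digits = NA)
  invisible(s)
}

setMethod("show", "ThermoCorpus", function(object) {
  s <- corpusSummary(object)
  cat("ThermoCorpus with", nrow(object@genomes), "genomes and",
      length(object@proteins), "proteins\n")
  cat("  labelled:", sum(!is.na(S4Vectors::mcols(object@proteins)$label_celsius)),
      "| per class (genomes/proteins):",
      paste(sprintf("%s %d/%d", substr(s$temp_class, 1, 3), s$n_genomes, s$n_proteins),
            collapse = ", "), "\n")
})
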