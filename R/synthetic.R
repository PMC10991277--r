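#' Define the synthetic study conditions
#'
#' The generator emulates genomes of three temperature classes whose protein
#' amino-acid composition is statistically linked to the genome's optimal
#' growth temperature, organised into cross-genome ortholog families.
#' Genome OGTs are drawn uniformly from (5, 19), (31, 39) and (51, 95)
#' degrees Celsius, so generated OGTs never fall in the excluded bands
#' [20, 30] and [40, 50]. Hot genomes are enriched for E/L/V/Y and depleted
#' of D/H/M/Q/S/T (and vice versa for cold genomes), with residue weights
#' varying linearly with OGT, scaled by \code{enrichment_strength}.
#'
#' @param n_genomes_per_class genomes per temperature class.
#' @param proteins_per_genome proteins per genome.
#' @param families number of ortholog families.
#' @param family_span c(min, max) genomes a family covers (uniform draw).
#' @param length_range c(min, max) protein length in residues.
#' @param hot_enriched,cold_enriched disjoint residue sets planted as the
#'   thermophilic / psychrophilic signal.
#' @param enrichment_strength tilt strength in [0, 1]; 0 plants no signal.
#' @param label_noise_sd sd (degrees C) of the jitter on the temperature at
#'   which each protein's composition is generated; the stored label remains
#'   the genome OGT exactly.
#' @param substitution_rate per-site substitution probability applied when an
#'   ancestor is copied into a member genome.
#' @param paralog_rate probability that a genome covered by a family
#'   contributes a second (paralogous) member alongside the first. Real
#'   orthogroups routinely hold several genes per genome; these same-genome
#'   near-duplicates share one label and are what makes homology leakage
#'   observable when a split ignores cluster boundaries.
#' @param seed integer seed; identical spec + seed reproduce byte-identical
#'   outputs.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(n_genomes_per_class = 6L, proteins_per_genome = 200L,
                          families = 600L, family_span = c(2L, 4L),
                          length_range = c(80L, 150L),
                          hot_enriched = c("E", "L", "V", "Y"),
                          cold_enriched = c("D", "H", "M", "Q", "S", "T"),
                          enrichment_strength = 0.8, label_noise_sd = 3,
                          substitution_rate = 0.1, paralog_rate = 0.3,
                          seed = 101L) {
  methods::new("SyntheticSpec",
               n_genomes_per_class = as.integer(n_genomes_per_class),
               proteins_per_genome = as.integer(proteins_per_genome),
               families = as.integer(families),
               family_span = as.integer(family_span),
               length_range = as.integer(length_range),
               hot_enriched = hot_enriched, cold_enriched = cold_enriched,
               enrichment_strength = enrichment_strength,
               label_noise_sd = label_noise_sd,
               substitution_rate = substitution_rate,
               paralog_rate = paralog_rate, seed = as.integer(seed))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", 3L * object@n_genomes_per_class, "genomes x",
      object@proteins_per_genome, "proteins,", object@families,
      "families (span", paste(object@family_span, collapse = "-"),
      "), enrichment", object@enrichment_strength,
      ", seed", object@seed, "\n")
})

# Residue probabilities of a genome generated at temperature t: weights vary
# linearly with the normalised temperature theta = (t - 50)/45, clamped to
# [-1, 1]: hot residues get 1 + s*theta, cold 1 - s*theta, others 1.
tiltProbs <- function(t, spec) {
  theta <- max(-1, min(1, (t - 50) / 45))
  w <- rep(1, 20)
  names(w) <- AA_ALPHABET20
  w[spec@hot_enriched] <- 1 + spec@enrichment_strength * theta
  w[spec@cold_enriched] <- 1 - spec@enrichment_strength * theta
  w / sum(w)
}

# Map shared per-site uniforms through a genome's residue distribution
# (inverse-CDF coupling over the canonical residue order).
residuesFromLatent <- function(u, probs) {
  cum <- cumsum(probs)
  cum[20] <- 1
  AA_ALPHABET20[findInterval(u, cum) + 1L]
}

#' Generate a synthetic corpus with a planted compositional signal
#'
#' Each ortholog family descends from one ancestor: a vector of shared
#' per-site latent draws, realised in every member genome through that
#' genome's temperature-tilted residue distribution and then hit by
#' \code{substitution_rate} per-site substitutions. Members of thermally
#' similar genomes are therefore near-identical (the homology the
#' cluster-aware split must respect), while every protein's marginal
#' composition carries its own genome's full temperature signal — the
#' compositional thermoadaptation the downstream model is meant to recover.
#' Proteins outside families (singletons) are drawn directly from their
#' genome's tilted distribution.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return list with \code{corpus} (\linkS4class{ThermoCorpus}),
#'   \code{clusters} (\linkS4class{OrthologClusters}; one per family), and
#'   \code{truth} (generator bookkeeping: genome table, per-protein family
#'   and generation temperature, enriched residue sets).
#' @export
generateCorpus <- function(spec) {
  methods::validObject(spec)
  n_cls <- spec@n_genomes_per_class
  n_gen <- 3L * n_cls
  if (spec@family_span[2] > n_gen)
    stop("family_span (", spec@family_span[2], ") exceeds the genome count (",
         n_gen, ")")
  with_seed(spec@seed, {
    gid <- c(sprintf("PSY%02d", seq_len(n_cls)),
             sprintf("MES%02d", seq_len(n_cls)),
             sprintf("THE%02d", seq_len(n_cls)))
    ogt <- c(runif(n_cls, 5, 19), runif(n_cls, 31, 39), runif(n_cls, 51, 95))
    genome_tbl <- data.frame(
      genome_id = gid,
      species = sprintf("Synthetica specimen %02d", seq_len(n_gen)),
      ogt_celsius = round(ogt, 2), stringsAsFactors = FALSE)
    # assign families to genome subsets
    spans <- sample(seq(spec@family_span[1], spec@family_span[2]),
                    spec@families, replace = TRUE)
    fam_genomes <- lapply(spans, function(s) sort(sample(gid, s)))
    # each covered genome contributes 1 or (with paralog_rate) 2 members
    fam_copies <- lapply(fam_genomes, function(gs)
      1L + stats::rbinom(length(gs), 1L, spec@paralog_rate))
    n_fam_per_genome <- tapply(unlist(fam_copies),
                               factor(unlist(fam_genomes), levels = gid),
                               sum, default = 0L)
    if (any(n_fam_per_genome > spec@proteins_per_genome))
      stop("infeasible spec: genome(s) assigned more family members (max ",
           max(n_fam_per_genome), ") than proteins_per_genome (",
           spec@proteins_per_genome, ")")

    ids <- character(0); gids <- character(0); seqs <- character(0)
    fams <- character(0); gen_temps <- numeric(0)
    cluster_members <- vector("list", spec@families)
    names(cluster_members) <- sprintf("OG%06d", seq_len(spec@families))

    ogt_of <- stats::setNames(genome_tbl$ogt_celsius, gid)
    for (j in seq_len(spec@families)) {
      len <- sample(seq(spec@length_range[1], spec@length_range[2]), 1L)
      u <- runif(len)
      mem_ids <- character(0)
      for (i in seq_along(fam_genomes[[j]])) {
        g <- fam_genomes[[j]][i]
        for (copy in seq_len(fam_copies[[j]][i])) {
          t_gen <- ogt_of[[g]] + rnorm(1, 0, spec@label_noise_sd)
          p <- tiltProbs(t_gen, spec)
          res <- residuesFromLatent(u, p)
          sub <- runif(len) < spec@substitution_rate
          if (any(sub))
            res[sub] <- sample(AA_ALPHABET20, sum(sub), replace = TRUE, prob = p)
          pid <- sprintf("%s|OG%06d.%d", g, j, copy)
          mem_ids <- c(mem_ids, pid)
          ids <- c(ids, pid); gids <- c(gids, g)
          seqs <- c(seqs, paste(res, collapse = ""))
          fams <- c(fams, names(cluster_members)[j])
          gen_temps <- c(gen_temps, t_gen)
        }
      }
      cluster_members[[j]] <- mem_ids
    }

    # fill every genome up to proteins_per_genome with singletons
    for (g in gid) {
      n_single <- spec@proteins_per_genome - as.integer(n_fam_per_genome[[g]])
      if (n_single <= 0) next
      for (s in seq_len(n_single)) {
        len <- sample(seq(spec@length_range[1], spec@length_range[2]), 1L)
        t_gen <- ogt_of[[g]] + rnorm(1, 0, spec@label_noise_sd)
        p <- tiltProbs(t_gen, spec)
        res <- sample(AA_ALPHABET20, len, replace = TRUE, prob = p)
        pid <- sprintf("%s|S%04d", g, s)
        ids <- c(ids, pid); gids <- c(gids, g)
        seqs <- c(seqs, paste(res, collapse = ""))
        fams <- c(fams, NA_character_); gen_temps <- c(gen_temps, t_gen)
      }
    }

    corpus <- makeCorpus(genome_tbl,
                         data.frame(protein_id = ids, genome_id = gids,
                                    sequence = seqs, stringsAsFactors = FALSE),
                         provenance = sprintf("synthetic corpus, seed %d", spec@seed))
    clusters <- methods::new("OrthologClusters",
                             members = IRanges::CharacterList(cluster_members))
    truth <- list(genomes = genome_tbl,
                  proteins = data.frame(protein_id = ids, genome_id = gids,
                                        family = fams, gen_temp = gen_temps,
                                        stringsAsFactors = FALSE),
                  hot_enriched = spec@hot_enriched,
                  cold_enriched = spec@cold_enriched, spec = spec)
    list(corpus = corpus, clusters = clusters, truth = truth)
  })
}

#' Write a generated corpus to standard on-disk formats
#'
#' Emits one amino-acid FASTA per genome, the metadata TSV dialect of
#' \code{\link{loadCorpus}}, and an Orthogroups.tsv in the dialect of
#' \code{\link{parseOrthogroups}}. Identical spec + seed produce
#' byte-identical files.
#'
#' @param generated output of \code{\link{generateCorpus}}.
#' @param dir output directory (created).
#' @return invisibly, a list of written paths (fasta, metadata, orthogroups).
#' @export
writeCorpusFiles <- function(generated, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generated$corpus
  g <- genomes(corpus)
  info <- proteinInfo(corpus)
  seqs <- asSequenceVector(corpus)
  fasta_paths <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    ids <- info$protein_id[info$genome_id == g$genome_id[i]]
    x <- Biostrings::AAStringSet(seqs[ids])
    fasta_paths[i] <- file.path(dir, paste0(g$genome_id[i], ".faa"))
    Biostrings::writeXStringSet(x, fasta_paths[i])
  }
  meta_path <- file.path(dir, "metadata.tsv")
  write.table(g[, c("genome_id", "species", "ogt_celsius")], meta_path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  og_path <- file.path(dir, "Orthogroups.tsv")
  mem <- members(generated$clusters)
  og <- data.frame(Orthogroup = names(mem), stringsAsFactors = FALSE)
  gid_of <- stats::setNames(info$genome_id, info$protein_id)
  for (gi in g$genome_id) {
    og[[gi]] <- vapply(as.list(mem), function(m)
      paste(m[gid_of[m] == gi], collapse = ", "), "")
  }
  write.table(og, og_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta_paths, metadata = meta_path, orthogroups = og_path))
}

#' Generate a mining fixture: FASTA plus a matching hmmsearch tblout
#'
#' Fabricates a small domain-screen scenario: \code{n_family_members} target
#' "family" proteins plus \code{n_decoys} decoys in one FASTA, and a
#' HMMER3-tblout-shaped table listing exactly the family members with
#' E-values at or below 1e-10 (decoys absent). Member compositions span the
#' whole temperature range so predictions spread across all three bins.
#'
#' @param spec a \linkS4class{SyntheticSpec} (lengths and tilt reused).
#' @param n_family_members,n_decoys positive counts.
#' @param dir output directory.
#' @param pfam_id accession written in the query-accession column.
#' @return list (fasta, tblout, member_ids, decoy_ids, member_temps).
#' @export
generateMiningFixture <- function(spec = syntheticSpec(), n_family_members = 5L,
                                  n_decoys = 3L, dir = tempfile("mining"),
                                  pfam_id = "PF00704.30") {
  stopifnot(n_family_members >= 1L, n_decoys >= 0L)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec@seed + 7L, {
    member_ids <- sprintf("mg_fam%03d", seq_len(n_family_members))
    decoy_ids <- if (n_decoys > 0) sprintf("mg_decoy%03d", seq_len(n_decoys))
                 else character(0)
    temps <- runif(n_family_members + n_decoys, 5, 95)
    all_ids <- c(member_ids, decoy_ids)
    seqs <- vapply(seq_along(all_ids), function(i) {
      len <- sample(seq(spec@length_range[1], spec@length_range[2]), 1L)
      paste(sample(AA_ALPHABET20, len, replace = TRUE,
                   prob = tiltProbs(temps[i], spec)), collapse = "")
    }, "")
    fasta <- file.path(dir, "catalogue.faa")
    x <- Biostrings::AAStringSet(stats::setNames(seqs, all_ids))
    Biostrings::writeXStringSet(x, fasta)

    tblout <- file.path(dir, "hits.tblout")
    evalues <- 10^-(10 + seq_len(n_family_members))
    scores <- 200 - seq_len(n_family_members)
    lines <- c(
      "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
      "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
      "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- ---- --- --- --- --- --- --- --- ---------------------",
      sprintf("%-20s -          %-20s %s %9.1e %6.1f   0.1 %9.1e %6.1f   0.1  1.0   1   0   0   1   1   1   1 synthetic family member",
              member_ids, "GH18_domain", pfam_id, evalues, scores,
              evalues, scores - 0.5),
      "#",
      "# Program:         hmmsearch")
    writeLines(lines, tblout)
    list(fasta = fasta, tblout = tblout, member_ids = member_ids,
         decoy_ids = decoy_ids,
         member_temps = stats::setNames(temps[seq_len(n_family_members)],
                                        member_ids))
  })
}
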