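# Shared in-code fixtures. Everything is generated programmatically; the
# expensive trained-model study is memoised so several test files can share
# one training run.

.fixture_env <- new.env(parent = emptyenv())

# A small three-class corpus with families, used across modules.
small_generated <- function(seed = 11L) {
  key <- paste0("gen", seed)
  if (is.null(.fixture_env[[key]])) {
    spec <- syntheticSpec(n_genomes_per_class = 2L, proteins_per_genome = 30L,
                          families = 12L, family_span = c(2L, 3L),
                          length_range = c(40L, 60L), seed = seed)
    .fixture_env[[key]] <- generateCorpus(spec)
  }
  .fixture_env[[key]]
}

# Hand-written two-genome corpus for exact-count assertions.
tiny_corpus_files <- function(dir = tempfile("corpus")) {
  dir.create(dir)
  f1 <- file.path(dir, "gA.faa")
  writeLines(c(">gA|p1 first protein", "MKLV", ">gA|p2", "AACD", ">gA|p3", "GGG"), f1)
  f2 <- file.path(dir, "gB.faa")
  writeLines(c(">gB|p1", "WYYW", ">gB|p2", "MKbuZ*"), f2)
  meta <- file.path(dir, "meta.tsv")
  writeLines(c("genome_id\tspecies\togt_celsius",
               "gA\tAlpha synthetica\t15",
               "gB\tBeta synthetica\t72"), meta)
  list(fasta = c(f1, f2), metadata = meta, dir = dir)
}

# Full-scale study under the default generator conditions; one cluster-split
# training plus the protein-level leakage control, shared by the acceptance
# tests and anything else that needs a trained model.
planted_study <- function() {
  if (is.null(.fixture_env$study))
    .fixture_env$study <- runPlantedSignalStudy(seed = 1L)
  .fixture_env$study
}

# Quick stub "model": mean-composition score mapped onto a temperature ramp;
# deterministic and cheap, used where a real model is irrelevant.
stub_model <- function(scale = 1) {
  function(seqs) {
    hot <- vapply(strsplit(seqs, ""), function(ch)
      mean(ch %in% c("E", "L", "V", "Y")), 0)
    stats::setNames(5 + 90 * hot * scale, names(seqs))
  }
}
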