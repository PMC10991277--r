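# Independent metric oracles written from the definitions, kept separate
# from the package implementations on purpose.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    (sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2)))
}
oracle_mae <- function(x, y) sum(abs(x - y)) / length(x)

test_that("pearsonR matches identity/antisymmetry and the covariance oracle", {
  x <- c(1, 3, 7, 2)
  expect_equal(pearsonR(x, x), 1.0)
  expect_equal(pearsonR(x, -x), -1.0)
  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(pearsonR(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_warning(r <- pearsonR(rep(1, 5), 1:5), "undefined")
  expect_true(is.na(r))
  expect_error(pearsonR(1:3, 1:4), "mismatch")
})

test_that("pearsonR is invariant under positive affine rescaling", {
  set.seed(11)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearsonR(2.5 * a + 7, b), pearsonR(a, b), tolerance = 1e-12)
  expect_equal(pearsonR(a, 0.1 * b - 3), pearsonR(a, b), tolerance = 1e-12)
})

test_that("maeCelsius matches examples, the oracle and translation equivariance", {
  expect_equal(maeCelsius(c(10, 20), c(12, 18)), 2.0)
  expect_equal(maeCelsius(1:5, 1:5), 0.0)
  set.seed(12)
  a <- rnorm(100, 50, 20); b <- rnorm(100, 50, 20)
  expect_equal(maeCelsius(a, b), oracle_mae(a, b), tolerance = 1e-12)
  expect_equal(maeCelsius(a + 4.2, b + 4.2), maeCelsius(a, b), tolerance = 1e-12)
  expect_error(maeCelsius(1:3, 1:4), "mismatch")
})

test_that("genome averages match a group-by oracle", {
  gen <- small_generated()
  info <- proteinInfo(gen$corpus)
  set.seed(13)
  pred <- stats::setNames(rnorm(nrow(info), 40, 15), info$protein_id)
  ga <- genomeAverage(pred, gen$corpus)
  # simple two-value check
  g1 <- info$protein_id[info$genome_id == ga$genome_id[1]]
  expect_equal(ga$optTem_pre[1], mean(pred[g1]))
  expect_equal(ga$n_proteins[1], length(g1))
  # full group-by oracle
  oracle <- tapply(pred, info$genome_id[match(names(pred), info$protein_id)], mean)
  expect_equal(ga$optTem_pre, as.vector(oracle[ga$genome_id]))
  # optTem_exp is the genome OGT
  g <- genomes(gen$corpus)
  expect_equal(ga$optTem_exp, g$ogt_celsius[match(ga$genome_id, g$genome_id)])
  # single-protein genome equals its prediction
  one <- genomeAverage(pred[1], gen$corpus)
  expect_equal(one$optTem_pre, unname(pred[1]))
})

test_that("two-point amino-acid correlations are exactly +/-1", {
  genome_tbl <- data.frame(genome_id = c("h", "c"), species = c("hot", "cold"),
                           ogt_celsius = c(80, 10))
  prot <- data.frame(protein_id = c("h|1", "c|1"), genome_id = c("h", "c"),
                     sequence = c("EE", "DD"))
  corpus <- OGTpred:::makeCorpus(genome_tbl, prot)
  aa <- aaFrequencyCorrelation(corpus)
  expect_equal(nrow(aa), 20L)
  expect_equal(aa$pearson_r[aa$amino_acid == "E"], 1.0)
  expect_equal(aa$pearson_r[aa$amino_acid == "D"], -1.0)
  # residues absent everywhere have constant (zero) frequency: undefined
  expect_true(is.na(aa$pearson_r[aa$amino_acid == "W"]))
  expect_gt(attr(aa, "n_undefined"), 0)
})

test_that("unknown residues are excluded from frequency denominators", {
  genome_tbl <- data.frame(genome_id = c("h", "c"), species = c("hot", "cold"),
                           ogt_celsius = c(80, 10))
  # X inflates raw length; frequencies must use standard residues only
  prot <- data.frame(protein_id = c("h|1", "c|1"), genome_id = c("h", "c"),
                     sequence = c("EXEX", "DXDX"))
  corpus <- OGTpred:::makeCorpus(genome_tbl, prot)
  aa <- aaFrequencyCorrelation(corpus)
  # frequency of E in "EXEX" is 2/2 = 1; constant across... only h has E
  expect_equal(aa$pearson_r[aa$amino_acid == "E"], 1.0)
})

test_that("evaluateCV reproduces stub-model metrics and hand-computed tables", {
  gen <- small_generated()
  retained <- filterMulticlassClusters(gen$clusters, gen$corpus)
  sp <- makeSplit(retained, gen$corpus, k = 2L, seed = 3)
  info <- proteinInfo(gen$corpus)
  lab <- stats::setNames(info$label_celsius, info$protein_id)

  # perfect-prediction stub: r = 1, mae = 0 everywhere
  perfect <- function(seqs) lab[names(seqs)]
  ev <- evaluateCV(list(perfect, perfect), sp, gen$corpus)
  expect_equal(ev@per_fold$pearson_r, rep(1, 4))
  expect_equal(ev@per_fold$mae_celsius, rep(0, 4))
  expect_equal(ev@test$pearson_r, 1)
  expect_equal(ev@test$mae_celsius, 0)

  # constant stub: undefined r, mae = mean absolute deviation from 50
  const <- function(seqs) stats::setNames(rep(50, length(seqs)), names(seqs))
  ev2 <- suppressWarnings(evaluateCV(list(const, const), sp, gen$corpus))
  expect_true(all(is.na(ev2@per_fold$pearson_r)))
  fop <- foldOfProtein(sp)
  v0 <- names(fop)[fop == 0L]
  expect_equal(ev2@per_fold$mae_celsius[ev2@per_fold$fold == 0 &
                                        ev2@per_fold$split == "validation"],
               mean(abs(lab[v0] - 50)))

  # hand-listed predictions: ensemble mean on the test pool
  shift_a <- function(seqs) lab[names(seqs)] + 2
  shift_b <- function(seqs) lab[names(seqs)] - 4
  ev3 <- evaluateCV(list(shift_a, shift_b), sp, gen$corpus)
  # ensemble mean is lab - 1 -> test mae exactly 1
  expect_equal(ev3@test$mae_celsius, 1)
  expect_equal(ev3@test$pearson_r, 1)
  # per-fold summary recomputes from the rows
  val <- ev3@per_fold[ev3@per_fold$split == "validation", ]
  expect_equal(ev3@summary$mean_mae[ev3@summary$split == "validation"],
               mean(val$mae_celsius))
  expect_error(evaluateCV(list(shift_a), sp, gen$corpus), "one model per fold")
})
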