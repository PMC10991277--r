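write_tblout <- function(lines, path = tempfile(fileext = ".tblout")) {
  writeLines(lines, path)
  path
}

tbl_line <- function(target, evalue, score, qacc = "PF00704.30") {
  sprintf("%s - GH18 %s %s %s 0.1 %s %s 0.1 1.0 1 0 0 1 1 1 1 candidate",
          target, qacc, format(evalue), format(score), format(evalue),
          format(score - 0.5))
}

test_that("tblout parsing keeps data lines and drops comments", {
  p <- write_tblout(c("# comment", "# another",
                      tbl_line("protA", 1e-30, 210),
                      tbl_line("protB", 1e-5, 55),
                      "#", tbl_line("protC", 0.2, 9), "# trailing"))
  hits <- parseHmmsearchTblout(p)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$protein_id, c("protA", "protB", "protC"))
  expect_equal(hits$full_seq_evalue[1], 1e-30)
  expect_equal(hits$pfam_id, rep("PF00704.30", 3))
  expect_equal(hits$full_seq_score, c(210, 55, 9))
})

test_that("malformed tblout lines error with their line number", {
  p <- write_tblout(c("# head", tbl_line("ok", 1e-9, 80), "truncated line"))
  expect_error(parseHmmsearchTblout(p), "line 3")
  p2 <- write_tblout(c(tbl_line("ok", 1e-9, 80),
                       gsub("1e-09", "notanumber", tbl_line("bad", 1e-9, 70))))
  expect_error(parseHmmsearchTblout(p2), "line 2")
  empty <- write_tblout(c("# only", "# comments"))
  expect_warning(h <- parseHmmsearchTblout(empty), "no data lines")
  expect_equal(nrow(h), 0L)
})

test_that("hit filtering applies the cutoff and keeps the best duplicate", {
  hits <- data.frame(protein_id = c("a", "b", "a"),
                     pfam_id = "PF00704",
                     full_seq_evalue = c(1e-4, 1e-1, 1e-10),
                     full_seq_score = c(40, 10, 90))
  f <- suppressMessages(filterHits(hits, evalue_max = 1e-3))
  expect_equal(f$protein_id, "a")
  expect_equal(f$full_seq_evalue, 1e-10)
  f2 <- suppressMessages(filterHits(hits, evalue_max = Inf))
  expect_equal(nrow(f2), 2L)  # dedup only
  expect_error(filterHits(hits, evalue_max = 0), "> 0")
})

test_that("mining bins, ranks and ties deterministically", {
  seqs <- c(p1 = "AAAA", p2 = "CCCC", p3 = "DDDD", p4 = "EEEE")
  hits <- data.frame(protein_id = c("p1", "p2", "p3", "p4"),
                     pfam_id = "PF00704",
                     full_seq_evalue = rep(1e-20, 4), full_seq_score = 50)
  temps <- c(p1 = 15, p2 = 35, p3 = 55, p4 = 55)
  stub <- function(s) temps[names(s)]
  res <- mineCandidates(hits, seqs, stub, t_low = 20, t_high = 50)
  expect_s4_class(res, "MiningResult")
  expect_equal(sum(res@bin_fractions), 1, tolerance = 1e-12)
  expect_equal(unname(res@bin_fractions),
               c(1, 1, 2) / 4)
  # tie at 55: lexicographically smaller id ranks first
  expect_equal(res@ranked$protein_id[1:2], c("p3", "p4"))
  expect_equal(res@ranked$rank, 1:4)
  # ranking is a permutation of the input
  expect_setequal(res@ranked$protein_id, hits$protein_id)
  # unresolvable ids error
  bad <- rbind(hits, data.frame(protein_id = "ghost", pfam_id = "PF00704",
                                full_seq_evalue = 1e-9, full_seq_score = 1))
  expect_error(mineCandidates(bad, seqs, stub), "ghost")
})

test_that("mining matches an independent sort oracle and is shuffle-stable", {
  fx <- generateMiningFixture(syntheticSpec(seed = 33L),
                              n_family_members = 20L, n_decoys = 7L)
  hits <- suppressMessages(filterHits(parseHmmsearchTblout(fx$tblout)))
  expect_setequal(hits$protein_id, fx$member_ids)
  seqs <- Biostrings::readAAStringSet(fx$fasta)
  stub <- stub_model()
  res <- mineCandidates(hits, seqs, stub)
  # sort oracle: order(-pred, id)
  pred <- stub(OGTpred:::asSequenceVector(seqs)[hits$protein_id])
  oracle <- hits$protein_id[order(-pred, hits$protein_id)]
  expect_equal(res@ranked$protein_id, oracle)
  # shuffling hit order must not change the ranked table
  set.seed(40)
  res2 <- mineCandidates(hits[sample(nrow(hits)), ], seqs, stub)
  expect_equal(res2@ranked, res@ranked)
  expect_equal(res2@ranked$protein_id[1], res@ranked$protein_id[1])
})

test_that("raising t_high never increases the thermophilic fraction", {
  fx <- generateMiningFixture(syntheticSpec(seed = 34L), 15L, 0L)
  hits <- suppressMessages(filterHits(parseHmmsearchTblout(fx$tblout)))
  seqs <- Biostrings::readAAStringSet(fx$fasta)
  fracs <- vapply(c(30, 50, 70, 90), function(th)
    mineCandidates(hits, seqs, stub_model(), t_low = 20, t_high = th)@bin_fractions[["thermophilic"]],
    0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("candidate export round-trips sequences and honours top_n", {
  fx <- generateMiningFixture(syntheticSpec(seed = 35L), 5L, 3L)
  hits <- suppressMessages(filterHits(parseHmmsearchTblout(fx$tblout)))
  seqs <- Biostrings::readAAStringSet(fx$fasta)
  res <- mineCandidates(hits, seqs, stub_model())
  fa <- tempfile(fileext = ".faa"); tsv <- tempfile(fileext = ".tsv")
  top <- exportCandidates(res, 1L, seqs, fa, tsv)
  expect_equal(nrow(top), 1L)
  reread <- Biostrings::readAAStringSet(fa)
  expect_equal(length(reread), 1L)
  rid <- sub("\\s.*$", "", names(reread))
  expect_equal(rid, res@ranked$protein_id[1])
  expect_equal(as.character(reread[[1]]),
               as.character(seqs[[which(sub("\\s.*$", "", names(seqs)) == rid)]]))
  # over-large top_n exports all with a warning; TSV row count matches
  expect_warning(all_out <- exportCandidates(res, 99L, seqs, fa, tsv), "exceeds")
  expect_equal(nrow(read.delim(tsv)), nrow(res@ranked))
})
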