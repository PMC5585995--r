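test_that("tally TSV round-trips losslessly", {
  set.seed(5)
  for (k in 1:3) {
    x <- random_tally(n_sites = 20, n_lines = k + 1)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_tally(x, f)
    y <- read_tally(f)
    expect_identical(tally_samples(y), tally_samples(x))
    expect_equal(as.data.frame(y), as.data.frame(x))
  }
})

test_that("gzipped tallies read transparently", {
  x <- random_tally(10, 2)
  f <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(f, "w"); on.exit(try(close(con), silent = TRUE), add = TRUE)
  writeLines(readr::read_lines(write_tally(x, withr::local_tempfile())), con)
  close(con)
  expect_equal(as.data.frame(read_tally(f)), as.data.frame(x))
})

test_that("malformed tally rows are rejected with their line number", {
  lines <- c("#chrom\tpos\tref\tancestor\tline1",
             "c\t1\tA\t1,0,0,0,1,0,0,0\t2,0,0,0,2,0,0,0",
             "c\t2\tA\t1,0,0,0,1,0,0\t2,0,0,0,2,0,0,0")
  f <- withr::local_tempfile()
  writeLines(lines, f)
  expect_error(read_tally(f), "line 3.*8")
  writeLines(c(lines[1:2], "c\t3\tA\t1,0,0,0,1,0,0,0"), f)
  expect_error(read_tally(f), "line 3")
  writeLines(c(lines[1:2], "c\t3\tA\t-1,0,0,0,1,0,0,0\t2,0,0,0,2,0,0,0"), f)
  expect_error(read_tally(f), "negative")
  writeLines(lines[2], f)
  expect_error(read_tally(f), "header")
})

test_that("pileup base strings are parsed by the strand/case convention", {
  txt <- paste("chr1", 10, "A", 4, ".,.,", "IIII", 3, "..C", "III", sep = "\t")
  x <- from_mpileup(txt, samples = c("anc", "d1"))
  expect_equal(unname(tally_counts(x, "anc", "fwd")[1, ]), c(2, 0, 0, 0))
  expect_equal(unname(tally_counts(x, "anc", "rev")[1, ]), c(2, 0, 0, 0))
  expect_equal(unname(tally_counts(x, "d1", "fwd")[1, ]), c(2, 1, 0, 0))
  ## read start/end markers, indels, deletions, skips, ambiguous bases
  txt2 <- paste("chr1", 11, "G", 8, "^]..$,+2AC.-1t,*>Nn", "IIIIIIII", sep = "\t")
  y <- from_mpileup(txt2, samples = "anc")
  expect_equal(unname(tally_counts(y, "anc", "fwd")[1, ]), c(0, 0, 3, 0))
  expect_equal(unname(tally_counts(y, "anc", "rev")[1, ]), c(0, 0, 2, 0))
  ## lowercase mismatches count on the reverse strand
  txt3 <- paste("chr1", 12, "T", 3, "t.c", "III", sep = "\t")
  z <- from_mpileup(txt3, samples = "anc")
  expect_equal(unname(tally_counts(z, "anc", "rev")[1, ]), c(0, 1, 0, 1))
  expect_equal(unname(tally_counts(z, "anc", "fwd")[1, ]), c(0, 0, 0, 1))
  expect_error(from_mpileup("chr1\t9\tA\t1\t.?\tI", samples = "anc"), "character")
  expect_error(from_mpileup(paste("chr1", 9, "A", 1, ".", sep = "\t")), "fields")
})

test_that("parsed counts never exceed the pileup depth field", {
  set.seed(8)
  for (k in 1:10) {
    n <- sample(1:20, 1)
    bases <- paste(sample(c(".", ",", "C", "g", "T", "a", "N", "*"), n, TRUE),
                   collapse = "")
    txt <- paste("c", 1, "A", n, bases, paste(rep("I", n), collapse = ""),
                 sep = "\t")
    x <- from_mpileup(txt, samples = "s")
    expect_lte(sum(tally_counts(x, "s")), n)
    expect_true(all(tally_counts(x, "s") >= 0))
  }
})

test_that("non-reference frequency profile summarises per sample", {
  allref <- mk_tally(matrix(rep(c(10L, 0L, 0L, 0L), each = 5), ncol = 4),
                     list(matrix(rep(c(8L, 0L, 0L, 0L), each = 5), ncol = 4)),
                     ref = "A")
  pr <- nonref_frequency_profile(allref)
  expect_equal(pr$summary$mean_nonref, c(0, 0))
  ## one sample at 50% non-reference everywhere
  half <- mk_tally(matrix(rep(c(10L, 0L, 0L, 0L), each = 5), ncol = 4),
                   list(matrix(rep(c(5L, 5L, 0L, 0L), each = 5), ncol = 4)),
                   ref = "A")
  pr2 <- nonref_frequency_profile(half)
  expect_equal(pr2$summary$mean_nonref[pr2$summary$sample == "line1"], 0.5)
  expect_equal(pr2$summary$mean_nonref[pr2$summary$sample == "ancestor"], 0)
  expect_equal(sum(pr2$histogram$count[pr2$histogram$sample == "line1"]), 5)
})

test_that("anomalous lines rank first in the non-reference profile", {
  sim <- simulate_experiment(n_sites = 400, n_lines = 5, seed = 21)
  bad <- inject_anomaly(sim$tally, c("line2", "line4"), noise_frac = 0.15,
                        seed = 22)
  pr <- nonref_frequency_profile(bad)
  top2 <- pr$summary$sample[order(-pr$summary$mean_nonref)][1:2]
  expect_setequal(top2, c("line2", "line4"))
  ## zero noise is the identity
  expect_identical(as.data.frame(inject_anomaly(sim$tally, "line1", 0)),
                   as.data.frame(sim$tally))
})
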