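ref120 <- fixture_reference(sequence = strrep("ACGT", 30))  # pos 10 is C

test_that("aligned bases are tallied per site with quality filtering", {
  # three reads covering position 10 with bases A, A, C; the A carriers have
  # a single mismatch in 100 aligned bases (identity 0.99, retained)
  rA <- matched_read(ref120, 1, 100, subs = c("10" = "A"))
  rC <- matched_read(ref120, 1, 100)
  reads <- data.frame(qname = c("r1", "r2", "r3"), flag = 0L, pos = 1L,
                      cigar = c(rA$cigar, rA$cigar, rC$cigar),
                      seq = c(rA$seq, rA$seq, rC$seq),
                      qual = c(rA$qual, rA$qual, rC$qual))
  sam <- write_fixture_sam(tempfile(fileext = ".sam"), ref120, reads)
  prof <- load_site_counts(sam, ref120)
  site <- prof$counts[10, ]
  expect_equal(unlist(site[BASES]), c(A = 2L, C = 1L, G = 0L, T = 0L),
               ignore_attr = TRUE)
  expect_equal(site$N, 3L)
  expect_equal(site$T_dom, 2L)
  expect_equal(site$dominant, "A")

  # same fixture, but the C-carrying base falls below quality 30
  lowq <- rC$qual
  substr(lowq, 10, 10) <- rawToChar(as.raw(20L + 33L))
  reads$qual[3] <- lowq
  sam2 <- write_fixture_sam(tempfile(fileext = ".sam"), ref120, reads)
  prof2 <- load_site_counts(sam2, ref120)
  expect_equal(prof2$counts$N[10], 2L)
  expect_equal(unlist(prof2$counts[10, BASES]),
               c(A = 2L, C = 0L, G = 0L, T = 0L), ignore_attr = TRUE)
  # the quality-masked base is gone but the read's other bases remain
  expect_equal(prof2$counts$N[11], 3L)
})

test_that("reads below the identity threshold contribute nothing", {
  # 1 mismatch in 20 aligned bases = 95% identity: whole read excluded
  bad <- matched_read(ref120, 101, 20, subs = c("5" = "C"))  # ref there is A
  good <- matched_read(ref120, 1, 100)
  reads <- data.frame(qname = c("good", "bad"), flag = 0L,
                      pos = c(1L, 101L),
                      cigar = c(good$cigar, bad$cigar),
                      seq = c(good$seq, bad$seq),
                      qual = c(good$qual, bad$qual))
  sam <- write_fixture_sam(tempfile(fileext = ".sam"), ref120, reads)
  prof <- load_site_counts(sam, ref120)
  expect_equal(prof$counts$N[110], 0L)  # covered only by the excluded read
  expect_true(all(prof$counts$N[101:120] == 0L))
  expect_equal(prof$counts$N[50], 1L)
})

test_that("indels and clips contribute no counts and do not shift coordinates", {
  s <- strsplit(ref120$sequence, "")[[1]]
  del <- list(seq = paste(c(s[1:50], s[52:100]), collapse = ""),
              cigar = "50M1D49M", qual = qual_string(40, 99))
  ins <- list(seq = paste(c(s[1:50], "A", "A", s[51:98]), collapse = ""),
              cigar = "50M2I48M", qual = qual_string(40, 100))
  clip <- list(seq = paste(c("T", "T", "T", s[1:95]), collapse = ""),
               cigar = "3S95M", qual = qual_string(40, 98))
  reads <- data.frame(qname = c("del", "ins", "clip"), flag = 0L, pos = 1L,
                      cigar = c(del$cigar, ins$cigar, clip$cigar),
                      seq = c(del$seq, ins$seq, clip$seq),
                      qual = c(del$qual, ins$qual, clip$qual))
  sam <- write_fixture_sam(tempfile(fileext = ".sam"), ref120, reads)
  prof <- load_site_counts(sam, ref120)
  n <- prof$counts$N
  refb <- prof$counts$dominant
  expect_equal(n[51], 2L)             # deletion gap: only ins + clip cover it
  expect_equal(n[50], 3L)
  expect_equal(n[96], 2L)             # clip read ends at 95
  expect_equal(n[98], 2L)             # del + ins still aligned here
  expect_equal(n[99], 1L)             # ins read ends at ref 98
  # no coordinate shift: every counted base matches the reference
  expect_true(all(refb[n > 0] == s[n > 0]))
})

test_that("degenerate alignment inputs are handled per contract", {
  good <- matched_read(ref120, 1, 100)
  # missing quality string -> hard error naming the read
  reads <- data.frame(qname = "noq", flag = 0L, pos = 1L,
                      cigar = good$cigar, seq = good$seq, qual = "*")
  sam <- write_fixture_sam(tempfile(fileext = ".sam"), ref120, reads)
  expect_error(load_site_counts(sam, ref120), "noq")

  # reference id mismatch -> hard error
  other <- reference_genome("otherref", ref120$sequence)
  sam2 <- write_fixture_sam(tempfile(fileext = ".sam"), other,
                            data.frame(qname = "r", flag = 0L, pos = 1L,
                                       cigar = good$cigar, seq = good$seq,
                                       qual = good$qual))
  expect_error(load_site_counts(sam2, ref120), "fixref")

  # unmapped-only input -> empty profile with warning
  um <- data.frame(qname = "u", flag = 4L, pos = 0L, cigar = "*",
                   seq = good$seq, qual = good$qual)
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", ref120$id, ref120$length),
             paste("u", 4, "*", 0, 0, "*", "*", 0, 0, good$seq, good$qual,
                   sep = "\t"))
  sam3 <- tempfile(fileext = ".sam")
  writeLines(lines, sam3)
  expect_warning(prof <- load_site_counts(sam3, ref120), "empty")
  expect_true(all(prof$counts$N == 0L))
})

test_that("raising the quality or identity thresholds never increases depth", {
  simr <- simulate_reference(1500, 2, seed = 11)
  truth <- simulate_strains(simr$reference, K = 2, divergence = 0.02,
                            seed = 12)
  sam <- tempfile(fileext = ".sam")
  simulate_sample(truth, c(0.7, 0.3), mean_coverage = 20, error_rate = 0.01,
                  seed = 13, sam = sam, base_quality = 40)
  n_by_id <- sapply(c(0.95, 0.99, 1.0), function(mi) {
    load_site_counts(sam, simr$reference, min_read_identity = mi)$counts$N
  })
  expect_true(all(diff(t(n_by_id)) <= 0))
  loose <- load_site_counts(sam, simr$reference, min_base_quality = 30)
  strict <- load_site_counts(sam, simr$reference, min_base_quality = 41)
  expect_true(all(strict$counts$N <= loose$counts$N))
  expect_true(all(strict$counts$N == 0L))  # simulated quality is 40
})

test_that("count tables round-trip and derive N/T/dominant", {
  ref <- fixture_reference(20)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("position\tA\tC\tG\tT", "10\t2\t1\t0\t0"), tsv)
  prof <- load_count_table(tsv, ref)
  expect_equal(prof$counts$N[10], 3L)
  expect_equal(prof$counts$T_dom[10], 2L)
  expect_equal(prof$counts$dominant[10], "A")

  # alphabetical tie-break, with a log message
  writeLines(c("position\tA\tC\tG\tT", "10\t2\t2\t0\t0"), tsv)
  expect_message(prof <- load_count_table(tsv, ref), "tie")
  expect_equal(prof$counts$T_dom[10], 2L)
  expect_equal(prof$counts$dominant[10], "A")

  # empty table -> all-zero coverage
  writeLines("position\tA\tC\tG\tT", tsv)
  expect_true(all(load_count_table(tsv, ref)$counts$N == 0L))

  # invalid tables -> hard errors
  writeLines(c("position\tA\tC\tG\tT", "10\t1\t0\t0\t0", "10\t2\t0\t0\t0"), tsv)
  expect_error(load_count_table(tsv, ref), "duplicate")
  writeLines(c("position\tA\tC\tG\tT", "10\t-1\t0\t0\t0"), tsv)
  expect_error(load_count_table(tsv, ref), "negative")
  writeLines(c("position\tA\tC\tG\tT", "25\t1\t0\t0\t0"), tsv)
  expect_error(load_count_table(tsv, ref), "bounds")
})

test_that("write/load count table is the identity on simulated profiles", {
  for (seed in 1:3) {
    simr <- simulate_reference(800, 1, seed = seed)
    truth <- simulate_strains(simr$reference, K = 2, divergence = 0.01,
                              seed = seed + 100)
    prof <- simulate_sample(truth, c(0.8, 0.2), mean_coverage = 30,
                            seed = seed + 200)
    tsv <- tempfile(fileext = ".tsv")
    write_count_table(prof, tsv)
    back <- load_count_table(tsv, simr$reference,
                             sample_id = prof$sample_id)
    expect_identical(back$counts, prof$counts)
  }
})

test_that("total depth is conserved under the filters", {
  # every simulated base passes the filters (quality 40, single strain,
  # zero error): summed N equals the number of aligned bases
  simr <- simulate_reference(600, 1, seed = 21)
  truth <- simulate_strains(simr$reference, K = 1, divergence = 0, seed = 22)
  sam <- tempfile(fileext = ".sam")
  prof <- simulate_sample(truth, 1, mean_coverage = 10, error_rate = 0,
                          seed = 23, sam = sam, read_length = 100)
  n_reads <- length(readLines(sam)) - 2L
  expect_equal(sum(prof$counts$N), n_reads * 100L)
  loaded <- load_site_counts(sam, simr$reference)
  expect_equal(sum(loaded$counts$N), n_reads * 100L)
})
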