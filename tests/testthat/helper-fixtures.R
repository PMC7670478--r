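# Brute-force binomial tail oracle: P(errors >= N - T) with
# errors ~ Binomial(N, E), summed term by term in log space. Kept
# independent of the pbinom-based implementation it checks.
oracle_tail_pvalue <- function(N, T_dom, E) {
  k <- seq.int(N - T_dom, N)
  sum(exp(lchoose(N, k) + k * log(E) + (N - k) * log1p(-E)))
}

# Same oracle for all T = 0..N at once: cumulative sums of the error PMF
# from the top (tail for T is the sum over k = N-T .. N).
oracle_tail_all_T <- function(N, E) {
  k <- 0:N
  pmf <- exp(lchoose(N, k) + k * log(E) + (N - k) * log1p(-E))
  cumsum(rev(pmf))
}

oracle_pmf <- function(N, T_dom, E) {
  exp(lchoose(N, T_dom) + (N - T_dom) * log(E) + T_dom * log1p(-E))
}

BASES <- c("A", "C", "G", "T")

# Reference of given sequence (or all-A of length L).
fixture_reference <- function(L = 120, sequence = strrep("A", L)) {
  strainpulse::reference_genome("fixref", sequence)
}

# Profile with explicit allele counts at chosen positions; all other
# positions uncovered.
fixture_profile <- function(reference, at = list(), ...) {
  counts <- matrix(0L, nrow = reference$length, ncol = 4L,
                   dimnames = list(NULL, BASES))
  for (pos in names(at)) {
    counts[as.integer(pos), ] <- as.integer(at[[pos]])
  }
  suppressMessages(
    strainpulse::sample_profile(counts, reference, ...)
  )
}

# Canonical per-site count patterns at N = 100 for building call sets with
# known classifications (tail test at E = 0.01, alpha = 0.05 rejects at
# >= 4 alternative reads).
COUNTS_NONPOLY <- c(100L, 0L, 0L, 0L)    # non_polymorphic
COUNTS_POLY <- c(60L, 40L, 0L, 0L)       # polymorphic (T = 60 >= 40)
COUNTS_MUT <- c(40L, 30L, 30L, 0L)       # mutation (T = 40 < 60)

# Build a poly_call with given positions polymorphic/mutation, everything
# else covered non-polymorphic, on an all-A reference of length L.
fixture_calls <- function(L, poly = integer(0), mut = integer(0), ...) {
  ref <- fixture_reference(L)
  counts <- matrix(rep(COUNTS_NONPOLY, each = L), nrow = L,
                   dimnames = list(NULL, BASES))
  for (p in poly) counts[p, ] <- COUNTS_POLY
  for (p in mut) counts[p, ] <- COUNTS_MUT
  prof <- suppressMessages(
    strainpulse::sample_profile(counts, ref, ...)
  )
  strainpulse::call_polymorphisms(prof)
}

# Minimal SAM writer for hand-built read fixtures.
# reads: data.frame with columns qname, flag, pos, cigar, seq, qual
write_fixture_sam <- function(path, reference, reads) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", reference$id, reference$length))
  for (i in seq_len(nrow(reads))) {
    lines <- c(lines, paste(reads$qname[i], reads$flag[i], reference$id,
                            reads$pos[i], 60, reads$cigar[i], "*", 0, 0,
                            reads$seq[i], reads$qual[i], sep = "\t"))
  }
  writeLines(lines, path)
  path
}

qual_string <- function(phred, n) {
  strrep(rawToChar(as.raw(phred + 33L)), n)
}

# A read matching the reference over [pos, pos+len-1] with optional
# substitutions: named integer offsets (1-based within the read) -> base.
matched_read <- function(reference, pos, len, subs = c(), phred = 40) {
  s <- strsplit(substr(reference$sequence, pos, pos + len - 1L), "")[[1]]
  if (length(subs) > 0) s[as.integer(names(subs))] <- subs
  list(seq = paste(s, collapse = ""), cigar = paste0(len, "M"),
       qual = qual_string(phred, len))
}
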