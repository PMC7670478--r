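#' Simulate a reference genome with gene annotations
#'
#' Draws a uniform random A/C/G/T sequence and places `n_genes`
#' non-overlapping gene intervals spanning at least 60% of the reference,
#' separated by evenly sized intergenic gaps. Deterministic for a fixed seed.
#'
#' @param length Reference length in bases.
#' @param n_genes Number of genes (0 for an empty annotation).
#' @param seed Integer seed, or NULL to use the current RNG state.
#' @return List with `reference` (a `reference_genome`) and `genes` (a gene
#'   table).
#' @export
simulate_reference <- function(length, n_genes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length >= 1, n_genes >= 0)
  seq <- paste(sample(BASES, length, replace = TRUE), collapse = "")
  ref <- reference_genome("simref", seq)
  if (n_genes == 0L) {
    genes <- gene_table(character(0), integer(0), integer(0),
                        character(0), character(0))
    return(list(reference = ref, genes = genes))
  }
  glen <- ceiling(0.7 * length / n_genes)
  if (glen * n_genes > length) {
    stop("n_genes incompatible with reference length")
  }
  gap <- (length - glen * n_genes) / (n_genes + 1)
  start <- as.integer(floor(gap * seq_len(n_genes) +
                              glen * (seq_len(n_genes) - 1L))) + 1L
  genes <- gene_table(gene_id = sprintf("gene%02d", seq_len(n_genes)),
                      start = start, end = start + glen - 1L,
                      strand = sample(c("+", "-"), n_genes, replace = TRUE))
  list(reference = ref, genes = genes)
}

#' Simulate substrain genotypes
#'
#' Embodies the dominant-plus-minor substrain model: strain 1 is the
#' reference lineage; each further strain mutates every reference position
#' independently with probability `divergence` to a uniformly chosen
#' different base. Positions are unlinked (the site-wise analysis carries no
#' linkage information).
#'
#' @param reference A `reference_genome`.
#' @param K Number of substrains (>= 1).
#' @param divergence Per-site substitution probability for strains 2..K.
#' @param seed Integer seed, or NULL.
#' @return Object of class `truth_table`: list with `reference_id`, `length`,
#'   `genotypes` (character matrix, length x K) and `divergence`.
#' @export
simulate_strains <- function(reference, K, divergence, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K >= 1, divergence >= 0, divergence <= 1)
  refchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  L <- reference$length
  geno <- matrix(refchars, nrow = L, ncol = K)
  if (K > 1L) {
    for (k in 2:K) {
      mut <- which(runif(L) < divergence & refchars %in% BASES)
      if (length(mut) > 0L) {
        shift <- sample.int(3L, length(mut), replace = TRUE)
        geno[mut, k] <- BASES[((match(refchars[mut], BASES) - 1L + shift) %% 4L) + 1L]
      }
    }
  }
  structure(
    list(reference_id = reference$id, length = L, genotypes = geno,
         divergence = divergence),
    class = "truth_table"
  )
}

#' @export
print.truth_table <- function(x, ...) {
  K <- ncol(x$genotypes)
  nvar <- sum(apply(x$genotypes != x$genotypes[, 1], 1, any))
  cat("<truth_table> ", K, " strain(s) on ", x$reference_id, " (",
      x$length, " bp), ", nvar, " variant position(s)\n", sep = "")
  invisible(x)
}

#' Ground-truth polymorphic positions
#'
#' Positions where at least two strains with nonzero abundance carry
#' different bases.
#'
#' @param truth A `truth_table`.
#' @param abundances Strain abundance vector (summing to 1). Defaults to all
#'   strains present.
#' @return Sorted integer vector of 1-based positions.
#' @export
truth_sites <- function(truth, abundances = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  K <- ncol(truth$genotypes)
  if (is.null(abundances)) abundances <- rep(1 / K, K)
  check_abundances(abundances, K)
  act <- which(abundances > 0)
  if (length(act) < 2L) return(integer(0))
  g <- truth$genotypes[, act, drop = FALSE]
  which(rowSums(g != g[, 1]) > 0L)
}

#' Ground-truth major base per position
#'
#' The base carrying the largest total abundance over strains, with
#' alphabetical tie-break — the base a majority consensus should recover at
#' saturating coverage.
#'
#' @inheritParams truth_sites
#' @return Character vector of length `truth$length`.
#' @export
truth_major_base <- function(truth, abundances = NULL) {
  stopifnot(inherits(truth, "truth_table"))
  K <- ncol(truth$genotypes)
  if (is.null(abundances)) abundances <- rep(1 / K, K)
  check_abundances(abundances, K)
  W <- matrix(0, nrow = truth$length, ncol = 4L, dimnames = list(NULL, BASES))
  for (k in seq_len(K)) {
    idx <- match(truth$genotypes[, k], BASES)
    ok <- !is.na(idx)
    cell <- (idx[ok] - 1L) * truth$length + which(ok)
    W[cell] <- W[cell] + abundances[k]
  }
  BASES[max.col(W, ties.method = "first")]
}

check_abundances <- function(abundances, K) {
  if (length(abundances) != K) {
    stop("abundances must have one entry per strain")
  }
  if (any(abundances < 0) || abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must be non-negative and sum to 1")
  }
  invisible(abundances)
}

# Vectorized multinomial draws across sites via sequential binomial thinning.
rmultinom_rows <- function(n, prob) {
  K <- length(prob)
  out <- matrix(0L, nrow = length(n), ncol = K)
  rem <- as.integer(n)
  prem <- 1
  for (k in seq_len(K - 1L)) {
    p <- if (prem > 0) min(1, prob[k] / prem) else 0
    out[, k] <- rbinom(length(rem), rem, p)
    rem <- rem - out[, k]
    prem <- prem - prob[k]
  }
  out[, K] <- rem
  out
}

# Apply uniform miscalls: each counted base flips with probability
# error_rate to one of the three other bases chosen uniformly.
apply_errors <- function(M, error_rate) {
  L <- nrow(M)
  out <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  for (b in 1:4) {
    err <- rbinom(L, M[, b], error_rate)
    out[, b] <- out[, b] + M[, b] - err
    others <- setdiff(1:4, b)
    e1 <- rbinom(L, err, 1 / 3)
    e2 <- rbinom(L, err - e1, 1 / 2)
    out[, others[1]] <- out[, others[1]] + e1
    out[, others[2]] <- out[, others[2]] + e2
    out[, others[3]] <- out[, others[3]] + (err - e1 - e2)
  }
  out
}

#' Simulate one sample from a substrain mixture
#'
#' Primary (pileup) mode draws, at every reference position, a Poisson
#' coverage, assigns each read to a strain according to the abundance vector,
#' and miscalls each base with probability `error_rate` to a uniformly chosen
#' different base — exactly the generative structure the binomial caller
#' assumes under its null (single strain) and alternative (mixture).
#'
#' Read mode (`reads = TRUE`, or `sam` given) instead emits fixed-length
#' reads at uniform start positions, applies per-base errors, optionally
#' writes a SAM file, and tallies the profile through the same base-quality
#' and read-identity filters that [load_site_counts()] applies — so the
#' returned profile and a profile re-loaded from the SAM file agree exactly.
#' All simulated bases carry the single Phred quality `base_quality`.
#'
#' @param truth A `truth_table` from [simulate_strains()].
#' @param abundances Strain abundances, summing to 1.
#' @param mean_coverage Poisson mean coverage per site.
#' @param error_rate Per-base miscall probability.
#' @param base_quality Phred quality assigned to all simulated bases.
#' @param seed Integer seed, or NULL.
#' @param sample_id,condition,material Sample metadata.
#' @param reads Use read mode.
#' @param read_length Read length in read mode.
#' @param sam Optional SAM output path (implies read mode).
#' @param min_base_quality,min_read_identity Filters replayed by the
#'   read-mode tally, matching [load_site_counts()] defaults.
#' @return A `sample_profile`.
#' @export
simulate_sample <- function(truth, abundances, mean_coverage,
                            error_rate = 0.01, base_quality = 40,
                            seed = NULL, sample_id = "sim",
                            condition = "healthy", material = "DNA",
                            reads = FALSE, read_length = 150, sam = NULL,
                            min_base_quality = 30, min_read_identity = 0.99) {
  stopifnot(inherits(truth, "truth_table"))
  if (!is.null(seed)) set.seed(seed)
  K <- ncol(truth$genotypes)
  check_abundances(abundances, K)
  stopifnot(error_rate >= 0, error_rate <= 1, mean_coverage > 0)
  L <- truth$length
  ref <- reference_genome(truth$reference_id,
                          paste(truth$genotypes[, 1], collapse = ""))
  if (reads || !is.null(sam)) {
    counts <- simulate_reads(truth, abundances, mean_coverage, error_rate,
                             base_quality, read_length, sam,
                             min_base_quality, min_read_identity)
  } else {
    n <- rpois(L, mean_coverage)
    stc <- rmultinom_rows(n, abundances)
    M <- matrix(0L, nrow = L, ncol = 4L)
    for (k in seq_len(K)) {
      idx <- match(truth$genotypes[, k], BASES)
      ok <- !is.na(idx) & stc[, k] > 0L
      cell <- (idx[ok] - 1L) * L + which(ok)
      M[cell] <- M[cell] + stc[ok, k]
    }
    counts <- if (error_rate > 0) apply_errors(M, error_rate) else M
  }
  sample_profile(counts, ref, sample_id = sample_id, condition = condition,
                 material = material)
}

simulate_reads <- function(truth, abundances, mean_coverage, error_rate,
                           base_quality, read_length, sam,
                           min_base_quality, min_read_identity) {
  L <- truth$length
  if (read_length > L) stop("read_length exceeds reference length")
  refchars <- truth$genotypes[, 1]
  n_reads <- max(1L, round(mean_coverage * L / read_length))
  starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
  strains <- sample.int(ncol(truth$genotypes), n_reads, replace = TRUE,
                        prob = abundances)
  qual_char <- rawToChar(as.raw(base_quality + 33L))
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  sam_lines <- if (!is.null(sam)) {
    c("@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", truth$reference_id, L))
  } else NULL
  pass_qual <- base_quality >= min_base_quality
  for (i in seq_len(n_reads)) {
    span <- starts[i]:(starts[i] + read_length - 1L)
    bases <- truth$genotypes[span, strains[i]]
    if (error_rate > 0) {
      flip <- which(runif(read_length) < error_rate)
      if (length(flip) > 0L) {
        shift <- sample.int(3L, length(flip), replace = TRUE)
        bases[flip] <- BASES[((match(bases[flip], BASES) - 1L + shift) %% 4L) + 1L]
      }
    }
    if (!is.null(sam_lines)) {
      sam_lines <- c(sam_lines, sprintf(
        "read%06d\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
        i, truth$reference_id, starts[i], read_length,
        paste(bases, collapse = ""),
        strrep(qual_char, read_length)))
    }
    # replay the ingestion filters so SAM round-trips exactly
    identity <- mean(bases == refchars[span])
    if (identity < min_read_identity || !pass_qual) next
    cell <- (match(bases, BASES) - 1L) * L + span
    counts[cell] <- counts[cell] + 1L
  }
  if (!is.null(sam)) writeLines(sam_lines, sam)
  counts
}

#' Confusion statistics of a call set against ground truth
#'
#' Over tested sites only (depth at or above the caller's coverage gate),
#' cross-tabulates the truth polymorphic set against sites called polymorphic
#' or mutation class. The false-positive rate is FP over truth-negative
#' tested sites; power is TP over truth-positive tested sites.
#'
#' @param calls A `poly_call`.
#' @param truth A `truth_table`.
#' @param abundances Abundances used to generate the evaluated sample.
#' @return List with `tp`, `fp`, `tn`, `fn`, `n_tested`, `fpr`, `power`.
#' @export
evaluate_calls <- function(calls, truth, abundances = NULL) {
  stopifnot(inherits(calls, "poly_call"), inherits(truth, "truth_table"))
  if (nrow(calls$calls) != truth$length) {
    stop("calls and truth are on different references")
  }
  tp_set <- truth_sites(truth, abundances)
  is_true <- seq_len(truth$length) %in% tp_set
  tested <- calls$calls$status != "untested"
  called <- calls$calls$status %in% c("polymorphic", "mutation")
  tp <- sum(tested & called & is_true)
  fp <- sum(tested & called & !is_true)
  fn <- sum(tested & !called & is_true)
  tn <- sum(tested & !called & !is_true)
  list(tp = tp, fp = fp, tn = tn, fn = fn, n_tested = sum(tested),
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       power = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}
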