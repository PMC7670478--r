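#' Construct a per-site allele-count profile
#'
#' The central per-sample container: for every reference position, the number
#' of filtered read bases supporting A, C, G and T. Derived columns hold the
#' site depth `N`, the count `T_dom` of the most abundant (dominant) allele
#' and the dominant base itself. Positions never covered have `N = 0` and an
#' `NA` dominant base. Ties for the dominant allele are broken alphabetically
#' (A < C < G < T) and reported via `message()` so they are visible in logs.
#'
#' @param counts Integer matrix with one row per reference position and
#'   columns A, C, G, T (row i = reference position i, 1-based).
#' @param reference A `reference_genome`.
#' @param sample_id Sample identifier.
#' @param condition One of "healthy", "diseased", "dead".
#' @param material One of "DNA", "RNA".
#' @return An object of class `sample_profile`: list with the metadata plus
#'   `counts`, a data.frame with columns `pos`, `A`, `C`, `G`, `T`, `N`,
#'   `T_dom`, `dominant`.
#' @export
sample_profile <- function(counts, reference, sample_id = "sample",
                           condition = c("healthy", "diseased", "dead"),
                           material = c("DNA", "RNA")) {
  condition <- match.arg(condition)
  material <- match.arg(material)
  stopifnot(is.matrix(counts), ncol(counts) == 4L)
  if (nrow(counts) != reference$length) {
    stop("counts matrix must have one row per reference position")
  }
  if (any(counts < 0L)) stop("negative allele counts")
  storage.mode(counts) <- "integer"
  colnames(counts) <- BASES
  N <- as.integer(rowSums(counts))
  Tdom <- as.integer(pmax(counts[, 1], counts[, 2], counts[, 3], counts[, 4]))
  dom_idx <- max.col(counts, ties.method = "first")
  dominant <- ifelse(N > 0L, BASES[dom_idx], NA_character_)
  n_tie <- sum(N > 0L & rowSums(counts == Tdom) > 1L)
  if (n_tie > 0L) {
    message(n_tie, " site(s) with tied dominant allele; ",
            "alphabetical tie-break applied")
  }
  structure(
    list(sample_id = as.character(sample_id), condition = condition,
         material = material, reference_id = reference$id,
         reference_length = reference$length,
         counts = data.frame(pos = seq_len(reference$length),
                             counts, N = N, T_dom = Tdom,
                             dominant = dominant,
                             stringsAsFactors = FALSE)),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cov <- x$counts$N > 0L
  cat("<sample_profile> ", x$sample_id, " (", x$condition, ", ", x$material,
      ") on ", x$reference_id, "\n", sep = "")
  cat("  ", sum(cov), "/", x$reference_length, " positions covered; ",
      "mean depth over covered sites ",
      if (any(cov)) round(mean(x$counts$N[cov]), 1) else 0, "\n", sep = "")
  invisible(x)
}

# Decode CIGAR strings into aligned (query, reference) column indices and
# compute the tally for one sample. Only M/=/X columns count as aligned
# columns: soft clips and insertions are excluded from the identity
# denominator, and deletions/skips contribute no allele count (SNV-only).
tally_alignments <- function(bam, reference, min_base_quality,
                             min_read_identity) {
  L <- reference$length
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  n <- length(bam$cigar)
  if (n == 0L) return(counts)
  refchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  ops <- GenomicAlignments::explodeCigarOps(bam$cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(bam$cigar)
  seqs <- as.character(bam$seq)
  quals <- as(bam$qual, "IntegerList")
  for (i in seq_len(n)) {
    op <- ops[[i]]
    ln <- lens[[i]]
    qpos <- 1L
    rpos <- bam$pos[i]
    qidx <- vector("list", length(op))
    ridx <- vector("list", length(op))
    for (j in seq_along(op)) {
      o <- op[j]
      l <- ln[j]
      if (o == "M" || o == "=" || o == "X") {
        qidx[[j]] <- seq.int(qpos, qpos + l - 1L)
        ridx[[j]] <- seq.int(rpos, rpos + l - 1L)
        qpos <- qpos + l
        rpos <- rpos + l
      } else if (o == "I" || o == "S") {
        qpos <- qpos + l
      } else if (o == "D" || o == "N") {
        rpos <- rpos + l
      }
    }
    qidx <- unlist(qidx)
    ridx <- unlist(ridx)
    if (length(qidx) == 0L) next
    inb <- ridx >= 1L & ridx <= L
    qidx <- qidx[inb]
    ridx <- ridx[inb]
    qb <- strsplit(seqs[i], "", fixed = TRUE)[[1]][qidx]
    identity <- mean(qb == refchars[ridx])
    if (is.nan(identity) || identity < min_read_identity) next
    qq <- quals[[i]][qidx]
    keep <- qq >= min_base_quality & qb %in% BASES
    if (!any(keep)) next
    cell <- (match(qb[keep], BASES) - 1L) * L + ridx[keep]
    counts[cell] <- counts[cell] + 1L
  }
  counts
}

#' Load per-site allele counts from a SAM/BAM alignment
#'
#' Reads alignments of one sample against a single reference, applies the
#' read- and base-level filters, and tallies per-site allele counts:
#' * reads flagged unmapped, secondary, duplicate or supplementary are
#'   skipped;
#' * reads whose identity to the reference over aligned columns (matches /
#'   M-type columns; soft-clipped and inserted bases excluded) is below
#'   `min_read_identity` contribute nothing;
#' * of the remaining reads, each aligned base with Phred quality at least
#'   `min_base_quality` increments exactly one allele counter; insertions and
#'   deletion gaps contribute nothing (substitution alleles only).
#'
#' Identity is computed on the raw aligned bases, before quality masking.
#'
#' @param path Path to a SAM or BAM file (SAM is converted on the fly).
#' @param reference A `reference_genome`; its `id` must appear in the
#'   alignment header, otherwise an error is raised.
#' @param min_base_quality Minimum Phred base quality (default 30).
#' @param min_read_identity Minimum read identity fraction (default 0.99).
#' @param sample_id,condition,material Sample metadata, see
#'   [sample_profile()].
#' @return A `sample_profile`. If the file contains only unmapped reads the
#'   profile is empty (all zero) and a warning is emitted. Reads without
#'   base-quality strings raise an error naming the first offending read.
#' @export
load_site_counts <- function(path, reference, min_base_quality = 30,
                             min_read_identity = 0.99,
                             sample_id = sub("\\.(s|b)am$", "", basename(path)),
                             condition = "healthy", material = "DNA") {
  stopifnot(min_read_identity >= 0, min_read_identity <= 1)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  if (!reference$id %in% names(hdr)) {
    stop("reference id '", reference$id,
         "' not found among alignment targets: ",
         paste(names(hdr), collapse = ", "))
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "qual"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE))
  bam <- Rsamtools::scanBam(path, param = param)[[1]]
  keep <- as.character(bam$rname) == reference$id
  bam <- lapply(bam, `[`, keep)
  if (length(bam$pos) == 0L) {
    warning("no usable mapped reads in ", path, "; returning empty profile")
    counts <- matrix(0L, nrow = reference$length, ncol = 4L)
  } else {
    # a missing quality string ("*") decodes to negative per-base values
    qmin <- suppressWarnings(min(as(bam$qual, "IntegerList")))
    noqual <- BiocGenerics::width(bam$qual) != BiocGenerics::width(bam$seq) |
      (is.finite(qmin) & qmin < 0L)
    if (any(noqual)) {
      stop("read '", bam$qname[which(noqual)[1]],
           "' has no base-quality string")
    }
    counts <- tally_alignments(bam, reference, min_base_quality,
                               min_read_identity)
  }
  sample_profile(counts, reference, sample_id = sample_id,
                 condition = condition, material = material)
}

#' Write a per-site allele-count table
#'
#' Writes covered positions (N > 0) as TSV with columns `position` (1-based),
#' `A`, `C`, `G`, `T`, `N`, `T_dominant`, `dominant_base`. Output is
#' bit-exact for fixed input; uncovered positions are omitted and restored as
#' zero-coverage rows by [load_count_table()].
#'
#' @param profile A `sample_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(profile, path) {
  cc <- profile$counts[profile$counts$N > 0L, , drop = FALSE]
  out <- data.frame(position = cc$pos, cc[BASES], N = cc$N,
                    T_dominant = cc$T_dom, dominant_base = cc$dominant)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a per-site allele-count table
#'
#' Alternate entry point so downstream analysis is testable without
#' alignments. Round-trips with [write_count_table()].
#'
#' @param path TSV with columns `position`, `A`, `C`, `G`, `T` (extra
#'   columns ignored). Positions are 1-based reference coordinates.
#' @param reference A `reference_genome`.
#' @param sample_id,condition,material Sample metadata.
#' @return A `sample_profile`. Duplicate positions, positions outside the
#'   reference and negative counts raise errors.
#' @export
load_count_table <- function(path, reference, sample_id = "sample",
                             condition = "healthy", material = "DNA") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", BASES)
  if (!all(need %in% names(tab))) {
    stop("count table must have columns: ", paste(need, collapse = ", "))
  }
  counts <- matrix(0L, nrow = reference$length, ncol = 4L)
  if (nrow(tab) > 0L) {
    pos <- as.integer(tab$position)
    if (anyDuplicated(pos)) stop("duplicate positions in count table")
    if (any(pos < 1L | pos > reference$length)) {
      stop("positions outside reference bounds")
    }
    vals <- as.matrix(tab[BASES])
    if (any(vals < 0)) stop("negative counts in count table")
    counts[pos, ] <- as.integer(vals)
  }
  sample_profile(counts, reference, sample_id = sample_id,
                 condition = condition, material = material)
}
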