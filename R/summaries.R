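#' Union of polymorphic positions across samples
#'
#' A position belongs to the union if it is polymorphic or mutation class in
#' at least one of the supplied call sets. All call sets must be on the same
#' reference.
#'
#' @param calls A list of `poly_call` objects (or a single one).
#' @return Sorted integer vector of 1-based positions.
#' @export
polymorphic_union <- function(calls) {
  if (inherits(calls, "poly_call")) calls <- list(calls)
  if (length(calls) == 0L) return(integer(0))
  stopifnot(all(vapply(calls, inherits, logical(1), "poly_call")))
  refs <- unique(vapply(calls, function(x) x$profile$reference_id,
                        character(1)))
  if (length(refs) > 1L) {
    stop("call sets are on different references: ",
         paste(refs, collapse = ", "))
  }
  sort(unique(unlist(lapply(calls, polymorphic_sites))))
}

summarize_interval <- function(calls_df, pos_set, union) {
  sub <- calls_df[calls_df$pos %in% pos_set, , drop = FALSE]
  poly <- sub$status %in% c("polymorphic", "mutation")
  u <- intersect(union, pos_set)
  n_poly <- sum(poly)
  n_mut <- sum(sub$status == "mutation")
  n_union_other <- length(setdiff(u, sub$pos[poly]))
  usize <- length(u)
  list(n_tested = sum(sub$status != "untested"),
       n_untested = sum(sub$status == "untested"),
       n_polymorphic = n_poly, n_mutation = n_mut,
       n_union_other = n_union_other, union_size = usize,
       total_reads = sum(sub$N),
       frac_union_other = if (usize) n_union_other / usize else NA_real_,
       frac_polymorphic_only = if (usize) (n_poly - n_mut) / usize else NA_real_,
       frac_mutation = if (usize) n_mut / usize else NA_real_)
}

#' Per-gene polymorphism summary for one sample
#'
#' For each gene, counts tested sites, polymorphic sites, mutation-class
#' sites, and sites that are in the cross-sample polymorphic union but not
#' polymorphic in this sample ("polymorphic elsewhere"). Fractions are
#' relative to the union size within the gene, so the three categories
#' (elsewhere-only, polymorphic-only, mutation) partition the union when the
#' union includes this sample. `total_reads` is the summed filtered depth
#' over the gene, the quantity encoded as circle size in the summary figure.
#'
#' Untested (shallow) sites are excluded from fraction denominators and
#' reported separately in `n_untested`. Sites in overlapping genes are
#' counted in every overlapping gene; use [summarize_sample()] for
#' position-level genome totals that never double-count.
#'
#' @param x A `poly_call` for the sample.
#' @param genes Gene table from [gene_table()] / [read_genes()].
#' @param union Integer positions from [polymorphic_union()]; defaults to
#'   this sample's own polymorphic set.
#' @return data.frame with one row per gene.
#' @export
summarize_genes <- function(x, genes, union = polymorphic_sites(x)) {
  stopifnot(inherits(x, "poly_call"))
  if (any(genes$end > x$profile$reference_length)) {
    stop("gene(s) extend beyond the reference")
  }
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    s <- summarize_interval(x$calls, genes$start[i]:genes$end[i], union)
    c(list(gene_id = genes$gene_id[i], kind = genes$kind[i],
           length = genes$end[i] - genes$start[i] + 1L), s)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Genome-wide summary of one sample's calls
#'
#' Combines the per-gene table from [summarize_genes()] with whole-genome and
#' intergenic totals. Genome totals are computed over positions, not by
#' summing gene rows, so sites in overlapping genes are never double-counted;
#' with disjoint genes the genic + intergenic decomposition is exactly
#' additive.
#'
#' @inheritParams summarize_genes
#' @return Object of class `sample_summary`: list with `sample_id`, `genes`
#'   (the per-gene data.frame), `genome` and `intergenic` (summary lists with
#'   the same fields).
#' @export
summarize_sample <- function(x, genes, union = polymorphic_sites(x)) {
  stopifnot(inherits(x, "poly_call"))
  L <- x$profile$reference_length
  genic <- rep(FALSE, L)
  for (i in seq_len(nrow(genes))) genic[genes$start[i]:genes$end[i]] <- TRUE
  structure(
    list(sample_id = x$profile$sample_id,
         condition = x$profile$condition,
         material = x$profile$material,
         genes = summarize_genes(x, genes, union),
         genome = summarize_interval(x$calls, seq_len(L), union),
         intergenic = summarize_interval(x$calls, which(!genic), union)),
    class = "sample_summary"
  )
}

#' @export
print.sample_summary <- function(x, ...) {
  g <- x$genome
  cat("<sample_summary> ", x$sample_id, " (", x$condition, ", ", x$material,
      "): ", nrow(x$genes), " genes\n", sep = "")
  cat("  genome: ", g$n_polymorphic, " polymorphic (", g$n_mutation,
      " mutation class) of ", g$n_tested, " tested sites; union size ",
      g$union_size, "\n", sep = "")
  invisible(x)
}

#' Write per-gene summaries for several samples as TSV
#'
#' @param summaries List of `sample_summary` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_summary_table <- function(summaries, path) {
  if (inherits(summaries, "sample_summary")) summaries <- list(summaries)
  tab <- do.call(rbind, lapply(summaries, function(s) {
    cbind(sample_id = s$sample_id, condition = s$condition,
          material = s$material, s$genes)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Majority-consensus sequence of a sample
#'
#' At every covered position the consensus is the dominant allele
#' (alphabetical tie-break); uncovered positions fall back to the reference
#' base, giving a full-length sequence suitable for downstream comparative
#' analysis. Set `polymorphic_only = TRUE` (with `calls`) to replace only
#' sites that rejected the error-model null, keeping the reference base at
#' all sites the test could not distinguish from noise.
#'
#' @param profile A `sample_profile`.
#' @param reference The matching `reference_genome`.
#' @param polymorphic_only Restrict substitutions to rejected sites.
#' @param calls A `poly_call`, required when `polymorphic_only = TRUE`.
#' @return Object of class `consensus_sequence`: list with `sample_id`,
#'   `sequence` (character, reference length) and `n_divergent` (positions
#'   differing from the reference).
#' @export
build_consensus <- function(profile, reference, polymorphic_only = FALSE,
                            calls = NULL) {
  stopifnot(inherits(profile, "sample_profile"),
            inherits(reference, "reference_genome"))
  if (profile$reference_length != reference$length) {
    stop("profile and reference lengths differ")
  }
  refchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  cons <- refchars
  covered <- profile$counts$N > 0L
  replace <- covered
  if (polymorphic_only) {
    if (is.null(calls)) stop("polymorphic_only = TRUE requires 'calls'")
    replace <- covered & calls$calls$status %in% c("polymorphic", "mutation")
  }
  cons[replace] <- profile$counts$dominant[replace]
  structure(
    list(sample_id = profile$sample_id,
         sequence = paste(cons, collapse = ""),
         n_divergent = sum(cons != refchars)),
    class = "consensus_sequence"
  )
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat("<consensus_sequence> ", x$sample_id, ": ", nchar(x$sequence),
      " bp, ", x$n_divergent, " position(s) divergent from reference\n",
      sep = "")
  invisible(x)
}

#' Write consensus sequences to FASTA
#'
#' @param consensuses A `consensus_sequence` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensuses, path) {
  if (inherits(consensuses, "consensus_sequence")) {
    consensuses <- list(consensuses)
  }
  seqs <- Biostrings::DNAStringSet(vapply(consensuses, `[[`, character(1),
                                          "sequence"))
  names(seqs) <- vapply(consensuses, `[[`, character(1), "sample_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Pie-chart figure of per-gene polymorphism decomposition
#'
#' One panel row per sample, one pie per gene. Each pie decomposes the
#' cross-sample union of polymorphic sites within the gene into: polymorphic
#' elsewhere only (light blue), polymorphic in this sample (dark blue) and
#' mutation class (red). Circle radius is a monotone transform (default
#' square root) of the total filtered reads over the gene, so deeply covered
#' genes draw larger circles. Genes with an empty union draw a small open
#' circle.
#'
#' @param summaries List of `sample_summary` objects (shared gene set).
#' @param radius_transform Function applied to `total_reads` before scaling
#'   radii; default `sqrt`.
#' @param file Optional output path ending in `.pdf`, `.png` or `.svg`; if
#'   `NULL`, draws on the current device.
#' @return Invisibly, the matrix of radii used.
#' @export
plot_gene_summaries <- function(summaries, radius_transform = sqrt,
                                file = NULL) {
  if (inherits(summaries, "sample_summary")) summaries <- list(summaries)
  stopifnot(length(summaries) > 0L)
  n_s <- length(summaries)
  gene_ids <- summaries[[1]]$genes$gene_id
  n_g <- length(gene_ids)
  if (!is.null(file)) {
    ext <- tolower(sub(".*\\.", "", file))
    switch(ext,
           pdf = grDevices::pdf(file, width = 1 + n_g, height = 1 + n_s),
           png = grDevices::png(file, width = 120 * (1 + n_g),
                                height = 120 * (1 + n_s)),
           svg = grDevices::svg(file, width = 1 + n_g, height = 1 + n_s),
           stop("unsupported figure format: .", ext))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  rad <- vapply(summaries, function(s) radius_transform(s$genes$total_reads),
                numeric(n_g))
  rad <- matrix(rad, nrow = n_g)
  rmax <- max(rad, 1)
  cols <- c(other = "lightblue", poly = "dodgerblue4", mut = "firebrick2")
  graphics::plot(NA, xlim = c(0.5, n_g + 0.5), ylim = c(0.5, n_s + 0.5),
                 xlab = "", ylab = "", axes = FALSE, asp = 1)
  graphics::axis(1, at = seq_len(n_g), labels = gene_ids, las = 2, tick = FALSE,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n_s),
                 labels = vapply(summaries, `[[`, character(1), "sample_id"),
                 las = 1, tick = FALSE, cex.axis = 0.7)
  for (si in seq_len(n_s)) {
    g <- summaries[[si]]$genes
    for (gi in seq_len(n_g)) {
      r <- 0.45 * rad[gi, si] / rmax
      fr <- c(g$frac_union_other[gi], g$frac_polymorphic_only[gi],
              g$frac_mutation[gi])
      if (anyNA(fr) || g$union_size[gi] == 0L) {
        graphics::symbols(gi, si, circles = 0.05, inches = FALSE,
                          add = TRUE, fg = "grey60")
        next
      }
      a0 <- 0
      for (k in seq_along(fr)) {
        if (fr[k] <= 0) next
        a1 <- a0 + fr[k] * 2 * pi
        th <- seq(a0, a1, length.out = max(8L, ceiling(64 * fr[k])))
        graphics::polygon(gi + c(0, r * cos(th), 0),
                          si + c(0, r * sin(th), 0),
                          col = cols[k], border = NA)
        a0 <- a1
      }
    }
  }
  graphics::legend("topright",
                   legend = c("polymorphic elsewhere", "polymorphic here",
                              "mutation class"),
                   fill = cols, bty = "n", cex = 0.7)
  invisible(rad)
}
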