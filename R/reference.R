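BASES <- c("A", "C", "G", "T")

#' Read a reference genome from FASTA
#'
#' Reads the first (or named) record of a FASTA file into a reference object
#' used throughout the package: a single small sequence (e.g. a chloroplast
#' genome fragment) that all samples are aligned against.
#'
#' @param path Path to a FASTA file.
#' @param id Optional record name to select; default the first record.
#' @return An object of class `reference_genome`: list with `id`, `sequence`
#'   (upper-case character string over A/C/G/T/N) and `length`.
#' @export
read_reference <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  if (!is.null(id)) {
    hit <- match(id, sub("\\s.*$", "", names(set)))
    if (is.na(hit)) stop("sequence '", id, "' not found in ", path)
    set <- set[hit]
  } else {
    set <- set[1]
  }
  reference_genome(sub("\\s.*$", "", names(set)), as.character(set))
}

#' Construct a reference genome object
#'
#' @param id Sequence identifier.
#' @param sequence DNA string over A/C/G/T/N (case-insensitive).
#' @return An object of class `reference_genome`.
#' @export
reference_genome <- function(id, sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("reference sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence contains characters outside A/C/G/T/N")
  }
  structure(
    list(id = as.character(id), sequence = sequence,
         length = nchar(sequence)),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat("<reference_genome> ", x$id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' Read gene annotations from BED or GFF3
#'
#' Converts a BED (3+ columns) or GFF3 annotation into the plain gene table
#' used by the summary functions. Coordinates are 1-based inclusive. For GFF3
#' input, only features of type gene, CDS, rRNA or tRNA are retained; the
#' feature type is recorded in `kind` (BED features get kind "other" unless a
#' name suggests rRNA/tRNA).
#'
#' @param path Path to a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @param reference Optional `reference_genome`; if given, genes are checked
#'   to lie within its bounds.
#' @return A data.frame with columns `gene_id`, `start`, `end`, `strand`,
#'   `kind`.
#' @export
read_genes <- function(path, reference = NULL) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if ("type" %in% names(df)) {  # GFF-like
    keep <- df$type %in% c("gene", "CDS", "rRNA", "tRNA")
    df <- df[keep, , drop = FALSE]
    ids <- if ("ID" %in% names(df)) df$ID else df$Name
    if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(df)))
    kind <- ifelse(df$type == "gene", "CDS", as.character(df$type))
  } else {
    ids <- if ("name" %in% names(df)) df$name else paste0("gene", seq_len(nrow(df)))
    kind <- rep("other", nrow(df))
  }
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  genes <- gene_table(gene_id = as.character(ids), start = df$start,
                      end = df$end, strand = as.character(df$strand),
                      kind = kind)
  if (!is.null(reference)) validate_genes(genes, reference)
  genes
}

#' Construct a gene annotation table
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param start,end 1-based inclusive coordinates on the reference.
#' @param strand "+" or "-" per gene ("*" tolerated, stored as "+").
#' @param kind Feature kind: CDS, rRNA, tRNA or other.
#' @return data.frame with the five columns, validated.
#' @export
gene_table <- function(gene_id, start, end,
                       strand = rep("+", length(gene_id)),
                       kind = rep("CDS", length(gene_id))) {
  strand[!strand %in% c("+", "-")] <- "+"
  df <- data.frame(gene_id = as.character(gene_id),
                   start = as.integer(start), end = as.integer(end),
                   strand = strand, kind = kind,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("gene_ids must be unique")
  if (any(df$start < 1L) || any(df$end < df$start)) {
    stop("gene intervals must satisfy 1 <= start <= end")
  }
  df
}

validate_genes <- function(genes, reference) {
  if (any(genes$end > reference$length)) {
    bad <- genes$gene_id[genes$end > reference$length]
    stop("gene(s) outside reference bounds: ", paste(bad, collapse = ", "))
  }
  invisible(genes)
}

#' Write gene annotations to BED
#'
#' @param genes Gene table from [gene_table()] or [read_genes()].
#' @param reference `reference_genome` the genes annotate.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, reference, path) {
  bed <- data.frame(chrom = reference$id, start = genes$start - 1L,
                    end = genes$end, name = genes$gene_id, score = 0L,
                    strand = genes$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
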