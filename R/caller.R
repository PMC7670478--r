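#' Binomial error-model p-value for a pileup site
#'
#' Under the non-polymorphic null every non-dominant read base is a
#' sequencing error occurring independently at rate `error_rate`, so the
#' dominant-allele count follows Binomial(N, 1 - E). With `mode = "tail"`
#' (default) the p-value is the probability of seeing at least `N - T` error
#' reads, i.e. `P(Binomial(N, 1 - E) <= T)`; `mode = "pmf"` returns the point
#' mass `P(Binomial(N, 1 - E) = T)` and is retained for sensitivity analysis
#' only, since a pure point mass is not a coherent rejection rule at large N.
#'
#' Evaluated via [stats::pbinom()] / [stats::dbinom()], which are stable for
#' depths well beyond 10^6. All arguments are vectorized.
#'
#' @param N Total filtered reads at the site (N >= 1).
#' @param T_dom Reads supporting the dominant allele (0 <= T_dom <= N).
#' @param error_rate Per-base sequencing error probability E in (0, 1);
#'   default 0.01 (Illumina).
#' @param mode "tail" or "pmf".
#' @return Numeric vector of p-values in `[0, 1]`.
#' @export
site_p_value <- function(N, T_dom, error_rate = 0.01,
                         mode = c("tail", "pmf")) {
  mode <- match.arg(mode)
  N <- as.numeric(N)
  T_dom <- as.numeric(T_dom)
  if (any(N < 1)) stop("N must be >= 1")
  if (any(T_dom < 0) || any(T_dom > N)) stop("T_dom must satisfy 0 <= T_dom <= N")
  if (error_rate <= 0 || error_rate >= 1) stop("error_rate must be in (0, 1)")
  if (mode == "tail") {
    pbinom(T_dom, N, 1 - error_rate)
  } else {
    dbinom(T_dom, N, 1 - error_rate)
  }
}

#' Classify pileup sites against the binomial error model
#'
#' Vectorized site classification:
#' * `N < min_coverage`: **untested** (too shallow to evaluate);
#' * p-value < `alpha` and `T_dom < N - T_dom`: **mutation** (alternative
#'   alleles jointly outnumber the dominant allele — evidence that the
#'   locally dominant lineage has been displaced);
#' * p-value < `alpha` otherwise: **polymorphic**;
#' * else **non_polymorphic**.
#'
#' @inheritParams site_p_value
#' @param alpha Per-site significance level (default 0.05, no multiplicity
#'   correction — see `bonferroni`).
#' @param min_coverage Minimum depth for a site to be tested (default 5).
#' @param bonferroni If TRUE, `alpha` is divided by the number of tested
#'   sites. Off by default: the test is applied per site.
#' @return data.frame with columns `N`, `T_dom`, `p_value` (NA for untested
#'   sites) and `status` (factor with levels untested, non_polymorphic,
#'   polymorphic, mutation).
#' @export
classify_sites <- function(N, T_dom, error_rate = 0.01, alpha = 0.05,
                           min_coverage = 5, mode = c("tail", "pmf"),
                           bonferroni = FALSE) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_coverage < 1) stop("min_coverage must be >= 1")
  N <- as.integer(N)
  T_dom <- as.integer(T_dom)
  tested <- N >= min_coverage
  p <- rep(NA_real_, length(N))
  if (any(tested)) {
    p[tested] <- site_p_value(N[tested], T_dom[tested], error_rate, mode)
  }
  thr <- if (bonferroni && sum(tested) > 0L) alpha / sum(tested) else alpha
  rejected <- !is.na(p) & p < thr
  status <- rep("non_polymorphic", length(N))
  status[!tested] <- "untested"
  status[rejected] <- ifelse(T_dom[rejected] < N[rejected] - T_dom[rejected],
                             "mutation", "polymorphic")
  data.frame(N = N, T_dom = T_dom, p_value = p,
             status = factor(status, levels = CALL_LEVELS))
}

CALL_LEVELS <- c("untested", "non_polymorphic", "polymorphic", "mutation")

#' Call polymorphic sites over a sample profile
#'
#' Applies the binomial error-model test to every reference position of a
#' sample's allele-count profile and returns a classed call-set object — the
#' package's central fitted object, with `print`, `summary` and `plot`
#' methods.
#'
#' @param profile A `sample_profile` (from [load_site_counts()],
#'   [load_count_table()] or [simulate_sample()]).
#' @inheritParams classify_sites
#' @return Object of class `poly_call`: list with
#'   \describe{
#'     \item{calls}{data.frame `pos`, `N`, `T_dom`, `dominant`, `p_value`,
#'       `status` over all reference positions, in position order.}
#'     \item{profile}{the input `sample_profile`.}
#'     \item{config}{list of the caller settings used.}
#'   }
#' @examples
#' ref <- simulate_reference(2000, n_genes = 3, seed = 1)
#' truth <- simulate_strains(ref$reference, K = 2, divergence = 0.01, seed = 2)
#' prof <- simulate_sample(truth, abundances = c(0.7, 0.3),
#'                         mean_coverage = 80, error_rate = 0.01, seed = 3)
#' pc <- call_polymorphisms(prof)
#' summary(pc)
#' @export
call_polymorphisms <- function(profile, error_rate = 0.01, alpha = 0.05,
                               min_coverage = 5, mode = c("tail", "pmf"),
                               bonferroni = FALSE) {
  stopifnot(inherits(profile, "sample_profile"))
  mode <- match.arg(mode)
  cc <- profile$counts
  cls <- classify_sites(cc$N, cc$T_dom, error_rate = error_rate,
                        alpha = alpha, min_coverage = min_coverage,
                        mode = mode, bonferroni = bonferroni)
  structure(
    list(calls = data.frame(pos = cc$pos, cls[c("N", "T_dom")],
                            dominant = cc$dominant,
                            p_value = cls$p_value, status = cls$status),
         profile = profile,
         config = list(error_rate = error_rate, alpha = alpha,
                       min_coverage = min_coverage, mode = mode,
                       bonferroni = bonferroni)),
    class = "poly_call"
  )
}

#' Extract positions with a given call status
#'
#' @param x A `poly_call`.
#' @param status Statuses to select; default the two rejected classes.
#' @return Integer vector of 1-based positions.
#' @export
polymorphic_sites <- function(x, status = c("polymorphic", "mutation")) {
  stopifnot(inherits(x, "poly_call"))
  status <- match.arg(status, CALL_LEVELS, several.ok = TRUE)
  x$calls$pos[x$calls$status %in% status]
}

#' @export
print.poly_call <- function(x, ...) {
  tab <- table(x$calls$status)
  cat("<poly_call> sample ", x$profile$sample_id, " on ",
      x$profile$reference_id, "\n", sep = "")
  cat("  E = ", x$config$error_rate, ", alpha = ", x$config$alpha,
      ", min coverage = ", x$config$min_coverage,
      ", mode = ", x$config$mode, "\n", sep = "")
  cat("  ", paste(names(tab), as.integer(tab), sep = ": ",
                  collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.poly_call <- function(object, ...) {
  calls <- object$calls
  tested <- calls$status != "untested"
  poly <- calls$status %in% c("polymorphic", "mutation")
  mut <- calls$status == "mutation"
  out <- list(
    sample_id = object$profile$sample_id,
    condition = object$profile$condition,
    material = object$profile$material,
    n_sites = nrow(calls),
    n_tested = sum(tested),
    n_polymorphic = sum(poly),
    n_mutation = sum(mut),
    f_poly = if (sum(tested)) sum(poly) / sum(tested) else NA_real_,
    f_mut_poly = if (sum(poly)) sum(mut) / sum(poly) else NA_real_,
    config = object$config)
  class(out) <- "summary.poly_call"
  out
}

#' @export
print.summary.poly_call <- function(x, ...) {
  cat("Polymorphism calls for sample ", x$sample_id, " (", x$condition,
      ", ", x$material, ")\n", sep = "")
  cat("  tested sites:        ", x$n_tested, " / ", x$n_sites, "\n", sep = "")
  cat("  polymorphic:         ", x$n_polymorphic,
      sprintf("  (%.3g%% of tested)", 100 * x$f_poly), "\n", sep = "")
  cat("  mutation class:      ", x$n_mutation,
      if (x$n_polymorphic > 0)
        sprintf("  (%.3g%% of polymorphic)", 100 * x$f_mut_poly) else "",
      "\n", sep = "")
  invisible(x)
}

#' Plot a call-set along the reference
#'
#' Depth along the reference with tested sites coloured by status; rejected
#' sites (polymorphic/mutation) are emphasized.
#'
#' @param x A `poly_call`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.poly_call <- function(x, ...) {
  calls <- x$calls
  cols <- c(untested = "grey80", non_polymorphic = "grey50",
            polymorphic = "dodgerblue3", mutation = "firebrick3")
  graphics::plot(calls$pos, calls$N, type = "h", col = cols[as.character(calls$status)],
                 xlab = sprintf("position on %s", x$profile$reference_id),
                 ylab = "filtered depth (N)", ...)
  sel <- calls$status %in% c("polymorphic", "mutation")
  if (any(sel)) {
    graphics::points(calls$pos[sel], calls$N[sel], pch = 16, cex = 0.6,
                     col = cols[as.character(calls$status[sel])])
  }
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Write calls as VCF 4.2
#'
#' One record per polymorphic or mutation-class site, 1-based coordinates.
#' REF is the reference base; ALT lists the observed non-reference alleles in
#' decreasing count order. INFO carries `NS_COV` (filtered depth N), `T_DOM`
#' (dominant-allele count), `PVAL` and `CLASS` (POLY or MUT).
#'
#' @param x A `poly_call`.
#' @param reference The `reference_genome` the calls are on.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, reference, path) {
  stopifnot(inherits(x, "poly_call"), inherits(reference, "reference_genome"))
  calls <- x$calls
  sel <- which(calls$status %in% c("polymorphic", "mutation"))
  refchars <- strsplit(reference$sequence, "", fixed = TRUE)[[1]]
  cnt <- as.matrix(x$profile$counts[BASES])
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", reference$id, reference$length),
    "##INFO=<ID=NS_COV,Number=1,Type=Integer,Description=\"Filtered read depth N at site\">",
    "##INFO=<ID=T_DOM,Number=1,Type=Integer,Description=\"Reads supporting the dominant allele\">",
    "##INFO=<ID=PVAL,Number=1,Type=Float,Description=\"Binomial error-model p-value\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"POLY (polymorphic) or MUT (alternative alleles outnumber dominant)\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  for (i in sel) {
    pos <- calls$pos[i]
    refb <- refchars[pos]
    alts <- BASES[cnt[pos, ] > 0L & BASES != refb]
    alts <- alts[order(-cnt[pos, alts])]
    if (length(alts) == 0L) alts <- "."
    lines <- c(lines, sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\tNS_COV=%d;T_DOM=%d;PVAL=%.3g;CLASS=%s",
      reference$id, pos, refb, paste(alts, collapse = ","),
      calls$N[i], calls$T_dom[i], calls$p_value[i],
      if (calls$status[i] == "mutation") "MUT" else "POLY"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the full per-site call table
#'
#' TSV over all reference positions (including untested and non-polymorphic
#' ones) with 1-based `position`, counts, `p_value` and `status`.
#'
#' @param x A `poly_call`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_table <- function(x, path) {
  stopifnot(inherits(x, "poly_call"))
  cc <- x$profile$counts
  out <- data.frame(position = cc$pos, cc[BASES], N = cc$N,
                    T_dominant = cc$T_dom,
                    p_value = x$calls$p_value, status = x$calls$status)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
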