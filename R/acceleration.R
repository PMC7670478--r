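#' Genome-wide mutation fraction from its two factors
#'
#' The fraction of mutation-class sites over the whole genome is the product
#' of the fraction of polymorphic positions genome-wide and the fraction of
#' mutation-class sites among the polymorphic positions.
#'
#' @param f_poly Fraction of polymorphic positions genome-wide, in `[0, 1]`.
#' @param f_mut_poly Fraction of mutation-class sites among polymorphic
#'   positions, in `[0, 1]`.
#' @return `f_poly * f_mut_poly`.
#' @examples
#' mutation_fraction_genome(0.016, 0.125)  # 0.002
#' @export
mutation_fraction_genome <- function(f_poly, f_mut_poly) {
  check_fraction(f_poly, "f_poly")
  check_fraction(f_mut_poly, "f_mut_poly")
  f_poly * f_mut_poly
}

check_fraction <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must be a fraction in [0, 1]")
  }
  invisible(x)
}

#' Mutation-rate acceleration against a molecular-clock background
#'
#' Compares the per-site substitution rate accrued during the disease episode
#' (`f_mut_genome / t_disease`) with the background lineage rate
#' (`d_background / t_divergence`):
#'
#'   acceleration = (f_mut_genome / t_disease) / (d_background / t_divergence)
#'
#' Either supply `f_mut_genome` directly or let it be computed as
#' `f_poly * f_mut_poly` via [mutation_fraction_genome()]. When all three are
#' given and disagree by more than `1e-6` a warning is emitted (the directly
#' supplied value wins). The background distance is used raw by default, as a
#' plain distance-over-time rate with no multiple-hit correction;
#' `jukes_cantor = TRUE` applies the Jukes–Cantor correction
#' `-3/4 log(1 - 4d/3)` to `d_background` first.
#'
#' @param f_mut_genome Genome-wide mutation-class fraction (dimensionless).
#' @param f_poly,f_mut_poly Alternative parameterization, see above.
#' @param d_background Genetic distance to the outgroup (substitutions/site).
#' @param t_divergence Separation time from the outgroup, in years.
#' @param t_disease Disease duration in years; default 1 (one season).
#' @param jukes_cantor Apply Jukes–Cantor multiple-hit correction to
#'   `d_background`.
#' @return Object of class `accel_estimate`: list with all inputs, the
#'   effective `f_mut_genome` and `d_background`, and `ratio` (the
#'   dimensionless acceleration factor).
#' @examples
#' # disease accrues 0.2% of the genome in one year against a 20% / 1 Myr
#' # background clock: a 10000-fold acceleration
#' acceleration_ratio(f_poly = 0.016, f_mut_poly = 0.125,
#'                    d_background = 0.20, t_divergence = 1e6)$ratio
#' @export
acceleration_ratio <- function(f_mut_genome = NULL, f_poly = NULL,
                               f_mut_poly = NULL, d_background,
                               t_divergence, t_disease = 1,
                               jukes_cantor = FALSE) {
  if (is.null(f_mut_genome)) {
    if (is.null(f_poly) || is.null(f_mut_poly)) {
      stop("supply f_mut_genome, or both f_poly and f_mut_poly")
    }
    f_mut_genome <- mutation_fraction_genome(f_poly, f_mut_poly)
  } else {
    check_fraction(f_mut_genome, "f_mut_genome")
    if (!is.null(f_poly) && !is.null(f_mut_poly) &&
        abs(f_mut_genome - f_poly * f_mut_poly) > 1e-6) {
      warning("f_mut_genome differs from f_poly * f_mut_poly; ",
              "using the supplied f_mut_genome")
    }
  }
  if (!is.finite(d_background) || d_background <= 0) {
    stop("d_background must be > 0")
  }
  if (t_divergence <= 0 || t_disease <= 0) stop("times must be > 0")
  d_eff <- if (jukes_cantor) {
    if (d_background >= 0.75) stop("Jukes-Cantor correction undefined for d >= 0.75")
    -0.75 * log(1 - 4 * d_background / 3)
  } else d_background
  structure(
    list(f_mut_genome = f_mut_genome, f_poly = f_poly,
         f_mut_poly = f_mut_poly, d_background = d_background,
         d_effective = d_eff, t_divergence = t_divergence,
         t_disease = t_disease, jukes_cantor = jukes_cantor,
         disease_rate = f_mut_genome / t_disease,
         background_rate = d_eff / t_divergence,
         ratio = (f_mut_genome / t_disease) / (d_eff / t_divergence)),
    class = "accel_estimate"
  )
}

#' @export
print.accel_estimate <- function(x, ...) {
  cat("Mutation-rate acceleration estimate\n")
  cat(sprintf("  genome-wide mutation fraction: %.4g (over %.3g yr)\n",
              x$f_mut_genome, x$t_disease))
  cat(sprintf("  background distance:           %.4g%s (over %.3g yr)\n",
              x$d_effective,
              if (x$jukes_cantor) " (Jukes-Cantor corrected)" else "",
              x$t_divergence))
  cat(sprintf("  disease rate / background rate = %.4g\n", x$ratio))
  invisible(x)
}

#' Acceleration estimate from observed calls
#'
#' Wires a genome-wide call summary into [acceleration_ratio()]:
#' `f_poly` is the genome fraction of tested sites called polymorphic and
#' `f_mut_poly` the fraction of those in the mutation class. Zero polymorphic
#' sites gives a ratio of 0.
#'
#' @param summary A `sample_summary` (from [summarize_sample()]) or a
#'   `poly_call` (summarized on the fly with no gene table).
#' @inheritParams acceleration_ratio
#' @return An `accel_estimate` whose fields echo every parameter used.
#' @export
acceleration_from_calls <- function(summary, d_background, t_divergence,
                                    t_disease = 1, jukes_cantor = FALSE) {
  g <- if (inherits(summary, "sample_summary")) {
    summary$genome
  } else if (inherits(summary, "poly_call")) {
    s <- summary(summary)
    list(n_tested = s$n_tested, n_polymorphic = s$n_polymorphic,
         n_mutation = s$n_mutation)
  } else {
    stop("'summary' must be a sample_summary or poly_call")
  }
  if (g$n_tested == 0L) stop("no tested sites; cannot estimate fractions")
  f_poly <- g$n_polymorphic / g$n_tested
  f_mut_poly <- if (g$n_polymorphic > 0L) g$n_mutation / g$n_polymorphic else 0
  acceleration_ratio(f_poly = f_poly, f_mut_poly = f_mut_poly,
                     d_background = d_background,
                     t_divergence = t_divergence, t_disease = t_disease,
                     jukes_cantor = jukes_cantor)
}

#' Write an acceleration report as JSON
#'
#' @param x An `accel_estimate`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accel_json <- function(x, path) {
  stopifnot(inherits(x, "accel_estimate"))
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
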