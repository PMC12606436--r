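#' Population state
#'
#' The state of a simulated population: the table of segregating alleles
#' (per-copy sex-specific effects `af`, `am` and derived-allele frequency
#' `x`), the fixed backgrounds `Ff`, `Fm` (trait value carried by fixations,
#' per sex), and the generation counter. Effects are stored with explicit
#' signs; alleles that fix are folded into the backgrounds and removed, so
#' the mean identity
#' \eqn{\bar z_f = \tilde F_f + \sum_i 2 a_{i,f} x_i} holds exactly at all
#' times (and likewise for males).
#'
#' @param af,am Numeric vectors of per-copy effects (delta units).
#' @param x Derived-allele frequencies, strictly in (0, 1).
#' @param Ff,Fm Fixed backgrounds (trait units).
#' @param generation Integer time.
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(af = numeric(0), am = numeric(0),
                             x = numeric(0), Ff = 0, Fm = 0, generation = 0L) {
  stopifnot(length(af) == length(am), length(af) == length(x))
  if (length(x) && (any(x <= 0) || any(x >= 1)))
    stop("allele frequencies must lie strictly in (0, 1)")
  structure(list(af = af, am = am, x = x, Ff = Ff, Fm = Fm,
                 generation = as.integer(generation)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  zz <- phenotypic_means(x)
  cat(sprintf(
    "Population state: generation %d, %d segregating alleles\n",
    x$generation, length(x$x)))
  cat(sprintf("  means: zf = %.4g, zm = %.4g  (fixed backgrounds %.4g, %.4g)\n",
              zz[["zf"]], zz[["zm"]], x$Ff, x$Fm))
  invisible(x)
}

#' Sex-specific phenotypic means
#'
#' \eqn{\bar z_\alpha = \tilde F_\alpha + \sum_i 2 a_{i,\alpha} x_i} for
#' \eqn{\alpha = f, m}: the fixed background plus the segregating
#' contribution.
#'
#' @param state A [population_state()].
#' @return Named numeric vector `c(zf = , zm = )`.
#' @export
phenotypic_means <- function(state) {
  c(zf = state$Ff + sum(2 * state$af * state$x),
    zm = state$Fm + sum(2 * state$am * state$x))
}

#' Serialize / restore population snapshots
#'
#' Writes the allele table as TSV (columns `af`, `am`, `x`) with a JSON
#' sidecar holding the fixed backgrounds, generation, and (optionally) model
#' parameters; `read_population()` restores the state.
#'
#' @param state A [population_state()].
#' @param file Path of the TSV file; the JSON header is written to
#'   `paste0(file, ".json")`.
#' @param params Optional [model_params()] recorded in the header.
#' @return `write_population()` returns `file` invisibly;
#'   `read_population()` returns a [population_state()].
#' @export
write_population <- function(state, file, params = NULL) {
  utils::write.table(
    data.frame(af = state$af, am = state$am, x = state$x),
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  header <- list(Ff = state$Ff, Fm = state$Fm, generation = state$generation)
  if (!is.null(params)) header$params <- unclass(params)
  jsonlite::write_json(header, paste0(file, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_population
#' @export
read_population <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t")
  hdr <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  population_state(af = tab$af, am = tab$am, x = tab$x,
                   Ff = hdr$Ff, Fm = hdr$Fm, generation = hdr$generation)
}
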