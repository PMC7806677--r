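# Temporal-trend testing under chronostratigraphic age uncertainty. Each
# species' age is only known to a stratigraphic interval, so the Pearson
# correlation between stress (MWAM) and age is repeated many times with ages
# resampled uniformly within the intervals; the resulting coefficient and
# p-value distributions are summarised as violin-style densities. Ages are in
# Mya (larger = older), so "stress increasing towards the present"
# corresponds to a negative correlation with age.

# run code with a reproducible, isolated RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Resample species ages within their chronostratigraphic ranges
#'
#' One age per species, drawn uniformly from `[younger_mya, older_mya]`;
#' a zero-width range always returns its single age. Uses the current RNG
#' state (seed management is done by [repeated_correlation()]).
#'
#' @param records Data frame with columns `older_mya` and `younger_mya`.
#' @return Numeric vector of ages (Mya).
#' @export
sample_ages <- function(records) {
  older <- records$older_mya
  younger <- records$younger_mya
  if (any(!is.finite(older)) || any(!is.finite(younger)) || any(younger < 0))
    stop("stratigraphic ranges must be finite and non-negative", call. = FALSE)
  if (any(older < younger))
    stop("inverted stratigraphic range (older_mya < younger_mya)", call. = FALSE)
  younger + runif(length(older)) * (older - younger)
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with elements `r` and `p` (p from the t transform with
#'   n - 2 degrees of freedom; 0 when |r| = 1).
#' @export
pearson_r_p <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3)
    stop("x and y must have equal length >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = sign(r), p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

#' Repeated age-resampled correlation between MWAM and species age
#'
#' For each of `n_reps` replicates, species ages are resampled within their
#' chronostratigraphic ranges and the Pearson correlation between the MWAM
#' values and the resampled ages is computed. The whole result is
#' reproducible bit-for-bit for a fixed seed.
#'
#' @param mwam_values One MWAM value (MPa) per species record.
#' @param records Species data frame with `older_mya`, `younger_mya`.
#' @param n_reps Number of replicates (the comparative analyses use 10,000).
#' @param seed Integer seed for the replicate RNG stream.
#' @return A `trend_result`: `coefficients` and `p_values` (length
#'   `n_reps`), `n_reps`, `seed`, and the `records` used.
#' @export
repeated_correlation <- function(mwam_values, records, n_reps = 10000, seed = 1) {
  if (length(mwam_values) != nrow(records))
    stop("need exactly one MWAM value per species record", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  res <- with_seed(seed, {
    r <- numeric(n_reps); p <- numeric(n_reps)
    for (i in seq_len(n_reps)) {
      ages <- sample_ages(records)
      rp <- pearson_r_p(mwam_values, ages)
      r[i] <- rp$r; p[i] <- rp$p
    }
    list(r = r, p = p)
  })
  structure(list(coefficients = res$r, p_values = res$p,
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 records = records),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  q <- stats::quantile(x$coefficients, c(0.025, 0.5, 0.975))
  cat(sprintf("<trend_result> %d replicates (seed %d): r median %.3f [95%% %.3f, %.3f]; median p %.3g\n",
              x$n_reps, x$seed, q[2], q[1], q[3], stats::median(x$p_values)))
  invisible(x)
}

#' Quantiles and kernel densities of a trend result for violin-style display
#'
#' @param result A `trend_result`.
#' @param probs Quantile probabilities.
#' @return List with `quantiles` (matrix: rows = coefficient/p_value) and
#'   `density` (kernel density estimates for both, or NULL for degenerate
#'   constant samples).
#' @export
density_summary <- function(result,
                            probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  stopifnot(inherits(result, "trend_result"))
  q <- rbind(coefficient = stats::quantile(result$coefficients, probs),
             p_value = stats::quantile(result$p_values, probs))
  colnames(q) <- paste0(100 * probs, "%")
  dens <- function(v) if (stats::var(v) > 0) stats::density(v) else NULL
  list(quantiles = q,
       density = list(coefficient = dens(result$coefficients),
                      p_value = dens(result$p_values)))
}

#' Export a trend result as CSV plus JSON metadata
#'
#' @param result A `trend_result`.
#' @param prefix Path prefix; writes `<prefix>_replicates.csv` and
#'   `<prefix>_meta.json`.
#' @return The two paths, invisibly.
#' @export
write_trend_result <- function(result, prefix) {
  cf <- paste0(prefix, "_replicates.csv")
  mf <- paste0(prefix, "_meta.json")
  utils::write.csv(data.frame(replicate = seq_len(result$n_reps),
                              r = result$coefficients, p = result$p_values),
                   cf, row.names = FALSE)
  meta <- list(seed = result$seed, n_reps = result$n_reps,
               records = result$records)
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(cf, mf))
}
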