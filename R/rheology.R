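# Storage/loss-modulus crossover analysis of frequency sweeps.
#
# In an oscillatory frequency sweep, G' (storage) dominates where the network
# responds elastically and G'' (loss) where it flows; the frequency where
# G'' overtakes G' reflects the degree of cross-linking — a less connected
# scaffold crosses over at a lower angular frequency. Crossovers are located
# as sign changes of log G' - log G'' along the grid and refined by linear
# interpolation in log-log space (moduli span decades, so linear-space
# interpolation would bias the estimate).

#' Construct and validate a rheology sweep
#'
#' @param data data.frame with columns `omega_rad_s` (strictly increasing,
#'   positive), `g_storage_pa`, `g_loss_pa` (positive), length >= 3.
#' @param label sample label.
#' @return data.frame of class `rheology_sweep`.
#' @export
rheology_sweep <- function(data, label = NA_character_) {
  if (!is.data.frame(data)) stopf("'data' must be a data.frame")
  for (col in c("omega_rad_s", "g_storage_pa", "g_loss_pa"))
    if (!col %in% names(data)) stopf("sweep is missing column '%s'", col)
  if (nrow(data) < 3L) stopf("a sweep needs at least 3 frequencies")
  if (any(data$omega_rad_s <= 0) || any(diff(data$omega_rad_s) <= 0))
    stopf("'omega_rad_s' must be strictly increasing and positive")
  if (any(data$g_storage_pa <= 0) || any(data$g_loss_pa <= 0))
    stopf("moduli must be strictly positive")
  attr(data, "label") <- label
  class(data) <- c("rheology_sweep", "data.frame")
  data
}

#' Locate storage/loss-modulus crossovers
#'
#' @param sweep a [rheology_sweep()].
#' @return object of class `crossover_report`: `crossovers` (rad/s, possibly
#'   empty), `primary` (first crossover or NA), `brackets` (grid index pairs),
#'   `method`. An exact tie at a grid point reports that grid frequency.
#' @export
crossover_frequency <- function(sweep) {
  if (!inherits(sweep, "rheology_sweep")) sweep <- rheology_sweep(sweep)
  lw <- log(sweep$omega_rad_s)
  d <- log(sweep$g_storage_pa) - log(sweep$g_loss_pa)
  n <- length(d)
  cross <- numeric(0); brackets <- list()
  for (i in seq_len(n - 1L)) {
    if (d[i] == 0) { cross <- c(cross, sweep$omega_rad_s[i]); brackets <- c(brackets, list(c(i, i))) }
    else if (d[i] * d[i + 1L] < 0) {
      t <- d[i] / (d[i] - d[i + 1L])
      cross <- c(cross, exp(lw[i] + t * (lw[i + 1L] - lw[i])))
      brackets <- c(brackets, list(c(i, i + 1L)))
    }
  }
  if (d[n] == 0) { cross <- c(cross, sweep$omega_rad_s[n]); brackets <- c(brackets, list(c(n, n))) }
  structure(list(crossovers = cross,
                 primary = if (length(cross)) cross[1] else NA_real_,
                 brackets = brackets, method = "log-log linear interpolation",
                 label = attr(sweep, "label")),
            class = "crossover_report")
}

#' Compare two frequency sweeps
#'
#' Crossover frequencies of both sweeps, their ratio, and per-frequency
#' modulus ratios on the common frequency range (log-log interpolated onto
#' the first sweep's grid points inside the overlap).
#'
#' @param a,b [rheology_sweep()] objects with overlapping frequency ranges.
#' @return list with `crossover_a`, `crossover_b`, `crossover_ratio`
#'   (a / b), and `modulus_ratios` (data.frame omega_rad_s, storage_ratio,
#'   loss_ratio; a over b).
#' @export
compare_sweeps <- function(a, b) {
  if (!inherits(a, "rheology_sweep")) a <- rheology_sweep(a)
  if (!inherits(b, "rheology_sweep")) b <- rheology_sweep(b)
  lo <- max(min(a$omega_rad_s), min(b$omega_rad_s))
  hi <- min(max(a$omega_rad_s), max(b$omega_rad_s))
  if (lo >= hi) stopf("sweeps have non-overlapping frequency ranges")
  ca <- crossover_frequency(a); cb <- crossover_frequency(b)
  grid <- a$omega_rad_s[a$omega_rad_s >= lo & a$omega_rad_s <= hi]
  interp <- function(sw, col) {
    exp(stats::approx(log(sw$omega_rad_s), log(sw[[col]]), xout = log(grid))$y)
  }
  ratios <- data.frame(
    omega_rad_s = grid,
    storage_ratio = interp(a, "g_storage_pa") / interp(b, "g_storage_pa"),
    loss_ratio = interp(a, "g_loss_pa") / interp(b, "g_loss_pa"))
  list(crossover_a = ca$primary, crossover_b = cb$primary,
       crossover_ratio = ca$primary / cb$primary, modulus_ratios = ratios)
}
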