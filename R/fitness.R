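#' Control parameters for the dictionary search
#'
#' @param mode scoring mode.  \code{"indicator"} (default) credits an
#'   individual with its full squared norm only once it is exactly
#'   reconstructable from the dictionary; \code{"residual"} gives partial
#'   credit for the variance reduction achieved by the closest reconstruction.
#'   Indicator mode is what reproduces the known greedy traces on small
#'   examples and is the recommended setting.
#' @param bias priority weight \code{b} applied to regular-genotype
#'   individuals (default 4); xor individuals always carry bias 1.
#' @param weight_missing when \code{TRUE}, each individual is weighted by the
#'   squared number of its observed loci, down-weighting heavily missing
#'   records.
#' @param tie_break how equal maximal gains are broken: \code{"lowest"}
#'   (deterministic, lowest column index) or \code{"random"} (seeded draw
#'   among the maximizers).
#' @param seed RNG seed used by \code{tie_break = "random"}.
#' @param max_block maximum block width \code{W} for partition-ligation
#'   (default 8); sequences longer than this are solved blockwise.
#' @param max_enum hard cap on the locus count for full candidate enumeration
#'   within one solve.
#' @return a list of class \code{xhsd_control}.
#' @export
xhsd_control <- function(mode = c("indicator", "residual"), bias = 4,
                         weight_missing = FALSE,
                         tie_break = c("lowest", "random"), seed = NULL,
                         max_block = 8L, max_enum = 16L) {
  mode <- match.arg(mode)
  tie_break <- match.arg(tie_break)
  if (bias < 1) stop("bias must be >= 1")
  if (max_block < 1L) stop("max_block must be >= 1")
  structure(list(mode = mode, bias = bias, weight_missing = weight_missing,
                 tie_break = tie_break, seed = seed,
                 max_block = as.integer(max_block),
                 max_enum = as.integer(max_enum)),
            class = "xhsd_control")
}

#' Missing-data weight of an observation
#'
#' The squared count of observed loci, a nondecreasing function of the
#' information content of the record; individuals with every locus missing get
#' weight 0 and contribute nothing.  Returns 1 when missing-weighting is off.
#'
#' @param obs an [xhsd_obs()] or a genotype vector with \code{NA} for missing.
#' @param on is missing-weighting enabled?
#' @return nonnegative scalar.
#' @examples
#' missing_weight(c(0, 1, NA, 0))        # 9
#' missing_weight(c(0, 1), on = FALSE)   # 1
#' @export
missing_weight <- function(obs, on = TRUE) {
  if (inherits(obs, "xhsd_obs")) obs <- obs$values
  if (!on) return(1)
  sum(!is.na(obs))^2
}

# Squared norm of the observed part of an observation (a regular genotype
# counts 2^2 = 4 per minor-homozygous site).
obs_norm2 <- function(values) {
  v <- values[!is.na(values)]
  sum(as.numeric(v)^2)
}

# Unweighted squared reconstruction distance on observed loci, +Inf when a
# support column is incompatible with a regular genotype.
residual_raw <- function(values, kind, support, mult = NULL) {
  L <- length(values)
  obs <- !is.na(values)
  if (kind == "regular") {
    for (k in support) {
      if (!hap_compatible(hap_column(k, L), values)) return(Inf)
    }
  }
  recon <- hap_reconstruct(support, L, kind = kind, mult = mult)
  sum((values[obs] - recon[obs])^2)
}

#' Reconstruction residual of an observation for a fixed support
#'
#' The minimum, over valid multiplicity assignments, of the squared Euclidean
#' distance between the observation and its reconstruction from the selected
#' candidate columns, restricted to observed loci and multiplied by the
#' observation's weight and bias.  For regular genotypes the support columns
#' must be compatible with the genotype; an incompatible column yields
#' \code{Inf} ("cannot explain"), not an error.
#'
#' @param obs an [xhsd_obs()].
#' @param support 1 or 2 candidate column indices.
#' @param control an [xhsd_control()]; supplies the missing-weighting switch.
#' @return nonnegative scalar (possibly \code{Inf}).
#' @examples
#' x <- xhsd_obs(c(0, 1, 1))
#' pair_residual(x, c(5, 3))  # 0: columns 001 and 010 xor to 011
#' @export
pair_residual <- function(obs, support, control = xhsd_control()) {
  stopifnot(inherits(obs, "xhsd_obs"))
  if (length(support) < 1L) stop("empty support")
  w <- missing_weight(obs, control$weight_missing)
  r <- residual_raw(obs$values, obs$kind, support)
  if (!is.finite(r)) return(Inf)
  w * obs$bias * r
}

#' Best explaining pair within a dictionary
#'
#' Searches all supports of size 1 (a doubled column) or 2 drawn from the
#' dictionary for the one minimizing the reconstruction residual; ties are
#' broken by the lexicographically smallest sorted support.
#'
#' @param obs an [xhsd_obs()].
#' @param D integer vector of dictionary column indices.
#' @return list with \code{support} (sorted indices) and \code{residual}
#'   (unweighted squared distance; \code{Inf} when no valid support exists).
#' @examples
#' best_pair(xhsd_obs(c(0, 0, 1)), c(5, 3, 1))  # support {1, 5}, residual 0
#' @export
best_pair <- function(obs, D) {
  stopifnot(inherits(obs, "xhsd_obs"))
  if (length(D) == 0L) return(list(support = integer(0), residual = Inf))
  D <- sort(unique(as.integer(D)))
  best <- list(support = integer(0), residual = Inf)
  for (a in seq_along(D)) {
    r <- residual_raw(obs$values, obs$kind, D[a])
    if (r < best$residual) best <- list(support = D[a], residual = r)
    if (a < length(D)) for (b in (a + 1L):length(D)) {
      r <- residual_raw(obs$values, obs$kind, c(D[a], D[b]))
      if (r < best$residual) best <- list(support = c(D[a], D[b]), residual = r)
    }
  }
  best
}

#' Fitness of one individual under a dictionary
#'
#' In indicator mode, the individual's weighted squared norm if the dictionary
#' reconstructs it exactly, else 0.  In residual mode, the weighted variance
#' reduction achieved by the best reconstruction, floored at 0.
#'
#' @inheritParams pair_residual
#' @param D dictionary column indices.
#' @return nonnegative scalar.
#' @export
individual_fitness <- function(obs, D, control = xhsd_control()) {
  stopifnot(inherits(obs, "xhsd_obs"))
  if (length(D) == 0L) return(0)
  w <- missing_weight(obs, control$weight_missing)
  if (w == 0) return(0)
  n2 <- obs_norm2(obs$values)
  bp <- best_pair(obs, D)
  if (control$mode == "indicator") {
    if (bp$residual == 0) w * obs$bias * n2 else 0
  } else {
    w * obs$bias * max(0, n2 - bp$residual)
  }
}

#' Average dictionary fitness over a population
#'
#' The arithmetic mean of [individual_fitness()] over all individuals; the
#' quantity the greedy search maximizes at each step.
#'
#' @param data an [xhsd_data()].
#' @param D dictionary column indices.
#' @param control an [xhsd_control()].
#' @return nonnegative scalar.
#' @examples
#' X <- matrix(c(0,0,1, 0,1,0, 0,1,1), nrow = 3)
#' dictionary_fitness(xhsd_data(X), c(5, 3))     # 2/3
#' dictionary_fitness(xhsd_data(X), c(5, 3, 1))  # 4/3
#' @export
dictionary_fitness <- function(data, D, control = xhsd_control()) {
  stopifnot(inherits(data, "xhsd_data"))
  if (data$N == 0L) stop("empty population")
  obs <- data_obs(data)
  mean(vapply(obs, individual_fitness, numeric(1), D = D, control = control))
}
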