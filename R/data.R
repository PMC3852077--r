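#' Observation container for xor- and regular-genotype populations
#'
#' Bundles a locus-by-individual matrix of observations with the per-individual
#' observation kind.  Xor-genotypes are coded over \{0,1\} (1 = heterozygous),
#' regular genotypes over \{0,1,2\} (0 = major-homozygous, 1 = heterozygous,
#' 2 = minor-homozygous); \code{NA} marks a missing (untyped) site.  Loci are
#' 1-based rows, individuals are columns.
#'
#' @param x integer matrix with \code{L} rows (loci) and \code{N} columns
#'   (individuals); \code{NA} allowed.
#' @param kind \code{"xor"} or \code{"regular"}, length 1 or \code{N}.
#' @param ids individual labels; defaults to column names or
#'   \code{ind1..indN}.
#' @param bias priority weight applied to regular-genotype individuals in the
#'   dictionary objective (xor individuals always have bias 1).
#' @param seed,params optional provenance fields recorded by the simulator
#'   and the file readers.
#' @return an object of class \code{xhsd_data} with elements \code{values},
#'   \code{kind}, \code{ids}, \code{L}, \code{N}, \code{bias}.
#' @examples
#' X <- matrix(c(0,0,1, 0,1,0, 0,1,1), nrow = 3)
#' d <- xhsd_data(X)
#' d
#' @export
xhsd_data <- function(x, kind = "xor", ids = NULL, bias = 4,
                      seed = NULL, params = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  L <- nrow(x)
  N <- ncol(x)
  if (L < 1L || N < 1L) stop_data("need at least one locus and one individual")
  kind <- rep_len(as.character(kind), N)
  if (!all(kind %in% c("xor", "regular"))) {
    stop_data("kind must be 'xor' or 'regular'")
  }
  for (i in seq_len(N)) {
    v <- x[, i]
    ok <- if (kind[i] == "xor") all(v %in% c(0L, 1L) | is.na(v))
          else all(v %in% c(0L, 1L, 2L) | is.na(v))
    if (!ok) stop_data("invalid entries for individual ", i,
                       " (kind ", kind[i], ")")
  }
  if (is.null(ids)) ids <- colnames(x) %||% paste0("ind", seq_len(N))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop_data("duplicate individual ids")
  if (length(ids) != N) stop_data("ids length must equal N")
  colnames(x) <- ids
  structure(list(values = x, kind = kind, ids = ids, L = L, N = N,
                 bias = ifelse(kind == "regular", bias, 1),
                 seed = seed, params = params),
            class = "xhsd_data")
}

#' @export
print.xhsd_data <- function(x, ...) {
  nreg <- sum(x$kind == "regular")
  nmiss <- sum(is.na(x$values))
  cat("xhsd_data: ", x$N, " individuals x ", x$L, " SNPs",
      if (nreg) paste0(" (", nreg, " regular-genotype)"), "\n", sep = "")
  if (nmiss) cat("  missing sites: ", nmiss,
                 sprintf(" (%.1f%%)", 100 * nmiss / length(x$values)), "\n",
                 sep = "")
  invisible(x)
}

#' @export
as.matrix.xhsd_data <- function(x, ...) x$values

#' Single observation (one individual)
#'
#' Light-weight constructor used by the low-level scoring functions.
#'
#' @param values genotype vector; \code{NA} = missing site.
#' @param kind \code{"xor"} or \code{"regular"}.
#' @param bias priority weight \code{b}; defaults to 1 for xor and 4 for
#'   regular observations.
#' @param id individual label.
#' @return object of class \code{xhsd_obs}.
#' @export
xhsd_obs <- function(values, kind = c("xor", "regular"), bias = NULL,
                     id = "ind1") {
  kind <- match.arg(kind)
  values <- as.integer(values)
  ok <- if (kind == "xor") all(values %in% c(0L, 1L) | is.na(values))
        else all(values %in% c(0L, 1L, 2L) | is.na(values))
  if (!ok) stop_data("invalid genotype entries for kind '", kind, "'")
  if (is.null(bias)) bias <- if (kind == "regular") 4 else 1
  if (bias < 1) stop_data("bias must be >= 1")
  structure(list(values = values, kind = kind, bias = bias, id = id,
                 L = length(values)),
            class = "xhsd_obs")
}

# Internal: list of xhsd_obs from an xhsd_data.
data_obs <- function(data) {
  lapply(seq_len(data$N), function(i) {
    xhsd_obs(data$values[, i], kind = data$kind[i], bias = data$bias[i],
             id = data$ids[i])
  })
}

# Restrict a dataset to a contiguous locus range (used by block partitioning).
slice_data <- function(data, l, m) {
  xhsd_data(data$values[l:m, , drop = FALSE], kind = data$kind,
            ids = data$ids, bias = max(data$bias), seed = data$seed)
}
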