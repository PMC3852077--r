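# Greedy sparse dictionary selection engine.
#
# Candidate columns are indexed 1..2^L (see hap_column()).  Per-individual
# "explained" tests are done in code space: the observed loci of a vector are
# packed into an integer, so a candidate pair (k, z) reconstructs an
# xor-genotype x exactly iff code(k) XOR code(z) == code(x).  This keeps each
# greedy step at O(M * (N + |D|)) without materializing reconstructions.

greedy_state <- function(data, control) {
  L <- data$L
  if (L > control$max_enum) {
    stop("L = ", L, " exceeds max_enum = ", control$max_enum,
         "; use block partitioning for long sequences")
  }
  M <- 2L^L
  Zbits <- cand_matrix(L)
  popcnt <- colSums(Zbits)            # popcnt[c + 1] = bits set in c
  obs <- data_obs(data)
  code_cache <- new.env(parent = emptyenv())
  per <- lapply(obs, function(o) {
    mask <- !is.na(o$values)
    key <- paste0("m", paste(which(mask), collapse = ","))
    if (is.null(code_cache[[key]])) {
      pw <- 2^(seq_len(sum(mask)) - 1L)
      code_cache[[key]] <- as.integer(pw %*% Zbits[mask, , drop = FALSE])
    }
    zcode <- code_cache[[key]]
    w <- missing_weight(o, control$weight_missing)
    st <- list(obs = o, mask = mask, w = w,
               n2 = obs_norm2(o$values),
               contrib = w * o$bias * obs_norm2(o$values),
               zcode = zcode,
               code = as.integer(bit_code(o$values[mask] %% 2L)))
    if (o$kind == "regular") {
      vobs <- o$values[mask]
      P <- vobs - Zbits[mask, , drop = FALSE]     # partner alleles g - k
      st$valid <- colSums(P < 0L | P > 1L) == 0L  # k compatible with g
      pw <- 2^(seq_len(sum(mask)) - 1L)
      st$pcode <- as.integer(pw %*% pmax(P, 0L))
      st$dbl_raw <- colSums((vobs - 2L * Zbits[mask, , drop = FALSE])^2)
      st$code <- as.integer(bit_code(vobs))       # unused for regular matches
    }
    st
  })
  list(L = L, M = M, N = data$N, Zbits = Zbits, popcnt = popcnt, per = per,
       control = control)
}

# Which candidate columns newly explain individual `st` when added to D?
# Returns a logical vector over all M candidates.
newly_explained <- function(st, D, state) {
  o <- st$obs
  if (o$kind == "xor") {
    if (st$code == 0L) return(rep(TRUE, state$M))  # any doubled column
    targets <- bitwXor(st$zcode[D], st$code)
    state_in <- st$zcode %in% targets
    return(state_in)
  }
  # regular: partner g - k must be a dictionary column (or k itself, doubled)
  hit <- st$valid & (st$pcode == st$zcode)
  if (length(D)) hit <- hit | (st$valid & st$pcode %in% st$zcode[D])
  hit
}

# Best raw residual over supports of size <= 2 drawn from D u {k}, for all k,
# given rbase = best raw residual within D alone.
resid_with_candidates <- function(st, D, rbase, state) {
  o <- st$obs
  M <- state$M
  if (o$kind == "xor") {
    best <- rep(st$n2, M)                            # doubled k -> all-zero
    for (z in D) {
      d <- state$popcnt[bitwXor(st$zcode, bitwXor(st$zcode[z], st$code)) + 1L]
      best <- pmin(best, d)
    }
    return(pmin(rbase, best))
  }
  best <- ifelse(st$valid, st$dbl_raw, Inf)
  mask <- st$mask
  vobs <- o$values[mask]
  for (z in D) {
    zb <- state$Zbits[mask, z]
    if (!all((vobs - zb) %in% c(0L, 1L))) next      # z incompatible with g
    d <- colSums((vobs - zb - state$Zbits[mask, , drop = FALSE])^2)
    d[!st$valid] <- Inf
    best <- pmin(best, d)
  }
  pmin(rbase, best)
}

# One greedy step against precomputed state.  `explained` and `rbase` describe
# the situation under the current dictionary D.
greedy_step_engine <- function(state, D, explained, rbase) {
  ctrl <- state$control
  M <- state$M
  N <- state$N
  gains <- numeric(M)
  base <- sum(vapply(which(explained), function(i) state$per[[i]]$contrib,
                     numeric(1)))
  newly <- vector("list", N)
  if (ctrl$mode == "indicator") {
    gains <- gains + base
    for (i in which(!explained)) {
      st <- state$per[[i]]
      if (st$w == 0) next
      newly[[i]] <- newly_explained(st, D, state)
      gains <- gains + st$contrib * newly[[i]]
    }
    gains <- gains / N
  } else {
    for (i in seq_len(N)) {
      st <- state$per[[i]]
      if (st$w == 0) next
      rb <- resid_with_candidates(st, D, rbase[i], state)
      gains <- gains + st$w * st$obs$bias * pmax(0, st$n2 - rb)
      if (!explained[i]) newly[[i]] <- rb == 0
    }
    gains <- gains / N
  }
  cand <- setdiff(seq_len(M), D)
  g <- gains[cand]
  mx <- max(g)
  fallback <- FALSE
  marginal <- if (ctrl$mode == "indicator") mx - base / N else mx
  if (ctrl$mode == "indicator" && marginal <= 1e-12) {
    # No candidate makes any individual exactly reconstructable (can happen
    # for regular-genotype individuals whose partner column is absent, and at
    # the very first iteration).  Prefer columns that are a compatible half
    # of some unexplained regular genotype -- the partner then completes the
    # pair on a later step -- and break ties by variance reduction, then by
    # lowest index.
    fallback <- TRUE
    half <- numeric(M)
    vr <- numeric(M)
    for (i in which(!explained)) {
      st <- state$per[[i]]
      if (st$w == 0) next
      if (st$obs$kind == "regular") half <- half + st$contrib * st$valid
      rb <- resid_with_candidates(st, D, rbase[i], state)
      vr <- vr + st$w * st$obs$bias * pmax(0, st$n2 - rb)
    }
    sel_pool <- cand[half[cand] >= max(half[cand]) - 1e-9]
    sel_pool <- sel_pool[vr[sel_pool] >= max(vr[sel_pool]) - 1e-9]
  } else {
    sel_pool <- cand[g >= mx - 1e-9]
  }
  selected <- if (ctrl$tie_break == "random" && length(sel_pool) > 1L) {
    sel_pool[sample.int(length(sel_pool), 1L)]
  } else {
    min(sel_pool)
  }
  structure(list(iteration = length(D) + 1L, candidates = cand,
                 gains = g, selected = selected, max_gain = mx,
                 fallback = fallback),
            class = "xhsd_trace")
}

#' One greedy dictionary-growth step
#'
#' Scores every candidate column outside the current dictionary by the average
#' dictionary fitness it would yield when added, and selects the maximizer
#' (ties broken per the control's \code{tie_break}; default lowest column
#' index).
#'
#' @param data an [xhsd_data()].
#' @param D current dictionary column indices (possibly empty).
#' @param control an [xhsd_control()].
#' @return an object of class \code{xhsd_trace}: \code{iteration},
#'   \code{candidates} (column indices scored, in ascending order),
#'   \code{gains} (fitness of \code{D + {k}} per candidate), \code{selected},
#'   \code{max_gain}.
#' @examples
#' X <- matrix(c(0,0,1, 0,1,0, 0,1,1), nrow = 3)
#' tr <- greedy_step(xhsd_data(X), D = 5L)
#' tr$selected   # 3
#' @export
greedy_step <- function(data, D = integer(0), control = xhsd_control()) {
  stopifnot(inherits(data, "xhsd_data"))
  state <- greedy_state(data, control)
  D <- as.integer(D)
  explained <- rep(FALSE, data$N)
  rbase <- rep(Inf, data$N)
  obs <- data_obs(data)
  for (i in seq_len(data$N)) {
    if (length(D)) {
      bp <- best_pair(obs[[i]], D)
      rbase[i] <- bp$residual
      explained[i] <- bp$residual == 0 ||
        missing_weight(obs[[i]], control$weight_missing) == 0
    }
  }
  greedy_step_engine(state, D, explained, rbase)
}

#' @export
print.xhsd_trace <- function(x, ...) {
  cat("greedy step ", x$iteration, ": selected column ", x$selected,
      sprintf(" (max gain %.4g", x$max_gain),
      if (isTRUE(x$fallback)) ", residual fallback", ")\n", sep = "")
  invisible(x)
}

# Full greedy growth until every individual is explained.  Returns the raw
# solution pieces; xhsd() wraps them into the user-facing object.
greedy_phase <- function(data, control = xhsd_control(), init = NULL) {
  state <- greedy_state(data, control)
  obs <- data_obs(data)
  N <- data$N
  D <- as.integer(init %||% integer(0))
  if (any(D < 1L | D > state$M)) stop("init column index out of range")
  explained <- rep(FALSE, N)
  rbase <- rep(Inf, N)
  zero_w <- vapply(seq_len(N), function(i) {
    missing_weight(obs[[i]], control$weight_missing) == 0 &&
      all(is.na(obs[[i]]$values))
  }, logical(1))
  refresh <- function(i) {
    bp <- best_pair(obs[[i]], D)
    rbase[i] <<- bp$residual
    explained[i] <<- bp$residual == 0
  }
  if (length(D)) for (i in seq_len(N)) refresh(i)
  explained <- explained | zero_w
  traces <- list()
  while (!all(explained)) {
    if (length(D) >= state$M) {
      stop("dictionary search failed to converge within 2^L iterations")
    }
    tr <- greedy_step_engine(state, D, explained, rbase)
    j <- tr$selected
    for (i in which(!explained)) {
      st <- state$per[[i]]
      nb <- resid_with_candidates(st, D, rbase[i], state)[j]
      if (nb < rbase[i]) rbase[i] <- nb
      if (nb == 0) explained[i] <- TRUE
    }
    D <- c(D, j)
    traces[[length(traces) + 1L]] <- tr
  }
  assignments <- lapply(obs, function(o) {
    bp <- best_pair(o, D)
    if (length(bp$support) == 0L) bp$support <- min(D)  # fully missing record
    mult <- if (length(bp$support) == 1L) 2L else c(1L, 1L)
    list(support = bp$support, mult = mult,
         residual = if (is.finite(bp$residual)) bp$residual else NA_real_)
  })
  list(D = D, traces = traces, assignments = assignments,
       iterations = length(traces),
       fitness = dictionary_fitness(data, D, control))
}
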