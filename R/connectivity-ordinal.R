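#' Ordinal-pattern parameters
#'
#' @param n embedding dimension (default 4).
#' @param tau time delay in samples (default 1).
#' @return List with class `"OrdinalParams"`.
#' @export
ordinalParams <- function(n = 4L, tau = 1L) {
  n <- as.integer(n)
  tau <- as.integer(tau)
  if (n < 2L) stop("embedding dimension n must be >= 2")
  if (tau < 1L) stop("time delay tau must be >= 1")
  structure(list(n = n, tau = tau), class = "OrdinalParams")
}

# All permutations of 0:(n-1) in lexicographic order, as rows.
.permutations <- function(n) {
  if (n == 1L) return(matrix(0L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (first in 0L:(n - 1L)) {
    rest <- setdiff(0L:(n - 1L), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ] + 1L])
      row <- row + 1L
    }
  }
  out
}

# Cached per-n symbol tables: the pattern list (argsort permutations),
# the rank-code -> symbol-index lookup, the opposite-symbol index map and
# the volume-conduction admissibility mask.
.symbol_cache <- new.env(parent = emptyenv())

.symbolTables <- function(n) {
  key <- as.character(n)
  if (!is.null(.symbol_cache[[key]])) return(.symbol_cache[[key]])
  perms <- .permutations(n) # argsort patterns
  nf <- nrow(perms)
  pow <- n^(0:(n - 1L))
  # rank vector = inverse permutation of the argsort pattern
  lookup <- integer(n^n)
  for (s in seq_len(nf)) {
    r <- integer(n)
    r[perms[s, ] + 1L] <- 0:(n - 1L)
    lookup[sum(r * pow) + 1L] <- s
  }
  # opposite symbol: pattern of the sign-flipped window = reversed argsort
  opp <- integer(nf)
  for (s in seq_len(nf)) {
    rv <- rev(perms[s, ])
    opp[s] <- which(apply(perms, 1L, function(p) all(p == rv)))
  }
  mask <- matrix(TRUE, nf, nf) # admissible cells after correction
  for (s in seq_len(nf)) {
    mask[s, s] <- FALSE
    mask[s, opp[s]] <- FALSE
  }
  tabs <- list(perms = perms, lookup = lookup, opp = opp, mask = mask,
    pow = pow, nf = nf)
  .symbol_cache[[key]] <- tabs
  tabs
}

#' All ordinal patterns of a given embedding dimension
#'
#' @param n embedding dimension.
#' @return Integer matrix with `factorial(n)` rows; each row is an
#'   argsort pattern (positions of the window values in ascending order,
#'   0-based), in lexicographic order.
#' @export
symbolPatterns <- function(n = 4L) .symbolTables(as.integer(n))$perms

#' Convert a series to a sequence of ordinal symbols
#'
#' Window `t` covers `(x_t, x_(t+tau), ..., x_(t+(n-1)tau))` and maps to
#' the permutation that sorts it ascending; ties are broken by temporal
#' order (stable sort), with no noise injection, so symbolization is
#' deterministic and invariant under monotone increasing transforms.
#'
#' @param x numeric series of length at least `(n-1)*tau + 1`.
#' @param params an [ordinalParams()] object.
#' @return Integer vector of symbol indices (1-based rows of
#'   [symbolPatterns()]) of length `length(x) - (n-1)*tau`, with
#'   attributes `n` and `tau`; class `"SymbolSequence"`.
#' @examples
#' s <- symbolize(c(1, 3, 2, 5), ordinalParams(4, 1))
#' symbolPatterns(4)[s, ] # 0 2 1 3
#' @export
symbolize <- function(x, params = ordinalParams()) {
  n <- params$n
  tau <- params$tau
  L <- length(x) - (n - 1L) * tau
  if (L < 1L) {
    stop(
      "series too short to symbolize: need at least ",
      (n - 1L) * tau + 1L, " samples"
    )
  }
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite input samples")
  tabs <- .symbolTables(n)
  W <- vapply(0:(n - 1L), function(k) x[seq_len(L) + k * tau],
    numeric(L)
  )
  if (L == 1L) W <- matrix(W, nrow = 1L)
  R <- matrix(0L, L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      lt <- W[, j] < W[, i]
      if (j < i) lt <- lt | (W[, j] == W[, i])
      R[, i] <- R[, i] + lt
    }
  }
  code <- as.integer(R %*% tabs$pow)
  out <- tabs$lookup[code + 1L]
  attr(out, "n") <- n
  attr(out, "tau") <- tau
  class(out) <- "SymbolSequence"
  out
}

#' Opposite-sign ordinal symbol
#'
#' The ordinal pattern of the sign-flipped window: reversing the sort
#' order of an argsort pattern. An involution on tie-free patterns
#' (`oppositeSymbol(oppositeSymbol(p)) == p`).
#'
#' @param pattern integer vector, a permutation of `0:(n-1)` (an argsort
#'   pattern as returned by [symbolPatterns()]).
#' @return The opposite pattern, same form.
#' @examples
#' oppositeSymbol(c(0, 1, 2, 3)) # 3 2 1 0
#' oppositeSymbol(c(0, 2, 1, 3)) # 3 1 2 0
#' @export
oppositeSymbol <- function(pattern) {
  n <- length(pattern)
  if (!setequal(pattern, 0:(n - 1L))) {
    stop("not a valid ordinal pattern (must be a permutation of 0:(n-1))")
  }
  rev(pattern)
}

#' Joint symbol probability matrix of two series
#'
#' Tabulates the relative frequencies of time-aligned ordinal symbol
#' pairs; rows index the first series' symbol, columns the second's.
#' Entries sum to 1 (before any volume-conduction correction).
#'
#' @param x,y equal-length numeric series.
#' @param params an [ordinalParams()].
#' @return `factorial(n)` x `factorial(n)` numeric matrix.
#' @export
jointSymbolMatrix <- function(x, y, params = ordinalParams()) {
  if (length(x) != length(y)) stop("series must have equal length")
  sx <- symbolize(x, params)
  sy <- symbolize(y, params)
  nf <- .symbolTables(params$n)$nf
  counts <- tabulate((unclass(sx) - 1L) * nf + unclass(sy), nbins = nf * nf)
  matrix(counts / length(sx), nrow = nf, ncol = nf, byrow = TRUE)
}

# Core JPE_inv from pre-computed symbol index vectors.
.jpeFromSymbols <- function(sx, sy, tabs, correct) {
  nf <- tabs$nf
  counts <- tabulate((sx - 1L) * nf + sy, nbins = nf * nf)
  if (correct) {
    keep <- as.vector(t(tabs$mask)) # row-major cell order used above
    counts[!keep] <- 0L
    n_admissible <- sum(tabs$mask)
  } else {
    n_admissible <- nf * nf
  }
  total <- sum(counts)
  if (total == 0L) {
    warning("fully-leakage-degenerate pair: all joint mass removed by ",
      "the volume-conduction correction", call. = FALSE)
    return(0)
  }
  p <- counts[counts > 0L] / total
  H <- -sum(p * log2(p))
  1 - H / log2(n_admissible)
}

#' Inverted joint permutation entropy of two series
#'
#' Connectivity as the (inverted, normalized) Shannon entropy of the
#' joint distribution of time-aligned ordinal patterns of two series.
#' With `correct = TRUE`, cells whose symbol pair is identical or
#' opposite-sign are zero-weighted before the entropy is taken -- the
#' volume-conduction correction -- and the remaining mass is renormalized.
#' The entropy (base 2) is normalized by `log2` of the number of
#' admissible cells, and inverted (`1 - H/Hmax`) so that higher values
#' indicate stronger coupling; results lie in `[0, 1]`.
#'
#' @param x,y equal-length numeric series; neither may be constant.
#' @param params an [ordinalParams()].
#' @param correct apply the volume-conduction correction (default `TRUE`).
#' @return Scalar in `[0, 1]`. If the correction removes all joint mass
#'   (e.g. `y` is a positive multiple of `x`), returns 0 with a
#'   `"fully-leakage-degenerate"` warning.
#' @examples
#' set.seed(1)
#' x <- rnorm(1000)
#' jpeInv(x, rnorm(1000)) # near 0: independent
#' @export
jpeInv <- function(x, y, params = ordinalParams(), correct = TRUE) {
  if (length(x) != length(y)) stop("series must have equal length")
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("no ordinal variability: constant input series")
  }
  tabs <- .symbolTables(params$n)
  if (correct && sum(tabs$mask) < 2L) {
    stop("volume-conduction correction leaves no admissible cells for n = ",
      params$n)
  }
  sx <- unclass(symbolize(x, params))
  sy <- unclass(symbolize(y, params))
  .jpeFromSymbols(sx, sy, tabs, correct)
}
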