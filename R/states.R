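# State spaces of the splicing Markov chains.
#
# Simple (pairing-only) engine: a state is a set P of executed pairings
# (i, j), i <= j, whose intron intervals are pairwise disjoint; the state is
# absorbing when the intervals exactly tile {1..N}. Full engine: a state
# additionally carries availability flags a5/a3 per intron; flags of splice
# sites covered by an executed pairing (endpoints or interior) are frozen.
#
# Both enumerations are deterministic: root (no pairings, no flags) first,
# then ordered by the largest intron index any pairing touches and
# lexicographically on the state signature. For the simple engine this makes
# the states reachable while only introns 1..m are synthesized a prefix of
# the list, which is what lets the propagation grow the probability vector
# phase by phase.

# All sets of pairwise-disjoint intervals over introns 1..N, as k x 2
# matrices. Positions are scanned left to right; an interval always starts at
# the first uncovered position, which makes the enumeration exhaustive and
# duplicate-free.
enumerate_interval_sets <- function(N) {
  rec <- function(pos) {
    if (pos > N) return(list(matrix(integer(), 0L, 2L)))
    out <- rec(pos + 1L)                   # intron `pos` left uncovered
    for (j in pos:N)
      out <- c(out, lapply(rec(j + 1L), function(m)
        rbind(c(pos, j), m)))
    out
  }
  lapply(rec(1L), function(m) {
    m <- m[order(m[, 1L]), , drop = FALSE]
    storage.mode(m) <- "integer"
    m
  })
}

pairing_key <- function(P) {
  if (nrow(P) == 0L) return("root")
  paste(sprintf("(%d,%d)", P[, 1L], P[, 2L]), collapse = "")
}

# introns covered by any interval in P
covered_mask <- function(P, N) {
  cov <- logical(N)
  for (r in seq_len(nrow(P))) cov[P[r, 1L]:P[r, 2L]] <- TRUE
  cov
}

disjoint_from <- function(P, i, j) {
  nrow(P) == 0L || all(P[, 2L] < i | P[, 1L] > j)
}

#' Enumerate the states of the pairing-only splicing chain
#'
#' A state is a set of executed, pairwise-disjoint pairings over the `N`
#' introns; the chain is a directed acyclic graph rooted at the unspliced
#' transcript, and its absorbing states (the fully spliced isoform patterns,
#' one composition of `N` each) number `2^(N-1)`.
#'
#' @param N number of introns (1 to 9; larger genes are outside the validated
#'   scale of this engine).
#' @return An object of class `"state_space"` with elements `model`, `N`,
#'   `n`, `key`, `maxj` (largest intron index any pairing touches; 0 for the
#'   root), `absorbing`, `states` (list of pairing matrices) and `edges`
#'   (transition template: `from`, `to`, `i`, `j`).
#' @examples
#' enumerate_simple_states(2)$key
#' @export
enumerate_simple_states <- function(N) {
  N <- as.integer(N)[1L]
  if (is.na(N) || N < 1L) stop("N must be >= 1", call. = FALSE)
  if (N > 9L)
    stop("the pairing-only engine is limited to 9 introns (", N,
         " requested)", call. = FALSE)
  cached <- state_cache_get("simple", N)
  if (!is.null(cached)) return(cached)
  states <- enumerate_interval_sets(N)
  key <- vapply(states, pairing_key, character(1L))
  maxj <- vapply(states, function(P)
    if (nrow(P)) max(P[, 2L]) else 0L, integer(1L))
  ord <- order(maxj, key)
  states <- states[ord]; key <- key[ord]; maxj <- maxj[ord]
  absorbing <- vapply(states, function(P)
    sum(P[, 2L] - P[, 1L] + 1L) == N, logical(1L))
  lookup <- seq_along(key); names(lookup) <- key
  ef <- et <- ei <- ej <- integer()
  for (s in seq_along(states)) {
    P <- states[[s]]
    for (i in 1:N) for (j in i:N) {
      if (!disjoint_from(P, i, j)) next
      P2 <- rbind(P, c(i, j))
      P2 <- P2[order(P2[, 1L]), , drop = FALSE]
      to <- lookup[[pairing_key(P2)]]
      ef <- c(ef, s); et <- c(et, to); ei <- c(ei, i); ej <- c(ej, j)
    }
  }
  space <- structure(
    list(model = "simple", N = N, n = length(states), key = key,
         maxj = maxj, absorbing = absorbing, states = states,
         edges = data.frame(from = ef, to = et, i = ei, j = ej)),
    class = "state_space")
  state_cache_set("simple", N, space)
  space
}

#' Enumerate the states of the full splicing chain
#'
#' A full-model state records, per intron, whether the 5' and 3' splice sites
#' have undergone their availability reaction, plus the set of executed
#' pairings. Pairing `(i, j)` requires both end sites to be available;
#' availability flags of sites covered by an executed pairing are frozen. For
#' an isoform that skips `n` exons the two unused splice sites flanking each
#' skipped exon may each be in either availability state, so that isoform
#' comprises `4^n` absorbing microstates.
#'
#' @param N number of introns (1 to 3; six splice sites is the tractability
#'   bound of this engine — use the pairing-only engine for larger genes).
#' @return An object of class `"state_space"`; `states` holds lists with
#'   `a5`, `a3` (logical per intron) and `P` (pairing matrix). `edges` has
#'   `type` (`"a5"`, `"a3"` or `"pair"`), `site` (for availability edges) and
#'   `i`, `j` (for pairing edges).
#' @examples
#' enumerate_full_states(1)$n   # 5 states, 1 absorbing
#' @export
enumerate_full_states <- function(N) {
  N <- as.integer(N)[1L]
  if (is.na(N) || N < 1L) stop("N must be >= 1", call. = FALSE)
  if (N > 3L)
    stop("the full engine is limited to 3 introns (6 splice sites); ",
         "use the pairing-only engine (model = \"simple\") for larger genes",
         call. = FALSE)
  cached <- state_cache_get("full", N)
  if (!is.null(cached)) return(cached)
  psets <- enumerate_interval_sets(N)
  states <- list()
  for (P in psets) {
    forced5 <- forced3 <- rep(NA, N)       # NA = free flag
    if (nrow(P)) {
      for (r in seq_len(nrow(P))) {
        forced5[P[r, 1L]] <- TRUE          # used 5' endpoint
        forced3[P[r, 2L]] <- TRUE          # used 3' endpoint
      }
    }
    free <- c(which(is.na(forced5)), which(is.na(forced3)))
    nfree <- length(free)
    combos <- if (nfree) expand.grid(rep(list(c(FALSE, TRUE)), nfree),
                                     KEEP.OUT.ATTRS = FALSE) else
      data.frame(row.names = 1L)
    for (r in seq_len(max(1L, nrow(combos)))) {
      a5 <- ifelse(is.na(forced5), FALSE, forced5)
      a3 <- ifelse(is.na(forced3), FALSE, forced3)
      if (nfree) {
        vals <- as.logical(combos[r, ])
        n5free <- sum(is.na(forced5))
        if (n5free) a5[is.na(forced5)] <- vals[seq_len(n5free)]
        if (nfree > n5free) a3[is.na(forced3)] <- vals[-seq_len(n5free)]
      }
      states[[length(states) + 1L]] <- list(a5 = a5, a3 = a3, P = P)
    }
  }
  key <- vapply(states, full_state_key, character(1L))
  maxj <- vapply(states, function(s)
    if (nrow(s$P)) max(s$P[, 2L]) else 0L, integer(1L))
  npair <- vapply(states, function(s) nrow(s$P), integer(1L))
  nflag <- vapply(states, function(s) sum(s$a5, s$a3), integer(1L))
  ord <- order(npair, nflag, key)          # root (no flags, no pairings) first
  states <- states[ord]; key <- key[ord]; maxj <- maxj[ord]
  absorbing <- vapply(states, function(s)
    nrow(s$P) > 0L && sum(s$P[, 2L] - s$P[, 1L] + 1L) == N, logical(1L))
  lookup <- seq_along(key); names(lookup) <- key
  ef <- et <- esite <- ei <- ej <- integer(); etype <- character()
  for (s in seq_along(states)) {
    st <- states[[s]]
    frozen <- covered_mask(st$P, N)        # both sites of covered introns
    for (site in 1:N) {                    # availability transitions
      if (!frozen[site] && !st$a5[site]) {
        to <- lookup[[full_state_key(modifyList(st, list(
          a5 = replace(st$a5, site, TRUE))))]]
        ef <- c(ef, s); et <- c(et, to); etype <- c(etype, "a5")
        esite <- c(esite, site); ei <- c(ei, NA_integer_); ej <- c(ej, NA_integer_)
      }
      if (!frozen[site] && !st$a3[site]) {
        to <- lookup[[full_state_key(modifyList(st, list(
          a3 = replace(st$a3, site, TRUE))))]]
        ef <- c(ef, s); et <- c(et, to); etype <- c(etype, "a3")
        esite <- c(esite, site); ei <- c(ei, NA_integer_); ej <- c(ej, NA_integer_)
      }
    }
    for (i in 1:N) for (j in i:N) {        # pairing transitions
      if (!st$a5[i] || !st$a3[j] || !disjoint_from(st$P, i, j)) next
      P2 <- rbind(st$P, c(i, j))
      P2 <- P2[order(P2[, 1L]), , drop = FALSE]
      to <- lookup[[full_state_key(list(a5 = st$a5, a3 = st$a3, P = P2))]]
      ef <- c(ef, s); et <- c(et, to); etype <- c(etype, "pair")
      esite <- c(esite, NA_integer_); ei <- c(ei, i); ej <- c(ej, j)
    }
  }
  space <- structure(
    list(model = "full", N = N, n = length(states), key = key,
         maxj = maxj, absorbing = absorbing, states = states,
         edges = data.frame(from = ef, to = et, type = etype,
                            site = esite, i = ei, j = ej)),
    class = "state_space")
  state_cache_set("full", N, space)
  space
}

full_state_key <- function(s) {
  paste0("5[", paste(as.integer(s$a5), collapse = ""), "]3[",
         paste(as.integer(s$a3), collapse = ""), "]", pairing_key(s$P))
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space (", x$model, " model): N = ", x$N, " introns, ", x$n,
      " states (", sum(x$absorbing), " absorbing), ",
      nrow(x$edges), " transitions\n", sep = "")
  invisible(x)
}

.state_cache <- new.env(parent = emptyenv())
state_cache_get <- function(model, N)
  get0(paste(model, N, sep = "."), envir = .state_cache)
state_cache_set <- function(model, N, space)
  assign(paste(model, N, sep = "."), space, envir = .state_cache)

# Per-edge base rates for a gene/rates/config combination. For full-model
# availability edges the 3' rate is state-dependent under exon definition.
edge_rates <- function(space, gene, rates, config) {
  e <- space$edges
  r <- numeric(nrow(e))
  if (space$model == "simple") {
    for (k in seq_len(nrow(e)))
      r[k] <- pairing_rate(e$i[k], e$j[k], gene, rates, config)
  } else {
    for (k in seq_len(nrow(e))) {
      r[k] <- switch(e$type[k],
        a5 = rates$k5[e$site[k]],
        a3 = effective_k3(e$site[k], space$states[[e$from[k]]]$a5,
                          rates, config),
        pair = pairing_rate(e$i[k], e$j[k], gene, rates, config))
    }
  }
  r
}

# Logical mask of edges enabled when n5 / n3 introns have their 5' / 3'
# splice sites synthesized. A pairing (i, j) needs the 3' site of intron j
# (its 5' partner lies upstream and exists already); an availability reaction
# needs its own site.
edge_enabled <- function(space, n5, n3) {
  e <- space$edges
  if (space$model == "simple") return(e$j <= n3)
  ifelse(e$type == "a5", e$site <= n5,
         ifelse(e$type == "a3", e$site <= n3, e$j <= n3))
}

#' Build the infinitesimal generator for one transcriptional phase
#'
#' Assembles the dense generator matrix `G` over (a leading block of) the
#' enumerated state space: `G[x, y]` is the rate of the single reaction
#' turning state `x` into state `y` and is nonzero only for reactions whose
#' splice sites have been synthesized; diagonal entries make every row sum to
#' zero, so `beta %*% expm(G T)` conserves probability. (In the propagator
#' notation `beta e^{-Q t}` used with transition matrix conventions,
#' `Q = -G`.)
#'
#' @param space a state space from [enumerate_simple_states()] or
#'   [enumerate_full_states()].
#' @param gene a [gene_structure()].
#' @param rates a [splice_rates()]; pass the result of pause overrides
#'   already applied if the phase has any.
#' @param config a [definition_config()].
#' @param n5,n3 number of introns whose 5' / 3' splice sites have been
#'   synthesized in this phase.
#' @param block number of leading states to include (defaults to the whole
#'   space).
#' @return A dense base `matrix` of dimension `block x block`.
#' @export
build_generator <- function(space, gene, rates,
                            config = definition_config(),
                            n5 = space$N, n3 = space$N, block = space$n) {
  rate <- edge_rates(space, gene, rates, config)
  on <- edge_enabled(space, n5, n3)
  e <- space$edges
  keep <- on & e$from <= block & e$to <= block & rate > 0
  G <- matrix(0, block, block)
  if (any(keep)) {
    from <- e$from[keep]; to <- e$to[keep]; rk <- rate[keep]
    for (k in seq_along(from))
      G[from[k], to[k]] <- G[from[k], to[k]] + rk[k]
    diag(G) <- diag(G) - rowSums(G)
  }
  G
}
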