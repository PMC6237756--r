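# Collapse absorbing microstates into fully spliced isoforms and compute
# inclusion / fidelity metrics. An isoform is the set of included internal
# exons, serialized as an inclusion bitstring over internal exons 5' to 3'
# ("1" = included), e.g. "10" for a 3-intron gene that skipped the last
# internal exon. A gene with N introns has 2^(N-1) isoforms; for N = 1 the
# single isoform has the empty bitstring.

# all inclusion bitstrings, ordered so that 1 + strtoi(label, 2) indexes them
isoform_labels <- function(N) {
  if (N == 1L) return("")
  k <- 0:(2L^(N - 1L) - 1L)
  vapply(k, function(x)
    paste(rev(as.integer(intToBits(x))[seq_len(N - 1L)]), collapse = ""),
    character(1L))
}

# inclusion bitstring of an absorbing state's pairing set: internal exon e
# (gene numbering 2..N) is skipped iff some pairing (i, j) has i < e <= j
pairing_isoform <- function(P, N) {
  if (N == 1L) return("")
  inc <- rep(1L, N - 1L)
  for (r in seq_len(nrow(P))) {
    i <- P[r, 1L]; j <- P[r, 2L]
    if (j > i) inc[i:(j - 1L)] <- 0L       # bit positions of exons i+1 .. j
  }
  paste(inc, collapse = "")
}

#' Collapse a state-probability vector into an isoform distribution
#'
#' Sums the probability of each isoform's absorbing microstates (all
#' microstates of one isoform share the same pairing pattern up to the frozen
#' availability flags of unused splice sites). The input must already be
#' absorbed: residual transient mass above `1e-6` is an error.
#'
#' @param theta probability vector over `space`'s states (mass on absorbing
#'   states only), e.g. the output of [absorb()].
#' @param space the matching state space.
#' @param gene_id label attached to the result.
#' @return An object of class `"isoform_distribution"`: a data frame with
#'   columns `isoform` (inclusion bitstring), `n_skipped` and `probability`,
#'   one row per possible isoform (`2^(N-1)` rows), ordered by number of
#'   exons skipped then bitstring.
#' @export
collapse_isoforms <- function(theta, space, gene_id = "gene") {
  stopifnot(inherits(space, "state_space"), length(theta) == space$n)
  resid <- sum(theta[!space$absorbing])
  if (resid > 1e-6)
    stop("collapse_isoforms: residual transient mass ", format(resid),
         "; absorb() the vector first", call. = FALSE)
  N <- space$N
  labels <- isoform_labels(N)
  prob <- numeric(length(labels))
  for (s in which(space$absorbing & theta > 0)) {
    P <- if (space$model == "simple") space$states[[s]] else
      space$states[[s]]$P
    lab <- pairing_isoform(P, N)
    prob[match(lab, labels)] <- prob[match(lab, labels)] + theta[s]
  }
  n_skipped <- if (N == 1L) 0L else
    (N - 1L) - vapply(strsplit(labels, ""), function(b)
      sum(b == "1"), numeric(1L))
  out <- data.frame(isoform = labels, n_skipped = as.integer(n_skipped),
                    probability = prob, stringsAsFactors = FALSE)
  out <- out[order(out$n_skipped, out$isoform), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("isoform_distribution", "data.frame"),
            gene_id = gene_id, N = N)
}

#' Probability that an internal exon is included
#'
#' @param x an [isoform_distribution][collapse_isoforms()] or a fitted
#'   [ctsplice()] object.
#' @param exon internal exon in gene numbering (`2..N` for a gene with `N`
#'   introns).
#' @param ... unused.
#' @return Inclusion probability; `1 - inclusion` is the skipping
#'   probability of that cassette exon.
#' @export
inclusion <- function(x, exon, ...) UseMethod("inclusion")

#' @export
inclusion.isoform_distribution <- function(x, exon, ...) {
  N <- attr(x, "N")
  exon <- as.integer(exon)[1L]
  if (is.na(exon) || exon < 2L || exon > N)
    stop("exon must be an internal exon (2..", N, ")", call. = FALSE)
  bit <- exon - 1L                         # position in the bitstring
  included <- substr(x$isoform, bit, bit) == "1"
  sum(x$probability[included])
}

#' Distribution of the number of exons skipped
#'
#' Groups the isoform distribution by the number of internal exons skipped
#' (0 to `N - 1`). Bin 0 is the probability of the perfect-fidelity isoform
#' that includes every internal exon.
#'
#' @param x an [isoform_distribution][collapse_isoforms()] or a fitted
#'   [ctsplice()] object.
#' @param ... unused.
#' @return A data frame with columns `n_skipped` and `probability`, one row
#'   per bin `0..N-1`.
#' @export
skipped_histogram <- function(x, ...) UseMethod("skipped_histogram")

#' @export
skipped_histogram.isoform_distribution <- function(x, ...) {
  N <- attr(x, "N")
  bins <- 0:max(N - 1L, 0L)
  p <- vapply(bins, function(b) sum(x$probability[x$n_skipped == b]),
              numeric(1L))
  data.frame(n_skipped = bins, probability = p)
}

#' @export
print.isoform_distribution <- function(x, digits = 6, ...) {
  cat("Isoform distribution for '", attr(x, "gene_id"), "' (",
      attr(x, "N"), " introns, ", nrow(x), " isoforms)\n", sep = "")
  df <- as.data.frame(x)
  df$probability <- round(df$probability, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
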