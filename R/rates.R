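#' Kinetic rate set for the splicing reactions
#'
#' For a gene with `N` introns the model has `2N` availability reactions (one
#' per 5' and one per 3' splice site, rates `k5` and `k3`, per minute) and
#' `N(N+1)/2` pairing reactions joining the 5' splice site of intron `i` to
#' the 3' splice site of intron `j >= i` (rates `kp[i, j]`, per minute;
#' `i == j` is constitutive, `i < j` skips the exons in between). `k3_fast` is
#' the stimulated 3' availability rate used by the exon-definition rule.
#'
#' Defaults: `kp0 = 1` per minute (the pairing rate consistent with the
#' fast/slow elongation skipping benchmarks, see the package vignette);
#' `k5 = 2`, `k3 = 1` per minute encode a 5' commitment step faster than the
#' rate-limiting 3' step.
#'
#' @param n_introns number of introns `N`.
#' @param k5,k3 per-intron availability rates (recycled to length `N`).
#' @param kp0 default pairing rate; fills every `kp[i, j]` not explicitly set.
#' @param kp optional pairing-rate overrides: a named numeric vector with
#'   names `"i-j"` (e.g. `c("1-2" = 0.5)`), or a full upper-triangular
#'   `N x N` matrix.
#' @param k3_fast stimulated 3' availability rate for exon definition.
#' @return An object of class `"splice_rates"`.
#' @examples
#' splice_rates(2)
#' splice_rates(2, kp = c("1-2" = 0))   # forbid the skipping reaction
#' @export
splice_rates <- function(n_introns, k5 = 2, k3 = 1, kp0 = 1, kp = NULL,
                         k3_fast = 4) {
  N <- as.integer(n_introns)[1L]
  if (is.na(N) || N < 1L) stop("n_introns must be >= 1", call. = FALSE)
  k5 <- rep_len(as.numeric(k5), N)
  k3 <- rep_len(as.numeric(k3), N)
  kp0 <- as.numeric(kp0)[1L]
  k3_fast <- as.numeric(k3_fast)[1L]
  kpm <- matrix(NA_real_, N, N)
  kpm[upper.tri(kpm, diag = TRUE)] <- kp0
  if (!is.null(kp)) {
    if (is.matrix(kp)) {
      stopifnot(dim(kp) == c(N, N))
      sel <- upper.tri(kpm, diag = TRUE) & !is.na(kp)
      kpm[sel] <- kp[sel]
    } else {
      if (is.null(names(kp)))
        stop("'kp' overrides must be named \"i-j\"", call. = FALSE)
      for (nm in names(kp)) {
        ij <- as.integer(strsplit(nm, "-", fixed = TRUE)[[1L]])
        if (length(ij) != 2L || anyNA(ij) || ij[1L] > ij[2L] ||
            ij[1L] < 1L || ij[2L] > N)
          stop("bad kp override name '", nm, "' (want \"i-j\", i <= j <= ",
               N, ")", call. = FALSE)
        kpm[ij[1L], ij[2L]] <- as.numeric(kp[[nm]])
      }
    }
  }
  vals <- c(k5, k3, kp0, k3_fast, kpm[upper.tri(kpm, diag = TRUE)])
  if (anyNA(vals) || any(vals < 0))
    stop("all rates must be >= 0", call. = FALSE)
  structure(list(N = N, k5 = k5, k3 = k3, kp0 = kp0, kp = kpm,
                 k3_fast = k3_fast),
            class = "splice_rates")
}

#' @export
print.splice_rates <- function(x, ...) {
  cat("Splice rates (per minute), N =", x$N, "introns\n")
  cat("  k5':", paste(signif(x$k5, 4), collapse = ", "), "\n")
  cat("  k3':", paste(signif(x$k3, 4), collapse = ", "),
      " (k3_fast =", signif(x$k3_fast, 4), ")\n")
  cat("  kp0:", signif(x$kp0, 4), "\n")
  ut <- which(upper.tri(x$kp, diag = TRUE), arr.ind = TRUE)
  off <- ut[x$kp[ut] != x$kp0, , drop = FALSE]
  if (nrow(off))
    cat("  kp overrides:",
        paste(sprintf("kp(%d,%d)=%g", off[, 1], off[, 2],
                      x$kp[off]), collapse = ", "), "\n")
  invisible(x)
}

#' Intron/exon definition configuration
#'
#' Intron definition models co-operativity between the splice sites of short
#' introns: pairing across a spliced segment of length `L` nt proceeds at
#' [intron_definition_rate()], flat at `kp0` up to 200 nt and decaying as the
#' square root of length beyond. Exon definition models co-operativity across
#' a short internal exon: the 3' availability reaction of the upstream intron
#' is stimulated (rate `k3_fast` instead of `k3`) once the 5' site on the far
#' side of the exon is already available; it requires the full engine.
#'
#' @param intron_definition logical; apply the length-dependent pairing rate.
#' @param exon_definition logical; apply the conditional 3' speed-up.
#' @param exon_def_exons internal exon numbers (gene numbering, so values in
#'   `2..N`) targeted by exon definition; validated against the gene at
#'   simulation time.
#' @param span_mode for skipping pairings (`i < j`) under intron definition,
#'   whether the penalized length spans the whole excised lariat
#'   (`"lariat"`: introns `i..j` plus the skipped internal exons, the
#'   default) or the intron lengths only (`"introns"`).
#' @return An object of class `"definition_config"`.
#' @export
definition_config <- function(intron_definition = FALSE,
                              exon_definition = FALSE,
                              exon_def_exons = integer(),
                              span_mode = c("lariat", "introns")) {
  structure(list(intron_definition = isTRUE(intron_definition),
                 exon_definition = isTRUE(exon_definition),
                 exon_def_exons = as.integer(exon_def_exons),
                 span_mode = match.arg(span_mode)),
            class = "definition_config")
}

validate_config <- function(config, gene) {
  N <- gene$n_introns
  if (config$exon_definition) {
    if (length(config$exon_def_exons) == 0L)
      stop("exon_definition is on but no target exons given", call. = FALSE)
    bad <- config$exon_def_exons < 2L | config$exon_def_exons > N
    if (any(bad))
      stop("exon-definition targets must be internal exons (2..", N,
           "): got ", paste(config$exon_def_exons[bad], collapse = ", "),
           call. = FALSE)
  }
  invisible(config)
}

#' Length-dependent pairing rate under intron definition
#'
#' `kp(L) = kp0 * (200 / max(L, 200))^(1/2)`: pairing across segments up to
#' 200 nt proceeds at the full rate `kp0`; beyond that the rate decays with
#' the square root of length, reflecting the looping propensity of structured
#' pre-mRNA.
#'
#' @param L spliced-segment length in nt (>= 1; vectorized).
#' @param kp0 default pairing rate, per minute.
#' @return Pairing rate(s) in per minute.
#' @examples
#' intron_definition_rate(c(50, 200, 800), 1)   # 1, 1, 0.5
#' @export
intron_definition_rate <- function(L, kp0) {
  L <- as.numeric(L)
  if (anyNA(L) || any(L <= 0))
    stop("segment length L must be positive", call. = FALSE)
  if (any(kp0 < 0)) stop("kp0 must be >= 0", call. = FALSE)
  kp0 * sqrt(200 / pmax(L, 200))
}

#' Pairing rate for joining intron i's 5' site to intron j's 3' site
#'
#' Without intron definition this is the configured `kp[i, j]`. With intron
#' definition the rate is [intron_definition_rate()] evaluated at the length
#' of the excised segment: intron lengths `i..j` plus (under the default
#' `"lariat"` span mode) the lengths of the skipped internal exons.
#'
#' @param i,j intron indices, `1 <= i <= j <= N`.
#' @param gene a [gene_structure()].
#' @param rates a [splice_rates()].
#' @param config a [definition_config()].
#' @return Rate in per minute.
#' @export
pairing_rate <- function(i, j, gene, rates, config = definition_config()) {
  if (j < i) stop("pairing_rate: need j >= i", call. = FALSE)
  if (i < 1L || j > gene$n_introns)
    stop("pairing_rate: intron index out of range", call. = FALSE)
  if (!config$intron_definition) return(rates$kp[i, j])
  L <- sum(gene$introns[i:j])
  if (j > i && config$span_mode == "lariat")
    L <- L + sum(gene$exons[(i + 1L):j])
  intron_definition_rate(L, rates$kp0)
}

#' State-dependent 3' availability rate (exon definition)
#'
#' Returns the stimulated rate `k3_fast` for the 3' splice site of intron `i`
#' when exon definition targets the downstream internal exon `i + 1` and the
#' 5' splice site of intron `i + 1` is already available in the current
#' state; otherwise the baseline `k3[i]`.
#'
#' @param i intron index.
#' @param a5 logical vector of 5' availability flags, one per intron.
#' @param rates a [splice_rates()].
#' @param config a [definition_config()].
#' @return Rate in per minute.
#' @export
effective_k3 <- function(i, a5, rates, config = definition_config()) {
  if (!config$exon_definition) return(rates$k3[i])
  if ((i + 1L) %in% config$exon_def_exons && isTRUE(a5[i + 1L]))
    rates$k3_fast else rates$k3[i]
}

# Apply pause-phase rate overrides. Recognized names: "k5", "k3" (all
# introns), "k5.i", "k3.i", "kp0", "k3_fast", "kp.i.j".
apply_rate_overrides <- function(rates, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(rates)
  r <- rates
  for (nm in names(overrides)) {
    val <- as.numeric(overrides[[nm]])
    if (is.na(val) || val < 0)
      stop("rate override '", nm, "' must be >= 0", call. = FALSE)
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    key <- parts[1L]
    if (key == "kp0") {                    # refresh kp entries still at default
      r$kp[!is.na(r$kp) & r$kp == r$kp0] <- val
      r$kp0 <- val
    }
    else if (key == "k3_fast") r$k3_fast <- val
    else if (key %in% c("k5", "k3") && length(parts) == 1L)
      r[[key]][] <- val
    else if (key %in% c("k5", "k3") && length(parts) == 2L) {
      i <- as.integer(parts[2L])
      if (is.na(i) || i < 1L || i > r$N)
        stop("bad rate override '", nm, "'", call. = FALSE)
      r[[key]][i] <- val
    } else if (key == "kp" && length(parts) == 3L) {
      i <- as.integer(parts[2L]); j <- as.integer(parts[3L])
      if (anyNA(c(i, j)) || i < 1L || j > r$N || i > j)
        stop("bad rate override '", nm, "'", call. = FALSE)
      r$kp[i, j] <- val
    } else stop("unknown rate override '", nm, "'", call. = FALSE)
  }
  r
}
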